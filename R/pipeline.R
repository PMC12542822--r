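# End-to-end orchestration with persisted intermediates and a
# machine-readable run manifest.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

.write_manifest <- function(manifest, out_dir) {
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

.validate_phospho_config <- function(config) {
  has_sim <- !is.null(config$sim)
  has_inputs <- !is.null(config$inputs)
  if (has_sim == has_inputs)
    .stop_config("sim/inputs",
                 "exactly one of a sim_config or input paths is required")
  if (has_sim && !inherits(config$sim, "sim_config"))
    .stop_config("sim", "must be a sim_config object")
  if (has_inputs) {
    need <- c("evidence", "protein_groups")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss))
      .stop_config("inputs", paste("missing path(s):",
                                   paste(miss, collapse = ", ")))
    if (is.null(config$design))
      .stop_config("design", "a channel design is required with input paths")
  }
  config$pep_max <- config$pep_max %||% 0.01
  config$alpha <- config$alpha %||% 0.05
  config$w <- config$w %||% 7L
  config$rank_max <- config$rank_max %||% 10L
  if (config$pep_max <= 0 || config$pep_max > 1)
    .stop_config("pep_max", "must lie in (0, 1]")
  if (config$alpha <= 0 || config$alpha > 1)
    .stop_config("alpha", "must lie in (0, 1]")
  config
}

#' Run the full TMT phosphoproteomics pipeline
#'
#' Executes the stages in order -- simulate (or read), confidence filter,
#' aggregate to sequence-PTM features, phospho/protein ratio
#' normalization, moderated differential testing, site localization,
#' motif matrices (foreground: significantly dephosphorylated peptides;
#' background: all dephosphorylated peptides), optional gene-set
#' over-representation and ward.D2 clustering of the significant,
#' row-scaled ratios -- persisting every intermediate TSV under `out_dir`
#' together with a JSON manifest of versions, seed, thresholds and
#' per-stage row counts. All randomness flows from the seed inside the
#' simulation config, so identical configs produce byte-identical
#' outputs.
#'
#' @param config A list with exactly one of `sim` (a [sim_config()]) or
#'   `inputs` (list of paths: `evidence`, `protein_groups`, optional
#'   `fasta`); `design` (required with `inputs`); thresholds `pep_max`
#'   (0.01), `alpha` (0.05), `w` (7), `rank_max` (10); optional
#'   `gene_sets` (named list or GMT path), `kinase_scores` (table or TSV
#'   path) and `kinases` (names to derive kinase-specific motifs for).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results (`results`,
#'   `ratio_matrix`, `sites`, `motif`, `enrichment`, `cluster`,
#'   `manifest`).
#' @export
run_phospho_pipeline <- function(config, out_dir) {
  config <- .validate_phospho_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "phosphodiff",
                   version = as.character(packageVersion("phosphodiff")),
                   pipeline = "phospho",
                   seed = if (!is.null(config$sim)) config$sim$seed else NA,
                   thresholds = list(pep_max = config$pep_max,
                                     alpha = config$alpha, w = config$w,
                                     rank_max = config$rank_max))

  dat <- .stage("input", {
    if (!is.null(config$sim)) {
      sim <- generate_phospho_dataset(config$sim)
      write_evidence(sim$psms, file.path(out_dir, "evidence.tsv"))
      write_protein_groups(sim$protein_groups,
                           file.path(out_dir, "protein_groups.tsv"))
      write_protein_fasta(sim$protein_seqs,
                          file.path(out_dir, "proteins.fasta"))
      .write_tsv(sim$truth, file.path(out_dir, "ground_truth.tsv"))
      sim
    } else {
      list(psms = read_evidence(config$inputs$evidence),
           protein_groups = read_protein_groups(config$inputs$protein_groups),
           protein_seqs = if (!is.null(config$inputs$fasta))
             read_protein_fasta(config$inputs$fasta) else NULL,
           design = config$design)
    }
  })
  design <- .validate_design(config$design %||% dat$design)

  fl <- .stage("filter", filter_psms(dat$psms, pep_max = config$pep_max))
  .write_tsv(fl$report, file.path(out_dir, "filter_report.tsv"))
  write_evidence(fl$psms, file.path(out_dir, "evidence_filtered.tsv"))
  pg <- .stage("filter", filter_protein_groups(dat$protein_groups))
  manifest$counts <- list(psms_input = fl$report$n_input,
                          psms_removed_decoy = fl$report$removed_decoy,
                          psms_removed_contaminant =
                            fl$report$removed_contaminant,
                          psms_removed_pep = fl$report$removed_pep,
                          psms_retained = fl$report$retained,
                          protein_groups = nrow(pg))

  features <- .stage("aggregate", aggregate_psms_to_features(fl$psms))
  .write_tsv(features, file.path(out_dir, "features.tsv"))
  manifest$counts$features <- nrow(features)

  rm_ <- .stage("normalize", compute_log_ratios(features, pg, design))
  write_ratio_matrix(rm_, file.path(out_dir, "ratio_matrix.tsv"))
  manifest$counts$features_matched <- nrow(rm_$ratios)
  manifest$match_rate <- rm_$match_rate

  res <- .stage("difftest", diff_test(rm_, alpha = config$alpha))
  .write_tsv(res, file.path(out_dir, "differential_results.tsv"))
  .write_tsv(attr(res, "volcano"), file.path(out_dir, "volcano.tsv"))
  prior <- attr(res, "prior")
  manifest$prior <- list(d0 = if (is.infinite(prior$d0)) "Inf" else prior$d0,
                         s0_sq = prior$s0_sq)
  manifest$counts$tested <- nrow(res)
  manifest$counts$skipped <- length(attr(res, "skipped"))
  manifest$counts$significant <- sum(res$significant)
  manifest$counts$significant_down <-
    sum(res$significant & res$direction == "down")
  manifest$counts$significant_up <-
    sum(res$significant & res$direction == "up")

  sites <- .stage("sites", aggregate_site_probabilities(fl$psms))
  write_sites(sites, file.path(out_dir, "sites.tsv"))
  manifest$counts$sites <- sum(!sites$unlocalizable)

  motif <- NULL
  if (!is.null(dat$protein_seqs)) {
    motif <- .stage("motifs", {
      feat_pep <- rm_$features$peptide_sequence[
        match(res$feature_id, rm_$features$feature_id)]
      bg_pep <- unique(feat_pep[res$log2fc < 0])
      fg_pep <- unique(feat_pep[res$significant & res$direction == "down"])
      manifest$counts$motif_foreground <- length(fg_pep)
      manifest$counts$motif_background <- length(bg_pep)
      if (length(fg_pep) >= 2L && length(bg_pep) >= 2L) {
        bg_w <- center_windows(
          sites[sites$peptide_sequence %in% bg_pep, , drop = FALSE],
          dat$protein_seqs, w = config$w)
        fg_w <- center_windows(
          sites[sites$peptide_sequence %in% fg_pep, , drop = FALSE],
          dat$protein_seqs, w = config$w)
        mm <- motif_information_content(fg_w, bg_w, pseudocount = 0.5)
        write_motif_matrix(mm, file.path(out_dir, "motif_matrix.tsv"))
        ks <- config$kinase_scores
        if (!is.null(ks)) {
          if (is.character(ks)) ks <- read_kinase_scores(ks)
          for (kin in config$kinases %||% unique(ks$kinase)) {
            sub <- select_kinase_subset(
              sites[sites$peptide_sequence %in% fg_pep, , drop = FALSE],
              ks, kin, rank_max = config$rank_max)
            if (nrow(sub) >= 2L) {
              kw <- center_windows(sub, dat$protein_seqs, w = config$w)
              write_motif_matrix(
                motif_information_content(kw, bg_w, pseudocount = 0.5),
                file.path(out_dir, sprintf("motif_matrix_%s.tsv", kin)))
            }
          }
        }
        mm
      } else NULL
    })
  }

  enrichment <- NULL
  if (!is.null(config$gene_sets)) {
    enrichment <- .stage("enrich", {
      gs <- config$gene_sets
      if (is.character(gs)) gs <- read_gmt(gs)
      universe <- unique(rm_$features$protein_group_id)
      coll <- gene_set_collection(gs, universe)
      query <- unique(rm_$features$protein_group_id[
        match(res$feature_id[res$significant], rm_$features$feature_id)])
      ora <- hypergeometric_ora(query, coll, alpha = config$alpha)
      .write_tsv(ora, file.path(out_dir, "enrichment.tsv"))
      manifest$counts$enriched_terms <- nrow(ora)
      ora
    })
  }

  cluster <- .stage("cluster", {
    sig <- res$feature_id[res$significant]
    sub <- rm_$ratios[rownames(rm_$ratios) %in% sig, , drop = FALSE]
    sub <- sub[rowSums(is.na(sub)) == 0L, , drop = FALSE]
    if (nrow(sub) >= 2L) {
      scaled <- scale_rows(sub)
      cl <- ward_d2_cluster(scaled, axis = "rows")
      write_cluster_result(cl, file.path(out_dir, "cluster_rows"))
      manifest$counts$clustered_features <- nrow(sub)
      cl
    } else NULL
  })

  manifest_path <- .write_manifest(manifest, out_dir)
  invisible(list(results = res, ratio_matrix = rm_, sites = sites,
                 motif = motif, enrichment = enrichment, cluster = cluster,
                 manifest = manifest, manifest_path = manifest_path,
                 out_dir = out_dir))
}

.validate_dia_config <- function(config) {
  has_sim <- !is.null(config$sim)
  has_inputs <- !is.null(config$inputs)
  if (has_sim == has_inputs)
    .stop_config("sim/inputs",
                 "exactly one of a sim_config or input paths is required")
  if (has_sim) {
    if (!inherits(config$sim, "sim_config"))
      .stop_config("sim", "must be a sim_config object")
    if (is.null(config$stages) || length(config$stages) == 0L)
      .stop_config("stages", "stage labels are required for simulation")
  } else {
    if (is.null(config$inputs$report) && is.null(config$inputs$matrix))
      .stop_config("inputs", "need a DIA report path or a matrix path")
    if (is.null(config$inputs$design))
      .stop_config("inputs", "a run-design path is required")
  }
  config$psm_q_max <- config$psm_q_max %||% 0.001
  config$pg_q_max <- config$pg_q_max %||% 0.05
  config$alpha <- config$alpha %||% 0.05
  config$lfc_min <- config$lfc_min %||% 0.5
  config$imputed_weight <- config$imputed_weight %||% 0.05
  config
}

#' Run the DIA time-course pipeline
#'
#' Simulates (or reads) a DIA protein quantity matrix, applies the
#' q-value filters when starting from a precursor report, builds the
#' log10 sample matrix with technical-replicate averaging, imputes
#' missing cells by the minimum replicate intensity with weight
#' `imputed_weight`, and tests treatment versus control per stage with
#' the weighted moderated engine, calling proteins at `p_adj <= alpha`
#' and `|log2fc| >= lfc_min`. All intermediates and a JSON manifest are
#' persisted under `out_dir`.
#'
#' @param config A list with exactly one of `sim` (a [sim_config()], plus
#'   `stages`, optional `n_bio`, `n_tech`) or `inputs` (paths: `report`
#'   or `matrix`, and `design`); thresholds `psm_q_max` (0.001),
#'   `pg_q_max` (0.05), `alpha` (0.05), `lfc_min` (0.5),
#'   `imputed_weight` (0.05); optional `contrast_stages`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with `matrix` (the imputed `dia_matrix`),
#'   `results` (named list of per-stage tables), `manifest`.
#' @export
run_dia_pipeline <- function(config, out_dir) {
  config <- .validate_dia_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "phosphodiff",
                   version = as.character(packageVersion("phosphodiff")),
                   pipeline = "dia",
                   seed = if (!is.null(config$sim)) config$sim$seed else NA,
                   thresholds = list(psm_q_max = config$psm_q_max,
                                     pg_q_max = config$pg_q_max,
                                     alpha = config$alpha,
                                     lfc_min = config$lfc_min,
                                     imputed_weight = config$imputed_weight))

  dat <- .stage("input", {
    if (!is.null(config$sim)) {
      sim <- generate_dia_timecourse(config$sim, config$stages,
                                     n_bio = config$n_bio %||% 2L,
                                     n_tech = config$n_tech %||% 3L)
      .write_tsv(data.frame(protein_id = rownames(sim$quant), sim$quant,
                            check.names = FALSE),
                 file.path(out_dir, "quantities.tsv"))
      .write_tsv(sim$design, file.path(out_dir, "run_design.tsv"))
      .write_tsv(sim$truth, file.path(out_dir, "ground_truth.tsv"))
      sim
    } else {
      design <- .validate_tc_design(.read_tsv(config$inputs$design))
      if (!is.null(config$inputs$report)) {
        rep_ <- read_dia_report(config$inputs$report)
        fl <- filter_dia(rep_, config$psm_q_max, config$pg_q_max)
        .write_tsv(fl$report, file.path(out_dir, "dia_filter_report.tsv"))
        manifest$counts <- list(report_rows = fl$report$n_input,
                                 report_retained = fl$report$retained)
        list(quant = fl$rows, design = design, truth = NULL)
      } else {
        qt <- .read_tsv(config$inputs$matrix)
        m <- as.matrix(qt[, -1, drop = FALSE])
        rownames(m) <- qt[[1]]
        list(quant = m, design = design, truth = NULL)
      }
    }
  })

  dm <- .stage("build", build_dia_matrix(dat$quant, dat$design,
                                         center = TRUE))
  write_dia_matrix(dm, file.path(out_dir, "log10_matrix.tsv"))
  write_dia_matrix(dm, file.path(out_dir, "centered_matrix.tsv"),
                   what = "centered")
  manifest$counts$proteins <- nrow(dm$log10)
  manifest$counts$samples <- ncol(dm$log10)

  dm <- .stage("impute", impute_and_weight(dm, config$imputed_weight))
  manifest$counts$imputed_cells <- sum(dm$imputed)
  manifest$counts$dropped_proteins <- length(attr(dm, "dropped"))

  stages <- config$contrast_stages %||% unique(dm$samples$stage)
  results <- list()
  for (st in stages) {
    res <- .stage(paste0("difftest_", st),
                  differential_dia(dm, st, alpha = config$alpha,
                                   lfc_min = config$lfc_min))
    .write_tsv(res, file.path(out_dir,
                              sprintf("dia_results_%s.tsv", st)))
    manifest$counts[[paste0("significant_", st)]] <- sum(res$significant)
    results[[st]] <- res
  }

  manifest_path <- .write_manifest(manifest, out_dir)
  invisible(list(matrix = dm, results = results, truth = dat$truth,
                 manifest = manifest, manifest_path = manifest_path,
                 out_dir = out_dir))
}
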