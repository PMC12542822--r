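#' Simulation configuration for synthetic phosphoproteomics data
#'
#' Bundles and validates every knob of the synthetic-data generators. The
#' defaults emulate a TMT 6-plex phospho experiment contrasting three
#' treated against three control channels, with a minority of truly
#' dephosphorylated features (negative log2 fold change), decoy and
#' contaminant contamination, Beta-distributed posterior error
#' probabilities, and Dirichlet site-localization vectors peaked at the
#' planted phosphosite.
#'
#' @param n_proteins Number of parent proteins.
#' @param peptides_per_protein Positive-integer distribution spec: a single
#'   integer, or `list(dist = "poisson", lambda = )` (shifted so counts are
#'   >= 1), or `list(dist = "uniform", min = , max = )`.
#' @param psms_per_peptide Distribution spec for PSM multiplicity per
#'   peptide, same forms as `peptides_per_protein`.
#' @param n_channels_per_condition Reporter channels per condition.
#' @param effect_fraction Proportion of features carrying a true effect.
#' @param effect_log2fc Planted log2 fold change (negative =
#'   dephosphorylation, the default direction).
#' @param reporter_noise_sd Log2-scale standard deviation of PSM reporter
#'   noise (log-normal multiplicative noise). Protein-group channel noise
#'   uses half this value, reflecting the averaging over many peptides that
#'   protein-level quantities enjoy.
#' @param pep_alpha_beta Length-2 Beta parameters for PSM posterior error
#'   probabilities; the default `c(0.5, 200)` leaves roughly 4.5% of PSMs
#'   above the conventional 0.01 confidence filter.
#' @param decoy_fraction,contaminant_fraction Fractions of PSM rows that
#'   are reverse-decoy / contaminant entries.
#' @param site_prob_concentration Dirichlet concentration placed on the true
#'   phosphosite relative to a unit concentration on every other S/T/Y
#'   position; larger values give cleaner localization.
#' @param missing_rate Per-cell missingness probability (reporter cells for
#'   the TMT generator; run cells for the DIA generator, where missingness
#'   is additionally enriched in low-abundance proteins).
#' @param seed Integer RNG seed; mandatory so every dataset is reproducible.
#' @return A validated `sim_config` object (a named list).
#' @seealso [generate_phospho_dataset()], [generate_dia_timecourse()]
#' @export
sim_config <- function(n_proteins = 200L,
                       peptides_per_protein = list(dist = "poisson", lambda = 1),
                       psms_per_peptide = list(dist = "poisson", lambda = 0.5),
                       n_channels_per_condition = 3L,
                       effect_fraction = 0.1,
                       effect_log2fc = -1,
                       reporter_noise_sd = 0.25,
                       pep_alpha_beta = c(0.5, 200),
                       decoy_fraction = 0.02,
                       contaminant_fraction = 0.02,
                       site_prob_concentration = 20,
                       missing_rate = 0,
                       seed) {
  if (missing(seed)) .stop_config("seed", "a seed is mandatory")
  cfg <- list(
    n_proteins = .check_count(n_proteins, "n_proteins"),
    peptides_per_protein = peptides_per_protein,
    psms_per_peptide = psms_per_peptide,
    n_channels_per_condition =
      .check_count(n_channels_per_condition, "n_channels_per_condition", 2L),
    effect_fraction = .check_prop(effect_fraction, "effect_fraction"),
    effect_log2fc = effect_log2fc,
    reporter_noise_sd = .check_pos(reporter_noise_sd, "reporter_noise_sd"),
    pep_alpha_beta = pep_alpha_beta,
    decoy_fraction = .check_prop(decoy_fraction, "decoy_fraction"),
    contaminant_fraction =
      .check_prop(contaminant_fraction, "contaminant_fraction"),
    site_prob_concentration =
      .check_pos(site_prob_concentration, "site_prob_concentration"),
    missing_rate = .check_prop(missing_rate, "missing_rate"),
    seed = .check_count(seed, "seed", min = 0L)
  )
  if (!is.numeric(cfg$effect_log2fc) || length(cfg$effect_log2fc) != 1L ||
      is.na(cfg$effect_log2fc))
    .stop_config("effect_log2fc", "must be a single real number")
  if (!is.numeric(pep_alpha_beta) || length(pep_alpha_beta) != 2L ||
      any(pep_alpha_beta <= 0))
    .stop_config("pep_alpha_beta", "must be two positive Beta parameters")
  class(cfg) <- "sim_config"
  cfg
}

# Random peptide sequences with a guaranteed S/T/Y at a chosen position.
.random_peptides <- function(n, min_len = 10L, max_len = 18L) {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  site_pos <- vapply(lens, function(L) sample.int(L, 1L), integer(1))
  site_res <- sample(c("S", "T", "Y"), n, replace = TRUE,
                     prob = c(0.6, 0.3, 0.1))
  seqs <- vapply(seq_len(n), function(i) {
    aa <- sample(.AA20, lens[i], replace = TRUE)
    aa[site_pos[i]] <- site_res[i]
    paste(aa, collapse = "")
  }, character(1))
  # regenerate the (vanishingly rare) duplicated draws
  while (anyDuplicated(seqs)) {
    idx <- which(duplicated(seqs))
    for (i in idx) {
      aa <- sample(.AA20, lens[i], replace = TRUE)
      aa[site_pos[i]] <- site_res[i]
      seqs[i] <- paste(aa, collapse = "")
    }
  }
  data.frame(peptide_sequence = seqs, site_pos = site_pos,
             site_res = site_res, length = lens, stringsAsFactors = FALSE)
}

.sty_positions <- function(seq) {
  which(strsplit(seq, "", fixed = TRUE)[[1]] %in% c("S", "T", "Y"))
}

# One Dirichlet draw over the peptide's S/T/Y positions, concentration
# `conc` on the true site and 1 elsewhere; rounded to 4 decimals.
.draw_site_probs <- function(sty, true_pos, conc) {
  alpha <- rep(1, length(sty))
  alpha[match(true_pos, sty)] <- conc
  g <- rgamma(length(sty), shape = alpha, rate = 1)
  p <- round(g / sum(g), 4)
  excess <- sum(p) - 1
  if (excess > 0) p[which.max(p)] <- p[which.max(p)] - excess
  names(p) <- as.character(sty)
  p
}

#' Generate a synthetic TMT phosphoproteomics dataset with ground truth
#'
#' Simulates parent proteins, phosphopeptides and peptide-spectrum matches
#' for a two-condition TMT experiment. Protein channel intensities are
#' log-normal around per-protein baselines; a planted minority of features
#' has its treated-channel reporter intensities shifted by
#' `2^effect_log2fc` relative to the parent protein, so the planted effect
#' is recoverable from phospho/protein log2 ratios. PSM site-probability
#' vectors are Dirichlet-distributed over the peptide's S/T/Y positions and
#' peaked at the true site. Decoy and contaminant PSM rows and
#' Beta-distributed posterior error probabilities exercise the confidence
#' filters downstream.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `psms` (evidence-style PSM table, one row
#'   per PSM, with a `site_probabilities` list column), `protein_groups`
#'   (protein-group table with reporter intensities), `truth` (one row per
#'   feature: `feature_id`, `peptide_sequence`, `parent_protein_id`,
#'   `true_effect`, `site_pos`, `site_res`, `protein_position`),
#'   `protein_seqs` (named character vector of parent protein sequences)
#'   and `design` (the [channel_design()] used).
#' @examples
#' sim <- generate_phospho_dataset(sim_config(n_proteins = 20, seed = 1))
#' head(sim$truth)
#' @export
generate_phospho_dataset <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("config must be a sim_config object", call. = FALSE)
  .with_seed(config$seed, .generate_phospho(config))
}

.generate_phospho <- function(cfg) {
  k <- cfg$n_channels_per_condition
  nchan <- 2L * k
  treated <- seq.int(k + 1L, nchan)
  npro <- cfg$n_proteins
  protein_id <- sprintf("PROT%05d", seq_len(npro))

  pro_base <- rnorm(npro, mean = 20, sd = 1.5)
  pro_log2 <- matrix(pro_base, npro, nchan) +
    matrix(rnorm(npro * nchan, 0, cfg$reporter_noise_sd / 2), npro, nchan)
  pro_int <- 2^pro_log2

  n_pep <- .draw_counts(cfg$peptides_per_protein, npro, "peptides_per_protein")
  P <- sum(n_pep)
  parent <- rep.int(seq_len(npro), n_pep)
  peps <- .random_peptides(P)
  mod_seq <- paste0(
    substr(peps$peptide_sequence, 1L, peps$site_pos), "(ph)",
    substring(peps$peptide_sequence, peps$site_pos + 1L)
  )

  # parent protein = 5-aa flank + its peptides concatenated + 5-aa flank
  flank_n <- vapply(seq_len(npro), function(i)
    paste(sample(.AA20, 5L, replace = TRUE), collapse = ""), character(1))
  flank_c <- vapply(seq_len(npro), function(i)
    paste(sample(.AA20, 5L, replace = TRUE), collapse = ""), character(1))
  pep_by_pro <- split(peps$peptide_sequence, parent)
  protein_seqs <- setNames(vapply(seq_len(npro), function(i)
    paste0(flank_n[i], paste(pep_by_pro[[as.character(i)]], collapse = ""),
           flank_c[i]), character(1)), protein_id)
  offsets <- unlist(lapply(seq_len(npro), function(i) {
    L <- peps$length[parent == i]
    5L + c(0L, cumsum(L)[-length(L)])
  }), use.names = FALSE)
  protein_position <- offsets + peps$site_pos

  n_eff <- round(cfg$effect_fraction * P)
  true_effect <- numeric(P)
  if (n_eff > 0)
    true_effect[sample.int(P, n_eff)] <- cfg$effect_log2fc

  truth <- data.frame(
    feature_id = mod_seq,
    peptide_sequence = peps$peptide_sequence,
    parent_protein_id = protein_id[parent],
    true_effect = true_effect,
    site_pos = peps$site_pos,
    site_res = peps$site_res,
    protein_position = protein_position,
    stringsAsFactors = FALSE
  )

  pep_base <- pro_base[parent] + rnorm(P, mean = -3, sd = 0.7)
  m <- .draw_counts(cfg$psms_per_peptide, P, "psms_per_peptide")
  M <- sum(m)
  pid <- rep.int(seq_len(P), m)

  shift <- matrix(0, M, nchan)
  shift[, treated] <- true_effect[pid]
  psm_log2 <- matrix(pep_base[pid] - log2(m[pid]), M, nchan) + shift +
    matrix(rnorm(M * nchan, 0, cfg$reporter_noise_sd), M, nchan)
  ri <- 2^psm_log2
  if (cfg$missing_rate > 0)
    ri[matrix(runif(M * nchan) < cfg$missing_rate, M, nchan)] <- NA_real_

  sty_list <- lapply(peps$peptide_sequence, .sty_positions)
  site_probs <- lapply(pid, function(j)
    .draw_site_probs(sty_list[[j]], peps$site_pos[j],
                     cfg$site_prob_concentration))

  target <- data.frame(
    peptide_sequence = peps$peptide_sequence[pid],
    modified_sequence = mod_seq[pid],
    protein_group_id = protein_id[parent[pid]],
    pep = round(rbeta(M, cfg$pep_alpha_beta[1], cfg$pep_alpha_beta[2]), 6),
    stringsAsFactors = FALSE
  )
  target$is_decoy <- FALSE
  target$is_contaminant <- FALSE

  # decoy / contaminant rows appended at the configured overall fractions
  denom <- 1 - cfg$decoy_fraction - cfg$contaminant_fraction
  n_dec <- round(cfg$decoy_fraction * M / denom)
  n_con <- round(cfg$contaminant_fraction * M / denom)
  junk <- function(n, prefix, decoy) {
    if (n == 0L) return(NULL)
    jp <- .random_peptides(n)
    jm <- paste0(substr(jp$peptide_sequence, 1L, jp$site_pos), "(ph)",
                 substring(jp$peptide_sequence, jp$site_pos + 1L))
    data.frame(
      peptide_sequence = jp$peptide_sequence,
      modified_sequence = jm,
      protein_group_id = sprintf("%s%04d", prefix, seq_len(n)),
      pep = round(rbeta(n, 2, if (decoy) 5 else 50), 6),
      is_decoy = decoy,
      is_contaminant = !decoy,
      stringsAsFactors = FALSE
    )
  }
  dec <- junk(n_dec, "REV__PROT", TRUE)
  con <- junk(n_con, "CON__PROT", FALSE)

  psms <- rbind(target, dec, con)
  extra <- nrow(psms) - M
  if (extra > 0) {
    ri <- rbind(ri, 2^matrix(rnorm(extra * nchan, 15, 1), extra, nchan))
    jp_seq <- psms$peptide_sequence[(M + 1L):nrow(psms)]
    site_probs <- c(site_probs, lapply(jp_seq, function(s) {
      sty <- .sty_positions(s)
      .draw_site_probs(sty, sty[1L], 5)
    }))
  }
  colnames(ri) <- paste0("ri_", seq_len(nchan))
  psms <- cbind(psm_id = sprintf("PSM%06d", seq_len(nrow(psms))), psms,
                as.data.frame(ri))
  psms$site_probabilities <- site_probs
  rownames(psms) <- NULL

  pg <- data.frame(group_id = protein_id,
                   accessions = protein_id,
                   gene_symbol = sprintf("gene%05d", seq_len(npro)),
                   stringsAsFactors = FALSE)
  pro_mat <- round(pro_int, 4)
  colnames(pro_mat) <- paste0("ri_", seq_len(nchan))
  pg <- cbind(pg, as.data.frame(pro_mat))
  pg$is_decoy <- FALSE
  pg$is_contaminant <- FALSE

  list(
    psms = psms,
    protein_groups = pg,
    truth = truth,
    protein_seqs = protein_seqs,
    design = channel_design(k)
  )
}

#' Generate a synthetic DIA time-course protein matrix with ground truth
#'
#' Simulates a label-free DIA experiment across meiotic stages in two
#' conditions. Most proteins are flat across stages; a planted minority
#' (`effect_fraction`) acquires a treatment-versus-control shift of
#' `effect_log2fc` (log2) at one designated stage, recorded in the ground
#' truth. Technical-replicate noise uses `reporter_noise_sd` (log2 scale)
#' and a between-biological-replicate variance knob is exposed as
#' `bio_sd`. Missing values are injected at `missing_rate`, enriched in
#' low-abundance proteins as in real DIA data.
#'
#' @param config A [sim_config()] object (fields `n_proteins`,
#'   `effect_fraction`, `effect_log2fc`, `reporter_noise_sd`,
#'   `missing_rate`, `seed` are used).
#' @param stages Non-empty character vector of ordered stage labels.
#' @param n_bio Biological replicates per condition (default 2).
#' @param n_tech Technical replicates per biological sample (default 3).
#' @param bio_sd Between-biological-replicate standard deviation on the
#'   log2 scale (default 0.15).
#' @return A list with `quant` (proteins x runs matrix of raw quantities,
#'   `NA` for missing), `design` (run-design table: `run`, `condition`,
#'   `stage`, `bio_rep`, `tech_rep`) and `truth` (`protein_id`,
#'   `true_effect`, `stage`; `true_effect` 0 for null proteins).
#' @examples
#' sim <- generate_dia_timecourse(sim_config(n_proteins = 50, seed = 1),
#'                                stages = c("GV", "MI", "MII"))
#' dim(sim$quant)
#' @export
generate_dia_timecourse <- function(config, stages, n_bio = 2L, n_tech = 3L,
                                    bio_sd = 0.15) {
  if (!inherits(config, "sim_config"))
    stop("config must be a sim_config object", call. = FALSE)
  if (length(stages) == 0L)
    .stop_config("stages", "stage list must be non-empty")
  n_bio <- .check_count(n_bio, "n_bio")
  n_tech <- .check_count(n_tech, "n_tech")
  .with_seed(config$seed,
             .generate_dia(config, as.character(stages), n_bio, n_tech, bio_sd))
}

.generate_dia <- function(cfg, stages, n_bio, n_tech, bio_sd) {
  conditions <- c("control", "treatment")
  design <- expand.grid(tech_rep = seq_len(n_tech), bio_rep = seq_len(n_bio),
                        condition = conditions, stage = stages,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("stage", "condition", "bio_rep", "tech_rep")]
  design$run <- sprintf("%s_%s_b%d_t%d", design$stage, design$condition,
                        design$bio_rep, design$tech_rep)
  design <- design[, c("run", "condition", "stage", "bio_rep", "tech_rep")]

  npro <- cfg$n_proteins
  protein_id <- sprintf("PROT%05d", seq_len(npro))
  base10 <- rnorm(npro, mean = 6, sd = 0.8)

  n_eff <- round(cfg$effect_fraction * npro)
  true_effect <- numeric(npro)
  eff_stage <- rep(NA_character_, npro)
  if (n_eff > 0) {
    hit <- sample.int(npro, n_eff)
    true_effect[hit] <- cfg$effect_log2fc
    eff_stage[hit] <- rep_len(stages, n_eff)
  }

  l10 <- log10(2)
  nrun <- nrow(design)
  # animal (biological) effects per protein x condition x bio replicate
  bio_eff <- array(rnorm(npro * 2L * n_bio, 0, bio_sd * l10),
                   dim = c(npro, 2L, n_bio))
  cond_idx <- match(design$condition, conditions)

  vals <- matrix(base10, npro, nrun)
  for (r in seq_len(nrun)) {
    vals[, r] <- vals[, r] + bio_eff[cbind(seq_len(npro), cond_idx[r],
                                           design$bio_rep[r])]
    if (design$condition[r] == "treatment") {
      on <- !is.na(eff_stage) & eff_stage == design$stage[r]
      vals[on, r] <- vals[on, r] + true_effect[on] * l10
    }
  }
  vals <- vals + matrix(rnorm(npro * nrun, 0, cfg$reporter_noise_sd * l10),
                        npro, nrun)
  quant <- 10^vals

  if (cfg$missing_rate > 0) {
    # missingness enriched in low-abundance proteins, mean rate preserved
    r <- (rank(base10) - 0.5) / npro
    p_mis <- pmin(cfg$missing_rate * 2 * (1 - r), 0.95)
    miss <- matrix(runif(npro * nrun), npro, nrun) < p_mis
    quant[miss] <- NA_real_
  }
  dimnames(quant) <- list(protein_id, design$run)

  truth <- data.frame(protein_id = protein_id, true_effect = true_effect,
                      stage = eff_stage, stringsAsFactors = FALSE)
  list(quant = quant, design = design, truth = truth)
}
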