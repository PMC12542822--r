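# DIA time-course branch: report filtering, matrix building, conservative
# imputation with down-weighting, and weighted differential testing.

#' Read / write a DIA report table
#'
#' The DIA report dialect carries one row per precursor and run: `run`,
#' `protein_group`, `precursor`, the precursor-level `q_value`, the
#' protein-group `pg_q_value` and the `quantity`.
#'
#' @param path TSV path.
#' @return `read_dia_report()`: the report `data.frame`.
#' @export
read_dia_report <- function(path) {
  df <- .read_tsv(path)
  need <- c("run", "protein_group", "precursor", "q_value", "pg_q_value",
            "quantity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("DIA report is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_dia_report
#' @param rows DIA report `data.frame`.
#' @export
write_dia_report <- function(rows, path) {
  .write_tsv(rows, path)
}

#' Filter a DIA report on precursor and protein-group q-values
#'
#' Keeps rows with `q_value <= psm_q_max` and `pg_q_value <= pg_q_max`
#' (both boundaries inclusive).
#'
#' @param rows DIA report `data.frame` (see [read_dia_report()]).
#' @param psm_q_max Precursor-level q-value threshold (default 0.001).
#' @param pg_q_max Protein-group q-value threshold (default 0.05).
#' @return A list with `rows` (retained) and a one-row `report`
#'   (`n_input`, `removed`, `retained`).
#' @export
filter_dia <- function(rows, psm_q_max = 0.001, pg_q_max = 0.05) {
  for (th in c(psm_q_max, pg_q_max))
    if (!is.numeric(th) || th <= 0 || th > 1)
      stop("q-value thresholds must lie in (0, 1]", call. = FALSE)
  keep <- rows$q_value <= psm_q_max & rows$pg_q_value <= pg_q_max
  list(rows = rows[keep, , drop = FALSE],
       report = data.frame(n_input = nrow(rows),
                           removed = sum(!keep), retained = sum(keep)))
}

#' Time-course run design
#'
#' @param run,condition,stage,bio_rep,tech_rep Vectors of equal length
#'   describing each run.
#' @return A validated design `data.frame`.
#' @export
time_course_design <- function(run, condition, stage, bio_rep, tech_rep) {
  d <- data.frame(run = as.character(run), condition = as.character(condition),
                  stage = as.character(stage), bio_rep = as.integer(bio_rep),
                  tech_rep = as.integer(tech_rep), stringsAsFactors = FALSE)
  .validate_tc_design(d)
}

.validate_tc_design <- function(d) {
  need <- c("run", "condition", "stage", "bio_rep", "tech_rep")
  if (!all(need %in% names(d)))
    stop("time-course design needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(d$run)) stop("duplicated run ids in design",
                                 call. = FALSE)
  d
}

#' Build a log10 protein quantity matrix for the time course
#'
#' Accepts either a filtered DIA report (precursor rows, summed to
#' protein x run) or a pre-aggregated protein quantity matrix (proteins x
#' runs; protein-level aggregation such as MaxLFQ is upstream and its
#' output is taken as given). Quantities are log10-transformed and
#' technical replicates are averaged within each (condition, stage,
#' biological replicate) so the model's units are biological samples.
#'
#' @param x DIA report `data.frame` or numeric matrix (proteins x runs).
#' @param design Time-course design (see [time_course_design()]).
#' @param center Also return a per-protein mean-centered copy of the
#'   sample matrix (for heatmap export).
#' @return A `dia_matrix` object: list with `log10` (proteins x samples),
#'   `samples` (per-column `condition`, `stage`, `bio_rep`), `weights`
#'   and `imputed` (filled by [impute_and_weight()], `NULL` here),
#'   `centered` (when requested) and `design`.
#' @export
build_dia_matrix <- function(x, design, center = FALSE) {
  design <- .validate_tc_design(design)
  if (is.data.frame(x)) {
    runs <- unique(x$run)
    unknown <- setdiff(runs, design$run)
    if (length(unknown))
      stop("run(s) absent from design: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    quant <- tapply(x$quantity, list(x$protein_group, x$run),
                    sum, na.rm = TRUE)
    quant <- quant[, intersect(design$run, colnames(quant)), drop = FALSE]
  } else {
    quant <- as.matrix(x)
    unknown <- setdiff(colnames(quant), design$run)
    if (length(unknown))
      stop("run(s) absent from design: ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  lg <- log10(quant)
  lg[!is.finite(lg)] <- NA_real_

  di <- design[match(colnames(lg), design$run), , drop = FALSE]
  sample_id <- sprintf("%s_%s_b%d", di$stage, di$condition, di$bio_rep)
  groups <- split(seq_len(ncol(lg)), sample_id)
  groups <- groups[order(vapply(groups, `[`, integer(1), 1L))]
  avg <- vapply(groups, function(j) {
    sub <- lg[, j, drop = FALSE]
    out <- rowMeans(sub, na.rm = TRUE)
    out[rowSums(!is.na(sub)) == 0L] <- NA_real_
    out
  }, numeric(nrow(lg)))
  if (!is.matrix(avg))
    avg <- matrix(avg, nrow = nrow(lg),
                  dimnames = list(rownames(lg), names(groups)))
  rownames(avg) <- rownames(lg)
  first <- vapply(groups, `[`, integer(1), 1L)
  samples <- data.frame(sample = names(groups),
                        condition = di$condition[first],
                        stage = di$stage[first],
                        bio_rep = di$bio_rep[first],
                        n_tech = lengths(groups),
                        stringsAsFactors = FALSE, row.names = NULL)
  out <- list(log10 = avg, samples = samples, weights = NULL,
              imputed = NULL, design = design)
  if (center) {
    ctr <- avg - rowMeans(avg, na.rm = TRUE)
    out$centered <- ctr
  }
  class(out) <- "dia_matrix"
  out
}

#' @export
print.dia_matrix <- function(x, ...) {
  cat(sprintf(
    "dia_matrix: %d proteins x %d samples (%s)%s\n", nrow(x$log10),
    ncol(x$log10), paste(unique(x$samples$stage), collapse = ", "),
    if (!is.null(x$weights)) "; imputed+weighted" else ""))
  invisible(x)
}

#' Conservative minimum-replicate imputation with down-weighting
#'
#' Fills each missing cell with the minimum observed value among the
#' protein's replicates within the same (condition, stage) group; if the
#' group is entirely missing, the protein-wide minimum is used. Imputed
#' cells receive weight 0.05 and observed cells weight 1, so imputed
#' values inform the fit only weakly. Proteins observed nowhere are
#' dropped and reported via the `dropped` attribute. Observed cells are
#' never altered.
#'
#' @param dm A `dia_matrix` from [build_dia_matrix()].
#' @param imputed_weight Weight assigned to imputed cells (default 0.05).
#' @return The `dia_matrix` with complete `log10`, a `weights` matrix in
#'   `{1, imputed_weight}` and a logical `imputed` mask.
#' @export
impute_and_weight <- function(dm, imputed_weight = 0.05) {
  stopifnot(inherits(dm, "dia_matrix"))
  m <- dm$log10
  all_na <- rowSums(!is.na(m)) == 0L
  dropped <- rownames(m)[all_na]
  if (any(all_na)) {
    message(sum(all_na), " protein(s) with no observation dropped")
    m <- m[!all_na, , drop = FALSE]
  }
  groups <- split(seq_len(ncol(m)),
                  paste(dm$samples$condition, dm$samples$stage))
  weights <- matrix(1, nrow(m), ncol(m), dimnames = dimnames(m))
  imputed <- is.na(m)
  row_min <- apply(m, 1L, min, na.rm = TRUE)
  for (j in groups) {
    sub <- m[, j, drop = FALSE]
    gmin <- suppressWarnings(apply(sub, 1L, min, na.rm = TRUE))
    gmin[!is.finite(gmin)] <- row_min[!is.finite(gmin)]
    for (cc in seq_along(j)) {
      miss <- is.na(sub[, cc])
      m[miss, j[cc]] <- gmin[miss]
    }
  }
  weights[imputed] <- imputed_weight
  dm$log10 <- m
  dm$weights <- weights
  dm$imputed <- imputed
  dm$samples <- dm$samples
  attr(dm, "dropped") <- dropped
  dm
}

#' Weighted differential test for one time-course contrast
#'
#' Tests treatment versus control at one stage with the weighted
#' per-protein two-group fit, empirical-Bayes moderation and BH
#' adjustment of the phospho engine, using the imputation weights when
#' present (all weights 1 reproduce the unweighted path exactly). Fits run
#' on the log10 scale; effects are converted to log2 fold changes. A
#' protein is called reliably changed when `p_adj <= alpha` and
#' `|log2fc| >= lfc_min` (both boundaries inclusive).
#'
#' @param dm A `dia_matrix`, typically after [impute_and_weight()].
#' @param stage Stage label to contrast.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param lfc_min Absolute log2 fold-change threshold (default 0.5).
#' @return A `data.frame` per tested protein: `protein_id`, `log2fc`,
#'   `log10_diff`, `t_mod`, `p`, `p_adj`, `large_effect`, `significant`
#'   (the combined call), `direction`; attributes `prior` and `skipped`.
#' @export
differential_dia <- function(dm, stage, alpha = 0.05, lfc_min = 0.5) {
  stopifnot(inherits(dm, "dia_matrix"))
  sel <- dm$samples$stage == stage
  if (!any(sel)) stop("stage '", stage, "' absent from design",
                      call. = FALSE)
  Y <- dm$log10[, sel, drop = FALSE]
  W <- if (is.null(dm$weights)) NULL else dm$weights[, sel, drop = FALSE]
  des <- data.frame(channel = seq_len(sum(sel)),
                    condition = dm$samples$condition[sel],
                    stringsAsFactors = FALSE)
  res <- diff_test(Y, design = des, weights = W, alpha = alpha)
  names(res)[names(res) == "feature_id"] <- "protein_id"
  res$log10_diff <- res$log2fc
  res$log2fc <- res$log10_diff * log2(10)
  res$large_effect <- abs(res$log2fc) >= lfc_min
  res$significant <- res$significant & res$large_effect
  res$direction <- ifelse(res$log2fc < 0, "down", "up")
  res <- res[, c("protein_id", "log2fc", "log10_diff", "s2", "d", "t_mod",
                 "p", "p_adj", "large_effect", "significant", "direction")]
  res
}

#' Write a DIA matrix (samples as columns) as TSV
#'
#' @param dm A `dia_matrix`.
#' @param path Output path.
#' @param what `"log10"` (default) or `"centered"`.
#' @export
write_dia_matrix <- function(dm, path, what = c("log10", "centered")) {
  what <- match.arg(what)
  m <- dm[[what]]
  if (is.null(m)) stop("matrix component '", what, "' not present",
                       call. = FALSE)
  df <- data.frame(protein_id = rownames(m), m, check.names = FALSE)
  .write_tsv(df, path)
}
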