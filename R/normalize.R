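# Phosphopeptide / parent-protein ratio normalization.

#' Aggregate filtered PSMs to sequence-PTM features
#'
#' The quantification unit of the phospho analysis is the sequence-PTM
#' combination (the modified sequence): all PSMs of the same modified
#' sequence are summed per reporter channel. A channel with no observed
#' intensity in any contributing PSM stays missing.
#'
#' @param psms Filtered PSM `data.frame` (see [filter_psms()]).
#' @return A `data.frame` with one row per modified sequence: `feature_id`
#'   (the modified sequence), `peptide_sequence`, `protein_group_id`,
#'   `n_psms` and summed reporter columns `ri_*`.
#' @export
aggregate_psms_to_features <- function(psms) {
  ri_cols <- grep("^ri_[0-9]+$", names(psms), value = TRUE)
  if (nrow(psms) == 0L) {
    out <- data.frame(feature_id = character(0),
                      peptide_sequence = character(0),
                      protein_group_id = character(0), n_psms = integer(0))
    for (cc in ri_cols) out[[cc]] <- numeric(0)
    return(out)
  }
  key <- psms$modified_sequence
  idx <- split(seq_len(nrow(psms)), key)
  # keep first-appearance order of features
  idx <- idx[order(vapply(idx, `[`, integer(1), 1L))]
  ri <- as.matrix(psms[, ri_cols, drop = FALSE])
  agg <- t(vapply(idx, function(i) {
    m <- ri[i, , drop = FALSE]
    s <- colSums(m, na.rm = TRUE)
    s[colSums(!is.na(m)) == 0L] <- NA_real_
    s
  }, numeric(length(ri_cols))))
  first <- vapply(idx, `[`, integer(1), 1L)
  out <- data.frame(
    feature_id = psms$modified_sequence[first],
    peptide_sequence = psms$peptide_sequence[first],
    protein_group_id = psms$protein_group_id[first],
    n_psms = lengths(idx),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(agg))
  rownames(out) <- NULL
  out
}

#' Phosphopeptide / parent-protein log2 ratio matrix
#'
#' For every sequence-PTM feature and reporter channel, the ratio of the
#' phosphopeptide intensity to its parent protein group's corrected
#' intensity is log2-transformed. Dividing by the parent protein separates
#' phosphorylation changes from protein-abundance changes. A cell is
#' missing unless both intensities are present and positive. Features whose
#' parent group contributes no intensity in any channel (or whose group id
#' is absent from the protein table) are excluded from the matrix but
#' counted in the `match_rate` denominator, mirroring how a fraction of
#' phosphopeptides in a real experiment lacks a total-protein match.
#'
#' @param features Feature table from [aggregate_psms_to_features()].
#' @param protein_groups Protein-group table (see [read_protein_groups()]).
#' @param design A [channel_design()].
#' @return A `ratio_matrix` object: list with `ratios` (features x
#'   channels matrix, rownames = feature ids, colnames = `ri_*`),
#'   `features` (metadata: `feature_id`, `peptide_sequence`,
#'   `protein_group_id`, `n_psms`), `match_rate` and `design`.
#' @examples
#' sim <- generate_phospho_dataset(sim_config(n_proteins = 20, seed = 1))
#' fl <- filter_psms(sim$psms)
#' rm_ <- compute_log_ratios(aggregate_psms_to_features(fl$psms),
#'                           sim$protein_groups, sim$design)
#' rm_$match_rate
#' @export
compute_log_ratios <- function(features, protein_groups, design) {
  design <- .validate_design(design)
  ri_cols <- paste0("ri_", design$channel)
  if (!all(ri_cols %in% names(features)) ||
      !all(ri_cols %in% names(protein_groups)))
    stop("design channels missing from feature or protein-group table",
         call. = FALSE)

  n_total <- nrow(features)
  pg_idx <- match(features$protein_group_id, protein_groups$group_id)
  unknown <- is.na(pg_idx)
  if (any(unknown))
    message(sum(unknown),
            " feature(s) reference unknown protein groups; excluded")

  fmat <- as.matrix(features[, ri_cols, drop = FALSE])
  pmat <- as.matrix(protein_groups[, ri_cols, drop = FALSE])[pg_idx, ,
                                                             drop = FALSE]
  ok <- !is.na(fmat) & !is.na(pmat) & fmat > 0 & pmat > 0
  ratios <- matrix(NA_real_, n_total, length(ri_cols),
                   dimnames = list(features$feature_id, ri_cols))
  ratios[ok] <- log2(fmat[ok] / pmat[ok])

  has_parent <- !unknown & rowSums(!is.na(pmat) & pmat > 0) > 0L
  match_rate <- if (n_total == 0L) NA_real_ else sum(has_parent) / n_total

  keep <- has_parent
  out <- list(
    ratios = ratios[keep, , drop = FALSE],
    features = features[keep, c("feature_id", "peptide_sequence",
                                "protein_group_id", "n_psms"), drop = FALSE],
    match_rate = match_rate,
    design = design
  )
  rownames(out$features) <- NULL
  class(out) <- "ratio_matrix"
  out
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat(sprintf(
    "ratio_matrix: %d features x %d channels; parent match rate %.1f%%\n",
    nrow(x$ratios), ncol(x$ratios), 100 * x$match_rate))
  invisible(x)
}

#' Write a ratio matrix as TSV
#'
#' @param rm_ A `ratio_matrix`.
#' @param path Output path.
#' @export
write_ratio_matrix <- function(rm_, path) {
  df <- cbind(rm_$features, as.data.frame(rm_$ratios, row.names = FALSE))
  .write_tsv(df, path)
}
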