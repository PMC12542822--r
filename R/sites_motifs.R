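# Phosphosite localization aggregation, sequence-window extraction and
# information-content motif matrices.

#' Aggregate phospho-STY localization probabilities across PSMs
#'
#' For each peptide sequence, per-position localization probabilities are
#' mean-aggregated across all of its PSMs: a position absent from one
#' PSM's vector contributes 0 to that PSM's value, so the denominator is
#' always the full number of PSMs. The most likely amino acid (argmax of
#' the per-position means, ties broken by the lowest position) is treated
#' as the phosphosite. Peptides whose PSMs carry no localization
#' information at all are flagged unlocalizable.
#'
#' @param psms PSM `data.frame` with `peptide_sequence`,
#'   `protein_group_id` and a `site_probabilities` list column.
#' @return A `data.frame` of localized sites: `peptide_sequence`,
#'   `protein_group_id`, `residue`, `peptide_position`,
#'   `mean_probability`, `n_psms`, `unlocalizable`. The per-peptide mean
#'   vectors are attached as attribute `position_means` (named list).
#' @examples
#' sim <- generate_phospho_dataset(sim_config(n_proteins = 20, seed = 1))
#' head(aggregate_site_probabilities(filter_psms(sim$psms)$psms))
#' @export
aggregate_site_probabilities <- function(psms) {
  stopifnot(is.data.frame(psms), "site_probabilities" %in% names(psms))
  idx <- split(seq_len(nrow(psms)), psms$peptide_sequence)
  idx <- idx[order(vapply(idx, `[`, integer(1), 1L))]

  means <- vector("list", length(idx))
  rows <- vector("list", length(idx))
  for (g in seq_along(idx)) {
    i <- idx[[g]]
    pep <- psms$peptide_sequence[i[1L]]
    vecs <- psms$site_probabilities[i]
    pos <- sort(unique(as.integer(unlist(lapply(vecs, names)))))
    n <- length(i)
    if (length(pos) == 0L) {
      means[[g]] <- setNames(numeric(0), character(0))
      rows[[g]] <- data.frame(
        peptide_sequence = pep,
        protein_group_id = psms$protein_group_id[i[1L]],
        residue = NA_character_, peptide_position = NA_integer_,
        mean_probability = NA_real_, n_psms = n, unlocalizable = TRUE,
        stringsAsFactors = FALSE)
      next
    }
    acc <- numeric(length(pos))
    for (v in vecs) {
      j <- match(as.integer(names(v)), pos)
      acc[j] <- acc[j] + unname(v)
    }
    m <- setNames(acc / n, as.character(pos))
    best <- pos[which.max(m)]  # which.max takes the first (lowest) position
    means[[g]] <- m
    rows[[g]] <- data.frame(
      peptide_sequence = pep,
      protein_group_id = psms$protein_group_id[i[1L]],
      residue = substring(pep, best, best),
      peptide_position = best,
      mean_probability = unname(m[as.character(best)]),
      n_psms = n, unlocalizable = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(means) <- out$peptide_sequence
  attr(out, "position_means") <- means
  out
}

#' Extract phosphosite-centered sequence windows
#'
#' Looks each localized site up in its parent protein sequence and
#' extracts the `(2w+1)`-mer centered on the phosphosite. Window positions
#' beyond the protein termini are padded with `-`, which later drops out
#' of the motif frequency counts. When the site table already carries a
#' `protein_position` column it is verified against the protein sequence;
#' otherwise the position is derived from the first occurrence of the
#' peptide in the protein.
#'
#' @param sites Localized-site `data.frame` from
#'   [aggregate_site_probabilities()] (unlocalizable rows are dropped).
#' @param proteins Named character vector of protein sequences (or an
#'   `AAStringSet`), keyed by protein group id.
#' @param w Window half-width; the default 7 gives the conventional
#'   15-mer kinase-motif window.
#' @return A `data.frame`: `peptide_sequence`, `protein_group_id`,
#'   `residue`, `protein_position`, `window`.
#' @export
center_windows <- function(sites, proteins, w = 7L) {
  w <- .check_count(w, "w")
  if (methods::is(proteins, "XStringSet"))
    proteins <- setNames(as.character(proteins), names(proteins))
  sites <- sites[!(sites$unlocalizable %||% FALSE), , drop = FALSE]
  n <- nrow(sites)
  prot <- proteins[sites$protein_group_id]
  if (anyNA(prot) || any(!nzchar(prot)))
    stop("no protein sequence for site(s): ",
         paste(unique(sites$protein_group_id[is.na(prot) | !nzchar(prot)]),
               collapse = ", "), call. = FALSE)

  if (!is.null(sites$protein_position) && !anyNA(sites$protein_position)) {
    ppos <- as.integer(sites$protein_position)
  } else {
    start <- vapply(seq_len(n), function(i)
      as.integer(regexpr(sites$peptide_sequence[i], prot[i],
                         fixed = TRUE)), integer(1))
    if (any(start < 1L))
      stop("peptide not found in its protein for site(s): ",
           paste(sites$peptide_sequence[start < 1L], collapse = ", "),
           call. = FALSE)
    ppos <- start + sites$peptide_position - 1L
  }
  at <- substring(prot, ppos, ppos)
  bad <- at != sites$residue
  if (any(bad))
    stop("site residue mismatch against protein sequence for: ",
         paste(sprintf("%s@%s%d (protein has '%s')",
                       sites$protein_group_id[bad], sites$residue[bad],
                       ppos[bad], at[bad]), collapse = ", "), call. = FALSE)

  windows <- vapply(seq_len(n), function(i) {
    s <- prot[i]; L <- nchar(s); c0 <- ppos[i]
    lo <- c0 - w; hi <- c0 + w
    core <- substring(s, max(1L, lo), min(L, hi))
    paste0(strrep("-", max(0L, 1L - lo)), core, strrep("-", max(0L, hi - L)))
  }, character(1))

  data.frame(peptide_sequence = sites$peptide_sequence,
             protein_group_id = sites$protein_group_id,
             residue = sites$residue, protein_position = ppos,
             window = windows, stringsAsFactors = FALSE)
}

.window_freqs <- function(windows, width, pseudocount) {
  counts <- matrix(0, nrow = width, ncol = length(.AA20),
                   dimnames = list(NULL, .AA20))
  chars <- do.call(rbind, strsplit(windows, "", fixed = TRUE))
  for (pos in seq_len(width)) {
    tb <- table(factor(chars[, pos], levels = .AA20))
    counts[pos, ] <- as.numeric(tb)
  }
  n_pos <- rowSums(counts)  # gap/non-standard symbols drop out
  denom <- n_pos + length(.AA20) * pseudocount
  freq <- matrix(0, width, length(.AA20), dimnames = dimnames(counts))
  ok <- denom > 0
  freq[ok, ] <- (counts[ok, , drop = FALSE] + pseudocount) / denom[ok]
  list(counts = counts, freq = freq, n_pos = n_pos)
}

#' Scaled information-content motif matrix
#'
#' Compares phosphosite-centered foreground windows against a background
#' window set. Per position and residue the enrichment contribution is
#' `f * log2(f / b)` with `f`, `b` the (optionally pseudocounted)
#' foreground and background frequencies; negative (depletion)
#' contributions are clipped to 0 and every cell is divided by
#' `log2(20)`, so a residue fully conserved in the foreground but uniform
#' in the background scores exactly 1. Gap symbols from terminal padding
#' are excluded from the frequency denominators. A residue present in the
#' foreground but absent from an un-pseudocounted background is scored
#' against a floor frequency of `1/(background size + 20)` (and the event
#' is messaged); cells are capped at 1.
#'
#' @param foreground,background Character vectors of equal-width windows
#'   (e.g. from [center_windows()]), or data frames with a `window`
#'   column.
#' @param pseudocount Added to every residue count before frequencies
#'   (default 0).
#' @return A `motif_matrix` object: list with `ic` (positions x 20
#'   residues matrix, rownames `-w`..`+w`), `fg_n`, `bg_n` (contributing
#'   sequences per position) and `fg_counts`, `bg_counts`.
#' @export
motif_information_content <- function(foreground, background,
                                      pseudocount = 0) {
  if (is.data.frame(foreground)) foreground <- foreground$window
  if (is.data.frame(background)) background <- background$window
  if (length(foreground) == 0L || length(background) == 0L)
    stop("foreground and background must be non-empty", call. = FALSE)
  width <- unique(nchar(c(foreground, background)))
  if (length(width) != 1L)
    stop("all windows must share one width", call. = FALSE)
  if (width %% 2L == 0L) stop("window width must be odd", call. = FALSE)

  fg <- .window_freqs(foreground, width, pseudocount)
  bg <- .window_freqs(background, width, pseudocount)

  b <- bg$freq
  zero_b <- b == 0 & fg$freq > 0
  if (any(zero_b)) {
    floor_b <- 1 / (matrix(bg$n_pos, width, length(.AA20)) + length(.AA20))
    b[zero_b] <- floor_b[zero_b]
    message(sum(zero_b),
            " motif cell(s) had a foreground-only residue; background ",
            "frequency floored at 1/(background size + 20)")
  }
  f <- fg$freq
  ic <- matrix(0, width, length(.AA20), dimnames = dimnames(f))
  nz <- f > 0
  ic[nz] <- f[nz] * log2(f[nz] / b[nz])
  ic[ic < 0] <- 0
  ic <- pmin(ic / log2(length(.AA20)), 1)

  w <- (width - 1L) %/% 2L
  rownames(ic) <- as.character(seq.int(-w, w))
  out <- list(ic = ic, fg_n = fg$n_pos, bg_n = bg$n_pos,
              fg_counts = fg$counts, bg_counts = bg$counts)
  class(out) <- "motif_matrix"
  out
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("motif_matrix: %d positions x %d residues; max IC %.3f\n",
              nrow(x$ic), ncol(x$ic), max(x$ic)))
  invisible(x)
}

#' Write a motif matrix as TSV (rows positions, columns residues)
#'
#' @param mm A `motif_matrix`.
#' @param path Output path.
#' @export
write_motif_matrix <- function(mm, path) {
  df <- data.frame(position = rownames(mm$ic), mm$ic, check.names = FALSE)
  .write_tsv(df, path)
}

#' Subset sites by predicted kinase rank
#'
#' Keeps the sites whose peptide has the named kinase among its top
#' `rank_max` predicted upstream kinases (rank `rank_max` itself is
#' included). Kinase predictions are produced externally and consumed as a
#' (peptide, kinase, rank) table.
#'
#' @param sites Localized-site `data.frame` (keyed by
#'   `peptide_sequence`).
#' @param kinase_scores `data.frame` with columns `peptide`, `kinase`,
#'   `rank`.
#' @param kinase Kinase name to select for.
#' @param rank_max Inclusive rank cutoff (default 10).
#' @return The subset of `sites`; empty (with a warning) when the kinase
#'   is absent from the score table.
#' @export
select_kinase_subset <- function(sites, kinase_scores, kinase,
                                 rank_max = 10L) {
  stopifnot(all(c("peptide", "kinase", "rank") %in% names(kinase_scores)))
  ks <- kinase_scores[kinase_scores$kinase == kinase, , drop = FALSE]
  if (nrow(ks) == 0L) {
    warning("kinase '", kinase, "' absent from the score table",
            call. = FALSE)
    return(sites[0L, , drop = FALSE])
  }
  ks <- ks[!is.na(ks$rank) & ks$rank <= rank_max, , drop = FALSE]
  sites[sites$peptide_sequence %in% ks$peptide, , drop = FALSE]
}

#' Read / write a kinase-score table (peptide, kinase, rank)
#'
#' @param path TSV path.
#' @return `read_kinase_scores()`: a `data.frame` with `peptide`,
#'   `kinase`, integer `rank`.
#' @export
read_kinase_scores <- function(path) {
  df <- .read_tsv(path)
  stopifnot(all(c("peptide", "kinase", "rank") %in% names(df)))
  df$rank <- as.integer(df$rank)
  df
}

#' Write localized sites as TSV
#'
#' @param sites Localized-site `data.frame`.
#' @param path Output path.
#' @export
write_sites <- function(sites, path) {
  .write_tsv(sites, path)
}
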