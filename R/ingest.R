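# Readers/writers for the evidence-style PSM dialect and protein-group
# tables, plus the confidence filters applied before quantification.

.EV_COLS <- c("id", "Sequence", "Modified sequence", "Protein group IDs",
              "PEP", "Phospho (STY) Probabilities", "Reverse",
              "Potential contaminant")

.encode_site_probs <- function(probs, peptide) {
  if (length(probs) == 0L) return("")
  pos <- as.integer(names(probs))
  res <- substring(peptide, pos, pos)
  paste(sprintf("%s%d:%s", res, pos, format(unname(probs), trim = TRUE,
                                            scientific = FALSE)),
        collapse = ";")
}

.parse_site_probs <- function(s, peptide, n_phospho, row) {
  if (is.na(s) || !nzchar(s)) return(setNames(numeric(0), character(0)))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([A-Z])([0-9]+):([0-9.eE+-]+)$", parts))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    stop(sprintf("row %d: malformed site-probability entry '%s'",
                 row, parts[bad][1]), call. = FALSE)
  res <- vapply(m, `[`, character(1), 2L)
  pos <- as.integer(vapply(m, `[`, character(1), 3L))
  p <- suppressWarnings(as.numeric(vapply(m, `[`, character(1), 4L)))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop(sprintf("row %d: site probability outside [0, 1]", row),
         call. = FALSE)
  if (any(pos < 1L) || any(pos > nchar(peptide)))
    stop(sprintf("row %d: site position outside peptide", row), call. = FALSE)
  actual <- substring(peptide, pos, pos)
  if (any(actual != res))
    stop(sprintf(
      "row %d: site residue '%s' at position %d does not match peptide ('%s')",
      row, res[actual != res][1], pos[actual != res][1],
      actual[actual != res][1]), call. = FALSE)
  if (any(!actual %in% c("S", "T", "Y")))
    stop(sprintf("row %d: site position %d is not an S/T/Y residue",
                 row, pos[!actual %in% c("S", "T", "Y")][1]), call. = FALSE)
  if (sum(p) > n_phospho + 1e-6)
    stop(sprintf("row %d: site probabilities sum to %.4f > %d phospho groups",
                 row, sum(p), n_phospho), call. = FALSE)
  setNames(p, as.character(pos))
}

#' Read an evidence-style PSM table
#'
#' Parses a tab-separated table in the evidence dialect: one row per
#' peptide-spectrum match carrying the peptide and modified sequence, the
#' protein group id, the posterior error probability, corrected reporter
#' intensities and a per-residue phospho localization string such as
#' `"S3:0.9;T5:0.1"`. Reporter intensities of 0 or empty cells are read as
#' missing (`NA`), following the search-engine convention that a zero
#' reporter is an absent measurement. Localization strings are validated
#' against the peptide sequence (S/T/Y residues only, probabilities in
#' [0, 1], total mass at most the number of phospho groups).
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with one row per PSM: `psm_id`,
#'   `peptide_sequence`, `modified_sequence`, `protein_group_id`, `pep`,
#'   reporter columns `ri_1`..`ri_k`, a `site_probabilities` list column
#'   (named numeric vectors keyed by 1-based peptide position), `is_decoy`
#'   and `is_contaminant`.
#' @seealso [write_evidence()], [filter_psms()]
#' @export
read_evidence <- function(path) {
  raw <- .read_tsv(path)
  ri_cols <- grep("^Reporter intensity corrected [0-9]+$", names(raw),
                  value = TRUE)
  missing_cols <- setdiff(.EV_COLS, names(raw))
  if (length(missing_cols) || length(ri_cols) == 0L)
    stop("evidence table is missing mandatory column(s): ",
         paste(c(missing_cols,
                 if (length(ri_cols) == 0L) "Reporter intensity corrected *"),
               collapse = ", "), call. = FALSE)
  ri_cols <- ri_cols[order(as.integer(sub(".* ", "", ri_cols)))]

  n <- nrow(raw)
  ri <- as.matrix(raw[, ri_cols, drop = FALSE])
  mode(ri) <- "numeric"
  ri[!is.na(ri) & ri == 0] <- NA_real_
  colnames(ri) <- paste0("ri_", seq_along(ri_cols))

  pep <- suppressWarnings(as.numeric(raw$PEP))
  if (anyNA(pep) || any(pep < 0 | pep > 1))
    stop("PEP values must be numbers in [0, 1] (first bad row: ",
         which(is.na(pep) | pep < 0 | pep > 1)[1], ")", call. = FALSE)

  n_ph <- pmax(1L, vapply(gregexpr("(ph)", raw$`Modified sequence`,
                                   fixed = TRUE),
                          function(g) if (g[1L] == -1L) 0L else length(g),
                          integer(1)))
  prob_str <- as.character(raw$`Phospho (STY) Probabilities`)
  probs <- lapply(seq_len(n), function(i)
    .parse_site_probs(prob_str[i], raw$Sequence[i], n_ph[i], i))

  out <- data.frame(
    psm_id = as.character(raw$id),
    peptide_sequence = raw$Sequence,
    modified_sequence = raw$`Modified sequence`,
    protein_group_id = as.character(raw$`Protein group IDs`),
    pep = pep,
    stringsAsFactors = FALSE
  )
  out$is_decoy <- !is.na(raw$Reverse) & raw$Reverse == "+"
  out$is_contaminant <- !is.na(raw$`Potential contaminant`) &
    raw$`Potential contaminant` == "+"
  out <- cbind(out, as.data.frame(ri))
  out$site_probabilities <- probs
  rownames(out) <- NULL
  out
}

#' Write an evidence-style PSM table
#'
#' Inverse of [read_evidence()]: serializes the internal PSM representation
#' back to the evidence TSV dialect. Missing reporter intensities are
#' written as empty cells.
#'
#' @param psms PSM `data.frame` as returned by [read_evidence()] or
#'   [generate_phospho_dataset()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_evidence <- function(psms, path) {
  ri_cols <- grep("^ri_[0-9]+$", names(psms), value = TRUE)
  out <- data.frame(
    id = psms$psm_id,
    Sequence = psms$peptide_sequence,
    `Modified sequence` = psms$modified_sequence,
    `Protein group IDs` = psms$protein_group_id,
    PEP = psms$pep,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  ri <- psms[, ri_cols, drop = FALSE]
  names(ri) <- paste("Reporter intensity corrected",
                     sub("^ri_", "", ri_cols))
  out <- cbind(out, ri)
  out$`Phospho (STY) Probabilities` <- vapply(seq_len(nrow(psms)), function(i)
    .encode_site_probs(psms$site_probabilities[[i]],
                       psms$peptide_sequence[i]), character(1))
  out$Reverse <- ifelse(psms$is_decoy, "+", "")
  out$`Potential contaminant` <- ifelse(psms$is_contaminant, "+", "")
  .write_tsv(out, path)
}

#' Read / write a protein-group table
#'
#' The protein-group dialect carries the group id, member accessions, an
#' optional gene symbol, corrected reporter intensities and
#' decoy/contaminant flags. Zero intensities are read as missing.
#'
#' @param path Path to the TSV file.
#' @return `read_protein_groups()`: a `data.frame` with `group_id`,
#'   `accessions`, `gene_symbol`, reporter columns `ri_*`, `is_decoy`,
#'   `is_contaminant`.
#' @export
read_protein_groups <- function(path) {
  raw <- .read_tsv(path)
  ri_cols <- grep("^Reporter intensity corrected [0-9]+$", names(raw),
                  value = TRUE)
  need <- c("id", "Protein IDs")
  if (!all(need %in% names(raw)) || length(ri_cols) == 0L)
    stop("protein-group table is missing mandatory column(s): ",
         paste(c(setdiff(need, names(raw)),
                 if (length(ri_cols) == 0L) "Reporter intensity corrected *"),
               collapse = ", "), call. = FALSE)
  ri_cols <- ri_cols[order(as.integer(sub(".* ", "", ri_cols)))]
  if (anyDuplicated(raw$id))
    stop("protein-group ids must be unique", call. = FALSE)
  ri <- as.matrix(raw[, ri_cols, drop = FALSE])
  mode(ri) <- "numeric"
  ri[!is.na(ri) & ri == 0] <- NA_real_
  colnames(ri) <- paste0("ri_", seq_along(ri_cols))
  out <- data.frame(
    group_id = as.character(raw$id),
    accessions = raw$`Protein IDs`,
    gene_symbol = if ("Gene names" %in% names(raw)) raw$`Gene names`
                  else NA_character_,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(ri))
  out$is_decoy <- if ("Reverse" %in% names(raw))
    !is.na(raw$Reverse) & raw$Reverse == "+" else FALSE
  out$is_contaminant <- if ("Potential contaminant" %in% names(raw))
    !is.na(raw$`Potential contaminant`) & raw$`Potential contaminant` == "+"
    else FALSE
  out
}

#' @rdname read_protein_groups
#' @param pg Protein-group `data.frame`.
#' @export
write_protein_groups <- function(pg, path) {
  ri_cols <- grep("^ri_[0-9]+$", names(pg), value = TRUE)
  out <- data.frame(id = pg$group_id, `Protein IDs` = pg$accessions,
                    `Gene names` = pg$gene_symbol,
                    check.names = FALSE, stringsAsFactors = FALSE)
  ri <- pg[, ri_cols, drop = FALSE]
  names(ri) <- paste("Reporter intensity corrected",
                     sub("^ri_", "", ri_cols))
  out <- cbind(out, ri)
  out$Reverse <- ifelse(pg$is_decoy, "+", "")
  out$`Potential contaminant` <- ifelse(pg$is_contaminant, "+", "")
  .write_tsv(out, path)
}

#' Filter PSMs on decoy, contaminant and confidence criteria
#'
#' Removes reverse-decoy matches, potential contaminants and low-confidence
#' PSMs whose posterior error probability is at or above `pep_max` (the
#' boundary value itself is removed). A record failing several criteria is
#' counted once, with priority decoy > contaminant > PEP, so the report's
#' removal counts and the retained count always sum to the input size.
#'
#' @param psms PSM `data.frame` (see [read_evidence()]).
#' @param pep_max PEP threshold in (0, 1]; records with `pep >= pep_max`
#'   are removed (default 0.01).
#' @return A list with `psms` (retained rows) and `report`, a one-row
#'   `data.frame` with `n_input`, `removed_decoy`, `removed_contaminant`,
#'   `removed_pep` and `retained`.
#' @examples
#' sim <- generate_phospho_dataset(sim_config(n_proteins = 20, seed = 1))
#' filter_psms(sim$psms)$report
#' @export
filter_psms <- function(psms, pep_max = 0.01) {
  if (!is.numeric(pep_max) || length(pep_max) != 1L || pep_max <= 0 ||
      pep_max > 1)
    stop("pep_max must be a single probability in (0, 1]", call. = FALSE)
  reason <- rep("retained", nrow(psms))
  reason[psms$pep >= pep_max] <- "pep"
  reason[psms$is_contaminant] <- "contaminant"
  reason[psms$is_decoy] <- "decoy"
  report <- data.frame(
    n_input = nrow(psms),
    removed_decoy = sum(reason == "decoy"),
    removed_contaminant = sum(reason == "contaminant"),
    removed_pep = sum(reason == "pep"),
    retained = sum(reason == "retained")
  )
  list(psms = psms[reason == "retained", , drop = FALSE], report = report)
}

#' Remove decoy and contaminant protein groups
#'
#' Protein groups are deliberately not post-filtered on peptide counts or
#' q-values, so that as many phosphopeptides as possible keep a parent
#' intensity for normalization; only decoy and contaminant entries are
#' dropped.
#'
#' @param pg Protein-group `data.frame`.
#' @return The table without flagged rows.
#' @export
filter_protein_groups <- function(pg) {
  pg[!(pg$is_decoy | pg$is_contaminant), , drop = FALSE]
}

#' Read or write parent protein sequences as FASTA
#'
#' @param path FASTA path.
#' @return `read_protein_fasta()`: a named character vector of amino-acid
#'   sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  setNames(as.character(aa), names(aa))
}

#' @rdname read_protein_fasta
#' @param seqs Named character vector of protein sequences.
#' @export
write_protein_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
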