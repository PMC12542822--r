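# In-code fixture builders.

# Build a PSM data.frame row-by-row. `probs` is a list of named numeric
# vectors (names = 1-based peptide positions).
make_psms <- function(peptide, modified = NULL, protein = "PG1",
                      pep = 0.001, ri = NULL, probs = NULL,
                      decoy = FALSE, contaminant = FALSE, n_channels = 6L) {
  n <- length(peptide)
  if (is.null(modified)) modified <- peptide
  protein <- rep_len(protein, n)
  pep <- rep_len(pep, n)
  decoy <- rep_len(decoy, n)
  contaminant <- rep_len(contaminant, n)
  if (is.null(ri)) ri <- matrix(1000, n, n_channels)
  ri <- matrix(as.numeric(ri), n, n_channels)
  colnames(ri) <- paste0("ri_", seq_len(n_channels))
  if (is.null(probs)) probs <- rep(list(setNames(numeric(0), character(0))), n)
  df <- data.frame(psm_id = sprintf("PSM%03d", seq_len(n)),
                   peptide_sequence = peptide,
                   modified_sequence = modified,
                   protein_group_id = protein, pep = pep,
                   is_decoy = decoy, is_contaminant = contaminant,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(ri))
  df$site_probabilities <- probs
  df
}

make_protein_groups <- function(group_id, ri, gene = NULL) {
  n <- length(group_id)
  ri <- matrix(as.numeric(ri), n)
  colnames(ri) <- paste0("ri_", seq_len(ncol(ri)))
  df <- data.frame(group_id = group_id, accessions = group_id,
                   gene_symbol = gene %||% paste0("g_", group_id),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(ri))
  df$is_decoy <- FALSE
  df$is_contaminant <- FALSE
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small helper running the TMT stages from PSMs to differential results.
run_tmt_stages <- function(sim, pep_max = 0.01, alpha = 0.05) {
  fl <- filter_psms(sim$psms, pep_max = pep_max)
  feats <- aggregate_psms_to_features(fl$psms)
  rm_ <- compute_log_ratios(feats, sim$protein_groups, sim$design)
  diff_test(rm_, alpha = alpha)
}
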