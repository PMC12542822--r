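# Gene-set over-representation analysis and ward.D2 clustering of
# row-scaled intensity matrices.

#' Build a gene-set collection restricted to a universe
#'
#' Restricts each gene set to the analysis universe (by default all
#' quantified, annotated proteins) and drops sets left empty, so the
#' hypergeometric model's population is consistent across terms.
#'
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param universe Character vector of gene ids forming the population.
#' @return A `gene_set_collection`: list with `sets` (restricted, no
#'   empties) and `universe`.
#' @export
gene_set_collection <- function(sets, universe) {
  stopifnot(is.list(sets), length(names(sets)) == length(sets))
  universe <- unique(as.character(universe))
  restricted <- lapply(sets, function(g) intersect(unique(g), universe))
  empty <- lengths(restricted) == 0L
  if (any(empty))
    message(sum(empty), " gene set(s) empty after universe restriction; ",
            "dropped")
  out <- list(sets = restricted[!empty], universe = universe)
  class(out) <- "gene_set_collection"
  out
}

#' Read a GMT gene-set file
#'
#' @param path Path to a GMT file (term, description, member genes).
#' @return Named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of the query list with the
#' one-sided upper-tail hypergeometric test, adjusts across tested terms
#' with Benjamini-Hochberg, and returns terms passing `p_adj <= alpha`
#' sorted by p-value. Query ids outside the universe are dropped with a
#' warning. The BH adjustment (in place of service-specific strategies
#' such as g:SCS) is recorded in the `adjustment` attribute.
#'
#' @param query Character vector of gene ids (e.g. proteins with at least
#'   one significantly changed phosphopeptide).
#' @param collection A [gene_set_collection()].
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param all_results Return all tested terms instead of only significant
#'   ones.
#' @return A `data.frame` with `term`, `k` (overlap), `K` (set size), `n`
#'   (query size), `N` (universe size), `p`, `p_adj` and `genes`
#'   (overlap ids, `;`-separated), sorted by `p`.
#' @export
hypergeometric_ora <- function(query, collection, alpha = 0.05,
                               all_results = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$universe)
  if (length(outside))
    warning(length(outside), " query id(s) outside the universe dropped",
            call. = FALSE)
  query <- intersect(query, collection$universe)
  N <- length(collection$universe)
  n <- length(query)
  if (n == 0L) {
    warning("empty query after universe restriction", call. = FALSE)
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), genes = character(0)))
  }
  terms <- names(collection$sets)
  K <- lengths(collection$sets)
  ov <- lapply(collection$sets, intersect, query)
  k <- lengths(ov)
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(term = terms, k = k, K = K, n = n, N = N, p = p,
                    p_adj = adjust_bh(p),
                    genes = vapply(ov, paste, character(1), collapse = ";"),
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$p, res$term), , drop = FALSE]
  if (!all_results) res <- res[res$p_adj <= alpha, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "adjustment") <- "BH"
  res
}

#' Scale matrix rows to mean 0 and SD 1
#'
#' Standard row scaling for heatmap display: per row, subtract the mean
#' and divide by the standard deviation (n-1 denominator), ignoring
#' missing cells. Constant rows cannot be scaled; they are emitted as
#' zeros with a warning and flagged in the `constant_rows` attribute.
#'
#' @param m Numeric matrix (features x samples).
#' @return The scaled matrix, same shape and dimnames.
#' @export
scale_rows <- function(m) {
  m <- as.matrix(m)
  mu <- rowMeans(m, na.rm = TRUE)
  s <- apply(m, 1L, sd, na.rm = TRUE)
  const <- !is.finite(s) | s == 0
  if (any(const)) {
    warning(sum(const), " constant row(s) emitted as zeros", call. = FALSE)
    s[const] <- 1
    mu[const] <- m[const, 1L]
  }
  out <- (m - mu) / s
  if (any(const)) out[const, ] <- 0
  attr(out, "constant_rows") <- which(const)
  out
}

#' Ward.D2 hierarchical clustering
#'
#' Agglomerative minimum-variance clustering of matrix rows (or columns)
#' on Euclidean distances, with merge heights on the unsquared scale (the
#' ward.D2 convention: Lance-Williams updates run on squared
#' dissimilarities and the reported heights are their square roots).
#'
#' @param m Numeric matrix, typically row-scaled via [scale_rows()].
#' @param axis Cluster `"rows"` (default) or `"columns"`.
#' @return A `cluster_result`: list with `hclust` (the full
#'   [stats::hclust] object), `merge`, `height`, `order` (leaf order),
#'   `labels` and `matrix` (the input, reordered to leaf order along the
#'   clustered axis).
#' @examples
#' ward_d2_cluster(cbind(x = c(0, 3, 4)))$height
#' @export
ward_d2_cluster <- function(m, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  m <- as.matrix(m)
  x <- if (axis == "rows") m else t(m)
  if (nrow(x) < 2L) stop("need at least two items to cluster", call. = FALSE)
  if (any(!is.finite(x)))
    stop("non-finite values in clustering input", call. = FALSE)
  hc <- hclust(dist(x), method = "ward.D2")
  ordered <- if (axis == "rows") m[hc$order, , drop = FALSE]
             else m[, hc$order, drop = FALSE]
  out <- list(hclust = hc, merge = hc$merge, height = hc$height,
              order = hc$order, labels = hc$labels, matrix = ordered)
  class(out) <- "cluster_result"
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d leaves, %d merges, max height %.4f\n",
              length(x$order), length(x$height), max(x$height)))
  invisible(x)
}

#' Write a cluster result (merge table + leaf order + ordered matrix)
#'
#' @param cl A `cluster_result`.
#' @param prefix Path prefix; writes `<prefix>_merges.tsv`,
#'   `<prefix>_order.tsv` and `<prefix>_matrix.tsv`.
#' @export
write_cluster_result <- function(cl, prefix) {
  merges <- data.frame(step = seq_along(cl$height),
                       left = cl$merge[, 1L], right = cl$merge[, 2L],
                       height = cl$height)
  .write_tsv(merges, paste0(prefix, "_merges.tsv"))
  leaves <- data.frame(position = seq_along(cl$order), item = cl$order,
                       label = (cl$labels %||% as.character(cl$order))[cl$order])
  .write_tsv(leaves, paste0(prefix, "_order.tsv"))
  mat <- data.frame(id = rownames(cl$matrix) %||%
                      seq_len(nrow(cl$matrix)), cl$matrix,
                    check.names = FALSE)
  .write_tsv(mat, paste0(prefix, "_matrix.tsv"))
  invisible(prefix)
}
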