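# Per-feature two-group least squares, empirical-Bayes variance
# moderation, BH adjustment and significance calling.

#' Two-group (weighted) least-squares fit for one feature
#'
#' Fits the two-group mean model to one feature's per-channel ratio values
#' by (weighted) least squares. The effect is the treatment-mean minus
#' control-mean of ratios; the residual variance is estimated on
#' `n_obs - 2` degrees of freedom. With equal weights this is exactly the
#' pooled two-sample estimator. The design scale `v`, the sum of inverse
#' effective group sizes (sums of weights), is returned for use by
#' [moderate()].
#'
#' @param values Numeric vector of per-channel values (may contain `NA`).
#' @param design A [channel_design()] whose rows align with `values`.
#' @param weights Optional non-negative per-channel weights (default all 1).
#' @return A list with `beta`, `s2`, `d` (residual df), `v`, `n_control`,
#'   `n_treatment` and `ok` (`FALSE` when a group has fewer than two
#'   observations, in which case the feature must be skipped).
#' @examples
#' d <- channel_design()
#' fit_feature_model(c(0.1, 0.2, 0.3, -0.9, -1.0, -1.1), d)
#' @export
fit_feature_model <- function(values, design, weights = NULL) {
  design <- .validate_design(design)
  f <- .fit_two_group(matrix(values, nrow = 1), design,
                      if (is.null(weights)) NULL else matrix(weights, nrow = 1))
  list(beta = f$beta[1], s2 = f$s2[1], d = f$d[1], v = f$v[1],
       n_control = f$n1[1], n_treatment = f$n2[1], ok = f$ok[1])
}

# Vectorized weighted two-group fit over the rows of Y.
.fit_two_group <- function(Y, design, W = NULL) {
  lev <- .design_levels(design)
  g1 <- design$condition == lev[1]
  g2 <- design$condition == lev[2]
  if (is.null(W)) W <- matrix(1, nrow(Y), ncol(Y))
  if (any(W < 0, na.rm = TRUE)) stop("weights must be non-negative",
                                     call. = FALSE)
  obs <- !is.na(Y) & !is.na(W) & W > 0
  Wm <- ifelse(obs, W, 0)
  Y0 <- ifelse(obs, Y, 0)

  sw1 <- rowSums(Wm[, g1, drop = FALSE])
  sw2 <- rowSums(Wm[, g2, drop = FALSE])
  n1 <- rowSums(obs[, g1, drop = FALSE])
  n2 <- rowSums(obs[, g2, drop = FALSE])
  m1 <- rowSums((Wm * Y0)[, g1, drop = FALSE]) / sw1
  m2 <- rowSums((Wm * Y0)[, g2, drop = FALSE]) / sw2

  fitted <- matrix(0, nrow(Y), ncol(Y))
  fitted[, g1] <- m1
  fitted[, g2] <- m2
  rss <- rowSums(Wm * (Y0 - fitted)^2)
  d <- n1 + n2 - 2L
  ok <- n1 >= 2L & n2 >= 2L
  s2 <- ifelse(ok & d > 0, rss / d, NA_real_)
  list(beta = m2 - m1, s2 = s2, d = ifelse(ok, d, 0L),
       v = 1 / sw1 + 1 / sw2, n1 = n1, n2 = n2, ok = ok)
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits a scaled inverse-chi-square prior to the observed residual
#' variances by method of moments on the log scale. With
#' `e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2)`, the prior degrees of
#' freedom solve `trigamma(d0/2) = var(e) - mean(trigamma(d_g/2))` by
#' Newton inversion of the trigamma function (tolerance 1e-8), and the
#' prior variance is `exp(mean(e) + digamma(d0/2) - log(d0/2))`. When the
#' spread of the log variances does not exceed what sampling alone
#' explains, the prior degrees of freedom are infinite and the prior
#' variance is `exp(mean(e))`.
#'
#' @param s2 Residual sample variances.
#' @param d Residual degrees of freedom (recycled if length 1).
#' @return A `moderation_prior` object: list with `d0` (possibly `Inf`)
#'   and `s0_sq`.
#' @export
estimate_prior <- function(s2, d) {
  if (length(d) == 1L) d <- rep(d, length(s2))
  keep <- is.finite(s2) & d > 0
  if (!any(keep)) stop("no usable variance estimates", call. = FALSE)
  if (all(s2[keep] == 0))
    stop("degenerate data: all residual variances are zero", call. = FALSE)
  pos <- keep & s2 > 0
  if (sum(pos) < 2L)
    stop("need at least two positive residual variances", call. = FALSE)
  s2 <- s2[pos]; d <- d[pos]

  e <- log(s2) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e)
  rhs <- evar - mean(trigamma(d / 2))
  if (!is.finite(rhs) || rhs <= 0) {
    prior <- list(d0 = Inf, s0_sq = exp(emean))
  } else {
    d0 <- 2 * .trigamma_inverse(rhs)
    prior <- list(d0 = d0,
                  s0_sq = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  }
  class(prior) <- "moderation_prior"
  prior
}

# Newton solve of trigamma(x) = y for x > 0, tolerance 1e-8.
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

#' Moderated t-statistic and p-value
#'
#' Shrinks the residual variance toward the prior,
#' `s2_post = (d0 * s0_sq + d * s2) / (d0 + d)` (the limit `s0_sq` when
#' `d0` is infinite), and forms `t = beta / sqrt(s2_post * v)` with
#' `d0 + d` degrees of freedom. Two-sided p-values; the normal tail is
#' used when the total degrees of freedom are infinite. With `d0 = 0` the
#' moderation vanishes and the ordinary two-sample t-statistic is
#' recovered.
#'
#' @param beta Effect estimates (treatment minus control means).
#' @param s2 Residual variances.
#' @param d Residual degrees of freedom.
#' @param prior A `moderation_prior` from [estimate_prior()] (or a list
#'   with `d0`, `s0_sq`).
#' @param v Design scale: sum of inverse effective group sizes
#'   (`1/n_control + 1/n_treatment` for the unweighted two-group design).
#' @return A list with `t_mod`, `p`, `s2_post` and `df_total`.
#' @export
moderate <- function(beta, s2, d, prior, v) {
  d0 <- prior$d0
  s0 <- prior$s0_sq
  if (is.null(d0) || is.null(s0) || d0 < 0 || s0 <= 0)
    stop("invalid moderation prior", call. = FALSE)
  if (any(d0 + d <= 0)) stop("total degrees of freedom must be positive",
                             call. = FALSE)
  s2_post <- if (is.infinite(d0)) rep(s0, length(s2)) else
    (d0 * s0 + d * s2) / (d0 + d)
  t_mod <- beta / sqrt(s2_post * v)
  df_total <- d0 + d
  p <- if (is.infinite(d0)) 2 * pnorm(-abs(t_mod)) else
    2 * pt(-abs(t_mod), df = df_total)
  list(t_mod = t_mod, p = p, s2_post = s2_post, df_total = df_total)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: p-values are validated to lie
#' in [0, 1] and adjusted so that `q_(i) = min_{j >= i} min(1,
#' p_(j) * m / j)`, returned in input order.
#'
#' @param p Numeric vector of p-values in [0, 1] (`NA` passed through).
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad))
    stop("p-values outside [0, 1] at position ", which(bad)[1], call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Call significant features and build a volcano table
#'
#' Flags features with `p_adj <= alpha` (the boundary value is
#' significant) and annotates the direction of change from the sign of the
#' effect. The volcano table pairs each effect with `-log10(p_adj)` and an
#' optional user-supplied category label.
#'
#' @param results `data.frame` with at least `feature_id`, `log2fc` and
#'   `p_adj`.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param category Optional character vector of per-feature labels.
#' @return A list with `results` (input plus `significant`, `direction`)
#'   and `volcano` (`feature_id`, `log2fc`, `neg_log10_p_adj`,
#'   `category`).
#' @export
call_significant <- function(results, alpha = 0.05, category = NULL) {
  results$significant <- !is.na(results$p_adj) & results$p_adj <= alpha
  results$direction <- ifelse(results$log2fc < 0, "down", "up")
  volcano <- data.frame(
    feature_id = results$feature_id,
    log2fc = results$log2fc,
    neg_log10_p_adj = -log10(results$p_adj),
    category = if (is.null(category)) NA_character_ else category,
    stringsAsFactors = FALSE
  )
  list(results = results, volcano = volcano)
}

#' Differential phosphorylation test on a ratio matrix
#'
#' Runs the full differential engine: per-feature two-group least squares
#' on the phospho/protein log2 ratios, empirical-Bayes variance moderation
#' across features, two-sided moderated t p-values, Benjamini-Hochberg
#' adjustment and significance calls at `p_adj <= alpha`. Features with
#' fewer than two observations in either group are excluded before prior
#' estimation and reported via the `skipped` attribute.
#'
#' @param x A `ratio_matrix` (see [compute_log_ratios()]) or a plain
#'   numeric matrix (features x channels).
#' @param design A [channel_design()]; taken from `x` when absent.
#' @param weights Optional weight matrix, same shape as the value matrix.
#' @param alpha Significance threshold on adjusted p-values.
#' @return A `data.frame` with one row per tested feature: `feature_id`,
#'   `log2fc`, `s2`, `d`, `t_mod`, `p`, `p_adj`, `significant`,
#'   `direction`. Attributes: `prior` (the [estimate_prior()] fit),
#'   `skipped` (feature ids with insufficient data), `volcano`.
#' @examples
#' sim <- generate_phospho_dataset(sim_config(n_proteins = 50, seed = 1))
#' fl <- filter_psms(sim$psms)
#' rm_ <- compute_log_ratios(aggregate_psms_to_features(fl$psms),
#'                           sim$protein_groups, sim$design)
#' head(diff_test(rm_))
#' @export
diff_test <- function(x, design = NULL, weights = NULL, alpha = 0.05) {
  if (inherits(x, "ratio_matrix")) {
    Y <- x$ratios
    design <- design %||% x$design
  } else {
    Y <- as.matrix(x)
  }
  design <- .validate_design(design)
  if (ncol(Y) != nrow(design))
    stop("value matrix and design disagree on channel count", call. = FALSE)

  f <- .fit_two_group(Y, design, weights)
  ok <- f$ok & is.finite(f$s2)
  skipped <- rownames(Y)[!ok]
  if (!any(ok)) stop("no feature has enough observations to test",
                     call. = FALSE)

  prior <- estimate_prior(f$s2[ok], f$d[ok])
  mod <- moderate(f$beta[ok], f$s2[ok], f$d[ok], prior, f$v[ok])
  res <- data.frame(
    feature_id = rownames(Y)[ok] %||% as.character(which(ok)),
    log2fc = f$beta[ok],
    s2 = f$s2[ok],
    d = f$d[ok],
    t_mod = mod$t_mod,
    p = mod$p,
    stringsAsFactors = FALSE
  )
  res$p_adj <- adjust_bh(res$p)
  called <- call_significant(res, alpha = alpha)
  res <- called$results
  rownames(res) <- NULL
  attr(res, "prior") <- prior
  attr(res, "skipped") <- skipped
  attr(res, "volcano") <- called$volcano
  res
}
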