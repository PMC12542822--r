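des <- channel_design()

test_that("the two-group fit matches hand-computed pooled estimators", {
  f <- fit_feature_model(c(0, 0, 0, 1, 1, 1), des)
  expect_equal(f$beta, 1)
  expect_equal(f$s2, 0)
  expect_identical(as.integer(f$d), 4L)

  f <- fit_feature_model(c(0.1, 0.2, 0.3, -0.9, -1.0, -1.1), des)
  expect_equal(f$beta, -1.2)
  expect_equal(f$s2, 0.01)
  expect_identical(as.integer(f$d), 4L)
  # ordinary pooled two-sample t through the d0 = 0 moderation path
  mod <- moderate(f$beta, f$s2, f$d,
                  list(d0 = 0, s0_sq = 1), f$v)
  expect_equal(mod$t_mod, -14.6969, tolerance = 1e-4)
  tt <- t.test(c(-0.9, -1.0, -1.1), c(0.1, 0.2, 0.3), var.equal = TRUE)
  expect_equal(mod$t_mod, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(mod$p, tt$p.value, tolerance = 1e-10)

  f <- fit_feature_model(c(0.1, 0.2, 0.3, -0.9, NA, -1.1), des)
  expect_identical(as.integer(f$d), 3L)
})

test_that("features with fewer than two observations per group are flagged", {
  f <- fit_feature_model(c(0.1, NA, NA, -0.9, -1.0, -1.1), des)
  expect_false(f$ok)
})

test_that("with equal weights the weighted fit is the unweighted fit", {
  y <- c(0.3, -0.1, 0.2, -0.8, -1.2, -0.7)
  a <- fit_feature_model(y, des)
  b <- fit_feature_model(y, des, weights = rep(2, 6))
  expect_equal(a$beta, b$beta)
  # residual variance scales with the weights, t is invariant
  pa <- moderate(a$beta, a$s2, a$d, list(d0 = 0, s0_sq = 1), a$v)
  pb <- moderate(b$beta, b$s2, b$d, list(d0 = 0, s0_sq = 1), b$v)
  expect_equal(pa$t_mod, pb$t_mod)
})

test_that("identical variances force an infinite-df prior", {
  prior <- estimate_prior(rep(0.5, 10), 4)
  expect_identical(prior$d0, Inf)
  expect_equal(prior$s0_sq, exp(mean(log(0.5) - digamma(2) + log(2))))
})

test_that("prior estimation agrees with direct moment-equation evaluation", {
  # two-feature case: spread below the sampling floor, infinite prior df
  o <- prior_oracle(c(1, exp(1)), 4)
  p <- estimate_prior(c(1, exp(1)), 4)
  expect_identical(p$d0, o$d0)
  expect_equal(p$s0_sq, o$s0_sq, tolerance = 1e-10)

  # wide spread hits the finite branch; Newton vs uniroot inversion
  s2 <- c(0.1, 1, 10, 0.5, 2, 0.05, 4)
  o <- prior_oracle(s2, 4)
  p <- estimate_prior(s2, 4)
  expect_equal(p$d0, o$d0, tolerance = 1e-6)
  expect_equal(p$s0_sq, o$s0_sq, tolerance = 1e-8)
})

test_that("prior estimation recovers known hyperparameters from simulation", {
  set.seed(42)
  n <- 5000; d0 <- 4; s0 <- 1; d <- 4
  sigma2 <- s0 * d0 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, d) / d
  prior <- estimate_prior(s2, d)
  expect_equal(prior$d0, d0, tolerance = 0.2)
  expect_equal(prior$s0_sq, s0, tolerance = 0.1)
})

test_that("prior estimation matches limma's fit on shared input", {
  skip_if_not_installed("limma")
  set.seed(7)
  s2 <- exp(rnorm(200, 0, 1))
  ours <- estimate_prior(s2, 4)
  ref <- limma::fitFDist(s2, df1 = 4)
  expect_equal(ours$d0, ref$df2, tolerance = 1e-6)
  expect_equal(ours$s0_sq, ref$scale, tolerance = 1e-6)
})

test_that("degenerate variance inputs are refused", {
  expect_error(estimate_prior(c(0, 0, 0), 4), "degenerate|zero")
})

test_that("moderation obeys its limit cases", {
  # infinite prior df pins the posterior variance at the prior
  mod <- moderate(1, s2 = 5, d = 4, list(d0 = Inf, s0_sq = 2), v = 2 / 3)
  expect_equal(mod$s2_post, 2)
  # zero effect gives t = 0, p = 1
  mod <- moderate(0, 1, 4, list(d0 = 4, s0_sq = 1), 2 / 3)
  expect_equal(mod$t_mod, 0)
  expect_equal(mod$p, 1)
  expect_error(moderate(1, 1, 0, list(d0 = 0, s0_sq = 1), 1), "freedom")
})

test_that("the posterior variance lies between sample and prior variance", {
  set.seed(13)
  for (i in 1:50) {
    s2 <- exp(rnorm(1)); s0 <- exp(rnorm(1)); d0 <- runif(1, 0.5, 50)
    mod <- moderate(1, s2, 4, list(d0 = d0, s0_sq = s0), 2 / 3)
    expect_gte(mod$s2_post, min(s2, s0) - 1e-12)
    expect_lte(mod$s2_post, max(s2, s0) + 1e-12)
  }
})

test_that("BH adjustment matches the closed-form examples", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(adjust_bh(c(0.5, 1.2)), "position 2")
})

test_that("BH adjustment equals the brute-force step-up on random vectors", {
  set.seed(99)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_bh(p), bh_oracle(p))
  }
})

test_that("BH is permutation-equivariant", {
  set.seed(5)
  p <- runif(30)
  perm <- sample(30)
  expect_equal(adjust_bh(p)[perm], adjust_bh(p[perm]))
})

test_that("significance calls honour the inclusive threshold boundary", {
  res <- data.frame(feature_id = c("a", "b", "c"),
                    log2fc = c(-1, 2, 0.1),
                    p_adj = c(0.05, 0.051, 0.0001))
  out <- call_significant(res, alpha = 0.05)
  expect_identical(out$results$significant, c(TRUE, FALSE, TRUE))
  expect_identical(out$results$direction, c("down", "up", "up"))
  expect_equal(out$volcano$neg_log10_p_adj[3], 4)
})

test_that("the moderated pipeline agrees with limma on a complete matrix", {
  skip_if_not_installed("limma")
  set.seed(31)
  # heteroskedastic rows so the prior degrees of freedom come out finite
  sdr <- sqrt(4 / rchisq(300, 4))
  Y <- matrix(rnorm(300 * 6), 300, 6,
              dimnames = list(sprintf("f%03d", 1:300), NULL)) * sdr
  Y[1:30, 4:6] <- Y[1:30, 4:6] - 1
  ours <- diff_test(Y, des)
  expect_true(is.finite(attr(ours, "prior")$d0))

  dm <- stats::model.matrix(~ rep(c(0, 1), each = 3))
  fit <- limma::eBayes(limma::lmFit(Y, dm))
  expect_equal(ours$log2fc, unname(fit$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(ours$t_mod, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(ours$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
  expect_equal(ours$p_adj,
               unname(p.adjust(fit$p.value[, 2], "BH")), tolerance = 1e-6)
})

test_that("null simulations yield calibrated moderated p-values", {
  sim <- generate_phospho_dataset(
    sim_config(n_proteins = 400, peptides_per_protein = 2L,
               effect_fraction = 0, seed = 17))
  res <- run_tmt_stages(sim)
  # raw p-values approximately uniform: rejection rate near alpha
  for (alpha in c(0.05, 0.2)) {
    frac <- mean(res$p <= alpha)
    se <- sqrt(alpha * (1 - alpha) / nrow(res))
    expect_lt(abs(frac - alpha), 4 * se + 0.005)
  }
})

test_that("features lacking observations are excluded before the prior", {
  Y <- matrix(rnorm(60), 10, 6)
  Y[1, 1:2] <- NA  # one control observation only
  rownames(Y) <- paste0("f", 1:10)
  res <- diff_test(Y, des)
  expect_identical(attr(res, "skipped"), "f1")
  expect_identical(nrow(res), 9L)
})
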