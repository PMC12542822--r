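tc_design <- function(stages = "MI", n_bio = 2, n_tech = 3) {
  g <- expand.grid(tech_rep = seq_len(n_tech), bio_rep = seq_len(n_bio),
                   condition = c("control", "treatment"), stage = stages,
                   stringsAsFactors = FALSE)
  time_course_design(
    run = sprintf("%s_%s_b%d_t%d", g$stage, g$condition, g$bio_rep,
                  g$tech_rep),
    condition = g$condition, stage = g$stage, bio_rep = g$bio_rep,
    tech_rep = g$tech_rep)
}

test_that("DIA q-value filters keep inclusive boundaries", {
  rows <- data.frame(
    run = "r1", protein_group = sprintf("P%d", 1:8),
    precursor = sprintf("pr%d", 1:8),
    q_value   = c(0.001, 0.002, 0.0005, 0.001, 0.01, 0.0001, 0.001, 0.0009),
    pg_q_value = c(0.05, 0.01, 0.06, 0.01, 0.06, 0.05, 0.04, 0.04),
    quantity = 1000)
  out <- filter_dia(rows)
  # three rows fail one or both filters: P2 (q), P3 (pg), P5 (q and pg)
  expect_identical(out$report$retained, nrow(rows) - out$report$removed)
  expect_true("P1" %in% out$rows$protein_group)   # both exactly at bound
  expect_false("P2" %in% out$rows$protein_group)  # q = 0.002 removed
  expect_false("P3" %in% out$rows$protein_group)
  expect_false("P5" %in% out$rows$protein_group)
  expect_identical(out$report$retained, 5L)
})

test_that("matrix building log-transforms, averages and centers", {
  des <- tc_design()
  quant <- matrix(1000, 3, 12, dimnames = list(paste0("P", 1:3), des$run))
  quant["P2", des$condition == "control" & des$bio_rep == 1] <-
    10^c(3.0, 3.1, 3.2)
  dm <- build_dia_matrix(quant, des, center = TRUE)
  expect_equal(dm$log10["P1", 1], 3)             # quantity 1000 -> 3.0
  expect_equal(dm$log10["P2", "MI_control_b1"], 3.1)  # tech-rep mean
  expect_identical(ncol(dm$log10), 4L)           # 2 cond x 2 bio

  m <- matrix(10^c(3, 4, 5), 1, 3,
              dimnames = list("P1", des$run[c(1, 4, 7)]))
  ctr <- build_dia_matrix(m, des, center = TRUE)$centered
  expect_equal(unname(ctr[1, ]), c(-1, 0, 1))

  bad <- matrix(1, 1, 1, dimnames = list("P1", "unknown_run"))
  expect_error(build_dia_matrix(bad, des), "unknown_run")
})

test_that("imputation follows the group-minimum rule with weight 0.05", {
  des <- tc_design()
  quant <- matrix(NA_real_, 3, 12, dimnames = list(paste0("P", 1:3),
                                                   des$run))
  ctrl <- des$run[des$condition == "control" & des$tech_rep == 1]
  trt <- des$run[des$condition == "treatment" & des$tech_rep == 1]
  # P1: one missing bio replicate in control
  quant["P1", ctrl] <- 10^c(5.0, NA)[c(1, 2)]
  quant["P1", ctrl[1]] <- 10^5.0
  quant["P1", trt] <- 10^c(5.2, 5.4)
  # P2: observed only in control -> treatment takes protein-wide minimum
  quant["P2", ctrl] <- 10^c(4.0, 4.6)
  # P3: fully observed
  quant["P3", c(ctrl, trt)] <- 10^c(3.0, 3.1, 3.2, 3.3)
  dm <- impute_and_weight(build_dia_matrix(quant, des))

  # P1's missing control cell takes the control-group minimum 5.0
  expect_equal(dm$log10["P1", "MI_control_b2"], 5.0)
  expect_equal(unname(dm$weights["P1", "MI_control_b2"]), 0.05)
  expect_equal(unname(dm$weights["P1", "MI_control_b1"]), 1)
  # P2's treatment cells fall back to the protein-wide minimum 4.0
  expect_equal(unname(dm$log10["P2", c("MI_treatment_b1",
                                       "MI_treatment_b2")]), c(4, 4))
  expect_true(all(dm$weights["P2", c("MI_treatment_b1",
                                     "MI_treatment_b2")] == 0.05))
  # P3 untouched, all weights 1
  expect_true(all(dm$weights["P3", ] == 1))
  expect_equal(unname(dm$log10["P3", ]), c(3.0, 3.1, 3.2, 3.3))
})

test_that("imputation never alters observed cells nor loses finite cells", {
  cfg <- sim_config(n_proteins = 80, missing_rate = 0.15, seed = 19)
  sim <- generate_dia_timecourse(cfg, stages = c("GV", "MI"))
  dm0 <- build_dia_matrix(sim$quant, sim$design)
  dm1 <- suppressMessages(impute_and_weight(dm0))
  common <- rownames(dm1$log10)
  obs <- !is.na(dm0$log10[common, ])
  expect_equal(dm1$log10[common, ][obs], dm0$log10[common, ][obs])
  expect_gte(sum(is.finite(dm1$log10)), sum(is.finite(dm0$log10)))
  expect_true(all(dm1$weights %in% c(1, 0.05)))
  expect_identical(unname(dm1$weights == 0.05), unname(dm1$imputed))
})

test_that("a fully observed matrix passes through imputation unchanged", {
  cfg <- sim_config(n_proteins = 40, missing_rate = 0, seed = 20)
  sim <- generate_dia_timecourse(cfg, stages = "MI")
  dm0 <- build_dia_matrix(sim$quant, sim$design)
  dm1 <- impute_and_weight(dm0)
  expect_equal(dm1$log10, dm0$log10)
  expect_true(all(dm1$weights == 1))
})

test_that("with all weights 1 the DIA test equals the unweighted engine", {
  cfg <- sim_config(n_proteins = 60, effect_fraction = 0.1,
                    missing_rate = 0, seed = 25)
  sim <- generate_dia_timecourse(cfg, stages = "MI")
  dm <- impute_and_weight(build_dia_matrix(sim$quant, sim$design))
  weighted <- differential_dia(dm, "MI")
  des <- data.frame(channel = 1:4, condition = dm$samples$condition)
  plain <- diff_test(dm$log10, des)
  expect_equal(weighted$log10_diff, plain$log2fc)
  expect_equal(weighted$t_mod, plain$t_mod)
  expect_equal(weighted$p, plain$p)
  expect_equal(weighted$p_adj, plain$p_adj)
})

test_that("weighted fits lie between observed-only and all-equal fits", {
  # 1-D bracketing: one imputed treatment cell pulled low
  des <- tc_design(n_bio = 3)
  runs1 <- des$run[des$tech_rep == 1]
  quant <- matrix(NA_real_, 2, nrow(des), dimnames = list(c("P1", "P2"),
                                                          des$run))
  quant["P1", runs1] <- 10^c(5.0, 5.1, 5.2, 5.5, 5.6, NA)
  quant["P2", runs1] <- 10^c(4, 4.2, 4.1, 4.4, 4.3, 4.5)
  dm <- impute_and_weight(build_dia_matrix(quant, des))
  w <- differential_dia(dm, "MI")
  beta_w <- w$log10_diff[w$protein_id == "P1"]

  obs_only <- mean(c(5.5, 5.6)) - mean(c(5.0, 5.1, 5.2))
  imp_min <- 5.0
  all_equal <- mean(c(5.5, 5.6, imp_min)) - mean(c(5.0, 5.1, 5.2))
  expect_gte(beta_w, min(obs_only, all_equal) - 1e-12)
  expect_lte(beta_w, max(obs_only, all_equal) + 1e-12)
})

test_that("the reliably-changed call needs both p and effect size", {
  des <- tc_design(n_bio = 3)
  runs1 <- des$run[des$tech_rep == 1]
  set.seed(44)
  quant <- matrix(NA_real_, 40, nrow(des),
                  dimnames = list(sprintf("P%02d", 1:40), des$run))
  base <- rnorm(40, 5, 0.5)
  noise <- matrix(rnorm(40 * 6, 0, 0.02), 40, 6)
  vals <- base + noise
  # P01: large, clean shift (called); P02: clean but small shift (not called)
  vals[1, 4:6] <- vals[1, 4:6] + 1
  vals[2, 4:6] <- vals[2, 4:6] + 0.1  # log2fc 0.33, below the 0.5 bound
  quant[, runs1] <- 10^vals
  dm <- impute_and_weight(build_dia_matrix(quant, des))
  res <- differential_dia(dm, "MI", alpha = 0.05, lfc_min = 0.5)
  r1 <- res[res$protein_id == "P01", ]
  r2 <- res[res$protein_id == "P02", ]
  expect_true(r1$significant)
  expect_identical(r1$direction, "up")
  expect_true(r2$p_adj <= 0.05)       # significant p ...
  expect_false(r2$large_effect)       # ... but below the effect threshold
  expect_false(r2$significant)
  # the effect-size bound is inclusive at exactly 0.5
  expect_identical(res$large_effect, abs(res$log2fc) >= 0.5)
})

test_that("the exact log2FC boundary value 0.5 is called", {
  d10 <- 0.5 / log2(10)
  expect_identical(d10 * log2(10), 0.5)  # representable boundary
  res <- data.frame(feature_id = "P1", log2fc = d10 * log2(10),
                    p_adj = 0.01)
  expect_true(abs(res$log2fc) >= 0.5)
})
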