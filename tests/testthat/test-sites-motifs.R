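test_that("site probabilities are mean-aggregated across PSMs", {
  one <- make_psms("AKSPSTYR", probs = list(c("3" = 0.9, "5" = 0.1)))
  s <- aggregate_site_probabilities(one)
  expect_identical(s$peptide_position, 3L)
  expect_identical(s$residue, "S")
  expect_equal(s$mean_probability, 0.9)

  two <- make_psms(rep("AKSPSTYR", 2),
                   probs = list(c("3" = 0.9, "5" = 0.1),
                                c("3" = 0.4, "5" = 0.6)))
  s <- aggregate_site_probabilities(two)
  m <- attr(s, "position_means")[["AKSPSTYR"]]
  expect_equal(m, c("3" = 0.65, "5" = 0.35))
  expect_identical(s$peptide_position, 3L)
})

test_that("positions absent from one PSM's vector contribute zero", {
  psms <- make_psms(rep("AKSPSTYR", 2),
                    probs = list(c("3" = 0.8), c("5" = 0.8)))
  m <- attr(aggregate_site_probabilities(psms), "position_means")[[1]]
  expect_equal(m, c("3" = 0.4, "5" = 0.4))
})

test_that("exact ties resolve to the lowest position", {
  psms <- make_psms(rep("AKSPSTYR", 2),
                    probs = list(c("3" = 0.5, "5" = 0.5),
                                 c("3" = 0.5, "5" = 0.5)))
  s <- aggregate_site_probabilities(psms)
  expect_identical(s$peptide_position, 3L)
})

test_that("aggregation is invariant to PSM order", {
  psms <- make_psms(rep("AKSPSTYR", 3),
                    probs = list(c("3" = 0.2, "5" = 0.7), c("6" = 1),
                                 c("3" = 0.9)))
  a <- aggregate_site_probabilities(psms)
  b <- aggregate_site_probabilities(psms[c(3, 1, 2), ])
  expect_equal(a$peptide_position, b$peptide_position)
  expect_equal(attr(a, "position_means"), attr(b, "position_means"))
})

test_that("peptides without any localization are flagged unlocalizable", {
  psms <- make_psms("AKSPSTYR", probs = list(setNames(numeric(0),
                                                      character(0))))
  s <- aggregate_site_probabilities(psms)
  expect_true(s$unlocalizable)
  expect_true(is.na(s$peptide_position))
})

test_that("windows are centered, padded at termini and verified", {
  prot <- c(PG1 = "SAAAAAAAAAAKRRRT")
  sites <- data.frame(peptide_sequence = "SAAAAAAA", protein_group_id = "PG1",
                      residue = "S", peptide_position = 1L,
                      mean_probability = 1, n_psms = 1L,
                      unlocalizable = FALSE, stringsAsFactors = FALSE)
  w <- center_windows(sites, prot, w = 7)
  expect_identical(w$protein_position, 1L)
  expect_identical(w$window, "-------SAAAAAAA")  # 7 leading gaps

  mid <- data.frame(peptide_sequence = "AAAAKRRRT", protein_group_id = "PG1",
                    residue = "T", peptide_position = 9L,
                    mean_probability = 1, n_psms = 1L,
                    unlocalizable = FALSE, stringsAsFactors = FALSE)
  w <- center_windows(mid, prot, w = 7)
  expect_identical(w$protein_position, 16L)
  expect_identical(nchar(w$window), 15L)
  expect_identical(substr(w$window, 8, 8), "T")

  # literal 15-mer for a fully internal site
  prot2 <- c(PG2 = paste0(strrep("A", 10), "KRSPK", strrep("G", 10)))
  s2 <- data.frame(peptide_sequence = "KRSPK", protein_group_id = "PG2",
                   residue = "S", peptide_position = 3L,
                   mean_probability = 1, n_psms = 1L,
                   unlocalizable = FALSE, stringsAsFactors = FALSE)
  w2 <- center_windows(s2, prot2, w = 7)
  expect_identical(w2$window, unname(substr(prot2, 6, 20)))

  # a wrong claimed protein position must be refused
  s2$protein_position <- 5L
  expect_error(center_windows(s2, prot2, w = 7), "mismatch")
})

test_that("motif matrix is zero when foreground equals background", {
  set.seed(3)
  wins <- vapply(1:20, function(i)
    paste(sample(c("A", "R", "S", "P", "K"), 15, replace = TRUE),
          collapse = ""), character(1))
  mm <- motif_information_content(wins, wins, pseudocount = 0.5)
  expect_true(all(mm$ic == 0))
})

test_that("full conservation over a uniform background scores exactly 1", {
  aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  # background: each residue once at every position => b = 1/20
  bg <- vapply(seq_along(aa20), function(i)
    strrep(aa20[i], 3), character(1))
  fg <- rep("SSP", 4)  # foreground all 'P' at +1
  mm <- motif_information_content(fg, bg, pseudocount = 0)
  expect_equal(mm$ic["1", "P"], 1)
})

test_that("motif matrix equals the brute-force frequency/KL oracle", {
  set.seed(8)
  alphabet <- c("A", "R", "N", "D", "S", "T", "P", "K", "G", "L")
  rand <- function(n) vapply(seq_len(n), function(i)
    paste(sample(alphabet, 15, replace = TRUE), collapse = ""), character(1))
  fg <- rand(10)
  bg <- rand(50)
  for (pc in c(0, 0.5)) {
    mm <- suppressMessages(motif_information_content(fg, bg,
                                                     pseudocount = pc))
    expect_equal(unname(mm$ic), unname(motif_oracle(fg, bg, pc)),
                 tolerance = 1e-12)
  }
})

test_that("motif values stay in [0,1] and depend on frequencies not counts", {
  set.seed(9)
  rand <- function(n) vapply(seq_len(n), function(i)
    paste(sample(c("A", "S", "P", "K", "R"), 15, replace = TRUE),
          collapse = ""), character(1))
  fg <- rand(8); bg <- rand(30)
  mm1 <- motif_information_content(fg, bg, pseudocount = 0)
  expect_true(all(mm1$ic >= 0 & mm1$ic <= 1))
  mm2 <- motif_information_content(rep(fg, 2), rep(bg, 2), pseudocount = 0)
  expect_equal(mm1$ic, mm2$ic)
})

test_that("gap padding is excluded from motif frequencies", {
  fg <- c("--ASPKR", "--ASPKR")
  bg <- c("KKASPKR", "RRASPKR")
  mm <- motif_information_content(fg, bg, pseudocount = 0)
  # at the padded positions the foreground has no observations at all
  expect_identical(unname(mm$fg_n[1:2]), c(0, 0))
  expect_true(all(mm$ic[1:2, ] == 0))
})

test_that("kinase subsets honour the inclusive top-rank rule", {
  sites <- data.frame(
    peptide_sequence = sprintf("PEP%d", 1:6),
    protein_group_id = "PG1", residue = "S", peptide_position = 1L,
    mean_probability = 1, n_psms = 1L, unlocalizable = FALSE,
    stringsAsFactors = FALSE)
  ks <- data.frame(peptide = sprintf("PEP%d", 1:5),
                   kinase = "MAPK1",
                   rank = c(1L, 3L, 10L, 11L, 20L))
  sel <- select_kinase_subset(sites, ks, "MAPK1", rank_max = 10)
  expect_identical(sel$peptide_sequence, c("PEP1", "PEP2", "PEP3"))
  expect_false("PEP4" %in% sel$peptide_sequence)  # rank 11 out
  expect_false("PEP6" %in% sel$peptide_sequence)  # missing from table
  expect_warning(none <- select_kinase_subset(sites, ks, "CDK1"),
                 "absent")
  expect_identical(nrow(none), 0L)
})
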