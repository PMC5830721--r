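test_that("chi-squared matches the hand Pearson formula", {
  tab <- matrix(c(10, 20, 20, 10), 2, 2, byrow = TRUE)
  out <- chi_square(tab)
  expect_equal(out$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(out$df, 1)
  orc <- oracle_pearson_chisq(tab)
  expect_equal(out$statistic, orc$statistic, tolerance = 1e-12)
  expect_equal(out$p_value, orc$p, tolerance = 1e-12)
})

test_that("chi-squared degenerate and symmetry contracts hold", {
  same <- rbind(c(30, 50, 20), c(30, 50, 20))
  out <- chi_square(same)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)

  tab <- rbind(c(5, 9, 30), c(12, 7, 20))
  perm <- tab[, c(3, 1, 2)]
  expect_equal(chi_square(tab)$statistic, chi_square(perm)$statistic,
               tolerance = 1e-12)

  zero_col <- rbind(c(5, 0, 30), c(12, 0, 20))
  expect_error(chi_square(zero_col), "merge")
})

test_that("t tests and correlation agree with hand oracles on random data", {
  withr::with_seed(17, {
    for (i in 1:50) {
      a <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
      b <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
      w <- welch_t(a, b)
      orc <- oracle_welch(a, b)
      expect_equal(w$statistic, orc$statistic, tolerance = 1e-9)
      expect_equal(w$df, orc$df, tolerance = 1e-9)
      expect_equal(w$p_value, orc$p, tolerance = 1e-6)

      n <- sample(5:30, 1)
      x <- rnorm(n); y <- rnorm(n)
      p <- paired_t(x, y)
      orc <- oracle_paired(x, y)
      expect_equal(p$statistic, orc$statistic, tolerance = 1e-9)
      expect_equal(p$p_value, orc$p, tolerance = 1e-6)

      r <- pearson_r(x, y)
      orc <- oracle_pearson_r(x, y)
      expect_equal(r$r, orc$r, tolerance = 1e-9)
      expect_equal(r$statistic, orc$statistic, tolerance = 1e-9)
      expect_equal(r$p_value, orc$p, tolerance = 1e-6)
    }
  })
})

test_that("identical-sample degenerate cases return t = 0, p = 1", {
  a <- c(1.2, 3.4, 2.2, 5.1)
  w <- welch_t(a, a)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 1)
  p <- paired_t(a, a)
  expect_equal(p$statistic, 0)
  expect_equal(p$p_value, 1)
})

test_that("zero-variance inputs error", {
  expect_error(welch_t(rep(1, 5), rep(2, 5)), "zero variance")
  expect_error(paired_t(1:5, 1:5 - 2), "constant non-zero")
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("Welch reduces to the pooled test for equal variances and sizes", {
  withr::with_seed(23, {
    a <- rnorm(20)
    b <- a - mean(a) + 0.8 # identical spread, shifted mean
    w <- welch_t(a, b)
    s <- welch_t(a, b, pooled = TRUE)
    expect_equal(w$statistic, s$statistic, tolerance = 1e-9)
    expect_equal(w$df, s$df, tolerance = 1e-9)
    expect_equal(w$p_value, s$p_value, tolerance = 1e-9)
  })
})

test_that("perfect linear dependence and independent noise behave as expected", {
  x <- seq(1, 10, by = 0.5)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  withr::with_seed(9, {
    out <- pearson_r(rnorm(5000), rnorm(5000))
    expect_lt(abs(out$r), 0.05)
  })
})

test_that("cohort summary conserves counts and normalizes histograms", {
  ref <- simulate_bond_cohort(120, seed = 41, chi3_location = 90)
  lab <- simulate_bond_cohort(60, seed = 42, chi3_location = 20, labile = TRUE)
  bonds <- dplyr::bind_rows(ref, lab)
  cs <- summarize_cohorts(bonds)
  expect_equal(sum(cs$config_table["reference", ]), 180) # reference = all bonds
  expect_equal(sum(cs$config_table["labile", ]), 60)
  expect_equal(sum(cs$ss_table["labile", ]), 60)
  for (h in cs$histograms) {
    expect_equal(sum(h$reference$rel_freq), 1, tolerance = 1e-9)
    expect_equal(sum(h$labile$rel_freq), 1, tolerance = 1e-9)
  }
  td <- generics::tidy(cs)
  expect_true(all(c("configuration_chisq", "dse_t", "allosteric_subset_dse_t")
                  %in% td$test))
  g <- generics::glance(cs)
  expect_equal(g$n_reference, 180)
  expect_equal(g$n_labile, 60)
})

test_that("two statistically identical cohorts yield null test results", {
  ref <- simulate_bond_cohort(80, seed = 51, chi3_location = 60)
  lab <- ref
  lab$labile <- TRUE
  lab$accession <- paste0(lab$accession, "L")
  cs <- summarize_cohorts(dplyr::bind_rows(ref, lab))
  # the labile cohort duplicates the non-labile set, so all class
  # proportions match exactly
  expect_equal(cs$config_test$statistic, 0, tolerance = 1e-9)
  expect_equal(cs$config_test$p_value, 1, tolerance = 1e-9)
})

test_that("a single-configuration cohort concentrates its frequency table", {
  geoms <- add_configuration(tibble::tibble(
    chi1 = rep(-60, 10), chi2 = -60, chi3 = -90, chi2p = -60, chi1p = -60))
  bonds <- dplyr::mutate(geoms, accession = sprintf("P%02d", 1:10),
                         pos_i = 1L, pos_j = 2L,
                         alpha1 = 104, alpha2 = 104, d = 2.038, dse = 2.51,
                         b_avg = 20, ss_pair = "loop-loop",
                         labile = rep(c(TRUE, FALSE), 5), in_reference = TRUE)
  cs <- summarize_cohorts(bonds)
  tab <- cs$config_table["reference", ]
  expect_equal(sum(tab > 0), 1)
  expect_equal(unname(tab["-LHspiral"]), 10)
})

test_that("a chi3-eclipsed labile cohort shows recoverable excess strain", {
  ref <- simulate_bond_cohort(200, seed = 61, chi3_location = 90)
  lab <- simulate_bond_cohort(200, seed = 62, chi3_location = 15, labile = TRUE)
  cs <- summarize_cohorts(dplyr::bind_rows(ref, lab))
  dse_row <- cs$metric_tests[cs$metric_tests$metric == "dse", ]
  expect_gt(dse_row$mean_a, dse_row$mean_b) # labile mean exceeds reference
  expect_lt(dse_row$p_value, 0.05)
})

test_that("the paired B-factor control uses per-bond present/missing means", {
  obs <- tibble::tibble(
    accession = rep(c("P1", "P2", "P3"), each = 2),
    pos_i = 10L, pos_j = 40L,
    pdb_id = rep(c("1AAA", "1BBB"), 3),
    chain = "A",
    status = rep(c("present", "missing"), 3),
    b_avg = c(20, 22, 35, 33, 28, 28.5))
  pt <- oracle_paired(c(20, 35, 28), c(22, 33, 28.5))
  ref <- simulate_bond_cohort(20, seed = 71)
  lab <- simulate_bond_cohort(10, seed = 72, labile = TRUE)
  cs <- summarize_cohorts(dplyr::bind_rows(ref, lab), observations = obs)
  expect_equal(cs$b_factor_test$statistic, pt$statistic, tolerance = 1e-9)
  expect_equal(cs$b_factor_test$n_pairs, 3)
})

test_that("empty cohorts are an error", {
  ref <- simulate_bond_cohort(10, seed = 81)
  expect_error(summarize_cohorts(ref), "empty cohort")
})

test_that("annotation tallies cross-tabulate without testing", {
  bonds <- tibble::tibble(accession = c("P1", "P1", "P2", "P3"),
                          labile = c(TRUE, FALSE, FALSE, TRUE))
  ann <- tibble::tibble(accession = c("P1", "P2"),
                        functional_class = c("oxidoreductase", "hydrolase"))
  out <- tally_annotations(bonds, ann, "functional_class")
  expect_equal(out$n_all[out$level == "oxidoreductase"], 2)
  expect_equal(out$n_labile[out$level == "oxidoreductase"], 1)
  expect_equal(out$n_all[out$level == "unannotated"], 1)
})
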