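#' Pearson chi-squared test on a contingency table
#'
#' Expected counts are formed from the marginal products; any zero expected
#' cell is an error (merge bins first). The statistic and p value come from
#' the standard Pearson test without continuity correction.
#'
#' @param tab Matrix or data frame of non-negative counts.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(!is.finite(tab))) {
    stop("chi_square(): counts must be finite and non-negative", call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    stop("chi_square(): zero expected cell; merge sparse bins before testing",
         call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value))
}

#' Welch two-sample t test
#'
#' Two-sided Welch test (Satterthwaite degrees of freedom). Set
#' `pooled = TRUE` for the classical equal-variance Student test.
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @param pooled Use the pooled-variance Student test instead of Welch.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(a, b, pooled = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    stop("welch_t(): zero variance in both samples", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = pooled)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 mean_a = mean(a), mean_b = mean(b))
}

#' Paired t test
#'
#' Two-sided paired t test on equal-length samples. Identical pairs (all
#' differences zero) return t = 0, p = 1 rather than erroring, matching the
#' degenerate-case contract.
#'
#' @param x,y Paired numeric samples of equal length (n >= 2).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `mean_difference`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble::tibble(statistic = 0, df = length(d) - 1, p_value = 1,
                            mean_difference = 0))
    }
    stop("paired_t(): constant non-zero differences", call. = FALSE)
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 mean_difference = mean(d))
}

#' Pearson correlation with t-transform p value
#'
#' @param x,y Numeric vectors (n >= 3), neither constant.
#' @return One-row tibble: `r`, `statistic`, `df`, `p_value`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_r(): zero variance", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ht$estimate),
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value))
}

hist_relfreq <- function(x, breaks) {
  x <- x[x >= breaks[1] & x <= breaks[length(breaks)]]
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  tibble::tibble(mid = h$mids, rel_freq = h$counts / max(1, length(x)))
}

count_table <- function(values, levels) {
  table(factor(values, levels = levels))
}

#' Compare labile bonds against the reference cohort
#'
#' Computes, for the reference cohort (all length-filter-passing unique
#' bonds, optionally restricted to a pre-culled chain list) and the labile
#' cohort:
#'
#' * configuration frequencies over the 20 classes and a chi-squared test;
#' * secondary-structure pair frequencies and a chi-squared test;
#' * means/SDs and Welch t tests for DSE, S-S distance and the average alpha
#'   angle, plus relative-frequency histograms over the conventional ranges
#'   (DSE 0-60 kJ/mol, d 1.96-2.14 angstrom, alpha 95-120 degrees);
#' * the allosteric-configuration subset comparison: DSE of labile bonds in
#'   the -RHstaple / -LHhook / -/+RHhook classes versus all reference bonds;
#' * when `observations` are supplied, the paired B-factor control: per
#'   labile bond, the mean 12-atom B of its present observations against the
#'   mean of its missing observations, paired t test.
#'
#' Configuration/ss categories with zero counts in both cohorts are dropped
#' before the chi-squared tests (their expected counts would be zero).
#'
#' @param bonds Unique-bond tibble from [mine_corpus()]/[aggregate_bonds()].
#' @param observations Optional observation tibble (for the B-factor
#'   control).
#' @param allosteric_subset Configuration names defining the allosteric
#'   subset.
#' @param pooled Use pooled-variance t tests instead of Welch.
#' @return An object of class `cohort_summary`.
#' @export
summarize_cohorts <- function(bonds, observations = NULL,
                              allosteric_subset = allosteric_configurations(),
                              pooled = FALSE) {
  with_geom <- bonds[!is.na(bonds$dse) & bonds$in_reference, , drop = FALSE]
  reference <- with_geom
  labile <- with_geom[with_geom$labile, , drop = FALSE]
  if (nrow(reference) == 0 || nrow(labile) == 0) {
    stop("summarize_cohorts(): empty cohort (no labile or no reference bonds with geometry)",
         call. = FALSE)
  }
  reference$alpha_avg <- (reference$alpha1 + reference$alpha2) / 2
  labile$alpha_avg <- (labile$alpha1 + labile$alpha2) / 2

  config_tab <- rbind(
    reference = count_table(reference$config, configuration_names()),
    labile = count_table(labile$config, configuration_names()))
  ss_levels <- c("helix-helix", "helix-strand", "helix-loop",
                 "strand-strand", "strand-loop", "loop-loop")
  ss_tab <- rbind(reference = count_table(reference$ss_pair, ss_levels),
                  labile = count_table(labile$ss_pair, ss_levels))

  drop_empty <- function(tab) tab[, colSums(tab) > 0, drop = FALSE]
  test_or_na <- function(tab) {
    tab <- drop_empty(tab)
    if (ncol(tab) < 2) {
      return(tibble::tibble(statistic = NA_real_, df = NA_real_,
                            p_value = NA_real_))
    }
    chi_square(tab)
  }
  config_test <- test_or_na(config_tab)
  ss_test <- test_or_na(ss_tab)

  # degenerate metrics (e.g. a constant S-S distance in an idealized cohort)
  # report their means with NA test results instead of failing the summary
  safe_welch <- function(a, b) {
    tryCatch(welch_t(a, b, pooled = pooled), error = function(e) {
      tibble::tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                     mean_a = mean(a), mean_b = mean(b))
    })
  }
  metric_tests <- dplyr::bind_rows(lapply(
    c(dse = "dse", d = "d", alpha = "alpha_avg"),
    function(col) safe_welch(labile[[col]], reference[[col]])))
  metric_tests$metric <- c("dse", "d", "alpha")

  allo <- labile[labile$config %in% allosteric_subset, , drop = FALSE]
  allo_test <- if (nrow(allo) >= 2) {
    cbind(safe_welch(allo$dse, reference$dse), n_subset = nrow(allo))
  } else {
    tibble::tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                   mean_a = ifelse(nrow(allo) > 0, mean(allo$dse), NA_real_),
                   mean_b = mean(reference$dse), n_subset = nrow(allo))
  }

  b_paired <- NULL
  if (!is.null(observations)) {
    pairs <- observations |>
      dplyr::filter(startsWith(.data$status, "present") |
                      .data$status == "missing",
                    !is.na(.data$b_avg)) |>
      dplyr::mutate(state = ifelse(startsWith(.data$status, "present"),
                                   "present", "missing")) |>
      dplyr::group_by(.data$accession, .data$pos_i, .data$pos_j, .data$state) |>
      dplyr::summarise(b = mean(.data$b_avg), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "state", values_from = "b") |>
      dplyr::filter(!is.na(.data$present), !is.na(.data$missing))
    if (nrow(pairs) >= 2) {
      b_paired <- cbind(paired_t(pairs$present, pairs$missing),
                        mean_present = mean(pairs$present),
                        mean_missing = mean(pairs$missing),
                        n_pairs = nrow(pairs))
    }
  }

  cohort_stats <- function(df, name) {
    tibble::tibble(
      cohort = name, n = nrow(df),
      mean_dse = mean(df$dse), sd_dse = stats::sd(df$dse),
      mean_d = mean(df$d), sd_d = stats::sd(df$d),
      mean_alpha = mean(df$alpha_avg), sd_alpha = stats::sd(df$alpha_avg))
  }

  structure(list(
    cohorts = dplyr::bind_rows(cohort_stats(reference, "reference"),
                               cohort_stats(labile, "labile")),
    config_table = config_tab,
    ss_table = ss_tab,
    config_test = config_test,
    ss_test = ss_test,
    metric_tests = metric_tests,
    allosteric_test = allo_test,
    b_factor_test = b_paired,
    histograms = list(
      dse = list(reference = hist_relfreq(reference$dse, seq(0, 60, by = 2.5)),
                 labile = hist_relfreq(labile$dse, seq(0, 60, by = 2.5))),
      d = list(reference = hist_relfreq(reference$d, seq(1.96, 2.14, by = 0.01)),
               labile = hist_relfreq(labile$d, seq(1.96, 2.14, by = 0.01))),
      alpha = list(reference = hist_relfreq(reference$alpha_avg, seq(95, 120, by = 1)),
                   labile = hist_relfreq(labile$alpha_avg, seq(95, 120, by = 1)))),
    allosteric_subset = allosteric_subset),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print(x$cohorts)
  cat(sprintf("configuration chi-squared: X2 = %.3f, df = %s, p = %.3g\n",
              x$config_test$statistic, format(x$config_test$df),
              x$config_test$p_value))
  for (i in seq_len(nrow(x$metric_tests))) {
    m <- x$metric_tests[i, ]
    cat(sprintf("%-5s labile %.3f vs reference %.3f: t = %.3f, p = %.3g\n",
                m$metric, m$mean_a, m$mean_b, m$statistic, m$p_value))
  }
  if (!is.null(x$b_factor_test)) {
    cat(sprintf("B-factor paired t (present %.2f vs missing %.2f): t = %.3f, p = %.3g\n",
                x$b_factor_test$mean_present, x$b_factor_test$mean_missing,
                x$b_factor_test$statistic, x$b_factor_test$p_value))
  }
  invisible(x)
}

#' Tidy a cohort summary into one row per statistical test
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return Tibble with columns `test`, `statistic`, `df`, `p_value` and the
#'   cohort means where applicable.
#' @export
tidy.cohort_summary <- function(x, ...) {
  rows <- list(
    tibble::tibble(test = "configuration_chisq",
                   statistic = x$config_test$statistic, df = x$config_test$df,
                   p_value = x$config_test$p_value),
    tibble::tibble(test = "ss_pair_chisq", statistic = x$ss_test$statistic,
                   df = x$ss_test$df, p_value = x$ss_test$p_value),
    tibble::tibble(test = paste0(x$metric_tests$metric, "_t"),
                   statistic = x$metric_tests$statistic,
                   df = x$metric_tests$df, p_value = x$metric_tests$p_value,
                   mean_labile = x$metric_tests$mean_a,
                   mean_reference = x$metric_tests$mean_b),
    tibble::tibble(test = "allosteric_subset_dse_t",
                   statistic = x$allosteric_test$statistic,
                   df = x$allosteric_test$df,
                   p_value = x$allosteric_test$p_value,
                   mean_labile = x$allosteric_test$mean_a,
                   mean_reference = x$allosteric_test$mean_b))
  if (!is.null(x$b_factor_test)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      test = "b_factor_paired_t", statistic = x$b_factor_test$statistic,
      df = x$b_factor_test$df, p_value = x$b_factor_test$p_value)
  }
  dplyr::bind_rows(rows)
}

#' One-row overview of a cohort summary
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return One-row tibble with cohort sizes and headline means.
#' @export
glance.cohort_summary <- function(x, ...) {
  ref <- x$cohorts[x$cohorts$cohort == "reference", ]
  lab <- x$cohorts[x$cohorts$cohort == "labile", ]
  tibble::tibble(
    n_reference = ref$n, n_labile = lab$n,
    mean_dse_reference = ref$mean_dse, mean_dse_labile = lab$mean_dse,
    mean_d_reference = ref$mean_d, mean_d_labile = lab$mean_d,
    mean_alpha_reference = ref$mean_alpha, mean_alpha_labile = lab$mean_alpha,
    p_dse = x$metric_tests$p_value[x$metric_tests$metric == "dse"],
    p_config = x$config_test$p_value)
}
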