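# shared fixture builders; everything is generated in code at test time

# atom tables for the two residues of a built cystine
cystine_sides <- function(spec) {
  atoms <- build_cystine(spec)
  list(res1 = atoms[atoms$residue == 1, ], res2 = atoms[atoms$residue == 2, ])
}

# a minimal hand-assembled two-cysteine structure as PDB text
minimal_cystine_pdb <- function(resolution = 1.50, chi = c(-60, -60, -90, -60, -60),
                                het_line = NULL, ssbond = TRUE) {
  sides <- cystine_sides(cystine_spec(chi = chi))
  atoms <- rbind(cbind(sides$res1, res_num = 10), cbind(sides$res2, res_num = 20))
  lines <- c(
    "HEADER    OXIDOREDUCTASE                          01-JAN-00   1TST",
    sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", resolution))
  if (ssbond) {
    lines <- c(lines,
               "SSBOND   1 CYS A   10    CYS A   20                          1555   1555  2.04")
  }
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    lines <- c(lines, sprintf(
      "ATOM  %5d  %-3s CYS A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, a$name, a$res_num, a$x, a$y, a$z, 1.0, a$b_factor, substr(a$name, 1, 1)))
  }
  if (!is.null(het_line)) lines <- c(lines, het_line)
  paste(c(lines, "END"), collapse = "\n")
}

# fixed-state ensemble spec covering every bond status and structure decoy
coverage_ensemble_spec <- function(accession = "COV001", seed = 11) {
  ensemble_spec(
    accession,
    n_structures = 8,
    bond_positions = list(c(20L, 60L)),
    states = matrix(c("present", "reduced", "present_long", "truncated",
                      "mutated", "unresolved", "present", "present"),
                    ncol = 1),
    resolutions = c(1.5, 1.8, 2.0, 2.2, 2.4, 2.49, 2.51, NA),
    het_codes = c(vector("list", 6), list("DTT"), list(character(0))),
    ss_context = list(c("helix", "strand")),
    seq_length = 80L,
    seed = seed)
}

# independent statistics oracles (hand formulas, no stats:: test functions)
oracle_pearson_chisq <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

oracle_welch <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

oracle_paired <- function(x, y) {
  d <- x - y
  t <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  list(statistic = t, df = length(d) - 1,
       p = 2 * stats::pt(-abs(t), length(d) - 1))
}

oracle_pearson_r <- function(x, y) {
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((length(x) - 2) / (1 - r^2))
  list(r = r, statistic = t, p = 2 * stats::pt(-abs(t), length(x) - 2))
}

# simulate a measured bond cohort by building cystines and measuring them
simulate_bond_cohort <- function(n, seed, chi3_location = NULL, labile = FALSE) {
  specs <- random_cystine_specs(n, seed, chi3_location = chi3_location)
  geoms <- dplyr::bind_rows(lapply(specs, function(s) {
    sides <- cystine_sides(s)
    measure_cystine(sides$res1, sides$res2)
  }))
  geoms <- add_configuration(geoms)
  geoms$accession <- sprintf("SIM%05d", seq_len(n) + ifelse(labile, 10000L, 0L))
  geoms$pos_i <- 10L
  geoms$pos_j <- 40L
  geoms$labile <- labile
  geoms$in_reference <- TRUE
  geoms$ss_pair <- "loop-loop"
  geoms$config <- geoms$config
  geoms
}
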