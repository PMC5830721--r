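test_that("the resolution screen excludes strictly above the cutoff", {
  m <- parse_pdb(minimal_cystine_pdb(resolution = 2.49))
  expect_equal(screen_structure(m)$status, "included")
  m <- parse_pdb(minimal_cystine_pdb(resolution = 2.50))
  expect_equal(screen_structure(m)$status, "included")
  m <- parse_pdb(minimal_cystine_pdb(resolution = 2.51))
  v <- screen_structure(m)
  expect_equal(v$status, "excluded")
  expect_match(v$reasons, "resolution_gt_2.5")
})

test_that("reducing agents and missing resolution are exclusion reasons", {
  dtt <- "HETATM  900  C1  DTT A 900      10.000  10.000  10.000  1.00 30.00           C"
  m <- parse_pdb(minimal_cystine_pdb(resolution = 1.8, het_line = dtt))
  v <- screen_structure(m)
  expect_equal(v$status, "excluded")
  expect_equal(v$reasons, "reducing_agent")

  txt <- sub("REMARK   2 RESOLUTION\\.[^\n]*",
             "REMARK   2 RESOLUTION. NOT APPLICABLE.", minimal_cystine_pdb())
  v <- screen_structure(parse_pdb(txt))
  expect_equal(v$reasons, "no_resolution")

  # a non-reductant heteroatom does not exclude
  gol <- "HETATM  900  C1  GOL A 900      10.000  10.000  10.000  1.00 30.00           C"
  m <- parse_pdb(minimal_cystine_pdb(resolution = 1.8, het_line = gol))
  expect_equal(screen_structure(m)$status, "included")
})

test_that("the length filter implements the 10 percent window inclusively", {
  expect_true(length_filter(2.05))
  expect_false(length_filter(2.30))
  expect_true(length_filter(2.2418))  # upper bound inclusive
  expect_true(length_filter(1.8342))  # lower bound inclusive
  expect_false(length_filter(2.2419))
  expect_false(length_filter(1.8341))
  # parameters scale the window
  expect_true(length_filter(2.4, equilibrium_length = 2.2, tolerance = 0.1))
})

make_mapped_model <- function(chi = c(-60, -60, -90, -60, -60),
                              resolution = 1.5, ssbond = TRUE) {
  m <- parse_pdb(minimal_cystine_pdb(resolution = resolution, chi = chi,
                                     ssbond = ssbond))
  seq1 <- paste(rep("A", 120), collapse = "")
  seq1 <- paste0(substr(seq1, 1, 49), "C", substr(seq1, 51, 110), "C",
                 substr(seq1, 112, 120))
  # author residues 10/20 are the cysteines; map them to canonical 50/111
  rt <- tibble::tibble(pdb_id = m$pdb_id, chain = "A",
                       author_resnum = c(10L, 20L), icode = "",
                       accession = "P11111", canonical_pos = c(50L, 111L))
  ct <- tibble::tibble(pdb_id = m$pdb_id, chain_id = "A", accession = "P11111")
  cm <- disulfidr:::map_structure_chains(m, ct, c(P11111 = seq1),
                                         residue_table = rt)
  list(model = m, chain_map = cm)
}

test_that("harvest maps an SSBOND to canonical positions with geometry", {
  mm <- make_mapped_model()
  h <- harvest_bonds(mm$model, mm$chain_map)
  expect_equal(nrow(h$bonds), 1)
  expect_equal(h$bonds$accession, "P11111")
  expect_equal(h$bonds$pos_i, 50L)
  expect_equal(h$bonds$pos_j, 111L)
  # the bond passed through 3-decimal PDB columns, so compare at that scale
  expect_equal(h$bonds$chi3, -90, tolerance = 1e-3)
  expect_equal(h$bonds$d, 2.038, tolerance = 1e-3)
})

test_that("duplicate SSBOND declarations collapse to one harvested bond", {
  mm <- make_mapped_model()
  mm$model$ssbonds <- rbind(mm$model$ssbonds, mm$model$ssbonds)
  h <- harvest_bonds(mm$model, mm$chain_map)
  expect_equal(nrow(h$bonds), 1)
})

test_that("inter-protein bonds yield no intra entries but a log line", {
  mm <- make_mapped_model()
  # remap the second cysteine's chain to a different accession
  m <- mm$model
  m$atoms$chain[m$atoms$res_num == 20] <- "B"
  m$ssbonds$chain2 <- "B"
  seqA <- paste0(paste(rep("A", 49), collapse = ""), "C",
                 paste(rep("A", 10), collapse = ""))
  seqB <- paste0(paste(rep("G", 30), collapse = ""), "C",
                 paste(rep("G", 10), collapse = ""))
  rt <- tibble::tibble(pdb_id = m$pdb_id, chain = c("A", "B"),
                       author_resnum = c(10L, 20L), icode = "",
                       accession = c("P11111", "P22222"),
                       canonical_pos = c(50L, 31L))
  ct <- tibble::tibble(pdb_id = m$pdb_id, chain_id = c("A", "B"),
                       accession = c("P11111", "P22222"))
  cm <- disulfidr:::map_structure_chains(m, ct, c(P11111 = seqA, P22222 = seqB),
                                         residue_table = rt)
  h <- harvest_bonds(m, cm)
  expect_equal(nrow(h$bonds), 0)
  expect_match(h$log$event, "inter-protein", all = FALSE)
})

test_that("dangling SSBONDs are logged and skipped", {
  mm <- make_mapped_model()
  mm$model$ssbonds$resnum2 <- 99L
  mm$model$ssbonds$dangling <- TRUE
  h <- harvest_bonds(mm$model, mm$chain_map)
  expect_equal(nrow(h$bonds), 0)
  expect_match(h$log$event, "dangling", all = FALSE)
})

test_that("geometric detection finds close SG pairs lacking SSBOND lines", {
  mm <- make_mapped_model(ssbond = FALSE)
  h <- harvest_bonds(mm$model, mm$chain_map, detection = "geometric")
  expect_equal(nrow(h$bonds), 1)
  expect_equal(h$bonds$pos_i, 50L)
  h2 <- harvest_bonds(mm$model, mm$chain_map) # default stays ssbond-only
  expect_equal(nrow(h2$bonds), 0)
})

test_that("absence assessment distinguishes its four outcomes", {
  ens <- generate_ensemble(coverage_ensemble_spec())
  # structures: 1 present / 2 reduced / 3 long / 4 truncated / 5 mutated /
  # 6 unresolved (7, 8 are screening decoys)
  ct <- ens$chains
  seqs <- stats::setNames(ens$sequence, "COV001")
  pos <- c(20L, 60L)
  statuses <- character(0)
  for (k in c(2, 4, 5, 6)) {
    m <- ens$models[[k]]
    cm <- disulfidr:::map_structure_chains(m, ct, seqs)
    statuses <- c(statuses,
                  assess_absence(m, "A", cm$mapping[[1]], pos))
  }
  expect_equal(statuses, c("missing", "excluded_truncated",
                           "excluded_mutated", "excluded_unresolved"))
})

test_that("aggregation flags lability only for valid absence evidence", {
  obs <- tibble::tibble(
    accession = "P1", pos_i = 10L, pos_j = 40L,
    pdb_id = c("1AAA", "1BBB", "1CCC"), chain = "A",
    status = c("present", "present", "missing"),
    resolution = c(2.0, 1.5, 1.8),
    chi1 = -60, chi2 = -60, chi3 = -90, chi2p = -60, chi1p = -60,
    alpha1 = 104, alpha2 = 104, d = 2.038, dse = 2.51, b_avg = 20,
    config = "-LHspiral", config_boundary = FALSE, ss_pair = "loop-loop")
  out <- aggregate_bonds(obs)
  expect_true(out$labile)
  expect_equal(out$n_present, 2)
  expect_equal(out$n_missing, 1)
  expect_equal(out$representative_pdb, "1BBB") # best resolution wins

  # absence only via an excluded chain is not lability evidence
  obs$status[3] <- "excluded_mutated"
  out <- aggregate_bonds(obs)
  expect_false(out$labile)
  expect_equal(out$n_excluded_mutated, 1)

  # filtered-length presence still counts as presence evidence
  obs$status <- c("present_filtered_length", "present_filtered_length", "missing")
  out <- aggregate_bonds(obs)
  expect_true(out$labile)
  expect_true(is.na(out$representative_pdb)) # but provides no cohort geometry
})

test_that("adding observations moves the labile flag monotonically", {
  base <- tibble::tibble(
    accession = "P1", pos_i = 10L, pos_j = 40L, pdb_id = "1AAA", chain = "A",
    status = "present", resolution = 2.0,
    chi1 = -60, chi2 = -60, chi3 = -90, chi2p = -60, chi1p = -60,
    alpha1 = 104, alpha2 = 104, d = 2.038, dse = 2.51, b_avg = 20,
    config = "-LHspiral", config_boundary = FALSE, ss_pair = "loop-loop")
  expect_false(aggregate_bonds(base)$labile)
  add_missing <- dplyr::mutate(base, pdb_id = "1BBB", status = "missing")
  expect_true(aggregate_bonds(rbind(base, add_missing))$labile)
  # an excluded observation never flips the flag either way
  add_excl <- dplyr::mutate(base, pdb_id = "1CCC", status = "excluded_truncated")
  expect_true(aggregate_bonds(rbind(base, add_missing, add_excl))$labile)
  expect_false(aggregate_bonds(rbind(base, add_excl))$labile)
})

test_that("ties in representative selection break lexicographically", {
  obs <- tibble::tibble(
    accession = "P1", pos_i = 10L, pos_j = 40L,
    pdb_id = c("1ZZZ", "1AAA"), chain = c("A", "B"),
    status = "present", resolution = 1.5,
    chi1 = -60, chi2 = -60, chi3 = -90, chi2p = -60, chi1p = -60,
    alpha1 = 104, alpha2 = 104, d = 2.038, dse = 2.51, b_avg = 20,
    config = "-LHspiral", config_boundary = FALSE, ss_pair = "loop-loop")
  expect_equal(aggregate_bonds(obs)$representative_pdb, "1AAA")
})

test_that("a culled chain list restricts reference membership", {
  obs <- tibble::tibble(
    accession = c("P1", "P2"), pos_i = 10L, pos_j = 40L,
    pdb_id = c("1AAA", "2BBB"), chain = "A",
    status = "present", resolution = 1.5,
    chi1 = -60, chi2 = -60, chi3 = -90, chi2p = -60, chi1p = -60,
    alpha1 = 104, alpha2 = 104, d = 2.038, dse = 2.51, b_avg = 20,
    config = "-LHspiral", config_boundary = FALSE, ss_pair = "loop-loop")
  culled <- tibble::tibble(pdb_id = "1AAA", chain_id = "A")
  out <- aggregate_bonds(obs, culled_chains = culled)
  expect_equal(out$in_reference, c(TRUE, FALSE))
})

test_that("statuses partition observations across unique bonds", {
  td <- withr::local_tempdir()
  truth <- run_simulate(td, n_proteins = 4, n_structures = 4, seed = 13)
  res <- mine_corpus(td, file.path(td, "chains.tsv"),
                     file.path(td, "sequences.fasta"))
  # every observation belongs to exactly one unique bond
  key <- paste(res$observations$accession, res$observations$pos_i,
               res$observations$pos_j)
  expect_true(all(key %in% paste(res$bonds$accession, res$bonds$pos_i,
                                 res$bonds$pos_j)))
  counts <- res$bonds$n_present + res$bonds$n_present_filtered +
    res$bonds$n_missing + res$bonds$n_excluded_truncated +
    res$bonds$n_excluded_mutated + res$bonds$n_excluded_unresolved
  expect_equal(sum(counts), nrow(res$observations))
})
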