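#' Run configuration for a mining run
#'
#' Bundles and validates the tunable parameters of [run_scan()]. Values may
#' come from a YAML config file (`load_run_config()`), with function
#' arguments taking precedence.
#'
#' @param input_dir Directory of structure files.
#' @param chain_table Path to the chain-mapping TSV.
#' @param fasta Path to the canonical FASTA.
#' @param output_dir Output directory.
#' @param resolution_cutoff Maximum resolution (angstrom), default 2.5.
#' @param length_tolerance Fractional S-S length tolerance, default 0.10.
#' @param equilibrium_length Equilibrium S-S length (angstrom), default 2.038.
#' @param reductant_codes Reducing-agent heteroatom codes.
#' @param detection `"ssbond"` or `"geometric"`.
#' @param residue_table Optional residue-level mapping TSV.
#' @param culled_chains Optional pre-culled chain list TSV.
#' @param seed Integer seed for any stochastic step.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, chain_table = NULL, fasta = NULL,
                       output_dir = ".", resolution_cutoff = 2.5,
                       length_tolerance = 0.10, equilibrium_length = 2.038,
                       reductant_codes = default_reductant_codes(),
                       detection = c("ssbond", "geometric"),
                       residue_table = NULL, culled_chains = NULL, seed = 1L) {
  detection <- match.arg(detection)
  if (resolution_cutoff <= 0 || equilibrium_length <= 0) {
    stop("run_config(): cutoffs must be positive", call. = FALSE)
  }
  if (length_tolerance <= 0 || length_tolerance >= 1) {
    stop("run_config(): length tolerance must lie in (0, 1)", call. = FALSE)
  }
  structure(list(input_dir = input_dir, chain_table = chain_table,
                 fasta = fasta, output_dir = output_dir,
                 resolution_cutoff = resolution_cutoff,
                 length_tolerance = length_tolerance,
                 equilibrium_length = equilibrium_length,
                 reductant_codes = reductant_codes, detection = detection,
                 residue_table = residue_table, culled_chains = culled_chains,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file of `run_config()` fields.
#' @param ... Overrides applied on top of the file values.
#' @return A `run_config`.
#' @export
load_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

#' Scan a structure corpus and write the mining tables
#'
#' Thin wrapper over [mine_corpus()] that writes `bonds.tsv`,
#' `observations.tsv` and `verdicts.tsv` (stably sorted, fixed column order)
#' into the output directory.
#'
#' @param config A `run_config` (or arguments forwarded to [run_config()]).
#' @param ... Overrides for config fields.
#' @return (Invisibly) the [mine_corpus()] result list.
#' @export
run_scan <- function(config, ...) {
  if (!inherits(config, "run_config")) {
    config <- do.call(run_config, utils::modifyList(as.list(config), list(...)))
  }
  res <- mine_corpus(
    input_dir = config$input_dir, chain_table = config$chain_table,
    fasta = config$fasta, residue_table = config$residue_table,
    culled_chains = config$culled_chains,
    resolution_cutoff = config$resolution_cutoff,
    reductant_codes = config$reductant_codes,
    equilibrium_length = config$equilibrium_length,
    length_tolerance = config$length_tolerance,
    detection = config$detection)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  bond_cols <- c("accession", "pos_i", "pos_j", "labile", "n_present",
                 "n_present_filtered", "n_missing", "n_excluded_truncated",
                 "n_excluded_mutated", "n_excluded_unresolved",
                 "same_file_lability", "in_reference", "representative_pdb",
                 "representative_chain", "chi1", "chi2", "chi3", "chi2p",
                 "chi1p", "alpha1", "alpha2", "d", "dse", "config",
                 "config_boundary", "b_avg", "ss_pair")
  readr::write_tsv(res$bonds[, intersect(bond_cols, names(res$bonds))],
                   file.path(config$output_dir, "bonds.tsv"))
  readr::write_tsv(res$observations,
                   file.path(config$output_dir, "observations.tsv"))
  readr::write_tsv(res$verdicts, file.path(config$output_dir, "verdicts.tsv"))
  invisible(res)
}

#' Per-bond geometry table of one structure file
#'
#' Parses a single structure and reports one row per SSBOND with the full
#' geometric characterization (five chi angles, two alpha angles, S-S
#' distance, DSE, configuration, B-factor average, secondary-structure
#' pair).
#'
#' @param path Path to a PDB file.
#' @return Tibble with one row per resolvable SSBOND.
#' @export
run_geometry <- function(path) {
  model <- parse_pdb(path)
  ss <- model$ssbonds[!model$ssbonds$dangling, , drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(ss))) {
    b <- ss[k, ]
    r1 <- residue_atoms(model, b$chain1, b$resnum1, b$icode1)
    r2 <- residue_atoms(model, b$chain2, b$resnum2, b$icode2)
    geom <- tryCatch(measure_cystine(r1, r2), error = function(e) NULL)
    if (is.null(geom)) next
    ss1 <- ss_state(b$chain1, b$resnum1, helices = model$helices,
                    sheets = model$sheets)
    ss2 <- ss_state(b$chain2, b$resnum2, helices = model$helices,
                    sheets = model$sheets)
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble::tibble(pdb_id = model$pdb_id, chain1 = b$chain1,
                     resnum1 = b$resnum1, chain2 = b$chain2,
                     resnum2 = b$resnum2),
      geom, tibble::tibble(ss_pair = ss_pair_label(ss1, ss2)))
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else tibble::tibble()
  if (nrow(out) > 0) out <- add_configuration(out)
  out
}

#' Generate a synthetic validation corpus
#'
#' Builds `n_proteins` randomized ensembles ([random_ensemble_spec()]) and
#' writes their structure files, mapping inputs and ground truth with
#' [generate_corpus()].
#'
#' @param dir Output directory.
#' @param n_proteins Number of accessions.
#' @param n_structures Structures per accession.
#' @param n_bonds Planted bonds per accession.
#' @param seed Integer seed.
#' @return (Invisibly) the [generate_corpus()] truth list.
#' @export
run_simulate <- function(dir, n_proteins = 5, n_structures = 4, n_bonds = 1,
                         seed = 1L) {
  specs <- lapply(seq_len(n_proteins), function(i) {
    random_ensemble_spec(sprintf("SYN%03d", i), seed = seed * 1000L + i,
                         n_structures = n_structures, n_bonds = n_bonds)
  })
  generate_corpus(specs, dir)
}

#' Cohort report over a mined bond table
#'
#' Runs [summarize_cohorts()] and writes the report tables
#' (`cohort_summary.tsv`, `cohort_tests.tsv`, `config_table.tsv`,
#' `ss_table.tsv`) plus a plain-text summary to the output directory.
#'
#' @param bonds Bond tibble or path to a `bonds.tsv` from [run_scan()].
#' @param observations Optional observations tibble or TSV path (enables
#'   the paired B-factor control).
#' @param output_dir Output directory (`NULL` skips writing).
#' @param ... Passed to [summarize_cohorts()].
#' @return (Invisibly) the `cohort_summary`.
#' @export
run_report <- function(bonds, observations = NULL, output_dir = NULL, ...) {
  if (!is.data.frame(bonds)) {
    bonds <- readr::read_tsv(bonds, show_col_types = FALSE)
  }
  if (!is.null(observations) && !is.data.frame(observations)) {
    observations <- readr::read_tsv(observations, show_col_types = FALSE)
  }
  if (!("in_reference" %in% names(bonds))) bonds$in_reference <- TRUE
  cs <- summarize_cohorts(bonds, observations = observations, ...)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(cs$cohorts, file.path(output_dir, "cohort_summary.tsv"))
    readr::write_tsv(generics::tidy(cs), file.path(output_dir, "cohort_tests.tsv"))
    readr::write_tsv(tibble::as_tibble(cs$config_table, rownames = "cohort"),
                     file.path(output_dir, "config_table.tsv"))
    readr::write_tsv(tibble::as_tibble(cs$ss_table, rownames = "cohort"),
                     file.path(output_dir, "ss_table.tsv"))
    con <- file(file.path(output_dir, "summary.txt"), "w")
    sink(con); print(cs); sink(); close(con)
  }
  invisible(cs)
}

#' Cross-tabulate bonds against a protein annotation table
#'
#' Plain descriptive tallies of a user-supplied per-accession annotation
#' (functional class, subcellular localization, ...) for all bonds versus
#' labile bonds. No enrichment testing is performed.
#'
#' @param bonds Unique-bond tibble.
#' @param annotations Data frame or TSV path with column `accession` plus
#'   one or more annotation columns.
#' @param column Annotation column to tally.
#' @return Tibble with `level`, `n_all`, `n_labile`.
#' @export
tally_annotations <- function(bonds, annotations, column) {
  if (!is.data.frame(annotations)) {
    annotations <- readr::read_tsv(annotations, show_col_types = FALSE)
  }
  stopifnot("accession" %in% names(annotations), column %in% names(annotations))
  merged <- dplyr::left_join(bonds, annotations, by = "accession")
  lv <- merged[[column]]
  lv[is.na(lv)] <- "unannotated"
  tibble::tibble(level = lv, labile = merged$labile) |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(n_all = dplyr::n(), n_labile = sum(.data$labile),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_all))
}
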