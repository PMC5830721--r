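#' Default reducing-agent heteroatom codes
#'
#' Residue codes whose presence among a structure's heteroatoms marks it as
#' crystallized with a reducing agent (dithiothreitol and relatives,
#' beta-mercaptoethanol, TCEP). Extend via the `reductant_codes` argument of
#' the screening functions.
#'
#' @return Character vector of 3-letter heteroatom codes.
#' @export
default_reductant_codes <- function() {
  c("DTT", "DTU", "DTV", "BME", "TCE")
}

#' Screen a structure for corpus inclusion
#'
#' A structure enters the mining corpus only if it has a stated resolution
#' of at most `resolution_cutoff` angstrom and carries no reducing-agent
#' heteroatom. Exclusion reasons: `resolution_gt_2.5`, `no_resolution`,
#' `reducing_agent`.
#'
#' @param model A `structure_model`.
#' @param resolution_cutoff Maximum admissible resolution (angstrom).
#' @param reductant_codes Heteroatom codes treated as reducing agents.
#' @return One-row tibble: `pdb_id`, `status` ("included"/"excluded"),
#'   `reasons` (";"-joined, "" when included).
#' @export
screen_structure <- function(model, resolution_cutoff = 2.5,
                             reductant_codes = default_reductant_codes()) {
  stopifnot(inherits(model, "structure_model"))
  reasons <- character(0)
  if (is.na(model$resolution)) {
    reasons <- c(reasons, "no_resolution")
  } else if (model$resolution > resolution_cutoff) {
    reasons <- c(reasons, sprintf("resolution_gt_%g", resolution_cutoff))
  }
  if (length(intersect(model$het_codes, reductant_codes)) > 0) {
    reasons <- c(reasons, "reducing_agent")
  }
  tibble::tibble(pdb_id = model$pdb_id,
                 status = ifelse(length(reasons) == 0, "included", "excluded"),
                 reasons = paste(sort(reasons), collapse = ";"))
}

#' Sulfur-sulfur length filter
#'
#' A bond's measured S-S distance must lie within `tolerance` (fractional)
#' of the equilibrium disulfide length for the bond's geometry to enter the
#' strain cohorts; the default window is 2.038 angstrom +/- 10%, i.e.
#' [1.8342, 2.2418] (inclusive).
#'
#' @param d S-S distance(s) in angstrom.
#' @param equilibrium_length Equilibrium disulfide bond length (angstrom).
#' @param tolerance Fractional tolerance.
#' @return Logical: TRUE where the distance passes.
#' @export
length_filter <- function(d, equilibrium_length = 2.038, tolerance = 0.10) {
  d >= (1 - tolerance) * equilibrium_length &
    d <= (1 + tolerance) * equilibrium_length
}

#' Harvest disulfide bonds declared in a structure
#'
#' One record per SSBOND whose two endpoints resolve to cysteines mapped to
#' canonical positions of the *same* accession (bonds joining chains of
#' different accessions are inter-protein and only logged). Geometry is
#' measured from the coordinates; duplicate SSBOND declarations of the same
#' canonical pair collapse to one record. An optional geometric mode also
#' reports SG-SG pairs closer than `geometric_cutoff` that lack an SSBOND
#' line (off by default).
#'
#' @param model A `structure_model`.
#' @param chain_map Tibble from `map_structure_chains()`.
#' @param detection `"ssbond"` (default) or `"geometric"`.
#' @param geometric_cutoff SG-SG distance cutoff (angstrom) for geometric
#'   mode.
#' @return List with `bonds` (tibble: accession, pos_i, pos_j, pdb_id,
#'   chain, plus the measured geometry columns) and `log` (tibble of skipped
#'   SSBONDs with reasons).
#' @export
harvest_bonds <- function(model, chain_map, detection = c("ssbond", "geometric"),
                          geometric_cutoff = 2.5) {
  detection <- match.arg(detection)
  log_rows <- list()
  note <- function(what) log_rows[[length(log_rows) + 1]] <<- tibble::tibble(
    pdb_id = model$pdb_id, event = what)

  mapping_of <- function(ch) {
    row <- chain_map[chain_map$chain == ch, , drop = FALSE]
    if (nrow(row) == 0 || row$accession[1] == "unmapped") NULL else row
  }

  ss <- model$ssbonds
  if (detection == "geometric") {
    ss <- dplyr::bind_rows(ss, geometric_ssbonds(model, geometric_cutoff))
  }
  rows <- list()
  if (nrow(ss) > 0) {
    for (k in seq_len(nrow(ss))) {
      b <- ss[k, ]
      if (isTRUE(b$dangling)) {
        note(sprintf("dangling SSBOND %s%d%s-%s%d%s skipped",
                     b$chain1, b$resnum1, b$icode1, b$chain2, b$resnum2, b$icode2))
        next
      }
      m1 <- mapping_of(b$chain1)
      m2 <- mapping_of(b$chain2)
      if (is.null(m1) || is.null(m2)) {
        note("SSBOND on unmapped chain skipped")
        next
      }
      if (m1$accession[1] != m2$accession[1]) {
        note(sprintf("inter-protein SSBOND %s:%s-%s:%s logged",
                     m1$accession[1], b$resnum1, m2$accession[1], b$resnum2))
        next
      }
      p1 <- canonical_position(m1$mapping[[1]], b$resnum1, b$icode1)
      p2 <- canonical_position(m2$mapping[[1]], b$resnum2, b$icode2)
      if (is.na(p1) || is.na(p2)) {
        note("SSBOND endpoint not covered by residue map")
        next
      }
      r1 <- residue_atoms(model, b$chain1, b$resnum1, b$icode1)
      r2 <- residue_atoms(model, b$chain2, b$resnum2, b$icode2)
      geom <- tryCatch(measure_cystine(r1, r2), error = function(e) {
        note(paste("geometry failed:", conditionMessage(e)))
        NULL
      })
      if (is.null(geom)) next
      if (p2 < p1) { # normalize orientation so pos_i < pos_j
        tmp <- p1; p1 <- p2; p2 <- tmp
        geom <- swap_cystine_sides(geom)
        side_chain <- c(b$chain2, b$chain1)
      } else {
        side_chain <- c(b$chain1, b$chain2)
      }
      ch_lab <- if (side_chain[1] == side_chain[2]) side_chain[1] else
        paste(side_chain, collapse = "")
      if (side_chain[1] == b$chain1) {
        a1 <- list(ch = b$chain1, rn = b$resnum1)
        a2 <- list(ch = b$chain2, rn = b$resnum2)
      } else {
        a1 <- list(ch = b$chain2, rn = b$resnum2)
        a2 <- list(ch = b$chain1, rn = b$resnum1)
      }
      ss1 <- ss_state(a1$ch, a1$rn, helices = model$helices, sheets = model$sheets)
      ss2 <- ss_state(a2$ch, a2$rn, helices = model$helices, sheets = model$sheets)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(accession = m1$accession[1], pos_i = p1, pos_j = p2,
                       pdb_id = model$pdb_id, chain = ch_lab),
        geom,
        tibble::tibble(ss_pair = ss_pair_label(ss1, ss2)))
    }
  }
  bonds <- if (length(rows) > 0) {
    dplyr::distinct(dplyr::bind_rows(rows), .data$accession, .data$pos_i,
                    .data$pos_j, .data$chain, .keep_all = TRUE)
  } else {
    tibble::tibble(accession = character(), pos_i = integer(),
                   pos_j = integer(), pdb_id = character(), chain = character())
  }
  list(bonds = bonds,
       log = if (length(log_rows) > 0) dplyr::bind_rows(log_rows) else
         tibble::tibble(pdb_id = character(), event = character()))
}

# relabel a measured geometry after swapping residue order
swap_cystine_sides <- function(geom) {
  out <- geom
  out$chi1 <- geom$chi1p; out$chi1p <- geom$chi1
  out$chi2 <- geom$chi2p; out$chi2p <- geom$chi2
  out$alpha1 <- geom$alpha2; out$alpha2 <- geom$alpha1
  out
}

geometric_ssbonds <- function(model, cutoff) {
  sg <- model$atoms[!model$atoms$is_het & model$atoms$name == "SG", , drop = FALSE]
  if (nrow(sg) < 2) {
    return(tibble::tibble(chain1 = character(), resnum1 = integer(),
                          icode1 = character(), chain2 = character(),
                          resnum2 = integer(), icode2 = character(),
                          declared_length = numeric(), dangling = logical()))
  }
  dm <- as.matrix(stats::dist(sg[, c("x", "y", "z")]))
  pairs <- which(dm < cutoff & upper.tri(dm), arr.ind = TRUE)
  known <- model$ssbonds
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    already <- nrow(known) > 0 && any(
      (known$chain1 == sg$chain[i] & known$resnum1 == sg$res_num[i] &
         known$chain2 == sg$chain[j] & known$resnum2 == sg$res_num[j]) |
        (known$chain1 == sg$chain[j] & known$resnum1 == sg$res_num[j] &
           known$chain2 == sg$chain[i] & known$resnum2 == sg$res_num[i]))
    if (already) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      chain1 = sg$chain[i], resnum1 = sg$res_num[i], icode1 = sg$i_code[i],
      chain2 = sg$chain[j], resnum2 = sg$res_num[j], icode2 = sg$i_code[j],
      declared_length = dm[i, j], dangling = FALSE)
  }
  if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble::tibble(chain1 = character(), resnum1 = integer(),
                   icode1 = character(), chain2 = character(),
                   resnum2 = integer(), icode2 = character(),
                   declared_length = numeric(), dangling = logical())
}

#' Classify the absence of an expected bond in one chain
#'
#' Given a chain mapped to the bond's accession in a structure with no
#' SSBOND for the canonical pair, decides whether the absence is valid
#' evidence of lability or must be excluded: `excluded_truncated` if either
#' canonical position is outside the construct (not covered by the residue
#' map), `excluded_mutated` if the aligned residue is not cysteine,
#' `excluded_unresolved` if it is cysteine but its SG atom is not modelled,
#' else `missing`.
#'
#' @param model A `structure_model`.
#' @param chain Chain identifier.
#' @param mapping The chain's `chain_mapping`.
#' @param pos_pair Length-2 integer vector of canonical positions.
#' @return One of `"missing"`, `"excluded_truncated"`, `"excluded_mutated"`,
#'   `"excluded_unresolved"`.
#' @export
assess_absence <- function(model, chain, mapping, pos_pair) {
  for (p in pos_pair) {
    row <- author_residue(mapping, p)
    if (is.null(row)) return("excluded_truncated")
    if (row$observed_aa != "C") return("excluded_mutated")
    at <- residue_atoms(model, chain, row$res_num, row$i_code)
    if (!("SG" %in% at$name)) return("excluded_unresolved")
  }
  "missing"
}

#' Aggregate bond observations into unique bonds
#'
#' Collapses per-(structure, chain) observations into one entry per
#' (accession, canonical position pair). A bond is labile when it has at
#' least one `present*` observation and at least one valid `missing`
#' observation. The representative geometry comes from the strict-`present`
#' (length-filter-passing) observation in the structure of best resolution,
#' ties broken by lexicographic (pdb_id, chain). If a pre-culled chain list
#' is supplied, reference-cohort membership (`in_reference`) is restricted
#' to bonds whose representative present observation comes from a culled
#' chain.
#'
#' @param observations Tibble of bond observations (as from [mine_corpus()]):
#'   columns `accession`, `pos_i`, `pos_j`, `pdb_id`, `chain`, `status`,
#'   `resolution`, geometry columns for present observations.
#' @param culled_chains Optional tibble (`pdb_id`, `chain_id`) restricting
#'   the reference cohort.
#' @return Tibble of unique bonds, one row per (accession, pos_i, pos_j),
#'   sorted; includes observation counts by status, the `labile` flag,
#'   `same_file_lability`, representative identity and geometry.
#' @export
aggregate_bonds <- function(observations, culled_chains = NULL) {
  obs <- observations
  if (nrow(obs) == 0) {
    stop("aggregate_bonds(): no observations", call. = FALSE)
  }
  geom_cols <- c("chi1", "chi2", "chi3", "chi2p", "chi1p", "alpha1", "alpha2",
                 "d", "dse", "b_avg", "config", "config_boundary", "ss_pair")
  groups <- obs |>
    dplyr::group_by(.data$accession, .data$pos_i, .data$pos_j)
  summary <- groups |>
    dplyr::summarise(
      n_present = sum(.data$status == "present"),
      n_present_filtered = sum(.data$status == "present_filtered_length"),
      n_missing = sum(.data$status == "missing"),
      n_excluded_truncated = sum(.data$status == "excluded_truncated"),
      n_excluded_mutated = sum(.data$status == "excluded_mutated"),
      n_excluded_unresolved = sum(.data$status == "excluded_unresolved"),
      labile = (sum(startsWith(.data$status, "present")) > 0) &
        (sum(.data$status == "missing") > 0),
      same_file_lability = any_same_file_lability(.data$status, .data$pdb_id),
      .groups = "drop")

  reps <- obs |>
    dplyr::filter(.data$status == "present") |>
    dplyr::arrange(.data$accession, .data$pos_i, .data$pos_j,
                   .data$resolution, .data$pdb_id, .data$chain) |>
    dplyr::group_by(.data$accession, .data$pos_i, .data$pos_j) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("accession", "pos_i", "pos_j",
                  representative_pdb = "pdb_id", representative_chain = "chain",
                  dplyr::any_of(geom_cols))

  out <- dplyr::left_join(summary, reps, by = c("accession", "pos_i", "pos_j"))

  if (!is.null(culled_chains)) {
    culled <- paste(culled_chains$pdb_id,
                    substr(culled_chains$chain_id, 1, 1), sep = "/")
    out$in_reference <- !is.na(out$representative_pdb) &
      paste(out$representative_pdb, substr(out$representative_chain, 1, 1),
            sep = "/") %in% culled
  } else {
    out$in_reference <- TRUE
  }
  dplyr::arrange(out, .data$accession, .data$pos_i, .data$pos_j)
}

any_same_file_lability <- function(status, pdb_id) {
  present_files <- unique(pdb_id[startsWith(status, "present")])
  missing_files <- unique(pdb_id[status == "missing"])
  length(intersect(present_files, missing_files)) > 0
}

#' Mine a corpus of structures for labile disulfide bonds
#'
#' The full pipeline over a directory of legacy PDB files: parse each file,
#' screen it (resolution, reducing agents), map its chains to accessions,
#' harvest SSBOND disulfides with measured geometry, validate the absence of
#' every known bond in every mapped chain lacking it, and aggregate into
#' unique bonds with lability flags.
#'
#' The set of expected bonds per accession is the union of all harvested
#' canonical position pairs across the included corpus, so a structure
#' missing a bond seen elsewhere contributes a `missing` (or excluded)
#' observation.
#'
#' @param input_dir Directory of `.pdb`/`.ent` files.
#' @param chain_table Chain mapping tibble or TSV path (see
#'   [load_chain_table()]).
#' @param fasta Canonical FASTA path or named character vector of sequences.
#' @param residue_table Optional residue-level mapping TSV/tibble to bypass
#'   alignment ([load_residue_table()]).
#' @param culled_chains Optional pre-culled chain list (tibble or TSV with
#'   `pdb_id`, `chain_id`) restricting the reference cohort.
#' @param resolution_cutoff,reductant_codes Screening parameters.
#' @param equilibrium_length,length_tolerance Length-filter parameters.
#' @param detection `"ssbond"` or `"geometric"` bond detection.
#' @return List of tibbles: `verdicts` (one row per structure),
#'   `observations` (one row per bond observation), `bonds` (unique bonds),
#'   `log` (harvest events).
#' @export
mine_corpus <- function(input_dir, chain_table, fasta,
                        residue_table = NULL, culled_chains = NULL,
                        resolution_cutoff = 2.5,
                        reductant_codes = default_reductant_codes(),
                        equilibrium_length = 2.038, length_tolerance = 0.10,
                        detection = "ssbond") {
  files <- sort(list.files(input_dir, pattern = "\\.(pdb|ent)$",
                           full.names = TRUE))
  if (length(files) == 0) {
    stop("mine_corpus(): no structures found in input directory", call. = FALSE)
  }
  if (!is.data.frame(chain_table)) chain_table <- load_chain_table(chain_table)
  sequences <- if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta)) {
    read_canonical_fasta(fasta)
  } else {
    fasta
  }
  if (!is.null(residue_table) && !is.data.frame(residue_table)) {
    residue_table <- load_residue_table(residue_table)
  }
  if (!is.null(culled_chains) && !is.data.frame(culled_chains)) {
    culled_chains <- readr::read_tsv(culled_chains, show_col_types = FALSE)
  }

  models <- lapply(files, parse_pdb)
  verdicts <- dplyr::bind_rows(lapply(models, screen_structure,
                                      resolution_cutoff = resolution_cutoff,
                                      reductant_codes = reductant_codes))
  chain_maps <- lapply(models, map_structure_chains, chain_table = chain_table,
                       sequences = sequences, residue_table = residue_table)

  # structures with no mappable chain are excluded with reason "unmapped"
  for (k in seq_along(models)) {
    if (verdicts$status[k] == "included" &&
        all(chain_maps[[k]]$accession == "unmapped")) {
      verdicts$status[k] <- "excluded"
      verdicts$reasons[k] <- paste(
        c(strsplit(verdicts$reasons[k], ";")[[1]], "unmapped")[
          nzchar(c(strsplit(verdicts$reasons[k], ";")[[1]], "unmapped"))],
        collapse = ";")
    }
  }
  included <- which(verdicts$status == "included")

  harvests <- list()
  logs <- list()
  for (k in included) {
    h <- harvest_bonds(models[[k]], chain_maps[[k]], detection = detection)
    harvests[[length(harvests) + 1]] <- h$bonds
    logs[[length(logs) + 1]] <- h$log
  }
  present_obs <- dplyr::bind_rows(harvests)
  log <- dplyr::bind_rows(logs)

  if (nrow(present_obs) > 0) {
    present_obs <- add_configuration(present_obs)
    present_obs$status <- ifelse(
      length_filter(present_obs$d, equilibrium_length, length_tolerance),
      "present", "present_filtered_length")
  } else {
    present_obs <- tibble::tibble(accession = character(), pos_i = integer(),
                                  pos_j = integer(), pdb_id = character(),
                                  chain = character(), status = character())
  }

  # union of known bonds per accession
  known <- dplyr::distinct(present_obs[, c("accession", "pos_i", "pos_j")])

  absence_rows <- list()
  if (nrow(known) > 0) {
    for (k in included) {
      model <- models[[k]]
      cm <- chain_maps[[k]]
      for (ci in seq_len(nrow(cm))) {
        if (cm$accession[ci] == "unmapped") next
        acc <- cm$accession[ci]
        mp <- cm$mapping[[ci]]
        ch <- cm$chain[ci]
        kb <- known[known$accession == acc, , drop = FALSE]
        for (bi in seq_len(nrow(kb))) {
          pos <- c(kb$pos_i[bi], kb$pos_j[bi])
          has_present <- any(
            present_obs$accession == acc & present_obs$pos_i == pos[1] &
              present_obs$pos_j == pos[2] & present_obs$pdb_id == model$pdb_id &
              grepl(ch, present_obs$chain, fixed = TRUE))
          if (has_present) next
          status <- assess_absence(model, ch, mp, pos)
          bavg <- NA_real_
          if (status == "missing") {
            r1 <- author_residue(mp, pos[1])
            r2 <- author_residue(mp, pos[2])
            a1 <- residue_atoms(model, ch, r1$res_num, r1$i_code)
            a2 <- residue_atoms(model, ch, r2$res_num, r2$i_code)
            bavg <- tryCatch(b_factor_average(a1, a2)$b_avg,
                             error = function(e) NA_real_)
          }
          absence_rows[[length(absence_rows) + 1]] <- tibble::tibble(
            accession = acc, pos_i = pos[1], pos_j = pos[2],
            pdb_id = model$pdb_id, chain = ch, status = status, b_avg = bavg)
        }
      }
    }
  }
  absent_obs <- if (length(absence_rows) > 0) dplyr::bind_rows(absence_rows) else
    tibble::tibble(accession = character(), pos_i = integer(),
                   pos_j = integer(), pdb_id = character(), chain = character(),
                   status = character(), b_avg = numeric())

  res_by_id <- stats::setNames(vapply(models, function(m) {
    ifelse(is.na(m$resolution), Inf, m$resolution)
  }, numeric(1)), vapply(models, function(m) m$pdb_id, ""))

  observations <- dplyr::bind_rows(present_obs, absent_obs)
  observations$resolution <- unname(res_by_id[observations$pdb_id])
  observations <- dplyr::arrange(observations, .data$accession, .data$pos_i,
                                 .data$pos_j, .data$pdb_id, .data$chain)

  bonds <- if (nrow(observations) > 0) {
    aggregate_bonds(observations, culled_chains = culled_chains)
  } else {
    tibble::tibble()
  }
  list(verdicts = dplyr::arrange(verdicts, .data$pdb_id),
       observations = observations, bonds = bonds, log = log)
}
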