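#' Specification of a synthetic multi-structure ensemble
#'
#' Describes a set of synthetic X-ray structures of one protein (accession)
#' in which each planted disulfide bond is, per structure, in one of six
#' states:
#'
#' * `present` — cystine built at the target chi angles, SSBOND written;
#' * `present_long` — as `present` but with a stretched S-S distance that
#'   fails the 10% length filter;
#' * `reduced` — both cysteines resolved with SG atoms, no SSBOND (valid
#'   evidence of lability);
#' * `truncated` — the construct starts after the first bonded position;
#' * `mutated` — the first bonded cysteine substituted (default to Tyr);
#' * `unresolved` — the cysteine present but its SG atom not modelled.
#'
#' Structure-level decoys are controlled by `resolutions` (values > 2.5
#' angstrom, or `NA` for an unstated resolution, cause exclusion) and
#' `het_codes` (e.g. `"DTT"` plants a reducing-agent heteroatom).
#'
#' All randomness (sequence, chi targets, filler B factors) derives from
#' `seed`, so identical specs generate byte-identical fixtures.
#'
#' @param accession Accession string for the canonical sequence.
#' @param n_structures Number of structure files.
#' @param bond_positions List of length-2 integer vectors: canonical
#'   positions of the planted cystines (i < j).
#' @param states Character matrix `n_structures x n_bonds` of the states
#'   above. Default: all `present` in odd files, all `reduced` in even ones.
#' @param resolutions Numeric vector (length `n_structures`) of declared
#'   resolutions in angstrom; `NA` writes "NOT APPLICABLE".
#' @param het_codes List (length `n_structures`) of character vectors of
#'   heteroatom residue codes to plant.
#' @param chi_targets Optional list indexed `[[structure]][[bond]]` of
#'   length-5 chi targets (degrees); drawn randomly away from sign
#'   boundaries when `NULL`.
#' @param ss_context Optional list (length n_bonds) of length-2 character
#'   vectors in `{helix, strand, loop}`: the secondary-structure context
#'   written into header records around each bonded cysteine.
#' @param seq_length Canonical sequence length.
#' @param author_offsets Integer vector: per-structure offset added to
#'   canonical positions to form author residue numbers.
#' @param b_cys Per-atom B factor given to planted cysteine atoms.
#' @param d_long S-S distance used for `present_long` bonds.
#' @param seed Integer seed.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(accession,
                          n_structures = 2,
                          bond_positions = list(c(30L, 80L)),
                          states = NULL,
                          resolutions = rep(1.8, n_structures),
                          het_codes = vector("list", n_structures),
                          chi_targets = NULL,
                          ss_context = NULL,
                          seq_length = 100L,
                          author_offsets = rep(0L, n_structures),
                          b_cys = 20,
                          d_long = 2.30,
                          seed = 1L) {
  n_bonds <- length(bond_positions)
  if (is.null(states)) {
    states <- matrix(rep(c("present", "reduced"), length.out = n_structures),
                     nrow = n_structures, ncol = n_bonds)
  }
  states <- matrix(states, nrow = n_structures, ncol = n_bonds)
  valid <- c("present", "present_long", "reduced", "truncated", "mutated",
             "unresolved")
  stopifnot(all(states %in% valid),
            length(resolutions) == n_structures,
            length(het_codes) == n_structures,
            length(author_offsets) == n_structures)
  for (bp in bond_positions) {
    stopifnot(length(bp) == 2, bp[1] < bp[2], bp[2] <= seq_length, bp[1] >= 2)
  }
  structure(list(accession = accession, n_structures = n_structures,
                 bond_positions = bond_positions, states = states,
                 resolutions = resolutions, het_codes = het_codes,
                 chi_targets = chi_targets, ss_context = ss_context,
                 seq_length = as.integer(seq_length),
                 author_offsets = as.integer(author_offsets),
                 b_cys = b_cys, d_long = d_long, seed = as.integer(seed)),
            class = "ensemble_spec")
}

base36_digit <- function(k) {
  alph <- c(0:9, LETTERS)
  paste(alph[(k %% 36) + 1], collapse = "")
}

# two-character token making synthetic PDB ids unique per accession
ensemble_token <- function(accession) {
  digits <- gsub("\\D", "", accession)
  idx <- if (nzchar(digits)) {
    as.integer(substr(digits, max(1, nchar(digits) - 3), nchar(digits)))
  } else {
    sum(utf8ToInt(accession))
  }
  idx <- idx %% 1296L
  paste0(base36_digit(idx %/% 36L), base36_digit(idx %% 36L))
}

# draw a chi target vector uniformly, at least `margin` degrees away from the
# 0/180 sign boundaries so classification is unambiguous
random_chi_targets <- function(margin = 5) {
  mag <- stats::runif(5, min = margin, max = 180 - margin)
  mag * sample(c(-1, 1), 5, replace = TRUE)
}

#' Generate the structure files and ground truth for one ensemble
#'
#' Deterministically (given the spec's seed) builds one synthetic PDB file
#' per structure — REMARK 2 resolution, SEQRES, HELIX/SHEET context, ATOM
#' records (CA trace plus full cysteine atoms built by [build_cystine()]),
#' SSBOND lines for present bonds and HETATM decoys — together with the
#' ground-truth tables that mining the ensemble must reproduce.
#'
#' @param spec An [ensemble_spec()].
#' @param dir Output directory for the fixture files; created if needed.
#'   `NULL` skips writing and returns the in-memory models only.
#' @return (Invisibly) a list with `models` (structure_model list),
#'   `sequence` (canonical sequence string), `chains` (chain-mapping tibble),
#'   `truth_verdicts`, `truth_observations` and `truth_bonds` tibbles.
#' @export
generate_ensemble <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "ensemble_spec"))
  withr::with_seed(spec$seed, generate_ensemble_impl(spec, dir))
}

generate_ensemble_impl <- function(spec, dir) {
  n_bonds <- length(spec$bond_positions)
  L <- spec$seq_length
  cys_pos <- sort(unique(unlist(spec$bond_positions)))
  aa_pool <- setdiff(names(AA_321), "CYS")
  seq3 <- sample(aa_pool, L, replace = TRUE)
  seq3[cys_pos] <- "CYS"
  seq1 <- paste(three_to_one(seq3), collapse = "")

  chi <- spec$chi_targets
  if (is.null(chi)) {
    chi <- lapply(seq_len(spec$n_structures), function(s) {
      lapply(seq_len(n_bonds), function(b) random_chi_targets())
    })
  }

  models <- list()
  obs_rows <- list()
  verdict_rows <- list()

  for (s in seq_len(spec$n_structures)) {
    pdb_id <- paste0("Z", ensemble_token(spec$accession), base36_digit(s))
    offset <- spec$author_offsets[s]
    res <- spec$resolutions[s]
    hets <- as.character(spec$het_codes[[s]])
    if (length(hets) == 0) hets <- character(0)
    st <- spec$states[s, ]

    # layout plan
    construct_start <- 1L
    mutated_pos <- integer(0)
    unresolved_pos <- integer(0)
    for (b in seq_len(n_bonds)) {
      ij <- spec$bond_positions[[b]]
      if (st[b] == "truncated") construct_start <- max(construct_start, ij[1] + 1L)
      if (st[b] == "mutated") mutated_pos <- c(mutated_pos, ij[1])
      if (st[b] == "unresolved") unresolved_pos <- c(unresolved_pos, ij[1])
    }
    kept <- construct_start:L
    res_names <- seq3
    res_names[mutated_pos] <- "TYR"

    atoms <- list()
    base_b <- stats::runif(1, 25, 45)
    special <- integer(0) # canonical positions owned by built cystines
    ssbond_rows <- list()

    for (b in seq_len(n_bonds)) {
      ij <- spec$bond_positions[[b]]
      if (!(st[b] %in% c("present", "present_long", "reduced"))) next
      if (any(!(ij %in% kept))) next
      d <- if (st[b] == "present_long") spec$d_long else 2.038
      cyst <- build_cystine(cystine_spec(chi = chi[[s]][[b]], d = d,
                                         b_factors = rep(spec$b_cys, 12)))
      shift <- c(3.8 * ij[1], 25 + 18 * b, 0)
      cyst$x <- cyst$x + shift[1]
      cyst$y <- cyst$y + shift[2]
      cyst$z <- cyst$z + shift[3]
      if (st[b] == "reduced") {
        r2 <- cyst$residue == 2
        cyst$z[r2] <- cyst$z[r2] + 12
      }
      for (side in 1:2) {
        sub <- cyst[cyst$residue == side, ]
        atoms[[length(atoms) + 1]] <- tibble::tibble(
          serial = 0L, name = sub$name, alt_loc = " ", res_name = "CYS",
          chain = "A", res_num = ij[side] + offset, i_code = "",
          x = sub$x, y = sub$y, z = sub$z, occupancy = 1,
          b_factor = sub$b_factor, element = substr(sub$name, 1, 1),
          is_het = FALSE)
      }
      special <- c(special, ij)
      if (st[b] %in% c("present", "present_long")) {
        ssbond_rows[[length(ssbond_rows) + 1]] <- tibble::tibble(
          chain1 = "A", resnum1 = ij[1] + offset, icode1 = "",
          chain2 = "A", resnum2 = ij[2] + offset, icode2 = "",
          declared_length = round(d, 2))
      }
    }

    # CA trace for every other construct residue (unresolved cysteines get a
    # CA but no SG; mutated positions carry the substituted residue name)
    for (p in kept) {
      if (p %in% special) next
      atoms[[length(atoms) + 1]] <- tibble::tibble(
        serial = 0L, name = "CA", alt_loc = " ", res_name = res_names[p],
        chain = "A", res_num = p + offset, i_code = "",
        x = 3.8 * p, y = 0, z = 0, occupancy = 1,
        b_factor = round(base_b + stats::rnorm(1, 0, 3), 2),
        element = "C", is_het = FALSE)
    }

    # reducing-agent (or other) heteroatom decoys
    for (h in seq_along(hets)) {
      atoms[[length(atoms) + 1]] <- tibble::tibble(
        serial = 0L, name = c("C1", "O1"), alt_loc = " ",
        res_name = hets[h], chain = "A", res_num = 900L + h, i_code = "",
        x = c(0, 1.4), y = -15, z = 3 * h, occupancy = 1, b_factor = 30,
        element = c("C", "O"), is_het = TRUE)
    }

    atoms <- dplyr::bind_rows(atoms)
    atoms <- dplyr::arrange(atoms, .data$res_num, .data$is_het)
    atoms$serial <- seq_len(nrow(atoms))

    # secondary-structure context records
    helices <- list()
    sheets <- list()
    if (!is.null(spec$ss_context)) {
      for (b in seq_len(n_bonds)) {
        ctx <- spec$ss_context[[b]]
        if (is.null(ctx)) next
        ij <- spec$bond_positions[[b]]
        for (side in 1:2) {
          rng <- tibble::tibble(chain = "A",
                                start_num = ij[side] + offset - 2L,
                                start_icode = "",
                                end_num = ij[side] + offset + 2L,
                                end_icode = "")
          if (ctx[side] == "helix") helices[[length(helices) + 1]] <- rng
          if (ctx[side] == "strand") sheets[[length(sheets) + 1]] <- rng
        }
      }
    }
    empty_range <- tibble::tibble(chain = character(), start_num = integer(),
                                  start_icode = character(),
                                  end_num = integer(), end_icode = character())
    ssbonds <- if (length(ssbond_rows) > 0) {
      dplyr::bind_rows(ssbond_rows)
    } else {
      tibble::tibble(chain1 = character(), resnum1 = integer(),
                     icode1 = character(), chain2 = character(),
                     resnum2 = integer(), icode2 = character(),
                     declared_length = numeric())
    }
    ssbonds$dangling <- FALSE

    model <- structure(list(
      pdb_id = pdb_id, resolution = res, atoms = atoms, ssbonds = ssbonds,
      helices = if (length(helices) > 0) dplyr::bind_rows(helices) else empty_range,
      sheets = if (length(sheets) > 0) dplyr::bind_rows(sheets) else empty_range,
      seqres = tibble::tibble(chain = "A", res_name = res_names[kept],
                              pos = seq_along(kept)),
      het_codes = setdiff(sort(unique(hets)), "HOH"),
      report = tibble::tibble(record = character(), line = integer(),
                              reason = character())), class = "structure_model")
    models[[s]] <- model

    ## ---- ground truth ----
    reasons <- character(0)
    if (is.na(res)) reasons <- c(reasons, "no_resolution")
    else if (res > 2.5) reasons <- c(reasons, "resolution_gt_2.5")
    if (any(hets %in% default_reductant_codes())) {
      reasons <- c(reasons, "reducing_agent")
    }
    included <- length(reasons) == 0
    verdict_rows[[length(verdict_rows) + 1]] <- tibble::tibble(
      pdb_id = pdb_id, status = ifelse(included, "included", "excluded"),
      reasons = paste(sort(reasons), collapse = ";"))

    if (included) {
      for (b in seq_len(n_bonds)) {
        ij <- spec$bond_positions[[b]]
        # a truncation planted for one bond can remove another bond's
        # residues too, so truncation is judged from the realized construct
        status <- if (any(!(ij %in% kept))) {
          "excluded_truncated"
        } else {
          switch(st[b],
                 present = "present",
                 present_long = "present_filtered_length",
                 reduced = "missing",
                 mutated = "excluded_mutated",
                 unresolved = "excluded_unresolved")
        }
        obs_rows[[length(obs_rows) + 1]] <- tibble::tibble(
          accession = spec$accession, pos_i = ij[1], pos_j = ij[2],
          pdb_id = pdb_id, chain = "A", status = status)
      }
    }
  }

  truth_obs <- if (length(obs_rows) > 0) dplyr::bind_rows(obs_rows) else
    tibble::tibble(accession = character(), pos_i = integer(),
                   pos_j = integer(), pdb_id = character(), chain = character(),
                   status = character())
  truth_verdicts <- dplyr::bind_rows(verdict_rows)
  # a bond is discoverable only if it is present (SSBOND) in at least one
  # included structure; without presence evidence the miner cannot know it
  truth_bonds <- truth_obs |>
    dplyr::group_by(.data$accession, .data$pos_i, .data$pos_j) |>
    dplyr::summarise(
      observable = any(startsWith(.data$status, "present")),
      labile = any(startsWith(.data$status, "present")) & any(.data$status == "missing"),
      .groups = "drop") |>
    dplyr::arrange(.data$accession, .data$pos_i, .data$pos_j)
  planted <- tibble::tibble(
    accession = spec$accession,
    pos_i = vapply(spec$bond_positions, `[`, integer(1), 1),
    pos_j = vapply(spec$bond_positions, `[`, integer(1), 2))
  truth_bonds <- dplyr::left_join(planted, truth_bonds,
                                  by = c("accession", "pos_i", "pos_j"))
  truth_bonds$labile[is.na(truth_bonds$labile)] <- FALSE
  truth_bonds$observable[is.na(truth_bonds$observable)] <- FALSE
  # observation-level truth is likewise restricted to discoverable bonds
  truth_obs <- dplyr::semi_join(
    truth_obs, truth_bonds[truth_bonds$observable, , drop = FALSE],
    by = c("accession", "pos_i", "pos_j"))

  chains <- tibble::tibble(pdb_id = vapply(models, function(m) m$pdb_id, ""),
                           chain_id = "A", accession = spec$accession)

  out <- list(models = models, sequence = seq1, chains = chains,
              truth_verdicts = truth_verdicts,
              truth_observations = truth_obs, truth_bonds = truth_bonds)
  if (!is.null(dir)) write_ensemble_files(out, spec$accession, dir)
  invisible(out)
}

write_ensemble_files <- function(ens, accession, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in ens$models) {
    write_pdb(m, file.path(dir, paste0(tolower(m$pdb_id), ".pdb")))
  }
  cat(sprintf(">%s\n%s\n", accession, ens$sequence),
      file = file.path(dir, paste0(accession, ".fasta")))
  invisible(ens)
}

#' Generate a corpus of ensembles with shared mapping inputs
#'
#' Runs [generate_ensemble()] for each spec and writes the pooled inputs a
#' mining run needs — structure files, a canonical FASTA, a chain-mapping
#' TSV — plus pooled ground-truth TSVs (`truth_verdicts.tsv`,
#' `truth_observations.tsv`, `truth_bonds.tsv`).
#'
#' @param specs List of [ensemble_spec()] objects (distinct accessions).
#' @param dir Output directory.
#' @return (Invisibly) list with `chains`, `sequences` (named character),
#'   `truth_verdicts`, `truth_observations`, `truth_bonds`.
#' @export
generate_corpus <- function(specs, dir) {
  stopifnot(length(specs) > 0)
  accs <- vapply(specs, function(s) s$accession, "")
  stopifnot(!anyDuplicated(accs))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  parts <- lapply(specs, generate_ensemble, dir = NULL)
  for (p in parts) {
    for (m in p$models) write_pdb(m, file.path(dir, paste0(tolower(m$pdb_id), ".pdb")))
  }
  seqs <- stats::setNames(vapply(parts, function(p) p$sequence, ""), accs)
  fasta <- file.path(dir, "sequences.fasta")
  cat(paste0(">", accs, "\n", unname(seqs), "\n", collapse = ""), file = fasta)
  chains <- dplyr::bind_rows(lapply(parts, function(p) p$chains))
  readr::write_tsv(chains, file.path(dir, "chains.tsv"))
  tv <- dplyr::bind_rows(lapply(parts, function(p) p$truth_verdicts))
  to <- dplyr::bind_rows(lapply(parts, function(p) p$truth_observations))
  tb <- dplyr::bind_rows(lapply(parts, function(p) p$truth_bonds))
  readr::write_tsv(tv, file.path(dir, "truth_verdicts.tsv"))
  readr::write_tsv(to, file.path(dir, "truth_observations.tsv"))
  readr::write_tsv(tb, file.path(dir, "truth_bonds.tsv"))
  invisible(list(chains = chains, sequences = seqs, truth_verdicts = tv,
                 truth_observations = to, truth_bonds = tb))
}

#' Randomized ensemble spec exercising every observation status
#'
#' Convenience generator for validation corpora: draws per-structure bond
#' states, decoy resolutions and reducing-agent heteroatoms at random
#' (deterministically, given `seed`).
#'
#' @param accession Accession string.
#' @param seed Integer seed.
#' @param n_structures Number of structures in the ensemble.
#' @param n_bonds Number of planted bonds.
#' @return An [ensemble_spec()].
#' @export
random_ensemble_spec <- function(accession, seed, n_structures = 4,
                                 n_bonds = 1) {
  withr::with_seed(seed + 7L, {
    L <- 60L + n_bonds * 40L
    bonds <- lapply(seq_len(n_bonds), function(b) {
      lo <- 10L + (b - 1L) * 40L
      c(lo, lo + sample(15:30, 1))
    })
    states <- matrix("present", n_structures, n_bonds)
    for (b in seq_len(n_bonds)) {
      pool <- c("present", "reduced", "present_long", "truncated", "mutated",
                "unresolved")
      states[, b] <- sample(pool, n_structures, replace = TRUE,
                            prob = c(0.35, 0.25, 0.1, 0.1, 0.1, 0.1))
    }
    resolutions <- sample(c(1.5, 1.9, 2.3, 2.8), n_structures, replace = TRUE,
                          prob = c(0.3, 0.3, 0.3, 0.1))
    if (stats::runif(1) < 0.2) resolutions[sample(n_structures, 1)] <- NA
    het_codes <- lapply(seq_len(n_structures), function(i) {
      if (stats::runif(1) < 0.15) "DTT" else character(0)
    })
    ss_pool <- c("helix", "strand", "loop")
    ss_context <- lapply(seq_len(n_bonds), function(b) sample(ss_pool, 2, replace = TRUE))
    ensemble_spec(accession, n_structures = n_structures,
                  bond_positions = bonds, states = states,
                  resolutions = resolutions, het_codes = het_codes,
                  ss_context = ss_context, seq_length = L,
                  author_offsets = sample(c(0L, 0L, 5L), n_structures,
                                          replace = TRUE),
                  seed = seed)
  })
}
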