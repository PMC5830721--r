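#' Load a chain-to-accession mapping table
#'
#' Reads a TSV with columns `pdb_id`, `chain_id`, `accession` assigning each
#' structure chain to a canonical protein accession. Rows that duplicate a
#' (pdb_id, chain_id) pair with *conflicting* accessions are an error;
#' identical duplicates are collapsed.
#'
#' @param path Path to the TSV file, or a data frame with the same columns.
#' @return A tibble (`pdb_id`, `chain_id`, `accession`), one row per chain.
#' @export
load_chain_table <- function(path) {
  tab <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_tsv(path, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  }
  need <- c("pdb_id", "chain_id", "accession")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop(sprintf("load_chain_table(): missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  tab <- dplyr::distinct(tab[, need])
  dup <- tab |>
    dplyr::count(.data$pdb_id, .data$chain_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop(sprintf(
      "load_chain_table(): conflicting accessions for chain(s): %s",
      paste(paste0(dup$pdb_id, "/", dup$chain_id), collapse = ", ")),
      call. = FALSE)
  }
  tab
}

#' Look up the accession of a structure chain
#'
#' @param chain_table Tibble from [load_chain_table()].
#' @param pdb_id,chain_id Chain identity.
#' @return The accession string, or `"unmapped"` if the chain is absent.
#' @export
lookup_accession <- function(chain_table, pdb_id, chain_id) {
  hit <- chain_table$accession[chain_table$pdb_id == pdb_id &
                                 chain_table$chain_id == chain_id]
  if (length(hit) == 0) "unmapped" else hit[1]
}

#' Read canonical sequences from a FASTA file
#'
#' Headers (up to the first whitespace) are taken as accessions.
#'
#' @param path FASTA file path.
#' @return Named character vector of one-letter sequences.
#' @export
read_canonical_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(aa))
  seqs
}

aa_identity_matrix <- function() {
  alph <- c(sort(unique(unname(AA_321))), "X")
  m <- matrix(-1, length(alph), length(alph), dimnames = list(alph, alph))
  diag(m) <- 1
  m
}

#' Align an observed chain onto its canonical sequence
#'
#' Global (Needleman-Wunsch) alignment of the residues observed in a chain's
#' ATOM records against the canonical sequence, scoring match +1, mismatch
#' -1, gap open -5, gap extend -1. The alignment yields the author-numbering
#' to canonical-position residue map, sequence coverage, and the list of
#' substitutions (candidate mutations).
#'
#' @param observed Tibble of observed residues in author order, with columns
#'   `res_num`, `i_code`, `aa` (one-letter codes; as from
#'   `chain_residues()`).
#' @param canonical Canonical sequence (one-letter string).
#' @param min_identity Alignments with identity below this fraction (over
#'   aligned residue pairs) are rejected as implausible mappings.
#' @return An object of class `chain_mapping`: list with `residue_map`
#'   (tibble `res_num`, `i_code`, `canonical_pos`, `observed_aa`,
#'   `canonical_aa`), `mismatches` (tibble `canonical_pos`, `canonical_aa`,
#'   `observed_aa`), `coverage` (fraction of canonical positions observed)
#'   and `identity`.
#' @export
align_chain <- function(observed, canonical, min_identity = 0.30) {
  stopifnot(is.data.frame(observed), nrow(observed) > 0,
            is.character(canonical), nchar(canonical) > 0)
  obs_seq <- paste(observed$aa, collapse = "")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(obs_seq),
    subject = Biostrings::AAString(canonical),
    type = "global",
    substitutionMatrix = aa_identity_matrix(),
    gapOpening = 5, gapExtension = 1)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]

  ip <- 0L # index into observed residues
  is <- 0L # canonical position
  rows <- vector("list", length(pat))
  n_aligned <- 0L
  n_match <- 0L
  for (k in seq_along(pat)) {
    p_gap <- pat[k] == "-"
    s_gap <- sub[k] == "-"
    if (!p_gap) ip <- ip + 1L
    if (!s_gap) is <- is + 1L
    if (!p_gap && !s_gap) {
      n_aligned <- n_aligned + 1L
      if (pat[k] == sub[k]) n_match <- n_match + 1L
      rows[[k]] <- tibble::tibble(
        res_num = observed$res_num[ip], i_code = observed$i_code[ip],
        canonical_pos = is, observed_aa = pat[k], canonical_aa = sub[k])
    }
  }
  residue_map <- dplyr::bind_rows(rows)
  identity <- if (n_aligned > 0) n_match / n_aligned else 0
  if (identity < min_identity) {
    stop(sprintf("align_chain(): implausible mapping (identity %.1f%% < %.0f%%)",
                 100 * identity, 100 * min_identity), call. = FALSE)
  }
  mismatches <- residue_map |>
    dplyr::filter(.data$observed_aa != .data$canonical_aa) |>
    dplyr::select("canonical_pos", "canonical_aa", "observed_aa")
  structure(list(residue_map = residue_map,
                 mismatches = mismatches,
                 coverage = nrow(residue_map) / nchar(canonical),
                 identity = identity),
            class = "chain_mapping")
}

#' @export
print.chain_mapping <- function(x, ...) {
  cat(sprintf("<chain_mapping> %d residues mapped, coverage %.2f, identity %.2f, %d mismatch(es)\n",
              nrow(x$residue_map), x$coverage, x$identity, nrow(x$mismatches)))
  invisible(x)
}

#' Load a residue-level mapping table
#'
#' A SIFTS-like TSV (`pdb_id`, `chain`, `author_resnum`, `icode`,
#' `accession`, `canonical_pos`) can be supplied to bypass alignment
#' entirely. Chains mapped to more than one accession (chimeric constructs)
#' are dropped with a message.
#'
#' @param path TSV path or equivalent data frame.
#' @return Tibble with the columns above, chimeric chains removed.
#' @export
load_residue_table <- function(path) {
  tab <- if (is.data.frame(path)) tibble::as_tibble(path) else
    readr::read_tsv(path, show_col_types = FALSE)
  need <- c("pdb_id", "chain", "author_resnum", "icode", "accession",
            "canonical_pos")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop(sprintf("load_residue_table(): missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  tab$icode[is.na(tab$icode)] <- ""
  chim <- tab |>
    dplyr::distinct(.data$pdb_id, .data$chain, .data$accession) |>
    dplyr::count(.data$pdb_id, .data$chain) |>
    dplyr::filter(.data$n > 1)
  if (nrow(chim) > 0) {
    message(sprintf("load_residue_table(): dropping chimeric chain(s): %s",
                    paste(paste0(chim$pdb_id, "/", chim$chain), collapse = ", ")))
    tab <- dplyr::anti_join(tab, chim, by = c("pdb_id", "chain"))
  }
  tab[, need]
}

# Map every chain of a model: returns tibble(chain, accession, mapping
# list-column of chain_mapping or NULL). Unmapped / unalignable chains get
# accession "unmapped" and a reason.
map_structure_chains <- function(model, chain_table, sequences,
                                 residue_table = NULL) {
  chains <- sort(unique(model$atoms$chain[!model$atoms$is_het]))
  rows <- lapply(chains, function(ch) {
    acc <- lookup_accession(chain_table, model$pdb_id, ch)
    if (acc == "unmapped" || !(acc %in% names(sequences))) {
      return(tibble::tibble(chain = ch, accession = "unmapped",
                            mapping = list(NULL), reason = "no accession"))
    }
    if (!is.null(residue_table)) {
      sub <- residue_table[residue_table$pdb_id == model$pdb_id &
                             residue_table$chain == ch, , drop = FALSE]
      if (nrow(sub) > 0) {
        obs <- chain_residues(model, ch)
        rm <- dplyr::inner_join(
          obs, dplyr::rename(sub, res_num = "author_resnum", i_code = "icode"),
          by = c("res_num", "i_code"))
        canon <- strsplit(sequences[[acc]], "")[[1]]
        residue_map <- tibble::tibble(
          res_num = rm$res_num, i_code = rm$i_code,
          canonical_pos = rm$canonical_pos, observed_aa = rm$aa,
          canonical_aa = canon[rm$canonical_pos])
        mp <- structure(list(
          residue_map = residue_map,
          mismatches = residue_map[residue_map$observed_aa != residue_map$canonical_aa,
                                   c("canonical_pos", "canonical_aa", "observed_aa")],
          coverage = nrow(residue_map) / length(canon),
          identity = mean(residue_map$observed_aa == residue_map$canonical_aa)),
          class = "chain_mapping")
        return(tibble::tibble(chain = ch, accession = acc, mapping = list(mp),
                              reason = ""))
      }
    }
    obs <- chain_residues(model, ch)
    mp <- tryCatch(align_chain(obs, sequences[[acc]]), error = function(e) NULL)
    if (is.null(mp)) {
      return(tibble::tibble(chain = ch, accession = "unmapped",
                            mapping = list(NULL), reason = "implausible alignment"))
    }
    tibble::tibble(chain = ch, accession = acc, mapping = list(mp), reason = "")
  })
  dplyr::bind_rows(rows)
}

# author residue id -> canonical position (NA if unmapped)
canonical_position <- function(mapping, res_num, i_code = "") {
  hit <- mapping$residue_map$canonical_pos[
    mapping$residue_map$res_num == res_num &
      mapping$residue_map$i_code == i_code]
  if (length(hit) == 0) NA_integer_ else hit[1]
}

# canonical position -> author residue row (NULL if not covered)
author_residue <- function(mapping, canonical_pos) {
  hit <- mapping$residue_map[mapping$residue_map$canonical_pos == canonical_pos, ,
                             drop = FALSE]
  if (nrow(hit) == 0) NULL else hit[1, ]
}
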