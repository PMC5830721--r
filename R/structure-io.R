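#' Parse a legacy-format PDB file
#'
#' Reads the subset of the fixed-column PDB v3.3 format needed for disulfide
#' mining: ATOM/HETATM coordinates, SSBOND, HELIX, SHEET, SEQRES and the
#' REMARK 2 resolution record. Parsing is total: malformed records are
#' skipped and counted in the parse report instead of raising errors. Only
#' the first MODEL of a multi-model file is read. For alternate locations,
#' the highest-occupancy conformer is kept (ties broken by the
#' alphabetically first altLoc identifier).
#'
#' @param x Path to a PDB file, or a character vector of PDB lines (any
#'   element containing a newline is split).
#' @param pdb_id Optional 4-character identifier; defaults to the HEADER
#'   record's ID code if present, else the file name stem.
#' @return An object of class `structure_model`: a list with elements
#'   `pdb_id`, `resolution` (angstrom, `NA` if not stated), `atoms`,
#'   `ssbonds`, `helices`, `sheets`, `seqres` (tibbles), `het_codes`
#'   (character vector of heteroatom residue codes, water excluded) and
#'   `report` (tibble of skipped records).
#' @export
parse_pdb <- function(x, pdb_id = NULL) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    if (is.null(pdb_id)) {
      pdb_id <- toupper(sub("\\.(pdb|ent)$", "", basename(x)))
    }
    lines <- readLines(x, warn = FALSE)
  } else {
    lines <- unlist(strsplit(as.character(x), "\n", fixed = TRUE))
  }
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    stop("parse_pdb(): empty input", call. = FALSE)
  }

  rec <- substr(lines, 1, 6)
  skipped <- list()
  note_skip <- function(record, lineno, reason) {
    skipped[[length(skipped) + 1]] <<- tibble::tibble(
      record = record, line = lineno, reason = reason)
  }

  # truncate at the end of the first model, if models are declared
  endmdl <- which(trimws(rec) == "ENDMDL")
  coord_limit <- if (length(endmdl) > 0) endmdl[1] else length(lines)

  if (is.null(pdb_id)) {
    hdr <- which(trimws(rec) == "HEADER")
    pdb_id <- if (length(hdr) > 0) trimws(substr(lines[hdr[1]], 63, 66)) else "XXXX"
    if (!nzchar(pdb_id)) pdb_id <- "XXXX"
  }

  ## REMARK 2 resolution
  resolution <- NA_real_
  rem2 <- lines[grepl("^REMARK   2 RESOLUTION\\.", lines)]
  if (length(rem2) > 0) {
    m <- regmatches(rem2[1], regexpr("[0-9]+\\.?[0-9]*(?=[[:space:]]*ANGSTROM)",
                                     rem2[1], perl = TRUE))
    if (length(m) == 1) {
      resolution <- suppressWarnings(as.numeric(m))
      if (!is.na(resolution) && resolution <= 0) {
        note_skip("REMARK 2", which(lines == rem2[1])[1], "non-positive resolution")
        resolution <- NA_real_
      }
    }
  }

  ## coordinates
  is_coord <- rec %in% c("ATOM  ", "HETATM") & seq_along(lines) <= coord_limit
  atoms <- parse_atom_lines(lines[is_coord], which(is_coord), note_skip)
  if (nrow(atoms) == 0) {
    stop("parse_pdb(): no coordinates (no parseable ATOM records)", call. = FALSE)
  }
  atoms <- resolve_altloc(atoms)

  ## SSBOND
  ss_lines <- which(rec == "SSBOND")
  ssbonds <- purrr::map_dfr(ss_lines, function(i) {
    ln <- lines[i]
    r1 <- suppressWarnings(as.integer(substr(ln, 18, 21)))
    r2 <- suppressWarnings(as.integer(substr(ln, 32, 35)))
    if (is.na(r1) || is.na(r2)) {
      note_skip("SSBOND", i, "unparseable residue number")
      return(NULL)
    }
    dl <- suppressWarnings(as.numeric(substr(ln, 74, 78)))
    tibble::tibble(
      chain1 = substr(ln, 16, 16), resnum1 = r1, icode1 = trimws(substr(ln, 22, 22)),
      chain2 = substr(ln, 30, 30), resnum2 = r2, icode2 = trimws(substr(ln, 36, 36)),
      declared_length = ifelse(is.na(dl), NA_real_, dl)
    )
  })
  if (nrow(ssbonds) == 0) {
    ssbonds <- tibble::tibble(chain1 = character(), resnum1 = integer(),
                              icode1 = character(), chain2 = character(),
                              resnum2 = integer(), icode2 = character(),
                              declared_length = numeric())
  }
  # an endpoint is dangling if no non-het CYS residue carries its identity
  cys <- dplyr::distinct(atoms[!atoms$is_het & atoms$res_name == "CYS",
                               c("chain", "res_num", "i_code")])
  has_cys <- function(ch, rn, ic) {
    any(cys$chain == ch & cys$res_num == rn & cys$i_code == ic)
  }
  ssbonds$dangling <- !purrr::pmap_lgl(
    list(ssbonds$chain1, ssbonds$resnum1, ssbonds$icode1,
         ssbonds$chain2, ssbonds$resnum2, ssbonds$icode2),
    function(c1, r1, i1, c2, r2, i2) has_cys(c1, r1, i1) && has_cys(c2, r2, i2))

  ## HELIX / SHEET
  helices <- purrr::map_dfr(which(rec == "HELIX "), function(i) {
    ln <- lines[i]
    s <- suppressWarnings(as.integer(substr(ln, 22, 25)))
    e <- suppressWarnings(as.integer(substr(ln, 34, 37)))
    if (is.na(s) || is.na(e)) {
      note_skip("HELIX", i, "unparseable range")
      return(NULL)
    }
    tibble::tibble(chain = substr(ln, 20, 20), start_num = s,
                   start_icode = trimws(substr(ln, 26, 26)),
                   end_num = e, end_icode = trimws(substr(ln, 38, 38)))
  })
  sheets <- purrr::map_dfr(which(rec == "SHEET "), function(i) {
    ln <- lines[i]
    s <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    e <- suppressWarnings(as.integer(substr(ln, 34, 37)))
    if (is.na(s) || is.na(e)) {
      note_skip("SHEET", i, "unparseable range")
      return(NULL)
    }
    tibble::tibble(chain = substr(ln, 22, 22), start_num = s,
                   start_icode = trimws(substr(ln, 27, 27)),
                   end_num = e, end_icode = trimws(substr(ln, 38, 38)))
  })
  empty_range <- tibble::tibble(chain = character(), start_num = integer(),
                                start_icode = character(), end_num = integer(),
                                end_icode = character())
  if (nrow(helices) == 0) helices <- empty_range
  if (nrow(sheets) == 0) sheets <- empty_range

  ## SEQRES
  seqres <- purrr::map_dfr(which(rec == "SEQRES"), function(i) {
    ln <- lines[i]
    codes <- strsplit(trimws(substr(ln, 20, 70)), "[[:space:]]+")[[1]]
    codes <- codes[nzchar(codes)]
    if (length(codes) == 0) return(NULL)
    tibble::tibble(chain = substr(ln, 12, 12), res_name = codes)
  })
  if (nrow(seqres) == 0) {
    seqres <- tibble::tibble(chain = character(), res_name = character(),
                             pos = integer())
  } else {
    seqres <- dplyr::mutate(dplyr::group_by(seqres, .data$chain),
                            pos = dplyr::row_number())
    seqres <- dplyr::ungroup(seqres)
  }

  het_codes <- sort(unique(atoms$res_name[atoms$is_het]))
  het_codes <- setdiff(het_codes, "HOH")

  report <- if (length(skipped) > 0) {
    dplyr::bind_rows(skipped)
  } else {
    tibble::tibble(record = character(), line = integer(), reason = character())
  }

  structure(
    list(pdb_id = pdb_id, resolution = resolution, atoms = atoms,
         ssbonds = ssbonds, helices = helices, sheets = sheets,
         seqres = seqres, het_codes = het_codes, report = report),
    class = "structure_model")
}

parse_atom_lines <- function(lns, linenos, note_skip) {
  if (length(lns) == 0) {
    return(tibble::tibble(serial = integer(), name = character(),
                          alt_loc = character(), res_name = character(),
                          chain = character(), res_num = integer(),
                          i_code = character(), x = numeric(), y = numeric(),
                          z = numeric(), occupancy = numeric(),
                          b_factor = numeric(), element = character(),
                          is_het = logical()))
  }
  num <- function(a, b) suppressWarnings(as.numeric(substr(lns, a, b)))
  int <- function(a, b) suppressWarnings(as.integer(substr(lns, a, b)))
  out <- tibble::tibble(
    serial = int(7, 11),
    name = trimws(substr(lns, 13, 16)),
    alt_loc = substr(lns, 17, 17),
    res_name = trimws(substr(lns, 18, 20)),
    chain = substr(lns, 22, 22),
    res_num = int(23, 26),
    i_code = trimws(substr(lns, 27, 27)),
    x = num(31, 38), y = num(39, 46), z = num(47, 54),
    occupancy = num(55, 60),
    b_factor = num(61, 66),
    element = trimws(substr(lns, 77, 78)),
    is_het = substr(lns, 1, 6) == "HETATM"
  )
  out$occupancy[is.na(out$occupancy)] <- 1
  out$b_factor[is.na(out$b_factor)] <- 0
  bad <- is.na(out$res_num) | is.na(out$x) | is.na(out$y) | is.na(out$z) |
    !is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z) |
    out$b_factor < 0 | out$occupancy < 0 | out$occupancy > 1 |
    !nzchar(out$name)
  for (i in which(bad)) {
    note_skip(substr(lns[i], 1, 6), linenos[i], "unparseable mandatory columns")
  }
  out[!bad, , drop = FALSE]
}

# keep one conformer per (residue, atom name): highest occupancy, ties to the
# alphabetically first altLoc
resolve_altloc <- function(atoms) {
  atoms |>
    dplyr::group_by(.data$chain, .data$res_num, .data$i_code, .data$res_name,
                    .data$name, .data$is_het) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$alt_loc,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$serial)
}

#' Serialize a structure model back to PDB text
#'
#' Writes ATOM/HETATM, SSBOND, HELIX, SHEET, SEQRES and REMARK 2 records in
#' fixed-column PDB v3.3 layout. Coordinates are written at 3 decimals and
#' B factors at 2, so `parse_pdb(write_pdb(m))` reproduces a model to column
#' precision.
#'
#' @param model A `structure_model`.
#' @param path Optional file path; if supplied, the text is also written
#'   there.
#' @return The PDB text as a single string (invisibly when `path` is given).
#' @export
write_pdb <- function(model, path = NULL) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  if (any(nchar(at$chain) != 1)) {
    stop("write_pdb(): chain identifiers must be single characters", call. = FALSE)
  }
  out <- character(0)
  out <- c(out, sprintf("HEADER    SYNTHETIC STRUCTURE                     01-JAN-00   %-4s", model$pdb_id))
  if (!is.na(model$resolution)) {
    out <- c(out, sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", model$resolution))
  } else {
    out <- c(out, "REMARK   2 RESOLUTION. NOT APPLICABLE.")
  }
  ## SEQRES (13 residues per record)
  if (nrow(model$seqres) > 0) {
    for (ch in unique(model$seqres$chain)) {
      codes <- model$seqres$res_name[model$seqres$chain == ch]
      n <- length(codes)
      for (k in seq_len(ceiling(n / 13))) {
        grp <- codes[((k - 1) * 13 + 1):min(k * 13, n)]
        out <- c(out, sprintf("SEQRES %3d %s %4d  %-51s", k, ch, n,
                              paste(sprintf("%-3s", grp), collapse = " ")))
      }
    }
  }
  ## HELIX / SHEET
  if (nrow(model$helices) > 0) {
    for (i in seq_len(nrow(model$helices))) {
      h <- model$helices[i, ]
      out <- c(out, sprintf(
        "HELIX  %3d %3s %3s %s %4d%1s %3s %s %4d%1s %2d%30s %5d",
        i, sprintf("H%02d", i %% 100), "ALA", h$chain, h$start_num,
        ifelse(nzchar(h$start_icode), h$start_icode, " "),
        "ALA", h$chain, h$end_num,
        ifelse(nzchar(h$end_icode), h$end_icode, " "),
        1, "", h$end_num - h$start_num + 1))
    }
  }
  if (nrow(model$sheets) > 0) {
    for (i in seq_len(nrow(model$sheets))) {
      s <- model$sheets[i, ]
      out <- c(out, sprintf(
        "SHEET  %3d %3s%2d %3s %s%4d%1s %3s %s%4d%1s%2d",
        i, sprintf("S%02d", i %% 100), 1, "ALA", s$chain, s$start_num,
        ifelse(nzchar(s$start_icode), s$start_icode, " "),
        "ALA", s$chain, s$end_num,
        ifelse(nzchar(s$end_icode), s$end_icode, " "), 0))
    }
  }
  ## SSBOND
  if (nrow(model$ssbonds) > 0) {
    for (i in seq_len(nrow(model$ssbonds))) {
      b <- model$ssbonds[i, ]
      len_field <- if (!is.na(b$declared_length)) sprintf("%5.2f", b$declared_length) else "     "
      out <- c(out, sprintf(
        "SSBOND %3d CYS %s %4d%1s   CYS %s %4d%1s %37s %s",
        i, b$chain1, b$resnum1, ifelse(nzchar(b$icode1), b$icode1, " "),
        b$chain2, b$resnum2, ifelse(nzchar(b$icode2), b$icode2, " "),
        "1555   1555", len_field))
    }
  }
  ## coordinates
  fmt_atom <- function(a, serial) {
    name_field <- if (nchar(a$name) < 4) sprintf(" %-3s", a$name) else a$name
    sprintf("%-6s%5d %4s%1s%-3s %s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f%10s%2s",
            ifelse(a$is_het, "HETATM", "ATOM"), serial, name_field,
            ifelse(nzchar(trimws(a$alt_loc)), a$alt_loc, " "),
            a$res_name, a$chain, a$res_num,
            ifelse(nzchar(a$i_code), a$i_code, " "),
            a$x, a$y, a$z, a$occupancy, a$b_factor, "",
            ifelse(nzchar(a$element), a$element, substr(a$name, 1, 1)))
  }
  for (i in seq_len(nrow(at))) {
    out <- c(out, fmt_atom(at[i, ], i))
  }
  out <- c(out, "END")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(txt))
  }
  txt
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model %s>\n", x$pdb_id))
  cat(sprintf("  resolution: %s\n",
              ifelse(is.na(x$resolution), "unknown", sprintf("%.2f A", x$resolution))))
  cat(sprintf("  atoms: %d in %d chain(s); ssbonds: %d; het codes: %s\n",
              nrow(x$atoms), length(unique(x$atoms$chain[!x$atoms$is_het])),
              nrow(x$ssbonds),
              ifelse(length(x$het_codes) > 0, paste(x$het_codes, collapse = ","), "none")))
  invisible(x)
}

# all atoms of one residue (non-het), as a tibble
residue_atoms <- function(model, chain, res_num, i_code = "") {
  a <- model$atoms
  a[!a$is_het & a$chain == chain & a$res_num == res_num & a$i_code == i_code, ,
    drop = FALSE]
}

# observed polymer residues of a chain in author order:
# tibble(res_num, i_code, res_name, aa)
chain_residues <- function(model, chain) {
  a <- model$atoms
  a <- a[!a$is_het & a$chain == chain, , drop = FALSE]
  res <- dplyr::distinct(a[, c("res_num", "i_code", "res_name")])
  res$aa <- three_to_one(res$res_name)
  tibble::as_tibble(res)
}

AA_321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

three_to_one <- function(codes) {
  out <- unname(AA_321[codes])
  out[is.na(out)] <- "X"
  out
}

one_to_three <- function(aa) {
  lut <- stats::setNames(names(AA_321), unname(AA_321))
  out <- unname(lut[aa])
  out[is.na(out)] <- "UNK"
  out
}
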