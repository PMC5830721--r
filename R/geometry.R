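#' Signed dihedral angle between four points
#'
#' Computes the torsion angle defined by four atoms using the atan2
#' formulation, with the IUPAC sign convention: looking down the p2 -> p3
#' axis, a clockwise rotation of the far bond relative to the near bond is
#' positive. Values lie in (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors of Cartesian coordinates (angstrom).
#' @return Signed angle in degrees, in (-180, 180].
#' @examples
#' dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)) # trans, 180
#' dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))  # cis, 0
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (any(!is.finite(c(p1, p2, p3, p4)))) {
    stop("dihedral_angle(): coordinates must be finite", call. = FALSE)
  }
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  eps <- 1e-10
  if (vnorm(b1) < eps || vnorm(b2) < eps || vnorm(b3) < eps ||
      vnorm(n1) < eps || vnorm(n2) < eps) {
    stop("dihedral_angle(): degenerate geometry (coincident or collinear points)",
         call. = FALSE)
  }
  y <- sum(cross3(n1, n2) * (b2 / vnorm(b2)))
  x <- sum(n1 * n2)
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Bond angle at the middle point
#'
#' @param p1,p2,p3 Numeric 3-vectors; the angle is measured at `p2`.
#' @return Angle in degrees, in [0, 180].
#' @export
bond_angle <- function(p1, p2, p3) {
  v1 <- p1 - p2
  v2 <- p3 - p2
  n1 <- vnorm(v1)
  n2 <- vnorm(v2)
  if (n1 < 1e-10 || n2 < 1e-10) {
    stop("bond_angle(): coincident points", call. = FALSE)
  }
  acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

# map any finite angle into (-180, 180]
wrap_angle <- function(a) {
  a <- a %% 360
  ifelse(a > 180, a - 360, a)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v * v))

#' Dihedral strain energy of a cystine
#'
#' Torsional strain estimate (kJ/mol) of a disulfide bond from its five chi
#' angles:
#'
#' DSE = 8.37 (1 + cos 3chi1) + 8.37 (1 + cos 3chi1') +
#'       4.18 (1 + cos 3chi2) + 4.18 (1 + cos 3chi2') +
#'       14.64 (1 + cos 2chi3) + 2.51 (1 + cos 3chi3)
#'
#' The constants are the torsional force-field barriers conventionally used
#' for cystine strain; they can be overridden via `constants` (named vector
#' with elements `chi1`, `chi2`, `chi3_2fold`, `chi3_3fold`). The function is
#' vectorized over its angle arguments.
#'
#' @param chi1,chi2,chi3,chi2p,chi1p Dihedral angles in degrees.
#' @param constants Named numeric vector of the four barrier heights (kJ/mol).
#' @return Strain energy in kJ/mol, in [0, 84.5] for the default constants.
#' @examples
#' dse(-60, -60, -90, -60, -60) # 2.51, the relaxed spiral geometry
#' dse(0, 0, 0, 0, 0)           # 84.5, the all-eclipsed maximum
#' @export
dse <- function(chi1, chi2, chi3, chi2p, chi1p,
                constants = c(chi1 = 8.37, chi2 = 4.18,
                              chi3_2fold = 14.64, chi3_3fold = 2.51)) {
  stopifnot(all(c("chi1", "chi2", "chi3_2fold", "chi3_3fold") %in% names(constants)))
  angs <- cbind(chi1, chi2, chi3, chi2p, chi1p)
  if (any(!is.finite(angs))) {
    stop("dse(): chi angles must be finite", call. = FALSE)
  }
  # cospi() keeps multiples of 60 degrees exact (cos(3 * 60deg) == -1 etc.)
  constants[["chi1"]] * (1 + cospi(3 * chi1 / 180)) +
    constants[["chi1"]] * (1 + cospi(3 * chi1p / 180)) +
    constants[["chi2"]] * (1 + cospi(3 * chi2 / 180)) +
    constants[["chi2"]] * (1 + cospi(3 * chi2p / 180)) +
    constants[["chi3_2fold"]] * (1 + cospi(2 * chi3 / 180)) +
    constants[["chi3_3fold"]] * (1 + cospi(3 * chi3 / 180))
}

# pull the coordinates of one named atom out of a residue atom table
atom_xyz <- function(atoms, name) {
  row <- atoms[atoms$name == name, , drop = FALSE]
  if (nrow(row) == 0) return(NULL)
  c(row$x[1], row$y[1], row$z[1])
}

#' Measure the geometry of a disulfide-bonded cysteine pair
#'
#' Given the atom tables of the two cysteines, measures the five chi
#' dihedrals, the two alpha bending angles at the sulfurs, the S-S distance,
#' the dihedral strain energy and the B-factor average over the (up to) 12
#' standard atoms. Angle definitions: chi1 = N-CA-CB-SG, chi2 = CA-CB-SG-SG',
#' chi3 = CB-SG-SG'-CB', with chi2' and chi1' mirrored on the second residue;
#' alpha1 = CB-SG-SG' and alpha2 = CB'-SG'-SG.
#'
#' @param res1,res2 Data frames of atoms for each cysteine, with columns
#'   `name`, `x`, `y`, `z` and (for the B-factor average) `b_factor`.
#' @return A one-row tibble with columns `chi1`, `chi2`, `chi3`, `chi2p`,
#'   `chi1p` (degrees), `alpha1`, `alpha2` (degrees), `d` (angstrom), `dse`
#'   (kJ/mol), `b_avg` (angstrom^2) and `b_n_missing` (atoms absent from the
#'   12-atom set).
#' @export
measure_cystine <- function(res1, res2) {
  need <- c("N", "CA", "CB", "SG")
  for (side in list(list(res = res1, label = "residue 1"),
                    list(res = res2, label = "residue 2"))) {
    miss <- setdiff(need, side$res$name)
    if (length(miss) > 0) {
      stop(sprintf("measure_cystine(): incomplete cystine, %s lacks atom(s) %s",
                   side$label, paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  n1 <- atom_xyz(res1, "N");  ca1 <- atom_xyz(res1, "CA")
  cb1 <- atom_xyz(res1, "CB"); sg1 <- atom_xyz(res1, "SG")
  n2 <- atom_xyz(res2, "N");  ca2 <- atom_xyz(res2, "CA")
  cb2 <- atom_xyz(res2, "CB"); sg2 <- atom_xyz(res2, "SG")

  chi1  <- dihedral_angle(n1, ca1, cb1, sg1)
  chi2  <- dihedral_angle(ca1, cb1, sg1, sg2)
  chi3  <- dihedral_angle(cb1, sg1, sg2, cb2)
  chi2p <- dihedral_angle(ca2, cb2, sg2, sg1)
  chi1p <- dihedral_angle(n2, ca2, cb2, sg2)
  alpha1 <- bond_angle(cb1, sg1, sg2)
  alpha2 <- bond_angle(cb2, sg2, sg1)
  d <- vnorm(sg2 - sg1)

  bavg <- b_factor_average(res1, res2)
  tibble::tibble(
    chi1 = chi1, chi2 = chi2, chi3 = chi3, chi2p = chi2p, chi1p = chi1p,
    alpha1 = alpha1, alpha2 = alpha2, d = d,
    dse = dse(chi1, chi2, chi3, chi2p, chi1p),
    b_avg = bavg$b_avg, b_n_missing = bavg$n_missing
  )
}

#' Average B factor over the 12 atoms of a cysteine pair
#'
#' The arithmetic mean of the B factors of the six standard atoms
#' (N, CA, C, O, CB, SG) of each cysteine. Atoms absent from the model are
#' skipped; the mean is taken over the atoms present and the deficit is
#' reported.
#'
#' @param res1,res2 Atom tables with columns `name` and `b_factor`.
#' @return A list with `b_avg` (mean B, angstrom^2) and `n_missing` (number
#'   of the 12 standard atoms not found).
#' @export
b_factor_average <- function(res1, res2) {
  standard <- c("N", "CA", "C", "O", "CB", "SG")
  pick <- function(res) {
    res <- res[res$name %in% standard, , drop = FALSE]
    res <- res[!duplicated(res$name), , drop = FALSE]
    res$b_factor
  }
  bs <- c(pick(res1), pick(res2))
  if (length(bs) == 0) {
    stop("b_factor_average(): no standard atoms present", call. = FALSE)
  }
  list(b_avg = mean(bs), n_missing = 12L - length(bs))
}

#' Secondary-structure state of a residue
#'
#' Assigns `"helix"` if the residue falls inside any declared HELIX range,
#' otherwise `"strand"` if inside any SHEET range, otherwise `"loop"`.
#' Residue ranges are taken from structure header records; helix takes
#' precedence over strand for malformed headers declaring both.
#'
#' @param chain Chain identifier of the residue.
#' @param res_num Author residue number.
#' @param i_code Insertion code ("" if none). Only used for exact-boundary
#'   comparisons; residues with insertion codes inside a numeric range are
#'   treated as inside it.
#' @param helices,sheets Tibbles of ranges with columns `chain`, `start_num`,
#'   `end_num` (as produced by [parse_pdb()]).
#' @return One of `"helix"`, `"strand"`, `"loop"`.
#' @export
ss_state <- function(chain, res_num, i_code = "", helices = NULL, sheets = NULL) {
  in_range <- function(ranges) {
    if (is.null(ranges) || nrow(ranges) == 0) return(FALSE)
    any(ranges$chain == chain & ranges$start_num <= res_num & res_num <= ranges$end_num)
  }
  if (in_range(helices)) return("helix")
  if (in_range(sheets)) return("strand")
  "loop"
}

# unordered secondary-structure pair label, e.g. "helix-loop"
ss_pair_label <- function(ss1, ss2) {
  lv <- c("helix", "strand", "loop")
  a <- match(ss1, lv)
  b <- match(ss2, lv)
  paste(lv[pmin(a, b)], lv[pmax(a, b)], sep = "-")
}
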