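#' Specification of an ideal cystine
#'
#' Bundles the internal coordinates from which [build_cystine()] constructs a
#' disulfide-bonded cysteine pair: the five target chi dihedrals, the S-S
#' distance, the two alpha bending angles, standard bond lengths and angles,
#' and per-atom B factors.
#'
#' Defaults are standard cysteine stereochemistry: N-CA 1.458, CA-CB 1.530,
#' CB-SG 1.810 angstrom; N-CA-CB 110.5 deg, CA-CB-SG 114.0 deg; S-S 2.038
#' angstrom (the equilibrium disulfide length) and CB-SG-SG' 104.0 deg.
#'
#' @param chi Numeric length-5 vector of target dihedrals
#'   (chi1, chi2, chi3, chi2', chi1') in degrees.
#' @param d Target S-S distance in angstrom.
#' @param alpha Numeric length-2 vector of the CB-SG-SG' angles (degrees).
#' @param b_factors Numeric length-12 vector of B factors for the atoms in
#'   the order N, CA, C, O, CB, SG of residue 1 then residue 2.
#' @param lengths Named numeric vector of bond lengths (angstrom).
#' @param angles Named numeric vector of bond angles (degrees).
#' @return An object of class `cystine_spec`.
#' @export
cystine_spec <- function(chi = c(-60, -60, -90, -60, -60),
                         d = 2.038,
                         alpha = c(104.0, 104.0),
                         b_factors = rep(20, 12),
                         lengths = c(n_ca = 1.458, ca_cb = 1.530, cb_sg = 1.810,
                                     ca_c = 1.525, c_o = 1.231),
                         angles = c(n_ca_cb = 110.5, ca_cb_sg = 114.0,
                                    cb_ca_c = 110.1, ca_c_o = 120.8)) {
  stopifnot(length(chi) == 5, length(alpha) == 2, length(b_factors) == 12)
  if (any(!is.finite(c(chi, d, alpha))) || d <= 0) {
    stop("cystine_spec(): non-finite targets or non-positive S-S distance",
         call. = FALSE)
  }
  if (any(lengths <= 0)) stop("cystine_spec(): bond lengths must be positive", call. = FALSE)
  if (any(c(alpha, angles) <= 0) || any(c(alpha, angles) >= 180)) {
    stop("cystine_spec(): bond angles must lie strictly inside (0, 180)", call. = FALSE)
  }
  structure(list(chi = chi, d = d, alpha = alpha, b_factors = b_factors,
                 lengths = lengths, angles = angles),
            class = "cystine_spec")
}

#' Draw random cystine specifications
#'
#' Chi targets are uniform in magnitude over (5, 175) degrees with random
#' signs (5 degrees away from the 0/180 sign boundaries, so configuration
#' classification is unambiguous); alpha angles uniform in (100, 110)
#' degrees. `chi3` can instead be drawn near a chosen location to emulate
#' torsionally strained (low |chi3|) or relaxed (|chi3| near 90) bond
#' populations.
#'
#' @param n Number of specs.
#' @param seed Integer seed.
#' @param chi3_location Optional |chi3| center (degrees); when given, chi3
#'   magnitudes are drawn normally around it (sd `chi3_sd`, clamped to
#'   (5, 175)) with random sign.
#' @param chi3_sd Spread of the chi3 magnitude draw.
#' @param d S-S distance (angstrom); by default drawn uniformly from the
#'   observed crystallographic range 1.98-2.10.
#' @return List of [cystine_spec()] objects.
#' @export
random_cystine_specs <- function(n, seed, chi3_location = NULL, chi3_sd = 15,
                                 d = NULL) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      chi <- random_chi_targets()
      if (!is.null(chi3_location)) {
        mag <- min(175, max(5, stats::rnorm(1, chi3_location, chi3_sd)))
        chi[3] <- mag * sample(c(-1, 1), 1)
      }
      cystine_spec(chi = chi,
                   d = if (is.null(d)) stats::runif(1, 1.98, 2.10) else d,
                   alpha = stats::runif(2, 100, 110),
                   b_factors = stats::runif(12, 10, 40))
    })
  })
}

# Natural-extension-reference-frame placement: position atom D bonded to c,
# with bond length r, bond angle theta at c (b-c-D) and torsion phi (a-b-c-D).
nerf_place <- function(a, b, c, r, theta_deg, phi_deg) {
  theta <- theta_deg * pi / 180
  phi <- phi_deg * pi / 180
  bc <- (c - b) / vnorm(c - b)
  n <- cross3(b - a, bc)
  if (vnorm(n) < 1e-10) {
    stop("nerf_place(): reference atoms are collinear", call. = FALSE)
  }
  n <- n / vnorm(n)
  m <- cross3(n, bc)
  d2 <- c(-r * cos(theta), r * sin(theta) * cos(phi), r * sin(theta) * sin(phi))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build cystine coordinates from internal coordinates
#'
#' Constructs the 12 atoms (N, CA, C, O, CB, SG per residue) of a
#' disulfide-bonded cysteine pair by sequential natural-extension-reference-
#' frame placement, so that [measure_cystine()] recovers the spec's chi
#' angles, alpha angles and S-S distance exactly (to numerical precision).
#' This is the inverse of the measurement and the workhorse of the
#' synthetic-fixture generator.
#'
#' @param spec A [cystine_spec()].
#' @return A tibble of 12 atoms with columns `residue` (1 or 2), `name`,
#'   `x`, `y`, `z`, `b_factor`, in PDB atom order per residue.
#' @export
build_cystine <- function(spec) {
  stopifnot(inherits(spec, "cystine_spec"))
  L <- spec$lengths
  A <- spec$angles
  chi <- spec$chi

  n1 <- c(0, 0, 0)
  ca1 <- c(L[["n_ca"]], 0, 0)
  # CB in the xy-plane making the N-CA-CB angle at CA
  ang <- A[["n_ca_cb"]] * pi / 180
  cb1 <- ca1 + L[["ca_cb"]] * c(cos(ang) * -1, sin(ang), 0)

  sg1 <- nerf_place(n1, ca1, cb1, L[["cb_sg"]], A[["ca_cb_sg"]], chi[1])
  sg2 <- nerf_place(ca1, cb1, sg1, spec$d, spec$alpha[1], chi[2])
  cb2 <- nerf_place(cb1, sg1, sg2, L[["cb_sg"]], spec$alpha[2], chi[3])
  ca2 <- nerf_place(sg1, sg2, cb2, L[["ca_cb"]], A[["ca_cb_sg"]], chi[4])
  n2 <- nerf_place(sg2, cb2, ca2, L[["n_ca"]], A[["n_ca_cb"]], chi[5])
  # carbonyl groups at fixed idealized geometry; torsions offset from chi1 so
  # the backbone stays chemically plausible around the tetrahedral CA
  c1 <- nerf_place(sg1, cb1, ca1, L[["ca_c"]], A[["cb_ca_c"]], wrap_angle(chi[1] - 122))
  o1 <- nerf_place(cb1, ca1, c1, L[["c_o"]], A[["ca_c_o"]], -60)
  c2 <- nerf_place(sg2, cb2, ca2, L[["ca_c"]], A[["cb_ca_c"]], wrap_angle(chi[5] - 122))
  o2 <- nerf_place(cb2, ca2, c2, L[["c_o"]], A[["ca_c_o"]], -60)

  coords <- unname(rbind(n1, ca1, c1, o1, cb1, sg1, n2, ca2, c2, o2, cb2, sg2))
  tibble::tibble(
    residue = rep(c(1L, 2L), each = 6),
    name = rep(c("N", "CA", "C", "O", "CB", "SG"), 2),
    x = unname(coords[, 1]), y = unname(coords[, 2]), z = unname(coords[, 3]),
    b_factor = unname(spec$b_factors)
  )
}
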