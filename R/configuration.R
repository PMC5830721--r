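#' Sign vector of a cystine's five chi angles
#'
#' Reduces (chi1, chi2, chi3, chi2', chi1') to "+"/"-" signs. Angles of
#' exactly 0 or +/-180 degrees sit on a classification boundary: they are
#' assigned "-" by the tie rule and flagged, so affected bonds can be kept
#' out of configuration tallies.
#'
#' @param chi1,chi2,chi3,chi2p,chi1p Dihedral angles in degrees, in
#'   (-180, 180].
#' @return A list with `signs` (character length-5 of "+"/"-") and
#'   `boundary` (logical, TRUE if any angle was exactly 0 or +/-180).
#' @export
sign_vector <- function(chi1, chi2, chi3, chi2p, chi1p) {
  chis <- c(chi1, chi2, chi3, chi2p, chi1p)
  if (any(!is.finite(chis))) {
    stop("sign_vector(): chi angles must be finite", call. = FALSE)
  }
  boundary <- chis == 0 | abs(chis) == 180
  signs <- ifelse(chis > 0 & !boundary, "+", "-")
  list(signs = signs, boundary = any(boundary))
}

#' Classify a sign vector into one of the 20 cystine configurations
#'
#' The class name has three parts. Handedness: RH if chi3 is positive, LH if
#' negative. Shape, from the signs of chi2 and chi2' relative to chi3: both
#' equal gives a spiral, both opposite a staple, one of each a hook. Prefix,
#' from the chi1/chi1' signs: "-" if both negative, "+" if both positive,
#' mixed otherwise. For spirals and staples the two sides are
#' interchangeable, so the mixed prefix is always rendered "-/+"; for hooks
#' the sides are distinguishable (one chi2 matches chi3, the other does not)
#' and the prefix is read with the chi3-matching side first, so mixed-chi1
#' hooks split into "-/+" and "+/-". This yields 10 names per handedness
#' (3 spirals + 3 staples + 4 hooks) = 20 configurations, and the name is
#' invariant under reversing the traversal direction of the bond.
#'
#' @param signs Character vector of five "+"/"-" signs, ordered
#'   (chi1, chi2, chi3, chi2', chi1').
#' @return A list with `name` (e.g. `"-RHstaple"`), `prefix`, `handedness`
#'   and `shape`.
#' @examples
#' classify_configuration(c("-", "-", "-", "-", "-"))$name # "-LHspiral"
#' classify_configuration(c("-", "-", "+", "-", "-"))$name # "-RHstaple"
#' @export
classify_configuration <- function(signs) {
  stopifnot(length(signs) == 5, all(signs %in% c("+", "-")))
  s1 <- signs[1]; s2 <- signs[2]; s3 <- signs[3]; s4 <- signs[4]; s5 <- signs[5]
  handedness <- if (s3 == "+") "RH" else "LH"
  shape <- if (s2 == s3 && s4 == s3) {
    "spiral"
  } else if (s2 != s3 && s4 != s3) {
    "staple"
  } else {
    "hook"
  }
  if (shape == "hook") {
    # canonical side order: the side whose chi2 sign matches chi3 comes first
    pair <- if (s2 == s3) c(s1, s5) else c(s5, s1)
    prefix <- if (pair[1] == "-" && pair[2] == "-") {
      "-"
    } else if (pair[1] == "+" && pair[2] == "+") {
      "+"
    } else if (pair[1] == "-") {
      "-/+"
    } else {
      "+/-"
    }
  } else {
    prefix <- if (s1 == "-" && s5 == "-") {
      "-"
    } else if (s1 == "+" && s5 == "+") {
      "+"
    } else {
      "-/+"
    }
  }
  list(name = paste0(prefix, handedness, shape),
       prefix = prefix, handedness = handedness, shape = shape)
}

#' The 20 cystine configuration names
#'
#' @return Character vector of all 20 configuration names in a fixed display
#'   order (LH before RH; spirals, hooks, staples; "-", "+", mixed).
#' @export
configuration_names <- function() {
  out <- character(0)
  for (hand in c("LH", "RH")) {
    out <- c(out,
             paste0(c("-", "+", "-/+"), hand, "spiral"),
             paste0(c("-", "+", "-/+", "+/-"), hand, "hook"),
             paste0(c("-", "+", "-/+"), hand, "staple"))
  }
  out
}

#' Configuration names conventionally regarded as allosteric
#'
#' The -RHstaple, -LHhook and -/+RHhook classes.
#'
#' @return Character vector of three configuration names.
#' @export
allosteric_configurations <- function() {
  c("-RHstaple", "-LHhook", "-/+RHhook")
}

#' Configuration of measured cystine geometries
#'
#' Vectorized convenience wrapper: takes a data frame of measured geometries
#' (as produced by [measure_cystine()]) and appends `config` and
#' `config_boundary` columns.
#'
#' @param geoms Data frame with columns `chi1`, `chi2`, `chi3`, `chi2p`,
#'   `chi1p`.
#' @return The input tibble with `config` (character) and `config_boundary`
#'   (logical) columns added.
#' @export
add_configuration <- function(geoms) {
  res <- purrr::pmap(
    list(geoms$chi1, geoms$chi2, geoms$chi3, geoms$chi2p, geoms$chi1p),
    function(c1, c2, c3, c4, c5) {
      if (any(is.na(c(c1, c2, c3, c4, c5)))) {
        return(list(name = NA_character_, boundary = NA))
      }
      sv <- sign_vector(c1, c2, c3, c4, c5)
      list(name = classify_configuration(sv$signs)$name, boundary = sv$boundary)
    }
  )
  geoms$config <- purrr::map_chr(res, "name")
  geoms$config_boundary <- purrr::map_lgl(res, "boundary")
  geoms
}
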