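# Cone-space constants ------------------------------------------------------
#
# Linear sRGB -> LMS after Hunt-Pointer-Estevez, in the unnormalised D65
# scaling used by Vienot, Brettel & Mollon (1999). The white axis of this
# matrix (LMS of linear RGB (1,1,1)) is the hinge of every projection below.
RGB_TO_LMS <- matrix(c(
  17.8824,    43.5161,  4.11935,
  3.45565,    27.1554,  3.86714,
  0.0299566,  0.184309, 1.46709
), nrow = 3, byrow = TRUE)

# Linear sRGB -> CIE XYZ (D65), used only to carry spectral anchor stimuli
# into the LMS space above.
RGB_TO_XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

# CIE 1931 2-degree colour-matching values at the Brettel anchor wavelengths.
CMF_ANCHORS <- list(
  nm485 = c(0.05795001, 0.1693147, 0.6162232),
  nm660 = c(0.1649, 0.0610, 0.0)
)

# Machado, Oliveira & Fernandes (2009) severity-1.0 simulation matrices
# (linear RGB -> linear RGB). Rows are renormalised at build time to sum to
# exactly 1 so the achromatic axis is preserved to machine precision.
MACHADO_MATRICES <- list(
  protanopia = matrix(c(
    0.152286, 1.052583, -0.204868,
    0.114503, 0.786281, 0.099216,
    -0.003882, -0.048116, 1.051998
  ), nrow = 3, byrow = TRUE),
  deuteranopia = matrix(c(
    0.367322, 0.860646, -0.227968,
    0.280085, 0.672501, 0.047413,
    -0.011820, 0.042940, 0.968881
  ), nrow = 3, byrow = TRUE),
  tritanopia = matrix(c(
    1.255528, -0.076749, -0.178779,
    -0.078411, 0.930809, 0.147602,
    0.004733, 0.691367, 0.303900
  ), nrow = 3, byrow = TRUE)
)

#' Supported color vision deficiency conditions
#'
#' The closed set of conditions understood by the simulator: `"none"`
#' (normal trichromacy, identity transform) and the three dichromacies
#' `"protanopia"` (no L cones), `"deuteranopia"` (no M cones) and
#' `"tritanopia"` (no S cones). Severity is always complete dichromacy.
#'
#' @param include_none Include `"none"` in the returned vector?
#' @return Character vector of condition names.
#' @export
cvd_conditions <- function(include_none = TRUE) {
  conds <- c("protanopia", "deuteranopia", "tritanopia")
  if (include_none) c("none", conds) else conds
}

match_condition <- function(condition, allow_none = TRUE) {
  cond <- rlang::arg_match0(condition, cvd_conditions(include_none = TRUE))
  if (!allow_none && cond == "none") {
    abort("no model for normal vision: condition must not be \"none\"")
  }
  cond
}

#' Build a dichromat simulation model
#'
#' Constructs the linear-algebraic machinery that simulates complete
#' dichromacy. Two model families are available:
#'
#' * `"brettel"` (default): projection in LMS cone space. Protanopia and
#'   deuteranopia use a single rank-2 idempotent projection onto a plane
#'   that contains the display-white axis (the Vienot et al. 1999
#'   single-plane reduction, re-anchored so the white axis is preserved
#'   exactly); tritanopia uses the Brettel et al. 1997 two half-plane
#'   construction, with planes through the white axis and spectral anchors
#'   at 485 nm and 660 nm, and a separating plane spanned by the white axis
#'   and the S-cone axis. Ties on the separating plane go to the first
#'   (660 nm) half-plane.
#' * `"machado"`: the Machado et al. (2009) severity-1.0 precomputed
#'   linear-RGB matrices, rows renormalised to sum to exactly 1.
#'
#' @param condition One of `"protanopia"`, `"deuteranopia"`, `"tritanopia"`.
#'   `"none"` is an error: normal vision needs no model.
#' @param model Model family, `"brettel"` or `"machado"`.
#' @return An object of class `cvd_model`. For the `"brettel"` family it
#'   holds `rgb_to_lms`, `lms_to_rgb`, either `projection` (protan/deutan)
#'   or `projection_1`/`projection_2` plus `separating_normal` (tritan).
#'   For `"machado"` it holds the single `rgb_matrix`.
#' @examples
#' m <- build_dichromat_model("protanopia")
#' max(abs(m$projection %*% m$projection - m$projection)) # idempotent
#' @export
build_dichromat_model <- function(condition, model = c("brettel", "machado")) {
  condition <- match_condition(condition, allow_none = FALSE)
  model <- rlang::arg_match(model)
  if (model == "machado") {
    mat <- MACHADO_MATRICES[[condition]]
    mat <- mat / rowSums(mat)
    out <- list(condition = condition, family = "machado", rgb_matrix = mat)
    class(out) <- "cvd_model"
    return(out)
  }

  lms_white <- as.vector(RGB_TO_LMS %*% c(1, 1, 1))
  out <- list(
    condition = condition, family = "brettel",
    rgb_to_lms = RGB_TO_LMS,
    lms_to_rgb = solve(RGB_TO_LMS),
    lms_white = lms_white
  )

  if (condition == "tritanopia") {
    xyz_to_lms <- RGB_TO_LMS %*% solve(RGB_TO_XYZ)
    a660 <- as.vector(xyz_to_lms %*% CMF_ANCHORS$nm660)
    a485 <- as.vector(xyz_to_lms %*% CMF_ANCHORS$nm485)
    out$projection_1 <- tritan_halfplane_projection(lms_white, a660)
    out$projection_2 <- tritan_halfplane_projection(lms_white, a485)
    # Separating plane spans the white axis and the missing (S) cone axis;
    # its normal has zero S component, so half-plane membership is invariant
    # under the projections themselves.
    out$separating_normal <- c(lms_white[2], -lms_white[1], 0)
    stopifnot(sum(out$separating_normal * a660) > 0,
              sum(out$separating_normal * a485) < 0)
  } else {
    out$projection <- vienot_projection(condition, lms_white)
  }
  class(out) <- "cvd_model"
  out
}

# Single-plane projection for protanopia/deuteranopia. The leading
# coefficient is the published Vienot value; the S coefficient is re-solved
# so that the projection plane contains the display white axis exactly.
vienot_projection <- function(condition, w) {
  if (condition == "protanopia") {
    a <- 2.02344
    b <- (w[1] - a * w[2]) / w[3]
    matrix(c(0, a, b,
             0, 1, 0,
             0, 0, 1), nrow = 3, byrow = TRUE)
  } else {
    a <- 0.494207
    b <- (w[2] - a * w[1]) / w[3]
    matrix(c(1, 0, 0,
             a, 0, b,
             0, 0, 1), nrow = 3, byrow = TRUE)
  }
}

# Projection onto the plane spanned by the white axis and one spectral
# anchor, along the S axis: S' = a*L + b*M with both generators preserved.
tritan_halfplane_projection <- function(w, anchor) {
  ab <- solve(
    rbind(c(w[1], w[2]), c(anchor[1], anchor[2])),
    c(w[3], anchor[3])
  )
  matrix(c(1, 0, 0,
           0, 1, 0,
           ab[1], ab[2], 0), nrow = 3, byrow = TRUE)
}

#' @export
print.cvd_model <- function(x, ...) {
  cat(sprintf("<cvd_model> %s (%s family)\n", x$condition, x$family))
  if (x$family == "brettel" && x$condition == "tritanopia") {
    cat("  two half-plane LMS projections (anchors 660 nm / 485 nm)\n")
  } else if (x$family == "brettel") {
    cat("  single-plane LMS projection through the white axis\n")
  } else {
    cat("  precomputed linear-RGB matrix, severity 1.0\n")
  }
  invisible(x)
}
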