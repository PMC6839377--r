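#' Dose-gradient magnitude of a reference grid
#'
#' Computes the spatial gradient of the reference dose expressed in percent
#' of the reference maximum, using central finite differences in the interior
#' and one-sided differences at the borders, and returns the Euclidean norm
#' of the two directional derivatives. Units are percent of the normalization
#' dose per mm, the quantity that converts a distance-to-agreement criterion
#' into a dose tolerance.
#'
#' @param reference a [dose_grid()] with at least 2 rows and 2 columns.
#' @return an object of class `gradient_map`: `magnitude` (matrix aligned to
#'   the reference grid, %/mm), plus the reference spacing and origin.
#' @export
dose_gradient <- function(reference) {
  assert_dose_grid(reference)
  v <- reference$values
  if (nrow(v) < 2 || ncol(v) < 2) {
    stop("gradient requires at least 2 rows and 2 columns", call. = FALSE)
  }
  rel <- 100 * v / max(v)
  # pracma::gradient: X differentiates across columns (spacing h1),
  # Y down rows (spacing h2)
  g <- pracma::gradient(rel, h1 = reference$spacing[2],
                        h2 = reference$spacing[1])
  structure(
    list(magnitude = sqrt(g$X^2 + g$Y^2),
         spacing = reference$spacing,
         origin = reference$origin),
    class = "gradient_map"
  )
}

#' Maximum allowed dose difference map
#'
#' Converts the DTA criterion into a dose tolerance by multiplying the local
#' reference dose gradient, and combines it with the dose-difference
#' criterion: by summation for the box form,
#' \eqn{MADD_b = \Delta D + g \cdot DTA}, or in quadrature for the gamma
#' form, \eqn{MADD_\gamma = \sqrt{\Delta D^2 + (g \cdot DTA)^2}}. The
#' gradient is evaluated on the high-resolution reference grid at the
#' reference point nearest each evaluated point (ties toward the lower
#' index); the measured grid is too coarse for meaningful gradients.
#'
#' @param reference the reference [dose_grid()].
#' @param evaluated the evaluated [dose_grid()] defining the points at which
#'   the tolerance is needed.
#' @param criteria a [criteria_pair()]; its `delta_d` and `dta` are used.
#' @param mode `"box"` (summation) or `"gamma"` (quadrature).
#' @return an object of class `madd_map`: `allowed` (matrix of tolerances in
#'   percent of the reference maximum, aligned to the evaluated grid),
#'   `mode`, `criteria`. `allowed >= delta_d` everywhere, and the box
#'   tolerance dominates the quadrature tolerance pointwise.
#' @export
madd_map <- function(reference, evaluated, criteria,
                     mode = c("box", "gamma")) {
  mode <- match.arg(mode)
  assert_dose_grid(reference)
  assert_dose_grid(evaluated)
  if (!inherits(criteria, "criteria_pair")) {
    stop("criteria must be a criteria_pair", call. = FALSE)
  }
  check_extent(reference, evaluated)
  grad <- dose_gradient(reference)
  ri <- nearest_index(axis_mm(evaluated, 1), reference$origin[1],
                      reference$spacing[1], nrow(reference$values))
  ci <- nearest_index(axis_mm(evaluated, 2), reference$origin[2],
                      reference$spacing[2], ncol(reference$values))
  g <- grad$magnitude[ri, ci, drop = FALSE]
  allowed <- if (mode == "box") {
    criteria$delta_d + g * criteria$dta
  } else {
    sqrt(criteria$delta_d^2 + (g * criteria$dta)^2)
  }
  structure(
    list(allowed = allowed, mode = mode, criteria = criteria),
    class = "madd_map"
  )
}

#' Normalized dose difference map (MADD agreement test)
#'
#' The per-point index is the absolute dose difference between the evaluated
#' point and the nearest reference point, expressed in percent of the
#' reference maximum, divided by the local maximum allowed dose difference.
#' Values at most 1 indicate agreement. Unlike gamma evaluation there is no
#' spatial search: the MADD test is pointwise by construction, which makes it
#' insensitive to dose-grid resolution.
#'
#' @param reference the reference [dose_grid()].
#' @param evaluated the evaluated [dose_grid()].
#' @param madd a [madd_map()] aligned to `evaluated`.
#' @param mask an `evaluation_mask` congruent with `evaluated`, or `NULL`
#'   for all points.
#' @return a `dose_comparison` with technique `"madd_box"` or `"madd_gamma"`.
#' @export
ndd_map <- function(reference, evaluated, madd, mask = NULL) {
  assert_dose_grid(reference)
  assert_dose_grid(evaluated)
  if (!inherits(madd, "madd_map")) {
    stop("madd must be a madd_map", call. = FALSE)
  }
  if (!identical(dim(madd$allowed), dim(evaluated$values))) {
    stop("madd map shape does not match the evaluated grid", call. = FALSE)
  }
  check_extent(reference, evaluated)
  if (is.null(mask)) {
    mask <- structure(
      list(included = matrix(TRUE, nrow(evaluated$values),
                             ncol(evaluated$values)),
           ldt_percent = 0),
      class = "evaluation_mask"
    )
  }
  if (any(madd$allowed <= 0)) {
    stop("internal error: non-positive MADD tolerance", call. = FALSE)
  }
  ref_ev <- reference_at(reference, evaluated)
  diff_pct <- 100 * (evaluated$values - ref_ev) / max(reference$values)
  idx <- abs(diff_pct) / madd$allowed
  idx[!mask$included] <- NA_real_
  new_dose_comparison(idx, mask, paste0("madd_", madd$mode), madd$criteria)
}
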