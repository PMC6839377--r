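#' Gamma evaluation criteria
#'
#' A pair of acceptance criteria for gamma evaluation: the dose-difference
#' criterion \eqn{\Delta D} (percent) and the distance-to-agreement criterion
#' DTA (mm), together with the normalization convention for percent dose
#' differences. Global normalization scales differences by the maximum of the
#' reference distribution; local normalization scales by the reference dose at
#' each candidate point.
#'
#' @param delta_d dose-difference criterion in percent (> 0).
#' @param dta distance-to-agreement criterion in mm (> 0).
#' @param normalization `"global"` or `"local"`.
#' @return an object of class `criteria_pair`.
#' @export
criteria_pair <- function(delta_d, dta, normalization = c("global", "local")) {
  normalization <- match.arg(normalization)
  if (!is.numeric(delta_d) || length(delta_d) != 1 || !is.finite(delta_d) ||
      delta_d <= 0) {
    stop("delta_d must be a single positive percentage", call. = FALSE)
  }
  if (!is.numeric(dta) || length(dta) != 1 || !is.finite(dta) || dta <= 0) {
    stop("dta must be a single positive distance in mm", call. = FALSE)
  }
  structure(
    list(delta_d = delta_d, dta = dta, normalization = normalization),
    class = "criteria_pair"
  )
}

#' @export
print.criteria_pair <- function(x, ...) {
  cat(sprintf("<criteria_pair> %g%%/%g mm, %s normalization\n",
              x$delta_d, x$dta, x$normalization))
  invisible(x)
}

format_criteria <- function(x) {
  if (inherits(x, "region_criteria")) {
    sprintf("dDgamma %g%% / %g mm", x$delta_d_gamma, x$dta)
  } else {
    sprintf("%g%%/%g mm (%s)", x$delta_d, x$dta, x$normalization)
  }
}

# Core per-map gamma engine. Returns the gamma value for every TRUE cell of
# `included`, NA elsewhere. `search = "optimized"` uses an exact windowed
# search: the gamma at the nearest reference node bounds the minimum from
# above, so no reference point whose spatial term alone exceeds that bound
# can be the minimizer; the window is sized accordingly and the result is
# identical to the exhaustive search.
gamma_values <- function(reference, evaluated, delta_d, dta, normalization,
                         included, search = "optimized") {
  V <- reference$values
  nr <- nrow(V); nc <- ncol(V)
  ry <- axis_mm(reference, 1); rx <- axis_mm(reference, 2)
  ey <- axis_mm(evaluated, 1); ex <- axis_mm(evaluated, 2)
  N <- max(V)
  local <- normalization == "local"
  dta2 <- dta^2
  dd2 <- delta_d^2
  sp <- reference$spacing
  EV <- evaluated$values
  out <- matrix(NA_real_, nrow(EV), ncol(EV))
  pts <- which(included)
  if (length(pts) == 0) return(out)
  ij <- arrayInd(pts, dim(EV))
  ri0 <- nearest_index(ey, reference$origin[1], sp[1], nr)
  ci0 <- nearest_index(ex, reference$origin[2], sp[2], nc)
  for (k in seq_along(pts)) {
    i <- ij[k, 1]; j <- ij[k, 2]
    De <- EV[pts[k]]
    dy2 <- (ry - ey[i])^2
    dx2 <- (rx - ex[j])^2
    rows <- seq_len(nr); cols <- seq_len(nc)
    if (search == "optimized") {
      i0 <- ri0[i]; j0 <- ci0[j]
      den0 <- if (local) V[i0, j0] else N
      if (!local || den0 > 0) {
        g0 <- sqrt((dy2[i0] + dx2[j0]) / dta2 +
                     (100 * (De - V[i0, j0]) / den0)^2 / dd2)
        r <- dta * g0
        rows <- max(1L, i0 - ceiling(r / sp[1])):min(nr, i0 + ceiling(r / sp[1]))
        cols <- max(1L, j0 - ceiling(r / sp[2])):min(nc, j0 + ceiling(r / sp[2]))
      }
    }
    sub <- V[rows, cols, drop = FALSE]
    dist2 <- outer(dy2[rows], dx2[cols], "+")
    if (local) {
      delta2 <- (100 * (De - sub) / sub)^2
      delta2[sub <= 0] <- Inf
    } else {
      delta2 <- (100 * (De - sub) / N)^2
    }
    out[pts[k]] <- sqrt(min(dist2 / dta2 + delta2 / dd2))
  }
  out
}

new_dose_comparison <- function(index_map, mask, technique, criteria,
                                subclass = NULL) {
  inc <- mask$included
  n_inc <- sum(inc)
  if (n_inc == 0) {
    stop("no evaluated points above the lower dose threshold", call. = FALSE)
  }
  vals <- index_map[inc]
  structure(
    list(
      index_map = index_map,
      mask = mask,
      agreement_index = 100 * sum(vals <= 1) / n_inc,
      n_included = n_inc,
      technique = technique,
      criteria = criteria
    ),
    class = c(subclass, "dose_comparison")
  )
}

#' Gamma map between a reference and an evaluated dose grid
#'
#' Computes, for each included evaluated point, the gamma index: the minimum
#' over reference points of
#' \deqn{\gamma = \sqrt{\frac{|r - r_e|^2}{DTA^2} + \frac{\delta^2}{\Delta D^2}}}
#' where \eqn{\delta} is the percent dose difference between the evaluated
#' point and the candidate reference point, normalized globally (to the
#' reference maximum) or locally (to the candidate's reference dose).
#' Reference points with zero dose are skipped under local normalization; if
#' every candidate is skipped, the point's gamma is `Inf` and it fails.
#'
#' The evaluated (typically measured, coarse) grid is compared against the
#' reference (typically calculated, fine) grid without interpolating either;
#' the search runs over the discrete reference points.
#'
#' @param reference the reference (planned) [dose_grid()], typically at fine
#'   resolution.
#' @param evaluated the evaluated (measured) [dose_grid()]; all its positions
#'   must lie inside the reference extent.
#' @param criteria a [criteria_pair()].
#' @param mask an `evaluation_mask` congruent with `evaluated`, e.g. from
#'   [apply_ldt()] on the reference sampled at the evaluated positions;
#'   `NULL` includes every point.
#' @param search `"optimized"` (exact windowed search) or `"exhaustive"`
#'   (minimum over every reference point). Both return identical values; the
#'   exhaustive mode exists as a cross-check.
#' @return a `dose_comparison` object: `index_map` (gamma per evaluated point,
#'   `NA` where excluded), `mask`, `agreement_index` (%GP, percentage of
#'   included points with gamma <= 1), `technique` and `criteria`.
#' @examples
#' ref <- dose_grid(matrix(rep(50, 121), 11, 11), spacing = 1)
#' ev <- dose_grid(matrix(rep(51.5, 4), 2, 2), spacing = 5, origin = c(2, 2))
#' gamma_map(ref, ev, criteria_pair(3, 3, "global"))
#' @export
gamma_map <- function(reference, evaluated, criteria, mask = NULL,
                      search = c("optimized", "exhaustive")) {
  search <- match.arg(search)
  assert_dose_grid(reference)
  assert_dose_grid(evaluated)
  if (!inherits(criteria, "criteria_pair")) {
    stop("criteria must be a criteria_pair", call. = FALSE)
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
  if (!identical(dim(mask$included), dim(evaluated$values))) {
    stop("mask shape does not match the evaluated grid", call. = FALSE)
  }
  idx <- gamma_values(reference, evaluated, criteria$delta_d, criteria$dta,
                      criteria$normalization, mask$included, search)
  technique <- paste0("gamma_", criteria$normalization)
  new_dose_comparison(idx, mask, technique, criteria)
}

#' Agreement index (pass rate) of a comparison
#'
#' The percentage of included evaluated points whose per-point index is at
#' most 1 (inclusive). Excluded points contribute to neither numerator nor
#' denominator.
#'
#' @param result a `dose_comparison` (from [gamma_map()], [ndd_map()],
#'   [dnc_evaluate()] or [compare_dose()]).
#' @return the agreement index in percent.
#' @export
pass_rate <- function(result) {
  if (!inherits(result, "dose_comparison")) {
    stop("result must be a dose_comparison", call. = FALSE)
  }
  inc <- result$mask$included
  if (sum(inc) == 0) {
    stop("no included points: agreement index undefined", call. = FALSE)
  }
  100 * sum(result$index_map[inc] <= 1) / sum(inc)
}

#' @export
print.dose_comparison <- function(x, ...) {
  cat(sprintf("<dose_comparison> technique %s, criteria %s\n",
              x$technique, format_criteria(x$criteria)))
  cat(sprintf("  %d included points (LDT %g%%), agreement index %.2f%%\n",
              x$n_included, x$mask$ldt_percent, x$agreement_index))
  invisible(x)
}

#' @export
summary.dose_comparison <- function(object, ...) {
  vals <- object$index_map[object$mask$included]
  structure(
    list(
      technique = object$technique,
      criteria = object$criteria,
      ldt_percent = object$mask$ldt_percent,
      n_included = object$n_included,
      n_fail = sum(vals > 1),
      agreement_index = object$agreement_index,
      index_quantiles = stats::quantile(
        vals[is.finite(vals)],
        c(0, 0.25, 0.5, 0.75, 0.95, 1), names = TRUE)
    ),
    class = "summary.dose_comparison"
  )
}

#' @export
print.summary.dose_comparison <- function(x, ...) {
  cat(sprintf("Dose comparison: %s at %s, LDT %g%%\n",
              x$technique, format_criteria(x$criteria), x$ldt_percent))
  cat(sprintf("  points: %d included, %d failing (index > 1)\n",
              x$n_included, x$n_fail))
  cat(sprintf("  agreement index: %.2f%%\n", x$agreement_index))
  cat("  index quantiles:\n")
  print(round(x$index_quantiles, 4))
  invisible(x)
}

#' Plot a per-point index map
#'
#' Displays the per-point comparison index (gamma or normalized dose
#' difference) as an image in physical coordinates; failing points
#' (index > 1) are overplotted with crosses.
#'
#' @param x a `dose_comparison`.
#' @param ... further arguments passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.dose_comparison <- function(x, ...) {
  m <- x$index_map
  finite_vals <- m[is.finite(m)]
  m[is.infinite(m)] <- if (length(finite_vals)) max(finite_vals, 2) else 2
  ys <- seq_len(nrow(m)); xs <- seq_len(ncol(m))
  graphics::image(xs, ys, t(m), xlab = "column", ylab = "row",
                  main = sprintf("%s, %s: %.1f%%", x$technique,
                                 format_criteria(x$criteria),
                                 x$agreement_index),
                  ...)
  fail <- which(x$index_map > 1 & x$mask$included, arr.ind = TRUE)
  if (nrow(fail) > 0) {
    graphics::points(fail[, 2], fail[, 1], pch = 4)
  }
  invisible(x)
}
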