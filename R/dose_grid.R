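#' Construct a 2D dose grid
#'
#' A `dose_grid` is the unit of comparison throughout the package: a planar
#' scalar dose field with uniform spacing, a physical origin, and a dose mode.
#' In absolute mode values are doses in Gy; in relative mode values are
#' percentages of the distribution maximum (so the maximum is exactly 100).
#'
#' The physical position of cell `(i, j)` (1-based indices) is
#' `origin + ((i-1) * row_spacing, (j-1) * col_spacing)` in mm, with positions
#' taken at cell centres. Row index increases along the first (y) axis.
#'
#' @param values numeric matrix of doses; all finite and non-negative.
#' @param spacing grid spacing in mm, either a single value or
#'   `c(row_mm, col_mm)`; strictly positive.
#' @param origin physical position `c(y_mm, x_mm)` of cell `(1, 1)`.
#' @param mode `"absolute"` (Gy) or `"relative"` (% of maximum; the maximum
#'   must equal 100 within 1e-9).
#' @return an object of class `dose_grid`.
#' @examples
#' g <- dose_grid(matrix(1:9, 3, 3), spacing = 10)
#' g
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0),
                      mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) {
    stop("dose values must all be finite", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("dose values must be non-negative", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- c(spacing, spacing)
  if (length(spacing) != 2 || !all(is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be one or two strictly positive values (mm)",
         call. = FALSE)
  }
  origin <- as.numeric(origin)
  if (length(origin) != 2 || !all(is.finite(origin))) {
    stop("origin must be two finite values (y_mm, x_mm)", call. = FALSE)
  }
  if (mode == "relative" && abs(max(values) - 100) > 1e-9) {
    stop("relative-mode grids must have maximum 100 (within 1e-9)",
         call. = FALSE)
  }
  structure(
    list(values = values, spacing = spacing, origin = origin, mode = mode),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf(
    "<dose_grid> %d x %d, spacing %g x %g mm, origin (%g, %g) mm, %s mode\n",
    nrow(x$values), ncol(x$values), x$spacing[1], x$spacing[2],
    x$origin[1], x$origin[2], x$mode
  ))
  cat(sprintf("  dose range: [%g, %g] %s\n", min(x$values), max(x$values),
              if (x$mode == "absolute") "Gy" else "% of max"))
  invisible(x)
}

is_dose_grid <- function(x) inherits(x, "dose_grid")

assert_dose_grid <- function(x, arg = deparse(substitute(x))) {
  if (!is_dose_grid(x)) {
    stop(sprintf("`%s` must be a dose_grid", arg), call. = FALSE)
  }
  invisible(x)
}

# physical coordinates (mm) of cell centres along one axis (1 = rows, 2 = cols)
axis_mm <- function(grid, axis) {
  n <- dim(grid$values)[axis]
  grid$origin[axis] + (seq_len(n) - 1) * grid$spacing[axis]
}

#' Normalize a dose grid to its maximum
#'
#' Rescales so that the maximum dose equals exactly 100 and marks the grid as
#' relative mode. Used for pairs measured in relative dose, where both the
#' planned and the measured distribution are normalized at dose maximum.
#' Idempotent: an already relative grid is returned unchanged up to floating
#' point.
#'
#' @param grid a [dose_grid()].
#' @return a relative-mode `dose_grid` with the same shape, spacing and origin.
#' @export
normalize_to_max <- function(grid) {
  assert_dose_grid(grid)
  mx <- max(grid$values)
  if (mx <= 0) {
    stop("cannot normalize an all-zero dose grid", call. = FALSE)
  }
  vals <- grid$values * (100 / mx)
  # guard against rounding pushing the maximum off 100
  vals[which.max(vals)] <- 100
  dose_grid(vals, grid$spacing, grid$origin, mode = "relative")
}

#' Build a lower-dose-threshold evaluation mask
#'
#' Points where the dose is strictly below `ldt_percent` of the grid maximum
#' are excluded from agreement analysis; they contribute to neither the
#' numerator nor the denominator of any agreement index. The threshold is
#' conventionally applied to the planned (reference) dose, sampled at the
#' evaluated positions (see [compare_dose()]).
#'
#' @param grid a [dose_grid()] supplying the thresholding dose.
#' @param ldt_percent lower dose threshold in percent of the grid maximum,
#'   in `[0, 100)`.
#' @return an object of class `evaluation_mask` with elements `included`
#'   (logical matrix congruent with `grid`) and `ldt_percent`.
#' @export
apply_ldt <- function(grid, ldt_percent) {
  assert_dose_grid(grid)
  if (!is.numeric(ldt_percent) || length(ldt_percent) != 1 ||
      !is.finite(ldt_percent) || ldt_percent < 0 || ldt_percent >= 100) {
    stop("ldt_percent must be a single value in [0, 100)", call. = FALSE)
  }
  included <- grid$values >= (ldt_percent / 100) * max(grid$values)
  structure(
    list(included = included, ldt_percent = ldt_percent),
    class = "evaluation_mask"
  )
}

#' @export
print.evaluation_mask <- function(x, ...) {
  cat(sprintf("<evaluation_mask> LDT %g%%: %d of %d points included\n",
              x$ldt_percent, sum(x$included), length(x$included)))
  invisible(x)
}

# nearest reference index for each evaluated coordinate along one axis;
# ties (exact midpoints) break toward the lower index
nearest_index <- function(eval_mm, ref_origin, ref_spacing, n_ref) {
  t <- (eval_mm - ref_origin) / ref_spacing
  i <- ceiling(t - 0.5) + 1L
  pmin(pmax(i, 1L), n_ref)
}

# reference dose sampled at the evaluated grid's positions (nearest point)
reference_at <- function(reference, evaluated) {
  ri <- nearest_index(axis_mm(evaluated, 1), reference$origin[1],
                      reference$spacing[1], nrow(reference$values))
  ci <- nearest_index(axis_mm(evaluated, 2), reference$origin[2],
                      reference$spacing[2], ncol(reference$values))
  reference$values[ri, ci, drop = FALSE]
}

# check that every evaluated position lies inside the reference extent
check_extent <- function(reference, evaluated, tol = 1e-6) {
  for (ax in 1:2) {
    e <- axis_mm(evaluated, ax)
    r <- axis_mm(reference, ax)
    if (min(e) < min(r) - tol || max(e) > max(r) + tol) {
      stop("evaluated grid positions fall outside the reference extent",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# comparison mask: LDT applied to the reference dose sampled at the
# evaluated positions
comparison_mask <- function(reference, evaluated, ldt_percent) {
  ref_ev <- reference_at(reference, evaluated)
  mx <- max(reference$values)
  included <- ref_ev >= (ldt_percent / 100) * mx
  structure(
    list(included = included, ldt_percent = ldt_percent),
    class = "evaluation_mask"
  )
}
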