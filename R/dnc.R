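#' Region-specific dose criteria for divide-and-conquer gamma
#'
#' The divide-and-conquer (D&C) method evaluates gamma separately in four
#' isodose regions of the planned distribution — high dose (HD, at or above
#' the 90% isodose), high gradient (HG, 50-90%), medium dose (MD, 20-50%)
#' and low dose (LD, 10-20%) — replacing the single dose-difference criterion
#' with a region-specific one. The per-region criteria are tabulated for base
#' criteria of 1, 2, 3 and 5 percent; no interpolation between rows is
#' offered. Criteria widen toward lower-dose regions so that the local dose
#' difference corresponds to approximately the same difference expressed in
#' percent of the maximum dose (see [dnc_global_equivalent()]).
#'
#' @param delta_d_gamma base dose-difference criterion in percent; one of
#'   1, 2, 3 or 5.
#' @param dta distance-to-agreement criterion in mm, shared by all regions.
#' @return an object of class `region_criteria` with elements
#'   `delta_d_gamma`, `delta_d_hd`, `delta_d_hg`, `delta_d_md`,
#'   `delta_d_ld` and `dta`.
#' @examples
#' dnc_criteria(2, dta = 2)
#' @export
dnc_criteria <- function(delta_d_gamma, dta) {
  rows <- list(
    `1` = c(hd = 1, hg = 1.5, md = 3, ld = 6),
    `2` = c(hd = 2, hg = 3, md = 5, ld = 8),
    `3` = c(hd = 3, hg = 4, md = 5, ld = 10),
    `5` = c(hd = 5, hg = 7, md = 10, ld = 15)
  )
  key <- as.character(delta_d_gamma)
  if (length(delta_d_gamma) != 1 || is.null(rows[[key]])) {
    stop("unsupported base criterion: delta_d_gamma must be 1, 2, 3 or 5 (%)",
         call. = FALSE)
  }
  if (!is.numeric(dta) || length(dta) != 1 || !is.finite(dta) || dta <= 0) {
    stop("dta must be a single positive distance in mm", call. = FALSE)
  }
  r <- rows[[key]]
  structure(
    list(delta_d_gamma = as.numeric(delta_d_gamma),
         delta_d_hd = r[["hd"]], delta_d_hg = r[["hg"]],
         delta_d_md = r[["md"]], delta_d_ld = r[["ld"]],
         dta = dta),
    class = "region_criteria"
  )
}

#' @export
print.region_criteria <- function(x, ...) {
  cat(sprintf(
    "<region_criteria> base %g%% / %g mm; HD %g%%, HG %g%%, MD %g%%, LD %g%%\n",
    x$delta_d_gamma, x$dta, x$delta_d_hd, x$delta_d_hg, x$delta_d_md,
    x$delta_d_ld))
  invisible(x)
}

#' Global-dose equivalent of a regional local criterion
#'
#' The rationale for the regional criteria: a local dose difference of
#' `local_dd` percent applied around the `isodose` percent isodose level
#' corresponds to a difference of `local_dd/100 * isodose/100` expressed as a
#' fraction of the maximum dose. For example a 7% difference centred on the
#' 70% isodose is about equal to a 5% difference of maximum dose
#' (0.7 x 0.07 = 0.049).
#'
#' @param local_dd local dose-difference criterion in percent.
#' @param isodose isodose level in percent of maximum dose.
#' @return the equivalent difference as a fraction of the maximum dose.
#' @examples
#' dnc_global_equivalent(7, 70) # 0.049
#' @export
dnc_global_equivalent <- function(local_dd, isodose) {
  (local_dd / 100) * (isodose / 100)
}

dnc_region_levels <- c("HD", "HG", "MD", "LD", "excluded")

#' Segment evaluated points into isodose regions
#'
#' Each evaluated point is labelled from the planned (reference) dose at the
#' nearest reference point, as a percentage of the reference maximum:
#' HD at or above 90%, HG in `[50, 90)`, MD in `[20, 50)`, LD in `[10, 20)`,
#' and excluded below 10%. Boundaries are lower-inclusive. Region membership
#' is frozen from the reference dose before any comparison; it never depends
#' on the measurement.
#'
#' @param reference the reference [dose_grid()].
#' @param evaluated the evaluated [dose_grid()].
#' @return an object of class `region_mask`: `labels`, a character matrix
#'   congruent with `evaluated` with entries in
#'   `c("HD", "HG", "MD", "LD", "excluded")`.
#' @export
segment_regions <- function(reference, evaluated) {
  assert_dose_grid(reference)
  assert_dose_grid(evaluated)
  check_extent(reference, evaluated)
  f <- 100 * reference_at(reference, evaluated) / max(reference$values)
  labels <- matrix("excluded", nrow(f), ncol(f))
  labels[f >= 10] <- "LD"
  labels[f >= 20] <- "MD"
  labels[f >= 50] <- "HG"
  labels[f >= 90] <- "HD"
  structure(list(labels = labels), class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  counts <- table(factor(x$labels, levels = dnc_region_levels))
  cat("<region_mask> point counts:\n")
  print(counts)
  invisible(x)
}

#' Divide-and-conquer regional gamma evaluation
#'
#' Runs gamma evaluation separately in the HD, HG, MD and LD isodose regions
#' of the planned distribution, using the shared DTA and the region's dose
#' criterion, then pools the results. By default percent dose differences are
#' normalized locally, matching the construction of the regional criteria
#' (each region's local criterion corresponds to approximately the same
#' global criterion); global normalization is available for sensitivity
#' analysis. The overall agreement index is the count-weighted pooled pass
#' fraction over the four regions, identical to a plain pass rate over the
#' union of regional points.
#'
#' An empty region is reported with count 0 and `NA` agreement, not an error.
#'
#' @param reference the reference [dose_grid()].
#' @param evaluated the evaluated [dose_grid()].
#' @param criteria a `region_criteria` from [dnc_criteria()] (or constructed
#'   directly for sensitivity studies).
#' @param normalization `"local"` (default) or `"global"`.
#' @param search passed to the gamma engine; see [gamma_map()].
#' @return an object of classes `dnc_result` and `dose_comparison`:
#'   `index_map` (per-point gamma under the point's regional criterion),
#'   `per_region` (data frame with region, dose criterion, point count, pass
#'   count and agreement index), `agreement_index` (overall pooled %GP),
#'   `mask` (the union of the four regions) and `criteria`.
#' @export
dnc_evaluate <- function(reference, evaluated, criteria,
                         normalization = c("local", "global"),
                         search = c("optimized", "exhaustive")) {
  normalization <- match.arg(normalization)
  search <- match.arg(search)
  assert_dose_grid(reference)
  assert_dose_grid(evaluated)
  if (!inherits(criteria, "region_criteria")) {
    stop("criteria must come from dnc_criteria()", call. = FALSE)
  }
  with(criteria, {
    if (!(delta_d_hd <= delta_d_hg && delta_d_hg <= delta_d_md &&
          delta_d_md <= delta_d_ld)) {
      stop("region criteria must widen from HD to LD", call. = FALSE)
    }
  })
  regions <- segment_regions(reference, evaluated)
  dd_by_region <- c(HD = criteria$delta_d_hd, HG = criteria$delta_d_hg,
                    MD = criteria$delta_d_md, LD = criteria$delta_d_ld)
  index_map <- matrix(NA_real_, nrow(evaluated$values),
                      ncol(evaluated$values))
  per <- data.frame(
    region = names(dd_by_region),
    delta_d = unname(dd_by_region),
    n = 0L, n_pass = 0L, agreement_index = NA_real_,
    stringsAsFactors = FALSE
  )
  for (r in seq_len(nrow(per))) {
    reg <- per$region[r]
    inc <- regions$labels == reg
    n <- sum(inc)
    per$n[r] <- n
    if (n == 0) next
    g <- gamma_values(reference, evaluated, dd_by_region[[reg]],
                      criteria$dta, normalization, inc, search)
    index_map[inc] <- g[inc]
    per$n_pass[r] <- sum(g[inc] <= 1)
    per$agreement_index[r] <- 100 * per$n_pass[r] / n
  }
  mask <- structure(
    list(included = regions$labels != "excluded", ldt_percent = 10),
    class = "evaluation_mask"
  )
  res <- new_dose_comparison(index_map, mask, "dnc", criteria,
                             subclass = "dnc_result")
  res$per_region <- per
  res$normalization <- normalization
  res
}

#' @export
print.dnc_result <- function(x, ...) {
  cat(sprintf("<dnc_result> base %g%% / %g mm, %s normalization\n",
              x$criteria$delta_d_gamma, x$criteria$dta, x$normalization))
  print(x$per_region, row.names = FALSE)
  cat(sprintf("  overall: %d points, agreement index %.2f%%\n",
              x$n_included, x$agreement_index))
  invisible(x)
}
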