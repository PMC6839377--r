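#' Agreement indices for every plan and analysis combination
#'
#' Runs every requested technique x criteria x lower-dose-threshold
#' combination over a cohort and tabulates the agreement indices, one row
#' per plan and one column per combination. Divide-and-conquer runs once per
#' criteria pair (its domain is fixed at the 10% isodose by the region
#' definitions) and only for tabulated base criteria; combinations it cannot
#' support are dropped. A plan whose files cannot be read is recorded as a
#' failure, its cells are set to `NA`, and the run continues.
#'
#' @param manifest a `cohort_manifest`.
#' @param techniques character vector drawn from `"gamma_global"`,
#'   `"gamma_local"`, `"madd_box"`, `"madd_gamma"`, `"dnc"`.
#' @param criteria_list list of `c(dd, dta)` pairs in percent and mm;
#'   default the six-pair sweep 1/1, 2/2, 2/3, 3/2, 3/3, 5/3.
#' @param ldt_list lower dose thresholds in percent; default `c(5, 10)`.
#' @param dir directory holding the cohort files when the manifest has no
#'   in-memory pairs.
#' @return an object of class `agreement_table`: `indices` (plans x
#'   combinations matrix of agreement indices in percent), `combos` (column
#'   metadata: technique, dd, dta, ldt), `plan_id`, `outcome`, `failures`.
#' @export
batch_indices <- function(manifest,
                          techniques = c("gamma_global", "gamma_local",
                                         "madd_box", "madd_gamma", "dnc"),
                          criteria_list = list(c(1, 1), c(2, 2), c(2, 3),
                                               c(3, 2), c(3, 3), c(5, 3)),
                          ldt_list = c(5, 10),
                          dir = NULL) {
  if (!inherits(manifest, "cohort_manifest")) {
    stop("manifest must be a cohort_manifest", call. = FALSE)
  }
  if (length(techniques) < 1 || length(criteria_list) < 1 ||
      length(ldt_list) < 1) {
    stop("at least one technique, criteria pair and LDT are required",
         call. = FALSE)
  }
  combos <- do.call(rbind, lapply(techniques, function(tech) {
    do.call(rbind, lapply(criteria_list, function(cr) {
      if (tech == "dnc") {
        if (!cr[1] %in% c(1, 2, 3, 5)) return(NULL)
        data.frame(technique = tech, dd = cr[1], dta = cr[2], ldt = 10)
      } else {
        data.frame(technique = tech, dd = cr[1], dta = cr[2], ldt = ldt_list)
      }
    }))
  }))
  combos <- unique(combos)
  rownames(combos) <- NULL
  colname <- function(r) {
    sprintf("%s|%g%%/%gmm|LDT%g", r$technique, r$dd, r$dta, r$ldt)
  }
  n <- nrow(manifest)
  indices <- matrix(NA_real_, n, nrow(combos),
                    dimnames = list(manifest$plan_id,
                                    vapply(seq_len(nrow(combos)),
                                           function(i) colname(combos[i, ]),
                                           character(1))))
  failures <- character(0)
  for (i in seq_len(n)) {
    pair <- tryCatch(cohort_pair(manifest, i, dir), error = function(e) e)
    if (inherits(pair, "error")) {
      failures <- c(failures, sprintf("%s: %s", manifest$plan_id[i],
                                      conditionMessage(pair)))
      next
    }
    for (j in seq_len(nrow(combos))) {
      cb <- combos[j, ]
      res <- tryCatch(
        compare_dose(pair$reference, pair$evaluated, cb$technique,
                     dd = cb$dd, dta = cb$dta, ldt = cb$ldt),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failures <- c(failures, sprintf("%s / %s: %s", manifest$plan_id[i],
                                        colname(cb), conditionMessage(res)))
      } else {
        indices[i, j] <- res$agreement_index
      }
    }
  }
  if (length(failures) > 0) {
    warning(sprintf("%d comparison(s) failed; see $failures",
                    length(failures)), call. = FALSE)
  }
  structure(
    list(indices = indices, combos = combos, plan_id = manifest$plan_id,
         outcome = manifest$outcome, failures = failures),
    class = "agreement_table"
  )
}

#' @export
print.agreement_table <- function(x, ...) {
  cat(sprintf("<agreement_table> %d plans x %d combinations\n",
              nrow(x$indices), ncol(x$indices)))
  if (length(x$failures) > 0) {
    cat(sprintf("  %d recorded failure(s)\n", length(x$failures)))
  }
  invisible(x)
}

#' Mean and SD of agreement indices per combination
#'
#' @param object an `agreement_table`.
#' @param ... unused.
#' @return a data frame with one row per combination: technique, dd, dta,
#'   ldt, n (non-missing plans), mean and sd of the agreement index.
#' @export
summary.agreement_table <- function(object, ...) {
  out <- object$combos
  out$n <- colSums(!is.na(object$indices))
  out$mean <- colMeans(object$indices, na.rm = TRUE)
  out$sd <- apply(object$indices, 2, stats::sd, na.rm = TRUE)
  rownames(out) <- colnames(object$indices)
  out
}

#' Simple linear regression with coefficient of determination
#'
#' Ordinary least squares of `y` on `x` with the coefficient of
#' determination \eqn{R^2 = 1 - SS_{res}/SS_{tot}} and the two-sided p-value
#' of the slope's t test. A constant `y` is reported as \eqn{R^2 = 0} and
#' flagged; a constant `x` leaves the regression undefined and raises an
#' error.
#'
#' @param x,y numeric vectors of equal length, at least 3 points.
#' @return a list: `r_squared`, `p_value`, `slope`, `intercept`, `n`,
#'   `constant_y`.
#' @export
ols_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    stop("regression needs at least 3 complete observations", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("regression undefined: x is constant", call. = FALSE)
  }
  if (stats::var(y) == 0) {
    return(list(r_squared = 0, p_value = NA_real_, slope = 0,
                intercept = y[1], n = length(x), constant_y = TRUE))
  }
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact fits; R2 = 1 is a legitimate outcome here
  s <- suppressWarnings(summary(fit))
  list(
    r_squared = s$r.squared,
    p_value = s$coefficients["x", "Pr(>|t|)"],
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n = length(x),
    constant_y = FALSE
  )
}

#' Sidak-corrected significance level
#'
#' For a family of `m` comparisons at family-wise level `alpha`, the
#' per-comparison level is \eqn{1 - (1 - \alpha)^{1/m}}: strictly between
#' the Bonferroni level `alpha/m` and `alpha` for `m >= 2`.
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return the corrected per-comparison level.
#' @examples
#' sidak_correct(0.05, 10)
#' @export
sidak_correct <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(m) || m < 1) stop("m must be at least 1", call. = FALSE)
  1 - (1 - alpha)^(1 / m)
}

#' Pairwise correlation report over agreement-table columns
#'
#' Regresses every requested pair of columns against each other
#' ([ols_r2()]), treating all pairs in the report as one family for the
#' Sidak correction, and flags pairs whose coefficient of determination
#' reaches the correlation threshold. The default threshold 0.64 is the
#' square of a Pearson correlation of 0.8, the conventional minimum for
#' clinically acceptable agreement. \eqn{R^2} is symmetric in the pair
#' order; slope and intercept are reported for the regression of the second
#' column on the first. Plans missing either index are dropped pairwise.
#'
#' @param table an `agreement_table`.
#' @param columns character vector of column names to cross; default all.
#' @param pairs optional two-column character matrix of explicit pairs;
#'   default all unordered pairs of `columns`.
#' @param alpha family-wise significance level.
#' @param r2_threshold coefficient-of-determination cutoff for declaring
#'   two columns correlated.
#' @return an object of class `correlation_report`: a data frame with one
#'   row per pair (`col_x`, `col_y`, `n`, `r_squared`, `p_value`,
#'   `significant_after_sidak`, `correlated`) with the family size `m`,
#'   `alpha`, the corrected level and the threshold as attributes.
#' @export
correlation_matrix <- function(table, columns = NULL, pairs = NULL,
                               alpha = 0.05, r2_threshold = 0.64) {
  if (!inherits(table, "agreement_table")) {
    stop("table must be an agreement_table", call. = FALSE)
  }
  if (is.null(columns)) columns <- colnames(table$indices)
  missing_cols <- setdiff(columns, colnames(table$indices))
  if (length(missing_cols) > 0) {
    stop(sprintf("unknown column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (is.null(pairs)) {
    if (length(columns) < 2) {
      stop("need at least two columns to correlate", call. = FALSE)
    }
    cmb <- utils::combn(columns, 2)
    pairs <- cbind(cmb[1, ], cmb[2, ])
  }
  m <- nrow(pairs)
  alpha_c <- sidak_correct(alpha, m)
  rows <- vector("list", m)
  for (k in seq_len(m)) {
    xv <- table$indices[, pairs[k, 1]]
    yv <- table$indices[, pairs[k, 2]]
    fit <- tryCatch(ols_r2(xv, yv), error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[k]] <- data.frame(
        col_x = pairs[k, 1], col_y = pairs[k, 2],
        n = sum(is.finite(xv) & is.finite(yv)),
        r_squared = NA_real_, p_value = NA_real_,
        significant_after_sidak = NA, correlated = NA,
        note = conditionMessage(fit), stringsAsFactors = FALSE
      )
    } else {
      rows[[k]] <- data.frame(
        col_x = pairs[k, 1], col_y = pairs[k, 2], n = fit$n,
        r_squared = fit$r_squared, p_value = fit$p_value,
        significant_after_sidak = isTRUE(fit$p_value <= alpha_c),
        correlated = fit$r_squared >= r2_threshold,
        note = if (fit$constant_y) "constant y" else "",
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  attr(out, "alpha_corrected") <- alpha_c
  attr(out, "r2_threshold") <- r2_threshold
  class(out) <- c("correlation_report", "data.frame")
  out
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf(
    "<correlation_report> %d pair(s); alpha %g (Sidak-corrected %.5g), R2 threshold %g\n",
    attr(x, "m"), attr(x, "alpha"), attr(x, "alpha_corrected"),
    attr(x, "r2_threshold")))
  df <- as.data.frame(x)
  df$r_squared <- round(df$r_squared, 4)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Square R-squared matrix from a correlation report
#'
#' Arranges the pairwise coefficients of determination as a symmetric
#' matrix over the columns appearing in the report (diagonal 1), the layout
#' used for cross-technique comparison tables.
#'
#' @param report a `correlation_report`.
#' @return a numeric matrix.
#' @export
r2_matrix <- function(report) {
  cols <- unique(c(report$col_x, report$col_y))
  m <- matrix(NA_real_, length(cols), length(cols),
              dimnames = list(cols, cols))
  diag(m) <- 1
  for (k in seq_len(nrow(report))) {
    m[report$col_x[k], report$col_y[k]] <- report$r_squared[k]
    m[report$col_y[k], report$col_x[k]] <- report$r_squared[k]
  }
  m
}

#' Scatter plot of one correlated pair
#'
#' @param x a `correlation_report`.
#' @param table the `agreement_table` the report was computed from.
#' @param pair row index of the pair to plot.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.correlation_report <- function(x, table, pair = 1, ...) {
  row <- x[pair, ]
  xv <- table$indices[, row$col_x]
  yv <- table$indices[, row$col_y]
  graphics::plot(xv, yv, xlab = row$col_x, ylab = row$col_y,
                 main = sprintf("R2 = %.3f", row$r_squared), ...)
  if (is.finite(row$r_squared) && stats::var(xv, na.rm = TRUE) > 0) {
    graphics::abline(stats::lm(yv ~ xv), lty = 2)
  }
  invisible(x)
}
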