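#' Specification of a synthetic treatment plan
#'
#' Synthetic planned dose distributions are analytic: a rectangular plateau
#' with error-function penumbra, a sum of Gaussian modulation lobes inside
#' the aperture, and a broad low-amplitude scatter component that produces
#' the extensive low-dose regions seen around clinical fields. Because the
#' form is analytic, rigid shifts are exact resamplings rather than grid
#' interpolations, which keeps distance-to-agreement tests free of
#' resampling artifacts.
#'
#' @param extent_mm grid extent `c(height, width)` in mm; the planned grid is
#'   sampled at 1 mm.
#' @param n_lobes number of Gaussian dose lobes (>= 1).
#' @param lobe_amplitude range of lobe amplitudes, relative to the plateau
#'   dose.
#' @param lobe_sd_mm range of lobe widths (Gaussian SD, mm).
#' @param lobe_center_frac lobe centres are drawn uniformly within this
#'   fraction of the aperture half-extent around the field centre; 0 pins
#'   all lobes to the centre.
#' @param aperture_half_mm half-size `c(y, x)` of the open field, mm.
#' @param penumbra_mm edge falloff scale (mm) of the error-function penumbra.
#' @param scatter_amplitude amplitude of the broad scatter component,
#'   relative to the plateau dose.
#' @param scatter_sd_mm width (Gaussian SD, mm) of the scatter component.
#' @param base_dose_gy plateau dose in Gy.
#' @param mode `"absolute"` (VMAT-like, doses in Gy) or `"relative"`
#'   (HT-like; both grids of a pair are normalized at dose maximum after
#'   error injection).
#' @return an object of class `plan_spec`.
#' @export
plan_spec <- function(extent_mm = c(120, 120),
                      n_lobes = 3,
                      lobe_amplitude = c(0.25, 0.6),
                      lobe_sd_mm = c(8, 18),
                      lobe_center_frac = 0.6,
                      aperture_half_mm = c(35, 35),
                      penumbra_mm = 6,
                      scatter_amplitude = 0.12,
                      scatter_sd_mm = 70,
                      base_dose_gy = 2,
                      mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  extent_mm <- rep_len(as.numeric(extent_mm), 2)
  aperture_half_mm <- rep_len(as.numeric(aperture_half_mm), 2)
  lobe_amplitude <- rep_len(as.numeric(lobe_amplitude), 2)
  lobe_sd_mm <- rep_len(as.numeric(lobe_sd_mm), 2)
  if (any(extent_mm <= 0)) stop("extent must be positive", call. = FALSE)
  if (n_lobes < 1) stop("n_lobes must be at least 1", call. = FALSE)
  if (penumbra_mm <= 0) stop("penumbra_mm must be positive", call. = FALSE)
  structure(
    list(extent_mm = extent_mm, n_lobes = as.integer(n_lobes),
         lobe_amplitude = lobe_amplitude, lobe_sd_mm = lobe_sd_mm,
         lobe_center_frac = lobe_center_frac,
         aperture_half_mm = aperture_half_mm, penumbra_mm = penumbra_mm,
         scatter_amplitude = scatter_amplitude,
         scatter_sd_mm = scatter_sd_mm,
         base_dose_gy = base_dose_gy, mode = mode),
    class = "plan_spec"
  )
}

# smooth 0..1 step with scale p
soft_edge <- function(t) 0.5 * (1 + pracma::erf(t))

# evaluate the analytic field at physical coordinates y (rows) and x (cols)
eval_field <- function(params, y, x) {
  p <- params$penumbra_mm
  cy <- params$center[1]; cx <- params$center[2]
  ay <- params$aperture_half[1]; ax <- params$aperture_half[2]
  py <- soft_edge((y - (cy - ay)) / p) * soft_edge(((cy + ay) - y) / p)
  px <- soft_edge((x - (cx - ax)) / p) * soft_edge(((cx + ax) - x) / p)
  D <- outer(py, px)
  lb <- params$lobes
  for (k in seq_len(nrow(lb))) {
    D <- D + lb$amplitude[k] *
      outer(exp(-(y - lb$y[k])^2 / (2 * lb$sd[k]^2)),
            exp(-(x - lb$x[k])^2 / (2 * lb$sd[k]^2)))
  }
  if (params$scatter_amplitude > 0) {
    D <- D + params$scatter_amplitude *
      outer(exp(-(y - cy)^2 / (2 * params$scatter_sd^2)),
            exp(-(x - cx)^2 / (2 * params$scatter_sd^2)))
  }
  params$base_dose * D
}

check_bands <- function(values) {
  f <- 100 * values / max(values)
  bands <- list(LD = c(10, 20), MD = c(20, 50), HG = c(50, 90),
                HD = c(90, 100.1))
  empty <- names(bands)[!vapply(bands, function(b) {
    any(f >= b[1] & f < b[2])
  }, logical(1))]
  if (length(empty) > 0) {
    stop(sprintf(
      "generated plan does not populate isodose band(s): %s; adjust the plan specification",
      paste(empty, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate a synthetic planned dose distribution
#'
#' Draws lobe centres, amplitudes and widths from the ranges in `spec` under
#' the given seed and evaluates the analytic field on a 1 mm grid. The
#' result is deterministic given `(spec, seed)`, smooth, and populates all
#' four isodose bands used by divide-and-conquer analysis (10-20, 20-50,
#' 50-90 and 90-100 percent of maximum); a specification that leaves a band
#' empty raises an error.
#'
#' The analytic field parameters are attached as attribute `"field_params"`,
#' which [inject_errors()] uses to apply rigid shifts by exact resampling.
#'
#' @param spec a [plan_spec()].
#' @param seed integer seed.
#' @return an absolute-mode [dose_grid()] at 1 mm spacing.
#' @export
generate_plan <- function(spec, seed) {
  if (!inherits(spec, "plan_spec")) {
    stop("spec must be a plan_spec", call. = FALSE)
  }
  set.seed(seed)
  center <- spec$extent_mm / 2
  m <- spec$lobe_center_frac
  n <- spec$n_lobes
  lobes <- data.frame(
    y = center[1] + stats::runif(n, -m, m) * spec$aperture_half_mm[1],
    x = center[2] + stats::runif(n, -m, m) * spec$aperture_half_mm[2],
    amplitude = stats::runif(n, spec$lobe_amplitude[1],
                             spec$lobe_amplitude[2]),
    sd = stats::runif(n, spec$lobe_sd_mm[1], spec$lobe_sd_mm[2])
  )
  params <- list(center = center, aperture_half = spec$aperture_half_mm,
                 penumbra_mm = spec$penumbra_mm, lobes = lobes,
                 scatter_amplitude = spec$scatter_amplitude,
                 scatter_sd = spec$scatter_sd_mm,
                 base_dose = spec$base_dose_gy)
  y <- seq(0, spec$extent_mm[1], by = 1)
  x <- seq(0, spec$extent_mm[2], by = 1)
  vals <- eval_field(params, y, x)
  check_bands(vals)
  g <- dose_grid(vals, spacing = 1, origin = c(0, 0), mode = "absolute")
  attr(g, "field_params") <- params
  g
}

#' Delivery-error model
#'
#' Describes the discrepancy injected between a planned distribution and its
#' synthetic "delivered" counterpart: a multiplicative dose scaling, a rigid
#' spatial shift, localized Gaussian perturbations ("blobs"), and additive
#' zero-mean Gaussian detector noise. The identity model (all defaults)
#' leaves the plan unchanged.
#'
#' @param scale_factor multiplicative dose error; 1 means none. Must be > 0.
#' @param shift_mm rigid displacement `c(dy, dx)` in mm, applied by
#'   resampling the analytic plan.
#' @param blobs `NULL` or a data frame with columns `y_mm`, `x_mm`, `sd_mm`,
#'   `amplitude_percent` (amplitude in percent of the plan maximum; may be
#'   negative).
#' @param noise_sd_percent SD of additive Gaussian noise, percent of the
#'   plan maximum; >= 0.
#' @return an object of class `error_model`.
#' @export
error_model <- function(scale_factor = 1, shift_mm = c(0, 0), blobs = NULL,
                        noise_sd_percent = 0) {
  if (!is.numeric(scale_factor) || scale_factor <= 0) {
    stop("scale_factor must be positive", call. = FALSE)
  }
  if (noise_sd_percent < 0) {
    stop("noise_sd_percent must be non-negative", call. = FALSE)
  }
  shift_mm <- rep_len(as.numeric(shift_mm), 2)
  if (!is.null(blobs)) {
    need <- c("y_mm", "x_mm", "sd_mm", "amplitude_percent")
    if (!is.data.frame(blobs) || !all(need %in% names(blobs))) {
      stop("blobs must be a data frame with columns y_mm, x_mm, sd_mm, amplitude_percent",
           call. = FALSE)
    }
  }
  structure(
    list(scale_factor = scale_factor, shift_mm = shift_mm, blobs = blobs,
         noise_sd_percent = noise_sd_percent),
    class = "error_model"
  )
}

is_identity_model <- function(m) {
  m$scale_factor == 1 && all(m$shift_mm == 0) &&
    (is.null(m$blobs) || nrow(m$blobs) == 0) && m$noise_sd_percent == 0
}

#' Inject delivery errors into a planned distribution
#'
#' Applies, in order: the rigid shift (by resampling the analytic field — the
#' plan must carry `"field_params"` from [generate_plan()] if the shift is
#' nonzero), the multiplicative scaling, the localized blob perturbations,
#' and the additive detector noise (the only stochastic step; deterministic
#' given `seed`). Doses are clamped at zero. Blob amplitudes and the noise SD
#' are percentages of the input plan's maximum.
#'
#' @param plan a [dose_grid()].
#' @param model an [error_model()].
#' @param seed integer seed for the noise draw.
#' @return a [dose_grid()] congruent with `plan`.
#' @export
inject_errors <- function(plan, model, seed = 1) {
  assert_dose_grid(plan)
  if (!inherits(model, "error_model")) {
    stop("model must be an error_model", call. = FALSE)
  }
  mx <- max(plan$values)
  vals <- plan$values
  if (any(model$shift_mm != 0)) {
    params <- attr(plan, "field_params")
    if (is.null(params)) {
      stop("rigid shifts require an analytic plan from generate_plan()",
           call. = FALSE)
    }
    ext_y <- range(axis_mm(plan, 1)); ext_x <- range(axis_mm(plan, 2))
    lo_y <- params$center[1] - params$aperture_half[1] + model$shift_mm[1]
    hi_y <- params$center[1] + params$aperture_half[1] + model$shift_mm[1]
    lo_x <- params$center[2] - params$aperture_half[2] + model$shift_mm[2]
    hi_x <- params$center[2] + params$aperture_half[2] + model$shift_mm[2]
    if (lo_y < ext_y[1] || hi_y > ext_y[2] || lo_x < ext_x[1] ||
        hi_x > ext_x[2]) {
      stop("shift moves the field aperture outside the grid extent",
           call. = FALSE)
    }
    # shifting the field by +s means the dose at y comes from y - s
    vals <- eval_field(params, axis_mm(plan, 1) - model$shift_mm[1],
                       axis_mm(plan, 2) - model$shift_mm[2])
  }
  if (model$scale_factor != 1) vals <- vals * model$scale_factor
  if (!is.null(model$blobs) && nrow(model$blobs) > 0) {
    y <- axis_mm(plan, 1); x <- axis_mm(plan, 2)
    for (k in seq_len(nrow(model$blobs))) {
      b <- model$blobs[k, ]
      vals <- vals + (b$amplitude_percent / 100) * mx *
        outer(exp(-(y - b$y_mm)^2 / (2 * b$sd_mm^2)),
              exp(-(x - b$x_mm)^2 / (2 * b$sd_mm^2)))
    }
  }
  if (model$noise_sd_percent > 0) {
    set.seed(seed)
    vals <- vals + stats::rnorm(length(vals),
                                sd = model$noise_sd_percent / 100 * mx)
  }
  vals <- pmax(vals, 0)
  dose_grid(vals, plan$spacing, plan$origin, mode = plan$mode)
}

#' Down-sample a fine grid to detector resolution
#'
#' Emulates a diode-array measurement by point sampling (no volume
#' averaging): every `ratio`-th grid point is kept, starting at the grid
#' origin, so sampled values exactly equal the source values at the sampled
#' positions and the detector lattice is aligned to the source lattice. The
#' target spacing must be an integer multiple of the source spacing.
#'
#' @param grid a [dose_grid()].
#' @param spacing_mm target detector spacing in mm (default 10, a 1 cm
#'   diode array).
#' @return a [dose_grid()] at the detector spacing.
#' @export
sample_detector <- function(grid, spacing_mm = 10) {
  assert_dose_grid(grid)
  ratio <- spacing_mm / grid$spacing
  if (any(abs(ratio - round(ratio)) > 1e-9) || any(round(ratio) < 1)) {
    stop("detector spacing must be an integer multiple of the grid spacing",
         call. = FALSE)
  }
  ratio <- round(ratio)
  rows <- seq(1, nrow(grid$values), by = ratio[1])
  cols <- seq(1, ncol(grid$values), by = ratio[2])
  dose_grid(grid$values[rows, cols, drop = FALSE],
            spacing = grid$spacing * ratio, origin = grid$origin,
            mode = grid$mode)
}

# Draw the default delivery-error model for an "errored" plan: localized
# perturbations centred in the flat low-dose scatter shelf (5-7.5% of the
# plan maximum), amplitudes 5-9% of maximum with random sign. Discrepancies
# there cannot be rescued by the distance-to-agreement search (the shelf is
# nearly gradient-free) and sit mostly below the 10% isodose, so raising the
# lower dose threshold removes the worst-disagreeing points.
draw_error_model <- function(plan, seed, noise_sd_percent = 0) {
  set.seed(seed)
  f <- 100 * plan$values / max(plan$values)
  cand <- which(f >= 5 & f < 7.5)
  if (length(cand) == 0) {
    stop("plan has no low-dose shelf (5-7.5% of maximum) to perturb",
         call. = FALSE)
  }
  n_blobs <- sample(3:5, 1)
  cells <- cand[sample.int(length(cand), min(n_blobs, length(cand)))]
  ij <- arrayInd(cells, dim(plan$values))
  y <- axis_mm(plan, 1); x <- axis_mm(plan, 2)
  blobs <- data.frame(
    y_mm = y[ij[, 1]],
    x_mm = x[ij[, 2]],
    sd_mm = stats::runif(nrow(ij), 8, 14),
    amplitude_percent = sample(c(-1, 1), nrow(ij), replace = TRUE) *
      stats::runif(nrow(ij), 5, 9)
  )
  error_model(blobs = blobs, noise_sd_percent = noise_sd_percent)
}

build_plan_pair <- function(plan_seed, errored, spec, noise_sd_percent,
                            detector_spacing_mm) {
  reference <- generate_plan(spec, seed = plan_seed)
  model <- if (errored) {
    draw_error_model(reference, seed = plan_seed + 1L,
                     noise_sd_percent = noise_sd_percent)
  } else {
    error_model(noise_sd_percent = noise_sd_percent)
  }
  delivered <- inject_errors(reference, model, seed = plan_seed + 2L)
  evaluated <- sample_detector(delivered, detector_spacing_mm)
  if (spec$mode == "relative") {
    reference <- normalize_to_max(reference)
    evaluated <- normalize_to_max(evaluated)
  }
  list(reference = reference, evaluated = evaluated, model = model)
}

#' Generate a synthetic planned/measured cohort
#'
#' Builds `n` plan pairs — a 1 mm planned grid and a detector-sampled
#' "measured" grid — of which `round(n * errored_fraction)` carry
#' non-identity delivery-error models (the rest differ from the plan only by
#' detector noise). Everything is a pure function of `(n, errored_fraction,
#' seed)` and the plan specification; regenerating from the manifest
#' reproduces the grids bit-identically.
#'
#' @param n number of plans (>= 2).
#' @param errored_fraction proportion of plans carrying delivery errors, in
#'   `[0, 1]`; default 0.12, a realistic clinical failure fraction.
#' @param seed integer cohort seed.
#' @param dir output directory; if non-`NULL`, planned and measured grids
#'   are written there as textgrid files along with `manifest.tsv`. With
#'   `dir = NULL` the pairs are kept in memory only.
#' @param spec a [plan_spec()] shared by all plans.
#' @param noise_sd_percent detector noise SD applied to every plan, percent
#'   of plan maximum; default 0.1.
#' @param detector_spacing_mm detector sampling pitch; default 10.
#' @return an object of class `cohort_manifest`: a data frame with columns
#'   `plan_id`, `seed`, `outcome` (`"clean"`/`"errored"`), `ref_file`,
#'   `eval_file`, with the generation parameters as attributes and the
#'   in-memory pairs as attribute `"pairs"`.
#' @export
generate_cohort <- function(n = 100, errored_fraction = 0.12, seed = 1,
                            dir = NULL, spec = plan_spec(),
                            noise_sd_percent = 0.1,
                            detector_spacing_mm = 10) {
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  if (errored_fraction < 0 || errored_fraction > 1) {
    stop("errored_fraction must be in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  plan_seeds <- sample.int(2147000000L, n)
  k <- round(n * errored_fraction)
  errored <- rep(FALSE, n)
  if (k > 0) errored[sample.int(n, k)] <- TRUE
  manifest <- data.frame(
    plan_id = sprintf("plan%03d", seq_len(n)),
    seed = plan_seeds,
    outcome = ifelse(errored, "errored", "clean"),
    ref_file = sprintf("plan%03d_ref.txt", seq_len(n)),
    eval_file = sprintf("plan%03d_eval.txt", seq_len(n)),
    stringsAsFactors = FALSE
  )
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    pairs[[i]] <- build_plan_pair(plan_seeds[i], errored[i], spec,
                                  noise_sd_percent, detector_spacing_mm)
  }
  names(pairs) <- manifest$plan_id
  attr(manifest, "pairs") <- pairs
  attr(manifest, "params") <- list(
    n = n, errored_fraction = errored_fraction, cohort_seed = seed,
    noise_sd_percent = noise_sd_percent,
    detector_spacing_mm = detector_spacing_mm, spec = spec
  )
  class(manifest) <- c("cohort_manifest", "data.frame")
  if (!is.null(dir)) {
    write_cohort_files(manifest, dir)
    attr(manifest, "dir") <- dir
  }
  manifest
}

write_cohort_files <- function(manifest, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) {
      stop(sprintf("cannot create output directory '%s'", dir),
           call. = FALSE)
    }
  }
  pairs <- attr(manifest, "pairs")
  for (i in seq_len(nrow(manifest))) {
    write_dose_grid(pairs[[i]]$reference,
                    file.path(dir, manifest$ref_file[i]))
    write_dose_grid(pairs[[i]]$evaluated,
                    file.path(dir, manifest$eval_file[i]))
  }
  write_manifest(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

#' Write a cohort manifest
#'
#' One row per plan (tab-separated), preceded by `#key value` header lines
#' recording the generation parameters so that [regenerate_cohort()] can
#' rebuild the grids bit-identically.
#'
#' @param manifest a `cohort_manifest`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  p <- attr(manifest, "params")
  s <- p$spec
  hdr <- c(
    sprintf("# n %d", p$n),
    sprintf("# errored_fraction %.17g", p$errored_fraction),
    sprintf("# cohort_seed %d", p$cohort_seed),
    sprintf("# noise_sd_percent %.17g", p$noise_sd_percent),
    sprintf("# detector_spacing_mm %.17g", p$detector_spacing_mm),
    sprintf("# spec_extent_mm %.17g %.17g", s$extent_mm[1], s$extent_mm[2]),
    sprintf("# spec_n_lobes %d", s$n_lobes),
    sprintf("# spec_lobe_amplitude %.17g %.17g", s$lobe_amplitude[1],
            s$lobe_amplitude[2]),
    sprintf("# spec_lobe_sd_mm %.17g %.17g", s$lobe_sd_mm[1],
            s$lobe_sd_mm[2]),
    sprintf("# spec_lobe_center_frac %.17g", s$lobe_center_frac),
    sprintf("# spec_aperture_half_mm %.17g %.17g", s$aperture_half_mm[1],
            s$aperture_half_mm[2]),
    sprintf("# spec_penumbra_mm %.17g", s$penumbra_mm),
    sprintf("# spec_scatter_amplitude %.17g", s$scatter_amplitude),
    sprintf("# spec_scatter_sd_mm %.17g", s$scatter_sd_mm),
    sprintf("# spec_base_dose_gy %.17g", s$base_dose_gy),
    sprintf("# spec_mode %s", s$mode)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("plan_id", "seed", "outcome", "ref_file", "eval_file"),
                   collapse = "\t"), con)
  for (i in seq_len(nrow(manifest))) {
    writeLines(paste(c(manifest$plan_id[i],
                       format(manifest$seed[i]),
                       manifest$outcome[i],
                       manifest$ref_file[i],
                       manifest$eval_file[i]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a cohort manifest
#'
#' @param path path to a manifest written by [write_manifest()].
#' @return a `cohort_manifest` (without in-memory pairs; see
#'   [regenerate_cohort()]).
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    parts <- strsplit(trimws(sub("^#", "", h)), "[[:space:]]+")[[1]]
    kv[[parts[1]]] <- parts[-1]
  }
  num <- function(key) as.numeric(kv[[key]])
  spec <- plan_spec(
    extent_mm = num("spec_extent_mm"),
    n_lobes = as.integer(num("spec_n_lobes")),
    lobe_amplitude = num("spec_lobe_amplitude"),
    lobe_sd_mm = num("spec_lobe_sd_mm"),
    lobe_center_frac = num("spec_lobe_center_frac"),
    aperture_half_mm = num("spec_aperture_half_mm"),
    penumbra_mm = num("spec_penumbra_mm"),
    scatter_amplitude = num("spec_scatter_amplitude"),
    scatter_sd_mm = num("spec_scatter_sd_mm"),
    base_dose_gy = num("spec_base_dose_gy"),
    mode = kv[["spec_mode"]]
  )
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  attr(df, "params") <- list(
    n = as.integer(num("n")),
    errored_fraction = num("errored_fraction"),
    cohort_seed = as.integer(num("cohort_seed")),
    noise_sd_percent = num("noise_sd_percent"),
    detector_spacing_mm = num("detector_spacing_mm"),
    spec = spec
  )
  attr(df, "dir") <- dirname(path)
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Regenerate cohort grids from a manifest
#'
#' Rebuilds every plan pair from the per-plan seeds and outcome labels
#' recorded in the manifest. Because every generation step is a pure
#' function of its seed, the rebuilt files are bit-identical to the
#' originals.
#'
#' @param manifest a `cohort_manifest` (from [generate_cohort()] or
#'   [read_manifest()]).
#' @param dir if non-`NULL`, write the rebuilt grids there.
#' @return the manifest with in-memory pairs attached.
#' @export
regenerate_cohort <- function(manifest, dir = NULL) {
  if (!inherits(manifest, "cohort_manifest")) {
    stop("manifest must be a cohort_manifest", call. = FALSE)
  }
  p <- attr(manifest, "params")
  pairs <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    pairs[[i]] <- build_plan_pair(manifest$seed[i],
                                  manifest$outcome[i] == "errored",
                                  p$spec, p$noise_sd_percent,
                                  p$detector_spacing_mm)
  }
  names(pairs) <- manifest$plan_id
  attr(manifest, "pairs") <- pairs
  if (!is.null(dir)) {
    write_cohort_files(manifest, dir)
    attr(manifest, "dir") <- dir
  }
  manifest
}

# fetch the i-th pair of a manifest, from memory if present, else from disk
cohort_pair <- function(manifest, i, dir = NULL) {
  pairs <- attr(manifest, "pairs")
  if (!is.null(pairs)) return(pairs[[i]])
  dir <- dir %||% attr(manifest, "dir")
  if (is.null(dir)) {
    stop("manifest has neither in-memory pairs nor a directory", call. = FALSE)
  }
  list(
    reference = read_dose_grid(file.path(dir, manifest$ref_file[i])),
    evaluated = read_dose_grid(file.path(dir, manifest$eval_file[i]))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohort_manifest <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "<cohort_manifest> %d plans (%d errored), seed %d, detector %g mm, noise %g%%\n",
    nrow(x), sum(x$outcome == "errored"), p$cohort_seed,
    p$detector_spacing_mm, p$noise_sd_percent))
  invisible(x)
}
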