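# Independent brute-force gamma oracle: plain double loop over every
# reference point, no search window, no shortcuts. Deliberately naive so it
# shares nothing with the package's engine beyond the definition.
oracle_gamma_point <- function(ref, ye, xe, de, dd, dta, normalization) {
  ry <- ref$origin[1] + (seq_len(nrow(ref$values)) - 1) * ref$spacing[1]
  rx <- ref$origin[2] + (seq_len(ncol(ref$values)) - 1) * ref$spacing[2]
  best <- Inf
  for (i in seq_along(ry)) {
    for (j in seq_along(rx)) {
      dr <- ref$values[i, j]
      den <- if (normalization == "local") dr else max(ref$values)
      if (normalization == "local" && dr <= 0) next
      dist2 <- (ry[i] - ye)^2 + (rx[j] - xe)^2
      delta <- 100 * (de - dr) / den
      g <- sqrt(dist2 / dta^2 + delta^2 / dd^2)
      if (g < best) best <- g
    }
  }
  best
}

oracle_gamma_map <- function(ref, ev, dd, dta, normalization,
                             included = NULL) {
  ey <- ev$origin[1] + (seq_len(nrow(ev$values)) - 1) * ev$spacing[1]
  ex <- ev$origin[2] + (seq_len(ncol(ev$values)) - 1) * ev$spacing[2]
  out <- matrix(NA_real_, nrow(ev$values), ncol(ev$values))
  for (i in seq_len(nrow(ev$values))) {
    for (j in seq_len(ncol(ev$values))) {
      if (!is.null(included) && !included[i, j]) next
      out[i, j] <- oracle_gamma_point(ref, ey[i], ex[j], ev$values[i, j],
                                      dd, dta, normalization)
    }
  }
  out
}

# random smooth-ish reference / coarse evaluated pair on an aligned lattice
random_pair <- function(seed, nref = 12, ratio = 5, jitter_sd = 2) {
  set.seed(seed)
  base <- matrix(stats::runif(nref * nref, 20, 100), nref, nref)
  # mild smoothing so doses look like fields rather than white noise
  k <- matrix(1 / 9, 3, 3)
  sm <- base
  for (i in 2:(nref - 1)) {
    for (j in 2:(nref - 1)) {
      sm[i, j] <- sum(base[(i - 1):(i + 1), (j - 1):(j + 1)] * k)
    }
  }
  ref <- dose_grid(sm, spacing = 1)
  rows <- seq(1, nref, by = ratio)
  ev_vals <- sm[rows, rows] + stats::rnorm(length(rows)^2, sd = jitter_sd)
  ev <- dose_grid(pmax(ev_vals, 0), spacing = ratio)
  list(ref = ref, ev = ev)
}

all_included <- function(grid) {
  structure(list(included = matrix(TRUE, nrow(grid$values),
                                   ncol(grid$values)),
                 ldt_percent = 0),
            class = "evaluation_mask")
}

# a small analytic plan/measurement pair for integration-style tests
small_pair <- function(seed = 5, errored = FALSE, noise = 0) {
  spec <- plan_spec()
  ref <- generate_plan(spec, seed = seed)
  model <- if (errored) {
    doseagree:::draw_error_model(ref, seed = seed + 1,
                                 noise_sd_percent = noise)
  } else {
    error_model(noise_sd_percent = noise)
  }
  ev <- sample_detector(inject_errors(ref, model, seed = seed + 2))
  list(ref = ref, ev = ev)
}
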