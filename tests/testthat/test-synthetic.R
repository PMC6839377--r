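test_that("plan generation is deterministic and populates all isodose bands", {
  spec <- plan_spec()
  a <- generate_plan(spec, seed = 101)
  b <- generate_plan(spec, seed = 101)
  expect_identical(a$values, b$values)
  expect_equal(a$spacing, c(1, 1))
  for (seed in seq(7, 7 + 19)) {
    v <- generate_plan(spec, seed)$values
    f <- 100 * v / max(v)
    expect_true(any(f >= 10 & f < 20))
    expect_true(any(f >= 20 & f < 50))
    expect_true(any(f >= 50 & f < 90))
    expect_true(any(f >= 90))
  }
})

test_that("a centred single-lobe plan is symmetric under 180-degree rotation", {
  spec <- plan_spec(n_lobes = 1, lobe_center_frac = 0,
                    lobe_amplitude = c(0.4, 0.4), lobe_sd_mm = c(12, 12))
  g <- generate_plan(spec, seed = 3)
  rotated <- g$values[rev(seq_len(nrow(g$values))),
                      rev(seq_len(ncol(g$values)))]
  expect_lt(max(abs(g$values - rotated)), 1e-9)
})

test_that("an unpopulatable specification fails with a diagnostic", {
  spec <- plan_spec(n_lobes = 1, lobe_amplitude = c(0, 0),
                    scatter_amplitude = 0, penumbra_mm = 0.01)
  expect_error(generate_plan(spec, seed = 1), "isodose band")
})

test_that("the identity error model returns the plan unchanged", {
  plan <- generate_plan(plan_spec(), seed = 5)
  out <- inject_errors(plan, error_model(), seed = 9)
  expect_identical(out$values, plan$values)
})

test_that("a 5% scaling on a plateau fails 3% and passes 5% global gamma", {
  ref <- dose_grid(matrix(100, 41, 41), spacing = 1)
  scaled <- inject_errors(ref, error_model(scale_factor = 1.05), seed = 1)
  ev <- sample_detector(scaled, 10)
  g3 <- gamma_map(ref, ev, criteria_pair(3, 3, "global"))
  interior <- matrix(FALSE, 5, 5); interior[2:4, 2:4] <- TRUE
  expect_true(all(g3$index_map[interior] > 1))
  g5 <- gamma_map(ref, ev, criteria_pair(5, 3, "global"))
  expect_equal(max(abs(g5$index_map - 1)), 0)
  expect_equal(g5$agreement_index, 100)
})

test_that("a pure shift within the DTA passes away from the grid border", {
  plan <- generate_plan(plan_spec(), seed = 12)
  shifted <- inject_errors(plan, error_model(shift_mm = c(2, 0)), seed = 1)
  ev <- sample_detector(shifted, 10)
  mask <- doseagree:::comparison_mask(plan, ev, 10)
  res <- gamma_map(plan, ev, criteria_pair(3, 3, "global"), mask)
  inc <- mask$included
  border <- matrix(TRUE, nrow(inc), ncol(inc))
  border[2:(nrow(inc) - 1), 2:(ncol(inc) - 1)] <- FALSE
  expect_true(all(res$index_map[inc & !border] <= 1))
  exh <- gamma_map(plan, ev, criteria_pair(3, 3, "global"), mask,
                   search = "exhaustive")
  expect_lt(max(abs(res$index_map[inc] - exh$index_map[inc])), 1e-12)
})

test_that("an excessive shift is rejected as a geometry error", {
  plan <- generate_plan(plan_spec(), seed = 12)
  expect_error(inject_errors(plan, error_model(shift_mm = c(40, 0))),
               "outside the grid extent")
  flat <- dose_grid(matrix(1, 5, 5), 1)
  expect_error(inject_errors(flat, error_model(shift_mm = c(1, 0))),
               "analytic plan")
})

test_that("detector sampling is exact point sampling on the source lattice", {
  plan <- generate_plan(plan_spec(), seed = 15)
  ev <- sample_detector(plan, 10)
  expect_equal(ev$spacing, c(10, 10))
  rows <- seq(1, nrow(plan$values), by = 10)
  expect_identical(ev$values, plan$values[rows, rows])
  # extent never grows
  expect_lte(max(doseagree:::axis_mm(ev, 1)), max(doseagree:::axis_mm(plan, 1)))
  uniform <- dose_grid(matrix(7, 21, 21), 1)
  expect_true(all(sample_detector(uniform, 10)$values == 7))
  expect_error(sample_detector(plan, 2.5), "integer multiple")
})

test_that("cohorts have the requested composition and regenerate bit-identically", {
  dir <- withr::local_tempdir()
  man <- generate_cohort(n = 6, errored_fraction = 0.34, seed = 77,
                         dir = dir)
  expect_equal(sum(man$outcome == "errored"), 2)  # round(6 * 0.34)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_equal(round(50 * 0.12), 6)  # the default composition arithmetic

  man2 <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(man2$seed, man$seed)
  expect_equal(man2$outcome, man$outcome)
  dir2 <- withr::local_tempdir()
  regenerate_cohort(man2, dir = dir2)
  for (f in c(man$ref_file, man$eval_file)) {
    expect_identical(readLines(file.path(dir2, f)),
                     readLines(file.path(dir, f)))
  }
})

test_that("clean pairs agree perfectly under every technique", {
  man <- generate_cohort(n = 3, errored_fraction = 0, seed = 31,
                         noise_sd_percent = 0)
  for (i in 1:3) {
    pair <- doseagree:::cohort_pair(man, i)
    for (tech in c("gamma_global", "gamma_local", "madd_box", "madd_gamma",
                   "dnc")) {
      res <- compare_dose(pair$reference, pair$evaluated, tech,
                          dd = 2, dta = 2, ldt = 10)
      expect_equal(res$agreement_index, 100)
      expect_equal(max(abs(res$index_map[res$mask$included])), 0)
    }
  }
})

test_that("relative-mode cohorts normalize both grids at dose maximum", {
  spec <- plan_spec(mode = "relative")
  man <- generate_cohort(n = 2, errored_fraction = 0.5, seed = 13,
                         spec = spec)
  for (i in 1:2) {
    pair <- doseagree:::cohort_pair(man, i)
    expect_identical(pair$reference$mode, "relative")
    expect_identical(pair$evaluated$mode, "relative")
    expect_equal(max(pair$reference$values), 100)
    expect_equal(max(pair$evaluated$values), 100)
  }
})
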