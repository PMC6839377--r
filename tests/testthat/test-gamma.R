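test_that("self-comparison gives gamma 0 and full pass everywhere", {
  set.seed(1)
  vals <- matrix(stats::runif(36, 10, 100), 6, 6)
  g <- dose_grid(vals, spacing = 2)
  for (norm in c("global", "local")) {
    res <- gamma_map(g, g, criteria_pair(3, 3, norm))
    expect_equal(max(abs(res$index_map)), 0)
    expect_equal(res$agreement_index, 100)
    expect_equal(pass_rate(res), 100)
  }
})

test_that("uniform field offset by exactly the criterion sits on the pass boundary", {
  ref <- dose_grid(matrix(100, 9, 9), spacing = 1)
  ev <- dose_grid(matrix(103, 3, 3), spacing = 4)
  res <- gamma_map(ref, ev, criteria_pair(3, 5, "global"))
  expect_equal(as.vector(res$index_map), rep(1, 9))
  expect_equal(res$agreement_index, 100)
})

test_that("optimized search matches the exhaustive brute-force oracle", {
  for (seed in 1:6) {
    pr <- random_pair(seed)
    for (norm in c("global", "local")) {
      cr <- criteria_pair(3, 3, norm)
      opt <- gamma_map(pr$ref, pr$ev, cr, search = "optimized")
      exh <- gamma_map(pr$ref, pr$ev, cr, search = "exhaustive")
      orc <- oracle_gamma_map(pr$ref, pr$ev, 3, 3, norm)
      expect_lt(max(abs(opt$index_map - orc)), 1e-12)
      expect_lt(max(abs(exh$index_map - orc)), 1e-12)
    }
  }
})

test_that("gamma maps are invariant under a common dose rescaling", {
  pr <- random_pair(11)
  for (norm in c("global", "local")) {
    cr <- criteria_pair(2, 2, norm)
    base <- gamma_map(pr$ref, pr$ev, cr)
    for (c_scale in c(0.25, 7)) {
      ref2 <- dose_grid(pr$ref$values * c_scale, pr$ref$spacing,
                        pr$ref$origin)
      ev2 <- dose_grid(pr$ev$values * c_scale, pr$ev$spacing, pr$ev$origin)
      scaled <- gamma_map(ref2, ev2, cr)
      expect_lt(max(abs(scaled$index_map - base$index_map)), 1e-9)
    }
  }
})

test_that("loosening criteria lowers gamma pointwise and raises the pass rate", {
  pr <- random_pair(23)
  for (norm in c("global", "local")) {
    tight <- gamma_map(pr$ref, pr$ev, criteria_pair(2, 2, norm))
    loose_d <- gamma_map(pr$ref, pr$ev, criteria_pair(3, 2, norm))
    loose_both <- gamma_map(pr$ref, pr$ev, criteria_pair(3, 3, norm))
    expect_true(all(loose_d$index_map <= tight$index_map + 1e-12))
    expect_true(all(loose_both$index_map <= loose_d$index_map + 1e-12))
    expect_gte(loose_both$agreement_index, tight$agreement_index)
  }
})

test_that("global gamma dominates local gamma at matched criteria", {
  for (seed in c(3, 17, 31)) {
    pr <- random_pair(seed)
    glob <- gamma_map(pr$ref, pr$ev, criteria_pair(2, 2, "global"))
    loc <- gamma_map(pr$ref, pr$ev, criteria_pair(2, 2, "local"))
    expect_true(all(glob$index_map <= loc$index_map + 1e-12))
    expect_gte(glob$agreement_index, loc$agreement_index)
  }
})

test_that("local normalization skips zero-dose reference points", {
  # reference entirely zero except one cell far from the evaluated point:
  # the near candidates are all skipped, the far one decides
  ref_vals <- matrix(0, 11, 11)
  ref_vals[1, 1] <- 50
  ref <- dose_grid(ref_vals, spacing = 1)
  ev <- dose_grid(matrix(50, 1, 1), spacing = 1, origin = c(10, 10))
  res <- gamma_map(ref, ev, criteria_pair(3, 3, "local"),
                   search = "exhaustive")
  expect_equal(res$index_map[1, 1], sqrt(200) / 3)
  # every reference dose zero: all candidates skipped -> Inf, point fails
  ref0 <- dose_grid(matrix(0, 5, 5), spacing = 1)
  ev0 <- dose_grid(matrix(1, 1, 1), spacing = 1, origin = c(2, 2))
  res0 <- gamma_map(ref0, ev0, criteria_pair(3, 3, "local"))
  expect_identical(res0$index_map[1, 1], Inf)
  expect_equal(res0$agreement_index, 0)
})

test_that("pass_rate counts only included points, inclusive at 1", {
  idx <- matrix(c(0.5, 1.5, 0.5, 9), 2, 2)
  mask <- structure(list(included = matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2),
                         ldt_percent = 10),
                    class = "evaluation_mask")
  res <- structure(list(index_map = idx, mask = mask,
                        agreement_index = NA, technique = "gamma_global",
                        criteria = criteria_pair(3, 3)),
                   class = "dose_comparison")
  expect_equal(pass_rate(res), 200 / 3)
  idx2 <- matrix(c(0.2, 0.9, 1.0, 2), 2, 2)
  mask$included <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  res$index_map <- idx2
  res$mask <- mask
  expect_equal(pass_rate(res), 100)
  res$mask$included[] <- FALSE
  expect_error(pass_rate(res), "no included points")
})

test_that("geometry and degenerate inputs are rejected", {
  ref <- dose_grid(matrix(1:9, 3, 3), spacing = 1)
  outside <- dose_grid(matrix(1, 1, 1), spacing = 1, origin = c(5, 5))
  expect_error(gamma_map(ref, outside, criteria_pair(3, 3)),
               "outside the reference extent")
  ev <- dose_grid(matrix(1, 1, 1), spacing = 1, origin = c(1, 1))
  empty <- structure(list(included = matrix(FALSE, 1, 1), ldt_percent = 95),
                     class = "evaluation_mask")
  expect_error(gamma_map(ref, ev, criteria_pair(3, 3), empty),
               "no evaluated points")
  expect_error(criteria_pair(0, 3), "positive")
  expect_error(criteria_pair(3, -1), "positive")
})
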