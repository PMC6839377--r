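test_that("ols_r2 matches the closed-form sums-of-squares computation", {
  # perfect affine relation
  x <- c(1, 2, 3, 4, 5)
  expect_equal(ols_r2(x, 2 * x + 1)$r_squared, 1)
  # symmetric pattern with zero slope
  fit0 <- ols_r2(c(1, 2, 3, 4), c(1, 2, 2, 1))
  expect_equal(fit0$r_squared, 0)
  expect_equal(fit0$slope, 0)
  # random fixture against an independent closed-form oracle
  set.seed(42)
  for (rep in 1:5) {
    xr <- stats::rnorm(10)
    yr <- 1.5 * xr + stats::rnorm(10)
    fit <- ols_r2(xr, yr)
    sxx <- sum((xr - mean(xr))^2)
    sxy <- sum((xr - mean(xr)) * (yr - mean(yr)))
    beta <- sxy / sxx
    alpha_hat <- mean(yr) - beta * mean(xr)
    resid <- yr - alpha_hat - beta * xr
    ss_res <- sum(resid^2)
    ss_tot <- sum((yr - mean(yr))^2)
    r2 <- 1 - ss_res / ss_tot
    se <- sqrt(ss_res / (10 - 2) / sxx)
    p <- 2 * stats::pt(abs(beta / se), df = 8, lower.tail = FALSE)
    expect_lt(abs(fit$r_squared - r2), 1e-10)
    expect_lt(abs(fit$p_value - p), 1e-10)
    expect_lt(abs(fit$slope - beta), 1e-10)
    # R2 is direction-independent for simple regression
    expect_lt(abs(ols_r2(yr, xr)$r_squared - fit$r_squared), 1e-10)
  }
  expect_error(ols_r2(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(ols_r2(1:2, 1:2), "at least 3")
  const_y <- ols_r2(1:5, rep(2, 5))
  expect_equal(const_y$r_squared, 0)
  expect_true(const_y$constant_y)
})

test_that("sidak correction matches its closed form and orderings", {
  expect_equal(sidak_correct(0.05, 1), 0.05)
  expect_equal(sidak_correct(0.05, 10), 1 - 0.95^0.1)
  ms <- c(2, 3, 5, 10, 50)
  levels <- vapply(ms, function(m) sidak_correct(0.05, m), numeric(1))
  expect_true(all(diff(levels) < 0))
  # strictly between Bonferroni and the uncorrected level
  for (m in ms) {
    a <- sidak_correct(0.05, m)
    expect_gt(a, 0.05 / m)
    expect_lt(a, 0.05)
  }
  expect_error(sidak_correct(0, 3), "alpha")
  expect_error(sidak_correct(0.05, 0), "m must be")
})

test_that("batch_indices tabulates every combination with summaries", {
  man <- generate_cohort(n = 3, errored_fraction = 1 / 3, seed = 5)
  tab <- batch_indices(man, techniques = c("gamma_global", "dnc"),
                       criteria_list = list(c(2, 2), c(3, 3)),
                       ldt_list = c(5, 10))
  # gamma: 2 criteria x 2 LDT; dnc collapses to one column per criteria
  expect_equal(ncol(tab$indices), 6)
  expect_equal(nrow(tab$indices), 3)
  expect_true(all(tab$indices >= 0 & tab$indices <= 100))
  s <- summary(tab)
  expect_equal(nrow(s), 6)
  expect_true(all(s$n == 3))
  # clean cohort at 3%/3mm global must average 100 with zero spread
  man0 <- generate_cohort(n = 3, errored_fraction = 0, seed = 6,
                          noise_sd_percent = 0)
  tab0 <- batch_indices(man0, techniques = "gamma_global",
                        criteria_list = list(c(3, 3)), ldt_list = 10)
  s0 <- summary(tab0)
  expect_equal(s0$mean, 100)
  expect_equal(s0$sd, 0)
})

test_that("unreadable plans are recorded as failures without stopping", {
  dir <- withr::local_tempdir()
  man <- generate_cohort(n = 3, errored_fraction = 0, seed = 8, dir = dir)
  man2 <- read_manifest(file.path(dir, "manifest.tsv"))
  file.remove(file.path(dir, man2$ref_file[2]))
  expect_warning(
    tab <- batch_indices(man2, techniques = "gamma_global",
                         criteria_list = list(c(3, 3)), ldt_list = 10),
    "failed"
  )
  expect_true(all(is.na(tab$indices[2, ])))
  expect_false(anyNA(tab$indices[-2, ]))
  expect_gt(length(tab$failures), 0)
})

test_that("correlation_matrix flags correlated pairs with Sidak control", {
  # self-pair: R2 exactly 1 and correlated
  man <- generate_cohort(n = 6, errored_fraction = 0.5, seed = 9)
  tab <- batch_indices(man, techniques = "gamma_local",
                       criteria_list = list(c(2, 2), c(3, 3)), ldt_list = 10)
  cols <- colnames(tab$indices)
  rep1 <- correlation_matrix(tab, pairs = cbind(cols[1], cols[1]))
  expect_equal(rep1$r_squared, 1)
  expect_true(rep1$correlated)

  # two independent noise columns stay below the 0.64 threshold
  fake <- tab
  set.seed(10)
  fake$indices <- cbind(a = stats::rnorm(200), b = stats::rnorm(200))
  rep2 <- correlation_matrix(fake, columns = c("a", "b"))
  expect_lt(rep2$r_squared, 0.64)
  expect_false(rep2$correlated)
  expect_equal(attr(rep2, "alpha_corrected"), 0.05)

  # R2 matrix layout is symmetric with unit diagonal
  tab5 <- batch_indices(man,
                        techniques = c("gamma_global", "gamma_local",
                                       "dnc", "madd_box", "madd_gamma"),
                        criteria_list = list(c(2, 2)), ldt_list = 10)
  rep5 <- correlation_matrix(tab5)
  expect_equal(attr(rep5, "m"), choose(5, 2))
  m5 <- r2_matrix(rep5)
  expect_equal(dim(m5), c(5, 5))
  expect_equal(m5, t(m5))
  expect_equal(unname(diag(m5)), rep(1, 5))
})

test_that("reports are reproducible from the same manifest and config", {
  man_a <- generate_cohort(n = 4, errored_fraction = 0.5, seed = 21)
  man_b <- generate_cohort(n = 4, errored_fraction = 0.5, seed = 21)
  args <- list(techniques = c("gamma_global", "gamma_local"),
               criteria_list = list(c(2, 2)), ldt_list = c(5, 10))
  tab_a <- do.call(batch_indices, c(list(man_a), args))
  tab_b <- do.call(batch_indices, c(list(man_b), args))
  expect_identical(tab_a$indices, tab_b$indices)
  expect_identical(correlation_matrix(tab_a)$r_squared,
                   correlation_matrix(tab_b)$r_squared)
})

test_that("raising the LDT does not lower global gamma on low-dose-error plans", {
  man <- generate_cohort(n = 5, errored_fraction = 1, seed = 34)
  tab <- batch_indices(man, techniques = "gamma_global",
                       criteria_list = list(c(2, 2)), ldt_list = c(5, 10))
  ldt5 <- tab$indices[, grepl("LDT5", colnames(tab$indices))]
  ldt10 <- tab$indices[, grepl("LDT10", colnames(tab$indices))]
  expect_true(all(ldt10 >= ldt5 - 1e-12))
})
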