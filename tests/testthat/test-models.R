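test_that("exponential fit recovers generating parameters without noise", {
  sph <- c(-5, -2.5, 0, 2.5, 5)
  pts <- data.frame(sph = sph, value = 0.1 + 0.2 * 1.5^sph)
  fit <- fit_exponential(pts)
  expect_equal(fit$a, 0.1, tolerance = 1e-6)
  expect_equal(fit$b, 0.2, tolerance = 1e-6)
  expect_equal(fit$c, 1.5, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
  expect_false(fit$degenerate)
  # shift equivariance: values + delta -> a + delta, b and c unchanged
  fit_s <- fit_exponential(transform(pts, value = value + 2.5))
  expect_equal(fit_s$a, fit$a + 2.5, tolerance = 1e-5)
  expect_equal(fit_s$b, fit$b, tolerance = 1e-5)
  expect_equal(fit_s$c, fit$c, tolerance = 1e-5)
})

test_that("flat data yields the degenerate fit and thin data errors", {
  flat <- fit_exponential(data.frame(sph = c(-1, 0, 1), value = 0.7))
  expect_true(flat$degenerate)
  expect_equal(flat$a, 0.7)
  expect_equal(flat$b, 0)
  expect_equal(flat$c, 1)
  expect_error(fit_exponential(data.frame(sph = c(0, 0, 1),
                                          value = c(1, 2, 3))),
               "distinct")
})

test_that("add groups differ mainly in offset and slope, barely in base", {
  ss <- default_stimuli()
  truth <- materialize_scale(scale_params(), ss)
  fits <- lapply(c(1, 3), function(ad) {
    sel <- !ss$is_reference & ss$add == ad
    fit_exponential(data.frame(sph = ss$sph[sel], value = truth[sel]))
  })
  d_a <- abs(fits[[1]]$a - fits[[2]]$a)
  d_b <- abs(fits[[1]]$b - fits[[2]]$b)
  d_c <- abs(fits[[1]]$c - fits[[2]]$c)
  expect_gt(d_a, 5 * d_c)
  expect_gt(d_b, 5 * d_c)
})

test_that("LOSO: identical exponential subjects are predicted perfectly", {
  ss <- default_stimuli()
  truth <- materialize_scale(scale_params(), ss)
  values <- matrix(truth, nrow = 11, ncol = 4)
  # reference value is 0 by construction, matching the 0-prediction rule
  rep <- loso_evaluate(values, ss, families = "exponential", seed = 1)
  expect_true(all(rep$r2 > 0.999))
})

test_that("LOSO honours training/test separation and reports negative R2", {
  ss <- default_stimuli()
  truth <- materialize_scale(scale_params(), ss)
  set.seed(3)
  values <- sapply(1:5, function(j) truth + rnorm(11, 0, 0.05))
  # an outlier subject far from the cohort mean must get r2 < 0
  values[, 5] <- mean(truth) + rnorm(11, 0, 0.01)
  rep <- loso_evaluate(values, ss, families = "linear", seed = 1)
  expect_lt(rep$r2[rep$subject == 5], 0)
  # external oracle for one fold: fitting on subjects 1-4 only and
  # scoring subject 5 must reproduce the reported r2 exactly -- i.e.
  # subject 5 contributed nothing to its own training fit
  train <- do.call(rbind, lapply(1:4, function(j) {
    data.frame(value = values[, j], sph = ss$sph, add = ss$add)
  }))
  test <- data.frame(value = values[, 5], sph = ss$sph, add = ss$add)
  fit <- lm(value ~ sph + add + sph:add, data = train)
  r2_oracle <- 1 - sum((test$value - predict(fit, test))^2) /
    sum((test$value - mean(test$value))^2)
  expect_equal(rep$r2[rep$subject == 5], r2_oracle)
  expect_error(loso_evaluate(values, ss, families = "spline"), "unknown")
})

test_that("exponential model beats the linear baseline on nonlinear cohorts", {
  ss <- default_stimuli()
  truth <- materialize_scale(scale_params(), ss)
  medians <- sapply(1:3, function(cs) {
    set.seed(100 + cs)
    values <- sapply(1:13, function(j) {
      v <- truth + rnorm(11, 0, 0.05)
      v[1] <- 0
      v
    })
    nm <- normalize_scales(gpa_align_1d(values), 1, 11)
    rep <- loso_evaluate(nm, ss, families = c("linear", "exponential"),
                         seed = cs)
    tapply(rep$r2, rep$family, median)
  })
  expect_true(all(medians["exponential", ] > medians["linear", ]))
})
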