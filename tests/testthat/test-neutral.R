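# Subclonal windowing, the cumulative M(f) curve, the zero-intercept 1/f
# fit and its classification, pooling, and the paired shift summary.

exact_set <- function(c = 10, n = 20, f_min = 0.10, f_max = 0.25) {
  # frequencies placed so that M(f) = c * (1/f - 1/f_max) exactly at the
  # observed points: 1/f_i = 1/f_max + i/c
  subclonal_window(1 / (1 / f_max + seq_len(n) / c), f_min, f_max)
}

test_that("the subclonal window is strict on both sides", {
  s <- subclonal_window(c(0.05, 0.10, 0.12, 0.249, 0.25, 0.5))
  expect_equal(s$vafs, c(0.12, 0.249))
  expect_length(subclonal_window(numeric(0))$vafs, 0)
  expect_length(subclonal_window(c(0.25, 0.3, 0.9))$vafs, 0)
  # public-data reading admits the lower boundary
  expect_equal(subclonal_window(c(0.10, 0.2), inclusive_lower = TRUE)$vafs,
               c(0.10, 0.2))
})

test_that("observed-frequency M(f) ranks descending frequencies with stable ties", {
  s <- exact_set(c = 10, n = 20)
  mf <- cumulative_mf(s)
  expect_equal(mf$x, (1:20) / 10, tolerance = 1e-12)
  expect_equal(mf$M, 1:20)

  one <- cumulative_mf(subclonal_window(0.2))
  expect_equal(one$x, 1 / 0.2 - 4)
  expect_equal(one$M, 1)

  ties <- cumulative_mf(subclonal_window(c(0.2, 0.2)))
  expect_equal(ties$x, c(1, 1))
  expect_equal(ties$M, c(1, 2))
})

test_that("grid-evaluated M(f) counts mutations above each grid frequency", {
  s <- subclonal_window(c(0.12, 0.2, 0.24))
  mf <- cumulative_mf(s, eval = "grid", grid_points = 50)
  expect_equal(nrow(mf), 50)
  expect_equal(max(mf$x), 1 / 0.1 - 1 / 0.25)
  for (i in c(1, 25, 50)) {
    expect_equal(mf$M[i], sum(s$vafs >= mf$f[i]))
  }
  expect_true(all(diff(mf$M) >= 0))
})

test_that("exact 1/f constructions are recovered to numerical precision", {
  d <- data.frame(x = (1:20) / 10, M = 1:20)
  f <- fit_neutral_model(d)
  expect_equal(f$slope, 10, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_identical(f$classification, "neutral")

  set.seed(31)
  for (i in 1:20) {
    c0 <- runif(1, 0.5, 40)
    n <- sample(2:min(50, floor(6 * c0)), 1)
    fit <- fit_neutral_model(exact_set(c0, n), mf_eval = "observed")
    expect_equal(fit$slope, c0, tolerance = 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("rescaling x rescales the slope and leaves r-squared unchanged", {
  set.seed(8)
  d <- data.frame(x = runif(30, 0.1, 6), M = sort(rpois(30, 20)))
  f1 <- fit_neutral_model(d)
  for (k in c(0.5, 2, 10)) {
    fk <- fit_neutral_model(data.frame(x = d$x * k, M = d$M))
    expect_equal(fk$slope, f1$slope / k, tolerance = 1e-12)
    expect_equal(fk$r_squared, f1$r_squared, tolerance = 1e-12)
  }
})

test_that("the fitted slope matches independent zero-intercept regression on 100 instances", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    d <- data.frame(x = runif(n, 0.05, 6), M = cumsum(rpois(n, 3)) + 1)
    f <- fit_neutral_model(d)
    ref <- unname(coef(lm(M ~ 0 + x, data = d)))
    expect_equal(f$slope, ref, tolerance = 1e-9)
  }
})

test_that("classification uses the strict 0.98 rule and the variant-count floor", {
  expect_identical(classify_evolution(0.9897), "neutral")
  expect_identical(classify_evolution(0.98), "non_neutral")
  expect_identical(classify_evolution(0.9571), "non_neutral")
  expect_identical(classify_evolution(0.99, n_variants = 3, min_variants = 12),
                   "insufficient")
  expect_identical(classify_evolution(0.99, n_variants = 20, min_variants = 12),
                   "neutral")
})

test_that("sparse fits flag single-point influence when one removal flips the call", {
  flip <- fit_neutral_model(data.frame(x = c(1, 2, 3), M = c(1, 2, 10)))
  expect_identical(flip$classification, "non_neutral")
  expect_true(flip$flagged_single_point_influence)

  stable <- fit_neutral_model(data.frame(x = (1:5), M = (1:5) * 3))
  expect_identical(stable$classification, "neutral")
  expect_false(stable$flagged_single_point_influence)

  expect_identical(fit_neutral_model(data.frame(x = 1, M = 1))$classification,
                   "insufficient")
})

test_that("pooling preserves linearity, matches single-sample fits and rejects mixed windows", {
  s <- exact_set(c = 10, n = 40)
  single <- fit_neutral_model(s)
  both <- pooled_fit(list(s, s))
  expect_equal(both$r_squared, single$r_squared, tolerance = 1e-12)
  expect_equal(both$slope, 2 * single$slope, tolerance = 1e-12)
  expect_equal(pooled_fit(list(s))$r_squared, single$r_squared)

  other <- subclonal_window(c(0.2, 0.3), f_min = 0.1, f_max = 0.45)
  expect_error(pooled_fit(list(s, other)), "different windows")
})

test_that("pooling a clustered (selected) sample drags r-squared below the neutral sample", {
  neutral <- exact_set(c = 10, n = 50)
  clustered <- subclonal_window(rep(0.18, 50))
  r2_neutral <- fit_neutral_model(neutral)$r_squared
  r2_pooled <- pooled_fit(list(neutral, clustered))$r_squared
  expect_lt(r2_pooled, r2_neutral)
})

test_that("paired shift summary counts decreases and runs the sign test", {
  fits <- data.frame(patient_id = c("A", "B", "C"),
                     r2_diagnosis = c(0.97, 0.90, 0.95),
                     r2_relapse = c(0.90, 0.97, 0.95))
  ps <- paired_shift_summary(fits)
  expect_identical(ps$table$decreased, c(TRUE, FALSE, FALSE))
  expect_equal(ps$n_decreased, 1)
  expect_equal(ps$n_pairs, 3)
  # ties are dropped from the sign test: 1 decrease of 2 untied pairs
  expect_equal(ps$sign_test_p, 1)
})

test_that("the neutral_fit object behaves like a fitted model", {
  s <- exact_set(c = 6, n = 30)
  f <- fit_neutral_model(s, mf_eval = "observed")
  expect_equal(unname(coef(f)), f$slope)
  expect_equal(length(residuals(f)), nrow(f$data))
  expect_equal(max(abs(residuals(f))), 0, tolerance = 1e-9)
  expect_equal(predict(f, data.frame(x = 2)), f$slope * 2)
  expect_equal(predict(f, data.frame(f = 0.2)), f$slope * (1 / 0.2 - 4))
  expect_output(print(f), "R-squared")
  expect_output(print(summary(f)), "Residuals")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
})
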