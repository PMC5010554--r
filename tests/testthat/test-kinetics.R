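# quick two-pattern series on a small grid
toy_series <- function(noise = 0, seed = 1) {
  q <- seq(0.5, 2.5, by = 0.1)
  fast <- new_difference_curve(q, sin(2 * q))
  slow <- new_difference_curve(q, cos(1.5 * q))
  ks <- kinetic_spec(
    t_half_fast = 3e-5, t_half_slow = 1e-2, noise = noise, seed = seed
  )
  list(series = make_timeseries(ks, fast, slow), fast = fast, slow = slow, spec = ks)
}

test_that("extract_basis picks the nearest early curve and averages the window", {
  ts <- toy_series()
  M <- series_matrix(ts$series)
  times <- series_times(ts$series)
  b <- extract_basis(ts$series, early_time = 3e-6, late_window = c(0.1, 2))
  i_early <- which.min(abs(times - 3e-6))
  expect_equal(b$early$dS, M[, i_early])
  in_late <- times >= 0.1 & times <= 2
  expect_equal(b$late$dS, rowMeans(M[, in_late, drop = FALSE]), tolerance = 1e-12)

  # a window holding exactly one time point returns that curve
  one <- extract_basis(ts$series, 3e-6, late_window = c(times[20] - 1e-9, times[20] + 1e-9))
  expect_equal(one$late$dS, M[, 20])
  expect_error(extract_basis(ts$series, 3e-6, c(5, 6)), "no sampled time")
})

test_that("a late window of identical curves averages to any one of them", {
  q <- seq(0.5, 2, by = 0.1)
  shape <- sin(q)
  series <- time_series_set(tibble::tibble(
    time = rep(c(1, 2, 3), each = length(q)),
    q = rep(q, 3),
    dS = rep(shape, 3)
  ))
  b <- extract_basis(series, early_time = 1, late_window = c(1.5, 3.5))
  expect_equal(b$late$dS, shape)
})

test_that("decompose_series reproduces exact mixtures to machine precision", {
  q <- seq(0.5, 2.5, by = 0.05)
  e <- new_difference_curve(q, sin(2 * q))
  l <- new_difference_curve(q, cos(1.5 * q))
  basis <- structure(
    list(early = e, late = l, early_time = 1e-6, late_times = 1),
    class = "basis_set"
  )
  mix <- time_series_set(tibble::tibble(
    time = rep(c(1e-5, 1e-3, 1e-1), each = length(q)),
    q = rep(q, 3),
    dS = c(e$dS, 0.3 * e$dS + 0.7 * l$dS, l$dS)
  ))
  tr <- decompose_series(mix, basis)
  expect_equal(tr$amp_early, c(1, 0.3, 0), tolerance = 1e-12)
  expect_equal(tr$amp_late, c(0, 0.7, 1), tolerance = 1e-12)
  expect_lt(max(tr$resid_norm), 1e-12) # series lies in the basis span
})

test_that("decompose_series matches the normal-equations oracle on noisy data", {
  ts <- toy_series(noise = 0.05, seed = 7)
  basis <- extract_basis(ts$series)
  tr <- decompose_series(ts$series, basis)
  B <- cbind(basis$early$dS, basis$late$dS)
  M <- series_matrix(ts$series)
  oracle <- solve(crossprod(B)) %*% crossprod(B, M) # pseudo-inverse route
  expect_equal(tr$amp_early, unname(oracle[1, ]), tolerance = 1e-10)
  expect_equal(tr$amp_late, unname(oracle[2, ]), tolerance = 1e-10)
})

test_that("a rank-deficient basis is rejected with a condition diagnostic", {
  q <- seq(0.5, 2.5, by = 0.1)
  e <- new_difference_curve(q, sin(q))
  l <- new_difference_curve(q, 2 * sin(q))
  basis <- structure(
    list(early = e, late = l, early_time = 1, late_times = 2),
    class = "basis_set"
  )
  tt <- rep(1:2, each = length(q))
  qq <- rep(q, 2)
  yy <- rep(sin(q), 2)
  series <- time_series_set(tibble::tibble(time = tt, q = qq, dS = yy))
  expect_error(decompose_series(series, basis), "condition number")
})

test_that("fit_halftime recovers noise-free half-times across the time range", {
  t <- 10^seq(-6, 0.3, length.out = 30)
  for (T in c(1e-4, 1e-3, 1e-2, 1e-1)) {
    rise <- tibble::tibble(time = t, amplitude = 2.5 * (1 - 2^(-t / T)))
    fr <- fit_halftime(rise, "rise")
    expect_equal(fr$t_half, T, tolerance = 1e-6)
    expect_equal(fr$amplitude, 2.5, tolerance = 1e-6)
    decay <- tibble::tibble(time = t, amplitude = -1.2 * 2^(-t / T))
    fd <- fit_halftime(decay, "decay")
    expect_equal(fd$t_half, T, tolerance = 1e-6)
    expect_equal(fd$amplitude, -1.2, tolerance = 1e-6)
  }
})

test_that("degenerate traces are rejected", {
  t <- 10^seq(-4, 0, length.out = 10)
  expect_error(
    fit_halftime(tibble::tibble(time = t, amplitude = 0), "rise"),
    "constant"
  )
  expect_error(
    fit_halftime(tibble::tibble(time = t[1:3], amplitude = c(1, 2, 3)), "rise"),
    "at least 4"
  )
})

test_that("fit_halftime is scale-equivariant", {
  t <- 10^seq(-5, 0, length.out = 25)
  set.seed(13)
  y <- 1.4 * (1 - 2^(-t / 3e-3)) + rnorm(25, 0, 0.02)
  f1 <- fit_halftime(tibble::tibble(time = t, amplitude = y), "rise")
  f2 <- fit_halftime(tibble::tibble(time = t, amplitude = 100 * y), "rise")
  expect_equal(f2$t_half, f1$t_half, tolerance = 1e-8)
  expect_equal(f2$amplitude, 100 * f1$amplitude, tolerance = 1e-6)
})

test_that("half-times are recovered within 10% under 5% noise", {
  T <- 2e-3
  t <- 10^seq(log10(0.1 * T), log10(100 * T), length.out = 30)
  shape <- 1 - 2^(-t / T)
  # Cramer-Rao bound for this design: sd(t_half)/t_half = 0.056 at sigma =
  # 0.05, i.e. P(|error| < 10%) <= 0.926 for ANY unbiased estimator; the
  # fit should sit essentially at that bound
  set.seed(99)
  hits <- vapply(1:200, function(i) {
    y <- shape + rnorm(30, 0, 0.05)
    fit <- fit_halftime(tibble::tibble(time = t, amplitude = y), "rise")
    abs(fit$t_half / T - 1) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("recovery bias is below 2% at 1% noise", {
  T <- 2e-3
  t <- 10^seq(log10(0.1 * T), log10(100 * T), length.out = 30)
  shape <- 1 - 2^(-t / T)
  set.seed(7)
  est <- vapply(1:200, function(i) {
    y <- shape + rnorm(30, 0, 0.01)
    fit_halftime(tibble::tibble(time = t, amplitude = y), "rise")$t_half
  }, numeric(1))
  expect_lt(abs(mean(est) / T - 1), 0.02)
})

test_that("tidy, glance and the singular-value report have broom-style shapes", {
  t <- 10^seq(-4, 0, length.out = 12)
  fit <- fit_halftime(
    tibble::tibble(time = t, amplitude = 1 - 2^(-t / 1e-2)), "rise"
  )
  td <- tidy(fit)
  expect_equal(td$term, c("t_half", "amplitude"))
  expect_true(all(is.finite(td$estimate)))
  gl <- glance(fit)
  expect_equal(gl$model, "rise")
  expect_equal(gl$nobs, 12L)

  ts <- toy_series(noise = 0.02, seed = 3)
  rr <- rank_report(ts$series, k = 3)
  expect_equal(nrow(rr), 3)
  expect_true(all(diff(rr$singular_value) <= 0))
  # a two-component series concentrates variance in two singular values
  expect_gt(sum(rr$variance_fraction[1:2]), 0.95)
})

test_that("component amplitudes separate when time scales are well separated", {
  ts <- toy_series(noise = 0.01, seed = 5)
  basis <- extract_basis(ts$series)
  tr <- decompose_series(ts$series, basis)
  times <- tr$time
  # at the early defining time: early ~ 1, late ~ 0
  i_early <- which.min(abs(times - 3e-6))
  expect_equal(tr$amp_early[i_early], 1, tolerance = 0.05)
  expect_equal(tr$amp_late[i_early], 0, tolerance = 0.05)
  # in the late window the slow component saturates and the fast one is gone
  late <- times > 0.5
  expect_true(all(abs(tr$amp_late[late] - 1) < 0.05))
  expect_true(all(abs(tr$amp_early[late]) < 0.05))
})
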