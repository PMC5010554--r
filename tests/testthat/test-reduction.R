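test_that("normalize_window is idempotent and handles constants", {
  q <- seq(1, 20, by = 0.5)
  set.seed(2)
  cv <- scattering_curve(q, runif(length(q), 1, 10))
  n1 <- normalize_window(cv)
  idx <- which(q >= 14 & q <= 16)
  expect_equal(mean(n1$I[idx]), 1, tolerance = 1e-12)
  n2 <- normalize_window(n1)
  expect_equal(n2$I, n1$I, tolerance = 1e-12) # idempotent

  const <- scattering_curve(q, rep(5, length(q)))
  expect_equal(normalize_window(const)$I, rep(1, length(q)))

  expect_error(normalize_window(cv, qmin = 30, qmax = 40), "no grid points")
  zero <- scattering_curve(q, rep(0, length(q)))
  expect_error(normalize_window(zero), "zero")
})

test_that("laser-off subtraction removes null signals and linear drift", {
  q <- seq(0.5, 5, by = 0.1)
  S <- scattering_curve(q, 3 + sin(q))

  null <- subtract_laser_off(S, S, S)
  expect_equal(null$dS, rep(0, length(q)))

  zero <- scattering_curve(q, rep(0, length(q)))
  expect_equal(subtract_laser_off(zero, S, zero)$dS, S$I)

  # linear drift: on sits midway between pre and post, so it cancels
  drift <- scattering_curve(q, 0.2 * q)
  pre <- scattering_curve(q, S$I)
  on <- scattering_curve(q, S$I + drift$I)
  post <- scattering_curve(q, S$I + 2 * drift$I)
  expect_equal(subtract_laser_off(pre, on, post)$dS, rep(0, length(q)),
    tolerance = 1e-12
  )

  expect_error(
    subtract_laser_off(S, S, scattering_curve(q[-1], S$I[-1])),
    "same q grid"
  )
})

test_that("laser-off subtraction is linear in all three inputs", {
  q <- seq(0.5, 5, by = 0.25)
  set.seed(5)
  mk <- function() scattering_curve(q, runif(length(q), 1, 4))
  a1 <- mk(); b1 <- mk(); c1 <- mk()
  a2 <- mk(); b2 <- mk(); c2 <- mk()
  lhs <- subtract_laser_off(
    scattering_curve(q, a1$I + a2$I),
    scattering_curve(q, b1$I + b2$I),
    scattering_curve(q, c1$I + c2$I)
  )
  rhs <- subtract_laser_off(a1, b1, c1)$dS + subtract_laser_off(a2, b2, c2)$dS
  expect_equal(lhs$dS, rhs, tolerance = 1e-12)
})

test_that("detector merging scales by the overlap ratio and splices at its midpoint", {
  qs <- seq(0.05, 6.7, by = 0.05)
  qw <- seq(5.2, 27.5, by = 0.05) # aligned with the fine grid in the overlap
  f <- function(q) 10 * exp(-0.05 * q) + 1
  small <- scattering_curve(qs, f(qs))

  ident <- merge_detectors(small, small)
  expect_equal(attr(ident, "scale"), 1, tolerance = 1e-12)
  expect_equal(ident$q, small$q)
  expect_equal(ident$I, small$I, tolerance = 1e-12)

  wide <- scattering_curve(qw, 0.5 * f(qw))
  merged <- merge_detectors(small, wide)
  expect_equal(attr(merged, "scale"), 2, tolerance = 1e-10)
  expect_false(is.unsorted(merged$q))
  mid <- (5.2 + 6.7) / 2
  # exclusive ranges equal the (scaled) source exactly
  lowq <- merged$q <= mid
  expect_equal(merged$I[lowq], small$I[small$q <= mid])
  expect_equal(merged$I[!lowq], 2 * wide$I[wide$q > mid], tolerance = 1e-12)

  expect_error(
    merge_detectors(small, scattering_curve(qw + 10, f(qw))),
    "overlap"
  )
})

test_that("noisy overlap scaling matches the least-squares oracle", {
  qs <- seq(1, 7, by = 0.02)
  qw <- seq(5, 20, by = 0.1)
  f <- function(q) 50 / (1 + q^2)
  set.seed(8)
  small <- scattering_curve(qs, f(qs) * (1 + rnorm(length(qs), 0, 0.01)))
  wide <- scattering_curve(qw, 0.37 * f(qw) * (1 + rnorm(length(qw), 0, 0.01)))
  merged <- merge_detectors(small, wide)
  # oracle: explicit least-squares on the interpolated overlap
  ov <- qs[qs >= 5 & qs <= 7]
  wi <- approx(wide$q, wide$I, xout = ov)$y
  si <- small$I[qs >= 5 & qs <= 7]
  oracle <- sum(si * wi) / sum(wi^2)
  expect_equal(attr(merged, "scale"), oracle, tolerance = 1e-8)
})

test_that("heat subtraction removes a scaled heat pattern", {
  q <- seq(0.5, 3, by = 0.05)
  heat <- new_difference_curve(q, -(q - 1.8)^2 + 1)

  pure <- new_difference_curve(q, 3 * heat$dS)
  cleaned <- subtract_heat(pure, heat)
  expect_equal(attr(cleaned, "heat_coef"), 3, tolerance = 1e-12)
  expect_equal(cleaned$dS, rep(0, length(q)), tolerance = 1e-12)

  # orthogonal over the fit window: untouched
  idx <- which(q >= 1 & q <= 2)
  y <- sin(6 * q)
  y[idx] <- y[idx] - sum(y[idx] * heat$dS[idx]) / sum(heat$dS[idx]^2) * heat$dS[idx]
  orth <- new_difference_curve(q, y)
  out <- subtract_heat(orth, heat)
  expect_equal(attr(out, "heat_coef"), 0, tolerance = 1e-12)
  expect_equal(out$dS, orth$dS)

  zero_heat <- new_difference_curve(q, ifelse(q < 0.9, 1, 0))
  expect_error(subtract_heat(pure, zero_heat), "zero")
})

test_that("a structural signal survives heat subtraction within 2% of its peak", {
  ens <- small_ensembles(seed = 3, n = 1, jitter_deg = 0, bead_jitter_nm = 0)
  q <- default_qgrid()
  struct <- difference_curve(
    debye_scattering(ens$pfr$model[[1]], q),
    debye_scattering(ens$pr$model[[1]], q)
  )
  heat_shape <- exp(-(q - 1.9)^2 / 0.3) * max(abs(struct$dS))
  heat <- new_difference_curve(q, heat_shape)
  contaminated <- new_difference_curve(q, struct$dS + 1.5 * heat$dS)
  recovered <- subtract_heat(contaminated, heat)
  # the heat coefficient absorbs 1.5 plus the structural projection; what
  # matters is that the recovered curve matches the structural signal
  expect_lt(
    max(abs(recovered$dS - struct$dS)) / max(abs(struct$dS)),
    0.02
  )
})

test_that("ring integration of a uniform image is flat at the uniform value", {
  img <- detector_image(
    matrix(7, 64, 64),
    center_px = c(32.5, 32.5), pixel_mm = 0.75,
    distance_mm = 300, wavelength_nm = 0.1
  )
  cv <- integrate_rings(img, n_bins = 20)
  expect_true(all(abs(cv$I - 7) < 1e-12))
  expect_false(is.unsorted(cv$q))
})

test_that("ring integration inverts the forward-painted image", {
  q <- seq(0.05, 6, by = 0.05)
  truth <- scattering_curve(q, 100 * exp(-q / 2) + 5)
  img <- make_detector_image(truth,
    shape = c(128, 128), pixel_mm = 0.9,
    distance_mm = 250, wavelength_nm = 0.1, noise = "none"
  )
  cv <- integrate_rings(img, n_bins = 60)
  ref <- approx(truth$q, truth$I, xout = cv$q, rule = 2)$y
  expect_lt(max(abs(cv$I - ref) / ref), 0.02) # within binning tolerance
})

test_that("detector images validate geometry and masking", {
  expect_error(
    detector_image(matrix(-1, 4, 4), c(2, 2), 1, 100, 0.1),
    ">= 0"
  )
  expect_error(
    detector_image(matrix(1, 4, 4), c(2, 2), -1, 100, 0.1),
    "positive"
  )
  img <- detector_image(matrix(1, 8, 8), c(20, 20), 1, 100, 0.1)
  expect_error(integrate_rings(img), "outside")
  masked <- detector_image(
    matrix(1, 8, 8), c(4, 4), 1, 100, 0.1,
    mask = matrix(TRUE, 8, 8)
  )
  expect_error(integrate_rings(masked), "fully masked")
})

test_that("synthetic detector images are seed-deterministic", {
  q <- seq(0.1, 5, by = 0.1)
  cv <- scattering_curve(q, 50 * exp(-q) + 2)
  a <- make_detector_image(cv, shape = c(32, 32), noise = "poisson", seed = 42)
  b <- make_detector_image(cv, shape = c(32, 32), noise = "poisson", seed = 42)
  c <- make_detector_image(cv, shape = c(32, 32), noise = "poisson", seed = 43)
  expect_identical(a$intensity, b$intensity)
  expect_false(identical(a$intensity, c$intensity))
})
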