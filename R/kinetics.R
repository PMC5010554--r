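#' Time series of difference curves
#'
#' A time series is a long tibble with columns `time` (seconds), `q` (nm^-1)
#' and `dS`, every time point sampled on one common q grid.
#' `time_series_set()` validates that shape; `series_times()` and
#' `series_grid()` extract the sorted time stamps and the shared grid;
#' `series_matrix()` returns the curves as an n_q x n_t matrix.
#'
#' @param data A data frame with columns `time`, `q`, `dS`.
#' @param series A validated time-series tibble.
#' @return `time_series_set()`: the validated tibble.
#' @export
time_series_set <- function(data) {
  data <- as_tibble(data)
  need <- c("time", "q", "dS")
  if (!all(need %in% names(data))) abort("need columns time, q, dS.")
  times <- sort(unique(data$time))
  if (length(times) < 2) abort("a time series needs at least 2 time points.")
  grids <- split(data$q, data$time)
  g0 <- sort(grids[[1]])
  check_qgrid(g0)
  same <- vapply(grids, function(g) {
    length(g) == length(g0) && isTRUE(all.equal(sort(g), g0, tolerance = 1e-12))
  }, logical(1))
  if (!all(same)) abort("all time points must share one common q grid.")
  dplyr::arrange(data, .data$time, .data$q)
}

#' @rdname time_series_set
#' @export
series_times <- function(series) sort(unique(series$time))

#' @rdname time_series_set
#' @export
series_grid <- function(series) sort(unique(series$q))

#' @rdname time_series_set
#' @export
series_matrix <- function(series) {
  series <- dplyr::arrange(series, .data$time, .data$q)
  times <- series_times(series)
  q <- series_grid(series)
  matrix(series$dS, nrow = length(q), ncol = length(times),
    dimnames = list(NULL, signif(times, 8))
  )
}

#' Extract early and late basis patterns from a time series
#'
#' The two-component description of the photocycle uses two fixed difference
#' patterns: an *early* pattern, the curve measured at (the sampled time
#' nearest to) `early_time`, and a *late* pattern, the pointwise mean of all
#' curves inside `late_window`. Defaults mirror a typical choice for a
#' microsecond-to-second series: the 3 microsecond curve and the steady state
#' averaged over 0.1-2 s.
#'
#' @param series A [time_series_set()] tibble.
#' @param early_time Target time (s) of the early pattern.
#' @param late_window Length-2 numeric window (s) averaged for the late
#'   pattern; must contain at least one sampled time.
#' @return A `basis_set`: list with difference curves `early` and `late` and
#'   the times they came from.
#' @export
extract_basis <- function(series, early_time = 3e-6, late_window = c(0.1, 2)) {
  M <- series_matrix(series)
  times <- series_times(series)
  q <- series_grid(series)
  i_early <- which.min(abs(times - early_time))
  in_late <- times >= late_window[1] & times <= late_window[2]
  if (!any(in_late)) abort("`late_window` contains no sampled time point.")
  late <- rowMeans(M[, in_late, drop = FALSE])
  structure(
    list(
      early = new_difference_curve(q, M[, i_early], time_s = times[i_early]),
      late = new_difference_curve(q, late),
      early_time = times[i_early],
      late_times = times[in_late]
    ),
    class = "basis_set"
  )
}

#' Decompose a time series onto two basis patterns
#'
#' Fits every time point's difference curve as a linear combination
#' `dS(q, t) = a_early(t) early(q) + a_late(t) late(q)` by ordinary least
#' squares over the q grid (the matrix-division view of the data matrix).
#' Amplitude pairs and the per-time residual 2-norm are returned; the basis
#' must be well-conditioned on the grid.
#'
#' @param series A [time_series_set()] tibble.
#' @param basis A `basis_set` from [extract_basis()], on the series grid.
#' @param max_condition Condition-number threshold above which the basis is
#'   treated as rank-deficient.
#' @return A tibble with columns `time`, `amp_early`, `amp_late`,
#'   `resid_norm`.
#' @export
decompose_series <- function(series, basis, max_condition = 1e8) {
  M <- series_matrix(series)
  q <- series_grid(series)
  check_same_grid(basis$early, basis$late)
  if (nrow(basis$early) != length(q) ||
    !isTRUE(all.equal(basis$early$q, q, tolerance = 1e-12))) {
    abort("basis patterns are not on the series q grid.")
  }
  B <- cbind(early = basis$early$dS, late = basis$late$dS)
  sv <- svd(B, nu = 0, nv = 0)$d
  cond <- if (min(sv) == 0) Inf else max(sv) / min(sv)
  if (!is.finite(cond) || cond > max_condition) {
    abort(paste0(
      "basis patterns are (near-)linearly dependent: condition number ",
      format(cond, digits = 3), " exceeds ", format(max_condition), "."
    ))
  }
  qrB <- qr(B)
  amps <- qr.coef(qrB, M) # 2 x n_t
  resid <- M - B %*% amps
  tibble(
    time = series_times(series),
    amp_early = unname(amps[1, ]),
    amp_late = unname(amps[2, ]),
    resid_norm = unname(sqrt(colSums(resid^2)))
  )
}

#' Fit an exponential half-time to an amplitude trace
#'
#' Fits either an exponential rise `A (1 - 2^(-t / t_half))` or a decay
#' `A 2^(-t / t_half)` to an amplitude-versus-time trace by nonlinear least
#' squares. Because the photocycle literature reports half-times, the model
#' is parameterised directly in `t_half` (the time to reach half the
#' asymptotic amplitude) rather than a rate constant. For a fixed `t_half`
#' the amplitude is linear, so initialisation profiles a log-spaced `t_half`
#' grid spanning the sampled time range, solves `A` in closed form at each
#' node, and refines the best node with Levenberg-Marquardt.
#'
#' @param trace A data frame with a time column (`time`, seconds) and an
#'   amplitude column (`amplitude`, or named via `amplitude_col`).
#' @param model `"rise"` or `"decay"`.
#' @param amplitude_col Name of the amplitude column (default: `"amplitude"`,
#'   falling back to the only non-time column).
#' @param n_grid Number of initialisation nodes.
#' @return An object of class `halftime_fit`: list with `t_half` (s),
#'   `amplitude`, standard errors, the model label, fitted values and the
#'   underlying `nls` object. Supports `tidy()`, `glance()`, `print()` and
#'   [ggplot2::autoplot()].
#' @examples
#' t <- 10^seq(-4, 0, length.out = 20)
#' tr <- tibble::tibble(time = t, amplitude = 2 * (1 - 2^(-t / 0.01)))
#' fit <- fit_halftime(tr, "rise")
#' fit$t_half
#' @export
fit_halftime <- function(trace, model = c("rise", "decay"),
                         amplitude_col = NULL, n_grid = 40) {
  model <- match.arg(model)
  if (!"time" %in% names(trace)) abort("`trace` needs a `time` column (seconds).")
  if (is.null(amplitude_col)) {
    amplitude_col <- if ("amplitude" %in% names(trace)) {
      "amplitude"
    } else {
      cand <- setdiff(names(trace), "time")
      if (length(cand) != 1) abort("ambiguous amplitude column; set `amplitude_col`.")
      cand
    }
  }
  t <- as.numeric(trace$time)
  y <- as.numeric(trace[[amplitude_col]])
  if (length(t) < 4) abort("need at least 4 time points to fit a half-time.")
  if (any(t <= 0)) abort("time points must be > 0.")
  if (sd(y) == 0) abort("trace constant: no kinetics to fit.")

  shape <- switch(model,
    rise = function(th) 1 - 2^(-t / th),
    decay = function(th) 2^(-t / th)
  )
  # profile a log-spaced grid of half-times; A is linear given t_half
  grid <- 10^seq(log10(min(t)), log10(max(t)), length.out = n_grid)
  prof <- vapply(grid, function(th) {
    g <- shape(th)
    gg <- sum(g^2)
    if (gg == 0) {
      return(c(NA_real_, Inf))
    }
    A <- sum(y * g) / gg
    c(A, sum((y - A * g)^2))
  }, numeric(2))
  best <- which.min(prof[2, ])
  A0 <- prof[1, best]
  th0 <- grid[best]
  if (!is.finite(A0)) {
    abort("half-time initialisation failed: degenerate model on the time grid.")
  }
  df <- data.frame(t = t, y = y)
  form <- switch(model,
    rise = y ~ A * (1 - 2^(-t / th)),
    decay = y ~ A * 2^(-t / th)
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(form,
      data = df, start = list(A = A0, th = th0),
      lower = c(-Inf, min(t) * 1e-3), upper = c(Inf, max(t) * 1e3),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      abort(paste0(
        "half-time fit did not converge (best grid node: t_half = ",
        signif(th0, 4), " s, sse = ", signif(prof[2, best], 4), "): ",
        conditionMessage(e)
      ))
    }
  )
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA_real_, NA_real_))
  structure(
    list(
      model = model,
      t_half = unname(est["th"]),
      amplitude = unname(est["A"]),
      t_half_se = unname(se[2]),
      amplitude_se = unname(se[1]),
      trace = tibble(time = t, amplitude = y, fitted = stats::fitted(fit)),
      rss = sum(stats::resid(fit)^2),
      fit = fit
    ),
    class = "halftime_fit"
  )
}

#' @export
print.halftime_fit <- function(x, ...) {
  cat("<halftime_fit> model:", x$model, "\n")
  cat(
    "  t_half    =", format(x$t_half, digits = 4), "s  (se",
    format(x$t_half_se, digits = 3), ")\n"
  )
  cat(
    "  amplitude =", format(x$amplitude, digits = 4), "  (se",
    format(x$amplitude_se, digits = 3), ")\n"
  )
  invisible(x)
}

#' @export
tidy.halftime_fit <- function(x, ...) {
  tibble(
    term = c("t_half", "amplitude"),
    estimate = c(x$t_half, x$amplitude),
    std.error = c(x$t_half_se, x$amplitude_se)
  )
}

#' @export
glance.halftime_fit <- function(x, ...) {
  tibble(
    model = x$model, t_half = x$t_half, amplitude = x$amplitude,
    rss = x$rss, nobs = nrow(x$trace)
  )
}

#' Diagnostic singular-value report for a time series
#'
#' Singular values of the time-series data matrix, as a quick check on how
#' many kinetic components the data support. Purely diagnostic; the analysis
#' itself always uses the two supplied basis patterns.
#'
#' @param series A [time_series_set()] tibble.
#' @param k Number of leading singular values to report.
#' @return A tibble with columns `component`, `singular_value`,
#'   `variance_fraction`.
#' @export
rank_report <- function(series, k = 5) {
  M <- series_matrix(series)
  d <- svd(M, nu = 0, nv = 0)$d
  k <- min(k, length(d))
  tibble(
    component = seq_len(k),
    singular_value = d[seq_len(k)],
    variance_fraction = (d^2 / sum(d^2))[seq_len(k)]
  )
}
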