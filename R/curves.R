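#' Scattering and difference curves
#'
#' Curves are plain tibbles so they compose with dplyr/ggplot2. A scattering
#' curve has columns `q` (scattering-vector modulus, nm^-1) and `I`
#' (intensity, arbitrary units); a difference curve has `q` and `dS` (signed
#' difference intensity). Both may carry an optional `sigma` column of
#' per-point uncertainties. `scattering_curve()` and `new_difference_curve()`
#' validate and construct them.
#'
#' @param q Numeric vector of scattering-vector moduli in nm^-1; must be
#'   strictly increasing and non-negative.
#' @param I,dS Numeric intensity / signed difference values, same length as
#'   `q`.
#' @param sigma Optional per-point uncertainties (>= 0), same length as `q`.
#' @param time_s Optional time stamp in seconds (difference curves only),
#'   stored as the `time_s` attribute.
#'
#' @return A tibble with columns `q`, `I` (or `dS`) and optionally `sigma`.
#' @examples
#' scattering_curve(q = c(0.5, 1, 1.5), I = c(9, 4, 1))
#' @export
scattering_curve <- function(q, I, sigma = NULL) {
  check_qgrid(q)
  if (length(I) != length(q)) abort("`I` and `q` must have the same length.")
  if (!all(is.finite(I))) abort("intensities must be finite.")
  out <- tibble(q = as.numeric(q), I = as.numeric(I))
  if (!is.null(sigma)) {
    if (length(sigma) != length(q)) abort("`sigma` and `q` must have the same length.")
    if (any(sigma < 0)) abort("`sigma` must be >= 0.")
    out$sigma <- as.numeric(sigma)
  }
  out
}

#' @rdname scattering_curve
#' @export
new_difference_curve <- function(q, dS, sigma = NULL, time_s = NULL) {
  check_qgrid(q)
  if (length(dS) != length(q)) abort("`dS` and `q` must have the same length.")
  if (!all(is.finite(dS))) abort("difference values must be finite.")
  out <- tibble(q = as.numeric(q), dS = as.numeric(dS))
  if (!is.null(sigma)) {
    if (length(sigma) != length(q)) abort("`sigma` and `q` must have the same length.")
    if (any(sigma < 0)) abort("`sigma` must be >= 0.")
    out$sigma <- as.numeric(sigma)
  }
  if (!is.null(time_s)) attr(out, "time_s") <- as.numeric(time_s)
  out
}

# q grid invariants: numeric, finite, non-negative, strictly increasing
check_qgrid <- function(q) {
  if (!is.numeric(q) || length(q) < 1) abort("`q` must be a non-empty numeric vector.")
  if (!all(is.finite(q))) abort("`q` must be finite.")
  if (any(q < 0)) abort("`q` must be non-negative.")
  if (length(q) > 1 && any(diff(q) <= 0)) abort("`q` must be strictly increasing.")
  invisible(q)
}

# shared-grid check used by every pointwise operation; no silent interpolation
check_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) || !isTRUE(all.equal(a$q, b$q, tolerance = 1e-12))) {
    abort("curves are not on the same q grid (interpolate explicitly first).")
  }
  invisible(TRUE)
}

#' Subtract two scattering curves into a difference curve
#'
#' Computes the pointwise difference `dS(q) = I_pfr(q) - I_pr(q)` between the
#' photoactivated-state and resting-state curves. Both curves must share an
#' identical q grid; no interpolation is performed.
#'
#' @param s_pfr,s_pr Scattering curves (tibbles with `q`, `I`) on a common
#'   grid.
#' @return A difference-curve tibble with columns `q` and `dS`.
#' @examples
#' a <- scattering_curve(1:3, c(4, 2, 1))
#' b <- scattering_curve(1:3, c(3, 2, 2))
#' difference_curve(a, b)
#' @export
difference_curve <- function(s_pfr, s_pr) {
  check_same_grid(s_pfr, s_pr)
  new_difference_curve(s_pfr$q, s_pfr$I - s_pr$I)
}

#' Read and write curve files
#'
#' Curves travel as whitespace- or comma-delimited text with columns
#' `q, value[, sigma]`; lines starting with `#` are comments and a single
#' non-numeric header line is tolerated. `read_curve()` returns a scattering
#' curve (`value` column named `I`) or a difference curve (`dS`) depending on
#' `type`.
#'
#' @param path File path.
#' @param type `"scattering"` or `"difference"`: names the value column.
#' @param curve A curve tibble to write.
#' @return `read_curve()`: a curve tibble. `write_curve()`: `path`,
#'   invisibly.
#' @export
read_curve <- function(path, type = c("scattering", "difference")) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("no data lines in ", path))
  parse_one <- function(x) {
    fields <- strsplit(trimws(x), "[,[:space:]]+")[[1]]
    suppressWarnings(as.numeric(fields))
  }
  first <- parse_one(lines[1])
  if (anyNA(first)) lines <- lines[-1] # header line
  rows <- lapply(lines, parse_one)
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1 || !(ncols %in% c(2L, 3L))) {
    abort(paste0("expected 2 or 3 numeric columns in ", path))
  }
  m <- do.call(rbind, rows)
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))[1]
    abort(paste0("non-numeric data at data line ", bad, " of ", path))
  }
  sig <- if (ncols == 3L) m[, 3] else NULL
  if (type == "scattering") {
    scattering_curve(m[, 1], m[, 2], sigma = sig)
  } else {
    new_difference_curve(m[, 1], m[, 2], sigma = sig)
  }
}

#' @rdname read_curve
#' @export
write_curve <- function(curve, path) {
  val <- if ("I" %in% names(curve)) curve$I else curve$dS
  cols <- cbind(curve$q, val)
  if ("sigma" %in% names(curve)) cols <- cbind(cols, curve$sigma)
  header <- if ("I" %in% names(curve)) "# q I" else "# q dS"
  if (ncol(cols) == 3) header <- paste(header, "sigma")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(format(cols, digits = 10, scientific = TRUE, trim = TRUE),
    con,
    quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

# indices of grid points inside [qmin, qmax] (inclusive endpoints)
window_idx <- function(q, qmin, qmax) {
  if (qmin > qmax) abort("`qmin` must be <= `qmax`.")
  which(q >= qmin & q <= qmax)
}
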