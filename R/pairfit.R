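#' Scale-optimised least-squares score for one difference-curve pair
#'
#' Scores a calculated difference curve `D(q)` against an experimental one by
#' minimising \deqn{SSE = \min_k \sum_q (\Delta S(q) - k D(q))^2} over the
#' scale factor `k`, restricted to grid points inside the scoring window
#' (endpoints inclusive). The minimiser is the closed-form projection
#' `k = sum(dS * D) / sum(D^2)`; when `D` vanishes identically on the window
#' the convention `k = 0`, `SSE = sum(dS^2)` applies. `k` is unconstrained in
#' sign and no per-point sigma weighting is used unless `weighted = TRUE`.
#'
#' @param delta_exp Experimental difference curve (tibble `q`, `dS`).
#' @param delta_calc Calculated difference curve on the same grid.
#' @param qmin,qmax Scoring window in nm^-1, endpoints inclusive; defaults to
#'   the 0.5-2.5 nm^-1 window where large-scale domain motion dominates.
#' @param weighted If `TRUE` and `delta_exp` carries a `sigma` column, points
#'   are weighted by `1/sigma^2`.
#' @return A list with elements `k` and `sse`.
#' @examples
#' q <- seq(0.5, 2.5, by = 0.1)
#' d <- new_difference_curve(q, sin(q))
#' e <- new_difference_curve(q, 2 * sin(q))
#' optimal_scale(e, d) # k = 2, sse = 0
#' @export
optimal_scale <- function(delta_exp, delta_calc, qmin = 0.5, qmax = 2.5,
                          weighted = FALSE) {
  check_same_grid(delta_exp, delta_calc)
  idx <- window_idx(delta_exp$q, qmin, qmax)
  if (length(idx) < 2) abort("the scoring window must contain at least 2 grid points.")
  y <- delta_exp$dS[idx]
  d <- delta_calc$dS[idx]
  w <- rep(1, length(idx))
  if (weighted) {
    if (!"sigma" %in% names(delta_exp)) abort("`weighted = TRUE` needs a `sigma` column.")
    if (any(delta_exp$sigma[idx] <= 0)) abort("weighted scoring needs sigma > 0.")
    w <- 1 / delta_exp$sigma[idx]^2
  }
  dd <- sum(w * d * d)
  if (dd == 0) {
    return(list(k = 0, sse = sum(w * y * y)))
  }
  k <- sum(w * y * d) / dd
  list(k = k, sse = sum(w * (y - k * d)^2))
}

#' Exhaustive all-pairs scoring of two conformer ensembles
#'
#' Scores every (resting, activated) conformer pair against an experimental
#' difference curve: for each pair the calculated difference
#' `D = I_pfr - I_pr` is scale-optimised against `delta_exp` (see
#' [optimal_scale()]) inside the scoring window, and all |Pr| x |Pfr| scores
#' are returned ranked by ascending residual. Ties are broken by (pr, pfr)
#' index order so the ranking is deterministic.
#'
#' Member curves are taken from the ensembles' `curve` list-column if present
#' (see [ensemble_curves()]) and computed with [debye_scattering()] otherwise.
#' The whole scan is vectorised through the cross-product matrix of the
#' member curves, so large scans stay cheap once curves are pre-computed.
#'
#' @param pr_ensemble,pfr_ensemble Ensemble tibbles (`id`, `state`, `model`,
#'   optional `curve`).
#' @param delta_exp Experimental difference curve defining the grid.
#' @param qmin,qmax Scoring window (nm^-1), endpoints inclusive.
#' @param max_pairs Optional cap: scan a deterministic subsample of at most
#'   this many pairs (for quick demonstrations).
#' @return A tibble with one row per pair: `pr`, `pfr` (indices), `pr_id`,
#'   `pfr_id`, `k`, `sse`, `rank`, sorted ascending by `sse`.
#' @export
pairwise_scan <- function(pr_ensemble, pfr_ensemble, delta_exp,
                          qmin = 0.5, qmax = 2.5, max_pairs = NULL) {
  q <- delta_exp$q
  idx <- window_idx(q, qmin, qmax)
  if (length(idx) < 2) abort("the scoring window must contain at least 2 grid points.")
  Cpr <- ensemble_curve_matrix(pr_ensemble, q)
  Cpfr <- ensemble_curve_matrix(pfr_ensemble, q)
  y <- delta_exp$dS[idx]
  A <- Cpr[idx, , drop = FALSE] # n_w x n_pr
  B <- Cpfr[idx, , drop = FALSE] # n_w x n_pfr
  n_pr <- ncol(A)
  n_pfr <- ncol(B)

  # For D = B_j - A_i:  y.D  = (y.B)_j - (y.A)_i
  #                     D.D  = |B_j|^2 + |A_i|^2 - 2 (A'B)_ij
  yA <- drop(crossprod(y, A))
  yB <- drop(crossprod(y, B))
  AA <- colSums(A^2)
  BB <- colSums(B^2)
  AB <- crossprod(A, B) # n_pr x n_pfr
  yD <- matrix(yB, n_pr, n_pfr, byrow = TRUE) - matrix(yA, n_pr, n_pfr)
  DD <- matrix(BB, n_pr, n_pfr, byrow = TRUE) + matrix(AA, n_pr, n_pfr) - 2 * AB
  DD[DD < 0] <- 0 # guard rounding
  yy <- sum(y^2)
  k <- ifelse(DD > 0, yD / DD, 0)
  sse <- pmax(yy - k * yD, 0)

  # the identity sse = |y|^2 - k (y.D) cancels catastrophically for
  # near-perfect fits; recompute those few residuals directly
  refit <- which(sse < 1e-6 * yy)
  for (idx2 in refit) {
    i <- (idx2 - 1L) %% n_pr + 1L
    j <- (idx2 - 1L) %/% n_pr + 1L
    r <- y - k[idx2] * (B[, j] - A[, i])
    sse[idx2] <- sum(r^2)
  }

  scores <- tibble(
    pr = rep(seq_len(n_pr), times = n_pfr),
    pfr = rep(seq_len(n_pfr), each = n_pr),
    pr_id = pr_ensemble$id[rep(seq_len(n_pr), times = n_pfr)],
    pfr_id = pfr_ensemble$id[rep(seq_len(n_pfr), each = n_pr)],
    k = as.numeric(k),
    sse = as.numeric(sse)
  )
  if (!is.null(max_pairs) && nrow(scores) > max_pairs) {
    keep <- round(seq(1, nrow(scores), length.out = max_pairs))
    scores <- scores[keep, , drop = FALSE]
  }
  scores <- scores[order(scores$sse, scores$pr, scores$pfr), , drop = FALSE]
  scores$rank <- seq_len(nrow(scores))
  scores
}

# member curves as an n_q x n_members matrix on the target grid
ensemble_curve_matrix <- function(ensemble, q) {
  if (nrow(ensemble) == 0) abort("ensembles must be non-empty.")
  if ("curve" %in% names(ensemble)) {
    mats <- lapply(ensemble$curve, function(cv) {
      if (nrow(cv) != length(q) || !isTRUE(all.equal(cv$q, q, tolerance = 1e-12))) {
        abort("pre-computed ensemble curves are not on the experimental q grid.")
      }
      cv$I
    })
  } else {
    mats <- lapply(ensemble$model, function(m) debye_scattering(m, q)$I)
  }
  do.call(cbind, mats)
}

#' Keep the best fraction (or count) of ranked pair scores
#'
#' Truncates a score table sorted ascending by `sse` to its best
#' `ceiling(fraction * n)` rows, or to an absolute count `n_best`. A request
#' for more rows than exist is clamped to the full table with a warning.
#'
#' @param scores Score tibble from [pairwise_scan()] (ascending `sse`).
#' @param fraction Fraction in (0, 1] of rows to keep.
#' @param n_best Absolute number of rows to keep (overrides `fraction`).
#' @return The truncated score tibble.
#' @export
top_fraction <- function(scores, fraction = 0.1, n_best = NULL) {
  if (is.unsorted(scores$sse)) abort("`scores` must be sorted ascending by sse.")
  n <- nrow(scores)
  if (!is.null(n_best)) {
    if (n_best < 1) abort("`n_best` must be >= 1.")
    if (n_best > n) {
      warn(paste0("requested ", n_best, " pairs but only ", n, " available; returning all."))
      n_best <- n
    }
    return(scores[seq_len(n_best), , drop = FALSE])
  }
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("`fraction` must lie in (0, 1].")
  }
  scores[seq_len(ceiling(fraction * n)), , drop = FALSE]
}
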