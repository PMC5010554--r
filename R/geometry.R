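#' Marker-residue selectors for the bend and twist coordinates
#'
#' Two scalar coordinates summarise the reorientation of the output (PHY)
#' domain relative to the chromophore-binding (PAS-GAF) core:
#'
#' * the **bend** angle at a hinge: the interior angle defined by three
#'   marker residues (helix start, hinge point, output-domain centre);
#' * the **twist** (dihedral) angle between a reference plane (p1, p2, p3)
#'   and a variable plane (p2, p3, p4), i.e. the torsion about the p2-p3
#'   axis.
#'
#' Defaults follow the marker residues used for the phytochrome photosensory
#' core: bend 300-317-439 and dihedral 288-300-317-439 on chain A, measured
#' at the C-alpha (bead) position of each residue.
#'
#' @param bend Integer vector of three residue numbers (p1, p2, p3).
#' @param dihedral Integer vector of four residue numbers (p1, p2, p3, p4).
#' @param chain Chain identifier the selectors resolve in.
#' @param atom Atom name resolved per residue (default `"CA"`).
#' @return An object of class `angle_spec`.
#' @export
angle_spec <- function(bend = c(300, 317, 439),
                       dihedral = c(288, 300, 317, 439),
                       chain = "A", atom = "CA") {
  if (length(bend) != 3 || anyDuplicated(bend)) {
    abort("`bend` must be three distinct residue numbers.")
  }
  if (length(dihedral) != 4 || anyDuplicated(dihedral)) {
    abort("`dihedral` must be four distinct residue numbers.")
  }
  structure(
    list(
      bend = as.integer(bend), dihedral = as.integer(dihedral),
      chain = chain, atom = atom
    ),
    class = "angle_spec"
  )
}

# resolve one (chain, resno, atom) selector to a single position (nm)
resolve_selector <- function(model, spec, resno) {
  hit <- model$chain == spec$chain & model$resno == resno &
    trimws(model$elety) == spec$atom
  n <- sum(hit)
  if (n != 1) {
    abort(paste0(
      "selector ", spec$chain, "/", resno, "/", spec$atom, " resolves to ",
      n, " atoms in model '", attr(model, "model_id") %||% "?", "' (need exactly 1)."
    ))
  }
  as.numeric(model[hit, c("x", "y", "z")])
}

#' Bend and dihedral angles of a structure model
#'
#' `bend_angle()` returns the interior angle (degrees, in \[0, 180\]) at the
#' middle marker of the bend triplet, from the arc-cosine of the normalised
#' dot product (clamped to \[-1, 1\] against rounding). `plane_dihedral()`
#' returns the signed torsion (degrees, in (-180, 180\]) about the p2-p3 axis
#' of the dihedral quadruplet, with the IUPAC sign convention.
#'
#' @param model A [structure_model()].
#' @param spec An [angle_spec()].
#' @return Angle in degrees.
#' @export
bend_angle <- function(model, spec = angle_spec()) {
  p <- lapply(spec$bend, function(r) resolve_selector(model, spec, r))
  v1 <- p[[1]] - p[[2]]
  v2 <- p[[3]] - p[[2]]
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) abort("coincident marker points: bend angle undefined.")
  cth <- sum(v1 * v2) / (n1 * n2)
  acos(min(1, max(-1, cth))) * 180 / pi
}

#' @rdname bend_angle
#' @export
plane_dihedral <- function(model, spec = angle_spec()) {
  p <- lapply(spec$dihedral, function(r) resolve_selector(model, spec, r))
  torsion_deg(p[[1]], p[[2]], p[[3]], p[[4]])
}

# signed torsion from plane normals; sign from the shared p2->p3 edge
torsion_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2) # normal of the reference plane (p1, p2, p3)
  n2 <- cross3(b2, b3) # normal of the variable plane (p2, p3, p4)
  if (sum(n1^2) == 0 || sum(n2^2) == 0) {
    abort("collinear marker triple: dihedral plane undefined.")
  }
  cth <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(min(1, max(-1, cth))) * 180 / pi
  s <- sum(n1 * b3) # side of the reference plane p4 falls on
  if (s < 0) ang <- -ang
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# wrap an angle difference to (-180, 180]
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Bend/twist changes for every scored conformer pair
#'
#' Annotates each pair from a [pairwise_scan()] score table with the change
#' in bend and dihedral angle between its activated (pfr) and resting (pr)
#' member, `delta = pfr - pr`, the dihedral difference wrapped to
#' (-180, 180].
#'
#' @param scores Score tibble (columns `pr`, `pfr`, `sse`).
#' @param pr_ensemble,pfr_ensemble Ensemble tibbles the indices refer to.
#' @param spec An [angle_spec()].
#' @return The score tibble with added columns `d_bend`, `d_dihedral`
#'   (degrees).
#' @export
pair_angle_table <- function(scores, pr_ensemble, pfr_ensemble, spec = angle_spec()) {
  ang <- function(ens) {
    b <- vapply(ens$model, bend_angle, numeric(1), spec = spec)
    d <- vapply(ens$model, plane_dihedral, numeric(1), spec = spec)
    list(bend = b, dihedral = d)
  }
  a_pr <- ang(pr_ensemble)
  a_pfr <- ang(pfr_ensemble)
  scores$d_bend <- a_pfr$bend[scores$pfr] - a_pr$bend[scores$pr]
  scores$d_dihedral <- wrap_angle(a_pfr$dihedral[scores$pfr] - a_pr$dihedral[scores$pr])
  scores
}

#' Residual landscape over bend/twist changes
#'
#' Bins scored pairs on a 2D grid of (bend change, dihedral change) and
#' summarises each occupied bin by the mean residual of its lowest-`fraction`
#' members (default: best 10%). Low-lying regions of this landscape are the
#' structural changes best supported by the difference-scattering data.
#'
#' Bins are left-closed, right-open (\[lo, hi)); the last bin includes its
#' upper edge. `landscape_edges()` builds an edge vector of a given width
#' covering a value range.
#'
#' @param table Pair table from [pair_angle_table()] (columns `d_bend`,
#'   `d_dihedral`, `sse`).
#' @param bend_edges,dihedral_edges Strictly increasing bin-edge vectors
#'   (degrees). Default: 2 degree bins spanning the data.
#' @param fraction Fraction in (0, 1] of lowest-sse pairs averaged per bin.
#' @return A tibble of class `saxs_landscape`: one row per bin with bin
#'   centres `bend`, `dihedral`, the best-fraction mean residual `stat`
#'   (`NA` for empty bins) and member count `n`.
#' @seealso [landscape_minimum()]
#' @export
build_landscape <- function(table, bend_edges = NULL, dihedral_edges = NULL,
                            fraction = 0.10) {
  if (!all(c("d_bend", "d_dihedral", "sse") %in% names(table))) {
    abort("`table` needs columns d_bend, d_dihedral, sse (see pair_angle_table()).")
  }
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("`fraction` must lie in (0, 1].")
  }
  bend_edges <- bend_edges %||% landscape_edges(table$d_bend, 2)
  dihedral_edges <- dihedral_edges %||% landscape_edges(table$d_dihedral, 2)
  for (e in list(bend_edges, dihedral_edges)) {
    if (length(e) < 2 || any(diff(e) <= 0)) abort("bin edges must be strictly increasing.")
  }
  bi <- bin_index(table$d_bend, bend_edges)
  di <- bin_index(table$d_dihedral, dihedral_edges)
  inside <- !is.na(bi) & !is.na(di)
  if (!any(inside)) abort("all bins empty: no pair falls inside the bin edges.")
  nb <- length(bend_edges) - 1L
  nd <- length(dihedral_edges) - 1L
  cell <- (di[inside] - 1L) * nb + bi[inside]
  sse_by_cell <- split(table$sse[inside], cell)
  stat <- rep(NA_real_, nb * nd)
  count <- rep(0L, nb * nd)
  for (nm in names(sse_by_cell)) {
    v <- sort(sse_by_cell[[nm]])
    kcell <- as.integer(nm)
    count[kcell] <- length(v)
    stat[kcell] <- mean(v[seq_len(ceiling(fraction * length(v)))])
  }
  centres_b <- (bend_edges[-1] + bend_edges[-length(bend_edges)]) / 2
  centres_d <- (dihedral_edges[-1] + dihedral_edges[-length(dihedral_edges)]) / 2
  out <- tibble(
    bend = rep(centres_b, times = nd),
    dihedral = rep(centres_d, each = nb),
    stat = stat,
    n = count
  )
  attr(out, "bend_edges") <- bend_edges
  attr(out, "dihedral_edges") <- dihedral_edges
  attr(out, "fraction") <- fraction
  class(out) <- c("saxs_landscape", class(out))
  out
}

# left-closed bins; values on the final upper edge fall in the last bin
bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[i < 1 | i > length(edges) - 1] <- NA_integer_
  i
}

#' @rdname build_landscape
#' @param x Numeric values the edges must cover.
#' @param width Bin width in degrees.
#' @export
landscape_edges <- function(x, width = 2) {
  if (width <= 0) abort("`width` must be > 0.")
  lo <- floor(min(x) / width) * width
  hi <- ceiling(max(x) / width) * width
  if (hi <= lo) hi <- lo + width
  seq(lo, hi, by = width)
}

#' Locate the minimum of a residual landscape
#'
#' @param landscape A `saxs_landscape` from [build_landscape()].
#' @return A one-row tibble: bin centres `bend`, `dihedral`, the bin
#'   statistic `stat` and count `n` of the occupied bin with the smallest
#'   best-fraction mean residual.
#' @export
landscape_minimum <- function(landscape) {
  occ <- which(!is.na(landscape$stat))
  if (length(occ) == 0) abort("landscape has no occupied bins.")
  best <- occ[which.min(landscape$stat[occ])]
  out <- landscape[best, c("bend", "dihedral", "stat", "n")]
  as_tibble(out)
}
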