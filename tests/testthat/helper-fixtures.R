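# Shared fixtures and independent oracles.

# a minimal one-residue glycine PDB (N, CA, C), written on demand
write_gly_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  N   GLY A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       2.000   2.500   3.100  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       3.100   2.200   3.300  1.00  0.00           C",
    "END"
  ), path)
  path
}

write_two_chain_pdb <- function(path = tempfile(fileext = ".pdb")) {
  fmt <- function(serial, elety, resid, chain, resno, x, y, z, ele) {
    sprintf(
      "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      serial, elety, resid, chain, resno, x, y, z, ele
    )
  }
  lines <- c(
    fmt(1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
    fmt(2, "CA", "ALA", "A", 2, 3.8, 0, 0, "C"),
    fmt(3, "CA", "SER", "A", 5, 7.6, 0, 0, "C"),
    fmt(4, "CA", "GLY", "B", 1, 0, 5, 0, "C"),
    fmt(5, "CA", "LYS", "B", 3, 3.8, 5, 0, "C"),
    "END"
  )
  writeLines(lines, path)
  path
}

# random bead model on unit-ish scale
random_model <- function(n, seed = 1, f = NULL) {
  set.seed(seed)
  structure_model(
    tibble::tibble(
      resno = seq_len(n),
      x = stats::runif(n, -2, 2), y = stats::runif(n, -2, 2),
      z = stats::runif(n, -2, 2),
      f = f %||% stats::runif(n, 0.5, 2)
    ),
    model_id = paste0("rand", seed)
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# naive O(N^2 * n_q) double-loop Debye sum: the independent oracle
debye_oracle <- function(model, q) {
  xyz <- as.matrix(model[c("x", "y", "z")])
  f <- model$f
  n <- nrow(xyz)
  vapply(q, function(qi) {
    acc <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        acc <- acc + f[i] * f[j] * (if (qi * r == 0) 1 else sin(qi * r) / (qi * r))
      }
    }
    acc
  }, numeric(1))
}

# two random difference curves on a shared grid
random_curve_pair <- function(seed, n = 40) {
  set.seed(seed)
  q <- sort(stats::runif(n, 0.4, 3))
  list(
    exp = new_difference_curve(q, stats::rnorm(n)),
    calc = new_difference_curve(q, stats::rnorm(n))
  )
}

# two-stage dense grid search over k: the independent minimiser
grid_search_k <- function(delta_exp, delta_calc, qmin = 0.5, qmax = 2.5) {
  idx <- which(delta_exp$q >= qmin & delta_exp$q <= qmax)
  y <- delta_exp$dS[idx]
  d <- delta_calc$dS[idx]
  sse_at <- function(k) vapply(k, function(kk) sum((y - kk * d)^2), numeric(1))
  coarse <- seq(-10, 10, by = 0.01)
  k1 <- coarse[which.min(sse_at(coarse))]
  fine <- seq(k1 - 0.02, k1 + 0.02, by = 2e-6)
  k2 <- fine[which.min(sse_at(fine))]
  list(k = k2, sse = sse_at(k2))
}

# wrap a list of 3-vectors into a model resolvable by an angle_spec
point_model <- function(pts, resnos = seq_along(pts)) {
  structure_model(tibble::tibble(
    resno = resnos,
    x = vapply(pts, `[`, numeric(1), 1),
    y = vapply(pts, `[`, numeric(1), 2),
    z = vapply(pts, `[`, numeric(1), 3),
    f = 1
  ))
}

# small synthetic ensembles shared by slow tests
small_ensembles <- function(seed = 1, n = 6, ...) {
  make_ensembles(hinge_model_spec(), n_pr = n, n_pfr = n, seed = seed, ...)
}
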