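# run code under a private RNG stream derived from `seed`
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Specification of the two-domain hinge bead model
#'
#' The synthetic conformers emulate the architecture probed in phytochrome
#' photosensory cores: a static chromophore-binding body (PAS-GAF-like), a
#' long scaffolding helix ending in a hinge, and a mobile output domain
#' (PHY-like) beyond the hinge. Activation is modelled as a rigid rotation of
#' the mobile domain about the hinge: a *bend* (rotation in the marker
#' plane, changing the 300-317-439 angle) plus a *twist* (rotation about the
#' helix axis, changing the 288-300-317-439 dihedral). Marker beads carry the
#' residue numbers used by the default [angle_spec()] so planted angles are
#' measurable exactly.
#'
#' All beads carry the electron count of a glycine residue, so models written
#' to PDB as glycine C-alpha traces reload with identical weights under the
#' default `calpha` scheme.
#'
#' @param n_body Beads in the static body domain.
#' @param body_rg Body radius of gyration target (nm).
#' @param n_move Beads in the mobile domain.
#' @param move_rg Mobile-domain radius of gyration target (nm).
#' @param helix_length Hinge-helix length (nm) from marker 300 to the hinge
#'   marker 317.
#' @param arm_length Distance (nm) from the hinge to the mobile-domain
#'   centre (marker 439).
#' @param base_bend Bend angle (degrees) of the resting-state geometry at
#'   the hinge.
#' @return A list of class `hinge_model_spec`.
#' @export
hinge_model_spec <- function(n_body = 60, body_rg = 2.0, n_move = 50,
                             move_rg = 1.5, helix_length = 2.6,
                             arm_length = 2.9, base_bend = 160) {
  if (n_body < 4 || n_move < 4) abort("domains need at least 4 beads each.")
  if (base_bend <= 90 || base_bend >= 180) abort("`base_bend` must lie in (90, 180).")
  p300 <- c(0, 0, 0)
  p317 <- c(0, 0, helix_length)
  off <- (180 - base_bend) * pi / 180 # tilt of the arm off the helix axis
  p439 <- p317 + arm_length * c(sin(off), 0, cos(off))
  structure(
    list(
      n_body = n_body, body_rg = body_rg, n_move = n_move, move_rg = move_rg,
      helix_length = helix_length, arm_length = arm_length,
      base_bend = base_bend,
      hinge_resno = 317L,
      markers = c(ref = 288L, helix_start = 300L, hinge = 317L, centre = 439L),
      p288 = c(1.0, 0, -0.65), p300 = p300, p317 = p317, p439 = p439,
      body_centre = c(0.4, 0, -2.3),
      twist_axis = c(0, 0, 1), # unit(p317 - p300): the helix axis
      bead_f = unname(.residue_electrons["GLY"])
    ),
    class = "hinge_model_spec"
  )
}

# deterministic resting-state bead model for a hinge spec
hinge_base_model <- function(spec = hinge_model_spec(), seed = 1) {
  with_seed(seed, {
    # anisotropic bead blob: protein domains are elongated, and the
    # anisotropy is what makes domain orientation visible in the scattering
    blob <- function(n, centre, rg, axes) {
      u <- matrix(rnorm(3 * n), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      r <- runif(n)^(1 / 3)
      p <- (u * r) %*% diag(axes)
      p <- sweep(p, 2, colMeans(p))
      s <- rg / sqrt(mean(rowSums(p^2)))
      sweep(p * s, 2, centre, `+`)
    }
    body <- blob(spec$n_body, spec$body_centre, spec$body_rg, c(1.5, 1, 0.8))
    move <- blob(spec$n_move, spec$p439, spec$move_rg, c(2, 1, 0.7))
    # linker beads between the reference marker and the helix start
    fr <- seq_len(11) / 12
    linker <- outer(fr, spec$p300 - spec$p288) + rep(1, 11) %o% spec$p288
    helix_res <- 300:317
    helix <- outer(
      (helix_res - 300) / 17,
      spec$p317 - spec$p300
    ) + rep(1, length(helix_res)) %o% spec$p300

    move_res <- sort(round(seq(318, 460, length.out = spec$n_move)))
    move_res[move_res == 439] <- 438L # keep the centre marker unique

    atoms <- tibble(
      chain = "A",
      resno = c(
        sort(round(seq(1, 284, length.out = spec$n_body))),
        288L, 289:299, helix_res, move_res, 439L
      ),
      x = c(body[, 1], spec$p288[1], linker[, 1], helix[, 1], move[, 1], spec$p439[1]),
      y = c(body[, 2], spec$p288[2], linker[, 2], helix[, 2], move[, 2], spec$p439[2]),
      z = c(body[, 3], spec$p288[3], linker[, 3], helix[, 3], move[, 3], spec$p439[3]),
      f = spec$bead_f
    )
    atoms <- dplyr::arrange(atoms, .data$resno)
    structure_model(atoms, state = "UNLABELLED", model_id = "hinge_base")
  })
}

#' Apply a planted bend/twist to a hinge model
#'
#' Rigidly rotates every bead beyond the hinge (residue number above the
#' hinge marker) by `bend_deg` about the in-plane hinge axis and then by
#' `twist_deg` about the helix axis, both through the hinge point. By
#' construction the bend adds exactly to the 300-317-439 angle and the twist
#' adds exactly to the 288-300-317-439 dihedral, so planted coordinates are
#' recovered exactly by [bend_angle()] and [plane_dihedral()].
#'
#' A third rigid mode, `spin_deg`, rotates the mobile domain about its own
#' connection axis (hinge to domain centre). It changes neither the bend nor
#' the dihedral marker coordinate — both defining atoms lie on its axis — but
#' it does change the structure, so ensemble members with different spins are
#' distinguishable by their scattering. It stands in for the conformational
#' variability real candidate pools carry beyond the two tracked coordinates.
#'
#' @param model A hinge-spec base model (see [make_ensembles()]).
#' @param bend_deg,twist_deg Planted angle changes in degrees.
#' @param spin_deg Nuisance rotation (degrees) about the hinge-to-centre
#'   axis.
#' @param spec The [hinge_model_spec()] the model was built from.
#' @return The transformed [structure_model()].
#' @export
hinge_transform <- function(model, bend_deg, twist_deg, spin_deg = 0,
                            spec = hinge_model_spec()) {
  v1 <- spec$p300 - spec$p317
  v2 <- spec$p439 - spec$p317
  n_bend <- cross3(v1, v2) # normal of the marker plane
  if (sum(n_bend^2) == 0) abort("degenerate hinge geometry: markers collinear.")
  moving <- model$resno > spec$hinge_resno
  xyz <- as.matrix(model[moving, c("x", "y", "z")])
  R <- rotation_matrix(spec$twist_axis, twist_deg) %*%
    rotation_matrix(n_bend, bend_deg) %*%
    rotation_matrix(v2, spin_deg)
  xyz <- sweep(sweep(xyz, 2, spec$p317) %*% t(R), 2, spec$p317, `+`)
  model$x[moving] <- xyz[, 1]
  model$y[moving] <- xyz[, 2]
  model$z[moving] <- xyz[, 3]
  model
}

#' Generate resting- and activated-state conformer ensembles
#'
#' Builds a deterministic base model from `spec`, then populates two
#' ensembles: resting-state (PR) members jittered by
#' `Normal(0, jitter_deg^2)` on both hinge coordinates around (0, 0), and
#' activated-state (PFR) members jittered around the planted change
#' `(bend_true, twist_true)`. The first member of each ensemble carries no
#' jitter, so the pair (1, 1) realises the planted transformation exactly.
#' Bead positions are otherwise identical across members.
#'
#' Members also differ by two nuisance modes a real candidate pool would
#' carry beyond the two tracked coordinates: a rigid spin of the mobile
#' domain about its own connection axis (standard deviation `jitter_deg`)
#' and small independent Cartesian displacements of every non-marker bead
#' (standard deviation `bead_jitter_nm` per coordinate). Neither changes the
#' bend or dihedral marker coordinates, but both make members
#' scattering-distinguishable, so a planted pair is identifiable in a scan.
#'
#' @param spec A [hinge_model_spec()].
#' @param n_pr,n_pfr Ensemble sizes (>= 1).
#' @param bend_true,twist_true Planted bend and twist changes (degrees).
#' @param jitter_deg Angular jitter standard deviation (degrees, >= 0),
#'   applied to bend, twist and spin.
#' @param bead_jitter_nm Per-coordinate bead displacement standard deviation
#'   (nm); marker beads are exempt so planted angles stay exact.
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `synthetic_ensembles`: ensemble tibbles `pr` and
#'   `pfr` (columns `id`, `state`, `model`, plus the member angles
#'   `bend_jitter`, `twist_jitter`) and a `truth` record with the planted
#'   values and seed.
#' @export
make_ensembles <- function(spec = hinge_model_spec(), n_pr = 20, n_pfr = 20,
                           bend_true = 5, twist_true = 20, jitter_deg = 5,
                           bead_jitter_nm = 0.012, seed = 1) {
  if (n_pr < 1 || n_pfr < 1) abort("ensemble sizes must be >= 1.")
  if (jitter_deg < 0 || bead_jitter_nm < 0) abort("jitter values must be >= 0.")
  base <- hinge_base_model(spec, seed = seed)
  markers <- base$resno %in% spec$markers
  with_seed(seed + 1L, {
    jit <- function(n, b0, t0, state) {
      db <- c(0, rnorm(n - 1, 0, jitter_deg))
      dt <- c(0, rnorm(n - 1, 0, jitter_deg))
      ds <- c(0, rnorm(n - 1, 0, jitter_deg)) # nuisance spin, untracked
      models <- lapply(seq_len(n), function(i) {
        m <- base
        if (i > 1 && bead_jitter_nm > 0) { # member 1 is the exact plant
          nfree <- sum(!markers)
          m$x[!markers] <- m$x[!markers] + rnorm(nfree, 0, bead_jitter_nm)
          m$y[!markers] <- m$y[!markers] + rnorm(nfree, 0, bead_jitter_nm)
          m$z[!markers] <- m$z[!markers] + rnorm(nfree, 0, bead_jitter_nm)
        }
        m <- hinge_transform(m, b0 + db[i], t0 + dt[i], ds[i], spec)
        attr(m, "state") <- state
        attr(m, "model_id") <- sprintf("%s_%03d", tolower(state), i)
        m
      })
      tibble(
        id = vapply(models, function(m) attr(m, "model_id"), character(1)),
        state = state,
        model = models,
        bend_jitter = db, twist_jitter = dt, spin_jitter = ds
      )
    }
    pr <- jit(n_pr, 0, 0, "PR")
    pfr <- jit(n_pfr, bend_true, twist_true, "PFR")
    structure(
      list(
        pr = pr, pfr = pfr,
        truth = list(
          bend_true = bend_true, twist_true = twist_true,
          jitter_deg = jitter_deg, bead_jitter_nm = bead_jitter_nm,
          n_pr = n_pr, n_pfr = n_pfr, seed = seed
        )
      ),
      class = "synthetic_ensembles"
    )
  })
}

#' Synthesise an experimental difference curve from a planted pair
#'
#' Computes the scattering of a chosen (pr, pfr) member pair, forms
#' `k_true * (I_pfr - I_pr)` on `q`, and adds Gaussian noise with standard
#' deviation `noise * max(abs(dS))`. The truth (pair, scale, noise, seed) is
#' attached as the `truth` attribute, and the noise level as the `sigma`
#' column.
#'
#' @param ensembles A `synthetic_ensembles` object (or a list with `pr` and
#'   `pfr` ensemble tibbles).
#' @param true_pair Integer pair (pr index, pfr index); default `c(1, 1)`,
#'   the un-jittered planted transformation.
#' @param k_true Planted scale factor.
#' @param noise Noise sigma as a fraction of `max(abs(dS))`.
#' @param q q grid (nm^-1).
#' @param seed Integer seed for the noise draw.
#' @return A difference-curve tibble with `sigma` and a `truth` attribute.
#' @export
make_difference_experiment <- function(ensembles, true_pair = c(1, 1),
                                       k_true = 1, noise = 0.01,
                                       q = default_qgrid(), seed = 1) {
  pr <- ensembles$pr
  pfr <- ensembles$pfr
  s_pr <- debye_scattering(pr$model[[true_pair[1]]], q)
  s_pfr <- debye_scattering(pfr$model[[true_pair[2]]], q)
  clean <- k_true * (s_pfr$I - s_pr$I)
  sig <- noise * max(abs(clean))
  dS <- with_seed(seed, clean + rnorm(length(q), 0, sig))
  out <- new_difference_curve(q, dS, sigma = rep(max(sig, 0), length(q)))
  attr(out, "truth") <- list(
    true_pair = true_pair, k_true = k_true, noise = noise, sigma_abs = sig,
    seed = seed
  )
  out
}

#' Default q grid for synthetic experiments
#'
#' 0.05 to 5 nm^-1 in 0.025 nm^-1 steps: covers the scoring window
#' (0.5-2.5 nm^-1) with 81 points and the surrounding context a
#' time-resolved solution-scattering experiment would record at small angle.
#'
#' @return Numeric q grid (nm^-1).
#' @export
default_qgrid <- function() seq(0.05, 5, by = 0.025)

#' Specification of a synthetic two-component kinetic experiment
#'
#' Defines the generative model for a time series of difference curves: a
#' fast component decaying as `amp_fast * 2^(-t / t_half_fast)` and a slow
#' component rising as `amp_slow * (1 - 2^(-t / t_half_slow))`, sampled on a
#' log-spaced time grid with additive Gaussian noise. Defaults emulate a
#' photoreceptor photocycle observed from microseconds to seconds: a fast
#' 30 microsecond decay and a slow 10 ms rise.
#'
#' @param t_half_fast,t_half_slow Component half-times in seconds
#'   (fast < slow).
#' @param amp_fast,amp_slow Component amplitudes.
#' @param times Sampled time points (s), strictly increasing; default 30
#'   log-spaced points from 1 microsecond to 2 s.
#' @param noise Noise sigma as a fraction of the maximum absolute signal.
#' @param seed Integer seed.
#' @return A list of class `kinetic_spec`.
#' @export
kinetic_spec <- function(t_half_fast = 3e-5, t_half_slow = 1e-2,
                         amp_fast = 1, amp_slow = 1,
                         times = 10^seq(log10(1e-6), log10(2), length.out = 30),
                         noise = 0.02, seed = 1) {
  if (t_half_fast <= 0 || t_half_slow <= 0) abort("half-times must be positive.")
  if (t_half_fast >= t_half_slow) abort("the fast half-time must be below the slow one.")
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")
  structure(
    list(
      t_half_fast = t_half_fast, t_half_slow = t_half_slow,
      amp_fast = amp_fast, amp_slow = amp_slow, times = times,
      noise = noise, seed = seed
    ),
    class = "kinetic_spec"
  )
}

#' Generate a synthetic time series of difference curves
#'
#' Realises the two-component model of a [kinetic_spec()] on the grid of the
#' supplied basis patterns:
#' `dS(q, t) = amp_fast 2^(-t/t_fast) fast(q) + amp_slow (1 - 2^(-t/t_slow)) slow(q) + noise`.
#' The generative record is attached as the `truth` attribute.
#'
#' @param spec A [kinetic_spec()].
#' @param basis_fast,basis_slow Difference curves (common grid) giving the
#'   spectral shape of each component.
#' @return A [time_series_set()] tibble with a `truth` attribute.
#' @export
make_timeseries <- function(spec, basis_fast, basis_slow) {
  check_same_grid(basis_fast, basis_slow)
  q <- basis_fast$q
  t <- spec$times
  clean <- outer(basis_fast$dS, spec$amp_fast * 2^(-t / spec$t_half_fast)) +
    outer(basis_slow$dS, spec$amp_slow * (1 - 2^(-t / spec$t_half_slow)))
  sig <- spec$noise * max(abs(clean))
  noisy <- with_seed(spec$seed, clean + matrix(rnorm(length(clean), 0, sig), nrow = length(q)))
  out <- time_series_set(tibble(
    time = rep(t, each = length(q)),
    q = rep(q, times = length(t)),
    dS = as.numeric(noisy)
  ))
  attr(out, "truth") <- c(unclass(spec), list(sigma_abs = sig))
  out
}

#' Paint a synthetic detector image from a scattering curve
#'
#' Forward model for the ring-integration stage: every pixel is assigned the
#' curve intensity at its scattering vector (linear interpolation; constant
#' extrapolation at the ends), optionally with Gaussian or Poisson noise, and
#' a border of masked pixels.
#'
#' @param curve A [scattering_curve()] tibble.
#' @param shape Image dimensions `c(rows, cols)`.
#' @param center_px Beam centre (row, col); default image centre.
#' @param pixel_mm,distance_mm,wavelength_nm Detector geometry.
#' @param noise `"none"`, `"gaussian"` (sd = `noise_level` x intensity scale)
#'   or `"poisson"` (counts scaled by `noise_level`).
#' @param noise_level Noise parameter (see `noise`).
#' @param mask_border Width (pixels) of the masked border.
#' @param seed Integer seed.
#' @return A [detector_image()].
#' @export
make_detector_image <- function(curve, shape = c(128, 128), center_px = NULL,
                                pixel_mm = 0.75, distance_mm = 300,
                                wavelength_nm = 0.1,
                                noise = c("none", "gaussian", "poisson"),
                                noise_level = 0.01, mask_border = 2, seed = 1) {
  noise <- match.arg(noise)
  center_px <- center_px %||% (shape + 1) / 2
  img <- detector_image(
    matrix(0, shape[1], shape[2]), center_px, pixel_mm, distance_mm,
    wavelength_nm
  )
  qpix <- pixel_q(img)
  I <- matrix(
    approx(curve$q, curve$I, xout = as.numeric(qpix), rule = 2)$y,
    shape[1], shape[2]
  )
  I <- with_seed(seed, switch(noise,
    none = I,
    gaussian = pmax(I + rnorm(length(I), 0, noise_level * max(I)), 0),
    poisson = {
      lam <- I / max(I) / noise_level
      matrix(rpois(length(I), lam) * max(I) * noise_level, shape[1], shape[2])
    }
  ))
  mask <- matrix(FALSE, shape[1], shape[2])
  if (mask_border > 0) {
    b <- seq_len(mask_border)
    mask[b, ] <- TRUE
    mask[nrow(mask) + 1 - b, ] <- TRUE
    mask[, b] <- TRUE
    mask[, ncol(mask) + 1 - b] <- TRUE
  }
  detector_image(I, center_px, pixel_mm, distance_mm, wavelength_nm, mask)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Writes bead models as glycine C-alpha traces (one MODEL/ENDMDL block per
#' member, occupancy 1.00, B-factor 0.00, coordinates in Angstrom at the
#' PDB's fixed 3-decimal precision), so that generated ensembles round-trip
#' through [load_ensemble()] with the default `calpha` weighting.
#'
#' @param ensemble Ensemble tibble (columns `id`, `model`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(ensemble))) {
    m <- ensemble$model[[k]]
    writeLines(sprintf("MODEL     %4d", k), con)
    lines <- sprintf(
      "ATOM  %5d  CA  GLY %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(m)), m$chain, m$resno, m$x * 10, m$y * 10, m$z * 10
    )
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a self-contained synthetic demo workspace
#'
#' Generates a complete input set for the pipeline under `dir`: multi-model
#' PDB ensembles for both states, a noisy "experimental" difference curve,
#' a kinetic time series (one curve file per time point plus a manifest CSV
#' of `filename, time_s`), and a JSON truth manifest recording every planted
#' parameter and seed.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer master seed.
#' @param n_pr,n_pfr Ensemble sizes.
#' @return Invisibly, the truth manifest list.
#' @export
make_demo <- function(dir, seed = 1, n_pr = 20, n_pfr = 20) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- hinge_model_spec()
  ens <- make_ensembles(spec, n_pr = n_pr, n_pfr = n_pfr, seed = seed)
  write_ensemble_pdb(ens$pr, file.path(dir, "pr_ensemble.pdb"))
  write_ensemble_pdb(ens$pfr, file.path(dir, "pfr_ensemble.pdb"))
  q <- default_qgrid()
  delta <- make_difference_experiment(ens, q = q, seed = seed + 1L)
  write_curve(delta, file.path(dir, "delta_exp.dat"))

  # late pattern: the planted structural transition; early pattern: a
  # spin-only rearrangement, structurally distinct from the slow signal
  base <- hinge_base_model(spec, seed = seed)
  slow <- difference_curve(
    debye_scattering(hinge_transform(base, 5, 20, 0, spec), q),
    debye_scattering(base, q)
  )
  fast <- difference_curve(
    debye_scattering(hinge_transform(base, 0, 0, 25, spec), q),
    debye_scattering(base, q)
  )
  # comparable peak amplitudes, as in measured photocycle series
  fast$dS <- fast$dS * max(abs(slow$dS)) / max(abs(fast$dS))
  kspec <- kinetic_spec(seed = seed + 2L)
  series <- make_timeseries(kspec, new_difference_curve(q, fast$dS),
    basis_slow = new_difference_curve(q, slow$dS)
  )
  ts_dir <- file.path(dir, "timeseries")
  dir.create(ts_dir, showWarnings = FALSE)
  times <- series_times(series)
  M <- series_matrix(series)
  files <- sprintf("t_%03d.dat", seq_along(times))
  for (i in seq_along(times)) {
    write_curve(new_difference_curve(q, M[, i]), file.path(ts_dir, files[i]))
  }
  write.csv(
    data.frame(filename = files, time_s = times),
    file.path(ts_dir, "manifest.csv"),
    row.names = FALSE
  )
  manifest <- list(
    seed = seed,
    ensembles = ens$truth,
    experiment = attr(delta, "truth"),
    kinetics = attr(series, "truth")[c(
      "t_half_fast", "t_half_slow", "amp_fast", "amp_slow", "noise", "seed"
    )]
  )
  jsonlite::write_json(manifest, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}

#' Read a time series from a manifest CSV
#'
#' Loads a directory of difference-curve files listed in a manifest CSV with
#' columns `filename, time_s` into a [time_series_set()].
#'
#' @param manifest_path Path to the manifest CSV; file names are resolved
#'   relative to its directory.
#' @return A [time_series_set()] tibble.
#' @export
read_timeseries <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("filename", "time_s") %in% names(man))) {
    abort("manifest must have columns filename, time_s.")
  }
  dir <- dirname(manifest_path)
  rows <- lapply(seq_len(nrow(man)), function(i) {
    cv <- read_curve(file.path(dir, man$filename[i]), type = "difference")
    tibble(time = man$time_s[i], q = cv$q, dS = cv$dS)
  })
  time_series_set(dplyr::bind_rows(rows))
}
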