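# electron counts: atomic numbers by element symbol
.element_electrons <- c(
  H = 1, C = 6, N = 7, O = 8, NA. = 11, MG = 12, P = 15, S = 16,
  CL = 17, K = 19, CA = 20, MN = 25, FE = 26, CU = 29, ZN = 30, SE = 34
)

# electrons per amino-acid residue as part of a chain (residue = AA - H2O)
.residue_electrons <- c(
  GLY = 30, ALA = 38, SER = 46, PRO = 52, VAL = 54, THR = 54, CYS = 54,
  LEU = 62, ILE = 62, ASN = 60, ASP = 60, GLN = 68, GLU = 68, LYS = 70,
  MET = 70, HIS = 72, PHE = 78, ARG = 84, TYR = 86, TRP = 98
)

#' Coordinate models with scattering weights
#'
#' A structure model is a tibble of scattering centres: one row per atom (or
#' bead) with columns `chain`, `resno` (residue number), `resid` (residue
#' name), `elety` (atom name), `x`, `y`, `z` (positions in nm) and `f`
#' (dimensionless effective electron count, the weight entering the Debye
#' sum). The state label (`"PR"`, `"PFR"` or `"UNLABELLED"`) and a model id
#' are carried as attributes.
#'
#' @param atoms A data frame with at least `chain`, `resno`, `x`, `y`, `z`,
#'   `f`; `resid` and `elety` default to `"GLY"`/`"CA"`.
#' @param state State label, one of `"PR"`, `"PFR"`, `"UNLABELLED"`.
#' @param model_id Free-text identifier.
#' @return A validated `structure_model` tibble.
#' @export
structure_model <- function(atoms, state = "UNLABELLED", model_id = "model") {
  atoms <- as_tibble(atoms)
  if (!"resid" %in% names(atoms)) atoms$resid <- "GLY"
  if (!"elety" %in% names(atoms)) atoms$elety <- "CA"
  if (!"chain" %in% names(atoms)) atoms$chain <- "A"
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z", "f")
  missing <- setdiff(need, names(atoms))
  if (length(missing)) abort(paste0("missing columns: ", paste(missing, collapse = ", ")))
  out <- atoms[need]
  validate_structure_model(out)
  attr(out, "state") <- match.arg(state, c("PR", "PFR", "UNLABELLED"))
  attr(out, "model_id") <- model_id
  class(out) <- c("structure_model", class(out))
  out
}

validate_structure_model <- function(atoms) {
  if (nrow(atoms) < 1) abort("a structure model needs at least one atom.")
  xyz <- as.matrix(atoms[c("x", "y", "z")])
  if (!all(is.finite(xyz))) abort("all positions must be finite.")
  if (!all(is.finite(atoms$f)) || any(atoms$f <= 0)) {
    abort("all scattering weights `f` must be finite and > 0.")
  }
  for (ch in unique(atoms$chain)) {
    r <- atoms$resno[atoms$chain == ch]
    if (any(diff(r) < 0)) {
      abort(paste0("residue numbers decrease within chain ", ch, "."))
    }
  }
  invisible(atoms)
}

#' @export
print.structure_model <- function(x, ...) {
  cat(
    "<structure_model> ", attr(x, "model_id"), " [", attr(x, "state"), "], ",
    nrow(x), " scattering centres\n",
    sep = ""
  )
  NextMethod()
}

#' Load a coordinate model from a PDB file
#'
#' Parses a PDB file (via bio3d), converts coordinates from Angstrom to nm,
#' and assigns per-centre scattering weights according to `weight_scheme`:
#'
#' * `"calpha"` (default): one bead per residue placed at the C-alpha
#'   position with weight equal to the residue's total electron count;
#' * `"electrons"`: every atom kept, weight = element electron count;
#' * `"uniform"`: every atom kept, weight 1.
#'
#' Multi-model files: `load_structure()` reads the first model;
#' `load_ensemble()` reads all models into an ensemble tibble (one row per
#' model, structure in the `model` list-column).
#'
#' @param path Path to a PDB file.
#' @param weight_scheme Weighting scheme (see above).
#' @param state State label for the loaded model(s).
#' @param model_id Identifier; defaults to the file name (with `_<k>` suffixes
#'   for ensemble members).
#' @return `load_structure()`: a [structure_model()]. `load_ensemble()`: a
#'   tibble with columns `id`, `state`, `model`.
#' @export
load_structure <- function(path, weight_scheme = c("calpha", "electrons", "uniform"),
                           state = "UNLABELLED", model_id = NULL) {
  ens <- load_ensemble(path, weight_scheme, state = state)
  m <- ens$model[[1]]
  attr(m, "model_id") <- model_id %||% basename(path)
  m
}

#' @rdname load_structure
#' @export
load_ensemble <- function(path, weight_scheme = c("calpha", "electrons", "uniform"),
                          state = "UNLABELLED", model_id = NULL) {
  weight_scheme <- match.arg(weight_scheme)
  state <- match.arg(state, c("PR", "PFR", "UNLABELLED"))
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) abort(paste0("cannot parse PDB file ", path, ": ", conditionMessage(e)))
  )
  at <- pdb$atom
  if (nrow(at) == 0) abort(paste0("no ATOM/HETATM records in ", path))
  at$chain[is.na(at$chain)] <- "A"
  n_models <- nrow(pdb$xyz)
  base_id <- model_id %||% basename(path)
  build_one <- function(k) {
    xyz <- matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE)
    atoms <- tibble(
      chain = at$chain, resno = at$resno, resid = at$resid, elety = at$elety,
      x = xyz[, 1] / 10, y = xyz[, 2] / 10, z = xyz[, 3] / 10
    )
    atoms <- assign_weights(atoms, at, weight_scheme)
    id <- if (n_models > 1) paste0(base_id, "_", k) else base_id
    structure_model(atoms, state = state, model_id = id)
  }
  models <- lapply(seq_len(n_models), build_one)
  tibble(
    id = vapply(models, function(m) attr(m, "model_id"), character(1)),
    state = state,
    model = models
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assign_weights <- function(atoms, at, scheme) {
  if (scheme == "uniform") {
    atoms$f <- 1.0
    return(atoms)
  }
  if (scheme == "electrons") {
    ele <- toupper(trimws(at$elesy))
    missing <- is.na(ele) | ele == ""
    # fall back to the leading letter of the atom name when the element
    # column is blank (common in coarse or hand-written files)
    ele[missing] <- toupper(substr(trimws(at$elety[missing]), 1, 1))
    ele[ele == "NA"] <- "NA."
    f <- unname(.element_electrons[ele])
    if (anyNA(f)) {
      bad <- which(is.na(f))[1]
      abort(paste0(
        "unknown element '", ele[bad], "' for atom ", at$eleno[bad],
        " (", trimws(at$elety[bad]), " in residue ", at$resid[bad], at$resno[bad], ")."
      ))
    }
    atoms$f <- f
    return(atoms)
  }
  # calpha: one bead per residue at the C-alpha, weight = residue electrons
  is_ca <- trimws(atoms$elety) == "CA" & trimws(at$type) %in% c("ATOM", "HETATM")
  beads <- atoms[is_ca, , drop = FALSE]
  if (nrow(beads) == 0) abort("no CA atoms found; cannot build a C-alpha bead model.")
  f <- unname(.residue_electrons[toupper(beads$resid)])
  if (anyNA(f)) {
    bad <- which(is.na(f))[1]
    abort(paste0(
      "unknown residue '", beads$resid[bad], "' at ", beads$chain[bad],
      beads$resno[bad], " under the calpha weighting scheme."
    ))
  }
  beads$f <- f
  beads
}

#' Rigid-body transforms of structure models
#'
#' `rotation_matrix()` builds the 3x3 matrix for a right-handed rotation of
#' `angle_deg` degrees about `axis`. `transform_model()` applies
#' `R (x - pivot) + pivot + translation` to every atom; scattering is
#' invariant under such transforms, which the test-suite exploits.
#'
#' @param axis Length-3 axis vector (need not be unit length).
#' @param angle_deg Rotation angle in degrees (right-hand rule).
#' @param model A [structure_model()].
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation in nm.
#' @param pivot Point the rotation is taken about.
#' @return `rotation_matrix()`: a 3x3 matrix; `transform_model()`: the
#'   transformed model.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  n <- as.numeric(axis)
  len <- sqrt(sum(n^2))
  if (len == 0) abort("rotation axis must be non-zero.")
  n <- n / len
  th <- angle_deg * pi / 180
  K <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' @rdname rotation_matrix
#' @export
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0),
                            pivot = c(0, 0, 0)) {
  xyz <- as.matrix(model[c("x", "y", "z")])
  xyz <- sweep(xyz, 2, pivot) %*% t(rotation)
  xyz <- sweep(xyz, 2, pivot + translation, `+`)
  model$x <- xyz[, 1]
  model$y <- xyz[, 2]
  model$z <- xyz[, 3]
  model
}
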