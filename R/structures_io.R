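# Reading and cleaning PDB structures, and the per-protein geometric
# quantities (center, radius of gyration, envelope volume) that the
# simulator and the diffusion analyses consume.

# Bondi van der Waals radii (Angstrom); unknown elements fall back to 1.7.
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90
)

# Standard atomic masses (Da) for molecular-weight synthesis.
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, CL = 35.45, BR = 79.904, I = 126.904, SE = 78.971,
  FE = 55.845, ZN = 65.38, MG = 24.305, CA = 40.078, MN = 54.938,
  CU = 63.546, `NA` = 22.990, K = 39.098
)

.vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- 1.7
  unname(r)
}

.atomic_mass <- function(element) {
  m <- .atomic_masses[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Construct a protein structure object
#'
#' Container for a rigid protein: an atom table with coordinates, element
#' assignments and C-alpha flags, plus a label and molecular weight. Most
#' users obtain one from [read_structure()] or [make_blob_protein()].
#'
#' @param label Identifier (e.g. a PDB id).
#' @param atoms `data.frame` with columns `name`, `element`, `x`, `y`, `z`,
#'   `is_calpha`.
#' @param molecular_weight Molecular weight in Da; computed from element
#'   masses when `NULL`.
#' @return An object of class `protein_structure`.
#' @export
protein_structure <- function(label, atoms, molecular_weight = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  need <- c("name", "element", "x", "y", "z", "is_calpha")
  if (!all(need %in% names(atoms))) {
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("atom coordinates must be finite")
  }
  if (is.null(molecular_weight)) {
    molecular_weight <- sum(.atomic_mass(atoms$element))
  }
  stopifnot(molecular_weight > 0)
  structure(
    list(label = label, atoms = atoms, molecular_weight = molecular_weight),
    class = "protein_structure"
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf(
    "<protein_structure> %s: %d atoms (%d C-alpha), Mw %.1f Da\n",
    x$label, nrow(x$atoms), sum(x$atoms$is_calpha), x$molecular_weight
  ))
  invisible(x)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records (all chains, first altloc only) via
#' [bio3d::read.pdb()]. Waters, ions and other HETATM records are dropped
#' unless `keep_het = TRUE`. Elements come from PDB columns 77-78 with a
#' fallback to atom-name heuristics; the molecular weight is summed from
#' element masses.
#'
#' @param path Path to a PDB-format file.
#' @param keep_het Keep HETATM records (default `FALSE`).
#' @param label Structure label; defaults to the file base name.
#' @return A [protein_structure()].
#' @export
read_structure <- function(path, keep_het = FALSE, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(label)) label <- sub("\\.(pdb|ent)$", "", basename(path))
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE, verbose = FALSE)
  a <- pdb$atom
  keep <- a$type == "ATOM"
  if (keep_het) keep <- keep | a$type == "HETATM"
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0L) stop("no atoms left after filtering: ", path)
  element <- toupper(a$elesy)
  bad <- is.na(element) | element == ""
  if (any(bad)) {
    # heuristic: first alphabetic character of the atom name
    guess <- toupper(substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", a$elety[bad])), 1, 1))
    element[bad] <- ifelse(guess == "", "C", guess)
  }
  atoms <- data.frame(
    name = a$elety,
    element = element,
    x = a$x, y = a$y, z = a$z,
    is_calpha = a$elety == "CA" & a$type == "ATOM",
    stringsAsFactors = FALSE
  )
  protein_structure(label, atoms)
}

#' Write a protein structure to a PDB file
#'
#' Coordinates are written at PDB precision (3 decimals); a
#' read/write/read round trip preserves them at that precision.
#'
#' @param s A [protein_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "protein_structure"))
  n <- nrow(s$atoms)
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(as.matrix(s$atoms[, c("x", "y", "z")]))),
    type = rep("ATOM", n),
    eleno = seq_len(n),
    elety = s$atoms$name,
    resid = rep("GLY", n),
    chain = rep("A", n),
    resno = cumsum(s$atoms$is_calpha) + 1L,
    elesy = s$atoms$element
  )
  invisible(path)
}

.coord_matrix <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' Geometric center of a structure
#'
#' Unweighted mean of the atom positions; this is the point whose
#' mean-square displacement defines translational diffusion downstream.
#'
#' @param s A [protein_structure()].
#' @return Numeric 3-vector (Angstrom).
#' @export
geometric_center <- function(s) {
  stopifnot(inherits(s, "protein_structure"))
  colMeans(.coord_matrix(s))
}

#' Radius of gyration
#'
#' Root-mean-square atom distance from the geometric center, unweighted
#' over all atoms by default; set `mass_weighted = TRUE` for the
#' mass-weighted convention (the two differ by a few percent for
#' globular proteins).
#'
#' @param s A [protein_structure()].
#' @param mass_weighted Use element masses as weights (default `FALSE`).
#' @return Length in Angstrom.
#' @export
radius_of_gyration <- function(s, mass_weighted = FALSE) {
  stopifnot(inherits(s, "protein_structure"))
  xyz <- .coord_matrix(s)
  if (mass_weighted) {
    w <- .atomic_mass(s$atoms$element)
    ctr <- colSums(xyz * w) / sum(w)
    d2 <- rowSums(sweep(xyz, 2, ctr)^2)
    sqrt(sum(w * d2) / sum(w))
  } else {
    ctr <- colMeans(xyz)
    sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
  }
}

#' Bounding-sphere radius about the geometric center
#'
#' Maximum atom distance from the geometric center plus that atom's van
#' der Waals radius; used for neighbor cutoffs and clash checks.
#'
#' @param s A [protein_structure()].
#' @return Length in Angstrom.
#' @export
bounding_radius <- function(s) {
  xyz <- .coord_matrix(s)
  ctr <- colMeans(xyz)
  d <- sqrt(rowSums(sweep(xyz, 2, ctr)^2))
  max(d + .vdw_radius(s$atoms$element))
}

#' Molecular envelope volume by voxel counting
#'
#' Volume of the union of atom van der Waals spheres, estimated by
#' counting voxels whose centers lie inside any sphere. Converges to the
#' exact union volume as `voxel` shrinks. This is the envelope volume
#' used to convert a target volume fraction into copy counts.
#'
#' @param s A [protein_structure()].
#' @param voxel Voxel edge in Angstrom (default 0.5).
#' @return Volume in cubic Angstrom.
#' @export
molecular_volume <- function(s, voxel = 0.5) {
  stopifnot(inherits(s, "protein_structure"))
  if (!is.numeric(voxel) || voxel <= 0) stop("voxel must be positive")
  xyz <- .coord_matrix(s)
  r <- .vdw_radius(s$atoms$element)
  lo <- apply(xyz, 2, min) - max(r) - voxel
  hi <- apply(xyz, 2, max) + max(r) + voxel
  gx <- seq(lo[1] + voxel / 2, hi[1], by = voxel)
  gy <- seq(lo[2] + voxel / 2, hi[2], by = voxel)
  gz <- seq(lo[3] + voxel / 2, hi[3], by = voxel)
  inside <- array(FALSE, dim = c(length(gx), length(gy), length(gz)))
  r2 <- r^2
  for (i in seq_len(nrow(xyz))) {
    ix <- which(abs(gx - xyz[i, 1]) <= r[i])
    iy <- which(abs(gy - xyz[i, 2]) <= r[i])
    iz <- which(abs(gz - xyz[i, 3]) <= r[i])
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - xyz[i, 1])^2
    dy2 <- (gy[iy] - xyz[i, 2])^2
    dz2 <- (gz[iz] - xyz[i, 3])^2
    sub <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r2[i]
    inside[ix, iy, iz] <- as.vector(inside[ix, iy, iz]) | as.vector(sub)
  }
  sum(inside) * voxel^3
}

#' Convert a mass concentration to a volume fraction
#'
#' `V = c * v / 1000` for a concentration `c` in g/l and a specific
#' volume `v` in ml/g, e.g. 275 g/l at 1.0 ml/g occupies a volume
#' fraction of about 0.27.
#'
#' @param conc_gl Concentration in g/l.
#' @param specific_volume_ml_g Effective protein specific volume in ml/g
#'   (default 1.0).
#' @return Dimensionless volume fraction.
#' @export
concentration_to_volume_fraction <- function(conc_gl, specific_volume_ml_g = 1.0) {
  stopifnot(conc_gl >= 0, specific_volume_ml_g > 0)
  conc_gl * specific_volume_ml_g / 1000
}

# Rigidly transform a structure (rotation about the origin, then shift).
transform_structure <- function(s, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(s, "protein_structure"))
  xyz <- .coord_matrix(s) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, `+`)
  s$atoms$x <- xyz[, 1]
  s$atoms$y <- xyz[, 2]
  s$atoms$z <- xyz[, 3]
  s
}
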