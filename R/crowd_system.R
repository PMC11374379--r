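# Building the initial crowded box at a preset volume fraction, and the
# periodic-geometry services (minimum image, neighbor queries) the MC
# engine relies on.

#' System composition
#'
#' @param structures Named list of [protein_structure()] objects (names
#'   are the type labels).
#' @param weights Positive relative copy shares, one per type; equal by
#'   default (each protein gets an equal share of copies). Use
#'   abundance-derived weights for cytoplasm-style systems.
#' @return Object of class `composition`.
#' @export
composition <- function(structures, weights = NULL) {
  stopifnot(length(structures) >= 1)
  labels <- names(structures)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- vapply(structures, function(s) s$label, character(1))
    names(structures) <- labels
  }
  if (is.null(weights)) weights <- rep(1, length(structures))
  stopifnot(length(weights) == length(structures), all(weights > 0))
  structure(
    list(structures = structures, labels = labels, weights = weights),
    class = "composition"
  )
}

#' Per-type copy counts for a target volume fraction
#'
#' The total copy number is chosen so that the summed envelope volume
#' matches `V * box_edge^3`; copies are split across types proportionally
#' to the composition weights with largest-remainder rounding. The
#' achieved fraction is within one protein volume of the target.
#'
#' @param comp A [composition()].
#' @param V Target volume fraction in (0, 1).
#' @param box_edge Box edge, Angstrom.
#' @param volumes Optional per-type envelope volumes (cubic Angstrom);
#'   computed with [molecular_volume()] when omitted.
#' @return Named integer vector of copy counts.
#' @export
copy_counts <- function(comp, V, box_edge, volumes = NULL) {
  stopifnot(inherits(comp, "composition"), V > 0, V < 1, box_edge > 0)
  if (is.null(volumes)) {
    volumes <- vapply(comp$structures, molecular_volume, numeric(1))
  }
  stopifnot(length(volumes) == length(comp$labels), all(volumes > 0))
  share <- comp$weights / sum(comp$weights)
  target_volume <- V * box_edge^3
  total <- target_volume / sum(share * volumes)
  raw <- share * total
  counts <- floor(raw)
  rem <- raw - counts
  short <- as.integer(round(sum(raw))) - as.integer(sum(counts))
  if (short > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[bump] <- counts[bump] + 1
  }
  counts <- as.integer(counts)
  if (sum(counts) < 1L) stop("volume fraction too small: no copy fits")
  stats::setNames(counts, comp$labels)
}

#' Initialize a crowded box
#'
#' Copies are placed on the smallest cubic lattice with `n^3 >= N` sites
#' (lattice step `box_edge / n`), each jittered uniformly within half a
#' lattice step per axis and given an independent uniform random
#' rotation. Site occupancy and type assignment are seeded shuffles, so
#' the same seed reproduces the state exactly.
#'
#' @param comp A [composition()].
#' @param V Target volume fraction in (0, 1).
#' @param box_edge Box edge, Angstrom (default 500).
#' @param seed Integer seed.
#' @param volumes Optional per-type envelope volumes (see [copy_counts()]).
#' @return Object of class `crowd_state`: `box_edge`, `labels`,
#'   `types` (integer index per instance), `rot` (3 x 3 x N orientation
#'   array), `centers_wrapped` / `centers_unwrapped` (N x 3),
#'   `energies` (per-instance energy of the last adopted pose, 0 at
#'   start), `radii` (per-instance bounding radii), `volume_fraction`.
#' @export
initialize_crowd <- function(comp, V, box_edge = 500, seed = 1, volumes = NULL) {
  counts <- copy_counts(comp, V, box_edge, volumes)
  n_inst <- sum(counts)
  rs <- .seeded_rng(seed)
  on.exit(rs$restore())
  n_lat <- ceiling(n_inst^(1 / 3) - 1e-9)
  while (n_lat^3 < n_inst) n_lat <- n_lat + 1L
  step <- box_edge / n_lat
  sites <- as.matrix(expand.grid(
    x = (seq_len(n_lat) - 0.5) * step,
    y = (seq_len(n_lat) - 0.5) * step,
    z = (seq_len(n_lat) - 0.5) * step
  ))
  occ <- sort(sample.int(n_lat^3, n_inst))
  centers <- sites[occ, , drop = FALSE] +
    matrix(stats::runif(3 * n_inst, -step / 2, step / 2), n_inst, 3)
  centers <- centers %% box_edge
  types <- sample(rep(seq_along(counts), counts))
  quats <- random_quaternion(n_inst)
  rot <- array(0, dim = c(3, 3, n_inst))
  for (i in seq_len(n_inst)) rot[, , i] <- quaternion_to_matrix(quats[i, ])
  type_radii <- vapply(comp$structures, bounding_radius, numeric(1))
  if (is.null(volumes)) {
    volumes <- vapply(comp$structures, molecular_volume, numeric(1))
  }
  structure(
    list(
      box_edge = box_edge,
      periodic = TRUE,
      labels = comp$labels,
      types = as.integer(types),
      rot = rot,
      centers_wrapped = centers,
      centers_unwrapped = centers,
      energies = numeric(n_inst),
      radii = as.numeric(type_radii[types]),
      type_radii = as.numeric(type_radii),
      type_volumes = as.numeric(volumes),
      counts = counts,
      volume_fraction = sum(counts * volumes) / box_edge^3
    ),
    class = "crowd_state"
  )
}

#' @export
print.crowd_state <- function(x, ...) {
  cat(sprintf(
    "<crowd_state> %d instances of %d types in %g A box (V = %.3f)\n",
    length(x$types), length(x$labels), x$box_edge, x$volume_fraction
  ))
  invisible(x)
}

#' Minimum-image displacement between two points
#'
#' Per-axis displacement `b - a` wrapped into
#' `(-box_edge/2, box_edge/2]`.
#'
#' @param a,b Numeric 3-vectors (or N x 3 matrices), Angstrom.
#' @param box_edge Box edge, Angstrom.
#' @return Displacement(s), same shape as the inputs.
#' @export
minimum_image <- function(a, b, box_edge) {
  d <- b - a
  d - box_edge * ceiling(d / box_edge - 0.5)
}

# Squared minimum-image distances from point `p` to the rows of `centers`.
.min_image_dist2 <- function(p, centers, box_edge) {
  dx <- centers[, 1] - p[1]; dx <- dx - box_edge * ceiling(dx / box_edge - 0.5)
  dy <- centers[, 2] - p[2]; dy <- dy - box_edge * ceiling(dy / box_edge - 0.5)
  dz <- centers[, 3] - p[3]; dz <- dz - box_edge * ceiling(dz / box_edge - 0.5)
  dx * dx + dy * dy + dz * dz
}

#' Neighbor query under periodic boundaries
#'
#' All instances `j != i` whose minimum-image center distance from
#' instance `i` is at most `cutoff`.
#'
#' @param state A `crowd_state`.
#' @param i Instance index.
#' @param cutoff Distance cutoff, Angstrom; either a scalar or a matrix
#'   of per-type-pair cutoffs indexed `[type_i, type_j]`.
#' @return Integer vector of instance indices.
#' @export
neighbors <- function(state, i, cutoff) {
  stopifnot(inherits(state, "crowd_state"), i >= 1, i <= length(state$types))
  d2 <- .min_image_dist2(state$centers_wrapped[i, ], state$centers_wrapped,
                         state$box_edge)
  if (is.matrix(cutoff)) {
    cut <- cutoff[state$types[i], state$types]
  } else {
    cut <- rep(cutoff, length(state$types))
  }
  out <- which(d2 <= cut^2)
  out[out != i]
}

# Default per-type-pair neighbor cutoffs: bounding radii sum + margin.
.default_cutoffs <- function(state, margin = 10) {
  outer(state$type_radii, state$type_radii, `+`) + margin
}
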