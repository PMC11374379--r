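# Independent oracles, deliberately implemented with plain loops and no
# shared code with the package internals they check.

# Brute-force sliding-sum correlation over all shifts where grids overlap.
brute_correlation <- function(rec_cells, lig_cells) {
  nr <- dim(rec_cells); nl <- dim(lig_cells)
  out <- array(0, dim = nr + nl - 1L)
  for (m1 in seq_len(nr[1] + nl[1] - 1L)) {
    d1 <- m1 - nl[1]
    x1 <- max(1L, 1L + d1):min(nr[1], nl[1] + d1)
    for (m2 in seq_len(nr[2] + nl[2] - 1L)) {
      d2 <- m2 - nl[2]
      x2 <- max(1L, 1L + d2):min(nr[2], nl[2] + d2)
      for (m3 in seq_len(nr[3] + nl[3] - 1L)) {
        d3 <- m3 - nl[3]
        x3 <- max(1L, 1L + d3):min(nr[3], nl[3] + d3)
        out[m1, m2, m3] <- sum(rec_cells[x1, x2, x3] *
                                 lig_cells[x1 - d1, x2 - d2, x3 - d3])
      }
    }
  }
  out
}

# Morphological erosion oracle: a cell is core iff every cell within
# Chebyshev distance `thickness` (array boundary counts as empty) is
# occupied. Direct per-cell loop.
brute_erosion <- function(occ, thickness = 1L) {
  nc <- dim(occ)
  core <- array(FALSE, dim = nc)
  for (i in seq_len(nc[1])) for (j in seq_len(nc[2])) for (k in seq_len(nc[3])) {
    if (!occ[i, j, k]) next
    ok <- TRUE
    for (di in -thickness:thickness) for (dj in -thickness:thickness) for (dk in -thickness:thickness) {
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || jj < 1 || kk < 1 || ii > nc[1] || jj > nc[2] || kk > nc[3] ||
          !occ[ii, jj, kk]) {
        ok <- FALSE
        break
      }
    }
    core[i, j, k] <- ok
  }
  core
}

# Minimum-image distance by explicit minimization over the 27 image cells.
brute_min_image_norm <- function(a, b, box) {
  best <- Inf
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
    d <- b + box * c(sx, sy, sz) - a
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

# O(N^2) neighbor scan oracle.
brute_neighbors <- function(centers, i, box, cutoffs) {
  out <- integer(0)
  for (j in seq_len(nrow(centers))) {
    if (j == i) next
    if (brute_min_image_norm(centers[i, ], centers[j, ], box) <= cutoffs[j]) {
      out <- c(out, j)
    }
  }
  out
}

# Union-find connected components over an explicit contact matrix.
brute_components <- function(contact) {
  n <- nrow(contact)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (contact[i, j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(table(roots))
}

# Build a small crowd_state by hand for geometry tests.
manual_state <- function(centers, box_edge, radii = NULL, labels = "a") {
  n <- nrow(centers)
  if (is.null(radii)) radii <- rep(1, n)
  rot <- array(0, dim = c(3, 3, n))
  for (i in seq_len(n)) rot[, , i] <- diag(3)
  structure(
    list(
      box_edge = box_edge, periodic = TRUE, labels = labels,
      types = rep(1L, n), rot = rot,
      centers_wrapped = centers %% box_edge, centers_unwrapped = centers,
      energies = numeric(n), radii = radii, type_radii = max(radii),
      type_volumes = 1, counts = n, volume_fraction = 0.1
    ),
    class = "crowd_state"
  )
}

# Shared small fixtures (built once per test run)
blob_pair_small <- function() {
  list(
    a = make_blob_protein(120, 7, seed = 201, label = "a"),
    b = make_blob_protein(180, 8.5, seed = 202, label = "b")
  )
}
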