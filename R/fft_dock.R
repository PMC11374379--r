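# Grid-based rigid-body docking: a Katchalski-Katzir-style shape
# correlation with a soft-core penalty, scanned over translations by FFT
# and over orientations on a deterministic Euler lattice. The ranked
# low-energy matches define the pairwise intermolecular landscape the MC
# engine hops on.

#' Docking parameters
#'
#' @param grid_step Grid spacing in Angstrom (default 3.5).
#' @param repulsion Core penalty weight (default 9.0): receptor core
#'   cells score `-repulsion`, surface cells `+1`.
#' @param rotation_interval Angular spacing of the orientation lattice in
#'   degrees (default 10).
#' @param top_k Number of lowest-energy matches kept per pair
#'   (default 30000).
#' @param surface_thickness Surface shell thickness in grid cells
#'   (default 1).
#' @param per_rotation_keep Best translations kept per rotation before
#'   the global merge (default 1000).
#' @param max_grid_cells Memory guard: refuse correlation grids larger
#'   than this many cells (default 2^24).
#' @return List of class `dock_params`.
#' @export
dock_params <- function(grid_step = 3.5, repulsion = 9.0,
                        rotation_interval = 10, top_k = 30000,
                        surface_thickness = 1, per_rotation_keep = 1000,
                        max_grid_cells = 2^24) {
  stopifnot(
    grid_step > 0, repulsion >= 0,
    rotation_interval > 0, rotation_interval <= 360,
    top_k >= 1, surface_thickness >= 1, per_rotation_keep >= 1
  )
  structure(
    list(
      grid_step = grid_step, repulsion = repulsion,
      rotation_interval = rotation_interval, top_k = as.integer(top_k),
      surface_thickness = as.integer(surface_thickness),
      per_rotation_keep = as.integer(per_rotation_keep),
      max_grid_cells = max_grid_cells
    ),
    class = "dock_params"
  )
}

# Occupancy array for a structure: a cell is occupied iff it contains an
# atom center or its own center lies inside an atom's vdW sphere.
.occupancy_grid <- function(s, step) {
  xyz <- .coord_matrix(s)
  r <- .vdw_radius(s$atoms$element)
  rmax <- max(r)
  lo <- apply(xyz, 2, min) - rmax
  hi <- apply(xyz, 2, max) + rmax
  nc <- pmax(1L, as.integer(ceiling((hi - lo) / step + 1e-9)))
  occ <- array(FALSE, dim = nc)
  centers <- lapply(1:3, function(a) lo[a] + (seq_len(nc[a]) - 0.5) * step)
  # atom-center cells
  idx <- sapply(1:3, function(a) pmin(nc[a], pmax(1L, floor((xyz[, a] - lo[a]) / step) + 1L)))
  if (is.null(dim(idx))) idx <- matrix(idx, 1, 3)
  occ[idx] <- TRUE
  # cells whose centers fall inside an atom sphere
  for (i in seq_len(nrow(xyz))) {
    ix <- which(abs(centers[[1]] - xyz[i, 1]) <= r[i])
    iy <- which(abs(centers[[2]] - xyz[i, 2]) <= r[i])
    iz <- which(abs(centers[[3]] - xyz[i, 3]) <= r[i])
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (centers[[1]][ix] - xyz[i, 1])^2
    dy2 <- (centers[[2]][iy] - xyz[i, 2])^2
    dz2 <- (centers[[3]][iz] - xyz[i, 3])^2
    sub <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r[i]^2
    occ[ix, iy, iz] <- as.vector(occ[ix, iy, iz]) | as.vector(sub)
  }
  list(occ = occ, origin = lo, step = step)
}

# Erode an occupancy array by a Chebyshev ball of the given radius
# (cells outside the array count as unoccupied).
.erode_occupancy <- function(occ, thickness) {
  core <- occ
  nc <- dim(occ)
  for (dx in -thickness:thickness) for (dy in -thickness:thickness) for (dz in -thickness:thickness) {
    if (dx == 0 && dy == 0 && dz == 0) next
    shifted <- array(FALSE, dim = nc)
    xs <- intersect(seq_len(nc[1]), seq_len(nc[1]) - dx)
    ys <- intersect(seq_len(nc[2]), seq_len(nc[2]) - dy)
    zs <- intersect(seq_len(nc[3]), seq_len(nc[3]) - dz)
    if (!length(xs) || !length(ys) || !length(zs)) {
      core[] <- FALSE
      next
    }
    shifted[xs, ys, zs] <- occ[xs + dx, ys + dy, zs + dz]
    core <- core & shifted
  }
  core
}

#' Build a docking score grid for one protein
#'
#' Discretizes the structure on a cubic grid. For the receptor role,
#' occupied cells within `surface_thickness` shells of an unoccupied
#' cell score `+1` (surface) and deeper cells `-repulsion` (core); for
#' the ligand role every occupied cell scores `+1`.
#'
#' @param s A [protein_structure()].
#' @param params A [dock_params()].
#' @param role `"receptor"` or `"ligand"`.
#' @return List of class `dock_grid`: `origin` (Angstrom position of the
#'   first cell's corner), `step`, `cells` (3-D numeric array), `role`.
#' @export
build_grid <- function(s, params, role = c("receptor", "ligand")) {
  role <- match.arg(role)
  stopifnot(inherits(s, "protein_structure"), inherits(params, "dock_params"))
  g <- .occupancy_grid(s, params$grid_step)
  if (role == "ligand") {
    cells <- array(as.numeric(g$occ), dim = dim(g$occ))
  } else {
    core <- .erode_occupancy(g$occ, params$surface_thickness)
    cells <- array(0, dim = dim(g$occ))
    cells[g$occ & !core] <- 1
    cells[core] <- -params$repulsion
  }
  structure(
    list(origin = g$origin, step = params$grid_step, cells = cells, role = role),
    class = "dock_grid"
  )
}

#' Deterministic orientation lattice
#'
#' z-y-z Euler-angle lattice at the requested angular spacing with
#' polar decimation: the number of alpha values at each beta ring scales
#' with `sin(beta)` so orientations are not oversampled near the poles.
#' The list is identical across runs and platforms.
#'
#' @param interval Angular spacing in degrees (0 < interval <= 360).
#' @return List of orthonormal 3x3 rotation matrices (determinant +1).
#' @export
rotation_set <- function(interval) {
  stopifnot(interval > 0, interval <= 360)
  n_gamma <- max(1L, as.integer(round(360 / interval)))
  betas <- seq(0, 180, by = interval)
  out <- list()
  for (beta in betas) {
    brad <- beta * pi / 180
    n_alpha <- max(1L, as.integer(round(360 / interval * sin(brad))))
    alphas <- (seq_len(n_alpha) - 1L) * 360 / n_alpha
    gammas <- (seq_len(n_gamma) - 1L) * 360 / n_gamma
    for (alpha in alphas) for (gamma in gammas) {
      out[[length(out) + 1L]] <- euler_zyz(alpha * pi / 180, brad, gamma * pi / 180)
    }
  }
  out
}

#' Translation scan of a ligand grid against a receptor grid
#'
#' Computes the correlation `score(d) = sum_x receptor(x) * ligand(x - d)`
#' for every integer cell shift `d` at which the grids can overlap, via
#' zero-padded FFTs. When both grids hold integer values the result is
#' rounded back to exact integers, so the scan is bit-identical to the
#' brute-force sliding sum.
#'
#' @param receptor,ligand `dock_grid` objects with matching `step`.
#' @return List of class `corr_field`: `scores` (3-D array of dimension
#'   `dim(receptor) + dim(ligand) - 1`) and `d_offset` such that entry
#'   `[m1, m2, m3]` is the score at shift `d = m + d_offset` (per axis).
#' @export
correlation_scan <- function(receptor, ligand) {
  stopifnot(inherits(receptor, "dock_grid"), inherits(ligand, "dock_grid"))
  if (abs(receptor$step - ligand$step) > 1e-9) stop("grid step mismatch")
  nr <- dim(receptor$cells)
  nl <- dim(ligand$cells)
  pd <- sapply(nr + nl - 1L, function(n) stats::nextn(n, factors = c(2, 3, 5)))
  rp <- array(0, dim = pd); rp[seq_len(nr[1]), seq_len(nr[2]), seq_len(nr[3])] <- receptor$cells
  lp <- array(0, dim = pd); lp[seq_len(nl[1]), seq_len(nl[2]), seq_len(nl[3])] <- ligand$cells
  cc <- Re(stats::fft(stats::fft(rp) * Conj(stats::fft(lp)), inverse = TRUE)) / prod(pd)
  # circular index k = d mod P  ->  output index m = d + nl (1-based)
  out_dim <- nr + nl - 1L
  take <- lapply(1:3, function(a) {
    d <- (1 - nl[a]):(nr[a] - 1)
    (d %% pd[a]) + 1L
  })
  scores <- cc[take[[1]], take[[2]], take[[3]], drop = FALSE]
  dim(scores) <- out_dim
  if (all(receptor$cells == round(receptor$cells)) &&
      all(ligand$cells == round(ligand$cells))) {
    scores <- round(scores)
  }
  structure(
    list(scores = scores, d_offset = -as.integer(nl)),
    class = "corr_field"
  )
}

#' Dock a protein pair over sampled rotations
#'
#' For each rotation the ligand is rotated about its geometric center,
#' gridded, and scanned against the receptor grid; the energy of a match
#' is minus the correlation score. The best `per_rotation_keep`
#' translations per rotation enter a global merge and the lowest-energy
#' `top_k` poses are returned, sorted ascending by energy with ties
#' broken by rotation index and then lexicographic translation.
#'
#' @param receptor,ligand [protein_structure()] objects.
#' @param params A [dock_params()].
#' @param rotations Optional list of rotation matrices; defaults to
#'   `rotation_set(params$rotation_interval)`.
#' @return A `pose_list` (see [pose_list()]).
#' @export
dock_pair <- function(receptor, ligand, params = dock_params(), rotations = NULL) {
  stopifnot(inherits(receptor, "protein_structure"),
            inherits(ligand, "protein_structure"))
  if (is.null(rotations)) rotations <- rotation_set(params$rotation_interval)
  rec_grid <- build_grid(receptor, params, "receptor")
  c_rec <- geometric_center(receptor)
  c_lig <- geometric_center(ligand)
  h <- params$grid_step
  keep <- params$per_rotation_keep
  acc_energy <- list(); acc_rot <- list(); acc_trans <- list(); acc_ridx <- list()
  for (m in seq_along(rotations)) {
    rot <- rotations[[m]]
    lig_rot <- transform_structure(
      transform_structure(ligand, diag(3), -c_lig), rot, c_lig
    )
    lig_grid <- build_grid(lig_rot, params, "ligand")
    n_tot <- prod(dim(rec_grid$cells) + dim(lig_grid$cells) - 1L)
    if (n_tot > params$max_grid_cells) {
      stop("correlation grid of ", n_tot, " cells exceeds max_grid_cells (",
           params$max_grid_cells, ")")
    }
    cf <- correlation_scan(rec_grid, lig_grid)
    en <- -as.vector(cf$scores)
    nbest <- min(keep, length(en))
    ord <- order(en)[seq_len(nbest)]
    di <- arrayInd(ord, dim(cf$scores))
    d <- sweep(di, 2, cf$d_offset, `+`)  # integer shifts
    # ligand placed with cell y at receptor cell y + d: spatial shift
    # rec_origin - lig_origin + d*h applied to the (center-preserving)
    # rotated ligand, so the center lands at c_lig + shift
    trans <- sweep(d * h, 2, c_lig + rec_grid$origin - lig_grid$origin - c_rec, `+`)
    acc_energy[[m]] <- en[ord]
    acc_trans[[m]] <- trans
    acc_ridx[[m]] <- rep.int(m, nbest)
  }
  energy <- unlist(acc_energy)
  trans <- do.call(rbind, acc_trans)
  ridx <- unlist(acc_ridx)
  ord <- order(energy, ridx, trans[, 1], trans[, 2], trans[, 3])
  ord <- ord[seq_len(min(params$top_k, length(ord)))]
  rot_flat <- t(vapply(ridx[ord], function(m) as.vector(t(rotations[[m]])),
                       numeric(9)))
  pose_list(
    ligand_label = ligand$label,
    receptor_label = receptor$label,
    params = params,
    energies = energy[ord],
    rotations = rot_flat,
    translations = trans[ord, , drop = FALSE]
  )
}
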