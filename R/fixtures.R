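# Synthetic generators with known ground truth: blob proteins, a
# pocket/plug docking pair, ideal Brownian trajectories, and enumerable
# toy landscapes for the Markov-chain stationarity oracle. Everything is
# deterministic under a seed so the rest of the package is testable
# without any external input.

#' Generate a synthetic "blob" protein
#'
#' Atoms are placed uniformly in a ball of the given radius; every fourth
#' atom is flagged as a C-alpha so rotational-vector analyses work.
#' Elements are assigned in protein-like proportions so the synthesized
#' molecular weight scales with atom count. For large `n_atoms` the
#' radius of gyration approaches `radius * sqrt(3/5)`.
#'
#' @param n_atoms Number of atoms (>= 1).
#' @param radius Ball radius in Angstrom.
#' @param seed Integer seed; the same seed gives an identical structure.
#' @param label Structure label.
#' @return A [protein_structure()].
#' @export
make_blob_protein <- function(n_atoms, radius, seed, label = sprintf("blob%d", n_atoms)) {
  stopifnot(n_atoms >= 1, radius > 0)
  rs <- .seeded_rng(seed)
  on.exit(rs$restore())
  # uniform in ball: direction uniform, radius ~ U^(1/3)
  dirs <- random_unit_vectors(n_atoms)
  rad <- radius * stats::runif(n_atoms)^(1 / 3)
  xyz <- dirs * rad
  elements <- sample(c("C", "N", "O", "S"), n_atoms, replace = TRUE,
                     prob = c(0.62, 0.17, 0.18, 0.03))
  is_ca <- (seq_len(n_atoms) - 1L) %% 4L == 0L
  atoms <- data.frame(
    name = ifelse(is_ca, "CA", elements),
    element = elements,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    is_calpha = is_ca,
    stringsAsFactors = FALSE
  )
  protein_structure(label, atoms)
}

#' Generate a receptor/ligand pair with a constructed docking optimum
#'
#' The receptor is a thick-walled cup: a spherical shell of atoms with a
#' conical opening, thick enough that grid erosion leaves a penalized
#' core inside the wall. The ligand is a ball sized to nestle into the
#' cavity, slightly interpenetrating the inner wall so the concentric
#' placement maximizes surface contact all around while any deeper or
#' off-axis press hits core cells. At identity rotation the best
#' shape-complementarity translation is therefore the cavity center,
#' returned as `optimal_translation` (ligand-center offset relative to
#' the receptor's geometric center).
#'
#' @param seed Integer seed (controls the atom-position jitter).
#' @param cavity_radius Inner wall radius in Angstrom (default 10).
#' @param wall_thickness Wall thickness in Angstrom (default 14; keep
#'   above about 3 grid steps so the wall has a core).
#' @param opening_half_angle Half-angle of the conical opening, radians
#'   (default `pi / 4`).
#' @return List with elements `receptor`, `ligand` (both
#'   [protein_structure()]) and `optimal_translation` (3-vector, Angstrom).
#' @export
make_pocket_pair <- function(seed, cavity_radius = 10, wall_thickness = 14,
                             opening_half_angle = pi / 4) {
  rs <- .seeded_rng(seed)
  on.exit(rs$restore())
  spacing <- 2.5
  outer <- cavity_radius + wall_thickness
  g <- seq(-(outer + 1), outer + 1, by = spacing)
  lat <- as.matrix(expand.grid(x = g, y = g, z = g))
  r <- sqrt(rowSums(lat^2))
  costh <- lat[, 1] / pmax(r, 1e-9)
  keep <- r >= cavity_radius & r <= outer & costh < cos(opening_half_angle)
  lat <- lat[keep, , drop = FALSE] +
    matrix(stats::runif(3 * sum(keep), -0.2, 0.2), sum(keep), 3)
  rec_atoms <- data.frame(
    name = "C", element = "C",
    x = lat[, 1], y = lat[, 2], z = lat[, 3],
    is_calpha = seq_len(nrow(lat)) %% 4L == 1L,
    stringsAsFactors = FALSE
  )
  receptor <- protein_structure("pocket_receptor", rec_atoms)
  # ligand: ball slightly wider than the cavity so the concentric pose
  # overlaps the inner surface layer in every direction
  plug_r <- cavity_radius + 0.5
  lx <- seq(-plug_r, plug_r, by = 2.0)
  plat <- as.matrix(expand.grid(x = lx, y = lx, z = lx))
  plat <- plat[sqrt(rowSums(plat^2)) <= plug_r, , drop = FALSE]
  lig_atoms <- data.frame(
    name = "C", element = "C",
    x = plat[, 1], y = plat[, 2], z = plat[, 3],
    is_calpha = seq_len(nrow(plat)) %% 4L == 1L,
    stringsAsFactors = FALSE
  )
  ligand <- protein_structure("pocket_ligand", lig_atoms)
  list(
    receptor = receptor,
    ligand = ligand,
    optimal_translation = c(0, 0, 0) - geometric_center(receptor)
  )
}

#' Generate an ideal Brownian trajectory with known diffusion constants
#'
#' Each copy performs an independent random walk: Gaussian center
#' displacements with per-axis variance `2 * D_t * dt_ns` per step, and
#' orientation updates by small rotations about uniformly random axes
#' with angle standard deviation `sqrt(6 * D_r * dt_ns)` (isotropic
#' rotational diffusion; the tracked-vector angular variance per step is
#' `4 * D_r * dt_ns` and the P2 autocorrelation decays as
#' `exp(-6 * D_r * t)`). The small-angle approximation requires
#' `4 * D_r * dt_ns` to be well below 1; the generator refuses otherwise.
#'
#' @param D_t Translational diffusion coefficient, A^2/ns.
#' @param D_r Rotational diffusion coefficient, 1/ns.
#' @param dt_ns Time per recorded frame, ns.
#' @param n_steps Number of steps (frames = `n_steps + 1`).
#' @param n_copies Number of independent copies.
#' @param seed Integer seed.
#' @param type_label Type label for all copies (default "ideal").
#' @return A `trajectory` object (see [run_mc()]).
#' @export
ideal_trajectory <- function(D_t, D_r, dt_ns, n_steps, n_copies, seed,
                             type_label = "ideal") {
  stopifnot(D_t >= 0, D_r >= 0, dt_ns > 0, n_steps >= 1, n_copies >= 1)
  if (4 * D_r * dt_ns > 0.15) {
    stop("4 * D_r * dt_ns = ", 4 * D_r * dt_ns,
         " violates the small-angle rotational step approximation")
  }
  rs <- .seeded_rng(seed)
  on.exit(rs$restore())
  n_frames <- n_steps + 1L
  centers <- array(0, dim = c(n_frames, 3, n_copies))
  sd_t <- sqrt(2 * D_t * dt_ns)
  for (k in seq_len(n_copies)) {
    steps <- matrix(stats::rnorm(3 * n_steps, sd = sd_t), n_steps, 3)
    centers[, , k] <- rbind(0, apply(steps, 2, cumsum))
  }
  quats <- array(0, dim = c(n_frames, 4, n_copies))
  quats[1, 1, ] <- 1
  if (D_r > 0) {
    sd_r <- sqrt(6 * D_r * dt_ns)
    cur <- matrix(rep(c(1, 0, 0, 0), n_copies), n_copies, 4, byrow = TRUE)
    for (t in seq_len(n_steps)) {
      axes <- random_unit_vectors(n_copies)
      ang <- stats::rnorm(n_copies, sd = sd_r)
      half <- ang / 2
      dq <- cbind(cos(half), axes * sin(half))
      cur <- quaternion_multiply(dq, cur)
      cur <- cur / sqrt(rowSums(cur^2))
      quats[t + 1L, , ] <- t(cur)
    }
  } else {
    for (t in seq_len(n_steps)) quats[t + 1L, 1, ] <- 1
  }
  new_trajectory(
    dt_ns = dt_ns,
    types = rep(type_label, n_copies),
    centers = centers,
    quats = quats,
    box_edge = NA_real_
  )
}

#' Generate an enumerable toy landscape with its exact stationary law
#'
#' Builds a random connected proposal graph over `n_states` states with
#' random energies, then constructs the explicit transition matrix of the
#' minima-hopping chain: from state `m` a neighbor is proposed uniformly
#' among the `N_m` graph neighbors and accepted with the
#' detailed-balance-normalized Metropolis probability
#' `min(1, exp(-(E_j - E_i)/T) * N_i/N_j)`. The exact stationary
#' distribution (the normalized Boltzmann weights, independent of the
#' degrees thanks to the `N_i/N_j` factor) is returned alongside the
#' left-eigenvector check.
#'
#' @param n_states Number of states (>= 2, <= 12 for exact enumeration).
#' @param seed Integer seed.
#' @param temperature Temperature scale (default 100).
#' @param energy_spread Energies are drawn uniformly on
#'   `[0, energy_spread * temperature]` (default 2).
#' @return List of class `toy_landscape`: `energies`, `neighbors` (list of
#'   integer vectors), `temperature`, `transition` (row-stochastic matrix)
#'   and `stationary` (exact stationary probabilities).
#' @export
make_toy_landscape <- function(n_states, seed, temperature = 100,
                               energy_spread = 2) {
  stopifnot(n_states >= 2, n_states <= 12)
  rs <- .seeded_rng(seed)
  on.exit(rs$restore())
  energies <- stats::runif(n_states, 0, energy_spread * temperature)
  # random connected graph: spanning tree + extra edges
  adj <- matrix(FALSE, n_states, n_states)
  perm <- sample.int(n_states)
  for (i in 2:n_states) {
    j <- perm[sample.int(i - 1L, 1L)]
    adj[perm[i], j] <- adj[j, perm[i]] <- TRUE
  }
  n_extra <- sample.int(n_states, 1L)
  for (e in seq_len(n_extra)) {
    ij <- sample.int(n_states, 2L)
    adj[ij[1], ij[2]] <- adj[ij[2], ij[1]] <- TRUE
  }
  neighbors <- lapply(seq_len(n_states), function(i) which(adj[i, ]))
  degree <- lengths(neighbors)
  stopifnot(all(degree >= 1L))
  trans <- matrix(0, n_states, n_states)
  for (i in seq_len(n_states)) {
    for (j in neighbors[[i]]) {
      p_acc <- acceptance_probability(energies[i], energies[j],
                                      degree[i], degree[j], temperature)
      trans[i, j] <- p_acc / degree[i]
    }
    trans[i, i] <- 1 - sum(trans[i, ])
  }
  ev <- eigen(t(trans))
  k <- which.min(abs(ev$values - 1))
  stat <- Re(ev$vectors[, k])
  stat <- stat / sum(stat)
  structure(
    list(
      energies = energies, neighbors = neighbors, temperature = temperature,
      transition = trans, stationary = stat
    ),
    class = "toy_landscape"
  )
}

# Save and restore .Random.seed around seeded generators so fixtures do
# not perturb the caller's RNG stream.
.seeded_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}
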