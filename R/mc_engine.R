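# Minima-hopping Markov chain Monte Carlo: one protein at a time jumps
# to a randomly drawn pre-computed docking match on a randomly drawn
# neighbor, accepted with a Metropolis rule normalized by the ratio of
# available moves so that detailed balance holds on the hop graph.

#' Monte Carlo run parameters
#'
#' @param temperature Energy scale T of the Metropolis rule (default 100,
#'   in docking score units).
#' @param step_time_ns Physical time per MC step, ns (default 20).
#' @param n_steps Number of MC steps.
#' @param record_every Record a trajectory frame every this many steps
#'   (default 1).
#' @param seed Integer seed.
#' @param neighbor_margin Added to the sum of bounding radii to form the
#'   per-pair neighbor cutoff, Angstrom (default 10).
#' @param overlap_tolerance Allowed bounding-sphere overlap with third
#'   proteins, as a fraction of the smaller radius (default 0.4); set
#'   `clash_check = FALSE` to disable the check entirely.
#' @param clash_check Reject moves that overlap a non-receptor instance
#'   beyond `overlap_tolerance` (default `TRUE`).
#' @param sweep_mode One step = one attempted move per instance
#'   (default `TRUE`); `FALSE` gives one attempted move per step.
#' @return List of class `mc_params`.
#' @export
mc_params <- function(temperature = 100, step_time_ns = 20, n_steps = 1000,
                      record_every = 1, seed = 1, neighbor_margin = 10,
                      overlap_tolerance = 0.4, clash_check = TRUE,
                      sweep_mode = TRUE) {
  stopifnot(temperature > 0, step_time_ns > 0, n_steps >= 1, record_every >= 1)
  structure(
    list(
      temperature = temperature, step_time_ns = step_time_ns,
      n_steps = as.integer(n_steps), record_every = as.integer(record_every),
      seed = as.integer(seed), neighbor_margin = neighbor_margin,
      overlap_tolerance = overlap_tolerance, clash_check = clash_check,
      sweep_mode = sweep_mode
    ),
    class = "mc_params"
  )
}

#' Detailed-balance-normalized Metropolis acceptance probability
#'
#' `min(1, exp(-(E_j - E_i) / T) * N_i / N_j)`, where `N_m` is the number
#' of moves available from state `m`. The `N_i / N_j` factor corrects the
#' non-uniform proposal density of the hop graph so the chain's
#' stationary law is the Boltzmann distribution over states.
#'
#' @param E_i,E_j Energies of the current and proposed states.
#' @param N_i,N_j Move counts at the current and proposed states (>= 1).
#' @param temperature Temperature scale T (> 0).
#' @return Probability in `[0, 1]`.
#' @export
acceptance_probability <- function(E_i, E_j, N_i, N_j, temperature) {
  stopifnot(temperature > 0, N_i >= 1, N_j >= 1)
  min(1, exp(-(E_j - E_i) / temperature) * N_i / N_j)
}

#' Propose one minima-hopping move
#'
#' Draws a ligand uniformly over instances, a receptor uniformly over
#' the ligand's neighbors, and a pose uniformly over the pose library of
#' the (ligand type, receptor type) pair; computes the move count at the
#' proposed destination. Uses the current R random stream. Returns
#' `NULL` when the ligand has no neighbors.
#'
#' @param state A `crowd_state`.
#' @param landscapes A `landscape_set` covering all ordered type pairs.
#' @param params An `mc_params`.
#' @return List of class `move_proposal` with fields `ligand`,
#'   `receptor`, `pose`, `E_i`, `E_j`, `N_i`, `N_j`, or `NULL`.
#' @export
propose_move <- function(state, landscapes, params = mc_params()) {
  cutmat <- .default_cutoffs(state, params$neighbor_margin)
  i <- sample.int(length(state$types), 1L)
  nbr <- neighbors(state, i, cutmat)
  if (length(nbr) == 0L) return(NULL)
  j <- nbr[sample.int(length(nbr), 1L)]
  pl <- get_landscape(landscapes, state$labels[state$types[i]],
                      state$labels[state$types[j]])
  pose <- sample_pose(pl)
  dest <- (state$centers_wrapped[j, ] +
             as.vector(state$rot[, , j] %*% pose$translation)) %% state$box_edge
  d2 <- .min_image_dist2(dest, state$centers_wrapped, state$box_edge)
  cut <- cutmat[state$types[i], state$types]
  n_j <- sum(d2 <= cut^2 & seq_along(d2) != i)
  structure(
    list(
      ligand = i, receptor = j, pose = pose,
      E_i = state$energies[i], E_j = pose$energy,
      N_i = length(nbr), N_j = max(1L, n_j),
      destination = dest
    ),
    class = "move_proposal"
  )
}

#' Apply an accepted move to the state
#'
#' The ligand adopts the docked pose in the receptor's frame: its
#' orientation becomes the receptor orientation composed with the pose
#' rotation, and its center the receptor center plus the
#' receptor-rotated pose translation, wrapped into the box. The
#' unwrapped coordinate advances by the minimum-image displacement
#' actually traveled.
#'
#' @param state A `crowd_state`.
#' @param proposal A `move_proposal` from [propose_move()].
#' @return The updated `crowd_state`.
#' @export
apply_move <- function(state, proposal) {
  i <- proposal$ligand
  j <- proposal$receptor
  new_c <- (state$centers_wrapped[j, ] +
              as.vector(state$rot[, , j] %*% proposal$pose$translation)) %% state$box_edge
  disp <- minimum_image(state$centers_wrapped[i, ], new_c, state$box_edge)
  state$centers_unwrapped[i, ] <- state$centers_unwrapped[i, ] + disp
  state$centers_wrapped[i, ] <- new_c
  state$rot[, , i] <- state$rot[, , j] %*% proposal$pose$rotation
  state$energies[i] <- proposal$pose$energy
  state
}

#' Run one attempted MC move (or one sweep) through the reference API
#'
#' Propose, optionally clash-check, then accept with
#' [acceptance_probability()]. Rejected or skipped attempts leave the
#' state unchanged. [run_mc()] uses an equivalent vectorized loop; this
#' entry point exists for stepwise inspection and testing.
#'
#' @param state A `crowd_state`.
#' @param landscapes A `landscape_set`.
#' @param params An `mc_params`.
#' @return List with `state` and logical `accepted`.
#' @export
mc_step <- function(state, landscapes, params = mc_params()) {
  prop <- propose_move(state, landscapes, params)
  if (is.null(prop)) return(list(state = state, accepted = FALSE))
  if (params$clash_check &&
      .clashes(state, prop$ligand, prop$receptor, prop$destination,
               params$overlap_tolerance)) {
    return(list(state = state, accepted = FALSE))
  }
  p <- acceptance_probability(prop$E_i, prop$E_j, prop$N_i, prop$N_j,
                              params$temperature)
  if (stats::runif(1) < p) {
    list(state = apply_move(state, prop), accepted = TRUE)
  } else {
    list(state = state, accepted = FALSE)
  }
}

.clashes <- function(state, i, j, dest, tol) {
  d2 <- .min_image_dist2(dest, state$centers_wrapped, state$box_edge)
  r_i <- state$radii[i]
  lim <- r_i + state$radii - tol * pmin(r_i, state$radii)
  bad <- d2 < lim^2
  bad[c(i, j)] <- FALSE
  any(bad)
}

#' Trajectory container
#'
#' @param dt_ns Physical time per recorded frame, ns.
#' @param types Character vector of per-instance type labels.
#' @param centers `n_frames x 3 x n_instances` array of unwrapped
#'   centers, Angstrom.
#' @param quats `n_frames x 4 x n_instances` array of unit orientation
#'   quaternions (w, x, y, z).
#' @param box_edge Box edge, Angstrom (`NA` for free-space trajectories).
#' @param acceptance_rate,mean_energy Optional run diagnostics.
#' @return Object of class `trajectory`.
#' @export
new_trajectory <- function(dt_ns, types, centers, quats, box_edge = NA_real_,
                           acceptance_rate = NA_real_, mean_energy = NA_real_) {
  stopifnot(length(dim(centers)) == 3, dim(centers)[2] == 3,
            length(dim(quats)) == 3, dim(quats)[2] == 4,
            dim(centers)[1] == dim(quats)[1],
            dim(centers)[3] == length(types))
  structure(
    list(
      dt_ns = dt_ns, types = as.character(types),
      centers = centers, quats = quats, box_edge = box_edge,
      acceptance_rate = acceptance_rate, mean_energy = mean_energy
    ),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d frames x %d instances, dt = %g ns (%.3g us total)%s\n",
    dim(x$centers)[1], dim(x$centers)[3], x$dt_ns,
    (dim(x$centers)[1] - 1) * x$dt_ns / 1000,
    if (is.finite(x$acceptance_rate)) {
      sprintf(", acceptance %.1f%%", 100 * x$acceptance_rate)
    } else ""
  ))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$centers)[1]

#' Run a minima-hopping MC simulation
#'
#' Executes `params$n_steps` steps from the given initial state and
#' records a frame (unwrapped centers + orientation quaternions for all
#' instances) every `params$record_every` steps, plus the initial frame.
#' In sweep mode (default) one step is one attempted move per instance,
#' so every protein moves on the `step_time_ns` scale. Draw order per
#' attempt: ligand index, receptor among neighbors, pose index, then the
#' acceptance uniform.
#'
#' @param state A `crowd_state` from [initialize_crowd()].
#' @param landscapes A `landscape_set` covering all ordered type pairs.
#' @param params An [mc_params()].
#' @param verbose Print an acceptance/energy summary (default `FALSE`).
#' @return A `trajectory`; frame `k` corresponds to time
#'   `(k - 1) * record_every * step_time_ns` ns.
#' @export
run_mc <- function(state, landscapes, params = mc_params(), verbose = FALSE) {
  stopifnot(inherits(state, "crowd_state"), inherits(landscapes, "landscape_set"))
  rs <- .seeded_rng(params$seed)
  on.exit(rs$restore())
  n_inst <- length(state$types)
  n_types <- length(state$labels)
  box <- state$box_edge
  temp <- params$temperature
  tol <- params$overlap_tolerance
  do_clash <- params$clash_check
  # flatten landscapes into indexable tables
  energies_tab <- vector("list", n_types * n_types)
  rot_tab <- vector("list", n_types * n_types)
  trans_tab <- vector("list", n_types * n_types)
  for (a in seq_len(n_types)) for (b in seq_len(n_types)) {
    pl <- get_landscape(landscapes, state$labels[a], state$labels[b])
    key <- (a - 1L) * n_types + b
    energies_tab[[key]] <- pl$energies
    rot_tab[[key]] <- pl$rotations
    trans_tab[[key]] <- pl$translations
  }
  cutmat <- .default_cutoffs(state, params$neighbor_margin)
  cut2 <- cutmat[, state$types, drop = FALSE]^2  # [type, instance]
  cw <- state$centers_wrapped
  cu <- state$centers_unwrapped
  rot <- state$rot
  en <- state$energies
  radii <- state$radii
  types <- state$types
  idx <- seq_len(n_inst)
  attempts_per_step <- if (params$sweep_mode) n_inst else 1L
  n_rec <- params$n_steps %/% params$record_every + 1L
  centers_rec <- array(NA_real_, dim = c(n_rec, 3, n_inst))
  quats_rec <- array(NA_real_, dim = c(n_rec, 4, n_inst))
  record <- function(frame) {
    centers_rec[frame, , ] <<- t(cu)
    for (ii in idx) quats_rec[frame, , ii] <<- matrix_to_quaternion(rot[, , ii])
  }
  record(1L)
  frame <- 1L
  n_acc <- 0L; n_att <- 0L
  for (step in seq_len(params$n_steps)) {
    for (att in seq_len(attempts_per_step)) {
      n_att <- n_att + 1L
      i <- sample.int(n_inst, 1L)
      ti <- types[i]
      d2 <- .min_image_dist2(cw[i, ], cw, box)
      nbr_mask <- d2 <= cut2[ti, ]
      nbr_mask[i] <- FALSE
      n_i <- sum(nbr_mask)
      if (n_i == 0L) next
      nbr <- idx[nbr_mask]
      j <- nbr[sample.int(n_i, 1L)]
      key <- (ti - 1L) * n_types + types[j]
      evec <- energies_tab[[key]]
      k <- sample.int(length(evec), 1L)
      a_j <- rot[, , j]
      t_lab <- a_j %*% trans_tab[[key]][k, ]
      dest <- (cw[j, ] + as.vector(t_lab)) %% box
      d2new <- .min_image_dist2(dest, cw, box)
      dest_mask <- d2new <= cut2[ti, ]
      dest_mask[i] <- FALSE
      n_j <- sum(dest_mask)
      if (n_j == 0L) n_j <- 1L
      if (do_clash) {
        lim <- radii[i] + radii - tol * pmin(radii[i], radii)
        bad <- d2new < lim^2
        bad[c(i, j)] <- FALSE
        if (any(bad)) next
      }
      e_j <- evec[k]
      p_acc <- min(1, exp(-(e_j - en[i]) / temp) * n_i / n_j)
      if (stats::runif(1) < p_acc) {
        disp <- minimum_image(cw[i, ], dest, box)
        cu[i, ] <- cu[i, ] + disp
        cw[i, ] <- dest
        rot[, , i] <- a_j %*% matrix(rot_tab[[key]][k, ], 3, 3, byrow = TRUE)
        en[i] <- e_j
        n_acc <- n_acc + 1L
      }
    }
    if (step %% params$record_every == 0L) {
      frame <- frame + 1L
      record(frame)
    }
  }
  if (verbose) {
    message(sprintf("run_mc: %d steps, acceptance %.1f%%, mean energy %.2f",
                    params$n_steps, 100 * n_acc / n_att, mean(en)))
  }
  new_trajectory(
    dt_ns = params$step_time_ns * params$record_every,
    types = state$labels[types],
    centers = centers_rec, quats = quats_rec, box_edge = box,
    acceptance_rate = n_acc / n_att, mean_energy = mean(en)
  )
}

#' Run the minima-hopping chain on an enumerable toy landscape
#'
#' Simulates the exact chain whose transition matrix
#' [make_toy_landscape()] constructs: uniform proposal over graph
#' neighbors, acceptance by [acceptance_probability()]. Used to verify
#' that empirical occupancies converge to the Boltzmann stationary law.
#'
#' @param landscape A `toy_landscape`.
#' @param n_steps Number of steps.
#' @param seed Integer seed.
#' @param start Starting state (default 1).
#' @return List with `occupancy` (visit fractions over states) and
#'   `final_state`.
#' @export
run_toy_chain <- function(landscape, n_steps, seed, start = 1L) {
  stopifnot(inherits(landscape, "toy_landscape"), n_steps >= 1)
  rs <- .seeded_rng(seed)
  on.exit(rs$restore())
  nbrs <- landscape$neighbors
  deg <- lengths(nbrs)
  n_states <- length(deg)
  temp <- landscape$temperature
  en <- landscape$energies
  # precompute pairwise acceptance probabilities over graph edges
  acc <- matrix(0, n_states, n_states)
  for (i in seq_len(n_states)) for (j in nbrs[[i]]) {
    acc[i, j] <- acceptance_probability(en[i], en[j], deg[i], deg[j], temp)
  }
  visits <- integer(n_states)
  cur <- as.integer(start)
  chunk <- 100000L
  done <- 0L
  while (done < n_steps) {
    n <- min(chunk, n_steps - done)
    u_prop <- stats::runif(n)
    u_acc <- stats::runif(n)
    for (t in seq_len(n)) {
      cand <- nbrs[[cur]][floor(u_prop[t] * deg[cur]) + 1L]
      if (u_acc[t] < acc[cur, cand]) cur <- cand
      visits[cur] <- visits[cur] + 1L
    }
    done <- done + n
  }
  list(occupancy = visits / n_steps, final_state = cur)
}

#' Write a trajectory to a TSV file
#'
#' '#'-prefixed header (format version, box edge, frame time, instance
#' table), then one row per frame: step index followed by
#' `x y z qw qx qy qz` for each instance.
#'
#' @param traj A `trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  ni <- dim(traj$centers)[3]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# crowdhop-trajectory v1",
    sprintf("# box_edge\t%.17g", traj$box_edge),
    sprintf("# dt_ns\t%.17g", traj$dt_ns),
    sprintf("# n_instances\t%d", ni),
    sprintf("# instance\t%d\t%s", seq_len(ni), traj$types)
  ), con)
  block <- matrix(NA_real_, nf, 7 * ni)
  for (i in seq_len(ni)) {
    block[, (i - 1) * 7 + 1:3] <- traj$centers[, , i]
    block[, (i - 1) * 7 + 4:7] <- traj$quats[, , i]
  }
  tab <- cbind(seq_len(nf) - 1L, block)
  utils::write.table(
    format(tab, digits = 10, scientific = FALSE, trim = TRUE),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path Path to a trajectory TSV.
#' @return A `trajectory`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  if (!length(hdr) || !grepl("^# crowdhop-trajectory v1", hdr[1])) {
    stop("not a crowdhop trajectory file: ", path)
  }
  box <- as.numeric(sub("^# box_edge\t", "", hdr[startsWith(hdr, "# box_edge\t")]))
  dt <- as.numeric(sub("^# dt_ns\t", "", hdr[startsWith(hdr, "# dt_ns\t")]))
  inst <- hdr[startsWith(hdr, "# instance\t")]
  types <- sub("^# instance\t[0-9]+\t", "", inst)
  ni <- length(types)
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t")
  if (ncol(tab) != 1 + 7 * ni) stop("malformed trajectory rows in ", path)
  nf <- nrow(tab)
  centers <- array(NA_real_, dim = c(nf, 3, ni))
  quats <- array(NA_real_, dim = c(nf, 4, ni))
  for (i in seq_len(ni)) {
    centers[, , i] <- as.matrix(tab[, 1 + (i - 1) * 7 + 1:3])
    quats[, , i] <- as.matrix(tab[, 1 + (i - 1) * 7 + 4:7])
  }
  new_trajectory(dt_ns = dt, types = types, centers = centers, quats = quats,
                 box_edge = box)
}
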