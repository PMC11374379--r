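# A self-contained scaled-down crowding study on synthetic proteins:
# three blob proteins sized like the villin / protein G / ubiquitin
# triplet are docked, simulated across volume fractions, and analyzed.
# Used by the test suite and the acceptance script; also a worked
# example of the full pipeline.

#' Synthetic three-protein mixture (villin / protein G / ubiquitin analogs)
#'
#' Blob proteins with ball radii chosen so their radii of gyration match
#' the real triplet (7.3, 10.6, 11.8 Angstrom) and atom counts roughly
#' proportional to molecular weight. Entirely synthetic stand-ins: no
#' experimental coordinates are used.
#'
#' @return Named list of three [protein_structure()] objects
#'   (`vil`, `gb1`, `ubq`).
#' @export
mix3_structures <- function() {
  list(
    vil = make_blob_protein(300, 9.4, seed = 101, label = "vil"),
    gb1 = make_blob_protein(460, 13.7, seed = 102, label = "gb1"),
    ubq = make_blob_protein(630, 15.2, seed = 103, label = "ubq")
  )
}

#' Run the scaled-down heterogeneous-crowding study
#'
#' Docks all ordered pairs of the synthetic 3-mix at coarse settings,
#' simulates the mixture at volume fractions 0.10 / 0.20 / 0.30 (plus
#' 0.25 for the mixture-vs-self comparison) with replica seeds derived
#' from `seed`, and computes per-type translational diffusion
#' coefficients, Cohen-Turnbull slowdown fits, and the relative
#' heterogeneous-vs-self rate of the smallest protein.
#'
#' @param seed Integer base seed for all stochastic stages.
#' @param n_sweeps MC sweeps per run (default 800).
#' @param n_replicas Replicas per condition (default 2).
#' @param box_edge Box edge, Angstrom (default 170).
#' @param rotation_interval Docking rotation interval, degrees
#'   (default 40).
#' @param top_k Poses kept per pair (default 5000).
#' @param verbose Print progress (default `FALSE`).
#' @return List with `D_t` (data.frame: type, V, D_t), `ct_fits`
#'   (per-type `cohen_turnbull_fit`), `slowdown_v020` (named vector of
#'   normalized D(0.2)/D0 per type), `vil_mix_v025` / `vil_self_v025`
#'   (villin-analog D_t in the mixture and self-crowded at V = 0.25),
#'   `relative_rate_vil` and `acceptance` (per-run rates).
#' @export
run_mix3_study <- function(seed = 1, n_sweeps = 800, n_replicas = 2,
                           box_edge = 170, rotation_interval = 40,
                           top_k = 5000, verbose = FALSE) {
  blobs <- mix3_structures()
  vols <- vapply(blobs, molecular_volume, numeric(1))
  dp <- dock_params(rotation_interval = rotation_interval, top_k = top_k,
                    per_rotation_keep = 300)
  pls <- list()
  for (a in names(blobs)) for (b in names(blobs)) {
    pls[[length(pls) + 1L]] <- dock_pair(blobs[[a]], blobs[[b]], dp)
    if (verbose) message("docked ", b, " -> ", a)
  }
  landscapes <- landscape_set(pls)

  acceptance <- numeric(0)
  run_system <- function(structs, V, seed_offset) {
    comp <- composition(structs)
    v <- vols[names(structs)]
    lapply(seq_len(n_replicas), function(r) {
      s <- seed + seed_offset + r
      st <- initialize_crowd(comp, V, box_edge, seed = s, volumes = v)
      tr <- run_mc(st, landscapes,
                   mc_params(n_steps = n_sweeps, seed = s + 500))
      acceptance[[length(acceptance) + 1L]] <<- tr$acceptance_rate
      if (verbose) {
        message(sprintf("V = %.2f replica %d: acceptance %.1f%%",
                        V, r, 100 * tr$acceptance_rate))
      }
      tr
    })
  }
  dt_of <- function(trajs, ty) {
    fit_dt(msd_curve(trajs, ty, mode = "sliding", lags = 1:40))
  }

  v_grid <- c(0.10, 0.20, 0.30)
  rows <- list()
  for (vi in seq_along(v_grid)) {
    trs <- run_system(blobs, v_grid[vi], seed_offset = 10 * vi)
    for (ty in names(blobs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        type = ty, V = v_grid[vi], D_t = dt_of(trs, ty),
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  ct_fits <- lapply(names(blobs), function(ty) {
    sub <- tab[tab$type == ty, ]
    fit_cohen_turnbull(sub$V, sub$D_t)
  })
  names(ct_fits) <- names(blobs)
  slowdown <- vapply(ct_fits, function(f) predict(f, 0.2, normalized = TRUE),
                     numeric(1))

  trs_mix25 <- run_system(blobs, 0.25, seed_offset = 100)
  trs_self25 <- run_system(blobs["vil"], 0.25, seed_offset = 200)
  vil_mix <- dt_of(trs_mix25, "vil")
  vil_self <- dt_of(trs_self25, "vil")

  list(
    D_t = tab,
    ct_fits = ct_fits,
    slowdown_v020 = slowdown,
    vil_mix_v025 = vil_mix,
    vil_self_v025 = vil_self,
    relative_rate_vil = relative_rate(vil_mix, vil_self),
    acceptance = acceptance
  )
}
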