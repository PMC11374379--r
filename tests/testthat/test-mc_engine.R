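# Metropolis rule, move mechanics, chain stationarity, trajectory
# recording and persistence.

# tiny fully-connected system with a flat single-pose landscape
flat_system <- function(n = 3, box = 60, pose_translation = c(10, 0, 0),
                        energy = -5) {
  s <- make_blob_protein(40, 5, seed = 900, label = "t")
  pl <- pose_list("t", "t", dock_params(),
                  energies = energy,
                  rotations = matrix(as.vector(t(diag(3))), 1, 9),
                  translations = matrix(pose_translation, 1, 3))
  centers <- matrix(stats::runif(3 * n, 25, 35), n, 3)
  st <- manual_state(centers, box, radii = rep(bounding_radius(s), n),
                     labels = "t")
  st$type_radii <- bounding_radius(s)
  list(state = st, landscapes = landscape_set(list(pl)), structure = s)
}

test_that("acceptance probability matches the closed forms and clamps at one", {
  expect_equal(acceptance_probability(3, 3, 5, 5, 100), 1)
  expect_equal(acceptance_probability(0, 100 * log(2), 4, 4, 100), 0.5)
  expect_equal(acceptance_probability(100 * log(10), 0, 1, 4, 100), 1)  # min(1, 2.5)
  # invariance under a constant energy shift
  for (sh in c(-1000, 3.7, 250)) {
    expect_equal(acceptance_probability(10 + sh, 35 + sh, 2, 7, 100),
                 acceptance_probability(10, 35, 2, 7, 100))
  }
  expect_error(acceptance_probability(0, 0, 0, 1, 100))
  expect_error(acceptance_probability(0, 0, 1, 1, -1))
})

test_that("a ligand with no neighbors yields no proposal", {
  fs <- flat_system(n = 1)
  set.seed(1)
  expect_null(propose_move(fs$state, fs$landscapes, mc_params()))
})

test_that("ligand selection is uniform and the proposal stream is seed-reproducible", {
  fs <- flat_system(n = 3)
  set.seed(5)
  picks <- replicate(3000, propose_move(fs$state, fs$landscapes)$ligand)
  freq <- tabulate(picks, 3) / 3000
  sigma <- sqrt((1 / 3) * (2 / 3) / 3000)
  expect_true(all(abs(freq - 1 / 3) < 4 * sigma))
  set.seed(11)
  a <- replicate(10, unlist(propose_move(fs$state, fs$landscapes)[c("ligand", "receptor")]))
  set.seed(11)
  b <- replicate(10, unlist(propose_move(fs$state, fs$landscapes)[c("ligand", "receptor")]))
  expect_identical(a, b)
})

test_that("applying a move composes the receptor frame correctly", {
  fs <- flat_system(n = 2)
  st <- fs$state
  st$centers_wrapped[1, ] <- c(30, 30, 30)
  st$centers_unwrapped[1, ] <- c(30, 30, 30)
  mk_prop <- function(receptor_rot, translation) {
    st$rot[, , 1] <- receptor_rot
    prop <- list(
      ligand = 2L, receptor = 1L,
      pose = list(rotation = diag(3), translation = translation,
                  energy = -5, index = 1L),
      E_i = 0, E_j = -5, N_i = 1L, N_j = 1L
    )
    apply_move(st, prop)
  }
  # identity receptor frame: ligand lands at receptor + translation
  st2 <- mk_prop(diag(3), c(10, 0, 0))
  expect_equal(st2$centers_wrapped[2, ], c(40, 30, 30))
  # receptor rotated 90 degrees about z: (10,0,0) maps to (0,10,0)
  rz90 <- euler_zyz(pi / 2, 0, 0)
  st3 <- mk_prop(rz90, c(10, 0, 0))
  expect_equal(st3$centers_wrapped[2, ], c(30, 40, 30), tolerance = 1e-9)
  # isometry: ligand-receptor distance equals |pose translation| for
  # random receptor frames
  set.seed(3)
  for (i in 1:20) {
    rr <- quaternion_to_matrix(random_quaternion(1)[1, ])
    tv <- stats::runif(3, -8, 8)
    st4 <- mk_prop(rr, tv)
    d <- st4$centers_wrapped[2, ] - st4$centers_wrapped[1, ]
    expect_equal(sqrt(sum(d^2)), sqrt(sum(tv^2)), tolerance = 1e-9)
  }
  # unwrapped coordinate advances by the minimum-image displacement
  expect_equal(st2$centers_unwrapped[2, ] %% st2$box_edge,
               st2$centers_wrapped[2, ], tolerance = 1e-9)
})

test_that("at infinite temperature with flat landscape every proposed move is accepted", {
  fs <- flat_system(n = 4)
  p <- mc_params(temperature = 1e12, clash_check = FALSE, seed = 2)
  set.seed(2)
  acc <- replicate(200, mc_step(fs$state, fs$landscapes, p)$accepted)
  expect_true(all(acc))
})

test_that("the chain reaches the exact two-state stationary distribution", {
  # 2 states, energy gap T*ln 3, symmetric proposals: odds 3:1
  tl <- structure(
    list(
      energies = c(0, 100 * log(3)), neighbors = list(2L, 1L),
      temperature = 100,
      transition = NULL, stationary = c(0.75, 0.25)
    ),
    class = "toy_landscape"
  )
  res <- run_toy_chain(tl, 2e5, seed = 21)
  expect_equal(res$occupancy, c(0.75, 0.25), tolerance = 0.02)
})

test_that("empirical occupancy matches the explicit transition-matrix stationary law", {
  tl <- make_toy_landscape(7, seed = 40)
  # stationary vector is a left fixed point and sums to one
  expect_equal(sum(tl$stationary), 1, tolerance = 1e-12)
  expect_lt(max(abs(as.vector(tl$stationary %*% tl$transition) - tl$stationary)),
            1e-12)
  res <- run_toy_chain(tl, 5e5, seed = 41)
  tv <- 0.5 * sum(abs(res$occupancy - tl$stationary))
  expect_lt(tv, 0.02)
})

test_that("runs are seed-deterministic with the declared frame bookkeeping", {
  fs <- flat_system(n = 5)
  p <- mc_params(n_steps = 40, record_every = 1, seed = 13, step_time_ns = 20)
  tr1 <- run_mc(fs$state, fs$landscapes, p)
  tr2 <- run_mc(fs$state, fs$landscapes, p)
  expect_identical(tr1$centers, tr2$centers)
  expect_identical(tr1$quats, tr2$quats)
  expect_equal(n_frames(tr1), 41L)  # record_every = 1: n_steps + 1 frames
  # 10000 steps at 20 ns = 200 us trajectory duration
  expect_equal(10000 * 20 / 1000, 200)
  p3 <- mc_params(n_steps = 40, record_every = 10, seed = 13)
  expect_equal(n_frames(run_mc(fs$state, fs$landscapes, p3)), 5L)
  # distinct replica seeds give distinct trajectories
  p4 <- mc_params(n_steps = 40, seed = 14)
  tr3 <- run_mc(fs$state, fs$landscapes, p4)
  expect_false(identical(tr1$centers, tr3$centers))
})

test_that("wrapped and unwrapped coordinates stay congruent along the run", {
  fs <- flat_system(n = 6)
  p <- mc_params(n_steps = 60, seed = 8)
  tr <- run_mc(fs$state, fs$landscapes, p)
  box <- tr$box_edge
  last <- tr$centers[n_frames(tr), , ] %% box
  expect_true(all(last >= 0 & last < box))
  # quaternions stay unit norm
  qn <- apply(tr$quats, c(1, 3), function(q) sum(q^2))
  expect_equal(max(abs(qn - 1)), 0, tolerance = 1e-9)
})

test_that("trajectory files round trip", {
  tr <- ideal_trajectory(0.05, 0.001, 20, 50, 3, seed = 2)
  tr$box_edge <- 100
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  tr2 <- read_trajectory(path)
  expect_equal(tr2$dt_ns, tr$dt_ns)
  expect_equal(tr2$types, tr$types)
  expect_equal(tr2$centers, tr$centers, tolerance = 1e-6)
  expect_equal(tr2$quats, tr$quats, tolerance = 1e-6)
  expect_error(read_trajectory(tempfile()), "no such file")
})
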