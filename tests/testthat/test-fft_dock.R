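# Grid docking: occupancy/erosion, rotation sampling, FFT correlation
# against the brute-force sliding sum, and pair docking.

random_grid <- function(dims, values = 0:2, seed) {
  set.seed(seed)
  structure(
    list(origin = c(0, 0, 0), step = 3.5,
         cells = array(sample(values, prod(dims), replace = TRUE), dim = dims),
         role = "receptor"),
    class = "dock_grid"
  )
}

test_that("a single small atom occupies exactly one cell, labeled surface", {
  one <- protein_structure("one", data.frame(
    name = "C", element = "C", x = 0.3, y = -0.2, z = 0.1, is_calpha = FALSE
  ))
  p <- dock_params(grid_step = 3.5)
  g <- build_grid(one, p, "receptor")
  expect_equal(sum(g$cells != 0), 1L)
  expect_equal(max(g$cells), 1)  # surface score, not core
  gl <- build_grid(one, p, "ligand")
  expect_true(all(gl$cells %in% c(0, 1)))
  expect_equal(sum(gl$cells), 1)
})

test_that("surface/core labels match the brute-force erosion oracle on a solid ball", {
  set.seed(42)
  pts <- as.matrix(expand.grid(x = seq(-9, 9, 1.5), y = seq(-9, 9, 1.5),
                               z = seq(-9, 9, 1.5)))
  pts <- pts[sqrt(rowSums(pts^2)) <= 9, ]
  ball <- protein_structure("ball", data.frame(
    name = "C", element = "C", x = pts[, 1], y = pts[, 2], z = pts[, 3],
    is_calpha = FALSE
  ))
  p <- dock_params(grid_step = 3.0, repulsion = 9)
  g <- build_grid(ball, p, "receptor")
  occ <- g$cells != 0
  core_oracle <- brute_erosion(occ, 1L)
  expect_true(all((g$cells == -9) == core_oracle))
  expect_true(all((g$cells == 1) == (occ & !core_oracle)))
  expect_gt(sum(core_oracle), 0)  # the ball is big enough to have a core
  # repulsion = 0 collapses the receptor grid to binary values
  g0 <- build_grid(ball, dock_params(grid_step = 3.0, repulsion = 0), "receptor")
  expect_true(all(g0$cells %in% c(0, 1)))
})

test_that("rotation lattice is deterministic, orthonormal, and counted by closed form", {
  expect_equal(rotation_set(360), list(diag(3)))
  rots <- rotation_set(30)
  for (m in rots) {
    expect_lt(max(abs(crossprod(m) - diag(3))), 1e-10)
    expect_equal(det(m), 1, tolerance = 1e-10)
  }
  # independent enumeration of the polar-decimated z-y-z lattice count
  count_oracle <- function(interval) {
    n_gamma <- max(1, round(360 / interval))
    total <- 0
    for (beta in seq(0, 180, by = interval)) {
      total <- total + max(1, round(360 / interval * sin(beta * pi / 180))) * n_gamma
    }
    total
  }
  expect_length(rotation_set(30), count_oracle(30))
  expect_length(rotation_set(10), count_oracle(10))
  expect_identical(rotation_set(45), rotation_set(45))
})

test_that("correlation scan: delta kernel reproduces the receptor grid, zero ligand annihilates", {
  rec <- random_grid(c(5, 4, 6), seed = 1)
  delta <- random_grid(c(1, 1, 1), seed = 2)
  delta$cells[] <- 1
  cf <- correlation_scan(rec, delta)
  expect_equal(dim(cf$scores), dim(rec$cells))
  expect_equal(cf$scores, rec$cells)
  zero <- random_grid(c(3, 3, 3), seed = 3)
  zero$cells[] <- 0
  expect_true(all(correlation_scan(rec, zero)$scores == 0))
  bad <- random_grid(c(2, 2, 2), seed = 4)
  bad$step <- 1
  expect_error(correlation_scan(rec, bad), "step mismatch")
})

test_that("FFT correlation equals the brute-force sliding sum exactly on random integer grids", {
  set.seed(99)
  for (rep in 1:20) {
    dr <- sample(2:12, 3, replace = TRUE)
    dl <- sample(1:8, 3, replace = TRUE)
    rec <- random_grid(dr, values = c(-9L, 0L, 1L), seed = 1000 + rep)
    lig <- random_grid(dl, values = 0:1, seed = 2000 + rep)
    cf <- correlation_scan(rec, lig)
    expect_identical(cf$scores, brute_correlation(rec$cells, lig$cells))
  }
})

test_that("dock_pair with identity rotation matches the brute-force best translation energy", {
  bp <- blob_pair_small()
  p <- dock_params(top_k = 10, per_rotation_keep = 10)
  pl <- dock_pair(bp$a, bp$b, p, rotations = list(diag(3)))
  rec_grid <- build_grid(bp$a, p, "receptor")
  lig_grid <- build_grid(bp$b, p, "ligand")
  best_score <- max(brute_correlation(rec_grid$cells, lig_grid$cells))
  expect_equal(pl$energies[1], -best_score)
  expect_false(is.unsorted(pl$energies))
})

test_that("pocket fixture: rank-1 pose lands within one grid step of the constructed optimum", {
  pp <- make_pocket_pair(seed = 8)
  p <- dock_params(top_k = 100, per_rotation_keep = 100)
  pl <- dock_pair(pp$receptor, pp$ligand, p, rotations = list(diag(3)))
  err <- sqrt(sum((pl$translations[1, ] - pp$optimal_translation)^2))
  expect_lte(err, p$grid_step)
})

test_that("top_k beyond the scored pose count returns everything, still sorted", {
  bp <- blob_pair_small()
  p <- dock_params(top_k = 1e7, per_rotation_keep = 50)
  pl <- dock_pair(bp$a, bp$b, p, rotations = rotation_set(180))
  expect_lte(n_poses(pl), 50 * length(rotation_set(180)))
  expect_false(is.unsorted(pl$energies))
  expect_lte(n_poses(pl), p$top_k)
})

test_that("score spectrum is invariant under joint rigid translation of both proteins", {
  bp <- blob_pair_small()
  p <- dock_params(top_k = 30, per_rotation_keep = 30)
  pl1 <- dock_pair(bp$a, bp$b, p, rotations = list(diag(3)))
  shift <- c(7.3, -2.1, 4.4)
  a2 <- transform_structure(bp$a, diag(3), shift)
  b2 <- transform_structure(bp$b, diag(3), shift)
  pl2 <- dock_pair(a2, b2, p, rotations = list(diag(3)))
  # identical up to one-cell discretization jitter: compare best energies loosely
  expect_lt(abs(pl1$energies[1] - pl2$energies[1]) /
              max(1, abs(pl1$energies[1])), 0.2)
})

test_that("oversized correlation grids are refused, not truncated", {
  bp <- blob_pair_small()
  p <- dock_params(top_k = 5, max_grid_cells = 10)
  expect_error(dock_pair(bp$a, bp$b, p, rotations = list(diag(3))),
               "max_grid_cells")
})
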