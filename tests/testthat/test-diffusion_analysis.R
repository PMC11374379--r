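# MSD and ACF estimators, the Einstein and tumbling relations, and the
# concentration/size fits.

# hand-built trajectory: constant velocity v A/frame along x, 1 copy
ballistic_trajectory <- function(v, n_frames, dt_ns) {
  centers <- array(0, dim = c(n_frames, 3, 1))
  centers[, 1, 1] <- (seq_len(n_frames) - 1) * v
  quats <- array(0, dim = c(n_frames, 4, 1))
  quats[, 1, ] <- 1
  new_trajectory(dt_ns = dt_ns, types = "b", centers = centers, quats = quats)
}

test_that("MSD is zero for a static trajectory and quadratic for ballistic motion", {
  static <- ballistic_trajectory(0, 200, 20)
  m <- msd_curve(static, "b", ref_time_us = 2)
  expect_true(all(m$msd == 0))
  expect_equal(fit_dt(m), 0)
  v_per_frame <- 0.5  # A per 20 ns frame
  bal <- msd_curve(ballistic_trajectory(v_per_frame, 300, 20), "b",
                   ref_time_us = 2)
  v_per_ns <- v_per_frame / 20
  expect_equal(bal$msd, (v_per_ns * bal$lag_ns)^2, tolerance = 1e-9)
  expect_error(msd_curve(static, "nope"), "unknown type")
  expect_error(msd_curve(ballistic_trajectory(0, 50, 20), "b", ref_time_us = 2),
               "shorter than the reference")
})

test_that("an exact Einstein line returns D to machine precision", {
  m <- structure(
    list(lag_ns = seq(20, 2000, by = 20),
         msd = 6 * 0.123 * seq(20, 2000, by = 20),
         n_copies = 1L, mode = "fixed", dt_ns = 20),
    class = "msd_curve"
  )
  expect_equal(fit_dt(m), 0.123, tolerance = 1e-12)
})

test_that("Brownian trajectories recover D_t within tolerance in both MSD modes", {
  tr <- ideal_trajectory(D_t = 0.05, D_r = 0, dt_ns = 20, n_steps = 2e4,
                         n_copies = 30, seed = 7)
  d_slide <- fit_dt(msd_curve(tr, "ideal", mode = "sliding"))
  expect_equal(d_slide, 0.05, tolerance = 0.05)
  d_fixed <- fit_dt(msd_curve(tr, "ideal", ref_time_us = 2, mode = "fixed"))
  expect_equal(d_fixed, 0.05, tolerance = 0.35)  # single-origin: noisy estimator
  # D_t invariant under global rotation of all coordinates
  rot <- euler_zyz(0.4, 1.0, -0.8)
  tr_rot <- tr
  for (i in seq_len(dim(tr$centers)[3])) {
    tr_rot$centers[, , i] <- tr$centers[, , i] %*% t(rot)
  }
  expect_equal(fit_dt(msd_curve(tr_rot, "ideal", mode = "sliding")), d_slide,
               tolerance = 1e-9)
})

test_that("unit conversion between A^2/ns and um^2/s is the exact constant", {
  # 1 A^2/ns = 1e-20 m^2 / 1e-9 s = 1e-11 m^2/s = 10 um^2/s
  expect_equal(dt_to_um2s(1), 10)
  expect_equal(dt_to_um2s(0.05), 0.5)
})

test_that("P2 autocorrelation: frozen orientation gives C = 1, a 90-degree flip gives -1/2", {
  frozen <- ideal_trajectory(0.01, 0, 20, 100, 2, seed = 1)
  a <- rotational_acf(frozen, "ideal", n_vectors = 4, max_lag = 10)
  expect_true(all(abs(a$C - 1) < 1e-9))
  expect_error(fit_exponential(a), "does not decay|noise floor")
  # two frames: identity then 90-degree rotation about z, vector on the equator
  centers <- array(0, dim = c(2, 3, 1))
  quats <- array(0, dim = c(2, 4, 1))
  quats[1, , 1] <- c(1, 0, 0, 0)
  quats[2, , 1] <- matrix_to_quaternion(euler_zyz(pi / 2, 0, 0))
  tr <- new_trajectory(20, "t", centers, quats)
  st <- protein_structure("t", data.frame(
    name = c("C", "CA"), element = "C", x = c(0, 2), y = 0, z = 0,
    is_calpha = c(FALSE, TRUE)
  ))
  a2 <- rotational_acf(tr, "t", n_vectors = 1, structure = st, max_lag = 1)
  expect_equal(a2$C[2], -0.5, tolerance = 1e-9)
  expect_error(rotational_acf(tr, "t", structure = protein_structure("x",
    data.frame(name = "C", element = "C", x = 0, y = 0, z = 0,
               is_calpha = FALSE))), "no C-alpha")
})

test_that("FFT and direct ACF routes agree to rounding", {
  tr <- ideal_trajectory(0.05, 0.002, 5, 1500, 3, seed = 44)
  set.seed(2)
  a1 <- rotational_acf(tr, "ideal", n_vectors = 4, max_lag = 25,
                       method = "direct")
  set.seed(2)
  a2 <- rotational_acf(tr, "ideal", n_vectors = 4, max_lag = 25,
                       method = "fft")
  expect_equal(a1$C, a2$C, tolerance = 1e-12)
})

test_that("exponential ACF fit: exact recovery, degenerate failure, noisy tolerance", {
  t <- seq(0, 400, by = 20)
  exact <- structure(list(lag_ns = t, C = 0.9 * exp(-t / 100), dt_ns = 20),
                     class = "acf_curve")
  f <- fit_exponential(exact)
  expect_equal(f$S, 0.9, tolerance = 1e-6)
  expect_equal(f$tau_ns, 100, tolerance = 1e-6)
  set.seed(9)
  noisy <- structure(list(lag_ns = t, C = 0.9 * exp(-t / 100) +
                            stats::rnorm(length(t), 0, 0.01), dt_ns = 20),
                     class = "acf_curve")
  expect_equal(fit_exponential(noisy)$tau_ns, 100, tolerance = 0.05)
  flat <- structure(list(lag_ns = t, C = rep(1, length(t)), dt_ns = 20),
                    class = "acf_curve")
  expect_error(fit_exponential(flat), "does not decay")
})

test_that("tumbling relation D_r = 1/(l(l+1) tau)", {
  f <- structure(list(S = 1, tau_ns = 1 / 6), class = "exp_fit")
  expect_equal(dr_from_tau(f), 1)
  expect_equal(dr_from_tau(structure(list(S = 1, tau_ns = 1 / 3),
                                     class = "exp_fit")),
               dr_from_tau(f) / 2)
  expect_equal(dr_from_tau(0.5, l = 1), 1)
})

test_that("rotational walk with known D_r decays as exp(-6 D_r t) and is recovered", {
  tr <- ideal_trajectory(D_t = 0, D_r = 0.001, dt_ns = 5, n_steps = 2e4,
                         n_copies = 20, seed = 12)
  a <- rotational_acf(tr, "ideal", n_vectors = 10, max_lag = 120)
  f <- fit_exponential(a)
  expect_equal(dr_from_tau(f), 0.001, tolerance = 0.1)
  expect_equal(f$S, 1, tolerance = 0.05)
})

test_that("Cohen-Turnbull fit recovers noiseless parameters exactly and decays monotonically", {
  V <- c(0.1, 0.15, 0.2, 0.25, 0.3)
  D <- 100 * exp(-2 * V / (1 - V))
  f <- fit_cohen_turnbull(V, D)
  expect_equal(coef(f), c(D0 = 100, alpha = 2), tolerance = 1e-9)
  expect_equal(predict(f, 0), 100)  # V = 0 limit is the dilute rate
  curve <- predict(f, seq(0.05, 0.45, by = 0.05), normalized = TRUE)
  expect_true(all(diff(curve) < 0))
  expect_error(fit_cohen_turnbull(c(0.1, 0.2), c(1, 2)), ">= 3 distinct")
  expect_error(fit_cohen_turnbull(c(0.1, 0.2, 1.2), c(1, 2, 3)), "lie in")
})

test_that("cytoplasm fit recovers a = 0.56 from noiseless synthetic data", {
  Mw <- c(5e3, 1e4, 3e4, 8e4, 2e5)
  r_p <- 0.0515 * Mw^0.392 * 10
  base <- 5.1^2 / 420^2 + 5.1^2 / r_p^2
  D0 <- 100
  a_true <- 0.56
  D_t <- D0 * exp(-base^(-a_true / 2))
  f <- fit_cytoplasm(Mw, D_t, D0)
  expect_equal(f$a, a_true, tolerance = 1e-3)
  expect_equal(predict(f, Mw, D0), D_t, tolerance = 1e-6)
  # r_p power law: doubling Mw scales r_p by 2^0.392
  expect_equal(f$r_p[2] / f$r_p[1], 2^0.392, tolerance = 1e-9)
  expect_error(fit_cytoplasm(Mw, rep(D0, 5), rep(D0, 5)), "no slowdown")
})

test_that("power-law exponent: exact synthetic, constant, and Stokes-Einstein limits", {
  Mw <- c(4e3, 9e3, 2e4, 6e4, 1.5e5)
  expect_equal(coef(fit_power_law(Mw, 3000 * Mw^-0.67)), c(beta = 0.67),
               tolerance = 1e-9)
  expect_equal(fit_power_law(Mw, rep(5, 5))$beta, 0, tolerance = 1e-12)
  expect_equal(fit_power_law(Mw, 200 * Mw^(-1 / 3))$beta, 1 / 3,
               tolerance = 1e-9)
  expect_error(fit_power_law(Mw, c(-1, 1, 1, 1, 1)), "positive")
})

test_that("relative mixture/self rates", {
  expect_equal(relative_rate(1, 1), 0)
  expect_equal(relative_rate(2, 1), 1)
  expect_equal(relative_rate(0.5, 1), -0.5)
  expect_error(relative_rate(1, 0), "positive")
})

test_that("cluster sizes equal union-find components of the contact graph", {
  # all distant: singletons
  far <- manual_state(rbind(c(0, 0, 0), c(40, 0, 0), c(0, 40, 0)), 100,
                      radii = rep(2, 3))
  expect_equal(cluster_sizes(far), c(1L, 1L, 1L))
  # touching linear chain
  chain <- manual_state(cbind(seq(0, 36, by = 3.9), 0, 0), 100,
                        radii = rep(2, 10))
  expect_equal(cluster_sizes(chain), 10L)
  # random configuration vs brute-force union-find
  set.seed(23)
  centers <- matrix(stats::runif(60 * 3, 0, 50), 60, 3)
  st <- manual_state(centers, 50, radii = rep(3, 60))
  contact <- matrix(FALSE, 60, 60)
  for (i in 1:59) for (j in (i + 1):60) {
    contact[i, j] <- brute_min_image_norm(centers[i, ] %% 50,
                                          centers[j, ] %% 50, 50) <= 6
  }
  expect_equal(sort(cluster_sizes(st)), sort(brute_components(contact)))
})
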