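# Diffusion analysis: translational coefficients from mean-square
# displacements (Einstein relation), rotational coefficients from the P2
# orientational autocorrelation and its exponential tumbling fit, and
# the concentration/size fits (Cohen-Turnbull slowdown, cytoplasm length
# scales, molecular-weight power law, homo- vs hetero-crowding rates).

AA2_PER_NS_TO_UM2_PER_S <- 10  # 1 A^2/ns = 1e-11 m^2/s = 10 um^2/s

#' Mean-square displacement curve
#'
#' Squared displacement of each copy's unwrapped center from its
#' position at the reference time, averaged over copies. The default
#' single fixed reference (2 us into the run) discards the
#' equilibration transient; `mode = "sliding"` instead averages over all
#' time origins at the requested lags, which is the statistically
#' efficient estimator for stationary trajectories.
#'
#' @param traj A `trajectory` (or list of replica trajectories, averaged
#'   together).
#' @param type_label Protein type to analyze.
#' @param ref_time_us Reference time in microseconds (default 2); used
#'   by `mode = "fixed"`.
#' @param mode `"fixed"` (single reference frame) or `"sliding"`
#'   (all origins).
#' @param lags Integer frame lags to evaluate in sliding mode; defaults
#'   to about 50 lags up to a quarter of the trajectory.
#' @return Object of class `msd_curve`: `lag_ns`, `msd` (A^2),
#'   `n_copies`, `mode`.
#' @export
msd_curve <- function(traj, type_label, ref_time_us = 2,
                      mode = c("fixed", "sliding"), lags = NULL) {
  mode <- match.arg(mode)
  trajs <- if (inherits(traj, "trajectory")) list(traj) else traj
  stopifnot(length(trajs) >= 1, all(vapply(trajs, inherits, TRUE, "trajectory")))
  dt <- trajs[[1]]$dt_ns
  nf <- min(vapply(trajs, n_frames, integer(1)))
  sel <- lapply(trajs, function(tr) which(tr$types == type_label))
  if (sum(lengths(sel)) == 0L) stop("unknown type label: ", type_label)
  if (mode == "fixed") {
    ref <- as.integer(round(ref_time_us * 1000 / dt)) + 1L
    if (ref >= nf) stop("trajectory shorter than the reference time")
    lag_idx <- seq_len(nf - ref)
    acc <- numeric(length(lag_idx))
    ncop <- 0L
    for (r in seq_along(trajs)) {
      x <- trajs[[r]]$centers
      for (i in sel[[r]]) {
        d <- sweep(x[ref + lag_idx, , i, drop = TRUE], 2, x[ref, , i], `-`)
        acc <- acc + rowSums(d^2)
        ncop <- ncop + 1L
      }
    }
    out <- list(lag_ns = lag_idx * dt, msd = acc / ncop,
                n_copies = ncop, mode = mode, dt_ns = dt)
  } else {
    if (is.null(lags)) {
      lmax <- max(10L, (nf - 1L) %/% 100L)
      lmax <- min(lmax, nf - 1L)
      lags <- unique(pmax(1L, as.integer(round(seq(1, lmax, length.out = 50)))))
    }
    acc <- numeric(length(lags))
    ncop <- 0L
    for (r in seq_along(trajs)) {
      x <- trajs[[r]]$centers
      for (i in sel[[r]]) {
        xi <- x[, , i, drop = TRUE]
        for (li in seq_along(lags)) {
          k <- lags[li]
          d <- xi[(1 + k):nf, , drop = FALSE] - xi[1:(nf - k), , drop = FALSE]
          acc[li] <- acc[li] + mean(rowSums(d^2))
        }
        ncop <- ncop + 1L
      }
    }
    out <- list(lag_ns = lags * dt, msd = acc / ncop,
                n_copies = ncop, mode = mode, dt_ns = dt)
  }
  structure(out, class = "msd_curve")
}

#' Translational diffusion coefficient from an MSD curve
#'
#' Least-squares slope of MSD versus lag time through the origin,
#' divided by 6 (Einstein relation in three dimensions).
#'
#' @param msd An `msd_curve`.
#' @return `D_t` in A^2/ns.
#' @export
fit_dt <- function(msd) {
  stopifnot(inherits(msd, "msd_curve"), length(msd$lag_ns) >= 2)
  t <- msd$lag_ns
  if (all(t == 0)) stop("degenerate MSD curve: all lags zero")
  sum(t * msd$msd) / sum(t * t) / 6
}

#' Convert a diffusion coefficient from A^2/ns to um^2/s
#'
#' @param d_aa2_ns Coefficient in A^2/ns.
#' @return Coefficient in um^2/s (exactly 10 x the input).
#' @export
dt_to_um2s <- function(d_aa2_ns) d_aa2_ns * AA2_PER_NS_TO_UM2_PER_S

#' Rotational P2 autocorrelation curve
#'
#' For each copy, body-fixed unit vectors (toward randomly chosen
#' C-alpha atoms when a structure is supplied, otherwise random unit
#' vectors) are propagated by the recorded orientations;
#' `C(k dt) = < P2(v(t + k dt) . v(t)) >` averaged over vectors, time
#' origins and copies, with `P2(x) = (3 x^2 - 1) / 2`.
#'
#' @param traj A `trajectory` (or list of replica trajectories).
#' @param type_label Protein type to analyze.
#' @param n_vectors Unit vectors per copy (default 10).
#' @param structure Optional [protein_structure()]; its C-alpha
#'   directions from the geometric center define the body vectors.
#' @param max_lag Largest frame lag (default: min(200, frames/2)).
#' @param method `"auto"` (FFT for long trajectories), `"fft"` or
#'   `"direct"`. The FFT route uses the identity
#'   `sum_t (v(t+k).v(t))^2 = sum_jl autocorr(v_j v_l)(k)` over the six
#'   quadratic coordinate products, so all lags come from six FFT
#'   autocorrelations per vector; both routes compute the same average.
#' @return Object of class `acf_curve`: `lag_ns`, `C`, `n_copies`.
#' @export
rotational_acf <- function(traj, type_label, n_vectors = 10,
                           structure = NULL, max_lag = NULL,
                           method = c("auto", "fft", "direct")) {
  method <- match.arg(method)
  trajs <- if (inherits(traj, "trajectory")) list(traj) else traj
  stopifnot(all(vapply(trajs, inherits, TRUE, "trajectory")))
  dt <- trajs[[1]]$dt_ns
  nf <- min(vapply(trajs, n_frames, integer(1)))
  if (nf < 2L) stop("need at least 2 frames")
  if (is.null(max_lag)) max_lag <- min(200L, nf %/% 2L)
  max_lag <- min(max_lag, nf - 1L)
  if (method == "auto") method <- if (nf > 2000L) "fft" else "direct"
  if (!is.null(structure)) {
    ca <- which(structure$atoms$is_calpha)
    if (!length(ca)) stop("structure has no C-alpha atoms")
    ctr <- geometric_center(structure)
    pick <- ca[sample.int(length(ca), min(n_vectors, length(ca)))]
    vb <- sweep(as.matrix(structure$atoms[pick, c("x", "y", "z")]), 2, ctr)
    vb <- vb / sqrt(rowSums(vb^2))
  } else {
    vb <- random_unit_vectors(n_vectors)
  }
  acc <- numeric(max_lag + 1L)
  cnt <- numeric(max_lag + 1L)
  npad <- stats::nextn(2L * nf, factors = 2)
  for (r in seq_along(trajs)) {
    tr <- trajs[[r]]
    for (i in which(tr$types == type_label)) {
      q <- tr$quats[seq_len(nf), , i, drop = TRUE]
      for (v in seq_len(nrow(vb))) {
        vt <- quaternion_rotate_vector(q, vb[v, ])
        if (method == "fft") {
          # sum_t dot_t^2 over origins, all lags at once
          s2 <- numeric(max_lag + 1L)
          for (jl in list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))) {
            w <- vt[, jl[1]] * vt[, jl[2]]
            wf <- stats::fft(c(w, numeric(npad - nf)))
            ac <- Re(stats::fft(wf * Conj(wf), inverse = TRUE))[1:(max_lag + 1L)] / npad
            s2 <- s2 + if (jl[1] == jl[2]) ac else 2 * ac
          }
          acc <- acc + 1.5 * s2 - 0.5 * (nf - 0:max_lag)
          cnt <- cnt + (nf - 0:max_lag)
        } else {
          for (k in 0:max_lag) {
            dots <- rowSums(vt[(1 + k):nf, , drop = FALSE] *
                              vt[1:(nf - k), , drop = FALSE])
            acc[k + 1L] <- acc[k + 1L] + sum(1.5 * dots^2 - 0.5)
            cnt[k + 1L] <- cnt[k + 1L] + (nf - k)
          }
        }
      }
    }
  }
  if (all(cnt == 0)) stop("unknown type label: ", type_label)
  structure(
    list(lag_ns = (0:max_lag) * dt, C = acc / cnt,
         n_copies = NA_integer_, dt_ns = dt),
    class = "acf_curve"
  )
}

#' Exponential fit of a rotational ACF
#'
#' Nonlinear least squares of `C(t) = S * exp(-t / tau)` over the lags
#' with `C` above the noise floor. Non-decaying data raise an error
#' rather than returning a spurious time constant.
#'
#' @param acf An `acf_curve`.
#' @param floor Fit-window threshold on C (default 0.05).
#' @return Object of class `exp_fit` with `S` (order parameter) and
#'   `tau_ns` (correlation time).
#' @export
fit_exponential <- function(acf, floor = 0.05) {
  stopifnot(inherits(acf, "acf_curve"))
  keep <- acf$C > floor
  # fit window: contiguous run from lag 0 while above the floor
  if (any(!keep)) keep[min(which(!keep)):length(keep)] <- FALSE
  t <- acf$lag_ns[keep]
  y <- acf$C[keep]
  if (length(t) < 3L) stop("fewer than 3 ACF points above the noise floor")
  pos <- y > 0
  slope <- unname(stats::coef(stats::lm(log(y[pos]) ~ t[pos]))[2])
  if (!is.finite(slope) || slope >= -1e-12) {
    stop("ACF does not decay; exponential fit is not identifiable")
  }
  start <- list(S = unname(min(1, max(y))), tau = -1 / slope)
  fit <- minpack.lm::nlsLM(
    y ~ S * exp(-t / tau), start = start,
    lower = c(S = 1e-6, tau = 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  co <- stats::coef(fit)
  if (co[["tau"]] > 100 * max(t)) {
    stop("ACF does not decay within the fit window")
  }
  structure(
    list(S = unname(co[["S"]]), tau_ns = unname(co[["tau"]]),
         n_points = length(t)),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> S = %.4f, tau = %.2f ns (%d points)\n",
              x$S, x$tau_ns, x$n_points))
  invisible(x)
}

#' Rotational diffusion coefficient from a correlation time
#'
#' `D_r = 1 / (l (l + 1) tau)` with `l = 2` for the P2 autocorrelation.
#'
#' @param fit An `exp_fit`, or a correlation time in ns.
#' @param l Legendre order (default 2).
#' @return `D_r` in 1/ns.
#' @export
dr_from_tau <- function(fit, l = 2) {
  tau <- if (inherits(fit, "exp_fit")) fit$tau_ns else fit
  stopifnot(tau > 0, l >= 1)
  1 / (l * (l + 1) * tau)
}

#' Cohen-Turnbull fit of concentration slowdown
#'
#' Least squares of the free-volume expression
#' `D(V) = D_0 * exp(-alpha * V / (1 - V))` to diffusion coefficients
#' measured at several volume fractions.
#'
#' @param V Volume fractions in (0, 1) (>= 3 distinct values) -- or a
#'   two-column data.frame of (V, D).
#' @param D Diffusion coefficients (same units as the returned `D0`).
#' @return Object of class `cohen_turnbull_fit` with `D0`, `alpha`,
#'   `fitted`, `residuals`; supports `coef()` and `predict()` (which
#'   also returns the normalized curve via `normalized = TRUE`).
#' @export
fit_cohen_turnbull <- function(V, D = NULL) {
  if (is.data.frame(V)) { D <- V[[2]]; V <- V[[1]] }
  stopifnot(length(V) == length(D), all(D > 0))
  if (any(V >= 1) || any(V < 0)) stop("volume fractions must lie in [0, 1)")
  if (length(unique(V)) < 3L) stop("need >= 3 distinct volume fractions")
  x <- V / (1 - V)
  lin <- stats::lm(log(D) ~ x)
  start <- list(D0 = exp(stats::coef(lin)[[1]]), alpha = -stats::coef(lin)[[2]])
  fit <- minpack.lm::nlsLM(
    D ~ D0 * exp(-alpha * x), start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  co <- stats::coef(fit)
  structure(
    list(
      D0 = unname(co[["D0"]]), alpha = unname(co[["alpha"]]),
      V = V, D = D, fitted = stats::fitted(fit),
      residuals = stats::residuals(fit)
    ),
    class = "cohen_turnbull_fit"
  )
}

#' @export
print.cohen_turnbull_fit <- function(x, ...) {
  cat(sprintf("<cohen_turnbull_fit> D0 = %.4g, alpha = %.4g (RMS residual %.3g)\n",
              x$D0, x$alpha, sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' @export
coef.cohen_turnbull_fit <- function(object, ...) {
  c(D0 = object$D0, alpha = object$alpha)
}

#' @export
predict.cohen_turnbull_fit <- function(object, V = object$V,
                                       normalized = FALSE, ...) {
  d <- object$D0 * exp(-object$alpha * V / (1 - V))
  if (normalized) d / object$D0 else d
}

#' Cytoplasm length-scale fit of diffusion versus molecular weight
#'
#' Fits `ln(D_0 / D_t) = (xi^2 / R_h^2 + xi^2 / r_p^2)^(-a/2)` with the
#' hydrodynamic radius parameterized as `r_p = 0.0515 * Mw^0.392` (nm,
#' converted to Angstrom) and the cytoplasm length scales `R_h` and `xi`
#' held fixed; the single free parameter `a` is found by bounded
#' least-squares minimization.
#'
#' @param Mw Molecular weights, Da (>= 2 proteins).
#' @param D_t Crowded diffusion coefficients.
#' @param D0 Dilute diffusion coefficients (scalar or per-protein).
#' @param R_h Cytoplasm hydrodynamic length, Angstrom (default 420).
#' @param xi Cytoplasm mesh length, Angstrom (default 5.1).
#' @param upper Upper bound for `a` (default 5).
#' @return Object of class `cytoplasm_fit` with `a`, `r_p` (Angstrom)
#'   and the fitted curve; supports `coef()` and `predict()`.
#' @export
fit_cytoplasm <- function(Mw, D_t, D0, R_h = 420, xi = 5.1, upper = 5) {
  stopifnot(length(Mw) >= 2, all(Mw > 0), all(D_t > 0), all(D0 > 0))
  lhs <- log(D0 / D_t)
  if (all(abs(lhs) < 1e-12)) {
    stop("no slowdown to fit: D_t equals D0 for every protein")
  }
  r_p <- 0.0515 * Mw^0.392 * 10  # nm -> Angstrom
  base <- xi^2 / R_h^2 + xi^2 / r_p^2
  obj <- function(a) sum((lhs - base^(-a / 2))^2)
  opt <- stats::optimize(obj, interval = c(1e-6, upper))
  a <- opt$minimum
  if (a > upper - 1e-4) {
    warning("cytoplasm fit hit the upper bound for a")
  }
  structure(
    list(
      a = a, R_h = R_h, xi = xi, Mw = Mw, r_p = r_p,
      fitted_lhs = base^(-a / 2), lhs = lhs, sse = opt$objective
    ),
    class = "cytoplasm_fit"
  )
}

#' @export
print.cytoplasm_fit <- function(x, ...) {
  cat(sprintf("<cytoplasm_fit> a = %.4f (R_h = %g A, xi = %g A, SSE %.3g)\n",
              x$a, x$R_h, x$xi, x$sse))
  invisible(x)
}

#' @export
coef.cytoplasm_fit <- function(object, ...) c(a = object$a)

#' @export
predict.cytoplasm_fit <- function(object, Mw = object$Mw, D0 = 1, ...) {
  r_p <- 0.0515 * Mw^0.392 * 10
  base <- object$xi^2 / object$R_h^2 + object$xi^2 / r_p^2
  D0 * exp(-base^(-object$a / 2))
}

#' Power-law exponent of diffusion versus molecular weight
#'
#' Fits `D_t = c * Mw^(-beta)` by least squares on the log-log scale and
#' returns `beta` (0.33 is the Stokes-Einstein limit for a homogeneous
#' medium; crowded cytoplasm gives steeper exponents).
#'
#' @param Mw Molecular weights, Da.
#' @param D_t Diffusion coefficients (> 0).
#' @return Object of class `power_law_fit` with `beta` and `prefactor`.
#' @export
fit_power_law <- function(Mw, D_t) {
  stopifnot(length(Mw) >= 2, length(Mw) == length(D_t))
  if (any(Mw <= 0) || any(D_t <= 0)) stop("Mw and D_t must be positive")
  fit <- stats::lm(log(D_t) ~ log(Mw))
  structure(
    list(beta = -unname(stats::coef(fit)[2]),
         prefactor = exp(unname(stats::coef(fit)[1]))),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> beta = %.4f\n", x$beta))
  invisible(x)
}

#' @export
coef.power_law_fit <- function(object, ...) c(beta = object$beta)

#' Relative normalized diffusion rate (mixture vs self-crowding)
#'
#' `(d_mix - d_self) / d_self`: positive when a protein diffuses faster
#' in the heterogeneous mixture than in its self-crowded solution.
#'
#' @param d_mix,d_self Normalized diffusion rates (`d_self > 0`).
#' @return Dimensionless relative rate.
#' @export
relative_rate <- function(d_mix, d_self) {
  if (any(d_self <= 0)) stop("d_self must be positive")
  (d_mix - d_self) / d_self
}

#' Cluster size distribution of a crowded state
#'
#' Two instances are in contact when their minimum-image center distance
#' is at most the sum of their bounding radii plus `slack`; clusters are
#' the connected components of the contact graph.
#'
#' @param state A `crowd_state`.
#' @param slack Additional contact slack, Angstrom (default 0).
#' @return Integer vector of component sizes (one entry per cluster).
#' @export
cluster_sizes <- function(state, slack = 0) {
  stopifnot(inherits(state, "crowd_state"))
  n <- length(state$types)
  if (n == 1L) return(1L)
  edges <- integer(0)
  for (i in seq_len(n - 1L)) {
    d2 <- .min_image_dist2(state$centers_wrapped[i, ],
                           state$centers_wrapped[(i + 1):n, , drop = FALSE],
                           state$box_edge)
    lim <- state$radii[i] + state$radii[(i + 1):n] + slack
    hit <- which(d2 <= lim^2)
    if (length(hit)) edges <- c(edges, rbind(i, i + hit))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  as.integer(igraph::components(g)$csize)
}
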