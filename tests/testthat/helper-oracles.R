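# Shared fixtures and independent oracles for the test suite.

g2_cal <- function() suppressWarnings(oxyphor_calibration("G2"))
r0_cal <- function() suppressWarnings(oxyphor_calibration("R0"))
rat_curve <- function() suppressWarnings(dissociation_curve())
dk_lit <- function() 1.97e-10 * 60

# compact scene for fast end-to-end tests (defaults otherwise)
small_scene <- function(noise_sigma = 0, seed = 7, curvature_sag_px = 3, ...) {
  build_scene(height_px = 60, depth_px = 60, retina_thickness_um = 144,
              interface_apex_px = 45, curvature_sag_px = curvature_sag_px,
              noise_sigma = noise_sigma, seed = seed,
              vessels = data.frame(label = c("artery", "vein"),
                                   center_y = c(15, 45), radius = 4,
                                   po2 = c(41, 25)),
              ...)
}

std_run_config <- function(input_dir, out_dir, seed = 1L) {
  list(input_dir = input_dir, out_dir = out_dir, seed = seed,
       calibration = list(tissue = list(tau0_s = 251e-6, kq = 281),
                          vascular = list(tau0_s = 637e-6, kq = 381)),
       curve = list(p50_mmHg = 36, hill_n = 2.7, hb_capacity = 0.2,
                    solubility = 3e-5),
       dk = dk_lit())
}

# Finite-difference / P1 finite-element oracle for the three-layer boundary
# value problem: Dk P'' = Q on [0, L], P(0) = pc, P(L) = pl, Q = q2 on
# [x1, x2], else 0. The source enters through exact tent-function (hat) load
# integration, the standard P1 Galerkin load vector; the tridiagonal system is
# solved with the Thomas algorithm. Entirely independent of the closed-form
# segment solution.
fd_three_layer <- function(params, n = 2000) {
  L <- params$L_um * 1e-4
  h <- L / (n - 1)
  xs <- seq(0, L, length.out = n)
  a <- params$x1_frac * L
  b <- params$x2_frac * L
  k <- params$q2 / params$Dk

  # integral of the hat centered at xj over [a, b] (source support)
  hat_integral <- function(xj) {
    # rising branch on [xj - h, xj]: t -> 1 - (xj - t)/h
    lo <- max(xj - h, a); hi <- min(xj, b)
    ri <- if (hi > lo) {
      Fi <- function(t) t * (1 - xj / h) + t^2 / (2 * h)
      Fi(hi) - Fi(lo)
    } else 0
    # falling branch on [xj, xj + h]: t -> 1 - (t - xj)/h
    lo <- max(xj, a); hi <- min(xj + h, b)
    fa <- if (hi > lo) {
      Ff <- function(t) t * (1 + xj / h) - t^2 / (2 * h)
      Ff(hi) - Ff(lo)
    } else 0
    ri + fa
  }

  m <- n - 2
  rhs <- numeric(m)
  for (j in seq_len(m)) {
    # node index j + 1; hat-weighted mean source over its support
    rhs[j] <- h^2 * k * hat_integral(xs[j + 1]) / h
  }
  rhs[1] <- rhs[1] - params$pc_mmHg
  rhs[m] <- rhs[m] - params$pl_mmHg
  # u_{j-1} - 2 u_j + u_{j+1} = h^2 f_j  (Thomas algorithm)
  diag_main <- rep(-2, m)
  cp <- numeric(m); dp <- numeric(m)
  cp[1] <- 1 / diag_main[1]
  dp[1] <- rhs[1] / diag_main[1]
  for (j in 2:m) {
    denom <- diag_main[j] - cp[j - 1]
    cp[j] <- 1 / denom
    dp[j] <- (rhs[j] - dp[j - 1]) / denom
  }
  u <- numeric(m)
  u[m] <- dp[m]
  for (j in (m - 1):1) u[j] <- dp[j] - cp[j] * u[j + 1]
  list(x_frac = xs / L, po2 = c(params$pc_mmHg, u, params$pl_mmHg))
}

# Dense grid search + local refinement over tau minimizing the SSE of the
# homodyne forward model (with A and B fit linearly at each tau). Independent
# of the cosine-basis estimator.
grid_tau_oracle <- function(intensities, phases_deg, freq_hz,
                            tau_max = 1e-3, n_grid = 4000) {
  th <- phases_deg * pi / 180
  omega <- 2 * pi * freq_hz
  sse_at <- function(tau) {
    X <- cbind(1, cos(th - atan(omega * tau)))
    sum(stats::lm.fit(X, intensities)$residuals^2)
  }
  taus <- seq(tau_max / n_grid, tau_max, length.out = n_grid)
  sses <- vapply(taus, sse_at, numeric(1))
  i <- which.min(sses)
  lo <- taus[max(1, i - 1)]; hi <- taus[min(n_grid, i + 1)]
  stats::optimize(sse_at, c(lo, hi), tol = 1e-14)$minimum
}
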