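#' Three-layer outer-retinal oxygen diffusion model parameters
#'
#' The outer retina is modeled as a one-dimensional slab of thickness `L_um`
#' with oxygen diffusing in from the choroid at the chorioretinal interface
#' (position x = 0) toward the boundary with the inner retina (x = L, the 50%
#' retinal-depth point). The slab is split into three layers by fractional
#' positions `x1_frac < x2_frac`: oxygen consumption is negligible in layers 1
#' (photoreceptor outer segments, x < x1) and 3 (outer nuclear layer, x > x2)
#' and constant (`q2`) in layer 2 (photoreceptor inner segments, where the
#' mitochondria sit). At steady state \eqn{Dk \, d^2P/dx^2 = Q(x)} with
#' Dirichlet boundary tensions `pc_mmHg` at the choroid and `pl_mmHg` at the
#' inner boundary, giving a linear-quadratic-linear tension profile.
#'
#' @param pc_mmHg Oxygen tension at the chorioretinal interface, mmHg.
#' @param pl_mmHg Oxygen tension at the outer/inner retinal boundary, mmHg.
#' @param x1_frac,x2_frac Layer boundaries as fractions of `L_um`, measured
#'   from the chorioretinal interface; `0 <= x1 < x2 <= 1`.
#' @param q2 Oxygen consumption rate in layer 2, mL O2 per mL tissue per min.
#' @param L_um Outer retinal thickness, micrometres.
#' @param Dk Oxygen diffusivity-solubility product, mL O2 cm^-1 min^-1 mmHg^-1.
#'   Defaults to [default_dk()] (with its warning).
#' @return An object of class `three_layer_params`.
#' @seealso [three_layer_po2()], [fit_three_layer()]
#' @export
three_layer_params <- function(pc_mmHg, pl_mmHg, x1_frac, x2_frac, q2, L_um,
                               Dk = NULL) {
  Dk <- Dk %||% default_dk()
  stopifnot(is.numeric(pc_mmHg), pc_mmHg >= 0,
            is.numeric(pl_mmHg), pl_mmHg >= 0,
            x1_frac >= 0, x1_frac < x2_frac, x2_frac <= 1,
            q2 >= 0, L_um > 0, Dk > 0)
  structure(list(pc_mmHg = pc_mmHg, pl_mmHg = pl_mmHg,
                 x1_frac = x1_frac, x2_frac = x2_frac,
                 q2 = q2, L_um = L_um, Dk = Dk),
            class = "three_layer_params")
}

#' @export
print.three_layer_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<three_layer_params> pc = %.2f, pl = %.2f mmHg; x1 = %.3f, x2 = %.3f; ",
    "q2 = %.4f mL O2/mL/min; L = %.1f um; QO2 = %.3f mL O2/100g/min\n"),
    x$pc_mmHg, x$pl_mmHg, x$x1_frac, x$x2_frac, x$q2, x$L_um, qo2_from_params(x)))
  invisible(x)
}

#' Averaged outer-retinal oxygen consumption implied by model parameters
#'
#' QO2 averaged over the whole outer-retinal slab: consumption happens only in
#' layer 2, so \eqn{QO_2 = 100 \, q_2 (x_2 - x_1)} in mL O2 per 100 g tissue
#' per minute (tissue density taken as 1 g/mL).
#'
#' @param params A [three_layer_params()] object.
#' @return QO2 in mL O2/100 g/min.
#' @export
qo2_from_params <- function(params) {
  100 * params$q2 * (params$x2_frac - params$x1_frac)
}

#' Closed-form three-layer oxygen tension profile
#'
#' Evaluates the steady-state solution of \eqn{Dk\, P'' = Q(x)} with Q = 0 in
#' layers 1 and 3 and Q = q2 in layer 2, tension `pc` at x = 0 (chorioretinal
#' interface) and `pl` at x = L, and continuity of tension and flux at the two
#' layer boundaries. The solution is linear in layers 1 and 3 and quadratic in
#' layer 2.
#'
#' @param x_frac Positions as fractions of the outer-retinal thickness,
#'   0 = chorioretinal interface, 1 = outer/inner boundary. Vectorized.
#' @param params A [three_layer_params()] object.
#' @return Oxygen tension in mmHg at each `x_frac`.
#' @examples
#' p <- three_layer_params(33, 23, 0.2, 0.4, q2 = 0.0285, L_um = 115,
#'                         Dk = 1.97e-10 * 60)
#' three_layer_po2(c(0, 0.3, 1), p)
#' @export
three_layer_po2 <- function(x_frac, params) {
  stopifnot(all(is.finite(x_frac)), all(x_frac >= -1e-12), all(x_frac <= 1 + 1e-12))
  x_frac <- pmin(pmax(x_frac, 0), 1)
  L <- params$L_um * 1e-4                 # cm
  k <- params$q2 / params$Dk              # P'' in layer 2, mmHg/cm^2
  x1 <- params$x1_frac * L
  x2 <- params$x2_frac * L
  x <- x_frac * L
  pc <- params$pc_mmHg
  pl <- params$pl_mmHg
  # segment coefficients from boundary conditions + continuity of P and flux
  b1 <- (pl - pc - (k / 2) * (x1^2 - x2^2) - k * L * (x2 - x1)) / L
  b2 <- b1 - k * x1
  b3 <- b2 + k * x2
  a1 <- pc
  a2 <- pc + (k / 2) * x1^2
  a3 <- a2 - (k / 2) * x2^2
  out <- numeric(length(x))
  i1 <- x < x1
  i2 <- x >= x1 & x <= x2
  i3 <- x > x2
  out[i1] <- a1 + b1 * x[i1]
  out[i2] <- a2 + b2 * x[i2] + (k / 2) * x[i2]^2
  out[i3] <- a3 + b3 * x[i3]
  out
}

#' Fit the three-layer diffusion model to an outer-retinal tension profile
#'
#' Non-linear least-squares fit of the five free parameters (pc, pl, x1, x2,
#' q2) of [three_layer_po2()] to measured tissue oxygen tension over the outer
#' half of the retina. Constraints (0 < x1 < x2 < 1, q2 >= 0) are enforced by
#' smooth reparameterization: x1 and the relative width (x2 - x1)/(1 - x1) go
#' through logistic transforms and q2 through a square. Levenberg-Marquardt
#' minimization ([minpack.lm::nls.lm]) with three jittered starts (seeded)
#' guards against local minima.
#'
#' @param profile A data frame with columns `fractional_depth` (0 = inner
#'   retinal surface, 1 = chorioretinal interface) and `tpo2_mmHg`. Only rows
#'   with `fractional_depth >= 0.5` (the outer retina) are used; depth d maps
#'   to model position `x_frac = 2 (1 - d)`.
#' @param L_um Outer-retinal thickness (half the retinal thickness), um. If
#'   `NULL`, taken from a `thickness_um` column of `profile` (half of it).
#' @param Dk Diffusivity-solubility product; defaults to [default_dk()].
#' @param init Optional named list overriding the default initialization
#'   (`pc`, `pl`, `x1`, `x2`, `q2`).
#' @param n_starts Number of optimizer starts (first = init, rest jittered).
#' @param seed Integer seed for the start jitter.
#' @param maxiter,ftol Levenberg-Marquardt iteration cap and relative
#'   RSS-change tolerance per start.
#' @param smooth_kernel_x Optional numeric vector of kernel tap offsets (in
#'   `x_frac` units). When the tension image was box-smoothed axially before
#'   profile extraction, each profile sample is an equal-weight average of the
#'   underlying field at these offsets; supplying them makes the fit's forward
#'   model apply the same averaging, so the known smoothing operator does not
#'   bias the recovered consumption. Samples whose kernel support crosses the
#'   outer-retina boundaries are excluded from the fit.
#' @return An object of class `three_layer_fit`: fitted `params`
#'   ([three_layer_params()]), `qo2_mlo2_per_100g_min`, `rss`, `r2`,
#'   `converged`, per-parameter `at_bound` flags, and a `fitted` tibble.
#' @seealso [tidy.three_layer_fit()], [glance.three_layer_fit()], [mean_qo2()]
#' @export
fit_three_layer <- function(profile, L_um = NULL, Dk = NULL, init = NULL,
                            n_starts = 3, seed = 1L, maxiter = 500,
                            ftol = 1e-8, smooth_kernel_x = NULL) {
  Dk <- Dk %||% default_dk()
  stopifnot(is.data.frame(profile),
            all(c("fractional_depth", "tpo2_mmHg") %in% names(profile)))
  if (is.null(L_um)) {
    if (!"thickness_um" %in% names(profile)) {
      stop("supply L_um or include a thickness_um column in the profile")
    }
    L_um <- stats::median(profile$thickness_um) / 2
  }
  outer <- profile[profile$fractional_depth >= 0.5 &
                     is.finite(profile$tpo2_mmHg), , drop = FALSE]
  if (nrow(outer) < 8) {
    stop("need at least 8 outer-retinal samples to fit the three-layer model")
  }
  x <- 2 * (1 - outer$fractional_depth)
  y <- outer$tpo2_mmHg
  if (!is.null(smooth_kernel_x) && length(smooth_kernel_x) > 0) {
    # keep only samples whose window is fully interior: near the interface the
    # mask-aware data smoothing renormalizes over partially valid windows,
    # which the plain-average forward model does not describe
    spacing <- if (length(smooth_kernel_x) > 1) {
      min(diff(sort(smooth_kernel_x)))
    } else 0
    keep <- x + max(smooth_kernel_x) <= 1 &
      x + min(smooth_kernel_x) >= spacing
    x <- x[keep]; y <- y[keep]
    if (length(x) < 8) {
      stop("need at least 8 outer-retinal samples clear of the smoothing ",
           "kernel support to fit the three-layer model")
    }
  }
  ord <- order(x)
  x <- x[ord]; y <- y[ord]

  to_params <- function(th) {
    x1 <- stats::plogis(th[3])
    x2 <- x1 + stats::plogis(th[4]) * (1 - x1)
    list(pc = th[1], pl = th[2], x1 = x1, x2 = x2, q2 = th[5]^2)
  }
  model_at <- function(th, xx) {
    p <- to_params(th)
    pr <- three_layer_params(max(p$pc, 0), max(p$pl, 0),
                             min(max(p$x1, 1e-9), 1 - 2e-9),
                             max(p$x2, p$x1 + 1e-9),
                             p$q2, L_um, Dk)
    if (is.null(smooth_kernel_x) || length(smooth_kernel_x) == 0) {
      three_layer_po2(xx, pr)
    } else {
      taps <- vapply(smooth_kernel_x, function(o) {
        three_layer_po2(pmin(pmax(xx + o, 0), 1), pr)
      }, numeric(length(xx)))
      rowMeans(matrix(taps, nrow = length(xx)))
    }
  }
  resid_fn <- function(th) model_at(th, x) - y

  # default initialization: pc from the interface end, pl from the 50% end,
  # q2 from the largest discrete curvature of the profile
  L_cm <- L_um * 1e-4
  d2 <- if (length(y) >= 3) diff(y, differences = 2) / mean(diff(x))^2 else 0
  q2_init <- max(max(d2, 0) * Dk / L_cm^2, 1e-4)
  init0 <- list(pc = max(y), pl = y[which.max(x)], x1 = 0.2, x2 = 0.4,
                q2 = q2_init)
  if (!is.null(init)) init0[names(init)] <- init
  th0 <- c(init0$pc, init0$pl,
           stats::qlogis(min(max(init0$x1, 1e-3), 1 - 1e-3)),
           stats::qlogis(min(max((init0$x2 - init0$x1) / (1 - init0$x1), 1e-3),
                             1 - 1e-3)),
           sqrt(max(init0$q2, 0)))

  starts <- list(th0)
  if (n_starts > 1) {
    starts <- c(starts, withr::with_seed(seed, {
      lapply(seq_len(n_starts - 1), function(i) {
        th0 + c(stats::rnorm(2, 0, 0.05 * max(abs(th0[1:2]), 1)),
                stats::rnorm(2, 0, 0.75),
                stats::rnorm(1, 0, 0.25 * max(abs(th0[5]), 1e-2)))
      })
    }))
  }

  best <- NULL
  for (th in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = th, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = ftol)),
      error = function(e) NULL)
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    conv <- res$info %in% 1:4
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = res, rss = rss, converged = conv)
    }
  }
  if (is.null(best)) stop("three-layer fit failed in all starts")

  th <- best$fit$par
  p <- to_params(th)
  at_bound <- c(x1 = p$x1 < 1e-4 || p$x1 > 1 - 1e-4,
                x2 = p$x2 < 1e-4 || p$x2 > 1 - 1e-4,
                width = (p$x2 - p$x1) < 1e-4)
  params <- three_layer_params(max(p$pc, 0), max(p$pl, 0),
                               min(max(p$x1, 1e-9), 1 - 2e-9),
                               min(max(p$x2, p$x1 + 1e-9), 1),
                               p$q2, L_um, Dk)
  fitted_vals <- model_at(th, x)
  tss <- sum((y - mean(y))^2)
  structure(list(
    params = params,
    qo2_mlo2_per_100g_min = qo2_from_params(params),
    rss = best$rss,
    r2 = if (tss > 0) 1 - best$rss / tss else NA_real_,
    converged = best$converged,
    at_bound = at_bound,
    n = length(y),
    fitted = tibble::tibble(x_frac = x, fractional_depth = 1 - x / 2,
                            observed = y, fitted = fitted_vals)
  ), class = "three_layer_fit")
}

#' @export
print.three_layer_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<three_layer_fit> QO2 = %.3f mL O2/100g/min (pc = %.2f, pl = %.2f, ",
    "x1 = %.3f, x2 = %.3f, q2 = %.4f); RSS = %.3g, R2 = %.3f, %s%s\n"),
    x$qo2_mlo2_per_100g_min, x$params$pc_mmHg, x$params$pl_mmHg,
    x$params$x1_frac, x$params$x2_frac, x$params$q2, x$rss, x$r2,
    if (x$converged) "converged" else "NOT converged",
    if (any(x$at_bound)) " (at bound)" else ""))
  invisible(x)
}

#' Tidy a three-layer fit
#'
#' @param x A `three_layer_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`pc_mmHg`, `pl_mmHg`,
#'   `x1_frac`, `x2_frac`, `q2`, `qo2`).
#' @method tidy three_layer_fit
#' @export
tidy.three_layer_fit <- function(x, ...) {
  tibble::tibble(
    term = c("pc_mmHg", "pl_mmHg", "x1_frac", "x2_frac", "q2", "qo2"),
    estimate = c(x$params$pc_mmHg, x$params$pl_mmHg, x$params$x1_frac,
                 x$params$x2_frac, x$params$q2, x$qo2_mlo2_per_100g_min))
}

#' Glance at a three-layer fit
#'
#' @param x A `three_layer_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `qo2`, `rss`, `r2`, `converged`, `at_bound`, `n`.
#' @method glance three_layer_fit
#' @export
glance.three_layer_fit <- function(x, ...) {
  tibble::tibble(qo2 = x$qo2_mlo2_per_100g_min, rss = x$rss, r2 = x$r2,
                 converged = x$converged, at_bound = any(x$at_bound), n = x$n)
}

#' Fit the three-layer model to every usable depth profile
#'
#' Applies [fit_three_layer()] to each usable profile in a depth-profile table
#' (as produced by [extract_profiles()]) and collects the per-profile results.
#'
#' @param profiles Depth-profile tibble with columns `profile`,
#'   `fractional_depth`, `tpo2_mmHg`, `thickness_um`, `usable`, `y_center_um`.
#' @param Dk Diffusivity-solubility product; defaults to [default_dk()].
#' @param seed Base seed; profile i uses `seed + i` for its start jitter.
#' @param smooth_z_px Axial size (pixels) of the box filter that was applied
#'   to the tension image before profile extraction; 0 (default) if none. When
#'   positive, the fit's forward model averages over the same kernel (see
#'   `smooth_kernel_x` of [fit_three_layer()]).
#' @param z_pixel_um Axial pixel pitch; required when `smooth_z_px > 0` to
#'   convert the kernel to fractional-depth units.
#' @param ... Passed to [fit_three_layer()].
#' @return A tibble with one row per fitted profile (`profile`, `y_center_um`,
#'   `qo2`, `rss`, `r2`, `converged`, `at_bound`, `n`) and the fit objects in a
#'   `fit` list-column.
#' @export
fit_qo2_profiles <- function(profiles, Dk = NULL, seed = 1L, smooth_z_px = 0,
                             z_pixel_um = NULL, ...) {
  Dk <- Dk %||% default_dk()
  stopifnot(is.data.frame(profiles), "profile" %in% names(profiles))
  if (smooth_z_px > 0 && is.null(z_pixel_um)) {
    stop("z_pixel_um is required to express the smoothing kernel in depth units")
  }
  ids <- unique(profiles$profile[profiles$usable])
  rows <- purrr::map(ids, function(id) {
    pr <- profiles[profiles$profile == id, , drop = FALSE]
    kernel <- NULL
    if (smooth_z_px > 0) {
      thick_px <- stats::median(pr$thickness_um) / z_pixel_um
      dz <- seq_len(smooth_z_px) - ceiling((smooth_z_px + 1) / 2)
      kernel <- -2 * dz / thick_px   # columns increase toward the choroid
    }
    fit <- tryCatch(
      fit_three_layer(pr, Dk = Dk, seed = seed + as.integer(id),
                      smooth_kernel_x = kernel, ...),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(profile = id, y_center_um = pr$y_center_um[1],
                            qo2 = NA_real_, rss = NA_real_, r2 = NA_real_,
                            converged = FALSE, at_bound = NA, n = NA_integer_,
                            fit = list(NULL)))
    }
    dplyr::bind_cols(tibble::tibble(profile = id,
                                    y_center_um = pr$y_center_um[1]),
                     glance(fit), tibble::tibble(fit = list(fit)))
  })
  dplyr::bind_rows(rows)
}

#' Mean outer-retinal oxygen consumption across depth-profile fits
#'
#' Arithmetic mean of QO2 over fits that converged and did not end on a
#' parameter bound; diverged or bound-limited fits are excluded and counted.
#'
#' @param fits Either a list of `three_layer_fit` objects or the tibble
#'   returned by [fit_qo2_profiles()].
#' @return A one-row tibble: `mean_qo2`, `n_used`, `n_excluded`. `mean_qo2` is
#'   `NA` when no fit is usable.
#' @export
mean_qo2 <- function(fits) {
  if (is.data.frame(fits)) {
    qo2 <- fits$qo2
    ok <- fits$converged & !is.na(fits$qo2) &
      (is.na(fits$at_bound) | !fits$at_bound)
    ok[is.na(ok)] <- FALSE
  } else {
    qo2 <- vapply(fits, function(f) {
      if (is.null(f)) NA_real_ else f$qo2_mlo2_per_100g_min
    }, numeric(1))
    ok <- vapply(fits, function(f) {
      !is.null(f) && f$converged && !any(f$at_bound)
    }, logical(1))
  }
  tibble::tibble(
    mean_qo2 = if (any(ok)) mean(qo2[ok]) else NA_real_,
    n_used = sum(ok),
    n_excluded = length(ok) - sum(ok))
}
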