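#' Phase-lifetime fit for a single pixel
#'
#' Fits the homodyne signal \eqn{I_k = a + b\cos\theta_k + c\sin\theta_k} by
#' exact linear least squares (the half-period phase coverage makes the basis
#' non-orthogonal, so the normal equations are solved rather than using Fourier
#' quadrature, which would be biased here). The phase lag is
#' \eqn{\phi = \mathrm{atan2}(c, b)} and the phase lifetime
#' \eqn{\tau = \tan(\phi)/\omega}. A fit is valid only when the phase lag
#' falls strictly inside (0, 90) degrees.
#'
#' @param intensities K measured intensities.
#' @param phases_deg K phase angles in degrees (at least 3 distinct values).
#' @param freq_hz Modulation frequency, Hz.
#' @return A list: `tau_s`, `amplitude` (DC term a), `mod_amplitude`
#'   (\eqn{\sqrt{b^2+c^2}}), `phi_deg`, `residual_rms`, `valid`. `tau_s` is
#'   `NA` when the phase is out of range (`valid = FALSE`), which is flagged,
#'   not an error.
#' @examples
#' I <- homodyne_intensity(250e-6, (0:9) * 18, 1600, amplitude = 1000,
#'                         mod_depth = 0.8)
#' fit_phase_pixel(I, (0:9) * 18, 1600)$tau_s
#' @export
fit_phase_pixel <- function(intensities, phases_deg, freq_hz) {
  K <- length(intensities)
  if (K < 3 || length(phases_deg) != K) {
    stop("need at least 3 intensities with matching phase angles")
  }
  th <- phases_deg * pi / 180
  X <- cbind(1, cos(th), sin(th))
  if (qr(X)$rank < 3) {
    stop("rank-deficient phase design: phases do not span the cosine basis")
  }
  coef <- qr.solve(X, intensities)
  a <- coef[1]; b <- coef[2]; cc <- coef[3]
  phi <- atan2(cc, b)
  res <- intensities - X %*% coef
  valid <- is.finite(phi) && phi > 0 && phi < pi / 2
  list(
    tau_s = if (valid) tan(phi) / (2 * pi * freq_hz) else NA_real_,
    amplitude = a,
    mod_amplitude = sqrt(b^2 + cc^2),
    phi_deg = phi * 180 / pi,
    residual_rms = sqrt(mean(res^2)),
    valid = valid)
}

#' Per-pixel lifetime map from a phase-delayed stack
#'
#' Vectorized application of the cosine-basis phase fit to every pixel of the
#' stack. Pixels are marked invalid when their fitted DC amplitude falls below
#' `amplitude_threshold` times the stack's 99th-percentile DC amplitude
#' (robust to hot pixels) or when the fitted phase lag is outside (0, 90)
#' degrees.
#'
#' @param stack A [phase_stack()].
#' @param amplitude_threshold Fraction of the 99th-percentile DC amplitude
#'   below which a pixel is invalid. Default 0.1.
#' @return An object of class `lifetime_map`: matrices `tau_s`, `amplitude`,
#'   `mod_amplitude`, `phi_deg`, `residual_rms`, logical `valid`, plus the
#'   stack's frequency, pixel pitch, channel and replicate.
#' @export
estimate_lifetime_map <- function(stack, amplitude_threshold = 0.1) {
  stopifnot(inherits(stack, "phase_stack"))
  d <- dim(stack$images)
  H <- d[1]; D <- d[2]; K <- d[3]
  th <- stack$phases_deg * pi / 180
  X <- cbind(1, cos(th), sin(th))
  if (qr(X)$rank < 3) {
    stop("rank-deficient phase design: phases do not span the cosine basis")
  }
  Y <- matrix(aperm(stack$images, c(3, 1, 2)), nrow = K)  # K x (H*D)
  coef <- solve(crossprod(X), crossprod(X, Y))            # 3 x N
  a <- coef[1, ]; b <- coef[2, ]; cc <- coef[3, ]
  phi <- atan2(cc, b)
  resid <- Y - X %*% coef
  rms <- sqrt(colMeans(resid^2))
  omega <- 2 * pi * stack$modulation_freq_hz

  thr <- amplitude_threshold *
    stats::quantile(a, 0.99, names = FALSE, type = 7)
  phase_ok <- is.finite(phi) & phi > 0 & phi < pi / 2
  valid <- phase_ok & a >= thr
  tau <- ifelse(phase_ok, tan(phi) / omega, NA_real_)

  shape <- function(v) matrix(v, H, D)
  structure(list(
    tau_s = shape(tau), amplitude = shape(a),
    mod_amplitude = shape(sqrt(b^2 + cc^2)),
    phi_deg = shape(phi * 180 / pi),
    residual_rms = shape(rms),
    valid = shape(valid),
    modulation_freq_hz = stack$modulation_freq_hz,
    y_pixel_um = stack$y_pixel_um, z_pixel_um = stack$z_pixel_um,
    channel = stack$channel, replicate = stack$replicate,
    amplitude_threshold = amplitude_threshold
  ), class = "lifetime_map")
}

#' @export
print.lifetime_map <- function(x, ...) {
  cat(sprintf(
    "<lifetime_map> %s replicate %d: %d x %d px, %.1f%% valid, median tau = %.1f us\n",
    x$channel, x$replicate, nrow(x$tau_s), ncol(x$tau_s),
    100 * mean(x$valid),
    1e6 * stats::median(x$tau_s[x$valid])))
  invisible(x)
}

#' Modulation lifetime diagnostic
#'
#' Lifetime from the demodulation ratio rather than the phase:
#' \eqn{M = B/(A m)} and \eqn{\tau_M = \sqrt{1/M^2 - 1}/\omega}. Requires the
#' modulation depth m to be known exactly, which is why the phase lifetime is
#' the primary estimate; this is exposed as a consistency diagnostic.
#'
#' @param lt A [estimate_lifetime_map()] result.
#' @param mod_depth The modulation depth m used during acquisition.
#' @return A matrix of modulation lifetimes (seconds), `NA` where invalid or
#'   where the demodulation ratio is outside (0, 1).
#' @export
modulation_lifetime <- function(lt, mod_depth) {
  stopifnot(inherits(lt, "lifetime_map"), mod_depth > 0, mod_depth <= 1)
  M <- lt$mod_amplitude / (lt$amplitude * mod_depth)
  M[!lt$valid | M <= 0 | M >= 1] <- NA
  sqrt(1 / M^2 - 1) / (2 * pi * lt$modulation_freq_hz)
}
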