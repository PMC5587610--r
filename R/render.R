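#' Acquisition settings for phase-delayed homodyne imaging
#'
#' Both the excitation and the detector gain are modulated at
#' `modulation_freq_hz`; images are taken at `n_phases` relative phase delays
#' spanning half a period. The defaults are the study protocol: 10 phases in
#' 18-degree steps starting at 0 degrees, 1.6 kHz modulation, 3 replicates per
#' channel.
#'
#' @param n_phases Number of phase-delayed images per stack.
#' @param phases_deg Phase angles in degrees, strictly increasing in
#'   `[0, 180)`. Default: `n_phases` equal steps from 0.
#' @param modulation_freq_hz Modulation frequency, Hz.
#' @param modulation_depth Effective modulation depth m in (0, 1] of the
#'   homodyne signal.
#' @param n_replicates Repeated acquisitions per channel.
#' @param amplitude Base DC intensity of a fully dye-covered pixel (arbitrary
#'   camera units).
#' @return An object of class `acquisition_settings`.
#' @export
acquisition_settings <- function(n_phases = 10, phases_deg = NULL,
                                 modulation_freq_hz = 1600,
                                 modulation_depth = 0.8,
                                 n_replicates = 3, amplitude = 1000) {
  phases_deg <- phases_deg %||% (seq_len(n_phases) - 1) * (180 / n_phases)
  stopifnot(length(phases_deg) >= 3,
            all(diff(phases_deg) > 0),
            all(phases_deg >= 0), all(phases_deg < 180),
            modulation_freq_hz > 0,
            modulation_depth > 0, modulation_depth <= 1,
            n_replicates >= 1, amplitude > 0)
  structure(list(phases_deg = phases_deg,
                 modulation_freq_hz = modulation_freq_hz,
                 modulation_depth = modulation_depth,
                 n_replicates = as.integer(n_replicates),
                 amplitude = amplitude),
            class = "acquisition_settings")
}

#' Phosphorescence lifetime from oxygen tension (Stern-Volmer forward model)
#'
#' \eqn{\tau = 1 / (1/\tau_0 + k_q \cdot PO_2)}. This is the exact inverse of
#' [stern_volmer_po2()].
#'
#' @param po2_mmHg Oxygen tension, mmHg (vectorized; must be >= 0).
#' @param calib An [oxyphor_calibration()].
#' @return Lifetime in seconds.
#' @export
sv_tau <- function(po2_mmHg, calib) {
  stopifnot(all(po2_mmHg[is.finite(po2_mmHg)] >= 0))
  1 / (1 / calib$tau0_s + calib$kq * po2_mmHg)
}

#' Homodyne phase lag and demodulation of an exponential decay
#'
#' For lifetime tau at modulation frequency f, the fundamental-harmonic
#' response lags the excitation by \eqn{\phi = \arctan(\omega\tau)} and is
#' demodulated by \eqn{M = (1 + (\omega\tau)^2)^{-1/2}}, \eqn{\omega = 2\pi f}.
#'
#' @param tau_s Lifetime, seconds (vectorized).
#' @param freq_hz Modulation frequency, Hz.
#' @return Phase lag in degrees / demodulation factor in (0, 1].
#' @export
phase_lag_deg <- function(tau_s, freq_hz) {
  atan(2 * pi * freq_hz * tau_s) * 180 / pi
}

#' @rdname phase_lag_deg
#' @export
demod_factor <- function(tau_s, freq_hz) {
  1 / sqrt(1 + (2 * pi * freq_hz * tau_s)^2)
}

#' Noise-free homodyne intensity model
#'
#' Intensity of a pixel with lifetime `tau_s` at each detector phase:
#' \eqn{I(\theta) = A [1 + m M(\tau) \cos(\theta - \phi(\tau))]}.
#'
#' @param tau_s Lifetime, seconds (scalar).
#' @param phases_deg Detector phase angles, degrees.
#' @param freq_hz Modulation frequency, Hz.
#' @param amplitude DC amplitude A.
#' @param mod_depth Modulation depth m.
#' @return Numeric vector of intensities, one per phase.
#' @export
homodyne_intensity <- function(tau_s, phases_deg, freq_hz, amplitude = 1,
                               mod_depth = 1) {
  wt <- 2 * pi * freq_hz * tau_s
  phi <- atan(wt)
  M <- 1 / sqrt(1 + wt^2)
  amplitude * (1 + mod_depth * M * cos(phases_deg * pi / 180 - phi))
}

#' Construct a phase-delayed image stack
#'
#' @param images 3-D numeric array (rows y, columns z, slices = phases).
#' @param phases_deg Phase angles, degrees, one per slice.
#' @param modulation_freq_hz Modulation frequency, Hz.
#' @param y_pixel_um,z_pixel_um Pixel pitch, micrometres.
#' @param channel `"tissue"` or `"vascular"`.
#' @param replicate Replicate index (1-based).
#' @return An object of class `phase_stack`.
#' @export
phase_stack <- function(images, phases_deg, modulation_freq_hz,
                        y_pixel_um, z_pixel_um,
                        channel = c("tissue", "vascular"), replicate = 1L) {
  channel <- match.arg(channel)
  stopifnot(is.array(images), length(dim(images)) == 3,
            dim(images)[3] == length(phases_deg),
            length(phases_deg) >= 3,
            all(phases_deg >= 0), all(phases_deg < 180),
            modulation_freq_hz > 0)
  structure(list(images = images, phases_deg = phases_deg,
                 modulation_freq_hz = modulation_freq_hz,
                 y_pixel_um = y_pixel_um, z_pixel_um = z_pixel_um,
                 channel = channel, replicate = as.integer(replicate)),
            class = "phase_stack")
}

#' @export
print.phase_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<phase_stack> %s replicate %d: %d x %d px, %d phases at %g Hz\n",
              x$channel, x$replicate, d[1], d[2], d[3], x$modulation_freq_hz))
  invisible(x)
}

#' Render noisy phase-delayed stacks from a ground-truth scene
#'
#' Forward model of the dual-oxyphor acquisition. Per pixel, the channel's
#' oxygen tension is converted to a lifetime by the Stern-Volmer relation for
#' that channel's probe, and the homodyne intensity
#' \eqn{A [1 + m M(\tau) \cos(\theta_k - \phi(\tau))]} is evaluated at every
#' detector phase, with amplitude `A = acq$amplitude * coverage` (tissue
#' channel: the whole retinal band; vascular channel: vessel cross-sections)
#' and independent additive Gaussian noise of standard deviation
#' `scene$noise_sigma` per pixel per phase. Replicates differ only in their
#' noise draws; all randomness flows from `seed`.
#'
#' @param scene A [build_scene()] scene.
#' @param acq An [acquisition_settings()] object.
#' @param calib_tissue,calib_vascular [oxyphor_calibration()] for the G2
#'   (tissue) and R0 (vascular) channels.
#' @param seed Seed for the noise draws; defaults to `scene$seed`.
#' @return A list with elements `tissue` and `vascular`, each a list of
#'   `acq$n_replicates` [phase_stack()] objects.
#' @export
render_phase_stacks <- function(scene, acq = acquisition_settings(),
                                calib_tissue, calib_vascular,
                                seed = NULL) {
  stopifnot(inherits(scene, "scene_truth"),
            inherits(acq, "acquisition_settings"),
            inherits(calib_tissue, "oxyphor_calibration"),
            inherits(calib_vascular, "oxyphor_calibration"))
  seed <- seed %||% scene$seed

  render_channel <- function(po2, coverage, calib, channel) {
    H <- scene$height_px; D <- scene$depth_px
    K <- length(acq$phases_deg)
    tau <- matrix(NA_real_, H, D)
    dye <- coverage > 0 & is.finite(po2)
    tau[dye] <- sv_tau(po2[dye], calib)
    wt <- 2 * pi * acq$modulation_freq_hz * tau
    phi <- atan(wt)
    MM <- 1 / sqrt(1 + wt^2)
    A <- acq$amplitude * coverage
    imgs <- array(0, dim = c(H, D, K))
    th <- acq$phases_deg * pi / 180
    for (k in seq_len(K)) {
      plane <- A
      plane[dye] <- A[dye] *
        (1 + acq$modulation_depth * MM[dye] * cos(th[k] - phi[dye]))
      imgs[, , k] <- plane
    }
    lapply(seq_len(acq$n_replicates), function(r) {
      noisy <- imgs
      if (scene$noise_sigma > 0) {
        noisy <- noisy + array(stats::rnorm(H * D * K, 0, scene$noise_sigma),
                               dim = c(H, D, K))
      }
      phase_stack(noisy, acq$phases_deg, acq$modulation_freq_hz,
                  scene$y_pixel_um, scene$z_pixel_um,
                  channel = channel, replicate = r)
    })
  }

  withr::with_seed(seed, {
    tissue <- render_channel(scene$tissue_po2, scene$tissue_coverage,
                             calib_tissue, "tissue")
    vascular <- render_channel(scene$vascular_po2, scene$vascular_coverage,
                               calib_vascular, "vascular")
    list(tissue = tissue, vascular = vascular)
  })
}
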