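# Depth-profile machinery: curvature flattening, anisotropic smoothing,
# vertical binning into tPO2-vs-depth profiles, and per-profile metrics.

shift_matrix <- function(x, dy, dz, fill = 0) {
  H <- nrow(x); D <- ncol(x)
  out <- matrix(fill, H, D)
  ys <- seq_len(H) + dy
  zs <- seq_len(D) + dz
  oky <- ys >= 1 & ys <= H
  okz <- zs >= 1 & zs <= D
  out[oky, okz] <- x[ys[oky], zs[okz]]
  out
}

#' Mask-aware anisotropic box smoothing
#'
#' Moving-window mean over a `size_y` x `size_z` pixel window (vertical x
#' axial). Windows are truncated at image borders and at invalid pixels and
#' renormalized by the number of valid pixels actually inside the window, so
#' boundary-adjacent values are not dragged toward zero. With the default
#' 3 um x 4.5 um pixels, the default 6 x 4 window spans 18 um in both axes.
#' Even window sizes are anchored with the extra pixel before the center
#' (offsets -3..2 for size 6).
#'
#' @param x A numeric matrix or a [po2_map()]. `NA`s count as invalid.
#' @param size_y,size_z Window size in pixels along rows (y) and columns (z).
#' @param valid Optional logical matrix marking valid pixels (matrices only;
#'   for a `po2_map` its own mask is used).
#' @return Same type as the input: smoothed matrix (with `NA` where no valid
#'   pixel fell in the window), or a `po2_map` with smoothed tension and
#'   amplitude and an updated mask.
#' @export
smooth_anisotropic <- function(x, size_y = 6, size_z = 4, valid = NULL) {
  stopifnot(size_y >= 1, size_z >= 1)
  if (inherits(x, "po2_map")) {
    out <- x
    out$po2_mmHg <- smooth_anisotropic(x$po2_mmHg, size_y, size_z,
                                       valid = x$valid)
    out$amplitude <- smooth_anisotropic(x$amplitude, size_y, size_z)
    out$valid <- !is.na(out$po2_mmHg)
    return(out)
  }
  stopifnot(is.matrix(x))
  w <- if (is.null(valid)) !is.na(x) else (valid & !is.na(x))
  xz <- x
  xz[!w] <- 0
  wm <- w * 1
  offs_y <- seq_len(size_y) - ceiling((size_y + 1) / 2)
  offs_z <- seq_len(size_z) - ceiling((size_z + 1) / 2)
  num <- matrix(0, nrow(x), ncol(x))
  den <- matrix(0, nrow(x), ncol(x))
  for (dy in offs_y) {
    for (dz in offs_z) {
      num <- num + shift_matrix(xz, dy, dz)
      den <- den + shift_matrix(wm, dy, dz)
    }
  }
  out <- num / den
  out[den == 0] <- NA
  out
}

# mask-aware 1-D box smoothing along a vector (used axially per row)
box_smooth_1d <- function(v, size) {
  n <- length(v)
  w <- as.numeric(is.finite(v))
  vz <- ifelse(is.finite(v), v, 0)
  offs <- seq_len(size) - ceiling((size + 1) / 2)
  num <- numeric(n); den <- numeric(n)
  for (d in offs) {
    idx <- seq_len(n) + d
    ok <- idx >= 1 & idx <= n
    num[ok] <- num[ok] + vz[idx[ok]]
    den[ok] <- den[ok] + w[idx[ok]]
  }
  out <- num / den
  out[den == 0] <- NA
  out
}

# last-index argmax (ties resolved toward the choroid, where the tension
# maximum physically sits)
argmax_last <- function(v) {
  if (all(!is.finite(v))) return(NA_integer_)
  m <- max(v, na.rm = TRUE)
  max(which(v == m))
}

# Sub-pixel edge refinement by coverage inversion. The dye band renders with
# partial-volume amplitude at its edges (a pixel straddling the boundary holds
# dye in part of its area), so for a falling edge whose last fully covered
# pixel is k0 the boundary sits at k0 + 0.5 + sum of fractional coverages
# beyond it. This is exact for a box-sampled step and is preserved (to first
# order) by the linear interpolation used during flattening.
refine_falling_edge <- function(amp_row, k) {
  D <- length(amp_row)
  lo <- max(1, k - 8)
  plateau <- stats::median(amp_row[lo:k][amp_row[lo:k] >
                                           0.5 * max(amp_row[lo:k],
                                                     na.rm = TRUE)],
                           na.rm = TRUE)
  if (!is.finite(plateau) || plateau <= 0) return(k)
  full <- which(amp_row[seq_len(min(k + 2, D))] >= 0.95 * plateau)
  if (length(full) == 0) return(k)
  k0 <- max(full)
  tail_idx <- seq(k0 + 1, min(k0 + 4, D))
  if (k0 >= D) return(D)
  partial <- sum(pmin(pmax(amp_row[tail_idx], 0), plateau)) / plateau
  k0 + 0.5 + partial
}

refine_rising_edge <- function(amp_row, k, plateau) {
  if (!is.finite(plateau) || plateau <= 0) return(k)
  D <- length(amp_row)
  full <- which(amp_row >= 0.95 * plateau)
  if (length(full) == 0) return(k)
  k0 <- min(full)
  if (k0 <= 1) return(0.5 + pmin(pmax(amp_row[1], 0), plateau) / plateau)
  head_idx <- seq(max(1, k0 - 4), k0 - 1)
  partial <- sum(pmin(pmax(amp_row[head_idx], 0), plateau)) / plateau
  k0 - 0.5 - partial
}

detect_boundaries <- function(po2, amp, presmooth_z = 5, inner_threshold = 0.1,
                              signal = c("po2", "amplitude")) {
  signal <- match.arg(signal)
  H <- nrow(po2)
  iface <- rep(NA_real_, H)
  inner <- rep(NA_real_, H)
  for (r in seq_len(H)) {
    sig <- if (signal == "po2") po2[r, ] else amp[r, ]
    sm <- box_smooth_1d(sig, presmooth_z)
    sm[!is.finite(sig)] <- NA  # the band must not grow past the masked edge
    k <- argmax_last(sm)
    if (is.na(k)) next
    if (!is.null(amp)) {
      iface[r] <- refine_falling_edge(amp[r, ], k)
      rowmax <- max(amp[r, ], na.rm = TRUE)
      plateau <- stats::median(amp[r, ][amp[r, ] > 0.5 * rowmax], na.rm = TRUE)
      k_in <- which(amp[r, ] >= inner_threshold * rowmax)[1]
      if (!is.na(k_in)) inner[r] <- refine_rising_edge(amp[r, ], k_in, plateau)
    } else {
      iface[r] <- k
      k_in <- which(is.finite(po2[r, ]))[1]
      inner[r] <- if (is.na(k_in)) NA_real_ else k_in
    }
  }
  list(interface = iface, inner = inner)
}

shift_row_linear <- function(v, s) {
  # new[j] = v[j - s], linear interpolation, NA outside support
  n <- length(v)
  js <- seq_len(n) - s
  j0 <- floor(js)
  wgt <- js - j0
  out <- rep(NA_real_, n)
  ok <- j0 >= 1 & j0 <= n
  lo <- rep(NA_real_, n); hi <- rep(NA_real_, n)
  lo[ok] <- v[j0[ok]]
  ok2 <- (j0 + 1) >= 1 & (j0 + 1) <= n
  hi[ok2] <- v[j0[ok2] + 1]
  out <- (1 - wgt) * lo + wgt * hi
  exact <- !is.na(lo) & wgt < 1e-12
  out[exact] <- lo[exact]
  out
}

#' Construct a flattened tissue oxygen tension map
#'
#' A flattened map is a tissue tension image whose chorioretinal interface has
#' been aligned to a (near-)constant column, together with the per-row
#' interface and inner-surface positions. Usually produced by
#' [flatten_curvature()]; this constructor also lets synthetic maps with known
#' boundaries be fed directly to [extract_profiles()].
#'
#' @param po2_mmHg Tension matrix (rows y, columns z), `NA` where invalid.
#' @param interface_trace,inner_trace Per-row axial positions (pixels,
#'   real-valued) of the chorioretinal interface and inner retinal surface;
#'   `inner_trace < interface_trace` row-wise.
#' @param amplitude Optional amplitude matrix.
#' @param y_pixel_um,z_pixel_um Pixel pitch.
#' @param shifts,excluded_rows Bookkeeping from [flatten_curvature()].
#' @return An object of class `flattened_map`.
#' @export
flattened_map <- function(po2_mmHg, interface_trace, inner_trace,
                          amplitude = NULL, y_pixel_um = 3, z_pixel_um = 4.5,
                          shifts = NULL, excluded_rows = integer(0)) {
  stopifnot(is.matrix(po2_mmHg),
            length(interface_trace) == nrow(po2_mmHg),
            length(inner_trace) == nrow(po2_mmHg))
  both <- is.finite(interface_trace) & is.finite(inner_trace)
  if (any(inner_trace[both] >= interface_trace[both])) {
    stop("inner boundary must lie before the chorioretinal interface")
  }
  structure(list(po2_mmHg = po2_mmHg, interface_trace = interface_trace,
                 inner_trace = inner_trace, amplitude = amplitude,
                 y_pixel_um = y_pixel_um, z_pixel_um = z_pixel_um,
                 shifts = shifts, excluded_rows = excluded_rows),
            class = "flattened_map")
}

#' @export
print.flattened_map <- function(x, ...) {
  cat(sprintf(paste0(
    "<flattened_map> %d x %d px; interface at %.2f +/- %.3f px, ",
    "mean thickness %.1f px (%d rows excluded)\n"),
    nrow(x$po2_mmHg), ncol(x$po2_mmHg),
    mean(x$interface_trace, na.rm = TRUE),
    stats::sd(x$interface_trace, na.rm = TRUE),
    mean(x$interface_trace - x$inner_trace, na.rm = TRUE),
    length(x$excluded_rows)))
  invisible(x)
}

#' Minimize retinal curvature by row-wise realignment
#'
#' Per row, the chorioretinal interface is located at the maximum of the
#' axially box-smoothed signal (tension by default) and refined to sub-pixel
#' precision from the 50% falling edge of the amplitude profile; a quadratic
#' trend in row index is fit to those positions and every row is shifted by
#' linear interpolation so the fitted interface becomes a constant column.
#' The inner retinal surface is then detected per row as the first position
#' whose amplitude exceeds `inner_threshold` of the row maximum (refined at the
#' 50% rising edge). Rows without detectable signal are excluded and flagged.
#'
#' @param map A tissue [po2_map()] (replicate mean), carrying an amplitude
#'   matrix.
#' @param signal Which per-row signal the interface maximum is taken from:
#'   the tension map (default; tension peaks at the chorioretinal interface)
#'   or the amplitude map.
#' @param presmooth_z Axial box width (pixels) for the pre-detection smoothing.
#' @param inner_threshold Fraction of the per-row maximum amplitude defining
#'   the inner-surface detection level.
#' @return A [flattened_map()] with the realigned tension and amplitude, the
#'   post-flattening boundary traces, per-row `shifts`, and `excluded_rows`.
#' @export
flatten_curvature <- function(map, signal = c("po2", "amplitude"),
                              presmooth_z = 5, inner_threshold = 0.1) {
  signal <- match.arg(signal)
  stopifnot(inherits(map, "po2_map") || inherits(map, "flattened_map"))
  po2 <- map$po2_mmHg
  amp <- map$amplitude
  H <- nrow(po2)
  if (!is.null(map$valid)) po2[!map$valid] <- NA

  det <- detect_boundaries(po2, amp, presmooth_z, inner_threshold, signal)
  usable <- is.finite(det$interface)
  if (sum(usable) < 3) stop("too few rows with detectable signal to flatten")
  r <- seq_len(H)
  fit <- stats::lm(iface ~ r + I(r^2),
                   data = data.frame(iface = det$interface, r = r)[usable, ])
  fitted_iface <- as.numeric(stats::predict(fit, newdata = data.frame(r = r)))
  target <- round(mean(fitted_iface[usable]))
  shifts <- target - fitted_iface

  po2_f <- po2; amp_f <- amp
  for (i in r[usable]) {
    po2_f[i, ] <- shift_row_linear(po2[i, ], shifts[i])
    if (!is.null(amp)) amp_f[i, ] <- shift_row_linear(amp[i, ], shifts[i])
  }
  po2_f[!usable, ] <- NA

  det2 <- detect_boundaries(po2_f, amp_f, presmooth_z, inner_threshold, signal)
  det2$interface[!usable] <- NA
  det2$inner[!usable] <- NA
  flattened_map(po2_f, det2$interface, det2$inner, amplitude = amp_f,
                y_pixel_um = map$y_pixel_um, z_pixel_um = map$z_pixel_um,
                shifts = shifts, excluded_rows = which(!usable))
}

#' Extract vertically binned tissue tension depth profiles
#'
#' Rows of a flattened map are grouped into `floor(H / bin_px)` contiguous
#' bins; within each bin the tension is averaged vertically (over valid
#' pixels) at every axial pixel between the bin's mean inner surface and mean
#' chorioretinal interface, and the axial coordinate is rescaled to fractional
#' retinal depth (0 = inner surface, 1 = interface) using those bin-mean
#' boundary positions. With 3 um rows, the default 10-row bin matches the
#' 30 um vertical averaging of the acquisition protocol. Bins whose retina is
#' thinner than `min_thickness_px` (or with no detected boundaries) are
#' flagged unusable.
#'
#' @param fm A [flattened_map()].
#' @param bin_px Rows per bin.
#' @param min_thickness_px Minimum retinal thickness (pixels) for a usable bin.
#' @return A tibble with one row per (profile, depth sample): `profile`,
#'   `y_center_um`, `fractional_depth`, `tpo2_mmHg`, `thickness_um`, `usable`.
#'   Zero-row (but well-formed) when the map has fewer than `bin_px` rows.
#' @export
extract_profiles <- function(fm, bin_px = 10, min_thickness_px = 4) {
  stopifnot(inherits(fm, "flattened_map"), bin_px >= 1)
  H <- nrow(fm$po2_mmHg)
  nbin <- floor(H / bin_px)
  empty <- tibble::tibble(profile = integer(0), y_center_um = numeric(0),
                          fractional_depth = numeric(0),
                          tpo2_mmHg = numeric(0), thickness_um = numeric(0),
                          usable = logical(0))
  if (nbin == 0) return(empty)
  out <- vector("list", nbin)
  for (b in seq_len(nbin)) {
    rows <- ((b - 1) * bin_px + 1):(b * bin_px)
    y_center <- (mean(rows) - 0.5) * fm$y_pixel_um
    iface <- mean(fm$interface_trace[rows], na.rm = TRUE)
    inner <- mean(fm$inner_trace[rows], na.rm = TRUE)
    thick <- iface - inner
    if (!is.finite(thick) || thick < min_thickness_px) {
      out[[b]] <- tibble::tibble(profile = b, y_center_um = y_center,
                                 fractional_depth = NA_real_,
                                 tpo2_mmHg = NA_real_,
                                 thickness_um = if (is.finite(thick))
                                   thick * fm$z_pixel_um else NA_real_,
                                 usable = FALSE)
      next
    }
    js <- seq.int(ceiling(inner), floor(iface))
    vals <- vapply(js, function(j) {
      v <- fm$po2_mmHg[rows, j]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    out[[b]] <- tibble::tibble(
      profile = b, y_center_um = y_center,
      fractional_depth = (js - inner) / thick,
      tpo2_mmHg = vals,
      thickness_um = thick * fm$z_pixel_um,
      usable = TRUE)
  }
  dplyr::bind_rows(out)
}

#' Per-profile inner/outer tension metrics
#'
#' For each depth profile: maximum and minimum tension over the outer retina
#' (fractional depth in [0.5, 1]; the 0.5 boundary sample counts as outer) and
#' mean tension over the inner retina (depth in [0, 0.5)).
#'
#' @param profiles An [extract_profiles()] tibble.
#' @return A tibble with one row per profile: `profile`, `y_center_um`,
#'   `usable`, `max_outer_tpo2`, `min_outer_tpo2`, `mean_inner_tpo2`,
#'   `n_outer`, `n_inner`. Metrics are `NA` (flagged by the n columns) where a
#'   region has no finite samples.
#' @export
profile_metrics <- function(profiles) {
  stopifnot(is.data.frame(profiles),
            all(c("profile", "fractional_depth", "tpo2_mmHg") %in%
                  names(profiles)))
  profiles |>
    dplyr::group_by(.data$profile) |>
    dplyr::summarise(
      y_center_um = .data$y_center_um[1],
      usable = .data$usable[1],
      n_outer = sum(is.finite(.data$tpo2_mmHg) & .data$fractional_depth >= 0.5),
      n_inner = sum(is.finite(.data$tpo2_mmHg) & .data$fractional_depth < 0.5),
      max_outer_tpo2 = if (.data$n_outer[1] > 0)
        max(.data$tpo2_mmHg[.data$fractional_depth >= 0.5], na.rm = TRUE)
      else NA_real_,
      min_outer_tpo2 = if (.data$n_outer[1] > 0)
        min(.data$tpo2_mmHg[.data$fractional_depth >= 0.5], na.rm = TRUE)
      else NA_real_,
      mean_inner_tpo2 = if (.data$n_inner[1] > 0)
        mean(.data$tpo2_mmHg[.data$fractional_depth < 0.5], na.rm = TRUE)
      else NA_real_,
      .groups = "drop") |>
    dplyr::relocate("n_outer", "n_inner", .after = "mean_inner_tpo2")
}

#' Inner retinal tension along the vertical scan direction
#'
#' One point per usable profile: the mean inner-retinal tension against the
#' profile's vertical position, ordered superior to inferior. Peaks in this
#' trace sit next to retinal arteries.
#'
#' @param profiles An [extract_profiles()] tibble.
#' @return A tibble: `y_center_um`, `mean_inner_tpo2`.
#' @export
inner_tpo2_trace <- function(profiles) {
  profile_metrics(profiles) |>
    dplyr::filter(.data$usable) |>
    dplyr::arrange(.data$y_center_um) |>
    dplyr::select("y_center_um", "mean_inner_tpo2")
}
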