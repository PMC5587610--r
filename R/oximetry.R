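#' Oxygen tension from phosphorescence lifetime (Stern-Volmer)
#'
#' \eqn{PO_2 = (1/\tau - 1/\tau_0) / k_q}. Small negative outputs caused by
#' estimation noise (within `epsilon` mmHg below zero) are clipped to 0; values
#' below `-epsilon` indicate a calibration problem and are returned as `NA`.
#'
#' @param tau_s Lifetimes in seconds (vector or matrix; `NA` passes through).
#'   Non-`NA` values must be positive.
#' @param calib An [oxyphor_calibration()].
#' @param epsilon Clip tolerance in mmHg (default 1).
#' @return Oxygen tension in mmHg, same shape as `tau_s`.
#' @export
stern_volmer_po2 <- function(tau_s, calib, epsilon = 1) {
  if (any(tau_s <= 0, na.rm = TRUE)) {
    stop("lifetimes must be positive for Stern-Volmer conversion")
  }
  po2 <- (1 / tau_s - 1 / calib$tau0_s) / calib$kq
  po2[!is.na(po2) & po2 <= -epsilon] <- NA
  po2[!is.na(po2) & po2 < 0] <- 0
  po2
}

#' Per-pixel oxygen tension map from a lifetime map
#'
#' Element-wise Stern-Volmer conversion; the validity mask of the lifetime map
#' is carried over, additionally invalidating pixels whose conversion failed
#' (lifetime above the zero-oxygen lifetime by more than the clip tolerance).
#'
#' @param lt An [estimate_lifetime_map()] result.
#' @param calib An [oxyphor_calibration()] for the map's channel.
#' @param epsilon Clip tolerance, mmHg (see [stern_volmer_po2()]).
#' @return An object of class `po2_map`: matrices `po2_mmHg`, `valid`,
#'   `amplitude` (carried from the lifetime fit, used downstream for boundary
#'   detection), plus channel/pixel geometry.
#' @export
po2_map <- function(lt, calib, epsilon = 1) {
  stopifnot(inherits(lt, "lifetime_map"))
  tau <- lt$tau_s
  tau[!lt$valid] <- NA
  po2 <- stern_volmer_po2(tau, calib, epsilon = epsilon)
  structure(list(
    po2_mmHg = po2,
    valid = lt$valid & !is.na(po2),
    amplitude = lt$amplitude,
    channel = lt$channel, replicate = lt$replicate,
    y_pixel_um = lt$y_pixel_um, z_pixel_um = lt$z_pixel_um
  ), class = "po2_map")
}

#' @export
print.po2_map <- function(x, ...) {
  cat(sprintf(
    "<po2_map> %s: %d x %d px, %.1f%% valid, median PO2 = %.1f mmHg\n",
    x$channel, nrow(x$po2_mmHg), ncol(x$po2_mmHg), 100 * mean(x$valid),
    stats::median(x$po2_mmHg[x$valid])))
  invisible(x)
}

#' Average replicate oxygen tension maps
#'
#' Per-pixel arithmetic mean across replicates; a pixel is valid in the mean
#' map only where it is valid in every replicate (mask conjunction). The
#' amplitude maps are averaged the same way.
#'
#' @param maps A non-empty list of [po2_map()]s of identical shape and channel.
#' @return A `po2_map` with `replicate = NA` (it is a replicate mean).
#' @export
average_replicate_maps <- function(maps) {
  if (length(maps) == 0) stop("no maps to average")
  stopifnot(all(vapply(maps, inherits, logical(1), "po2_map")))
  dims <- lapply(maps, function(m) dim(m$po2_mmHg))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("replicate maps have mismatched shapes")
  }
  if (length(unique(vapply(maps, `[[`, character(1), "channel"))) != 1) {
    stop("replicate maps come from different channels")
  }
  valid <- Reduce(`&`, lapply(maps, `[[`, "valid"))
  po2 <- Reduce(`+`, lapply(maps, function(m) {
    x <- m$po2_mmHg; x[is.na(x)] <- 0; x
  })) / length(maps)
  po2[!valid] <- NA
  amp <- Reduce(`+`, lapply(maps, `[[`, "amplitude")) / length(maps)
  out <- maps[[1]]
  out$po2_mmHg <- po2
  out$valid <- valid
  out$amplitude <- amp
  out$replicate <- NA_integer_
  out
}

#' Vessel oxygen tension from circular ROIs
#'
#' For each ROI, the per-replicate vessel tension is the mean over valid
#' pixels inside the circle, and the vessel tension is the mean of the
#' replicate values (the order of operations of the acquisition protocol:
#' three repeated measurements are averaged per vessel).
#'
#' @param maps A list of vascular [po2_map()]s (one per replicate), or a single
#'   map.
#' @param rois A data frame with columns `label` ("artery"/"vein"), `center_y`,
#'   `center_z`, `radius` (pixels).
#' @return A tibble with one row per ROI: `label`, ROI geometry,
#'   `per_replicate_po2` (list-column), `mean_po2`, `n_replicates`, `missing`
#'   (TRUE when no replicate had any valid ROI pixel).
#' @export
vessel_po2 <- function(maps, rois) {
  if (inherits(maps, "po2_map")) maps <- list(maps)
  stopifnot(length(maps) >= 1, is.data.frame(rois),
            all(c("label", "center_y", "center_z", "radius") %in% names(rois)))
  H <- nrow(maps[[1]]$po2_mmHg); D <- ncol(maps[[1]]$po2_mmHg)
  ymat <- matrix(seq_len(H), H, D)
  zmat <- matrix(seq_len(D), H, D, byrow = TRUE)
  purrr::map_dfr(seq_len(nrow(rois)), function(i) {
    r <- rois[i, ]
    if (r$center_y < 1 || r$center_y > H || r$center_z < 1 || r$center_z > D) {
      stop(sprintf("ROI %d (%s) lies outside the image", i, r$label))
    }
    inside <- (ymat - r$center_y)^2 + (zmat - r$center_z)^2 <= r$radius^2
    reps <- vapply(maps, function(m) {
      sel <- inside & m$valid
      if (!any(sel)) NA_real_ else mean(m$po2_mmHg[sel])
    }, numeric(1))
    tibble::tibble(
      label = r$label, center_y = r$center_y, center_z = r$center_z,
      radius = r$radius,
      per_replicate_po2 = list(reps),
      mean_po2 = if (all(is.na(reps))) NA_real_ else mean(reps, na.rm = TRUE),
      n_replicates = sum(!is.na(reps)),
      missing = all(is.na(reps)))
  })
}

#' Mean arterial and venous oxygen tension
#'
#' Averages per-vessel tensions within each vessel type, yielding the
#' per-animal arterial and venous means (PO2A, PO2V).
#'
#' @param vessels A [vessel_po2()] tibble.
#' @return A one-row tibble: `po2a`, `po2v`, `n_arteries`, `n_veins`. A missing
#'   vessel type yields `NA` for its mean.
#' @export
cohort_vessel_means <- function(vessels) {
  stopifnot(is.data.frame(vessels),
            all(c("label", "mean_po2") %in% names(vessels)))
  ok <- !is.na(vessels$mean_po2)
  art <- vessels$mean_po2[ok & vessels$label == "artery"]
  ven <- vessels$mean_po2[ok & vessels$label == "vein"]
  tibble::tibble(
    po2a = if (length(art)) mean(art) else NA_real_,
    po2v = if (length(ven)) mean(ven) else NA_real_,
    n_arteries = length(art), n_veins = length(ven))
}
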