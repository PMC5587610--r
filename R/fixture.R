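#' Write a rendered acquisition to disk as a portable fixture
#'
#' Serializes the stacks as multi-page TIFFs (one file per channel per
#' replicate, one page per phase), a `metadata.yaml` sidecar describing every
#' stack (channel, replicate, phase angles, modulation frequency and depth,
#' pixel pitch, intensity offset/scale), a `rois.csv` with the vessel ROI
#' definitions, and a `truth.json` with the ground-truth scene parameters and
#' summary values for test assertions.
#'
#' Intensities are digitized to 16 bits: stored value = round((I - offset) /
#' scale * 65535) with the affine constants recorded in the sidecar, emulating
#' the camera ADC. [read_fixture()] restores physical units; the
#' write-read-write cycle is idempotent.
#'
#' @param scene The [build_scene()] scene the stacks were rendered from.
#' @param stacks The list returned by [render_phase_stacks()].
#' @param dir Output directory (created if missing).
#' @param acq The [acquisition_settings()] used (for the sidecar); if `NULL`,
#'   reconstructed from the first stack.
#' @return Invisibly, a character vector of written file paths.
#' @export
write_fixture <- function(scene, stacks, dir, acq = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create fixture directory: ", dir)
  }
  all_stacks <- c(stacks$tissue, stacks$vascular)
  rng <- range(vapply(all_stacks, function(s) range(s$images), numeric(2)))
  offset <- rng[1]
  scale <- max(rng[2] - rng[1], 1e-12)

  written <- character(0)
  meta_stacks <- list()
  for (s in all_stacks) {
    fname <- sprintf("%s_rep%d.tif", s$channel, s$replicate)
    path <- file.path(dir, fname)
    K <- dim(s$images)[3]
    pages <- lapply(seq_len(K), function(k) {
      round((s$images[, , k] - offset) / scale * 65535) / 65535
    })
    ok <- tryCatch(
      suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                                       compression = "none")),
      error = function(e) stop("failed to write ", path, ": ",
                               conditionMessage(e)))
    written <- c(written, path)
    meta_stacks[[length(meta_stacks) + 1]] <- list(
      file = fname, channel = s$channel, replicate = s$replicate,
      phases_deg = s$phases_deg,
      modulation_freq_hz = s$modulation_freq_hz,
      modulation_depth = if (!is.null(acq)) acq$modulation_depth else NA,
      y_pixel_um = s$y_pixel_um, z_pixel_um = s$z_pixel_um,
      n_pages = K,
      intensity_offset = offset, intensity_scale = scale)
  }

  meta_path <- file.path(dir, "metadata.yaml")
  yaml::write_yaml(list(stacks = meta_stacks), meta_path)
  written <- c(written, meta_path)

  roi_path <- file.path(dir, "rois.csv")
  utils::write.csv(
    scene$vessels[, c("label", "center_y", "center_z", "radius")],
    roi_path, row.names = FALSE)
  written <- c(written, roi_path)

  truth <- scene_summary(scene)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(list(
    height_px = scene$height_px, depth_px = scene$depth_px,
    y_pixel_um = scene$y_pixel_um, z_pixel_um = scene$z_pixel_um,
    retina_thickness_um = scene$retina_thickness_um,
    inner_po2_base = scene$inner_po2_base,
    noise_sigma = scene$noise_sigma, seed = scene$seed,
    outer_params = unclass(scene$outer_params),
    interface_trace = scene$interface_trace,
    vessels = scene$vessels,
    mean_inner_tpo2 = truth$mean_inner_tpo2,
    min_outer_tpo2 = truth$min_outer_tpo2,
    max_outer_tpo2 = truth$max_outer_tpo2,
    qo2 = truth$qo2, po2a = truth$po2a, po2v = truth$po2v
  ), truth_path, auto_unbox = TRUE, digits = NA)
  written <- c(written, truth_path)
  invisible(written)
}

#' Read one phase-delayed TIFF stack using its sidecar entry
#'
#' @param path Path to a multi-page TIFF written by [write_fixture()].
#' @param meta The matching stack entry from the `metadata.yaml` sidecar.
#' @return A [phase_stack()].
#' @export
read_phase_stack <- function(path, meta) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != meta$n_pages) {
    stop(sprintf("%s: expected %d pages, found %d", path, meta$n_pages,
                 length(pages)))
  }
  imgs <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) {
    imgs[, , k] <- meta$intensity_offset + meta$intensity_scale * pages[[k]]
  }
  phase_stack(imgs, unlist(meta$phases_deg), meta$modulation_freq_hz,
              meta$y_pixel_um, meta$z_pixel_um,
              channel = meta$channel, replicate = meta$replicate)
}

#' Read a fixture directory back into phase stacks
#'
#' @param dir A directory written by [write_fixture()] (or laid out the same
#'   way: TIFF stacks plus `metadata.yaml`, optional `rois.csv`/`truth.json`).
#' @return A list: `stacks` (list with `tissue` and `vascular` lists of
#'   [phase_stack()]s), `metadata` (parsed sidecar), `rois` (tibble or NULL),
#'   `truth` (parsed JSON or NULL).
#' @export
read_fixture <- function(dir) {
  meta_path <- file.path(dir, "metadata.yaml")
  if (!file.exists(meta_path)) stop("no metadata.yaml in ", dir)
  meta <- yaml::read_yaml(meta_path)
  stacks <- list(tissue = list(), vascular = list())
  for (m in meta$stacks) {
    s <- read_phase_stack(file.path(dir, m$file), m)
    stacks[[m$channel]][[length(stacks[[m$channel]]) + 1]] <- s
  }
  roi_path <- file.path(dir, "rois.csv")
  rois <- if (file.exists(roi_path)) {
    tibble::as_tibble(utils::read.csv(roi_path, stringsAsFactors = FALSE))
  }
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  }
  list(stacks = stacks, metadata = meta, rois = rois, truth = truth)
}
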