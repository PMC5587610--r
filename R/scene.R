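#' Build a ground-truth retinal oxygen tension scene
#'
#' Constructs the synthetic scene a phase-delayed optical-section acquisition
#' is rendered from: a curved retinal band in a (y, z) image plane (rows = the
#' vertical line scanned on the retina, columns = axial depth, increasing
#' toward the choroid), a per-pixel tissue oxygen tension field, and circular
#' vessel cross-sections in the inner retina.
#'
#' The tissue field is assembled in fractional-depth coordinates (0 = inner
#' vitreal surface, 1 = chorioretinal interface): the outer half (depth 0.5-1)
#' is the closed-form three-layer diffusion solution in `outer_params` (with
#' the model's x = 0 at the interface), and the inner half is a smooth field at
#' `inner_po2_base` with an optional Gaussian elevation around each artery that
#' decays to zero at the 50% depth boundary. The chorioretinal interface
#' follows a quadratic in row index with total sag `curvature_sag_px` at the
#' image edges relative to the central apex column `interface_apex_px`.
#'
#' Pixels straddling a retinal boundary carry fractional dye coverage
#' (partial-volume rendering), which is what makes sub-pixel boundary recovery
#' by the analysis pipeline possible.
#'
#' Defaults reproduce the in vivo study conditions: a ~1 mm vertical scan line
#' (350 rows of 3 um), 230 um retinal thickness, chorioretinal boundary tension
#' 33 mmHg (the cohort's mean maximum outer tPO2), inner-retinal tension
#' 23 mmHg, an outer consumption profile with QO2 = 0.57 mL O2/100 g/min, two
#' arteries at 41 mmHg and one vein at 25 mmHg.
#'
#' @param height_px,depth_px Image size: rows (vertical y, superior to
#'   inferior) and columns (axial z).
#' @param y_pixel_um,z_pixel_um Pixel pitch, micrometres.
#' @param retina_thickness_um Retinal thickness (inner surface to
#'   chorioretinal interface), micrometres.
#' @param interface_apex_px Axial position (column, pixels) of the interface at
#'   the central row.
#' @param curvature_sag_px Quadratic sag of the interface at the first/last row
#'   relative to the apex, pixels; 0 gives a flat interface.
#' @param pc_mmHg,pl_mmHg,x1_frac,x2_frac,qo2 Outer-retina three-layer model
#'   settings; `qo2` (mL O2/100 g/min) sets the layer-2 consumption rate via
#'   `q2 = qo2 / (100 (x2 - x1))`.
#' @param Dk Diffusivity-solubility product; defaults to [default_dk()]
#'   (silently here - the scene is synthetic by construction).
#' @param inner_po2_base Inner-retinal tissue tension, mmHg.
#' @param artery_elevation_mmHg Peak inner-tissue tension elevation adjacent to
#'   each artery (0 disables it).
#' @param artery_elevation_sigma_um Gaussian width of that elevation along y.
#' @param vessels Data frame with columns `label` ("artery"/"vein"),
#'   `center_y` (row, px), `radius` (px), `po2` (mmHg). Vessels are placed at
#'   fractional depth `vessel_depth_frac` in the inner retina.
#' @param vessel_depth_frac Fractional retinal depth of vessel centers (must be
#'   in the inner half, < 0.5 - radius).
#' @param noise_sigma Additive Gaussian intensity noise (per pixel, per phase)
#'   used when rendering, in the same units as the acquisition amplitude.
#' @param seed Integer seed controlling all rendering randomness.
#' @return An object of class `scene_truth`.
#' @examples
#' sc <- build_scene(height_px = 60, depth_px = 60, curvature_sag_px = 0)
#' @export
build_scene <- function(height_px = 350, depth_px = 100,
                        y_pixel_um = 3, z_pixel_um = 4.5,
                        retina_thickness_um = 230,
                        interface_apex_px = NULL, curvature_sag_px = 8,
                        pc_mmHg = 33, pl_mmHg = 23,
                        x1_frac = 0.2, x2_frac = 0.4, qo2 = 0.57,
                        Dk = NULL,
                        inner_po2_base = 23,
                        artery_elevation_mmHg = 4,
                        artery_elevation_sigma_um = 60,
                        vessels = NULL, vessel_depth_frac = 0.25,
                        noise_sigma = 20, seed = 1L) {
  if (height_px <= 0 || depth_px <= 0 || y_pixel_um <= 0 || z_pixel_um <= 0 ||
      retina_thickness_um <= 0) {
    stop("invalid scene configuration: sizes and pixel pitches must be positive")
  }
  Dk <- Dk %||% suppressWarnings(default_dk())
  thickness_px <- retina_thickness_um / z_pixel_um
  interface_apex_px <- interface_apex_px %||% (depth_px - thickness_px / 3)
  q2 <- qo2 / (100 * (x2_frac - x1_frac))
  outer_params <- three_layer_params(pc_mmHg, pl_mmHg, x1_frac, x2_frac,
                                     q2, L_um = retina_thickness_um / 2,
                                     Dk = Dk)
  rows <- seq_len(height_px)
  rc <- (height_px + 1) / 2
  half_span <- max(rc - 1, 1)
  interface_trace <- interface_apex_px +
    curvature_sag_px * ((rows - rc) / half_span)^2
  inner_trace <- interface_trace - thickness_px
  if (any(interface_trace >= depth_px) || any(inner_trace < 1)) {
    stop("invalid scene configuration: retina does not fit in the axial range")
  }

  if (is.null(vessels)) {
    vr <- 5
    vessels <- tibble::tibble(
      label = c("artery", "vein", "artery"),
      center_y = round(height_px * c(0.28, 0.5, 0.72)),
      radius = vr,
      po2 = c(41, 25, 41))
  }
  vessels <- tibble::as_tibble(vessels)
  stopifnot(all(c("label", "center_y", "radius", "po2") %in% names(vessels)),
            all(vessels$po2 >= 0),
            all(vessels$label %in% c("artery", "vein")))
  vessels$center_z <- inner_trace[pmin(pmax(round(vessels$center_y), 1),
                                       height_px)] +
    vessel_depth_frac * thickness_px
  if (any(vessel_depth_frac + vessels$radius / thickness_px >= 0.5)) {
    stop("vessels must lie within the inner half of the retinal depth")
  }

  # per-pixel fractional depth (at pixel centers) and dye coverage
  z <- seq_len(depth_px)
  zmat <- matrix(z, height_px, depth_px, byrow = TRUE)
  inner_mat <- matrix(inner_trace, height_px, depth_px)
  iface_mat <- matrix(interface_trace, height_px, depth_px)
  frac_depth <- (zmat - inner_mat) / (iface_mat - inner_mat)
  coverage <- pmin(zmat + 0.5, iface_mat) - pmax(zmat - 0.5, inner_mat)
  coverage <- pmin(pmax(coverage, 0), 1)

  elev <- rep(0, height_px)
  arteries <- vessels[vessels$label == "artery", , drop = FALSE]
  if (artery_elevation_mmHg > 0 && nrow(arteries) > 0) {
    y_um <- (rows - 0.5) * y_pixel_um
    for (i in seq_len(nrow(arteries))) {
      cy_um <- (arteries$center_y[i] - 0.5) * y_pixel_um
      elev <- elev + artery_elevation_mmHg *
        exp(-(y_um - cy_um)^2 / (2 * artery_elevation_sigma_um^2))
    }
  }

  d_clamped <- pmin(pmax(frac_depth, 0), 1)
  tissue_po2 <- matrix(NA_real_, height_px, depth_px)
  in_dye <- coverage > 0
  d <- d_clamped[in_dye]
  vals <- numeric(length(d))
  outer_idx <- d >= 0.5
  vals[outer_idx] <- three_layer_po2(2 * (1 - d[outer_idx]), outer_params)
  inner_idx <- !outer_idx
  elev_mat <- matrix(elev, height_px, depth_px)
  vals[inner_idx] <- inner_po2_base +
    elev_mat[in_dye][inner_idx] * (1 - 2 * d[inner_idx])
  tissue_po2[in_dye] <- pmax(vals, 0)

  vascular_po2 <- matrix(NA_real_, height_px, depth_px)
  vascular_coverage <- matrix(0, height_px, depth_px)
  ymat <- matrix(rows, height_px, depth_px)
  for (i in seq_len(nrow(vessels))) {
    inside <- (ymat - vessels$center_y[i])^2 + (zmat - vessels$center_z[i])^2 <=
      vessels$radius[i]^2
    vascular_po2[inside] <- vessels$po2[i]
    vascular_coverage[inside] <- 1
  }

  structure(list(
    height_px = height_px, depth_px = depth_px,
    y_pixel_um = y_pixel_um, z_pixel_um = z_pixel_um,
    retina_thickness_um = retina_thickness_um,
    interface_trace = interface_trace, inner_trace = inner_trace,
    frac_depth = frac_depth,
    tissue_po2 = tissue_po2, tissue_coverage = coverage,
    vascular_po2 = vascular_po2, vascular_coverage = vascular_coverage,
    vessels = vessels, outer_params = outer_params,
    inner_po2_base = inner_po2_base,
    noise_sigma = noise_sigma, seed = as.integer(seed)
  ), class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf(paste0(
    "<scene_truth> %d x %d px (%g x %g um), retina %g um, %d vessels, ",
    "QO2 = %.3f mL O2/100g/min, noise sigma = %g, seed = %d\n"),
    x$height_px, x$depth_px, x$y_pixel_um, x$z_pixel_um,
    x$retina_thickness_um, nrow(x$vessels),
    qo2_from_params(x$outer_params), x$noise_sigma, x$seed))
  invisible(x)
}

#' Ground-truth summary statistics of a scene
#'
#' Brute-force summaries of the true tension field, for comparison with
#' pipeline output: mean inner-retinal tissue tension, minimum and maximum
#' outer-retinal tension (over pixels whose centers lie in the retina), the
#' outer-retinal QO2 implied by the scene parameters, and per-vessel tensions.
#'
#' @param scene A [build_scene()] object.
#' @return A list with `mean_inner_tpo2`, `min_outer_tpo2`, `max_outer_tpo2`,
#'   `qo2`, `po2a`, `po2v`, and the `vessels` tibble.
#' @export
scene_summary <- function(scene) {
  d <- scene$frac_depth
  inside <- is.finite(d) & d >= 0 & d <= 1
  inner <- inside & d < 0.5
  outer <- inside & d >= 0.5
  list(
    mean_inner_tpo2 = mean(scene$tissue_po2[inner]),
    min_outer_tpo2 = min(scene$tissue_po2[outer]),
    max_outer_tpo2 = max(scene$tissue_po2[outer]),
    qo2 = qo2_from_params(scene$outer_params),
    po2a = mean(scene$vessels$po2[scene$vessels$label == "artery"]),
    po2v = mean(scene$vessels$po2[scene$vessels$label == "vein"]),
    vessels = scene$vessels)
}
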