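#' Assemble and validate a pipeline run configuration
#'
#' @param config A named list, or the path to a YAML file containing one.
#'   Recognized fields (all optional unless noted): `input_dir` (required),
#'   `out_dir` (required), `seed`, `rois` (path; default
#'   `<input_dir>/rois.csv`), `calibration` (list with `tissue`/`vascular`,
#'   each `tau0_s` + `kq`), `curve` (`p50_mmHg`, `hill_n`, `hb_capacity`,
#'   `solubility`), `dk`, `amplitude_threshold`, `inner_threshold`,
#'   `smooth_y`, `smooth_z`, `bin_px`, `epsilon`.
#' @return A validated `run_config` list with defaults filled in (warnings are
#'   emitted for physiology constants that fall back to literature
#'   placeholders).
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$input_dir)) stop("config must name an input_dir")
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  if (!dir.exists(config$input_dir)) {
    stop("input_dir does not exist: ", config$input_dir)
  }
  cfg <- list(
    input_dir = config$input_dir,
    out_dir = config$out_dir,
    seed = as.integer(config$seed %||% 1L),
    rois = config$rois %||% file.path(config$input_dir, "rois.csv"),
    amplitude_threshold = config$amplitude_threshold %||% 0.1,
    inner_threshold = config$inner_threshold %||% 0.1,
    smooth_y = config$smooth_y %||% 6,
    smooth_z = config$smooth_z %||% 4,
    bin_px = config$bin_px %||% 10,
    epsilon = config$epsilon %||% 1)
  if (!file.exists(cfg$rois)) stop("ROI file does not exist: ", cfg$rois)
  mk_cal <- function(ch, name) {
    cc <- config$calibration[[ch]]
    if (is.null(cc)) stop("missing calibration for channel: ", ch)
    oxyphor_calibration(name, tau0_s = cc$tau0_s, kq = cc$kq,
                        source = cc$source %||% NULL)
  }
  if (is.null(config$calibration)) {
    stop("config must provide calibration for both channels ",
         "(calibration$tissue, calibration$vascular)")
  }
  cfg$calib_tissue <- mk_cal("tissue", "G2")
  cfg$calib_vascular <- mk_cal("vascular", "R0")
  crv <- config$curve %||% list()
  cfg$curve <- dissociation_curve(crv$p50_mmHg, crv$hill_n, crv$hb_capacity,
                                  crv$solubility)
  cfg$dk <- config$dk %||% default_dk()
  structure(cfg, class = "run_config")
}

#' Validate a set of phase-delayed stacks against their metadata
#'
#' Checks, without aborting: every declared file exists and has the declared
#' page count; all stacks share one image shape; phase angles are strictly
#' increasing within [0, 180) and match the declared count; both channels are
#' present with equal replicate counts.
#'
#' @param files Character vector of stack paths (as on disk).
#' @param metadata Parsed `metadata.yaml` sidecar (list with a `stacks` entry).
#' @return A tibble of violations (`file`, `check`, `detail`); zero rows when
#'   the set is consistent.
#' @export
validate_stack_set <- function(files, metadata) {
  v <- list()
  note <- function(file, check, detail) {
    v[[length(v) + 1]] <<- tibble::tibble(file = file, check = check,
                                          detail = detail)
  }
  shapes <- list()
  channels <- character(0)
  for (m in metadata$stacks) {
    path <- files[basename(files) == m$file]
    if (length(path) == 0) {
      note(m$file, "file_missing", "declared in metadata but not supplied")
      next
    }
    pages <- tryCatch(tiff::readTIFF(path[1], all = TRUE),
                      error = function(e) NULL)
    if (is.null(pages)) {
      note(m$file, "unreadable", "could not read TIFF")
      next
    }
    if (length(pages) != m$n_pages) {
      note(m$file, "page_count",
           sprintf("expected %d pages, found %d", m$n_pages, length(pages)))
    }
    ph <- unlist(m$phases_deg)
    if (length(ph) != m$n_pages) {
      note(m$file, "phase_count",
           sprintf("%d phase angles for %d pages", length(ph), m$n_pages))
    }
    if (any(diff(ph) <= 0) || any(ph < 0) || any(ph >= 180)) {
      note(m$file, "phase_range",
           "phase angles must be strictly increasing within [0, 180)")
    }
    shapes[[length(shapes) + 1]] <- dim(pages[[1]])
    channels <- c(channels, m$channel)
  }
  if (length(shapes) > 1) {
    ref <- shapes[[1]]
    if (!all(vapply(shapes, identical, logical(1), ref))) {
      note("(set)", "shape", "stacks have differing image shapes")
    }
  }
  for (ch in c("tissue", "vascular")) {
    if (!ch %in% channels) {
      note("(set)", "channel_missing", paste("no", ch, "stack present"))
    }
  }
  if (all(c("tissue", "vascular") %in% channels) &&
      sum(channels == "tissue") != sum(channels == "vascular")) {
    note("(set)", "replicates",
         "unequal replicate counts between channels")
  }
  if (length(v) == 0) {
    tibble::tibble(file = character(0), check = character(0),
                   detail = character(0))
  } else {
    dplyr::bind_rows(v)
  }
}

#' Run the full oxygen tension analysis pipeline
#'
#' End-to-end analysis of one acquisition: per-replicate lifetime estimation
#' and Stern-Volmer conversion for both channels; on the vascular channel,
#' vessel-ROI tensions, per-animal arterial/venous means and the inner retinal
#' oxygen extraction fraction; on the tissue channel, the replicate-mean
#' tension image, curvature flattening, anisotropic smoothing, vertically
#' binned depth profiles, per-profile metrics, three-layer diffusion fits and
#' the mean outer retinal QO2. Results are written to `cfg$out_dir` (tension
#' map TIFFs with a YAML scale sidecar, profiles/metrics/summary CSVs, fits
#' JSON, and a structured plain-text log of every constant, threshold,
#' exclusion and the seed). Any stage failure aborts with a stage-named error
#' after removing partial outputs.
#'
#' @param cfg A [run_config()] (or a list/YAML path accepted by it).
#' @return A result bundle: `vessels`, `vessel_means`, `oef`, `tissue_map`,
#'   `flattened`, `profiles`, `metrics`, `fits`, `qo2`, `summary`,
#'   `violations`, `paths`.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  written <- character(0)
  stage <- "setup"
  on_fail <- function(e) {
    unlink(written)
    stop(sprintf("pipeline failed at stage [%s]: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    stage <- "read"
    fx <- read_fixture(cfg$input_dir)
    rois <- tibble::as_tibble(utils::read.csv(cfg$rois,
                                              stringsAsFactors = FALSE))

    stage <- "validate"
    files <- list.files(cfg$input_dir, pattern = "\\.tif$", full.names = TRUE)
    violations <- validate_stack_set(files, fx$metadata)
    if (nrow(violations) > 0) {
      stop("stack set failed validation: ",
           paste(violations$check, collapse = ", "))
    }
    for (ch in c("tissue", "vascular")) {
      if (length(fx$stacks[[ch]]) == 0) stop("no stacks for channel: ", ch)
    }

    stage <- "lifetime"
    lt_tissue <- lapply(fx$stacks$tissue, estimate_lifetime_map,
                        amplitude_threshold = cfg$amplitude_threshold)
    lt_vascular <- lapply(fx$stacks$vascular, estimate_lifetime_map,
                          amplitude_threshold = cfg$amplitude_threshold)

    stage <- "po2"
    po2_tissue <- lapply(lt_tissue, po2_map, calib = cfg$calib_tissue,
                         epsilon = cfg$epsilon)
    po2_vascular <- lapply(lt_vascular, po2_map, calib = cfg$calib_vascular,
                           epsilon = cfg$epsilon)
    tissue_mean <- average_replicate_maps(po2_tissue)

    stage <- "vessels"
    vessels <- vessel_po2(po2_vascular, rois)
    vmeans <- cohort_vessel_means(vessels)

    stage <- "oef"
    oef_res <- if (is.finite(vmeans$po2a) && is.finite(vmeans$po2v)) {
      oef(vmeans$po2a, vmeans$po2v, cfg$curve)
    } else {
      tibble::tibble(po2a_mmHg = NA_real_, po2v_mmHg = NA_real_, sa = NA_real_,
                     sv = NA_real_, ca = NA_real_, cv = NA_real_,
                     oef = NA_real_)
    }

    stage <- "flatten"
    flat <- flatten_curvature(tissue_mean,
                              inner_threshold = cfg$inner_threshold)

    stage <- "smooth"
    flat$po2_mmHg <- smooth_anisotropic(flat$po2_mmHg,
                                        size_y = cfg$smooth_y,
                                        size_z = cfg$smooth_z)

    stage <- "profiles"
    profiles <- extract_profiles(flat, bin_px = cfg$bin_px)
    metrics <- profile_metrics(profiles)

    stage <- "qo2"
    fits <- fit_qo2_profiles(profiles, Dk = cfg$dk, seed = cfg$seed,
                             smooth_z_px = cfg$smooth_z,
                             z_pixel_um = tissue_mean$z_pixel_um)
    qo2 <- mean_qo2(fits)

    stage <- "write"
    if (!dir.exists(cfg$out_dir)) {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    }
    wfile <- function(name) {
      p <- file.path(cfg$out_dir, name)
      written <<- c(written, p)
      p
    }
    map_scales <- list()
    write_map <- function(map, name) {
      x <- map$po2_mmHg
      x[is.na(x)] <- -1
      off <- -1
      sc <- max(max(x), 1) - off
      suppressWarnings(tiff::writeTIFF(
        list(round((x - off) / sc * (2^32 - 1)) / (2^32 - 1)),
        wfile(name), bits.per.sample = 32L, compression = "none"))
      map_scales[[name]] <<- list(intensity_offset = off, intensity_scale = sc,
                                  invalid_value = -1)
    }
    write_map(tissue_mean, "po2_tissue.tif")
    write_map(average_replicate_maps(po2_vascular), "po2_vascular.tif")
    yaml::write_yaml(map_scales, wfile("po2_maps.yaml"))

    utils::write.csv(profiles, wfile("profiles.csv"), row.names = FALSE)
    utils::write.csv(metrics, wfile("metrics.csv"), row.names = FALSE)
    utils::write.csv(vessels[, setdiff(names(vessels), "per_replicate_po2")],
                     wfile("vessels.csv"), row.names = FALSE)
    jsonlite::write_json(
      dplyr::select(fits, -"fit"), wfile("fits.json"),
      auto_unbox = TRUE, digits = NA)

    usable_metrics <- metrics[metrics$usable, , drop = FALSE]
    summary_row <- tibble::tibble(
      po2a = vmeans$po2a, po2v = vmeans$po2v, oef = oef_res$oef,
      mean_inner_tpo2 = mean(usable_metrics$mean_inner_tpo2, na.rm = TRUE),
      mean_max_outer_tpo2 = mean(usable_metrics$max_outer_tpo2, na.rm = TRUE),
      mean_min_outer_tpo2 = mean(usable_metrics$min_outer_tpo2, na.rm = TRUE),
      mean_qo2 = qo2$mean_qo2,
      n_profiles = sum(metrics$usable),
      n_fits_used = qo2$n_used, n_fits_excluded = qo2$n_excluded)
    utils::write.csv(summary_row, wfile("summary.csv"), row.names = FALSE)

    log_lines <- c(
      sprintf("seed=%d", cfg$seed),
      sprintf("calib_tissue tau0_s=%.8g kq=%.8g", cfg$calib_tissue$tau0_s,
              cfg$calib_tissue$kq),
      sprintf("calib_vascular tau0_s=%.8g kq=%.8g", cfg$calib_vascular$tau0_s,
              cfg$calib_vascular$kq),
      sprintf("curve p50=%.8g n=%.8g hb_capacity=%.8g solubility=%.8g",
              cfg$curve$p50_mmHg, cfg$curve$hill_n, cfg$curve$hb_capacity,
              cfg$curve$solubility),
      sprintf("dk=%.8g", cfg$dk),
      sprintf("amplitude_threshold=%.8g", cfg$amplitude_threshold),
      sprintf("inner_threshold=%.8g", cfg$inner_threshold),
      sprintf("smooth=%dx%d bin_px=%d epsilon=%.8g",
              as.integer(cfg$smooth_y), as.integer(cfg$smooth_z),
              as.integer(cfg$bin_px), cfg$epsilon),
      sprintf("rows_excluded_in_flatten=%d", length(flat$excluded_rows)),
      sprintf("profiles_usable=%d of %d", sum(metrics$usable),
              nrow(metrics)),
      sprintf("fits_used=%d fits_excluded=%d", qo2$n_used, qo2$n_excluded),
      sprintf("vessels_missing=%d", sum(vessels$missing)))
    writeLines(log_lines, wfile("log.txt"))

    list(vessels = vessels, vessel_means = vmeans, oef = oef_res,
         tissue_map = tissue_mean, flattened = flat, profiles = profiles,
         metrics = metrics, fits = fits, qo2 = qo2, summary = summary_row,
         violations = violations, paths = written)
  }, error = on_fail)
}
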