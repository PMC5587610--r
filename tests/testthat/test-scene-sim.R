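test_that("zero curvature gives a constant interface and zero consumption a flat outer profile", {
  sc <- small_scene(curvature_sag_px = 0)
  expect_equal(diff(range(sc$interface_trace)), 0)

  flat <- build_scene(height_px = 40, depth_px = 60,
                      retina_thickness_um = 144, interface_apex_px = 45,
                      curvature_sag_px = 0, pc_mmHg = 30, pl_mmHg = 30,
                      qo2 = 0, x1_frac = 0.2, x2_frac = 0.4,
                      inner_po2_base = 30, artery_elevation_mmHg = 0,
                      noise_sigma = 0, Dk = dk_lit())
  d <- flat$frac_depth
  outer <- is.finite(d) & d >= 0.5 & d <= 1
  expect_true(all(abs(flat$tissue_po2[outer] - 30) < 1e-12))
})

test_that("the default depth profile peaks in the outer half (brute-force argmax)", {
  sc <- build_scene(pc_mmHg = 60, inner_po2_base = 23, noise_sigma = 0,
                    Dk = dk_lit())
  for (r in c(1, 100, 175, 350)) {
    row_d <- sc$frac_depth[r, ]
    row_v <- sc$tissue_po2[r, ]
    inside <- is.finite(row_d) & row_d >= 0 & row_d <= 1
    expect_gte(row_d[inside][which.max(row_v[inside])], 0.5)
  }
})

test_that("invalid scene configurations are rejected", {
  expect_error(build_scene(retina_thickness_um = -1), "positive")
  expect_error(build_scene(height_px = 0), "positive")
  expect_error(build_scene(depth_px = 30, retina_thickness_um = 230,
                           Dk = dk_lit()), "fit")
  expect_error(small_scene(vessel_depth_frac = 0.45), "inner half")
})

test_that("rendered noise-free intensities match the closed-form homodyne model", {
  sc <- small_scene()
  acq <- acquisition_settings(n_replicates = 1)
  st <- render_phase_stacks(sc, acq, g2_cal(), r0_cal())
  s <- st$tissue[[1]]
  # spot-check pixels across the retina against independent formula evaluation
  set.seed(42)
  pix <- cbind(sample(sc$height_px, 25, TRUE), sample(sc$depth_px, 25, TRUE))
  for (i in seq_len(nrow(pix))) {
    r <- pix[i, 1]; cc <- pix[i, 2]
    cov <- sc$tissue_coverage[r, cc]
    if (cov == 0) {
      expect_equal(s$images[r, cc, ], rep(0, 10))
    } else {
      tau <- 1 / (1 / 251e-6 + 281 * sc$tissue_po2[r, cc])
      w <- 2 * pi * 1600 * tau
      expected <- 1000 * cov *
        (1 + 0.8 / sqrt(1 + w^2) * cos((0:9) * 18 * pi / 180 - atan(w)))
      expect_equal(s$images[r, cc, ], expected, tolerance = 1e-12)
    }
  }
})

test_that("rendering is deterministic in the seed and replicates only differ by noise", {
  sc <- small_scene(noise_sigma = 5)
  acq <- acquisition_settings(n_replicates = 2)
  a <- render_phase_stacks(sc, acq, g2_cal(), r0_cal())
  b <- render_phase_stacks(sc, acq, g2_cal(), r0_cal())
  expect_identical(a$tissue[[1]]$images, b$tissue[[1]]$images)
  expect_identical(a$vascular[[2]]$images, b$vascular[[2]]$images)
  expect_false(identical(a$tissue[[1]]$images, a$tissue[[2]]$images))

  sc0 <- small_scene(noise_sigma = 0)
  z <- render_phase_stacks(sc0, acq, g2_cal(), r0_cal())
  expect_identical(z$tissue[[1]]$images, z$tissue[[2]]$images)
})

test_that("zero oxygen gives tau0 and omega*tau = 1 gives a 45 degree lag", {
  expect_equal(sv_tau(0, g2_cal()), 251e-6)
  tau45 <- 1 / (2 * pi * 1600)
  expect_equal(phase_lag_deg(tau45, 1600), 45)
  # and the lag is monotone decreasing in PO2 at fixed frequency
  po2 <- seq(0, 100, by = 5)
  taus <- sv_tau(po2, g2_cal())
  expect_true(all(diff(taus) < 0))
  expect_true(all(diff(phase_lag_deg(taus, 1600)) < 0))
})

test_that("fixtures serialize with the protocol's file and page counts and read back stably", {
  sc <- small_scene()
  acq <- acquisition_settings(n_replicates = 3)
  st <- render_phase_stacks(sc, acq, g2_cal(), r0_cal())
  d1 <- withr::local_tempdir()
  write_fixture(sc, st, d1, acq = acq)

  tifs <- list.files(d1, pattern = "\\.tif$")
  expect_length(tifs, 6)  # 2 channels x 3 replicates
  expect_length(tiff::readTIFF(file.path(d1, tifs[1]), all = TRUE), 10)

  fx1 <- read_fixture(d1)
  # write-read-write round trip is bit-stable
  d2 <- withr::local_tempdir()
  write_fixture(sc, fx1$stacks, d2, acq = acq)
  fx2 <- read_fixture(d2)
  expect_identical(fx1$stacks$tissue[[2]]$images, fx2$stacks$tissue[[2]]$images)
  expect_identical(fx1$stacks$vascular[[3]]$images,
                   fx2$stacks$vascular[[3]]$images)
  expect_identical(unname(tools::md5sum(file.path(d1, "tissue_rep1.tif"))),
                   unname(tools::md5sum(file.path(d2, "tissue_rep1.tif"))))
})
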