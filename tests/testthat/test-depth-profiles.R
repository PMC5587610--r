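test_that("anisotropic smoothing is a renormalized window mean", {
  set.seed(3)
  x <- matrix(rnorm(30 * 20, 50, 5), 30, 20)
  s <- smooth_anisotropic(x, 6, 4)
  # interior pixel against direct summation with the same window anchoring
  for (px in list(c(10, 10), c(15, 5), c(25, 17))) {
    r <- px[1]; cc <- px[2]
    win <- x[r + (-3:2), cc + (-2:1)]
    expect_equal(s[r, cc], mean(win))
  }
  # constant maps are unchanged, including at borders
  k <- matrix(23, 15, 15)
  expect_equal(smooth_anisotropic(k, 6, 4), k)
  # a single valid pixel among invalid neighbours keeps its value
  one <- matrix(NA_real_, 9, 9)
  one[5, 5] <- 17
  expect_equal(smooth_anisotropic(one, 6, 4)[5, 5], 17)
})

test_that("flattening is near-identity on flat scenes and recovers quadratic sag", {
  calT <- g2_cal(); calV <- r0_cal()
  mk_map <- function(sc) {
    st <- render_phase_stacks(sc, acquisition_settings(n_replicates = 1),
                              calT, calV)
    po2_map(estimate_lifetime_map(st$tissue[[1]]), calT)
  }
  flat_sc <- small_scene(curvature_sag_px = 0)
  ff <- flatten_curvature(mk_map(flat_sc))
  expect_lt(max(abs(ff$shifts)), 0.5)

  sag_sc <- build_scene(height_px = 80, depth_px = 80,
                        retina_thickness_um = 144, interface_apex_px = 55,
                        curvature_sag_px = 10, noise_sigma = 0, seed = 2,
                        Dk = dk_lit(),
                        vessels = data.frame(label = c("artery", "vein"),
                                             center_y = c(20, 60), radius = 4,
                                             po2 = c(41, 25)))
  fs <- flatten_curvature(mk_map(sag_sc))
  # the applied shift encodes the detected interface: target - shift
  target <- mean(fs$interface_trace, na.rm = TRUE)
  recovered <- target - fs$shifts
  expect_lt(max(abs(recovered - sag_sc$interface_trace)), 1)
  # after flattening the interface is a near-constant column
  expect_lt(stats::var(fs$interface_trace, na.rm = TRUE), 1)

  # idempotence: a second pass moves rows by less than half a pixel
  fs2 <- flatten_curvature(fs)
  expect_lt(max(abs(fs2$shifts), na.rm = TRUE), 0.5)
})

test_that("profile extraction bins rows exactly and handles degenerate maps", {
  set.seed(11)
  H <- 350; D <- 60
  po2 <- matrix(rnorm(H * D, 30, 3), H, D)
  fm <- flattened_map(po2, interface_trace = rep(52.5, H),
                      inner_trace = rep(8.5, H))
  pr <- extract_profiles(fm, bin_px = 10)
  expect_length(unique(pr$profile), 35)
  expect_true(all(pr$usable))
  # each profile value is the brute-force mean of its 10 source rows
  for (b in c(1, 17, 35)) {
    rows <- ((b - 1) * 10 + 1):(b * 10)
    js <- 9:52
    expect_equal(pr$tpo2_mmHg[pr$profile == b], colMeans(po2[rows, js]))
    expect_equal(pr$fractional_depth[pr$profile == b], (js - 8.5) / 44)
  }
  # conservation: the mean over a bin's profile equals the mean of its pixels
  b1 <- pr[pr$profile == 1, ]
  expect_equal(mean(b1$tpo2_mmHg), mean(po2[1:10, 9:52]))

  # fewer rows than a bin: explicit empty result
  tiny <- flattened_map(po2[1:9, ], rep(52.5, 9), rep(8.5, 9))
  expect_identical(nrow(extract_profiles(tiny, bin_px = 10)), 0L)

  # a bin with a too-thin retina is flagged unusable
  thin <- flattened_map(po2[1:20, ], c(rep(12, 10), rep(52.5, 10)),
                        rep(8.5, 20))
  thin_pr <- extract_profiles(thin, bin_px = 10)
  expect_false(any(thin_pr$usable[thin_pr$profile == 1]))
  expect_true(all(thin_pr$usable[thin_pr$profile == 2]))
})

test_that("profile metrics split inner and outer retina at 50% depth", {
  const <- tibble::tibble(profile = 1L, y_center_um = 15,
                          fractional_depth = seq(0, 1, by = 0.05),
                          tpo2_mmHg = 23, thickness_um = 230, usable = TRUE)
  m <- profile_metrics(const)
  expect_equal(m$max_outer_tpo2, 23)
  expect_equal(m$min_outer_tpo2, 23)
  expect_equal(m$mean_inner_tpo2, 23)

  inc <- const
  inc$tpo2_mmHg <- 10 + 30 * inc$fractional_depth
  mi <- profile_metrics(inc)
  expect_equal(mi$max_outer_tpo2, 40)       # at depth 1.0
  expect_equal(mi$min_outer_tpo2, 10 + 30 * 0.5)  # 0.5 belongs to the outer retina
  expect_equal(mi$mean_inner_tpo2,
               mean(inc$tpo2_mmHg[inc$fractional_depth < 0.5]))
})

test_that("simulated profiles match a brute-force scan of the ground-truth field", {
  sc <- small_scene(curvature_sag_px = 0, artery_elevation_mmHg = 0)
  st <- render_phase_stacks(sc, acquisition_settings(n_replicates = 1),
                            g2_cal(), r0_cal())
  fl <- flatten_curvature(po2_map(estimate_lifetime_map(st$tissue[[1]]),
                                  g2_cal()))
  pr <- extract_profiles(fl)
  met <- profile_metrics(pr)
  truth <- scene_summary(sc)
  # no artery elevation: the tissue field is y-uniform, every profile sees the
  # same ground truth (vessels live in the other imaging channel)
  expect_lt(max(abs(met$max_outer_tpo2 - truth$max_outer_tpo2)), 1)
  expect_lt(max(abs(met$min_outer_tpo2 - truth$min_outer_tpo2)), 1)
  expect_lt(max(abs(met$mean_inner_tpo2 - sc$inner_po2_base)), 1)
  # noise-free flatten + extract recovers the depth profile shape to < 1 mmHg
  p1 <- pr[pr$profile == met$profile[1] & pr$fractional_depth >= 0.5, ]
  model <- three_layer_po2(2 * (1 - p1$fractional_depth), sc$outer_params)
  expect_lt(sqrt(mean((p1$tpo2_mmHg - model)^2)), 1)
})

test_that("metrics are invariant to vertical flips and the inner trace peaks at arteries", {
  sc <- small_scene(curvature_sag_px = 0)
  st <- render_phase_stacks(sc, acquisition_settings(n_replicates = 1),
                            g2_cal(), r0_cal())
  fl <- flatten_curvature(po2_map(estimate_lifetime_map(st$tissue[[1]]),
                                  g2_cal()))
  pr <- extract_profiles(fl)
  met <- profile_metrics(pr)

  flipped <- flattened_map(fl$po2_mmHg[nrow(fl$po2_mmHg):1, ],
                           rev(fl$interface_trace), rev(fl$inner_trace),
                           amplitude = fl$amplitude[nrow(fl$po2_mmHg):1, ],
                           y_pixel_um = fl$y_pixel_um,
                           z_pixel_um = fl$z_pixel_um)
  met_f <- profile_metrics(extract_profiles(flipped))
  expect_equal(met_f$max_outer_tpo2, rev(met$max_outer_tpo2), tolerance = 1e-12)
  expect_equal(met_f$min_outer_tpo2, rev(met$min_outer_tpo2), tolerance = 1e-12)
  expect_equal(met_f$mean_inner_tpo2, rev(met$mean_inner_tpo2),
               tolerance = 1e-12)

  tr <- inner_tpo2_trace(pr)
  expect_equal(nrow(tr), sum(unique(pr$profile) %in%
                               pr$profile[pr$usable]))
  # the single-artery side of the scene: peak within 60 um of the artery
  artery_y <- (sc$vessels$center_y[sc$vessels$label == "artery"] - 0.5) *
    sc$y_pixel_um
  peak_y <- tr$y_center_um[which.max(tr$mean_inner_tpo2)]
  expect_lt(min(abs(peak_y - artery_y)), 60)

  # a uniform inner field gives a constant trace
  sc0 <- small_scene(curvature_sag_px = 0, artery_elevation_mmHg = 0)
  st0 <- render_phase_stacks(sc0, acquisition_settings(n_replicates = 1),
                             g2_cal(), r0_cal())
  fl0 <- flatten_curvature(po2_map(estimate_lifetime_map(st0$tissue[[1]]),
                                   g2_cal()))
  tr0 <- inner_tpo2_trace(extract_profiles(fl0))
  expect_lt(diff(range(tr0$mean_inner_tpo2)), 0.2)
})
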