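test_that("Stern-Volmer conversion hits its identities and is the simulator's inverse", {
  g2 <- g2_cal()
  expect_equal(stern_volmer_po2(g2$tau0_s, g2), 0)
  # direct evaluation with the shipped G2 constants
  expect_equal(stern_volmer_po2(100e-6, g2), (1e4 - 1 / 251e-6) / 281,
               tolerance = 1e-12)
  expect_equal(stern_volmer_po2(100e-6, g2), 21.41, tolerance = 1e-3)

  po2 <- seq(0, 100, by = 0.25)
  back <- stern_volmer_po2(sv_tau(po2, g2), g2)
  expect_lt(max(abs(back - po2)), 1e-9)
  # strictly decreasing in tau
  taus <- seq(20e-6, 250e-6, length.out = 50)
  expect_true(all(diff(stern_volmer_po2(taus, g2)) < 0))

  expect_error(stern_volmer_po2(-1e-6, g2), "positive")
  # noise-induced small negatives clip to zero; gross ones invalidate
  tau_small_neg <- 1 / (1 / g2$tau0_s - g2$kq * 0.5)
  expect_equal(stern_volmer_po2(tau_small_neg, g2), 0)
  tau_big_neg <- 1 / (1 / g2$tau0_s - g2$kq * 5)
  expect_true(is.na(stern_volmer_po2(tau_big_neg, g2)))
})

test_that("po2 maps propagate masks and invert the forward model end to end", {
  sc <- small_scene()
  st <- render_phase_stacks(sc, acquisition_settings(n_replicates = 1),
                            g2_cal(), r0_cal())
  lt <- estimate_lifetime_map(st$tissue[[1]])
  pm <- po2_map(lt, g2_cal())
  sel <- pm$valid & sc$tissue_coverage > 0.999
  expect_lt(max(abs(pm$po2_mmHg[sel] - sc$tissue_po2[sel])), 1e-4)

  lt$valid[] <- FALSE
  expect_false(any(po2_map(lt, g2_cal())$valid))
})

test_that("replicate averaging is an idempotent, mask-conjunctive pixel mean", {
  base <- small_scene()
  st <- render_phase_stacks(base, acquisition_settings(n_replicates = 1),
                            g2_cal(), r0_cal())
  m <- po2_map(estimate_lifetime_map(st$tissue[[1]]), g2_cal())
  expect_equal(average_replicate_maps(list(m, m, m))$po2_mmHg, m$po2_mmHg)

  m1 <- m; m2 <- m; m3 <- m
  px <- which(m$valid)[1]
  m1$po2_mmHg[px] <- 10; m2$po2_mmHg[px] <- 20; m3$po2_mmHg[px] <- 30
  avg <- average_replicate_maps(list(m1, m2, m3))
  expect_equal(avg$po2_mmHg[px], 20)

  m2$valid[px] <- FALSE
  avg2 <- average_replicate_maps(list(m1, m2, m3))
  expect_false(avg2$valid[px])
  expect_true(is.na(avg2$po2_mmHg[px]))

  expect_error(average_replicate_maps(list()), "no maps")
  shrunk <- m
  shrunk$po2_mmHg <- m$po2_mmHg[1:10, ]
  shrunk$valid <- m$valid[1:10, ]
  expect_error(average_replicate_maps(list(m, shrunk)), "shape")
})

test_that("vessel ROI tensions recover the scene's arterial and venous values", {
  sc <- small_scene()
  st <- render_phase_stacks(sc, acquisition_settings(n_replicates = 3),
                            g2_cal(), r0_cal())
  maps <- lapply(st$vascular, function(s) {
    po2_map(estimate_lifetime_map(s), r0_cal())
  })
  vs <- vessel_po2(maps, sc$vessels)
  expect_equal(vs$mean_po2[vs$label == "artery"], 41, tolerance = 1e-3)
  expect_equal(vs$mean_po2[vs$label == "vein"], 25, tolerance = 1e-3)
  expect_false(any(vs$missing))
  expect_true(all(vs$n_replicates == 3))

  # a uniform field inside the ROI returns exactly that value
  m <- maps[[1]]
  m$po2_mmHg[] <- 41
  m$valid[] <- TRUE
  one <- vessel_po2(m, data.frame(label = "artery", center_y = 30,
                                  center_z = 30, radius = 4))
  expect_equal(one$mean_po2, 41)

  # an ROI with no valid pixels is flagged missing, not an error
  m$valid[] <- FALSE
  none <- vessel_po2(m, data.frame(label = "vein", center_y = 30,
                                   center_z = 30, radius = 4))
  expect_true(none$missing)
  expect_error(vessel_po2(m, data.frame(label = "vein", center_y = 500,
                                        center_z = 30, radius = 4)),
               "outside")
})

test_that("per-animal vessel means average within type and ignore order", {
  vs <- tibble::tibble(label = c("artery", "artery", "vein"),
                       mean_po2 = c(40, 42, 25))
  cm <- cohort_vessel_means(vs)
  expect_equal(cm$po2a, 41)
  expect_equal(cm$po2v, 25)
  expect_identical(cohort_vessel_means(vs[c(3, 1, 2), ]), cm)

  single <- cohort_vessel_means(tibble::tibble(label = "artery",
                                               mean_po2 = 38.5))
  expect_equal(single$po2a, 38.5)
  expect_true(is.na(single$po2v))
  expect_equal(single$n_veins, 0)
})

test_that("averaging replicates in tension and lifetime domains differ off constant fields", {
  g2 <- g2_cal()
  t1 <- sv_tau(20, g2); t2 <- sv_tau(40, g2)
  po2_domain <- mean(stern_volmer_po2(c(t1, t2), g2))
  tau_domain <- stern_volmer_po2(mean(c(t1, t2)), g2)
  expect_equal(po2_domain, 30)           # the pipeline's convention
  expect_gt(abs(po2_domain - tau_domain), 0.5)  # the two orders disagree
  # ... but coincide for a constant field
  expect_equal(mean(stern_volmer_po2(c(t1, t1), g2)),
               stern_volmer_po2(mean(c(t1, t1)), g2))
})
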