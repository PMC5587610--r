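test_that("the closed form satisfies its boundary and continuity constraints", {
  p <- three_layer_params(60, 20, 0.2, 0.4, q2 = 0.0285, L_um = 115,
                          Dk = dk_lit())
  expect_equal(three_layer_po2(0, p), 60)
  expect_equal(three_layer_po2(1, p), 20)
  eps <- 1e-9
  for (xb in c(0.2, 0.4)) {
    expect_lt(abs(three_layer_po2(xb - eps, p) - three_layer_po2(xb + eps, p)),
              1e-6)
    # flux continuity via one-sided difference quotients
    h <- 1e-7
    dl <- (three_layer_po2(xb - h, p) - three_layer_po2(xb - 2 * h, p)) / h
    dr <- (three_layer_po2(xb + 2 * h, p) - three_layer_po2(xb + h, p)) / h
    # slopes differ across the boundary by at most the layer-2 curvature step
    k_frac <- p$q2 / p$Dk * (p$L_um * 1e-4)^2  # d2P/dxfrac2
    expect_lt(abs(dr - dl), 3 * h * k_frac + 1e-6)
  }

  # no consumption: straight line; equal boundaries: constant
  lin <- three_layer_params(60, 20, 0.2, 0.4, q2 = 0, L_um = 115,
                            Dk = dk_lit())
  xg <- seq(0, 1, by = 0.05)
  expect_equal(three_layer_po2(xg, lin), 60 - 40 * xg, tolerance = 1e-12)
  flat <- three_layer_params(30, 30, 0.2, 0.4, q2 = 0, L_um = 115,
                             Dk = dk_lit())
  expect_equal(three_layer_po2(xg, flat), rep(30, length(xg)))

  expect_error(three_layer_params(60, 20, 0.5, 0.4, 0.01, 115, dk_lit()))
  expect_error(three_layer_params(60, 20, 0.2, 0.4, -1, 115, dk_lit()))
})

test_that("the discrete curvature is q2/Dk inside layer 2 and zero outside", {
  p <- three_layer_params(60, 20, 0.25, 0.55, q2 = 0.02, L_um = 120,
                          Dk = dk_lit())
  L_cm <- 120e-4
  h <- 1e-3  # in x_frac
  xg <- seq(h, 1 - h, by = h)
  P <- three_layer_po2(xg, p)
  d2 <- (P[-c(1, 2)] - 2 * P[-c(1, length(P))] + P[-c(length(P) - 1,
                                                      length(P))]) /
    (h * L_cm)^2
  xm <- xg[-c(1, length(xg))]
  in2 <- xm > 0.25 + 2 * h & xm < 0.55 - 2 * h
  out2 <- xm < 0.25 - 2 * h | xm > 0.55 + 2 * h
  expect_equal(max(abs(d2[in2] - p$q2 / p$Dk)) / (p$q2 / p$Dk), 0,
               tolerance = 1e-6)
  expect_lt(max(abs(d2[out2])), 1e-9 * p$q2 / p$Dk + 1e-3)
})

test_that("the closed form matches the finite-difference oracle on random draws", {
  set.seed(202)
  for (i in 1:10) {
    x1 <- runif(1, 0.05, 0.5)
    p <- three_layer_params(runif(1, 20, 80), runif(1, 10, 40),
                            x1, x1 + runif(1, 0.05, 0.9 - x1),
                            q2 = runif(1, 0, 0.06),
                            L_um = runif(1, 80, 150), Dk = dk_lit())
    fd <- fd_three_layer(p, n = 2000)
    expect_lt(max(abs(three_layer_po2(fd$x_frac, p) - fd$po2)), 1e-3)
  }
})

test_that("consumption is invariant to a consistent change of length units", {
  # expressing the slab in different length units (L -> cL, Dk -> c^2 Dk)
  # leaves both the profile and the averaged consumption unchanged
  base <- three_layer_params(45, 22, 0.3, 0.5, q2 = 0.03, L_um = 110,
                             Dk = dk_lit())
  scaled <- three_layer_params(45, 22, 0.3, 0.5, q2 = 0.03, L_um = 1100,
                               Dk = dk_lit() * 100)
  xg <- seq(0, 1, by = 0.02)
  expect_equal(three_layer_po2(xg, base), three_layer_po2(xg, scaled),
               tolerance = 1e-12)
  expect_equal(qo2_from_params(base), qo2_from_params(scaled))
})

test_that("raising q2 strictly lowers the minimum layer tension", {
  # consumption rates high enough for an interior minimum to form
  mins <- vapply(c(0.03, 0.045, 0.06, 0.08), function(q2) {
    p <- three_layer_params(45, 25, 0.2, 0.4, q2 = q2, L_um = 115,
                            Dk = dk_lit())
    min(three_layer_po2(seq(0, 1, length.out = 400), p))
  }, numeric(1))
  expect_true(all(diff(mins) < 0))
})

test_that("noise-free model-generated profiles are recovered almost exactly", {
  xg <- seq(0, 1, length.out = 26)
  for (truth in list(
    three_layer_params(33, 23, 0.2, 0.4, q2 = 0.0285, L_um = 115,
                       Dk = dk_lit()),
    three_layer_params(55, 18, 0.3, 0.55, q2 = 0.015, L_um = 130,
                       Dk = dk_lit()))) {
    prof <- tibble::tibble(fractional_depth = 1 - xg / 2,
                           tpo2_mmHg = three_layer_po2(xg, truth))
    fit <- fit_three_layer(prof, L_um = truth$L_um, Dk = truth$Dk, seed = 5)
    expect_true(fit$converged)
    expect_equal(fit$qo2_mlo2_per_100g_min, qo2_from_params(truth),
                 tolerance = 1e-3)
    expect_equal(fit$params$pc_mmHg, truth$pc_mmHg, tolerance = 1e-3)
    expect_equal(fit$params$x1_frac, truth$x1_frac, tolerance = 5e-3)
  }

  # a flat profile fits with essentially zero consumption
  flat_prof <- tibble::tibble(fractional_depth = 1 - xg / 2, tpo2_mmHg = 30)
  flat_fit <- fit_three_layer(flat_prof, L_um = 115, Dk = dk_lit(), seed = 5)
  expect_lt(flat_fit$qo2_mlo2_per_100g_min, 1e-6)

  expect_error(fit_three_layer(flat_prof[1:5, ], L_um = 115, Dk = dk_lit()),
               "at least 8")
})

test_that("tidy and glance expose the fitted parameters", {
  xg <- seq(0, 1, length.out = 20)
  truth <- three_layer_params(40, 22, 0.2, 0.45, q2 = 0.02, L_um = 115,
                              Dk = dk_lit())
  fit <- fit_three_layer(
    tibble::tibble(fractional_depth = 1 - xg / 2,
                   tpo2_mmHg = three_layer_po2(xg, truth)),
    L_um = 115, Dk = dk_lit(), seed = 3)
  td <- tidy(fit)
  expect_setequal(td$term, c("pc_mmHg", "pl_mmHg", "x1_frac", "x2_frac",
                             "q2", "qo2"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$qo2, fit$qo2_mlo2_per_100g_min)
})

test_that("mean consumption excludes diverged fits and ignores order", {
  tb <- tibble::tibble(
    profile = 1:4, y_center_um = 1:4 * 30,
    qo2 = c(0.5, 0.6, 5, 0.55), rss = 0.1, r2 = 0.99,
    converged = c(TRUE, TRUE, FALSE, TRUE),
    at_bound = c(FALSE, FALSE, FALSE, FALSE), n = 20L)
  mq <- mean_qo2(tb)
  expect_equal(mq$mean_qo2, mean(c(0.5, 0.6, 0.55)))
  expect_equal(mq$n_used, 3L)
  expect_equal(mq$n_excluded, 1L)
  expect_equal(mean_qo2(tb[sample(4), ])$mean_qo2, mq$mean_qo2)
  # all identical fits return that value
  same <- tb; same$qo2 <- 0.57; same$converged <- TRUE
  expect_equal(mean_qo2(same)$mean_qo2, 0.57)
  none <- tb; none$converged <- FALSE
  expect_true(is.na(mean_qo2(none)$mean_qo2))
})
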