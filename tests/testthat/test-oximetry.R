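test_that("ROI extraction: single A-line, linearity, empty-mask contract", {
  ch <- arterial_chain()
  ilm <- ch$surf$ilm
  mask1 <- matrix(FALSE, 32, 64); mask1[16, 10] <- TRUE
  ds <- extract_roi_spectra(ch$stack, mask1, ilm)
  i0 <- round(ilm[16, 10])
  L <- nrow(ds$I_z_lambda)
  expect_equal(ds$I_z_lambda,
               ch$stack$subbands[i0:(i0 + L - 1), 10, 16, ],
               ignore_attr = TRUE)
  # averaging over wavelength and over space commute
  mask2 <- matrix(FALSE, 32, 64); mask2[16, 10:12] <- TRUE
  ds2 <- extract_roi_spectra(ch$stack, mask2, ilm)
  per_px <- sapply(10:12, function(a) {
    i <- round(ilm[16, a])
    rowMeans(ch$stack$subbands[i:(i + nrow(ds2$I_z_lambda) - 1), a, 16, ])
  })
  expect_equal(ds2$mean_subband, rowMeans(per_px))
  expect_error(extract_roi_spectra(ch$stack, matrix(FALSE, 32, 64), ilm),
               "empty ROI")
})

test_that("RNFL normalization cancels the reference and rejects bad references", {
  m <- matrix(stats::runif(5 * 11, 1, 2), 5, 11)
  ds <- manual_ds(m)
  # reference equal to one row makes that row unity
  nd <- normalize_by_rnfl(ds, ref = m[3, ])
  expect_equal(unname(nd$I_z_lambda[3, ]), rep(1, 11))
  # flat reference is a pure rescale
  nd2 <- normalize_by_rnfl(ds, ref = rep(2, 11))
  expect_equal(nd2$I_z_lambda, m / 2)
  expect_error(normalize_by_rnfl(ds, ref = c(rep(1, 10), 0)), "positive")
  expect_error(normalize_by_rnfl(ds, ref = rep(1, 4)), "mismatch")
})

test_that("vessel bottom is the second reflective peak below the ILM", {
  z <- 1:60
  prof <- exp(-0.5 * ((z - 10) / 1.5)^2) + 0.8 * exp(-0.5 * ((z - 25) / 1.5)^2)
  ds <- manual_ds(matrix(prof, 60, 11), mean_aline = prof)
  bot <- find_vessel_bottom(ds)
  expect_equal(as.integer(bot), 25)
  expect_equal(attr(bot, "top"), 10)
  # monotone profile has no second peak: the vessel is excluded
  ds2 <- manual_ds(matrix(exp(-z / 10), 60, 11), mean_aline = exp(-z / 10))
  expect_error(find_vessel_bottom(ds2), "bottom not found")
})

test_that("bottom-window spectrum averaging is constant-preserving and clips at edges", {
  m <- matrix(rep(c(1, 2, 3), each = 30), 30, 3)
  ds <- manual_ds(m, lambda = c(530, 560, 590))
  expect_equal(unname(extract_bottom_spectrum(ds, 15)), c(1, 2, 3))
  expect_equal(unname(extract_bottom_spectrum(ds, 2)), c(1, 2, 3))
  expect_equal(unname(extract_bottom_spectrum(ds, 29)), c(1, 2, 3))
  expect_error(extract_bottom_spectrum(ds), "not set")
})

test_that("forward model obeys its endpoint and limit identities", {
  tab <- ext_tab()
  lam <- seq(520, 600, length.out = 11)
  mu <- mu_attenuation(tab, lam)
  s1 <- model_spectrum(1, 2, 0.5, 0.04, tab, lam)
  expect_equal(log(2 * (lam / 560)^-0.5) - log(s1), mu$mu_hbo2 * 0.04)
  # z -> 0 leaves the bare power law
  s0 <- model_spectrum(0.7, 2, 0.5, 1e-12, tab, lam)
  expect_equal(s0, 2 * (lam / 560)^-0.5, tolerance = 1e-6)
  # attenuation exponent is linear in sO2
  sa <- model_spectrum(0, 1, 0, 0.05, tab, lam)
  sb <- model_spectrum(1, 1, 0, 0.05, tab, lam)
  sm <- model_spectrum(0.5, 1, 0, 0.05, tab, lam)
  expect_equal(log(sm), (log(sa) + log(sb)) / 2)
})

test_that("noiseless spectra at the cohort mean saturations invert exactly", {
  tab <- ext_tab()
  lam <- seq(520, 600, length.out = 11)
  for (truth in c(0.921, 0.484)) {
    sp <- model_spectrum(truth, 1, 1, 0.05, tab, lam)
    f <- fit_so2(sp, lam, 0.05, tab)
    expect_true(f$success)
    expect_lt(abs(f$so2 - truth), 1e-3)
    expect_equal(f$so2_volpct, 100 * f$so2)
  }
})

test_that("bounded least squares agrees with the exhaustive grid oracle", {
  tab <- ext_tab()
  lam <- seq(520, 600, length.out = 11)
  set.seed(42)
  for (i in 1:20) {
    truth <- runif(1); A <- exp(runif(1, -1, 1))
    al <- runif(1, -3, 3); z <- runif(1, 0.02, 0.08)
    sp <- model_spectrum(truth, A, al, z, tab, lam)
    f <- fit_so2(sp, lam, z, tab)
    g <- oracle_grid_so2(sp, lam, z, tab)
    expect_lt(abs(f$so2 - g), 0.005)
  }
})

test_that("fitted sO2 is strictly increasing in true sO2 and scale invariant", {
  tab <- ext_tab()
  lam <- seq(520, 600, length.out = 11)
  grid <- seq(0, 1, by = 0.1)
  fits <- vapply(grid, function(s) {
    fit_so2(model_spectrum(s, 1, 1, 0.05, tab, lam), lam, 0.05, tab)$so2
  }, 0)
  expect_true(all(diff(fits) > 0))
  sp <- model_spectrum(0.6, 1, 1, 0.05, tab, lam)
  f1 <- fit_so2(sp, lam, 0.05, tab)
  f2 <- fit_so2(37 * sp, lam, 0.05, tab)
  expect_equal(f1$so2, f2$so2, tolerance = 1e-6)
  expect_equal(f2$A_refl / f1$A_refl, 37, tolerance = 1e-4)
  expect_error(fit_so2(c(sp[-11], -1), lam, 0.05, tab), "positive")
})

test_that("phantom forward-inverse chain recovers the configured saturation", {
  # the spectrum extracted at the phantom vessel bottom, normalized by the
  # measured RNFL reference, inverts to the generating sO2 (the residual
  # few-percent bias comes from window-edge truncation and reflex
  # cross-talk, documented in the methods vignette)
  ch <- arterial_chain()
  tr <- ch$ph$truth$vessel_masks[[1]]
  ref <- measure_rnfl_spectrum(ch$stack, ch$surf$ilm, tr)
  res <- vessel_oximetry(ch$stack, tr, ch$surf$ilm, ref, ch$tab, 1.55)
  expect_true(res$fit$success)
  expect_lt(abs(res$fit$so2_volpct - 92.1), 4)
  # detected bottom row agrees with the buried lumen geometry
  rel_bottom <- res$ds$bottom_idx - 1
  expect_lte(abs(rel_bottom - ch$ph$truth$vessel_rel_bottom[1]), 2)
  expect_equal(res$ds$z_path_mm, 2 * 24.8 / 1000, tolerance = 0.07)
})
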