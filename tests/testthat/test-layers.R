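test_that("raw RPE detection recovers a flat bright RPE exactly and flags dead A-lines", {
  cfg <- phantom_config(n_bscans = 4, n_alines = 32, n_depth = 128,
                        n_spectral = 256, fov_mm = 32 * 0.02,
                        rpe = list(center_px = 90, bow_px = 0), retina_px = 60, seed = 2)
  ph <- make_phantom(cfg, ext_tab())
  vol <- reconstruct_fullband(ph$volume)
  raw <- detect_rpe_raw(vol)
  expect_equal(raw, ph$truth$rpe_depth, ignore_attr = TRUE)
  vol[, 5, 2] <- 0
  raw2 <- detect_rpe_raw(vol)
  expect_true(is.na(raw2[2, 5]))
  expect_equal(raw2[1, ], ph$truth$rpe_depth[1, ], ignore_attr = TRUE)
})

test_that("an A-line with brighter inner retina than RPE yields an intentional outlier", {
  Z <- 128; nA <- 64
  vol <- array(0, dim = c(Z, nA, 1))
  vol[90, , 1] <- 1            # RPE
  vol[30, 20:26, 1] <- 12      # hyper-reflective RNFL patch
  raw <- detect_rpe_raw(vol)
  expect_lt(raw[1, 23], 60)
  expect_equal(raw[1, 50], 90)
})

test_that("iterative polynomial refinement rejects spikes and is idempotent on clean curves", {
  x <- seq_len(64)
  cubic <- 200 + 0.5 * x - 0.01 * x^2 + 1e-4 * x^3
  cfg <- segmentation_config()
  clean <- refine_curve(cubic, cfg)
  expect_equal(sum(clean$outliers), 0)
  expect_equal(clean$curve, cubic, tolerance = 1e-8)

  spiked <- cubic
  at <- c(5, 17, 33, 48, 60)
  spiked[at] <- spiked[at] + 40
  rc <- refine_curve(spiked, cfg)
  expect_true(all(rc$outliers[at]))
  expect_equal(sum(rc$outliers), 5)
  expect_lt(max(abs(rc$curve - cubic)), 1)
  expect_lte(rc$iterations, cfg$max_iter)
  # idempotent: refining its own output changes nothing
  again <- refine_curve(rc$curve, cfg)
  expect_equal(again$curve, rc$curve, tolerance = 1e-8)
  expect_equal(sum(again$outliers), 0)
})

test_that("refinement errors when too few points survive, naming the B-scan", {
  expect_error(refine_curve(c(1, 2, NA, NA, NA, NA), segmentation_config(),
                            bscan = 13),
               "B-scan 13")
})

test_that("COV rejection replaces nothing when all B-scan curves agree", {
  m <- matrix(rep(100 + sin(seq_len(32) / 5), 8), nrow = 8, byrow = TRUE)
  rb <- reject_bscan_outliers(m)
  expect_length(rb$replaced_bscans, 0)
  expect_equal(rb$rpe_fit, m)
  expect_length(rb$cov_trace, 8)
})

test_that("corrupt B-scans are exactly the ones flagged on a tilt-only phantom", {
  cfg <- phantom_config(n_bscans = 32, n_alines = 64, n_depth = 256,
                        n_spectral = 512, fov_mm = 64 * 0.012,
                        rpe = list(center_px = 200, bow_px = 0, tilt_px = 8),
                        corrupt_bscans = c(10, 21), seed = 3)
  ph <- make_phantom(cfg, ext_tab())
  surf <- segment_layers(reconstruct_fullband(ph$volume))
  expect_equal(surf$replaced_bscans, c(10, 21))
  # replacement preserves the B-scan count and stays in range
  expect_equal(dim(surf$rpe_fit), c(32, 64))
  good <- setdiff(1:32, c(10, 21))
  expect_lt(sqrt(mean((surf$rpe_fit[good, ] -
                       ph$truth$rpe_depth[good, ])^2)), 1)
})

test_that("flattening pins the RPE to one row and is invertible", {
  Z <- 64; nA <- 16; nB <- 2
  vol <- array(stats::runif(Z * nA * nB), dim = c(Z, nA, nB))
  # constant-depth RPE: identity shift
  rpe_const <- matrix(40, nB, nA)
  fv <- flatten(vol, rpe_const)
  expect_equal(fv$shifts, matrix(0, nB, nA))
  expect_equal(fv$volume, vol)
  # tilted plane: flattened RPE has zero variance
  rpe_tilt <- matrix(rep(20 + seq_len(nA), each = nB), nB, nA)
  vol2 <- array(0, dim = c(Z, nA, nB))
  for (b in seq_len(nB)) for (a in seq_len(nA)) vol2[rpe_tilt[b, a], a, b] <- 1
  fv2 <- flatten(vol2, rpe_tilt)
  flat_rpe <- apply(fv2$volume, c(2, 3), which.max)
  expect_equal(var(as.vector(flat_rpe)), 0)
  # round trip
  expect_equal(unflatten(fv2), vol2)
})

test_that("ILM lands within a pixel of truth and stays above the RPE", {
  ch <- arterial_chain()
  expect_lte(max(abs(ch$surf$ilm - ch$ph$truth$ilm_depth)), 1)
  expect_true(all(ch$surf$ilm < ch$surf$rpe_fit))
})

test_that("en-face projection: constant volume, vessel shadows, top clipping", {
  vol <- array(3, dim = c(64, 8, 4))
  en <- make_enface(vol, matrix(50, 4, 8))
  expect_equal(en, matrix(3, 4, 8))
  # band clipped at the volume top without error
  en_top <- make_enface(vol, matrix(6, 4, 8))
  expect_true(all(is.finite(en_top)))
  # phantom vessels are local minima of the en-face image
  tv <- two_vessel_chain()
  tr <- tv$ph$truth$vessel_masks[[1]] | tv$ph$truth$vessel_masks[[2]]
  expect_lt(min(tv$enface[tr]), 0.6 * median(tv$enface[!tr]))
})

test_that("adaptive vessel mask: blank images, Dice against truth, small-object removal", {
  expect_equal(sum(vessel_mask(matrix(1, 16, 16))), 0)
  tv <- two_vessel_chain()
  m <- vessel_mask(tv$enface)
  tr <- tv$ph$truth$vessel_masks[[1]] | tv$ph$truth$vessel_masks[[2]]
  dice <- 2 * sum(m & tr) / (sum(m) + sum(tr))
  expect_gte(dice, 0.7)
  # tiny children vessels (below the minimum object size) are neglected
  en <- matrix(10, 48, 48)
  en[20:21, 20:22] <- 1          # 6-px dark dot
  expect_equal(sum(vessel_mask(en)), 0)
})

test_that("segmentation keeps depth maps inside the volume", {
  ch <- arterial_chain()
  Z <- dim(ch$full)[1]
  expect_true(all(ch$surf$rpe_fit >= 1 & ch$surf$rpe_fit <= Z))
  expect_true(all(ch$surf$ilm >= 1 & ch$surf$ilm <= Z))
})
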