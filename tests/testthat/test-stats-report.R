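test_that("Pearson correlation hits its exact endpoints", {
  x <- c(1.2, 2.5, 3.1, 4.8, 5.0, 6.3)
  pc <- pearson_corr(x, 2 * x)
  expect_equal(pc$r, 1)
  expect_equal(pc$p, 0)
  # orthogonal by construction
  y <- c(1, -1, 1, -1, 1, -1)
  x0 <- c(1, 1, -1, -1, 0, 0)
  expect_equal(pearson_corr(x0, y)$r, 0, tolerance = 1e-12)
})

test_that("t-transform reproduces the printed IOP-VsO2 p-value at n = 16", {
  expect_lt(abs(r_to_p(-0.530, 16) - 0.035), 0.001)
})

test_that("r_to_p matches cor.test on random data", {
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(14); y <- rnorm(14) + 0.4 * x
    ct <- cor.test(x, y)
    pc <- pearson_corr(x, y)
    expect_equal(pc$r, unname(ct$estimate))
    expect_equal(pc$p, ct$p.value, tolerance = 1e-12)
  }
})

test_that("correlation is invariant under affine transforms", {
  set.seed(8)
  x <- rnorm(20); y <- rnorm(20) + x
  base <- pearson_corr(x, y)
  tr <- pearson_corr(3 * x - 7, 0.5 * y + 11)
  expect_equal(tr$r, base$r)
  expect_equal(tr$p, base$p)
})

test_that("unpaired t-test handles degenerate, separated, and textbook cases", {
  expect_equal(unpaired_ttest(c(2, 2, 2), c(2, 2, 2))$p, 1)
  expect_lt(unpaired_ttest(rnorm(20, 0, 0.1), rnorm(20, 50, 0.1))$p, 1e-6)
  # closed-form small case: pooled sp = 1, t = -sqrt(3/2)
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  tt <- unpaired_ttest(a, b)
  t_exact <- (mean(a) - mean(b)) / (1 * sqrt(1 / 3 + 1 / 3))
  expect_equal(tt$t, t_exact)
  expect_equal(tt$p, 2 * pt(t_exact, 4))
  # Welch flag reaches the unequal-variance test
  w <- unpaired_ttest(c(1, 2, 3, 4), c(10, 30, 50, 90), var_equal = FALSE)
  expect_equal(w$p, t.test(c(1, 2, 3, 4), c(10, 30, 50, 90))$p.value)
})

test_that("printed correlation table is internally consistent at its implied sample sizes", {
  chk <- check_printed_correlations()
  expect_equal(nrow(chk), 21)
  expect_true(all(chk$consistent))
  # 18 of 21 pairs are consistent with 16 eyes ...
  at16 <- check_printed_correlations(n = 16)
  expect_equal(sum(at16$consistent), 18)
  # ... and the three cylinder pairs are consistent only with 13 eyes
  cyl <- at16[at16$parameter == "Cylinder", ]
  expect_false(any(cyl$consistent))
  cyl13 <- check_printed_correlations(baseline_cohort_correlations()[4:6, ],
                                      n = 13)
  expect_true(all(cyl13$consistent))
})

test_that("synthetic cohorts reproduce the configured moments exactly", {
  means <- c(AsO2 = 92.1, VsO2 = 48.4, IOP = 15.4, Age = 61)
  sds <- c(AsO2 = 7.1, VsO2 = 5.0, IOP = 2.3, Age = 13.3)
  eyes <- make_synthetic_cohort(16, means, sds, seed = 4)
  for (v in names(means)) {
    expect_equal(mean(eyes[[v]]), unname(means[v]))
    expect_equal(sd(eyes[[v]]), unname(sds[v]))
  }
  # AV difference is per-eye, not a difference of summaries
  expect_equal(eyes$AV_diff, eyes$AsO2 - eyes$VsO2)
  sm <- summarize_eyes(eyes)
  expect_equal(sm$mean[sm$characteristic == "AsO2"], 92.1)
  # a single eye has zero SD
  one <- summarize_eyes(eyes[1, ])
  expect_true(all(one$sd == 0))
})

test_that("correlation and segment summary tables have the reporting layout", {
  means <- c(AsO2 = 92.1, VsO2 = 48.4, IOP = 15.4, Age = 61, CDR = 0.33)
  sds <- c(AsO2 = 7.1, VsO2 = 5.0, IOP = 2.3, Age = 13.3, CDR = 0.09)
  eyes <- make_synthetic_cohort(16, means, sds, seed = 4)
  ct <- correlation_table(eyes, covariates = c("IOP", "Age", "CDR"))
  expect_equal(nrow(ct), 9)
  expect_true(all(ct$n == 16))
  expect_true(all(abs(ct$r) <= 1))
  expect_equal(ct$significant, ct$p < 0.05)

  set.seed(2)
  segs <- data.frame(
    label = rep(c("artery", "vein"), c(8, 7)),
    L_mm = c(rnorm(8, 1.19, 0.3), rnorm(7, 1.23, 0.3)),
    D_um = c(rnorm(8, 24.8, 2), rnorm(7, 28.4, 2)),
    so2_volpct = c(rnorm(8, 91, 5), rnorm(7, 51, 5))
  )
  tab <- summarize_segments(segs)
  expect_equal(tab$feature, c("L_mm", "D_um", "so2_volpct"))
  i <- which(tab$feature == "D_um")
  expect_equal(tab$p[i],
               t.test(segs$D_um[segs$label == "artery"],
                      segs$D_um[segs$label == "vein"],
                      var.equal = TRUE)$p.value)
  expect_lt(tab$p[tab$feature == "so2_volpct"], 1e-6)
})
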