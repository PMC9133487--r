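#' Two-sided p-value for a Pearson correlation coefficient
#'
#' The t-transform `t = r sqrt((n - 2) / (1 - r^2))` referred to a
#' t-distribution with `n - 2` degrees of freedom, two-sided.
#'
#' @param r correlation coefficient(s), |r| <= 1.
#' @param n sample size(s), n > 2.
#' @return two-sided p-value(s).
#' @export
r_to_p <- function(r, n) {
  stopifnot(all(abs(r) <= 1), all(n > 2))
  p <- ifelse(abs(r) == 1, 0,
              2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2))
  unname(p)
}

#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation on complete pairs with the two-sided
#' t-transform p-value, flagged significant at p < 0.05.
#'
#' @param x,y numeric vectors.
#' @return list with `r`, `p`, `n`, `significant`.
#' @export
pearson_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  r <- stats::cor(x, y)
  p <- r_to_p(r, n)
  list(r = r, p = p, n = n, significant = is.finite(p) && p < 0.05)
}

#' Unpaired two-sample t-test
#'
#' Pooled-variance (parametric) two-sample t-test by default; Welch
#' available by flag. Degenerate zero-variance inputs are handled: equal
#' constant samples give t = 0, p = 1.
#'
#' @param a,b numeric samples.
#' @param var_equal pooled variance if `TRUE` (default), Welch otherwise.
#' @return list with `t`, `p`, `df`.
#' @export
unpaired_ttest <- function(a, b, var_equal = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    df <- length(a) + length(b) - 2
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = df))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0, df = df))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Published baseline correlations between clinical parameters and sO2
#'
#' The reference per-eye correlation table of the parafoveal oximetry
#' baseline cohort (16 eyes): Pearson r and two-sided p between each
#' clinical parameter and arterial sO2 (AsO2), venous sO2 (VsO2) and the
#' arteriovenous difference (AV_diff). The `n` column is the effective
#' sample size implied by each printed (r, p) pair: 16 eyes throughout,
#' except the refraction-cylinder rows, whose printed p-values are
#' consistent only with 13 eyes (three eyes evidently lacked a cylinder
#' measurement). See [check_printed_correlations()].
#'
#' @return `data.frame` with columns `parameter`, `target`, `r`, `p`, `n`.
#' @export
baseline_cohort_correlations <- function() {
  data.frame(
    parameter = rep(c("Sphere", "Cylinder", "IOP", "CDR", "GCC",
                      "cpRNFL", "Age"), each = 3),
    target = rep(c("AsO2", "VsO2", "AV_diff"), times = 7),
    r = c(-0.185, -0.368, 0.055,
          0.195, 0.184, 0.045,
          0.253, -0.530, 0.466,
          -0.173, 0.514, -0.398,
          -0.007, -0.168, 0.083,
          -0.180, 0.283, -0.282,
          0.174, -0.546, 0.414),
    p = c(0.492, 0.160, 0.838,
          0.524, 0.546, 0.884,
          0.344, 0.035, 0.069,
          0.521, 0.042, 0.127,
          0.980, 0.534, 0.760,
          0.504, 0.288, 0.291,
          0.520, 0.029, 0.110),
    n = rep(c(16, 13, 16, 16, 16, 16, 16), each = 3),
    stringsAsFactors = FALSE
  )
}

#' Internal-consistency check of printed correlation tables
#'
#' Recomputes each printed two-sided p-value from the printed r and the
#' sample size via [r_to_p()] and flags pairs whose recomputed p agrees
#' with the printed one within a tolerance (default +/- 0.01, i.e. printed
#' rounding). Used as a validation suite over the published baseline table.
#'
#' @param printed `data.frame` with columns `r`, `p` and (unless `n` is
#'   given) `n`; defaults to [baseline_cohort_correlations()].
#' @param n optional sample size overriding the table's `n` column for all
#'   rows.
#' @param tol agreement tolerance on p.
#' @return the input with extra columns `p_calc` and `consistent`.
#' @export
check_printed_correlations <- function(printed = baseline_cohort_correlations(),
                                       n = NULL, tol = 0.01) {
  nn <- if (is.null(n)) printed$n else rep(n, nrow(printed))
  printed$p_calc <- r_to_p(printed$r, nn)
  printed$consistent <- abs(printed$p_calc - printed$p) <= tol
  printed
}

#' Synthetic eye cohort with exact sample moments
#'
#' Draws a cohort of eye records whose per-variable sample mean and SD are
#' exactly the configured values (standard normal draws are re-centered and
#' re-scaled). The arteriovenous difference is computed per eye as
#' `AsO2 - VsO2`.
#'
#' @param n_eyes number of eyes (>= 2).
#' @param means,sds named numeric vectors over the same variable names;
#'   must include `AsO2` and `VsO2`.
#' @param seed RNG seed.
#' @return `data.frame` with `eye_id`, the configured variables, and
#'   `AV_diff`.
#' @export
make_synthetic_cohort <- function(n_eyes, means, sds, seed = 1) {
  stopifnot(n_eyes >= 2, all(names(means) == names(sds)),
            all(c("AsO2", "VsO2") %in% names(means)))
  set.seed(seed)
  out <- data.frame(eye_id = seq_len(n_eyes))
  for (v in names(means)) {
    z <- stats::rnorm(n_eyes)
    z <- (z - mean(z)) / stats::sd(z)
    out[[v]] <- means[[v]] + sds[[v]] * z
  }
  out$AV_diff <- out$AsO2 - out$VsO2
  out
}

#' Per-eye characteristics summary (mean and SD)
#'
#' One row per numeric characteristic, mean (SD) across eyes, in the layout
#' of a cohort characteristics table.
#'
#' @param eyes `data.frame` of eye records.
#' @param vars characteristics to summarize; defaults to all numeric
#'   columns except `eye_id`.
#' @return `data.frame` with `characteristic`, `mean`, `sd`, `formatted`.
#' @export
summarize_eyes <- function(eyes, vars = NULL) {
  if (is.null(vars)) {
    vars <- setdiff(names(eyes)[vapply(eyes, is.numeric, TRUE)], "eye_id")
  }
  mu <- vapply(vars, function(v) mean(eyes[[v]], na.rm = TRUE), 0)
  sd_ <- vapply(vars, function(v) {
    x <- eyes[[v]][is.finite(eyes[[v]])]
    if (length(x) > 1) stats::sd(x) else 0
  }, 0)
  data.frame(characteristic = vars, mean = mu, sd = sd_,
             formatted = sprintf("%.1f (%.1f)", mu, sd_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-eye correlation table between clinical parameters and sO2
#'
#' Pearson r and t-based p between each covariate and each sO2 target,
#' mirroring the baseline study's correlation-table layout. No
#' multiple-testing correction is applied (single-comparison p-values;
#' noted in the output attribute `footer`).
#'
#' @param eyes `data.frame` of eye records.
#' @param covariates covariate column names.
#' @param targets sO2 column names (default `AsO2`, `VsO2`, `AV_diff`).
#' @return long `data.frame` with `parameter`, `target`, `r`, `p`, `n`,
#'   `significant`.
#' @export
correlation_table <- function(eyes,
                              covariates = c("Sphere", "Cylinder", "IOP",
                                             "CDR", "GCC", "cpRNFL", "Age"),
                              targets = c("AsO2", "VsO2", "AV_diff")) {
  covariates <- intersect(covariates, names(eyes))
  rows <- do.call(rbind, lapply(covariates, function(cv) {
    do.call(rbind, lapply(targets, function(tg) {
      pc <- pearson_corr(eyes[[cv]], eyes[[tg]])
      data.frame(parameter = cv, target = tg, r = pc$r, p = pc$p,
                 n = pc$n, significant = pc$significant,
                 stringsAsFactors = FALSE)
    }))
  }))
  attr(rows, "footer") <- "p-values are uncorrected for multiple testing"
  rows
}

#' Arteriole-versus-venule segment comparison table
#'
#' Mean +/- SD of each topographic feature and sO2 per vessel class, with
#' the pooled-variance unpaired t-test p-value, mirroring the per-segment
#' summary-table layout.
#'
#' @param segments `data.frame` with a `label` column (`"artery"`/`"vein"`)
#'   and feature columns.
#' @param features feature columns to compare.
#' @return `data.frame` with `feature`, artery/vein means and SDs,
#'   formatted columns and `p`.
#' @export
summarize_segments <- function(segments,
                               features = c("L_mm", "A_1e3mm2", "D_um",
                                            "rho_min_mm", "rho_max_mm",
                                            "so2_volpct")) {
  features <- intersect(features, names(segments))
  art <- segments[segments$label == "artery", , drop = FALSE]
  ven <- segments[segments$label == "vein", , drop = FALSE]
  do.call(rbind, lapply(features, function(f) {
    a <- art[[f]]; v <- ven[[f]]
    tt <- unpaired_ttest(a, v)
    data.frame(
      feature = f,
      artery_mean = mean(a), artery_sd = stats::sd(a),
      vein_mean = mean(v), vein_sd = stats::sd(v),
      artery = sprintf("%.2f ± %.2f", mean(a), stats::sd(a)),
      vein = sprintf("%.2f ± %.2f", mean(v), stats::sd(v)),
      p = tt$p, stringsAsFactors = FALSE
    )
  }))
}
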