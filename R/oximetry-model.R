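#' Beer-Lambert vessel-bottom spectrum model
#'
#' Forward model for the normalized intensity reflected from a vessel bottom:
#' \deqn{I(\lambda) = A \, (\lambda/560)^{-\alpha} \,
#'       e^{-[sO_2 \mu_{HbO_2}(\lambda) + (1-sO_2)\mu_{Hb}(\lambda)] z}}
#' The power law models the scattering spectrum of the vessel wall; the
#' exponential is double-pass Beer-Lambert attenuation through the blood
#' column with effective attenuation `mu = mu_a + W*mu_s` per species. The
#' source spectrum and reference-arm reflectance are taken as unity because
#' spectra are normalized by the non-vascular RNFL reference before fitting;
#' any residual smooth spectral shape is absorbed by `A` and `alpha`.
#' Wavelengths in the power law are normalized by 560 nm so that `A` stays
#' of order one.
#'
#' @param so2 oxygen saturation, fraction in \[0, 1\].
#' @param A_refl dimensionless reflectance amplitude, > 0.
#' @param alpha scattering power-law exponent.
#' @param z_path_mm optical path length through blood (mm), > 0. The package
#'   convention is round-trip: twice the lumen depth to the vessel bottom.
#' @param table an [extinction_table()].
#' @param lambda_nm wavelengths (nm) at which to evaluate, typically the 11
#'   sub-band centers.
#' @return numeric vector of modeled intensities, same length as `lambda_nm`.
#' @export
model_spectrum <- function(so2, A_refl, alpha, z_path_mm, table, lambda_nm) {
  stopifnot(so2 >= 0, so2 <= 1, A_refl > 0, z_path_mm > 0)
  mu <- mu_attenuation(table, lambda_nm)
  mu_mix <- so2 * mu$mu_hbo2 + (1 - so2) * mu$mu_hb
  A_refl * (lambda_nm / 560)^(-alpha) * exp(-mu_mix * z_path_mm)
}

# profile the linear parameters (log A, alpha) at fixed so2 by ordinary least
# squares in log space; returns list(logA, alpha, rss)
profile_linear <- function(log_s, log_lam_rel, mu_z_at) {
  function(so2) {
    y <- log_s + mu_z_at(so2)      # = logA - alpha * log(lambda/560) + resid
    fit <- stats::lm.fit(cbind(1, -log_lam_rel), y)
    list(logA = fit$coefficients[1], alpha = fit$coefficients[2],
         rss = sum(fit$residuals^2))
  }
}

#' Least-squares inversion for oxygen saturation
#'
#' Fits the [model_spectrum()] to an extracted 11-point vessel-bottom
#' spectrum by bounded least squares in log-intensity space (log
#' linearizes the Beer-Lambert exponent and stabilizes the fit).
#' Optimization uses `L-BFGS-B` over `(so2, log A, alpha)` with
#' `so2` in \[0, 1\] and `alpha` in \[-4, 4\], multi-started from
#' `so2 = 0.25, 0.5, 0.75` (the linear parameters are profiled in closed
#' form at each start). Ties are broken by lowest residual, then lowest
#' so2. The fit is invariant to overall scaling of the spectrum, which is
#' absorbed by `A_refl`.
#'
#' @param spectrum positive intensities at `lambda_nm`.
#' @param lambda_nm wavelengths (nm).
#' @param z_path_mm assumed round-trip path through blood (mm).
#' @param table an [extinction_table()].
#' @param starts so2 multi-start values.
#' @return object of class `oximetry_fit`: list with `so2` (fraction),
#'   `so2_volpct` (so2 * 100, the reporting unit), `A_refl`, `alpha`,
#'   `residual_norm` and `success`.
#' @export
fit_so2 <- function(spectrum, lambda_nm, z_path_mm, table,
                    starts = c(0.25, 0.5, 0.75)) {
  if (length(spectrum) != length(lambda_nm)) {
    stop("spectrum and lambda_nm lengths differ")
  }
  if (any(!is.finite(spectrum)) || any(spectrum <= 0)) {
    stop("spectrum must be finite and strictly positive")
  }
  stopifnot(z_path_mm > 0)
  mu <- mu_attenuation(table, lambda_nm)
  log_s <- log(spectrum)
  log_lam_rel <- log(lambda_nm / 560)
  mu_z_at <- function(so2) {
    (so2 * mu$mu_hbo2 + (1 - so2) * mu$mu_hb) * z_path_mm
  }
  prof <- profile_linear(log_s, log_lam_rel, mu_z_at)

  obj <- function(par) {
    m <- par[2] - par[3] * log_lam_rel - mu_z_at(par[1])
    sum((log_s - m)^2)
  }
  lower <- c(0, -20, -4)
  upper <- c(1, 20, 4)
  best <- NULL
  ok <- FALSE
  for (s0 in starts) {
    p0 <- prof(s0)
    init <- c(s0, unname(p0$logA), max(-4, min(4, unname(p0$alpha))))
    res <- tryCatch(
      stats::optim(init, obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(res)) next
    ok <- TRUE
    better <- is.null(best) ||
      res$value < best$value - 1e-12 ||
      (abs(res$value - best$value) <= 1e-12 && res$par[1] < best$par[1])
    if (better) best <- res
  }
  if (!ok) {
    return(structure(list(so2 = NA_real_, so2_volpct = NA_real_,
                          A_refl = NA_real_, alpha = NA_real_,
                          residual_norm = NA_real_, success = FALSE),
                     class = "oximetry_fit"))
  }
  structure(list(
    so2 = best$par[1],
    so2_volpct = 100 * best$par[1],
    A_refl = exp(best$par[2]),
    alpha = best$par[3],
    residual_norm = sqrt(best$value),
    success = best$convergence == 0
  ), class = "oximetry_fit")
}

#' @export
print.oximetry_fit <- function(x, ...) {
  cat(sprintf("oximetry fit: sO2 = %.1f vol%% (A = %.3g, alpha = %.2f, resid = %.3g)\n",
              x$so2_volpct, x$A_refl, x$alpha, x$residual_norm))
  invisible(x)
}
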