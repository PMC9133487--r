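#' Reconstruct the full-band intensity volume
#'
#' Standard spectral-domain OCT reconstruction: per A-line, remove DC
#' (subtract the spectral mean), Fourier-transform along the spectral axis,
#' and keep the magnitude of the positive-depth half. A dispersion hook is
#' accepted but defaults to the identity (phantom fringes are synthesized
#' dispersion-free in linear k).
#'
#' Depth convention: row 1 is the zero-delay line, depth increases with row
#' index; the output has `n_spectral / 2` depth rows.
#'
#' @param v an `interferogram_volume` (see [make_phantom()]).
#' @param dispersion_hook function applied to the fringe matrix of each
#'   B-scan before the FFT; identity by default.
#' @return numeric array depth x A-line x B-scan of non-negative intensities.
#' @export
reconstruct_fullband <- function(v, dispersion_hook = identity) {
  stopifnot(inherits(v, "interferogram_volume"))
  if (!all(is.finite(v$fringes))) stop("non-finite values in fringes")
  d <- dim(v$fringes)
  N <- d[1]; nA <- d[2]; nB <- d[3]
  Z <- N %/% 2
  out <- array(0, dim = c(Z, nA, nB))
  for (b in seq_len(nB)) {
    M <- dispersion_hook(v$fringes[, , b])
    M <- sweep(M, 2, colMeans(M))
    out[, , b] <- abs(stats::mvfft(M))[seq_len(Z), , drop = FALSE]
  }
  out
}

#' Short-time Fourier transform into spectral sub-bands
#'
#' Sweeps the spectral interferogram with Gaussian windows equally spaced in
#' wavenumber and reconstructs one depth volume per window, yielding the
#' wavelength-dependent 4-D data I(x, y, z, lambda) used for oximetry. The
#' window count defaults to 11; the FWHM defaults to 1/8 of the spectral
#' support (about 50% overlap between neighbors), and the first/last centers
#' are inset by half a window so every window is fully supported. Windows
#' are normalized to unit sum so a spectrally flat reflector produces equal
#' sub-band amplitudes.
#'
#' @param v an `interferogram_volume`.
#' @param n_windows number of Gaussian windows (>= 2).
#' @param fwhm_nm window full width at half maximum expressed in nm of
#'   source support; default `support/8`. Must be smaller than the support.
#' @param fullband optional precomputed [reconstruct_fullband()] output
#'   (recomputed if `NULL`).
#' @return object of class `subband_stack`: list with `fullband`, `subbands`
#'   (depth x A-line x B-scan x window, ordered by ascending center
#'   wavelength), `lambda_centers` (nm), `window_fwhm_nm`.
#' @export
stft_subbands <- function(v, n_windows = 11, fwhm_nm = NULL, fullband = NULL) {
  stopifnot(inherits(v, "interferogram_volume"), n_windows >= 2)
  d <- dim(v$fringes)
  N <- d[1]; nA <- d[2]; nB <- d[3]
  Z <- N %/% 2
  support_nm <- abs(diff(range(v$lambda_axis)))
  if (is.null(fwhm_nm)) fwhm_nm <- support_nm / 8
  if (fwhm_nm >= support_nm) stop("window FWHM exceeds the spectral support")

  fwhm_samp <- fwhm_nm / support_nm * N
  sigma <- fwhm_samp / (2 * sqrt(2 * log(2)))
  centers <- seq(1 + fwhm_samp / 2, N - fwhm_samp / 2,
                 length.out = n_windows)
  n_idx <- seq_len(N)
  lambda_centers <- stats::approx(n_idx, v$lambda_axis, xout = centers)$y

  if (is.null(fullband)) fullband <- reconstruct_fullband(v)
  sub <- array(0, dim = c(Z, nA, nB, n_windows))
  wins <- lapply(centers, function(cc) {
    w <- exp(-0.5 * ((n_idx - cc) / sigma)^2)
    w / sum(w)
  })
  for (b in seq_len(nB)) {
    M <- v$fringes[, , b]
    M <- sweep(M, 2, colMeans(M))
    for (k in seq_len(n_windows)) {
      sub[, , b, k] <- abs(stats::mvfft(M * wins[[k]]))[seq_len(Z), ,
                                                        drop = FALSE]
    }
  }
  ord <- order(lambda_centers)
  structure(list(
    fullband = fullband,
    subbands = sub[, , , ord, drop = FALSE],
    lambda_centers = lambda_centers[ord],
    window_fwhm_nm = fwhm_nm
  ), class = "subband_stack")
}
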