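#' Depth-resolved spectrum of a vessel ROI
#'
#' Shifts all A-lines within a vessel ROI so that the ILM sits at row 1,
#' then averages them per sub-band, yielding the depth-resolved spectrum
#' I(z, lambda) (depth rows x 11 sub-band columns). The wavelength-averaged
#' profile (`mean_aline`) is used for vessel-bottom detection.
#'
#' The depth profile used for peak detection (`mean_aline`) is the ROI
#' average of the full-band reconstruction — the coherent average over the
#' whole source spectrum — because the sub-band volumes trade axial
#' resolution for spectral resolution and can merge the top/bottom reflexes
#' of a 20-30 um vessel. The per-sub-band average of `I_z_lambda` is kept
#' as `mean_subband`.
#'
#' @param stack a `subband_stack` (see [stft_subbands()]).
#' @param roi_mask logical en-face mask (B-scan x A-line) of the vessel ROI.
#' @param ilm ILM depth map in volume coordinates.
#' @param n_rows number of depth rows to keep below the ILM; defaults to the
#'   deepest common extent of the masked A-lines.
#' @return object of class `depth_spectrum`: `I_z_lambda` (rows = depth
#'   below ILM, row 1 = ILM), `mean_aline` (full-band profile),
#'   `mean_subband`, `lambda_centers`, `bottom_idx`/`top_idx` (NA until
#'   located), `z_path_mm` (NA until set), `n_px`.
#' @export
extract_roi_spectra <- function(stack, roi_mask, ilm, n_rows = NULL) {
  stopifnot(inherits(stack, "subband_stack"))
  idx <- which(roi_mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty ROI mask")
  Z <- dim(stack$subbands)[1]
  K <- dim(stack$subbands)[4]
  i0 <- round(ilm[idx])
  if (any(!is.finite(i0))) stop("ILM undefined under the ROI mask")
  L <- min(Z - i0 + 1)
  if (!is.null(n_rows)) L <- min(L, n_rows)
  acc <- matrix(0, L, K)
  prof <- numeric(L)
  for (j in seq_len(nrow(idx))) {
    rows <- i0[j]:(i0[j] + L - 1)
    acc <- acc + stack$subbands[rows, idx[j, 2], idx[j, 1], ]
    prof <- prof + stack$fullband[rows, idx[j, 2], idx[j, 1]]
  }
  I_z_lambda <- acc / nrow(idx)
  structure(list(I_z_lambda = I_z_lambda,
                 mean_aline = prof / nrow(idx),
                 mean_subband = rowMeans(I_z_lambda),
                 lambda_centers = stack$lambda_centers,
                 bottom_idx = NA_integer_, top_idx = NA_integer_,
                 z_path_mm = NA_real_, n_px = nrow(idx)),
            class = "depth_spectrum")
}

#' Normalize a depth spectrum by the non-vascular RNFL reference
#'
#' Divides each sub-band column by the reference RNFL spectrum, cancelling
#' the source spectrum and any common spectral response of the system.
#'
#' @param ds a `depth_spectrum`.
#' @param ref positive reference spectrum, one value per sub-band (from
#'   [measure_rnfl_spectrum()] on real data or
#'   [make_reference_rnfl_spectrum()] on phantoms).
#' @return the normalized `depth_spectrum` (mean A-line recomputed).
#' @export
normalize_by_rnfl <- function(ds, ref) {
  stopifnot(inherits(ds, "depth_spectrum"))
  if (length(ref) != ncol(ds$I_z_lambda)) stop("reference length mismatch")
  if (any(!is.finite(ref)) || any(ref <= 0)) {
    stop("reference spectrum must be strictly positive")
  }
  ds$I_z_lambda <- sweep(ds$I_z_lambda, 2, ref, `/`)
  ds$mean_subband <- rowMeans(ds$I_z_lambda)
  ds$normalized <- TRUE
  ds
}

#' Measure the non-vascular RNFL spectrum from a volume
#'
#' Averages, per sub-band, the intensity in a thin band at the ILM over all
#' A-lines outside any vessel mask. Because it travels through the same
#' reconstruction chain as the vessel spectra, dividing by it cancels the
#' source spectrum and window responses.
#'
#' @param stack a `subband_stack`.
#' @param ilm ILM depth map.
#' @param exclude_mask logical mask of A-lines to exclude (vessels).
#' @param band_rows row offsets below the ILM to average (default 0:2).
#' @return spectrum vector, one value per sub-band.
#' @export
measure_rnfl_spectrum <- function(stack, ilm, exclude_mask = NULL,
                                  band_rows = 0:2) {
  stopifnot(inherits(stack, "subband_stack"))
  d <- dim(stack$subbands)
  keep <- is.finite(ilm)
  if (!is.null(exclude_mask)) keep <- keep & !exclude_mask
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no non-vascular A-lines available")
  acc <- numeric(d[4]); n <- 0L
  for (j in seq_len(nrow(idx))) {
    rows <- round(ilm[idx[j, 1], idx[j, 2]]) + band_rows
    rows <- rows[rows >= 1 & rows <= d[1]]
    if (!length(rows)) next
    v <- stack$subbands[rows, idx[j, 2], idx[j, 1], , drop = FALSE]
    acc <- acc + apply(v, 4, mean)
    n <- n + 1L
  }
  if (n == 0L) stop("no usable RNFL rows")
  acc / n
}

# peak detection on the wavelength-averaged A-line; returns (top, bottom)
locate_vessel_peaks <- function(ds, min_row = 4, prominence_frac = 0.05,
                                smooth_sigma = 1) {
  prof <- smooth_gauss1d(ds$mean_aline, smooth_sigma)
  pk <- pracma::findpeaks(prof, minpeakdistance = 2,
                          minpeakheight = prominence_frac * max(prof))
  if (is.null(pk)) stop("vessel bottom not found: no reflective peaks")
  rows <- sort(pk[, 2])
  rows <- rows[rows >= min_row]
  if (length(rows) < 2) {
    stop("vessel bottom not found: fewer than two peaks below the ILM")
  }
  list(top = rows[1], bottom = rows[2])
}

#' Locate the vessel bottom on the averaged A-line
#'
#' Detects local maxima on the lightly smoothed wavelength-averaged A-line
#' and returns the second reflective peak below the ILM row (the first peak
#' is the vessel top). Vessels without a detectable second peak raise an
#' error and are excluded from analysis, mirroring clinical practice where
#' the vessel bottom cannot always be resolved.
#'
#' @param ds a `depth_spectrum`.
#' @param min_row first depth row considered (excludes the ILM complex).
#' @param prominence_frac minimum peak height as a fraction of the profile
#'   maximum.
#' @param smooth_sigma Gaussian SD of the profile smoothing (pixels).
#' @return integer vessel-bottom depth row (relative to the ILM at row 1),
#'   with the vessel-top row attached as attribute `"top"`.
#' @export
find_vessel_bottom <- function(ds, min_row = 4, prominence_frac = 0.05,
                               smooth_sigma = 1) {
  stopifnot(inherits(ds, "depth_spectrum"))
  pk <- locate_vessel_peaks(ds, min_row, prominence_frac, smooth_sigma)
  structure(pk$bottom, top = pk$top)
}

#' Average the spectrum around the vessel bottom
#'
#' Column-means of I(z, lambda) over the half-open depth window
#' `[bottom - 5, bottom + 10)` (5 pixels above through 9 below the bottom),
#' clipped at the matrix edges without error.
#'
#' @param ds a `depth_spectrum`.
#' @param bottom_idx vessel-bottom row; defaults to `ds$bottom_idx`.
#' @param above,below window extent in pixels.
#' @return spectrum vector, one value per sub-band.
#' @export
extract_bottom_spectrum <- function(ds, bottom_idx = ds$bottom_idx,
                                    above = 5, below = 10) {
  stopifnot(inherits(ds, "depth_spectrum"))
  if (!is.finite(bottom_idx)) stop("bottom_idx is not set")
  L <- nrow(ds$I_z_lambda)
  rows <- max(1L, bottom_idx - above):min(L, bottom_idx + below - 1L)
  colMeans(ds$I_z_lambda[rows, , drop = FALSE])
}

#' One-call oximetry of a single vessel ROI
#'
#' Runs the per-vessel chain: ROI spectrum extraction, RNFL normalization,
#' vessel-bottom detection, bottom-window spectrum extraction, and the
#' least-squares sO2 inversion. The blood path length is set by the
#' round-trip convention: twice the detected lumen depth
#' (`2 * (bottom - top) * axial_pitch`).
#'
#' @param stack a `subband_stack`.
#' @param roi_mask logical vessel ROI mask.
#' @param ilm ILM depth map.
#' @param ref RNFL reference spectrum.
#' @param table an [extinction_table()].
#' @param axial_pitch_um axial pixel pitch (um).
#' @return list: `fit` (an `oximetry_fit`), `ds` (the `depth_spectrum` with
#'   `bottom_idx`, `top_idx` and `z_path_mm` filled in), `spectrum`.
#' @export
vessel_oximetry <- function(stack, roi_mask, ilm, ref, table,
                            axial_pitch_um) {
  ds <- extract_roi_spectra(stack, roi_mask, ilm)
  ds <- normalize_by_rnfl(ds, ref)
  pk <- locate_vessel_peaks(ds)
  ds$bottom_idx <- pk$bottom
  ds$top_idx <- pk$top
  ds$z_path_mm <- 2 * (pk$bottom - pk$top) * axial_pitch_um / 1000
  spec <- extract_bottom_spectrum(ds)
  fit <- fit_so2(spec, ds$lambda_centers, ds$z_path_mm, table)
  list(fit = fit, ds = ds, spectrum = spec)
}
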