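#' Segmentation configuration
#'
#' Parameters of the RPE/ILM segmentation and vessel-mask stages. Defaults
#' follow the processing conventions of the pipeline: a Gaussian blur with
#' standard deviation 7 pixels before RPE peak detection, third-order
#' polynomial surface fits, the mean +/- 1.8 x SD outlier rule, and an
#' en-face projection band of 20 pixels above the RPE.
#'
#' @param blur_sigma Gaussian blur SD (pixels) applied to each B-scan before
#'   per-A-line argmax RPE detection.
#' @param poly_order polynomial order of the per-B-scan RPE fit.
#' @param outlier_k multiplier of the SD in the outlier rule.
#' @param enface_band_px depth band above the RPE averaged into the en-face
#'   image (half-open: `[rpe - band, rpe)`).
#' @param max_iter bound on refinement iterations.
#' @param mask_window_frac adaptive-threshold window = image width divided
#'   by this factor.
#' @param mask_offset adaptive-threshold offset, as a fraction of the
#'   en-face dynamic range.
#' @param min_object_px vessel-mask objects below this pixel count are
#'   removed (tiny children vessels are deliberately neglected).
#' @param ilm_gap_px exclusion gap above the flattened RPE row when
#'   searching for the ILM.
#' @param ilm_top_margin topmost row considered for the ILM.
#' @param ilm_smooth_sigma Gaussian SD (pixels) of the light axial smoothing
#'   applied before the ILM gradient search (stabilizes ties).
#' @return object of class `segmentation_config`.
#' @export
segmentation_config <- function(blur_sigma = 7, poly_order = 3,
                                outlier_k = 1.8, enface_band_px = 20,
                                max_iter = 25, mask_window_frac = 8,
                                mask_offset = 0.10, min_object_px = 10,
                                ilm_gap_px = 8, ilm_top_margin = 4,
                                ilm_smooth_sigma = 1) {
  stopifnot(outlier_k > 0, poly_order >= 1, max_iter >= 1)
  structure(list(blur_sigma = blur_sigma, poly_order = poly_order,
                 outlier_k = outlier_k, enface_band_px = enface_band_px,
                 max_iter = max_iter, mask_window_frac = mask_window_frac,
                 mask_offset = mask_offset, min_object_px = min_object_px,
                 ilm_gap_px = ilm_gap_px, ilm_top_margin = ilm_top_margin,
                 ilm_smooth_sigma = ilm_smooth_sigma),
            class = "segmentation_config")
}

# 1-D Gaussian smoothing with edge renormalization
smooth_gauss1d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, 0, sigma)
  n <- length(x)
  xp <- c(rep(x[1], r), x, rep(x[n], r))
  stats::convolve(xp, rev(k), type = "filter") / sum(k)
}

#' Raw RPE detection by blurred per-A-line maximum
#'
#' Blurs each B-scan with a 2-D Gaussian (SD `cfg$blur_sigma`) and takes the
#' depth of the maximum intensity along each A-line. Vessel shadows, bright
#' RNFL and noise create outliers in this raw map; they are handled by
#' [refine_curve()] and [reject_bscan_outliers()].
#'
#' @param volume reconstructed full-band array (depth x A-line x B-scan).
#' @param cfg a [segmentation_config()].
#' @return depth map, B-scan x A-line; all-zero A-lines are `NA`.
#' @export
detect_rpe_raw <- function(volume, cfg = segmentation_config()) {
  d <- dim(volume)
  nA <- d[2]; nB <- d[3]
  out <- matrix(NA_real_, nB, nA)
  for (b in seq_len(nB)) {
    M <- volume[, , b]
    zero_col <- colSums(abs(M)) == 0
    r <- 2 * ceiling(3 * cfg$blur_sigma) + 1
    r <- min(r, min(dim(M)) - 1 - (min(dim(M)) %% 2))  # odd, fits the image
    Mb <- EBImage::imageData(EBImage::gblur(EBImage::Image(M),
                                            sigma = cfg$blur_sigma,
                                            radius = r,
                                            boundary = "replicate"))
    idx <- apply(Mb, 2, which.max)
    idx[zero_col] <- NA
    out[b, ] <- idx
  }
  out
}

#' Iterative polynomial refinement of a detected surface curve
#'
#' Fits a polynomial (order `cfg$poly_order`, default 3) to the detected
#' depth curve of one B-scan, computes the residuals, deletes points whose
#' residual falls outside mean +/- `outlier_k` x SD (statistics recomputed
#' over current inliers each iteration), refits, and repeats until no new
#' outlier is found or `max_iter` is reached. Deleted points are replaced by
#' the fitted values.
#'
#' @param raw_curve detected depths along one B-scan (`NA` = missing).
#' @param cfg a [segmentation_config()].
#' @param bscan B-scan index used in error messages.
#' @return list: `curve` (outliers/missing replaced by fitted values),
#'   `fit` (polynomial evaluated everywhere), `outliers` (logical flags,
#'   `TRUE` for deleted or missing points), `iterations`.
#' @export
refine_curve <- function(raw_curve, cfg = segmentation_config(), bscan = NA) {
  n <- length(raw_curve)
  x <- seq_len(n)
  xs <- (x - mean(x)) / (n / 2)           # scale to ~[-1, 1] for conditioning
  X <- outer(xs, 0:cfg$poly_order, `^`)
  inlier <- is.finite(raw_curve)
  iterations <- 0L
  coef <- NULL
  repeat {
    if (sum(inlier) < cfg$poly_order + 2) {
      stop("too few inliers to fit the surface in B-scan ", bscan)
    }
    fit <- stats::lm.fit(X[inlier, , drop = FALSE], raw_curve[inlier])
    coef <- fit$coefficients
    iterations <- iterations + 1L
    res <- raw_curve[inlier] - X[inlier, , drop = FALSE] %*% coef
    s <- stats::sd(res)
    # residual spread at floating-point noise level means a perfect fit
    tiny <- 1e-8 * max(1, mean(abs(raw_curve[inlier])))
    bad <- if (is.na(s) || s <= tiny) rep(FALSE, length(res)) else
      abs(res - mean(res)) > cfg$outlier_k * s
    if (!any(bad) || iterations >= cfg$max_iter) break
    inlier[which(inlier)[bad]] <- FALSE
  }
  fitted <- as.numeric(X %*% coef)
  curve <- raw_curve
  curve[!inlier] <- fitted[!inlier]
  list(curve = curve, fit = fitted, outliers = !inlier,
       iterations = iterations)
}

#' COV-based rejection of failed B-scan segmentations
#'
#' Computes the coefficient of variation (SD/mean) of each B-scan's fitted
#' RPE curve, flags COV values outside mean +/- `outlier_k` x SD over all
#' B-scans (the same standard as the per-point rule), and replaces each
#' flagged B-scan's curves by the nearest previous valid curve (the nearest
#' following one when the first B-scan is flagged). Detection is repeated
#' on the updated COV trace until no new outlier is found, so that a few
#' grossly failed segmentations cannot mask each other in the first pass.
#'
#' @param rpe_fit fitted RPE depth map (B-scan x A-line).
#' @param rpe_curve point-wise refined curve map (same shape), replaced in
#'   lockstep; defaults to `rpe_fit`.
#' @param cfg a [segmentation_config()].
#' @return list: `rpe_fit`, `rpe_curve` (with replacements), `cov_trace`
#'   (COVs before any replacement), `replaced_bscans` (sorted indices
#'   flagged and replaced).
#' @export
reject_bscan_outliers <- function(rpe_fit, rpe_curve = rpe_fit,
                                  cfg = segmentation_config()) {
  bscan_cov <- function(m) apply(m, 1, function(r) stats::sd(r) / mean(r))
  cov_trace <- bscan_cov(rpe_fit)
  replaced <- integer(0)
  for (it in seq_len(cfg$max_iter)) {
    cv <- bscan_cov(rpe_fit)
    s <- stats::sd(cv)
    flagged <- if (is.na(s) || s == 0) rep(FALSE, length(cv)) else
      abs(cv - mean(cv)) > cfg$outlier_k * s
    new_idx <- setdiff(which(flagged), replaced)
    if (!length(new_idx)) break
    replaced <- sort(c(replaced, new_idx))
    valid <- setdiff(seq_along(cv), replaced)
    if (!length(valid)) stop("all B-scans flagged as outliers")
    for (b in new_idx) {
      prev <- valid[valid < b]
      src <- if (length(prev)) max(prev) else min(valid[valid > b])
      rpe_fit[b, ] <- rpe_fit[src, ]
      rpe_curve[b, ] <- rpe_curve[src, ]
    }
  }
  list(rpe_fit = rpe_fit, rpe_curve = rpe_curve, cov_trace = cov_trace,
       replaced_bscans = replaced)
}

#' Flatten the retina to a common RPE row
#'
#' Circularly shifts each A-line so that its fitted RPE depth sits at a
#' common target row. The shift map is retained so the operation is
#' invertible ([unflatten()]).
#'
#' @param volume intensity array depth x A-line x B-scan.
#' @param rpe_fit fitted RPE depth map (B-scan x A-line).
#' @param target_row common RPE row; defaults to the rounded median RPE
#'   depth.
#' @return object of class `flattened_volume`: list with `volume`, `shifts`
#'   (B-scan x A-line), `target_row`.
#' @export
flatten <- function(volume, rpe_fit, target_row = NULL) {
  d <- dim(volume)
  Z <- d[1]; nA <- d[2]; nB <- d[3]
  if (is.null(target_row)) target_row <- round(stats::median(rpe_fit))
  shifts <- target_row - round(rpe_fit)
  out <- array(0, dim = d)
  zi <- seq_len(Z)
  for (b in seq_len(nB)) {
    for (a in seq_len(nA)) {
      s <- shifts[b, a] %% Z
      out[, a, b] <- volume[((zi - 1 - s) %% Z) + 1, a, b]
    }
  }
  structure(list(volume = out, shifts = shifts, target_row = target_row),
            class = "flattened_volume")
}

#' Invert [flatten()]
#' @param fv a `flattened_volume`.
#' @return the original intensity array.
#' @export
unflatten <- function(fv) {
  stopifnot(inherits(fv, "flattened_volume"))
  d <- dim(fv$volume)
  Z <- d[1]
  out <- array(0, dim = d)
  zi <- seq_len(Z)
  for (b in seq_len(d[3])) {
    for (a in seq_len(d[2])) {
      s <- fv$shifts[b, a] %% Z
      out[, a, b] <- fv$volume[((zi - 1 + s) %% Z) + 1, a, b]
    }
  }
  out
}

#' ILM detection by the greatest axial intensity gradient
#'
#' On the flattened volume, finds per A-line the largest positive axial
#' gradient in the band above the common RPE row (from `ilm_top_margin` to
#' `target_row - ilm_gap_px`), after light Gaussian smoothing of the axial
#' profile to stabilize ties.
#'
#' @param fv a `flattened_volume`.
#' @param cfg a [segmentation_config()].
#' @return ILM depth map (B-scan x A-line) in the original (unflattened)
#'   coordinates; the flattened-coordinate map is attached as attribute
#'   `"flat"`.
#' @export
detect_ilm <- function(fv, cfg = segmentation_config()) {
  stopifnot(inherits(fv, "flattened_volume"))
  d <- dim(fv$volume)
  nA <- d[2]; nB <- d[3]
  lo <- max(2L, cfg$ilm_top_margin)
  hi <- fv$target_row - cfg$ilm_gap_px
  if (hi <= lo) stop("no depth band available above the RPE for the ILM")
  ilm_flat <- matrix(NA_real_, nB, nA)
  for (b in seq_len(nB)) {
    for (a in seq_len(nA)) {
      p <- smooth_gauss1d(fv$volume[seq_len(hi), a, b], cfg$ilm_smooth_sigma)
      g <- diff(p)
      w <- lo:(hi - 1)
      ilm_flat[b, a] <- w[which.max(g[w])] + 1   # row of the rising edge top
    }
  }
  ilm <- ilm_flat - fv$shifts
  attr(ilm, "flat") <- ilm_flat
  ilm
}

#' En-face projection above the RPE
#'
#' Averages, per A-line, the intensities in the half-open depth band
#' `[rpe - enface_band_px, rpe)`; the band is clipped at the volume top
#' without error. A guard gap (`guard_px`, default 2) excludes the rows
#' immediately above the fitted RPE so that a +/- 1 px segmentation error
#' cannot leak the bright RPE peak into the projection.
#'
#' @param volume intensity array depth x A-line x B-scan.
#' @param rpe_fit fitted RPE depth map.
#' @param cfg a [segmentation_config()].
#' @param guard_px rows adjacent to the RPE excluded from the band.
#' @return en-face image (B-scan x A-line).
#' @export
make_enface <- function(volume, rpe_fit, cfg = segmentation_config(),
                        guard_px = 2) {
  d <- dim(volume)
  nA <- d[2]; nB <- d[3]
  out <- matrix(0, nB, nA)
  for (b in seq_len(nB)) {
    for (a in seq_len(nA)) {
      r <- round(rpe_fit[b, a])
      lo <- max(1L, r - cfg$enface_band_px)
      hi <- r - 1L - guard_px
      out[b, a] <- if (hi >= lo) mean(volume[lo:hi, a, b]) else 0
    }
  }
  out
}

#' Adaptive-threshold vessel mask from the en-face image
#'
#' Vessels cast shadows and appear dark in the en-face projection. The
#' image is inverted and binarized with a local-mean adaptive threshold
#' (window = image width / `mask_window_frac`, offset a fraction of the
#' dynamic range), then connected components smaller than `min_object_px`
#' pixels are removed (tiny children vessels are neglected).
#'
#' @param enface en-face image (B-scan x A-line).
#' @param cfg a [segmentation_config()].
#' @return logical vessel mask, same shape; blank images give an empty mask.
#' @export
vessel_mask <- function(enface, cfg = segmentation_config()) {
  rng <- range(enface)
  if (diff(rng) == 0) return(matrix(FALSE, nrow(enface), ncol(enface)))
  inv <- (rng[2] - enface) / diff(rng)
  w <- max(2L, round(ncol(enface) / cfg$mask_window_frac / 2))
  bw <- EBImage::thresh(EBImage::Image(inv), w = w, h = w,
                        offset = cfg$mask_offset)
  lab <- EBImage::bwlabel(bw)
  m <- EBImage::imageData(lab)
  sizes <- tabulate(m[m > 0])
  keep <- which(sizes >= cfg$min_object_px)
  matrix(m %in% keep, nrow(enface), ncol(enface))
}

#' Full layer segmentation of a reconstructed volume
#'
#' Orchestrates the segmentation stage: raw RPE detection, per-B-scan
#' iterative polynomial refinement, COV-based B-scan rejection, retinal
#' flattening, and ILM detection.
#'
#' @param volume reconstructed full-band array (depth x A-line x B-scan).
#' @param cfg a [segmentation_config()].
#' @return object of class `layer_surfaces`: `rpe_raw`, `rpe_fit` (after
#'   refinement and B-scan replacement), `rpe_curve` (point-wise curve),
#'   `ilm`, `outlier_mask`, `cov_trace`, `replaced_bscans`, `flattened`
#'   (the `flattened_volume`), `cfg`.
#' @export
segment_layers <- function(volume, cfg = segmentation_config()) {
  d <- dim(volume)
  nA <- d[2]; nB <- d[3]
  rpe_raw <- detect_rpe_raw(volume, cfg)
  rpe_fit <- matrix(NA_real_, nB, nA)
  rpe_curve <- matrix(NA_real_, nB, nA)
  outlier_mask <- matrix(FALSE, nB, nA)
  for (b in seq_len(nB)) {
    rc <- refine_curve(rpe_raw[b, ], cfg, bscan = b)
    rpe_fit[b, ] <- rc$fit
    rpe_curve[b, ] <- rc$curve
    outlier_mask[b, ] <- rc$outliers
  }
  rb <- reject_bscan_outliers(rpe_fit, rpe_curve, cfg)
  fv <- flatten(volume, rb$rpe_fit)
  ilm <- detect_ilm(fv, cfg)
  structure(list(rpe_raw = rpe_raw, rpe_fit = rb$rpe_fit,
                 rpe_curve = rb$rpe_curve, ilm = ilm,
                 outlier_mask = outlier_mask, cov_trace = rb$cov_trace,
                 replaced_bscans = rb$replaced_bscans, flattened = fv,
                 cfg = cfg),
            class = "layer_surfaces")
}
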