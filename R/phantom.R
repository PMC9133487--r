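#' Phantom configuration
#'
#' Defines a synthetic VIS-OCT acquisition: raster geometry, spectral
#' support, layered-retina geometry, vessels, and corruption/noise settings.
#' Every downstream stage of the pipeline can be validated against the
#' ground truth buried in the phantom.
#'
#' The default desk-scale raster is 64 B-scans x 128 A-lines x 512 depth
#' pixels from 1024 spectral samples; the clinical raster (512 x 256) is
#' reachable by configuration. Spectral support defaults to 520-600 nm and
#' the axial pitch to 3 um/pixel, so a 24 um vessel spans 8 axial pixels.
#'
#' @param n_bscans,n_alines,n_depth,n_spectral raster geometry;
#'   `n_depth <= n_spectral / 2`.
#' @param fov_mm lateral field of view along the A-line axis (mm). The
#'   lateral pitch is `fov_mm / n_alines` and is applied isotropically to
#'   both lateral axes.
#' @param depth_pitch_um axial size of one depth pixel (um).
#' @param lambda_range_nm source support `(min, max)` in nm.
#' @param vessel_specs list of vessels; each is a list with `path` (matrix
#'   of centerline waypoints, columns = B-scan and A-line pixel
#'   coordinates), `diameter_um`, `so2` (fraction), `label`
#'   ("artery"/"vein") and optional `depth_offset_px` (lumen center depth
#'   below the ILM, default 30).
#' @param rpe list: `center_px` mean RPE depth, `bow_px` parabolic bowing,
#'   `tilt_px` linear tilt, `spike_rate` per-A-line probability of a bright
#'   spurious reflector above the RPE (creates realistic RPE-detection
#'   outliers).
#' @param retina_px ILM-to-RPE thickness in depth pixels.
#' @param corrupt_bscans indices of B-scans replaced by saturated noise.
#' @param noise_sd relative shot-noise sigma (fraction of the DC level).
#' @param source `"gaussian"` (band-limited source) or `"flat"`.
#' @param rnfl list `amp`, `alpha`: non-vascular RNFL reflectance power law
#'   `amp * (lambda/560)^-alpha`.
#' @param fovea_xy fovea position (B-scan, A-line) in pixels; defaults to
#'   the raster center.
#' @param diameter_band_um admissible vessel-diameter band (um); parafoveal
#'   arterioles and venules are all below 40 um.
#' @param seed integer fixing all phantom randomness.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(n_bscans = 64, n_alines = 128, n_depth = 512,
                           n_spectral = 1024, fov_mm = 5.0,
                           depth_pitch_um = 3.0,
                           lambda_range_nm = c(520, 600),
                           vessel_specs = list(),
                           rpe = list(center_px = 380, bow_px = 6,
                                      tilt_px = 0, spike_rate = 0),
                           retina_px = 100,
                           corrupt_bscans = integer(0),
                           noise_sd = 0,
                           source = c("gaussian", "flat"),
                           rnfl = list(amp = 0.30, alpha = 1.0),
                           fovea_xy = NULL,
                           diameter_band_um = c(20, 40),
                           seed = 1) {
  source <- match.arg(source)
  if (n_depth > n_spectral / 2) stop("n_depth must be <= n_spectral/2")
  if (lambda_range_nm[1] >= lambda_range_nm[2]) stop("invalid lambda range")
  rpe_def <- list(center_px = 380, bow_px = 6, tilt_px = 0, spike_rate = 0)
  rpe <- utils::modifyList(rpe_def, rpe)
  for (v in vessel_specs) {
    stopifnot(is.matrix(v$path), ncol(v$path) == 2,
              v$so2 >= 0, v$so2 <= 1,
              v$label %in% c("artery", "vein"))
    if (v$diameter_um < diameter_band_um[1] ||
        v$diameter_um > diameter_band_um[2]) {
      stop("vessel diameter ", v$diameter_um, " um outside the band [",
           diameter_band_um[1], ", ", diameter_band_um[2], "] um")
    }
  }
  if (is.null(fovea_xy)) fovea_xy <- c((n_bscans + 1) / 2, (n_alines + 1) / 2)
  structure(list(
    n_bscans = n_bscans, n_alines = n_alines, n_depth = n_depth,
    n_spectral = n_spectral, fov_mm = fov_mm,
    depth_pitch_um = depth_pitch_um, lambda_range_nm = lambda_range_nm,
    vessel_specs = vessel_specs, rpe = rpe, retina_px = retina_px,
    corrupt_bscans = as.integer(corrupt_bscans), noise_sd = noise_sd,
    source = source, rnfl = rnfl, fovea_xy = fovea_xy,
    diameter_band_um = diameter_band_um, seed = as.integer(seed)
  ), class = "phantom_config")
}

# source power spectrum on a wavelength grid
phantom_source_spectrum <- function(config, lambda_nm) {
  if (config$source == "flat") return(rep(1, length(lambda_nm)))
  lc <- mean(config$lambda_range_nm)
  sg <- 0.35 * diff(config$lambda_range_nm)
  0.05 + exp(-0.5 * ((lambda_nm - lc) / sg)^2)
}

#' Ground-truth non-vascular RNFL reference spectrum
#'
#' The phantom's known non-vascular RNFL reflectance spectrum (source
#' spectrum times the RNFL power law), used as the normalization ground
#' truth for noiseless forward-model consistency checks.
#'
#' @param config a [phantom_config()].
#' @param lambda_nm wavelengths (nm); defaults to 11 points across the
#'   source support.
#' @return positive numeric vector, one value per wavelength.
#' @export
make_reference_rnfl_spectrum <- function(config,
                                         lambda_nm = seq(config$lambda_range_nm[1],
                                                         config$lambda_range_nm[2],
                                                         length.out = 11)) {
  phantom_source_spectrum(config, lambda_nm) *
    config$rnfl$amp * (lambda_nm / 560)^(-config$rnfl$alpha)
}

# densify a polyline to ~0.25 px steps; returns matrix (b, a)
densify_path <- function(path, step = 0.25) {
  if (nrow(path) == 1) return(path)
  seglen <- sqrt(rowSums((path[-1, , drop = FALSE] -
                          path[-nrow(path), , drop = FALSE])^2))
  s <- c(0, cumsum(seglen))
  ss <- seq(0, s[length(s)], by = step)
  cbind(stats::approx(s, path[, 1], xout = ss)$y,
        stats::approx(s, path[, 2], xout = ss)$y)
}

#' Generate a synthetic VIS-OCT interferogram volume with known truth
#'
#' Synthesizes spectral fringes directly in linear wavenumber (k) space,
#' dispersion-free. Each A-line is a DC term plus a sum over interfaces j of
#' `I0(lambda) R_j(lambda) cos(2 pi (z_j - 1) n / N)`: the ILM (RNFL power
#' law), a diffuse inner-retina scatter band above the RPE, vessel top/bottom
#' interfaces where a vessel crosses, and the RPE (bright, spectrally flat).
#' The vessel-bottom reflectance and the shadow cast on everything beneath
#' the vessel follow double-pass Beer-Lambert attenuation through the lumen
#' chord at the configured true sO2, evaluated with [model_spectrum()]'s
#' attenuation table. The vessel bottom is given a finite Gaussian axial
#' extent (sigma 1.5 px) so second-peak detection is realistic. Corrupt
#' B-scans are replaced by saturated noise. All randomness is fixed by
#' `config$seed`.
#'
#' @param config a [phantom_config()].
#' @param table an [extinction_table()] for the intravascular attenuation.
#' @return list with `volume` (class `interferogram_volume`: fringes array
#'   spectral x A-line x B-scan plus `k_axis`, `lambda_axis`) and `truth`
#'   (class `phantom_truth`: RPE/ILM depth maps, per-vessel en-face masks,
#'   vessel top/bottom depths, true sO2, fovea position, pixel pitches,
#'   corrupt-B-scan and spike bookkeeping).
#' @export
make_phantom <- function(config, table = extinction_table()) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  nB <- config$n_bscans; nA <- config$n_alines
  N <- config$n_spectral; Z <- config$n_depth
  lam_rng <- config$lambda_range_nm

  k_axis <- seq(1 / lam_rng[2], 1 / lam_rng[1], length.out = N)
  lambda_axis <- 1 / k_axis                      # decreasing in sample index
  I0 <- phantom_source_spectrum(config, lambda_axis)

  # --- truth surfaces (integer depth rows; the generator lives on the grid)
  an <- (seq_len(nA) - (nA + 1) / 2) / nA
  bn <- (seq_len(nB) - (nB + 1) / 2) / nB
  rpe_depth <- round(config$rpe$center_px +
    4 * config$rpe$bow_px * outer(bn^2, an^2, `+`) +
    2 * config$rpe$tilt_px * matrix(an, nB, nA, byrow = TRUE))
  rpe_depth <- pmin(pmax(rpe_depth, 12L), Z - 4L)
  ilm_depth <- rpe_depth - config$retina_px
  if (any(ilm_depth < 4)) stop("retina_px too large for rpe profile")

  lat_mm <- config$fov_mm / nA
  lat_um <- lat_mm * 1000
  pitch <- config$depth_pitch_um

  # --- vessels: masks, chord maps, spectral attenuation
  nV <- length(config$vessel_specs)
  vessel_masks <- vector("list", nV)
  chord_px_maps <- vector("list", nV)
  mu_mix_v <- vector("list", nV)
  true_so2 <- numeric(nV); labels <- character(nV)
  diam_um <- numeric(nV); offs <- numeric(nV)
  bg <- as.matrix(expand.grid(b = seq_len(nB), a = seq_len(nA)))
  mu_ax <- mu_attenuation(table, lambda_axis)
  for (i in seq_len(nV)) {
    v <- config$vessel_specs[[i]]
    off <- if (is.null(v$depth_offset_px)) 30 else v$depth_offset_px
    dp <- densify_path(v$path)
    d2 <- matrix(Inf, nB, nA)
    for (j in seq_len(nrow(dp))) {
      dj <- (bg[, 1] - dp[j, 1])^2 + (bg[, 2] - dp[j, 2])^2
      d2[] <- pmin(d2, dj)
    }
    dist_um <- sqrt(d2) * lat_um
    mask <- dist_um <= v$diameter_um / 2
    if (!any(mask)) {
      stop("vessel ", i, " has an empty footprint at this lateral pitch (",
           round(lat_um, 1), " um/px)")
    }
    chord_um <- matrix(0, nB, nA)
    chord_um[mask] <- 2 * sqrt((v$diameter_um / 2)^2 - dist_um[mask]^2)
    top <- ilm_depth + off - chord_um / (2 * pitch)
    bot <- ilm_depth + off + chord_um / (2 * pitch)
    if (any(top[mask] <= ilm_depth[mask] + 2) ||
        any(bot[mask] >= rpe_depth[mask] - 2)) {
      stop("vessel ", i, " extends outside the ILM-RPE band; adjust ",
           "depth_offset_px or diameter")
    }
    if (any(which(mask, arr.ind = TRUE)[, 1] %in% config$corrupt_bscans)) {
      stop("vessel ", i, " crosses a corrupt B-scan; masks must be ",
           "disjoint from corrupt regions")
    }
    vessel_masks[[i]] <- mask
    chord_px_maps[[i]] <- chord_um / pitch
    mu_mix_v[[i]] <- v$so2 * mu_ax$mu_hbo2 + (1 - v$so2) * mu_ax$mu_hb
    true_so2[i] <- v$so2; labels[i] <- v$label
    diam_um[i] <- v$diameter_um; offs[i] <- off
  }

  # spike outliers: hyper-reflective RNFL patches that out-shine the RPE,
  # the classic cause of RPE argmax detection jumping to the inner retina.
  # Modeled as patches ~14 A-lines wide (isolated single-A-line spikes would
  # vanish under the segmentation blur), at most one per B-scan;
  # spike_rate is the expected fraction of affected A-lines.
  spike_mask <- matrix(FALSE, nB, nA)
  if (config$rpe$spike_rate > 0) {
    patch_w <- min(14L, nA)
    n_events <- max(1L, round(config$rpe$spike_rate * nB * nA / patch_w))
    n_events <- min(n_events, nB - length(config$corrupt_bscans))
    ev_b <- sample(setdiff(seq_len(nB), config$corrupt_bscans), n_events)
    for (b in ev_b) {
      a0 <- sample(seq_len(nA - patch_w + 1), 1)
      spike_mask[b, a0:(a0 + patch_w - 1)] <- TRUE
    }
  }

  # --- fringe synthesis
  tt <- (seq_len(N) - 1) / N
  basis <- new.env(parent = emptyenv())
  cosv <- function(z) {
    key <- sprintf("%.4f", z)
    v <- basis[[key]]
    if (is.null(v)) {
      v <- cos(2 * pi * (z - 1) * tt)
      assign(key, v, envir = basis)
    }
    v
  }
  R_rnfl <- config$rnfl$amp * (lambda_axis / 560)^(-config$rnfl$alpha)
  R_wall <- 0.12 * (lambda_axis / 560)^(-2)
  R_rpe <- 1.0
  # continuous diffuse scatter band above the RPE (en-face signal carrier);
  # kept weak so the one-sided band does not bias the blurred RPE argmax by
  # more than a fraction of a pixel, and continuous so that +/- 1 px
  # segmentation jitter changes the en-face band content only marginally
  R_diff <- 0.012
  diffuse_off <- 3:19
  dc_level <- 3.0
  # posterior-wall reflex: a single sharp interface. OCT fringes arise from
  # sharp index steps; the reconstruction PSF (and any spectral window)
  # already gives the reconstructed peak its finite axial width, and a
  # coherent multi-row synthesis would imprint a spurious carrier-phase
  # modulation on the sub-band spectra.

  fr <- array(0, dim = c(N, nA, nB))
  for (b in seq_len(nB)) {
    for (a in seq_len(nA)) {
      zr <- rpe_depth[b, a]; zi <- ilm_depth[b, a]
      shadow <- 1  # spectral transmission of everything below a vessel
      acc <- R_rnfl * cosv(zi)
      vcontrib <- 0
      for (i in seq_len(nV)) {
        if (!vessel_masks[[i]][b, a]) next
        ch_px <- chord_px_maps[[i]][b, a]
        zc <- zi + offs[i]
        zpath_mm <- 2 * ch_px * pitch / 1000
        att <- exp(-mu_mix_v[[i]] * zpath_mm)
        shadow <- shadow * att
        vcontrib <- vcontrib + R_wall * cosv(zc - ch_px / 2) +
          R_wall * att * cosv(zc + ch_px / 2)
      }
      dsum <- 0
      for (d in diffuse_off) dsum <- dsum + cosv(zr - d)
      acc <- acc + vcontrib + shadow * (R_diff * dsum + R_rpe * cosv(zr))
      # bright enough that the patch dominates the RPE after the sigma-7 blur
      if (spike_mask[b, a]) acc <- acc + 2.5 * cosv(zi)
      # DC kept spectrally flat so per-A-line mean subtraction removes it
      # exactly; the source shape modulates the interference terms (axial
      # PSF) only
      f <- dc_level + I0 * acc
      if (config$noise_sd > 0) {
        f <- f + stats::rnorm(N, 0, config$noise_sd * dc_level)
      }
      fr[, a, b] <- f
    }
  }
  if (length(config$corrupt_bscans)) {
    amp <- 3 * max(abs(fr))
    for (b in config$corrupt_bscans) {
      fr[, , b] <- amp * stats::runif(N * nA, -1, 1)
    }
  }

  volume <- structure(list(fringes = fr, k_axis = k_axis,
                           lambda_axis = lambda_axis, n_depth = Z),
                      class = "interferogram_volume")
  mid <- vapply(seq_len(nV), function(i) {
    wp <- config$vessel_specs[[i]]$path
    m <- wp[ceiling(nrow(wp) / 2), ]
    ilm_depth[round(m[1]), round(m[2])]
  }, 0)
  truth <- structure(list(
    rpe_depth = rpe_depth, ilm_depth = ilm_depth,
    vessel_masks = vessel_masks,
    vessel_top_depth = mid + offs - diam_um / (2 * pitch),
    vessel_bottom_depth = mid + offs + diam_um / (2 * pitch),
    vessel_rel_top = offs - diam_um / (2 * pitch),
    vessel_rel_bottom = offs + diam_um / (2 * pitch),
    true_so2 = true_so2, labels = labels, diameters_um = diam_um,
    z_path_mm = 2 * diam_um / 1000,
    fovea_xy = config$fovea_xy,
    pixel_pitches = c(lateral_mm_px = lat_mm, axial_um_px = pitch),
    corrupt_bscans = config$corrupt_bscans,
    spike_mask = spike_mask,
    rnfl = config$rnfl
  ), class = "phantom_truth")
  list(volume = volume, truth = truth)
}
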