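# shared fixtures, built once per session

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

ext_tab <- function() fixture("ext_tab", function() extinction_table())

# hand-built interferogram volume, independent of make_phantom: a sum of
# cosines with given per-reflector spectral amplitude functions
synth_volume <- function(reflectors, N = 512, nA = 4, nB = 2,
                         lambda_range = c(520, 600)) {
  k <- seq(1 / lambda_range[2], 1 / lambda_range[1], length.out = N)
  lam <- 1 / k
  n <- (seq_len(N) - 1) / N
  fr <- array(0, dim = c(N, nA, nB))
  aline <- numeric(N)
  for (r in reflectors) {
    amp <- if (is.function(r$R)) r$R(lam) else rep(r$R, N)
    aline <- aline + amp * cos(2 * pi * (r$z - 1) * (seq_len(N) - 1) / N)
  }
  for (b in seq_len(nB)) for (a in seq_len(nA)) fr[, a, b] <- aline
  structure(list(fringes = fr, k_axis = k, lambda_axis = lam,
                 n_depth = N %/% 2),
            class = "interferogram_volume")
}

# single-vessel oximetry phantom at 1.55 um axial pitch (24.8 um lumen =
# 16 px, so the 5-above/10-below extraction window stays inside the lumen)
oxi_phantom_config <- function(so2, seed, diameter_um = 24.8,
                               label = "artery") {
  nA <- 64; nB <- 32
  vspec <- list(path = cbind(seq(6, nB - 5), nA / 2),
                diameter_um = diameter_um, so2 = so2, label = label,
                depth_offset_px = 40)
  phantom_config(n_bscans = nB, n_alines = nA, n_depth = 512,
                 n_spectral = 1024, fov_mm = nA * 0.02,
                 depth_pitch_um = 1.55,
                 rpe = list(center_px = 380, bow_px = 4), retina_px = 200,
                 vessel_specs = list(vspec), seed = seed)
}

# phantom -> reconstructed stack + surfaces, cached
oxi_chain <- function(name, cfg) {
  fixture(name, function() {
    tab <- ext_tab()
    ph <- make_phantom(cfg, tab)
    full <- reconstruct_fullband(ph$volume)
    stack <- stft_subbands(ph$volume, fullband = full)
    surf <- segment_layers(full)
    list(ph = ph, full = full, stack = stack, surf = surf, tab = tab)
  })
}

arterial_chain <- function() oxi_chain("art", oxi_phantom_config(0.921, 5))

# two parallel 32-um vessels at 10 um lateral pitch (for mask/topography)
two_vessel_chain <- function() {
  fixture("twovessel", function() {
    nA <- 96; nB <- 48
    v1 <- list(path = cbind(seq(8, nB - 7), 30), diameter_um = 32,
               so2 = 0.92, label = "artery", depth_offset_px = 40)
    v2 <- list(path = cbind(seq(8, nB - 7), 66), diameter_um = 32,
               so2 = 0.48, label = "vein", depth_offset_px = 40)
    cfg <- phantom_config(n_bscans = nB, n_alines = nA, n_depth = 512,
                          n_spectral = 1024, fov_mm = nA * 0.010,
                          depth_pitch_um = 1.55,
                          rpe = list(center_px = 380, bow_px = 4),
                          retina_px = 200, vessel_specs = list(v1, v2),
                          seed = 9)
    tab <- ext_tab()
    ph <- make_phantom(cfg, tab)
    full <- reconstruct_fullband(ph$volume)
    surf <- segment_layers(full)
    list(cfg = cfg, ph = ph, full = full, surf = surf,
         enface = make_enface(full, surf$rpe_fit))
  })
}

# independent sO2 oracle: exhaustive grid with the linear parameters
# profiled in closed form at each grid point
oracle_grid_so2 <- function(spectrum, lambda_nm, z_path_mm, table,
                            step = 0.001) {
  mu <- mu_attenuation(table, lambda_nm)
  ls <- log(spectrum)
  ll <- log(lambda_nm / 560)
  grid <- seq(0, 1, by = step)
  rss <- vapply(grid, function(g) {
    y <- ls + (g * mu$mu_hbo2 + (1 - g) * mu$mu_hb) * z_path_mm
    sum(stats::lm.fit(cbind(1, -ll), y)$residuals^2)
  }, 0)
  grid[which.min(rss)]
}

# a depth_spectrum built directly from numbers (no reconstruction)
manual_ds <- function(mat, mean_aline = rowMeans(mat),
                      lambda = seq(520, 600, length.out = ncol(mat))) {
  structure(list(I_z_lambda = mat, mean_aline = mean_aline,
                 mean_subband = rowMeans(mat), lambda_centers = lambda,
                 bottom_idx = NA_integer_, top_idx = NA_integer_,
                 z_path_mm = NA_real_, n_px = 1L),
            class = "depth_spectrum")
}
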