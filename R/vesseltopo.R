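#' Skeletonize a binary vessel mask
#'
#' Morphological thinning (Zhang-Suen) of a binary en-face mask down to a
#' one-pixel-wide centerline.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same shape containing the skeleton.
#' @export
skeletonize_mask <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  pad <- matrix(0L, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  nr <- nrow(pad); nc <- ncol(pad)
  nbr <- function(p) {
    # neighbors P2..P9 clockwise from north, as nr x nc x 8
    sh <- function(dr, dc) {
      q <- matrix(0L, nr, nc)
      rs <- (1 + max(0, -dr)):(nr - max(0, dr))
      cs <- (1 + max(0, -dc)):(nc - max(0, dc))
      q[rs + dr, cs + dc] <- p[rs, cs]
      q
    }
    list(sh(-1, 0), sh(-1, 1), sh(0, 1), sh(1, 1),
         sh(1, 0), sh(1, -1), sh(0, -1), sh(-1, -1))
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- nbr(pad)
      B <- Reduce(`+`, nb)
      ring <- c(nb, nb[1])
      A <- Reduce(`+`, lapply(1:8, function(i) {
        (ring[[i]] == 0L) * (ring[[i + 1]] == 1L)
      }))
      if (step == 1) {
        c1 <- nb[[1]] * nb[[3]] * nb[[5]]   # P2*P4*P6
        c2 <- nb[[3]] * nb[[5]] * nb[[7]]   # P4*P6*P8
      } else {
        c1 <- nb[[1]] * nb[[3]] * nb[[7]]   # P2*P4*P8
        c2 <- nb[[1]] * nb[[5]] * nb[[7]]   # P2*P6*P8
      }
      del <- pad == 1L & B >= 2 & B <= 6 & A == 1 & c1 == 0 & c2 == 0
      if (any(del)) {
        pad[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] == 1L
}

#' Centerline length of a vessel segment
#'
#' Skeletonizes the mask and measures the longest geodesic along the
#' skeleton, with unit steps for 4-neighbors and sqrt(2) steps for
#' diagonals, converted by the lateral pixel pitch.
#'
#' @param mask logical vessel mask.
#' @param lateral_pitch_mm lateral pixel pitch (mm/px).
#' @return centerline length in mm (0 for masks with fewer than 2 skeleton
#'   pixels).
#' @export
centerline_length <- function(mask, lateral_pitch_mm) {
  sk <- skeletonize_mask(mask)
  px <- which(sk, arr.ind = TRUE)
  n <- nrow(px)
  if (n < 2) return(0)
  ed <- NULL
  wt <- NULL
  for (i in seq_len(n - 1)) {
    dr <- abs(px[(i + 1):n, 1] - px[i, 1])
    dc <- abs(px[(i + 1):n, 2] - px[i, 2])
    j <- which(dr <= 1 & dc <= 1)
    if (length(j)) {
      ed <- rbind(ed, cbind(i, i + j))
      wt <- c(wt, ifelse(dr[j] + dc[j] == 2, sqrt(2), 1))
    }
  }
  if (is.null(ed)) return(0)
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  igraph::E(g)$weight <- wt
  d <- igraph::distances(g)
  max(d[is.finite(d)]) * lateral_pitch_mm
}

#' Vessel ROI area
#'
#' @param mask logical vessel mask.
#' @param lateral_pitch_mm lateral pixel pitch (mm/px).
#' @return mask area in mm^2 (pixel count x pitch^2).
#' @export
mask_area <- function(mask, lateral_pitch_mm) {
  sum(mask) * lateral_pitch_mm^2
}

#' Axial vessel diameter from the averaged A-line
#'
#' The diameter is the distance between the vessel-top and vessel-bottom
#' reflective peaks of the ROI-averaged A-line (axial, not lateral mask
#' width), converted by the axial pixel pitch. Peaks are located with
#' [find_vessel_bottom()]'s detector if not already set on the
#' `depth_spectrum`.
#'
#' @param ds a `depth_spectrum`.
#' @param axial_pitch_um axial pixel pitch (um/px).
#' @return diameter in um.
#' @export
vessel_diameter <- function(ds, axial_pitch_um) {
  stopifnot(inherits(ds, "depth_spectrum"))
  if (!is.finite(ds$bottom_idx) || !is.finite(ds$top_idx)) {
    pk <- locate_vessel_peaks(ds)
    ds$top_idx <- pk$top
    ds$bottom_idx <- pk$bottom
  }
  (ds$bottom_idx - ds$top_idx) * axial_pitch_um
}

#' Minimum and maximum distance from the fovea to a vessel segment
#'
#' Euclidean distances from the fovea to every mask pixel center.
#'
#' @param mask logical vessel mask.
#' @param fovea_xy fovea position (B-scan, A-line) in pixels.
#' @param lateral_pitch_mm lateral pixel pitch (mm/px).
#' @return named vector `c(rho_min_mm, rho_max_mm)`.
#' @export
fovea_distances <- function(mask, fovea_xy, lateral_pitch_mm) {
  px <- which(mask, arr.ind = TRUE)
  if (nrow(px) == 0) stop("empty mask")
  d <- sqrt((px[, 1] - fovea_xy[1])^2 + (px[, 2] - fovea_xy[2])^2) *
    lateral_pitch_mm
  c(rho_min_mm = min(d), rho_max_mm = max(d))
}

#' All topographic features of one vessel segment
#'
#' @param mask logical vessel ROI mask.
#' @param ds the vessel's `depth_spectrum` (for the axial diameter).
#' @param fovea_xy fovea position (pixels).
#' @param lateral_pitch_mm,axial_pitch_um pixel pitches.
#' @param label `"artery"` or `"vein"`.
#' @return one-row `data.frame`: `L_mm`, `A_mm2`, `A_1e3mm2`, `D_um`,
#'   `rho_min_mm`, `rho_max_mm`, `label`.
#' @export
vessel_topography <- function(mask, ds, fovea_xy, lateral_pitch_mm,
                              axial_pitch_um, label) {
  rho <- fovea_distances(mask, fovea_xy, lateral_pitch_mm)
  A <- mask_area(mask, lateral_pitch_mm)
  data.frame(
    L_mm = centerline_length(mask, lateral_pitch_mm),
    A_mm2 = A, A_1e3mm2 = 1000 * A,
    D_um = vessel_diameter(ds, axial_pitch_um),
    rho_min_mm = unname(rho[1]), rho_max_mm = unname(rho[2]),
    label = label, stringsAsFactors = FALSE
  )
}
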