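# ---- first-order and shape features ---------------------------------------
#
# Definitions follow the IBSI / common radiomics conventions. Divergences
# from mesh-based reference implementations are deliberate and documented:
# surface area is computed from exposed voxel faces (which makes the
# sphericity of a cubic region exactly (36*pi)^(1/3)/6 ~ 0.806) and mesh
# volume equals voxel volume under this voxel-face convention. Maximum
# diameters use voxel centres. All moment-based statistics use the
# population (1/N) convention.

#' Discretize intensities to a fixed number of bins
#'
#' Equal-width bins between the region minimum and maximum; a constant
#' region maps to bin 1. Used for all texture matrices and for first-order
#' entropy/uniformity.
#'
#' @param x numeric vector or array.
#' @param nbins number of gray levels (>= 2).
#' @return integer bins in 1..nbins (NA preserved).
#' @export
discretize_fixed_bins <- function(x, nbins = 32L) {
  stopifnot(nbins >= 2)
  fin <- x[is.finite(x)]
  if (!length(fin)) stop("no finite values to discretize")
  lo <- min(fin); hi <- max(fin)
  if (hi - lo < 1e-300) {
    out <- x; out[is.finite(out)] <- 1L
    return(out)
  }
  b <- floor((x - lo) / (hi - lo) * nbins) + 1L
  b[b > nbins] <- nbins
  b
}

firstorder_names <- c("Energy", "TotalEnergy", "Entropy", "Minimum",
                      "10Percentile", "90Percentile", "Maximum", "Mean",
                      "Median", "InterquartileRange", "Range",
                      "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
                      "RootMeanSquared", "Skewness", "Kurtosis", "Variance",
                      "Uniformity")

#' First-order intensity features of a region
#'
#' @param x numeric vector of region intensities.
#' @param voxel_volume_mm3 volume of one voxel (for TotalEnergy).
#' @param nbins gray levels for Entropy/Uniformity discretization.
#' @return named numeric vector of 18 features.
#' @export
firstorder_features <- function(x, voxel_volume_mm3 = 1, nbins = 32L) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  robust <- x[x >= q[1] & x <= q[5]]
  b <- discretize_fixed_bins(x, nbins)
  p <- tabulate(b, nbins) / n
  p <- p[p > 0]
  c(Energy = sum(x^2),
    TotalEnergy = voxel_volume_mm3 * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(robust)) mean(abs(robust - mean(robust))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 1e-15) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 1e-15) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}

shape_names <- c("MeshVolume", "VoxelVolume", "SurfaceArea",
                 "SurfaceVolumeRatio", "Sphericity", "Maximum3DDiameter",
                 "Maximum2DDiameterSlice", "Maximum2DDiameterColumn",
                 "Maximum2DDiameterRow", "MajorAxisLength", "MinorAxisLength",
                 "LeastAxisLength", "Elongation", "Flatness")

max_pairwise_dist <- function(p) {
  if (nrow(p) < 2) return(0)
  if (nrow(p) > 2000) {  # subsample deterministically for very large surfaces
    keep <- unique(round(seq(1, nrow(p), length.out = 2000)))
    p <- p[keep, , drop = FALSE]
  }
  sqrt(max(stats::dist(p)^2))
}

#' Shape features of a 3D region
#'
#' Computed on the original (unfiltered) geometry only. Surface area counts
#' exposed voxel faces; axis lengths come from the eigenvalues of the
#' physical-coordinate covariance (4 * sqrt(lambda)).
#'
#' @param mask binary 3D array.
#' @param spacing mm per voxel.
#' @return named numeric vector of 14 features.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  stopifnot_vol(mask)
  spacing <- rep_len(spacing, 3L)
  m <- mask > 0
  n <- sum(m)
  if (n == 0) stop("empty region")
  vv <- prod(spacing)
  vol <- n * vv
  # exposed faces per axis
  sa <- 0
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  for (ax in 1:3) {
    d <- c(0L, 0L, 0L); d[ax] <- 1L
    nb_pos <- shift_array(m * 1, d, fill = 0) > 0
    nb_neg <- shift_array(m * 1, -d, fill = 0) > 0
    sa <- sa + face_area[ax] * (sum(m & !nb_pos) + sum(m & !nb_neg))
  }
  sph <- (36 * pi * vol^2)^(1 / 3) / sa
  co <- arrayInd(which(m), dim(m))
  xyz <- sweep(co, 2, spacing, `*`)
  # surface voxels only, for diameters
  interior <- m
  for (ax in 1:3) {
    d <- c(0L, 0L, 0L); d[ax] <- 1L
    interior <- interior & (shift_array(m * 1, d, fill = 0) > 0) &
                           (shift_array(m * 1, -d, fill = 0) > 0)
  }
  surf <- m & !interior
  sco <- arrayInd(which(surf), dim(m))
  sxyz <- sweep(sco, 2, spacing, `*`)
  d3 <- max_pairwise_dist(sxyz)
  # 2D diameters: maximum in-plane distance within any fixed slice
  plane_max <- function(fixed_ax) {
    keep_ax <- setdiff(1:3, fixed_ax)
    mx <- 0
    for (s in unique(sco[, fixed_ax])) {
      pts <- sxyz[sco[, fixed_ax] == s, keep_ax, drop = FALSE]
      mx <- max(mx, max_pairwise_dist(pts))
    }
    mx
  }
  d2_slice <- plane_max(3L)   # fixed z: axial plane
  d2_col <- plane_max(2L)     # fixed y
  d2_row <- plane_max(1L)     # fixed x
  ev <- if (n > 1) {
    cv <- stats::cov(xyz) * (n - 1) / n  # population covariance
    sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
         decreasing = TRUE)
  } else c(0, 0, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])
  c(MeshVolume = vol, VoxelVolume = vol, SurfaceArea = sa,
    SurfaceVolumeRatio = sa / vol, Sphericity = sph,
    Maximum3DDiameter = d3, Maximum2DDiameterSlice = d2_slice,
    Maximum2DDiameterColumn = d2_col, Maximum2DDiameterRow = d2_row,
    MajorAxisLength = major, MinorAxisLength = minor,
    LeastAxisLength = least,
    Elongation = if (ev[1] > 1e-15) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 1e-15) sqrt(ev[3] / ev[1]) else 0)
}
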