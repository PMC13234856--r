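# ---- low-level 3D array helpers ------------------------------------------
# All volumes in this package are plain 3D numeric arrays indexed [x, y, z],
# with a numeric length-3 `spacing` (mm per voxel along each axis) carried
# alongside rather than inside the array.

stopifnot_vol <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("expected a 3D array", call. = FALSE)
}

#' Shift a 3D array by an integer offset, filling with NA
#'
#' `shift_array(a, c(1,0,0))[i,j,k]` equals `a[i-1,j,k]` (content moves in
#' the +x direction); out-of-range positions become `fill`.
#' @param a 3D array.
#' @param d integer offset of length 3.
#' @param fill value used outside the original extent.
#' @return array of the same dimension.
#' @keywords internal
shift_array <- function(a, d, fill = NA_real_) {
  stopifnot_vol(a)
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      if (d[ax] >= dm[ax]) return(out)
      src[[ax]] <- seq_len(dm[ax] - d[ax])
      dst[[ax]] <- seq_len(dm[ax] - d[ax]) + d[ax]
    } else {
      if (-d[ax] >= dm[ax]) return(out)
      src[[ax]] <- seq_len(dm[ax] + d[ax]) - d[ax]
      dst[[ax]] <- seq_len(dm[ax] + d[ax])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# 26-neighbourhood / 6-neighbourhood integer offsets (excluding the origin)
neighbor_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  g
}

#' Label connected components of a binary 3D mask
#'
#' Vectorized minimum-label propagation: every foreground voxel starts with
#' its linear index and repeatedly adopts the smallest neighbouring label
#' until convergence. Components are numbered by the scan order of their
#' smallest member (1 = component containing the first TRUE voxel).
#' @param mask logical/numeric 3D array.
#' @param connectivity 6 or 26.
#' @param gray optional array: labels propagate only between voxels with
#'   equal `gray` values (used for size-zone extraction).
#' @return integer array, 0 outside the mask.
#' @keywords internal
label_components <- function(mask, connectivity = 26L, gray = NULL) {
  stopifnot_vol(mask)
  dm <- dim(mask)
  m <- mask > 0
  out <- array(0L, dm)
  nfg <- sum(m)
  if (nfg == 0L) return(out)
  # vertex index per foreground voxel, NA elsewhere
  vid <- array(NA_real_, dm)
  vid[m] <- seq_len(nfg)
  offs <- neighbor_offsets(connectivity)
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
               (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]  # half the offsets suffice for undirected edges
  from <- to <- list()
  for (o in seq_len(nrow(offs))) {
    nb <- shift_array(vid, offs[o, ])
    ok <- !is.na(vid) & !is.na(nb)
    if (!is.null(gray)) {
      gb <- shift_array(gray * 1, offs[o, ])
      ok <- ok & !is.na(gb) & gb == gray
    }
    if (any(ok)) { from[[o]] <- vid[ok]; to[[o]] <- nb[ok] }
  }
  ed <- c(rbind(unlist(from), unlist(to)))
  memb <- if (!length(ed)) seq_len(nfg) else
    igraph::components(igraph::make_graph(ed, n = nfg,
                                          directed = FALSE))$membership
  # igraph numbers components by first-vertex (scan) order already
  out[m] <- as.integer(memb)
  out
}

#' Keep the largest connected component of a mask
#' @keywords internal
largest_component <- function(mask, connectivity = 26L) {
  lab <- label_components(mask, connectivity)
  if (!any(lab > 0L)) return(array(FALSE, dim(mask)))
  tb <- tabulate(lab[lab > 0L])
  lab == which.max(tb)
}

# spherical structuring-element offsets for morphology, radius in voxels
ball_offsets <- function(r_vox) {
  r <- pmax(0, r_vox)
  ri <- ceiling(r)
  if (all(ri == 0)) return(matrix(0L, 0L, 3L))
  g <- as.matrix(expand.grid(dx = -ri[1]:ri[1], dy = -ri[2]:ri[2], dz = -ri[3]:ri[3]))
  d2 <- (g[, 1] / max(r[1], 1e-9))^2 + (g[, 2] / max(r[2], 1e-9))^2 +
        (g[, 3] / max(r[3], 1e-9))^2
  g <- g[d2 <= 1 + 1e-9 & rowSums(abs(g)) > 0, , drop = FALSE]
  g
}

#' Binary dilation / erosion with an ellipsoidal structuring element
#' @param mask logical 3D array.
#' @param r_vox radius in voxels per axis (length 1 or 3).
#' @keywords internal
dilate_mask <- function(mask, r_vox) {
  stopifnot_vol(mask)
  r_vox <- rep_len(r_vox, 3L)
  offs <- ball_offsets(r_vox)
  out <- mask > 0
  for (o in seq_len(nrow(offs)))
    out <- out | (shift_array((mask > 0) * 1, offs[o, ], fill = 0) > 0)
  out
}

#' @rdname dilate_mask
#' @keywords internal
erode_mask <- function(mask, r_vox) {
  !dilate_mask(!(mask > 0), r_vox)
}

# ---- separable convolution ------------------------------------------------

# Build an n x n convolution matrix for a 1D kernel with symmetric
# (mirror, half-sample) boundary handling: out = K %*% signal.
conv_matrix_1d <- function(n, kernel) {
  kl <- length(kernel)
  r <- (kl - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (t in seq_len(kl)) {
      j <- i + (t - r - 1L)          # sample index the tap reads
      # symmetric half-sample reflection: ... 2 1 | 1 2 ... n | n n-1 ...
      while (j < 1L || j > n) {
        if (j < 1L) j <- 1L - j
        if (j > n)  j <- 2L * n + 1L - j
      }
      K[i, j] <- K[i, j] + kernel[t]
    }
  }
  K
}

# Apply a 1D kernel along one axis of a 3D array (symmetric padding).
conv_axis <- function(a, kernel, axis) {
  stopifnot_vol(a)
  dm <- dim(a)
  K <- conv_matrix_1d(dm[axis], kernel)
  if (axis == 1L) {
    array(K %*% matrix(a, dm[1]), dm)
  } else if (axis == 2L) {
    ap <- aperm(a, c(2, 1, 3))
    ap <- array(K %*% matrix(ap, dm[2]), dim(ap))
    aperm(ap, c(2, 1, 3))
  } else {
    ap <- aperm(a, c(3, 1, 2))
    ap <- array(K %*% matrix(ap, dm[3]), dim(ap))
    aperm(ap, c(2, 3, 1))
  }
}

# Sampled Gaussian kernel, renormalised to unit sum (sigma in voxels).
gauss_kernel <- function(sigma, truncate = 4) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(truncate * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing of a 3D array (separable, symmetric padding)
#' @param a 3D array.
#' @param sigma_vox standard deviation in voxels (length 1 or 3).
#' @keywords internal
gaussian_smooth <- function(a, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  out <- a
  for (ax in 1:3)
    if (sigma_vox[ax] > 0) out <- conv_axis(out, gauss_kernel(sigma_vox[ax]), ax)
  out
}

# ---- misc -----------------------------------------------------------------

# derive a deterministic child seed (< 2^31) from a base seed and a tag
# (polynomial string hash mixed with an LCG step; collisions across the
# package's tag set are vanishingly rare)
child_seed <- function(seed, tag) {
  h <- 17
  for (ch in utf8ToInt(as.character(tag)))
    h <- (h * 131 + ch) %% 2147483647
  h <- (h + as.numeric(seed) * 2654435761) %% 2147483647
  as.integer((h * 48271) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
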