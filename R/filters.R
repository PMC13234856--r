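# ---- image filters for the radiomics bank ---------------------------------
#
# "Wavelet" means the 8 subbands (all L/H combinations per axis) of a
# single-level undecimated 3D separable wavelet transform: this is the
# standard radiomics convention, and it is the only reading consistent with
# the 1,037-feature count (14 shape + 93 x (1 original + 8 wavelet + 2 LoG)).
# The basis is coif1; boundaries are handled by symmetric reflection.
# LoG responses are scale-normalised (multiplied by sigma^2) so different
# sigmas are comparable.

# coif1 decomposition filters (orthonormal; sum(lo) = sqrt(2), sum(hi) = 0)
coif1_lo <- c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
              0.8525720202116004, 0.3378976624574818, -0.07273261951252645)
coif1_hi <- c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
              0.3848648468648578, 0.07273261951252645, -0.015655728135791993)

#' Single-level undecimated 3D wavelet subbands
#'
#' Returns the 8 subbands `LLL, HLL, LHL, HHL, LLH, HLH, LHH, HHH`, where
#' the letters give the filter (low/high-pass coif1) applied along the x, y
#' and z axes respectively. Subbands keep the input resolution.
#'
#' @param volume 3D array, each dimension >= the filter length (6).
#' @return named list of 8 arrays.
#' @export
wavelet_subbands <- function(volume) {
  stopifnot_vol(volume)
  if (any(dim(volume) < length(coif1_lo)))
    stop("volume smaller than the wavelet support")
  ax_filt <- function(a, which, axis)
    conv_axis(a, if (which == "L") coif1_lo else coif1_hi, axis)
  out <- list()
  for (fz in c("L", "H")) for (fy in c("L", "H")) for (fx in c("L", "H")) {
    nm <- paste0(fx, fy, fz)
    out[[nm]] <- ax_filt(ax_filt(ax_filt(volume, fx, 1L), fy, 2L), fz, 3L)
  }
  out[c("LLL", "HLL", "LHL", "HHL", "LLH", "HLH", "LHH", "HHH")]
}

#' Laplacian-of-Gaussian filter response
#'
#' Separable implementation of the scale-normalised LoG,
#' `sigma^2 * (d2G/dx2 + d2G/dy2 + d2G/dz2) * I`, using sampled Gaussian and
#' second-derivative-of-Gaussian kernels truncated at 4 sigma. `sigma` is in
#' mm and converted to voxels via `spacing`.
#'
#' @param volume 3D array.
#' @param sigma_mm Gaussian scale in mm.
#' @param spacing mm per voxel (length 1 or 3).
#' @return filtered array at input resolution.
#' @export
log_filter <- function(volume, sigma_mm, spacing = c(1, 1, 1)) {
  stopifnot_vol(volume)
  if (sigma_mm <= 0) stop("sigma must be positive")
  spacing <- rep_len(spacing, 3L)
  sig <- sigma_mm / spacing  # voxels per axis
  g_k <- function(s) {
    r <- max(1L, ceiling(4 * s)); x <- (-r):r
    k <- exp(-x^2 / (2 * s^2)) / (s * sqrt(2 * pi))
    k
  }
  d2g_k <- function(s) {
    r <- max(1L, ceiling(4 * s)); x <- (-r):r
    k <- (x^2 - s^2) / s^4 * exp(-x^2 / (2 * s^2)) / (s * sqrt(2 * pi))
    k - mean(k)  # zero-DC so constant regions give exactly zero response
  }
  out <- array(0, dim(volume))
  for (ax in 1:3) {
    t <- volume
    for (ax2 in 1:3) {
      k <- if (ax2 == ax) d2g_k(sig[ax2]) else g_k(sig[ax2])
      t <- conv_axis(t, k, ax2)
    }
    out <- out + t
  }
  sigma_mm^2 * out
}

#' All filtered images for the radiomics bank
#'
#' @param volume 3D array (a preprocessed sequence).
#' @param spacing mm per voxel.
#' @param filters character vector: subset of `"original"`,
#'   `"wavelet"` (expands to the 8 subbands) and `"log_sigma_3.0"`,
#'   `"log_sigma_4.0"`.
#' @return named list `original`, `wavelet-LLL`, ..., `log-sigma-3-0`, ...
#' @export
filter_images <- function(volume, spacing = c(1, 1, 1),
                          filters = c("original", "wavelet",
                                      "log_sigma_3.0", "log_sigma_4.0")) {
  out <- list()
  if ("original" %in% filters) out$original <- volume
  if ("wavelet" %in% filters) {
    wb <- wavelet_subbands(volume)
    names(wb) <- paste0("wavelet-", names(wb))
    out <- c(out, wb)
  }
  for (f in grep("^log_sigma_", filters, value = TRUE)) {
    s <- as.numeric(sub("log_sigma_", "", f))
    out[[sprintf("log-sigma-%g-mm", s)]] <- log_filter(volume, s, spacing)
  }
  out
}
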