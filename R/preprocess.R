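# ---- image preprocessing: resample -> clip -> z-score ---------------------
#
# The fixed order mirrors standard radiomics practice: volumes are first
# resampled to isotropic spacing (linear for images, nearest-neighbour for
# masks), intensities inside the tumor VOI are clipped to configurable
# percentiles, and each (patient, sequence) volume is z-scored.

#' Preprocessing configuration
#'
#' @param target_spacing mm per voxel after resampling (length 1 or 3).
#' @param clip_percentiles `c(low, high)` percentiles (in %) for VOI
#'   intensity clipping; defaults to `(0.5, 99.5)`, a standard outlier trim.
#' @param zscore_scope `"whole_volume"` (default) or `"voi"`: the region over
#'   which the z-score mean/SD are computed.
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_spacing = c(1, 1, 1),
                              clip_percentiles = c(0.5, 99.5),
                              zscore_scope = c("whole_volume", "voi")) {
  target_spacing <- rep_len(target_spacing, 3L)
  zscore_scope <- match.arg(zscore_scope)
  stopifnot(all(target_spacing > 0),
            length(clip_percentiles) == 2,
            clip_percentiles[1] >= 0, clip_percentiles[2] <= 100,
            clip_percentiles[1] < clip_percentiles[2])
  structure(list(target_spacing = target_spacing,
                 clip_percentiles = clip_percentiles,
                 zscore_scope = zscore_scope),
            class = "preprocess_config")
}

# per-axis interpolation matrix mapping an input axis (n_in samples at
# spacing s_in) onto the output axis (n_out samples at spacing s_out);
# voxel i has physical centre (i-1)*s, sampling clamps to the volume edge
interp_matrix_1d <- function(n_in, s_in, s_out, method) {
  n_out <- ceiling(n_in * s_in / s_out)
  pos <- (seq_len(n_out) - 1) * s_out / s_in + 1  # continuous input index
  pos <- pmin(pmax(pos, 1), n_in)
  K <- matrix(0, n_out, n_in)
  if (method == "nearest") {
    j <- pmin(pmax(round(pos), 1), n_in)
    K[cbind(seq_len(n_out), j)] <- 1
  } else {
    j0 <- pmin(floor(pos), n_in - ifelse(n_in > 1, 1, 0))
    j0 <- pmax(j0, 1)
    w <- pos - j0
    j1 <- pmin(j0 + 1, n_in)
    for (i in seq_len(n_out)) {
      K[i, j0[i]] <- K[i, j0[i]] + (1 - w[i])
      K[i, j1[i]] <- K[i, j1[i]] + w[i]
    }
  }
  K
}

apply_axis_matrix <- function(a, K, axis) {
  dm <- dim(a)
  if (axis == 1L) {
    out <- K %*% matrix(a, dm[1])
    array(out, c(nrow(K), dm[2], dm[3]))
  } else if (axis == 2L) {
    ap <- aperm(a, c(2, 1, 3))
    out <- K %*% matrix(ap, dm[2])
    aperm(array(out, c(nrow(K), dm[1], dm[3])), c(2, 1, 3))
  } else {
    ap <- aperm(a, c(3, 1, 2))
    out <- K %*% matrix(ap, dm[3])
    aperm(array(out, c(nrow(K), dm[1], dm[2])), c(2, 3, 1))
  }
}

#' Resample a 3D volume to a new voxel spacing
#'
#' Output grid shape is `ceiling(shape * spacing_in / spacing_out)`; voxel
#' `i` is taken to have physical centre `(i-1) * spacing`, and sampling
#' positions are clamped to the volume extent. Linear interpolation is
#' separable trilinear; `"nearest"` preserves the input value set (so a
#' binary mask stays binary).
#'
#' @param volume 3D array.
#' @param spacing_in,spacing_out mm per voxel (length 1 or 3 each).
#' @param method `"linear"` or `"nearest"`.
#' @return resampled 3D array.
#' @export
resample_volume <- function(volume, spacing_in, spacing_out,
                            method = c("linear", "nearest")) {
  stopifnot_vol(volume)
  method <- match.arg(method)
  spacing_in <- rep_len(spacing_in, 3L)
  spacing_out <- rep_len(spacing_out, 3L)
  if (any(spacing_in <= 0) || any(spacing_out <= 0))
    stop("spacings must be positive")
  out <- volume
  for (ax in 1:3) {
    K <- interp_matrix_1d(dim(out)[ax], spacing_in[ax], spacing_out[ax], method)
    out <- apply_axis_matrix(out, K, ax)
  }
  out
}

#' Clip intensities inside a VOI to percentiles of the masked distribution
#'
#' Voxels outside the mask are untouched; within the mask, values below the
#' `low` percentile (or above the `high` percentile) of the masked intensity
#' distribution are set to that percentile value.
#'
#' @param volume 3D array.
#' @param mask binary 3D array, non-empty.
#' @param low,high percentiles in % with `low < high`.
#' @return clipped volume.
#' @export
clip_to_percentiles <- function(volume, mask, low = 0.5, high = 99.5) {
  stopifnot_vol(volume)
  m <- mask > 0
  if (!any(m)) stop("mask is empty")
  if (low >= high) stop("low percentile must be < high percentile")
  v <- volume[m]
  q <- stats::quantile(v, probs = c(low, high) / 100, names = FALSE, type = 7)
  volume[m] <- pmin(pmax(v, q[1]), q[2])
  volume
}

#' Z-score standardize a volume
#'
#' Uses the population SD convention (`1/N`), fixed across the package.
#' With `mask = NULL` the scope is the whole volume; otherwise the mean/SD
#' are computed over the masked voxels but applied to the whole volume.
#'
#' @param volume 3D array.
#' @param mask optional binary scope region.
#' @param label identifier used in error messages (patient/sequence).
#' @return standardized volume (scope mean 0, population SD 1).
#' @export
zscore_volume <- function(volume, mask = NULL, label = "volume") {
  stopifnot_vol(volume)
  v <- if (is.null(mask)) as.vector(volume) else volume[mask > 0]
  if (length(v) < 2) stop("z-score scope has fewer than 2 voxels: ", label)
  mu <- mean(v)
  sdp <- sqrt(mean((v - mu)^2))
  if (sdp < 1e-12)
    stop("zero variance in z-score scope: ", label)
  (volume - mu) / sdp
}

#' Preprocess one study: resample, clip, z-score
#'
#' Applies the fixed pipeline to every sequence of a study: resampling to
#' the target spacing (linear for images, nearest for masks), percentile
#' clipping within the tumor VOI, and z-score standardization per sequence.
#'
#' @param study an `mpmri_study`.
#' @param config a [preprocess_config()].
#' @return the study with standardized sequences, resampled masks, and a
#'   `preprocessed` flag.
#' @export
preprocess_study <- function(study, config = preprocess_config()) {
  stopifnot(inherits(study, "mpmri_study"))
  sp_in <- study$spacing
  sp_out <- config$target_spacing
  mask <- resample_volume(study$tumor_mask * 1, sp_in, sp_out, "nearest") > 0
  mask2 <- resample_volume(study$tumor_mask_rater2 * 1, sp_in, sp_out, "nearest") > 0
  truth <- if (!is.null(study$habitat_truth))
    resample_volume(study$habitat_truth, sp_in, sp_out, "nearest") else NULL
  seqs <- lapply(names(study$sequences), function(s) {
    v <- resample_volume(study$sequences[[s]], sp_in, sp_out, "linear")
    v <- clip_to_percentiles(v, mask, config$clip_percentiles[1],
                             config$clip_percentiles[2])
    scope <- if (config$zscore_scope == "voi") mask else NULL
    zscore_volume(v, scope, label = paste(study$patient_id, s))
  })
  names(seqs) <- names(study$sequences)
  out <- study
  out$sequences <- seqs
  out$spacing <- sp_out
  out$tumor_mask <- mask
  out$tumor_mask_rater2 <- mask2
  out$habitat_truth <- truth
  out$preprocessed <- TRUE
  out
}

#' Preprocess every study in a cohort
#' @param cohort an `mpmri_cohort`.
#' @param config a [preprocess_config()].
#' @return the cohort with preprocessed studies.
#' @export
preprocess_cohort <- function(cohort, config = preprocess_config()) {
  cohort$studies <- lapply(cohort$studies, preprocess_study, config = config)
  cohort
}
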