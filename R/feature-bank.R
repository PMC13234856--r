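# ---- the radiomics feature bank -------------------------------------------
#
# 14 shape features (original geometry only) plus 93 intensity features
# (18 first-order + 24 GLCM + 14 GLDM + 16 GLRLM + 16 GLSZM + 5 NGTDM) on
# each of 11 images (original, 8 wavelet subbands, 2 LoG scales):
# 14 + 93 * 11 = 1,037 features per (region, sequence).

intensity_family_sizes <- c(firstorder = 18L, glcm = 24L, gldm = 14L,
                            glrlm = 16L, glszm = 16L, ngtdm = 5L)

#' Feature-bank configuration
#'
#' @param families feature families to compute; `"shape"` is geometric and
#'   computed on the original image only.
#' @param filters image filters; `"wavelet"` expands to 8 subbands.
#' @param nbins fixed discretization bin count for texture and first-order
#'   entropy/uniformity (bin count rather than bin width, because inputs
#'   are z-scored).
#' @param min_region_voxels regions below this size yield a missing-flagged
#'   vector instead of values.
#' @return object of class `feature_bank_config`.
#' @export
feature_bank_config <- function(families = c("shape", "firstorder", "glcm",
                                             "gldm", "glrlm", "glszm",
                                             "ngtdm"),
                                filters = c("original", "wavelet",
                                            "log_sigma_3.0", "log_sigma_4.0"),
                                nbins = 32L,
                                min_region_voxels = 10L) {
  families <- match.arg(families, several.ok = TRUE)
  stopifnot(nbins >= 2, "original" %in% filters || length(filters) > 0)
  structure(list(families = families, filters = filters,
                 nbins = as.integer(nbins),
                 min_region_voxels = as.integer(min_region_voxels)),
            class = "feature_bank_config")
}

# expanded filter-image names for a config
filter_image_names <- function(config) {
  out <- character(0)
  if ("original" %in% config$filters) out <- c(out, "original")
  if ("wavelet" %in% config$filters)
    out <- c(out, paste0("wavelet-", c("LLL", "HLL", "LHL", "HHL",
                                       "LLH", "HLH", "LHH", "HHH")))
  for (f in grep("^log_sigma_", config$filters, value = TRUE))
    out <- c(out, sprintf("log-sigma-%g-mm", as.numeric(sub("log_sigma_", "", f))))
  out
}

#' Number of features per (region, sequence) implied by a configuration
#'
#' `shape_count + intensity_count * n_images`: under the default
#' configuration, 14 + 93 * (1 + 8 + 2) = 1,037.
#'
#' @param config a [feature_bank_config()].
#' @return integer count.
#' @export
count_features <- function(config = feature_bank_config()) {
  n_shape <- if ("shape" %in% config$families) 14L else 0L
  fam <- intersect(config$families, names(intensity_family_sizes))
  n_int <- sum(intensity_family_sizes[fam])
  n_img <- length(filter_image_names(config))
  as.integer(n_shape + n_int * n_img)
}

# ordered feature names for one (region, sequence)
region_feature_names <- function(config = feature_bank_config()) {
  nms <- character(0)
  if ("shape" %in% config$families)
    nms <- paste0("original_shape_", shape_names)
  fam_names <- list(firstorder = firstorder_names, glcm = glcm_names,
                    gldm = gldm_names, glrlm = glrlm_names,
                    glszm = glszm_names, ngtdm = ngtdm_names)
  for (img in filter_image_names(config))
    for (f in intersect(config$families, names(fam_names)))
      nms <- c(nms, paste0(img, "_", f, "_", fam_names[[f]]))
  nms
}

#' Extract the full feature vector for one region of one sequence
#'
#' @param filtered named list of filtered images (from [filter_images()]).
#' @param mask_region binary 3D array for the region.
#' @param spacing mm per voxel.
#' @param config a [feature_bank_config()].
#' @return named numeric vector of length `count_features(config)`; if the
#'   region is below `min_region_voxels` every value is NA and the result
#'   carries `attr(, "missing_reason")`.
#' @export
extract_region_features <- function(filtered, mask_region, spacing,
                                    config = feature_bank_config()) {
  nms <- region_feature_names(config)
  nvox <- sum(mask_region > 0)
  if (nvox < config$min_region_voxels) {
    out <- stats::setNames(rep(NA_real_, length(nms)), nms)
    attr(out, "missing_reason") <- sprintf(
      "region has %d voxels (< %d)", nvox, config$min_region_voxels)
    return(out)
  }
  out <- numeric(0)
  if ("shape" %in% config$families)
    out <- stats::setNames(shape_features(mask_region, spacing),
                           paste0("original_shape_", shape_names))
  vv <- prod(rep_len(spacing, 3L))
  fam <- intersect(config$families, names(intensity_family_sizes))
  for (img in filter_image_names(config)) {
    vol <- filtered[[img]]
    if (is.null(vol)) stop("missing filtered image: ", img)
    x <- vol[mask_region > 0]
    binned <- vol
    binned[] <- NA_real_
    binned[mask_region > 0] <- discretize_fixed_bins(x, config$nbins)
    bbox <- region_bbox(binned, mask_region)
    ng <- config$nbins
    for (f in fam) {
      v <- switch(f,
        firstorder = firstorder_features(x, vv, config$nbins),
        glcm = glcm_features(bbox, ng),
        gldm = gldm_features(bbox, ng),
        glrlm = glrlm_features(bbox, ng),
        glszm = glszm_features(bbox, ng),
        ngtdm = ngtdm_features(bbox, ng))
      out <- c(out, stats::setNames(v, paste0(img, "_", f, "_", names(v))))
    }
  }
  stopifnot(identical(names(out), nms))
  out
}

#' Extract conventional, habitat and fusion feature tables for a cohort
#'
#' Column naming follows the sequence/region convention: conventional
#' features are `SEQ_filter_family_feature`, habitat features are
#' `SEQ_habitatH_filter_family_feature`. Widths are
#' `count * 3` (conventional), `count * 3 * K` (habitat) and their sum
#' (fusion). Empty habitats give missing-flagged columns for that patient;
#' the schema is unchanged.
#'
#' @param cohort a preprocessed `mpmri_cohort`.
#' @param habitat_maps named list of `habitat_map` objects (one per
#'   patient), e.g. from [build_habitats()]; NULL extracts the conventional
#'   table only.
#' @param config a [feature_bank_config()].
#' @param masks which rater's masks to use (`"rater1"` or `"rater2"`).
#' @param verbose print progress.
#' @return list of data.frames `conventional`, `habitat`, `fusion` (rows =
#'   patients), each carrying a `pool` attribute.
#' @export
extract_cohort_tables <- function(cohort, habitat_maps = NULL,
                                  config = feature_bank_config(),
                                  masks = c("rater1", "rater2"),
                                  verbose = FALSE) {
  masks <- match.arg(masks)
  K <- if (!is.null(habitat_maps)) habitat_maps[[1]]$K else 0L
  ids <- names(cohort$studies)
  conv_rows <- vector("list", length(ids))
  hab_rows <- if (K > 0) vector("list", length(ids)) else NULL
  for (pi in seq_along(ids)) {
    st <- cohort$studies[[ids[pi]]]
    if (length(st$sequences) != 3L)
      stop("patient ", st$patient_id, " is missing a sequence")
    mask <- if (masks == "rater1") st$tumor_mask else st$tumor_mask_rater2
    conv <- numeric(0); hab <- numeric(0)
    for (s in names(st$sequences)) {
      filtered <- filter_images(st$sequences[[s]], st$spacing, config$filters)
      v <- extract_region_features(filtered, mask, st$spacing, config)
      conv <- c(conv, stats::setNames(v, paste0(s, "_", names(v))))
      if (K > 0) {
        hm <- habitat_maps[[ids[pi]]]
        for (h in seq_len(K)) {
          rmask <- (hm$labels == h) & (mask > 0)
          vh <- extract_region_features(filtered, rmask, st$spacing, config)
          hab <- c(hab, stats::setNames(vh,
                     paste0(s, "_habitat", h, "_", names(vh))))
        }
      }
    }
    conv_rows[[pi]] <- conv
    if (K > 0) hab_rows[[pi]] <- hab
    if (verbose) message("extracted ", ids[pi])
  }
  conv_df <- as.data.frame(do.call(rbind, conv_rows))
  rownames(conv_df) <- ids
  attr(conv_df, "pool") <- "conventional"
  out <- list(conventional = conv_df)
  if (K > 0) {
    hab_df <- as.data.frame(do.call(rbind, hab_rows))
    rownames(hab_df) <- ids
    attr(hab_df, "pool") <- "habitat"
    fus <- cbind(conv_df, hab_df)
    attr(fus, "pool") <- "fusion"
    out$habitat <- hab_df
    out$fusion <- fus
  }
  out
}
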