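# ---- synthetic mpMRI cohort with planted habitat structure ----------------
#
# The generator emulates the study conditions under which the pipeline is
# meant to operate: ~125 breast-cancer patients, 66 ALNM vs 59 non-ALNM,
# three co-registered sequences (T2WI, DWI, DCE) at near-isotropic spacing,
# tumors composed of three spatially contiguous habitats (necrotic core /
# transition zone / vascularised rim), a second-rater perturbed mask for
# ICC, and class-conditional clinical effects (e.g. ALN length 18.4 +/- 11.9
# mm in ALNM vs 5.0 +/- 5.9 mm in non-ALNM; washout TIC enriched in ALNM).

# Class-conditional clinical targets: list(non_alnm =, alnm =) per covariate;
# continuous entries are c(mean, sd), categorical entries are probability
# vectors over the category levels.
default_clinical_effects <- function() {
  list(
    age          = list(non_alnm = c(47.4, 9.9),  alnm = c(50.5, 9.2)),
    tumor_length = list(non_alnm = c(26.6, 9.6),  alnm = c(30.4, 17.7)),
    aln_length   = list(non_alnm = c(5.0, 5.9),   alnm = c(18.4, 11.9)),
    alb_glb      = list(non_alnm = c(1.7, 0.3),   alnm = c(1.6, 0.3)),
    tc           = list(non_alnm = c(4.4, 0.8),   alnm = c(4.8, 1.0)),
    hdl_c        = list(non_alnm = c(1.3, 0.3),   alnm = c(1.3, 0.3)),
    ldl_c        = list(non_alnm = c(2.5, 0.7),   alnm = c(2.8, 0.7)),
    # P(washout)
    tic          = list(non_alnm = 25 / 59,       alnm = 50 / 66),
    # P(4a4b, 4c, 5)
    bi_rads      = list(non_alnm = c(12, 21, 26) / 59, alnm = c(5, 12, 49) / 66),
    # P(G3)
    grade        = list(non_alnm = 24 / 59,       alnm = 52 / 66),
    # P(Ki-67 >= 20%)
    ki67         = list(non_alnm = 37 / 59,       alnm = 52 / 66),
    # P(postmenopausal)
    menopause    = list(non_alnm = 25 / 59,       alnm = 32 / 66),
    # planted imaging signals coupling the ALNM label to tumor biology:
    # volume fraction of habitat 3 (vascularised rim) and the rim's extra
    # DCE enhancement (cases enhance harder, as expected for angiogenic,
    # metastasis-prone tumors)
    habitat3_frac = list(non_alnm = c(0.25, 0.07), alnm = c(0.42, 0.07)),
    rim_enhancement = list(non_alnm = c(-0.15, 0.15), alnm = c(0.15, 0.15))
  )
}

#' Configuration for the synthetic mpMRI cohort generator
#'
#' Defines the study conditions the generator emulates: cohort size and
#' class balance, image grid and spacing, the number of planted habitats and
#' their per-sequence intensity contrasts, class-conditional clinical
#' effects, and the second-rater mask perturbation.
#'
#' @param n_patients number of patients (>= 4).
#' @param aln_frac fraction of ALNM cases in (0, 1).
#' @param grid_shape integer length-3 voxel grid per axis.
#' @param voxel_spacing mm per voxel per axis.
#' @param n_habitats_true number of planted habitats (2..10).
#' @param habitat_intensity_means list with one numeric vector per sequence
#'   (`T2WI`, `DWI`, `DCE`), each of length `n_habitats_true`, giving the
#'   mean intensity of each habitat (habitat 1 = core, last = rim).
#' @param habitat_texture_scales noise correlation length (mm) per habitat.
#' @param noise_sd standard deviation of the voxel noise before spatial
#'   correlation is imposed.
#' @param clinical_effects class-conditional covariate targets; see
#'   `default_clinical_effects` in the source for the layout. Continuous
#'   covariates are `c(mean, sd)` per class, categorical ones are category
#'   probabilities per class.
#' @param rater2_radius_mm morphological perturbation radius for the
#'   second-rater mask.
#' @param rater2_noise_frac fraction of boundary voxels toggled for the
#'   second-rater mask.
#' @param seed RNG seed (integer).
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 125,
                             aln_frac = 66 / 125,
                             grid_shape = c(40L, 40L, 40L),
                             voxel_spacing = c(1, 1, 1),
                             n_habitats_true = 3,
                             habitat_intensity_means = list(
                               T2WI = c(2.5, 0.3, 0.1),
                               DWI  = c(0.3, 2.2, 0.5),
                               DCE  = c(0.2, 0.5, 2.5)),
                             habitat_texture_scales = c(2.5, 1.2, 0.6),
                             noise_sd = 0.2,
                             clinical_effects = default_clinical_effects(),
                             rater2_radius_mm = 1,
                             rater2_noise_frac = 0.15,
                             seed = 1L) {
  stopifnot(n_patients >= 4, aln_frac > 0, aln_frac < 1,
            n_habitats_true >= 2, n_habitats_true <= 10,
            length(grid_shape) == 3, length(voxel_spacing) == 3,
            all(grid_shape >= 12), all(voxel_spacing > 0))
  if (prod(grid_shape - 6) < 200)
    stop("grid_shape cannot admit a tumor of >= 200 voxels")
  for (s in c("T2WI", "DWI", "DCE")) {
    if (length(habitat_intensity_means[[s]]) != n_habitats_true)
      stop("habitat_intensity_means$", s, " must have length n_habitats_true")
  }
  for (cv in names(clinical_effects)) {
    for (cl in c("non_alnm", "alnm")) {
      v <- clinical_effects[[cv]][[cl]]
      if (length(v) == 2 && cv %in% c("age", "tumor_length", "aln_length",
                                      "alb_glb", "tc", "hdl_c", "ldl_c",
                                      "habitat3_frac") && v[2] < 0)
        stop("negative SD for ", cv)
    }
  }
  structure(list(
    n_patients = as.integer(n_patients), aln_frac = aln_frac,
    grid_shape = as.integer(grid_shape), voxel_spacing = as.numeric(voxel_spacing),
    n_habitats_true = as.integer(n_habitats_true),
    habitat_intensity_means = habitat_intensity_means,
    habitat_texture_scales = rep_len(habitat_texture_scales, n_habitats_true),
    noise_sd = noise_sd,
    clinical_effects = clinical_effects,
    rater2_radius_mm = rater2_radius_mm,
    rater2_noise_frac = rater2_noise_frac,
    seed = as.integer(seed)), class = "synthetic_config")
}

# draw one clinical record given the class label
draw_clinical <- function(eff, alnm) {
  cl <- if (alnm) "alnm" else "non_alnm"
  g <- function(v) eff[[v]][[cl]]
  rn <- function(v) stats::rnorm(1, g(v)[1], g(v)[2])
  # gamma moment-matched to (mean, sd): nonnegative support, mean preserved
  rgam <- function(v) {
    m <- g(v)[1]; s <- g(v)[2]
    if (s <= 0) return(m)
    sh <- (m / s)^2
    stats::rgamma(1, shape = sh, scale = s^2 / m)
  }
  list(
    age = rn("age"),
    tumor_length = max(8, rn("tumor_length")),
    aln_length = rgam("aln_length"),
    alb_glb = rn("alb_glb"),
    tc = rn("tc"),
    hdl_c = rn("hdl_c"),
    ldl_c = rn("ldl_c"),
    tic = if (stats::runif(1) < g("tic")) "washout" else "inflow_or_platform",
    bi_rads = sample(c("4a4b", "4c", "5"), 1, prob = g("bi_rads")),
    grade = if (stats::runif(1) < g("grade")) "G3" else "G1_2",
    ki67 = if (stats::runif(1) < g("ki67")) "ge20" else "lt20",
    menopause = as.integer(stats::runif(1) < g("menopause")),
    alnm = as.integer(alnm)
  )
}

# spatially correlated noise field: Gaussian-filtered white noise rescaled
# to unit variance, correlation length in voxels
correlated_noise <- function(dm, corr_vox) {
  w <- array(stats::rnorm(prod(dm)), dm)
  if (all(corr_vox <= 0)) return(w)
  s <- gaussian_smooth(w, pmax(corr_vox, 1e-6))
  sd0 <- stats::sd(as.vector(s))
  if (sd0 < 1e-12) return(w)
  s / sd0
}

# Build one tumor mask + habitat partition on the configured grid.
# Tumor: ellipsoid with a smoothed random boundary; habitats: bands of the
# normalised ellipsoidal radius (concentric core/transition/rim), with the
# band cut-offs chosen so habitat K occupies `rim_frac` of the volume.
make_tumor_geometry <- function(cfg, tumor_length_mm, rim_frac) {
  dm <- cfg$grid_shape; sp <- cfg$voxel_spacing
  K <- cfg$n_habitats_true
  ctr <- (dm + 1) / 2 + stats::runif(3, -1.5, 1.5)
  # semi-axes in voxels; the grid is a tumor-centred crop with generous
  # background margin, so tumor extent is capped at 30% of the grid edge —
  # keeps the whole-volume z-score statistics background-dominated, as in
  # a real breast-MRI field of view
  ax_mm <- tumor_length_mm / 2 * c(1, stats::runif(1, 0.7, 1), stats::runif(1, 0.55, 0.9))
  ax <- pmin(ax_mm / sp, 0.3 * dm)
  ax <- pmax(ax, 3.2)
  # grow undersized tumors so every mask holds >= 200 voxels (plus margin)
  vol_vox <- 4 / 3 * pi * prod(ax)
  if (vol_vox < 280) {
    ax <- pmin(ax * (280 / vol_vox)^(1 / 3), (dm - 5) / 2)
    if (4 / 3 * pi * prod(ax) < 220)
      stop("infeasible geometry: grid too small for a 200-voxel tumor")
  }
  xs <- (seq_len(dm[1]) - ctr[1]) / ax[1]
  ys <- (seq_len(dm[2]) - ctr[2]) / ax[2]
  zs <- (seq_len(dm[3]) - ctr[3]) / ax[3]
  q <- sqrt(outer(outer(xs^2, ys^2, `+`), zs^2, `+`))  # normalised radius
  bump <- correlated_noise(dm, 3 / sp) * 0.12          # smooth boundary jitter
  rho <- q + bump
  mask <- largest_component(rho < 1, 6L)
  if (sum(mask) < 200) {  # noise carved the tumor too small: fall back
    mask <- largest_component(q < 1, 6L)
    rho <- q
  }
  if (sum(mask) < 200) stop("infeasible geometry: tumor below 200 voxels")
  # habitats: bands of a smooth radial + lateral field, so subregions are
  # thick, contiguous sub-lobes (core-to-rim gradient with a lateral tilt)
  # rather than thin concentric shells that supervoxels would straddle
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  tco <- arrayInd(which(mask), dm)
  tvec <- sweep(tco, 2, ctr)
  tproj <- as.vector(tvec %*% (u / max(ax)))
  svals <- 0.6 * rho[mask] + tproj
  cut_hi <- stats::quantile(svals, probs = 1 - rim_frac, names = FALSE)
  inner_q <- seq(0, 1, length.out = K)[-c(1, K)]  # interior band boundaries
  cuts <- c(stats::quantile(svals[svals <= cut_hi], probs = inner_q,
                            names = FALSE), cut_hi)
  hab <- array(0L, dm)
  hab[mask] <- 1L + findInterval(svals, cuts, left.open = TRUE)
  hab[hab > K] <- K
  list(mask = mask, habitat = hab, rho = rho)
}

# render the three sequences for a study given its habitat partition;
# rim_shift adds the patient's class-coupled extra enhancement to the rim
# habitat's DCE mean (and half of it to DWI)
render_sequences <- function(cfg, geo, rim_shift = 0) {
  dm <- cfg$grid_shape; sp <- cfg$voxel_spacing; K <- cfg$n_habitats_true
  seqs <- list()
  for (s in c("T2WI", "DWI", "DCE")) {
    vol <- array(0, dm)
    mus <- cfg$habitat_intensity_means[[s]]
    if (s == "DCE") mus[K] <- mus[K] + rim_shift
    if (s == "DWI") mus[K] <- mus[K] + 0.5 * rim_shift
    for (h in seq_len(K)) {
      sel <- geo$habitat == h
      if (!any(sel)) next
      nz <- correlated_noise(dm, cfg$habitat_texture_scales[h] / sp)
      vol[sel] <- mus[h] + cfg$noise_sd * nz[sel]
    }
    # parenchyma-like background: appreciable signal and spatial variance,
    # so the whole-volume z-score scale does not hinge on tumor fraction
    bg <- 0.4 + 0.35 * correlated_noise(dm, 3 / sp) +
          0.1 * stats::rnorm(prod(dm))
    vol[!geo$mask] <- bg[!geo$mask]
    seqs[[s]] <- vol
  }
  seqs
}

#' Perturb a tumor mask to emulate a second rater's delineation
#'
#' A random systematic bias (toward over- or under-segmentation) toggles
#' each voxel of the radius-`radius_mm` morphological shell with
#' probability one half — a partial-volume style disagreement that keeps
#' the Dice overlap high — then a fraction of boundary voxels is toggled as
#' unstructured noise, and the largest connected component is kept.
#' Identity when both `radius_mm` and `noise_frac` are zero.
#'
#' @param mask logical/binary 3D array with at least one foreground voxel.
#' @param spacing mm per voxel (length 3).
#' @param radius_mm morphological radius in mm.
#' @param noise_frac fraction of boundary voxels to toggle.
#' @param seed RNG seed.
#' @return logical 3D array (non-empty, connected).
#' @export
perturb_mask <- function(mask, spacing = c(1, 1, 1), radius_mm = 1,
                         noise_frac = 0.15, seed = 1L) {
  stopifnot_vol(mask)
  m <- mask > 0
  if (!any(m)) stop("mask is empty")
  if (radius_mm == 0 && noise_frac == 0) return(m)
  set.seed(as.integer(seed))
  r_vox <- radius_mm / rep_len(spacing, 3L)
  out <- m
  if (radius_mm > 0) {
    if (stats::runif(1) < 0.5) {
      shell <- which(dilate_mask(m, r_vox) & !m)      # over-segmentation bias
      add <- shell[stats::runif(length(shell)) < 0.5]
      out[add] <- TRUE
    } else {
      shell <- which(m & !erode_mask(m, r_vox))       # under-segmentation bias
      drop <- shell[stats::runif(length(shell)) < 0.5]
      out[drop] <- FALSE
    }
    if (!any(out)) out <- m  # never let the bias empty a thin mask
  }
  if (noise_frac > 0) {
    inner_b <- out & !erode_mask(out, 1)          # boundary shell (inside)
    outer_b <- dilate_mask(out, 1) & !out         # boundary shell (outside)
    bidx <- c(which(inner_b), which(outer_b))
    ntog <- round(noise_frac * length(bidx))
    if (ntog > 0) {
      tog <- sample(bidx, ntog)
      out[tog] <- !out[tog]
    }
  }
  out <- largest_component(out, 26L)
  if (!any(out & m)) stop("perturbation emptied the mask")
  out
}

#' Generate one synthetic mpMRI study
#' @keywords internal
generate_study <- function(cfg, patient_id, alnm, seed) {
  set.seed(seed)
  clin <- draw_clinical(cfg$clinical_effects, alnm)
  h3 <- cfg$clinical_effects$habitat3_frac[[if (alnm) "alnm" else "non_alnm"]]
  rim_frac <- min(max(stats::rnorm(1, h3[1], h3[2]), 0.08), 0.75)
  re <- cfg$clinical_effects$rim_enhancement[[if (alnm) "alnm" else "non_alnm"]]
  rim_shift <- if (is.null(re)) 0 else stats::rnorm(1, re[1], re[2])
  geo <- make_tumor_geometry(cfg, clin$tumor_length, rim_frac)
  seqs <- render_sequences(cfg, geo, rim_shift)
  mask2 <- perturb_mask(geo$mask, cfg$voxel_spacing, cfg$rater2_radius_mm,
                        cfg$rater2_noise_frac, seed = child_seed(seed, "rater2"))
  structure(list(
    patient_id = patient_id,
    sequences = seqs,
    spacing = cfg$voxel_spacing,
    tumor_mask = geo$mask,
    tumor_mask_rater2 = mask2,
    habitat_truth = geo$habitat,
    clinical = clin), class = "mpmri_study")
}

#' Generate a reproducible synthetic mpMRI cohort
#'
#' Labels are drawn first (`round(n_patients * aln_frac)` ALNM cases), then
#' clinical covariates and the planted imaging signal (the volume fraction
#' of the high-enhancement rim habitat) are drawn conditionally on class, so
#' the ALNM label correlates with both ALN length and habitat composition.
#' The whole cohort is a pure function of the configuration (seed included).
#'
#' @param config a [synthetic_config()].
#' @return object of class `mpmri_cohort`: list with `studies` (list of
#'   `mpmri_study`), `clinical` (data.frame, one row per patient) and
#'   `config`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  n_case <- round(cfg$n_patients * cfg$aln_frac)
  labels <- c(rep(1L, n_case), rep(0L, cfg$n_patients - n_case))
  studies <- vector("list", cfg$n_patients)
  ids <- sprintf("P%03d", seq_len(cfg$n_patients))
  for (i in seq_len(cfg$n_patients)) {
    studies[[i]] <- generate_study(cfg, ids[i], labels[i] == 1L,
                                   seed = child_seed(cfg$seed, paste0("pt", i)))
  }
  clin <- do.call(rbind, lapply(studies, function(s)
    as.data.frame(s$clinical, stringsAsFactors = FALSE)))
  clin <- cbind(patient_id = ids, clin)
  rownames(clin) <- ids
  structure(list(studies = stats::setNames(studies, ids),
                 clinical = clin, config = cfg),
            class = "mpmri_cohort")
}

#' @export
print.mpmri_cohort <- function(x, ...) {
  cat("Synthetic mpMRI cohort:", length(x$studies), "patients (",
      sum(x$clinical$alnm), "ALNM /", sum(1 - x$clinical$alnm), "non-ALNM )\n")
  cat("  grid:", paste(x$config$grid_shape, collapse = "x"),
      " spacing:", paste(x$config$voxel_spacing, collapse = "x"), "mm\n")
  cat("  planted habitats:", x$config$n_habitats_true, "\n")
  invisible(x)
}

#' Stratified train/test split of a cohort
#'
#' Train size is `floor(train_frac * n)`; per-class train counts are
#' `floor(train_frac * n_class)` topped up by largest fractional remainder
#' (RNG-tie-broken) until the total is reached, so class proportions stay
#' within one patient of exact.
#'
#' @param labels binary outcome vector (or an `mpmri_cohort`).
#' @param train_frac fraction of patients assigned to training.
#' @param seed RNG seed.
#' @return character vector `"train"`/`"test"`, named by patient id when
#'   available.
#' @export
split_cohort <- function(labels, train_frac = 0.7, seed = 1L) {
  if (inherits(labels, "mpmri_cohort")) {
    ids <- labels$clinical$patient_id
    labels <- labels$clinical$alnm
  } else ids <- names(labels)
  labels <- as.integer(labels)
  n <- length(labels)
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab < 2)) stop("need >= 2 patients per class to stratify")
  n_train <- floor(train_frac * n)
  set.seed(as.integer(seed))
  per_cl <- floor(train_frac * as.numeric(tab))
  rem <- train_frac * as.numeric(tab) - per_cl
  short <- n_train - sum(per_cl)
  if (short > 0) {
    ord <- order(rem + stats::runif(2) * 1e-9, decreasing = TRUE)
    per_cl[ord[seq_len(short)]] <- per_cl[ord[seq_len(short)]] + 1
  }
  split <- rep("test", n)
  for (cl in 0:1) {
    idx <- which(labels == cl)
    take <- sample(idx, per_cl[cl + 1])
    split[take] <- "train"
  }
  # both classes must be present in both splits
  for (s in c("train", "test"))
    if (length(unique(labels[split == s])) < 2)
      stop("degenerate split: a class is absent from the ", s, " set")
  if (!is.null(ids)) names(split) <- ids
  split
}

#' Write a cohort to disk (NIfTI volumes + clinical CSV + JSON manifest)
#'
#' @param cohort an `mpmri_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mpmri_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (st in cohort$studies) {
    pd <- file.path(dir, st$patient_id)
    dir.create(pd, showWarnings = FALSE)
    wr <- function(arr, name) {
      img <- RNifti::asNifti(arr * 1, reference = NULL)
      RNifti::pixdim(img) <- st$spacing
      RNifti::writeNifti(img, file.path(pd, paste0(name, ".nii.gz")))
    }
    for (s in names(st$sequences)) wr(st$sequences[[s]], s)
    wr(st$tumor_mask, "mask")
    wr(st$tumor_mask_rater2, "mask_rater2")
    wr(st$habitat_truth, "habitat_truth")
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  cfg_json <- cfg[setdiff(names(cfg), "clinical_effects")]
  jsonlite::write_json(list(config = cfg_json,
                            n_patients = length(cohort$studies)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
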