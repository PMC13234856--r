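# ---- extract-then-pool habitat generation ---------------------------------
#
# Voxel-level local features in a fixed sliding window -> SLIC supervoxels
# -> mean pooling within supervoxel boundaries -> one population K-means
# over pooled vectors from all training patients, K in 2..10 selected by
# the mean silhouette coefficient -> per-patient habitat label maps by
# nearest centroid. Clusters are ordered by ascending mean DCE intensity so
# habitat 1 reads as the low-enhancement core and habitat K as the
# vascularised rim, consistently across patients.

local_feature_names <- function(seq_names) {
  feats <- c("mean", "sd", "skewness", "kurtosis", "entropy", "energy")
  as.vector(t(outer(seq_names, feats, paste, sep = "_")))
}

#' Voxel-level sliding-window feature maps over the tumor ROI
#'
#' For every tumor voxel, local first-order statistics (mean, SD, skewness,
#' kurtosis, entropy, energy) of each sequence are computed over the cubic
#' window intersected with the tumor mask. Entropy uses an 8-bin histogram
#' with bin edges fixed per sequence over the whole tumor; energy is the
#' mean of squared intensities. Degenerate windows (SD ~ 0) get skewness
#' and kurtosis 0.
#'
#' @param study a preprocessed `mpmri_study`.
#' @param window odd cubic window edge in voxels (>= 3).
#' @return object of class `voxel_feature_map`: list with `features`
#'   (n_tumor_voxels x n_channels matrix), `voxels` (linear indices),
#'   `mask`, `dim`, `spacing`.
#' @export
voxel_feature_maps <- function(study, window = 3L) {
  stopifnot(inherits(study, "mpmri_study"))
  if (window %% 2 == 0 || window < 3) stop("window must be odd and >= 3")
  dm <- dim(study$tumor_mask)
  if (any(window > dm)) stop("window larger than the volume")
  mask <- study$tumor_mask > 0
  r <- (window - 1L) / 2L
  offs <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  vox <- which(mask)
  nb_bins <- 8L
  chans <- list()
  for (s in names(study$sequences)) {
    v <- study$sequences[[s]]
    vm <- v; vm[!mask] <- NA_real_
    # accumulate masked window sums via shifts
    n <- s1 <- s2 <- s3 <- s4 <- array(0, dm)
    tv <- v[mask]
    edges <- seq(min(tv), max(tv), length.out = nb_bins + 1)
    binv <- array(pmin(pmax(findInterval(vm, edges, all.inside = TRUE), 1L),
                       nb_bins), dm)
    binv[!mask] <- NA_integer_
    hist_cnt <- array(0, c(dm, nb_bins))
    for (o in seq_len(nrow(offs))) {
      sh <- shift_array(vm, offs[o, ])
      ok <- !is.na(sh)
      n <- n + ok
      sh[!ok] <- 0
      s1 <- s1 + sh; s2 <- s2 + sh^2; s3 <- s3 + sh^3; s4 <- s4 + sh^4
      bh <- shift_array(binv * 1, offs[o, ])
      for (b in seq_len(nb_bins))
        hist_cnt[, , , b] <- hist_cnt[, , , b] + (!is.na(bh) & bh == b)
    }
    n[n == 0] <- NA
    mu <- s1 / n
    m2 <- s2 / n - mu^2
    m2 <- pmax(m2, 0)
    sdv <- sqrt(m2)
    m3 <- s3 / n - 3 * mu * s2 / n + 2 * mu^3
    m4 <- s4 / n - 4 * mu * s3 / n + 6 * mu^2 * s2 / n - 3 * mu^4
    sk <- ifelse(sdv > 1e-8, m3 / sdv^3, 0)
    ku <- ifelse(sdv > 1e-8, m4 / m2^2, 0)
    ent <- array(0, dm)
    for (b in seq_len(nb_bins)) {
      p <- hist_cnt[, , , b] / n
      ent <- ent - ifelse(!is.na(p) & p > 0, p * log2(p), 0)
    }
    en <- s2 / n
    chans[[paste0(s, "_mean")]] <- mu[vox]
    chans[[paste0(s, "_sd")]] <- sdv[vox]
    chans[[paste0(s, "_skewness")]] <- sk[vox]
    chans[[paste0(s, "_kurtosis")]] <- ku[vox]
    chans[[paste0(s, "_entropy")]] <- ent[vox]
    chans[[paste0(s, "_energy")]] <- en[vox]
  }
  feat <- do.call(cbind, chans)
  rownames(feat) <- NULL
  structure(list(features = feat, voxels = vox, mask = mask,
                 dim = dm, spacing = study$spacing, window = window,
                 patient_id = study$patient_id),
            class = "voxel_feature_map")
}

#' SLIC supervoxels over the tumor mask
#'
#' Mask-constrained SLIC: seeds are placed on a regular physical grid with
#' spacing `S = (tumor_volume / n_supervoxels)^(1/3)` (snapped to the
#' nearest tumor voxel), then iteratively assigned by the combined distance
#' `sqrt(d_feat^2 + compactness^2 * (d_spatial/S)^2)` within a 2S search
#' box, with centre updates. Connectivity is enforced afterwards: each
#' label's disconnected fragments are merged into the neighbouring
#' supervoxel with the largest contact area. Deterministic (no RNG).
#'
#' @param vfm a [voxel_feature_maps()] result.
#' @param n_supervoxels requested number of supervoxels (actual count may
#'   differ by up to ~50%, the usual SLIC behaviour).
#' @param compactness spatial regularity weight.
#' @param iterations assignment/update sweeps.
#' @param channels feature channels entering the SLIC distance (default:
#'   the local mean channels; higher-moment channels of a small window are
#'   noise-dominated and would distort the geometry). Pooled vectors always
#'   cover every channel.
#' @return object of class `supervoxel_set`: `labels` (integer array, 0
#'   outside tumor), `pooled` (n_sv x n_channels mean-pooled matrix),
#'   `sizes`, `centers_mm`.
#' @export
slic_supervoxels <- function(vfm, n_supervoxels = NULL, compactness = 0.1,
                             iterations = 10L, channels = NULL) {
  stopifnot(inherits(vfm, "voxel_feature_map"))
  vox <- vfm$voxels
  nv <- length(vox)
  sp <- vfm$spacing
  vol_mm3 <- nv * prod(sp)
  if (is.null(n_supervoxels))  # ~1 supervoxel / 100 mm^3, floor of 12 so
    n_supervoxels <- max(12L, round(vol_mm3 / 100))  # small tumors stay divisible
  if (nv < n_supervoxels) stop("mask smaller than requested supervoxel count")
  co <- arrayInd(vox, vfm$dim)
  xyz <- sweep(co, 2, sp, `*`)  # physical coordinates, mm
  # channels are already on comparable (z-scored intensity) scales; no
  # per-channel re-standardization here, or flat-region noise would be
  # amplified to unit variance and drown the spatial term
  f <- vfm$features
  if (is.null(channels))
    channels <- grep("_mean$", colnames(f), value = TRUE)
  if (!length(channels)) channels <- colnames(f)
  fz <- f[, channels, drop = FALSE]
  if (n_supervoxels == 1L) {
    labels <- array(0L, vfm$dim); labels[vox] <- 1L
    pooled <- matrix(colMeans(f), 1, dimnames = list(NULL, colnames(f)))
    return(structure(list(labels = labels, pooled = pooled,
                          sizes = nv, centers_mm = matrix(colMeans(xyz), 1),
                          feature_names = colnames(f), window = vfm$window),
                     class = "supervoxel_set"))
  }
  S <- (vol_mm3 / n_supervoxels)^(1 / 3)
  # seed grid in physical space, snapped to nearest tumor voxel
  rng <- apply(xyz, 2, range)
  grid_pts <- expand.grid(
    x = seq(rng[1, 1] + S / 2, rng[2, 1], by = S),
    y = seq(rng[1, 2] + S / 2, rng[2, 2], by = S),
    z = seq(rng[1, 3] + S / 2, rng[2, 3], by = S))
  seeds <- integer(0)
  for (g in seq_len(nrow(grid_pts))) {
    d2 <- (xyz[, 1] - grid_pts[g, 1])^2 + (xyz[, 2] - grid_pts[g, 2])^2 +
          (xyz[, 3] - grid_pts[g, 3])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) <= S) seeds <- c(seeds, j)
  }
  seeds <- unique(seeds)
  if (length(seeds) < 2) {  # tiny/flat masks: fall back to spread seeds
    seeds <- unique(round(seq(1, nv, length.out = min(n_supervoxels, nv))))
  }
  k <- length(seeds)
  cf <- fz[seeds, , drop = FALSE]       # cluster feature centres
  cx <- xyz[seeds, , drop = FALSE]      # cluster spatial centres
  assign <- integer(nv)
  for (it in seq_len(iterations)) {
    best_d <- rep(Inf, nv)
    assign_new <- assign
    for (c in seq_len(k)) {
      in_box <- abs(xyz[, 1] - cx[c, 1]) <= 2 * S &
                abs(xyz[, 2] - cx[c, 2]) <= 2 * S &
                abs(xyz[, 3] - cx[c, 3]) <= 2 * S
      idx <- which(in_box)
      if (!length(idx)) next
      # feature term is the mean squared channel difference so the
      # compactness weight is channel-count invariant
      df2 <- rowSums((fz[idx, , drop = FALSE] -
                      matrix(cf[c, ], length(idx), ncol(fz), byrow = TRUE))^2) /
             ncol(fz)
      ds2 <- ((xyz[idx, 1] - cx[c, 1])^2 + (xyz[idx, 2] - cx[c, 2])^2 +
              (xyz[idx, 3] - cx[c, 3])^2) / S^2
      d <- df2 + compactness * ds2
      upd <- d < best_d[idx]
      best_d[idx[upd]] <- d[upd]
      assign_new[idx[upd]] <- c
    }
    # orphans (outside every search box): nearest centre globally
    orph <- which(assign_new == 0L)
    for (j in orph) {
      d <- rowSums((cf - matrix(fz[j, ], k, ncol(fz), byrow = TRUE))^2) /
        ncol(fz) +
        compactness * ((cx[, 1] - xyz[j, 1])^2 + (cx[, 2] - xyz[j, 2])^2 +
                       (cx[, 3] - xyz[j, 3])^2) / S^2
      assign_new[j] <- which.min(d)
    }
    if (it > 1 && all(assign_new == assign)) { assign <- assign_new; break }
    assign <- assign_new
    for (c in seq_len(k)) {
      mem <- assign == c
      if (any(mem)) {
        cf[c, ] <- colMeans(fz[mem, , drop = FALSE])
        cx[c, ] <- colMeans(xyz[mem, , drop = FALSE])
      }
    }
  }
  lab_arr <- array(0L, vfm$dim)
  lab_arr[vox] <- assign
  lab_arr <- enforce_connectivity(lab_arr, vfm$mask,
                                  min_size = max(2L, round(S^3 / prod(sp) / 8)))
  assign <- lab_arr[vox]
  ids <- sort(unique(assign))
  assign <- match(assign, ids)          # compact 1..n_sv
  lab_arr[vox] <- assign
  n_sv <- length(ids)
  pooled <- matrix(0, n_sv, ncol(f), dimnames = list(NULL, colnames(f)))
  sizes <- integer(n_sv)
  centers <- matrix(0, n_sv, 3)
  for (c in seq_len(n_sv)) {
    mem <- assign == c
    pooled[c, ] <- colMeans(f[mem, , drop = FALSE])
    sizes[c] <- sum(mem)
    centers[c, ] <- colMeans(xyz[mem, , drop = FALSE])
  }
  structure(list(labels = lab_arr, pooled = pooled, sizes = sizes,
                 centers_mm = centers, feature_names = colnames(f),
                 window = vfm$window),
            class = "supervoxel_set")
}

# split disconnected label fragments into their own components, then merge
# every component smaller than min_size into the touching component with
# the largest 6-neighbour contact (the usual SLIC post-processing)
enforce_connectivity <- function(lab_arr, mask, min_size = 2L) {
  dm <- dim(lab_arr)
  comp_all <- array(0L, dm)
  nxt <- 0L
  for (l in sort(unique(lab_arr[mask]))) {
    comp <- label_components(lab_arr == l, 6L)
    nc <- max(comp)
    comp_all[comp > 0] <- comp[comp > 0] + nxt
    nxt <- nxt + nc
  }
  offs <- neighbor_offsets(6L)
  neighbor_labels <- function(sel) {
    cc <- arrayInd(sel, dm)
    nb <- integer(0)
    for (o in seq_len(nrow(offs))) {
      cand <- cc + matrix(offs[o, ], nrow(cc), 3, byrow = TRUE)
      ok <- cand[, 1] >= 1 & cand[, 1] <= dm[1] &
            cand[, 2] >= 1 & cand[, 2] <= dm[2] &
            cand[, 3] >= 1 & cand[, 3] <= dm[3]
      ci <- cand[ok, 1] + (cand[ok, 2] - 1L) * dm[1] +
            (cand[ok, 3] - 1L) * dm[1] * dm[2]
      v <- comp_all[ci]
      nb <- c(nb, v[v > 0])
    }
    nb
  }
  repeat {
    szs <- table(comp_all[mask])
    small <- as.integer(names(szs))[as.numeric(szs) < min_size]
    if (!length(small) || length(szs) <= 1) break
    changed <- FALSE
    # merge smallest first
    small <- small[order(szs[as.character(small)])]
    for (l in small) {
      sel <- which(comp_all == l)
      if (!length(sel)) next
      nb <- neighbor_labels(sel)
      nb <- nb[nb != l]
      if (length(nb)) {
        tb <- table(nb)
        comp_all[sel] <- as.integer(names(tb))[which.max(tb)]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp_all
}

#' Mean silhouette coefficient of a clustering
#'
#' Textbook definition: for point i with within-cluster mean distance a(i)
#' and smallest other-cluster mean distance b(i), s(i) =
#' (b(i) - a(i)) / max(a(i), b(i)); singleton clusters get s(i) = 0.
#'
#' @param x numeric matrix (points x features).
#' @param labels integer cluster labels.
#' @return mean silhouette width.
#' @export
silhouette_mean <- function(x, labels) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  cl <- unique(labels)
  if (length(cl) < 2) stop("silhouette needs >= 2 clusters")
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- sum(d[i, own]) / (sum(own) - 1)
    b <- min(vapply(cl[cl != labels[i]], function(c2)
      mean(d[i, labels == c2]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Fit the population habitat model on pooled training supervoxels
#'
#' Pools supervoxel feature vectors from all training patients, standardizes
#' the channels, and runs K-means (k-means++-style multiple restarts via
#' `nstart`) for each K in `k_range`, selecting the K with the highest mean
#' silhouette (ties toward smaller K). Clusters are then ordered by
#' ascending mean of the `DCE_mean` channel (raw scale), so habitat 1 is the
#' least-enhancing subregion.
#'
#' @param pooled matrix of pooled supervoxel features from all training
#'   patients (rows), or a list of `supervoxel_set` objects.
#' @param k_range candidate cluster counts (default 2:10).
#' @param nstart K-means restarts.
#' @param seed RNG seed.
#' @param channels columns used for clustering. The default — the local
#'   mean channels — reflects that higher-moment statistics of a 3-cubed
#'   window are noise-dominated and destabilize silhouette model selection;
#'   all pooled channels remain available here.
#' @return object of class `habitat_model`.
#' @export
fit_habitat_model <- function(pooled, k_range = 2:10, nstart = 10L, seed = 1L,
                              channels = NULL) {
  if (is.list(pooled) && !is.matrix(pooled))
    pooled <- do.call(rbind, lapply(pooled, function(s) s$pooled))
  stopifnot(is.matrix(pooled))
  if (is.null(channels))
    channels <- grep("_mean$", colnames(pooled), value = TRUE)
  if (!length(channels)) channels <- colnames(pooled)
  stopifnot(all(channels %in% colnames(pooled)))
  pooled <- pooled[, channels, drop = FALSE]
  if (any(!is.finite(pooled))) stop("non-finite pooled features")
  n <- nrow(pooled)
  if (n < 11) {
    k_range <- k_range[k_range < n]
    if (!length(k_range)) stop("too few supervoxels to cluster")
    warning("fewer supervoxels than max(k_range); shrunk to ",
            paste(range(k_range), collapse = ":"))
  } else k_range <- k_range[k_range < n]
  mu <- colMeans(pooled)
  sdv <- apply(pooled, 2, stats::sd)
  if (all(sdv < 1e-12)) stop("zero variance: all supervoxels identical")
  sdv[sdv < 1e-12] <- 1
  z <- sweep(sweep(pooled, 2, mu), 2, sdv, `/`)
  sil <- stats::setNames(numeric(length(k_range)), k_range)
  fits <- vector("list", length(k_range))
  for (j in seq_along(k_range)) {
    set.seed(child_seed(seed, paste0("kmeans", k_range[j])))
    km <- stats::kmeans(z, centers = k_range[j], nstart = nstart,
                        iter.max = 100)
    fits[[j]] <- km
    sil[j] <- silhouette_mean(z, km$cluster)
  }
  best <- which(sil >= max(sil) - 1e-12)[1]  # ties toward smaller k
  km <- fits[[best]]
  K <- k_range[best]
  # order clusters by ascending mean DCE intensity (raw scale)
  dce_col <- grep("^DCE_mean$", colnames(pooled))
  ord_stat <- if (length(dce_col) == 1) {
    vapply(seq_len(K), function(c)
      mean(pooled[km$cluster == c, dce_col]), numeric(1))
  } else km$centers[, 1]  # fall back to first channel
  perm <- order(ord_stat)
  centroids <- km$centers[perm, , drop = FALSE]
  rownames(centroids) <- paste0("habitat", seq_len(K))
  structure(list(K = K, centroids = centroids,
                 silhouette_by_k = sil,
                 scaling = list(mean = mu, sd = sdv),
                 ordering_rule = "ascending mean DCE intensity",
                 ordering_stat = sort(ord_stat),
                 feature_names = colnames(pooled)),
            class = "habitat_model")
}

#' @export
print.habitat_model <- function(x, ...) {
  cat("Habitat model: K =", x$K, "clusters over",
      length(x$feature_names), "pooled channels\n")
  cat("  silhouette by k:\n")
  print(round(x$silhouette_by_k, 3))
  cat("  ordering:", x$ordering_rule, "\n")
  invisible(x)
}

#' Assign habitat labels to a study's supervoxels by nearest centroid
#'
#' @param svs a `supervoxel_set` for the study (same window/features as the
#'   training pooling).
#' @param model a `habitat_model`.
#' @return object of class `habitat_map`: `labels` (integer array with
#'   values 1..K on tumor voxels), `counts` (voxels per habitat, empty
#'   habitats recorded as 0), `sv_habitat` (habitat per supervoxel).
#' @export
assign_habitats <- function(svs, model) {
  stopifnot(inherits(svs, "supervoxel_set"), inherits(model, "habitat_model"))
  if (!all(model$feature_names %in% colnames(svs$pooled)))
    stop("feature-dimension mismatch between supervoxels and habitat model")
  pooled <- svs$pooled[, model$feature_names, drop = FALSE]
  z <- sweep(sweep(pooled, 2, model$scaling$mean), 2, model$scaling$sd, `/`)
  K <- model$K
  d2 <- vapply(seq_len(K), function(c)
    rowSums((z - matrix(model$centroids[c, ], nrow(z), ncol(z), byrow = TRUE))^2),
    numeric(nrow(z)))
  d2 <- matrix(d2, nrow = nrow(z))
  sv_hab <- max.col(-d2, ties.method = "first")
  lab <- svs$labels
  lab[lab > 0] <- sv_hab[lab[lab > 0]]
  counts <- vapply(seq_len(K), function(h) sum(lab == h), integer(1))
  structure(list(labels = lab, counts = stats::setNames(counts,
                 paste0("habitat", seq_len(K))), sv_habitat = sv_hab, K = K),
            class = "habitat_map")
}

#' Build supervoxels and habitat maps for every study in a cohort
#'
#' Convenience wrapper: computes voxel feature maps and SLIC supervoxels per
#' study, fits the population habitat model on the training patients'
#' pooled vectors, and assigns habitats to everyone.
#'
#' @param cohort a preprocessed `mpmri_cohort`.
#' @param split named train/test assignment from [split_cohort()].
#' @param window sliding-window edge (voxels).
#' @param n_supervoxels per-study supervoxel target (NULL = ~1 / 100 mm^3).
#' @param compactness SLIC compactness.
#' @param k_range candidate habitat counts.
#' @param seed RNG seed.
#' @return list with `model` (`habitat_model`), `maps` (named list of
#'   `habitat_map`), `supervoxels` (named list of `supervoxel_set`).
#' @export
build_habitats <- function(cohort, split, window = 3L, n_supervoxels = NULL,
                           compactness = 0.1, k_range = 2:10, seed = 1L) {
  svs <- lapply(cohort$studies, function(st)
    slic_supervoxels(voxel_feature_maps(st, window), n_supervoxels,
                     compactness))
  train_ids <- names(split)[split == "train"]
  pooled <- do.call(rbind, lapply(svs[train_ids], function(s) s$pooled))
  model <- fit_habitat_model(pooled, k_range = k_range, seed = seed)
  maps <- lapply(svs, assign_habitats, model = model)
  list(model = model, maps = maps, supervoxels = svs)
}
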