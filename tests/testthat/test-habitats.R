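# extract-then-pool habitat generation: voxel feature maps, SLIC
# supervoxels, mean pooling, silhouette-selected K-means, assignment

make_study <- function(vols, mask, spacing = c(1, 1, 1)) {
  structure(list(patient_id = "T", sequences = vols, spacing = spacing,
                 tumor_mask = mask, tumor_mask_rater2 = mask,
                 clinical = list(), preprocessed = TRUE),
            class = "mpmri_study")
}

test_that("voxel feature maps match brute-force windowed statistics", {
  dm <- c(7L, 7L, 7L)
  set.seed(3)
  v <- array(stats::rnorm(prod(dm)), dm)
  mask <- array(FALSE, dm); mask[2:6, 2:6, 2:6] <- TRUE
  st <- make_study(list(T2WI = v, DWI = v, DCE = v), mask)
  vfm <- voxel_feature_maps(st, 3L)
  co <- arrayInd(vfm$voxels, dm)
  for (r in c(1, 20, 60)) {
    p <- co[r, ]
    win <- expand.grid(x = (p[1] - 1):(p[1] + 1), y = (p[2] - 1):(p[2] + 1),
                       z = (p[3] - 1):(p[3] + 1))
    keep <- win[mask[as.matrix(win)], , drop = FALSE]
    vals <- v[as.matrix(keep)]
    expect_equal(unname(vfm$features[r, "T2WI_mean"]), mean(vals), tolerance = 1e-9)
    m2 <- mean((vals - mean(vals))^2)
    expect_equal(unname(vfm$features[r, "T2WI_sd"]), sqrt(m2), tolerance = 1e-8)
    expect_equal(unname(vfm$features[r, "T2WI_skewness"]),
                 mean((vals - mean(vals))^3) / m2^1.5, tolerance = 1e-7)
    expect_equal(unname(vfm$features[r, "T2WI_energy"]), mean(vals^2), tolerance = 1e-8)
  }
})

test_that("constant image gives constant mean channel and zero SD channel", {
  dm <- c(6L, 6L, 6L)
  mask <- array(TRUE, dm)
  st <- make_study(list(T2WI = array(2.5, dm), DWI = array(0, dm),
                        DCE = array(-1, dm)), mask)
  vfm <- voxel_feature_maps(st, 3L)
  expect_true(all(abs(vfm$features[, "T2WI_mean"] - 2.5) < 1e-12))
  expect_true(all(abs(vfm$features[, "T2WI_sd"]) < 1e-12))
  expect_true(all(abs(vfm$features[, "T2WI_skewness"]) < 1e-12))
  expect_error(voxel_feature_maps(st, 4L), "odd")
  expect_error(voxel_feature_maps(st, 7L + 2L), "larger")
})

test_that("local entropy peaks at a two-valued interface", {
  dm <- c(9L, 9L, 9L)
  v <- array(0, dm); v[6:9, , ] <- 1
  mask <- array(TRUE, dm)
  st <- make_study(list(T2WI = v, DWI = v, DCE = v), mask)
  vfm <- voxel_feature_maps(st, 3L)
  co <- arrayInd(vfm$voxels, dm)
  ent <- vfm$features[, "T2WI_entropy"]
  # windows wholly inside one side have entropy 0; interface windows > 0
  expect_true(all(ent[co[, 1] <= 3] < 1e-12))
  expect_true(all(ent[co[, 1] >= 8] < 1e-12))
  iface <- ent[co[, 1] %in% 5:6]
  expect_true(all(iface > 0.8))   # near-balanced two-bin window: ~1 bit
  expect_equal(max(ent), max(iface))
})

test_that("SLIC covers the mask with connected, non-overlapping supervoxels", {
  dm <- c(16L, 16L, 16L)
  co <- arrayInd(seq_len(prod(dm)), dm)
  mask <- array(sqrt(rowSums(sweep(co, 2, c(8.5, 8.5, 8.5))^2)) < 6.5, dm)
  set.seed(1)
  v <- array(stats::rnorm(prod(dm), 0, 0.05), dm)
  st <- make_study(list(T2WI = v, DWI = v, DCE = v), mask)
  vfm <- voxel_feature_maps(st, 3L)
  sv <- slic_supervoxels(vfm, n_supervoxels = 8)
  expect_true(all((sv$labels > 0) == mask))      # exact cover
  n_sv <- nrow(sv$pooled)
  expect_gte(n_sv, 4); expect_lte(n_sv, 12)      # within ~50% of request
  for (c in seq_len(n_sv))
    expect_equal(max(habitatr:::label_components(sv$labels == c, 6L)), 1L)
  # homogeneous sphere: volumes within 3x of each other
  expect_lte(max(sv$sizes) / min(sv$sizes), 3)
  # pooling linearity: pooled vector equals mean of member voxel vectors
  lab_v <- sv$labels[vfm$voxels]
  for (c in c(1L, n_sv)) {
    expect_equal(sv$pooled[c, ],
                 colMeans(vfm$features[lab_v == c, , drop = FALSE]),
                 tolerance = 1e-12)
  }
  # single supervoxel: whole tumor, pooled = tumor-wide mean
  sv1 <- slic_supervoxels(vfm, n_supervoxels = 1)
  expect_equal(nrow(sv1$pooled), 1L)
  expect_equal(sv1$pooled[1, ], colMeans(vfm$features), tolerance = 1e-12)
  expect_error(slic_supervoxels(vfm, n_supervoxels = sum(mask) + 1), "mask")
})

test_that("supervoxels respect a sharp two-lobe intensity boundary", {
  dm <- c(14L, 14L, 14L)
  mask <- array(FALSE, dm); mask[3:12, 3:12, 3:12] <- TRUE
  v <- array(0, dm); v[8:14, , ] <- 4   # two lobes, strong contrast
  st <- make_study(list(T2WI = v, DWI = v, DCE = v), mask)
  vfm <- voxel_feature_maps(st, 3L)
  sv <- slic_supervoxels(vfm, n_supervoxels = 8, compactness = 0.1)
  lab_v <- sv$labels[vfm$voxels]
  side <- arrayInd(vfm$voxels, dm)[, 1] >= 8
  # purity: no supervoxel mixes interior voxels of the two lobes
  # (the 1-voxel interface layer is ambiguous by construction)
  interior <- arrayInd(vfm$voxels, dm)[, 1] %in% c(3:6, 9:12)
  for (c in seq_len(nrow(sv$pooled))) {
    mem <- lab_v == c & interior
    if (sum(mem) > 1) expect_lte(diff(range(side[mem])), 0)
  }
})

test_that("silhouette matches the textbook definition and cluster::silhouette", {
  # 6-point hand example in 1D: {0, 0.5, 1} and {10, 10.5, 11}
  x <- matrix(c(0, 0.5, 1, 10, 10.5, 11), ncol = 1)
  lab <- c(1, 1, 1, 2, 2, 2)
  # hand computation for point 1: a = (0.5 + 1)/2 = 0.75,
  # b = (10 + 10.5 + 11)/3 = 10.5, s = (10.5 - 0.75)/10.5
  d <- as.matrix(dist(x))
  s_hand <- vapply(1:6, function(i) {
    own <- lab == lab[i]
    a <- sum(d[i, own]) / (sum(own) - 1)
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_equal(silhouette_mean(x, lab), mean(s_hand), tolerance = 1e-12)
  expect_equal(s_hand[1], (10.5 - 0.75) / 10.5, tolerance = 1e-12)
  skip_if_not_installed("cluster")
  sil <- cluster::silhouette(lab, dist(x))
  expect_equal(silhouette_mean(x, lab), mean(sil[, "sil_width"]),
               tolerance = 1e-12)
})

test_that("silhouette-selected K recovers well-separated Gaussian blobs", {
  set.seed(8)
  blob <- function(mu, n = 40) sweep(matrix(stats::rnorm(n * 3, sd = 0.1), n), 2, mu, `+`)
  x3 <- rbind(blob(c(0, 0, 0)), blob(c(5, 0, 2)), blob(c(0, 5, 4)))
  colnames(x3) <- c("DCE_mean", "T2WI_mean", "DWI_mean")
  m3 <- fit_habitat_model(x3, k_range = 2:6, seed = 1)
  expect_equal(m3$K, 3L)
  x2 <- rbind(blob(c(0, 0, 0)), blob(c(5, 5, 5)))
  colnames(x2) <- c("DCE_mean", "T2WI_mean", "DWI_mean")
  m2 <- fit_habitat_model(x2, k_range = 2:6, seed = 1)
  expect_equal(m2$K, 2L)
  # K = argmax of the stored silhouette trace
  expect_equal(unname(m3$K),
               as.integer(names(which.max(m3$silhouette_by_k))))
  # identical supervoxels: zero variance error
  xx <- matrix(1, 30, 3, dimnames = list(NULL, c("DCE_mean", "T2WI_mean", "DWI_mean")))
  expect_error(fit_habitat_model(xx, seed = 1), "variance")
  # same seed reproduces identical centroids
  m3b <- fit_habitat_model(x3, k_range = 2:6, seed = 1)
  expect_identical(m3$centroids, m3b$centroids)
})

test_that("habitats are ordered by ascending DCE intensity and assignment is stable", {
  set.seed(9)
  blob <- function(mu, n = 30) sweep(matrix(stats::rnorm(n * 2, sd = 0.1), n), 2, mu, `+`)
  pooled <- rbind(blob(c(3, 1)), blob(c(0, 0)), blob(c(6, 2)))
  colnames(pooled) <- c("DCE_mean", "T2WI_mean")
  m <- fit_habitat_model(pooled, k_range = 2:5, seed = 2)
  expect_equal(m$K, 3L)
  # ordering statistic ascending in DCE
  expect_true(all(diff(m$ordering_stat) > 0))
  # a vector exactly at a centroid maps to that habitat
  labs <- habitatr:::`assign_habitats`
  sv <- structure(list(labels = array(c(1L), c(1, 1, 1)),
                       pooled = matrix(m$centroids[2, ] * m$scaling$sd +
                                       m$scaling$mean, 1,
                                       dimnames = list(NULL, m$feature_names)),
                       sizes = 1L),
                  class = "supervoxel_set")
  hm <- assign_habitats(sv, m)
  expect_equal(hm$sv_habitat, 2L)
  # feature mismatch errors
  sv_bad <- sv; colnames(sv_bad$pooled) <- c("x", "y")
  expect_error(assign_habitats(sv_bad, m), "mismatch")
})

test_that("training assignment reproduces the fitted cluster labels", {
  set.seed(10)
  blob <- function(mu, n = 25) sweep(matrix(stats::rnorm(n * 2, sd = 0.08), n), 2, mu, `+`)
  pooled <- rbind(blob(c(0, 1)), blob(c(4, 0)), blob(c(8, 2)))
  colnames(pooled) <- c("DCE_mean", "T2WI_mean")
  m <- fit_habitat_model(pooled, k_range = 2:5, seed = 3)
  z <- sweep(sweep(pooled, 2, m$scaling$mean), 2, m$scaling$sd, `/`)
  d2 <- vapply(seq_len(m$K), function(c)
    rowSums(sweep(z, 2, m$centroids[c, ])^2), numeric(nrow(z)))
  nearest <- max.col(-d2)
  # blocks of 25 all land in one habitat each, in ascending DCE order
  expect_equal(unique(nearest[1:25]), 1L)
  expect_equal(unique(nearest[26:50]), 2L)
  expect_equal(unique(nearest[51:75]), 3L)
})

test_that("k_range shrinks with a warning when supervoxels are scarce", {
  set.seed(12)
  pooled <- matrix(stats::rnorm(8 * 2), 8,
                   dimnames = list(NULL, c("DCE_mean", "T2WI_mean")))
  pooled[5:8, 1] <- pooled[5:8, 1] + 6
  expect_warning(m <- fit_habitat_model(pooled, k_range = 2:10, seed = 1),
                 "shrunk")
  expect_lt(max(as.integer(names(m$silhouette_by_k))), 8)
})
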