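# ---- texture-matrix feature families --------------------------------------
#
# Five gray-level matrix families (GLCM, GLRLM, GLSZM, GLDM, NGTDM) on
# region intensities discretized to a fixed bin count. GLCM and GLRLM are
# direction-averaged over the 13 unique 3D offsets (feature values averaged
# across directions, the common aggregation); GLSZM/GLDM/NGTDM use the
# 26-neighbourhood. Undefined-value conventions (constant regions etc.) are
# stated per feature in the code.

# 13 unique 3D direction offsets (one per +/- pair)
offsets13 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
          (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  g[keep, , drop = FALSE]
}

# binned bounding-box array with NA outside the region
region_bbox <- function(binned_vol, mask) {
  idx <- which(mask > 0)
  co <- arrayInd(idx, dim(mask))
  rg <- apply(co, 2, range)
  a <- binned_vol[rg[1, 1]:rg[2, 1], rg[1, 2]:rg[2, 2], rg[1, 3]:rg[2, 3],
                  drop = FALSE]
  msk <- mask[rg[1, 1]:rg[2, 1], rg[1, 2]:rg[2, 2], rg[1, 3]:rg[2, 3],
              drop = FALSE] > 0
  a <- array(a, dim(msk))
  a[!msk] <- NA_integer_
  a
}

glcm_names <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
                "ClusterTendency", "Contrast", "Correlation",
                "DifferenceAverage", "DifferenceEntropy",
                "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1",
                "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
                "JointEntropy", "MCC", "MaximumProbability", "SumAverage",
                "SumEntropy", "SumSquares")

# symmetric co-occurrence counts for one offset on a bbox array
glcm_counts <- function(a, d, ng) {
  dm <- dim(a)
  x1 <- max(1, 1 + d[1]):min(dm[1], dm[1] + d[1])
  y1 <- max(1, 1 + d[2]):min(dm[2], dm[2] + d[2])
  z1 <- max(1, 1 + d[3]):min(dm[3], dm[3] + d[3])
  if (!length(x1) || !length(y1) || !length(z1)) return(matrix(0, ng, ng))
  v1 <- a[x1, y1, z1, drop = FALSE]                       # voxel at p
  v0 <- a[x1 - d[1], y1 - d[2], z1 - d[3], drop = FALSE]  # voxel at p - d
  ok <- !is.na(v1) & !is.na(v0)
  if (!any(ok)) return(matrix(0, ng, ng))
  C <- matrix(tabulate((v0[ok] - 1L) * ng + v1[ok], ng * ng), ng, ng)
  C + t(C)
}

glcm_features_one <- function(P) {
  ng <- nrow(P)
  tot <- sum(P)
  if (tot == 0) return(stats::setNames(rep(NA_real_, 24), glcm_names))
  p <- P / tot
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  # p_{x+y} over k = 2..2ng, p_{x-y} over k = 0..ng-1
  kxy <- as.vector(i + j); kdiff <- as.vector(abs(i - j))
  pxy <- tapply(as.vector(p), kxy, sum)
  ks <- as.integer(names(pxy))
  pdiff_full <- tapply(as.vector(p), kdiff, sum)
  kd <- as.integer(names(pdiff_full))
  da <- sum(kd * pdiff_full)
  ent0 <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hx <- ent0(px); hy <- ent0(py); hxy <- ent0(as.vector(p))
  eps <- 1e-30
  pq <- outer(px, py)
  hxy1 <- -sum(p * log2(pq + eps))
  hxy2 <- -sum(pq * log2(pq + eps))
  corr <- if (sx * sy > 1e-12)
    (sum(i * j * p) - mux * muy) / (sx * sy) else 1  # constant region: 1
  # MCC via Q = Dx^-1 P Dy^-1 P^T restricted to occupied levels
  occ <- px > 0
  mcc <- if (sum(occ) < 2) 1 else {
    Ps <- p[occ, occ, drop = FALSE]
    Q <- diag(1 / px[occ]) %*% Ps %*% diag(1 / py[occ]) %*% t(Ps)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, min(1, ev[2])))
  }
  imc1 <- if (max(hx, hy) > 1e-12) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  c(Autocorrelation = sum(i * j * p),
    ClusterProminence = sum((i + j - mux - muy)^4 * p),
    ClusterShade = sum((i + j - mux - muy)^3 * p),
    ClusterTendency = sum((i + j - mux - muy)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = ent0(pdiff_full),
    DifferenceVariance = sum((kd - da)^2 * pdiff_full),
    Id = sum(pdiff_full / (1 + kd)),
    Idm = sum(pdiff_full / (1 + kd^2)),
    Idmn = sum(pdiff_full / (1 + (kd / ng)^2)),
    Idn = sum(pdiff_full / (1 + kd / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(pdiff_full[kd > 0] / kd[kd > 0]^2),
    JointAverage = mux,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(ks * pxy),
    SumEntropy = ent0(pxy),
    SumSquares = sum((i - mux)^2 * p))
}

#' GLCM features, averaged over the 13 3D directions
#' @param bbox binned bounding-box array (NA outside the region).
#' @param ng number of gray levels.
#' @return named numeric vector of 24 features.
#' @export
glcm_features <- function(bbox, ng) {
  offs <- offsets13()
  vals <- vapply(seq_len(nrow(offs)), function(o) {
    C <- glcm_counts(bbox, offs[o, ], ng)
    glcm_features_one(C)
  }, numeric(24))
  out <- rowMeans(vals, na.rm = TRUE)
  out[!is.finite(out)] <- 0
  stats::setNames(out, glcm_names)
}

glrlm_names <- c("ShortRunEmphasis", "LongRunEmphasis",
                 "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                 "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
                 "RunPercentage", "GrayLevelVariance", "RunVariance",
                 "RunEntropy", "LowGrayLevelRunEmphasis",
                 "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
                 "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
                 "LongRunHighGrayLevelEmphasis")

# run-length counts (gray x length) along one direction
glrlm_counts <- function(bbox, d, ng) {
  dm <- dim(bbox)
  co <- arrayInd(seq_len(prod(dm)), dm)
  # scan parameter t along the direction, line key = coord - t * d
  ax0 <- which(d != 0)[1]
  t <- co[, ax0] * d[ax0]
  key <- co - t %*% t(d)
  ordi <- order(key[, 1], key[, 2], key[, 3], t)
  v <- bbox[ordi]
  k1 <- key[ordi, 1]; k2 <- key[ordi, 2]; k3 <- key[ordi, 3]
  n <- length(v)
  newline <- c(TRUE, k1[-1] != k1[-n] | k2[-1] != k2[-n] | k3[-1] != k3[-n])
  same <- c(FALSE, !newline[-1] &
              ((is.na(v[-1]) & is.na(v[-n])) |
               (!is.na(v[-1]) & !is.na(v[-n]) & v[-1] == v[-n])))
  run_id <- cumsum(!same)
  lens <- tabulate(run_id)
  gray <- v[!duplicated(run_id)]
  keep <- !is.na(gray)
  lens <- lens[keep]; gray <- gray[keep]
  maxl <- max(lens, 1L)
  P <- matrix(0, ng, maxl)
  for (r in seq_along(lens)) P[gray[r], lens[r]] <- P[gray[r], lens[r]] + 1
  P
}

run_type_features <- function(P, np) {
  # shared feature arithmetic for run-length (GLRLM) and size-zone (GLSZM)
  nr <- sum(P)
  if (nr == 0) return(rep(NA_real_, 16))
  ng <- nrow(P); nl <- ncol(P)
  ii <- seq_len(ng); ll <- seq_len(nl)
  pg <- rowSums(P); pl <- colSums(P)
  pn <- P / nr
  mu_g <- sum(ii * rowSums(pn)); mu_l <- sum(ll * colSums(pn))
  pe <- pn[pn > 0]
  c(sum(pl / ll^2) / nr,                       # short emphasis
    sum(pl * ll^2) / nr,                       # long emphasis
    sum(pg^2) / nr,                            # GLN
    sum(pg^2) / nr^2,                          # GLNN
    sum(pl^2) / nr,                            # RLN / SZN
    sum(pl^2) / nr^2,                          # RLNN / SZNN
    nr / np,                                   # percentage
    sum((ii - mu_g)^2 * rowSums(pn)),          # gray-level variance
    sum((ll - mu_l)^2 * colSums(pn)),          # run/zone variance
    -sum(pe * log2(pe)),                       # entropy
    sum(pg / ii^2) / nr,                       # low gray
    sum(pg * ii^2) / nr,                       # high gray
    sum(outer(1 / ii^2, 1 / ll^2) * P) / nr,   # short+low
    sum(outer(ii^2, 1 / ll^2) * P) / nr,       # short+high
    sum(outer(1 / ii^2, ll^2) * P) / nr,       # long+low
    sum(outer(ii^2, ll^2) * P) / nr)           # long+high
}

#' GLRLM features, averaged over the 13 3D directions
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features.
#' @export
glrlm_features <- function(bbox, ng) {
  np <- sum(!is.na(bbox))
  offs <- offsets13()
  vals <- vapply(seq_len(nrow(offs)), function(o)
    run_type_features(glrlm_counts(bbox, offs[o, ], ng), np),
    numeric(16))
  out <- rowMeans(vals, na.rm = TRUE)
  out[!is.finite(out)] <- 0
  stats::setNames(out, glrlm_names)
}

glszm_names <- c("SmallAreaEmphasis", "LargeAreaEmphasis",
                 "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                 "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
                 "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
                 "ZoneEntropy", "LowGrayLevelZoneEmphasis",
                 "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
                 "SmallAreaHighGrayLevelEmphasis",
                 "LargeAreaLowGrayLevelEmphasis",
                 "LargeAreaHighGrayLevelEmphasis")

#' GLSZM features (zones = 26-connected equal-gray components)
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features.
#' @export
glszm_features <- function(bbox, ng) {
  np <- sum(!is.na(bbox))
  m <- !is.na(bbox)
  # all gray levels labelled in one pass: propagation restricted to equal
  # gray values yields the per-level 26-connected zones directly
  lab <- label_components(m, 26L, gray = bbox)
  if (max(lab) == 0)
    return(stats::setNames(rep(0, 16), glszm_names))
  zones_s <- tabulate(lab[lab > 0])
  first <- match(seq_along(zones_s), lab)
  zones_g <- bbox[first]
  maxs <- max(zones_s)
  P <- matrix(0, ng, maxs)
  for (z in seq_along(zones_g))
    P[zones_g[z], zones_s[z]] <- P[zones_g[z], zones_s[z]] + 1
  out <- run_type_features(P, np)
  out[!is.finite(out)] <- 0
  stats::setNames(out, glszm_names)
}

gldm_names <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
                "GrayLevelNonUniformity", "DependenceNonUniformity",
                "DependenceNonUniformityNormalized", "GrayLevelVariance",
                "DependenceVariance", "DependenceEntropy",
                "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
                "SmallDependenceLowGrayLevelEmphasis",
                "SmallDependenceHighGrayLevelEmphasis",
                "LargeDependenceLowGrayLevelEmphasis",
                "LargeDependenceHighGrayLevelEmphasis")

#' GLDM features (alpha = 0, 26-neighbourhood dependence)
#' @inheritParams glcm_features
#' @param alpha dependence tolerance on the gray-level difference.
#' @return named numeric vector of 14 features.
#' @export
gldm_features <- function(bbox, ng, alpha = 0) {
  m <- !is.na(bbox)
  offs <- neighbor_offsets(26L)
  dep <- array(0L, dim(bbox))
  for (o in seq_len(nrow(offs))) {
    nb <- shift_array(bbox, offs[o, ])
    dep <- dep + (!is.na(nb) & m & abs(nb - bbox) <= alpha)
  }
  g <- bbox[m]; d <- dep[m] + 1L   # dependence size j = d + 1
  nd <- max(d)
  P <- matrix(0, ng, nd)
  for (t in seq_along(g)) P[g[t], d[t]] <- P[g[t], d[t]] + 1
  nz <- sum(P)
  ii <- seq_len(ng); jj <- seq_len(nd)
  pg <- rowSums(P); pj <- colSums(P)
  pn <- P / nz
  mu_g <- sum(ii * rowSums(pn)); mu_j <- sum(jj * colSums(pn))
  pe <- pn[pn > 0]
  out <- c(sum(pj / jj^2) / nz,
           sum(pj * jj^2) / nz,
           sum(pg^2) / nz,
           sum(pj^2) / nz,
           sum(pj^2) / nz^2,
           sum((ii - mu_g)^2 * rowSums(pn)),
           sum((jj - mu_j)^2 * colSums(pn)),
           -sum(pe * log2(pe)),
           sum(pg / ii^2) / nz,
           sum(pg * ii^2) / nz,
           sum(outer(1 / ii^2, 1 / jj^2) * P) / nz,
           sum(outer(ii^2, 1 / jj^2) * P) / nz,
           sum(outer(1 / ii^2, jj^2) * P) / nz,
           sum(outer(ii^2, jj^2) * P) / nz)
  out[!is.finite(out)] <- 0
  stats::setNames(out, gldm_names)
}

ngtdm_names <- c("Coarseness", "Contrast", "Busyness", "Complexity",
                 "Strength")

#' NGTDM features (26-neighbourhood gray-tone difference)
#' @inheritParams glcm_features
#' @return named numeric vector of 5 features.
#' @export
ngtdm_features <- function(bbox, ng) {
  m <- !is.na(bbox)
  offs <- neighbor_offsets(26L)
  ssum <- array(0, dim(bbox)); scnt <- array(0L, dim(bbox))
  for (o in seq_len(nrow(offs))) {
    nb <- shift_array(bbox, offs[o, ])
    ok <- !is.na(nb) & m
    nb[!ok] <- 0
    ssum <- ssum + nb
    scnt <- scnt + ok
  }
  g <- bbox[m]
  nv <- length(g)
  has_nb <- scnt[m] > 0
  abar <- ifelse(has_nb, ssum[m] / pmax(scnt[m], 1L), g)  # isolated: |g-g|=0
  s_i <- numeric(ng); n_i <- numeric(ng)
  for (lev in seq_len(ng)) {
    sel <- g == lev
    n_i[lev] <- sum(sel)
    if (any(sel)) s_i[lev] <- sum(abs(lev - abar[sel]))
  }
  p_i <- n_i / nv
  occ <- p_i > 0
  ngp <- sum(occ)
  lv <- seq_len(ng)
  coars_den <- sum(p_i * s_i)
  coarseness <- if (coars_den > 1e-12) 1 / coars_den else 1e6
  contrast <- if (ngp > 1) {
    sum(outer(p_i[occ], p_i[occ]) * outer(lv[occ], lv[occ], `-`)^2) /
      (ngp * (ngp - 1)) * sum(s_i) / nv
  } else 0
  busy_den <- sum(abs(outer(lv[occ] * p_i[occ], lv[occ] * p_i[occ], `-`)))
  # denominator: double sum over ordered pairs of |i*p_i - j*p_j| (i = j
  # terms vanish), per the standard definition
  busyness <- if (busy_den > 1e-12) sum(p_i * s_i) / busy_den else 0
  cplx <- 0; strg <- 0
  if (ngp > 1) {
    io <- lv[occ]; po <- p_i[occ]; so <- s_i[occ]
    for (a in seq_along(io)) for (b in seq_along(io)) {
      if (a == b) next
      cplx <- cplx + abs(io[a] - io[b]) *
        (po[a] * so[a] + po[b] * so[b]) / (po[a] + po[b])
      strg <- strg + (po[a] + po[b]) * (io[a] - io[b])^2
    }
    cplx <- cplx / nv
    strg <- if (sum(s_i) > 1e-12) strg / sum(s_i) else 0
  }
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = cplx, Strength = strg)
}
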