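# Shared fixtures and independent reference implementations used as
# oracles. The references are written as plain definitional loops so they
# stay independent of the package's vectorized code paths.

# memoised small preprocessed cohort shared across tests
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generate_cohort(synthetic_config(n_patients = 6,
                                             grid_shape = c(24L, 24L, 24L),
                                             seed = 42))
      cache <<- preprocess_cohort(co)
    }
    cache
  }
})

# random binned bbox array with NA border, for texture oracles
random_bbox <- function(dims = c(4, 4, 3), ng = 4, na_frac = 0.2, seed = 1) {
  set.seed(seed)
  a <- array(sample.int(ng, prod(dims), replace = TRUE), dims)
  a[stats::runif(prod(dims)) < na_frac] <- NA
  storage.mode(a) <- "double"
  a
}

# ---- definitional texture-matrix references -------------------------------

ref_glcm_counts <- function(a, d, ng) {
  dm <- dim(a)
  C <- matrix(0, ng, ng)
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    x2 <- x + d[1]; y2 <- y + d[2]; z2 <- z + d[3]
    if (x2 < 1 || x2 > dm[1] || y2 < 1 || y2 > dm[2] || z2 < 1 || z2 > dm[3])
      next
    v1 <- a[x, y, z]; v2 <- a[x2, y2, z2]
    if (is.na(v1) || is.na(v2)) next
    C[v1, v2] <- C[v1, v2] + 1
  }
  C + t(C)
}

ref_glrlm_counts <- function(a, d, ng) {
  dm <- dim(a)
  runs_g <- integer(0); runs_l <- integer(0)
  inb <- function(p) all(p >= 1) && all(p <= dm)
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    p <- c(x, y, z)
    prev <- p - d
    v <- a[x, y, z]
    if (is.na(v)) next
    # start of a run: predecessor out of bounds, NA, or different value
    vprev <- if (inb(prev)) a[prev[1], prev[2], prev[3]] else NA
    if (!is.na(vprev) && vprev == v) next
    len <- 1L
    q <- p + d
    while (inb(q) && !is.na(a[q[1], q[2], q[3]]) && a[q[1], q[2], q[3]] == v) {
      len <- len + 1L
      q <- q + d
    }
    runs_g <- c(runs_g, v); runs_l <- c(runs_l, len)
  }
  P <- matrix(0, ng, max(runs_l, 1L))
  for (r in seq_along(runs_g)) P[runs_g[r], runs_l[r]] <- P[runs_g[r], runs_l[r]] + 1
  P
}

ref_glszm_zones <- function(a) {
  # returns data.frame(gray, size) via stack-based flood fill, 26-connected
  dm <- dim(a)
  seen <- array(FALSE, dm)
  zg <- integer(0); zs <- integer(0)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (i in which(!is.na(a))) {
    if (seen[i]) next
    g <- a[i]
    stack <- i; seen[i] <- TRUE; size <- 0L
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      size <- size + 1L
      cc <- arrayInd(cur, dm)
      for (o in seq_len(nrow(offs))) {
        p <- cc + offs[o, ]
        if (any(p < 1) || any(p > dm)) next
        j <- p[1] + (p[2] - 1) * dm[1] + (p[3] - 1) * dm[1] * dm[2]
        if (!seen[j] && !is.na(a[j]) && a[j] == g) {
          seen[j] <- TRUE; stack <- c(stack, j)
        }
      }
    }
    zg <- c(zg, g); zs <- c(zs, size)
  }
  data.frame(gray = zg, size = zs)
}

ref_gldm_counts <- function(a, ng, alpha = 0) {
  dm <- dim(a)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  gs <- integer(0); ds <- integer(0)
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    v <- a[x, y, z]
    if (is.na(v)) next
    dep <- 0L
    for (o in seq_len(nrow(offs))) {
      p <- c(x, y, z) + offs[o, ]
      if (any(p < 1) || any(p > dm)) next
      w <- a[p[1], p[2], p[3]]
      if (!is.na(w) && abs(w - v) <= alpha) dep <- dep + 1L
    }
    gs <- c(gs, v); ds <- c(ds, dep + 1L)
  }
  P <- matrix(0, ng, max(ds))
  for (r in seq_along(gs)) P[gs[r], ds[r]] <- P[gs[r], ds[r]] + 1
  P
}

ref_ngtdm <- function(a, ng) {
  dm <- dim(a)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  s_i <- numeric(ng); n_i <- numeric(ng)
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    v <- a[x, y, z]
    if (is.na(v)) next
    nb <- numeric(0)
    for (o in seq_len(nrow(offs))) {
      p <- c(x, y, z) + offs[o, ]
      if (any(p < 1) || any(p > dm)) next
      w <- a[p[1], p[2], p[3]]
      if (!is.na(w)) nb <- c(nb, w)
    }
    n_i[v] <- n_i[v] + 1
    s_i[v] <- s_i[v] + if (length(nb)) abs(v - mean(nb)) else 0
  }
  list(s = s_i, n = n_i)
}

# ---- tree-model value function and exhaustive Shapley ---------------------

# cover-weighted conditional expectation of an xgboost ensemble given the
# feature subset S (path-dependent convention)
xgb_value_fn <- function(tree_df, x, S) {
  total <- 0
  for (tid in unique(tree_df$Tree)) {
    tr <- tree_df[tree_df$Tree == tid, ]
    rec <- function(node_id) {
      row <- tr[tr$Node == node_id, ]
      if (row$Feature == "Leaf") return(row$Gain)
      if (row$Feature %in% S) {
        go <- if (x[[row$Feature]] < row$Split) row$Yes else row$No
        return(rec(as.integer(sub(".*-", "", go))))
      }
      yid <- as.integer(sub(".*-", "", row$Yes))
      nid <- as.integer(sub(".*-", "", row$No))
      cy <- tr$Cover[tr$Node == yid]; cn <- tr$Cover[tr$Node == nid]
      (cy * rec(yid) + cn * rec(nid)) / (cy + cn)
    }
    total <- total + rec(0L)
  }
  total
}

exhaustive_shapley <- function(booster, x, feature_names) {
  td <- xgboost::xgb.model.dt.tree(model = booster)
  td <- as.data.frame(td)
  # the ensemble margin includes the global base_score (logit scale)
  cfg <- xgboost::xgb.config(booster)
  if (is.character(cfg)) cfg <- jsonlite::fromJSON(cfg)
  b0 <- stats::qlogis(as.numeric(
    cfg$learner$learner_model_param$base_score))
  used <- setdiff(unique(td$Feature), "Leaf")
  M <- length(used)
  stopifnot(M <= 10)
  phi <- stats::setNames(numeric(length(feature_names)), feature_names)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), M))
  vcache <- new.env()
  vS <- function(sel) {
    key <- paste(sel, collapse = "")
    if (!is.null(vcache[[key]])) return(vcache[[key]])
    v <- xgb_value_fn(td, x, used[sel])
    vcache[[key]] <- v
    v
  }
  for (f in used) {
    fi <- match(f, used)
    tot <- 0
    for (r in seq_len(nrow(subsets))) {
      sel <- as.logical(subsets[r, ])
      if (sel[fi]) next
      s <- sum(sel)
      w <- factorial(s) * factorial(M - s - 1) / factorial(M)
      sel2 <- sel; sel2[fi] <- TRUE
      tot <- tot + w * (vS(sel2) - vS(sel))
    }
    phi[f] <- tot
  }
  list(phi = phi, base = vS(rep(FALSE, M)) + b0)
}

# tie-corrected AUC by explicit pair counting (oracle)
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# minimal boosted_model wrapper for interpretation tests
fit_small_booster <- function(x, y, depth = 2L, nrounds = 5L, eta = 0.5,
                              colsample = 1) {
  d <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = depth,
                  eta = eta, lambda = 0, nthread = 1, seed = 1,
                  colsample_bytree = colsample),
    data = d, nrounds = nrounds, verbose = 0)
  structure(list(booster = booster, feature_names = colnames(x),
                 best = data.frame(depth = depth, eta = eta,
                                   nrounds = nrounds, subsample = 1,
                                   mean_auc = NA),
                 train_pred = stats::predict(booster, as.matrix(x))),
            class = "boosted_model")
}


# TRUE when some root-to-leaf path splits twice on one feature; the
# cover-game exhaustive Shapley oracle equals path-dependent TreeSHAP only
# when this is FALSE
paths_have_repeats <- function(booster) {
  td <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  for (tid in unique(td$Tree)) {
    tr <- td[td$Tree == tid, ]
    walk <- function(node_id, seen) {
      row <- tr[tr$Node == node_id, ]
      if (row$Feature == "Leaf") return(FALSE)
      if (row$Feature %in% seen) return(TRUE)
      seen <- c(seen, row$Feature)
      walk(as.integer(sub(".*-", "", row$Yes)), seen) ||
        walk(as.integer(sub(".*-", "", row$No)), seen)
    }
    if (walk(0L, character(0))) return(TRUE)
  }
  FALSE
}

# deterministically pick the first data seed whose fitted small model has
# no repeated feature along any path (precondition of the oracle)
fit_booster_without_path_repeats <- function(start_seed, n = 100,
                                             depth = 2L, nrounds = 5L,
                                             eta = 0.4) {
  for (s in start_seed + 0:20) {
    set.seed(s)
    x <- data.frame(a = stats::rnorm(n), b = stats::rnorm(n),
                    c = stats::rnorm(n), d = stats::rnorm(n))
    y <- as.integer(x$a + x$b - 0.8 * x$c + stats::rnorm(n, sd = 0.4) > 0)
    m <- fit_small_booster(x, y, depth = depth, nrounds = nrounds, eta = eta)
    if (!paths_have_repeats(m$booster)) return(list(model = m, x = x))
  }
  stop("no repeat-free model found")
}
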