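# ---- five-stage feature-selection cascade ---------------------------------
#
# ICC reproducibility filter -> z-score standardization -> univariate test
# (Welch t or Mann-Whitney U, gated by Shapiro-Wilk) -> Spearman redundancy
# pruning -> mRMR (FCQ) -> LASSO logistic with 10-fold CV. Every statistic
# is fit on the training split only; stage survivor sets are nested.

#' Selection-cascade configuration
#'
#' @param icc_threshold minimum ICC(2,1) for reproducibility (default 0.90).
#' @param p_threshold univariate retention threshold.
#' @param shapiro_alpha normality-test level gating t-test vs Mann-Whitney.
#' @param spearman_cutoff redundancy pruning cutoff on |rho|.
#' @param mrmr_k number of features kept by mRMR.
#' @param lasso_folds CV folds for the LASSO stage.
#' @param seed RNG seed (fold assignment).
#' @return object of class `selection_config`.
#' @export
selection_config <- function(icc_threshold = 0.90, p_threshold = 0.05,
                             shapiro_alpha = 0.05, spearman_cutoff = 0.90,
                             mrmr_k = 30L, lasso_folds = 10L, seed = 1L) {
  stopifnot(icc_threshold > 0, icc_threshold < 1,
            p_threshold > 0, p_threshold < 1,
            spearman_cutoff > 0, spearman_cutoff <= 1, mrmr_k >= 1)
  structure(list(icc_threshold = icc_threshold, p_threshold = p_threshold,
                 shapiro_alpha = shapiro_alpha,
                 spearman_cutoff = spearman_cutoff,
                 mrmr_k = as.integer(mrmr_k),
                 lasso_folds = as.integer(lasso_folds),
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single rater — the usual
#' radiomics reproducibility form. Computed from the two-way ANOVA mean
#' squares. Zero between-subject variance returns 0 with a
#' `"degenerate"` attribute.
#'
#' @param r1,r2 paired per-subject ratings from the two raters.
#' @return ICC in \[-1, 1\].
#' @export
icc21 <- function(r1, r2) {
  stopifnot(length(r1) == length(r2), length(r1) >= 3,
            all(is.finite(r1)), all(is.finite(r2)))
  n <- length(r1); k <- 2
  x <- cbind(r1, r2)
  row_m <- rowMeans(x); col_m <- colMeans(x); g <- mean(x)
  msr <- k * sum((row_m - g)^2) / (n - 1)              # between subjects
  msc <- n * sum((col_m - g)^2) / (k - 1)              # between raters
  sse <- sum((x - outer(row_m, rep(1, k)) -
              outer(rep(1, n), col_m) + g)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (abs(msr) < 1e-14 || abs(denom) < 1e-14) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (msr - mse) / denom
}

#' ICC reproducibility filter over two raters' feature tables
#'
#' @param tab1,tab2 data.frames of the same schema (rater 1 and rater 2);
#'   training rows only.
#' @param threshold minimum ICC.
#' @return list with `survivors` (feature names) and `icc` (named vector;
#'   NA for features with missing values in either table).
#' @export
icc_filter <- function(tab1, tab2, threshold = 0.90) {
  stopifnot(identical(colnames(tab1), colnames(tab2)))
  icc <- vapply(colnames(tab1), function(f) {
    a <- tab1[[f]]; b <- tab2[[f]]
    if (anyNA(a) || anyNA(b) || stats::sd(a) < 1e-12) return(NA_real_)
    as.numeric(icc21(a, b))
  }, numeric(1))
  list(survivors = names(icc)[!is.na(icc) & icc >= threshold], icc = icc)
}

#' Univariate filter: Welch t-test or Mann-Whitney U, gated by Shapiro-Wilk
#'
#' A feature is compared between classes with a two-sided Welch t-test when
#' Shapiro-Wilk does not reject normality in either class (at
#' `shapiro_alpha`), otherwise with the Mann-Whitney U test. Features with
#' p < `p_threshold` survive; constant features are excluded with a reason.
#'
#' @param tab training data.frame (rows = patients).
#' @param labels binary outcome for the same rows.
#' @param config a [selection_config()].
#' @return list with `survivors`, `p` (named), `test` (named character),
#'   `excluded` (named character reasons).
#' @export
univariate_filter <- function(tab, labels, config = selection_config()) {
  labels <- as.integer(labels)
  stopifnot(nrow(tab) == length(labels), all(table(labels) >= 2))
  p <- stats::setNames(rep(NA_real_, ncol(tab)), colnames(tab))
  test <- stats::setNames(rep(NA_character_, ncol(tab)), colnames(tab))
  excluded <- character(0)
  for (f in colnames(tab)) {
    x <- tab[[f]]
    if (anyNA(x) || stats::sd(x) < 1e-12 ||
        stats::sd(x[labels == 0]) < 1e-12 && stats::sd(x[labels == 1]) < 1e-12) {
      excluded[f] <- "constant or missing"
      next
    }
    norm_ok <- tryCatch({
      p0 <- stats::shapiro.test(x[labels == 0])$p.value
      p1 <- stats::shapiro.test(x[labels == 1])$p.value
      p0 > config$shapiro_alpha && p1 > config$shapiro_alpha
    }, error = function(e) FALSE)
    if (norm_ok) {
      test[f] <- "welch_t"
      p[f] <- stats::t.test(x ~ labels)$p.value
    } else {
      test[f] <- "mann_whitney"
      p[f] <- suppressWarnings(stats::wilcox.test(x ~ labels)$p.value)
    }
  }
  surv <- names(p)[!is.na(p) & p < config$p_threshold]
  list(survivors = surv, p = p, test = test, excluded = excluded)
}

#' Spearman redundancy pruning
#'
#' Greedy: features are visited by ascending priority value (univariate p);
#' a feature is kept unless its |Spearman rho| with an already-kept feature
#' exceeds the cutoff. Deterministic; name order breaks priority ties.
#'
#' @param tab training data.frame.
#' @param survivors candidate feature names.
#' @param cutoff |rho| above which the later feature is dropped.
#' @param priority named numeric (lower = kept first), e.g. univariate p.
#' @return character vector of surviving features.
#' @export
spearman_prune <- function(tab, survivors, cutoff = 0.90, priority = NULL) {
  if (!length(survivors)) stop("no survivors to prune")
  if (is.null(priority)) priority <- stats::setNames(seq_along(survivors),
                                                     survivors)
  ord <- survivors[order(priority[survivors], survivors)]
  rho <- abs(stats::cor(tab[, ord, drop = FALSE], method = "spearman"))
  kept <- character(0)
  for (f in ord) {
    if (!length(kept) || all(rho[f, kept] <= cutoff)) kept <- c(kept, f)
  }
  kept
}

# F-statistic of a one-way ANOVA of x against a binary/grouping label
anova_f <- function(x, g) {
  g <- factor(g)
  gm <- tapply(x, g, mean)
  n_g <- tapply(x, g, length)
  grand <- mean(x)
  ssb <- sum(n_g * (gm - grand)^2)
  ssw <- sum((x - gm[g])^2)
  dfb <- nlevels(g) - 1
  dfw <- length(x) - nlevels(g)
  if (ssw < 1e-300) return(Inf)
  (ssb / dfb) / (ssw / dfw)
}

#' mRMR feature selection (F-test Correlation Quotient variant)
#'
#' Greedy: the first pick maximizes relevance (ANOVA F-statistic against
#' the label); each subsequent pick maximizes
#' `F / mean(|Pearson rho| to already-selected)`. Deterministic; ties break
#' by feature-name order.
#'
#' @param tab training data.frame.
#' @param labels binary outcome.
#' @param k number of features to select.
#' @param candidates optional candidate subset (default all columns).
#' @return character vector of selected features, in selection order.
#' @export
mrmr_select <- function(tab, labels, k = 30L, candidates = colnames(tab)) {
  candidates <- sort(candidates)
  if (k > length(candidates)) {
    warning("k > available features; selecting all")
    k <- length(candidates)
  }
  x <- as.matrix(tab[, candidates, drop = FALSE])
  f_rel <- vapply(candidates, function(f) anova_f(x[, f], labels), numeric(1))
  sel <- character(0)
  avail <- candidates
  for (step in seq_len(k)) {
    if (!length(sel)) {
      score <- f_rel[avail]
    } else {
      red <- vapply(avail, function(f)
        mean(abs(stats::cor(x[, f], x[, sel, drop = FALSE]))), numeric(1))
      score <- f_rel[avail] / pmax(red, 1e-12)
    }
    pick <- avail[which.max(score)]  # which.max: first max = name order
    sel <- c(sel, pick)
    avail <- setdiff(avail, pick)
    if (!length(avail)) break
  }
  sel
}

#' LASSO-logistic embedded selection
#'
#' L1-penalized logistic regression over glmnet's log-spaced lambda grid;
#' lambda* minimizes the mean cross-validated binomial deviance; survivors
#' are the features with nonzero coefficients at lambda*. Fold assignment
#' is fixed by the seed, so the result is deterministic.
#'
#' @param tab training data.frame (standardized features).
#' @param labels binary outcome.
#' @param candidates feature subset to run on.
#' @param folds number of CV folds.
#' @param seed RNG seed for fold assignment.
#' @return list with `survivors`, `lambda`, `fit` (the cv.glmnet object).
#' @export
lasso_select <- function(tab, labels, candidates = colnames(tab),
                         folds = 10L, seed = 1L) {
  x <- as.matrix(tab[, candidates, drop = FALSE])
  y <- as.integer(labels)
  stopifnot(min(table(y)) >= folds || folds <= min(table(y)) * 2)
  set.seed(as.integer(seed))
  foldid <- integer(length(y))
  for (cl in unique(y)) {       # stratified folds
    idx <- sample(which(y == cl))
    foldid[idx] <- rep_len(seq_len(folds), length(idx))
  }
  if (ncol(x) < 2) {  # glmnet needs >= 2 columns; duplicate guard column
    return(list(survivors = candidates, lambda = 0, fit = NULL))
  }
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", foldid = foldid,
                          type.measure = "deviance", standardize = TRUE)
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, , drop = FALSE]
  surv <- rownames(co)[abs(co[, 1]) > 1e-10]
  if (!length(surv))
    warning("LASSO selected no features at lambda.min")
  list(survivors = surv, lambda = cv$lambda.min, fit = cv)
}

#' Run the five-stage selection cascade on one feature pool
#'
#' Fits every stage on the training rows only. The ICC stage uses both
#' raters' training tables; the remaining stages use the rater-1 table
#' standardized with training means/SDs.
#'
#' @param tab rater-1 feature data.frame (all patients; rows named by id).
#' @param tab_rater2 rater-2 table of the same schema, or NULL to skip the
#'   ICC stage.
#' @param labels named binary outcome vector for all patients.
#' @param split named train/test assignment ([split_cohort()]).
#' @param config a [selection_config()].
#' @return object of class `selection_report`: per-stage survivors and
#'   statistics, the standardization parameters, and the pool tag.
#' @export
select_features <- function(tab, tab_rater2 = NULL, labels, split,
                            config = selection_config()) {
  ids <- rownames(tab)
  stopifnot(!is.null(ids), all(ids %in% names(split)),
            all(ids %in% names(labels)))
  train_ids <- ids[split[ids] == "train"]
  tr <- tab[train_ids, , drop = FALSE]
  y <- as.integer(labels[train_ids])
  stages <- list()
  # stage 1: ICC reproducibility (drops missing-flagged features too)
  complete <- colnames(tr)[!vapply(tr, anyNA, logical(1))]
  if (!is.null(tab_rater2)) {
    ic <- icc_filter(tr[, complete, drop = FALSE],
                     tab_rater2[train_ids, complete, drop = FALSE],
                     config$icc_threshold)
    stages$icc <- list(survivors = ic$survivors, icc = ic$icc)
  } else {
    stages$icc <- list(survivors = complete, icc = NULL)
  }
  s1 <- stages$icc$survivors
  if (!length(s1)) stop("no features survived the ICC stage")
  # stage 2: z-score standardization (train-fitted, population SD)
  mu <- colMeans(tr[, s1, drop = FALSE])
  sdv <- vapply(tr[, s1, drop = FALSE], function(v) sqrt(mean((v - mean(v))^2)),
                numeric(1))
  keep <- names(sdv)[sdv > 1e-12]
  ztr <- as.data.frame(sweep(sweep(tr[, keep, drop = FALSE], 2, mu[keep]),
                             2, sdv[keep], `/`))
  # stage 3: univariate filter
  uv <- univariate_filter(ztr, y, config)
  if (!length(uv$survivors)) stop("no features survived the univariate stage")
  stages$univariate <- uv
  # stage 4: Spearman pruning (priority = univariate p)
  sp <- spearman_prune(ztr, uv$survivors, config$spearman_cutoff, uv$p)
  stages$spearman <- list(survivors = sp)
  # stage 5: mRMR
  mr <- mrmr_select(ztr, y, k = config$mrmr_k, candidates = sp)
  stages$mrmr <- list(survivors = mr)
  # stage 6: LASSO
  la <- lasso_select(ztr, y, candidates = mr, folds = config$lasso_folds,
                     seed = config$seed)
  stages$lasso <- list(survivors = la$survivors, lambda = la$lambda)
  structure(list(stages = stages, selected = la$survivors,
                 scaling = list(mean = mu[keep], sd = sdv[keep]),
                 pool = attr(tab, "pool") %||% "features",
                 train_ids = train_ids, config = config),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Selection cascade (", x$pool, " pool):\n", sep = "")
  counts <- vapply(x$stages, function(s) length(s$survivors), integer(1))
  for (nm in names(counts)) cat(sprintf("  %-11s %d survivors\n", nm, counts[nm]))
  invisible(x)
}

#' Standardize any table with a selection report's training scaling
#' @param report a `selection_report`.
#' @param tab feature data.frame (any rows).
#' @return data.frame restricted to the selected features, standardized.
#' @export
apply_selection <- function(report, tab) {
  f <- report$selected
  z <- sweep(sweep(tab[, f, drop = FALSE], 2, report$scaling$mean[f]),
             2, report$scaling$sd[f], `/`)
  as.data.frame(z)
}
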