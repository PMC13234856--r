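# ---- clinical screening and the four gradient-boosted models --------------
#
# Univariable logistic regression screens clinicopathological covariates;
# those with p < 0.05 enter a multivariable fit, whose significant terms
# define the clinical model's feature set. Four XGBoost classifiers
# (clinical / conventional radiomics / habitat radiomics / combined) are
# tuned by exhaustive grid search under 5-fold stratified CV on mean
# validation AUC, then refit on the full training split.

#' Odds ratio and Woolf 95% CI from a 2x2 table
#'
#' `OR = (a * d) / (b * c)` with a = exposed cases, b = exposed controls,
#' c = unexposed cases, d = unexposed controls; the Woolf CI is
#' `exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param exposed_cases,unexposed_cases,exposed_controls,unexposed_controls
#'   nonnegative cell counts.
#' @param continuity add 0.5 to every cell when any cell is zero.
#' @return list with `or`, `ci` (length 2), `log_se`.
#' @export
odds_ratio_2x2 <- function(exposed_cases, unexposed_cases,
                           exposed_controls, unexposed_controls,
                           continuity = FALSE) {
  a <- exposed_cases; b <- exposed_controls
  c <- unexposed_cases; d <- unexposed_controls
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (any(c(a, b, c, d) == 0)) {
    if (!continuity)
      stop("zero cell; set continuity = TRUE for the 0.5 correction")
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, ci = exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se),
       log_se = se)
}

# reference levels for the categorical clinical covariates
clinical_terms <- function() {
  list(age = "numeric", tumor_length = "numeric", aln_length = "numeric",
       alb_glb = "numeric", tc = "numeric", hdl_c = "numeric",
       ldl_c = "numeric",
       tic = c("inflow_or_platform", "washout"),
       bi_rads = c("4a4b", "4c", "5"),
       grade = c("G1_2", "G3"),
       ki67 = c("lt20", "ge20"),
       menopause = "numeric")
}

# expand the clinical data.frame into a model frame with stated reference
# levels (first level = reference)
clinical_model_frame <- function(clin) {
  terms <- clinical_terms()
  out <- data.frame(row.names = rownames(clin))
  for (v in names(terms)) {
    if (!v %in% colnames(clin)) next
    if (identical(terms[[v]], "numeric")) {
      out[[v]] <- as.numeric(clin[[v]])
    } else {
      f <- factor(clin[[v]], levels = terms[[v]])
      for (lv in terms[[v]][-1])
        out[[paste0(v, "_", lv)]] <- as.integer(f == lv)
    }
  }
  out
}

#' Univariable logistic screening of clinical covariates
#'
#' One maximum-likelihood logistic fit per covariate (categorical
#' covariates expanded against their reference level within a single fit).
#' Wald CIs; perfect separation is flagged with an infinite-OR sentinel.
#'
#' @param clin clinical data.frame (training rows).
#' @param labels binary ALNM outcome for the same rows.
#' @return data.frame of class `logistic_screen`: term, coefficient, OR,
#'   CI bounds, Wald p, and the parent variable.
#' @export
univariable_screen <- function(clin, labels) {
  labels <- as.integer(labels)
  terms <- clinical_terms()
  rows <- list()
  for (v in intersect(names(terms), colnames(clin))) {
    if (identical(terms[[v]], "numeric")) {
      df <- data.frame(y = labels, x = as.numeric(clin[[v]]))
      fit <- suppressWarnings(stats::glm(y ~ x, data = df, family = stats::binomial()))
      cf <- summary(fit)$coefficients
      sep <- !fit$converged || any(abs(cf[-1, 1]) > 15)
      rows[[v]] <- data.frame(
        variable = v, term = v, coef = cf[2, 1], or = exp(cf[2, 1]),
        ci_lo = exp(cf[2, 1] - 1.96 * cf[2, 2]),
        ci_hi = exp(cf[2, 1] + 1.96 * cf[2, 2]),
        p = cf[2, 4], separation = sep)
    } else {
      f <- factor(clin[[v]], levels = terms[[v]])
      df <- data.frame(y = labels, x = f)
      fit <- suppressWarnings(stats::glm(y ~ x, data = df, family = stats::binomial()))
      cf <- summary(fit)$coefficients
      sep <- !fit$converged || any(abs(cf[-1, 1]) > 15)
      lv <- terms[[v]][-1]
      rows[[v]] <- data.frame(
        variable = v, term = paste0(v, "_", lv),
        coef = cf[-1, 1], or = exp(cf[-1, 1]),
        ci_lo = exp(cf[-1, 1] - 1.96 * cf[-1, 2]),
        ci_hi = exp(cf[-1, 1] + 1.96 * cf[-1, 2]),
        p = cf[-1, 4], separation = sep)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$or[out$separation & out$coef > 15] <- Inf
  class(out) <- c("logistic_screen", class(out))
  out
}

#' Multivariable logistic fit on the screened covariates
#'
#' @param clin clinical data.frame (training rows).
#' @param labels binary outcome.
#' @param screened_vars variable names with univariable p < threshold.
#' @return data.frame like [univariable_screen()] plus a
#'   `clinical_features` attribute: the terms significant at p < 0.05,
#'   which become the clinical model's feature set.
#' @export
multivariable_fit <- function(clin, labels, screened_vars) {
  labels <- as.integer(labels)
  mf <- clinical_model_frame(clin)
  terms <- clinical_terms()
  cols <- unlist(lapply(screened_vars, function(v)
    if (identical(terms[[v]], "numeric")) v
    else paste0(v, "_", terms[[v]][-1])))
  cols <- intersect(cols, colnames(mf))
  df <- cbind(y = labels, mf[, cols, drop = FALSE])
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  cf <- summary(fit)$coefficients
  sep <- !fit$converged || any(abs(cf[-1, 1]) > 15)
  out <- data.frame(term = rownames(cf)[-1], coef = cf[-1, 1],
                    or = exp(cf[-1, 1]),
                    ci_lo = exp(cf[-1, 1] - 1.96 * cf[-1, 2]),
                    ci_hi = exp(cf[-1, 1] + 1.96 * cf[-1, 2]),
                    p = cf[-1, 4], separation = sep)
  rownames(out) <- NULL
  attr(out, "clinical_features") <- out$term[out$p < 0.05]
  attr(out, "fit") <- fit
  class(out) <- c("logistic_screen", class(out))
  out
}

#' Gradient-boosting tuning configuration
#'
#' @param max_depth,eta,nrounds,subsample,colsample,lambda grid values.
#' @param cv_folds stratified CV folds.
#' @param seed RNG seed.
#' @return object of class `boost_config`.
#' @export
boost_config <- function(max_depth = c(2L, 3L, 4L),
                         eta = c(0.05, 0.1, 0.3),
                         nrounds = c(50L, 100L, 200L),
                         subsample = c(0.8, 1.0),
                         colsample = 1.0, lambda = 1.0,
                         cv_folds = 5L, seed = 1L) {
  stopifnot(cv_folds >= 2, length(max_depth) >= 1)
  structure(list(max_depth = max_depth, eta = eta,
                 nrounds = sort(as.integer(nrounds)), subsample = subsample,
                 colsample = colsample, lambda = lambda,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "boost_config")
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

xgb_fit <- function(x, y, depth, eta, nrounds, subsample, colsample,
                    lambda, seed) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
  params <- list(objective = "binary:logistic", max_depth = depth,
                 eta = eta, subsample = subsample,
                 colsample_bytree = colsample, lambda = lambda,
                 nthread = 1, seed = seed)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                     verbose = 0)
}

#' Tune and fit one gradient-boosted classifier
#'
#' Exhaustive grid scan under stratified k-fold CV; for each
#' (depth, eta, subsample) the model is trained once to `max(nrounds)` per
#' fold and evaluated at every `nrounds` value via prediction truncation.
#' The winner (highest mean validation AUC; ties toward fewer trees, then
#' shallower depth, then smaller eta) is refit on all training rows.
#'
#' @param x training feature data.frame/matrix (training rows ONLY; the
#'   function asserts no test-tagged rows reach it via the `split`
#'   attribute when present).
#' @param y binary outcome.
#' @param config a [boost_config()].
#' @return object of class `boosted_model`: the xgboost handle, feature
#'   names, chosen grid point, and the CV AUC table.
#' @export
tune_and_fit <- function(x, y, config = boost_config()) {
  y <- as.integer(y)
  if (!is.null(attr(x, "split")) && any(attr(x, "split") != "train"))
    stop("test rows reached tune_and_fit")  # leakage guard
  stopifnot(min(table(y)) >= config$cv_folds)
  xm <- as.matrix(x)
  fold <- stratified_folds(y, config$cv_folds, child_seed(config$seed, "folds"))
  grid <- expand.grid(depth = config$max_depth, eta = config$eta,
                      subsample = config$subsample,
                      colsample = config$colsample, lambda = config$lambda,
                      KEEP.OUT.ATTRS = FALSE)
  max_rounds <- max(config$nrounds)
  res <- list()
  for (gi in seq_len(nrow(grid))) {
    g <- grid[gi, ]
    auc_by_round <- matrix(NA_real_, config$cv_folds, length(config$nrounds))
    for (f in seq_len(config$cv_folds)) {
      tr <- fold != f
      fit <- xgb_fit(xm[tr, , drop = FALSE], y[tr], g$depth, g$eta,
                     max_rounds, g$subsample, g$colsample, g$lambda,
                     child_seed(config$seed, paste0("g", gi, "f", f)))
      for (ri in seq_along(config$nrounds)) {
        pr <- stats::predict(fit, xm[!tr, , drop = FALSE],
                             iterationrange = c(1, config$nrounds[ri]))
        auc_by_round[f, ri] <- auc_simple(pr, y[!tr])
      }
    }
    for (ri in seq_along(config$nrounds))
      res[[length(res) + 1]] <- cbind(g, nrounds = config$nrounds[ri],
                                      mean_auc = mean(auc_by_round[, ri]))
  }
  res <- do.call(rbind, res)
  # ties toward simpler: fewer trees, shallower, smaller eta
  ord <- order(-res$mean_auc, res$nrounds, res$depth, res$eta)
  best <- res[ord[1], ]
  final <- xgb_fit(xm, y, best$depth, best$eta, best$nrounds,
                   best$subsample, best$colsample, best$lambda,
                   child_seed(config$seed, "final"))
  structure(list(booster = final, feature_names = colnames(xm),
                 best = best, cv_table = res,
                 train_pred = stats::predict(final, xm)),
            class = "boosted_model")
}

#' @export
predict.boosted_model <- function(object, newdata, type = c("prob", "margin"),
                                  ...) {
  type <- match.arg(type)
  xm <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  stats::predict(object$booster, xm, outputmargin = (type == "margin"))
}

#' @export
print.boosted_model <- function(x, ...) {
  b <- x$best
  cat("Boosted classifier:", length(x$feature_names), "features;",
      sprintf("depth %d, eta %g, %d trees, subsample %g (CV AUC %.3f)\n",
              b$depth, b$eta, b$nrounds, b$subsample, b$mean_auc))
  invisible(x)
}

# train-fitted median imputation for missing habitat features
impute_median <- function(tab, train_ids) {
  med <- vapply(tab[train_ids, , drop = FALSE], function(v)
    stats::median(v, na.rm = TRUE), numeric(1))
  med[!is.finite(med)] <- 0
  for (j in seq_along(tab)) {
    nas <- is.na(tab[[j]])
    if (any(nas)) tab[nas, j] <- med[j]
  }
  tab
}

#' Build the four-model bundle
#'
#' clinical = multivariable-significant covariates; conventional / habitat =
#' the LASSO survivors of the respective pools; combined = fusion-pool
#' survivors plus the clinical features. Each is a gradient-boosted
#' classifier tuned on the training split only.
#'
#' @param tables list with `conventional`, `habitat`, `fusion` feature
#'   data.frames (all patients).
#' @param reports list of `selection_report`s keyed the same way.
#' @param clin clinical data.frame (all patients, rows named by id).
#' @param labels named binary outcome vector.
#' @param split named train/test assignment.
#' @param config a [boost_config()].
#' @return object of class `alnm_bundle` with fitted models, feature lists
#'   and train/test predictions.
#' @export
build_bundle <- function(tables, reports, clin, labels, split,
                         config = boost_config()) {
  ids <- rownames(clin)
  train_ids <- ids[split[ids] == "train"]
  y <- as.integer(labels[ids]); names(y) <- ids
  mf <- clinical_model_frame(clin)
  scr <- univariable_screen(clin[train_ids, ], y[train_ids])
  screened <- unique(scr$variable[scr$p < 0.05])
  if (!length(screened)) {
    warning("no clinical variable passed univariable screening; ",
            "falling back to the smallest-p variable")
    screened <- scr$variable[which.min(scr$p)]
  }
  mv <- multivariable_fit(clin[train_ids, ], y[train_ids], screened)
  clin_feats <- attr(mv, "clinical_features")
  if (!length(clin_feats)) clin_feats <- mv$term[which.min(mv$p)]
  feature_sets <- list(clinical = clin_feats)
  design <- list(clinical = mf)
  for (pool in c("conventional", "habitat", "fusion")) {
    if (is.null(reports[[pool]])) next
    sel <- reports[[pool]]$selected
    if (!length(sel)) stop("empty feature list for the ", pool, " pool")
    tab <- impute_median(tables[[pool]], train_ids)
    z <- apply_selection(reports[[pool]], tab)
    nm <- if (pool == "fusion") "combined" else pool
    design[[nm]] <- z
    feature_sets[[nm]] <- sel
  }
  if ("combined" %in% names(design)) {
    design$combined <- cbind(design$combined,
                             mf[rownames(design$combined), clin_feats,
                                drop = FALSE])
    feature_sets$combined <- c(feature_sets$combined, clin_feats)
  }
  models <- list(); preds <- list()
  for (nm in names(design)) {
    d <- design[[nm]][, feature_sets[[nm]], drop = FALSE]
    xtr <- d[train_ids, , drop = FALSE]
    attr(xtr, "split") <- rep("train", nrow(xtr))
    cfg <- config; cfg$seed <- child_seed(config$seed, nm)
    models[[nm]] <- tune_and_fit(xtr, y[train_ids], cfg)
    p <- predict.boosted_model(models[[nm]], d)
    names(p) <- rownames(d)
    preds[[nm]] <- p
  }
  structure(list(models = models, feature_sets = feature_sets,
                 predictions = preds, design = design,
                 univariable = scr, multivariable = mv,
                 labels = y, split = split[ids]),
            class = "alnm_bundle")
}

#' @export
print.alnm_bundle <- function(x, ...) {
  cat("ALNM model bundle (", paste(names(x$models), collapse = ", "), ")\n",
      sep = "")
  for (nm in names(x$models))
    cat(sprintf("  %-12s %3d features, CV AUC %.3f\n", nm,
                length(x$feature_sets[[nm]]), x$models[[nm]]$best$mean_auc))
  invisible(x)
}

#' @export
summary.alnm_bundle <- function(object, ...) {
  y <- object$labels; sp <- object$split
  out <- do.call(rbind, lapply(names(object$models), function(nm) {
    p <- object$predictions[[nm]]
    data.frame(model = nm,
               auc_train = auc_simple(p[sp == "train"], y[sp == "train"]),
               auc_test = auc_simple(p[sp == "test"], y[sp == "test"]))
  }))
  out
}
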