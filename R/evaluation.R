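# ---- model evaluation: ROC/AUC, DeLong, calibration, DCA, confusion ------
#
# All statistics are implemented from their definitions: AUC as the
# tie-corrected Mann-Whitney statistic, its variance and paired comparison
# via DeLong's placement-value (structural-component) method, the
# Hosmer-Lemeshow C statistic on deciles of risk, and net benefit
# NB(pt) = TP/n - FP/n * pt/(1-pt).

# tie-corrected AUC via midranks (fast path used inside CV loops)
auc_simple <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values: V10 (per case), V01 (per control)
delong_placements <- function(scores, labels) {
  labels <- as.integer(labels)
  x <- scores[labels == 1]; yv <- scores[labels == 0]
  m <- length(x); n <- length(yv)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(x, function(a) mean(psi(a, yv)), numeric(1))
  v01 <- vapply(yv, function(b) mean(psi(x, b)), numeric(1))
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' ROC curve and AUC with DeLong variance
#'
#' AUC equals the Mann-Whitney U statistic normalized by the number of
#' case/control pairs, ties counted one half. The variance is DeLong's
#' structural-component estimate; the 95% CI is normal-approximation,
#' clipped to \[0, 1\].
#'
#' @param scores numeric predictions (higher = more likely positive).
#' @param labels binary outcomes.
#' @return object of class `roc_result`: `auc`, `var`, `ci`, and the ROC
#'   points (FPR, TPR, threshold).
#' @export
auc_delong <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  pl <- delong_placements(scores, labels)
  v <- stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
  ci <- pmin(pmax(pl$auc + c(-1, 1) * stats::qnorm(0.975) * sqrt(v), 0), 1)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[labels == 0] >= t), numeric(1))
  structure(list(auc = pl$auc, var = v, ci = ci,
                 roc = data.frame(threshold = th, fpr = fpr, tpr = tpr)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$ci[1], x$ci[2]))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of two models' predictions on the same samples:
#' z = (AUC_A - AUC_B) / SE, with the SE from the DeLong covariance of the
#' placement values; two-sided normal p. Zero variance of the difference
#' (e.g. identical scores) returns p = 1 with a flag.
#'
#' @param scores_a,scores_b paired predictions.
#' @param labels binary outcomes.
#' @return list with `auc_a`, `auc_b`, `delta`, `z`, `p`, `flag`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / pa$m + s01 / pa$n
  vd <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  delta <- pa$auc - pb$auc
  if (vd < 1e-14) {
    return(list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, z = 0,
                p = 1, flag = "zero variance of difference"))
  }
  z <- delta / sqrt(vd)
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, z = z,
       p = 2 * stats::pnorm(-abs(z)), flag = NA_character_)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk grouping: equal-count bins by predicted probability with
#' ties kept in one bin; empty bins are merged with a neighbour (with a
#' warning). C statistic `sum((O - E)^2 / (E * (1 - E / n_g)))` with
#' df = g - 2.
#'
#' @param probs predicted probabilities.
#' @param labels binary outcomes.
#' @param g number of groups (default 10).
#' @return list with `statistic`, `df`, `p`, and the per-bin table.
#' @export
hosmer_lemeshow <- function(probs, labels, g = 10L) {
  labels <- as.integer(labels)
  n <- length(probs)
  stopifnot(n >= g, all(probs >= 0 & probs <= 1))
  qs <- stats::quantile(probs, probs = seq_len(g - 1) / g, names = FALSE,
                        type = 7)
  bin <- findInterval(probs, unique(qs), left.open = FALSE) + 1L
  bins <- sort(unique(bin))
  if (length(bins) < g)
    warning("tied probabilities reduced the Hosmer-Lemeshow bins to ",
            length(bins))
  tab <- do.call(rbind, lapply(bins, function(b) {
    sel <- bin == b
    data.frame(n = sum(sel), obs = sum(labels[sel]),
               exp = sum(probs[sel]), mean_p = mean(probs[sel]))
  }))
  denom <- tab$exp * (1 - tab$exp / tab$n)
  ok <- denom > 1e-12
  stat <- sum((tab$obs[ok] - tab$exp[ok])^2 / denom[ok])
  df <- max(length(bins) - 2, 1)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE), table = tab)
}

#' Decision curve: net benefit across threshold probabilities
#'
#' `NB(pt) = TP/n - FP/n * pt / (1 - pt)`, with treat-all and treat-none
#' reference strategies.
#'
#' @param probs predicted probabilities.
#' @param labels binary outcomes.
#' @param thresholds threshold grid in (0, 1).
#' @return data.frame with `threshold`, `net_benefit`, `treat_all`,
#'   `treat_none`.
#' @export
decision_curve <- function(probs, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  labels <- as.integer(labels)
  stopifnot(all(thresholds > 0 & thresholds < 1))
  n <- length(labels)
  prev <- mean(labels)
  nb <- vapply(thresholds, function(pt) {
    pos <- probs >= pt
    tp <- sum(pos & labels == 1); fp <- sum(pos & labels == 0)
    tp / n - fp / n * pt / (1 - pt)
  }, numeric(1))
  ta <- prev - (1 - prev) * thresholds / (1 - thresholds)
  data.frame(threshold = thresholds, net_benefit = nb,
             treat_all = ta, treat_none = 0)
}

#' Confusion metrics at a probability threshold
#'
#' accuracy, sensitivity, specificity, precision, PPV (identical to
#' precision by definition, asserted), NPV. Zero-denominator metrics are
#' returned as NA with a flag rather than NaN.
#'
#' @param probs predicted probabilities.
#' @param labels binary outcomes.
#' @param threshold classification threshold (default 0.5).
#' @return named list of metrics plus the confusion counts.
#' @export
confusion_metrics <- function(probs, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  sdiv <- function(a, b) if (b == 0) NA_real_ else a / b
  prec <- sdiv(tp, tp + fp)
  out <- list(accuracy = (tp + tn) / length(labels),
              sensitivity = sdiv(tp, tp + fn),
              specificity = sdiv(tn, tn + fp),
              precision = prec, ppv = prec, npv = sdiv(tn, tn + fn),
              tp = tp, fp = fp, fn = fn, tn = tn,
              flag = if (tp + fp == 0 || tn + fn == 0)
                "undefined metric (zero denominator)" else NA_character_)
  stopifnot(identical(out$precision, out$ppv))
  out
}

#' Calibration curve: per-bin mean predicted vs observed event fraction
#'
#' @param probs predicted probabilities.
#' @param labels binary outcomes.
#' @param bins number of equal-count bins.
#' @return data.frame with `mean_predicted`, `observed_fraction`, `n`.
#' @export
calibration_curve <- function(probs, labels, bins = 10L) {
  labels <- as.integer(labels)
  stopifnot(length(probs) >= bins)
  ord <- order(probs)
  grp <- ceiling(seq_along(ord) / (length(ord) / bins))
  out <- do.call(rbind, lapply(sort(unique(grp)), function(b) {
    sel <- ord[grp == b]
    data.frame(mean_predicted = mean(probs[sel]),
               observed_fraction = mean(labels[sel]), n = length(sel))
  }))
  out
}

#' Evaluate a fitted model bundle on train and test splits
#'
#' @param bundle an `alnm_bundle`.
#' @return object of class `alnm_evaluation`: per-model `roc_result`s,
#'   pairwise DeLong comparisons on the test split, Hosmer-Lemeshow,
#'   decision curves and threshold-0.5 confusion metrics.
#' @export
evaluate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "alnm_bundle"))
  y <- bundle$labels; sp <- bundle$split
  out <- list(roc = list(), hl = list(), dca = list(), confusion = list())
  for (nm in names(bundle$models)) {
    p <- bundle$predictions[[nm]]
    out$roc[[nm]] <- list(
      train = auc_delong(p[sp == "train"], y[sp == "train"]),
      test = auc_delong(p[sp == "test"], y[sp == "test"]))
    out$hl[[nm]] <- hosmer_lemeshow(p[sp == "test"], y[sp == "test"],
                                    g = min(10L, floor(sum(sp == "test") / 2)))
    out$dca[[nm]] <- decision_curve(p[sp == "test"], y[sp == "test"])
    out$confusion[[nm]] <- confusion_metrics(p[sp == "test"], y[sp == "test"])
  }
  nms <- names(bundle$models)
  pairs <- utils::combn(nms, 2)
  out$delong <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    dt <- delong_test(bundle$predictions[[a]][sp == "test"],
                      bundle$predictions[[b]][sp == "test"], y[sp == "test"])
    data.frame(model_a = a, model_b = b, auc_a = dt$auc_a, auc_b = dt$auc_b,
               delta = dt$delta, z = dt$z, p = dt$p)
  }))
  class(out) <- "alnm_evaluation"
  out
}

#' @export
print.alnm_evaluation <- function(x, ...) {
  cat("Model evaluation (test split):\n")
  for (nm in names(x$roc))
    cat(sprintf("  %-12s AUC %.3f (train %.3f)  HL p %.3f\n", nm,
                x$roc[[nm]]$test$auc, x$roc[[nm]]$train$auc, x$hl[[nm]]$p))
  cat("Pairwise DeLong (test):\n")
  print(x$delong, digits = 3)
  invisible(x)
}

#' Plot ROC curves (and optionally calibration) for a bundle evaluation
#' @param x an `alnm_evaluation`.
#' @param which `"roc"` or `"dca"`.
#' @param ... passed to plotting primitives.
#' @export
plot.alnm_evaluation <- function(x, which = c("roc", "dca"), ...) {
  which <- match.arg(which)
  nms <- names(x$roc)
  cols <- seq_along(nms) + 1
  if (which == "roc") {
    graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey",
                   xlab = "False positive rate", ylab = "True positive rate",
                   main = "ROC (test split)")
    for (i in seq_along(nms)) {
      r <- x$roc[[nms[i]]]$test$roc
      graphics::lines(r$fpr, r$tpr, col = cols[i], lwd = 2)
    }
    graphics::legend("bottomright", sprintf("%s (AUC %.2f)", nms,
      vapply(nms, function(n) x$roc[[n]]$test$auc, numeric(1))),
      col = cols, lwd = 2, bty = "n")
  } else {
    d1 <- x$dca[[1]]
    graphics::plot(d1$threshold, d1$treat_all, type = "l", col = "grey",
                   ylim = c(-0.05, max(vapply(x$dca, function(d)
                     max(d$net_benefit), numeric(1)), d1$treat_all)),
                   xlab = "Threshold probability", ylab = "Net benefit",
                   main = "Decision curves (test split)")
    graphics::abline(h = 0, col = "grey")
    for (i in seq_along(nms))
      graphics::lines(x$dca[[nms[i]]]$threshold,
                      x$dca[[nms[i]]]$net_benefit, col = cols[i], lwd = 2)
    graphics::legend("topright", nms, col = cols, lwd = 2, bty = "n")
  }
  invisible(x)
}
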