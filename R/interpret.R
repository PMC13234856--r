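# ---- Shapley-value interpretation of the boosted models -------------------
#
# Attributions are exact tree-Shapley values in log-odds (margin) space,
# computed by the boosting engine's path-dependent TreeSHAP. Local accuracy
# (base value + sum of attributions = margin output) holds exactly for
# every sample; the brute-force subset-enumeration oracle in the test suite
# cross-checks the values on small trees.

#' Shapley attributions for a boosted model
#'
#' @param model a `boosted_model` (from [tune_and_fit()] or a bundle).
#' @param newdata data.frame of samples to explain (e.g. the test split);
#'   columns must match the training schema.
#' @return object of class `shap_explanation`: `base_value` (expected
#'   margin), `attributions` (samples x features), `output` (per-sample
#'   margin), `space = "log-odds"`.
#' @export
explain_model <- function(model, newdata) {
  stopifnot(inherits(model, "boosted_model"))
  if (!all(model$feature_names %in% colnames(newdata)))
    stop("feature schema mismatch: missing ",
         paste(setdiff(model$feature_names, colnames(newdata)), collapse = ", "))
  xm <- as.matrix(newdata[, model$feature_names, drop = FALSE])
  contrib <- stats::predict(model$booster, xm, predcontrib = TRUE)
  contrib <- matrix(contrib, nrow = nrow(xm),
                    dimnames = list(rownames(newdata),
                                    c(model$feature_names, "BIAS")))
  phi <- contrib[, model$feature_names, drop = FALSE]
  base <- contrib[, "BIAS"]
  out <- stats::predict(model$booster, xm, outputmargin = TRUE)
  structure(list(base_value = unname(base[1]), attributions = phi,
                 output = out, feature_names = model$feature_names,
                 space = "log-odds"),
            class = "shap_explanation")
}

#' @export
print.shap_explanation <- function(x, ...) {
  cat("Shapley explanation:", nrow(x$attributions), "samples x",
      ncol(x$attributions), "features (", x$space, "space )\n")
  imp <- utils::head(global_importance(x), 5)
  cat("top features:\n")
  print(round(imp, 4))
  invisible(x)
}

#' Global feature importance: mean absolute attribution
#'
#' @param explanation a `shap_explanation`.
#' @return named numeric vector, descending; ties in stable name order.
#' @export
global_importance <- function(explanation) {
  stopifnot(inherits(explanation, "shap_explanation"))
  imp <- colMeans(abs(explanation$attributions))
  imp[order(-imp, names(imp))]
}

#' Waterfall data for one sample
#'
#' Contributions ordered by decreasing |attribution|; the cumulative sum
#' starts at the base value and ends at the sample's model output.
#'
#' @param explanation a `shap_explanation`.
#' @param sample_id row name or index.
#' @return data.frame with `feature`, `attribution`, `cumulative`.
#' @export
waterfall_data <- function(explanation, sample_id) {
  stopifnot(inherits(explanation, "shap_explanation"))
  phi <- explanation$attributions
  if (is.character(sample_id) && !sample_id %in% rownames(phi))
    stop("unknown sample: ", sample_id)
  v <- phi[sample_id, ]
  ord <- order(-abs(v), names(v))
  v <- v[ord]
  data.frame(feature = names(v), attribution = unname(v),
             cumulative = explanation$base_value + cumsum(unname(v)))
}

#' Export figure-ready attribution summaries
#'
#' Writes the bar (global importance), beeswarm (long per-sample table) and
#' per-sample waterfall data as CSV/JSON into a directory.
#'
#' @param explanation a `shap_explanation`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
export_shap <- function(explanation, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  imp <- global_importance(explanation)
  utils::write.csv(data.frame(feature = names(imp), mean_abs_shap = imp),
                   file.path(dir, "shap_importance.csv"), row.names = FALSE)
  phi <- explanation$attributions
  long <- data.frame(sample = rep(rownames(phi) %||%
                                  as.character(seq_len(nrow(phi))), ncol(phi)),
                     feature = rep(colnames(phi), each = nrow(phi)),
                     shap = as.vector(phi))
  utils::write.csv(long, file.path(dir, "shap_beeswarm.csv"), row.names = FALSE)
  jsonlite::write_json(list(base_value = explanation$base_value,
                            space = explanation$space),
                       file.path(dir, "shap_meta.json"), auto_unbox = TRUE)
  invisible(dir)
}
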