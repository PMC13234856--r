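# ---- end-to-end pipeline orchestration ------------------------------------
#
# generate -> preprocess -> habitats -> features -> select -> train ->
# evaluate -> explain, driven by one nested configuration, with per-stage
# caching keyed by a configuration hash and a JSON provenance manifest.

#' Pipeline configuration
#'
#' Nested configurations for every stage plus stage toggles, the output
#' directory and the global seed (from which all stage seeds derive).
#'
#' @param synthetic a [synthetic_config()].
#' @param preprocess a [preprocess_config()].
#' @param features a [feature_bank_config()].
#' @param selection a [selection_config()].
#' @param boost a [boost_config()].
#' @param train_frac training fraction for the stratified split.
#' @param window sliding-window edge for voxel feature maps.
#' @param n_supervoxels per-study SLIC target (NULL = ~1 per 100 mm^3).
#' @param compactness SLIC compactness.
#' @param k_range candidate habitat counts.
#' @param use_icc run the ICC reproducibility stage (requires rater-2
#'   feature extraction, which doubles extraction cost).
#' @param stages character vector of stages to run.
#' @param output_dir results directory (NULL = no files written).
#' @param seed global seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            preprocess = preprocess_config(),
                            features = feature_bank_config(),
                            selection = selection_config(),
                            boost = boost_config(),
                            train_frac = 0.7,
                            window = 3L, n_supervoxels = NULL,
                            compactness = 0.1, k_range = 2:10,
                            use_icc = TRUE,
                            stages = c("generate", "preprocess", "habitats",
                                       "features", "select", "train",
                                       "evaluate", "explain"),
                            output_dir = NULL, seed = 1L) {
  structure(list(synthetic = synthetic, preprocess = preprocess,
                 features = features, selection = selection, boost = boost,
                 train_frac = train_frac, window = as.integer(window),
                 n_supervoxels = n_supervoxels, compactness = compactness,
                 k_range = k_range, use_icc = use_icc, stages = stages,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(x) {
  # stable short hash of a configuration subtree for stage caching
  s <- paste(utils::capture.output(utils::str(x, digits.d = 10)), collapse = "\n")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 251 + 1)) %% 4294967291)
}

#' Run the habitat-radiomics pipeline end to end
#'
#' Executes the enabled stages in order; each stage's result is cached in
#' the returned object (and on disk when `output_dir` is set) keyed by the
#' hash of the configuration that produced it. Downstream stages refuse to
#' run when an upstream result is missing.
#'
#' @param config a [pipeline_config()].
#' @param state optional previous `alnm_pipeline` object to reuse cached
#'   stages from.
#' @param verbose log per-stage progress.
#' @return object of class `alnm_pipeline` with entries per stage:
#'   `cohort`, `split`, `habitats`, `tables`, `reports`, `bundle`,
#'   `evaluation`, `explanation`, and a `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), state = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- state %||% structure(list(manifest = list()), class = "alnm_pipeline")
  log <- function(...) if (verbose) message(sprintf(...))
  t_stage <- function(stage, hash, expr) {
    cached <- !is.null(st$manifest[[stage]]) &&
      identical(st$manifest[[stage]]$hash, hash)
    if (cached) { log("[%s] cached", stage); return(NULL) }
    t0 <- proc.time()[3]
    val <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    st$manifest[[stage]] <<- list(hash = hash,
                                  seconds = round(proc.time()[3] - t0, 2))
    log("[%s] done in %.1fs", stage, proc.time()[3] - t0)
    val
  }
  need <- function(what, stage) {
    if (is.null(st[[what]]))
      stop("stage '", stage, "' needs '", what,
           "' but that stage has not been run", call. = FALSE)
    st[[what]]
  }
  if ("generate" %in% config$stages) {
    h <- config_hash(config$synthetic)
    v <- t_stage("generate", h, {
      cohort <- generate_cohort(config$synthetic)
      split <- split_cohort(cohort, config$train_frac,
                            seed = child_seed(config$seed, "split"))
      list(cohort = cohort, split = split)
    })
    if (!is.null(v)) { st$cohort <- v$cohort; st$split <- v$split }
  }
  if ("preprocess" %in% config$stages) {
    h <- config_hash(list(config$synthetic, config$preprocess))
    v <- t_stage("preprocess", h,
      preprocess_cohort(need("cohort", "preprocess"), config$preprocess))
    if (!is.null(v)) st$cohort <- v
  }
  if ("habitats" %in% config$stages) {
    h <- config_hash(list(config$synthetic, config$preprocess, config$window,
                          config$n_supervoxels, config$compactness,
                          config$k_range, config$seed))
    v <- t_stage("habitats", h,
      build_habitats(need("cohort", "habitats"), need("split", "habitats"),
                     window = config$window,
                     n_supervoxels = config$n_supervoxels,
                     compactness = config$compactness,
                     k_range = config$k_range,
                     seed = child_seed(config$seed, "habitats")))
    if (!is.null(v)) st$habitats <- v
  }
  if ("features" %in% config$stages) {
    h <- config_hash(list(config$synthetic, config$features, config$use_icc))
    v <- t_stage("features", h, {
      cohort <- need("cohort", "features")
      maps <- need("habitats", "features")$maps
      tabs <- extract_cohort_tables(cohort, maps, config$features)
      tabs2 <- if (config$use_icc)
        extract_cohort_tables(cohort, maps, config$features, masks = "rater2")
      else NULL
      list(tables = tabs, tables_rater2 = tabs2)
    })
    if (!is.null(v)) { st$tables <- v$tables; st$tables_rater2 <- v$tables_rater2 }
  }
  if ("select" %in% config$stages) {
    h <- config_hash(list(config$synthetic, config$features, config$selection,
                          config$use_icc))
    v <- t_stage("select", h, {
      tabs <- need("tables", "select")
      cohort <- need("cohort", "select")
      labels <- stats::setNames(cohort$clinical$alnm,
                                cohort$clinical$patient_id)
      sel_cfg <- config$selection
      sel_cfg$seed <- child_seed(config$seed, "lasso")
      lapply(stats::setNames(nm = names(tabs)), function(pool)
        select_features(tabs[[pool]],
                        if (config$use_icc) st$tables_rater2[[pool]] else NULL,
                        labels, need("split", "select"), sel_cfg))
    })
    if (!is.null(v)) st$reports <- v
  }
  if ("train" %in% config$stages) {
    h <- config_hash(list(config$synthetic, config$features, config$selection,
                          config$boost, config$use_icc))
    v <- t_stage("train", h, {
      cohort <- need("cohort", "train")
      labels <- stats::setNames(cohort$clinical$alnm,
                                cohort$clinical$patient_id)
      clin <- cohort$clinical
      rownames(clin) <- clin$patient_id
      bcfg <- config$boost
      bcfg$seed <- child_seed(config$seed, "boost")
      build_bundle(need("tables", "train"), need("reports", "train"),
                   clin, labels, need("split", "train"), bcfg)
    })
    if (!is.null(v)) st$bundle <- v
  }
  if ("evaluate" %in% config$stages) {
    h <- config_hash(list(config$synthetic, config$boost, config$selection))
    v <- t_stage("evaluate", h, evaluate_bundle(need("bundle", "evaluate")))
    if (!is.null(v)) st$evaluation <- v
  }
  if ("explain" %in% config$stages) {
    h <- config_hash(list(config$synthetic, config$boost, "explain"))
    v <- t_stage("explain", h, {
      bundle <- need("bundle", "explain")
      test_ids <- names(bundle$split)[bundle$split == "test"]
      explain_model(bundle$models$combined %||% bundle$models[[1]],
                    (bundle$design$combined %||%
                     bundle$design[[1]])[test_ids, , drop = FALSE])
    })
    if (!is.null(v)) st$explanation <- v
  }
  if (!is.null(config$output_dir)) write_pipeline_outputs(st, config)
  st$config <- config
  st
}

write_pipeline_outputs <- function(st, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(st$manifest, file.path(config$output_dir,
                                              "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(st$evaluation)) {
    for (nm in names(st$evaluation$roc)) {
      d <- file.path(config$output_dir, nm)
      dir.create(d, showWarnings = FALSE)
      utils::write.csv(st$evaluation$roc[[nm]]$test$roc,
                       file.path(d, "roc_test.csv"), row.names = FALSE)
      utils::write.csv(st$evaluation$dca[[nm]],
                       file.path(d, "dca_test.csv"), row.names = FALSE)
    }
    utils::write.csv(st$evaluation$delong,
                     file.path(config$output_dir, "delong_pairwise.csv"),
                     row.names = FALSE)
  }
  if (!is.null(st$explanation))
    export_shap(st$explanation, file.path(config$output_dir, "combined"))
  invisible(config$output_dir)
}

#' @export
print.alnm_pipeline <- function(x, ...) {
  cat("Habitat-radiomics pipeline state; completed stages:\n  ",
      paste(names(x$manifest), collapse = ", "), "\n", sep = "")
  if (!is.null(x$habitats))
    cat("  habitat model: K =", x$habitats$model$K, "\n")
  if (!is.null(x$evaluation)) {
    s <- vapply(names(x$evaluation$roc), function(nm)
      x$evaluation$roc[[nm]]$test$auc, numeric(1))
    cat("  test AUCs:", paste(sprintf("%s %.3f", names(s), s),
                              collapse = ", "), "\n")
  }
  invisible(x)
}
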