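# five-stage selection cascade: ICC, univariate filter, Spearman pruning,
# mRMR, LASSO, and the nesting/train-only invariants

test_that("ICC(2,1) matches the two-way ANOVA mean-squares oracle", {
  # 6-subject hand table
  r1 <- c(9, 6, 8, 7, 10, 6)
  r2 <- c(10, 6, 9, 8, 10, 7)
  # oracle via aov mean squares
  df <- data.frame(y = c(r1, r2),
                   subj = factor(rep(1:6, 2)), rater = factor(rep(1:2, each = 6)))
  ms <- summary(stats::aov(y ~ subj + rater, df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 6; k <- 2
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc21(r1, r2), icc_oracle, tolerance = 1e-12)
  # identical raters with between-subject variance: 1
  expect_equal(icc21(r1, r1), 1, tolerance = 1e-12)
  # constant offset penalized by absolute agreement
  expect_lt(icc21(r1, r1 + 5), 1)
  expect_gt(icc21(r1, r1 + 5), 0)
  # zero between-subject variance: 0 with degenerate flag
  z <- icc21(rep(3, 5), rep(3, 5))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
})

test_that("icc_filter keeps reproducible features only", {
  set.seed(1)
  base <- matrix(stats::rnorm(40 * 3), 40)
  colnames(base) <- c("good", "noisy", "flat")
  t1 <- as.data.frame(base)
  t2 <- t1
  t2$good <- t1$good + stats::rnorm(40, sd = 0.05)   # near-identical
  t2$noisy <- stats::rnorm(40)                       # unrelated
  t1$flat <- 1; t2$flat <- 1                         # zero variance
  out <- icc_filter(t1, t2, threshold = 0.9)
  expect_true("good" %in% out$survivors)
  expect_false("noisy" %in% out$survivors)
  expect_false("flat" %in% out$survivors)
})

test_that("univariate filter retains signal, excludes constants, gates by normality", {
  set.seed(2)
  n <- 87
  y <- rep(c(0, 1), length.out = n)
  tab <- data.frame(signal = y + stats::rnorm(n, sd = 0.05),
                    noise = stats::rnorm(n),
                    constant = rep(1, n),
                    skewed = exp(stats::rnorm(n)))
  out <- univariate_filter(tab, y, selection_config())
  expect_true("signal" %in% out$survivors)
  expect_false("constant" %in% out$survivors)
  expect_match(out$excluded["constant"], "constant")
  # heavy-tailed feature routed to Mann-Whitney
  expect_equal(unname(out$test["skewed"]), "mann_whitney")
  # near-normal feature routed to the Welch t-test
  expect_equal(unname(out$test["noise"]), "welch_t")
})

test_that("univariate type-I error is near nominal on pure noise", {
  set.seed(3)
  n <- 87
  y <- rep(c(0, 1), length.out = n)
  m <- 400
  tab <- as.data.frame(matrix(stats::rnorm(n * m), n))
  out <- univariate_filter(tab, y, selection_config())
  rate <- length(out$survivors) / m
  # binomial 99% envelope around 0.05
  expect_lt(abs(rate - 0.05), 2.6 * sqrt(0.05 * 0.95 / m))
})

test_that("Spearman pruning removes duplicates and matches a greedy hand oracle", {
  set.seed(4)
  n <- 60
  a <- stats::rnorm(n)
  tab <- data.frame(a = a, dup = a, mono = exp(a),
                    b = stats::rnorm(n), c = stats::rnorm(n))
  pr <- stats::setNames(c(1, 2, 3, 4, 5), colnames(tab))
  out <- spearman_prune(tab, colnames(tab), cutoff = 0.9, priority = pr)
  # exactly one of each perfectly-correlated block survives, the best one
  expect_true("a" %in% out)
  expect_false("dup" %in% out)
  expect_false("mono" %in% out)   # |rho| = 1 with a
  expect_true(all(c("b", "c") %in% out))
  # no surviving pair exceeds the cutoff
  rho <- abs(stats::cor(tab[, out], method = "spearman"))
  expect_true(all(rho[upper.tri(rho)] <= 0.9))
  # hand oracle on a 6-feature structure: greedy by priority
  x1 <- stats::rnorm(n); x2 <- x1 + stats::rnorm(n, sd = 0.01)
  x3 <- stats::rnorm(n); x4 <- x3 + stats::rnorm(n, sd = 0.01)
  tab2 <- data.frame(f1 = x1, f2 = x2, f3 = x3, f4 = x4,
                     f5 = stats::rnorm(n), f6 = stats::rnorm(n))
  pr2 <- stats::setNames(c(0.2, 0.1, 0.3, 0.05, 0.5, 0.6), colnames(tab2))
  out2 <- spearman_prune(tab2, colnames(tab2), cutoff = 0.9, priority = pr2)
  expect_setequal(out2, c("f4", "f2", "f5", "f6"))  # best of each block
})

test_that("mRMR FCQ picks match brute-force maximization", {
  set.seed(5)
  n <- 80
  y <- rep(c(0, 1), length.out = n)
  best <- y + stats::rnorm(n, sd = 0.3)
  tab <- data.frame(best = best, dupbest = best,
                    weak = y + stats::rnorm(n, sd = 0.31),
                    n1 = stats::rnorm(n), n2 = stats::rnorm(n))
  # single candidate: itself
  expect_equal(mrmr_select(tab, y, k = 1, candidates = "weak"), "weak")
  # duplicated best feature is not chosen second (redundancy ~ 1)
  sel2 <- mrmr_select(tab, y, k = 2)
  expect_equal(sel2[1], "best")
  expect_false(sel2[2] == "dupbest")
  # exhaustive oracle over ordered pairs for k = 2
  fstat <- function(x) {
    g <- factor(y)
    gm <- tapply(x, g, mean); ng <- tapply(x, g, length)
    ssb <- sum(ng * (gm - mean(x))^2); ssw <- sum((x - gm[g])^2)
    (ssb / 1) / (ssw / (n - 2))
  }
  cands <- colnames(tab)
  f_rel <- vapply(cands, function(f) fstat(tab[[f]]), numeric(1))
  first <- cands[which.max(f_rel)]
  others <- setdiff(cands, first)
  q <- vapply(others, function(f)
    f_rel[f] / abs(stats::cor(tab[[f]], tab[[first]])), numeric(1))
  expect_equal(sel2, c(first, others[which.max(q)]))
  # k larger than available: select all with a warning
  expect_warning(all5 <- mrmr_select(tab, y, k = 10), "available")
  expect_setequal(all5, cands)
})

test_that("LASSO selection is deterministic, finds planted signal, matches glm at lambda ~ 0", {
  set.seed(6)
  n <- 120
  y <- rep(c(0, 1), length.out = n)
  tab <- as.data.frame(matrix(stats::rnorm(n * 10), n))
  colnames(tab) <- paste0("f", 1:10)
  tab$f1 <- y * 2 + stats::rnorm(n, sd = 0.8)   # strong predictor
  hits <- vapply(1:10, function(s)
    "f1" %in% lasso_select(tab, y, folds = 5, seed = s)$survivors, logical(1))
  expect_gte(sum(hits), 9)
  # determinism under a fixed seed
  a <- lasso_select(tab, y, folds = 5, seed = 3)
  b <- lasso_select(tab, y, folds = 5, seed = 3)
  expect_identical(a$survivors, b$survivors)
  expect_identical(a$lambda, b$lambda)
  # unpenalized limit: glmnet at tiny lambda matches glm coefficients
  xs <- scale(as.matrix(tab[, c("f1", "f2")]))
  fit_glmnet <- glmnet::glmnet(xs, y, family = "binomial", lambda = 1e-5,
                               standardize = FALSE, thresh = 1e-12)
  fit_glm <- stats::glm(y ~ xs, family = stats::binomial())
  expect_equal(as.numeric(stats::coef(fit_glmnet)),
               as.numeric(stats::coef(fit_glm)), tolerance = 1e-3)
})

test_that("cascade output is nested, train-only, and small on planted data", {
  set.seed(7)
  n <- 100
  ids <- sprintf("P%03d", 1:n)
  y <- stats::setNames(rep(c(0L, 1L), length.out = n), ids)
  m <- 60
  tab <- as.data.frame(matrix(stats::rnorm(n * m), n))
  colnames(tab) <- paste0("f", seq_len(m))
  rownames(tab) <- ids
  for (j in 1:4) tab[[j]] <- y * (1 + j / 4) + stats::rnorm(n, sd = 1)
  tab$f9 <- tab$f1 + stats::rnorm(n, sd = 0.01)   # redundant copy
  tab2 <- tab + matrix(stats::rnorm(n * m, sd = 0.02), n)  # rater 2
  rownames(tab2) <- ids
  split <- stats::setNames(rep(c("train", "test"), c(70, 30)), ids)
  rep_ <- suppressWarnings(
    select_features(tab, tab2, y, split,
                    selection_config(mrmr_k = 10, lasso_folds = 5,
                                     seed = 2)))
  st <- rep_$stages
  expect_true(all(st$univariate$survivors %in% st$icc$survivors))
  expect_true(all(st$spearman$survivors %in% st$univariate$survivors))
  expect_true(all(st$mrmr$survivors %in% st$spearman$survivors))
  expect_true(all(st$lasso$survivors %in% st$mrmr$survivors))
  # planted features retained, redundant copy pruned, set is small
  expect_true(any(c("f1", "f9") %in% rep_$selected))
  expect_false(all(c("f1", "f9") %in% rep_$selected))
  expect_lte(length(rep_$selected), 10)
  expect_gte(length(rep_$selected), 1)
  # standardization parameters come from the training rows only
  f <- rep_$selected[1]
  tr_rows <- names(split)[split == "train"]
  expect_equal(unname(rep_$scaling$mean[f]), mean(tab[tr_rows, f]),
               tolerance = 1e-12)
  # applying the selection gives standardized train columns
  z <- apply_selection(rep_, tab)
  expect_lt(abs(mean(z[tr_rows, f])), 1e-10)
})
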