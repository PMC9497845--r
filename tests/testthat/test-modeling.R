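blobs <- function(n = 40, sep = 10, seed = 1, p = 4) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n / 2 * p), ncol = p),
             matrix(rnorm(n / 2 * p, mean = sep), ncol = p))
  df <- as.data.frame(X)
  df$label <- rep(c("noncancer", "cancer"), each = n / 2)
  df
}

test_that("every model separates far-apart blobs perfectly", {
  f <- blobs()
  for (mn in lsdlspectra:::model_names) {
    r <- evaluate_cv(f, mn, cv_config(seed = 1))
    expect_equal(unname(c(r$acc, r$sens, r$spec, r$auc)), rep(100, 4),
                 info = mn)
  }
})

test_that("pooled confusion counts always sum to the dataset size", {
  f <- blobs(n = 60, sep = 0.5, seed = 2)
  for (mn in c("DT", "LDA", "KNN", "LSVM", "LR")) {
    r <- evaluate_cv(f, mn, cv_config(seed = 2))
    expect_equal(sum(r$confusion), 60, info = mn)
  }
})

test_that("label permutation gives chance-level accuracy", {
  accs <- vapply(1:20, function(sd) {
    f <- blobs(n = 62, sep = 8, seed = sd)
    set.seed(1000 + sd)
    f$label <- sample(f$label)
    r <- evaluate_cv(f, "LDA", cv_config(seed = sd))
    r$raw[["acc"]]
  }, numeric(1))
  expect_gte(median(accs), 40)
  expect_lte(median(accs), 60)
})

test_that("SMOTE before CV inflates null accuracy; fold-internal SMOTE does not", {
  accs <- vapply(1:5, function(sd) {
    set.seed(400 + sd)
    f <- data.frame(matrix(rnorm(53 * 6), ncol = 6))
    f$label <- rep(c("noncancer", "cancer"), c(31, 22))
    bal <- balance_spec(seed = sd); cv <- cv_config(seed = sd)
    leaky <- evaluate_cv(smote_balance(f, bal), "KNN", cv)$raw[["acc"]]
    safe <- evaluate_cv(f, "KNN", cv, balance = bal)$raw[["acc"]]
    c(leaky, safe)
  }, numeric(2))
  expect_gt(mean(accs[1, ]), mean(accs[2, ]))
  expect_lt(abs(mean(accs[2, ]) - 50), 12)   # fold-safe stays near chance
})

test_that("QDA reports n/a on a singular class covariance", {
  f <- blobs(n = 40, seed = 3)
  f$V4 <- f$V3                          # duplicated column -> singular
  r <- evaluate_cv(f, "QDA", cv_config(seed = 3))
  expect_true(is.na(r$acc))
  expect_match(r$reason, "rank|singular|deficiency", ignore.case = TRUE)
  tab <- evaluate_models(f, models = c("LDA", "QDA"), cv = cv_config(seed = 3))
  expect_true(is.na(tab$acc[tab$model == "QDA"]))
  expect_false(is.na(tab$acc[tab$model == "LDA"]))
})

test_that("swapping the positive-class convention swaps Sens and Spec", {
  f <- blobs(n = 40, sep = 1.2, seed = 4)
  r1 <- evaluate_cv(f, "LDA", cv_config(seed = 4))
  f2 <- f
  # same partition structure; "cancer" rows are now the negative class
  f2$label <- ifelse(f$label == "cancer", "low_grade", "high_grade")
  r2 <- evaluate_cv(f2, "LDA", cv_config(seed = 4))
  expect_equal(r1$raw[["sens"]], r2$raw[["spec"]])
  expect_equal(r1$raw[["spec"]], r2$raw[["sens"]])
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(5)
  score <- rnorm(100); y <- rbinom(100, 1, plogis(score))
  a1 <- lsdlspectra:::auc_score(score, y)
  a2 <- lsdlspectra:::auc_score(exp(score), y)
  a3 <- lsdlspectra:::auc_score(rank(score), y)
  expect_equal(a1, a2)
  expect_equal(a1, a3)
})

test_that("fold assignment is reproducible and stratified", {
  labels <- rep(c("a", "b"), c(31, 31))
  f1 <- lsdlspectra:::make_folds(labels, cv_config(seed = 7))
  f2 <- lsdlspectra:::make_folds(labels, cv_config(seed = 7))
  expect_identical(f1, f2)
  expect_false(identical(f1, lsdlspectra:::make_folds(labels, cv_config(seed = 8))))
  per_fold <- table(f1[labels == "a"])
  expect_lte(max(per_fold) - min(per_fold), 1)
})

test_that("run_grid yields one nine-row table per dataset, deterministically", {
  dsets <- list(d1 = blobs(seed = 9), d2 = blobs(seed = 10))
  g1 <- run_grid(dsets, cv = cv_config(seed = 1))
  g2 <- run_grid(dsets, cv = cv_config(seed = 1))
  expect_named(g1, c("d1", "d2"))
  expect_equal(nrow(g1$d1), 9)
  expect_identical(as.data.frame(g1$d1), as.data.frame(g2$d1))
  lines <- format_metrics_table(g1$d1)
  expect_length(lines, 10)
  expect_match(lines[1], "Acc \\(%\\)")
})

test_that("metrics table writes n/a literals to CSV", {
  f <- blobs(n = 40, seed = 3)
  f$V4 <- f$V3
  tab <- evaluate_models(f, models = c("QDA", "LR"), cv = cv_config(seed = 3))
  p <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(tab, p)
  txt <- readLines(p)
  expect_match(txt[2], "n/a")
})

test_that("PCA projection keeps enough components and conserves variance", {
  set.seed(6)
  r1 <- matrix(rnorm(30), ncol = 3)
  rank1 <- r1[, c(1, 1, 1)] + matrix(rnorm(30, sd = 1e-8), ncol = 3)
  pr <- pca_projection(as.data.frame(rank1))
  expect_equal(pr$n_components, 1)
  expect_gt(pr$explained[1], 0.99)

  X <- as.data.frame(matrix(rnorm(200), ncol = 5))
  pr2 <- pca_projection(X, variance_target = 0.98)
  expect_equal(sum(pr2$explained), 1, tolerance = 1e-12)
  expect_gte(sum(pr2$explained[seq_len(pr2$n_components)]), 0.98)
  expect_error(pca_projection(as.data.frame(matrix(1, 10, 3))), "constant")
})
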