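#' Cross-validation configuration
#'
#' @param folds number of folds (default 10).
#' @param stratified stratify fold assignment by class (default TRUE).
#' @param seed RNG seed governing the fold partition.
#' @return list of class `"cv_config"`.
#' @export
cv_config <- function(folds = 10L, stratified = TRUE, seed = 1L) {
  if (folds < 2) stop("folds must be >= 2")
  structure(list(folds = as.integer(folds), stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "cv_config")
}

# Fold assignment depends only on (seed, labels, n).
make_folds <- function(labels, cv) {
  set.seed(cv$seed)
  n <- length(labels)
  fold <- integer(n)
  if (cv$stratified) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep(seq_len(cv$folds), length.out = length(idx)))
    }
  } else {
    fold <- sample(rep(seq_len(cv$folds), length.out = n))
  }
  fold
}

# The class treated as "positive" in sensitivity/AUC.
positive_class <- function(labels) {
  u <- unique(labels)
  hit <- intersect(c("cancer", "high_grade"), u)
  if (length(hit)) hit[1] else sort(u)[2]
}

# Rank-based AUC (equals the trapezoidal ROC area, ties handled).
auc_score <- function(score, y01) {
  n1 <- sum(y01 == 1); n0 <- sum(y01 == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[y01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

round_half_up <- function(x) floor(x + 0.5)

#' Cross-validated metrics for one model
#'
#' Stratified K-fold CV with per-fold z-scoring from training-fold
#' statistics; out-of-fold predictions are pooled into a single confusion
#' matrix (not fold-averaged). Sensitivity takes `"cancer"` /
#' `"high_grade"` as the positive class; AUC is computed from pooled
#' continuous scores. A model-fitting failure on any fold (e.g. a
#' singular class covariance for QDA) yields an "n/a" row carrying the
#' failure reason rather than an error.
#'
#' @param features data.frame of numeric features plus a `label` column.
#' @param model a [model_spec()] or model name.
#' @param cv a [cv_config()].
#' @param balance optional [balance_spec()]: when given, SMOTE is re-run
#'   inside each training fold (leakage-safe placement) instead of the
#'   caller balancing the whole table up front.
#' @return list of class `"metrics_row"`: `model`, `acc`/`sens`/`spec`/
#'   `auc` (integer percent, the usual rounded-table convention), `raw`
#'   (unrounded), `confusion`, `n`, and `reason` when n/a.
#' @export
evaluate_cv <- function(features, model, cv = cv_config(), balance = NULL) {
  if (is.character(model)) model <- model_spec(model)
  labels <- as.character(features$label)
  fcols <- setdiff(names(features), c("label", "is_synthetic"))
  X <- as.matrix(features[, fcols, drop = FALSE])
  pos <- positive_class(labels)
  y01 <- as.integer(labels == pos)
  if (min(table(y01)) < cv$folds) {
    if (is.null(balance))
      stop("each class needs at least `folds` members")
    # fold-internal balancing runs on the real (unbalanced) rows; cap the
    # fold count at the smallest class so every fold sees both classes
    cv$folds <- as.integer(min(table(y01)))
    message(sprintf("reducing folds to %d (smallest real class)", cv$folds))
  }
  fold <- make_folds(labels, cv)
  pred <- integer(length(y01)); score <- numeric(length(y01))
  na_reason <- NULL
  for (f in seq_len(cv$folds)) {
    tr <- fold != f; te <- !tr
    Xtr <- X[tr, , drop = FALSE]; ytr <- y01[tr]
    if (!is.null(balance)) {
      bspec <- balance
      bspec$seed <- balance$seed + f
      btab <- smote_balance(
        data.frame(X[tr, , drop = FALSE],
                   label = labels[tr], check.names = FALSE), bspec)
      Xtr <- as.matrix(btab[, fcols, drop = FALSE])
      ytr <- as.integer(btab$label == pos)
    }
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Ztr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
    Zte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sdv, "/")
    res <- tryCatch(fit_predict_model(model, Ztr, ytr, Zte),
                    error = function(e) e)
    if (inherits(res, "error")) { na_reason <- conditionMessage(res); break }
    pred[te] <- res$pred; score[te] <- res$score
  }
  if (!is.null(na_reason)) {
    return(structure(list(model = model$name, acc = NA, sens = NA, spec = NA,
                          auc = NA, raw = NULL, confusion = NULL,
                          n = length(y01), reason = na_reason),
                     class = "metrics_row"))
  }
  tp <- sum(pred == 1 & y01 == 1); tn <- sum(pred == 0 & y01 == 0)
  fp <- sum(pred == 1 & y01 == 0); fn <- sum(pred == 0 & y01 == 1)
  raw <- c(acc = 100 * (tp + tn) / length(y01),
           sens = 100 * tp / (tp + fn),
           spec = 100 * tn / (tn + fp),
           auc = 100 * auc_score(score, y01))
  structure(list(model = model$name,
                 acc = round_half_up(raw[["acc"]]),
                 sens = round_half_up(raw[["sens"]]),
                 spec = round_half_up(raw[["spec"]]),
                 auc = round_half_up(raw[["auc"]]),
                 raw = raw,
                 confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 n = length(y01), reason = NULL),
            class = "metrics_row")
}

#' @export
print.metrics_row <- function(x, ...) {
  if (is.na(x$acc))
    cat(sprintf("%-6s n/a (%s)\n", x$model, x$reason))
  else
    cat(sprintf("%-6s Acc %d%%  Sens %d%%  Spec %d%%  AUC %d%%\n",
                x$model, x$acc, x$sens, x$spec, x$auc))
  invisible(x)
}

#' Benchmark all nine models on one feature table
#'
#' @param features data.frame of features plus `label`.
#' @param models model names (default all nine).
#' @param cv a [cv_config()].
#' @param balance optional fold-internal [balance_spec()] (see
#'   [evaluate_cv()]).
#' @return data.frame of class `"metrics_table"`: one row per model with
#'   integer-percent Acc/Sens/Spec/AUC (NA = n/a) and a `reason` column.
#' @export
evaluate_models <- function(features, models = model_names,
                            cv = cv_config(), balance = NULL) {
  rows <- lapply(models, function(m) evaluate_cv(features, m, cv, balance))
  df <- data.frame(
    model = vapply(rows, function(r) r$model, character(1)),
    acc = vapply(rows, function(r) as.numeric(r$acc), numeric(1)),
    sens = vapply(rows, function(r) as.numeric(r$sens), numeric(1)),
    spec = vapply(rows, function(r) as.numeric(r$spec), numeric(1)),
    auc = vapply(rows, function(r) as.numeric(r$auc), numeric(1)),
    reason = vapply(rows, function(r)
      if (is.null(r$reason)) NA_character_ else r$reason, character(1)),
    stringsAsFactors = FALSE)
  attr(df, "raw") <- lapply(rows, function(r) r$raw)
  class(df) <- c("metrics_table", "data.frame")
  df
}

#' Benchmark a named collection of feature tables
#'
#' Runs the full nine-model comparison per table — the result-table grid
#' of the benchmark (one table per dataset and representation).
#'
#' @param datasets named list of feature data.frames (each with `label`).
#' @param models model names.
#' @param cv a [cv_config()].
#' @param balance optional fold-internal [balance_spec()] (see
#'   [evaluate_cv()]).
#' @return named list of `metrics_table`s.
#' @export
run_grid <- function(datasets, models = model_names, cv = cv_config(),
                     balance = NULL) {
  stopifnot(is.list(datasets), !is.null(names(datasets)))
  lapply(datasets, evaluate_models, models = models, cv = cv,
         balance = balance)
}

#' Format a metrics table in the benchmark layout
#'
#' @param table a `metrics_table`.
#' @return character vector of aligned text lines with an
#'   `Acc (%) Sens (%) Spec (%) AUC (%)` header and `n/a` literals.
#' @export
format_metrics_table <- function(table) {
  fmt <- function(v) ifelse(is.na(v), "n/a", sprintf("%d", v))
  lines <- sprintf("%-6s %7s %8s %8s %7s", table$model, fmt(table$acc),
                   fmt(table$sens), fmt(table$spec), fmt(table$auc))
  c(sprintf("%-6s %7s %8s %8s %7s", "", "Acc (%)", "Sens (%)",
            "Spec (%)", "AUC (%)"), lines)
}

#' Write a metrics table as CSV
#' @param table a `metrics_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(table, path) {
  out <- as.data.frame(table)
  utils::write.csv(out, path, row.names = FALSE, na = "n/a")
  invisible(path)
}

#' PCA separability projection
#'
#' Z-scores the features, runs PCA, and keeps the smallest number of
#' components reaching `variance_target` cumulative explained variance.
#' The first two score columns support the standard separability scatter
#' (positive class blue, negative red).
#'
#' @param features data.frame of features plus `label`, or numeric matrix.
#' @param variance_target cumulative explained-variance fraction
#'   (default 0.98).
#' @return list: `scores` (2-column matrix), `explained` (all
#'   explained-variance fractions), `n_components`, `labels`.
#' @export
pca_projection <- function(features, variance_target = 0.98) {
  labels <- NULL
  if (is.data.frame(features)) {
    labels <- if ("label" %in% names(features)) features$label else NULL
    features <- as.matrix(
      features[, setdiff(names(features), c("label", "is_synthetic")),
               drop = FALSE])
  }
  if (nrow(features) < 3) stop("need at least 3 samples")
  sdv <- apply(features, 2, stats::sd)
  if (all(sdv == 0)) stop("degenerate input: constant feature matrix")
  keep <- sdv > 0
  pc <- stats::prcomp(features[, keep, drop = FALSE], center = TRUE,
                      scale. = TRUE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(ev) >= variance_target)[1]
  if (is.na(k)) k <- length(ev)
  list(scores = pc$x[, 1:min(2, ncol(pc$x)), drop = FALSE],
       explained = ev, n_components = k, labels = labels)
}

#' Plot a PCA projection (positive class blue, negative red)
#'
#' @param proj a [pca_projection()] result.
#' @param path PNG path; `NULL` draws on the active device.
#' @param main plot title.
#' @return `path`, invisibly.
#' @export
plot_pca_projection <- function(proj, path = NULL, main = "PCA projection") {
  if (!is.null(path)) grDevices::png(path, width = 720, height = 600)
  labels <- proj$labels
  pos <- if (!is.null(labels)) positive_class(labels) else NULL
  col <- if (is.null(labels)) "black" else
    ifelse(labels == pos, "blue", "red")
  graphics::plot(proj$scores[, 1], proj$scores[, 2], col = col, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * proj$explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * proj$explained[2]),
                 main = main)
  if (!is.null(labels))
    graphics::legend("topright", legend = c(pos, setdiff(unique(labels), pos)),
                     col = c("blue", "red"), pch = 19, bty = "n")
  if (!is.null(path)) grDevices::dev.off()
  invisible(path)
}
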