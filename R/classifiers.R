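# The nine benchmark classifiers. Each fit_* returns a closure scoring new
# rows with a continuous statistic oriented so that larger = positive
# class; class predictions threshold that score. Features arrive already
# z-scored with training-fold statistics.

model_names <- c("DT", "LDA", "QDA", "KNN", "LSVM", "QSVM", "CSVM",
                 "FGSVM", "LR")

#' Benchmark model specification
#'
#' Fixed, documented hyperparameters replace interactive tuning: KNN uses
#' K = 1 with Euclidean distance; the four SVMs use linear, quadratic
#' (degree-2 polynomial), cubic (degree-3 polynomial) and "fine Gaussian"
#' (RBF with kernel scale `sqrt(P)/4`, P = feature count) kernels, all at
#' C = 1 on standardized features; the decision tree is a Gini CART with
#' depth cap 8; LDA/QDA are Gaussian discriminants; LR is a binomial GLM.
#'
#' @param name one of `"DT"`, `"LDA"`, `"QDA"`, `"KNN"`, `"LSVM"`,
#'   `"QSVM"`, `"CSVM"`, `"FGSVM"`, `"LR"`.
#' @return list of class `"model_spec"` with `name` and `hyperparameters`.
#' @export
model_spec <- function(name) {
  name <- match.arg(name, model_names)
  hp <- switch(name,
    DT = list(criterion = "gini", max_depth = 8L, min_split = 4L),
    LDA = list(), QDA = list(),
    KNN = list(k = 1L, metric = "euclidean"),
    LSVM = list(kernel = "linear", C = 1),
    QSVM = list(kernel = "polynomial", degree = 2L, C = 1),
    CSVM = list(kernel = "polynomial", degree = 3L, C = 1),
    FGSVM = list(kernel = "rbf", scale = "sqrt(P)/4", C = 1),
    LR = list())
  structure(list(name = name, hyperparameters = hp), class = "model_spec")
}

## ---- decision tree (Gini CART) ----

gini_impurity <- function(y) {
  p <- mean(y)
  2 * p * (1 - p)
}

grow_tree <- function(X, y, depth, max_depth, min_split) {
  n <- length(y)
  prob <- mean(y)
  if (depth >= max_depth || n < min_split || prob == 0 || prob == 1)
    return(list(leaf = TRUE, prob = prob))
  parent <- gini_impurity(y)
  best <- NULL; best_gain <- 1e-12
  for (j in seq_len(ncol(X))) {
    xv <- X[, j]
    cuts <- unique(stats::quantile(xv, probs = seq(0.05, 0.95, by = 0.05),
                                   names = FALSE, type = 7))
    for (cv in cuts) {
      left <- xv <= cv
      nl <- sum(left)
      if (nl == 0 || nl == n) next
      gain <- parent - (nl * gini_impurity(y[left]) +
                        (n - nl) * gini_impurity(y[!left])) / n
      if (gain > best_gain) {
        best_gain <- gain
        best <- list(j = j, cut = cv)
      }
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, prob = prob))
  left <- X[, best$j] <= best$cut
  list(leaf = FALSE, j = best$j, cut = best$cut, prob = prob,
       left = grow_tree(X[left, , drop = FALSE], y[left], depth + 1,
                        max_depth, min_split),
       right = grow_tree(X[!left, , drop = FALSE], y[!left], depth + 1,
                         max_depth, min_split))
}

predict_tree <- function(node, x) {
  while (!node$leaf)
    node <- if (x[node$j] <= node$cut) node$left else node$right
  node$prob
}

fit_dt <- function(X, y01, hp) {
  tree <- grow_tree(X, y01, 0L, hp$max_depth, hp$min_split)
  function(Xn) apply(Xn, 1, function(r) predict_tree(tree, r)) - 0.5
}

## ---- SVM via the dual QP (quadprog) ----

kernel_matrix <- function(kernel, A, B, degree = 2L, scale = 1) {
  G <- A %*% t(B)
  switch(kernel,
    linear = G,
    polynomial = (1 + G)^degree,
    rbf = {
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * G
      exp(-pmax(d2, 0) / scale^2)
    })
}

fit_svm <- function(X, y01, hp) {
  y <- ifelse(y01 == 1, 1, -1)
  n <- nrow(X)
  scale <- if (identical(hp$kernel, "rbf")) sqrt(ncol(X)) / 4 else 1
  degree <- if (!is.null(hp$degree)) hp$degree else 2L
  K <- kernel_matrix(hp$kernel, X, X, degree, scale)
  D <- (y %o% y) * K
  diag(D) <- diag(D) + 1e-8          # ridge for strict positive definiteness
  C <- hp$C
  Amat <- cbind(y, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(Dmat = D, dvec = rep(1, n), Amat = Amat,
                            bvec = bvec, meq = 1)
  a <- pmin(pmax(sol$solution, 0), C)
  sv <- a > 1e-6
  if (!any(sv)) stop("SVM fit degenerate: no support vectors")
  margin_sv <- which(a > 1e-6 & a < C - 1e-6)
  if (!length(margin_sv)) margin_sv <- which(sv)
  f_nosign <- K[margin_sv, sv, drop = FALSE] %*% (a[sv] * y[sv])
  b <- mean(y[margin_sv] - f_nosign)
  Xsv <- X[sv, , drop = FALSE]; coef <- a[sv] * y[sv]
  function(Xn)
    as.numeric(kernel_matrix(hp$kernel, Xn, Xsv, degree, scale) %*% coef + b)
}

## ---- dispatcher ----

# Fits `spec` on (X, y01) and scores Xnew; y01 is 0/1 with 1 = positive.
fit_predict_model <- function(spec, X, y01, Xnew) {
  hp <- spec$hyperparameters
  scorer <- switch(spec$name,
    DT = fit_dt(X, y01, hp),
    LDA = {
      fit <- suppressWarnings(
        MASS::lda(X, grouping = factor(y01, levels = c(0, 1))))
      function(Xn) stats::predict(fit, Xn)$posterior[, "1"] - 0.5
    },
    QDA = {
      fit <- suppressWarnings(
        MASS::qda(X, grouping = factor(y01, levels = c(0, 1))))
      function(Xn) stats::predict(fit, Xn)$posterior[, "1"] - 0.5
    },
    KNN = {
      # 1-NN with a continuous margin: distance to the nearest negative
      # minus distance to the nearest positive training row.
      Xp <- X[y01 == 1, , drop = FALSE]; Xq <- X[y01 == 0, , drop = FALSE]
      function(Xn) {
        dp <- FNN::get.knnx(Xp, Xn, k = 1)$nn.dist[, 1]
        dq <- FNN::get.knnx(Xq, Xn, k = 1)$nn.dist[, 1]
        dq - dp
      }
    },
    LSVM = , QSVM = , CSVM = , FGSVM = fit_svm(X, y01, hp),
    LR = {
      df <- as.data.frame(X)
      fit <- suppressWarnings(stats::glm(y01 ~ ., data = cbind(y01 = y01, df),
                                         family = stats::binomial()))
      function(Xn) suppressWarnings(
        stats::predict(fit, newdata = as.data.frame(Xn), type = "link"))
    })
  score <- scorer(Xnew)
  list(score = as.numeric(score), pred = as.integer(score > 0))
}
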