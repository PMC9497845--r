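#' SMOTE balancing specification
#'
#' @param k_neighbors nearest same-class neighbors considered when
#'   interpolating (default 5); must be smaller than the smallest class
#'   being oversampled.
#' @param target_per_class `"majority"` (raise every class to the largest
#'   real-class size) or an explicit per-class count. The grade exercise
#'   uses 20 (9 -> 20 and 13 -> 20, i.e. 40 rows).
#' @param seed RNG seed.
#' @return A list of class `"balance_spec"`.
#' @export
balance_spec <- function(k_neighbors = 5L, target_per_class = "majority",
                         seed = 1L) {
  structure(list(k_neighbors = as.integer(k_neighbors),
                 target_per_class = target_per_class,
                 seed = as.integer(seed)),
            class = "balance_spec")
}

#' SMOTE oversampling to stated per-class counts
#'
#' Classic SMOTE in feature space: each synthetic row is
#' `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)`, `x` a real row of the
#' class being grown and `x_nn` one of its `k_neighbors` nearest
#' same-class neighbors (Euclidean distance). Real rows are never
#' modified or removed; synthetic rows carry `is_synthetic = TRUE`.
#'
#' @param features data.frame with numeric feature columns and a `label`
#'   column (binary), e.g. from [extract_feature_matrix()].
#' @param spec a [balance_spec()].
#' @return data.frame with each class at its target count and an
#'   `is_synthetic` logical column.
#' @export
smote_balance <- function(features, spec = balance_spec()) {
  stopifnot(is.data.frame(features), "label" %in% names(features))
  labels <- as.character(features$label)
  cls <- sort(unique(labels))
  if (length(cls) != 2) stop("smote_balance expects binary labels")
  fcols <- setdiff(names(features), c("label", "is_synthetic"))
  X <- as.matrix(features[, fcols, drop = FALSE])
  if (anyNA(X) || any(!is.finite(X)))
    stop("feature matrix contains missing or non-finite values")
  counts <- table(labels)
  target <- if (identical(spec$target_per_class, "majority"))
    max(counts) else as.integer(spec$target_per_class)
  if (any(counts > target))
    stop(sprintf("target %d is below an existing class size (%d); no undersampling",
                 target, max(counts)))
  set.seed(spec$seed)
  out <- features[, c(fcols, "label")]
  out$is_synthetic <- FALSE
  for (cl in cls) {
    need <- target - counts[[cl]]
    if (need == 0) next
    rows <- which(labels == cl)
    if (length(rows) < spec$k_neighbors + 1L)
      stop(sprintf("class '%s' has %d rows, fewer than k_neighbors + 1 = %d; use a smaller k",
                   cl, length(rows), spec$k_neighbors + 1L))
    Xc <- X[rows, , drop = FALSE]
    nn <- FNN::get.knn(Xc, k = spec$k_neighbors)$nn.index
    base <- rep(seq_len(nrow(Xc)), length.out = need)
    picks <- sample.int(spec$k_neighbors, need, replace = TRUE)
    u <- stats::runif(need)
    synth <- Xc[base, , drop = FALSE] +
      u * (Xc[nn[cbind(base, picks)], , drop = FALSE] - Xc[base, , drop = FALSE])
    add <- as.data.frame(synth)
    names(add) <- fcols
    add$label <- cl
    add$is_synthetic <- TRUE
    out <- rbind(out, add)
  }
  rownames(out) <- NULL
  out
}
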