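#' Amplitude threshold scheme
#'
#' One decomposition rule of the linear series decomposition learner
#' (LSDL): keep the samples of a signal lying on one side of an
#' amplitude level. `direction = "upper"` retains samples with intensity
#' `>= level`; `"lower"` retains `<= level`.
#'
#' @param direction `"upper"` or `"lower"`.
#' @param level amplitude threshold (a.u.).
#' @param iteration refinement iteration the scheme came from (>= 1).
#' @return A list of class `"threshold_scheme"`.
#' @export
threshold_scheme <- function(direction = c("upper", "lower"), level,
                             iteration = 1L) {
  direction <- match.arg(direction)
  if (!is.finite(level)) stop("level must be finite")
  if (iteration < 1) stop("iteration must be >= 1")
  structure(list(direction = direction, level = as.numeric(level),
                 iteration = as.integer(iteration)),
            class = "threshold_scheme")
}

#' Decompose a signal by an amplitude threshold
#'
#' Retains the samples meeting the scheme's amplitude condition, in
#' original index order. The retained run is the "sub-signal" on which the
#' reduced feature battery operates; it is treated downstream as a
#' contiguous series.
#'
#' @param signal a [spectrum()] or numeric series.
#' @param scheme a [threshold_scheme()].
#' @return A list of class `"sub_signal"` with fields `parent_id`,
#'   `retained`, `retained_count`, `scheme`. May be empty.
#' @export
lsdl_decompose <- function(signal, scheme) {
  stopifnot(inherits(scheme, "threshold_scheme"))
  x <- signal_series(signal)
  keep <- if (scheme$direction == "upper") x >= scheme$level else x <= scheme$level
  retained <- x[keep]
  structure(list(parent_id = if (inherits(signal, "spectrum"))
                   signal$sample_id else "series",
                 retained = retained,
                 retained_count = length(retained),
                 scheme = scheme),
            class = "sub_signal")
}

#' Normalized Euclidean-distance class separability index
#'
#' The LSDL performance index J: each feature is z-scored on the pooled
#' two-class sample (mean 0, unit variance, n-1 convention), class
#' centroids `p` and `q` are the per-class column means, `ED(p, q)` is
#' their Euclidean distance over all `Nw` feature dimensions, `sigma_m`
#' is the mean of the per-feature standard deviations of the pooled
#' (standardized) sample, and `J = ED(p, q) / sigma_m`. The pooled
#' z-scoring makes J invariant to per-feature rescaling, which is what
#' "normalized" buys.
#'
#' @param features_a,features_b numeric matrices (samples x features) for
#'   the two classes, same columns, >= 2 rows each, no missing values.
#' @return A list of class `"class_separation_stats"` with fields `p`,
#'   `q`, `per_feature_sd`, `sigma_m`, `ed`, `j`.
#' @export
performance_index <- function(features_a, features_b) {
  A <- as.matrix(features_a); B <- as.matrix(features_b)
  if (ncol(A) != ncol(B)) stop("feature columns differ between classes")
  if (nrow(A) < 2 || nrow(B) < 2) stop("need >= 2 samples per class")
  pooled <- rbind(A, B)
  if (anyNA(pooled) || any(!is.finite(pooled)))
    stop("degenerate input: missing or non-finite feature values")
  mu <- colMeans(pooled)
  sdv <- apply(pooled, 2, stats::sd)
  if (any(sdv == 0))
    stop("degenerate input: constant feature column (sd = 0)")
  z <- sweep(sweep(pooled, 2, mu), 2, sdv, "/")
  za <- z[seq_len(nrow(A)), , drop = FALSE]
  zb <- z[nrow(A) + seq_len(nrow(B)), , drop = FALSE]
  p <- colMeans(za); q <- colMeans(zb)
  per_feature_sd <- apply(z, 2, stats::sd)
  sigma_m <- mean(per_feature_sd)
  ed <- sqrt(sum((p - q)^2))
  structure(list(p = p, q = q, per_feature_sd = per_feature_sd,
                 sigma_m = sigma_m, ed = ed, j = ed / sigma_m),
            class = "class_separation_stats")
}

# Score one candidate level: decompose every spectrum, extract the reduced
# battery, compute J. Returns j = NA with a reason when any signal retains
# fewer than min_samples points or a feature degenerates.
score_candidate <- function(series_list, labels, direction, level,
                            min_samples, config) {
  schemes <- threshold_scheme(direction, level)
  subs <- lapply(series_list, function(s) {
    keep <- if (direction == "upper") s >= level else s <= level
    s[keep]
  })
  counts <- lengths(subs)
  if (any(counts < min_samples))
    return(list(j = NA_real_, reason = "insufficient_samples",
                min_retained = min(counts), features = NULL))
  feats <- tryCatch(
    do.call(rbind, lapply(subs, function(s)
      as.numeric(extract_features(s, config)))),
    error = function(e) NULL)
  if (is.null(feats) || anyNA(feats))
    return(list(j = NA_real_, reason = "degenerate_feature",
                min_retained = min(counts), features = feats))
  cls <- sort(unique(labels))
  j <- tryCatch(
    performance_index(feats[labels == cls[1], , drop = FALSE],
                      feats[labels == cls[2], , drop = FALSE])$j,
    error = function(e) NA_real_)
  list(j = j,
       reason = if (is.na(j)) "degenerate_feature" else NA_character_,
       min_retained = min(counts), features = feats)
}

#' Learn the optimal amplitude band (LSDL threshold search)
#'
#' Coarse-to-fine search over amplitude thresholds in both directions.
#' Iteration 1 scans `levels_per_iteration` equally spaced levels across
#' the pooled amplitude range of the training spectra; each later
#' iteration re-scans an interval of half the previous width centered on
#' the direction's incumbent best level. Every candidate decomposes every
#' training spectrum, extracts the reduced feature battery (ZC/DFA/MF
#' dropped) from each sub-signal, and scores the class separability index
#' J; candidates leaving any signal with fewer than `min_samples` retained
#' points are recorded "n/a" (the inadequate-sample rule). The winning
#' scheme is the global argmax of J, ties broken toward the lower
#' iteration and then toward the upper direction.
#'
#' @param training a [spectra_dataset()] with exactly two label values.
#' @param config a [feature_config()]; forced to the reduced battery.
#' @param n_iterations refinement iterations (default 4).
#' @param levels_per_iteration candidate levels per iteration (default 16).
#' @param min_samples minimum retained samples per signal (default 8, the
#'   smallest count at which the AR(4) and SampEn members are computable).
#' @param keep_features cache per-candidate feature matrices (needed by
#'   [lsdl_permutation_null()]).
#' @return A list of class `"lsdl_model"`: `scheme` (the optimum),
#'   `search_table` (best level per direction x iteration with n/a
#'   markers, the two-row layout of the decomposition-results tables),
#'   `candidates` (full candidate data.frame), `min_samples`, `config`,
#'   `labels`, and optionally `features_cache`.
#' @export
lsdl_threshold_search <- function(training, config = feature_config(),
                                  n_iterations = 4L,
                                  levels_per_iteration = 16L,
                                  min_samples = 8L, keep_features = TRUE) {
  stopifnot(inherits(training, "spectra_dataset"))
  labels <- dataset_labels(training)
  cls <- sort(unique(labels))
  if (length(cls) != 2) stop("training data must contain exactly two classes")
  config$reduced_after_lsdl <- TRUE
  series_list <- lapply(training$spectra, function(s) s$intensities)
  rng <- range(unlist(series_list))
  full_width <- diff(rng)
  if (full_width == 0) stop("degenerate input: constant spectra")

  cand <- list(); cache <- list(); idx <- 0L
  for (direction in c("upper", "lower")) {
    best_level <- NA_real_; best_j <- -Inf
    for (it in seq_len(n_iterations)) {
      if (it == 1L) {
        lo <- rng[1]; hi <- rng[2]
      } else {
        if (!is.finite(best_j)) break   # nothing valid to refine around
        w <- full_width / 2^(it - 1)
        lo <- max(rng[1], best_level - w / 2)
        hi <- min(rng[2], best_level + w / 2)
      }
      levels <- seq(lo, hi, length.out = levels_per_iteration)
      for (lv in levels) {
        sc <- score_candidate(series_list, labels, direction, lv,
                              min_samples, config)
        idx <- idx + 1L
        cand[[idx]] <- data.frame(direction = direction, iteration = it,
                                  level = lv, j = sc$j,
                                  min_retained = sc$min_retained,
                                  reason = sc$reason,
                                  stringsAsFactors = FALSE)
        cache[[idx]] <- if (keep_features) sc$features else NULL
        if (!is.na(sc$j) && sc$j > best_j) {
          best_j <- sc$j; best_level <- lv
        }
      }
    }
  }
  candidates <- do.call(rbind, cand)
  if (all(is.na(candidates$j)))
    stop(sprintf(paste0("search failure: every candidate left a signal with ",
                        "fewer than min_samples = %d retained points or a ",
                        "degenerate feature"), min_samples))

  # global optimum; ties -> lower iteration, then upper direction
  ok <- which(!is.na(candidates$j))
  ord <- ok[order(-candidates$j[ok], candidates$iteration[ok],
                  candidates$direction[ok] != "upper")]
  best <- candidates[ord[1], ]
  scheme <- threshold_scheme(best$direction, best$level, best$iteration)

  search_table <- do.call(rbind, lapply(c("upper", "lower"), function(d) {
    do.call(rbind, lapply(seq_len(n_iterations), function(it) {
      rows <- candidates[candidates$direction == d &
                           candidates$iteration == it, ]
      if (nrow(rows) == 0 || all(is.na(rows$j)))
        data.frame(direction = d, iteration = it, level = NA_real_,
                   j = NA_real_,
                   note = if (nrow(rows) == 0) "not_searched"
                          else rows$reason[1],
                   stringsAsFactors = FALSE)
      else {
        b <- rows[which.max(rows$j), ]
        data.frame(direction = d, iteration = it, level = b$level, j = b$j,
                   note = NA_character_, stringsAsFactors = FALSE)
      }
    }))
  }))

  structure(list(scheme = scheme, search_table = search_table,
                 candidates = candidates, min_samples = as.integer(min_samples),
                 config = config, labels = labels,
                 classes = cls,
                 features_cache = if (keep_features) cache else NULL,
                 amplitude_range = rng),
            class = "lsdl_model")
}

#' @export
print.lsdl_model <- function(x, ...) {
  cat(sprintf("<lsdl_model> optimum: %s @ %.4f (iteration %d), J = %.4f\n",
              x$scheme$direction, x$scheme$level, x$scheme$iteration,
              max(x$candidates$j, na.rm = TRUE)))
  print(format_search_table(x))
  invisible(x)
}

#' Search table in the two-row Upper/Lower layout
#'
#' Formats the per-iteration best levels as a character matrix with rows
#' `Upper`/`Lower` and one column per iteration; inadequate-sample
#' iterations print as `"n/a"`.
#'
#' @param model an [lsdl_threshold_search()] result.
#' @param digits decimal places for levels.
#' @return character matrix.
#' @export
format_search_table <- function(model, digits = 4) {
  st <- model$search_table
  its <- sort(unique(st$iteration))
  m <- matrix("n/a", nrow = 2, ncol = length(its),
              dimnames = list(c("Upper", "Lower"),
                              sprintf("Iteration %d", its)))
  for (i in seq_len(nrow(st))) {
    r <- if (st$direction[i] == "upper") 1 else 2
    if (!is.na(st$level[i]))
      m[r, st$iteration[i]] <- formatC(st$level[i], digits = digits,
                                       format = "f")
  }
  m
}

#' Write the search table as CSV
#' @param model an `lsdl_model`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_search_table <- function(model, path) {
  m <- format_search_table(model)
  df <- data.frame(`Threshold Level` = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Apply a learned decomposition to a dataset
#'
#' Decomposes every spectrum with the model's optimal scheme, preserving
#' order. Spectra retaining fewer than `min_samples` points are flagged
#' (attribute `flagged`) and a warning reports the count; downstream
#' stages exclude flagged signals.
#'
#' @param model an `lsdl_model`.
#' @param dataset a [spectra_dataset()].
#' @return list of `sub_signal`s with logical attribute `flagged`.
#' @export
lsdl_apply <- function(model, dataset) {
  stopifnot(inherits(model, "lsdl_model"), inherits(dataset, "spectra_dataset"))
  subs <- lapply(dataset$spectra, lsdl_decompose, scheme = model$scheme)
  flagged <- vapply(subs, function(s) s$retained_count < model$min_samples,
                    logical(1))
  if (any(flagged))
    warning(sprintf("%d of %d signals retain fewer than %d samples under the learned scheme",
                    sum(flagged), length(subs), model$min_samples))
  attr(subs, "flagged") <- flagged
  subs
}

#' Permutation null for the threshold search
#'
#' Re-scores candidate levels under label permutations, using the feature
#' matrices cached during the search (features do not depend on labels,
#' so only J is recomputed). Significance is judged on the max-J
#' statistic across candidates, which controls the family-wise error
#' over the scanned levels. Only candidates from the fixed iteration-1
#' grid are used by default: later iterations place their levels
#' adaptively around the observed optimum, so observed and permuted
#' maxima over them would not be exchangeable under the null.
#'
#' @param model an `lsdl_model` built with `keep_features = TRUE`.
#' @param n_permutations label permutations (default 200).
#' @param seed RNG seed.
#' @param iterations which search iterations contribute candidates
#'   (default 1, the non-adaptive grid).
#' @return list with `observed_max_j`, `null_max_j` (vector), `p_value`,
#'   and `per_level` data.frame of per-candidate permutation p-values.
#' @export
lsdl_permutation_null <- function(model, n_permutations = 200L, seed = 1L,
                                  iterations = 1L) {
  if (is.null(model$features_cache))
    stop("model was built with keep_features = FALSE")
  set.seed(seed)
  labels <- model$labels
  cls <- model$classes
  valid <- which(!is.na(model$candidates$j) &
                   model$candidates$iteration %in% iterations &
                   !vapply(model$features_cache, is.null, logical(1)))
  if (!length(valid)) stop("no valid candidates to permute")
  obs <- model$candidates$j[valid]
  null_j <- matrix(NA_real_, nrow = n_permutations, ncol = length(valid))
  for (b in seq_len(n_permutations)) {
    yl <- sample(labels)
    for (ci in seq_along(valid)) {
      f <- model$features_cache[[valid[ci]]]
      null_j[b, ci] <- tryCatch(
        performance_index(f[yl == cls[1], , drop = FALSE],
                          f[yl == cls[2], , drop = FALSE])$j,
        error = function(e) NA_real_)
    }
  }
  null_max <- apply(null_j, 1, max, na.rm = TRUE)
  obs_max <- max(obs)
  per_level <- data.frame(
    candidate = valid,
    level = model$candidates$level[valid],
    direction = model$candidates$direction[valid],
    j = obs,
    p = vapply(seq_along(valid), function(ci)
      mean(null_j[, ci] >= obs[ci], na.rm = TRUE), numeric(1)))
  list(observed_max_j = obs_max, null_max_j = null_max,
       p_value = mean(null_max >= obs_max), per_level = per_level)
}

#' Serialize / restore an LSDL model (JSON)
#'
#' Stores the learned scheme, the search table with n/a markers,
#' `min_samples` and the feature configuration — everything needed to
#' decompose further signals from the same source. The feature cache is
#' not serialized.
#'
#' @param model an `lsdl_model`.
#' @param path JSON file path.
#' @return `path` invisibly (write); an `lsdl_model` without cache (read).
#' @export
write_lsdl_model <- function(model, path) {
  out <- list(scheme = model$scheme[c("direction", "level", "iteration")],
              search_table = model$search_table,
              min_samples = model$min_samples,
              feature_config = unclass(model$config),
              classes = model$classes,
              amplitude_range = model$amplitude_range)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_lsdl_model
#' @export
read_lsdl_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(feature_config, raw$feature_config[
    setdiff(names(raw$feature_config), character(0))])
  structure(list(
    scheme = threshold_scheme(raw$scheme$direction, raw$scheme$level,
                              raw$scheme$iteration),
    search_table = as.data.frame(raw$search_table),
    candidates = NULL, min_samples = as.integer(raw$min_samples),
    config = cfg, labels = NULL, classes = raw$classes,
    features_cache = NULL, amplitude_range = raw$amplitude_range),
    class = "lsdl_model")
}
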