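# Shared fixtures. Heavy simulation products (threshold searches over the
# default 1676-point grid) are computed once per session and shared by the
# acceptance tests that measure different aspects of the same stated world.

# Small grid for fast unit-level search tests.
small_grid <- function() default_wavenumber_grid(1800, 900, 4)

# An effect spec without nuisance components, for analytic examples.
plain_effect <- function(...) {
  effect_spec(peak_centers = 1650, peak_widths = 45, base_amplitudes = 1,
              class_shift = 0, subject_amplitude_cv = 0,
              texture = NULL, shoulder = NULL, noise_sd = 0,
              baseline_intercept_range = c(0, 0), replicate_jitter_sd = 0,
              baseline_slope_range = c(0, 0), ...)
}

# Independent brute-force sample entropy (direct O(n^2) template count,
# no shared code with the package implementation).
brute_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  a <- 0L; b <- 0L
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        b <- b + 1L
        if (abs(x[i + m] - x[j + m]) <= r) a <- a + 1L
      }
    }
  }
  if (b == 0 || a == 0) return(Inf)
  -log(a / b)
}

# Independent brute-force normalized Euclidean distance index: literal
# formula chain (pooled z-score, centroids, ED, mean of per-feature sds).
brute_perf_index <- function(A, B) {
  P <- rbind(A, B)
  Z <- P
  for (w in seq_len(ncol(P))) {
    mu <- sum(P[, w]) / nrow(P)
    sdv <- sqrt(sum((P[, w] - mu)^2) / (nrow(P) - 1))
    Z[, w] <- (P[, w] - mu) / sdv
  }
  p <- q <- numeric(ncol(P))
  for (w in seq_len(ncol(P))) {
    p[w] <- mean(Z[seq_len(nrow(A)), w])
    q[w] <- mean(Z[nrow(A) + seq_len(nrow(B)), w])
  }
  ed <- sqrt(sum((p - q)^2))
  sig <- numeric(ncol(P))
  for (w in seq_len(ncol(P)))
    sig[w] <- sqrt(sum((Z[, w] - mean(Z[, w]))^2) / (nrow(P) - 1))
  ed / mean(sig)
}

# ---- session-shared heavy fixtures -----------------------------------

.fixture_env <- new.env(parent = emptyenv())

# Planted-effect world at the stated defaults, 20 seeds: threshold-search
# recovery plus raw/decomposed CV accuracy per seed.
signal_world <- function() {
  if (!is.null(.fixture_env$signal)) return(.fixture_env$signal)
  res <- lapply(1:20, function(sd) {
    pair <- generate_cohort(cohort_spec(seed = sd), effect_spec())
    ds <- pair$dataset1
    m <- lsdl_threshold_search(ds, keep_features = FALSE)
    raw <- extract_feature_matrix(ds)
    subs <- lsdl_apply(m, ds)
    lsd <- extract_feature_matrix(subs, feature_config(reduced_after_lsdl = TRUE),
                                  labels = dataset_labels(ds))
    bal <- balance_spec(seed = sd)
    cv <- cv_config(seed = sd)
    t_raw <- evaluate_models(smote_balance(raw, bal), cv = cv)
    t_lsdl <- evaluate_models(smote_balance(lsd, bal), cv = cv)
    acc_of <- function(tab) mean(vapply(attr(tab, "raw"), function(r)
      if (is.null(r)) NA_real_ else r[["acc"]], numeric(1)), na.rm = TRUE)
    list(direction = m$scheme$direction, level = m$scheme$level,
         step4 = diff(m$amplitude_range) / 8 / (16 - 1),
         acc_raw = acc_of(t_raw), acc_lsdl = acc_of(t_lsdl))
  })
  .fixture_env$signal <- res
  res
}

# Null world (class effect zero), 20 seeds: full pipeline with
# leakage-safe balancing, plus a 200-permutation max-J null per seed.
null_world <- function() {
  if (!is.null(.fixture_env$null)) return(.fixture_env$null)
  res <- lapply(1:20, function(sd) {
    eff <- effect_spec(class_shift = 0)
    pair <- generate_cohort(cohort_spec(seed = sd), eff)
    ds <- pair$dataset1
    m <- lsdl_threshold_search(ds, keep_features = TRUE)
    perm <- lsdl_permutation_null(m, n_permutations = 200L, seed = sd)
    subs <- lsdl_apply(m, ds)
    lsd <- extract_feature_matrix(subs, feature_config(reduced_after_lsdl = TRUE),
                                  labels = dataset_labels(ds))
    tab <- evaluate_models(lsd, cv = cv_config(seed = sd),
                           balance = balance_spec(seed = sd))
    acc <- mean(vapply(attr(tab, "raw"), function(r)
      if (is.null(r)) NA_real_ else r[["acc"]], numeric(1)), na.rm = TRUE)
    list(acc = acc, perm_p = perm$p_value)
  })
  .fixture_env$null <- res
  res
}
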