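test_that("amplitude decomposition retains exactly the qualifying samples", {
  x <- c(0.5, 2.2, 1.0, 3.0)
  up <- lsdl_decompose(x, threshold_scheme("upper", 2.0))
  expect_equal(up$retained, c(2.2, 3.0))
  expect_equal(up$retained_count, 2)
  low <- lsdl_decompose(x, threshold_scheme("lower", max(x)))
  expect_equal(low$retained, x)                     # identity bound
  empty <- lsdl_decompose(x, threshold_scheme("upper", max(x) + 1))
  expect_equal(empty$retained_count, 0)
})

test_that("decomposition nests monotonically in the threshold", {
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(200)
    t1 <- runif(1, -1, 0); t2 <- t1 + runif(1, 0, 1)
    up1 <- lsdl_decompose(x, threshold_scheme("upper", t1))$retained
    up2 <- lsdl_decompose(x, threshold_scheme("upper", t2))$retained
    expect_true(all(up2 %in% up1))
    lo1 <- lsdl_decompose(x, threshold_scheme("lower", t1))$retained
    lo2 <- lsdl_decompose(x, threshold_scheme("lower", t2))$retained
    expect_true(all(lo1 %in% lo2))
  }
})

test_that("performance index reproduces the hand-computed 1-D case", {
  A <- matrix(c(0, 0), ncol = 1); B <- matrix(c(2, 2), ncol = 1)
  st <- performance_index(A, B)
  # pooled sd of {0,0,2,2} (n-1) = 1.1547 -> standardized centroids -/+0.8660
  expect_equal(st$p[[1]], -0.8660, tolerance = 1e-4)
  expect_equal(st$q[[1]], 0.8660, tolerance = 1e-4)
  expect_equal(st$sigma_m, 1, tolerance = 1e-12)
  expect_equal(st$j, 1.7321, tolerance = 1e-4)
})

test_that("performance index: degenerate and invariance properties", {
  set.seed(22)
  A <- matrix(rnorm(20), 5)
  expect_equal(performance_index(A, A)$j, 0, tolerance = 1e-12)
  B <- matrix(rnorm(20, 1), 5)
  expect_equal(performance_index(A * 5, B * 5)$j, performance_index(A, B)$j,
               tolerance = 1e-10)
  Ac <- cbind(A, 1); Bc <- cbind(B, 1)
  expect_error(performance_index(Ac, Bc), "constant feature")
  expect_error(performance_index(A[1, , drop = FALSE], B), ">= 2 samples")
})

test_that("performance index agrees with the brute-force oracle", {
  set.seed(23)
  for (i in 1:100) {
    nf <- sample(1:6, 1)
    A <- matrix(rnorm(nf * sample(3:8, 1), sd = runif(1, 0.5, 3)), ncol = nf)
    B <- matrix(rnorm(nf * sample(3:8, 1), mean = runif(1, -1, 1)), ncol = nf)
    expect_equal(performance_index(A, B)$j, brute_perf_index(A, B),
                 tolerance = 1e-10)
  }
})

test_that("threshold search on a small planted world finds an upper scheme", {
  co <- cohort_spec(n_noncancer = 12L, n_cancer = 12L,
                    gleason_counts = c(lt7 = 4L, eq7 = 4L, gt7 = 4L),
                    grid = small_grid(), seed = 31)
  pair <- generate_cohort(co, effect_spec())
  m <- lsdl_threshold_search(pair$dataset1)
  expect_s3_class(m, "lsdl_model")
  expect_equal(m$scheme$direction, "upper")
  # the optimum row appears in the candidate table with the maximal J
  best_j <- max(m$candidates$j, na.rm = TRUE)
  hit <- m$candidates[!is.na(m$candidates$j) & m$candidates$j == best_j, ]
  expect_equal(hit$level[1], m$scheme$level)
  # n/a entries carry a reason
  nas <- m$candidates[is.na(m$candidates$j), ]
  if (nrow(nas)) expect_true(all(!is.na(nas$reason)))
  # the formatted table has the two-row layout
  tab <- format_search_table(m)
  expect_equal(rownames(tab), c("Upper", "Lower"))
  expect_equal(ncol(tab), 4)
})

test_that("candidates sweeping past the amplitude maximum are n/a", {
  co <- cohort_spec(n_noncancer = 8L, n_cancer = 8L,
                    gleason_counts = c(lt7 = 3L, eq7 = 3L, gt7 = 2L),
                    grid = small_grid(), seed = 32)
  pair <- generate_cohort(co, effect_spec())
  m <- lsdl_threshold_search(pair$dataset1)
  top <- m$candidates[m$candidates$direction == "upper" &
                        m$candidates$iteration == 1, ]
  # the highest iteration-1 candidate equals the global max: at most one
  # spectrum attains it, so some signal must fall below min_samples
  expect_true(is.na(top$j[which.max(top$level)]))
  expect_equal(top$reason[which.max(top$level)], "insufficient_samples")
})

test_that("applying the model reproduces training retention and flags", {
  co <- cohort_spec(n_noncancer = 10L, n_cancer = 10L,
                    gleason_counts = c(lt7 = 3L, eq7 = 3L, gt7 = 4L),
                    grid = small_grid(), seed = 33)
  pair <- generate_cohort(co, effect_spec())
  m <- lsdl_threshold_search(pair$dataset1)
  subs <- lsdl_apply(m, pair$dataset1)
  expect_length(subs, 20)
  counts <- vapply(subs, function(s) s$retained_count, integer(1))
  expect_gte(min(counts), m$min_samples)

  # identity scheme
  mx <- max(dataset_matrix(pair$dataset1))
  m2 <- m; m2$scheme <- threshold_scheme("lower", mx)
  subs2 <- lsdl_apply(m2, pair$dataset1)
  expect_equal(subs2[[1]]$retained, pair$dataset1$spectra[[1]]$intensities)

  # empty dataset
  expect_length(lsdl_apply(m, spectra_dataset(list(), "empty")), 0)

  # a spectrum that retains too little is flagged with a warning
  tiny <- spectra_dataset(list(spectrum(seq(900, 700, -4),
                                        rep(0, 51), sample_id = "flat",
                                        label = "cancer")), "tiny")
  m3 <- m; m3$scheme <- threshold_scheme("upper", 1)
  expect_warning(s3 <- lsdl_apply(m3, tiny), "fewer than")
  expect_true(attr(s3, "flagged")[1])
})

test_that("model serialization round-trips scheme and search table", {
  co <- cohort_spec(n_noncancer = 8L, n_cancer = 8L,
                    gleason_counts = c(lt7 = 3L, eq7 = 3L, gt7 = 2L),
                    grid = small_grid(), seed = 34)
  pair <- generate_cohort(co, effect_spec())
  m <- lsdl_threshold_search(pair$dataset1)
  p <- withr::local_tempfile(fileext = ".json")
  write_lsdl_model(m, p)
  back <- read_lsdl_model(p)
  expect_equal(back$scheme$direction, m$scheme$direction)
  expect_equal(back$scheme$level, m$scheme$level)
  expect_equal(back$min_samples, m$min_samples)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_search_table(m, p2)
  expect_equal(nrow(utils::read.csv(p2, check.names = FALSE)), 2)
})

test_that("search cost grows about linearly in the sample count", {
  mk <- function(n, seed) generate_cohort(
    cohort_spec(n_noncancer = n, n_cancer = n,
                gleason_counts = NULL, grid = small_grid(), seed = seed),
    effect_spec())$dataset1
  small <- mk(6L, 41); big <- mk(12L, 41)
  t1 <- system.time(lsdl_threshold_search(small, n_iterations = 2L))[["elapsed"]]
  t2 <- system.time(lsdl_threshold_search(big, n_iterations = 2L))[["elapsed"]]
  expect_lt(t2 / max(t1, 0.05), 4)     # doubling n stays well below quadratic
})
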