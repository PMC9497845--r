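test_that("time-domain features match hand arithmetic and symmetries", {
  expect_equal(mav(c(1, -2, 3)), 2)
  expect_equal(mav(rep(-4, 5)), 4)
  expect_equal(mav(-c(1, -2, 3)), mav(c(1, -2, 3)))

  expect_equal(waveform_length(c(0, 1, 3)), 3)
  expect_equal(waveform_length(rep(2, 10)), 0)
  x <- cumsum(runif(20))
  expect_equal(waveform_length(rev(x)), waveform_length(x))

  expect_equal(slope_sign_changes(c(0, 1, 0, 1, 0)), 3)
  expect_equal(slope_sign_changes(1:10), 0)
  expect_equal(slope_sign_changes(c(0, 1, 0, 1, 0), eps = 2), 0)

  expect_equal(zero_crossings(c(1, -1, 1)), 2)
  expect_equal(zero_crossings(abs(rnorm(50)) + 1), 0)
  y <- abs(rnorm(50)) + 1
  expect_gt(zero_crossings(y - mean(y)), 0)

  expect_equal(sum_of_peaks(c(0, 2, 0, 3, 0)), 2)
  expect_equal(sum_of_peaks(1:10), 0)
  expect_equal(sum_of_peaks(c(0, 1, 1, 0)), 1)   # plateau tie rule

  expect_equal(maximum_fractal_length(c(0, 1, 3)), log10(sqrt(5)))
  x <- rnorm(100)
  expect_equal(maximum_fractal_length(10 * x),
               maximum_fractal_length(x) + 1)
  expect_identical(maximum_fractal_length(rep(1, 10)), -Inf)
})

test_that("AR(4) coefficient: white-noise null and parameter recovery", {
  set.seed(11)
  a4_wn <- vapply(1:50, function(i) ar4_coefficient(rnorm(1024)), numeric(1))
  expect_lt(median(abs(a4_wn)), 0.1)

  phi <- c(0.5, -0.3, 0.2, -0.1)        # a = -phi in the stored convention
  rec <- vapply(1:5, function(i)
    ar4_coefficient(as.numeric(arima.sim(list(ar = phi), 4096))), numeric(1))
  expect_lt(abs(mean(rec) - (-phi[4])), 0.05)

  expect_error(ar4_coefficient(rnorm(7)), "length >= 8")
  expect_error(ar4_coefficient(rep(1, 20)), "constant")
})

test_that("cepstral coefficient follows the AR recursion", {
  set.seed(12)
  x <- as.numeric(arima.sim(list(ar = c(0.6, -0.2, 0.1, 0.05)), 2048))
  a <- lsdlspectra:::burg_coeffs(x, 4)
  expect_equal(cepstral_coefficient(x), -a[1])
  # a process built with a1 = 0 (phi1 = 0): c1 should be near zero
  y <- as.numeric(arima.sim(list(ar = c(0, -0.3, 0, -0.05)), 4096))
  expect_lt(abs(cepstral_coefficient(y)), 0.05)
})

test_that("sample entropy equals the brute-force oracle and known limits", {
  set.seed(13)
  for (i in 1:50) {
    x <- rnorm(64)
    r <- 0.2 * sd(x)
    expect_equal(sample_entropy(x, 2, 0.2), brute_sampen(x, 2, r),
                 tolerance = 1e-10)
  }
  expect_equal(sample_entropy(rep(c(0, 1), 32), 2, 0.2), 0)

  # shuffling an autocorrelated series does not decrease SampEn
  deltas <- vapply(1:20, function(i) {
    set.seed(100 + i)
    x <- as.numeric(stats::filter(rnorm(128), rep(1, 8), sides = 1))
    x <- x[!is.na(x)]
    sample_entropy(sample(x), 2, 0.2) - sample_entropy(x, 2, 0.2)
  }, numeric(1))
  expect_gte(median(deltas), 0)

  expect_error(sample_entropy(rnorm(5), 2), "length >= 6")
  expect_error(sample_entropy(rep(1, 20), 2), "sd")
})

test_that("Higuchi fractal dimension hits its theoretical limits", {
  expect_equal(higuchi_fd(seq(0, 1, length.out = 512), 8), 1, tolerance = 0.05)
  set.seed(14)
  h <- vapply(1:20, function(i) higuchi_fd(rnorm(512), 8), numeric(1))
  expect_equal(median(h), 2, tolerance = 0.15)
  x <- rnorm(256)
  expect_equal(higuchi_fd(3 * x + 7, 8), higuchi_fd(x, 8), tolerance = 1e-12)
  expect_error(higuchi_fd(rnorm(10), 8), "2\\*kmax")
})

test_that("DFA recovers the white-noise and integrated exponents", {
  set.seed(15)
  a_wn <- vapply(1:20, function(i) dfa_exponent(rnorm(2048)), numeric(1))
  expect_equal(median(a_wn), 0.5, tolerance = 0.1)
  a_int <- vapply(1:20, function(i) dfa_exponent(cumsum(rnorm(2048))), numeric(1))
  expect_equal(median(a_int), 1.5, tolerance = 0.15)
  x <- rnorm(512)
  expect_equal(dfa_exponent(5 * x), dfa_exponent(x), tolerance = 1e-12)
  expect_error(dfa_exponent(rnorm(10)), "3 usable scales")
})

test_that("median frequency splits the periodogram correctly", {
  x <- sin(2 * pi * 0.25 * (1:256))
  expect_lt(abs(median_frequency(x) - 0.25), 1 / 256)
  set.seed(16)
  mf <- vapply(1:20, function(i) median_frequency(rnorm(4096)), numeric(1))
  expect_equal(median(mf), 0.25, tolerance = 0.02)
  expect_error(median_frequency(rep(2, 64)), "zero spectral power")
})

test_that("extract_features returns the full or reduced battery", {
  set.seed(17)
  s <- generate_spectrum(effect_spec(), "cancer", seed = 17)
  full <- extract_features(s)
  expect_length(full, 12)
  expect_named(full, c("MAV", "WL", "SSC", "ZC", "4thAR", "SampEN", "Ceps",
                       "MFL", "HFD", "DFA", "MF", "SP"))
  red <- extract_features(s, feature_config(reduced_after_lsdl = TRUE))
  expect_length(red, 9)
  expect_false(any(c("ZC", "DFA", "MF") %in% names(red)))
  expect_identical(as.numeric(extract_features(s)), as.numeric(full))

  # short sub-signal: reduced battery still computable at min_samples = 8
  sub <- lsdl_decompose(rnorm(30) + 10, threshold_scheme("upper", 0))
  expect_length(extract_features(sub, feature_config(reduced_after_lsdl = TRUE)), 9)
  expect_error(extract_features(rnorm(5), feature_config(reduced_after_lsdl = TRUE)),
               "too short")

  # degenerate values become NA sentinels with flags
  v <- extract_features(c(rep(1, 30), 2), feature_config(reduced_after_lsdl = TRUE))
  expect_true("4thAR" %in% attr(v, "missing") || !anyNA(v))
})

test_that("feature matrix has one row per signal and a label column", {
  pair <- generate_cohort(cohort_spec(n_noncancer = 3L, n_cancer = 3L,
                                      gleason_counts = c(lt7 = 1L, eq7 = 1L, gt7 = 1L),
                                      grid = small_grid(), seed = 3),
                          effect_spec())
  fm <- extract_feature_matrix(pair$dataset1)
  expect_equal(dim(fm), c(6, 13))
  expect_equal(names(fm)[13], "label")
  expect_equal(sum(fm$label == "cancer"), 3)
})
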