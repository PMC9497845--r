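#' Default wavenumber grid
#'
#' Mid-IR ATR range, descending. The source study never states range or
#' resolution, so the grid is configurable; 4000–650 cm^-1 at 2 cm^-1 is a
#' common ATR-FTIR acquisition setting and is the package default.
#'
#' @param from,to,by grid end points and step (cm^-1).
#' @return Descending numeric wavenumber axis.
#' @export
default_wavenumber_grid <- function(from = 4000, to = 650, by = 2) {
  seq(from, to, by = -abs(by))
}

#' Cohort design for the synthetic generator
#'
#' Defaults reproduce the emulated study cohort: 31 noncancer + 22 cancer
#' subjects (53 total), with the cancer arm split 4 / 5 / 13 across
#' Gleason score groups GS < 7, GS = 7, GS > 7.
#'
#' @param n_noncancer,n_cancer subject counts.
#' @param gleason_counts named counts `c(lt7 = , eq7 = , gt7 = )`; must sum
#'   to `n_cancer`.
#' @param grid wavenumber axis (descending).
#' @param seed integer seed for cohort generation.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_noncancer = 31L, n_cancer = 22L,
                        gleason_counts = c(lt7 = 4L, eq7 = 5L, gt7 = 13L),
                        grid = default_wavenumber_grid(), seed = 1L) {
  stopifnot(n_noncancer >= 0, n_cancer >= 0)
  if (!is.null(gleason_counts)) {
    gleason_counts <- unlist(gleason_counts)   # accept YAML-style lists
    if (!all(c("lt7", "eq7", "gt7") %in% names(gleason_counts)))
      stop("gleason_counts needs named entries lt7, eq7, gt7")
    if (sum(gleason_counts) != n_cancer)
      stop("gleason_counts must sum to n_cancer")
  }
  structure(list(n_noncancer = as.integer(n_noncancer),
                 n_cancer = as.integer(n_cancer),
                 gleason_counts = gleason_counts,
                 grid = grid, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Spectral effect model for the synthetic generator
#'
#' Spectra are sums of Gaussian bands plus a linear baseline and additive
#' white noise. The class effect is an amplitude elevation of the curve
#' region lying above the floor of `affected_band`: positive-class
#' (`"cancer"` / `"high_grade"`) curves gain `class_shift` a.u. wherever
#' the base curve exceeds the band floor (smooth 0.05 a.u. onset ramp),
#' and are bit-identical to negative-class curves below it. The class
#' difference is therefore concentrated strictly inside one absorbance
#' amplitude band — the premise of amplitude-threshold decomposition —
#' and the band's lower boundary is the recoverable planted threshold.
#' In practice the elevated region is the tops of the bands taller than
#' the floor (with the defaults: CH stretch ~2925, amide I ~1650 and
#' carbohydrate ~1080 cm^-1). Default band positions are canonical
#' biofluid assignments (amide I ~1650, amide II ~1540, CH stretch
#' ~2925, carbohydrate ~1080, amide A ~3300 cm^-1); positions are
#' scaffolding, not biology.
#'
#' @param peak_centers band centers (cm^-1).
#' @param peak_widths Gaussian sd per band (cm^-1).
#' @param base_amplitudes peak heights (a.u.).
#' @param class_shift a.u. of positive-class elevation inside the band;
#'   0 makes the two classes one distribution.
#' @param affected_band amplitude interval `[lo, hi]` (a.u.); the class
#'   effect lives above `lo`.
#' @param subject_amplitude_cv per-subject log-normal coefficient of
#'   variation of every band amplitude (default 0.1): biofluid FTIR
#'   cohorts show band-intensity variability of this order between
#'   subjects, and it is what makes sweeping uninformative amplitude
#'   regions into a sub-signal costly for class separability.
#' @param texture fingerprint-region micro-structure: a list with
#'   `n_peaks` narrow bands of Gaussian sd `width` cm^-1 at fixed centers
#'   across `range`, each with a per-subject amplitude drawn uniformly
#'   from `[0, amp]` (identically in both classes) and capped so the
#'   resulting curve stays 0.1 a.u. below the affected band's floor —
#'   the texture is sub-band variability by construction. Real biofluid
#'   fingerprint regions (~1800-950 cm^-1) are dense with narrow
#'   overlapping bands whose intensities vary strongly between subjects;
#'   this is the uninformative, subject-specific variability that an
#'   amplitude decomposition is supposed to leave behind. `NULL`
#'   disables it.
#' @param shoulder a broad shared band (default centered at 2250 cm^-1,
#'   Gaussian sd `width` cm^-1) whose per-subject height is uniform on
#'   `amp_range`, reaching up to just below the affected band's floor.
#'   Its flat, subject-variable top populates the amplitudes immediately
#'   below the floor, so sweeping the threshold below the band instantly
#'   admits a large, subject-specific point mass — the dilution penalty
#'   that localizes the separability optimum at the boundary. `NULL`
#'   disables it.
#' @param noise_sd additive instrument noise sd (a.u.).
#' @param baseline_intercept_range,baseline_slope_range uniform ranges for
#'   the per-spectrum linear baseline; the slope is expressed as total
#'   drift across the axis (a.u.).
#' @param replicate_jitter_sd extra per-acquisition noise sd (a.u.)
#'   distinguishing replicate acquisitions of one sample.
#' @return A list of class `"effect_spec"`.
#' @export
effect_spec <- function(peak_centers = c(3300, 2925, 1650, 1540, 1400, 1080),
                        peak_widths = c(150, 85, 65, 40, 50, 75),
                        base_amplitudes = c(2.5, 2.35, 2.6, 1.2, 0.9, 2.2),
                        class_shift = 0.5,
                        affected_band = c(2.0, 3.5),
                        subject_amplitude_cv = 0.1,
                        texture = list(n_peaks = 30L, width = 8,
                                       amp = 1.4, range = c(950, 1800)),
                        shoulder = list(center = 2250, width = 180,
                                        amp_range = c(1.4, 1.95)),
                        noise_sd = 0.05,
                        baseline_intercept_range = c(0, 0.05),
                        baseline_slope_range = c(-0.05, 0.05),
                        replicate_jitter_sd = 0.02) {
  stopifnot(length(peak_centers) == length(peak_widths),
            length(peak_centers) == length(base_amplitudes))
  if (any(peak_widths <= 0)) stop("validation error: peak widths must be positive")
  if (noise_sd < 0 || replicate_jitter_sd < 0)
    stop("validation error: noise sds must be nonnegative")
  if (length(affected_band) != 2 || affected_band[1] > affected_band[2])
    stop("validation error: affected_band must be [lo, hi]")
  if (subject_amplitude_cv < 0)
    stop("validation error: subject_amplitude_cv must be nonnegative")
  structure(list(peak_centers = peak_centers, peak_widths = peak_widths,
                 base_amplitudes = base_amplitudes, class_shift = class_shift,
                 affected_band = affected_band,
                 subject_amplitude_cv = subject_amplitude_cv,
                 texture = texture, shoulder = shoulder,
                 noise_sd = noise_sd,
                 baseline_intercept_range = baseline_intercept_range,
                 baseline_slope_range = baseline_slope_range,
                 replicate_jitter_sd = replicate_jitter_sd),
            class = "effect_spec")
}

positive_labels <- c("cancer", "high_grade")

# All subject-level randomness in one draw: band amplitudes (log-normal
# around the base), fingerprint-texture amplitudes, and the baseline.
draw_subject <- function(effect) {
  cv <- effect$subject_amplitude_cv
  amps <- if (is.null(cv) || cv == 0) effect$base_amplitudes else
    effect$base_amplitudes *
      exp(stats::rnorm(length(effect$base_amplitudes), 0, cv))
  n_tex <- if (is.null(effect$texture)) 0L else effect$texture$n_peaks
  # each narrow band is present in a random ~60% of subjects, with a
  # subject-specific position jitter: between-subject variability in the
  # fingerprint region is compositional (which bands, where), not just a
  # matter of intensity
  tex_amps <- if (n_tex) stats::runif(n_tex) *
    (stats::runif(n_tex) < 0.6) else numeric(0)
  tex_jitter <- if (n_tex) stats::runif(n_tex, -8, 8) else numeric(0)
  shoulder_amp <- if (is.null(effect$shoulder)) NA_real_ else
    stats::runif(1, effect$shoulder$amp_range[1], effect$shoulder$amp_range[2])
  list(amps = amps, tex_amps = tex_amps, tex_jitter = tex_jitter,
       shoulder_amp = shoulder_amp,
       phase = stats::runif(1, 0, 2 * pi),
       intercept = stats::runif(1, effect$baseline_intercept_range[1],
                                effect$baseline_intercept_range[2]),
       slope = stats::runif(1, effect$baseline_slope_range[1],
                            effect$baseline_slope_range[2]))
}

# Deterministic part of a subject's spectrum: Gaussian bands, a linear
# baseline, and — for positive-class subjects — an amplitude-localized
# elevation of the curve above the affected band's floor. The elevation
# ramps in over 0.05 a.u. (the instrument-noise scale, so the planted
# boundary is as sharp as the noise floor allows) and saturates at
# class_shift; the curve below the band floor is identical across
# classes, so the class difference lives strictly inside the amplitude
# band — which is what makes the band's lower boundary recoverable by a
# threshold learner.
synth_curve <- function(effect, label, grid, subj) {
  y <- numeric(length(grid))
  for (k in seq_along(subj$amps))
    y <- y + subj$amps[k] * exp(-((grid - effect$peak_centers[k])^2) /
                                  (2 * effect$peak_widths[k]^2))
  lo <- effect$affected_band[1]
  if (!is.null(effect$shoulder) && !is.na(subj$shoulder_amp))
    y <- y + subj$shoulder_amp *
      exp(-((grid - effect$shoulder$center)^2) /
            (2 * effect$shoulder$width^2))
  if (length(subj$tex_amps)) {
    tx <- effect$texture
    centers <- seq(tx$range[1], tx$range[2], length.out = tx$n_peaks) +
      subj$tex_jitter
    for (k in seq_along(centers)) {
      if (subj$tex_amps[k] == 0) next
      # cap so base + texture stays below the band floor (0.1 margin)
      base_k <- y[which.min(abs(grid - centers[k]))]
      cap <- max(0, (lo - 0.1) - base_k)
      a <- subj$tex_amps[k] * min(tx$amp, cap)
      if (a > 0)
        y <- y + a * exp(-((grid - centers[k])^2) / (2 * tx$width^2))
    }
  }
  if (!is.na(label) && label %in% positive_labels && effect$class_shift != 0) {
    # onset centered on the band floor (half effect exactly at lo)
    ramp <- pmin(1, pmax(0, (y - lo + 0.02) / 0.04))
    # elevation plus new narrow sub-bands (subject-random phase),
    # confined to the amplitude band above lo
    y <- y + effect$class_shift * ramp *
      (0.5 + 0.5 * cos(2 * pi * grid / 20 + subj$phase))
  }
  t01 <- (max(grid) - grid) / (max(grid) - min(grid))
  y + subj$intercept + subj$slope * t01
}

#' Generate one synthetic spectrum
#'
#' @param effect an [effect_spec()].
#' @param label class label; the class shift applies when the label is
#'   `"cancer"` or `"high_grade"`.
#' @param grid wavenumber axis.
#' @param sample_id identifier.
#' @param seed optional integer; when given, the RNG is seeded so the
#'   spectrum is reproducible bit-for-bit.
#' @return A [spectrum()] with `acquisition_mode = "synthetic"`; values
#'   are clipped at zero.
#' @export
generate_spectrum <- function(effect, label = "noncancer",
                              grid = default_wavenumber_grid(),
                              sample_id = "synthetic", seed = NULL) {
  stopifnot(inherits(effect, "effect_spec"))
  if (!is.null(seed)) set.seed(seed)
  y <- synth_curve(effect, label, grid, draw_subject(effect))
  if (effect$noise_sd > 0) y <- y + stats::rnorm(length(grid), 0, effect$noise_sd)
  spectrum(grid, pmax(y, 0), sample_id = sample_id, label = label,
           acquisition_mode = "synthetic")
}

# Gleason scores realizing the cohort's gleason_counts: GS<7 -> 6,
# GS=7 -> 7, GS>7 -> cycle 8,9,10.
gleason_assignment <- function(gleason_counts) {
  gt <- gleason_counts[["gt7"]]
  c(rep(6L, gleason_counts[["lt7"]]),
    rep(7L, gleason_counts[["eq7"]]),
    if (gt > 0) rep(c(8L, 9L, 10L), length.out = gt))
}

#' Generate the paired averaged / single-acquisition cohort
#'
#' Per subject, `replicates` acquisitions are simulated (shared
#' deterministic curve, independent acquisition noise of sd
#' `sqrt(noise_sd^2 + replicate_jitter_sd^2)` per point).
#' `dataset1` holds the per-subject replicate averages (the
#' triple-acquisition-averaged protocol); `dataset2` the first acquisition
#' alone (single-acquisition protocol). Both carry identical subject
#' labels; cancer subjects additionally carry Gleason scores drawn from
#' the cohort's `gleason_counts`.
#'
#' @param cohort a [cohort_spec()].
#' @param effect an [effect_spec()].
#' @param replicates acquisitions per subject (default 3).
#' @return `list(dataset1 = , dataset2 = )` of [spectra_dataset()]s, each
#'   with `n_noncancer + n_cancer` members.
#' @export
generate_cohort <- function(cohort, effect, replicates = 3L) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(effect, "effect_spec"))
  if (replicates < 1) stop("replicates must be >= 1")
  set.seed(cohort$seed)
  labels <- c(rep("noncancer", cohort$n_noncancer),
              rep("cancer", cohort$n_cancer))
  gs <- rep(NA_integer_, length(labels))
  if (cohort$n_cancer > 0 && !is.null(cohort$gleason_counts))
    gs[labels == "cancer"] <- gleason_assignment(cohort$gleason_counts)
  acq_sd <- sqrt(effect$noise_sd^2 + effect$replicate_jitter_sd^2)
  grid <- cohort$grid
  avg <- vector("list", length(labels))
  single <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    sid <- sprintf("subj%02d", i)
    curve <- synth_curve(effect, labels[i], grid, draw_subject(effect))
    acqs <- lapply(seq_len(replicates), function(r) {
      y <- curve
      if (acq_sd > 0) y <- y + stats::rnorm(length(grid), 0, acq_sd)
      spectrum(grid, pmax(y, 0), sample_id = sid, label = labels[i],
               acquisition_mode = "single", gleason = gs[i])
    })
    avg[[i]] <- if (replicates > 1) average_replicates(acqs, n_required = 1L)
                else {
                  s <- acqs[[1]]; s$acquisition_mode <- "averaged"; s
                }
    single[[i]] <- acqs[[1]]
  }
  list(dataset1 = spectra_dataset(avg, name = "dataset1"),
       dataset2 = spectra_dataset(single, name = "dataset2"))
}

# GS <= 7 -> low_grade, GS > 7 -> high_grade (the grouping rule of the
# grade-prediction exercise).
grade_from_gleason <- function(gs) ifelse(gs > 7L, "high_grade", "low_grade")

#' Generate a Gleason-grade cohort
#'
#' Builds the cancer-arm grade dataset: subjects with GS <= 7 form the
#' low-grade class (4 + 5 = 9 under the default counts) and GS > 7 the
#' high-grade class (13). Low-grade spectra are drawn from `effect_low`
#' and high-grade from `effect_high` (the class shift applies to the
#' high-grade / positive class).
#'
#' @param cohort a [cohort_spec()]; its `gleason_counts` must be set.
#' @param effect_low,effect_high [effect_spec()]s for the two grades.
#' @param replicates acquisitions per subject; 1 returns single spectra.
#' @param mode `"single"` returns one dataset (first acquisition);
#'   `"pair"` returns `list(dataset1 = averaged, dataset2 = single)`.
#' @return A [spectra_dataset()] (or a list of two for `mode = "pair"`).
#' @export
generate_grade_cohort <- function(cohort, effect_low = effect_spec(),
                                  effect_high = effect_low,
                                  replicates = 1L,
                                  mode = c("single", "pair")) {
  mode <- match.arg(mode)
  if (is.null(cohort$gleason_counts))
    stop("validation error: cohort gleason_counts are required")
  set.seed(cohort$seed + 1L)
  gs <- gleason_assignment(cohort$gleason_counts)
  grades <- grade_from_gleason(gs)
  grid <- cohort$grid
  avg <- vector("list", length(gs))
  single <- vector("list", length(gs))
  for (i in seq_along(gs)) {
    eff <- if (grades[i] == "high_grade") effect_high else effect_low
    acq_sd <- sqrt(eff$noise_sd^2 + eff$replicate_jitter_sd^2)
    sid <- sprintf("gsubj%02d", i)
    curve <- synth_curve(eff, grades[i], grid, draw_subject(eff))
    acqs <- lapply(seq_len(max(replicates, 1L)), function(r) {
      y <- curve
      if (acq_sd > 0) y <- y + stats::rnorm(length(grid), 0, acq_sd)
      spectrum(grid, pmax(y, 0), sample_id = sid, label = grades[i],
               acquisition_mode = "single", gleason = gs[i])
    })
    avg[[i]] <- if (length(acqs) > 1) average_replicates(acqs, n_required = 1L)
                else acqs[[1]]
    single[[i]] <- acqs[[1]]
  }
  if (mode == "pair")
    list(dataset1 = spectra_dataset(avg, name = "grade_dataset1"),
         dataset2 = spectra_dataset(single, name = "grade_dataset2"))
  else
    spectra_dataset(single, name = "grade_cohort")
}
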