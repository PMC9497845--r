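test_that("spectrum enforces its invariants and normalizes axis direction", {
  wn <- seq(650, 4000, by = 2)           # ascending input
  s <- spectrum(wn, seq_along(wn), sample_id = "a")
  expect_true(all(diff(s$wavenumbers) < 0))          # stored descending
  expect_equal(s$intensities[1], length(wn))         # reordered in lockstep
  expect_error(spectrum(1:10, 1:9), "equal length")
  expect_error(spectrum(1:7, 1:7), "at least 8")
  expect_error(spectrum(c(1:8, 8), 1:9), "duplicate|monotonic")
  expect_error(spectrum(c(1:5, 4, 6:8), 1:9), "monotonic")
  expect_error(spectrum(1:8, c(1:7, NA)), "finite")
  expect_error(spectrum(1:8, 1:8, gleason = 11), "gleason")
})

test_that("CSV round trip preserves values and labels in both orientations", {
  wn <- seq(4000, 650, by = -50)
  set.seed(5)
  ds <- spectra_dataset(lapply(1:3, function(i)
    spectrum(wn, runif(length(wn)), sample_id = paste0("s", i),
             label = c("cancer", "noncancer", "cancer")[i])), "demo")
  p <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(ds, p)
  back <- read_spectra_csv(p)
  expect_equal(length(back$spectra), 3)
  expect_equal(back$spectra[[2]]$label, "noncancer")
  expect_equal(unname(back$class_counts["cancer"]), 2L)
  for (i in 1:3)
    expect_equal(back$spectra[[i]]$intensities, ds$spectra[[i]]$intensities,
                 tolerance = 1e-9)

  # columns orientation with a label row
  lines <- c(paste(c("wavenumber", "a", "b"), collapse = ","),
             vapply(seq_along(wn), function(i)
               paste(c(wn[i], i, 2 * i), collapse = ","), character(1)),
             "label,cancer,noncancer")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, p2)
  ds2 <- read_spectra_csv(p2, orientation = "samples_as_columns")
  expect_equal(length(ds2$spectra), 2)
  expect_equal(ds2$spectra[[1]]$label, "cancer")
  expect_equal(ds2$spectra[[2]]$intensities, 2 * ds2$spectra[[1]]$intensities)
})

test_that("CSV reader rejects ragged rows, bad cells, duplicate axes", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,100,101,102,103,104,105,106,107,label",
               "s1,1,2,3,4,5,6,7,8,cancer",
               "s2,1,2,3,4,5,6,7,cancer"), p)
  expect_error(read_spectra_csv(p), "ragged row 3")
  writeLines(c("sample_id,100,101,102,103,104,105,106,107,label",
               "s1,1,2,NaN,4,5,6,7,8,cancer"), p)
  expect_error(read_spectra_csv(p), "row 2, column 4")
  writeLines(c("sample_id,100,101,101,103,104,105,106,107,label",
               "s1,1,2,3,4,5,6,7,8,cancer"), p)
  expect_error(read_spectra_csv(p), "duplicate wavenumber")
})

test_that("JCAMP-DX subset reads, scales, validates and round-trips", {
  p <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=mini", "##JCAMP-DX=4.24", "##XUNITS=1/CM",
               "##YUNITS=ABSORBANCE", "##FIRSTX=4000", "##LASTX=3930",
               "##DELTAX=-10", "##NPOINTS=8", "##XFACTOR=1",
               "##YFACTOR=0.001", "##XYDATA=(X++(Y..Y))",
               "4000 100 200 300 400", "3960 500 600 700 800",
               "##END="), p)
  s <- read_jcampdx(p)
  expect_equal(s$intensities[s$wavenumbers == 4000], 0.1)   # YFACTOR applied
  expect_equal(length(s$wavenumbers), 8)

  # inconsistent LASTX
  writeLines(c("##TITLE=bad", "##FIRSTX=4000", "##LASTX=3000",
               "##DELTAX=-10", "##NPOINTS=8", "##XYDATA=(X++(Y..Y))",
               "4000 1 2 3 4", "3960 5 6 7 8", "##END="), p)
  expect_error(read_jcampdx(p), "inconsistent")

  # compressed dialect
  writeLines(c("##TITLE=sqz", "##FIRSTX=4000", "##LASTX=3930",
               "##DELTAX=-10", "##NPOINTS=8", "##XYDATA=(X++(Y..Y))",
               "4000 @ABC", "##END="), p)
  expect_error(read_jcampdx(p), "unsupported dialect")

  # write-then-read identity
  wn <- seq(4000, 650, by = -25)
  orig <- spectrum(wn, sin(seq_along(wn)) + 2, sample_id = "rt")
  p3 <- withr::local_tempfile(fileext = ".jdx")
  write_jcampdx(orig, p3)
  back <- read_jcampdx(p3)
  expect_equal(back$wavenumbers, orig$wavenumbers, tolerance = 1e-9)
  expect_equal(back$intensities, orig$intensities, tolerance = 1e-9)
})

test_that("average_replicates is the pointwise mean and permutation-invariant", {
  wn <- seq(800, 650, by = -2)
  mk <- function(v) spectrum(wn, rep(v, length(wn)), sample_id = "s")
  avg <- average_replicates(list(mk(0), mk(3), mk(6)))
  expect_equal(unique(avg$intensities), 3)
  expect_equal(avg$acquisition_mode, "averaged")

  set.seed(2)
  reps <- lapply(1:3, function(i) spectrum(wn, runif(length(wn)), sample_id = "s"))
  a1 <- average_replicates(reps)
  a2 <- average_replicates(rev(reps))
  expect_identical(a1$intensities, a2$intensities)

  expect_error(average_replicates(reps[1:2]), "at least 3")
  bad <- spectrum(wn + 1, runif(length(wn)), sample_id = "s")
  expect_error(average_replicates(list(reps[[1]], reps[[2]], bad)), "grids differ")
})

test_that("concatenation is count-additive and keeps provenance", {
  wn <- seq(800, 650, by = -2)
  mk_ds <- function(n, name, mode) spectra_dataset(lapply(seq_len(n), function(i)
    spectrum(wn, runif(length(wn)), sample_id = paste0(name, i),
             label = "cancer", acquisition_mode = mode)), name)
  set.seed(3)
  a <- mk_ds(62, "a", "averaged"); b <- mk_ds(62, "b", "single")
  ab <- concatenate_datasets(a, b)
  expect_equal(length(ab$spectra), 124)
  expect_equal(length(concatenate_datasets(mk_ds(40, "c", "averaged"),
                                           mk_ds(40, "d", "single"))$spectra), 80)
  modes <- vapply(ab$spectra, function(s) s$acquisition_mode, character(1))
  expect_equal(sum(modes == "averaged"), 62)

  empty <- spectra_dataset(list(), "empty")
  expect_equal(length(concatenate_datasets(a, empty)$spectra), 62)
  bad <- mk_ds(2, "e", "single"); bad$spectra[[1]]$wavenumbers[1] <- 9999
  # grid mismatch between datasets
  wn2 <- seq(802, 652, by = -2)
  c2 <- spectra_dataset(list(spectrum(wn2, runif(length(wn2)))), "c2")
  expect_error(concatenate_datasets(a, c2), "grid")
})

test_that("manifest round-trips through YAML", {
  p <- withr::local_tempfile(fileext = ".yaml")
  entries <- list(dataset1 = list(path = "dataset1.csv", n = 53,
                                  acquisition_mode = "averaged"))
  write_manifest(entries, p)
  expect_equal(read_manifest(p)$dataset1$n, 53)
})
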