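#' Construct a single FTIR spectrum
#'
#' A `spectrum` is one sample's absorbance series on a wavenumber axis,
#' plus its class label and acquisition metadata. Internally the axis is
#' always stored descending (4000 -> 650 cm^-1, the usual ATR-FTIR print
#' order); constructors accept either direction and reorder intensities in
#' lockstep.
#'
#' @param wavenumbers numeric, strictly monotonic wavenumber axis (cm^-1).
#' @param intensities numeric absorbance values (a.u.), same length.
#' @param sample_id character scalar identifier.
#' @param label class label: `"cancer"`/`"noncancer"`, `"low_grade"`/
#'   `"high_grade"`, or `NA` for unlabeled.
#' @param acquisition_mode one of `"averaged"`, `"single"`, `"synthetic"`.
#' @param gleason optional integer Gleason score in 2..10.
#' @return An object of class `"spectrum"`.
#' @export
spectrum <- function(wavenumbers, intensities, sample_id = "s1",
                     label = NA_character_,
                     acquisition_mode = c("single", "averaged", "synthetic"),
                     gleason = NA_integer_) {
  acquisition_mode <- match.arg(acquisition_mode)
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities))
    stop("wavenumbers and intensities must have equal length")
  if (length(wavenumbers) < 8L)
    stop("a spectrum needs at least 8 points")
  d <- diff(wavenumbers)
  if (any(d == 0)) stop("duplicate wavenumber values in axis")
  if (!(all(d > 0) || all(d < 0)))
    stop("wavenumber axis must be strictly monotonic")
  if (!all(is.finite(wavenumbers))) stop("non-finite wavenumber")
  if (!all(is.finite(intensities))) stop("non-finite intensity")
  if (all(d > 0)) {           # ascending input: store descending
    wavenumbers <- rev(wavenumbers)
    intensities <- rev(intensities)
  }
  if (!is.na(gleason)) {
    gleason <- as.integer(gleason)
    if (gleason < 2L || gleason > 10L) stop("gleason must be in 2..10")
  }
  structure(list(sample_id = as.character(sample_id),
                 wavenumbers = wavenumbers,
                 intensities = intensities,
                 label = as.character(label),
                 acquisition_mode = acquisition_mode,
                 gleason = gleason),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s: %d points, %.1f..%.1f cm-1, label=%s, mode=%s\n",
              x$sample_id, length(x$wavenumbers),
              max(x$wavenumbers), min(x$wavenumbers),
              ifelse(is.na(x$label), "<none>", x$label), x$acquisition_mode))
  invisible(x)
}

#' Bundle spectra sharing one wavenumber grid into a dataset
#'
#' @param spectra list of [spectrum()] objects on an identical grid.
#' @param name dataset name, e.g. `"dataset1"`.
#' @return An object of class `"spectra_dataset"` with fields `spectra`,
#'   `name` and `class_counts` (a named table over the member labels).
#' @export
spectra_dataset <- function(spectra, name = "dataset") {
  stopifnot(is.list(spectra))
  if (length(spectra) > 0) {
    if (!all(vapply(spectra, inherits, logical(1), "spectrum")))
      stop("all members must be spectrum objects")
    grid <- spectra[[1]]$wavenumbers
    same <- vapply(spectra, function(s)
      length(s$wavenumbers) == length(grid) && all(s$wavenumbers == grid),
      logical(1))
    if (!all(same)) stop("all member spectra must share one wavenumber grid")
  }
  labs <- vapply(spectra, function(s) s$label, character(1))
  structure(list(spectra = spectra, name = name,
                 class_counts = table(labs[!is.na(labs)])),
            class = "spectra_dataset")
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat(sprintf("<spectra_dataset> '%s': %d spectra\n", x$name, length(x$spectra)))
  if (length(x$class_counts)) print(x$class_counts)
  invisible(x)
}

#' @export
length.spectra_dataset <- function(x) length(x$spectra)

#' Labels of a dataset's members
#' @param dataset a [spectra_dataset()].
#' @return character vector of labels, one per member.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset$spectra, function(s) s$label, character(1))
}

#' Intensity matrix of a dataset (samples in rows)
#' @param dataset a [spectra_dataset()].
#' @return numeric matrix, one row per spectrum, columns follow the stored
#'   (descending) wavenumber grid.
#' @export
dataset_matrix <- function(dataset) {
  if (length(dataset$spectra) == 0) return(matrix(numeric(0), nrow = 0))
  m <- do.call(rbind, lapply(dataset$spectra, function(s) s$intensities))
  rownames(m) <- vapply(dataset$spectra, function(s) s$sample_id, character(1))
  colnames(m) <- sprintf("%.6g", dataset$spectra[[1]]$wavenumbers)
  m
}

#' Average replicate acquisitions of one sample
#'
#' Emulates the replicate-averaged acquisition protocol in which several
#' consecutive FTIR acquisitions of the same urine sample are taken and
#' their pointwise mean forms the final spectrum.
#'
#' @param replicates list of [spectrum()] objects sharing grid and
#'   `sample_id`.
#' @param n_required minimum replicate count (default 3).
#' @return A [spectrum()] with the pointwise mean intensities and
#'   `acquisition_mode = "averaged"`.
#' @export
average_replicates <- function(replicates, n_required = 3L) {
  if (length(replicates) < n_required)
    stop(sprintf("need at least %d replicates, got %d",
                 n_required, length(replicates)))
  ref <- replicates[[1]]
  for (r in replicates) {
    if (length(r$wavenumbers) != length(ref$wavenumbers) ||
        !all(r$wavenumbers == ref$wavenumbers))
      stop("replicate wavenumber grids differ")
    if (r$sample_id != ref$sample_id)
      stop("replicates must share one sample_id")
  }
  m <- rowMeans(vapply(replicates, function(r) r$intensities,
                       numeric(length(ref$intensities))))
  spectrum(ref$wavenumbers, m, sample_id = ref$sample_id, label = ref$label,
           acquisition_mode = "averaged", gleason = ref$gleason)
}

#' Concatenate two datasets sharing a grid and label scheme
#'
#' @param a,b [spectra_dataset()] objects on the same wavenumber grid.
#' @param name name for the combined dataset (default `"dataset3"`, the
#'   conventional name for the pooled averaged + single-acquisition set).
#' @return A [spectra_dataset()] with `length(a) + length(b)` members;
#'   per-spectrum provenance (acquisition_mode) is retained.
#' @export
concatenate_datasets <- function(a, b, name = "dataset3") {
  stopifnot(inherits(a, "spectra_dataset"), inherits(b, "spectra_dataset"))
  if (length(a$spectra) > 0 && length(b$spectra) > 0) {
    ga <- a$spectra[[1]]$wavenumbers
    gb <- b$spectra[[1]]$wavenumbers
    if (length(ga) != length(gb) || !all(ga == gb))
      stop("datasets must share one wavenumber grid")
  }
  spectra_dataset(c(a$spectra, b$spectra), name = name)
}
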