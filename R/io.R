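#' Read a labeled spectra matrix from CSV
#'
#' The interchange format is comma-separated, period decimal, UTF-8, with a
#' mandatory header row. Two orientations are supported:
#' * `samples_as_rows`: header is `sample_id`, then the wavenumber axis
#'   values, optionally a final `label` column; one row per sample.
#' * `samples_as_columns`: header is `wavenumber`, then sample ids; one row
#'   per wavenumber; an optional final row whose first cell is the literal
#'   `label` carries the class labels.
#'
#' Axes may be ascending or descending on disk; spectra are stored
#' descending. Ragged rows, non-numeric or non-finite cells, and duplicate
#' wavenumbers are rejected with the offending location named.
#'
#' @param path CSV file path.
#' @param orientation `"samples_as_rows"` (default) or
#'   `"samples_as_columns"`.
#' @param name dataset name.
#' @param acquisition_mode acquisition mode recorded on each spectrum.
#' @return A [spectra_dataset()].
#' @export
read_spectra_csv <- function(path,
                             orientation = c("samples_as_rows",
                                             "samples_as_columns"),
                             name = tools::file_path_sans_ext(basename(path)),
                             acquisition_mode = "single") {
  orientation <- match.arg(orientation)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("format error: CSV needs a header and data rows")
  cells <- strsplit(lines, ",", fixed = TRUE)
  ncol0 <- length(cells[[1]])
  ragged <- which(vapply(cells, length, integer(1)) != ncol0)
  if (length(ragged))
    stop(sprintf("format error: ragged row %d (expected %d cells)",
                 ragged[1], ncol0))
  header <- trimws(cells[[1]])
  body <- lapply(cells[-1], trimws)

  num_cell <- function(x, row, col) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v) || !is.finite(v))
      stop(sprintf("parse error: non-numeric or non-finite cell at row %d, column %d ('%s')",
                   row, col, x))
    v
  }

  if (orientation == "samples_as_rows") {
    has_label <- identical(tolower(header[length(header)]), "label")
    wn_cols <- seq(2L, length(header) - has_label)
    wn <- vapply(seq_along(wn_cols), function(j)
      num_cell(header[wn_cols[j]], 1L, wn_cols[j]), numeric(1))
    if (anyDuplicated(wn)) stop("validation error: duplicate wavenumber in header")
    specs <- lapply(seq_along(body), function(i) {
      row <- body[[i]]
      ints <- vapply(seq_along(wn_cols), function(j)
        num_cell(row[wn_cols[j]], i + 1L, wn_cols[j]), numeric(1))
      lab <- if (has_label) row[length(row)] else NA_character_
      if (!is.na(lab) && lab == "") lab <- NA_character_
      spectrum(wn, ints, sample_id = row[1], label = lab,
               acquisition_mode = acquisition_mode)
    })
  } else {
    label_row <- which(vapply(body, function(r) tolower(r[1]) == "label",
                              logical(1)))
    labs <- if (length(label_row)) body[[label_row[1]]][-1] else
      rep(NA_character_, ncol0 - 1L)
    data_rows <- if (length(label_row)) body[-label_row[1]] else body
    wn <- vapply(seq_along(data_rows), function(i)
      num_cell(data_rows[[i]][1], i + 1L, 1L), numeric(1))
    if (anyDuplicated(wn)) stop("validation error: duplicate wavenumber")
    specs <- lapply(seq_len(ncol0 - 1L), function(j) {
      ints <- vapply(seq_along(data_rows), function(i)
        num_cell(data_rows[[i]][j + 1L], i + 1L, j + 1L), numeric(1))
      lab <- labs[j]
      if (!is.na(lab) && lab == "") lab <- NA_character_
      spectrum(wn, ints, sample_id = header[j + 1L], label = lab,
               acquisition_mode = acquisition_mode)
    })
  }
  spectra_dataset(specs, name = name)
}

#' Write a dataset to the CSV interchange format
#'
#' Writes `samples_as_rows` orientation: header `sample_id`, wavenumbers,
#' `label`; full precision (round-trips to 1e-9 and beyond).
#'
#' @param dataset a [spectra_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "spectra_dataset"), length(dataset$spectra) > 0)
  wn <- dataset$spectra[[1]]$wavenumbers
  header <- paste(c("sample_id", sprintf("%.12g", wn), "label"), collapse = ",")
  rows <- vapply(dataset$spectra, function(s)
    paste(c(s$sample_id, sprintf("%.12g", s$intensities),
            ifelse(is.na(s$label), "", s$label)), collapse = ","),
    character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

jdx_field <- function(lines, key, required = TRUE, numeric = TRUE) {
  pat <- paste0("^##", key, "\\s*=")
  hit <- grep(pat, lines, ignore.case = TRUE, value = TRUE)
  if (!length(hit)) {
    if (required) stop(sprintf("format error: missing ##%s=", key))
    return(NULL)
  }
  val <- trimws(sub(pat, "", hit[1], ignore.case = TRUE))
  if (numeric) as.numeric(val) else val
}

#' Read a JCAMP-DX spectrum (4.24 subset, AFFN only)
#'
#' Supports `##XYDATA=(X++(Y..Y))` and `##XYPOINTS=(XY..XY)` blocks with
#' plain (AFFN) numbers; `XFACTOR`/`YFACTOR` are applied. Compressed
#' dialects (SQZ/DIF/DUP/PAC pseudo-digits) raise an explicit
#' "unsupported dialect" error.
#'
#' @param path JCAMP-DX file path.
#' @param label,acquisition_mode metadata attached to the result.
#' @return A [spectrum()].
#' @export
read_jcampdx <- function(path, label = NA_character_,
                         acquisition_mode = "single") {
  lines <- readLines(path, encoding = "UTF-8")
  title <- jdx_field(lines, "TITLE", required = FALSE, numeric = FALSE)
  npoints <- jdx_field(lines, "NPOINTS")
  xfactor <- jdx_field(lines, "XFACTOR", required = FALSE)
  yfactor <- jdx_field(lines, "YFACTOR", required = FALSE)
  if (is.null(xfactor)) xfactor <- 1
  if (is.null(yfactor)) yfactor <- 1

  start_xy <- grep("^##XYDATA\\s*=", lines, ignore.case = TRUE)
  start_pts <- grep("^##XYPOINTS\\s*=", lines, ignore.case = TRUE)
  end <- grep("^##END", lines, ignore.case = TRUE)
  if (!length(end)) end <- length(lines) + 1L

  check_affn <- function(txt) {
    if (grepl("[A-DF-Za-df-z@%]", txt))   # SQZ/DIF/DUP pseudo-digits ('E' ok)
      stop("unsupported dialect: compressed (non-AFFN) JCAMP-DX data")
  }

  if (length(start_xy)) {
    form <- lines[start_xy[1]]
    if (!grepl("X\\+\\+\\(Y\\.\\.Y\\)", form))
      stop("unsupported dialect: only (X++(Y..Y)) XYDATA is supported")
    block <- lines[seq(start_xy[1] + 1L, end[1] - 1L)]
    block <- block[!grepl("^##", block)]
    x <- numeric(0); y <- numeric(0)
    firstx <- jdx_field(lines, "FIRSTX")
    lastx <- jdx_field(lines, "LASTX")
    deltax <- jdx_field(lines, "DELTAX", required = FALSE)
    if (is.null(deltax) || is.na(deltax))
      deltax <- (lastx - firstx) / (npoints - 1)
    for (ln in block) {
      check_affn(ln)
      vals <- as.numeric(strsplit(trimws(ln), "[,[:space:]]+")[[1]])
      if (any(is.na(vals))) stop("parse error in XYDATA line")
      y <- c(y, vals[-1])
      x <- c(x, vals[1])
    }
    if (length(y) != npoints)
      stop(sprintf("format error: NPOINTS=%d but %d ordinates decoded",
                   npoints, length(y)))
    implied_last <- firstx + (npoints - 1) * deltax
    if (abs(implied_last - lastx) > 0.5 * abs(deltax))
      stop("format error: FIRSTX/LASTX/DELTAX/NPOINTS inconsistent")
    wn <- (firstx + deltax * (seq_len(npoints) - 1)) * xfactor
    ints <- y * yfactor
  } else if (length(start_pts)) {
    block <- lines[seq(start_pts[1] + 1L, end[1] - 1L)]
    block <- block[!grepl("^##", block)]
    check_affn(paste(block, collapse = " "))
    toks <- unlist(strsplit(trimws(block), "[;,[:space:]]+"))
    toks <- toks[nzchar(toks)]
    vals <- as.numeric(toks)
    if (any(is.na(vals)) || length(vals) %% 2 != 0)
      stop("parse error in XYPOINTS block")
    wn <- vals[seq(1, length(vals), 2)] * xfactor
    ints <- vals[seq(2, length(vals), 2)] * yfactor
    if (length(wn) != npoints)
      stop(sprintf("format error: NPOINTS=%d but %d points decoded",
                   npoints, length(wn)))
  } else stop("format error: no XYDATA or XYPOINTS block")

  spectrum(wn, ints,
           sample_id = if (is.null(title) || !nzchar(title)) basename(path) else title,
           label = label, acquisition_mode = acquisition_mode)
}

#' Write a spectrum as JCAMP-DX (X++(Y..Y), AFFN)
#'
#' @param spec a [spectrum()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jcampdx <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  wn <- spec$wavenumbers
  n <- length(wn)
  deltax <- (wn[n] - wn[1]) / (n - 1)
  hdr <- c(sprintf("##TITLE=%s", spec$sample_id),
           "##JCAMP-DX=4.24",
           "##DATA TYPE=INFRARED SPECTRUM",
           "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
           "##XFACTOR=1", "##YFACTOR=1",
           sprintf("##FIRSTX=%.12g", wn[1]),
           sprintf("##LASTX=%.12g", wn[n]),
           sprintf("##DELTAX=%.12g", deltax),
           sprintf("##NPOINTS=%d", n),
           "##XYDATA=(X++(Y..Y))")
  idx <- split(seq_len(n), ceiling(seq_len(n) / 6))
  body <- vapply(idx, function(ii)
    paste(c(sprintf("%.12g", wn[ii[1]]),
            sprintf("%.12g", spec$intensities[ii])), collapse = " "),
    character(1))
  writeLines(c(hdr, body, "##END="), path, useBytes = TRUE)
  invisible(path)
}

#' Write / read a dataset manifest (YAML)
#'
#' The manifest records, per dataset, the CSV path, acquisition mode and
#' name — the on-disk handover format between pipeline stages.
#'
#' @param entries named list: each element a list with `path`,
#'   `acquisition_mode`, and optional `n` and `name`.
#' @param path YAML file path.
#' @return `path` invisibly (write) / named list (read).
#' @export
write_manifest <- function(entries, path) {
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) yaml::read_yaml(path)
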