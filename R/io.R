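#' Read spectra from delimited text
#'
#' Two plain-text dialects are supported.
#'
#' * `"two-column"`: rows of `wavenumber, intensity` (comma, tab or
#'   whitespace separated, autodetected), with optional `# key: value`
#'   comment-header lines carrying `subject_id`, `replicate_id` and
#'   `class_label`.
#' * `"matrix"`: a header row whose first field is `wavenumber` and whose
#'   remaining fields are `subject_id/replicate_id/class_label` triplets,
#'   followed by one row per grid point.
#'
#' Files stored with a descending wavenumber axis are reversed on read and
#' tagged `"axis-reversed"` in the provenance.
#'
#' @param path Path to the file.
#' @param dialect `"auto"` (default), `"two-column"` or `"matrix"`.
#' @return A `sers_spectra` object.
#' @export
read_spectra <- function(path, dialect = c("auto", "two-column", "matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readr::read_lines(path)
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) abort(sprintf("No data rows in %s", path))
  if (dialect == "auto") {
    first <- tolower(split_fields(body[1])[1])
    dialect <- if (first %in% c("wavenumber", "wn", "cm-1")) "matrix" else "two-column"
  }
  if (dialect == "two-column") {
    read_two_column(body, meta_lines)
  } else {
    read_matrix_dialect(body)
  }
}

split_fields <- function(line) {
  line <- trimws(line)
  if (grepl(",", line, fixed = TRUE)) {
    trimws(strsplit(line, ",", fixed = TRUE)[[1]])
  } else {
    strsplit(line, "[\t ]+")[[1]]
  }
}

parse_numeric_cell <- function(x, row, col) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad) > 0) {
    abort(sprintf(
      "Non-numeric value '%s' at data row %d, column %d.",
      x[bad[1]], row[bad[1]], col[bad[1]]
    ))
  }
  v
}

read_two_column <- function(body, meta_lines) {
  fields <- lapply(body, split_fields)
  nf <- vapply(fields, length, 1L)
  if (any(nf != 2)) {
    abort(sprintf("Expected 2 fields per row, found %d at data row %d.", nf[nf != 2][1], which(nf != 2)[1]))
  }
  rows <- seq_along(body)
  wn <- parse_numeric_cell(vapply(fields, `[`, "", 1), rows, rep(1L, length(rows)))
  ii <- parse_numeric_cell(vapply(fields, `[`, "", 2), rows, rep(2L, length(rows)))
  meta <- parse_meta(meta_lines)
  reversed <- FALSE
  if (all(diff(wn) < 0)) {
    wn <- rev(wn)
    ii <- rev(ii)
    reversed <- TRUE
  }
  if (anyDuplicated(wn)) {
    abort(sprintf("Duplicate wavenumber %g in input.", wn[duplicated(wn)][1]))
  }
  df <- tibble(
    subject_id = meta$subject_id %||% "S1",
    replicate_id = meta$replicate_id %||% "r1",
    class_label = meta$class_label %||% "UNKNOWN",
    wavenumber = wn, intensity = ii
  )
  prov <- if (reversed) "axis-reversed" else character()
  as_spectra(df, provenance = prov)
}

parse_meta <- function(meta_lines) {
  out <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) out[[m[2]]] <- trimws(m[3])
  }
  out
}

read_matrix_dialect <- function(body) {
  header <- split_fields(body[1])
  if (length(header) < 2) abort("Matrix dialect needs a wavenumber column plus at least one spectrum column.")
  specs <- header[-1]
  trip <- strsplit(specs, "/", fixed = TRUE)
  meta <- tibble(
    subject_id = vapply(trip, function(x) x[1], ""),
    replicate_id = vapply(trip, function(x) if (length(x) >= 2) x[2] else "r1", ""),
    class_label = vapply(trip, function(x) if (length(x) >= 3) x[3] else "UNKNOWN", "")
  )
  meta$class_label <- validate_class_labels(meta$class_label)
  fields <- lapply(body[-1], split_fields)
  nf <- vapply(fields, length, 1L)
  if (any(nf != length(header))) {
    abort(sprintf(
      "Expected %d fields per row, found %d at data row %d.",
      length(header), nf[nf != length(header)][1], which(nf != length(header))[1] + 1L
    ))
  }
  vals <- matrix(NA_real_, nrow = length(fields), ncol = length(header))
  for (j in seq_along(header)) {
    vals[, j] <- parse_numeric_cell(
      vapply(fields, `[`, "", j),
      seq_along(fields) + 1L, rep(j, length(fields))
    )
  }
  wn <- vals[, 1]
  reversed <- FALSE
  if (all(diff(wn) < 0)) {
    wn <- rev(wn)
    vals <- vals[rev(seq_len(nrow(vals))), , drop = FALSE]
    reversed <- TRUE
  }
  if (anyDuplicated(wn)) {
    abort(sprintf("Duplicate wavenumber %g in input.", wn[duplicated(wn)][1]))
  }
  out <- matrix_to_spectra(wn, meta, t(vals[, -1, drop = FALSE]),
    provenance = if (reversed) "axis-reversed" else character()
  )
  validate_spectra(out)
}

#' Write spectra to delimited text
#'
#' Writes at full double precision (17 significant digits) so that a
#' write/read round trip reproduces values bit-identically.
#'
#' @param s A `sers_spectra` object.
#' @param path Output file path.
#' @param dialect `"two-column"` (single spectrum only) or `"matrix"`.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(s, path, dialect = c("matrix", "two-column"), sep = "\t") {
  dialect <- match.arg(dialect)
  n <- n_spectra(s)
  if (n == 0) abort("Refusing to write an empty spectra set.")
  fmt <- function(x) sprintf("%.17g", x)
  if (dialect == "two-column") {
    if (n != 1) abort("The two-column dialect holds a single spectrum; use dialect = 'matrix'.")
    meta <- spectra_meta(s)
    hdr <- c(
      sprintf("# subject_id: %s", meta$subject_id),
      sprintf("# replicate_id: %s", meta$replicate_id),
      sprintf("# class_label: %s", as.character(meta$class_label))
    )
    rows <- paste(fmt(s$wavenumber), fmt(s$intensity), sep = sep)
    readr::write_lines(c(hdr, rows), path)
  } else {
    w <- spectra_matrix(s)
    hdr <- paste(c("wavenumber", paste(w$meta$subject_id, w$meta$replicate_id,
      as.character(w$meta$class_label),
      sep = "/"
    )), collapse = sep)
    rows <- vapply(seq_along(w$grid), function(i) {
      paste(c(fmt(w$grid[i]), fmt(w$m[, i])), collapse = sep)
    }, "")
    readr::write_lines(c(hdr, rows), path)
  }
  invisible(path)
}
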