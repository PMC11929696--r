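#' Construct a load-displacement curve
#'
#' The elementary record of one destructive compression test: displacement of
#' the machine actuator (mm, monotone non-decreasing) against measured load
#' (N). Nominal acquisition is 128 Hz at an actuator rate of 0.1 mm/s, the
#' usual quasi-static destructive-test setting.
#'
#' @param displacement Numeric vector, mm. Non-decreasing, first value >= 0.
#'   Transient decreases no larger than `jitter_tol` are clamped.
#' @param load Numeric vector, N, same length as `displacement`; all finite.
#' @param specimen_id Identifier of the specimen (character scalar).
#' @param state `"intact"` or `"instrumented"`.
#' @param sample_rate Samples per second (nominal 128).
#' @param actuator_rate Actuator speed, mm/s (nominal 0.1).
#' @param jitter_tol Largest tolerated displacement decrease, mm.
#'
#' @return An object of class `"ld_curve"`.
#' @export
#' @examples
#' ld_curve(c(0, 1, 2), c(0, 100, 200), specimen_id = "S1")
ld_curve <- function(displacement, load, specimen_id = "unknown",
                     state = c("intact", "instrumented"),
                     sample_rate = 128, actuator_rate = 0.1,
                     jitter_tol = 1e-6) {
  state <- match.arg(state)
  displacement <- as.numeric(displacement)
  load <- as.numeric(load)
  if (length(displacement) != length(load))
    stop("displacement and load must have identical length")
  if (length(displacement) < 2)
    stop("a curve needs at least 2 samples")
  if (anyNA(displacement) || anyNA(load) || !all(is.finite(load)) ||
      !all(is.finite(displacement)))
    stop("curve samples must be finite and non-missing")
  if (displacement[1] < 0)
    stop("first displacement must be >= 0, got ", displacement[1])
  dec <- diff(displacement)
  if (any(dec < -jitter_tol)) {
    i <- which(dec < -jitter_tol)[1]
    stop(sprintf(
      "displacement decreases by %.3g mm at sample %d (tolerance %.3g mm)",
      -dec[i], i + 1L, jitter_tol))
  }
  # clamp sub-tolerance jitter so downstream windowing sees a monotone axis
  displacement <- cummax(displacement)
  structure(list(specimen_id = as.character(specimen_id), state = state,
                 displacement = displacement, load = load,
                 sample_rate = sample_rate, actuator_rate = actuator_rate),
            class = "ld_curve")
}

#' @export
print.ld_curve <- function(x, ...) {
  cat(sprintf(
    "<ld_curve> %s [%s]: %d samples, displacement %.3f-%.3f mm, peak load %.1f N\n",
    x$specimen_id, x$state, length(x$load),
    x$displacement[1], max(x$displacement), max(x$load)))
  invisible(x)
}

#' @export
as.data.frame.ld_curve <- function(x, ...) {
  data.frame(displacement_mm = x$displacement, load_n = x$load)
}

#' Read a load-displacement curve from delimited text
#'
#' Testing-machine exports vary in dialect; the reader sniffs the delimiter
#' (comma, semicolon, tab or whitespace) from the first data line unless one
#' is given, resolves columns by header name or index, and supports a comma
#' decimal mark. All rows must parse: a row with unparsable numerics aborts
#' the read, naming the offending row.
#'
#' @param path Path to a delimited text file.
#' @param col_displacement,col_load Column selectors: integer index or, when
#'   the file has a header, column name. Defaults: columns 1 and 2.
#' @param delim Field delimiter; `NULL` (default) sniffs among `","`, `";"`,
#'   tab and whitespace.
#' @param decimal_mark `"."` (default) or `","` (then the delimiter must not
#'   be a comma).
#' @param header `NA` (default) auto-detects a non-numeric first row; or
#'   logical.
#' @param unit_displacement,unit_load Multiplicative factors applied at
#'   ingestion to convert into mm and N (e.g. `unit_displacement = 1000` for
#'   metres).
#' @param re_zero If `TRUE`, subtract the first displacement sample so the
#'   curve starts at 0 (for machines that log absolute actuator position
#'   after preload). Default `FALSE`.
#' @param specimen_id,state,sample_rate,actuator_rate Metadata passed to
#'   [ld_curve()]; `specimen_id` defaults to the file name without extension.
#' @param jitter_tol Displacement jitter tolerance in mm, see [ld_curve()].
#'
#' @return An `"ld_curve"` object.
#' @export
read_curve <- function(path, col_displacement = 1, col_load = 2,
                       delim = NULL, decimal_mark = ".", header = NA,
                       unit_displacement = 1, unit_load = 1,
                       re_zero = FALSE,
                       specimen_id = NULL,
                       state = c("intact", "instrumented"),
                       sample_rate = 128, actuator_rate = 0.1,
                       jitter_tol = 1e-6) {
  state <- match.arg(state)
  if (!file.exists(path)) stop("curve file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("curve file has fewer than 2 data rows: ", path)
  if (identical(decimal_mark, ",") && identical(delim, ","))
    stop("decimal_mark ',' is incompatible with delimiter ','")

  if (is.null(delim)) delim <- sniff_delim(lines, decimal_mark)
  split_row <- function(x) {
    parts <- if (delim == " ") strsplit(trimws(x), "[ \t]+")[[1]]
             else strsplit(x, delim, fixed = TRUE)[[1]]
    trimws(parts)
  }
  rows <- lapply(lines, split_row)

  parse_num <- function(v) {
    if (decimal_mark == ",") v <- gsub(",", ".", v, fixed = TRUE)
    suppressWarnings(as.numeric(v))
  }
  first_numeric <- !anyNA(parse_num(rows[[1]]))
  has_header <- if (is.na(header)) !first_numeric else isTRUE(header)
  col_names <- if (has_header) rows[[1]] else NULL
  data_rows <- if (has_header) rows[-1] else rows
  row_offset <- if (has_header) 1L else 0L
  if (length(data_rows) < 2)
    stop("curve file has fewer than 2 data rows: ", path)

  resolve <- function(sel, what) {
    if (is.character(sel)) {
      if (is.null(col_names)) stop("column name '", sel,
                                   "' given but file has no header")
      i <- match(sel, col_names)
      if (is.na(i)) stop("column '", sel, "' not found in header (",
                         paste(col_names, collapse = ", "), ")")
      i
    } else as.integer(sel)
  }
  i_d <- resolve(col_displacement, "displacement")
  i_l <- resolve(col_load, "load")

  ncols <- lengths(data_rows)
  if (any(ncols < max(i_d, i_l))) {
    bad <- which(ncols < max(i_d, i_l))[1]
    stop("row ", bad + row_offset, " has too few fields in ", path)
  }
  d_raw <- vapply(data_rows, `[[`, "", i_d)
  l_raw <- vapply(data_rows, `[[`, "", i_l)
  d <- parse_num(d_raw)
  l <- parse_num(l_raw)
  bad <- which(is.na(d) | is.na(l))
  if (length(bad))
    stop("unparsable numeric value in row ",
         paste(bad + row_offset, collapse = ", "), " of ", path)

  d <- d * unit_displacement
  l <- l * unit_load
  if (re_zero) d <- d - d[1]
  if (is.null(specimen_id))
    specimen_id <- sub("\\.[^.]*$", "", basename(path))
  ld_curve(d, l, specimen_id = specimen_id, state = state,
           sample_rate = sample_rate, actuator_rate = actuator_rate,
           jitter_tol = jitter_tol)
}

sniff_delim <- function(lines, decimal_mark = ".") {
  probe <- lines[min(2L, length(lines))]
  cands <- c(";", "\t", ",", " ")
  if (decimal_mark == ",") cands <- setdiff(cands, ",")
  counts <- vapply(cands, function(s) {
    if (s == " ") length(strsplit(trimws(probe), "[ \t]+")[[1]]) - 1L
    else lengths(regmatches(probe, gregexpr(s, probe, fixed = TRUE)))
  }, integer(1))
  if (all(counts == 0)) stop("could not sniff a delimiter from: ", probe)
  cands[which.max(counts)]
}

#' Write a load-displacement curve to CSV
#'
#' Two columns, `displacement_mm` and `load_n`, with a header; the exact
#' inverse of [read_curve()] with default options.
#'
#' @param curve An `"ld_curve"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "ld_curve"))
  readr::write_csv(tibble::tibble(displacement_mm = curve$displacement,
                                  load_n = curve$load), path)
  invisible(path)
}
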