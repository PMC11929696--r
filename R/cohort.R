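#' @keywords internal
cohort_outcome_cols <- c("stiffness_intact", "yield_intact", "ultimate_intact",
                         "stiffness_instr", "yield_instr", "ultimate_instr")

cohort_required_cols <- c("specimen_id", "fixation_group", "sex", "age",
                          "vbmd", "ct_tt_ratio", "hla", "vla",
                          "fracture_type", cohort_outcome_cols)

#' Construct a cohort table
#'
#' One row per specimen with its group assignment, covariates and the paired
#' intact/instrumented mechanical outcomes. Absent covariates or outcomes are
#' `NA`, never zero, and propagate as per-analysis exclusions.
#'
#' @param data A data frame with columns `specimen_id`, `fixation_group`
#'   (`"cannulated"`/`"allograft"`), `sex` (`"f"`/`"m"`), `age` (years),
#'   `vbmd` (mg HA/cm^3, may be `NA`), `ct_tt_ratio` (percent, may be `NA`),
#'   `hla` (degrees, 0 or -50), `vla` (degrees, -15/0/15), `fracture_type`
#'   (`"II"`/`"III"`), and the six outcome columns `stiffness_intact`,
#'   `yield_intact`, `ultimate_intact`, `stiffness_instr`, `yield_instr`,
#'   `ultimate_instr` (N/mm or N, may be `NA`). Optional: `failure_mode`,
#'   `flags_intact`, `flags_instr` (semicolon-joined flag strings, `""` if
#'   none).
#' @param provenance `"synthetic"` or `"external"`.
#' @param seed Integer seed that produced a synthetic table, or `NA`.
#'
#' @return A tibble of class `"cohort_table"`.
#' @export
cohort_table <- function(data, provenance = c("external", "synthetic"),
                         seed = NA_integer_) {
  provenance <- match.arg(provenance)
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(cohort_required_cols, names(data))
  if (length(missing_cols))
    stop("cohort table missing columns: ", paste(missing_cols, collapse = ", "))
  for (opt in c("failure_mode", "flags_intact", "flags_instr"))
    if (!opt %in% names(data))
      data[[opt]] <- if (opt == "failure_mode") NA_character_ else ""
  data$specimen_id <- as.character(data$specimen_id)
  data$fixation_group <- as.character(data$fixation_group)
  data$sex <- as.character(data$sex)
  data$fracture_type <- as.character(data$fracture_type)
  data$failure_mode <- as.character(data$failure_mode)
  for (col in c("age", "vbmd", "ct_tt_ratio", "hla", "vla",
                cohort_outcome_cols))
    data[[col]] <- as.numeric(data[[col]])

  check_enum <- function(col, levels, allow_na = FALSE) {
    v <- data[[col]]
    bad <- if (allow_na) which(!is.na(v) & !v %in% levels)
           else which(is.na(v) | !v %in% levels)
    if (length(bad))
      stop(sprintf("invalid %s '%s' in row %d (allowed: %s)",
                   col, v[bad[1]], bad[1], paste(levels, collapse = ", ")))
  }
  check_enum("fixation_group", c("cannulated", "allograft"))
  check_enum("sex", c("f", "m"))
  check_enum("fracture_type", c("II", "III"))
  check_enum("hla", c(0, -50))
  check_enum("vla", c(-15, 0, 15))
  dup <- data$specimen_id[duplicated(data$specimen_id)]
  if (length(dup))
    stop("duplicate specimen_id: ", paste(unique(dup), collapse = ", "))

  attr(data, "provenance") <- provenance
  attr(data, "seed") <- seed
  class(data) <- c("cohort_table", class(data))
  data
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d specimens (%s", nrow(x),
              attr(x, "provenance")))
  if (!is.na(attr(x, "seed"))) cat(", seed ", attr(x, "seed"), sep = "")
  cat(")\n")
  print(dplyr::count(tibble::as_tibble(x), .data$fixation_group))
  NextMethod()
}

#' Read / write a cohort table
#'
#' Plain CSV. `"wide"` has one row per specimen with the columns documented
#' in [cohort_table()]; `"long"` has one row per specimen-state with a
#' `state` column and columns `stiffness`, `yield`, `ultimate`, `flags`
#' (metadata repeated on both rows and checked for consistency). Writing
#' then reading reproduces the table field for field.
#'
#' @param path CSV path.
#' @param format `"wide"` (default) or `"long"`.
#' @param provenance,seed Metadata attached to the returned table.
#' @return [read_cohort()]: a `"cohort_table"`; [write_cohort()]: `path`,
#'   invisibly.
#' @export
read_cohort <- function(path, format = c("wide", "long"),
                        provenance = c("external", "synthetic"),
                        seed = NA_integer_) {
  format <- match.arg(format)
  provenance <- match.arg(provenance)
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (format == "long") raw <- cohort_long_to_wide(raw)
  if ("flags_intact" %in% names(raw))
    raw$flags_intact <- dplyr::coalesce(as.character(raw$flags_intact), "")
  if ("flags_instr" %in% names(raw))
    raw$flags_instr <- dplyr::coalesce(as.character(raw$flags_instr), "")
  cohort_table(raw, provenance = provenance, seed = seed)
}

#' @rdname read_cohort
#' @param table A `"cohort_table"`.
#' @export
write_cohort <- function(table, path, format = c("wide", "long")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "cohort_table"))
  out <- tibble::as_tibble(table)
  if (format == "long") out <- cohort_wide_to_long(out)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

cohort_wide_to_long <- function(wide) {
  meta <- setdiff(names(wide), c(cohort_outcome_cols,
                                 "flags_intact", "flags_instr"))
  long <- tidyr::pivot_longer(
    wide,
    cols = dplyr::all_of(c(cohort_outcome_cols, "flags_intact", "flags_instr")),
    names_to = c(".value", "state"),
    names_pattern = "(stiffness|yield|ultimate|flags)_(intact|instr)")
  long$state <- ifelse(long$state == "instr", "instrumented", "intact")
  dplyr::relocate(long, dplyr::all_of(meta), "state")
}

cohort_long_to_wide <- function(long) {
  need <- c("specimen_id", "state", "stiffness", "yield", "ultimate")
  missing_cols <- setdiff(need, names(long))
  if (length(missing_cols))
    stop("long cohort table missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (!"flags" %in% names(long)) long$flags <- ""
  long$state <- ifelse(long$state == "instrumented", "instr", long$state)
  bad_state <- setdiff(unique(long$state), c("intact", "instr"))
  if (length(bad_state)) stop("unknown state: ", paste(bad_state, collapse = ", "))
  meta <- setdiff(names(long), c("state", "stiffness", "yield", "ultimate",
                                 "flags"))
  incons <- dplyr::group_by(long[, meta], .data$specimen_id)
  incons <- dplyr::filter(dplyr::summarise(
    incons, n_variants = dplyr::n_distinct(dplyr::pick(dplyr::everything())),
    .groups = "drop"), .data$n_variants > 1)
  if (nrow(incons))
    stop("inconsistent metadata across states for specimen ",
         paste(incons$specimen_id, collapse = ", "))
  tidyr::pivot_wider(long, id_cols = dplyr::all_of(meta),
                     names_from = "state",
                     values_from = c("stiffness", "yield", "ultimate", "flags"),
                     names_glue = "{.value}_{state}")
}
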