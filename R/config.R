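#' Pipeline configuration
#'
#' Collects every tunable threshold of the extraction pipeline in one place.
#' All lengths are millimetres, loads newtons.
#'
#' @param kernel_mm Width of the moving regression kernel used for stiffness
#'   (default 1 mm).
#' @param toe_mm End of the toe region; candidate stiffness windows start at
#'   or after this displacement (default 1 mm).
#' @param r_threshold Pearson correlation threshold below which the expanding
#'   yield-search window declares loss of linearity (default 0.85).
#' @param r_plausibility Minimum best-window correlation considered a
#'   plausible linear region; below it the curve is flagged
#'   `nonlinear_curve` for manual review (default 0.99).
#' @param drop_fraction Fractional load drop after the maximum required to
#'   consider the failure "major"; curves that never fall below
#'   `(1 - drop_fraction) * F_UL` are flagged `no_load_drop` (default 0.2).
#' @param jitter_tol Largest tolerated transient decrease in displacement
#'   (transducer jitter), in mm (default 1e-6).
#' @param yield_policy `"expand"` (right edge grows from the best-fit window,
#'   left edge anchored at its start) or `"slide"` (the 1 mm kernel keeps
#'   moving right and yield is the first window with r below threshold).
#' @param smooth_width Odd integer width of an optional moving-average load
#'   filter applied before extraction; `1` disables smoothing (default).
#'
#' @return A list of class `"om_config"`.
#' @export
#' @examples
#' pipeline_config(kernel_mm = 0.5)
pipeline_config <- function(kernel_mm = 1.0,
                            toe_mm = 1.0,
                            r_threshold = 0.85,
                            r_plausibility = 0.99,
                            drop_fraction = 0.2,
                            jitter_tol = 1e-6,
                            yield_policy = c("expand", "slide"),
                            smooth_width = 1L) {
  yield_policy <- match.arg(yield_policy)
  stopifnot(kernel_mm > 0, toe_mm >= 0, r_threshold > 0, r_threshold < 1,
            drop_fraction > 0, drop_fraction < 1, jitter_tol >= 0,
            smooth_width >= 1, smooth_width %% 2 == 1)
  structure(list(kernel_mm = kernel_mm, toe_mm = toe_mm,
                 r_threshold = r_threshold, r_plausibility = r_plausibility,
                 drop_fraction = drop_fraction, jitter_tol = jitter_tol,
                 yield_policy = yield_policy,
                 smooth_width = as.integer(smooth_width)),
            class = "om_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys absent from the file keep their [pipeline_config()] defaults;
#' unknown keys are an error, so typos never pass silently.
#'
#' @param path Path to a YAML file of key-value pairs.
#' @return A list of class `"om_config"`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @export
print.om_config <- function(x, ...) {
  cat("<odontomech pipeline config>\n")
  for (k in names(x)) cat(sprintf("  %-15s %s\n", k, format(x[[k]])))
  invisible(x)
}
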