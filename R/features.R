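#' @keywords internal
#' Vectorised OLS statistics over many index windows of one curve.
#' Data are centred once per curve before forming cumulative sums, which
#' keeps the running-sum formulas well conditioned for long records.
window_stats <- function(d, f, i_start, i_end) {
  xc <- d - mean(d)
  yc <- f - mean(f)
  c1x <- c(0, cumsum(xc));  c1y <- c(0, cumsum(yc))
  c2x <- c(0, cumsum(xc^2)); c2y <- c(0, cumsum(yc^2))
  cxy <- c(0, cumsum(xc * yc))
  n  <- i_end - i_start + 1
  sx <- c1x[i_end + 1] - c1x[i_start]
  sy <- c1y[i_end + 1] - c1y[i_start]
  vx <- (c2x[i_end + 1] - c2x[i_start]) - sx^2 / n
  vy <- (c2y[i_end + 1] - c2y[i_start]) - sy^2 / n
  sxy <- (cxy[i_end + 1] - cxy[i_start]) - sx * sy / n
  # a window variance at the level of accumulated rounding error is a
  # degenerate (constant) window, not signal
  tol_x <- n * mean(xc^2) * 1e-11
  tol_y <- n * mean(yc^2) * 1e-11
  slope <- ifelse(vx > tol_x, sxy / vx, NA_real_)
  r <- ifelse(vx > tol_x & vy > tol_y, sxy / sqrt(vx * vy), NA_real_)
  r <- snap_r(r)
  mean_x <- sx / n + mean(d)
  mean_y <- sy / n + mean(f)
  list(slope = slope, intercept = mean_y - slope * mean_x, r = r, n = n)
}

# Exactly collinear windows come out of the running sums as 1 +- a few
# ulp; snapping restores the exact tie so that "earliest window wins" is
# deterministic and matches a plain cor()-based scan.
snap_r <- function(r) {
  r <- pmin(pmax(r, -1), 1)
  ifelse(!is.na(r) & r > 1 - 1e-10, 1, r)
}

kernel_fit <- function(stats_i, i_start, i_end, d) {
  structure(list(window_start = d[i_start], window_end = d[i_end],
                 slope = stats_i$slope, intercept = stats_i$intercept,
                 pearson_r = stats_i$r, n_points = stats_i$n,
                 i_start = i_start, i_end = i_end),
            class = "kernel_fit")
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat(sprintf(
    "<kernel_fit> window [%.4f, %.4f] mm, slope %.2f N/mm, r %.6f, n=%d\n",
    x$window_start, x$window_end, x$slope, x$pearson_r, x$n_points))
  invisible(x)
}

#' Ultimate load of a load-displacement curve
#'
#' The ultimate load is the absolute maximum of the curve. A curve that
#' never subsequently falls below `(1 - drop_fraction) * F_UL` shows no
#' major failure drop; the maximum is still returned but flagged
#' `no_load_drop` so it can be routed to manual review rather than silently
#' trusted.
#'
#' @param curve An [ld_curve()].
#' @param drop_fraction Fractional drop defining a "major" load drop
#'   (default 0.2).
#' @return A list with `f_ul` (N), `d_ul` (mm), `i_ul` (sample index) and
#'   `flags` (character vector).
#' @export
#' @examples
#' cv <- ld_curve(0:3, c(0, 50, 120, 80))
#' compute_ultimate_load(cv)
compute_ultimate_load <- function(curve, drop_fraction = 0.2) {
  stopifnot(inherits(curve, "ld_curve"))
  i_ul <- which.max(curve$load)
  f_ul <- curve$load[i_ul]
  flags <- character()
  post_min <- min(curve$load[i_ul:length(curve$load)])
  if (post_min > (1 - drop_fraction) * f_ul) flags <- "no_load_drop"
  list(f_ul = f_ul, d_ul = curve$displacement[i_ul], i_ul = i_ul,
       flags = flags)
}

#' Stiffness from the most linear curve segment
#'
#' Stiffness is the slope of the ordinary least-squares line fitted on a
#' contiguous window of width `kernel_mm` of the load-displacement curve.
#' The window is chosen by moving the kernel one sample at a time over all
#' admissible positions -- starts in `[toe_end_mm, d(F_UL) - kernel_mm]`,
#' ends at or before the displacement of the ultimate load -- and taking the
#' window with the highest Pearson correlation coefficient; ties break
#' toward the earliest window.
#'
#' @param curve An [ld_curve()].
#' @param toe_end_mm End of the toe region; no window starts before it
#'   (default 1 mm).
#' @param kernel_mm Kernel width in mm (default 1).
#' @param search_end_mm Upper displacement cap for window ends; `NULL`
#'   (default) uses the displacement of the ultimate load, a conservative
#'   stand-in for the unknown onset of plasticity.
#' @param r_plausibility If the best window's correlation falls below this,
#'   the curve is flagged `nonlinear_curve` (stiffness is still returned).
#' @param drop_fraction Passed to [compute_ultimate_load()] for the cap.
#' @return A list with `stiffness` (N/mm, `NA` if all windows are
#'   degenerate), `best_fit` (a `kernel_fit`, or `NULL`), and `flags`.
#' @export
compute_stiffness <- function(curve, toe_end_mm = 1.0, kernel_mm = 1.0,
                              search_end_mm = NULL, r_plausibility = 0.99,
                              drop_fraction = 0.2) {
  stopifnot(inherits(curve, "ld_curve"))
  d <- curve$displacement
  f <- curve$load
  if (max(d) - d[1] < toe_end_mm + kernel_mm)
    stop(sprintf(
      "curve too short: spans %.3f mm, needs toe (%g) + kernel (%g) mm",
      max(d) - d[1], toe_end_mm, kernel_mm))
  if (is.null(search_end_mm)) {
    ul <- compute_ultimate_load(curve, drop_fraction)
    search_end_mm <- ul$d_ul
    i_cap <- ul$i_ul
  } else {
    i_cap <- max(which(d <= search_end_mm + 1e-9))
  }
  tol <- 1e-9
  starts <- which(d >= toe_end_mm - tol & d <= search_end_mm - kernel_mm + tol)
  if (!length(starts))
    stop(sprintf(
      "no admissible stiffness window: toe %g mm + kernel %g mm exceeds the %.3f mm available before the load maximum",
      toe_end_mm, kernel_mm, search_end_mm))
  ends <- findInterval(d[starts] + kernel_mm + tol, d)
  keep <- ends <= i_cap & (ends - starts + 1) >= 3
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts))
    stop("no admissible stiffness window with >= 3 samples before the load maximum")

  ws <- window_stats(d, f, starts, ends)
  if (all(is.na(ws$r)))
    return(list(stiffness = NA_real_, best_fit = NULL,
                flags = "nonlinear_curve"))
  r_use <- ifelse(is.na(ws$r), -Inf, ws$r)
  best <- which.max(r_use)   # first index among exact ties -> earliest window
  fit <- kernel_fit(lapply(ws, `[`, best), starts[best], ends[best], d)
  flags <- character()
  if (fit$pearson_r < r_plausibility) flags <- "nonlinear_curve"
  list(stiffness = fit$slope, best_fit = fit, flags = flags)
}

#' Yield load by correlation decay
#'
#' Starting from the best stiffness window, the regression window's right
#' edge is extended sample by sample (left edge anchored at the window
#' start) and the Pearson correlation recomputed; the yield load is the load
#' at the first right-edge sample where the correlation drops below
#' `r_threshold`, marking the loss of linearity at the onset of irreversible
#' deformation. The search is capped at the displacement of the ultimate
#' load; if the correlation never drops below the threshold before the cap,
#' the yield is absent and `yield_not_found` is flagged.
#'
#' @param curve An [ld_curve()].
#' @param best_fit The `kernel_fit` returned by [compute_stiffness()] on the
#'   same curve.
#' @param r_threshold Correlation threshold (default 0.85).
#' @param policy `"expand"` (default, as described) or `"slide"`: the
#'   fixed-width kernel keeps moving right and yield is taken at the right
#'   edge of the first window whose correlation is below threshold.
#' @param i_cap Sample index of the search cap; defaults to the index of
#'   the ultimate load.
#' @return A list with `f_yl` (N or `NA`), `d_yl` (mm or `NA`), `flags`,
#'   and `r_trace` (a tibble of right-edge displacement and correlation, for
#'   audit).
#' @export
compute_yield_load <- function(curve, best_fit, r_threshold = 0.85,
                               policy = c("expand", "slide"), i_cap = NULL) {
  stopifnot(inherits(curve, "ld_curve"))
  if (is.null(best_fit) || !inherits(best_fit, "kernel_fit"))
    stop("compute_yield_load needs the best_fit window from compute_stiffness")
  policy <- match.arg(policy)
  d <- curve$displacement
  f <- curve$load
  if (is.null(i_cap)) i_cap <- compute_ultimate_load(curve)$i_ul

  if (policy == "expand") {
    a <- best_fit$i_start
    js <- if (best_fit$i_end + 1L > i_cap) integer()
          else seq.int(best_fit$i_end + 1L, i_cap)
    ws <- if (length(js)) window_stats(d, f, rep.int(a, length(js)), js)
          else list(r = numeric())
  } else {
    kernel_mm <- best_fit$window_end - best_fit$window_start
    a0 <- best_fit$i_start + 1L
    starts <- if (a0 > i_cap) integer() else seq.int(a0, i_cap)
    ends <- findInterval(d[starts] + kernel_mm + 1e-9, d)
    keep <- ends <= i_cap & (ends - starts + 1) >= 3
    starts <- starts[keep]; js <- ends[keep]
    ws <- if (length(js)) window_stats(d, f, starts, js)
          else list(r = numeric())
  }
  r_trace <- tibble::tibble(displacement = d[js], pearson_r = ws$r)
  hit <- which(!is.na(ws$r) & ws$r < r_threshold)
  if (!length(hit))
    return(list(f_yl = NA_real_, d_yl = NA_real_, flags = "yield_not_found",
                r_trace = r_trace))
  j <- js[hit[1]]
  list(f_yl = f[j], d_yl = d[j], flags = character(), r_trace = r_trace)
}

#' Mechanical outcomes of one curve
#'
#' @param stiffness,yield_load,ultimate_load Scalars (N/mm, N, N) or `NA`.
#' @param stiffness_window Numeric length-2, displacement of the chosen
#'   stiffness window, or `NULL`.
#' @param yield_displacement,ultimate_displacement Scalars, mm, or `NA`.
#' @param flags Character vector drawn from `nonlinear_curve`,
#'   `no_load_drop`, `yield_not_found`, `manual_review`.
#' @return A list of class `"mech_outcomes"`.
#' @export
mech_outcomes <- function(stiffness = NA_real_, yield_load = NA_real_,
                          ultimate_load = NA_real_, stiffness_window = NULL,
                          yield_displacement = NA_real_,
                          ultimate_displacement = NA_real_,
                          flags = character()) {
  known <- c("nonlinear_curve", "no_load_drop", "yield_not_found",
             "manual_review")
  bad <- setdiff(flags, known)
  if (length(bad)) stop("unknown flag: ", paste(bad, collapse = ", "))
  if (!is.na(stiffness) && stiffness <= 0)
    stop("stiffness must be positive when present")
  if (!is.na(yield_load) && !is.na(ultimate_load) &&
      yield_load > ultimate_load)
    stop("yield load cannot exceed ultimate load")
  structure(list(stiffness = stiffness, yield_load = yield_load,
                 ultimate_load = ultimate_load,
                 stiffness_window = stiffness_window,
                 yield_displacement = yield_displacement,
                 ultimate_displacement = ultimate_displacement,
                 flags = unique(flags)),
            class = "mech_outcomes")
}

#' @export
print.mech_outcomes <- function(x, ...) {
  fmt <- function(v, u) if (is.na(v)) "absent" else sprintf("%.2f %s", v, u)
  cat("<mech_outcomes>\n")
  cat("  stiffness:     ", fmt(x$stiffness, "N/mm"), "\n")
  cat("  yield load:    ", fmt(x$yield_load, "N"), "\n")
  cat("  ultimate load: ", fmt(x$ultimate_load, "N"), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Extract all mechanical outcomes from one curve
#'
#' Composes [compute_ultimate_load()], [compute_stiffness()] and
#' [compute_yield_load()] under a single configuration. Any flag raised by a
#' component additionally marks the specimen `manual_review`, mirroring the
#' visual-verification triage such tests receive in practice; the audit trail
#' (chosen window, correlation trace, drop check) is attached as attribute
#' `"audit"`.
#'
#' @param curve An [ld_curve()].
#' @param config A [pipeline_config()].
#' @return A [mech_outcomes()] with attribute `"audit"`.
#' @export
#' @examples
#' sim <- simulate_curve(curve_params(s_true = 181, f_yield = 755,
#'                                    f_ult = 825, sample_spacing = 0.01))
#' extract_outcomes(sim$curve)
extract_outcomes <- function(curve, config = pipeline_config()) {
  stopifnot(inherits(curve, "ld_curve"), inherits(config, "om_config"))
  if (config$smooth_width > 1) {
    k <- config$smooth_width
    sm <- stats::filter(curve$load, rep(1 / k, k), sides = 2)
    pad <- (k - 1) / 2
    sm[seq_len(pad)] <- curve$load[seq_len(pad)]
    n <- length(sm)
    sm[seq.int(n - pad + 1, n)] <- curve$load[seq.int(n - pad + 1, n)]
    curve$load <- as.numeric(sm)
  }
  ul <- compute_ultimate_load(curve, config$drop_fraction)
  st <- compute_stiffness(curve, toe_end_mm = config$toe_mm,
                          kernel_mm = config$kernel_mm,
                          r_plausibility = config$r_plausibility,
                          drop_fraction = config$drop_fraction)
  if (is.null(st$best_fit)) {
    yl <- list(f_yl = NA_real_, d_yl = NA_real_, flags = "yield_not_found",
               r_trace = tibble::tibble(displacement = numeric(),
                                        pearson_r = numeric()))
  } else {
    yl <- compute_yield_load(curve, st$best_fit,
                             r_threshold = config$r_threshold,
                             policy = config$yield_policy, i_cap = ul$i_ul)
  }
  flags <- unique(c(ul$flags, st$flags, yl$flags))
  if (length(flags)) flags <- c(flags, "manual_review")
  out <- mech_outcomes(
    stiffness = st$stiffness,
    yield_load = yl$f_yl,
    ultimate_load = ul$f_ul,
    stiffness_window = if (!is.null(st$best_fit))
      c(st$best_fit$window_start, st$best_fit$window_end),
    yield_displacement = yl$d_yl,
    ultimate_displacement = ul$d_ul,
    flags = flags)
  attr(out, "audit") <- list(specimen_id = curve$specimen_id,
                             state = curve$state,
                             best_fit = st$best_fit,
                             r_trace = yl$r_trace,
                             drop_checked = !("no_load_drop" %in% ul$flags))
  out
}
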