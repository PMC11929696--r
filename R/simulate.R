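#' Ground-truth parameters of one synthetic load-displacement curve
#'
#' The synthetic curve is piecewise: a sub-linear power-law toe on
#' `[0, toe_end]` joined C1-continuously to the linear elastic segment of
#' slope `s_true`, a shallow linear post-yield (hardening) segment of slope
#' `hardening_fraction * s_true` rising from the yield load to the ultimate
#' load, an abrupt catastrophic drop to `drop_fraction_post * f_ult`, and a
#' short residual plateau. I.i.d. Gaussian noise of SD `noise_sd` is added
#' to the load only (displacement is actuator-controlled).
#'
#' @param s_true Elastic stiffness, N/mm.
#' @param f_yield True yield load, N; must exceed the toe-end load
#'   `s_true * toe_end / toe_shape` and not exceed `f_ult`.
#' @param f_ult True ultimate load, N.
#' @param toe_end End of the toe region, mm (default 1).
#' @param toe_shape Power-law exponent >= 1 of the toe ramp (default 2).
#' @param hardening_fraction Post-yield slope as a fraction of `s_true`, in
#'   `[0, 1)` (default 0.04). The shallow long segment makes the loss of
#'   linearity detectable by correlation decay before the load peak.
#' @param drop_fraction_post Load retained after the catastrophic drop, as a
#'   fraction of `f_ult`, in `[0, 1)` (default 0.25).
#' @param noise_sd Load noise SD, N (default 0).
#' @param sample_spacing Displacement between samples, mm; the default
#'   0.1/128 reproduces acquisition at 0.1 mm/s digitised at 128 Hz.
#' @param post_drop_mm Length of the post-failure plateau, mm (default 0.8).
#' @return A list of class `"curve_params"`, including the derived yield and
#'   ultimate displacements `d_yield`, `d_ult`.
#' @export
curve_params <- function(s_true, f_yield, f_ult, toe_end = 1.0,
                         toe_shape = 2, hardening_fraction = 0.04,
                         drop_fraction_post = 0.25, noise_sd = 0,
                         sample_spacing = 0.1 / 128, post_drop_mm = 0.8) {
  stopifnot(s_true > 0, f_yield > 0, toe_end > 0, toe_shape >= 1,
            hardening_fraction >= 0, hardening_fraction < 1,
            drop_fraction_post >= 0, drop_fraction_post < 1,
            noise_sd >= 0, sample_spacing > 0, post_drop_mm >= 0)
  if (f_yield > f_ult)
    stop("f_yield (", f_yield, ") must not exceed f_ult (", f_ult, ")")
  f_toe <- s_true * toe_end / toe_shape
  if (f_yield <= f_toe)
    stop(sprintf(
      "f_yield (%.1f N) must exceed the toe-end load s_true*toe_end/toe_shape (%.1f N)",
      f_yield, f_toe))
  if (f_ult > f_yield && hardening_fraction == 0)
    stop("hardening_fraction = 0 cannot raise the load from f_yield to f_ult")
  d_yield <- toe_end + (f_yield - f_toe) / s_true
  d_ult <- if (f_ult > f_yield)
    d_yield + (f_ult - f_yield) / (hardening_fraction * s_true) else d_yield
  structure(list(s_true = s_true, f_yield = f_yield, f_ult = f_ult,
                 toe_end = toe_end, toe_shape = toe_shape,
                 hardening_fraction = hardening_fraction,
                 drop_fraction_post = drop_fraction_post,
                 noise_sd = noise_sd, sample_spacing = sample_spacing,
                 post_drop_mm = post_drop_mm, f_toe = f_toe,
                 d_yield = d_yield, d_ult = d_ult),
            class = "curve_params")
}

#' Simulate one load-displacement curve with known ground truth
#'
#' @param params A [curve_params()].
#' @param seed Optional integer seed for the load noise.
#' @param specimen_id,state Metadata for the returned curve.
#' @return A list with `curve` (an [ld_curve()]) and `truth` (the true
#'   stiffness, yield and ultimate loads, their displacements, and the
#'   post-yield softening band within which a correlation-decay yield
#'   detection is expected to land).
#' @export
#' @examples
#' sim <- simulate_curve(curve_params(200, 700, 760, sample_spacing = 0.01))
#' plot(sim$curve$displacement, sim$curve$load, type = "l")
simulate_curve <- function(params, seed = NULL, specimen_id = "sim",
                           state = c("intact", "instrumented")) {
  stopifnot(inherits(params, "curve_params"))
  state <- match.arg(state)
  if (!is.null(seed)) set.seed(seed)
  p <- params
  d_end <- p$d_ult + p$post_drop_mm
  d <- seq(0, d_end, by = p$sample_spacing)
  f <- numeric(length(d))
  toe <- d <= p$toe_end
  lin <- d > p$toe_end & d <= p$d_yield
  hard <- d > p$d_yield & d <= p$d_ult
  post <- d > p$d_ult
  f[toe] <- p$f_toe * (d[toe] / p$toe_end)^p$toe_shape
  f[lin] <- p$f_toe + p$s_true * (d[lin] - p$toe_end)
  f[hard] <- p$f_yield + p$hardening_fraction * p$s_true * (d[hard] - p$d_yield)
  f[post] <- p$drop_fraction_post * p$f_ult
  if (p$noise_sd > 0) f <- f + rnorm(length(f), sd = p$noise_sd)
  curve <- ld_curve(d, f, specimen_id = specimen_id, state = state,
                    sample_rate = 128,
                    actuator_rate = 128 * p$sample_spacing)
  truth <- list(s_true = p$s_true, f_yield = p$f_yield, f_ult = p$f_ult,
                d_yield = p$d_yield, d_ult = p$d_ult,
                softening_band_d = c(p$d_yield, p$d_ult),
                softening_band_f = c(p$f_yield, p$f_ult))
  list(curve = curve, truth = truth)
}

#' Draw random curve parameters
#'
#' Uniform draws over the ranges spanned by typical intact and instrumented
#' odontoid tests: stiffness 80-400 N/mm, an ultimate load of 2.6-5 times
#' the stiffness-by-1-mm load (matching observed load/stiffness ratios and
#' guaranteeing an elastic span longer than the regression kernel), and a
#' yield/ultimate ratio of 0.85-0.92. Used for property-based testing of
#' the extraction chain.
#'
#' @param n Number of parameter sets.
#' @param seed Optional integer seed.
#' @param noise_sd,sample_spacing Passed to every [curve_params()].
#' @return A list of `curve_params`.
#' @export
random_curve_params <- function(n, seed = NULL, noise_sd = 0,
                                sample_spacing = 0.02) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) {
    s <- runif(1, 80, 400)
    fu <- s * runif(1, 2.6, 5.0)
    fy <- runif(1, 0.85, 0.92) * fu
    curve_params(s_true = s, f_yield = fy, f_ult = fu,
                 noise_sd = noise_sd, sample_spacing = sample_spacing)
  })
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate a two-group cadaveric odontoid-fixation study on older
#' donors: two fixation groups (25 cannulated-screw, 22 bone-allograft
#' specimens), group-specific donor age, sex, vBMD and Ct.Ar/Tt.Ar
#' distributions, intact mechanical outcomes driven linearly by vBMD and
#' Ct.Ar/Tt.Ar, and instrumented outcomes equal to a per-group restoration
#' fraction of the intact value times mean-one lognormal specimen noise.
#'
#' @param n_per_group Named integer vector, specimens per fixation group.
#' @param restoration_fraction 2 x 3 matrix (rows cannulated/allograft,
#'   columns stiffness/yield/ultimate) of true restoration fractions, or a
#'   single number applied everywhere. Defaults are the observed unadjusted
#'   group means scaled to fractions.
#' @param covariates Per-group means/SDs/ranges of age (years), probability
#'   of female sex, vBMD (mg HA/cm^3) and Ct.Ar/Tt.Ar (%); see defaults.
#' @param coef_vbmd_ultimate Increase in intact ultimate load per unit vBMD
#'   (N per mg HA/cm^3); the default 1.84, with `sd_ultimate` 228 N, targets
#'   a vBMD-ultimate coefficient of determination of about 0.5.
#' @param coef_vbmd_stiffness,coef_ctr_stiffness Linear effects of vBMD and
#'   Ct.Ar/Tt.Ar on intact stiffness (N/mm per unit).
#' @param sd_stiffness,sd_ultimate Residual SDs of the intact outcomes.
#' @param yield_ratio_range Range of the per-specimen intact yield/ultimate
#'   load ratio.
#' @param instr_sdlog Named per-outcome SD (log scale) of the mean-one
#'   lognormal noise on instrumented outcomes.
#' @param missing_prob_vbmd,missing_prob_ctr Per-group probability that the
#'   imaging covariate is missing (corrupt scan).
#' @param curve Default [curve_params()] settings (toe, hardening, drop,
#'   noise, spacing) used when curves are materialised.
#' @param seed Default integer seed.
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(
    n_per_group = c(cannulated = 25, allograft = 22),
    restoration_fraction = rbind(
      cannulated = c(stiffness = 0.5697, yield = 0.4808, ultimate = 0.4999),
      allograft = c(stiffness = 0.3200, yield = 0.2684, ultimate = 0.2899)),
    covariates = list(
      cannulated = list(age_mean = 82.5, age_sd = 8.4, age_range = c(65, 101),
                        p_female = 0.60,
                        vbmd_mean = 531.40, vbmd_sd = 139.27,
                        vbmd_range = c(300, 900),
                        ctr_mean = 39.60, ctr_sd = 9.98,
                        ctr_range = c(20, 66)),
      allograft = list(age_mean = 71.2, age_sd = 5.6, age_range = c(59, 79),
                       p_female = 0.27,
                       vbmd_mean = 556.59, vbmd_sd = 115.87,
                       vbmd_range = c(300, 900),
                       ctr_mean = 41.88, ctr_sd = 9.13,
                       ctr_range = c(20, 66))),
    ultimate_mean = c(cannulated = 825.4, allograft = 1130.5),
    stiffness_mean = c(cannulated = 181.3, allograft = 375.8),
    coef_vbmd_ultimate = 1.84, sd_ultimate = 228,
    coef_vbmd_stiffness = 0.45, coef_ctr_stiffness = 2.5, sd_stiffness = 70,
    yield_ratio_range = c(0.85, 0.92),
    instr_sdlog = c(stiffness = 0.60, yield = 0.55, ultimate = 0.45),
    missing_prob_vbmd = c(cannulated = 0, allograft = 3 / 22),
    missing_prob_ctr = c(cannulated = 1 / 25, allograft = 3 / 22),
    curve = list(toe_end = 1.0, toe_shape = 2, hardening_fraction = 0.04,
                 drop_fraction_post = 0.25, noise_sd = 5,
                 sample_spacing = 0.1 / 128),
    seed = 1L) {
  if (is.null(names(n_per_group)))
    names(n_per_group) <- c("cannulated", "allograft")
  if (length(restoration_fraction) == 1)
    restoration_fraction <- matrix(restoration_fraction, 2, 3,
      dimnames = list(c("cannulated", "allograft"),
                      c("stiffness", "yield", "ultimate")))
  stopifnot(all(n_per_group > 0), all(restoration_fraction > 0),
            all(instr_sdlog >= 0), sd_ultimate >= 0, sd_stiffness >= 0,
            all(yield_ratio_range > 0 & yield_ratio_range < 1))
  structure(list(n_per_group = n_per_group,
                 restoration_fraction = restoration_fraction,
                 covariates = covariates,
                 ultimate_mean = ultimate_mean,
                 stiffness_mean = stiffness_mean,
                 coef_vbmd_ultimate = coef_vbmd_ultimate,
                 sd_ultimate = sd_ultimate,
                 coef_vbmd_stiffness = coef_vbmd_stiffness,
                 coef_ctr_stiffness = coef_ctr_stiffness,
                 sd_stiffness = sd_stiffness,
                 yield_ratio_range = yield_ratio_range,
                 instr_sdlog = instr_sdlog,
                 missing_prob_vbmd = missing_prob_vbmd,
                 missing_prob_ctr = missing_prob_ctr,
                 curve = curve, seed = as.integer(seed)),
            class = "sim_config")
}

# truncated-normal draw by rejection (ranges are several SDs wide, so the
# acceptance rate is high)
rtnorm <- function(n, mean, sd, lo, hi) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

#' Simulate a paired two-group cohort
#'
#' Draws per-group covariates, intact mechanical outcomes as linear
#' functions of vBMD and Ct.Ar/Tt.Ar plus Gaussian noise, and instrumented
#' outcomes as `restoration_fraction * intact * lognormal(mean 1)`. With
#' `measure = "curves"` every specimen-state is additionally materialised as
#' a synthetic load-displacement curve and the outcomes are re-measured by
#' [extract_outcomes()], so the whole pipeline (simulate, extract, restore,
#' analyse) runs end to end. Ground truth is always attached as attribute
#' `"ground_truth"`.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; defaults to `config$seed`. Curve noise uses
#'   per-specimen substreams derived from it, so individual specimens are
#'   reproducible in isolation.
#' @param measure `"truth"` (default): measured outcomes equal the true
#'   values. `"curves"`: outcomes are extracted from materialised curves.
#' @param pipeline A [pipeline_config()] used when `measure = "curves"`.
#' @param emit_curves Optional directory; when given (with
#'   `measure = "curves"`), each curve is written as
#'   `<specimen_id>_<state>.csv`.
#' @return A [cohort_table()] with attributes `ground_truth` (tibble of true
#'   values) and `seed`.
#' @export
#' @examples
#' coh <- simulate_cohort(simulation_config(n_per_group = c(4, 4)), seed = 7)
#' pair_and_restore(coh)$group_summary
simulate_cohort <- function(config = simulation_config(),
                            seed = config$seed,
                            measure = c("truth", "curves"),
                            pipeline = pipeline_config(),
                            emit_curves = NULL) {
  stopifnot(inherits(config, "sim_config"))
  measure <- match.arg(measure)
  set.seed(seed)
  groups <- names(config$n_per_group)

  rows <- lapply(groups, function(g) {
    n <- config$n_per_group[[g]]
    cv <- config$covariates[[g]]
    age <- rtnorm(n, cv$age_mean, cv$age_sd, cv$age_range[1], cv$age_range[2])
    sex <- ifelse(runif(n) < cv$p_female, "f", "m")
    vbmd <- rtnorm(n, cv$vbmd_mean, cv$vbmd_sd, cv$vbmd_range[1],
                   cv$vbmd_range[2])
    ctr <- rtnorm(n, cv$ctr_mean, cv$ctr_sd, cv$ctr_range[1], cv$ctr_range[2])
    s_int <- config$stiffness_mean[[g]] +
      config$coef_vbmd_stiffness * (vbmd - cv$vbmd_mean) +
      config$coef_ctr_stiffness * (ctr - cv$ctr_mean) +
      rnorm(n, sd = config$sd_stiffness)
    s_int <- pmax(s_int, 40)
    ful_int <- config$ultimate_mean[[g]] +
      config$coef_vbmd_ultimate * (vbmd - cv$vbmd_mean) +
      rnorm(n, sd = config$sd_ultimate)
    # floors keep the piecewise curve model realisable: the yield load must
    # clear the toe-end load (s/2 at the default toe) and stay below the
    # ultimate load; they bind only in extreme tails of the noise draws
    ful_int <- pmax(ful_int, 0.75 * s_int)
    yr <- runif(n, config$yield_ratio_range[1], config$yield_ratio_range[2])
    fyl_int <- yr * ful_int

    rf <- config$restoration_fraction[g, ]
    # mean-one lognormal specimen noise; yield and ultimate share one
    # specimen factor (fixation quality), which reproduces their strong
    # observed correlation and keeps yield below ultimate almost surely;
    # stiffness loads the same factor at 0.7 (same trabecular bed carries
    # the implant), which keeps load/stiffness ratios physiological
    lnoise <- function(sdlog, z) exp(sdlog * z - sdlog^2 / 2)
    z_load <- rnorm(n)
    z_stiff <- 0.7 * z_load + sqrt(1 - 0.49) * rnorm(n)
    s_ins <- rf[["stiffness"]] * s_int *
      lnoise(config$instr_sdlog[["stiffness"]], z_stiff)
    fyl_ins <- rf[["yield"]] * fyl_int *
      lnoise(config$instr_sdlog[["yield"]], z_load)
    ful_ins <- rf[["ultimate"]] * ful_int *
      lnoise(config$instr_sdlog[["ultimate"]], z_load)
    ful_ins <- pmax(ful_ins, 0.75 * s_ins)
    fyl_ins <- pmin(pmax(fyl_ins, 0.62 * s_ins), 0.97 * ful_ins)

    miss_v <- runif(n) < config$missing_prob_vbmd[[g]]
    miss_c <- runif(n) < config$missing_prob_ctr[[g]]
    vbmd[miss_v] <- NA
    ctr[miss_c] <- NA

    fmode <- if (g == "allograft") {
      p_break <- stats::plogis(-0.75 +
        1.1 * (ful_int - mean(ful_int)) / max(sd(ful_int), 1))
      ifelse(runif(n) < p_break, "implant_breakage", "other")
    } else rep("screw_cutout_or_fracture", n)

    tibble::tibble(
      specimen_id = sprintf("%s%02d", toupper(substr(g, 1, 1)), seq_len(n)),
      fixation_group = g, sex = sex, age = age, vbmd = vbmd,
      ct_tt_ratio = ctr,
      hla = sample(c(0, -50), n, replace = TRUE,
                   prob = if (g == "cannulated") c(10, 15) else c(12, 10)),
      vla = sample(c(-15, 0, 15), n, replace = TRUE,
                   prob = if (g == "cannulated") c(9, 9, 7) else c(8, 9, 5)),
      fracture_type = sample(c("II", "III"), n, replace = TRUE,
                             prob = if (g == "cannulated") c(13, 12)
                                    else c(10, 12)),
      failure_mode = fmode,
      stiffness_intact = s_int, yield_intact = fyl_int,
      ultimate_intact = ful_int,
      stiffness_instr = s_ins, yield_instr = fyl_ins,
      ultimate_instr = ful_ins,
      flags_intact = "", flags_instr = "")
  })
  tb <- dplyr::bind_rows(rows)
  truth <- tb[, c("specimen_id", "fixation_group", cohort_outcome_cols)]

  if (measure == "curves") {
    if (!is.null(emit_curves) && !dir.exists(emit_curves))
      dir.create(emit_curves, recursive = TRUE)
    cp <- config$curve
    for (i in seq_len(nrow(tb))) {
      sub_seed <- (seed * 1009 + i * 7919) %% 2147483647
      for (st in c("intact", "instr")) {
        state <- if (st == "intact") "intact" else "instrumented"
        pars <- curve_params(
          s_true = tb[[paste0("stiffness_", st)]][i],
          f_yield = tb[[paste0("yield_", st)]][i],
          f_ult = tb[[paste0("ultimate_", st)]][i],
          toe_end = cp$toe_end, toe_shape = cp$toe_shape,
          hardening_fraction = cp$hardening_fraction,
          drop_fraction_post = cp$drop_fraction_post,
          noise_sd = cp$noise_sd, sample_spacing = cp$sample_spacing)
        sim <- simulate_curve(pars,
                              seed = sub_seed + (st == "instr"),
                              specimen_id = tb$specimen_id[i], state = state)
        # a curve the extractor cannot process at all (e.g. failure before
        # toe + kernel of travel) is a manual-review case, not an abort
        out <- tryCatch(
          extract_outcomes(sim$curve, config = pipeline),
          error = function(e) mech_outcomes(
            ultimate_load = max(sim$curve$load),
            ultimate_displacement =
              sim$curve$displacement[which.max(sim$curve$load)],
            flags = c("nonlinear_curve", "manual_review")))
        tb[[paste0("stiffness_", st)]][i] <- out$stiffness
        tb[[paste0("yield_", st)]][i] <- out$yield_load
        tb[[paste0("ultimate_", st)]][i] <- out$ultimate_load
        tb[[paste0("flags_", st)]][i] <- paste(out$flags, collapse = ";")
        if (!is.null(emit_curves))
          write_curve(sim$curve, file.path(
            emit_curves, sprintf("%s_%s.csv", tb$specimen_id[i], state)))
      }
    }
  }
  coh <- cohort_table(tb, provenance = "synthetic", seed = seed)
  attr(coh, "ground_truth") <- truth
  coh
}
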