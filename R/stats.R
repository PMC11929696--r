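#' Simple linear regression between two variables
#'
#' Ordinary least squares of `y` on `x` over complete pairs, with the
#' squared Pearson correlation and the two-sided p-value of the slope.
#'
#' @param x,y Numeric vectors of equal length; pairs with any `NA` are
#'   dropped. At least 3 complete pairs and non-zero variance in `x` are
#'   required.
#' @param x_name,y_name Labels carried into the result.
#' @return A list of class `"regression_result"`: `x_name`, `y_name`,
#'   `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
#' @examples
#' linear_regression(1:10, 2 * (1:10) + 1)
linear_regression <- function(x, y, x_name = deparse(substitute(x)),
                              y_name = deparse(substitute(y))) {
  force(x_name); force(y_name)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs, got ", length(x))
  if (var(x) == 0) stop("zero variance in x (", x_name, ")")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(list(x_name = x_name, y_name = y_name,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 slope_se = sm$coefficients[2, 2],
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s ~ %s: slope %.4g, R^2 = %.3f, p = %.4g (n = %d)\n",
              x$y_name, x$x_name, x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples. The p-value is
#' exact (full enumeration of the U distribution) when the combined sample
#' size is at most `exact_max_n` and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param sample_a,sample_b Numeric vectors; `NA` dropped; both non-empty.
#' @param exact_max_n Combined-n switch point for the exact test (default
#'   16).
#' @return A list: `U` (statistic for `sample_a`), `p_value`, `method`
#'   (`"exact"`/`"normal_approx"`), `n` (per sample).
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
mann_whitney <- function(sample_a, sample_b, exact_max_n = 16) {
  a <- sample_a[!is.na(sample_a)]
  b <- sample_b[!is.na(sample_b)]
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= exact_max_n) && !ties
  ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact) "exact" else "normal_approx",
       n = c(length(a), length(b)))
}

#' Homogeneity of regression slopes
#'
#' Pre-check for ANCOVA: fits the full model with group-by-covariate
#' interactions and tests each interaction with a partial F-test. The
#' slopes are considered homogeneous if no interaction is significant at
#' `alpha`.
#'
#' @param data A data frame.
#' @param outcome,group Column names (strings) of the outcome and the
#'   grouping factor.
#' @param covariates Character vector of covariate column names (numeric or
#'   factor).
#' @param alpha Significance level for the homogeneity decision (default
#'   0.05).
#' @return A list: `tests` (tibble with one row per interaction: term, df1,
#'   df2, F, p_value) and `homogeneous` (logical).
#' @export
check_slope_homogeneity <- function(data, outcome, group, covariates,
                                    alpha = 0.05) {
  d <- stats_frame(data, outcome, group, covariates)
  rhs <- paste0(".group * (", paste(covariates, collapse = " + "), ")")
  fit <- lm(as.formula(paste(".outcome ~", rhs)), data = d)
  check_full_rank(fit)
  n_par <- length(coef(fit))
  if (nrow(d) < n_par + 2)
    stop("too few complete cases (", nrow(d), ") for ", n_par,
         " parameters + 2")
  dr <- drop1(fit, test = "F")
  terms_int <- rownames(dr)[grepl(":", rownames(dr))]
  tests <- tibble::tibble(
    term = sub("^\\.group:", paste0(group, ":"), terms_int),
    df1 = dr[terms_int, "Df"],
    df2 = df.residual(fit),
    F = dr[terms_int, "F value"],
    p_value = dr[terms_int, "Pr(>F)"])
  list(tests = tests, homogeneous = all(tests$p_value >= alpha))
}

#' One-way ANCOVA with covariate-adjusted means
#'
#' Fits `outcome ~ group + covariates` by least squares on listwise-complete
#' cases. The group effect is the partial (type-III) F-test comparing the
#' full model against the model without the group term. Adjusted means are
#' the model predictions per group with every covariate held at the grand
#' mean of the included cases (factor covariates at their observed
#' proportions), with standard errors from the coefficient covariance.
#'
#' @inheritParams check_slope_homogeneity
#' @param covariates Character vector of covariate column names; may be
#'   empty, in which case the test reduces exactly to one-way ANOVA.
#' @param check_slopes If `TRUE` (default), run
#'   [check_slope_homogeneity()] first and warn (not block) on violation.
#' @param alpha Level used by the slope pre-check.
#' @return A list of class `"ancova_result"`: `outcome_name`,
#'   `adjusted_means` (tibble: group, n, adjusted_mean, se), `F_stat`, `df`
#'   (numerator, denominator), `p_value`, `n_used`, `slopes` (pre-check
#'   result or `NULL`), `model` (the fitted `lm`).
#' @export
ancova <- function(data, outcome, group, covariates = character(),
                   check_slopes = TRUE, alpha = 0.05) {
  d <- stats_frame(data, outcome, group, covariates)
  slopes <- NULL
  if (check_slopes && length(covariates)) {
    slopes <- check_slope_homogeneity(data, outcome, group, covariates,
                                      alpha = alpha)
    if (!slopes$homogeneous)
      warning("regression slopes not homogeneous across groups (",
              outcome, "); ANCOVA adjusted means may be misleading")
  }
  rhs <- if (length(covariates))
    paste(c(".group", covariates), collapse = " + ") else ".group"
  full <- lm(as.formula(paste(".outcome ~", rhs)), data = d)
  check_full_rank(full)
  if (df.residual(full) < 1) stop("too few cases: no residual df")
  reduced <- lm(as.formula(
    if (length(covariates))
      paste(".outcome ~", paste(covariates, collapse = " + "))
    else ".outcome ~ 1"), data = d)
  cmp <- anova(reduced, full)
  F_stat <- cmp$F[2]
  df <- c(cmp$Df[2], cmp$Res.Df[2])
  p_value <- cmp$`Pr(>F)`[2]

  # adjusted means: design-matrix column means with the group dummies
  # switched to each level in turn
  X <- model.matrix(full)
  xbar <- colMeans(X)
  asgn <- attr(X, "assign")
  term_labels <- attr(terms(full), "term.labels")
  grp_cols <- which(asgn == match(".group", term_labels))
  lv <- levels(d$.group)
  V <- vcov(full)
  beta <- coef(full)
  adj <- lapply(seq_along(lv), function(k) {
    xg <- xbar
    ref <- stats::contrasts(d$.group)[k, ]   # dummy codes for level k
    xg[grp_cols] <- ref
    c(mean = sum(xg * beta), se = sqrt(drop(t(xg) %*% V %*% xg)))
  })
  n_used <- table(d$.group)
  adjusted_means <- tibble::tibble(
    group = lv,
    n = as.integer(n_used[lv]),
    adjusted_mean = vapply(adj, `[[`, 0, "mean"),
    se = vapply(adj, `[[`, 0, "se"))

  structure(list(outcome_name = outcome, adjusted_means = adjusted_means,
                 F_stat = F_stat, df = df, p_value = p_value,
                 n_used = n_used, slopes = slopes, model = full),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA on %s: F(%d,%d) = %.3f, p = %.3f\n",
              x$outcome_name, x$df[1], x$df[2], x$F_stat, x$p_value))
  print(x$adjusted_means)
  if (!is.null(x$slopes))
    cat("slopes homogeneous:", x$slopes$homogeneous, "\n")
  invisible(x)
}

# listwise-complete analysis frame with canonical .outcome / .group columns
stats_frame <- function(data, outcome, group, covariates) {
  cols <- c(outcome, group, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("columns not in data: ", paste(missing_cols, collapse = ", "))
  d <- as.data.frame(data)[, cols, drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  for (cv in covariates) {
    if (is.character(d[[cv]])) d[[cv]] <- factor(d[[cv]])
    if (is.factor(d[[cv]])) {
      d[[cv]] <- droplevels(d[[cv]])
      if (nlevels(d[[cv]]) < 2)
        stop("rank-deficient design; covariate '", cv,
             "' has a single level among complete cases")
    }
  }
  d$.outcome <- d[[outcome]]
  d$.group <- droplevels(factor(d[[group]]))
  if (nlevels(d$.group) < 2)
    stop("need at least 2 groups with complete cases, got ",
         nlevels(d$.group))
  d
}

check_full_rank <- function(fit) {
  aliased <- is.na(coef(fit))
  if (any(aliased))
    stop("rank-deficient design; collinear columns: ",
         paste(names(coef(fit))[aliased], collapse = ", "))
  invisible(fit)
}

#' Run the full fixation-stability analysis plan
#'
#' Executes the study's statistical plan on a cohort with paired outcomes:
#' donor-age comparison between fixation groups (Mann-Whitney U); the three
#' restoration percentages with unadjusted group means; a
#' homogeneity-of-slopes check and a one-way ANCOVA per restored percentage,
#' adjusted for the matching intact-state value, sex, age (optional), vBMD
#' and Ct.Ar/Tt.Ar; a linear-regression grid relating age, vBMD and
#' Ct.Ar/Tt.Ar to stiffness, yield and ultimate load in both states;
#' yield-versus-ultimate regressions; and, when a `failure_mode` column is
#' present, a Mann-Whitney comparison of intact and instrumented ultimate
#' load between implant-breakage and other failures within the allograft
#' group. Alpha is applied per test without multiplicity correction unless
#' `p_adjust` is set.
#'
#' @param cohort A [cohort_table()].
#' @param include_age Include donor age among the ANCOVA covariates
#'   (default `TRUE`).
#' @param alpha Significance level (default 0.05).
#' @param p_adjust Optional method passed to [stats::p.adjust()] (e.g.
#'   `"holm"`) applied to the three ANCOVA p-values; `"none"` (default)
#'   mirrors per-test alpha.
#' @return A list of class `"study_report"`.
#' @export
run_study_analysis <- function(cohort, include_age = TRUE, alpha = 0.05,
                               p_adjust = "none") {
  stopifnot(inherits(cohort, "cohort_table"))
  tb <- tibble::as_tibble(cohort)

  characteristics <- dplyr::summarise(
    dplyr::group_by(tb, .data$fixation_group),
    n = dplyr::n(),
    n_female = sum(.data$sex == "f"),
    age_mean = mean(.data$age), age_sd = sd(.data$age),
    vbmd_n = sum(!is.na(.data$vbmd)),
    vbmd_mean = mean(.data$vbmd, na.rm = TRUE),
    vbmd_sd = sd(.data$vbmd, na.rm = TRUE),
    ct_tt_n = sum(!is.na(.data$ct_tt_ratio)),
    ct_tt_mean = mean(.data$ct_tt_ratio, na.rm = TRUE),
    ct_tt_sd = sd(.data$ct_tt_ratio, na.rm = TRUE),
    .groups = "drop")

  grp_split <- split(tb, tb$fixation_group)
  age_test <- mann_whitney(grp_split[[1]]$age, grp_split[[2]]$age)

  long <- tidyr::pivot_longer(
    tb, dplyr::all_of(cohort_outcome_cols),
    names_to = c("outcome", "state"), names_sep = "_", values_to = "value")
  outcome_summary <- dplyr::summarise(
    dplyr::group_by(long, .data$fixation_group, .data$outcome, .data$state),
    n = sum(!is.na(.data$value)),
    mean = mean(.data$value, na.rm = TRUE),
    sd = sd(.data$value, na.rm = TRUE),
    min = suppressWarnings(min(.data$value, na.rm = TRUE)),
    max = suppressWarnings(max(.data$value, na.rm = TRUE)),
    .groups = "drop")

  restoration <- pair_and_restore(cohort)
  adat <- dplyr::left_join(
    restoration$per_specimen,
    tb[, c("specimen_id", "sex", "age", "vbmd", "ct_tt_ratio",
           "stiffness_intact", "yield_intact", "ultimate_intact")],
    by = "specimen_id")

  base_covs <- c("sex", if (include_age) "age", "vbmd", "ct_tt_ratio")
  # a covariate recorded for no specimen cannot adjust anything: drop it
  # rather than letting listwise deletion empty the analysis
  all_missing <- base_covs[vapply(base_covs,
                                  function(cv) all(is.na(adat[[cv]])), TRUE)]
  if (length(all_missing)) {
    message("dropping covariate(s) with no observed values: ",
            paste(all_missing, collapse = ", "))
    base_covs <- setdiff(base_covs, all_missing)
  }
  spec <- list(stiffness = c("stiffness_intact", base_covs),
               yield = c("yield_intact", base_covs),
               ultimate = c("ultimate_intact", base_covs))
  ancovas <- lapply(names(spec), function(oc) {
    ancova(adat, outcome = paste0("pct_", oc), group = "fixation_group",
           covariates = spec[[oc]], alpha = alpha)
  })
  names(ancovas) <- names(spec)
  p_anc <- stats::p.adjust(vapply(ancovas, `[[`, 0, "p_value"),
                           method = p_adjust)

  grid <- tidyr::expand_grid(
    predictor = c("age", "vbmd", "ct_tt_ratio"),
    response = cohort_outcome_cols)
  regressions <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    fit <- tryCatch(
      linear_regression(tb[[grid$predictor[i]]], tb[[grid$response[i]]],
                        x_name = grid$predictor[i],
                        y_name = grid$response[i]),
      error = function(e) list(x_name = grid$predictor[i],
                               y_name = grid$response[i], slope = NA_real_,
                               r_squared = NA_real_, p_value = NA_real_,
                               n = 0L))
    tibble::tibble(predictor = fit$x_name, response = fit$y_name,
                   slope = fit$slope, r_squared = fit$r_squared,
                   p_value = fit$p_value, n = fit$n)
  }))

  yv <- list(
    intact_pooled = linear_regression(tb$yield_intact, tb$ultimate_intact,
                                      "yield_intact", "ultimate_intact"))
  for (g in names(grp_split)) {
    gi <- grp_split[[g]]
    yv[[paste0("intact_", g)]] <- linear_regression(
      gi$yield_intact, gi$ultimate_intact, "yield_intact", "ultimate_intact")
    yv[[paste0("instr_", g)]] <- linear_regression(
      gi$yield_instr, gi$ultimate_instr, "yield_instr", "ultimate_instr")
  }

  failure_subgroup <- NULL
  allo <- tb[tb$fixation_group == "allograft" & !is.na(tb$failure_mode), ]
  if (nrow(allo) && any(allo$failure_mode == "implant_breakage") &&
      any(allo$failure_mode != "implant_breakage")) {
    brk <- allo$failure_mode == "implant_breakage"
    failure_subgroup <- list(
      n = c(breakage = sum(brk), other = sum(!brk)),
      ultimate_intact = mann_whitney(allo$ultimate_intact[brk],
                                     allo$ultimate_intact[!brk]),
      ultimate_instr = mann_whitney(allo$ultimate_instr[brk],
                                    allo$ultimate_instr[!brk]),
      means_intact = c(breakage = mean(allo$ultimate_intact[brk], na.rm = TRUE),
                       other = mean(allo$ultimate_intact[!brk], na.rm = TRUE)),
      means_instr = c(breakage = mean(allo$ultimate_instr[brk], na.rm = TRUE),
                      other = mean(allo$ultimate_instr[!brk], na.rm = TRUE)))
  }

  structure(list(characteristics = characteristics, age_test = age_test,
                 outcome_summary = outcome_summary,
                 restoration = restoration, ancovas = ancovas,
                 ancova_p_adjusted = p_anc, regressions = regressions,
                 yield_vs_ultimate = yv, failure_subgroup = failure_subgroup,
                 alpha = alpha),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("== Fixation stability study report ==\n\n")
  cat("Cohort characteristics:\n"); print(x$characteristics)
  cat(sprintf("\nDonor age between groups: Mann-Whitney U = %.1f, p = %.4f\n",
              x$age_test$U, x$age_test$p_value))
  cat("\nUnadjusted restoration (mean % +- SD):\n")
  print(x$restoration$group_summary)
  cat("\nANCOVA (covariate-adjusted group comparison):\n")
  for (nm in names(x$ancovas)) {
    a <- x$ancovas[[nm]]
    cat(sprintf("  %% %s restored: F(%d,%d) = %.3f, p = %.3f\n",
                nm, a$df[1], a$df[2], a$F_stat, x$ancova_p_adjusted[nm]))
    m <- a$adjusted_means
    for (i in seq_len(nrow(m)))
      cat(sprintf("    %-12s adj. mean %.2f +- %.2f (n = %d)\n",
                  m$group[i], m$adjusted_mean[i], m$se[i], m$n[i]))
  }
  cat("\nStrongest bone-quality regressions (top 3 by R^2):\n")
  top <- dplyr::slice_max(x$regressions, .data$r_squared, n = 3)
  print(top)
  if (!is.null(x$failure_subgroup)) {
    fs <- x$failure_subgroup
    cat(sprintf(
      "\nAllograft failure subgroup (breakage n=%d vs other n=%d):\n",
      fs$n["breakage"], fs$n["other"]))
    cat(sprintf("  F_UL intact %.1f vs %.1f N, p = %.3f\n",
                fs$means_intact["breakage"], fs$means_intact["other"],
                fs$ultimate_intact$p_value))
    cat(sprintf("  F_UL instr  %.1f vs %.1f N, p = %.3f\n",
                fs$means_instr["breakage"], fs$means_instr["other"],
                fs$ultimate_instr$p_value))
  }
  invisible(x)
}
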