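test_that("an exactly linear curve gives its slope, r = 1, earliest window", {
  d <- seq(0, 5, by = 0.01)
  cv <- ld_curve(d, 100 * d)
  st <- compute_stiffness(cv)
  expect_equal(st$stiffness, 100, tolerance = 1e-9)
  expect_equal(st$best_fit$pearson_r, 1, tolerance = 1e-12)
  # ties broken toward the earliest admissible window (start at toe end)
  expect_equal(st$best_fit$window_start, 1, tolerance = 1e-9)
  expect_equal(st$best_fit$window_end, 2, tolerance = 1e-9)
})

test_that("chosen kernel equals the exhaustive arg-max-r window on random curves", {
  params <- random_curve_params(25, seed = 42, noise_sd = 4,
                                sample_spacing = 0.03)
  for (k in seq_along(params)) {
    sim <- simulate_curve(params[[k]], seed = 100 + k)
    st <- compute_stiffness(sim$curve)
    orc <- oracle_best_window(sim$curve$displacement, sim$curve$load)
    expect_identical(st$best_fit$i_start, orc$i_start)
    expect_identical(st$best_fit$i_end, orc$i_end)
    expect_equal(st$stiffness, orc$slope, tolerance = 1e-9)
    expect_equal(st$best_fit$pearson_r, orc$r, tolerance = 1e-12)
  }
})

test_that("noise-free simulated curve recovers the true stiffness within 1%", {
  sim <- simulate_curve(curve_params(181, 755, 825, sample_spacing = 0.01))
  st <- compute_stiffness(sim$curve)
  expect_lt(abs(st$stiffness - 181) / 181, 0.01)
})

test_that("stiffness under load noise stays accurate (50 seeds, median rel err <= 5%)", {
  pars <- curve_params(181, 755, 825, noise_sd = 5, sample_spacing = 0.02)
  errs <- vapply(1:50, function(s) {
    sim <- simulate_curve(pars, seed = s)
    abs(compute_stiffness(sim$curve)$stiffness - 181) / 181
  }, 0)
  expect_lte(median(errs), 0.05)
})

test_that("ultimate load is the curve maximum; missing drop is flagged", {
  cv <- ld_curve(0:3, c(0, 50, 120, 80))
  ul <- compute_ultimate_load(cv)
  expect_equal(ul$f_ul, 120)
  expect_equal(ul$i_ul, 3L)
  expect_length(ul$flags, 0)

  inc <- ld_curve(seq(0, 5, by = 0.1), seq(0, 500, by = 10))
  ul2 <- compute_ultimate_load(inc)
  expect_equal(ul2$f_ul, 500)
  expect_identical(ul2$flags, "no_load_drop")

  sim <- simulate_curve(curve_params(181, 755, 825, sample_spacing = 0.01))
  ul3 <- compute_ultimate_load(sim$curve)
  # within one sample's load increment of the true peak
  expect_lt(825 - ul3$f_ul, 0.04 * 181 * 0.01 + 1e-9)
  expect_length(ul3$flags, 0)
})

test_that("yield detection matches the expanding-window oracle on the bilinear fixture", {
  cv <- make_bilinear(kink = 4, s1 = 100, s2 = 5, d_end = 12, spacing = 0.01)
  st <- compute_stiffness(cv)
  expect_equal(st$best_fit$window_start, 1, tolerance = 1e-9)
  yl <- compute_yield_load(cv, st$best_fit)
  orc <- oracle_expand_yield(cv$displacement, cv$load,
                             st$best_fit$i_start, st$best_fit$i_end)
  expect_equal(yl$d_yl, orc$d_yl)
  expect_equal(yl$f_yl, orc$f_yl)
  # frozen oracle values for this fixture
  expect_equal(yl$d_yl, 9.08, tolerance = 1e-8)
  expect_equal(yl$f_yl, 425.4, tolerance = 1e-8)
})

test_that("an exactly linear curve has no detectable yield", {
  d <- seq(0, 6, by = 0.01)
  cv <- ld_curve(d, 200 * d)
  st <- compute_stiffness(cv)
  yl <- compute_yield_load(cv, st$best_fit)
  expect_true(is.na(yl$f_yl))
  expect_identical(yl$flags, "yield_not_found")
  expect_error(compute_yield_load(cv, NULL), "best_fit")
})

test_that("yield never exceeds ultimate on simulated cohort curves", {
  params <- random_curve_params(20, seed = 9, sample_spacing = 0.03)
  for (p in params) {
    o <- extract_outcomes(simulate_curve(p)$curve)
    expect_false(is.na(o$yield_load))
    expect_lte(o$yield_load, o$ultimate_load)
  }
})

test_that("extract_outcomes on a clean simulated curve yields all three, no flags", {
  sim <- simulate_curve(curve_params(250, 900, 1000, sample_spacing = 0.01))
  o <- extract_outcomes(sim$curve)
  expect_false(anyNA(c(o$stiffness, o$yield_load, o$ultimate_load)))
  expect_length(o$flags, 0)
  expect_lt(abs(o$stiffness - 250) / 250, 0.01)
  # yield lands inside the declared softening band
  expect_gte(o$yield_load, sim$truth$softening_band_f[1])
  expect_lte(o$yield_load, sim$truth$softening_band_f[2])
  expect_gte(o$yield_displacement, sim$truth$softening_band_d[1])
  expect_lte(o$yield_displacement, sim$truth$softening_band_d[2])
  # audit trail accompanies the outcomes
  audit <- attr(o, "audit")
  expect_s3_class(audit$best_fit, "kernel_fit")
  expect_gt(nrow(audit$r_trace), 0)
})

test_that("a strongly saturating monotone curve is flagged nonlinear", {
  d <- seq(0, 6, by = 0.01)
  cv <- ld_curve(d, 1000 * (1 - exp(-1.2 * d)))
  o <- extract_outcomes(cv)
  expect_true("nonlinear_curve" %in% o$flags)
  expect_true("manual_review" %in% o$flags)
})

test_that("stiffness window respects the configured kernel width", {
  sim <- simulate_curve(curve_params(181, 755, 825, sample_spacing = 0.01))
  for (k in c(0.5, 1, 2)) {
    st <- compute_stiffness(sim$curve, kernel_mm = k)
    width <- st$best_fit$window_end - st$best_fit$window_start
    expect_lte(abs(width - k), 0.01 + 1e-9)   # within one sample spacing
  }
})

test_that("a curve truncated before toe + kernel errors", {
  d <- seq(0, 1.5, by = 0.01)
  cv <- ld_curve(d, 100 * d)
  expect_error(compute_stiffness(cv), "too short")
})

test_that("all-degenerate windows give absent stiffness with nonlinear flag", {
  d <- seq(0, 4, by = 0.01)
  f <- c(rep(0, length(d) - 1), 1)  # flat until a final step
  cv <- ld_curve(d, f)
  st <- compute_stiffness(cv, search_end_mm = 3)
  expect_true(is.na(st$stiffness))
  expect_identical(st$flags, "nonlinear_curve")
})

test_that("appending post-ultimate samples changes neither stiffness nor yield", {
  sim <- simulate_curve(curve_params(181, 755, 825, noise_sd = 3,
                                     sample_spacing = 0.02), seed = 4)
  cv <- sim$curve
  o1 <- extract_outcomes(cv)
  d_ext <- c(cv$displacement, max(cv$displacement) + seq(0.02, 1, by = 0.02))
  f_ext <- c(cv$load, rep(0.1 * max(cv$load), 50))
  o2 <- extract_outcomes(ld_curve(d_ext, f_ext))
  expect_equal(o2$stiffness, o1$stiffness)
  expect_equal(o2$yield_load, o1$yield_load)
  expect_equal(o2$ultimate_load, o1$ultimate_load)
})

test_that("scaling loads by c scales outcomes by c, leaving windows and flags fixed", {
  sim <- simulate_curve(curve_params(220, 640, 700, noise_sd = 4,
                                     sample_spacing = 0.02), seed = 6)
  cv <- sim$curve
  o1 <- extract_outcomes(cv)
  for (c_scale in c(0.25, 3)) {
    cv2 <- ld_curve(cv$displacement, cv$load * c_scale,
                    specimen_id = cv$specimen_id)
    o2 <- extract_outcomes(cv2)
    expect_equal(o2$stiffness, c_scale * o1$stiffness, tolerance = 1e-9)
    expect_equal(o2$yield_load, c_scale * o1$yield_load, tolerance = 1e-9)
    expect_equal(o2$ultimate_load, c_scale * o1$ultimate_load,
                 tolerance = 1e-12)
    expect_identical(o2$stiffness_window, o1$stiffness_window)
    expect_identical(o2$flags, o1$flags)
  }
})

test_that("sliding-window yield policy is available and capped like the default", {
  cv <- make_bilinear(kink = 4, s1 = 100, s2 = 0.5, d_end = 12,
                      spacing = 0.02)
  st <- compute_stiffness(cv)
  yl <- compute_yield_load(cv, st$best_fit, policy = "slide")
  # the sliding kernel sees the kink locally, so detection is near the kink
  expect_false(is.na(yl$f_yl))
  expect_gt(yl$d_yl, 4)
  expect_lt(yl$d_yl, 6)
})

test_that("mech_outcomes enforces its invariants", {
  expect_error(mech_outcomes(stiffness = -1), "positive")
  expect_error(mech_outcomes(yield_load = 500, ultimate_load = 400),
               "exceed")
  expect_error(mech_outcomes(flags = "bogus"), "unknown flag")
})
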