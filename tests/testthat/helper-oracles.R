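# Independent oracles: deliberately plain-loop implementations built on
# stats::cor / lm / combn, kept separate from the package's vectorised code
# paths.

# Exhaustive moving-kernel search: for every admissible start index, fit the
# window with stats::cor and return the arg-max-r window (first index on
# exact ties).
oracle_best_window <- function(d, f, toe_mm = 1, kernel_mm = 1,
                               i_cap = which.max(f)) {
  tol <- 1e-9
  best_r <- -Inf; best <- NULL
  d_cap <- d[i_cap]
  for (i in seq_along(d)) {
    if (d[i] < toe_mm - tol || d[i] > d_cap - kernel_mm + tol) next
    j <- max(which(d <= d[i] + kernel_mm + tol))
    if (j > i_cap || j - i + 1 < 3) next
    r <- suppressWarnings(stats::cor(d[i:j], f[i:j]))
    # same exact-tie convention as the package: collinear windows are r = 1
    if (is.finite(r) && r > 1 - 1e-10) r <- 1
    if (is.finite(r) && r > best_r) {
      best_r <- r
      best <- list(i_start = i, i_end = j, r = r,
                   slope = unname(stats::coef(stats::lm(f[i:j] ~ d[i:j]))[2]))
    }
  }
  best
}

# Expanding-window yield search, recomputing r with stats::cor at every
# right-edge sample.
oracle_expand_yield <- function(d, f, i_start, i_end0,
                                i_cap = which.max(f), r_threshold = 0.85) {
  if (i_end0 + 1 > i_cap) return(NULL)
  for (j in seq.int(i_end0 + 1, i_cap)) {
    r <- suppressWarnings(stats::cor(d[i_start:j], f[i_start:j]))
    if (is.finite(r) && r < r_threshold)
      return(list(j = j, d_yl = d[j], f_yl = f[j], r = r))
  }
  NULL
}

# ANCOVA by explicit normal equations on a hand-built design matrix.
oracle_ancova <- function(y, g, covs) {
  g <- factor(g)
  X_full <- cbind(1, as.integer(g == levels(g)[2]),
                  as.matrix(as.data.frame(covs)))
  X_red <- X_full[, -2, drop = FALSE]
  solve_ols <- function(X, y) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    res <- y - X %*% beta
    list(beta = drop(beta), rss = sum(res^2), df = length(y) - ncol(X))
  }
  full <- solve_ols(X_full, y)
  red <- solve_ols(X_red, y)
  F_stat <- (red$rss - full$rss) / (full$rss / full$df)
  sigma2 <- full$rss / full$df
  V <- sigma2 * solve(t(X_full) %*% X_full)
  xbar <- colMeans(X_full)
  adj <- vapply(0:1, function(lvl) {
    xg <- xbar; xg[2] <- lvl
    c(mean = sum(xg * full$beta), se = sqrt(drop(t(xg) %*% V %*% xg)))
  }, c(mean = 0, se = 0))
  list(beta = full$beta, F_stat = F_stat,
       df = c(1, full$df),
       p_value = stats::pf(F_stat, 1, full$df, lower.tail = FALSE),
       adjusted_means = adj["mean", ], adjusted_se = adj["se", ])
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments;
# two-sided p doubles the smaller tail (capped at 1).
oracle_mw_exact <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n, n1)
  us <- apply(idx, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(U = u_obs, p_value = min(1, p))
}

# Piecewise-linear toy curve builder used across feature tests.
make_bilinear <- function(kink = 4, s1 = 100, s2 = 5, d_end = 12,
                          spacing = 0.01) {
  d <- seq(0, d_end, by = spacing)
  f <- ifelse(d < kink, s1 * d, s1 * kink + s2 * (d - kink))
  ld_curve(d, f, specimen_id = "bilinear")
}
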