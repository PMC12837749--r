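#' Convert event timestamps to radian time-of-day
#'
#' Clock time is mapped to the circle: seconds since midnight divided by
#' 86400, times 2*pi, giving values in `[0, 2*pi)` (midnight = 0, noon = pi).
#'
#' @param x `POSIXct` timestamps, or an events data frame with an
#'   `event_start` column.
#' @return Numeric vector of radians in `[0, 2*pi)`.
#' @export
to_radians <- function(x) {
  if (is.data.frame(x)) x <- x$event_start
  lt <- as.POSIXlt(x, tz = "UTC")
  sec <- lt$hour * 3600 + lt$min * 60 + lt$sec
  (sec / 86400) * 2 * pi
}

# von Mises density; expon.scaled keeps large kappa finite
dvonmises <- function(theta, mu, kappa) {
  exp(kappa * (cos(theta - mu) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

# Best & Fisher (1979) rejection sampler
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1
    }
  }
  out %% (2 * pi)
}

# ML estimate of von Mises concentration from the mean resultant length
# (Best & Fisher approximation, as used for circular bandwidth selection).
a1inv <- function(R) {
  if (R >= 0 && R < 0.53) {
    2 * R + R^3 + 5 * R^5 / 6
  } else if (R < 0.85) {
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  } else {
    1 / (R^3 - 4 * R^2 + 3 * R)
  }
}

#' Plug-in bandwidth (kernel concentration) for circular density estimation
#'
#' Taylor's plug-in rule for von Mises kernels: fit a von Mises concentration
#' `kappa.hat` by maximum likelihood, then
#' `kappa = [3 n kappa.hat^2 I_2(2 kappa.hat) / (4 sqrt(pi) I_1(kappa.hat)^2)]^(2/5)`.
#' Larger `adjust` means a more concentrated kernel, i.e. a wigglier curve.
#'
#' @param theta Radian sample.
#' @param kmax Upper cap on the fitted concentration (guards against
#'   degenerate, near-point samples).
#' @return Scalar kernel concentration.
#' @export
bandwidth_kappa <- function(theta, kmax = 3) {
  n <- length(theta)
  if (n < 2) stop("need at least 2 observations for a bandwidth")
  C <- sum(cos(theta)); S <- sum(sin(theta))
  R <- sqrt(C^2 + S^2) / n
  k_hat <- min(a1inv(R), kmax)
  if (k_hat < 1e-8) k_hat <- 1e-8
  num <- 3 * n * k_hat^2 * besselI(2 * k_hat, 2, expon.scaled = TRUE) *
    exp(2 * k_hat)
  den <- 4 * sqrt(pi) * (besselI(k_hat, 1, expon.scaled = TRUE) *
                           exp(k_hat))^2
  (num / den)^(2 / 5)
}

#' Circular kernel density estimate of a diel activity pattern
#'
#' Places a von Mises kernel on each radian observation; the kernel
#' concentration comes from [bandwidth_kappa()] scaled by `adjust`
#' (concentration divided by `adjust`, so `adjust > 1` smooths). The result
#' integrates to 1 over the circle.
#'
#' @param theta Radian sample, length >= 2.
#' @param adjust Smoothing multiplier (0.8 pairs with the small-sample
#'   overlap estimator, 1.0 with the large-sample one).
#' @param n_grid Number of evaluation points on `[0, 2*pi)`.
#' @return List of class `circular_kde`: `grid`, `density`, `kappa`, `n`.
#' @export
circular_kde <- function(theta, adjust = 1, n_grid = 512) {
  if (length(theta) < 2) stop("need at least 2 observations")
  stopifnot(adjust > 0)
  kappa <- bandwidth_kappa(theta) / adjust
  grid <- seq(0, 2 * pi, length.out = n_grid + 1)[1:n_grid]
  dens <- kde_eval(grid, theta, kappa)
  structure(list(grid = grid, density = dens, kappa = kappa,
                 n = length(theta), adjust = adjust),
            class = "circular_kde")
}

kde_eval <- function(x, theta, kappa) {
  K <- exp(kappa * (cos(outer(x, theta, "-")) - 1))
  rowMeans(K) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' @export
print.circular_kde <- function(x, ...) {
  cat(sprintf("circular_kde: n = %d, kernel kappa = %.3f, %d grid points\n",
              x$n, x$kappa, length(x$grid)))
  invisible(x)
}

#' Diel activity overlap coefficient for a species pair
#'
#' The overlap coefficient Delta is the area under the pointwise minimum of
#' the two activity densities. Two estimators are used, following the
#' standard small/large-sample convention: `Dhat1` integrates
#' `min(f1, f2)` of the two kernel density estimates on a fixed grid
#' (trapezoidal rule on the circle, `adjust = 0.8`); `Dhat4` averages
#' `min(f2/f1, 1)` and `min(f1/f2, 1)` over the respective samples
#' (`adjust = 1`). By default `Dhat1` is chosen when the smaller sample has
#' fewer than `switch_n` observations, `Dhat4` otherwise.
#'
#' @param theta1,theta2 Radian samples (each length >= 2).
#' @param estimator `"auto"` (default), `"Dhat1"` or `"Dhat4"`.
#' @param switch_n Sample-size threshold for the automatic choice.
#' @param n_grid Quadrature points for `Dhat1`.
#' @return List of class `overlap_estimate`: `delta`, `estimator`, `n1`,
#'   `n2`.
#' @export
overlap_delta <- function(theta1, theta2, estimator = c("auto", "Dhat1", "Dhat4"),
                          switch_n = 75, n_grid = 512) {
  estimator <- match.arg(estimator)
  n1 <- length(theta1); n2 <- length(theta2)
  if (n1 < 2 || n2 < 2) stop("need at least 2 observations per species")
  if (estimator == "auto") {
    estimator <- if (min(n1, n2) < switch_n) "Dhat1" else "Dhat4"
  }
  if (estimator == "Dhat1") {
    k1 <- bandwidth_kappa(theta1) / 0.8
    k2 <- bandwidth_kappa(theta2) / 0.8
    grid <- seq(0, 2 * pi, length.out = n_grid + 1)[1:n_grid]
    f1 <- kde_eval(grid, theta1, k1)
    f2 <- kde_eval(grid, theta2, k2)
    # periodic trapezoid = mean * period
    delta <- mean(pmin(f1, f2)) * 2 * pi
  } else {
    k1 <- bandwidth_kappa(theta1) / 1.0
    k2 <- bandwidth_kappa(theta2) / 1.0
    f1at1 <- kde_eval(theta1, theta1, k1)
    f2at1 <- kde_eval(theta1, theta2, k2)
    f1at2 <- kde_eval(theta2, theta1, k1)
    f2at2 <- kde_eval(theta2, theta2, k2)
    delta <- (mean(pmin(f2at1 / f1at1, 1)) + mean(pmin(f1at2 / f2at2, 1))) / 2
  }
  structure(list(delta = min(max(delta, 0), 1), estimator = estimator,
                 n1 = n1, n2 = n2),
            class = "overlap_estimate")
}

#' @export
print.overlap_estimate <- function(x, ...) {
  ci <- if (!is.null(x$ci_low)) sprintf(" (95%% CI %.2f-%.2f)", x$ci_low,
                                        x$ci_high) else ""
  cat(sprintf("Delta = %.2f [%s, n = %d/%d]%s\n", x$delta, x$estimator,
              x$n1, x$n2, ci))
  invisible(x)
}

#' Smoothed-bootstrap confidence interval for an activity overlap
#'
#' Resamples each species' radian times from its fitted von Mises kernel
#' density (resample data points with replacement, add von Mises kernel
#' noise), recomputes Delta each iteration, and returns the percentile
#' interval recentred on the point estimate (quantiles shifted by
#' `delta_hat - mean(bootstrap)`), clamped to `[0, 1]`. Deterministic for a
#' fixed seed.
#'
#' @inheritParams overlap_delta
#' @param n_boot Bootstrap iterations (default 1000).
#' @param seed Integer RNG seed.
#' @return An `overlap_estimate` with `ci_low`, `ci_high` and `n_boot` added.
#' @export
bootstrap_ci <- function(theta1, theta2, n_boot = 1000, seed = 1,
                         estimator = "auto", switch_n = 75, n_grid = 512) {
  if (n_boot < 1) stop("n_boot must be a positive integer")
  est <- overlap_delta(theta1, theta2, estimator, switch_n, n_grid)
  k1 <- bandwidth_kappa(theta1)
  k2 <- bandwidth_kappa(theta2)
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    t1 <- sample(theta1, replace = TRUE) + rvonmises(length(theta1), 0, k1)
    t2 <- sample(theta2, replace = TRUE) + rvonmises(length(theta2), 0, k2)
    overlap_delta(t1 %% (2 * pi), t2 %% (2 * pi), est$estimator,
                  switch_n, n_grid)$delta
  }, numeric(1))
  qs <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  shift <- est$delta - mean(boot)
  est$ci_low <- min(max(qs[1] + shift, 0), 1)
  est$ci_high <- min(max(qs[2] + shift, 0), 1)
  est$n_boot <- n_boot
  est
}

#' Permutation test for a difference in diel activity pattern
#'
#' Uses `1 - Delta` as the discrepancy statistic and permutes species labels
#' over the pooled radian sample; the p-value is the fraction of permuted
#' statistics at least as large as the observed one. This is a generic
#' label-permutation stand-in for a formal rhythm-comparison test and is
#' flagged as such in pipeline metadata.
#'
#' @inheritParams overlap_delta
#' @param n_perm Number of permutations.
#' @param seed Integer RNG seed.
#' @return List `p`, `observed` (1 - Delta), `n_perm`.
#' @export
rhythm_difference_test <- function(theta1, theta2, n_perm = 1000, seed = 1,
                                   estimator = "auto", switch_n = 75,
                                   n_grid = 512) {
  n1 <- length(theta1); n2 <- length(theta2)
  if (n1 < 5 || n2 < 5) stop("need at least 5 observations per species")
  if (n_perm < 1) stop("n_perm must be a positive integer")
  obs <- 1 - overlap_delta(theta1, theta2, estimator, switch_n, n_grid)$delta
  pooled <- c(theta1, theta2)
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(n1 + n2, n1)
    1 - overlap_delta(pooled[idx], pooled[-idx], estimator, switch_n,
                      n_grid)$delta
  }, numeric(1))
  list(p = mean(perm >= obs), observed = obs, n_perm = n_perm)
}

#' Pairwise activity overlap table
#'
#' Computes Delta with bootstrap CI (and optionally the permutation test)
#' between a focal species and every other species with enough events.
#'
#' @param events Events data frame from [filter_independent()].
#' @param focal Focal species name; `NULL` for all pairs.
#' @param min_n Minimum events per species to include (default 10).
#' @param n_boot,n_perm Replicates for the CI and permutation test
#'   (`n_perm = 0` skips the test).
#' @param seed Integer RNG seed.
#' @return Data frame `species_a`, `species_b`, `estimator`, `n1`, `n2`,
#'   `delta`, `ci_low`, `ci_high` and (if requested) `p_perm`.
#' @export
activity_overlap_table <- function(events, focal = NULL, min_n = 10,
                                   n_boot = 1000, n_perm = 0, seed = 1) {
  rad <- split(to_radians(events), events$species)
  rad <- rad[vapply(rad, length, 1L) >= min_n]
  sp <- names(rad)
  if (length(sp) < 2) stop("fewer than two species with >= min_n events")
  pairs <- utils::combn(length(sp), 2)
  keep <- if (is.null(focal)) seq_len(ncol(pairs)) else
    which(apply(pairs, 2, function(ik) focal %in% sp[ik]))
  if (!is.null(focal) && length(keep) == 0) {
    stop("focal species has fewer than min_n events or is absent: ", focal)
  }
  rows <- lapply(keep, function(j) {
    ik <- pairs[, j]
    est <- bootstrap_ci(rad[[ik[1]]], rad[[ik[2]]], n_boot = n_boot,
                        seed = seed + j)
    row <- data.frame(species_a = sp[ik[1]], species_b = sp[ik[2]],
                      estimator = est$estimator, n1 = est$n1, n2 = est$n2,
                      delta = est$delta, ci_low = est$ci_low,
                      ci_high = est$ci_high, stringsAsFactors = FALSE)
    if (n_perm > 0) {
      row$p_perm <- rhythm_difference_test(rad[[ik[1]]], rad[[ik[2]]],
                                           n_perm = n_perm, seed = seed + j)$p
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Density-curve table for plotting diel activity
#' @param theta Radian sample.
#' @param adjust Smoothing multiplier.
#' @param n_grid Grid size.
#' @return Data frame `time_h` (hours), `angle` (radians), `density`
#'   (per-radian).
#' @export
activity_curve <- function(theta, adjust = 1, n_grid = 512) {
  k <- circular_kde(theta, adjust = adjust, n_grid = n_grid)
  data.frame(time_h = k$grid / (2 * pi) * 24, angle = k$grid,
             density = k$density)
}
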