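test_that("window planner handles single-window and overlapping layouts", {
  p1 <- plan_windows(2000)
  expect_equal(nrow(p1), 1)
  expect_equal(c(p1$start, p1$end), c(1, 2000))

  p2 <- plan_windows(3500)
  expect_equal(p2$start, c(1, 1501))
  expect_equal(p2$end, c(2000, 3500))
  expect_equal(p2$from, c(1, 1751))
  expect_equal(p2$to, c(1750, 3499))
})

test_that("window planner invariants hold over random sizes", {
  set.seed(42)
  for (n in c(2, 1999, 2000, 2001, 3499, 3500, 3501,
              sample(2002:60000, 20))) {
    p <- plan_windows(n)
    expect_equal(p$start[1], 1)
    expect_equal(p$end[nrow(p)], n)
    expect_true(all(p$end - p$start + 1 <= 2000))
    if (nrow(p) > 1) {
      # every SNP covered, overlaps >= 500
      expect_true(all(p$start[-1] <= p$end[-nrow(p)] + 1))
      expect_true(all(p$end[-nrow(p)] - p$start[-1] + 1 >= 500))
      expect_equal(p$end[nrow(p)] - p$start[nrow(p)] + 1, 2000)
    }
    # contribution ranges partition 1:(n-1)
    expect_equal(p$from[1], 1)
    expect_equal(p$to[nrow(p)], n - 1)
    if (nrow(p) > 1)
      expect_equal(p$from[-1], p$to[-nrow(p)] + 1)
    # contributions lie inside their window
    expect_true(all(p$from >= p$start & p$to <= p$end - 1))
  }
})

test_that("stitching partitions intervals and preserves map length", {
  # two-window layout from the planner's own arithmetic
  n <- 3500
  plan <- plan_windows(n)
  positions <- seq(0, by = 100, length.out = n)
  set.seed(7)
  w1 <- runif(1999, 1, 2)
  w2 <- runif(1999, 3, 4)
  stitched <- stitch_windows(list(w1, w2), plan, positions)
  expect_length(stitched$rho, n - 1)
  # window 1 contributes intervals 1..1750, window 2 the rest
  expect_equal(stitched$rho[1:1750], w1[1:1750])
  expect_equal(stitched$rho[1751:3499], w2[(1751:3499) - 1500])
  # total genetic length equals the sum over contributed segments
  lens <- diff(positions)
  expect_equal(sum(stitched$rho * lens),
               sum(w1[1:1750] * lens[1:1750]) +
                 sum(w2[(1751:3499) - 1500] * lens[1751:3499]))

  # single window is the identity
  plan1 <- plan_windows(100)
  pos1 <- sort(sample.int(1e5, 100))
  v <- runif(99)
  expect_equal(stitch_windows(list(v), plan1, pos1)$rho, v)

  expect_error(stitch_windows(list(v), plan, positions), "windows of rates")
  expect_error(stitch_windows(list(w1, w2[-1]), plan, positions),
               "expected")
})

test_that("rho/r conversion is linear, invertible and validated", {
  expect_equal(rho_to_r(0, 1000), 0)
  r <- rho_to_r(c(1e-3, 2e-3), 25000)
  expect_equal(r[2], 2 * r[1])                  # linearity
  expect_equal(r_to_rho(r, 25000), c(1e-3, 2e-3))  # exact round trip
  expect_error(rho_to_r(1e-3, 0), "Ne")
  expect_error(rho_to_r(-1e-3, 100), "non-negative")
})

test_that("ratemap summary: constant map, skewness, bootstrap coverage", {
  meta <- data.frame(population = "p", Ne = 25000, F = 0.1, n = 10)
  cm <- const_map(L = 2e4, rho = 1e-3)
  s <- summarize_ratemap(list(cm), meta)
  expect_equal(s$mean_r, s$median_r)
  expect_equal(s$ci_lower, s$mean_r)
  expect_equal(s$ci_upper, s$mean_r)

  # rare large spikes push the mean above the median
  set.seed(3)
  pos <- seq(0, 2e5, by = 100)
  rho <- rep(1e-3, length(pos) - 1)
  rho[sample.int(length(rho), 20)] <- 0.1
  sk <- summarize_ratemap(list(rate_map("chr1", pos, rho, "p")), meta)
  expect_gt(sk$mean_r, sk$median_r)

  # bootstrap CI of the mean covers the true mean ~95% of the time on
  # iid maps (gamma rates, known mean)
  set.seed(11)
  true_mean_r <- rho_to_r(4e-3, 25000)
  hit <- vapply(1:200, function(i) {
    rho_i <- rgamma(200, shape = 4, rate = 1000)  # mean 4e-3
    m <- rate_map("chr1", seq(0, by = 100, length.out = 201), rho_i, "p")
    s_i <- summarize_ratemap(list(m), meta, n_boot = 400,
                             seed = sample.int(1e6, 1))
    s_i$ci_lower <= true_mean_r && true_mean_r <= s_i$ci_upper
  }, TRUE)
  expect_gte(mean(hit), 0.90)
  expect_lte(mean(hit), 0.99)
})

test_that("trace uncertainty: widths and ratio", {
  cm <- const_map(L = 1e4, spacing = 100, rho = 2e-3)
  k <- length(cm$rho)
  # constant trace -> zero-width credibility interval
  tu <- trace_uncertainty(matrix(2e-3, k, 50), cm)
  expect_equal(unname(tu$site_cri["width"]), 0)

  # N(est, sigma^2) trace -> CrI width ~ 3.92 sigma (5%, 1e4 samples)
  set.seed(5)
  sigma <- 1e-4
  tr <- matrix(pmax(0, rnorm(k * 1e4, mean = 2e-3, sd = sigma)), k)
  tu2 <- trace_uncertainty(tr, cm)
  expect_equal(unname(tu2$site_cri["width"]), 3.92 * sigma,
               tolerance = 0.05)

  # narrow traces + wide landscape -> ratio >> 1
  set.seed(6)
  pos <- seq(0, 1e5, by = 100)
  rho <- rlnorm(length(pos) - 1, log(2e-3), 1.5)
  wide <- rate_map("chr1", pos, rho, "p")
  tr3 <- rho * exp(matrix(rnorm(length(rho) * 100, 0, 0.01),
                          length(rho)))
  tu3 <- trace_uncertainty(tr3, wide)
  expect_gt(tu3$width_ratio, 10)

  expect_warning(trace_uncertainty(matrix(1e-3, k, 10), cm), "40")
})

test_that("rate comparison: exact Wilcoxon, ties, Bonferroni", {
  x <- list(a = c(1, 2, 3), b = c(4, 5, 6))
  cr <- compare_rates(x)
  expect_equal(cr$pairwise_p["a", "b"], 0.1)  # 20 assignments, exact
  expect_equal(cr$pairwise_p["a", "b"], wilcox_enum_p(x$a, x$b))

  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  expect_equal(suppressWarnings(compare_rates(same))$pairwise_p["a", "b"], 1)

  ten <- setNames(lapply(1:10, function(i) rnorm(20)), letters[1:10])
  cr10 <- compare_rates(ten)
  expect_equal(cr10$n_comparisons, 45)
  expect_equal(round(cr10$bonferroni_cutoff, 4), 0.0011)

  expect_error(compare_rates(list(a = 1:5)), "at least 2")
  expect_error(compare_rates(list(a = 1:5, b = 3)), "fewer than 2")
})

test_that("Wilcoxon agrees with exhaustive enumeration up to (7,7)", {
  set.seed(9)
  for (m in 2:7) for (n in 2:7) {
    x <- runif(m); y <- runif(n) + 0.3
    p_pkg <- compare_rates(list(a = x, b = y))$pairwise_p["a", "b"]
    expect_equal(p_pkg, wilcox_enum_p(x, y),
                 info = sprintf("m=%d n=%d", m, n))
  }
})

test_that("confound regression: exactness, oracle, type-I error", {
  x <- c(1, 2, 3, 4, 5)
  f <- confound_regression(2 * x + 1, x)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(unname(residuals(f$fit)), rep(0, 5), tolerance = 1e-12)

  # normal-equations oracle on random 10-point data
  set.seed(21)
  x10 <- rnorm(10); y10 <- rnorm(10)
  X <- cbind(1, x10)
  beta <- solve(t(X) %*% X, t(X) %*% y10)
  f10 <- confound_regression(y10, x10)
  expect_equal(f10$intercept, beta[1], tolerance = 1e-10)
  expect_equal(f10$slope, beta[2], tolerance = 1e-10)

  # independent y -> ~uniform slope p, type-I error near 0.05
  set.seed(22)
  ps <- vapply(1:200, function(i)
    confound_regression(rnorm(10), rnorm(10))$slope_p, 0)
  expect_gt(mean(ps <= 0.05), 0.005)
  expect_lt(mean(ps <= 0.05), 0.12)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)

  expect_error(confound_regression(1:5, rep(2, 5)), "constant")
})
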