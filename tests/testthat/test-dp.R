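test_that("the Laplace sampler matches its distribution's moments", {
  set.seed(101)
  draws <- laplace_sample(1e5, scale = 1)
  expect_lt(abs(mean(draws)), 3 * sqrt(2) / sqrt(1e5))       # mean 0 within 3 SE
  expect_lt(abs(stats::var(draws) - 2) / 2, 0.05)            # var 2b^2 within 5%
  b <- 2.5
  set.seed(102)
  draws_b <- laplace_sample(1e5, scale = b)
  expect_lt(abs(stats::var(draws_b) - 2 * b^2) / (2 * b^2), 0.05)
})

test_that("the sampler is deterministic under a fixed RNG state", {
  set.seed(7); a <- laplace_sample(10, 1)
  set.seed(7); b <- laplace_sample(10, 1)
  expect_identical(a, b)
  set.seed(8); c <- laplace_sample(10, 1)
  expect_false(any(a == c))
  expect_error(laplace_sample(1, 0), "positive")
  expect_error(laplace_sample(1, -1), "positive")
})

test_that("noisy_count equals the independently recomputed inverse-CDF draw", {
  params <- dp_params(0.2, sensitivity = 1)
  set.seed(33)
  got <- noisy_count(37, params)
  # independent recomputation from the same uniform stream
  set.seed(33)
  u <- stats::runif(1) - 0.5
  expected <- 37 + (-(1 / 0.2) * sign(u) * log(1 - 2 * abs(u)))
  expect_equal(got$dp_value, max(0, expected))
  expect_equal(got$epsilon_spent, 0.2)
  expect_equal(got$noise_scale, 5)
})

test_that("noisy_count clamps at zero and converges to the raw count as eps grows", {
  params <- dp_params(0.5)
  set.seed(11)
  zeros <- replicate(200, noisy_count(0, params)$dp_value)
  expect_true(all(zeros >= 0))
  set.seed(1)
  huge <- noisy_count(100, dp_params(1e6))
  expect_lt(abs(huge$dp_value - 100), 1e-3)
  expect_error(dp_params(0), "positive")
  expect_error(dp_params(-1), "positive")
})

test_that("noisy_percentage matches an independent recomputation and stays in range", {
  res <- list(numerator = 37, denominator = 1000)
  set.seed(55)
  got <- noisy_percentage(res, dp_params(0.2))
  set.seed(55)
  b <- 1 / (0.2 / 2)
  u1 <- stats::runif(1) - 0.5
  c_noisy <- 37 - b * sign(u1) * log(1 - 2 * abs(u1))
  u2 <- stats::runif(1) - 0.5
  n_noisy <- max(1, 1000 - b * sign(u2) * log(1 - 2 * abs(u2)))
  c_noisy <- min(max(0, c_noisy), n_noisy)
  expect_equal(got$dp_percent, round(100 * c_noisy / n_noisy, 2))
  expect_equal(got$epsilon_spent, 0.2)

  for (s in 1:50) {
    set.seed(s)
    out <- noisy_percentage(list(numerator = 1, denominator = 2),
                            dp_params(0.05))
    expect_gte(out$dp_percent, 0)
    expect_lte(out$dp_percent, 100)
  }
  expect_error(noisy_percentage(list(numerator = 0, denominator = 0),
                                dp_params(1)),
               "insufficient population")
})

test_that("huge budgets return the raw percentage exactly after rounding", {
  set.seed(3)
  out <- noisy_percentage(list(numerator = 37, denominator = 1000),
                          dp_params(1e9))
  expect_equal(out$dp_percent, 3.70)
  set.seed(3)
  out2 <- noisy_percentage(list(numerator = 37, denominator = 1000),
                           dp_params(1e9), pair_split = FALSE)
  expect_equal(out2$dp_percent, 3.70)
})

test_that("stratum budget splits are uniform and conserve the total", {
  expect_equal(split_stratum_budget(0.3, 2), c(0.15, 0.15))
  expect_equal(split_stratum_budget(0.7, 1), 0.7)
  for (k in c(2, 3, 7)) {
    shares <- split_stratum_budget(0.31, k)
    expect_length(shares, k)
    expect_identical(sum(shares), 0.31)
  }
  expect_error(split_stratum_budget(0.3, 0), "positive")
})

test_that("one stratum reduces stratified noising to the plain mechanism", {
  res <- run_check(builtin_checks()[[3]], tiny_dataset())
  set.seed(21)
  strat <- stratified_noisy_rates(res, 0.3)
  set.seed(21)
  plain <- noisy_percentage(res, dp_params(0.3))
  expect_equal(strat[[1]]$dp_percent, plain$dp_percent)
  expect_equal(strat[[1]]$epsilon_spent, plain$epsilon_spent)
  expect_error(stratified_noisy_rates(res[0, ], 0.3), "at least one")
})

test_that("stratified noise follows the k-scaled variance law", {
  # numerator-only mode: noise scale df*k/eps_total, variance 2(df*k/eps)^2
  res <- tibble::tibble(numerator = c(5000, 5000),
                        denominator = c(10000, 10000))
  eps_total <- 1; k <- 2
  set.seed(500)
  noise <- replicate(1e4, {
    out <- stratified_noisy_rates(res, eps_total, pair_split = FALSE)
    out[[1]]$noisy_numerator - 5000
  })
  expected <- stratification_variance(1, k, eps_total)
  expect_lt(abs(stats::var(noise) - expected) / expected, 0.1)
})

test_that("low-count suppression rounds small releases to zero, strictly below threshold", {
  set.seed(2)
  noisy <- noisy_percentage(list(numerator = 3, denominator = 100),
                            dp_params(0.5))
  out <- suppress_low_count(noisy, raw_numerator = 3, threshold = 10)
  expect_equal(out$dp_percent, 0)
  expect_true(out$suppressed)
  # boundary: equal to the threshold is not suppressed
  at <- suppress_low_count(noisy, raw_numerator = 10, threshold = 10)
  expect_false(at$suppressed)
  off <- suppress_low_count(noisy, raw_numerator = 3, threshold = 0)
  expect_false(off$suppressed)
  expect_equal(off$dp_percent, noisy$dp_percent)
})

test_that("neighbouring counts satisfy the empirical epsilon-DP bound", {
  eps <- 1
  n_rep <- 4e4
  sample_release <- function(count) {
    vapply(seq_len(n_rep), function(i) {
      noisy_count(count, dp_params(eps))$dp_value
    }, numeric(1))
  }
  set.seed(900)
  a <- round(sample_release(3))
  b <- round(sample_release(4))
  bins <- intersect(unique(a), unique(b))
  ta <- table(factor(a, levels = bins))
  tb <- table(factor(b, levels = bins))
  keep <- ta >= 300 & tb >= 300  # bins with enough mass for a stable ratio
  expect_gt(sum(keep), 3)
  log_ratio <- abs(log(as.numeric(ta[keep]) / as.numeric(tb[keep])))
  # each integer bin aggregates one unit of Laplace mass, whose probability
  # ratio between neighbouring counts is bounded by e^eps; allow MC slack
  expect_true(all(log_ratio <= eps + 0.25))
})
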