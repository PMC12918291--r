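#' Differential-privacy parameters
#'
#' Parameters of the Laplace mechanism: the privacy budget ε, the slack δ
#' (fixed at 0 — the Laplace mechanism provides pure ε-DP), and the query
#' sensitivity Δf.
#'
#' @param epsilon Positive privacy budget ε.
#' @param delta Must be 0; retained so the (ε, δ) form is explicit.
#' @param sensitivity Positive integer sensitivity Δf.
#' @return Object of class `dp_params`.
#' @export
dp_params <- function(epsilon, delta = 0, sensitivity = 1L) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    stop("epsilon must be a single positive number")
  }
  if (delta != 0) stop("the Laplace mechanism provides pure eps-DP; delta must be 0")
  if (sensitivity < 1) stop("sensitivity must be >= 1")
  structure(list(epsilon = epsilon, delta = 0,
                 sensitivity = as.numeric(sensitivity)),
            class = "dp_params")
}

#' Draw Laplace noise
#'
#' Samples from the centred Laplace distribution with the given scale via the
#' inverse-CDF transform of a uniform draw:
#' `x = -b * sign(u) * log(1 - 2|u|)` with `u ~ Uniform(-1/2, 1/2)`.
#' Consumes the R global RNG stream, so results are reproducible under
#' `set.seed()` and identical across platforms.
#'
#' @param n Number of draws.
#' @param scale Positive scale b; the mechanism uses b = Δf/ε.
#' @return Numeric vector of draws; `Var = 2 b^2`.
#' @export
laplace_sample <- function(n = 1, scale) {
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    stop("scale must be a single positive number")
  }
  u <- stats::runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

#' Laplace mechanism for a count
#'
#' Releases `count + Lap(Δf/ε)`, clamped to be non-negative. Clamping is
#' post-processing — applied to the noised value, never to the raw statistic —
#' so the ε-DP guarantee is preserved.
#'
#' @param count Non-negative integer raw count f(D).
#' @param params A [dp_params()].
#' @param seed_tag Opaque local-only label recording the noise provenance.
#' @return Object of class `noisy_result` with fields `raw_value` (local
#'   only), `dp_value`, `epsilon_spent`, `noise_scale`, `seed_tag`.
#' @export
noisy_count <- function(count, params, seed_tag = NA_character_) {
  stopifnot(inherits(params, "dp_params"), count >= 0)
  b <- params$sensitivity / params$epsilon
  dp <- max(0, count + laplace_sample(1, b))
  structure(list(raw_value = count, dp_value = dp,
                 epsilon_spent = params$epsilon, noise_scale = b,
                 seed_tag = seed_tag),
            class = "noisy_result")
}

#' Laplace mechanism for a percentage (noisy numerator and denominator)
#'
#' Perturbs both the numerator c and the denominator n of a check result with
#' independent Laplace draws and reports the obfuscated percentage
#' `(c~ / n~) * 100`. By default the check's budget ε is halved between the
#' two draws (each at scale Δf/(ε/2)), a conservative self-contained
#' accounting; with `pair_split = FALSE` only the numerator is noised, at the
#' full ε — the single-query setting the closed-form utility forecasts in
#' [ratio_sd()] describe. The denominator is clamped to at least 1 and the
#' numerator to `[0, n~]`, so the percentage always lies in [0, 100];
#' clamping and rounding are post-processing.
#'
#' @param result One-row check result (as from [run_check()]) or any list
#'   with `numerator` and `denominator`.
#' @param params A [dp_params()]; `params$epsilon` is the total budget for
#'   the pair.
#' @param pair_split Halve ε between numerator and denominator (default) or
#'   spend it all on the numerator.
#' @param seed_tag Opaque local-only label.
#' @return Object of class `noisy_ratio`: `noisy_numerator`,
#'   `noisy_denominator`, `dp_percent` (rounded to 2 decimals),
#'   `raw_percent` (local only), `epsilon_spent`, `suppressed`.
#' @export
noisy_percentage <- function(result, params, pair_split = TRUE,
                             seed_tag = NA_character_) {
  stopifnot(inherits(params, "dp_params"))
  c_raw <- as.numeric(result$numerator)
  n_raw <- as.numeric(result$denominator)
  if (is.na(n_raw) || n_raw <= 0) {
    stop("insufficient population: denominator must be positive")
  }
  if (pair_split) {
    b <- params$sensitivity / (params$epsilon / 2)
    c_noisy <- c_raw + laplace_sample(1, b)
    n_noisy <- n_raw + laplace_sample(1, b)
  } else {
    b <- params$sensitivity / params$epsilon
    c_noisy <- c_raw + laplace_sample(1, b)
    n_noisy <- n_raw
  }
  n_noisy <- max(1, n_noisy)
  c_noisy <- min(max(0, c_noisy), n_noisy)
  structure(list(
    noisy_numerator = c_noisy,
    noisy_denominator = n_noisy,
    dp_percent = round(100 * c_noisy / n_noisy, 2),
    raw_percent = round(100 * c_raw / n_raw, 2),
    epsilon_spent = params$epsilon,
    noise_scale = b,
    suppressed = FALSE,
    seed_tag = seed_tag
  ), class = "noisy_ratio")
}

#' Split a stratified check's budget across strata
#'
#' Uniform split ε_i = ε_total / k, the allocation that preserves the fixed
#' total budget under sequential composition across strata. The shares sum to
#' ε_total exactly.
#'
#' @param epsilon_total Positive total budget for the stratified check.
#' @param k Positive integer number of strata.
#' @return Numeric vector of k shares.
#' @export
split_stratum_budget <- function(epsilon_total, k) {
  stopifnot(epsilon_total > 0)
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    stop("k must be a positive integer")
  }
  k <- as.integer(k)
  shares <- rep(epsilon_total / k, k)
  shares[k] <- epsilon_total - sum(shares[-k])
  shares
}

#' Perturb a stratified check result
#'
#' Applies [noisy_percentage()] to each stratum with its uniform share
#' ε_i = ε_total / k, so the whole stratified check consumes ε_total under
#' sequential composition. The per-stratum noise scale therefore grows
#' linearly in k (Δf·k/ε_total in the numerator-only mode) and its variance
#' quadratically — the utility cost of stratification.
#'
#' @param results Check-result rows sharing a check id, one per stratum
#'   (a tibble as from [run_check()]).
#' @param epsilon_total Positive total budget for the check.
#' @param sensitivity Δf.
#' @param pair_split Passed through to [noisy_percentage()].
#' @return List of `noisy_ratio`, one per stratum, in input order.
#' @export
stratified_noisy_rates <- function(results, epsilon_total, sensitivity = 1L,
                                   pair_split = TRUE) {
  k <- nrow(results)
  if (is.null(k) || k == 0) stop("results must contain at least one stratum")
  shares <- split_stratum_budget(epsilon_total, k)
  lapply(seq_len(k), function(i) {
    noisy_percentage(results[i, ],
                     dp_params(shares[i], sensitivity = sensitivity),
                     pair_split = pair_split)
  })
}

#' Low-count suppression
#'
#' Optional post-processing for small numerators: when the raw numerator is
#' strictly below the threshold, the released percentage is rounded down to
#' zero and flagged as suppressed. A threshold of 0 disables suppression.
#' Because only the already-noised release is modified, the DP guarantee is
#' unaffected.
#'
#' @param noisy A `noisy_ratio`.
#' @param raw_numerator The raw count the release was computed from.
#' @param threshold Non-negative integer; strict less-than comparison.
#' @return The (possibly suppressed) `noisy_ratio`.
#' @export
suppress_low_count <- function(noisy, raw_numerator, threshold = 10) {
  stopifnot(inherits(noisy, "noisy_ratio"), threshold >= 0)
  if (threshold > 0 && raw_numerator < threshold) {
    noisy$dp_percent <- 0
    noisy$suppressed <- TRUE
  }
  noisy
}
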