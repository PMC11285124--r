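#' Bit-score threshold from Gumbel parameters
#'
#' Ungapped maximal-segment scores of random sequences follow a Gumbel
#' (type-I extreme value) distribution with location `mu` and scale `lambda`,
#' with survival convention `P(S >= s) = 1 - exp(-exp(-lambda (s - mu)))`.
#' The filter threshold is the score whose survival probability equals the
#' requested P-value target: `t = mu - log(-log(1 - p)) / lambda`, plus an
#' optional additive adjustment in bits for conventions that correct the
#' precomputed parameters for the ungapped model's removed state transitions.
#'
#' @param p Filter P-value target, in (0, 1) (default used by the pipeline:
#'   0.02, the conventional ungapped-filter pass rate).
#' @param mu Gumbel location (bits).
#' @param lambda Gumbel scale (per bit, > 0).
#' @param adjust_bits Additive threshold adjustment in bits (default 0).
#' @return Threshold score `t` in bits; strictly decreasing in `p`.
#' @export
threshold_from_gumbel <- function(p, mu, lambda, adjust_bits = 0) {
  if (!is.finite(p) || p <= 0 || p >= 1) stop("p must be in (0, 1)")
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0")
  mu - log(-log1p(-p)) / lambda + adjust_bits
}

#' Gumbel survival function
#'
#' `P(S >= s)` under the convention used by [threshold_from_gumbel()];
#' exposed so the inversion can be checked directly.
#' @param s Score in bits.
#' @param mu,lambda Gumbel location and scale.
#' @return Survival probability.
#' @export
gumbel_survival <- function(s, mu, lambda) {
  -expm1(-exp(-lambda * (s - mu)))
}

#' Accumulator scaling factor
#'
#' The fixed-point engine checks hits against the constant 256 rather than a
#' per-model threshold, so emission scores are scaled by `tau = 256 / t`:
#' an accumulated bit score of exactly `t` then lands exactly on 256.
#'
#' @param t Threshold in bits (> 0).
#' @return `tau = 256 / t`.
#' @export
compute_tau <- function(t) {
  if (!is.finite(t) || t <= 0)
    stop("threshold t must be > 0 (increase the P-value target or mu)")
  256 / t
}

#' Reproject emission scores onto the tau-scaled signed 8-bit scale
#'
#' A negative-natural-log emission score `s` converts to bits against the
#' uniform 1/4 nucleotide background as `log2(exp(-s) / (1/4))`, and the
#' tau-scaled projection simplifies to
#' `s' = 2 tau - s tau log2(e)`.
#' Each projected score is rounded to the nearest integer (ties away from
#' zero, as C `lround`) and saturated to the int8 range \[-128, 127\];
#' `clamped_count` reports how many entries saturated, a sign of quantization
#' stress at small thresholds.
#'
#' @param hmm A [profile_hmm()].
#' @param tau Positive scaling factor, typically from [compute_tau()].
#' @return A `ProjectedModel`: `source`, `threshold_bits` (= 256/tau), `tau`,
#'   `scores8` (K x 4 integer matrix in \[-128, 127\]), `scores_unrounded`
#'   (the full-precision projection, kept for quantization-envelope
#'   reasoning), `clamped_count`, and `p_value` (filled by
#'   [project_model()]).
#' @export
reproject_scores <- function(hmm, tau) {
  stopifnot(inherits(hmm, "ProfileHMM"))
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0")
  unrounded <- 2 * tau - hmm$match_scores * tau * LOG2E
  rounded <- round_half_away(unrounded)
  clamped <- sum(rounded < -128 | rounded > 127)
  scores8 <- pmin(pmax(rounded, -128), 127)
  storage.mode(scores8) <- "integer"
  structure(
    list(source = hmm, threshold_bits = 256 / tau, tau = tau,
         p_value = NA_real_, scores8 = scores8,
         scores_unrounded = unrounded, clamped_count = as.integer(clamped)),
    class = "ProjectedModel"
  )
}

#' Project a model at a P-value target
#'
#' Convenience wrapper: derive the bit threshold from the model's Gumbel
#' parameters at `p_value`, compute `tau`, and reproject the emissions.
#'
#' @param hmm A [profile_hmm()] with Gumbel parameters set.
#' @param p_value Filter P target (default 0.02).
#' @param adjust_bits Threshold adjustment in bits (default 0).
#' @return A `ProjectedModel` (see [reproject_scores()]).
#' @export
project_model <- function(hmm, p_value = 0.02, adjust_bits = 0) {
  stopifnot(inherits(hmm, "ProfileHMM"))
  if (is.na(hmm$gumbel_mu) || is.na(hmm$gumbel_lambda))
    stop("model '", hmm$name, "' has no Gumbel parameters; ",
         "supply a STATS line or calibrate_gumbel_by_simulation()")
  t <- threshold_from_gumbel(p_value, hmm$gumbel_mu, hmm$gumbel_lambda,
                             adjust_bits)
  pm <- reproject_scores(hmm, compute_tau(t))
  pm$p_value <- p_value
  pm
}

#' @export
print.ProjectedModel <- function(x, ...) {
  cat(sprintf(
    "ProjectedModel '%s': t = %.3f bits, tau = %.4f, %d/%d entries clamped\n",
    x$source$name, x$threshold_bits, x$tau, x$clamped_count,
    length(x$scores8)))
  invisible(x)
}

# full-precision bit scores against the uniform background (K x 4)
bit_scores <- function(hmm) {
  2 - hmm$match_scores * LOG2E
}

#' Calibrate Gumbel parameters by simulation
#'
#' For models without precomputed statistics, the null distribution of the
#' maximal ungapped segment score is estimated directly: `n_seqs` i.i.d.
#' uniform random sequences of length `seq_len` are scored with the
#' full-precision recurrence ([ssv_max_score()]) in background-normalized
#' bits, and a Gumbel is fitted to the maxima by maximum likelihood. Because
#' the location parameter grows with target length, calibrate with `seq_len`
#' comparable to the sequences that will be searched.
#'
#' @param hmm A [profile_hmm()].
#' @param n_seqs Number of simulated sequences (>= 100).
#' @param seq_len Length of each simulated sequence (>= K).
#' @param seed Integer seed; the same `(hmm, n_seqs, seq_len, seed)` always
#'   returns identical parameters.
#' @return Named numeric vector `c(mu =, lambda =)`.
#' @export
calibrate_gumbel_by_simulation <- function(hmm, n_seqs = 1000L,
                                           seq_len = 1000L, seed = 1L) {
  stopifnot(inherits(hmm, "ProfileHMM"))
  if (n_seqs < 100L) stop("n_seqs must be >= 100 for a stable fit")
  if (seq_len < hmm$K) stop("seq_len must be >= the model length K")
  B <- bit_scores(hmm)
  maxima <- with_seed(seed, {
    vapply(seq_len(n_seqs), function(i) {
      codes <- sample(0:3, seq_len, replace = TRUE)
      ssv_max_score_cpp(codes, B)
    }, numeric(1))
  })
  fit_gumbel_mle(maxima)
}

#' Fit a Gumbel distribution by maximum likelihood
#'
#' Moment-based initialization (`beta0 = sd sqrt(6)/pi`), then BFGS on
#' `(mu, log beta)`; returned `lambda = 1/beta`.
#'
#' @param x Numeric sample (maxima), length >= 10, non-degenerate.
#' @return Named numeric vector `c(mu =, lambda =)`.
#' @export
fit_gumbel_mle <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 10L) stop("need at least 10 observations")
  s <- sd(x)
  if (!is.finite(s) || s < sqrt(.Machine$double.eps))
    stop("degenerate score distribution: all maxima (nearly) equal")
  beta0 <- s * sqrt(6) / pi
  mu0 <- mean(x) - 0.57721566490153286 * beta0
  nll <- function(par) {
    mu <- par[1]; beta <- exp(par[2])
    z <- (x - mu) / beta
    length(x) * log(beta) + sum(z + exp(-z))
  }
  fit <- optim(c(mu0, log(beta0)), nll, method = "BFGS")
  c(mu = fit$par[1], lambda = 1 / exp(fit$par[2]))
}
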