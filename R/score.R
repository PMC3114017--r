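#' Ratio enrichment score
#'
#' The default per-nucleotide enrichment score: the moment-matched IP value
#' over the background-floored control value, `t_i = max(y'_i, 0) /
#' y_floor_i`.  Negative moment-matched IP values are a normalization
#' artifact with no enrichment meaning and clamp to 0.  Because the control
#' is floored at `beta > 0`, the denominator is always positive.  Compared
#' to a Poisson tail probability, the ratio depends less on the statistical
#' power (depth) of the particular experiment, making scores more
#' comparable across experiments.
#'
#' @param ip_norm moment-matched IP `genome_track` (see [moment_match()]).
#' @param control_floored background-floored control `genome_track` (see
#'   [floor_control()]).
#' @param beta the background floor applied to `control_floored`; must be
#'   positive.
#' @return A score `genome_track` with non-negative values.
#' @export
ratio_score <- function(ip_norm, control_floored, beta) {
  stopifnot_scalar_number(beta, "beta")
  if (beta <= 0)
    stop("beta must be positive for the ratio score", call. = FALSE)
  track_map2(ip_norm, control_floored,
             function(y2, y1) pmax(y2, 0) / pmax(y1, beta),
             kind = "score",
             meta = list(test = "ratio", beta = beta))
}

#' Poisson enrichment score
#'
#' Per-nucleotide upper-tail Poisson test: with the floored control value
#' as the rate `lambda_i` and `k_i = ceiling(max(y'_i, 0))` as the
#' observation, the score is `t_i = -log10 P(Y >= k_i)`, `Y ~
#' Poisson(lambda_i)`.  Larger scores indicate stronger enrichment;
#' `k_i = 0` gives probability 1 and score 0.  The tail is computed on the
#' log scale, so deep-coverage positions do not underflow.  The ceiling is
#' conservative: it never inflates significance relative to the continuous
#' normalized value.
#'
#' @inheritParams ratio_score
#' @return A score `genome_track` with non-negative values (in -log10
#'   units).
#' @export
poisson_score <- function(ip_norm, control_floored, beta) {
  stopifnot_scalar_number(beta, "beta")
  if (beta <= 0)
    stop("beta must be positive (flooring failed?)", call. = FALSE)
  track_map2(ip_norm, control_floored,
             function(y2, y1) {
               k <- ceiling(pmax(y2, 0))
               lam <- pmax(y1, beta)
               # P(Y >= k) = P(Y > k - 1); log scale for stability
               -stats::ppois(k - 1, lambda = lam, lower.tail = FALSE,
                             log.p = TRUE) / log(10)
             },
             kind = "score",
             meta = list(test = "poisson", beta = beta))
}

#' Per-nucleotide enrichment scores
#'
#' Dispatches to [ratio_score()] (default) or [poisson_score()].
#'
#' @inheritParams ratio_score
#' @param test `"ratio"` or `"poisson"`.
#' @return A score `genome_track`.
#' @export
enrichment_score <- function(ip_norm, control_floored, beta,
                             test = c("ratio", "poisson")) {
  test <- match.arg(test)
  switch(test,
         ratio = ratio_score(ip_norm, control_floored, beta),
         poisson = poisson_score(ip_norm, control_floored, beta))
}
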