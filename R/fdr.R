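#' Randomly permute sample labels over pooled reads
#'
#' Pools the control and IP reads and randomly repartitions them into two
#' sets of the original sizes.  Because permuting labels destroys any
#' relationship between a read and the sample it came from, analyses of
#' permuted datasets sample the score distribution under the null
#' hypothesis of no enrichment.
#'
#' @param control,ip non-empty [read_set()]s.
#' @param seed RNG seed; the same seed always yields the same partition.
#' @return A list with elements `control` and `ip`: read sets of sizes
#'   `total_mapped(control)` and `total_mapped(ip)` whose union (as a
#'   multiset) equals the union of the inputs.
#' @export
permute_labels <- function(control, ip, seed = NULL) {
  if (nrow(control) == 0L || nrow(ip) == 0L)
    stop("both read sets must be non-empty", call. = FALSE)
  pooled <- rbind(as.data.frame(control), as.data.frame(ip))
  n <- nrow(pooled)
  n1 <- nrow(control)
  idx <- with_seed(seed, sample.int(n, n1))
  list(control = as_read_set(pooled[idx, , drop = FALSE],
                             label = read_label(control)),
       ip = as_read_set(pooled[-idx, , drop = FALSE],
                        label = read_label(ip)))
}

# Bundle of pipeline parameters shared by the observed analysis and every
# permutation.  Kept internal; peak_call() and permutation_null() build it.
pipeline_config <- function(fragment_length, theta = 1,
                            strand_mode = "minimum", test = "ratio",
                            cutoff = 2, merge_distance = 100,
                            c_user = NULL) {
  stopifnot_scalar_number(fragment_length, "fragment_length", positive = TRUE)
  list(fragment_length = fragment_length, theta = theta,
       strand_mode = match.arg(strand_mode,
                               c("minimum", "forward", "reverse", "sum")),
       test = match.arg(test, c("ratio", "poisson")),
       cutoff = cutoff, merge_distance = merge_distance, c_user = c_user)
}

# One full scoring pass: coverage -> scale -> moment-match -> background
# floor -> score -> candidate regions.  Returns the full bundle when
# full = TRUE, otherwise just the region data.frame.
analyze_pair <- function(control, ip, genome, config, full = FALSE) {
  xc <- extend_and_count(control, genome, config$fragment_length,
                         config$strand_mode)
  xi <- extend_and_count(ip, genome, config$fragment_length,
                         config$strand_mode)
  yc <- scale_counts(xc, total_mapped(control), config$theta)
  yi <- scale_counts(xi, total_mapped(ip), config$theta)
  mm <- moment_match(yi, yc)
  bg <- compute_background(xi, total_mapped(ip), mm$params,
                           theta = config$theta, c_user = config$c_user)
  ycf <- floor_control(yc, bg$beta)
  scores <- enrichment_score(mm$track, ycf, bg$beta, test = config$test)
  regions <- call_candidate_regions(scores, config$cutoff,
                                    config$merge_distance)
  if (!full) return(regions)
  list(regions = regions, scores = scores, params = mm$params,
       background = bg, coverage = list(control = xc, ip = xi),
       ip_norm = mm$track, control_floored = ycf)
}

#' Null distribution of region scores by label permutation
#'
#' Re-runs the complete scoring pipeline (coverage, depth scaling,
#' moment matching, background floor, scoring, candidate-region calling)
#' on `n_perm` label-permuted datasets with identical parameters, recording
#' every region max-score.  Over a sufficient number of permutations this
#' estimates the distribution of the region test statistic under the null
#' hypothesis.
#'
#' @inheritParams permute_labels
#' @param genome a [genome_spec()].
#' @param fragment_length average sequenced-fragment length (bp).
#' @param theta depth-scaling constant (see [scale_counts()]).
#' @param strand_mode strand combination rule (see [extend_and_count()]).
#' @param test `"ratio"` or `"poisson"` (see [enrichment_score()]).
#' @param cutoff candidate score cutoff (see [call_candidate_regions()]).
#' @param merge_distance region merge distance in bp.
#' @param c_user optional user-supplied background level
#'   (see [compute_background()]).
#' @param n_perm number of permutations.
#' @param seed base RNG seed; permutation `p` uses `seed + p`, so a single
#'   seed fans out deterministically.
#' @return A `permutation_null`: list with `n_perm`, `null_scores` (one
#'   numeric vector of region max-scores per permutation), `seed` and
#'   `config`.  A permutation with a degenerate (constant-coverage) sample
#'   is recorded as zero regions, with a warning.
#' @export
permutation_null <- function(control, ip, genome, fragment_length,
                             theta = 1, strand_mode = "minimum",
                             test = "ratio", cutoff = 2,
                             merge_distance = 100, c_user = NULL,
                             n_perm = 20, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  config <- pipeline_config(fragment_length, theta, strand_mode, test,
                            cutoff, merge_distance, c_user)
  null_scores <- vector("list", n_perm)
  for (p in seq_len(n_perm)) {
    perm <- permute_labels(control, ip, seed = seed + p)
    null_scores[[p]] <- tryCatch(
      analyze_pair(perm$control, perm$ip, genome, config)$t_max,
      error = function(e) {
        warning(sprintf("permutation %d degenerate (%s); recorded 0 regions",
                        p, conditionMessage(e)), call. = FALSE)
        numeric(0)
      })
  }
  structure(list(n_perm = n_perm, null_scores = null_scores,
                 seed = seed, config = config),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  ns <- lengths(x$null_scores)
  cat(sprintf("<permutation_null> %d permutation(s), %d null region score(s) total\n",
              x$n_perm, sum(ns)))
  if (sum(ns))
    cat(sprintf("  null max-score range: [%.4g, %.4g]\n",
                min(unlist(x$null_scores)), max(unlist(x$null_scores))))
  invisible(x)
}

#' Permutation FDR threshold for region scores
#'
#' For each candidate threshold `t` among the distinct observed region
#' max-scores, the estimated false discovery rate is the plug-in ratio
#' `FDR(t) = mean_p #\{null scores >= t\} / #\{observed scores >= t\}`.
#' The curve is monotonized by a cumulative minimum (so that raising the
#' threshold never raises the estimated FDR), and the reported threshold
#' is the smallest observed score whose monotonized FDR does not exceed
#' `fdr_level` -- i.e. the most inclusive threshold still controlling the
#' FDR.  If no threshold qualifies, the threshold is `Inf` and nothing is
#' significant.
#'
#' @param observed observed regions: a region `data.frame` (column
#'   `t_max`) or a numeric vector of max-scores.  Must be non-empty.
#' @param null a [permutation_null()].
#' @param fdr_level target FDR (default 0.05).
#' @return An `fdr_threshold` object: list with `threshold`,
#'   `n_significant`, `fdr_level`, `n_perm` and `fdr_curve` (a
#'   `data.frame` of candidate thresholds with raw and monotonized FDR
#'   estimates, ascending in threshold).
#' @examples
#' null <- structure(list(n_perm = 2, null_scores = list(c(5, 3), c(7, 1))),
#'                   class = "permutation_null")
#' fdr_threshold(c(10, 8, 6, 4), null, fdr_level = 0.05)  # threshold 8
#' @export
fdr_threshold <- function(observed, null, fdr_level = 0.05) {
  obs <- if (is.data.frame(observed)) observed$t_max else as.numeric(observed)
  if (length(obs) == 0L)
    stop("no observed regions; FDR threshold is undefined", call. = FALSE)
  stopifnot_scalar_number(fdr_level, "fdr_level", positive = TRUE)
  cand <- sort(unique(obs))
  nullv <- null$null_scores
  mean_exceed <- vapply(cand, function(t)
    mean(vapply(nullv, function(v) sum(v >= t), numeric(1))), numeric(1))
  obs_exceed <- vapply(cand, function(t) sum(obs >= t), numeric(1))
  fdr_raw <- pmin(mean_exceed / obs_exceed, 1)  # an FDR is a proportion
  fdr_mono <- cummin(fdr_raw)   # ascending t: min over all thresholds <= t
  ok <- which(fdr_mono <= fdr_level)
  threshold <- if (length(ok)) cand[ok[1]] else Inf
  structure(list(threshold = threshold,
                 n_significant = sum(obs >= threshold),
                 fdr_level = fdr_level,
                 n_perm = null$n_perm,
                 fdr_curve = data.frame(threshold = cand,
                                        fdr_raw = fdr_raw,
                                        fdr = fdr_mono)),
            class = "fdr_threshold")
}

#' @export
print.fdr_threshold <- function(x, ...) {
  cat(sprintf("<fdr_threshold> FDR <= %.3g: threshold %s, %d significant region(s) (%d permutations)\n",
              x$fdr_level,
              if (is.finite(x$threshold)) format(x$threshold, digits = 5)
              else "Inf (none qualify)",
              x$n_significant, x$n_perm))
  invisible(x)
}
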