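#' Detect protein-bound regions from ChIP-seq read sets
#'
#' The package's main entry point: runs the complete analysis on a
#' control/IP pair of mapped-read sets and returns a fitted `peak_call`
#' object.  The workflow is
#' \enumerate{
#'   \item drop reads on excluded/unknown chromosomes
#'     ([filter_chromosomes()]);
#'   \item extend reads to `fragment_length` and count per-strand hits,
#'     combined by `strand_mode` ([extend_and_count()]);
#'   \item scale both samples to hits per `theta` million reads
#'     ([scale_counts()]) and moment-match the IP coverage distribution to
#'     the control ([moment_match()]);
#'   \item derive the background floor `beta` and floor the control
#'     ([compute_background()], [floor_control()]);
#'   \item score every nucleotide by the ratio or Poisson test
#'     ([enrichment_score()]) and call candidate regions above `cutoff`,
#'     merging runs closer than `merge_distance`
#'     ([call_candidate_regions()]);
#'   \item estimate the null distribution of region max-scores by `n_perm`
#'     label permutations ([permutation_null()]) and pick the score
#'     threshold controlling the FDR at `fdr_level` ([fdr_threshold()]).
#' }
#'
#' @param control,ip [read_set()]s for the control and IP samples.
#' @param genome a [genome_spec()].
#' @param fragment_length average sequenced-fragment length in bp
#'   (user-provided; no default, as it is a property of the library).
#' @param theta depth-scaling constant (default 1: hits per million
#'   reads).
#' @param strand_mode strand combination rule (default `"minimum"`; see
#'   [extend_and_count()]).
#' @param test `"ratio"` (default) or `"poisson"`.
#' @param cutoff candidate score cutoff (default 2).
#' @param merge_distance merge gap in bp (default 100).
#' @param fdr_level target false discovery rate (default 0.05).
#' @param n_perm number of label permutations (default 20).
#' @param c_user optional user-supplied background level.
#' @param seed RNG seed driving the permutations.
#' @return A `peak_call` object: list with `regions` (candidate regions
#'   with a `significant` flag), `threshold` ([fdr_threshold()] result, or
#'   `NULL` when there were no candidate regions), `null`
#'   ([permutation_null()]), `scores` (score `genome_track`), `params`
#'   (normalization moments), `background` (`c`, `n0`, `beta`), `qc`
#'   (duplicate reports per sample), `config`, `genome` and `seed`.
#'   Supports `print()`, `summary()` and `plot()`; see
#'   [significant_regions()].
#' @examples
#' sim <- simulate_chipseq(50000, n_peaks = 3, depth = 5000, seed = 42)
#' fit <- peak_call(sim$control, sim$ip, sim$truth$genome,
#'                  fragment_length = 150, n_perm = 5, seed = 42)
#' fit
#' @export
peak_call <- function(control, ip, genome, fragment_length,
                      theta = 1, strand_mode = "minimum", test = "ratio",
                      cutoff = 2, merge_distance = 100, fdr_level = 0.05,
                      n_perm = 20, c_user = NULL, seed = 1) {
  config <- pipeline_config(fragment_length, theta, strand_mode, test,
                            cutoff, merge_distance, c_user)
  control <- filter_chromosomes(control, genome)
  ip <- filter_chromosomes(ip, genome)
  if (nrow(control) == 0L || nrow(ip) == 0L)
    stop("no reads left after chromosome filtering", call. = FALSE)

  obs <- analyze_pair(control, ip, genome, config, full = TRUE)
  regions <- obs$regions

  if (nrow(regions)) {
    null <- permutation_null(control, ip, genome,
                             fragment_length = fragment_length,
                             theta = theta, strand_mode = strand_mode,
                             test = test, cutoff = cutoff,
                             merge_distance = merge_distance,
                             c_user = c_user, n_perm = n_perm, seed = seed)
    thr <- fdr_threshold(regions, null, fdr_level = fdr_level)
    regions$significant <- regions$t_max >= thr$threshold
  } else {
    null <- NULL
    thr <- NULL
    regions$significant <- logical(0)
  }

  structure(list(regions = regions, threshold = thr, null = null,
                 scores = obs$scores, params = obs$params,
                 background = obs$background,
                 qc = list(control = duplicate_stats(control),
                           ip = duplicate_stats(ip)),
                 n_reads = c(control = nrow(control), ip = nrow(ip)),
                 config = config, fdr_level = fdr_level,
                 genome = genome, seed = seed),
            class = "peak_call")
}

#' Significant regions of a peak_call fit
#'
#' @param fit a [peak_call()] object.
#' @return The rows of `fit$regions` passing the FDR threshold.
#' @export
significant_regions <- function(fit) {
  fit$regions[fit$regions$significant, , drop = FALSE]
}

#' @export
print.peak_call <- function(x, ...) {
  cat("Permutation-calibrated ChIP-seq peak call\n")
  cat(sprintf("  test: %s (cutoff %g, merge < %g bp, strand mode '%s')\n",
              x$config$test, x$config$cutoff, x$config$merge_distance,
              x$config$strand_mode))
  cat(sprintf("  reads: %s control, %s IP; fragment length %g bp\n",
              format(x$n_reads[["control"]], big.mark = ","),
              format(x$n_reads[["ip"]], big.mark = ","),
              x$config$fragment_length))
  cat(sprintf("  candidate regions: %d\n", nrow(x$regions)))
  if (is.null(x$threshold)) {
    cat("  no candidate regions; nothing to test\n")
  } else {
    cat(sprintf("  FDR <= %.3g (%d permutations): threshold %s -> %d significant\n",
                x$fdr_level, x$null$n_perm,
                if (is.finite(x$threshold$threshold))
                  format(x$threshold$threshold, digits = 5) else "Inf",
                x$threshold$n_significant))
  }
  invisible(x)
}

#' @method summary peak_call
#' @export
summary.peak_call <- function(object, ...) {
  structure(list(fit = object), class = "summary.peak_call")
}

#' @export
print.summary.peak_call <- function(x, ...) {
  f <- x$fit
  print(f)
  p <- f$params
  cat(sprintf("  normalization: control mean %.4g sd %.4g | IP mean %.4g sd %.4g (moment-matched)\n",
              p$mean_control, p$sd_control, p$mean_ip, p$sd_ip))
  cat(sprintf("  background: c = %.4g over n0 = %s nonzero positions -> beta = %.4g\n",
              f$background$c, format(f$background$n0, big.mark = ","),
              f$background$beta))
  cat(sprintf("  duplicates: control %d%%, IP %d%%\n",
              round(f$qc$control$pct_duplicated),
              round(f$qc$ip$pct_duplicated)))
  sig <- significant_regions(f)
  if (nrow(sig)) {
    cat(sprintf("  top significant regions (of %d):\n", nrow(sig)))
    top <- sig[order(-sig$t_max), , drop = FALSE]
    print(utils::head(top, 5L), row.names = FALSE)
  }
  invisible(x)
}

#' Plot a peak_call fit
#'
#' `type = "fdr"` draws the estimated FDR as a function of the score
#' threshold, with the chosen threshold marked; `type = "scores"` draws
#' the per-nucleotide score track of one chromosome with significant
#' regions shaded.
#'
#' @param x a [peak_call()] object.
#' @param type `"fdr"` or `"scores"`.
#' @param chrom chromosome to draw for `type = "scores"` (default: the
#'   first).
#' @param ... passed to the underlying plot call.
#' @return `x`, invisibly.
#' @method plot peak_call
#' @export
plot.peak_call <- function(x, type = c("fdr", "scores"), chrom = NULL, ...) {
  type <- match.arg(type)
  if (type == "fdr") {
    if (is.null(x$threshold)) {
      warning("no candidate regions; nothing to plot", call. = FALSE)
      return(invisible(x))
    }
    cv <- x$threshold$fdr_curve
    graphics::plot(cv$threshold, cv$fdr, type = "s",
                   xlab = "score threshold", ylab = "estimated FDR",
                   main = "Permutation FDR curve", ...)
    graphics::abline(h = x$fdr_level, lty = 2)
    if (is.finite(x$threshold$threshold))
      graphics::abline(v = x$threshold$threshold, col = 2)
  } else {
    if (is.null(chrom)) chrom <- names(x$scores)[1]
    t <- x$scores[[chrom]]
    graphics::plot(seq_along(t), t, type = "l",
                   xlab = sprintf("position on %s (bp)", chrom),
                   ylab = sprintf("enrichment score (%s)", x$config$test),
                   main = "Per-nucleotide enrichment", ...)
    sig <- significant_regions(x)
    sig <- sig[sig$chrom == chrom, , drop = FALSE]
    if (nrow(sig))
      graphics::rect(sig$start, 0, sig$end, max(t),
                     col = grDevices::adjustcolor(2, 0.2), border = NA)
    graphics::abline(h = x$config$cutoff, lty = 3)
  }
  invisible(x)
}
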