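#' Simulation study of realized FDR control
#'
#' Repeatedly simulates a ChIP-seq experiment with planted peaks
#' ([simulate_chipseq()]), runs the full pipeline ([peak_call()])
#' requesting FDR control at `fdr_level`, and measures the realized
#' false-discovery proportion: a significant region counts as a false
#' discovery when no true region lies within `within` bp of it
#' ([region_overlap()]).  Also records sensitivity (the fraction of true
#' regions recovered by a significant region within `within` bp).
#'
#' Replicate `i` uses seed `seed + 10000 * i` for both the simulation and
#' the permutations, so a single seed fans out deterministically without
#' overlapping the per-permutation seed streams.
#'
#' @param n_rep number of simulation replicates.
#' @param seed base RNG seed.
#' @param genome_length genome size in bp (one chromosome).
#' @param n_peaks,enrichment,peak_halfwidth,depth,read_length simulation
#'   parameters (see [simulate_chipseq()]).
#' @param fragment_length fragment length used for both simulation and
#'   analysis.
#' @param n_perm,cutoff,test,fdr_level analysis parameters (see
#'   [peak_call()]).
#' @param within match distance in bp between called and true regions.
#' @return An `fdr_study` object: list with `replicates` (a `data.frame`
#'   of per-replicate `n_candidate`, `n_significant`, `n_false`, `fdp`,
#'   `sensitivity`, `threshold`), `mean_fdp`, `se_fdp` (Monte-Carlo
#'   standard error of the mean FDP), `mean_sensitivity`, `fdr_level` and
#'   the parameters used.
#' @export
fdr_study <- function(n_rep = 20, seed = 1, genome_length = 200000,
                      n_peaks = 20, enrichment = 8, peak_halfwidth = 150,
                      depth = 50000, fragment_length = 150,
                      read_length = 36, n_perm = 50, cutoff = 2,
                      test = "ratio", fdr_level = 0.05, within = 250) {
  rows <- vector("list", n_rep)
  for (i in seq_len(n_rep)) {
    rep_seed <- seed + 10000 * i
    sim <- simulate_chipseq(genome_length, n_peaks = n_peaks,
                            enrichment = enrichment,
                            peak_halfwidth = peak_halfwidth, depth = depth,
                            fragment_length = fragment_length,
                            read_length = read_length, seed = rep_seed)
    fit <- peak_call(sim$control, sim$ip, sim$truth$genome,
                     fragment_length = fragment_length, test = test,
                     cutoff = cutoff, fdr_level = fdr_level,
                     n_perm = n_perm, seed = rep_seed)
    sig <- significant_regions(fit)
    truth <- sim$truth$regions
    n_false <- if (nrow(sig))
      sum(!region_overlap(sig, truth, within = within)) else 0L
    recovered <- if (nrow(sig))
      sum(region_overlap(truth, sig, within = within)) else 0L
    rows[[i]] <- data.frame(
      replicate = i, seed = rep_seed,
      n_candidate = nrow(fit$regions),
      n_significant = nrow(sig), n_false = n_false,
      fdp = if (nrow(sig)) n_false / nrow(sig) else 0,
      sensitivity = recovered / nrow(truth),
      threshold = if (is.null(fit$threshold)) Inf
        else fit$threshold$threshold)
  }
  reps <- do.call(rbind, rows)
  structure(list(replicates = reps,
                 mean_fdp = mean(reps$fdp),
                 se_fdp = stats::sd(reps$fdp) / sqrt(n_rep),
                 mean_sensitivity = mean(reps$sensitivity),
                 fdr_level = fdr_level,
                 params = list(n_rep = n_rep, seed = seed,
                               genome_length = genome_length,
                               n_peaks = n_peaks, enrichment = enrichment,
                               peak_halfwidth = peak_halfwidth,
                               depth = depth,
                               fragment_length = fragment_length,
                               read_length = read_length, n_perm = n_perm,
                               cutoff = cutoff, test = test,
                               within = within)),
            class = "fdr_study")
}

#' @export
print.fdr_study <- function(x, ...) {
  p <- x$params
  cat(sprintf("FDR simulation study: %d replicates (%s bp genome, %d peaks, %gx enrichment, %s reads/sample, %d permutations)\n",
              p$n_rep,
              format(p$genome_length, big.mark = ",", scientific = FALSE),
              p$n_peaks,
              p$enrichment, format(p$depth, big.mark = ","), p$n_perm))
  cat(sprintf("  target FDR:        %.3g\n", x$fdr_level))
  cat(sprintf("  mean realized FDP: %.4f (MC se %.4f)\n",
              x$mean_fdp, x$se_fdp))
  cat(sprintf("  mean sensitivity:  %.3f\n", x$mean_sensitivity))
  invisible(x)
}
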