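# Independent brute-force oracles.  These recompute results by direct
# enumeration (per-position interval stabbing, all-pairs scans, double
# loops) and are deliberately kept free of the package's own algorithms.

# Per-position interval-stabbing coverage of extended reads on one
# chromosome of length L.
oracle_coverage <- function(rs, L, fragment_length,
                            strand_mode = "minimum") {
  ext <- pmax(fragment_length, rs$read_length)
  fwd <- rs$strand == "+"
  s <- ifelse(fwd, rs$pos, rs$pos + rs$read_length - ext)
  e <- s + ext - 1
  count_at <- function(i, sel) sum(sel & s <= i & i <= e)
  f <- vapply(seq_len(L), count_at, numeric(1), sel = fwd)
  r <- vapply(seq_len(L), count_at, numeric(1), sel = !fwd)
  switch(strand_mode,
         minimum = pmin(f, r), forward = f, reverse = r, sum = f + r)
}

# All-pairs edge-distance matching.
oracle_overlap <- function(a, b, within) {
  vapply(seq_len(nrow(a)), function(i) {
    hit <- FALSE
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      gap <- if (b$start[j] > a$end[i]) b$start[j] - a$end[i] - 1
        else if (a$start[i] > b$end[j]) a$start[i] - b$end[j] - 1
        else 0
      if (gap <= within) hit <- TRUE
    }
    hit
  }, logical(1))
}

# Double-loop permutation FDR threshold: for every distinct observed score
# t (ascending), FDR(t) = mean_p #{null >= t} / #{obs >= t}; monotonize by
# the running minimum; return the smallest t controlling the level.
oracle_fdr_threshold <- function(obs, null_lists, level) {
  cand <- sort(unique(obs))
  best <- Inf
  running_min <- Inf
  for (t in cand) {
    tot <- 0
    for (v in null_lists) {
      cnt <- 0
      for (x in v) if (x >= t) cnt <- cnt + 1
      tot <- tot + cnt
    }
    fdr <- min(1, (tot / length(null_lists)) / sum(obs >= t))
    running_min <- min(running_min, fdr)
    if (running_min <= level && !is.finite(best)) best <- t
  }
  list(threshold = best,
       n_significant = if (is.finite(best)) sum(obs >= best) else 0L)
}

# All-pairs signed distances from region summits to strand-oriented gene
# starts.
oracle_distances <- function(regions, feats) {
  out <- NULL
  for (i in seq_len(nrow(regions))) for (j in seq_len(nrow(feats))) {
    if (regions$chrom[i] != feats$chrom[j]) next
    d <- if (feats$strand[j] == "+") regions$pos_max[i] - feats$start[j]
      else feats$start[j] - regions$pos_max[i]
    out <- rbind(out, data.frame(region = i, id = feats$id[j],
                                 distance = d))
  }
  out
}
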