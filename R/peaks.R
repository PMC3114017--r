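#' Call candidate enriched regions
#'
#' Candidate peaks are maximal runs of positions whose score is strictly
#' greater than `cutoff`.  Runs on the same chromosome separated by less
#' than `merge_distance` bp (gap measured exclusively between closest
#' edges) are merged transitively.  Each region carries the maximum score
#' inside it -- the test statistic later compared against the permutation
#' null -- and the leftmost position attaining it.
#'
#' @param scores a score `genome_track` (see [enrichment_score()]).
#' @param cutoff candidate score cutoff; positions with `t_i > cutoff`
#'   seed regions.
#' @param merge_distance gaps of `1 .. merge_distance - 1` bp between runs
#'   are bridged (default 100).
#' @return A `data.frame` with columns `chrom`, `start`, `end` (1-based,
#'   closed), `t_max`, `pos_max`, sorted by chromosome then start.
#' @export
call_candidate_regions <- function(scores, cutoff, merge_distance = 100) {
  stopifnot_scalar_number(cutoff, "cutoff")
  stopifnot_scalar_number(merge_distance, "merge_distance")
  if (merge_distance < 0) stop("merge_distance must be >= 0", call. = FALSE)
  out <- vector("list", length(scores))
  for (ci in seq_along(scores)) {
    chrom <- names(scores)[ci]
    t <- scores[[ci]]
    r <- rle(t > cutoff)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values)
    if (!length(hit)) next
    s <- starts[hit]; e <- ends[hit]
    # transitive merge of runs with sub-threshold gaps < merge_distance
    if (length(s) > 1L) {
      gap <- s[-1L] - e[-length(e)] - 1L
      grp <- cumsum(c(0L, as.integer(gap >= merge_distance)))
      s <- as.integer(tapply(s, grp, min))
      e <- as.integer(tapply(e, grp, max))
    }
    tm <- numeric(length(s)); pm <- integer(length(s))
    for (j in seq_along(s)) {
      seg <- t[s[j]:e[j]]
      w <- which.max(seg)           # leftmost maximum
      tm[j] <- seg[w]
      pm[j] <- s[j] + w - 1L
    }
    out[[ci]] <- data.frame(chrom = chrom, start = s, end = e,
                            t_max = tm, pos_max = pm,
                            stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), t_max = numeric(),
                      pos_max = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Match regions between two region lists
#'
#' For each region in `a`, reports whether some region in `b` lies within
#' `within` bp: the gap between closest edges, with overlapping regions
#' counting as distance 0.  Used, e.g., to compare called regions against
#' a gold standard or planted truth.
#'
#' @param a,b region `data.frame`s with columns `chrom`, `start`, `end`.
#' @param within maximum edge-to-edge gap in bp (default 250).
#' @return A logical vector along the rows of `a`.
#' @export
region_overlap <- function(a, b, within = 250) {
  stopifnot_scalar_number(within, "within")
  matched <- logical(nrow(a))
  if (nrow(a) == 0L || nrow(b) == 0L) return(matched)
  bs <- split(seq_len(nrow(b)), b$chrom)
  for (i in seq_len(nrow(a))) {
    j <- bs[[a$chrom[i]]]
    if (is.null(j)) next
    gap <- pmax(0, pmax(b$start[j] - a$end[i], a$start[i] - b$end[j]) - 1)
    matched[i] <- any(gap <= within)
  }
  matched
}
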