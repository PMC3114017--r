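#' Distances between region summits and gene starts
#'
#' For proteins that bind preferentially near promoters, the distribution
#' of distances between enriched regions and gene start positions is a
#' useful quality check: a sensible experiment shows enrichment at the
#' expected positions (e.g. promoters).  Distances are signed in each
#' gene's strand-oriented frame: negative = upstream of the gene start,
#' positive = downstream.  The region is anchored at `pos_max`, the
#' position of its maximum score (the binding-evidence summit).
#'
#' @param regions region `data.frame` with columns `chrom`, `pos_max`.
#' @param feats feature `data.frame` from [read_features()] (columns
#'   `chrom`, `start`, `strand`, `id`).
#' @return A `data.frame` with one row per same-chromosome region/feature
#'   pair: `region` (row index into `regions`), `chrom`, `pos_max`, `id`,
#'   `distance` (bp, signed) and `nearest` (logical; `TRUE` for each
#'   region's smallest absolute distance, leftmost feature on ties).  The
#'   full `distance` column is the multiset to histogram for QC.
#' @export
distance_to_starts <- function(regions, feats) {
  out <- list()
  if (nrow(regions) && nrow(feats)) {
    fs <- split(seq_len(nrow(feats)), feats$chrom)
    for (i in seq_len(nrow(regions))) {
      j <- fs[[regions$chrom[i]]]
      if (is.null(j)) next
      d <- ifelse(feats$strand[j] == "+",
                  regions$pos_max[i] - feats$start[j],
                  feats$start[j] - regions$pos_max[i])
      nearest <- logical(length(j))
      nearest[which.min(abs(d))] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        region = i, chrom = regions$chrom[i],
        pos_max = regions$pos_max[i], id = feats$id[j],
        distance = d, nearest = nearest, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(region = integer(), chrom = character(),
                      pos_max = integer(), id = character(),
                      distance = numeric(), nearest = logical(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign regions to target genes
#'
#' A gene is a target of a region when the region summit (`pos_max`) lies
#' within the gene's promoter-proximal window: from `upstream_bp` upstream
#' to `downstream_bp` downstream of the gene start, in the gene's
#' strand-oriented frame (window closed at both edges).  The default
#' window, 3 kb upstream / 1 kb downstream, is the conventional
#' peak-to-gene assignment window for promoter-binding transcription
#' factors.
#'
#' @inheritParams distance_to_starts
#' @param upstream_bp,downstream_bp window extent in bp around the gene
#'   start.
#' @return A `data.frame` with columns `region`, `chrom`, `pos_max`, `id`,
#'   `distance`; one row per (region, target gene) pair, possibly several
#'   genes per region and none for regions with no gene in range.
#' @export
assign_targets <- function(regions, feats, upstream_bp = 3000,
                           downstream_bp = 1000) {
  d <- distance_to_starts(regions, feats)
  res <- d[d$distance >= -upstream_bp & d$distance <= downstream_bp,
           c("region", "chrom", "pos_max", "id", "distance"),
           drop = FALSE]
  rownames(res) <- NULL
  res
}
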