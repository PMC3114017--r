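#' Strand-specific extended-read coverage
#'
#' Each uniquely mapped read is virtually extended to the average length of
#' the DNA fragments subjected to sequencing, directionally from its 5'
#' end: a `+` read occupies `[pos, pos + fragment_length - 1]`, a `-` read
#' occupies `[pos + read_length - fragment_length, pos + read_length - 1]`
#' (both clipped to the chromosome).  The number of extended reads
#' overlapping each nucleotide position is then counted for each strand
#' independently.
#'
#' @param rs a [read_set()] (apply [filter_chromosomes()] first).
#' @param genome a [genome_spec()].
#' @param fragment_length average sequenced-fragment length in bp.  Must be
#'   supplied by the user; reads longer than `fragment_length` keep their
#'   own footprint (with a warning).
#' @return A list with elements `forward` and `reverse`, each a
#'   `genome_track` of integer hit counts.
#' @export
strand_counts <- function(rs, genome, fragment_length) {
  stopifnot_scalar_number(fragment_length, "fragment_length", positive = TRUE)
  unknown <- setdiff(unique(rs$chrom), names(genome$chroms))
  if (length(unknown))
    stop(sprintf("reads map to chromosome(s) absent from the genome: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (nrow(rs) && any(rs$read_length > fragment_length))
    warning("some reads are longer than fragment_length; ",
            "their extension equals their own footprint", call. = FALSE)
  ext <- pmax(fragment_length, rs$read_length)
  is_fwd <- rs$strand == "+"
  start <- ifelse(is_fwd, rs$pos, rs$pos + rs$read_length - ext)
  end <- start + ext - 1

  one_strand <- function(sel) {
    out <- vector("list", length(genome$chroms))
    names(out) <- names(genome$chroms)
    for (chrom in names(genome$chroms)) {
      L <- genome$chroms[[chrom]]
      i <- which(sel & rs$chrom == chrom)
      s <- pmax(start[i], 1)
      e <- pmin(end[i], L)
      ok <- s <= e
      out[[chrom]] <- as.integer(
        IRanges::coverage(IRanges::IRanges(s[ok], e[ok]), width = L))
    }
    out
  }
  meta <- list(fragment_length = fragment_length, label = read_label(rs))
  list(forward = new_track(one_strand(is_fwd), "coverage",
                           c(meta, strand_mode = "forward")),
       reverse = new_track(one_strand(!is_fwd), "coverage",
                           c(meta, strand_mode = "reverse")))
}

#' Per-nucleotide hit counts from extended reads
#'
#' Computes strand-specific extended-read coverage (see [strand_counts()])
#' and combines the two strands.  The default, the per-position
#' \emph{minimum} across strands, encodes the expectation that fragments
#' from a genuinely protein-bound site are sequenced from both ends and so
#' support the site on both strands; read stacks present on a single
#' strand only -- the signature of PCR duplicate artifacts -- contribute
#' nothing where the opposite strand has no coverage.
#'
#' @inheritParams strand_counts
#' @param strand_mode how to combine the strand-specific counts:
#'   `"minimum"` (default), `"forward"`, `"reverse"`, or `"sum"` (total
#'   coverage, merging the information of both strands).
#' @return A `genome_track` of integer hit counts, one vector per
#'   chromosome.
#' @examples
#' g <- genome_spec(c(chr1 = 60))
#' rs <- read_set(c("chr1", "chr1"), c(10L, 25L), c("+", "-"),
#'                c(5L, 5L), label = "IP")
#' x <- extend_and_count(rs, g, fragment_length = 20)
#' which(x$chr1 > 0)  # positions 10..29: both strands support the site
#' @export
extend_and_count <- function(rs, genome, fragment_length,
                             strand_mode = c("minimum", "forward",
                                             "reverse", "sum")) {
  strand_mode <- match.arg(strand_mode)
  sc <- strand_counts(rs, genome, fragment_length)
  meta <- list(fragment_length = fragment_length,
               strand_mode = strand_mode, label = read_label(rs))
  comb <- switch(strand_mode,
                 minimum = function(f, r) pmin(f, r),
                 forward = function(f, r) f,
                 reverse = function(f, r) r,
                 sum = function(f, r) f + r)
  track_map2(sc$forward, sc$reverse, comb, kind = "coverage", meta = meta)
}
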