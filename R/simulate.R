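#' Simulate a ChIP-seq experiment with planted enriched regions
#'
#' Generates a matched control/IP pair of read sets with known ground
#' truth, for validating the pipeline and calibrating error rates.  Both
#' samples draw `depth` background fragments uniformly over the genome;
#' the IP sample additionally draws fragments over each true region at a
#' start density of `(enrichment - 1)` times the background density over a
#' window widened by one fragment length, so that expected fragment
#' coverage is uniformly `enrichment`-fold across the region.  Every
#' fragment yields a single read of `read_length` bp from one of its two
#' ends, chosen uniformly: the left end gives a `+` read, the right end a
#' `-` read.  True binding sites are therefore supported on both strands,
#' the pattern the strand-minimum counting rule rewards.
#'
#' When `true_regions` is not supplied, `n_peaks` regions are planted, one
#' per equal-width chromosome bin, uniformly within the bin interior (kept
#' clear of bin and chromosome edges by `peak_halfwidth + fragment_length`
#' bp), guaranteeing well-separated, in-bounds truth regions.
#'
#' @param genome a [genome_spec()], or a single number: the length of a
#'   one-chromosome (`"chr1"`) genome.
#' @param n_peaks number of regions to plant (ignored when `true_regions`
#'   is given).
#' @param enrichment fold enrichment of IP fragment coverage inside true
#'   regions (> 1).
#' @param peak_halfwidth half-width of each true region in bp.
#' @param depth background fragments (= reads) drawn per sample.
#' @param fragment_length,read_length fragment and read lengths in bp.
#' @param true_regions optional `data.frame` with columns `chrom`,
#'   `center`, `halfwidth`, `enrichment`, overriding automatic placement.
#' @param seed RNG seed; the same seed reproduces the read sets exactly.
#' @return A `chipseq_sim`: list with `control` and `ip` ([read_set()]s)
#'   and `truth` (list: `genome`, `regions` -- a `data.frame` with
#'   `chrom`, `center`, `halfwidth`, `start`, `end`, `enrichment` --,
#'   `depth`, `fragment_length`, `read_length`, `background_rate` in
#'   fragments/bp, `seed`).
#' @export
simulate_chipseq <- function(genome, n_peaks = 20, enrichment = 8,
                             peak_halfwidth = 150, depth = 50000,
                             fragment_length = 150, read_length = 36,
                             true_regions = NULL, seed = 1) {
  if (!inherits(genome, "genome_spec")) {
    stopifnot_scalar_number(genome, "genome", positive = TRUE)
    genome <- genome_spec(c(chr1 = genome))
  }
  stopifnot_scalar_number(depth, "depth", positive = TRUE)
  stopifnot_scalar_number(enrichment, "enrichment", positive = TRUE)
  if (read_length > fragment_length)
    stop("read_length must not exceed fragment_length", call. = FALSE)
  lens <- genome$chroms
  total_len <- sum(as.numeric(lens))

  with_seed(seed, {
    if (is.null(true_regions)) {
      true_regions <- place_peaks(lens, n_peaks, peak_halfwidth,
                                  fragment_length)
      true_regions$enrichment <- rep(enrichment, nrow(true_regions))
    }
    regions <- true_regions
    if (nrow(regions)) {
      L <- lens[regions$chrom]
      if (anyNA(L))
        stop("true region on a chromosome absent from the genome",
             call. = FALSE)
      if (any(2 * regions$halfwidth + 1 > L))
        stop("true region wider than its chromosome", call. = FALSE)
      if (any(regions$enrichment <= 1))
        stop("enrichment factors must exceed 1", call. = FALSE)
      regions$start <- pmax(1L, as.integer(regions$center - regions$halfwidth))
      regions$end <- pmin(as.integer(L),
                          as.integer(regions$center + regions$halfwidth))
    } else {
      regions$start <- integer(0); regions$end <- integer(0)
    }

    frag_density <- depth / total_len   # background fragment starts per bp

    sample_background <- function() {
      n_chrom <- if (length(lens) == 1L) stats::setNames(depth, names(lens))
        else stats::setNames(
          as.vector(stats::rmultinom(1, depth, as.numeric(lens) / total_len)),
          names(lens))
      chrom <- rep(names(n_chrom), n_chrom)
      fs <- unlist(lapply(names(n_chrom), function(cn) {
        hi <- max(lens[[cn]] - fragment_length + 1L, 1L)
        sample.int(hi, n_chrom[[cn]], replace = TRUE)
      }), use.names = FALSE)
      list(chrom = chrom, frag_start = fs)
    }

    reads_from_fragments <- function(chrom, frag_start, label) {
      left <- stats::runif(length(frag_start)) < 0.5
      pos <- ifelse(left, frag_start,
                    frag_start + fragment_length - read_length)
      read_set(chrom, pos, ifelse(left, "+", "-"),
               rep(read_length, length(pos)), label = label)
    }

    bg_c <- sample_background()
    control <- reads_from_fragments(bg_c$chrom, bg_c$frag_start, "control")

    bg_i <- sample_background()
    ex_chrom <- character(0); ex_start <- integer(0)
    for (k in seq_len(nrow(regions))) {
      win_lo <- regions$start[k] - fragment_length + 1L
      win_hi <- regions$end[k]
      lam <- (regions$enrichment[k] - 1) * frag_density *
        (win_hi - win_lo + 1L)
      n_extra <- stats::rpois(1, lam)
      if (n_extra > 0) {
        fs <- win_lo + sample.int(win_hi - win_lo + 1L, n_extra,
                                  replace = TRUE) - 1L
        fs <- pmin(pmax(fs, 1L), lens[[regions$chrom[k]]] -
                     fragment_length + 1L)
        ex_chrom <- c(ex_chrom, rep(regions$chrom[k], n_extra))
        ex_start <- c(ex_start, fs)
      }
    }
    ip <- reads_from_fragments(c(bg_i$chrom, ex_chrom),
                               c(bg_i$frag_start, ex_start), "IP")

    structure(list(control = control, ip = ip,
                   truth = list(genome = genome, regions = regions,
                                depth = depth,
                                fragment_length = fragment_length,
                                read_length = read_length,
                                background_rate = frag_density,
                                seed = seed)),
              class = "chipseq_sim")
  })
}

# Deterministic peak placement: one peak per equal-width bin, uniform
# within the bin interior, clear of edges by halfwidth + fragment_length.
place_peaks <- function(lens, n_peaks, halfwidth, fragment_length) {
  if (n_peaks == 0)
    return(data.frame(chrom = character(), center = integer(),
                      halfwidth = integer(), stringsAsFactors = FALSE))
  total <- sum(as.numeric(lens))
  alloc <- diff(c(0, round(cumsum(as.numeric(lens) / total * n_peaks))))
  margin <- halfwidth + fragment_length
  chroms <- character(0); centers <- integer(0)
  for (ci in seq_along(lens)) {
    k <- alloc[ci]
    if (k == 0) next
    L <- lens[[ci]]
    bin <- L / k
    if (bin < 2 * margin + 2)
      stop("too many peaks for the chromosome length", call. = FALSE)
    lo <- floor((seq_len(k) - 1) * bin) + margin + 1
    hi <- floor(seq_len(k) * bin) - margin
    centers <- c(centers, as.integer(lo + floor(stats::runif(k) *
                                                  (hi - lo + 1))))
    chroms <- c(chroms, rep(names(lens)[ci], k))
  }
  data.frame(chrom = chroms, center = centers,
             halfwidth = as.integer(halfwidth), stringsAsFactors = FALSE)
}

#' @export
print.chipseq_sim <- function(x, ...) {
  cat(sprintf("<chipseq_sim> %s control / %s IP reads, %d true region(s), seed %s\n",
              format(nrow(x$control), big.mark = ","),
              format(nrow(x$ip), big.mark = ","),
              nrow(x$truth$regions), format(x$truth$seed)))
  invisible(x)
}

#' Inject PCR-duplicate artifacts into a read set
#'
#' Emulates in-silico PCR over-amplification: `n_reads` distinct reads are
#' chosen uniformly without replacement and `amplification` exact copies
#' of each are appended.  The number of distinct reads is unchanged, so
#' the duplicate percentage rises from `100 * (1 - u/m)` to
#' `100 * (1 - u/(m + n_reads * amplification))`.
#'
#' @param rs a [read_set()] with at least `n_reads` distinct reads.
#' @param n_reads number of distinct reads to amplify (default 2000).
#' @param amplification copies appended per chosen read (default 100).
#' @param seed RNG seed for the read choice.
#' @return The augmented `read_set`, with `n_reads * amplification` more
#'   rows than `rs`.
#' @export
inject_pcr_duplicates <- function(rs, n_reads = 2000, amplification = 100,
                                  seed = NULL) {
  if (n_reads == 0) return(rs)
  uniq <- which(!duplicated(read_key(rs)))
  if (n_reads > length(uniq))
    stop(sprintf("asked to amplify %d reads but only %d distinct reads exist",
                 n_reads, length(uniq)), call. = FALSE)
  chosen <- with_seed(seed, sample(uniq, n_reads))
  copies <- as.data.frame(rs)[rep(chosen, each = amplification), ,
                              drop = FALSE]
  as_read_set(rbind(as.data.frame(rs), copies), label = read_label(rs))
}

#' Inject a one-strand duplicate stack
#'
#' Appends `copies` identical reads at a single position and strand: the
#' adversarial PCR artifact that coverage rules must neutralize.  Under
#' `strand_mode = "minimum"` the stack contributes nothing wherever the
#' opposite strand has no coverage, since a one-strand pile cannot raise
#' the cross-strand minimum above the opposite strand's level.
#'
#' @param rs a [read_set()].
#' @param chrom,pos,strand,read_length the stacked read.
#' @param copies number of identical copies to append.
#' @return The augmented `read_set`.
#' @export
inject_onesided_stack <- function(rs, chrom, pos, strand, copies,
                                  read_length = 36L) {
  if (copies == 0) return(rs)
  stack <- data.frame(chrom = rep(chrom, copies),
                      pos = rep(as.integer(pos), copies),
                      strand = rep(strand, copies),
                      read_length = rep(as.integer(read_length), copies),
                      n_loc = rep(1L, copies), stringsAsFactors = FALSE)
  validate_read_set(stack)
  as_read_set(rbind(as.data.frame(rs), stack), label = read_label(rs))
}
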