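#' Construct a set of mapped reads
#'
#' A read set is the package's representation of one sequencing sample after
#' mapping: one row per read with its chromosome, 1-based leftmost coordinate
#' on the forward genome strand, strand, read length and the number of
#' genomic locations the read maps to.
#'
#' `pos` is the leftmost forward-strand coordinate for reads on either
#' strand, as short-read mappers report it; the 5' end of a minus-strand
#' read is therefore `pos + read_length - 1`.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based leftmost mapping coordinates (bp).
#' @param strand character vector of `"+"` / `"-"`.
#' @param read_length integer vector of read lengths (bp).
#' @param n_loc integer vector: number of genomic locations each read maps
#'   to (1 = uniquely mapped).
#' @param label sample label, typically `"control"` or `"IP"`.
#' @return A `read_set`: a `data.frame` with columns `chrom`, `pos`,
#'   `strand`, `read_length`, `n_loc` and a `label` attribute.  The number
#'   of rows is the sample's total mapped-read count used for depth scaling
#'   (see [total_mapped()]).
#' @seealso [read_reads()], [filter_chromosomes()], [duplicate_stats()]
#' @export
read_set <- function(chrom = character(), pos = integer(),
                     strand = character(), read_length = integer(),
                     n_loc = 1L, label = NA_character_) {
  n <- length(pos)
  df <- data.frame(chrom = as.character(chrom),
                   pos = as.integer(pos),
                   strand = as.character(strand),
                   read_length = as.integer(read_length),
                   n_loc = as.integer(rep_len(n_loc, n)),
                   stringsAsFactors = FALSE)
  validate_read_set(df)
  structure(df, label = label, class = c("read_set", "data.frame"))
}

validate_read_set <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  bad <- which(!(df$strand %in% c("+", "-")))
  if (length(bad))
    stop(sprintf("invalid strand symbol '%s' (row %d); expected '+' or '-'",
                 df$strand[bad[1]], bad[1]), call. = FALSE)
  if (anyNA(df$pos) || any(df$pos < 1L))
    stop("read positions must be integers >= 1", call. = FALSE)
  if (anyNA(df$read_length) || any(df$read_length < 1L))
    stop("read lengths must be integers >= 1", call. = FALSE)
  if (anyNA(df$n_loc) || any(df$n_loc < 1L))
    stop("n_loc must be integers >= 1", call. = FALSE)
  invisible(df)
}

as_read_set <- function(df, label = NA_character_) {
  rownames(df) <- NULL
  structure(df[c("chrom", "pos", "strand", "read_length", "n_loc")],
            label = label, class = c("read_set", "data.frame"))
}

#' Number of mapped reads in a read set
#'
#' The per-sample read total used for depth scaling: the number of reads
#' retained after any filtering.
#'
#' @param rs a [read_set()].
#' @return Integer count.
#' @export
total_mapped <- function(rs) nrow(rs)

#' Sample label of a read set
#' @param rs a [read_set()].
#' @return The label character scalar (possibly `NA`).
#' @export
read_label <- function(rs) attr(rs, "label")

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set%s> %s reads on %d chromosome(s)\n",
              if (is.na(read_label(x))) "" else paste0(": ", read_label(x)),
              format(nrow(x), big.mark = ","),
              length(unique(x$chrom))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Describe the genome under analysis
#'
#' @param lengths named numeric vector of chromosome lengths in bp
#'   (names are chromosome names), or a two-column `data.frame`
#'   (name, length).
#' @param exclude character vector of chromosome names to drop from the
#'   analysis (e.g. organellar genomes such as `"chrC"`/`"chrM"`, whose
#'   reads would otherwise distort the coverage distribution).
#' @return A `genome_spec`: list with elements `chroms` (named integer
#'   lengths, excluded names removed) and `excluded`.
#' @export
genome_spec <- function(lengths, exclude = character()) {
  if (is.data.frame(lengths)) {
    nm <- as.character(lengths[[1]])
    lengths <- stats::setNames(as.numeric(lengths[[2]]), nm)
  }
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chromosome lengths must be named", call. = FALSE)
  if (anyDuplicated(names(lengths)))
    stop("duplicated chromosome names", call. = FALSE)
  if (any(!is.finite(lengths)) || any(lengths < 1))
    stop("chromosome lengths must be positive", call. = FALSE)
  keep <- !(names(lengths) %in% exclude)
  structure(list(chroms = vapply(lengths[keep], as.integer, integer(1)),
                 excluded = as.character(exclude)),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> %d chromosome(s), %s bp total",
              length(x$chroms), format(sum(as.numeric(x$chroms)),
                                       big.mark = ",")))
  if (length(x$excluded))
    cat("; excluded:", paste(x$excluded, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Drop reads on excluded or unknown chromosomes
#'
#' Reads mapping to chromosomes listed in `genome$excluded`, or to
#' chromosomes absent from `genome$chroms`, are removed; reads landing
#' beyond the chromosome end are removed as well.
#'
#' @param rs a [read_set()].
#' @param genome a [genome_spec()].
#' @return The filtered `read_set`; [total_mapped()] reflects the retained
#'   reads.
#' @export
filter_chromosomes <- function(rs, genome) {
  keep <- rs$chrom %in% names(genome$chroms)
  if (any(keep)) {
    lens <- genome$chroms[rs$chrom[keep]]
    keep[keep] <- rs$pos[keep] <= lens
  }
  as_read_set(rs[keep, , drop = FALSE], label = read_label(rs))
}

#' Duplicate-read statistics for a sample
#'
#' A read is a duplicate when another read in the sample is identical in
#' chromosome, position, strand and read length.  High duplicate
#' percentages indicate PCR over-amplification during library preparation
#' and are a standard ChIP-seq quality measure worth reporting for every
#' library.
#'
#' @param rs a non-empty [read_set()].
#' @return A `duplicate_report`: list with `n_mapped`, `n_unique` (reads
#'   distinct by chrom/pos/strand/read_length) and `pct_duplicated`
#'   (`100 * (1 - n_unique / n_mapped)`, stored exactly, displayed to the
#'   nearest percent).
#' @examples
#' rs <- read_set(rep("chr1", 4), rep(100L, 4), rep("+", 4), rep(36L, 4))
#' duplicate_stats(rs)  # 4 copies of one read: 75% duplicated
#' @export
duplicate_stats <- function(rs) {
  if (nrow(rs) == 0L)
    stop("duplicate percentage is undefined for an empty read set",
         call. = FALSE)
  n_mapped <- nrow(rs)
  n_unique <- sum(!duplicated(read_key(rs)))
  structure(list(n_mapped = n_mapped, n_unique = n_unique,
                 pct_duplicated = dup_pct(n_mapped, n_unique),
                 label = read_label(rs)),
            class = "duplicate_report")
}

# One string key per read identifying the molecule: two reads of different
# lengths at the same position are distinct.
read_key <- function(rs) {
  paste(rs$chrom, rs$pos, rs$strand, rs$read_length, sep = "\r")
}

dup_pct <- function(n_mapped, n_unique) 100 * (1 - n_unique / n_mapped)

#' @export
print.duplicate_report <- function(x, ...) {
  cat(sprintf("<duplicate_report%s> mapped: %s  unique: %s  duplicated: %d%%\n",
              if (is.null(x$label) || is.na(x$label)) ""
              else paste0(": ", x$label),
              format(x$n_mapped, big.mark = ","),
              format(x$n_unique, big.mark = ","),
              round(x$pct_duplicated)))
  invisible(x)
}
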