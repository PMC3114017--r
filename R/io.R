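#' Read a mapped-read table
#'
#' Parses plain-text tables of mapped reads in one of three dialects and
#' returns a [read_set()].  Any tabular format carrying, for each read, the
#' chromosome, 1-based location, strand, read length and mapping
#' multiplicity can be adapted through `columns`.
#'
#' Dialects:
#' \describe{
#'   \item{`tsv`}{five tab-separated columns, no header:
#'     chrom, pos (1-based), strand, read_length, n_loc.}
#'   \item{`soap`}{SOAPv2 alignment text; fields 4 (hit count),
#'     6 (read length), 7 (strand), 8 (chromosome) and 9 (1-based
#'     location) are used.}
#'   \item{`bed`}{BED6; `pos = start + 1` (BED starts are 0-based),
#'     `read_length = end - start`, the score column carries the mapping
#'     multiplicity (`.` or an empty score means 1).}
#' }
#'
#' @param path file to read.
#' @param dialect one of `"tsv"`, `"soap"`, `"bed"`.
#' @param unique_only drop reads mapping to more than one genomic location
#'   (default `TRUE`; only uniquely mapped reads enter the coverage
#'   computation).
#' @param columns optional named integer vector overriding the column
#'   indices of a `tsv`-like file; names among `chrom`, `pos`, `strand`,
#'   `read_length`, `n_loc`.
#' @param label sample label stored on the result.
#' @return A [read_set()].
#' @export
read_reads <- function(path, dialect = c("tsv", "soap", "bed"),
                       unique_only = TRUE, columns = NULL,
                       label = NA_character_) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  keep <- !grepl("^(#|track |browser )", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L)
    return(read_set(label = label))
  split_re <- if (dialect == "bed") "[ \t]+" else "\t"
  fields <- strsplit(lines[idx], split_re)

  cols <- switch(dialect,
    tsv  = c(chrom = 1L, pos = 2L, strand = 3L, read_length = 4L, n_loc = 5L),
    soap = c(chrom = 8L, pos = 9L, strand = 7L, read_length = 6L, n_loc = 4L),
    bed  = c(chrom = 1L, pos = 2L, strand = 6L, read_length = 3L, n_loc = 5L))
  if (!is.null(columns)) {
    if (dialect != "tsv")
      stop("'columns' remapping is only supported for the tsv dialect",
           call. = FALSE)
    cols[names(columns)] <- as.integer(columns)
  }
  need <- max(cols)
  nf <- lengths(fields)
  if (dialect == "bed") {
    # BED3-BED5 rows lack a strand column and cannot describe a read
    need <- 6L
  }
  bad <- which(nf < need)
  if (length(bad))
    stop(sprintf("malformed row at line %d of '%s': %d field(s), expected >= %d",
                 idx[bad[1]], path, nf[bad[1]], need), call. = FALSE)

  pick <- function(j) vapply(fields, `[[`, character(1), j)
  chrom <- pick(cols[["chrom"]])
  strand <- pick(cols[["strand"]])
  badstr <- which(!(strand %in% c("+", "-")))
  if (length(badstr))
    stop(sprintf("unknown strand symbol '%s' at line %d of '%s'",
                 strand[badstr[1]], idx[badstr[1]], path), call. = FALSE)

  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(pick(j)))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("malformed %s at line %d of '%s'",
                   what, idx[bad[1]], path), call. = FALSE)
    v
  }
  if (dialect == "bed") {
    start0 <- num(2L, "start")
    end <- num(3L, "end")
    pos <- start0 + 1
    read_length <- end - start0
    score <- pick(5L)
    n_loc <- ifelse(score %in% c(".", ""), 1,
                    suppressWarnings(as.numeric(score)))
    n_loc[is.na(n_loc) | n_loc < 1] <- 1
  } else {
    pos <- num(cols[["pos"]], "position")
    read_length <- num(cols[["read_length"]], "read length")
    n_loc <- num(cols[["n_loc"]], "mapping count")
  }

  rs <- read_set(chrom, pos, strand, read_length, n_loc, label = label)
  if (unique_only)
    rs <- as_read_set(rs[rs$n_loc == 1L, , drop = FALSE], label = label)
  rs
}

#' Write a read set
#'
#' Inverse of [read_reads()] for the `tsv` and `bed` dialects.
#'
#' @param rs a [read_set()].
#' @param path output file.
#' @param dialect `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_reads <- function(rs, path, dialect = c("tsv", "bed")) {
  dialect <- match.arg(dialect)
  lines <- if (nrow(rs) == 0L) character() else switch(dialect,
    tsv = sprintf("%s\t%d\t%s\t%d\t%d",
                  rs$chrom, rs$pos, rs$strand, rs$read_length, rs$n_loc),
    bed = sprintf("%s\t%d\t%d\tread_%d\t%d\t%s",
                  rs$chrom, rs$pos - 1L, rs$pos - 1L + rs$read_length,
                  seq_len(nrow(rs)), rs$n_loc, rs$strand))
  writeLines(lines, path)
  invisible(path)
}

#' Read a chromosome-length table
#'
#' Two tab-separated columns, no header: chromosome name, length in bp.
#'
#' @param path file to read.
#' @param exclude chromosome names to drop (see [genome_spec()]).
#' @return A [genome_spec()].
#' @export
read_genome <- function(path, exclude = character()) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("name", "length"),
                          colClasses = c("character", "numeric"))
  genome_spec(stats::setNames(df$length, df$name), exclude = exclude)
}

#' Read gene-start features
#'
#' Loads gene start positions used by [distance_to_starts()] and
#' [assign_targets()].  For GFF3 input, rows of type `gene` are used and
#' the strand-oriented gene start is taken: the `start` coordinate for
#' `+` genes and the `end` coordinate for `-` genes.
#'
#' @param path file to read.
#' @param format `"gff3"` or `"tsv"` (four tab-separated columns, no
#'   header: chrom, start (1-based), strand, id).
#' @return A `data.frame` with columns `chrom`, `start`, `strand`, `id`.
#' @export
read_features <- function(path, format = c("gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "gff3") {
    g <- rtracklayer::readGFF(path)
    g <- g[g$type == "gene", , drop = FALSE]
    id <- if (!is.null(g$ID)) as.character(g$ID) else as.character(g$Name)
    id[is.na(id)] <- sprintf("gene_%d", which(is.na(id)))
    strand <- as.character(g$strand)
    feats <- data.frame(chrom = as.character(g$seqid),
                        start = ifelse(strand == "-", g$end, g$start),
                        strand = strand,
                        id = id, stringsAsFactors = FALSE)
  } else {
    feats <- utils::read.table(path, sep = "\t", header = FALSE,
                               col.names = c("chrom", "start", "strand", "id"),
                               colClasses = c("character", "integer",
                                              "character", "character"))
  }
  if (any(feats$start < 1L))
    stop("feature start positions must be >= 1", call. = FALSE)
  if (any(!feats$strand %in% c("+", "-")))
    stop("feature strands must be '+' or '-'", call. = FALSE)
  feats
}

#' Write a per-position track as UCSC wiggle
#'
#' Emits a `variableStep` wiggle file (span 1, 1-based coordinates) with
#' one declaration line per chromosome, writing only positions whose value
#' is at least `min_emit` to keep files browser-sized.
#'
#' @param track a `genome_track` (e.g. an enrichment-score track).
#' @param path output file.
#' @param min_emit smallest value emitted (default `0.1`).
#' @param name track name written to the `track` header line.
#' @return `path`, invisibly.
#' @export
write_wig <- function(track, path, min_emit = 0.1, name = "permpeaks") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=wiggle_0 name=\"%s\"", name), con)
  for (chrom in names(track)) {
    writeLines(sprintf("variableStep chrom=%s span=1", chrom), con)
    v <- track[[chrom]]
    i <- which(v >= min_emit)
    if (length(i))
      writeLines(sprintf("%d %.17g", i, v[i]), con)
  }
  invisible(path)
}

#' Read a variableStep wiggle file
#'
#' Companion parser for [write_wig()], mainly for round-trip checks.
#'
#' @param path file to read.
#' @return A `data.frame` with columns `chrom`, `pos`, `score`.
#' @export
read_wig <- function(path) {
  lines <- readLines(path)
  out <- list(chrom = character(), pos = integer(), score = numeric())
  chrom <- NA_character_
  decl <- grepl("^variableStep", lines)
  chrom_of <- cumsum(decl)
  chrom_names <- sub(".*chrom=(\\S+).*", "\\1", lines[decl])
  data_rows <- !decl & !grepl("^(track|browser|#)", lines) & nzchar(lines)
  if (!any(data_rows))
    return(data.frame(chrom = character(), pos = integer(), score = numeric()))
  parts <- strsplit(lines[data_rows], "[ \t]+")
  data.frame(chrom = chrom_names[chrom_of[data_rows]],
             pos = as.integer(vapply(parts, `[[`, character(1), 1L)),
             score = as.numeric(vapply(parts, `[[`, character(1), 2L)),
             stringsAsFactors = FALSE)
}

#' Write called regions
#'
#' @param regions a region `data.frame` as returned by
#'   [call_candidate_regions()] (columns `chrom`, `start`, `end`, `t_max`,
#'   `pos_max`, optionally `significant`).
#' @param path output file.
#' @param format `"tsv"` (1-based closed intervals, header row) or
#'   `"bed"` (0-based half-open starts per the BED convention, score =
#'   `t_max`).
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    cols <- intersect(c("chrom", "start", "end", "t_max", "pos_max",
                        "significant"), names(regions))
    utils::write.table(regions[, cols, drop = FALSE], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    lines <- if (nrow(regions) == 0L) character() else
      sprintf("%s\t%d\t%d\tregion_%d\t%.17g\t.",
              regions$chrom, regions$start - 1L, regions$end,
              seq_len(nrow(regions)), regions$t_max)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a region table written by [write_regions()]
#'
#' @param path TSV file to read.
#' @return A region `data.frame`.
#' @export
read_regions <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
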