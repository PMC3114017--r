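# Fixture builders shared across the suite.

tiny_genome <- function(lengths = c(chr1 = 1000L), exclude = character()) {
  genome_spec(lengths, exclude = exclude)
}

# A random read set on one chromosome, fully inside [1, L].
random_read_set <- function(n, L = 1000L, read_length = c(5L, 10L),
                            chrom = "chr1", label = NA_character_) {
  rl <- sample(seq(read_length[1], read_length[2]), n, replace = TRUE)
  read_set(chrom = rep(chrom, n),
           pos = sample.int(L - max(rl), n, replace = TRUE),
           strand = sample(c("+", "-"), n, replace = TRUE),
           read_length = rl, label = label)
}

# Wrap per-chromosome numeric vectors as a scaled/score track for tests.
as_track <- function(..., kind = "scaled") {
  vals <- list(...)
  permpeaks:::new_track(vals, kind = kind)
}
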