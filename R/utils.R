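# Internal helpers shared across the package.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.  All user-facing randomness flows through this helper.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}

## ---- per-chromosome track container ------------------------------------

# A genome track is a named list (one element per chromosome) of per-position
# vectors, with metadata kept in attributes.  Used for raw hit counts
# (integer), depth-scaled values, moment-matched IP values and enrichment
# scores (double).
new_track <- function(values, kind, meta = list()) {
  stopifnot(is.list(values), !is.null(names(values)))
  structure(values, kind = kind, meta = meta, class = "genome_track")
}

track_meta <- function(track) attr(track, "meta")

track_kind <- function(track) attr(track, "kind")

# All per-position values of a track as one vector (chromosome order).
track_values <- function(track) {
  unlist(unclass(track), use.names = FALSE)
}

# Apply f chromosome-wise, preserving names and metadata.
track_map <- function(track, f, kind = track_kind(track),
                      meta = track_meta(track)) {
  out <- lapply(unclass(track), f)
  names(out) <- names(track)
  new_track(out, kind = kind, meta = meta)
}

track_map2 <- function(a, b, f, kind, meta = list()) {
  if (!identical(names(a), names(b)))
    stop("tracks cover different chromosome sets", call. = FALSE)
  out <- Map(f, unclass(a), unclass(b))
  names(out) <- names(a)
  new_track(out, kind = kind, meta = meta)
}

# Population (n-denominator) mean and sd over every position of the track.
track_moments <- function(track) {
  n <- 0; s <- 0; s2 <- 0
  for (v in unclass(track)) {
    n <- n + length(v)
    s <- s + sum(as.numeric(v))
    s2 <- s2 + sum(as.numeric(v)^2)
  }
  if (n == 0L) stop("track has no positions", call. = FALSE)
  m <- s / n
  list(mean = m, sd = sqrt(max(s2 / n - m^2, 0)), n_positions = n)
}

#' @export
print.genome_track <- function(x, ...) {
  lens <- vapply(unclass(x), length, integer(1))
  cat(sprintf("<genome_track: %s> %d chromosome(s), %s positions\n",
              track_kind(x), length(x), format(sum(lens), big.mark = ",")))
  meta <- track_meta(x)
  if (length(meta))
    cat("  ", paste(names(meta),
                    vapply(meta, function(m) paste(format(m), collapse = ","),
                           character(1)),
                    sep = "=", collapse = "; "), "\n", sep = "")
  invisible(x)
}
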