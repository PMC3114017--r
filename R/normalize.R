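#' Scale hit counts to a common sequencing depth
#'
#' Transforms raw per-position hit counts to the number of hits per
#' `theta` million mapped reads, removing the effect of variable
#' sequencing depth between samples: `y_i = x_i * theta * 1e6 / total_mapped`.
#'
#' @param track a coverage `genome_track` from [extend_and_count()].
#' @param total_mapped number of mapped reads in the sample the track was
#'   computed from (see [total_mapped()]).
#' @param theta scaling constant; the default 1 reports hits per million
#'   reads.
#' @return A `genome_track` of depth-scaled values.
#' @export
scale_counts <- function(track, total_mapped, theta = 1) {
  stopifnot_scalar_number(theta, "theta", positive = TRUE)
  stopifnot_scalar_number(total_mapped, "total_mapped")
  if (total_mapped < 1)
    stop("total_mapped must be >= 1", call. = FALSE)
  f <- theta * 1e6 / total_mapped
  meta <- c(track_meta(track),
            list(theta = theta, total_mapped = total_mapped))
  track_map(track, function(v) as.numeric(v) * f, kind = "scaled",
            meta = meta)
}

#' Moment-match the IP coverage distribution to the control
#'
#' Depth scaling alone does not make IP and control coverage comparable:
#' the IP library samples preferentially from (true and false positive)
#' bound regions, so its coverage distribution differs in shape as well as
#' depth.  This step normalizes the IP coverage distribution to have the
#' same mean and variance as the control by the method of moments:
#' `y'_i = (y_i - mean_ip) * sd_control / sd_ip + mean_control`.
#'
#' Moments are population (n-denominator) statistics computed jointly over
#' every position of every analyzed chromosome, zeros included.
#'
#' @param ip,control depth-scaled `genome_track`s from [scale_counts()]
#'   covering the same chromosomes.
#' @return A list: `track` (the moment-matched IP `genome_track`) and
#'   `params` (list `mean_control`, `sd_control`, `mean_ip`, `sd_ip`,
#'   `n_positions`).
#' @export
moment_match <- function(ip, control) {
  if (!identical(names(ip), names(control)))
    stop("IP and control tracks cover different chromosome sets",
         call. = FALSE)
  mc <- track_moments(control)
  mi <- track_moments(ip)
  if (mi$sd == 0)
    stop("IP track is constant (sd = 0); cannot moment-match", call. = FALSE)
  if (mc$sd == 0)
    stop("control track is constant (sd = 0); cannot moment-match",
         call. = FALSE)
  a <- mc$sd / mi$sd
  params <- list(mean_control = mc$mean, sd_control = mc$sd,
                 mean_ip = mi$mean, sd_ip = mi$sd,
                 n_positions = mi$n_positions)
  list(track = track_map(ip, function(v) (v - mi$mean) * a + mc$mean,
                         kind = "normalized",
                         meta = c(track_meta(ip), list(params = params))),
       params = params)
}

#' Background coverage level of the IP sample
#'
#' The background parameter `beta` guards the enrichment test against
#' regions where the control has no or very low coverage and hence no
#' usable coverage estimate.  It is the raw IP background coverage level
#' `c` carried through the same scaling and moment-matching transforms as
#' any other IP value.  By default `c` is estimated as the mean raw IP
#' hit count over the `n0` positions with nonzero IP coverage,
#' `c = sum(x) / n0`; it can also be supplied directly.
#'
#' @param ip_raw the raw (unscaled) IP coverage `genome_track`.
#' @param total_mapped mapped-read count of the IP sample.
#' @param params normalization parameters from [moment_match()].
#' @param theta scaling constant used in [scale_counts()].
#' @param c_user optional user-supplied value of `c` (raw-coverage scale),
#'   overriding the automatic estimate.
#' @return A list with `c`, `n0` and `beta`.
#' @export
compute_background <- function(ip_raw, total_mapped, params, theta = 1,
                               c_user = NULL) {
  x <- track_values(ip_raw)
  n0 <- sum(x > 0)
  if (is.null(c_user)) {
    if (n0 == 0L)
      stop("IP track is all zero; background level is undefined",
           call. = FALSE)
    cc <- sum(as.numeric(x)) / n0
  } else {
    cc <- stopifnot_scalar_number(c_user, "c_user", positive = TRUE)
  }
  y <- cc * theta * 1e6 / total_mapped
  beta <- (y - params$mean_ip) * (params$sd_control / params$sd_ip) +
    params$mean_control
  list(c = cc, n0 = n0, beta = beta)
}

#' Floor the control track at the background level
#'
#' Positions where the (depth-scaled) control coverage falls below `beta`
#' are raised to `beta`, so that coverage deserts in the control cannot
#' produce runaway enrichment scores.
#'
#' @param control a depth-scaled control `genome_track`.
#' @param beta background floor from [compute_background()].
#' @return The floored `genome_track` (`pmax(y, beta)` per position).
#' @export
floor_control <- function(control, beta) {
  stopifnot_scalar_number(beta, "beta")
  track_map(control, function(v) pmax(v, beta), kind = "scaled",
            meta = c(track_meta(control), list(beta = beta)))
}
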