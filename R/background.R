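#' Estimate per-interval background rates
#'
#' The acquisition is tiled into fixed-length intervals (50 s by default) and,
#' for each interval and each photon stream (DD, DA, AA, and all photons
#' pooled), the background rate is estimated by maximum-likelihood fitting of
#' the exponential tail of the interphoton delay distribution.  Delays longer
#' than a threshold (4 x the median delay) are taken as background-dominated;
#' for a censored exponential the MLE of the rate is
#' `1 / (mean(tail delays) - threshold)`.  Intervals with fewer than 20
#' retained delays for a stream fall back to the whole-acquisition estimate
#' for that stream, with a warning.
#'
#' @param stream a [photon_stream()].
#' @param interval tiling interval, seconds.
#' @param min_delays minimum number of tail delays for a per-interval fit.
#' @return A data frame of class `background_estimate` with columns
#'   `interval`, `t_start`, `t_stop`, `stream` (`"DD"`, `"DA"`, `"AA"`,
#'   `"all"`), `rate` (photons/s), `n_delays`, `threshold` (s), and
#'   `fallback` (logical).
#' @export
estimate_background <- function(stream, interval = 50, min_delays = 20L) {
  stopifnot(inherits(stream, "photon_stream"), interval > 0)
  if (!length(stream$timestamps)) stop("photon stream is empty")
  t <- photon_times(stream)
  lab <- stream_label(stream)
  n_int <- max(1L, ceiling(stream$duration / interval))
  if (stream$duration <= interval) n_int <- 1L
  edges <- seq(0, by = interval, length.out = n_int + 1L)
  edges[n_int + 1L] <- max(stream$duration, edges[n_int + 1L])
  streams <- c("DD", "DA", "AA", "all")

  global <- lapply(streams, function(s) {
    ts <- if (s == "all") t[lab != "DX"] else t[lab == s]
    fit <- tail_mle(ts)
    if (is.na(fit$rate)) {
      # stream with (almost) no photons: naive whole-acquisition rate
      fit$rate <- length(ts) / stream$duration
    }
    fit
  })
  names(global) <- streams

  out <- vector("list", n_int * length(streams))
  fell_back <- FALSE
  k <- 0L
  for (i in seq_len(n_int)) {
    in_i <- t >= edges[i] & t < edges[i + 1L]
    for (s in streams) {
      sel <- if (s == "all") in_i & lab != "DX" else in_i & lab == s
      fit <- tail_mle(t[sel])
      fb <- FALSE
      if (is.na(fit$rate) || fit$n_delays < min_delays) {
        fit <- global[[s]]
        fb <- TRUE
        fell_back <- TRUE
      }
      k <- k + 1L
      out[[k]] <- data.frame(interval = i, t_start = edges[i],
                             t_stop = edges[i + 1L], stream = s,
                             rate = fit$rate, n_delays = fit$n_delays,
                             threshold = fit$threshold, fallback = fb)
    }
  }
  if (fell_back) {
    warning("some intervals had too few tail delays; ",
            "whole-acquisition background used there")
  }
  res <- do.call(rbind, out)
  class(res) <- c("background_estimate", "data.frame")
  res
}

# censored-exponential MLE on the delay tail
tail_mle <- function(times) {
  d <- diff(times)
  d <- d[d > 0]
  if (length(d) < 2L) {
    return(list(rate = NA_real_, n_delays = length(d), threshold = NA_real_))
  }
  thr <- 4 * median(d)
  tail_d <- d[d > thr]
  if (length(tail_d) < 2L || mean(tail_d) <= thr) {
    return(list(rate = NA_real_, n_delays = length(tail_d), threshold = thr))
  }
  list(rate = 1 / (mean(tail_d) - thr), n_delays = length(tail_d),
       threshold = thr)
}

# background rate (photons/s) applicable to a search channel, per interval
channel_background <- function(background, channel) {
  sub <- function(s) background[background$stream == s, c("interval", "rate")]
  switch(channel,
    donor = {
      m <- merge(sub("DD"), sub("DA"), by = "interval")
      data.frame(interval = m$interval, rate = m$rate.x + m$rate.y)
    },
    acceptor = setNames(sub("AA"), c("interval", "rate")),
    all = setNames(sub("all"), c("interval", "rate"))
  )
}
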