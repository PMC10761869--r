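#' Photon timestamp stream
#'
#' The raw substrate of diffusion-based smFRET burst analysis: a time-ordered
#' record of detected photons, each carrying a detector label (donor or
#' acceptor channel) and an excitation-period label (donor or acceptor
#' excitation) derived from the laser alternation.  Timestamps are 0-based
#' integer clock ticks stored as doubles (tick counts can exceed the 32-bit
#' integer range in long acquisitions).
#'
#' Photon "streams" in the ALEX sense are derived labels:
#' \describe{
#'   \item{DD}{donor detector, donor excitation}
#'   \item{DA}{acceptor detector, donor excitation (FRET-sensitized)}
#'   \item{AA}{acceptor detector, acceptor excitation}
#'   \item{DX}{donor detector, acceptor excitation -- retained in the
#'     container but excluded from all analysis counts}
#' }
#'
#' @param timestamps numeric vector of non-decreasing clock ticks.
#' @param detector integer/character vector, one of `"donor"`/`"acceptor"`
#'   (or codes 0/1), same length as `timestamps`.
#' @param excitation like `detector`: which excitation window each photon
#'   fell in.
#' @param clock_period timestamp resolution in seconds.
#' @param duration acquisition length in seconds.
#' @param metadata free-form provenance list (seed, simulation config,
#'   alternation scheme, pile-up log, ...).
#'
#' @return An object of class `photon_stream`.
#' @export
photon_stream <- function(timestamps, detector, excitation, clock_period,
                          duration, metadata = list()) {
  timestamps <- as.numeric(timestamps)
  detector <- canon_label(detector, "detector")
  excitation <- canon_label(excitation, "excitation")
  n <- length(timestamps)
  if (length(detector) != n || length(excitation) != n) {
    stop("detector/excitation must have the same length as timestamps")
  }
  if (n > 1L) {
    bad <- which(diff(timestamps) < 0)
    if (length(bad)) {
      stop("timestamps not sorted: first offending index ", bad[1L] + 1L)
    }
  }
  stopifnot(clock_period > 0, duration >= 0)
  structure(
    list(
      timestamps = timestamps,
      detector = detector,
      excitation = excitation,
      clock_period = as.numeric(clock_period),
      duration = as.numeric(duration),
      metadata = metadata
    ),
    class = "photon_stream"
  )
}

# normalize detector/excitation labels to integer codes 0 = donor, 1 = acceptor
canon_label <- function(x, what) {
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    code <- match(x, c("donor", "acceptor")) - 1L
    if (anyNA(code)) stop("unknown ", what, " code: ",
                          paste(unique(x[is.na(code)]), collapse = ", "))
    return(code)
  }
  x <- as.integer(x)
  if (length(x) && (anyNA(x) || any(x < 0L | x > 1L))) {
    stop("unknown ", what, " code (must be 0/1 or donor/acceptor)")
  }
  x
}

#' @export
print.photon_stream <- function(x, ...) {
  cnt <- table(factor(stream_label(x), levels = c("DD", "DA", "AA", "DX")))
  cat("<photon_stream> ", length(x$timestamps), " photons over ",
      format(x$duration), " s (clock ", format(x$clock_period), " s)\n",
      "  DD ", cnt[["DD"]], " | DA ", cnt[["DA"]], " | AA ", cnt[["AA"]],
      " | donor-det/acc-exc ", cnt[["DX"]], "\n", sep = "")
  invisible(x)
}

#' Stream label of each photon
#'
#' @param stream a [photon_stream()].
#' @return character vector in `c("DD","DA","AA","DX")`.
#' @export
stream_label <- function(stream) {
  det <- stream$detector
  exc <- stream$excitation
  out <- character(length(det))
  out[det == 0L & exc == 0L] <- "DD"
  out[det == 1L & exc == 0L] <- "DA"
  out[det == 1L & exc == 1L] <- "AA"
  out[det == 0L & exc == 1L] <- "DX"
  out
}

#' Photon times in seconds
#' @param stream a [photon_stream()].
#' @return numeric vector of arrival times (s).
#' @export
photon_times <- function(stream) stream$timestamps * stream$clock_period

#' Laser alternation scheme
#'
#' Defines the half-open donor- and acceptor-excitation windows within one
#' alternation period.  Windows must be disjoint; their union may leave guard
#' intervals whose photons are dropped (and tallied) on assignment.
#'
#' @param period alternation period in seconds.
#' @param donor_window numeric length-2, half-open `[start, end)` in seconds
#'   within the period.
#' @param acceptor_window as `donor_window`.
#' @return An object of class `alternation_scheme`.
#' @export
alternation_scheme <- function(period,
                               donor_window = c(0, period / 2),
                               acceptor_window = c(period / 2, period)) {
  stopifnot(period > 0, length(donor_window) == 2, length(acceptor_window) == 2)
  w <- rbind(donor_window, acceptor_window)
  if (any(w < 0) || any(w > period) || any(w[, 2] <= w[, 1])) {
    stop("windows must be non-empty sub-intervals of [0, period]")
  }
  # half-open intervals overlap iff starts are each below the other's end
  if (donor_window[1] < acceptor_window[2] &&
      acceptor_window[1] < donor_window[2]) {
    stop("donor and acceptor windows overlap")
  }
  structure(list(period = period,
                 donor_window = as.numeric(donor_window),
                 acceptor_window = as.numeric(acceptor_window)),
            class = "alternation_scheme")
}

#' Assign excitation-period labels from an alternation scheme
#'
#' Each photon is labelled by which window `(time mod period)` falls in,
#' using the half-open `[start, end)` convention.  Photons in guard intervals
#' (outside both windows) are removed and their count recorded in
#' `metadata$guard_dropped`.
#'
#' @param stream a [photon_stream()] (its existing excitation labels, if any,
#'   are discarded).
#' @param scheme an [alternation_scheme()].
#' @return A relabelled [photon_stream()].
#' @export
assign_excitation <- function(stream, scheme) {
  stopifnot(inherits(scheme, "alternation_scheme"))
  clk <- stream$clock_period
  bounds <- c(scheme$period, scheme$donor_window, scheme$acceptor_window) / clk
  if (all(abs(bounds - round(bounds)) < 1e-6)) {
    # all edges fall on whole clock ticks: integer arithmetic avoids
    # floating-point drift at window boundaries
    b <- round(bounds)
    t_mod <- stream$timestamps %% b[1L]
    in_d <- t_mod >= b[2L] & t_mod < b[3L]
    in_a <- t_mod >= b[4L] & t_mod < b[5L]
  } else {
    t_mod <- (stream$timestamps * clk) %% scheme$period
    in_d <- t_mod >= scheme$donor_window[1] & t_mod < scheme$donor_window[2]
    in_a <- t_mod >= scheme$acceptor_window[1] & t_mod < scheme$acceptor_window[2]
  }
  keep <- in_d | in_a
  exc <- ifelse(in_a, 1L, 0L)[keep]
  md <- stream$metadata
  md$guard_dropped <- sum(!keep)
  md$alternation <- list(period = scheme$period,
                         donor_window = scheme$donor_window,
                         acceptor_window = scheme$acceptor_window)
  photon_stream(stream$timestamps[keep], stream$detector[keep], exc,
                stream$clock_period, stream$duration, md)
}
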