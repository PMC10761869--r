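#' Sliding-window burst search
#'
#' Identifies single-molecule transits as runs of photons whose local count
#' rate exceeds `F`-fold the local background rate.  A window of `m`
#' consecutive photons (of the chosen excitation channel) is "hot" when its
#' duration is shorter than `m / (F * background)`, an equivalent formulation
#' of "rate at least F-fold higher than background"; all photons covered by a
#' hot window are hot, and maximal runs of at least `m` hot photons become
#' bursts.  Burst spans are expressed on the full stream and counts
#' (`n_DD`, `n_DA`, `n_AA`) are taken from all photons inside the span;
#' E* and S are filled in via [compute_es()].
#'
#' @param stream a [photon_stream()].
#' @param m minimum number of consecutive photons (window size).
#' @param F rate threshold, fold over background.
#' @param background a [estimate_background()] result.
#' @param channel photons used for the search: `"donor"` (DD + DA),
#'   `"acceptor"` (AA), or `"all"`.
#' @return A data frame of class `burst_set`: columns `burst_id`, `i_start`,
#'   `i_stop` (photon index span on the full stream, half-open), `t_start`,
#'   `t_stop` (seconds), `duration`, `n_DD`, `n_DA`, `n_AA`, `E_star`, `S`.
#' @export
burst_search <- function(stream, m = 10L, F = 15, background,
                         channel = c("all", "donor", "acceptor")) {
  channel <- match.arg(channel)
  stopifnot(inherits(stream, "photon_stream"), m >= 2L, F > 1)
  if (missing(background) || is.null(background)) {
    stop("background estimate required (F x background defines the threshold)")
  }
  bg <- channel_background(background, channel)
  if (any(!is.finite(bg$rate)) || any(bg$rate <= 0)) {
    stop("background rate must be positive for burst search")
  }
  lab <- stream_label(stream)
  t_all <- photon_times(stream)
  idx <- switch(channel,
    donor = which(lab %in% c("DD", "DA")),
    acceptor = which(lab == "AA"),
    all = which(lab != "DX")
  )
  tc <- t_all[idx]
  n <- length(tc)
  if (n < m) return(empty_burst_set())

  interval_len <- background$t_stop[1L] - background$t_start[1L]
  int_of <- pmin(pmax(floor(tc / interval_len) + 1L, 1L), max(bg$interval))
  bg_rate <- bg$rate[match(int_of, bg$interval)]

  span <- tc[seq_len(n - m + 1L) + (m - 1L)] - tc[seq_len(n - m + 1L)]
  hot_start <- span < m / (F * bg_rate[seq_len(n - m + 1L)])
  # photons covered by any hot window, via a difference array
  cover <- integer(n + 1L)
  w <- which(hot_start)
  if (!length(w)) return(empty_burst_set())
  cover[w] <- cover[w] + 1L
  cover[w + m] <- cover[w + m] - 1L
  hot <- cumsum(cover[seq_len(n)]) > 0L
  r <- rle(hot)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  ok <- r$values & r$lengths >= m
  if (!any(ok)) return(empty_burst_set())
  first <- idx[run_start[ok]]
  last <- idx[run_end[ok]]
  make_burst_set(stream, t_all[first], t_all[last])
}

# Assemble a burst_set from time spans [t_first, t_last] (inclusive of the
# edge photons; stored half-open at one clock tick past the last photon).
make_burst_set <- function(stream, t_first, t_last) {
  t_all <- photon_times(stream)
  lab <- stream_label(stream)
  nb <- length(t_first)
  i_start <- findInterval(t_first - stream$clock_period / 2, t_all) + 1L
  i_stop <- findInterval(t_last + stream$clock_period / 2, t_all) + 1L
  count_in <- function(which_lab) {
    cs <- c(0L, cumsum(lab == which_lab))
    cs[i_stop] - cs[i_start]
  }
  n_DD <- count_in("DD"); n_DA <- count_in("DA"); n_AA <- count_in("AA")
  out <- data.frame(
    burst_id = seq_len(nb),
    i_start = i_start, i_stop = i_stop,
    t_start = t_first, t_stop = t_last + stream$clock_period,
    duration = t_last - t_first,
    n_DD = n_DD, n_DA = n_DA, n_AA = n_AA
  )
  out <- compute_es(out)
  class(out) <- c("burst_set", "data.frame")
  out
}

empty_burst_set <- function() {
  out <- data.frame(burst_id = integer(0), i_start = integer(0),
                    i_stop = integer(0), t_start = numeric(0),
                    t_stop = numeric(0), duration = numeric(0),
                    n_DD = integer(0), n_DA = integer(0), n_AA = integer(0),
                    E_star = numeric(0), S = numeric(0))
  class(out) <- c("burst_set", "data.frame")
  out
}

#' Dual-channel burst search
#'
#' Runs [burst_search()] independently on the donor-excitation photons and on
#' the acceptor-excitation photons, then keeps the time-intersections of
#' overlapping burst intervals from the two searches.  Transits of donor-only
#' molecules (no AA signal) and acceptor-only molecules (no donor-excitation
#' signal) fail one of the two searches and are screened out.  Counts and
#' E*/S are recomputed over each intersection.
#'
#' @inheritParams burst_search
#' @return A `burst_set` data frame (see [burst_search()]).
#' @export
dual_channel_burst_search <- function(stream, m = 10L, F = 15, background) {
  bd <- burst_search(stream, m, F, background, channel = "donor")
  ba <- burst_search(stream, m, F, background, channel = "acceptor")
  if (!nrow(bd) || !nrow(ba)) return(empty_burst_set())
  ## all pairwise overlaps of the two sorted interval sets
  starts <- ends <- numeric(0)
  nB <- nrow(ba)
  ji <- 1L
  for (i in seq_len(nrow(bd))) {
    while (ji <= nB && ba$t_stop[ji] <= bd$t_start[i]) ji <- ji + 1L
    j <- ji
    while (j <= nB && ba$t_start[j] < bd$t_stop[i]) {
      s <- max(bd$t_start[i], ba$t_start[j])
      e <- min(bd$t_stop[i], ba$t_stop[j])
      if (e > s) { starts <- c(starts, s); ends <- c(ends, e) }
      j <- j + 1L
    }
  }
  if (!length(starts)) return(empty_burst_set())
  make_burst_set(stream, starts, ends - stream$clock_period)
}

#' Filter bursts on per-stream photon counts
#'
#' Keeps bursts with at least `min_donor_exc` donor-excitation photons
#' (`n_DD + n_DA`, excluding acceptor-only species) and at least `min_aa`
#' AA photons (excluding donor-only species).  The number of bursts removed
#' by each criterion is attached as attribute `removed`.
#'
#' @param bursts a `burst_set`.
#' @param min_donor_exc threshold on `n_DD + n_DA`.
#' @param min_aa threshold on `n_AA`.
#' @return The filtered `burst_set`.
#' @export
filter_bursts <- function(bursts, min_donor_exc = 15L, min_aa = 15L) {
  c1 <- (bursts$n_DD + bursts$n_DA) >= min_donor_exc
  c2 <- bursts$n_AA >= min_aa
  out <- bursts[c1 & c2, , drop = FALSE]
  attr(out, "removed") <- c(donor_exc = sum(!c1), aa = sum(!c2))
  class(out) <- c("burst_set", "data.frame")
  out
}

#' Apparent FRET efficiency and stoichiometry per burst
#'
#' Uncorrected values: `E* = n_DA / (n_DD + n_DA)` and
#' `S = (n_DD + n_DA) / (n_DD + n_DA + n_AA)`.  E* is `NA` when there are no
#' donor-excitation photons; S is `NA` when the burst is empty.
#'
#' @param bursts a `burst_set` (or any data frame with `n_DD`, `n_DA`,
#'   `n_AA` columns).
#' @return `bursts` with `E_star` and `S` columns (re)computed.
#' @export
compute_es <- function(bursts) {
  nd <- bursts$n_DD + bursts$n_DA
  tot <- nd + bursts$n_AA
  bursts$E_star <- ifelse(nd > 0, bursts$n_DA / nd, NA_real_)
  bursts$S <- ifelse(tot > 0, nd / tot, NA_real_)
  bursts
}

#' E* histogram of S-selected bursts
#'
#' Selects bursts whose stoichiometry falls in the closed range `s_range`
#' (doubly labelled FRET pairs) and histograms their apparent FRET
#' efficiencies.
#'
#' @param bursts a `burst_set`.
#' @param s_range closed stoichiometry selection interval.
#' @param bin_width E* bin width.
#' @param e_range range tiled by the bins.
#' @return A list of class `es_histogram`: `table` (data frame with
#'   `bin_lo`, `bin_hi`, `center`, `count`), `modal_e` (center of the highest
#'   bin), `n_bursts`.
#' @export
es_histogram <- function(bursts, s_range = c(0.2, 0.8), bin_width = 0.035,
                         e_range = c(-0.1, 1.1)) {
  sel <- !is.na(bursts$S) & !is.na(bursts$E_star) &
    bursts$S >= s_range[1L] & bursts$S <= s_range[2L]
  e <- bursts$E_star[sel]
  if (!length(e)) {
    stop("no bursts with S in [", s_range[1L], ", ", s_range[2L], "]")
  }
  breaks <- seq(e_range[1L], e_range[2L] + bin_width, by = bin_width)
  bin <- pmin(pmax(findInterval(e, breaks), 1L), length(breaks) - 1L)
  count <- tabulate(bin, nbins = length(breaks) - 1L)
  tab <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
                    center = (breaks[-length(breaks)] + breaks[-1L]) / 2,
                    count = count)
  structure(list(table = tab,
                 modal_e = tab$center[which.max(tab$count)],
                 n_bursts = length(e)),
            class = "es_histogram")
}

#' Local maxima of an E* histogram
#'
#' Convenience for locating histogram modes, e.g. the high-FRET peak that
#' appears when closed-state occupancy grows.  A bin is a local maximum when
#' its count is at least that of both neighbours and positive.
#'
#' @param hist an [es_histogram()].
#' @param e_min,e_max restrict the search to bin centers in this range.
#' @return Data frame of the local maxima (`center`, `count`), ordered by
#'   decreasing count.
#' @export
histogram_modes <- function(hist, e_min = -Inf, e_max = Inf) {
  tab <- hist$table
  n <- nrow(tab)
  cnt <- tab$count
  left <- c(-1, cnt[-n]); right <- c(cnt[-1L], -1)
  is_max <- cnt > 0 & cnt >= left & cnt >= right
  out <- tab[is_max & tab$center >= e_min & tab$center <= e_max,
             c("center", "count")]
  out[order(-out$count), , drop = FALSE]
}
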