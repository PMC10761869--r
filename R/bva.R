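#' Shot-noise (static) limit of the E* standard deviation
#'
#' For a static molecule the probability that a donor-excitation photon is
#' FRET-sensitized is binomial, so the expected standard deviation of E*
#' estimated from `n` donor-excitation photons is `sqrt(E*(1 - E*)/n)`.
#'
#' @param e_star apparent FRET efficiency (0..1), vectorized.
#' @param n number of donor-excitation photons.
#' @return standard deviation(s).
#' @export
static_limit <- function(e_star, n) {
  stopifnot(all(e_star >= 0 & e_star <= 1), all(n >= 1))
  sqrt(e_star * (1 - e_star) / n)
}

#' Burst variance analysis
#'
#' Splits the donor-excitation photons (DD + DA) of each burst into
#' consecutive, non-overlapping sub-bursts of `n_sub` photons (the remainder
#' is dropped), computes the sub-burst proximity ratios
#' `e* = (DA count)/n_sub`, and the per-burst standard deviation of e* around
#' the burst E*:
#' `SD = sqrt(mean((e*_i - E*)^2))`.
#' Bursts with fewer than `n_sub` donor-excitation photons are skipped and
#' counted.
#'
#' @param stream the [photon_stream()] the bursts were found in.
#' @param bursts a `burst_set` (filtered; see [filter_bursts()]).
#' @param n_sub sub-burst size in donor-excitation photons.
#' @return A list of class `bva_result`: `bursts` (data frame with
#'   `burst_id`, `E_star`, `sd_e`, `M`), `sub_e` (list of sub-burst e*
#'   vectors, same order), `n_sub`, `n_skipped`.
#' @export
burst_sd <- function(stream, bursts, n_sub = 5L) {
  stopifnot(inherits(stream, "photon_stream"), n_sub >= 2L)
  lab <- stream_label(stream)
  keep <- logical(nrow(bursts))
  sd_e <- numeric(nrow(bursts))
  M <- integer(nrow(bursts))
  sub_e <- vector("list", nrow(bursts))
  e_burst <- numeric(nrow(bursts))
  for (b in seq_len(nrow(bursts))) {
    sl <- lab[seq.int(bursts$i_start[b], bursts$i_stop[b] - 1L)]
    sl <- sl[sl %in% c("DD", "DA")]
    m_b <- length(sl) %/% n_sub
    if (m_b < 1L) next
    keep[b] <- TRUE
    is_da <- sl[seq_len(m_b * n_sub)] == "DA"
    grp <- rep(seq_len(m_b), each = n_sub)
    e_sub <- tapply(is_da, grp, mean)
    es <- sum(sl == "DA") / length(sl)      # burst E* from the same photons
    e_burst[b] <- es
    sub_e[[b]] <- as.numeric(e_sub)
    M[b] <- m_b
    sd_e[b] <- sqrt(mean((e_sub - es)^2))
  }
  structure(list(
    bursts = data.frame(burst_id = bursts$burst_id[keep],
                        E_star = e_burst[keep],
                        sd_e = sd_e[keep], M = M[keep]),
    sub_e = sub_e[keep],
    n_sub = n_sub,
    n_skipped = sum(!keep)
  ), class = "bva_result")
}

#' Binned pooled sub-burst SD of E*
#'
#' Pools the sub-burst proximity ratios of all bursts whose E* falls in each
#' bin `[L, U)` along the E* axis (the top bin is closed) and computes the
#' pooled standard deviation around the pooled mean: with `M_i` sub-bursts in
#' burst `i`,
#' `SD_E* = sqrt( sum_ij (e*_ij - mu)^2 / sum_i M_i )`,
#' `mu = sum_ij e*_ij / sum_i M_i`.
#' Only bins holding at least `min_fraction` of all bursts report an SD; the
#' static limit at the bin center (for `n_sub` photons) is tabulated for
#' comparison.
#'
#' @param bva a [burst_sd()] result.
#' @param n_bins number of bins tiling `[0, 1]`.
#' @param width bin width.
#' @param min_fraction minimum fraction of all bursts a bin must hold.
#' @return Data frame with `bin_lo`, `bin_hi`, `center`, `n_bursts`,
#'   `fraction`, `sd_e` (`NA` below `min_fraction`), `static_limit`.
#' @export
binned_sd <- function(bva, n_bins = 20L, width = 0.05, min_fraction = 0.025) {
  stopifnot(inherits(bva, "bva_result"))
  df <- bva$bursts
  if (!nrow(df)) stop("no qualifying bursts")
  lo <- (seq_len(n_bins) - 1L) * width
  hi <- lo + width
  total <- nrow(df)
  out <- data.frame(bin_lo = lo, bin_hi = hi, center = (lo + hi) / 2,
                    n_bursts = 0L, fraction = 0, sd_e = NA_real_,
                    static_limit = static_limit(pmin(pmax((lo + hi) / 2, 0), 1),
                                                bva$n_sub))
  bin_of <- pmin(pmax(floor(df$E_star / width) + 1L, 1L), n_bins)
  for (k in seq_len(n_bins)) {
    in_k <- bin_of == k
    out$n_bursts[k] <- sum(in_k)
    out$fraction[k] <- sum(in_k) / total
    if (out$fraction[k] >= min_fraction) {
      e_all <- unlist(bva$sub_e[in_k])
      mu <- mean(e_all)
      out$sd_e[k] <- sqrt(mean((e_all - mu)^2))
    }
  }
  out
}
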