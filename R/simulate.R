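#' Simulate a continuous-time Markov state path
#'
#' Exact (Gillespie-style) event-time sampling of a continuous-time Markov
#' chain.  Unless `init_state` is given, the initial state is drawn from the
#' stationary distribution of the rate matrix, reflecting molecules that have
#' equilibrated between transits.
#'
#' @param rates K x K matrix of transition rate constants (s^-1); diagonal
#'   ignored.
#' @param duration path length, seconds.
#' @param seed optional integer seed (`set.seed` is called when supplied).
#' @param init_state optional fixed initial state index.
#' @return An object of class `state_path`: a list with `times` (dwell
#'   boundaries, length n+1, spanning `[0, duration]`) and `states` (state
#'   index per dwell, length n; consecutive entries differ).
#' @export
simulate_state_path <- function(rates, duration, seed = NULL, init_state = NULL) {
  rates <- validate_rate_matrix(rates)
  stopifnot(duration > 0)
  if (!is.null(seed)) set.seed(seed)
  K <- nrow(rates)
  exit <- rowSums(rates)
  s <- if (is.null(init_state)) {
    sample.int(K, 1L, prob = ctmc_stationary(rates))
  } else as.integer(init_state)
  times <- 0
  states <- integer(0)
  t <- 0
  repeat {
    states <- c(states, s)
    if (exit[s] <= 0) break            # absorbing: dwell to the end
    t <- t + rexp(1L, exit[s])
    if (t >= duration) break
    times <- c(times, t)
    s <- sample.int(K, 1L, prob = rates[s, ])
  }
  structure(list(times = c(times, duration), states = states),
            class = "state_path")
}

#' Stationary distribution of a continuous-time Markov chain
#'
#' @param rates K x K rate matrix (diagonal ignored).
#' @return probability vector of length K.
#' @export
ctmc_stationary <- function(rates) {
  rates <- validate_rate_matrix(rates)
  K <- nrow(rates)
  if (K == 1L) return(1)
  if (all(rates == 0)) return(rep(1 / K, K))  # frozen chain: uniform draw
  Q <- rates
  diag(Q) <- -rowSums(rates)
  A <- rbind(t(Q), rep(1, K))
  pi_ <- tryCatch(qr.solve(A, c(rep(0, K), 1)), error = function(e) {
    # reducible chain: null space of t(Q) via SVD
    v <- svd(t(Q))$v[, K]
    v / sum(v)
  })
  pi_ <- pmax(pi_, 0)
  pi_ / sum(pi_)
}

#' Simulate a us-ALEX photon stream
#'
#' Generates a synthetic acquisition with the statistical structure the burst
#' analysis assumes: molecule transits placed by a Poisson process with
#' exponential durations; a species drawn per transit (doubly labelled
#' molecules carry a [simulate_state_path()] realization, donor-only species
#' emit only DD photons, acceptor-only species only AA); photons emitted as
#' an inhomogeneous Poisson process gated by the laser alternation (DD/DA
#' only during donor-excitation windows, AA only during acceptor-excitation
#' windows; the acceptor-dark state emits all donor-excitation photons into
#' DD); homogeneous per-stream background over the full acquisition; all
#' arrival times quantized to clock ticks, merged, and sorted with same-tick
#' ties broken by the fixed stream order DD < DA < AA.  Two photons landing
#' on the same tick of the same stream count as pile-up: one is kept, the
#' number dropped is recorded in `metadata$pileup_dropped`.
#'
#' The ground truth (transit table with species, state paths, and the seed)
#' is recorded in `metadata$truth` for downstream parameter-recovery checks.
#'
#' @param config a [sim_config()].
#' @return A [photon_stream()].
#' @export
simulate_photon_stream <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  P <- config$alternation_period
  fd <- config$donor_fraction_of_period
  dur <- config$duration
  clk <- config$clock_period

  ## --- transit windows -------------------------------------------------
  n_b <- rpois(1L, config$burst_rate * dur)
  t0 <- sort(runif(n_b, 0, dur))
  len <- rexp(n_b, 1 / config$burst_duration_mean)
  t1 <- pmin(t0 + len, dur)
  species <- if (n_b) sample.int(3L, n_b, replace = TRUE,
                                 prob = config$species_fractions) else integer(0)

  ## --- piecewise-constant emission segments ----------------------------
  # columns: start, end, rDD, rDA, rAA  (rates while in the spot)
  em <- config$state_emission
  starts <- ends <- vector("list", n_b)
  rates_l <- vector("list", n_b)
  paths <- vector("list", n_b)
  don_rate <- sum(em[1L, 1:2])     # reference single-dye brightness
  acc_rate <- em[1L, 3L]
  for (b in seq_len(n_b)) {
    if (t1[b] <= t0[b]) next
    if (species[b] == 1L) {
      sp <- simulate_state_path(config$state_rates, t1[b] - t0[b])
      paths[[b]] <- sp
      nd <- length(sp$states)
      starts[[b]] <- t0[b] + sp$times[seq_len(nd)]
      ends[[b]] <- t0[b] + sp$times[seq_len(nd) + 1L]
      rates_l[[b]] <- em[sp$states, , drop = FALSE]
    } else {
      starts[[b]] <- t0[b]; ends[[b]] <- t1[b]
      rates_l[[b]] <- if (species[b] == 2L) {
        matrix(c(don_rate, 0, 0), 1)
      } else matrix(c(0, 0, acc_rate), 1)
    }
  }
  seg_start <- unlist(starts); seg_end <- unlist(ends)
  seg_rates <- do.call(rbind, rates_l)
  if (is.null(seg_rates)) seg_rates <- matrix(numeric(0), ncol = 3)

  ## --- gate segments by excitation windows and draw photons ------------
  d_pieces <- clip_to_windows(seg_start, seg_end, P, 0, fd * P)
  a_pieces <- clip_to_windows(seg_start, seg_end, P, fd * P, P)
  t_DD <- draw_piece_photons(d_pieces, seg_rates[, 1L])
  t_DA <- draw_piece_photons(d_pieces, seg_rates[, 2L])
  t_AA <- draw_piece_photons(a_pieces, seg_rates[, 3L])

  ## --- background -------------------------------------------------------
  np <- round(dur / P)
  bg <- config$background_rates
  t_DD <- c(t_DD, draw_background(bg[1L], dur, np, P, 0, fd * P))
  t_DA <- c(t_DA, draw_background(bg[2L], dur, np, P, 0, fd * P))
  t_AA <- c(t_AA, draw_background(bg[3L], dur, np, P, fd * P, P))

  ## --- quantize, merge, sort, de-pile -----------------------------------
  tick <- floor(c(t_DD, t_DA, t_AA) / clk)
  stream <- rep.int(1:3, c(length(t_DD), length(t_DA), length(t_AA)))
  o <- order(tick, stream)
  tick <- tick[o]; stream <- stream[o]
  dup <- duplicated(data.frame(tick, stream))
  n_drop <- sum(dup)
  tick <- tick[!dup]; stream <- stream[!dup]

  # excitation labels follow the quantized timestamps (integer tick
  # arithmetic), exactly as a reader would re-derive them; the rare photon
  # quantized across a window edge keeps its detector but changes window
  detector <- ifelse(stream == 1L, 0L, 1L)
  p_ticks <- round(P / clk)
  d_ticks <- round(fd * P / clk)
  excitation <- as.integer((tick %% p_ticks) >= d_ticks)
  truth <- list(
    bursts = data.frame(t_start = t0, t_stop = t1, species = species),
    state_paths = paths
  )
  photon_stream(tick, detector, excitation, clk, dur,
                metadata = list(
                  seed = config$seed,
                  config = config,
                  pileup_dropped = n_drop,
                  alternation = list(period = P,
                                     donor_window = c(0, fd * P),
                                     acceptor_window = c(fd * P, P)),
                  truth = truth
                ))
}

# Overlaps of half-open segments [a, b) with the periodic windows
# [kP + w0, kP + w1).  Returns list(seg = segment index, start, end).
clip_to_windows <- function(a, b, P, w0, w1) {
  if (!length(a)) return(list(seg = integer(0), start = numeric(0),
                              end = numeric(0)))
  k0 <- floor((a - w1) / P) + 1   # first period whose window can intersect
  k1 <- floor((b - w0) / P)
  nk <- pmax(0, k1 - k0 + 1)
  idx <- rep.int(seq_along(a), nk)
  k <- k0[idx] + sequence(nk) - 1
  s <- pmax(a[idx], k * P + w0)
  e <- pmin(b[idx], k * P + w1)
  keep <- e > s
  list(seg = idx[keep], start = s[keep], end = e[keep])
}

draw_piece_photons <- function(pieces, seg_rate) {
  if (!length(pieces$seg)) return(numeric(0))
  lam <- seg_rate[pieces$seg] * (pieces$end - pieces$start)
  n <- rpois(length(lam), lam)
  if (!sum(n)) return(numeric(0))
  i <- rep.int(seq_along(n), n)
  runif(sum(n), pieces$start[i], pieces$end[i])
}

draw_background <- function(rate, dur, np, P, w0, w1) {
  n <- rpois(1L, rate * dur)
  if (!n) return(numeric(0))
  k <- sample.int(np, n, replace = TRUE) - 1
  k * P + runif(n, w0, w1)
}
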