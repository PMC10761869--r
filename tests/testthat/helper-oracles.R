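# Independent brute-force oracles for the photon-colour HMM, plus small
# builders used across test files.

# exhaustive path-sum likelihood: sum over all K^n state paths of
# pi * prod(A^dt * B) -- independent of the forward implementation
brute_loglik <- function(pi, A, B, colors, dt) {
  K <- length(pi)
  n <- length(colors)
  Ad <- lapply(seq_len(n), function(k) {
    d <- max(1, dt[k])
    M <- diag(K)
    for (i in seq_len(d)) M <- M %*% A
    M
  })
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- pi[s[1L]] * B[s[1L], colors[1L]]
    if (n > 1L) {
      for (k in 2:n) p <- p * Ad[[k]][s[k - 1L], s[k]] * B[s[k], colors[k]]
    }
    tot <- tot + p
  }
  log(tot)
}

# exhaustive most-probable path
brute_viterbi <- function(pi, A, B, colors, dt) {
  K <- length(pi)
  n <- length(colors)
  Ad <- lapply(seq_len(n), function(k) {
    d <- max(1, dt[k])
    M <- diag(K)
    for (i in seq_len(d)) M <- M %*% A
    M
  })
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  best <- -Inf
  best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    lp <- log(pi[s[1L]]) + log(B[s[1L], colors[1L]])
    if (n > 1L) {
      for (k in 2:n) {
        lp <- lp + log(Ad[[k]][s[k - 1L], s[k]]) + log(B[s[k], colors[k]])
      }
    }
    if (lp > best) { best <- lp; best_path <- s }
  }
  list(path = best_path, loglik = best)
}

# random row-stochastic matrix
rand_stoch <- function(nr, nc) {
  M <- matrix(rexp(nr * nc), nr)
  M / rowSums(M)
}

# hand-built photon_set from explicit colour/gap sequences (list of bursts)
make_photon_set <- function(colors_list, dt_list, clock_period = 1e-7) {
  len <- vapply(colors_list, length, 1L)
  ticks <- unlist(lapply(dt_list, cumsum))
  structure(list(colors = unlist(colors_list), dt = unlist(dt_list),
                 ticks = ticks,
                 burst_id = rep.int(seq_along(colors_list), len),
                 ptr = c(0L, cumsum(len)),
                 clock_period = clock_period,
                 n_bursts = length(colors_list)),
            class = "photon_set")
}

# hand-built photon stream from times (s) and stream labels ("DD","DA","AA")
make_stream <- function(times, labels, clock_period = 1e-7, duration = NULL) {
  det <- ifelse(labels == "DD", 0L, 1L)
  exc <- ifelse(labels == "AA", 1L, 0L)
  o <- order(times)
  photon_stream(floor(times[o] / clock_period), det[o], exc[o], clock_period,
                duration %||% (max(times) + 1e-3))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# synthetic background table with a fixed rate for every stream
make_bg_table <- function(rate, duration, interval = 50) {
  n_int <- max(1L, ceiling(duration / interval))
  if (duration <= interval) n_int <- 1L
  edges <- seq(0, by = interval, length.out = n_int + 1L)
  edges[n_int + 1L] <- max(duration, edges[n_int + 1L])
  out <- expand.grid(interval = seq_len(n_int),
                     stream = c("DD", "DA", "AA", "all"),
                     stringsAsFactors = FALSE)
  out$t_start <- edges[out$interval]
  out$t_stop <- edges[out$interval + 1L]
  out$rate <- rate
  out$n_delays <- 1000L
  out$threshold <- 1e-4
  out$fallback <- FALSE
  class(out) <- c("background_estimate", "data.frame")
  out
}

# standard small simulated dataset processed through the full burst pipeline
sim_pipeline <- function(cfg, s_range = c(0.2, 0.8)) {
  st <- simulate_photon_stream(cfg)
  bg <- estimate_background(st)
  b <- filter_bursts(dual_channel_burst_search(st, background = bg))
  sel <- b[!is.na(b$S) & b$S >= s_range[1] & b$S <= s_range[2], ]
  list(stream = st, background = bg, bursts = b, selected = sel,
       photons = burst_photons(st, sel))
}
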