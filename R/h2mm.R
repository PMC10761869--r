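#' Photon-colour hidden Markov model
#'
#' A K-state model of photon-by-photon dynamics: the hidden chain steps once
#' per clock tick with transition probability matrix `A`; photons are
#' observed at their arrival ticks with per-state colour probabilities `B`
#' over the streams DD, DA, AA; bursts start from the initial distribution
#' `pi`.  Between photons separated by `dt` ticks the transition operator is
#' `A^dt`.
#'
#' @param pi initial state distribution (length K).
#' @param A K x K per-tick transition probability matrix (rows sum to 1).
#' @param B K x 3 emission matrix over colours DD, DA, AA (rows sum to 1).
#' @param clock_period tick length in seconds.
#' @return An object of class `h2mm_model`.
#' @export
h2mm_model <- function(pi, A, B, clock_period) {
  A <- as.matrix(A); B <- as.matrix(B)
  K <- length(pi)
  stopifnot(nrow(A) == K, ncol(A) == K, nrow(B) == K, ncol(B) == 3,
            clock_period > 0)
  if (any(abs(rowSums(A) - 1) > 1e-10) || any(A < -1e-12)) {
    stop("A must be row-stochastic")
  }
  if (any(abs(rowSums(B) - 1) > 1e-10) || any(B < -1e-12)) {
    stop("B must be row-stochastic")
  }
  if (abs(sum(pi) - 1) > 1e-8 || any(pi < -1e-12)) {
    stop("pi must be a probability vector")
  }
  structure(list(pi = as.numeric(pi), A = unname(A), B = unname(B),
                 clock_period = clock_period, n_states = K),
            class = "h2mm_model")
}

#' @export
print.h2mm_model <- function(x, ...) {
  es <- state_es(x)
  cat("<h2mm_model> ", x$n_states, " states, clock ",
      format(x$clock_period), " s\n", sep = "")
  print(data.frame(E_state = round(es$E_state, 3),
                   S_state = round(es$S_state, 3),
                   pi = round(x$pi, 3)))
  invisible(x)
}

#' Per-state apparent FRET efficiency and stoichiometry
#'
#' `E_state = B[DA] / (B[DD] + B[DA])`,
#' `S_state = (B[DD] + B[DA]) / (B[DD] + B[DA] + B[AA])`.
#'
#' @param model an [h2mm_model()].
#' @return list with numeric vectors `E_state`, `S_state`.
#' @export
state_es <- function(model) {
  B <- model$B
  nd <- B[, 1L] + B[, 2L]
  list(E_state = ifelse(nd > 0, B[, 2L] / nd, NA_real_),
       S_state = nd / (nd + B[, 3L]))
}

#' Burst photon sequences for photon-by-photon modelling
#'
#' Extracts, for each burst, the colour sequence (DD = 1, DA = 2, AA = 3) and
#' integer tick gaps of its analysis photons (donor-detector photons during
#' acceptor excitation are excluded).  Same-tick photons yield a gap of 1
#' tick (pile-up convention).
#'
#' @param stream a [photon_stream()].
#' @param bursts a `burst_set` from [burst_search()] /
#'   [dual_channel_burst_search()], normally after [filter_bursts()].
#' @return A list of class `photon_set`: `colors` (integer 1..3), `dt`
#'   (ticks to previous photon, 0 for burst-initial photons), `ticks`,
#'   `burst_id`, `ptr` (0-based burst offsets, length nb+1),
#'   `clock_period`, `n_bursts`.
#' @export
burst_photons <- function(stream, bursts) {
  stopifnot(inherits(stream, "photon_stream"))
  lab <- stream_label(stream)
  nb <- nrow(bursts)
  colors <- ticks <- ids <- vector("list", nb)
  for (b in seq_len(nb)) {
    i <- seq.int(bursts$i_start[b], bursts$i_stop[b] - 1L)
    i <- i[lab[i] != "DX"]
    colors[[b]] <- match(lab[i], c("DD", "DA", "AA"))
    ticks[[b]] <- stream$timestamps[i]
    ids[[b]] <- rep.int(bursts$burst_id[b], length(i))
  }
  len <- vapply(colors, length, 1L)
  dt <- lapply(ticks, function(tk) if (length(tk)) c(0, diff(tk)) else numeric(0))
  structure(list(colors = unlist(colors), dt = unlist(dt),
                 ticks = unlist(ticks), burst_id = unlist(ids),
                 ptr = c(0L, cumsum(len)),
                 clock_period = stream$clock_period,
                 n_bursts = nb),
            class = "photon_set")
}

#' Forward-algorithm log-likelihood
#'
#' Sum over bursts of the scaled forward-pass log-likelihood with
#' arrival-time-dependent transition operators `A^dt`.
#'
#' @param model an [h2mm_model()].
#' @param photons a [burst_photons()] set.
#' @return total log-likelihood.
#' @export
h2mm_loglik <- function(model, photons) {
  stopifnot(inherits(model, "h2mm_model"), inherits(photons, "photon_set"))
  h2mm_loglik_cpp(model$pi, model$A, model$B,
                  as.integer(photons$colors) - 1L, photons$dt,
                  as.integer(photons$ptr))
}

#' Fit a K-state photon-by-photon hidden Markov model
#'
#' Baum-Welch expectation-maximization with exact expected tick-transition
#' counts over the `A^dt` segments between photons.  The log-likelihood is
#' non-decreasing across iterations; fitting stops when the per-photon
#' improvement falls below `tol` or after `max_iter` iterations.  Initial
#' state means are placed at quantiles of the per-burst E* distribution; when
#' `K >= 3` the last state is initialized as an acceptor-dark photophysical
#' state (E* ~ 0, S ~ 1).  Additional restarts jitter the initialization;
#' the best-likelihood fit is kept.
#'
#' @param photons a [burst_photons()] set.
#' @param K number of states.
#' @param init optional [h2mm_model()] to start from (restarts then jitter
#'   around it).
#' @param tol per-photon log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param restarts number of EM starts (first is deterministic).
#' @param seed optional seed for restart jitter.
#' @return An object of class `h2mm_fit`: `model`, `loglik`, `ll_trace`,
#'   `iterations`, `converged`, `K`, `n_photons`.
#' @export
fit_h2mm <- function(photons, K, init = NULL, tol = 1e-7, max_iter = 1000L,
                     restarts = 5L, seed = NULL) {
  stopifnot(inherits(photons, "photon_set"), K >= 1L)
  if (photons$n_bursts < 1L || !length(photons$colors)) {
    stop("no bursts to fit")
  }
  if (!is.null(seed)) set.seed(seed)
  colors0 <- as.integer(photons$colors) - 1L
  ptr <- as.integer(photons$ptr)
  best <- NULL
  for (r in seq_len(max(1L, restarts))) {
    m0 <- if (!is.null(init) && r == 1L) init else {
      init_h2mm(photons, K, jitter = (r > 1L))
    }
    fit <- h2mm_em_cpp(m0$pi, m0$A, m0$B, colors0, photons$dt, ptr,
                       as.integer(max_iter), tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  model <- h2mm_model(best$pi, renormalize_rows(best$A),
                      renormalize_rows(best$B), photons$clock_period)
  check_state_collapse(model)
  structure(list(model = model, loglik = best$loglik,
                 ll_trace = best$ll_trace, iterations = best$iterations,
                 converged = best$converged, K = K,
                 n_photons = length(photons$colors)),
            class = "h2mm_fit")
}

renormalize_rows <- function(M) {
  M[M < 0] <- 0
  sweep(M, 1, rowSums(M), "/")
}

check_state_collapse <- function(model) {
  K <- model$n_states
  if (K < 2L) return(invisible(FALSE))
  for (i in seq_len(K - 1L)) {
    for (j in seq.int(i + 1L, K)) {
      if (all(abs(model$B[i, ] - model$B[j, ]) < 1e-3) &&
          all(abs(model$A[i, ] - model$A[j, ]) < 1e-3)) {
        warning("states ", i, " and ", j, " have collapsed ",
                "(emissions and transitions agree within 1e-3)")
        return(invisible(TRUE))
      }
    }
  }
  invisible(FALSE)
}

# deterministic (or jittered) initialization at E* quantiles of the bursts
init_h2mm <- function(photons, K, jitter = FALSE, rate_init = 100) {
  eb <- burst_es_from_photons(photons)
  n_dark <- if (K >= 3L) 1L else 0L
  Kc <- K - n_dark
  e0 <- if (Kc > 0) {
    stats::quantile(eb$E, probs = seq(0.5 / Kc, 1 - 0.5 / Kc, length.out = Kc),
                    na.rm = TRUE, names = FALSE)
  } else numeric(0)
  s0 <- rep(0.5, Kc)
  if (n_dark) { e0 <- c(e0, 0.02); s0 <- c(s0, 0.95) }
  if (jitter) {
    e0 <- pmin(pmax(e0 + runif(K, -0.08, 0.08), 0.01), 0.99)
    s0 <- pmin(pmax(s0 + runif(K, -0.08, 0.08), 0.05), 0.99)
  }
  B <- cbind(DD = s0 * (1 - e0), DA = s0 * e0, AA = 1 - s0)
  rate <- if (jitter) rate_init * exp(runif(1, -1, 1)) else rate_init
  p <- rate * photons$clock_period
  A <- matrix(p, K, K)
  diag(A) <- 0
  diag(A) <- 1 - rowSums(A)
  h2mm_model(rep(1 / K, K), A, B, photons$clock_period)
}

burst_es_from_photons <- function(photons) {
  f <- factor(photons$burst_id)
  nDD <- tapply(photons$colors == 1L, f, sum)
  nDA <- tapply(photons$colors == 2L, f, sum)
  nAA <- tapply(photons$colors == 3L, f, sum)
  nd <- nDD + nDA
  list(E = ifelse(nd > 0, nDA / nd, NA_real_),
       S = nd / pmax(nd + nAA, 1))
}

#' Integrated complete likelihood of a fitted model
#'
#' `ICL = -(complete-data log-likelihood along the Viterbi path
#' - (d/2) ln(N_photons))` with `d = (K-1) + K(K-1) + 2K` free parameters
#' (initial distribution, transitions, emissions over 3 colours).  Lower is
#' better; the penalty term grows monotonically with K.
#'
#' @param fit an [fit_h2mm()] result (or an [h2mm_model()]).
#' @param photons a [burst_photons()] set.
#' @return ICL value (numeric).
#' @export
icl <- function(fit, photons) {
  model <- if (inherits(fit, "h2mm_fit")) fit$model else fit
  stopifnot(inherits(model, "h2mm_model"), inherits(photons, "photon_set"))
  states <- h2mm_viterbi_cpp(model$pi, model$A, model$B,
                             as.integer(photons$colors) - 1L, photons$dt,
                             as.integer(photons$ptr))
  cll <- h2mm_path_loglik_cpp(model$pi, model$A, model$B,
                              as.integer(photons$colors) - 1L, photons$dt,
                              as.integer(photons$ptr), states)
  K <- model$n_states
  d <- (K - 1) + K * (K - 1) + 2 * K
  -(cll - d / 2 * log(length(photons$colors)))
}

#' Fit models of increasing size and select by ICL
#'
#' Fits K = 1..`K_max` and returns the minimum-ICL model.  Models containing
#' any inter-state transition rate below `slow_rate_threshold` (too slow to
#' be detectable within bursts, hence physically unreasonable) are flagged
#' and excluded from selection unless every model is flagged, in which case
#' the minimum-ICL model is returned with a warning.
#'
#' @param photons a [burst_photons()] set.
#' @param K_max largest model tested.
#' @param slow_rate_threshold rate flag threshold, s^-1.
#' @param ... passed to [fit_h2mm()].
#' @return A list of class `h2mm_selection`: `best` (an `h2mm_fit`),
#'   `table` (data frame K, loglik, ICL, flagged), `fits`.
#' @export
select_model <- function(photons, K_max = 5L, slow_rate_threshold = 1, ...) {
  stopifnot(photons$n_bursts >= 1L)
  fits <- vector("list", K_max)
  tab <- data.frame(K = seq_len(K_max), loglik = NA_real_, ICL = NA_real_,
                    flagged = FALSE)
  for (K in seq_len(K_max)) {
    fits[[K]] <- fit_h2mm(photons, K, ...)
    tab$loglik[K] <- fits[[K]]$loglik
    tab$ICL[K] <- icl(fits[[K]], photons)
    if (K >= 2L) {
      Q <- rates_from_model(fits[[K]]$model)
      off <- Q[row(Q) != col(Q)]
      tab$flagged[K] <- any(off < slow_rate_threshold)
    }
  }
  usable <- which(!tab$flagged)
  if (!length(usable)) {
    warning("all candidate models contain transition rates below ",
            slow_rate_threshold, " /s; returning minimum-ICL model")
    usable <- seq_len(K_max)
  }
  best_K <- usable[which.min(tab$ICL[usable])]
  structure(list(best = fits[[best_K]], table = tab, fits = fits),
            class = "h2mm_selection")
}

#' Transition rate constants from a fitted model
#'
#' Converts the per-tick transition matrix to rate constants in s^-1 via the
#' matrix logarithm `Q = log(A) / clock_period`, projected to the nearest
#' valid generator (negative off-diagonal entries clipped to zero, diagonal
#' rebalanced).  For the small per-tick probabilities typical of photon data
#' this equals `A_ij / clock_period` to first order.
#'
#' @param model an [h2mm_model()].
#' @return K x K rate matrix (s^-1), diagonal = -rowsums.
#' @export
rates_from_model <- function(model) {
  A <- model$A
  eg <- eigen(A)
  lam <- eg$values
  # A is stochastic: eigenvalues in the unit disc; log is principal branch
  L <- eg$vectors %*% diag(log(as.complex(lam)), nrow = length(lam)) %*%
    solve(eg$vectors)
  Q <- Re(L) / model$clock_period
  off <- Q
  diag(off) <- 0
  off[off < 0] <- 0
  diag(off) <- -rowSums(off)
  off
}

#' State roles: open, closed, photophysical
#'
#' For models with three or more states, the state with the highest
#' stoichiometry is taken as the acceptor-dark photophysical state (S ~ 1);
#' of the remaining (conformational) states, the lowest-E* state is "open"
#' and the highest-E* state "closed".  Two-state models have no dark state.
#'
#' @param model an [h2mm_model()].
#' @return list with integer indices `open`, `closed`, `dark` (NA if none).
#' @export
identify_states <- function(model) {
  es <- state_es(model)
  K <- model$n_states
  if (K < 2L) stop("need at least 2 states to identify open/closed")
  idx <- seq_len(K)
  dark <- NA_integer_
  if (K >= 3L) {
    dark <- idx[which.max(es$S_state)]
    idx <- setdiff(idx, dark)
  }
  conf <- idx[order(es$E_state[idx])]
  list(open = conf[1L], closed = conf[length(conf)], dark = dark)
}

#' Closing equilibrium constant
#'
#' `K_closing = k_open->closed / k_closed->open`, the equilibrium of the
#' open-to-closed conformational rearrangement, computed from the fitted
#' conformational rate constants (the photophysical state is excluded).
#'
#' @param fit an [fit_h2mm()] result or [h2mm_model()].
#' @return list: `K_closing`, `k_open_closed`, `k_closed_open` (s^-1),
#'   `states` (role indices).
#' @export
k_closing <- function(fit) {
  model <- if (inherits(fit, "h2mm_fit")) fit$model else fit
  roles <- identify_states(model)
  Q <- rates_from_model(model)
  k_oc <- Q[roles$open, roles$closed]
  k_co <- Q[roles$closed, roles$open]
  if (k_co <= 0) stop("closed->open rate is not positive")
  list(K_closing = k_oc / k_co, k_open_closed = k_oc, k_closed_open = k_co,
       states = roles)
}

#' Viterbi state path and dwell table
#'
#' Decodes the most probable state path of every burst and groups successive
#' photons assigned to the same state into dwells.  Dwell E* and S are
#' computed from the dwell's photon counts exactly as for bursts.
#'
#' @param fit an [fit_h2mm()] result or [h2mm_model()].
#' @param photons a [burst_photons()] set.
#' @return A list of class `dwell_set`: `dwells` (data frame with
#'   `burst_id`, `state`, `n_DD`, `n_DA`, `n_AA`, `E_star`, `S`,
#'   `duration` in seconds), `states` (per-photon Viterbi states, 1-based).
#' @export
viterbi_dwells <- function(fit, photons) {
  model <- if (inherits(fit, "h2mm_fit")) fit$model else fit
  stopifnot(inherits(model, "h2mm_model"), inherits(photons, "photon_set"))
  st <- h2mm_viterbi_cpp(model$pi, model$A, model$B,
                         as.integer(photons$colors) - 1L, photons$dt,
                         as.integer(photons$ptr)) + 1L
  nb <- photons$n_bursts
  out <- vector("list", nb)
  for (b in seq_len(nb)) {
    i0 <- photons$ptr[b] + 1L
    i1 <- photons$ptr[b + 1L]
    if (i1 < i0) next
    i <- seq.int(i0, i1)
    r <- rle(st[i])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cols <- photons$colors[i]
    tks <- photons$ticks[i]
    out[[b]] <- data.frame(
      burst_id = photons$burst_id[i0],
      state = r$values,
      n_DD = vapply(seq_along(r$values),
                    function(d) sum(cols[starts[d]:ends[d]] == 1L), 1L),
      n_DA = vapply(seq_along(r$values),
                    function(d) sum(cols[starts[d]:ends[d]] == 2L), 1L),
      n_AA = vapply(seq_along(r$values),
                    function(d) sum(cols[starts[d]:ends[d]] == 3L), 1L),
      duration = (tks[ends] - tks[starts]) * photons$clock_period
    )
  }
  dw <- do.call(rbind, out)
  dw <- compute_es(dw)
  names(dw)[names(dw) == "E_star"] <- "E_star"
  structure(list(dwells = dw, states = st), class = "dwell_set")
}

#' Subset-based uncertainty of the kinetic constants
#'
#' Partitions the bursts sequentially (in acquisition order) into subsets of
#' `subset_size` bursts, refits the model on each subset, and reports the
#' standard deviation of the conformational rate constants across subsets.
#' The K_closing uncertainty follows by propagation:
#' `sigma(K)/K = sqrt((sigma(k_oc)/k_oc)^2 + (sigma(k_co)/k_co)^2)`.
#'
#' @param photons a [burst_photons()] set.
#' @param subset_size bursts per subset.
#' @param K number of states (3-state model by default).
#' @param init optional [h2mm_model()] used to start every subset fit
#'   (typically the full-data fit).
#' @param ... passed to [fit_h2mm()].
#' @return list: `k_open_closed`, `k_closed_open`, `K_closing` (means across
#'   subsets), `sd_k_open_closed`, `sd_k_closed_open`, `sd_K_closing`,
#'   `subsets` (per-subset data frame), `n_subsets`.
#' @export
subset_uncertainty <- function(photons, subset_size = 1850L, K = 3L,
                               init = NULL, ...) {
  nb <- photons$n_bursts
  ns <- nb %/% subset_size
  if (ns < 2L) {
    stop("need at least 2 full subsets (", 2L * subset_size,
         " bursts); have ", nb, " - collect more data")
  }
  rows <- vector("list", ns)
  for (s in seq_len(ns)) {
    keep_b <- seq.int((s - 1L) * subset_size + 1L, s * subset_size)
    sub <- subset_photon_set(photons, keep_b)
    fit <- fit_h2mm(sub, K, init = init, ...)
    kc <- k_closing(fit)
    rows[[s]] <- data.frame(subset = s, k_open_closed = kc$k_open_closed,
                            k_closed_open = kc$k_closed_open,
                            K_closing = kc$K_closing)
  }
  df <- do.call(rbind, rows)
  k_oc <- mean(df$k_open_closed); k_co <- mean(df$k_closed_open)
  s_oc <- sd(df$k_open_closed); s_co <- sd(df$k_closed_open)
  Kc <- k_oc / k_co
  list(k_open_closed = k_oc, k_closed_open = k_co, K_closing = Kc,
       sd_k_open_closed = s_oc, sd_k_closed_open = s_co,
       sd_K_closing = Kc * sqrt((s_oc / k_oc)^2 + (s_co / k_co)^2),
       subsets = df, n_subsets = ns)
}

# photon_set restricted to the given burst positions (1-based, in order)
subset_photon_set <- function(photons, burst_pos) {
  keep <- unlist(lapply(burst_pos, function(b) {
    if (photons$ptr[b + 1L] <= photons$ptr[b]) return(integer(0))
    seq.int(photons$ptr[b] + 1L, photons$ptr[b + 1L])
  }))
  len <- photons$ptr[burst_pos + 1L] - photons$ptr[burst_pos]
  structure(list(colors = photons$colors[keep], dt = photons$dt[keep],
                 ticks = photons$ticks[keep],
                 burst_id = photons$burst_id[keep],
                 ptr = c(0L, cumsum(len)),
                 clock_period = photons$clock_period,
                 n_bursts = length(burst_pos)),
            class = "photon_set")
}
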