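test_that("forward likelihood matches exhaustive enumeration", {
  set.seed(40)
  for (rep in 1:25) {
    K <- sample(1:3, 1L)
    n <- sample(2:7, 1L)
    A <- rand_stoch(K, K); B <- rand_stoch(K, 3)
    pi <- rexp(K); pi <- pi / sum(pi)
    colors <- sample(1:3, n, replace = TRUE)
    dt <- c(0, sample(1:15, n - 1L, replace = TRUE))
    m <- h2mm_model(pi, A, B, 1e-7)
    ph <- make_photon_set(list(colors), list(dt))
    expect_equal(h2mm_loglik(m, ph), brute_loglik(pi, A, B, colors, dt),
                 tolerance = 1e-10)
  }
})

test_that("degenerate one-state model reduces to iid categorical likelihood", {
  B <- rand_stoch(1, 3)
  m <- h2mm_model(1, matrix(1, 1, 1), B, 1e-7)
  colors <- sample(1:3, 50, replace = TRUE)
  ph <- make_photon_set(list(colors), list(c(0, rep(5, 49))))
  expect_equal(h2mm_loglik(m, ph), sum(log(B[1L, colors])))
})

test_that("identity transitions give the frozen-chain mixture likelihood", {
  set.seed(41)
  K <- 3
  B <- rand_stoch(K, 3)
  pi <- c(0.2, 0.5, 0.3)
  m <- h2mm_model(pi, diag(K), B, 1e-7)
  colors <- sample(1:3, 12, replace = TRUE)
  ph <- make_photon_set(list(colors), list(c(0, sample(1:9, 11, TRUE))))
  mix <- sum(pi * apply(B, 1, function(row) prod(row[colors])))
  expect_equal(h2mm_loglik(m, ph), log(mix), tolerance = 1e-12)
})

test_that("Viterbi equals the brute-force most probable path", {
  set.seed(42)
  for (rep in 1:15) {
    K <- sample(2:3, 1L)
    n <- sample(3:6, 1L)
    A <- rand_stoch(K, K); B <- rand_stoch(K, 3)
    pi <- rexp(K); pi <- pi / sum(pi)
    colors <- sample(1:3, n, replace = TRUE)
    dt <- c(0, sample(1:10, n - 1L, replace = TRUE))
    got <- burstdyn:::h2mm_viterbi_cpp(pi, A, B, colors - 1L, dt,
                                       c(0L, n)) + 1L
    want <- brute_viterbi(pi, A, B, colors, dt)$path
    expect_equal(as.integer(got), as.integer(want))
  }
})

test_that("EM log-likelihood is monotone and improves on the truth no worse", {
  cfg <- sim_config(duration = 8, seed = 43)
  pl <- sim_pipeline(cfg)
  fit <- fit_h2mm(pl$photons, 3, restarts = 1, max_iter = 60)
  ll <- fit$ll_trace
  expect_true(all(diff(ll) >= -1e-6 * abs(ll[-1L])))
  # refitting from the converged model cannot decrease the likelihood
  refit <- fit_h2mm(pl$photons, 3, init = fit$model, restarts = 1,
                    max_iter = 10)
  expect_gte(refit$loglik, fit$loglik - 1e-6 * abs(fit$loglik))
})

test_that("one-state fit returns the pooled colour frequencies", {
  cfg <- sim_config(duration = 5, seed = 44)
  pl <- sim_pipeline(cfg)
  fit <- fit_h2mm(pl$photons, 1, restarts = 1)
  freq <- tabulate(pl$photons$colors, 3) / length(pl$photons$colors)
  expect_equal(as.numeric(fit$model$B), freq, tolerance = 1e-6)
})

test_that("two-state parameter recovery from simulated photon data", {
  cfg <- sim_config(duration = 100,
                    state_rates = matrix(c(0, 150, 300, 0), 2, byrow = TRUE),
                    state_emission = state_emission_rates(c(0.2, 0.8),
                                                          dark_state = FALSE),
                    species_fractions = c(1, 0, 0),
                    seed = 45)
  pl <- sim_pipeline(cfg)
  expect_gt(pl$photons$n_bursts, 2000)
  fit <- fit_h2mm(pl$photons, 2, restarts = 1)
  es <- state_es(fit$model)
  o <- order(es$E_state)
  expect_lt(abs(es$E_state[o[1L]] - 0.2), 0.03)
  expect_lt(abs(es$E_state[o[2L]] - 0.8), 0.03)
  Q <- rates_from_model(fit$model)
  expect_lt(abs(Q[o[1L], o[2L]] - 150) / 150, 0.2)
  expect_lt(abs(Q[o[2L], o[1L]] - 300) / 300, 0.2)
})

test_that("ICL penalty grows with K and prefers 2 states for bimodal data", {
  cfg <- sim_config(duration = 25,
                    state_rates = matrix(c(0, 150, 300, 0), 2, byrow = TRUE),
                    state_emission = state_emission_rates(c(0.2, 0.8),
                                                          dark_state = FALSE),
                    species_fractions = c(1, 0, 0),
                    seed = 46)
  pl <- sim_pipeline(cfg)
  f1 <- fit_h2mm(pl$photons, 1, restarts = 1)
  f2 <- fit_h2mm(pl$photons, 2, restarts = 1, max_iter = 300)
  expect_lt(icl(f2, pl$photons), icl(f1, pl$photons))
  # penalty term alone is monotone increasing in K at fixed data
  N <- length(pl$photons$colors)
  pen <- vapply(1:5, function(K) ((K - 1) + K * (K - 1) + 2 * K) / 2 * log(N),
                1)
  expect_true(all(diff(pen) > 0))
})

test_that("state relabelling leaves LL, ICL, and K_closing unchanged", {
  cfg <- sim_config(duration = 10, seed = 47)
  pl <- sim_pipeline(cfg)
  fit <- fit_h2mm(pl$photons, 3, restarts = 1)
  perm <- c(3L, 1L, 2L)
  mperm <- h2mm_model(fit$model$pi[perm], fit$model$A[perm, perm],
                      fit$model$B[perm, ], fit$model$clock_period)
  expect_equal(h2mm_loglik(mperm, pl$photons),
               h2mm_loglik(fit$model, pl$photons), tolerance = 1e-9)
  expect_equal(icl(mperm, pl$photons), icl(fit$model, pl$photons),
               tolerance = 1e-9)
  expect_equal(k_closing(mperm)$K_closing, k_closing(fit)$K_closing,
               tolerance = 1e-9)
})

test_that("K_closing arithmetic and state identification", {
  clock <- 1e-7
  mk <- function(k_oc, k_co) {
    A <- diag(3)
    A[1, 2] <- k_oc * clock; A[2, 1] <- k_co * clock
    A[1, 3] <- A[2, 3] <- 20 * clock
    A[3, 1] <- A[3, 2] <- 150 * clock
    diag(A) <- 0; diag(A) <- 1 - rowSums(A)
    B <- rbind(c(0.4, 0.1, 0.5),      # open: E* = 0.2, S = 0.5
               c(0.1, 0.4, 0.5),      # closed: E* = 0.8, S = 0.5
               c(0.93, 0.02, 0.05))   # dark: E* ~ 0, S ~ 1
    h2mm_model(rep(1 / 3, 3), A, B, clock)
  }
  expect_equal(k_closing(mk(100, 100))$K_closing, 1, tolerance = 1e-4)
  kc <- k_closing(mk(50, 100))
  expect_equal(kc$K_closing, 0.5, tolerance = 1e-4)
  expect_equal(kc$states$open, 1L)
  expect_equal(kc$states$closed, 2L)
  expect_equal(kc$states$dark, 3L)
  # identification is by E*/S role, not index: permute and re-check
  m <- mk(50, 100)
  perm <- c(2L, 3L, 1L)
  mp <- h2mm_model(m$pi[perm], m$A[perm, perm], m$B[perm, ], clock)
  expect_equal(k_closing(mp)$K_closing, 0.5, tolerance = 1e-4)
})

test_that("rates from the matrix logarithm match per-tick rates", {
  clock <- 1e-7
  A <- diag(3)
  A[1, 2] <- 100 * clock; A[2, 1] <- 250 * clock
  A[1, 3] <- 30 * clock; A[3, 1] <- 200 * clock
  A[2, 3] <- 10 * clock; A[3, 2] <- 120 * clock
  diag(A) <- 0; diag(A) <- 1 - rowSums(A)
  m <- h2mm_model(rep(1 / 3, 3), A, rand_stoch(3, 3), clock)
  Q <- rates_from_model(m)
  expect_equal(Q[1, 2], 100, tolerance = 1e-4)
  expect_equal(Q[2, 1], 250, tolerance = 1e-4)
  expect_equal(diag(Q), -rowSums(Q - diag(diag(Q))), tolerance = 1e-9)
})

test_that("Viterbi dwells conserve burst counts and compute dwell E*/S", {
  # single-state burst: one dwell carrying every photon
  B <- rbind(c(0.45, 0.1, 0.45), c(0.05, 0.6, 0.35))
  A <- matrix(c(0.9999, 1e-4, 1e-4, 0.9999), 2, byrow = TRUE)
  m <- h2mm_model(c(0.99, 0.01), A, B, 1e-7)
  colors <- rep(c(1L, 3L), 10)
  ph <- make_photon_set(list(colors), list(c(0, rep(3, 19))))
  dw <- viterbi_dwells(m, ph)
  expect_equal(nrow(dw$dwells), 1L)
  expect_equal(dw$dwells$n_DD, 10L)
  expect_equal(dw$dwells$n_AA, 10L)
  # dwell with counts (1, 3) has E* = 0.75
  b2 <- data.frame(n_DD = 1L, n_DA = 3L, n_AA = 0L)
  expect_equal(compute_es(b2)$E_star, 0.75)
})

test_that("subset uncertainty: duplicated subsets give zero spread", {
  cfg <- sim_config(duration = 6, seed = 48)
  pl <- sim_pipeline(cfg)
  nb <- pl$photons$n_bursts
  # duplicate the same bursts so both subsets are identical
  ph2 <- burstdyn:::subset_photon_set(pl$photons, c(seq_len(nb), seq_len(nb)))
  fit <- fit_h2mm(pl$photons, 3, restarts = 1)
  su <- subset_uncertainty(ph2, subset_size = nb, K = 3, init = fit$model,
                           restarts = 1)
  expect_equal(su$n_subsets, 2L)
  expect_lt(su$sd_K_closing / su$K_closing, 1e-6)
  expect_error(subset_uncertainty(pl$photons, subset_size = nb, K = 3),
               "at least 2")
})
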