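test_that("background MLE recovers a homogeneous Poisson rate", {
  set.seed(10)
  t <- cumsum(rexp(2000 * 60, 2000)) / 1  # ~60 s at 2000 /s
  t <- t[t < 60]
  ps <- photon_stream(floor(t / 1e-7), rep(0L, length(t)), rep(0L, length(t)),
                      1e-7, 60)
  bg <- suppressWarnings(estimate_background(ps, interval = 50))
  r_all <- bg$rate[bg$stream == "all"]
  expect_true(all(abs(r_all - 2000) / 2000 < 0.05))
})

test_that("short acquisitions give a single background interval", {
  set.seed(11)
  t <- sort(runif(3000, 0, 49))
  ps <- photon_stream(floor(t / 1e-7), rep(0L, 3000), rep(0L, 3000), 1e-7, 49)
  bg <- suppressWarnings(estimate_background(ps, interval = 50))
  expect_equal(max(bg$interval), 1L)
  expect_true(all(bg$t_start == 0) && all(bg$t_stop >= 49))
})

test_that("tail fit excludes burst photons from the background estimate", {
  cfg <- sim_config(duration = 10, seed = 12)
  st <- simulate_photon_stream(cfg)
  bg <- estimate_background(st)
  naive <- length(st$timestamps) / st$duration
  expect_lt(bg$rate[bg$stream == "all"][1L], naive)
})

test_that("burst search finds a hand-constructed photon cluster", {
  set.seed(13)
  t_bg <- sort(runif(60 * 1000, 0, 60))           # 1 kHz background
  t_cl <- 30 + cumsum(rexp(50, 1e5))              # 50-photon 100 kHz cluster
  ps <- make_stream(c(t_bg, t_cl), rep("DD", length(t_bg) + 50), duration = 60)
  bg <- suppressWarnings(estimate_background(ps))
  bursts <- burst_search(ps, m = 10, background = bg, channel = "all")
  expect_equal(nrow(bursts), 1L)
  expect_lte(bursts$t_start, t_cl[1L])
  expect_gte(bursts$t_stop, t_cl[50L])
  # bursts from a single-channel search are disjoint photon spans
  expect_true(all(diff(as.vector(rbind(bursts$i_start, bursts$i_stop))) >= 0))
})

test_that("a 9-photon cluster fails the m = 10 criterion", {
  # isolated 9-photon spike; background photons too far to complete a window
  t_cl <- 30 + seq_len(9) * 1e-5
  t_far <- c(10, 20, 40, 50)
  ps <- make_stream(c(t_far, t_cl), rep("DD", 13), duration = 60)
  bg <- make_bg_table(rate = 5000, duration = 60)
  expect_equal(nrow(burst_search(ps, m = 10, background = bg,
                                 channel = "all")), 0L)
  # the same spike with one more photon passes
  t_cl10 <- 30 + seq_len(10) * 1e-5
  ps10 <- make_stream(c(t_far, t_cl10), rep("DD", 14), duration = 60)
  expect_equal(nrow(burst_search(ps10, m = 10, background = bg,
                                 channel = "all")), 1L)
})

test_that("uniform Poisson photons produce essentially no false bursts", {
  set.seed(15)
  t <- sort(runif(60 * 2000, 0, 60))
  ps <- make_stream(t, rep("DD", length(t)), duration = 60)
  bg <- suppressWarnings(estimate_background(ps))
  bursts <- burst_search(ps, m = 10, F = 15, background = bg, channel = "all")
  expect_lte(nrow(bursts), 1L)
})

test_that("burst search requires a positive background", {
  ps <- make_stream(sort(runif(100, 0, 1)), rep("DD", 100))
  expect_error(burst_search(ps, background = NULL), "background")
})

test_that("dual-channel search screens out donor-only species", {
  cfg <- sim_config(duration = 10, species_fractions = c(0, 1, 0), seed = 16)
  st <- simulate_photon_stream(cfg)
  bg <- estimate_background(st)
  d_only <- burst_search(st, background = bg, channel = "donor")
  expect_gt(nrow(d_only), 10)          # plenty of donor-channel bursts
  expect_equal(nrow(dual_channel_burst_search(st, background = bg)), 0L)
})

test_that("dual-channel intersections are contained in both parent spans", {
  cfg <- sim_config(duration = 10, seed = 17)
  st <- simulate_photon_stream(cfg)
  bg <- estimate_background(st)
  bd <- burst_search(st, background = bg, channel = "donor")
  ba <- burst_search(st, background = bg, channel = "acceptor")
  dc <- dual_channel_burst_search(st, background = bg)
  expect_gt(nrow(dc), 0)
  for (i in seq_len(nrow(dc))) {
    in_d <- any(bd$t_start <= dc$t_start[i] + 1e-12 &
                  bd$t_stop >= dc$t_stop[i] - 1e-12)
    in_a <- any(ba$t_start <= dc$t_start[i] + 1e-12 &
                  ba$t_stop >= dc$t_stop[i] - 1e-12)
    expect_true(in_d && in_a)
  }
})

test_that("one long donor burst against two acceptor bursts intersects twice", {
  set.seed(20)
  dur <- 60
  t_bg_d <- sort(runif(dur * 1000, 0, dur))       # 1 kHz DD background
  t_bg_a <- sort(runif(dur * 1000, 0, dur))       # 1 kHz AA background
  t_long <- seq(30.0, 30.01, by = 1e-5)           # 100 kHz DD for 10 ms
  t_sh1 <- seq(30.001, 30.003, by = 1e-5)         # two AA clusters inside
  t_sh2 <- seq(30.005, 30.007, by = 1e-5)
  ps <- make_stream(c(t_bg_d, t_long, t_bg_a, t_sh1, t_sh2),
                    rep(c("DD", "AA"),
                        c(length(t_bg_d) + length(t_long),
                          length(t_bg_a) + length(t_sh1) + length(t_sh2))),
                    duration = dur)
  bg <- suppressWarnings(estimate_background(ps))
  dc <- dual_channel_burst_search(ps, background = bg)
  expect_equal(nrow(dc), 2L)
  expect_true(all(dc$t_start >= 30.0 & dc$t_stop <= 30.011))
})

test_that("count filters apply the printed thresholds inclusively", {
  b <- data.frame(burst_id = 1:3, i_start = 1L, i_stop = 1L,
                  t_start = 0, t_stop = 1, duration = 1,
                  n_DD = c(20L, 8L, 7L), n_DA = c(5L, 7L, 7L),
                  n_AA = c(3L, 15L, 20L))
  b <- compute_es(b)
  out <- filter_bursts(b)
  expect_equal(out$burst_id, 2L)       # (8,7,15) kept at the threshold
  expect_equal(unname(attr(out, "removed")["aa"]), 1L)
  expect_equal(unname(attr(out, "removed")["donor_exc"]), 1L)
  # idempotent
  expect_equal(nrow(filter_bursts(out)), 1L)
  # monotone: raising thresholds never adds bursts
  expect_lte(nrow(filter_bursts(b, 20, 20)), nrow(out) + 2L)
  expect_equal(nrow(filter_bursts(b, 30, 30)), 0L)
})

test_that("E* and S arithmetic matches the definitions", {
  b <- data.frame(n_DD = c(30L, 10L, 0L, 0L), n_DA = c(10L, 0L, 5L, 0L),
                  n_AA = c(40L, 3L, 0L, 0L))
  b <- compute_es(b)
  expect_equal(b$E_star[1L], 0.25)
  expect_equal(b$S[1L], 0.5)
  expect_equal(b$E_star[2L], 0)        # no acceptor signal
  expect_equal(b$E_star[3L], 1)        # acceptor-only donor excitation
  expect_equal(b$S[3L], 1)
  expect_true(is.na(b$E_star[4L]) && is.na(b$S[4L]))
  ok <- !is.na(b$E_star)
  expect_true(all(b$E_star[ok] >= 0 & b$E_star[ok] <= 1))
})

test_that("E* histogram recovers the generating mean of a static dataset", {
  cfg <- sim_config(duration = 20,
                    state_rates = matrix(0, 1, 1),
                    state_emission = state_emission_rates(0.15,
                                                          dark_state = FALSE),
                    seed = 18)
  pl <- sim_pipeline(cfg)
  h <- es_histogram(pl$bursts)
  expect_lt(abs(h$modal_e - 0.15), 0.05)
})

test_that("S-selection outside the data errors cleanly", {
  b <- data.frame(n_DD = rep(20L, 5), n_DA = rep(20L, 5), n_AA = rep(2L, 5))
  b <- compute_es(b)                   # S ~ 0.95 for all bursts
  expect_error(es_histogram(b, s_range = c(0.2, 0.8)), "no bursts")
})

test_that("a static mixture yields a bimodal E* histogram", {
  cfg <- sim_config(duration = 30,
                    state_rates = matrix(0, 2, 2),
                    state_emission = state_emission_rates(c(0.2, 0.8),
                                                          dark_state = FALSE),
                    seed = 19)
  pl <- sim_pipeline(cfg)
  h <- es_histogram(pl$bursts)
  modes <- histogram_modes(h)
  top2 <- sort(head(modes$center[modes$count > 0.2 * max(modes$count)], 2))
  expect_lt(abs(top2[1L] - 0.2), 0.06)
  expect_lt(abs(top2[2L] - 0.8), 0.06)
})
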