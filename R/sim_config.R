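#' Generative specification for synthetic photon streams
#'
#' Bundles everything needed to emulate a us-ALEX acquisition of freely
#' diffusing, doubly labelled molecules: the conformational/photophysical
#' state model (a continuous-time Markov rate matrix plus per-state detected
#' emission rates into the DD/DA/AA streams), the transit (burst) statistics,
#' the laser alternation, per-stream background, and the species mixture
#' (doubly labelled, donor-only, acceptor-only).
#'
#' Burst emission is modelled as a top-hat intensity window per molecule
#' transit (no diffusion-profile shaping); transits are placed by a Poisson
#' process with exponentially distributed durations.  The default state model
#' has an open (low-FRET) and a closed (high-FRET) conformation
#' interconverting on the millisecond timescale plus an acceptor-dark
#' (blinking) state that emits only donor-channel photons (E* ~ 0, S ~ 1).
#'
#' `duration` is rounded up to a whole number of alternation periods so that
#' background photons can be placed exactly within excitation windows.
#'
#' @param duration acquisition length, seconds.
#' @param alternation_period laser alternation period, seconds.
#' @param donor_fraction_of_period fraction of each period under donor
#'   excitation (donor window is `[0, f*P)`, acceptor window `[f*P, P)`).
#' @param clock_period timestamp resolution, seconds; must divide the
#'   alternation windows and be at most `alternation_period / 100`.
#' @param state_rates K x K matrix of transition rate constants (s^-1) among
#'   the states of the doubly labelled species; diagonal ignored.
#' @param state_emission K x 3 matrix of mean detected photon rates (s^-1)
#'   into streams DD, DA, AA while a molecule is in the confocal spot.  DD/DA
#'   rates apply during donor-excitation windows, AA during
#'   acceptor-excitation windows.
#' @param burst_rate molecule transits per second.
#' @param burst_duration_mean mean transit duration, seconds.
#' @param background_rates length-3 mean detected background rates (s^-1)
#'   for DD, DA, AA (averaged over the full acquisition).
#' @param species_fractions length-3 fractions of doubly labelled,
#'   donor-only, and acceptor-only transits; must sum to 1.
#' @param seed integer RNG seed recorded in the output metadata, or `NULL`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration = 60,
                       alternation_period = 25e-6,
                       donor_fraction_of_period = 0.5,
                       clock_period = 100e-9,
                       state_rates = three_state_rates(),
                       state_emission = state_emission_rates(),
                       burst_rate = 25,
                       burst_duration_mean = 1.5e-3,
                       background_rates = c(DD = 1500, DA = 1500, AA = 1500),
                       species_fractions = c(doubly = 0.75, donor_only = 0.15,
                                             acceptor_only = 0.10),
                       seed = NULL) {
  stopifnot(duration > 0, alternation_period > 0, burst_rate >= 0,
            burst_duration_mean > 0)
  if (donor_fraction_of_period <= 0 || donor_fraction_of_period >= 1) {
    stop("donor_fraction_of_period must lie strictly between 0 and 1")
  }
  if (clock_period > alternation_period / 100) {
    stop("clock_period must be at most alternation_period / 100")
  }
  state_rates <- validate_rate_matrix(state_rates)
  state_emission <- as.matrix(state_emission)
  if (nrow(state_emission) != nrow(state_rates) || ncol(state_emission) != 3) {
    stop("state_emission must be K x 3 (DD, DA, AA) matching state_rates")
  }
  if (any(state_emission < 0) || any(background_rates < 0)) {
    stop("emission and background rates must be non-negative")
  }
  if (length(background_rates) != 3) stop("background_rates must have length 3")
  if (length(species_fractions) != 3 ||
      abs(sum(species_fractions) - 1) > 1e-12 || any(species_fractions < 0)) {
    stop("species_fractions must be 3 non-negative fractions summing to 1")
  }
  half_ticks <- donor_fraction_of_period * alternation_period / clock_period
  if (abs(half_ticks - round(half_ticks)) > 1e-6) {
    warning("donor window is not a whole number of clock ticks; ",
            "quantization may move photons across window edges")
  }
  duration <- ceiling(duration / alternation_period - 1e-9) * alternation_period
  structure(list(
    duration = duration,
    alternation_period = alternation_period,
    donor_fraction_of_period = donor_fraction_of_period,
    clock_period = clock_period,
    state_rates = state_rates,
    state_emission = state_emission,
    burst_rate = burst_rate,
    burst_duration_mean = burst_duration_mean,
    background_rates = unname(background_rates),
    species_fractions = unname(species_fractions),
    seed = seed
  ), class = "sim_config")
}

validate_rate_matrix <- function(rates) {
  rates <- as.matrix(rates)
  if (nrow(rates) != ncol(rates)) stop("rate matrix must be square")
  off <- rates
  diag(off) <- 0
  if (any(!is.finite(off)) || any(off < 0)) {
    stop("off-diagonal transition rates must be finite and non-negative")
  }
  diag(rates) <- 0
  rates
}

#' Three-state rate matrix: open, closed, acceptor-dark
#'
#' Builds the conformational + photophysical rate matrix used as the default
#' generative model: open <-> closed interconversion at the supplied rates,
#' plus entry into and exit from an acceptor-dark (blinking) state.  The
#' closing equilibrium of the generated chain is
#' `k_open_closed / k_closed_open`.
#'
#' @param k_open_closed,k_closed_open conformational rates, s^-1.
#' @param k_dark rate of entering the acceptor-dark state from either
#'   conformation, s^-1.
#' @param k_recover total rate of leaving the dark state, s^-1 (split equally
#'   between the two conformations).
#' @return 3 x 3 rate matrix (states: open, closed, dark).
#' @export
three_state_rates <- function(k_open_closed = 0.221 * 300,
                              k_closed_open = 300,
                              k_dark = 30, k_recover = 300) {
  matrix(c(
    0,             k_open_closed, k_dark,
    k_closed_open, 0,             k_dark,
    k_recover / 2, k_recover / 2, 0
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("open", "closed", "dark"),
                  c("open", "closed", "dark")))
}

#' Per-state detected emission rates
#'
#' Converts per-state apparent FRET efficiencies into DD/DA/AA detected count
#' rates under a symmetric alternation: during donor-excitation windows the
#' molecule emits `rate_donor_exc` photons/s split between DD and DA according
#' to the state's E*; during acceptor-excitation windows it emits
#' `rate_acceptor_exc` photons/s into AA.  A final acceptor-dark row (all
#' donor-excitation photons in DD, no AA) is appended when `dark_state` is
#' `TRUE`.
#'
#' @param e_states apparent FRET efficiency of each conformational state.
#' @param rate_donor_exc,rate_acceptor_exc in-spot detected rates (s^-1)
#'   during the respective excitation windows.
#' @param dark_state append an acceptor-blinking row?
#' @return K x 3 matrix with columns DD, DA, AA.
#' @export
state_emission_rates <- function(e_states = c(open = 0.2, closed = 0.8),
                                 rate_donor_exc = 1e5,
                                 rate_acceptor_exc = 1e5,
                                 dark_state = TRUE) {
  stopifnot(all(e_states >= 0 & e_states <= 1))
  em <- cbind(DD = (1 - e_states) * rate_donor_exc,
              DA = e_states * rate_donor_exc,
              AA = rep(rate_acceptor_exc, length(e_states)))
  if (dark_state) {
    em <- rbind(em, dark = c(rate_donor_exc, 0, 0))
  }
  em
}

#' Write / read a simulation config as YAML
#'
#' @param config a [sim_config()].
#' @param path YAML file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$state_rates <- apply(unname(x$state_rates), 1, as.list)
  x$state_emission <- apply(unname(x$state_emission), 1, as.list)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$state_rates <- do.call(rbind, lapply(x$state_rates, unlist))
  x$state_emission <- do.call(rbind, lapply(x$state_emission, unlist))
  do.call(sim_config, x)
}
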