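#' Chase-kinetics model specification
#'
#' Mass-action models of substrate (TA) release from a chaperone-substrate
#' complex upon addition of an excess chase chaperone (CaM, cpSRP43, ...).
#' Two mechanisms are implemented:
#' \describe{
#'   \item{`"spontaneous"`}{the chase acts purely as a trap:
#'     `Sgt2-TA <-> Sgt2 + TA` (k1, k-1) followed by
#'     `TA + CaM <-> CaM-TA` (k2, k-2).  Release is rate-limited by
#'     spontaneous dissociation and independent of chase concentration.}
#'   \item{`"invasion"`}{the chase invades the complex directly:
#'     `Sgt2-TA + CaM <-> Sgt2-TA.CaM` (k1, k-1) followed by
#'     `Sgt2-TA.CaM <-> Sgt2 + CaM-TA` (k2, k-2).  Release accelerates
#'     with chase concentration.}
#' }
#' Units are minutes and micromolar throughout; second-order constants
#' printed as `M^-1 min^-1` must be supplied in `uM^-1 min^-1`
#' (`0.035e6 M^-1 min^-1` = `0.035 uM^-1 min^-1`).  Defaults are the
#' constants of the respective mechanism with a 0.05 uM preformed complex.
#'
#' @param variant `"spontaneous"` or `"invasion"`.
#' @param k1,km1,k2,km2 rate constants (min^-1 or uM^-1 min^-1 per role).
#' @param k_off optional spontaneous-leak channel for the invasion variant:
#'   a first-order `Sgt2-TA -> Sgt2 + TA` dissociation (min^-1) whose
#'   released substrate is sequestered by the excess chase (treated as
#'   terminal on the experiment timescale).  This reproduces the observed
#'   concentration dependence `k_obs = k_off + slope x [chase]` whose
#'   y-intercept is the intrinsic dissociation rate.  Default 0 (pure
#'   invasion).
#' @param conc0 named initial concentrations in uM; recognised species are
#'   `SgtTA`, `Sgt`, `TA`, `CaM`, `SgtTACaM`, `CaMTA`.
#' @return An object of class `chase_model`.
#' @export
chase_model <- function(variant = c("spontaneous", "invasion"),
                        k1 = NULL, km1 = NULL, k2 = NULL, km2 = NULL,
                        k_off = 0, conc0 = list()) {
  variant <- match.arg(variant)
  defaults <- if (variant == "spontaneous") {
    list(k1 = 0.015, km1 = 1, k2 = 10, km2 = 10)
  } else {
    list(k1 = 0.035, km1 = 1, k2 = 10, km2 = 20)
  }
  k1 <- k1 %||% defaults$k1; km1 <- km1 %||% defaults$km1
  k2 <- k2 %||% defaults$k2; km2 <- km2 %||% defaults$km2
  if (any(c(k1, km1, k2, km2, k_off) < 0)) stop("rate constants must be >= 0")
  if (variant == "spontaneous" && k_off > 0) {
    stop("k_off applies to the invasion variant only (it IS k1 here)")
  }
  y0 <- c(SgtTA = 0.05, Sgt = 0, TA = 0, CaM = 0, SgtTACaM = 0, CaMTA = 0)
  for (nm in names(conc0)) {
    if (!nm %in% names(y0)) stop("unknown species: ", nm)
    y0[nm] <- conc0[[nm]]
  }
  if (any(y0 < 0)) stop("concentrations must be >= 0")
  structure(list(variant = variant, k1 = k1, km1 = km1, k2 = k2, km2 = km2,
                 k_off = k_off, conc0 = y0), class = "chase_model")
}

total_ta <- function(y) unname(y["SgtTA"] + y["TA"] + y["SgtTACaM"] + y["CaMTA"])

#' Integrate a chase-kinetics model
#'
#' Stiff-capable integration (lsoda, relative tolerance 1e-9) of the
#' mass-action equations, converted to a normalized-fluorescence readout:
#' for the spontaneous (trap) mechanism
#' `F = 1 - [Sgt2-TA]/([Sgt2-TA] + [CaM-TA] + [TA])`, and for the invasion
#' mechanism `F = 1 - [Sgt2-TA]/([Sgt2-TA] + [Sgt2-TA.CaM] + [CaM-TA])`.
#' Total TA is conserved to 1e-9 relative; a larger drift or a negative
#' concentration aborts with a diagnostic.
#'
#' @param model a [chase_model()].
#' @param times time grid, minutes (increasing).
#' @return A data frame of class `trace`: `time` (min), `F` (normalized
#'   fluorescence), plus species concentrations.
#' @export
simulate_release <- function(model, times) {
  stopifnot(inherits(model, "chase_model"), length(times) >= 2,
            all(diff(times) > 0))
  y0 <- model$conc0
  p <- model[c("k1", "km1", "k2", "km2", "k_off")]
  deriv <- if (model$variant == "spontaneous") {
    function(t, y, p) {
      v1 <- p$k1 * y["SgtTA"] - p$km1 * y["Sgt"] * y["TA"]
      v2 <- p$k2 * y["TA"] * y["CaM"] - p$km2 * y["CaMTA"]
      list(c(SgtTA = -v1, Sgt = v1, TA = v1 - v2, CaM = -v2,
             SgtTACaM = 0, CaMTA = v2))
    }
  } else {
    function(t, y, p) {
      v1 <- p$k1 * y["SgtTA"] * y["CaM"] - p$km1 * y["SgtTACaM"]
      v2 <- p$k2 * y["SgtTACaM"] - p$km2 * y["Sgt"] * y["CaMTA"]
      v0 <- p$k_off * y["SgtTA"]      # leak: chase-sequestered free substrate
      list(c(SgtTA = -v1 - v0, Sgt = v2 + v0, TA = v0, CaM = -v1 + v2,
             SgtTACaM = v1 - v2, CaMTA = v2))
    }
  }
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = p,
                      method = "lsoda", rtol = 1e-9, atol = 1e-12)
  sol <- as.data.frame(sol)
  tot0 <- total_ta(y0)
  if (tot0 > 0) {
    tot <- sol$SgtTA + sol$TA + sol$SgtTACaM + sol$CaMTA
    drift <- max(abs(tot - tot0)) / tot0
    if (drift > 1e-9) stop("TA mass conservation violated (relative drift ",
                           format(drift), ")")
  }
  if (min(sol[-1]) < -1e-9) stop("integrator produced negative concentrations")
  denom <- if (model$variant == "spontaneous") {
    sol$SgtTA + sol$CaMTA + sol$TA
  } else {
    # free TA only arises through the optional leak channel; with k_off = 0
    # this is the plain invasion readout
    sol$SgtTA + sol$SgtTACaM + sol$CaMTA + sol$TA
  }
  Fv <- ifelse(denom > 0, 1 - sol$SgtTA / denom, 0)
  out <- data.frame(time = sol$time, F = Fv, sol[-1])
  class(out) <- c("trace", "data.frame")
  out
}

#' Simulate a noisy chase trace
#'
#' Integrates the model and adds i.i.d. Gaussian noise to the normalized
#' fluorescence.
#'
#' @param model a [chase_model()].
#' @param times time grid, minutes.
#' @param noise_sd Gaussian noise standard deviation (fraction of full
#'   scale).
#' @param seed optional seed.
#' @return A `trace` data frame (`time`, `F`).
#' @export
simulate_chase_trace <- function(model, times, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- simulate_release(model, times)
  out <- data.frame(time = tr$time, F = tr$F + rnorm(length(tr$F), 0, noise_sd))
  class(out) <- c("trace", "data.frame")
  out
}

#' Single-exponential fit of a normalized chase trace
#'
#' Nonlinear least squares of `F = A (1 - exp(-k t))`.  A lag-1 residual
#' autocorrelation above 0.5 is flagged as systematic misfit (e.g. data that
#' are really biphasic).
#'
#' @param trace a data frame with `time` (min) and `F`.
#' @return list of class `exp_fit`: `A`, `k` (min^-1), standard errors,
#'   `residuals`, `misfit_flag`, and the `nls` object.
#' @export
fit_single_exp <- function(trace) {
  stopifnot(nrow(trace) >= 5)
  df <- data.frame(t = trace$time, y = trace$F)
  A0 <- max(df$y)
  if (A0 <= 0) A0 <- 1
  k0 <- init_rate_guess(df)
  fit <- minpack.lm::nlsLM(y ~ A * (1 - exp(-k * t)), data = df,
                           start = list(A = A0, k = k0),
                           lower = c(0, 1e-12),
                           control = nls.control(maxiter = 200))
  co <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  res <- stats::residuals(fit)
  ac <- if (length(res) >= 10 && sd(res) > 0) {
    stats::cor(res[-1], res[-length(res)])
  } else 0
  structure(list(A = unname(co["A"]), k = unname(co["k"]),
                 se_A = unname(se["A"]), se_k = unname(se["k"]),
                 residuals = res, residual_autocorr = ac,
                 misfit_flag = is.finite(ac) && ac > 0.5, fit = fit),
            class = "exp_fit")
}

init_rate_guess <- function(df) {
  # time to half the final amplitude
  yf <- df$y[which.max(df$t)]
  if (yf <= 0) return(0.1)
  i <- which(df$y >= yf / 2)[1]
  t_half <- if (is.na(i) || df$t[i] <= 0) max(df$t) / 4 else df$t[i]
  log(2) / t_half
}

#' Double-exponential fit of a normalized chase trace
#'
#' Nonlinear least squares of
#' `F = A_fast (1 - exp(-k_fast t)) + A_slow (1 - exp(-k_slow t))` with the
#' ordering `k_fast > k_slow` enforced by relabelling.  If either amplitude
#' is below 1% of the total, or the two rates are nearly equal, a
#' single-exponential description is recommended via a warning.
#'
#' @param trace a data frame with `time` (min) and `F`.
#' @return list of class `exp_fit2`: `A_fast`, `k_fast`, `A_slow`, `k_slow`,
#'   standard errors, `residuals`, `degenerate`, and the `nls` object.
#' @export
fit_double_exp <- function(trace) {
  stopifnot(nrow(trace) >= 8)
  df <- data.frame(t = trace$time, y = trace$F)
  A0 <- max(df$y)
  if (A0 <= 0) A0 <- 1
  k0 <- init_rate_guess(df)
  fit <- minpack.lm::nlsLM(
    y ~ Af * (1 - exp(-kf * t)) + As * (1 - exp(-ks * t)), data = df,
    start = list(Af = A0 / 2, kf = k0 * 5, As = A0 / 2, ks = k0 / 5),
    lower = c(0, 1e-12, 0, 1e-12),
    control = nls.control(maxiter = 500))
  co <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  if (co["kf"] < co["ks"]) {   # enforce k_fast > k_slow by relabelling
    co <- co[c("As", "ks", "Af", "kf")]
    se <- se[c("As", "ks", "Af", "kf")]
    names(co) <- names(se) <- c("Af", "kf", "As", "ks")
  }
  tot <- co["Af"] + co["As"]
  degenerate <- FALSE
  if (tot > 0 && (co["Af"] / tot < 0.01 || co["As"] / tot < 0.01)) {
    warning("one phase has < 1% amplitude; a single exponential may suffice")
    degenerate <- TRUE
  }
  if (co["kf"] <= 1.05 * co["ks"]) {
    warning("rate constants nearly equal; fit is degenerate - ",
            "consider fit_single_exp()")
    degenerate <- TRUE
  }
  structure(list(A_fast = unname(co["Af"]), k_fast = unname(co["kf"]),
                 A_slow = unname(co["As"]), k_slow = unname(co["ks"]),
                 se = se, residuals = stats::residuals(fit),
                 degenerate = degenerate, fit = fit),
            class = "exp_fit2")
}

#' Observed release rate versus chase concentration
#'
#' Ordinary least-squares line through (chase concentration, k_obs).  The
#' intercept estimates the intrinsic (spontaneous) dissociation rate; the
#' slope estimates the second-order invasion constant.
#'
#' @param concentrations chase concentrations (uM), length >= 3.
#' @param k_obs observed rate constants (min^-1).
#' @return list: `slope` (uM^-1 min^-1), `intercept` (min^-1), their
#'   standard errors, and the `lm` fit.
#' @export
kobs_vs_chase <- function(concentrations, k_obs) {
  if (length(concentrations) < 3) {
    stop("need at least 3 chase concentrations")
  }
  stopifnot(length(concentrations) == length(k_obs))
  fit <- lm(k_obs ~ concentrations)
  co <- coef(fit)
  se <- suppressWarnings(sqrt(diag(vcov(fit))))  # exact fits have zero RSS
  list(slope = unname(co[2L]), intercept = unname(co[1L]),
       se_slope = unname(se[2L]), se_intercept = unname(se[1L]), fit = fit)
}

#' Hyperbolic solubilization fit
#'
#' Fits `S_obsd = S_Max [chaperone] / (K_soluble + [chaperone])`, the
#' apparent substrate solubilization isotherm.  If the largest concentration
#' does not reach twice the fitted `K_soluble`, the data do not constrain
#' saturation and a warning is issued.
#'
#' @param concs chaperone concentrations (uM), length >= 4.
#' @param s_obsd observed percent solubilized.
#' @return list of class `solubilization_fit`: `S_max` (%), `K_soluble`
#'   (uM), standard errors, and the `nls` object.
#' @export
fit_solubilization <- function(concs, s_obsd) {
  stopifnot(length(concs) >= 4, length(concs) == length(s_obsd))
  df <- data.frame(c = concs, s = s_obsd)
  fit <- minpack.lm::nlsLM(s ~ Smax * c / (K + c), data = df,
                           start = list(Smax = max(df$s), K = median(df$c)),
                           lower = c(0, 1e-9),
                           control = nls.control(maxiter = 200))
  co <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  if (max(concs) < 2 * co["K"]) {
    warning("no saturation in the data; K_soluble is poorly constrained")
  }
  structure(list(S_max = unname(co["Smax"]), K_soluble = unname(co["K"]),
                 se_S_max = unname(se["Smax"]), se_K_soluble = unname(se["K"]),
                 fit = fit),
            class = "solubilization_fit")
}
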