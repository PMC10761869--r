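#' End-to-end run configuration
#'
#' Collects every analysis parameter at its standard default: burst search
#' m = 10 photons at F = 15-fold over 50-s background intervals, count
#' filters at 15 photons, S-selection 0.2 to 0.8, sub-bursts of 5 photons
#' over 20 x 0.05 E* bins with a 2.5% bin threshold, models up to 5 states,
#' and uncertainty subsets of 1700-2000 bursts.
#'
#' @param sim a [sim_config()] to simulate, or `NULL` if `input` is given.
#' @param input path to a columnar photon file (ignored when `sim` given).
#' @param out_dir output directory for the report bundle.
#' @param m,F burst-search window and rate threshold.
#' @param bg_interval background interval, seconds.
#' @param s_range stoichiometry selection.
#' @param hist_bin_width E* histogram bin width.
#' @param n_sub BVA sub-burst size.
#' @param bva_bins,bva_min_fraction BVA binning parameters.
#' @param k_states states fitted for the kinetic model (3: open, closed,
#'   photophysical).
#' @param select_k also run ICL model selection up to `k_max`?
#' @param k_max largest model for selection.
#' @param tol,max_iter,restarts EM settings.
#' @param subset_size bursts per uncertainty subset.
#' @param seed seed for simulation and fitting.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = NULL, input = NULL, out_dir = tempfile("burstdyn_"),
                       m = 10L, F = 15, bg_interval = 50,
                       s_range = c(0.2, 0.8), hist_bin_width = 0.035,
                       n_sub = 5L, bva_bins = 20L, bva_min_fraction = 0.025,
                       k_states = 3L, select_k = FALSE, k_max = 5L,
                       tol = 1e-7, max_iter = 1000L, restarts = 5L,
                       subset_size = 1850L, seed = 1L) {
  if (is.null(sim) && is.null(input)) stop("either sim or input is required")
  structure(as.list(environment()), class = "run_config")
}

#' Run the full burst-analysis pipeline
#'
#' Simulates (or reads) a photon stream, estimates background, runs the
#' dual-channel burst search and count filters, builds the S-selected E*
#' histogram, burst variance analysis, and the photon-by-photon hidden
#' Markov fit with closing-equilibrium and (data permitting) subset-based
#' uncertainties, writing each product to `out_dir`:
#' `burst_table.csv`, `es_histogram.csv`, `bva.csv`, `h2mm.json`,
#' `provenance.json`.  Failures abort with the stage name; products of
#' completed stages are preserved.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory results (`stream`,
#'   `background`, `bursts`, `histogram`, `bva`, `fit`, `k_closing`,
#'   `uncertainty`, `selection`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  res$stream <- stage("input", {
    if (!is.null(config$sim)) {
      cfg <- config$sim
      cfg$seed <- cfg$seed %||% config$seed
      simulate_photon_stream(cfg)
    } else {
      read_photons(config$input)
    }
  })

  res$background <- stage("background",
    estimate_background(res$stream, interval = config$bg_interval))

  res$bursts <- stage("burst_search", {
    b <- dual_channel_burst_search(res$stream, m = config$m, F = config$F,
                                   background = res$background)
    filter_bursts(b)
  })
  write.csv(res$bursts[, c("burst_id", "t_start", "t_stop", "n_DD", "n_DA",
                           "n_AA", "E_star", "S")],
            file.path(config$out_dir, "burst_table.csv"), row.names = FALSE)

  res$histogram <- stage("histogram",
    es_histogram(res$bursts, s_range = config$s_range,
                 bin_width = config$hist_bin_width))
  write.csv(res$histogram$table,
            file.path(config$out_dir, "es_histogram.csv"), row.names = FALSE)

  res$bva <- stage("bva", {
    bv <- burst_sd(res$stream, res$bursts, n_sub = config$n_sub)
    binned_sd(bv, n_bins = config$bva_bins,
              min_fraction = config$bva_min_fraction)
  })
  write.csv(res$bva, file.path(config$out_dir, "bva.csv"), row.names = FALSE)

  res$fit <- stage("h2mm", {
    sel <- res$bursts[!is.na(res$bursts$S) &
                        res$bursts$S >= config$s_range[1L] &
                        res$bursts$S <= config$s_range[2L], , drop = FALSE]
    ph <- burst_photons(res$stream, sel)
    if (config$select_k) {
      res$selection <- select_model(ph, K_max = config$k_max,
                                    tol = config$tol,
                                    max_iter = config$max_iter,
                                    restarts = config$restarts,
                                    seed = config$seed)
      res$selection$best
    } else {
      fit_h2mm(ph, config$k_states, tol = config$tol,
               max_iter = config$max_iter, restarts = config$restarts,
               seed = config$seed)
    }
  })
  res$photons <- stage("h2mm", {
    sel <- res$bursts[!is.na(res$bursts$S) &
                        res$bursts$S >= config$s_range[1L] &
                        res$bursts$S <= config$s_range[2L], , drop = FALSE]
    burst_photons(res$stream, sel)
  })

  res$k_closing <- stage("k_closing", k_closing(res$fit))
  res$uncertainty <- if (res$photons$n_bursts >= 2L * config$subset_size) {
    stage("uncertainty",
          subset_uncertainty(res$photons, subset_size = config$subset_size,
                             K = res$fit$K, init = res$fit$model,
                             tol = config$tol, max_iter = config$max_iter,
                             restarts = 1L))
  } else NULL

  es <- state_es(res$fit$model)
  h2mm_out <- list(
    K = res$fit$K, loglik = res$fit$loglik, converged = res$fit$converged,
    ICL = icl(res$fit, res$photons),
    pi = res$fit$model$pi, A = res$fit$model$A, B = res$fit$model$B,
    rates_per_s = rates_from_model(res$fit$model),
    E_state = es$E_state, S_state = es$S_state,
    K_closing = res$k_closing$K_closing,
    k_open_closed = res$k_closing$k_open_closed,
    k_closed_open = res$k_closing$k_closed_open,
    sd_K_closing = res$uncertainty$sd_K_closing
  )
  jsonlite::write_json(h2mm_out, file.path(config$out_dir, "h2mm.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")

  prov <- list(
    package = "burstdyn",
    version = as.character(utils::packageVersion("burstdyn")),
    seed = config$seed,
    parameters = config[c("m", "F", "bg_interval", "s_range",
                          "hist_bin_width", "n_sub", "bva_bins",
                          "bva_min_fraction", "k_states", "k_max", "tol",
                          "max_iter", "restarts", "subset_size")],
    n_bursts = nrow(res$bursts)
  )
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
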