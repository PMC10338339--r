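#' Configuration of a simulated PCQLS run
#'
#' Collects every physical and instrumental parameter of the heralded
#' single-photon experiment the simulator emulates. Defaults are the
#' operating point of the modelled experiment: a 75.7-MHz pulsed pair
#' source at mean pair number `n_p` = 0.0458 per pulse, a herald arm whose
#' detection probability reproduces the printed herald rate, a lumped
#' heralded-fluorescence channel efficiency of 1.244e-4, a 1.2-ns
#' fluorescence lifetime and 150-ps (1 s.d.) Gaussian detector jitter.
#'
#' @param R_r pump repetition rate (Hz).
#' @param n_p mean photon pairs generated per pump pulse.
#' @param eta_herald herald-arm detection probability per photon. The
#'   default is calibrated so that the *click* rate of the
#'   non-number-resolving herald detector,
#'   `R_r * n_p * eta / (1 + n_p * eta)` under thermal pair statistics,
#'   reproduces a printed herald rate of 9.73e5 counts per second at
#'   n_p = 0.0458; it is therefore slightly above the naive ratio
#'   R_h / R_p = 0.2804, which ignores the click saturation of
#'   multi-pair pulses.
#' @param p_detect_fluor per-incident-photon probability of registering a
#'   fluorescence detection. Lumps sample transmission, absorption, energy
#'   transfer, emission quantum yield, collection, filters and detector
#'   efficiency; to first order it equals the observable channel efficiency
#'   e_hf = R_hf / R_h.
#' @param p_detect_residue per-photon probability of a click on the
#'   incident-residue monitor (channel 0), used for IRF estimation;
#'   0 disables the channel.
#' @param tau_fl fluorescence lifetime (ps).
#' @param irf_sigma Gaussian timing-jitter s.d. per detection (ps). The
#'   herald-fluorescence delay axis therefore carries jitter
#'   `sqrt(2) * irf_sigma`, since both tags jitter independently.
#' @param gate_fluor fluorescence gate length after each herald (ps).
#' @param gate_incident incident-photon gate length (ps).
#' @param dark_rates named or unnamed numeric vector of per-detector Poisson
#'   dark-count rates (counts per second) for channels 0..3; a scalar is
#'   recycled.
#' @param dead_time per-detector dead time (ps); tags within `dead_time`
#'   after an accepted tag on the same detector are dropped. The default 0
#'   matches an analysis that never corrects for dead time.
#' @param splitter logical; `TRUE` routes detected sample-channel photons
#'   50:50 to detectors 2 and 3 (three-detector g2 mode), `FALSE` sends all
#'   to detector 2.
#' @param fluorescence logical; `TRUE` delays each sample-channel detection
#'   by an exponential fluorescence delay, `FALSE` emulates the no-sample
#'   variant in which incident photons are detected directly (jitter only).
#' @param duration_s acquisition duration (s).
#' @param seed integer RNG seed for reproducible streams.
#' @return an object of class `experiment_config` (named list).
#' @examples
#' cfg <- experiment_config(duration_s = 0.05, seed = 1)
#' @export
experiment_config <- function(R_r = 75.7e6,
                              n_p = 0.0458,
                              eta_herald = herald_efficiency_for_rate(),
                              p_detect_fluor = 1.244e-4,
                              p_detect_residue = 0,
                              tau_fl = 1200,
                              irf_sigma = 150,
                              gate_fluor = 10000,
                              gate_incident = 6000,
                              dark_rates = 0,
                              dead_time = 0,
                              splitter = FALSE,
                              fluorescence = TRUE,
                              duration_s = 1,
                              seed = 1L) {
  if (length(dark_rates) == 1L) dark_rates <- rep(dark_rates, 4L)
  if (is.null(names(dark_rates))) names(dark_rates) <- as.character(0:3)
  cfg <- list(R_r = R_r, n_p = n_p, eta_herald = eta_herald,
              p_detect_fluor = p_detect_fluor,
              p_detect_residue = p_detect_residue,
              tau_fl = tau_fl, irf_sigma = irf_sigma,
              gate_fluor = gate_fluor, gate_incident = gate_incident,
              dark_rates = dark_rates, dead_time = dead_time,
              splitter = isTRUE(splitter), fluorescence = isTRUE(fluorescence),
              duration_s = duration_s, seed = as.integer(seed))
  class(cfg) <- "experiment_config"
  validate_config(cfg)
  cfg
}

#' Herald-arm efficiency reproducing a printed herald click rate
#'
#' Inverts the click-rate relation of a non-number-resolving herald
#' detector viewing one arm of a thermal pair source,
#' `R_h = R_r * (1 - E[(1 - eta)^M]) = R_r * n_p * eta / (1 + n_p * eta)`,
#' for the per-photon efficiency `eta`. Defaults solve for the printed
#' operating point R_h = 9.73e5 counts per second at n_p = 0.0458 and
#' R_r = 75.7 MHz, giving eta of about 0.2843 (the naive ratio
#' R_h / R_p = 0.2804 neglects click saturation of multi-pair pulses).
#'
#' @param R_h target herald click rate (counts per second).
#' @param R_r pump repetition rate (Hz).
#' @param n_p mean pairs per pulse.
#' @return per-photon herald-arm detection probability.
#' @export
herald_efficiency_for_rate <- function(R_h = 9.73e5, R_r = 75.7e6,
                                       n_p = 0.0458) {
  r <- R_h / R_r
  if (r >= n_p / (1 + n_p))
    stop("target click rate unreachable: exceeds the occupied-pulse rate")
  r / (1 - r) / n_p
}

validate_config <- function(cfg) {
  with(cfg, {
    if (R_r <= 0) stop("R_r must be positive")
    if (n_p < 0) stop("n_p must be non-negative")
    for (p in c(eta_herald, p_detect_fluor, p_detect_residue))
      if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
    if (tau_fl <= 0) stop("tau_fl must be positive")
    if (irf_sigma < 0 || gate_fluor <= 0 || gate_incident <= 0 ||
        dead_time < 0 || any(dark_rates < 0))
      stop("rates and times must be non-negative (gates positive)")
    if (duration_s <= 0) stop("duration_s must be positive")
    if (duration_s * R_r < 1) stop("duration must cover at least one pulse")
    if (duration_s * 1e12 >= 2^53)
      stop("duration exceeds exact integer-picosecond range (about 2.5 h)")
  })
  invisible(cfg)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config>\n")
  cat(sprintf("  R_r = %g Hz, n_p = %g, eta_herald = %.4g\n",
              x$R_r, x$n_p, x$eta_herald))
  cat(sprintf("  p_detect_fluor = %.4g, tau_fl = %g ps, irf_sigma = %g ps\n",
              x$p_detect_fluor, x$tau_fl, x$irf_sigma))
  cat(sprintf("  splitter = %s, fluorescence = %s, duration = %g s, seed = %d\n",
              x$splitter, x$fluorescence, x$duration_s, x$seed))
  invisible(x)
}

# run code under a private RNG stream without disturbing the caller's RNG
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# sorted 1-based indices of pulses containing >= 1 pair, by exact geometric
# inter-occurrence gaps (avoids materializing all n_pulses Bernoulli draws)
occupied_pulses <- function(n_pulses, q) {
  if (q <= 0) return(numeric(0))
  pos <- numeric(0)
  last <- 0
  expected <- n_pulses * q
  repeat {
    n_draw <- max(1000, ceiling(expected - length(pos) +
                                  6 * sqrt(expected + 1)))
    gaps <- stats::rgeom(n_draw, q)
    new <- last + cumsum(as.numeric(gaps) + 1)
    keep <- new <= n_pulses
    pos <- c(pos, new[keep])
    if (!all(keep) || n_draw == 0) break
    last <- new[length(new)]
    if (last >= n_pulses) break
  }
  pos
}

# enforce detector dead time on a sorted time vector (ps): scalar scan,
# a tag is dropped when within `dead` of the last *accepted* tag
apply_dead_time <- function(t, dead) {
  if (dead <= 0 || length(t) < 2L) return(t)
  if (all(diff(t) > dead)) return(t)
  keep <- logical(length(t))
  keep[1L] <- TRUE
  last_t <- t[1L]
  for (i in 2:length(t)) {
    if (t[i] - last_t > dead) {
      keep[i] <- TRUE
      last_t <- t[i]
    }
  }
  t[keep]
}

#' Simulate a PCQLS time-tag stream by stochastic trajectories
#'
#' Monte Carlo model of the full experiment. For each pump pulse k at
#' `t_k = k / R_r`, the number of pairs M is drawn from the thermal
#' distribution [pair_number_pmf()]; the herald detector (a
#' non-number-resolving click detector, at most one tag per pulse) fires
#' with probability `1 - (1 - eta_herald)^M` at `t_k` plus Gaussian jitter;
#' each of the M signal photons independently yields a detected
#' fluorescence with probability `p_detect_fluor`, time-tagged at `t_k`
#' plus an exponential emission delay of mean `tau_fl` plus Gaussian
#' jitter, routed 50:50 to channels 2/3 in splitter mode (else channel 2).
#' Optionally a residue monitor (channel 0) clicks per photon with
#' `p_detect_residue` at `t_k` plus jitter. Homogeneous Poisson dark counts
#' are superposed per detector and dead-time shadowing applied. Only pulses
#' containing at least one pair are ever materialized, so the cost scales
#' with the occupied-pulse count, not the pulse count.
#'
#' With a fixed `seed` the output is bit-reproducible.
#'
#' @param config an [experiment_config()].
#' @param log logical; additionally return a per-occupied-pulse trajectory
#'   log (pairs generated, herald click, fluorescence detections with true
#'   emission delays). Only sensible for small runs.
#' @return a [tag_stream()] (with the generating config and seed in
#'   `meta`); if `log = TRUE`, a list with elements `stream` and
#'   `trajectories` (a data.frame).
#' @examples
#' s <- simulate_stream(experiment_config(duration_s = 0.01, seed = 7))
#' stream_rates(s)
#' @export
simulate_stream <- function(config, log = FALSE) {
  validate_config(config)
  with_seed(config$seed, {
    n_pulses <- floor(config$duration_s * config$R_r)
    period_ps <- 1e12 / config$R_r
    q <- config$n_p / (1 + config$n_p)   # P(M >= 1), thermal
    pos <- occupied_pulses(n_pulses, q)
    K <- length(pos)
    t_pulse <- (pos - 1) * period_ps
    chan <- integer(0); tim <- numeric(0)
    M <- integer(0); herald <- integer(0); k_fl <- integer(0)
    if (K > 0) {
      # M | M >= 1 is 1 + Geom by memorylessness of the thermal law
      M <- 1L + stats::rgeom(K, 1 / (1 + config$n_p))
      herald <- stats::rbinom(K, 1L, 1 - (1 - config$eta_herald)^M)
      hsel <- herald == 1L
      t_h <- t_pulse[hsel] + stats::rnorm(sum(hsel), 0, config$irf_sigma)
      chan <- c(chan, rep(1L, length(t_h)))
      tim <- c(tim, t_h)
      # detected sample-channel photons; detectors are click detectors, so
      # at most one tag per pulse per channel survives (earliest arrival)
      k_fl <- stats::rbinom(K, M, config$p_detect_fluor)
      n_det <- sum(k_fl)
      if (n_det > 0) {
        pulse_id <- rep(seq_len(K), k_fl)
        t0 <- t_pulse[pulse_id]
        delay_true <- if (config$fluorescence)
          stats::rexp(n_det, rate = 1 / config$tau_fl) else numeric(n_det)
        t_f <- t0 + delay_true + stats::rnorm(n_det, 0, config$irf_sigma)
        ch_f <- if (config$splitter) 2L + stats::rbinom(n_det, 1L, 0.5)
                else rep(2L, n_det)
        o <- order(pulse_id, ch_f, t_f)
        key <- pulse_id[o] * 4 + ch_f[o]
        first <- c(TRUE, diff(key) != 0)
        chan <- c(chan, ch_f[o][first])
        tim <- c(tim, t_f[o][first])
      }
      if (config$p_detect_residue > 0) {
        k_r <- stats::rbinom(K, M, config$p_detect_residue)
        hit_r <- k_r > 0L   # click detector: one tag per pulse
        n_r <- sum(hit_r)
        if (n_r > 0) {
          t_r <- t_pulse[hit_r] + stats::rnorm(n_r, 0, config$irf_sigma)
          chan <- c(chan, rep(0L, n_r))
          tim <- c(tim, t_r)
        }
      }
    }
    # dark counts: homogeneous Poisson per detector
    dur_ps <- config$duration_s * 1e12
    for (d in seq_along(config$dark_rates)) {
      rate <- config$dark_rates[[d]]
      if (rate > 0) {
        nd <- stats::rpois(1, rate * config$duration_s)
        if (nd > 0) {
          chan <- c(chan, rep(as.integer(names(config$dark_rates)[d]), nd))
          tim <- c(tim, stats::runif(nd, 0, dur_ps))
        }
      }
    }
    tim <- round(tim)
    ok <- tim >= 0 & tim <= dur_ps
    chan <- chan[ok]; tim <- tim[ok]
    if (config$dead_time > 0) {
      keep_c <- integer(0); keep_t <- numeric(0)
      for (ch in sort(unique(chan))) {
        tc <- sort(tim[chan == ch])
        tc <- apply_dead_time(tc, config$dead_time)
        keep_c <- c(keep_c, rep(ch, length(tc)))
        keep_t <- c(keep_t, tc)
      }
      chan <- keep_c; tim <- keep_t
    }
    roles <- c("0" = "residue", "1" = "herald",
               "2" = "fluor", "3" = "fluor")
    if (!config$splitter) roles <- roles[c("0", "1", "2")]
    if (config$p_detect_residue == 0 && config$dark_rates[["0"]] == 0)
      roles <- roles[names(roles) != "0"]
    stream <- tag_stream(chan, tim,
                         meta = list(repetition_rate_hz = config$R_r,
                                     duration_s = config$duration_s,
                                     seed = config$seed,
                                     channel_roles = roles,
                                     config = config))
    if (!log) return(stream)
    traj <- data.frame(pulse = pos, t_pulse = t_pulse, pairs = M,
                       herald = herald, fluor_detections = k_fl)
    list(stream = stream, trajectories = traj)
  })
}

#' Simulated heralds-per-fluorescence counting experiment
#'
#' Runs [simulate_stream()] followed by [herald_count_distribution()],
#' returning the empirical P(N) with event totals. With `repeats > 1` the
#' experiment is repeated with independent sub-seeds (derived from
#' `config$seed`), the use case being the study of how the Poisson counting
#' noise of P(N = 1) shrinks with integration time.
#'
#' @param config an [experiment_config()].
#' @param repeats number of independent repetitions.
#' @return a single [herald_count_distribution()] result when
#'   `repeats == 1`, else a list of them (one per repetition).
#' @export
simulate_pn_experiment <- function(config, repeats = 1L) {
  validate_config(config)
  one <- function(seed) {
    cfg <- config
    cfg$seed <- as.integer(seed)
    s <- simulate_stream(cfg)
    herald_count_distribution(s, gate_ps = config$gate_fluor)
  }
  if (repeats == 1L) return(one(config$seed))
  # sub-seeds kept within 32-bit integer range
  seeds <- (as.numeric(config$seed) * 1009 + 7919 * seq_len(repeats)) %% 2147483647
  lapply(seeds, one)
}

#' Write an experiment configuration as a flat key=value file
#' @param config an [experiment_config()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  flat <- config
  flat$dark_rates <- paste(names(config$dark_rates), config$dark_rates,
                           sep = ":", collapse = ",")
  lines <- vapply(names(flat), function(k)
    sprintf("%s=%s", k, format(flat[[k]], digits = 17)), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an experiment configuration from a flat key=value file
#' @param path file written by [write_config()] (or hand-written; missing
#'   keys take their [experiment_config()] defaults).
#' @return an [experiment_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), "")
  args <- list()
  for (i in seq_along(keys)) {
    k <- trimws(keys[i]); v <- trimws(vals[i])
    if (k == "dark_rates") {
      parts <- strsplit(strsplit(v, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
      dr <- as.numeric(vapply(parts, `[`, "", 2L))
      names(dr) <- vapply(parts, `[`, "", 1L)
      args$dark_rates <- dr
    } else if (k %in% c("splitter", "fluorescence")) {
      args[[k]] <- toupper(v) %in% c("TRUE", "T", "1", "YES")
    } else {
      args[[k]] <- as.numeric(v)
    }
  }
  args <- args[names(args) %in% names(formals(experiment_config))]
  do.call(experiment_config, args)
}
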