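test_that("config validation rejects nonphysical fields", {
  expect_error(experiment_config(n_p = -0.1), "non-negative")
  expect_error(experiment_config(eta_herald = 1.3), "\\[0, 1\\]")
  expect_error(experiment_config(tau_fl = 0), "positive")
  expect_error(experiment_config(duration_s = 1e-9), "at least one pulse")
  expect_error(experiment_config(duration_s = 4 * 3600), "2.5 h")
})

test_that("herald_efficiency_for_rate inverts the click-rate relation", {
  eta <- herald_efficiency_for_rate(9.73e5, 75.7e6, 0.0458)
  np <- 0.0458
  expect_equal(75.7e6 * np * eta / (1 + np * eta), 9.73e5, tolerance = 1e-12)
  expect_error(herald_efficiency_for_rate(1e8, 75.7e6, 0.0458),
               "unreachable")
})

test_that("vacuum source emits only dark counts", {
  cfg <- experiment_config(n_p = 0, duration_s = 0.01, seed = 1,
                           dark_rates = c("0" = 0, "1" = 0, "2" = 5000,
                                          "3" = 0))
  s <- simulate_stream(cfg)
  expect_true(all(s$channel == 2L))
  expect_gt(length(s$time), 0)
  cfg0 <- experiment_config(n_p = 0, duration_s = 0.01, seed = 1)
  expect_length(simulate_stream(cfg0)$time, 0)
})

test_that("simulate_stream is bit-reproducible under a fixed seed", {
  cfg <- experiment_config(duration_s = 0.02, p_detect_fluor = 0.01,
                           p_detect_residue = 0.005, splitter = TRUE,
                           seed = 77)
  a <- simulate_stream(cfg)
  b <- simulate_stream(cfg)
  expect_identical(a$time, b$time)
  expect_identical(a$channel, b$channel)
  cfg2 <- cfg
  cfg2$seed <- 78L
  expect_false(identical(a$time, simulate_stream(cfg2)$time))
})

test_that("herald rate matches the click-model contract and printed rate", {
  cfg <- experiment_config(duration_s = 0.2, seed = 3)
  s <- simulate_stream(cfg)
  N_H <- sum(s$channel == 1L)
  exp_rate <- click_model_expectations(cfg$n_p, cfg$eta_herald,
                                       cfg$p_detect_fluor,
                                       splitter = FALSE)$p_herald * cfg$R_r
  expect_lt(abs(N_H / 0.2 - exp_rate), 3 * sqrt(N_H) / 0.2)
  # printed operating point: R_h = 9.73e5 counts per second
  expect_lt(abs(N_H / 0.2 - 9.73e5), 3 * sqrt(N_H) / 0.2)
})

test_that("measured e_hf matches p_detect_fluor within binomial error", {
  cfg <- experiment_config(duration_s = 2, seed = 17)
  s <- simulate_stream(cfg)
  ms <- measure_rates(s, gate_ps = cfg$gate_fluor)
  p <- cfg$p_detect_fluor   # 1.244e-4, the printed channel efficiency
  expect_lt(abs(ms$e_hf - p), 3 * sqrt(p * (1 - p) / ms$N_H))
})

test_that("e_hf is essentially constant across the three pair rates", {
  es <- vapply(c(0.0458, 0.0214, 0.0103), function(np) {
    cfg <- experiment_config(n_p = np, duration_s = 1.5,
                             p_detect_fluor = 0.01, seed = 29)
    measure_rates(simulate_stream(cfg), gate_ps = 10000)$e_hf
  }, 0)
  # pairwise agreement within combined 3-sigma binomial errors (~1e-3 scale)
  expect_lt(max(es) - min(es), 0.15 * mean(es))
})

test_that("fluorescence delays are exponential with mean tau_fl", {
  # jitter off, perfect herald: every occupied pulse gives herald + fluor
  cfg <- experiment_config(n_p = 0.002, eta_herald = 1, p_detect_fluor = 1,
                           irf_sigma = 0, duration_s = 0.04, seed = 13)
  s <- simulate_stream(cfg)
  h <- channel_times(s, 1L)
  f <- channel_times(s, 2L)
  hist <- crosscorrelate(h, f, bin_ps = 16, window_ps = 6600)
  cen <- bin_centers(hist)
  pos <- cen > 0
  tau <- sum(cen[pos] * hist$counts[pos]) / sum(hist$counts[pos])
  W <- max(cen)
  # analytic mean of an Exp(tau0) truncated at the window edge
  tau0 <- cfg$tau_fl
  trunc_mean <- tau0 - W * exp(-W / tau0) / (1 - exp(-W / tau0))
  n <- sum(hist$counts[pos])
  expect_gt(n, 5000)
  expect_lt(abs(tau - trunc_mean), 3 * tau0 / sqrt(n))
})

test_that("click detectors emit at most one tag per pulse per channel", {
  # bright source, unit detection: tags per pulse would exceed 1 without
  # click saturation
  cfg <- experiment_config(n_p = 3, eta_herald = 1, p_detect_fluor = 1,
                           irf_sigma = 0, fluorescence = FALSE,
                           duration_s = 2e-5, seed = 5)
  s <- simulate_stream(cfg)
  f <- channel_times(s, 2L)
  expect_equal(length(f), length(unique(f)))   # one tag per pulse time
  h <- channel_times(s, 1L)
  expect_equal(length(h), length(f))           # herald also clicks once
})

test_that("dead time removes close-spaced tags", {
  cfg <- experiment_config(n_p = 0, duration_s = 0.001, seed = 8,
                           dark_rates = c("0" = 0, "1" = 0, "2" = 2e6,
                                          "3" = 0),
                           dead_time = 50000)
  s <- simulate_stream(cfg)
  expect_true(all(diff(channel_times(s, 2L)) > 50000))
})

test_that("heralded g2 is insensitive to halving the efficiencies", {
  run_g2 <- function(eta_scale, p_scale, seed) {
    cfg <- experiment_config(duration_s = 1.2, splitter = TRUE, seed = seed,
                             p_detect_fluor = 0.08 * p_scale)
    cfg$eta_herald <- cfg$eta_herald * eta_scale
    conditional_g2(gated_counts(simulate_stream(cfg), gate_ps = 10000))
  }
  a <- run_g2(1, 1, 41)
  b <- run_g2(0.5, 0.5, 42)
  expect_lt(abs(a$g2 - b$g2), 3 * sqrt(a$sd^2 + b$sd^2))
})

test_that("simulate_pn_experiment returns P(N) with totals and sub-seeds", {
  # every herald fluoresces: P(N = 1) ~ 1 (jitter off, otherwise the
  # IRF-broadened rising edge leaks a few % of tags ahead of the gate)
  cfg <- experiment_config(n_p = 0.01, eta_herald = 1, p_detect_fluor = 1,
                           irf_sigma = 0, duration_s = 1e-3, seed = 2)
  d <- simulate_pn_experiment(cfg)
  expect_gt(d$prob[d$N == 1], 0.99)
  # repeats give independent but reproducible distributions
  cfg2 <- experiment_config(duration_s = 0.05, p_detect_fluor = 0.05,
                            seed = 31)
  reps <- simulate_pn_experiment(cfg2, repeats = 3)
  expect_length(reps, 3)
  p1 <- vapply(reps, function(d) d$prob[d$N == 1], 0)
  expect_gt(stats::sd(p1), 0)
  reps2 <- simulate_pn_experiment(cfg2, repeats = 3)
  expect_identical(vapply(reps2, function(d) d$total_events, 0L),
                   vapply(reps, function(d) d$total_events, 0L))
})

test_that("longer integration shrinks the P(N = 1) counting noise", {
  base <- experiment_config(duration_s = 0.02, p_detect_fluor = 0.05,
                            seed = 19)
  short <- simulate_pn_experiment(base)
  long_cfg <- base
  long_cfg$duration_s <- base$duration_s * 25
  long <- simulate_pn_experiment(long_cfg)
  sd_short <- short$sd[short$N == 1]
  sd_long <- long$sd[long$N == 1]
  expect_lt(sd_long, sd_short / 3)   # ~5x reduction expected for 25x time
})

test_that("config files round-trip through write_config/read_config", {
  cfg <- experiment_config(duration_s = 0.3, splitter = TRUE,
                           dark_rates = c("0" = 0, "1" = 10, "2" = 5,
                                          "3" = 5),
                           seed = 123)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_config(cfg, path)
  back <- read_config(path)
  for (k in setdiff(names(cfg), "dark_rates"))
    expect_equal(back[[k]], cfg[[k]], info = k)
  expect_equal(unname(back$dark_rates), unname(cfg$dark_rates))
})
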