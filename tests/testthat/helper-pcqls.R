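# shared test utilities

# independent closed-form oracle for the click-detector model: exact
# per-pulse expectations of herald clicks, gated singles and gated
# coincidences under thermal pair statistics, by direct truncated summation
# over the pair number M (truncation error far below double precision for
# the n_p used in tests)
click_model_expectations <- function(n_p, eta, p, splitter = TRUE,
                                     M_max = 400) {
  M <- 0:M_max
  pmf <- n_p^M / (1 + n_p)^(M + 1)
  h <- 1 - (1 - eta)^M
  if (splitter) {
    a <- 1 - (1 - p / 2)^M            # P(detector 2 fires | M)
    c2 <- 1 - 2 * (1 - p / 2)^M + (1 - p)^M  # P(both fire | M)
  } else {
    a <- 1 - (1 - p)^M
    c2 <- 0 * M
  }
  list(p_herald = sum(pmf * h),
       p_h_and_2 = sum(pmf * h * a),
       p_h_and_c = sum(pmf * h * c2),
       g2_expected = sum(pmf * h) * sum(pmf * h * c2) / sum(pmf * h * a)^2)
}

# random small multi-channel stream for property-based oracle comparisons
random_small_stream <- function(n_max = 50, t_max = 5e5) {
  n1 <- sample.int(n_max, 1L)
  n2 <- sample.int(n_max, 1L)
  n3 <- sample.int(n_max, 1L)
  tag_stream(channel = c(rep(1L, n1), rep(2L, n2), rep(3L, n3)),
             time = sample.int(t_max, n1 + n2 + n3, replace = TRUE) - 1,
             meta = list(duration_s = t_max / 1e12))
}

# empirical herald-count distribution from a plain vector of N draws
dist_from_draws <- function(N) {
  tab <- table(N)
  list(N = as.integer(names(tab)), counts = as.integer(tab))
}
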