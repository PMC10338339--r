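test_that("crosscorrelate handles the elementary cases", {
  # one pair at +500 ps lands in bin [384, 512)
  h <- crosscorrelate(0, 500, bin_ps = 128, window_ps = 6400)
  expect_equal(sum(h$counts), 1)
  hit <- which(h$counts == 1)
  expect_equal(h$bin_edges[hit], 384)
  expect_equal(h$bin_edges[hit + 1L], 512)
  # identical streams: peak of height n at tau = 0 (self-pairing);
  # spacing larger than the window so only self-pairs contribute
  t <- (1:20) * 5000
  hh <- crosscorrelate(t, t, bin_ps = 128, window_ps = 1280)
  zero_bin <- which(hh$bin_edges == 0)
  expect_equal(hh$counts[zero_bin], 20)
  expect_error(crosscorrelate(0, 1, bin_ps = -1), "positive")
  expect_error(crosscorrelate(0, 1, bin_ps = 128, window_ps = 64),
               "at least one bin")
})

test_that("sweep cross-correlation equals the brute-force oracle", {
  withr::with_seed(101, {
    for (i in 1:60) {
      n <- sample.int(50, 1); m <- sample.int(50, 1)
      heralds <- sort(sample.int(1e5, n, replace = TRUE)) - 1
      partners <- sort(sample.int(1e5, m, replace = TRUE)) - 1
      bin <- sample(c(64, 128, 250), 1)
      win <- sample(c(500, 2000, 2e4), 1)
      a <- crosscorrelate(heralds, partners, bin, win)
      b <- crosscorrelate_brute(heralds, partners, bin, win)
      expect_identical(a$counts, b$counts)
      expect_identical(a$bin_edges, b$bin_edges)
    }
  })
})

test_that("gated_counts implements the truncated-gate attribution", {
  # one herald, one D2 tag inside gate, none on D3
  s <- tag_stream(c(1L, 2L), c(1000, 4000))
  gc1 <- gated_counts(s, gate_ps = 10000)
  expect_equal(unlist(gc1[c("N_H", "N_2", "N_3", "N_C")],
                      use.names = FALSE), c(1, 1, 0, 0))
  # both D2 and D3 in the gate -> a coincidence
  s2 <- tag_stream(c(1L, 2L, 3L), c(1000, 4000, 9000))
  expect_equal(gated_counts(s2, gate_ps = 10000)$N_C, 1)
  # tag after gate end does not count
  s3 <- tag_stream(c(1L, 2L), c(1000, 12000))
  expect_equal(gated_counts(s3, gate_ps = 10000)$N_2, 0)
  # a tag between two close heralds belongs to the most recent one
  s4 <- tag_stream(c(1L, 1L, 2L), c(0, 4000, 5000))
  gc4 <- gated_counts(s4, gate_ps = 10000)
  expect_equal(gc4$N_2, 1)   # one gate (the second) has the tag
  expect_error(gated_counts(tag_stream(2L, 5), gate_ps = 100), "herald")
})

test_that("gated_counts equals the brute-force per-herald scan", {
  withr::with_seed(202, {
    for (i in 1:60) {
      s <- random_small_stream()
      gate <- sample(c(500, 6000, 10000), 1)
      off <- sample(c(0, 1000), 1)
      a <- gated_counts(s, gate, off)
      b <- gated_counts_brute(s, gate, off)
      expect_equal(a[c("N_H", "N_2", "N_3", "N_C")],
                   b[c("N_H", "N_2", "N_3", "N_C")])
    }
  })
})

test_that("conditional_g2 formula, symmetry and zero-coincidence handling", {
  # uncorrelated Poissonian construction gives exactly 1
  expect_equal(conditional_g2(list(N_H = 100, N_C = 25, N_2 = 50,
                                   N_3 = 50))$g2, 1)
  # symmetric under swapping N_2 and N_3
  a <- conditional_g2(list(N_H = 1e6, N_C = 3, N_2 = 400, N_3 = 700))
  b <- conditional_g2(list(N_H = 1e6, N_C = 3, N_2 = 700, N_3 = 400))
  expect_equal(a$g2, b$g2)
  expect_equal(a$sd, b$sd)
  z <- conditional_g2(list(N_H = 1e6, N_C = 0, N_2 = 400, N_3 = 700))
  expect_equal(z$g2, 0)
  expect_true(z$zero_coincidences)
  expect_gt(z$sd, 0)
  expect_error(conditional_g2(list(N_H = 10, N_C = 0, N_2 = 0, N_3 = 5)),
               "zero gated singles")
})

test_that("conditional_g2 is about 1 for independent Poissonian channels", {
  withr::with_seed(33, {
    dur <- 1e9  # 1 ms in ps
    s <- tag_stream(
      channel = c(rep(1L, 4000), rep(2L, 3000), rep(3L, 3000)),
      time = round(runif(10000, 0, dur)),
      meta = list(duration_s = 1e-3))
    g <- conditional_g2(gated_counts(s, gate_ps = 10000))
    expect_lt(abs(g$g2 - 1), 3 * g$sd)
  })
})

test_that("herald_count_distribution counts heralds between events", {
  # heralds every 100 ns; fluorescence after heralds 3 and 5 only
  h_t <- (1:6) * 1e5
  s <- tag_stream(c(rep(1L, 6), 2L, 2L), c(h_t, 3e5 + 2000, 5e5 + 1500))
  d <- herald_count_distribution(s, gate_ps = 10000)
  expect_equal(d$total_heralds, 6)
  expect_equal(d$total_events, 2)
  # first event after 3 heralds (inclusive), second after 2 more
  expect_equal(d$counts[d$N == 3], 1)
  expect_equal(d$counts[d$N == 2], 1)
  expect_equal(sum(d$prob), 1)
  # every herald heralds exactly one fluorescence -> P(N = 1) = 1
  s2 <- tag_stream(c(rep(1L, 5), rep(2L, 5)),
                   c((1:5) * 1e5, (1:5) * 1e5 + 1000))
  d2 <- herald_count_distribution(s2, gate_ps = 10000)
  expect_equal(d2$prob[d2$N == 1], 1)
})

test_that("double detections populate N = 0 and match gated coincidences", {
  # herald 2's gate holds tags on both detectors: one event at its N plus
  # one extra at N = 0; the same gate is the N_C coincidence
  s <- tag_stream(c(1L, 1L, 2L, 3L, 1L, 2L),
                  c(1e5, 2e5, 2e5 + 1000, 2e5 + 3000, 3e5, 3e5 + 500))
  d <- herald_count_distribution(s, gate_ps = 10000)
  expect_equal(d$n_double, 1)
  expect_equal(d$counts[d$N == 0], 1)
  expect_equal(d$n_double_cross, 1)
  expect_equal(d$total_events,
               sum(d$counts[d$N >= 1]) + d$n_double)  # conservation
  gc <- gated_counts(s, gate_ps = 10000)
  expect_equal(gc$N_C, d$n_double_cross)
  expect_equal(d$prob[d$N == 0], 1 / d$total_events)
})
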