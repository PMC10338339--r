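#' Cross-correlation histogram between two tag sequences
#'
#' Histograms the relative delays `tau = t_partner - t_herald` over all
#' herald/partner pairs with `|tau|` up to `window_ps`, on a uniform grid of
#' `bin_ps`-wide bins aligned to zero (floor binning). This is the standard
#' start-stop-free full cross-correlation: the herald-fluorescence version
#' shows the fluorescence decay, the herald-residue version the instrument
#' response. Computed by a sorted two-pointer/binary sweep in
#' O((n + m) log + pairs); identical by construction to the all-pairs
#' brute-force histogram (see [crosscorrelate_brute()], kept as an
#' independent oracle).
#'
#' @param heralds sorted numeric vector of reference tag times (ps), or a
#'   [tag_stream()] (channel 1 is used).
#' @param partners sorted numeric vector of partner tag times (ps), or a
#'   [tag_stream()] (channels 2 and 3 combined).
#' @param bin_ps bin width (ps), default 128.
#' @param window_ps maximum |delay| histogrammed (ps). The histogram covers
#'   `[-ceiling(window/bin), +ceiling(window/bin)] * bin_ps`.
#' @return a [delay_histogram()] (normalization `"none"`); the number of
#'   pairs histogrammed equals `sum(counts)`.
#' @examples
#' h <- crosscorrelate(c(0, 1e6), c(500, 1e6 + 700), bin_ps = 128,
#'                     window_ps = 6400)
#' sum(h$counts)
#' @export
crosscorrelate <- function(heralds, partners, bin_ps = 128,
                           window_ps = 6600) {
  if (inherits(heralds, "tag_stream")) heralds <- channel_times(heralds, 1L)
  if (inherits(partners, "tag_stream"))
    partners <- sort(c(channel_times(partners, 2L), channel_times(partners, 3L)))
  if (bin_ps <= 0) stop("bin_ps must be positive")
  if (window_ps < bin_ps) stop("window_ps must be at least one bin")
  if (is.unsorted(heralds) || is.unsorted(partners))
    stop("input tag sequences must be sorted")
  half <- ceiling(window_ps / bin_ps)
  lo <- -half * bin_ps
  hi <- half * bin_ps
  edges <- seq.int(-half, half) * bin_ps
  nbins <- 2L * half
  if (length(heralds) == 0L || length(partners) == 0L)
    return(delay_histogram(edges, integer(nbins)))
  # for each partner, the run of heralds with lo <= tau < hi
  first <- findInterval(partners - hi, heralds) + 1L
  last <- findInterval(partners - lo, heralds)
  cnt <- pmax(0L, last - first + 1L)
  tot <- sum(cnt)
  if (tot == 0L) return(delay_histogram(edges, integer(nbins)))
  idx <- sequence(cnt, from = first)
  tau <- rep(partners, cnt) - heralds[idx]
  bins <- floor((tau - lo) / bin_ps) + 1
  delay_histogram(edges, tabulate(bins, nbins = nbins))
}

#' Brute-force all-pairs cross-correlation (independent oracle)
#'
#' O(n * m) reference implementation of [crosscorrelate()], enumerating
#' every herald/partner pair explicitly. Intended for validation on small
#' streams.
#'
#' @inheritParams crosscorrelate
#' @return a [delay_histogram()].
#' @export
crosscorrelate_brute <- function(heralds, partners, bin_ps = 128,
                                 window_ps = 6600) {
  if (inherits(heralds, "tag_stream")) heralds <- channel_times(heralds, 1L)
  if (inherits(partners, "tag_stream"))
    partners <- sort(c(channel_times(partners, 2L), channel_times(partners, 3L)))
  if (bin_ps <= 0) stop("bin_ps must be positive")
  if (window_ps < bin_ps) stop("window_ps must be at least one bin")
  half <- ceiling(window_ps / bin_ps)
  lo <- -half * bin_ps
  hi <- half * bin_ps
  edges <- seq.int(-half, half) * bin_ps
  tau <- as.vector(outer(partners, heralds, `-`))
  tau <- tau[tau >= lo & tau < hi]
  bins <- floor((tau - lo) / bin_ps) + 1
  delay_histogram(edges, tabulate(bins, nbins = 2L * half))
}

#' Gated singles and coincidences of a three-detector measurement
#'
#' Implements the counting scheme of the three-detector conditional g2(0)
#' measurement: every herald tag on channel 1 opens a gate
#' `[t_h + offset, t_h + offset + gate_ps)`; `N_2` (`N_3`) counts gates in
#' which detector 2 (3) registered at least one tag, and `N_C` counts gates
#' in which both did. A tag is attributed to the most recent herald whose
#' gate covers it, so overlapping gates are truncated at the next herald.
#'
#' @param stream a [tag_stream()] with channels 1, 2 and 3.
#' @param gate_ps gate length (ps), e.g. 10000 for fluorescence, 6000 for
#'   incident photons.
#' @param offset_ps electronic delay between herald tag and gate opening
#'   (ps), default 0.
#' @return object of class `gated_counts`: list with `N_H`, `N_2`, `N_3`,
#'   `N_C`, `gate_ps`, `offset_ps`.
#' @export
gated_counts <- function(stream, gate_ps, offset_ps = 0) {
  if (gate_ps <= 0) stop("gate_ps must be positive")
  h <- channel_times(stream, 1L)
  if (length(h) == 0L) stop("no herald tags (channel 1) in stream")
  gate_hits <- function(ch) {
    t <- channel_times(stream, ch)
    if (length(t) == 0L) return(integer(0))
    idx <- findInterval(t - offset_ps, h)
    ok <- idx >= 1L
    ok[ok] <- (t[ok] - (h[idx[ok]] + offset_ps)) < gate_ps
    unique(idx[ok])
  }
  g2 <- gate_hits(2L)
  g3 <- gate_hits(3L)
  structure(list(N_H = length(h), N_2 = length(g2), N_3 = length(g3),
                 N_C = length(intersect(g2, g3)),
                 gate_ps = gate_ps, offset_ps = offset_ps),
            class = "gated_counts")
}

#' Brute-force gated counting (independent oracle)
#'
#' Reference implementation of [gated_counts()] by explicit per-herald
#' interval scan, for validation on small streams.
#'
#' @inheritParams gated_counts
#' @return a `gated_counts` object.
#' @export
gated_counts_brute <- function(stream, gate_ps, offset_ps = 0) {
  if (gate_ps <= 0) stop("gate_ps must be positive")
  h <- channel_times(stream, 1L)
  if (length(h) == 0L) stop("no herald tags (channel 1) in stream")
  t2 <- channel_times(stream, 2L)
  t3 <- channel_times(stream, 3L)
  n2 <- 0L; n3 <- 0L; nc <- 0L
  for (i in seq_along(h)) {
    a <- h[i] + offset_ps
    b <- a + gate_ps
    if (i < length(h)) b <- min(b, h[i + 1L] + offset_ps)  # truncate at next
    hit2 <- any(t2 >= a & t2 < b)
    hit3 <- any(t3 >= a & t3 < b)
    n2 <- n2 + hit2
    n3 <- n3 + hit3
    nc <- nc + (hit2 && hit3)
  }
  structure(list(N_H = length(h), N_2 = n2, N_3 = n3, N_C = nc,
                 gate_ps = gate_ps, offset_ps = offset_ps),
            class = "gated_counts")
}

#' @export
print.gated_counts <- function(x, ...) {
  cat(sprintf("<gated_counts: N_H=%s N_2=%s N_3=%s N_C=%s (gate %g ps)>\n",
              format(x$N_H, big.mark = ","), format(x$N_2, big.mark = ","),
              format(x$N_3, big.mark = ","), format(x$N_C, big.mark = ","),
              x$gate_ps))
  invisible(x)
}

#' Conditional g2(0) from gated three-detector counts
#'
#' Evaluates the standard heralded second-order coherence estimator
#' \deqn{g^{(2)}(0) = (N_H \times N_C) / (N_2 \times N_3)}
#' with its standard deviation from independent Poisson error propagation,
#' \eqn{sd = g^{(2)} \sqrt{1/N_C + 1/N_H + 1/N_2 + 1/N_3}}. A value below
#' 0.5 certifies single-photon character of the gated field. When
#' `N_C = 0` the value is 0 and the s.d. is the bound obtained by
#' substituting one coincidence, flagged via `zero_coincidences`.
#'
#' @param gc a `gated_counts` object (or list with `N_H`, `N_2`, `N_3`,
#'   `N_C`).
#' @return list with `g2`, `sd`, `zero_coincidences` and the input counts.
#' @examples
#' conditional_g2(list(N_H = 17773649622, N_C = 8,
#'                     N_2 = 819108, N_3 = 849299))
#' @export
conditional_g2 <- function(gc) {
  # counts can exceed .Machine$integer.max products; work in doubles
  N_H <- as.numeric(gc$N_H); N_2 <- as.numeric(gc$N_2)
  N_3 <- as.numeric(gc$N_3); N_C <- as.numeric(gc$N_C)
  stopifnot(N_H >= 0, N_C >= 0, N_C <= min(N_2, N_3))
  if (N_2 <= 0 || N_3 <= 0) stop("zero gated singles: g2 undefined")
  if (N_C == 0) {
    # substitute the +-1 coincidence bound for the error estimate
    bound <- (N_H * 1) / (N_2 * N_3)
    return(list(g2 = 0, sd = bound * sqrt(1 + 1 / N_H + 1 / N_2 + 1 / N_3),
                zero_coincidences = TRUE,
                N_H = N_H, N_2 = N_2, N_3 = N_3, N_C = N_C))
  }
  g2 <- (N_H * N_C) / (N_2 * N_3)
  sd <- g2 * sqrt(1 / N_C + 1 / N_H + 1 / N_2 + 1 / N_3)
  list(g2 = g2, sd = sd, zero_coincidences = FALSE,
       N_H = N_H, N_2 = N_2, N_3 = N_3, N_C = N_C)
}

#' Distribution of the number of heralds per heralded fluorescence photon
#'
#' Scans the heralds of a stream in time order, maintaining a herald
#' counter. Whenever a herald's gate contains at least one fluorescence tag
#' (channels 2 and 3 combined), the number N of heralds since the previous
#' recorded event — inclusive of the current herald — is recorded and the
#' counter reset. If one gate contains two or more fluorescence detections
#' (e.g. one on each splitter output), each additional detection is
#' recorded as N = 0; these double events are the same events that produce
#' gated D2-D3 coincidences in the g2 measurement. Under single-photon
#' operation the distribution is geometric ([geometric_pn()]) with success
#' probability e_hf.
#'
#' @param stream a [tag_stream()] with herald channel 1 and at least one of
#'   channels 2/3.
#' @param gate_ps fluorescence gate length (ps).
#' @param offset_ps gate opening delay after the herald tag (ps).
#' @return object of class `herald_count_distribution`: list with integer
#'   vectors `N` (0..max) and `counts`, `prob` (= counts / total events),
#'   `sd` (per-bin Poisson s.d., sqrt(counts)/total), `total_events`,
#'   `total_heralds`, `n_double` (extra detections recorded at N = 0) and
#'   a diagnostic split of doubles into cross-detector and same-detector
#'   multiples.
#' @export
herald_count_distribution <- function(stream, gate_ps, offset_ps = 0) {
  if (gate_ps <= 0) stop("gate_ps must be positive")
  h <- channel_times(stream, 1L)
  if (length(h) == 0L) stop("no herald tags (channel 1) in stream")
  t2 <- channel_times(stream, 2L)
  t3 <- channel_times(stream, 3L)
  if (length(t2) + length(t3) == 0L)
    stop("no fluorescence tags (channels 2/3) in stream")
  per_herald <- function(t) {
    if (length(t) == 0L) return(integer(length(h)))
    idx <- findInterval(t - offset_ps, h)
    ok <- idx >= 1L
    ok[ok] <- (t[ok] - (h[idx[ok]] + offset_ps)) < gate_ps
    tabulate(idx[ok], nbins = length(h))
  }
  k2 <- per_herald(t2)
  k3 <- per_herald(t3)
  k <- k2 + k3
  succ <- which(k > 0L)
  if (length(succ) == 0L)
    stop("no heralded fluorescence events within gates")
  N_vals <- diff(c(0L, succ))          # heralds since previous event, inclusive
  extras <- sum(k[succ] - 1L)          # additional detections -> N = 0
  n_cross <- sum(k2[succ] > 0L & k3[succ] > 0L)
  n_same <- sum(pmax(k2[succ] - 1L, 0L) + pmax(k3[succ] - 1L, 0L))
  maxN <- max(N_vals)
  counts <- tabulate(N_vals, nbins = maxN)       # N = 1..maxN
  counts <- c(extras, counts)                    # prepend N = 0
  total <- sum(counts)
  structure(list(N = 0:maxN, counts = counts,
                 prob = counts / total,
                 sd = sqrt(counts) / total,
                 total_events = total,
                 total_heralds = length(h),
                 n_double = extras,
                 n_double_cross = n_cross,
                 n_double_same = n_same,
                 gate_ps = gate_ps, offset_ps = offset_ps),
            class = "herald_count_distribution")
}

#' @export
print.herald_count_distribution <- function(x, ...) {
  cat(sprintf(paste0("<herald_count_distribution: %s events over %s heralds,",
                     " P(N=0)=%.3g, mode(N>=1)=%d>\n"),
              format(x$total_events, big.mark = ","),
              format(x$total_heralds, big.mark = ","),
              x$prob[1L], x$N[-1L][which.max(x$counts[-1L])]))
  invisible(x)
}
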