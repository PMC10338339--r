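#' Construct a multi-channel photon time-tag stream
#'
#' A `tag_stream` is the package's central container: a time-ordered table of
#' detection events (one integer channel label and one integer picosecond
#' timestamp per event) plus acquisition metadata. Channel conventions follow
#' the usual heralded-source layout: 1 = herald detector (D1), 2 = D2,
#' 3 = D3 (the second output of the 50:50 splitter in three-detector mode),
#' 0 = incident-residue monitor used for instrument-response estimation.
#'
#' Timestamps are integer picoseconds since acquisition start, stored as
#' doubles. They remain exact as long as the acquisition is shorter than
#' 2^53 ps (about 2.5 h); longer durations are rejected at validation.
#'
#' @param channel integer vector of channel labels.
#' @param time numeric vector of integer-valued picosecond timestamps.
#' @param meta named list of acquisition metadata. Recognised keys:
#'   `repetition_rate_hz` (pump repetition rate R_r), `duration_s`,
#'   `channel_roles` (named character vector), `seed`, `config` (the
#'   generating [experiment_config()] for simulated streams).
#' @param validate check invariants (sortedness is always enforced).
#'
#' @return An object of class `tag_stream`: a list with elements `channel`,
#'   `time` (parallel vectors sorted by time, ties broken by channel) and
#'   `meta`.
#' @examples
#' s <- tag_stream(c(1L, 2L, 1L), c(0, 500, 1200),
#'                 meta = list(duration_s = 1e-9, repetition_rate_hz = 75.7e6))
#' stream_rates(s)
#' @export
tag_stream <- function(channel, time, meta = list(), validate = TRUE) {
  stopifnot(length(channel) == length(time))
  channel <- as.integer(channel)
  time <- as.numeric(time)
  if (is.unsorted(time)) {
    o <- order(time, channel)
    channel <- channel[o]
    time <- time[o]
  } else {
    # enforce deterministic tie order by channel within equal timestamps
    o <- order(time, channel)
    if (is.unsorted(o, strictly = TRUE)) {
      channel <- channel[o]
      time <- time[o]
    }
  }
  s <- structure(list(channel = channel, time = time, meta = meta),
                 class = "tag_stream")
  if (validate) validate_stream(s)
  s
}

#' Validate a tag_stream against its invariants
#'
#' Checks non-negative integer timestamps, non-decreasing order, membership
#' of channels in the declared channel set (when `meta$channel_roles` is
#' present) and containment within the declared duration.
#'
#' @param stream a [tag_stream()].
#' @return `stream`, invisibly; errors on violation.
#' @export
validate_stream <- function(stream) {
  stopifnot(inherits(stream, "tag_stream"))
  n <- length(stream$time)
  if (n == 0L) return(invisible(stream))
  if (anyNA(stream$time) || anyNA(stream$channel))
    stop("tag_stream contains missing values")
  if (min(stream$time) < 0)
    stop("negative timestamp in tag_stream")
  if (any(stream$time != floor(stream$time)))
    stop("timestamps must be integer picoseconds")
  if (max(stream$time) >= 2^53)
    stop("timestamps exceed the exact-integer range of doubles (2^53 ps)")
  if (is.unsorted(stream$time))
    stop("timestamps not sorted")
  roles <- stream$meta$channel_roles
  if (!is.null(roles)) {
    declared <- as.integer(names(roles))
    bad <- setdiff(unique(stream$channel), declared)
    if (length(bad))
      stop("unknown channel(s): ", paste(bad, collapse = ", "))
  }
  dur <- stream$meta$duration_s
  if (!is.null(dur) && max(stream$time) > dur * 1e12)
    stop("timestamps exceed declared duration")
  invisible(stream)
}

#' @export
print.tag_stream <- function(x, ...) {
  cat(sprintf("<tag_stream: %d tags on channels {%s}>\n",
              length(x$time),
              paste(sort(unique(x$channel)), collapse = ",")))
  if (!is.null(x$meta$duration_s))
    cat(sprintf("  duration: %g s", x$meta$duration_s))
  if (!is.null(x$meta$repetition_rate_hz))
    cat(sprintf("  R_r: %g Hz", x$meta$repetition_rate_hz))
  cat("\n")
  invisible(x)
}

#' @export
`==.tag_stream` <- function(e1, e2) {
  identical(e1$channel, e2$channel) && identical(e1$time, e2$time)
}

#' Extract tag times on one channel
#' @param stream a [tag_stream()].
#' @param channel channel label.
#' @return sorted numeric vector of picosecond timestamps.
#' @export
channel_times <- function(stream, channel) {
  stream$time[stream$channel == channel]
}

# metadata keys serialized in the text header, in a fixed order
.meta_keys <- c("format", "repetition_rate_hz", "duration_s",
                "channel_roles", "seed")

#' Write a tag_stream to a self-describing text file
#'
#' On-disk format: a '#'-prefixed `key=value` metadata header followed by a
#' two-column tab-separated body (`channel`, `time`). The format is plain
#' text so streams are inspectable and diff-able; [read_stream()] inverts it
#' bit-exactly.
#'
#' @param stream a valid [tag_stream()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  validate_stream(stream)
  hdr <- c("# pcqls-timetags v1")
  m <- stream$meta
  fmt_val <- function(v) {
    if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
  }
  for (k in setdiff(names(m), c("config", "channel_roles"))) {
    v <- m[[k]]
    if (is.null(v) || length(v) != 1L) next
    hdr <- c(hdr, sprintf("# %s=%s", k, fmt_val(v)))
  }
  if (!is.null(m$channel_roles)) {
    roles <- m$channel_roles
    hdr <- c(hdr, sprintf("# channel_roles=%s",
                          paste(names(roles), roles, sep = ":", collapse = ",")))
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(hdr, "channel\ttime"), con)
  if (length(stream$time)) {
    body <- paste(stream$channel, sprintf("%.0f", stream$time), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a tag_stream from disk
#'
#' Reads the text format written by [write_stream()] (or any conforming
#' channel/time table with the same header). Unsorted files are re-sorted
#' with a warning; malformed rows and invariant violations are errors.
#'
#' @param path file written by [write_stream()].
#' @return a valid [tag_stream()].
#' @export
read_stream <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, n = 64L)
  n_hdr <- 0L
  meta <- list()
  for (ln in lines) {
    if (!startsWith(ln, "#")) break
    n_hdr <- n_hdr + 1L
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) next
    key <- substr(kv, 1L, eq - 1L)
    val <- substr(kv, eq + 1L, nchar(kv))
    if (key == "channel_roles") {
      parts <- strsplit(strsplit(val, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
      roles <- vapply(parts, `[`, "", 2L)
      names(roles) <- vapply(parts, `[`, "", 1L)
      meta$channel_roles <- roles
    } else {
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (is.na(num)) val else num
    }
  }
  dt <- data.table::fread(path, skip = n_hdr, header = TRUE, sep = "\t",
                          colClasses = list(integer = "channel",
                                            double = "time"),
                          showProgress = FALSE)
  if (!identical(names(dt), c("channel", "time")))
    stop("malformed time-tag file (expected 'channel' and 'time' columns): ",
         path)
  ch <- suppressWarnings(as.integer(dt$channel))
  tm <- suppressWarnings(as.numeric(dt$time))
  if (anyNA(ch) || anyNA(tm)) {
    bad <- which(is.na(ch) | is.na(tm))[1L]
    stop("malformed row at body line ", bad, " of ", path)
  }
  if (is.unsorted(tm))
    warning("time-tag file not sorted; re-sorting: ", path)
  tag_stream(ch, tm, meta = meta)
}

#' Per-channel count rates of a stream
#'
#' Divides the tag count on each channel by the acquisition duration, giving
#' counts per second — e.g. the herald rate R_h on channel 1 and the heralded
#' fluorescence rate on the fluorescence channels.
#'
#' @param stream a [tag_stream()] whose `meta$duration_s` is positive.
#' @return named numeric vector, channel label -> counts per second.
#' @export
stream_rates <- function(stream) {
  dur <- stream$meta$duration_s
  if (is.null(dur) || !is.finite(dur) || dur <= 0)
    stop("stream_rates needs a positive meta$duration_s")
  tab <- table(stream$channel)
  r <- as.numeric(tab) / dur
  names(r) <- names(tab)
  r
}

#' Construct a binned delay histogram
#'
#' Container for coincidence/decay histograms: uniform picosecond bin edges,
#' non-negative integer counts, and a normalization tag (`"none"` keeps raw
#' counts, `"peak"` divides by the maximum — the convention used when
#' plotting normalized cross-correlations — and `"area"` divides by total
#' counts times bin width).
#'
#' @param bin_edges numeric vector of uniform-width bin edges (ps).
#' @param counts integer counts per bin; `length(counts) == length(bin_edges) - 1`.
#' @param normalization one of `"none"`, `"peak"`, `"area"`.
#' @return object of class `delay_histogram` with fields `bin_edges`,
#'   `counts`, `density` (counts transformed per `normalization`),
#'   `normalization`.
#' @export
delay_histogram <- function(bin_edges, counts, normalization = "none") {
  normalization <- match.arg(normalization, c("none", "peak", "area"))
  stopifnot(length(counts) == length(bin_edges) - 1L,
            all(counts >= 0))
  w <- diff(bin_edges)
  if (length(w) > 1L && diff(range(w)) > 1e-9 * w[1L])
    stop("bin edges must be uniform")
  dens <- switch(normalization,
                 none = counts,
                 peak = if (max(counts) > 0) counts / max(counts) else counts,
                 area = if (sum(counts) > 0) counts / (sum(counts) * w[1L]) else counts)
  structure(list(bin_edges = bin_edges, counts = counts,
                 density = dens, normalization = normalization),
            class = "delay_histogram")
}

#' Re-normalize a delay histogram
#' @param hist a [delay_histogram()].
#' @param normalization target normalization.
#' @return a new `delay_histogram` sharing the raw counts.
#' @export
normalize_histogram <- function(hist, normalization = c("peak", "area", "none")) {
  delay_histogram(hist$bin_edges, hist$counts, match.arg(normalization))
}

#' @export
print.delay_histogram <- function(x, ...) {
  cat(sprintf("<delay_histogram: %d bins of %g ps, %d counts, normalization=%s>\n",
              length(x$counts), diff(x$bin_edges[1:2]), sum(x$counts),
              x$normalization))
  invisible(x)
}

#' Bin centres of a delay histogram
#' @param hist a [delay_histogram()].
#' @return numeric vector of bin-centre delays (ps).
#' @export
bin_centers <- function(hist) {
  (hist$bin_edges[-1L] + hist$bin_edges[-length(hist$bin_edges)]) / 2
}
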