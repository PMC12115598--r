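# Windowing and the 14-feature x 8-channel (112-dim) feature bank.
#
# Channels, in fixed order: ax, ay, az, amag, wx, wy, wz, wmag
# (acceleration triplet + magnitude, gyro triplet + magnitude).
# Features, in fixed order: mean, median, std, zcr, ptp, sum, sum_abs,
# rms, avg_variation, skewness, kurtosis, time_between_peaks,
# dominant_frequency, dominant_spectral_density.

#' @rdname extract_features
#' @export
feature_channels <- c("ax", "ay", "az", "amag", "wx", "wy", "wz", "wmag")

#' @rdname extract_features
#' @export
feature_names <- c("mean", "median", "std", "zcr", "ptp", "sum", "sum_abs",
                   "rms", "avg_variation", "skewness", "kurtosis",
                   "time_between_peaks", "dominant_frequency",
                   "dominant_spectral_density")

#' Build one analysis window from an event recording
#'
#' Collects the 8 feature channels (acceleration from the requested frame,
#' gyro shared by both frames, plus the elementwise magnitudes) for a run
#' of samples.
#'
#' @param rec an [event_recording()].
#' @param frame `"body"` or `"world"` acceleration channels.
#' @param start first sample index (1-based).
#' @param n number of samples.
#' @return an object of class `signal_window`: list with `channels`
#'   (data.frame of the 8 channels), `fs`, `frame`.
#' @export
signal_window <- function(rec, frame = c("body", "world"), start = 1,
                          n = nrow(rec$data) - start + 1) {
  frame <- match.arg(frame)
  idx <- seq(start, length.out = n)
  stopifnot(start >= 1, max(idx) <= nrow(rec$data))
  acc <- if (frame == "body") {
    rec$data[idx, c("ax_body", "ay_body", "az_body")]
  } else {
    rec$data[idx, c("ax_world", "ay_world", "az_world")]
  }
  gyr <- rec$data[idx, c("gyro_x", "gyro_y", "gyro_z")]
  ch <- data.frame(
    ax = acc[[1]], ay = acc[[2]], az = acc[[3]],
    amag = sqrt(acc[[1]]^2 + acc[[2]]^2 + acc[[3]]^2),
    wx = gyr[[1]], wy = gyr[[2]], wz = gyr[[3]],
    wmag = sqrt(gyr[[1]]^2 + gyr[[2]]^2 + gyr[[3]]^2)
  )
  structure(list(channels = ch, fs = rec$fs, frame = frame),
            class = "signal_window")
}

#' Segment an event into fixed-length windows
#'
#' @param rec an [event_recording()].
#' @param window_s window length in seconds (7 by default: the minimum
#'   labeled event duration, so one window always captures the onset).
#' @param mode `"first"` (one window at the event start; the default, so
#'   each labeled event contributes one sample) or `"tiled"`
#'   (`floor(duration/window_s)` consecutive non-overlapping windows).
#' @param frame acceleration frame, see [signal_window()].
#' @return list of `signal_window`s; empty (with a warning) when the event
#'   is shorter than one window.
#' @export
segment_windows <- function(rec, window_s = 7, mode = c("first", "tiled"),
                            frame = c("body", "world")) {
  mode <- match.arg(mode)
  frame <- match.arg(frame)
  n_win <- round(window_s * rec$fs)
  n <- nrow(rec$data)
  if (n < n_win) {
    warning(sprintf("event (%s, %.1f s) shorter than the %g s window; skipped",
                    rec$behavior, n / rec$fs, window_s))
    return(list())
  }
  k <- if (mode == "first") 1L else n %/% n_win
  lapply(seq_len(k), function(i) {
    signal_window(rec, frame = frame, start = (i - 1L) * n_win + 1L, n = n_win)
  })
}

#' Basic order/amplitude statistics of a signal
#'
#' Population (divisor N) standard deviation; median is the middle order
#' statistic (mean of the two middles for even N).
#'
#' @param x numeric vector, length >= 1.
#' @return named vector `(mean, median, std, sum, sum_abs, ptp, rms)`.
#' @export
basic_stats <- function(x) {
  if (!length(x)) stop("empty input")
  m <- mean(x)
  c(mean = m,
    median = median(x),
    std = sqrt(mean((x - m)^2)),
    sum = sum(x),
    sum_abs = sum(abs(x)),
    ptp = max(x) - min(x),
    rms = sqrt(mean(x^2)))
}

#' Zero-crossing rate of the mean-centered signal
#'
#' Raw accelerometer channels carry large offsets (gravity), so crossings
#' are counted on the mean-centered signal: strict sign changes between
#' consecutive samples divided by (N-1). Exact zeros count as no crossing.
#'
#' @param x numeric vector, length >= 2.
#' @return rate in `[0, 1]`.
#' @export
zero_crossing_rate <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples")
  xc <- x - mean(x)
  sum(xc[-length(xc)] * xc[-1] < 0) / (length(x) - 1)
}

#' Mean absolute successive difference
#'
#' @param x numeric vector, length >= 2.
#' @return `sum(|x[i+1] - x[i]|) / (N - 1)`.
#' @export
avg_variation <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples")
  mean(abs(diff(x)))
}

#' Skewness and excess kurtosis
#'
#' Central moments with divisor N; `skewness = m3 / m2^1.5`,
#' `kurtosis = m4 / m2^2 - 3` (Fisher). A zero-variance signal has both
#' defined as 0 by convention.
#'
#' @param x numeric vector, length >= 2.
#' @return named vector `(skewness, kurtosis)`.
#' @export
shape_moments <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples")
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 < 1e-300) return(c(skewness = 0, kurtosis = 0))
  c(skewness = mean(d^3) / m2^1.5,
    kurtosis = mean(d^4) / m2^2 - 3)
}

# interior local maxima; strictly greater than both neighbouring distinct
# values, plateaus attributed to their first index
find_peaks <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  keep <- c(TRUE, diff(x) != 0)     # first index of each run of equal values
  ridx <- which(keep)
  rx <- x[ridx]
  m <- length(rx)
  if (m < 3) return(integer())
  is_pk <- c(FALSE, rx[2:(m - 1)] > rx[1:(m - 2)] & rx[2:(m - 1)] > rx[3:m], FALSE)
  # a terminal plateau is not a peak even if rising into it; already FALSE
  ridx[is_pk]
}

#' Mean time between local maxima
#'
#' Peaks are interior samples strictly greater than both neighbors
#' (plateaus take their first index; no prominence threshold). With fewer
#' than two peaks the value is 0 by convention.
#'
#' @param x numeric vector, length >= 3.
#' @param fs sampling rate, Hz.
#' @return mean inter-peak interval in seconds.
#' @export
time_between_peaks <- function(x, fs) {
  if (length(x) < 3) stop("need at least 3 samples")
  pk <- find_peaks(x)
  if (length(pk) < 2) return(0)
  mean(diff(pk)) / fs
}

#' Dominant frequency and spectral density
#'
#' Periodogram of the mean-removed signal over the one-sided DFT grid,
#' no taper, `I(f_k) = |X_k|^2 / N`. The DC bin is excluded from the
#' argmax; ties break toward the lower frequency. A constant signal has
#' an identically-zero periodogram and reports frequency 0 and density 0
#' (consistent with the all-degenerate-window convention).
#'
#' @param x numeric vector, length >= 4.
#' @param fs sampling rate, Hz.
#' @return named vector `(dominant_frequency, dominant_spectral_density)`.
#' @export
spectral_features <- function(x, fs) {
  n <- length(x)
  if (n < 4) stop("need at least 4 samples")
  xc <- x - mean(x)
  spec <- Mod(fft(xc))^2 / n
  k <- seq_len(n %/% 2)            # non-DC one-sided bins
  pgram <- spec[k + 1]
  if (max(pgram) < 1e-300) {
    return(c(dominant_frequency = 0, dominant_spectral_density = 0))
  }
  kmax <- which.max(pgram)         # which.max takes the first of ties
  c(dominant_frequency = k[kmax] * fs / n,
    dominant_spectral_density = pgram[kmax])
}

#' The 112-dimensional window feature vector
#'
#' Applies the 14 features to each of the 8 channels in the fixed
#' documented order (channels outer, features inner), producing a named
#' vector `"<channel>__<feature>"` of length 112. Deterministic: the same
#' window always yields the same vector.
#'
#' `feature_channels` and `feature_names` give the fixed channel/feature
#' orderings.
#'
#' @param w a [signal_window()].
#' @return named numeric vector of length 112.
#' @export
extract_features <- function(w) {
  stopifnot(inherits(w, "signal_window"))
  fs <- w$fs
  vals <- lapply(feature_channels, function(ch) {
    x <- w$channels[[ch]]
    bs <- basic_stats(x)
    sm <- shape_moments(x)
    sp <- spectral_features(x, fs)
    c(bs[["mean"]], bs[["median"]], bs[["std"]],
      zero_crossing_rate(x),
      bs[["ptp"]], bs[["sum"]], bs[["sum_abs"]], bs[["rms"]],
      avg_variation(x),
      sm[["skewness"]], sm[["kurtosis"]],
      time_between_peaks(x, fs),
      sp[["dominant_frequency"]], sp[["dominant_spectral_density"]])
  })
  out <- unlist(vals)
  names(out) <- as.vector(t(outer(feature_channels, feature_names,
                                  paste, sep = "__")))
  out
}

#' Build the design matrix for the binary mount-detection task
#'
#' One row per window; label 1 for active mounting events, 0 for every
#' other behavior (one-vs-rest). Acceleration channels come from the
#' requested frame; gyro-derived columns are identical across frames.
#'
#' @param db list of [event_recording()]s.
#' @param frame `"body"` or `"world"`.
#' @param window_s,mode see [segment_windows()].
#' @return list with `X` (n x 112 matrix, named columns), `y` (0/1
#'   integer), and `meta` (data.frame: `event_id`, `behavior`,
#'   `window`, `frame`).
#' @export
build_design_matrix <- function(db, frame = c("body", "world"),
                                window_s = 7, mode = c("first", "tiled")) {
  frame <- match.arg(frame)
  mode <- match.arg(mode)
  if (!length(db)) stop("empty database")
  rows <- list(); labs <- integer(); meta <- list()
  for (i in seq_along(db)) {
    rec <- db[[i]]
    wins <- segment_windows(rec, window_s = window_s, mode = mode, frame = frame)
    eid <- format_event_filename(rec$behavior, rec$cow_id, rec$start_time)
    for (j in seq_along(wins)) {
      rows[[length(rows) + 1L]] <- extract_features(wins[[j]])
      labs <- c(labs, as.integer(rec$behavior == "active_mounting"))
      meta[[length(meta) + 1L]] <- data.frame(
        event_id = eid, behavior = rec$behavior, window = j, frame = frame)
    }
  }
  if (!length(rows)) stop("no usable windows: every event is shorter than the window")
  X <- do.call(rbind, rows)
  rownames(X) <- NULL
  list(X = X, y = labs, meta = do.call(rbind, meta))
}

#' Export a design matrix to CSV
#'
#' Named feature columns plus `label`, `event_id`, `behavior`, `frame`.
#'
#' @param design result of [build_design_matrix()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_design_csv <- function(design, path) {
  df <- as.data.frame(design$X)
  df$label <- design$y
  df$event_id <- design$meta$event_id
  df$behavior <- design$meta$behavior
  df$frame <- design$meta$frame
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
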