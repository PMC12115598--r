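# Independent brute-force oracles, written naively (explicit loops,
# textbook formulas) so they share no code path with the implementation.

oracle_mean <- function(x) sum(x) / length(x)

oracle_median <- function(x) {
  s <- sort(x); n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_std <- function(x) {
  m <- oracle_mean(x)
  sqrt(sum((x - m)^2) / length(x))
}

oracle_rms <- function(x) sqrt(sum(x^2) / length(x))

oracle_zcr <- function(x) {
  xc <- x - oracle_mean(x)
  k <- 0L
  for (i in seq_len(length(xc) - 1)) {
    if (xc[i] * xc[i + 1] < 0) k <- k + 1L
  }
  k / (length(x) - 1)
}

oracle_avg_variation <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1)) s <- s + abs(x[i + 1] - x[i])
  s / (length(x) - 1)
}

oracle_skew_kurt <- function(x) {
  n <- length(x); m <- oracle_mean(x)
  m2 <- sum((x - m)^2) / n
  if (m2 == 0) return(c(0, 0))
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  c(m3 / m2^1.5, m4 / m2^2 - 3)
}

oracle_peaks <- function(x) {
  # first index of runs; strict maxima over neighbouring distinct values
  pk <- integer()
  i <- 2L
  n <- length(x)
  while (i <= n - 1) {
    if (x[i] == x[i - 1]) { i <- i + 1L; next }
    j <- i
    while (j < n && x[j + 1] == x[j]) j <- j + 1L   # plateau end
    if (j < n && x[i] > x[i - 1] && x[i] > x[j + 1]) pk <- c(pk, i)
    i <- j + 1L
  }
  pk
}

oracle_time_between_peaks <- function(x, fs) {
  pk <- oracle_peaks(x)
  if (length(pk) < 2) return(0)
  gaps <- numeric(length(pk) - 1)
  for (i in seq_len(length(pk) - 1)) gaps[i] <- pk[i + 1] - pk[i]
  oracle_mean(gaps) / fs
}

# naive DFT periodogram: explicit cos/sin sums, no fft
oracle_spectral <- function(x, fs) {
  n <- length(x)
  xc <- x - oracle_mean(x)
  kmax <- n %/% 2
  dens <- numeric(kmax)
  for (k in seq_len(kmax)) {
    re <- 0; im <- 0
    for (t in 0:(n - 1)) {
      re <- re + xc[t + 1] * cos(2 * pi * k * t / n)
      im <- im - xc[t + 1] * sin(2 * pi * k * t / n)
    }
    dens[k] <- (re^2 + im^2) / n
  }
  if (max(dens) < 1e-300) return(c(0, 0))
  k <- which.max(dens)
  c(k * fs / n, dens[k])
}

oracle_feature_vector <- function(w) {
  out <- numeric(0)
  for (ch in c("ax", "ay", "az", "amag", "wx", "wy", "wz", "wmag")) {
    x <- w$channels[[ch]]
    sk <- oracle_skew_kurt(x)
    sp <- oracle_spectral(x, w$fs)
    out <- c(out,
             oracle_mean(x), oracle_median(x), oracle_std(x), oracle_zcr(x),
             max(x) - min(x), sum(x), sum(abs(x)), oracle_rms(x),
             oracle_avg_variation(x), sk[1], sk[2],
             oracle_time_between_peaks(x, w$fs), sp[1], sp[2])
  }
  out
}

# O(n1*n2) pairwise Mann-Whitney count
oracle_mwu <- function(g1, g2) {
  u <- 0
  for (x in g1) for (y in g2) {
    if (x > y) u <- u + 1 else if (x == y) u <- u + 0.5
  }
  u
}

# quaternion sandwich product q * (0,v) * conj(q) as a second rotation route
oracle_rotate <- function(v, q) {
  q <- q / sqrt(sum(q^2))
  conj_q <- c(q[1], -q[2:4])
  p <- cowmotion::quat_multiply(cowmotion::quat_multiply(q, c(0, v)), conj_q)
  p[2:4]
}

# small synthetic window around a noisy sinusoid, for oracle sweeps
random_window <- function(seed, n = 70, fs = 10) {
  set.seed(seed)
  t <- (0:(n - 1)) / fs
  mk <- function() runif(1, 0.2, 4) * sin(2 * pi * runif(1, 0.3, 4) * t +
                                            runif(1, 0, 2 * pi)) +
    rnorm(n, sd = runif(1, 0.01, 1)) + rnorm(1, 0, 5)
  ax <- mk(); ay <- mk(); az <- mk() + 9.807
  wx <- mk() * 20; wy <- mk() * 20; wz <- mk() * 20
  structure(list(channels = data.frame(
    ax = ax, ay = ay, az = az, amag = sqrt(ax^2 + ay^2 + az^2),
    wx = wx, wy = wy, wz = wz, wmag = sqrt(wx^2 + wy^2 + wz^2)),
    fs = fs, frame = "body"), class = "signal_window")
}

# small in-memory db used by several suites
small_db <- function(seed = 2, counts = c(active_mounting = 8, walking = 8,
                                          resting = 6, head_nodding = 6,
                                          grazing = 5)) {
  generate_recordings(counts, seed = seed)
}
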