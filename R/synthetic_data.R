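# Synthetic five-behavior collar-IMU database generator. Signal models
# are phenomenological (sinusoids, Poisson bursts, peak envelopes) tuned
# to the qualitative per-behavior signatures: mounts show a high-quiet-
# high energy envelope (push-up peak, immobile middle, dismount peak),
# walking is rhythmic on x/y, nodding rhythmic on z, grazing bursty,
# resting near-silent with world-frame z pinned at gravity.

#' A behavior signal profile
#'
#' All profiles share one numeric field set so profiles can be linearly
#' interpolated (useful for studying how classification degrades as the
#' mount signature converges toward the nodding signature).
#'
#' @param name behavior label.
#' @param dur_mean,dur_sd,dur_min event duration distribution, seconds
#'   (truncated normal; `dur_min >= 7` so every event hosts one window).
#' @param osc_freq oscillation frequency, Hz.
#' @param osc_amp length-3 body-axis oscillation amplitudes, m/s^2.
#' @param burst_rate Poisson rate of movement bursts, 1/s.
#' @param burst_amp burst amplitude, m/s^2.
#' @param peak_amp amplitude of the mount start/end peaks, m/s^2.
#' @param peak_width_s width of each mount peak, seconds.
#' @param noise_sd white accelerometer noise sd, m/s^2.
#' @param gyro_scale angular-rate activity scale, deg/s.
#' @return object of class `behavior_profile`.
#' @export
behavior_profile <- function(name, dur_mean, dur_sd, dur_min = 7,
                             osc_freq = 0, osc_amp = c(0, 0, 0),
                             burst_rate = 0, burst_amp = 0,
                             peak_amp = 0, peak_width_s = 0,
                             noise_sd = 0.1, gyro_scale = 5) {
  stopifnot(dur_min >= 7 || name == "grazing", dur_mean > 0,
            all(osc_amp >= 0), noise_sd >= 0, gyro_scale >= 0)
  structure(list(name = name, dur_mean = dur_mean, dur_sd = dur_sd,
                 dur_min = dur_min, osc_freq = osc_freq,
                 osc_amp = osc_amp, burst_rate = burst_rate,
                 burst_amp = burst_amp, peak_amp = peak_amp,
                 peak_width_s = peak_width_s, noise_sd = noise_sd,
                 gyro_scale = gyro_scale),
            class = "behavior_profile")
}

#' Default behavior profiles
#'
#' Mean durations follow the field database (9 s mount, 14 s walk, 20 s
#' rest, 8 s nod, 71 s graze). Amplitudes are declared modeling
#' assumptions: walking 1.5 Hz / 2 m/s^2 on x-y, nodding 1.5 Hz /
#' 3 m/s^2 on z, grazing bursts at 1.5/s / 4 m/s^2, mount peaks 8 m/s^2
#' lasting ~1 s at event start and end, resting noise sd 0.05 m/s^2.
#'
#' @return named list of [behavior_profile()]s, one per behavior.
#' @export
default_profiles <- function() {
  list(
    active_mounting = behavior_profile("active_mounting", 9, 1.5, 7,
                                       peak_amp = 8, peak_width_s = 1,
                                       noise_sd = 0.2, gyro_scale = 60),
    walking = behavior_profile("walking", 14, 3, 7,
                               osc_freq = 1.5, osc_amp = c(2, 2, 0.5),
                               noise_sd = 0.3, gyro_scale = 30),
    resting = behavior_profile("resting", 20, 4, 7,
                               noise_sd = 0.05, gyro_scale = 2),
    grazing = behavior_profile("grazing", 71, 15, 10,
                               burst_rate = 1.5, burst_amp = 4,
                               noise_sd = 0.3, gyro_scale = 50),
    head_nodding = behavior_profile("head_nodding", 8, 1, 7,
                                    osc_freq = 1.5, osc_amp = c(0.3, 0.3, 3),
                                    noise_sd = 0.3, gyro_scale = 40)
  )
}

#' Linear interpolation between two behavior profiles
#'
#' Element-wise `(1 - t) * a + t * b` over all numeric fields; the name
#' is kept from `a`. Used to morph one behavior's signature toward
#' another's (e.g. mount toward nodding) for separability studies.
#'
#' @param a,b [behavior_profile()]s.
#' @param t interpolation weight in `[0, 1]`.
#' @return a `behavior_profile`.
#' @export
interpolate_profiles <- function(a, b, t) {
  stopifnot(t >= 0, t <= 1)
  out <- a
  for (f in setdiff(names(a), "name")) {
    out[[f]] <- (1 - t) * a[[f]] + t * b[[f]]
  }
  out$dur_min <- max(out$dur_min, 7)
  out
}

#' Random-walk orientation trace
#'
#' Starting from a base orientation, each 10 Hz step rotates by
#' `wobble_deg_s / fs` degrees about a uniformly random axis, emulating a
#' slowly drifting collar attitude. Every quaternion is unit-norm; the
#' per-step rotation angle is bounded by construction.
#'
#' @param n number of samples.
#' @param base scalar-first base quaternion (default identity).
#' @param wobble_deg_s drift rate, degrees per second (0 = constant).
#' @param fs sampling rate, Hz.
#' @param seed integer seed.
#' @return n x 4 matrix of unit quaternions.
#' @export
make_orientation_trace <- function(n, base = c(1, 0, 0, 0), wobble_deg_s = 0,
                                   fs = 10, seed = 1) {
  stopifnot(n >= 1, wobble_deg_s >= 0)
  set.seed(seed)
  q <- quat_normalize(base)
  out <- matrix(0, n, 4)
  out[1, ] <- q
  step_rad <- wobble_deg_s / fs * pi / 180
  if (n > 1) {
    for (i in 2:n) {
      ax <- rnorm(3)
      ax <- ax / sqrt(sum(ax^2))
      dq <- c(cos(step_rad / 2), sin(step_rad / 2) * ax)
      q <- quat_normalize(quat_multiply(q, dq))
      out[i, ] <- q
    }
  }
  out
}

#' Draw a uniformly random unit quaternion
#'
#' @param seed integer seed.
#' @return scalar-first unit quaternion.
#' @export
random_quaternion <- function(seed) {
  set.seed(seed)
  quat_normalize(rnorm(4))
}

# gaussian bump helper for mount peaks / bursts
bump <- function(t, center, width, amp) amp * exp(-((t - center) / (width / 2.355))^2 / 2)

# body-frame motion (n x 3) for one behavior
behavior_motion <- function(profile, n, fs, rng_seed) {
  set.seed(rng_seed)
  t <- (seq_len(n) - 1) / fs
  motion <- matrix(0, n, 3)
  if (any(profile$osc_amp > 0) && profile$osc_freq > 0) {
    phases <- runif(3, 0, 2 * pi)
    for (a in 1:3) {
      motion[, a] <- motion[, a] +
        profile$osc_amp[a] * sin(2 * pi * profile$osc_freq * t + phases[a])
    }
  }
  if (profile$burst_rate > 0 && profile$burst_amp > 0) {
    n_burst <- max(1L, stats::rpois(1, profile$burst_rate * n / fs))
    centers <- runif(n_burst, 0, n / fs)
    for (c0 in centers) {
      axis <- sample.int(3, 1)
      sgn <- sample(c(-1, 1), 1)
      motion[, axis] <- motion[, axis] +
        sgn * bump(t, c0, 0.3, profile$burst_amp)
    }
  }
  if (profile$peak_amp > 0 && profile$peak_width_s > 0) {
    dur <- n / fs
    # push-up peak near the start, dismount peak near the end, on all
    # three axes with per-axis jitter; quiet middle by construction
    for (center in c(profile$peak_width_s / 2 + 0.2,
                     dur - profile$peak_width_s / 2 - 0.2)) {
      for (a in 1:3) {
        motion[, a] <- motion[, a] +
          sample(c(-1, 1), 1) * runif(1, 0.7, 1) *
            bump(t, center + rnorm(1, 0, 0.05), profile$peak_width_s,
                 profile$peak_amp)
      }
    }
  }
  if (profile$noise_sd > 0) {
    motion <- motion + matrix(rnorm(3 * n, 0, profile$noise_sd), n, 3)
  }
  motion
}

# activity envelope in [0,1] used to scale gyro activity; for mounts it
# mirrors the high-quiet-high acceleration envelope
activity_envelope <- function(profile, n, fs) {
  if (profile$peak_amp <= 0) return(rep(1, n))
  t <- (seq_len(n) - 1) / fs
  dur <- n / fs
  base_frac <- if (profile$peak_amp > 0) {
    # interpolated profiles keep some floor activity as peaks fade
    min(1, 0.15 + (8 - profile$peak_amp) / 8)
  } else 1
  env <- bump(t, profile$peak_width_s / 2 + 0.2, profile$peak_width_s, 1) +
    bump(t, dur - profile$peak_width_s / 2 - 0.2, profile$peak_width_s, 1)
  pmin(1, base_frac + env)
}

#' Generate one labeled synthetic event
#'
#' Body-frame specific force = `R(q)^T (0,0,9.807)` + behavior motion +
#' noise; world-frame channels are the exact rotation `R(q)` of the
#' body-frame channels, so frame consistency holds to machine precision.
#' Gyro channels are behavior-scaled band-limited noise (plus the mount
#' activity envelope); magnetometer channels carry a rotated constant
#' field + noise for schema completeness only.
#'
#' @param behavior one of [behaviors].
#' @param profile a [behavior_profile()]; default the behavior's default.
#' @param seed integer seed (drives duration, orientation and signals).
#' @param orientation optional n x 4 quaternion trace (rows >= samples);
#'   by default a random base orientation with 2 deg/s wobble.
#' @param cow_id,start_time metadata for the recording.
#' @param fs sampling rate, Hz.
#' @param duration_s optional fixed duration override, seconds.
#' @return an [event_recording()].
#' @export
generate_event <- function(behavior, profile = default_profiles()[[behavior]],
                           seed = 1, orientation = NULL, cow_id = "cow01",
                           start_time = "2024-01-01 08:00:00", fs = 10,
                           duration_s = NULL) {
  behavior <- match.arg(behavior, behaviors)
  set.seed(derive_seed(seed, 11))
  dur <- duration_s %||% max(profile$dur_min, rnorm(1, profile$dur_mean, profile$dur_sd))
  if (dur < profile$dur_min) stop("duration below the class minimum")
  n <- max(2L, round(dur * fs))
  if (is.null(orientation)) {
    base <- random_quaternion(derive_seed(seed, 13))
    orientation <- make_orientation_trace(n, base, wobble_deg_s = 2, fs = fs,
                                          seed = derive_seed(seed, 17))
  }
  stopifnot(nrow(orientation) >= n)
  orientation <- orientation[seq_len(n), , drop = FALSE]

  g_world <- c(0, 0, STANDARD_GRAVITY)
  motion <- behavior_motion(profile, n, fs, derive_seed(seed, 19))
  bf <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    R <- quat_to_rotation(orientation[i, ])
    bf[i, ] <- drop(t(R) %*% g_world) + motion[i, ]
  }
  wf <- rotate_to_world(bf, orientation)

  # gyro: smoothed white noise scaled by activity; deg/s
  set.seed(derive_seed(seed, 23))
  env <- activity_envelope(profile, n, fs)
  smooth3 <- function(v) as.numeric(stats::filter(v, rep(1 / 3, 3), sides = 2)) |>
    (\(s) ifelse(is.na(s), v, s))()
  gyro <- sapply(1:3, function(a) profile$gyro_scale * env * smooth3(rnorm(n)))
  if (profile$osc_freq > 0) {
    t <- (seq_len(n) - 1) / fs
    gyro <- gyro + 0.3 * profile$gyro_scale *
      sin(2 * pi * profile$osc_freq * t + runif(1, 0, 2 * pi))
  }

  # magnetometer: constant world field rotated into the body frame
  field <- c(20, 0, -44)
  mag <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    mag[i, ] <- drop(t(quat_to_rotation(orientation[i, ])) %*% field) + rnorm(3, 0, 0.5)
  }

  data <- data.frame(
    ax_world = wf[, 1], ay_world = wf[, 2], az_world = wf[, 3],
    ax_body = bf[, 1], ay_body = bf[, 2], az_body = bf[, 3],
    gyro_x = gyro[, 1], gyro_y = gyro[, 2], gyro_z = gyro[, 3],
    mag_x = mag[, 1], mag_y = mag[, 2], mag_z = mag[, 3],
    q1 = orientation[, 1], q2 = orientation[, 2],
    q3 = orientation[, 3], q4 = orientation[, 4],
    mpu_ax = bf[, 1] + rnorm(n, 0, 0.05),
    mpu_ay = bf[, 2] + rnorm(n, 0, 0.05),
    mpu_az = bf[, 3] + rnorm(n, 0, 0.05),
    mpu_gx = gyro[, 1] + rnorm(n, 0, 0.5),
    mpu_gy = gyro[, 2] + rnorm(n, 0, 0.5),
    mpu_gz = gyro[, 3] + rnorm(n, 0, 0.5),
    mpu_mx = mag[, 1] + rnorm(n, 0, 0.5),
    mpu_my = mag[, 2] + rnorm(n, 0, 0.5),
    mpu_mz = mag[, 3] + rnorm(n, 0, 0.5)
  )
  event_recording(behavior, cow_id, start_time, data, fs = fs)
}

#' Encode physical channels back to raw ADC counts
#'
#' Nearest-integer inverse of the linear count scaling, per channel kind;
#' the decode -> encode round trip errs by at most half an LSB. Values
#' beyond the representable count range raise a clipping error naming
#' the offending channel and sample.
#'
#' @param rec an [event_recording()].
#' @param spec a [sensor_spec()] (applied to the BNO055 accel/gyro
#'   channels).
#' @return data.frame of integer counts for the six body-frame
#'   acceleration/gyro channels (`ax_body..az_body`, `gyro_x..gyro_z`).
#' @export
encode_raw_counts <- function(rec, spec = sensor_preset("bno055")) {
  a_lsb <- spec$accel_range_g * spec$gravity / 2^spec$accel_bits
  w_lsb <- spec$gyro_range_dps / 2^spec$gyro_bits
  enc <- function(vals, lsb, bits, ch) {
    counts <- round(vals / lsb)
    bad <- which(abs(counts) >= 2^bits)
    if (length(bad)) {
      stop("clipping: channel '", ch, "', sample ", bad[1], " (value ",
           signif(vals[bad[1]], 5), ") exceeds the representable range")
    }
    as.integer(counts)
  }
  acc <- c("ax_body", "ay_body", "az_body")
  gyr <- c("gyro_x", "gyro_y", "gyro_z")
  out <- c(
    lapply(acc, function(ch) enc(rec$data[[ch]], a_lsb, spec$accel_bits, ch)),
    lapply(gyr, function(ch) enc(rec$data[[ch]], w_lsb, spec$gyro_bits, ch))
  )
  names(out) <- c(acc, gyr)
  as.data.frame(out)
}

#' Generate a full synthetic behavior database on disk
#'
#' Populates `<root>/<BehaviorToken>/` with one event CSV per requested
#' event and writes a `manifest.json` recording each event's seed,
#' behavior, duration and base orientation. Deterministic: the same seed
#' yields byte-identical CSVs.
#'
#' @param root output directory (created if needed).
#' @param counts named integer vector of events per behavior, e.g.
#'   `c(active_mounting = 21, walking = 186, resting = 83, head_nodding = 43, grazing = 82)`.
#' @param profiles named list of [behavior_profile()]s.
#' @param seed integer root seed.
#' @return `root`, invisibly; side effect: files on disk.
#' @export
generate_database <- function(root, counts, profiles = default_profiles(),
                              seed = 1) {
  recs <- generate_recordings(counts, profiles = profiles, seed = seed)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (b in behaviors) {
    dir.create(file.path(root, behavior_tokens[[b]]), showWarnings = FALSE)
  }
  manifest <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    path <- write_event_csv(rec, file.path(root, behavior_tokens[[rec$behavior]]))
    manifest[[i]] <- list(
      file = basename(path), behavior = rec$behavior,
      seed = attr(rec, "sim_seed"),
      duration_s = event_duration(rec),
      base_quaternion = unname(as.numeric(rec$data[1, c("q1", "q2", "q3", "q4")])))
  }
  jsonlite::write_json(list(seed = seed, n_events = length(recs),
                            events = manifest),
                       file.path(root, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(root)
}

#' Generate a synthetic database in memory
#'
#' Same construction as [generate_database()] without touching disk;
#' convenient for tests and experiments.
#'
#' @inheritParams generate_database
#' @return list of [event_recording()]s.
#' @export
generate_recordings <- function(counts, profiles = default_profiles(),
                                seed = 1) {
  stopifnot(all(names(counts) %in% behaviors), all(counts >= 0))
  recs <- list()
  base_time <- as.POSIXct("2024-01-01 08:00:00", tz = "",
                          format = "%Y-%m-%d %H:%M:%S")
  ev <- 0L
  for (b in behaviors) {
    k <- if (b %in% names(counts)) counts[[b]] else 0L
    if (is.na(k) || k == 0) next
    for (i in seq_len(k)) {
      ev <- ev + 1L
      es <- derive_seed(seed, 1000 + ev)
      set.seed(derive_seed(es, 3))
      cow <- sprintf("cow%02d", sample.int(8, 1))
      start <- base_time + (ev - 1L) * 600
      rec <- generate_event(
        b, profile = profiles[[b]], seed = es, cow_id = cow,
        start_time = format(start, "%Y-%m-%d %H:%M:%S"))
      attr(rec, "sim_seed") <- es
      recs[[length(recs) + 1L]] <- rec
    }
  }
  recs
}
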