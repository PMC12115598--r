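# Event-CSV behavior database: schema, filename convention, read/write,
# and per-behavior summaries. Layout: <root>/<BehaviorToken>/<event>.csv,
# one folder per behavior class, one CSV per labeled event.

#' Behavior classes
#'
#' Canonical labels of the five behavior classes, and the CamelCase tokens
#' used in folder and file names.
#'
#' @format `behaviors` is a character vector of the five canonical labels;
#'   `behavior_tokens` a named character vector mapping labels to file
#'   tokens.
#' @export
behaviors <- c("active_mounting", "walking", "resting", "grazing",
               "head_nodding")

#' @rdname behaviors
#' @export
behavior_tokens <- c(
  active_mounting = "ActiveMounting",
  walking         = "Walking",
  resting         = "Resting",
  grazing         = "Grazing",
  head_nodding    = "HeadNodding"
)

#' Column schema of the 26-column event CSV
#'
#' One timestamp column plus 25 numeric channels: BNO055 world-frame and
#' body-frame acceleration (m/s^2), gyroscope (deg/s), magnetometer
#' (unitless), the four orientation quaternion components, and the MPU9250
#' body-frame acceleration, gyroscope and magnetometer triplets. Column
#' order is fixed and round-trip stable.
#'
#' @param name_map optional named character vector mapping the canonical
#'   CSV header names to the names actually present in a file, so published
#'   databases with different header spellings can be read without code
#'   changes (`names(name_map)` = canonical, values = actual).
#' @return a list with `csv_names` (26 headers), `internal` (25 channel
#'   names used inside [event_recording()]), and `units`.
#' @export
event_schema <- function(name_map = NULL) {
  csv_names <- c(
    "time",
    "BNO055_ax_world", "BNO055_ay_world", "BNO055_az_world",
    "BNO055_ax_body", "BNO055_ay_body", "BNO055_az_body",
    "GX", "GY", "GZ",
    "MX", "MY", "MZ",
    "Q1", "Q2", "Q3", "Q4",
    "MPU9250_ax", "MPU9250_ay", "MPU9250_az",
    "MPU9250_gx", "MPU9250_gy", "MPU9250_gz",
    "MPU9250_mx", "MPU9250_my", "MPU9250_mz"
  )
  internal <- c(
    "ax_world", "ay_world", "az_world",
    "ax_body", "ay_body", "az_body",
    "gyro_x", "gyro_y", "gyro_z",
    "mag_x", "mag_y", "mag_z",
    "q1", "q2", "q3", "q4",
    "mpu_ax", "mpu_ay", "mpu_az",
    "mpu_gx", "mpu_gy", "mpu_gz",
    "mpu_mx", "mpu_my", "mpu_mz"
  )
  units <- c("timestamp", rep("m/s^2", 6), rep("deg/s", 3), rep("-", 3),
             rep("-", 4), rep("m/s^2", 3), rep("deg/s", 3), rep("-", 3))
  if (!is.null(name_map)) {
    bad <- setdiff(names(name_map), csv_names)
    if (length(bad)) {
      stop("name_map refers to unknown canonical columns: ",
           paste(bad, collapse = ", "))
    }
    idx <- match(csv_names, names(name_map))
    csv_names <- ifelse(is.na(idx), csv_names, unname(name_map[idx]))
  }
  list(csv_names = csv_names, internal = internal, units = units)
}

#' Construct a labeled event recording
#'
#' @param behavior one of [behaviors].
#' @param cow_id identifier token, e.g. `"cow03"`.
#' @param start_time event start, `POSIXct` or `"YYYY-MM-DD hh:mm:ss"`
#'   string (naive local time).
#' @param data data.frame with the 25 numeric channels named as in
#'   `event_schema()$internal`, one row per sample.
#' @param fs sampling rate in Hz (10 for the collar hardware).
#' @return an object of class `event_recording`.
#' @export
event_recording <- function(behavior, cow_id, start_time, data, fs = 10) {
  behavior <- match.arg(behavior, behaviors)
  if (is.character(start_time)) {
    start_time <- as.POSIXct(start_time, tz = "", format = "%Y-%m-%d %H:%M:%S")
  }
  if (is.na(start_time)) stop("start_time could not be parsed")
  if (fs <= 0) stop("sample rate must be strictly positive")
  internal <- event_schema()$internal
  if (!all(internal %in% names(data))) {
    stop("data is missing channels: ",
         paste(setdiff(internal, names(data)), collapse = ", "))
  }
  data <- as.data.frame(data)[internal]
  if (nrow(data) < 2) {
    stop("event has fewer than 2 samples; zero-length/single-sample events are rejected")
  }
  if (!all(vapply(data, is.numeric, logical(1)))) stop("non-numeric channel")
  structure(
    list(behavior = behavior, cow_id = as.character(cow_id),
         start_time = start_time, fs = fs, data = data),
    class = "event_recording"
  )
}

#' @export
print.event_recording <- function(x, ...) {
  cat(sprintf("<event_recording> %s  cow=%s  %s  %d samples (%.1f s @ %g Hz)\n",
              x$behavior, x$cow_id,
              format(x$start_time, "%Y-%m-%d %H:%M:%S"),
              nrow(x$data), nrow(x$data) / x$fs, x$fs))
  invisible(x)
}

#' Event duration in seconds
#' @param rec an `event_recording`.
#' @return duration in seconds (`n samples / fs`).
#' @export
event_duration <- function(rec) nrow(rec$data) / rec$fs

#' Parse / format the event filename convention
#'
#' Filenames encode the behavior, the cow id and the event start:
#' `<BehaviorToken>_<cowID>_<YYYY-MM-DD>_<hh-mm-ss>.csv` with CamelCase
#' behavior tokens (see [behavior_tokens]). A custom `pattern` with three
#' capture groups (token, cow id, datetime with `-` separators) can be
#' supplied to match other conventions.
#'
#' @param name filename (basename is taken).
#' @param pattern regex with 3 capture groups; group 3 must read
#'   `YYYY-MM-DD_hh-mm-ss`.
#' @return `parse_event_filename`: a list with `behavior`, `cow_id`,
#'   `start_time` (POSIXct).
#' @export
parse_event_filename <- function(
    name,
    pattern = "^([A-Za-z]+)_([A-Za-z0-9]+)_(\\d{4}-\\d{2}-\\d{2}_\\d{2}-\\d{2}-\\d{2})\\.csv$") {
  base <- basename(name)
  m <- regmatches(base, regexec(pattern, base))[[1]]
  if (length(m) != 4) {
    stop("filename '", base, "' does not match the event naming convention ",
         "<Behavior>_<cowID>_<YYYY-MM-DD>_<hh-mm-ss>.csv")
  }
  token <- m[2]
  behavior <- names(behavior_tokens)[match(token, behavior_tokens)]
  if (is.na(behavior)) {
    stop("filename '", base, "': unknown behavior token '", token, "'")
  }
  ts <- as.POSIXct(m[4], tz = "", format = "%Y-%m-%d_%H-%M-%S")
  if (is.na(ts)) stop("filename '", base, "': unparseable timestamp '", m[4], "'")
  list(behavior = behavior, cow_id = m[3], start_time = ts)
}

#' @rdname parse_event_filename
#' @param behavior,cow_id,start_time components to encode.
#' @return `format_event_filename`: the filename string.
#' @export
format_event_filename <- function(behavior, cow_id, start_time) {
  behavior <- match.arg(behavior, behaviors)
  if (is.character(start_time)) {
    start_time <- as.POSIXct(start_time, tz = "", format = "%Y-%m-%d %H:%M:%S")
  }
  sprintf("%s_%s_%s.csv", behavior_tokens[[behavior]], cow_id,
          format(start_time, "%Y-%m-%d_%H-%M-%S"))
}

#' Read one event CSV
#'
#' Validates the 26-column header against the schema (leading/trailing
#' whitespace in header names is tolerated), parses the 25 numeric
#' channels, and takes behavior/cow/start metadata from the filename when
#' it follows the convention, else from the timestamp column.
#'
#' @param path path to the CSV file.
#' @param schema from [event_schema()]; pass a `name_map` there to read
#'   files with different header spellings.
#' @param behavior,cow_id optional overrides when the filename does not
#'   encode them.
#' @return an [event_recording()].
#' @export
read_event_csv <- function(path, schema = event_schema(),
                           behavior = NULL, cow_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 colClasses = "character")
  names(df) <- trimws(names(df))
  expect <- trimws(schema$csv_names)
  if (length(names(df)) != 26 || !all(names(df) == expect)) {
    missing <- setdiff(expect, names(df))
    extra <- setdiff(names(df), expect)
    stop("schema error in ", basename(path), ": ",
         if (length(missing)) paste0("missing columns [", paste(missing, collapse = ", "), "] "),
         if (length(extra)) paste0("unexpected columns [", paste(extra, collapse = ", "), "] "),
         if (!length(missing) && !length(extra)) "column order differs from schema")
  }
  num <- df[-1]
  parsed <- lapply(num, function(col) suppressWarnings(as.numeric(col)))
  for (j in seq_along(parsed)) {
    bad <- which(is.na(parsed[[j]]) & !is.na(num[[j]]) & nzchar(trimws(num[[j]])))
    nas <- which(is.na(parsed[[j]]))
    if (length(nas)) {
      stop("parse error in ", basename(path), ", column '", names(num)[j],
           "', row ", nas[1], ": non-numeric value '", num[[j]][nas[1]], "'")
    }
  }
  data <- as.data.frame(parsed)
  names(data) <- schema$internal
  meta <- tryCatch(parse_event_filename(path), error = function(e) NULL)
  if (is.null(meta)) {
    if (is.null(behavior)) {
      stop("cannot infer behavior: filename '", basename(path),
           "' does not follow the convention and no behavior= was given")
    }
    meta <- list(behavior = behavior, cow_id = cow_id %||% "unknown",
                 start_time = as.POSIXct(df$time[1], tz = "",
                                         format = "%Y-%m-%d %H:%M:%S"))
  }
  event_recording(behavior %||% meta$behavior,
                  cow_id = cow_id %||% meta$cow_id,
                  start_time = meta$start_time, data = data)
}

#' Write one event CSV
#'
#' Emits the 26-column CSV; the written file reads back to an equal
#' recording (channels preserved to text-serialization precision). If
#' `path` is an existing directory the conventional filename is composed
#' from the recording's metadata.
#'
#' @param rec an [event_recording()].
#' @param path output file path, or a directory.
#' @param digits significant digits for numeric channels.
#' @return the written file path, invisibly.
#' @export
write_event_csv <- function(rec, path, digits = 9) {
  stopifnot(inherits(rec, "event_recording"))
  if (nrow(rec$data) < 2) stop("refusing to write a degenerate event")
  if (dir.exists(path)) {
    path <- file.path(path, format_event_filename(rec$behavior, rec$cow_id,
                                                  rec$start_time))
  }
  schema <- event_schema()
  # per-row wall-clock timestamps carry whole seconds only; sub-second
  # sample times are reconstructed from row index / fs on read
  secs <- floor((seq_len(nrow(rec$data)) - 1) / rec$fs)
  time <- format(rec$start_time + secs, "%Y-%m-%d %H:%M:%S")
  out <- cbind(data.frame(time = time),
               as.data.frame(lapply(rec$data, signif, digits = digits)))
  names(out) <- schema$csv_names
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize a behavior database directory
#'
#' Walks `<root>/<BehaviorToken>/*.csv` and reports, per behavior, the
#' archive count and the total and average event duration. Folders that
#' are not a known behavior token are skipped with a warning.
#'
#' @param root database root directory.
#' @return data.frame of class `database_summary` with columns `behavior`,
#'   `n_events`, `total_s`, `mean_s`, `total_hms`, `mean_hms`.
#' @export
summarize_database <- function(root) {
  if (!dir.exists(root)) stop("no such directory: ", root)
  dirs <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  unknown <- setdiff(dirs, unname(behavior_tokens))
  if (length(unknown)) {
    warning("skipping unknown behavior folder(s): ",
            paste(unknown, collapse = ", "))
  }
  rows <- lapply(behaviors, function(b) {
    d <- file.path(root, behavior_tokens[[b]])
    files <- if (dir.exists(d)) list.files(d, pattern = "\\.csv$",
                                           full.names = TRUE) else character()
    durs <- vapply(files, function(f) {
      n <- length(readLines(f, warn = FALSE)) - 1L  # minus header
      n / 10
    }, numeric(1))
    data.frame(behavior = b, n_events = length(files),
               total_s = sum(durs),
               mean_s = if (length(durs)) mean(durs) else 0)
  })
  out <- do.call(rbind, rows)
  out$total_hms <- format_hms(out$total_s)
  out$mean_hms <- format_hms(out$mean_s)
  class(out) <- c("database_summary", "data.frame")
  out
}

#' Read every event in a behavior database
#'
#' @param root database root (`<root>/<BehaviorToken>/*.csv`).
#' @param schema see [read_event_csv()].
#' @return list of [event_recording()] objects.
#' @export
read_database <- function(root, schema = event_schema()) {
  if (!dir.exists(root)) stop("no such directory: ", root)
  recs <- list()
  for (b in behaviors) {
    d <- file.path(root, behavior_tokens[[b]])
    if (!dir.exists(d)) next
    for (f in sort(list.files(d, pattern = "\\.csv$", full.names = TRUE))) {
      recs[[length(recs) + 1L]] <- read_event_csv(f, schema = schema)
    }
  }
  recs
}
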