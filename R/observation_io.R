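#' Behavioural states of dusky dolphin groups
#'
#' The five mutually exclusive, wholly inclusive group behavioural states
#' recorded by scan sampling a focal group: the predominant activity of the
#' majority of group members at each 150 s sample.
#'
#' @return Character vector of the five state labels, in canonical order.
#' @export
behaviour_states <- function() {
  c("Resting", "Traveling", "Milling", "Socialising", "Feeding")
}

#' Season labels
#' @return Character vector of the four austral season labels.
#' @export
season_levels <- function() c("Summer", "Autumn", "Winter", "Spring")

#' Time-of-day block labels
#' @return Character vector: Morning, Midday, Afternoon.
#' @export
time_block_levels <- function() c("Morning", "Midday", "Afternoon")

#' Parse an HH:MM or HH:MM:SS clock time into seconds since midnight
#'
#' @param x character vector of clock times.
#' @return Numeric seconds since midnight; NA for unparseable values.
#' @export
hms_to_seconds <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- grepl("^\\s*\\d{1,2}:\\d{2}(:\\d{2})?\\s*$", x)
  parts <- strsplit(trimws(x[ok]), ":", fixed = TRUE)
  out[ok] <- vapply(parts, function(p) {
    p <- as.numeric(p)
    if (length(p) == 2) p <- c(p, 0)
    p[1] * 3600 + p[2] * 60 + p[3]
  }, numeric(1))
  out[ok][out[ok] >= 86400] <- NA_real_
  out
}

#' Format seconds since midnight as HH:MM:SS
#' @param x numeric seconds since midnight.
#' @return Character vector.
#' @export
seconds_to_hms <- function(x) {
  sprintf("%02d:%02d:%02d", x %/% 3600, (x %% 3600) %/% 60, round(x %% 60))
}

#' Coerce a data frame to a validated observation log
#'
#' An observation log holds one row per 150 s scan sample of a focal dolphin
#' group: the follow it belongs to, the sample timestamp, the group
#' behavioural state, the number of vessels (including qualifying aircraft)
#' within the interaction threshold, and the calendar date with its observed
#' sunrise and sunset times.  Rows are ordered by follow and timestamp.
#'
#' @param df data frame with columns `follow_id`, `timestamp` (POSIXct),
#'   `state`, `n_vessels`, `date` (Date), `sunrise` and `sunset` (numeric
#'   seconds since midnight).
#' @param states permitted state labels.
#' @return The validated, ordered data frame with class `observation_log`.
#' @export
as_observation_log <- function(df, states = behaviour_states()) {
  required <- c("follow_id", "timestamp", "state", "n_vessels",
                "date", "sunrise", "sunset")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("observation log is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[required]
  df$follow_id <- as.character(df$follow_id)
  if (!inherits(df$timestamp, "POSIXct")) {
    stop("`timestamp` must be POSIXct", call. = FALSE)
  }
  if (!inherits(df$date, "Date")) df$date <- as.Date(df$date)
  df$n_vessels <- as.integer(df$n_vessels)
  df$sunrise <- as.numeric(df$sunrise)
  df$sunset <- as.numeric(df$sunset)

  problems <- character(0)
  bad_state <- which(!(df$state %in% states))
  if (length(bad_state) > 0) {
    problems <- c(problems, sprintf(
      "row %d: unknown behavioural state '%s'", bad_state, df$state[bad_state]))
  }
  bad_vessels <- which(is.na(df$n_vessels) | df$n_vessels < 0)
  if (length(bad_vessels) > 0) {
    problems <- c(problems, sprintf(
      "row %d: n_vessels must be a non-negative integer", bad_vessels))
  }
  bad_sun <- which(!(df$sunrise < df$sunset))
  if (length(bad_sun) > 0) {
    problems <- c(problems, sprintf(
      "row %d: sunrise must precede sunset", bad_sun))
  }
  day_start <- as.POSIXct(paste(format(df$date), "00:00:00"), tz = "UTC")
  bad_day <- which(is.na(df$timestamp) |
                     df$timestamp < day_start |
                     df$timestamp >= day_start + 86400)
  if (length(bad_day) > 0) {
    problems <- c(problems, sprintf(
      "row %d: timestamp does not fall on its stated date", bad_day))
  }
  if (length(problems) > 0) {
    stop("invalid observation log:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  df$state <- factor(df$state, levels = states)
  ord <- order(df$follow_id, df$timestamp)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("observation_log", "data.frame")
  df
}

seconds_of_day <- function(timestamp) {
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  lt$hour * 3600 + lt$min * 60 + lt$sec
}

#' Read a focal-follow observation log from CSV
#'
#' Expects a UTF-8 CSV with a header row and columns `follow_id`,
#' `timestamp` (ISO 8601), `state`, `n_vessels`, `date` (ISO 8601),
#' `sunrise` and `sunset` (HH:MM or HH:MM:SS).  Malformed rows are reported
#' with their row numbers (header = row 0).
#'
#' @param path path to the CSV file.
#' @param states permitted state labels.
#' @return An [as_observation_log()] data frame, grouped by follow and
#'   sorted by timestamp within follow.
#' @export
read_observation_log <- function(path, states = behaviour_states()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  required <- c("follow_id", "timestamp", "state", "n_vessels",
                "date", "sunrise", "sunset")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("observation log is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  problems <- character(0)
  ts <- as.POSIXct(strptime(raw$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  alt <- is.na(ts)
  ts[alt] <- as.POSIXct(strptime(raw$timestamp[alt], "%Y-%m-%d %H:%M:%S",
                                 tz = "UTC"))
  bad <- which(is.na(ts) & !is.na(raw$timestamp))
  if (length(bad) > 0) {
    problems <- c(problems, sprintf(
      "row %d: unparseable timestamp '%s'", bad, raw$timestamp[bad]))
  }
  dt <- as.Date(raw$date, format = "%Y-%m-%d")
  bad <- which(is.na(dt))
  if (length(bad) > 0) {
    problems <- c(problems, sprintf(
      "row %d: unparseable date '%s'", bad, raw$date[bad]))
  }
  bad <- which(!(raw$state %in% states))
  if (length(bad) > 0) {
    problems <- c(problems, sprintf(
      "row %d: unknown behavioural state '%s'", bad, raw$state[bad]))
  }
  nv <- suppressWarnings(as.integer(raw$n_vessels))
  bad <- which(is.na(nv) | nv < 0)
  if (length(bad) > 0) {
    problems <- c(problems, sprintf(
      "row %d: invalid vessel count '%s'", bad, raw$n_vessels[bad]))
  }
  sr <- hms_to_seconds(raw$sunrise)
  ss <- hms_to_seconds(raw$sunset)
  bad <- which(is.na(sr))
  if (length(bad) > 0) {
    problems <- c(problems, sprintf(
      "row %d: unparseable sunrise '%s'", bad, raw$sunrise[bad]))
  }
  bad <- which(is.na(ss))
  if (length(bad) > 0) {
    problems <- c(problems, sprintf(
      "row %d: unparseable sunset '%s'", bad, raw$sunset[bad]))
  }
  if (length(problems) > 0) {
    stop("malformed observation log '", path, "':\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }

  as_observation_log(data.frame(
    follow_id = raw$follow_id, timestamp = ts, state = raw$state,
    n_vessels = nv, date = dt, sunrise = sr, sunset = ss,
    stringsAsFactors = FALSE
  ), states = states)
}

#' Write an observation log to CSV
#'
#' Inverse of [read_observation_log()]: a written log reads back
#' field-for-field identical.
#'
#' @param log an `observation_log`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_observation_log <- function(log, path) {
  out <- data.frame(
    follow_id = log$follow_id,
    timestamp = format(log$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    state = as.character(log$state),
    n_vessels = log$n_vessels,
    date = format(log$date, "%Y-%m-%d"),
    sunrise = seconds_to_hms(log$sunrise),
    sunset = seconds_to_hms(log$sunset),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Time-of-day index: fraction of daylight elapsed
#'
#' The index is the time since sunrise divided by the length of daylight, so
#' that sunrise = 0, midday = 0.5 and sunset = 1.  Samples before sunrise or
#' after sunset yield indices outside \[0, 1\]; they are permitted (tours can
#' be on the water before sunrise) and should be flagged downstream.
#'
#' @param timestamp POSIXct sample times, or numeric seconds since midnight.
#' @param sunrise,sunset numeric seconds since midnight; sunrise must precede
#'   sunset.
#' @return Numeric index; typically in \[0, 1\] for daylight samples.
#' @export
time_of_day_index <- function(timestamp, sunrise, sunset) {
  if (any(sunset <= sunrise)) {
    stop("sunset must be after sunrise", call. = FALSE)
  }
  tod <- if (inherits(timestamp, "POSIXct")) {
    seconds_of_day(timestamp)
  } else {
    as.numeric(timestamp)
  }
  (tod - sunrise) / (sunset - sunrise)
}

#' Classify a time-of-day index into Morning, Midday or Afternoon
#'
#' Daylight is split into thirds of the sunrise-to-sunset interval: morning
#' (index < 0.33), midday (0.33 to 0.66, both boundaries inclusive) and
#' afternoon (index > 0.66).  Indices below 0 (pre-dawn samples) clamp to
#' Morning and above 1 to Afternoon; such samples are flagged via the
#' `"flagged"` attribute and a warning.
#'
#' @param index numeric time-of-day index from [time_of_day_index()].
#' @return Factor with levels Morning, Midday, Afternoon and a logical
#'   `"flagged"` attribute marking out-of-daylight samples.
#' @export
classify_time_block <- function(index) {
  if (any(!is.finite(index))) {
    stop("time-of-day index must be finite", call. = FALSE)
  }
  block <- ifelse(index < 0.33, "Morning",
                  ifelse(index <= 0.66, "Midday", "Afternoon"))
  flagged <- index < 0 | index > 1
  if (any(flagged)) {
    warning(sum(flagged), " sample(s) outside daylight hours clamped into ",
            "Morning/Afternoon", call. = FALSE)
  }
  out <- factor(block, levels = time_block_levels())
  attr(out, "flagged") <- flagged
  out
}

#' Classify a date into an austral season
#'
#' Uses only the month: Dec-Feb = Summer, Mar-May = Autumn, Jun-Aug = Winter,
#' Sep-Nov = Spring.
#'
#' @param date a Date vector (or anything `as.Date()` accepts).
#' @return Factor with levels Summer, Autumn, Winter, Spring.
#' @export
classify_season <- function(date) {
  m <- as.POSIXlt(as.Date(date))$mon + 1L
  season <- c("Summer", "Summer", rep("Autumn", 3), rep("Winter", 3),
              rep("Spring", 3), "Summer")[m]
  factor(season, levels = season_levels())
}

#' Validate an observation log file or data frame
#'
#' Runs the schema and invariant checks of [read_observation_log()] /
#' [as_observation_log()] but collects problems instead of stopping.
#'
#' @param x a path to a CSV log, or a data frame.
#' @return List with elements `valid` (logical) and `problems`
#'   (character vector of row-level messages, empty when clean).
#' @export
validate_observation_log <- function(x) {
  res <- tryCatch({
    if (is.character(x) && length(x) == 1) read_observation_log(x)
    else as_observation_log(x)
    character(0)
  }, error = function(e) {
    strsplit(conditionMessage(e), "\n  ", fixed = TRUE)[[1]]
  })
  list(valid = length(res) == 0, problems = res)
}
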