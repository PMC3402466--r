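#' Extract behavioural-state transitions from an observation log
#'
#' Each pair of consecutive samples within a follow whose spacing lies within
#' `nominal_interval +/- gap_tolerance` yields one first-order transition:
#' preceding state at time 0, succeeding state at time 1.  Pairs spanning
#' follows, or gaps outside the tolerance, break the chain and produce no
#' transition.  The transition's stratum (season, time block) is taken from
#' its first sample, which anchors the Markov step.
#'
#' @param log an [as_observation_log()] data frame, sorted by timestamp
#'   within follow (as the constructor guarantees).
#' @param nominal_interval nominal sampling interval in seconds (150 s).
#' @param gap_tolerance permitted jitter around the nominal interval, seconds.
#' @return Data frame of transitions with columns `follow_id`, `t0`
#'   (POSIXct of first sample), `preceding`, `succeeding`, `v0`, `v1`
#'   (vessel counts at the endpoints), `season`, `tod_index`, `time_block`,
#'   and `.row0` (row index of the first sample in `log`).
#' @export
extract_transitions <- function(log, nominal_interval = 150,
                                gap_tolerance = 30) {
  stopifnot(nominal_interval > 0, gap_tolerance >= 0)
  if (nrow(log) == 0) return(empty_transitions())
  t_num <- as.numeric(log$timestamp)
  same_follow <- log$follow_id[-1] == log$follow_id[-nrow(log)]
  if (any(diff(t_num)[same_follow] < 0)) {
    stop("records are not sorted by timestamp within follow", call. = FALSE)
  }
  dt <- diff(t_num)
  ok <- same_follow & abs(dt - nominal_interval) <= gap_tolerance
  i <- which(ok)
  if (length(i) == 0) return(empty_transitions())
  idx <- time_of_day_index(log$timestamp[i], log$sunrise[i], log$sunset[i])
  block <- suppressWarnings(classify_time_block(idx))
  out <- data.frame(
    follow_id = log$follow_id[i],
    t0 = log$timestamp[i],
    preceding = log$state[i],
    succeeding = log$state[i + 1],
    v0 = log$n_vessels[i],
    v1 = log$n_vessels[i + 1],
    season = classify_season(log$date[i]),
    tod_index = idx,
    time_block = as.vector(block),
    .row0 = i,
    stringsAsFactors = FALSE
  )
  out$time_block <- factor(out$time_block, levels = time_block_levels())
  rownames(out) <- NULL
  out
}

empty_transitions <- function() {
  data.frame(
    follow_id = character(0),
    t0 = as.POSIXct(character(0), tz = "UTC"),
    preceding = factor(character(0), levels = behaviour_states()),
    succeeding = factor(character(0), levels = behaviour_states()),
    v0 = integer(0), v1 = integer(0),
    season = factor(character(0), levels = season_levels()),
    tod_index = numeric(0),
    time_block = factor(character(0), levels = time_block_levels()),
    .row0 = integer(0),
    stringsAsFactors = FALSE
  )
}

#' Assign each transition to the Control or Treatment chain
#'
#' A transition is Treatment when vessels are present (within the 300 m
#' interaction threshold, aircraft included) at both endpoint samples.  It is
#' Control only when no vessels are present at either endpoint *and* every
#' sample in the `buffer` window (default 15 min) preceding its first sample
#' is vessel-free, with the window fully observed: an unbroken run of samples
#' reaching back at least `buffer` seconds.  Follow starts or chain breaks
#' inside the window leave the vessel-free history unverifiable, and the
#' transition is Excluded; so are mixed transitions with a vessel at exactly
#' one endpoint (vessel arrival or departure mid-transition).
#'
#' @param transitions output of [extract_transitions()].
#' @param log the observation log the transitions were extracted from.
#' @param buffer vessel-free history required before a Control transition,
#'   seconds (900 s = 15 min).
#' @param nominal_interval,gap_tolerance chain-continuity parameters; must
#'   match those used in [extract_transitions()].
#' @return `transitions` with an added `condition` factor
#'   (Control / Treatment / Excluded).
#' @export
assign_condition <- function(transitions, log, buffer = 900,
                             nominal_interval = 150, gap_tolerance = 30) {
  stopifnot(buffer >= 0)
  if (nrow(transitions) == 0) {
    transitions$condition <- factor(character(0),
                                    levels = c("Control", "Treatment", "Excluded"))
    return(transitions)
  }
  t_num <- as.numeric(log$timestamp)
  n <- nrow(log)
  new_follow <- c(TRUE, log$follow_id[-1] != log$follow_id[-n])
  gap_break <- c(TRUE, abs(diff(t_num) - nominal_interval) > gap_tolerance)
  run <- cumsum(new_follow | gap_break)
  run_start <- stats::ave(t_num, run, FUN = min)
  # latest vessel sighting at or before each sample, within its unbroken run
  vessel_time <- ifelse(log$n_vessels > 0, t_num, -Inf)
  last_vessel <- stats::ave(vessel_time, run, FUN = cummax)

  i <- transitions$.row0
  t0 <- t_num[i]
  treat <- transitions$v0 > 0 & transitions$v1 > 0
  history_ok <- (t0 - run_start[i]) >= buffer
  vessel_free <- last_vessel[i] < (t0 - buffer)
  ctrl <- transitions$v0 == 0 & transitions$v1 == 0 & history_ok & vessel_free
  condition <- ifelse(treat, "Treatment", ifelse(ctrl, "Control", "Excluded"))
  transitions$condition <- factor(condition,
                                  levels = c("Control", "Treatment", "Excluded"))
  transitions
}

#' Tabulate transitions into a five-way count table
#'
#' Counts transitions by preceding state x succeeding state x season x
#' time block x condition.  Excluded transitions must be filtered out first;
#' the total of the table equals the number of input transitions.
#'
#' @param transitions classified transitions from [assign_condition()],
#'   restricted to Control and Treatment.
#' @param states ordered state labels for the behaviour axes.
#' @return A 5-way integer array of class `transition_table` with dimensions
#'   preceding, succeeding, season, time_block, condition.
#' @export
tabulate_transitions <- function(transitions, states = behaviour_states()) {
  if (any(transitions$condition == "Excluded", na.rm = TRUE)) {
    stop("transitions contain Excluded entries; filter them out before ",
         "tabulating", call. = FALSE)
  }
  tab <- table(
    preceding = factor(transitions$preceding, levels = states),
    succeeding = factor(transitions$succeeding, levels = states),
    season = factor(transitions$season, levels = season_levels()),
    time_block = factor(transitions$time_block, levels = time_block_levels()),
    condition = factor(transitions$condition, levels = c("Control", "Treatment"))
  )
  out <- array(as.integer(tab), dim = dim(tab), dimnames = dimnames(tab))
  class(out) <- c("transition_table", class(out))
  out
}

#' Remove a behavioural state from a transition count table
#'
#' Drops the state's row and column from the behaviour axes; transitions
#' touching the state are discarded, not bridged (bridging two 150 s steps
#' would fabricate a 300 s "transition").  Used to remove Feeding, which is
#' too rare (< 0.5 % of samples) to model.
#'
#' @param table a `transition_table`.
#' @param state state label to remove.
#' @return The reduced `transition_table`.
#' @export
drop_state <- function(table, state = "Feeding") {
  states <- dimnames(table)$preceding
  if (!(state %in% states)) {
    stop("state '", state, "' is not present in the table", call. = FALSE)
  }
  keep <- setdiff(states, state)
  out <- table[keep, keep, , , , drop = FALSE]
  class(out) <- c("transition_table", "array")
  out
}

#' Stratum totals of a transition table
#'
#' Collapses the behaviour axes to give the season x time block x condition
#' transition totals — the 24-cell layout in which field studies print their
#' sample-size breakdown.
#'
#' @param table a `transition_table`.
#' @return Data frame with columns `season`, `time_block`, `condition`,
#'   `count` (one row per stratum).
#' @export
stratum_totals <- function(table) {
  tot <- apply(table, c("season", "time_block", "condition"), sum)
  out <- as.data.frame.table(tot, responseName = "count",
                             stringsAsFactors = FALSE)
  out$count <- as.integer(out$count)
  out[order(out$season, out$time_block, out$condition), c(
    "season", "time_block", "condition", "count")] -> out
  rownames(out) <- NULL
  out
}

#' Write / read a transition table as tidy CSV
#'
#' Serialises the five-way counts as one row per cell with columns
#' `preceding`, `succeeding`, `season`, `time_block`, `condition`, `count`.
#'
#' @param table a `transition_table`.
#' @param path CSV path.
#' @return `write_transition_table()` returns `path` invisibly;
#'   `read_transition_table()` returns the `transition_table`.
#' @export
write_transition_table <- function(table, path) {
  df <- as.data.frame.table(table, responseName = "count",
                            stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transition_table
#' @export
read_transition_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("preceding", "succeeding", "season", "time_block",
                "condition", "count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("transition table CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  states <- unique(df$preceding)
  tab <- stats::xtabs(count ~ preceding + succeeding + season + time_block +
                        condition,
                      data = transform(
                        df,
                        preceding = factor(preceding, levels = states),
                        succeeding = factor(succeeding, levels = states),
                        season = factor(season, levels = season_levels()),
                        time_block = factor(time_block, levels = time_block_levels()),
                        condition = factor(condition,
                                           levels = sort(unique(df$condition)))
                      ))
  out <- array(as.integer(tab), dim = dim(tab), dimnames = dimnames(tab))
  class(out) <- c("transition_table", class(out))
  out
}
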