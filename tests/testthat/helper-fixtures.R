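# Build a single-follow observation log on the 150 s sampling grid.
grid_log <- function(states, vessels = 0, follow_id = "F1",
                     date = "2009-04-15", start_sec = 10 * 3600,
                     sunrise = "06:45", sunset = "18:15", interval = 150,
                     times = NULL) {
  n <- length(states)
  vessels <- rep_len(vessels, n)
  secs <- if (is.null(times)) start_sec + interval * (seq_len(n) - 1) else times
  df <- data.frame(
    follow_id = follow_id,
    timestamp = as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + secs,
    state = states,
    n_vessels = vessels,
    date = as.Date(date),
    sunrise = hms_to_seconds(sunrise),
    sunset = hms_to_seconds(sunset),
    stringsAsFactors = FALSE
  )
  as_observation_log(df)
}

bind_logs <- function(...) {
  as_observation_log(do.call(rbind, lapply(list(...), as.data.frame)))
}

# Random strictly positive row-stochastic matrix (irreducible by construction).
random_stochastic_matrix <- function(n = 4, concentration = 1,
                                     states = head(analysis_states(), n)) {
  m <- matrix(stats::rgamma(n * n, shape = concentration) + 1e-4, n, n,
              dimnames = list(states, states))
  m / rowSums(m)
}

# Count consecutive state pairs of a simulated sequence into a matrix.
sequence_to_counts <- function(seq_states, levels) {
  n <- length(seq_states)
  table(factor(seq_states[-n], levels = levels),
        factor(seq_states[-1], levels = levels))
}
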