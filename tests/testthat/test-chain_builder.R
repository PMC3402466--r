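test_that("transitions come only from consecutive samples within a follow", {
  log <- grid_log(c("Resting", "Resting", "Traveling"))
  tr <- extract_transitions(log)
  expect_equal(nrow(tr), 2)
  expect_equal(as.character(tr$preceding), c("Resting", "Resting"))
  expect_equal(as.character(tr$succeeding), c("Resting", "Traveling"))

  # a 450 s gap breaks the chain
  gap <- grid_log(c("Resting", "Milling", "Traveling"),
                  times = 10 * 3600 + c(0, 150, 600))
  expect_equal(nrow(extract_transitions(gap, gap_tolerance = 30)), 1)

  # no transition spans a follow boundary
  two <- bind_logs(grid_log(c("Resting", "Milling"), follow_id = "A"),
                   grid_log(c("Traveling", "Resting"), follow_id = "B"))
  tr2 <- extract_transitions(two)
  expect_equal(nrow(tr2), 2)
  expect_equal(sort(unique(tr2$follow_id)), c("A", "B"))

  expect_equal(nrow(extract_transitions(grid_log("Resting"))), 0)

  shuffled <- grid_log(c("Resting", "Milling", "Traveling"))
  shuffled <- shuffled[c(3, 1, 2), ]
  expect_error(extract_transitions(shuffled), "sorted")
})

test_that("stratum of a transition comes from its first sample", {
  # follow crossing the morning/midday boundary (sunrise 06:00, sunset 18:00):
  # index 0.33 is at 09:57:36
  log <- grid_log(c("Resting", "Resting", "Resting", "Resting"),
                  sunrise = "06:00", sunset = "18:00",
                  start_sec = hms_to_seconds("09:55"))
  tr <- extract_transitions(log)
  # block boundary index 0.33 falls at 09:57:36
  expect_equal(as.character(tr$time_block), c("Morning", "Morning", "Midday"))
  expect_equal(as.character(tr$season), rep("Autumn", 3))
})

test_that("condition assignment follows the 15-minute control buffer rule", {
  states <- rep("Resting", 10)
  # vessels at both endpoints -> Treatment
  log <- grid_log(states, vessels = 1)
  tr <- assign_condition(extract_transitions(log), log)
  expect_true(all(tr$condition == "Treatment"))

  # vessel-free follow: Control only once 900 s of history is observed
  log <- grid_log(states, vessels = 0)
  tr <- assign_condition(extract_transitions(log), log)
  # first sample at t=0; transitions starting before 900 s lack history
  elapsed <- as.numeric(tr$t0) - as.numeric(log$timestamp[1])
  expect_equal(as.character(tr$condition),
               ifelse(elapsed >= 900, "Control", "Excluded"))
  expect_equal(sum(tr$condition == "Control"), 3)

  # a vessel 10 min before an otherwise clean transition -> Excluded
  vessels <- rep(0, 14)
  vessels[4] <- 2    # vessel at t = 450 s
  log <- grid_log(rep("Milling", 14), vessels = vessels)
  tr <- assign_condition(extract_transitions(log), log)
  t0 <- as.numeric(tr$t0) - as.numeric(log$timestamp[1])
  # transition at t0 = 1050 s: vessel 600 s earlier, inside the buffer
  expect_equal(as.character(tr$condition[t0 == 1050]), "Excluded")
  # transition at t0 = 1350 s: vessel exactly 900 s earlier still disqualifies
  expect_equal(as.character(tr$condition[t0 == 1350]), "Excluded")
  # transition at t0 = 1500 s: vessel 1050 s earlier, buffer clean
  expect_equal(as.character(tr$condition[t0 == 1500]), "Control")

  # vessel at exactly one endpoint -> Excluded (mixed transition)
  log <- grid_log(rep("Resting", 2), vessels = c(0, 1))
  tr <- assign_condition(extract_transitions(log), log)
  expect_equal(as.character(tr$condition), "Excluded")

  # condition assignment is a partition
  set.seed(7)
  log <- grid_log(sample(analysis_states(), 50, replace = TRUE),
                  vessels = sample(0:2, 50, replace = TRUE))
  tr <- assign_condition(extract_transitions(log), log)
  expect_false(any(is.na(tr$condition)))
  expect_true(all(tr$condition %in% c("Control", "Treatment", "Excluded")))
})

test_that("a chain break inside the buffer window spoils control history", {
  # two unbroken runs separated by a 600 s gap; second run is vessel-free
  # but its early transitions cannot verify 15 vessel-free minutes
  times <- c(0, 150, 300, 900, 1050, 1200, 1350, 1500, 1650, 1800, 1950,
             2100) + 10 * 3600
  log <- grid_log(rep("Traveling", 12), vessels = 0, times = times)
  tr <- assign_condition(extract_transitions(log), log)
  t0 <- as.numeric(tr$t0) -
    as.numeric(as.POSIXct("2009-04-15", tz = "UTC")) - 10 * 3600
  expect_equal(as.character(tr$condition[t0 < 1800]),
               rep("Excluded", sum(t0 < 1800)))
  expect_equal(as.character(tr$condition[t0 >= 1800]),
               rep("Control", sum(t0 >= 1800)))
})

test_that("tabulation conserves transitions and ignores input order", {
  log <- grid_log(rep(c("Resting", "Milling"), 6), vessels = 1,
                  start_sec = 12 * 3600)
  tr <- assign_condition(extract_transitions(log), log)
  tab <- tabulate_transitions(tr)
  expect_s3_class(tab, "transition_table")
  expect_equal(sum(tab), nrow(tr))
  expect_equal(dim(tab), c(5, 5, 4, 3, 2))
  # two identical transitions land in one cell
  cell <- tab["Resting", "Milling", "Autumn", "Midday", "Treatment"]
  expect_equal(as.integer(cell), 6)

  set.seed(1)
  perm <- tr[sample(nrow(tr)), ]
  expect_equal(tabulate_transitions(perm), tab)

  empty <- tabulate_transitions(tr[0, ])
  expect_equal(sum(empty), 0)

  tr$condition[1] <- "Excluded"
  expect_error(tabulate_transitions(tr), "Excluded")
})

test_that("dropping a state removes its row, column and transitions", {
  log <- grid_log(c("Resting", "Feeding", "Resting", "Milling"), vessels = 1)
  tab <- tabulate_transitions(
    assign_condition(extract_transitions(log), log))
  expect_equal(sum(tab), 3)
  red <- drop_state(tab, "Feeding")
  expect_equal(dim(red)[1:2], c(4, 4))
  expect_equal(sum(red), 1)    # Resting->Feeding and Feeding->Resting gone
  expect_error(drop_state(red, "Feeding"), "not present")

  # absent state: dropping is lossless on the remaining counts
  log2 <- grid_log(c("Resting", "Milling", "Resting"), vessels = 1)
  tab2 <- tabulate_transitions(
    assign_condition(extract_transitions(log2), log2))
  red2 <- drop_state(tab2, "Feeding")
  expect_equal(sum(red2), sum(tab2))
})

test_that("stratum totals and tidy CSV round-trip preserve the table", {
  set.seed(2)
  log <- grid_log(sample(analysis_states(), 40, replace = TRUE), vessels = 1)
  tab <- tabulate_transitions(
    assign_condition(extract_transitions(log), log))
  tot <- stratum_totals(tab)
  expect_equal(nrow(tot), 24)
  expect_equal(sum(tot$count), sum(tab))

  path <- withr::local_tempfile(fileext = ".csv")
  write_transition_table(tab, path)
  back <- read_transition_table(path)
  expect_equal(sum(back), sum(tab))
  expect_equal(back["Resting", "Milling", "Autumn", "Midday", "Treatment"],
               tab["Resting", "Milling", "Autumn", "Midday", "Treatment"])
})
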