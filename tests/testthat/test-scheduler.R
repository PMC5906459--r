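test_that("a well-to-well transition emits the seven-phase choreography in under 2 s", {
  tr <- transition_sequence("A1", "A2")
  ev <- tr$events
  expect_equal(nrow(ev), 7)
  expect_equal(ev$actor, c("out_valve", "bp_valve", "servo", "plate",
                           "servo", "bp_valve", "out_valve"))
  expect_equal(ev$action, c("close", "open", "raise", "move", "lower",
                            "close", "open"))
  expect_lt(tr$duration_s, 2)
  expect_true(all(diff(ev$time_s) >= 0))

  # same-well transition: move phase collapses, other phases unchanged
  tr0 <- transition_sequence("A1", "A1")
  expect_equal(nrow(tr0$events), 7)
  expect_equal(tr0$duration_s, tr$duration_s - timing_profile()$t_move_per_well)

  zero <- timing_profile(0, 0, 0, 0, 0, 0, 0)
  trz <- transition_sequence("A1", "B5", zero)
  expect_equal(trz$duration_s, 0)
  expect_equal(unique(trz$events$time_s), 0)
  expect_equal(nrow(trz$events), 7)
})

test_that("the staining protocol compiles to ten exposure steps summing 85.5 min", {
  sp <- staining_protocol()
  tl <- compile_protocol(sp$map, sp$steps)
  expect_equal(nrow(tl$steps), 10)
  expect_equal(exposure_minutes(tl), 85.5)
  expect_equal(tl$steps$fluid[c(2, 4, 6, 7, 9)],
               c("PFA-4%", "TritonX100-0.25%", "BSA-1%",
                 "phalloidin-AF488", "Hoechst-33342"))
  # the two 30-min incubations pause flow; nothing else does
  expect_equal(tl$steps$paused, c(FALSE, FALSE, FALSE, FALSE, FALSE,
                                  TRUE, TRUE, FALSE, FALSE, FALSE))
  # exact duration: exposures + fill delays + transitions
  expect_equal(tl$duration_s,
               85.5 * 60 + 9 * 30 + sum(vapply(1:10, function(i) {
                 from <- if (i == 1) NULL else sp$steps[[i - 1]]$well
                 transition_sequence(from, sp$steps[[i]]$well)$duration_s
               }, numeric(1))))
  expect_equal(validate_timeline(tl), data.frame(time_s = numeric(0),
                                                 type = character(0),
                                                 message = character(0),
                                                 stringsAsFactors = FALSE),
               ignore_attr = TRUE)
  expect_equal(timeline_commands(tl),
               commands_for_order(paste0("A", 1:10)))
})

test_that("empty protocols compile to an empty timeline", {
  sp <- staining_protocol()
  tl <- compile_protocol(sp$map, list())
  expect_equal(tl$duration_s, 0)
  expect_equal(nrow(tl$events), 0)
})

test_that("a dose-response step spans fill delay plus four stimulus periods", {
  st <- dose_response_step("A2")
  expect_equal(st$fill_delay_s, 45)
  expect_equal(st$duration_s, 240)
  p <- plate_spec("96-deep")
  df <- data.frame(well = c("A1", "A2"), fluid = c("buffer", "odor"),
                   concentration = NA_real_, volume_ul = 2000)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  map <- read_plate_map(path, p)
  tl <- compile_protocol(map, list(dose_response_step("A2")))
  per_well <- tl$steps$exposure_end_s - tl$steps$fill_start_s
  expect_equal(per_well, 45 + 4 * 60)
  # four odor pulses and four acquisitions
  expect_equal(sum(tl$events$actor == "stim" & tl$events$action == "pulse_on"), 4)
  expect_equal(sum(tl$events$actor == "camera" &
                     tl$events$action == "acquire_start"), 4)
  pulse_on <- tl$events$time_s[tl$events$actor == "stim" &
                                 tl$events$action == "pulse_on"]
  expect_equal(diff(pulse_on), rep(60, 3))
})

test_that("fill delay and well flow budget follow their closed forms", {
  tb <- tube_spec(); fl <- flow_spec()
  expect_equal(fill_delay_for(tb, fl, 5), 5 * tube_volume(tb) / 2)
  expect_equal(fill_delay_for(tb, fl, 5), 27, tolerance = 1e-3)
  expect_equal(fill_delay_for(tb, fl, 0), 0)
  # 11 uL nominal volume at 2 uL/s: about the programmed 30 s
  expect_equal(5 * 11 / 2, 27.5)
  expect_error(fill_delay_for(tb, flow_spec(flowrate_ul_s = 0)), "flowrate")

  expect_equal(well_flow_budget(2000), 1000 / 60)
  expect_equal(round(well_flow_budget(2000)), 17)
  expect_equal(well_flow_budget(600), 5)
  expect_equal(well_flow_budget(0), 0)
  expect_error(well_flow_budget(100, flow_spec(flowrate_ul_s = 0)), "flowrate")
})

test_that("compilation rejects unassigned wells, wrong fluids, and overdrawn wells", {
  sp <- staining_protocol()
  expect_error(compile_protocol(sp$map, list(protocol_step("B1", 10))),
               "B1 is not assigned")
  expect_error(compile_protocol(sp$map, list(protocol_step("A1", 10, fluid = "PFA-4%"))),
               "holds")
  # 2000 uL at 2 uL/s allows 1000 s of flow; 1200 s overdraws
  expect_error(compile_protocol(
    sp$map, list(protocol_step("A2", 1200, fill_delay_s = 0, pause_flow = FALSE))),
    "overdraw in well A2")
  # the same exposure with paused flow only draws the fill volume
  tl <- compile_protocol(
    sp$map, list(protocol_step("A2", 1200, fill_delay_s = 30, pause_flow = TRUE)))
  expect_equal(tl$steps$drawn_ul, 60)
})

test_that("validate_timeline catches injected valve-safety and overdraw faults", {
  # outlet opened while the servo is still raised
  bad <- rbind(
    data.frame(time_s = 0, actor = "servo", action = "raise", detail = NA),
    data.frame(time_s = 1, actor = "out_valve", action = "open", detail = NA))
  tl <- structure(list(events = bad, steps = NULL, duration_s = 1, map = NULL),
                  class = "timeline")
  v <- validate_timeline(tl)
  expect_equal(v$type, "valve_safety")

  sp <- staining_protocol()
  tl2 <- compile_protocol(sp$map, list(protocol_step("A1", 20, fill_delay_s = 0)))
  tl2$steps$drawn_ul <- 99999   # corrupt the budget record
  v2 <- validate_timeline(tl2)
  expect_true(any(v2$type == "volume_overdraw"))
})

test_that("compiled timelines always satisfy the valve-safety invariant", {
  sp <- staining_protocol()
  protos <- list(
    sp$steps,
    list(protocol_step("A1", 5), protocol_step("A3", 5),
         protocol_step("A1", 5)),
    list(dose_response_step("A2", fill_delay_s = 10))
  )
  for (steps in protos) {
    tl <- compile_protocol(sp$map, steps)
    expect_equal(nrow(validate_timeline(tl)), 0)
  }
})

test_that("compilation is deterministic and preserves step order", {
  sp <- staining_protocol()
  tl1 <- compile_protocol(sp$map, sp$steps)
  tl2 <- compile_protocol(sp$map, sp$steps)
  expect_identical(tl1, tl2)
  expect_equal(tl1$steps$well, paste0("A", 1:10))
  expect_equal(tl1$steps$step, 1:10)
  # duration identity: exposures + fills + transitions
  trans <- sum(tl1$events$time_s[tl1$events$action == "move"] * 0) +
    tl1$duration_s - sum(tl1$steps$duration_s) - sum(tl1$steps$fill_delay_s)
  expect_gt(trans, 0)
  expect_equal(tl1$duration_s,
               sum(tl1$steps$duration_s) + sum(tl1$steps$fill_delay_s) + trans)
})

test_that("timelines export to CSV and JSON", {
  sp <- staining_protocol()
  tl <- compile_protocol(sp$map, sp$steps[1:3])
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_timeline_csv(tl, csv)
  ev <- read.csv(csv)
  expect_equal(nrow(ev), nrow(tl$events))
  timeline_to_json(tl, js)
  back <- jsonlite::fromJSON(js)
  expect_equal(back$duration_s, tl$duration_s)
  expect_equal(nrow(back$steps), 3)
})
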