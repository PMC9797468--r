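mk_events <- function(t, tag, box, pos, enc = "E1") {
  data.frame(timestamp = t, tag_id = tag, box_id = box, position = pos,
             enclosure_id = enc, stringsAsFactors = FALSE)
}

test_that("visit pairing follows the two-antenna automaton", {
  # entry outer->inner, exit inner->outer
  ev <- mk_events(c(10, 12, 50, 52), "x", "box1",
                  c("outer", "inner", "inner", "outer"))
  v <- extract_visits(ev)
  expect_equal(nrow(v), 1)
  expect_equal(v$t_enter, 12)
  expect_equal(v$t_exit, 52)

  # exit without entry is equivocal, no visit
  ev2 <- mk_events(c(10, 12), "x", "box1", c("inner", "outer"))
  v2 <- extract_visits(ev2)
  expect_equal(nrow(v2), 0)
  expect_gt(attr(v2, "equivocal"), 0)

  # a new credible entry closes the open visit at its inner-read time
  ev3 <- mk_events(c(10, 12, 30, 32, 60, 62), "x", "box2",
                   c("outer", "inner", "outer", "inner", "inner", "outer"))
  v3 <- extract_visits(ev3)
  expect_equal(nrow(v3), 2)
  expect_equal(v3$t_enter, c(12, 32))
  expect_equal(v3$t_exit, c(32, 62))
})

test_that("visit totals are invariant under time translation", {
  set.seed(4)
  run <- simulate_run(sim_config(duration_days = 2, birth_rate = 0,
                                 emigration_rate = 0), seed = 4)
  v1 <- extract_visits(run$events)
  ev2 <- run$events
  ev2$timestamp <- ev2$timestamp + 12345
  v2 <- extract_visits(ev2)
  tot1 <- tapply(v1$t_exit - v1$t_enter, paste(v1$tag_id, v1$box_id), sum)
  tot2 <- tapply(v2$t_exit - v2$t_enter, paste(v2$tag_id, v2$box_id), sum)
  expect_equal(tot1, tot2)
})

test_that("check censoring removes events until the following midnight", {
  # check 09:00-10:00 on day 5 (day counting from 0): all events from
  # 09:00 to midnight removed
  t_day5 <- 5 * DAY
  ev <- mk_events(t_day5 + c(8, 9.5, 15, 23.9, 24.1) * 3600, "x", "box1",
                  "inner")
  checks <- data.frame(start = t_day5 + 9 * 3600, end = t_day5 + 10 * 3600,
                       kind = "minor")
  out <- censor_checks(ev, checks)
  expect_equal(out$timestamp, t_day5 + c(8, 24.1) * 3600)

  # no checks: unchanged
  expect_equal(censor_checks(ev, NULL), ev)

  # check ending 23:59 censors until the next midnight, one minute later
  checks2 <- data.frame(start = t_day5 + 23 * 3600,
                        end = t_day5 + 23.9833 * 3600, kind = "minor")
  out2 <- censor_checks(ev, checks2)
  expect_true(all(out2$timestamp < t_day5 + 23 * 3600 |
                    out2$timestamp >= 6 * DAY))
  expect_true((t_day5 + 24.1 * 3600) %in% out2$timestamp)
})

test_that("retained visits lie wholly outside censored windows", {
  # visit spanning a check window is clipped at the boundary
  v <- data.frame(tag_id = "x", box_id = "box1",
                  t_enter = c(100, 5000), t_exit = c(90000, 6000),
                  stringsAsFactors = FALSE)
  checks <- data.frame(start = 10000, end = 20000, kind = "minor")
  out <- clip_visits_to_checks(v, checks)
  win_end <- DAY  # next midnight after 20000 s
  expect_true(all(out$t_exit <= 10000 | out$t_enter >= win_end))
  # total retained time is the part outside [10000, 86400)
  expect_equal(sum(out$t_exit - out$t_enter), (10000 - 100) + 1000 + (90000 - DAY))
})

test_that("time layers split at silent gaps and caps, then merge short ones", {
  # continuous 30 h of reads -> one layer
  ev <- mk_events(seq(0, 30 * 3600, by = 600), "x", "box1", "inner")
  lay <- build_time_layers(ev)
  expect_equal(nrow(lay), 1)
  expect_equal(lay$mid_time_days, (0 + 30 * 3600) / 2 / DAY)

  # 40 h record with a 2 h silence at hour 10: the 10 h piece merges back
  tt <- c(seq(0, 10 * 3600, by = 600), seq(12 * 3600, 40 * 3600, by = 600))
  lay2 <- build_time_layers(mk_events(tt, "x", "box1", "inner"))
  expect_equal(nrow(lay2), 1)
  expect_equal(lay2$t_start, 0)
  expect_equal(lay2$t_end, 40 * 3600)

  # a 100 h continuous record is capped into 48 h pieces (48+48+4 -> the
  # 4 h remnant merges into its neighbour)
  lay3 <- build_time_layers(mk_events(seq(0, 100 * 3600, by = 600), "x",
                                      "box1", "inner"))
  expect_equal(nrow(lay3), 2)
  expect_true(all(lay3$t_end - lay3$t_start >= 24 * 3600))

  # determinism
  expect_identical(lay3, build_time_layers(mk_events(seq(0, 100 * 3600, by = 600),
                                                     "x", "box1", "inner")))
  expect_error(build_time_layers(data.frame(timestamp = numeric(0))),
               "no events")
})

test_that("simulated records produce layer spans of 24-107 h, mostly short", {
  spans <- unlist(lapply(1:3, function(s) {
    run <- simulate_run(sim_config(duration_days = 12, birth_rate = 0,
                                   emigration_rate = 0), seed = s)
    lay <- build_time_layers(run$events)
    (lay$t_end - lay$t_start) / 3600
  }))
  expect_true(all(spans >= 24 & spans <= 107))
  expect_gt(mean(spans < 72), 0.5)
})

test_that("visits split at layer boundaries conserve their time", {
  v <- data.frame(tag_id = "x", box_id = "box1", t_enter = 100,
                  t_exit = 50000, stringsAsFactors = FALSE)
  layers <- data.frame(index = 1:2, t_start = c(0, 30000),
                       t_end = c(30000, 60000),
                       mid_time_days = c(15000, 45000) / DAY)
  lv <- assign_visits_to_layers(v, layers)
  expect_equal(nrow(lv), 2)
  expect_equal(sum(lv$t_exit - lv$t_enter), 50000 - 100)
})

test_that("migration detection counts enclosure switches and attempts", {
  # single-enclosure reads: no migrations
  ev <- mk_events(1:3, "x", "box1", "inner", enc = "A")
  res <- detect_migrations(ev)
  expect_equal(nrow(res$migrations), 0)

  # A, A, B, B, A -> two migrations
  ev2 <- mk_events(1:5, "x", "box1", "inner", enc = c("A", "A", "B", "B", "A"))
  res2 <- detect_migrations(ev2)
  expect_equal(nrow(res2$migrations), 2)
  expect_equal(res2$migrations$from_enclosure, c("A", "B"))
  expect_equal(res2$migrations$to_enclosure, c("B", "A"))

  # tube hit followed by a same-enclosure read: an attempt, not a migration
  ev3 <- mk_events(1:3, "x", c("box1", "connector-left", "box2"),
                   c("inner", "single", "inner"), enc = "A")
  res3 <- detect_migrations(ev3)
  expect_equal(nrow(res3$migrations), 0)
  expect_equal(res3$attempts, 1)
})
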