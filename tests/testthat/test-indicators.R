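test_that("sedentary bouts implement the occupied/vacated subtraction", {
  b <- detect_sedentary_bouts(mk_mat(c(0, 300), c(TRUE, FALSE)))
  expect_equal(nrow(b), 1)
  expect_equal(b$s, 300)
  expect_true(b$complete)
  expect_equal(secs_between(b$t_pre_occupied, b$t_unoccupied), b$s)

  expect_equal(nrow(detect_sedentary_bouts(mk_mat(numeric(), logical()))), 0)

  # flicker shorter than the debounce merges into one bout
  b <- detect_sedentary_bouts(
    mk_mat(c(0, 100, 101, 400), c(TRUE, FALSE, TRUE, FALSE)), debounce_s = 2)
  expect_equal(b$s, 400)

  # trailing occupied is an open, incomplete bout
  b <- detect_sedentary_bouts(mk_mat(c(0, 50, 60), c(TRUE, FALSE, TRUE)))
  expect_equal(b$complete, c(TRUE, FALSE))
  expect_true(is.na(b$s[2]))

  expect_error(detect_sedentary_bouts(mk_mat(c(10, 0), c(TRUE, FALSE))),
               "sorted")
  expect_error(detect_sedentary_bouts(mk_motion(0, "kitchen")), "mat")
})

test_that("sedentary pairing matches the enumeration oracle (length <= 6)", {
  # all occupancy flag sequences of length 1..6 on a fixed grid, two
  # debounce settings, one min-bout setting
  for (len in 1:6) {
    grid <- expand.grid(rep(list(c(TRUE, FALSE)), len))
    times <- cumsum(c(0, rep_len(c(3, 1), len)[-1]))
    for (g in seq_len(nrow(grid))) {
      flags <- unlist(grid[g, ], use.names = FALSE)
      for (deb in c(0, 2)) {
        got <- detect_sedentary_bouts(mk_mat(times, flags), debounce_s = deb)
        want <- oracle_bouts(flags, times, debounce_s = deb)
        comp <- got[got$complete, , drop = FALSE]
        expect_equal(nrow(comp), length(want$complete))
        if (nrow(comp)) {
          expect_equal(comp$s,
                       vapply(want$complete, function(b) b$end - b$start, 0))
        }
        expect_equal(any(!got$complete), !is.na(want$open_start))
      }
    }
  }
})

test_that("stair climbs implement the two-trigger subtraction", {
  c1 <- detect_stair_climbs(mk_distance(c(0, 12.3),
                                        c("first_step", "last_step")))
  expect_equal(c1$sc, 12.3)
  expect_equal(c1$direction, "up")
  expect_true(c1$complete)

  c2 <- detect_stair_climbs(mk_distance(c(0, 9), c("last_step", "first_step")))
  expect_equal(c2$sc, 9)
  expect_equal(c2$direction, "down")

  c3 <- detect_stair_climbs(mk_distance(c(0, 121),
                                        c("first_step", "first_step")),
                            pairing_window_s = 120)
  expect_equal(c3$complete, c(FALSE, FALSE))

  expect_error(detect_stair_climbs(mk_mat(0, TRUE)), "distance")
})

test_that("stair pairing matches the brute-force oracle (length <= 5)", {
  positions <- c("first_step", "last_step")
  for (len in 1:5) {
    combos <- expand.grid(rep(list(positions), len),
                          stringsAsFactors = FALSE)
    times <- cumsum(c(0, rep_len(c(5, 40), len)[-1]))
    for (g in seq_len(nrow(combos))) {
      pos <- unlist(combos[g, ], use.names = FALSE)
      for (win in c(30, 120)) {
        got <- detect_stair_climbs(mk_distance(times, pos),
                                   pairing_window_s = win)
        want <- oracle_climbs(times, pos, win)
        expect_equal(nrow(got), length(want))
        expect_equal(sum(got$complete),
                     sum(vapply(want, function(w) w$complete, TRUE)))
        gsc <- sort(got$sc[got$complete])
        wsc <- sort(vapply(Filter(function(w) w$complete, want),
                           function(w) w$sc, 0))
        expect_equal(gsc, wsc)
      }
    }
  }
})

test_that("room presence confirms transitions and tiles the session", {
  r <- compute_room_presence(mk_motion(c(0, 240), c("living_room", "kitchen")))
  expect_equal(r$r[1], 240)
  expect_equal(r$room, c("living_room", "kitchen"))
  expect_false(r$complete[2])

  single <- compute_room_presence(mk_motion(0, "kitchen"))
  expect_equal(nrow(single), 1)
  expect_true(is.na(single$r))

  # consecutive same-room triggers collapse; durations conserve the span
  ev <- mk_motion(c(0, 10, 30, 100, 400),
                  c("living_room", "living_room", "kitchen", "living_room",
                    "bedroom"))
  r <- compute_room_presence(ev)
  expect_equal(r$room, c("living_room", "kitchen", "living_room", "bedroom"))
  expect_equal(sum(r$r, na.rm = TRUE), 400)  # span 1st..last transition
  # no overlap: each interval starts where the previous one ends
  expect_equal(as.numeric(r$t_next_motion[-nrow(r)]),
               as.numeric(r$t_pre_motion[-1]))

  expect_error(compute_room_presence(mk_motion(0, "garage"),
                                     rooms = c("kitchen", "bedroom")),
               "floor plan")
})

test_that("room presence conservation holds on fuzzed trigger trains", {
  set.seed(5)
  rooms <- c("a", "b", "c")
  for (rep in 1:20) {
    n <- sample(2:25, 1)
    t <- sort(round(runif(n, 0, 2000), 3))
    lab <- sample(rooms, n, replace = TRUE)
    r <- compute_room_presence(mk_motion(t, lab))
    expect_equal(sum(r$r, na.rm = TRUE),
                 as.numeric(r$t_pre_motion[nrow(r)]) -
                   as.numeric(r$t_pre_motion[1]))
  }
})

test_that("outings follow the five-minute no-interior-event rule", {
  o1 <- detect_outings(mk_door(c(0, 360)))
  expect_equal(o1$od, 360)
  expect_equal(o1$o, 1L)

  o2 <- detect_outings(mk_door(c(0, 240)))
  expect_equal(o2$o, 0L)

  o3 <- detect_outings(mk_door(c(0, 600)), mk_motion(300, "kitchen"))
  expect_equal(o3$od, 600)
  expect_equal(o3$o, 0L)

  # boundary: exactly 5 min is not an outing (strict inequality)
  expect_equal(detect_outings(mk_door(c(0, 300)))$o, 0L)
  # events at the door instants themselves do not cancel
  o4 <- detect_outings(mk_door(c(0, 400)), mk_motion(c(0, 400), c("a", "a")))
  expect_equal(o4$o, 1L)
})

test_that("outing enumeration matches the rule oracle (length <= 6)", {
  # door-event counts 0..4 and interior-event counts 0..2, on coarse grids
  door_sets <- list(numeric(), 0, c(0, 200), c(0, 400), c(0, 310, 400),
                    c(0, 400, 650, 1500))
  other_sets <- list(numeric(), 100, c(100, 500))
  for (d in door_sets) {
    for (ot in other_sets) {
      got <- detect_outings(
        if (length(d)) mk_door(d) else empty_events_fixture(),
        if (length(ot)) mk_motion(ot, rep("a", length(ot)))
        else empty_events_fixture())
      want <- oracle_outings(d, ot)
      expect_equal(got$od, want$od)
      expect_equal(got$o, want$o)
    }
  }

  # limit case: zero threshold and no interior events marks every span
  o <- detect_outings(mk_door(c(0, 1, 5, 100)), min_outing_s = 0)
  expect_equal(o$o, rep(1L, 3))
})

test_that("indicator detectors are monotone in their tolerances", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(4:14, 1)
    flags <- sample(c(TRUE, FALSE), n, replace = TRUE)
    t <- sort(round(runif(n, 0, 500), 2))
    n_bouts <- vapply(c(0, 1, 5, 30), function(deb) {
      nrow(detect_sedentary_bouts(mk_mat(t, flags), debounce_s = deb))
    }, 0)
    expect_true(all(diff(n_bouts) <= 0))

    pos <- sample(c("first_step", "last_step"), n, replace = TRUE)
    n_complete <- vapply(c(5, 20, 100, 600), function(w) {
      sum(detect_stair_climbs(mk_distance(t, pos), pairing_window_s = w)$complete)
    }, 0)
    expect_true(all(diff(n_complete) >= 0))
  }
})

test_that("derive_indicators dispatches and passes weight/speaker through", {
  empty <- derive_indicators(event_log())
  expect_s3_class(empty, "indicator_set")
  expect_equal(nrow(empty$bouts) + nrow(empty$climbs) + nrow(empty$presences) +
                 nrow(empty$outings) + nrow(empty$weights) +
                 nrow(empty$dialogue), 0)

  mat_only <- event_log(mk_mat(c(0, 60), c(TRUE, FALSE)))
  ind <- derive_indicators(mat_only)
  expect_equal(nrow(ind$bouts), 1)
  expect_equal(nrow(ind$climbs), 0)
  expect_equal(nrow(ind$presences), 0)

  mixed <- event_log(rbind(
    mk_mat(c(0, 90), c(TRUE, FALSE)),
    sensor_events("scale", "weight_scale", T0 + 120, mass_kg = 80.5),
    sensor_events("spk", "speaker", T0 + 150, question_id = "frequency",
                  answer = "rare")))
  ind <- derive_indicators(mixed)
  expect_equal(ind$weights$mass_kg, 80.5)
  expect_equal(ind$dialogue$answer, "rare")
})
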