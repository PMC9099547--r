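test_that("generated sessions follow the three-run protocol", {
  acts <- generate_session(seed = 2)
  expect_gte(nrow(acts), 18)
  tab <- table(acts$activity_type, acts$run_id)
  expect_true(all(tab[frailtykit:::ACTIVITY_TYPES, ] >= 1))
  # chronological and non-overlapping
  expect_false(is.unsorted(as.numeric(acts$start)))
  expect_true(all(as.numeric(acts$start[-1]) >=
                    as.numeric(acts$end[-nrow(acts)])))
  # determinism
  expect_identical(generate_session(seed = 2), generate_session(seed = 2))
  expect_false(identical(generate_session(seed = 2),
                         generate_session(seed = 3)))
})

test_that("every seed in a sweep covers all six activity types per run", {
  for (seed in 1:60) {
    acts <- generate_session(seed = seed)
    tab <- table(factor(acts$activity_type,
                        levels = frailtykit:::ACTIVITY_TYPES),
                 acts$run_id)
    expect_true(all(tab >= 1), label = paste("seed", seed))
  }
})

test_that("guided room visits cluster around the protocol's two minutes", {
  durs <- unlist(lapply(1:20, function(s) {
    acts <- generate_session(seed = s)
    rp <- acts[acts$activity_type == "room_presence" & acts$run_id == 1 &
                 acts$location != "bathroom", ]
    secs_between(rp$start, rp$end)
  }))
  expect_gt(mean(durs), 100)
  expect_lt(mean(durs), 140)
})

test_that("the slow run stretches stair and sitting durations", {
  ratios <- vapply(1:15, function(s) {
    acts <- generate_session(seed = s)
    sl <- acts$activity_type == "sitting"
    mean(secs_between(acts$start[sl & acts$run_id == 3],
                      acts$end[sl & acts$run_id == 3])) /
      mean(secs_between(acts$start[sl & acts$run_id == 1],
                        acts$end[sl & acts$run_id == 1]))
  }, 0)
  expect_gt(mean(ratios), 1.4)
})

test_that("observation is deterministic and per-type streams independent", {
  acts <- generate_session(seed = 4)
  a <- observe(acts, sensor_model(), seed = 9)
  b <- observe(acts, sensor_model(), seed = 9)
  expect_identical(a$events, b$events)
  # changing only the speaker's noise leaves other streams untouched
  m2 <- sensor_model(speaker_garble_prob = 0.9)
  c2 <- observe(acts, m2, seed = 9)
  for (ty in c("motion", "mat", "distance", "door", "weight_scale")) {
    expect_identical(subset_events(c2, ty)$timestamp,
                     subset_events(a, ty)$timestamp)
  }
})

test_that("zero-noise observation reproduces ground truth exactly", {
  acts <- generate_session(seed = 6)
  log <- observe(acts, sensor_model_zero_noise(), seed = 10)
  ind <- derive_indicators(log)
  sits <- acts[acts$activity_type == "sitting", ]
  expect_equal(sort(ind$bouts$s[ind$bouts$complete]),
               sort(secs_between(sits$start, sits$end)))
  climbs <- acts[acts$activity_type == "stair_climbing", ]
  expect_equal(sort(ind$climbs$sc[ind$climbs$complete]),
               sort(secs_between(climbs$start, climbs$end)))
  expect_equal(sum(ind$outings$o), 3)  # one confirmed outing per run
})

test_that("detection rates recover configured miss probabilities", {
  # binomial parameter recovery at n = 500 with 99% bands
  n <- 500
  starts <- seq(0, by = 120, length.out = n)
  acts <- activity_records("p", 1, rep("stair_climbing", n), "stairs",
                           T0 + starts, T0 + starts + 12)
  m <- sensor_model(miss_probability = c(distance = 0.5))
  log <- observe(acts, m, seed = 77)
  ind <- derive_indicators(log)
  det <- sum(ind$climbs$complete)
  band <- 2.576 * sqrt(0.5 * 0.5 / n)
  expect_lt(abs(det / n - 0.5), band)

  doors <- activity_records("p", 1, rep("entry_exit", n), "entrance",
                            T0 + starts, T0 + starts)
  m2 <- sensor_model(miss_probability = c(door = 0.125))
  log2 <- observe(doors, m2, seed = 78)
  det2 <- nrow(subset_events(log2, "door"))
  band2 <- 2.576 * sqrt(0.125 * 0.875 / n)
  expect_lt(abs(det2 / n - 0.875), band2)
})

test_that("duration-difference spread grows with configured jitter", {
  sds <- vapply(c(0, 0.5, 2), function(jit) {
    diffs <- unlist(lapply(1:4, function(s) {
      acts <- generate_session(seed = s)
      m <- sensor_model(miss_probability = c(distance = 0, door = 0),
                        jitter_sd_s = c(mat = jit))
      ind <- derive_indicators(observe(acts, m, seed = 100 + s))
      al <- align_for_agreement(acts, ind)
      al$sedentary$sensor - al$sedentary$reference
    }))
    sd(diffs)
  }, 0)
  expect_true(all(diff(sds) > 0))
  expect_equal(sds[1], 0)
})

test_that("mat flicker shorter than the debounce does not split bouts", {
  acts <- generate_session(seed = 12)
  m <- sensor_model(miss_probability = c(distance = 0, door = 0),
                    flicker_rate_per_min = c(mat = 3))
  ind <- derive_indicators(observe(acts, m, seed = 13))
  sits <- acts[acts$activity_type == "sitting", ]
  expect_equal(sort(round(ind$bouts$s[ind$bouts$complete], 3)),
               sort(round(secs_between(sits$start, sits$end), 3)))
})

test_that("the full validation study is deterministic and coherent", {
  rep1 <- run_validation_study(3, seed = 42)
  rep2 <- run_validation_study(3, seed = 42)
  p1 <- file.path(tempdir(), "r1.json"); p2 <- file.path(tempdir(), "r2.json")
  write_validation_report(rep1, p1)
  write_validation_report(rep2, p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical report
  expect_s3_class(rep1, "ft_validation_report")
  expect_gte(rep1$totals$n_activities, 3 * 18)
  expect_true(all(c("speaker", "motion", "door", "mat", "distance",
                    "weight") %in% names(rep1)))
  expect_output(print(rep1), "kappa")
})
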