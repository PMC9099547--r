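# HomeLab activity simulator: replays the three-run sensor-testing protocol
# as ground-truth activity records, then corrupts them into sensor events
# through per-sensor observation models (missed detections, latency jitter,
# occupancy flicker).  The full derivation-plus-validation pipeline can
# therefore run with no external data.

#' Default HomeLab floor plan
#'
#' A single-story one-bedroom apartment with a flight of stairs: each
#' functional room carries one motion sensor; a pressure mat sits on the
#' living-room chair, two distance sensors bound the stairs, a door contact
#' watches the entrance, and the smart scale lives in the bathroom.
#'
#' @param rooms character vector of room labels with motion sensors.
#' @return a `floor_plan` object (rooms plus a sensor-placement table).
#' @export
floor_plan <- function(rooms = c("living_room", "dining_room", "kitchen",
                                 "bedroom", "bathroom", "entrance")) {
  sensors <- rbind(
    data.frame(sensor_id = paste0("motion_", rooms), sensor_type = "motion",
               place = rooms, stringsAsFactors = FALSE),
    data.frame(sensor_id = c("mat_chair", "distance_first", "distance_last",
                             "door_main", "scale_bathroom", "speaker_living"),
               sensor_type = c("mat", "distance", "distance", "door",
                               "weight_scale", "speaker"),
               place = c("living_room", "stairs", "stairs", "entrance",
                         "bathroom", "living_room"),
               stringsAsFactors = FALSE))
  structure(list(rooms = rooms, sensors = sensors), class = "floor_plan")
}

#' Per-sensor observation model
#'
#' Defaults restate the study's observed failure rates: the door contact
#' missed 12.5 percent of passages and the distance sensors missed half of
#' the stair climbs (participant beyond the 60 cm range for the whole
#' climb, so a distance miss drops both triggers of a climb).  Motion, mat,
#' speaker misses and all noise terms default to zero because the study
#' reports near-perfect agreement for those channels.
#'
#' @param miss_probability named numeric vector of miss probabilities per
#'   sensor type; for `distance` the probability applies per climb.
#' @param jitter_sd_s named numeric vector of timestamp-jitter standard
#'   deviations in seconds per sensor type.
#' @param flicker_rate_per_min spurious re-trigger rate per occupied minute
#'   (`mat` inserts a brief vacate/re-occupy pair, `motion` a same-room
#'   re-trigger).
#' @param mat_flicker_gap_s length of an inserted mat vacancy flicker,
#'   default 0.5 (below the default 2 s debounce).
#' @param weight_noise_sd_kg smart-scale reading noise.
#' @param reference_scale_sd_kg traditional-scale reading noise used for the
#'   weight-correlation reference.
#' @param speaker_garble_prob probability a spoken token is recognized as an
#'   out-of-vocabulary token.
#' @return a `sensor_model` object.
#' @export
sensor_model <- function(miss_probability = c(motion = 0, mat = 0,
                                              distance = 0.5, door = 0.125,
                                              weight_scale = 0, speaker = 0),
                         jitter_sd_s = c(motion = 0, mat = 0, distance = 0,
                                         door = 0, weight_scale = 0,
                                         speaker = 0),
                         flicker_rate_per_min = c(mat = 0, motion = 0),
                         mat_flicker_gap_s = 0.5,
                         weight_noise_sd_kg = 0,
                         reference_scale_sd_kg = 0.5,
                         speaker_garble_prob = 0) {
  fill <- function(x, defaults) {
    out <- defaults
    out[names(x)] <- x
    out
  }
  miss_probability <- fill(miss_probability,
                           stats::setNames(numeric(6), SENSOR_TYPES))
  jitter_sd_s <- fill(jitter_sd_s, stats::setNames(numeric(6), SENSOR_TYPES))
  flicker_rate_per_min <- fill(flicker_rate_per_min,
                               c(mat = 0, motion = 0))
  stopifnot(all(miss_probability >= 0 & miss_probability <= 1),
            all(jitter_sd_s >= 0), all(flicker_rate_per_min >= 0),
            speaker_garble_prob >= 0, speaker_garble_prob <= 1)
  structure(list(miss_probability = miss_probability,
                 jitter_sd_s = jitter_sd_s,
                 flicker_rate_per_min = flicker_rate_per_min,
                 mat_flicker_gap_s = mat_flicker_gap_s,
                 weight_noise_sd_kg = weight_noise_sd_kg,
                 reference_scale_sd_kg = reference_scale_sd_kg,
                 speaker_garble_prob = speaker_garble_prob),
            class = "sensor_model")
}

#' Noise-free observation model (identity limit)
#' @return a `sensor_model` with every miss, jitter, flicker and noise term
#'   set to zero.
#' @export
sensor_model_zero_noise <- function() {
  sensor_model(miss_probability = stats::setNames(numeric(6), SENSOR_TYPES),
               reference_scale_sd_kg = 0)
}

#' Three-run test protocol script
#'
#' Run 1 is guided at normal pace, run 2 self-paced at normal pace, run 3
#' self-paced and slow, mimicking frail older adults (stair and sitting
#' durations multiplied by `slow_multiplier`).  Every run performs all six
#' activity types at least once; room visits target the protocol's 2
#' minutes per room.
#'
#' @param room_presence_mean_s mean room visit length (default 120 s, the
#'   protocol's "2 min").
#' @param room_presence_sd_s visit-length SD for self-paced runs (guided
#'   runs use a third of it).
#' @param sitting_mean_s,sitting_sd_s sedentary bout length.
#' @param stair_mean_s,stair_sd_s single stair climb length.
#' @param weight_duration_s time on the scale.
#' @param dialogue_duration_s speaker conversation length.
#' @param outing_mean_s absence length for the entry/exit test (default
#'   420 s, comfortably over the 5 min outing threshold).
#' @param gap_mean_s mean exponential gap between activities.
#' @param break_between_runs_s rest between runs.
#' @param slow_multiplier run-3 multiplier on stair and sitting durations.
#' @param n_room_visits room visits per run (>= 2 distinct rooms).
#' @param n_climbs stair climbs per run (alternating up/down).
#' @return a `protocol_script` object.
#' @export
protocol_script <- function(room_presence_mean_s = 120,
                            room_presence_sd_s = 15,
                            sitting_mean_s = 90, sitting_sd_s = 15,
                            stair_mean_s = 12, stair_sd_s = 2,
                            weight_duration_s = 30,
                            dialogue_duration_s = 40,
                            outing_mean_s = 420,
                            gap_mean_s = 20,
                            break_between_runs_s = 120,
                            slow_multiplier = 2,
                            n_room_visits = 4L,
                            n_climbs = 2L) {
  stopifnot(n_room_visits >= 2L, n_climbs >= 1L, outing_mean_s > 0)
  structure(list(
    run_types = c("guided_normal", "self_paced_normal", "self_paced_slow"),
    room_presence_mean_s = room_presence_mean_s,
    room_presence_sd_s = room_presence_sd_s,
    sitting_mean_s = sitting_mean_s, sitting_sd_s = sitting_sd_s,
    stair_mean_s = stair_mean_s, stair_sd_s = stair_sd_s,
    weight_duration_s = weight_duration_s,
    dialogue_duration_s = dialogue_duration_s,
    outing_mean_s = outing_mean_s,
    gap_mean_s = gap_mean_s,
    break_between_runs_s = break_between_runs_s,
    slow_multiplier = slow_multiplier,
    n_room_visits = as.integer(n_room_visits),
    n_climbs = as.integer(n_climbs)
  ), class = "protocol_script")
}

# Derive an independent sub-seed (kept below 2^31) from a master seed.
stream_seed <- function(seed, idx) {
  v <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(idx) * 104729
  as.integer(v %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

rtnorm <- function(n, mean, sd, lower = 1) {
  pmax(lower, stats::rnorm(n, mean, sd))
}

#' Simulate a ground-truth session
#'
#' One participant performs the three-run protocol; every run contains each
#' of the six activity types at least once, in chronological, non-overlapping
#' order.  `entry_exit` passages are instantaneous records bounding the
#' absence used for the outing test.  Deterministic for a fixed seed.
#'
#' @param plan a `floor_plan`.
#' @param script a `protocol_script`.
#' @param seed integer seed.
#' @param participant_id character id.
#' @param t0 session start (`POSIXct` or ISO string).
#' @return activity `data.frame`; intended dialogue answers are attached as
#'   attribute `"dialogues"` (`data.frame` of `run_id`, `question_id`,
#'   `token`).
#' @export
generate_session <- function(plan = floor_plan(), script = protocol_script(),
                             seed = 1L, participant_id = "p01",
                             t0 = "2021-06-01T09:00:00.000Z") {
  stopifnot(inherits(plan, "floor_plan"), inherits(script, "protocol_script"))
  if (is.character(t0)) t0 <- parse_ts(t0)
  visit_rooms <- setdiff(plan$rooms, "entrance")
  if (length(visit_rooms) < 2L) stop("floor plan needs at least 2 rooms")
  with_seed(seed, {
    rows <- list()
    dial <- list()
    now <- as.numeric(t0)
    gap <- function() stats::rexp(1, 1 / script$gap_mean_s)
    add <- function(run, type, loc, dur) {
      rows[[length(rows) + 1L]] <<- data.frame(
        participant_id = participant_id, run_id = run, activity_type = type,
        location = loc, start = now, end = now + dur,
        stringsAsFactors = FALSE)
      now <<- now + dur + gap()
    }
    for (run in 1:3) {
      slow <- if (script$run_types[run] == "self_paced_slow") {
        script$slow_multiplier
      } else 1
      guided <- script$run_types[run] == "guided_normal"
      rp_sd <- if (guided) script$room_presence_sd_s / 3 else
        script$room_presence_sd_s
      visits <- sample(visit_rooms, script$n_room_visits,
                       replace = script$n_room_visits > length(visit_rooms))
      # ensure consecutive visits change rooms
      for (i in seq_along(visits)[-1L]) {
        if (visits[i] == visits[i - 1L]) {
          visits[i] <- sample(setdiff(visit_rooms, visits[i - 1L]), 1L)
        }
      }
      mid <- ceiling(length(visits) / 2)
      for (room in visits[seq_len(mid)]) {
        add(run, "room_presence", room,
            rtnorm(1, script$room_presence_mean_s, rp_sd, lower = 30))
      }
      add(run, "sitting", "living_room",
          rtnorm(1, script$sitting_mean_s * slow, script$sitting_sd_s * slow,
                 lower = 10))
      add(run, "room_presence", "bathroom",
          rtnorm(1, script$room_presence_mean_s / 2, rp_sd, lower = 30))
      add(run, "weight_measuring", "bathroom", script$weight_duration_s)
      for (cl in seq_len(script$n_climbs)) {
        add(run, "stair_climbing", "stairs",
            rtnorm(1, script$stair_mean_s * slow, script$stair_sd_s * slow,
                   lower = 3))
      }
      for (room in visits[setdiff(seq_along(visits), seq_len(mid))]) {
        add(run, "room_presence", room,
            rtnorm(1, script$room_presence_mean_s, rp_sd, lower = 30))
      }
      add(run, "exhaustion_report", "living_room", script$dialogue_duration_s)
      avail <- "yes"
      exh <- sample(c("yes", "no"), 1L)
      freq <- if (slow > 1) sample(c("sometimes", "always"), 1L) else
        sample(c("rare", "sometimes", "always"), 1L,
               prob = c(0.6, 0.25, 0.15))
      dial[[run]] <- data.frame(
        run_id = run, question_id = c("availability", "exhaustion", "frequency"),
        token = c(avail, exh, freq), stringsAsFactors = FALSE)
      # outing: leave, stay out past the 5 min threshold, come back
      add(run, "entry_exit", "entrance", 0)
      now <- now + stats::rexp(1, 1 / script$outing_mean_s) + 301
      add(run, "entry_exit", "entrance", 0)
      now <- now + script$break_between_runs_s
    }
    out <- do.call(rbind, rows)
    out <- activity_records(out$participant_id, out$run_id, out$activity_type,
                            out$location,
                            as.POSIXct(out$start, origin = "1970-01-01",
                                       tz = "UTC"),
                            as.POSIXct(out$end, origin = "1970-01-01",
                                       tz = "UTC"))
    attr(out, "dialogues") <- do.call(rbind, dial)
    out
  })
}

#' Corrupt ground-truth activities into an event log
#'
#' Maps each activity to its sensor firing pattern, then applies the
#' observation model: independent missed detections (per firing, except the
#' distance sensors where a miss drops the whole climb), Gaussian latency
#' jitter, and mat/motion flicker.  One pseudo-random stream per sensor
#' type is keyed from the seed, so changing one sensor's noise leaves the
#' other streams untouched.
#'
#' @param activities ground-truth activity `data.frame` (with the
#'   `"dialogues"` attribute from [generate_session()], if available).
#' @param model a `sensor_model`.
#' @param plan a `floor_plan`.
#' @param seed integer seed.
#' @param body_mass_kg participant's true mass for scale readings.
#' @param session_id metadata label.
#' @return an `event_log`; the recognized speaker tokens and their intended
#'   values are attached as attribute `"speaker_truth"`.
#' @export
observe <- function(activities, model = sensor_model(), plan = floor_plan(),
                    seed = 1L, body_mass_kg = 75, session_id = "sim") {
  stopifnot(inherits(model, "sensor_model"), inherits(plan, "floor_plan"))
  validate_activities(activities)
  acts <- activities[order(as.numeric(activities$start)), , drop = FALSE]
  dial <- attr(activities, "dialogues")
  chunks <- list()
  jit <- function(t, sd) if (sd > 0) t + stats::rnorm(length(t), 0, sd) else t
  type_idx <- stats::setNames(seq_along(SENSOR_TYPES), SENSOR_TYPES)

  # ---- motion ----------------------------------------------------------
  obs_motion <- function() {
    roomy <- acts[acts$location %in% plan$rooms &
                    acts$activity_type != "entry_exit", , drop = FALSE]
    if (nrow(roomy) == 0L) return(NULL)
    times <- as.numeric(roomy$start)
    rooms <- roomy$location
    # flicker: extra same-room triggers during room presences
    fr <- model$flicker_rate_per_min[["motion"]]
    if (fr > 0) {
      for (i in which(roomy$activity_type == "room_presence")) {
        dur_min <- secs_between(roomy$start[i], roomy$end[i]) / 60
        k <- stats::rpois(1, fr * dur_min)
        if (k > 0) {
          extra <- stats::runif(k, as.numeric(roomy$start[i]),
                                as.numeric(roomy$end[i]))
          times <- c(times, extra)
          rooms <- c(rooms, rep(roomy$location[i], k))
        }
      }
    }
    keep <- stats::runif(length(times)) >= model$miss_probability[["motion"]]
    if (!any(keep)) return(NULL)
    times <- jit(times[keep], model$jitter_sd_s[["motion"]])
    sensor_events(sensor_id = paste0("motion_", rooms[keep]),
                  sensor_type = "motion",
                  timestamp = as.POSIXct(times, origin = "1970-01-01",
                                         tz = "UTC"),
                  room = rooms[keep])
  }
  chunks$motion <- with_seed(stream_seed(seed, type_idx["motion"]),
                             obs_motion())

  # ---- mat -------------------------------------------------------------
  obs_mat <- function() {
    sits <- acts[acts$activity_type == "sitting", , drop = FALSE]
    if (nrow(sits) == 0L) return(NULL)
    times <- c(); occ <- c()
    fr <- model$flicker_rate_per_min[["mat"]]
    for (i in seq_len(nrow(sits))) {
      s <- as.numeric(sits$start[i]); e <- as.numeric(sits$end[i])
      t_i <- c(s, e); o_i <- c(TRUE, FALSE)
      if (fr > 0) {
        k <- stats::rpois(1, fr * (e - s) / 60)
        if (k > 0 && e - s > 2 * model$mat_flicker_gap_s) {
          at <- stats::runif(k, s + model$mat_flicker_gap_s,
                             e - model$mat_flicker_gap_s)
          t_i <- c(t_i, at, at + model$mat_flicker_gap_s)
          o_i <- c(o_i, rep(FALSE, k), rep(TRUE, k))
        }
      }
      times <- c(times, t_i); occ <- c(occ, o_i)
    }
    keep <- stats::runif(length(times)) >= model$miss_probability[["mat"]]
    if (!any(keep)) return(NULL)
    times <- jit(times[keep], model$jitter_sd_s[["mat"]])
    sensor_events(sensor_id = "mat_chair", sensor_type = "mat",
                  timestamp = as.POSIXct(times, origin = "1970-01-01",
                                         tz = "UTC"),
                  occupied = occ[keep])
  }
  chunks$mat <- with_seed(stream_seed(seed, type_idx["mat"]), obs_mat())

  # ---- distance (miss applies per climb) -------------------------------
  obs_distance <- function() {
    climbs <- acts[acts$activity_type == "stair_climbing", , drop = FALSE]
    if (nrow(climbs) == 0L) return(NULL)
    keep <- stats::runif(nrow(climbs)) >= model$miss_probability[["distance"]]
    climbs <- climbs[keep, , drop = FALSE]
    if (nrow(climbs) == 0L) return(NULL)
    up <- seq_len(nrow(climbs)) %% 2L == 1L  # alternate up/down
    first_pos <- ifelse(up, "first_step", "last_step")
    last_pos <- ifelse(up, "last_step", "first_step")
    times <- c(as.numeric(climbs$start), as.numeric(climbs$end))
    pos <- c(first_pos, last_pos)
    times <- jit(times, model$jitter_sd_s[["distance"]])
    sensor_events(
      sensor_id = ifelse(pos == "first_step", "distance_first",
                         "distance_last"),
      sensor_type = "distance",
      timestamp = as.POSIXct(times, origin = "1970-01-01", tz = "UTC"),
      position = pos)
  }
  chunks$distance <- with_seed(stream_seed(seed, type_idx["distance"]),
                               obs_distance())

  # ---- door ------------------------------------------------------------
  obs_door <- function() {
    passes <- acts[acts$activity_type == "entry_exit", , drop = FALSE]
    if (nrow(passes) == 0L) return(NULL)
    keep <- stats::runif(nrow(passes)) >= model$miss_probability[["door"]]
    passes <- passes[keep, , drop = FALSE]
    if (nrow(passes) == 0L) return(NULL)
    times <- jit(as.numeric(passes$start), model$jitter_sd_s[["door"]])
    sensor_events(sensor_id = "door_main", sensor_type = "door",
                  timestamp = as.POSIXct(times, origin = "1970-01-01",
                                         tz = "UTC"),
                  door_state = "opened")
  }
  chunks$door <- with_seed(stream_seed(seed, type_idx["door"]), obs_door())

  # ---- weight scale ----------------------------------------------------
  obs_weight <- function() {
    wm <- acts[acts$activity_type == "weight_measuring", , drop = FALSE]
    if (nrow(wm) == 0L) return(NULL)
    keep <- stats::runif(nrow(wm)) >= model$miss_probability[["weight_scale"]]
    wm <- wm[keep, , drop = FALSE]
    if (nrow(wm) == 0L) return(NULL)
    mass <- body_mass_kg + stats::rnorm(nrow(wm), 0, model$weight_noise_sd_kg)
    times <- jit(as.numeric(wm$end), model$jitter_sd_s[["weight_scale"]])
    sensor_events(sensor_id = "scale_bathroom", sensor_type = "weight_scale",
                  timestamp = as.POSIXct(times, origin = "1970-01-01",
                                         tz = "UTC"),
                  mass_kg = pmax(mass, 1))
  }
  chunks$weight <- with_seed(stream_seed(seed, type_idx["weight_scale"]),
                             obs_weight())

  # ---- speaker ---------------------------------------------------------
  speaker_truth <- NULL
  obs_speaker <- function() {
    reps <- acts[acts$activity_type == "exhaustion_report", , drop = FALSE]
    if (nrow(reps) == 0L) return(NULL)
    rows <- list(); truth <- list()
    for (i in seq_len(nrow(reps))) {
      run <- reps$run_id[i]
      intended <- if (!is.null(dial)) {
        d <- dial[dial$run_id == run, , drop = FALSE]
        stats::setNames(d$token, d$question_id)
      } else c(availability = "yes", exhaustion = "no", frequency = "rare")
      t_answers <- as.numeric(reps$start[i]) + c(6, 18, 30)
      for (j in seq_along(QUESTION_IDS)) {
        qid <- QUESTION_IDS[j]
        tok <- unname(intended[[qid]])
        heard <- if (stats::runif(1) < model$speaker_garble_prob) "garble"
                 else tok
        if (stats::runif(1) < model$miss_probability[["speaker"]]) next
        rows[[length(rows) + 1L]] <- data.frame(
          t = t_answers[j], qid = qid, heard = heard,
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          run_id = run, question_id = qid, intended = tok, recognized = heard,
          stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) return(NULL)
    rr <- do.call(rbind, rows)
    speaker_truth <<- do.call(rbind, truth)
    times <- jit(rr$t, model$jitter_sd_s[["speaker"]])
    sensor_events(sensor_id = "speaker_living", sensor_type = "speaker",
                  timestamp = as.POSIXct(times, origin = "1970-01-01",
                                         tz = "UTC"),
                  question_id = rr$qid, answer = rr$heard)
  }
  chunks$speaker <- with_seed(stream_seed(seed, type_idx["speaker"]),
                              obs_speaker())

  ev <- do.call(rbind, Filter(Negate(is.null), unname(chunks)))
  if (is.null(ev)) ev <- empty_events()
  log <- event_log(ev, session_id = session_id, seed = seed)
  attr(log, "speaker_truth") <- speaker_truth
  log
}

#' Run a full simulated validation study
#'
#' Generates one session per participant, observes it through the sensor
#' model, derives indicators, aligns them with the ground truth, and pools
#' the agreement statistics into one report block per sensor comparison.
#'
#' @param n_participants number of participants (default 9).
#' @param script a `protocol_script`.
#' @param model a `sensor_model`.
#' @param plan a `floor_plan`.
#' @param seed master seed; per-participant seeds are derived from it.
#' @param config pipeline parameters, see [default_config()].
#' @return an `ft_validation_report`: list with `speaker`, `motion`, `door`,
#'   `mat`, `distance`, `weight` blocks plus `totals`.
#' @export
run_validation_study <- function(n_participants = 9L,
                                 script = protocol_script(),
                                 model = sensor_model(),
                                 plan = floor_plan(),
                                 seed = 1L,
                                 config = default_config()) {
  room_s <- room_r <- character()
  sed_s <- sed_r <- st_s <- st_r <- numeric()
  sed_det <- c(0L, 0L); st_det <- c(0L, 0L); door_det <- c(0L, 0L)
  w_sensor <- w_ref <- numeric()
  spk_rec <- spk_int <- character()
  n_activities <- 0L
  ref_noise <- with_seed(stream_seed(seed, 999L), {
    stats::rnorm(n_participants * 10, 0, model$reference_scale_sd_kg)
  })
  masses <- with_seed(stream_seed(seed, 998L), {
    rtnorm(n_participants, 75, 12, lower = 40)
  })
  ref_i <- 0L
  for (p in seq_len(n_participants)) {
    pid <- sprintf("p%02d", p)
    sd_p <- stream_seed(seed, p)
    truth <- generate_session(plan, script, seed = sd_p, participant_id = pid)
    log <- observe(truth, model, plan, seed = stream_seed(sd_p, 7L),
                   body_mass_kg = masses[p], session_id = pid)
    ind <- derive_indicators(log, config, rooms = plan$rooms)
    al <- align_for_agreement(
      truth, ind, door_events = subset_events(log, "door"),
      match_tolerance_s = config$agreement$match_tolerance_s,
      grid_s = config$agreement$grid_s)
    n_activities <- n_activities + nrow(truth)
    room_s <- c(room_s, al$room$sensor)
    room_r <- c(room_r, al$room$reference)
    sed_s <- c(sed_s, al$sedentary$sensor)
    sed_r <- c(sed_r, al$sedentary$reference)
    sed_det <- sed_det + c(al$sedentary$detected, al$sedentary$undetected)
    st_s <- c(st_s, al$stairs$sensor)
    st_r <- c(st_r, al$stairs$reference)
    st_det <- st_det + c(al$stairs$detected, al$stairs$undetected)
    door_det <- door_det + c(al$door$detected, al$door$undetected)
    w <- ind$weights
    if (nrow(w)) {
      w_sensor <- c(w_sensor, w$mass_kg)
      w_ref <- c(w_ref, masses[p] + ref_noise[ref_i + seq_len(nrow(w))])
      ref_i <- ref_i + nrow(w)
    }
    stt <- attr(log, "speaker_truth")
    if (!is.null(stt)) {
      spk_rec <- c(spk_rec, stt$recognized)
      spk_int <- c(spk_int, stt$intended)
    }
  }
  za <- config$agreement
  report <- list(
    speaker = if (length(spk_rec)) {
      list(pct_agreement = percent_recognition_agreement(spk_rec, spk_int),
           n = length(spk_rec))
    },
    motion = if (length(room_s) >= 2L) cohens_kappa(room_s, room_r),
    door = if (sum(door_det)) detection_rate(door_det[1L], door_det[2L]),
    mat = list(
      detection = if (sum(sed_det)) detection_rate(sed_det[1L], sed_det[2L]),
      bland_altman = if (length(sed_s) >= 2L) {
        bland_altman(sed_s, sed_r, z_mult = za$z_mult,
                     outside_threshold_pct = za$outside_threshold_pct)
      }),
    distance = list(
      detection = if (sum(st_det)) detection_rate(st_det[1L], st_det[2L]),
      bland_altman = if (length(st_s) >= 2L) {
        bland_altman(st_s, st_r, z_mult = za$z_mult,
                     outside_threshold_pct = za$outside_threshold_pct)
      }),
    weight = if (length(w_sensor) >= 3L && stats::var(w_sensor) > 0 &&
                 stats::var(w_ref) > 0) {
      pearson_correlation(w_sensor, w_ref)
    },
    totals = list(n_participants = n_participants,
                  n_activities = n_activities, seed = seed)
  )
  if (!is.null(report$motion)) report$motion$table <- NULL
  structure(report, class = "ft_validation_report")
}

#' @export
print.ft_validation_report <- function(x, ...) {
  fmt <- function(v, d = 3) formatC(v, digits = d, format = "f")
  cat("Simulated concurrent-validity report (",
      x$totals$n_participants, " participants, ",
      x$totals$n_activities, " activities, seed ", x$totals$seed, ")\n",
      sep = "")
  if (!is.null(x$speaker)) {
    cat("  speaker : ", fmt(x$speaker$pct_agreement, 1),
        "% token agreement (n = ", x$speaker$n, ")\n", sep = "")
  }
  if (!is.null(x$motion)) {
    cat("  motion  : kappa = ", fmt(x$motion$k), " (p_o = ",
        fmt(x$motion$p_o, 4), ", p_e = ", fmt(x$motion$p_e, 4),
        ", p ", ifelse(x$motion$p_value < 0.001, "< 0.001",
                       paste0("= ", fmt(x$motion$p_value))), ")\n", sep = "")
  }
  if (!is.null(x$door)) {
    cat("  door    : ", fmt(x$door$pct, 1), "% detected (",
        x$door$detected, "/", x$door$detected + x$door$undetected, ")\n",
        sep = "")
  }
  ba_line <- function(label, blk) {
    if (!is.null(blk$detection)) {
      cat("  ", label, ": ", fmt(blk$detection$pct, 1), "% detected",
          sep = "")
    }
    ba <- blk$bland_altman
    if (!is.null(ba)) {
      cat("; bias = ", fmt(ba$bias), ", sd = ", fmt(ba$sd),
          ", LoA = (", fmt(ba$lower_loa), ", ", fmt(ba$upper_loa), "), ",
          fmt(ba$pct_outside, 1), "% outside -> ",
          if (ba$agreement) "agreement" else "no agreement", sep = "")
    }
    cat("\n")
  }
  ba_line("mat     ", x$mat)
  ba_line("distance", x$distance)
  if (!is.null(x$weight)) {
    cat("  weight  : r = ", fmt(x$weight$r), " (n = ", x$weight$n, ")\n",
        sep = "")
  }
  invisible(x)
}

#' Serialize a validation report as JSON
#' @param report an `ft_validation_report`.
#' @param path destination file.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "ft_validation_report"))
  strip <- function(x) {
    if (is.list(x)) lapply(x, strip) else x
  }
  out <- strip(unclass(report))
  # drop bulky per-pair vectors from the serialized form
  for (blk in c("mat", "distance")) {
    if (!is.null(out[[blk]]$bland_altman)) {
      out[[blk]]$bland_altman$differences <- NULL
      out[[blk]]$bland_altman$means <- NULL
    }
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
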