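# Derivation of frailty indicators from an event log: sedentary bouts from
# the pressure mat, stair-climbing times from the paired distance sensors,
# room-presence durations from the motion sensors, and confirmed outings
# from the door contact.  Every duration is the plain subtraction of the two
# selected event times, in seconds.

check_sorted <- function(ev) {
  if (nrow(ev) > 1L && is.unsorted(as.numeric(ev$timestamp))) {
    stop("events must be sorted by timestamp", call. = FALSE)
  }
}

check_only_type <- function(ev, type) {
  if (nrow(ev) && any(ev$sensor_type != type)) {
    stop("expected only ", type, " events, got ",
         paste(setdiff(unique(ev$sensor_type), type), collapse = ", "),
         call. = FALSE)
  }
}

#' Detect sedentary bouts from mat-sensor events
#'
#' A bout runs from an occupied transition to the next vacated transition;
#' its duration is `s = t_unoccupied - t_pre_occupied` in seconds.  Brief
#' vacancies shorter than `debounce_s` (pressure-mat flicker while the
#' sitter shifts weight) are merged into the surrounding bout.  A trailing
#' occupied transition with no vacate yields an open bout with
#' `complete = FALSE` and `s = NA`.
#'
#' @param mat_events sorted event rows with `sensor_type == "mat"`; the
#'   `occupied` payload is the seat state after the transition.
#' @param debounce_s vacancy gaps shorter than this many seconds are merged
#'   (default 2; 0 disables merging).
#' @param min_bout_s completed bouts shorter than this are dropped
#'   (default 0).
#' @return `data.frame` with `t_pre_occupied`, `t_unoccupied`, `s`,
#'   `complete`; non-overlapping, in time order.
#' @export
detect_sedentary_bouts <- function(mat_events, debounce_s = 2, min_bout_s = 0) {
  check_only_type(mat_events, "mat")
  check_sorted(mat_events)
  out <- data.frame(t_pre_occupied = as.POSIXct(character(), tz = "UTC"),
                    t_unoccupied = as.POSIXct(character(), tz = "UTC"),
                    s = numeric(), complete = logical())
  if (nrow(mat_events) == 0L) return(out)
  # keep state transitions only (repeated identical readings collapse)
  keep <- c(TRUE, diff(as.integer(mat_events$occupied)) != 0L)
  ev <- mat_events[keep, , drop = FALSE]
  starts <- list(); ends <- list()
  open_start <- NULL
  for (i in seq_len(nrow(ev))) {
    if (ev$occupied[i]) {
      if (is.null(open_start)) {
        n <- length(ends)
        # re-occupied within the debounce window: resume the previous bout
        if (n > 0L && !is.na(ends[[n]]) &&
            secs_between(ends[[n]], ev$timestamp[i]) < debounce_s) {
          open_start <- starts[[n]]
          starts[[n]] <- NULL; ends[[n]] <- NULL
        } else {
          open_start <- ev$timestamp[i]
        }
      }
    } else if (!is.null(open_start)) {
      starts[[length(starts) + 1L]] <- open_start
      ends[[length(ends) + 1L]] <- ev$timestamp[i]
      open_start <- NULL
    }
  }
  n <- length(starts)
  if (n) {
    t0 <- ts_round(as.POSIXct(vapply(starts, as.numeric, 0),
                              origin = "1970-01-01", tz = "UTC"))
    t1 <- ts_round(as.POSIXct(vapply(ends, as.numeric, 0),
                              origin = "1970-01-01", tz = "UTC"))
    out <- data.frame(t_pre_occupied = t0, t_unoccupied = t1,
                      s = secs_between(t0, t1), complete = TRUE)
    out <- out[out$s >= min_bout_s, , drop = FALSE]
  }
  if (!is.null(open_start)) {
    out <- rbind(out, data.frame(t_pre_occupied = open_start,
                                 t_unoccupied = as.POSIXct(NA, tz = "UTC"),
                                 s = NA_real_, complete = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Detect stair climbs from the paired distance sensors
#'
#' Each climb is bounded by proximity triggers at the first and last step of
#' the flight; its duration is `sc = |t_distance_sensor2 - t_distance_sensor1|`
#' in seconds.  Triggers are paired greedily: a pending trigger is matched to
#' the earliest opposite-position trigger arriving within
#' `pairing_window_s`; anything left unmatched is emitted with
#' `complete = FALSE` (and excluded from agreement statistics downstream).
#' `direction` is `"up"` when the first-step trigger precedes the last-step
#' trigger, `"down"` otherwise.
#'
#' @param distance_events sorted event rows with `sensor_type == "distance"`.
#' @param pairing_window_s maximum seconds between the two triggers of one
#'   climb (default 120).
#' @return `data.frame` with `t_distance_sensor1`, `t_distance_sensor2`,
#'   `sc`, `direction`, `complete`.
#' @export
detect_stair_climbs <- function(distance_events, pairing_window_s = 120) {
  check_only_type(distance_events, "distance")
  check_sorted(distance_events)
  n <- nrow(distance_events)
  tms <- distance_events$timestamp
  pos <- distance_events$position
  paired <- logical(n)
  res <- list()
  for (i in seq_len(n)) {
    if (paired[i]) next
    j <- NA_integer_
    for (k in seq_len(n)[seq_len(n) > i]) {
      if (paired[k] || pos[k] == pos[i]) next
      if (secs_between(tms[i], tms[k]) <= pairing_window_s) j <- k
      break
    }
    if (!is.na(j)) {
      paired[c(i, j)] <- TRUE
      res[[length(res) + 1L]] <- data.frame(
        t_distance_sensor1 = tms[i], t_distance_sensor2 = tms[j],
        sc = abs(secs_between(tms[i], tms[j])),
        direction = if (pos[i] == "first_step") "up" else "down",
        complete = TRUE, stringsAsFactors = FALSE)
    } else {
      res[[length(res) + 1L]] <- data.frame(
        t_distance_sensor1 = tms[i],
        t_distance_sensor2 = as.POSIXct(NA, tz = "UTC"),
        sc = NA_real_,
        direction = if (pos[i] == "first_step") "up" else "down",
        complete = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(t_distance_sensor1 = as.POSIXct(character(), tz = "UTC"),
                      t_distance_sensor2 = as.POSIXct(character(), tz = "UTC"),
                      sc = numeric(), direction = character(),
                      complete = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(as.numeric(out$t_distance_sensor1)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute room-presence intervals from motion-sensor events
#'
#' Consecutive triggers of the same room's sensor collapse into one run; the
#' first trigger of each maximal same-room run is the confirmed transition
#' into that room.  The presence duration is
#' `r = t_next_motion - t_pre_motion`, the gap between consecutive confirmed
#' transitions.  The final room yields an open interval (`complete = FALSE`,
#' `r = NA`).
#'
#' @param motion_events sorted event rows with `sensor_type == "motion"`.
#' @param confirm_quiet_s optional quiet period: a new room's trigger only
#'   confirms a transition if no trigger of the previous room follows within
#'   this many seconds (default 0, i.e. first trigger confirms).
#' @param rooms optional character vector of valid room labels (the floor
#'   plan); unknown labels raise an error.
#' @return `data.frame` with `room`, `t_pre_motion`, `t_next_motion`, `r`,
#'   `complete`; intervals tile the span between first and last transition.
#' @export
compute_room_presence <- function(motion_events, confirm_quiet_s = 0,
                                  rooms = NULL) {
  check_only_type(motion_events, "motion")
  check_sorted(motion_events)
  empty <- data.frame(room = character(),
                      t_pre_motion = as.POSIXct(character(), tz = "UTC"),
                      t_next_motion = as.POSIXct(character(), tz = "UTC"),
                      r = numeric(), complete = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(motion_events) == 0L) return(empty)
  if (!is.null(rooms)) {
    bad <- setdiff(unique(motion_events$room), rooms)
    if (length(bad)) {
      stop("motion event room label(s) not in floor plan: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  ev <- motion_events
  if (confirm_quiet_s > 0 && nrow(ev) > 1L) {
    # drop candidate transitions contradicted by the previous room
    # re-triggering within the quiet period
    repeat {
      runs <- rle(ev$room)
      if (length(runs$lengths) < 3L) break
      idx_start <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
      drop_rows <- integer()
      for (k in seq(2L, length(runs$lengths) - 1L)) {
        cur <- idx_start[k]
        nxt <- idx_start[k + 1L]
        if (ev$room[nxt] == runs$values[k - 1L] &&
            secs_between(ev$timestamp[cur], ev$timestamp[nxt]) <=
              confirm_quiet_s) {
          drop_rows <- seq(cur, nxt - 1L)
          break
        }
      }
      if (!length(drop_rows)) break
      ev <- ev[-drop_rows, , drop = FALSE]
    }
  }
  runs <- rle(ev$room)
  first_idx <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
  t_conf <- ev$timestamp[first_idx]
  n <- length(t_conf)
  out <- data.frame(
    room = runs$values,
    t_pre_motion = t_conf,
    t_next_motion = c(t_conf[-1L], as.POSIXct(NA, tz = "UTC")),
    r = c(diff(as.numeric(t_conf)), NA_real_),
    complete = c(rep(TRUE, n - 1L), FALSE),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Detect outings from door events
#'
#' Candidate absences are the spans between consecutive door events
#' (`od = t_door_event - t_pre_door_event` in seconds, both opened and
#' closed payloads count as door events).  An absence is a confirmed outing
#' (`o = 1`) iff `od > min_outing_s` (strict) and no event from any other
#' sensor falls strictly inside the span.
#'
#' @param door_events sorted event rows with `sensor_type == "door"`.
#' @param other_events sorted event rows of all non-door sensors.
#' @param min_outing_s outing threshold in seconds (default 300, i.e.
#'   5 minutes).
#' @param coalesce_s optional window: door events within this many seconds
#'   of the previous one collapse into a single event (default 0, off).
#' @return `data.frame` with `t_pre_door_event`, `t_door_event`, `od`,
#'   `interior_event_count`, `o`.
#' @export
detect_outings <- function(door_events, other_events = empty_events(),
                           min_outing_s = 300, coalesce_s = 0) {
  check_only_type(door_events, "door")
  check_sorted(door_events)
  if (nrow(other_events) && any(other_events$sensor_type == "door")) {
    stop("other_events must not contain door events", call. = FALSE)
  }
  check_sorted(other_events)
  empty <- data.frame(t_pre_door_event = as.POSIXct(character(), tz = "UTC"),
                      t_door_event = as.POSIXct(character(), tz = "UTC"),
                      od = numeric(), interior_event_count = integer(),
                      o = integer())
  if (nrow(door_events) < 2L) return(empty)
  t <- door_events$timestamp
  if (coalesce_s > 0) {
    keep <- c(TRUE, diff(as.numeric(t)) > coalesce_s)
    t <- t[keep]
    if (length(t) < 2L) return(empty)
  }
  ot <- as.numeric(other_events$timestamp)
  t0 <- t[-length(t)]; t1 <- t[-1L]
  cnt <- vapply(seq_along(t0), function(i) {
    sum(ot > as.numeric(t0[i]) & ot < as.numeric(t1[i]))
  }, integer(1))
  od <- secs_between(t0, t1)
  data.frame(t_pre_door_event = t0, t_door_event = t1, od = od,
             interior_event_count = cnt,
             o = as.integer(od > min_outing_s & cnt == 0L))
}

#' Derive the full indicator set from an event log
#'
#' Dispatches the per-sensor event streams to the four detectors and passes
#' through weight readings and speaker dialogue answers.
#'
#' @param log an `event_log`.
#' @param config indicator parameters, see [default_config()]; uses
#'   `config$indicators$debounce_s`, `min_bout_s`, `pairing_window_s`,
#'   `confirm_quiet_s`, `min_outing_s`, `door_coalesce_s`.
#' @param rooms optional floor-plan room labels for motion validation.
#' @return an `indicator_set`: list with `bouts`, `climbs`, `presences`,
#'   `outings`, `weights`, `dialogue`.
#' @export
derive_indicators <- function(log, config = default_config(), rooms = NULL) {
  stopifnot(inherits(log, "event_log"))
  p <- config$indicators
  ev <- log$events
  weights <- ev[ev$sensor_type == "weight_scale",
                c("timestamp", "mass_kg"), drop = FALSE]
  names(weights) <- c("timestamp", "mass_kg")
  rownames(weights) <- NULL
  dialogue <- ev[ev$sensor_type == "speaker",
                 c("timestamp", "question_id", "answer"), drop = FALSE]
  rownames(dialogue) <- NULL
  structure(list(
    bouts = detect_sedentary_bouts(subset_events(log, "mat"),
                                   debounce_s = p$debounce_s,
                                   min_bout_s = p$min_bout_s),
    climbs = detect_stair_climbs(subset_events(log, "distance"),
                                 pairing_window_s = p$pairing_window_s),
    presences = compute_room_presence(subset_events(log, "motion"),
                                      confirm_quiet_s = p$confirm_quiet_s,
                                      rooms = rooms),
    outings = detect_outings(subset_events(log, "door"),
                             subset_events(log, setdiff(SENSOR_TYPES, "door")),
                             min_outing_s = p$min_outing_s,
                             coalesce_s = p$door_coalesce_s),
    weights = weights,
    dialogue = dialogue
  ), class = "indicator_set", session_id = log$metadata$session_id)
}

#' @export
print.indicator_set <- function(x, ...) {
  cat("<indicator_set>",
      nrow(x$bouts), "sedentary bouts,",
      nrow(x$climbs), "stair climbs,",
      nrow(x$presences), "room presences,",
      sum(x$outings$o), "confirmed outings /", nrow(x$outings), "spans,",
      nrow(x$weights), "weight readings,",
      nrow(x$dialogue), "dialogue answers\n")
  invisible(x)
}

#' Write indicator tables to a directory (one CSV per indicator kind)
#' @param ind an `indicator_set`.
#' @param dir output directory (created if needed).
#' @return invisibly the written paths.
#' @export
write_indicators <- function(ind, dir) {
  stopifnot(inherits(ind, "indicator_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (kind in c("bouts", "climbs", "presences", "outings", "weights",
                 "dialogue")) {
    df <- ind[[kind]]
    for (col in names(df)) {
      if (inherits(df[[col]], "POSIXct")) {
        df[[col]] <- ifelse(is.na(df[[col]]), "", format_ts(df[[col]]))
      }
    }
    p <- file.path(dir, paste0(kind, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
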