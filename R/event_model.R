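# Core data types for sensor events and ground-truth activities, plus
# readers/writers for the interchange formats every other module consumes.

SENSOR_TYPES <- c("motion", "mat", "distance", "door", "weight_scale", "speaker")
DISTANCE_POSITIONS <- c("first_step", "last_step")
DOOR_STATES <- c("opened", "closed")
QUESTION_IDS <- c("availability", "exhaustion", "frequency")
ACTIVITY_TYPES <- c("room_presence", "sitting", "weight_measuring",
                    "stair_climbing", "exhaustion_report", "entry_exit")

# Payload columns of the flattened event table; exactly the columns required
# by a sensor type may be non-NA in a valid record.
PAYLOAD_COLS <- c("room", "occupied", "position", "door_state", "mass_kg",
                  "question_id", "answer")
PAYLOAD_BY_TYPE <- list(
  motion       = "room",
  mat          = "occupied",
  distance     = "position",
  door         = "door_state",
  weight_scale = "mass_kg",
  speaker      = c("question_id", "answer")
)

# ---- timestamps -------------------------------------------------------------
# All timestamps are UTC instants at millisecond resolution.  Formatting and
# parsing go through integer millisecond arithmetic so that a write/read
# round trip is lossless (strftime("%OS3") truncates fractional seconds).

#' Parse ISO-8601 UTC timestamps with milliseconds
#'
#' @param x character vector like `"2021-06-01T09:00:00.250Z"` (the trailing
#'   `Z` and fractional part are optional).
#' @return `POSIXct` (UTC), rounded to the millisecond.
#' @keywords internal
parse_ts <- function(x) {
  x <- as.character(x)
  bad <- !grepl("^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}:\\d{2}(\\.\\d+)?Z?$", x)
  if (any(bad)) {
    stop("malformed timestamp: '", x[which(bad)[1L]], "'", call. = FALSE)
  }
  x <- sub("Z$", "", x)
  frac <- rep(0, length(x))
  has_frac <- grepl("\\.", x)
  frac[has_frac] <- as.numeric(sub("^.*(\\.\\d+)$", "\\1", x[has_frac]))
  whole <- sub("\\.\\d+$", "", x)
  base <- as.POSIXct(whole, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  alt <- is.na(base)
  if (any(alt)) {
    base[alt] <- as.POSIXct(whole[alt], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  }
  if (anyNA(base)) {
    stop("malformed timestamp: '", x[which(is.na(base))[1L]], "'", call. = FALSE)
  }
  ts_round(base + frac)
}

#' Format timestamps as ISO-8601 UTC with milliseconds
#' @param t `POSIXct` vector.
#' @return character vector `"%Y-%m-%dT%H:%M:%OS3Z"` (lossless at ms).
#' @keywords internal
format_ts <- function(t) {
  if (length(t) == 0L) return(character())
  ms <- round(as.numeric(t) * 1000)
  secs <- ms %/% 1000
  rem <- ms %% 1000
  head <- format(as.POSIXct(secs, origin = "1970-01-01", tz = "UTC"),
                 "%Y-%m-%dT%H:%M:%S")
  paste0(head, ".", sprintf("%03d", rem), "Z")
}

ts_round <- function(t) {
  as.POSIXct(round(as.numeric(t) * 1000) / 1000,
             origin = "1970-01-01", tz = "UTC")
}

secs_between <- function(a, b) as.numeric(b) - as.numeric(a)

# ---- sensor events ----------------------------------------------------------

empty_events <- function() {
  data.frame(
    sensor_id = character(), sensor_type = character(),
    timestamp = as.POSIXct(character(), tz = "UTC"),
    room = character(), occupied = logical(), position = character(),
    door_state = character(), mass_kg = numeric(),
    question_id = character(), answer = character(),
    stringsAsFactors = FALSE
  )
}

#' Construct a table of sensor events
#'
#' One row per sensor firing.  The payload is flattened: exactly the
#' column(s) belonging to the row's `sensor_type` must be filled
#' (`motion` -> `room`, `mat` -> `occupied`, `distance` -> `position`,
#' `door` -> `door_state`, `weight_scale` -> `mass_kg`,
#' `speaker` -> `question_id` + `answer`), all others `NA`.
#'
#' @param sensor_id character vector of device identifiers.
#' @param sensor_type one of `motion`, `mat`, `distance`, `door`,
#'   `weight_scale`, `speaker` per row.
#' @param timestamp `POSIXct` (UTC) or ISO-8601 strings; ms resolution.
#' @param room,occupied,position,door_state,mass_kg,question_id,answer
#'   payload columns; leave `NA` where not applicable.
#' @return validated `data.frame` of events (unsorted).
#' @export
sensor_events <- function(sensor_id, sensor_type, timestamp,
                          room = NA_character_, occupied = NA,
                          position = NA_character_, door_state = NA_character_,
                          mass_kg = NA_real_, question_id = NA_character_,
                          answer = NA_character_) {
  if (is.character(timestamp)) timestamp <- parse_ts(timestamp)
  if (length(timestamp) == 0L) return(empty_events())
  ev <- data.frame(
    sensor_id = as.character(sensor_id),
    sensor_type = as.character(sensor_type),
    timestamp = ts_round(timestamp),
    room = as.character(room), occupied = as.logical(occupied),
    position = as.character(position), door_state = as.character(door_state),
    mass_kg = as.numeric(mass_kg),
    question_id = as.character(question_id), answer = as.character(answer),
    stringsAsFactors = FALSE
  )
  validate_events(ev)
  ev
}

#' Validate sensor-event records against the payload/type contract
#' @param ev event `data.frame`.
#' @return invisibly `ev`; stops with a schema error on violation.
#' @keywords internal
validate_events <- function(ev) {
  if (nrow(ev) == 0L) return(invisible(ev))
  bad_type <- !ev$sensor_type %in% SENSOR_TYPES
  if (any(bad_type)) {
    stop("unknown sensor_type '", ev$sensor_type[which(bad_type)[1L]],
         "' (record ", which(bad_type)[1L], ")", call. = FALSE)
  }
  if (anyNA(ev$timestamp) || any(!is.finite(as.numeric(ev$timestamp)))) {
    stop("non-finite timestamp (record ", which(is.na(ev$timestamp))[1L], ")",
         call. = FALSE)
  }
  for (i in seq_len(nrow(ev))) {
    ty <- ev$sensor_type[i]
    need <- PAYLOAD_BY_TYPE[[ty]]
    other <- setdiff(PAYLOAD_COLS, need)
    if (anyNA(ev[i, need])) {
      stop("schema error: record ", i, " (", ty, ") is missing payload field(s) ",
           paste(need[is.na(ev[i, need])], collapse = ", "), call. = FALSE)
    }
    filled <- other[!is.na(ev[i, other])]
    if (length(filled)) {
      stop("schema error: record ", i, " (", ty, ") carries foreign payload field(s) ",
           paste(filled, collapse = ", "), call. = FALSE)
    }
  }
  wk <- ev$sensor_type == "weight_scale"
  if (any(wk) && any(ev$mass_kg[wk] <= 0)) {
    stop("schema error: mass_kg must be > 0", call. = FALSE)
  }
  ds <- ev$sensor_type == "distance"
  if (any(ds) && any(!ev$position[ds] %in% DISTANCE_POSITIONS)) {
    stop("schema error: distance position must be first_step or last_step",
         call. = FALSE)
  }
  dr <- ev$sensor_type == "door"
  if (any(dr) && any(!ev$door_state[dr] %in% DOOR_STATES)) {
    stop("schema error: door state must be opened or closed", call. = FALSE)
  }
  sp <- ev$sensor_type == "speaker"
  if (any(sp) && any(!ev$question_id[sp] %in% QUESTION_IDS)) {
    stop("schema error: speaker question_id must be one of ",
         paste(QUESTION_IDS, collapse = ", "), call. = FALSE)
  }
  invisible(ev)
}

#' Build an event log
#'
#' An `event_log` is a canonically sorted table of sensor events plus
#' session metadata.  Canonical order is `(timestamp, sensor_id)`; exact
#' duplicate records (same timestamp, sensor and payload) are rejected.
#'
#' @param events event `data.frame` (see [sensor_events()]); may be empty.
#' @param session_id character scalar naming the session.
#' @param seed generator seed if the log is synthetic, else `NA`.
#' @return an `event_log` object.
#' @export
event_log <- function(events = empty_events(), session_id = "session",
                      seed = NA_integer_) {
  if (nrow(events)) {
    validate_events(events)
    events <- events[order(as.numeric(events$timestamp), events$sensor_id), ,
                     drop = FALSE]
    rownames(events) <- NULL
    key <- do.call(paste, c(lapply(events, as.character), sep = "\r"))
    if (anyDuplicated(key)) {
      stop("duplicate event record (same timestamp, sensor and payload) at row ",
           which(duplicated(key))[1L], call. = FALSE)
    }
  }
  structure(list(events = events,
                 metadata = list(session_id = as.character(session_id),
                                 seed = seed)),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat("<event_log> session '", x$metadata$session_id, "': ",
      nrow(x$events), " events", sep = "")
  if (nrow(x$events)) {
    cat(" (", paste(names(sort(table(x$events$sensor_type), decreasing = TRUE)),
                    collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Number of events in a log
#' @param x an `event_log`.
#' @export
n_events <- function(x) nrow(x$events)

subset_events <- function(log, type) {
  ev <- log$events
  ev[ev$sensor_type %in% type, , drop = FALSE]
}

# ---- event log I/O ----------------------------------------------------------

#' Read a sensor event log
#'
#' @param path file path.
#' @param dialect `"jsonl"` (one JSON object per line, nested payload) or
#'   `"csv"` (RFC-4180 with flattened payload columns).  Default guesses
#'   from the file extension.
#' @return an `event_log`, canonically sorted and schema-validated.  An
#'   empty file yields an empty log.
#' @export
read_event_log <- function(path, dialect = c("auto", "jsonl", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.jsonl?$", path)) "jsonl" else "csv"
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "jsonl") read_event_jsonl(path) else read_event_csv(path)
}

read_event_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(event_log())
  meta <- list(session_id = "session", seed = NA_integer_)
  rows <- vector("list", length(lines))
  n <- 0L
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) {
                      stop("parse error on line ", i, ": ", conditionMessage(e),
                           call. = FALSE)
                    })
    if (!is.null(obj$metadata)) {
      meta <- utils::modifyList(meta, obj$metadata)
      next
    }
    n <- n + 1L
    pl <- obj$payload
    row <- tryCatch(
      sensor_events(
        sensor_id = obj$sensor_id, sensor_type = obj$sensor_type,
        timestamp = obj$timestamp,
        room = pl$room %||% NA_character_,
        occupied = pl$occupied %||% NA,
        position = pl$position %||% NA_character_,
        door_state = pl$state %||% NA_character_,
        mass_kg = pl$mass_kg %||% NA_real_,
        question_id = pl$question_id %||% NA_character_,
        answer = pl$answer %||% NA_character_
      ),
      error = function(e) stop("line ", i, ": ", conditionMessage(e),
                               call. = FALSE))
    rows[[n]] <- row
  }
  ev <- if (n) do.call(rbind, rows[seq_len(n)]) else empty_events()
  event_log(ev, session_id = meta$session_id,
            seed = if (is.null(meta$seed)) NA_integer_ else meta$seed)
}

read_event_csv <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  meta <- list(session_id = "session", seed = NA_integer_)
  if (length(first) && startsWith(first, "#")) {
    kv <- strsplit(sub("^#\\s*", "", first), ",")[[1L]]
    for (pair in kv) {
      p <- strsplit(pair, "=")[[1L]]
      if (length(p) == 2L) {
        key <- trimws(p[1L]); val <- trimws(p[2L])
        if (key == "seed") {
          meta$seed <- suppressWarnings(as.integer(val))
        } else meta[[key]] <- val
      }
    }
  }
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", colClasses = "character",
                    check.names = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L) return(event_log(session_id = meta$session_id,
                                       seed = meta$seed))
  need <- c("sensor_id", "sensor_type", "timestamp", PAYLOAD_COLS)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("csv event log is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  blank <- function(x) ifelse(is.na(x) | x == "", NA, x)
  ts <- tryCatch(parse_ts(df$timestamp), error = function(e) {
    bad <- which(!grepl("^\\d{4}-", df$timestamp))[1L]
    stop("parse error on data line ",
         if (is.na(bad)) "?" else bad, ": ", conditionMessage(e),
         call. = FALSE)
  })
  ev <- sensor_events(
    sensor_id = df$sensor_id, sensor_type = df$sensor_type, timestamp = ts,
    room = blank(df$room),
    occupied = as.logical(blank(df$occupied)),
    position = blank(df$position),
    door_state = blank(df$door_state),
    mass_kg = as.numeric(blank(df$mass_kg)),
    question_id = blank(df$question_id),
    answer = blank(df$answer)
  )
  event_log(ev, session_id = meta$session_id, seed = meta$seed)
}

#' Write a sensor event log
#'
#' Inverse of [read_event_log()]: the written file reads back to an equal
#' log (field-exact at millisecond timestamp resolution).
#'
#' @param log an `event_log`.
#' @param path destination file path.
#' @param dialect `"jsonl"` or `"csv"` (default guesses from the extension).
#' @export
write_event_log <- function(log, path, dialect = c("auto", "jsonl", "csv")) {
  stopifnot(inherits(log, "event_log"))
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.jsonl?$", path)) "jsonl" else "csv"
  }
  ev <- log$events
  if (dialect == "jsonl") {
    hdr <- jsonlite::toJSON(list(metadata = log$metadata), auto_unbox = TRUE,
                            null = "null", na = "null")
    lines <- character(nrow(ev))
    for (i in seq_len(nrow(ev))) {
      ty <- ev$sensor_type[i]
      pl <- switch(ty,
        motion = list(room = ev$room[i]),
        mat = list(occupied = ev$occupied[i]),
        distance = list(position = ev$position[i]),
        door = list(state = ev$door_state[i]),
        weight_scale = list(mass_kg = ev$mass_kg[i]),
        speaker = list(question_id = ev$question_id[i], answer = ev$answer[i]))
      lines[i] <- jsonlite::toJSON(
        list(sensor_id = ev$sensor_id[i], sensor_type = ty,
             timestamp = format_ts(ev$timestamp[i]), payload = pl),
        auto_unbox = TRUE, digits = NA)
    }
    writeLines(c(hdr, lines), path)
  } else {
    out <- ev
    out$timestamp <- format_ts(ev$timestamp)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# session_id=%s,seed=%s", log$metadata$session_id,
                       ifelse(is.na(log$metadata$seed), "NA",
                              log$metadata$seed)), con)
    utils::write.csv(out, con, row.names = FALSE, na = "")
  }
  invisible(path)
}

# ---- activity logs ----------------------------------------------------------

#' Construct ground-truth activity records
#'
#' One row per performed activity interval, using the half-open convention
#' `[start, end)`.
#'
#' @param participant_id character.
#' @param run_id integer in 1..3 (the protocol's three runs).
#' @param activity_type one of `room_presence`, `sitting`,
#'   `weight_measuring`, `stair_climbing`, `exhaustion_report`, `entry_exit`.
#' @param location room label, `"stairs"` or `"entrance"`.
#' @param start,end UTC instants (`POSIXct` or ISO strings); `start <= end`.
#' @return validated `data.frame` of activity records.
#' @export
activity_records <- function(participant_id, run_id, activity_type, location,
                             start, end) {
  if (is.character(start)) start <- parse_ts(start)
  if (is.character(end)) end <- parse_ts(end)
  df <- data.frame(
    participant_id = as.character(participant_id),
    run_id = as.integer(run_id),
    activity_type = as.character(activity_type),
    location = as.character(location),
    start = ts_round(start), end = ts_round(end),
    stringsAsFactors = FALSE
  )
  validate_activities(df)
  df
}

validate_activities <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  bad <- !df$activity_type %in% ACTIVITY_TYPES
  if (any(bad)) {
    stop("unknown activity_type '", df$activity_type[which(bad)[1L]], "'",
         call. = FALSE)
  }
  if (any(!df$run_id %in% 1:3)) stop("run_id must be in 1..3", call. = FALSE)
  rev <- as.numeric(df$end) < as.numeric(df$start)
  if (any(rev)) {
    stop("activity record ", which(rev)[1L], " has end < start", call. = FALSE)
  }
  invisible(df)
}

#' Read a ground-truth activity log (CSV)
#' @param path CSV with columns
#'   `participant_id,run_id,activity_type,location,start,end`.
#' @return validated activity `data.frame` sorted by `(start, end)`.
#' @export
read_activity_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0L) {
    return(activity_records(character(), integer(), character(), character(),
                            as.POSIXct(character(), tz = "UTC"),
                            as.POSIXct(character(), tz = "UTC")))
  }
  out <- activity_records(df$participant_id, as.integer(df$run_id),
                          df$activity_type, df$location,
                          parse_ts(df$start), parse_ts(df$end))
  out <- out[order(as.numeric(out$start), as.numeric(out$end)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a ground-truth activity log (CSV)
#' @param activities activity `data.frame`.
#' @param path destination path.
#' @export
write_activity_log <- function(activities, path) {
  validate_activities(activities)
  out <- activities[, c("participant_id", "run_id", "activity_type",
                        "location", "start", "end")]
  out$start <- format_ts(activities$start)
  out$end <- format_ts(activities$end)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
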