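# Shared fixture builders and independent oracles.  Oracles are written
# against the stated contracts only and never call the implementation path
# they check.

T0 <- as.POSIXct("2021-06-01 09:00:00", tz = "UTC")

# internal helpers exercised directly by the suite
parse_ts <- frailtykit:::parse_ts
format_ts <- frailtykit:::format_ts
ts_round <- frailtykit:::ts_round
secs_between <- frailtykit:::secs_between
subset_events <- frailtykit:::subset_events
stream_seed <- frailtykit:::stream_seed
empty_events_fixture <- frailtykit:::empty_events

mk_mat <- function(offsets_s, occupied) {
  sensor_events("mat_chair", "mat", T0 + offsets_s, occupied = occupied)
}

mk_motion <- function(offsets_s, rooms) {
  sensor_events(paste0("motion_", rooms), "motion", T0 + offsets_s,
                room = rooms)
}

mk_distance <- function(offsets_s, positions) {
  sensor_events("dist", "distance", T0 + offsets_s, position = positions)
}

mk_door <- function(offsets_s) {
  sensor_events("door_main", "door", T0 + offsets_s, door_state = "opened")
}

# ---- oracle: sedentary bout pairing ----------------------------------------
# Enumerative re-statement of the contract: walk occupied/vacated
# transitions, merge vacancy gaps shorter than debounce, drop short bouts,
# flag a trailing open bout.
oracle_bouts <- function(occ_flags, times_s, debounce_s = 0, min_bout_s = 0) {
  state <- FALSE
  open_t <- NA_real_
  bouts <- list()
  for (i in seq_along(occ_flags)) {
    if (occ_flags[i] == state) next
    state <- occ_flags[i]
    if (state) {
      n <- length(bouts)
      if (n > 0 && !is.na(bouts[[n]]$end) &&
          times_s[i] - bouts[[n]]$end < debounce_s) {
        open_t <- bouts[[n]]$start
        bouts[[n]] <- NULL
      } else {
        open_t <- times_s[i]
      }
    } else if (!is.na(open_t)) {
      bouts[[length(bouts) + 1]] <- list(start = open_t, end = times_s[i])
      open_t <- NA_real_
    }
  }
  res <- Filter(function(b) b$end - b$start >= min_bout_s, bouts)
  list(complete = res, open_start = if (state) open_t else NA_real_)
}

# ---- oracle: stair trigger pairing -----------------------------------------
# Greedy earliest-opposite pairing on explicit index bookkeeping.
oracle_climbs <- function(times_s, positions, window_s) {
  n <- length(times_s)
  paired <- logical(n)
  out <- list()
  for (i in seq_len(n)) {
    if (paired[i]) next
    j <- NA
    for (k in seq_len(n)) {
      if (k <= i || paired[k] || positions[k] == positions[i]) next
      if (times_s[k] - times_s[i] <= window_s) j <- k
      break
    }
    if (!is.na(j)) {
      paired[i] <- paired[j] <- TRUE
      out[[length(out) + 1]] <- list(t1 = times_s[i], t2 = times_s[j],
                                     sc = abs(times_s[j] - times_s[i]),
                                     complete = TRUE)
    } else {
      out[[length(out) + 1]] <- list(t1 = times_s[i], t2 = NA, sc = NA,
                                     complete = FALSE)
    }
  }
  out
}

# ---- oracle: outing rule ----------------------------------------------------
oracle_outings <- function(door_s, other_s, min_outing_s = 300) {
  if (length(door_s) < 2) return(data.frame(od = numeric(), o = integer()))
  t0 <- door_s[-length(door_s)]
  t1 <- door_s[-1]
  od <- t1 - t0
  o <- integer(length(od))
  for (i in seq_along(od)) {
    inside <- sum(other_s > t0[i] & other_s < t1[i])
    o[i] <- as.integer(od[i] > min_outing_s && inside == 0)
  }
  data.frame(od = od, o = o)
}

# ---- oracle: kappa from a 2x2 confusion matrix ------------------------------
oracle_kappa_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  po <- (a + d) / n
  pe <- ((a + b) / n) * ((a + c) / n) + ((c + d) / n) * ((b + d) / n)
  if (pe >= 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

# ---- oracle: dialogue transition table --------------------------------------
# Hand-written restatement of the three-question machine: per question, up
# to two attempts; a recognized token advances, availability "no" aborts,
# two failures abort.  Tokens are consumed from `seq`; exhaustion = silence.
oracle_dialogue <- function(seq) {
  vocab <- list(availability = c("yes", "no"),
                exhaustion = c("yes", "no"),
                frequency = c("always", "sometimes", "rare"))
  i <- 0
  nxt <- function() {
    i <<- i + 1
    if (i > length(seq)) NA_character_ else seq[i]
  }
  ans <- list()
  for (q in names(vocab)) {
    got <- NA_character_
    for (attempt in 1:2) {
      tok <- nxt()
      if (!is.na(tok) && tok %in% vocab[[q]]) {
        got <- tok
        break
      }
    }
    if (is.na(got)) return(list(completed = FALSE, positive = NA))
    ans[[q]] <- got
    if (q == "availability" && got == "no") {
      return(list(completed = FALSE, positive = NA))
    }
  }
  list(completed = TRUE,
       positive = ans$frequency %in% c("always", "sometimes"))
}

# ---- oracle: exhaustive one-to-one interval matching ------------------------
# Maximum matching under the midpoint-tolerance constraint, found by brute
# force over all injective assignments (fine for <= 6 intervals); among
# maximum matchings pick any (count is what tests compare).
oracle_max_matching <- function(t_mid, d_mid, tol) {
  nt <- length(t_mid); nd <- length(d_mid)
  if (!nt || !nd) return(0L)
  best <- 0L
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  subsets <- function(n, k) utils::combn(n, k, simplify = FALSE)
  for (k in seq_len(min(nt, nd))) {
    for (ts in subsets(nt, k)) {
      for (ds in subsets(nd, k)) {
        for (p in perms(ds)) {
          if (all(abs(t_mid[ts] - d_mid[p]) <= tol)) best <- max(best, k)
        }
      }
    }
  }
  best
}

expect_pos_equal <- function(a, b) {
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-9)
}
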