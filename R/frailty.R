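# Aggregation of per-criterion flags into a Fried-phenotype frailty state,
# plus weight-change tracking across smart-scale readings.

FRAILTY_CRITERIA <- c("sedentary_strength", "stair_performance", "exhaustion",
                      "low_activity", "weight_loss", "constricted_life_space")

#' Classify a frailty state from criterion flags
#'
#' Counts `"positive"` flags (missing flags are excluded, not imputed):
#' 0 positives -> `non_frail`, 1-2 -> `pre_frail`, 3-5 -> `frail`.
#'
#' @param flags named character vector or list over the criterion set, each
#'   `"positive"`, `"negative"` or `"missing"`.
#' @return list with `positive_count` and `state`.
#' @export
classify_state <- function(flags) {
  flags <- unlist(flags)
  bad <- setdiff(flags, c("positive", "negative", "missing"))
  if (length(bad)) {
    stop("invalid flag value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  count <- sum(flags == "positive")
  if (count > length(flags)) stop("positive count exceeds criterion count")
  state <- if (count == 0L) "non_frail" else if (count <= 2L) "pre_frail"
           else "frail"
  list(positive_count = count, state = state)
}

#' Weight change per consecutive window
#'
#' Splits the reading series into consecutive windows of `window` seconds
#' anchored at the first reading and reports, for each window holding at
#' least two readings, the change from its earliest to its latest reading.
#'
#' @param readings `data.frame` with `timestamp` (`POSIXct`) and `mass_kg`
#'   (> 0) columns.
#' @param window window length in seconds (default `Inf`: one window over
#'   the whole series).
#' @return `data.frame` with `window_start`, `window_end` (reading times),
#'   `delta_kg` (latest - earliest) and `delta_percent` (relative to the
#'   earliest reading); zero rows if no window has two readings.
#' @export
weight_change <- function(readings, window = Inf) {
  empty <- data.frame(window_start = as.POSIXct(character(), tz = "UTC"),
                      window_end = as.POSIXct(character(), tz = "UTC"),
                      delta_kg = numeric(), delta_percent = numeric())
  if (is.null(readings) || nrow(readings) < 2L) return(empty)
  if (any(readings$mass_kg <= 0)) stop("mass_kg must be > 0", call. = FALSE)
  ord <- order(as.numeric(readings$timestamp))
  readings <- readings[ord, , drop = FALSE]
  t0 <- as.numeric(readings$timestamp[1L])
  idx <- if (is.finite(window)) {
    floor((as.numeric(readings$timestamp) - t0) / window)
  } else rep(0, nrow(readings))
  out <- empty
  for (k in unique(idx)) {
    sub <- readings[idx == k, , drop = FALSE]
    if (nrow(sub) < 2L) next
    first <- sub[1L, ]; last <- sub[nrow(sub), ]
    out <- rbind(out, data.frame(
      window_start = first$timestamp, window_end = last$timestamp,
      delta_kg = last$mass_kg - first$mass_kg,
      delta_percent = 100 * (last$mass_kg - first$mass_kg) / first$mass_kg))
  }
  rownames(out) <- NULL
  out
}

#' Criterion thresholds
#'
#' The source study validates sensor measurements, not clinical cut-offs, so
#' only two criteria are enabled by default: `weight_loss` (loss of at least
#' 5 percent, consistent with the Fried "shrinking" criterion) and
#' `exhaustion` (scored directly from the speaker dialogue).  The remaining
#' criteria ship disabled with documented placeholder values; the `"demo"`
#' profile enables all six for end-to-end demonstrations and tests.
#'
#' @param profile `"default"` or `"demo"`.
#' @return named list of per-criterion settings (`enabled` plus the
#'   criterion's threshold, units in the field names).
#' @export
frailty_thresholds <- function(profile = c("default", "demo")) {
  profile <- match.arg(profile)
  th <- list(
    sedentary_strength = list(enabled = FALSE, mean_bout_min_s = 300),
    stair_performance = list(enabled = FALSE, mean_climb_min_s = 20),
    exhaustion = list(enabled = TRUE),
    low_activity = list(enabled = FALSE, max_transitions_per_hour = 2),
    weight_loss = list(enabled = TRUE, loss_percent = 5),
    constricted_life_space = list(enabled = FALSE, max_outings_per_day = 1)
  )
  if (profile == "demo") {
    for (k in names(th)) th[[k]]$enabled <- TRUE
  }
  th
}

#' Flag frailty criteria from an indicator set
#'
#' Applies the configured thresholds to the derived indicators.  Disabled
#' criteria, and enabled criteria with no supporting data, are `"missing"`
#' (and therefore excluded from the positive count by [classify_state()]).
#'
#' @param indicators an `indicator_set`.
#' @param thresholds see [frailty_thresholds()].
#' @param observation_span_s span of the observation period in seconds, used
#'   to normalize rates (transitions/hour, outings/day); default is the span
#'   of the derived room-presence intervals.
#' @return named character vector of flags over the six criteria.
#' @export
flag_criteria <- function(indicators, thresholds = frailty_thresholds(),
                          observation_span_s = NULL) {
  stopifnot(inherits(indicators, "indicator_set"))
  miss <- setdiff(FRAILTY_CRITERIA, names(thresholds))
  if (length(miss)) {
    stop("thresholds missing for criterion/criteria: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  flags <- stats::setNames(rep("missing", length(FRAILTY_CRITERIA)),
                           FRAILTY_CRITERIA)
  pr <- indicators$presences
  if (is.null(observation_span_s)) {
    observation_span_s <- if (nrow(pr) >= 2L) {
      secs_between(pr$t_pre_motion[1L],
                   max(pr$t_pre_motion, pr$t_next_motion, na.rm = TRUE))
    } else NA_real_
  }
  pos_neg <- function(x) if (isTRUE(x)) "positive" else "negative"

  th <- thresholds$sedentary_strength
  bouts <- indicators$bouts[indicators$bouts$complete, , drop = FALSE]
  if (th$enabled && nrow(bouts)) {
    if (is.null(th$mean_bout_min_s)) stop("sedentary_strength threshold not set")
    flags["sedentary_strength"] <- pos_neg(mean(bouts$s) >= th$mean_bout_min_s)
  }
  th <- thresholds$stair_performance
  climbs <- indicators$climbs[indicators$climbs$complete, , drop = FALSE]
  if (th$enabled && nrow(climbs)) {
    if (is.null(th$mean_climb_min_s)) stop("stair_performance threshold not set")
    flags["stair_performance"] <- pos_neg(mean(climbs$sc) >= th$mean_climb_min_s)
  }
  if (thresholds$exhaustion$enabled && nrow(indicators$dialogue)) {
    freq <- indicators$dialogue[indicators$dialogue$question_id == "frequency",
                                , drop = FALSE]
    if (nrow(freq)) {
      last_tok <- freq$answer[which.max(as.numeric(freq$timestamp))]
      if (last_tok %in% c(FRAIL_FREQUENCY_TOKENS, "rare")) {
        flags["exhaustion"] <- pos_neg(last_tok %in% FRAIL_FREQUENCY_TOKENS)
      }
    }
  }
  th <- thresholds$low_activity
  if (th$enabled && nrow(pr) >= 2L && is.finite(observation_span_s) &&
      observation_span_s > 0) {
    if (is.null(th$max_transitions_per_hour)) stop("low_activity threshold not set")
    rate <- (nrow(pr) - 1L) / (observation_span_s / 3600)
    flags["low_activity"] <- pos_neg(rate <= th$max_transitions_per_hour)
  }
  th <- thresholds$weight_loss
  if (th$enabled && nrow(indicators$weights) >= 2L) {
    if (is.null(th$loss_percent)) stop("weight_loss threshold not set")
    wc <- weight_change(indicators$weights)
    flags["weight_loss"] <- pos_neg(any(wc$delta_percent <= -th$loss_percent))
  }
  th <- thresholds$constricted_life_space
  if (th$enabled && nrow(indicators$outings) && is.finite(observation_span_s) &&
      observation_span_s > 0) {
    if (is.null(th$max_outings_per_day)) stop("constricted_life_space threshold not set")
    rate <- sum(indicators$outings$o) / (observation_span_s / 86400)
    flags["constricted_life_space"] <- pos_neg(rate <= th$max_outings_per_day)
  }
  flags
}

#' Write a frailty summary as JSON
#' @param flags criterion flags from [flag_criteria()].
#' @param path destination file.
#' @return invisibly the summary list.
#' @export
write_frailty_summary <- function(flags, path) {
  st <- classify_state(flags)
  out <- list(flags = as.list(flags), positive_count = st$positive_count,
              state = st$state)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
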