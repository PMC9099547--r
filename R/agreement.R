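# Concurrent-validity statistics: Cohen's kappa for categorical agreement,
# Bland-Altman limits of agreement with the 20%-outside rule, detection
# rates, Pearson correlation, and the truth/derived alignment that feeds
# them.

#' Cohen's kappa from agreement proportions
#'
#' `k = (p_o - p_e) / (1 - p_e)` with `p_o` the observed agreement
#' proportion and `p_e` the chance-agreement proportion.
#'
#' @param p_o observed agreement in \[0, 1\].
#' @param p_e chance agreement in \[0, 1).
#' @return list with `p_o`, `p_e`, `k`.
#' @export
cohens_kappa_from_proportions <- function(p_o, p_e) {
  stopifnot(p_o >= 0, p_o <= 1, p_e >= 0)
  if (p_e >= 1) {
    stop("degenerate agreement: chance agreement p_e = 1", call. = FALSE)
  }
  list(p_o = p_o, p_e = p_e, k = (p_o - p_e) / (1 - p_e))
}

#' Cohen's kappa from paired categorical labels
#'
#' Builds the confusion matrix over the union of observed categories;
#' `p_o` is the trace proportion, `p_e` the sum of row-by-column marginal
#' products, and `k` per the proportions formula.  Significance against the
#' null of chance agreement uses the normal approximation
#' `z = k / SE0` with the marginal-based null standard error.
#'
#' @param sensor_labels,reference_labels equal-length character vectors of
#'   paired labels.
#' @return list with `p_o`, `p_e`, `k`, `se0`, `z`, `p_value`, `n` and the
#'   confusion `table`.
#' @export
cohens_kappa <- function(sensor_labels, reference_labels) {
  if (length(sensor_labels) != length(reference_labels)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  n <- length(sensor_labels)
  if (n == 0L) stop("no pairs", call. = FALSE)
  cats <- sort(unique(c(sensor_labels, reference_labels)))
  tab <- table(factor(sensor_labels, levels = cats),
               factor(reference_labels, levels = cats))
  p <- tab / n
  p_o <- sum(diag(p))
  pr <- rowSums(p); pc <- colSums(p)
  p_e <- sum(pr * pc)
  if (p_e >= 1) {
    stop("degenerate agreement: a single category on both sides", call. = FALSE)
  }
  k <- (p_o - p_e) / (1 - p_e)
  # null (k = 0) standard error from the marginals (Fleiss, Cohen & Everitt)
  se0_num <- p_e + p_e^2 - sum(pr * pc * (pr + pc))
  se0 <- sqrt(max(se0_num, 0) / (n * (1 - p_e)^2))
  z <- if (se0 > 0) k / se0 else NA_real_
  p_value <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  list(p_o = p_o, p_e = p_e, k = k, se0 = se0, z = z, p_value = p_value,
       n = n, table = tab)
}

#' Bland-Altman limits of agreement
#'
#' Differences are `sensor - reference`.  Limits are
#' `bias +/- z_mult * sd` with the sample standard deviation (n - 1
#' denominator).  A pair is outside the limits on strict inequality; the
#' methods agree when at most `outside_threshold_pct` percent of pairs fall
#' outside.  Proportional bias is the least-squares slope of the differences
#' on the pair means, with its t statistic and two-sided p.
#'
#' @param sensor,reference equal-length numeric vectors of paired
#'   measurements (n >= 2).
#' @param z_mult limit multiplier, default 1.96.
#' @param outside_threshold_pct no-agreement threshold, default 20.
#' @return list with `n`, `bias`, `sd`, `lower_loa`, `upper_loa`,
#'   `n_outside`, `pct_outside`, `agreement`, `prop_bias_slope`,
#'   `prop_bias_t`, `prop_bias_p`, and the `differences`/`means` vectors.
#' @export
bland_altman <- function(sensor, reference, z_mult = 1.96,
                         outside_threshold_pct = 20) {
  if (length(sensor) != length(reference)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  n <- length(sensor)
  if (n < 2L) stop("Bland-Altman needs at least 2 pairs", call. = FALSE)
  d <- sensor - reference
  m <- (sensor + reference) / 2
  bias <- mean(d)
  sd_d <- stats::sd(d)
  lims <- bland_altman_limits(bias, sd_d, z_mult)
  outside <- d < lims$lower_loa | d > lims$upper_loa
  n_outside <- sum(outside)
  pct_outside <- 100 * n_outside / n
  # proportional bias: slope of differences on pair means
  slope <- t_stat <- p_val <- NA_real_
  if (stats::var(m) > 0 && n >= 3L) {
    fit <- stats::lm(d ~ m)
    co <- suppressWarnings(summary(fit))$coefficients
    if (nrow(co) >= 2L) {
      slope <- co[2L, 1L]; t_stat <- co[2L, 3L]; p_val <- co[2L, 4L]
    }
  }
  list(n = n, bias = bias, sd = sd_d,
       lower_loa = lims$lower_loa, upper_loa = lims$upper_loa,
       n_outside = n_outside, pct_outside = pct_outside,
       agreement = pct_outside <= outside_threshold_pct,
       prop_bias_slope = slope, prop_bias_t = t_stat, prop_bias_p = p_val,
       differences = d, means = m)
}

#' Limits of agreement from a reported bias and standard deviation
#' @param bias mean of differences.
#' @param sd standard deviation of differences.
#' @param z_mult limit multiplier, default 1.96.
#' @return list with `lower_loa = bias - z_mult * sd` and
#'   `upper_loa = bias + z_mult * sd`.
#' @export
bland_altman_limits <- function(bias, sd, z_mult = 1.96) {
  list(lower_loa = bias - z_mult * sd, upper_loa = bias + z_mult * sd)
}

#' Detection success rate
#' @param detected,undetected non-negative counts, not both zero.
#' @return list with `detected`, `undetected`, `pct`
#'   (`100 * detected / (detected + undetected)`).
#' @export
detection_rate <- function(detected, undetected) {
  stopifnot(detected >= 0, undetected >= 0)
  if (detected + undetected == 0) {
    stop("detection rate undefined with zero events", call. = FALSE)
  }
  list(detected = detected, undetected = undetected,
       pct = 100 * detected / (detected + undetected))
}

#' Pearson correlation with two-sided t-based p value
#' @param x,y equal-length numeric vectors, n >= 3, both with nonzero
#'   variance.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  n <- length(x)
  if (n < 3L) stop("correlation needs at least 3 pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}

# ---- alignment --------------------------------------------------------------

# Greedy one-to-one interval matching by midpoint proximity: truth and
# derived intervals are candidate-paired when their midpoints are within
# tol seconds; closest pairs match first.
match_intervals <- function(truth_mid, derived_mid, tol) {
  if (!length(truth_mid) || !length(derived_mid)) {
    return(data.frame(truth = integer(), derived = integer()))
  }
  cand <- expand.grid(truth = seq_along(truth_mid),
                      derived = seq_along(derived_mid))
  cand$dist <- abs(truth_mid[cand$truth] - derived_mid[cand$derived])
  cand <- cand[cand$dist <= tol, , drop = FALSE]
  cand <- cand[order(cand$dist, cand$truth, cand$derived), , drop = FALSE]
  used_t <- logical(length(truth_mid)); used_d <- logical(length(derived_mid))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ti <- cand$truth[i]; di <- cand$derived[i]
    if (!used_t[ti] && !used_d[di]) {
      keep[i] <- TRUE; used_t[ti] <- TRUE; used_d[di] <- TRUE
    }
  }
  cand[keep, c("truth", "derived"), drop = FALSE]
}

interval_mid <- function(start, end) (as.numeric(start) + as.numeric(end)) / 2

#' Align ground-truth activities with derived indicators
#'
#' Produces the paired samples behind each concurrent-validity comparison:
#' \describe{
#'   \item{room}{categorical pairs (derived room, true room) sampled every
#'     `grid_s` seconds at instants covered by both a truth `room_presence`
#'     interval and a derived presence interval.}
#'   \item{sedentary}{durations of truth `sitting` intervals matched
#'     one-to-one to complete derived bouts whose midpoints lie within
#'     `match_tolerance_s`; plus detected/undetected/spurious tallies.}
#'   \item{stairs}{same for truth `stair_climbing` vs. complete derived
#'     climbs.}
#'   \item{door}{truth `entry_exit` passages matched to door events within
#'     `match_tolerance_s`; detection tallies only.}
#' }
#'
#' @param truth activity `data.frame` (ground truth for one session).
#' @param derived an `indicator_set` from the same session.
#' @param door_events door-sensor event rows from the same log (needed for
#'   the door detection tally); optional.
#' @param match_tolerance_s midpoint tolerance for interval matching,
#'   default 30.
#' @param grid_s room-label sampling step in seconds, default 1.
#' @return list of comparison blocks as described above.
#' @export
align_for_agreement <- function(truth, derived, door_events = empty_events(),
                                match_tolerance_s = 30, grid_s = 1) {
  stopifnot(inherits(derived, "indicator_set"))
  if (nrow(truth) == 0L) stop("empty ground truth", call. = FALSE)
  validate_activities(truth)

  # -- room labels on a time grid
  tp <- truth[truth$activity_type == "room_presence", , drop = FALSE]
  pres <- derived$presences
  room_pairs <- data.frame(sensor = character(), reference = character())
  if (nrow(tp) && nrow(pres)) {
    # derived presence intervals; the open last interval extends to the end
    # of the truth span so the final room is scorable
    span_end <- max(as.numeric(truth$end))
    d_start <- as.numeric(pres$t_pre_motion)
    d_end <- ifelse(is.na(pres$t_next_motion), span_end,
                    as.numeric(pres$t_next_motion))
    grid <- unlist(lapply(seq_len(nrow(tp)), function(i) {
      s <- as.numeric(tp$start[i]); e <- as.numeric(tp$end[i])
      if (e - s < grid_s) return(numeric())
      seq(s, e - 1e-9, by = grid_s)
    }))
    if (length(grid)) {
      ref_lab <- vapply(grid, function(g) {
        hit <- which(as.numeric(tp$start) <= g & g < as.numeric(tp$end))
        if (length(hit)) tp$location[hit[1L]] else NA_character_
      }, character(1))
      sen_lab <- vapply(grid, function(g) {
        hit <- which(d_start <= g & g < d_end)
        if (length(hit)) pres$room[hit[length(hit)]] else NA_character_
      }, character(1))
      ok <- !is.na(ref_lab) & !is.na(sen_lab)
      room_pairs <- data.frame(sensor = sen_lab[ok], reference = ref_lab[ok],
                               stringsAsFactors = FALSE)
    }
  }

  pair_block <- function(truth_iv, d_start, d_end, d_dur) {
    t_mid <- interval_mid(truth_iv$start, truth_iv$end)
    d_mid <- (as.numeric(d_start) + as.numeric(d_end)) / 2
    mm <- match_intervals(t_mid, d_mid, match_tolerance_s)
    list(
      sensor = d_dur[mm$derived],
      reference = secs_between(truth_iv$start, truth_iv$end)[mm$truth],
      detected = nrow(mm),
      undetected = nrow(truth_iv) - nrow(mm),
      spurious = length(d_dur) - nrow(mm))
  }

  ts_sit <- truth[truth$activity_type == "sitting", , drop = FALSE]
  bouts <- derived$bouts[derived$bouts$complete, , drop = FALSE]
  sedentary <- pair_block(ts_sit, bouts$t_pre_occupied, bouts$t_unoccupied,
                          bouts$s)

  ts_st <- truth[truth$activity_type == "stair_climbing", , drop = FALSE]
  climbs <- derived$climbs[derived$climbs$complete, , drop = FALSE]
  stairs <- pair_block(ts_st, climbs$t_distance_sensor1,
                       climbs$t_distance_sensor2, climbs$sc)

  ts_door <- truth[truth$activity_type == "entry_exit", , drop = FALSE]
  door <- list(detected = 0L, undetected = nrow(ts_door), spurious = 0L)
  if (nrow(ts_door)) {
    dmid <- interval_mid(ts_door$start, ts_door$end)
    emid <- as.numeric(door_events$timestamp)
    mm <- match_intervals(dmid, emid, match_tolerance_s)
    door <- list(detected = nrow(mm), undetected = nrow(ts_door) - nrow(mm),
                 spurious = nrow(door_events) - nrow(mm))
  }

  list(room = room_pairs, sedentary = sedentary, stairs = stairs, door = door)
}

#' Bland-Altman plot (difference vs. mean with bias and limit lines)
#' @param ba a result from [bland_altman()].
#' @param main plot title.
#' @export
plot_bland_altman <- function(ba, main = "Bland-Altman plot") {
  plot(ba$means, ba$differences, pch = 19,
       xlab = "Mean of the two methods", ylab = "Difference (sensor - truth)",
       main = main)
  graphics::abline(h = ba$bias, col = "purple", lwd = 2)
  graphics::abline(h = c(ba$lower_loa, ba$upper_loa), col = "darkgreen",
                   lwd = 2)
  invisible(ba)
}
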