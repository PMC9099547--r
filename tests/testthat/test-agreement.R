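test_that("kappa from proportions follows the chance-corrected formula", {
  expect_equal(round(cohens_kappa_from_proportions(0.9558, 0.2882)$k, 3),
               0.938)
  expect_equal(cohens_kappa_from_proportions(1, 0.5)$k, 1)
  for (p in c(0, 0.3, 0.7, 0.99)) {
    expect_equal(cohens_kappa_from_proportions(p, p)$k, 0)
  }
  expect_error(cohens_kappa_from_proportions(0.9, 1), "degenerate")
})

test_that("kappa from pairs builds marginals correctly", {
  lab <- rep(c("a", "b", "c"), times = c(4, 3, 3))
  res <- cohens_kappa(lab, lab)
  expect_equal(res$k, 1)
  expect_equal(res$p_o, 1)

  expect_error(cohens_kappa(character(), character()), "no pairs")
  expect_error(cohens_kappa(rep("a", 5), rep("a", 5)), "degenerate")

  # internal consistency: pairs route equals the proportions route applied
  # to its own confusion-matrix marginals
  set.seed(3)
  s <- sample(c("x", "y", "z"), 200, replace = TRUE)
  r <- ifelse(runif(200) < 0.8, s, sample(c("x", "y", "z"), 200, TRUE))
  res <- cohens_kappa(s, r)
  expect_equal(res$k,
               cohens_kappa_from_proportions(res$p_o, res$p_e)$k)
  # kappa invariant under category relabeling
  relab <- c(x = "q1", y = "q2", z = "q3")
  expect_equal(cohens_kappa(unname(relab[s]), unname(relab[r]))$k, res$k)
})

test_that("kappa matches the brute-force oracle on all small 2x2 tables", {
  checked <- 0
  worst <- 0
  degenerate_ok <- TRUE
  for (a in 0:6) for (b in 0:6) for (c in 0:6) for (d in 0:6) {
    n <- a + b + c + d
    if (n == 0) next
    want <- oracle_kappa_2x2(a, b, c, d)
    labs_s <- rep(c("p", "p", "n", "n"), times = c(a, b, c, d))
    labs_r <- rep(c("p", "n", "p", "n"), times = c(a, b, c, d))
    if (is.na(want)) {
      got <- tryCatch(cohens_kappa(labs_s, labs_r), error = identity)
      degenerate_ok <- degenerate_ok && inherits(got, "error") &&
        grepl("degenerate", conditionMessage(got))
    } else {
      worst <- max(worst, abs(cohens_kappa(labs_s, labs_r)$k - want))
      checked <- checked + 1
    }
  }
  expect_gt(checked, 2000)
  expect_lt(worst, 1e-12)
  expect_true(degenerate_ok)
})

test_that("random independent labels give kappa near zero", {
  set.seed(8)
  n <- 4000
  s <- sample(c("a", "b", "c"), n, replace = TRUE)
  r <- sample(c("a", "b", "c"), n, replace = TRUE)
  res <- cohens_kappa(s, r)
  expect_lt(abs(res$k), 3 * res$se0)
})

test_that("Bland-Altman limits reproduce the reported worked examples", {
  l1 <- bland_altman_limits(-0.286, 8.046)
  expect_equal(round(l1$lower_loa, 3), -16.056) # -0.286 - 1.96*8.046
  expect_equal(round(l1$upper_loa, 3), 15.484)
  # the published figures round the products before summing; agree to 2 dp
  expect_equal(l1$lower_loa, -16.057, tolerance = 2e-3)
  expect_equal(l1$upper_loa, 15.485, tolerance = 2e-3)

  l2 <- bland_altman_limits(0.526, 4.273)
  expect_equal(l2$lower_loa, -7.848, tolerance = 2e-3)
  expect_equal(l2$upper_loa, 8.901, tolerance = 2e-3)
  # limits symmetric about the bias; width exactly 2 * 1.96 * sd
  expect_equal(l2$upper_loa + l2$lower_loa, 2 * 0.526)
  expect_equal(l2$upper_loa - l2$lower_loa, 2 * 1.96 * 4.273)
})

test_that("bland_altman computes bias, limits, outside rule and prop bias", {
  x <- c(10, 12, 15, 20, 25, 31)
  ba <- bland_altman(x, x)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, 0)
  expect_equal(ba$n_outside, 0)
  expect_true(ba$agreement)

  expect_error(bland_altman(1, 2), "at least 2")

  set.seed(21)
  ref <- runif(40, 50, 300)
  sen <- ref + rnorm(40, 0.5, 6)
  ba <- bland_altman(sen, ref)
  d <- sen - ref
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$sd, sd(d))  # sample SD, n-1 denominator
  expect_equal(ba$lower_loa, mean(d) - 1.96 * sd(d))
  expect_equal(ba$n_outside, sum(d < ba$lower_loa | d > ba$upper_loa))
  fit <- summary(lm(d ~ I((sen + ref) / 2)))$coefficients
  expect_equal(ba$prop_bias_t, fit[2, 3])
  expect_equal(ba$prop_bias_p, fit[2, 4])

  # strictly-outside: a difference exactly on a limit is inside
  d0 <- c(-1, 1, -1, 1)
  ba0 <- bland_altman(d0, rep(0, 4))
  expect_equal(ba0$upper_loa, 1.96 * sd(d0))
  expect_equal(ba0$n_outside, 0)
})

test_that("the 20% outside rule gives the reported verdict for 2 of 42", {
  pct <- 100 * 2 / 42
  expect_equal(round(pct, 1), 4.8)
  expect_true(pct <= 20)
  # and the complementary no-agreement branch
  ref <- seq(100, 145, by = 5)
  sen <- ref + c(rep(0, 9), 50)   # one gross outlier in ten pairs
  ba <- bland_altman(sen, ref, outside_threshold_pct = 5)
  expect_gt(ba$pct_outside, 5)
  expect_false(ba$agreement)
})

test_that("detection rates are exact percentages", {
  expect_equal(detection_rate(35, 5)$pct, 87.5)
  expect_equal(detection_rate(38, 38)$pct, 50)
  expect_equal(detection_rate(12, 0)$pct, 100)
  expect_error(detection_rate(0, 0), "zero")
  set.seed(6)
  for (rep in 1:10) {
    a <- sample(1:50, 1); b <- sample(1:50, 1)
    expect_equal(detection_rate(a, b)$pct + detection_rate(b, a)$pct, 100)
  }
})

test_that("pearson correlation matches the direct covariance formula", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 3)$r, 1)
  expect_equal(pearson_correlation(x, -0.5 * x + 1)$r, -1)
  expect_error(pearson_correlation(1:2, 2:3), "at least 3")
  expect_error(pearson_correlation(rep(1, 5), 1:5), "variance")
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    a <- rnorm(n); b <- rnorm(n) + 0.4 * a
    r_direct <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pearson_correlation(a, b)$r, r_direct, tolerance = 1e-12)
  }
})

test_that("alignment pairs a perfect derived set exactly", {
  truth <- generate_session(seed = 23)
  log <- observe(truth, sensor_model_zero_noise(), seed = 24)
  ind <- derive_indicators(log)
  al <- align_for_agreement(truth, ind,
                            door_events = subset_events(log, "door"))
  expect_equal(cohens_kappa(al$room$sensor, al$room$reference)$p_o, 1)
  expect_equal(al$sedentary$sensor, al$sedentary$reference)
  expect_equal(al$sedentary$undetected, 0)
  expect_equal(al$stairs$sensor, al$stairs$reference)
  expect_equal(al$door$undetected, 0)
  expect_error(align_for_agreement(truth[0, ], ind), "empty")
})

test_that("a missing climb yields the counting detection rate", {
  truth <- activity_records("p", 1, rep("stair_climbing", 4), "stairs",
                            T0 + c(0, 100, 200, 300),
                            T0 + c(12, 112, 212, 312))
  # derived set contains only 3 of the 4 climbs
  ev <- mk_distance(c(0, 12, 100, 112, 200, 212),
                    rep(c("first_step", "last_step"), 3))
  ind <- derive_indicators(event_log(ev))
  al <- align_for_agreement(truth, ind)
  dr <- detection_rate(al$stairs$detected, al$stairs$undetected)
  expect_equal(dr$pct, 75)
})

test_that("pairing count is invariant to jitter within tolerance", {
  set.seed(55)
  for (rep in 1:8) {
    nt <- sample(2:5, 1)
    t_start <- sort(runif(nt, 0, 3000))
    t_start <- t_start[c(TRUE, diff(t_start) > 200)]  # well separated
    nt <- length(t_start)
    dur <- runif(nt, 20, 60)
    truth <- activity_records("p", 1, rep("sitting", nt), "living_room",
                              T0 + t_start, T0 + t_start + dur)
    jit <- runif(nt, -10, 10)   # well within the 30 s tolerance
    ev <- do.call(rbind, lapply(seq_len(nt), function(i) {
      mk_mat(c(t_start[i] + jit[i], t_start[i] + jit[i] + dur[i]),
             c(TRUE, FALSE))
    }))
    ev <- ev[order(as.numeric(ev$timestamp)), ]
    ind <- derive_indicators(event_log(ev))
    al <- align_for_agreement(truth, ind)
    want <- oracle_max_matching(
      t_start + dur / 2,
      secs_between(T0, ind$bouts$t_pre_occupied) + ind$bouts$s / 2, 30)
    expect_equal(al$sedentary$detected, want)
    expect_equal(al$sedentary$detected, nt)
  }
})
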