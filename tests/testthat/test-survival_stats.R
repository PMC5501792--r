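test_that("Kaplan-Meier matches the closed form on the three-event toy", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$times, c(1, 2, 3))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$at_risk, c(3L, 2L, 1L))
})

test_that("an all-censored sample yields a constant-1 curve with a warning", {
  expect_warning(km <- km_estimate(c(2, 5, 9), c(0, 0, 0)), "no events")
  expect_length(km$times, 0)
})

test_that("Kaplan-Meier matches an independent product-limit oracle", {
  set.seed(14)
  for (rep in 1:10) {
    time <- round(rexp(30, 0.1), 1) + 0.1
    event <- rbinom(30, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    km <- km_estimate(time, event)
    oracle <- km_oracle(time, event)
    expect_equal(km$times, oracle$times)
    expect_equal(km$survival, oracle$survival, tolerance = 1e-12)
  }
})

test_that("log-rank statistic is zero for duplicated groups and matches the toy", {
  time <- c(1, 3, 5, 7, 9)
  event <- c(1, 0, 1, 1, 0)
  lr <- logrank_test(c(time, time), c(event, event),
                     rep(1:2, each = 5))
  expect_lt(lr$statistic, 1e-10)
  expect_equal(lr$p_value, 1, tolerance = 1e-6)

  # fully separated two-group toy against the O/E oracle
  lr2 <- logrank_test(c(1, 2, 3, 4, 5, 6), rep(1, 6), rep(1:2, each = 3))
  oracle <- logrank2_oracle(c(1, 2, 3, 4, 5, 6), rep(1, 6),
                            rep(1:2, each = 3))
  expect_equal(lr2$statistic, oracle$statistic, tolerance = 1e-8)
  expect_equal(unname(lr2$per_group_expected[1]), oracle$expected1,
               tolerance = 1e-10)
})

test_that("log-rank agrees with the O/E oracle on random censored data", {
  set.seed(41)
  for (rep in 1:20) {
    n <- 40
    g <- rep(1:2, each = 20)
    time <- rexp(n, ifelse(g == 1, 0.05, 0.11))
    cens <- runif(n, 0, 30)
    ev <- as.integer(time <= cens)
    tm <- pmin(time, cens)
    if (sum(ev) == 0) next
    lr <- logrank_test(tm, ev, g)
    expect_equal(lr$statistic, logrank2_oracle(tm, ev, g)$statistic,
                 tolerance = 1e-8)
    expect_equal(sum(lr$per_group_observed), sum(lr$per_group_expected),
                 tolerance = 1e-8)
  }
})

test_that("log-rank is invariant to group relabeling and late censoring", {
  set.seed(55)
  tm <- rexp(30, 0.1)
  ev <- rbinom(30, 1, 0.8)
  ev[1] <- 1
  g <- rep(1:3, each = 10)
  a <- logrank_test(tm, ev, g)
  b <- logrank_test(tm, ev, c(3, 1, 2)[g])
  expect_equal(a$statistic, b$statistic, tolerance = 1e-10)
  expect_identical(a$df, 2L)
  # moving a censoring time that already lies beyond the last event
  # changes nothing: that subject is in every risk set either way
  tm2 <- c(tm, max(tm) + 5)
  ev2 <- c(ev, 0)
  g2 <- c(g, 1)
  tm3 <- tm2
  tm3[length(tm3)] <- max(tm) + 50
  a2 <- logrank_test(tm2, ev2, g2)
  a3 <- logrank_test(tm3, ev2, g2)
  expect_equal(a2$statistic, a3$statistic, tolerance = 1e-10)
  expect_equal(km_estimate(tm2, ev2)$survival,
               km_estimate(tm3, ev2)$survival, tolerance = 1e-12)
})

test_that("the two-group statistic is the squared standardized O-E scalar", {
  set.seed(77)
  tm <- rexp(26, 0.08)
  ev <- rbinom(26, 1, 0.75)
  ev[2] <- 1
  g <- rep(1:2, each = 13)
  lr <- logrank_test(tm, ev, g)
  oe <- logrank2_oracle(tm, ev, g)
  z <- (oe$observed1 - oe$expected1) / sqrt(oe$variance)
  expect_equal(lr$statistic, z^2, tolerance = 1e-8)
})

test_that("hazard ratio has the Mantel-Haenszel form and reciprocity", {
  set.seed(19)
  tm <- rexp(40, 0.1)
  ev <- rep(1L, 40)
  g <- rep(1:2, each = 20)
  tm[g == 2] <- tm[g == 2] * 3        # group 2 lives longer
  hr <- hazard_ratio_two_group(tm, ev, g)
  lr <- logrank_test(tm, ev, g)
  O <- lr$per_group_observed; E <- lr$per_group_expected
  expect_equal(hr$hr, unname((O[1] / E[1]) / (O[2] / E[2])),
               tolerance = 1e-12)
  expect_equal(hr$ci_low,
               unname(exp(log(hr$hr) - 1.96 * sqrt(1 / E[1] + 1 / E[2]))),
               tolerance = 1e-12)
  expect_true(hr$ci_low <= hr$hr && hr$hr <= hr$ci_high)
  expect_gt(hr$hr, 1)
  # swapping labels inverts the ratio and the interval
  hr_sw <- hazard_ratio_two_group(tm, ev, 3 - g)
  expect_equal(hr_sw$hr, 1 / hr$hr, tolerance = 1e-10)
  expect_equal(hr_sw$ci_low, 1 / hr$ci_high, tolerance = 1e-10)
})

test_that("degenerate survival inputs raise the documented errors", {
  expect_error(logrank_test(c(1, 2), c(1, 1), c(1, 1)), "2 groups")
  expect_error(logrank_test(c(1, 2), c(0, 0), c(1, 2)), "no events")
  expect_error(hazard_ratio_two_group(c(1, 2, 3, 4), c(1, 1, 0, 0),
                                      c(1, 1, 2, 2)), "zero events")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "positive")
})

test_that("per-group KM curves are computed for each subtype", {
  co <- blob_cohort(n = 40, k = 2)
  km <- suppressWarnings(km_by_group(co$clinical$time, co$clinical$event,
                                     co$true_labels))
  expect_named(km, c("1", "2"))
  expect_s3_class(km[["1"]], "km_curve")
})
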