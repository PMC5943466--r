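# Endpoint derivation: DSN, nadir, time to recovery, febrile neutropenia,
# per-arm summaries.

test_that("DSN is the interval from grade-4 onset to recovery >= 2.0", {
  s <- ser(c(`1` = 5.0, `2` = 4.0, `3` = 8.0, `7` = 0.4, `8` = 0.3,
             `9` = 0.9, `10` = 2.5))
  expect_equal(as.integer(derive_dsn(s)), 3L)     # onset Day 7, recovery Day 10
  expect_false(attr(derive_dsn(s), "censored"))

  expect_equal(as.integer(derive_dsn(ser(c(`1` = 5, `7` = 0.6, `10` = 3)))), 0L)
  expect_equal(as.integer(derive_dsn(ser(c(`1` = 5, `7` = 0.4, `8` = 2.1)))), 1L)
})

test_that("series without observed recovery are censored at observed severe days", {
  s <- ser(c(`1` = 5, `7` = 0.4, `8` = 0.3, `9` = 0.2))
  d <- derive_dsn(s)
  expect_equal(as.integer(d), 3L)                 # 9 - 7 + 1
  expect_true(attr(d, "censored"))
})

test_that("malformed series are rejected", {
  expect_error(derive_dsn(data.frame(study_day = integer(0), anc = numeric(0))),
               "empty")
  expect_error(derive_dsn(data.frame(study_day = c(3, 2), anc = c(1, 1))),
               "increasing")
  expect_error(derive_dsn(data.frame(study_day = 1, anc = -0.1)), "negative")
})

test_that("derive_dsn agrees with the pair-enumeration oracle on random series", {
  set.seed(7)
  for (i in 1:1000) {
    s <- random_series()
    got <- derive_dsn(s)
    want <- oracle_dsn(s)
    expect_equal(as.integer(got), want$dsn)
    expect_equal(attr(got, "censored"), want$censored)
    # DSN = 0 iff min ANC >= 0.5; DSN > 0 implies the series dipped below 2.0
    expect_equal(as.integer(got) == 0L, min(s$anc) >= 0.5)
    if (as.integer(got) > 0L) expect_lt(min(s$anc), 2.0)
  }
})

test_that("nadir is the minimum ANC with earliest-day tie-break", {
  n <- derive_nadir(ser(c(`1` = 5.0, `7` = 0.8, `9` = 0.8, `14` = 3.0)))
  expect_equal(n, list(depth = 0.8, nadir_day = 7L, time_to_nadir = 7L))
  n <- derive_nadir(ser(c(`1` = 5, `2` = 5, `3` = 5)))
  expect_equal(n, list(depth = 5, nadir_day = 1L, time_to_nadir = 1L))
})

test_that("time to recovery needs a dip below 2.0 and a post-nadir rise to >= 2.0", {
  expect_equal(as.integer(derive_time_to_recovery(
    ser(c(`1` = 5.0, `3` = 8.0, `7` = 0.8, `9` = 2.5)))), 9L)
  expect_true(is.na(derive_time_to_recovery(ser(c(`1` = 5, `7` = 2.0, `10` = 3)))))
  # boundary: 1.9 counts as dipped, 2.0 counts as recovered
  expect_equal(as.integer(derive_time_to_recovery(
    ser(c(`1` = 5.0, `7` = 1.9, `8` = 2.0)))), 8L)
  # dipped but never recovered: NA with censoring flag
  ttr <- derive_time_to_recovery(ser(c(`1` = 5, `7` = 1.0, `9` = 1.2)))
  expect_true(is.na(ttr))
  expect_true(attr(ttr, "censored"))
})

test_that("febrile neutropenia needs temp > 38.2 C within 1 day of grade-4 ANC", {
  s <- ser(c(`1` = 5, `7` = 0.4, `10` = 3))
  temp <- function(day, t) data.frame(study_day = day, temp_c = t)
  expect_true(flag_febrile_neutropenia(s, temp(8, 38.5)))
  expect_true(flag_febrile_neutropenia(s, temp(6, 38.3)))
  expect_false(flag_febrile_neutropenia(s, temp(8, 38.2)))  # strict >
  expect_false(flag_febrile_neutropenia(s, temp(9, 39.0)))  # window exceeded
  expect_false(flag_febrile_neutropenia(s, NULL))
  expect_true(flag_febrile_neutropenia(s, NULL, ae_flag = TRUE))
  # fever without grade-4 neutropenia is not the endpoint
  expect_false(flag_febrile_neutropenia(ser(c(`1` = 5, `7` = 0.6)), temp(7, 39)))
})

test_that("arm summaries reproduce the fixture's published mean and SD", {
  ep <- derive_endpoints(reference_cohort())
  s45 <- summarize_arm(ep[ep$arm == "eflapegrastim_45", ])
  expect_equal(round_half_up(s45$mean_dsn, 2), 1.03)
  expect_equal(round_half_up(s45$sd_dsn, 2), 1.55)
  s270 <- summarize_arm(ep[ep$arm == "eflapegrastim_270", ])
  expect_equal(round_half_up(s270$mean_dsn, 2), 0.03)
  expect_equal(round_half_up(s270$sd_dsn, 2), 0.17)
  expect_equal(s45$median_dsn, 0)
  expect_equal(s45$n_dipped, 14L)
  expect_equal(s45$median_time_to_recovery, 10)
})

test_that("summary frequency counts sum to n and re-yield the mean; n = 1 flags SD", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    df <- data.frame(arm = "x", cycle = 1L,
                     dsn_days = sample(0:5, n, replace = TRUE),
                     dipped_below_2 = FALSE, time_to_recovery = NA_integer_,
                     nadir_depth = 1, nadir_day = 7L,
                     febrile_neutropenia = FALSE, dsn_censored = FALSE)
    s <- summarize_arm(df)
    expect_equal(sum(s$dsn_frequency), n)
    k <- as.numeric(names(s$dsn_frequency))
    expect_equal(sum(k * s$dsn_frequency) / n, s$mean_dsn)
  }
  s1 <- summarize_arm(data.frame(arm = "x", cycle = 1L, dsn_days = 0,
                                 dipped_below_2 = FALSE,
                                 time_to_recovery = NA_integer_,
                                 nadir_depth = 1, nadir_day = 7L,
                                 febrile_neutropenia = FALSE,
                                 dsn_censored = FALSE))
  expect_equal(s1$sd_dsn, 0)
  expect_true(s1$sd_undefined)
})
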