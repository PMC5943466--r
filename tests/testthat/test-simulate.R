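# Trajectory simulator, adaptive monitoring schedule, cohort generator.

test_that("full-potency dose cancels suppression and never drops below baseline", {
  cfg <- sim_config(obs_noise_cv = 0)
  traj <- simulate_dense_trajectory(cfg, dose_potency = 1, baseline = 4)
  expect_true(all(traj >= 4 - 1e-12))
  # identical to a config with the suppression term removed
  cfg0 <- sim_config(obs_noise_cv = 0, suppression_depth = 0)
  expect_equal(traj, simulate_dense_trajectory(cfg0, 1, baseline = 4))
})

test_that("noise-free nadir with default kernels falls on days 5-10", {
  cfg <- sim_config(obs_noise_cv = 0)
  for (p in c(0, 0.25, 0.5, 0.75)) {
    traj <- simulate_dense_trajectory(cfg, p, baseline = 4)
    expect_true(which.min(traj) %in% 5:10, label = sprintf("potency %.2f", p))
  }
})

test_that("noise-free nadir depth is non-decreasing in dose potency", {
  cfg <- sim_config(obs_noise_cv = 0)
  grid <- seq(0, 1, by = 0.1)
  depths <- vapply(grid, function(p) {
    min(simulate_dense_trajectory(cfg, p, baseline = 4))
  }, numeric(1))
  expect_true(all(diff(depths) >= -1e-12))
})

test_that("invalid potency and malformed configs are rejected", {
  cfg <- sim_config()
  expect_error(simulate_dense_trajectory(cfg, 1.2), "\\[0, 1\\]")
  expect_error(simulate_dense_trajectory(cfg, -0.1), "\\[0, 1\\]")
  expect_error(sim_config(stim_day = 8), "stim_day < suppression_day")
  expect_error(sim_config(suppression_depth = -1), "amplitudes")
  expect_error(sim_arm("x", 0.5, 0), "positive")
  expect_error(sim_arm("x", 1.5, 10), "\\[0, 1\\]")
})

test_that("monitoring schedule follows the protocol's adaptive rule", {
  # never below 1.5: Days 1-3 plus the twice-weekly grid
  obs <- apply_monitoring_schedule(rep(5, 21))
  expect_equal(obs$study_day, c(1, 2, 3, 7, 10, 14, 17, 21))

  # dips below 1.5 first at Day 7, recovers >= 1.5 at Day 11: daily 8-11,
  # then the grid resumes at Day 14
  dense <- rep(5, 21)
  dense[4:10] <- 1.0
  dense[11:21] <- 2.0
  obs <- apply_monitoring_schedule(dense)
  expect_equal(obs$study_day, c(1, 2, 3, 7, 8, 9, 10, 11, 14, 17, 21))

  # already below 1.5 at Day 3: daily from Day 4 until recovery at Day 9
  dense <- c(5, 5, 1.2, 1.0, 0.8, 0.6, 0.9, 1.2, 2.0, rep(5, 12))
  obs <- apply_monitoring_schedule(dense)
  expect_equal(obs$study_day, c(1:9, 10, 14, 17, 21))
})

test_that("schedule-thinned DSN equals dense-daily DSN when the 1.5 trigger is observed first", {
  set.seed(42)
  for (i in 1:200) {
    dense <- random_soundness_trajectory()
    dense_series <- data.frame(study_day = 1:21, anc = dense)
    thinned <- apply_monitoring_schedule(dense)
    expect_equal(as.integer(derive_dsn(thinned)),
                 as.integer(derive_dsn(dense_series)))
  }
})

test_that("cohorts are reproducible from the seed and invariant to arm order", {
  arms <- list(sim_arm("a", 0.3, 5), sim_arm("b", 0.7, 4))
  cfg <- sim_config(arms = arms, seed = 99)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1, co2)

  cfg_rev <- sim_config(arms = rev(arms), seed = 99)
  co3 <- simulate_cohort(cfg_rev)
  key <- function(co) {
    o <- co$observations[order(co$observations$patient_id,
                               co$observations$cycle,
                               co$observations$study_day), ]
    rownames(o) <- NULL
    o
  }
  expect_equal(key(co1), key(co3))
  p1 <- co1$patients[order(co1$patients$patient_id), ]
  p3 <- co3$patients[order(co3$patients$patient_id), ]
  rownames(p1) <- rownames(p3) <- NULL
  expect_equal(p1, p3)
})

test_that("weight strata follow the <65 / 65-75 / >75 kg cut-points", {
  expect_equal(weight_stratum(c(50, 64.9, 65, 70, 75, 75.1, 100)),
               c("<65", "<65", "65-75", "65-75", "65-75", ">75", ">75"))
  expect_error(weight_stratum(-1), "positive")
  # degenerate weight model puts everyone in the middle stratum
  cfg <- sim_config(arms = list(sim_arm("a", 0.5, 10)),
                    weight_log_mean = log(70), weight_log_sd = 0, seed = 1)
  co <- simulate_cohort(cfg)
  expect_true(all(co$patients$stratum == "65-75"))
})

test_that("mean DSN decreases and nadir depth rises with dose potency at n = 200", {
  arms <- list(sim_arm("low", 0.1, 200), sim_arm("mid", 0.5, 200),
               sim_arm("high", 0.9, 200))
  co <- simulate_cohort(sim_config(arms = arms, seed = 2024))
  ep <- derive_endpoints(co)
  mean_dsn <- tapply(ep$dsn_days, ep$arm, mean)[c("low", "mid", "high")]
  expect_true(all(diff(mean_dsn) < 0))
  mean_depth <- tapply(ep$nadir_depth, ep$arm, mean)[c("low", "mid", "high")]
  expect_true(all(diff(mean_depth) > 0))
})

test_that("fixture cohort has the published arm sizes and DSN multisets round-trip", {
  co <- reference_cohort()
  sizes <- table(co$patients$arm)
  expect_equal(sizes[["eflapegrastim_45"]], 39)
  expect_equal(sizes[["eflapegrastim_135"]], 36)
  expect_equal(sizes[["eflapegrastim_270"]], 36)
  expect_equal(sizes[["pegfilgrastim"]], 36)

  ep <- derive_endpoints(co)
  expect_equal(sum(ep$dsn_days[ep$arm == "eflapegrastim_270"] == 0), 35)
  for (a in names(reference_dsn_multisets())) {
    expect_equal(sort(ep$dsn_days[ep$arm == a]),
                 sort(reference_dsn_multisets()[[a]]),
                 label = a)
  }
  expect_false(any(ep$dsn_censored))
})

test_that("fixture cohort serializes byte-identically across builds", {
  d1 <- file.path(tempdir(), "ref1"); d2 <- file.path(tempdir(), "ref2")
  write_cohort(reference_cohort(), d1)
  write_cohort(reference_cohort(), d2)
  for (f in c("cohort_patients.csv", "cohort_observations.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
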