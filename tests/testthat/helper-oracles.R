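# Shared test helpers: series constructors, independent oracles, generators.

# Build an ANC series from a named vector: names are study days.
ser <- function(x) {
  data.frame(study_day = as.integer(names(x)), anc = unname(x))
}

# Independent DSN oracle: enumerate all (onset, recovery) observation pairs
# rather than scanning forward.  Returns list(dsn, censored).
oracle_dsn <- function(series) {
  d <- series$study_day
  a <- series$anc
  onsets <- d[a < 0.5]
  if (!length(onsets)) return(list(dsn = 0L, censored = FALSE))
  pairs <- expand.grid(u = seq_along(d), v = seq_along(d))
  ok <- a[pairs$u] < 0.5 & a[pairs$v] >= 2.0 & d[pairs$v] >= d[pairs$u]
  pairs <- pairs[ok, , drop = FALSE]
  first_onset <- min(onsets)
  pairs <- pairs[d[pairs$u] == first_onset, , drop = FALSE]
  if (!nrow(pairs)) {
    return(list(dsn = as.integer(max(d) - first_onset + 1L), censored = TRUE))
  }
  list(dsn = as.integer(min(d[pairs$v]) - first_onset), censored = FALSE)
}

# Random observed ANC series on sorted distinct days, mixing benign and
# neutropenic shapes; guarantees a valid series (>=1 row, days increasing).
random_series <- function() {
  n_obs <- sample(3:12, 1)
  days <- sort(sample(1:21, n_obs))
  anc <- rlnorm(n_obs, log(2), 1)
  # with prob 1/2 force a severe dip followed (sometimes) by recovery
  if (runif(1) < 0.5) {
    i <- sample(seq_len(n_obs), 1)
    anc[i] <- runif(1, 0, 0.49)
    if (runif(1) < 0.7 && i < n_obs) {
      j <- sample((i + 1):n_obs, 1)
      anc[j] <- runif(1, 2, 6)
    }
  }
  data.frame(study_day = days, anc = anc)
}

# Independently coded plain (unstratified) bootstrap of the mean difference.
plain_bootstrap_diffs <- function(x_exp, x_ctrl, B, seed) {
  set.seed(seed)
  vapply(seq_len(B), function(b) {
    mean(sample(x_exp, length(x_exp), replace = TRUE)) -
      mean(sample(x_ctrl, length(x_ctrl), replace = TRUE))
  }, numeric(1))
}

# Dense daily trajectories (days 1..21) for which the adaptive schedule is
# lossless for DSN: ANC crosses 1.5 at an observed day (Day 3 or Day 7 with
# Day 3 still >= 1.5) before any grade-4 value, and recovery jumps from below
# 1.5 directly to >= 2.0 so the recovery day is observed.
random_soundness_trajectory <- function() {
  anc <- rep(5, 21)
  if (runif(1) < 0.5) {
    trigger <- 3L                      # dips below 1.5 on Day 3
    anc[1:2] <- runif(2, 2, 6)
  } else {
    trigger <- 7L                      # Day 3 fine, trigger at grid Day 7
    anc[1:6] <- runif(6, 1.5, 6)
  }
  onset <- trigger + sample(0:3, 1)    # first grade-4 day (daily obs by then)
  recovery <- onset + sample(1:6, 1)
  recovery <- min(recovery, 21L)
  if (trigger < onset) anc[trigger:(onset - 1)] <- runif(onset - trigger, 0.5, 1.49)
  anc[onset:(recovery - 1)] <- runif(recovery - onset, 0, 0.49)
  anc[recovery:21] <- runif(22 - recovery, 2, 6)
  anc
}

# Fixture DSN multisets per arm (the published Cycle-1 frequency rows).
reference_dsn_multisets <- function() {
  list(
    eflapegrastim_45  = rep(c(0, 1, 2, 3, 4, 5), c(25, 1, 5, 5, 1, 2)),
    eflapegrastim_135 = rep(c(0, 1, 2, 7), c(29, 3, 3, 1)),
    eflapegrastim_270 = rep(c(0, 1), c(35, 1)),
    pegfilgrastim     = rep(c(0, 1, 2, 3), c(31, 1, 2, 2))
  )
}
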