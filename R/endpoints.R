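# Protocol endpoint derivation from one patient-cycle's ANC series.
#
# Boundary conventions, all as specified by the protocol: grade-4 neutropenia
# is ANC < 0.5 x 10^9/L (strict), recovery is ANC >= 2.0 (inclusive), the
# daily-monitoring trigger is ANC < 1.5 (strict).

check_series <- function(series) {
  if (!is.data.frame(series) || !all(c("study_day", "anc") %in% names(series))) {
    stop("`series` must be a data frame with columns study_day and anc")
  }
  if (nrow(series) == 0L) stop("empty ANC series")
  if (is.unsorted(series$study_day, strictly = TRUE)) {
    stop("series days must be strictly increasing")
  }
  if (any(series$anc < 0)) stop("negative ANC values are invalid")
  series
}

# Shared onset/recovery scan; returns list(dsn, censored, onset_day).
dsn_scan <- function(series) {
  d <- series$study_day
  a <- series$anc
  onset_idx <- which(a < 0.5)
  if (!length(onset_idx)) {
    return(list(dsn = 0L, censored = FALSE, onset_day = NA_integer_))
  }
  i0 <- onset_idx[1L]
  rec_idx <- which(d >= d[i0] & a >= 2.0)
  if (length(rec_idx)) {
    list(dsn = as.integer(d[rec_idx[1L]] - d[i0]), censored = FALSE,
         onset_day = as.integer(d[i0]))
  } else {
    # no in-cycle recovery observed: count observed severe span, flag censored
    list(dsn = as.integer(d[length(d)] - d[i0] + 1L), censored = TRUE,
         onset_day = as.integer(d[i0]))
  }
}

#' Duration of severe neutropenia (DSN) for one patient-cycle
#'
#' DSN is the interval from the day of first observed grade-4 neutropenia
#' (ANC < 0.5 x 10^9/L) to the first ANC recovery to >= 2.0 x 10^9/L at or
#' after that day, in days (`recovery day - onset day`, so a single grade-4
#' day followed by next-day recovery counts as 1 day).  Series with no grade-4
#' observation return 0.  Series with grade-4 onset but no observed recovery
#' are censored: the count of observed severe days
#' (`last day - onset day + 1`) is returned with attribute `censored = TRUE`.
#'
#' @param series Data frame with strictly increasing `study_day` and
#'   non-negative `anc` (x 10^9/L).
#' @return Integer number of days, with logical attribute `censored`.
#' @export
derive_dsn <- function(series) {
  res <- dsn_scan(check_series(series))
  structure(res$dsn, censored = res$censored)
}

#' ANC nadir depth and timing for one patient-cycle
#'
#' Depth is the lowest observed ANC; the nadir day is the earliest day
#' attaining it; time to nadir is `nadir day - chemotherapy day + 1`.
#'
#' @inheritParams derive_dsn
#' @param chemo_day Study day of chemotherapy administration (Day 1).
#' @return List with `depth` (x 10^9/L), `nadir_day`, `time_to_nadir` (days).
#' @export
derive_nadir <- function(series, chemo_day = 1L) {
  series <- check_series(series)
  i <- which.min(series$anc)  # earliest index on ties
  list(depth = series$anc[i],
       nadir_day = as.integer(series$study_day[i]),
       time_to_nadir = as.integer(series$study_day[i] - chemo_day + 1L))
}

#' Time to ANC recovery for one patient-cycle
#'
#' Defined only for patients whose ANC decreased below 2.0 x 10^9/L: the time
#' from chemotherapy administration until the first ANC >= 2.0 observed after
#' the nadir day (`recovery day - chemotherapy day + 1`).  Returns `NA` when
#' the series never dipped below 2.0 (endpoint not applicable) and `NA` with
#' attribute `censored = TRUE` when it dipped but no post-nadir recovery was
#' observed.
#'
#' @inheritParams derive_nadir
#' @return Integer number of days or `NA_integer_`; attribute `censored`.
#' @export
derive_time_to_recovery <- function(series, chemo_day = 1L) {
  series <- check_series(series)
  if (!any(series$anc < 2.0)) {
    return(structure(NA_integer_, censored = FALSE))
  }
  nadir_day <- derive_nadir(series, chemo_day)$nadir_day
  rec_idx <- which(series$study_day > nadir_day & series$anc >= 2.0)
  if (!length(rec_idx)) {
    return(structure(NA_integer_, censored = TRUE))
  }
  structure(as.integer(series$study_day[rec_idx[1L]] - chemo_day + 1L),
            censored = FALSE)
}

#' Febrile neutropenia flag for one patient-cycle
#'
#' True when a temperature strictly above 38.2 C occurs within one day of an
#' observed ANC < 0.5 x 10^9/L, or when an externally reported febrile
#' neutropenia adverse event is supplied.  Missing temperature data never set
#' the flag on their own.
#'
#' @inheritParams derive_dsn
#' @param temps Data frame with columns `study_day` and `temp_c`, or `NULL`.
#' @param ae_flag Logical: a reported febrile-neutropenia adverse event.
#' @return Logical scalar.
#' @export
flag_febrile_neutropenia <- function(series, temps = NULL, ae_flag = FALSE) {
  if (isTRUE(ae_flag)) return(TRUE)
  if (is.null(temps) || nrow(temps) == 0L) return(FALSE)
  series <- check_series(series)
  severe_days <- series$study_day[series$anc < 0.5]
  if (!length(severe_days)) return(FALSE)
  fever_days <- temps$study_day[temps$temp_c > 38.2]
  if (!length(fever_days)) return(FALSE)
  any(vapply(fever_days, function(t) any(abs(t - severe_days) <= 1), logical(1)))
}

#' Derive all protocol endpoints for every patient in a cohort cycle
#'
#' @param cohort An `anc_cohort` (see [simulate_cohort()], [read_cohort()]).
#' @param cycle Cycle number to analyse.
#' @param chemo_day Study day of chemotherapy administration.
#' @return Data frame, one row per patient: `patient_id`, `arm`, `weight_kg`,
#'   `stratum`, `cycle`, `dsn_days`, `dsn_censored`, `nadir_depth`,
#'   `nadir_day`, `time_to_nadir`, `time_to_recovery` (NA if never below 2.0
#'   or censored), `recovery_censored`, `dipped_below_2`,
#'   `febrile_neutropenia`.
#' @export
derive_endpoints <- function(cohort, cycle = 1L, chemo_day = 1L) {
  stopifnot(inherits(cohort, "anc_cohort"))
  obs <- cohort$observations[cohort$observations$cycle == cycle, , drop = FALSE]
  if (nrow(obs) == 0L) stop("no observations for cycle ", cycle)
  temps <- cohort$temperatures
  temps <- temps[temps$cycle == cycle, , drop = FALSE]

  rows <- lapply(seq_len(nrow(cohort$patients)), function(i) {
    p <- cohort$patients[i, ]
    ser <- obs[obs$patient_id == p$patient_id, c("study_day", "anc")]
    if (nrow(ser) == 0L) return(NULL)  # patient absent from this cycle
    ser <- ser[order(ser$study_day), , drop = FALSE]
    scan <- dsn_scan(ser)
    nad <- derive_nadir(ser, chemo_day)
    ttr <- derive_time_to_recovery(ser, chemo_day)
    ptemps <- temps[temps$patient_id == p$patient_id, , drop = FALSE]
    data.frame(
      patient_id = p$patient_id, arm = p$arm, weight_kg = p$weight_kg,
      stratum = p$stratum, cycle = cycle,
      dsn_days = scan$dsn, dsn_censored = scan$censored,
      nadir_depth = nad$depth, nadir_day = nad$nadir_day,
      time_to_nadir = nad$time_to_nadir,
      time_to_recovery = as.integer(ttr),
      recovery_censored = isTRUE(attr(ttr, "censored")),
      dipped_below_2 = min(ser$anc) < 2.0,
      febrile_neutropenia = flag_febrile_neutropenia(ser, ptemps),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Summarise endpoints for one arm
#'
#' @param results Data frame of [derive_endpoints()] rows for a single arm.
#' @return An `arm_summary` list: `n`, `mean_dsn`, `sd_dsn` (n-1 denominator;
#'   0 with `sd_undefined = TRUE` for n = 1), `median_dsn`, `dsn_frequency`
#'   (named integer vector, day-count -> n), `n_dipped`,
#'   `median_time_to_recovery` (among patients who dipped below 2.0 and
#'   recovered), `median_nadir_depth`, `median_nadir_day`, `fn_count`,
#'   `censored_n`, `cycle`, `arm`.
#' @export
summarize_arm <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  if (length(unique(results$arm)) != 1L) {
    stop("`results` must contain a single arm; see arm_summary_table() for all arms")
  }
  n <- nrow(results)
  dsn <- results$dsn_days
  freq <- table(factor(dsn, levels = sort(unique(dsn))))
  ttr <- results$time_to_recovery[results$dipped_below_2]
  structure(list(
    arm = results$arm[1L], cycle = results$cycle[1L], n = n,
    mean_dsn = mean(dsn),
    sd_dsn = if (n > 1L) stats::sd(dsn) else 0,
    sd_undefined = n == 1L,
    median_dsn = stats::median(dsn),
    dsn_frequency = stats::setNames(as.integer(freq), names(freq)),
    n_dipped = sum(results$dipped_below_2),
    median_time_to_recovery =
      if (any(results$dipped_below_2)) stats::median(ttr, na.rm = TRUE) else NA_real_,
    median_nadir_depth = stats::median(results$nadir_depth),
    median_nadir_day = stats::median(results$nadir_day),
    fn_count = sum(results$febrile_neutropenia),
    censored_n = sum(results$dsn_censored)
  ), class = "arm_summary")
}

#' @export
print.arm_summary <- function(x, ...) {
  cat(sprintf("Arm %s (cycle %d): n=%d, DSN mean %.2f +/- %.2f days, median %.1f\n",
              x$arm, x$cycle, x$n, x$mean_dsn, x$sd_dsn, x$median_dsn))
  cat("  DSN frequency:",
      paste(sprintf("%s d: %d", names(x$dsn_frequency), x$dsn_frequency),
            collapse = ", "), "\n")
  cat(sprintf("  dipped <2.0: %d; median time to recovery %s d; FN: %d; censored: %d\n",
              x$n_dipped,
              ifelse(is.na(x$median_time_to_recovery), "-",
                     format(x$median_time_to_recovery)),
              x$fn_count, x$censored_n))
  invisible(x)
}

#' Per-arm endpoint summary table
#'
#' @param endpoints Data frame from [derive_endpoints()].
#' @param arms Optional arm ordering; defaults to order of first appearance.
#' @return Data frame, one row per arm, with the scalar [summarize_arm()]
#'   fields.
#' @export
arm_summary_table <- function(endpoints, arms = unique(endpoints$arm)) {
  rows <- lapply(arms, function(a) {
    s <- summarize_arm(endpoints[endpoints$arm == a, , drop = FALSE])
    data.frame(arm = s$arm, cycle = s$cycle, n = s$n,
               mean_dsn = s$mean_dsn, sd_dsn = s$sd_dsn,
               median_dsn = s$median_dsn, n_dipped = s$n_dipped,
               median_time_to_recovery = s$median_time_to_recovery,
               median_nadir_depth = s$median_nadir_depth,
               median_nadir_day = s$median_nadir_day,
               fn_count = s$fn_count, censored_n = s$censored_n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
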