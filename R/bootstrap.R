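# Weight-stratified bootstrap comparison of mean DSN between two arms.

#' Bootstrap specification
#'
#' @param n_resamples Number of bootstrap replicates (the trial design used
#'   10,000).
#' @param ci_level Two-sided confidence level for the percentile interval.
#' @param margin_days Noninferiority margin on the mean-DSN difference (days);
#'   noninferiority is declared when the CI upper limit is below it.
#' @param seed Integer seed for the resampling stream.
#' @return A `bootstrap_spec` list.
#' @export
bootstrap_spec <- function(n_resamples = 10000L, ci_level = 0.95,
                           margin_days = 1, seed = 1L) {
  stopifnot(n_resamples >= 1L, ci_level > 0, ci_level < 1, margin_days > 0)
  structure(list(n_resamples = as.integer(n_resamples), ci_level = ci_level,
                 margin_days = margin_days, seed = as.integer(seed)),
            class = "bootstrap_spec")
}

#' Stratified bootstrap resample differences in mean DSN
#'
#' Each replicate resamples patients with replacement within every
#' (arm x baseline-weight stratum) cell at its observed size, then records
#' `mean(exp*) - mean(ctrl*)`.  Stratum sizes are fixed at their observed
#' values, the standard meaning of a stratified bootstrap.
#'
#' @param exp,ctrl Data frames with columns `dsn` (numeric) and `stratum`
#'   (character) for the experimental and control arm.
#' @param spec A [bootstrap_spec()].
#' @return Numeric vector of `n_resamples` mean differences (days).
#' @export
stratified_resample_diffs <- function(exp, ctrl, spec = bootstrap_spec()) {
  for (df in list(exp, ctrl)) {
    if (!is.data.frame(df) || !all(c("dsn", "stratum") %in% names(df))) {
      stop("arms must be data frames with columns `dsn` and `stratum`")
    }
    if (nrow(df) == 0L) stop("empty arm: both arms must contain patients")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(spec$seed)

  B <- spec$n_resamples
  arm_mean_resamples <- function(df) {
    total <- numeric(B)
    for (s in sort(unique(df$stratum))) {   # sorted: order-independent stream
      x <- df$dsn[df$stratum == s]
      n <- length(x)
      idx <- sample.int(n, n * B, replace = TRUE)
      total <- total + colSums(matrix(x[idx], nrow = n))
    }
    total / nrow(df)
  }
  arm_mean_resamples(exp) - arm_mean_resamples(ctrl)
}

#' Percentile bootstrap confidence interval
#'
#' Empirical quantiles at `(1 - level)/2` and `1 - (1 - level)/2` of the
#' resampled differences, using linear interpolation between order statistics
#' (R quantile type 7), fixed so results are stable across platforms.
#'
#' @param diffs Numeric vector of resampled statistics.
#' @param level Two-sided confidence level in (0, 1).
#' @return Numeric vector `c(low, high)`.
#' @export
percentile_ci <- function(diffs, level = 0.95) {
  stopifnot(length(diffs) >= 1L, level > 0, level < 1)
  alpha <- (1 - level) / 2
  unname(stats::quantile(diffs, c(alpha, 1 - alpha), type = 7, names = FALSE))
}

#' Resampling-based noninferiority P-value
#'
#' Twice the proportion of resampled treatment differences strictly exceeding
#' the margin, capped at 1.  Ties with the margin count as not exceeding.
#'
#' @inheritParams percentile_ci
#' @param margin Noninferiority margin (days).
#' @return Probability in \[0, 1\].
#' @export
noninferiority_pvalue <- function(diffs, margin = 1) {
  stopifnot(length(diffs) >= 1L)
  min(1, 2 * mean(diffs > margin))
}

#' Resampling-based superiority P-value
#'
#' Twice the proportion of resampled treatment differences strictly exceeding
#' zero, capped at 1.
#'
#' @inheritParams percentile_ci
#' @return Probability in \[0, 1\].
#' @export
superiority_pvalue <- function(diffs) {
  stopifnot(length(diffs) >= 1L)
  min(1, 2 * mean(diffs > 0))
}

#' Compare an experimental arm with the control arm on mean DSN
#'
#' Chains endpoint derivation, the stratified bootstrap, the percentile CI,
#' both resampling P-values and the margin decision
#' (`noninferior <=> ci_high < margin_days`).
#'
#' @param cohort An `anc_cohort`.
#' @param exp_label,ctrl_label Arm labels present in the cohort.
#' @param cycle Cycle to analyse.
#' @param spec A [bootstrap_spec()].
#' @param endpoints Optional precomputed [derive_endpoints()] table for
#'   `cycle` (saves rederiving when comparing several arms).
#' @return A `dsn_comparison` list: sample sizes, arm means/SDs, `point_diff`,
#'   `ci_low`, `ci_high`, `p_noninferiority`, `p_superiority`, `noninferior`,
#'   the [bootstrap_spec()] settings, and `resample_diffs` retained for audit.
#' @export
compare_arms <- function(cohort, exp_label, ctrl_label, cycle = 1L,
                         spec = bootstrap_spec(), endpoints = NULL) {
  stopifnot(inherits(cohort, "anc_cohort"))
  arms <- unique(cohort$patients$arm)
  for (lab in c(exp_label, ctrl_label)) {
    if (!lab %in% arms) stop("unknown arm label: ", lab)
  }
  if (is.null(endpoints)) endpoints <- derive_endpoints(cohort, cycle = cycle)
  pick <- function(lab) {
    df <- endpoints[endpoints$arm == lab, , drop = FALSE]
    if (nrow(df) == 0L) stop("arm ", lab, " has no patients in cycle ", cycle)
    data.frame(dsn = df$dsn_days, stratum = df$stratum,
               stringsAsFactors = FALSE)
  }
  e <- pick(exp_label)
  c_ <- pick(ctrl_label)
  diffs <- stratified_resample_diffs(e, c_, spec)
  ci <- percentile_ci(diffs, spec$ci_level)
  structure(list(
    exp_label = exp_label, ctrl_label = ctrl_label, cycle = cycle,
    n_exp = nrow(e), n_ctrl = nrow(c_),
    mean_exp = mean(e$dsn), mean_ctrl = mean(c_$dsn),
    sd_exp = if (nrow(e) > 1L) stats::sd(e$dsn) else 0,
    sd_ctrl = if (nrow(c_) > 1L) stats::sd(c_$dsn) else 0,
    point_diff = mean(e$dsn) - mean(c_$dsn),
    ci_low = ci[1L], ci_high = ci[2L], ci_level = spec$ci_level,
    p_noninferiority = noninferiority_pvalue(diffs, spec$margin_days),
    p_superiority = superiority_pvalue(diffs),
    noninferior = ci[2L] < spec$margin_days,
    margin_days = spec$margin_days, n_resamples = spec$n_resamples,
    seed = spec$seed, resample_diffs = diffs
  ), class = "dsn_comparison")
}

#' @export
print.dsn_comparison <- function(x, ...) {
  cat(sprintf("DSN comparison, cycle %d: %s (n=%d) vs %s (n=%d)\n",
              x$cycle, x$exp_label, x$n_exp, x$ctrl_label, x$n_ctrl))
  cat(sprintf("  mean DSN %.2f vs %.2f; difference %.2f days, %d%% CI (%.2f, %.2f)\n",
              x$mean_exp, x$mean_ctrl, x$point_diff,
              round(100 * x$ci_level), x$ci_low, x$ci_high))
  cat(sprintf("  P(noninferiority) = %.3f, P(superiority) = %.3f; %s (margin %g day)\n",
              x$p_noninferiority, x$p_superiority,
              if (x$noninferior) "NONINFERIOR" else "noninferiority NOT shown",
              x$margin_days))
  cat(sprintf("  [%d stratified resamples, seed %d]\n", x$n_resamples, x$seed))
  invisible(x)
}
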