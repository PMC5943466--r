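# Planning computations for the noninferiority design: normal-approximation
# power, simulation-based power, and minimal sample sizes.

#' Noninferiority design specification
#'
#' Defaults are the trial's planning assumptions: pooled DSN standard
#' deviation 2.1 days (from prior pegfilgrastim studies), 1-day margin,
#' one-sided alpha 0.05, and a pooled experimental arm of 108 vs 36 controls
#' (total 144 at 3:1 allocation).
#'
#' @param sd_dsn Assumed common SD of Cycle-1 DSN (days).
#' @param margin Noninferiority margin (days).
#' @param one_sided_alpha One-sided alpha of the upper confidence limit.
#' @param n_experimental Pooled experimental-arm size.
#' @param n_control Control-arm size.
#' @param n_sim Number of simulated trials for [power_simulated()].
#' @param seed Integer seed for the simulation.
#' @return A `design_spec` list.
#' @export
design_spec <- function(sd_dsn = 2.1, margin = 1, one_sided_alpha = 0.05,
                        n_experimental = 108L, n_control = 36L,
                        n_sim = 10000L, seed = 1L) {
  stopifnot(sd_dsn > 0, margin > 0,
            one_sided_alpha > 0, one_sided_alpha < 0.5,
            n_experimental >= 2L, n_control >= 2L, n_sim >= 1L)
  structure(list(sd_dsn = sd_dsn, margin = margin,
                 one_sided_alpha = one_sided_alpha,
                 n_experimental = as.integer(n_experimental),
                 n_control = as.integer(n_control),
                 n_sim = as.integer(n_sim), seed = as.integer(seed)),
            class = "design_spec")
}

#' Analytic power to establish noninferiority
#'
#' Normal-approximation (known-variance) power at true mean difference 0:
#' success is the one-sided `(1 - alpha)` upper confidence limit of the mean
#' DSN difference falling below the margin, giving
#' `Phi(margin / (sd * sqrt(1/nE + 1/nC)) - z_(1-alpha))`.
#'
#' @param spec A [design_spec()].
#' @return Probability in (0, 1).
#' @export
power_analytic <- function(spec = design_spec()) {
  stopifnot(inherits(spec, "design_spec"))
  se <- spec$sd_dsn * sqrt(1 / spec$n_experimental + 1 / spec$n_control)
  stats::pnorm(spec$margin / se - stats::qnorm(1 - spec$one_sided_alpha))
}

#' Simulated power to establish noninferiority
#'
#' Simulates `n_sim` trials with normally distributed DSN (common SD, true
#' difference 0) and counts those whose one-sided `(1 - alpha)` upper
#' confidence limit of the mean difference is below the margin.  By default
#' the limit uses the pooled estimated SD with a t critical value — the
#' criterion an actual analysis would apply — quantifying the gap from the
#' known-variance analytic formula; `sd_known = TRUE` swaps in the true SD
#' and the normal critical value, matching [power_analytic()]'s assumptions.
#'
#' @inheritParams power_analytic
#' @param sd_known Use the known-variance z criterion instead of the
#'   estimated-SD t criterion.
#' @return Fraction of simulated trials concluding noninferiority, with
#'   attribute `mc_se` (binomial Monte-Carlo standard error).
#' @export
power_simulated <- function(spec = design_spec(), sd_known = FALSE) {
  stopifnot(inherits(spec, "design_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(spec$seed)

  B <- spec$n_sim
  nE <- spec$n_experimental
  nC <- spec$n_control
  xE <- matrix(stats::rnorm(B * nE, 0, spec$sd_dsn), nrow = B)
  xC <- matrix(stats::rnorm(B * nC, 0, spec$sd_dsn), nrow = B)
  mE <- rowMeans(xE)
  mC <- rowMeans(xC)
  if (sd_known) {
    crit <- stats::qnorm(1 - spec$one_sided_alpha)
    sdev <- spec$sd_dsn
  } else {
    crit <- stats::qt(1 - spec$one_sided_alpha, df = nE + nC - 2L)
    sdev <- sqrt((rowSums((xE - mE)^2) + rowSums((xC - mC)^2)) / (nE + nC - 2L))
  }
  upper <- (mE - mC) + crit * sdev * sqrt(1 / nE + 1 / nC)
  p <- mean(upper < spec$margin)
  structure(p, mc_se = sqrt(p * (1 - p) / B))
}

#' Minimal sample sizes achieving a target noninferiority power
#'
#' Starts from the closed-form solution
#' `1/nE + 1/nC <= (margin / (sd * (z_(1-alpha) + z_target)))^2` at the given
#' experimental:control allocation ratio, then trims each arm down greedily
#' while [power_analytic()] stays at or above the target, so that
#' decrementing either arm drops the power below it.
#'
#' @param target_power Required power in (alpha-level, 1).
#' @param allocation_ratio `n_experimental / n_control`.
#' @inheritParams design_spec
#' @return List `n_experimental`, `n_control`, `total`, `achieved_power`.
#' @export
required_n <- function(target_power = 0.80, allocation_ratio = 3,
                       sd_dsn = 2.1, margin = 1, one_sided_alpha = 0.05) {
  stopifnot(target_power > 0, target_power < 1, allocation_ratio > 0)
  z <- stats::qnorm(1 - one_sided_alpha) + stats::qnorm(target_power)
  if (!is.finite(z) || z <= 0) stop("unreachable power target")
  cap <- (margin / (sd_dsn * z))^2   # bound on 1/nE + 1/nC
  nC <- max(2L, as.integer(ceiling((1 + 1 / allocation_ratio) / cap)))
  nE <- max(2L, as.integer(ceiling(allocation_ratio * nC)))
  pw <- function(nE, nC) power_analytic(design_spec(
    sd_dsn = sd_dsn, margin = margin, one_sided_alpha = one_sided_alpha,
    n_experimental = nE, n_control = nC))
  if (pw(nE, nC) < target_power) stop("power target unreachable at these sizes")
  repeat {
    if (nE > 2L && pw(nE - 1L, nC) >= target_power) {
      nE <- nE - 1L
    } else if (nC > 2L && pw(nE, nC - 1L) >= target_power) {
      nC <- nC - 1L
    } else break
  }
  list(n_experimental = nE, n_control = nC, total = nE + nC,
       achieved_power = pw(nE, nC))
}
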