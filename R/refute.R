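# Refutation tests: robustness checks that probe whether the causal
# estimate behaves as a genuine interventional quantity should.
# - random common cause: adding an independent random covariate to the
#   adjustment set must leave the estimate essentially unchanged;
# - placebo treatment: replacing the treatments with independent random
#   variables (permutations of the observed columns, preserving their
#   marginal distributions) must drive the estimate to zero;
# - data subset: the estimate must be stable under re-estimation on random
#   subsets of the data.
# Pass thresholds are conventions of this package (the source analyses
# report the checks without numeric criteria) and are configurable.

.refutation_result <- function(refuter, original, reps, pass, criterion,
                               seed, extra = list()) {
  structure(c(list(refuter = refuter, original = original,
                   refuted = mean(reps), reps = reps, n_rep = length(reps),
                   mc_se = if (length(reps) > 1) stats::sd(reps) / sqrt(length(reps))
                           else NA_real_,
                   pass = pass, criterion = criterion, seed = seed),
              extra),
            class = "refutation_result")
}

#' @export
print.refutation_result <- function(x, ...) {
  cat(sprintf("Refuter '%s': original %.3f, refuted %.3f (n_rep = %d)\n",
              x$refuter, x$original, x$refuted, x$n_rep))
  cat(sprintf("  criterion: %s\n  pass: %s\n", x$criterion,
              if (isTRUE(x$pass)) "yes" else if (isFALSE(x$pass)) "NO" else "NA"))
  invisible(x)
}

.original_effect <- function(data, estimand) {
  .effect_scalar(estimate_effect(data, estimand))
}

#' Refutation: add a random common cause
#'
#' Per repetition, an independent standard-Gaussian covariate is appended
#' to the adjustment set and the effect re-estimated. A sound estimate is
#' essentially unchanged; the test passes when the mean refuted effect is
#' within `tolerance` (default 10%) relative change of the original.
#'
#' @param data An `embryo_data` data frame.
#' @param estimand An [identify_backdoor()] result.
#' @param n_rep Number of repetitions (`>= 1`).
#' @param seed Base seed; repetition seeds are derived by counter.
#' @param tolerance Maximum relative change to pass.
#' @return A `refutation_result`.
#' @export
refute_random_common_cause <- function(data, estimand, n_rep = 100, seed = 1L,
                                       tolerance = 0.1) {
  if (n_rep < 1) stop_("n_rep must be >= 1")
  original <- .original_effect(data, estimand)
  estimand2 <- estimand
  estimand2$adjustment_set <- c(estimand$adjustment_set, ".random_cc")
  reps <- vapply(seq_len(n_rep), function(r) with_seed(rep_seed(seed, r), {
    d <- data
    d$.random_cc <- stats::rnorm(nrow(d))
    .effect_scalar(estimate_effect(d, estimand2, drop_collinear = TRUE))
  }), numeric(1))
  refuted <- mean(reps)
  rel <- abs(refuted - original) / max(abs(original), .Machine$double.eps)
  .refutation_result("random_common_cause", original, reps,
                     pass = rel <= tolerance,
                     criterion = sprintf("relative change %.3g <= %g", rel, tolerance),
                     seed = seed)
}

#' Refutation: placebo treatment
#'
#' Per repetition, every treatment column is replaced by an independent
#' random permutation of itself (an independent variable with the same
#' marginal distribution) and the effect re-estimated. Under a genuine
#' causal effect the placebo estimate should be statistically
#' indistinguishable from zero: the test passes when the mean refuted
#' effect is within 2 Monte-Carlo standard errors of 0.
#'
#' @inheritParams refute_random_common_cause
#' @return A `refutation_result` (with `n_rep = 1` the Monte-Carlo SE, and
#'   hence the pass flag, is `NA`).
#' @export
refute_placebo_treatment <- function(data, estimand, n_rep = 100, seed = 1L) {
  if (n_rep < 1) stop_("n_rep must be >= 1")
  original <- .original_effect(data, estimand)
  tcols <- var_column(estimand$treatments)
  reps <- vapply(seq_len(n_rep), function(r) with_seed(rep_seed(seed, r), {
    d <- data
    for (cl in tcols) d[[cl]] <- sample(d[[cl]])
    .effect_scalar(estimate_effect(d, estimand))
  }), numeric(1))
  mc_se <- if (n_rep > 1) stats::sd(reps) / sqrt(n_rep) else NA_real_
  pass <- if (is.na(mc_se)) NA else abs(mean(reps)) <= 2 * mc_se
  .refutation_result("placebo_treatment", original, reps, pass = pass,
                     criterion = sprintf("|mean refuted| = %.3g <= 2 x MC SE = %.3g",
                                         abs(mean(reps)), 2 * mc_se),
                     seed = seed)
}

#' Refutation: re-estimate on data subsets
#'
#' Per repetition, a uniformly random fraction of the embryos is dropped
#' and the effect re-estimated. The test passes when the original estimate
#' lies within the 2.5--97.5% band of the refuted effects.
#'
#' @inheritParams refute_random_common_cause
#' @param drop_fraction Fraction of rows to drop, in (0, 1).
#' @return A `refutation_result` with the quantile `band` attached.
#' @export
refute_data_subset <- function(data, estimand, drop_fraction = 0.2,
                               n_rep = 100, seed = 1L) {
  if (n_rep < 1) stop_("n_rep must be >= 1")
  if (!is.numeric(drop_fraction) || drop_fraction <= 0 || drop_fraction >= 1)
    stop_("drop_fraction must be in (0, 1)")
  n <- nrow(data)
  n_keep <- n - floor(drop_fraction * n)
  p <- 1L + length(estimand$treatments) + length(estimand$adjustment_set)
  if (n_keep <= p)
    stop_("remaining sample (%d) too small for %d coefficients", n_keep, p)
  original <- .original_effect(data, estimand)
  reps <- vapply(seq_len(n_rep), function(r) with_seed(rep_seed(seed, r), {
    idx <- sample(n, n_keep)
    .effect_scalar(estimate_effect(data[idx, , drop = FALSE], estimand))
  }), numeric(1))
  band <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  pass <- original >= band[1] && original <= band[2]
  .refutation_result("data_subset", original, reps, pass = pass,
                     criterion = sprintf("original within refuted [%.3f, %.3f] band",
                                         band[1], band[2]),
                     seed = seed, extra = list(band = band,
                                               drop_fraction = drop_fraction))
}
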