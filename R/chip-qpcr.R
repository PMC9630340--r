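# ChIP-qPCR percent-input quantification and antibody-vs-IgG enrichment
# tests.

#' Percent input from ChIP-qPCR Ct values
#'
#' Computes `%Input = 2^(-dCt[normalized ChIP]) x 100` with
#' `dCt[normalized ChIP] = Ct[ChIP] - (Ct[Input] - log2(dilution factor))`,
#' the input dilution factor defaulting to 10. With numeric inputs the
#' percentages are returned directly; with a Ct table (columns `region`,
#' `antibody`, `replicate`, `ct_chip`, `ct_input`, `dilution_factor`) a
#' per-replicate table with `delta_ct_normalized` and `percent` columns is
#' returned.
#'
#' @param x Numeric vector of ChIP Ct values, or a Ct table data frame.
#' @param ... Passed to methods.
#' @return Numeric percentages, or a `percent_input` data frame.
#' @export
percent_input <- function(x, ...) UseMethod("percent_input")

.check_ct <- function(ct, label) {
  if (any(!is.finite(ct) | ct <= 0 | ct >= 45))
    stop_("%s values must lie in the plausible cycle range (0, 45)", label)
}

#' @rdname percent_input
#' @param ct_input Numeric input-sample Ct values.
#' @param dilution_factor Positive input dilution factor (default 10).
#' @export
percent_input.numeric <- function(x, ct_input, dilution_factor = 10, ...) {
  if (any(dilution_factor <= 0)) stop_("dilution_factor must be > 0")
  .check_ct(x, "ct_chip"); .check_ct(ct_input, "ct_input")
  # algebraically 2^(-dCt[normalized]) x 100 with
  # dCt[normalized] = ct_chip - (ct_input - log2(dilution)); this form is
  # exact for integer Ct differences and power-of-two-free dilutions
  2^(-(x - ct_input)) / dilution_factor * 100
}

#' @rdname percent_input
#' @export
percent_input.data.frame <- function(x, ...) {
  require_columns(x, c("region", "antibody", "replicate", "ct_chip",
                       "ct_input", "dilution_factor"), "Ct table")
  if (any(x$dilution_factor <= 0)) stop_("dilution_factor must be > 0")
  .check_ct(x$ct_chip, "ct_chip"); .check_ct(x$ct_input, "ct_input")
  delta <- x$ct_chip - (x$ct_input - log2(x$dilution_factor))
  out <- data.frame(region = x$region, antibody = x$antibody,
                    replicate = x$replicate,
                    delta_ct_normalized = delta,
                    percent = 2^(-(x$ct_chip - x$ct_input)) /
                      x$dilution_factor * 100)
  class(out) <- c("percent_input", "data.frame")
  out
}

#' Significance stars
#'
#' `ns` for p >= 0.05, `*` for p < 0.05, `**` for p < 0.01, `***` for
#' p < 0.001.
#'
#' @param p Numeric p-values.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Compare antibody %input against the IgG control
#'
#' Two-sample two-sided t-test on percent-input values, Student
#' (equal-variance) by default to match the usual spreadsheet-software
#' convention, Welch by option. With the minimal two replicates per group
#' the test runs but carries a low-power warning. Degenerate inputs with
#' zero pooled variance are handled by convention: equal means give
#' `t = 0, p = 1`; unequal means give `|t| = Inf, p = 0`.
#'
#' @param percents_ab Numeric %input values for the specific antibody.
#' @param percents_igg Numeric %input values for the IgG control.
#' @param var_equal Use the pooled-variance Student t-test (default) or
#'   Welch when `FALSE`.
#' @param region,antibody Optional labels carried into the result.
#' @return Object of class `enrichment_test`: `mean_diff`, `t`, `df`, `p`,
#'   `stars`, group sizes and labels.
#' @export
compare_to_igg <- function(percents_ab, percents_igg, var_equal = TRUE,
                           region = NA_character_, antibody = NA_character_) {
  if (length(percents_ab) < 2L || length(percents_igg) < 2L)
    stop_("at least 2 replicates are required per group")
  if (length(percents_ab) == 2L && length(percents_igg) == 2L)
    warn_("n = 2 replicates per group: the t-test has very low power")
  diff <- mean(percents_ab) - mean(percents_igg)
  if (stats::var(percents_ab) == 0 && stats::var(percents_igg) == 0) {
    df <- length(percents_ab) + length(percents_igg) - 2L
    tt <- list(statistic = if (diff == 0) 0 else sign(diff) * Inf,
               parameter = df, p.value = if (diff == 0) 1 else 0)
  } else {
    ht <- stats::t.test(percents_ab, percents_igg, var.equal = var_equal)
    tt <- list(statistic = unname(ht$statistic), parameter = unname(ht$parameter),
               p.value = ht$p.value)
  }
  structure(list(region = region, antibody = antibody, mean_diff = diff,
                 t = tt$statistic, df = tt$parameter, p = tt$p.value,
                 stars = significance_stars(tt$p.value),
                 n_ab = length(percents_ab), n_igg = length(percents_igg),
                 method = if (var_equal) "Student" else "Welch"),
            class = "enrichment_test")
}

#' @export
print.enrichment_test <- function(x, ...) {
  cat(sprintf("%s t-test%s: mean diff %.3g %%input, t = %.3g (df %.3g), p = %.3g [%s]\n",
              x$method,
              if (!is.na(x$region)) sprintf(" (%s, %s vs IgG)", x$region, x$antibody) else "",
              x$mean_diff, x$t, x$df, x$p, x$stars))
  invisible(x)
}

#' Enrichment tests for a whole %input table
#'
#' For each region, compares each non-control antibody's replicates
#' against the IgG control's. No multiple-testing correction is applied by
#' default; Bonferroni is available.
#'
#' @param percents A `percent_input` data frame (or Ct table, converted
#'   on the fly).
#' @param igg_pattern Regular expression identifying the control antibody.
#' @param var_equal See [compare_to_igg()].
#' @param p_adjust `"none"` (default) or `"bonferroni"`.
#' @return Data frame with one row per (region, antibody) comparison.
#' @export
test_enrichment <- function(percents, igg_pattern = "IgG", var_equal = TRUE,
                            p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  if (!inherits(percents, "percent_input")) percents <- percent_input(percents)
  is_igg <- grepl(igg_pattern, percents$antibody, ignore.case = TRUE)
  if (!any(is_igg)) stop_("no IgG control rows match pattern '%s'", igg_pattern)
  rows <- list()
  for (rg in unique(percents$region)) {
    sub <- percents[percents$region == rg, ]
    igg <- sub$percent[grepl(igg_pattern, sub$antibody, ignore.case = TRUE)]
    for (ab in setdiff(unique(sub$antibody),
                       unique(sub$antibody[grepl(igg_pattern, sub$antibody,
                                                 ignore.case = TRUE)]))) {
      et <- compare_to_igg(sub$percent[sub$antibody == ab], igg,
                           var_equal = var_equal, region = rg, antibody = ab)
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, antibody = ab, mean_diff = et$mean_diff, t = et$t,
        df = et$df, p = et$p)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  out$stars <- significance_stars(out$p_adj)
  rownames(out) <- NULL
  out
}

#' Simulate a ChIP-qPCR Ct table with known enrichment
#'
#' Inverts the percent-input formula: given a true %input per (region,
#' antibody), `Ct[ChIP] = Ct[Input] - log2(dilution) - log2(%input/100)`,
#' plus optional Gaussian Ct noise. At zero noise the round trip through
#' [percent_input()] is exact.
#'
#' @param true_percent Data frame with columns `region`, `antibody`,
#'   `percent` (> 0).
#' @param dilution_factor Positive input dilution factor (default 10).
#' @param noise_sd Gaussian SD added to the ChIP Ct values (cycles).
#' @param n_replicates Replicates per (region, antibody), `>= 2`.
#' @param ct_input Input-sample Ct value (cycles).
#' @param seed Integer seed.
#' @return A Ct table data frame (class `ct_table`).
#' @export
simulate_ct_table <- function(true_percent, dilution_factor = 10, noise_sd = 0,
                              n_replicates = 2L, ct_input = 20, seed = 1L) {
  require_columns(true_percent, c("region", "antibody", "percent"),
                  "true_percent")
  if (any(true_percent$percent <= 0)) stop_("true percent values must be > 0")
  if (dilution_factor <= 0) stop_("dilution_factor must be > 0")
  if (noise_sd < 0) stop_("noise_sd must be >= 0")
  if (n_replicates < 2L) stop_("n_replicates must be >= 2")
  grid <- true_percent[rep(seq_len(nrow(true_percent)), each = n_replicates), ]
  grid$replicate <- rep(seq_len(n_replicates), times = nrow(true_percent))
  ct_chip <- ct_input - log2(dilution_factor) - log2(grid$percent / 100)
  if (noise_sd > 0)
    ct_chip <- ct_chip + with_seed(seed, stats::rnorm(length(ct_chip), 0, noise_sd))
  out <- data.frame(region = grid$region, antibody = grid$antibody,
                    replicate = grid$replicate, ct_chip = ct_chip,
                    ct_input = ct_input, dilution_factor = dilution_factor)
  class(out) <- c("ct_table", "data.frame")
  out
}
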