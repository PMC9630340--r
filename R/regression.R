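# Multiple linear regression by maximum likelihood (equivalently ordinary
# least squares under Gaussian noise), with coefficient t-tests. Fitting is
# done via a QR decomposition of the design matrix; standard errors use the
# unbiased residual-variance estimator (n - p degrees of freedom), which the
# coefficient t-tests require even though the pure-ML variance would divide
# by n.

#' Ordinary least squares with coefficient t-tests
#'
#' Fits `y = X b + e` by QR decomposition and reports, per coefficient, the
#' estimate, standard error, t statistic and two-sided p-value from the t
#' distribution on `n - p` degrees of freedom. In an exact (zero-residual)
#' fit the standard errors are 0 and t/p are `NA`.
#'
#' @param X Design matrix (or data frame), including any intercept column.
#' @param y Numeric response.
#' @return Object of class `ols_fit`: `coefficients`, `standard_errors`,
#'   `t_stats`, `p_values` (named by column), `residuals`,
#'   `residual_variance`, `df_residual`, `n_obs`, `log_likelihood`,
#'   `vcov` and the gene label (when fitted through [fit_full_model()]).
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_("length(y) (%d) != nrow(X) (%d)", length(y), n)
  if (n <= p) stop_("n_obs (%d) must exceed the number of coefficients (%d)", n, p)
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop_("singular design matrix; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qx, y)
  res <- as.numeric(y - X %*% coefs)
  rss <- sum(res^2)
  df <- n - p
  sigma2 <- rss / df
  # (X'X)^{-1} from the R factor, undoing any column pivoting
  Rinv <- backsolve(qr.R(qx), diag(p))
  xtx_inv_piv <- tcrossprod(Rinv)
  piv <- qx$pivot
  xtx_inv <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  xtx_inv[piv, piv] <- xtx_inv_piv
  vc <- sigma2 * xtx_inv
  se <- sqrt(diag(vc))
  t_stats <- ifelse(se > 0, coefs / se, NA_real_)
  p_values <- ifelse(se > 0, 2 * stats::pt(-abs(coefs / se), df), NA_real_)
  # Gaussian maximum likelihood at the ML variance rss/n
  loglik <- if (rss > 0) -n / 2 * (log(2 * pi) + log(rss / n) + 1) else Inf
  structure(list(coefficients = coefs, standard_errors = se,
                 t_stats = t_stats, p_values = p_values,
                 residuals = res, residual_variance = sigma2,
                 df_residual = df, n_obs = n, log_likelihood = loglik,
                 vcov = vc, gene = NULL),
            class = "ols_fit")
}

#' @export
coef.ols_fit <- function(object, ...) object$coefficients

#' @export
vcov.ols_fit <- function(object, ...) object$vcov

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("Linear model fit%s: n = %d, residual SD = %.4g\n",
              if (!is.null(x$gene)) paste0(" for ", x$gene) else "",
              x$n_obs, sqrt(x$residual_variance)))
  cm <- cbind(Estimate = x$coefficients, `Std. Error` = x$standard_errors,
              `t value` = x$t_stats, `Pr(>|t|)` = x$p_values)
  stats::printCoefmat(cm, P.values = TRUE, has.Pvalue = TRUE, na.print = "NA")
  invisible(x)
}

#' @export
as.data.frame.ols_fit <- function(x, ...) {
  data.frame(gene = x$gene %||% NA_character_,
             factor = names(x$coefficients),
             coefficient = unname(x$coefficients),
             se = unname(x$standard_errors),
             t = unname(x$t_stats),
             p = unname(x$p_values), row.names = NULL)
}

.model_matrix <- function(data, factors, response) {
  require_columns(data, c(var_column(factors), var_column(response)))
  X <- cbind(intercept = 1,
             do.call(cbind, stats::setNames(
               lapply(var_column(factors), function(cl) as.numeric(data[[cl]])),
               factors)))
  list(X = X, y = as.numeric(data[[var_column(response)]]))
}

.check_binary_varies <- function(data, factors) {
  for (f in setdiff(factors, "time")) {
    v <- data[[var_column(f)]]
    if (length(unique(v)) < 2L)
      stop_("factor column %s is constant in the data; the design is singular",
            var_column(f))
  }
}

#' Fit the full regression model for one gene
#'
#' Regresses the gene's intensity on the maternal Eomesa indicator, the
#' Hwa/beta-catenin indicator, the Nodal/Smad2 indicator and developmental
#' time (hpf), plus an intercept.
#'
#' @param data An `embryo_data` data frame.
#' @param gene `"ndr1"` or `"ndr2"`.
#' @return An `ols_fit` with coefficients named `intercept`, `eomesa`,
#'   `bcatenin`, `smad2`, `time`.
#' @export
fit_full_model <- function(data, gene = c("ndr1", "ndr2")) {
  gene <- match.arg(gene)
  .check_binary_varies(data, FACTOR_VARS)
  mm <- .model_matrix(data, FACTOR_VARS, gene)
  fit <- fit_ols(mm$X, mm$y)
  fit$gene <- gene
  fit
}

#' Per-timepoint regression fits
#'
#' Fits the time-free model (intercept + three binary factors) separately
#' within each developmental stage, yielding the coefficient trajectories
#' plotted against stage. Stages with too few embryos, or where a factor
#' does not vary, are skipped with a warning rather than aborting the
#' analysis.
#'
#' @param data An `embryo_data` data frame.
#' @param gene `"ndr1"` or `"ndr2"`.
#' @return Object of class `timepoint_fits`: list with `gene` and `fits`,
#'   a stage-named list of `ols_fit`s in increasing stage order.
#' @export
fit_per_timepoint <- function(data, gene = c("ndr1", "ndr2")) {
  gene <- match.arg(gene)
  require_columns(data, "time_hpf")
  stages <- sort(unique(data$time_hpf))
  factors <- setdiff(FACTOR_VARS, "time")
  p <- length(factors) + 1L
  fits <- list()
  for (tp in stages) {
    sub <- data[data$time_hpf == tp, , drop = FALSE]
    if (nrow(sub) < p + 1L) {
      warn_("stage %g hpf skipped: %d embryos (< %d required)", tp, nrow(sub), p + 1L)
      next
    }
    fit <- tryCatch({
      .check_binary_varies(sub, factors)
      mm <- .model_matrix(sub, factors, gene)
      f <- fit_ols(mm$X, mm$y)
      f$gene <- gene
      f
    }, error = function(e) {
      warn_("stage %g hpf skipped: %s", tp, conditionMessage(e))
      NULL
    })
    if (!is.null(fit)) fits[[as.character(tp)]] <- fit
  }
  structure(list(gene = gene, fits = fits), class = "timepoint_fits")
}

#' @export
print.timepoint_fits <- function(x, ...) {
  cat(sprintf("Per-timepoint fits for %s at %d stage(s): %s hpf\n", x$gene,
              length(x$fits), paste(names(x$fits), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.timepoint_fits <- function(x, ...) {
  do.call(rbind, lapply(names(x$fits), function(tp) {
    d <- as.data.frame(x$fits[[tp]])
    cbind(d[, "gene", drop = FALSE], stage = as.numeric(tp),
          d[, c("factor", "coefficient", "se", "t", "p")])
  }))
}

#' Relative contribution of factors across stages
#'
#' At each stage the contribution share of a factor is its absolute
#' per-stage coefficient divided by the sum of absolute coefficients over
#' the requested factors (the binary indicators share a common 0/1 scale,
#' making their coefficients directly comparable). Shares sum to one at
#' each stage. Note coefficients themselves are often displayed scaled
#' down by 1000 (see attribute `display_scale`); shares are scale-free.
#'
#' @param fits A [fit_per_timepoint()] result.
#' @param factors Factors to include (default the three binary factors);
#'   the intercept is not allowed.
#' @return Data frame of class `contribution_profile` with columns
#'   `gene`, `time_hpf`, `factor`, `coefficient`, `share`.
#' @export
relative_contributions <- function(fits,
                                   factors = c("eomesa", "bcatenin", "smad2")) {
  if (!inherits(fits, "timepoint_fits")) stop_("fits must be a timepoint_fits object")
  if ("intercept" %in% factors) stop_("the intercept has no contribution share")
  out <- lapply(names(fits$fits), function(tp) {
    co <- stats::coef(fits$fits[[tp]])
    missing <- setdiff(factors, names(co))
    if (length(missing))
      stop_("factor(s) %s not in the stage-%s fit", paste(missing, collapse = ", "), tp)
    a <- abs(co[factors])
    tot <- sum(a)
    if (tot == 0)
      stop_("all requested coefficients are zero at stage %s hpf; shares undefined", tp)
    data.frame(gene = fits$gene, time_hpf = as.numeric(tp), factor = factors,
               coefficient = unname(co[factors]), share = unname(a / tot))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "display_scale") <- 1e-3  # coefficients shown x 1e-3 in figures
  class(out) <- c("contribution_profile", "data.frame")
  out
}

#' Construct a variable screen
#'
#' Partition of the candidate factors into treatment variables and common
#' causes for one outcome gene.
#'
#' @param treatments,common_causes Disjoint character vectors covering the
#'   candidate factors.
#' @param threshold Screening p-value threshold the partition was derived
#'   with (informational).
#' @param gene Outcome gene label.
#' @param p_values Optional named p-values backing the partition.
#' @return Object of class `variable_screen`.
#' @export
variable_screen <- function(treatments, common_causes, threshold = 0.2,
                            gene = NULL, p_values = NULL) {
  if (length(intersect(treatments, common_causes)))
    stop_("treatments and common_causes must be disjoint")
  if (!setequal(union(treatments, common_causes), FACTOR_VARS))
    stop_("treatments and common_causes must together cover: %s",
          paste(FACTOR_VARS, collapse = ", "))
  structure(list(gene = gene, treatments = treatments,
                 common_causes = common_causes, threshold = threshold,
                 p_values = p_values),
            class = "variable_screen")
}

#' Screen candidate factors into treatments and common causes
#'
#' A factor whose full-model coefficient has p-value strictly greater than
#' the threshold is deemed to have no significant direct effect on the
#' outcome and is classified as a candidate common cause; the rest are
#' treatment variables. Time is always retained as a treatment variable.
#' The boundary `p == threshold` classifies as treatment (strict ">").
#'
#' @param fit An `ols_fit` from [fit_full_model()].
#' @param threshold Screening threshold on the coefficient p-value
#'   (default 0.2).
#' @return A [variable_screen()] object.
#' @export
screen_variables <- function(fit, threshold = 0.2) {
  if (!inherits(fit, "ols_fit")) stop_("fit must be an ols_fit")
  candidates <- setdiff(names(stats::coef(fit)), c("intercept", "time"))
  p <- fit$p_values[candidates]
  if (anyNA(p))
    stop_("missing p-value for factor(s): %s",
          paste(candidates[is.na(p)], collapse = ", "))
  common <- candidates[p > threshold]
  treatments <- c(setdiff(candidates, common),
                  intersect("time", names(stats::coef(fit))))
  variable_screen(treatments = treatments, common_causes = common,
                  threshold = threshold, gene = fit$gene, p_values = p)
}

#' @export
print.variable_screen <- function(x, ...) {
  cat(sprintf("Variable screen%s (p > %g -> common cause):\n",
              if (!is.null(x$gene)) paste0(" for ", x$gene) else "", x$threshold))
  cat("  treatments:   ", paste(x$treatments, collapse = ", "), "\n")
  cat("  common causes:", if (length(x$common_causes))
    paste(x$common_causes, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
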