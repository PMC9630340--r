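# Causal graphical model and backdoor-adjusted effect estimation.
#
# The graph follows the study's structure: screened common causes (plus the
# other nodal gene measured in the same embryo) point into both the
# treatment variables and the outcome; treatments point into the outcome.
# With all common causes observed, the backdoor criterion identifies the
# interventional contrast E[Y|do(X=1)] - E[Y|do(X=0)] as the W-averaged
# conditional contrast, which a linear outcome model estimates as the
# treatment coefficient(s) of the regression of Y on treatments and W.

#' Build the causal graphical model for one outcome gene
#'
#' Nodes are the outcome gene, the screened treatment variables, and the
#' common causes; the other nodal gene (measured in the same embryo by
#' double FISH) is always added as a common cause. Edges: each common
#' cause into every treatment and into the outcome; each treatment into
#' the outcome. For the default screens this yields, for ndr1, treatments
#' {bcatenin, smad2, time} with common causes {eomesa, ndr2}, and the
#' symmetric structure for ndr2.
#'
#' @param screen A [variable_screen()].
#' @param outcome `"ndr1"` or `"ndr2"`.
#' @param extra_edges Optional data frame of additional directed edges
#'   (`from`, `to`); rejected if they create a cycle or leave the outcome
#'   with outgoing edges.
#' @param include_other_gene Add the companion gene to the common causes
#'   (default `TRUE`, the study's structure).
#' @return Object of class `causal_graph`: `outcome`, `treatments`,
#'   `common_causes`, `edges`, and an igraph representation `igraph`.
#' @export
build_causal_graph <- function(screen, outcome = c("ndr1", "ndr2"),
                               extra_edges = NULL, include_other_gene = TRUE) {
  outcome <- match.arg(outcome)
  if (!inherits(screen, "variable_screen")) stop_("screen must be a variable_screen")
  treatments <- screen$treatments
  if (outcome %in% treatments)
    stop_("outcome %s cannot be one of the treatments", outcome)
  common <- unique(c(screen$common_causes,
                     if (include_other_gene) setdiff(GENES, outcome)))
  edges <- rbind(
    if (length(common))
      expand.grid(from = common, to = c(treatments, outcome),
                  KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    data.frame(from = treatments, to = outcome))
  if (!is.null(extra_edges)) {
    require_columns(extra_edges, c("from", "to"), "extra_edges")
    edges <- unique(rbind(edges, extra_edges[, c("from", "to")]))
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  if (!igraph::is_dag(g)) stop_("edge set is cyclic; a causal graph must be acyclic")
  if (igraph::degree(g, v = outcome, mode = "out") != 0)
    stop_("the outcome node must have no outgoing edges")
  structure(list(outcome = outcome, treatments = treatments,
                 common_causes = common, edges = edges, igraph = g),
            class = "causal_graph")
}

#' @export
print.causal_graph <- function(x, ...) {
  cat(sprintf("Causal graph for outcome %s\n", x$outcome))
  cat("  treatments:   ", paste(x$treatments, collapse = ", "), "\n")
  cat("  common causes:", if (length(x$common_causes))
    paste(x$common_causes, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Export a causal graph in DOT format
#'
#' @param graph A [build_causal_graph()] result.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_graph_dot <- function(graph, path) {
  if (!inherits(graph, "causal_graph")) stop_("graph must be a causal_graph")
  igraph::write_graph(graph$igraph, path, format = "dot")
  invisible(path)
}

#' Identify the backdoor adjustment set
#'
#' With every common cause of the treatments and the outcome observed, the
#' backdoor criterion identifies the interventional contrast by adjusting
#' for exactly those common causes: W = all common-cause nodes.
#'
#' @param graph A [build_causal_graph()] result.
#' @param data Optional dataset used to verify that every common cause is
#'   actually observed (identification fails otherwise).
#' @return Object of class `causal_estimand`: `outcome`, `treatments`,
#'   `adjustment_set`, and a human-readable `expression`.
#' @export
identify_backdoor <- function(graph, data = NULL) {
  if (!inherits(graph, "causal_graph")) stop_("graph must be a causal_graph")
  W <- graph$common_causes
  if (!is.null(data)) {
    cols <- var_column(W)
    missing <- W[!(cols %in% names(data))]
    if (length(missing))
      stop_(paste("common cause(s) %s not observed in the dataset;",
                  "backdoor identification fails"),
            paste(missing, collapse = ", "))
  }
  expr <- sprintf(
    "E[Y(%s)|do(X=1)] - E[Y(%s)|do(X=0)] = E_W[ E[Y|X=1, W] - E[Y|X=0, W] ], W = {%s}",
    graph$outcome, graph$outcome,
    if (length(W)) paste(W, collapse = ", ") else "")
  structure(list(outcome = graph$outcome, treatments = graph$treatments,
                 adjustment_set = W, expression = expr),
            class = "causal_estimand")
}

#' @export
print.causal_estimand <- function(x, ...) {
  cat("Backdoor estimand:\n  ", x$expression, "\n", sep = "")
  cat("  treatments:", paste(x$treatments, collapse = ", "), "\n")
  invisible(x)
}

# Design matrix for the adjustment regression: intercept, treatments, W.
# drop_collinear removes linearly dependent adjustment columns (never
# treatments or the intercept), which keeps the estimator defined when a
# refuter appends a redundant common cause.
.adjustment_matrix <- function(data, estimand, drop_collinear = FALSE) {
  tcols <- var_column(estimand$treatments)
  wcols <- var_column(estimand$adjustment_set)
  require_columns(data, c(tcols, wcols))
  for (i in seq_along(tcols)) {
    if (length(unique(data[[tcols[i]]])) < 2L)
      stop_("treatment '%s' is constant in the data; its effect is inestimable",
            estimand$treatments[i])
  }
  X <- cbind(intercept = 1,
             do.call(cbind, stats::setNames(
               lapply(c(tcols, wcols), function(cl) as.numeric(data[[cl]])),
               c(estimand$treatments, estimand$adjustment_set))))
  if (drop_collinear) {
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
      protected <- intersect(dropped, c("intercept", estimand$treatments))
      if (length(protected))
        stop_("cannot drop collinear treatment column(s): %s",
              paste(protected, collapse = ", "))
      X <- X[, sort(qx$pivot[seq_len(qx$rank)]), drop = FALSE]
    }
  }
  X
}

#' Estimate the interventional effect with the linear backdoor estimator
#'
#' Regresses the outcome on the treatment variables plus the adjustment
#' set. In `per-treatment` mode each treatment's coefficient is its
#' unit-intervention effect (per hpf for time, the only continuous
#' treatment); `joint` mode additionally emphasizes the all-on vs all-off
#' contrast of the binary treatments -- the sum of their coefficients at
#' fixed W and fixed time. Both are always computed and returned.
#'
#' @param data An `embryo_data` data frame.
#' @param estimand An [identify_backdoor()] result.
#' @param mode `"per-treatment"` or `"joint"` (which scalar the
#'   refutation tests track).
#' @param drop_collinear Drop linearly dependent adjustment columns
#'   instead of erroring (used by the refuters).
#' @return Object of class `causal_estimate`: `effects` (data frame
#'   `term`, `effect`, `se`), `joint` (list `effect`, `se`, `treatments`),
#'   the underlying `fit`, `estimand` and `mode`.
#' @export
estimate_effect <- function(data, estimand, mode = c("per-treatment", "joint"),
                            drop_collinear = FALSE) {
  mode <- match.arg(mode)
  if (!inherits(estimand, "causal_estimand"))
    stop_("estimand must be a causal_estimand")
  X <- .adjustment_matrix(data, estimand, drop_collinear)
  y <- as.numeric(data[[var_column(estimand$outcome)]])
  fit <- fit_ols(X, y)
  fit$gene <- estimand$outcome
  tr <- estimand$treatments
  effects <- data.frame(term = tr,
                        effect = unname(stats::coef(fit)[tr]),
                        se = unname(fit$standard_errors[tr]))
  binary <- tr[vapply(var_column(tr), function(cl) is_binary01(data[[cl]]), TRUE)]
  joint <- if (length(binary)) {
    V <- fit$vcov[binary, binary, drop = FALSE]
    list(effect = sum(stats::coef(fit)[binary]), se = sqrt(sum(V)),
         treatments = binary)
  }
  structure(list(estimand = estimand, mode = mode, effects = effects,
                 joint = joint, fit = fit, n_obs = fit$n_obs),
            class = "causal_estimate")
}

# Scalar effect tracked by the refuters: the joint binary-treatment
# contrast (the all-on vs all-off intervention).
.effect_scalar <- function(estimate) {
  if (is.null(estimate$joint))
    stop_("no binary treatments; the joint contrast is undefined")
  estimate$joint$effect
}

#' @export
print.causal_estimate <- function(x, ...) {
  cat(sprintf("Backdoor causal estimate for %s (n = %d), W = {%s}\n",
              x$estimand$outcome, x$n_obs,
              paste(x$estimand$adjustment_set, collapse = ", ")))
  eff <- x$effects
  for (i in seq_len(nrow(eff)))
    cat(sprintf("  %-9s %10.2f  (SE %.2f)%s\n", eff$term[i], eff$effect[i],
                eff$se[i], if (eff$term[i] == "time") " per hpf" else ""))
  if (!is.null(x$joint))
    cat(sprintf("  joint all-on vs all-off (%s): %.2f  (SE %.2f)\n",
                paste(x$joint$treatments, collapse = "+"),
                x$joint$effect, x$joint$se))
  invisible(x)
}
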