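# End-to-end pipeline: simulate (or load) an embryo table, fit the full
# regression per gene, screen variables, build the causal graph, identify
# and estimate the backdoor effect, run the three refutation tests, and
# compute per-timepoint coefficient trajectories with contribution
# profiles. All randomness derives from one configured seed.

EMBRYO_COLUMNS <- c("embryo_id", "genotype", "treatment", "time_hpf",
                    "x_eomesa", "x_bcatenin", "x_smad2", "y_ndr1", "y_ndr2")

#' Pipeline configuration
#'
#' @param design A [design_config()].
#' @param scm An [scm_params()] generating model (ignored when observed
#'   data are supplied to [run_pipeline()]).
#' @param screen_threshold Variable-screening p-value threshold.
#' @param n_rep Repetitions per refutation test.
#' @param drop_fraction Subset-refuter drop fraction.
#' @param rcc_tolerance Random-common-cause relative-change tolerance.
#' @param seed Master seed; all stage seeds are derived from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = design_config(), scm = scm_params(),
                            screen_threshold = 0.2, n_rep = 100,
                            drop_fraction = 0.2, rcc_tolerance = 0.1,
                            seed = 1L) {
  if (!inherits(design, "design_config")) stop_("design must be a design_config")
  if (!inherits(scm, "scm_params")) stop_("scm must be an scm_params")
  if (n_rep < 1) stop_("n_rep must be >= 1")
  structure(list(design = design, scm = scm,
                 screen_threshold = screen_threshold, n_rep = n_rep,
                 drop_fraction = drop_fraction, rcc_tolerance = rcc_tolerance,
                 seed = seed),
            class = "pipeline_config")
}

.log_stage <- function(fmt, ...) message(sprintf(paste0("[nodalcausal] ", fmt), ...))

.config_md5 <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass_recursive(config)), tmp)
  unname(tools::md5sum(tmp))
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

#' Run the full causal-analysis pipeline
#'
#' Executes, for each gene: full-model fit, variable screening, causal
#' graph construction, backdoor identification, linear effect estimation,
#' the three refutation tests, per-timepoint fits and contribution
#' profiles. Deterministic for a fixed configuration seed. Progress is
#' logged to stderr; results never are.
#'
#' @param config A [pipeline_config()].
#' @param data Optional observed `embryo_data` table (e.g. from
#'   [read_embryo_table()]); when `NULL`, data are simulated from the
#'   configured design and SCM.
#' @param out_dir Optional output directory; when given, all artifacts are
#'   written there via [write_report()].
#' @return Object of class `run_report`.
#' @export
run_pipeline <- function(config, data = NULL, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) stop_("config must be a pipeline_config")
  t0 <- proc.time()[["elapsed"]]
  stage <- function(what, code) {
    s <- proc.time()[["elapsed"]]
    out <- tryCatch(code, error = function(e)
      stop_("stage '%s' failed: %s", what, conditionMessage(e)))
    .log_stage("%s (%.2fs)", what, proc.time()[["elapsed"]] - s)
    out
  }
  if (is.null(data)) {
    data <- stage("simulate", simulate_dataset(build_design(config$design),
                                               config$scm, seed = config$seed))
  } else {
    stage("validate input table", validate_embryo_data(data))
  }
  genes <- list()
  for (g in seq_along(GENES)) {
    gene <- GENES[g]
    full <- stage(paste("fit full model:", gene), fit_full_model(data, gene))
    screen <- stage(paste("screen variables:", gene),
                    screen_variables(full, config$screen_threshold))
    graph <- build_causal_graph(screen, gene)
    estimand <- identify_backdoor(graph, data)
    estimate <- stage(paste("estimate effect:", gene),
                      estimate_effect(data, estimand))
    base <- rep_seed(config$seed, 10000 * g)
    refutations <- stage(paste("refutation tests:", gene), list(
      random_common_cause = refute_random_common_cause(
        data, estimand, n_rep = config$n_rep, seed = rep_seed(base, 1000),
        tolerance = config$rcc_tolerance),
      placebo_treatment = refute_placebo_treatment(
        data, estimand, n_rep = config$n_rep, seed = rep_seed(base, 2000)),
      data_subset = refute_data_subset(
        data, estimand, drop_fraction = config$drop_fraction,
        n_rep = config$n_rep, seed = rep_seed(base, 3000))))
    tp <- stage(paste("per-timepoint fits:", gene), fit_per_timepoint(data, gene))
    contributions <- relative_contributions(tp)
    genes[[gene]] <- list(full_fit = full, screen = screen, graph = graph,
                          estimand = estimand, estimate = estimate,
                          refutations = refutations, timepoint_fits = tp,
                          contributions = contributions)
  }
  .log_stage("pipeline done (%.2fs total)", proc.time()[["elapsed"]] - t0)
  report <- structure(list(data = data, genes = genes,
                           provenance = list(
                             package = "nodalcausal",
                             version = as.character(utils::packageVersion("nodalcausal")),
                             seed = config$seed,
                             config_md5 = .config_md5(config)),
                           config = config),
                      class = "run_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("nodalcausal run report (seed %s, config %s)\n",
              x$provenance$seed, substr(x$provenance$config_md5, 1, 8)))
  for (gene in names(x$genes)) {
    res <- x$genes[[gene]]
    cat(sprintf("\n== %s ==\n", gene))
    print(res$screen)
    print(res$estimate)
    for (r in res$refutations) print(r)
  }
  invisible(x)
}

#' Read and validate an embryo intensity table
#'
#' Reads the standard CSV schema and validates it: all columns present,
#' numeric stages and non-negative intensities, 0/1 indicator columns
#' consistent with the genotype/treatment labels. Malformed rows are
#' reported with their file line numbers.
#'
#' @param path CSV file path.
#' @return A validated `embryo_data` data frame.
#' @export
read_embryo_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(raw, EMBRYO_COLUMNS, sprintf("embryo table '%s'", path))
  validate_embryo_data(raw, line_offset = 1L)
  class(raw) <- c("embryo_data", "data.frame")
  raw
}

validate_embryo_data <- function(data, line_offset = 0L) {
  require_columns(data, EMBRYO_COLUMNS, "embryo table")
  problems <- character()
  flag <- function(rows, why) {
    if (any(rows))
      problems <<- c(problems, sprintf("line %d: %s",
                                       which(rows) + line_offset, why))
  }
  for (cl in c("time_hpf", "y_ndr1", "y_ndr2")) {
    v <- suppressWarnings(as.numeric(data[[cl]]))
    flag(is.na(v), sprintf("non-numeric %s", cl))
    data[[cl]] <- v
  }
  flag(!is.na(data$y_ndr1) & data$y_ndr1 < 0, "negative y_ndr1 intensity")
  flag(!is.na(data$y_ndr2) & data$y_ndr2 < 0, "negative y_ndr2 intensity")
  enc <- encode_factors(data$genotype, data$treatment, data$time_hpf)
  for (cl in c("x_eomesa", "x_bcatenin", "x_smad2")) {
    flag(!(data[[cl]] %in% c(0, 1)), sprintf("%s not 0/1", cl))
    ok <- data[[cl]] %in% c(0, 1)
    flag(ok & data[[cl]] != enc[[cl]],
         sprintf("%s inconsistent with genotype/treatment labels", cl))
  }
  if (length(problems))
    stop_("invalid embryo table:\n  %s",
          paste(utils::head(problems, 10), collapse = "\n  "))
  invisible(TRUE)
}

#' Write all pipeline artifacts
#'
#' Writes the embryo table, tidy fit tables (full-model and per-stage),
#' contribution profiles, causal estimates, refutation summary, screen
#' JSON, provenance YAML, DOT graphs, and a human-readable report.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "run_report")) stop_("report must be a run_report")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(dir, f)
  files <- character()
  put_csv <- function(df, f) {
    utils::write.csv(df, path(f), row.names = FALSE, quote = FALSE)
    files <<- c(files, path(f))
  }
  write_embryo_table(report$data, path("embryo_data.csv"))
  files <- c(files, path("embryo_data.csv"))

  fits <- do.call(rbind, lapply(report$genes, function(res) {
    full <- as.data.frame(res$full_fit)
    full <- cbind(full[, "gene", drop = FALSE], stage = "all",
                  full[, c("factor", "coefficient", "se", "t", "p")])
    tp <- as.data.frame(res$timepoint_fits)
    tp$stage <- as.character(tp$stage)
    rbind(full, tp)
  }))
  put_csv(fits, "fits.csv")
  put_csv(do.call(rbind, lapply(report$genes, function(res)
    as.data.frame(res$contributions))), "contributions.csv")
  put_csv(do.call(rbind, lapply(names(report$genes), function(gene) {
    res <- report$genes[[gene]]
    eff <- cbind(gene = gene, res$estimate$effects)
    if (!is.null(res$estimate$joint))
      eff <- rbind(eff, data.frame(gene = gene, term = "joint",
                                   effect = res$estimate$joint$effect,
                                   se = res$estimate$joint$se))
    eff
  })), "estimates.csv")
  put_csv(do.call(rbind, lapply(names(report$genes), function(gene) {
    do.call(rbind, lapply(report$genes[[gene]]$refutations, function(r)
      data.frame(gene = gene, refuter = r$refuter, original = r$original,
                 refuted = r$refuted, mc_se = r$mc_se, n_rep = r$n_rep,
                 pass = r$pass)))
  })), "refutations.csv")

  jsonlite::write_json(lapply(report$genes, function(res)
    list(treatments = res$screen$treatments,
         common_causes = res$screen$common_causes,
         threshold = res$screen$threshold)),
    path("screen.json"), auto_unbox = TRUE, digits = NA)
  files <- c(files, path("screen.json"))
  yaml::write_yaml(report$provenance, path("provenance.yaml"))
  files <- c(files, path("provenance.yaml"))
  for (gene in names(report$genes)) {
    f <- path(sprintf("graph_%s.dot", gene))
    export_graph_dot(report$genes[[gene]]$graph, f)
    files <- c(files, f)
  }
  writeLines(utils::capture.output(print(report)), path("report.txt"))
  files <- c(files, path("report.txt"))
  invisible(files)
}
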