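# End-to-end orchestration: load or simulate a matrix, filter, compute
# ratios, run both classifiers and the pathway summaries, and write all
# reports with a full config echo.

default_roles <- list(baseline = "baseline", perturbed = "perturbed",
                      treated = "treated", endpoint = "endpoint",
                      pre_endpoint = "pre_endpoint")

#' Read a pipeline configuration file
#'
#' @param path YAML (or JSON, a YAML subset) pipeline configuration.
#' @return the configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    rt_abort(sprintf("config file not found: %s", path),
             "revtraj_error_missing_file")
  yaml::read_yaml(path)
}

#' Run the full classification pipeline
#'
#' Loads (or simulates) an expression matrix, applies the detectability
#' filter, computes the perturbation (`r1`), treatment (`rT`) and, when
#' endpoint roles are present, endpoint (`r2`) and pre-endpoint (`r3`)
#' ratio tables, then runs the treatment-response classifier, the
#' trajectory classifier and the per-gene-set direction summaries, and
#' writes every report to `out_dir`. Re-running with identical inputs
#' produces byte-identical outputs. Progress and gene-count conservation
#' are logged to stderr.
#'
#' Configuration fields: `matrix` (TSV path) or `simulate` (a list of
#' [generator_config()] fields); `roles` mapping the condition roles
#' `baseline`, `perturbed`, `treated` and optionally `endpoint`,
#' `pre_endpoint` to column names; optional `gene_sets` (GMT path);
#' optional `classification` ([classification_config()] overrides);
#' optional `fold_threshold` (default 2); `out_dir`.
#'
#' @param config a configuration list or the path to a YAML file.
#' @param out_dir output directory; overrides `config$out_dir`.
#' @param seed overrides `config$simulate$seed`.
#' @return the summary report (config echo, version, gene counts at each
#'   filter step, stratum report, favorability report, pathway reports,
#'   file manifest), invisibly; all reports are also written to
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir))
    rt_abort("an output directory is required (out_dir)",
             "revtraj_error_bad_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ccfg <- do.call(classification_config, config$classification %||% list())
  fold_threshold <- config$fold_threshold %||% 2
  roles <- utils::modifyList(default_roles, config$roles %||% list())

  truth <- NULL
  gcfg <- NULL
  if (!is.null(config$simulate)) {
    gargs <- config$simulate
    if (!is.null(seed)) gargs$seed <- seed
    gcfg <- do.call(generator_config, gargs)
    sim <- simulate_expression(gcfg)
    m <- sim$matrix
    truth <- sim$truth
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_expr_matrix(m, file.path(out_dir, "simulated_matrix.tsv"))
  } else if (!is.null(config$matrix)) {
    m <- read_expr_matrix(config$matrix)
  } else {
    rt_abort("config needs either `matrix` or `simulate`",
             "revtraj_error_bad_config")
  }

  required <- unlist(roles[c("baseline", "perturbed", "treated")])
  missing <- setdiff(required, colnames(m))
  if (length(missing))
    rt_abort(sprintf("role column(s) absent from matrix: %s",
                     paste(missing, collapse = ", ")),
             "revtraj_error_bad_config")

  n_input <- nrow(m)
  md <- filter_detectable(m, ccfg$min_tpm, ccfg$min_conditions)
  n_detectable <- nrow(md)
  message(sprintf("[revtraj] genes: input %d = retained %d + filtered %d",
                  n_input, n_detectable, n_input - n_detectable))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  r1 <- stage("ratios", compute_ratio(md, roles$perturbed, roles$baseline,
                                      ccfg$pseudocount))
  rT <- stage("ratios", compute_ratio(md, roles$treated, roles$perturbed,
                                      ccfg$pseudocount))

  labels <- stage("classify", classify_t20_response(r1, rT, ccfg))
  files <- character(0)
  write_out <- function(obj, name, writer) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    files <<- c(files, name)
  }
  tsv_writer <- function(obj, path)
    utils::write.table(obj, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  json_writer <- function(obj, path)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE, null = "null")

  write_out(labels, "response_labels.tsv", tsv_writer)
  strata <- summarize_strata(labels)
  bins <- summarize_bins(r1, rT, ccfg)
  write_out(list(strata = strata, bins = bins, config = unclass(ccfg)),
            "stratum_report.json", json_writer)

  favorability <- NULL
  traj <- NULL
  has_endpoint <- roles$endpoint %in% colnames(m)
  if (has_endpoint) {
    r2 <- stage("trajectory", compute_ratio(md, roles$endpoint,
                                            roles$baseline, ccfg$pseudocount))
    r3 <- if (roles$pre_endpoint %in% colnames(m))
      compute_ratio(md, roles$pre_endpoint, roles$endpoint, ccfg$pseudocount)
    traj <- stage("trajectory", classify_trajectory(
      r1, r2, r3, ccfg, genes = select_responsive_genes(r1, fold_threshold)))
    write_out(traj, "trajectory_labels.tsv", tsv_writer)
    favorability <- favorability_report(traj)
    write_out(c(unclass(favorability),
                list(fold_threshold = fold_threshold,
                     config = unclass(ccfg))),
              "favorability_report.json", json_writer)
  }

  pathway_reports <- NULL
  if (!is.null(config$gene_sets)) {
    sets <- stage("pathways", read_gmt(config$gene_sets))
    pathway_reports <- lapply(sets, function(s)
      unclass(pathway_direction_fractions(m, s, r1, rT, ccfg)))
    write_out(pathway_reports, "pathway_reports.json", json_writer)
  }

  report <- list(
    package_version = as.character(utils::packageVersion("revtraj")),
    seed = if (!is.null(gcfg)) gcfg$seed,
    classification_config = unclass(ccfg),
    generator_config = if (!is.null(gcfg))
      unclass(gcfg)[!vapply(unclass(gcfg), is.null, logical(1))],
    fold_threshold = fold_threshold,
    roles = roles,
    gene_counts = list(input = n_input, detectable = n_detectable,
                       filtered_out = n_input - n_detectable,
                       responsive = if (!is.null(traj)) nrow(traj)),
    stratum_report = strata,
    favorability_report = if (!is.null(favorability)) unclass(favorability),
    pathway_reports = pathway_reports,
    manifest = files)
  json_writer(report, file.path(out_dir, "summary_report.json"))
  invisible(report)
}
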