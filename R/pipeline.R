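#' Pipeline configuration
#'
#' Collects every tunable parameter of the inference pipeline with its
#' default: the three-label Gaussian membership configuration (centers
#' 0.2/0.5/0.8, variance 0.25), magnitude-based effectivity thresholding,
#' no ridge penalty, contemporaneous regression (lag 0), net-support cutoff
#' 1, harmonic F weighting 0.5 and 5 imputation neighbours.
#'
#' @param centers,variance,labels Membership-function setup, see [mf_params()].
#' @param threshold_mode `"abs"` or `"literal"`, see [effectivity_threshold()].
#' @param ridge Nonnegative ridge penalty for weight learning.
#' @param lag Input-to-target lag in time steps.
#' @param min_score Minimum net support for a final edge.
#' @param dominant_sign Keep only the stronger sign per gene pair.
#' @param alpha F-score weighting factor.
#' @param knn_k Imputation neighbour count.
#' @param seed Optional integer seed recorded in reports.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(centers = c(0.2, 0.5, 0.8), variance = 0.25,
                            labels = c("Low", "Medium", "High"),
                            threshold_mode = c("abs", "literal"),
                            ridge = 0, lag = 0L, min_score = 1L,
                            dominant_sign = FALSE, alpha = 0.5, knn_k = 5L,
                            seed = NULL) {
  mf_params(centers, variance, labels)  # validates the MF block
  structure(list(centers = centers, variance = variance, labels = labels,
                 threshold_mode = match.arg(threshold_mode),
                 ridge = ridge, lag = as.integer(lag),
                 min_score = as.integer(min_score),
                 dominant_sign = isTRUE(dominant_sign), alpha = alpha,
                 knn_k = as.integer(knn_k), seed = seed),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML/key-value file
#'
#' Keys not present in the file keep their [pipeline_config()] defaults;
#' unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()].
#' @export
load_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run inference on an expression file and write the results
#'
#' Thin file-level wrapper around [infer_network()]: reads the expression
#' matrix, runs the pipeline, writes the inferred network as SIF (and TSV
#' with scores alongside when `out_report` is given, as JSON).  Stage errors
#' carry the stage name.
#'
#' @param expr_path Expression TSV/CSV path.
#' @param out_sif Output SIF path.
#' @param out_report Optional JSON report path.
#' @param config [pipeline_config()].
#' @param delimiter Expression file delimiter.
#' @return The `grn_inference` result, invisibly.
#' @export
run_infer <- function(expr_path, out_sif, out_report = NULL,
                      config = pipeline_config(), delimiter = "\t") {
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  expr <- stage("read_expression", read_expression(expr_path, delimiter))
  res <- stage("infer_network", infer_network(expr, config))
  stage("write_network", write_network(res$network, out_sif, "sif"))
  if (!is.null(out_report)) {
    jsonlite::write_json(res$report, out_report, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(res)
}

#' Evaluate a predicted network file against a reference file
#'
#' @param pred_path Predicted network path (SIF or TSV).
#' @param ref_path Reference network path (SIF or TSV).
#' @param alpha F-score weighting factor.
#' @param out_json Optional path for the metrics JSON.
#' @return The [evaluate_network()] result, invisibly.
#' @export
run_evaluate <- function(pred_path, ref_path, alpha = 0.5, out_json = NULL) {
  pred <- read_network(pred_path)
  ref <- read_network(ref_path)
  res <- suppressWarnings(evaluate_network(pred, ref, alpha = alpha))
  if (!is.null(out_json)) {
    jsonlite::write_json(res, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(res)
}

#' Simulate a benchmark and write the files a user would feed back in
#'
#' @param cfg [simulation_config()].
#' @param out_prefix Path prefix; writes `<prefix>.expr.tsv` and
#'   `<prefix>.truth.sif`.
#' @return List with the `network`, the `expression` matrix and the two
#'   paths, invisibly.
#' @export
run_simulate <- function(cfg = simulation_config(), out_prefix = "synthetic") {
  net <- generate_grn(cfg)
  expr <- simulate_expression(net, cfg)
  if (cfg$missing_fraction > 0) {
    expr <- inject_missing(expr, cfg$missing_fraction, seed = cfg$seed + 2L)
  }
  expr_path <- paste0(out_prefix, ".expr.tsv")
  truth_path <- paste0(out_prefix, ".truth.sif")
  write_expression(expr, expr_path)
  write_network(net, truth_path, "sif")
  invisible(list(network = net, expression = expr,
                 expr_path = expr_path, truth_path = truth_path))
}
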