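## Command-line pipeline: simulate / learn / evaluate / predict / citest.
## run_pipeline() is the programmatic entry point; inst/cli/causalcoxmgm.R
## wraps it for shell use.

log_msg <- function(quiet, level, ...) {
  if (quiet && level == "INFO") return(invisible())
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level, "] ", ...)
}

## tiny flag parser: --key value pairs (logical flags get TRUE)
parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      out[[key]] <- TRUE
      i <- i + 1L
    }
  }
  out
}

flag <- function(flags, name, default = NULL, as = identity) {
  if (is.null(flags[[name]])) default else as(flags[[name]])
}

load_dataset <- function(data_path, meta_path) {
  if (!file.exists(data_path)) stop("missing input file: ", data_path)
  if (!file.exists(meta_path)) stop("missing input file: ", meta_path)
  raw <- utils::read.csv(data_path, check.names = FALSE)
  specs <- read_variable_specs(meta_path)
  validate_dataset(raw, specs)
}

write_run_config <- function(flags, out_dir) {
  cfg <- c(flags, list(tool_version = as.character(utils::packageVersion("coxmgm"))))
  jsonlite::write_json(cfg, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Run a pipeline subcommand
#'
#' Dispatches `simulate`, `learn`, `evaluate`, `predict`, or `citest` with
#' `--key value` flags (see the package README). Results, the serialized
#' run configuration, and logs are written under `--out`.
#'
#' @param args Character vector: subcommand followed by flags.
#' @return Exit status, invisibly (0 on success).
#' @export
run_pipeline <- function(args) {
  status <- tryCatch({
    if (!length(args)) stop("usage: <simulate|learn|evaluate|predict|citest> --flags")
    cmd <- args[1L]
    flags <- parse_flags(args[-1L])
    quiet <- isTRUE(flag(flags, "quiet", FALSE))
    switch(cmd,
           simulate = cmd_simulate(flags, quiet),
           learn = cmd_learn(flags, quiet),
           evaluate = cmd_evaluate(flags, quiet),
           predict = cmd_predict(flags, quiet),
           citest = cmd_citest(flags, quiet),
           stop("unknown subcommand: ", cmd))
    0L
  }, error = function(e) {
    message("ERROR: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cmd_simulate <- function(flags, quiet) {
  out_dir <- flag(flags, "out", stop("--out required"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(
    n_nodes = flag(flags, "nodes", 110L, as.integer),
    topology = flag(flags, "topology", "er"),
    degree = flag(flags, "degree", 4, as.numeric),
    n_samples = flag(flags, "samples", 500L, as.integer),
    censoring = flag(flags, "censoring", "light"),
    seed = flag(flags, "seed", 1L, as.integer))
  log_msg(quiet, "INFO", "generating ", cfg$topology, " DAG with ",
          cfg$n_nodes, " nodes")
  model <- generate_dag(cfg)
  sim <- simulate_mixed_data(model)
  utils::write.csv(dataset_to_table(sim$data),
                   file.path(out_dir, "data.csv"), row.names = FALSE)
  write_variable_specs(sim$data$specs, file.path(out_dir, "data.yaml"))
  write_graph_file(truth_graph(model), file.path(out_dir, "truth.txt"))
  write_run_config(flags, out_dir)
  log_msg(quiet, "INFO", "wrote data.csv, data.yaml, truth.txt to ", out_dir)
}

cmd_learn <- function(flags, quiet) {
  out_dir <- flag(flags, "out", stop("--out required"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data <- load_dataset(flag(flags, "data", stop("--data required")),
                       flag(flags, "meta", stop("--meta required")))
  mode <- flag(flags, "mode", "mpc")
  seed <- flag(flags, "seed", 1L, as.integer)
  alpha <- flag(flags, "alpha", 0.05, as.numeric)
  max_depth <- flag(flags, "max-depth", 3L, as.integer)
  lam_flag <- flag(flags, "lambda", NULL)
  if (mode == "mgm") {
    lambda <- if (is.null(lam_flag)) NULL else
      penalty_vector(as.numeric(strsplit(lam_flag, ",")[[1L]]))
    if (is.null(lambda)) {
      cc <- causal_config(selection = flag(flags, "lambda-selection", "steps"),
                          K = flag(flags, "path-length", 30L, as.integer),
                          B = flag(flags, "subsamples", 20L, as.integer),
                          stability_threshold =
                            flag(flags, "stability-threshold", 0.05, as.numeric),
                          seed = seed)
      path <- build_lambda_path(data, cc$K)
      prof <- stability_profile(data, path, B = cc$B, seed = seed)
      write_stability_profile(prof, file.path(out_dir, "stability.json"))
      lambda <- if (cc$selection == "stars") stars_select(prof)
      else steps_select(prof)
    }
    log_msg(quiet, "INFO", "fitting CoxMGM at lambda = ",
            paste(signif(lambda, 3), collapse = ","))
    fit <- fit_coxmgm(data, lambda)
    g <- params_to_graph(fit)
  } else {
    cc <- causal_config(alpha = alpha, max_depth = max_depth, mode = mode,
                        selection = flag(flags, "lambda-selection", "steps"),
                        K = flag(flags, "path-length", 30L, as.integer),
                        B = flag(flags, "subsamples", 20L, as.integer),
                        stability_threshold =
                          flag(flags, "stability-threshold", 0.05, as.numeric),
                        seed = seed)
    log_msg(quiet, "INFO", "running CausalCoxMGM (", mode, ")")
    res <- causal_cox_mgm(data, cc)
    if (!is.null(res$profile))
      write_stability_profile(res$profile, file.path(out_dir, "stability.json"))
    g <- res$graph
  }
  write_graph_file(g, file.path(out_dir, "graph.txt"))
  write_run_config(flags, out_dir)
  log_msg(quiet, "INFO", "wrote graph.txt (", n_edges(g), " edges)")
}

cmd_evaluate <- function(flags, quiet) {
  out_dir <- flag(flags, "out", stop("--out required"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  est_p <- flag(flags, "est", stop("--est required"))
  tru_p <- flag(flags, "truth", stop("--truth required"))
  if (!file.exists(est_p)) stop("missing input file: ", est_p)
  if (!file.exists(tru_p)) stop("missing input file: ", tru_p)
  est <- read_graph_file(est_p, gclass = "cpdag")
  truth <- read_graph_file(tru_p, gclass = "dag")
  ## carry variable kinds from node-name prefixes when available
  infer_kinds <- function(nodes) {
    k <- rep("continuous", length(nodes))
    k[startsWith(nodes, "Y")] <- "discrete"
    k[startsWith(nodes, "S")] <- "censored"
    stats::setNames(k, nodes)
  }
  est$kinds <- infer_kinds(est$nodes)
  truth$kinds <- infer_kinds(truth$nodes)
  report <- evaluate_run(est, truth)
  write_metrics_report(report, file.path(out_dir, "report.json"))
  write_run_config(flags, out_dir)
  log_msg(quiet, "INFO", "wrote report.json")
}

cmd_predict <- function(flags, quiet) {
  out_dir <- flag(flags, "out", stop("--out required"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data <- load_dataset(flag(flags, "data", stop("--data required")),
                       flag(flags, "meta", stop("--meta required")))
  graph_p <- flag(flags, "graph", stop("--graph required"))
  if (!file.exists(graph_p)) stop("missing input file: ", graph_p)
  g <- read_graph_file(graph_p, gclass = "cpdag")
  target <- flag(flags, "target", stop("--target required"))
  seed <- flag(flags, "seed", 1L, as.integer)
  cv <- flag(flags, "cv", 0L, as.integer)
  pred <- fit_mb_cox(data, g, target)
  out <- list(target = target, mb = pred$mb, coef = pred$coef_table)
  if (cv >= 2L) {
    res <- cross_validated_concordance(
      data, function(d) g, target, folds = cv, seed = seed)
    out$cv_concordance <- res$concordance
    log_msg(quiet, "INFO", "pooled ", cv, "-fold concordance: ",
            round(res$concordance, 4))
  }
  jsonlite::write_json(out, file.path(out_dir, "pred.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_run_config(flags, out_dir)
  log_msg(quiet, "INFO", "wrote pred.json")
}

cmd_citest <- function(flags, quiet) {
  data <- load_dataset(flag(flags, "data", stop("--data required")),
                       flag(flags, "meta", stop("--meta required")))
  S <- flag(flags, "given", NULL)
  S <- if (is.null(S)) character(0) else strsplit(S, ",")[[1L]]
  res <- ci_test(flag(flags, "x", stop("--x required")),
                 flag(flags, "y", stop("--y required")),
                 S, data)
  cat(jsonlite::toJSON(unclass(res), auto_unbox = TRUE, digits = NA), "\n")
}
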