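#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. Either an input society
#' table (`input`) or a synthetic generator config (`synthetic`) must be
#' given; when the input lacks covariates they can be filled from a second
#' table or a generator via `attach`-style joins before calling.
#'
#' @param input Path to a society-table CSV, or a `society_dataset`, or
#'   `NULL` when `synthetic` is given.
#' @param synthetic A [synthetic_config()] used when `input` is `NULL`.
#' @param stages Character subset of
#'   `c("tests", "network", "pairs", "screen", "pattern")`; dependencies are
#'   enforced (`screen` and `pattern` imply `pairs`).
#' @param alpha Significance level used for routing and verdicts.
#' @param n_perm HHG permutations (>= 99).
#' @param k_outer,k_inner Nested-CV fold counts.
#' @param control A [cv_control()] for the predictive stage.
#' @param seed Master seed.
#' @param out_dir Output directory (created if absent).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            stages = c("tests", "network", "pairs",
                                       "screen", "pattern"),
                            alpha = 0.05, n_perm = 999,
                            k_outer = 10, k_inner = 5,
                            control = cv_control(),
                            seed = 1L, out_dir = "results") {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(input) && is.null(synthetic))
    stop("either an input table or a synthetic config is required")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (any(c("screen", "pattern") %in% stages))
    stages <- union(stages, "pairs")
  structure(list(input = input, synthetic = synthetic, stages = stages,
                 alpha = alpha, n_perm = n_perm, k_outer = k_outer,
                 k_inner = k_inner, control = control, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Maps a flat YAML document onto [pipeline_config()]; the `synthetic` block,
#' if present, is passed to [synthetic_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- if (!is.null(y$synthetic)) do.call(synthetic_config, y$synthetic)
  args <- y[setdiff(names(y), "synthetic")]
  args$synthetic <- syn
  do.call(pipeline_config, args)
}

pipeline_log <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order and writes one file per
#' output table into `out_dir`: the exploratory test table and its
#' seven-method correction table, the GraphML network and edge list, the
#' pairwise design, the dependence screen with its four corrected tables, the
#' fold-MSE table and ANOVA table, and a JSON run manifest recording the
#' seed, stage row counts and package version. Stage timers are logged to
#' stderr. Any stage failure aborts with a stage-named error; outputs written
#' so far are kept.
#'
#' @param config A [pipeline_config()].
#' @return The manifest list, invisibly; outputs on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dataset <- if (!is.null(config$input)) {
    if (inherits(config$input, "society_dataset")) config$input
    else load_society_table(config$input)
  } else generate_dataset(config$synthetic)
  validate_society_dataset(dataset)

  manifest <- list(seed = config$seed, stages = config$stages,
                   n_societies = n_societies(dataset),
                   n_practices = length(practice_codes()),
                   n_variables = length(dataset$roster),
                   package_version = as.character(utils::packageVersion("cultshare")),
                   outputs = list())
  out <- function(name) file.path(config$out_dir, name)
  run_stage <- function(stage, fn) {
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    pipeline_log(sprintf("stage %-8s %5.1fs", stage,
                         as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  if ("tests" %in% config$stages) {
    manifest$outputs$tests <- run_stage("tests", function() {
      sweep <- exploratory_sweep(dataset, alpha_assumptions = config$alpha)
      write_results(sweep, out("exploratory_tests.csv"))
      tested <- !is.na(sweep$p_value)
      corr <- cbind(sweep[tested, c("practice", "variable", "test")],
                    correction_table(sweep$p_value[tested]))
      write_results(corr, out("exploratory_corrections.csv"))
      list(files = c("exploratory_tests.csv", "exploratory_corrections.csv"),
           n_scheduled = attr(sweep, "n_scheduled"),
           n_rows = nrow(sweep))
    })
  }
  if ("network" %in% config$stages) {
    manifest$outputs$network <- run_stage("network", function() {
      net <- build_network(dataset)
      export_network(net, out("network.graphml"), "graphml")
      export_network(net, out("network_edges.csv"), "edgelist_csv")
      list(files = c("network.graphml", "network_edges.csv"),
           n_nodes = igraph::vcount(net), n_edges = igraph::ecount(net))
    })
  }
  pairs <- NULL
  if ("pairs" %in% config$stages) {
    manifest$outputs$pairs <- run_stage("pairs", function() {
      pairs <<- build_pairwise_table(dataset)
      write_results(pairs, out("pairwise_table.csv"))
      list(files = "pairwise_table.csv", n_rows = nrow(pairs))
    })
  }
  if ("screen" %in% config$stages) {
    manifest$outputs$screen <- run_stage("screen", function() {
      scr <- dependence_screen(pairs, n_perm = config$n_perm,
                               seed = config$seed)
      write_results(scr, out("dependence_screen.csv"))
      corr <- dependence_corrections(scr)
      for (f in names(corr))
        write_results(corr[[f]], out(paste0("dependence_corrected_", f, ".csv")))
      list(files = c("dependence_screen.csv",
                     paste0("dependence_corrected_", names(corr), ".csv")),
           n_rows = nrow(scr))
    })
  }
  if ("pattern" %in% config$stages) {
    manifest$outputs$pattern <- run_stage("pattern", function() {
      pt <- pattern_test(pairs, k_outer = config$k_outer,
                         k_inner = config$k_inner, control = config$control,
                         seed = config$seed, alpha = config$alpha)
      write_results(fold_mse_summary(pt$fold_mse), out("fold_mse.csv"))
      write_results(pt$anova$table, out("anova.csv"))
      list(files = c("fold_mse.csv", "anova.csv"),
           F = pt$anova$F, p = pt$anova$p, verdict = pt$verdict)
    })
  }
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
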