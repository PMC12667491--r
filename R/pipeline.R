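# End-to-end pipeline binding all modules, plus config file handling for
# the command-line interface (inst/cli/spatchwork.R).

#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by [run_pipeline()]:
#' input paths or a simulation block, preprocessing, graph, training and
#' clustering parameters, output directory and root seed. Any subset can
#' be overridden via `...` (nested lists are merged shallowly per block).
#'
#' @param ... named overrides, e.g. `training = list(epochs_pretrain = 200)`.
#' @return a `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    input = list(paths = NULL, format = "mtx"),
    simulate = NULL,                    # a simulation_spec-style list, or NULL
    preprocess = list(min_spots = 50, min_total = 10, n_hvg = 2000,
                      n_components = 200),
    graph = list(k = 8, metric = "euclidean"),
    training = list(),                  # training_config() overrides
    clustering = list(n_domains = NULL, perplexity = 30),
    outdir = NULL,
    seed = 1L)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration file
#'
#' YAML (preferred, requires the yaml package) or JSON.
#'
#' @param path config file path.
#' @return a `run_config` list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the yaml package; use JSON instead",
           call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_config, raw)
}

config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$outdir <- NULL                 # hash the science, not the paths
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                        null = "null", force = TRUE)
  # small rolling hash; provenance marker, not cryptographic
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Run the full pipeline
#'
#' Executes simulate-or-load, preprocessing, graph construction, masked
#' VGAE pretraining, DEC + triplet fine-tuning, model-based clustering
#' and evaluation. When `outdir` is set, writes `embedding.csv`,
#' `labels.csv`, `metrics.json`, per-stage loss logs and the config
#' snapshot (with hash and seed).
#'
#' @param config a `run_config` from [default_config()] /
#'   [read_config()], or a list of overrides.
#' @return list of class `pipeline_result`: `dataset`, `pretrain`,
#'   `finetune`, `labels`, `metrics`, `config`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (!inherits(config, "run_config")) config <- do.call(default_config, config)
  seed <- config$seed %||% 1L

  slices <- if (!is.null(config$simulate)) {
    simargs <- config$simulate
    simargs$seed <- simargs$seed %||% seed
    sim <- simulate_slices(do.call(simulation_spec, simargs))
    sim$slices
  } else if (!is.null(config$input$paths)) {
    load_slices(config$input$paths, format = config$input$format)
  } else stop("config must provide either input$paths or a simulate block",
              call. = FALSE)

  pp <- config$preprocess
  dataset <- build_joint_dataset(
    slices, min_spots = pp$min_spots, min_total = pp$min_total,
    n_hvg = pp$n_hvg, n_components = pp$n_components,
    k = config$graph$k, metric = config$graph$metric, seed = seed)

  tc_args <- config$training
  tc_args$seed <- tc_args$seed %||% seed
  tc <- do.call(training_config, tc_args)

  outdir <- config$outdir
  logf <- function(name) if (!is.null(outdir)) file.path(outdir, name)
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)

  pre <- pretrain(dataset, tc, log_file = logf("loss_pretrain.tsv"))
  fin <- finetune(dataset, pre, tc, log_file = logf("loss_finetune.tsv"))
  Z <- fin$embedding$Z

  n_domains <- config$clustering$n_domains %||%
    (if (!is.null(dataset$labels)) length(unique(dataset$labels)) else
       stop("clustering$n_domains must be set when no labels are available",
            call. = FALSE))
  labels <- cluster_embedding(Z, n_domains = n_domains,
                              seed = derive_seed(seed, "cluster"))

  metrics <- evaluate_embedding(
    Z, pred = labels, truth = dataset$labels,
    batch = dataset$slice_of,
    perplexity = config$clustering$perplexity %||% 30)

  if (!is.null(outdir)) {
    emb <- data.frame(spot_id = rownames(dataset$X) %||%
                        seq_len(dataset$n),
                      slice = dataset$slice_of, Z)
    utils::write.csv(emb, file.path(outdir, "embedding.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(spot_id = emb$spot_id,
                                slice = dataset$slice_of,
                                domain = labels),
                     file.path(outdir, "labels.csv"), row.names = FALSE)
    jsonlite::write_json(
      c(list(config_hash = config_hash(config), seed = seed),
        unclass(metrics)),
      file.path(outdir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(unclass(config), file.path(outdir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  structure(list(dataset = dataset, pretrain = pre, finetune = fin,
                 labels = labels, metrics = metrics, config = config),
            class = "pipeline_result")
}
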