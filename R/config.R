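# Run configuration: one YAML file per run, flat key-value blocks. Unknown
# keys are rejected up front; defaults are filled in, and every command
# writes the fully-resolved config next to its outputs so a run can be
# reproduced bit-exact from that file plus its seed.

config_error <- function(...) {
  stop(errorCondition(sprintf(...), class = c("dbnexpr_config_error", "error")))
}

config_defaults <- function() {
  list(
    seed = 1L,
    task = list(expression = NULL, labels = NULL,
                orientation = "samples-as-rows", log_transform = FALSE,
                positive_class = NULL),
    model = list(type = "dbn", architecture = "A-50-10-1", algorithm = "rprop",
                 epochs = 100L, batch_size = 10L, learning_rate = 0.1,
                 weight_cost = 0, momentum_initial = 0.5, momentum_final = 0.9,
                 momentum_switch = 50L, early_stop_epoch = NULL,
                 weight_normalization = FALSE, encoding = NULL,
                 soft_target_p = 0.9, pretrain = TRUE, hidden = c(50L, 10L),
                 cd_k = 1L, cd_epochs = 20L, cd_learning_rate = 0.1,
                 cd_batch_size = 10L, selection_k = NULL,
                 selection_scope = "fold"),
    hybrid = list(source = "finetuned-dbn", layer_index = NULL,
                  kernel = "linear", cost = 1, gamma = NULL),
    evaluation = list(classifier = "dbn", k = 10L, balance = TRUE,
                      stratify = TRUE),
    simulate = list(n_per_class = c(77L, 77L), n_genes = 1000L,
                    n_differential = 50L, effect_size = 1, noise_sd = 1,
                    baseline_mean = 8, baseline_sd = 2),
    model_path = NULL
  )
}

merge_block <- function(defaults, user, block) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    config_error("unknown key(s) in '%s' block: %s", block,
                 paste(unknown, collapse = ", "))
  }
  for (k in names(user)) defaults[[k]] <- user[[k]]
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, rejects unknown keys, fills defaults, and
#' performs basic type/range checks. `overrides` (a nested list) are applied
#' on top of the file values, mirroring command-line flag overrides.
#'
#' @param path path to a YAML config file, or `NULL` for pure defaults.
#' @param overrides nested list merged over the file values.
#' @return The resolved configuration list (class `run_config`).
#' @export
load_run_config <- function(path = NULL, overrides = NULL) {
  user <- if (!is.null(path)) {
    if (!file.exists(path)) config_error("config file not found: %s", path)
    yaml::read_yaml(path)
  } else list()
  if (!is.null(overrides)) {
    for (b in names(overrides)) {
      if (is.list(overrides[[b]])) {
        user[[b]] <- utils::modifyList(user[[b]] %||% list(), overrides[[b]])
      } else {
        user[[b]] <- overrides[[b]]
      }
    }
  }
  defaults <- config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    config_error("unknown top-level key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- defaults
  for (b in c("task", "model", "hybrid", "evaluation", "simulate")) {
    cfg[[b]] <- merge_block(defaults[[b]], user[[b]], b)
  }
  if (!is.null(user$seed)) cfg$seed <- user$seed
  if (!is.null(user$model_path)) cfg$model_path <- user$model_path
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    config_error("'seed' must be a single integer")
  }
  m <- cfg$model
  if (!m$type %in% c("dbn", "autoencoder")) {
    config_error("model type must be 'dbn' or 'autoencoder', got '%s'", m$type)
  }
  if (!m$algorithm %in% c("bprop", "rprop")) {
    config_error("algorithm must be 'bprop' or 'rprop', got '%s'", m$algorithm)
  }
  if (!is.null(m$encoding) && !m$encoding %in% c("single", "multi")) {
    config_error("encoding must be 'single' or 'multi'")
  }
  if (!m$selection_scope %in% c("fold", "global")) {
    config_error("selection_scope must be 'fold' or 'global'")
  }
  if (m$epochs < 0 || m$cd_epochs < 0) config_error("epoch counts must be >= 0")
  h <- cfg$hybrid
  if (!h$source %in% c("finetuned-dbn", "pretrained-stack", "autoencoder",
                       "passthrough")) {
    config_error("unknown hybrid source '%s'", h$source)
  }
  if (!h$kernel %in% c("linear", "radial")) {
    config_error("kernel must be 'linear' or 'radial'")
  }
  e <- cfg$evaluation
  if (!e$classifier %in% c("dbn", "svm", "hybrid", "rbm-svm", "autoencoder-svm")) {
    config_error("unknown classifier '%s'", e$classifier)
  }
  if (e$k < 2) config_error("evaluation k must be >= 2")
  s <- cfg$simulate
  if (s$noise_sd <= 0) config_error("simulate noise_sd must be > 0")
  if (any(s$n_per_class < 1)) config_error("simulate n_per_class must be positive")
  invisible(cfg)
}

write_resolved_config <- function(cfg, out_dir) {
  path <- file.path(out_dir, "resolved_config.yaml")
  yaml::write_yaml(unclass(cfg), path)
  path
}

train_control_from <- function(cfg) {
  m <- cfg$model
  train_control(algorithm = m$algorithm, learning_rate = m$learning_rate,
                weight_cost = m$weight_cost,
                momentum_initial = m$momentum_initial,
                momentum_final = m$momentum_final,
                momentum_switch = m$momentum_switch, epochs = m$epochs,
                batch_size = m$batch_size,
                early_stop_epoch = m$early_stop_epoch,
                weight_normalization = m$weight_normalization,
                seed = derive_seed(cfg$seed, 2))
}

cd_control_from <- function(cfg) {
  m <- cfg$model
  cd_control(k = m$cd_k, learning_rate = m$cd_learning_rate,
             epochs = m$cd_epochs, batch_size = m$cd_batch_size,
             seed = derive_seed(cfg$seed, 1))
}

encoding_from <- function(cfg) {
  m <- cfg$model
  if (is.null(m$encoding)) NULL else output_encoding(m$encoding, m$soft_target_p)
}

load_task_dataset <- function(cfg) {
  task <- cfg$task
  if (is.null(task$expression)) config_error("task$expression path is required")
  ds <- read_expression_matrix(task$expression, orientation = task$orientation)
  if (isTRUE(task$log_transform)) ds <- log_transform(ds)
  if (!is.null(task$labels)) {
    tab <- utils::read.table(task$labels, sep = "\t", header = TRUE,
                             colClasses = "character")
    ds <- attach_labels(ds, tab)
  }
  ds
}

learner_from_config <- function(cfg) {
  m <- cfg$model; h <- cfg$hybrid
  control <- train_control_from(cfg)
  cd <- cd_control_from(cfg)
  switch(cfg$evaluation$classifier,
    "svm" = learner_svm(kernel = h$kernel, cost = h$cost, gamma = h$gamma,
                        select_k = m$selection_k),
    "dbn" = learner_dbn(architecture = m$architecture, control = control,
                        cd = cd, encoding = encoding_from(cfg),
                        pretrain = m$pretrain, select_k = m$selection_k),
    "hybrid" = learner_hybrid(source = h$source, architecture = m$architecture,
                              control = control, cd = cd,
                              encoding = encoding_from(cfg),
                              pretrain = m$pretrain, hidden = m$hidden,
                              layer_index = h$layer_index, kernel = h$kernel,
                              cost = h$cost, gamma = h$gamma,
                              select_k = m$selection_k),
    "rbm-svm" = learner_hybrid(source = "pretrained-stack",
                               architecture = m$architecture, control = control,
                               cd = cd, encoding = encoding_from(cfg),
                               layer_index = h$layer_index, kernel = h$kernel,
                               cost = h$cost, gamma = h$gamma,
                               select_k = m$selection_k),
    "autoencoder-svm" = learner_hybrid(source = "autoencoder", control = control,
                                       cd = cd, hidden = m$hidden,
                                       kernel = h$kernel, cost = h$cost,
                                       gamma = h$gamma, select_k = m$selection_k)
  )
}

#' Run commands: simulate, train, evaluate, extract
#'
#' The package's reproducible-run entry points, also exposed through the
#' `dbnexpr` command-line wrapper installed under `exec/`. Each command
#' validates its configuration (see [load_run_config()]), performs its stage,
#' writes its outputs under `out_dir`, and writes the fully-resolved
#' configuration (`resolved_config.yaml`) next to them; re-running from that
#' file reproduces the outputs bit-exact.
#'
#' * `cmd_simulate()` generates a synthetic dataset
#'   ([simulate_expression()]) and writes the expression/label TSV pair plus
#'   the ground-truth differential gene indices.
#' * `cmd_train()` loads the task data, fits the configured model (DBN or
#'   autoencoder), and writes the model container and the per-epoch training
#'   history.
#' * `cmd_evaluate()` runs [cross_validate()] for the configured classifier
#'   and writes the fold-level and summary report tables.
#' * `cmd_extract()` loads a model container and writes the extracted
#'   feature matrix for the task data as TSV.
#'
#' @param config a config list from [load_run_config()], or a path to a YAML
#'   file.
#' @param out_dir output directory (created if needed).
#' @param verbose emit stage-level log lines.
#' @return The main output of the command, invisibly (dataset, model,
#'   `cv_report`, or feature matrix).
#' @name run-commands
NULL

as_run_config <- function(config) {
  if (inherits(config, "run_config")) config else load_run_config(config)
}

#' @rdname run-commands
#' @export
cmd_simulate <- function(config, out_dir, verbose = FALSE) {
  cfg <- as_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  s <- cfg$simulate
  log_line("simulate: %d classes, %d genes", length(s$n_per_class), s$n_genes,
           verbose = verbose)
  sim <- simulate_expression(s$n_per_class, s$n_genes, s$n_differential,
                             effect_size = s$effect_size, noise_sd = s$noise_sd,
                             baseline_mean = s$baseline_mean,
                             baseline_sd = s$baseline_sd,
                             seed = derive_seed(cfg$seed, 10))
  write_expression_dataset(sim$dataset, file.path(out_dir, "synthetic"))
  jsonlite::write_json(sim$differential,
                       file.path(out_dir, "synthetic_differential.json"),
                       auto_unbox = FALSE)
  write_resolved_config(cfg, out_dir)
  invisible(sim$dataset)
}

#' @rdname run-commands
#' @export
cmd_train <- function(config, out_dir, verbose = FALSE) {
  cfg <- as_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- load_task_dataset(cfg)
  m <- cfg$model
  log_line("train: %s on %d x %d", m$type, nrow(ds$expression),
           ncol(ds$expression), verbose = verbose)
  fit <- if (m$type == "dbn") {
    if (is.null(ds$labels)) config_error("training a dbn requires task$labels")
    dbn(ds, architecture = m$architecture, control = train_control_from(cfg),
        cd = cd_control_from(cfg), encoding = encoding_from(cfg),
        pretrain = m$pretrain, select_k = m$selection_k)
  } else {
    autoencoder(ds, hidden = m$hidden, control = train_control_from(cfg),
                cd = cd_control_from(cfg), select_k = m$selection_k)
  }
  write_model(fit, file.path(out_dir, "model.json"))
  utils::write.table(fit$history, file.path(out_dir, "history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_resolved_config(cfg, out_dir)
  invisible(fit)
}

#' @rdname run-commands
#' @export
cmd_evaluate <- function(config, out_dir, verbose = FALSE) {
  cfg <- as_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- load_task_dataset(cfg)
  if (is.null(ds$labels)) config_error("evaluation requires task$labels")
  e <- cfg$evaluation
  log_line("evaluate: %s, %d-fold CV", e$classifier, e$k, verbose = verbose)
  report <- cross_validate(ds, learner_from_config(cfg), k = e$k,
                           balance = e$balance, stratify = e$stratify,
                           selection_scope = cfg$model$selection_scope,
                           positive = cfg$task$positive_class, seed = cfg$seed)
  write_cv_report(report, file.path(out_dir, "report"))
  write_resolved_config(cfg, out_dir)
  invisible(report)
}

#' @rdname run-commands
#' @export
cmd_extract <- function(config, out_dir, verbose = FALSE) {
  cfg <- as_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cfg$model_path)) config_error("'model_path' is required for extract")
  model <- read_model(cfg$model_path)
  ds <- load_task_dataset(cfg)
  source <- if (inherits(model, "autoencoder")) "autoencoder"
            else cfg$hybrid$source
  ext <- representation_extractor(source, model, cfg$hybrid$layer_index)
  feats <- extract_features(ext, ds)
  log_line("extract: %d x %d features", nrow(feats), ncol(feats),
           verbose = verbose)
  out <- data.frame(sample_id = rownames(ds$expression), feats,
                    check.names = FALSE)
  utils::write.table(out, file.path(out_dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_resolved_config(cfg, out_dir)
  invisible(feats)
}

#' Command-line entry point
#'
#' Dispatches `simulate`, `train`, `evaluate`, or `extract` from character
#' arguments (`--config <file>`, `--out <dir>`, `--seed <int>`,
#' `--verbose`). Returns the process exit code: 0 on success, 2 on
#' configuration/validation errors, 1 on runtime errors. The installed
#' `exec/dbnexpr` script is a thin wrapper around this function.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit code, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: dbnexpr <simulate|train|evaluate|extract> --config <yaml> --out <dir> [--seed <int>] [--verbose]"
  code <- tryCatch({
    if (!length(args)) stop(errorCondition(usage, class = "dbnexpr_config_error"))
    cmd <- args[1]
    opts <- list(config = NULL, out = ".", seed = NULL, verbose = FALSE)
    i <- 2
    while (i <= length(args)) {
      a <- args[i]
      if (a == "--config") { opts$config <- args[i + 1]; i <- i + 2 }
      else if (a == "--out") { opts$out <- args[i + 1]; i <- i + 2 }
      else if (a == "--seed") { opts$seed <- as.integer(args[i + 1]); i <- i + 2 }
      else if (a == "--verbose") { opts$verbose <- TRUE; i <- i + 1 }
      else stop(errorCondition(paste("unknown argument:", a),
                               class = "dbnexpr_config_error"))
    }
    overrides <- if (!is.null(opts$seed)) list(seed = opts$seed)
    cfg <- load_run_config(opts$config, overrides = overrides)
    fun <- switch(cmd,
                  simulate = cmd_simulate, train = cmd_train,
                  evaluate = cmd_evaluate, extract = cmd_extract,
                  stop(errorCondition(paste("unknown command:", cmd, "\n", usage),
                                      class = "dbnexpr_config_error")))
    fun(cfg, opts$out, verbose = opts$verbose)
    0L
  },
  dbnexpr_config_error = function(e) { message("config error: ", conditionMessage(e)); 2L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(code)
}
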