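#' Validate an experiment configuration file
#'
#' Parses a YAML experiment configuration and lists *all* violations found,
#' not just the first. See [run_experiment()] for the schema.
#'
#' @param path Path to a YAML configuration file, or an already-parsed list.
#' @return A tibble with columns `field` and `message`; zero rows means the
#'   configuration is valid.
#' @export
validate_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    tryCatch(yaml::read_yaml(path), error = function(e) {
      abort(paste0("cannot parse configuration file: ", conditionMessage(e)),
            class = "bwasrep_parse_error")
    })
  }
  v <- list()
  bad <- function(field, message) {
    v[[length(v) + 1]] <<- tibble::tibble(field = field, message = message)
  }

  data_cfg <- cfg$data
  has_syn <- !is.null(data_cfg$synthetic)
  has_files <- !is.null(data_cfg$files)
  if (has_syn + has_files != 1) {
    bad("data", "exactly one data source (`synthetic` or `files`) is required.")
  }
  n_samples <- NULL
  if (has_syn) {
    syn <- data_cfg$synthetic
    n_samples <- syn$n_samples
    chk <- function(field, value, lower, upper = Inf, open_upper = FALSE) {
      if (is.null(value)) return(invisible())
      ok <- is.numeric(value) && length(value) == 1 && is.finite(value) &&
        value >= lower && (if (open_upper) value < upper else value <= upper)
      if (!ok) bad(paste0("data.synthetic.", field),
                   sprintf("must be a number in [%s, %s%s.", format(lower),
                           format(upper), if (open_upper) ")" else "]"))
    }
    chk("n_samples", syn$n_samples, 4)
    chk("n_features", syn$n_features, 1)
    chk("rho_true", syn$rho_true, 0, 1, open_upper = TRUE)
    chk("block_rho", syn$block_rho, 0, 1, open_upper = TRUE)
    if (!is.null(syn$n_signal) && !is.null(syn$n_features) &&
        is.numeric(syn$n_signal) && is.numeric(syn$n_features) &&
        syn$n_signal > syn$n_features) {
      bad("data.synthetic.n_signal", "must not exceed n_features.")
    }
  }
  if (has_files) {
    fl <- data_cfg$files
    for (f in c("features", "phenotype")) {
      if (is.null(fl[[f]])) {
        bad(paste0("data.files.", f), "path is required.")
      } else if (!file.exists(fl[[f]])) {
        bad(paste0("data.files.", f), sprintf("file not found: %s", fl[[f]]))
      }
    }
  }

  bm <- cfg$benchmark
  if (is.null(bm)) {
    bad("benchmark", "a benchmark block is required.")
  } else {
    if (!is.null(bm$alpha) &&
        (!is.numeric(bm$alpha) || bm$alpha <= 0 || bm$alpha >= 1)) {
      bad("benchmark.alpha", "must lie strictly between 0 and 1.")
    }
    if (!is.null(bm$n_grid)) {
      if (!is.numeric(bm$n_grid) || length(bm$n_grid) < 1 ||
          any(diff(bm$n_grid) <= 0)) {
        bad("benchmark.n_grid", "must be a strictly increasing numeric vector.")
      } else if (!is.null(n_samples) && is.numeric(n_samples) &&
                 2 * max(bm$n_grid) > n_samples) {
        bad("benchmark.n_grid",
            sprintf("2 * max(n_grid) = %d exceeds n_samples = %d.",
                    2L * as.integer(max(bm$n_grid)), as.integer(n_samples)))
      }
    }
    if (!is.null(bm$n_bootstrap) &&
        (!is.numeric(bm$n_bootstrap) || bm$n_bootstrap < 1)) {
      bad("benchmark.n_bootstrap", "must be a positive integer.")
    }
    if (!is.null(bm$conditioning) &&
        !bm$conditioning %in% c("discovery_significant", "none",
                                "replication_significant", "both")) {
      bad("benchmark.conditioning", "unknown conditioning mode.")
    }
  }

  if (!is.null(cfg$model$family) &&
      !cfg$model$family %in% c("ridge", "pca_svr")) {
    bad("model.family", "must be `ridge` or `pca_svr`.")
  }
  nl <- cfg$nulls
  if (!is.null(nl)) {
    if (!is.null(nl$estimators) &&
        !all(nl$estimators %in% c("cv", "in_sample"))) {
      bad("nulls.estimators", "must be a subset of {cv, in_sample}.")
    }
    if (!is.null(nl$n_permutations) &&
        (!is.numeric(nl$n_permutations) || nl$n_permutations < 20)) {
      bad("nulls.n_permutations", "must be at least 20.")
    }
  }

  if (length(v) == 0) {
    tibble::tibble(field = character(), message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

config_model_spec <- function(model_cfg) {
  if (is.null(model_cfg)) return(model_spec("ridge"))
  do.call(model_spec, model_cfg)
}

#' Run a complete synthetic replicability experiment
#'
#' One call (or one YAML file) ties the stages together: generate or load a
#' dataset, run the discovery/replication benchmark, aggregate metrics,
#' derive minimal sample sizes, optionally run permutation-null analyses, and
#' write everything as plain CSV plus a run log. Re-running with the same
#' configuration reproduces all numeric outputs exactly.
#'
#' The YAML schema (all blocks except `data` and `benchmark` optional):
#' ```yaml
#' data:
#'   synthetic: {n_samples: 600, n_features: 100, rho_true: 0.3, seed: 1}
#'   # or files: {features: x.tsv, phenotype: y.tsv}
#' model: {family: ridge, ridge_shrinkage: 1}
#' benchmark: {n_grid: [50, 100], n_bootstrap: 20, alpha: 0.05, k_folds: 10,
#'             conditioning: discovery_significant, seed: 1}
#' nulls: {estimators: [cv, in_sample], n_grid: [100], n_permutations: 50}
#' min_n: {threshold: 0.8}
#' output_dir: out
#' ```
#'
#' @param config Path to a YAML file or an equivalent nested list.
#' @param out_dir Output directory (overrides the config's `output_dir`).
#' @param seed Master seed (overrides the config's `benchmark.seed`).
#' @param jobs Accepted for interface compatibility; execution is serial and
#'   the output is by construction independent of this value.
#' @param quiet Suppress progress messages.
#' @return (Invisibly) a list with the benchmark records, metrics table,
#'   min-n summary, any null summaries, and the paths written.
#' @export
run_experiment <- function(config, out_dir = NULL, seed = NULL, jobs = 1,
                           quiet = FALSE) {
  cfg <- if (is.list(config)) config else yaml::read_yaml(config)
  violations <- validate_config(cfg)
  if (nrow(violations) > 0) {
    abort(paste0(
      "invalid configuration:\n",
      paste0("  - ", violations$field, ": ", violations$message,
             collapse = "\n")
    ), class = "bwasrep_config_error")
  }
  out_dir <- out_dir %||% cfg$output_dir %||% "bwasrep_experiment"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  incomplete <- file.path(out_dir, "INCOMPLETE")
  file.create(incomplete)
  say <- function(...) if (!quiet) message(...)

  bm <- cfg$benchmark
  master_seed <- as.integer(seed %||% bm$seed %||% 1L)
  spec <- config_model_spec(cfg$model)

  result <- tryCatch({
    if (!is.null(cfg$data$synthetic)) {
      say("generating synthetic dataset ...")
      syn <- cfg$data$synthetic
      syn$seed <- syn$seed %||% derive_seed(master_seed, 1L)
      ds <- do.call(simulate_bwas_data, syn)
    } else {
      say("loading dataset from files ...")
      ds <- read_bwas_data(cfg$data$files$features, cfg$data$files$phenotype)
    }

    bench_cfg <- benchmark_config(
      n_grid = bm$n_grid %||% c(25, 50, 75, 100, 150, 200, 300, 400, 500),
      n_bootstrap = bm$n_bootstrap %||% 100,
      alpha = bm$alpha %||% 0.05,
      model = spec,
      k_folds = bm$k_folds %||% 10,
      conditioning = bm$conditioning %||% "discovery_significant",
      sidedness = bm$sidedness %||% "two_sided",
      seed = master_seed
    )
    say("running benchmark (", length(bench_cfg$n_grid), " grid sizes x ",
        bench_cfg$n_bootstrap, " replicates) ...")
    records <- run_benchmark(ds, bench_cfg)
    metrics <- aggregate_benchmark(records,
                                   seed = derive_seed(master_seed, 2L))

    thr <- cfg$min_n$threshold %||% 0.8
    minn_raw <- lapply(c(power = "power", p_rep = "p_rep"), function(m) {
      suppressWarnings(min_n(metrics, m, thr))
    })
    minn <- tibble::tibble(
      metric = names(minn_raw),
      threshold = thr,
      min_n = vapply(minn_raw, as.numeric, numeric(1)),
      label = vapply(minn_raw, attr, character(1), "label")
    )

    nulls <- NULL
    if (!is.null(cfg$nulls)) {
      say("running permutation-null analyses ...")
      nl <- cfg$nulls
      nulls <- dplyr::bind_rows(lapply(
        nl$estimators %||% "cv",
        function(est) {
          permutation_null(
            ds, spec, estimator = est,
            n_grid = nl$n_grid %||% min(200, nrow(ds)),
            n_permutations = nl$n_permutations %||% 100,
            k_folds = bench_cfg$k_folds,
            seed = derive_seed(master_seed, 3L)
          )
        }
      ))
    }

    paths <- list(
      records = file.path(out_dir, "records.csv"),
      metrics = file.path(out_dir, "metrics.csv"),
      min_n = file.path(out_dir, "min_n.csv"),
      log = file.path(out_dir, "run_log.txt")
    )
    readr::write_csv(tibble::as_tibble(records), paths$records)
    readr::write_csv(tibble::as_tibble(metrics), paths$metrics)
    readr::write_csv(minn, paths$min_n)
    if (!is.null(nulls)) {
      paths$nulls <- file.path(out_dir, "null_distribution.csv")
      readr::write_csv(tibble::as_tibble(nulls), paths$nulls)
    }

    log_lines <- c(
      paste0("bwasrep ", as.character(utils::packageVersion("bwasrep"))),
      paste0("R ", R.version.string),
      paste0("master_seed: ", master_seed),
      paste0("jobs (serial execution): ", jobs),
      "effective configuration:",
      strsplit(yaml::as.yaml(list(
        data = cfg$data,
        model = unclass(spec),
        benchmark = unclass(bench_cfg)[setdiff(names(bench_cfg), "model")],
        nulls = cfg$nulls,
        min_n = list(threshold = thr),
        output_dir = out_dir
      )), "\n")[[1]]
    )
    writeLines(log_lines, paths$log)
    unlink(incomplete)
    say("done: ", out_dir)
    list(records = records, metrics = metrics, min_n = minn, nulls = nulls,
         paths = paths)
  }, error = function(e) {
    writeLines(paste0("experiment failed: ", conditionMessage(e)), incomplete)
    abort(paste0("experiment failed (incomplete outputs marked in ", out_dir,
                 "): ", conditionMessage(e)),
          class = "bwasrep_experiment_error", parent = e)
  })
  invisible(result)
}
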