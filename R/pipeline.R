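## End-to-end orchestration: QC -> MWAS -> coding -> CV evaluation ->
## (optional) all-cross prediction, with a JSON manifest of every artifact,
## plus the command-line entry point (see inst/cli/mmgp.R).

validation_error <- function(...) {
  stop(structure(class = c("mmgp_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Assemble and validate a pipeline configuration
#'
#' @param genotypes,metabolome,parent_phenotypes,hybrid_phenotypes,crosses
#'   input file paths (delimited dialect); ignored when \code{simulate} is
#'   given.
#' @param metabolome_meta optional metabolite metadata path.
#' @param out_dir output directory.
#' @param traits traits to analyze; default all hybrid traits.
#' @param models model configurations to evaluate.
#' @param engines prediction engines ("kernel", "boosting").
#' @param maf_min,missing_max SNP QC thresholds.
#' @param replicate_alpha replicate-concordance threshold.
#' @param normalization "zscore" or "log-zscore".
#' @param mwas_alpha MWAS significance threshold.
#' @param marker_mode "per_fold" or "global" marker selection in CV.
#' @param k,repeats,seed cross-validation controls.
#' @param tissue optional tissue restriction of the metabolome.
#' @param predict_crosses logical: rank the full diallel after CV.
#' @param top_k selection size for the cross summary.
#' @param tune_boosting tune boosting hyperparameters per fold (slow).
#' @param n_trials TPE trials when tuning.
#' @param simulate optional list of \code{\link{sim_config}} arguments;
#'   when present the pipeline generates its own inputs.
#' @return list of class \code{PipelineConfig}.
#' @export
pipeline_config <- function(genotypes = NULL, metabolome = NULL,
                            parent_phenotypes = NULL,
                            hybrid_phenotypes = NULL, crosses = NULL,
                            metabolome_meta = NULL,
                            out_dir = "mmgp_out", traits = NULL,
                            models = c("GP", "MM_GP"),
                            engines = "kernel",
                            maf_min = 0.05, missing_max = 0.1,
                            replicate_alpha = 0.01,
                            normalization = "zscore",
                            mwas_alpha = 0.05,
                            marker_mode = "per_fold",
                            k = 10, repeats = 20, seed = 1,
                            tissue = NULL,
                            predict_crosses = FALSE, top_k = 100,
                            tune_boosting = FALSE, n_trials = 20,
                            simulate = NULL) {
  cfg <- as.list(environment())
  if (k < 2) validation_error("k must be >= 2 (got ", k, ")")
  if (repeats < 1) validation_error("repeats must be >= 1")
  if (is.null(seed)) validation_error("seed is required")
  bad <- setdiff(models, model_tags)
  if (length(bad)) validation_error("unknown models: ",
                                    paste(bad, collapse = ", "))
  bad <- setdiff(engines, c("kernel", "boosting"))
  if (length(bad)) validation_error("unknown engines: ",
                                    paste(bad, collapse = ", "))
  if (is.null(simulate)) {
    for (f in c("genotypes", "metabolome", "parent_phenotypes",
                "hybrid_phenotypes", "crosses")) {
      if (is.null(cfg[[f]]))
        validation_error("missing input path: ", f)
      if (!file.exists(cfg[[f]]))
        validation_error("input file not found: ", cfg[[f]])
    }
  }
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#' @param path configuration file; the schema mirrors
#'   \code{\link{pipeline_config}} arguments.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) validation_error("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      validation_error("YAML configs require the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

pipeline_log <- function(con, level, ...) {
  line <- sprintf("[%s] %-5s %s", format(Sys.time(), "%H:%M:%S"), level,
                  paste0(...))
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full analysis pipeline
#'
#' Stages: input/simulation, SNP QC and imputation, metabolome QC and
#' normalization, MWAS per trait, cross-validated evaluation of every
#' (model, engine) combination, optional all-cross prediction. Every
#' intermediate table is written under \code{out_dir} and listed in
#' \code{manifest.json}. A stage failure aborts with the stage name;
#' partial outputs are retained.
#'
#' @param config a \code{PipelineConfig}.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$out_dir, "pipeline.log")
  con <- file(logfile, open = "wt")
  on.exit(close(con), add = TRUE)
  artifacts <- list()
  stage <- function(name, expr) {
    pipeline_log(con, "INFO", "stage: ", name)
    tryCatch(expr, error = function(e) {
      pipeline_log(con, "ERROR", name, ": ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           "\n  (partial outputs kept under ", config$out_dir, ")",
           call. = FALSE)
    })
  }
  emit <- function(key, path) {
    artifacts[[key]] <<- basename(path)
    path
  }

  inputs <- stage("input", {
    if (!is.null(config$simulate)) {
      sim <- do.call(sim_config, config$simulate)
      bundle <- simulate_dataset(sim, dir = file.path(config$out_dir,
                                                      "simulated_inputs"))
      list(G = bundle$data$genotypes, raw_met = bundle$raw,
           parent_ph = bundle$data$parent_phenotypes,
           hybrid_ph = bundle$data$hybrid_phenotypes,
           crosses = bundle$data$crosses, truth = bundle$truth,
           premet = bundle$data$metabolome)
    } else {
      G <- read_genotypes(config$genotypes)
      raw_met <- read_metabolome(config$metabolome,
                                 meta_path = config$metabolome_meta)
      list(G = G, raw_met = raw_met,
           parent_ph = read_phenotypes(config$parent_phenotypes),
           hybrid_ph = read_phenotypes(config$hybrid_phenotypes),
           crosses = read_crosses(config$crosses, genotypes = G),
           premet = NULL)
    }
  })

  G <- stage("snp_qc", {
    G <- filter_snps(inputs$G, config$maf_min, config$missing_max)
    G <- impute_missing(G)
    write_genotypes(G, emit("genotypes_qc",
                            file.path(config$out_dir, "genotypes_qc.tsv")))
    G
  })

  Mline <- stage("metabolome_qc", {
    if (!is.null(inputs$premet)) {
      Mline <- inputs$premet  # simulation already ran the standard prep
    } else {
      mx <- inputs$raw_met
      if (!is.null(config$tissue)) mx <- subset_metabolome(mx, config$tissue)
      if (!is.null(mx$replicate)) {
        qc <- replicate_concordance_filter(mx, config$replicate_alpha)
        write_qc_report(qc$report,
                        emit("metabolite_qc",
                             file.path(config$out_dir,
                                       "metabolite_qc.tsv")))
        mx <- qc$metabolome
      }
      Mline <- normalize_metabolome(average_replicates(mx),
                                    method = config$normalization)
    }
    write_metabolome(Mline, emit("metabolome_norm",
                                 file.path(config$out_dir,
                                           "metabolome_normalized.tsv")))
    Mline
  })

  data <- stage("bundle", {
    mmgp_data(G, Mline, inputs$parent_ph, inputs$hybrid_ph, inputs$crosses)
  })

  traits <- config$traits
  if (is.null(traits)) traits <- colnames(data$hybrid_phenotypes$values)

  mwas_results <- stage("mwas", {
    out <- list()
    for (tr in traits) {
      res <- lasso_entry_pvalues(Mline, data$parent_phenotypes, tr,
                                 alpha = config$mwas_alpha)
      f <- file.path(config$out_dir, paste0("mwas_", tr, ".tsv"))
      write_mwas(res, emit(paste0("mwas_", tr), f))
      out[[tr]] <- res
    }
    out
  })

  cv_results <- stage("cv", {
    out <- list()
    for (tr in traits) for (mtag in config$models)
      for (eng in config$engines) {
        key <- paste(tr, mtag, eng, sep = "_")
        cv <- cross_validate(data, tr, mtag, engine = eng, k = config$k,
                             repeats = config$repeats, seed = config$seed,
                             alpha = config$mwas_alpha,
                             marker_mode = if (
                               model_uses_markers(mtag)) config$marker_mode
                               else "per_fold",
                             tune = config$tune_boosting,
                             n_trials = config$n_trials)
        f <- file.path(config$out_dir, paste0("cv_", key, ".tsv"))
        write_cv_result(cv, emit(paste0("cv_", key), f))
        pipeline_log(con, "INFO", sprintf(
          "  %s: mean ability %.3f (SD %.3f)", key, cv$mean_ability,
          cv$sd_ability))
        out[[key]] <- cv
      }
    out
  })

  stage("compare", {
    for (tr in traits) for (eng in config$engines) {
      rs <- cv_results[paste(tr, config$models, eng, sep = "_")]
      rs <- rs[!vapply(rs, is.null, logical(1))]
      if (length(rs) >= 2) {
        cmp <- compare_models(rs)
        f <- file.path(config$out_dir,
                       paste0("comparison_", tr, "_", eng, ".tsv"))
        data.table::fwrite(cmp$table, f, sep = "\t", quote = FALSE)
        emit(paste0("comparison_", tr, "_", eng), f)
      }
    }
    NULL
  })

  if (isTRUE(config$predict_crosses)) {
    stage("predict_crosses", {
      for (tr in traits) {
        tab <- predict_all_crosses(data, tr,
                                   model_tag = config$models[length(
                                     config$models)],
                                   engine = config$engines[1],
                                   alpha = config$mwas_alpha,
                                   seed = config$seed)
        f <- file.path(config$out_dir, paste0("crosses_", tr, ".tsv"))
        write_cross_predictions(tab, emit(paste0("crosses_", tr), f))
        s <- top_bottom_summary(tab, k = min(config$top_k, nrow(tab)))
        gain <- selection_gain(s$top_mean, s$population_mean)
        pipeline_log(con, "INFO", sprintf(
          "  %s: top-%d mean %.3f, population %.3f, gain %.1f%%",
          tr, s$k, s$top_mean, s$population_mean, gain$percent))
      }
      NULL
    })
  }

  manifest <- stage("manifest", {
    inp <- config[c("genotypes", "metabolome", "parent_phenotypes",
                    "hybrid_phenotypes", "crosses")]
    inp <- inp[!vapply(inp, is.null, logical(1))]
    man <- list(
      package_version = as.character(utils::packageVersion("mmgp")),
      r_version = R.version.string,
      seed = config$seed,
      traits = traits, models = config$models, engines = config$engines,
      input_checksums = if (length(inp))
        as.list(tools::md5sum(unlist(inp))) else NULL,
      artifacts = artifacts,
      log = basename(logfile))
    jsonlite::write_json(man, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null")
    man
  })
  pipeline_log(con, "INFO", "pipeline complete")
  invisible(manifest)
}

## ------------------------------------------------------------------- CLI

parse_cli_args <- function(args) {
  opts <- list(); pos <- character()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (grepl("^--[A-Za-z_]+=", a)) {
      key <- sub("^--", "", sub("=.*$", "", a))
      opts[[key]] <- sub("^--[A-Za-z_]+=", "", a)
    } else if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (i < length(args) && !grepl("^--", args[i + 1])) {
        opts[[key]] <- args[i + 1]; i <- i + 1
      } else opts[[key]] <- TRUE
    } else pos <- c(pos, a)
    i <- i + 1
  }
  list(opts = opts, positional = pos)
}

coerce_cli_value <- function(x) {
  if (!is.character(x)) return(x)
  if (grepl(",", x)) return(strsplit(x, ",")[[1]])
  if (x %in% c("true", "TRUE")) return(TRUE)
  if (x %in% c("false", "FALSE")) return(FALSE)
  num <- suppressWarnings(as.numeric(x))
  if (!is.na(num)) return(num)
  x
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate}, \code{qc}, \code{mwas}, \code{code},
#' \code{cv}, \code{predict-crosses}, \code{run}. Options mirror
#' \code{\link{pipeline_config}} keys (\code{--key value} or
#' \code{--key=value}); \code{--config path} loads a YAML/JSON file whose
#' values are overridden by explicit flags. Exit codes: 0 success,
#' 2 validation error, 1 runtime failure (applied by the wrapper script
#' in \code{inst/cli/mmgp.R}).
#'
#' @param args character vector, defaults to \code{commandArgs(TRUE)}.
#' @return 0 on success (invisibly); raises conditions on failure.
#' @export
mmgp_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  parsed <- parse_cli_args(args)
  cmd <- if (length(parsed$positional)) parsed$positional[1] else "help"
  opts <- lapply(parsed$opts, coerce_cli_value)
  cfg_args <- list()
  if (!is.null(opts$config)) {
    path <- opts$config
    cfg_args <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
      else jsonlite::read_json(path, simplifyVector = TRUE)
    opts$config <- NULL
  }
  sim_keys <- names(formals(sim_config))
  sim_args <- opts[intersect(names(opts), sim_keys)]
  opts_cfg <- opts[intersect(names(opts), names(formals(pipeline_config)))]
  cfg_args[names(opts_cfg)] <- opts_cfg

  if (cmd == "help" || cmd == "--help") {
    cat("usage: mmgp <simulate|qc|mwas|cv|predict-crosses|run> [--key value]\n",
        "       options mirror pipeline_config() / sim_config() arguments\n")
    return(invisible(0))
  }
  if (cmd == "simulate") {
    out <- if (!is.null(opts$out_dir)) opts$out_dir else "mmgp_sim"
    cfgs <- do.call(sim_config, sim_args)
    simulate_dataset(cfgs, dir = out)
    message("simulated dataset written to ", out)
    return(invisible(0))
  }
  stagemap <- list(qc = list(models = character(0),
                             predict_crosses = FALSE),
                   mwas = list(models = character(0),
                               predict_crosses = FALSE),
                   code = list(models = character(0),
                               predict_crosses = FALSE),
                   cv = list(predict_crosses = FALSE),
                   `predict-crosses` = list(predict_crosses = TRUE),
                   run = list())
  if (!cmd %in% names(stagemap))
    validation_error("unknown subcommand: ", cmd)
  cfg_args[names(stagemap[[cmd]])] <- stagemap[[cmd]]
  if (length(sim_args) && is.null(cfg_args$simulate) &&
      !is.null(opts$simulate))
    cfg_args$simulate <- sim_args
  cfg <- do.call(pipeline_config, cfg_args)
  run_pipeline(cfg)
  invisible(0)
}
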