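# End-to-end pipeline: generate or load a corpus, preprocess, decompose,
# build feature tables, cross-validate the predictors and evaluate the
# closed loop, writing every artifact (with config and seed provenance)
# under one output directory.

#' Pipeline configuration
#'
#' @param input Optional CSV path of recorded kinematics; if `NULL`, a
#'   synthetic corpus of `n_reaches` is generated.
#' @param n_reaches Synthetic corpus size (ignored when `input` is given).
#' @param out_dir Output directory for artifacts.
#' @param seed Master seed; every random draw in the pipeline flows from it.
#' @param generator A [generator_config()].
#' @param decomposition A [decomposition_config()].
#' @param training A [training_config()].
#' @param simulation A [simulation_config()].
#' @param features A [feature_config()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, n_reaches = 50,
                            out_dir = "submovekit_run", seed = 0,
                            generator = generator_config(),
                            decomposition = decomposition_config(),
                            training = training_config(),
                            simulation = simulation_config(),
                            features = feature_config()) {
  structure(as.list(environment()), class = "pipeline_config")
}

decomp_to_json <- function(decomps, path) {
  ser <- lapply(decomps, function(d) list(
    trial_id = d$trial_id, n_star = d$n_star,
    cost_curve = d$cost_curve, n_range = d$n_range,
    recon_vaf = d$recon_vaf,
    submovements = lapply(d$submovements, function(s)
      list(t0 = s$t0, D = s$D, A = s$A))))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes synthesis/loading, preprocessing, decomposition, feature-table
#' construction, 10-fold cross-validated training, and closed-loop
#' evaluation. Artifacts written under `cfg$out_dir`: the corpus CSV (when
#' synthetic), the per-trial decomposition JSON, a trained model JSON (the
#' first fold's networks), and a report JSON whose keys mirror the
#' performance-table row names (per-submovement VAF, sensitivity,
#' specificity, target acquisition rate, end distances, RMSE, VAF).
#'
#' @param cfg A [pipeline_config()].
#' @param verbose Emit progress messages.
#' @return The report, invisibly (a named list).
#' @export
run_pipeline <- function(cfg = pipeline_config(), verbose = TRUE) {
  if (!is.null(cfg$input) && !file.exists(cfg$input))
    stop("run_pipeline: input file not found: ", cfg$input, call. = FALSE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  if (is.null(cfg$input)) {
    say("generating %d synthetic reaches (seed %d)", cfg$n_reaches, cfg$seed)
    corpus <- synth_corpus(cfg$n_reaches, cfg$generator, seed = cfg$seed)
    export_corpus(corpus, file.path(cfg$out_dir, "corpus.csv"),
                  file.path(cfg$out_dir, "corpus_truth.json"))
    dataset <- corpus$dataset
  } else {
    say("loading %s", cfg$input)
    dataset <- load_dataset(cfg$input)
  }
  say("preprocessing %d trials", length(dataset$trials))
  dataset <- preprocess_dataset(dataset)
  say("decomposing %d trials", length(dataset$trials))
  dcfg <- cfg$decomposition
  if (is.null(dcfg$seed)) dcfg$seed <- cfg$seed
  decomps <- decompose_dataset(dataset, dcfg, verbose = FALSE)
  decomp_to_json(decomps, file.path(cfg$out_dir, "decomposition.json"))
  say("building feature tables")
  tables <- build_training_tables(dataset, decomps, cfg$features)
  say("cross-validated training and closed-loop evaluation")
  tcfg <- cfg$training; tcfg$seed <- cfg$seed
  cv <- crossval_evaluate(dataset, tables, tcfg, sim_cfg = cfg$simulation,
                          feature_cfg = cfg$features)
  save_model(cv$nets_by_fold[[1]], file.path(cfg$out_dir, "model.json"))
  n_star <- vapply(decomps, `[[`, 0L, "n_star")
  report <- list(
    seed = cfg$seed,
    n_reaches = length(dataset$trials),
    mean_submovements_per_reach = mean(n_star),
    submovement_count_range = range(n_star),
    mean_recon_vaf = mean(vapply(decomps, `[[`, 0, "recon_vaf")),
    initiation_vaf_2nd = cv$initiation$vaf_2nd,
    initiation_vaf_3rd = cv$initiation$vaf_3rd,
    initiation_vaf_overall = cv$initiation$vaf_overall,
    sensitivity = cv$initiation$sensitivity,
    specificity = cv$initiation$specificity,
    duration_vaf_1st = cv$duration$vaf_1st,
    duration_vaf_2nd = cv$duration$vaf_2nd,
    duration_vaf_3rd = cv$duration$vaf_3rd,
    duration_vaf_overall = cv$duration$vaf_overall,
    amplitude_vaf_1st = cv$amplitude$vaf_1st,
    amplitude_vaf_2nd = cv$amplitude$vaf_2nd,
    amplitude_vaf_3rd = cv$amplitude$vaf_3rd,
    amplitude_vaf_overall = cv$amplitude$vaf_overall,
    target_acquisition_rate = cv$closed_loop$acquisition_rate,
    end_distance_mean = cv$closed_loop$end_distance_mean,
    end_distance_sd = cv$closed_loop$end_distance_sd,
    end_distance_failed_mean = cv$closed_loop$end_distance_failed_mean,
    closed_loop_rmse = cv$closed_loop$rmse,
    closed_loop_vaf = cv$closed_loop$vaf)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE)
  say("done; artifacts in %s", cfg$out_dir)
  invisible(report)
}
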