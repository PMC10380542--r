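# End-to-end pipeline orchestration: simulate/ingest -> preprocess ->
# split -> train cascade -> evaluate -> select bands -> re-evaluate on the
# selected bands, with a reproducibility manifest.

#' Pipeline configuration
#'
#' @param out_dir Output directory for all artifacts.
#' @param domain `"THz"` or `"NIR"` (selects the default simulation design
#'   and keep interval).
#' @param spectra_csv Optional path to an existing per-seed spectrum CSV
#'   (as written by [write_spectrum_csv()]); when `NULL`, the bundled
#'   synthetic design is simulated.
#' @param n_per_cell Samples per (variety, GM) cell when simulating.
#' @param seed Global RNG seed recorded in every artifact.
#' @param epochs,learning_rate,batch_size Cascade training parameters.
#' @param gm_epochs Epochs for the per-variety GM models (`NULL`: same as
#'   `epochs`; the subtler GM contrast usually needs more).
#' @param split_ratio Train fraction of the 7:3-style split.
#' @param guided_iterations Guided-backpropagation iterations.
#' @param spa_max_k Maximum SPA subset size.
#' @param resume Reuse artifacts already present in `out_dir`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, domain = c("THz", "NIR"),
                            spectra_csv = NULL, n_per_cell = 200L,
                            seed = 1L, epochs = 40L, gm_epochs = 120L,
                            learning_rate = 5e-4,
                            batch_size = 64L, split_ratio = 0.7,
                            guided_iterations = 600L, spa_max_k = 13L,
                            resume = FALSE) {
  domain <- match.arg(domain)
  structure(list(out_dir = out_dir, domain = domain,
                 spectra_csv = spectra_csv, n_per_cell = as.integer(n_per_cell),
                 seed = as.integer(seed), epochs = as.integer(epochs),
                 gm_epochs = if (!is.null(gm_epochs)) as.integer(gm_epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 split_ratio = split_ratio,
                 guided_iterations = as.integer(guided_iterations),
                 spa_max_k = as.integer(spa_max_k), resume = isTRUE(resume)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

# Hash of the scientific configuration only: where outputs land (and
# whether stages are resumed) must not change the recorded identity of a
# run.
config_hash <- function(cfg) {
  u <- unclass(cfg)
  u$out_dir <- NULL
  u$resume <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(u, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full discrimination pipeline
#'
#' Executes simulate/ingest, preprocessing, the stratified split, cascade
#' training, evaluation (variety, GM, joint and cross-variety), band
#' selection (guided backpropagation and SPA), and a re-evaluation of an
#' RBF-SVM (C = 100) restricted to the guided-selected bands. Every
#' artifact is written under `cfg$out_dir` and listed, with its MD5 hash,
#' in `manifest.json`; a stage failure marks the manifest and halts
#' downstream stages.
#'
#' @param cfg A [pipeline_config()].
#' @return The run manifest (list), invisibly on write.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) stop("expected a `pipeline_config`", call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(cfg), config_hash = config_hash(cfg),
                   seed = cfg$seed, started = format(Sys.time(), tz = "UTC"),
                   stages = list(), artifacts = list())
  art_path <- function(name) file.path(cfg$out_dir, name)
  add_artifact <- function(name) {
    manifest$artifacts[[name]] <<- list(
      path = name, md5 = unname(tools::md5sum(art_path(name))),
      config_hash = manifest$config_hash, seed = cfg$seed)
  }
  run_stage <- function(name, fun) {
    t0 <- proc.time()[3]
    res <- tryCatch(fun(), error = function(e) e)
    status <- if (inherits(res, "error")) "failed" else "ok"
    manifest$stages[[name]] <<- list(
      status = status, seconds = round(proc.time()[3] - t0, 2),
      error = if (status == "failed") conditionMessage(res))
    message(sprintf("[%s] stage %-12s %s (%.1fs)",
                    format(Sys.time(), "%H:%M:%S"), name, status,
                    proc.time()[3] - t0))
    if (status == "failed") {
      write_manifest()
      stop("pipeline stage `", name, "` failed: ", conditionMessage(res),
           call. = FALSE)
    }
    res
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, art_path("manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  # 1. simulate or ingest
  spectra <- run_stage("ingest", function() {
    f <- art_path("spectra_raw.csv")
    if (cfg$resume && file.exists(f)) return(read_spectrum_csv(f))
    set <- if (!is.null(cfg$spectra_csv)) {
      read_spectrum_csv(cfg$spectra_csv)
    } else {
      design <- if (cfg$domain == "THz") {
        sim_design_thz(n_per_cell = cfg$n_per_cell, rng_seed = cfg$seed)
      } else {
        sim_design_nir(n_per_cell = cfg$n_per_cell, rng_seed = cfg$seed)
      }
      simulate_spectrum_set(design)
    }
    write_spectrum_csv(set, f)
    set
  })
  add_artifact("spectra_raw.csv")

  # 2. preprocess
  prep <- run_stage("preprocess", function() {
    f <- art_path("spectra_preprocessed.csv")
    if (cfg$resume && file.exists(f)) return(read_spectrum_csv(f))
    out <- preprocess_spectra(spectra)
    write_spectrum_csv(out, f)
    out
  })
  add_artifact("spectra_preprocessed.csv")

  # 3. split
  plan <- run_stage("split", function() {
    split_dataset(prep, ratio = cfg$split_ratio, rng_seed = cfg$seed)
  })
  train_set <- subset_samples(prep, plan$train)
  test_set <- subset_samples(prep, plan$test)

  # 4. train cascade
  cascade <- run_stage("train", function() {
    tcfg <- train_config(epochs = cfg$epochs,
                         learning_rate = cfg$learning_rate,
                         batch_size = cfg$batch_size, rng_seed = cfg$seed)
    gcfg2 <- tcfg
    if (!is.null(cfg$gm_epochs)) gcfg2$epochs <- cfg$gm_epochs
    model_dir <- art_path("models")
    stem1 <- file.path(model_dir, "cascadeseed1")
    if (cfg$resume && file.exists(paste0(stem1, ".json"))) {
      m1 <- load_cascadeseed(stem1)
      reg <- list()
      for (v in sort(unique(train_set$variety))) {
        reg[[v]] <- load_cascadeseed(file.path(model_dir, paste0("cascadeseed2_", v)))
      }
      return(cascade_model(m1, reg))
    }
    cas <- train_cascade(train_set, tcfg, rng_seed = cfg$seed, gm_cfg = gcfg2)
    dir.create(model_dir, showWarnings = FALSE)
    save_cascadeseed(cas$variety_model, stem1)
    for (v in names(cas$gm_registry)) {
      save_cascadeseed(cas$gm_registry[[v]], file.path(model_dir, paste0("cascadeseed2_", v)))
    }
    cas
  })

  # 5. evaluate
  reports <- run_stage("evaluate", function() {
    pred <- cascade_predict(cascade, test_set)
    utils::write.csv(pred, art_path("predictions.csv"), row.names = FALSE)
    variety_rep <- evaluate_predictions(test_set$variety, pred$variety,
                                        cascade$variety_model$classes)
    joint_true <- paste(test_set$variety, test_set$gm, sep = "-")
    joint_pred <- paste(pred$variety, pred$gm, sep = "-")
    joint_rep <- evaluate_predictions(joint_true, joint_pred,
                                      sort(unique(c(joint_true, joint_pred))))
    gm_acc <- vapply(names(cascade$gm_registry), function(v) {
      rows <- test_set$variety == v
      mean(pred$gm[rows] == test_set$gm[rows])
    }, numeric(1))
    per_v_tests <- lapply(names(cascade$gm_registry), function(v) {
      subset_samples(test_set, test_set$variety == v)
    })
    names(per_v_tests) <- names(cascade$gm_registry)
    transfer <- cross_variety_matrix(cascade$gm_registry, per_v_tests)
    utils::write.csv(as.data.frame(variety_rep$confusion),
                     art_path("confusion_variety.csv"))
    utils::write.csv(as.data.frame(transfer), art_path("cross_variety.csv"))
    jsonlite::write_json(
      list(variety_accuracy = variety_rep$accuracy,
           variety_macro_f1 = variety_rep$macro_f1,
           variety_micro_f1 = variety_rep$micro_f1,
           gm_accuracy_per_variety = as.list(gm_acc),
           joint_accuracy = joint_rep$accuracy,
           seed = cfg$seed, config_hash = manifest$config_hash),
      art_path("evaluation.json"), auto_unbox = TRUE, digits = NA)
    list(variety = variety_rep, joint = joint_rep, gm_acc = gm_acc,
         transfer = transfer)
  })
  add_artifact("predictions.csv")
  add_artifact("confusion_variety.csv")
  add_artifact("cross_variety.csv")
  add_artifact("evaluation.json")

  # 6. select bands
  selection <- run_stage("select", function() {
    gcfg <- guided_config(iterations = cfg$guided_iterations,
                          rng_seed = cfg$seed)
    guided <- guided_select(cascade$variety_model, gcfg,
                            band_axis = prep$band_axis, task = "variety")
    spa <- spa_select(train_set, max_k = cfg$spa_max_k, label = "variety",
                      rng_seed = cfg$seed)
    for (sel in list(guided, spa)) {
      jsonlite::write_json(
        list(method = sel$method, task = sel$task, indices = sel$indices,
             centers = sel$centers,
             per_class = sel$per_class, score = sel$score,
             seed = cfg$seed, config_hash = manifest$config_hash),
        art_path(sprintf("selection_%s.json", tolower(sel$method))),
        auto_unbox = TRUE, digits = NA, null = "null")
    }
    list(guided = guided, spa = spa)
  })
  add_artifact("selection_guided.json")
  add_artifact("selection_spa.json")

  # 7. re-evaluate an SVM on the selected bands
  run_stage("reevaluate", function() {
    idx <- selection$guided$indices
    svm <- svm_fit(subset_bands(train_set, idx), C = 100, label = "variety")
    pred <- svm_predict(svm, subset_bands(test_set, idx))
    rep <- evaluate_predictions(test_set$variety, pred,
                                sort(unique(train_set$variety)))
    jsonlite::write_json(
      list(classifier = "svm_c100", bands_used = length(idx),
           band_indices = idx, accuracy = rep$accuracy,
           macro_f1 = rep$macro_f1, seed = cfg$seed,
           config_hash = manifest$config_hash),
      art_path("evaluation_selected.json"), auto_unbox = TRUE, digits = NA)
    rep
  })
  add_artifact("evaluation_selected.json")

  manifest$finished <- format(Sys.time(), tz = "UTC")
  write_manifest()
  add_artifact("manifest.json")
  write_manifest()
  invisible(manifest)
}
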