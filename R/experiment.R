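# End-to-end experiment orchestration ------------------------------------------

# Small stable polynomial hash over the serialized object so every output
# table can carry a config fingerprint for audit.
config_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  h <- 0
  for (b in as.integer(bytes)) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Experiment configuration
#'
#' Either construct programmatically or load from a YAML/JSON file whose
#' top-level keys mirror the arguments.
#'
#' @param cohort A [cohort_config()] for synthetic data, or a directory path
#'   of a saved cohort.
#' @param ratios A [split_ratios()].
#' @param ecg An [ecg_encoder_config()].
#' @param image An [image_encoder_config()].
#' @param training A [train_config()].
#' @param rho Agreement weight for the cooperative model; ignored when
#'   `search` is given.
#' @param search Optional [search_space()] to tune (rho, lr, batch) first.
#' @param n_bootstrap Bootstrap replicates for evaluation (default 1000).
#' @param explain Also compute interpretability and faithfulness summaries
#'   on a few test images.
#' @param seed Master seed.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              ratios = split_ratios(),
                              ecg = ecg_encoder_config(),
                              image = image_encoder_config(),
                              training = train_config(),
                              rho = 0.5,
                              search = NULL,
                              n_bootstrap = 1000L,
                              explain = FALSE,
                              seed = 1L) {
  structure(list(cohort = cohort, ratios = ratios, ecg = ecg, image = image,
                 training = training, rho = rho, search = search,
                 n_bootstrap = as.integer(n_bootstrap),
                 explain = isTRUE(explain), seed = as.integer(seed)),
            class = "experiment_config")
}

#' Load an experiment configuration from YAML or JSON
#'
#' @param path Config file path.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  build <- function(fn, args) do.call(fn, args %||% list())
  experiment_config(
    cohort = if (is.character(raw$cohort)) raw$cohort else
      build(cohort_config, raw$cohort),
    ratios = build(split_ratios, raw$ratios),
    ecg = build(ecg_encoder_config, raw$ecg),
    image = build(image_encoder_config, raw$image),
    training = build(train_config, raw$training),
    rho = raw$rho %||% 0.5,
    search = if (!is.null(raw$search)) build(search_space, raw$search),
    n_bootstrap = raw$n_bootstrap %||% 1000L,
    explain = isTRUE(raw$explain),
    seed = raw$seed %||% 1L
  )
}

#' Run the full experiment pipeline
#'
#' Generate or load the cohort, split by patient, train the two unimodal
#' baselines and the cooperative model, evaluate all three on the held-out
#' test set with bootstrap CIs, and compare every model pair; optionally add
#' interpretability and faithfulness summaries. All outputs (run report
#' JSON, metric and comparison tables, training histories) are written under
#' `output_dir`, stamped with the config hash and seed.
#'
#' @param config An [experiment_config()].
#' @param output_dir Output directory; `NULL` skips file output.
#' @return The run report (list) invisibly contains per-model metric
#'   reports, the comparison table, config echo and seeds.
#' @export
run_experiment <- function(config, output_dir = NULL) {
  assert_that(inherits(config, "experiment_config"),
              "config must be an experiment_config()")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_coop("[stage: ", name, "] ", conditionMessage(e),
                class = "coopAS_stage_error")
    })
  }
  hash <- config_hash(config)

  cohort <- stage("cohort", {
    if (is.character(config$cohort)) load_cohort(config$cohort) else {
      cc <- config$cohort
      cc$seed <- cc$seed %||% child_seed(config$seed, 1)
      generate_cohort(cc)
    }
  })
  splits <- stage("split",
                  split_by_patient(cohort, config$ratios,
                                   seed = child_seed(config$seed, 2)))

  tcfg <- config$training
  fits <- list()
  fits$ecg <- stage("train-ecg", {
    t1 <- tcfg; t1$seed <- child_seed(config$seed, 3)
    train_unimodal(splits$train, splits$validation, "ecg",
                   ecg_config = config$ecg, tcfg = t1)
  })
  fits$cxr <- stage("train-image", {
    t2 <- tcfg; t2$seed <- child_seed(config$seed, 4)
    train_unimodal(splits$train, splits$validation, "image",
                   image_config = config$image, tcfg = t2)
  })
  rho <- config$rho
  search_log <- NULL
  if (!is.null(config$search)) {
    tuned <- stage("tune", {
      sp <- config$search
      sp$seed <- sp$seed %||% child_seed(config$seed, 5)
      tune_hyperparameters(sp, make_cooperative_trainer(
        splits$train, splits$validation, config$ecg, config$image, tcfg))
    })
    rho <- tuned$best$rho
    tcfg$learning_rate <- tuned$best$learning_rate
    tcfg$batch_size <- tuned$best$batch_size
    search_log <- tuned$trials
  }
  fits$cooperative <- stage("train-cooperative", {
    t3 <- tcfg; t3$seed <- child_seed(config$seed, 6)
    train_cooperative(splits$train, splits$validation,
                      ecg_config = config$ecg, image_config = config$image,
                      tcfg = t3, rho = rho)
  })

  report <- stage("evaluate", {
    preds <- lapply(fits, predict_scores, records = splits$test)
    val_preds <- lapply(fits, predict_scores, records = splits$validation)
    metrics <- list()
    for (m in names(fits)) {
      thr <- select_threshold(val_preds[[m]]$fused, val_preds[[m]]$label)
      metrics[[m]] <- list(
        threshold = thr,
        auroc = bootstrap_metric(preds[[m]]$fused, preds[[m]]$label,
                                 "auroc", n = config$n_bootstrap,
                                 seed = child_seed(config$seed, 7)),
        auprc = bootstrap_metric(preds[[m]]$fused, preds[[m]]$label,
                                 "auprc", n = config$n_bootstrap,
                                 seed = child_seed(config$seed, 8)),
        thresholded = threshold_metrics(preds[[m]]$fused,
                                        preds[[m]]$label, thr))
    }
    pairs <- utils::combn(names(fits), 2, simplify = FALSE)
    comparisons <- lapply(pairs, function(pr) {
      cmp <- compare_models(preds[[pr[1]]]$fused, preds[[pr[2]]]$fused,
                            preds[[pr[1]]]$label, "auroc",
                            n = config$n_bootstrap,
                            seed = child_seed(config$seed, 9))
      c(list(model_a = pr[1], model_b = pr[2]), cmp)
    })
    list(models = metrics, comparisons = comparisons, predictions = preds)
  })

  explain_summary <- NULL
  if (config$explain) {
    explain_summary <- stage("explain", {
      rec <- splits$test[[1]]
      img <- prepare_image(rec$image * 1.0,
                           out_size = config$image$input_size)
      sal <- gradcam_2d(fits$cooperative, img)
      seg <- augment_ecg(extract_segment(rec$ecg),
                         augment_config(noise_range = 0))
      att <- lead_attention(fits$cooperative, seg)
      curve <- perturbation_curve(fits$cooperative, img, sal,
                                  perturbation_protocol("deletion"))
      list(lead_attention = as.numeric(att),
           gradcam_mass_in_mask = if (!is.null(rec$signal_mask) &&
                                        all(dim(sal) == dim(rec$signal_mask)))
             sum(sal[rec$signal_mask]) / max(sum(sal), 1e-12) else NA_real_,
           deletion_aopc = aopc(curve))
    })
  }

  run_report <- list(
    config_hash = hash,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("coopAS")),
    n_records = length(cohort),
    n_patients = length(unique(record_patient_ids(cohort))),
    split_sizes = vapply(splits, length, integer(1)),
    rho = rho,
    search = search_log,
    models = lapply(report$models, function(m) list(
      threshold = m$threshold,
      auroc = unclass(m$auroc), auprc = unclass(m$auprc),
      thresholded = m$thresholded)),
    comparisons = report$comparisons,
    histories = lapply(fits, function(f) f$history)
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(run_report,
                         file.path(output_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (m in names(fits)) {
      hist <- fits[[m]]$history
      hist$config_hash <- hash
      hist$seed <- config$seed
      utils::write.csv(hist,
                       file.path(output_dir, paste0("history_", m, ".csv")),
                       row.names = FALSE)
      save_checkpoint(fits[[m]],
                      file.path(output_dir, paste0("model_", m, ".rds")))
    }
    cmp_df <- do.call(rbind, lapply(report$comparisons, as.data.frame))
    cmp_df$config_hash <- hash
    cmp_df$seed <- config$seed
    utils::write.csv(cmp_df, file.path(output_dir, "comparisons.csv"),
                     row.names = FALSE)
  }
  run_report$fits <- fits
  run_report$explain <- explain_summary
  invisible(run_report)
}

#' Build a cooperative-trainer closure for hyperparameter tuning
#'
#' @param train_records,val_records Patient-disjoint record sets.
#' @param ecg_config,image_config Branch configurations.
#' @param tcfg Base [train_config()]; learning rate, batch size and seed are
#'   overridden per trial.
#' @return `function(rho, learning_rate, batch_size, seed)` returning
#'   `list(val_auroc, fit)`.
#' @export
make_cooperative_trainer <- function(train_records, val_records,
                                     ecg_config, image_config, tcfg) {
  function(rho, learning_rate, batch_size, seed = NULL) {
    t <- tcfg
    t$learning_rate <- learning_rate
    t$batch_size <- as.integer(batch_size)
    t$seed <- seed
    fit <- train_cooperative(train_records, val_records, ecg_config,
                             image_config, t, rho = rho)
    pred <- predict_scores(fit, val_records)
    list(val_auroc = roc_auc(pred$fused, pred$label), fit = fit)
  }
}
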