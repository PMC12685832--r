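random_record_table <- function(n_patients, max_records = 4) {
  counts <- sample.int(max_records, n_patients, replace = TRUE)
  data.frame(patient_id = rep(sprintf("P%03d", seq_len(n_patients)), counts))
}

test_that("patient-level splitting never leaks patients and tracks the ratios", {
  df <- data.frame(patient_id = sprintf("P%02d", 1:10))
  sp <- split_by_patient(df, seed = 0)
  ids <- lapply(sp, function(s) unique(s$patient_id))
  expect_equal(sum(lengths(ids)), 10L)
  expect_length(Reduce(intersect, ids), 0)
  expect_gte(nrow(sp$train), 6)
  # a single patient lands wholly in one split (warns: splits must go empty)
  one <- data.frame(patient_id = rep("P1", 5))
  expect_warning(sp1 <- split_by_patient(one, seed = 1), "fewer patients")
  expect_equal(sort(unname(vapply(sp1, nrow, integer(1)))), c(0L, 0L, 5L))
  # a dominant patient cannot be divided even if ratios then deviate
  dom <- data.frame(patient_id = c(rep("BIG", 50), sprintf("P%02d", 1:50)))
  spd <- split_by_patient(dom, seed = 2)
  big_in <- vapply(spd, function(s) any(s$patient_id == "BIG"), logical(1))
  expect_equal(sum(big_in), 1L)
  expect_equal(sum(spd[[which(big_in)]]$patient_id == "BIG"), 50L)
})

test_that("splitting is seeded and respects ratio targets on many random cohorts", {
  withr::with_seed(3, {
    for (i in 1:50) {
      df <- random_record_table(sample(30:80, 1))
      sp <- split_by_patient(df, seed = i)
      ids <- lapply(sp, function(s) unique(s$patient_id))
      expect_length(intersect(ids$train, ids$validation), 0)
      expect_length(intersect(ids$train, ids$test), 0)
      expect_length(intersect(ids$validation, ids$test), 0)
      fr <- vapply(sp, nrow, integer(1)) / nrow(df)
      if (max(table(df$patient_id)) <= 0.05 * nrow(df)) {
        expect_true(all(abs(fr - c(0.7, 0.15, 0.15)) <= 0.05))
      }
    }
  })
  df <- random_record_table(40)
  expect_identical(split_by_patient(df, seed = 7),
                   split_by_patient(df, seed = 7))
})

test_that("label-stratified splits spread positive patients across all splits", {
  withr::with_seed(9, {
    n_pat <- 60
    counts <- sample.int(4, n_pat, replace = TRUE)
    pat_label <- rep(c(1, 0), c(9, n_pat - 9))  # 15% positive patients
    df <- data.frame(
      patient_id = rep(sprintf("P%03d", seq_len(n_pat)), counts),
      label = rep(pat_label, counts))
  })
  for (s in 1:10) {
    sp <- split_by_patient(df, seed = s)
    pos <- vapply(sp, function(x) sum(x$label > 0), numeric(1))
    expect_true(all(pos > 0))   # every split keeps some positives
    ids <- lapply(sp, function(x) unique(x$patient_id))
    expect_length(Reduce(intersect, ids), 0)
    # unstratified path remains available and patient-disjoint
    spu <- split_by_patient(df, seed = s, stratify = FALSE)
    idsu <- lapply(spu, function(x) unique(x$patient_id))
    expect_length(Reduce(intersect, idsu), 0)
  }
})

test_that("the cosine schedule starts at the peak and bottoms out at the period", {
  expect_equal(cosine_lr(0, 1e-3, period = 10), 1e-3)
  expect_equal(cosine_lr(10, 1e-3, period = 10), 0)
  expect_equal(cosine_lr(5, 1e-3, period = 10), 5e-4)
  expect_equal(cosine_lr(20, 1e-3, period = 10), 1e-3)  # mirrored cycle
})

test_that("training is deterministic under a fixed seed and keeps the best checkpoint", {
  coh <- tiny_cohort()
  sp <- split_by_patient(coh, seed = 5)
  tcfg <- train_config(learning_rate = 3e-3, batch_size = 8, max_epochs = 3,
                       patience = 3, seed = 11)
  fit1 <- train_cooperative(sp$train, sp$validation, tiny_ecg_config(),
                            tiny_image_config(), tcfg, rho = 0.4)
  fit2 <- train_cooperative(sp$train, sp$validation, tiny_ecg_config(),
                            tiny_image_config(), tcfg, rho = 0.4)
  expect_identical(fit1$history, fit2$history)
  expect_identical(predict_scores(fit1, sp$test),
                   predict_scores(fit2, sp$test))
  # returned weights come from the epoch with the lowest validation loss
  expect_equal(min(fit1$history$val_loss),
               fit1$history$val_loss[fit1$best_epoch])
  # training refuses overlapping patients
  expect_error(train_cooperative(sp$train, sp$train, tiny_ecg_config(),
                                 tiny_image_config(), tcfg),
               class = "coopAS_patient_leak")
  # checkpoints round-trip through serialization
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit1, path)
  expect_identical(predict_scores(load_checkpoint(path), sp$test),
                   predict_scores(fit1, sp$test))
})

test_that("unimodal training tracks whichever modality carries the label signal", {
  # severity expresses only in the image (ECG effect size zero, everything
  # else at generator defaults): the image branch must win. 64-px images,
  # because per-image min-max windowing leaves morphology, not brightness,
  # as the usable signal, and morphology needs the larger grid
  coh <- generate_cohort(cohort_config(
    n_patients = 100, records_per_patient = c(1L, 3L), image_size = 64,
    target_prevalence = 0.2, severity_effect_ecg = 0, seed = 31))
  sp <- split_by_patient(coh, split_ratios(0.5, 0.3, 0.2), seed = 1)
  tcfg <- train_config(learning_rate = 1e-3, batch_size = 16,
                       max_epochs = 30, patience = 30, seed = 2)
  f_img <- train_unimodal(sp$train, sp$validation, "image",
                          image_config = image_encoder_config(
                            "small-cnn", input_size = 64,
                            base_channels = 8),
                          tcfg = tcfg)
  f_ecg <- train_unimodal(sp$train, sp$validation, "ecg",
                          ecg_config = tiny_ecg_config(),
                          tcfg = train_config(learning_rate = 1e-3,
                                              batch_size = 16,
                                              max_epochs = 10, patience = 10,
                                              seed = 2))
  auroc <- function(f) {
    p <- predict_scores(f, sp$validation)
    roc_auc(p$fused, p$label)
  }
  expect_gt(auroc(f_img), auroc(f_ecg))
  expect_gt(auroc(f_img), 0.5)
})

test_that("hyperparameter search returns the argmax trial and is seeded", {
  # analytic trainer: a linear cooperative problem whose label lives in the
  # disagreement direction of a shared factor, so forcing the branches to
  # agree destroys signal and rho = 0 is optimal by construction
  withr::with_seed(8, {
    n <- 800
    z <- rnorm(n); ue <- rnorm(n); uc <- rnorm(n)
    Xe <- cbind(z + ue, rnorm(n))
    Xc <- cbind(z - uc, rnorm(n))
    y <- as.numeric(ue + uc + rnorm(n, 0, 0.5) > 0)
    tr_idx <- 1:400
  })
  trainer <- function(rho, learning_rate, batch_size, seed = NULL) {
    cf <- linear_closed_form(Xe[tr_idx, ], Xc[tr_idx, ], y[tr_idx], rho)
    val <- Xe[-tr_idx, ] %*% cf$beta_ecg + Xc[-tr_idx, ] %*% cf$beta_cxr
    roc_auc(as.vector(val), y[-tr_idx])
  }
  one <- tune_hyperparameters(search_space(n_trials = 1, seed = 4), trainer)
  expect_equal(nrow(one$trials), 1L)
  expect_equal(one$best$val_auroc, max(one$trials$val_auroc))
  for (method in c("random", "tpe")) {
    sp8 <- search_space(n_trials = 10, method = method, seed = 21)
    res1 <- tune_hyperparameters(sp8, trainer)
    res2 <- tune_hyperparameters(sp8, trainer)
    expect_identical(res1$trials, res2$trials)
    expect_lt(res1$best$rho, 0.5)
  }
  # a trainer that always fails raises a tuning error
  expect_error(
    tune_hyperparameters(search_space(n_trials = 2, seed = 1),
                         function(...) stop("boom")),
    class = "coopAS_tuning_error")
})
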