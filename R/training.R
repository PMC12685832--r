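# Training protocol -----------------------------------------------------------

#' Split ratios
#'
#' @param train,validation,test Positive fractions summing to 1
#'   (defaults 0.70 / 0.15 / 0.15).
#' @return Object of class `split_ratios`.
#' @export
split_ratios <- function(train = 0.70, validation = 0.15, test = 0.15) {
  assert_that(train > 0 && validation > 0 && test > 0,
              "all split fractions must be positive")
  assert_that(abs(train + validation + test - 1) < 1e-8,
              "split fractions must sum to 1")
  structure(list(train = train, validation = validation, test = test),
            class = "split_ratios")
}

record_patient_ids <- function(records) {
  if (is.data.frame(records)) return(as.character(records$patient_id))
  vapply(records, function(r) as.character(r$patient_id), character(1))
}

record_labels <- function(records) {
  if (is.data.frame(records)) return(as.numeric(records$label))
  vapply(records, function(r) as.numeric(r$label), numeric(1))
}

subset_records <- function(records, idx) {
  if (is.data.frame(records)) return(records[idx, , drop = FALSE])
  structure(records[idx], class = class(records))
}

#' Patient-level train/validation/test split
#'
#' Patients (never records) are partitioned: after a seeded shuffle, each
#' patient is assigned greedily to the split whose record count is furthest
#' below its target share, so realized record fractions approach the ratios
#' while no patient ever spans two splits. When records carry labels (and
#' `stratify = TRUE`), the shuffle-and-assign runs separately within the
#' positive-patient and negative-patient strata, so each split also receives
#' its proportional share of positive records; at low prevalence an
#' unstratified split regularly leaves the validation or test set without a
#' single positive, which breaks loss-based checkpoint selection and leaves
#' rank metrics undefined.
#'
#' @param records A `coop_cohort` list or a data frame with a `patient_id`
#'   column (one row per record).
#' @param ratios A [split_ratios()].
#' @param seed Optional integer seed for the patient shuffle.
#' @param stratify Stratify the patient shuffle by patient-level label when
#'   labels are available (default `TRUE`).
#' @return Named list `train`, `validation`, `test` of record subsets.
#' @export
split_by_patient <- function(records, ratios = split_ratios(), seed = NULL,
                             stratify = TRUE) {
  pids <- record_patient_ids(records)
  assert_that(length(pids) > 0 && all(nzchar(pids)),
              "every record must carry a patient_id")
  patients <- unique(pids)
  if (length(patients) < 3) {
    warning("fewer patients than splits; some splits will be empty")
  }
  labels <- tryCatch(record_labels(records), error = function(e) NULL)
  strata <- if (stratify && !is.null(labels) &&
                length(labels) == length(pids) && !anyNA(labels)) {
    # patient-level label: positive if any record is positive
    pos_patient <- vapply(split(labels, pids), function(l) any(l == 1),
                          logical(1))
    split(names(pos_patient), pos_patient)
  } else {
    list(all = patients)
  }
  n_per <- table(pids)
  ratio_vec <- c(ratios$train, ratios$validation, ratios$test)
  assign <- stats::setNames(integer(length(patients)), patients)
  with_seed(seed, {
    for (stratum in strata) {
      counts <- c(0, 0, 0)
      target <- ratio_vec * sum(n_per[stratum])
      for (p in sample(stratum)) {
        k <- which.max(target - counts)
        assign[p] <- k
        counts[k] <- counts[k] + n_per[[p]]
      }
    }
  })
  splits <- lapply(1:3, function(k) {
    subset_records(records, which(assign[pids] == k))
  })
  names(splits) <- c("train", "validation", "test")
  splits
}

#' Training configuration
#'
#' Adam optimization with cosine-annealing learning rate, early stopping on
#' validation loss, and the checkpoint taken from the epoch with the lowest
#' validation loss.
#'
#' @param learning_rate Peak learning rate (> 0).
#' @param batch_size Minibatch size (>= 1).
#' @param max_epochs Epoch cap (default 100).
#' @param patience Early-stopping patience in epochs (default 20; must not
#'   exceed `max_epochs`).
#' @param cosine_period Cosine-annealing half-period in epochs (default 10).
#' @param beta1,beta2 Adam moment decay rates.
#' @param mixed_precision Reduced-precision arithmetic flag; R computes in
#'   double precision, so enabling it only emits a note and runs in full
#'   precision (kept for configuration compatibility).
#' @param augment An [augment_config()] applied in training mode.
#' @param seed Optional integer seed controlling initialization, shuffling
#'   and augmentation for a fully reproducible run.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 32L,
                         max_epochs = 100L, patience = 20L,
                         cosine_period = 10L, beta1 = 0.9, beta2 = 0.999,
                         mixed_precision = FALSE,
                         augment = augment_config(), seed = NULL) {
  assert_that(learning_rate > 0, "learning_rate must be positive")
  assert_that(batch_size >= 1, "batch_size must be at least 1")
  assert_that(patience <= max_epochs, "patience must not exceed max_epochs")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 cosine_period = as.integer(cosine_period),
                 beta1 = beta1, beta2 = beta2,
                 mixed_precision = isTRUE(mixed_precision),
                 augment = augment, seed = seed),
            class = "train_config")
}

# Build model-ready tensors for a set of records.
# mode "train" consumes the ambient RNG stream (segment offsets, noise,
# rotations); mode "eval" is fully deterministic.
make_batch <- function(records, mode, aug, image_size, need_ecg, need_image) {
  B <- length(records)
  segs <- NULL; imgs <- NULL
  if (need_ecg) {
    segs <- array(0, c(B, 12L, 1000L))
    for (i in seq_len(B)) {
      seg <- extract_segment(records[[i]]$ecg, mode = mode)
      if (mode == "train") {
        seg <- augment_ecg(seg, aug)
      } else {
        seg <- augment_ecg(seg, augment_config(noise_range = 0))
      }
      segs[i, , ] <- seg
    }
  }
  if (need_image) {
    imgs <- array(0, c(B, 1L, image_size, image_size))
    for (i in seq_len(B)) {
      img <- prepare_image(records[[i]]$image * 1.0, out_size = image_size)
      if (mode == "train") img <- augment_image(img, aug)
      imgs[i, 1, , ] <- img
    }
  }
  list(segs = segs, imgs = imgs, y = record_labels(records))
}

# Shared optimization engine for the cooperative and unimodal trainers.
# grad_fn(y, f_ecg, f_cxr) returns per-sample dscore for each active branch;
# loss_fn(y, f_ecg, f_cxr) the scalar batch loss.
train_engine <- function(train_records, val_records, ecg_model, image_model,
                         tcfg, loss_fn, grad_fn) {
  assert_that(length(train_records) > 0 && length(val_records) > 0,
              "training and validation sets must be nonempty",
              class = "coopAS_empty_split")
  if (tcfg$mixed_precision) {
    message("mixed_precision requested; R computes in double precision")
  }
  need_ecg <- !is.null(ecg_model)
  need_image <- !is.null(image_model)
  image_size <- if (need_image) image_model$arch$input_size else NA_integer_
  st_e <- if (need_ecg) adam_init(ecg_model$params)
  st_i <- if (need_image) adam_init(image_model$params)

  val_batch <- make_batch(val_records, "eval", tcfg$augment, image_size,
                          need_ecg, need_image)
  y_val <- val_batch$y
  # prepared images are deterministic per record: compute once, augment per epoch
  img_cache <- if (need_image) {
    lapply(train_records, function(r)
      prepare_image(r$image * 1.0, out_size = image_size))
  }
  y_train <- record_labels(train_records)
  train_batch <- function(idx) {
    B <- length(idx)
    segs <- NULL; imgs <- NULL
    if (need_ecg) {
      segs <- array(0, c(B, 12L, 1000L))
      for (i in seq_len(B)) {
        segs[i, , ] <- augment_ecg(
          extract_segment(train_records[[idx[i]]]$ecg, mode = "train"),
          tcfg$augment)
      }
    }
    if (need_image) {
      imgs <- array(0, c(B, 1L, image_size, image_size))
      for (i in seq_len(B)) {
        imgs[i, 1, , ] <- augment_image(img_cache[[idx[i]]], tcfg$augment)
      }
    }
    list(segs = segs, imgs = imgs, y = y_train[idx])
  }

  n <- length(train_records)
  history <- NULL
  best <- list(loss = Inf, epoch = NA_integer_,
               ecg = if (need_ecg) ecg_model$params,
               image = if (need_image) image_model$params)
  wait <- 0L

  eval_scores <- function(batch) {
    f_e <- if (need_ecg) ecg_forward_batch(ecg_model, batch$segs)$score else
      numeric(length(batch$y))
    f_i <- if (need_image) image_forward_batch(image_model, batch$imgs)$score
      else numeric(length(batch$y))
    list(f_ecg = f_e, f_cxr = f_i)
  }

  for (epoch in seq_len(tcfg$max_epochs)) {
    lr <- cosine_lr(epoch - 1L, tcfg$learning_rate, tcfg$cosine_period)
    perm <- sample.int(n)
    starts <- seq(1L, n, by = tcfg$batch_size)
    tr_loss <- 0; tr_n <- 0L
    for (s in starts) {
      idx <- perm[s:min(s + tcfg$batch_size - 1L, n)]
      batch <- train_batch(idx)
      B <- length(idx)
      fw_e <- if (need_ecg) ecg_forward_batch(ecg_model, batch$segs)
      fw_i <- if (need_image) image_forward_batch(image_model, batch$imgs)
      f_e <- if (need_ecg) fw_e$score else numeric(B)
      f_i <- if (need_image) fw_i$score else numeric(B)
      loss <- loss_fn(batch$y, f_e, f_i)
      if (!is.finite(loss)) {
        stop_coop("non-finite training loss at epoch ", epoch,
                  " (lr=", signif(lr, 3), "); lower the learning rate",
                  class = "coopAS_training_error")
      }
      tr_loss <- tr_loss + loss * B
      tr_n <- tr_n + B
      g <- grad_fn(batch$y, f_e, f_i)
      if (need_ecg) {
        bk <- ecg_backward_batch(ecg_model, fw_e, g$g_ecg / B)
        up <- adam_step(ecg_model$params, bk$grads, st_e, lr,
                        tcfg$beta1, tcfg$beta2)
        ecg_model$params <- up$params; st_e <- up$state
      }
      if (need_image) {
        bk <- image_backward_batch(image_model, fw_i, g$g_cxr / B)
        up <- adam_step(image_model$params, bk$grads, st_i, lr,
                        tcfg$beta1, tcfg$beta2)
        image_model$params <- up$params; st_i <- up$state
      }
    }
    sc <- eval_scores(val_batch)
    val_loss <- loss_fn(y_val, sc$f_ecg, sc$f_cxr)
    fused <- sc$f_ecg + sc$f_cxr
    val_auroc <- if (length(unique(y_val)) == 2) roc_auc(fused, y_val) else
      NA_real_
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, train_loss = tr_loss / tr_n,
      val_loss = val_loss, val_auroc = val_auroc))
    if (val_loss < best$loss - 1e-12) {
      best$loss <- val_loss
      best$epoch <- epoch
      if (need_ecg) best$ecg <- ecg_model$params
      if (need_image) best$image <- image_model$params
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= tcfg$patience) break
    }
  }
  if (need_ecg) ecg_model$params <- best$ecg
  if (need_image) image_model$params <- best$image
  list(ecg_model = ecg_model, image_model = image_model,
       history = history, best_epoch = best$epoch, best_val_loss = best$loss)
}

#' Train the cooperative two-branch model
#'
#' Joint Adam optimization of the ECG and image branches under the
#' cooperative objective, with cosine-annealed learning rate, early stopping
#' on validation cooperative loss (patience epochs without improvement), and
#' the returned weights taken from the epoch with the lowest validation
#' loss.
#'
#' @param train_records,val_records Patient-disjoint record sets (e.g. from
#'   [split_by_patient()]).
#' @param ecg_config An [ecg_encoder_config()].
#' @param image_config An [image_encoder_config()]; its `input_size` should
#'   match the cohort image size for desk-scale runs.
#' @param tcfg A [train_config()].
#' @param rho Agreement-penalty weight (>= 0).
#' @return Object of class `coop_fit` with the two trained branches,
#'   per-epoch `history` (train/val loss, val AUROC, learning rate) and
#'   `best_epoch`.
#' @export
train_cooperative <- function(train_records, val_records,
                              ecg_config = ecg_encoder_config(),
                              image_config = image_encoder_config(),
                              tcfg = train_config(), rho = 0.5) {
  assert_that(rho >= 0, "rho must be nonnegative")
  check_patient_disjoint(train_records, val_records)
  with_seed(tcfg$seed, {
    ecg_model <- ecg_model_init(ecg_config)
    image_model <- image_model_init(image_config)
    res <- train_engine(
      train_records, val_records, ecg_model, image_model, tcfg,
      loss_fn = function(y, fe, fi) cooperative_loss(y, fe, fi, rho),
      grad_fn = function(y, fe, fi) loss_gradients(y, fe, fi, rho)
    )
    structure(list(type = "cooperative", rho = rho,
                   ecg_model = res$ecg_model, image_model = res$image_model,
                   history = res$history, best_epoch = res$best_epoch,
                   train_config = tcfg),
              class = "coop_fit")
  })
}

check_patient_disjoint <- function(a, b) {
  pa <- unique(record_patient_ids(a))
  pb <- unique(record_patient_ids(b))
  assert_that(length(intersect(pa, pb)) == 0,
              "train and validation sets share patients",
              class = "coopAS_patient_leak")
}

#' Train a single-branch baseline model
#'
#' Same optimization protocol as the cooperative trainer but with a single
#' branch under squared-error loss `1/2 (y - f)^2` (or, optionally,
#' sigmoid cross-entropy); serves as the unimodal comparison arm.
#'
#' @inheritParams train_cooperative
#' @param branch `"ecg"` or `"image"`.
#' @param loss `"squared"` (default) or `"cross-entropy"`.
#' @param ecg_config,image_config Config for whichever branch is trained.
#' @return Object of class `coop_fit` (type `"ecg"` or `"image"`).
#' @export
train_unimodal <- function(train_records, val_records,
                           branch = c("ecg", "image"),
                           ecg_config = ecg_encoder_config(),
                           image_config = image_encoder_config(),
                           tcfg = train_config(),
                           loss = c("squared", "cross-entropy")) {
  branch <- match.arg(branch)
  loss <- match.arg(loss)
  check_patient_disjoint(train_records, val_records)
  with_seed(tcfg$seed, {
    ecg_model <- if (branch == "ecg") ecg_model_init(ecg_config)
    image_model <- if (branch == "image") image_model_init(image_config)
    pick <- function(fe, fi) if (branch == "ecg") fe else fi
    loss_fn <- function(y, fe, fi) {
      f <- pick(fe, fi)
      if (loss == "squared") mean(0.5 * (y - f)^2) else
        mean(-y * log(sigmoid(f)) - (1 - y) * log(1 - sigmoid(f)))
    }
    grad_fn <- function(y, fe, fi) {
      f <- pick(fe, fi)
      g <- if (loss == "squared") -(y - f) else sigmoid(f) - y
      list(g_ecg = g, g_cxr = g)
    }
    res <- train_engine(train_records, val_records, ecg_model, image_model,
                        tcfg, loss_fn, grad_fn)
    structure(list(type = branch, rho = NA_real_,
                   ecg_model = res$ecg_model, image_model = res$image_model,
                   history = res$history, best_epoch = res$best_epoch,
                   train_config = tcfg),
              class = "coop_fit")
  })
}

#' Score records with a trained model
#'
#' Uses the deterministic eval pipeline (centre ECG crop, baseline zeroing,
#' no augmentation).
#'
#' @param fit A `coop_fit`.
#' @param records Record set to score.
#' @return Data frame with per-record branch scores, the fused score (for
#'   unimodal fits, the single branch score), the sigmoid probability and
#'   the label.
#' @export
predict_scores <- function(fit, records) {
  assert_that(inherits(fit, "coop_fit"), "fit must be a coop_fit")
  need_ecg <- !is.null(fit$ecg_model)
  need_image <- !is.null(fit$image_model)
  image_size <- if (need_image) fit$image_model$arch$input_size else NA
  batch <- make_batch(records, "eval", augment_config(), image_size,
                      need_ecg, need_image)
  f_e <- if (need_ecg) ecg_forward_batch(fit$ecg_model, batch$segs)$score
    else rep(NA_real_, length(records))
  f_i <- if (need_image) image_forward_batch(fit$image_model,
                                             batch$imgs)$score
    else rep(NA_real_, length(records))
  fused <- switch(fit$type,
                  cooperative = f_e + f_i,
                  ecg = f_e,
                  image = f_i)
  data.frame(
    record_id = vapply(records, function(r)
      as.character(r$record_id %||% NA_character_), character(1)),
    patient_id = record_patient_ids(records),
    label = batch$y,
    f_ecg = f_e, f_cxr = f_i,
    fused = fused, prob = sigmoid(fused),
    stringsAsFactors = FALSE)
}

#' @export
print.coop_fit <- function(x, ...) {
  cat("coopAS fit [", x$type, "]",
      if (x$type == "cooperative") paste0(" rho=", signif(x$rho, 3)) else "",
      ": best epoch ", x$best_epoch, " of ", nrow(x$history),
      ", best val loss ", signif(min(x$history$val_loss), 4), "\n", sep = "")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are RDS files containing the full fit (architecture configs
#' embedded with the weights, so reload is self-describing).
#'
#' @param fit A `coop_fit`.
#' @param path File path.
#' @return `load_checkpoint` returns the fit.
#' @export
save_checkpoint <- function(fit, path) {
  assert_that(inherits(fit, "coop_fit"), "fit must be a coop_fit")
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  assert_that(inherits(fit, "coop_fit"), "checkpoint does not contain a fit")
  fit
}

#' Hyperparameter search space
#'
#' @param rho_range Interval for the agreement weight (default \[0, 1\]).
#' @param batch_choices Candidate batch sizes (default 64 and 128).
#' @param lr_range Learning-rate interval sampled log-uniformly
#'   (default \[1e-6, 1e-3\]).
#' @param n_trials Number of trials (>= 1, default 20).
#' @param method `"random"` (seeded random search) or `"tpe"`
#'   (tree-structured-Parzen-style sequential model-based search).
#' @param seed Optional integer seed.
#' @return Object of class `search_space`.
#' @export
search_space <- function(rho_range = c(0, 1), batch_choices = c(64L, 128L),
                         lr_range = c(1e-6, 1e-3), n_trials = 20L,
                         method = c("random", "tpe"), seed = NULL) {
  method <- match.arg(method)
  assert_that(rho_range[1] <= rho_range[2] && lr_range[1] <= lr_range[2],
              "range bounds must be ordered")
  assert_that(is_count(n_trials), "n_trials must be a positive integer")
  structure(list(rho_range = rho_range, batch_choices = batch_choices,
                 lr_range = lr_range, n_trials = as.integer(n_trials),
                 method = method, seed = seed),
            class = "search_space")
}

# Parzen-style proposal: model good/bad trial densities and pick the
# candidate maximizing their ratio.
tpe_propose <- function(trials, space, n_cand = 24L) {
  ok <- trials[is.finite(trials$val_auroc), , drop = FALSE]
  n <- nrow(ok)
  n_good <- max(2L, ceiling(0.25 * n))
  o <- order(ok$val_auroc, decreasing = TRUE)
  good <- ok[o[seq_len(n_good)], , drop = FALSE]
  bad <- ok[o[-seq_len(n_good)], , drop = FALSE]
  if (nrow(bad) < 2) bad <- ok
  kde_ll <- function(x, centres, lo, hi) {
    bw <- max(1.06 * stats::sd(centres) * length(centres)^(-0.2),
              (hi - lo) / 50)
    log(rowMeans(outer(x, centres, function(a, b)
      stats::dnorm(a, b, bw))) + 1e-12)
  }
  draw_from <- function(centres, lo, hi, m) {
    bw <- max(1.06 * stats::sd(centres) * length(centres)^(-0.2),
              (hi - lo) / 50)
    pmin(pmax(sample(centres, m, replace = TRUE) +
                stats::rnorm(m, 0, bw), lo), hi)
  }
  rho_c <- draw_from(good$rho, space$rho_range[1], space$rho_range[2], n_cand)
  llr <- log(space$lr_range)
  lr_c <- draw_from(log(good$learning_rate), llr[1], llr[2], n_cand)
  score <- kde_ll(rho_c, good$rho, space$rho_range[1], space$rho_range[2]) -
    kde_ll(rho_c, bad$rho, space$rho_range[1], space$rho_range[2]) +
    kde_ll(lr_c, log(good$learning_rate), llr[1], llr[2]) -
    kde_ll(lr_c, log(bad$learning_rate), llr[1], llr[2])
  bi <- which.max(score)
  # batch size: smoothed categorical frequencies in good vs bad trials
  tab <- function(d) (table(factor(d$batch_size, levels = space$batch_choices))
                      + 1) / (nrow(d) + length(space$batch_choices))
  ratio <- as.numeric(tab(good)) / as.numeric(tab(bad))
  list(rho = rho_c[bi], learning_rate = exp(lr_c[bi]),
       batch_size = space$batch_choices[which.max(ratio)])
}

#' Tune hyperparameters against validation AUROC
#'
#' Sequential search over (rho, learning rate, batch size) maximizing the
#' validation AUROC returned by `trainer`. The default method is seeded
#' random search; `method = "tpe"` in the space switches to a
#' Parzen-estimator-style sequential proposal after 5 startup trials.
#'
#' @param space A [search_space()].
#' @param trainer `function(rho, learning_rate, batch_size, seed)` returning
#'   either a single numeric validation AUROC or a list with elements
#'   `val_auroc` and (optionally) `fit`.
#' @return List with `best` (winning configuration and its AUROC), `trials`
#'   (full trial log) and `fit` (the winning trial's fit when the trainer
#'   supplies one).
#' @export
tune_hyperparameters <- function(space, trainer) {
  assert_that(inherits(space, "search_space"), "space must be a search_space()")
  trials <- data.frame()
  fits <- list()
  with_seed(space$seed, {
    for (i in seq_len(space$n_trials)) {
      if (space$method == "tpe" && i > 5 &&
          sum(is.finite(trials$val_auroc)) >= 5) {
        prop <- tpe_propose(trials, space)
      } else {
        prop <- list(
          rho = stats::runif(1, space$rho_range[1], space$rho_range[2]),
          learning_rate = exp(stats::runif(1, log(space$lr_range[1]),
                                           log(space$lr_range[2]))),
          batch_size = if (length(space$batch_choices) == 1L)
            space$batch_choices else sample(space$batch_choices, 1L))
      }
      res <- tryCatch(
        trainer(prop$rho, prop$learning_rate, prop$batch_size,
                seed = child_seed(space$seed, i) %||% i),
        error = function(e) NULL)
      auroc <- if (is.null(res)) NA_real_ else if (is.list(res))
        res$val_auroc else as.numeric(res)
      fits[i] <- list(if (is.list(res)) res$fit else NULL)
      trials <- rbind(trials, data.frame(
        trial = i, rho = prop$rho, learning_rate = prop$learning_rate,
        batch_size = prop$batch_size, val_auroc = auroc))
    }
  })
  if (!any(is.finite(trials$val_auroc))) {
    stop_coop("all tuning trials failed", class = "coopAS_tuning_error")
  }
  bi <- which.max(trials$val_auroc)
  list(best = as.list(trials[bi, c("rho", "learning_rate", "batch_size",
                                   "val_auroc")]),
       trials = trials,
       fit = fits[[bi]])
}
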