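#' Patch-classifier configuration
#'
#' The classifier head follows a fixed recipe: backbone features feeding two
#' dense layers of 198 units each, a dropout layer at rate 0.5, and a final
#' dense layer with one pre-softmax output ("logit") per class.
#'
#' Two backbone names are recognised. `small_convnet_test` is a compact
#' convolutional backbone (3x3 mean pool, one 5x5/8-filter stride-2
#' convolution, 5x5 mean pool) that trains in seconds on a CPU and is the
#' backbone used throughout the test suite and the synthetic end-to-end
#' runs. `residual50_pretrained` names the 50-layer residual network
#' pretrained on ImageNet used for production-scale runs; its pretrained
#' weights are not bundled with this package, so requesting it raises a
#' configuration error unless a weight source is installed separately.
#'
#' @param backbone `"small_convnet_test"` or `"residual50_pretrained"`.
#' @param n_classes Number of terminal classes (default 5; 2 or 4 for
#'   ablation runs).
#' @param dense_units Length-2 integer vector of head widths (fixed default
#'   `c(198, 198)`).
#' @param dropout_rate Head dropout rate in \[0, 1) (default 0.5).
#' @param batch_size Mini-batch size (default 16).
#' @param classes Label vocabulary in code order; defaults to the first
#'   `n_classes` entries of [rib_classes()].
#' @return A `model_config` list.
#' @export
model_config <- function(backbone = c("small_convnet_test",
                                      "residual50_pretrained"),
                         n_classes = 5L, dense_units = c(198L, 198L),
                         dropout_rate = 0.5, batch_size = 16L,
                         classes = NULL) {
  backbone <- match.arg(backbone)
  n_classes <- as.integer(n_classes)
  stopifnot(n_classes >= 2L, dropout_rate >= 0, dropout_rate < 1,
            length(dense_units) == 2L, all(dense_units >= 1L),
            batch_size >= 1L)
  classes <- classes %||% rib_classes()[seq_len(n_classes)]
  stopifnot(length(classes) == n_classes)
  structure(list(backbone = backbone, n_classes = n_classes,
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size), classes = classes),
            class = "model_config")
}

#' Two-phase training schedule
#'
#' Phase 1 freezes the backbone and trains only the head at a learning rate
#' of 1e-4; phase 2 unfreezes everything and fine-tunes at 8e-5. Both phases
#' use categorical cross-entropy with Adam, stop early when the validation
#' loss has not improved for `early_stop_patience` epochs (restoring the
#' best-validation-loss weights), and multiply the learning rate by
#' `plateau_factor` whenever the validation loss stalls for
#' `plateau_patience` epochs.
#'
#' @param lr_phase1,lr_phase2 Learning rates (> 0) for the frozen and
#'   fine-tuning phase.
#' @param max_epochs_phase1,max_epochs_phase2 Epoch caps (default 100 each).
#' @param early_stop_patience Early-stopping patience in epochs (default 15).
#' @param plateau_patience Epochs without improvement before the learning
#'   rate is reduced (default 2).
#' @param plateau_factor Multiplicative learning-rate reduction (default 0.1).
#' @return A `train_schedule` list.
#' @export
train_schedule <- function(lr_phase1 = 1e-4, lr_phase2 = 8e-5,
                           max_epochs_phase1 = 100L, max_epochs_phase2 = 100L,
                           early_stop_patience = 15L, plateau_patience = 2L,
                           plateau_factor = 0.1) {
  stopifnot(lr_phase1 > 0, lr_phase2 > 0, early_stop_patience >= 1L,
            plateau_patience >= 1L, plateau_factor > 0, plateau_factor < 1,
            max_epochs_phase1 >= 1L, max_epochs_phase2 >= 1L)
  structure(list(lr_phase1 = lr_phase1, lr_phase2 = lr_phase2,
                 max_epochs_phase1 = as.integer(max_epochs_phase1),
                 max_epochs_phase2 = as.integer(max_epochs_phase2),
                 early_stop_patience = as.integer(early_stop_patience),
                 plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor,
                 loss = "categorical_crossentropy", optimizer = "adam"),
            class = "train_schedule")
}

#' Build a patch classifier
#'
#' Instantiates the backbone and the dense-198/dense-198/dropout/dense-C
#' head with seeded He-normal initial weights. The model maps one 99x99
#' grayscale patch to `n_classes` pre-softmax scores.
#'
#' @param cfg A [model_config()].
#' @param input_size Patch edge length (default 99).
#' @param seed Integer seed for weight initialisation.
#' @return A `rib_model` object.
#' @export
build_model <- function(cfg, input_size = 99L, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  if (cfg$backbone == "residual50_pretrained") {
    stop("backbone 'residual50_pretrained' requires ImageNet-pretrained ",
         "weights, which are not bundled with this package; use backbone ",
         "'small_convnet_test' or install a weight source")
  }
  input_size <- as.integer(input_size)
  stopifnot(input_size %% 3L == 0L || input_size == 99L)
  n33 <- input_size %/% 3L
  npos <- (n33 - CONV_KERNEL) %/% CONV_STRIDE + 1L
  m <- max(1L, npos %/% 5L)
  while (npos %% m != 0L) m <- m - 1L
  idx <- list(pool1 = pool_index(input_size, 3L),
              conv = conv_index(n33, CONV_KERNEL, CONV_STRIDE),
              pool2 = pool_matrix(npos, m))
  n_feat <- ncol(idx$pool2) * CONV_FILTERS
  params <- with_seed(derive_seed(seed, "init"), list(
    Wc = he_init(CONV_KERNEL^2, CONV_FILTERS),
    bc = numeric(CONV_FILTERS),
    W1 = he_init(n_feat, cfg$dense_units[1L]),
    b1 = numeric(cfg$dense_units[1L]),
    W2 = he_init(cfg$dense_units[1L], cfg$dense_units[2L]),
    b2 = numeric(cfg$dense_units[2L]),
    W3 = he_init(cfg$dense_units[2L], cfg$n_classes),
    b3 = numeric(cfg$n_classes)))
  structure(list(cfg = cfg, input_size = input_size, idx = idx,
                 params = params, trained = FALSE, history = NULL),
            class = "rib_model")
}

#' @export
print.rib_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 1L))
  cat(sprintf(
    "<rib_model> backbone=%s, %d classes, %d parameters, %strained\n",
    x$cfg$backbone, x$cfg$n_classes, n_par, if (x$trained) "" else "un"))
  invisible(x)
}

backbone_param_names <- function() c("Wc", "bc")

## pull (Xp, y) training tensors out of a patch_set
prepare_training_data <- function(model, ps) {
  if (is.null(ps$pixels)) stop("patch set has no materialised pixels")
  if (nrow(ps$samples) == 0L) stop("empty dataset")
  y <- match(ps$samples$label, model$cfg$classes) - 1L
  if (anyNA(y)) {
    stop("labels outside the model's class vocabulary: ",
         paste(setdiff(unique(ps$samples$label), model$cfg$classes),
               collapse = ", "))
  }
  list(Xp = nn_preprocess(model, ps$pixels), y = as.integer(y))
}

## one training phase: epochs of seeded shuffled mini-batches with Adam,
## LR-on-plateau, early stopping with best-weight restoration
train_phase <- function(model, fitd, vald, lr0, max_epochs, schedule,
                        frozen, phase_name, seed) {
  with_seed(derive_seed(seed, phase_name), {
    n <- nrow(fitd$Xp)
    bs <- model$cfg$batch_size
    opt <- adam_state(model$params)
    lr <- lr0
    best_loss <- Inf
    best_params <- model$params
    es_wait <- 0L
    plateau_wait <- 0L
    hist <- NULL
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      tr_loss <- 0
      for (b0 in seq.int(1L, n, by = bs)) {
        bi <- ord[b0:min(b0 + bs - 1L, n)]
        cache <- nn_forward(model, fitd$Xp[bi, , drop = FALSE],
                            training = TRUE, keep_cache = TRUE)
        tr_loss <- tr_loss + nn_loss(cache$logits, fitd$y[bi]) * length(bi)
        grads <- nn_backward(model, cache, fitd$y[bi], frozen)
        if (frozen) grads <- grads[setdiff(names(grads),
                                           backbone_param_names())]
        upd <- adam_step(model$params, grads, opt, lr)
        model$params <- upd$params
        opt <- upd$state
      }
      val_logits <- nn_forward(model, vald$Xp)$logits
      val_loss <- nn_loss(val_logits, vald$y)
      val_pred <- max.col(val_logits, ties.method = "first") - 1L
      hist <- rbind(hist, data.frame(
        phase = phase_name, epoch = epoch,
        train_loss = tr_loss / n, val_loss = val_loss, lr = lr,
        val_f1 = macro_f1(vald$y, val_pred, model$cfg$n_classes)))

      if (val_loss < best_loss - 1e-9) {
        best_loss <- val_loss
        best_params <- model$params
        es_wait <- 0L
        plateau_wait <- 0L
      } else {
        es_wait <- es_wait + 1L
        plateau_wait <- plateau_wait + 1L
        if (plateau_wait >= schedule$plateau_patience) {
          lr <- lr * schedule$plateau_factor
          plateau_wait <- 0L
        }
        if (es_wait >= schedule$early_stop_patience) break
      }
    }
    model$params <- best_params   # restore best-validation-loss weights
    list(model = model, history = hist)
  })
}

#' Train with the two-phase freeze/unfreeze schedule
#'
#' Phase 1 trains only the head while the backbone weights stay frozen
#' (bit-identical before and after); phase 2 unfreezes all weights and
#' fine-tunes at the lower learning rate. Each phase applies early stopping
#' on the validation loss (restoring the best weights) and
#' learning-rate-on-plateau reduction.
#'
#' @param model A `rib_model` from [build_model()].
#' @param fit,val Group-disjoint `patch_set`s with materialised pixels.
#' @param schedule A [train_schedule()].
#' @param seed Integer seed controlling shuffling and dropout.
#' @return The trained `rib_model`; `$history` holds one row per epoch with
#'   `phase`, `epoch`, `train_loss`, `val_loss`, `lr`, `val_f1`.
#' @export
train_two_phase <- function(model, fit, val, schedule = train_schedule(),
                            seed = 1L) {
  stopifnot(inherits(model, "rib_model"), inherits(schedule, "train_schedule"))
  if (!groups_disjoint(fit, val)) {
    stop("fit and validation sets share groups (data leakage)")
  }
  fitd <- prepare_training_data(model, fit)
  vald <- prepare_training_data(model, val)

  p1 <- train_phase(model, fitd, vald, schedule$lr_phase1,
                    schedule$max_epochs_phase1, schedule, frozen = TRUE,
                    phase_name = "phase1", seed = seed)
  p2 <- train_phase(p1$model, fitd, vald, schedule$lr_phase2,
                    schedule$max_epochs_phase2, schedule, frozen = FALSE,
                    phase_name = "phase2", seed = seed)
  model <- p2$model
  model$trained <- TRUE
  model$history <- rbind(p1$history, p2$history)
  model
}

#' Per-patch predictions with pre-softmax scores
#'
#' Runs the model in evaluation mode (dropout disabled, deterministic) and
#' returns one record per sample, in input order: the sample's bookkeeping
#' columns, the predicted label (argmax of the scores, ties broken toward
#' the lowest class index) and one `logit_<class>` column per class holding
#' the pre-softmax score.
#'
#' @param model A trained `rib_model`.
#' @param samples A `patch_set` with pixels, or a bare `n x size^2` matrix.
#' @return A data frame of logit records.
#' @export
predict_logits <- function(model, samples) {
  if (inherits(samples, "patch_set")) {
    if (is.null(samples$pixels)) stop("patch set has no materialised pixels")
    X <- samples$pixels
    meta <- samples$samples[c("image_id", "group_id", "label", "X", "Y")]
    names(meta)[names(meta) == "label"] <- "true_label"
  } else {
    X <- samples
    meta <- data.frame(row = seq_len(nrow(X)))
  }
  logits <- nn_forward(model, nn_preprocess(model, X))$logits
  pred_code <- max.col(logits, ties.method = "first") - 1L
  out <- cbind(meta,
               data.frame(predicted_label = model$cfg$classes[pred_code + 1L],
                          stringsAsFactors = FALSE))
  colnames(logits) <- paste0("logit_", model$cfg$classes)
  cbind(out, as.data.frame(logits))
}

#' Select the best hyperparameter candidate from cross-validation results
#'
#' Each candidate carries its configuration and one training history per
#' fold. A candidate's score is the mean over folds of the best-epoch
#' validation F1; the highest score wins, ties broken by fewer mean epochs
#' to the best F1, then by candidate order. Candidates with any failed fold
#' are disqualified.
#'
#' @param cv_results A list of candidates, each
#'   `list(config = ..., folds = list(<history data frames>))`.
#' @return The winning candidate's `config`, with attributes `score`
#'   (mean best validation F1) and `mean_epochs`.
#' @export
select_hyperparameters <- function(cv_results) {
  if (!length(cv_results)) stop("no cross-validation results supplied")
  scores <- epochs <- rep(NA_real_, length(cv_results))
  for (i in seq_along(cv_results)) {
    folds <- cv_results[[i]]$folds
    ok <- length(folds) > 0L &&
      all(vapply(folds, function(h) is.data.frame(h) && nrow(h) > 0L, TRUE))
    if (!ok) next   # disqualified: missing or failed fold
    best_f1 <- vapply(folds, function(h) max(h$val_f1, na.rm = TRUE), 1)
    best_ep <- vapply(folds, function(h) which.max(h$val_f1), 1L)
    scores[i] <- mean(best_f1)
    epochs[i] <- mean(best_ep)
  }
  if (all(is.na(scores))) stop("every candidate had a failed fold")
  best <- which(scores == max(scores, na.rm = TRUE))
  if (length(best) > 1L) best <- best[order(epochs[best])]
  winner <- best[1L]
  structure(cv_results[[winner]]$config,
            score = scores[winner], mean_epochs = epochs[winner])
}

#' Cross-validate candidate configurations on grouped folds
#'
#' Convenience wrapper: trains each candidate `(config, schedule)` on every
#' fold of [kfold_groups()] and collects histories in the shape expected by
#' [select_hyperparameters()].
#'
#' @param folds Result of [kfold_groups()] (fit/val pairs with pixels).
#' @param candidates List of `list(config = model_config,
#'   schedule = train_schedule)` candidates.
#' @param seed Integer seed.
#' @return A `cv_results` list.
#' @export
cross_validate <- function(folds, candidates, seed = 1L) {
  lapply(seq_along(candidates), function(i) {
    cand <- candidates[[i]]
    hists <- lapply(seq_along(folds), function(f) {
      m <- build_model(cand$config, seed = derive_seed(seed, paste0("cv", i, "_", f)))
      tryCatch(
        train_two_phase(m, folds[[f]]$fit, folds[[f]]$val,
                        cand$schedule,
                        seed = derive_seed(seed, paste0("cvtrain", i, "_", f)))$history,
        error = function(e) NULL)
    })
    list(config = cand$config, folds = hists)
  })
}

#' Save / load a trained model
#'
#' The checkpoint is an RDS file holding the full model object plus a JSON
#' sidecar (`<path>.json`) recording the configuration and training history
#' for provenance.
#'
#' @param model A `rib_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the `rib_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(config = unclass(model$cfg), trained = model$trained,
                  history = model$history)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "rib_model"))
  model
}
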