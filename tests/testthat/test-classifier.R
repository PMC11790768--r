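test_that("the model emits one pre-softmax score per class, deterministically", {
  m <- build_model(model_config(), seed = 1L)
  ps <- make_separable_patches(n_groups_per_class = 1L, reps = 1L)
  rec <- predict_logits(m, ps)
  expect_equal(nrow(rec), nrow(ps$samples))
  expect_true(all(paste0("logit_", rib_classes()) %in% names(rec)))
  ## eval mode: repeated prediction is bit-identical (dropout disabled)
  rec2 <- predict_logits(m, ps)
  expect_identical(rec, rec2)
  ## records preserve input order and refs
  expect_equal(rec$group_id, ps$samples$group_id)

  expect_error(build_model(model_config("residual50_pretrained")),
               "pretrained")
  expect_error(model_config(dropout_rate = 1))
})

test_that("softmax of the scores is a probability vector and argmax is shift-invariant", {
  m <- build_model(model_config(), seed = 2L)
  ps <- make_separable_patches(n_groups_per_class = 1L, reps = 2L)
  rec <- predict_logits(m, ps)
  sc <- as.matrix(rec[paste0("logit_", rib_classes())])
  pr <- exp(sc) / rowSums(exp(sc))
  expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-6)
  ## adding a constant to one record's scores cannot change its argmax
  shifted <- sc + 3.7
  expect_equal(max.col(shifted, ties.method = "first"),
               max.col(sc, ties.method = "first"))
})

test_that("analytic gradients match finite differences", {
  m <- build_model(model_config(batch_size = 4L), seed = 3L)
  set.seed(5)
  X <- matrix(runif(4 * 99^2, 0, 255), 4, 99^2)
  y <- c(0L, 1L, 3L, 4L)
  Xp <- ribfrax:::nn_preprocess(m, X)
  cache <- ribfrax:::nn_forward(m, Xp, training = FALSE, keep_cache = TRUE)
  grads <- ribfrax:::nn_backward(m, cache, y, frozen = FALSE)
  loss_at <- function(model) {
    ribfrax:::nn_loss(ribfrax:::nn_forward(model, Xp)$logits, y)
  }
  eps <- 1e-5
  for (nm in c("Wc", "bc", "W1", "b2", "W3", "b3")) {
    idx <- sample(length(m$params[[nm]]), min(8L, length(m$params[[nm]])))
    for (i in idx) {
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("phase one freezes the backbone bit-for-bit", {
  ps <- make_separable_patches(n_groups_per_class = 3L, reps = 2L,
                               classes = c("no_fracture", "ad_latus"))
  sp <- group_split(ps, 0.3, seed = 1L, tolerance = 0.2)
  cfg <- model_config(n_classes = 2L,
                      classes = c("no_fracture", "ad_latus"))
  m0 <- build_model(cfg, seed = 1L)
  fitd <- ribfrax:::prepare_training_data(m0, sp$train)
  vald <- ribfrax:::prepare_training_data(m0, sp$test)
  sched <- train_schedule(max_epochs_phase1 = 3L, max_epochs_phase2 = 2L)
  p1 <- ribfrax:::train_phase(m0, fitd, vald, sched$lr_phase1, 3L, sched,
                              frozen = TRUE, phase_name = "phase1", seed = 1L)
  expect_identical(p1$model$params$Wc, m0$params$Wc)
  expect_identical(p1$model$params$bc, m0$params$bc)
  expect_false(identical(p1$model$params$W1, m0$params$W1))
  ## phase 2 trains the backbone too
  p2 <- ribfrax:::train_phase(p1$model, fitd, vald, sched$lr_phase2, 2L, sched,
                              frozen = FALSE, phase_name = "phase2", seed = 1L)
  expect_false(identical(p2$model$params$Wc, m0$params$Wc))
})

test_that("two-phase training is seed-reproducible and leakage-guarded", {
  ps <- make_separable_patches(n_groups_per_class = 3L, reps = 2L,
                               classes = c("no_fracture", "nondisplaced"))
  sp <- group_split(ps, 0.3, seed = 2L, tolerance = 0.2)
  cfg <- model_config(n_classes = 2L,
                      classes = c("no_fracture", "nondisplaced"))
  sched <- train_schedule(max_epochs_phase1 = 3L, max_epochs_phase2 = 2L)
  m1 <- train_two_phase(build_model(cfg, seed = 7L), sp$train, sp$test,
                        sched, seed = 9L)
  m2 <- train_two_phase(build_model(cfg, seed = 7L), sp$train, sp$test,
                        sched, seed = 9L)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  expect_equal(unique(m1$history$phase), c("phase1", "phase2"))
  ## learning rate never increases within a phase
  for (ph in c("phase1", "phase2")) {
    lr <- m1$history$lr[m1$history$phase == ph]
    expect_true(all(diff(lr) <= 0))
  }
  expect_error(train_two_phase(build_model(cfg), sp$train, sp$train, sched),
               "leakage")
})

test_that("hyperparameter selection follows mean best-F1 with epoch tie-breaks", {
  cfgA <- model_config(); cfgB <- model_config(batch_size = 8L)
  hist <- function(f1s) data.frame(phase = "phase1",
                                   epoch = seq_along(f1s),
                                   train_loss = 1, val_loss = 1, lr = 1e-4,
                                   val_f1 = f1s)
  ## A folds best F1 (0.9, 0.9) at epochs (1, 1); B (0.8, 1.0) at (2, 2):
  ## equal means, A wins on fewer epochs
  cv <- list(list(config = cfgA, folds = list(hist(c(0.9, 0.5)),
                                              hist(c(0.9, 0.1)))),
             list(config = cfgB, folds = list(hist(c(0.1, 0.8)),
                                              hist(c(0.5, 1.0)))))
  best <- select_hyperparameters(cv)
  expect_equal(best, cfgA, ignore_attr = TRUE)
  expect_equal(attr(best, "score"), 0.9)

  single <- select_hyperparameters(list(list(config = cfgB,
                                             folds = list(hist(0.5)))))
  expect_equal(single, cfgB, ignore_attr = TRUE)

  ## a failed fold disqualifies the better-scoring candidate
  cv_fail <- list(list(config = cfgA, folds = list(hist(1.0), NULL)),
                  list(config = cfgB, folds = list(hist(0.4), hist(0.4))))
  expect_equal(select_hyperparameters(cv_fail), cfgB, ignore_attr = TRUE)
  expect_error(select_hyperparameters(list()), "no cross-validation")
})

test_that("checkpoints round trip with a JSON sidecar", {
  m <- build_model(model_config(), seed = 4L)
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  expect_true(file.exists(paste0(f, ".json")))
  back <- load_model(f)
  expect_identical(back$params, m$params)
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(side$config$backbone, "small_convnet_test")
  unlink(c(f, paste0(f, ".json")))
})
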