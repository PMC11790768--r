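#' Pipeline configuration
#'
#' One validated configuration object drives every stage of the pipeline.
#' Defaults describe the standard synthetic study: 12 positive and 4
#' negative unfolded-rib images at the post-crop 500 x 1000 geometry (so the
#' crop is an identity), upscaled 3x to 1500 x 3000, mined into roughly two
#' thousand balanced 99 x 99 patches, split ~70/30 by group, and classified
#' with the CPU test backbone.
#'
#' @param workdir Directory where stages read and write their artifacts.
#' @param sim_params [simulation_params()] for the synthetic stage. The
#'   default uses a clearly separable rendering (motif magnitude 14 px on
#'   14-px bands, noise sigma 1) so that classifier quality reflects the
#'   pipeline, not the generator's difficulty dial.
#' @param n_positive,n_negative Synthetic image counts.
#' @param crop A [crop_spec()].
#' @param upscale_factor Integer upscale factor (default 3).
#' @param patch_size,stride Patch geometry (default 99 / 25).
#' @param shift A [shift_scheme()].
#' @param curation_fraction Minimum extent-box overlap for shifted samples.
#' @param test_fraction,split_tolerance Grouped train/test split control.
#' @param k_folds Cross-validation folds on the training side (default 5).
#' @param model A [model_config()].
#' @param schedule A [train_schedule()].
#' @param seed Master seed for the whole run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(workdir = "ribfrax_run",
                            sim_params = simulation_params(
                              motif_magnitude = 14L, noise_sigma = 1,
                              fractures_per_image = 5L),
                            n_positive = 16L, n_negative = 4L,
                            crop = crop_spec(), upscale_factor = 3L,
                            patch_size = 99L, stride = 25L,
                            shift = shift_scheme(),
                            curation_fraction = 0.5,
                            test_fraction = 0.3, split_tolerance = 0.03,
                            k_folds = 5L,
                            model = model_config(),
                            schedule = train_schedule(),
                            seed = 1L) {
  cfg <- list(workdir = workdir, sim_params = sim_params,
              n_positive = as.integer(n_positive),
              n_negative = as.integer(n_negative),
              crop = crop, upscale_factor = as.integer(upscale_factor),
              patch_size = as.integer(patch_size), stride = as.integer(stride),
              shift = shift, curation_fraction = curation_fraction,
              test_fraction = test_fraction, split_tolerance = split_tolerance,
              k_folds = as.integer(k_folds), model = model,
              schedule = schedule, seed = as.integer(seed))
  stopifnot(inherits(cfg$sim_params, "simulation_params"),
            inherits(cfg$crop, "crop_spec"),
            inherits(cfg$shift, "shift_scheme"),
            inherits(cfg$model, "model_config"),
            inherits(cfg$schedule, "train_schedule"),
            cfg$upscale_factor >= 1L, cfg$patch_size %% 2L == 1L,
            cfg$stride >= 1L, cfg$test_fraction > 0, cfg$test_fraction < 1,
            cfg$curation_fraction >= 0, cfg$curation_fraction <= 1,
            cfg$n_positive >= 0L, cfg$n_negative >= 0L)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognised keys mirror the arguments of [pipeline_config()]; nested
#' sections `sim_params`, `crop`, `shift`, `model` and `schedule` are passed
#' to their respective constructors. Missing keys keep their defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @param workdir Optional workdir override.
#' @param seed Optional seed override.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, workdir = NULL, seed = NULL) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (key in c("workdir", "n_positive", "n_negative", "upscale_factor",
                "patch_size", "stride", "curation_fraction", "test_fraction",
                "split_tolerance", "k_folds", "seed")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  if (!is.null(raw$sim_params)) {
    sp <- raw$sim_params
    if (!is.null(sp$class_mix)) sp$class_mix <- unlist(sp$class_mix)
    args$sim_params <- do.call(simulation_params, sp)
  }
  if (!is.null(raw$crop)) args$crop <- do.call(crop_spec, raw$crop)
  if (!is.null(raw$shift)) args$shift <- do.call(shift_scheme, raw$shift)
  if (!is.null(raw$model)) args$model <- do.call(model_config, raw$model)
  if (!is.null(raw$schedule)) args$schedule <- do.call(train_schedule, raw$schedule)
  if (!is.null(workdir)) args$workdir <- workdir
  if (!is.null(seed)) args$seed <- seed
  do.call(pipeline_config, args)
}

stage_paths <- function(cfg) {
  w <- cfg$workdir
  list(raw = file.path(w, "raw"),
       large = file.path(w, "large"),
       annotations_large = file.path(w, "annotations_large.csv"),
       mined = file.path(w, "mined"),
       splits = file.path(w, "splits.csv"),
       model = file.path(w, "model.rds"),
       predictions = file.path(w, "predictions.csv"),
       aggregated = file.path(w, "aggregated.csv"),
       metrics = file.path(w, "metrics"),
       manifest = file.path(w, "run_manifest.json"))
}

require_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    stop(sprintf("missing artifact '%s'; run the '%s' stage first",
                 path, producer))
  }
  path
}

update_run_manifest <- function(cfg, stage) {
  p <- stage_paths(cfg)
  manifest <- if (file.exists(p$manifest)) {
    jsonlite::read_json(p$manifest, simplifyVector = TRUE)
  } else {
    list(config = serialize_config(cfg), seed = cfg$seed,
         package_version = as.character(utils::packageVersion("ribfrax")),
         stages = character(0))
  }
  manifest$stages <- union(manifest$stages, stage)
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

serialize_config <- function(cfg) {
  out <- lapply(unclass(cfg), function(x) {
    if (is.list(x) || !is.null(attr(x, "class"))) unclass(x) else x
  })
  out$sim_params$class_mix <- as.list(cfg$sim_params$class_mix)
  out
}

read_large_images <- function(cfg, ids) {
  p <- stage_paths(cfg)
  out <- list()
  for (id in ids) {
    f <- require_artifact(file.path(p$large, paste0(id, ".png")), "preprocess")
    out[[id]] <- read_unfolded(f, image_id = id, stage = "large")
  }
  out
}

stage_simulate <- function(cfg) {
  p <- stage_paths(cfg)
  params <- cfg$sim_params
  params$seed <- derive_seed(cfg$seed, "simulate")
  generate_dataset(params, cfg$n_positive, cfg$n_negative, p$raw)
}

stage_preprocess <- function(cfg) {
  p <- stage_paths(cfg)
  manifest <- jsonlite::read_json(
    require_artifact(file.path(p$raw, "manifest.json"), "simulate"),
    simplifyVector = TRUE)
  dir.create(p$large, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(manifest$images))) {
    id <- manifest$images$image_id[i]
    raw <- read_unfolded(file.path(p$raw, manifest$images$file[i]),
                         image_id = id, stage = "raw")
    large <- upscale_image(crop_image(raw, cfg$crop), cfg$upscale_factor)
    write_unfolded(large, file.path(p$large, paste0(id, ".png")))
  }
  anns <- utils::read.csv(
    require_artifact(file.path(p$raw, "annotations.csv"), "simulate"),
    stringsAsFactors = FALSE)
  anns <- annotations_to_large(anns, cfg$crop, cfg$upscale_factor)
  utils::write.csv(anns, p$annotations_large, row.names = FALSE, quote = FALSE)
  invisible(anns)
}

stage_mine <- function(cfg) {
  p <- stage_paths(cfg)
  manifest <- jsonlite::read_json(
    require_artifact(file.path(p$raw, "manifest.json"), "simulate"),
    simplifyVector = TRUE)
  anns <- utils::read.csv(require_artifact(p$annotations_large, "preprocess"),
                          stringsAsFactors = FALSE)
  curation <- curation_overlap(cfg$curation_fraction)

  pos_ids <- manifest$images$image_id[manifest$images$role == "positive"]
  neg_ids <- manifest$images$image_id[manifest$images$role == "negative"]

  pos_sets <- list()
  for (id in pos_ids) {
    img <- read_large_images(cfg, id)[[1L]]
    pos_sets[[id]] <- mine_fracture_samples(
      img, anns[anns$image_id == id, , drop = FALSE], cfg$shift, curation,
      size = cfg$patch_size)
  }
  positives <- if (length(pos_sets)) do.call(bind_patches, pos_sets) else NULL

  neg_sets <- list()
  for (id in neg_ids) {
    img <- read_large_images(cfg, id)[[1L]]
    neg_sets[[id]] <- mine_negative_samples(img, anns, size = cfg$patch_size,
                                            stride = cfg$stride)
  }
  mined <- NULL
  if (length(neg_sets)) {
    negatives <- do.call(bind_patches, neg_sets)
    n_target <- if (is.null(positives)) nrow(negatives$samples)
                else min(nrow(positives$samples), nrow(negatives$samples))
    negatives <- balance_negatives(negatives, n_target,
                                   derive_seed(cfg$seed, "mine"))
    negatives <- materialize_patches(negatives, read_large_images(cfg, neg_ids))
    mined <- if (is.null(positives)) negatives
             else bind_patches(positives, negatives)
  } else {
    mined <- positives
  }
  if (is.null(mined) || !nrow(mined$samples)) stop("mining produced no samples")
  write_patches(mined, p$mined)
  invisible(mined)
}

stage_split <- function(cfg) {
  p <- stage_paths(cfg)
  require_artifact(file.path(p$mined, "samples.csv"), "mine")
  mined <- read_patches(p$mined)
  split <- group_split(mined, cfg$test_fraction,
                       seed = derive_seed(cfg$seed, "split"),
                       tolerance = cfg$split_tolerance)
  folds <- kfold_groups(split$train, cfg$k_folds,
                        seed = derive_seed(cfg$seed, "folds"))
  write_split_manifest(split, folds, p$splits)
  invisible(split)
}

load_split <- function(cfg) {
  p <- stage_paths(cfg)
  manifest <- utils::read.csv(require_artifact(p$splits, "split"),
                              stringsAsFactors = FALSE)
  mined <- read_patches(p$mined)
  gid <- mined$samples$group_id
  part <- manifest$partition[match(gid, manifest$group_id)]
  fold <- manifest$fold[match(gid, manifest$group_id)]
  list(train = subset_patches(mined, which(part == "train")),
       test = subset_patches(mined, which(part == "test")),
       train_fold = fold[part == "train"])
}

stage_train <- function(cfg) {
  p <- stage_paths(cfg)
  sp <- load_split(cfg)
  ## fold 1 of the grouped CV partition serves as the early-stopping
  ## validation split for the final model
  in_val <- sp$train_fold == 1L
  fit <- subset_patches(sp$train, which(!in_val))
  val <- subset_patches(sp$train, which(in_val))
  model <- build_model(cfg$model, input_size = cfg$patch_size,
                       seed = derive_seed(cfg$seed, "init"))
  model <- train_two_phase(model, fit, val, cfg$schedule,
                           seed = derive_seed(cfg$seed, "train"))
  save_model(model, p$model)
  invisible(model)
}

stage_predict <- function(cfg) {
  p <- stage_paths(cfg)
  model <- load_model(require_artifact(p$model, "train"))
  sp <- load_split(cfg)
  records <- predict_logits(model, sp$test)
  utils::write.csv(records, p$predictions, row.names = FALSE, quote = FALSE)
  invisible(records)
}

stage_aggregate <- function(cfg) {
  p <- stage_paths(cfg)
  records <- utils::read.csv(require_artifact(p$predictions, "predict"),
                             stringsAsFactors = FALSE)
  agg <- aggregate_predictions(records, cfg$model$classes)
  utils::write.csv(agg, p$aggregated, row.names = FALSE, quote = FALSE)
  invisible(agg)
}

stage_evaluate <- function(cfg) {
  p <- stage_paths(cfg)
  records <- utils::read.csv(require_artifact(p$predictions, "predict"),
                             stringsAsFactors = FALSE)
  agg <- utils::read.csv(require_artifact(p$aggregated, "aggregate"),
                         stringsAsFactors = FALSE)
  reports <- evaluate_all(records, agg)
  dir.create(p$metrics, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(reports)) {
    write_metrics(reports[[nm]], file.path(p$metrics, paste0(nm, ".json")))
  }
  summary_lines <- vapply(reports, function(r) {
    sprintf("%-16s n=%5d  accuracy=%.3f  F1=%.3f  precision=%.3f  recall=%.3f",
            paste0(r$level, "/", r$assessment), r$n, r$accuracy, r$macro_f1,
            r$macro_precision, r$macro_recall)
  }, "")
  writeLines(summary_lines, file.path(p$metrics, "summary.txt"))
  invisible(reports)
}

#' Run one pipeline stage (or all of them)
#'
#' Stages communicate through files under `cfg$workdir`, so any stage can be
#' rerun in isolation once its upstream artifacts exist; a missing upstream
#' artifact raises an error naming the stage that produces it. Every stage
#' updates `run_manifest.json` (configuration, seed, package version,
#' completed stages) so a run is reconstructible from its manifest.
#'
#' @param name One of `"simulate"`, `"preprocess"`, `"mine"`, `"split"`,
#'   `"train"`, `"predict"`, `"aggregate"`, `"evaluate"`, `"all"`.
#' @param cfg A [pipeline_config()].
#' @return The stage's main in-memory artifact, invisibly (`evaluate` and
#'   `all` return the named list of six `metrics_report`s).
#' @export
run_subcommand <- function(name = c("simulate", "preprocess", "mine", "split",
                                    "train", "predict", "aggregate",
                                    "evaluate", "all"),
                           cfg) {
  name <- match.arg(name)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$workdir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (name == "all") {
    c("simulate", "preprocess", "mine", "split", "train", "predict",
      "aggregate", "evaluate")
  } else name
  out <- NULL
  for (st in stages) {
    out <- switch(st,
      simulate = stage_simulate(cfg),
      preprocess = stage_preprocess(cfg),
      mine = stage_mine(cfg),
      split = stage_split(cfg),
      train = stage_train(cfg),
      predict = stage_predict(cfg),
      aggregate = stage_aggregate(cfg),
      evaluate = stage_evaluate(cfg))
    update_run_manifest(cfg, st)
  }
  invisible(out)
}
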