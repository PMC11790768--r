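## Shared fixtures, all built in code at test time.

## A flat synthetic band segment: horizontal band of `thickness` rows
## centred vertically, intensity `band` on background `bg`.
flat_band_segment <- function(nrow = 60L, ncol = 69L, thickness = 14L,
                              band = 200, bg = 20) {
  seg <- matrix(bg, nrow, ncol)
  mid <- nrow %/% 2L
  rows <- (mid - thickness %/% 2L):(mid + thickness %/% 2L - 1L)
  seg[rows, ] <- band
  seg
}

## Per-column intensity-weighted vertical centroid of the band pixels.
band_centroids <- function(seg) {
  thr <- (min(seg) + max(seg)) / 2
  vapply(seq_len(ncol(seg)), function(cc) {
    w <- pmax(seg[, cc] - min(seg), 0)
    w[seg[, cc] <= thr] <- 0
    if (sum(w) == 0) NA_real_ else sum(seq_len(nrow(seg)) * w) / sum(w)
  }, numeric(1))
}

## Metadata-only grouped dataset: n_groups groups with labels over the five
## terminal classes and group sizes in 1..17 (negatives size 1).
make_grouped_metadata <- function(n_groups = 200L, seed = 1L) {
  withr::with_seed(seed, {
    labels <- sample(rib_classes(), n_groups, replace = TRUE)
    rows <- lapply(seq_len(n_groups), function(g) {
      n <- if (labels[g] == "no_fracture") 1L else sample(1:17, 1L)
      data.frame(image_id = sprintf("img%02d", g %% 10L),
                 group_id = sprintf("g%04d", g), label = labels[g],
                 X = 500L, Y = 500L,
                 dx = c(0L, seq_len(n - 1L) * 0L)[seq_len(n)], dy = 0L,
                 stringsAsFactors = FALSE)
    })
    patch_set(do.call(rbind, rows), NULL, 99L)
  })
}

## Small separable patch_set for classifier unit tests: each class gets a
## distinct bright block on a noisy background; groups of `reps` patches.
make_separable_patches <- function(n_groups_per_class = 4L, reps = 3L,
                                   classes = rib_classes(), seed = 1L,
                                   size = 99L) {
  withr::with_seed(seed, {
    samples <- list(); px <- list()
    k <- 0L
    for (cl in classes) {
      code <- match(cl, rib_classes()) - 1L
      for (g in seq_len(n_groups_per_class)) {
        k <- k + 1L
        gid <- sprintf("%s_g%02d", cl, g)
        for (r in seq_len(reps)) {
          m <- matrix(stats::runif(size^2, 0, 40), size, size)
          if (code > 0L) {
            rows <- ((code - 1L) * 20L + 5L):((code - 1L) * 20L + 20L)
            m[rows, 30:70] <- 220
          }
          samples[[length(samples) + 1L]] <- data.frame(
            image_id = "synthetic", group_id = gid, label = cl,
            X = 50L, Y = 50L, dx = 0L, dy = 0L, stringsAsFactors = FALSE)
          px[[length(px) + 1L]] <- as.vector(m)
        }
      }
    }
    patch_set(do.call(rbind, samples), do.call(rbind, px), size)
  })
}

## Literal enumeration of the two aggregation equations, written
## independently of the package implementation (scalar loops).
oracle_aggregate <- function(labels, score_matrix) {
  s <- 0
  for (i in seq_along(labels)) s <- s + labels[i]
  Y <- if (s == 0) 0L else 1L
  if (Y == 0L) return(list(Y = 0L, final_label = 0L))
  n <- nrow(score_matrix)
  best_c <- NA_integer_; best_mean <- -Inf
  for (cl in 2:ncol(score_matrix)) {      # fracture classes only
    tot <- 0
    for (i in seq_len(n)) tot <- tot + score_matrix[i, cl]
    m <- tot / n
    if (m > best_mean + 1e-12) { best_mean <- m; best_c <- cl - 1L }
  }
  list(Y = 1L, final_label = best_c)
}

## A random logit_group with consistent labels (argmax of each row).
random_logit_group <- function(n_max = 5L, c_max = 5L) {
  n <- sample.int(n_max, 1L)
  scores <- matrix(stats::rnorm(n * c_max), n, c_max)
  logit_group(paste0("rg", sample.int(1e6, 1L)),
              labels = max.col(scores, ties.method = "first") - 1L,
              score_matrix = scores,
              true_label = sample(rib_classes(), 1L))
}

## Tiny pipeline config for file-based orchestration tests.
tiny_pipeline_config <- function(workdir, seed = 42L) {
  pipeline_config(
    workdir = workdir,
    sim_params = simulation_params(
      image_height = 150L, image_width = 400L, n_rib_bands = 3L,
      motif_magnitude = 14L, noise_sigma = 1, fractures_per_image = 2L,
      class_mix = c(nondisplaced = 0.5, cum_distractione = 0.5)),
    n_positive = 4L, n_negative = 2L,
    crop = crop_spec(height = 150L, width = 400L),
    schedule = train_schedule(max_epochs_phase1 = 2L, max_epochs_phase2 = 2L),
    k_folds = 2L, split_tolerance = 0.2, seed = seed)
}
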