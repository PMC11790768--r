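#' Group table of a patch set
#'
#' Summarises a `patch_set` at the aggregation-unit level: one row per
#' `group_id` with its terminal label and sample count. All representations
#' of one fracture share a group; every group carries exactly one label.
#'
#' @param ps A `patch_set`.
#' @return Data frame with columns `group_id`, `label`, `n`.
#' @export
group_table <- function(ps) {
  s <- ps$samples
  lab <- tapply(s$label, s$group_id, unique, simplify = FALSE)
  bad <- names(lab)[lengths(lab) != 1L]
  if (length(bad)) {
    stop("group(s) with mixed labels: ", paste(bad, collapse = ", "))
  }
  n <- tapply(seq_len(nrow(s)), s$group_id, length)
  data.frame(group_id = names(lab), label = unlist(lab),
             n = as.integer(n[names(lab)]), row.names = NULL,
             stringsAsFactors = FALSE)
}

## greedy per-class assignment of whole groups to the test side until the
## class's test sample mass reaches test_fraction; the last group of a class
## is never moved so both sides keep every class.
assign_groups_test <- function(gt, test_fraction) {
  test_ids <- character(0)
  for (cl in unique(gt$label)) {
    g <- gt[gt$label == cl, , drop = FALSE]
    if (nrow(g) < 2L) {
      stop(sprintf(
        "class '%s' has a single group; cannot stratify a grouped split", cl))
    }
    g <- g[sample.int(nrow(g)), , drop = FALSE]
    target <- test_fraction * sum(g$n)
    cum <- 0
    for (i in seq_len(nrow(g) - 1L)) {   # keep >= 1 group on the train side
      if (cum >= target) break
      test_ids <- c(test_ids, g$group_id[i])
      cum <- cum + g$n[i]
    }
  }
  test_ids
}

#' Leakage-safe grouped train/test split
#'
#' Assigns whole groups (all representations of one fracture, or one negative
#' window) to either side so no group is ever split across the boundary.
#' Assignment is stratified by terminal class — every class appears on both
#' sides — and targets a realised test sample-fraction of `test_fraction`
#' (achieved within `tolerance` when group sizes allow; a warning is raised
#' otherwise).
#'
#' @param ps A `patch_set`.
#' @param test_fraction Fraction of samples routed to the test side
#'   (default 0.3, i.e. a ~70/30 split).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param tolerance Allowed deviation of the realised fraction (default 0.03).
#' @return A list with `train` and `test` `patch_set`s and the realised
#'   `test_fraction`.
#' @export
group_split <- function(ps, test_fraction = 0.3, seed = 1L, tolerance = 0.03) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  gt <- group_table(ps)
  test_ids <- with_seed(derive_seed(seed, "group_split"),
                        assign_groups_test(gt, test_fraction))
  in_test <- ps$samples$group_id %in% test_ids
  realized <- mean(in_test)
  if (abs(realized - test_fraction) > tolerance) {
    warning(sprintf(
      "realised test fraction %.3f outside %.3f +/- %.3f (group sizes are indivisible)",
      realized, test_fraction, tolerance))
  }
  list(train = subset_patches(ps, which(!in_test)),
       test = subset_patches(ps, which(in_test)),
       test_fraction = realized)
}

#' Grouped, stratified k-fold partition
#'
#' Partitions the groups of a training set into `k` disjoint folds (groups
#' dealt round-robin per class after a seeded shuffle, so per-class group
#' counts per fold differ by at most one). Each fold serves as the validation
#' set exactly once; group integrity holds within every (fit, val) pair.
#'
#' @param ps A `patch_set` (the training side of [group_split()]).
#' @param k Number of folds (default 5); must be >= 2 and <= number of groups.
#' @param seed Integer seed.
#' @return A list of `k` elements, each `list(fit = patch_set,
#'   val = patch_set)`, with an `assignment` attribute mapping `group_id`
#'   to fold.
#' @export
kfold_groups <- function(ps, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k-fold cross-validation requires k >= 2")
  gt <- group_table(ps)
  if (nrow(gt) < k) {
    stop(sprintf("only %d groups available for %d folds", nrow(gt), k))
  }
  fold_of <- with_seed(derive_seed(seed, "kfold"), {
    out <- integer(nrow(gt))
    names(out) <- gt$group_id
    offset <- 0L
    for (cl in unique(gt$label)) {
      ids <- gt$group_id[gt$label == cl]
      ids <- ids[sample.int(length(ids))]
      out[ids] <- ((seq_along(ids) - 1L + offset) %% k) + 1L
      offset <- offset + length(ids)
    }
    out
  })
  folds <- lapply(seq_len(k), function(f) {
    val_ids <- names(fold_of)[fold_of == f]
    in_val <- ps$samples$group_id %in% val_ids
    list(fit = subset_patches(ps, which(!in_val)),
         val = subset_patches(ps, which(in_val)))
  })
  attr(folds, "assignment") <- data.frame(
    group_id = names(fold_of), fold = unname(fold_of),
    stringsAsFactors = FALSE)
  folds
}

#' Check that two patch sets share no group
#'
#' The defining leakage property of every split boundary in the pipeline.
#'
#' @param a,b `patch_set`s.
#' @return `TRUE` if the group-id sets are disjoint, else `FALSE`.
#' @export
groups_disjoint <- function(a, b) {
  !any(unique(a$samples$group_id) %in% unique(b$samples$group_id))
}

#' Write a split manifest for exact reruns
#'
#' @param split Result of [group_split()].
#' @param folds Optional result of [kfold_groups()] on the train side.
#' @param path CSV output path.
#' @return The manifest data frame (columns `group_id`, `partition`,
#'   `fold`), invisibly.
#' @export
write_split_manifest <- function(split, folds = NULL, path) {
  tr <- unique(split$train$samples$group_id)
  te <- unique(split$test$samples$group_id)
  df <- data.frame(group_id = c(tr, te),
                   partition = c(rep("train", length(tr)),
                                 rep("test", length(te))),
                   fold = NA_integer_, stringsAsFactors = FALSE)
  if (!is.null(folds)) {
    asg <- attr(folds, "assignment")
    df$fold[match(asg$group_id, df$group_id)] <- asg$fold
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
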