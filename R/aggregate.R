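#' Per-fracture collection of patch predictions
#'
#' Holds everything the aggregation formulas consume for one group (one
#' fracture, or one negative window): the n predicted labels
#' \eqn{\hat{y}_1..\hat{y}_n} (0-based integer codes, 0 = no fracture) and
#' the n x c matrix of per-class pre-softmax scores \eqn{logit_i^c}.
#'
#' @param group_id Group identifier.
#' @param labels Integer vector of predicted class codes (each the argmax of
#'   the corresponding score row; validated).
#' @param score_matrix `n x c` numeric matrix of pre-softmax scores.
#' @param true_label The group's true terminal label (optional, for scoring).
#' @return A `logit_group` object.
#' @export
logit_group <- function(group_id, labels, score_matrix, true_label = NA) {
  labels <- as.integer(labels)
  stopifnot(is.matrix(score_matrix), length(labels) == nrow(score_matrix),
            length(labels) >= 1L, all(labels >= 0L),
            all(labels <= ncol(score_matrix) - 1L))
  argmax <- max.col(score_matrix, ties.method = "first") - 1L
  if (!all(labels == argmax)) {
    stop("labels must be the argmax of their score rows")
  }
  structure(list(group_id = as.character(group_id), n = length(labels),
                 c_max = ncol(score_matrix), labels = labels,
                 score_matrix = score_matrix, true_label = true_label),
            class = "logit_group")
}

#' Fracture-presence indicator Y
#'
#' The aggregation gate over a group's predicted labels: returns 0 iff the
#' label sum is zero, i.e. every representation was predicted `no_fracture`
#' (class 0); otherwise 1. A single representation predicting any fracture
#' class is therefore enough to flag the group as a fracture — the weakest
#' signal wins.
#'
#' @param labels Non-empty integer vector of predicted class codes (>= 0).
#' @return `0L` or `1L`.
#' @export
#' @examples
#' indicator_Y(c(0, 0, 0))  # 0
#' indicator_Y(c(0, 0, 3))  # 1
indicator_Y <- function(labels) {
  if (length(labels) == 0L) stop("indicator_Y requires at least one label")
  labels <- as.integer(labels)
  stopifnot(all(labels >= 0L))
  if (sum(labels) == 0L) 0L else 1L
}

#' Mean-logit fracture-type selection k
#'
#' Given the group's score matrix, averages each class's pre-softmax score
#' over the n representations, \eqn{(1/n)\sum_i logit_i^c}, and returns the
#' fracture class attaining the maximum mean. Class 0 (`no_fracture`) is
#' excluded from the maximisation — this function is only called once the Y
#' gate has decided a fracture is present. Ties break toward the lowest
#' class index.
#'
#' @param score_matrix `n x c` matrix of pre-softmax scores (column 1 is
#'   class 0).
#' @return Integer class code in `1..(c-1)`.
#' @export
select_class_k <- function(score_matrix) {
  stopifnot(is.matrix(score_matrix), nrow(score_matrix) >= 1L,
            ncol(score_matrix) >= 2L)
  means <- colMeans(score_matrix)[-1L]
  which.max(means)   # ties: lowest index; codes are 1-based after dropping 0
}

#' Aggregate one group to a single prediction
#'
#' Applies the Y gate to the predicted labels; when Y = 0 the group's final
#' label is class 0, otherwise the fracture type is chosen by
#' [select_class_k()] on the mean pre-softmax scores.
#'
#' @param g A [logit_group()].
#' @return A list with `group_id`, `true_label`, `Y`, `final_label`
#'   (integer code) and `mean_scores`.
#' @export
aggregate_group <- function(g) {
  stopifnot(inherits(g, "logit_group"))
  Y <- indicator_Y(g$labels)
  final <- if (Y == 0L) 0L else as.integer(select_class_k(g$score_matrix))
  list(group_id = g$group_id, true_label = g$true_label, Y = Y,
       final_label = final, mean_scores = colMeans(g$score_matrix))
}

#' Build logit groups from per-patch prediction records
#'
#' Splits the output of [predict_logits()] by `group_id` into
#' [logit_group()] objects (the `logit_*` columns supply the score matrix).
#'
#' @param records Data frame from [predict_logits()] with `group_id`,
#'   `true_label`, `predicted_label` and `logit_*` columns.
#' @param classes Label vocabulary in code order.
#' @return Named list of `logit_group` objects.
#' @export
records_to_groups <- function(records, classes = rib_classes()) {
  score_cols <- paste0("logit_", classes)
  stopifnot(all(score_cols %in% names(records)))
  lapply(split(records, records$group_id), function(r) {
    logit_group(r$group_id[1L],
                labels = match(r$predicted_label, classes) - 1L,
                score_matrix = as.matrix(r[score_cols]),
                true_label = r$true_label[1L])
  })
}

#' Aggregate all groups of a prediction set
#'
#' @param records Data frame from [predict_logits()].
#' @param classes Label vocabulary in code order.
#' @return Data frame with one row per group: `group_id`, `true_label`,
#'   `Y`, `final_label` (as a class label) and `mean_score_<class>` columns.
#' @export
aggregate_predictions <- function(records, classes = rib_classes()) {
  groups <- records_to_groups(records, classes)
  rows <- lapply(groups, function(g) {
    a <- aggregate_group(g)
    out <- data.frame(group_id = a$group_id, true_label = a$true_label,
                      Y = a$Y, final_label = classes[a$final_label + 1L],
                      stringsAsFactors = FALSE)
    ms <- as.data.frame(as.list(a$mean_scores))
    names(ms) <- paste0("mean_score_", classes)
    cbind(out, ms)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
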