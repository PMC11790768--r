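#' Hierarchical taxonomy levels
#'
#' The three evaluation levels of the fracture taxonomy:
#' \describe{
#'   \item{high}{all items in scope; binary `no_fracture` vs `fracture`.}
#'   \item{mid}{items whose true label is a fracture; binary `nondisplaced`
#'     vs `displaced` (= ad latus, cum contractione, cum distractione).}
#'   \item{low}{items whose true label is a displaced subtype; three-class
#'     over the displaced subtypes.}
#' }
#' At mid and low level a prediction can fall outside the level's classes
#' (e.g. a predicted `no_fracture` for a true displaced fracture); such
#' predictions are kept as an explicit `out_of_level` confusion column that
#' counts against the true class's recall but against no in-level class's
#' precision.
#'
#' @param name `"high"`, `"mid"` or `"low"`.
#' @return A `taxonomy_level` object with the level's class set, scope
#'   predicate and terminal-to-level label map.
#' @export
taxonomy_level <- function(name = c("high", "mid", "low")) {
  name <- match.arg(name)
  displaced <- c("ad_latus", "cum_contractione", "cum_distractione")
  lvl <- switch(name,
    high = list(
      classes = c("no_fracture", "fracture"),
      in_scope = function(truth) rep(TRUE, length(truth)),
      class_map = function(lab) ifelse(lab == "no_fracture",
                                       "no_fracture", "fracture")),
    mid = list(
      classes = c("nondisplaced", "displaced"),
      in_scope = function(truth) truth %in% fracture_classes(),
      class_map = function(lab) ifelse(lab == "nondisplaced", "nondisplaced",
                               ifelse(lab %in% displaced, "displaced",
                                      "out_of_level"))),
    low = list(
      classes = displaced,
      in_scope = function(truth) truth %in% displaced,
      class_map = function(lab) ifelse(lab %in% displaced, lab,
                                       "out_of_level")))
  structure(c(list(name = name), lvl), class = "taxonomy_level")
}

#' Score terminal-label predictions at one taxonomy level
#'
#' Restricts to items whose true label is in the level's scope, maps truths
#' and predictions to the level's classes (out-of-level predictions form an
#' explicit error column), and computes the absolute and row-normalised
#' confusion matrices plus accuracy and macro-averaged F1 / precision /
#' recall over the in-level classes. Classes with zero support are flagged
#' and excluded from the macro averages; their relative-confusion rows are
#' all zero.
#'
#' @param truths,preds Aligned character vectors of terminal labels.
#' @param level A [taxonomy_level()].
#' @param assessment Tag recorded on the report (`"standard"` or
#'   `"aggregated"`).
#' @return A `metrics_report` object.
#' @export
score_level <- function(truths, preds, level, assessment = "standard") {
  stopifnot(inherits(level, "taxonomy_level"))
  if (length(truths) != length(preds)) {
    stop("truths and preds must have the same length")
  }
  keep <- level$in_scope(truths)
  truths <- truths[keep]; preds <- preds[keep]
  cls <- level$classes
  has_ool <- level$name != "high"
  cols <- if (has_ool) c(cls, "out_of_level") else cls
  empty <- length(truths) == 0L

  tm <- factor(level$class_map(truths), levels = cls)
  pm <- factor(level$class_map(preds), levels = cols)
  conf <- table(truth = tm, prediction = pm)
  conf <- matrix(as.integer(conf), nrow = length(cls),
                 dimnames = list(truth = cls, prediction = cols))

  support <- rowSums(conf)
  rel <- conf / ifelse(support > 0, support, 1)
  rel[support == 0, ] <- 0

  diag_counts <- conf[cbind(cls, cls)]
  accuracy <- if (sum(conf) > 0) sum(diag_counts) / sum(conf) else NA_real_
  pred_tot <- colSums(conf)[cls]
  precision <- ifelse(pred_tot > 0, diag_counts / pred_tot, 0)
  recall <- ifelse(support > 0, diag_counts / support, NA_real_)
  f1 <- ifelse(!is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall),
               ifelse(is.na(recall), NA_real_, 0))
  scored <- support > 0
  per_class <- data.frame(class = cls, support = as.integer(support),
                          precision = as.numeric(precision),
                          recall = as.numeric(recall), f1 = as.numeric(f1),
                          row.names = NULL, stringsAsFactors = FALSE)

  structure(list(
    level = level$name, assessment = assessment, n = length(truths),
    empty = empty,
    accuracy = accuracy,
    macro_f1 = if (any(scored)) mean(f1[scored]) else NA_real_,
    macro_precision = if (any(scored)) mean(precision[scored]) else NA_real_,
    macro_recall = if (any(scored)) mean(recall[scored]) else NA_real_,
    per_class = per_class,
    zero_support = cls[!scored],
    confusion_abs = conf, confusion_rel = rel), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat(sprintf("<metrics_report> level=%s, assessment=%s, n=%d\n",
              x$level, x$assessment, x$n))
  if (x$empty) {
    cat("  (no items in scope)\n")
    return(invisible(x))
  }
  cat(sprintf("  accuracy=%.*f  macro F1=%.*f  precision=%.*f  recall=%.*f\n",
              digits, x$accuracy, digits, x$macro_f1,
              digits, x$macro_precision, digits, x$macro_recall))
  cat("  confusion (absolute):\n")
  print(x$confusion_abs)
  invisible(x)
}

#' Standard (per-patch) assessment
#'
#' Scores every patch prediction as an independent item, as in plain image
#' classification.
#'
#' @param records Data frame from [predict_logits()] (columns `true_label`,
#'   `predicted_label`).
#' @param level A [taxonomy_level()].
#' @return A `metrics_report`.
#' @export
assess_standard <- function(records, level) {
  if (!nrow(records)) stop("no prediction records to assess")
  score_level(records$true_label, records$predicted_label, level,
              assessment = "standard")
}

#' Aggregated (per-fracture) assessment
#'
#' Scores each group's single aggregated prediction as one item: truth is
#' the group's true label, prediction its aggregated `final_label`.
#'
#' @param aggregated Data frame from [aggregate_predictions()].
#' @param level A [taxonomy_level()].
#' @return A `metrics_report`.
#' @export
assess_aggregated <- function(aggregated, level) {
  if (!nrow(aggregated)) stop("no aggregated predictions to assess")
  score_level(aggregated$true_label, aggregated$final_label, level,
              assessment = "aggregated")
}

#' Evaluate predictions at all levels and assessments
#'
#' Produces the six reports of the full evaluation: three taxonomy levels
#' times the standard and aggregated assessments.
#'
#' @param records Per-patch records from [predict_logits()].
#' @param aggregated Per-group table from [aggregate_predictions()].
#' @return Named list of six `metrics_report`s
#'   (`<level>_<assessment>`).
#' @export
evaluate_all <- function(records, aggregated) {
  out <- list()
  for (lv in c("high", "mid", "low")) {
    level <- taxonomy_level(lv)
    out[[paste0(lv, "_standard")]] <- assess_standard(records, level)
    out[[paste0(lv, "_aggregated")]] <- assess_aggregated(aggregated, level)
  }
  out
}

#' Serialise a metrics report
#'
#' Writes the report as JSON and, optionally, the two confusion matrices as
#' CSV next to it.
#'
#' @param report A `metrics_report`.
#' @param path JSON output path.
#' @param confusion_csv If `TRUE`, also write
#'   `<path>_confusion_{abs,rel}.csv`.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path, confusion_csv = TRUE) {
  obj <- report
  obj$confusion_abs <- as.data.frame.matrix(report$confusion_abs)
  obj$confusion_rel <- as.data.frame.matrix(report$confusion_rel)
  jsonlite::write_json(unclass(obj), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (confusion_csv) {
    stem <- sub("\\.json$", "", path)
    utils::write.csv(report$confusion_abs,
                     paste0(stem, "_confusion_abs.csv"))
    utils::write.csv(report$confusion_rel,
                     paste0(stem, "_confusion_rel.csv"))
  }
  invisible(path)
}
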