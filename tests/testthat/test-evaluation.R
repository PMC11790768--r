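lbl <- function(codes) rib_classes()[codes + 1L]

test_that("perfect predictions score 1.0 with diagonal confusion at every level", {
  truths <- lbl(c(0, 0, 1, 2, 3, 4, 1, 2))
  for (lv in c("high", "mid", "low")) {
    rep <- score_level(truths, truths, taxonomy_level(lv))
    expect_equal(rep$accuracy, 1)
    expect_equal(rep$macro_f1, 1)
    expect_equal(rep$macro_precision, 1)
    expect_equal(rep$macro_recall, 1)
    conf <- rep$confusion_abs
    off <- conf; off[cbind(rownames(conf), rownames(conf))] <- 0L
    expect_true(all(off == 0L))
  }
})

test_that("high-level scoring maps terminals to the binary task", {
  truths <- lbl(c(0, 0, 1, 3))
  preds <- lbl(c(0, 4, 1, 0))
  rep <- score_level(truths, preds, taxonomy_level("high"))
  expect_equal(rep$accuracy, 0.5)   # items 1 and 3 are correct
  expect_equal(rep$n, 4L)
  expect_equal(sum(rep$confusion_abs), 4L)
  expect_equal(rownames(rep$confusion_abs), c("no_fracture", "fracture"))
})

test_that("out-of-level predictions hit recall but not in-level precision", {
  ## two true displaced items: one predicted correctly, one predicted
  ## no_fracture (out of level at mid)
  truths <- lbl(c(2, 2, 1))
  preds <- lbl(c(2, 0, 1))
  rep <- score_level(truths, preds, taxonomy_level("mid"))
  pc <- rep$per_class
  disp <- pc[pc$class == "displaced", ]
  expect_equal(disp$support, 2L)
  expect_equal(disp$recall, 0.5)       # denominator includes the lost item
  expect_equal(disp$precision, 1)      # no in-level column absorbed it
  expect_equal(rep$confusion_abs["displaced", "out_of_level"], 1L)
  expect_equal(sum(rep$confusion_abs[, "out_of_level"]), 1L)

  ## without the out-of-level item precision and recall are both perfect
  rep2 <- score_level(truths[c(1, 3)], preds[c(1, 3)], taxonomy_level("mid"))
  expect_equal(rep2$macro_recall, 1)
})

test_that("relative confusion rows are class recalls and sum to one", {
  set.seed(13)
  truths <- sample(rib_classes(), 300, replace = TRUE)
  preds <- ifelse(runif(300) < 0.6, truths,
                  sample(rib_classes(), 300, replace = TRUE))
  for (lv in c("high", "mid", "low")) {
    rep <- score_level(truths, preds, taxonomy_level(lv))
    sums <- rowSums(rep$confusion_rel)
    support <- rowSums(rep$confusion_abs)
    expect_equal(unname(sums[support > 0]),
                 rep(1, sum(support > 0)), tolerance = 1e-9)
    expect_true(all(sums[support == 0] == 0))
    diag_rel <- rep$confusion_rel[cbind(rownames(rep$confusion_rel),
                                        rownames(rep$confusion_rel))]
    pc <- rep$per_class
    expect_equal(unname(diag_rel[pc$support > 0]),
                 pc$recall[pc$support > 0])
  }
})

test_that("scoring is invariant under item permutation", {
  set.seed(21)
  truths <- sample(rib_classes(), 120, replace = TRUE)
  preds <- sample(rib_classes(), 120, replace = TRUE)
  perm <- sample(120)
  for (lv in c("high", "mid", "low")) {
    a <- score_level(truths, preds, taxonomy_level(lv))
    b <- score_level(truths[perm], preds[perm], taxonomy_level(lv))
    expect_equal(a$confusion_abs, b$confusion_abs)
    expect_equal(a$macro_f1, b$macro_f1)
  }
})

test_that("empty in-scope sets are flagged, not fabricated", {
  rep <- score_level(lbl(c(0, 0)), lbl(c(0, 1)), taxonomy_level("low"))
  expect_true(rep$empty)
  expect_equal(rep$n, 0L)
  expect_true(is.na(rep$accuracy))
  expect_error(score_level(lbl(c(0, 1)), lbl(0), taxonomy_level("high")),
               "length")
})

test_that("standard and aggregated assessments count their own units", {
  classes <- rib_classes()
  ## one fracture group of 17 identical correct patches, one negative group
  rec <- data.frame(
    image_id = "i",
    group_id = rep(c("f1", "n1"), c(17L, 1L)),
    true_label = rep(c("nondisplaced", "no_fracture"), c(17L, 1L)),
    predicted_label = rep(c("nondisplaced", "no_fracture"), c(17L, 1L)))
  sc <- matrix(0, 18, 5, dimnames = list(NULL, paste0("logit_", classes)))
  sc[1:17, 2] <- 3; sc[18, 1] <- 3
  rec <- cbind(rec, as.data.frame(sc))
  std <- assess_standard(rec, taxonomy_level("high"))
  expect_equal(std$n, 18L)          # 17 correct patch items + 1 negative
  agg <- aggregate_predictions(rec, classes)
  agr <- assess_aggregated(agg, taxonomy_level("high"))
  expect_equal(agr$n, 2L)           # one item per group
  expect_equal(agr$accuracy, 1)

  ## groups of n = 1 make the two assessments coincide
  rec1 <- rec[17:18, ]
  rec1$group_id <- c("f1", "n1")
  agg1 <- aggregate_predictions(rec1, classes)
  s1 <- assess_standard(rec1, taxonomy_level("high"))
  a1 <- assess_aggregated(agg1, taxonomy_level("high"))
  expect_equal(s1$confusion_abs, a1$confusion_abs)
})

test_that("the Y gate makes aggregated accuracy at least standard on mixed groups", {
  classes <- rib_classes()
  ## each fracture group holds >= 1 correctly-labelled patch, negatives are
  ## clean: aggregation can only help at the high level
  set.seed(31)
  recs <- list()
  for (g in 1:12) {
    n <- sample(3:6, 1)
    true <- sample(fracture_classes(), 1)
    pred <- c(true, sample(c("no_fracture", true), n - 1L, replace = TRUE))
    sc <- matrix(rnorm(n * 5, sd = 0.1), n, 5)
    for (i in seq_len(n)) {
      sc[i, match(pred[i], classes)] <- 2
    }
    colnames(sc) <- paste0("logit_", classes)
    recs[[g]] <- cbind(data.frame(image_id = "i",
                                  group_id = sprintf("g%02d", g),
                                  true_label = true, predicted_label = pred),
                       as.data.frame(sc))
  }
  rec <- do.call(rbind, recs)
  ## labels must be consistent with score argmax for aggregation
  agg <- aggregate_predictions(rec, classes)
  std <- assess_standard(rec, taxonomy_level("high"))
  agr <- assess_aggregated(agg, taxonomy_level("high"))
  expect_gte(agr$accuracy, std$accuracy)
  expect_equal(agr$accuracy, 1)   # every group had at least one hit
})

test_that("metrics reports serialise to JSON with confusion CSVs", {
  rep <- score_level(lbl(c(0, 1, 2, 3)), lbl(c(0, 1, 2, 4)),
                     taxonomy_level("high"))
  f <- tempfile(fileext = ".json")
  write_metrics(rep, f)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(obj$level, "high")
  expect_equal(obj$accuracy, 1)
  expect_true(file.exists(sub("\\.json$", "_confusion_abs.csv", f)))
  unlink(c(f, sub("\\.json$", "_confusion_abs.csv", f),
           sub("\\.json$", "_confusion_rel.csv", f)))
})
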