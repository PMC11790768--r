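large_const <- function(nr = 300L, nc = 400L, id = "L") {
  unfolded_image(matrix(17, nr, nc), id, "large")
}

test_that("patch extraction is pixel-exact and bounds-checked", {
  img <- unfolded_image(matrix(seq_len(300 * 400) %% 251, 300, 400), "L", "large")
  p <- extract_patch(img, c(50, 50), 99L)
  expect_equal(dim(p), c(99L, 99L))
  expect_equal(p[1, 1], unclass(img)[1, 1])   # window top-left at (1, 1)
  expect_equal(p[99, 99], unclass(img)[99, 99])
  expect_error(extract_patch(img, c(49, 50), 99L), "border")
  expect_error(extract_patch(img, c(50, 352), 99L), "border")
  cp <- extract_patch(large_const(), c(150, 150))
  expect_true(all(cp == 17))
})

test_that("the default shift scheme enumerates the sixteen cardinal shifts", {
  ac <- augment_centers(c(100, 200), shift_scheme())
  expect_equal(nrow(ac), 16L)
  expect_false(any(ac$dx == 0 & ac$dy == 0))
  expect_equal(nrow(unique(ac[c("X", "Y")])), 16L)
  ## extreme shifts in each cardinal direction
  expect_true(all(c(140, 60) %in% ac$X[ac$dy == 0]))
  expect_true(all(c(240, 160) %in% ac$Y[ac$dx == 0]))
  ## shifts move along one axis only
  expect_true(all(xor(ac$dx != 0, ac$dy != 0)))
  expect_equal(nrow(augment_centers(c(1, 1), shift_scheme(10, 0))), 0L)
})

test_that("fracture mining yields 17 grouped samples away from borders", {
  img <- large_const(400, 400)
  anns <- data.frame(image_id = "L", X = 200L, Y = 200L,
                     label = "ad_latus",
                     box_X0 = 180L, box_Y0 = 180L, box_X1 = 220L,
                     box_Y1 = 220L)
  ps <- mine_fracture_samples(img, anns, curation = curation_accept_all())
  expect_equal(nrow(ps$samples), 17L)
  expect_equal(length(unique(ps$samples$group_id)), 1L)
  expect_true(all(ps$samples$label == "ad_latus"))
  ## original retained and flagged by zero shift
  expect_equal(sum(ps$samples$dx == 0 & ps$samples$dy == 0), 1L)

  only_orig <- mine_fracture_samples(img, anns,
                                     curation = curation_reject_shifted())
  expect_equal(nrow(only_orig$samples), 1L)
  expect_equal(only_orig$samples$dx, 0L)
})

test_that("border fractures lose exactly the out-of-bounds shifts", {
  img <- large_const(400, 400)
  ## X = 60: left shifts of 20, 30, 40 px put the window edge past column 1
  anns <- data.frame(image_id = "L", X = 60L, Y = 200L, label = "nondisplaced",
                     box_X0 = 40L, box_Y0 = 180L, box_X1 = 80L, box_Y1 = 220L)
  ps <- mine_fracture_samples(img, anns, curation = curation_accept_all())
  expect_equal(nrow(ps$samples), 14L)          # 17 - 3 dropped left shifts
  expect_setequal(ps$samples$dx[ps$samples$dy == 0],
                  c(0L, 10L, 20L, 30L, 40L, -10L))
  ## original window itself out of bounds: fracture skipped with a warning
  anns$X <- 40L; anns$box_X0 <- 20L; anns$box_X1 <- 60L
  expect_warning(out <- mine_fracture_samples(img, anns), "skipped")
  expect_equal(nrow(out$samples), 0L)
})

test_that("curation drops shifted samples with low extent-box overlap", {
  img <- large_const(600, 600)
  anns <- data.frame(image_id = "L", X = 300L, Y = 300L, label = "ad_latus",
                     box_X0 = 245L, box_Y0 = 230L, box_X1 = 355L,
                     box_Y1 = 370L)   # 111 x 141 box centred on the fracture
  ps <- mine_fracture_samples(img, anns, curation = curation_overlap(0.5))
  ## horizontal shifts of 30/40 px reduce the box overlap below one half
  expect_false(any(abs(ps$samples$dx) > 20))
  expect_true(all(c(-40L, 40L) %in% ps$samples$dy))
})

test_that("sliding-window negatives tile fully-inside windows", {
  img <- unfolded_image(matrix(5, 1500, 3000), "N", "large")
  neg <- mine_negative_samples(img)
  expect_equal(nrow(neg$samples), 57L * 117L)   # 6,669
  expect_equal(length(unique(neg$samples$group_id)), nrow(neg$samples))
  expect_true(all(neg$samples$label == "no_fracture"))
  ## all windows fully inside
  expect_true(all(neg$samples$X - 49 >= 1 & neg$samples$X + 49 <= 3000))
  expect_true(all(neg$samples$Y - 49 >= 1 & neg$samples$Y + 49 <= 1500))

  tiny <- unfolded_image(matrix(5, 98, 200), "T", "large")
  expect_equal(nrow(mine_negative_samples(tiny)$samples), 0L)

  tall <- unfolded_image(matrix(5, 700, 300), "W", "large")
  one_col <- mine_negative_samples(tall, stride = 300L)
  expect_true(all(one_col$samples$X == 50))
  expect_equal(one_col$samples$Y, c(50L, 350L, 650L))  # single window column

  anns <- data.frame(image_id = "N", X = 1, Y = 1, label = "ad_latus")
  expect_error(mine_negative_samples(img, anns), "annotations")
})

test_that("negative balancing is a seeded uniform subset", {
  img <- unfolded_image(matrix(5, 300, 500), "N", "large")
  neg <- mine_negative_samples(img)
  full <- balance_negatives(neg, nrow(neg$samples), seed = 1L)
  expect_setequal(full$samples$group_id, neg$samples$group_id)

  a <- balance_negatives(neg, 20L, seed = 9L)
  b <- balance_negatives(neg, 20L, seed = 9L)
  expect_identical(a$samples, b$samples)
  expect_equal(nrow(a$samples), 20L)
  c <- balance_negatives(neg, 20L, seed = 10L)
  expect_false(identical(a$samples$group_id, c$samples$group_id))
  expect_error(balance_negatives(neg, nrow(neg$samples) + 1L, seed = 1L),
               "available")
})

test_that("augmented windows keep the annotated centre in view", {
  ## max shift 40 < half window 49, so the centre stays inside every patch
  set.seed(4)
  for (i in 1:25) {
    ctr <- c(sample(200:800, 1), sample(200:800, 1))
    ac <- augment_centers(ctr, shift_scheme())
    expect_true(all(abs(ac$X - ctr[1]) <= 49 - 1))
    expect_true(all(abs(ac$Y - ctr[2]) <= 49 - 1))
  }
})

test_that("patch sets round trip through the PNG + CSV store", {
  ps <- make_separable_patches(n_groups_per_class = 1L, reps = 2L,
                               classes = c("no_fracture", "ad_latus"))
  d <- file.path(tempdir(), "patch_store")
  write_patches(ps, d)
  back <- read_patches(d)
  expect_equal(back$samples$group_id, ps$samples$group_id)
  expect_equal(back$samples$label, ps$samples$label)
  expect_equal(back$pixels, round(ps$pixels), ignore_attr = TRUE)
  unlink(d, recursive = TRUE)
})
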