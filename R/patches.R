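#' Patch sample sets
#'
#' A `patch_set` couples a sample table with (optionally materialised) pixel
#' windows. The table has one row per 99x99 patch with columns:
#' `image_id`, `group_id` (fracture id for positives, unique per-sample id
#' for negatives), `label` (terminal class), `X`, `Y` (window centre,
#' large-image frame, 1-based) and `dx`, `dy` (shift relative to the
#' annotated centre; 0,0 for originals and all negatives).
#'
#' Pixels are stored as an `n x size^2` matrix (one flattened column-major
#' window per row) and may be `NULL` until [materialize_patches()] is called
#' — negative mining can enumerate hundreds of thousands of windows per
#' image, which are only extracted after balancing.
#'
#' @param samples Sample data frame as described above.
#' @param pixels Optional `nrow(samples) x size^2` numeric matrix.
#' @param size Odd window edge length in pixels.
#' @return A `patch_set` object.
#' @export
patch_set <- function(samples, pixels = NULL, size = 99L) {
  need <- c("image_id", "group_id", "label", "X", "Y", "dx", "dy")
  stopifnot(is.data.frame(samples), all(need %in% names(samples)))
  if (!is.null(pixels)) {
    stopifnot(is.matrix(pixels), nrow(pixels) == nrow(samples),
              ncol(pixels) == size * size)
  }
  structure(list(samples = samples, pixels = pixels, size = as.integer(size)),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d samples, %d groups, %dx%d px (%s)\n",
              nrow(x$samples), length(unique(x$samples$group_id)),
              x$size, x$size,
              if (is.null(x$pixels)) "pixels pending" else "pixels loaded"))
  if (nrow(x$samples)) print(table(x$samples$label))
  invisible(x)
}

#' Subset a patch set by row indices
#' @param ps A `patch_set`.
#' @param idx Integer row indices.
#' @return A `patch_set` with the selected samples (and pixels, if loaded).
#' @export
subset_patches <- function(ps, idx) {
  patch_set(ps$samples[idx, , drop = FALSE],
            if (is.null(ps$pixels)) NULL else ps$pixels[idx, , drop = FALSE],
            ps$size)
}

#' Concatenate patch sets
#' @param ... `patch_set` objects with the same size and pixel state.
#' @return The combined `patch_set`.
#' @export
bind_patches <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L,
            length(unique(vapply(sets, function(s) s$size, 1L))) == 1L)
  has_px <- vapply(sets, function(s) !is.null(s$pixels), TRUE)
  if (any(has_px) && !all(has_px)) {
    stop("cannot bind patch sets with mixed pixel states")
  }
  patch_set(do.call(rbind, c(lapply(sets, `[[`, "samples"),
                             make.row.names = FALSE)),
            if (all(has_px)) do.call(rbind, lapply(sets, `[[`, "pixels")),
            sets[[1L]]$size)
}

#' Extract one square window from a large image
#'
#' Returns the `size` x `size` pixel-exact window centred on `(X, Y)`.
#' The window must lie fully inside the image; callers that sweep centres
#' near the border catch the error and skip.
#'
#' @param img An `unfolded_image` (stage `"large"` in the standard pipeline).
#' @param center Length-2 vector `(X, Y)`: centre column and row, 1-based.
#' @param size Odd window edge length (default 99).
#' @return A `size` x `size` numeric matrix.
#' @export
extract_patch <- function(img, center, size = 99L) {
  size <- as.integer(size)
  stopifnot(size %% 2L == 1L, size >= 1L)
  h <- (size - 1L) %/% 2L
  X <- as.integer(center[[1L]]); Y <- as.integer(center[[2L]])
  if (X - h < 1L || Y - h < 1L || X + h > ncol(img) || Y + h > nrow(img)) {
    stop(sprintf("patch window at (%d, %d) crosses the image border", X, Y))
  }
  unclass(img)[(Y - h):(Y + h), (X - h):(X + h), drop = FALSE]
}

#' Cardinal shift-augmentation scheme
#'
#' The augmentation used for fracture patches: the sampling window is shifted
#' from the annotated centre along each of the four cardinal directions in
#' steps of `step` pixels, `steps_per_direction` times, yielding
#' `4 * steps_per_direction` additional centres (16 by default).
#'
#' @param step Shift step in pixels (default 10).
#' @param steps_per_direction Shifts per cardinal direction (default 4).
#' @return A `shift_scheme` list.
#' @export
shift_scheme <- function(step = 10L, steps_per_direction = 4L) {
  stopifnot(step >= 1L, steps_per_direction >= 0L)
  structure(list(step = as.integer(step),
                 steps_per_direction = as.integer(steps_per_direction)),
            class = "shift_scheme")
}

#' Enumerate shift-augmented window centres
#'
#' @param center Length-2 vector `(X, Y)`.
#' @param scheme A [shift_scheme()].
#' @return Data frame with columns `X`, `Y`, `dx`, `dy`; exactly
#'   `4 * steps_per_direction` rows, the original centre not included.
#' @export
#' @examples
#' nrow(augment_centers(c(100, 200), shift_scheme()))  # 16
augment_centers <- function(center, scheme = shift_scheme()) {
  X <- as.integer(center[[1L]]); Y <- as.integer(center[[2L]])
  if (scheme$steps_per_direction == 0L) {
    return(data.frame(X = integer(0), Y = integer(0),
                      dx = integer(0), dy = integer(0)))
  }
  k <- scheme$step * seq_len(scheme$steps_per_direction)
  dx <- c(k, -k, rep(0L, 2L * length(k)))
  dy <- c(rep(0L, 2L * length(k)), k, -k)
  data.frame(X = X + dx, Y = Y + dy, dx = as.integer(dx), dy = as.integer(dy))
}

#' Curation predicates for shifted fracture samples
#'
#' The shifted samples are curated before entering the dataset: a shifted
#' window is kept only if the fracture is still usefully visible. The
#' automated proxy used here keeps a shifted sample iff the annotation's
#' extent box overlaps the patch window by at least `min_fraction` of the
#' box's area. `curation_accept_all()` and `curation_reject_shifted()` are
#' the two degenerate predicates.
#'
#' @param min_fraction Minimum overlap fraction of the extent box (default 0.5).
#' @return A predicate `function(window, box)` taking two boxes as
#'   `c(x0, y0, x1, y1)` vectors and returning `TRUE` to keep the sample.
#' @export
curation_overlap <- function(min_fraction = 0.5) {
  force(min_fraction)
  function(window, box) {
    ix <- max(0, min(window[3], box[3]) - max(window[1], box[1]) + 1)
    iy <- max(0, min(window[4], box[4]) - max(window[2], box[2]) + 1)
    area <- (box[3] - box[1] + 1) * (box[4] - box[2] + 1)
    (ix * iy) / area >= min_fraction
  }
}

#' @rdname curation_overlap
#' @export
curation_accept_all <- function() function(window, box) TRUE

#' @rdname curation_overlap
#' @export
curation_reject_shifted <- function() function(window, box) FALSE

#' Map annotations from the raw/cropped frame to the large-image frame
#'
#' Applies [to_large_coords()] to the fracture centres and extent boxes of an
#' annotation table (as produced by [generate_image()]).
#'
#' @param anns Annotation data frame.
#' @param spec The [crop_spec()] in effect.
#' @param factor Upscale factor.
#' @return The annotation table with columns `X`, `Y`, `box_X0`, `box_Y0`,
#'   `box_X1`, `box_Y1` appended (large frame).
#' @export
annotations_to_large <- function(anns, spec = crop_spec(), factor = 3L) {
  if (!nrow(anns)) {
    anns[c("X", "Y", "box_X0", "box_Y0", "box_X1", "box_Y1")] <- integer(0)
    return(anns)
  }
  ctr <- to_large_coords(anns$x, anns$y, spec, factor)
  lo <- to_large_coords(anns$box_x0, anns$box_y0, spec, factor)
  hi <- to_large_coords(anns$box_x1, anns$box_y1, spec, factor)
  h <- (factor - 1L) %/% 2L
  anns$X <- ctr$X; anns$Y <- ctr$Y
  anns$box_X0 <- lo$X - h; anns$box_Y0 <- lo$Y - h
  anns$box_X1 <- hi$X + h; anns$box_Y1 <- hi$Y + h
  anns
}

#' Mine shift-augmented fracture patches from one large image
#'
#' For each annotated fracture, samples the original centred window plus the
#' shift-augmented windows of `scheme` (16 by default). Windows that leave
#' the image are dropped; shifted windows failing the curation predicate are
#' dropped; the original window is always retained when in bounds. All
#' samples of one fracture share a `group_id` so that partitioning can keep
#' them together.
#'
#' @param img An `unfolded_image` at stage `"large"`.
#' @param anns Annotations in large-frame coordinates (see
#'   [annotations_to_large()]) for this image.
#' @param scheme A [shift_scheme()].
#' @param curation A curation predicate (see [curation_overlap()]).
#' @param size Window edge length.
#' @return A `patch_set` with materialised pixels; up to
#'   `1 + 4 * steps_per_direction` samples per fracture.
#' @export
mine_fracture_samples <- function(img, anns, scheme = shift_scheme(),
                                  curation = curation_overlap(), size = 99L) {
  stopifnot(all(c("X", "Y", "label") %in% names(anns)))
  if (nrow(anns) && !all(anns$label %in% fracture_classes())) {
    stop("fracture annotations must carry fracture class labels")
  }
  rows <- list(); px <- list()
  for (i in seq_len(nrow(anns))) {
    a <- anns[i, ]
    gid <- sprintf("%s_f%02d", a$image_id, i)
    box <- c(a$box_X0 %||% (a$X - 1L), a$box_Y0 %||% (a$Y - 1L),
             a$box_X1 %||% (a$X + 1L), a$box_Y1 %||% (a$Y + 1L))
    centers <- rbind(data.frame(X = a$X, Y = a$Y, dx = 0L, dy = 0L),
                     augment_centers(c(a$X, a$Y), scheme))
    h <- (size - 1L) %/% 2L
    in_bounds <- centers$X - h >= 1L & centers$Y - h >= 1L &
      centers$X + h <= ncol(img) & centers$Y + h <= nrow(img)
    if (!in_bounds[1L]) {
      warning(sprintf(
        "fracture %s at (%d, %d): original window out of bounds; skipped",
        gid, a$X, a$Y))
      next
    }
    keep <- in_bounds
    for (j in which(in_bounds)[-1L]) {
      window <- c(centers$X[j] - h, centers$Y[j] - h,
                  centers$X[j] + h, centers$Y[j] + h)
      keep[j] <- isTRUE(curation(window, box))
    }
    sel <- which(keep)
    rows[[gid]] <- data.frame(
      image_id = a$image_id, group_id = gid, label = a$label,
      X = centers$X[sel], Y = centers$Y[sel],
      dx = centers$dx[sel], dy = centers$dy[sel],
      stringsAsFactors = FALSE)
    px[[gid]] <- t(vapply(sel, function(j) {
      as.vector(extract_patch(img, c(centers$X[j], centers$Y[j]), size))
    }, numeric(size * size)))
  }
  if (!length(rows)) {
    return(patch_set(data.frame(image_id = character(0), group_id = character(0),
                                label = character(0), X = integer(0),
                                Y = integer(0), dx = integer(0),
                                dy = integer(0)),
                     matrix(numeric(0), 0L, size * size), size))
  }
  patch_set(do.call(rbind, c(rows, make.row.names = FALSE)),
            do.call(rbind, px), size)
}

#' Enumerate sliding-window negative samples on a fracture-free image
#'
#' Tiles the image with `size` x `size` windows whose top-left corners sit at
#' multiples of `stride` starting from (1, 1), keeping only fully-inside
#' windows. Each window is its own aggregation unit (unique `group_id`) and
#' is labelled `no_fracture`. On the default 1500 x 3000 large image with
#' stride 25 this yields 57 x 117 = 6,669 windows.
#'
#' Pixels are not materialised (see [materialize_patches()]): enumerate, then
#' balance, then extract.
#'
#' @param img An `unfolded_image` at stage `"large"`.
#' @param anns Annotation table; any row for this image is a contract
#'   violation (negatives come from fracture-free images only).
#' @param size Window edge length (default 99).
#' @param stride Grid stride in pixels (default 25).
#' @return A `patch_set` without pixels.
#' @export
mine_negative_samples <- function(img, anns = NULL, size = 99L, stride = 25L) {
  if (!is.null(anns) && any(anns$image_id == image_id(img))) {
    stop("mine_negative_samples called on an image with fracture annotations: ",
         image_id(img))
  }
  h <- (size - 1L) %/% 2L
  tops <- seq.int(1L, nrow(img), by = stride)
  lefts <- seq.int(1L, ncol(img), by = stride)
  tops <- tops[tops + size - 1L <= nrow(img)]
  lefts <- lefts[lefts + size - 1L <= ncol(img)]
  if (!length(tops) || !length(lefts)) {
    samples <- data.frame(image_id = character(0), group_id = character(0),
                          label = character(0), X = integer(0), Y = integer(0),
                          dx = integer(0), dy = integer(0))
    return(patch_set(samples, NULL, size))
  }
  grid <- expand.grid(Y = tops + h, X = lefts + h)
  samples <- data.frame(
    image_id = image_id(img),
    group_id = sprintf("%s_n%06d", image_id(img), seq_len(nrow(grid))),
    label = "no_fracture", X = grid$X, Y = grid$Y, dx = 0L, dy = 0L,
    stringsAsFactors = FALSE)
  patch_set(samples, NULL, size)
}

#' Randomly subsample negatives to balance the dataset
#'
#' Uniform subset without replacement, reproducible for a fixed seed; used to
#' bring the `no_fracture` mass down to the fracture-sample count.
#'
#' @param negatives A `patch_set` of negative samples.
#' @param n_target Target sample count; must not exceed the available count.
#' @param seed Integer seed.
#' @return A `patch_set` of `n_target` samples.
#' @export
balance_negatives <- function(negatives, n_target, seed) {
  n <- nrow(negatives$samples)
  if (n_target > n) {
    stop(sprintf("requested %d negatives but only %d are available",
                 n_target, n))
  }
  idx <- with_seed(derive_seed(seed, "balance_negatives"),
                   sort(sample.int(n, n_target)))
  subset_patches(negatives, idx)
}

#' Materialise pixel windows for a patch set
#'
#' Extracts the pixel window of every sample from its source image. Images
#' are supplied as a named list (or an environment-like getter) keyed by
#' `image_id`, at the large stage.
#'
#' @param ps A `patch_set` (pixels may be `NULL`).
#' @param images Named list of `unfolded_image` objects.
#' @return The `patch_set` with `pixels` filled in.
#' @export
materialize_patches <- function(ps, images) {
  n <- nrow(ps$samples)
  px <- matrix(0, n, ps$size^2)
  for (id in unique(ps$samples$image_id)) {
    img <- images[[id]]
    if (is.null(img)) stop("no image supplied for image_id ", id)
    for (i in which(ps$samples$image_id == id)) {
      px[i, ] <- as.vector(extract_patch(
        img, c(ps$samples$X[i], ps$samples$Y[i]), ps$size))
    }
  }
  patch_set(ps$samples, px, ps$size)
}

#' Write / read a patch set as PNG files plus a samples CSV
#'
#' The on-disk layout is a directory of one 8-bit grayscale PNG per patch and
#' a `samples.csv` with columns
#' `patch_path,image_id,group_id,label,X,Y,dx,dy`.
#'
#' @param ps A `patch_set` with pixels.
#' @param dir Output directory.
#' @return `write_patches()` returns the CSV path invisibly; `read_patches()`
#'   returns a `patch_set`.
#' @export
write_patches <- function(ps, dir) {
  stopifnot(!is.null(ps$pixels))
  dir.create(file.path(dir, "patches"), recursive = TRUE, showWarnings = FALSE)
  paths <- sprintf("patches/patch_%06d.png", seq_len(nrow(ps$samples)))
  for (i in seq_len(nrow(ps$samples))) {
    png::writePNG(matrix(ps$pixels[i, ] / 255, ps$size, ps$size),
                  file.path(dir, paths[i]))
  }
  df <- cbind(data.frame(patch_path = paths), ps$samples)
  csv <- file.path(dir, "samples.csv")
  utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  invisible(csv)
}

#' @rdname write_patches
#' @export
read_patches <- function(dir) {
  df <- utils::read.csv(file.path(dir, "samples.csv"),
                        stringsAsFactors = FALSE)
  size <- NULL
  px <- NULL
  for (i in seq_len(nrow(df))) {
    m <- png::readPNG(file.path(dir, df$patch_path[i]))
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    if (is.null(px)) {
      size <- nrow(m)
      px <- matrix(0, nrow(df), size^2)
    }
    px[i, ] <- as.vector(round(m * 255))
  }
  patch_set(df[setdiff(names(df), "patch_path")], px, size %||% 99L)
}
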