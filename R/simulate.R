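#' Parameters for synthetic unfolded-rib-cage images
#'
#' Controls the seeded generator that emulates the 2-D planar ("unfolded")
#' representation of the rib cage: near-horizontal bright rib bands on a dark
#' background, optionally interrupted by one of four fracture motifs. The
#' generator exists so every downstream stage (mining, splitting, training,
#' aggregation, evaluation) is testable without access to post-mortem CT
#' data, which is private.
#'
#' @param image_height,image_width Output geometry in pixels. Defaults match
#'   the post-crop frame (500 x 1000) so cropping is an identity by default.
#' @param n_rib_bands Number of rib bands drawn.
#' @param band_thickness Band thickness in pixels (>= 3).
#' @param band_intensity,background_intensity Grayscale levels in \[0, 255\].
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise,
#'   in grayscale units.
#' @param motif_magnitude Size in pixels of the class-defining displacement:
#'   the sideways offset (ad latus), the overlap (cum contractione) or the
#'   gap (cum distractione).
#' @param fractures_per_image Number of fractures placed per positive image
#'   (at most one per band).
#' @param class_mix Named numeric vector of probabilities over the four
#'   fracture classes; must sum to 1.
#' @param seed Integer master seed; together with an image id it fully
#'   determines the generated pixels and annotations.
#' @return A validated `simulation_params` list.
#' @export
simulation_params <- function(image_height = 500L, image_width = 1000L,
                              n_rib_bands = 6L, band_thickness = 14L,
                              band_intensity = 200, background_intensity = 20,
                              noise_sigma = 4, motif_magnitude = 10L,
                              fractures_per_image = 4L,
                              class_mix = c(nondisplaced = 0.25, ad_latus = 0.25,
                                            cum_contractione = 0.25,
                                            cum_distractione = 0.25),
                              seed = 1L) {
  p <- list(image_height = as.integer(image_height),
            image_width = as.integer(image_width),
            n_rib_bands = as.integer(n_rib_bands),
            band_thickness = as.integer(band_thickness),
            band_intensity = as.numeric(band_intensity),
            background_intensity = as.numeric(background_intensity),
            noise_sigma = as.numeric(noise_sigma),
            motif_magnitude = as.integer(motif_magnitude),
            fractures_per_image = as.integer(fractures_per_image),
            class_mix = class_mix, seed = as.integer(seed))
  if (abs(sum(p$class_mix) - 1) > 1e-9) {
    stop("class_mix probabilities must sum to 1")
  }
  if (!all(names(p$class_mix) %in% fracture_classes())) {
    stop("class_mix names must be fracture classes: ",
         paste(fracture_classes(), collapse = ", "))
  }
  stopifnot(p$motif_magnitude >= 0L, p$band_thickness >= 3L,
            p$band_intensity >= 0, p$band_intensity <= 255,
            p$background_intensity >= 0, p$background_intensity <= 255,
            p$noise_sigma >= 0, p$fractures_per_image >= 0L,
            p$n_rib_bands >= 1L, p$image_height >= 20L, p$image_width >= 80L)
  structure(p, class = "simulation_params")
}

## Half-width of the motif working segment. Chosen so that the segment edge
## (where the ad-latus shift ends) lies outside every shift-augmented patch
## window: max patch reach from the centre is (40 large px)/3 + 16 = 30
## cropped-frame columns.
motif_halfwidth <- function(magnitude) max(34L, as.integer(3L * magnitude))

#' Render one fracture motif onto a band segment
#'
#' Takes a small intensity grid containing a (roughly horizontal) bright band
#' on a dark background and stamps the geometry that defines one of the four
#' fracture classes at the segment's central column:
#' \describe{
#'   \item{nondisplaced}{a thin dark transverse line; the band's vertical
#'     centre is unchanged on both sides}
#'   \item{ad_latus}{the right half of the band is offset downward by
#'     `magnitude` pixels}
#'   \item{cum_contractione}{a `magnitude`-wide overlap zone where the two
#'     fragments superimpose: brighter and slightly thicker than the band}
#'   \item{cum_distractione}{a `magnitude`-wide gap at background intensity
#'     between the two fragments}
#' }
#' The band is located by thresholding halfway between the segment's minimum
#' and maximum intensity, so the function is intended for the noise-free
#' rendering stage.
#'
#' @param band_segment Numeric matrix containing the band.
#' @param label One of the four fracture classes (never `no_fracture`).
#' @param magnitude Displacement size in pixels.
#' @return The modified segment (same shape).
#' @export
render_motif <- function(band_segment, label, magnitude) {
  stopifnot(is.matrix(band_segment))
  magnitude <- as.integer(magnitude)
  if (!label %in% fracture_classes()) {
    stop("unknown motif label: ", label)
  }
  seg <- band_segment
  nr <- nrow(seg); nc <- ncol(seg)
  if (nc < max(4L, magnitude + 2L)) stop("band segment too narrow for motif")
  bg <- min(seg)
  thr <- (min(seg) + max(seg)) / 2
  mask <- seg > thr
  if (!any(mask)) stop("band segment contains no band above threshold")
  mid <- nc %/% 2L

  if (label == "nondisplaced") {
    cols <- intersect(c(mid, mid + 1L), seq_len(nc))
    for (cc in cols) seg[mask[, cc], cc] <- bg
  } else if (label == "ad_latus") {
    if (magnitude >= nr) stop("segment too short for ad_latus offset")
    if (magnitude > 0L) {
      right <- (mid + 1L):nc
      shifted <- rbind(matrix(bg, magnitude, length(right)),
                       seg[seq_len(nr - magnitude), right, drop = FALSE])
      seg[, right] <- shifted
    }
  } else if (label == "cum_contractione") {
    cols <- (mid - (magnitude %/% 2L)):(mid - (magnitude %/% 2L) + magnitude - 1L)
    cols <- cols[cols >= 1L & cols <= nc]
    bright <- min(255, max(seg) * 1.35)
    for (cc in cols) {
      rows <- which(mask[, cc])
      if (!length(rows)) next
      rows <- max(1L, min(rows) - 2L):min(nr, max(rows) + 2L)
      seg[rows, cc] <- bright
    }
  } else if (label == "cum_distractione") {
    cols <- (mid - (magnitude %/% 2L)):(mid - (magnitude %/% 2L) + magnitude - 1L)
    cols <- cols[cols >= 1L & cols <= nc]
    band_rows <- which(rowSums(mask) > 0)
    if (length(cols) && length(band_rows)) {
      seg[min(band_rows):max(band_rows), cols] <- bg
    }
  }
  seg
}

#' Generate one annotated synthetic unfolded-rib image
#'
#' Draws `n_rib_bands` near-horizontal bands with slight seeded curvature,
#' places `fractures_per_image` motifs (at most one per band, away from the
#' borders), adds Gaussian noise and quantises to 8-bit. The pair
#' `(params, image_id)` fully determines the output.
#'
#' @param params A [simulation_params()] object.
#' @param image_id Character id recorded on the image and its annotations.
#' @return A list with `image` (an `unfolded_image`, stage `"cropped"`) and
#'   `annotations` (a data frame with columns `image_id, x, y, label,
#'   box_x0, box_y0, box_x1, box_y1`; one row per fracture, coordinates
#'   1-based in the generated frame).
#' @export
generate_image <- function(params, image_id) {
  stopifnot(inherits(params, "simulation_params"))
  H <- params$image_height; W <- params$image_width
  t2 <- params$band_thickness / 2
  S <- motif_halfwidth(params$motif_magnitude)
  xmargin <- S + 2L
  if (params$fractures_per_image > 0L) {
    if (params$fractures_per_image > params$n_rib_bands) {
      stop("cannot place ", params$fractures_per_image, " fractures on ",
           params$n_rib_bands, " bands (one fracture per band)")
    }
    if (W < 2L * xmargin + 4L) {
      stop("image too narrow to place fracture motifs away from the borders")
    }
  }

  with_seed(derive_seed(params$seed, image_id), {
    ## band centre-line paths with slight curvature
    base <- H * (seq_len(params$n_rib_bands) - 0.5) / params$n_rib_bands
    base <- base + stats::runif(params$n_rib_bands, -H * 0.02, H * 0.02)
    amp <- stats::runif(params$n_rib_bands, 1, 4)
    phase <- stats::runif(params$n_rib_bands, 0, 2 * pi)
    period <- W * stats::runif(params$n_rib_bands, 1.2, 2.5)
    cols <- seq_len(W)
    px <- matrix(params$background_intensity, H, W)
    paths <- matrix(0, params$n_rib_bands, W)
    for (b in seq_len(params$n_rib_bands)) {
      yb <- base[b] + amp[b] * sin(2 * pi * cols / period[b] + phase[b])
      paths[b, ] <- yb
      bandmask <- abs(outer(seq_len(H), yb, "-")) <= t2
      px[bandmask] <- params$band_intensity
    }

    anns <- data.frame(image_id = character(0), x = integer(0), y = integer(0),
                       label = character(0), box_x0 = integer(0),
                       box_y0 = integer(0), box_x1 = integer(0),
                       box_y1 = integer(0), stringsAsFactors = FALSE)
    if (params$fractures_per_image > 0L) {
      bands <- sample(params$n_rib_bands, params$fractures_per_image)
      labels <- sample(names(params$class_mix), params$fractures_per_image,
                       replace = TRUE, prob = params$class_mix)
      xs <- sample(seq.int(xmargin, W - xmargin), params$fractures_per_image)
      mag <- params$motif_magnitude
      for (i in seq_len(params$fractures_per_image)) {
        b <- bands[i]; x <- xs[i]
        y <- as.integer(round(paths[b, x]))
        rows <- max(1L, y - as.integer(ceiling(t2)) - mag - 4L):
          min(H, y + as.integer(ceiling(t2)) + mag + 4L)
        seg_cols <- (x - S):(x + S)
        seg <- px[rows, seg_cols, drop = FALSE]
        px[rows, seg_cols] <- render_motif(seg, labels[i], mag)
        half_w <- mag + 4L
        anns <- rbind(anns, data.frame(
          image_id = as.character(image_id), x = x, y = y, label = labels[i],
          box_x0 = max(1L, x - half_w),
          box_y0 = max(1L, y - as.integer(ceiling(t2)) - mag - 2L),
          box_x1 = min(W, x + half_w),
          box_y1 = min(H, y + as.integer(ceiling(t2)) + mag + 2L),
          stringsAsFactors = FALSE))
      }
    }

    if (params$noise_sigma > 0) {
      px <- px + matrix(stats::rnorm(H * W, 0, params$noise_sigma), H, W)
    }
    px <- round(pmin(pmax(px, 0), 255))
    list(image = unfolded_image(px, image_id, stage = "cropped"),
         annotations = anns)
  })
}

#' Generate a dataset of synthetic images on disk
#'
#' Writes `n_positive_images` annotated images and `n_negative_images`
#' fracture-free images as 8-bit grayscale PNGs, one annotation CSV covering
#' all positives, and a JSON manifest listing every file with its role.
#'
#' @param params A [simulation_params()] object.
#' @param n_positive_images,n_negative_images Non-negative image counts.
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly: a list with `images` (data frame of
#'   `image_id`, `file`, `role`), `annotations_csv`, and the parameters used.
#' @export
generate_dataset <- function(params, n_positive_images, n_negative_images,
                             out_dir) {
  stopifnot(n_positive_images >= 0L, n_negative_images >= 0L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  neg_params <- params
  neg_params$fractures_per_image <- 0L

  ids <- c(sprintf("pos_%03d", seq_len(n_positive_images)),
           sprintf("neg_%03d", seq_len(n_negative_images)))
  roles <- c(rep("positive", n_positive_images),
             rep("negative", n_negative_images))
  files <- file.path(out_dir, paste0(ids, ".png"))
  all_anns <- list()
  for (i in seq_along(ids)) {
    p <- if (roles[i] == "positive") params else neg_params
    g <- generate_image(p, ids[i])
    write_unfolded(g$image, files[i])
    if (nrow(g$annotations)) all_anns[[ids[i]]] <- g$annotations
  }
  anns <- if (length(all_anns)) do.call(rbind, c(all_anns, make.row.names = FALSE))
          else data.frame(image_id = character(0), x = integer(0),
                          y = integer(0), label = character(0),
                          box_x0 = integer(0), box_y0 = integer(0),
                          box_x1 = integer(0), box_y1 = integer(0))
  ann_path <- file.path(out_dir, "annotations.csv")
  utils::write.csv(anns, ann_path, row.names = FALSE, quote = FALSE)

  manifest <- list(
    images = data.frame(image_id = ids, file = basename(files), role = roles,
                        stringsAsFactors = FALSE),
    annotations_csv = basename(ann_path),
    params = unclass(params))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}
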