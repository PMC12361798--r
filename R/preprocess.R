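#' ROI bounding box
#'
#' Half-open, 0-based pixel box `[x0, x1) x [y0, y1)`.
#'
#' @param x0,y0,x1,y1 box coordinates.
#' @return object of class `roi_box`.
#' @export
roi_box <- function(x0, y0, x1, y1) {
  if (x1 <= x0 || y1 <= y0) stop("invalid roi_box: x1 > x0 and y1 > y0 required")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1)),
            class = "roi_box")
}

#' Extract the imaging-zone ROI by threshold segmentation
#'
#' Returns the bounding box of the largest 8-connected component of pixels
#' above the intensity threshold. In cine echocardiography the imaging zone is
#' the bright sector on a black background, so plain threshold segmentation
#' isolates it. The default threshold is Otsu's method on the frame histogram
#' (parameter-free); the result is invariant to any monotone photometric
#' rescaling that preserves the threshold ordering when the threshold is
#' supplied on the rescaled range.
#'
#' @param frame grayscale matrix in `[0, 1]`.
#' @param intensity_threshold numeric scalar; pixels strictly above it are
#'   foreground. `NULL` (default) uses Otsu's threshold.
#' @return a [roi_box()].
#' @export
extract_roi <- function(frame, intensity_threshold = NULL) {
  if (length(frame) == 0) stop("frame is empty")
  thr <- if (is.null(intensity_threshold)) otsu_threshold(frame) else intensity_threshold
  fg <- frame > thr
  if (!any(fg)) stop("empty ROI: no pixel above the intensity threshold")
  lab <- label_components(fg)
  areas <- tabulate(lab[lab > 0])
  main <- which.max(areas)
  idx <- which(lab == main, arr.ind = TRUE)
  roi_box(x0 = min(idx[, 2]) - 1L, y0 = min(idx[, 1]) - 1L,
          x1 = max(idx[, 2]), y1 = max(idx[, 1]))
}

#' Crop a frame (and optionally a mask) to a ROI box
#' @param frame image matrix.
#' @param box a [roi_box()].
#' @return cropped matrix.
#' @export
crop_roi <- function(frame, box) {
  frame[(box$y0 + 1L):box$y1, (box$x0 + 1L):box$x1, drop = FALSE]
}

#' Training-time augmentation configuration
#'
#' Defaults follow the training protocol: random crop from 400 x 400 down to
#' 224 x 224, horizontal flip with probability 0.5, rotation in -10..10
#' degrees, and photometric (brightness/contrast, and hue when input is RGB)
#' scaling in 0.5..1.5 of the original value. Hue is a no-op on grayscale
#' frames.
#'
#' @param crop_from,crop_to integer `(width, height)` crop geometry.
#' @param hflip_prob horizontal flip probability in `[0, 1]`.
#' @param rotation_range_deg numeric `(min, max)` rotation in degrees.
#' @param photometric_range numeric `(min, max)` multiplicative range.
#' @param seed optional integer; when given, [augment()] is reproducible.
#' @return object of class `augment_config`.
#' @export
augment_config <- function(crop_from = c(400, 400), crop_to = c(224, 224),
                           hflip_prob = 0.5, rotation_range_deg = c(-10, 10),
                           photometric_range = c(0.5, 1.5), seed = NULL) {
  if (any(crop_to > crop_from))
    stop("invalid augment_config: crop_to must be <= crop_from componentwise")
  if (hflip_prob < 0 || hflip_prob > 1)
    stop("invalid augment_config: hflip_prob must be in [0, 1]")
  structure(list(crop_from = as.integer(crop_from), crop_to = as.integer(crop_to),
                 hflip_prob = hflip_prob, rotation_range_deg = rotation_range_deg,
                 photometric_range = photometric_range, seed = seed),
            class = "augment_config")
}

#' Apply training-time augmentation to a frame (and its mask)
#'
#' The same geometric transform (resize to `crop_from` if smaller, rotation,
#' horizontal flip, random crop to `crop_to`) is applied to image and mask;
#' the mask uses nearest-neighbour interpolation throughout so no new labels
#' are created. Photometric transforms (brightness then contrast) apply to
#' the image only.
#'
#' @param frame grayscale matrix in `[0, 1]`.
#' @param mask optional integer label matrix of the same size.
#' @param cfg an [augment_config()].
#' @return list with `image` (crop_to-sized matrix) and `mask` (or `NULL`).
#' @export
augment <- function(frame, mask = NULL, cfg = augment_config()) {
  do_aug <- function() {
    img <- frame; msk <- mask
    cw <- cfg$crop_from[1]; ch <- cfg$crop_from[2]
    if (nrow(img) < ch || ncol(img) < cw) {
      th <- max(nrow(img), ch); tw <- max(ncol(img), cw)
      img <- resize_img(img, th, tw, "bilinear")
      if (!is.null(msk)) {
        msk <- resize_img(msk, th, tw, "nearest")
        storage.mode(msk) <- "integer"
      }
    }
    theta <- stats::runif(1, cfg$rotation_range_deg[1], cfg$rotation_range_deg[2])
    if (theta != 0) {
      img <- rotate_img(img, theta, "bilinear")
      if (!is.null(msk)) {
        msk <- rotate_img(msk, theta, "nearest", pad = 0)
        storage.mode(msk) <- "integer"
      }
    }
    if (stats::runif(1) < cfg$hflip_prob) {
      img <- flip_horizontal(img)
      if (!is.null(msk)) msk <- flip_horizontal(msk)
    }
    # random crop crop_from -> crop_to (same offset for image and mask)
    ow <- cfg$crop_to[1]; oh <- cfg$crop_to[2]
    oy <- if (nrow(img) > oh) sample.int(nrow(img) - oh, 1) else 0L
    ox <- if (ncol(img) > ow) sample.int(ncol(img) - ow, 1) else 0L
    img <- img[(oy + 1L):(oy + oh), (ox + 1L):(ox + ow), drop = FALSE]
    if (!is.null(msk)) msk <- msk[(oy + 1L):(oy + oh), (ox + 1L):(ox + ow), drop = FALSE]
    # photometric: brightness then contrast about the mean, image only
    b <- stats::runif(1, cfg$photometric_range[1], cfg$photometric_range[2])
    cc <- stats::runif(1, cfg$photometric_range[1], cfg$photometric_range[2])
    img <- img * b
    img <- (img - mean(img)) * cc + mean(img)
    list(image = clamp01(img), mask = msk)
  }
  if (!is.null(cfg$seed)) run_with_seed(cfg$seed, do_aug()) else do_aug()
}
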