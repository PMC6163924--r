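# RGB canopy-cover segmentation in HSV color space.
#
# Images are numeric arrays height x width x 3 (red, green, blue) with
# 8-bit values in 0..255, as returned by read_rgb_image().

check_rgb_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3)
    stop_ev("ev_config_error", "image must be a height x width x 3 array")
  if (dim(image)[1] < 1 || dim(image)[2] < 1)
    stop_ev("ev_size_error", "empty image")
  if (min(image) < 0 || max(image) > 255)
    stop_ev("ev_config_error", "channel values must lie in 0..255")
  invisible(image)
}

#' Read an RGB image from PNG or JPEG
#'
#' @param path image path; PNG is read losslessly. JPEG is accepted when a
#'   JPEG reader is installed, but PNG is preferred because pixel counts are
#'   compression-dependent for JPEG.
#' @return numeric array height x width x 3 with values 0..255.
#' @export
read_rgb_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  a <- a[, , 1:3, drop = FALSE] * 255
  check_rgb_image(a)
}

#' Write an RGB image (or a binary mask) as PNG
#'
#' @param image height x width x 3 array in 0..255, or a binary matrix
#'   (mask) written as grayscale.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  if (is.matrix(image)) {
    png::writePNG(pmin(pmax(image, 0), 1), path)
  } else {
    check_rgb_image(image)
    png::writePNG(image / 255, path)
  }
  invisible(path)
}

#' Convert an RGB image to HSV channels
#'
#' Standard hexcone transform. Hue is reported in degrees [0, 360);
#' saturation and value as fractions in [0, 1]. Hue is undefined for gray
#' pixels (saturation 0) and reported as 0 there.
#'
#' @param image height x width x 3 array in 0..255.
#' @return list with matrices `h` (degrees), `s`, `v`.
#' @export
rgb_to_hsv <- function(image) {
  check_rgb_image(image)
  d <- dim(image)
  m <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
             as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  list(h = matrix(hsv[1, ] * 360, d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

#' HSV segmentation thresholds
#'
#' The plant/soil decision rule: a pixel is vegetation iff its hue lies in
#' [hue_min, hue_max] (wrap-around across 0 degrees permitted when
#' hue_min > hue_max), saturation >= sat_min and value >= val_min.
#' Defaults delimit the green hue range with a mild saturation floor that
#' rejects gray/washed-out soil; the value floor only removes near-black
#' pixels.
#'
#' @param hue_min,hue_max hue window in degrees [0, 360).
#' @param sat_min minimum saturation fraction.
#' @param val_min minimum value (brightness) fraction.
#' @return object of class `"hsv_thresholds"`.
#' @export
hsv_thresholds <- function(hue_min = 60, hue_max = 180, sat_min = 0.15,
                           val_min = 0.05) {
  if (any(c(hue_min, hue_max) < 0) || any(c(hue_min, hue_max) >= 360))
    stop_ev("ev_config_error", "hue bounds must lie in [0, 360)")
  if (sat_min < 0 || sat_min > 1 || val_min < 0 || val_min > 1)
    stop_ev("ev_config_error", "sat_min and val_min must lie in [0, 1]")
  structure(list(hue_min = hue_min, hue_max = hue_max,
                 sat_min = sat_min, val_min = val_min),
            class = "hsv_thresholds")
}

#' @export
print.hsv_thresholds <- function(x, ...) {
  cat(sprintf("<hsv_thresholds> hue [%g, %g] deg, sat >= %g, val >= %g\n",
              x$hue_min, x$hue_max, x$sat_min, x$val_min))
  invisible(x)
}

#' Segment green vegetation from soil
#'
#' Applies the HSV threshold rule pixel-wise and reports canopy cover as
#' the exact fraction of vegetation pixels.
#'
#' @param image height x width x 3 array in 0..255.
#' @param thresholds an [hsv_thresholds()] (defaults apply).
#' @param min_component_size optional morphological cleanup: connected
#'   vegetation components (4-neighborhood) smaller than this pixel count
#'   are removed. Default 0 (off).
#' @return object of class `"segmentation"`: list with `mask` (logical
#'   matrix, TRUE = vegetation), `canopy_cover`, `n_vegetation_pixels`,
#'   `n_total_pixels`, `thresholds`.
#' @export
segment_green <- function(image, thresholds = hsv_thresholds(),
                          min_component_size = 0) {
  check_rgb_image(image)
  hsv <- rgb_to_hsv(image)
  mask <- in_hue_window(hsv$h, thresholds$hue_min, thresholds$hue_max) &
    hsv$s >= thresholds$sat_min & hsv$v >= thresholds$val_min
  if (min_component_size > 0)
    mask <- drop_small_components(mask, min_component_size)
  n_veg <- sum(mask); n_tot <- length(mask)
  structure(list(mask = mask, canopy_cover = n_veg / n_tot,
                 n_vegetation_pixels = n_veg, n_total_pixels = n_tot,
                 thresholds = thresholds),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> canopy cover %.4f (%d / %d pixels)\n",
              x$canopy_cover, x$n_vegetation_pixels, x$n_total_pixels))
  invisible(x)
}

# remove 4-connected TRUE components below min_size (simple flood fill)
drop_small_components <- function(mask, min_size) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  idx <- which(mask & lab == 0L)
  nr <- nrow(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    comp <- integer(0)
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[p] != 0L || !mask[p]) next
      lab[p] <- cur
      comp <- c(comp, p)
      r <- (p - 1L) %% nr + 1L; cl <- (p - 1L) %/% nr + 1L
      if (r > 1L) stack <- c(stack, p - 1L)
      if (r < nr) stack <- c(stack, p + 1L)
      if (cl > 1L) stack <- c(stack, p - nr)
      if (cl < ncol(mask)) stack <- c(stack, p + nr)
    }
    if (length(comp) < min_size) mask[comp] <- FALSE
  }
  mask
}

#' Crop an image to a marked quadrat
#'
#' The sampling quadrat is tagged by four corner points; the crop is the
#' axis-aligned bounding box of those corners. No perspective rectification
#' is applied (near-nadir images).
#'
#' @param image height x width x 3 array.
#' @param corners 4 x 2 matrix of (x, y) pixel coordinates (x = column,
#'   y = row, 1-based) forming a convex, non-degenerate quadrilateral
#'   inside the image.
#' @return the cropped image array.
#' @export
crop_quadrat <- function(image, corners) {
  check_rgb_image(image)
  corners <- as.matrix(corners)
  if (!all(dim(corners) == c(4, 2)))
    stop_ev("ev_coordinate_error", "corners must be a 4 x 2 (x, y) matrix")
  h <- dim(image)[1]; w <- dim(image)[2]
  x <- corners[, 1]; y <- corners[, 2]
  if (any(x < 1 | x > w | y < 1 | y > h))
    stop_ev("ev_coordinate_error", "corner outside image bounds")
  # convexity / non-degeneracy: consecutive-edge cross products must share
  # one strict sign
  cross <- vapply(1:4, function(i) {
    a <- corners[i, ]; b <- corners[i %% 4 + 1, ]; c <- corners[(i + 1) %% 4 + 1, ]
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }, numeric(1))
  if (any(cross == 0) || !(all(cross > 0) || all(cross < 0)))
    stop_ev("ev_coordinate_error", "corners are collinear or not convex")
  image[floor(min(y)):ceiling(max(y)), floor(min(x)):ceiling(max(x)), , drop = FALSE]
}

#' Calibrate HSV thresholds against reference masks
#'
#' Reproducible surrogate for manual per-date threshold tuning: grid-search
#' over (hue_min, hue_max, sat_min) maximizing the mean pixel-wise Jaccard
#' overlap with user-supplied reference masks. Ties are resolved toward the
#' wider hue window, then the lower saturation floor (the most inclusive
#' rule among equals).
#'
#' @param reference_images list of RGB image arrays.
#' @param reference_masks list of logical matrices (TRUE = vegetation) of
#'   matching sizes; at least one mask must contain vegetation.
#' @param hue_min_grid,hue_max_grid,sat_min_grid candidate values.
#' @param val_min value floor held fixed (default 0.05).
#' @return the best [hsv_thresholds()], with attributes `jaccard` (achieved
#'   mean overlap) and `grid_size`.
#' @export
calibrate_thresholds <- function(reference_images, reference_masks,
                                 hue_min_grid = seq(30, 90, by = 10),
                                 hue_max_grid = seq(140, 220, by = 10),
                                 sat_min_grid = seq(0.05, 0.45, by = 0.05),
                                 val_min = 0.05) {
  if (length(reference_images) < 1 ||
      length(reference_images) != length(reference_masks))
    stop_ev("ev_calibration_error", "need >= 1 image/mask reference pair")
  if (!any(vapply(reference_masks, any, logical(1))))
    stop_ev("ev_calibration_error", "all reference masks are empty")
  hsv <- lapply(reference_images, rgb_to_hsv)
  best <- NULL; best_score <- -Inf; best_width <- -Inf; best_sat <- Inf
  for (hmin in hue_min_grid) for (hmax in hue_max_grid) {
    if (hmax <= hmin) next
    for (smin in sat_min_grid) {
      score <- mean(mapply(function(ch, ref) {
        m <- in_hue_window(ch$h, hmin, hmax) & ch$s >= smin & ch$v >= val_min
        u <- sum(m | ref)
        if (u == 0) 1 else sum(m & ref) / u
      }, hsv, reference_masks))
      width <- hmax - hmin
      better <- score > best_score + 1e-12 ||
        (abs(score - best_score) <= 1e-12 &&
           (width > best_width ||
              (width == best_width && smin < best_sat)))
      if (better) {
        best_score <- score; best_width <- width; best_sat <- smin
        best <- hsv_thresholds(hmin, hmax, smin, val_min)
      }
    }
  }
  attr(best, "jaccard") <- best_score
  attr(best, "grid_size") <- length(hue_min_grid) * length(hue_max_grid) *
    length(sat_min_grid)
  best
}

#' Segment a set of images and tabulate canopy cover
#'
#' @param images named list of RGB image arrays.
#' @param thresholds an [hsv_thresholds()].
#' @param ... passed to [segment_green()].
#' @return data.frame with columns `image_id, canopy_cover, n_veg, n_total`.
#' @export
canopy_cover_table <- function(images, thresholds = hsv_thresholds(), ...) {
  ids <- names(images)
  if (is.null(ids)) ids <- as.character(seq_along(images))
  res <- lapply(images, segment_green, thresholds = thresholds, ...)
  data.frame(image_id = ids,
             canopy_cover = vapply(res, `[[`, numeric(1), "canopy_cover"),
             n_veg = vapply(res, `[[`, numeric(1), "n_vegetation_pixels"),
             n_total = vapply(res, `[[`, numeric(1), "n_total_pixels"),
             row.names = NULL, stringsAsFactors = FALSE)
}
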