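#' Red-region HSV thresholds for weak labels
#'
#' Hue is stored on the half-degree scale \[0, 180) so the printed upper band
#' bound of 180 coincides with 0; band bounds are inclusive. Saturation and
#' value are 8-bit (0--255), bounds inclusive.
#'
#' @param hue_bands List of `c(lo, hi)` hue bands in half-degrees.
#' @param sat_range,val_range Inclusive `c(lo, hi)` ranges.
#' @return An object of class `red_thresholds`.
#' @export
red_thresholds <- function(hue_bands = list(c(0, 8), c(172, 180)),
                           sat_range = c(90, 255), val_range = c(50, 255)) {
  for (b in hue_bands) {
    if (length(b) != 2 || b[1] > b[2] || b[1] < 0 || b[2] > 180)
      stop("hue bands must be c(lo, hi) within [0, 180]", call. = FALSE)
  }
  stopifnot(sat_range[1] <= sat_range[2], val_range[1] <= val_range[2])
  structure(list(hue_bands = hue_bands, sat_range = sat_range,
                 val_range = val_range), class = "red_thresholds")
}

#' Field-of-view HSV thresholds
#'
#' The illuminated endoscopic field is bright and coloured; the lens margin is
#' black. A pixel belongs to the field of view iff saturation > `sat_min` and
#' value > `val_min`, both strict.
#'
#' @param sat_min,val_min Strict lower bounds, 0--255.
#' @return An object of class `fov_thresholds`.
#' @export
fov_thresholds <- function(sat_min = 60, val_min = 70) {
  stopifnot(sat_min >= 0, sat_min <= 255, val_min >= 0, val_min <= 255)
  structure(list(sat_min = sat_min, val_min = val_min),
            class = "fov_thresholds")
}

#' Convert an 8-bit RGB image to HSV
#'
#' Standard hexcone conversion with hue on the half-degree scale \[0, 180) and
#' saturation/value on 0--255. Saturation of achromatic pixels (max = 0) is 0.
#'
#' @param image H x W x 3 array, values 0--255.
#' @return An object of class `endo_hsv`: list of matrices `h`, `s`, `v`.
#' @export
rgb_to_hsv <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("image must be an H x W x 3 array", call. = FALSE)
  m <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
             as.vector(image[, , 3]))
  hsv <- rgb2hsv(m, maxColorValue = 255)
  structure(list(h = matrix(hsv[1, ] * 180, d[1], d[2]),
                 s = matrix(hsv[2, ] * 255, d[1], d[2]),
                 v = matrix(hsv[3, ] * 255, d[1], d[2])),
            class = "endo_hsv")
}

#' Binary mask of red pixels
#'
#' A pixel is red iff its hue lies in any band and saturation and value lie in
#' their ranges, all bounds inclusive. Hue 180 is identified with hue 0.
#'
#' @param hsv An `endo_hsv` image.
#' @param thr A [red_thresholds()] object.
#' @return Logical matrix.
#' @export
red_mask <- function(hsv, thr = red_thresholds()) {
  stopifnot(inherits(hsv, "endo_hsv"), inherits(thr, "red_thresholds"))
  h <- hsv$h %% 180
  in_band <- matrix(FALSE, nrow(h), ncol(h))
  for (b in thr$hue_bands) {
    in_band <- in_band | (h >= b[1] & h <= b[2])
    if (b[2] >= 180) in_band <- in_band | h == 0  # 180 wraps to 0
  }
  in_band & hsv$s >= thr$sat_range[1] & hsv$s <= thr$sat_range[2] &
    hsv$v >= thr$val_range[1] & hsv$v <= thr$val_range[2]
}

#' Binary mask of the endoscopic field of view
#'
#' @param hsv An `endo_hsv` image.
#' @param thr A [fov_thresholds()] object.
#' @return Logical matrix; `TRUE` iff saturation and value strictly exceed
#'   their minima.
#' @export
fov_mask <- function(hsv, thr = fov_thresholds()) {
  stopifnot(inherits(hsv, "endo_hsv"), inherits(thr, "fov_thresholds"))
  hsv$s > thr$sat_min & hsv$v > thr$val_min
}

#' Weak label: red regions within the endoscopic field
#'
#' Composes [red_mask()] and [fov_mask()]: the weak-label mask is their
#' intersection and the red-area ratio is its pixel count divided by the
#' field-of-view pixel count. A frame with an empty field of view (e.g. an
#' all-black frame) is degenerate and raises an error of class
#' `endobleed_degenerate_frame`.
#'
#' @param image H x W x 3 RGB array, 0--255.
#' @param red_thr,fov_thr Threshold objects.
#' @return List with `mask` (logical), `ratio` (in \[0,1\]), and `fov`
#'   (logical field-of-view mask).
#' @export
weak_label <- function(image, red_thr = red_thresholds(),
                       fov_thr = fov_thresholds()) {
  hsv <- rgb_to_hsv(image)
  fov <- fov_mask(hsv, fov_thr)
  if (!any(fov))
    stop_endobleed("empty field of view (degenerate frame)",
                   "endobleed_degenerate_frame")
  mask <- red_mask(hsv, red_thr) & fov
  list(mask = mask, ratio = sum(mask) / sum(fov), fov = fov)
}

#' Construct a labelled image/mask pair
#'
#' @param image Image array or a path to one.
#' @param mask Binary weak-label mask.
#' @param ratio Red-area ratio within the field of view.
#' @param source_id Provenance (video) identifier used for leakage-safe splits.
#' @return An object of class `labeled_pair`.
#' @export
labeled_pair <- function(image, mask, ratio, source_id) {
  stopifnot(ratio >= 0, ratio <= 1)
  structure(list(image = image, mask = as_mask(mask), ratio = ratio,
                 source_id = as.character(source_id)), class = "labeled_pair")
}

#' Keep pairs whose red-area ratio exceeds a minimum
#'
#' The dataset filter drops frames with insignificant red content. "Exceeding"
#' is read as strict by default; set `strict = FALSE` for an inclusive bound.
#'
#' @param pairs List of [labeled_pair()] objects (or anything with `$ratio`).
#' @param min_ratio Minimum red-area ratio (default 0.01, i.e. 1%).
#' @param strict Use `ratio > min_ratio` (default) rather than `>=`.
#' @return The retained pairs, original order preserved.
#' @export
filter_pairs <- function(pairs, min_ratio = 0.01, strict = TRUE) {
  keep <- vapply(pairs, function(p) {
    if (strict) p$ratio > min_ratio else p$ratio >= min_ratio
  }, logical(1))
  pairs[keep]
}

#' Write / read a binary mask as an 8-bit grayscale PNG (0/255)
#'
#' @param mask Logical (or 0/1) matrix.
#' @param path Output path.
#' @return `write_mask`: invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  mask <- as_mask(mask)
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_mask
#' @param strict If `TRUE` (default) a file containing grey values other than
#'   0 and 255 is a format error; if `FALSE`, values > 127 map to `TRUE`.
#' @return `read_mask`: logical matrix.
#' @export
read_mask <- function(path, strict = TRUE) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  lv <- sort(unique(round(as.vector(x) * 255)))
  if (strict && !all(lv %in% c(0L, 255L)))
    stop_endobleed(sprintf("mask file %s contains grey values other than 0/255", path),
                   "endobleed_mask_format")
  x > 127 / 255
}
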