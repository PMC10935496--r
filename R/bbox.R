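#' Normalized bounding box
#'
#' Axis-aligned rectangle in normalized page coordinates: `left` and `top`
#' are fractions of page width/height from the top-left corner, `width` and
#' `height` are fractions of the page extent. All geometric reasoning in the
#' pipeline (box merging, overlap fractions, expansion) happens on this type.
#'
#' A small tolerance (`1e-6`) on `left + width <= 1` and `top + height <= 1`
#' absorbs rounding in upstream OCR output.
#'
#' @param left,top Top-left corner, fractions in `[0, 1]`.
#' @param width,height Extent, fractions in `[0, 1]`.
#' @param validate Check invariants (disable only in tight loops over
#'   already-validated geometry).
#' @return A `bbox`: a named numeric vector of length 4.
#' @examples
#' b <- bbox(0.1, 0.2, 0.3, 0.05)
#' bbox_area(b)
#' @export
bbox <- function(left, top, width, height, validate = TRUE) {
  b <- c(left = as.numeric(left), top = as.numeric(top),
         width = as.numeric(width), height = as.numeric(height))
  class(b) <- "bbox"
  if (validate) validate_bbox(b)
  b
}

validate_bbox <- function(b) {
  eps <- 1e-6
  if (anyNA(b) || length(b) != 4L) {
    stop("bbox must be 4 non-missing numbers", call. = FALSE)
  }
  if (b[["left"]] < 0 || b[["top"]] < 0) {
    stop("bbox left/top must be >= 0", call. = FALSE)
  }
  if (b[["width"]] < 0 || b[["height"]] < 0) {
    stop("bbox width/height must be >= 0", call. = FALSE)
  }
  if (b[["left"]] + b[["width"]] > 1 + eps || b[["top"]] + b[["height"]] > 1 + eps) {
    stop("bbox extends beyond the unit page", call. = FALSE)
  }
  invisible(b)
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox left=%.4f top=%.4f width=%.4f height=%.4f>\n",
              x[["left"]], x[["top"]], x[["width"]], x[["height"]]))
  invisible(x)
}

#' Coerce to a bounding box
#'
#' Accepts a `bbox`, a numeric vector `(left, top, width, height)`, or a
#' list with Textract-style `Left`/`Top`/`Width`/`Height` fields.
#'
#' @param x Object to coerce.
#' @return A [bbox()].
#' @export
as_bbox <- function(x) {
  if (inherits(x, "bbox")) return(x)
  if (is.list(x) && all(c("Left", "Top", "Width", "Height") %in% names(x))) {
    return(bbox(x$Left, x$Top, x$Width, x$Height))
  }
  if (is.numeric(x) && length(x) == 4L) {
    return(bbox(x[[1]], x[[2]], x[[3]], x[[4]]))
  }
  stop("cannot coerce to bbox", call. = FALSE)
}

#' Area of a bounding box
#'
#' @param b A [bbox()].
#' @return Area as a fraction of the page area.
#' @export
bbox_area <- function(b) {
  unname(b[["width"]] * b[["height"]])
}

#' Rectangle intersection area
#'
#' Area of the intersection of two boxes, in page-area fractions. Zero when
#' the boxes are disjoint; symmetric in its arguments.
#'
#' @param a,b [bbox()] objects.
#' @return Non-negative scalar.
#' @export
intersection_area <- function(a, b) {
  w <- min(a[["left"]] + a[["width"]], b[["left"]] + b[["width"]]) -
    max(a[["left"]], b[["left"]])
  h <- min(a[["top"]] + a[["height"]], b[["top"]] + b[["height"]]) -
    max(a[["top"]], b[["top"]])
  if (w <= 0 || h <= 0) return(0)
  w * h
}

#' Fraction of a line box covered by a region
#'
#' The overlap statistic used to excise table lines: the intersection area
#' divided by the area of `line_box`. Normalizing by the line's own area
#' puts the value in `[0, 1]` and matches the scale on which removal
#' thresholds (0.25, 0.35) are expressed.
#'
#' @param line_box Box of the candidate line; must have positive area.
#' @param region Reference region (e.g. a table's max bounding box).
#' @return Scalar in `[0, 1]`.
#' @export
overlap_fraction <- function(line_box, region) {
  a <- bbox_area(line_box)
  if (a <= 0) {
    stop("degenerate geometry: line box has zero area", call. = FALSE)
  }
  min(1, intersection_area(line_box, region) / a)
}

#' Merge boxes into their bounding hull
#'
#' Smallest axis-aligned rectangle containing all input boxes. This is the
#' "max bounding box" operation used to grow keyword hits into a table
#' region.
#'
#' @param boxes Non-empty list of [bbox()] objects.
#' @return A [bbox()].
#' @export
merge_boxes <- function(boxes) {
  if (!is.list(boxes) || length(boxes) == 0L) {
    stop("merge_boxes() needs a non-empty list of boxes", call. = FALSE)
  }
  l <- min(vapply(boxes, `[[`, numeric(1), "left"))
  t <- min(vapply(boxes, `[[`, numeric(1), "top"))
  r <- max(vapply(boxes, function(b) b[["left"]] + b[["width"]], numeric(1)))
  d <- max(vapply(boxes, function(b) b[["top"]] + b[["height"]], numeric(1)))
  bbox(l, t, r - l, d - t)
}

#' Expand a box by per-side offsets
#'
#' Grows a box by the given page-fraction offsets and clips the result to
#' the unit page. Used to turn a keyword line's box into the custom
#' per-keyword region around it.
#'
#' @param box A [bbox()].
#' @param offsets Named numeric vector or list with non-negative elements
#'   `left`, `right`, `up`, `down` (page fractions). Missing names default
#'   to 0.
#' @return A [bbox()] clipped to `[0, 1]^2`.
#' @export
expand_box <- function(box, offsets = c(left = 0, right = 0, up = 0, down = 0)) {
  off <- c(left = 0, right = 0, up = 0, down = 0)
  off[names(offsets)] <- unlist(offsets)
  if (any(off < 0)) stop("expansion offsets must be >= 0", call. = FALSE)
  l <- max(0, box[["left"]] - off[["left"]])
  t <- max(0, box[["top"]] - off[["up"]])
  r <- min(1, box[["left"]] + box[["width"]] + off[["right"]])
  d <- min(1, box[["top"]] + box[["height"]] + off[["down"]])
  bbox(l, t, r - l, d - t)
}
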