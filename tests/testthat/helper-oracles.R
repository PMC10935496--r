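# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Axis-wise rasterization on a grid of cells of side `res` with centers at
# (k - 1/2) * res: count covered cells per axis in closed form and multiply.
raster_count <- function(lo, hi, res) {
  max(0, floor(hi / res + 0.5) - ceiling(lo / res + 0.5) + 1)
}

raster_intersection <- function(a, b, res = 1e-5) {
  nx <- raster_count(max(a[["left"]], b[["left"]]),
                     min(a[["left"]] + a[["width"]], b[["left"]] + b[["width"]]),
                     res)
  ny <- raster_count(max(a[["top"]], b[["top"]]),
                     min(a[["top"]] + a[["height"]], b[["top"]] + b[["height"]]),
                     res)
  nx * ny * res^2
}

# Overlap fraction on the same grid: cells of `a` also covered by `region`,
# over the cells of `a`; the shared grid keeps quantization error tied to
# the cell count of `a`, not to its absolute area.
raster_overlap_fraction <- function(a, region, res = 1e-5) {
  nx_a <- raster_count(a[["left"]], a[["left"]] + a[["width"]], res)
  ny_a <- raster_count(a[["top"]], a[["top"]] + a[["height"]], res)
  nx_b <- raster_count(max(a[["left"]], region[["left"]]),
                       min(a[["left"]] + a[["width"]],
                           region[["left"]] + region[["width"]]), res)
  ny_b <- raster_count(max(a[["top"]], region[["top"]]),
                       min(a[["top"]] + a[["height"]],
                           region[["top"]] + region[["height"]]), res)
  (nx_b * ny_b) / (nx_a * ny_a)
}

# Full 2-D grid rasterization (coarser; used for spot checks).
raster_intersection_2d <- function(a, b, res = 1e-3) {
  gx <- seq(res / 2, 1 - res / 2, by = res)
  gy <- gx
  in_x <- gx >= pmax(a[["left"]], b[["left"]]) &
    gx <= pmin(a[["left"]] + a[["width"]], b[["left"]] + b[["width"]])
  in_y <- gy >= pmax(a[["top"]], b[["top"]]) &
    gy <= pmin(a[["top"]] + a[["height"]], b[["top"]] + b[["height"]])
  sum(in_x) * sum(in_y) * res^2
}

random_bbox <- function() {
  l <- runif(1, 0, 0.8)
  t <- runif(1, 0, 0.8)
  bbox(l, t, runif(1, 0.01, 1 - l), runif(1, 0.01, 1 - t))
}

# Naive non-overlapping leftmost substring scan (case-insensitive).
naive_substring_find <- function(haystack, phrase) {
  h <- tolower(haystack)
  p <- tolower(phrase)
  m <- gregexpr(p, h, fixed = TRUE)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(), end = integer()))
  data.frame(start = as.integer(m),
             end = as.integer(m) + nchar(p) - 1L)
}

# Minimal edit distance of phrase to any substring, via utils::adist.
adist_partial <- function(phrase, haystack) {
  utils::adist(tolower(phrase), tolower(haystack), partial = TRUE)[1, 1]
}

# O(n^2) pairwise-concordance AU-ROC.
pairwise_auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
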