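## Image-plumbing helpers: boxes, bilinear resizing, grayscale PNG IO.
## Images are plain base matrices indexed [row = y, col = x], intensities
## in [0, 1]. Boxes are 0-based half-open rectangles [x0, x1) x [y0, y1)
## with (x, y) = (column, row).

#' Construct a rectangular region of interest
#'
#' Boxes are 0-based and half-open: the pixel columns covered are
#' `x0 .. x1-1` and the rows `y0 .. y1-1`.
#'
#' @param x0,y0,x1,y1 Integer pixel coordinates with `x0 < x1`, `y0 < y1`.
#' @return Named numeric vector `c(x0, y0, x1, y1)` of class `baa_box`.
#' @export
roiBox <- function(x0, y0, x1, y1) {
  x0 <- as.numeric(x0); y0 <- as.numeric(y0)
  x1 <- as.numeric(x1); y1 <- as.numeric(y1)
  if (!(x0 < x1 && y0 < y1)) stop("box must satisfy x0 < x1 and y0 < y1")
  structure(c(x0 = x0, y0 = y0, x1 = x1, y1 = y1), class = "baa_box")
}

#' Intersection-over-union of two boxes
#'
#' @param a,b Boxes as produced by [roiBox()] (or any named vector with
#'   `x0, y0, x1, y1`).
#' @return IoU in \[0, 1\].
#' @export
boxIoU <- function(a, b) {
  ix <- max(0, min(a[["x1"]], b[["x1"]]) - max(a[["x0"]], b[["x0"]]))
  iy <- max(0, min(a[["y1"]], b[["y1"]]) - max(a[["y0"]], b[["y0"]]))
  inter <- ix * iy
  areaA <- (a[["x1"]] - a[["x0"]]) * (a[["y1"]] - a[["y0"]])
  areaB <- (b[["x1"]] - b[["x0"]]) * (b[["y1"]] - b[["y0"]])
  inter / (areaA + areaB - inter)
}

# Rescale a box between coordinate frames (e.g. activation grid -> image
# pixels) by the ratio of spatial sizes. Sizes are c(height, width).
scaleBox <- function(box, fromSize, toSize) {
  sy <- toSize[1] / fromSize[1]
  sx <- toSize[2] / fromSize[2]
  x0 <- floor(box[["x0"]] * sx); x1 <- ceiling(box[["x1"]] * sx)
  y0 <- floor(box[["y0"]] * sy); y1 <- ceiling(box[["y1"]] * sy)
  x0 <- max(0, x0); y0 <- max(0, y0)
  x1 <- min(toSize[2], max(x1, x0 + 1)); y1 <- min(toSize[1], max(y1, y0 + 1))
  roiBox(x0, y0, x1, y1)
}

#' Crop a region from an image and resample it bilinearly
#'
#' The box must be expressed in the image's own pixel frame; boxes reaching
#' outside the image are clamped with a warning. Resampling uses bilinear
#' interpolation (half-pixel-centre convention).
#'
#' @param image Numeric matrix \[row = y, col = x\].
#' @param box A [roiBox()] within the image frame.
#' @param outSize Output size as `c(width, height)`. Default `c(576, 576)`,
#'   the uniform input size of the hand branch.
#' @return Numeric matrix of dimension `outSize[2] x outSize[1]`.
#' @export
cropAndResize <- function(image, box, outSize = c(576, 576)) {
  stopifnot(is.matrix(image))
  H <- nrow(image); W <- ncol(image)
  x0 <- box[["x0"]]; y0 <- box[["y0"]]; x1 <- box[["x1"]]; y1 <- box[["y1"]]
  if (x0 < 0 || y0 < 0 || x1 > W || y1 > H) {
    warning("box extends outside the image; clamped")
    x0 <- max(0, x0); y0 <- max(0, y0)
    x1 <- min(W, x1); y1 <- min(H, y1)
    if (x0 >= x1 || y0 >= y1) stop("box does not intersect the image")
  }
  crop <- image[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  resizeBilinear(crop, width = outSize[1], height = outSize[2])
}

# Bilinear resize of a plain [y, x] matrix. EBImage treats the first array
# dimension as x, so w/h are swapped accordingly.
resizeBilinear <- function(m, width, height) {
  if (nrow(m) == height && ncol(m) == width) return(m)
  if (nrow(m) == 1L && ncol(m) == 1L)
    return(matrix(m[1, 1], nrow = height, ncol = width))
  out <- EBImage::resize(m, w = height, h = width, filter = "bilinear")
  matrix(as.numeric(out), nrow = height, ncol = width)
}

#' Resize with aspect-ratio-preserving letterbox padding
#'
#' Scales the image so the longer side matches `size`, then pads the shorter
#' side symmetrically with `fill` to a `size x size` square.
#'
#' @param image Numeric matrix.
#' @param size Output side length in pixels.
#' @param fill Padding intensity (default 0).
#' @return `size x size` numeric matrix.
#' @export
letterboxResize <- function(image, size, fill = 0) {
  H <- nrow(image); W <- ncol(image)
  if (H == W) return(resizeBilinear(image, size, size))
  s <- size / max(H, W)
  h <- max(1L, round(H * s)); w <- max(1L, round(W * s))
  core <- resizeBilinear(image, width = w, height = h)
  out <- matrix(fill, size, size)
  oy <- (size - h) %/% 2; ox <- (size - w) %/% 2
  out[(oy + 1):(oy + h), (ox + 1):(ox + w)] <- core
  out
}

#' Read a grayscale image as a matrix
#'
#' Multi-channel images are averaged to a single channel. Intensities are
#' returned in \[0, 1\], indexed \[row = y, col = x\].
#'
#' @param path Image file (PNG/JPEG/TIFF).
#' @return Numeric matrix.
#' @export
readImageGray <- function(path) {
  img <- EBImage::readImage(path)
  a <- as.array(img)
  if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), mean)
  t(a)  # EBImage stores x in the first dimension
}

#' Write a matrix as an 8-bit grayscale PNG
#'
#' @param image Numeric matrix with intensities in \[0, 1\].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
writeImageGray <- function(image, path) {
  EBImage::writeImage(EBImage::Image(t(pmin(pmax(image, 0), 1))), path)
  invisible(path)
}

#' Dump a normalized activation channel as a heatmap PNG
#'
#' Min-max normalizes the channel, upscales it to the target size by
#' nearest-neighbour interpolation and writes an 8-bit grayscale PNG.
#'
#' @param channel Numeric matrix (one activation channel).
#' @param path Output PNG path.
#' @param size Output size `c(height, width)`; default the channel size.
#' @return `path`, invisibly.
#' @export
saveActivationHeatmap <- function(channel, path, size = dim(channel)) {
  z <- minmaxNormalize(channel)
  ry <- rep(seq_len(nrow(z)), each = ceiling(size[1] / nrow(z)))[seq_len(size[1])]
  rx <- rep(seq_len(ncol(z)), each = ceiling(size[2] / ncol(z)))[seq_len(size[2])]
  writeImageGray(z[ry, rx, drop = FALSE], path)
}
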