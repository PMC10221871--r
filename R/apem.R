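## Attention part extraction module (APEM): stretch the activation channel
## to sharpen its peaks, enumerate anchor boxes on a strided lattice, score
## each by the mean stretched activation under it, suppress overlaps, and
## keep the top-N bone-part regions.

#' Min-max normalization to \[0, 1\]
#'
#' \eqn{z(x) = (x - \min x) / (\max x - \min x)}. A constant input maps to
#' all zeros (declared degenerate convention).
#'
#' @param x Non-empty numeric array.
#' @return Array of the same shape with values in \[0, 1\].
#' @export
minmaxNormalize <- function(x) {
  if (length(x) == 0L) stop("empty input")
  rng <- range(x)
  if (rng[1] == rng[2]) return(x * 0)
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Exponentially stretch an activation channel
#'
#' \eqn{S = z(\exp(\eta \, z(A)))}: normalize, exponentiate the scaled
#' values, renormalize. Larger `eta` widens the gap between local peaks and
#' their surroundings, protecting peak-centred proposals during NMS.
#'
#' @param channel Numeric matrix (activation channel).
#' @param eta Stretch factor, > 0. Default 4.
#' @return Matrix in \[0, 1\] with attribute `eta`.
#' @export
stretchMap <- function(channel, eta = 4) {
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0)
    stop("eta must be a single positive value")
  S <- minmaxNormalize(exp(eta * minmaxNormalize(channel)))
  attr(S, "eta") <- eta
  S
}

#' Anchor configuration for part proposals
#'
#' Aspect ratios and scales follow the region-proposal design for the
#' 576 x 576 activation frame: ratios \{2:3, 1:1, 3:2\} and scales
#' \{128, 160, 224, 288, 384\} (so each lattice point spawns 15 anchors).
#' The lattice stride keeps the proposal count tractable; scales and stride
#' are interpreted in the frame the map is resized to and should be rescaled
#' proportionally for smaller frames.
#'
#' @param ratios Width:height ratios (numeric).
#' @param scales Anchor side lengths (square-root of the anchor area), in
#'   pixels of the resized map.
#' @param stride Lattice step in pixels.
#' @return List of class `baa_anchor_config`.
#' @export
anchorConfig <- function(ratios = c(2 / 3, 1, 3 / 2),
                         scales = c(128, 160, 224, 288, 384),
                         stride = 32L) {
  stopifnot(all(ratios > 0), all(scales > 0), stride >= 1)
  structure(list(ratios = ratios, scales = scales, stride = as.integer(stride)),
            class = "baa_anchor_config")
}

# Rescale an anchor configuration from its native 576-frame to another frame.
scaleAnchorConfig <- function(cfg, frame, native = 576) {
  s <- frame / native
  anchorConfig(ratios = cfg$ratios,
               scales = pmax(2, cfg$scales * s),
               stride = max(1L, as.integer(round(cfg$stride * s))))
}

#' Enumerate anchor boxes on a strided lattice
#'
#' For each lattice point, one box per (ratio, scale) pair is generated,
#' centred there, with area `scale^2` and width:height equal to the ratio.
#' Boxes extending outside the map are discarded (never clipped), so region
#' scores are never computed on truncated areas.
#'
#' @param mapSize Map size `c(height, width)`.
#' @param cfg An [anchorConfig()].
#' @param filterBoundary Discard boxes that stick out of the map
#'   (default TRUE).
#' @return Data frame with columns `x0, y0, x1, y1` (0-based, half-open) and
#'   `cx, cy` (lattice centre).
#' @export
generateAnchors <- function(mapSize, cfg = anchorConfig(),
                            filterBoundary = TRUE) {
  H <- mapSize[1]; W <- mapSize[2]
  cy <- seq(cfg$stride / 2, H, by = cfg$stride)
  cx <- seq(cfg$stride / 2, W, by = cfg$stride)
  grid <- expand.grid(cx = cx, cy = cy)
  shapes <- expand.grid(ratio = cfg$ratios, scale = cfg$scales)
  w <- shapes$scale * sqrt(shapes$ratio)
  h <- shapes$scale / sqrt(shapes$ratio)
  n <- nrow(grid); m <- nrow(shapes)
  out <- data.frame(
    x0 = round(rep(grid$cx, each = m) - rep(w, n) / 2),
    y0 = round(rep(grid$cy, each = m) - rep(h, n) / 2),
    x1 = round(rep(grid$cx, each = m) + rep(w, n) / 2),
    y1 = round(rep(grid$cy, each = m) + rep(h, n) / 2),
    cx = rep(grid$cx, each = m),
    cy = rep(grid$cy, each = m)
  )
  if (filterBoundary)
    out <- out[out$x0 >= 0 & out$y0 >= 0 & out$x1 <= W & out$y1 <= H, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score candidate regions by mean stretched activation
#'
#' Each region's confidence is the arithmetic mean of the stretched map over
#' the pixels it covers, computed exactly via a summed-area table.
#'
#' @param S Stretched map (matrix).
#' @param boxes Data frame with `x0, y0, x1, y1` (0-based, half-open), all
#'   within the map.
#' @return `boxes` with an added `score` column, unreordered.
#' @export
scoreRegions <- function(S, boxes) {
  H <- nrow(S); W <- ncol(S)
  if (nrow(boxes) == 0L)
    return(cbind(boxes, score = numeric(0)))
  if (any(boxes$x0 < 0 | boxes$y0 < 0 | boxes$x1 > W | boxes$y1 > H))
    stop("boxes must lie within the map")
  if (any(boxes$x1 <= boxes$x0 | boxes$y1 <= boxes$y0))
    stop("empty box")
  # summed-area table with zero padding: sat[i+1, j+1] = sum S[1:i, 1:j]
  sat <- matrix(0, H + 1, W + 1)
  sat[-1, -1] <- apply(apply(S, 2, cumsum), 1, cumsum) |> t()
  x0 <- boxes$x0 + 1; y0 <- boxes$y0 + 1
  x1 <- boxes$x1 + 1; y1 <- boxes$y1 + 1
  tot <- sat[cbind(y1, x1)] - sat[cbind(y0, x1)] -
         sat[cbind(y1, x0)] + sat[cbind(y0, x0)]
  area <- (boxes$x1 - boxes$x0) * (boxes$y1 - boxes$y0)
  boxes$score <- tot / area
  boxes
}

#' Greedy non-maximum suppression
#'
#' Repeatedly keeps the highest-scoring region and removes all remaining
#' regions whose IoU with it exceeds `iouThreshold`. Score ties break toward
#' the earlier input row (stable ordering).
#'
#' @param regions Data frame with `x0, y0, x1, y1, score`.
#' @param iouThreshold IoU above which a region is suppressed. Default 0.25
#'   (a low threshold forces spatially distinct bone parts).
#' @return Kept regions in descending score order.
#' @export
nmsRegions <- function(regions, iouThreshold = 0.25) {
  if (any(!is.finite(regions$score))) stop("scores must be finite")
  ord <- order(-regions$score, seq_len(nrow(regions)))
  r <- regions[ord, , drop = FALSE]
  keep <- logical(nrow(r))
  alive <- rep(TRUE, nrow(r))
  for (i in seq_len(nrow(r))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i == nrow(r)) break
    j <- which(alive & seq_len(nrow(r)) > i)
    if (!length(j)) next
    ix <- pmax(0, pmin(r$x1[j], r$x1[i]) - pmax(r$x0[j], r$x0[i]))
    iy <- pmax(0, pmin(r$y1[j], r$y1[i]) - pmax(r$y0[j], r$y0[i]))
    inter <- ix * iy
    areaI <- (r$x1[i] - r$x0[i]) * (r$y1[i] - r$y0[i])
    areaJ <- (r$x1[j] - r$x0[j]) * (r$y1[j] - r$y0[j])
    iou <- inter / (areaI + areaJ - inter)
    alive[j[iou > iouThreshold]] <- FALSE
  }
  out <- r[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep the top-N part regions
#'
#' @param regions NMS survivors (descending score).
#' @param n Number of parts to keep, >= 1.
#' @return The first `n` rows; if fewer survive, all of them with attribute
#'   `shortfall = TRUE`.
#' @export
topNParts <- function(regions, n = 4) {
  stopifnot(n >= 1)
  if (nrow(regions) <= n) {
    attr(regions, "shortfall") <- nrow(regions) < n
    return(regions)
  }
  out <- regions[seq_len(n), , drop = FALSE]
  attr(out, "shortfall") <- FALSE
  out
}

#' Crop part regions from the hand image
#'
#' Each region is cropped from the image and bilinearly resampled to
#' `partSize` (288 x 288 by default). Regions must be expressed in the
#' image's pixel frame; out-of-bounds regions are clamped with a warning.
#'
#' @param image Hand-crop image matrix.
#' @param regions Data frame with `x0, y0, x1, y1` in image pixels.
#' @param partSize Output size `c(width, height)`. Default `c(288, 288)`.
#' @return List of part-image matrices.
#' @export
extractParts <- function(image, regions, partSize = c(288, 288)) {
  lapply(seq_len(nrow(regions)), function(i) {
    cropAndResize(image,
                  roiBox(regions$x0[i], regions$y0[i],
                         regions$x1[i], regions$y1[i]),
                  outSize = partSize)
  })
}

#' Write part-proposal boxes to a debug CSV
#'
#' @param regions Scored regions (data frame with `x0, y0, x1, y1, score`).
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
writePartsCSV <- function(regions, path) {
  df <- data.frame(part_index = seq_len(nrow(regions)),
                   regions[, c("x0", "y0", "x1", "y1", "score")])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
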