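## Synthetic phantom radiographs: schematic hand images whose local geometry
## encodes a known bone age, with paired ambiguous report strings. The
## phantoms give the localization modules findable structure (a bright hand
## region containing a carpal blob cluster and five phalange bars) and the
## label codec parseable text; they are deliberately not anatomically
## realistic.

.gaussBlob <- function(img, cy, cx, radius, intensity) {
  H <- nrow(img); W <- ncol(img)
  y <- pmax(1, round(cy - 3 * radius)):pmin(H, round(cy + 3 * radius))
  x <- pmax(1, round(cx - 3 * radius)):pmin(W, round(cx + 3 * radius))
  g <- exp(-(outer((y - cy)^2, (x - cx)^2, "+")) / (2 * radius^2))
  img[y, x] <- pmax(img[y, x], intensity * g)
  img
}

#' Render one phantom radiograph
#'
#' A bright "hand" rectangle on dark Gaussian noise. Inside the hand, a
#' carpal cluster near the wrist holds `1 + floor(age / 24)` bright blobs
#' (a stepwise-coarse age signal) and five vertical phalange bars grow
#' linearly in length with age (a fine signal). Identical specs render
#' bit-identical images.
#'
#' @param ageMonths Bone age in (0, 240] months.
#' @param imageSize Square image side in pixels. Default 160.
#' @param handOffset Placement `c(dy, dx)` of the hand's top-left corner;
#'   `NULL` (default) draws a small seeded jitter.
#' @param noiseSd Additive Gaussian pixel-noise SD. Default 0.03.
#' @param seed Integer seed.
#' @return List: `image` (matrix in \[0, 1\]), `handBox` (true hand
#'   [roiBox()]), `partCenters` (data frame `x, y` of carpal centre and bar
#'   midpoints), `barLength` (phalange bar length in pixels),
#'   `ageMonths`.
#' @export
generatePhantom <- function(ageMonths, imageSize = 160L, handOffset = NULL,
                            noiseSd = 0.03, seed = 1L) {
  stopifnot(ageMonths > 0, ageMonths <= 240)
  rs <- .saveRNG(); on.exit(.restoreRNG(rs))
  set.seed(seed)

  H <- W <- as.integer(imageSize)
  img <- matrix(stats::rnorm(H * W, mean = 0.08, sd = noiseSd), H, W)

  handH <- round(0.62 * H); handW <- round(0.55 * W)
  if (is.null(handOffset)) {
    handOffset <- c(
      sample(round(0.08 * H):round(0.25 * H), 1),
      sample(round(0.10 * W):round(0.30 * W), 1))
  }
  oy <- handOffset[1]; ox <- handOffset[2]
  stopifnot(oy >= 1, ox >= 1, oy + handH <= H, ox + handW <= W)
  img[oy:(oy + handH - 1), ox:(ox + handW - 1)] <- 0.45

  # five phalange bars from the top of the hand, length linear in age
  barMin <- round(0.08 * handH)
  barMax <- round(0.55 * handH)
  barLen <- round(barMin + (barMax - barMin) * ageMonths / 240)
  barW <- max(2L, round(0.04 * handW))
  xs <- ox + round(seq(0.12, 0.88, length.out = 5) * handW)
  barTop <- oy + round(0.05 * handH)
  centers <- data.frame(x = numeric(0), y = numeric(0))
  for (cx in xs) {
    img[barTop:(barTop + barLen - 1),
        (cx - barW %/% 2):(cx + barW %/% 2)] <- 0.9
    centers <- rbind(centers,
                     data.frame(x = cx, y = barTop + barLen / 2))
  }

  # carpal blob cluster near the wrist, blob count stepwise in age
  nBlobs <- 1L + min(9L, floor(ageMonths / 24))
  ccy <- oy + round(0.82 * handH); ccx <- ox + round(0.5 * handW)
  ang <- seq(0, 2 * pi, length.out = nBlobs + 1L)[seq_len(nBlobs)]
  rad <- 0.10 * min(handH, handW)
  for (k in seq_len(nBlobs)) {
    img <- .gaussBlob(img, ccy + rad * sin(ang[k]), ccx + rad * cos(ang[k]),
                      radius = max(2, 0.03 * handH), intensity = 0.95)
  }
  centers <- rbind(centers, data.frame(x = ccx, y = ccy))

  img <- img + matrix(stats::rnorm(H * W, sd = noiseSd), H, W)
  img <- pmin(pmax(img, 0), 1)

  list(image = img,
       handBox = roiBox(ox - 1, oy - 1, ox + handW - 1, oy + handH - 1),
       partCenters = centers,
       barLength = barLen,
       ageMonths = ageMonths)
}

#' Generate an ambiguous report string for an age
#'
#' Point style: "approximately Y years old" with Y = round(age / 12).
#' Interval style: "Y–(Y+1) years old" bracketing the age. Either phrasing
#' parses back through [parseReportLabel()] with a centre within 6 months of
#' the true age.
#'
#' @param ageMonths Bone age in (0, 240] months.
#' @param style `"point"` or `"interval"`.
#' @param seed Seed for phrasing variation among synonymous point patterns.
#' @return Report string.
#' @export
generateReport <- function(ageMonths, style = c("point", "interval"),
                           seed = 1L) {
  style <- match.arg(style)
  stopifnot(ageMonths > 0, ageMonths <= 240)
  if (style == "point") {
    y <- round(ageMonths / 12)
    if (y < 1) return(sprintf("approximately %d months", round(ageMonths)))
    qual <- c("approximately", "about")[(seed %% 2) + 1]
    sprintf("%s %d years old", qual, y)
  } else {
    y <- min(floor(ageMonths / 12), 19)
    if (y < 1) y <- 1
    sprintf("%d–%d years old", y, y + 1)
  }
}

#' Generate a phantom dataset with manifest and ground truth
#'
#' Draws `n` ages uniformly on \[24, 228\] months, alternates point and
#' interval report styles, renders the phantoms, writes 8-bit grayscale
#' PNGs, a manifest CSV (`image_path, label_text, mu_months, split`) and a
#' `truth.csv` (true age, hand box, part centers, bar length).
#'
#' @param n Number of phantoms.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param dir Output directory (created if missing).
#' @param splitFractions Named fractions for `train`/`val`/`test`; must sum
#'   to 1.
#' @param imageSize,noiseSd Passed to [generatePhantom()].
#' @return List with `manifest` and `truth` data frames (also written under
#'   `dir`).
#' @export
generateDataset <- function(n, seed = 0L, dir = tempfile("phantoms"),
                            splitFractions = c(train = 0.8, val = 0.1,
                                               test = 0.1),
                            imageSize = 160L, noiseSd = 0.03) {
  stopifnot(n >= 1, abs(sum(splitFractions) - 1) < 1e-9)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rs <- .saveRNG(); on.exit(.restoreRNG(rs))
  set.seed(seed)

  ages <- stats::runif(n, 24, 228)
  styles <- rep(c("point", "interval"), length.out = n)
  nTrain <- round(splitFractions[["train"]] * n)
  nVal <- round(splitFractions[["val"]] * n)
  split <- rep("test", n)
  split[seq_len(nTrain)] <- "train"
  if (nVal > 0) split[nTrain + seq_len(min(nVal, n - nTrain))] <- "val"

  phantomSeeds <- sample.int(.Machine$integer.max %/% 2L, n)
  rows <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generatePhantom(ages[i], imageSize = imageSize, noiseSd = noiseSd,
                          seed = phantomSeeds[i])
    path <- file.path(dir, sprintf("phantom_%04d.png", i))
    writeImageGray(ph$image, path)
    txt <- generateReport(ages[i], styles[i], seed = phantomSeeds[i])
    mu <- labelToMu(parseReportLabel(txt))
    rows[[i]] <- data.frame(image_path = path, label_text = txt,
                            mu_months = mu, split = split[i])
    b <- ph$handBox
    truths[[i]] <- data.frame(
      image_path = path, age_months = ages[i],
      hand_x0 = b[["x0"]], hand_y0 = b[["y0"]],
      hand_x1 = b[["x1"]], hand_y1 = b[["y1"]],
      bar_length = ph$barLength,
      part_centers = paste(sprintf("%.1f:%.1f", ph$partCenters$x,
                                   ph$partCenters$y), collapse = ";"))
  }
  manifest <- do.call(rbind, rows)
  truth <- do.call(rbind, truths)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  list(manifest = manifest, truth = truth, dir = dir)
}
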