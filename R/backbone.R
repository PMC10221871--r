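## Pluggable image backbone. Any function image -> H x W x K array works as
## a feature extractor; the package ships a small fixed convolutional
## backbone (4 blocks of 3x3 convolution + ReLU + 2x2 max pooling, He-init
## from a seed, downsampling x16) whose weights are frozen — the trainable
## parameters of the model are the 1x1 projection head. Convolutions are
## implemented as nine shifted matrix products, which keeps desk-scale
## training fast in plain R.

# 3x3 same-convolution (zero padding) of an H x W x Cin array with a
# 3 x 3 x Cin x Cout kernel, as a sum of shifted matrix multiplications.
conv3x3 <- function(x, kernel) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]
  Cout <- dim(kernel)[4]
  pad <- array(0, dim = c(H + 2, W + 2, Cin))
  pad[2:(H + 1), 2:(W + 1), ] <- x
  out <- matrix(0, H * W, Cout)
  for (dy in 0:2) for (dx in 0:2) {
    slice <- pad[(1 + dy):(H + dy), (1 + dx):(W + dx), , drop = FALSE]
    Wk <- matrix(kernel[dy + 1, dx + 1, , ], nrow = Cin, ncol = Cout)
    out <- out + matrix(slice, nrow = H * W, ncol = Cin) %*% Wk
  }
  array(out, dim = c(H, W, Cout))
}

# 2x2 max pooling with stride 2 (H, W must be even).
maxPool2 <- function(x) {
  d <- dim(x)
  i <- seq(1, d[1], by = 2); j <- seq(1, d[2], by = 2)
  pmax(x[i, j, , drop = FALSE], x[i + 1, j, , drop = FALSE],
       x[i, j + 1, , drop = FALSE], x[i + 1, j + 1, , drop = FALSE])
}

#' Create the tiny fixed convolutional backbone
#'
#' Four blocks of 3x3 convolution (He-initialized from `seed`), ReLU, and
#' 2x2 max pooling; channel widths 8-16-32-32; spatial downsampling x16.
#' The weights are fixed at creation: the backbone is a deterministic
#' feature extractor and the model's learning happens in the projection
#' head. Input side lengths must be divisible by 16.
#'
#' @param seed Integer seed for the weight draw.
#' @param channels Channel widths of the four blocks.
#' @return List of kernels with attributes `K` (output channels) and
#'   `downsample` (16).
#' @export
tinyBackbone <- function(seed = 1L, channels = c(8L, 16L, 32L, 32L)) {
  rs <- .saveRNG()
  on.exit(.restoreRNG(rs))
  set.seed(seed)
  cin <- c(1L, channels[-length(channels)])
  kernels <- lapply(seq_along(channels), function(i) {
    fanIn <- 9 * cin[i]
    array(stats::rnorm(9 * cin[i] * channels[i], sd = sqrt(2 / fanIn)),
          dim = c(3, 3, cin[i], channels[i]))
  })
  attr(kernels, "K") <- channels[length(channels)]
  attr(kernels, "downsample") <- 16L
  kernels
}

#' Run the backbone on a grayscale image
#'
#' @param image Numeric matrix in \[0, 1\], sides divisible by 16.
#' @param backbone Kernel list from [tinyBackbone()].
#' @return Feature array of dimension (H/16) x (W/16) x K.
#' @export
backboneForward <- function(image, backbone) {
  if (nrow(image) %% 16L != 0L || ncol(image) %% 16L != 0L)
    stop("image sides must be divisible by 16")
  x <- array(image, dim = c(dim(image), 1L))
  for (k in backbone) {
    x <- conv3x3(x, k)
    x[x < 0] <- 0
    x <- maxPool2(x)
  }
  x
}

# RNG bookkeeping: capture/restore the global RNG stream so that seeded
# helpers do not perturb the caller's stream.
.saveRNG <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restoreRNG <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
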