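# Internal numerical helpers shared by the layer and stimulus code.

#' 3x3 convolution with zero padding
#'
#' Convolves a matrix with a 3x3 kernel, treating pixels outside the frame as
#' zero. Both kernels used by the model (lateral inhibition and grouping) are
#' symmetric, so convolution and correlation coincide.
#'
#' @param x numeric matrix.
#' @param kernel 3x3 numeric kernel.
#' @return numeric matrix of the same dimensions as `x`.
#' @examples
#' imp <- matrix(0, 5, 5); imp[3, 3] <- 1
#' conv3x3(imp, inhibitionKernel())[3, 2]  # 0.25 at a 4-neighbour
#' @export
conv3x3 <- function(x, kernel) {
  if (!is.matrix(x)) stop("`x` must be a matrix")
  if (!identical(dim(kernel), c(3L, 3L))) stop("`kernel` must be 3x3")
  H <- nrow(x)
  W <- ncol(x)
  out <- matrix(0, H, W)
  for (di in -1:1) {
    for (dj in -1:1) {
      w <- kernel[di + 2L, dj + 2L]
      if (w == 0) next
      rs <- max(1L, 1L - di):min(H, H - di)
      cs <- max(1L, 1L - dj):min(W, W - dj)
      out[rs, cs] <- out[rs, cs] + w * x[rs + di, cs + dj]
    }
  }
  out
}

#' Lateral inhibition kernel
#'
#' The 3x3 surround kernel of the delayed inhibition pathway: 1/4 at the four
#' nearest neighbours, 1/8 at the diagonals, 0 at the centre.
#'
#' @return 3x3 numeric matrix.
#' @export
inhibitionKernel <- function() {
  matrix(c(1 / 8, 1 / 4, 1 / 8,
           1 / 4, 0,     1 / 4,
           1 / 8, 1 / 4, 1 / 8), nrow = 3, byrow = TRUE)
}

#' Grouping kernel
#'
#' The equal-weighted 3x3 averaging kernel (all entries 1/9) used to compute
#' the passing coefficient of the grouping layer.
#'
#' @return 3x3 numeric matrix.
#' @export
groupingKernel <- function() {
  matrix(1 / 9, nrow = 3, ncol = 3)
}

# clamp to 8-bit grayscale
clamp8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

# format doubles so that read.csv()/as.numeric round-trips exactly
fmt_full <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}
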