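#' @import methods
NULL

## Run `expr` under a fixed RNG seed without disturbing the caller's stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Discrete Gaussian kernel from its full width at half maximum
#'
#' Builds the normalized one-dimensional Gaussian kernel used throughout the
#' post-processing pipeline: \eqn{\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})},
#' truncated at \eqn{\pm 4\sigma} and renormalized to unit sum.
#'
#' @param fwhmPx kernel full width at half maximum, in pixels (> 0).
#' @return Numeric vector of odd length summing to 1.
#' @examples
#' k <- gaussianKernel1d(3.25)
#' sum(k)  # 1
#' @export
gaussianKernel1d <- function(fwhmPx) {
  stopifnot(is.numeric(fwhmPx), length(fwhmPx) == 1L, fwhmPx > 0)
  sigma <- fwhmPx / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(4 * sigma))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## Reflect-pad a matrix by (rPad, cPad) pixels on each side.
padReflect <- function(m, rPad, cPad) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(rPad < nr, cPad < nc)
  ## mirror without repeating the border pixel: indices r+1..2 | 1..n | n-1..n-r
  ri <- c(rev(seq_len(rPad)) + 1L, seq_len(nr), nr - seq_len(rPad))
  ci <- c(rev(seq_len(cPad)) + 1L, seq_len(nc), nc - seq_len(cPad))
  m[ri, ci, drop = FALSE]
}

## Separable convolution with reflected edges; `kernel` is a 1-D normalized
## kernel applied along rows then columns.
convolveSeparable <- function(m, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(m * kernel)
  p <- padReflect(m, r, r)
  nr <- nrow(m); nc <- ncol(m)
  ## pass along rows (vertical direction)
  tmp <- matrix(0, nr, nc + 2L * r)
  for (j in seq_along(kernel))
    tmp <- tmp + kernel[j] * p[(j - 1L) + seq_len(nr), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (j in seq_along(kernel))
    out <- out + kernel[j] * tmp[, (j - 1L) + seq_len(nc), drop = FALSE]
  out
}

## Zero-mean, unit-variance correlated Gaussian random field: white noise
## smoothed with a Gaussian of the given FWHM (px), rescaled analytically so
## the marginal sd is 1 (filtered white noise has sd sqrt(sum(w2d^2))).
correlatedField <- function(nrow, ncol, fwhmPx) {
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  if (fwhmPx <= 0) return(z)
  k <- gaussianKernel1d(fwhmPx)
  sd2d <- sum(k^2)            # per-axis sum of squared weights
  convolveSeparable(z, k) / sd2d
}

## Pixel-center coordinate grids in cm; row 0 is the top (dorsal) edge.
## Returns matrices R (row coord) and C (col coord) of the grid shape.
coordGrids <- function(gridShape, pixelSize) {
  r <- (seq_len(gridShape[1]) - 0.5) * pixelSize
  c <- (seq_len(gridShape[2]) - 0.5) * pixelSize
  list(R = matrix(r, gridShape[1], gridShape[2]),
       C = matrix(c, gridShape[1], gridShape[2], byrow = TRUE))
}

## Logical mask of an axis-aligned ellipse (cm units).
ellipseMask <- function(grids, centerRow, centerCol, semiRow, semiCol) {
  ((grids$R - centerRow) / semiRow)^2 + ((grids$C - centerCol) / semiCol)^2 <= 1
}

capFirst <- function(x) paste0(toupper(substring(x, 1, 1)), substring(x, 2))

## Recursive named-list merge (override wins; nested lists merged).
.mergeLists <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .mergeLists(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}
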