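## Shared image helpers: separable convolution with replicated borders,
## Gaussian blur, and strict local-maximum detection. Images are numeric
## matrices indexed [v + 1, u + 1] (row = v, col = u, 0-based pixel centers
## at integer coordinates).

#' Separable convolution with clamped (replicated) borders
#'
#' Applies the same 1D kernel along rows and columns. \code{offsets} are the
#' tap positions (may include holes for a-trous filtering).
#' @keywords internal
sep_convolve_clamp <- function(img, offsets, weights) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  idx <- function(i, n) pmin(pmax(i, 1L), n)
  for (k in seq_along(offsets)) {      # rows (vertical)
    out <- out + weights[k] * img[idx(seq_len(nr) + offsets[k], nr), ,
                                  drop = FALSE]
  }
  out2 <- matrix(0, nr, nc)
  for (k in seq_along(offsets)) {      # cols (horizontal)
    out2 <- out2 + weights[k] * out[, idx(seq_len(nc) + offsets[k], nc),
                                    drop = FALSE]
  }
  out2
}

#' Gaussian blur (separable, truncated at 3 sigma)
#' @keywords internal
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  off <- -r:r
  w <- exp(-off^2 / (2 * sigma^2))
  w <- w / sum(w)
  sep_convolve_clamp(img, off, w)
}

#' 8-neighborhood local maxima above a threshold
#'
#' Plateau ties (e.g. a spot centred exactly between pixels) are broken by
#' raster order: a pixel must exceed its earlier neighbors and be at least
#' equal to its later ones, so each plateau yields exactly one candidate.
#'
#' @param img numeric matrix.
#' @param threshold minimum value.
#' @return data frame with 0-based \code{u}, \code{v} and \code{value},
#'   sorted by decreasing value.
#' @keywords internal
local_maxima <- function(img, threshold = -Inf) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 3 || nc < 3)
    return(data.frame(u = integer(0), v = integer(0), value = numeric(0)))
  core <- img[2:(nr - 1), 2:(nc - 1)]
  ok <- core > threshold
  for (dv in -1:1) for (du in -1:1) {
    if (dv == 0 && du == 0) next
    nb <- img[2:(nr - 1) + dv, 2:(nc - 1) + du]
    earlier <- du < 0 || (du == 0 && dv < 0)  # column-major raster order
    ok <- ok & (if (earlier) core > nb else core >= nb)
  }
  w <- which(ok, arr.ind = TRUE)
  if (nrow(w) == 0)
    return(data.frame(u = integer(0), v = integer(0), value = numeric(0)))
  v <- w[, 1] + 1L; u <- w[, 2] + 1L   # back to full-image 1-based indices
  val <- img[cbind(v, u)]
  o <- order(val, decreasing = TRUE)
  data.frame(u = u[o] - 1L, v = v[o] - 1L, value = val[o])
}
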