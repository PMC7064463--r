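#' Class-boundary contour mask
#'
#' @param boundary_mask logical matrix marking boundary pixels.
#' @param method name of the edge operator that produced it.
#' @return An object of class `contour_map`.
#' @export
contour_map <- function(boundary_mask, method) {
  structure(list(boundary_mask = boundary_mask, method = method),
            class = "contour_map")
}

#' @export
print.contour_map <- function(x, ...) {
  cat(sprintf("<contour_map> %d x %d px, %d boundary px (%s)\n",
              nrow(x$boundary_mask), ncol(x$boundary_mask),
              sum(x$boundary_mask), x$method))
  invisible(x)
}

label_boundary_mask <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  m <- matrix(FALSE, nr, nc)
  if (nr > 1L) {
    diff_v <- labels[-1L, , drop = FALSE] != labels[-nr, , drop = FALSE]
    m[-nr, ] <- m[-nr, ] | diff_v
    m[-1L, ] <- m[-1L, ] | diff_v
  }
  if (nc > 1L) {
    diff_h <- labels[, -1L, drop = FALSE] != labels[, -nc, drop = FALSE]
    m[, -nc] <- m[, -nc] | diff_h
    m[, -1L] <- m[, -1L] | diff_h
  }
  m
}

# Separable replicate-padded Gaussian smoothing.
gaussian_smooth <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) pmin(pmax(seq_len(n + 2L * r) - r, 1L), n)
  conv1 <- function(m) {                       # along rows (first dim)
    mp <- m[pad_idx(nrow(m)), , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * mp[seq_len(nrow(m)) + j - 1L, , drop = FALSE]
    out
  }
  t(conv1(t(conv1(x))))
}

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Classical Canny: Gaussian blur, Sobel gradients, non-maximum suppression
# along the quantized gradient direction, double threshold with hysteresis.
canny_edges <- function(x, sigma = 1, low = 0.1, high = 0.2) {
  x <- as.matrix(x)
  rng <- diff(range(x))
  if (rng == 0) return(matrix(FALSE, nrow(x), ncol(x)))
  x <- (x - min(x)) / rng
  s <- gaussian_smooth(x, sigma)
  # Sobel kernels on (row, col) axes
  gr <- shift_mat(s, 1L, -1L) + 2 * shift_mat(s, 1L, 0L) + shift_mat(s, 1L, 1L) -
        shift_mat(s, -1L, -1L) - 2 * shift_mat(s, -1L, 0L) - shift_mat(s, -1L, 1L)
  gc <- shift_mat(s, -1L, 1L) + 2 * shift_mat(s, 0L, 1L) + shift_mat(s, 1L, 1L) -
        shift_mat(s, -1L, -1L) - 2 * shift_mat(s, 0L, -1L) - shift_mat(s, 1L, -1L)
  mag <- sqrt(gr^2 + gc^2)
  if (max(mag) == 0) return(matrix(FALSE, nrow(x), ncol(x)))
  ang <- atan2(gr, gc)                          # direction of the gradient
  sector <- (round(ang / (pi / 4)) %% 4)        # 0:E,1:NE,2:N,3:NW
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  nms <- matrix(FALSE, nrow(x), ncol(x))
  for (sct in 0:3) {
    o <- offs[[sct + 1L]]
    keep <- sector == sct &
      mag >= shift_mat(mag, o[1L], o[2L]) &
      mag >= shift_mat(mag, -o[1L], -o[2L])
    nms <- nms | keep
  }
  mmax <- max(mag)
  strong <- nms & mag >= high * mmax
  weak <- nms & mag >= low * mmax
  # hysteresis: grow strong edges through 8-connected weak pixels
  edges <- strong
  repeat {
    grown <- edges
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0L || dc != 0L) grown <- grown | shift_mat(edges, dr, dc)
    grown <- grown & weak
    if (identical(grown, edges)) break
    edges <- grown
  }
  edges
}

#' Extract boundary contours from a classification map
#'
#' Method `"label_boundary"` (the default) marks exactly the pixels whose
#' 4-neighborhood contains a different label — parameter-free and exact on a
#' label map. Method `"canny"` runs the classical Canny edge operator on the
#' label raster rendered as an intensity image: Gaussian blur of width
#' `sigma`, Sobel gradients, non-maximum suppression, and hysteresis
#' thresholding at `low`/`high` fractions of the maximum gradient magnitude.
#'
#' @param cmap a [classification_map()].
#' @param method edge operator.
#' @param sigma,low,high Canny parameters (ignored for `label_boundary`).
#' @return A [contour_map()] of the same shape as the map.
#' @export
extract_contours <- function(cmap, method = c("label_boundary", "canny"),
                             sigma = 1, low = 0.1, high = 0.2) {
  method <- match.arg(method)
  mask <- switch(method,
    label_boundary = label_boundary_mask(cmap$labels),
    canny = canny_edges(cmap$labels, sigma = sigma, low = low, high = high)
  )
  contour_map(mask, method)
}
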