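# Shared correlation and interpolation numerics for the tracking stages.
#
# Conventions: matrices are row = y (down), col = x (right), 1-based in R.
# A reported offset (dx, dy) means the moving image equals the reference
# translated by +dx px right and +dy px down; shifting the moving image by
# (-dx, -dy) aligns it back onto the reference.

fft2 <- function(x, inverse = FALSE) stats::fft(x, inverse = inverse)

# Summed-area table padded with a zero row/col so window sums vectorize.
sat_pad <- function(x) {
  s <- apply(apply(x, 2, cumsum), 1, cumsum)  # t(cumsum both dims)
  s <- t(s)
  rbind(0, cbind(0, s))
}

# Sums of all h x w windows of x (valid positions only).
window_sums <- function(x, h, w) {
  s <- sat_pad(x)
  H <- nrow(x); W <- ncol(x)
  i <- seq_len(H - h + 1L); j <- seq_len(W - w + 1L)
  s[i + h, j + w, drop = FALSE] - s[i, j + w, drop = FALSE] -
    s[i + h, j, drop = FALSE] + s[i, j, drop = FALSE]
}

#' Normalized cross-correlation map of a template over an image
#'
#' Computes the zero-mean normalized cross-correlation (NCC) of `template`
#' against every fully contained placement in `image`, using FFT
#' cross-correlation for the numerator and summed-area tables for the local
#' mean/variance terms. Entry `[i, j]` is the NCC of the template with the
#' image window whose top-left pixel is `(i, j)`.
#'
#' @param image numeric matrix.
#' @param template numeric matrix, no larger than `image`.
#' @return matrix of NCC values in \[-1, 1\], dimensions
#'   `(nrow(image)-nrow(template)+1) x (ncol(image)-ncol(template)+1)`.
#' @export
ncc_match <- function(image, template) {
  H <- nrow(image); W <- ncol(image)
  h <- nrow(template); w <- ncol(template)
  if (h > H || w > W)
    stop("template larger than image", call. = FALSE)
  tz <- template - mean(template)
  tss <- sum(tz^2)
  tp <- matrix(0, H, W); tp[1:h, 1:w] <- tz
  num <- Re(fft2(fft2(image) * Conj(fft2(tp)), inverse = TRUE)) / (H * W)
  num <- num[seq_len(H - h + 1L), seq_len(W - w + 1L), drop = FALSE]
  s1 <- window_sums(image, h, w)
  s2 <- window_sums(image^2, h, w)
  varsum <- pmax(s2 - s1^2 / (h * w), 0)
  den <- sqrt(varsum * tss)
  out <- num / den
  out[!is.finite(out) | den < 1e-12] <- 0
  out[out > 1] <- 1; out[out < -1] <- -1
  out
}

# Locate the NCC peak with optional 3-point parabolic sub-pixel refinement.
# Returns list(row, col, ncc) with fractional row/col when refined.
ncc_peak <- function(map, subpixel = TRUE) {
  k <- which.max(map)
  iy <- (k - 1L) %% nrow(map) + 1L
  ix <- (k - 1L) %/% nrow(map) + 1L
  ry <- iy; rx <- ix
  if (subpixel) {
    if (iy > 1 && iy < nrow(map))
      ry <- iy + peak_refine(map[(iy - 1):(iy + 1), ix])
    if (ix > 1 && ix < ncol(map))
      rx <- ix + peak_refine(map[iy, (ix - 1):(ix + 1)])
  }
  list(row = ry, col = rx, ncc = map[iy, ix])
}

#' Rigid offset between a moving image and a reference
#'
#' Finds the single translation maximizing zero-mean NCC within a square
#' search radius, by matching the central crop of the moving image inside
#' the reference. Positive `dx`/`dy` mean the moving image content sits
#' right/down of its position in the reference.
#'
#' @param moving,reference equally sized numeric matrices.
#' @param search_radius maximum displacement searched, px.
#' @param subpixel refine the correlation peak by a 3-point parabolic fit.
#' @return list with `dx`, `dy` (px, possibly fractional) and `ncc`.
#' @export
best_shift <- function(moving, reference, search_radius = 64,
                       subpixel = TRUE) {
  if (!all(dim(moving) == dim(reference)))
    stop("`moving` and `reference` must have the same shape", call. = FALSE)
  r <- as.integer(search_radius)
  r <- min(r, (min(dim(moving)) - 8L) %/% 2L)
  if (r < 1L) stop("image too small for the search radius", call. = FALSE)
  tpl <- moving[(r + 1):(nrow(moving) - r), (r + 1):(ncol(moving) - r),
                drop = FALSE]
  map <- ncc_match(reference, tpl)
  pk <- ncc_peak(map, subpixel)
  # template nominal top-left in the reference is (r+1, r+1)
  list(dx = (r + 1) - pk$col, dy = (r + 1) - pk$row, ncc = pk$ncc)
}

# Match a patch whose nominal top-left in `reference` is (row0, col0),
# searching +/- search_y rows and +/- search_x cols. Returns the offset of
# the patch content relative to nominal (same sign convention as best_shift)
# and the absolute placement (row, col) of the patch in reference coords.
match_patch <- function(reference, patch, row0, col0, search_y, search_x,
                        subpixel = TRUE) {
  h <- nrow(patch); w <- ncol(patch)
  r1 <- max(1L, row0 - search_y); r2 <- min(nrow(reference), row0 + h - 1L + search_y)
  c1 <- max(1L, col0 - search_x); c2 <- min(ncol(reference), col0 + w - 1L + search_x)
  sub <- reference[r1:r2, c1:c2, drop = FALSE]
  if (nrow(sub) < h || ncol(sub) < w)
    return(list(dx = NA_real_, dy = NA_real_, ncc = -Inf,
                row = NA_real_, col = NA_real_))
  map <- ncc_match(sub, patch)
  pk <- ncc_peak(map, subpixel)
  found_row <- r1 + pk$row - 1
  found_col <- c1 + pk$col - 1
  list(dx = col0 - found_col, dy = row0 - found_row, ncc = pk$ncc,
       row = found_row, col = found_col)
}

# ---- interpolation ---------------------------------------------------------

# Bilinear sample of img at the grid defined by fractional row coords ys and
# col coords xs (vectors). Out-of-range coordinates clamp to the border.
bilinear_grid <- function(img, ys, xs) {
  H <- nrow(img); W <- ncol(img)
  ys <- pmin(pmax(ys, 1), H); xs <- pmin(pmax(xs, 1), W)
  y0 <- pmin(floor(ys), H - 1L); x0 <- pmin(floor(xs), W - 1L)
  fy <- ys - y0; fx <- xs - x0
  # outer-product expansion of the four corner contributions
  i00 <- img[y0, x0, drop = FALSE]
  i01 <- img[y0, x0 + 1, drop = FALSE]
  i10 <- img[y0 + 1, x0, drop = FALSE]
  i11 <- img[y0 + 1, x0 + 1, drop = FALSE]
  wy <- matrix(fy, length(ys), length(xs))
  wx <- matrix(fx, length(ys), length(xs), byrow = TRUE)
  i00 * (1 - wy) * (1 - wx) + i01 * (1 - wy) * wx +
    i10 * wy * (1 - wx) + i11 * wy * wx
}

# Translate an image by (dx, dy) (content moves right/down for positive),
# bilinear, border-clamped.
shift_image <- function(img, dx, dy) {
  bilinear_grid(img, seq_len(nrow(img)) - dy, seq_len(ncol(img)) - dx)
}

#' Gaussian pre-smoothing for low-photon registration
#'
#' Convolves an image with an isotropic 2-d Gaussian kernel. Used before
#' cross-correlating weak-photon (fluorescence) frames; rendering always
#' uses the raw pixels. `sigma = 0` is the identity.
#'
#' @param image numeric matrix.
#' @param sigma Gaussian standard deviation in px (default 5).
#' @return smoothed matrix of the same size.
#' @export
presmooth <- function(image, sigma = 5) {
  if (sigma <= 0) return(image)
  sm <- EBImage::gblur(image, sigma = sigma)
  matrix(EBImage::imageData(sm), nrow(image), ncol(image))
}
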