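#' Trichrome image container
#'
#' Wraps an RGB raster of a Masson's-trichrome-stained section as a numeric
#' `H x W x 3` array with channel intensities in `[0, 1]`, optionally carrying
#' the physical pixel size. All fiber-analysis functions in the package take
#' this container as input.
#'
#' Pixel coordinates are 0-based with the origin at the top-left corner;
#' `x` runs along columns, `y` along rows (down the image).
#'
#' @param pixels numeric array `H x W x 3` with values in `[0, 1]`.
#' @param pixel_size_um optional physical pixel size in micrometres per pixel.
#' @return An object of class `trichrome_image`: a list with elements
#'   `pixels` and `pixel_size_um`.
#' @examples
#' img <- trichrome_image(array(0.5, dim = c(64, 64, 3)))
#' dim(img$pixels)
#' @export
trichrome_image <- function(pixels, pixel_size_um = NA_real_) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one pixel")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("channel values must lie in [0, 1]")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "trichrome_image")
}

#' @export
print.trichrome_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("trichrome_image: %d x %d px, RGB in [0,1]%s\n", d[1], d[2],
              if (is.na(x$pixel_size_um)) ""
              else sprintf(", %.3g um/px", x$pixel_size_um)))
  invisible(x)
}

#' Read and write trichrome images as 8-bit RGB PNG
#'
#' @param path file path.
#' @param image a [trichrome_image()].
#' @param pixel_size_um pixel size attached to the image on reading.
#' @return `read_trichrome_png` returns a `trichrome_image`;
#'   `write_trichrome_png` returns `path` invisibly.
#' @export
read_trichrome_png <- function(path, pixel_size_um = NA_real_) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  trichrome_image(px, pixel_size_um)
}

#' @rdname read_trichrome_png
#' @export
write_trichrome_png <- function(image, path) {
  stopifnot(inherits(image, "trichrome_image"))
  # quantize to 8 bit so written output is reproducible byte-for-byte
  q <- round(image$pixels * 255) / 255
  png::writePNG(q, path)
  invisible(path)
}

## ---- internal geometry / FFT helpers -------------------------------------

# Integer offsets (drow, dcol) within a Euclidean disk of the given radius.
# include_center = FALSE drops the (0,0) offset.
disk_offsets <- function(radius, include_center = TRUE) {
  r <- as.integer(radius)
  g <- expand.grid(drow = -r:r, dcol = -r:r)
  keep <- g$drow^2 + g$dcol^2 <= radius^2
  if (!include_center) keep <- keep & !(g$drow == 0 & g$dcol == 0)
  g[keep, , drop = FALSE]
}

# Dense (2r+1)^2 kernel from a function of the offsets; kernel value is 0
# outside the disk.
disk_kernel <- function(radius, fun, include_center = TRUE) {
  r <- as.integer(radius)
  n <- 2L * r + 1L
  k <- matrix(0 + 0i, n, n)
  off <- disk_offsets(radius, include_center)
  k[cbind(off$drow + r + 1L, off$dcol + r + 1L)] <- fun(off$drow, off$dcol)
  k
}

# Centered 2-D convolution with zero padding ("same" size). For the symmetric
# kernels used here convolution and cross-correlation coincide.
conv2_same <- function(x, k) {
  H <- nrow(x); W <- ncol(x)
  kh <- nrow(k); kw <- ncol(k)
  # pad to highly composite sizes: mixed-radix FFTs degrade on large primes
  ph <- stats::nextn(H + kh - 1L, c(2, 3, 5))
  pw <- stats::nextn(W + kw - 1L, c(2, 3, 5))
  X <- matrix(0 + 0i, ph, pw); X[seq_len(H), seq_len(W)] <- x
  K <- matrix(0 + 0i, ph, pw); K[seq_len(kh), seq_len(kw)] <- k
  full <- stats::fft(stats::fft(X) * stats::fft(K), inverse = TRUE) / (ph * pw)
  r0 <- (kh + 1L) / 2L; c0 <- (kw + 1L) / 2L
  full[r0:(r0 + H - 1L), c0:(c0 + W - 1L)]
}
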