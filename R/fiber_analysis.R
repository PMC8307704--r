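#' Segment collagen by the blue-red intensity ratio
#'
#' In Masson's trichrome staining collagen takes up the blue dye while
#' cytoplasm and muscle stain red, so the per-pixel blue/red intensity ratio
#' locates the collagen. A pixel belongs to the collagen mask when
#' `blue / (red + 1e-6) > ratio_threshold` (strict inequality: neutral gray is
#' excluded at the default threshold of 1). The collagen weight of a mask
#' pixel is its blue-minus-red excess normalized to `[0, 1]`
#' (`clip(blue - red, 0, 1)`); weights are 0 off the mask.
#'
#' @param image a [trichrome_image()].
#' @param ratio_threshold positive blue/red ratio cut, default 1.
#' @return a `collagen_map`: list with logical `mask` (H x W) and numeric
#'   `weight` (H x W in `[0, 1]`, zero off-mask).
#' @examples
#' px <- array(0, dim = c(64, 64, 3)); px[, , 3] <- 1
#' cm <- segment_collagen(trichrome_image(px))
#' mean(cm$mask)  # all collagen
#' @export
segment_collagen <- function(image, ratio_threshold = 1) {
  stopifnot(inherits(image, "trichrome_image"), ratio_threshold > 0)
  red <- image$pixels[, , 1]
  blue <- image$pixels[, , 3]
  mask <- blue / (red + 1e-6) > ratio_threshold
  weight <- pmin(1, pmax(0, blue - red)) * mask
  structure(list(mask = mask, weight = weight), class = "collagen_map")
}

#' Estimate the per-pixel axial fiber orientation by weighted vector summation
#'
#' For every collagen pixel `c`, all other collagen pixels `j` within a disk
#' of radius `window_radius_px` contribute a unit vector at twice the angle of
#' the segment `c -> j`, scaled by the collagen weight of `j` (doubling the
#' angle makes the statistic axial: `j` and its mirror image reinforce rather
#' than cancel). The orientation at `c` is half the angle of the resultant,
#' mapped to `[0, 180)` degrees; the certainty is the resultant length divided
#' by the total contributing weight, in `[0, 1]`. Pixels whose neighborhood
#' weight falls below `1e-9` (isolated pixels, empty disks at borders) carry
#' no orientation. Disks are truncated at image borders and normalized by the
#' included weight only.
#'
#' The summation over all pixels is evaluated as an exact FFT
#' cross-correlation with a fixed complex disk kernel; it equals the literal
#' per-pixel double loop to floating-point precision.
#'
#' @param cmap a `collagen_map` from [segment_collagen()].
#' @param window_radius_px disk radius in pixels, `>= 1`; default 8 (must
#'   exceed the fiber thickness for the segment direction to dominate).
#' @return an `orientation_field`: list with `theta_deg` (H x W, `NA` where
#'   undefined), `certainty` (H x W, `NA` where undefined), `defined`
#'   (logical H x W), and the carried collagen `weight` map.
#' @export
estimate_orientation_field <- function(cmap, window_radius_px = 8) {
  stopifnot(inherits(cmap, "collagen_map"), window_radius_px >= 1)
  w <- cmap$weight
  # angle of the offset (drow, dcol) measured CCW on screen: atan2(-drow, dcol)
  kern <- disk_kernel(window_radius_px,
                      function(dr, dc) exp(2i * atan2(-dr, dc)),
                      include_center = FALSE)
  wsum_kern <- disk_kernel(window_radius_px, function(dr, dc) 1 + 0i,
                           include_center = FALSE)
  resultant <- conv2_same(w, kern)
  wsum <- Re(conv2_same(w, wsum_kern))
  defined <- cmap$mask & wsum >= 1e-9
  theta <- matrix(NA_real_, nrow(w), ncol(w))
  cert <- matrix(NA_real_, nrow(w), ncol(w))
  ang <- (Arg(resultant) %% (2 * pi)) / 2 * 180 / pi
  r <- Mod(resultant) / pmax(wsum, 1e-300)
  theta[defined] <- ang[defined] %% 180
  cert[defined] <- pmin(1, r[defined])
  structure(list(theta_deg = theta, certainty = cert, defined = defined,
                 weight = w, window_radius_px = window_radius_px),
            class = "orientation_field")
}

#' Directional variance of axial orientations
#'
#' The weighted circular variance on doubled angles:
#' `V = 1 - |sum(w * exp(2i * theta))| / sum(w)`, with `theta` in degrees.
#' `V = 0` for perfectly aligned orientations and `V -> 1` for uniformly
#' random orientations; two equally weighted orientations 90 degrees apart
#' give exactly 1 (their doubled angles are antipodal).
#'
#' @param theta_deg axial angles in degrees.
#' @param weights nonnegative weights, same length; default equal weights.
#' @return directional variance in `[0, 1]`; `NA` (with a warning) when the
#'   total weight is zero or no orientations are supplied.
#' @examples
#' directional_variance(c(30, 30, 30))      # 0
#' directional_variance(c(0, 90))           # 1
#' @export
directional_variance <- function(theta_deg, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(theta_deg))
  if (length(theta_deg) != length(weights))
    stop("orientations and weights must have the same length")
  if (any(weights < 0)) stop("weights must be nonnegative")
  keep <- !is.na(theta_deg)
  theta_deg <- theta_deg[keep]; weights <- weights[keep]
  sw <- sum(weights)
  if (length(theta_deg) == 0 || sw <= 0) {
    warning("directional variance undefined: no weighted orientations")
    return(NA_real_)
  }
  z <- sum(weights * exp(2i * theta_deg * pi / 180))
  1 - Mod(z) / sw
}

#' Local directional variance map
#'
#' At every pixel with a defined orientation, the directional variance of the
#' orientations within the surrounding disk (including the pixel itself),
#' weighted by collagen weight, truncated at image borders. The summary value
#' is the unweighted mean of the map over defined pixels.
#'
#' @param field an `orientation_field` from [estimate_orientation_field()].
#' @param radius_px neighborhood radius in pixels, default 50.
#' @param region optional `region` restricting the mean (the map is computed
#'   over the full field; neighborhoods always use all defined pixels).
#' @return list with `map` (H x W, `NA` where undefined) and `mean`. The mean
#'   is `NA` with a warning when the field has no defined pixels in the
#'   region.
#' @export
local_directional_variance <- function(field, radius_px = 50, region = NULL) {
  stopifnot(inherits(field, "orientation_field"), radius_px >= 1)
  w <- pixel_variance_weight(field)
  z <- matrix(0 + 0i, nrow(w), ncol(w))
  z[field$defined] <- w[field$defined] *
    exp(2i * field$theta_deg[field$defined] * pi / 180)
  kern <- disk_kernel(radius_px, function(dr, dc) 1 + 0i)
  num <- Mod(conv2_same(z, kern))
  den <- Re(conv2_same(w, kern))
  map <- matrix(NA_real_, nrow(w), ncol(w))
  ok <- field$defined & den >= 1e-9
  map[ok] <- pmin(1, pmax(0, 1 - num[ok] / den[ok]))
  sel <- region_mask(region, nrow(w), ncol(w)) & !is.na(map)
  if (!any(sel)) {
    warning("local directional variance undefined: no defined pixels")
    return(list(map = map, mean = NA_real_))
  }
  list(map = map, mean = mean(map[sel]))
}

# Standard per-pixel weight for variance statistics: collagen weight times
# squared orientation certainty. Incoherent pixels (fiber crossings, contact
# points between neighboring fibers) carry noisy orientation estimates that
# would otherwise inflate the variance; certainty weighting suppresses them.
pixel_variance_weight <- function(field) {
  w <- field$weight * 0
  w[field$defined] <- field$weight[field$defined] *
    field$certainty[field$defined]^2
  w
}

#' Overall directional variance over a region
#'
#' Single directional variance pooled over all defined pixels of the region,
#' each pixel weighted by its collagen weight times its squared orientation
#' certainty (coherently oriented pixels dominate; pixels at fiber crossings
#' contribute little).
#'
#' @inheritParams local_directional_variance
#' @param region a `region` ([region_box()] etc.) or `NULL` for the whole
#'   field.
#' @return directional variance in `[0, 1]`.
#' @export
overall_directional_variance <- function(field, region = NULL) {
  stopifnot(inherits(field, "orientation_field"))
  sel <- region_mask(region, nrow(field$theta_deg), ncol(field$theta_deg)) &
    field$defined
  w <- pixel_variance_weight(field)
  directional_variance(field$theta_deg[sel], w[sel])
}

#' Fiber density of a region
#'
#' Fraction of region pixels on the collagen mask.
#'
#' @param cmap a `collagen_map`.
#' @param region a `region` or `NULL` for the whole image.
#' @return fraction in `[0, 1]`.
#' @export
fiber_density <- function(cmap, region = NULL) {
  stopifnot(inherits(cmap, "collagen_map"))
  sel <- region_mask(region, nrow(cmap$mask), ncol(cmap$mask))
  if (!any(sel)) stop("empty region")
  mean(cmap$mask[sel])
}

#' Mean blue intensity over collagen pixels of a region
#'
#' @param image a [trichrome_image()].
#' @param cmap its `collagen_map`.
#' @param region a `region` or `NULL`.
#' @return mean normalized blue channel value over mask pixels, in `[0, 1]`.
#' @export
blue_intensity <- function(image, cmap, region = NULL) {
  stopifnot(inherits(image, "trichrome_image"), inherits(cmap, "collagen_map"))
  sel <- region_mask(region, nrow(cmap$mask), ncol(cmap$mask)) & cmap$mask
  if (!any(sel)) stop("no collagen pixels in region")
  mean(image$pixels[, , 3][sel])
}

#' Fiber-analysis parameters
#'
#' @param ratio_threshold blue/red segmentation cut (default 1).
#' @param window_radius_px orientation summation radius (default 8 px).
#' @param local_radius_px local-variance neighborhood radius (default 50 px).
#' @return a named list of parameters.
#' @export
fiber_params <- function(ratio_threshold = 1, window_radius_px = 8,
                         local_radius_px = 50) {
  list(ratio_threshold = ratio_threshold,
       window_radius_px = window_radius_px,
       local_radius_px = local_radius_px)
}

#' Analyze a trichrome section over the standard five-region layout
#'
#' Runs the full fiber pipeline — blue-red segmentation, weighted vector
#' summation orientation field, directional variance — and reports the four
#' region metrics (overall directional variance, mean local directional
#' variance, fiber density, mean blue intensity) for the scar `S` and the
#' four flanking boxes, plus pooled rows for the distal (`RD&LD`) and
#' proximal (`RP&LP`) pairs. Pooled rows pool the per-pixel data of the two
#' boxes, not the per-box metric averages.
#'
#' @param image a [trichrome_image()].
#' @param layout a [region_layout()].
#' @param params a [fiber_params()] list.
#' @return data.frame with one row per region (`S`, `LD`, `LP`, `RP`, `RD`,
#'   `Distal`, `Proximal`) and columns `directional_variance`,
#'   `local_directional_variance`, `fiber_density`, `blue_intensity`.
#' @export
analyze_section <- function(image, layout, params = fiber_params()) {
  stopifnot(inherits(image, "trichrome_image"),
            inherits(layout, "region_layout"))
  H <- dim(image$pixels)[1]; W <- dim(image$pixels)[2]
  cmap <- segment_collagen(image, params$ratio_threshold)
  field <- estimate_orientation_field(cmap, params$window_radius_px)
  loc <- local_directional_variance(field, params$local_radius_px)
  regs <- layout_regions(layout)
  masks <- lapply(regs, region_mask, H = H, W = W)
  masks$Distal <- masks$RD | masks$LD
  masks$Proximal <- masks$RP | masks$LP
  vw <- pixel_variance_weight(field)
  one <- function(sel) {
    dsel <- sel & field$defined
    data.frame(
      directional_variance =
        directional_variance(field$theta_deg[dsel], vw[dsel]),
      local_directional_variance = {
        s <- sel & !is.na(loc$map)
        if (any(s)) mean(loc$map[s]) else NA_real_
      },
      fiber_density = mean(cmap$mask[sel]),
      blue_intensity = if (any(sel & cmap$mask))
        mean(image$pixels[, , 3][sel & cmap$mask]) else NA_real_
    )
  }
  out <- do.call(rbind, lapply(masks, one))
  data.frame(region = names(masks), out, row.names = NULL)
}
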