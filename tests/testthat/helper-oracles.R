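# Independent oracles and small fixture builders shared across tests.

# Build a collagen_map directly from a mask (and optional weight) matrix.
make_cmap <- function(mask, weight = NULL) {
  if (is.null(weight)) weight <- mask * 1
  structure(list(mask = mask, weight = weight), class = "collagen_map")
}

# Literal double-loop weighted vector summation: the reference
# implementation of the orientation field, O(pixels * disk area).
brute_orientation_field <- function(cmap, R) {
  w <- cmap$weight
  H <- nrow(w); W <- ncol(w)
  theta <- matrix(NA_real_, H, W)
  cert <- matrix(NA_real_, H, W)
  defined <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!cmap$mask[i, j]) next
    res <- 0 + 0i; sw <- 0
    for (di in -R:R) for (dj in -R:R) {
      if (di == 0 && dj == 0) next
      if (di * di + dj * dj > R * R) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > H || jj < 1 || jj > W) next
      wij <- w[ii, jj]
      if (wij <= 0) next
      res <- res + wij * exp(2i * atan2(-di, dj))
      sw <- sw + wij
    }
    if (sw < 1e-9) next
    defined[i, j] <- TRUE
    theta[i, j] <- ((Arg(res) %% (2 * pi)) / 2 * 180 / pi) %% 180
    cert[i, j] <- min(1, Mod(res) / sw)
  }
  list(theta_deg = theta, certainty = cert, defined = defined)
}

# Direct circular-statistics computation on doubled angles (degrees in,
# mean resultant length out).
doubled_angle_resultant <- function(theta_deg) {
  Mod(mean(exp(2i * theta_deg * pi / 180)))
}

# Rotate a trichrome image counterclockwise by k * 90 degrees.
rotate_image <- function(image, k) {
  rot1 <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  px <- image$pixels
  for (i in seq_len(k %% 4)) {
    px <- {
      out <- array(0, dim = c(dim(px)[2], dim(px)[1], 3))
      for (ch in 1:3) out[, , ch] <- rot1(px[, , ch])
      out
    }
  }
  trichrome_image(px, image$pixel_size_um)
}

# Axis-angle difference between two axial orientations in degrees.
axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Small five-region layout for section-phantom tests (boxes of side `side`).
small_layout <- function(side = 96) {
  gap <- 16
  xs <- gap + (0:4) * (side + gap)
  region_layout(scar = region_box(xs[3], gap, side),
                LD = c(xs[1], gap), LP = c(xs[2], gap),
                RP = c(xs[4], gap), RD = c(xs[5], gap),
                box_side = side)
}

small_section_specs <- function(side = 96, scar_kappa = 0, flank_kappa = 5,
                                density = 0.35, seed = 1) {
  mk <- function(kappa, off) phantom_spec(
    image_height_px = side, image_width_px = side, n_fibers = 3000,
    kappa = kappa, mean_orientation_deg = 30, target_density = density,
    fiber_thickness_px = 2, fiber_length_px = 24, seed = seed + off)
  list(S = mk(scar_kappa, 0), LD = mk(flank_kappa, 1), LP = mk(flank_kappa, 2),
       RP = mk(flank_kappa, 3), RD = mk(flank_kappa, 4))
}
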