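#' Analysis regions and the standard five-region layout
#'
#' Fiber metrics are evaluated over named regions of a section image: the scar
#' zone `S` plus four square flanking boxes — left/right distant (`LD`, `RD`)
#' and left/right proximal (`LP`, `RP`). Boxes are axis-aligned squares of a
#' common side (500 px in the standard layout); the scar region may be a box
#' or an arbitrary polygon.
#'
#' Coordinates are 0-based pixel units with `x` along columns and `y` along
#' rows; boxes are half-open (`x0 <= x < x0 + side`).
#'
#' @param x0,y0 top-left corner of a box, 0-based pixels.
#' @param side box side in pixels.
#' @param xy two-column matrix of polygon vertices (x, y), 0-based pixels;
#'   the polygon is implicitly closed.
#' @return a `region` object (list with a `type` field).
#' @export
region_box <- function(x0, y0, side) {
  stopifnot(side >= 1)
  structure(list(type = "box", x0 = as.numeric(x0), y0 = as.numeric(y0),
                 width = as.numeric(side), height = as.numeric(side)),
            class = "region")
}

#' @rdname region_box
#' @param width,height box dimensions for a non-square rectangle.
#' @export
region_rect <- function(x0, y0, width, height) {
  stopifnot(width >= 1, height >= 1)
  structure(list(type = "box", x0 = as.numeric(x0), y0 = as.numeric(y0),
                 width = as.numeric(width), height = as.numeric(height)),
            class = "region")
}

#' @rdname region_box
#' @export
region_polygon <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3L) stop("a polygon region needs at least 3 vertices")
  structure(list(type = "polygon", xy = xy), class = "region")
}

# Logical H x W membership mask for a region (internal).
region_mask <- function(region, H, W) {
  if (is.null(region)) return(matrix(TRUE, H, W))
  stopifnot(inherits(region, "region"))
  if (region$type == "box") {
    m <- matrix(FALSE, H, W)
    rows <- seq.int(floor(region$y0) + 1L, floor(region$y0 + region$height))
    cols <- seq.int(floor(region$x0) + 1L, floor(region$x0 + region$width))
    if (min(rows) < 1L || max(rows) > H || min(cols) < 1L || max(cols) > W)
      stop("box region exceeds image bounds")
    m[rows, cols] <- TRUE
    m
  } else {
    px <- rep(seq_len(W) - 1L, each = H)   # x at pixel centers (0-based)
    py <- rep(seq_len(H) - 1L, times = W)  # y
    matrix(points_in_polygon(px, py, region$xy), H, W)
  }
}

# Even-odd rule point-in-polygon test, vectorized over points (internal).
points_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]; xj <- xy[j, 1]; yj <- xy[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' @rdname region_box
#' @param scar `region` for the scar zone `S`.
#' @param LD,LP,RD,RP top-left `c(x0, y0)` anchors of the four flanking boxes.
#' @param box_side side of the flanking boxes in pixels (standard layout:
#'   500 px).
#' @export
region_layout <- function(scar, LD, LP, RP, RD, box_side = 500) {
  stopifnot(inherits(scar, "region"))
  boxes <- list(LD = LD, LP = LP, RP = RP, RD = RD)
  regs <- lapply(boxes, function(a) region_box(a[1], a[2], box_side))
  # pairwise non-overlap of the four boxes
  nm <- names(regs)
  for (i in seq_along(regs)) for (j in seq_along(regs)) {
    if (i >= j) next
    a <- regs[[i]]; b <- regs[[j]]
    if (a$x0 < b$x0 + b$width && b$x0 < a$x0 + a$width &&
        a$y0 < b$y0 + b$height && b$y0 < a$y0 + a$height)
      stop(sprintf("boxes %s and %s overlap", nm[i], nm[j]))
  }
  structure(c(list(S = scar), regs, list(box_side = box_side)),
            class = "region_layout")
}

#' @export
print.region_layout <- function(x, ...) {
  cat(sprintf("region_layout: scar (%s) + 4 boxes of side %g px\n",
              x$S$type, x$box_side))
  invisible(x)
}

layout_regions <- function(layout) layout[c("S", "LD", "LP", "RP", "RD")]
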