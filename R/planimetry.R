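#' Calibrated polygon area from a wound photograph annotation
#'
#' Shoelace area of a pixel-coordinate polygon converted to mm2 with the
#' pixels-per-mm calibration taken from the millimetre scale photographed
#' next to the wound. Orientation-independent; the polygon is implicitly
#' closed; self-intersecting polygons are rejected.
#'
#' @param vertices two-column matrix (x, y) of at least 3 pixel vertices.
#' @param pixels_per_mm positive calibration factor.
#' @return area in mm2.
#' @examples
#' polygon_area(rbind(c(0, 0), c(4, 0), c(0, 3)), pixels_per_mm = 1)  # 6
#' @export
polygon_area <- function(vertices, pixels_per_mm) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3) stop("polygon needs at least 3 vertices")
  if (pixels_per_mm <= 0) stop("calibration must be positive")
  if (polygon_self_intersects(v)) stop("self-intersecting polygon")
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2 / pixels_per_mm^2
}

# Segment-crossing test for non-adjacent polygon edges (internal).
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- function(i) list(a = v[i, ], b = v[i %% n + 1, ])
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  intersects <- function(p, q) {
    d1 <- cross(q$a, q$b, p$a); d2 <- cross(q$a, q$b, p$b)
    d3 <- cross(p$a, p$b, q$a); d4 <- cross(p$a, p$b, q$b)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  if (n <= 3) return(FALSE)
  for (i in seq_len(n - 2)) for (j in (i + 2):n) {
    if (i == 1 && j == n) next  # adjacent through closure
    if (intersects(seg(i), seg(j))) return(TRUE)
  }
  FALSE
}

#' Calibrated polyline length
#'
#' Sum of Euclidean segment lengths of a pixel-coordinate polyline divided by
#' the pixels-per-mm calibration.
#'
#' @param points two-column matrix (x, y) of at least 2 pixel points.
#' @inheritParams polygon_area
#' @return length in mm.
#' @examples
#' polyline_length(rbind(c(0, 0), c(30, 0)), pixels_per_mm = 10)  # 3
#' @export
polyline_length <- function(points, pixels_per_mm) {
  p <- as.matrix(points)
  if (nrow(p) < 2) stop("polyline needs at least 2 points")
  if (pixels_per_mm <= 0) stop("calibration must be positive")
  d <- diff(p)
  sum(sqrt(rowSums(d^2))) / pixels_per_mm
}

#' Scar annotation of one wound photograph
#'
#' Replicated manual annotations of one wound at one day: up to 3 area
#' polygons, up to 3 length polylines, and width segments (up to 3 per
#' region, regions rostral/central/caudal of the scar), plus the
#' pixels-per-mm calibration.
#'
#' @param area_polygons list of vertex matrices (1-3 replicates).
#' @param length_polylines list of point matrices (1-3 replicates).
#' @param width_segments list of 2x2 point matrices (segment endpoints), up
#'   to 9 (3 regions x 3 replicates).
#' @param pixels_per_mm positive calibration.
#' @param animal,wound_site,group,day record metadata; `day` must be one of
#'   the standard observation days ([observation_days()]).
#' @return a `scar_annotation` object.
#' @export
scar_annotation <- function(area_polygons, length_polylines, width_segments,
                            pixels_per_mm, animal = "a1",
                            wound_site = "central", group = "CONT", day = 1) {
  if (length(area_polygons) < 1 || length(length_polylines) < 1 ||
      length(width_segments) < 1) stop("annotation needs replicates")
  if (length(area_polygons) > 3 || length(length_polylines) > 3 ||
      length(width_segments) > 9) stop("too many replicates")
  if (!day %in% observation_days()) stop("day not in the observation schedule")
  structure(list(area_polygons = area_polygons,
                 length_polylines = length_polylines,
                 width_segments = width_segments,
                 pixels_per_mm = pixels_per_mm, animal = animal,
                 wound_site = wound_site, group = group, day = day),
            class = "scar_annotation")
}

#' Summarize a wound annotation into a planimetry record
#'
#' Area is the mean of the replicate polygon areas, length the mean of the
#' replicate polyline lengths, and width the equal-weight mean of all width
#' segments (all 9 when 3 regions x 3 replicates are present).
#'
#' @param annotation a [scar_annotation()].
#' @return one-row data.frame with columns `animal`, `wound_site`, `group`,
#'   `day`, `area_mm2`, `length_mm`, `width_mm`.
#' @export
summarize_wound <- function(annotation) {
  stopifnot(inherits(annotation, "scar_annotation"))
  ppm <- annotation$pixels_per_mm
  data.frame(
    animal = annotation$animal, wound_site = annotation$wound_site,
    group = annotation$group, day = annotation$day,
    area_mm2 = mean(vapply(annotation$area_polygons, polygon_area,
                           numeric(1), pixels_per_mm = ppm)),
    length_mm = mean(vapply(annotation$length_polylines, polyline_length,
                            numeric(1), pixels_per_mm = ppm)),
    width_mm = mean(vapply(annotation$width_segments, polyline_length,
                           numeric(1), pixels_per_mm = ppm)))
}

#' Group-by-day planimetry summary table
#'
#' Mean and SD of scar area, length, and width per group and observation day,
#' the summary fed to the group-comparison pipeline.
#'
#' @param records data.frame of planimetry records (as produced by
#'   [summarize_wound()] or [generate_scar_timeseries()]).
#' @return data.frame with one row per group x day and mean/sd/n columns for
#'   each measure (SD is `NA` for singleton cells).
#' @export
build_timeseries <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop("no planimetry records")
  agg <- function(var) {
    a <- stats::aggregate(records[[var]],
                          by = records[c("group", "day")],
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
    out <- data.frame(a[c("group", "day")], a$x)
    names(out)[3:5] <- paste0(var, c("_mean", "_sd", "_n"))
    out
  }
  out <- Reduce(function(a, b) merge(a, b, by = c("group", "day")),
                lapply(c("area_mm2", "length_mm", "width_mm"), agg))
  out[order(out$group, out$day), ]
}
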