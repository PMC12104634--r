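#' Define the three operating-table zones
#'
#' The activity classifier tests three pose subsets against three annotated
#' image areas around the operating table: both wrists must lie in the wrist
#' (table) zone, both shoulders in the shoulder zone and the head centroid in
#' the head zone. Zones are simple polygons in image-pixel coordinates
#' (origin top-left, y downward) annotated once per camera viewpoint; in
#' practice they are drawn as nested areas so that the shoulder and head
#' constraints reject passers-by whose wrist alone crosses the table area.
#'
#' @param wrist_zone,shoulder_zone,head_zone A polygon: a data frame or
#'   2-column matrix of vertex `x`/`y` pixel coordinates (>= 3 vertices,
#'   non-self-intersecting, positive area). The closing edge is implicit.
#' @param camera_id Label of the camera viewpoint the zones were annotated on.
#' @return A `zone_set` object (list of three polygon tibbles + camera id).
#' @export
#' @examples
#' z <- zone_set(
#'   wrist_zone    = data.frame(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100)),
#'   shoulder_zone = data.frame(x = c(-40, 140, 140, -40), y = c(-40, -40, 140, 140)),
#'   head_zone     = data.frame(x = c(-80, 180, 180, -80), y = c(-80, -80, 180, 180))
#' )
#' zone_area(z$wrist_zone)
zone_set <- function(wrist_zone, shoulder_zone, head_zone, camera_id = "cam1") {
  zs <- list(
    wrist_zone = as_polygon(wrist_zone, "wrist_zone"),
    shoulder_zone = as_polygon(shoulder_zone, "shoulder_zone"),
    head_zone = as_polygon(head_zone, "head_zone"),
    camera_id = as.character(camera_id)
  )
  structure(zs, class = "zone_set")
}

#' @export
print.zone_set <- function(x, ...) {
  cat("<zone_set> camera:", x$camera_id, "\n")
  for (nm in c("wrist_zone", "shoulder_zone", "head_zone")) {
    cat(sprintf(
      "  %-13s %d vertices, area %.0f px^2\n",
      nm, nrow(x[[nm]]), zone_area(x[[nm]])
    ))
  }
  invisible(x)
}

as_polygon <- function(p, name) {
  if (is.matrix(p)) p <- as.data.frame(p)
  if (!is.data.frame(p)) abort(sprintf("`%s` must be a data frame or matrix", name))
  if (is.null(names(p)) || !all(c("x", "y") %in% names(p))) {
    if (ncol(p) == 2L) names(p) <- c("x", "y") else {
      abort(sprintf("`%s` must have columns x and y", name))
    }
  }
  p <- as_tibble(p[, c("x", "y")])
  if (nrow(p) < 3L) abort(sprintf("`%s`: a zone polygon needs >= 3 vertices", name))
  if (any(!is.finite(p$x)) || any(!is.finite(p$y))) {
    abort(sprintf("`%s`: polygon vertices must be finite", name))
  }
  # drop a repeated closing vertex if supplied
  nr <- nrow(p)
  if (p$x[1] == p$x[nr] && p$y[1] == p$y[nr]) p <- p[-nr, , drop = FALSE]
  if (nrow(p) < 3L) abort(sprintf("`%s`: a zone polygon needs >= 3 vertices", name))
  if (polygon_self_intersects(p)) {
    abort(sprintf("`%s`: polygon is self-intersecting", name))
  }
  if (abs(zone_area(p)) < .Machine$double.eps) {
    abort(sprintf("`%s`: polygon has zero area", name))
  }
  p
}

#' Polygon area (shoelace formula)
#'
#' @param poly Polygon tibble with columns `x`, `y`.
#' @return Absolute area in square pixels.
#' @export
zone_area <- function(poly) {
  x <- poly$x
  y <- poly$y
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# proper-crossing test between non-adjacent edges; shared endpoints allowed
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  seg <- cbind(p$x, p$y, p$x[c(2:n, 1)], p$y[c(2:n, 1)])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (adjacent) next
      d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Point-in-zone membership test
#'
#' Vectorised point-in-polygon with the polygon boundary counted as inside,
#' which keeps the classifier deterministic for points exactly on a zone edge.
#'
#' @param x,y Numeric vectors of pixel coordinates.
#' @param poly Polygon tibble (one element of a [zone_set()]).
#' @return Logical vector.
#' @export
point_in_zone <- function(x, y, poly) {
  if (length(x) == 0L) return(logical(0))
  pracma::inpolygon(x, y, poly$x, poly$y, boundary = TRUE)
}

#' Default zone annotation used by the scene simulator
#'
#' Three nested axis-aligned rectangles around a table at the centre of a
#' nominal 1280x720 view: the wrist (table) area, a wider shoulder area and a
#' widest head area. Staff simulated as "active" stand with their shoulders
#' in the ring between the wrist and shoulder rectangles, wrists reaching
#' into the table area.
#'
#' @param camera_id Camera label.
#' @return A [zone_set()].
#' @export
default_zone_set <- function(camera_id = "cam1") {
  rect <- function(x0, x1, y0, y1) {
    tibble(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  }
  zone_set(
    wrist_zone = rect(540, 740, 280, 440),
    shoulder_zone = rect(480, 800, 220, 500),
    head_zone = rect(420, 860, 160, 560),
    camera_id = camera_id
  )
}
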