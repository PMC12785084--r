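# Exact planar geometry primitives used by the synthetic-tissue ground truth
# and by the exact-geometry counting mode of the stereology module.

#' Area of a disk clipped to an axis-aligned rectangle
#'
#' Computes the exact area of the intersection between the disk of radius `r`
#' centred at `(cx, cy)` and the rectangle `[x0, x1] x [y0, y1]`, by
#' inclusion-exclusion over the closed-form quadrant integral of the circle.
#' Used to clip tubule and cell profiles to the field of view when computing
#' analytic area fractions.
#'
#' @param cx,cy Disk centre.
#' @param r Disk radius (> 0).
#' @param x0,y0,x1,y1 Rectangle corners with `x0 < x1`, `y0 < y1`.
#' @return Intersection area (same squared units as the inputs).
#' @examples
#' disk_rect_area(0.5, 0.5, 0.2, 0, 0, 1, 1)  # pi * 0.04, fully interior
#' @export
disk_rect_area <- function(cx, cy, r, x0, y0, x1, y1) {
  stopifnot(r > 0, x1 > x0, y1 > y0)
  f <- function(x, y) .disk_quadrant_area(x, y, r)
  f(x1 - cx, y1 - cy) - f(x0 - cx, y1 - cy) -
    f(x1 - cx, y0 - cy) + f(x0 - cx, y0 - cy)
}

# Area of {(X,Y): X^2+Y^2 <= r^2, X <= x, Y <= y} for a disk centred at the
# origin. Piecewise closed form; G() is the antiderivative of sqrt(r^2-X^2).
.disk_quadrant_area <- function(x, y, r) {
  if (x <= -r || y <= -r) return(0)
  x <- min(x, r)
  G <- function(X) 0.5 * (X * sqrt(pmax(r^2 - X^2, 0)) + r^2 * asin(pmax(-1, pmin(1, X / r))))
  if (y >= r) {
    # full vertical extent everywhere: integral of 2*sqrt(r^2-X^2)
    return(2 * (G(x) - G(-r)))
  }
  a <- sqrt(max(r^2 - y^2, 0))
  if (y >= 0) {
    # |X| < a: chord clipped at y (integrand sqrt + y); |X| >= a: full chord
    lo <- -r; hi <- x
    area <- 0
    seg1_hi <- min(hi, -a)
    if (seg1_hi > lo) area <- area + 2 * (G(seg1_hi) - G(lo))
    seg2_lo <- max(lo, -a); seg2_hi <- min(hi, a)
    if (seg2_hi > seg2_lo) {
      area <- area + (G(seg2_hi) - G(seg2_lo)) + y * (seg2_hi - seg2_lo)
    }
    seg3_lo <- max(lo, a)
    if (hi > seg3_lo) area <- area + 2 * (G(hi) - G(seg3_lo))
    area
  } else {
    # only |X| <= a contributes, with integrand sqrt(r^2-X^2) + y (>= 0 there)
    lo <- max(-r, -a); hi <- min(x, a)
    if (hi <= lo) return(0)
    (G(hi) - G(lo)) + y * (hi - lo)
  }
}

#' Arc length of a circle clipped to a rectangle
#'
#' Exact length of the part of the circle of radius `r` centred at `(cx, cy)`
#' lying inside `[x0, x1] x [y0, y1]`. Used for the boundary-length density
#' ground truth (clipped tubule perimeters).
#'
#' @inheritParams disk_rect_area
#' @return Arc length inside the rectangle.
#' @export
circle_rect_arclength <- function(cx, cy, r, x0, y0, x1, y1) {
  stopifnot(r > 0, x1 > x0, y1 > y0)
  # fully inside?
  if (cx - r >= x0 && cx + r <= x1 && cy - r >= y0 && cy + r <= y1) {
    return(2 * pi * r)
  }
  # candidate crossing angles with the four edge lines
  ang <- numeric(0)
  for (x in c(x0, x1)) {
    c_ <- (x - cx) / r
    if (abs(c_) <= 1) ang <- c(ang, acos(c_), -acos(c_))
  }
  for (y in c(y0, y1)) {
    s_ <- (y - cy) / r
    if (abs(s_) <= 1) ang <- c(ang, asin(s_), pi - asin(s_))
  }
  ang <- sort(unique(ang %% (2 * pi)))
  if (length(ang) == 0) {
    # no edge crossings: circle entirely inside or outside
    inside <- cx >= x0 && cx <= x1 && cy >= y0 && cy <= y1
    return(if (inside) 2 * pi * r else 0)
  }
  bounds <- c(ang, ang[1] + 2 * pi)
  total <- 0
  for (i in seq_along(ang)) {
    mid <- (bounds[i] + bounds[i + 1]) / 2
    px <- cx + r * cos(mid); py <- cy + r * sin(mid)
    if (px >= x0 && px <= x1 && py >= y0 && py <= y1) {
      total <- total + r * (bounds[i + 1] - bounds[i])
    }
  }
  total
}

#' Number of intersections between a segment and a circle
#'
#' Counts transversal crossings of the closed segment `p0 -> p1` with the
#' circle of radius `r` at `(cx, cy)`. Tangencies count once (a measure-zero
#' event under randomised grid translation; any consistent convention is
#' unbiased).
#'
#' @param p0x,p0y,p1x,p1y Segment end points.
#' @param cx,cy,r Circle centre and radius.
#' @return Integer 0, 1 or 2.
#' @export
segment_circle_intersections <- function(p0x, p0y, p1x, p1y, cx, cy, r) {
  dx <- p1x - p0x; dy <- p1y - p0y
  fx <- p0x - cx;  fy <- p0y - cy
  a <- dx * dx + dy * dy
  if (a == 0) return(0L)
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx * fx + fy * fy - r * r
  disc <- b * b - 4 * a * cc
  tol <- 1e-12 * max(a, 1)
  if (disc < -tol) return(0L)
  if (abs(disc) <= tol) {              # tangency
    t <- -b / (2 * a)
    return(if (t >= 0 && t <= 1) 1L else 0L)
  }
  sq <- sqrt(disc)
  t1 <- (-b - sq) / (2 * a)
  t2 <- (-b + sq) / (2 * a)
  sum(c(t1, t2) >= 0 & c(t1, t2) <= 1)
}

# Distance from a point to an axis-aligned rectangle (0 when inside).
.point_rect_distance <- function(px, py, x0, y0, x1, y1) {
  dx <- pmax(pmax(x0 - px, 0), px - x1)
  dy <- pmax(pmax(y0 - py, 0), py - y1)
  sqrt(dx^2 + dy^2)
}
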