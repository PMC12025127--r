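# Geometric primitives shared by the two gaze estimators: plane construction,
# ray/plane and ray/sphere intersection, angular error, and the pinhole
# back-projection used to lift 2D landmarks to the camera frame.
# Convention: right-handed camera frame, camera at the origin, lengths in cm.

#' Plane through three points
#'
#' Builds the target plane from three non-collinear points. The normal is
#' unit-norm with a deterministic sign: its z component is >= 0 (ties broken
#' by y >= 0, then x >= 0), so downstream intersection signs are stable.
#'
#' @param p1,p2,p3 Numeric length-3 points (cm).
#' @return A list with class `gaze_plane`: `point` (on the plane) and unit
#'   `normal`.
#' @export
#' @examples
#' plane_from_points(c(0, 0, -398.3), c(1, 0, -398.3), c(0, 1, -398.3))
plane_from_points <- function(p1, p2, p3) {
  p1 <- check_finite3(p1); p2 <- check_finite3(p2); p3 <- check_finite3(p3)
  n <- c(
    (p2[2] - p1[2]) * (p3[3] - p1[3]) - (p2[3] - p1[3]) * (p3[2] - p1[2]),
    (p2[3] - p1[3]) * (p3[1] - p1[1]) - (p2[1] - p1[1]) * (p3[3] - p1[3]),
    (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
  )
  scale <- max(vnorm(p2 - p1), vnorm(p3 - p1))
  if (scale == 0 || vnorm(n) < 1e-10 * scale^2) {
    abort("the three points are collinear or coincident", class = "rgbdgaze_degenerate")
  }
  n <- n / vnorm(n)
  flip <- if (abs(n[3]) > 1e-12) n[3] < 0 else if (abs(n[2]) > 1e-12) n[2] < 0 else n[1] < 0
  if (flip) n <- -n
  structure(list(point = p1, normal = n), class = "gaze_plane")
}

#' Ray-plane intersection
#'
#' Intersects the forward half-line (parameter t > 0) with a plane. Parallel
#' rays and intersections behind the origin are a no-hit, returned as `NULL`
#' rather than an error: a person cannot gaze backwards through their own
#' head.
#'
#' @param ray A [gaze_ray()].
#' @param plane A [plane_from_points()] result (or list with `point`,
#'   `normal`).
#' @return The intersection point (numeric length-3, cm), or `NULL` on
#'   no-hit.
#' @export
ray_plane_intersection <- function(ray, plane) {
  denom <- sum(ray$direction * plane$normal)
  if (abs(denom) < 1e-12) return(NULL)
  t <- sum((plane$point - ray$origin) * plane$normal) / denom
  if (t <= 0) return(NULL)
  ray$origin + t * ray$direction
}

#' Ray-sphere intersection
#'
#' Tests whether the forward half-line meets a sphere; tangency counts as a
#' hit. Used to decide whether one person's gaze lands on the sphere
#' enclosing another person's head.
#'
#' @param ray A [gaze_ray()].
#' @param center Sphere centre (numeric length-3, cm).
#' @param radius Sphere radius in cm, > 0.
#' @return A list: `hit` (logical) and `point` (nearest intersection, or
#'   `NULL` on miss).
#' @export
ray_sphere_hit <- function(ray, center, radius) {
  stopifnot(radius > 0)
  oc <- ray$origin - check_finite3(center, "center")
  b <- sum(ray$direction * oc)
  cc <- sum(oc * oc) - radius^2
  disc <- b^2 - cc
  if (disc < 0) return(list(hit = FALSE, point = NULL))
  sq <- sqrt(disc)
  t1 <- -b - sq
  t2 <- -b + sq
  t <- if (t1 > 0) t1 else if (t2 > 0) t2 else return(list(hit = FALSE, point = NULL))
  list(hit = TRUE, point = ray$origin + t * ray$direction)
}

#' Angular error between two directions, in degrees
#'
#' theta = arccos(v1 . v2 / (|v1||v2|)), the standard gaze-accuracy metric.
#' Scale-invariant in both arguments; the cosine is clamped to \[-1, 1\] to
#' absorb floating-point drift. Vectorized: matrices with one direction per
#' row give one angle per row.
#'
#' @param v1,v2 Numeric length-3 vectors, or n x 3 matrices.
#' @return Angle(s) in degrees, in \[0, 180\].
#' @export
#' @examples
#' angular_error(c(1, 0, 0), c(0, 1, 0)) # 90
angular_error <- function(v1, v2) {
  a <- as_row3(v1); b <- as_row3(v2)
  na <- row_norm(a); nb <- row_norm(b)
  if (any(na < 1e-12) || any(nb < 1e-12)) {
    abort("angular_error is undefined for zero vectors", class = "rgbdgaze_invalid_input")
  }
  cosang <- pmin(1, pmax(-1, row_dot(a, b) / (na * nb)))
  acos(cosang) * 180 / pi
}

#' Pinhole camera model
#'
#' Minimal intrinsics used to lift detected 2D landmarks into the 3D camera
#' frame when a depth value is available.
#'
#' @param fx,fy Focal lengths in pixels (> 0).
#' @param cx,cy Principal point in pixels.
#' @return A list with class `camera_model`.
#' @export
camera_model <- function(fx, fy, cx, cy) {
  stopifnot(fx > 0, fy > 0)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy), class = "camera_model")
}

#' Back-project a pixel with depth into the camera frame
#'
#' X = (u - cx) * depth / fx, Y = (v - cy) * depth / fy, Z = depth.
#' Vectorized over u, v, depth.
#'
#' @param u,v Pixel coordinates.
#' @param depth Depth in cm, > 0.
#' @param cam A [camera_model()].
#' @return Numeric length-3 point, or an n x 3 matrix for vector input.
#' @export
backproject <- function(u, v, depth, cam) {
  if (any(depth <= 0)) abort("depth must be > 0", class = "rgbdgaze_invalid_input")
  out <- unname(cbind((u - cam$cx) * depth / cam$fx, (v - cam$cy) * depth / cam$fy, depth))
  dimnames(out) <- NULL
  if (nrow(out) == 1) drop(out) else out
}

#' Project a camera-frame point to pixels
#'
#' Inverse of [backproject()]; exposed mainly for round-trip checks and for
#' preparing synthetic 2D landmark streams.
#'
#' @param p Numeric length-3 point with z > 0, or an n x 3 matrix.
#' @param cam A [camera_model()].
#' @return A list with vectors `u`, `v`, `depth`.
#' @export
project_point <- function(p, cam) {
  p <- as_row3(p)
  if (any(p[, 3] <= 0)) abort("can only project points with depth > 0", class = "rgbdgaze_invalid_input")
  list(u = p[, 1] * cam$fx / p[, 3] + cam$cx, v = p[, 2] * cam$fy / p[, 3] + cam$cy, depth = p[, 3])
}
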