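# Eye-centre gaze model. The eyeball is treated as a sphere; the two eye
# corners C1, C2 and a frontal surface point Oe' all lie on it. The circle
# through the three points gives the radius via the chord-sagitta relation
#   R = h/2 + c^2 / (8 h),   h = |Oe' - C|, c = |C1 - C2|, C = (C1 + C2)/2,
# and the centre lies on the line from Oe' through C at distance R. Gaze is
# the anatomical axis from the recovered centre through the iris centre.

#' Midpoint of the eye-corner chord
#'
#' @param c1,c2 The two eye-corner points (numeric length-3, cm).
#' @return The chord midpoint.
#' @export
chord_midpoint <- function(c1, c2) {
  c1 <- check_finite3(c1); c2 <- check_finite3(c2)
  if (vnorm(c1 - c2) < 1e-9) abort("eye corners coincide", class = "rgbdgaze_degenerate")
  (c1 + c2) / 2
}

#' Eyeball radius from corners and a frontal surface point
#'
#' Chord-sagitta relation: with chord length c = |C1 C2| and sagitta
#' h = |Oe' - C| (C the chord midpoint), the circle through the three points
#' has radius R = h/2 + c^2/(8h). Exact when Oe' sits on the perpendicular
#' at the chord midpoint; with noisy landmarks h is used as measured and the
#' approximation error shows up in the noise-sensitivity tests.
#'
#' @param c1,c2 Eye corners (cm).
#' @param surface Frontal eye-surface point Oe' (cm).
#' @return Radius in cm.
#' @export
eye_radius <- function(c1, c2, surface) {
  surface <- check_finite3(surface, "surface")
  mid <- chord_midpoint(c1, c2)
  h <- vnorm(surface - mid)
  if (h < 1e-6) abort("surface point collapsed onto the chord midpoint", class = "rgbdgaze_degenerate")
  cc <- vnorm(check_finite3(c1) - check_finite3(c2))
  h / 2 + cc^2 / (8 * h)
}

#' Eyeball centre from corners and a frontal surface point
#'
#' The centre lies on the line from the surface point Oe' through the chord
#' midpoint C, at distance R = [eye_radius()] from Oe'.
#'
#' @inheritParams eye_radius
#' @return A list with class `eye_geometry`: `center`, `radius`,
#'   `chord_midpoint`.
#' @export
eye_center <- function(c1, c2, surface) {
  r <- eye_radius(c1, c2, surface)
  surface <- check_finite3(surface, "surface")
  mid <- chord_midpoint(c1, c2)
  center <- surface + r * vunit(mid - surface)
  structure(list(center = center, radius = r, chord_midpoint = mid), class = "eye_geometry")
}

#' Anatomical-axis gaze ray of one eye
#'
#' The gaze proxy is the line from the eyeball centre through the iris
#' centre (anatomical axis; no kappa-angle correction).
#'
#' @param geom An [eye_center()] result.
#' @param iris_center Iris centre point (cm).
#' @return A [gaze_ray()] with origin at the eyeball centre.
#' @export
eye_gaze_ray <- function(geom, iris_center) {
  iris_center <- check_finite3(iris_center, "iris_center")
  d <- iris_center - geom$center
  if (vnorm(d) < 1e-9) abort("iris centre coincides with the eye centre", class = "rgbdgaze_degenerate")
  gaze_ray(geom$center, d)
}

#' Combine two monocular rays into one binocular gaze ray
#'
#' Origin is the midpoint of the two origins; direction is the normalized
#' sum of the two unit directions (the angular bisector).
#'
#' @param left,right [gaze_ray()]s for the two eyes.
#' @return A [gaze_ray()].
#' @export
binocular_gaze <- function(left, right) {
  d <- left$direction + right$direction
  if (vnorm(d) < 1e-9) abort("eye directions are antipodal", class = "rgbdgaze_degenerate")
  gaze_ray((left$origin + right$origin) / 2, d)
}
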