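# Head-orientation gaze from five skeletal face joints (right/left eye,
# nose, right/left ear), each with an Azure-Kinect-style confidence score in
# {0,1,2,3}. Joints scoring < 2 are treated as occluded and, when at least
# three well-detected joints remain, recovered by rigidly aligning the last
# fully-observed joint template onto the current frame (the five points are
# rigid on the skull). The gaze axis runs from the ear midpoint ME through
# the eyes+nose centroid MN; MN is the lower, more central face point, which
# compensates the upward eye-over-ear tilt.

JOINT_NAMES <- c("eye_r", "eye_l", "nose", "ear_r", "ear_l")

#' Is a skeletal joint well detected?
#'
#' Confidence semantics: 0 out of range, 1 occlusion-predicted, 2 moderate,
#' 3 high. Well detected means confidence >= 2. Vectorized.
#'
#' @param confidence Integer score(s) in 0..3.
#' @return Logical vector.
#' @export
joint_valid <- function(confidence) {
  stopifnot(all(confidence %in% 0:3))
  confidence >= 2
}

# Kabsch: least-squares rotation (det +1) + translation mapping rows of A
# onto rows of B. Returns NULL when the support is rank-deficient
# (collinear points leave a free rotation about the line).
kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- crossprod(A0, B0)
  sv <- svd(H)
  span <- svd(A0)$d
  if (span[2] < 1e-8 * max(span[1], 1e-12)) return(NULL)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = cb - as.numeric(R %*% ca))
}

#' Recover occluded face joints from a rigid template
#'
#' Aligns the template joints onto the currently valid ones with an
#' orthogonal least-squares (Kabsch) fit -- rotation with determinant +1
#' plus translation, no scaling -- and replaces invalid joints by their
#' transformed template positions. Valid joints pass through unchanged.
#'
#' @param template 5 x 3 matrix of joint positions (rows in the order
#'   eye_r, eye_l, nose, ear_r, ear_l) from the most recent frame where all
#'   five joints had confidence >= 2.
#' @param current 5 x 3 matrix of current joint positions (rows may be
#'   garbage where invalid).
#' @param valid Logical length-5: which current joints have confidence >= 2.
#' @return A list: `joints` (completed 5 x 3 matrix), `recovered` (logical
#'   length-5), or `NULL` when fewer than 3 valid joints remain or the valid
#'   support is collinear (recovery failed; the frame's head estimate is
#'   invalid).
#' @export
rigid_recover <- function(template, current, valid) {
  stopifnot(nrow(template) == 5, nrow(current) == 5, length(valid) == 5)
  if (all(valid)) return(list(joints = current, recovered = rep(FALSE, 5)))
  if (sum(valid) < 3) return(NULL)
  fit <- kabsch(template[valid, , drop = FALSE], current[valid, , drop = FALSE])
  if (is.null(fit)) return(NULL)
  moved <- sweep(template %*% t(fit$R), 2, fit$t, "+")
  out <- current
  out[!valid, ] <- moved[!valid, ]
  list(joints = out, recovered = !valid)
}

#' Ear midpoint and face centroid of a completed joint set
#'
#' ME is the midpoint of the two ear joints; MN the centroid of the two eye
#' joints and the nose.
#'
#' @param joints 5 x 3 matrix in the order eye_r, eye_l, nose, ear_r, ear_l.
#' @return A list with `me` and `mn` (numeric length-3, cm).
#' @export
head_centers <- function(joints) {
  stopifnot(nrow(joints) == 5)
  list(
    me = (joints[4, ] + joints[5, ]) / 2,
    mn = (joints[1, ] + joints[2, ] + joints[3, ]) / 3
  )
}

#' Head-orientation gaze ray
#'
#' Origin at the face centroid MN, direction along ME -> MN (out of the
#' face). Translation-invariant and rotation-equivariant.
#'
#' @inheritParams head_centers
#' @return A [gaze_ray()].
#' @export
head_gaze_ray <- function(joints) {
  ctr <- head_centers(joints)
  d <- ctr$mn - ctr$me
  if (vnorm(d) < 1e-9) abort("ear midpoint coincides with face centroid", class = "rgbdgaze_degenerate")
  gaze_ray(ctr$mn, d)
}
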