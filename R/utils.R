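# Row-wise vector algebra on n x 3 matrices. All pipeline math is expressed
# through these so that whole frame streams are processed without R-level
# loops.

as_row3 <- function(v) {
  if (is.matrix(v)) {
    stopifnot(ncol(v) == 3)
    v
  } else {
    stopifnot(length(v) == 3)
    matrix(as.numeric(v), ncol = 3)
  }
}

row_dot <- function(a, b) rowSums(a * b)

row_norm <- function(a) sqrt(rowSums(a * a))

row_unit <- function(a) {
  n <- row_norm(a)
  a / n
}

row_cross <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

# scalar helpers for the single-vector API
v3 <- function(x, y = NULL, z = NULL) {
  if (is.null(y)) as.numeric(x) else c(x, y, z)
}

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("cannot normalize a (near-)zero vector", class = "rgbdgaze_degenerate")
  v / n
}

check_finite3 <- function(v, what = "point") {
  if (length(v) != 3 || !all(is.finite(v))) {
    abort(paste0(what, " must be a finite length-3 numeric"), class = "rgbdgaze_invalid_input")
  }
  as.numeric(v)
}

#' Construct a gaze ray
#'
#' A ray is an origin point plus a unit direction; every gaze estimate in the
#' package is ultimately one of these.
#'
#' @param origin Numeric length-3 origin, in cm (camera frame).
#' @param direction Numeric length-3 direction; normalized internally.
#' @return A list with class `gaze_ray` and elements `origin`, `direction`
#'   (unit norm).
#' @export
#' @examples
#' gaze_ray(c(0, 0, 0), c(0, 0, -2))
gaze_ray <- function(origin, direction) {
  origin <- check_finite3(origin, "origin")
  direction <- check_finite3(direction, "direction")
  structure(list(origin = origin, direction = vunit(direction)), class = "gaze_ray")
}

#' @export
print.gaze_ray <- function(x, ...) {
  cat(sprintf(
    "<gaze_ray> origin (%.3f, %.3f, %.3f) cm, direction (%.4f, %.4f, %.4f)\n",
    x$origin[1], x$origin[2], x$origin[3],
    x$direction[1], x$direction[2], x$direction[3]
  ))
  invisible(x)
}
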