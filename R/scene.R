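# Scene configuration: the target plane, named targets on it, head spheres,
# and the distance gate that switches between the eye and head methods.

#' Default target-board layout
#'
#' Seven targets on a board parallel to the camera X-Y plane at Z =
#' -398.3 cm, the layout used throughout the package's worked examples.
#'
#' @return A tibble with columns `name`, `x`, `y`, `z` (cm).
#' @export
default_targets <- function() {
  tibble(
    name = paste0("target_", 1:7),
    x = c(603.5, 603.5, 603.5, 0, -576.5, -576.5, -576.5),
    y = c(427.3, 0, -432.7, -432.7, -432.7, 0, 432.7),
    z = rep(-398.3, 7)
  )
}

#' Default subject positions
#'
#' Five head positions in front of the camera, at depths 55-340 cm (the
#' range over which the distance gate trades the eye method for the head
#' method).
#'
#' @return A tibble with columns `position`, `x`, `y`, `z` (cm).
#' @export
default_positions <- function() {
  tibble(
    position = 1:5,
    x = c(0, 0, 76, -75, 0),
    y = rep(143, 5),
    z = c(55, 120, 194, 284, 340)
  )
}

#' Build a scene configuration
#'
#' @param plane_points 3 x 3 matrix (rows = points, cm) defining the target
#'   plane, or `NULL` for no plane. Default: three non-collinear default
#'   targets.
#' @param targets Tibble with `name`, `x`, `y`, `z`: named points on the
#'   plane used to label plane hits. Default [default_targets()].
#' @param spheres Tibble with `name`, `person`, `x`, `y`, `z`, `radius`
#'   describing head spheres. When `person` is non-`NA` the sphere centre
#'   follows that person's face centroid frame by frame; otherwise the
#'   fixed centre (`x`, `y`, `z`) is used. `NULL` for none.
#' @param gate_cm Gating depth in cm: at or below it the eye method is
#'   preferred, above it the head method. Default 70.
#' @return A list with class `scene_config`.
#' @export
scene_config <- function(plane_points = NULL, targets = default_targets(),
                         spheres = NULL, gate_cm = 70) {
  stopifnot(gate_cm > 0)
  if (is.null(plane_points)) {
    tg <- default_targets()
    plane_points <- as.matrix(tg[c(1, 2, 4), c("x", "y", "z")])
  }
  plane <- if (is.matrix(plane_points)) {
    plane_from_points(plane_points[1, ], plane_points[2, ], plane_points[3, ])
  } else {
    NULL
  }
  if (!is.null(spheres)) {
    stopifnot(all(c("name", "radius") %in% names(spheres)), all(spheres$radius > 0))
    if (!"person" %in% names(spheres)) spheres$person <- NA_character_
    for (col in c("x", "y", "z")) if (!col %in% names(spheres)) spheres[[col]] <- NA_real_
  }
  structure(
    list(plane_points = plane_points, plane = plane, targets = targets,
         spheres = spheres, gate_cm = gate_cm),
    class = "scene_config"
  )
}

#' Head sphere following a person
#'
#' Convenience row for [scene_config()]'s `spheres`: a sphere of the given
#' radius centred on `person`'s face centroid in every frame.
#'
#' @param name Sphere name (becomes the `hit_<name>` column).
#' @param person Person id whose face centroid is tracked.
#' @param radius Radius in cm (default 12, an enclosing head sphere).
#' @return One-row tibble.
#' @export
head_sphere <- function(name, person, radius = 12) {
  tibble(name = name, person = person, x = NA_real_, y = NA_real_, z = NA_real_, radius = radius)
}

#' Read / write a scene configuration as YAML
#'
#' Keys: `plane_points` (list of three xyz triples), `targets`, `spheres`,
#' `gate_cm`.
#'
#' @param path File path.
#' @return [read_scene_config()] returns a `scene_config`;
#'   `write_scene_config()` returns `path` invisibly.
#' @export
read_scene_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pp <- if (!is.null(cfg$plane_points)) do.call(rbind, lapply(cfg$plane_points, as.numeric)) else NULL
  tg <- if (!is.null(cfg$targets)) dplyr::bind_rows(lapply(cfg$targets, as_tibble)) else default_targets()
  sp <- if (!is.null(cfg$spheres)) dplyr::bind_rows(lapply(cfg$spheres, \(s) {
    tibble(
      name = s$name, person = s$person %||% NA_character_,
      x = as.numeric(s$x %||% NA), y = as.numeric(s$y %||% NA), z = as.numeric(s$z %||% NA),
      radius = as.numeric(s$radius)
    )
  })) else NULL
  scene_config(plane_points = pp, targets = tg, spheres = sp, gate_cm = cfg$gate_cm %||% 70)
}

#' @rdname read_scene_config
#' @param scene A `scene_config`.
#' @export
write_scene_config <- function(scene, path) {
  out <- list(
    plane_points = if (!is.null(scene$plane_points)) apply(scene$plane_points, 1, as.numeric, simplify = FALSE),
    targets = purrr::transpose(as.list(scene$targets)),
    spheres = if (!is.null(scene$spheres)) purrr::transpose(as.list(scene$spheres)),
    gate_cm = scene$gate_cm
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
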