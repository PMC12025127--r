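# Synthetic frame streams with known ground truth: single-subject
# target-board sessions and two-person interaction sessions with scripted
# gaze schedules. The generator emulates a 30 FPS fused RGB-D skeleton
# stream: five face joints per person with confidence scores, optional
# per-eye landmark sets, Gaussian landmark noise, and random confidence
# dropouts. Head joints are a rigid template rotated so the ME -> MN axis
# points at the scripted gaze target; eye corners are fixed in the head
# frame while the iris follows gaze, so the eye and head methods can
# disagree under eye-in-head rotation.

#' Default rigid head-joint template
#'
#' Anatomically plausible joint offsets (cm) relative to the head centre,
#' rows in the order eye_r, eye_l, nose, ear_r, ear_l; forward is -z.
#'
#' @return A 5 x 3 matrix.
#' @export
default_head_template <- function() {
  m <- rbind(
    eye_r = c(-3, 0, -8),
    eye_l = c(3, 0, -8),
    nose  = c(0, -4, -10),
    ear_r = c(-7, 1, 0),
    ear_l = c(7, 1, 0)
  )
  colnames(m) <- c("x", "y", "z")
  m
}

#' Synthetic-stream configuration
#'
#' @param fps Frames per second (default 30, the recording rate the
#'   pipeline is designed for).
#' @param duration_s Stream duration in seconds.
#' @param eyeball_radius Eyeball radius in cm (default 1.2, adult average).
#' @param corner_half_angle Angular offset of each eye corner from the
#'   head-forward axis on the eyeball sphere, degrees (default 40).
#' @param head_template 5 x 3 joint-offset matrix ([default_head_template()]).
#' @param noise_sd Gaussian landmark noise sigma in cm per coordinate
#'   (default 0).
#' @param dropout_prob Probability that a joint is demoted to confidence 1
#'   (occlusion-predicted) in a frame (default 0).
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @return A list with class `synthetic_config`.
#' @export
synthetic_config <- function(fps = 30, duration_s = 10, eyeball_radius = 1.2,
                             corner_half_angle = 40,
                             head_template = default_head_template(),
                             noise_sd = 0, dropout_prob = 0, seed = NULL) {
  stopifnot(fps > 0, duration_s > 0, eyeball_radius > 0,
            corner_half_angle > 0, corner_half_angle < 90,
            noise_sd >= 0, dropout_prob >= 0, dropout_prob <= 1)
  structure(
    list(fps = fps, duration_s = duration_s, eyeball_radius = eyeball_radius,
         corner_half_angle = corner_half_angle, head_template = head_template,
         noise_sd = noise_sd, dropout_prob = dropout_prob, seed = seed),
    class = "synthetic_config"
  )
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Rodrigues rotation taking unit vector a onto unit vector b.
rotation_between <- function(a, b) {
  a <- vunit(a); b <- vunit(b)
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  s <- vnorm(v)
  cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antipodal: rotate pi about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- vunit(p - sum(p * a) * a)
    return(2 * outer(ax, ax) - diag(3))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

# Joint positions for a head whose face centroid sits at `pos` with the
# ME -> MN axis aimed at `look_at`. Returns the 5 x 3 world-frame joints
# plus the head-forward and head-right unit axes.
posed_head <- function(template, pos, look_at) {
  me0 <- (template[4, ] + template[5, ]) / 2
  mn0 <- colMeans(template[1:3, , drop = FALSE])
  f0 <- vunit(mn0 - me0)
  f <- vunit(look_at - pos)
  R <- rotation_between(f0, f)
  joints <- sweep(template, 2, mn0) %*% t(R)
  joints <- sweep(joints, 2, pos, "+")
  list(joints = joints, forward = f, right = as.numeric(R %*% c(1, 0, 0)))
}

resolve_point <- function(x, table, idcol) {
  if (length(x) == 1 && is.numeric(x)) {
    row <- table[table[[idcol]] == x | seq_len(nrow(table)) == x, ][1, ]
    c(row$x, row$y, row$z)
  } else {
    check_finite3(x)
  }
}

# Replicates one posed person over n frames, adds landmark noise and
# confidence dropouts, and returns the frame rows as a tibble.
emit_frames <- function(t, person, joints_per_frame, eye_list, cfg) {
  n <- length(t)
  out <- tibble(t = t, person = person)
  for (k in seq_along(JOINT_NAMES)) {
    J <- joints_per_frame[[k]]  # n x 3
    if (cfg$noise_sd > 0) J <- J + matrix(rnorm(3 * n, 0, cfg$noise_sd), n, 3)
    conf <- rep(3L, n)
    if (cfg$dropout_prob > 0) conf[runif(n) < cfg$dropout_prob] <- 1L
    out[[paste0(JOINT_NAMES[k], "_x")]] <- J[, 1]
    out[[paste0(JOINT_NAMES[k], "_y")]] <- J[, 2]
    out[[paste0(JOINT_NAMES[k], "_z")]] <- J[, 3]
    out[[paste0(JOINT_NAMES[k], "_conf")]] <- conf
  }
  out$has_eyes <- !is.null(eye_list)
  if (!is.null(eye_list)) {
    for (nm in names(eye_list)) {
      P <- eye_list[[nm]]  # n x 3
      if (cfg$noise_sd > 0) P <- P + matrix(rnorm(3 * n, 0, cfg$noise_sd), n, 3)
      out[[paste0(nm, "_x")]] <- P[, 1]
      out[[paste0(nm, "_y")]] <- P[, 2]
      out[[paste0(nm, "_z")]] <- P[, 3]
    }
  } else {
    for (col in frame_eye_cols()) out[[col]] <- NA_real_
  }
  out[, c("t", "person", frame_joint_cols(), "has_eyes", frame_eye_cols())]
}

#' Simulate a single-subject target-board session
#'
#' The subject's face centroid sits at one of the five default positions
#' (or an explicit point) with the head aimed at the requested board
#' target. Eyeball centres coincide with the skeletal eye joints; corners
#' sit at +/- the configured half-angle from the head-forward axis on the
#' eyeball sphere, the surface point Oe' on the head-forward axis, and the
#' iris at Oe + r g for the shared true gaze direction g from the mid-eye
#' point to the target.
#'
#' @param config A [synthetic_config()].
#' @param position Position index 1-5 ([default_positions()]) or a length-3
#'   point (cm).
#' @param target Target index 1-7 ([default_targets()]) or a length-3 point
#'   (cm).
#' @param person Person id for the emitted frames.
#' @return A list: `frames` (frames tibble) and `truth` (tibble with the
#'   per-frame true gaze: `gaze_dir_{x,y,z}` from the mid-eye point
#'   `eye_origin_*` (drives the irises), `head_dir_{x,y,z}` from the face
#'   centroid `head_origin_*`, and the fixated `target_*` coordinates).
#' @export
simulate_board_session <- function(config = synthetic_config(), position = 1,
                                   target = 4, person = "subject") {
  pos_tbl <- dplyr::rename(default_positions(), name = "position")
  P <- resolve_point(position, pos_tbl, "name")
  tg <- default_targets()
  tg$idx <- seq_len(nrow(tg))
  Tg <- if (length(target) == 1 && is.numeric(target)) {
    c(tg$x[target], tg$y[target], tg$z[target])
  } else {
    check_finite3(target)
  }
  if (vnorm(Tg - P) < 1e-6) abort("target coincides with the subject", class = "rgbdgaze_degenerate")

  ph <- posed_head(config$head_template, P, Tg)
  r <- config$eyeball_radius
  alpha <- config$corner_half_angle * pi / 180
  oe_r <- ph$joints[1, ]; oe_l <- ph$joints[2, ]
  m <- (oe_r + oe_l) / 2
  g <- vunit(Tg - m)
  f <- ph$forward; u <- ph$right
  corner1 <- function(oe) oe + r * (cos(alpha) * f + sin(alpha) * u)
  corner2 <- function(oe) oe + r * (cos(alpha) * f - sin(alpha) * u)
  eye_pts <- list(
    eyer_c1 = corner1(oe_r), eyer_c2 = corner2(oe_r),
    eyer_surf = oe_r + r * f, eyer_iris = oe_r + r * g,
    eyel_c1 = corner1(oe_l), eyel_c2 = corner2(oe_l),
    eyel_surf = oe_l + r * f, eyel_iris = oe_l + r * g
  )

  n <- round(config$fps * config$duration_s)
  t <- (seq_len(n) - 1) / config$fps
  rep_mat <- function(v) matrix(v, n, 3, byrow = TRUE)
  frames <- with_seed(config$seed, emit_frames(
    t, person,
    lapply(seq_len(5), function(k) rep_mat(ph$joints[k, ])),
    lapply(eye_pts, rep_mat),
    config
  ))
  truth <- tibble(
    t = t, person = person,
    target_x = Tg[1], target_y = Tg[2], target_z = Tg[3],
    gaze_dir_x = g[1], gaze_dir_y = g[2], gaze_dir_z = g[3],
    eye_origin_x = m[1], eye_origin_y = m[2], eye_origin_z = m[3],
    head_dir_x = f[1], head_dir_y = f[2], head_dir_z = f[3],
    head_origin_x = P[1], head_origin_y = P[2], head_origin_z = P[3]
  )
  list(frames = frames, truth = truth)
}

#' Simulate a two-person interaction session
#'
#' Two people at fixed positions. During each person's scheduled intervals
#' (closed `[start_s, end_s]`, whole seconds) their head is aimed at the
#' other person's face centroid; otherwise at their own away-point
#' (`position + away_offset`). Confidence dropouts and landmark noise as
#' configured; eye landmarks are not emitted (at interaction distances the
#' pipeline uses the head method).
#'
#' @param config A [synthetic_config()] (`duration_s` sets the timeline).
#' @param schedule_a Periods tibble (`start_s`, `end_s`) when person A
#'   gazes at person B.
#' @param schedule_b Periods for B gazing at A (default: none).
#' @param positions Named list of the two positions, e.g.
#'   `list(p1 = c(-60, 143, 150), p2 = c(60, 143, 150))` (cm).
#' @param away_offset Offset from each position to that person's away-point
#'   (cm); the default points well clear of the partner.
#' @return A list: `frames`, `truth` (per-frame gaze state per person), and
#'   `scene` (a [scene_config()] with one tracked head sphere per person,
#'   radius 12 cm).
#' @export
simulate_interaction <- function(config = synthetic_config(duration_s = 60),
                                 schedule_a,
                                 schedule_b = period_tbl(integer(0), integer(0)),
                                 positions = list(p1 = c(-60, 143, 150),
                                                  p2 = c(60, 143, 150)),
                                 away_offset = c(0, 0, 300)) {
  stopifnot(length(positions) == 2, !is.null(names(positions)))
  ids <- names(positions)
  dur <- config$duration_s
  check_sched <- function(s, who) {
    s <- check_period_list(s, who)
    if (nrow(s) > 0 && (min(s$start_s) < 0 || max(s$end_s) > dur)) {
      abort(paste0(who, " schedule falls outside the session duration"),
            class = "rgbdgaze_invalid_input")
    }
    s
  }
  scheds <- list(check_sched(schedule_a, ids[1]), check_sched(schedule_b, ids[2]))

  n <- round(config$fps * dur)
  t <- (seq_len(n) - 1) / config$fps
  sec <- floor(t)
  blocks <- with_seed(config$seed, {
    lapply(1:2, function(i) {
      me <- check_finite3(positions[[i]]); other <- check_finite3(positions[[3 - i]])
      gaze <- posed_head(config$head_template, me, other)$joints
      away <- posed_head(config$head_template, me, me + away_offset)$joints
      s <- scheds[[i]]
      on <- rep(FALSE, n)
      for (k in seq_len(nrow(s))) on <- on | (sec >= s$start_s[k] & sec <= s$end_s[k])
      joints <- lapply(seq_len(5), function(j) {
        ifelse(matrix(on, n, 3), 1, 0) * matrix(gaze[j, ], n, 3, byrow = TRUE) +
          ifelse(matrix(on, n, 3), 0, 1) * matrix(away[j, ], n, 3, byrow = TRUE)
      })
      list(frames = emit_frames(t, ids[i], joints, NULL, config),
           state = tibble(t = t, person = ids[i], gazing = on))
    })
  })
  spheres <- dplyr::bind_rows(
    head_sphere(paste0(ids[1], "_head"), ids[1]),
    head_sphere(paste0(ids[2], "_head"), ids[2])
  )
  list(
    frames = dplyr::bind_rows(blocks[[1]]$frames, blocks[[2]]$frames),
    truth = dplyr::bind_rows(blocks[[1]]$state, blocks[[2]]$state),
    scene = scene_config(spheres = spheres)
  )
}
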