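# Distance-gated per-frame gaze estimation. Frames arrive as a wide tibble
# (one row per person per frame); the estimator picks the eye-centre method
# at close range (face-centroid depth <= gate, eye landmarks present) and
# the skeletal head-pose method otherwise, maintains per-person rigid
# templates for occlusion recovery, and intersects the resulting ray with
# the scene plane and head spheres. Everything except the (rare) recovery
# solve is vectorized over frames.

frame_joint_cols <- function() {
  as.vector(vapply(JOINT_NAMES, function(j) paste0(j, c("_x", "_y", "_z", "_conf")),
                   character(4)))
}

frame_eye_cols <- function() {
  as.vector(vapply(c("l", "r"), function(s) {
    as.vector(vapply(c("c1", "c2", "surf", "iris"),
                     function(p) paste0("eye", s, "_", p, "_", c("x", "y", "z")),
                     character(3)))
  }, character(12)))
}

#' Empty frame stream
#'
#' A zero-row tibble with the full frame schema: `t` (seconds), `person`,
#' five joints as `<joint>_{x,y,z,conf}` (joints `eye_r`, `eye_l`, `nose`,
#' `ear_r`, `ear_l`), `has_eyes`, and per-eye landmark columns
#' `eye{l,r}_{c1,c2,surf,iris}_{x,y,z}`.
#'
#' @return A zero-row frames tibble.
#' @export
empty_frames <- function() {
  cols <- c("t", frame_joint_cols(), "has_eyes", frame_eye_cols())
  out <- as_tibble(setNames(lapply(cols, function(x) numeric(0)), cols))
  out$has_eyes <- logical(0)
  dplyr::mutate(out, person = character(0), .after = "t")
}

check_frames <- function(frames) {
  need <- c("t", "person", frame_joint_cols())
  missing <- setdiff(need, names(frames))
  if (length(missing) > 0) {
    abort(paste0("frames are missing columns: ", paste(missing, collapse = ", ")),
          class = "rgbdgaze_invalid_input")
  }
  bad <- frames |>
    dplyr::group_by(.data$person) |>
    dplyr::summarise(ok = !is.unsorted(.data$t), .groups = "drop")
  if (any(!bad$ok)) {
    abort("frame timestamps must be non-decreasing within each person",
          class = "rgbdgaze_input_order")
  }
  invisible(frames)
}

joint_mats <- function(frames) {
  lapply(c("x", "y", "z", "conf"), function(s) {
    as.matrix(frames[paste0(JOINT_NAMES, "_", s)])
  }) |> setNames(c("x", "y", "z", "conf"))
}

#' Gating depth of each frame
#'
#' The camera-frame depth |Z| of the face centroid MN (centroid of the two
#' eye joints and the nose), used to select the estimation method.
#'
#' @param frames A frames tibble (see [empty_frames()] for the schema).
#' @return Numeric vector of depths in cm.
#' @export
gating_distance <- function(frames) {
  jz <- as.matrix(frames[paste0(c("eye_r", "eye_l", "nose"), "_z")])
  abs(rowMeans(jz))
}

# Completed joints + head ray for one person's frame block.
# Returns coordinate matrices with occluded joints recovered from the most
# recent fully-observed template, plus validity flags.
head_pass <- function(fr) {
  n <- nrow(fr)
  jm <- joint_mats(fr)
  valid <- jm$conf >= 2
  all_valid <- rowSums(valid) == 5
  idx <- seq_len(n)
  tmpl <- cummax(ifelse(all_valid, idx, 0L))
  head_ok <- all_valid
  recovered <- rep(FALSE, n)
  X <- jm$x; Y <- jm$y; Z <- jm$z
  for (i in idx[!all_valid]) {
    if (tmpl[i] == 0L || sum(valid[i, ]) < 3) next
    tm <- cbind(jm$x[tmpl[i], ], jm$y[tmpl[i], ], jm$z[tmpl[i], ])
    cur <- cbind(jm$x[i, ], jm$y[i, ], jm$z[i, ])
    res <- rigid_recover(tm, cur, valid[i, ])
    if (is.null(res)) next
    X[i, ] <- res$joints[, 1]; Y[i, ] <- res$joints[, 2]; Z[i, ] <- res$joints[, 3]
    head_ok[i] <- TRUE
    recovered[i] <- TRUE
  }
  me <- cbind((X[, 4] + X[, 5]) / 2, (Y[, 4] + Y[, 5]) / 2, (Z[, 4] + Z[, 5]) / 2)
  mn <- cbind(rowMeans(X[, 1:3, drop = FALSE]), rowMeans(Y[, 1:3, drop = FALSE]),
              rowMeans(Z[, 1:3, drop = FALSE]))
  d <- mn - me
  nd <- row_norm(d)
  head_ok <- head_ok & nd > 1e-9
  dir <- d / ifelse(nd > 0, nd, 1)
  list(me = me, mn = mn, dir = dir, head_ok = head_ok, recovered = recovered,
       depth = abs(mn[, 3]))
}

# Binocular eye-method rays for a frame block, NA-safe and vectorized.
eye_pass <- function(fr) {
  n <- nrow(fr)
  none <- list(ok = rep(FALSE, n), origin = matrix(NA_real_, n, 3),
               dir = matrix(NA_real_, n, 3), monocular = rep(FALSE, n))
  if (!all(frame_eye_cols() %in% names(fr)) || !"has_eyes" %in% names(fr)) return(none)
  has <- !is.na(fr$has_eyes) & fr$has_eyes
  if (!any(has)) return(none)

  one_side <- function(s) {
    get3 <- function(p) as.matrix(fr[paste0("eye", s, "_", p, "_", c("x", "y", "z"))])
    c1 <- get3("c1"); c2 <- get3("c2"); surf <- get3("surf"); iris <- get3("iris")
    mid <- (c1 + c2) / 2
    hvec <- surf - mid
    h <- row_norm(hvec)
    chord <- row_norm(c1 - c2)
    ok <- has & !is.na(h) & h > 1e-6 & chord > 1e-9
    r <- h / 2 + chord^2 / (8 * h)
    center <- surf + r / h * (mid - surf)
    gd <- iris - center
    ng <- row_norm(gd)
    ok <- ok & !is.na(ng) & ng > 1e-9
    list(ok = ok, origin = center, dir = gd / ifelse(is.na(ng) | ng == 0, 1, ng))
  }
  L <- one_side("l"); R <- one_side("r")
  both <- L$ok & R$ok
  dsum <- L$dir + R$dir
  nds <- row_norm(dsum)
  both <- both & !is.na(nds) & nds > 1e-9
  origin <- (L$origin + R$origin) / 2
  dir <- dsum / ifelse(is.na(nds) | nds == 0, 1, nds)
  mono_l <- L$ok & !both
  mono_r <- R$ok & !both & !mono_l
  origin[mono_l, ] <- L$origin[mono_l, ]; dir[mono_l, ] <- L$dir[mono_l, ]
  origin[mono_r, ] <- R$origin[mono_r, ]; dir[mono_r, ] <- R$dir[mono_r, ]
  ok <- both | mono_l | mono_r
  list(ok = ok, origin = origin, dir = dir, monocular = mono_l | mono_r)
}

ray_plane_rows <- function(origin, dir, plane, ok) {
  n <- nrow(origin)
  hit <- matrix(NA_real_, n, 3)
  denom <- dir %*% plane$normal
  num <- sweep(-origin, 2, plane$point, "+") %*% plane$normal
  t <- ifelse(abs(denom) < 1e-12, NA_real_, num / denom)
  good <- ok & !is.na(t) & t > 0
  hit[good, ] <- origin[good, ] + t[good] * dir[good, ]
  hit
}

ray_sphere_rows <- function(origin, dir, center, radius, ok) {
  oc <- origin - center
  b <- row_dot(dir, oc)
  cc <- row_dot(oc, oc) - radius^2
  disc <- b^2 - cc
  sq <- sqrt(pmax(disc, 0))
  t1 <- -b - sq
  t2 <- -b + sq
  t <- ifelse(t1 > 0, t1, ifelse(t2 > 0, t2, NA_real_))
  ok & !is.na(disc) & disc >= 0 & !is.na(t)
}

#' Estimate gaze for a stream of frames
#'
#' Runs the distance-gated two-method estimator over a frame stream. Per
#' person, the most recent frame in which all five face joints scored
#' confidence >= 2 is kept as a rigid template; later occluded joints are
#' recovered by Kabsch alignment. The eye-centre method is used when the
#' face-centroid depth is at or below `scene$gate_cm` and usable eye
#' landmarks are present; otherwise the head-pose method is used (at close
#' range this fallback is flagged). Frames where neither method is viable
#' are kept with `valid = FALSE` so period denominators stay correct.
#'
#' @param frames A frames tibble (schema of [empty_frames()]), sorted by
#'   time within each person.
#' @param scene A [scene_config()].
#' @param force_method `NULL` (gated switching), `"eye"`, or `"head"` --
#'   the forced modes remove the distance condition for method comparison.
#' @return A tibble with one row per input frame: `t`, `person`, `method`
#'   (`"eye"`/`"head"`/`NA`), `valid`, `fallback` (head method used below
#'   the gate), `monocular`, `recovered` (joints recovered this frame),
#'   `depth_cm`, ray columns `origin_{x,y,z}`, `dir_{x,y,z}`, plane
#'   intersection `plane_{x,y,z}` plus `target_hit` (nearest named target),
#'   and one logical `hit_<name>` column per scene sphere.
#' @export
estimate_gaze <- function(frames, scene = scene_config(), force_method = NULL) {
  if (!is.null(force_method)) {
    force_method <- match.arg(force_method, c("eye", "head"))
  }
  if (nrow(frames) == 0) {
    out <- tibble(
      t = numeric(0), person = character(0), method = character(0),
      valid = logical(0), fallback = logical(0), monocular = logical(0),
      recovered = logical(0), depth_cm = numeric(0),
      origin_x = numeric(0), origin_y = numeric(0), origin_z = numeric(0),
      dir_x = numeric(0), dir_y = numeric(0), dir_z = numeric(0)
    )
    return(out)
  }
  check_frames(frames)
  n <- nrow(frames)
  ord <- order(frames$person)  # stable block split; undone at the end
  fr <- frames[ord, ]
  blocks <- split(seq_len(n), fr$person)

  me <- mn <- hdir <- matrix(NA_real_, n, 3)
  head_ok <- recovered <- rep(FALSE, n)
  depth <- rep(NA_real_, n)
  for (rows in blocks) {
    hp <- head_pass(fr[rows, ])
    me[rows, ] <- hp$me; mn[rows, ] <- hp$mn; hdir[rows, ] <- hp$dir
    head_ok[rows] <- hp$head_ok; recovered[rows] <- hp$recovered
    depth[rows] <- hp$depth
  }
  ep <- eye_pass(fr)

  if (is.null(force_method)) {
    use_eye <- !is.na(depth) & depth <= scene$gate_cm & ep$ok
    use_head <- !use_eye & head_ok
    fallback <- use_head & !is.na(depth) & depth <= scene$gate_cm
  } else if (force_method == "eye") {
    use_eye <- ep$ok
    use_head <- rep(FALSE, n)
    fallback <- rep(FALSE, n)
  } else {
    use_eye <- rep(FALSE, n)
    use_head <- head_ok
    fallback <- rep(FALSE, n)
  }
  valid <- use_eye | use_head
  method <- ifelse(use_eye, "eye", ifelse(use_head, "head", NA_character_))

  origin <- dir <- matrix(NA_real_, n, 3)
  origin[use_eye, ] <- ep$origin[use_eye, ]; dir[use_eye, ] <- ep$dir[use_eye, ]
  origin[use_head, ] <- mn[use_head, ]; dir[use_head, ] <- hdir[use_head, ]

  out <- tibble(
    t = fr$t, person = fr$person, method = method, valid = valid,
    fallback = fallback, monocular = ep$monocular & use_eye,
    recovered = recovered, depth_cm = depth,
    origin_x = origin[, 1], origin_y = origin[, 2], origin_z = origin[, 3],
    dir_x = dir[, 1], dir_y = dir[, 2], dir_z = dir[, 3]
  )

  if (!is.null(scene$plane)) {
    hit <- ray_plane_rows(origin, dir, scene$plane, valid)
    out$plane_x <- hit[, 1]; out$plane_y <- hit[, 2]; out$plane_z <- hit[, 3]
    if (!is.null(scene$targets) && nrow(scene$targets) > 0) {
      tg <- scene$targets
      d2 <- vapply(seq_len(nrow(tg)), function(k) {
        (hit[, 1] - tg$x[k])^2 + (hit[, 2] - tg$y[k])^2 + (hit[, 3] - tg$z[k])^2
      }, numeric(n))
      d2 <- matrix(d2, nrow = n)
      nearest <- apply(d2, 1, function(r) if (all(is.na(r))) NA_integer_ else which.min(r))
      out$target_hit <- tg$name[nearest]
    }
  }

  if (!is.null(scene$spheres) && nrow(scene$spheres) > 0) {
    for (k in seq_len(nrow(scene$spheres))) {
      sp <- scene$spheres[k, ]
      if (!is.na(sp$person)) {
        src <- which(fr$person == sp$person)
        pos <- match(out$t, fr$t[src])
        center <- matrix(NA_real_, n, 3)
        okc <- !is.na(pos) & head_ok[src][ifelse(is.na(pos), 1, pos)]
        center[okc, ] <- mn[src[pos[okc]], , drop = FALSE]
        self <- out$person == sp$person
        hitk <- ray_sphere_rows(origin, dir, center, sp$radius,
                                valid & okc & !self)
      } else {
        center <- matrix(rep(c(sp$x, sp$y, sp$z), each = n), n, 3)
        hitk <- ray_sphere_rows(origin, dir, center, sp$radius, valid)
      }
      out[[paste0("hit_", sp$name)]] <- hitk
    }
  }

  out[order(ord), ]
}
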