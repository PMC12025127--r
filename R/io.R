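# File formats: JSON-lines frame streams, periods CSV (two mm:ss dialects),
# and time helpers. Internally times are float seconds; periods are integer
# seconds.

#' Parse mm:ss period times to seconds
#'
#' Accepts `"MM:SS"`, the long dialect `"MM min SS s"`, and plain integer
#' seconds. Vectorized.
#'
#' @param x Character vector of times.
#' @return Integer seconds.
#' @export
#' @examples
#' parse_mmss(c("05:37", "20 min 44 s", "90"))
parse_mmss <- function(x) {
  x <- stringr::str_trim(as.character(x))
  out <- rep(NA_integer_, length(x))
  m1 <- stringr::str_match(x, "^(\\d+)\\s*min\\s*(\\d+)\\s*s$")
  m2 <- stringr::str_match(x, "^(\\d+):([0-5]?\\d)$")
  m3 <- stringr::str_detect(x, "^\\d+$")
  hit1 <- !is.na(m1[, 1])
  hit2 <- !hit1 & !is.na(m2[, 1])
  hit3 <- !hit1 & !hit2 & m3
  out[hit1] <- as.integer(m1[hit1, 2]) * 60L + as.integer(m1[hit1, 3])
  out[hit2] <- as.integer(m2[hit2, 2]) * 60L + as.integer(m2[hit2, 3])
  out[hit3] <- as.integer(x[hit3])
  if (anyNA(out)) {
    abort(paste0("unparseable period time(s): ",
                 paste(unique(x[is.na(out)]), collapse = ", ")),
          class = "rgbdgaze_parse_error")
  }
  out
}

#' Format seconds as mm:ss
#'
#' @param s Integer seconds.
#' @return Character vector `"MM:SS"`.
#' @export
format_mmss <- function(s) {
  sprintf("%d:%02d", as.integer(s) %/% 60L, as.integer(s) %% 60L)
}

#' Read / write a periods CSV
#'
#' The CSV must have `start` and `end` columns in either mm:ss dialect (or
#' already in plain seconds); any other columns (e.g. `person_id`,
#' `target`) are kept. Writing emits `person_id`, `target` (when present),
#' `start_s`, `end_s`, `start_mmss`, `end_mmss`.
#'
#' @param path File path.
#' @return A periods tibble with `start_s`, `end_s`, `start_mmss`,
#'   `end_mmss`.
#' @export
read_periods_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  nm <- names(raw)
  s_col <- intersect(c("start", "start_s", "start_mmss"), nm)[1]
  e_col <- intersect(c("end", "end_s", "end_mmss"), nm)[1]
  if (is.na(s_col) || is.na(e_col)) {
    abort(paste0(path, ": need start/end columns"), class = "rgbdgaze_parse_error")
  }
  start_s <- parse_mmss(raw[[s_col]])
  end_s <- parse_mmss(raw[[e_col]])
  if (any(end_s < start_s)) {
    abort(paste0(path, ": period end before start"), class = "rgbdgaze_parse_error")
  }
  extra <- raw[setdiff(nm, c(s_col, e_col, "start_s", "end_s", "start_mmss", "end_mmss"))]
  dplyr::bind_cols(
    extra,
    tibble(start_s = start_s, end_s = end_s,
           start_mmss = format_mmss(start_s), end_mmss = format_mmss(end_s))
  )
}

#' @rdname read_periods_csv
#' @param periods Periods tibble with `start_s`, `end_s`.
#' @export
write_periods_csv <- function(periods, path) {
  keep <- intersect(c("person", "person_id", "target"), names(periods))
  out <- dplyr::bind_cols(
    periods[keep],
    tibble(
      start_s = periods$start_s, end_s = periods$end_s,
      start_mmss = format_mmss(periods$start_s),
      end_mmss = format_mmss(periods$end_s)
    )
  )
  readr::write_csv(out, path)
  invisible(path)
}

JOINT_JSON_NAMES <- c(
  eye_r = "eye_right", eye_l = "eye_left", nose = "nose",
  ear_r = "ear_right", ear_l = "ear_left"
)

#' Read / write frame streams as JSON-lines
#'
#' One JSON object per line:
#' `{"t": 0.0, "person": "p1", "joints": [{"name": "eye_right", "x": ...,
#' "y": ..., "z": ..., "conf": 3}, ... 5 joints ...], "eyes": [{"side":
#' "left", "c1": [x,y,z], "c2": [...], "surface": [...], "iris": [...]},
#' ...]}` -- `eyes` optional. Unknown fields and malformed records are
#' rejected with the offending line number. An empty file is an empty
#' stream, not an error. Round-trips losslessly within float printing
#' precision.
#'
#' @param path File path.
#' @return [read_frames()] returns a frames tibble ([empty_frames()]
#'   schema); `write_frames()` returns `path` invisibly.
#' @export
read_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_frames())
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) NULL)
    ok <- !is.null(rec) &&
      all(names(rec) %in% c("t", "person", "joints", "eyes")) &&
      all(c("t", "person", "joints") %in% names(rec)) &&
      length(rec$joints) == 5
    if (!ok) {
      abort(sprintf("%s:%d: malformed frame record", path, i),
            class = "rgbdgaze_parse_error")
    }
    row <- list(t = as.numeric(rec$t), person = as.character(rec$person))
    for (j in rec$joints) {
      if (!all(names(j) %in% c("name", "x", "y", "z", "conf")) ||
          !j$name %in% JOINT_JSON_NAMES) {
        abort(sprintf("%s:%d: malformed joint record", path, i),
              class = "rgbdgaze_parse_error")
      }
      key <- names(JOINT_JSON_NAMES)[JOINT_JSON_NAMES == j$name]
      row[paste0(key, c("_x", "_y", "_z", "_conf"))] <-
        list(as.numeric(j$x), as.numeric(j$y), as.numeric(j$z), as.integer(j$conf))
    }
    if (length(setdiff(names(JOINT_JSON_NAMES),
                       sub("_conf$", "", grep("_conf$", names(row), value = TRUE)))) > 0) {
      abort(sprintf("%s:%d: frame must carry all five head joints", path, i),
            class = "rgbdgaze_parse_error")
    }
    row$has_eyes <- FALSE
    if (!is.null(rec$eyes)) {
      for (eye in rec$eyes) {
        if (!all(names(eye) %in% c("side", "c1", "c2", "surface", "iris")) ||
            !eye$side %in% c("left", "right")) {
          abort(sprintf("%s:%d: malformed eye record", path, i),
                class = "rgbdgaze_parse_error")
        }
        s <- if (eye$side == "left") "l" else "r"
        parts <- c(c1 = "c1", c2 = "c2", surf = "surface", iris = "iris")
        for (k in names(parts)) {
          src <- as.numeric(unlist(eye[[parts[[k]]]]))
          if (length(src) != 3) {
            abort(sprintf("%s:%d: eye landmark `%s` must be an xyz triple", path, i, parts[[k]]),
                  class = "rgbdgaze_parse_error")
          }
          row[paste0("eye", s, "_", k, "_", c("x", "y", "z"))] <- as.list(src)
        }
      }
      row$has_eyes <- TRUE
    }
    recs[[i]] <- row
  }
  out <- dplyr::bind_rows(recs)
  for (col in setdiff(frame_eye_cols(), names(out))) out[[col]] <- NA_real_
  out[, c("t", "person", frame_joint_cols(), "has_eyes", frame_eye_cols())]
}

#' @rdname read_frames
#' @param frames Frames tibble.
#' @export
write_frames <- function(frames, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(frames) > 0) {
    lines <- vapply(seq_len(nrow(frames)), function(i) {
      fr <- frames[i, ]
      joints <- lapply(JOINT_NAMES, function(j) {
        list(name = unname(JOINT_JSON_NAMES[[j]]),
             x = fr[[paste0(j, "_x")]], y = fr[[paste0(j, "_y")]],
             z = fr[[paste0(j, "_z")]], conf = fr[[paste0(j, "_conf")]])
      })
      rec <- list(t = fr$t, person = fr$person, joints = joints)
      if (isTRUE(fr$has_eyes)) {
        rec$eyes <- lapply(c(l = "left", r = "right"), function(side) {
          s <- if (side == "left") "l" else "r"
          get3 <- function(p) unname(unlist(fr[paste0("eye", s, "_", p, "_", c("x", "y", "z"))]))
          list(side = side, c1 = get3("c1"), c2 = get3("c2"),
               surface = get3("surf"), iris = get3("iris"))
        })
        names(rec$eyes) <- NULL
      }
      jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, con)
  }
  invisible(path)
}
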