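# From per-frame sphere-hit streams to second-resolution interaction
# periods. Annotations are at mm:ss resolution, so frames are first
# aggregated into per-second hit flags (a second counts as a hit when the
# hit fraction among its *valid* frames reaches a threshold), then maximal
# runs of hit seconds become closed [start, end] intervals.

#' Collapse a frame-level hit stream to per-second flags
#'
#' Seconds are floor(t). A second is a hit iff
#' (hit frames) / (valid frames in that second) >= `frame_fraction`;
#' seconds with no valid frame are non-hits. The full range of observed
#' seconds is returned so gaps are explicit.
#'
#' @param hits Tibble with columns `t` (seconds), `valid` (logical), `hit`
#'   (logical; `NA` treated as no hit).
#' @param frame_fraction Required hit fraction among valid frames, in
#'   (0, 1]. Default 0.5.
#' @return Tibble with columns `second` (integer) and `hit` (logical),
#'   one row per second from the first to the last observed second.
#' @export
binarize_seconds <- function(hits, frame_fraction = 0.5) {
  stopifnot(frame_fraction > 0, frame_fraction <= 1)
  if (nrow(hits) == 0) return(tibble(second = integer(0), hit = logical(0)))
  per <- hits |>
    dplyr::mutate(second = as.integer(floor(.data$t))) |>
    dplyr::group_by(.data$second) |>
    dplyr::summarise(
      n_valid = sum(.data$valid, na.rm = TRUE),
      n_hit = sum(.data$valid & !is.na(.data$hit) & .data$hit, na.rm = TRUE),
      .groups = "drop"
    )
  full <- tibble(second = seq(min(per$second), max(per$second)))
  full |>
    dplyr::left_join(per, by = "second") |>
    dplyr::mutate(hit = !is.na(.data$n_valid) & .data$n_valid > 0 &
                    .data$n_hit / .data$n_valid >= frame_fraction) |>
    dplyr::select("second", "hit")
}

#' Extract interaction periods from per-second hit flags
#'
#' Maximal runs of hit seconds become closed intervals `[start_s, end_s]`
#' (whole seconds, matching mm:ss annotation granularity). Runs separated
#' by gaps of at most `max_gap_s` non-hit seconds are merged; runs whose
#' duration `end_s - start_s` is below `min_duration_s` are discarded.
#'
#' @param seconds Tibble from [binarize_seconds()] (`second`, `hit`).
#' @param min_duration_s Minimum duration in seconds (default 1).
#' @param max_gap_s Largest bridged gap in seconds (default 0).
#' @return Tibble of periods: `start_s`, `end_s`, `start_mmss`, `end_mmss`,
#'   sorted and disjoint.
#' @export
extract_periods <- function(seconds, min_duration_s = 1, max_gap_s = 0) {
  stopifnot(min_duration_s >= 0, max_gap_s >= 0)
  s <- sort(seconds$second[seconds$hit])
  if (length(s) == 0) return(period_tbl(integer(0), integer(0)))
  brk <- which(diff(s) > max_gap_s + 1)
  start <- s[c(1, brk + 1)]
  end <- s[c(brk, length(s))]
  keep <- (end - start) >= min_duration_s
  period_tbl(start[keep], end[keep])
}

period_tbl <- function(start_s, end_s) {
  tibble(
    start_s = as.integer(start_s), end_s = as.integer(end_s),
    start_mmss = format_mmss(start_s), end_mmss = format_mmss(end_s)
  )
}

#' Detect gaze periods from estimates
#'
#' Convenience wrapper: filters one gazer's estimates, binarizes the chosen
#' sphere-hit column per second and extracts periods.
#'
#' @param estimates Output of [estimate_gaze()].
#' @param person Gazing person id.
#' @param target Sphere name (uses column `hit_<target>`).
#' @inheritParams binarize_seconds
#' @inheritParams extract_periods
#' @return Periods tibble as in [extract_periods()], with `person` and
#'   `target` columns prepended.
#' @export
detect_periods <- function(estimates, person, target, frame_fraction = 0.5,
                           min_duration_s = 1, max_gap_s = 0) {
  col <- paste0("hit_", target)
  if (!col %in% names(estimates)) {
    abort(paste0("no sphere-hit column `", col, "` in the estimates"),
          class = "rgbdgaze_invalid_input")
  }
  hits <- estimates |>
    dplyr::filter(.data$person == !!person) |>
    dplyr::transmute(t = .data$t, valid = .data$valid, hit = .data[[col]])
  out <- extract_periods(binarize_seconds(hits, frame_fraction),
                         min_duration_s, max_gap_s)
  dplyr::mutate(out, person = person, target = target, .before = 1)
}

#' Mutual-gaze periods
#'
#' Periods during which both hit streams (A's gaze on B's head and B's gaze
#' on A's head) are simultaneously on, at second resolution: the per-second
#' AND of the two binarized streams, run through the same period rules.
#'
#' @param hits_a_to_b,hits_b_to_a Hit tibbles as for [binarize_seconds()],
#'   covering the same timeline.
#' @inheritParams detect_periods
#' @return Periods tibble as in [extract_periods()].
#' @export
mutual_gaze <- function(hits_a_to_b, hits_b_to_a, frame_fraction = 0.5,
                        min_duration_s = 1, max_gap_s = 0) {
  a <- binarize_seconds(hits_a_to_b, frame_fraction)
  b <- binarize_seconds(hits_b_to_a, frame_fraction)
  if (nrow(a) != nrow(b) || (nrow(a) > 0 && !all(a$second == b$second))) {
    abort("the two hit streams cover different timelines",
          class = "rgbdgaze_invalid_input")
  }
  both <- tibble(second = a$second, hit = a$hit & b$hit)
  extract_periods(both, min_duration_s, max_gap_s)
}
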