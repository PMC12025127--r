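# Scoring detected interaction periods against manual annotations.
# Two period-level metrics:
#   interval IoU = (min(Et,Ep) - max(St,Sp)) / (max(Et,Ep) - min(St,Sp)),
#     clipped to 0 for disjoint pairs (the raw formula would go negative);
#   OBOA (off-by-one accuracy) = 1 iff |truth duration - detected duration|
#     <= tolerance (1 s), durations measured as end - start.
# Truth and detected lists are paired greedily by descending IoU; truth
# periods with no overlapping detection are paired to the nearest-in-time
# unused detection so every annotated period yields a scored row, and
# leftover detections are reported as false detections.

#' Interval intersection-over-union
#'
#' IoU of two closed time intervals on integer seconds. Disjoint pairs
#' score 0; two identical zero-length intervals score 1. Vectorized.
#'
#' @param truth_start,truth_end Truth interval bounds in seconds.
#' @param det_start,det_end Detected interval bounds in seconds.
#' @return IoU value(s) in \[0, 1\].
#' @export
#' @examples
#' interval_iou(1244, 1245, 1244, 1272) # 1/28
interval_iou <- function(truth_start, truth_end, det_start, det_end) {
  stopifnot(all(truth_end >= truth_start), all(det_end >= det_start))
  num <- pmin(truth_end, det_end) - pmax(truth_start, det_start)
  den <- pmax(truth_end, det_end) - pmin(truth_start, det_start)
  ifelse(den == 0, as.numeric(num == 0), pmax(num, 0) / den)
}

#' Off-by-one accuracy indicator
#'
#' 1 iff the two period durations (end - start, seconds) differ by at most
#' `tolerance_s`. Vectorized.
#'
#' @inheritParams interval_iou
#' @param tolerance_s Allowed duration difference in seconds (default 1).
#' @return Integer 0/1 value(s).
#' @export
oboa_indicator <- function(truth_start, truth_end, det_start, det_end,
                           tolerance_s = 1) {
  stopifnot(all(truth_end >= truth_start), all(det_end >= det_start))
  as.integer(abs((truth_end - truth_start) - (det_end - det_start)) <= tolerance_s)
}

check_period_list <- function(p, what) {
  if (!all(c("start_s", "end_s") %in% names(p))) {
    abort(paste0(what, " periods need `start_s` and `end_s` columns"),
          class = "rgbdgaze_invalid_input")
  }
  if (nrow(p) > 1) {
    o <- order(p$start_s)
    if (any(p$start_s[o][-1] <= p$end_s[o][-nrow(p)])) {
      abort(paste0(what, " periods overlap within the list"),
            class = "rgbdgaze_invalid_input")
    }
  }
  p[order(p$start_s), c("start_s", "end_s")]
}

#' Match detected periods to annotated truth periods
#'
#' Pairs are formed greedily in descending IoU order (each detection used
#' at most once). Truth periods left without a positive-IoU candidate are
#' paired to the unused detection whose start time is nearest (ties to the
#' earlier detection), so every annotated period yields a scored row;
#' detections that remain unused are false detections.
#'
#' @param truth,detected Period tibbles with `start_s`, `end_s` (integer
#'   seconds), each internally disjoint.
#' @param oboa_tolerance_s Passed to [oboa_indicator()].
#' @return An object of class `period_matches`: a list with `matches`
#'   (tibble: truth/detected/overlap bounds, `iou`, `oboa`),
#'   `unmatched_truth`, `false_detections`. Use [tidy()] for the per-pair
#'   rows and [glance()] (or [summarize_session()]) for session means.
#' @export
match_periods <- function(truth, detected, oboa_tolerance_s = 1) {
  tr <- check_period_list(truth, "truth")
  de <- check_period_list(detected, "detected")
  nt <- nrow(tr); nd <- nrow(de)
  t_of <- integer(0)
  d_of <- integer(0)
  if (nt > 0 && nd > 0) {
    iou <- outer(seq_len(nt), seq_len(nd), function(i, j) {
      interval_iou(tr$start_s[i], tr$end_s[i], de$start_s[j], de$end_s[j])
    })
    free_t <- rep(TRUE, nt); free_d <- rep(TRUE, nd)
    repeat {
      m <- iou * outer(free_t, free_d)
      if (max(m) <= 0) break
      best <- which(m == max(m), arr.ind = TRUE)
      best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
      t_of <- c(t_of, best[1]); d_of <- c(d_of, best[2])
      free_t[best[1]] <- FALSE; free_d[best[2]] <- FALSE
    }
    for (i in which(free_t)) {
      cand <- which(free_d)
      if (length(cand) == 0) break
      dist <- abs(de$start_s[cand] - tr$start_s[i])
      j <- cand[order(dist, de$start_s[cand])][1]
      t_of <- c(t_of, i); d_of <- c(d_of, j)
      free_t[i] <- FALSE; free_d[j] <- FALSE
    }
  } else {
    free_t <- rep(TRUE, nt); free_d <- rep(TRUE, nd)
  }
  ord <- order(tr$start_s[t_of])
  t_of <- t_of[ord]; d_of <- d_of[ord]
  iou_v <- interval_iou(tr$start_s[t_of], tr$end_s[t_of], de$start_s[d_of], de$end_s[d_of])
  ov_s <- pmax(tr$start_s[t_of], de$start_s[d_of])
  ov_e <- pmin(tr$end_s[t_of], de$end_s[d_of])
  disjoint <- ov_e < ov_s
  matches <- tibble(
    truth_start_s = tr$start_s[t_of], truth_end_s = tr$end_s[t_of],
    det_start_s = de$start_s[d_of], det_end_s = de$end_s[d_of],
    overlap_start_s = ifelse(disjoint, NA_integer_, ov_s),
    overlap_end_s = ifelse(disjoint, NA_integer_, ov_e),
    iou = iou_v,
    oboa = oboa_indicator(tr$start_s[t_of], tr$end_s[t_of],
                          de$start_s[d_of], de$end_s[d_of], oboa_tolerance_s)
  ) |>
    dplyr::mutate(
      truth = paste(format_mmss(.data$truth_start_s), format_mmss(.data$truth_end_s), sep = "-"),
      detected = paste(format_mmss(.data$det_start_s), format_mmss(.data$det_end_s), sep = "-"),
      overlap = ifelse(is.na(.data$overlap_start_s), NA_character_,
                       paste(format_mmss(.data$overlap_start_s),
                             format_mmss(.data$overlap_end_s), sep = "-"))
    )
  unmatched <- if (nt > 0) tr[free_t, ] else tr
  false_det <- if (nd > 0) de[free_d, ] else de
  structure(
    list(matches = matches, unmatched_truth = unmatched, false_detections = false_det),
    class = "period_matches"
  )
}

#' @export
print.period_matches <- function(x, ...) {
  cat(sprintf("<period_matches> %d matched, %d missed truth, %d false detections\n",
              nrow(x$matches), nrow(x$unmatched_truth), nrow(x$false_detections)))
  print(dplyr::select(x$matches, "truth", "detected", "overlap", "iou", "oboa"), ...)
  invisible(x)
}

#' Tidy per-pair rows of a period matching
#'
#' @param x A [match_periods()] result.
#' @param ... Unused.
#' @return The per-pair tibble (one row per matched truth period).
#' @export
tidy.period_matches <- function(x, ...) x$matches

#' Session-level summary of a period matching
#'
#' Arithmetic means of IoU and OBOA over the matched truth rows (the
#' denominator is the number of matched periods), plus bookkeeping counts.
#'
#' @param x A [match_periods()] result.
#' @param ... Unused.
#' @return One-row tibble: `mean_iou`, `mean_oboa`, `n_matched`,
#'   `n_missed_truth`, `n_false_detections`.
#' @export
glance.period_matches <- function(x, ...) {
  if (nrow(x$matches) == 0) {
    abort("no matched periods to summarise", class = "rgbdgaze_empty_input")
  }
  tibble(
    mean_iou = mean(x$matches$iou),
    mean_oboa = mean(x$matches$oboa),
    n_matched = nrow(x$matches),
    n_missed_truth = nrow(x$unmatched_truth),
    n_false_detections = nrow(x$false_detections)
  )
}

#' @rdname glance.period_matches
#' @param matches A [match_periods()] result.
#' @export
summarize_session <- function(matches) glance(matches)

#' Packaged annotation and detection period lists
#'
#' The two child-clinician sessions shipped with the package: manual
#' annotations of when the child looked at the clinician (`"truth"`) and
#' the periods the gaze pipeline detected (`"detected"`).
#'
#' @param session 1 or 2.
#' @param source `"truth"` or `"detected"`.
#' @return Periods tibble (`start_s`, `end_s`, `start_mmss`, `end_mmss`).
#' @export
session_periods <- function(session = 1, source = c("truth", "detected")) {
  source <- match.arg(source)
  stopifnot(session %in% 1:2)
  path <- system.file("extdata", sprintf("session%d_%s.csv", session, source),
                      package = "rgbdgaze", mustWork = TRUE)
  read_periods_csv(path)
}

#' Score the packaged sessions
#'
#' Runs [match_periods()] on the packaged truth/detected period lists of
#' both sessions and returns the per-pair IoU/OBOA rows plus session means.
#'
#' @param sessions Which sessions to score (default both).
#' @return A list with `pairs` (tibble, one row per matched truth period,
#'   with `session`) and `summary` (one row per session).
#' @export
score_sessions <- function(sessions = 1:2) {
  res <- purrr::map(sessions, function(s) {
    m <- match_periods(session_periods(s, "truth"), session_periods(s, "detected"))
    list(
      pairs = dplyr::mutate(tidy(m), session = s, .before = 1),
      summary = dplyr::mutate(glance(m), session = s, .before = 1)
    )
  })
  list(
    pairs = dplyr::bind_rows(purrr::map(res, "pairs")),
    summary = dplyr::bind_rows(purrr::map(res, "summary"))
  )
}
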