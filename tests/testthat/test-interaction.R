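make_hits <- function(sec_spec) {
  # sec_spec: list of (second, n_frames, n_valid, n_hit)
  dplyr::bind_rows(lapply(sec_spec, function(s) {
    tibble::tibble(
      t = s[1] + (seq_len(s[2]) - 1) / s[2],
      valid = seq_len(s[2]) <= s[3],
      hit = seq_len(s[2]) <= s[4]
    )
  }))
}

test_that("binarize_seconds thresholds the hit fraction among valid frames", {
  h <- make_hits(list(c(5, 30, 30, 30)))
  expect_identical(binarize_seconds(h), tibble::tibble(second = 5L, hit = TRUE))

  # 14/30 < 0.5 is a non-hit
  h2 <- make_hits(list(c(0, 30, 30, 14)))
  expect_false(binarize_seconds(h2)$hit)

  # denominator counts only valid frames: 5 hits among 10 valid of 15 frames
  h3 <- make_hits(list(c(0, 15, 10, 5)))
  expect_true(binarize_seconds(h3)$hit)

  # a second with no valid frames is a non-hit and gaps appear explicitly
  h4 <- make_hits(list(c(0, 10, 10, 10), c(2, 10, 0, 0), c(3, 10, 10, 10)))
  b4 <- binarize_seconds(h4)
  expect_identical(b4$second, 0:3)
  expect_identical(b4$hit, c(TRUE, FALSE, FALSE, TRUE))

  expect_identical(nrow(binarize_seconds(tibble::tibble(t = numeric(0), valid = logical(0),
                                                        hit = logical(0)))), 0L)
})

test_that("extract_periods merges gaps, drops short runs, reports closed intervals", {
  none <- extract_periods(tibble::tibble(second = 0:9, hit = FALSE))
  expect_identical(nrow(none), 0L)

  two <- extract_periods(tibble::tibble(second = 330:345, hit = 330:345 %in% c(337, 338)))
  expect_identical(two$start_s, 337L)
  expect_identical(two$end_s, 338L)
  expect_identical(two$start_mmss, "5:37")
  expect_identical(two$end_mmss, "5:38")

  merged <- extract_periods(tibble::tibble(second = 0:20, hit = 0:20 %in% c(10, 11, 13, 14)),
                            max_gap_s = 1)
  expect_identical(merged$start_s, 10L)
  expect_identical(merged$end_s, 14L)

  # without gap bridging the two runs stay separate; both reach min duration
  split <- extract_periods(tibble::tibble(second = 0:20, hit = 0:20 %in% c(10, 11, 13, 14)))
  expect_identical(split$start_s, c(10L, 13L))

  # single-second runs fall below the default 1 s minimum duration
  short <- extract_periods(tibble::tibble(second = 0:10, hit = 0:10 == 5))
  expect_identical(nrow(short), 0L)
  kept <- extract_periods(tibble::tibble(second = 0:10, hit = 0:10 == 5), min_duration_s = 0)
  expect_identical(kept$start_s, 5L)
})

test_that("extracted periods are disjoint, sorted and long enough on random streams", {
  set.seed(15)
  for (i in 1:30) {
    flags <- tibble::tibble(second = 0:119, hit = runif(120) < 0.3)
    gap <- sample(0:2, 1); mind <- sample(0:3, 1)
    p <- extract_periods(flags, min_duration_s = mind, max_gap_s = gap)
    if (nrow(p) > 1) {
      expect_true(all(diff(p$start_s) > 0))
      expect_true(all(p$start_s[-1] - p$end_s[-nrow(p)] > gap + 1))
    }
    if (nrow(p) > 0) {
      expect_true(all(p$end_s - p$start_s >= mind))
      expect_true(all(flags$hit[flags$second %in% c(p$start_s, p$end_s)]))
    }
  }
})

test_that("mutual_gaze is the per-second intersection of the two streams", {
  tl <- function(hit_sec) {
    tibble::tibble(t = seq(0, 19.9, by = 0.1),
                   valid = TRUE,
                   hit = floor(seq(0, 19.9, by = 0.1)) %in% hit_sec)
  }
  full <- mutual_gaze(tl(0:19), tl(0:19))
  expect_identical(full$start_s, 0L)
  expect_identical(full$end_s, 19L)

  expect_identical(nrow(mutual_gaze(tl(0:5), tl(10:19))), 0L)

  m <- mutual_gaze(tl(0:10), tl(5:15))
  expect_identical(m$start_s, 5L)
  expect_identical(m$end_s, 10L)

  # mutual seconds are a subset of each direction's own seconds
  set.seed(16)
  a_sec <- sort(sample(0:19, 10)); b_sec <- sort(sample(0:19, 10))
  mm <- mutual_gaze(tl(a_sec), tl(b_sec), min_duration_s = 0)
  mut_secs <- unlist(Map(seq, mm$start_s, mm$end_s))
  expect_true(all(mut_secs %in% a_sec) && all(mut_secs %in% b_sec))

  expect_error(mutual_gaze(tl(0:5), tl(0:5)[1:100, ]), class = "rgbdgaze_invalid_input")
})

test_that("a scripted two-person schedule is recovered exactly at 1-s resolution", {
  sched_a <- tibble::tibble(start_s = c(3L, 12L, 30L), end_s = c(6L, 14L, 41L))
  sched_b <- tibble::tibble(start_s = c(5L, 35L), end_s = c(13L, 38L))
  sim <- simulate_interaction(synthetic_config(duration_s = 50), sched_a, sched_b)
  est <- estimate_gaze(sim$frames, sim$scene)
  pa <- detect_periods(est, "p1", "p2_head")
  pb <- detect_periods(est, "p2", "p1_head")
  expect_identical(pa[, c("start_s", "end_s")], sched_a)
  expect_identical(pb[, c("start_s", "end_s")], sched_b)

  hit_of <- function(gazer, col) {
    e <- est[est$person == gazer, ]
    tibble::tibble(t = e$t, valid = e$valid, hit = e[[col]])
  }
  # schedule intersection: [5,6], [12,13], [35,38]
  mg <- mutual_gaze(hit_of("p1", "hit_p2_head"), hit_of("p2", "hit_p1_head"))
  expect_identical(mg$start_s, c(5L, 12L, 35L))
  expect_identical(mg$end_s, c(6L, 13L, 38L))
})
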