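test_that("interval_iou matches the published worked pairs", {
  # truth 20:44-20:45 vs detected 20:44-21:12 -> 1/28
  expect_equal(interval_iou(1244, 1245, 1244, 1272), 1 / 28, tolerance = 1e-12)
  # truth 45:18-45:20 vs detected 45:17-45:19 -> 1/3
  expect_equal(interval_iou(2718, 2720, 2717, 2719), 1 / 3, tolerance = 1e-12)
  expect_equal(interval_iou(10, 20, 10, 20), 1)
  expect_equal(interval_iou(0, 5, 10, 20), 0)
  # identical zero-length intervals are a perfect match
  expect_equal(interval_iou(7, 7, 7, 7), 1)
  expect_equal(interval_iou(7, 7, 8, 8), 0)
})

test_that("interval_iou agrees with a set-based oracle and its invariances hold", {
  set.seed(17)
  n <- 10000
  ts <- sample(0:3000, n, replace = TRUE)
  te <- ts + sample(0:120, n, replace = TRUE)
  ds <- sample(0:3000, n, replace = TRUE)
  de <- ds + sample(0:120, n, replace = TRUE)
  got <- interval_iou(ts, te, ds, de)
  inter <- pmax(0, pmin(te, de) - pmax(ts, ds))
  union <- (te - ts) + (de - ds) - inter
  overlap <- pmin(te, de) > pmax(ts, ds)
  # for genuinely overlapping segments the hull equals the union
  expect_equal(got[overlap], (inter / union)[overlap], tolerance = 1e-12)
  expect_true(all(got[!overlap & (pmin(te, de) < pmax(ts, ds))] == 0))
  expect_true(all(got >= 0 & got <= 1))
  # symmetry and common-shift invariance
  expect_equal(got, interval_iou(ds, de, ts, te))
  expect_equal(got, interval_iou(ts + 500, te + 500, ds + 500, de + 500))
})

test_that("oboa_indicator compares durations with a 1-s tolerance", {
  expect_identical(oboa_indicator(2718, 2720, 2717, 2719), 1L)  # 2 s vs 2 s
  expect_identical(oboa_indicator(1244, 1245, 1244, 1272), 0L)  # 1 s vs 28 s
  expect_identical(oboa_indicator(0, 2, 10, 13), 1L)            # differ by exactly 1 s
  expect_identical(oboa_indicator(0, 2, 10, 14), 0L)
  expect_identical(oboa_indicator(0, 2, 10, 14, tolerance_s = 2), 1L)
})

test_that("match_periods pairs greedily by IoU with a nearest-in-time fallback", {
  truth <- session_periods(1, "truth")
  det <- session_periods(1, "detected")
  m <- match_periods(truth, det)
  expect_identical(nrow(m$matches), 11L)
  expect_identical(nrow(m$false_detections), 1L)
  expect_identical(m$false_detections$start_s, 1833L)  # 30:33-30:34
  expect_identical(nrow(m$unmatched_truth), 0L)
  expect_true(all(c(1 / 28, 1 / 47, 1 / 82, 1 / 3) %in% round(m$matches$iou, 10) |
                    sapply(c(1 / 28, 1 / 47, 1 / 82, 1 / 3),
                           function(v) any(abs(m$matches$iou - v) < 1e-9))))

  ident <- match_periods(truth, truth)
  expect_true(all(ident$matches$iou == 1))
  expect_identical(nrow(ident$false_detections), 0L)

  # one truth period overlapping two detections pairs with the higher IoU;
  # brute force over both assignments confirms
  tr1 <- tibble::tibble(start_s = 10L, end_s = 20L)
  de2 <- tibble::tibble(start_s = c(8L, 15L), end_s = c(14L, 21L))
  m2 <- match_periods(tr1, de2)
  iou_both <- interval_iou(10, 20, de2$start_s, de2$end_s)
  expect_identical(m2$matches$det_start_s, de2$start_s[which.max(iou_both)])
  expect_equal(m2$matches$iou, max(iou_both))

  # a truth period with no overlap is matched to the nearest unused detection
  tr3 <- tibble::tibble(start_s = c(10L, 100L), end_s = c(12L, 102L))
  de3 <- tibble::tibble(start_s = c(10L, 140L), end_s = c(12L, 141L))
  m3 <- match_periods(tr3, de3)
  expect_identical(m3$matches$det_start_s, c(10L, 140L))
  expect_identical(m3$matches$iou, c(1, 0))
  expect_true(is.na(m3$matches$overlap[2]))

  expect_error(match_periods(tibble::tibble(start_s = c(0L, 5L), end_s = c(6L, 9L)), de3),
               class = "rgbdgaze_invalid_input")
})

test_that("glance and summarize_session average over matched rows only", {
  m <- match_periods(session_periods(1, "truth"), session_periods(1, "detected"))
  g <- glance(m)
  expect_identical(g$n_matched, 11L)
  expect_equal(round(g$mean_iou, 2), 0.67)
  expect_equal(round(g$mean_oboa, 2), 0.73)
  expect_identical(summarize_session(m), g)
  expect_identical(tidy(m), m$matches)

  perfect <- tibble::tibble(start_s = c(0L, 10L), end_s = c(5L, 15L))
  gp <- glance(match_periods(perfect, perfect))
  expect_equal(gp$mean_iou, 1)
  expect_equal(gp$mean_oboa, 1)

  none <- match_periods(tibble::tibble(start_s = integer(0), end_s = integer(0)),
                        perfect)
  expect_error(glance(none), class = "rgbdgaze_empty_input")
})

test_that("autoplot and timeline plots build without error", {
  m <- match_periods(session_periods(1, "truth"), session_periods(1, "detected"))
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
  p2 <- plot_period_timeline(session_periods(2, "truth"), session_periods(2, "detected"))
  expect_s3_class(p2, "ggplot")
})
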