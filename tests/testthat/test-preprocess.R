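# Median-per-second resampling, artifact correction, missing-data policy,
# trigger alignment.

test_that("resampling takes per-second medians in half-open bins", {
  tr <- new_proximity_trace(c(0, 300, 600, 1000, 1500),
                            c(100, 102, 300, 50, 60), resolution = "raw")
  rs <- resample_proximity(tr)
  expect_identical(trace_res <- attr(rs, "resolution"), "1hz")
  expect_equal(rs$distance_cm, c(102, 55))  # median(100,102,300); median(50,60)
  expect_equal(rs$t_ms, c(0, 1000))
  expect_false(any(rs$interpolated))
})

test_that("empty interior bins are linearly interpolated and flagged", {
  tr <- new_proximity_trace(c(0, 500, 2000, 2500), c(100, 100, 110, 110),
                            resolution = "raw")
  rs <- resample_proximity(tr)
  expect_equal(rs$distance_cm, c(100, 105, 110))
  expect_identical(rs$interpolated, c(FALSE, TRUE, FALSE))
})

test_that("resampling is idempotent on constants and commutes with shifts", {
  tr <- new_proximity_trace(seq(0, 4999, by = 100), rep(77, 50),
                            resolution = "raw")
  expect_true(all(resample_proximity(tr)$distance_cm == 77))
  expect_identical(nrow(resample_proximity(tr)), 5L)

  for (i in 1:20) {
    set.seed(i)
    t_ms <- sort(runif(60, 0, 8000))
    d <- runif(60, 40, 400)
    shift <- runif(1, 0, 50)
    a <- resample_proximity(new_proximity_trace(t_ms, d, resolution = "raw"))
    b <- resample_proximity(new_proximity_trace(t_ms, d + shift,
                                                resolution = "raw"))
    expect_equal(b$distance_cm, a$distance_cm + shift)
  }
  empty <- resample_proximity(new_proximity_trace(numeric(0), numeric(0),
                                                  resolution = "raw"))
  expect_identical(nrow(empty), 0L)
})

test_that("artifact correction replaces exactly the rule-flagged beats", {
  res <- correct_artifacts(make_stream(c(800, 805, 1300, 810)))
  expect_equal(res$stream$rr_ms, c(800, 805, 807.5, 810))
  expect_identical(res$report$n_replaced_threshold, 1L)
  expect_identical(res$report$n_replaced_zscore, 0L)
  expect_equal(res$report$replacement_value_ms, 807.5)

  # a beat of exactly 1200 ms is replaced (threshold is inclusive)
  res2 <- correct_artifacts(make_stream(c(900, 910, 1200, 905, 895)))
  expect_false(any(res2$stream$rr_ms >= 1200))
  expect_identical(res2$report$n_replaced_threshold, 1L)

  # constant series: sd = 0 path, nothing replaced, note logged
  res3 <- correct_artifacts(make_stream(rep(800, 5)))
  expect_equal(res3$stream$rr_ms, rep(800, 5))
  expect_identical(res3$report$n_replaced_threshold +
                     res3$report$n_replaced_zscore, 0L)
  expect_match(res3$report$notes, "sd is 0")

  expect_error(correct_artifacts(make_stream(numeric(0))), "empty")
})

test_that("z-rule flags outliers below 1200 ms; both-rule beats count once", {
  # 199 beats at ~800 and one at 1100: z = |1100-801.5|/sd >> 2, < 1200 ms
  rr <- c(rep(800, 100), rep(803, 99), 1100)
  res <- correct_artifacts(make_stream(rr))
  expect_identical(res$report$n_replaced_zscore, 1L)
  expect_identical(res$report$n_replaced_threshold, 0L)
  expect_equal(res$stream$rr_ms[200], median(rr))

  # spike >= 1200 with huge z: counted once, under the threshold rule
  rr2 <- c(rep(800, 50), rep(804, 50), 1500)
  res2 <- correct_artifacts(make_stream(rr2))
  expect_identical(res2$report$n_replaced_threshold, 1L)
  expect_identical(res2$report$n_replaced_zscore, 0L)
})

test_that("artifact correction preserves length and timestamps (property)", {
  for (i in 1:25) {
    s <- simulate_rr_series(120, 750, 35, artifact_rate = 0.05, seed = 400 + i)
    before <- make_stream(rr_values(s))
    res <- correct_artifacts(before)
    expect_identical(nrow(res$stream), nrow(before))
    expect_identical(res$stream$t_s, before$t_s)
    expect_false(any(res$stream$rr_ms >= 1200))
  }
})

test_that("trigger alignment snaps to local minima within the radius", {
  # minima at t = 5 (value 90, plateau of 2) and t = 14 (value 80)
  v <- c(500, 400, 300, 200, 100, 90, 90, 200, 300, 400, 500, 300, 150, 90, 80,
         150, 300, 500)
  tr <- make_trace_1hz(v)
  keys <- condition_keys()[1:2, ]
  trg <- new_trigger_set(c(3, 16), keys)
  out <- align_triggers(trg, tr)
  expect_equal(out$t_s, c(5, 14))

  # already-aligned triggers are a fixed point
  expect_equal(align_triggers(out, tr)$t_s, c(5, 14))

  # overrides are honoured verbatim, applied last
  ov <- data.frame(trigger_index = 2, t_s = 412)
  expect_equal(align_triggers(trg, tr, overrides = ov)$t_s, c(5, 412))

  # out-of-range trigger left unchanged with a warning
  expect_warning(res <- align_triggers(new_trigger_set(c(5, 16.5), keys),
                                       make_trace_1hz(c(500, rep(500, 30)))),
                 "no local minimum")

  # two triggers collapsing onto one minimum is a collision error
  expect_error(align_triggers(new_trigger_set(c(4, 6), keys), tr),
               "collide")
})

test_that("drop_incomplete excludes HRV-incomplete participants listwise", {
  co <- simulate_cohort(sim_config(n_asd = 2, n_cp = 5, sample_rate_hz = 5,
                                   seed = 31))
  full <- drop_incomplete(co)
  expect_identical(full$hrv_ids, co$metadata$participant)
  expect_length(full$report$participants_dropped, 0)

  # 2 of 5 CP sessions lose their RR record -> HRV set keeps 3 CP, all 5
  # stay in the distance set
  cp_ids <- co$metadata$participant[co$metadata$group == "CP"][1:2]
  for (id in cp_ids) co$sessions[[id]]$rr <- NULL
  res <- drop_incomplete(co)
  expect_setequal(res$distance_ids, co$metadata$participant)
  kept_cp <- intersect(res$hrv_ids,
                       co$metadata$participant[co$metadata$group == "CP"])
  expect_length(kept_cp, 3)
  expect_identical(unname(res$report$participants_dropped[cp_ids]),
                   rep("no RR record", 2))
})
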