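test_that("side assignment follows handedness with midline exclusion", {
  labels <- default_body_parts("right")$sensor
  sides <- assign_sides(labels, "right")
  expect_equal(unname(sides["forearm_right"]), "performing")
  expect_equal(unname(sides["forearm_left"]), "nonperforming")
  expect_equal(unname(sides["forehead"]), "midline")
  expect_equal(unname(sides["t7"]), "midline")
  # left-handed mirror
  labL <- default_body_parts("left")$sensor
  sidesL <- assign_sides(labL, "left")
  expect_equal(unname(sidesL["forearm_left"]), "performing")
  expect_equal(unname(sidesL["forearm_right"]), "nonperforming")
  expect_equal(sum(sides == "performing"), 4L)
})

# build a comparison object with prescribed deltas for rule tests
mock_comparison <- function(seg_delta, side_delta, lag_cells = NULL) {
  deltas <- data.frame(
    metric = "nsr_aa", contrast = c("segment", "side"),
    delta = c(seg_delta, side_delta))
  cells <- data.frame(metric = "lag_heart",
                      cell = c("forward", "backward", "performing",
                               "nonperforming"),
                      value = lag_cells %||% c(0.1, -0.1, 0.05, -0.2))
  structure(list(participant = "m", cells = cells,
                 grid = data.frame(metric = character(0)),
                 deltas = deltas, n_valid_trials = 10L),
            class = "intent_comparison")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("consistency symbols follow the all / most / none rule", {
  mk <- function(signs) lapply(signs, function(s) mock_comparison(s, s))
  sm <- summarize_cohort(mk(rep(1, 8)))
  row <- sm$summary[sm$summary$contrast == "segment", ]
  expect_equal(row$symbol, "o")
  expect_equal(row$favored, "forward")
  sm <- summarize_cohort(mk(c(rep(1, 6), -1, -1)))
  row <- sm$summary[sm$summary$contrast == "segment", ]
  expect_equal(row$symbol, "triangle")
  expect_equal(row$favored, "forward")
  sm <- summarize_cohort(mk(c(rep(1, 4), rep(-1, 4))))
  row <- sm$summary[sm$summary$contrast == "segment", ]
  expect_equal(row$symbol, "-")
  # all negative favors the other category with o
  sm <- summarize_cohort(mk(rep(-1, 5)))
  row <- sm$summary[sm$summary$contrast == "segment", ]
  expect_equal(row$symbol, "o")
  expect_equal(row$favored, "backward")
})

test_that("summary is invariant to participant ordering", {
  set.seed(8)
  comps <- lapply(1:6, function(i)
    mock_comparison(rnorm(1), rnorm(1), rnorm(4)))
  s1 <- summarize_cohort(comps)
  s2 <- summarize_cohort(rev(comps))
  expect_equal(s1$summary, s2$summary)
  expect_equal(s1$lead, s2$lead)
  expect_error(summarize_cohort(comps[1]), "2")
})

test_that("lead cells report which signal leads", {
  comps <- lapply(1:4, function(i)
    mock_comparison(1, 1, c(0.12, -0.2, 0.03, -0.25)))
  sm <- summarize_cohort(comps)
  expect_equal(sm$lead$leads, c("EKG", "LS", "EKG", "LS"))
  expect_true(all(sm$lead$symbol == "o"))
})

test_that("aggregation produces the full cell and delta structure", {
  cfg <- session_config(n_trials = 8, seed = 61)
  m <- analyze_session(generate_session(cfg))
  cp <- aggregate_metrics(m, participant = "P1")
  expect_s3_class(cp, "intent_comparison")
  cells <- c("forward", "backward", "performing", "nonperforming")
  for (met in c("nsr_aa", "nsr_aa_diff", "xcorr_body", "clustering",
                "emd_heart", "xcorr_heart", "lag_heart"))
    expect_setequal(cp$cells$cell[cp$cells$metric == met], cells)
  expect_true(all(c("segment", "side") %in% cp$deltas$contrast))
  expect_true(all(c("segment|performing", "side|backward") %in%
                    cp$deltas$contrast))
  # conditional grid covers segment x side for the heart metrics
  expect_equal(nrow(cp$grid[cp$grid$metric == "emd_heart", ]), 4L)
})

test_that("a symmetric generator yields deltas centered on zero", {
  gp <- default_gamma_params()
  gp$shape <- 400
  gp$scale <- 0.62 / 400
  dd <- vapply(1:5, function(i) {
    cfg <- session_config(
      n_trials = 26, seed = 400 + i, gamma_params = gp,
      coupling = c(forward = 0.7, backward = 0.7),
      side_coupling = c(performing = 0.7, midline = 0.7,
                        nonperforming = 0.7),
      follower_delay_ms = c(performing = 0, midline = 0, nonperforming = 0),
      speed_jitter = c(forward = 0.08, backward = 0.08),
      heart_lead_ms = c(forward = 0, backward = 0))
    cp <- aggregate_metrics(analyze_session(generate_session(cfg)))
    cp$deltas$delta[cp$deltas$metric == "nsr_aa" &
                      cp$deltas$contrast == "segment"]
  }, numeric(1))
  # no systematic sign: mean within 4 standard errors of zero
  expect_lt(abs(mean(dd)) / (sd(dd) / sqrt(length(dd)) + 1e-12), 4)
})
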