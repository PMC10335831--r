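test_that("instant velocity is displacement over the frame interval", {
  traj <- data.frame(t_s = c(0, 2, 4), x_um = c(0, 1, 2), y_um = 0)
  expect_equal(instant_velocity(traj), c(0.5, 0.5))

  static <- data.frame(t_s = c(0, 2, 4, 6), x_um = 1, y_um = 2)
  expect_equal(instant_velocity(static), c(0, 0, 0))

  traj2 <- data.frame(t_s = c(0, 2, 4, 6), x_um = c(0, 0.3, 0.3, 1.5),
                      y_um = 0)
  expect_equal(instant_velocity(traj2), c(0.15, 0, 0.6))

  # 2-D displacement is Euclidean
  diag2 <- data.frame(t_s = c(0, 2), x_um = c(0, 3), y_um = c(0, 4))
  expect_equal(instant_velocity(diag2), 2.5)
})

test_that("non-uniform sampling is rejected naming the offending frame", {
  bad <- data.frame(t_s = c(0, 2, 4, 7), x_um = 0:3, y_um = 0)
  expect_error(instant_velocity(bad), "frame 4",
               class = "mtk_trajectory_error")
  expect_error(instant_velocity(data.frame(t_s = c(0, 2, 2), x_um = 0:2,
                                           y_um = 0)),
               class = "mtk_trajectory_error")
})

test_that("segmentation labels pauses strictly below the speed threshold", {
  p <- segmentation_params()
  seg <- segment_run(c(0.5, 0.1, 0.1, 0.6), p)
  expect_equal(seg$labels, c("transport", "pause", "pause", "transport"))
  expect_equal(nrow(seg$events), 1L)
  expect_equal(seg$events$n_intervals, 2L)

  # all below threshold: one pause spanning the run
  seg2 <- segment_run(rep(0.19, 5), p)
  expect_true(all(seg2$labels == "pause"))
  expect_equal(nrow(seg2$events), 1L)

  # two maximal pause stretches are two events
  seg3 <- segment_run(c(0.1, 0.5, 0.1), p)
  expect_equal(nrow(seg3$events), 2L)

  # boundary: exactly v_pause is transported
  seg4 <- segment_run(c(0.2, 0.19), p)
  expect_equal(seg4$labels, c("transport", "pause"))
})

test_that("run window spans first to last supra-threshold interval", {
  p <- segmentation_params()
  tr <- track_from_speeds(c(0, 0, 0.5, 0.5, 0, 0))
  expect_equal(detect_run_window(tr, p), list(start = 3L, stop = 4L))

  tr_all <- track_from_speeds(rep(0.5, 4))
  expect_equal(detect_run_window(tr_all, p), list(start = 1L, stop = 4L))

  expect_null(detect_run_window(track_from_speeds(rep(0.1, 5)), p))
})

test_that("motility requires strictly more than the distance threshold", {
  p <- segmentation_params()
  expect_true(is_motile(track_from_speeds(rep(0.5, 5)), p))   # 5 um
  # exactly 2.0 um of transport: not motile ("more than 2 um")
  expect_false(is_motile(track_from_speeds(c(0.5, 0.5), p$v_pause), p))
  expect_false(is_motile(track_from_speeds(rep(0.1, 5)), p))  # never motile
})

test_that("transport metrics match their definitions", {
  p <- segmentation_params()
  m <- compute_metrics(track_from_speeds(rep(0.5, 4)), p)
  expect_equal(m$run_length, 4)
  expect_equal(m$run_time, 8)
  expect_equal(m$total_run_velocity, 0.5)
  expect_equal(m$transport_velocity, 0.5)
  expect_equal(m$pausing_time_ratio, 0)
  expect_equal(m$pausing_frequency, 0)

  m2 <- compute_metrics(track_from_speeds(c(0.6, 0.6, 0, 0, 0.6)), p)
  expect_equal(m2$run_length, 3.6)
  expect_equal(m2$run_time, 10)
  expect_equal(m2$total_run_velocity, 0.36)
  expect_equal(m2$transport_velocity, 0.6)
  expect_equal(m2$pausing_time_total, 4)
  expect_equal(m2$pausing_time_ratio, 0.4)
  expect_equal(m2$n_pauses, 1L)
  expect_equal(m2$pausing_frequency, 1 / 3.6)

  expect_error(compute_metrics(track_from_speeds(rep(0.1, 4)), p),
               class = "mtk_never_motile_error")
})

test_that("run time decomposes exactly into pausing and transporting time", {
  p <- segmentation_params()
  set.seed(7)
  for (i in 1:50) {
    speeds <- round(stats::runif(12, 0, 0.8), 3)
    if (max(speeds) < p$v_pause) next
    tr <- track_from_speeds(speeds)
    m <- compute_metrics(tr, p)
    w <- detect_run_window(tr, p)
    seg <- segment_run(tr, p, window = w)
    transporting_time <- sum(seg$labels == "transport") * 2
    expect_equal(m$run_time, m$pausing_time_total + transporting_time,
                 tolerance = 1e-12)
    expect_gte(m$pausing_time_ratio, 0)
    expect_lte(m$pausing_time_ratio, 1)
  }
})

test_that("direction comes from net displacement projected on the axis", {
  fwd <- data.frame(t_s = c(0, 2, 4), x_um = c(0, 3, 6), y_um = 0)
  expect_equal(assign_direction(fwd, c(1, 0)), "anterograde")
  expect_equal(assign_direction(fwd, c(-1, 0)), "retrograde")
  bwd <- data.frame(t_s = c(0, 2, 4), x_um = c(6, 3, 0), y_um = 0)
  expect_equal(assign_direction(bwd, c(1, 0)), "retrograde")
  amb <- data.frame(t_s = c(0, 2, 4), x_um = c(0, 2, 0.2), y_um = 0)
  expect_equal(assign_direction(amb, c(1, 0)), "ambiguous")
  expect_error(assign_direction(fwd, c(0, 0)), class = "mtk_config_error")
})

test_that("kymograph trace has slope = speed and one plateau per pause", {
  tr <- track_from_speeds(rep(0.5, 6))
  ky <- trajectory_kymograph(tr)
  slopes <- diff(ky$d_um) / diff(ky$t_s)
  expect_equal(slopes, rep(0.5, 6))

  tr2 <- track_from_speeds(c(0.6, 0.6, 0, 0, 0.6))
  ky2 <- trajectory_kymograph(tr2)
  expect_equal(nrow(ky2$pauses), 1L)
  expect_equal(ky2$pauses$t_end - ky2$pauses$t_start, 4)
  # plateau count equals n_pauses from the metrics
  m2 <- compute_metrics(tr2)
  expect_equal(nrow(ky2$pauses), m2$n_pauses)
})

test_that("group comparison matches exact enumeration and closed forms", {
  # exact Mann-Whitney on {1,2} vs {3,4}: enumeration gives 1/3
  expect_equal(oracle_mw_p(c(1, 2), c(3, 4)), 1 / 3)
  cmp <- compare_groups(c(1, 2), c(3, 4), test = "mannwhitney")
  expect_equal(cmp$p_value, 1 / 3)

  # SEM of {1,2,3} = 1/sqrt(3)
  cmp2 <- compare_groups(c(1, 2, 3), c(4, 5, 6), test = "t")
  expect_equal(cmp2$sem_a, 1 / sqrt(3))

  # identical groups: p = 1 under the t-test
  cmp3 <- compare_groups(c(1, 2, 3), c(1, 2, 3), test = "t")
  expect_equal(cmp3$p_value, 1)

  # exact MW agrees with enumeration on a larger unbalanced case
  a <- c(0.3, 1.2, 2.2, 2.9)
  b <- c(0.9, 1.7, 3.4, 4.1, 4.4)
  cmp4 <- compare_groups(a, b, test = "mannwhitney")
  expect_equal(cmp4$p_value, oracle_mw_p(a, b))

  expect_error(compare_groups(1, c(1, 2)),
               class = "mtk_insufficient_data_error")
})

test_that("transport_metrics runs window -> segment -> filter per track", {
  sim <- simulate_trajectories(trajectory_sim_config(n_tracks = 6,
                                                     seed = 21))
  res <- transport_metrics(sim$tracks)
  expect_true(all(c("track_id", "run_length", "motile",
                    "direction") %in% names(res)))
  expect_true(all(res$direction %in%
                    c("anterograde", "retrograde", "ambiguous")))
  # a never-motile track is excluded, not errored
  still <- data.frame(track_id = 99, frame = 0:5, t_s = seq(0, 10, 2),
                      x_um = 0.01 * (0:5), y_um = 0)
  res2 <- transport_metrics(rbind(sim$tracks, still))
  expect_true("99" %in% attr(res2, "excluded"))
})
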