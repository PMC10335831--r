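# Streaming: simulator ground truth, kymographs, flow estimation,
# rotation-center fitting, and pattern classification.

make_flow <- function(x, y, vx, vy, h = 80, w = 110) {
  fl <- data.frame(x = x, y = y, vx = vx, vy = vy, peak = 1,
                   pair = 1L)
  fl$speed <- sqrt(fl$vx^2 + fl$vy^2)
  structure(fl, class = c("mtk_flow", "data.frame"), field_dim = c(h, w),
            pixel_size_um = 1, frame_interval_s = 2)
}

test_that("noise-free circular ground-truth velocities are tangential", {
  cfg <- streaming_sim_config(pattern = "circular_central", noise_sd = 0,
                              n_vesicles = 40, duration_s = 20, seed = 1)
  mv <- simulate_streaming_movie(cfg)
  ctr <- mv$truth$center_px
  for (f in c(1, 5, 10)) {
    r <- cbind(mv$truth$positions[, 1, f] - ctr[1],
               mv$truth$positions[, 2, f] - ctr[2])
    v <- mv$truth$velocities[, , f]
    radial <- rowSums(r * v)
    expect_equal(radial, rep(0, nrow(r)), tolerance = 1e-10)
  }
})

test_that("zero angular speed gives a static movie up to rendering noise", {
  cfg <- streaming_sim_config(pattern = "circular_central",
                              angular_speed = 0, noise_sd = 0,
                              n_vesicles = 30, duration_s = 20, seed = 2)
  mv <- simulate_streaming_movie(cfg)
  d <- mv$frames[, , 1] - mv$frames[, , 5]
  # difference contains only the additive camera noise (sd 3 per frame)
  expect_lt(stats::sd(d), 3 * sqrt(2) * 1.1)
  expect_lt(abs(mean(d)), 0.5)
})

test_that("vesicles stay in the field so spot count is conserved", {
  cfg <- streaming_sim_config(pattern = "circular_central",
                              angular_speed = 0.004, n_vesicles = 50,
                              seed = 3)
  mv <- simulate_streaming_movie(cfg)
  pos <- mv$truth$positions
  expect_true(all(pos[, 1, ] >= 1 & pos[, 1, ] <= cfg$field_shape[2]))
  expect_true(all(pos[, 2, ] >= 1 & pos[, 2, ] <= cfg$field_shape[1]))
})

test_that("movie simulation is deterministic and rejects empty movies", {
  cfg <- streaming_sim_config(pattern = "disordered", n_vesicles = 25,
                              duration_s = 20, seed = 4)
  expect_identical(simulate_streaming_movie(cfg),
                   simulate_streaming_movie(cfg))
  expect_error(streaming_sim_config(n_vesicles = 0),
               class = "mtk_empty_movie_error")
})

test_that("kymograph columns are identical for a static movie", {
  frames <- array(rep(matrix(stats::runif(40 * 60), 40, 60), 5),
                  c(40, 60, 5))
  mv <- structure(list(frames = frames, pixel_size_um = 1,
                       frame_interval_s = 2), class = "mtk_movie")
  line <- cbind(seq(5, 55, length.out = 30), seq(5, 35, length.out = 30))
  ky <- build_kymograph(mv, line, width = 3)
  for (f in 2:5) expect_equal(ky$matrix[, f], ky$matrix[, 1])
  expect_error(build_kymograph(mv, cbind(c(-5, 10), c(10, 10))),
               class = "mtk_bounds_error")
})

test_that("a translating spot draws a streak of slope = speed", {
  h <- 40; w <- 80; nf <- 15
  frames <- array(0, c(h, w, nf))
  for (f in 1:nf) {
    frames[, , f] <- mtkit:::render_spots(h, w, 6 + 2 * (f - 1), 20, 2, 100)
  }
  mv <- structure(list(frames = frames, pixel_size_um = 1,
                       frame_interval_s = 1), class = "mtk_movie")
  ky <- build_kymograph(mv, cbind(seq(2, 78, 1), 20), width = 1)
  peak_pos <- ky$s_px[apply(ky$matrix, 2, which.max)]
  slope <- stats::coef(stats::lm(peak_pos ~ seq_len(nf)))[[2]]
  expect_lt(abs(slope - 2), 1)  # within +-1 px/frame discretization
  # width 1 on the line equals direct pixel sampling
  row20 <- frames[20, 2:78, 1]
  expect_equal(ky$matrix[seq_along(row20), 1], row20, tolerance = 1e-9)
})

test_that("flow estimation recovers pure translation exactly", {
  set.seed(5)
  h <- 64; w <- 96
  base <- matrix(0, h, w)
  xs <- stats::runif(60, 5, w - 10)
  ys <- stats::runif(60, 5, h - 5)
  frames <- array(0, c(h, w, 5))
  for (f in 1:5) {
    frames[, , f] <- mtkit:::render_spots(h, w, xs + 2 * (f - 1), ys, 2, 100)
  }
  mv <- structure(list(frames = frames, pixel_size_um = 1,
                       frame_interval_s = 1), class = "mtk_movie")
  fl <- estimate_flow(mv, patch_px = 16, step_px = 8, search_px = 4,
                      frame_lag = 1, pair_step = 1)
  expect_gt(nrow(fl), 10)
  dx <- fl$vx  # px/frame since pixel_size = frame_interval factor = 1
  modal <- as.integer(names(sort(table(dx), decreasing = TRUE))[1])
  expect_equal(modal, 2L)
  # static movie: all retained velocities are zero
  frames0 <- array(rep(frames[, , 1], 3), c(h, w, 3))
  mv0 <- structure(list(frames = frames0, pixel_size_um = 1,
                        frame_interval_s = 1), class = "mtk_movie")
  fl0 <- estimate_flow(mv0, patch_px = 16, step_px = 8, search_px = 4,
                       frame_lag = 1, pair_step = 1)
  expect_true(all(fl0$speed == 0))
})

test_that("rotation-center fit recovers analytic fields", {
  set.seed(6)
  x <- stats::runif(150, 0, 110); y <- stats::runif(150, 0, 80)
  fl <- make_flow(x, y, -(y - 40), (x - 55))
  fit <- fit_rotation_center(fl)
  expect_lt(sqrt(sum((fit$center - c(55, 40))^2)), 0.02 * 110)
  expect_gt(fit$kappa, 0.95)

  # i.i.d. random directions: kappa ~ 1/sqrt(n)
  a <- stats::runif(200, 0, 2 * pi)
  fr <- make_flow(stats::runif(200, 0, 110), stats::runif(200, 0, 80),
                  cos(a), sin(a))
  expect_lt(fit_rotation_center(fr)$kappa, 0.2)

  # counter-rotating halves about a shared center: the tangential signs
  # cancel, so kappa is near zero despite perfect local order
  xc <- stats::runif(200, 0, 110); yc <- stats::runif(200, 0, 80)
  sgn <- ifelse(xc < stats::median(xc), 1, -1)
  fc <- make_flow(xc, yc, -sgn * (yc - 40), sgn * (xc - 55))
  expect_lt(fit_rotation_center(fc)$kappa, 0.1)
})

test_that("center fit is translation-equivariant and kappa scale-free", {
  set.seed(7)
  x <- stats::runif(120, 0, 100); y <- stats::runif(120, 0, 70)
  fl <- make_flow(x, y, -(y - 30), (x - 45))
  f1 <- fit_rotation_center(fl)
  shift <- c(13.5, -7.25)
  fl2 <- make_flow(x + shift[1], y + shift[2], -(y - 30), (x - 45))
  f2 <- fit_rotation_center(fl2)
  expect_equal(f2$center, f1$center + shift, tolerance = 1e-3)
  fl3 <- make_flow(x, y, -3.7 * (y - 30), 3.7 * (x - 45))
  expect_equal(fit_rotation_center(fl3)$kappa, f1$kappa, tolerance = 1e-6)
})

test_that("simulated patterns classify to their taxonomy labels", {
  for (pat in names(expected_call)) {
    cl <- classify_movie(pat, seed = 101)
    expect_equal(cl$pattern, unname(expected_call[pat]),
                 label = sprintf("pattern %s", pat))
  }
  # anterior-biased center recovered within 5% of the AP length
  mv <- simulate_streaming_movie(
    streaming_sim_config(pattern = "circular_anterior_biased", seed = 102))
  cl <- classify_streaming(estimate_flow(mv))
  expect_lt(abs(cl$center_frac_ap - 0.3), 0.05)
})

test_that("pattern percentages reproduce published rounding", {
  calls <- data.frame(
    genotype = c(rep("control", 17), rep("rescued", 7), rep("mutant", 21)),
    pattern = c(rep("circular_central", 17),
                rep(c("circular_central", "abnormal_chaotic"), c(5, 2)),
                rep(c("abnormal_chaotic", "abnormal_partial",
                      "circular_central"), c(8, 8, 5))))
  s <- summarize_patterns(calls)
  expect_equal(s$pct_circular[s$genotype == "control"], 100)  # 17/17
  expect_equal(s$pct_circular[s$genotype == "rescued"], 71)   # 5/7
  expect_equal(s$pct_abnormal[s$genotype == "mutant"], 76)    # 16/21
  expect_equal(s$n, c(17L, 7L, 21L))
})

test_that("cortical unidirectionality separates one-way from balanced", {
  h <- 30; w <- 90; nf <- 12
  one_way <- array(0, c(h, w, nf))
  both <- array(0, c(h, w, nf))
  for (f in 1:nf) {
    xs <- c(10, 30, 50) + 2 * (f - 1)
    one_way[, , f] <- mtkit:::render_spots(h, w, xs, rep(15, 3), 2, 100)
    both[, , f] <- mtkit:::render_spots(h, w, c(xs, 80 - xs),
                                        rep(15, 6), 2, 100)
  }
  line <- cbind(seq(2, 88, 1), 15)
  u1 <- cortical_unidirectionality(build_kymograph(
    structure(list(frames = one_way, pixel_size_um = 1,
                   frame_interval_s = 1), class = "mtk_movie"), line))
  expect_gt(u1$fraction, 0.9)
  u2 <- cortical_unidirectionality(build_kymograph(
    structure(list(frames = both, pixel_size_um = 1,
                   frame_interval_s = 1), class = "mtk_movie"), line))
  expect_lt(u2$fraction, 0.65)
  expect_warning(
    u3 <- cortical_unidirectionality(matrix(5, 20, 10)), "featureless")
  expect_true(is.na(u3$fraction))
})

test_that("movies round-trip through 16-bit TIFF", {
  mv <- simulate_streaming_movie(
    streaming_sim_config(n_vesicles = 20, duration_s = 8, seed = 9))
  path <- withr::local_tempfile(fileext = ".tif")
  write_movie_tiff(mv, path)
  back <- read_movie_tiff(path, pixel_size_um = mv$pixel_size_um,
                          frame_interval_s = mv$frame_interval_s)
  expect_equal(dim(back$frames), dim(mv$frames))
  # 16-bit quantization of the 0..4096 scale is 0.0625 counts
  expect_lt(max(abs(back$frames - mv$frames)), 0.07)
})
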