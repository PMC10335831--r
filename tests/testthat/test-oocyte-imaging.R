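# Oocyte image quantification: crescent length, AP profiles, inner
# peaks, and the posterior-enrichment call, validated against the
# generator's ground truth.

test_that("crescent length round-trips within 10% of the true arc", {
  for (arc in c(40, 80)) {
    sim <- simulate_oocyte_image(oocyte_sim_config(crescent_arc_um = arc,
                                                   seed = arc))
    got <- measure_crescent_length(sim$image, sim$geometry)
    expect_lt(abs(got - arc), 0.1 * arc)
  }
})

test_that("a contrast-free cortex measures zero crescent", {
  sim <- simulate_oocyte_image(oocyte_sim_config(crescent_amplitude = 0,
                                                 noise_sd = 0, seed = 1))
  uniform <- matrix(50, nrow(sim$image), ncol(sim$image))
  expect_warning(len <- measure_crescent_length(uniform, sim$geometry),
                 "crescent length 0")
  expect_equal(len, 0)
})

test_that("the longest contiguous bright arc wins", {
  sim <- simulate_oocyte_image(oocyte_sim_config(crescent_amplitude = 0,
                                                 noise_sd = 0, seed = 2))
  geom <- sim$geometry
  rp <- mtkit:::resample_polyline(geom$cortex, step = 1)
  img <- sim$image
  paint <- function(img, s_lo, s_hi) {
    sel <- rp$s * geom$pixel_size_um >= s_lo &
      rp$s * geom$pixel_size_um <= s_hi
    img + mtkit:::render_spots(nrow(img), ncol(img), rp$x[sel], rp$y[sel],
                               2, 200 / (2 * sqrt(2 * pi)))
  }
  # two disjoint arcs: 30 um and 10 um
  img <- paint(img, 100, 130)
  img <- paint(img, 200, 210)
  got <- measure_crescent_length(img, geom)
  expect_lt(abs(got - 30), 4)
})

test_that("crescent length is monotone in the generated arc", {
  lens <- vapply(c(20, 40, 60, 90), function(arc) {
    sim <- simulate_oocyte_image(oocyte_sim_config(
      crescent_arc_um = arc, noise_sd = 5, seed = 77))
    measure_crescent_length(sim$image, sim$geometry)
  }, numeric(1))
  expect_true(all(diff(lens) > 0))
})

test_that("crescent length in um is invariant to pixel size", {
  coarse <- simulate_oocyte_image(oocyte_sim_config(
    image_shape = c(200, 260), pixel_size_um = 0.5,
    crescent_arc_um = 40, seed = 5))
  fine <- simulate_oocyte_image(oocyte_sim_config(
    image_shape = c(400, 520), pixel_size_um = 0.25,
    crescent_arc_um = 40, seed = 5))
  l1 <- measure_crescent_length(coarse$image, coarse$geometry)
  l2 <- measure_crescent_length(fine$image, fine$geometry)
  expect_lt(abs(l1 - l2), 0.1 * 40)
})

test_that("AP profiles are flat on uniform images and peak where built", {
  sim <- simulate_oocyte_image(oocyte_sim_config(
    crescent_amplitude = 0, noise_sd = 0, seed = 3))
  geom <- sim$geometry
  uni <- matrix(7, nrow(sim$image), ncol(sim$image))
  pr_u <- ap_profile(uni, geom)
  expect_equal(pr_u$intensity, rep(7, length(pr_u$intensity)))

  sim_pk <- simulate_oocyte_image(oocyte_sim_config(
    crescent_amplitude = 0, inner_peaks = list(c(0.6, 120, 8)),
    noise_sd = 0, seed = 4))
  pr <- ap_profile(sim_pk$image, sim_pk$geometry)
  expect_lt(abs(pr$ap_fraction[which.max(pr$intensity)] - 0.6), 0.02)

  # width 1 equals single-line sampling
  geom1 <- sim_pk$geometry
  geom1$line_width <- 1L
  pr1 <- ap_profile(sim_pk$image, geom1)
  y0 <- geom1$ap_line[1, 2]
  xs <- geom1$ap_line[1, 1] + pr1$ap_fraction *
    (geom1$ap_line[2, 1] - geom1$ap_line[1, 1])
  direct <- mtkit:::bilinear_sample(sim_pk$image, xs, rep(y0, length(xs)))
  expect_equal(pr1$intensity, unname(direct), tolerance = 1e-9)
})

test_that("inner peaks classify into none / single / double", {
  one <- simulate_oocyte_image(oocyte_sim_config(
    inner_peaks = list(c(0.55, 120, 8)), seed = 6))
  pk1 <- detect_inner_peaks(ap_profile(one$image, one$geometry))
  expect_equal(pk1$classification, "single_central")
  expect_equal(nrow(pk1$peaks), 1L)
  expect_lt(abs(pk1$peaks$ap_fraction - 0.55), 0.02)

  ant <- simulate_oocyte_image(oocyte_sim_config(
    inner_peaks = list(c(0.3, 120, 8)), seed = 7))
  expect_equal(detect_inner_peaks(
    ap_profile(ant$image, ant$geometry))$classification, "single_anterior")

  two <- simulate_oocyte_image(oocyte_sim_config(
    inner_peaks = list(c(0.3, 120, 8), c(0.75, 120, 8)), seed = 8))
  pk2 <- detect_inner_peaks(ap_profile(two$image, two$geometry))
  expect_equal(pk2$classification, "double_peak")
  expect_equal(pk2$peaks$ap_fraction, c(0.3, 0.75), tolerance = 0.1)

  # a flat noisy profile has no peaks: the relative-prominence rule is
  # backed by a noise floor on the profile's MAD
  flat <- simulate_oocyte_image(oocyte_sim_config(
    crescent_amplitude = 0, noise_sd = 5, seed = 9))
  flat_img <- matrix(100, nrow(flat$image), ncol(flat$image)) +
    matrix(stats::rnorm(length(flat$image), 0, 5), nrow(flat$image))
  expect_equal(detect_inner_peaks(
    ap_profile(flat_img, flat$geometry))$classification, "none")
})

test_that("posterior enrichment is called by the band/rest ratio", {
  post <- simulate_oocyte_image(oocyte_sim_config(seed = 10))
  expect_true(call_posterior_enrichment(post$image,
                                        post$geometry)$enriched)
  flat <- simulate_oocyte_image(oocyte_sim_config(crescent_amplitude = 0,
                                                  seed = 11))
  expect_false(call_posterior_enrichment(flat$image,
                                         flat$geometry)$enriched)
  ant <- simulate_oocyte_image(oocyte_sim_config(
    crescent_center_arc_frac = 0.02, seed = 12))
  expect_false(call_posterior_enrichment(ant$image,
                                         ant$geometry)$enriched)
})

test_that("positive-call percentages use half-up rounding", {
  s <- summarize_fractions(rep(c(TRUE, FALSE), c(28, 9)))
  expect_equal(s$pct_positive, 76)  # 28 of 37
  expect_equal(s$n, 37L)
  s0 <- summarize_fractions(rep(FALSE, 10))
  expect_equal(s0$pct_positive, 0)
})

test_that("cohorts with different true arcs separate at alpha 0.005", {
  arcs_a <- vapply(1:15, function(i) {
    sim <- simulate_oocyte_image(oocyte_sim_config(
      crescent_arc_um = 40, seed = 300 + i))
    measure_crescent_length(sim$image, sim$geometry)
  }, numeric(1))
  arcs_b <- vapply(1:15, function(i) {
    sim <- simulate_oocyte_image(oocyte_sim_config(
      crescent_arc_um = 80, seed = 400 + i))
    measure_crescent_length(sim$image, sim$geometry)
  }, numeric(1))
  cmp <- compare_groups(arcs_a, arcs_b, test = "mannwhitney")
  expect_lt(cmp$p_value, 0.005)
})

test_that("geometry round-trips through JSON", {
  sim <- simulate_oocyte_image(oocyte_sim_config(seed = 13))
  path <- withr::local_tempfile(fileext = ".json")
  write_geometry_json(sim$geometry, path)
  back <- read_geometry_json(path)
  expect_equal(back$cortex, unname(as.matrix(sim$geometry$cortex)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$pixel_size_um, sim$geometry$pixel_size_um)
})

test_that("invalid oocyte configurations are rejected", {
  expect_error(simulate_oocyte_image(oocyte_sim_config(
    crescent_arc_um = 1e5)), class = "mtk_config_error")
  expect_error(oocyte_sim_config(inner_peaks = list(c(1.5, 10, 5))),
               class = "mtk_config_error")
})
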