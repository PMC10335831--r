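# Synthetic ooplasmic-streaming movies: vesicles advected by a
# configurable flow pattern and rendered as Gaussian spots, frame every
# 2 s for 2 min by default (bright-field-like time lapse of a stage 10B
# oocyte).

#' Configuration for the streaming movie simulator
#'
#' The anterior-posterior (AP) axis runs along image columns (x), with
#' the anterior at x = 0.  Four flow patterns are available:
#' \describe{
#'   \item{circular_central}{rigid rotation about a center at
#'     `center_frac_ap` of the AP length (default 0.5).}
#'   \item{circular_anterior_biased}{same, with the center shifted
#'     anteriorly (default `center_frac_ap = 0.3`).}
#'   \item{disordered}{a frozen random direction per spatial patch;
#'     vesicles follow the local direction at a speed comparable to the
#'     circular tangential speeds and reflect at the field border.}
#'   \item{partial_posterior_disrupted}{rigid rotation in the anterior
#'     60% of the field, with all coherent flow zeroed in the
#'     posterior 40% (vesicles there only jitter with noise).}
#' }
#'
#' @param field_shape Integer `c(height, width)` in pixels.
#' @param n_vesicles Number of vesicles (must be > 0).
#' @param pattern Flow pattern, see above.
#' @param center_frac_ap Rotation-center x-position as a fraction of
#'   the AP (width) extent; defaults to 0.5 for `circular_central` and
#'   0.3 for `circular_anterior_biased`.
#' @param angular_speed Rotation rate in rad/s (0.012 rad/s gives
#'   tangential speeds of ~0.36 um/s at a 30 um radius, in the range of
#'   fast streaming).
#' @param noise_sd SD of the random velocity component (um/s).
#' @param frame_interval_s Seconds between frames.
#' @param duration_s Movie duration in seconds.
#' @param pixel_size_um Pixel size (um).
#' @param spot_sigma_px Gaussian spot width (px) used for rendering.
#' @param seed Integer seed; fixed seed gives bit-identical movies.
#' @return Object of class `mtk_streaming_sim_config`.
#' @export
streaming_sim_config <- function(field_shape = c(80L, 110L),
                                 n_vesicles = 120L,
                                 pattern = c("circular_central",
                                             "circular_anterior_biased",
                                             "disordered",
                                             "partial_posterior_disrupted"),
                                 center_frac_ap = NULL,
                                 angular_speed = 0.012,
                                 noise_sd = 0.08,
                                 frame_interval_s = 2,
                                 duration_s = 120,
                                 pixel_size_um = 1,
                                 spot_sigma_px = 2,
                                 seed = 1L) {
  pattern <- match.arg(pattern)
  if (length(field_shape) != 2L || any(field_shape < 32)) {
    stop_mtk("field_shape must be c(height, width), each >= 32 px",
             "mtk_config_error")
  }
  check_count(n_vesicles, "n_vesicles", min = 0L)
  if (n_vesicles == 0L) {
    stop_mtk("n_vesicles must be positive (empty movie)",
             "mtk_empty_movie_error")
  }
  if (is.null(center_frac_ap)) {
    center_frac_ap <- if (pattern == "circular_anterior_biased") 0.3 else 0.5
  }
  check_prob(center_frac_ap, "center_frac_ap")
  check_positive(angular_speed, "angular_speed", strict = FALSE)
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  check_positive(frame_interval_s, "frame_interval_s")
  check_positive(duration_s, "duration_s")
  check_positive(pixel_size_um, "pixel_size_um")
  structure(list(field_shape = as.integer(field_shape),
                 n_vesicles = as.integer(n_vesicles),
                 pattern = pattern, center_frac_ap = center_frac_ap,
                 angular_speed = angular_speed, noise_sd = noise_sd,
                 frame_interval_s = frame_interval_s,
                 duration_s = duration_s, pixel_size_um = pixel_size_um,
                 spot_sigma_px = spot_sigma_px, seed = as.integer(seed)),
            class = "mtk_streaming_sim_config")
}

render_spots <- function(h, w, xs, ys, sigma, amplitude) {
  img <- matrix(0, h, w)
  ys <- rep(ys, length.out = length(xs))
  r <- ceiling(3 * sigma)
  for (i in seq_along(xs)) {
    x <- xs[i]; y <- ys[i]
    if (x < 1 - r || x > w + r || y < 1 - r || y > h + r) next
    cx0 <- max(1L, floor(x) - r); cx1 <- min(w, floor(x) + r + 1L)
    cy0 <- max(1L, floor(y) - r); cy1 <- min(h, floor(y) + r + 1L)
    if (cx0 > cx1 || cy0 > cy1) next
    gx <- exp(-((cx0:cx1) - x)^2 / (2 * sigma^2))
    gy <- exp(-((cy0:cy1) - y)^2 / (2 * sigma^2))
    img[cy0:cy1, cx0:cx1] <- img[cy0:cy1, cx0:cx1] +
      amplitude * outer(gy, gx)
  }
  img
}

#' Simulate an ooplasmic streaming movie
#'
#' Advects vesicles under the configured flow pattern and renders each
#' frame as a sum of Gaussian spots over a constant background with
#' light camera noise.  Ground truth (vesicle positions, instantaneous
#' coherent-flow velocities, rotation center, pattern label) is
#' returned alongside the frames.
#'
#' @param cfg A [streaming_sim_config()].
#' @return Object of class `mtk_movie`: a list with `frames` (array
#'   `height x width x n_frames`), `pixel_size_um`,
#'   `frame_interval_s`, and `truth` (list with `pattern`, `center_px`,
#'   `positions` (`n_vesicles x 2 x n_frames`, columns x,y in px), and
#'   `velocities` (`n_vesicles x 2 x n_frames`, um/s, the coherent
#'   component only)).
#' @export
simulate_streaming_movie <- function(cfg) {
  stopifnot(inherits(cfg, "mtk_streaming_sim_config"))
  set.seed(cfg$seed)
  h <- cfg$field_shape[1]; w <- cfg$field_shape[2]
  dt <- cfg$frame_interval_s
  n_frames <- as.integer(round(cfg$duration_s / dt)) + 1L
  center <- c(cfg$center_frac_ap * w, h / 2)
  margin <- 4
  n <- cfg$n_vesicles

  xs <- stats::runif(n, margin, w - margin)
  ys <- stats::runif(n, margin, h - margin)

  # frozen per-patch random directions for the disordered pattern
  patch <- 20
  npx <- ceiling(w / patch); npy <- ceiling(h / patch)
  ang <- matrix(stats::runif(npx * npy, 0, 2 * pi), npy, npx)
  v_dis <- cfg$angular_speed * min(h, w) / 4 * cfg$pixel_size_um  # um/s

  posterior_x0 <- 0.6 * w  # coherent flow zeroed beyond this for 'partial'
  omega <- cfg$angular_speed
  noise_px <- cfg$noise_sd * dt / cfg$pixel_size_um

  positions <- array(NA_real_, c(n, 2, n_frames))
  velocities <- array(0, c(n, 2, n_frames))
  frames <- array(0, c(h, w, n_frames))

  coherent_velocity <- function(x, y) {
    # instantaneous coherent velocity in um/s at px position (x, y)
    switch(cfg$pattern,
      circular_central = ,
      circular_anterior_biased = {
        rx <- x - center[1]; ry <- y - center[2]
        cbind(-omega * ry, omega * rx) * cfg$pixel_size_um
      },
      disordered = {
        i <- pmin(pmax(ceiling(y / patch), 1), npy)
        j <- pmin(pmax(ceiling(x / patch), 1), npx)
        a <- ang[cbind(i, j)]
        cbind(cos(a), sin(a)) * v_dis
      },
      partial_posterior_disrupted = {
        rx <- x - center[1]; ry <- y - center[2]
        v <- cbind(-omega * ry, omega * rx) * cfg$pixel_size_um
        v[x >= posterior_x0, ] <- 0
        v
      })
  }

  for (f in seq_len(n_frames)) {
    positions[, 1, f] <- xs
    positions[, 2, f] <- ys
    vel <- coherent_velocity(xs, ys)
    velocities[, , f] <- vel
    frames[, , f] <- render_spots(h, w, xs, ys, cfg$spot_sigma_px, 400) +
      100 + matrix(stats::rnorm(h * w, 0, 3), h, w)
    if (f < n_frames) {
      if (cfg$pattern %in% c("circular_central",
                             "circular_anterior_biased")) {
        # exact rigid rotation keeps radii constant
        th <- omega * dt
        rx <- xs - center[1]; ry <- ys - center[2]
        xs <- center[1] + cos(th) * rx - sin(th) * ry
        ys <- center[2] + sin(th) * rx + cos(th) * ry
      } else if (cfg$pattern == "partial_posterior_disrupted") {
        th <- omega * dt
        rot <- xs < posterior_x0
        rx <- xs[rot] - center[1]; ry <- ys[rot] - center[2]
        xs[rot] <- center[1] + cos(th) * rx - sin(th) * ry
        ys[rot] <- center[2] + sin(th) * rx + cos(th) * ry
      } else {
        xs <- xs + vel[, 1] * dt / cfg$pixel_size_um
        ys <- ys + vel[, 2] * dt / cfg$pixel_size_um
      }
      if (noise_px > 0) {
        xs <- xs + stats::rnorm(n, 0, noise_px)
        ys <- ys + stats::rnorm(n, 0, noise_px)
      }
      # reflect at the border so vesicle density stays constant
      xs <- pmin(pmax(xs, 2 * margin - xs), 2 * (w - margin) - xs)
      ys <- pmin(pmax(ys, 2 * margin - ys), 2 * (h - margin) - ys)
      xs <- pmin(pmax(xs, 1), w)
      ys <- pmin(pmax(ys, 1), h)
    }
  }
  structure(list(frames = frames, pixel_size_um = cfg$pixel_size_um,
                 frame_interval_s = cfg$frame_interval_s,
                 truth = list(pattern = cfg$pattern, center_px = center,
                              center_frac_ap = cfg$center_frac_ap,
                              positions = positions,
                              velocities = velocities),
                 config = cfg),
            class = "mtk_movie")
}

#' Write a movie as a 16-bit multi-page TIFF
#'
#' Intensities are scaled by `scale` to the 16-bit range; the scale is
#' recorded nowhere in the file, so pass the same value to
#' [read_movie_tiff()] for a round trip in original units.
#'
#' @param movie `mtk_movie` object or plain `h x w x t` array.
#' @param path Output path.
#' @param scale Counts mapped to the full 16-bit range.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, scale = 4096) {
  frames <- if (inherits(movie, "mtk_movie")) movie$frames else movie
  pages <- lapply(seq_len(dim(frames)[3]), function(f) {
    pmin(pmax(frames[, , f] / scale, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as a movie array
#'
#' @param path TIFF file path.
#' @param pixel_size_um,frame_interval_s Acquisition metadata to attach.
#' @param scale Inverse of the scale used when writing.
#' @return `mtk_movie` object (without ground truth).
#' @export
read_movie_tiff <- function(path, pixel_size_um = 1, frame_interval_s = 2,
                            scale = 4096) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (f in seq_along(pages)) {
    pg <- pages[[f]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]
    frames[, , f] <- pg * scale
  }
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s, truth = NULL),
            class = "mtk_movie")
}
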