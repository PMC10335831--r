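# Synthetic single-plane oocyte images: an elliptical oocyte with a
# cortical crescent of configurable arc length and optional inner
# intensity peaks along the AP axis, plus the matching geometry
# (cortex polyline and AP axis line).

#' Configuration for the oocyte image simulator
#'
#' The oocyte is an ellipse inscribed in the image; the anterior pole
#' is at the left end of the horizontal AP axis.  The cortical crescent
#' is a constant-intensity arc of length `crescent_arc_um` centered at
#' `crescent_center_arc_frac` of the cortex arc length (default: the
#' posterior pole), rendered as a Gaussian ridge of transverse width
#' ~2 px.  Inner peaks are isotropic Gaussians centered on the AP axis.
#'
#' @param image_shape `c(height, width)` in px.
#' @param pixel_size_um Pixel size (um).
#' @param crescent_arc_um Crescent arc length (um); must be shorter
#'   than the full cortex.
#' @param crescent_center_arc_frac Arc position of the crescent center
#'   as a fraction of total cortex length (`NULL` = posterior pole).
#' @param crescent_amplitude Peak crescent intensity above background.
#' @param inner_peaks List of `c(ap_fraction, amplitude, width_um)`
#'   triples.
#' @param background Intensity inside the oocyte.
#' @param noise_sd Gaussian noise SD.
#' @param seed Integer seed.
#' @return Object of class `mtk_oocyte_sim_config`.
#' @export
oocyte_sim_config <- function(image_shape = c(200L, 260L),
                              pixel_size_um = 0.5,
                              crescent_arc_um = 40,
                              crescent_center_arc_frac = NULL,
                              crescent_amplitude = 200,
                              inner_peaks = list(),
                              background = 100,
                              noise_sd = 5,
                              seed = 1L) {
  if (length(image_shape) != 2L || any(image_shape < 64)) {
    stop_mtk("image_shape must be c(height, width), each >= 64 px",
             "mtk_config_error")
  }
  check_positive(pixel_size_um, "pixel_size_um")
  check_positive(crescent_arc_um, "crescent_arc_um", strict = FALSE)
  check_positive(crescent_amplitude, "crescent_amplitude", strict = FALSE)
  check_positive(background, "background", strict = FALSE)
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  for (p in inner_peaks) {
    if (length(p) != 3L || p[1] < 0 || p[1] > 1 || p[3] <= 0) {
      stop_mtk(paste("each inner peak must be",
                     "c(ap_fraction in [0,1], amplitude, width_um > 0)"),
               "mtk_config_error")
    }
  }
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size_um = pixel_size_um,
                 crescent_arc_um = crescent_arc_um,
                 crescent_center_arc_frac = crescent_center_arc_frac,
                 crescent_amplitude = crescent_amplitude,
                 inner_peaks = inner_peaks, background = background,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "mtk_oocyte_sim_config")
}

ellipse_cortex <- function(h, w, n = 256L) {
  cx <- (w + 1) / 2
  cy <- (h + 1) / 2
  a <- w / 2 - 10
  b <- h / 2 - 10
  # start at the anterior pole (theta = pi) so the posterior crescent
  # does not wrap around the parameterization origin
  th <- seq(pi, pi + 2 * pi, length.out = n + 1L)
  cbind(x = cx + a * cos(th), y = cy + b * sin(th))
}

#' Simulate a single-plane oocyte image with geometry
#'
#' @param cfg An [oocyte_sim_config()].
#' @return List of class `mtk_oocyte_sim` with `image` (matrix),
#'   `geometry` (an [oocyte_geometry()]), and `truth` (crescent arc
#'   length in um, crescent center arc fraction, inner peak AP
#'   fractions).
#' @export
simulate_oocyte_image <- function(cfg) {
  stopifnot(inherits(cfg, "mtk_oocyte_sim_config"))
  set.seed(cfg$seed)
  h <- cfg$image_shape[1]; w <- cfg$image_shape[2]
  cortex <- ellipse_cortex(h, w)
  rp <- resample_polyline(cortex, step = 1)
  cortex_um <- rp$total * cfg$pixel_size_um
  if (cfg$crescent_arc_um >= cortex_um) {
    stop_mtk(sprintf("crescent (%g um) must be shorter than the cortex (%g um)",
                     cfg$crescent_arc_um, cortex_um), "mtk_config_error")
  }
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  a <- w / 2 - 10; b <- h / 2 - 10
  img <- matrix(0, h, w)

  # interior fill
  xg <- matrix(rep(seq_len(w), each = h), h, w)
  yg <- matrix(rep(seq_len(h), times = w), h, w)
  inside <- ((xg - cx) / a)^2 + ((yg - cy) / b)^2 <= 1
  img[inside] <- cfg$background

  # cortical crescent: Gaussian ridge along an arc window
  center_frac <- cfg$crescent_center_arc_frac %||% 0.5  # posterior pole
  center_s <- center_frac * rp$total
  half_px <- (cfg$crescent_arc_um / cfg$pixel_size_um) / 2
  in_arc <- abs(rp$s - center_s) <= half_px
  if (any(in_arc) && cfg$crescent_amplitude > 0) {
    sigma <- 2
    stamp_amp <- cfg$crescent_amplitude / (sigma * sqrt(2 * pi))
    img <- img + render_spots(h, w, rp$x[in_arc], rp$y[in_arc],
                              sigma, stamp_amp)
  }

  # inner peaks on the AP axis
  ap_a <- c(cx - a, cy)
  ap_p <- c(cx + a, cy)
  for (p in cfg$inner_peaks) {
    px <- ap_a[1] + p[1] * (ap_p[1] - ap_a[1])
    sig <- p[3] / cfg$pixel_size_um
    g <- p[2] * exp(-((xg - px)^2 + (yg - cy)^2) / (2 * sig^2))
    img <- img + g
  }

  if (cfg$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(h * w, 0, cfg$noise_sd), h, w)
  }
  geometry <- oocyte_geometry(cortex = cortex,
                              ap_line = rbind(ap_a, ap_p),
                              pixel_size_um = cfg$pixel_size_um)
  structure(list(image = img, geometry = geometry,
                 truth = list(
                   crescent_arc_um = cfg$crescent_arc_um,
                   crescent_center_arc_frac = center_frac,
                   inner_peak_ap = vapply(cfg$inner_peaks, `[`,
                                          numeric(1), 1L),
                   cortex_length_um = cortex_um),
                 config = cfg),
            class = "mtk_oocyte_sim")
}

#' Write a single-plane image as 16-bit TIFF
#'
#' @param image Numeric matrix.
#' @param path Output path.
#' @param scale Counts mapped to the full 16-bit range.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path, scale = 4096) {
  tiff::writeTIFF(pmin(pmax(image / scale, 0), 1), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Read a single-plane TIFF image
#'
#' @param path TIFF file path.
#' @param scale Inverse of the scale used when writing.
#' @return Numeric matrix.
#' @export
read_image_tiff <- function(path, scale = 4096) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img * scale
}
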