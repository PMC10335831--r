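# Oocyte image quantification: crescent length along the cortex,
# AP-axis band intensity profiles, inner-peak detection, and the
# posterior-enrichment call.

#' Oocyte measurement geometry
#'
#' @param cortex `n x 2` matrix of cortex polyline vertices (x, y in
#'   px).  A closed cortex (first ~ last vertex) is handled circularly
#'   when measuring arcs.
#' @param ap_line `2 x 2` matrix: anterior endpoint first, posterior
#'   second.
#' @param line_width Band width in px for the AP profile (the
#'   measurement tool's "50 units").
#' @param pixel_size_um Pixel size (um).
#' @return Object of class `mtk_oocyte_geometry`.
#' @export
oocyte_geometry <- function(cortex, ap_line, line_width = 50L,
                            pixel_size_um = 0.5) {
  cortex <- as.matrix(cortex)
  ap_line <- as.matrix(ap_line)
  if (ncol(cortex) != 2L || nrow(cortex) < 3L) {
    stop_mtk("cortex must be an n x 2 polyline with n >= 3",
             "mtk_config_error")
  }
  if (!all(dim(ap_line) == c(2L, 2L))) {
    stop_mtk("ap_line must be a 2 x 2 matrix (anterior first)",
             "mtk_config_error")
  }
  check_positive(pixel_size_um, "pixel_size_um")
  structure(list(cortex = cortex, ap_line = ap_line,
                 line_width = as.integer(line_width),
                 pixel_size_um = pixel_size_um),
            class = "mtk_oocyte_geometry")
}

is_closed_polyline <- function(poly, tol = 2) {
  sqrt(sum((poly[1, ] - poly[nrow(poly), ])^2)) <= tol
}

#' Measure the cortical crescent length
#'
#' Samples the image in a thin band along the cortex polyline,
#' subtracts the median cortical intensity as background, and returns
#' the arc length (um) of the longest contiguous stretch whose
#' intensity reaches `threshold_frac` of the background-subtracted
#' peak.  On a closed cortex the stretch may wrap around the polyline
#' origin.  A shorter crescent indicates tighter posterior
#' localization.
#'
#' @param image Numeric matrix (single plane; apply a max-projection
#'   first if starting from a stack).
#' @param geometry [oocyte_geometry()].
#' @param threshold_frac Fraction of (peak - background) that counts as
#'   crescent signal (default 0.5, half-max).
#' @param band_width Sampling band width in px across the cortex line.
#' @return Crescent length in um (0, with a warning, when the cortex
#'   shows no contrast above threshold).
#' @export
measure_crescent_length <- function(image, geometry, threshold_frac = 0.5,
                                    band_width = 5L) {
  bp <- band_profile(image, geometry$cortex, width = band_width)
  intens <- bp$intensity
  bg <- stats::median(intens)
  peak <- max(intens)
  if (peak <= bg) {
    warning("no cortical intensity above background; crescent length 0",
            call. = FALSE)
    return(0)
  }
  thr <- bg + threshold_frac * (peak - bg)
  above <- intens >= thr
  if (!any(above)) {
    warning("no cortical pixel above threshold; crescent length 0",
            call. = FALSE)
    return(0)
  }
  closed <- is_closed_polyline(geometry$cortex)
  if (closed && all(above)) {
    return(bp$s[length(bp$s)] * geometry$pixel_size_um)
  }
  runs <- if (closed) rle(c(above, above)) else rle(above)
  len <- max(runs$lengths[runs$values])
  if (closed) len <- min(len, length(above))
  # arc step is 1 px; a run of k samples spans k-1 steps plus the two
  # half-steps at its ends
  len * 1 * geometry$pixel_size_um
}

#' Intensity profile along the AP axis
#'
#' At each 1-px step along the AP line, the mean of `line_width`
#' evenly spaced, bilinearly interpolated samples across the local
#' normal.  Offsets falling outside the image are clamped to the
#' border (with a warning).
#'
#' @param image Numeric matrix.
#' @param geometry [oocyte_geometry()]; uses `ap_line` and
#'   `line_width`.
#' @return Object of class `mtk_ap_profile`: list with `ap_fraction`
#'   (positions 0-1, anterior to posterior), `position_um`,
#'   `intensity`.
#' @export
ap_profile <- function(image, geometry) {
  ap <- geometry$ap_line
  h <- nrow(image); w <- ncol(image)
  if (any(ap[, 1] < 1 | ap[, 1] > w | ap[, 2] < 1 | ap[, 2] > h)) {
    stop_mtk("AP line exits the image", "mtk_bounds_error")
  }
  half <- (geometry$line_width - 1) / 2
  normal <- c(-(ap[2, 2] - ap[1, 2]), ap[2, 1] - ap[1, 1])
  normal <- normal / sqrt(sum(normal^2))
  ends <- rbind(ap[1, ] + half * normal, ap[1, ] - half * normal,
                ap[2, ] + half * normal, ap[2, ] - half * normal)
  if (any(ends[, 1] < 1 | ends[, 1] > w | ends[, 2] < 1 | ends[, 2] > h)) {
    warning("AP band partially outside the image; samples clamped",
            call. = FALSE)
  }
  bp <- band_profile(image, ap, width = geometry$line_width)
  total <- bp$s[length(bp$s)]
  structure(list(ap_fraction = bp$s / total,
                 position_um = bp$s * geometry$pixel_size_um,
                 intensity = bp$intensity),
            class = "mtk_ap_profile")
}

# prominence of local maxima of a 1-D signal (classic definition:
# height above the highest minimum separating the peak from a higher
# peak or the signal end)
peak_prominences <- function(x, peaks) {
  vapply(peaks, function(p) {
    left_min <- x[p]
    i <- p
    while (i > 1L && x[i] <= x[p]) {
      i <- i - 1L
      left_min <- min(left_min, x[i])
      if (x[i] > x[p]) break
    }
    right_min <- x[p]
    i <- p
    while (i < length(x) && x[i] <= x[p]) {
      i <- i + 1L
      right_min <- min(right_min, x[i])
      if (x[i] > x[p]) break
    }
    x[p] - max(left_min, right_min)
  }, numeric(1))
}

#' Detect inner intensity peaks along the AP profile
#'
#' Local maxima of the (lightly smoothed) AP profile with prominence at
#' least `prominence_frac` of the profile's dynamic range, excluding a
#' margin at each end (where nurse-cell border and posterior follicle
#' cell signal live).  Classification: no peak = `"none"`; one peak at
#' AP < 0.5 = `"single_anterior"`, otherwise `"single_central"`; two or
#' more peaks = `"double_peak"`.
#'
#' @param profile `mtk_ap_profile` from [ap_profile()].
#' @param margin_frac Fraction of the AP length excluded at each end.
#' @param prominence_frac Minimum prominence as a fraction of
#'   `max - min` of the interior profile.
#' @param smooth_px Half-width of the moving-average smoother.
#' @param noise_k Noise floor: prominences must also exceed `noise_k`
#'   times the profile noise scale (MAD of successive differences), so
#'   a flat noisy profile yields no peaks even though its dynamic
#'   range is pure noise.
#' @return List with `peaks` (data frame `ap_fraction, intensity,
#'   prominence`, sorted by position) and `classification`.
#' @export
detect_inner_peaks <- function(profile, margin_frac = 0.1,
                               prominence_frac = 0.2, smooth_px = 3L,
                               noise_k = 8) {
  x <- profile$intensity
  f <- profile$ap_fraction
  k <- 2L * smooth_px + 1L
  xs <- stats::filter(x, rep(1 / k, k), sides = 2)
  xs[is.na(xs)] <- x[is.na(xs)]
  xs <- as.numeric(xs)
  interior <- which(f >= margin_frac & f <= 1 - margin_frac)
  rng <- diff(range(xs[interior]))
  cand <- interior[-c(1L, length(interior))]
  is_max <- xs[cand] > xs[cand - 1L] & xs[cand] >= xs[cand + 1L]
  cand <- cand[is_max]
  if (length(cand) && rng > 0) {
    noise_sigma <- stats::mad(diff(x[interior])) / sqrt(2)
    floor_prom <- max(prominence_frac * rng, noise_k * noise_sigma)
    prom <- peak_prominences(xs, cand)
    keep <- prom >= floor_prom
    cand <- cand[keep]
    prom <- prom[keep]
  } else {
    prom <- numeric(0)
    cand <- integer(0)
  }
  ord <- order(f[cand])
  peaks <- data.frame(ap_fraction = f[cand][ord],
                      intensity = x[cand][ord],
                      prominence = prom[ord])
  classification <- if (nrow(peaks) == 0L) "none"
    else if (nrow(peaks) >= 2L) "double_peak"
    else if (peaks$ap_fraction[1] < 0.5) "single_anterior"
    else "single_central"
  list(peaks = peaks, classification = classification)
}

#' Call posterior enrichment of a cortical signal
#'
#' Deterministic surrogate for blind visual scoring: `TRUE` iff the
#' mean intensity of the posterior cortical band (the cortex arc
#' spanning `band_frac` of the total arc length around the posterior
#' pole, dilated `dilate_px` inward) is at least `ratio_min` times the
#' mean intensity of the rest of the oocyte.
#'
#' @param image Numeric matrix.
#' @param geometry [oocyte_geometry()].
#' @param band_frac Fraction of the cortex arc forming the posterior
#'   band.
#' @param ratio_min Minimum band/rest intensity ratio.
#' @param dilate_px Inward dilation of the band (px).
#' @return List with `enriched` (logical), `ratio`, `band_mean`,
#'   `rest_mean`.
#' @export
call_posterior_enrichment <- function(image, geometry, band_frac = 0.15,
                                      ratio_min = 1.3, dilate_px = 5) {
  h <- nrow(image); w <- ncol(image)
  rp <- resample_polyline(geometry$cortex, step = 1)
  # posterior pole: cortex point with maximal projection on the AP axis
  ap_dir <- geometry$ap_line[2, ] - geometry$ap_line[1, ]
  ap_dir <- ap_dir / sqrt(sum(ap_dir^2))
  proj <- rp$x * ap_dir[1] + rp$y * ap_dir[2]
  pole_i <- which.max(proj)
  arc_half <- band_frac * rp$total / 2
  d_arc <- abs(rp$s - rp$s[pole_i])
  if (is_closed_polyline(geometry$cortex)) {
    d_arc <- pmin(d_arc, rp$total - d_arc)
  }
  band_pts <- cbind(rp$x[d_arc <= arc_half], rp$y[d_arc <= arc_half])
  if (nrow(band_pts) == 0L) {
    stop_mtk("empty posterior band", "mtk_config_error")
  }
  # oocyte mask from the cortex polygon
  xg <- rep(seq_len(w), each = h)
  yg <- rep(seq_len(h), times = w)
  inside <- mgcv::in.out(rbind(geometry$cortex,
                               geometry$cortex[1, , drop = FALSE]),
                         cbind(xg, yg))
  mask <- matrix(inside, h, w)
  # band mask: inside pixels within dilate_px of a band cortex point
  bb_x <- range(band_pts[, 1]) + c(-1, 1) * (dilate_px + 1)
  bb_y <- range(band_pts[, 2]) + c(-1, 1) * (dilate_px + 1)
  cand <- which(mask & xg >= bb_x[1] & xg <= bb_x[2] &
                  yg >= bb_y[1] & yg <= bb_y[2])
  band_idx <- integer(0)
  if (length(cand)) {
    d2 <- matrix(Inf, length(cand), 1)
    for (i in seq_len(nrow(band_pts))) {
      d2 <- pmin(d2, (xg[cand] - band_pts[i, 1])^2 +
                   (yg[cand] - band_pts[i, 2])^2)
    }
    band_idx <- cand[d2 <= dilate_px^2]
  }
  if (length(band_idx) == 0L) {
    stop_mtk("empty posterior band", "mtk_config_error")
  }
  band_mask <- matrix(FALSE, h, w)
  band_mask[band_idx] <- TRUE
  rest_mask <- mask & !band_mask
  band_mean <- mean(image[band_mask])
  rest_mean <- mean(image[rest_mask])
  ratio <- band_mean / rest_mean
  list(enriched = is.finite(ratio) && ratio >= ratio_min,
       ratio = ratio, band_mean = band_mean, rest_mean = rest_mean)
}

#' Per-genotype percentage of positive calls
#'
#' Percent of `TRUE` calls per genotype, rounded half-up (28/37 -> 76).
#'
#' @param calls Logical vector.
#' @param genotype Genotype label per call.
#' @return Data frame `genotype, n, n_positive, pct_positive`.
#' @export
summarize_fractions <- function(calls, genotype = rep("all", length(calls))) {
  if (length(calls) == 0L) {
    stop_mtk("need at least one call", "mtk_insufficient_data_error")
  }
  gts <- unique(genotype)
  rows <- lapply(gts, function(g) {
    sub <- calls[genotype == g]
    data.frame(genotype = g, n = length(sub), n_positive = sum(sub),
               pct_positive = round_half_up(100 * mean(sub)))
  })
  do.call(rbind, rows)
}

#' Write oocyte geometry to JSON
#'
#' @param geometry [oocyte_geometry()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geometry_json <- function(geometry, path) {
  jsonlite::write_json(
    list(cortex = unname(as.matrix(geometry$cortex)),
         ap_line = unname(as.matrix(geometry$ap_line)),
         line_width = geometry$line_width,
         pixel_size_um = geometry$pixel_size_um),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read oocyte geometry from JSON
#'
#' @param path JSON file written by [write_geometry_json()].
#' @return [oocyte_geometry()] object.
#' @export
read_geometry_json <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = TRUE)
  oocyte_geometry(cortex = gj$cortex, ap_line = gj$ap_line,
                  line_width = gj$line_width,
                  pixel_size_um = gj$pixel_size_um)
}
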