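# Kymographs along cortical polylines, patch-correlation flow fields,
# rotation-center fitting, and classification of ooplasmic streaming
# patterns.

#' Classifier thresholds for streaming patterns
#'
#' The published pattern taxonomy is scored by eye; these constants
#' make the surrogate classifier explicit and reproducible.  A movie is
#' "circular" when the tangential coherence about the fitted rotation
#' center is at least `kappa_circular` and the posterior part of the
#' field also streams coherently (`kappa_posterior_min`); circular
#' movies with a rotation center in the anterior `ap_anterior_max`
#' fraction of the AP axis are "anterior-biased".  Non-circular movies
#' whose anterior part still streams coherently
#' (`kappa_anterior_min`) while the posterior does not
#' (`kappa_posterior_max`) are "partially disrupted"; the rest are
#' "chaotic".
#'
#' @param kappa_circular Minimum whole-field tangential coherence for a
#'   circular call.
#' @param ap_anterior_max AP fraction below which a circular center is
#'   anterior-biased.
#' @param posterior_frac Posterior fraction of the AP extent used for
#'   the posterior-coherence window (0.4 = posterior 40%).
#' @param kappa_posterior_min Minimum posterior coherence for a
#'   circular call.
#' @param kappa_anterior_min Minimum anterior coherence for a
#'   partially-disrupted call.
#' @param kappa_posterior_max Maximum posterior coherence for a
#'   partially-disrupted call.
#' @param min_vectors Minimum number of flow vectors for a region's
#'   coherence to be considered measured; below it the region counts
#'   as having no coherent flow (coherence 0).
#' @return List of thresholds.
#' @export
streaming_thresholds <- function(kappa_circular = 0.6,
                                 ap_anterior_max = 0.4,
                                 posterior_frac = 0.4,
                                 kappa_posterior_min = 0.3,
                                 kappa_anterior_min = 0.6,
                                 kappa_posterior_max = 0.3,
                                 min_vectors = 5L) {
  list(kappa_circular = kappa_circular,
       ap_anterior_max = ap_anterior_max,
       posterior_frac = posterior_frac,
       kappa_posterior_min = kappa_posterior_min,
       kappa_anterior_min = kappa_anterior_min,
       kappa_posterior_max = kappa_posterior_max,
       min_vectors = as.integer(min_vectors))
}

#' Build a kymograph along a polyline
#'
#' Samples the image stack along the polyline at 1-px arc-length steps;
#' each row averages `width` evenly spaced, bilinearly interpolated
#' offsets along the local normal.  Columns are frames, so moving
#' particles appear as sloped streaks.
#'
#' @param movie `mtk_movie` or `h x w x t` array.
#' @param polyline `n x 2` matrix of (x, y) pixel coordinates.
#' @param width Band width in pixels.
#' @return Object of class `mtk_kymograph`: list with `matrix`
#'   (distance x time), `s_px` (arc positions), `line`, `width`,
#'   `pixel_size_um`, `frame_interval_s`.
#' @export
build_kymograph <- function(movie, polyline, width = 1) {
  frames <- if (inherits(movie, "mtk_movie")) movie$frames else movie
  h <- dim(frames)[1]; w <- dim(frames)[2]
  polyline <- as.matrix(polyline)
  if (any(polyline[, 1] < 1 | polyline[, 1] > w |
          polyline[, 2] < 1 | polyline[, 2] > h)) {
    stop_mtk("polyline exits the image bounds", "mtk_bounds_error")
  }
  n_frames <- dim(frames)[3]
  first <- band_profile(frames[, , 1], polyline, width = width)
  mat <- matrix(0, length(first$s), n_frames)
  mat[, 1] <- first$intensity
  for (f in seq_len(n_frames)[-1]) {
    mat[, f] <- band_profile(frames[, , f], polyline, width = width)$intensity
  }
  structure(list(matrix = mat, s_px = first$s, line = polyline,
                 width = width,
                 pixel_size_um = if (inherits(movie, "mtk_movie"))
                   movie$pixel_size_um else NA_real_,
                 frame_interval_s = if (inherits(movie, "mtk_movie"))
                   movie$frame_interval_s else NA_real_),
            class = "mtk_kymograph")
}

#' Estimate a flow field by patch cross-correlation
#'
#' For each square patch on a regular grid and each sampled frame pair
#' `(t, t + frame_lag)`, the displacement is the argmax of the
#' normalized cross-correlation within `search_px` pixels; patches
#' whose correlation peak falls below `min_peak` are dropped (no
#' reliable texture match).  Displacements convert to um/s through the
#' pixel size and the pair time base.
#'
#' @param movie `mtk_movie` object (frames plus acquisition metadata).
#' @param patch_px Patch side length (px).
#' @param step_px Grid step between patch origins (px).
#' @param search_px Search radius (px).
#' @param frame_lag Frames between the two members of a pair; larger
#'   lags resolve slower flows at the cost of temporal smearing.
#' @param pair_step Stride between successive pair start frames.
#' @param min_peak Minimum correlation peak to keep a vector.
#' @return Object of class `mtk_flow`: data frame `x, y` (patch center,
#'   px), `vx, vy` (um/s), `speed`, `peak`, `pair`, with the field
#'   dimensions, pixel size and time base as attributes.
#' @export
estimate_flow <- function(movie, patch_px = 16L, step_px = 12L,
                          search_px = 8L, frame_lag = 3L, pair_step = 10L,
                          min_peak = 0.3) {
  stopifnot(inherits(movie, "mtk_movie"))
  frames <- movie$frames
  h <- dim(frames)[1]; w <- dim(frames)[2]; n_frames <- dim(frames)[3]
  if (n_frames < frame_lag + 1L) {
    stop_mtk("movie too short for the requested frame lag",
             "mtk_config_error")
  }
  p <- as.integer(patch_px); s <- as.integer(search_px)
  ys <- seq(s + 1L, h - p + 1L - s, by = step_px)
  xs <- seq(s + 1L, w - p + 1L - s, by = step_px)
  if (length(ys) == 0L || length(xs) == 0L) {
    stop_mtk("field too small for patch size and search radius",
             "mtk_config_error")
  }
  starts <- seq(1L, n_frames - frame_lag, by = pair_step)
  dt_pair <- frame_lag * movie$frame_interval_s
  n_area <- p * p
  shifts <- expand.grid(dy = -s:s, dx = -s:s)

  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    f1 <- frames[, , starts[k]]
    f2 <- frames[, , starts[k] + frame_lag]
    ii1 <- integral_image(f1)
    ii1sq <- integral_image(f1^2)
    ii2 <- integral_image(f2)
    ii2sq <- integral_image(f2^2)
    s1 <- patch_sums(ii1, ys, xs, p)
    v1 <- patch_sums(ii1sq, ys, xs, p) - s1^2 / n_area
    best <- matrix(-Inf, length(ys), length(xs))
    bdx <- matrix(0L, length(ys), length(xs))
    bdy <- matrix(0L, length(ys), length(xs))
    for (q in seq_len(nrow(shifts))) {
      dy <- shifts$dy[q]; dx <- shifts$dx[q]
      s2 <- patch_sums(ii2, ys + dy, xs + dx, p)
      v2 <- patch_sums(ii2sq, ys + dy, xs + dx, p) - s2^2 / n_area
      # cross term: f1 .* f2 shifted by (dy, dx)
      prod <- matrix(0, h, w)
      ry <- max(1L, 1L - dy):min(h, h - dy)
      rx <- max(1L, 1L - dx):min(w, w - dx)
      prod[ry, rx] <- f1[ry, rx] * f2[ry + dy, rx + dx]
      sc <- patch_sums(integral_image(prod), ys, xs, p)
      ncc <- (sc - s1 * s2 / n_area) / sqrt(pmax(v1 * v2, 1e-12))
      upd <- ncc > best
      best[upd] <- ncc[upd]
      bdx[upd] <- dx
      bdy[upd] <- dy
    }
    keep <- best >= min_peak
    if (!any(keep)) next
    cy <- rep(ys + (p - 1) / 2, times = length(xs))
    cx <- rep(xs + (p - 1) / 2, each = length(ys))
    out[[k]] <- data.frame(
      x = cx[keep], y = cy[keep],
      vx = bdx[keep] * movie$pixel_size_um / dt_pair,
      vy = bdy[keep] * movie$pixel_size_um / dt_pair,
      peak = best[keep], pair = starts[k]
    )
  }
  flow <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(flow)) flow <- data.frame(x = numeric(0), y = numeric(0),
                                        vx = numeric(0), vy = numeric(0),
                                        peak = numeric(0),
                                        pair = integer(0))
  flow$speed <- sqrt(flow$vx^2 + flow$vy^2)
  structure(flow, class = c("mtk_flow", "data.frame"),
            field_dim = c(h, w), pixel_size_um = movie$pixel_size_um,
            frame_interval_s = movie$frame_interval_s)
}

# tangential coherence of a set of vectors about a center:
# |mean over vectors of (v . t_hat) / |v||.  Patches with no detectable
# motion (zero displacement) have no direction and contribute 0, so a
# region full of static patches is incoherent, not undefined.
kappa_about <- function(flow, center) {
  v <- cbind(flow$vx, flow$vy)
  speed <- sqrt(rowSums(v^2))
  ok <- speed > 1e-12
  if (!any(ok)) return(0)
  rx <- flow$x[ok] - center[1]
  ry <- flow$y[ok] - center[2]
  rn <- pmax(sqrt(rx^2 + ry^2), 1e-9)
  tx <- -ry / rn
  ty <- rx / rn
  abs(sum((v[ok, 1] * tx + v[ok, 2] * ty) / speed[ok]) / nrow(v))
}

# radial energy fraction: sum (v . r_hat)^2 / sum |v|^2
radial_energy <- function(flow, center) {
  v <- cbind(flow$vx, flow$vy)
  speed2 <- rowSums(v^2)
  ok <- speed2 > 1e-24
  if (!any(ok)) return(Inf)
  rx <- flow$x[ok] - center[1]
  ry <- flow$y[ok] - center[2]
  rn <- pmax(sqrt(rx^2 + ry^2), 1e-9)
  sum(((v[ok, 1] * rx + v[ok, 2] * ry) / rn)^2) / sum(speed2[ok])
}

#' Fit the rotation center of a flow field
#'
#' The center minimizes the radial energy fraction (squared projections
#' of the velocity vectors onto the radial direction) over a coarse
#' grid spanning the vector bounding box, refined by Nelder-Mead.  The
#' tangential coherence kappa about the fitted center is
#' `|mean((v . t_hat) / |v|)|`: 1 for a perfect unidirectional
#' rotation, ~0 for random or counterbalanced flow.  If the refined
#' center runs far outside the field (near-parallel vectors have no
#' finite rotation center), a no-center flag is set and kappa is
#' computed about the vector centroid.
#'
#' @param flow `mtk_flow` data frame (>= 8 vectors with nonzero speed).
#' @param grid_n Coarse grid resolution per axis.
#' @return List with `center` (x, y in px), `kappa`, `no_center`, and
#'   `n` (vectors used).
#' @export
fit_rotation_center <- function(flow, grid_n = 12L) {
  speed <- sqrt(flow$vx^2 + flow$vy^2)
  fl <- flow[speed > 1e-12, , drop = FALSE]
  if (nrow(fl) < 8L) {
    stop_mtk("need at least 8 nonzero flow vectors", "mtk_config_error")
  }
  xr <- range(fl$x); yr <- range(fl$y)
  pad_x <- 0.25 * diff(xr); pad_y <- 0.25 * diff(yr)
  gx <- seq(xr[1] - pad_x, xr[2] + pad_x, length.out = grid_n)
  gy <- seq(yr[1] - pad_y, yr[2] + pad_y, length.out = grid_n)
  obj <- outer(gy, gx, Vectorize(function(y, x) radial_energy(fl, c(x, y))))
  idx <- arrayInd(which.min(obj), dim(obj))
  start <- c(gx[idx[2]], gy[idx[1]])
  fit <- stats::optim(start, function(c2) radial_energy(fl, c2),
                      method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-8))
  center <- fit$par
  span <- max(diff(xr), diff(yr))
  no_center <- any(center < c(xr[1], yr[1]) - 1.5 * span) ||
    any(center > c(xr[2], yr[2]) + 1.5 * span)
  if (no_center) {
    center <- c(mean(fl$x), mean(fl$y))
  }
  list(center = center, kappa = kappa_about(fl, center),
       no_center = no_center, n = nrow(fl))
}

region_kappa <- function(flow, center, min_vectors) {
  if (nrow(flow) < min_vectors) return(0)
  k <- kappa_about(flow, center)
  if (is.na(k)) 0 else k
}

#' Classify the streaming pattern of a flow field
#'
#' Deterministic surrogate for visual pattern scoring.  With the AP
#' axis along image columns: the movie is circular (central or
#' anterior-biased by the fitted center's AP fraction) when both the
#' whole-field tangential coherence and the posterior-window coherence
#' are high; otherwise it is abnormal, partitioned into partially
#' disrupted (anterior still coherent, posterior not) and chaotic.
#' A region with fewer than `min_vectors` usable vectors counts as
#' having no coherent flow.
#'
#' @param flow `mtk_flow` from [estimate_flow()].
#' @param thresholds [streaming_thresholds()].
#' @return Object of class `mtk_streaming_call`: list with `pattern`
#'   (one of `circular_central`, `circular_anterior_biased`,
#'   `abnormal_partial`, `abnormal_chaotic`), `rotation_center`,
#'   `center_frac_ap`, `coherence`, `posterior_coherence`,
#'   `anterior_coherence`, `n_vectors`.
#' @export
classify_streaming <- function(flow, thresholds = streaming_thresholds()) {
  dims <- attr(flow, "field_dim")
  if (is.null(dims)) {
    stop_mtk("flow lacks field dimensions; use estimate_flow()",
             "mtk_config_error")
  }
  w <- dims[2]
  th <- thresholds
  post_x0 <- (1 - th$posterior_frac) * w
  fit <- fit_rotation_center(flow)
  # whole-field coherence over all retained patches (static ones count
  # against coherence), about the center fitted on the moving ones
  kappa_full <- kappa_about(flow, fit$center)
  post <- flow[flow$x >= post_x0, , drop = FALSE]
  ant <- flow[flow$x < post_x0, , drop = FALSE]
  kappa_post <- region_kappa(post, fit$center, th$min_vectors)
  ap_frac <- fit$center[1] / w

  if (!fit$no_center && kappa_full >= th$kappa_circular &&
      kappa_post >= th$kappa_posterior_min) {
    pattern <- if (ap_frac < th$ap_anterior_max) "circular_anterior_biased"
               else "circular_central"
    kappa_ant <- region_kappa(ant, fit$center, th$min_vectors)
  } else {
    # judge the anterior part on its own rotation center
    kappa_ant <- 0
    ant_center <- fit$center
    if (nrow(ant[sqrt(ant$vx^2 + ant$vy^2) > 1e-12, ]) >= 8L) {
      afit <- fit_rotation_center(ant)
      ant_center <- afit$center
      kappa_ant <- if (afit$no_center) 0 else afit$kappa
    }
    kappa_post_a <- region_kappa(post, ant_center, th$min_vectors)
    pattern <- if (kappa_ant >= th$kappa_anterior_min &&
                   kappa_post_a <= th$kappa_posterior_max)
      "abnormal_partial" else "abnormal_chaotic"
  }
  structure(list(pattern = pattern,
                 rotation_center = fit$center,
                 center_frac_ap = ap_frac,
                 coherence = kappa_full,
                 posterior_coherence = kappa_post,
                 anterior_coherence = kappa_ant,
                 no_center = fit$no_center,
                 n_vectors = nrow(flow)),
            class = "mtk_streaming_call")
}

#' Per-genotype percentage summary of streaming calls
#'
#' Pools the two circular subtypes as "circular" and the two abnormal
#' subtypes as "abnormal"; percentages are rounded half-up to integers
#' (so 12/17 -> 71, 16/21 -> 76).
#'
#' @param calls Data frame with columns `genotype` and `pattern`, or a
#'   list of `mtk_streaming_call` objects plus a `genotype` vector.
#' @param genotype Genotype labels when `calls` is a list of calls.
#' @return Data frame `genotype, n, n_circular, n_abnormal,
#'   pct_circular, pct_abnormal`.
#' @export
summarize_patterns <- function(calls, genotype = NULL) {
  if (!is.data.frame(calls)) {
    calls <- data.frame(
      genotype = genotype %||% rep("all", length(calls)),
      pattern = vapply(calls, function(cl) cl$pattern, character(1))
    )
  }
  if (nrow(calls) == 0L) {
    stop_mtk("need at least one call", "mtk_insufficient_data_error")
  }
  circ <- c("circular_central", "circular_anterior_biased")
  gts <- unique(calls$genotype)
  rows <- lapply(gts, function(g) {
    sub <- calls[calls$genotype == g, , drop = FALSE]
    n <- nrow(sub)
    nc <- sum(sub$pattern %in% circ)
    data.frame(genotype = g, n = n, n_circular = nc, n_abnormal = n - nc,
               pct_circular = round_half_up(100 * nc / n),
               pct_abnormal = round_half_up(100 * (n - nc) / n))
  })
  do.call(rbind, rows)
}

#' Fraction of kymograph streak orientation mass with the dominant slope
#'
#' For a streak moving at velocity v, intensity is conserved along the
#' motion, so the product of the spatial and temporal image gradients
#' has the opposite sign of the slope.  The per-pixel product
#' `-g_s * g_t`, weighted by its magnitude, votes for a positive or
#' negative streak slope; the returned fraction is the share of total
#' gradient mass voting for the winning sign (about 1 for
#' unidirectional streaming along the cortex, about 0.5 for balanced
#' counter-movement).
#'
#' @param kymo `mtk_kymograph` (or plain distance x time matrix).
#' @param min_mass Minimum total gradient mass; below it the kymograph
#'   is featureless and the result is `NA` with a warning.
#' @return List with `fraction` (in [0.5, 1] or `NA`), `sign` (+1 or
#'   -1, slope sign of the dominant direction), and `mass`.
#' @export
cortical_unidirectionality <- function(kymo, min_mass = 1e-6) {
  m <- if (inherits(kymo, "mtk_kymograph")) kymo$matrix else kymo
  if (nrow(m) < 3L || ncol(m) < 3L) {
    stop_mtk("kymograph too small", "mtk_config_error")
  }
  gs <- (m[-c(1, 2), ] - m[-c(nrow(m) - 1, nrow(m)), ]) / 2
  gs <- gs[, -c(1, ncol(m)), drop = FALSE]
  gt <- (m[, -c(1, 2)] - m[, -c(ncol(m) - 1, ncol(m))]) / 2
  gt <- gt[-c(1, nrow(m)), , drop = FALSE]
  vote <- -(gs * gt)   # >0 means positive slope (moving toward larger s)
  mass <- sum(abs(vote))
  if (mass < min_mass) {
    warning("featureless kymograph: unidirectionality undefined",
            call. = FALSE)
    return(list(fraction = NA_real_, sign = NA_integer_, mass = mass))
  }
  pos <- sum(abs(vote)[vote > 0]) / mass
  if (pos >= 0.5) list(fraction = pos, sign = 1L, mass = mass)
  else list(fraction = 1 - pos, sign = -1L, mass = mass)
}
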