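# Run/pause segmentation of particle trajectories and the five transport
# statistics: run length, total run velocity, transport velocity, pausing
# time ratio, and pausing frequency.

#' Segmentation parameters for run/pause calling
#'
#' @param v_pause Speed threshold in um/s.  An inter-frame interval is a
#'   pause iff its instant speed is strictly below `v_pause`; a speed
#'   exactly equal to the threshold counts as transported.
#' @param d_min_motile Minimum total transport distance (um) for a track
#'   to be called motile (strictly greater than).
#' @param min_pause_frames Minimum number of consecutive sub-threshold
#'   intervals that constitute a pause event; shorter stretches are
#'   reclassified as transport.
#' @return Object of class `mtk_segmentation_params`.
#' @export
segmentation_params <- function(v_pause = 0.2, d_min_motile = 2,
                                min_pause_frames = 1L) {
  check_positive(v_pause, "v_pause")
  check_positive(d_min_motile, "d_min_motile", strict = FALSE)
  check_count(min_pause_frames, "min_pause_frames", min = 1L)
  structure(list(v_pause = v_pause, d_min_motile = d_min_motile,
                 min_pause_frames = as.integer(min_pause_frames)),
            class = "mtk_segmentation_params")
}

as_one_track <- function(traj) {
  if (is.data.frame(traj)) {
    need <- c("t_s", "x_um")
    if (!all(need %in% names(traj))) {
      stop_mtk("trajectory must have columns t_s and x_um (y_um optional)",
               "mtk_trajectory_error")
    }
    if ("track_id" %in% names(traj) &&
        length(unique(traj$track_id)) > 1L) {
      stop_mtk("trajectory contains more than one track_id; split first",
               "mtk_trajectory_error")
    }
    if (nrow(traj) < 2L) {
      stop_mtk("trajectory needs at least 2 points", "mtk_trajectory_error")
    }
    list(t = traj$t_s,
         xy = cbind(traj$x_um, traj$y_um %||% rep(0, nrow(traj))))
  } else {
    stop_mtk("trajectory must be a data frame", "mtk_trajectory_error")
  }
}

#' Per-interval instant speed of a trajectory
#'
#' Instant speed between consecutive frames: Euclidean inter-frame
#' displacement divided by the frame interval.  Sampling must be
#' uniform; a non-uniform frame interval is rejected naming the
#' offending frame.
#'
#' @param traj Data frame for a single track with columns `t_s`, `x_um`
#'   and optionally `y_um`.
#' @return Numeric vector of length `nrow(traj) - 1` (um/s).
#' @examples
#' traj <- data.frame(t_s = c(0, 2, 4), x_um = c(0, 1, 2), y_um = 0)
#' instant_velocity(traj)  # 0.5 0.5
#' @export
instant_velocity <- function(traj) {
  tr <- as_one_track(traj)
  dts <- diff(tr$t)
  if (any(dts <= 0)) {
    stop_mtk(sprintf("time stamps must be strictly increasing (frame %d)",
                     which(dts <= 0)[1]), "mtk_trajectory_error")
  }
  if (max(abs(dts - dts[1])) > 1e-6) {
    bad <- which(abs(dts - dts[1]) > 1e-6)[1]
    stop_mtk(sprintf(
      "non-uniform frame interval at frame %d (%.6g s vs %.6g s)",
      bad + 1L, dts[bad], dts[1]), "mtk_trajectory_error")
  }
  disp <- sqrt(rowSums(diff(tr$xy)^2))
  disp / dts[1]
}

#' Detect the run window of a trajectory
#'
#' The run starts at the first inter-frame interval whose speed reaches
#' `v_pause` (a motile particle starting to move away from a stationary
#' position, or a track entering mid-movement) and stops at the last
#' such interval (the particle terminating movement or leaving the
#' focal plane).  Leading and trailing stationary tails are excluded
#' from the run time.
#'
#' @param traj Single-track data frame (see [instant_velocity()]).
#' @param params [segmentation_params()].
#' @return `list(start, stop)` of 1-based interval indices, or `NULL` if
#'   no interval ever reaches `v_pause` (a never-motile track).
#' @export
detect_run_window <- function(traj, params = segmentation_params()) {
  speeds <- instant_velocity(traj)
  supra <- which(speeds >= params$v_pause)
  if (length(supra) == 0L) return(NULL)
  list(start = supra[1], stop = supra[length(supra)])
}

# rle-based pause event extraction from a logical pause vector
pause_events_from_labels <- function(is_pause, min_pause_frames) {
  r <- rle(is_pause)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_pause_frames
  data.frame(start = starts[keep], end = ends[keep],
             n_intervals = r$lengths[keep])
}

#' Segment a run into transport and pause intervals
#'
#' Within the run window, an interval is a pause iff its instant speed
#' is strictly below `v_pause`; otherwise it is transported.  Maximal
#' stretches of at least `min_pause_frames` consecutive pause intervals
#' form pause events; shorter stretches are reclassified as transport
#' so that the time decomposition stays exact.
#'
#' @param traj Single-track data frame, or a numeric vector of
#'   per-interval speeds (um/s).
#' @param params [segmentation_params()].
#' @param window Optional `list(start, stop)` restricting segmentation
#'   to a run window (as from [detect_run_window()]); default is the
#'   whole series.
#' @return List with `labels` (character vector `"transport"`/`"pause"`,
#'   one per interval in the window), `events` (data frame
#'   `start, end, n_intervals`, indices relative to the window), and
#'   `window`.
#' @export
segment_run <- function(traj, params = segmentation_params(),
                        window = NULL) {
  speeds <- if (is.numeric(traj)) traj else instant_velocity(traj)
  if (is.null(window)) window <- list(start = 1L, stop = length(speeds))
  sp <- speeds[window$start:window$stop]
  is_pause <- sp < params$v_pause
  events <- pause_events_from_labels(is_pause, params$min_pause_frames)
  labels <- rep("transport", length(sp))
  for (i in seq_len(nrow(events))) {
    labels[events$start[i]:events$end[i]] <- "pause"
  }
  list(labels = labels, events = events, window = window)
}

#' Is a track motile?
#'
#' A track is motile iff its total transport distance (run length)
#' strictly exceeds `d_min_motile` (default 2 um).  Never-motile tracks
#' (no interval reaching `v_pause`) are not motile.
#'
#' @inheritParams detect_run_window
#' @return `TRUE` or `FALSE`.
#' @export
is_motile <- function(traj, params = segmentation_params()) {
  window <- detect_run_window(traj, params)
  if (is.null(window)) return(FALSE)
  m <- compute_metrics(traj, params, window = window)
  m$run_length > params$d_min_motile
}

#' Transport metrics for one motile track
#'
#' Computes, over the detected run window:
#' \describe{
#'   \item{run_length}{sum of inter-frame distances travelled while in a
#'     transporting state (um).}
#'   \item{run_time}{total pausing time plus total transporting time (s).}
#'   \item{total_run_velocity}{run length divided by run time (um/s).}
#'   \item{transport_velocity}{mean instant velocity over transported
#'     intervals (um/s).}
#'   \item{pausing_time_total}{summed duration of pause intervals (s).}
#'   \item{pausing_time_ratio}{total pausing time / run time, in [0,1].}
#'   \item{n_pauses}{number of pause events (maximal pause stretches).}
#'   \item{pausing_frequency}{pause events per um of run length.}
#' }
#'
#' @inheritParams detect_run_window
#' @param window Optional precomputed run window.
#' @return One-row data frame with the metric fields above plus
#'   `n_intervals` (window length).
#' @export
compute_metrics <- function(traj, params = segmentation_params(),
                            window = NULL) {
  speeds <- instant_velocity(traj)
  dt <- diff(as_one_track(traj)$t)[1]
  if (is.null(window)) window <- detect_run_window(traj, params)
  if (is.null(window)) {
    stop_mtk("track never reaches v_pause (never motile)",
             "mtk_never_motile_error")
  }
  seg <- segment_run(speeds, params, window = window)
  sp <- speeds[window$start:window$stop]
  transporting <- seg$labels == "transport"
  run_length <- sum(sp[transporting] * dt)
  run_time <- length(sp) * dt
  pausing_time <- sum(!transporting) * dt
  n_pauses <- nrow(seg$events)
  data.frame(
    run_length = run_length,
    run_time = run_time,
    total_run_velocity = run_length / run_time,
    transport_velocity = if (any(transporting)) mean(sp[transporting])
                         else NA_real_,
    pausing_time_total = pausing_time,
    pausing_time_ratio = pausing_time / run_time,
    n_pauses = n_pauses,
    pausing_frequency = if (run_length > 0) n_pauses / run_length
                        else NA_real_,
    n_intervals = length(sp)
  )
}

#' Direction of net transport relative to an axis
#'
#' Projects the net displacement (last minus first position) onto the
#' anterograde axis; positive projections are anterograde, negative
#' retrograde.  Net projections smaller than `ambiguous_um` in absolute
#' value are returned as `"ambiguous"` (e.g. tracks that reverse and
#' end near their start).
#'
#' @param traj Single-track data frame.
#' @param axis Numeric length-2 vector giving the anterograde direction
#'   (need not be unit length).
#' @param ambiguous_um Net-displacement threshold in um (default 0.5).
#' @return `"anterograde"`, `"retrograde"`, or `"ambiguous"`.
#' @export
assign_direction <- function(traj, axis = c(1, 0), ambiguous_um = 0.5) {
  if (length(axis) != 2L || !all(is.finite(axis)) ||
      sqrt(sum(axis^2)) == 0) {
    stop_mtk("axis must be a finite, non-zero length-2 vector",
             "mtk_config_error")
  }
  tr <- as_one_track(traj)
  u <- axis / sqrt(sum(axis^2))
  net <- tr$xy[nrow(tr$xy), ] - tr$xy[1, ]
  proj <- sum(net * u)
  if (abs(proj) < ambiguous_um) "ambiguous"
  else if (proj > 0) "anterograde" else "retrograde"
}

#' Distance-versus-time trace of a trajectory (kymograph-style)
#'
#' Cumulative signed path coordinate against time, suitable for
#' plotting a single-particle kymograph in which pauses appear as
#' horizontal plateaus.  Displacement increments are signed by their
#' projection onto the track's net-displacement direction (falling back
#' to unsigned path length for tracks with no net displacement).
#' Pause events from the run segmentation are annotated.
#'
#' @inheritParams detect_run_window
#' @return List of class `mtk_kymo_trace` with `t_s` (time), `d_um`
#'   (signed cumulative distance), and `pauses` (data frame
#'   `t_start, t_end` of pause events within the run window; empty if
#'   the track is never motile).
#' @export
trajectory_kymograph <- function(traj, params = segmentation_params()) {
  tr <- as_one_track(traj)
  steps <- diff(tr$xy)
  net <- colSums(steps)
  nn <- sqrt(sum(net^2))
  d_inc <- if (nn > 0) {
    u <- net / nn
    sign_step <- sign(steps %*% u)
    sign_step[sign_step == 0] <- 1
    sqrt(rowSums(steps^2)) * as.vector(sign_step)
  } else {
    sqrt(rowSums(steps^2))
  }
  window <- detect_run_window(traj, params)
  pauses <- data.frame(t_start = numeric(0), t_end = numeric(0))
  if (!is.null(window)) {
    seg <- segment_run(traj, params, window = window)
    if (nrow(seg$events) > 0) {
      # interval i spans t[i] .. t[i+1]; event indices are window-relative
      abs_start <- seg$events$start + window$start - 1L
      abs_end <- seg$events$end + window$start - 1L
      pauses <- data.frame(t_start = tr$t[abs_start],
                           t_end = tr$t[abs_end + 1L])
    }
  }
  structure(list(t_s = tr$t, d_um = c(0, cumsum(d_inc)), pauses = pauses),
            class = "mtk_kymo_trace")
}

#' Per-track transport metrics for a tracking table
#'
#' Applies window detection, segmentation, the motility filter, and
#' direction assignment to every track of a tracking table, in that
#' order.
#'
#' @param tracks Tracking table (`track_id, frame, t_s, x_um, y_um`).
#' @param params [segmentation_params()].
#' @param axis Anterograde axis passed to [assign_direction()].
#' @return Data frame with one row per track that is at least once
#'   motile: `track_id`, the [compute_metrics()] columns, `motile`
#'   (run length strictly above `d_min_motile`), and `direction`.
#'   Never-motile tracks are dropped; their ids are kept in the
#'   `"excluded"` attribute.
#' @export
transport_metrics <- function(tracks, params = segmentation_params(),
                              axis = c(1, 0)) {
  ids <- unique(tracks$track_id)
  out <- vector("list", length(ids))
  excluded <- character(0)
  for (i in seq_along(ids)) {
    traj <- tracks[tracks$track_id == ids[i], , drop = FALSE]
    window <- detect_run_window(traj, params)
    if (is.null(window)) {
      excluded <- c(excluded, as.character(ids[i]))
      next
    }
    m <- compute_metrics(traj, params, window = window)
    m$track_id <- ids[i]
    m$motile <- m$run_length > params$d_min_motile
    m$direction <- assign_direction(traj, axis)
    out[[i]] <- m
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame()
  } else {
    res <- res[, c("track_id", setdiff(names(res), "track_id"))]
  }
  attr(res, "excluded") <- excluded
  res
}

#' Compare transport metrics between two groups
#'
#' Per-metric group means, standard errors of the mean, and a two-sided
#' p-value from either Student's t-test (equal variances) or the
#' Mann-Whitney (Wilcoxon rank-sum) test.  The Mann-Whitney p-value is
#' exact when the smaller group has at most `exact_max` observations
#' and there are no ties, matching small-sample usage.
#'
#' @param metrics_a,metrics_b Data frames of per-track metrics (as from
#'   [transport_metrics()]), or plain numeric vectors for a single
#'   measure.
#' @param test `"t"` or `"mannwhitney"`.
#' @param metrics Character vector of metric columns to compare;
#'   default is the shared numeric columns.
#' @param exact_max Largest min(n, m) for which the Mann-Whitney test
#'   is computed exactly (default 8).
#' @return Data frame `metric, n_a, mean_a, sem_a, n_b, mean_b, sem_b,
#'   p_value`.
#' @examples
#' compare_groups(c(1, 2), c(3, 4), test = "mannwhitney")$p_value  # 1/3
#' @export
compare_groups <- function(metrics_a, metrics_b,
                           test = c("t", "mannwhitney"),
                           metrics = NULL, exact_max = 8L) {
  test <- match.arg(test)
  if (is.numeric(metrics_a)) metrics_a <- data.frame(value = metrics_a)
  if (is.numeric(metrics_b)) metrics_b <- data.frame(value = metrics_b)
  if (nrow(metrics_a) < 2L || nrow(metrics_b) < 2L) {
    stop_mtk("each group needs at least 2 observations",
             "mtk_insufficient_data_error")
  }
  if (is.null(metrics)) {
    num_a <- names(metrics_a)[vapply(metrics_a, is.numeric, logical(1))]
    num_b <- names(metrics_b)[vapply(metrics_b, is.numeric, logical(1))]
    metrics <- setdiff(intersect(num_a, num_b),
                       c("track_id", "n_intervals"))
  }
  rows <- lapply(metrics, function(m) {
    a <- metrics_a[[m]]
    b <- metrics_b[[m]]
    a <- a[is.finite(a)]
    b <- b[is.finite(b)]
    p <- if (test == "t") {
      if (stats::sd(c(a, b)) == 0) {
        1  # both groups constant and equal
      } else {
        stats::t.test(a, b, var.equal = TRUE)$p.value
      }
    } else {
      ex <- min(length(a), length(b)) <= exact_max
      suppressWarnings(
        stats::wilcox.test(a, b, exact = ex, correct = !ex)$p.value
      )
    }
    data.frame(metric = m,
               n_a = length(a), mean_a = mean(a),
               sem_a = stats::sd(a) / sqrt(length(a)),
               n_b = length(b), mean_b = mean(b),
               sem_b = stats::sd(b) / sqrt(length(b)),
               p_value = p)
  })
  do.call(rbind, rows)
}
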