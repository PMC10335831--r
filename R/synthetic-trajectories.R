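# Two-state (transport/pause) trajectory simulator.
#
# Particles move along a 1-D axonal coordinate embedded in the 2-D image
# plane; the hidden state alternates between "transport" (constant-ish
# speed drawn per interval) and "pause" (zero drift).  Observed positions
# add isotropic localization noise, which is the only displacement source
# during pauses, so the error rate of a fixed speed threshold is
# analytically computable.

#' Configuration for the two-state trajectory simulator
#'
#' Trajectories emulate time-lapse tracking of organelles (e.g. axonal
#' mitochondria) filmed at 0.5 frames/s for 3 minutes.  The hidden state
#' is a two-state Markov chain: from transport the particle enters a
#' pause with probability `p_pause_per_frame` per interval, and leaves a
#' pause with probability `p_resume_per_frame`.  The stationary pause
#' probability is therefore `p_pause / (p_pause + p_resume)`.
#'
#' @param n_tracks Number of trajectories.
#' @param duration_s Track duration in seconds.
#' @param frame_interval_s Frame interval in seconds (2 s = 0.5 frames/s).
#' @param transport_speed_mean,transport_speed_sd Mean and SD of the
#'   per-interval transport speed (um/s).  Keep the mean several SDs
#'   above the downstream 0.2 um/s pause threshold so that true
#'   transport intervals stay separable from pauses.
#' @param min_transport_speed Optional lower truncation bound for
#'   transport speed draws (um/s).  The default 0 leaves the normal
#'   draws untruncated, so the realized mean equals
#'   `transport_speed_mean`; truncating shifts it upward (truncated
#'   normal), which matters when recovery is checked against the
#'   configured mean.
#' @param p_pause_per_frame,p_resume_per_frame Per-interval transition
#'   probabilities of the hidden state chain.
#' @param localization_sd Isotropic localization noise SD (um) added to
#'   each observed position; typical centroid-fitting precision for
#'   fluorescent spot tracking is 20-50 nm.
#' @param direction `"anterograde"` (+x) or `"retrograde"` (-x).
#' @param reversal_prob_per_frame Probability per interval that the
#'   travel direction flips sign (bidirectional tracks).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return An object of class `mtk_trajectory_sim_config`.
#' @seealso [simulate_trajectories()]
#' @export
trajectory_sim_config <- function(n_tracks = 20L,
                                  duration_s = 180,
                                  frame_interval_s = 2,
                                  transport_speed_mean = 0.5,
                                  transport_speed_sd = 0.1,
                                  min_transport_speed = 0,
                                  p_pause_per_frame = 0.1,
                                  p_resume_per_frame = 0.5,
                                  localization_sd = 0.03,
                                  direction = c("anterograde", "retrograde"),
                                  reversal_prob_per_frame = 0,
                                  seed = 1L) {
  direction <- match.arg(direction)
  check_count(n_tracks, "n_tracks", min = 1L)
  check_positive(duration_s, "duration_s")
  check_positive(frame_interval_s, "frame_interval_s")
  check_positive(transport_speed_mean, "transport_speed_mean")
  check_positive(transport_speed_sd, "transport_speed_sd", strict = FALSE)
  check_positive(min_transport_speed, "min_transport_speed", strict = FALSE)
  check_prob(p_pause_per_frame, "p_pause_per_frame")
  check_prob(p_resume_per_frame, "p_resume_per_frame")
  check_positive(localization_sd, "localization_sd", strict = FALSE)
  check_prob(reversal_prob_per_frame, "reversal_prob_per_frame")
  cfg <- list(
    n_tracks = as.integer(n_tracks), duration_s = duration_s,
    frame_interval_s = frame_interval_s,
    transport_speed_mean = transport_speed_mean,
    transport_speed_sd = transport_speed_sd,
    min_transport_speed = min_transport_speed,
    p_pause_per_frame = p_pause_per_frame,
    p_resume_per_frame = p_resume_per_frame,
    localization_sd = localization_sd,
    direction = direction,
    reversal_prob_per_frame = reversal_prob_per_frame,
    seed = as.integer(seed)
  )
  structure(cfg, class = "mtk_trajectory_sim_config")
}

#' Simulate two-state transport/pause trajectories
#'
#' Generates `cfg$n_tracks` trajectories of
#' `duration_s / frame_interval_s + 1` positions each, together with the
#' ground-truth per-interval hidden states.  Tracks start in the
#' transport state (a "run" begins when the particle starts to move).
#'
#' @param cfg A [trajectory_sim_config()].
#' @return A list of class `mtk_trajectory_sim` with elements
#'   \describe{
#'     \item{tracks}{data frame `track_id, frame, t_s, x_um, y_um` in the
#'       tracking-table format used throughout the package.}
#'     \item{states}{data frame `track_id, interval, state, true_speed`
#'       with one row per inter-frame interval (`state` is
#'       `"transport"` or `"pause"`; `true_speed` is the drawn transport
#'       speed, 0 during pauses).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_trajectories <- function(cfg) {
  stopifnot(inherits(cfg, "mtk_trajectory_sim_config"))
  set.seed(cfg$seed)
  n_frames <- as.integer(round(cfg$duration_s / cfg$frame_interval_s)) + 1L
  n_int <- n_frames - 1L
  dt <- cfg$frame_interval_s
  dir_sign0 <- if (cfg$direction == "anterograde") 1 else -1

  tracks <- vector("list", cfg$n_tracks)
  states <- vector("list", cfg$n_tracks)
  for (k in seq_len(cfg$n_tracks)) {
    state <- character(n_int)
    speed <- numeric(n_int)
    x_true <- numeric(n_frames)
    s <- "transport"
    dir_sign <- dir_sign0
    for (i in seq_len(n_int)) {
      state[i] <- s
      if (s == "transport") {
        v <- stats::rnorm(1, cfg$transport_speed_mean, cfg$transport_speed_sd)
        while (v < cfg$min_transport_speed || v < 0) {
          v <- stats::rnorm(1, cfg$transport_speed_mean,
                            cfg$transport_speed_sd)
        }
        if (cfg$reversal_prob_per_frame > 0 &&
            stats::runif(1) < cfg$reversal_prob_per_frame) {
          dir_sign <- -dir_sign
        }
        speed[i] <- v
        x_true[i + 1L] <- x_true[i] + dir_sign * v * dt
        if (stats::runif(1) < cfg$p_pause_per_frame) s <- "pause"
      } else {
        speed[i] <- 0
        x_true[i + 1L] <- x_true[i]
        if (stats::runif(1) < cfg$p_resume_per_frame) s <- "transport"
      }
    }
    noise_x <- stats::rnorm(n_frames, 0, cfg$localization_sd)
    noise_y <- stats::rnorm(n_frames, 0, cfg$localization_sd)
    tracks[[k]] <- data.frame(
      track_id = k,
      frame = seq_len(n_frames) - 1L,
      t_s = (seq_len(n_frames) - 1L) * dt,
      x_um = x_true + noise_x,
      y_um = noise_y
    )
    states[[k]] <- data.frame(
      track_id = k, interval = seq_len(n_int),
      state = state, true_speed = speed
    )
  }
  structure(list(tracks = do.call(rbind, tracks),
                 states = do.call(rbind, states),
                 config = cfg),
            class = "mtk_trajectory_sim")
}

#' Write a tracking table to CSV
#'
#' @param tracks Data frame with columns
#'   `track_id, frame, t_s, x_um, y_um`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  need <- c("track_id", "frame", "t_s", "x_um", "y_um")
  if (!all(need %in% names(tracks))) {
    stop_mtk(sprintf("tracking table must have columns: %s",
                     paste(need, collapse = ", ")), "mtk_io_error")
  }
  utils::write.csv(tracks[, need], path, row.names = FALSE)
  invisible(path)
}

#' Read a tracking table from CSV
#'
#' @param path CSV file with header
#'   `track_id, frame, t_s, x_um, y_um`.
#' @return Data frame of tracked positions.
#' @export
read_tracks_csv <- function(path) {
  tracks <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "t_s", "x_um", "y_um")
  if (!all(need %in% names(tracks))) {
    stop_mtk(sprintf("'%s' is not a tracking table (need columns %s)",
                     path, paste(need, collapse = ", ")), "mtk_io_error")
  }
  tracks
}
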