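# Independent reference implementations used as oracles.  These are
# deliberately written as plain, slow loops, sharing no code with the
# package internals.

# Brute-force run/pause reference: takes per-interval speeds (um/s) and
# the frame interval, applies the threshold rules literally, and
# returns the run window, labels, and the five transport metrics.
oracle_transport <- function(speeds, dt, v_pause = 0.2,
                             min_pause_frames = 1L) {
  n <- length(speeds)
  supra <- c()
  for (i in 1:n) if (speeds[i] >= v_pause) supra <- c(supra, i)
  if (length(supra) == 0) return(list(motile = FALSE))
  start <- supra[1]
  stop <- supra[length(supra)]
  lab <- character(0)
  for (i in start:stop) {
    lab <- c(lab, if (speeds[i] < v_pause) "pause" else "transport")
  }
  # pause events: maximal pause stretches of >= min_pause_frames
  events <- 0
  i <- 1
  lab2 <- lab
  while (i <= length(lab)) {
    if (lab[i] == "pause") {
      j <- i
      while (j < length(lab) && lab[j + 1] == "pause") j <- j + 1
      if (j - i + 1 >= min_pause_frames) {
        events <- events + 1
      } else {
        for (k in i:j) lab2[k] <- "transport"
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  sp <- speeds[start:stop]
  run_length <- 0
  t_speeds <- c()
  n_pause_int <- 0
  for (i in seq_along(sp)) {
    if (lab2[i] == "transport") {
      run_length <- run_length + sp[i] * dt
      t_speeds <- c(t_speeds, sp[i])
    } else {
      n_pause_int <- n_pause_int + 1
    }
  }
  run_time <- length(sp) * dt
  list(motile = TRUE, start = start, stop = stop, labels = lab2,
       run_length = run_length, run_time = run_time,
       total_run_velocity = run_length / run_time,
       transport_velocity = if (length(t_speeds)) mean(t_speeds) else NA,
       pausing_time_total = n_pause_int * dt,
       pausing_time_ratio = n_pause_int * dt / run_time,
       n_pauses = events,
       pausing_frequency = if (run_length > 0) events / run_length else NA)
}

# Turns a speed sequence into a 1-D tracking table (positions are the
# cumulative displacements).
track_from_speeds <- function(speeds, dt = 2) {
  data.frame(t_s = (0:length(speeds)) * dt,
             x_um = cumsum(c(0, speeds * dt)),
             y_um = 0)
}

# Exhaustive two-sided Mann-Whitney p-value for two small samples
# without ties: enumerates every assignment of the pooled values to
# group A.
oracle_mw_p <- function(a, b) {
  pool <- c(a, b)
  n_a <- length(a)
  idx <- utils::combn(length(pool), n_a)
  u_obs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  us <- apply(idx, 2, function(ii) {
    aa <- pool[ii]
    bb <- pool[-ii]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  })
  m <- length(us)
  p <- 2 * min(sum(us <= u_obs) / m, sum(us >= u_obs) / m)
  min(p, 1)
}

# Weak compositions of total into k parts by filtering a full grid.
oracle_compositions <- function(k, total) {
  g <- as.matrix(expand.grid(rep(list(0:total), k)))
  g[rowSums(g) == total, , drop = FALSE]
}

# Streaming: map generator patterns to the expected classifier call.
expected_call <- c(circular_central = "circular_central",
                   circular_anterior_biased = "circular_anterior_biased",
                   disordered = "abnormal_chaotic",
                   partial_posterior_disrupted = "abnormal_partial")

classify_movie <- function(pattern, seed, ...) {
  mv <- simulate_streaming_movie(
    streaming_sim_config(pattern = pattern, seed = seed, ...))
  classify_streaming(estimate_flow(mv))
}
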