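# End-to-end pipeline: one configuration object holding every module's
# thresholds, a fixture generator with ground truth, and a runner that
# turns a fixture-layout input directory into metric tables and summary
# reports.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    transport = list(v_pause = 0.2, d_min_motile = 2, min_pause_frames = 1L,
                     axis = c(1, 0)),
    streaming = list(kappa_circular = 0.6, ap_anterior_max = 0.4,
                     posterior_frac = 0.4, kappa_posterior_min = 0.3,
                     kappa_anterior_min = 0.6, kappa_posterior_max = 0.3,
                     min_vectors = 5L, patch_px = 16L, step_px = 12L,
                     search_px = 8L, frame_lag = 3L, pair_step = 10L,
                     min_peak = 0.3),
    ptm = list(tolerance_da = 0.01),
    oocyte = list(threshold_frac = 0.5, line_width = 50L,
                  margin_frac = 0.1, prominence_frac = 0.2,
                  band_frac = 0.15, ratio_min = 1.3)
  )
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, "$", key) else key
    if (!key %in% names(base)) {
      stop_mtk(sprintf("unknown configuration key '%s'", full),
               "mtk_config_error")
    }
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]])) {
        stop_mtk(sprintf("'%s' must be a named list", full),
                 "mtk_config_error")
      }
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Pipeline configuration
#'
#' All module parameters in one validated object.  Defaults equal the
#' documented per-module defaults; unknown keys are rejected so a typo
#' cannot silently fall back to a default.
#'
#' @param ... Named overrides, nested per module, e.g.
#'   `transport = list(v_pause = 0.25)`.
#' @return Object of class `mtk_pipeline_config`.
#' @examples
#' cfg <- pipeline_config(seed = 7, transport = list(v_pause = 0.25))
#' @export
pipeline_config <- function(...) {
  cfg <- merge_config(default_pipeline_config(), list(...))
  check_positive(cfg$transport$v_pause, "transport$v_pause")
  check_positive(cfg$transport$d_min_motile, "transport$d_min_motile",
                 strict = FALSE)
  check_count(cfg$transport$min_pause_frames, "transport$min_pause_frames",
              min = 1L)
  check_prob(cfg$streaming$posterior_frac, "streaming$posterior_frac")
  check_positive(cfg$ptm$tolerance_da, "ptm$tolerance_da")
  check_prob(cfg$oocyte$margin_frac, "oocyte$margin_frac")
  structure(cfg, class = "mtk_pipeline_config")
}

#' Generate the packaged demo fixture set
#'
#' Writes, under `out_dir`: an exact-counts PSM table reproducing the
#' published wild-type / hypomorph / null count structure
#' (58 general-isotype PSMs split 17/29/8/4 over 0-3 added Glu, 24 with
#' a single mono-glutamylated PSM, 6 unmodified, plus 12/12/4
#' ovarian-isotype PSMs), 20 trajectories, 4 streaming movies (one per
#' pattern), and 6 oocyte images with geometry, each with ground-truth
#' JSON sidecars.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving all generators.
#' @return Invisibly, a list of written file paths.
#' @export
generate_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(seed, 40L)
  paths <- list()

  # --- PSM table: exact published count structure ------------------
  cfgs <- list(
    psm_sim_config(genotype = "w", n_psm_84bd = 58L, n_psm_67c = 12L,
                   sidechain_probs = c(17, 29, 8, 4) / 58,
                   exact_counts = TRUE, seed = seeds[1]),
    psm_sim_config(genotype = "TTLL5_pBac", n_psm_84bd = 24L,
                   n_psm_67c = 12L,
                   sidechain_probs = c(23, 1, 0, 0) / 24,
                   exact_counts = TRUE, seed = seeds[2]),
    psm_sim_config(genotype = "TTLL5_MiEx", n_psm_84bd = 6L,
                   n_psm_67c = 4L,
                   sidechain_probs = c(1, 0, 0, 0),
                   exact_counts = TRUE, seed = seeds[3])
  )
  psms <- simulate_psm_table(cfgs)
  paths$psms <- write_psm_tsv(psms, file.path(out_dir, "psms.tsv"))
  jsonlite::write_json(attr(psms, "truth"),
                       file.path(out_dir, "psms_truth.json"),
                       dataframe = "rows", digits = NA)

  # --- trajectories -------------------------------------------------
  sim <- simulate_trajectories(trajectory_sim_config(n_tracks = 20L,
                                                     seed = seeds[4]))
  paths$tracks <- write_tracks_csv(sim$tracks,
                                   file.path(out_dir, "tracks.csv"))
  jsonlite::write_json(sim$states, file.path(out_dir, "tracks_truth.json"),
                       dataframe = "rows", digits = NA)

  # --- streaming movies (one per pattern) ---------------------------
  patterns <- c("circular_central", "circular_anterior_biased",
                "disordered", "partial_posterior_disrupted")
  movie_truth <- list()
  for (i in seq_along(patterns)) {
    mv <- simulate_streaming_movie(
      streaming_sim_config(pattern = patterns[i], seed = seeds[4 + i]))
    f <- file.path(out_dir, sprintf("movie_%s.tif", patterns[i]))
    write_movie_tiff(mv, f)
    paths[[paste0("movie_", patterns[i])]] <- f
    movie_truth[[patterns[i]]] <- list(
      pattern = patterns[i],
      center_frac_ap = mv$truth$center_frac_ap,
      pixel_size_um = mv$pixel_size_um,
      frame_interval_s = mv$frame_interval_s)
  }
  jsonlite::write_json(movie_truth, file.path(out_dir, "movies_truth.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- oocyte images ------------------------------------------------
  oo_cfgs <- list(
    crescent40 = oocyte_sim_config(crescent_arc_um = 40, seed = seeds[10]),
    crescent80 = oocyte_sim_config(crescent_arc_um = 80, seed = seeds[11]),
    flat = oocyte_sim_config(crescent_amplitude = 0, seed = seeds[12]),
    central_peak = oocyte_sim_config(
      inner_peaks = list(c(0.6, 120, 8)), seed = seeds[13]),
    double_peak = oocyte_sim_config(
      inner_peaks = list(c(0.3, 120, 8), c(0.75, 120, 8)),
      seed = seeds[14]),
    anterior_crescent = oocyte_sim_config(
      crescent_center_arc_frac = 0.02, seed = seeds[15])
  )
  oo_truth <- list()
  for (nm in names(oo_cfgs)) {
    sim_o <- simulate_oocyte_image(oo_cfgs[[nm]])
    f <- file.path(out_dir, sprintf("oocyte_%s.tif", nm))
    write_image_tiff(sim_o$image, f)
    write_geometry_json(sim_o$geometry,
                        file.path(out_dir, sprintf("oocyte_%s_geom.json", nm)))
    paths[[paste0("oocyte_", nm)]] <- f
    oo_truth[[nm]] <- sim_o$truth
  }
  jsonlite::write_json(oo_truth, file.path(out_dir, "oocytes_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Run the full analysis pipeline on an input directory
#'
#' Expects the fixture layout written by [generate_fixtures()]
#' (`tracks.csv`, `psms.tsv`, `movie_*.tif` + `movies_truth.json` for
#' acquisition metadata, `oocyte_*.tif` + matching `*_geom.json`); any
#' of the four input kinds may be absent and its stage is skipped.
#' Writes per-track metric CSVs, pattern and enrichment summaries, and
#' a JSON log of every parameter used.  Deterministic given the
#' configuration seed.
#'
#' @param config [pipeline_config()].
#' @param input_dir Directory with the inputs.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results per stage.
#' @export
run_pipeline <- function(config, input_dir, out_dir) {
  stopifnot(inherits(config, "mtk_pipeline_config"))
  if (!dir.exists(input_dir)) {
    stop_mtk(sprintf("input directory '%s' does not exist", input_dir),
             "mtk_io_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  results <- list()

  tr_path <- file.path(input_dir, "tracks.csv")
  if (file.exists(tr_path)) {
    params <- segmentation_params(config$transport$v_pause,
                                  config$transport$d_min_motile,
                                  config$transport$min_pause_frames)
    metrics <- transport_metrics(read_tracks_csv(tr_path), params,
                                 axis = config$transport$axis)
    utils::write.csv(metrics, file.path(out_dir, "transport_metrics.csv"),
                     row.names = FALSE)
    results$transport <- metrics
  }

  psm_path <- file.path(input_dir, "psms.tsv")
  if (file.exists(psm_path)) {
    summ <- summarize_glutamylation(read_psm_tsv(psm_path),
                                    tolerance_da = config$ptm$tolerance_da)
    utils::write.csv(as.data.frame(summ),
                     file.path(out_dir, "ptm_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.data.frame(summ),
                         file.path(out_dir, "ptm_summary.json"),
                         dataframe = "rows", digits = NA)
    results$ptm <- summ
  }

  movie_files <- sort(list.files(input_dir, pattern = "^movie_.*\\.tif$",
                                 full.names = TRUE))
  if (length(movie_files)) {
    meta_path <- file.path(input_dir, "movies_truth.json")
    meta <- if (file.exists(meta_path)) {
      jsonlite::read_json(meta_path, simplifyVector = TRUE)
    } else NULL
    th <- streaming_thresholds(
      config$streaming$kappa_circular, config$streaming$ap_anterior_max,
      config$streaming$posterior_frac, config$streaming$kappa_posterior_min,
      config$streaming$kappa_anterior_min,
      config$streaming$kappa_posterior_max, config$streaming$min_vectors)
    calls <- lapply(movie_files, function(f) {
      key <- sub("^movie_(.*)\\.tif$", "\\1", basename(f))
      px <- meta[[key]]$pixel_size_um %||% 1
      dt <- meta[[key]]$frame_interval_s %||% 2
      mv <- read_movie_tiff(f, pixel_size_um = px, frame_interval_s = dt)
      flow <- estimate_flow(mv, config$streaming$patch_px,
                            config$streaming$step_px,
                            config$streaming$search_px,
                            config$streaming$frame_lag,
                            config$streaming$pair_step,
                            config$streaming$min_peak)
      cl <- classify_streaming(flow, th)
      list(movie = basename(f), pattern = cl$pattern,
           coherence = cl$coherence,
           posterior_coherence = cl$posterior_coherence,
           center_frac_ap = cl$center_frac_ap)
    })
    calls_df <- do.call(rbind, lapply(calls, as.data.frame))
    jsonlite::write_json(calls_df, file.path(out_dir, "streaming_calls.json"),
                         dataframe = "rows", digits = NA)
    summary_df <- summarize_patterns(
      data.frame(genotype = "all", pattern = calls_df$pattern))
    utils::write.csv(summary_df,
                     file.path(out_dir, "streaming_summary.csv"),
                     row.names = FALSE)
    results$streaming <- list(calls = calls_df, summary = summary_df)
  }

  oo_files <- sort(list.files(input_dir, pattern = "^oocyte_.*\\.tif$",
                              full.names = TRUE))
  if (length(oo_files)) {
    rows <- lapply(oo_files, function(f) {
      geom_path <- sub("\\.tif$", "_geom.json", f)
      if (!file.exists(geom_path)) {
        stop_mtk(sprintf("missing geometry file '%s'", geom_path),
                 "mtk_io_error")
      }
      geom <- read_geometry_json(geom_path)
      geom$line_width <- config$oocyte$line_width
      img <- read_image_tiff(f)
      cres <- suppressWarnings(
        measure_crescent_length(img, geom, config$oocyte$threshold_frac))
      prof <- ap_profile(img, geom)
      pk <- detect_inner_peaks(prof, config$oocyte$margin_frac,
                               config$oocyte$prominence_frac)
      enr <- call_posterior_enrichment(img, geom, config$oocyte$band_frac,
                                       config$oocyte$ratio_min)
      data.frame(image = basename(f), crescent_um = cres,
                 peak_class = pk$classification,
                 posterior_enriched = enr$enriched,
                 enrichment_ratio = enr$ratio)
    })
    oo_df <- do.call(rbind, rows)
    utils::write.csv(oo_df, file.path(out_dir, "oocyte_measurements.csv"),
                     row.names = FALSE)
    results$oocyte <- oo_df
  }

  log <- list(config = unclass(config),
              inputs = list.files(input_dir),
              outputs = list.files(out_dir))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
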