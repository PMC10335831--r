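# Synthetic PSM-table generator with programmed per-genotype sidechain
# length distributions over the four modifiable tail glutamates.

#' Configuration for the PSM table simulator
#'
#' Generates one genotype's worth of C-terminal PSMs for the two
#' alpha-tubulin isotype classes, with a programmed distribution of
#' total added glutamates (0-3) for the general (Tyr-terminal) isotype
#' and, by default, no modification on the ovarian (Phe-terminal)
#' isotype.
#'
#' @param genotype Genotype label written into each row.
#' @param n_psm_84bd,n_psm_67c PSM counts for the two isotype classes.
#' @param sidechain_probs Probability vector `(p0, p1, p2, p3)` over
#'   total added Glu for the general isotype; must sum to 1 within
#'   1e-9.
#' @param sidechain_probs_67c Same for the ovarian isotype (default:
#'   all mass on 0).
#' @param site_weights Probability weights over the four modifiable
#'   sites E443, E445, E448, E449 used when placing sidechains; must
#'   sum to 1 within 1e-9.
#' @param exact_counts If `TRUE`, category counts are assigned
#'   deterministically as `n * p` (each must then be an integer within
#'   1e-9) instead of drawn multinomially; site placement still uses
#'   the seed.  This mode reproduces printed count tables exactly.
#' @param tails [tail_model()] supplying tail sequences and site
#'   positions.
#' @param peptide_prefix Residues prepended to the tail to form the
#'   full peptide.
#' @param seed Integer seed.
#' @return Object of class `mtk_psm_sim_config`.
#' @export
psm_sim_config <- function(genotype = "w",
                           n_psm_84bd = 58L,
                           n_psm_67c = 12L,
                           sidechain_probs = c(17, 29, 8, 4) / 58,
                           sidechain_probs_67c = c(1, 0, 0, 0),
                           site_weights = c(E443 = 0.2, E445 = 0.3,
                                            E448 = 0.3, E449 = 0.2),
                           exact_counts = FALSE,
                           tails = tail_model(),
                           peptide_prefix = "KDYEEVGVDSV",
                           seed = 1L) {
  check_count(n_psm_84bd, "n_psm_84bd", min = 0L)
  check_count(n_psm_67c, "n_psm_67c", min = 0L)
  check_probvec <- function(p, name, len) {
    if (length(p) != len || any(!is.finite(p)) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-9) {
      stop_mtk(sprintf("'%s' must be %d non-negative values summing to 1",
                       name, len), "mtk_config_error")
    }
  }
  check_probvec(sidechain_probs, "sidechain_probs", 4L)
  check_probvec(sidechain_probs_67c, "sidechain_probs_67c", 4L)
  check_probvec(site_weights, "site_weights", 4L)
  structure(list(genotype = genotype,
                 n_psm_84bd = as.integer(n_psm_84bd),
                 n_psm_67c = as.integer(n_psm_67c),
                 sidechain_probs = sidechain_probs,
                 sidechain_probs_67c = sidechain_probs_67c,
                 site_weights = site_weights,
                 exact_counts = isTRUE(exact_counts),
                 tails = tails,
                 peptide_prefix = peptide_prefix,
                 seed = as.integer(seed)),
            class = "mtk_psm_sim_config")
}

category_counts <- function(n, probs, exact) {
  if (n == 0L) return(integer(4))
  if (exact) {
    counts <- n * probs
    if (any(abs(counts - round(counts)) > 1e-9)) {
      stop_mtk("exact-counts mode needs n * probs to be integers",
               "mtk_config_error")
    }
    as.integer(round(counts))
  } else {
    as.integer(stats::rmultinom(1, n, probs))
  }
}

mods_string_for_length <- function(len, site_weights, site_positions) {
  if (len == 0L) return("")
  draws <- sample(names(site_weights), len, replace = TRUE,
                  prob = site_weights)
  per_site <- table(draws)
  pos <- site_positions[match(names(per_site),
                              names(site_positions))]
  ord <- order(pos)
  paste(sprintf("E%d(+%.4f)", pos[ord],
                as.integer(per_site)[ord] * GLU_RESIDUE_MASS),
        collapse = ";")
}

#' Simulate a PSM table
#'
#' Emits one row per PSM with the peptide sequence (prefix + full
#' isotype tail), a modification string placing the drawn sidechain
#' glutamates on the configured sites, and the genotype label.
#' Category counts follow the configured sidechain-length distribution
#' (multinomially, or exactly in `exact_counts` mode).
#'
#' @param cfg A [psm_sim_config()], or a list of them (one per
#'   genotype) whose tables are concatenated.
#' @return Data frame `psm_id, genotype, isotype_hint, peptide, mods,
#'   score` with a `"truth"` attribute holding the per-isotype category
#'   counts.
#' @export
simulate_psm_table <- function(cfg) {
  if (!inherits(cfg, "mtk_psm_sim_config")) {
    if (is.list(cfg) &&
        all(vapply(cfg, inherits, logical(1), "mtk_psm_sim_config"))) {
      tabs <- lapply(cfg, simulate_psm_table)
      out <- do.call(rbind, tabs)
      out$psm_id <- sprintf("psm%05d", seq_len(nrow(out)))
      attr(out, "truth") <- do.call(rbind, lapply(tabs, attr, "truth"))
      return(out)
    }
    stop_mtk("cfg must be a psm_sim_config or list of them",
             "mtk_config_error")
  }
  set.seed(cfg$seed)
  tails <- cfg$tails
  site_positions <- stats::setNames(tails$site_positions,
                                    names(tails$sites_84bd))

  counts_84 <- category_counts(cfg$n_psm_84bd, cfg$sidechain_probs,
                               cfg$exact_counts)
  counts_67 <- category_counts(cfg$n_psm_67c, cfg$sidechain_probs_67c,
                               cfg$exact_counts)
  lens_84 <- rep(0:3, counts_84)
  lens_67 <- rep(0:3, counts_67)

  make_rows <- function(lens, tail_seq, hint) {
    if (length(lens) == 0L) return(NULL)
    data.frame(
      genotype = cfg$genotype,
      isotype_hint = hint,
      peptide = paste0(cfg$peptide_prefix, tail_seq),
      mods = vapply(lens, mods_string_for_length, character(1),
                    site_weights = cfg$site_weights,
                    site_positions = site_positions),
      score = round(stats::runif(length(lens), 40, 120), 2)
    )
  }
  out <- rbind(make_rows(lens_84, tails$tail_84bd, "tub84bd"),
               make_rows(lens_67, tails$tail_67c, "tub67c"))
  if (is.null(out)) {
    stop_mtk("configuration generates an empty PSM table",
             "mtk_config_error")
  }
  out <- cbind(psm_id = sprintf("psm%05d", seq_len(nrow(out))), out)
  attr(out, "truth") <- data.frame(
    genotype = cfg$genotype,
    isotype = c("tub84bd", "tub67c"),
    n0 = c(counts_84[1], counts_67[1]),
    n1 = c(counts_84[2], counts_67[2]),
    n2 = c(counts_84[3], counts_67[3]),
    n3 = c(counts_84[4], counts_67[4])
  )
  out
}
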