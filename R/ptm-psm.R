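# Tabulation of alpha-tubulin C-terminal glutamylation from
# peptide-spectrum-match (PSM) tables: isotype assignment by C-terminal
# tail, decomposition of modification mass deltas into glutamyl sidechain
# lengths, and genotype-level frequency summaries.

# Monoisotopic mass of a glutamyl residue added to a sidechain (Da).
GLU_RESIDUE_MASS <- 129.04259
# Glycylation has the same nominal mass change as the alkylation artifact
# on Glu, so +57.021464 Da can never be attributed unambiguously.
GLY_RESIDUE_MASS <- 57.021464

#' C-terminal tail model for alpha-tubulin isotypes
#'
#' Drosophila alpha-tubulin isotypes are distinguished by their
#' C-terminal tails: the general isotypes end in Tyr (the tryptic
#' C-terminal peptides of the two general isotypes are identical, so
#' they are pooled as one class), while the ovarian-specific isotype
#' ends in Phe.  The modifiable sites of the Tyr-terminal tail are the
#' four glutamates E443 and E445 (context -GEGEG-) and the consecutive
#' E448/E449 (context -GAEEY).
#'
#' @param tail_84bd Tail suffix of the pooled general isotype
#'   (`"GEGEGAEEY"`, positions 442-450).
#' @param start_84bd Residue number of the first tail position.
#' @param sites_84bd Named integer vector of modifiable-site offsets
#'   within `tail_84bd` (1-based).
#' @param tail_67c Tail suffix of the ovarian-specific isotype.  The
#'   default is a synthetic stand-in that carries the defining terminal
#'   Phe; replace it with the true sequence when matching real search
#'   output.
#' @return Object of class `mtk_tail_model`.
#' @export
tail_model <- function(tail_84bd = "GEGEGAEEY",
                       start_84bd = 442L,
                       sites_84bd = c(E443 = 2L, E445 = 4L,
                                      E448 = 7L, E449 = 8L),
                       tail_67c = "GEGEGAEEF") {
  stopifnot(is.character(tail_84bd), is.character(tail_67c))
  offs <- as.integer(sites_84bd)
  if (any(offs < 1L | offs > nchar(tail_84bd))) {
    stop_mtk("site offsets must lie within the tail sequence",
             "mtk_config_error")
  }
  if (any(substring(tail_84bd, offs, offs) != "E")) {
    stop_mtk("all modifiable sites must be glutamates in the tail",
             "mtk_config_error")
  }
  structure(list(tail_84bd = tail_84bd, start_84bd = as.integer(start_84bd),
                 sites_84bd = sites_84bd, tail_67c = tail_67c,
                 site_positions = start_84bd - 1L + offs),
            class = "mtk_tail_model")
}

#' Assign an alpha-tubulin isotype from a peptide sequence
#'
#' Suffix match of the peptide against the isotype tails of the tail
#' model.  Peptides that carry neither full tail (including ragged or
#' partial C-termini) are `"other"` and are excluded from frequency
#' totals, which count only peptides containing the entire primary
#' C-terminal sequence.
#'
#' @param peptide Amino-acid string.
#' @param tails A [tail_model()].
#' @return `"tub84bd"`, `"tub67c"`, or `"other"`.
#' @export
assign_isotype <- function(peptide, tails = tail_model()) {
  if (!is.character(peptide) || length(peptide) != 1L || !nzchar(peptide)) {
    stop_mtk("peptide must be a non-empty string", "mtk_parse_error")
  }
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", peptide)) {
    stop_mtk(sprintf("peptide '%s' contains non-amino-acid characters",
                     peptide), "mtk_parse_error")
  }
  if (endsWith(peptide, tails$tail_84bd)) "tub84bd"
  else if (endsWith(peptide, tails$tail_67c)) "tub67c"
  else "other"
}

#' Parse a modification string
#'
#' Modifications are encoded `"SITE(+MASS)"`, semicolon-separated, e.g.
#' `"E443(+129.0426);E449(+258.0852)"`.
#'
#' @param mods Modification string (may be empty or `NA` for an
#'   unmodified peptide).
#' @return Data frame `residue, position, delta_mass` (0 rows if
#'   unmodified).
#' @export
parse_mods <- function(mods) {
  if (is.na(mods) || !nzchar(trimws(mods))) {
    return(data.frame(residue = character(0), position = integer(0),
                      delta_mass = numeric(0)))
  }
  parts <- trimws(strsplit(mods, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  m <- regmatches(parts, regexec("^([A-Z])([0-9]+)\\(\\+([0-9.]+)\\)$",
                                 parts))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop_mtk(sprintf("cannot parse modification '%s'", parts[bad][1]),
             "mtk_parse_error")
  }
  data.frame(
    residue = vapply(m, `[`, character(1), 2L),
    position = as.integer(vapply(m, `[`, character(1), 3L)),
    delta_mass = as.numeric(vapply(m, `[`, character(1), 4L))
  )
}

#' Glutamyl sidechain length of one PSM
#'
#' Matches each modification mass delta to an integer number of
#' glutamyl residues (n x 129.04259 Da) within `tolerance_da` per added
#' Glu.  Deltas matching +57.021464 Da are flagged ambiguous - the
#' standard cysteine-alkylation step can modify Glu with exactly the
#' mass change of glycylation - and are never counted as Glu.  Deltas
#' matching neither series raise an unknown-modification warning and
#' the record keeps the length of its resolvable modifications.
#'
#' @param mods Modification string or pre-parsed data frame from
#'   [parse_mods()].
#' @param tolerance_da Mass tolerance per added Glu (Da).
#' @return List with `total` (added Glu count), `by_site` (named
#'   integer vector, names `"E<position>"`), and `ambiguous` (TRUE if
#'   any +57.021464 Da delta was seen).
#' @export
sidechain_length <- function(mods, tolerance_da = 0.01) {
  tab <- if (is.data.frame(mods)) mods else parse_mods(mods)
  by_site <- integer(0)
  ambiguous <- FALSE
  total <- 0L
  for (i in seq_len(nrow(tab))) {
    delta <- tab$delta_mass[i]
    if (delta <= 0) {
      stop_mtk("modification mass deltas must be positive",
               "mtk_parse_error")
    }
    n <- round(delta / GLU_RESIDUE_MASS)
    if (n >= 1 && abs(delta - n * GLU_RESIDUE_MASS) <= tolerance_da * n) {
      key <- paste0(tab$residue[i], tab$position[i])
      by_site[key] <- (if (key %in% names(by_site)) by_site[[key]] else 0L) +
        as.integer(n)
      total <- total + as.integer(n)
    } else if (abs(delta - GLY_RESIDUE_MASS) <= tolerance_da) {
      ambiguous <- TRUE
    } else {
      warning(sprintf(
        "unknown modification mass %+0.5f Da at %s%d; not counted",
        delta, tab$residue[i], tab$position[i]), call. = FALSE)
    }
  }
  list(total = total, by_site = by_site, ambiguous = ambiguous)
}

#' Summarize C-terminal glutamylation per genotype and isotype
#'
#' Counts, per genotype and isotype, the PSMs whose C-terminal peptide
#' contains the entire primary tail sequence, split by total glutamyl
#' sidechain length (0, 1, 2, 3, or more).  Frequencies are the
#' category counts divided by the total PSM count, as percentages
#' rounded half-up; the total modified frequency derives from the raw
#' counts `(n1 + n2 + n3 + n_gt3) / total`, not from the rounded
#' per-category percentages.  Counts are canonical: percentages are
#' always recomputed from them.
#'
#' @param psm_table Data frame with columns `genotype`, `peptide`,
#'   `mods` (and optionally `psm_id`, `score`), e.g. from
#'   [read_psm_tsv()] or [simulate_psm_table()].
#' @param tails A [tail_model()].
#' @param tolerance_da Mass tolerance per added Glu (Da).
#' @return Object of class `mtk_glu_summary`: a data frame with one row
#'   per genotype x isotype (`genotype, isotype, total_psm, n0, n1, n2,
#'   n3, n_gt3, n_ambiguous, pct_1e, pct_2e, pct_3e, pct_modified`).
#' @export
summarize_glutamylation <- function(psm_table, tails = tail_model(),
                                    tolerance_da = 0.01) {
  need <- c("genotype", "peptide", "mods")
  if (!all(need %in% names(psm_table))) {
    stop_mtk(sprintf("PSM table must have columns: %s",
                     paste(need, collapse = ", ")), "mtk_parse_error")
  }
  iso <- vapply(psm_table$peptide, assign_isotype, character(1),
                tails = tails, USE.NAMES = FALSE)
  lens <- integer(nrow(psm_table))
  amb <- logical(nrow(psm_table))
  for (i in seq_len(nrow(psm_table))) {
    sl <- sidechain_length(psm_table$mods[i], tolerance_da)
    lens[i] <- sl$total
    amb[i] <- sl$ambiguous
  }
  keep <- iso != "other"
  if (!all(keep)) {
    warning(sprintf(
      "%d PSM(s) without a complete C-terminal tail excluded from totals",
      sum(!keep)), call. = FALSE)
  }
  df <- data.frame(genotype = psm_table$genotype[keep],
                   isotype = iso[keep], len = lens[keep],
                   ambiguous = amb[keep])
  if (nrow(df) == 0L) {
    stop_mtk("no PSM matches any isotype tail", "mtk_parse_error")
  }
  cells <- unique(df[, c("genotype", "isotype")])
  cells <- cells[order(cells$genotype, cells$isotype), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- df[df$genotype == cells$genotype[i] &
                df$isotype == cells$isotype[i], ]
    total <- nrow(sub)
    n <- function(k) sum(sub$len == k)
    n_gt3 <- sum(sub$len > 3)
    n_mod <- sum(sub$len >= 1)
    data.frame(
      genotype = cells$genotype[i], isotype = cells$isotype[i],
      total_psm = total, n0 = n(0), n1 = n(1), n2 = n(2), n3 = n(3),
      n_gt3 = n_gt3, n_ambiguous = sum(sub$ambiguous),
      pct_1e = round_half_up(100 * n(1) / total),
      pct_2e = round_half_up(100 * n(2) / total),
      pct_3e = round_half_up(100 * n(3) / total),
      pct_modified = round_half_up(100 * n_mod / total)
    )
  })
  structure(do.call(rbind, rows), class = c("mtk_glu_summary",
                                            "data.frame"))
}

#' Ratio of general to ovarian-specific isotype PSM totals
#'
#' Plain ratio of total C-terminal PSM counts (Tyr-terminal general
#' isotype over Phe-terminal ovarian isotype) per genotype, reported to
#' one decimal.
#'
#' @param summary A [summarize_glutamylation()] result.
#' @return Data frame `genotype, total_84bd, total_67c, ratio`.  The
#'   ratio is `NA` (with a warning) when the denominator is zero.
#' @export
isotype_ratio <- function(summary) {
  gts <- unique(summary$genotype)
  rows <- lapply(gts, function(g) {
    t84 <- summary$total_psm[summary$genotype == g &
                               summary$isotype == "tub84bd"]
    t67 <- summary$total_psm[summary$genotype == g &
                               summary$isotype == "tub67c"]
    t84 <- if (length(t84)) t84 else 0L
    t67 <- if (length(t67)) t67 else 0L
    r <- if (t67 > 0) round(t84 / t67, 1) else NA_real_
    if (t67 == 0) {
      warning(sprintf("genotype '%s': no ovarian-isotype PSMs; ratio undefined",
                      g), call. = FALSE)
    }
    data.frame(genotype = g, total_84bd = t84, total_67c = t67, ratio = r)
  })
  do.call(rbind, rows)
}

#' Enumerate glutamylation isoforms
#'
#' All ways of distributing `total_E` added glutamates over `n_sites`
#' modifiable sites (weak compositions).  The count is
#' `choose(total_E + n_sites - 1, n_sites - 1)`.
#'
#' @param n_sites Number of modifiable sites (>= 1).
#' @param total_E Total added glutamates (>= 0).
#' @return Integer matrix with one row per isoform and one column per
#'   site.
#' @examples
#' nrow(enumerate_isoforms(4, 2))  # 10
#' @export
enumerate_isoforms <- function(n_sites, total_E) {
  check_count(n_sites, "n_sites", min = 1L)
  check_count(total_E, "total_E", min = 0L)
  if (n_sites == 1L) return(matrix(as.integer(total_E), 1L, 1L))
  out <- list()
  for (k in 0:total_E) {
    rest <- enumerate_isoforms(n_sites - 1L, total_E - k)
    out[[length(out) + 1L]] <- cbind(as.integer(k), rest)
  }
  res <- do.call(rbind, out)
  dimnames(res) <- NULL
  res
}

#' Read a PSM table from TSV
#'
#' Expected columns: `psm_id, genotype, peptide, mods` (plus optional
#' `isotype_hint`, `score`).  A named `column_map` adapts third-party
#' exports, e.g. `c(peptide = "Sequence", mods = "Modifications")`.
#'
#' @param path TSV file path.
#' @param column_map Optional named character vector mapping standard
#'   column names to the names used in the file.
#' @return Data frame in the standard PSM layout.
#' @export
read_psm_tsv <- function(path, column_map = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  for (std in names(column_map)) {
    src <- column_map[[std]]
    if (!src %in% names(tab)) {
      stop_mtk(sprintf("mapped column '%s' not found in '%s'", src, path),
               "mtk_io_error")
    }
    tab[[std]] <- tab[[src]]
  }
  need <- c("genotype", "peptide", "mods")
  if (!all(need %in% names(tab))) {
    stop_mtk(sprintf("'%s' lacks PSM columns: %s", path,
                     paste(setdiff(need, names(tab)), collapse = ", ")),
             "mtk_io_error")
  }
  tab$mods[is.na(tab$mods)] <- ""
  tab
}

#' Write a PSM table to TSV
#'
#' @param psm_table Data frame in the standard PSM layout.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psm_tsv <- function(psm_table, path) {
  utils::write.table(psm_table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
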