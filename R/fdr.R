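#' Target-decoy q-values at the PSM level
#'
#' Assumes rank-1 filtering (one PSM per scan, as produced by
#' [search_spectra()]). At each score threshold the FDR estimate is
#' `#decoys >= s / max(1, #targets >= s)` (optionally with the +1 correction
#' on the decoy count), and q-values are the running minimum of the estimate
#' from high to low score, so they are monotone non-increasing in score.
#'
#' @param psms PSM tibble with `score` and `is_decoy` columns.
#' @param plus_one Add 1 to the decoy count (conservative variant).
#' @return `psms` with a `qvalue` column appended (original row order).
#' @export
compute_qvalues <- function(psms, plus_one = FALSE) {
  if (nrow(psms) == 0L) {
    psms$qvalue <- numeric(0)
    return(psms)
  }
  tie_ppm <- if ("precursor_ppm" %in% names(psms)) {
    abs(psms$precursor_ppm)
  } else {
    rep(0, nrow(psms))
  }
  ord <- order(-psms$score, tie_ppm)
  dec <- psms$is_decoy[ord]
  n_dec <- cumsum(dec)
  n_tgt <- cumsum(!dec)
  fdr <- (n_dec + as.integer(plus_one)) / pmax(1L, n_tgt)
  # equal scores share the worst estimate of their block
  s <- psms$score[ord]
  for (i in rev(seq_along(fdr))[-1L]) {
    if (s[i] == s[i + 1L]) fdr[i] <- fdr[i + 1L]
  }
  q <- rev(cummin(rev(pmin(fdr, 1))))
  psms$qvalue <- numeric(nrow(psms))
  psms$qvalue[ord] <- q
  psms
}

#' Accept PSMs at an FDR threshold
#'
#' Keeps target PSMs with `qvalue <= alpha`; decoys passing the threshold are
#' excluded from the report but their count is attached as the
#' `n_decoys_passing` attribute for logging.
#'
#' @param psms PSM tibble with q-values (see [compute_qvalues()]).
#' @param alpha FDR threshold (default 0.05, the conventional PSM-level cut).
#' @return Accepted target PSMs.
#' @export
filter_at_fdr <- function(psms, alpha = 0.05) {
  stopifnot("qvalue" %in% names(psms))
  keep <- psms$qvalue <= alpha
  out <- psms[keep & !psms$is_decoy, ]
  attr(out, "n_decoys_passing") <- sum(keep & psms$is_decoy)
  out
}

#' Collapse accepted PSMs to unique cross-linked peptides
#'
#' The unique key is (bait peptide, prey peptide, prey site, modifications) —
#' the most granular reading of a "cross-linked peptide". The best-scoring
#' PSM is kept as representative of each unique pair.
#'
#' @param accepted Accepted PSM tibble from [filter_at_fdr()].
#' @return List of tibbles: `unique_peptides` (one row per unique pair, with
#'   `n_psms`), `binders` (one row per prey protein with peptide/PSM counts),
#'   `sites` (distinct prey protein residues cross-linked).
#' @export
collapse_to_unique <- function(accepted) {
  if (nrow(accepted) == 0L) {
    return(list(unique_peptides = accepted,
                binders = tibble::tibble(prey_protein = character(),
                                         n_unique_peptides = integer(),
                                         n_psms = integer()),
                sites = tibble::tibble(prey_protein = character(),
                                       site_protein_pos = integer(),
                                       site_residue = character())))
  }
  uniq <- accepted |>
    dplyr::group_by(.data$bait_sequence, .data$prey_sequence,
                    .data$site_position, .data$mods) |>
    dplyr::arrange(dplyr::desc(.data$score), .by_group = TRUE) |>
    dplyr::mutate(n_psms = dplyr::n()) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  binders <- uniq |>
    dplyr::group_by(prey_protein = .data$prey_protein) |>
    dplyr::summarise(n_unique_peptides = dplyr::n(),
                     n_psms = sum(.data$n_psms), .groups = "drop")
  sites <- dplyr::distinct(
    uniq[, c("prey_protein", "site_protein_pos", "site_residue")]
  )
  list(unique_peptides = uniq, binders = binders, sites = sites)
}
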