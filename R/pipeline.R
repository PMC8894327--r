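#' Run configuration for a search
#'
#' Defaults follow the standard acquisition/search parameterization for this
#' chemistry: 10 ppm precursor and 20 ppm fragment tolerance, 5% PSM-level
#' FDR, trypsin with up to 3 missed cleavages, the eight-nucleophile
#' reactive set, and variable Cys carbamidomethylation (+57.02146 Da).
#'
#' @param ncaa_mass ncAA residue mass in Da (required; depends on the ncAA).
#' @param ncaa_site 1-based ncAA position in the bait protein.
#' @param precursor_tol_ppm,frag_tol_ppm Tolerances in ppm.
#' @param fdr PSM-level FDR threshold.
#' @param max_missed Maximum missed cleavages.
#' @param protease Protease rule name (see [protease_rule()]).
#' @param proline_rule Suppress cleavage before proline.
#' @param reactive_residues Allowed cross-link site residues.
#' @param use_cam Include variable Cys carbamidomethylation.
#' @param max_mods Maximum variable modifications per peptide.
#' @param add_decoys Append reversed decoys to the database before indexing.
#' @return A `gecx_run_config` list.
#' @export
run_config <- function(ncaa_mass, ncaa_site,
                       precursor_tol_ppm = 10, frag_tol_ppm = 20,
                       fdr = 0.05, max_missed = 3L, protease = "trypsin",
                       proline_rule = TRUE,
                       reactive_residues = nucleophile_set(),
                       use_cam = TRUE, max_mods = 3L, add_decoys = TRUE) {
  structure(
    list(ncaa_mass = ncaa_mass, ncaa_site = ncaa_site,
         precursor_tol_ppm = precursor_tol_ppm, frag_tol_ppm = frag_tol_ppm,
         fdr = fdr, max_missed = as.integer(max_missed), protease = protease,
         proline_rule = proline_rule, reactive_residues = reactive_residues,
         use_cam = use_cam, max_mods = as.integer(max_mods),
         add_decoys = add_decoys),
    class = "gecx_run_config"
  )
}

#' Run the full cross-link search pipeline
#'
#' Digest, index, search, q-value estimation and FDR filtering, wired
#' together: the computation behind a complete run from database plus
#' spectra to accepted cross-linked peptides.
#'
#' @param proteome Prey protein tibble (targets only; decoys are appended
#'   according to `config$add_decoys`).
#' @param bait_sequence Bait protein sequence.
#' @param spectra Spectrum tibble ([read_mgf()] shape).
#' @param config A [run_config()].
#' @return A `gecx_search` object: list with `psms` (all rank-1 PSMs with
#'   q-values), `accepted`, `collapsed` (see [collapse_to_unique()]),
#'   `counts` (per-stage sizes) and `config`.
#' @export
run_search <- function(proteome, bait_sequence, spectra, config) {
  stopifnot(inherits(config, "gecx_run_config"))
  linker <- crosslinker(ncaa_residue_mass = config$ncaa_mass,
                        reactive_residues = config$reactive_residues)
  rule <- protease_rule(
    config$protease,
    suppressed_before = if (config$proline_rule) NULL else character(),
    max_missed = config$max_missed
  )
  db <- if (config$add_decoys) make_decoys(proteome) else proteome
  mods <- if (config$use_cam) carbamidomethyl() else NULL
  index <- build_prey_index(db, rule, linker, mods = mods,
                            max_mods = config$max_mods)
  baits <- bait_peptides(bait_sequence, config$ncaa_site, rule,
                         linker = linker)
  psms <- search_spectra(spectra, baits, index, linker,
                         precursor_tol_ppm = config$precursor_tol_ppm,
                         frag_tol_ppm = config$frag_tol_ppm,
                         mods = mods, max_mods = config$max_mods)
  psms <- compute_qvalues(psms)
  accepted <- filter_at_fdr(psms, alpha = config$fdr)
  collapsed <- collapse_to_unique(accepted)
  counts <- tibble::tibble(
    n_proteins = nrow(proteome),
    n_index_variants = nrow(index$peptides),
    n_bait_peptides = nrow(baits),
    n_spectra = length(unique(spectra$scan_id)),
    n_psms = nrow(psms),
    n_decoy_psms = sum(psms$is_decoy),
    n_accepted = nrow(accepted),
    n_decoys_passing = attr(accepted, "n_decoys_passing") %||% 0L,
    n_unique_peptides = nrow(collapsed$unique_peptides),
    n_binders = nrow(collapsed$binders)
  )
  structure(
    list(psms = psms, accepted = accepted, collapsed = collapsed,
         counts = counts, config = config),
    class = "gecx_search"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gecx_search <- function(x, ...) {
  c <- x$counts
  cat("<gecx_search> ", c$n_psms, " PSMs from ", c$n_spectra, " spectra; ",
      c$n_accepted, " accepted at q<=", x$config$fdr, " (",
      c$n_unique_peptides, " unique peptides, ", c$n_binders,
      " binder proteins)\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a search result into its PSM table
#'
#' @param x A `gecx_search` object.
#' @param ... Unused.
#' @return The rank-1 PSM tibble with q-values.
#' @method tidy gecx_search
#' @export
tidy.gecx_search <- function(x, ...) x$psms

#' One-row summary of a search run
#'
#' @param x A `gecx_search` object.
#' @param ... Unused.
#' @return One-row tibble of per-stage counts.
#' @method glance gecx_search
#' @export
glance.gecx_search <- function(x, ...) x$counts

#' Evaluate search results against a simulation ground truth
#'
#' Recall is the fraction of implanted links recovered by an accepted PSM
#' with the correct bait and prey peptide; the false discovery proportion
#' (FDP) is the fraction of accepted PSMs that are background scans or wrong
#' pairs (entrapment hits included); site accuracy is the fraction of
#' correct-pair PSMs whose localized site matches the implanted residue.
#'
#' @param result A `gecx_search` object or accepted-PSM tibble.
#' @param truth Ground-truth tibble from [simulate_run()] (with `scan_id`
#'   and `is_background`).
#' @return One-row tibble: `recall`, `fdp`, `site_accuracy`, `n_accepted`,
#'   `n_false`, `n_links`.
#' @export
run_evaluate <- function(result, truth) {
  accepted <- if (inherits(result, "gecx_search")) result$accepted else result
  links <- truth[!truth$is_background, ]
  if (nrow(accepted) == 0L) {
    return(tibble::tibble(recall = 0, fdp = 0, site_accuracy = NA_real_,
                          n_accepted = 0L, n_false = 0L,
                          n_links = nrow(links)))
  }
  m <- match(accepted$scan_id, truth$scan_id)
  tr <- truth[m, ]
  correct_pair <- !is.na(m) & !tr$is_background &
    accepted$bait_sequence == tr$bait_sequence &
    accepted$prey_sequence == tr$prey_sequence &
    accepted$prey_protein == tr$prey_protein
  correct_pair[is.na(correct_pair)] <- FALSE
  n_false <- sum(!correct_pair)
  recovered <- unique(tr$link_id[correct_pair])
  correct_site <- correct_pair &
    accepted$site_position == tr$site_position
  tibble::tibble(
    recall = length(recovered) / max(1L, nrow(links)),
    fdp = n_false / nrow(accepted),
    site_accuracy = if (any(correct_pair)) {
      sum(correct_site, na.rm = TRUE) / sum(correct_pair)
    } else NA_real_,
    n_accepted = nrow(accepted),
    n_false = n_false,
    n_links = nrow(links)
  )
}
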