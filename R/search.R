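#' Enumerate cross-link candidates for one spectrum
#'
#' For every bait variant, looks up prey variants whose conjugate mass lies
#' within the precursor tolerance of the observed neutral mass, then expands
#' one candidate per reactive residue in the prey (positions carrying a
#' variable modification are excluded: a modified side chain cannot also be
#' the cross-link site).
#'
#' @param spectrum One spectrum row (`precursor_mz`, `precursor_charge`).
#' @param baits Bait variant tibble from [prepare_baits()].
#' @param index A [build_prey_index()] result.
#' @param linker A [crosslinker()].
#' @param tol_ppm Precursor tolerance in ppm of the theoretical conjugate
#'   mass.
#' @return Candidate tibble (possibly empty) with bait_/prey_ prefixed
#'   columns, `site_position`, `site_residue`, `theoretical_mass`,
#'   `precursor_ppm`.
#' @export
enumerate_candidates <- function(spectrum, baits, index, linker,
                                 tol_ppm = 10) {
  neutral <- mz_to_neutral(spectrum$precursor_mz, spectrum$precursor_charge)
  lg <- linker$leaving_group_mass
  m <- index$peptides$mass
  bait_rows <- integer(0)
  hit_rows <- integer(0)
  for (bi in seq_len(nrow(baits))) {
    bmass <- baits$mass[bi]
    lo <- neutral / (1 + tol_ppm * 1e-6) - bmass + lg
    hi <- neutral / (1 - tol_ppm * 1e-6) - bmass + lg
    i <- findInterval(lo, m, left.open = TRUE) + 1L
    j <- findInterval(hi, m)
    if (i > j) next
    rows <- i:j
    theo <- bmass + m[rows] - lg
    keep <- abs(ppm_error(neutral, theo)) <= tol_ppm
    rows <- rows[keep]
    if (length(rows) == 0L) next
    bait_rows <- c(bait_rows, rep(bi, length(rows)))
    hit_rows <- c(hit_rows, rows)
  }
  if (length(hit_rows) == 0L) {
    return(empty_candidates())
  }
  h0 <- index$peptides[hit_rows, ]
  sites <- h0$reactive_sites
  nsite <- lengths(sites)
  if (sum(nsite) == 0L) {
    return(empty_candidates())
  }
  rep_i <- rep(seq_along(hit_rows), nsite)
  site_pos <- unlist(sites)
  h <- h0[rep_i, ]
  b <- baits[rep(bait_rows, nsite), ]
  theo <- b$mass + h$mass - lg
  tibble::tibble(
    bait_row = rep(bait_rows, nsite),
    bait_sequence = b$sequence,
    bait_ncaa_position = b$ncaa_position,
    bait_start = b$start,
    bait_mod_positions = b$mod_positions,
    bait_mod_masses = b$mod_masses,
    bait_mods = b$mods,
    bait_mass = b$mass,
    prey_sequence = h$sequence,
    prey_protein = h$protein_id,
    prey_start = h$start,
    prey_end = h$end,
    prey_mod_positions = h$mod_positions,
    prey_mod_masses = h$mod_masses,
    prey_mods = h$mods,
    prey_variant_id = h$variant_id,
    is_decoy = h$is_decoy,
    site_position = site_pos,
    site_residue = substring(h$sequence, site_pos, site_pos),
    theoretical_mass = theo,
    precursor_ppm = ppm_error(neutral, theo)
  )
}

empty_candidates <- function() {
  tibble::tibble(
    bait_row = integer(),
    bait_sequence = character(), bait_ncaa_position = integer(),
    bait_start = integer(), bait_mod_positions = list(),
    bait_mod_masses = list(), bait_mods = character(), bait_mass = numeric(),
    prey_sequence = character(), prey_protein = character(),
    prey_start = integer(), prey_end = integer(),
    prey_mod_positions = list(), prey_mod_masses = list(),
    prey_mods = character(), prey_variant_id = integer(),
    is_decoy = logical(), site_position = integer(),
    site_residue = character(), theoretical_mass = numeric(),
    precursor_ppm = numeric()
  )
}

#' Localize the cross-link site among scored site variants
#'
#' Given scored candidates sharing the same bait and prey peptide (site
#' variants of one pair), returns the best-scoring site, the score margin to
#' the best alternative site (`site_delta_score`), and the tied site set when
#' the margin is zero.
#'
#' @param scored Candidate tibble with `site_position` and `score` columns
#'   (one bait/prey pair).
#' @return List: `best` (row index into `scored`), `site_position`,
#'   `site_delta_score`, `ambiguous_sites` (integer vector, length > 1 only
#'   on ties).
#' @export
localize_site <- function(scored) {
  stopifnot(nrow(scored) >= 1L)
  ord <- order(-scored$score, scored$site_position)
  best <- ord[1L]
  delta <- if (nrow(scored) == 1L) {
    Inf
  } else {
    scored$score[best] - max(scored$score[ord[-1L]])
  }
  tied <- which(scored$score == scored$score[best])
  list(
    best = best,
    site_position = scored$site_position[best],
    site_delta_score = delta,
    ambiguous_sites = if (delta == 0) sort(scored$site_position[tied]) else
      scored$site_position[best]
  )
}

#' Search spectra for cross-linked peptide pairs
#'
#' The engine core: for each spectrum (and each assumed charge), candidates
#' are enumerated within the precursor tolerance, scored with the two-chain
#' binomial model, site-localized within each bait/prey pair, and reduced to
#' the rank-1 PSM per scan. A reportable PSM must have at least one matched
#' fragment on each chain. Ties are broken by lower absolute precursor ppm
#' error, then lexicographic peptide order.
#'
#' @param spectra Spectrum tibble from [read_mgf()]/[read_mzml()].
#' @param baits Bait peptide tibble from [bait_peptides()] (variants are
#'   prepared internally when no `mass` column is present).
#' @param index A [build_prey_index()] result.
#' @param linker A [crosslinker()].
#' @param precursor_tol_ppm,frag_tol_ppm Tolerances in ppm.
#' @param frag_charges Fragment charges considered.
#' @param mods,max_mods Variable modification settings for bait variants.
#' @param require_both_chains Drop PSMs lacking matched fragments on either
#'   chain (default `TRUE`).
#' @return PSM tibble, one row per scan with any reportable match: result
#'   columns (see [write_results()]) minus `qvalue`, plus `ambiguous_sites`.
#' @export
search_spectra <- function(spectra, baits, index, linker,
                           precursor_tol_ppm = 10, frag_tol_ppm = 20,
                           frag_charges = 1:2, mods = carbamidomethyl(),
                           max_mods = 3L, require_both_chains = TRUE) {
  if (!"mass" %in% names(baits)) {
    baits <- prepare_baits(baits, linker, mods = mods, max_mods = max_mods)
  }
  bait_res_list <- purrr::map(seq_len(nrow(baits)), function(bi) {
    chain_residue_masses(baits$sequence[bi], baits$ncaa_position[bi], linker,
                         baits$mod_positions[[bi]], baits$mod_masses[[bi]])
  })
  prey_res_cache <- new.env(parent = emptyenv())
  psms <- vector("list", nrow(spectra))
  for (si in seq_len(nrow(spectra))) {
    sp <- spectra[si, ]
    cands <- enumerate_candidates(sp, baits, index, linker,
                                  tol_ppm = precursor_tol_ppm)
    if (nrow(cands) == 0L) next
    peaks <- sp$peaks[[1L]]
    lg <- linker$leaving_group_mass
    pv_id <- cands$prey_variant_id
    nc <- nrow(cands)
    bait_row <- cands$bait_row
    ncaa_pos <- cands$bait_ncaa_position
    site_pos <- cands$site_position
    prey_seq <- cands$prey_sequence
    prey_modp <- cands$prey_mod_positions
    prey_modm <- cands$prey_mod_masses
    scores <- matrix(0, nrow = nc, ncol = 5L)
    # site variants of one (bait variant, prey variant) pair share their
    # fragment ladders; only the partner-mass placement moves with the site
    pair_key <- paste(bait_row, pv_id)
    pair_groups <- split(seq_len(nc), factor(pair_key, levels = unique(pair_key)))
    w <- water_mass()
    pm <- proton_mass()
    tot_int <- sum(peaks$intensity)
    p_rand <- random_match_prob(peaks$mz, frag_tol_ppm)
    chain_score <- function(k, N) {
      if (k == 0L || N == 0L || p_rand <= 0) return(0)
      -stats::pbinom(k - 1L, N, p_rand, lower.tail = FALSE, log.p = TRUE) /
        log(10)
    }
    for (g in pair_groups) {
      ci0 <- g[1L]
      key <- as.character(pv_id[ci0])
      pres <- prey_res_cache[[key]]
      if (is.null(pres)) {
        pres <- chain_residue_masses(prey_seq[ci0], NA_integer_, NULL,
                                     prey_modp[[ci0]], prey_modm[[ci0]])
        prey_res_cache[[key]] <- pres
      }
      bres <- bait_res_list[[bait_row[ci0]]]
      prey_mass <- sum(pres) + w
      bait_v <- chain_fragment_vectors(bres, ncaa_pos[ci0], prey_mass - lg,
                                       frag_charges)
      mb <- match_fragments(bait_v$mz, peaks$mz, frag_tol_ppm)
      kb <- sum(!is.na(mb))
      int_b <- sum(peaks$intensity[mb[!is.na(mb)]])
      sb <- chain_score(kb, length(bait_v$mz))
      fb <- if (tot_int > 0) int_b / tot_int else 0
      # peaks explained by the bait chain are not available to the prey
      # chain: unique matching holds across chains
      avail <- setdiff(seq_along(peaks$mz), mb[!is.na(mb)])
      avail_mz <- peaks$mz[avail]
      avail_int <- peaks$intensity[avail]
      # prey ladder base (no partner), per-site partner placement
      n <- length(pres)
      if (n < 2L) next
      k <- seq_len(n - 1L)
      cs <- cumsum(pres)
      base1 <- c(cs[k], cs[n] - cs[n - k] + w)
      nz <- length(frag_charges)
      basen <- rep(base1, times = nz)
      chg <- rep(as.integer(frag_charges), each = length(base1))
      partner <- sum(bres) + w - lg
      for (ci in g) {
        sp_i <- site_pos[ci]
        carries1 <- c(k >= sp_i, k >= (n - sp_i + 1L))
        neutral <- basen + rep(carries1, times = nz) * partner
        pmz <- (neutral + chg * pm) / chg
        mp <- match_fragments(pmz, avail_mz, frag_tol_ppm)
        kp <- sum(!is.na(mp))
        int_p <- sum(avail_int[mp[!is.na(mp)]])
        scores[ci, ] <- c(sb + chain_score(kp, length(pmz)), kb, kp, fb,
                          if (tot_int > 0) int_p / tot_int else 0)
      }
    }
    cands$score <- scores[, 1L]
    cands$matched_bait <- as.integer(scores[, 2L])
    cands$matched_prey <- as.integer(scores[, 3L])
    cands$frac_int_bait <- scores[, 4L]
    cands$frac_int_prey <- scores[, 5L]
    # site localization within each bait/prey pair
    grp <- paste(cands$bait_row, pv_id, sep = "\r")
    groups <- split(seq_len(nc), grp)
    best_idx <- integer(length(groups))
    deltas <- numeric(length(groups))
    ambs <- character(length(groups))
    for (gi in seq_along(groups)) {
      idx <- groups[[gi]]
      sc <- cands$score[idx]
      sp_g <- site_pos[idx]
      o <- order(-sc, sp_g)
      b1 <- o[1L]
      delta <- if (length(idx) == 1L) Inf else sc[b1] - max(sc[o[-1L]])
      best_idx[gi] <- idx[b1]
      deltas[gi] <- delta
      ambs[gi] <- if (delta == 0) {
        paste(sort(sp_g[sc == sc[b1]]), collapse = ";")
      } else {
        as.character(sp_g[b1])
      }
    }
    reps <- cands[best_idx, ]
    reps$site_delta_score <- deltas
    reps$ambiguous_sites <- ambs
    if (require_both_chains) {
      reps <- reps[reps$matched_bait >= 1L & reps$matched_prey >= 1L, ]
    }
    if (nrow(reps) == 0L) next
    ord <- order(-reps$score, abs(reps$precursor_ppm), reps$bait_sequence,
                 reps$prey_sequence, reps$site_position)
    top <- reps[ord[1L], ]
    top$scan_id <- sp$scan_id
    top$precursor_charge <- sp$precursor_charge
    psms[[si]] <- top
  }
  psms <- dplyr::bind_rows(psms)
  if (nrow(psms) == 0L) {
    return(psms)
  }
  # one PSM per scan across assumed charges
  psms <- psms |>
    dplyr::group_by(.data$scan_id) |>
    dplyr::arrange(dplyr::desc(.data$score), abs(.data$precursor_ppm),
                   .data$bait_sequence, .data$prey_sequence,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  psms$site_protein_pos <- psms$prey_start + psms$site_position - 1L
  psms$bait_ncaa_protein_pos <- psms$bait_start + psms$bait_ncaa_position - 1L
  psms$mods <- ifelse(
    nzchar(psms$bait_mods) & nzchar(psms$prey_mods),
    paste0("bait:", psms$bait_mods, "|prey:", psms$prey_mods),
    ifelse(nzchar(psms$bait_mods), paste0("bait:", psms$bait_mods),
           ifelse(nzchar(psms$prey_mods), paste0("prey:", psms$prey_mods), ""))
  )
  psms
}
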