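# Variable-modification expansion. For each peptide, emits one variant per
# subset (up to max_mods) of modifiable positions. Only positions whose
# residue is in the modification's target set are considered; `exclude`
# positions (e.g. the ncAA site) are never modified.
expand_mod_variants <- function(peptides, mod = carbamidomethyl(),
                                max_mods = 3L) {
  if (nrow(peptides) == 0L) {
    peptides$mod_positions <- list()
    peptides$mod_masses <- list()
    peptides$mods <- character()
    return(peptides)
  }
  delta <- mod$delta_mass[1L]
  targets <- mod$targets[[1L]]
  mname <- mod$name[1L]
  res_list <- strsplit(peptides$sequence, "", fixed = TRUE)
  subset_list <- purrr::map(seq_along(res_list), function(i) {
    sites <- which(res_list[[i]] %in% targets)
    np <- peptides$ncaa_position[i]
    if (!is.na(np)) sites <- setdiff(sites, np)
    subsets <- list(integer())
    if (length(sites) > 0L) {
      for (k in seq_len(min(max_mods, length(sites)))) {
        subsets <- c(subsets, utils::combn(sites, k, simplify = FALSE))
      }
    }
    subsets
  })
  nvar <- lengths(subset_list)
  out <- peptides[rep(seq_len(nrow(peptides)), nvar), ]
  subsets <- unlist(subset_list, recursive = FALSE)
  out$mod_positions <- lapply(subsets, as.integer)
  out$mod_masses <- lapply(subsets, function(s) rep(delta, length(s)))
  out$mods <- vapply(subsets, function(s) {
    if (length(s) == 0L) "" else paste(paste0(mname, "@", s), collapse = ";")
  }, character(1))
  out
}

peptide_variant_mass <- function(peptides, linker = NULL) {
  base <- pepmass_vec(peptides$sequence)
  np <- peptides$ncaa_position
  has_ncaa <- !is.na(np)
  if (any(has_ncaa)) {
    stopifnot(!is.null(linker))
    aa <- amino_acid_masses()
    orig <- substring(peptides$sequence[has_ncaa], np[has_ncaa], np[has_ncaa])
    base[has_ncaa] <- base[has_ncaa] - aa[orig] + linker$ncaa_residue_mass
  }
  base + vapply(peptides$mod_masses, sum, numeric(1))
}

#' Build the mass-sorted prey peptide index
#'
#' Digests the (target plus decoy) database, keeps peptides containing at
#' least one reactive residue, expands variable-modification variants, and
#' sorts by neutral mass for window lookup.
#'
#' @param proteins Protein tibble (targets and decoys, see [make_decoys()]).
#' @param rule A [protease_rule()].
#' @param linker A [crosslinker()]; its `reactive_residues` define the filter.
#' @param mods Variable modification (default [carbamidomethyl()]); `NULL`
#'   for none.
#' @param max_mods Maximum variable modifications per peptide.
#' @inheritParams digest
#' @return A `gecx_prey_index` with the variant tibble (`$peptides`, sorted
#'   by `mass`) and the linker.
#' @export
build_prey_index <- function(proteins, rule, linker, mods = carbamidomethyl(),
                             max_mods = 3L, min_length = 5L, max_length = 60L,
                             min_mass = 500, max_mass = 6000) {
  if (nrow(proteins) == 0L) stop("empty protein database", call. = FALSE)
  peps <- digest(proteins, rule, min_length = min_length,
                 max_length = max_length, min_mass = min_mass,
                 max_mass = max_mass)
  reactive <- linker$reactive_residues
  keep <- vapply(strsplit(peps$sequence, "", fixed = TRUE),
                 function(r) any(r %in% reactive), logical(1))
  peps <- peps[keep, ]
  if (!is.null(mods)) {
    peps <- expand_mod_variants(peps, mod = mods, max_mods = max_mods)
  } else {
    peps$mod_positions <- rep(list(integer()), nrow(peps))
    peps$mod_masses <- rep(list(numeric()), nrow(peps))
    peps$mods <- rep("", nrow(peps))
  }
  peps$mass <- peptide_variant_mass(peps)
  # reactive site positions per variant, modified positions excluded
  # (a modified side chain cannot simultaneously be the cross-link site)
  res_l <- strsplit(peps$sequence, "", fixed = TRUE)
  peps$reactive_sites <- purrr::map(seq_len(nrow(peps)), function(i) {
    setdiff(which(res_l[[i]] %in% reactive), peps$mod_positions[[i]])
  })
  peps <- peps[order(peps$mass, peps$sequence, peps$mods), ]
  peps$variant_id <- seq_len(nrow(peps))
  structure(list(peptides = peps, linker = linker, rule = rule),
            class = "gecx_prey_index")
}

#' @export
print.gecx_prey_index <- function(x, ...) {
  cat("<gecx_prey_index> ", nrow(x$peptides), " peptide variants (",
      sum(x$peptides$is_decoy), " decoy), mass ",
      round(min(x$peptides$mass), 1), "-", round(max(x$peptides$mass), 1),
      " Da\n", sep = "")
  invisible(x)
}

#' Look up index entries in a neutral-mass window
#'
#' @param index A [build_prey_index()] result.
#' @param lo,hi Window bounds in Da.
#' @return The peptide variant rows with `lo <= mass <= hi`.
#' @export
index_lookup <- function(index, lo, hi) {
  m <- index$peptides$mass
  i <- findInterval(lo, m, left.open = TRUE) + 1L
  j <- findInterval(hi, m)
  if (i > j) {
    return(index$peptides[0L, ])
  }
  index$peptides[i:j, ]
}

#' Prepare bait peptide variants for searching
#'
#' Expands variable modifications over bait peptides (the ncAA position is
#' never modified) and attaches the neutral mass including the ncAA residue.
#'
#' @param baits Bait peptide tibble from [bait_peptides()].
#' @param linker A [crosslinker()].
#' @inheritParams build_prey_index
#' @return Bait variant tibble with `mass` column.
#' @export
prepare_baits <- function(baits, linker, mods = carbamidomethyl(),
                          max_mods = 3L) {
  stopifnot(nrow(baits) > 0L, all(!is.na(baits$ncaa_position)))
  if (!is.null(mods)) {
    baits <- expand_mod_variants(baits, mod = mods, max_mods = max_mods)
  } else {
    baits$mod_positions <- rep(list(integer()), nrow(baits))
    baits$mod_masses <- rep(list(numeric()), nrow(baits))
    baits$mods <- rep("", nrow(baits))
  }
  baits$mass <- peptide_variant_mass(baits, linker = linker)
  baits
}
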