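#' Monoisotopic atomic masses
#'
#' Monoisotopic masses (Da) of the elements needed for peptide and
#' cross-linker chemistry, keyed by element symbol. Values are the masses of
#' the most abundant stable isotope (1H, 12C, 14N, 16O, 32S, 79Br, 31P).
#'
#' @return Named numeric vector of monoisotopic masses in Da.
#' @export
#' @examples
#' atomic_masses()[["O"]]
atomic_masses <- function() {
  c(
    H  = 1.00782503207,
    C  = 12.0,
    N  = 14.0030740048,
    O  = 15.9949146196,
    S  = 31.97207100,
    P  = 30.97376163,
    Br = 78.9183371
  )
}

# Residue (i.e. amino-acid-minus-water) elemental compositions for the
# 20 canonical residues. Residue masses are derived from these, never stored.
residue_formulas <- function() {
  c(
    G = "C2H3NO",   A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
    V = "C5H9NO",   T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
    I = "C6H11NO",  N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
    K = "C6H12N2O", E = "C5H7NO3",  M = "C5H9NOS",  H = "C6H7N3O",
    F = "C9H9NO",   R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
  )
}

#' Monoisotopic mass of an elemental formula
#'
#' Parses a Hill-style formula such as `"C2H3NO"` or `"H2O"` and returns the
#' sum of count times monoisotopic atomic mass. The empty formula has mass 0.
#'
#' @param formula Character scalar, e.g. `"C2H3NO"` (carbamidomethyl,
#'   57.02146 Da). Element symbols from [atomic_masses()]; counts default 1.
#' @return Monoisotopic mass in Da.
#' @export
#' @examples
#' formula_mass("C2H3NO") # carbamidomethyl, 57.02146
#' formula_mass("H2O")
formula_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  if (!nzchar(formula)) {
    return(0)
  }
  m <- stringr::str_match_all(formula, "([A-Z][a-z]?)(\\d*)")[[1]]
  m <- m[nzchar(m[, 1L]), , drop = FALSE]
  if (sum(nchar(m[, 1L])) != nchar(formula)) {
    stop("malformed formula: ", formula, call. = FALSE)
  }
  atoms <- atomic_masses()
  unknown <- setdiff(m[, 2L], names(atoms))
  if (length(unknown) > 0L) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  counts <- ifelse(nzchar(m[, 3L]), as.numeric(m[, 3L]), 1)
  sum(counts * atoms[m[, 2L]])
}

#' Monoisotopic residue masses of the 20 canonical amino acids
#'
#' Each residue mass is the sum of its elemental composition's atomic masses,
#' so the table is consistent with [formula_mass()] by construction.
#'
#' @return Named numeric vector (1-letter code to Da).
#' @export
#' @examples
#' amino_acid_masses()[["G"]] # 57.02146, same as carbamidomethyl
amino_acid_masses <- function() {
  cached <- get0("aa_masses", envir = .gecx_cache)
  if (is.null(cached)) {
    cached <- vapply(residue_formulas(), formula_mass, numeric(1))
    assign("aa_masses", cached, envir = .gecx_cache)
  }
  cached
}

.gecx_cache <- new.env(parent = emptyenv())

# Vectorized neutral peptide mass over canonical sequences (no mods/ncAA);
# the hot path behind digestion bounds and index construction.
pepmass_vec <- function(sequences) {
  aa <- amino_acid_masses()
  w <- water_mass()
  vapply(strsplit(sequences, "", fixed = TRUE),
         function(r) sum(aa[r]), numeric(1)) + w
}

#' @rdname physical_constants
#' @export
water_mass <- function() {
  cached <- get0("water", envir = .gecx_cache)
  if (is.null(cached)) {
    cached <- formula_mass("H2O")
    assign("water", cached, envir = .gecx_cache)
  }
  cached
}

#' Physical constants of the mass scale
#'
#' `water_mass()` is the monoisotopic mass of H2O added to every peptide
#' backbone; `proton_mass()` is the CODATA proton mass used in all m/z
#' conversions (it differs from the 1H atom mass by the electron mass).
#'
#' @name physical_constants
#' @return Mass in Da.
#' @export
proton_mass <- function() 1.00727646688

#' Define a modification
#'
#' @param name Modification name.
#' @param delta_mass Mass shift in Da, or `NULL` to derive it from `formula`.
#' @param formula Elemental composition of the added group (used when
#'   `delta_mass` is `NULL`).
#' @param targets Character vector of 1-letter residue codes the modification
#'   can occupy; must be non-empty.
#' @param variable Logical; `TRUE` for a variable modification.
#' @return A one-row tibble describing the modification.
#' @export
#' @examples
#' modification("carbamidomethyl", formula = "C2H3NO", targets = "C")
modification <- function(name, delta_mass = NULL, formula = NULL,
                         targets, variable = TRUE) {
  if (is.null(delta_mass)) {
    if (is.null(formula)) stop("give delta_mass or formula", call. = FALSE)
    delta_mass <- formula_mass(formula)
  }
  stopifnot(is.finite(delta_mass), length(targets) > 0L)
  tibble::tibble(
    name = name,
    delta_mass = delta_mass,
    targets = list(targets),
    variable = variable
  )
}

#' Carbamidomethylation of cysteine
#'
#' The +57.02146 Da iodoacetamide adduct on Cys, treated as a variable
#' modification during the search.
#'
#' @return A one-row modification tibble.
#' @export
carbamidomethyl <- function() {
  modification("carbamidomethyl", formula = "C2H3NO", targets = "C",
               variable = TRUE)
}

#' Define a proximity-reactive cross-linker
#'
#' Describes an electrophilic non-canonical amino acid (ncAA) carried by the
#' bait protein. On reaction with a nucleophilic side chain the leaving group
#' is expelled, so the conjugate mass is
#' `m(bait) + m(prey) - leaving_group_mass`. For alkyl-bromide chemistry the
#' leaving group is HBr.
#'
#' @param ncaa_residue_mass Monoisotopic residue mass (Da) of the intact ncAA
#'   as incorporated; required, there is no default because the value depends
#'   on the particular ncAA structure.
#' @param name Linker name.
#' @param leaving_group Elemental formula of the leaving group (default
#'   `"HBr"`).
#' @param leaving_group_mass Override mass in Da; derived from
#'   `leaving_group` when `NULL`.
#' @param reactive_residues Residues a cross-link site may occupy; defaults to
#'   the eight nucleophiles C, D, E, H, K, S, T, Y.
#' @return A `gecx_crosslinker` list.
#' @export
#' @examples
#' xl <- crosslinker(ncaa_residue_mass = 269.005128)
#' xl$leaving_group_mass # HBr, about 79.92616
crosslinker <- function(ncaa_residue_mass,
                        name = "alkyl-bromide-ncAA",
                        leaving_group = "HBr",
                        leaving_group_mass = NULL,
                        reactive_residues = c("C", "D", "E", "H", "K", "S", "T", "Y")) {
  stopifnot(is.numeric(ncaa_residue_mass), ncaa_residue_mass > 0)
  if (is.null(leaving_group_mass)) {
    leaving_group_mass <- formula_mass(leaving_group)
  }
  stopifnot(leaving_group_mass >= 0, length(reactive_residues) > 0L)
  structure(
    list(
      name = name,
      ncaa_residue_mass = ncaa_residue_mass,
      leaving_group_mass = leaving_group_mass,
      reactive_residues = reactive_residues
    ),
    class = "gecx_crosslinker"
  )
}

#' @export
print.gecx_crosslinker <- function(x, ...) {
  cat("<gecx_crosslinker> ", x$name, "\n",
      "  ncAA residue mass: ", format(x$ncaa_residue_mass), " Da\n",
      "  leaving group:     ", format(x$leaving_group_mass), " Da\n",
      "  reactive residues: ", paste(x$reactive_residues, collapse = ""), "\n",
      sep = "")
  invisible(x)
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus one water, plus any modification deltas. When
#' `ncaa_position` is given, that position contributes the ncAA residue mass
#' from `linker` instead of the canonical residue mass.
#'
#' @param sequence Peptide sequence (1-letter codes).
#' @param mod_positions Integer vector of modified positions (1-based).
#' @param mod_deltas Numeric vector of modification mass shifts, parallel to
#'   `mod_positions`.
#' @param mod_targets Optional list of allowed residue sets, parallel to
#'   `mod_positions`; when given, a modification landing on an incompatible
#'   residue is an error.
#' @param ncaa_position Optional 1-based index of the ncAA within the peptide.
#' @param linker A [crosslinker()]; required when `ncaa_position` is set.
#' @return Neutral mass in Da.
#' @export
#' @examples
#' peptide_mass("ACK")
#' peptide_mass("ACK", mod_positions = 2, mod_deltas = 57.02146)
peptide_mass <- function(sequence, mod_positions = integer(),
                         mod_deltas = numeric(), mod_targets = NULL,
                         ncaa_position = NULL, linker = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  aa <- amino_acid_masses()
  bad <- setdiff(res, names(aa))
  if (length(bad) > 0L) {
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  masses <- aa[res]
  if (!is.null(ncaa_position)) {
    stopifnot(!is.null(linker),
              ncaa_position >= 1L, ncaa_position <= length(res))
    masses[ncaa_position] <- linker$ncaa_residue_mass
  }
  if (length(mod_positions) > 0L) {
    stopifnot(length(mod_deltas) == length(mod_positions),
              all(mod_positions >= 1L), all(mod_positions <= length(res)))
    if (!is.null(mod_targets)) {
      ok <- mapply(function(p, tg) res[p] %in% tg, mod_positions, mod_targets)
      if (!all(ok)) {
        stop("modification on incompatible residue at position(s) ",
             paste(mod_positions[!ok], collapse = ", "), call. = FALSE)
      }
    }
  }
  sum(masses) + water_mass() + sum(mod_deltas)
}

#' Neutral mass of a cross-linked peptide pair
#'
#' The covalent conjugate of an ncAA-bearing bait peptide and a nucleophilic
#' prey peptide: `m(bait) + m(prey) - leaving_group_mass`. Symmetric in the
#' two chain masses.
#'
#' @param bait_mass,prey_mass Neutral peptide masses in Da (the bait mass must
#'   already include the ncAA residue).
#' @param linker A [crosslinker()].
#' @return Neutral conjugate mass in Da.
#' @export
crosslink_mass <- function(bait_mass, prey_mass, linker) {
  stopifnot(bait_mass > 0, prey_mass > 0)
  bait_mass + prey_mass - linker$leaving_group_mass
}

#' m/z and ppm conversions
#'
#' `mz_to_neutral()` and `neutral_to_mz()` convert between measured m/z at
#' charge z and neutral mass using the proton mass; `ppm_error()` is the
#' relative mass error in parts per million of the theoretical mass.
#'
#' @param mz Measured m/z.
#' @param z Positive integer charge.
#' @param neutral Neutral mass in Da.
#' @param observed,theoretical Masses in Da (or m/z on a common scale).
#' @return Numeric vector.
#' @name mz_conversions
#' @export
#' @examples
#' mz_to_neutral(500, 2) # 997.985447
#' ppm_error(500.005, 500) # +10 ppm
mz_to_neutral <- function(mz, z) {
  stopifnot(all(z >= 1L))
  z * mz - z * proton_mass()
}

#' @rdname mz_conversions
#' @export
neutral_to_mz <- function(neutral, z) {
  stopifnot(all(z >= 1L))
  (neutral + z * proton_mass()) / z
}

#' @rdname mz_conversions
#' @export
ppm_error <- function(observed, theoretical) {
  1e6 * (observed - theoretical) / theoretical
}
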