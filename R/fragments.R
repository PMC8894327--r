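# Per-position residue masses of one chain, with the ncAA substitution and
# any modification deltas applied in place.
chain_residue_masses <- function(sequence, ncaa_position = NA_integer_,
                                 linker = NULL, mod_positions = integer(),
                                 mod_masses = numeric()) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  m <- amino_acid_masses()[res]
  if (!is.na(ncaa_position) && !is.null(linker)) {
    m[ncaa_position] <- linker$ncaa_residue_mass
  }
  if (length(mod_positions) > 0L) {
    m[mod_positions] <- m[mod_positions] + mod_masses
  }
  unname(m)
}

# b/y fragment vectors of one chain (no tibble overhead; the search hot path).
# Returns parallel vectors; ordinals 1..n-1 for each series and charge.
chain_fragment_vectors <- function(resmass, site_pos, partner_add,
                                   frag_charges) {
  n <- length(resmass)
  if (n < 2L) {
    return(list(series = character(), ordinal = integer(),
                charge = integer(), carries = logical(),
                neutral = numeric(), mz = numeric()))
  }
  k <- seq_len(n - 1L)
  cs <- cumsum(resmass)
  b_neutral <- cs[k]
  y_neutral <- cs[n] - cs[n - k] + water_mass() # suffix sums of length k
  b_carries <- k >= site_pos
  y_carries <- k >= (n - site_pos + 1L)
  neutral1 <- c(b_neutral + b_carries * partner_add,
                y_neutral + y_carries * partner_add)
  nz <- length(frag_charges)
  m <- length(neutral1)
  neutral <- rep(neutral1, times = nz)
  charge <- rep(as.integer(frag_charges), each = m)
  list(
    series = rep(rep(c("b", "y"), each = n - 1L), times = nz),
    ordinal = rep(c(k, k), times = nz),
    charge = charge,
    carries = rep(c(b_carries, y_carries), times = nz),
    neutral = neutral,
    mz = (neutral + charge * proton_mass()) / charge
  )
}

# Fragment m/z vectors for a cross-linked candidate, split by chain.
xl_fragment_vectors <- function(bait_res, ncaa_pos, prey_res, site_pos,
                                leaving_group_mass, frag_charges) {
  w <- water_mass()
  bait_mass <- sum(bait_res) + w
  prey_mass <- sum(prey_res) + w
  b <- chain_fragment_vectors(bait_res, ncaa_pos,
                              prey_mass - leaving_group_mass, frag_charges)
  p <- chain_fragment_vectors(prey_res, site_pos,
                              bait_mass - leaving_group_mass, frag_charges)
  list(bait = b, prey = p)
}

#' Theoretical fragment ions of a cross-linked candidate
#'
#' b/y ions of both chains at the given fragment charges. A fragment whose
#' residue span covers its chain's cross-link position (the ncAA on the bait,
#' the reactive site on the prey) carries the partner chain's full mass minus
#' the leaving group; the complementary fragment of the same bond does not,
#' so `neutral(b_k) + neutral(y_(n-k))` always equals the chain-conjugate
#' total mass.
#'
#' @param candidate One-row candidate tibble or list with fields
#'   `bait_sequence`, `bait_ncaa_position`, `bait_mod_positions`,
#'   `bait_mod_masses`, `prey_sequence`, `site_position`,
#'   `prey_mod_positions`, `prey_mod_masses` (mod fields may be absent).
#' @param linker A [crosslinker()].
#' @param frag_charges Fragment charges (default 1:2).
#' @return Tibble of fragments: `chain`, `series`, `ordinal`, `charge`,
#'   `carries_partner`, `neutral`, `mz`.
#' @export
theoretical_fragments <- function(candidate, linker, frag_charges = 1:2) {
  cand <- as.list(candidate)
  unwrap <- function(x, default) {
    if (is.null(x)) return(default)
    if (is.list(x)) x <- x[[1L]]
    x
  }
  bait_res <- chain_residue_masses(
    unwrap(cand$bait_sequence, NULL), unwrap(cand$bait_ncaa_position, NULL),
    linker, unwrap(cand$bait_mod_positions, integer()),
    unwrap(cand$bait_mod_masses, numeric())
  )
  prey_res <- chain_residue_masses(
    unwrap(cand$prey_sequence, NULL), NA_integer_, NULL,
    unwrap(cand$prey_mod_positions, integer()),
    unwrap(cand$prey_mod_masses, numeric())
  )
  v <- xl_fragment_vectors(bait_res, unwrap(cand$bait_ncaa_position, NULL),
                           prey_res, unwrap(cand$site_position, NULL),
                           linker$leaving_group_mass, frag_charges)
  nb <- length(v$bait$mz)
  np <- length(v$prey$mz)
  tibble::tibble(
    chain = c(rep("bait", nb), rep("prey", np)),
    series = c(v$bait$series, v$prey$series),
    ordinal = c(v$bait$ordinal, v$prey$ordinal),
    charge = c(v$bait$charge, v$prey$charge),
    carries_partner = c(v$bait$carries, v$prey$carries),
    neutral = c(v$bait$neutral, v$prey$neutral),
    mz = c(v$bait$mz, v$prey$mz)
  )
}
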