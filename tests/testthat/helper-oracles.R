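# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: masses come from a frozen literature table,
# digestion from exhaustive substring enumeration.

# Residue masses rounded to tabulated precision, frozen from standard
# reference tables (used for per-residue spot checks).
oracle_residue_5dp <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
oracle_water <- 18.0105646863

# Atom-by-atom brute-force peptide mass: per-residue atom counts summed one
# atom at a time from IUPAC monoisotopic atomic masses.
oracle_atoms <- c(H = 1.00782503207, C = 12.0, N = 14.0030740048,
                  O = 15.9949146196, S = 31.97207100)
# residue compositions as C,H,N,O,S counts
oracle_comp <- list(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0)
)

oracle_residue_masses <- vapply(oracle_comp, function(cnt) {
  total <- 0
  for (el in seq_along(cnt)) {
    for (a in seq_len(cnt[el])) {
      total <- total + oracle_atoms[c("C", "H", "N", "O", "S")[el]]
    }
  }
  total
}, numeric(1))

oracle_peptide_mass <- function(sequence) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  total <- oracle_water
  for (r in res) total <- total + oracle_residue_masses[[r]]
  total
}

# Exhaustive digestion oracle: every substring passing the cleavage
# predicate, with its missed-cleavage count.
oracle_digest <- function(sequence, cleave_after, suppressed_before,
                          max_missed) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  cut_after <- function(i) {
    i >= 1 && i < n && res[i] %in% cleave_after &&
      !(res[i + 1] %in% suppressed_before)
  }
  out <- list()
  for (a in seq_len(n)) {
    for (b in a:n) {
      ok_start <- a == 1 || cut_after(a - 1)
      ok_end <- b == n || cut_after(b)
      if (!ok_start || !ok_end) next
      internal <- if (b > a) sum(vapply(a:(b - 1), cut_after, logical(1))) else 0
      if (internal <= max_missed) {
        out[[length(out) + 1]] <- data.frame(
          sequence = paste(res[a:b], collapse = ""),
          start = a, end = b, missed_cleavages = internal
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(sequence = character(), start = integer(),
                      end = integer(), missed_cleavages = integer()))
  }
  do.call(rbind, out)
}

random_protein <- function(n, letters = names(oracle_residue_masses)) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

digest_key <- function(df) {
  sort(paste(df$sequence, df$start, df$end, df$missed_cleavages))
}
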