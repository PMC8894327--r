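xl_test <- crosslinker(ncaa_residue_mass = 269.005128)

tiny_index <- function(seqs, ids = sprintf("P%d", seq_along(seqs)),
                       rule = protease_rule("trypsin", max_missed = 1L),
                       mods = NULL) {
  build_prey_index(tibble::tibble(id = ids, sequence = seqs), rule, xl_test,
                   mods = mods, min_length = 1L, min_mass = 0, max_mass = Inf)
}

spectrum_for <- function(cand, charge = 3L, linker = xl_test) {
  frags <- theoretical_fragments(cand, linker)
  peaks <- tibble::tibble(mz = sort(frags$mz),
                          intensity = rep(100, nrow(frags)))
  m <- crosslink_mass(
    peptide_mass(cand$bait_sequence, ncaa_position = cand$bait_ncaa_position,
                 linker = linker),
    peptide_mass(cand$prey_sequence), linker
  )
  tibble::tibble(scan_id = "t1", precursor_mz = neutral_to_mz(m, charge),
                 precursor_charge = charge, retention_time = NA_real_,
                 peaks = list(peaks))
}

cand_list <- function(bait = "GGYGGK", ncaa = 3L, prey = "ACDK", site = 2L) {
  list(bait_sequence = bait, bait_ncaa_position = ncaa,
       prey_sequence = prey, site_position = site)
}

test_that("prey index keeps only reactive peptides, sorted by mass", {
  idx <- tiny_index(c("GGGGK", "GGGGGGFFFF"))
  # K is itself a nucleophile, so the first peptide is indexed
  expect_true("GGGGK" %in% idx$peptides$sequence)
  # a peptide with no reactive residue is excluded
  expect_false("GGGGGGFFFF" %in% idx$peptides$sequence)
  expect_false(is.unsorted(idx$peptides$mass))
})

test_that("index window lookup equals a linear scan oracle", {
  set.seed(31)
  seqs <- replicate(40, random_protein(sample(10:40, 1)))
  idx <- tiny_index(seqs)
  for (i in 1:50) {
    m <- runif(1, min(idx$peptides$mass), max(idx$peptides$mass))
    eps <- runif(1, 0.001, 5)
    got <- index_lookup(idx, m - eps, m + eps)$variant_id
    want <- idx$peptides$variant_id[idx$peptides$mass >= m - eps &
                                      idx$peptides$mass <= m + eps]
    expect_identical(sort(got), sort(want))
  }
})

test_that("candidate enumeration respects the precursor tolerance window", {
  idx <- tiny_index("AAAACDKAAR", rule = protease_rule("trypsin"))
  baits <- prepare_baits(
    tibble::tibble(sequence = "GGYGGK", protein_id = "bait", start = 1L,
                   end = 6L, missed_cleavages = 0L, ncaa_position = 3L,
                   is_decoy = FALSE),
    xl_test, mods = NULL
  )
  m <- crosslink_mass(baits$mass, peptide_mass("AAAACDK"), xl_test)
  sp <- tibble::tibble(scan_id = "s", precursor_mz = neutral_to_mz(m, 3L),
                       precursor_charge = 3L, retention_time = NA_real_,
                       peaks = list(tibble::tibble(mz = 500, intensity = 1)))
  cands <- enumerate_candidates(sp, baits, idx, xl_test, tol_ppm = 10)
  # prey AAAACDK carries three reactive residues: C, D and the terminal K
  expect_equal(sort(unique(cands$site_residue)), c("C", "D", "K"))
  expect_equal(nrow(cands), 3L)

  sp25 <- sp
  sp25$precursor_mz <- neutral_to_mz(m * (1 + 25e-6), 3L)
  expect_equal(nrow(enumerate_candidates(sp25, baits, idx, xl_test, 10)), 0L)
})

test_that("index enumeration equals a brute-force all-pairs scan", {
  set.seed(32)
  seqs <- replicate(30, random_protein(sample(10:50, 1)))
  idx <- tiny_index(seqs, mods = carbamidomethyl())
  expect_lte(nrow(idx$peptides), 600)
  baits <- prepare_baits(
    tibble::tibble(sequence = c("GGYGGK", "AAYCGK"), protein_id = "bait",
                   start = 1L, end = 6L, missed_cleavages = 0L,
                   ncaa_position = 3L, is_decoy = FALSE),
    xl_test
  )
  for (i in 1:25) {
    target <- sample(idx$peptides$mass, 1) + baits$mass[sample.int(nrow(baits), 1)] -
      xl_test$leaving_group_mass + runif(1, -0.02, 0.02)
    sp <- tibble::tibble(scan_id = "s", precursor_mz = neutral_to_mz(target, 3L),
                         precursor_charge = 3L, retention_time = NA_real_,
                         peaks = list(tibble::tibble(mz = 500, intensity = 1)))
    got <- enumerate_candidates(sp, baits, idx, xl_test, tol_ppm = 10)
    # oracle: scan all (bait variant, prey variant, site) triples
    want <- 0L
    for (bi in seq_len(nrow(baits))) {
      theo <- baits$mass[bi] + idx$peptides$mass - xl_test$leaving_group_mass
      hit <- abs(ppm_error(target, theo)) <= 10
      want <- want + sum(lengths(idx$peptides$reactive_sites[hit]))
    }
    expect_equal(nrow(got), want)
  }
})

test_that("fragment bookkeeping conserves the conjugate mass", {
  set.seed(33)
  for (i in 1:20) {
    prey <- random_protein(sample(4:15, 1))
    sites <- which(strsplit(prey, "")[[1]] %in% c("C", "D", "E", "H", "K", "S", "T", "Y"))
    if (length(sites) == 0) next
    cand <- cand_list(prey = prey, site = sites[1])
    frags <- theoretical_fragments(cand, xl_test)
    M <- crosslink_mass(
      peptide_mass(cand$bait_sequence, ncaa_position = cand$bait_ncaa_position,
                   linker = xl_test),
      peptide_mass(prey), xl_test
    )
    for (chain in c("bait", "prey")) {
      f1 <- frags[frags$chain == chain & frags$charge == 1, ]
      n <- nchar(if (chain == "bait") cand$bait_sequence else prey)
      for (k in seq_len(n - 1)) {
        b <- f1$neutral[f1$series == "b" & f1$ordinal == k]
        y <- f1$neutral[f1$series == "y" & f1$ordinal == n - k]
        expect_lt(abs(b + y - M), 1e-6)
      }
    }
  }
})

test_that("fragment counts and partner placement follow the two-chain model", {
  cand <- cand_list(bait = "GGYGGK", ncaa = 3L, prey = "ACDK", site = 2L)
  frags <- theoretical_fragments(cand, xl_test)
  # (n-1) b and (n-1) y ordinals per chain per charge
  expect_equal(sum(frags$chain == "bait"), 2L * 5L * 2L)
  expect_equal(sum(frags$chain == "prey"), 2L * 3L * 2L)
  # prey y1 (K) does not cover site 2: plain mass
  y1 <- frags[frags$chain == "prey" & frags$series == "y" &
                frags$ordinal == 1 & frags$charge == 1, ]
  expect_false(y1$carries_partner)
  expect_equal(y1$neutral, peptide_mass("K"))
  # prey b2 covers the site: plain b2 plus bait mass minus leaving group
  b2 <- frags[frags$chain == "prey" & frags$series == "b" &
                frags$ordinal == 2 & frags$charge == 1, ]
  bait_mass <- peptide_mass("GGYGGK", ncaa_position = 3, linker = xl_test)
  expect_true(b2$carries_partner)
  expect_equal(b2$neutral,
               peptide_mass("AC") - water_mass() + bait_mass -
                 xl_test$leaving_group_mass)
})

test_that("self-match dominates: the true candidate outscores alternatives", {
  set.seed(34)
  cand <- cand_list(prey = "ACDEFGHK", site = 2L)
  sp <- spectrum_for(cand)
  self <- score_candidate(sp, cand, xl_test)
  expect_equal(self$matched_bait, 20L) # all 2*(6-1)*2 bait ions
  scores <- replicate(100, {
    rnd <- cand_list(prey = random_protein(8), site = 1L)
    score_candidate(sp, rnd, xl_test)$score
  })
  expect_lt(mean(scores), self$score)
  expect_true(all(scores <= self$score))

  # empty peak list scores zero with no matches
  sp0 <- sp
  sp0$peaks <- list(tibble::tibble(mz = numeric(), intensity = numeric()))
  z <- score_candidate(sp0, cand, xl_test)
  expect_equal(z$score, 0)
  expect_equal(z$matched_bait + z$matched_prey, 0L)
})

test_that("matched counts are monotone in tolerance and added peaks", {
  set.seed(35)
  cand <- cand_list(prey = "ACDEFGHK", site = 2L)
  sp <- spectrum_for(cand)
  # jitter peaks by 8 ppm so tolerance matters
  pk <- sp$peaks[[1]]
  pk$mz <- pk$mz * (1 + runif(nrow(pk), -8e-6, 8e-6))
  sp$peaks <- list(pk[order(pk$mz), ])
  counts <- vapply(c(2, 5, 10, 20, 50), function(tol) {
    s <- score_candidate(sp, cand, xl_test, frag_tol_ppm = tol)
    s$matched_bait + s$matched_prey
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))

  with_noise <- sp
  pk2 <- rbind(pk, tibble::tibble(mz = runif(50, 100, 2000),
                                  intensity = runif(50, 1, 10)))
  with_noise$peaks <- list(pk2[order(pk2$mz), ])
  n0 <- score_candidate(sp, cand, xl_test)
  n1 <- score_candidate(with_noise, cand, xl_test)
  expect_gte(n1$matched_bait + n1$matched_prey, n0$matched_bait + n0$matched_prey)
})

test_that("site localization identifies the true site and reports ties", {
  # full noiseless coverage: implanted site C wins with positive margin
  idx <- tiny_index("AAAAGCDEKAAR", rule = protease_rule("trypsin"))
  baits <- prepare_baits(
    tibble::tibble(sequence = "GGYGGK", protein_id = "bait", start = 1L,
                   end = 6L, missed_cleavages = 0L, ncaa_position = 3L,
                   is_decoy = FALSE),
    xl_test, mods = NULL
  )
  cand <- cand_list(prey = "AAAAGCDEK", site = 6L)
  sp <- spectrum_for(cand)
  psm <- search_spectra(sp, baits, idx, xl_test, mods = NULL)
  expect_equal(nrow(psm), 1L)
  expect_equal(psm$site_residue, "C")
  expect_gt(psm$site_delta_score, 0)

  # scored variants via the exported localizer
  scored <- tibble::tibble(site_position = c(2L, 6L, 7L),
                           score = c(1.5, 9.0, 4.0))
  loc <- localize_site(scored)
  expect_equal(loc$site_position, 6L)
  expect_equal(loc$site_delta_score, 5.0)

  # exact tie: ambiguous set reported with zero margin
  tie <- tibble::tibble(site_position = c(3L, 7L), score = c(2.0, 2.0))
  loc2 <- localize_site(tie)
  expect_equal(loc2$site_delta_score, 0)
  expect_equal(loc2$ambiguous_sites, c(3L, 7L))
})
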