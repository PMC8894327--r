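small_cfg <- function(...) {
  args <- utils::modifyList(
    list(seed = 7, n_proteins = 15L, n_true_links = 8L,
         protein_length_range = c(80L, 150L)),
    list(...)
  )
  do.call(sim_config, args)
}

test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- small_cfg()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_run(cfg, d1)
  simulate_run(cfg, d2)
  for (fn in c("db.fasta", "bait.fasta", "run.mgf", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, fn)),
                     readLines(file.path(d2, fn)),
                     label = fn)
  }
})

test_that("proteome generation honors size, entrapment and composition", {
  cfg <- small_cfg()
  sim <- simulate_proteome(cfg)
  expect_equal(nrow(sim$proteome), 15L)
  expect_gt(sim$ncaa_site, 1L)
  expect_lt(sim$ncaa_site, nchar(sim$bait$sequence))

  # n_proteins = 0 leaves only the bait
  sim0 <- simulate_proteome(small_cfg(n_proteins = 0L))
  expect_equal(nrow(sim0$proteome), 0L)
  expect_equal(nrow(sim0$bait), 1L)

  half <- simulate_proteome(small_cfg(entrapment_fraction = 0.5))
  expect_equal(sum(half$proteome$is_entrapment), 7L) # floor(0.5 * 15)

  # residue composition follows the stated uniform model (chi-squared)
  big <- simulate_proteome(sim_config(seed = 9, n_proteins = 300L,
                                      protein_length_range = c(330L, 340L)))
  res <- table(strsplit(paste(big$proteome$sequence, collapse = ""), "")[[1]])
  expect_gt(stats::chisq.test(res)$p.value, 0.01)
})

test_that("implantation follows the reactivity prior", {
  # degenerate weights: every site is a Cys
  wC <- c(C = 1, D = 0, E = 0, H = 0, K = 0, S = 0, T = 0, Y = 0)
  cfg <- small_cfg(reactivity_weights = wC, n_true_links = 12L)
  sim <- simulate_proteome(cfg)
  truth <- implant_crosslinks(sim, cfg)
  expect_true(all(truth$site_residue == "C"))
  # the implanted (peptide, site) pairs are distinct
  expect_equal(anyDuplicated(paste(truth$prey_sequence, truth$site_position)), 0L)
  # implanted site coordinates are consistent
  expect_equal(substring(truth$prey_sequence, truth$site_position,
                         truth$site_position), truth$site_residue)

  # uniform weights: empirical distribution consistent with multinomial
  wU <- stats::setNames(rep(1 / 8, 8), c("C", "D", "E", "H", "K", "S", "T", "Y"))
  cfgU <- sim_config(seed = 13, n_proteins = 80L, n_true_links = 400L,
                     reactivity_weights = wU)
  simU <- simulate_proteome(cfgU)
  truthU <- implant_crosslinks(simU, cfgU)
  tab <- table(factor(truthU$site_residue, levels = names(wU)))
  expect_gt(stats::chisq.test(tab, p = wU)$p.value, 0.01)

  # asking for more links than distinct pairs fails loudly
  tiny <- small_cfg(n_proteins = 1L, n_true_links = 5000L)
  simT <- simulate_proteome(tiny)
  expect_error(implant_crosslinks(simT, tiny), "available")
})

test_that("noiseless rendering reproduces theoretical fragment m/z exactly", {
  cfg <- noiseless(small_cfg())
  out <- simulate_run(cfg)
  linker <- crosslinker(cfg$ncaa_mass)
  for (i in seq_len(nrow(out$truth))) {
    tr <- out$truth[i, ]
    sp <- out$spectra[out$spectra$scan_id == tr$scan_id, ]
    frags <- theoretical_fragments(
      list(bait_sequence = tr$bait_sequence,
           bait_ncaa_position = tr$bait_ncaa_position,
           prey_sequence = tr$prey_sequence,
           site_position = tr$site_position),
      linker
    )
    # every rendered peak sits exactly on a theoretical m/z (to print precision)
    d <- vapply(sp$peaks[[1]]$mz,
                function(x) min(abs(x - frags$mz)), numeric(1))
    expect_lt(max(d), 1e-5)
    # precursor placed at the true conjugate mass
    m <- crosslink_mass(
      peptide_mass(tr$bait_sequence, ncaa_position = tr$bait_ncaa_position,
                   linker = linker),
      peptide_mass(tr$prey_sequence), linker
    )
    expect_lt(abs(mz_to_neutral(sp$precursor_mz, sp$precursor_charge) - m) / m,
              1e-6)
  }
})

test_that("background fraction one yields only background spectra", {
  cfg <- small_cfg(background_spectra_fraction = 1)
  out <- simulate_run(cfg)
  expect_true(all(out$truth$is_background))
  expect_gt(nrow(out$spectra), 0L)
})

test_that("precursor charges come from the configured 3-7 range", {
  out <- simulate_run(small_cfg(n_true_links = 20L))
  expect_true(all(out$spectra$precursor_charge %in% 3:7))
})
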