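#' Simulation configuration
#'
#' Study-shaped defaults: a Cys-dominant reactivity prior (C = 0.7, the
#' remaining seven nucleophiles uniform), precursor charges 3-7 weighted
#' toward lower states, ppm-scale mass errors well inside the 10/20 ppm
#' search tolerances, incomplete fragment coverage, and a background of
#' unexplained linear-peptide spectra.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_proteins Prey proteins in the database.
#' @param protein_length_range Uniform range of protein lengths.
#' @param n_true_links Implanted cross-links (one spectrum each).
#' @param reactivity_weights Named probabilities over the nucleophile set;
#'   must sum to 1.
#' @param residue_freqs Named residue frequencies for random proteins
#'   (default uniform over the 20 canonical residues).
#' @param fragment_dropout_prob Probability an individual theoretical ion is
#'   absent from the rendered spectrum.
#' @param mz_noise_ppm_sd Gaussian fragment m/z error (ppm).
#' @param precursor_ppm_sd Gaussian precursor m/z error (ppm).
#' @param n_noise_peaks_lambda Poisson mean of uniform noise peaks added per
#'   spectrum.
#' @param background_spectra_fraction Fraction of emitted spectra that are
#'   background (random linear peptides, no implanted link).
#' @param charge_range,charge_weights Precursor charge states and sampling
#'   weights.
#' @param entrapment_fraction Fraction of prey proteins replaced by shuffled
#'   (entrapment) sequences that never receive implanted links.
#' @param ncaa_mass Residue mass of the incorporated ncAA (Da). Default
#'   269.005128 Da, the monoisotopic residue mass of composition C11H12BrNO2
#'   (an O-(2-bromoethyl)-tyrosine-type alkyl-bromide residue).
#' @param bait_length Bait construct length.
#' @return A `gecx_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_proteins = 200L,
                       protein_length_range = c(150L, 450L),
                       n_true_links = 150L,
                       reactivity_weights = c(C = 0.7, D = 0.3 / 7,
                                              E = 0.3 / 7, H = 0.3 / 7,
                                              K = 0.3 / 7, S = 0.3 / 7,
                                              T = 0.3 / 7, Y = 0.3 / 7),
                       residue_freqs = NULL,
                       fragment_dropout_prob = 0.1,
                       mz_noise_ppm_sd = 4,
                       precursor_ppm_sd = 2,
                       n_noise_peaks_lambda = 30,
                       background_spectra_fraction = 0.4,
                       charge_range = 3:7,
                       charge_weights = c(0.35, 0.3, 0.2, 0.1, 0.05),
                       entrapment_fraction = 0,
                       ncaa_mass = 269.005128,
                       bait_length = 120L) {
  if (is.null(residue_freqs)) {
    aas <- names(residue_formulas())
    residue_freqs <- stats::setNames(rep(1 / length(aas), length(aas)), aas)
  }
  stopifnot(
    abs(sum(reactivity_weights) - 1) < 1e-8,
    all(names(reactivity_weights) %in% nucleophile_set()),
    fragment_dropout_prob >= 0, fragment_dropout_prob <= 1,
    background_spectra_fraction >= 0, background_spectra_fraction <= 1,
    entrapment_fraction >= 0, entrapment_fraction <= 1,
    length(charge_weights) == length(charge_range)
  )
  structure(
    list(seed = as.integer(seed) %% .Machine$integer.max,
         n_proteins = n_proteins,
         protein_length_range = protein_length_range,
         n_true_links = n_true_links,
         reactivity_weights = reactivity_weights,
         residue_freqs = residue_freqs,
         fragment_dropout_prob = fragment_dropout_prob,
         mz_noise_ppm_sd = mz_noise_ppm_sd,
         precursor_ppm_sd = precursor_ppm_sd,
         n_noise_peaks_lambda = n_noise_peaks_lambda,
         background_spectra_fraction = background_spectra_fraction,
         charge_range = charge_range,
         charge_weights = charge_weights,
         entrapment_fraction = entrapment_fraction,
         ncaa_mass = ncaa_mass,
         bait_length = bait_length),
    class = "gecx_sim_config"
  )
}

#' Noise-free variant of a simulation configuration
#'
#' @param config A [sim_config()].
#' @return The configuration with all noise sources (dropout, m/z error,
#'   noise peaks, background spectra) set to zero.
#' @export
noiseless <- function(config) {
  config$fragment_dropout_prob <- 0
  config$mz_noise_ppm_sd <- 0
  config$precursor_ppm_sd <- 0
  config$n_noise_peaks_lambda <- 0
  config$background_spectra_fraction <- 0
  config
}

random_sequence <- function(n, freqs) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

#' Simulate a prey proteome and bait construct
#'
#' Emits `n_proteins` random proteins from the configured residue
#' composition model (an `entrapment_fraction` of them flagged as shuffled
#' entrapment sequences) and one bait protein whose ncAA site falls inside a
#' fully-tryptic peptide of searchable length.
#'
#' @param config A [sim_config()].
#' @return List: `proteome` tibble (`id`, `description`, `sequence`,
#'   `is_decoy`, `is_entrapment`), `bait` tibble, `ncaa_site`.
#' @export
simulate_proteome <- function(config) {
  set.seed(config$seed)
  n <- config$n_proteins
  lens <- if (n > 0L) {
    sample(config$protein_length_range[1L]:config$protein_length_range[2L],
           n, replace = TRUE)
  } else integer()
  seqs <- vapply(lens, random_sequence, character(1),
                 freqs = config$residue_freqs)
  n_entrap <- floor(config$entrapment_fraction * n)
  is_entrap <- rep(FALSE, n)
  if (n_entrap > 0L) {
    idx <- seq_len(n_entrap)
    is_entrap[idx] <- TRUE
    seqs[idx] <- vapply(seqs[idx], function(s) {
      paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
    }, character(1))
  }
  proteome <- tibble::tibble(
    id = sprintf("SIM%04d", seq_len(n)),
    description = ifelse(is_entrap, "entrapment", "simulated"),
    sequence = seqs,
    is_decoy = FALSE,
    is_entrapment = is_entrap
  )
  # bait: resample until the ncAA site sits inside a bounded tryptic peptide
  rule0 <- protease_rule("trypsin", max_missed = 0L)
  repeat {
    bseq <- random_sequence(config$bait_length, config$residue_freqs)
    cand <- digest_one(bseq, rule0)
    len <- nchar(cand$sequence)
    ok <- cand[len >= 6L & len <= 25L, ]
    if (nrow(ok) == 0L) next
    pep <- ok[sample.int(nrow(ok), 1L), ]
    off <- sample.int(pep$end - pep$start - 1L, 1L) # interior, keeps termini
    site <- pep$start + off
    if (site > 1L && site < config$bait_length) break
  }
  bait <- tibble::tibble(id = "bait", description = "ncAA bait construct",
                         sequence = bseq, is_decoy = FALSE)
  list(proteome = proteome, bait = bait, ncaa_site = as.integer(site))
}

#' Implant ground-truth cross-links
#'
#' Samples `n_true_links` distinct (prey peptide, site) pairs from the
#' digest-surviving peptides of non-entrapment proteins. The site residue is
#' drawn from the reactivity prior restricted to residues actually present;
#' the bait chain is the fully-tryptic ncAA peptide.
#'
#' @param sim A [simulate_proteome()] result.
#' @param config A [sim_config()].
#' @param rule Digestion rule used for implantation (default trypsin with 3
#'   missed cleavages, matching the search).
#' @return Ground-truth tibble: one row per link with bait and prey chain
#'   descriptions.
#' @export
implant_crosslinks <- function(sim, config,
                               rule = protease_rule("trypsin", max_missed = 3L)) {
  set.seed(config$seed + 1L)
  linker <- crosslinker(ncaa_residue_mass = config$ncaa_mass)
  baits <- bait_peptides(sim$bait$sequence, sim$ncaa_site,
                         protease_rule("trypsin", max_missed = 0L),
                         linker = linker, min_length = 1L, min_mass = 0,
                         max_mass = Inf)
  stopifnot(nrow(baits) >= 1L)
  bait_pep <- baits[1L, ]
  eligible <- sim$proteome[!sim$proteome$is_entrapment, ]
  peps <- digest(eligible, rule)
  # candidate (peptide, site) pairs over the nucleophile set
  sites <- purrr::map(strsplit(peps$sequence, "", fixed = TRUE),
                      function(r) which(r %in% nucleophile_set()))
  nsite <- lengths(sites)
  pool <- tibble::tibble(
    pep_row = rep(seq_len(nrow(peps)), nsite),
    site_position = unlist(sites)
  )
  pool$site_residue <- substring(peps$sequence[pool$pep_row],
                                 pool$site_position, pool$site_position)
  pool_key <- paste(peps$sequence[pool$pep_row], pool$site_position)
  pool <- pool[!duplicated(pool_key), ]
  if (config$n_true_links > nrow(pool)) {
    stop("requested ", config$n_true_links, " links but only ", nrow(pool),
         " distinct (peptide, site) pairs available", call. = FALSE)
  }
  w <- config$reactivity_weights[pool$site_residue]
  w[is.na(w)] <- 0
  picked <- sample.int(nrow(pool), config$n_true_links, prob = w)
  sel <- pool[picked, ]
  pr <- peps[sel$pep_row, ]
  tibble::tibble(
    link_id = sprintf("link%04d", seq_len(nrow(sel))),
    bait_sequence = bait_pep$sequence,
    bait_ncaa_position = bait_pep$ncaa_position,
    bait_start = bait_pep$start,
    prey_sequence = pr$sequence,
    prey_protein = pr$protein_id,
    prey_start = pr$start,
    prey_end = pr$end,
    site_position = sel$site_position,
    site_residue = sel$site_residue,
    site_protein_pos = pr$start + sel$site_position - 1L
  )
}

render_one_spectrum <- function(frags, precursor_neutral, charge, config,
                                scan_id) {
  keep <- stats::runif(nrow(frags)) >= config$fragment_dropout_prob
  frags <- frags[keep, ]
  mz <- frags$mz * (1 + stats::rnorm(nrow(frags), 0,
                                     config$mz_noise_ppm_sd * 1e-6))
  # exponential intensity with rank decay: major ions dominate
  intensity <- 1000 * stats::rexp(length(mz)) *
    exp(-0.02 * rank(-frags$neutral, ties.method = "first"))
  n_noise <- stats::rpois(1L, config$n_noise_peaks_lambda)
  if (n_noise > 0L) {
    lim <- if (length(mz) > 0L) max(mz) * 1.05 else 2000
    mz <- c(mz, stats::runif(n_noise, 100, lim))
    intensity <- c(intensity, 50 * stats::rexp(n_noise))
  }
  ord <- order(mz)
  peaks <- tibble::tibble(mz = round(mz[ord], 6),
                          intensity = round(intensity[ord], 2))
  pre_mz <- neutral_to_mz(precursor_neutral, charge) *
    (1 + stats::rnorm(1L, 0, config$precursor_ppm_sd * 1e-6))
  tibble::tibble(scan_id = scan_id, precursor_mz = round(pre_mz, 6),
                 precursor_charge = as.integer(charge),
                 retention_time = NA_real_, peaks = list(peaks))
}

#' Render noisy MS/MS spectra for implanted links
#'
#' For each link, fragments from the two-chain b/y model are subjected to
#' dropout, Gaussian ppm m/z error and exponential intensities; Poisson
#' numbers of uniform noise peaks are added; the precursor is placed at the
#' true conjugate mass with Gaussian ppm error at a sampled charge.
#' Background spectra are rendered from random linear peptides of the
#' database (entrapment included).
#'
#' @param truth Ground-truth tibble from [implant_crosslinks()].
#' @param sim A [simulate_proteome()] result.
#' @param config A [sim_config()].
#' @return List: `spectra` tibble (MGF-shaped), `truth` with `scan_id`
#'   attached plus background rows flagged by `is_background`.
#' @export
render_spectra <- function(truth, sim, config) {
  set.seed(config$seed + 2L)
  linker <- crosslinker(ncaa_residue_mass = config$ncaa_mass)
  n_links <- nrow(truth)
  f <- config$background_spectra_fraction
  if (f >= 1) {
    # pure-background run: no link spectrum is emitted at all
    truth <- truth[0L, ]
    n_links <- 0L
  }
  specs <- vector("list", n_links)
  for (i in seq_len(n_links)) {
    tr <- truth[i, ]
    cand <- list(
      bait_sequence = tr$bait_sequence,
      bait_ncaa_position = tr$bait_ncaa_position,
      prey_sequence = tr$prey_sequence,
      site_position = tr$site_position
    )
    frags <- theoretical_fragments(cand, linker)
    m <- crosslink_mass(
      peptide_mass(tr$bait_sequence, ncaa_position = tr$bait_ncaa_position,
                   linker = linker),
      peptide_mass(tr$prey_sequence), linker
    )
    z <- sample(config$charge_range, 1L, prob = config$charge_weights)
    specs[[i]] <- render_one_spectrum(frags, m, z, config,
                                      sprintf("scan%05d", i))
  }
  n_bg <- if (f >= 1) {
    config$n_true_links
  } else if (f > 0) {
    round(f / (1 - f) * n_links)
  } else 0L
  bg_specs <- vector("list", n_bg)
  if (n_bg > 0L) {
    bg_peps <- digest(sim$proteome, protease_rule("trypsin", max_missed = 1L))
    stopifnot(nrow(bg_peps) > 0L)
    for (j in seq_len(n_bg)) {
      pep <- bg_peps$sequence[sample.int(nrow(bg_peps), 1L)]
      res <- chain_residue_masses(pep)
      v <- chain_fragment_vectors(res, site_pos = 1L, partner_add = 0,
                                  frag_charges = 1:2)
      frags <- tibble::tibble(mz = v$mz, neutral = v$neutral)
      z <- sample(config$charge_range, 1L, prob = config$charge_weights)
      m <- peptide_mass(pep)
      bg_specs[[j]] <- render_one_spectrum(
        frags, m, z, config, sprintf("scan%05d", n_links + j)
      )
    }
  }
  spectra <- dplyr::bind_rows(c(specs, bg_specs))
  truth$scan_id <- sprintf("scan%05d", seq_len(n_links))
  truth$is_background <- FALSE
  if (n_bg > 0L) {
    bg_truth <- tibble::tibble(
      link_id = NA_character_,
      bait_sequence = NA_character_, bait_ncaa_position = NA_integer_,
      bait_start = NA_integer_, prey_sequence = NA_character_,
      prey_protein = NA_character_, prey_start = NA_integer_,
      prey_end = NA_integer_, site_position = NA_integer_,
      site_residue = NA_character_, site_protein_pos = NA_integer_,
      scan_id = sprintf("scan%05d", n_links + seq_len(n_bg)),
      is_background = TRUE
    )
    truth <- dplyr::bind_rows(truth, bg_truth)
  }
  list(spectra = spectra, truth = truth)
}

#' Run the full simulator and write a benchmark directory
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory; created if needed. Writes `db.fasta`,
#'   `bait.fasta`, `run.mgf`, `truth.tsv` and `config.used.txt`.
#' @return Invisibly, a list with the in-memory `proteome`, `bait`,
#'   `ncaa_site`, `truth` and `spectra`.
#' @export
simulate_run <- function(config, out_dir = NULL) {
  sim <- simulate_proteome(config)
  truth <- implant_crosslinks(sim, config)
  rend <- render_spectra(truth, sim, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(sim$proteome, file.path(out_dir, "db.fasta"))
    write_fasta(sim$bait, file.path(out_dir, "bait.fasta"))
    write_mgf(rend$spectra, file.path(out_dir, "run.mgf"))
    tr <- rend$truth
    utils::write.table(tr, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cfg <- config
    cfg$reactivity_weights <- paste(names(cfg$reactivity_weights),
                                    cfg$reactivity_weights, sep = "=",
                                    collapse = ",")
    cfg$residue_freqs <- paste(names(cfg$residue_freqs), cfg$residue_freqs,
                               sep = "=", collapse = ",")
    lines <- paste0(names(cfg), ": ",
                    vapply(cfg, function(v) paste(v, collapse = " "),
                           character(1)))
    writeLines(c(lines, paste0("ncaa_site: ", sim$ncaa_site)),
               file.path(out_dir, "config.used.txt"))
  }
  invisible(list(proteome = sim$proteome, bait = sim$bait,
                 ncaa_site = sim$ncaa_site, truth = rend$truth,
                 spectra = rend$spectra))
}
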