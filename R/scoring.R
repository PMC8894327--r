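# Greedy unique matching of theoretical ion m/z values to observed peaks
# within a ppm tolerance. Candidate (ion, peak) pairs are ranked by absolute
# ppm error and accepted while both sides are unused, so the assignment is
# deterministic and each peak explains at most one ion. Returns the matched
# peak index per ion (NA when unmatched).
match_fragments <- function(fmz, peak_mz, frag_tol_ppm = 20) {
  nf <- length(fmz)
  np <- length(peak_mz)
  matched <- rep(NA_integer_, nf)
  if (nf == 0L || np == 0L) {
    return(matched)
  }
  lo <- findInterval(fmz * (1 - frag_tol_ppm * 1e-6), peak_mz,
                     left.open = TRUE) + 1L
  hi <- findInterval(fmz * (1 + frag_tol_ppm * 1e-6), peak_mz)
  nhit <- pmax(0L, hi - lo + 1L)
  if (sum(nhit) == 0L) {
    return(matched)
  }
  pairs_f <- rep(seq_len(nf), nhit)
  pairs_p <- sequence(nhit, from = lo)
  if (all(nhit <= 1L) && !anyDuplicated(pairs_p)) {
    # no contention: direct assignment
    matched[pairs_f] <- pairs_p
    return(matched)
  }
  ppm <- abs(ppm_error(peak_mz[pairs_p], fmz[pairs_f]))
  ord <- order(ppm, pairs_f, pairs_p)
  peak_used <- rep(FALSE, np)
  for (k in ord) {
    i <- pairs_f[k]
    j <- pairs_p[k]
    if (is.na(matched[i]) && !peak_used[j]) {
      matched[i] <- j
      peak_used[j] <- TRUE
    }
  }
  matched
}

# Per-ion random match probability from spectrum peak density: the chance a
# random m/z lands within the tolerance window of any peak.
random_match_prob <- function(peak_mz, frag_tol_ppm) {
  np <- length(peak_mz)
  if (np == 0L) {
    return(0)
  }
  span <- max(max(peak_mz) - min(peak_mz), 200)
  width <- 2 * frag_tol_ppm * 1e-6 * mean(peak_mz)
  min(0.3, np * width / span)
}

# Two-chain binomial-tail score from fragment vectors (search hot path).
score_from_vectors <- function(frag_v, peaks, frag_tol_ppm = 20) {
  nb <- length(frag_v$bait$mz)
  np <- length(frag_v$prey$mz)
  fmz <- c(frag_v$bait$mz, frag_v$prey$mz)
  matched <- match_fragments(fmz, peaks$mz, frag_tol_ppm)
  tot_int <- sum(peaks$intensity)
  p <- random_match_prob(peaks$mz, frag_tol_ppm)
  chain_stats <- function(idx) {
    N <- length(idx)
    hit <- matched[idx]
    k <- sum(!is.na(hit))
    mint <- sum(peaks$intensity[hit[!is.na(hit)]])
    sc <- if (k == 0L || N == 0L || p <= 0) {
      0
    } else {
      # log-scale tail probability: long chains underflow double precision
      -stats::pbinom(k - 1L, N, p, lower.tail = FALSE, log.p = TRUE) / log(10)
    }
    list(k = k, frac = if (tot_int > 0) mint / tot_int else 0, score = sc)
  }
  b <- chain_stats(seq_len(nb))
  y <- chain_stats(nb + seq_len(np))
  c(score = b$score + y$score,
    matched_bait = b$k, matched_prey = y$k,
    frac_int_bait = b$frac, frac_int_prey = y$frac)
}

#' Score one candidate against one spectrum
#'
#' Matches theoretical ions to peaks greedily within the fragment tolerance,
#' then scores each chain as the negative log10 binomial tail probability of
#' observing at least the matched count among that chain's theoretical ions,
#' with the per-ion match probability estimated from spectrum peak density.
#' The reported score is the sum over the two chains, so both chains must
#' carry evidence for a high score.
#'
#' @param spectrum One spectrum row (as from [read_mgf()]); only `peaks` is
#'   used.
#' @param candidate One-row candidate (see [theoretical_fragments()]).
#' @param linker A [crosslinker()].
#' @param frag_tol_ppm Fragment tolerance in ppm.
#' @param frag_charges Fragment charges considered.
#' @return One-row tibble: `score`, `matched_bait`, `matched_prey`,
#'   `frac_int_bait`, `frac_int_prey`.
#' @export
score_candidate <- function(spectrum, candidate, linker, frag_tol_ppm = 20,
                            frag_charges = 1:2) {
  peaks <- spectrum$peaks
  if (is.list(peaks) && !is.data.frame(peaks)) peaks <- peaks[[1L]]
  frags <- theoretical_fragments(candidate, linker, frag_charges)
  frag_v <- list(bait = list(mz = frags$mz[frags$chain == "bait"]),
                 prey = list(mz = frags$mz[frags$chain == "prey"]))
  v <- score_from_vectors(frag_v, peaks, frag_tol_ppm)
  tibble::as_tibble(as.list(v))
}
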