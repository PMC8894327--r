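nucleophile_set <- function() c("C", "D", "E", "H", "K", "S", "T", "Y")

#' Reactivity profile across the nucleophile set
#'
#' Tallies unique cross-linked peptides by cross-link-site residue over the
#' eight nucleophiles (C, D, E, H, K, S, T, Y). Peptides whose site could not
#' be localized (`site_delta_score == 0`) are counted in a separate
#' `ambiguous` bucket rather than split fractionally.
#'
#' @param unique_peptides Unique-peptide tibble from [collapse_to_unique()].
#' @return A `gecx_reactivity` tibble: `residue`, `n`, with `cys`, `non_cys`
#'   and `ambiguous` totals as attributes.
#' @export
count_by_residue <- function(unique_peptides) {
  res <- nucleophile_set()
  if (nrow(unique_peptides) == 0L) {
    counts <- stats::setNames(rep(0L, length(res)), res)
    amb <- 0L
  } else {
    ambiguous <- !is.na(unique_peptides$site_delta_score) &
      unique_peptides$site_delta_score == 0
    amb <- sum(ambiguous)
    tab <- table(factor(unique_peptides$site_residue[!ambiguous],
                        levels = res))
    counts <- as.integer(tab)
    names(counts) <- res
  }
  out <- tibble::tibble(
    residue = c(res, "ambiguous"),
    n = c(as.integer(counts), as.integer(amb))
  )
  attr(out, "cys") <- unname(counts["C"])
  attr(out, "non_cys") <- sum(counts[setdiff(res, "C")])
  attr(out, "total") <- sum(counts) + amb
  class(out) <- c("gecx_reactivity", class(out))
  out
}

#' Extract site-centered motif windows
#'
#' Builds 31-residue windows (site plus/minus 15) around cross-link sites,
#' padded with `-` where the window runs past a protein terminus, plus a
#' position frequency matrix, the background residue frequencies of the full
#' database, and a log-odds matrix (pseudocount 1 per residue per column).
#'
#' @param sites Tibble with `prey_protein` and `site_protein_pos` columns.
#' @param proteome Protein tibble (the prey database; used both to look up
#'   windows and as background).
#' @param flank Residues on each side of the site (default 15).
#' @return A `gecx_motif_windows` list: `windows` tibble, `pfm` and
#'   `log_odds` matrices (positions x residues), `background` frequencies.
#' @export
extract_windows <- function(sites, proteome, flank = 15L) {
  width <- 2L * flank + 1L
  seqs <- stats::setNames(proteome$sequence, proteome$id)
  aas <- sort(names(residue_formulas()))
  win <- purrr::map2_chr(sites$prey_protein, sites$site_protein_pos,
                         function(pid, pos) {
    s <- seqs[[pid]]
    if (is.null(s)) stop("unknown protein: ", pid, call. = FALSE)
    n <- nchar(s)
    if (pos < 1L || pos > n) {
      stop("site ", pid, ":", pos, " outside protein of length ", n,
           call. = FALSE)
    }
    lo <- pos - flank
    hi <- pos + flank
    core <- substring(s, max(1L, lo), min(n, hi))
    paste0(strrep("-", max(0L, 1L - lo)), core, strrep("-", max(0L, hi - n)))
  })
  stopifnot(all(nchar(win) == width))
  pfm <- matrix(0L, nrow = width, ncol = length(aas),
                dimnames = list(position = NULL, residue = aas))
  if (length(win) > 0L) {
    chars <- do.call(rbind, strsplit(win, "", fixed = TRUE))
    for (j in seq_len(width)) {
      tb <- table(factor(chars[, j], levels = aas))
      pfm[j, ] <- as.integer(tb)
    }
  }
  bg_tab <- table(factor(unlist(strsplit(paste(proteome$sequence, collapse = ""),
                                         "", fixed = TRUE)), levels = aas))
  background <- as.numeric(bg_tab) / max(1, sum(bg_tab))
  names(background) <- aas
  # pseudocount 1 per residue per column avoids log 0
  col_tot <- rowSums(pfm)
  freq <- (pfm + 1) / (col_tot + length(aas))
  log_odds <- log2(sweep(freq, 2L, pmax(background, 1e-9), "/"))
  structure(
    list(
      windows = tibble::tibble(prey_protein = sites$prey_protein,
                               site_protein_pos = sites$site_protein_pos,
                               window = unname(win)),
      pfm = pfm, background = background, log_odds = log_odds,
      flank = flank
    ),
    class = "gecx_motif_windows"
  )
}

#' @export
print.gecx_motif_windows <- function(x, ...) {
  cat("<gecx_motif_windows> ", nrow(x$windows), " windows of width ",
      2L * x$flank + 1L, "\n", sep = "")
  invisible(x)
}

#' Export motif windows as FASTA for external motif discovery
#'
#' Terminal pads are stripped (motif scanners expect plain sequence);
#' record names are deterministic `protein|position` identifiers.
#'
#' @param windows A [extract_windows()] result.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
export_meme_fasta <- function(windows, path) {
  w <- windows$windows
  if (nrow(w) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  out <- tibble::tibble(
    id = paste0(w$prey_protein, "|", w$site_protein_pos),
    description = "",
    sequence = gsub("^-+|-+$", "", w$window)
  )
  write_fasta(out, path)
  invisible(path)
}
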