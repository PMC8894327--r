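#' Protease cleavage rules
#'
#' A rule cleaves C-terminal to any residue in `cleave_after`, except when the
#' next residue is in `suppressed_before`. Built-in rules: `"trypsin"`
#' (after K/R, not before P), `"lysc"` (after K), `"none"` (no cleavage,
#' returns the intact protein).
#'
#' @param name Rule name, or one of the built-ins.
#' @param cleave_after Residues cleaved after; required unless `name` is a
#'   built-in.
#' @param suppressed_before Residues suppressing cleavage when next in
#'   sequence (default none).
#' @param max_missed Maximum internal uncut sites allowed in a peptide.
#' @return A `gecx_protease` list.
#' @export
#' @examples
#' protease_rule("trypsin", max_missed = 3)
#' protease_rule("trypsin", suppressed_before = character()) # no proline rule
protease_rule <- function(name, cleave_after = NULL, suppressed_before = NULL,
                          max_missed = 0L) {
  builtin <- list(
    trypsin = list(cleave_after = c("K", "R"), suppressed_before = "P"),
    lysc    = list(cleave_after = "K", suppressed_before = character()),
    none    = list(cleave_after = character(), suppressed_before = character())
  )
  if (is.null(cleave_after) && name %in% names(builtin)) {
    cleave_after <- builtin[[name]]$cleave_after
    if (is.null(suppressed_before)) {
      suppressed_before <- builtin[[name]]$suppressed_before
    }
  }
  if (is.null(suppressed_before)) suppressed_before <- character()
  stopifnot(max_missed >= 0L)
  if (name != "none" && length(cleave_after) == 0L) {
    stop("cleave_after must be non-empty for rule '", name, "'", call. = FALSE)
  }
  structure(
    list(name = name, cleave_after = cleave_after,
         suppressed_before = suppressed_before,
         max_missed = as.integer(max_missed)),
    class = "gecx_protease"
  )
}

# Cleavage boundaries of one sequence under a rule: positions i such that the
# bond after residue i is cut. `exclude` positions never cleave (models an
# ncAA occupying a canonical cleavage letter).
cleavage_sites <- function(res, rule, exclude = integer()) {
  n <- length(res)
  if (n <= 1L || length(rule$cleave_after) == 0L) {
    return(integer())
  }
  i <- which(res[-n] %in% rule$cleave_after)
  if (length(rule$suppressed_before) > 0L && length(i) > 0L) {
    i <- i[!(res[i + 1L] %in% rule$suppressed_before)]
  }
  setdiff(i, exclude)
}

digest_one <- function(sequence, rule, exclude = integer()) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  if (n == 0L) {
    return(tibble::tibble(sequence = character(), start = integer(),
                          end = integer(), missed_cleavages = integer()))
  }
  bounds <- c(0L, cleavage_sites(res, rule, exclude), n)
  nb <- length(bounds)
  out <- vector("list", nb - 1L)
  for (j in seq_len(nb - 1L)) {
    kmax <- min(rule$max_missed, nb - 1L - j)
    ks <- 0:kmax
    out[[j]] <- tibble::tibble(
      start = bounds[j] + 1L,
      end = bounds[j + 1L + ks],
      missed_cleavages = ks
    )
  }
  out <- dplyr::bind_rows(out)
  out$sequence <- substring(sequence, out$start, out$end)
  out[, c("sequence", "start", "end", "missed_cleavages")]
}

#' In-silico protease digestion
#'
#' Digests each protein into peptides with 0 to `max_missed` internal uncut
#' sites, then applies length and mass bounds. Pass `min_length = 1`,
#' `min_mass = 0`, `max_mass = Inf` etc. to disable the bounds.
#'
#' @param proteins Data frame with columns `id`, `sequence`, and optionally
#'   `is_decoy`.
#' @param rule A [protease_rule()].
#' @param min_length,max_length Peptide length bounds (residues).
#' @param min_mass,max_mass Peptide neutral mass bounds (Da).
#' @return Tibble of peptides: `sequence`, `protein_id`, `start`, `end`
#'   (1-based inclusive protein coordinates), `missed_cleavages`,
#'   `ncaa_position` (`NA`), `is_decoy`.
#' @export
#' @examples
#' prot <- tibble::tibble(id = "P1", sequence = "AAKGGRCC")
#' digest(prot, protease_rule("trypsin"), min_length = 1, min_mass = 0)
digest <- function(proteins, rule, min_length = 5L, max_length = 60L,
                   min_mass = 500, max_mass = 6000) {
  stopifnot(is.data.frame(proteins), all(c("id", "sequence") %in% names(proteins)))
  if (!"is_decoy" %in% names(proteins)) proteins$is_decoy <- FALSE
  peps <- purrr::pmap(
    list(proteins$id, proteins$sequence, proteins$is_decoy),
    function(id, seqn, dec) {
      p <- digest_one(seqn, rule)
      p$protein_id <- id
      p$is_decoy <- dec
      p
    }
  )
  peps <- dplyr::bind_rows(peps)
  if (nrow(peps) == 0L) {
    return(empty_peptides())
  }
  peps$ncaa_position <- NA_integer_
  len <- nchar(peps$sequence)
  peps <- peps[len >= min_length & len <= max_length, ]
  if (is.finite(max_mass) || min_mass > 0) {
    mss <- pepmass_vec(peps$sequence)
    peps <- peps[mss >= min_mass & mss <= max_mass, ]
  }
  tibble::as_tibble(peps[, c("sequence", "protein_id", "start", "end",
                             "missed_cleavages", "ncaa_position", "is_decoy")])
}

empty_peptides <- function() {
  tibble::tibble(sequence = character(), protein_id = character(),
                 start = integer(), end = integer(),
                 missed_cleavages = integer(), ncaa_position = integer(),
                 is_decoy = logical())
}

#' Sequential two-protease digestion
#'
#' Models the enrichment workflow in which a first protease (typically Lys-C)
#' releases large fragments, a subset of fragments is retained (e.g. those
#' still carrying a C-terminal affinity tag, or the ncAA), and the retained
#' fragments are digested by a second protease (typically trypsin).
#'
#' @param proteins Protein data frame as for [digest()].
#' @param first,second [protease_rule()]s for the two stages.
#' @param retained Predicate taking the stage-one peptide tibble and returning
#'   a logical vector of fragments to keep; default keeps all.
#' @inheritParams digest
#' @return Peptide tibble as for [digest()], coordinates in the parent
#'   protein; `missed_cleavages` counts stage-two missed sites.
#' @export
double_digest <- function(proteins, first, second, retained = NULL,
                          min_length = 5L, max_length = 60L,
                          min_mass = 500, max_mass = 6000) {
  stage1 <- digest(proteins, first, min_length = 1L, max_length = Inf,
                   min_mass = 0, max_mass = Inf)
  if (!is.null(retained) && nrow(stage1) > 0L) {
    keep <- retained(stage1)
    stopifnot(is.logical(keep), length(keep) == nrow(stage1))
    stage1 <- stage1[keep, ]
  }
  if (nrow(stage1) == 0L) {
    return(empty_peptides())
  }
  frag_proteins <- tibble::tibble(
    id = stage1$protein_id, sequence = stage1$sequence,
    is_decoy = stage1$is_decoy, offset = stage1$start - 1L
  )
  out <- purrr::pmap(
    list(frag_proteins$id, frag_proteins$sequence, frag_proteins$is_decoy,
         frag_proteins$offset),
    function(id, seqn, dec, off) {
      p <- digest_one(seqn, second)
      p$start <- p$start + off
      p$end <- p$end + off
      p$protein_id <- id
      p$is_decoy <- dec
      p
    }
  )
  out <- dplyr::bind_rows(out)
  out$ncaa_position <- NA_integer_
  out <- dplyr::distinct(out)
  len <- nchar(out$sequence)
  out <- out[len >= min_length & len <= max_length, ]
  if (nrow(out) > 0L && (is.finite(max_mass) || min_mass > 0)) {
    mss <- pepmass_vec(out$sequence)
    out <- out[mss >= min_mass & mss <= max_mass, ]
  }
  tibble::as_tibble(out[, c("sequence", "protein_id", "start", "end",
                            "missed_cleavages", "ncaa_position", "is_decoy")])
}

#' Bait peptides covering the ncAA site
#'
#' Digests the bait construct and returns every peptide covering the ncAA
#' position, with `ncaa_position` set to the site's 1-based index within the
#' peptide. The ncAA site itself is never treated as a cleavage site even if
#' the canonical letter at that position is cleavable: the incorporated
#' residue is not a protease substrate.
#'
#' @param bait_sequence Bait protein sequence (canonical letters; the ncAA
#'   occupies `ncaa_site`).
#' @param ncaa_site 1-based position of the ncAA in the bait protein.
#' @param rule A [protease_rule()].
#' @param linker Optional [crosslinker()] used for the mass bound; when
#'   absent, mass bounds use the canonical residue at the site.
#' @inheritParams digest
#' @return Peptide tibble with `ncaa_position` set; `protein_id` is `"bait"`.
#' @export
bait_peptides <- function(bait_sequence, ncaa_site, rule, linker = NULL,
                          min_length = 5L, max_length = 60L,
                          min_mass = 500, max_mass = 6000) {
  n <- nchar(bait_sequence)
  if (ncaa_site < 1L || ncaa_site > n) {
    stop("ncaa_site ", ncaa_site, " outside protein of length ", n,
         call. = FALSE)
  }
  p <- digest_one(bait_sequence, rule, exclude = ncaa_site)
  p <- p[p$start <= ncaa_site & p$end >= ncaa_site, ]
  p$protein_id <- "bait"
  p$is_decoy <- FALSE
  p$ncaa_position <- as.integer(ncaa_site - p$start + 1L)
  len <- nchar(p$sequence)
  p <- p[len >= min_length & len <= max_length, ]
  if (nrow(p) > 0L && (is.finite(max_mass) || min_mass > 0)) {
    mss <- mapply(function(s, np) {
      peptide_mass(s, ncaa_position = if (is.null(linker)) NULL else np,
                   linker = linker)
    }, p$sequence, p$ncaa_position)
    p <- p[mss >= min_mass & mss <= max_mass, ]
  }
  tibble::as_tibble(p[, c("sequence", "protein_id", "start", "end",
                          "missed_cleavages", "ncaa_position", "is_decoy")])
}
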