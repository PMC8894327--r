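#' Read a protein FASTA file
#'
#' Sequences are uppercased and trailing stop characters (`*`) stripped.
#' Record ids (first whitespace-delimited token of the header) must be unique.
#'
#' @param path FASTA file path.
#' @return Tibble with columns `id`, `description`, `sequence`, `is_decoy`
#'   (`TRUE` for ids carrying the decoy prefix `rev_`).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  first <- nonempty[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA: line ", first, " is not a header", call. = FALSE)
  }
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(aa))
  seqs <- gsub("*", "", seqs, fixed = TRUE)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id: ", ids[!nzchar(seqs)][1L], call. = FALSE)
  }
  tibble::tibble(
    id = unname(ids),
    description = unname(desc),
    sequence = unname(seqs),
    is_decoy = startsWith(unname(ids), "rev_")
  )
}

#' Write a protein FASTA file
#'
#' @param proteins Data frame with `id`, `sequence` and optionally
#'   `description` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  hdr <- proteins$id
  if ("description" %in% names(proteins)) {
    hdr <- ifelse(nzchar(proteins$description),
                  paste(proteins$id, proteins$description), proteins$id)
  }
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- hdr
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Append reversed-sequence decoys to a protein database
#'
#' One decoy per target protein: the full sequence reversed, the id prefixed
#' with `rev_`, and `is_decoy` set. Decoys are appended after the targets.
#'
#' @param proteins Target protein tibble as from [read_fasta()].
#' @param prefix Decoy id prefix.
#' @return Tibble with `2 * nrow(proteins)` rows.
#' @export
#' @examples
#' db <- tibble::tibble(id = "P1", description = "", sequence = "ABCK")
#' make_decoys(db)$sequence
make_decoys <- function(proteins, prefix = "rev_") {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  if (!"description" %in% names(proteins)) proteins$description <- ""
  decoys <- tibble::tibble(
    id = paste0(prefix, proteins$id),
    description = proteins$description,
    sequence = reverse_string(proteins$sequence),
    is_decoy = TRUE
  )
  proteins$is_decoy <- FALSE
  dplyr::bind_rows(
    proteins[, c("id", "description", "sequence", "is_decoy")],
    decoys
  )
}

reverse_string <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}
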