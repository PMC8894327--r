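results_columns <- function() {
  c("scan_id", "bait_sequence", "bait_ncaa_position",
    "bait_ncaa_protein_pos", "prey_sequence",
    "prey_protein", "prey_start", "prey_end", "site_position",
    "site_residue", "site_protein_pos", "mods", "score", "site_delta_score",
    "qvalue", "precursor_ppm", "matched_bait", "matched_prey", "is_decoy")
}

results_version_line <- "# gecxms-results-v1"

#' Write and read cross-link search results
#'
#' Results are tab-separated with a frozen, versioned column order; the first
#' line is a version comment. `read_results()` accepts exactly what
#' `write_results()` produces.
#'
#' @param rows PSM tibble containing at least the frozen result columns.
#' @param path Output path.
#' @return `path` (write) or the results tibble (read).
#' @export
write_results <- function(rows, path) {
  cols <- results_columns()
  missing <- setdiff(cols, names(rows))
  if (length(missing) > 0L) {
    stop("results missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(rows) > 0L) {
    stopifnot(all(rows$qvalue >= 0 & rows$qvalue <= 1, na.rm = TRUE))
  }
  out <- rows[, cols]
  # fixed formatting keeps equal runs byte-identical
  num <- c("score", "site_delta_score", "qvalue", "precursor_ppm")
  for (cl in num) out[[cl]] <- sprintf("%.6f", out[[cl]])
  writeLines(results_version_line, path)
  suppressWarnings(utils::write.table(
    out, path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE
  ))
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  first <- readLines(path, n = 1L)
  if (!identical(first, results_version_line)) {
    stop("not a gecxms results file: ", path, call. = FALSE)
  }
  out <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  tibble::as_tibble(out)
}

#' Export distance restraints for docking
#'
#' One line per accepted cross-link pairing the bait ncAA residue (protein
#' coordinate) with the prey protein residue, plus an upper distance bound in
#' Angstrom for use as a docking restraint.
#'
#' @param rows Accepted result tibble (see [write_results()]) with bait ncAA
#'   protein positions in `bait_ncaa_protein_pos`, or computable from
#'   `bait_start + bait_ncaa_position - 1` when `bait_start` is present.
#' @param path Output path.
#' @param bait_protein Name written in the bait column.
#' @param max_distance Upper distance bound in Angstrom. The side-chain span
#'   of an alkyl-bromide ncAA conjugate is short; the default allows backbone
#'   flexibility.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(rows, path, bait_protein = "bait",
                             max_distance = 10) {
  pos <- if ("bait_ncaa_protein_pos" %in% names(rows)) {
    rows$bait_ncaa_protein_pos
  } else if ("bait_start" %in% names(rows)) {
    rows$bait_start + rows$bait_ncaa_position - 1L
  } else {
    rows$bait_ncaa_position
  }
  out <- tibble::tibble(
    bait_protein = bait_protein,
    bait_residue = pos,
    prey_protein = rows$prey_protein,
    prey_residue = rows$site_protein_pos,
    prey_site_aa = rows$site_residue,
    max_distance_angstrom = max_distance
  )
  out <- dplyr::distinct(out)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
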