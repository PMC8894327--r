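#' Read centroided MS/MS spectra from an MGF file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS`, `CHARGE`
#' and optional `RTINSECONDS` keys. Peaks are sorted by m/z on load. A block
#' without a `CHARGE` line is expanded into one record per charge in
#' `charges_if_missing`, sharing the scan id, so downstream rank-1 selection
#' still picks a single interpretation per scan.
#'
#' @param path MGF file path.
#' @param charges_if_missing Integer charges assumed for blocks lacking a
#'   `CHARGE` line.
#' @return Tibble with columns `scan_id`, `precursor_mz`, `precursor_charge`,
#'   `retention_time`, and a `peaks` list-column of tibbles
#'   (`mz`, `intensity`).
#' @export
read_mgf <- function(path, charges_if_missing = 3:7) {
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(begins > ends)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path,
         call. = FALSE)
  }
  out <- purrr::map2(begins, ends, function(b, e) {
    block <- lines[(b + 1L):(e - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*$", "", block[kv])
    vals <- sub("^[^=]*=", "", block[kv])
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else
      paste0("scan_", b)
    pepmass <- if ("PEPMASS" %in% keys) {
      as.numeric(strsplit(vals[match("PEPMASS", keys)], "\\s+")[[1]][1L])
    } else {
      stop("malformed MGF: block '", title, "' lacks PEPMASS", call. = FALSE)
    }
    rt <- if ("RTINSECONDS" %in% keys) {
      as.numeric(vals[match("RTINSECONDS", keys)])
    } else NA_real_
    charge <- if ("CHARGE" %in% keys) {
      as.integer(sub("[+-]$", "", vals[match("CHARGE", keys)]))
    } else NA_integer_
    peak_lines <- block[!kv & nzchar(trimws(block))]
    if (length(peak_lines) > 0L) {
      mat <- do.call(rbind, strsplit(trimws(peak_lines), "[ \t]+"))
      peaks <- tibble::tibble(mz = as.numeric(mat[, 1L]),
                              intensity = as.numeric(mat[, 2L]))
      if (anyNA(peaks$mz) || anyNA(peaks$intensity) ||
          any(peaks$intensity < 0)) {
        stop("malformed MGF: bad peak line in block '", title, "'",
             call. = FALSE)
      }
      peaks <- peaks[order(peaks$mz), ]
    } else {
      peaks <- tibble::tibble(mz = numeric(), intensity = numeric())
    }
    charges <- if (is.na(charge)) charges_if_missing else charge
    tibble::tibble(scan_id = title, precursor_mz = pepmass,
                   precursor_charge = as.integer(charges),
                   retention_time = rt, peaks = rep(list(peaks), length(charges)))
  })
  dplyr::bind_rows(out)
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()] for spectra with known charge; numeric fields are
#' printed with fixed precision so identical inputs yield identical bytes.
#'
#' @param spectra Spectrum tibble as from [read_mgf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- purrr::pmap(
    list(spectra$scan_id, spectra$precursor_mz, spectra$precursor_charge,
         spectra$retention_time, spectra$peaks),
    function(id, mz, z, rt, peaks) {
      c("BEGIN IONS",
        paste0("TITLE=", id),
        paste0("PEPMASS=", sprintf("%.6f", mz)),
        paste0("CHARGE=", z, "+"),
        if (!is.na(rt)) paste0("RTINSECONDS=", sprintf("%.2f", rt)),
        sprintf("%.6f %.2f", peaks$mz, peaks$intensity),
        "END IONS", "")
    }
  )
  writeLines(unlist(blocks), path)
  invisible(path)
}

#' Read centroided spectra from an mzML file
#'
#' Thin wrapper over the proteowizard-backed mzML reader; MS2 scans are
#' returned in the same shape as [read_mgf()].
#'
#' @inheritParams read_mgf
#' @return Spectrum tibble as for [read_mgf()].
#' @export
read_mzml <- function(path, charges_if_missing = 3:7) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("mzML reading requires the mzR package", call. = FALSE)
  }
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  ms2 <- which(hd$msLevel == 2L)
  out <- purrr::map(ms2, function(i) {
    pk <- mzR::peaks(fh, i)
    peaks <- tibble::tibble(mz = pk[, 1L], intensity = pk[, 2L])
    peaks <- peaks[order(peaks$mz), ]
    z <- hd$precursorCharge[i]
    charges <- if (is.na(z) || z < 1L) charges_if_missing else z
    tibble::tibble(
      scan_id = paste0("scan_", hd$acquisitionNum[i]),
      precursor_mz = hd$precursorMZ[i],
      precursor_charge = as.integer(charges),
      retention_time = hd$retentionTime[i],
      peaks = rep(list(peaks), length(charges))
    )
  })
  dplyr::bind_rows(out)
}
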