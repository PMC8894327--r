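uniq_frame <- function(residues, delta = 1) {
  tibble::tibble(
    bait_sequence = "GGYGGK", prey_sequence = sprintf("p%d", seq_along(residues)),
    site_position = 1L, mods = "", prey_protein = sprintf("P%d", seq_along(residues)),
    site_residue = residues, site_protein_pos = 5L,
    site_delta_score = rep_len(delta, length(residues)), score = 10
  )
}

test_that("reactivity table tallies site residues with an ambiguous bucket", {
  rt <- count_by_residue(uniq_frame(c("C", "C", "C", "K")))
  expect_equal(rt$n[rt$residue == "C"], 3L)
  expect_equal(rt$n[rt$residue == "K"], 1L)
  expect_equal(attr(rt, "non_cys"), 1L)
  expect_equal(attr(rt, "cys"), 3L)

  z <- count_by_residue(uniq_frame(character()))
  expect_true(all(z$n == 0L))

  # zero-margin localizations go to the ambiguous bucket, not a residue
  mix <- uniq_frame(c("C", "D", "E"), delta = c(1, 0, 1))
  rt2 <- count_by_residue(mix)
  expect_equal(rt2$n[rt2$residue == "ambiguous"], 1L)
  expect_equal(rt2$n[rt2$residue == "D"], 0L)
  expect_equal(attr(rt2, "total"), 3L)
})

test_that("reactivity totals are conserved under any partition", {
  set.seed(51)
  res <- sample(c("C", "D", "E", "H", "K", "S", "T", "Y"), 60, replace = TRUE,
                prob = c(0.7, rep(0.3 / 7, 7)))
  u <- uniq_frame(res)
  whole <- count_by_residue(u)
  split1 <- count_by_residue(u[1:25, ])
  split2 <- count_by_residue(u[26:60, ])
  expect_equal(whole$n, split1$n + split2$n)
  expect_equal(attr(whole, "total"), nrow(u))
})

test_that("motif windows pad at termini and center the site at position 16", {
  proteome <- tibble::tibble(id = "P1", sequence = "AYCDEFGHIK")
  w <- extract_windows(tibble::tibble(prey_protein = "P1",
                                      site_protein_pos = 3L), proteome)
  win <- w$windows$window[1]
  expect_equal(nchar(win), 31L)
  expect_equal(substr(win, 1, 13), strrep("-", 13))  # 13 left pads
  expect_equal(substr(win, 16, 16), "C")             # site centered
  expect_equal(substr(win, 24, 31), strrep("-", 8))  # 8 right pads
  expect_equal(gsub("-", "", win), "AYCDEFGHIK")

  # centered site in a long protein needs no padding
  long <- tibble::tibble(id = "P2", sequence = strrep("ACDK", 20))
  w2 <- extract_windows(tibble::tibble(prey_protein = "P2",
                                       site_protein_pos = 40L), long)
  expect_false(grepl("-", w2$windows$window[1], fixed = TRUE))

  expect_error(
    extract_windows(tibble::tibble(prey_protein = "P1",
                                   site_protein_pos = 99L), proteome),
    "P1:99"
  )
  # pfm rows sum to the non-pad observations at each offset
  expect_equal(unname(rowSums(w$pfm)),
               as.integer(strsplit(win, "")[[1]] != "-"))
})

test_that("planted CXXC contexts elevate C log-odds at offsets 0 and +3", {
  set.seed(52)
  mk <- function() {
    s <- random_protein(80)
    pos <- sample(20:60, 1)
    substr(s, pos, pos + 3) <- paste0("C", substr(s, pos + 1, pos + 2), "C")
    list(seq = s, pos = pos)
  }
  planted <- purrr::map(1:40, ~mk())
  proteome <- tibble::tibble(id = sprintf("P%d", 1:40),
                             sequence = purrr::map_chr(planted, "seq"))
  sites <- tibble::tibble(prey_protein = proteome$id,
                          site_protein_pos = purrr::map_int(planted, "pos"))
  w <- extract_windows(sites, proteome)
  expect_gt(w$log_odds[16, "C"], 0)      # offset 0
  expect_gt(w$log_odds[19, "C"], 0)      # offset +3
  # a column whose composition matches background has near-zero log-odds
  expect_lt(max(abs(w$log_odds[2, ])), max(w$log_odds[16, "C"], w$log_odds[19, "C"]))
})

test_that("motif FASTA export strips pads and names records deterministically", {
  proteome <- tibble::tibble(id = "P1", sequence = "AYCDEFGHIK")
  w <- extract_windows(tibble::tibble(prey_protein = "P1",
                                      site_protein_pos = 3L), proteome)
  f <- withr::local_tempfile(fileext = ".fasta")
  export_meme_fasta(w, f)
  back <- read_fasta(f)
  expect_equal(nrow(back), 1L)
  expect_equal(back$id, "P1|3")
  expect_equal(back$sequence, "AYCDEFGHIK")

  # zero windows produce an empty (but valid) file
  w0 <- extract_windows(tibble::tibble(prey_protein = character(),
                                       site_protein_pos = integer()), proteome)
  export_meme_fasta(w0, f)
  expect_equal(length(readLines(f)), 0L)
})
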