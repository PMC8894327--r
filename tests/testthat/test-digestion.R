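unbounded <- function(proteins, rule) {
  digest(proteins, rule, min_length = 1L, max_length = Inf,
         min_mass = 0, max_mass = Inf)
}

test_that("trypsin rule cuts after K/R, suppressed before P", {
  tryp <- protease_rule("trypsin")
  p <- function(s) tibble::tibble(id = "P1", sequence = s)
  expect_setequal(unbounded(p("AAKGGRCC"), tryp)$sequence, c("AAK", "GGR", "CC"))
  tryp1 <- protease_rule("trypsin", max_missed = 1L)
  expect_setequal(unbounded(p("AAKGGR"), tryp1)$sequence,
                  c("AAK", "GGR", "AAKGGR"))
  expect_setequal(unbounded(p("AKPGGR"), tryp)$sequence, "AKPGGR")
  # proline rule switchable off
  no_p <- protease_rule("trypsin", suppressed_before = character())
  expect_setequal(unbounded(p("AKPGGR"), no_p)$sequence, c("AK", "PGGR"))
  # no-op protease returns the intact protein
  expect_setequal(unbounded(p("AAKGGR"), protease_rule("none"))$sequence,
                  "AAKGGR")
  expect_equal(nrow(unbounded(p(""), tryp)), 0L)
})

test_that("digest equals the exhaustive substring-filter oracle", {
  set.seed(21)
  tryp <- protease_rule("trypsin", max_missed = 3L)
  for (i in 1:40) {
    s <- random_protein(sample(5:60, 1))
    got <- unbounded(tibble::tibble(id = "P", sequence = s), tryp)
    want <- oracle_digest(s, c("K", "R"), "P", 3L)
    expect_identical(digest_key(got), digest_key(want))
  }
})

test_that("k-missed peptides concatenate k+1 adjacent fully-cleaved peptides", {
  set.seed(22)
  tryp3 <- protease_rule("trypsin", max_missed = 3L)
  tryp0 <- protease_rule("trypsin", max_missed = 0L)
  for (i in 1:20) {
    s <- random_protein(60)
    full <- unbounded(tibble::tibble(id = "P", sequence = s), tryp3)
    zero <- unbounded(tibble::tibble(id = "P", sequence = s), tryp0)
    zero <- zero[order(zero$start), ]
    for (j in which(full$missed_cleavages > 0)) {
      span <- zero[zero$start >= full$start[j] & zero$end <= full$end[j], ]
      expect_equal(nrow(span), full$missed_cleavages[j] + 1L)
      expect_identical(paste(span$sequence, collapse = ""), full$sequence[j])
    }
  }
})

test_that("sequential digestion composes two rules through a retention filter", {
  lysc <- protease_rule("lysc")
  tryp <- protease_rule("trypsin")
  # His-tag style enrichment: only the tag-bearing Lys-C fragment survives
  prot <- tibble::tibble(id = "B", sequence = "AARGGKCCDRHHHHHH")
  got <- double_digest(prot, lysc, tryp,
                       retained = function(p) endsWith(p$sequence, "HHHHHH"),
                       min_length = 1L, min_mass = 0, max_mass = Inf)
  expect_setequal(got$sequence, c("CCDR", "HHHHHH"))
  expect_true(all(got$protein_id == "B"))
  # coordinates stay in the parent protein frame
  expect_equal(got$start[got$sequence == "CCDR"], 7L)

  # retained == TRUE equals brute-force sequential oracle
  set.seed(23)
  for (i in 1:15) {
    s <- random_protein(60)
    got <- double_digest(tibble::tibble(id = "P", sequence = s),
                         protease_rule("lysc", max_missed = 1L),
                         protease_rule("trypsin", max_missed = 1L),
                         min_length = 1L, min_mass = 0, max_mass = Inf)
    st1 <- oracle_digest(s, "K", character(), 1L)
    want <- list()
    for (j in seq_len(nrow(st1))) {
      sub <- oracle_digest(st1$sequence[j], c("K", "R"), "P", 1L)
      if (nrow(sub) > 0) {
        sub$start <- sub$start + st1$start[j] - 1L
        sub$end <- sub$end + st1$start[j] - 1L
        want[[length(want) + 1]] <- sub
      }
    }
    want <- unique(do.call(rbind, want))
    expect_identical(digest_key(got), digest_key(want))
  }

  # second rule with no cleavage leaves stage-one fragments unchanged
  got2 <- double_digest(prot, lysc, protease_rule("none"),
                        min_length = 1L, min_mass = 0, max_mass = Inf)
  st1 <- unbounded(prot, lysc)
  expect_setequal(got2$sequence, st1$sequence)
})

test_that("bait peptides cover the ncAA site and never cleave at it", {
  tryp <- protease_rule("trypsin")
  # unique covering peptide at 0 missed cleavages
  b <- bait_peptides("AAKGGYGGRCCK", 6, tryp, min_length = 1L, min_mass = 0,
                     max_mass = Inf)
  expect_equal(nrow(b), 1L)
  expect_identical(b$sequence, "GGYGGR")
  expect_equal(b$ncaa_position, 3L)

  tryp3 <- protease_rule("trypsin", max_missed = 3L)
  b3 <- bait_peptides("AAKGGYGGRCCKDDK", 6, tryp3, min_length = 1L,
                      min_mass = 0, max_mass = Inf)
  expect_true(all(b3$start <= 6 & b3$end >= 6))
  expect_true(all(b3$missed_cleavages <= 3))
  expect_true(nrow(b3) >= 4)

  # an ncAA replacing a K is not a protease substrate
  bk <- bait_peptides("AAKGGKGGR", 6, tryp, min_length = 1L, min_mass = 0,
                      max_mass = Inf)
  expect_identical(bk$sequence, "GGKGGR")

  expect_error(bait_peptides("AAK", 9, tryp), "outside")
})
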