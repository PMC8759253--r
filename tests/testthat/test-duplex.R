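mir21 <- "TGACCGATGTTGACCTTGGCA"

test_that("perfect complement yields one hit with Allen 0 and ratio 1", {
  set.seed(31)
  tx <- random_transcript(200)
  pl <- plant_site(tx, mir21, 90)
  h <- enumerate_duplexes("m", mir21, "t", pl$seq)
  h <- h[h$site_start == 90, ]
  expect_equal(nrow(h), 1L)
  expect_equal(h$allen_score, 0)
  expect_equal(h$mfe_ratio, 1)
  expect_equal(h$pairing, strrep("|", 21))
  expect_equal(h$cleavage_pos, 90 + 11)
})

test_that("Allen penalties follow the position-weighted scoring table", {
  expect_equal(allen_score(strrep("|", 21)), 0)
  expect_equal(allen_score(paste0(strrep("|", 14), "o", strrep("|", 6))), 0.5)
  expect_equal(allen_score(paste0(strrep("|", 4), "o", strrep("|", 16))), 1)
  expect_equal(allen_score(paste0(strrep("|", 4), "x", strrep("|", 16))), 2)
  # a defect moved from position 15 to position 5 exactly doubles
  at15 <- allen_score(paste0(strrep("|", 14), "x", strrep("|", 6)))
  at5 <- allen_score(paste0(strrep("|", 4), "x", strrep("|", 16)))
  expect_equal(at5, 2 * at15)
  # additivity over independent defects
  both <- allen_score(paste0(strrep("|", 4), "x",
                             strrep("|", 9), "x", strrep("|", 6)))
  expect_equal(both, at5 + at15)
  # bulges on either strand cost one per nucleotide, doubled in 2-13
  expect_equal(allen_score(paste0(strrep("|", 4), "-", strrep("|", 16))), 2)
  expect_equal(allen_score(paste0(strrep("|", 15), "^", strrep("|", 6))), 1)
  expect_equal(allen_score(paste0(strrep("|", 4), "^", strrep("|", 17))), 2)
})

test_that("Allen score ignores sequence outside the aligned window", {
  set.seed(32)
  pairing <- paste0(strrep("|", 7), "x", strrep("|", 13))
  for (r in 1:3) {
    tx <- random_transcript(300)
    pl <- plant_site(tx, mir21, 140, pairing)
    h <- enumerate_duplexes("m", mir21, "t", pl$seq, max_allen = 4)
    h <- h[h$site_start == 140, ]
    expect_equal(h$allen_score, 2)
    expect_equal(h$pairing, pairing)
  }
})

test_that("duplex energies order GC-rich above AU-rich and bound the ratio", {
  gc_rich <- strrep("GC", 10)
  au_rich <- strrep("AT", 10)
  expect_lt(perfect_mfe(gc_rich), perfect_mfe(au_rich))
  expect_lt(perfect_mfe(au_rich), 0)
  # |mfe| <= |mfe_perfect| over random degenerate pairings
  set.seed(33)
  for (r in 1:100) {
    mi <- random_transcript(21)
    pairing <- random_pairing(mi, n_gu = sample(0:2, 1),
                              n_mm = sample(0:2, 1),
                              n_bulge = sample(0:1, 1))
    expect_gte(duplex_mfe(mi, pairing), perfect_mfe(mi))
  }
})

test_that("mfe ratio is the energy quotient and decreases with lost pairs", {
  expect_equal(mfe_ratio(-20.7, -30), 0.69)
  expect_equal(mfe_ratio(perfect_mfe(mir21), perfect_mfe(mir21)), 1)
  set.seed(34)
  mi <- "GGCAGGCAGGCAGGCAGGCAG"  # strong duplex so truncations stay stable
  perf <- perfect_mfe(mi)
  ratios <- vapply(0:4, function(k) {
    pairing <- paste0(strrep("x", k), strrep("|", 21 - k))
    mfe_ratio(duplex_mfe(mi, pairing), perf)
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("cleavage coordinate follows the pairing walk, bulges included", {
  set.seed(35)
  # ungapped: site_start + 11 for a 21-nt small RNA
  tx <- plant_site(random_transcript(200), mir21, 60)
  h <- enumerate_duplexes("m", mir21, "t", tx$seq)
  h <- h[h$site_start == 60, ]
  expect_equal(h$cleavage_pos, 71)
  # bulged sites: compare against the independent pairing walk
  for (r in 1:20) {
    pairing <- random_pairing(mir21, n_gu = 0, n_mm = sample(0:1, 1),
                              n_bulge = sample(1:2, 1))
    pl <- plant_site(random_transcript(260), mir21, 101, pairing)
    expect_equal(pl$cleavage_pos,
                 oracle_cleavage_walk(pairing, pl$site_end))
    hh <- enumerate_duplexes("m", mir21, "t", pl$seq, max_allen = 6,
                             min_mfe_ratio = 0.3)
    hh <- hh[hh$site_start >= 95 & hh$site_start <= 107, ]
    if (nrow(hh) == 1 && hh$pairing == pairing)
      expect_equal(hh$cleavage_pos,
                   oracle_cleavage_walk(pairing, hh$site_end))
  }
})

test_that("enumeration matches the exhaustive oracle on planted transcripts", {
  set.seed(36)
  for (r in 1:6) {
    mi <- random_transcript(sample(20:22, 1))
    tx <- random_transcript(sample(120:220, 1))
    n_def <- sample(0:2, 1)
    pairing <- random_pairing(mi, n_gu = sample(0:1, 1), n_mm = n_def,
                              n_bulge = sample(0:1, 1))
    tx <- plant_site(tx, mi, sample(40:80, 1), pairing)$seq
    got <- enumerate_duplexes("m", mi, "t", tx, max_allen = 5,
                              min_mfe_ratio = 0.5)
    want <- oracle_enumerate(mi, tx, max_allen = 5, min_ratio = 0.5)
    expect_equal(got$site_start, want$site_start)
    expect_equal(got$site_end, want$site_end)
    expect_equal(got$allen_score, want$allen_score)
    expect_equal(got$pairing, want$pairing)
    expect_equal(got$cleavage_pos, want$cleavage_pos)
  }
})

test_that("reported hits always satisfy the ratio and score bounds", {
  set.seed(37)
  for (r in 1:5) {
    mi <- random_transcript(21)
    tx <- plant_site(random_transcript(300), mi, 101,
                     random_pairing(mi, n_mm = 1))$seq
    h <- enumerate_duplexes("m", mi, "t", tx, max_allen = 5,
                            min_mfe_ratio = 0.5)
    expect_true(all(h$mfe_ratio > 0 & h$mfe_ratio <= 1))
    expect_true(all(h$allen_score <= 5))
    expect_true(all(h$site_start <= h$cleavage_pos &
                    h$cleavage_pos <= h$site_end))
  }
})

test_that("small RNA FASTA abundances parse from _xN headers and TSV", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">mi1_x200", "UGACCGAUGUUGACCUUGGCA",
               ">mi2", "UUCAGGAGUCACGUUCAAGGU"), fa)
  srs <- read_small_rnas(fa, library_total = 1e6)
  expect_equal(srs$count, c(200, 1))
  expect_equal(srs$rpm, c(200, 1))
  expect_equal(srs$seq[1], "TGACCGATGTTGACCTTGGCA")
  ab <- tempfile(fileext = ".tsv")
  writeLines("mi2\t5000", ab)
  srs2 <- read_small_rnas(fa, abundance_tsv = ab, library_total = 1e6)
  expect_equal(srs2$count, c(200, 5000))
})
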