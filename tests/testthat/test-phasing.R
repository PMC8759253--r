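ladder_hits <- function(tx, anchor, register = 0, cycles = 9,
                        abundance = 5, minus_cycles = integer(),
                        n_noise = 0) {
  ph <- simulate_phasing(tx, anchor, register, cycles, abundance,
                         minus_cycles, n_noise)
  data.frame(read_seq = ph$seq, transcript_id = "tas", pos = ph$pos,
             strand = ph$strand, mismatches = 0L, count = ph$count,
             stringsAsFactors = FALSE)
}

test_that("a perfect ladder is phased at its register only", {
  set.seed(51)
  tx <- random_transcript(400)
  h <- ladder_hits(tx, anchor = 100)
  sc <- phase_scan(h, 100, nchar(tx))
  expect_equal(nrow(sc), 21L)
  r0 <- sc[sc$register == 0, ]
  expect_equal(r0$n, 9L)
  expect_equal(r0$k, 9L)
  expect_equal(r0$p_value, 1 / choose(189, 9))
  expect_true(all(sc$k[sc$register != 0] == 0))
  # the same ladder shifted +3 nt lands on register 3
  h3 <- ladder_hits(tx, anchor = 100, register = 3)
  sc3 <- phase_scan(h3, 100, nchar(tx))
  expect_equal(sc3$k[sc3$register == 3], 9L)
  expect_equal(sc3$k[sc3$register == 0], 0L)
  expect_error(phase_scan(h, 500, nchar(tx)), "anchor")
})

test_that("uniform 5' ends give a phased fraction near 1/21", {
  set.seed(52)
  fr <- replicate(200, {
    n <- 30
    pos <- sample(189, n)
    h <- data.frame(read_seq = strrep("A", 21), transcript_id = "t",
                    pos = 100 + pos, strand = "+", mismatches = 0L,
                    count = 1L, stringsAsFactors = FALSE)
    sc <- phase_scan(h, 100, 400)
    sc$k[sc$register == 0] / sc$n[sc$register == 0]
  })
  expect_equal(mean(fr), 1 / 21, tolerance = 0.15)
})

test_that("hypergeometric tail matches direct summation and enumeration", {
  # closed-form single term
  expect_equal(phasing_pvalue(189, 9, 9, 9), 1 / choose(189, 9))
  expect_equal(phasing_pvalue(189, 9, 9, 0), 1)
  # direct summation over the tail, many parameter combinations
  set.seed(53)
  for (r in 1:200) {
    L <- sample(10:200, 1)
    m <- sample(1:min(L, 20), 1)
    n <- sample(0:min(L, 30), 1)
    k <- sample(0:min(n, m), 1)
    expect_equal(phasing_pvalue(L, m, n, k), oracle_phyper_sum(L, m, n, k))
  }
  # full enumeration over all occupancy patterns at small size
  for (cs in list(c(12, 3, 4), c(21, 6, 5), c(42, 2, 6), c(30, 5, 4))) {
    L <- cs[1]; m <- cs[2]; n <- cs[3]
    for (k in 0:min(n, m))
      expect_equal(phasing_pvalue(L, m, n, k),
                   oracle_phyper_enum(L, m, n, k), tolerance = 1e-12)
  }
  # tail is non-increasing in k
  ps <- vapply(0:6, function(k) phasing_pvalue(100, 10, 12, k), numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(phasing_pvalue(10, 3, 4, 5), "invalid")
})

test_that("cycle labels follow the D-numbering with the strand offset", {
  expect_equal(name_phased(101, "+", 100, 0), "D1(+)")
  expect_equal(name_phased(101 + 7 * 21, "+", 100, 0), "D8(+)")
  # minus partner of the D8 duplex sits 2 nt upstream of the plus read
  expect_equal(name_phased(101 + 7 * 21 - 2, "-", 100, 0), "D8(-)")
  expect_true(is.na(name_phased(105, "+", 100, 0)))
  expect_equal(name_phased(104, "+", 100, 3), "D1(+)")
})

test_that("phased reads from significant windows become small RNAs", {
  set.seed(54)
  tx <- random_transcript(400)
  h <- ladder_hits(tx, 100, minus_cycles = c(4, 8))
  sc <- phase_scan(h, 100, nchar(tx))
  sec <- extract_secondary(sc, h, p_cutoff = 0.01)
  expect_equal(nrow(sec), 11L)              # 9 plus + 2 minus
  expect_true(all(grepl("^tas_r0_D[1-9]\\([+-]\\)$", sec$id)))
  expect_true(all(nchar(sec$seq) == 21L))
  expect_equal(sum(grepl("\\(-\\)", sec$id)), 2L)
  # no significant window -> empty set
  noise <- data.frame(read_seq = substr(tx, 121, 141), transcript_id = "tas",
                      pos = 121L, strand = "+", mismatches = 0L, count = 1L,
                      stringsAsFactors = FALSE)
  sc2 <- phase_scan(noise, 100, nchar(tx))
  expect_equal(nrow(extract_secondary(sc2, noise, 0.01)), 0L)
})

test_that("ladders survive added noise as the minimal-p register", {
  set.seed(55)
  tx <- random_transcript(400)
  for (r in 1:20) {
    reg <- sample(0:20, 1)
    h <- ladder_hits(tx, 60, register = reg, cycles = 8, n_noise = 8)
    sc <- phase_scan(h, 60, nchar(tx))
    expect_equal(sc$register[which.min(sc$p_value)], reg)
  }
})

test_that("noise-only windows are rarely significant", {
  set.seed(56)
  sig <- replicate(200, {
    n <- sample(5:15, 1)
    h <- data.frame(read_seq = strrep("A", 21), transcript_id = "t",
                    pos = 100 + sample(189, n), strand = "+",
                    mismatches = 0L, count = 1L, stringsAsFactors = FALSE)
    sc <- phase_scan(h, 100, 400)
    min(sc$p_value) <= 0.01
  })
  # multiple registers are tested per window, so allow the union bound
  expect_lt(mean(sig), 21 * 0.01 + 3 * sqrt(0.21 * 0.79 / 200))
})

test_that("secondary siRNAs validate against parent and sibling targets", {
  set.seed(57)
  parent <- random_transcript(420)
  ladder <- simulate_phasing(parent, 80, cycles = 9, abundance = 5)
  d3 <- ladder$seq[ladder$cycle == 3][1]
  sibling <- plant_site(random_transcript(300), d3, 141)
  parent2 <- plant_site(parent, d3, 350)
  txome <- c(parent = parent2$seq, sib = sibling$seq)
  peaks <- data.frame(transcript_id = c("sib", "parent"),
                      pos = c(sibling$cleavage_pos, parent2$cleavage_pos),
                      count = 20L)
  profs <- lapply(split(peaks, peaks$transcript_id), function(d)
    build_profile(data.frame(transcript_id = d$transcript_id, pos = d$pos,
                             strand = "+", count = d$count,
                             stringsAsFactors = FALSE),
                  library_mapped_total = 1e5))
  sec <- small_rna_set(c("D3", "D5"), c(d3, ladder$seq[ladder$cycle == 5][1]),
                       count = c(5, 5), library_total = 100)
  recs <- validate_secondary(sec, txome, profs)
  expect_equal(sort(unique(recs$transcript_id)), c("parent", "sib"))
  expect_true(all(recs$origin == "secondary"))
  expect_true(all(recs$mirna_id == "D3"))
  expect_true(all(recs$allen_score == 0))
  # a siRNA whose only site fails the ratio floor yields nothing
  weak <- small_rna_set("w", random_transcript(21), 5, library_total = 100)
  expect_equal(nrow(validate_secondary(weak, txome, profs)), 0L)
})
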