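# small helper building a profile list from planted peak tables
peaks_to_profiles <- function(peaks, total = 1e6) {
  lapply(split(peaks, peaks$transcript_id), function(d)
    build_profile(data.frame(transcript_id = d$transcript_id[1],
                             pos = d$pos, strand = "+", count = d$count,
                             stringsAsFactors = FALSE),
                  library_mapped_total = total))
}

mkhit <- function(mirna = "m1", tx = "t1", cleav = 112, allen = 2,
                  ratio = 0.9, rpm = 10, seq = "TGACCGATGTTGACCTTGGCA") {
  data.frame(mirna_id = mirna, mirna_seq = seq, transcript_id = tx,
             site_start = cleav - 11L, site_end = cleav + 9L,
             pairing = strrep("|", 21), allen_score = allen, mfe = -30,
             mfe_perfect = -35, mfe_ratio = ratio,
             cleavage_pos = as.integer(cleav), mirna_rpm = rpm,
             stringsAsFactors = FALSE)
}

test_that("a duplex hit validates when a degradome 5' end is at the site", {
  prof <- peaks_to_profiles(data.frame(transcript_id = "t1", pos = 112L,
                                       count = 9L))
  rec <- validate_targets(mkhit(), prof)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$matched_pos, 112L)
  expect_equal(rec$cut_count, 9L)
  expect_equal(rec$category, 1L)
  # no degradome evidence -> no record
  far <- peaks_to_profiles(data.frame(transcript_id = "t1", pos = 300L,
                                      count = 9L))
  expect_equal(nrow(validate_targets(mkhit(), far)), 0L)
})

test_that("the matching window widens inclusively", {
  prof <- peaks_to_profiles(data.frame(transcript_id = "t1", pos = 114L,
                                       count = 5L))
  w0 <- validate_targets(mkhit(), prof, window = 0)
  w1 <- validate_targets(mkhit(), prof, window = 1)
  w2 <- validate_targets(mkhit(), prof, window = 2)
  expect_equal(nrow(w0), 0L)
  expect_equal(nrow(w1), 0L)
  expect_equal(nrow(w2), 1L)
  # windows nest: every record at window w is present at w+1
  prof2 <- peaks_to_profiles(data.frame(transcript_id = "t1",
                                        pos = c(112L, 113L),
                                        count = c(2L, 8L)))
  r0 <- validate_targets(mkhit(), prof2, window = 0)
  r1 <- validate_targets(mkhit(), prof2, window = 1)
  expect_true(all(r0$transcript_id %in% r1$transcript_id))
})

test_that("multi-target retention keeps paralogs and multiple sites", {
  hits <- rbind(mkhit(tx = "t1"), mkhit(tx = "t2"), mkhit(tx = "t3"))
  prof <- peaks_to_profiles(data.frame(
    transcript_id = c("t1", "t2", "t3"), pos = 112L, count = c(9L, 7L, 5L)))
  rec <- validate_targets(hits, prof)
  expect_equal(nrow(rec), 3L)                       # no best-mfe collapse
  expect_equal(sort(rec$transcript_id), c("t1", "t2", "t3"))
  # CleaveLand-compatibility mode: exactly one record per miRNA
  hits$mfe_ratio <- c(0.8, 0.95, 0.9)
  one <- validate_targets(hits, prof, collapse_to_best_mfe = TRUE)
  expect_equal(nrow(one), 1L)
  expect_equal(one$transcript_id, "t2")             # highest mfe ratio
  expect_true(all(paste(one$mirna_id, one$transcript_id) %in%
                  paste(rec$mirna_id, rec$transcript_id)))
})

test_that("filter boundaries are inclusive and tiers split correctly", {
  at_boundary <- validate_targets(
    mkhit(allen = 4, ratio = 0.69, rpm = 0.5),
    peaks_to_profiles(data.frame(transcript_id = "t1", pos = 112L,
                                 count = 3L)))
  kept <- apply_filters(at_boundary)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$tier, "stringent")
  candidate <- apply_filters(validate_targets(
    mkhit(allen = 4.5, ratio = 0.9, rpm = 10),
    peaks_to_profiles(data.frame(transcript_id = "t1", pos = 112L,
                                 count = 3L))))
  expect_equal(candidate$tier, "candidate")
  dropped <- apply_filters(validate_targets(
    mkhit(allen = 2, ratio = 0.5, rpm = 10),
    peaks_to_profiles(data.frame(transcript_id = "t1", pos = 112L,
                                 count = 3L))))
  expect_equal(nrow(dropped), 0L)
})

test_that("loosening any threshold never removes a stringent record", {
  set.seed(41)
  recs <- do.call(rbind, lapply(1:40, function(i)
    validate_targets(mkhit(mirna = paste0("m", i),
                           allen = sample(seq(0, 6, 0.5), 1),
                           ratio = round(stats::runif(1, 0.4, 1), 2),
                           rpm = round(stats::runif(1, 0, 3), 2)),
                     peaks_to_profiles(data.frame(transcript_id = "t1",
                                                  pos = 112L, count = 3L)))))
  base <- apply_filters(recs)
  strict_keys <- paste(base$mirna_id[base$tier == "stringent"])
  looser <- list(
    apply_filters(recs, allen_max = 5),
    apply_filters(recs, mfe_ratio_min = 0.5),
    apply_filters(recs, mirna_rpm_min = 0))
  for (l in looser) {
    keys <- paste(l$mirna_id[l$tier == "stringent"])
    expect_true(all(strict_keys %in% keys))
  }
})

test_that("sample comparison counts common and unique pairs by category", {
  profA <- peaks_to_profiles(data.frame(transcript_id = c("t1", "t2"),
                                        pos = 112L, count = c(9L, 9L)))
  profB <- peaks_to_profiles(data.frame(transcript_id = "t1", pos = 112L,
                                        count = 4L))
  A <- apply_filters(validate_targets(rbind(mkhit(tx = "t1"),
                                            mkhit(tx = "t2")), profA,
                                      sample_label = "A"))
  B <- apply_filters(validate_targets(mkhit(tx = "t1"), profB,
                                      sample_label = "B"))
  cmp <- compare_samples(list(A = A, B = B))
  expect_equal(cmp$n_common, 1L)
  expect_equal(unname(cmp$n_unique["A"]), 1L)
  expect_equal(unname(cmp$n_unique["B"]), 0L)
  expect_equal(sum(cmp$summary$common[cmp$summary$sample == "A"]), 1)
  # identical sets: all common
  cmp2 <- compare_samples(list(A = A, A2 = A))
  expect_equal(cmp2$n_common, 2L)
  expect_equal(sum(cmp2$n_unique), 0L)
})

test_that("comparison reproduces planted overlap structure", {
  set.seed(42)
  # plant 30 pairs in A, 22 in B, 15 shared
  all_tx <- sprintf("t%02d", 1:40)
  a_tx <- all_tx[1:30]; b_tx <- all_tx[c(1:15, 31:37)]
  mk <- function(txs, label, prof_count) {
    prof <- peaks_to_profiles(data.frame(transcript_id = txs, pos = 112L,
                                         count = prof_count))
    apply_filters(validate_targets(
      do.call(rbind, lapply(txs, function(t) mkhit(tx = t))), prof,
      sample_label = label))
  }
  cmp <- compare_samples(list(A = mk(a_tx, "A", 9L), B = mk(b_tx, "B", 9L)))
  expect_equal(cmp$n_common, 15L)
  expect_equal(unname(cmp$n_unique), c(15L, 7L))
  expect_equal(nrow(cmp$pairs), 37L)
  # common + unique(A) + unique(B) = union size
  expect_equal(cmp$n_common + sum(cmp$n_unique), nrow(cmp$pairs))
})
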