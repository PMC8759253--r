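#' Random transcript sequence
#'
#' @param length transcript length (nt).
#' @param gc GC fraction.
#' @return a character scalar on `{A,C,G,T}`.
#' @export
random_transcript <- function(length, gc = 0.45) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

# Target site sequence (5'->3') implied by a miRNA and a pairing string.
# The walk runs along the miRNA 5'->3' and consumes target nucleotides
# 3'->5', so the collected characters are reversed at the end.
site_from_pairing <- function(mirna_seq, pairing) {
  mi <- strsplit(canonicalize_seq(mirna_seq), "", fixed = TRUE)[[1]]
  sym <- strsplit(pairing, "", fixed = TRUE)[[1]]
  if (sum(sym != "^") != length(mi))
    stop("pairing string inconsistent with miRNA length")
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  wobble <- c(G = "T", T = "G")
  out <- character(0)
  i <- 0L
  for (s in sym) {
    if (s != "^") i <- i + 1L
    out <- c(out, switch(s,
      "|" = wc[[mi[i]]],
      "o" = {
        if (!mi[i] %in% names(wobble))
          stop("G:U wobble impossible at miRNA position ", i,
               " (base ", mi[i], ")")
        wobble[[mi[i]]]
      },
      "x" = {
        # any base that neither Watson-Crick- nor wobble-pairs mi[i]
        bad <- c(wc[[mi[i]]], if (mi[i] %in% names(wobble)) wobble[[mi[i]]])
        sample(setdiff(c("A", "C", "G", "T"), bad), 1)
      },
      "-" = character(0),
      "^" = sample(c("A", "C", "G", "T"), 1),
      stop("unknown pairing symbol: ", s)))
  }
  paste(rev(out), collapse = "")
}

#' Plant a small RNA target site into a transcript
#'
#' Writes, starting at `position`, the target sequence implied by the
#' pairing string, so that duplex enumeration recovers the planted pairing
#' at the planted position.
#'
#' @param transcript transcript sequence.
#' @param mirna_seq small RNA sequence (5' to 3').
#' @param position 1-based site start on the transcript.
#' @param pairing pairing string (see [enumerate_duplexes()]); default
#'   perfect complementarity.
#' @return list with `seq` (modified transcript), `site_start`,
#'   `site_end`, `cleavage_pos` and `site_seq`.
#' @export
plant_site <- function(transcript, mirna_seq, position,
                       pairing = strrep("|", nchar(mirna_seq))) {
  site <- site_from_pairing(mirna_seq, pairing)
  if (position + nchar(site) - 1L > nchar(transcript))
    stop("planted site exceeds transcript bounds")
  seq <- paste0(substr(transcript, 1, position - 1L), site,
                substr(transcript, position + nchar(site),
                       nchar(transcript)))
  # cleavage = transcript coordinate paired with miRNA position 10; walk
  # the pairing from the site 3' end
  sym <- strsplit(pairing, "", fixed = TRUE)[[1]]
  t <- position + nchar(site) - 1L
  i <- 0L; cleav <- NA_integer_
  for (s in sym) {
    if (s == "^") { t <- t - 1L; next }
    i <- i + 1L
    if (s != "-") {
      if (i == 10L) cleav <- t
      t <- t - 1L
    }
  }
  list(seq = seq, site_start = position,
       site_end = position + nchar(site) - 1L,
       cleavage_pos = cleav, site_seq = site)
}

#' Simulate a degradome read library
#'
#' Emits 20-21 nt sense-strand reads whose 5' ends realize the requested
#' per-position counts, plus a uniform background. Background 5' ends
#' avoid an exclusion zone around every planted peak (and any extra
#' excluded intervals) so that planted categories cannot be perturbed.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param peaks data.frame with columns `transcript_id`, `pos`, `count`.
#' @param n_background number of background reads.
#' @param read_lengths lengths sampled for reads (default 20:21).
#' @param exclude_margin half-width of the exclusion zone around peaks.
#' @param exclude list of extra excluded intervals, each
#'   `list(transcript_id, lo, hi)`.
#' @return list with `reads` (a [read_set()]), `truth` (data.frame of
#'   intended per-position counts with their cleavage categories, computed
#'   from the generator's own count bookkeeping by direct evaluation of
#'   the category clauses).
#' @export
simulate_degradome <- function(transcripts, peaks, n_background = 0L,
                               read_lengths = 20:21, exclude_margin = 2L,
                               exclude = list()) {
  stopifnot(all(peaks$transcript_id %in% names(transcripts)))
  tab <- peaks[, c("transcript_id", "pos", "count")]
  # background positions, uniform over transcripts, outside exclusions
  if (n_background > 0L) {
    lens <- nchar(transcripts)
    max_len <- max(read_lengths)
    bg <- data.frame(transcript_id = character(), pos = integer())
    tries <- 0L
    while (nrow(bg) < n_background && tries < 50L * n_background) {
      tries <- tries + 1L
      ti <- sample(length(transcripts), 1)
      if (lens[ti] < max_len + 1L) next
      p <- sample(lens[ti] - max_len, 1)
      tid <- names(transcripts)[ti]
      near_peak <- any(peaks$transcript_id == tid &
                       abs(peaks$pos - p) <= exclude_margin)
      in_excl <- any(vapply(exclude, function(e)
        e[[1]] == tid && p >= e[[2]] && p <= e[[3]], logical(1)))
      if (!near_peak && !in_excl)
        bg <- rbind(bg, data.frame(transcript_id = tid, pos = p))
    }
    if (nrow(bg)) {
      bg$count <- 1L
      tab <- rbind(tab, bg)
    }
  }
  # realized count table (summing duplicate background positions)
  key <- paste(tab$transcript_id, tab$pos)
  agg <- rowsum(tab$count, key)
  parts <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
  truth <- data.frame(transcript_id = parts[, 1],
                      pos = as.integer(parts[, 2]),
                      count = as.integer(agg[, 1]),
                      stringsAsFactors = FALSE)
  # category clauses evaluated directly on the intended counts
  truth <- do.call(rbind, lapply(split(truth, truth$transcript_id),
                                 function(d) {
    mx <- max(d$count); mean_occ <- mean(d$count)
    d$category <- ifelse(d$count == 1L, 4L,
                  ifelse(d$count == mx, 1L,
                  ifelse(d$count > mean_occ, 2L, 3L)))
    d
  }))
  truth <- truth[order(truth$transcript_id, truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  seqs <- character(0); cnts <- integer(0)
  for (i in seq_len(nrow(truth))) {
    len <- sample(read_lengths, 1)
    tx <- transcripts[[truth$transcript_id[i]]]
    if (truth$pos[i] + len - 1L > nchar(tx)) len <- min(read_lengths)
    if (truth$pos[i] + len - 1L > nchar(tx)) next
    seqs <- c(seqs, substr(tx, truth$pos[i], truth$pos[i] + len - 1L))
    cnts <- c(cnts, truth$count[i])
  }
  list(reads = collapse_reads(read_set(seqs, cnts,
                                       source_label = "sim_degradome")),
       truth = truth)
}

#' Simulate a phased siRNA ladder
#'
#' Generates a 21-nt plus-strand ladder at the requested register and
#' cycle count downstream of an anchor, optional minus-strand partners at
#' the 2-nt 3'-overhang offset, and off-lattice noise reads.
#'
#' @param transcript transcript sequence.
#' @param anchor cleavage anchor coordinate.
#' @param register phase register (0-20).
#' @param cycles number of plus-strand cycles.
#' @param abundance per-read abundance.
#' @param minus_cycles integer vector of cycles that also get a minus-
#'   strand partner read.
#' @param n_noise number of off-lattice plus-strand noise reads (within
#'   the window, never on the planted register lattice).
#' @param phase phase length (21).
#' @param span window length (189).
#' @return data.frame with columns `seq`, `strand`, `pos` (leftmost
#'   transcript coordinate), `cycle`, `count`, `phased`.
#' @export
simulate_phasing <- function(transcript, anchor, register = 0L,
                             cycles = 9L, abundance = 5L,
                             minus_cycles = integer(),
                             n_noise = 0L, phase = 21L, span = 189L) {
  L <- nchar(transcript)
  starts <- anchor + 1L + register + (seq_len(cycles) - 1L) * phase
  if (any(starts + phase - 1L > L))
    stop("ladder exceeds transcript length")
  rows <- data.frame(seq = character(), strand = character(),
                     pos = integer(), cycle = integer(), count = integer(),
                     phased = logical(), stringsAsFactors = FALSE)
  if (cycles > 0L)
    rows <- data.frame(
      seq = substring(transcript, starts, starts + phase - 1L),
      strand = rep("+", cycles), pos = starts, cycle = seq_len(cycles),
      count = rep(abundance, cycles), phased = rep(TRUE, cycles),
      stringsAsFactors = FALSE)
  for (cy in minus_cycles) {
    st <- anchor + 1L + register + (cy - 1L) * phase - 2L
    if (st < 1L) next
    rows <- rbind(rows, data.frame(
      seq = reverse_complement(substr(transcript, st, st + phase - 1L)),
      strand = "-", pos = st, cycle = cy, count = abundance,
      phased = TRUE, stringsAsFactors = FALSE))
  }
  lattice <- anchor + 1L + register + (0:((span %/% phase))) * phase
  made <- 0L; tries <- 0L
  while (made < n_noise && tries < 50L * max(1L, n_noise)) {
    tries <- tries + 1L
    p <- anchor + 1L + sample(span - phase, 1)
    if (p %in% lattice || p + phase - 1L > L) next
    rows <- rbind(rows, data.frame(
      seq = substr(transcript, p, p + phase - 1L),
      strand = "+", pos = p, cycle = NA_integer_, count = 1L,
      phased = FALSE, stringsAsFactors = FALSE))
    made <- made + 1L
  }
  rows
}

#' Generate the golden miniature dataset
#'
#' A fully specified fixture exercising every pipeline stage: three
#' paralogous transcripts sharing an identical planted cut-site block
#' (site plus downstream sequence, so the cut-site degradome read
#' multi-maps to all three), a TAS-like transcript carrying a second
#' miRNA's site that triggers a 9-cycle 21-nt phased siRNA ladder, and a
#' downstream (ARF-like) transcript targeted by one of the phased siRNAs
#' — which also re-targets its parent. Degradome peaks realize category-1
#' signals at every planted cleavage site; background reads avoid all
#' planted regions.
#'
#' @param seed integer seed; the same seed reproduces the fixture
#'   byte-identically.
#' @param peak_count degradome read count at each planted cleavage site.
#' @param n_background background degradome reads.
#' @return list with `transcriptome`, `mirnas` (a [small_rna_set()]),
#'   `degradome` (a [read_set()]), `srna` (a [read_set()] for the phasing
#'   stage), `truth_targets` (planted miRNA and secondary-siRNA target
#'   records), `truth_degradome` (per-position counts and categories),
#'   `anchor`, `tas_id` and `phasing` (the planted ladder table).
#' @export
make_golden_fixture <- function(seed = 1814L, peak_count = 30L,
                                n_background = 45L) {
  set.seed(seed)
  mir_a <- "TGACCGATGTTGACCTTGGCA"   # targets the paralog family
  mir_b <- "TTCAGGAGTCACGTTCAAGGT"   # triggers the TAS-like ladder
  # paralogs share site + 21 nt downstream so 20-21 nt cut-site reads are
  # identical across family members
  shared_down <- random_transcript(21)
  site_pos <- c(PARA1 = 201L, PARA2 = 331L, PARA3 = 151L)
  transcriptome <- character(0)
  truth_targets <- list()
  for (tid in names(site_pos)) {
    tx <- random_transcript(800)
    pl <- plant_site(tx, mir_a, site_pos[[tid]])
    tx <- pl$seq
    down_at <- pl$site_end + 1L
    tx <- paste0(substr(tx, 1, down_at - 1L), shared_down,
                 substr(tx, down_at + 21L, nchar(tx)))
    transcriptome[[tid]] <- tx
    truth_targets[[length(truth_targets) + 1L]] <- data.frame(
      mirna_id = "mir_a", transcript_id = tid,
      cleavage_pos = pl$cleavage_pos, allen_score = 0, origin = "mirna",
      stringsAsFactors = FALSE)
  }
  # TAS-like transcript: mir_b site with a single seed mismatch
  tas <- random_transcript(400)
  pair_b <- paste0(strrep("|", 15), "x", strrep("|", 5))  # MM at pos 16
  pl_b <- plant_site(tas, mir_b, 101L, pair_b)
  tas <- pl_b$seq
  anchor <- pl_b$cleavage_pos
  truth_targets[[length(truth_targets) + 1L]] <- data.frame(
    mirna_id = "mir_b", transcript_id = "TASL1",
    cleavage_pos = anchor, allen_score = 1, origin = "mirna",
    stringsAsFactors = FALSE)
  transcriptome[["TASL1"]] <- tas
  phasing <- simulate_phasing(tas, anchor, register = 0L, cycles = 9L,
                              abundance = 5L, minus_cycles = c(4L, 8L),
                              n_noise = 6L)
  d4_seq <- phasing$seq[phasing$strand == "+" & phasing$cycle == 4][1]
  # cascade: D4(+) gets a perfect site in an ARF-like transcript and in
  # its own parent, downstream of the ladder window
  arf <- random_transcript(600)
  pl_arf <- plant_site(arf, d4_seq, 301L)
  transcriptome[["ARFL1"]] <- pl_arf$seq
  pl_parent <- plant_site(transcriptome[["TASL1"]], d4_seq, 340L)
  transcriptome[["TASL1"]] <- pl_parent$seq
  truth_targets[[length(truth_targets) + 1L]] <- data.frame(
    mirna_id = "TASL1_r0_D4(+)", transcript_id = "ARFL1",
    cleavage_pos = pl_arf$cleavage_pos, allen_score = 0,
    origin = "secondary", stringsAsFactors = FALSE)
  truth_targets[[length(truth_targets) + 1L]] <- data.frame(
    mirna_id = "TASL1_r0_D4(+)", transcript_id = "TASL1",
    cleavage_pos = pl_parent$cleavage_pos, allen_score = 0,
    origin = "secondary", stringsAsFactors = FALSE)
  truth_targets <- do.call(rbind, truth_targets)
  peaks <- data.frame(
    transcript_id = truth_targets$transcript_id,
    pos = truth_targets$cleavage_pos,
    count = peak_count, stringsAsFactors = FALSE)
  sim <- simulate_degradome(
    transcriptome, peaks, n_background = n_background,
    exclude = list(list("TASL1", anchor - 2L, anchor + 191L),
                   list("TASL1", 330L, 370L),
                   list("ARFL1", 290L, 330L),
                   list("PARA1", site_pos[["PARA1"]], site_pos[["PARA1"]] + 45L),
                   list("PARA2", site_pos[["PARA2"]], site_pos[["PARA2"]] + 45L),
                   list("PARA3", site_pos[["PARA3"]], site_pos[["PARA3"]] + 45L)))
  tr <- merge(truth_targets,
              stats::setNames(sim$truth[, c("transcript_id", "pos",
                                            "category")],
                              c("transcript_id", "cleavage_pos", "category")),
              by = c("transcript_id", "cleavage_pos"), all.x = TRUE)
  truth_targets <- tr[order(tr$origin, tr$mirna_id, tr$transcript_id), ,
                      drop = FALSE]
  rownames(truth_targets) <- NULL
  srna <- read_set(phasing$seq, phasing$count, source_label = "sim_srna")
  mirnas <- small_rna_set(c("mir_a", "mir_b"), c(mir_a, mir_b),
                          count = c(50, 50), library_total = 1000)
  list(transcriptome = transcriptome, mirnas = mirnas,
       degradome = sim$reads, srna = collapse_reads(srna),
       truth_targets = truth_targets, truth_degradome = sim$truth,
       anchor = anchor, tas_id = "TASL1", phasing = phasing)
}

#' Write the golden fixture as plain-text files
#'
#' @param fx a [make_golden_fixture()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_golden_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tx_lines <- as.vector(rbind(paste0(">", names(fx$transcriptome)),
                              unname(fx$transcriptome)))
  writeLines(tx_lines, file.path(dir, "transcripts.fa"))
  writeLines(as.vector(rbind(sprintf(">%s_x%d", fx$mirnas$id,
                                     as.integer(fx$mirnas$count)),
                             fx$mirnas$seq)),
             file.path(dir, "mirnas.fa"))
  write_collapsed_fasta(fx$degradome, file.path(dir, "degradome.fa"),
                        prefix = "deg")
  write_collapsed_fasta(fx$srna, file.path(dir, "srna.fa"), prefix = "sr")
  utils::write.table(fx$truth_targets,
                     file.path(dir, "truth_targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fx$truth_degradome,
                     file.path(dir, "truth_degradome.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
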