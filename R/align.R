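#' Read a transcriptome FASTA
#'
#' @param path FASTA of cDNA/transcript sequences.
#' @return named character vector of canonicalized sequences; names are
#'   transcript ids (first whitespace-delimited token of each header).
#' @export
read_transcriptome <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate transcript id: ",
                               ids[duplicated(ids)][1])
  seqs <- canonicalize_seq(as.character(ss))
  names(seqs) <- ids
  seqs
}

#' Build an exact k-mer index over a transcriptome
#'
#' The index supports all-occurrence lookup of k-mers and backs the
#' pigeonhole seed-and-verify aligner: a read with at most `m` mismatches
#' must contain at least one of `m + 1` non-overlapping exact seeds.
#'
#' @param transcriptome named character vector of transcript sequences
#'   (ids as names), as from [read_transcriptome()].
#' @param seed_k seed k-mer length.
#' @return an object of class `kmer_index`.
#' @export
build_index <- function(transcriptome, seed_k = 10L) {
  if (!length(transcriptome)) stop("empty transcriptome")
  ids <- names(transcriptome)
  if (is.null(ids) || anyDuplicated(ids))
    stop("transcript ids must be unique and non-null")
  seed_k <- as.integer(seed_k)
  seqs <- canonicalize_seq(transcriptome)
  kmers <- list(); txi <- list(); pos <- list()
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[[i]])
    if (L < seed_k) next
    st <- seq_len(L - seed_k + 1L)
    kmers[[i]] <- substring(seqs[[i]], st, st + seed_k - 1L)
    txi[[i]] <- rep.int(i, length(st))
    pos[[i]] <- st
  }
  km <- unlist(kmers); tx <- unlist(txi); ps <- unlist(pos)
  o <- order(km)
  structure(list(
    ids = ids, seqs = unname(seqs), seed_k = seed_k,
    lookup = split(data.frame(tx = tx[o], pos = ps[o]), km[o])
  ), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: %d transcripts, k = %d, %d distinct k-mers\n",
              length(x$ids), x$seed_k, length(x$lookup)))
  invisible(x)
}

# Hamming distance between a read and the transcript window starting at p,
# capped at cap + 1 (N counts as mismatch).
count_mismatches <- function(read, txseq, p, cap) {
  w <- substr(txseq, p, p + nchar(read) - 1L)
  if (nchar(w) < nchar(read)) return(cap + 1L)
  if (read == w) return(0L)
  sum(strsplit(read, "", fixed = TRUE)[[1]] !=
      strsplit(w, "", fixed = TRUE)[[1]])
}

#' Align one read to all placements in the transcriptome
#'
#' Reports every sense-strand placement with at most `max_mismatches`
#' mismatches, across all transcripts. There is no best-hit selection:
#' a cut-site read shared by several gene-family members is reported on
#' every member. Hits are ordered by transcript id then position.
#'
#' @param read read sequence (character scalar).
#' @param index a [build_index()] object.
#' @param max_mismatches mismatch budget (default 1 for degradome reads;
#'   use 0 for sRNA alignment in the phasing stage).
#' @param count read multiplicity attached to each hit.
#' @param strand `"+"` aligns the read as given (degradome reads are
#'   sense-strand by construction); `"both"` additionally aligns the
#'   reverse complement and reports those hits with `strand = "-"`.
#' @return data.frame with columns `read_seq`, `transcript_id`, `pos`
#'   (1-based position of the placement's leftmost transcript base),
#'   `strand`, `mismatches`, `count`.
#' @export
align_read <- function(read, index, max_mismatches = 1L, count = 1L,
                       strand = c("+", "both")) {
  strand <- match.arg(strand)
  read <- canonicalize_seq(read)
  hits <- align_read_one_strand(read, index, max_mismatches, count, "+")
  if (strand == "both") {
    rc <- reverse_complement(read)
    hits <- rbind(hits,
                  align_read_one_strand(rc, index, max_mismatches, count, "-",
                                        report_seq = read))
  }
  hits <- hits[order(hits$transcript_id, hits$pos, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

align_read_one_strand <- function(read, index, max_mismatches, count,
                                  strand, report_seq = read) {
  empty <- data.frame(read_seq = character(), transcript_id = character(),
                      pos = integer(), strand = character(),
                      mismatches = integer(), count = integer(),
                      stringsAsFactors = FALSE)
  L <- nchar(read)
  k <- index$seed_k
  if (L < k) return(empty)
  n_seeds <- max_mismatches + 1L
  cand_tx <- integer(); cand_pos <- integer()
  if (L %/% k < n_seeds) {
    # read too short for pigeonhole seeding at this k: enumerate every
    # window of every transcript as a candidate (exact, rarely triggered)
    for (t in seq_along(index$seqs)) {
      nw <- nchar(index$seqs[[t]]) - L + 1L
      if (nw < 1L) next
      cand_tx <- c(cand_tx, rep.int(t, nw))
      cand_pos <- c(cand_pos, seq_len(nw))
    }
  } else {
    # pigeonhole: with <= m mismatches one of m+1 disjoint seeds is exact
    offs <- 1L + (seq_len(n_seeds) - 1L) * k
    for (off in offs) {
      seed <- substr(read, off, off + k - 1L)
      occ <- index$lookup[[seed]]
      if (is.null(occ)) next
      start <- occ$pos - off + 1L
      ok <- start >= 1L
      cand_tx <- c(cand_tx, occ$tx[ok])
      cand_pos <- c(cand_pos, start[ok])
    }
  }
  if (!length(cand_tx)) return(empty)
  key <- !duplicated(paste(cand_tx, cand_pos))
  cand_tx <- cand_tx[key]; cand_pos <- cand_pos[key]
  mm <- mapply(function(t, p) count_mismatches(read, index$seqs[[t]], p,
                                               max_mismatches),
               cand_tx, cand_pos)
  ok <- mm <= max_mismatches
  if (!any(ok)) return(empty)
  data.frame(read_seq = report_seq, transcript_id = index$ids[cand_tx[ok]],
             pos = cand_pos[ok], strand = strand,
             mismatches = as.integer(mm[ok]), count = as.integer(count),
             stringsAsFactors = FALSE)
}

#' Align a read set to the transcriptome
#'
#' Aligns every read at every placement within the mismatch budget. The
#' mapped-read total counts each read once regardless of how many places
#' it maps to; it is the reads-per-million denominator.
#'
#' @param rs a [read_set()].
#' @param index a [build_index()] object.
#' @inheritParams align_read
#' @return a list of class `alignment_set` with elements `hits` (one
#'   data.frame as in [align_read()], all reads pooled), `mapped_total`
#'   (reads with at least one placement, counting multiplicity), and
#'   `source_label`.
#' @export
align_all <- function(rs, index, max_mismatches = 1L, strand = c("+", "both")) {
  strand <- match.arg(strand)
  pieces <- vector("list", nrow(rs$reads))
  mapped <- 0L
  for (i in seq_len(nrow(rs$reads))) {
    h <- align_read(rs$reads$seq[i], index, max_mismatches,
                    count = rs$reads$count[i], strand = strand)
    if (nrow(h)) mapped <- mapped + rs$reads$count[i]
    pieces[[i]] <- h
  }
  hits <- do.call(rbind, pieces)
  if (is.null(hits)) hits <- align_read("A", index, -1L)  # empty frame shape
  hits <- hits[order(hits$transcript_id, hits$pos), , drop = FALSE]
  rownames(hits) <- NULL
  structure(list(hits = hits, mapped_total = mapped,
                 source_label = rs$source_label),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("alignment_set '%s': %d hits on %d transcripts, mapped total %d\n",
              x$source_label, nrow(x$hits),
              length(unique(x$hits$transcript_id)), x$mapped_total))
  invisible(x)
}

#' Export hits as SAM
#'
#' Minimal single-end SAM: flag 0 (or 16 for minus-strand hits), MAPQ 255,
#' ungapped CIGAR, NM tag carrying the mismatch count. One line per
#' placement (multi-mapped reads repeat).
#'
#' @param aln an [align_all()] result.
#' @param index the [build_index()] used for alignment (for `@SQ` headers).
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, index, path) {
  hd <- c("@HD\tVN:1.6\tSO:unsorted",
          sprintf("@SQ\tSN:%s\tLN:%d", index$ids, nchar(index$seqs)))
  h <- aln$hits
  body <- if (nrow(h)) {
    seq_out <- ifelse(h$strand == "-", reverse_complement(h$read_seq),
                      h$read_seq)
    sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
            paste0("r", seq_len(nrow(h))),
            ifelse(h$strand == "-", 16L, 0L),
            h$transcript_id, h$pos, nchar(h$read_seq), seq_out, h$mismatches)
  } else character()
  writeLines(c(hd, body), path)
  invisible(path)
}
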