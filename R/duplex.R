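#' Small RNA collection
#'
#' Mature miRNAs or secondary siRNAs with abundances. Counts can come from
#' `_xN` FASTA headers or a two-column TSV; RPM is computed against the
#' sRNA library total.
#'
#' @param id character vector of small RNA ids.
#' @param seq sequences (18-24 nt typical), canonicalized to DNA alphabet.
#' @param count abundances (reads).
#' @param library_total sRNA library total used as the RPM denominator;
#'   default `sum(count)`.
#' @return data.frame of class `small_rna_set` with columns `id`, `seq`,
#'   `count`, `rpm` and attribute `library_total`.
#' @export
small_rna_set <- function(id, seq, count = rep(1L, length(seq)),
                          library_total = sum(count)) {
  stopifnot(length(id) == length(seq), length(seq) == length(count))
  out <- data.frame(id = as.character(id), seq = canonicalize_seq(seq),
                    count = as.numeric(count),
                    stringsAsFactors = FALSE)
  out$rpm <- rpm(out$count, library_total)
  attr(out, "library_total") <- library_total
  class(out) <- c("small_rna_set", "data.frame")
  out
}

#' Read mature small RNAs with abundances
#'
#' FASTA headers of the form `name_xN` carry the read count N; otherwise
#' counts default to 1. Alternatively a two-column TSV (id, count) can
#' accompany the FASTA.
#'
#' @param path FASTA of mature sequences.
#' @param abundance_tsv optional TSV with columns id and count (no header).
#' @param library_total RPM denominator; defaults to the summed counts.
#' @return a [small_rna_set()].
#' @export
read_small_rnas <- function(path, abundance_tsv = NULL, library_total = NULL) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  counts <- rep(1, length(ss))
  has_x <- grepl("_x[0-9]+$", ids)
  counts[has_x] <- as.numeric(sub(".*_x([0-9]+)$", "\\1", ids[has_x]))
  ids[has_x] <- sub("_x[0-9]+$", "", ids[has_x])
  if (!is.null(abundance_tsv)) {
    ab <- utils::read.table(abundance_tsv, sep = "\t", header = FALSE,
                            col.names = c("id", "count"),
                            stringsAsFactors = FALSE)
    m <- match(ids, ab$id)
    counts[!is.na(m)] <- ab$count[m[!is.na(m)]]
  }
  small_rna_set(ids, as.character(ss), counts,
                library_total = library_total %||% sum(counts))
}

#' Allen complementarity score of a pairing
#'
#' Additive penalty over miRNA positions: Watson-Crick 0, G:U wobble 0.5,
#' mismatch 1.0, each bulged nucleotide on either strand 1.0. Penalties
#' are doubled in the seed-proximal region (miRNA positions 2-13, counting
#' position 1 as the miRNA 5' end). A bulged target nucleotide takes the
#' multiplier of the miRNA position whose slot it sits in (the next
#' paired/bulged miRNA position).
#'
#' @param pairing pairing string over `|`, `o`, `x`, `-`, `^` (see
#'   [enumerate_duplexes()]).
#' @param scoring an [allen_params()] object.
#' @return non-negative score (half-integer granularity at the defaults).
#' @export
allen_score <- function(pairing, scoring = allen_params()) {
  sym <- strsplit(pairing, "", fixed = TRUE)[[1]]
  # miRNA slot of each symbol: target bulges take the following position
  slot <- cumsum(sym != "^")
  slot[sym == "^"] <- slot[sym == "^"] + 1L
  pen <- c("|" = 0, o = scoring$gu, x = scoring$mm,
           "-" = scoring$bulge, "^" = scoring$bulge)[sym]
  mult <- ifelse(slot >= scoring$double_lo & slot <= scoring$double_hi,
                 scoring$double_mult, 1)
  sum(pen * mult)
}

#' Allen scoring constants
#'
#' @param mm mismatch penalty.
#' @param gu G:U wobble penalty.
#' @param bulge penalty per bulged nucleotide (either strand).
#' @param double_lo,double_hi miRNA position window in which penalties are
#'   doubled (position 1 = miRNA 5' end).
#' @param double_mult multiplier applied inside the window.
#' @return list of class `allen_params`.
#' @export
allen_params <- function(mm = 1, gu = 0.5, bulge = 1,
                         double_lo = 2L, double_hi = 13L, double_mult = 2) {
  structure(list(mm = mm, gu = gu, bulge = bulge,
                 double_lo = as.integer(double_lo),
                 double_hi = as.integer(double_hi),
                 double_mult = double_mult),
            class = "allen_params")
}

#' Enumerate candidate miRNA target duplexes on a transcript
#'
#' Exhaustively aligns the small RNA antiparallel against every transcript
#' window, allowing up to `max_bulges` bulged nucleotides on either strand
#' (never at the slicing-center miRNA positions 10-11), and reports every
#' site whose Allen score is at most `max_allen` and whose minimum free
#' energy ratio is at least `min_mfe_ratio`. Overlapping candidate windows
#' are reduced to the locally best site: minimum Allen score, ties broken
#' by maximum MFE ratio, then leftmost start.
#'
#' Pairing strings read along the miRNA 5' to 3': `|` Watson-Crick pair,
#' `o` G:U wobble, `x` mismatch, `-` bulged miRNA nucleotide, `^` bulged
#' target nucleotide. The predicted cleavage coordinate is the transcript
#' position paired with miRNA position 10 — the expected 5' end of the
#' degradome read from the 3' cleavage fragment.
#'
#' @param mirna_id,mirna_seq small RNA id and sequence (5' to 3').
#' @param transcript_id,transcript_seq target transcript id and sequence.
#' @param max_allen maximum reported Allen score.
#' @param min_mfe_ratio minimum reported MFE ratio.
#' @param max_bulges maximum total bulged nucleotides per duplex.
#' @param scoring an [allen_params()] object.
#' @param params an [energy_params()] object.
#' @param mfe_fun optional hook `function(mirna_seq, pairing, site_seq)`
#'   returning an externally computed duplex energy (kcal/mol); defaults
#'   to the internal nearest-neighbor model.
#' @param reduce_overlaps collapse overlapping candidate windows to the
#'   locally best site (default TRUE).
#' @return data.frame with columns `mirna_id`, `transcript_id`,
#'   `site_start`, `site_end`, `pairing`, `allen_score`, `mfe`,
#'   `mfe_perfect`, `mfe_ratio`, `cleavage_pos`.
#' @export
enumerate_duplexes <- function(mirna_id, mirna_seq, transcript_id,
                               transcript_seq,
                               max_allen = 5, min_mfe_ratio = 0.5,
                               max_bulges = 2L,
                               scoring = allen_params(),
                               params = energy_params(),
                               mfe_fun = NULL,
                               reduce_overlaps = TRUE) {
  mirna_seq <- canonicalize_seq(mirna_seq)
  transcript_seq <- canonicalize_seq(transcript_seq)
  if (nchar(transcript_seq) <= nchar(mirna_seq))
    stop("transcript must be longer than the small RNA")
  cand <- .scan_duplexes_cpp(
    encode_seq(transcript_seq), encode_seq(mirna_seq),
    max_allen, scoring$mm, scoring$gu, scoring$bulge,
    scoring$double_lo, scoring$double_hi, scoring$double_mult,
    as.integer(max_bulges), 10L, 11L, 10L)
  empty <- data.frame(mirna_id = character(), transcript_id = character(),
                      site_start = integer(), site_end = integer(),
                      pairing = character(), allen_score = numeric(),
                      mfe = numeric(), mfe_perfect = numeric(),
                      mfe_ratio = numeric(), cleavage_pos = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(cand)) return(empty)
  mfe_perf <- perfect_mfe(mirna_seq, params)
  mfe <- if (is.null(mfe_fun)) {
    vapply(cand$pairing, function(p) duplex_mfe(mirna_seq, p, params),
           numeric(1), USE.NAMES = FALSE)
  } else {
    site_seq <- substring(transcript_seq, cand$site_start, cand$site_end)
    mapply(mfe_fun, mirna_seq, cand$pairing, site_seq, USE.NAMES = FALSE)
  }
  ratio <- mfe / mfe_perf
  keep <- mfe < 0 & ratio >= min_mfe_ratio
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  mfe <- mfe[keep]; ratio <- ratio[keep]
  out <- data.frame(mirna_id = mirna_id, transcript_id = transcript_id,
                    site_start = cand$site_start, site_end = cand$site_end,
                    pairing = cand$pairing, allen_score = cand$allen_score,
                    mfe = mfe, mfe_perfect = mfe_perf, mfe_ratio = ratio,
                    cleavage_pos = cand$cleavage_pos,
                    stringsAsFactors = FALSE)
  if (reduce_overlaps) out <- reduce_overlapping_sites(out)
  rownames(out) <- NULL
  out
}

# Collapse overlapping candidate windows to the locally best duplex:
# min Allen, ties -> max mfe_ratio, ties -> leftmost, then shortest.
reduce_overlapping_sites <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  o <- order(hits$site_start, hits$site_end)
  hits <- hits[o, , drop = FALSE]
  cluster <- integer(nrow(hits))
  cl <- 1L; max_end <- hits$site_end[1]
  cluster[1] <- 1L
  for (i in seq_len(nrow(hits))[-1]) {
    if (hits$site_start[i] > max_end) { cl <- cl + 1L; max_end <- hits$site_end[i] }
    else max_end <- max(max_end, hits$site_end[i])
    cluster[i] <- cl
  }
  best <- unlist(lapply(split(seq_len(nrow(hits)), cluster), function(ix) {
    h <- hits[ix, , drop = FALSE]
    ix[order(h$allen_score, -h$mfe_ratio, h$site_start,
             h$site_end - h$site_start)[1]]
  }))
  out <- hits[sort(best), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predicted cleavage coordinate of a duplex hit
#'
#' @param hit one row of an [enumerate_duplexes()] result.
#' @return 1-based transcript coordinate paired with miRNA position 10.
#' @export
cleavage_position <- function(hit) hit$cleavage_pos

#' Enumerate duplexes for a small RNA set against a transcriptome
#'
#' @param srnas a [small_rna_set()].
#' @param transcriptome named character vector of transcript sequences.
#' @param ... passed to [enumerate_duplexes()].
#' @return row-bound data.frame of hits over all (small RNA, transcript)
#'   pairs.
#' @export
predict_targets <- function(srnas, transcriptome, ...) {
  pieces <- list()
  for (i in seq_len(nrow(srnas))) {
    for (j in seq_along(transcriptome)) {
      if (nchar(transcriptome[[j]]) <= nchar(srnas$seq[i])) next
      h <- enumerate_duplexes(srnas$id[i], srnas$seq[i],
                              names(transcriptome)[j], transcriptome[[j]],
                              ...)
      if (nrow(h)) {
        h$mirna_seq <- srnas$seq[i]
        h$mirna_rpm <- srnas$rpm[i]
        pieces[[length(pieces) + 1L]] <- h
      }
    }
  }
  if (!length(pieces))
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      site_start = integer(), site_end = integer(),
                      pairing = character(), allen_score = numeric(),
                      mfe = numeric(), mfe_perfect = numeric(),
                      mfe_ratio = numeric(), cleavage_pos = integer(),
                      mirna_seq = character(), mirna_rpm = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
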