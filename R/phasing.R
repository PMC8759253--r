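#' Scan a transcript for phased siRNA registers
#'
#' Tests, downstream of a cleavage anchor, whether 21-nt sRNA 5' ends fall
#' preferentially on one of the 21 possible phase registers. Reads must be
#' aligned with zero mismatches; only 21-nt reads enter the lattice test.
#' Minus-strand reads are brought onto the plus-strand lattice with the
#' 2-nt 3'-overhang correction of the dicing duplex (their leftmost
#' transcript coordinate is shifted by `minus_offset` before the modulus
#' test).
#'
#' For register `r` (0-20) the lattice is the set of window positions `p`
#' with `(p + offset - anchor - 1 - r) mod phase = 0`. `occupied` is the
#' set of distinct corrected 5'-end positions in the window with summed
#' abundance at least `min_abundance`; `phased` is its intersection with
#' the lattice. Significance is the hypergeometric tail
#' [phasing_pvalue()].
#'
#' @param hits data.frame of sRNA hits on one transcript (columns
#'   `pos`, `strand`, `count`, `read_seq` as from [align_read()]).
#' @param anchor cleavage anchor coordinate (typically a degradome-
#'   validated cleavage position of the triggering miRNA); the window
#'   starts at `anchor + 1`.
#' @param transcript_length length of the transcript (for bounds checks).
#' @param phase phase length in nt (21).
#' @param span window length L in nt (default 189 = 9 cycles).
#' @param min_abundance minimum summed abundance for a position to count
#'   as occupied.
#' @param minus_offset minus-strand lattice correction in nt (default 2).
#' @return data.frame of class `phasing_scan`, one row per register:
#'   `transcript_id`, `anchor`, `register`, `span`, `m` (lattice
#'   positions), `n` (occupied), `k` (phased), `p_value`; attribute
#'   `positions` holds the per-register occupied/phased position sets.
#' @export
phase_scan <- function(hits, anchor, transcript_length,
                       phase = 21L, span = 189L, min_abundance = 1,
                       minus_offset = 2L) {
  if (anchor < 0 || anchor >= transcript_length)
    stop("anchor outside transcript")
  tid <- if (nrow(hits)) unique(hits$transcript_id)[1] else NA_character_
  is21 <- nchar(hits$read_seq) == phase
  h <- hits[is21, , drop = FALSE]
  corr <- h$pos + ifelse(h$strand == "-", minus_offset, 0L)
  lo <- anchor + 1L
  hi <- min(anchor + span, transcript_length)
  L <- hi - lo + 1L
  inw <- corr >= lo & corr <= hi
  h <- h[inw, , drop = FALSE]; corr <- corr[inw]
  ab <- if (nrow(h)) rowsum(h$count, corr) else
    matrix(numeric(), 0, 1)
  occ <- as.integer(rownames(ab))[ab[, 1] >= min_abundance]
  registers <- 0:(phase - 1L)
  pos_sets <- vector("list", length(registers))
  rows <- lapply(registers, function(r) {
    lattice <- if (lo + r > hi) integer() else
      seq.int(lo + r, hi, by = phase)
    phased <- intersect(occ, lattice)
    pos_sets[[r + 1L]] <<- list(occupied = occ, phased = phased,
                                lattice = lattice)
    data.frame(transcript_id = tid, anchor = anchor, register = r,
               span = L, m = length(lattice), n = length(occ),
               k = length(phased),
               p_value = phasing_pvalue(L, length(lattice), length(occ),
                                        length(phased)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "positions") <- pos_sets
  class(out) <- c("phasing_scan", "data.frame")
  out
}

#' Hypergeometric phasing p-value
#'
#' Probability that at least `k` of `n` occupied positions fall on the
#' `m` lattice positions of a window of length `L`, if occupancy were
#' uniform: the hypergeometric tail
#' \deqn{P(X \ge k) = \sum_{x=k}^{\min(n,m)} \binom{m}{x}
#'   \binom{L-m}{n-x} / \binom{L}{n}.}
#'
#' @param L window length (positions).
#' @param m lattice (in-phase) positions in the window.
#' @param n occupied positions.
#' @param k phased (occupied and in-phase) positions.
#' @return the tail probability in `[0, 1]`.
#' @export
phasing_pvalue <- function(L, m, n, k) {
  if (k > min(n, m) || n > L || m > L || k < 0 || min(L, m, n) < 0)
    stop("invalid phasing counts: need k <= min(n, m) and n, m <= L")
  if (k == 0) return(1)
  stats::phyper(k - 1, m, L - m, n, lower.tail = FALSE)
}

#' Cycle label of a phased read
#'
#' Names a phased read by its 21-nt cycle downstream of the cut site:
#' D1 is the first full cycle starting at `anchor + 1 + register`. Minus-
#' strand reads are labelled with the cycle of the duplex they complement
#' (2-nt 3'-overhang correction applied to their leftmost coordinate).
#'
#' @param position leftmost transcript coordinate of the read.
#' @param strand `"+"` or `"-"`.
#' @param anchor cleavage anchor.
#' @param register phase register (0-20).
#' @param phase phase length (21).
#' @param minus_offset minus-strand correction (2).
#' @return character label such as `"D8(-)"`; `NA` if the position is off
#'   the register lattice.
#' @export
name_phased <- function(position, strand, anchor, register,
                        phase = 21L, minus_offset = 2L) {
  corr <- position + ifelse(strand == "-", minus_offset, 0L)
  off <- corr - anchor - 1L - register
  n <- off / phase + 1
  ifelse(off %% phase == 0 & off >= 0,
         sprintf("D%d(%s)", as.integer(n), strand), NA_character_)
}

#' Extract phased secondary siRNAs from significant windows
#'
#' Collects the phased 21-nt reads of every register with p at most
#' `p_cutoff`, labels them by cycle, and packages them as a
#' [small_rna_set()] ready for duplex scoring; abundances carry through.
#'
#' @param scan a [phase_scan()] result.
#' @param hits the sRNA hit data.frame the scan was built from.
#' @param p_cutoff significance cutoff (default 0.01).
#' @param phase,minus_offset as in [phase_scan()].
#' @param library_total sRNA library total for RPM; default sum of counts.
#' @return a [small_rna_set()] of phased reads (ids
#'   `<transcript>_r<register>_D<cycle>(<strand>)`); zero rows when no
#'   window is significant.
#' @export
extract_secondary <- function(scan, hits, p_cutoff = 0.01,
                              phase = 21L, minus_offset = 2L,
                              library_total = NULL) {
  sig <- scan[scan$p_value <= p_cutoff, , drop = FALSE]
  pos_sets <- attr(scan, "positions")
  rows <- list()
  for (i in seq_len(nrow(sig))) {
    r <- sig$register[i]
    ph <- pos_sets[[r + 1L]]$phased
    if (!length(ph)) next
    is21 <- nchar(hits$read_seq) == phase
    h <- hits[is21, , drop = FALSE]
    corr <- h$pos + ifelse(h$strand == "-", minus_offset, 0L)
    sel <- h[corr %in% ph, , drop = FALSE]
    if (!nrow(sel)) next
    lab <- name_phased(sel$pos, sel$strand, sig$anchor[i], r,
                       phase, minus_offset)
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("%s_r%d_%s", sig$transcript_id[i], r, lab),
      seq = sel$read_seq, count = sel$count, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(small_rna_set(character(), character(), numeric(),
                         library_total = library_total %||% 1))
  d <- do.call(rbind, rows)
  d <- d[!duplicated(d$id), , drop = FALSE]
  small_rna_set(d$id, d$seq, d$count,
                library_total = library_total %||% sum(d$count))
}

#' Validate secondary siRNA targets
#'
#' Runs phased secondary siRNAs through duplex scoring and degradome
#' validation with the stringent cut-offs (Allen score at most 4, MFE
#' ratio at least 0.69), tagging the records as secondary. Secondary
#' siRNAs routinely re-target their parent transcript and its family
#' members; all qualifying records are kept.
#'
#' @param secondary a [small_rna_set()] of phased siRNAs.
#' @param transcriptome named character vector of transcript sequences.
#' @param profiles named list of degradome profiles.
#' @param allen_max,mfe_ratio_min,mirna_rpm_min stringent thresholds.
#' @param window cut-site matching window.
#' @param sample_label sample tag.
#' @param ... further arguments to [predict_targets()].
#' @return filtered record data.frame with `tier` and `origin =
#'   "secondary"`.
#' @export
validate_secondary <- function(secondary, transcriptome, profiles,
                               allen_max = 4, mfe_ratio_min = 0.69,
                               mirna_rpm_min = 0, window = 1L,
                               sample_label = "sample", ...) {
  hits <- predict_targets(secondary, transcriptome,
                          max_allen = allen_max,
                          min_mfe_ratio = mfe_ratio_min, ...)
  recs <- validate_targets(hits, profiles, window = window,
                           sample_label = sample_label)
  out <- apply_filters(recs, allen_max = allen_max,
                       mfe_ratio_min = mfe_ratio_min,
                       mirna_rpm_min = mirna_rpm_min,
                       allen_report_max = allen_max)
  if (nrow(out)) out$origin <- "secondary"
  else out$origin <- character()
  out
}
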