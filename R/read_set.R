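#' Read sets
#'
#' A `read_set` holds a small RNA or degradome read library as a table of
#' sequences with multiplicities, together with the library label and the
#' raw input read count. Sequences are stored on the canonical DNA alphabet
#' (U converted to T); duplicate sequences may be collapsed with
#' [collapse_reads()], which sums their counts.
#'
#' @param seq character vector of read sequences.
#' @param count integer vector of read multiplicities (default all 1).
#' @param source_label single string naming the library.
#' @param total_raw total number of raw input reads this set derives from;
#'   defaults to `sum(count)`.
#' @return an object of class `read_set`: a list with elements `reads`
#'   (data.frame with columns `seq`, `count`), `source_label`, `total_raw`.
#' @export
read_set <- function(seq = character(), count = rep(1L, length(seq)),
                     source_label = "library", total_raw = sum(count)) {
  stopifnot(length(seq) == length(count))
  count <- as.integer(count)
  if (length(count) && any(count < 1L)) stop("read counts must be >= 1")
  if (length(seq) && any(!nzchar(seq))) stop("read sequences must be non-empty")
  structure(list(
    reads = data.frame(seq = canonicalize_seq(as.character(seq)),
                       count = count, stringsAsFactors = FALSE),
    source_label = source_label,
    total_raw = as.integer(total_raw)
  ), class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set '%s': %d distinct sequences, %d reads (raw input %d)\n",
              x$source_label, nrow(x$reads), sum(x$reads$count), x$total_raw))
  invisible(x)
}

#' Total read count of a read set
#' @param rs a [read_set()].
#' @return integer, the sum of sequence multiplicities.
#' @export
n_reads <- function(rs) sum(rs$reads$count)

#' Read sequences from FASTA or FASTQ
#'
#' Parses one record per entry (duplicates are not collapsed), canonicalizes
#' U to T, and retains `N`. FASTQ qualities are read and discarded; no
#' quality trimming is performed. A header suffix `_xN` is interpreted as a
#' pre-collapsed read count of N.
#'
#' @param path input file.
#' @param format `"fasta"` or `"fastq"`; default guessed from the extension.
#' @param source_label library label; defaults to the file name.
#' @return a [read_set()] with one entry per record and
#'   `total_raw` = total read count.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           source_label = basename(path)) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  ss <- Biostrings::readBStringSet(path, format = format)
  seqs <- canonicalize_seq(as.character(ss))
  ids <- names(ss) %||% character(length(ss))
  counts <- rep(1L, length(seqs))
  m <- regmatches(ids, regexpr("_x([0-9]+)\\b", ids))
  has_x <- grepl("_x[0-9]+\\b", ids)
  counts[has_x] <- as.integer(sub(".*_x([0-9]+)\\b.*", "\\1", ids[has_x]))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop(sprintf("record %d: sequence contains non-nucleotide characters",
                             which(bad)[1]))
  names(seqs) <- NULL
  read_set(seqs, counts, source_label = source_label,
           total_raw = sum(counts))
}

#' Collapse identical read sequences
#'
#' Sums the counts of identical sequences; `total_raw` is unchanged, so the
#' multiset of reads is conserved.
#'
#' @param rs a [read_set()].
#' @return a [read_set()] with unique sequences.
#' @export
collapse_reads <- function(rs) {
  if (!nrow(rs$reads)) return(rs)
  agg <- rowsum(rs$reads$count, rs$reads$seq)
  out <- read_set(rownames(agg), as.integer(agg[, 1]),
                  source_label = rs$source_label, total_raw = rs$total_raw)
  out$reads <- out$reads[order(out$reads$seq), , drop = FALSE]
  rownames(out$reads) <- NULL
  out
}

#' Write a collapsed read set as FASTA
#'
#' Headers carry the read count in the conventional `id_xN` form.
#'
#' @param rs a [read_set()] (collapsed first if necessary).
#' @param path output FASTA path.
#' @param prefix header prefix before the running index.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(rs, path, prefix = "read") {
  rs <- collapse_reads(rs)
  lines <- character(2L * nrow(rs$reads))
  if (nrow(rs$reads)) {
    lines[c(TRUE, FALSE)] <- sprintf(">%s%d_x%d", prefix,
                                     seq_len(nrow(rs$reads)), rs$reads$count)
    lines[c(FALSE, TRUE)] <- rs$reads$seq
  }
  writeLines(lines, path)
  invisible(path)
}
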