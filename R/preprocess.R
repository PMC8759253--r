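#' Preprocessing configuration
#'
#' Bundles the degradome / sRNA read-cleaning parameters: the 3' adapter
#' sequence, the minimum number of leading adapter bases that must match
#' (exactly) for a trim, and the retained length window. Defaults follow
#' the standard PARE protocol: MmeI releases ~20-21 nt tags, so the
#' degradome window is 20-21 nt; sRNA libraries use 20-24 nt.
#'
#' @param adapter 3' adapter sequence.
#' @param min_adapter_overlap minimum exact match of leading adapter bases.
#' @param min_len,max_len retained read length window.
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(adapter = "TGGAATTCTCGGGTGCCAAGGAA",
                              min_adapter_overlap = 6L,
                              min_len = 20L, max_len = 21L) {
  stopifnot(nzchar(adapter), min_adapter_overlap >= 1L, min_len <= max_len)
  structure(list(adapter = canonicalize_seq(adapter),
                 min_adapter_overlap = as.integer(min_adapter_overlap),
                 min_len = as.integer(min_len), max_len = as.integer(max_len)),
            class = "preprocess_config")
}

# Leftmost start of a 3' adapter match in one read: either a full internal
# occurrence of the adapter, or a read suffix equal to a leading piece of
# the adapter of length >= min_overlap. Exact matching only. Returns the
# 1-based position of the first adapter base, or NA if the adapter was
# never reached.
find_adapter_start <- function(seq, adapter, min_overlap) {
  L <- nchar(seq); A <- nchar(adapter)
  full <- regexpr(adapter, seq, fixed = TRUE)
  cand <- if (full > 0) as.integer(full) else NA_integer_
  # suffix-anchored partial match cannot start before L - A + 1 would allow
  # a full match; scan starts that leave overlap >= min_overlap
  first <- max(1L, L - A + 2L)
  for (j in seq.int(first, max(first, L - min_overlap + 1L))) {
    if (j > L) break
    ov <- L - j + 1L
    if (ov < min_overlap) break
    if (substr(seq, j, L) == substr(adapter, 1L, ov)) {
      cand <- min(cand, j, na.rm = TRUE)
      break
    }
  }
  if (is.na(cand) || cand > L) NA_integer_ else cand
}

#' Trim the 3' adapter from every read
#'
#' Locates, for each read, the leftmost exact occurrence of the adapter --
#' either the full adapter internally or at least `min_adapter_overlap`
#' leading adapter bases as a read suffix -- and truncates the read before
#' it. Reads in which no such match exists never reached the adapter and
#' are discarded (the insert ran past the read length). Reads whose insert
#' is empty (adapter at position 1) are likewise discarded.
#'
#' @param rs a [read_set()].
#' @param cfg a [preprocess_config()].
#' @return a trimmed [read_set()].
#' @export
trim_adapter <- function(rs, cfg = preprocess_config()) {
  if (!nrow(rs$reads)) return(rs)
  starts <- vapply(rs$reads$seq, find_adapter_start, integer(1),
                   adapter = cfg$adapter,
                   min_overlap = cfg$min_adapter_overlap,
                   USE.NAMES = FALSE)
  keep <- !is.na(starts) & starts > 1L
  out <- rs
  out$reads <- data.frame(
    seq = substr(rs$reads$seq[keep], 1L, starts[keep] - 1L),
    count = rs$reads$count[keep], stringsAsFactors = FALSE)
  rownames(out$reads) <- NULL
  out
}

#' Remove reads matching contaminant sequences
#'
#' Drops reads that occur exactly, or as an exact substring, within any
#' contaminant sequence (typically tRNA/rRNA). Matching is on the given
#' strand only.
#'
#' @param rs a [read_set()].
#' @param contaminants character vector of contaminant sequences, or a
#'   FASTA path.
#' @return the filtered [read_set()].
#' @export
filter_contaminants <- function(rs, contaminants) {
  if (is.character(contaminants) && length(contaminants) == 1L &&
      file.exists(contaminants)) {
    contaminants <- as.character(Biostrings::readBStringSet(contaminants))
  }
  contaminants <- canonicalize_seq(as.character(contaminants))
  if (!length(contaminants) || !nrow(rs$reads)) return(rs)
  # '#' separator prevents substring matches from spanning contaminants
  bank <- paste(contaminants, collapse = "#")
  hit <- vapply(rs$reads$seq, function(s) grepl(s, bank, fixed = TRUE),
                logical(1), USE.NAMES = FALSE)
  out <- rs
  out$reads <- rs$reads[!hit, , drop = FALSE]
  rownames(out$reads) <- NULL
  out
}

#' Retain reads within a length window
#'
#' @param rs a [read_set()].
#' @param min_len,max_len inclusive length bounds.
#' @return the size-selected [read_set()].
#' @export
size_select <- function(rs, min_len = 20L, max_len = 21L) {
  stopifnot(min_len <= max_len)
  len <- nchar(rs$reads$seq)
  out <- rs
  out$reads <- rs$reads[len >= min_len & len <= max_len, , drop = FALSE]
  rownames(out$reads) <- NULL
  out
}

#' Discard reads containing N
#'
#' Ambiguous bases count as a mismatch at every alignment position, which
#' inflates multi-mapping; reads containing N after trimming are removed
#' before alignment.
#'
#' @param rs a [read_set()].
#' @return the filtered [read_set()].
#' @export
drop_ambiguous <- function(rs) {
  out <- rs
  out$reads <- rs$reads[!grepl("N", rs$reads$seq, fixed = TRUE), , drop = FALSE]
  rownames(out$reads) <- NULL
  out
}

#' Merge read libraries
#'
#' Pools several libraries (e.g. seedling, panicle and flag-leaf samples of
#' one species) into one set: counts of identical sequences are summed and
#' raw totals add. The operation is associative and commutative on
#' collapsed sets.
#'
#' @param ... [read_set()] objects, or a single list of them.
#' @param source_label label for the merged library.
#' @return a collapsed, merged [read_set()].
#' @export
merge_libraries <- function(..., source_label = "merged") {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "read_set")) sets <- sets[[1]]
  stopifnot(all(vapply(sets, inherits, logical(1), "read_set")))
  merged <- read_set(
    unlist(lapply(sets, function(s) s$reads$seq)),
    unlist(lapply(sets, function(s) s$reads$count)),
    source_label = source_label,
    total_raw = sum(vapply(sets, function(s) s$total_raw, integer(1))))
  collapse_reads(merged)
}

#' Run the full degradome read preprocessing
#'
#' Adapter trimming, optional contaminant (t/rRNA) removal, size selection
#' and removal of N-containing reads, with a per-stage read-count report.
#'
#' @param rs a [read_set()].
#' @param cfg a [preprocess_config()].
#' @param contaminants optional contaminant sequences or FASTA path.
#' @return a list with elements `reads` (the cleaned, collapsed
#'   [read_set()]) and `report` (data.frame of read counts after each
#'   stage).
#' @export
preprocess_reads <- function(rs, cfg = preprocess_config(),
                             contaminants = NULL) {
  stages <- c(input = n_reads(rs))
  rs <- trim_adapter(rs, cfg)
  stages["adapter_trimmed"] <- n_reads(rs)
  if (!is.null(contaminants)) {
    rs <- filter_contaminants(rs, contaminants)
  }
  stages["contaminant_filtered"] <- n_reads(rs)
  rs <- size_select(rs, cfg$min_len, cfg$max_len)
  stages["size_selected"] <- n_reads(rs)
  rs <- drop_ambiguous(rs)
  stages["ambiguity_filtered"] <- n_reads(rs)
  rs <- collapse_reads(rs)
  list(reads = rs,
       report = data.frame(library = rs$source_label,
                           stage = names(stages),
                           reads = as.integer(stages),
                           stringsAsFactors = FALSE))
}
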