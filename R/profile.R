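#' Build a degradome 5'-end profile for one transcript
#'
#' Tallies, for every transcript position, the number of degradome reads
#' whose 5' end falls there. Multi-mapped reads contribute their full count
#' at every placement.
#'
#' @param hits data.frame of hits on one transcript (as from
#'   [align_read()]); columns `pos` and `count` are used.
#' @param transcript_id transcript identifier; defaults to the (unique)
#'   `transcript_id` in `hits`.
#' @param library_mapped_total mapped-read total of the library (the RPM
#'   denominator).
#' @return an object of class `degradome_profile`: list with `transcript_id`,
#'   `counts` (named integer vector, names are positions, only occupied
#'   positions stored) and `library_mapped_total`.
#' @export
build_profile <- function(hits, transcript_id = NULL,
                          library_mapped_total = 0L) {
  if (is.null(transcript_id)) {
    transcript_id <- if (nrow(hits)) unique(hits$transcript_id) else NA_character_
    if (length(transcript_id) != 1L)
      stop("hits span more than one transcript; pass them per transcript")
  }
  counts <- integer()
  if (nrow(hits)) {
    agg <- rowsum(hits$count, hits$pos)
    counts <- as.integer(agg[, 1])
    names(counts) <- rownames(agg)
    counts <- counts[order(as.integer(names(counts)))]
  }
  structure(list(transcript_id = transcript_id, counts = counts,
                 library_mapped_total = as.integer(library_mapped_total)),
            class = "degradome_profile")
}

#' Build profiles for every transcript in an alignment set
#'
#' @param aln an [align_all()] result (sense-strand degradome hits).
#' @return named list of [build_profile()] objects, keyed by transcript id;
#'   each carries the set's `mapped_total` as the RPM denominator.
#' @export
build_profiles <- function(aln) {
  h <- aln$hits[aln$hits$strand == "+", , drop = FALSE]
  out <- lapply(split(h, h$transcript_id), build_profile,
                library_mapped_total = aln$mapped_total)
  out[order(names(out))]
}

#' @export
print.degradome_profile <- function(x, ...) {
  cat(sprintf("degradome_profile %s: %d occupied positions, max %s, total %d\n",
              x$transcript_id, length(x$counts),
              if (length(x$counts)) max(x$counts) else "-", sum(x$counts)))
  invisible(x)
}

#' Reads per million
#'
#' @param count raw read count (vectorized).
#' @param library_mapped_total mapped-read total of the library.
#' @return `count * 1e6 / library_mapped_total`; 0 where `count` is 0.
#' @export
rpm <- function(count, library_mapped_total) {
  out <- count * 1e6 / library_mapped_total
  out[count == 0] <- 0
  out
}

#' Classify occupied positions into cleavage categories
#'
#' CleaveLand-style categories on raw 5'-end counts, with the two maximum
#' classes (unique maximum, formerly category 0, and tied maximum,
#' formerly 1) merged into category 1:
#' \describe{
#'   \item{1}{more than one read, and the position carries the transcript
#'     maximum (unique or tied).}
#'   \item{2}{more than one read, count above the mean over occupied
#'     positions and below the maximum.}
#'   \item{3}{more than one read, count at or below the occupied mean.}
#'   \item{4}{exactly one read at the position.}
#' }
#' The occupied mean is the average of counts over positions with at least
#' one read. A count-1 position is category 4 even when it equals the
#' transcript maximum: the maximum classes require more than one read.
#'
#' @param profile a [build_profile()] object.
#' @param pos position(s) to classify; default all occupied positions.
#' @return integer vector of categories in `{1,2,3,4}`, named by position.
#' @export
classify_position <- function(profile, pos = NULL) {
  cnt <- profile$counts
  if (is.null(pos)) pos <- as.integer(names(cnt))
  idx <- match(as.character(pos), names(cnt))
  if (anyNA(idx)) stop("position ", pos[is.na(idx)][1],
                       " has no degradome read")
  mx <- max(cnt)
  mean_occ <- mean(cnt)
  x <- as.numeric(cnt[idx])
  out <- ifelse(x == 1, 4L,
         ifelse(x == mx, 1L,
         ifelse(x > mean_occ, 2L, 3L)))
  names(out) <- as.character(pos)
  out
}

#' Tabulate a profile with RPM and categories
#'
#' The T-plot data table: one row per occupied position with its raw count,
#' RPM and cleavage category.
#'
#' @param profile a [build_profile()] object.
#' @return data.frame with columns `transcript_id`, `pos`, `count`, `rpm`,
#'   `category`.
#' @export
profile_table <- function(profile) {
  if (!length(profile$counts))
    return(data.frame(transcript_id = character(), pos = integer(),
                      count = integer(), rpm = numeric(),
                      category = integer(), stringsAsFactors = FALSE))
  data.frame(
    transcript_id = profile$transcript_id,
    pos = as.integer(names(profile$counts)),
    count = as.integer(profile$counts),
    rpm = rpm(as.integer(profile$counts), profile$library_mapped_total),
    category = as.integer(classify_position(profile)),
    stringsAsFactors = FALSE, row.names = NULL)
}
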