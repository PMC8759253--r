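#' Join duplex predictions with degradome evidence
#'
#' A predicted duplex becomes a validated target record when a degradome
#' 5' end exists within `window` nucleotides of its predicted cleavage
#' coordinate. The matched position's raw count, RPM and cleavage category
#' attach to the record. Every qualifying record is kept: a miRNA with
#' valid sites on several transcripts yields one record per site, and a
#' cut-site read shared by paralogs yields one record per paralog. The
#' `collapse_to_best_mfe` compatibility switch instead keeps only the
#' single highest-MFE-ratio record per miRNA, reproducing the classic
#' CleaveLand behavior for regression comparison.
#'
#' @param hits data.frame from [predict_targets()] (or
#'   [enumerate_duplexes()] rows plus `mirna_rpm`).
#' @param profiles named list of [build_profile()] objects keyed by
#'   transcript id, built from the same transcriptome.
#' @param window cut-site matching half-width in nt (default 1; degradome
#'   5' ends wobble by a nucleotide).
#' @param sample_label label recorded on each record.
#' @param collapse_to_best_mfe compatibility mode: one record per miRNA,
#'   the one with the highest MFE ratio (ties: lowest Allen, first
#'   transcript).
#' @return data.frame of target records: `mirna_id`, `mirna_seq`,
#'   `transcript_id`, `cleavage_pos` (predicted), `matched_pos` (degradome
#'   position that validated it), `category`, `cut_count`, `cut_rpm`,
#'   `allen_score`, `mfe_ratio`, `mirna_rpm`, `sample_label`.
#' @export
validate_targets <- function(hits, profiles, window = 1L,
                             sample_label = "sample",
                             collapse_to_best_mfe = FALSE) {
  empty <- data.frame(mirna_id = character(), mirna_seq = character(),
                      transcript_id = character(), cleavage_pos = integer(),
                      matched_pos = integer(), category = integer(),
                      cut_count = integer(), cut_rpm = numeric(),
                      allen_score = numeric(), mfe_ratio = numeric(),
                      mirna_rpm = numeric(), sample_label = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(hits)) return(empty)
  recs <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    pr <- profiles[[hits$transcript_id[i]]]
    if (is.null(pr) || !length(pr$counts)) next
    pos <- as.integer(names(pr$counts))
    near <- which(abs(pos - hits$cleavage_pos[i]) <= window)
    if (!length(near)) next
    # strongest signal wins; ties to the position nearest the prediction
    cnt <- as.integer(pr$counts[near])
    pick <- near[order(-cnt, abs(pos[near] - hits$cleavage_pos[i]),
                       pos[near])[1]]
    p <- pos[pick]
    recs[[i]] <- data.frame(
      mirna_id = hits$mirna_id[i],
      mirna_seq = hits$mirna_seq[i] %||% NA_character_,
      transcript_id = hits$transcript_id[i],
      cleavage_pos = hits$cleavage_pos[i],
      matched_pos = p,
      category = as.integer(classify_position(pr, p)),
      cut_count = as.integer(pr$counts[as.character(p)]),
      cut_rpm = rpm(as.integer(pr$counts[as.character(p)]),
                    pr$library_mapped_total),
      allen_score = hits$allen_score[i],
      mfe_ratio = hits$mfe_ratio[i],
      mirna_rpm = hits$mirna_rpm[i] %||% NA_real_,
      sample_label = sample_label,
      stringsAsFactors = FALSE)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) return(empty)
  out <- do.call(rbind, recs)
  if (collapse_to_best_mfe) {
    out <- do.call(rbind, lapply(split(out, out$mirna_id), function(d) {
      d[order(-d$mfe_ratio, d$allen_score, d$transcript_id,
              d$cleavage_pos)[1], , drop = FALSE]
    }))
  }
  out <- out[order(out$mirna_id, out$transcript_id, out$cleavage_pos), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the stringent filter stack
#'
#' A record passes the stringent tier when its Allen score is at most
#' `allen_max`, its MFE ratio at least `mfe_ratio_min`, and the miRNA
#' abundance at least `mirna_rpm_min` RPM — all boundaries inclusive, so a
#' record at exactly (4, 0.69, 0.5) passes. Records failing only the Allen
#' cut but within `allen_report_max` are retained as the looser
#' "candidate" tier.
#'
#' @param records data.frame from [validate_targets()].
#' @param allen_max stringent Allen score ceiling.
#' @param mfe_ratio_min MFE ratio floor.
#' @param mirna_rpm_min miRNA abundance floor (RPM).
#' @param allen_report_max Allen ceiling for the candidate tier.
#' @return `records` with an added `tier` column (`"stringent"` or
#'   `"candidate"`), rows failing both tiers dropped.
#' @export
apply_filters <- function(records, allen_max = 4, mfe_ratio_min = 0.69,
                          mirna_rpm_min = 0.5, allen_report_max = 5) {
  ok_common <- records$mfe_ratio >= mfe_ratio_min &
    records$mirna_rpm >= mirna_rpm_min
  stringent <- ok_common & records$allen_score <= allen_max
  candidate <- ok_common & !stringent & records$allen_score <= allen_report_max
  out <- records[stringent | candidate, , drop = FALSE]
  out$tier <- ifelse(stringent[stringent | candidate], "stringent",
                     "candidate")
  rownames(out) <- NULL
  out
}

#' Compare validated target sets across samples
#'
#' Records are grouped into miRNA families by identical mature sequence
#' (after U/T canonicalization) and keyed on (family, transcript). A pair
#' is "common" when present, post-filter, in every compared sample;
#' otherwise it is unique to the samples that contain it. Per-sample
#' category counts are reported for stacked-bar style summaries.
#'
#' @param records_by_sample named list of filtered record data.frames
#'   (one per sample).
#' @return list of class `comparison_table`: `pairs` (one row per (family,
#'   transcript) with presence flags and per-sample category), `summary`
#'   (per sample and category: common and unique counts), `n_common`,
#'   `n_unique` (named per sample).
#' @export
compare_samples <- function(records_by_sample) {
  stopifnot(length(records_by_sample) >= 2L,
            !is.null(names(records_by_sample)))
  samples <- names(records_by_sample)
  keyed <- lapply(records_by_sample, function(d) {
    fam <- d$mirna_seq %||% d$mirna_id
    key <- paste(fam, d$transcript_id, sep = "\r")
    # one category per pair within a sample: keep the strongest cut site
    o <- order(key, -d$cut_count)
    d <- d[o, , drop = FALSE]; key <- key[o]
    d$._key <- key
    d[!duplicated(key), , drop = FALSE]
  })
  all_keys <- sort(unique(unlist(lapply(keyed, function(d) d$._key))))
  pres <- sapply(keyed, function(d) all_keys %in% d$._key)
  pres <- matrix(pres, nrow = length(all_keys),
                 dimnames = list(NULL, samples))
  cat_m <- sapply(keyed, function(d) {
    d$category[match(all_keys, d$._key)]
  })
  cat_m <- matrix(cat_m, nrow = length(all_keys),
                  dimnames = list(NULL, paste0("category_", samples)))
  common <- rowSums(pres) == length(samples)
  parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  pairs <- data.frame(family = parts[, 1], transcript_id = parts[, 2],
                      pres, cat_m, common = common,
                      stringsAsFactors = FALSE, check.names = FALSE)
  summ <- do.call(rbind, lapply(samples, function(s) {
    idx <- pres[, s]
    data.frame(sample = s,
               category = 1:4,
               common = vapply(1:4, function(k)
                 sum(idx & common & cat_m[, paste0("category_", s)] == k,
                     na.rm = TRUE), numeric(1)),
               unique = vapply(1:4, function(k)
                 sum(idx & !common & cat_m[, paste0("category_", s)] == k,
                     na.rm = TRUE), numeric(1)),
               stringsAsFactors = FALSE)
  }))
  structure(list(pairs = pairs, summary = summ,
                 n_common = sum(common),
                 n_unique = colSums(pres & !common)),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("comparison_table: %d pairs, %d common; unique: %s\n",
              nrow(x$pairs), x$n_common,
              paste(sprintf("%s=%d", names(x$n_unique), x$n_unique),
                    collapse = ", ")))
  invisible(x)
}

#' Write validated targets as TSV
#'
#' Column layout mirrors a per-target table: miRNA, locus, cut site, Allen
#' score, MFE ratio, category, abundances and tier.
#'
#' @param records data.frame from [validate_targets()] / [apply_filters()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_target_tsv <- function(records, path) {
  utils::write.table(format(records, digits = 6, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
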