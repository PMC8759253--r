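#' Run the degradome target-validation pipeline on one sample
#'
#' Convenience wrapper over the module functions: aligns the (already
#' preprocessed) degradome reads at every placement, builds per-transcript
#' cleavage profiles, enumerates candidate duplexes for every small RNA,
#' joins them with the degradome evidence and applies the filter stack.
#'
#' @param transcriptome named character vector of transcript sequences.
#' @param mirnas a [small_rna_set()].
#' @param degradome a [read_set()] of cleaned degradome reads.
#' @param config a [default_run_config()].
#' @param sample_label sample tag on the records.
#' @param index optional prebuilt [build_index()] (reused across samples).
#' @return list with `records` (filtered target records with `tier`),
#'   `all_records` (pre-filter), `profiles`, `alignment`, `hits`, `index`.
#' @export
degradome_pipeline <- function(transcriptome, mirnas, degradome,
                               config = default_run_config(),
                               sample_label = "sample", index = NULL) {
  if (is.null(index)) index <- build_index(transcriptome, config$seed_k)
  aln <- align_all(degradome, index,
                   max_mismatches = config$degradome_mismatches)
  profiles <- build_profiles(aln)
  hits <- predict_targets(mirnas, transcriptome,
                          max_allen = config$allen_report_max,
                          min_mfe_ratio = config$mfe_ratio_min,
                          max_bulges = config$max_bulges)
  all_records <- validate_targets(hits, profiles,
                                  window = config$cut_site_window,
                                  sample_label = sample_label)
  records <- apply_filters(all_records,
                           allen_max = config$allen_max,
                           mfe_ratio_min = config$mfe_ratio_min,
                           mirna_rpm_min = config$mirna_rpm_min,
                           allen_report_max = config$allen_report_max)
  list(records = records, all_records = all_records, profiles = profiles,
       alignment = aln, hits = hits, index = index)
}

#' Run the phasing and cascade-validation stage on one transcript
#'
#' Aligns the sRNA library (zero mismatches, both strands) to the anchor
#' transcript, scans all 21 phase registers, extracts the phased reads of
#' significant registers and validates their targets against the whole
#' transcriptome with the stringent cut-offs.
#'
#' @param transcriptome named character vector.
#' @param srna a [read_set()] of 20-24 nt sRNA reads.
#' @param transcript_id transcript to scan.
#' @param anchor cleavage anchor (e.g. a validated cleavage position of
#'   the triggering miRNA).
#' @param profiles degradome profiles for secondary-target validation.
#' @param config a [default_run_config()].
#' @param index optional prebuilt index.
#' @param sample_label sample tag.
#' @return list with `scan` (a [phase_scan()] table), `secondary` (the
#'   phased [small_rna_set()]), `cascade` (validated secondary-target
#'   records), `srna_hits`.
#' @export
phasing_pipeline <- function(transcriptome, srna, transcript_id, anchor,
                             profiles, config = default_run_config(),
                             index = NULL, sample_label = "sample") {
  if (is.null(index)) index <- build_index(transcriptome, config$seed_k)
  srna <- size_select(srna, config$srna_min_len, config$srna_max_len)
  aln <- align_all(srna, index, max_mismatches = config$srna_mismatches,
                   strand = "both")
  h <- aln$hits[aln$hits$transcript_id == transcript_id, , drop = FALSE]
  scan <- phase_scan(h, anchor,
                     transcript_length = nchar(transcriptome[[transcript_id]]),
                     phase = config$phase, span = config$span,
                     min_abundance = config$min_abundance,
                     minus_offset = config$minus_offset)
  secondary <- extract_secondary(scan, h, p_cutoff = config$p_cutoff,
                                 phase = config$phase,
                                 minus_offset = config$minus_offset,
                                 library_total = aln$mapped_total)
  cascade <- validate_secondary(secondary, transcriptome, profiles,
                                allen_max = config$allen_max,
                                mfe_ratio_min = config$mfe_ratio_min,
                                window = config$cut_site_window,
                                sample_label = sample_label,
                                max_bulges = config$max_bulges)
  list(scan = scan, secondary = secondary, cascade = cascade,
       srna_hits = h)
}
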