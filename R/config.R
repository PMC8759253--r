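#' Default run configuration
#'
#' Every threshold of the pipeline with its default: 3' adapter
#' `TGGAATTCTCGGGTGCCAAGGAA` with minimum overlap 6, degradome size window
#' 20-21 nt and sRNA window 20-24 nt, mismatch budgets 1 (degradome to
#' cDNA) and 0 (sRNA, phasing stage), stringent Allen ceiling 4 with a
#' candidate tier at 5, MFE-ratio floor 0.69, miRNA abundance floor 0.5
#' RPM, cut-site matching window 1 nt, phase 21 nt over a 189-nt span,
#' phasing p-value cutoff 0.01 with minimum occupying abundance 1.
#'
#' @param ... overrides for individual keys.
#' @return named list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    adapter = "TGGAATTCTCGGGTGCCAAGGAA",
    min_adapter_overlap = 6L,
    degradome_min_len = 20L, degradome_max_len = 21L,
    srna_min_len = 20L, srna_max_len = 24L,
    degradome_mismatches = 1L, srna_mismatches = 0L,
    seed_k = 10L,
    allen_max = 4, allen_report_max = 5,
    mfe_ratio_min = 0.69, mirna_rpm_min = 0.5,
    cut_site_window = 1L,
    max_bulges = 2L,
    phase = 21L, span = 189L,
    p_cutoff = 0.01, min_abundance = 1,
    minus_offset = 2L,
    seed = 1L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config key: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_run_config(structure(cfg, class = "run_config"))
}

validate_run_config <- function(cfg) {
  with(cfg, {
    stopifnot(nzchar(adapter), min_adapter_overlap >= 1,
              degradome_min_len <= degradome_max_len,
              srna_min_len <= srna_max_len,
              degradome_mismatches >= 0, srna_mismatches >= 0,
              allen_max >= 0, allen_report_max >= allen_max,
              mfe_ratio_min > 0, mfe_ratio_min <= 1,
              mirna_rpm_min >= 0, cut_site_window >= 0,
              phase >= 1, span >= phase,
              p_cutoff > 0, p_cutoff <= 1, min_abundance >= 1)
  })
  cfg
}

#' Read a key-value run configuration file
#'
#' Plain-text `key = value` lines; `#` starts a comment. Unknown keys are
#' an error, raised before any work.
#'
#' @param path config file path.
#' @return a [default_run_config()] with the file's overrides applied.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("cannot parse config line: ", lines[bad][1])
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  defaults <- default_run_config()
  ovr <- lapply(seq_along(keys), function(i) {
    k <- keys[i]
    if (!k %in% names(defaults)) stop("unknown config key: ", k)
    proto <- defaults[[k]]
    if (is.character(proto)) vals[i]
    else if (is.integer(proto)) as.integer(vals[i])
    else as.numeric(vals[i])
  })
  names(ovr) <- keys
  do.call(default_run_config, ovr)
}

#' Write a run configuration (full default echo)
#'
#' @param cfg a `run_config`.
#' @param path output path or connection; `""` prints to stdout.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path = "") {
  lines <- vapply(names(cfg), function(k)
    sprintf("%s = %s", k, format(cfg[[k]], scientific = FALSE)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  write_run_config(x)
  invisible(x)
}
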