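# Intermolecular duplex free-energy model.
#
# Hybridization energy is summed over nearest-neighbor stacks of
# consecutive paired positions, plus fixed penalties for interior
# loops/bulges, a duplex initiation term, and terminal AU/GU penalties.
# No intramolecular structure is considered. Because every non-mismatch
# partner nucleotide is implied by the miRNA base (WC complement, or the
# wobble partner for G:U), the energy is a function of the miRNA sequence
# and the pairing string alone; a hook accepts externally computed duplex
# energies instead (e.g. from an RNAplex run) when reconciliation with
# another backend is wanted.

# Watson-Crick nearest-neighbor stacks, ΔG37 kcal/mol, keyed by the miRNA
# (5'->3') dinucleotide; values follow the standard RNA parameter set and
# respect reverse-complement symmetry.
.wc_stack <- c(
  AA = -0.93, AC = -2.24, AG = -2.08, AT = -1.10,
  CA = -2.11, CC = -3.26, CG = -2.36, CT = -2.08,
  GA = -2.35, GC = -3.42, GG = -3.26, GT = -2.24,
  TA = -1.33, TC = -2.35, TG = -2.11, TT = -0.93)

#' Duplex energy model parameters
#'
#' @param init duplex initiation penalty (kcal/mol).
#' @param terminal_au penalty per helix end closed by an A:U or G:U pair.
#' @param mm_loop penalty per mismatched (interior-loop) position.
#' @param bulge_loop penalty per bulged nucleotide.
#' @param gu_scale multiplicative weakening of a stack per G:U pair it
#'   involves (0 < gu_scale < 1).
#' @return list of class `energy_params`.
#' @export
energy_params <- function(init = 4.09, terminal_au = 0.45,
                          mm_loop = 1.7, bulge_loop = 3.5,
                          gu_scale = 0.4) {
  structure(list(init = init, terminal_au = terminal_au, mm_loop = mm_loop,
                 bulge_loop = bulge_loop, gu_scale = gu_scale),
            class = "energy_params")
}

#' Intermolecular duplex minimum free energy
#'
#' Nearest-neighbor hybridization energy of a small RNA : target duplex
#' described by a pairing string (see [enumerate_duplexes()] for the
#' symbol alphabet). Stacks accrue only between positions that are paired
#' and adjacent on both strands; each mismatch and each bulged nucleotide
#' interrupts the helix and adds its loop penalty.
#'
#' @param mirna_seq small RNA sequence, 5' to 3'.
#' @param pairing pairing string over `|` (Watson-Crick), `o` (G:U), `x`
#'   (mismatch), `-` (bulged miRNA nt), `^` (bulged target nt).
#' @param params an [energy_params()] object.
#' @param target_site_seq optional target site sequence (5' to 3'); only
#'   checked for consistency with the pairing when supplied.
#' @return free energy in kcal/mol (negative for a stable duplex).
#' @export
duplex_mfe <- function(mirna_seq, pairing, params = energy_params(),
                       target_site_seq = NULL) {
  mi <- strsplit(canonicalize_seq(mirna_seq), "", fixed = TRUE)[[1]]
  sym <- strsplit(pairing, "", fixed = TRUE)[[1]]
  if (sum(sym != "^") != length(mi))
    stop("pairing string inconsistent with miRNA length")
  if (!is.null(target_site_seq) &&
      sum(sym != "-") != nchar(canonicalize_seq(target_site_seq)))
    stop("pairing string inconsistent with target site length")
  # miRNA position of each symbol (NA for target bulges)
  mi_pos <- cumsum(sym != "^")
  mi_pos[sym == "^"] <- NA_integer_
  e <- params$init
  paired <- sym %in% c("|", "o")
  # loop penalties
  e <- e + params$mm_loop * sum(sym == "x") +
    params$bulge_loop * sum(sym %in% c("-", "^"))
  # stacks between consecutive symbols that are both paired
  idx <- which(paired)
  if (length(idx) >= 2) {
    for (j in seq_len(length(idx) - 1L)) {
      a <- idx[j]; b <- idx[j + 1L]
      if (b != a + 1L) next  # helix interrupted
      step <- paste0(mi[mi_pos[a]], mi[mi_pos[b]])
      val <- .wc_stack[[step]]
      n_gu <- (sym[a] == "o") + (sym[b] == "o")
      e <- e + val * params$gu_scale^n_gu
    }
  }
  # terminal penalty at each duplex end closed by A:U or G:U
  if (length(idx)) {
    for (end in c(idx[1], idx[length(idx)])) {
      nt <- mi[mi_pos[end]]
      if (sym[end] == "o" || nt %in% c("A", "T")) e <- e + params$terminal_au
    }
  }
  e
}

#' Minimum free energy of the perfectly complementary duplex
#'
#' @param mirna_seq small RNA sequence, 5' to 3'.
#' @param params an [energy_params()] object.
#' @return energy (kcal/mol) of the all-Watson-Crick duplex of the same
#'   small RNA.
#' @export
perfect_mfe <- function(mirna_seq, params = energy_params()) {
  duplex_mfe(mirna_seq, strrep("|", nchar(mirna_seq)), params)
}

#' Minimum-free-energy ratio
#'
#' The duplex energy divided by the energy of the perfect complement of
#' the same small RNA. Both energies are negative, so the ratio is
#' positive and equals 1 for the perfect duplex.
#'
#' @param mfe duplex energy (kcal/mol).
#' @param mfe_perfect perfect-complement energy (kcal/mol).
#' @return `mfe / mfe_perfect`.
#' @export
mfe_ratio <- function(mfe, mfe_perfect) {
  if (any(mfe_perfect >= 0)) stop("perfect-duplex energy must be negative")
  mfe / mfe_perfect
}
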