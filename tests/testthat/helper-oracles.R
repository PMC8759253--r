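# Independent oracles used to cross-check the implementation. These
# re-derive each quantity from first principles (direct clause evaluation,
# brute-force scanning, exhaustive enumeration) and deliberately share no
# code with the package paths they check.

# --- cleavage-category oracle: literal evaluation of the four clauses ----
# counts: named numeric vector (names = positions), pos: a position.
oracle_category <- function(counts, pos) {
  x <- unname(counts[[as.character(pos)]])
  max_abund <- max(counts)
  avg_depth <- sum(counts) / length(counts)  # mean over occupied positions
  if (x == 1) return(4L)                                   # single read
  if (x > 1 && x == max_abund) return(1L)                  # (tied) maximum
  if (x > 1 && x > avg_depth && x < max_abund) return(2L)  # above average
  if (x > 1 && x <= avg_depth) return(3L)                  # at/below average
  stop("position does not satisfy any category clause")
}

# --- brute-force aligner: compare the read to every window ---------------
oracle_align <- function(read, transcriptome, max_mismatches) {
  rchars <- strsplit(read, "", fixed = TRUE)[[1]]
  L <- length(rchars)
  out <- NULL
  for (tid in names(transcriptome)) {
    tchars <- strsplit(transcriptome[[tid]], "", fixed = TRUE)[[1]]
    if (length(tchars) < L) next
    for (p in seq_len(length(tchars) - L + 1L)) {
      mm <- sum(rchars != tchars[p:(p + L - 1L)])
      if (mm <= max_mismatches)
        out <- rbind(out, data.frame(transcript_id = tid, pos = p,
                                     mismatches = mm,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(transcript_id = character(), pos = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  out[order(out$transcript_id, out$pos), , drop = FALSE]
}

# --- exhaustive duplex-search oracle -------------------------------------
# Enumerates every (site end, bulge pattern) alignment of the miRNA
# against the transcript: up to 2 bulged nucleotides on either strand,
# none at miRNA positions 10-11 (and no target bulge between them),
# penalties doubled at positions 2-13. Vectorized over site ends only.

oracle_patterns <- function(m, max_bulges = 2L) {
  bpos <- setdiff(2:(m - 1L), c(10L, 11L))
  slots <- setdiff(2:m, 11L)
  pats <- list(list(miB = integer(), tS = integer()))
  if (max_bulges >= 1L) {
    for (b in bpos) pats[[length(pats) + 1L]] <- list(miB = b, tS = integer())
    for (s in slots) pats[[length(pats) + 1L]] <- list(miB = integer(), tS = s)
  }
  if (max_bulges >= 2L) {
    if (length(bpos) > 1L)
      for (a in seq_along(bpos)[-length(bpos)])
        for (b in (a + 1L):length(bpos))
          pats[[length(pats) + 1L]] <- list(miB = c(bpos[a], bpos[b]),
                                            tS = integer())
    for (a in seq_along(slots))
      for (b in a:length(slots))
        pats[[length(pats) + 1L]] <- list(miB = integer(),
                                          tS = c(slots[a], slots[b]))
    for (b in bpos) for (s in slots)
      pats[[length(pats) + 1L]] <- list(miB = b, tS = s)
  }
  pats
}

# pairing-walk layout of one pattern: symbol slots in order, with the
# miRNA position, target offset from the site end, and doubling slot
oracle_layout <- function(m, pat) {
  rows <- list()
  t_off <- 0L
  for (i in seq_len(m)) {
    for (s in pat$tS) if (s == i) {
      rows[[length(rows) + 1L]] <- list(type = "^", mi = NA_integer_,
                                        off = t_off, slot = i)
      t_off <- t_off + 1L
    }
    if (i %in% pat$miB) {
      rows[[length(rows) + 1L]] <- list(type = "-", mi = i,
                                        off = NA_integer_, slot = i)
    } else {
      rows[[length(rows) + 1L]] <- list(type = "pair", mi = i, off = t_off,
                                        slot = i)
      t_off <- t_off + 1L
    }
  }
  list(rows = rows, span = t_off)
}

# 5x5 penalty lookup (mi code x tx code), codes A=1 C=2 G=3 T=4 N=5
oracle_pen_matrix <- function(mm = 1, gu = 0.5) {
  pen <- matrix(mm, 5, 5)
  pen[1, 4] <- 0; pen[4, 1] <- 0; pen[2, 3] <- 0; pen[3, 2] <- 0  # WC
  pen[3, 4] <- gu; pen[4, 3] <- gu                                # G:U
  pen
}

oracle_code <- function(s) {
  m <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  m[is.na(m)] <- 5L
  m
}

oracle_enumerate <- function(mi_seq, tx_seq, max_allen = 5,
                             min_ratio = 0.5, max_bulges = 2L) {
  mi <- oracle_code(mi_seq); tx <- oracle_code(tx_seq)
  m <- length(mi); n <- length(tx)
  pen <- oracle_pen_matrix()
  sym_of_pair <- matrix("x", 5, 5)
  sym_of_pair[1, 4] <- "|"; sym_of_pair[4, 1] <- "|"
  sym_of_pair[2, 3] <- "|"; sym_of_pair[3, 2] <- "|"
  sym_of_pair[3, 4] <- "o"; sym_of_pair[4, 3] <- "o"
  mfe_perf <- pared::perfect_mfe(mi_seq)
  cand <- list()
  for (pat in oracle_patterns(m, max_bulges)) {
    lay <- oracle_layout(m, pat)
    span <- lay$span
    ends <- span:n                        # 1-based site end coordinates
    if (!length(ends)) next
    allen <- numeric(length(ends))
    for (r in lay$rows) {
      mult <- if (r$slot >= 2 && r$slot <= 13) 2 else 1
      if (r$type == "pair") {
        allen <- allen + pen[mi[r$mi], tx[ends - r$off]] * mult
      } else {
        allen <- allen + 1 * mult         # each bulged nucleotide
      }
    }
    ok <- which(allen <= max_allen + 1e-9)
    for (j in ok) {
      e <- ends[j]
      syms <- vapply(lay$rows, function(r) {
        if (r$type == "pair") sym_of_pair[mi[r$mi], tx[e - r$off]] else r$type
      }, character(1))
      pairing <- paste(syms, collapse = "")
      cleav_off <- vapply(lay$rows, function(r)
        if (r$type == "pair" && r$mi == 10L) r$off else NA_integer_,
        integer(1))
      cleav <- e - cleav_off[!is.na(cleav_off)][1]
      mfe <- pared::duplex_mfe(mi_seq, pairing)
      ratio <- mfe / mfe_perf
      if (mfe < 0 && ratio >= min_ratio)
        cand[[length(cand) + 1L]] <- data.frame(
          site_start = e - span + 1L, site_end = e, pairing = pairing,
          allen_score = allen[j], mfe = mfe, mfe_ratio = ratio,
          cleavage_pos = cleav, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand))
    return(data.frame(site_start = integer(), site_end = integer(),
                      pairing = character(), allen_score = numeric(),
                      mfe = numeric(), mfe_ratio = numeric(),
                      cleavage_pos = integer(), stringsAsFactors = FALSE))
  hits <- do.call(rbind, cand)
  # overlap reduction: merge overlapping intervals, keep the locally best
  hits <- hits[order(hits$site_start, hits$site_end), , drop = FALSE]
  groups <- integer(nrow(hits)); g <- 0L; reach <- -1L
  for (i in seq_len(nrow(hits))) {
    if (hits$site_start[i] > reach) { g <- g + 1L; reach <- hits$site_end[i] }
    else reach <- max(reach, hits$site_end[i])
    groups[i] <- g
  }
  keep <- vapply(split(seq_len(nrow(hits)), groups), function(ix) {
    h <- hits[ix, , drop = FALSE]
    ix[order(h$allen_score, -h$mfe_ratio, h$site_start,
             h$site_end - h$site_start)[1]]
  }, integer(1))
  out <- hits[sort(unname(keep)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- hypergeometric tail by direct summation and by full enumeration -----
oracle_phyper_sum <- function(L, m, n, k) {
  if (k == 0) return(1)
  x <- k:min(n, m)
  sum(choose(m, x) * choose(L - m, n - x)) / choose(L, n)
}

oracle_phyper_enum <- function(L, m, n, k) {
  # all C(L, n) occupancy patterns; lattice = first m positions (exchangeable)
  combos <- utils::combn(L, n)
  mean(colSums(combos <= m) >= k)
}

# --- cleavage coordinate by an independent pairing walk ------------------
oracle_cleavage_walk <- function(pairing, site_end) {
  t <- site_end; i <- 0L
  for (s in strsplit(pairing, "", fixed = TRUE)[[1]]) {
    if (s == "^") { t <- t - 1L; next }
    i <- i + 1L
    if (s == "-") next
    if (i == 10L) return(t)
    t <- t - 1L
  }
  NA_integer_
}

# random pairing string with a chosen number of defects, for planting;
# G:U defects are placed only where the miRNA base admits a wobble
random_pairing <- function(mirna_seq, n_gu = 0L, n_mm = 0L, n_bulge = 0L) {
  mi <- strsplit(mirna_seq, "", fixed = TRUE)[[1]]
  m <- length(mi)
  sym <- rep("|", m)
  pos <- setdiff(2:(m - 1L), c(10L, 11L))
  gu_ok <- intersect(pos, which(mi %in% c("G", "T")))
  gu <- if (n_gu) sample(gu_ok, n_gu) else integer()
  mm <- if (n_mm) sample(setdiff(pos, gu), n_mm) else integer()
  sym[gu] <- "o"; sym[mm] <- "x"
  if (n_bulge) {
    b <- sample(setdiff(pos, c(gu, mm)), n_bulge)
    for (p in sort(b, decreasing = TRUE)) {
      if (stats::runif(1) < 0.5) sym[p] <- "-"
      else sym <- append(sym, "^", after = p - 1L)
    }
  }
  paste(sym, collapse = "")
}
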