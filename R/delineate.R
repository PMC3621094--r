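#' Find the flanking LTR pair of a candidate locus by self-alignment
#'
#' Mirrors a BLASTn-style self-alignment of the locus (match +1, mismatch
#' -3, gap costs of existence 5 and extension 2): the best local alignment
#' between the region upstream of the gene block and the region downstream
#' of it is taken as the direct-repeat (LTR) pair. Boundaries are then
#' refined by ungapped outward extension while consecutive columns match,
#' and snapped to the canonical TG...CA retroviral LTR termini when those
#' dinucleotides occur within 6 nt of the alignment ends.
#' The pair is accepted when both arms fall within `len_bounds` and the
#' identity (matches / alignment columns) reaches `min_identity`, and --
#' when gene spans are supplied -- the inner interval contains them.
#'
#' @param locus_seq DNA of the candidate locus including its padding flanks.
#' @param gene_spans optional data.frame/list with numeric `start`/`end` of
#'   the gag/pol/env hits in locus coordinates; used to split the search and
#'   to check containment.
#' @param min_identity minimum LTR-pair identity (default 0.8).
#' @param len_bounds admissible LTR lengths, nt.
#' @param match,mismatch,gap_open,gap_extend self-alignment scoring.
#' @return an `ltr_pair` (list with `ltr5_start/end`, `ltr3_start/end`,
#'   `len5`, `len3`, `identity`) or NULL when no qualifying repeat exists
#'   (the locus is then only a betaERV-like retroelement).
#' @export
find_ltr_pair <- function(locus_seq, gene_spans = NULL, min_identity = 0.8,
                          len_bounds = c(250L, 1500L),
                          match = 1L, mismatch = -3L,
                          gap_open = 5, gap_extend = 2) {
  L <- nchar(locus_seq)
  if (!is.null(gene_spans)) {
    inner_lo <- min(unlist(gene_spans$start))
    inner_hi <- max(unlist(gene_spans$end))
  } else {
    inner_lo <- inner_hi <- floor(L / 2)
  }
  left_hi <- min(L, inner_lo + 50L)
  right_lo <- max(1L, inner_hi - 50L)
  if (left_hi < len_bounds[1] || L - right_lo + 1L < len_bounds[1])
    return(NULL)
  left <- substr(locus_seq, 1L, left_hi)
  right <- substr(locus_seq, right_lo, L)

  al <- align_dna(left, right, type = "local", match = match,
                  mismatch = mismatch, gap_open = gap_open,
                  gap_extend = gap_extend)
  if (al$score <= 0) return(NULL)

  s5 <- al$astart; e5 <- al$aend
  s3 <- right_lo + al$bstart - 1L
  e3 <- right_lo + al$bend - 1L

  # ungapped outward extension while columns keep matching exactly
  while (s5 > 1L && s3 > right_lo &&
         substr(locus_seq, s5 - 1L, s5 - 1L) ==
         substr(locus_seq, s3 - 1L, s3 - 1L) &&
         substr(locus_seq, s5 - 1L, s5 - 1L) != "N") {
    s5 <- s5 - 1L; s3 <- s3 - 1L
  }
  while (e5 < left_hi && e3 < L &&
         substr(locus_seq, e5 + 1L, e5 + 1L) ==
         substr(locus_seq, e3 + 1L, e3 + 1L) &&
         substr(locus_seq, e5 + 1L, e5 + 1L) != "N") {
    e5 <- e5 + 1L; e3 <- e3 + 1L
  }

  # snap boundaries to the canonical TG...CA LTR termini within a small
  # window; self-alignment ends are fuzzy by a few nt (chance matches in
  # the flanks) and retroviral LTRs start TG and end CA
  has <- function(p, motif) {
    p >= 1L && p + 1L <= L && substr(locus_seq, p, p + 1L) == motif
  }
  # inner edges (5' LTR end, 3' LTR start): conservative per-copy snap to
  # the canonical CA / TG terminus within +/-3 nt (indels near one copy's
  # edge decouple the two copies, so each is snapped on its own)
  one <- function(p, motif, win = 3L) {
    for (dd in (-win:win)[order(abs(-win:win))]) {
      if (has(p + dd, motif)) return(dd)
    }
    0L
  }
  e5 <- e5 + one(e5 - 1L, "CA")
  s3 <- s3 + one(s3, "TG")
  # outer corners (5' LTR start, 3' LTR end): joint search over shifts,
  # scored by the TG / CA termini plus an exact 4-nt target-site
  # duplication in the immediate flanks (integration evidence)
  tsd_at <- function(da, db) {
    p <- s5 + da; q <- e3 + db
    if (p - 4L < 1L || q + 4L > L) return(FALSE)
    up <- substr(locus_seq, p - 4L, p - 1L)
    dn <- substr(locus_seq, q + 1L, q + 4L)
    up == dn && !grepl("N", up, fixed = TRUE)
  }
  shifts <- (-12:12)[order(abs(-12:12))]
  best_sc <- -1; best_da <- 0L; best_db <- 0L; best_rank <- Inf
  for (da in shifts) for (db in shifts) {
    tg <- has(s5 + da, "TG"); ca <- has(e3 + db - 1L, "CA")
    # both termini together score an extra point so that a chance flank
    # 4-mer plus one spurious terminus never outranks an intact TG...CA pair
    sc <- tg + ca + (tg && ca) + 2L * tsd_at(da, db)
    rank <- abs(da) + abs(db)
    if (sc > best_sc || (sc == best_sc && rank < best_rank)) {
      best_sc <- sc; best_da <- da; best_db <- db; best_rank <- rank
    }
  }
  s5 <- s5 + best_da
  e3 <- e3 + best_db

  # length reconciliation: heavy decay right at one copy's inner edge can
  # leave the self-alignment short there; the TSD-validated outer corners
  # pin down the other copy's length, which bounds the fuzzy edge. The
  # extension is accepted only when the reconciled segment still looks like
  # LTR sequence in both copies (>= 50% cross-copy identity).
  len5 <- e5 - s5 + 1L; len3 <- e3 - s3 + 1L
  if (abs(len5 - len3) > 4L) {
    seg_ident <- function(a_start, a_end, b_start, b_end) {
      a <- seq_chars(substr(locus_seq, a_start, a_end))
      b <- seq_chars(substr(locus_seq, b_start, b_end))
      n <- min(length(a), length(b))
      if (n == 0) return(0)
      mean(a[seq_len(n)] == b[seq_len(n)])
    }
    if (len5 < len3) {
      e5p <- s5 + len3 - 1L
      e5p <- e5p + one(e5p - 1L, "CA")
      k <- e5p - e5
      if (k > 0 && e5p < s3 &&
          seg_ident(e5 + 1L, e5p, e3 - k + 1L, e3) >= 0.5) e5 <- e5p
    } else {
      s3p <- e3 - len5 + 1L
      s3p <- s3p + one(s3p, "TG")
      k <- s3 - s3p
      if (k > 0 && s3p > e5 &&
          seg_ident(s3p, s3 - 1L, s5, s5 + k - 1L) >= 0.5) s3 <- s3p
    }
  }

  len5 <- e5 - s5 + 1L
  len3 <- e3 - s3 + 1L
  if (len5 < len_bounds[1] || len5 > len_bounds[2] ||
      len3 < len_bounds[1] || len3 > len_bounds[2]) return(NULL)
  if (al$identity < min_identity) return(NULL)
  if (e5 >= s3) return(NULL)
  if (!is.null(gene_spans)) {
    # small tolerance: hit spans are local-alignment trims of the true genes
    if (!(e5 <= inner_lo + 50L && s3 >= inner_hi - 50L)) return(NULL)
  }
  structure(list(ltr5_start = s5, ltr5_end = e5, ltr3_start = s3,
                 ltr3_end = e3, len5 = len5, len3 = len3,
                 identity = al$identity), class = "ltr_pair")
}

#' @export
print.ltr_pair <- function(x, ...) {
  cat(sprintf("<ltr_pair> 5' [%d,%d] (%d nt)  3' [%d,%d] (%d nt)  id %.1f%%\n",
              x$ltr5_start, x$ltr5_end, x$len5, x$ltr3_start, x$ltr3_end,
              x$len3, 100 * x$identity))
  invisible(x)
}

#' Target-site duplication call
#'
#' A provirus generated by integration is flanked by a 4-nt duplication of
#' host sequence. The call is positive only when the 4-mer immediately 5'
#' of the 5' LTR exactly equals the 4-mer immediately 3' of the 3' LTR
#' (no mismatch tolerance). Flanks overlapping an N-run give a "masked"
#' call; insufficient flank gives "none".
#'
#' @param seq the scaffold or locus DNA the LTR coordinates refer to.
#' @param ltr_pair an `ltr_pair` from [find_ltr_pair()].
#' @return list of class `tsd_call`: `status` ("present"/"none"/"masked"),
#'   `sequence` (4-mer or NA), `pos5`, `pos3` (starts of the two copies).
#' @export
find_tsd <- function(seq, ltr_pair) {
  s <- ltr_pair$ltr5_start; e <- ltr_pair$ltr3_end
  none <- list(status = "none", sequence = NA_character_,
               pos5 = NA_integer_, pos3 = NA_integer_)
  class(none) <- "tsd_call"
  if (s - 4L < 1L || e + 4L > nchar(seq)) return(none)
  up <- substr(seq, s - 4L, s - 1L)
  dn <- substr(seq, e + 1L, e + 4L)
  if (grepl("N", up, fixed = TRUE) || grepl("N", dn, fixed = TRUE)) {
    out <- none; out$status <- "masked"; return(out)
  }
  if (up != dn) return(none)
  structure(list(status = "present", sequence = up, pos5 = s - 4L,
                 pos3 = e + 1L), class = "tsd_call")
}

#' Polypurine tract immediately upstream of the 3' LTR
#'
#' Scans the window 5' of the 3' LTR for the longest stretch with purine
#' (A/G) fraction at or above `min_purine` whose 3' end lies within
#' `max_gap` nt of the LTR. Ties prefer the longer window, then the one
#' closest to the LTR.
#'
#' @param upstream DNA immediately 5' of the 3' LTR (its last character
#'   abuts the LTR).
#' @param min_len minimum PPT length, nt.
#' @param min_purine minimum purine fraction.
#' @param max_gap maximum distance between the PPT end and the LTR, nt.
#' @return list of class `ppt_call` (`start`, `end` relative to `upstream`,
#'   `length`, `purine_fraction`) or NULL.
#' @export
find_ppt <- function(upstream, min_len = 12L, min_purine = 0.85,
                     max_gap = 5L) {
  L <- nchar(upstream)
  if (L < min_len) return(NULL)
  is_pur <- seq_chars(upstream) %in% PURINES
  cum <- c(0L, cumsum(is_pur))
  best <- NULL
  for (e in seq(L, max(min_len, L - max_gap), by = -1L)) {
    for (s in seq_len(e - min_len + 1L)) {
      len <- e - s + 1L
      frac <- (cum[e + 1L] - cum[s]) / len
      if (frac >= min_purine) {
        if (is.null(best) || len > best$length ||
            (len == best$length && e > best$end)) {
          best <- list(start = s, end = e, length = len,
                       purine_fraction = frac)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  class(best) <- "ppt_call"
  best
}

#' Compare the chromosomal flanks of two proviruses
#'
#' Detects post-integration duplications: two proviruses descend from one
#' integration when the host DNA immediately up- and downstream of both is
#' homologous. Each side is compared by local alignment; the verdict is
#' "homologous" when both sides align at >= `min_identity` identity over at
#' least half of `flank_len`. Proviruses with less than `flank_len` of
#' non-N flank are "indeterminate".
#'
#' @param rec_a,rec_b lists with `seq` (scaffold DNA) plus `outer_start`,
#'   `outer_end` (outermost provirus coordinates, e.g. the LTR edges).
#' @param flank_len flank length to compare, nt.
#' @param min_identity minimum alignment identity.
#' @return "homologous", "not" or "indeterminate".
#' @export
compare_flanks <- function(rec_a, rec_b, flank_len = 1000L,
                           min_identity = 0.8) {
  get_flanks <- function(r) {
    up <- substr(r$seq, max(1L, r$outer_start - flank_len),
                 r$outer_start - 1L)
    dn <- substr(r$seq, r$outer_end + 1L,
                 min(nchar(r$seq), r$outer_end + flank_len))
    list(up = up, dn = dn)
  }
  fa <- get_flanks(rec_a); fb <- get_flanks(rec_b)
  usable <- function(x) {
    nchar(x) >= flank_len && sum(seq_chars(x) == "N") < 0.5 * nchar(x) &&
      !all(seq_chars(x) == "N")
  }
  if (!usable(fa$up) || !usable(fa$dn) || !usable(fb$up) || !usable(fb$dn))
    return("indeterminate")
  side_ok <- function(a, b) {
    al <- align_dna(a, b, type = "local")
    al$columns >= 0.5 * flank_len && al$identity >= min_identity
  }
  if (side_ok(fa$up, fb$up) && side_ok(fa$dn, fb$dn)) "homologous" else "not"
}

#' Merge two transcripts through a perfect overlap
#'
#' Merges `t1` and `t2` when a suffix of one equals a prefix of the other
#' over at least `min_overlap` nt with 100% identity (optionally after
#' trimming `trim5` nt from the start of the downstream sequence and
#' `trim3` nt from the end of the upstream one). The merged length is
#' `len1 + len2 - overlap`. More than one qualifying overlap length is an
#' ambiguity (possible recombination) and raises an error.
#'
#' @param t1,t2 DNA sequences.
#' @param min_overlap minimum exact overlap, nt.
#' @param trim5,trim3 end trims applied before the overlap search.
#' @return merged sequence, or NULL when no qualifying overlap exists.
#' @export
merge_overlapping_transcripts <- function(t1, t2, min_overlap = 100L,
                                          trim5 = 0L, trim3 = 0L) {
  stopifnot(nchar(t1) > 0, nchar(t2) > 0)
  overlaps <- function(up, dn) {
    if (trim3 > 0) up <- substr(up, 1L, nchar(up) - trim3)
    if (trim5 > 0) dn <- substr(dn, trim5 + 1L, nchar(dn))
    n1 <- nchar(up); n2 <- nchar(dn)
    found <- integer(0)
    for (v in seq(min(n1, n2), min_overlap, by = -1L)) {
      if (substr(up, n1 - v + 1L, n1) == substr(dn, 1L, v))
        found <- c(found, v)
    }
    list(up = up, dn = dn, v = found)
  }
  cand <- list()
  fwd <- overlaps(t1, t2)
  for (v in fwd$v) cand[[length(cand) + 1L]] <-
      paste0(fwd$up, substr(fwd$dn, v + 1L, nchar(fwd$dn)))
  if (t1 != t2) {
    bwd <- overlaps(t2, t1)
    for (v in bwd$v) cand[[length(cand) + 1L]] <-
        paste0(bwd$up, substr(bwd$dn, v + 1L, nchar(bwd$dn)))
  }
  cand <- unique(cand)
  if (length(cand) == 0) return(NULL)
  if (length(cand) > 1)
    stop("ambiguous merge: ", length(cand),
         " distinct qualifying overlaps (possible recombination)")
  cand[[1]]
}
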