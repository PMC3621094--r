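#' Open reading frames above a codon cutoff
#'
#' All ATG-to-stop spans of at least `min_codons` codons (stop excluded) on
#' the forward frames (and reverse frames when `both_strands`), one ORF per
#' stop (the longest, i.e. the first ATG after the previous stop in that
#' frame). ORFs spanning a frameshift are never stitched; each frame is
#' scanned independently. A 100-codon cutoff limits incidental non-coding
#' ORFs.
#'
#' @param dna DNA sequence.
#' @param min_codons minimum ORF length in codons, stop excluded.
#' @param both_strands also scan the reverse-complement frames.
#' @param provirus_map optional data.frame (element/start/end) used to
#'   classify each ORF's placement: `pre-gag`, `within-core-alt-frame`,
#'   `post-env`, `in-LTR`, or `other`.
#' @return data.frame with `start`, `end` (1-based inclusive, including the
#'   stop codon), `strand`, `frame`, `codons`, `placement`.
#' @export
find_orfs <- function(dna, min_codons = 100L, both_strands = FALSE,
                      provirus_map = NULL) {
  out <- list()
  frames <- if (both_strands) c(1:3, -(1:3)) else 1:3
  L <- nchar(dna)
  for (fr in frames) {
    off <- abs(fr) - 1L
    src <- if (fr > 0) dna else revcomp(dna)
    n_codon <- (nchar(src) - off) %/% 3L
    if (n_codon < min_codons + 1L) next
    starts <- off + 3L * (seq_len(n_codon) - 1L) + 1L
    codons <- substring(src, starts, starts + 2L)
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    is_atg <- codons == "ATG"
    prev_stop <- 0L
    for (i in which(is_stop)) {
      atg <- which(is_atg[(prev_stop + 1L):(i - 1L)])
      if (length(atg) > 0) {
        a <- prev_stop + atg[1L]
        len <- i - a
        if (len >= min_codons) {
          s_src <- starts[a]; e_src <- starts[i] + 2L
          if (fr > 0) { s <- s_src; e <- e_src }
          else { s <- L - e_src + 1L; e <- L - s_src + 1L }
          out[[length(out) + 1L]] <- data.frame(
            start = s, end = e, strand = if (fr > 0) "+" else "-",
            frame = fr, codons = len, stringsAsFactors = FALSE)
        }
      }
      prev_stop <- i
    }
  }
  orfs <- if (length(out) == 0) {
    data.frame(start = integer(0), end = integer(0), strand = character(0),
               frame = integer(0), codons = integer(0))
  } else do.call(rbind, out)
  orfs$placement <- if (nrow(orfs) > 0 && !is.null(provirus_map)) {
    vapply(seq_len(nrow(orfs)), function(i)
      classify_orf_placement(orfs$start[i], orfs$end[i], provirus_map), "")
  } else rep(NA_character_, nrow(orfs))
  orfs[order(orfs$start), , drop = FALSE]
}

classify_orf_placement <- function(s, e, map) {
  get <- function(el) map[map$element == el, , drop = FALSE]
  mid <- (s + e) / 2
  within <- function(el) {
    r <- get(el); nrow(r) > 0 && mid >= r$start && mid <= r$end
  }
  if (within("ltr5") || within("ltr3")) return("in-LTR")
  gag <- get("gag"); env <- get("env")
  if (nrow(gag) > 0 && mid < gag$start) return("pre-gag")
  if (nrow(env) > 0 && mid > env$end) return("post-env")
  if (nrow(gag) > 0 && nrow(env) > 0 && mid >= gag$start && mid <= env$end) {
    # inside the core block: the ORF is one of the core genes themselves
    # when it lies almost entirely within a single gene span and covers
    # most of it; anything else is an extra alternate-frame ORF
    core <- map[map$element %in% c("gag", "pro", "pol", "env"), ,
                drop = FALSE]
    for (i in seq_len(nrow(core))) {
      ov <- min(e, core$end[i]) - max(s, core$start[i]) + 1L
      if (ov > 0 && ov >= 0.8 * (e - s + 1L) && ov >= 0.5 *
          (core$end[i] - core$start[i] + 1L)) return("core-gene")
    }
    return("within-core-alt-frame")
  }
  "other"
}

#' Assign the primer-binding site to a lysine tRNA
#'
#' Slides the reverse complement of each tRNA 3'-end 18-mer along the
#' leader (the region between the 5' LTR and gag) without gaps and counts
#' matches. The top tRNA is called when it reaches `min_matches` and beats
#' the runner-up by at least 2 matches; otherwise the call is `unknown`.
#' A leader that is fully N (or shorter than the window) is `unknown`
#' (status "masked" when N).
#'
#' @param leader DNA between the 5' LTR and the gag start.
#' @param trna_lib named character vector of tRNA 3'-end 18-mers (see
#'   [trna_lys_library()]).
#' @param min_matches minimum matches out of `window`.
#' @param window probe length.
#' @return list of class `pbs_call`: `trna_id` (library name or "unknown"),
#'   `matches`, `window`, `start`, `end` (leader coordinates), `status`.
#' @export
assign_pbs <- function(leader, trna_lib = trna_lys_library(),
                       min_matches = 14L, window = 18L) {
  unknown <- structure(list(trna_id = "unknown", matches = NA_integer_,
                            window = window, start = NA_integer_,
                            end = NA_integer_, status = "no-call"),
                       class = "pbs_call")
  Lc <- seq_chars(leader)
  if (nchar(leader) < window) return(unknown)
  if (all(Lc == "N")) { unknown$status <- "masked"; return(unknown) }

  best <- data.frame(id = names(trna_lib), matches = 0L, start = NA_integer_,
                     stringsAsFactors = FALSE)
  for (i in seq_along(trna_lib)) {
    probe <- seq_chars(revcomp(substr(trna_lib[[i]],
                                      nchar(trna_lib[[i]]) - window + 1L,
                                      nchar(trna_lib[[i]]))))
    for (s in seq_len(nchar(leader) - window + 1L)) {
      w <- Lc[s:(s + window - 1L)]
      m <- sum(w == probe & w != "N")
      if (m > best$matches[i]) { best$matches[i] <- m; best$start[i] <- s }
    }
  }
  best <- best[order(-best$matches), , drop = FALSE]
  top <- best[1, ]
  if (top$matches < min_matches) {
    if (any(Lc == "N")) unknown$status <- "masked"
    return(unknown)
  }
  if (nrow(best) > 1 && top$matches - best$matches[2] < 2L) return(unknown)
  structure(list(trna_id = top$id, matches = top$matches, window = window,
                 start = top$start, end = top$start + window - 1L,
                 status = "called"), class = "pbs_call")
}

## motif scan ----------------------------------------------------------------

#' Scan gene translations for conserved retroviral motifs
#'
#' Motifs are anchored by alignment, not free-floating pattern matching:
#' each gene translation is locally aligned to its reference protein, the
#' reference anchor of every motif block is mapped through the alignment,
#' and the block's fixed-length pattern is checked in a +/-2 residue window
#' at the mapped position. A motif is present only when all of its blocks
#' match; genes whose reference alignment fails are "not assessable".
#'
#' @param translations named character vector of (frame-corrected) protein
#'   sequences per gene, e.g. `c(gag=..., pro=..., pol=...)`.
#' @param refs named character vector of reference proteins for the same
#'   genes.
#' @param patterns motif pattern table (see [motif_patterns()]).
#' @param params alignment parameters for the anchoring alignment.
#' @return data.frame with `motif_id`, `gene`, `status`
#'   ("present"/"absent"/"not assessable"), `position` (query position of
#'   the first block when present).
#' @export
scan_motifs <- function(translations, refs, patterns = motif_patterns(),
                        params = alignment_params(low_complexity_filter = FALSE)) {
  res <- list()
  for (gene in unique(patterns$gene)) {
    pat <- patterns[patterns$gene == gene, , drop = FALSE]
    ids <- unique(pat$motif_id)
    if (!gene %in% names(translations) || !gene %in% names(refs) ||
        is.na(translations[[gene]]) || nchar(translations[[gene]]) < 10) {
      res[[length(res) + 1L]] <- data.frame(
        motif_id = ids, gene = gene, status = "not assessable",
        position = NA_integer_, stringsAsFactors = FALSE)
      next
    }
    qry <- translations[[gene]]
    al <- local_align_protein(refs[[gene]], qry, params)
    if (al$score <= 0 || al$length < 0.3 * nchar(refs[[gene]])) {
      res[[length(res) + 1L]] <- data.frame(
        motif_id = ids, gene = gene, status = "not assessable",
        position = NA_integer_, stringsAsFactors = FALSE)
      next
    }
    # map reference positions to query positions through alignment columns
    rmap <- rep(NA_integer_, nchar(refs[[gene]]))
    lastq <- NA_integer_
    for (k in seq_along(al$qpos)) {
      if (al$tpos[k] > 0) lastq <- al$tpos[k]
      if (al$qpos[k] > 0 && al$tpos[k] > 0) rmap[al$qpos[k]] <- al$tpos[k]
    }
    for (id in ids) {
      blocks <- pat[pat$motif_id == id, , drop = FALSE]
      ok <- TRUE; first_pos <- NA_integer_
      for (b in seq_len(nrow(blocks))) {
        anchor <- blocks$anchor[b]
        qpos <- if (anchor <= length(rmap)) rmap[anchor] else NA_integer_
        if (is.na(qpos)) { ok <- FALSE; break }
        plen <- nchar(blocks$pattern[b])
        win <- substr(qry, max(1L, qpos - 2L), min(nchar(qry), qpos + plen + 1L))
        if (!grepl(blocks$pattern[b], win)) { ok <- FALSE; break }
        if (is.na(first_pos)) first_pos <- qpos
      }
      res[[length(res) + 1L]] <- data.frame(
        motif_id = id, gene = gene,
        status = if (ok) "present" else "absent",
        position = if (ok) first_pos else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

## repeats -------------------------------------------------------------------

#' Direct and inverted repeats by self-comparison
#'
#' Self-comparison of the region within and downstream of env (the
#' architecture search for constitutive-transport-element-like direct
#' repeats), with low-complexity filtering off. Exact word seeds of length
#' `word` are merged along diagonals into maximal arms; arms of at least
#' `min_arm` nt are reported. Inverted repeats compare the sequence against
#' its reverse complement.
#'
#' @param dna region to scan (env start to the 3'-LTR polyA position; when
#'   no polyA signal is annotated the 3' LTR end is used).
#' @param word seed word size.
#' @param min_arm minimum arm length, nt.
#' @param tbe_from optional coordinate (e.g. the env stop): direct repeats
#'   whose arms both start at or after it are flagged `tbe_candidate`.
#' @return data.frame with `kind` ("direct"/"inverted"), `start1`, `end1`,
#'   `start2`, `end2`, `arm_len`, `tbe_candidate`.
#' @export
find_repeats <- function(dna, word = 11L, min_arm = 11L, tbe_from = NULL) {
  L <- nchar(dna)
  empty <- data.frame(kind = character(0), start1 = integer(0),
                      end1 = integer(0), start2 = integer(0),
                      end2 = integer(0), arm_len = integer(0),
                      tbe_candidate = logical(0))
  if (L < 2L * min_arm) return(empty)

  kmers <- substring(dna, 1:(L - word + 1L), word:L)
  valid <- !grepl("N", kmers, fixed = TRUE)

  # direct: pairs of positions sharing a word, merged along diagonals
  direct <- diagonal_pairs(kmers, kmers, valid, valid, self = TRUE)
  rcdna <- revcomp(dna)
  rck <- substring(rcdna, 1:(L - word + 1L), word:L)
  rcvalid <- !grepl("N", rck, fixed = TRUE)
  inv <- diagonal_pairs(kmers, rck, valid, rcvalid, self = FALSE)

  rows <- list()
  mk <- function(p1, p2, len, kind) {
    data.frame(kind = kind, start1 = p1, end1 = p1 + len - 1L,
               start2 = p2, end2 = p2 + len - 1L, arm_len = len,
               stringsAsFactors = FALSE)
  }
  for (r in direct) {
    len <- r$len + word - 1L
    if (len < min_arm) next
    p1 <- r$i; p2 <- r$j
    if (p2 < p1) { tmp <- p1; p1 <- p2; p2 <- tmp }
    if (p1 + len - 1L >= p2) next # overlapping arms
    rows[[length(rows) + 1L]] <- mk(p1, p2, len, "direct")
  }
  for (r in inv) {
    len <- r$len + word - 1L
    if (len < min_arm) next
    p1 <- r$i
    # arm2 on the forward strand: rc position j covers forward span
    p2 <- L - (r$j + len - 1L) + 1L
    if (p2 < p1) next # keep one orientation of each symmetric pair
    if (p1 + len - 1L >= p2) next
    rows[[length(rows) + 1L]] <- mk(p1, p2, len, "inverted")
  }
  if (length(rows) == 0) return(empty)
  out <- unique(do.call(rbind, rows))
  out$tbe_candidate <- if (!is.null(tbe_from)) {
    out$kind == "direct" & out$start1 >= tbe_from & out$start2 >= tbe_from
  } else rep(FALSE, nrow(out))
  out <- out[order(out$kind, out$start1), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# merge shared-word seed pairs into maximal diagonal runs; returns a list of
# list(i, j, len) with len in words
diagonal_pairs <- function(k1, k2, v1, v2, self = FALSE) {
  idx2 <- split(which(v2), k2[v2])
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (i in which(v1)) {
    js <- idx2[[k1[i]]]
    if (is.null(js)) next
    if (self) js <- js[js > i]
    if (length(js) > 0) {
      pairs_i <- c(pairs_i, rep.int(i, length(js)))
      pairs_j <- c(pairs_j, js)
    }
  }
  if (length(pairs_i) == 0) return(list())
  diag <- pairs_j - pairs_i
  ord <- order(diag, pairs_i)
  pairs_i <- pairs_i[ord]; pairs_j <- pairs_j[ord]; diag <- diag[ord]
  runs <- list()
  s <- 1L
  n <- length(pairs_i)
  for (t in seq_len(n)) {
    if (t == n || diag[t + 1L] != diag[t] ||
        pairs_i[t + 1L] != pairs_i[t] + 1L) {
      runs[[length(runs) + 1L]] <- list(i = pairs_i[s], j = pairs_j[s],
                                        len = t - s + 1L)
      s <- t + 1L
    }
  }
  runs
}
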