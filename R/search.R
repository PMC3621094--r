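#' Translated homology search of protein queries against DNA scaffolds
#'
#' Six-frame translates every scaffold and runs an exact affine-gap
#' Smith-Waterman of each query protein against each frame (no heuristic
#' seeding; desk-scale inputs make full DP affordable). Hits are assessed
#' with Karlin-Altschul statistics, E = K*m*n*exp(-lambda*S), where m is
#' the query length and n the total number of translated residues searched,
#' and reported when E falls below the cutoff. Secondary hits on the same
#' frame are recovered by masking accepted target spans to X and
#' re-aligning (up to `max_hits_per_frame` iterations), so several
#' proviruses on one scaffold are each reported.
#'
#' @param query_set named list of named character vectors of protein
#'   queries, one list element per gene class, e.g.
#'   `list(gag = c(ref1 = "..."), pol = ..., env = ...)`.
#' @param scaffolds named character vector of DNA scaffolds (or a list of
#'   `synth_scaffold` objects).
#' @param params an [alignment_params()] object.
#' @param max_hits_per_frame cap on mask-and-realign iterations.
#' @return data.frame with BLAST-tabular-like columns: `gene`, `qid`, `sid`,
#'   `frame`, `strand`, `pident`, `length`, `qstart`, `qend`, `sstart`,
#'   `send` (1-based inclusive DNA coordinates on the forward strand),
#'   `score`, `evalue`; sorted by E ascending.
#' @export
search_genome <- function(query_set, scaffolds, params = alignment_params(),
                          max_hits_per_frame = 4L) {
  stopifnot(length(query_set) >= 1)
  scaffolds <- as_scaffold_set(scaffolds)
  empty <- data.frame(gene = character(0), qid = character(0),
                      sid = character(0), frame = integer(0),
                      strand = character(0), pident = numeric(0),
                      length = integer(0), qstart = integer(0),
                      qend = integer(0), sstart = integer(0),
                      send = integer(0), score = numeric(0),
                      evalue = numeric(0))
  if (length(scaffolds) == 0) return(empty)

  frames <- lapply(scaffolds, six_frame_translate)
  n_db <- sum(vapply(frames, function(fs)
    sum(vapply(fs, function(f) nchar(f$aa), 1L)), 1L))

  alpha <- rownames(params$matrix)
  x_code <- match("X", alpha) - 1L
  # integer-code every frame once; masking happens in code space
  frame_codes <- lapply(frames, function(fs)
    lapply(fs, function(f) aa_codes(f$aa, alpha)))

  rows <- list()
  for (gene in names(query_set)) {
    for (qid in names(query_set[[gene]])) {
      qseq <- query_set[[gene]][[qid]]
      if (params$low_complexity_filter) qseq <- mask_low_complexity(qseq)
      m <- nchar(qseq)
      qcode <- aa_codes(qseq, alpha)
      # score needed to clear the cutoff; skip tracebacks below it
      s_min <- log(params$K * m * n_db / params$evalue_cutoff) / params$lambda
      for (sid in names(frames)) {
        for (fi in seq_along(frames[[sid]])) {
          f <- frames[[sid]][[fi]]
          tcode <- frame_codes[[sid]][[fi]]
          for (it in seq_len(max_hits_per_frame)) {
            sc <- cpp_sw_align(qcode, tcode, params$matrix,
                               params$gap_open, params$gap_extend,
                               traceback = FALSE)
            if (sc$score < s_min) break
            al <- cpp_sw_align(qcode, tcode, params$matrix,
                               params$gap_open, params$gap_extend,
                               traceback = TRUE)
            dsp <- aa_to_dna(f$frame, al$tstart, al$tend, f$dna_len)
            rows[[length(rows) + 1L]] <- data.frame(
              gene = gene, qid = qid, sid = sid, frame = f$frame,
              strand = if (f$frame > 0) "+" else "-",
              pident = round(100 * al$matches / al$length, 2),
              length = al$length, qstart = al$qstart, qend = al$qend,
              sstart = dsp[1], send = dsp[2], score = al$score,
              evalue = evalue(al$score, m, n_db, params),
              stringsAsFactors = FALSE)
            # mask the hit and look for further copies
            tcode[al$tstart:al$tend] <- x_code
          }
        }
      }
    }
  }
  if (length(rows) == 0) return(empty)
  hits <- do.call(rbind, rows)
  hits <- hits[hits$evalue < params$evalue_cutoff, , drop = FALSE]
  hits[order(hits$evalue), , drop = FALSE]
}

as_scaffold_set <- function(scaffolds) {
  if (is.character(scaffolds)) return(as.list(scaffolds))
  if (inherits(scaffolds, "synth_scaffold")) scaffolds <- list(scaffolds)
  if (is.list(scaffolds) && all(vapply(scaffolds, inherits, TRUE,
                                       "synth_scaffold"))) {
    return(setNames(lapply(scaffolds, `[[`, "seq"),
                    vapply(scaffolds, `[[`, "", "id")))
  }
  stop("scaffolds must be a named character vector or synth_scaffold list")
}

#' Per-gene hit summary (lowest E-value and hit count)
#'
#' @param hits a hit table from [search_genome()].
#' @return data.frame with `gene`, `qid`, `lowest_evalue`, `n_hits`.
#' @export
summarize_hits <- function(hits) {
  if (nrow(hits) == 0)
    return(data.frame(gene = character(0), qid = character(0),
                      lowest_evalue = numeric(0), n_hits = integer(0)))
  sp <- split(hits, list(hits$gene, hits$qid), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(h) data.frame(
    gene = h$gene[1], qid = h$qid[1], lowest_evalue = min(h$evalue),
    n_hits = nrow(h), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$gene, out$qid), , drop = FALSE]
}

#' Intersect gag/pol/env hits into candidate full-length loci
#'
#' A candidate locus is a scaffold region carrying colinear, same-strand
#' gag, pol and env hits in gene order within `max_span` nt. Overlapping
#' triples are merged; the bounding span is padded by `flank` nt on each
#' side (clipped to the scaffold) to keep the flanking LTRs and target-site
#' duplications inside the locus.
#'
#' @param hits hit table from [search_genome()] (must contain gene classes
#'   `gag`, `pol`, `env`).
#' @param scaffold_lengths named integer vector of scaffold lengths (for
#'   clipping the padding); optional.
#' @param max_span maximum extent of the gag..env span, nt.
#' @param flank padding added to each side of the bounding span, nt.
#' @return data.frame of class `candidate_loci`: `sid`, `strand`,
#'   `gag_start`, `gag_end`, `pol_start`, `pol_end`, `env_start`, `env_end`,
#'   `start`, `end` (padded locus span).
#' @export
intersect_gene_hits <- function(hits, scaffold_lengths = NULL,
                                max_span = 15000L, flank = 2000L) {
  empty <- data.frame(sid = character(0), strand = character(0),
                      gag_start = integer(0), gag_end = integer(0),
                      pol_start = integer(0), pol_end = integer(0),
                      env_start = integer(0), env_end = integer(0),
                      start = integer(0), end = integer(0))
  need <- c("gag", "pol", "env")
  if (nrow(hits) == 0 || !all(need %in% hits$gene)) return(empty)

  loci <- list()
  for (sid in unique(hits$sid)) {
    for (strand in c("+", "-")) {
      h <- hits[hits$sid == sid & hits$strand == strand, , drop = FALSE]
      if (!all(need %in% h$gene)) next
      best_per_gene <- function(g) {
        x <- h[h$gene == g, , drop = FALSE]
        x$mid <- (x$sstart + x$send) / 2
        x[order(x$evalue), , drop = FALSE]
      }
      gg <- best_per_gene("gag"); pp <- best_per_gene("pol")
      ee <- best_per_gene("env")
      for (i in seq_len(nrow(gg))) for (j in seq_len(nrow(pp)))
        for (k in seq_len(nrow(ee))) {
          ordered <- if (strand == "+")
            gg$mid[i] < pp$mid[j] && pp$mid[j] < ee$mid[k]
          else gg$mid[i] > pp$mid[j] && pp$mid[j] > ee$mid[k]
          if (!ordered) next
          lo <- min(gg$sstart[i], pp$sstart[j], ee$sstart[k])
          hi <- max(gg$send[i], pp$send[j], ee$send[k])
          if (hi - lo + 1L > max_span) next
          loci[[length(loci) + 1L]] <- data.frame(
            sid = sid, strand = strand,
            gag_start = gg$sstart[i], gag_end = gg$send[i],
            pol_start = pp$sstart[j], pol_end = pp$send[j],
            env_start = ee$sstart[k], env_end = ee$send[k],
            start = lo, end = hi, evalue = gg$evalue[i] + pp$evalue[j] +
              ee$evalue[k],
            stringsAsFactors = FALSE)
        }
    }
  }
  if (length(loci) == 0) return(empty)
  loci <- do.call(rbind, loci)

  # merge overlapping triples per scaffold/strand, keeping the best triple
  merged <- list()
  for (key in unique(paste(loci$sid, loci$strand))) {
    x <- loci[paste(loci$sid, loci$strand) == key, , drop = FALSE]
    x <- x[order(x$start), , drop = FALSE]
    cur <- x[1, , drop = FALSE]
    if (nrow(x) > 1) for (i in 2:nrow(x)) {
      if (x$start[i] <= cur$end) {
        if (x$evalue[i] < cur$evalue) {
          keep_lo <- min(cur$start, x$start[i])
          keep_hi <- max(cur$end, x$end[i])
          cur <- x[i, , drop = FALSE]
          cur$start <- keep_lo; cur$end <- keep_hi
        } else {
          cur$end <- max(cur$end, x$end[i])
          cur$start <- min(cur$start, x$start[i])
        }
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- x[i, , drop = FALSE]
      }
    }
    merged[[length(merged) + 1L]] <- cur
  }
  out <- do.call(rbind, merged)
  out$evalue <- NULL

  # pad by flank, clip to scaffold
  out$start <- pmax(1L, out$start - as.integer(flank))
  if (!is.null(scaffold_lengths)) {
    out$end <- pmin(as.integer(scaffold_lengths[out$sid]),
                    out$end + as.integer(flank))
  } else {
    out$end <- out$end + as.integer(flank)
  }
  rownames(out) <- NULL
  class(out) <- c("candidate_loci", "data.frame")
  out
}
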