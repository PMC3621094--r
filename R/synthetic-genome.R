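#' @title Synthetic genomes with planted betaretroviral proviruses
#'
#' @description
#' Generator for background scaffolds, provirus templates built from the
#' synthetic reference panel, neutral post-integration decay, and a ground
#' truth channel, so that search, delineation, annotation, dating and
#' classification can all be validated against known answers without any
#' external data.
#' @name synthetic-genome
NULL

#' Background scaffold
#'
#' I.i.d. nucleotides with a target GC content, with optional N-runs
#' emulating the non-sequenced regions (NSR) of a low-coverage assembly.
#'
#' @param length scaffold length (>= 1).
#' @param gc expected GC fraction in (0, 1).
#' @param n_run_spec list of 1-based inclusive `c(start, end)` spans to fill
#'   with N; spans outside the sequence are rejected.
#' @param seed optional RNG seed.
#' @param id scaffold identifier.
#' @return an object of class `synth_scaffold`: list with `id`, `seq`,
#'   `n_runs` (data.frame start/end).
#' @export
make_background <- function(length, gc = 0.5, n_run_spec = list(),
                            seed = NULL, id = "scaffold1") {
  stopifnot(length >= 1, gc > 0, gc < 1)
  if (!is.null(seed)) set.seed(seed)
  seq <- random_dna(length, gc)
  runs <- data.frame(start = integer(0), end = integer(0))
  for (sp in n_run_spec) {
    s <- as.integer(sp[1]); e <- as.integer(sp[2])
    if (s < 1 || e > length || s > e)
      stop("N-run span [", s, ",", e, "] outside sequence of length ", length)
    substr(seq, s, e) <- strrep("N", e - s + 1L)
    runs <- rbind(runs, data.frame(start = s, end = e))
  }
  structure(list(id = id, seq = seq, n_runs = runs), class = "synth_scaffold")
}

#' @export
print.synth_scaffold <- function(x, ...) {
  cat("<synth_scaffold>", x$id, "-", nchar(x$seq), "nt,",
      nrow(x$n_runs), "N-run(s)\n")
  invisible(x)
}

## codon encoding ------------------------------------------------------------

codon_table_inverse <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

encode_protein <- function(aa, add_stop = TRUE) {
  inv <- codon_table_inverse()
  ch <- seq_chars(aa)
  codons <- vapply(ch, function(a) {
    opts <- inv[[a]]
    if (is.null(opts)) stop("cannot encode residue ", a)
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, "")
  paste0(paste(codons, collapse = ""), if (add_stop) "TAA" else "")
}

random_orf_dna <- function(n_codons) {
  inv <- codon_table_inverse()
  sense <- unlist(inv[setdiff(names(inv), "*")], use.names = FALSE)
  sense <- setdiff(sense, c("ATG")) # avoid nested starts dominating
  body <- paste(sample(sense, n_codons - 1L, replace = TRUE), collapse = "")
  paste0("ATG", body, "TAA")
}

## templates -----------------------------------------------------------------

group_config <- function() {
  list(
    I    = list(pol = "HERVK",        pbs = "Lys1_2", ltr = 968L,
                gag = "TYPE_B", env = c("beta", "TYPE_B"), extra = NULL),
    II   = list(pol = "BAT_EARLY",    pbs = "Lys1_2", ltr = 422L,
                gag = "TYPE_B", env = c("beta", "TYPE_B"), extra = NULL),
    III  = list(pol = "MICROBAT_DIV", pbs = "Lys3",   ltr = 479L,
                gag = "TYPE_D", env = c("beta", "TYPE_D"), extra = NULL),
    IV   = list(pol = "TYPE_B",       pbs = "LysAlt", ltr = 500L,
                gag = "TYPE_B", env = c("beta", "TYPE_B"), extra = NULL),
    V    = list(pol = "TYPE_B",       pbs = "Lys3",   ltr = 1265L,
                gag = "TYPE_B", env = c("beta", "TYPE_B"),
                extra = list(placement = "in-LTR", codons = 123L)),
    VI   = list(pol = "TYPE_D",       pbs = "Lys1_2", ltr = 398L,
                gag = "TYPE_D", env = c("beta", "TYPE_D"), extra = NULL),
    VII  = list(pol = "TYPE_D",       pbs = "Lys3",   ltr = 370L,
                gag = "TYPE_D", env = c("beta", "TYPE_D"),
                extra = list(placement = "pre-gag", codons = 101L)),
    VIII = list(pol = "TYPE_D",       pbs = "Lys1_2", ltr = 427L,
                gag = "TYPE_D", env = c("gamma", "G1"),
                extra = list(placement = "post-env", codons = 90L))
  )
}

#' Provirus template for one of the eight betaretroviral sub-groups
#'
#' Builds a template whose coding genes are codon-encodings of mildly
#' diverged copies of the panel reference proteins, with the group's
#' characteristic LTR length, primer-binding site, env lineage and extra
#' ORFs (a 123-codon ORF inside the LTR for group V, a pre-gag leader ORF
#' for group VII, a short post-env ORF for group VIII).
#'
#' @param group one of `"I"` to `"VIII"`.
#' @param panel a reference panel (see [load_reference_panel()]).
#' @param seed optional RNG seed.
#' @param ltr_len override the group's default LTR length (must lie in
#'   `[300, 1400]`).
#' @param aa_divergence amino-acid divergence of the template's proteins
#'   from the panel references (motif blocks are never mutated).
#' @param name template name.
#' @return an object of class `provirus_template`.
#' @export
betaretro_template <- function(group = "V", panel = load_reference_panel(),
                               seed = NULL, ltr_len = NULL,
                               aa_divergence = 0.03,
                               name = paste0("synthERV-", group)) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- group_config()[[match.arg(group, names(group_config()))]]
  if (is.null(ltr_len)) ltr_len <- cfg$ltr
  stopifnot(ltr_len >= 300, ltr_len <= 1400)

  fam <- cfg$gag
  prot <- list(
    gag = mutate_protein(panel$proteins$gag[[fam]], aa_divergence,
                         protected_positions("gag")),
    pro = mutate_protein(panel$proteins$pro[[fam]], aa_divergence,
                         protected_positions("pro")),
    pol = mutate_protein(panel$proteins$pol[[cfg$pol]], aa_divergence,
                         protected_positions("pol")),
    env = mutate_protein(
      if (cfg$env[1] == "beta") panel$proteins$env_beta[[cfg$env[2]]]
      else panel$proteins$env_gamma[[cfg$env[2]]], aa_divergence)
  )
  genes <- lapply(prot, encode_protein)

  # LTR with canonical TG...CA termini, optionally with an embedded ORF
  # (group V architecture)
  ltr <- random_dna(ltr_len, gc = 0.45)
  substr(ltr, 1L, 2L) <- "TG"
  substr(ltr, ltr_len - 1L, ltr_len) <- "CA"
  extra <- cfg$extra
  if (!is.null(extra) && extra$placement == "in-LTR") {
    orf <- random_orf_dna(extra$codons + 1L)
    at <- max(1L, floor(ltr_len * 0.25))
    stopifnot(at + nchar(orf) - 1L <= ltr_len)
    substr(ltr, at, at + nchar(orf) - 1L) <- orf
  }

  pbs <- revcomp(panel$trna[[cfg$pbs]])
  leader <- if (!is.null(extra) && extra$placement == "pre-gag") {
    paste0(random_dna(30, 0.45), random_orf_dna(extra$codons + 1L),
           random_dna(26, 0.45))
  } else {
    random_dna(90, 0.45)
  }
  post_env <- if (!is.null(extra) && extra$placement == "post-env") {
    paste0(random_dna(40, 0.45), random_orf_dna(extra$codons + 1L),
           random_dna(20, 0.45))
  } else {
    random_dna(50, 0.45)
  }
  ppt <- paste(sample(PURINES, 19, replace = TRUE, prob = c(0.45, 0.55)),
               collapse = "")

  structure(list(
    name = name, group = group, ltr_seq = ltr, pbs_trna = cfg$pbs,
    pbs_seq = pbs, leader_seq = leader, genes = genes, proteins = prot,
    post_env_seq = post_env, ppt_seq = ppt,
    extra_orfs = extra, env_lineage = cfg$env[1], pol_cluster = cfg$pol),
    class = "provirus_template")
}

#' @export
print.provirus_template <- function(x, ...) {
  cat("<provirus_template>", x$name, "group", x$group,
      "| LTR", nchar(x$ltr_seq), "nt | PBS", x$pbs_trna,
      "| env", x$env_lineage, "\n")
  invisible(x)
}

#' Assemble a provirus from a template
#'
#' Layout: 5'LTR + PBS + leader + gag + pro + pol + env + post-env + PPT +
#' 3'LTR, with the two LTRs exactly identical (the age-zero state) and the
#' PPT immediately 5' of the 3' LTR. Short spacers separate the core genes.
#'
#' @param template a [betaretro_template()] object.
#' @return list of class `provirus_build` with `seq`, `map` (data.frame
#'   element/start/end, 1-based inclusive), and the `template`.
#' @export
build_provirus <- function(template) {
  stopifnot(inherits(template, "provirus_template"))
  parts <- list(
    ltr5 = template$ltr_seq,
    pbs = template$pbs_seq,
    leader = template$leader_seq,
    gag = template$genes$gag,
    spacer1 = random_dna(10, 0.45),
    pro = template$genes$pro,
    spacer2 = random_dna(10, 0.45),
    pol = template$genes$pol,
    spacer3 = random_dna(10, 0.45),
    env = template$genes$env,
    post_env = template$post_env_seq,
    ppt = template$ppt_seq,
    ltr3 = template$ltr_seq
  )
  lens <- vapply(parts, nchar, 1L)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  map <- data.frame(element = names(parts), start = unname(starts),
                    end = unname(ends), stringsAsFactors = FALSE)
  structure(list(seq = paste(unlist(parts), collapse = ""), map = map,
                 template = template), class = "provirus_build")
}

#' @export
print.provirus_build <- function(x, ...) {
  cat("<provirus_build>", x$template$name, "-", nchar(x$seq), "nt\n")
  invisible(x)
}

## decay ----------------------------------------------------------------------

#' Neutral post-integration decay parameters
#'
#' @param rate_R substitution rate (substitutions/site/year), > 0.
#' @param age_T age in years, >= 0.
#' @param indel_rate indel events as a fraction of the substitution rate,
#'   in `[0, 0.2]`; indel lengths are uniform on 1-3 nt.
#' @param seed optional RNG seed applied by [plant()].
#' @return object of class `decay_params`.
#' @export
decay_params <- function(rate_R, age_T, indel_rate = 0.05, seed = NULL) {
  stopifnot(rate_R > 0, age_T >= 0, indel_rate >= 0, indel_rate <= 0.2)
  structure(list(rate_R = rate_R, age_T = age_T, indel_rate = indel_rate,
                 seed = seed), class = "decay_params")
}

# draw substitution and indel events for a sequence of length L under a
# per-site Poisson(lambda) substitution load; positions refer to the
# original coordinates (substitutions are applied before indels, indels in
# decreasing position order)
draw_events <- function(L, lambda, indel_rate) {
  ev <- data.frame(type = character(0), pos = integer(0), len = integer(0),
                   to = character(0), stringsAsFactors = FALSE)
  if (L == 0 || lambda <= 0) return(ev)
  n_sub <- rpois(1, L * lambda)
  if (n_sub > 0) {
    pos <- sample.int(L, n_sub, replace = TRUE)
    ev <- rbind(ev, data.frame(type = "sub", pos = pos, len = 1L,
                               to = NA_character_, stringsAsFactors = FALSE))
  }
  n_ind <- rpois(1, L * lambda * indel_rate)
  if (n_ind > 0) {
    pos <- sample.int(L, n_ind, replace = TRUE)
    len <- sample(1:3, n_ind, replace = TRUE)
    typ <- sample(c("ins", "del"), n_ind, replace = TRUE)
    ins_seq <- vapply(len, function(k) random_dna(k, 0.5), "")
    ev <- rbind(ev, data.frame(type = typ, pos = pos, len = len,
                               to = ifelse(typ == "ins", ins_seq, NA),
                               stringsAsFactors = FALSE))
  }
  ev
}

#' Apply mutation events to a sequence
#'
#' Substitutions (`sub`) replace the base at `pos` with `to` (or a random
#' different base when `to` is NA); insertions (`ins`) insert `to` before
#' `pos`; deletions (`del`) remove `len` bases starting at `pos`.
#' Substitutions are applied first (original coordinates), then indels in
#' decreasing position order, so all event positions refer to the original
#' sequence.
#'
#' @param seq DNA sequence.
#' @param events data.frame with columns type, pos, len, to.
#' @return mutated sequence.
#' @export
apply_events <- function(seq, events) {
  if (nrow(events) == 0) return(seq)
  subs <- events[events$type == "sub", , drop = FALSE]
  for (i in seq_len(nrow(subs))) {
    p <- subs$pos[i]
    cur <- substr(seq, p, p)
    if (cur == "N") next
    to <- subs$to[i]
    if (is.na(to)) to <- sample(setdiff(DNA_BASES, cur), 1L)
    substr(seq, p, p) <- to
  }
  ind <- events[events$type != "sub", , drop = FALSE]
  if (nrow(ind) > 0) {
    ind <- ind[order(-ind$pos), , drop = FALSE]
    for (i in seq_len(nrow(ind))) {
      p <- ind$pos[i]
      if (ind$type[i] == "ins") {
        seq <- paste0(substr(seq, 1, p - 1L), ind$to[i],
                      substr(seq, p, nchar(seq)))
      } else {
        e <- min(p + ind$len[i] - 1L, nchar(seq))
        seq <- paste0(substr(seq, 1, p - 1L), substr(seq, e + 1L, nchar(seq)))
      }
    }
  }
  seq
}

#' Plant a provirus into a scaffold with neutral decay
#'
#' Duplicates a 4-nt target site (TSD, drawn uniformly among non-homopolymer
#' 4-mers) flanking the provirus and lets each element of the provirus
#' accumulate Poisson(rate_R x age_T) substitutions per site (plus indels at
#' `indel_rate`) independently -- in particular the two LTRs diverge with
#' expectation 2 x rate_R x age_T. Ground truth records the insertion point,
#' the TSD, realized element spans and every mutation event.
#'
#' @param scaffold a `synth_scaffold`.
#' @param provirus a `provirus_build`.
#' @param decay a [decay_params()] object.
#' @param insert_pos 1-based position after which the provirus is inserted;
#'   drawn at random (outside N-runs) when NULL.
#' @return list with the modified `scaffold` and a `truth` object of class
#'   `plant_truth`.
#' @export
plant <- function(scaffold, provirus, decay, insert_pos = NULL) {
  stopifnot(inherits(scaffold, "synth_scaffold"),
            inherits(provirus, "provirus_build"),
            inherits(decay, "decay_params"))
  if (!is.null(decay$seed)) set.seed(decay$seed)
  L <- nchar(scaffold$seq)
  in_nrun <- function(p) {
    nrow(scaffold$n_runs) > 0 &&
      any(p >= scaffold$n_runs$start & p <= scaffold$n_runs$end)
  }
  if (is.null(insert_pos)) {
    repeat {
      insert_pos <- sample(seq(10L, L - 10L), 1L)
      if (!in_nrun(insert_pos)) break
    }
  } else if (in_nrun(insert_pos)) {
    stop("insertion site lies inside an N-run")
  }

  repeat {
    tsd <- random_dna(4, 0.5)
    if (length(unique(seq_chars(tsd))) > 1L) break
  }

  lambda <- decay$rate_R * decay$age_T
  map <- provirus$map
  pieces <- character(nrow(map))
  events <- vector("list", nrow(map))
  for (i in seq_len(nrow(map))) {
    el <- substr(provirus$seq, map$start[i], map$end[i])
    ev <- draw_events(nchar(el), lambda, decay$indel_rate)
    pieces[i] <- apply_events(el, ev)
    events[[i]] <- ev
  }
  names(events) <- map$element

  body <- paste(pieces, collapse = "")
  newseq <- paste0(substr(scaffold$seq, 1, insert_pos), tsd, body, tsd,
                   substr(scaffold$seq, insert_pos + 1L, L))

  lens <- nchar(pieces)
  offset <- insert_pos + 4L # after 5' TSD
  ends <- offset + cumsum(lens)
  starts <- ends - lens + 1L
  spans <- data.frame(element = map$element, start = starts, end = ends,
                      stringsAsFactors = FALSE)
  spans <- rbind(
    data.frame(element = "tsd5", start = insert_pos + 1L,
               end = insert_pos + 4L),
    spans,
    data.frame(element = "tsd3", start = ends[length(ends)] + 1L,
               end = ends[length(ends)] + 4L))

  ins_len <- nchar(newseq) - L
  n_runs <- scaffold$n_runs
  if (nrow(n_runs) > 0) {
    shift <- n_runs$start > insert_pos
    n_runs$start[shift] <- n_runs$start[shift] + ins_len
    n_runs$end[shift] <- n_runs$end[shift] + ins_len
  }

  ltr5 <- pieces[map$element == "ltr5"]
  ltr3 <- pieces[map$element == "ltr3"]
  div <- ltr_divergence(ltr5, ltr3)

  truth <- structure(list(
    scaffold_id = scaffold$id, insert_pos = insert_pos, tsd = tsd,
    spans = spans, events = events,
    template = provirus$template$name, group = provirus$template$group,
    pbs_trna = provirus$template$pbs_trna,
    env_lineage = provirus$template$env_lineage,
    pol_cluster = provirus$template$pol_cluster,
    rate_R = decay$rate_R, age_T = decay$age_T,
    realized_divergence = div$D), class = "plant_truth")

  out <- scaffold
  out$seq <- newseq
  out$n_runs <- n_runs
  list(scaffold = out, truth = truth)
}

#' @export
print.plant_truth <- function(x, ...) {
  cat("<plant_truth>", x$template, "in", x$scaffold_id, "at", x$insert_pos,
      "| TSD", x$tsd, "| age", x$age_T / 1e6, "Myr | D =",
      signif(x$realized_divergence, 3), "\n")
  invisible(x)
}

#' Minimal provirus for calibration experiments
#'
#' A bare LTR-body-LTR element (no genes) used to study LTR-divergence
#' dating in isolation: planting it and re-estimating the age exercises the
#' decay model and the molecular clock without the cost of a full template.
#'
#' @param ltr_len LTR length, nt.
#' @param body_len internal body length, nt.
#' @param gc GC content.
#' @return a `provirus_build`.
#' @export
toy_provirus <- function(ltr_len = 500L, body_len = 300L, gc = 0.45) {
  ltr <- random_dna(ltr_len, gc)
  substr(ltr, 1L, 2L) <- "TG"
  substr(ltr, ltr_len - 1L, ltr_len) <- "CA"
  body <- random_dna(body_len, gc)
  parts <- list(ltr5 = ltr, body = body, ltr3 = ltr)
  lens <- vapply(parts, nchar, 1L)
  ends <- cumsum(lens)
  map <- data.frame(element = names(parts), start = ends - lens + 1L,
                    end = ends, stringsAsFactors = FALSE)
  tpl <- structure(list(name = "toy", group = NA_character_,
                        pbs_trna = NA_character_, env_lineage = NA_character_,
                        pol_cluster = NA_character_),
                   class = "provirus_template")
  structure(list(seq = paste(unlist(parts), collapse = ""), map = map,
                 template = tpl), class = "provirus_build")
}

#' Fragment a provirus into overlapping transcript contigs
#'
#' Tiles the provirus left to right with the given fragment lengths such
#' that consecutive fragments overlap by exactly `overlap` nt (with
#' identical overlap sequence, being substrings of the same source). The
#' tiling must cover the provirus exactly:
#' `sum(fragment_lengths) - (k-1)*overlap == nchar(dna)`.
#'
#' @param dna provirus DNA.
#' @param fragment_lengths integer vector of fragment lengths (>= 2).
#' @param overlap exact overlap between consecutive fragments; must be
#'   >= 1 (a zero overlap could not support a later identity merge) and
#'   smaller than every fragment.
#' @param seed optional seed (fragments are emitted in shuffled order).
#' @return list with `seqs` (named character vector) and `coords`
#'   (data.frame id/start/end on the source).
#' @export
make_transcripts <- function(dna, fragment_lengths, overlap, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(dna)
  k <- length(fragment_lengths)
  stopifnot(k >= 2)
  if (overlap < 1) stop("overlap must be >= 1 for a later identity merge")
  if (overlap >= min(fragment_lengths))
    stop("overlap must be smaller than every fragment")
  if (any(fragment_lengths > L)) stop("fragment longer than the provirus")
  starts <- integer(k)
  starts[1] <- 1L
  for (i in 2:k) starts[i] <- starts[i - 1] + fragment_lengths[i - 1] - overlap
  ends <- starts + fragment_lengths - 1L
  if (ends[k] != L)
    stop("fragment lengths and overlap do not tile the provirus exactly (",
         "cover ", ends[k], " of ", L, " nt)")
  ids <- paste0("frag", seq_len(k))
  seqs <- setNames(substring(dna, starts, ends), ids)
  ord <- sample(k)
  list(seqs = seqs[ord],
       coords = data.frame(id = ids, start = starts, end = ends,
                           stringsAsFactors = FALSE))
}
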