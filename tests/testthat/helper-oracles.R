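# Independent brute-force oracles and shared fixtures.

# Affine-gap local alignment oracle: plain three-matrix DP written independently
# of the package's C++ engine. Gap of length k costs open + k * ext.
oracle_sw_score <- function(q, t, mat, open = 11, ext = 1) {
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  m <- length(qc); n <- length(tc)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  for (i in 1:m) for (j in 1:n) {
    E[i + 1, j + 1] <- max(H[i + 1, j] - (open + ext), E[i + 1, j] - ext)
    F[i + 1, j + 1] <- max(H[i, j + 1] - (open + ext), F[i, j + 1] - ext)
    H[i + 1, j + 1] <- max(0, H[i, j] + mat[qc[i], tc[j]],
                           E[i + 1, j + 1], F[i + 1, j + 1])
  }
  max(H)
}

# codon-walk translation oracle
oracle_translate <- function(dna, frame) {
  code <- c(TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
            ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
            TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
            ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
            TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
            AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
            TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
            AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")
  rc <- function(x) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }
  src <- if (frame > 0) dna else rc(dna)
  off <- abs(frame) - 1
  aa <- character(0)
  i <- off + 1
  while (i + 2 <= nchar(src)) {
    cod <- substr(src, i, i + 2)
    aa <- c(aa, if (cod %in% names(code)) code[[cod]] else "X")
    i <- i + 3
  }
  paste(aa, collapse = "")
}

# exhaustive PPT window oracle
oracle_ppt <- function(upstream, min_len = 12, min_purine = 0.85,
                       max_gap = 5) {
  L <- nchar(upstream)
  if (L < min_len) return(NULL)
  ch <- strsplit(upstream, "")[[1]]
  best <- NULL
  for (s in 1:(L - min_len + 1)) for (e in (s + min_len - 1):L) {
    if (L - e > max_gap) next
    w <- ch[s:e]
    frac <- mean(w %in% c("A", "G"))
    if (frac >= min_purine) {
      len <- e - s + 1
      if (is.null(best) || len > best$length ||
          (len == best$length && e > best$end))
        best <- list(start = s, end = e, length = len,
                     purine_fraction = frac)
    }
  }
  best
}

# exhaustive per-frame ORF oracle (forward frames)
oracle_orfs <- function(dna, min_codons = 100) {
  stops <- c("TAA", "TAG", "TGA")
  out <- data.frame(start = integer(0), end = integer(0),
                    codons = integer(0))
  for (off in 0:2) {
    n <- (nchar(dna) - off) %/% 3
    if (n < 1) next
    cods <- substring(dna, off + 1 + 3 * (0:(n - 1)), off + 3 * (1:n))
    prev <- 0
    for (i in which(cods %in% stops)) {
      cands <- which(cods[(prev + 1):(i - 1)] == "ATG")
      if (length(cands) > 0) {
        a <- prev + cands[1]
        if (i - a >= min_codons) {
          out <- rbind(out, data.frame(start = off + 3 * (a - 1) + 1,
                                       end = off + 3 * i,
                                       codons = i - a))
        }
      }
      prev <- i
    }
  }
  out[order(out$start), , drop = FALSE]
}

# exhaustive repeat oracle: all maximal shared-word diagonal runs
oracle_direct_repeats <- function(dna, word = 11, min_arm = 11) {
  L <- nchar(dna)
  ks <- substring(dna, 1:(L - word + 1), word:L)
  hits <- list()
  for (i in seq_along(ks)) for (j in seq_along(ks)) {
    if (j <= i) next
    if (ks[i] == ks[j]) hits[[length(hits) + 1]] <- c(i, j)
  }
  if (length(hits) == 0) return(data.frame(start1 = integer(0)))
  h <- do.call(rbind, hits)
  d <- h[, 2] - h[, 1]
  h <- h[order(d, h[, 1]), , drop = FALSE]
  d <- h[, 2] - h[, 1]
  runs <- list()
  s <- 1
  for (t in seq_len(nrow(h))) {
    if (t == nrow(h) || d[t + 1] != d[t] || h[t + 1, 1] != h[t, 1] + 1) {
      len <- (t - s + 1) + word - 1
      if (len >= min_arm && h[s, 1] + len - 1 < h[s, 2])
        runs[[length(runs) + 1]] <- data.frame(
          start1 = h[s, 1], end1 = h[s, 1] + len - 1,
          start2 = h[s, 2], end2 = h[s, 2] + len - 1, arm_len = len)
      s <- t + 1
    }
  }
  if (length(runs) == 0) return(data.frame(start1 = integer(0)))
  do.call(rbind, runs)
}

# shared fixture cache (expensive synthetic worlds built once per run)
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

panel_fixture <- function() fixture("panel", function() load_reference_panel())

# 20 planted proviruses (LTR divergence <= 0.06) plus clean scaffolds, with
# the slim Type D query set used for the recall experiments
recall_world <- function() fixture("recall_world", function() {
  panel <- panel_fixture()
  set.seed(424242)
  groups <- rep(c("III", "VI", "VII"), length.out = 20)
  plants <- vector("list", 20)
  scaffolds <- vector("list", 20)
  rate <- default_rates()[["megabat"]]
  for (i in 1:20) {
    tpl <- betaretro_template(groups[i], panel)
    pv <- build_provirus(tpl)
    bg <- make_background(2000, gc = 0.42, id = sprintf("plant_%02d", i))
    # ages chosen so realized divergence 2RT stays <= 0.06
    age <- sample(seq(2e6, 6e7, by = 2e6), 1)
    res <- plant(bg, pv, decay_params(rate, age, indel_rate = 0.05))
    plants[[i]] <- res$truth
    scaffolds[[i]] <- res$scaffold
  }
  clean <- lapply(1:50, function(j)
    make_background(6000, gc = 0.42, id = sprintf("clean_%02d", j)))
  queries <- list(gag = panel$proteins$gag["TYPE_D"],
                  pol = panel$proteins$pol["TYPE_D"],
                  env = panel$proteins$env_beta["TYPE_D"])
  list(plants = plants, scaffolds = scaffolds, clean = clean,
       queries = queries, panel = panel)
})

recall_hits <- function() fixture("recall_hits", function() {
  w <- recall_world()
  all_sc <- c(w$scaffolds, w$clean)
  hits <- search_genome(w$queries, all_sc)
  lens <- setNames(vapply(all_sc, function(s) nchar(s$seq), 1L),
                   vapply(all_sc, `[[`, "", "id"))
  loci <- intersect_gene_hits(hits, scaffold_lengths = lens)
  list(hits = hits, loci = loci, lens = lens)
})

# delineated records for every planted locus, keyed by scaffold id
recall_records <- function() fixture("recall_records", function() {
  w <- recall_world()
  rh <- recall_hits()
  all_seqs <- setNames(
    lapply(c(w$scaffolds, w$clean), `[[`, "seq"),
    vapply(c(w$scaffolds, w$clean), `[[`, "", "id"))
  recs <- list()
  for (i in seq_len(nrow(rh$loci))) {
    lc <- rh$loci[i, ]
    recs[[lc$sid]] <- delineate_provirus(all_seqs[[lc$sid]], lc, w$panel,
                                         full = FALSE)
  }
  recs
})
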