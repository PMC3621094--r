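#' @title Synthetic reference panel
#'
#' @description
#' The pipeline anchors its searches, motif scans and phylogenetic proxy on
#' a panel of reference Gag/Pro/Pol/Env proteins plus a lysine-tRNA 3'-end
#' library. The packaged panel is *synthetic*: deterministic pseudo-proteins
#' that reproduce the architecture of extant betaretroviral references
#' (conserved MHR and CCHC zinc knuckles in Gag; dUTPase blocks and the
#' DxG protease active site in Pro; the reverse-transcriptase DDD and
#' integrase DDE catalytic residues in Pol; distinct beta and gamma Env
#' families; five Pol lineage clusters at roughly 65-75% pairwise identity,
#' matching the similarity range typical of the genus). They are not real
#' viral sequences and are labelled `synthetic` in the packaged files.
#' @name reference-panel
NULL

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
AA_FREQ <- c(8.3, 5.5, 4.0, 5.5, 1.4, 3.9, 6.7, 7.1, 2.3, 6.0,
             9.7, 5.8, 2.4, 3.9, 4.7, 6.6, 5.3, 1.1, 2.9, 6.9)

#' Evaluate code under a temporary RNG seed
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

random_protein <- function(n) {
  aa <- sample(AA20, n, replace = TRUE, prob = AA_FREQ)
  aa[1] <- "M"
  paste(aa, collapse = "")
}

# substitute a fraction of residues, never touching protected positions
mutate_protein <- function(aa, rate, protected = integer(0)) {
  ch <- seq_chars(aa)
  cand <- setdiff(2:length(ch), protected)
  k <- round(rate * length(cand))
  pos <- sample(cand, k)
  ch[pos] <- vapply(ch[pos], function(a) sample(setdiff(AA20, a), 1), "")
  paste(ch, collapse = "")
}

plant_block <- function(aa, anchor, block) {
  substr(aa, anchor, anchor + nchar(block) - 1L) <- block
  aa
}

# motif blocks written into every reference variant at fixed anchors
motif_blocks <- function() {
  list(
    gag = list(c(300, "QGPKEPFQSYVDRLLQ"),   # major homology region
               c(420, "CAYCKEKGHWAKDC"),     # zinc knuckle 1 (CCHC)
               c(450, "CQICGKMGHWAKQC")),    # zinc knuckle 2 (CCHC)
    pro = list(c(20,  "AGLDL"), c(60, "GGFGST"), c(95, "DRSS"),
               c(130, "VDADY"), c(165, "RGEGGFGS"),   # dUTPase blocks
               c(230, "DTGA")),                        # protease DxG
    pol = list(c(108, "LVDAG"), c(185, "YVDDL"),       # RT catalytic DDD
               c(678, "CLDGK"), c(730, "GIDWV"),
               c(766, "AGEAV")),                       # IN catalytic DDE
    env = list()
  )
}

#' Motif pattern table
#'
#' One row per pattern block: a motif is called present only when all of its
#' blocks match at their alignment-anchored positions. Patterns are
#' fixed-length regular expressions applied to a small window around the
#' reference anchor mapped through the gene-to-reference alignment.
#'
#' @return data.frame with columns `motif_id`, `gene`, `anchor`, `pattern`.
#' @export
motif_patterns <- function() {
  rbind(
    data.frame(motif_id = "MHR", gene = "gag", anchor = 300L,
               pattern = "Q.P..PFQ.Y.DRL"),
    data.frame(motif_id = "zinc_knuckle_CCHC", gene = "gag", anchor = 420L,
               pattern = "C..C....H....C"),
    data.frame(motif_id = "zinc_knuckle_CCHC", gene = "gag", anchor = 450L,
               pattern = "C..C....H....C"),
    data.frame(motif_id = "dUTPase", gene = "pro",
               anchor = c(20L, 60L, 95L, 130L, 165L),
               pattern = c("AG.DL", "G.FG.T", "DR.S", ".D.DY", "RG.GGF")),
    data.frame(motif_id = "protease_DxG", gene = "pro", anchor = 230L,
               pattern = "D.G"),
    data.frame(motif_id = "RT_DDD", gene = "pol",
               anchor = c(110L, 187L, 188L), pattern = c("D", "D", "D")),
    data.frame(motif_id = "IN_DDE", gene = "pol",
               anchor = c(680L, 732L, 768L), pattern = c("D", "D", "E"))
  )
}

protected_positions <- function(gene) {
  blocks <- motif_blocks()[[gene]]
  if (length(blocks) == 0) return(integer(0))
  unlist(lapply(blocks, function(b) {
    a <- as.integer(b[1]); a:(a + nchar(b[2]) - 1L)
  }))
}

make_gene_ancestor <- function(gene, len) {
  aa <- random_protein(len)
  for (b in motif_blocks()[[gene]]) {
    aa <- plant_block(aa, as.integer(b[1]), b[2])
  }
  aa
}

#' Lysine tRNA 3'-end library (synthetic)
#'
#' 18-mer 3' termini of three lysine tRNA classes. Lys1_2 and Lys3 differ
#' at 5 positions (so a primer-binding site carrying up to two mutations
#' still separates them with a >= 2-match margin); LysAlt differs from both
#' at >= 8 positions. Synthetic stand-ins, not database tRNAs.
#'
#' @return named character vector `c(Lys1_2=, Lys3=, LysAlt=)`.
#' @export
trna_lys_library <- function() {
  lys3 <- "GTCCCTGTTCGGGCGCCA"
  l12 <- seq_chars(lys3)
  l12[c(2, 6, 9, 12, 15)] <- c("G", "A", "C", "T", "T")
  alt <- seq_chars(lys3)
  alt[c(1, 3, 5, 7, 10, 11, 13, 14)] <- c("A", "A", "T", "C", "A", "T", "C", "T")
  c(Lys1_2 = paste(l12, collapse = ""), Lys3 = lys3,
    LysAlt = paste(alt, collapse = ""))
}

#' Generate the synthetic reference panel
#'
#' Deterministic for a given seed. Pol carries five lineage clusters used as
#' the phylogenetic-placement proxy (HERVK, BAT_EARLY, MICROBAT_DIV, TYPE_B,
#' TYPE_D); Gag and Pro carry Type B/D variants; Env carries a beta family
#' and an unrelated gamma family. Motif blocks are identical across variants.
#'
#' @param seed RNG seed.
#' @return list with `proteins` (gag, pro, pol, env_beta, env_gamma; each a
#'   named character vector), `trna`, and `motifs` (pattern table).
#' @export
generate_reference_panel <- function(seed = 101L) {
  with_seed(seed, {
    gag0 <- make_gene_ancestor("gag", 480L)
    pro0 <- make_gene_ancestor("pro", 310L)
    pol0 <- make_gene_ancestor("pol", 860L)
    envb0 <- make_gene_ancestor("env", 540L)
    envg0 <- make_gene_ancestor("env", 540L) # independent gamma family
    pg <- protected_positions("gag")
    pp <- protected_positions("pro")
    pl <- protected_positions("pol")
    pol_clusters <- c("HERVK", "BAT_EARLY", "MICROBAT_DIV", "TYPE_B", "TYPE_D")
    list(
      proteins = list(
        gag = c(TYPE_B = mutate_protein(gag0, 0.08, pg),
                TYPE_D = mutate_protein(gag0, 0.08, pg)),
        pro = c(TYPE_B = mutate_protein(pro0, 0.05, pp),
                TYPE_D = mutate_protein(pro0, 0.05, pp)),
        pol = setNames(vapply(pol_clusters, function(cl)
          mutate_protein(pol0, 0.15, pl), ""), pol_clusters),
        env_beta = c(TYPE_B = mutate_protein(envb0, 0.10),
                     TYPE_D = mutate_protein(envb0, 0.10)),
        env_gamma = c(G1 = mutate_protein(envg0, 0.10),
                      G2 = mutate_protein(envg0, 0.10))
      ),
      trna = trna_lys_library(),
      motifs = motif_patterns()
    )
  })
}

#' Load the packaged synthetic reference panel
#'
#' Reads the FASTA/TSV fixtures under `inst/extdata` (written once from
#' [generate_reference_panel()] with its default seed).
#' @return same structure as [generate_reference_panel()].
#' @export
load_reference_panel <- function() {
  ext <- function(f) system.file("extdata", f, package = "proviscan",
                                 mustWork = TRUE)
  strip <- function(x, prefix) {
    setNames(unname(x), sub(paste0("^", prefix, "\\|"), "", names(x)))
  }
  gag <- read_fasta(ext("refs_gag.synthetic.faa"))
  pro <- read_fasta(ext("refs_pro.synthetic.faa"))
  pol <- read_fasta(ext("refs_pol.synthetic.faa"))
  env <- read_fasta(ext("refs_env.synthetic.faa"))
  env_beta <- env[grepl("^env\\|beta", names(env))]
  env_gamma <- env[grepl("^env\\|gamma", names(env))]
  names(env_beta) <- sub("^env\\|beta\\|", "", names(env_beta))
  names(env_gamma) <- sub("^env\\|gamma\\|", "", names(env_gamma))
  list(
    proteins = list(gag = strip(gag, "gag"), pro = strip(pro, "pro"),
                    pol = strip(pol, "pol"),
                    env_beta = env_beta, env_gamma = env_gamma),
    trna = read_fasta(ext("trna_lys.synthetic.fa")),
    motifs = read.delim(ext("motif_patterns.tsv"), stringsAsFactors = FALSE)
  )
}
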