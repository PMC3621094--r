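test_that("an exact planted coding sequence is found at ~100% identity", {
  panel <- panel_fixture()
  set.seed(21)
  qaa <- panel$proteins$gag[["TYPE_D"]]
  coding <- proviscan:::encode_protein(qaa, add_stop = FALSE)
  sc <- paste0(random_dna(1500, 0.42), coding, random_dna(1500, 0.42))
  hits <- search_genome(list(gag = c(ref = qaa)), c(s1 = sc))
  expect_equal(nrow(hits), 1)
  expect_gt(hits$pident, 99.9)
  expect_lt(hits$evalue, 1e-50)
  expect_equal(hits$sstart, 1501)
  expect_equal(hits$send, 1500 + nchar(coding))
  expect_identical(hits$strand, "+")

  # and on the reverse strand
  hits_rc <- search_genome(list(gag = c(ref = qaa)), c(s1 = revcomp(sc)))
  expect_equal(nrow(hits_rc), 1)
  expect_identical(hits_rc$strand, "-")
  expect_equal(hits_rc$send, nchar(sc) - 1500)
})

test_that("a random 100-kb scaffold yields no hits at the 1e-10 cutoff", {
  panel <- panel_fixture()
  set.seed(22)
  sc <- random_dna(1e5, 0.42)
  hits <- search_genome(list(pol = panel$proteins$pol["TYPE_D"]), c(bg = sc))
  expect_equal(nrow(hits), 0)
})

test_that("true targets beat composition-preserving shuffles", {
  panel <- panel_fixture()
  set.seed(23)
  qaa <- substr(panel$proteins$env_beta[["TYPE_D"]], 1, 200)
  coding <- proviscan:::encode_protein(qaa, add_stop = FALSE)
  target <- paste0(random_dna(300, 0.42), coding, random_dna(300, 0.42))
  p <- alignment_params(low_complexity_filter = FALSE)
  true_score <- local_align_protein(
    qaa, Filter(function(f) f$frame == 1,
                six_frame_translate(target))[[1]]$aa,
    p, score_only = TRUE)$score
  tc <- strsplit(target, "")[[1]]
  wins <- 0
  for (i in 1:100) {
    shuf <- paste(sample(tc), collapse = "")
    best <- max(vapply(six_frame_translate(shuf), function(f)
      local_align_protein(qaa, f$aa, p, score_only = TRUE)$score, 1))
    if (true_score > best) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("locus intersection requires all three genes, colinear and near", {
  h <- function(gene, sstart, send, sid = "s1", strand = "+",
                e = 1e-30) {
    data.frame(gene = gene, qid = "r", sid = sid, frame = 1,
               strand = strand, pident = 99, length = 100,
               qstart = 1, qend = 100, sstart = sstart, send = send,
               score = 500, evalue = e, stringsAsFactors = FALSE)
  }
  # env missing -> no locus (conjunction)
  hits <- rbind(h("gag", 100, 400), h("pol", 600, 1200))
  expect_equal(nrow(intersect_gene_hits(hits)), 0)
  # colinear triple -> one locus
  hits3 <- rbind(h("gag", 100, 400), h("pol", 600, 1200),
                 h("env", 1400, 1800))
  loci <- intersect_gene_hits(hits3, c(s1 = 5000), flank = 50)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$start, 50)
  expect_equal(loci$end, 1850)
  # wrong order -> none
  hits_bad <- rbind(h("gag", 1400, 1800), h("pol", 600, 1200),
                    h("env", 100, 400))
  expect_equal(nrow(intersect_gene_hits(hits_bad)), 0)
  # same hits read on the minus strand are colinear in reverse
  hits_bad$strand <- "-"
  expect_equal(nrow(intersect_gene_hits(hits_bad)), 1)
  # two distant triples -> two loci
  off <- 40000
  hits6 <- rbind(hits3, h("gag", 100 + off, 400 + off),
                 h("pol", 600 + off, 1200 + off),
                 h("env", 1400 + off, 1800 + off))
  expect_equal(nrow(intersect_gene_hits(hits6, c(s1 = 60000))), 2)
  # a triple wider than max_span is rejected
  hits_wide <- rbind(h("gag", 100, 400), h("pol", 9000, 9600),
                     h("env", 19000, 19400))
  expect_equal(nrow(intersect_gene_hits(hits_wide, max_span = 15000)), 0)
})

test_that("two proviruses on one scaffold are both recovered", {
  panel <- panel_fixture()
  set.seed(24)
  qaa <- list(gag = panel$proteins$gag["TYPE_D"],
              pol = panel$proteins$pol["TYPE_D"],
              env = panel$proteins$env_beta["TYPE_D"])
  tpl <- betaretro_template("VI", panel)
  pv <- build_provirus(tpl)
  bg <- make_background(26000 + 2 * nchar(pv$seq), gc = 0.42, id = "dbl")
  r1 <- plant(bg, pv, decay_params(4e-10, 5e6), insert_pos = 3000)
  r2 <- plant(r1$scaffold, pv, decay_params(4e-10, 5e6),
              insert_pos = 24000 + nchar(pv$seq))
  hits <- search_genome(qaa, list(r2$scaffold))
  loci <- intersect_gene_hits(hits, c(dbl = nchar(r2$scaffold$seq)))
  expect_equal(nrow(loci), 2)
})

test_that("hit summaries report the lowest e-value and count per gene", {
  expect_equal(nrow(summarize_hits(
    data.frame(gene = character(0), qid = character(0),
               evalue = numeric(0)))), 0)
  hits <- data.frame(gene = c("gag", "gag", "pol"), qid = "r",
                     evalue = c(1e-20, 1e-40, 1e-15))
  s <- summarize_hits(hits)
  expect_equal(s$lowest_evalue[s$gene == "gag"], 1e-40)
  expect_equal(s$n_hits[s$gene == "gag"], 2)
})
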