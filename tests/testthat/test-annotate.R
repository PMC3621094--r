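test_that("ORF finder matches the exhaustive frame-scan oracle", {
  expect_equal(nrow(find_orfs("CCCCCCCCC", min_codons = 1)), 0)
  set.seed(41)
  for (i in 1:40) {
    dna <- random_dna(if (i <= 3) 10000 else 2000, 0.45)
    got <- find_orfs(dna, min_codons = 30)
    want <- oracle_orfs(dna, min_codons = 30)
    expect_equal(got$start, want$start, label = paste("case", i))
    expect_equal(got$end, want$end, label = paste("case", i))
    expect_equal(got$codons, want$codons, label = paste("case", i))
  }
})

test_that("ORFs are placed against the provirus map, including in-LTR", {
  panel <- panel_fixture()
  tpl <- betaretro_template("V", panel, seed = 42)
  pv <- build_provirus(tpl)
  orfs <- find_orfs(pv$seq, min_codons = 100, provirus_map = pv$map)
  in_ltr <- orfs[orfs$placement == "in-LTR", , drop = FALSE]
  expect_gte(nrow(in_ltr), 2) # the planted ORF appears in both LTR copies
  expect_true(any(in_ltr$codons >= 123))
  # each core gene is recovered as an ORF recognized as core, not "extra"
  core <- orfs[orfs$placement == "core-gene", , drop = FALSE]
  for (g in c("gag", "pro", "pol", "env")) {
    r <- pv$map[pv$map$element == g, ]
    ov <- pmin(core$end, r$end) - pmax(core$start, r$start) + 1
    expect_true(any(ov >= 0.9 * (r$end - r$start + 1)), label = g)
  }
})

test_that("PBS assignment separates the lysine tRNA classes", {
  lib <- trna_lys_library()
  set.seed(43)
  leader <- function(pbs) paste0(random_dna(20, 0.45), pbs,
                                 random_dna(60, 0.45))
  # exact PBS: 18/18 and never a miscall between Lys1_2 and Lys3
  for (id in names(lib)) {
    call <- assign_pbs(leader(revcomp(lib[[id]])), lib)
    expect_identical(call$trna_id, id)
    expect_equal(call$matches, 18)
  }
  # up to 2 mutations: recovered in >= 95% of plants
  ok <- 0; n <- 120
  for (i in 1:n) {
    id <- sample(names(lib), 1)
    pbs <- revcomp(lib[[id]])
    k <- sample(1:2, 1)
    ev <- data.frame(type = "sub", pos = sample(18, k), len = 1L,
                     to = NA_character_)
    call <- assign_pbs(leader(apply_events(pbs, ev)), lib)
    if (identical(call$trna_id, id)) ok <- ok + 1
    expect_false(call$trna_id != id && call$trna_id != "unknown",
                 label = sprintf("case %d: miscall %s as %s", i, id,
                                 call$trna_id))
  }
  expect_gte(ok / n, 0.95)
  # fully masked leader
  expect_identical(assign_pbs(strrep("N", 80), lib)$status, "masked")
  # leader shorter than the window
  expect_identical(assign_pbs("ACGT", lib)$trna_id, "unknown")
})

test_that("motifs are found by anchored alignment and lost on ablation", {
  panel <- panel_fixture()
  tpl <- betaretro_template("III", panel, seed = 44)
  trans <- c(gag = tpl$proteins$gag, pro = tpl$proteins$pro,
             pol = tpl$proteins$pol)
  refs <- c(gag = panel$proteins$gag[["TYPE_D"]],
            pro = panel$proteins$pro[["TYPE_D"]],
            pol = panel$proteins$pol[["MICROBAT_DIV"]])
  m <- scan_motifs(trans, refs, panel$motifs)
  expect_setequal(unique(m$motif_id),
                  c("MHR", "zinc_knuckle_CCHC", "dUTPase", "protease_DxG",
                    "RT_DDD", "IN_DDE"))
  expect_true(all(m$status == "present"))

  # D -> A in the protease active site ablates protease_DxG only
  pro_mut <- trans[["pro"]]
  substr(pro_mut, 230, 230) <- "A"
  m2 <- scan_motifs(c(trans[c("gag", "pol")], pro = pro_mut), refs,
                    panel$motifs)
  expect_identical(m2$status[m2$motif_id == "protease_DxG"], "absent")
  expect_true(all(m2$status[m2$motif_id == "dUTPase"] == "present"))

  # missing translation: not assessable
  m3 <- scan_motifs(c(gag = NA_character_), refs["gag"], panel$motifs)
  expect_true(all(m3$status[m3$gene == "gag"] == "not assessable"))
})

test_that("the dUTPase signature is present in pro across all templates", {
  panel <- panel_fixture()
  for (g in c("I", "II", "IV", "VI", "VIII")) {
    tpl <- betaretro_template(g, panel, seed = 45)
    fam <- if (g %in% c("I", "II", "IV")) "TYPE_B" else "TYPE_D"
    m <- scan_motifs(c(pro = tpl$proteins$pro),
                     c(pro = panel$proteins$pro[[fam]]), panel$motifs)
    expect_true(all(m$status[m$motif_id == "dUTPase"] == "present"),
                label = paste("group", g))
  }
})

test_that("gene states: intact, frameshift and stop events, NSR unknown", {
  panel <- panel_fixture()
  ref <- panel$proteins$gag[["TYPE_D"]]
  set.seed(46)
  gene <- proviscan:::encode_protein(ref, add_stop = FALSE)

  st <- call_gene_state(gene, ref)
  expect_identical(st$state, "intact")
  expect_equal(nrow(st$events), 0)
  expect_gt(st$identity, 0.99)

  # single inserted nucleotide: one frameshift at (codon-resolution) position
  for (pos in c(151, 600, 1100)) {
    ev <- data.frame(type = "ins", pos = pos, len = 1L, to = "A")
    st2 <- call_gene_state(apply_events(gene, ev), ref)
    expect_identical(st2$state, "defective")
    fs <- st2$events[st2$events$type == "frameshift", ]
    expect_equal(nrow(fs), 1, label = paste("ins at", pos))
    expect_lte(abs(fs$pos - pos), 3)
  }

  # single premature stop: TGG (W) -> TGA at a known codon
  wpos <- regexpr("TGG", gene)[1]
  expect_gt(wpos, 0)
  stop_pos <- wpos + 2
  ev <- data.frame(type = "sub", pos = stop_pos, len = 1L, to = "A")
  st3 <- call_gene_state(apply_events(gene, ev), ref)
  expect_identical(st3$state, "defective")
  ps <- st3$events[st3$events$type == "premature_stop", ]
  expect_equal(nrow(ps), 1)
  expect_lte(abs(ps$pos - wpos), 3)
  expect_equal(nrow(st3$events), 1) # the stop is the only event

  # NSR overlap: unknown
  geneN <- gene
  substr(geneN, 300, 360) <- strrep("N", 61)
  expect_identical(call_gene_state(geneN, ref)$state, "unknown")
})

test_that("repeat finder agrees with the exhaustive k-mer oracle", {
  set.seed(47)
  arm <- "ACGTACGTTTGG"
  dna <- paste0(random_dna(400, 0.5), arm, random_dna(300, 0.5), arm,
                random_dna(200, 0.5))
  reps <- find_repeats(dna, min_arm = 12)
  direct <- reps[reps$kind == "direct", ]
  expect_gte(nrow(direct), 1)
  expect_true(any(direct$arm_len >= 12 &
                    substr(dna, direct$start1, direct$end1) ==
                    substr(dna, direct$start2, direct$end2)))

  stem <- random_dna(14, 0.5)
  dna2 <- paste0(random_dna(300, 0.5), stem, random_dna(120, 0.5),
                 revcomp(stem), random_dna(300, 0.5))
  inv <- find_repeats(dna2, min_arm = 14)
  inv <- inv[inv$kind == "inverted", ]
  expect_gte(nrow(inv), 1)
  i1 <- inv[1, ]
  expect_identical(substr(dna2, i1$start2, i1$end2),
                   revcomp(substr(dna2, i1$start1, i1$end1)))

  # random 2-kb region: direct repeats equal the brute-force enumeration
  for (s in 1:3) {
    set.seed(s * 100)
    d <- random_dna(2000, 0.5)
    got <- find_repeats(d)
    got <- got[got$kind == "direct", c("start1", "start2", "arm_len")]
    got <- got[order(got$start1, got$start2), , drop = FALSE]
    want <- oracle_direct_repeats(d)
    expect_equal(nrow(got), nrow(want), label = paste("seed", s))
    if (nrow(want) > 0) {
      want <- want[order(want$start1, want$start2), , drop = FALSE]
      expect_equal(got$start1, want$start1)
      expect_equal(got$start2, want$start2)
      expect_equal(got$arm_len, want$arm_len)
    }
  }

  # TBE candidacy: direct repeats downstream of the env stop are flagged
  dna3 <- paste0(random_dna(100, 0.5), arm, random_dna(80, 0.5), arm,
                 random_dna(60, 0.5))
  r3 <- find_repeats(dna3, min_arm = 12, tbe_from = 50)
  expect_true(any(r3$tbe_candidate[r3$kind == "direct"]))
})
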