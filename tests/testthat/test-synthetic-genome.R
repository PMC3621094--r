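test_that("background scaffolds honour length, N-runs and GC content", {
  sc <- make_background(100, 0.5, seed = 1)
  expect_equal(nchar(sc$seq), 100)
  expect_false(grepl("N", sc$seq, fixed = TRUE))

  sc2 <- make_background(1000, 0.5, n_run_spec = list(c(100, 150)), seed = 1)
  expect_equal(substr(sc2$seq, 100, 150), strrep("N", 51))
  expect_false(grepl("N", substr(sc2$seq, 1, 99), fixed = TRUE))

  expect_error(make_background(100, 0.5, n_run_spec = list(c(90, 120))),
               "outside")

  # observed GC within 3 SD of binomial(1e5, 0.42)
  sc3 <- make_background(1e5, 0.42, seed = 7)
  gc <- sum(strsplit(sc3$seq, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 42000), 3 * sqrt(1e5 * 0.42 * 0.58))
})

test_that("built proviruses have identical LTRs, correct PBS and layout", {
  panel <- panel_fixture()
  tpl <- betaretro_template("VII", panel, seed = 11, ltr_len = 400)
  pv <- build_provirus(tpl)
  at <- function(el) {
    r <- pv$map[pv$map$element == el, ]
    substr(pv$seq, r$start, r$end)
  }
  expect_identical(at("ltr5"), at("ltr3"))
  expect_identical(at("pbs"), revcomp(panel$trna[["Lys3"]]))
  # gene order and PPT immediately 5' of the 3' LTR
  ord <- match(c("gag", "pro", "pol", "env"), pv$map$element)
  expect_true(all(diff(ord) > 0))
  expect_equal(pv$map$end[pv$map$element == "ppt"] + 1L,
               pv$map$start[pv$map$element == "ltr3"])

  # group V template reproduces the long-LTR architecture (1265 nt, Lys3,
  # ORF inside the LTR)
  tplV <- betaretro_template("V", panel, seed = 12)
  pvV <- build_provirus(tplV)
  expect_equal(nchar(tplV$ltr_seq), 1265)
  expect_identical(tplV$pbs_trna, "Lys3")
  m <- pvV$map
  ltr_len <- m$end[m$element == "ltr5"] - m$start[m$element == "ltr5"] + 1L
  expect_equal(ltr_len, 1265)
})

test_that("planting duplicates the target site and age-0 plants are exact", {
  panel <- panel_fixture()
  pv <- toy_provirus(400, 600)
  bg <- make_background(3000, 0.42, seed = 3)
  res <- plant(bg, pv, decay_params(4e-10, 0, seed = 4))
  tr <- res$truth
  sq <- res$scaffold$seq
  at <- function(el) {
    r <- tr$spans[tr$spans$element == el, ]
    substr(sq, r$start, r$end)
  }
  expect_identical(at("ltr5"), at("ltr3"))
  expect_equal(ltr_divergence(at("ltr5"), at("ltr3"))$D, 0)
  expect_identical(at("tsd5"), at("tsd3"))
  expect_identical(at("tsd5"), tr$tsd)
  # round trip: every truth span slices back to a piece of expected length
  expect_true(all(tr$spans$end <= nchar(sq) & tr$spans$start >= 1))
})

test_that("realized LTR divergence matches the 2RT Poisson expectation", {
  set.seed(99)
  pv <- toy_provirus(500, 100)
  diffs <- replicate(200, {
    bg <- make_background(1200, 0.42)
    res <- plant(bg, pv, decay_params(4e-10, 2.5e7, indel_rate = 0))
    res$truth$realized_divergence * 500
  })
  # expected mean differences = 500 * 2RT = 10
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 10), 3 * se)
})

test_that("transcript fragmentation tiles exactly and remaps to source", {
  set.seed(5)
  dna <- random_dna(8111, 0.45)
  tx <- make_transcripts(dna, c(5433, 5830), overlap = 3152, seed = 6)
  expect_equal(sort(unname(nchar(tx$seqs))), c(5433, 5830))
  merged <- merge_overlapping_transcripts(tx$seqs[["frag1"]],
                                          tx$seqs[["frag2"]])
  expect_equal(nchar(merged), 8111)
  expect_identical(merged, dna)
  # coordinates point back at identical substrings
  for (i in seq_len(nrow(tx$coords))) {
    cc <- tx$coords[i, ]
    expect_identical(tx$seqs[[cc$id]], substr(dna, cc$start, cc$end))
  }
  expect_error(make_transcripts(dna, c(5433, 5830), overlap = 0), "overlap")
  expect_error(make_transcripts(dna, c(9000, 5830), overlap = 3152),
               "longer")
  expect_error(make_transcripts(dna, c(5433, 5830), overlap = 3000), "tile")
})
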