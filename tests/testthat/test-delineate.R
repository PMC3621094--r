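test_that("exact 400-nt repeats flanking an insert are found at 100%", {
  set.seed(31)
  ltr <- random_dna(400, 0.45)
  substr(ltr, 1, 2) <- "TG"; substr(ltr, 399, 400) <- "CA"
  insert <- random_dna(6000, 0.45)
  locus <- paste0(random_dna(500, 0.42), ltr, insert, ltr,
                  random_dna(500, 0.42))
  lp <- find_ltr_pair(locus)
  expect_false(is.null(lp))
  expect_equal(lp$identity, 1)
  expect_equal(lp$ltr5_start, 501)
  expect_equal(lp$len5, 400)
  expect_equal(lp$ltr3_start, 501 + 400 + 6000)
})

test_that("2%-diverged repeats are found with identity in [97, 99.5]%", {
  set.seed(32)
  ltr <- random_dna(400, 0.45)
  substr(ltr, 1, 2) <- "TG"; substr(ltr, 399, 400) <- "CA"
  # mutate exactly 8 interior positions of the 3' copy
  pos <- sample(3:398, 8)
  ev <- data.frame(type = "sub", pos = pos, len = 1L, to = NA_character_)
  ltr3 <- apply_events(ltr, ev)
  locus <- paste0(random_dna(600, 0.42), ltr, random_dna(5000, 0.45), ltr3,
                  random_dna(600, 0.42))
  lp <- find_ltr_pair(locus)
  expect_false(is.null(lp))
  expect_gte(lp$identity, 0.97)
  expect_lte(lp$identity, 0.995)
  expect_lte(abs(lp$len5 - 400), 5)
})

test_that("no LTR pair is reported on provirus-free scaffolds", {
  for (seed in 1:20) {
    set.seed(seed)
    sc <- random_dna(9000, 0.42)
    expect_null(find_ltr_pair(sc), label = paste("seed", seed))
  }
})

test_that("TSD calls require exact flanking duplication", {
  set.seed(33)
  ltr <- random_dna(300, 0.45)
  substr(ltr, 1, 2) <- "TG"; substr(ltr, 299, 300) <- "CA"
  inner <- random_dna(4000, 0.45)
  tsd <- "GATC"
  locus <- paste0(random_dna(300, 0.42), tsd, ltr, inner, ltr, tsd,
                  random_dna(300, 0.42))
  lp <- find_ltr_pair(locus)
  expect_false(is.null(lp))
  call <- find_tsd(locus, lp)
  expect_identical(call$status, "present")
  expect_identical(call$sequence, tsd)

  # random (non-duplicated) flanks: no call
  locus2 <- paste0(random_dna(300, 0.42), "GATC", ltr, inner, ltr, "TTAG",
                   random_dna(300, 0.42))
  lp2 <- find_ltr_pair(locus2)
  expect_identical(find_tsd(locus2, lp2)$status, "none")

  # masked flank
  locus3 <- paste0(random_dna(296, 0.42), "NNNN", "GATC", ltr, inner, ltr,
                   "NNNN", random_dna(300, 0.42))
  lp3 <- find_ltr_pair(locus3)
  expect_identical(find_tsd(locus3, lp3)$status, "masked")
})

test_that("a truncated 3' LTR leaves the element without a TSD", {
  set.seed(34)
  ltr <- random_dna(400, 0.45)
  substr(ltr, 1, 2) <- "TG"; substr(ltr, 399, 400) <- "CA"
  trunc <- substr(ltr, 1, 250) # 3' LTR truncated at the scaffold edge
  locus <- paste0(random_dna(400, 0.42), "GATC", ltr, random_dna(5000, 0.45),
                  trunc)
  lp <- find_ltr_pair(locus)
  if (!is.null(lp)) {
    expect_identical(find_tsd(locus, lp)$status, "none")
  } else {
    succeed("truncated repeat below length floor: no pair, no TSD")
  }
})

test_that("PPT detection matches the exhaustive window oracle", {
  # pure 19-nt purine run abutting the LTR
  p <- find_ppt("AAAAGGGGGAAAGGGGGGA")
  expect_equal(p$length, 19)
  expect_equal(p$purine_fraction, 1)
  # pyrimidine-rich flank: none
  expect_null(find_ppt("CTCTCTCCCTTTCTCTCCCT"))
  # random 200-mers against the oracle
  set.seed(35)
  for (i in 1:300) {
    up <- random_dna(200, if (i %% 3 == 0) 0.6 else 0.45)
    got <- find_ppt(up)
    want <- oracle_ppt(up)
    if (is.null(want)) {
      expect_null(got, label = paste("case", i))
    } else {
      expect_equal(got$start, want$start, label = paste("case", i))
      expect_equal(got$end, want$end, label = paste("case", i))
    }
  }
})

test_that("flank comparison separates duplicated from independent plants", {
  set.seed(36)
  panel <- panel_fixture()
  pv <- toy_provirus(300, 2000)
  bg <- make_background(5000, 0.42, id = "a")
  res <- plant(bg, pv, decay_params(4e-10, 5e6), insert_pos = 2500)
  sp <- res$truth$spans
  outer <- c(sp$start[sp$element == "ltr5"], sp$end[sp$element == "ltr3"])
  rec <- list(seq = res$scaffold$seq, outer_start = outer[1],
              outer_end = outer[2])
  # a duplicated provirus (copied with its flanks) is homologous
  expect_identical(compare_flanks(rec, rec), "homologous")
  # independent plants on random backgrounds are not
  for (i in 1:20) {
    bg2 <- make_background(5000, 0.42, id = "b")
    res2 <- plant(bg2, pv, decay_params(4e-10, 5e6), insert_pos = 2500)
    sp2 <- res2$truth$spans
    rec2 <- list(seq = res2$scaffold$seq,
                 outer_start = sp2$start[sp2$element == "ltr5"],
                 outer_end = sp2$end[sp2$element == "ltr3"])
    expect_identical(compare_flanks(rec, rec2), "not",
                     label = paste("pair", i))
  }
  # all-N flank is indeterminate
  recN <- rec
  recN$seq <- paste0(strrep("N", outer[1] - 1),
                     substr(rec$seq, outer[1], nchar(rec$seq)))
  expect_identical(compare_flanks(recN, rec), "indeterminate")
})

test_that("transcript merge demands a perfect overlap and flags ambiguity", {
  set.seed(37)
  dna <- random_dna(8111, 0.45)
  t1 <- substr(dna, 1, 5433)
  t2 <- substr(dna, 5433 - 3152 + 1, 8111)
  expect_equal(nchar(t2), 5830)
  merged <- merge_overlapping_transcripts(t1, t2)
  expect_equal(nchar(merged), 5433 + 5830 - 3152)
  expect_gt(nchar(merged), 8103)
  expect_identical(merged, dna)
  # argument order must not matter
  expect_identical(merge_overlapping_transcripts(t2, t1), dna)
  # identical sequences merge to themselves
  expect_identical(merge_overlapping_transcripts(t1, t1), t1)
  # one mismatch inside the overlap: no merge
  t2bad <- t2
  substr(t2bad, 1000, 1000) <- if (substr(t2bad, 1000, 1000) == "A") "C"
  else "A"
  expect_null(merge_overlapping_transcripts(t1, t2bad))
  # trimming recovers a merge spoiled at the overlap extremities
  t2trim <- t2
  substr(t2trim, 3, 3) <- if (substr(t2trim, 3, 3) == "A") "C" else "A"
  expect_null(merge_overlapping_transcripts(t1, t2trim))
  # 10 nt trimmed from the start of t2, overlap shrinks by 10: same total
  expect_equal(nchar(merge_overlapping_transcripts(t1, t2trim, trim5 = 10)),
               8111)
  # two distinct qualifying overlaps: ambiguity error
  rep_unit <- random_dna(150, 0.5)
  a <- paste0(random_dna(400, 0.5), rep_unit, rep_unit)
  b <- paste0(rep_unit, rep_unit, random_dna(400, 0.5))
  expect_error(merge_overlapping_transcripts(a, b, min_overlap = 100),
               "ambiguous")
})
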