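test_that("the eight canonical representatives get eight distinct groups", {
  labs <- vapply(canonical_feature_vectors(), function(f)
    classify_group(f)$group, "")
  expect_equal(unname(labs),
               c("I", "II", "III", "IV", "V", "VI", "VII", "VIII"))
  expect_equal(length(unique(labs)), 8)
})

test_that("published bat ERV feature vectors reproduce their groups", {
  # Groups as assigned in the source survey: PvERV-A (unknown PBS, early bat
  # cluster) II; PvERV-B (Lys3, 1265-nt LTR, Type B) V; PvERV-D (Lys1_2,
  # short LTR, beta env) VI; PvERV-E..I (Lys3, short LTR) VII; PvERV-J/K
  # (gamma env) VIII; MlERV-A/B II; MlERV-C (divergent microbat pol, Lys3)
  # III; MlERV-E (LysAlt, Type B) IV.
  cases <- list(
    list(feature_vector("unknown", 430, "beta", character(0), TRUE,
                        "BAT_EARLY"), "II"),
    list(feature_vector("Lys3", 1265, "beta", "in-LTR", TRUE, "TYPE_B"),
         "V"),
    list(feature_vector("Lys1_2", 398, "beta", "within-core-alt-frame",
                        TRUE, "TYPE_D"), "VI"),
    list(feature_vector("Lys3", 371, "beta", "pre-gag", TRUE, "TYPE_D"),
         "VII"),
    list(feature_vector("Lys1_2", 427, "gamma", "post-env", TRUE, "TYPE_D"),
         "VIII"),
    list(feature_vector("Lys1_2", 422, "beta", "in-LTR", TRUE, "BAT_EARLY"),
         "II"),
    list(feature_vector("Lys3", 480, "beta", character(0), TRUE,
                        "BAT_EARLY"), "II"),
    list(feature_vector("Lys3", 479, "beta", character(0), TRUE,
                        "MICROBAT_DIV"), "III"),
    list(feature_vector("LysAlt", 470, "beta", character(0), TRUE,
                        "TYPE_B"), "IV"))
  for (cs in cases) {
    expect_identical(classify_group(cs[[1]])$group, cs[[2]])
  }
})

test_that("gamma env dominates with a conflict warning; ambiguity is exposed", {
  g <- classify_group(feature_vector("Lys3", 1265, "gamma", character(0),
                                     TRUE, "TYPE_B"))
  expect_identical(g$group, "VIII")
  expect_true(any(grepl("warning", g$trace)))

  amb <- classify_group(feature_vector("Lys3", 400, "beta", character(0),
                                       TRUE, "BAT_AMBIG"))
  expect_identical(amb$group, "II-or-III")

  un <- classify_group(feature_vector())
  expect_identical(un$group, "unclassified")
  expect_length(un$trace, 0)
})

test_that("env lineage assignment by reference scoring with a margin rule", {
  panel <- panel_fixture()
  # an exact gamma reference is gamma; a beta template env is beta
  g <- env_lineage(panel$proteins$env_gamma[["G1"]],
                   panel$proteins$env_beta, panel$proteins$env_gamma)
  expect_identical(g$lineage, "gamma")
  tpl <- betaretro_template("VI", panel, seed = 61)
  b <- env_lineage(tpl$proteins$env, panel$proteins$env_beta,
                   panel$proteins$env_gamma)
  expect_identical(b$lineage, "beta")
  # a 50/50 beta-gamma chimera is unknown under the margin rule
  half_b <- substr(panel$proteins$env_beta[["TYPE_D"]], 1, 270)
  half_g <- substr(panel$proteins$env_gamma[["G1"]], 271, 540)
  ch <- env_lineage(paste0(half_b, half_g), panel$proteins$env_beta,
                    panel$proteins$env_gamma)
  expect_identical(ch$lineage, "unknown")
  # nothing alignable is unknown
  expect_identical(env_lineage(strrep("P", 120), panel$proteins$env_beta,
                               panel$proteins$env_gamma)$lineage, "unknown")
})

test_that("pol proxy picks the nearest cluster and flags bat ambiguity", {
  panel <- panel_fixture()
  for (cl in names(panel$proteins$pol)) {
    px <- phylo_proxy(panel$proteins$pol[[cl]], panel$proteins$pol)
    expect_identical(px$cluster, cl)
  }
  tpl <- betaretro_template("III", panel, seed = 62)
  expect_identical(phylo_proxy(tpl$proteins$pol, panel$proteins$pol)$cluster,
                   "MICROBAT_DIV")
})
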