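test_that("LTR divergence is a gap/N-excluded p-distance", {
  set.seed(51)
  ltr <- random_dna(400, 0.45)
  expect_equal(ltr_divergence(ltr, ltr)$D, 0)

  # exactly 8 substituted sites, no indels -> D = 0.02
  ev <- data.frame(type = "sub", pos = sample(400, 8), len = 1L,
                   to = NA_character_)
  d <- ltr_divergence(ltr, apply_events(ltr, ev))
  expect_equal(d$D, 0.02)
  expect_equal(d$aligned_sites, 400)
  expect_equal(d$differences, 8)

  # N columns are excluded
  ltrN <- ltr
  substr(ltrN, 10, 29) <- strrep("N", 20)
  dN <- ltr_divergence(ltr, ltrN)
  expect_equal(dN$aligned_sites, 380)
  expect_equal(dN$D, 0)

  # an indel adds gap columns that are excluded
  ev2 <- data.frame(type = "del", pos = 200, len = 3L, to = NA_character_)
  d2 <- ltr_divergence(ltr, apply_events(ltr, ev2))
  expect_equal(d2$excluded, 3)
  expect_equal(d2$D, 0)
})

test_that("planted pairs at 2RT = 0.024 land inside the binomial CI", {
  set.seed(52)
  pv <- toy_provirus(500, 100)
  ds <- replicate(200, {
    bg <- make_background(1200, 0.42)
    res <- plant(bg, pv, decay_params(4e-10, 3e7, indel_rate = 0))
    sp <- res$truth$spans
    at <- function(el) {
      r <- sp[sp$element == el, ]
      substr(res$scaffold$seq, r$start, r$end)
    }
    ltr_divergence(at("ltr5"), at("ltr3"))$D
  })
  se <- sqrt(0.024 * (1 - 0.024) / 500) / sqrt(200)
  expect_lt(abs(mean(ds) - 0.024), 3 * se)
})

test_that("T = (D/R)/2 with one-decimal report rounding", {
  expect_equal(estimate_age(0, 4e-10)$T_myr, 0)
  # back-calculated megabat rate reproduces the printed ages
  r_mega <- 0.006 / (2 * 7.5e6)
  expect_equal(estimate_age(0.024, r_mega)$T_myr, 30.0)
  expect_equal(estimate_age(0.029, r_mega)$T_myr, 36.3)
  r_micro <- 0.008 / (2 * 4.2e6)
  expect_equal(estimate_age(0.043, r_micro)$T_myr, 22.6)
  # ND semantics
  nd <- estimate_age(NA_real_, r_mega)
  expect_true(is.na(nd$T_myr))
  # linear in D, inversely linear in R
  for (D in c(0.01, 0.02, 0.04)) for (R in c(2e-10, 4e-10, 8e-10)) {
    expect_equal(estimate_age(D, R)$T_years, (D / R) / 2)
    expect_equal(estimate_age(2 * D, R)$T_years,
                 2 * estimate_age(D, R)$T_years)
    expect_equal(estimate_age(D, 2 * R)$T_years,
                 estimate_age(D, R)$T_years / 2)
  }
})

test_that("dating round-trips through the simulator within 5% for T >= 3 Myr", {
  set.seed(53)
  rate <- default_rates()[["megabat"]]
  pv <- toy_provirus(500, 100)
  for (T_true in c(5e6, 20e6)) {
    est <- replicate(120, {
      bg <- make_background(1200, 0.42)
      res <- plant(bg, pv, decay_params(rate, T_true, indel_rate = 0.05))
      sp <- res$truth$spans
      at <- function(el) {
        r <- sp[sp$element == el, ]
        substr(res$scaffold$seq, r$start, r$end)
      }
      estimate_age(ltr_divergence(at("ltr5"), at("ltr3")), rate)$T_years
    })
    expect_lt(abs(mean(est) - T_true) / T_true, 0.05)
  }
})
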