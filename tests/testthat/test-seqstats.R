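test_that("heat-map cells average exactly 800 or 8000 sequences on the full design", {
  rec <- data.frame(variant = nterm_variants(), func_mean = 1)
  hm <- residue_position_means(rec)
  expect_true(all(hm$mean == 1))  # constant field
  expect_true(all(hm$n[hm$position %in% c(2, 4, 5)] == 800L))
  expect_true(all(hm$n[hm$position == 3] == 8000L))
  expect_equal(nrow(hm), 62L)
})

test_that("heat-map means match exhaustive enumeration on a toy set", {
  toy <- data.frame(variant = c("ASGV", "ASGI", "ATGV", "FSGV",
                                "FTLL", "FTGM", "ASLV", "FSLM"),
                    func_mean = c(1, 2, 3, 4, 5, 6, 7, 8))
  hm <- residue_position_means(toy)
  g <- function(pos, res) hm$mean[hm$position == pos & hm$residue == res]
  expect_equal(g(2, "A"), mean(c(1, 2, 3, 7)))
  expect_equal(g(2, "F"), mean(c(4, 5, 6, 8)))
  expect_equal(g(3, "S"), mean(c(1, 2, 4, 7, 8)))
  expect_equal(g(3, "T"), mean(c(3, 5, 6)))
  expect_equal(g(5, "V"), mean(c(1, 3, 4, 7)))
  expect_true(is.na(g(2, "C")))  # residue absent from the toy set
})

test_that("distribution summaries use interpolated percentiles with n = 800", {
  rec <- data.frame(variant = nterm_variants(), func_mean = 0)
  # assign scores 1..800 to the 800 Ala2 sequences
  ia <- residue_at(rec$variant, 2) == "A"
  rec$func_mean[ia] <- seq_len(800)
  ds <- score_distribution_summary(rec, 2)
  arow <- ds[ds$residue == "A", ]
  expect_equal(arow$n, 800L)
  q <- unname(quantile(1:800, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7))
  expect_equal(unlist(arow[c("p10", "p25", "median", "p75", "p90")],
                      use.names = FALSE), q)
  expect_true(all(ds$n == 800L))
  # ordering invariant
  expect_true(all(arow$p10 <= arow$p25 & arow$p25 <= arow$median &
                    arow$median <= arow$p75 & arow$p75 <= arow$p90))
  # symmetric scores: median equals mean
  expect_equal(arow$median, mean(seq_len(800)))
})

test_that("logo heights equal direct binomial tail summation", {
  fg <- c(rep("ASGV", 7), rep("FSGV", 2), "FTLM")
  lg <- binomial_logo(fg, bonferroni_m = 62)
  for (i in sample(nrow(lg), 20)) {
    k <- lg$k[i]; n <- lg$n[i]; p <- lg$p_bg[i]
    expected <- if (k / n > p) -log10(sum_binom_upper(k, n, p))
    else if (k / n < p) log10(sum_binom_lower(k, n, p))
    else 0
    expect_equal(lg$height[i], expected, tolerance = 1e-9)
  }
  # large-n agreement with the summation oracle
  lg2 <- binomial_logo(rep(c("ASGV", "ATGV"), c(6000, 4000)))
  r <- lg2[lg2$position == 3 & lg2$residue == "S", ]
  expect_equal(r$height, -log10(sum_binom_upper(6000, 10000, 0.5)),
               tolerance = 1e-9)
})

test_that("fully constrained foregrounds give the closed-form logo height", {
  # n = 10, k = 10, p = 0.05: height = 10 * log10(20)
  lg <- binomial_logo(rep("ASGV", 10))
  expect_equal(lg$height[lg$position == 2 & lg$residue == "A"],
               10 * log10(20), tolerance = 1e-9)
  expect_equal(round(lg$height[lg$position == 2 & lg$residue == "A"], 4),
               13.0103)
  # degenerate background p = 1: forced residue carries no information
  bg <- design_background()
  bg$p_bg[bg$position == 3 & bg$residue == "S"] <- 1
  bg$p_bg[bg$position == 3 & bg$residue == "T"] <- 0
  bg <- bg[bg$p_bg > 0, ]
  lg2 <- binomial_logo(rep("ASGV", 10), background = bg)
  expect_equal(lg2$height[lg2$position == 3 & lg2$residue == "S"], 0)
  # threshold is the Bonferroni-corrected alpha
  expect_equal(unique(lg$threshold), -log10(0.05 / 62))
  expect_identical(lg$significant, abs(lg$height) >= lg$threshold)
  expect_error(binomial_logo(character(0)), "empty")
})

test_that("covariation expectations conserve the set size and handle degenerates", {
  scr <- small_screen()
  rec <- score_screen(scr$sim$counts)
  top <- top_enriched(rec, 400)
  cv <- pairwise_covariation(top)
  for (pp in list(c(2, 3), c(2, 4), c(2, 5), c(3, 4), c(3, 5), c(4, 5))) {
    s <- sum(cv$expected[cv$pos_i == pp[1] & cv$pos_j == pp[2]])
    expect_equal(s, length(top), tolerance = 1e-9)
  }
  # single-sequence set: its own residue pairs have obs = exp = 1
  one <- pairwise_covariation("ASGV")
  expect_true(all(one$observed == 1))
  expect_true(all(one$expected == 1))
  expect_error(pairwise_covariation(character(0)), "empty")
  expect_error(pairwise_covariation("ASGV", position_pairs = list(c(1, 2))),
               "outside")
})

test_that("co-selected residue pairs are over-represented among top sequences", {
  # the generator builds in a Gly4-Val5 synergy; the most enriched
  # sequences should carry the pair above independence expectation
  scr <- small_screen()
  rec <- score_screen(scr$sim$counts)
  cv <- pairwise_covariation(top_enriched(rec, 400),
                             position_pairs = list(c(4, 5)))
  gv <- cv[cv$res_i == "G" & cv$res_j == "V", ]
  expect_gt(gv$log2_obs_exp, 0)
})

test_that("covariation type-I error is controlled under positional independence", {
  # selected sets drawn with independent residues carry no true linkage
  set.seed(42)
  n_sets <- 60
  any_hit <- logical(n_sets)
  for (i in seq_len(n_sets)) {
    sel <- paste0(sample(AA_ALPHABET, 300, TRUE),
                  sample(c("S", "T"), 300, TRUE),
                  sample(AA_ALPHABET, 300, TRUE),
                  sample(AA_ALPHABET, 300, TRUE))
    cv <- pairwise_covariation(sel, position_pairs = list(c(4, 5)))
    any_hit[i] <- any(cv$significant)
  }
  expect_lte(mean(any_hit), 0.05)
})
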