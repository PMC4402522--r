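test_that("AGEZ scanning follows the stated offset convention", {
  # upstream AG with its G at -12 -> 9 nt strictly between the AGs
  r <- make_region("UAGUUUUUUUUCAG")
  ag <- find_agez(r)
  expect_equal(ag$agez_length, 9L)
  expect_equal(ag$upstream_ag_offset, -12L)
  expect_false(ag$censored)

  # no upstream AG: censored at up_len - 2
  ag <- find_agez(make_region("UUUUUUUUUUUUAG"))
  expect_true(ag$censored)
  expect_equal(ag$agez_length, 12L)
  expect_true(is.na(ag$upstream_ag_offset))

  # adjacent AG edge case: nearest eligible G sits at -3
  ag <- find_agez(make_region("AGAGAGAGAGAGAG"))
  expect_equal(ag$agez_length, 0L)
  expect_equal(ag$upstream_ag_offset, -3L)

  # non-canonical regions are flagged but still computed
  ag <- find_agez(make_region("UAGUUUUUUUUCAU"))
  expect_false(ag$canonical)
  expect_equal(ag$agez_length, 9L)
})

test_that("AGEZ agrees with a brute-force dinucleotide scan on random input", {
  set.seed(101)
  for (i in 1:1000) {
    up <- paste0(random_rna(sample(6:60, 1)), "AG")
    r <- make_region(up)
    expect_identical(find_agez(r)$agez_length, brute_agez(r))
  }
})

test_that("purine dinucleotide profiles mark first bases of occurrences", {
  r <- make_region("GGGGAG")
  gg <- count_purine_dinucleotides(r, "GG")
  expect_identical(unname(gg), c(1L, 1L, 1L, 0L, 0L))
  expect_identical(names(gg), as.character(-6:-2))

  r2 <- make_region("ACUCAG")
  expect_true(all(count_purine_dinucleotides(r2, "AG")[1:3] == 0L))
  expect_error(count_purine_dinucleotides(r2, "AU"), "over A, G")
})

test_that("planted AG-free zones produce a frequency dip at the zone", {
  cfg <- small_cohort(n = 40L, seed = 9L,
                      agez = list(up = c(60, 0), down = c(60, 0),
                                  control = c(60, 0)))
  coh <- generate_cohort(cfg, withr::local_tempdir())
  hits <- sapply(coh$regions, count_purine_dinucleotides, "AG")
  freq <- rowMeans(hits)
  offs <- as.integer(rownames(hits))
  zone <- offs >= -60L & offs <= -4L     # inside the planted exclusion zone
  outside <- offs < -70L
  expect_equal(max(freq[zone]), 0)
  expect_gt(mean(freq[outside]), 0.02)
})

test_that("site model training smooths counts and recovers sampled columns", {
  m <- train_site_model(rep("UACUAAC", 2), "bp", pseudocount = 0)
  expect_true(all(apply(m$prob, 1, max) == 1))
  expect_equal(rowSums(m$prob), rep(1, 7), ignore_attr = TRUE)

  m2 <- train_site_model(rep("UACUAAC", 2), "bp", pseudocount = 0.5)
  expect_true(all(m2$prob > 0))
  expect_error(train_site_model(c("ACGU", "ACG"), "3ss"), "ragged")

  # sampling recovery at n = 1000, tolerance 0.05
  set.seed(21)
  truth <- matrix(c(0.7, 0.1, 0.1, 0.1,
                    0.1, 0.4, 0.4, 0.1,
                    0.25, 0.25, 0.25, 0.25), 3, 4, byrow = TRUE)
  draws <- vapply(1:1000, function(i) {
    paste(vapply(1:3, function(j)
      sample(c("A", "C", "G", "U"), 1, prob = truth[j, ]), character(1)),
      collapse = "")
  }, character(1))
  fit <- train_site_model(draws, "3ss", pseudocount = 0)
  expect_lt(max(abs(fit$prob - truth)), 0.05)
})

test_that("training on model-sampled sites recovers columns at n = 1e4", {
  set.seed(22)
  model <- train_site_model(c("UACUAAC", "UGCUAAC", "CACUAAU", "UACUGAC"),
                            "bp", pseudocount = 0.2)
  draws <- vapply(1:10000, function(i) {
    paste(vapply(1:7, function(j)
      sample(c("A", "C", "G", "U"), 1, prob = model$prob[j, ]),
      character(1)), collapse = "")
  }, character(1))
  refit <- train_site_model(draws, "bp", pseudocount = 0)
  expect_lt(max(abs(refit$prob - model$prob)), 0.02)
})

test_that("log-odds scoring is additive and matches hand arithmetic", {
  m0 <- train_site_model(rep("UACUAAC", 2), "bp", pseudocount = 0)
  expect_equal(score_site("UACUAAC", m0), 7 * log2(4))   # 14 bits

  # columns equal to background score 0 for every sequence
  flat <- train_site_model(c("ACGU", "CGUA", "GUAC", "UACG"), "3ss",
                           pseudocount = 0)
  for (s in c("AAAA", "ACGU", "UUUU")) expect_equal(score_site(s, flat), 0)

  # pseudocount 0.1, n = 2: mismatching final base
  m <- train_site_model(rep("UACUAAC", 2), "bp", pseudocount = 0.1)
  expected <- 6 * log2((2.1 / 2.4) / 0.25) + log2((0.1 / 2.4) / 0.25)
  expect_equal(score_site("UACUAAU", m), expected)

  # additivity: per-position contributions sum to the total
  contrib <- vapply(1:7, function(j) {
    base <- substr("UACUAAU", j, j)
    log2(m$prob[j, base] / m$background[base])
  }, numeric(1))
  expect_equal(score_site("UACUAAU", m), sum(contrib))

  expect_error(score_site("UACUA", m), "length")
  expect_true(is.na(score_site("UACUANC", m)))
})

test_that("branch point search finds planted motifs and applies tie rules", {
  up <- paste0(strrep("U", 20), "UACUAAC", strrep("U", 20), "CAG")
  r <- make_region(up)
  cand <- score_branch_points(r)
  # planted branch A is 25 nt from the 3' end of the upstream part
  expect_equal(cand$bp_offset[1], -25L)
  expect_identical(cand$window[1], "UACUAAC")

  # no adenosine in range -> empty
  r2 <- make_region(paste0(strrep("C", 40), "AG"))
  expect_equal(nrow(score_branch_points(r2)), 0L)

  # two identical motifs: 3'ss-proximal one wins the tie
  up3 <- paste0("UACUAAC", strrep("U", 10), "UACUAAC", strrep("U", 10), "CAG")
  cand3 <- score_branch_points(make_region(up3))
  top2 <- cand3[cand3$score == max(cand3$score), ]
  expect_equal(top2$bp_offset[1], max(top2$bp_offset))
})

test_that("PPT search maximizes the declared score with tie-breaks", {
  # poly-U tract flanked by purines between BP and -3
  up <- paste0(strrep("G", 10), "A", "UUUUUUUUUU", "A", "AG")
  r <- make_region(up)
  ppt <- ppt_for_branch_point(r, list(bp_offset = -15L))
  expect_equal(ppt$ppt_length, 10L)
  expect_equal(ppt$pyrimidine_fraction, 1.0)
  expect_equal(ppt$ppt_start_offset, -13L)
  expect_equal(ppt$ppt_end_offset, -4L)

  # single absorbed purine: full window (score 8 - 2) beats either 4-run
  up2 <- paste0(strrep("C", 10), "UUUUAUUUU", "A", "AG")
  ppt2 <- ppt_for_branch_point(make_region(up2), list(bp_offset = -13L))
  expect_equal(ppt2$ppt_length, 9L)
  expect_equal(ppt2$ppt_start_offset, -12L)
  expect_equal(ppt2$ppt_end_offset, -4L)
  # exhaustive oracle over all windows
  seqs <- strsplit("UUUUAUUUU", "")[[1]]
  best <- -Inf
  for (a in 1:9) for (b in a:9) {
    if (b - a + 1 < 5) next
    w <- seqs[a:b]
    if (mean(w %in% c("C", "U")) < 0.6) next
    best <- max(best, sum(w %in% c("C", "U")) - 2 * sum(w %in% c("A", "G")))
  }
  got <- sum(seqs[1:9] %in% c("C", "U")) - 2 * sum(seqs[1:9] %in% c("A", "G"))
  expect_equal(got, best)

  # all purines: no qualifying window
  up3 <- paste0(strrep("C", 10), "UACUAAC", "AAAAAAAA", "CAG")
  ppt3 <- ppt_for_branch_point(make_region(up3), list(bp_offset = -12L))
  expect_equal(ppt3$ppt_length, 0L)
  expect_true(is.na(ppt3$ppt_start_offset))
})

test_that("best-BP PPT always lies between the branch point and -3", {
  set.seed(33)
  for (i in 1:100) {
    r <- make_region(paste0(random_rna(sample(30:70, 1)), "AG"))
    cand <- score_branch_points(r)
    if (nrow(cand) == 0L) next
    ppt <- ppt_for_branch_point(r, cand[1, ])
    if (ppt$ppt_length == 0L) next
    expect_gt(ppt$ppt_start_offset, ppt$bp_offset)
    expect_lte(ppt$ppt_end_offset, -3L)
    expect_equal(ppt$ppt_length,
                 ppt$ppt_end_offset - ppt$ppt_start_offset + 1L)
  }
})

test_that("site pair preference counts strict wins and applies the binomial", {
  even <- site_pair_preference(cbind(c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2),
                                     c(2, 1, 2, 1, 2, 1, 2, 1, 2, 1)))
  expect_equal(even$n_stronger, 5)
  expect_equal(even$two_tail_p, 1.0)

  none <- site_pair_preference(cbind(rep(0, 8), rep(1, 8)))
  expect_equal(none$n_stronger, 0)
  expect_equal(none$two_tail_p, 2 * 0.5^8)

  ties <- site_pair_preference(cbind(c(1, 1, 2), c(1, 1, 1)))
  expect_equal(ties$n_ties, 2)
  expect_equal(ties$n_stronger, 1)
})

test_that("site models survive a serialization round trip", {
  m <- default_bp_model()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_site_model(m, f)
  back <- read_site_model(f)
  expect_equal(back$prob, m$prob, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$site_type, "bp")
  expect_equal(back$branch_a_pos, m$branch_a_pos)
  expect_equal(score_site("UACUAAC", back), score_site("UACUAAC", m),
               tolerance = 1e-10)
})
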