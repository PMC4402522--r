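test_that("positional frequencies are indicators for identical regions", {
  r <- make_region("UUCAG", "GA")
  tab <- positional_nucleotide_frequencies(rep(list(r), 10))
  expect_true(all(tab$prob %in% c(0, 1)))
  expect_equal(unname(tab$prob[tab$offsets == -3, "C"]), 1)
  expect_true(all(tab$count == 10))
})

test_that("uniform random regions give near-uniform base probabilities", {
  set.seed(81)
  regions <- lapply(1:500, function(i)
    three_prime_region(paste0("r", i), random_rna(12), 8L, 4L))
  tab <- positional_nucleotide_frequencies(regions)
  expect_true(all(abs(tab$prob - 0.25) < 0.07))
})

test_that("planted adenosine depletion shows as negative log2 enrichment", {
  cfg <- small_cohort(n = 60L, seed = 82L)
  coh <- generate_cohort(cfg, withr::local_tempdir())
  ups <- coh$regions[coh$truth$group == "up"]
  ctrl <- coh$regions[coh$truth$group == "control"]
  offs <- -38:-17
  lr <- enrichment_profile(positional_nucleotide_frequencies(ups, offs),
                           positional_nucleotide_frequencies(ctrl, offs))
  # the depletion applies to background-sampled positions; offsets holding
  # the group-invariant branch-point motif dilute the per-offset signal,
  # so the aggregate ratio is the planted quantity
  expect_lt(mean(lr[, "A"]), -0.5)
  expect_gt(mean(lr[, "A"] < 0), 0.6)
})

test_that("composition at an offset counts bases and excludes N", {
  rs <- list(make_region("UUCAG"), make_region("UACAG"),
             make_region("UGCAG"), make_region("UNCAG"))
  # offset -4 differs between regions; N dropped from the counts
  expect_equal(composition_at(rs, -4L), c(A = 1L, C = 0L, G = 1L, U = 1L))
  expect_equal(composition_at(rs, -3L), c(A = 0L, C = 4L, G = 0L, U = 0L))
})

test_that("group comparisons behave on identical, shifted and planted data", {
  a <- c(1, 2, 3, 4, 5)
  same_w <- compare_feature(a, a, "wilcoxon")
  expect_equal(same_w$p, 1)
  same_t <- compare_feature(a, a, "t")
  expect_equal(same_t$statistic, 0)

  set.seed(83)
  x <- rnorm(50, 70, 15); y <- rnorm(50, 40, 12)
  p1 <- compare_feature(x, y, "t")
  p2 <- compare_feature(x + 100, y + 100, "t")
  expect_equal(p1$p, p2$p)
  expect_gt(p1$statistic, 0)

  # zero variance in both groups and equal means
  flat <- compare_feature(c(2, 2, 2), c(2, 2, 2), "t")
  expect_equal(flat$p, 1)
})

test_that("planted AGEZ separation is detected with overwhelming power", {
  cfg <- small_cohort(n = 100L, seed = 84L)
  coh <- generate_cohort(cfg, withr::local_tempdir())
  ag <- vapply(coh$regions, function(r) find_agez(r)$agez_length, numeric(1))
  up <- ag[coh$truth$group == "up"]; down <- ag[coh$truth$group == "down"]
  expect_lt(compare_feature(up, down, "t")$p, 1e-6)
})

test_that("two-tailed binomial follows the point-probability definition", {
  expect_equal(binomial_two_tail(5, 10, 0.5), 1.0)
  expect_equal(binomial_two_tail(0, 8, 0.5), 2 * 0.5^8)

  # independent summation oracle
  oracle <- function(k, n, p0) {
    pk <- dbinom(k, n, p0)
    min(1, sum(dbinom(0:n, n, p0)[dbinom(0:n, n, p0) <= pk * (1 + 1e-7)]))
  }
  expect_equal(binomial_two_tail(10, 30, 0.5), oracle(10, 30, 0.5))
  expect_equal(binomial_two_tail(51, 138, 0.5), oracle(51, 138, 0.5))
  expect_equal(binomial_two_tail(7, 20, 0.3), oracle(7, 20, 0.3))

  # symmetry at p0 = 0.5
  for (n in c(7, 20, 138)) {
    for (k in c(0, 3, floor(n / 3))) {
      expect_equal(binomial_two_tail(k, n, 0.5),
                   binomial_two_tail(n - k, n, 0.5))
    }
  }
})

test_that("chi-squared matches the textbook formula and closed forms", {
  prop <- rbind(c(10, 20), c(5, 10), c(15, 30))
  res <- chi_square_contingency(prop)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  diag <- rbind(c(10, 0), c(0, 10))
  res2 <- chi_square_contingency(diag)
  expect_equal(res2$statistic, 20)
  expect_equal(res2$p, stats::pchisq(20, 1, lower.tail = FALSE))

  set.seed(85)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 20) + 1, 3, 2)
    got <- chi_square_contingency(tab)
    expected_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - expected_counts)^2 / expected_counts)
    expect_equal(got$statistic, stat, tolerance = 1e-12)
    expect_equal(got$effect, 2)   # df of a 3x2 table
  }
  expect_error(chi_square_contingency(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("hypergeometric enrichment matches combinatorial closed forms", {
  expect_equal(hypergeometric_enrichment(1, 1, 1, 1), 1)
  expect_equal(hypergeometric_enrichment(2, 2, 2, 4), 1 / 6)

  # direct summation oracle
  oracle <- function(k, m, K, N) {
    sum(vapply(k:min(m, K), function(x)
      choose(K, x) * choose(N - K, m - x) / choose(N, m), numeric(1)))
  }
  expect_equal(hypergeometric_enrichment(14, 51, 3518, 20000),
               oracle(14, 51, 3518, 20000), tolerance = 1e-12)
  expect_equal(hypergeometric_enrichment(5, 20, 50, 200),
               oracle(5, 20, 50, 200), tolerance = 1e-12)
  expect_error(hypergeometric_enrichment(3, 2, 5, 10), "inconsistent")
})

test_that("pearson correlation handles exact, affine and degenerate cases", {
  x <- c(1, 3, 7, 2, 9, 4)
  expect_equal(pearson_correlation(x, 2 * x)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)

  set.seed(86)
  a <- rnorm(30); b <- a + rnorm(30)
  r1 <- pearson_correlation(a, b)
  r2 <- pearson_correlation(3 * a + 5, 0.5 * b - 2)
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)

  flat <- pearson_correlation(rep(1, 5), rnorm(5))
  expect_false(flat$defined)
  expect_true(is.na(flat$r))
})

test_that("planted correlation is recovered within the Fisher-z interval", {
  cfg <- small_cohort(n = 100L, seed = 87L)
  coh <- generate_cohort(cfg, withr::local_tempdir())
  up <- coh$truth[coh$truth$group == "up", ]
  est <- pearson_correlation(up$agez_length, up$expression_change)
  expect_lt(abs(atanh(est$r) - atanh(0.4)), 1.96 / sqrt(100 - 3))
})

test_that("BH adjustment is monotone, order-preserving and bounded", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)

  set.seed(88)
  p <- runif(100)
  q <- bh_adjust(p)
  expect_true(all(q <= 1))
  expect_gte(min(q), min(p))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  # permuting the input permutes the output identically
  perm <- sample(100)
  expect_equal(bh_adjust(p[perm]), q[perm])
})
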