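# Group-level statistics: positional composition profiles and the standard
# battery of tests (Welch t, Wilcoxon-Mann-Whitney, exact binomial, chi2,
# hypergeometric, Pearson) reported in a uniform comparison record.
# Implementations delegate to the base R tests; this module fixes the
# conventions (two-tailed point-probability binomial, no chi2 continuity
# correction, Welch variances) and the output contract.

group_comparison <- function(test, statistic, p, n_a, n_b = NA_integer_,
                             effect = NA_real_) {
  structure(list(test = test, statistic = unname(statistic), p = unname(p),
                 n_a = n_a, n_b = n_b, effect = unname(effect)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, p = %.4g (n = %s vs %s)\n",
              x$test, x$statistic, x$p, x$n_a, x$n_b))
  invisible(x)
}

#' Positional nucleotide frequencies over a set of regions
#'
#' Per-offset probabilities of A, C, G, U; `N`s are excluded from the
#' denominators.
#'
#' @param regions List of [three_prime_region()] objects.
#' @param offsets Integer vector of offsets to tabulate (default: union of
#'   offsets covered by any region).
#' @return List of class `positional_freq`: `offsets`, `prob` (matrix
#'   offsets x ACGU), `count` (non-N counts per offset).
#' @export
positional_nucleotide_frequencies <- function(regions, offsets = NULL) {
  if (length(regions) < 1L) stop("need at least one region")
  if (is.null(offsets)) {
    offsets <- sort(unique(unlist(lapply(regions, region_offsets))))
  }
  counts <- matrix(0L, length(offsets), 4L,
                   dimnames = list(offsets, RNA_BASES))
  for (r in regions) {
    ro <- region_offsets(r)
    ch <- strsplit(r$sequence, "")[[1]]
    keep <- ro %in% offsets & ch %in% RNA_BASES
    if (!any(keep)) next
    ij <- cbind(match(ro[keep], offsets), match(ch[keep], RNA_BASES))
    for (k in seq_len(nrow(ij)))
      counts[ij[k, 1], ij[k, 2]] <- counts[ij[k, 1], ij[k, 2]] + 1L
  }
  tot <- rowSums(counts)
  prob <- counts / ifelse(tot > 0, tot, NA)
  structure(list(offsets = offsets, prob = prob, count = tot),
            class = "positional_freq")
}

#' Per-offset log2 enrichment between two frequency tables
#'
#' `log2(prob_a / prob_b)` per offset and base, with infinities from zero
#' cells clamped at +/- `clamp`.
#'
#' @param table_a,table_b [positional_nucleotide_frequencies()] results
#'   over the same offsets.
#' @param clamp Clamp magnitude for zero-cell ratios.
#' @return Matrix offsets x ACGU of clamped log2 ratios.
#' @export
enrichment_profile <- function(table_a, table_b, clamp = 5) {
  stopifnot(identical(table_a$offsets, table_b$offsets))
  lr <- log2(table_a$prob / table_b$prob)
  lr[lr > clamp] <- clamp
  lr[lr < -clamp] <- -clamp
  lr
}

#' Base counts at a single offset
#'
#' @param regions List of regions.
#' @param offset Signed offset covered by every region counted.
#' @return Named integer vector over A, C, G, U (N excluded).
#' @export
composition_at <- function(regions, offset) {
  ch <- vapply(regions, function(r) {
    ro <- region_offsets(r)
    if (offset %in% ro) region_char_at(r, offset) else NA_character_
  }, character(1))
  ch <- ch[!is.na(ch) & ch %in% RNA_BASES]
  stats::setNames(tabulate(factor(ch, levels = RNA_BASES), nbins = 4L),
                  RNA_BASES)
}

#' Compare a feature between two groups
#'
#' Welch t-test (unequal variances) or two-sided Wilcoxon-Mann-Whitney.
#' The statistic sign follows `mean(a) - mean(b)`.  If both groups have
#' zero variance and equal means, `p = 1` by convention.
#'
#' @param values_a,values_b Numeric vectors (each `n >= 2`).
#' @param test `"t"` or `"wilcoxon"`.
#' @return A `group_comparison` (effect = mean difference).
#' @export
compare_feature <- function(values_a, values_b, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 finite values")
  diff_means <- mean(values_a) - mean(values_b)
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (diff_means == 0)
      return(group_comparison(test, 0, 1, length(values_a),
                              length(values_b), 0))
    if (test == "t")
      return(group_comparison("t", sign(diff_means) * Inf, 0,
                              length(values_a), length(values_b), diff_means))
  }
  if (test == "t") {
    ht <- stats::t.test(values_a, values_b)
    group_comparison("t", ht$statistic, ht$p.value,
                     length(values_a), length(values_b), diff_means)
  } else {
    exact <- length(values_a) <= 12L && length(values_b) <= 12L &&
      !anyDuplicated(c(values_a, values_b))
    ht <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, exact = exact, correct = TRUE))
    group_comparison("wilcoxon", ht$statistic, ht$p.value,
                     length(values_a), length(values_b), diff_means)
  }
}

#' Exact two-tailed binomial test
#'
#' Point-probability method: the two-tailed p is the sum of probabilities
#' of all outcomes whose point probability does not exceed that of the
#' observed count, capped at 1.
#'
#' @param k Successes.
#' @param n Trials.
#' @param p0 Null success probability.
#' @return Two-tailed p-value.
#' @export
binomial_two_tail <- function(k, n, p0 = 0.5) {
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  min(1, stats::binom.test(k, n, p0)$p.value)
}

#' Pearson chi-squared test on an r x c contingency table
#'
#' No continuity correction; df = (r-1)(c-1).
#'
#' @param table Matrix of counts with positive marginals.
#' @return A `group_comparison` (`n_a` = total count, effect = df).
#' @export
chi_square_contingency <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("contingency table has a zero marginal")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  group_comparison("chi2", ht$statistic, ht$p.value, sum(table),
                   NA_integer_, effect = unname(ht$parameter))
}

#' Upper-tail hypergeometric enrichment
#'
#' P(X >= k) when drawing `m` items from a universe of `N` containing `K`
#' marked items.
#'
#' @param hits_in_set Observed marked items in the set (k).
#' @param set_size Set size (m).
#' @param hits_total Marked items in the universe (K).
#' @param universe Universe size (N).
#' @return Upper-tail p-value.
#' @export
hypergeometric_enrichment <- function(hits_in_set, set_size, hits_total,
                                      universe) {
  k <- hits_in_set; m <- set_size; K <- hits_total; N <- universe
  if (k > min(m, K) || K > N || m > N)
    stop("inconsistent hypergeometric counts")
  stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE)
}

#' Pearson correlation with two-sided p
#'
#' @param x,y Numeric vectors, `n >= 3`, finite.
#' @return List: `r`, `p`, `n`, `defined` (FALSE when a variable has zero
#'   variance, in which case `r` is `NA`).
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x), defined = FALSE))
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x),
       defined = TRUE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; input order is
#' preserved.  `NA`s pass through.
#'
#' @param pvalues Numeric vector of p-values.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}
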