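# 3'ss architecture features: AG exclusion zone, branch-point candidates,
# polypyrimidine tract anchored at the best branch point, and intrinsic
# site strength scoring of competing 3'ss pairs.

#' Locate the AG exclusion zone of a 3'ss window
#'
#' Scans upstream offsets `-3, -4, ...` for the first AG dinucleotide read
#' 5'->3' (A at offset `o`, G at `o + 1`, requiring `o + 1 <= -3`).  The
#' AGEZ length is the number of nucleotides strictly between that G and the
#' A of the 3'ss AG, i.e. `|G offset| - 3`.  When no upstream AG exists in
#' the window, the result is censored with `agez_length = up_len - 2`.
#'
#' Regions without a canonical AG at offsets -2/-1 are flagged but still
#' scanned.
#'
#' @param region A [three_prime_region()] with `up_len >= 4`.
#' @return A list of class `agez_result`: `exon_id`, `agez_length`,
#'   `upstream_ag_offset` (offset of the G, `NA` when censored),
#'   `censored`, `canonical`.
#' @export
find_agez <- function(region) {
  stopifnot(inherits(region, "three_prime_region"))
  if (region$up_len < 4L) stop("find_agez needs up_len >= 4")
  ch <- strsplit(region$sequence, "")[[1]][seq_len(region$up_len)]
  # index i holds offset i - up_len - 1; G at offset g <= -3 means index
  # g + up_len + 1 <= up_len - 2
  g_idx_max <- region$up_len - 2L
  g_off <- NA_integer_
  for (gi in seq(g_idx_max, 2L)) {
    if (ch[gi] == "G" && ch[gi - 1L] == "A") {
      g_off <- gi - region$up_len - 1L
      break
    }
  }
  censored <- is.na(g_off)
  structure(list(
    exon_id = region$exon_id,
    agez_length = if (censored) region$up_len - 2L else -g_off - 3L,
    upstream_ag_offset = g_off,
    censored = censored,
    canonical = region$canonical
  ), class = "agez_result")
}

#' Per-offset presence of a purine dinucleotide upstream of the 3'ss
#'
#' Marks the first base of every occurrence of the given purine
#' dinucleotide over the upstream offsets.  Aggregating the binary vectors
#' across a group of regions yields per-offset occurrence frequencies,
#' used to check that an AG-specific depletion is not shared by AA, AG,
#' GA, GG alike.
#'
#' @param region A [three_prime_region()].
#' @param dinucleotide Two-character string over A, G.
#' @return Named integer vector (0/1) over upstream offsets
#'   `-up_len .. -2` (the first base of a dinucleotide ending at -1 sits
#'   at -2).
#' @export
count_purine_dinucleotides <- function(region, dinucleotide = "AG") {
  stopifnot(inherits(region, "three_prime_region"))
  dinucleotide <- toupper(dinucleotide)
  if (!grepl("^[AG]{2}$", dinucleotide))
    stop("dinucleotide must be a 2-mer over A, G")
  ch <- strsplit(region$sequence, "")[[1]][seq_len(region$up_len)]
  first <- substr(dinucleotide, 1, 1)
  second <- substr(dinucleotide, 2, 2)
  hit <- as.integer(ch[-length(ch)] == first & ch[-1] == second)
  names(hit) <- seq_len(region$up_len - 1L) - region$up_len - 1L
  hit
}

#' Score branch-point candidates in a 3'ss window
#'
#' Every adenosine whose scoring window fits inside the region and the
#' configured search range is scored under a branch-point weight matrix
#' (branch A fixed at the model's `branch_a_pos`).  Candidates are sorted
#' by decreasing score; exact ties are broken toward the 3'ss-proximal
#' offset.
#'
#' @param region A [three_prime_region()].
#' @param bp_model A `site_model` of type `"bp"` (default
#'   [default_bp_model()]).
#' @param search_range Integer vector `c(nearest, farthest)` of branch-A
#'   offsets searched (default `c(-9, -100)`, clipped to the window).
#' @return data.frame of class `bp_candidates` with columns `bp_offset`,
#'   `score`, `window`; zero rows when no adenosine is in range.
#' @export
score_branch_points <- function(region, bp_model = default_bp_model(),
                                search_range = c(-9L, -100L)) {
  stopifnot(inherits(region, "three_prime_region"),
            identical(bp_model$site_type, "bp"))
  L <- nrow(bp_model$prob)
  apos <- bp_model$branch_a_pos
  near <- max(search_range)
  far <- min(search_range)
  empty <- data.frame(bp_offset = integer(0), score = numeric(0),
                      window = character(0), stringsAsFactors = FALSE)
  out <- empty
  for (off in seq(near, far)) {
    # window occupies offsets off - apos + 1 .. off + (L - apos)
    w_lo <- off - apos + 1L
    w_hi <- off + (L - apos)
    if (w_lo < -region$up_len || w_hi > region$down_len - 1L) next
    if (region_char_at(region, off) != "A") next
    win <- substr(region$sequence, region_index_of(region, w_lo),
                  region_index_of(region, w_hi))
    sc <- score_site(win, bp_model)
    if (is.na(sc)) next
    out <- rbind(out, data.frame(bp_offset = off, score = sc, window = win,
                                 stringsAsFactors = FALSE))
  }
  if (nrow(out) > 0L) {
    # stable sort: decreasing score, ties toward larger (3'ss-proximal) offset
    out <- out[order(-out$score, -out$bp_offset), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("bp_candidates", "data.frame")
  out
}

#' Polypyrimidine tract anchored at a branch point
#'
#' Exhaustively scans contiguous windows between `bp_offset + 1` and `-3`
#' under the score `#pyrimidines - 2 * #purines` (N counts as neither),
#' keeping windows of length >= `min_len` with pyrimidine fraction >=
#' `min_fraction`.  The maximal-scoring window wins; ties are broken toward
#' the longer window, then toward the 3'ss-proximal one.  When no window
#' qualifies, `ppt_length` is 0 with empty bounds.
#'
#' @param region A [three_prime_region()].
#' @param bp A single branch-point candidate (one row of
#'   [score_branch_points()] output, or a list with `bp_offset`).
#' @param min_len Minimum window length (nt).
#' @param min_fraction Minimum pyrimidine fraction of a qualifying window.
#' @param purine_penalty Score subtracted per purine.
#' @return List of class `ppt_result`: `exon_id`, `bp_offset`,
#'   `ppt_start_offset`, `ppt_end_offset` (`NA` when empty), `ppt_length`,
#'   `pyrimidine_fraction`.
#' @export
ppt_for_branch_point <- function(region, bp, min_len = 5L,
                                 min_fraction = 0.6, purine_penalty = 2) {
  stopifnot(inherits(region, "three_prime_region"))
  bp_offset <- as.integer(bp$bp_offset[1])
  if (bp_offset >= -3L) stop("branch point must lie 5' of offset -3")
  offs <- seq(bp_offset + 1L, -3L)
  ch <- vapply(offs, function(o) region_char_at(region, o), character(1))
  is_pyr <- ch %in% c("C", "U")
  is_pur <- ch %in% c("A", "G")
  best <- NULL
  n <- length(offs)
  for (a in seq_len(n)) {
    if (n - a + 1L < min_len) break
    np <- 0L; nr <- 0L
    for (b in a:n) {
      np <- np + is_pyr[b]
      nr <- nr + is_pur[b]
      len <- b - a + 1L
      if (len < min_len) next
      if (np / len < min_fraction) next
      sc <- np - purine_penalty * nr
      if (is.null(best) || sc > best$sc ||
          (sc == best$sc && (len > best$len ||
                             (len == best$len && offs[b] > best$end)))) {
        best <- list(sc = sc, len = len, start = offs[a], end = offs[b],
                     frac = np / len)
      }
    }
  }
  if (is.null(best)) {
    res <- list(exon_id = region$exon_id, bp_offset = bp_offset,
                ppt_start_offset = NA_integer_, ppt_end_offset = NA_integer_,
                ppt_length = 0L, pyrimidine_fraction = NA_real_)
  } else {
    res <- list(exon_id = region$exon_id, bp_offset = bp_offset,
                ppt_start_offset = best$start, ppt_end_offset = best$end,
                ppt_length = best$len, pyrimidine_fraction = best$frac)
  }
  class(res) <- "ppt_result"
  res
}

#' Intrinsic-strength preference among competing 3'ss pairs
#'
#' Given intrinsic scores of promoted and repressed sites of each pair,
#' counts how often the promoted site is strictly stronger and tests the
#' proportion against the even-preference null with an exact two-tailed
#' binomial test.  Exact ties count as not-stronger and are reported
#' separately.
#'
#' @param score_pairs Two-column matrix or data.frame: column 1 the
#'   promoted-site score, column 2 the repressed-site score of each pair.
#' @return List: `n_stronger`, `n_ties`, `n_total`, `proportion`,
#'   `two_tail_p`.
#' @export
site_pair_preference <- function(score_pairs) {
  sp <- as.matrix(score_pairs)
  if (nrow(sp) < 1L) stop("need at least one score pair")
  if (ncol(sp) != 2L) stop("score_pairs must have two columns")
  n_stronger <- sum(sp[, 1] > sp[, 2])
  n_ties <- sum(sp[, 1] == sp[, 2])
  n_total <- nrow(sp)
  list(n_stronger = n_stronger, n_ties = n_ties, n_total = n_total,
       proportion = n_stronger / n_total,
       two_tail_p = binomial_two_tail(n_stronger, n_total, 0.5))
}

#' Architecture feature table for a set of regions
#'
#' Convenience wrapper computing, per region: AGEZ length, best branch
#' point, its PPT, and the intrinsic 3'ss score (window -20..+2 under
#' `ss_model`; `NA` when the window does not fit or contains N).
#'
#' @param regions List of [three_prime_region()] objects.
#' @param records Optional data.frame with `exon_id`, `group`,
#'   `expression_change` merged into the output.
#' @param bp_model,ss_model Site models (defaults bundled).
#' @param bp_search Branch-point search range.
#' @return data.frame, one row per region.
#' @export
architecture_features <- function(regions, records = NULL,
                                  bp_model = default_bp_model(),
                                  ss_model = default_3ss_model(),
                                  bp_search = c(-9L, -100L)) {
  rows <- lapply(regions, function(r) {
    ag <- find_agez(r)
    cand <- score_branch_points(r, bp_model, bp_search)
    if (nrow(cand) > 0L) {
      ppt <- ppt_for_branch_point(r, cand[1, ])
      bp_off <- cand$bp_offset[1]; bp_sc <- cand$score[1]
      ppt_len <- ppt$ppt_length; pyr <- ppt$pyrimidine_fraction
    } else {
      bp_off <- NA_integer_; bp_sc <- NA_real_
      ppt_len <- NA_integer_; pyr <- NA_real_
    }
    L <- nrow(ss_model$prob)       # window -(L-3) .. +2
    ss_sc <- if (r$up_len >= L - 3L && r$down_len >= 3L) {
      score_site(substr(r$sequence, region_index_of(r, -(L - 3L)),
                        region_index_of(r, 2L)), ss_model)
    } else NA_real_
    data.frame(exon_id = r$exon_id, agez_length = ag$agez_length,
               censored = ag$censored, canonical = ag$canonical,
               bp_offset = bp_off, bp_score = bp_sc, ppt_length = ppt_len,
               pyrimidine_fraction = pyr, site_score_3ss = ss_sc,
               stringsAsFactors = FALSE)
  })
  feat <- do.call(rbind, rows)
  if (!is.null(records)) {
    feat <- merge(feat,
                  records[, intersect(c("exon_id", "group",
                                        "expression_change"), names(records))],
                  by = "exon_id", sort = FALSE)
  }
  feat
}
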