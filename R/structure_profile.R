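# Equilibrium secondary-structure ensemble under a pair-additive energy
# model: partition function, base-pair probabilities, per-position unpaired
# probabilities (PU), group PU profiles and positional delta-PU statistics.

#' Pair-additive RNA energy model
#'
#' Watson-Crick and wobble pairs carry a flat per-pair energy (kcal/mol,
#' negative favorable); structures are pseudoknot-free with a minimum
#' hairpin loop.  This stacking-free model keeps the whole ensemble exactly
#' enumerable, so the cubic-time recursions can be verified against brute
#' force; an external folding engine can be slotted in via the `fold_fun`
#' argument of the PU operations without changing any downstream contract.
#'
#' @param gc,au,gu Pair energies (kcal/mol) for GC/CG, AU/UA, GU/UG.
#' @param kT Thermal energy (kcal/mol).
#' @param min_hairpin Minimum unpaired nucleotides enclosed by a hairpin.
#' @return Object of class `energy_model`.
#' @export
energy_model <- function(gc = -3.0, au = -2.0, gu = -1.0, kT = 0.616,
                         min_hairpin = 3L) {
  stopifnot(kT > 0, min_hairpin >= 3L)
  pe <- c(GC = gc, CG = gc, AU = au, UA = au, GU = gu, UG = gu)
  structure(list(pair_energy = pe, kT = kT,
                 min_hairpin = as.integer(min_hairpin)),
            class = "energy_model")
}

seq_codes <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  codes <- match(ch, c(RNA_BASES, "N")) - 1L
  if (any(is.na(codes))) stop("invalid letters in sequence (need A,C,G,U,N)")
  codes
}

pair_weight_matrix <- function(model) {
  W <- matrix(0, 5, 5)
  b <- c(A = 1L, C = 2L, G = 3L, U = 4L)  # N (5) never pairs
  for (pp in names(model$pair_energy)) {
    i <- b[[substr(pp, 1, 1)]]
    j <- b[[substr(pp, 2, 2)]]
    W[i, j] <- exp(-model$pair_energy[[pp]] / model$kT)
  }
  W
}

#' Partition function and base-pair probabilities
#'
#' McCaskill-style inside-outside recursions (cubic time) over the
#' pair-additive model: Z sums Boltzmann weights `exp(-E/kT)` over all
#' pseudoknot-free structures with `E` the sum of pair energies.
#'
#' @param seq RNA text over A, C, G, U, N (N never pairs).
#' @param model An [energy_model()].
#' @param unpaired Optional integer vector of 1-based positions constrained
#'   to stay unpaired (restricted-ensemble calculations).
#' @return Object of class `pair_prob_matrix`: `n`, symmetric matrix `p` of
#'   pairing probabilities, `Z`, `logZ`.
#' @export
partition_function <- function(seq, model = energy_model(), unpaired = integer(0)) {
  n <- nchar(seq)
  if (n < 1L || n > 5000L) stop("sequence length must be in 1..5000")
  codes <- seq_codes(seq)
  W <- pair_weight_matrix(model)
  # per-nucleotide scale against overflow: between the empty-structure
  # weight 1 and the strongest all-paired weight
  wmax <- max(W, 1)
  scale <- exp(log(wmax) / 4)
  res <- .partition_cpp(codes, W, model$min_hairpin, scale, as.integer(unpaired))
  structure(list(n = n, p = res$p, Z = exp(res$logZ), logZ = res$logZ),
            class = "pair_prob_matrix")
}

#' Per-position unpaired probabilities of a sequence
#'
#' `PU_i = 1 - sum_j p[i, j]`.
#'
#' @inheritParams partition_function
#' @return Numeric vector of PU values.
#' @export
unpaired_probabilities <- function(seq, model = energy_model()) {
  pm <- partition_function(seq, model)
  pmin(pmax(1 - rowSums(pm$p), 0), 1)
}

#' Probability that a whole substring is unpaired
#'
#' Restricted-ensemble ratio: Z with positions `from..to` forbidden to
#' pair, divided by the unconstrained Z.  Generalizes per-position PU to
#' substring length > 1; the positional pipeline uses length 1 only.
#'
#' @param seq RNA text.
#' @param from,to 1-based substring bounds.
#' @param model An [energy_model()].
#' @return Probability in \[0, 1\].
#' @export
pu_unpaired_stretch <- function(seq, from, to, model = energy_model()) {
  stopifnot(from >= 1, to >= from, to <= nchar(seq))
  z1 <- partition_function(seq, model, unpaired = seq.int(from, to))$logZ
  z0 <- partition_function(seq, model)$logZ
  min(1, exp(z1 - z0))
}

#' Exhaustive structure enumeration (test oracle)
#'
#' Explicitly enumerates every pseudoknot-free set of allowed pairs
#' respecting the minimum hairpin loop, Boltzmann-weights them, and returns
#' the exact partition function and pair probabilities.  Exponential time;
#' refused above 22 nt.  Kept independent of the recursive implementation
#' so the two can verify each other.
#'
#' @inheritParams partition_function
#' @return List: `Z`, `p` (exact pair-probability matrix),
#'   `n_structures`.
#' @export
enumerate_structures <- function(seq, model = energy_model()) {
  n <- nchar(seq)
  if (n > 22L) stop("enumeration oracle is capped at 22 nt")
  codes <- seq_codes(seq)
  W <- pair_weight_matrix(model)
  mh <- model$min_hairpin
  # recursively enumerate pair sets over interval i..j
  enum <- function(i, j) {
    if (i >= j) return(list(list(pairs = NULL, w = 1)))
    out <- list()
    # case: i unpaired
    for (s in enum(i + 1L, j)) out[[length(out) + 1L]] <- s
    # case: i paired with k
    ks <- if (i + mh + 1L <= j) seq.int(i + mh + 1L, j) else integer(0)
    for (k in ks) {
      w <- W[codes[i] + 1L, codes[k] + 1L]
      if (w == 0) next
      inner <- enum(i + 1L, k - 1L)
      outer <- enum(k + 1L, j)
      for (si in inner) for (so in outer) {
        out[[length(out) + 1L]] <- list(
          pairs = rbind(si$pairs, so$pairs, c(i, k)),
          w = w * si$w * so$w)
      }
    }
    out
  }
  structs <- enum(1L, n)
  Z <- sum(vapply(structs, `[[`, numeric(1), "w"))
  P <- matrix(0, n, n)
  for (s in structs) {
    if (!is.null(s$pairs)) {
      for (r in seq_len(nrow(s$pairs))) {
        i <- s$pairs[r, 1]; j <- s$pairs[r, 2]
        P[i, j] <- P[i, j] + s$w
        P[j, i] <- P[j, i] + s$w
      }
    }
  }
  list(Z = Z, p = P / Z, n_structures = length(structs))
}

#' PU vector of one region, folded in its genomic context
#'
#' The region sequence is extended by up to `flank` nt of stored context on
#' each side, folded once, and the PU values of the unextended window are
#' reported.
#'
#' @param region A [three_prime_region()] (context comes from its
#'   `flank_up`/`flank_down` fields; `flank = 0` folds the bare window).
#' @param flank Flank length (nt) drawn from the stored context.
#' @param model An [energy_model()].
#' @param fold_fun Optional replacement folding engine: a
#'   `function(seq)` returning per-position PU values for the full
#'   extended sequence (adapter slot for external engines).
#' @return Named numeric vector of PU values, names = signed offsets.
#' @export
pu_profile_region <- function(region, flank = 30L, model = energy_model(),
                              fold_fun = NULL) {
  stopifnot(inherits(region, "three_prime_region"), flank >= 0L)
  fu <- region$flank_up; fd <- region$flank_down
  if (flank < nchar(fu)) fu <- substr(fu, nchar(fu) - flank + 1L, nchar(fu))
  if (flank < nchar(fd)) fd <- substr(fd, 1L, flank)
  ext <- paste0(fu, region$sequence, fd)
  pu <- if (is.null(fold_fun)) unpaired_probabilities(ext, model)
        else fold_fun(ext)
  core <- pu[nchar(fu) + seq_len(region$up_len + region$down_len)]
  stats::setNames(core, region_offsets(region))
}

#' Mean PU profile of a group of regions
#'
#' Arithmetic mean of per-region PU at each offset over the regions
#' covering it.
#'
#' @param regions Non-empty list of regions.
#' @param group Group label attached to the result.
#' @inheritParams pu_profile_region
#' @return data.frame of class `pu_profile`: `offset`, `mean_pu`, `n`.
#' @export
group_pu_profile <- function(regions, group = "group", flank = 30L,
                             model = energy_model(), fold_fun = NULL) {
  if (length(regions) < 1L) stop("need at least one region")
  pus <- lapply(regions, pu_profile_region, flank = flank, model = model,
                fold_fun = fold_fun)
  offsets <- sort(unique(unlist(lapply(pus, function(x) as.integer(names(x))))))
  mat <- vapply(pus, function(x) {
    x[match(as.character(offsets), names(x))]
  }, numeric(length(offsets)))
  mat <- matrix(mat, nrow = length(offsets))
  out <- data.frame(offset = offsets,
                    mean_pu = rowMeans(mat, na.rm = TRUE),
                    n = rowSums(!is.na(mat)))
  attr(out, "group") <- group
  class(out) <- c("pu_profile", "data.frame")
  out
}

#' Positional delta-PU between upregulated and downregulated groups
#'
#' Per offset: `delta = mean PU(up) - mean PU(down)`, a two-sided
#' Wilcoxon-Mann-Whitney test on the per-region PU values (exact when both
#' groups have <= 12 regions at the offset and no ties; tie-corrected
#' normal approximation with continuity correction otherwise), BH q-values
#' across offsets, and a significance star at raw `p < 0.05` (the starring
#' convention; q is reported alongside).  Offsets covered by fewer than 2
#' regions in either group get `NA` p.
#'
#' @param up_regions,down_regions Non-empty lists of regions.
#' @inheritParams pu_profile_region
#' @param star_alpha Raw-p threshold for the significance flag.
#' @return data.frame of class `delta_pu`: `offset`, `mean_up`, `n_up`,
#'   `mean_down`, `n_down`, `delta`, `p`, `q`, `star`.
#' @export
delta_pu <- function(up_regions, down_regions, flank = 30L,
                     model = energy_model(), fold_fun = NULL,
                     star_alpha = 0.05) {
  if (length(up_regions) < 1L || length(down_regions) < 1L)
    stop("both groups must be non-empty")
  pu_mat <- function(regions) {
    lapply(regions, pu_profile_region, flank = flank, model = model,
           fold_fun = fold_fun)
  }
  ups <- pu_mat(up_regions)
  downs <- pu_mat(down_regions)
  offsets <- sort(unique(c(
    unlist(lapply(ups, function(x) as.integer(names(x)))),
    unlist(lapply(downs, function(x) as.integer(names(x)))))))
  vals_at <- function(lst, off) {
    v <- vapply(lst, function(x) {
      i <- match(as.character(off), names(x))
      if (is.na(i)) NA_real_ else x[[i]]
    }, numeric(1))
    v[!is.na(v)]
  }
  rows <- lapply(offsets, function(off) {
    a <- vals_at(ups, off)
    b <- vals_at(downs, off)
    delta <- mean(a) - mean(b)
    p <- if (length(a) >= 2L && length(b) >= 2L) {
      exact <- length(a) <= 12L && length(b) <= 12L &&
        !anyDuplicated(c(a, b))
      suppressWarnings(
        stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
    } else NA_real_
    data.frame(offset = off, mean_up = mean(a), n_up = length(a),
               mean_down = mean(b), n_down = length(b), delta = delta, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$star <- !is.na(out$p) & out$p < star_alpha
  class(out) <- c("delta_pu", "data.frame")
  out
}
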