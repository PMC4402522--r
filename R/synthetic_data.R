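# Deterministic synthetic cohorts of 3'ss-anchored regions with planted,
# parameterized effects: AGEZ length distributions per group, branch-point
# motif and PPT composition, positional base-frequency modifiers,
# optional upstream hairpins, and expression changes correlated with AGEZ.
# Sequences are built outward from the anchored 3'ss so that planted
# features are exact by construction, which makes planted = measured tests
# possible.  A single integer seed drives one root stream; per-region
# substreams are derived by counter so cohorts are reproducible
# independently of generation order.

#' Cohort configuration
#'
#' Defaults encode the study conditions the pipeline is designed around:
#' upregulated exons carry longer AG exclusion zones (mean 70 vs 40 nt for
#' downregulated, controls intermediate at 45 nt), a more pyrimidine-rich
#' tract, adenosine depletion over the optimal branch-point zone (-17..-38),
#' and an AGEZ-correlated expression change (r = 0.4); downregulated exons
#' are the mirror group and controls are neutral.
#'
#' @param n Named integer vector: regions per group (up, down, control).
#' @param up_len,down_len Window lengths (nt).
#' @param flank Context (nt) written around each window in the cohort
#'   contigs, available for folding with flanks.
#' @param agez Named list per group of `c(mean, sd)` AGEZ lengths (nt);
#'   sampled values are clamped to `[28, up_len - 6]` so the branch-point
#'   motif and boundary AG always fit.
#' @param ppt_fraction Named numeric: pyrimidine fraction of the tract
#'   between branch point and -3, per group.
#' @param bp_motif Branch-point 7-mer planted with its branch A at a
#'   sampled offset (`bp_mean`, `bp_sd`).
#' @param bp_mean,bp_sd Branch-A offset distribution.
#' @param a_depletion Named list per group: `list(zone = c(hi, lo),
#'   factor)` multiplicative adenosine weight over the offset zone.
#' @param structure_mode Named character per group: `"unstructured"` or
#'   `"hairpin_upstream"` (complementary stem planted over -25..-50).
#' @param stem_len Hairpin stem length (nt, 8-12).
#' @param expression Named list per group: `list(mean, sd, r)` for the
#'   expression-change draw; `r` is the planted Pearson correlation with
#'   the realized AGEZ length.
#' @param seed Root seed (integer).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(
    n = c(up = 100L, down = 100L, control = 100L),
    up_len = 100L, down_len = 50L, flank = 30L,
    agez = list(up = c(70, 15), down = c(40, 12), control = c(45, 12)),
    ppt_fraction = c(up = 0.9, down = 0.75, control = 0.8),
    bp_motif = "UACUAAC", bp_mean = -24, bp_sd = 3,
    a_depletion = list(up = list(zone = c(-17L, -38L), factor = 0.45)),
    structure_mode = c(up = "unstructured", down = "unstructured",
                       control = "unstructured"),
    stem_len = 11L,
    expression = list(up = list(mean = 1.5, sd = 0.8, r = 0.4),
                      down = list(mean = -1.5, sd = 0.8, r = 0),
                      control = list(mean = 0, sd = 0.3, r = 0)),
    seed = 1L) {
  stopifnot(all(GROUP_LEVELS %in% names(n)), all(n >= 1L),
            up_len >= 40L, down_len >= 10L,
            stem_len >= 8L, stem_len <= 12L,
            all(ppt_fraction >= 0 & ppt_fraction <= 1))
  for (g in GROUP_LEVELS) {
    if (agez[[g]][1] > up_len - 2L)
      stop("infeasible config: AGEZ zone longer than up_len - 2 for ", g)
  }
  structure(list(n = n, up_len = as.integer(up_len),
                 down_len = as.integer(down_len), flank = as.integer(flank),
                 agez = agez, ppt_fraction = ppt_fraction,
                 bp_motif = toupper(bp_motif), bp_mean = bp_mean,
                 bp_sd = bp_sd, a_depletion = a_depletion,
                 structure_mode = structure_mode, stem_len = as.integer(stem_len),
                 expression = expression, seed = as.integer(seed)),
            class = "cohort_config")
}

# counter-derived substream seed (32-bit safe)
region_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 2654435761 + counter * 40503 + 97) %%
               2147483647)
}

# background intron composition; structure-zone composition per mode
BG_INTRON <- c(A = 0.22, C = 0.22, G = 0.20, U = 0.36)
BG_EXON <- c(A = 0.26, C = 0.26, G = 0.26, U = 0.22)
BG_UNSTRUCTURED <- c(A = 0.15, C = 0.30, G = 0.05, U = 0.50)

sample_base <- function(weights) {
  sample(RNA_BASES, 1L, prob = weights)
}

#' Generate one synthetic region with planted features
#'
#' The upstream sequence is constructed outward from the fixed 3'ss AG:
#' an AG-free zone of the sampled AGEZ length (AG dinucleotides rejected at
#' sampling time), a branch-point motif, a pyrimidine tract of the
#' configured composition between branch point and -3, the planted boundary
#' AG, and free background beyond it.  Positional adenosine modifiers and
#' the structure mode are applied inside the zone.
#'
#' @param config A [cohort_config()].
#' @param group One of `"up"`, `"down"`, `"control"`.
#' @param counter Region counter within the cohort (drives the substream).
#' @return List: `region` (a [three_prime_region()] with flanks),
#'   `record` (exon metadata incl. `expression_change` placeholder set by
#'   the caller or drawn here), `truth` (planted parameter row).
#' @export
generate_region <- function(config, group, counter = 1L) {
  stopifnot(inherits(config, "cohort_config"), group %in% GROUP_LEVELS)
  set.seed(region_seed(config$seed, counter))
  up_len <- config$up_len; down_len <- config$down_len
  agez_cfg <- config$agez[[group]]
  L <- round(stats::rnorm(1, agez_cfg[1], agez_cfg[2]))
  L <- max(28L, min(as.integer(L), up_len - 6L))

  # branch A offset, clamped so motif and a >=5 nt tract fit in the zone
  motif <- strsplit(config$bp_motif, "")[[1]]
  mlen <- length(motif)          # branch A at position mlen - 1
  apos <- mlen - 1L
  bpA <- round(stats::rnorm(1, config$bp_mean, config$bp_sd))
  bpA <- max(-(L - 3L), min(as.integer(bpA), -9L))

  # upstream chars indexed by offset -up_len..-1
  up <- rep(NA_character_, up_len)
  chr_at <- function(off) up[off + up_len + 1L]
  set_at <- function(off, val) up[off + up_len + 1L] <<- val
  set_at(-2L, "A"); set_at(-1L, "G")                    # 3'ss AG
  set_at(-(L + 4L), "A"); set_at(-(L + 3L), "G")        # boundary AG
  for (i in seq_len(mlen))                              # BP motif
    set_at(bpA - apos + i, motif[i])                    # window bpA-5..bpA+1

  # hairpin plant: stem1 / loop / stem2 spanning -25..-50 (transcript 5'->3'
  # order is stem1 at the far end); rejection-sample a stem that introduces
  # no AG inside the exclusion zone
  structure_mode <- config$structure_mode[[group]]
  sl <- config$stem_len
  if (structure_mode == "hairpin_upstream") {
    loop_len <- 4L
    lo <- -(25L + 2L * sl + loop_len - 1L)               # far offset
    if (lo < -up_len) stop("hairpin plant does not fit in up_len")
    for (try in 1:50) {
      stem1 <- sample(c("C", "G", "U"), sl, replace = TRUE,
                      prob = c(0.4, 0.3, 0.3))
      stem2 <- rev(chartr("CGU", "GCA", stem1))
      block <- c(stem1, rep("C", loop_len), stem2)
      txt <- paste(block, collapse = "")
      if (!grepl("AG", txt)) break
    }
    for (i in seq_along(block)) set_at(lo + i - 1L, block[i])
  }

  # positional adenosine modifier zones for this group
  dep <- config$a_depletion[[group]]
  a_factor <- function(off) {
    if (is.null(dep)) return(1)
    z <- dep$zone
    if (off <= max(z) && off >= min(z)) dep$factor else 1
  }

  # fill remaining upstream positions from -3 downward, avoiding AG inside
  # the exclusion zone (offsets -3 .. -(L + 2))
  zone_lo <- -(L + 2L)
  in_zone <- function(off) off <= -3L && off >= zone_lo
  ppt_hi <- -3L; ppt_lo <- bpA + 2L
  pyr <- config$ppt_fraction[[group]]
  for (off in seq(-3L, -up_len)) {
    if (!is.na(chr_at(off))) next
    w <- if (off <= ppt_hi && off >= ppt_lo) {
      c(A = (1 - pyr) / 2, C = pyr * 0.35, G = (1 - pyr) / 2, U = pyr * 0.65)
    } else if (structure_mode == "unstructured" && off <= -25L && off >= -50L) {
      BG_UNSTRUCTURED
    } else {
      BG_INTRON
    }
    w[["A"]] <- w[["A"]] * a_factor(off)
    nxt <- if (off + 1L <= -1L) chr_at(off + 1L) else NA
    if (!is.na(nxt) && nxt == "G" && in_zone(off + 1L)) w[["A"]] <- 0
    prv <- if (off - 1L >= -up_len) chr_at(off - 1L) else NA
    if (!is.na(prv) && prv == "A" && in_zone(off)) w[["G"]] <- 0
    set_at(off, sample_base(w / sum(w)))
  }

  exon <- vapply(seq_len(down_len), function(i) sample_base(BG_EXON),
                 character(1))
  # keep +0 purine-ish but never G after a terminal A (cannot happen: -1 is G)
  seqs <- paste(c(up, exon), collapse = "")
  flank_up <- paste(vapply(seq_len(config$flank),
                           function(i) sample_base(BG_INTRON), character(1)),
                    collapse = "")
  # no AG straddling the flank/window boundary inside the zone: the zone
  # never reaches -up_len when up_len >= L + 4, enforced above
  flank_down <- paste(vapply(seq_len(config$flank),
                             function(i) sample_base(BG_EXON), character(1)),
                      collapse = "")

  # expression change with the configured correlation to the realized AGEZ
  ex <- config$expression[[group]]
  z_noise <- stats::rnorm(1)
  truth <- data.frame(
    exon_id = sprintf("%s_%04d", group, counter), group = group,
    agez_length = L, bp_offset = bpA,
    ppt_fraction = pyr, structure_mode = structure_mode,
    z_noise = z_noise, stringsAsFactors = FALSE)

  region <- three_prime_region(truth$exon_id, seqs, up_len, down_len,
                               flank_up = flank_up, flank_down = flank_down)
  list(region = region, truth = truth)
}

#' Generate a full synthetic cohort on disk
#'
#' Writes a genome FASTA (one contig per region: flank + window + flank,
#' DNA alphabet), a BED 6 exon file and a tab-separated group table in
#' exactly the dialects [read_fasta()] and [read_exon_table()] read.
#' Expression changes are drawn per group with the configured correlation
#' to the realized AGEZ lengths.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list: `fasta`, `bed`, `groups` (paths), `truth`
#'   (data.frame of planted per-region parameters incl.
#'   `expression_change`), `regions` (list of [three_prime_region()]).
#' @export
generate_cohort <- function(config, dir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counter <- 0L
  regions <- list(); truths <- list()
  for (g in GROUP_LEVELS) {
    for (i in seq_len(config$n[[g]])) {
      counter <- counter + 1L
      gr <- generate_region(config, g, counter)
      regions[[counter]] <- gr$region
      truths[[counter]] <- gr$truth
    }
  }
  truth <- do.call(rbind, truths)

  # expression change: z-scored realized AGEZ mixed with the stored noise
  truth$expression_change <- NA_real_
  for (g in GROUP_LEVELS) {
    idx <- truth$group == g
    ex <- config$expression[[g]]
    a <- truth$agez_length[idx]
    za <- if (length(a) > 1L && stats::sd(a) > 0)
      (a - mean(a)) / stats::sd(a) else a * 0
    mix <- ex$r * za + sqrt(max(0, 1 - ex$r^2)) * truth$z_noise[idx]
    truth$expression_change[idx] <- ex$mean + ex$sd * mix
  }
  truth$z_noise <- NULL

  contigs <- vapply(regions, function(r)
    chartr("U", "T", paste0(r$flank_up, r$sequence, r$flank_down)),
    character(1))
  names(contigs) <- paste0(truth$exon_id, "_ctg")
  fasta <- file.path(dir, "cohort.fa")
  write_fasta(contigs, fasta)

  bed <- file.path(dir, "cohort.bed")
  start <- config$flank + config$up_len
  bed_df <- data.frame(contig = names(contigs), start = start,
                       end = start + config$down_len, name = truth$exon_id,
                       score = 0L, strand = "+")
  utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  groups <- file.path(dir, "cohort_groups.tsv")
  gt <- data.frame(exon_id = truth$exon_id, group = truth$group,
                   expression_change = truth$expression_change)
  utils::write.table(gt, groups, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(fasta = fasta, bed = bed, groups = groups,
                 truth = truth, regions = regions))
}

#' Toy annotation fixture for APA classification
#'
#' Twelve unambiguous genes covering the three APA categories, both
#' strands and both shift directions, plus two deliberately ambiguous
#' cases (conflicting shift evidence) that must come back flagged.
#'
#' @return List: `transcripts` (list of [transcript_model()]),
#'   `apa_sites` (data.frame), `exon_records` (data.frame of differential
#'   exons with groups), `truth` (data.frame gene_id, category, shift; the
#'   ambiguous genes carry `NA` shift).
#' @export
generate_toy_annotation <- function() {
  txs <- list(); sites <- list(); recs <- list(); truth <- list()
  add_site <- function(gene, contig, pos, id) {
    sites[[length(sites) + 1L]] <<- data.frame(
      site_id = id, gene_id = gene, contig = contig, pos = pos,
      stringsAsFactors = FALSE)
  }
  add_rec <- function(gene, contig, start, end, group, id) {
    recs[[length(recs) + 1L]] <<- data.frame(
      exon_id = id, gene_id = gene, contig = contig, start = start,
      end = end, group = group, stringsAsFactors = FALSE)
  }
  add_truth <- function(gene, cat, shift) {
    truth[[length(truth) + 1L]] <<- data.frame(
      gene_id = gene, category = cat, shift = shift, stringsAsFactors = FALSE)
  }

  # tandem 3'UTR template (plus strand): one transcript, terminal exon
  # [300, 700) holding both APA sites at 400 and 650
  tandem_plus <- function(g, ctg, shift) {
    txs[[length(txs) + 1L]] <<- transcript_model(
      paste0(g, ".t1"), g, ctg, "+",
      data.frame(start = c(100L, 300L), end = c(200L, 700L)))
    add_site(g, ctg, 400L, paste0(g, ".p"))
    add_site(g, ctg, 650L, paste0(g, ".d"))
    pg <- if (shift == "proximal") "up" else "down"
    dg <- if (shift == "proximal") "down" else "up"
    add_rec(g, ctg, 300L, 450L, pg, paste0(g, ".e1"))
    add_rec(g, ctg, 550L, 700L, dg, paste0(g, ".e2"))
    add_truth(g, "tandem_3utr", shift)
  }
  tandem_minus <- function(g, ctg, shift) {
    # mirror of the plus template on [0, 800)
    txs[[length(txs) + 1L]] <<- transcript_model(
      paste0(g, ".t1"), g, ctg, "-",
      data.frame(start = c(600L, 100L), end = c(700L, 500L)))
    add_site(g, ctg, 400L, paste0(g, ".p"))   # proximal = higher tx coord
    add_site(g, ctg, 150L, paste0(g, ".d"))
    pg <- if (shift == "proximal") "up" else "down"
    dg <- if (shift == "proximal") "down" else "up"
    add_rec(g, ctg, 350L, 500L, pg, paste0(g, ".e1"))
    add_rec(g, ctg, 100L, 250L, dg, paste0(g, ".e2"))
    add_truth(g, "tandem_3utr", shift)
  }
  # intronic APA: single isoform E1[100,200) E2[500,600) E3[800,1000);
  # proximal site 350 in intron 1, distal 900 in terminal exon; the
  # intronic terminal segment [250,400) is a differential exon but not an
  # annotated exon
  intronic_plus <- function(g, ctg, shift) {
    txs[[length(txs) + 1L]] <<- transcript_model(
      paste0(g, ".t1"), g, ctg, "+",
      data.frame(start = c(100L, 500L, 800L), end = c(200L, 600L, 1000L)))
    add_site(g, ctg, 350L, paste0(g, ".p"))
    add_site(g, ctg, 900L, paste0(g, ".d"))
    pg <- if (shift == "proximal") "up" else "down"
    dg <- if (shift == "proximal") "down" else "up"
    add_rec(g, ctg, 250L, 400L, pg, paste0(g, ".e1"))
    add_rec(g, ctg, 800L, 1000L, dg, paste0(g, ".e2"))
    add_truth(g, "intronic_apa", shift)
  }
  intronic_minus <- function(g, ctg, shift) {
    txs[[length(txs) + 1L]] <<- transcript_model(
      paste0(g, ".t1"), g, ctg, "-",
      data.frame(start = c(900L, 500L, 100L), end = c(1000L, 600L, 300L)))
    add_site(g, ctg, 750L, paste0(g, ".p"))   # intron 850..? no: intron 600..900
    add_site(g, ctg, 150L, paste0(g, ".d"))   # in terminal exon [100,300)
    pg <- if (shift == "proximal") "up" else "down"
    dg <- if (shift == "proximal") "down" else "up"
    add_rec(g, ctg, 700L, 800L, pg, paste0(g, ".e1"))
    add_rec(g, ctg, 100L, 300L, dg, paste0(g, ".e2"))
    add_truth(g, "intronic_apa", shift)
  }
  # alternative-3'ss APA: two isoforms with overlapping terminal exons
  # starting at distinct 3'ss; proximal site only in the first, distal only
  # in the second
  alt3_plus <- function(g, ctg, shift) {
    txs[[length(txs) + 1L]] <<- transcript_model(
      paste0(g, ".t1"), g, ctg, "+",
      data.frame(start = c(100L, 400L), end = c(200L, 560L)))
    txs[[length(txs) + 1L]] <<- transcript_model(
      paste0(g, ".t2"), g, ctg, "+",
      data.frame(start = c(100L, 520L), end = c(200L, 700L)))
    add_site(g, ctg, 480L, paste0(g, ".p"))
    add_site(g, ctg, 680L, paste0(g, ".d"))
    pg <- if (shift == "proximal") "up" else "down"
    dg <- if (shift == "proximal") "down" else "up"
    add_rec(g, ctg, 400L, 560L, pg, paste0(g, ".e1"))
    add_rec(g, ctg, 650L, 700L, dg, paste0(g, ".e2"))
    add_truth(g, "alt3ss_apa", shift)
  }
  alt3_minus <- function(g, ctg, shift) {
    txs[[length(txs) + 1L]] <<- transcript_model(
      paste0(g, ".t1"), g, ctg, "-",
      data.frame(start = c(600L, 240L), end = c(700L, 400L)))
    txs[[length(txs) + 1L]] <<- transcript_model(
      paste0(g, ".t2"), g, ctg, "-",
      data.frame(start = c(600L, 100L), end = c(700L, 280L)))
    add_site(g, ctg, 320L, paste0(g, ".p"))   # only in t1 terminal [240,400)
    add_site(g, ctg, 120L, paste0(g, ".d"))   # only in t2 terminal [100,280)
    pg <- if (shift == "proximal") "up" else "down"
    dg <- if (shift == "proximal") "down" else "up"
    add_rec(g, ctg, 300L, 400L, pg, paste0(g, ".e1"))
    add_rec(g, ctg, 100L, 150L, dg, paste0(g, ".e2"))
    add_truth(g, "alt3ss_apa", shift)
  }

  tandem_plus("g01", "g01", "proximal")
  tandem_plus("g02", "g02", "distal")
  tandem_minus("g03", "g03", "proximal")
  tandem_minus("g04", "g04", "distal")
  intronic_plus("g05", "g05", "proximal")
  intronic_plus("g06", "g06", "distal")
  intronic_minus("g07", "g07", "proximal")
  intronic_minus("g08", "g08", "distal")
  alt3_plus("g09", "g09", "proximal")
  alt3_plus("g10", "g10", "distal")
  alt3_minus("g11", "g11", "proximal")
  alt3_minus("g12", "g12", "distal")

  # ambiguous 1: tandem-like but both segments upregulated
  txs[[length(txs) + 1L]] <- transcript_model(
    "g13.t1", "g13", "g13", "+",
    data.frame(start = c(100L, 300L), end = c(200L, 700L)))
  add_site("g13", "g13", 400L, "g13.p")
  add_site("g13", "g13", 650L, "g13.d")
  add_rec("g13", "g13", 300L, 450L, "up", "g13.e1")
  add_rec("g13", "g13", 550L, 700L, "up", "g13.e2")
  add_truth("g13", "tandem_3utr", NA_character_)
  # ambiguous 2: intronic-like but neither segment upregulated
  txs[[length(txs) + 1L]] <- transcript_model(
    "g14.t1", "g14", "g14", "+",
    data.frame(start = c(100L, 500L, 800L), end = c(200L, 600L, 1000L)))
  add_site("g14", "g14", 350L, "g14.p")
  add_site("g14", "g14", 900L, "g14.d")
  add_rec("g14", "g14", 250L, 400L, "down", "g14.e1")
  add_rec("g14", "g14", 800L, 1000L, "control", "g14.e2")
  add_truth("g14", "intronic_apa", NA_character_)

  list(transcripts = txs,
       apa_sites = do.call(rbind, sites),
       exon_records = do.call(rbind, recs),
       truth = do.call(rbind, truth))
}
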