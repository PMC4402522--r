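# End-to-end orchestration: architecture, structure and APA stages over
# real inputs (FASTA + BED + group table + optional GTF/APA BED) or a
# synthetic cohort, writing stable tab-separated report tables and a run
# manifest.  Manifests carry the full config echo and every declared
# constant, and contain nothing volatile, so identical config + seed gives
# byte-identical outputs.

#' Run configuration
#'
#' Exactly one of `paths` (real inputs) or `cohort` (synthetic config) is
#' active.
#'
#' @param paths Named list of input paths (`genome`, `exons`, `groups`,
#'   optionally `annotation` (GTF) and `apa_sites` (BED)), or `NULL`.
#' @param cohort A [cohort_config()], or `NULL`.
#' @param up_len,down_len Extraction window (nt).
#' @param flank Folding flank (nt).
#' @param model An [energy_model()].
#' @param star_alpha Raw-p starring threshold for delta-PU.
#' @param seed Seed recorded in the manifest (the synthetic path draws all
#'   randomness from the cohort config's own seed).
#' @return Object of class `run_config`.
#' @export
run_config <- function(paths = NULL, cohort = NULL, up_len = 100L,
                       down_len = 50L, flank = 30L, model = energy_model(),
                       star_alpha = 0.05, seed = 1L) {
  if (is.null(paths) == is.null(cohort))
    stop("exactly one of 'paths' or 'cohort' must be given")
  structure(list(paths = paths, cohort = cohort, up_len = as.integer(up_len),
                 down_len = as.integer(down_len), flank = as.integer(flank),
                 model = model, star_alpha = star_alpha,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

manifest_lines <- function(config, stage) {
  fmt <- function(x) {
    if (is.list(x)) paste(vapply(x, fmt, character(1)), collapse = ",")
    else paste(format(x, digits = 15), collapse = ",")
  }
  cc <- config$cohort
  c(sprintf("stage\t%s", stage),
    sprintf("seed\t%d", config$seed),
    sprintf("up_len\t%d", config$up_len),
    sprintf("down_len\t%d", config$down_len),
    sprintf("flank\t%d", config$flank),
    sprintf("pair_energy\t%s", fmt(as.list(config$model$pair_energy))),
    sprintf("kT\t%s", fmt(config$model$kT)),
    sprintf("min_hairpin\t%d", config$model$min_hairpin),
    sprintf("star_alpha\t%s", fmt(config$star_alpha)),
    sprintf("ppt_min_len\t5"),
    sprintf("ppt_min_fraction\t0.6"),
    sprintf("ppt_purine_penalty\t2"),
    if (!is.null(cc)) sprintf("cohort_seed\t%d", cc$seed),
    if (!is.null(cc)) sprintf("cohort_n\t%s", fmt(as.list(cc$n))),
    if (!is.null(config$paths))
      sprintf("inputs\t%s", fmt(config$paths)))
}

# materialize inputs: returns list(regions, records)
load_inputs <- function(config, out_dir) {
  if (!is.null(config$cohort)) {
    coh <- generate_cohort(config$cohort, file.path(out_dir, "cohort"))
    genome <- read_fasta(coh$fasta)
    tab <- read_exon_table(coh$bed, coh$groups)
  } else {
    genome <- read_fasta(config$paths$genome)
    tab <- read_exon_table(config$paths$exons, config$paths$groups)
  }
  records <- tab$records
  regions <- lapply(seq_len(nrow(records)), function(i)
    extract_three_prime_region(genome, records[i, ], config$up_len,
                               config$down_len, context = config$flank))
  list(regions = regions, records = records, rejects = tab$rejects)
}

#' Architecture stage: features, group tests, correlations
#'
#' Extracts 3'ss windows, computes AGEZ / branch point / PPT / intrinsic
#' site score per exon, compares AGEZ and PPT length between groups
#' (Welch t by default) and correlates both features with the expression
#' change within each group.  Writes `features.tsv`, `comparisons.tsv` and
#' `manifest.txt`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param test `"t"` or `"wilcoxon"` for the group comparisons.
#' @return Invisibly, list with `features` and `comparisons` data.frames.
#' @export
run_architecture <- function(config, out_dir, test = "t") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- load_inputs(config, out_dir)
  feat <- architecture_features(inp$regions, inp$records)

  comparisons <- list()
  add_cmp <- function(contrast, gc) {
    comparisons[[length(comparisons) + 1L]] <<- data.frame(
      contrast = contrast, test = gc$test, statistic = gc$statistic,
      p = gc$p, n_a = gc$n_a, n_b = gc$n_b, effect = gc$effect,
      stringsAsFactors = FALSE)
  }
  by_group <- split(feat, feat$group)
  pairs <- list(c("up", "down"), c("up", "control"), c("down", "control"))
  for (feature in c("agez_length", "ppt_length")) {
    for (pr in pairs) {
      a <- by_group[[pr[1]]][[feature]]
      b <- by_group[[pr[2]]][[feature]]
      if (length(a) >= 2L && length(b) >= 2L)
        add_cmp(sprintf("%s:%s_vs_%s", feature, pr[1], pr[2]),
                compare_feature(a, b, test))
    }
    for (g in intersect(GROUP_LEVELS, names(by_group))) {
      d <- by_group[[g]]
      ok <- is.finite(d[[feature]]) & is.finite(d$expression_change)
      if (sum(ok) >= 3L) {
        pc <- pearson_correlation(d[[feature]][ok], d$expression_change[ok])
        comparisons[[length(comparisons) + 1L]] <- data.frame(
          contrast = sprintf("%s:change_correlation_%s", feature, g),
          test = "pearson", statistic = pc$r, p = pc$p, n_a = pc$n,
          n_b = NA_integer_, effect = pc$r, stringsAsFactors = FALSE)
      }
    }
  }
  comparisons <- do.call(rbind, comparisons)

  write_tsv(feat, file.path(out_dir, "features.tsv"))
  write_tsv(comparisons, file.path(out_dir, "comparisons.tsv"))
  writeLines(manifest_lines(config, "architecture"),
             file.path(out_dir, "manifest.txt"))
  invisible(list(features = feat, comparisons = comparisons))
}

#' Structure stage: PU profiles and positional delta-PU
#'
#' Folds each extended window once, writes per-group mean PU profiles
#' (`pu_profile.tsv`), the delta-PU table with Wilcoxon p, BH q and
#' significance stars (`delta_pu.tsv`), and the manifest.
#'
#' @inheritParams run_architecture
#' @return Invisibly, list with `pu_profiles` and `delta_pu`.
#' @export
run_structure <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- load_inputs(config, out_dir)
  grp <- vapply(inp$records$group, identity, character(1))
  regions_of <- function(g) inp$regions[grp == g]
  profs <- list()
  for (g in intersect(GROUP_LEVELS, unique(grp))) {
    pp <- group_pu_profile(regions_of(g), group = g, flank = config$flank,
                           model = config$model)
    pp$group <- g
    profs[[g]] <- pp
  }
  pu_profiles <- do.call(rbind, profs)
  dp <- delta_pu(regions_of("up"), regions_of("down"), flank = config$flank,
                 model = config$model, star_alpha = config$star_alpha)

  write_tsv(pu_profiles, file.path(out_dir, "pu_profile.tsv"))
  write_tsv(as.data.frame(dp), file.path(out_dir, "delta_pu.tsv"))
  writeLines(manifest_lines(config, "structure"),
             file.path(out_dir, "manifest.txt"))
  invisible(list(pu_profiles = pu_profiles, delta_pu = dp))
}

#' APA stage: event categorization, shift tallies, exon-class test
#'
#' Classifies differential exons by transcript position (3x2 chi-squared on
#' start/internal/terminal x up/down), categorizes APA events and tallies
#' proximal/distal shifts per category.  Writes `apa_events.tsv`,
#' `apa_tallies.tsv`, `exon_classes.tsv`, `comparisons.tsv` and the
#' manifest.
#'
#' @param config A [run_config()] (ignored except for the manifest when
#'   `annotation` is given directly).
#' @param out_dir Output directory.
#' @param annotation List as returned by [generate_toy_annotation()]
#'   (`transcripts`, `apa_sites`, `exon_records`); when `NULL`, the toy
#'   fixture is used for a synthetic config and the configured GTF/BED
#'   paths for real inputs.
#' @return Invisibly, list with `events`, `tallies`, `exon_classes`,
#'   `comparisons`, `rejects`.
#' @export
run_apa <- function(config, out_dir, annotation = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(annotation)) {
    if (!is.null(config$cohort)) {
      annotation <- generate_toy_annotation()
    } else {
      txs <- read_transcript_models(config$paths$annotation)
      gr <- rtracklayer::import(config$paths$apa_sites, format = "BED")
      apa <- data.frame(
        site_id = as.character(S4Vectors::mcols(gr)$name),
        gene_id = sub("\\..*$", "", as.character(S4Vectors::mcols(gr)$name)),
        contig = as.character(GenomicRanges::seqnames(gr)),
        pos = GenomicRanges::start(gr) - 1L, stringsAsFactors = FALSE)
      grp <- utils::read.table(config$paths$groups, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      annotation <- list(transcripts = txs, apa_sites = apa,
                         exon_records = grp)
    }
  }
  cls <- classify_apa_event(annotation$exon_records, annotation$transcripts,
                            annotation$apa_sites)
  tal <- tally_shifts(cls$events)

  # exon-class 3x2 table over the differential exons that match an
  # annotated exon exactly
  tx_by_gene <- split(annotation$transcripts,
                      vapply(annotation$transcripts, `[[`, character(1),
                             "gene_id"))
  recs <- annotation$exon_records
  classes <- vapply(seq_len(nrow(recs)), function(i) {
    e <- recs[i, ]
    txs <- tx_by_gene[[e$gene_id]]
    if (is.null(txs)) return(NA_character_)
    for (tx in txs) {
      hit <- tryCatch(classify_exon_position(e, tx), error = function(...) NA)
      if (!is.na(hit)) return(hit)
    }
    NA_character_
  }, character(1))
  ec <- data.frame(exon_id = recs$exon_id, group = recs$group,
                   class = classes, stringsAsFactors = FALSE)
  comparisons <- data.frame(contrast = character(0), test = character(0),
                            statistic = numeric(0), p = numeric(0),
                            n_a = integer(0), n_b = integer(0),
                            effect = numeric(0), stringsAsFactors = FALSE)
  keep <- !is.na(ec$class) & ec$group %in% c("up", "down")
  if (any(keep)) {
    tab <- table(factor(ec$class[keep],
                        levels = c("start", "internal", "terminal")),
                 factor(ec$group[keep], levels = c("up", "down")))
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) >= 2L && all(colSums(tab) > 0)) {
      gc <- chi_square_contingency(tab)
      comparisons <- data.frame(contrast = "exon_class_3x2", test = gc$test,
                                statistic = gc$statistic, p = gc$p,
                                n_a = gc$n_a, n_b = NA_integer_,
                                effect = gc$effect, stringsAsFactors = FALSE)
    }
  }

  write_tsv(cls$events, file.path(out_dir, "apa_events.tsv"))
  write_tsv(tal, file.path(out_dir, "apa_tallies.tsv"))
  write_tsv(ec, file.path(out_dir, "exon_classes.tsv"))
  write_tsv(comparisons, file.path(out_dir, "comparisons.tsv"))
  writeLines(manifest_lines(config, "apa"), file.path(out_dir, "manifest.txt"))
  invisible(list(events = cls$events, tallies = tal, exon_classes = ec,
                 comparisons = comparisons, rejects = cls$rejects))
}

#' Run every stage into one output directory
#'
#' @inheritParams run_architecture
#' @return Invisibly, list of the per-stage results.
#' @export
run_all <- function(config, out_dir) {
  arch <- run_architecture(config, file.path(out_dir, "architecture"))
  stru <- run_structure(config, file.path(out_dir, "structure"))
  apa <- run_apa(config, file.path(out_dir, "apa"))
  writeLines(manifest_lines(config, "all"), file.path(out_dir, "manifest.txt"))
  invisible(list(architecture = arch, structure = stru, apa = apa))
}
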