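# Positional classification of differentially used exons and rule-based
# categorization of alternative polyadenylation (APA) events into tandem
# 3'UTR, intronic and alternative-3'ss APA, with proximal/distal shift
# calls.  The categories encode, as an explicit and reproducible rule
# cascade, distinctions that are often drawn by manual genome-browser
# inspection; events the rules underdetermine are emitted with an
# ambiguity flag and excluded from tallies.

#' Construct a transcript model
#'
#' @param transcript_id,gene_id Identifiers.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with `start`, `end` (0-based half-open),
#'   non-overlapping; stored ordered 5'->3' in transcript orientation.
#' @return Object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, contig, strand, exons) {
  stopifnot(strand %in% c("+", "-"), all(exons$start < exons$end))
  ord <- order(exons$start)
  exons <- exons[ord, , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("transcript exons overlap: ", transcript_id)
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  rownames(exons) <- NULL
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 contig = contig, strand = strand, exons = exons),
            class = "transcript_model")
}

# position in transcript orientation: larger = further 3'
tx_coord <- function(strand, pos) if (strand == "+") pos else -pos

#' Classify an exon as start, internal or terminal
#'
#' First exon in transcript orientation is `start`, last is `terminal`,
#' anything else `internal`; a single-exon transcript is `terminal`
#' (declared rule).  The exon must match one annotated exon exactly
#' (tolerance 0 nt).
#'
#' @param exon List or one-row data.frame with `start`, `end` (0-based
#'   half-open) and `exon_id`.
#' @param transcript A [transcript_model()].
#' @return One of `"start"`, `"internal"`, `"terminal"`.
#' @export
classify_exon_position <- function(exon, transcript) {
  exon <- as.list(exon)
  hit <- which(transcript$exons$start == exon$start &
               transcript$exons$end == exon$end)
  if (length(hit) != 1L)
    stop("exon ", exon$exon_id, " does not match transcript ",
         transcript$transcript_id)
  n <- nrow(transcript$exons)
  if (n == 1L) return("terminal")
  if (hit == 1L) "start" else if (hit == n) "terminal" else "internal"
}

exon_contains <- function(exons, pos) {
  any(exons$start <= pos & pos < exons$end)
}

intron_contains <- function(exons_sorted_genomic, pos) {
  if (nrow(exons_sorted_genomic) < 2L) return(FALSE)
  s <- exons_sorted_genomic[order(exons_sorted_genomic$start), , drop = FALSE]
  any(s$end[-nrow(s)] <= pos & pos < s$start[-1])
}

#' Categorize APA events of differentially used exons
#'
#' For each gene with exactly two attributable APA sites (proximal and
#' distal in transcript orientation) the cascade is applied in order:
#'
#' 1. both sites inside one annotated terminal exon -> `tandem_3utr`;
#' 2. proximal site inside an annotated intron of at least one isoform,
#'    contained in no annotated exon, with the distal site in or 3' of a
#'    downstream terminal exon -> `intronic_apa`;
#' 3. two isoforms whose terminal exons overlap but start at distinct 3'ss,
#'    one holding the proximal and the other the distal site ->
#'    `alt3ss_apa`.
#'
#' The shift is `proximal` when the differential exon nearest the proximal
#' site is upregulated and the one nearest the distal site is not (and vice
#' versa for `distal`); conflicting evidence flags the event as ambiguous.
#' Sites not attributable to any gene, or genes without two sites, go to
#' the rejects report.
#'
#' @param exon_records data.frame of differential exons: `exon_id`,
#'   `gene_id`, `contig`, `start`, `end`, `group`.
#' @param transcripts List of [transcript_model()] objects.
#' @param apa_sites data.frame: `site_id`, `gene_id`, `contig`, `pos`
#'   (0-based point coordinate).
#' @return List with `events` (data.frame: gene_id, category, shift,
#'   proximal_site, distal_site, proximal_exon, distal_exon, ambiguous)
#'   and `rejects` (character vector of site or gene ids).
#' @export
classify_apa_event <- function(exon_records, transcripts, apa_sites) {
  tx_by_gene <- split(transcripts,
                      vapply(transcripts, `[[`, character(1), "gene_id"))
  rejects <- character(0)
  orphan <- !apa_sites$gene_id %in% names(tx_by_gene)
  if (any(orphan)) rejects <- c(rejects, apa_sites$site_id[orphan])
  apa_sites <- apa_sites[!orphan, , drop = FALSE]
  events <- list()
  for (g in unique(apa_sites$gene_id)) {
    sites <- apa_sites[apa_sites$gene_id == g, , drop = FALSE]
    txs <- tx_by_gene[[g]]
    strand <- txs[[1]]$strand
    if (nrow(sites) != 2L) {
      rejects <- c(rejects, paste0(g, ":needs-two-sites"))
      next
    }
    ord <- order(tx_coord(strand, sites$pos))
    prox <- sites$pos[ord[1]]
    dist <- sites$pos[ord[2]]

    term_exon <- function(tx) tx$exons[nrow(tx$exons), , drop = FALSE]
    in_any_exon <- any(vapply(txs, function(tx)
      exon_contains(tx$exons, prox), logical(1)))

    category <- NA_character_
    # rule 1: both sites inside a single annotated terminal exon
    for (tx in txs) {
      te <- term_exon(tx)
      if (exon_contains(te, prox) && exon_contains(te, dist)) {
        category <- "tandem_3utr"
        break
      }
    }
    # rule 2: intronic proximal site, distal in/after a terminal exon
    if (is.na(category) && !in_any_exon) {
      intronic <- any(vapply(txs, function(tx)
        intron_contains(tx$exons, prox), logical(1)))
      distal_ok <- any(vapply(txs, function(tx) {
        te <- term_exon(tx)
        exon_contains(te, dist) ||
          tx_coord(strand, dist) >= tx_coord(strand,
            if (strand == "+") te$start else te$end - 1L)
      }, logical(1)))
      if (intronic && distal_ok) category <- "intronic_apa"
    }
    # rule 3: overlapping terminal exons with distinct 3'ss
    if (is.na(category) && length(txs) >= 2L) {
      for (a in seq_along(txs)) for (b in seq_along(txs)) {
        if (a == b) next
        ta <- term_exon(txs[[a]]); tb <- term_exon(txs[[b]])
        overlap <- ta$start < tb$end && tb$start < ta$end
        ss <- function(te) if (strand == "+") te$start else te$end
        if (overlap && ss(ta) != ss(tb) &&
            exon_contains(ta, prox) && exon_contains(tb, dist)) {
          category <- "alt3ss_apa"
          break
        }
      }
    }
    if (is.na(category)) {
      rejects <- c(rejects, paste0(g, ":uncategorized"))
      next
    }

    # shift from the groups of the differential exons nearest each site
    recs <- exon_records[exon_records$gene_id == g, , drop = FALSE]
    nearest_group <- function(pos) {
      if (nrow(recs) == 0L) return(NA_character_)
      d <- pmax(recs$start - pos, pos - (recs$end - 1L), 0L)
      hit <- which(d == min(d))
      grp <- unique(recs$group[hit])
      if (length(grp) != 1L) NA_character_ else grp
    }
    pg <- nearest_group(prox)
    dg <- nearest_group(dist)
    ambiguous <- FALSE
    shift <- NA_character_
    if (!is.na(pg) && !is.na(dg) && pg == "up" && dg != "up") {
      shift <- "proximal"
    } else if (!is.na(pg) && !is.na(dg) && dg == "up" && pg != "up") {
      shift <- "distal"
    } else {
      ambiguous <- TRUE
    }
    events[[length(events) + 1L]] <- data.frame(
      gene_id = g, category = category, shift = shift,
      proximal_site = prox, distal_site = dist,
      proximal_group = pg, distal_group = dg,
      ambiguous = ambiguous, stringsAsFactors = FALSE)
  }
  events <- if (length(events) > 0L) do.call(rbind, events) else
    data.frame(gene_id = character(0), category = character(0),
               shift = character(0), proximal_site = integer(0),
               distal_site = integer(0), proximal_group = character(0),
               distal_group = character(0), ambiguous = logical(0),
               stringsAsFactors = FALSE)
  list(events = events, rejects = rejects)
}

#' Tally proximal/distal shifts per APA category
#'
#' Ambiguity-flagged events are excluded.
#'
#' @param events Events data.frame from [classify_apa_event()].
#' @return data.frame: `category`, `n_proximal`, `n_distal`.
#' @export
tally_shifts <- function(events) {
  cats <- c("alt3ss_apa", "intronic_apa", "tandem_3utr")
  keep <- events[!events$ambiguous, , drop = FALSE]
  data.frame(
    category = cats,
    n_proximal = vapply(cats, function(cc)
      sum(keep$category == cc & keep$shift == "proximal"), integer(1)),
    n_distal = vapply(cats, function(cc)
      sum(keep$category == cc & keep$shift == "distal"), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Read transcript models from a GTF file
#'
#' Uses exon features; transcripts are grouped by `transcript_id` with
#' `gene_id` metadata.
#'
#' @param path GTF path.
#' @return List of [transcript_model()] objects.
#' @export
read_transcript_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  df <- data.frame(
    transcript_id = as.character(S4Vectors::mcols(gr)$transcript_id),
    gene_id = as.character(S4Vectors::mcols(gr)$gene_id),
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  lapply(split(df, df$transcript_id), function(d) {
    transcript_model(d$transcript_id[1], d$gene_id[1], d$contig[1],
                     d$strand[1], d[, c("start", "end")])
  })
}

#' Write transcript models to a GTF file
#'
#' @param transcripts List of [transcript_model()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_transcript_gtf <- function(transcripts, path) {
  lines <- unlist(lapply(transcripts, function(tx) {
    ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
    vapply(seq_len(nrow(ex)), function(i) {
      paste(tx$contig, "splicearch", "exon", ex$start[i] + 1L, ex$end[i],
            ".", tx$strand, ".",
            sprintf('gene_id "%s"; transcript_id "%s";',
                    tx$gene_id, tx$transcript_id),
            sep = "\t")
    }, character(1))
  }))
  writeLines(lines, path)
  invisible(path)
}
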