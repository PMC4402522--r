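# Reading of standard formats and construction of strand-corrected,
# 3'ss-anchored sequence windows.
#
# Coordinate convention used throughout the package: genomic intervals are
# 0-based half-open (BED); window positions are signed offsets anchored at
# the 3' splice site, with -1 the last intron nucleotide (the G of the 3'ss
# AG), -2 its A, and +0 the first exon nucleotide.  There is no separate
# "zero" on the intron side.

#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased but otherwise kept raw (DNA `T`s are *not*
#' transliterated to `U`; that happens only when a 3'ss window is
#' extracted).  Record ids are the first whitespace-delimited token of the
#' header line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate FASTA ids: ", paste(dup, collapse = ", "))
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line width for sequence folding.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read exon intervals and group assignments
#'
#' Joins a BED 6 file of exon intervals with a tab-separated group table
#' (header columns `exon_id`, `group`, `expression_change`) assigning each
#' exon to one of `up`, `down`, `control` together with a signed log2-fold
#' usage change (positive = higher usage in depleted cells).  Group labels
#' are case-normalized.  BED records without a group row are returned in a
#' rejects report; group rows whose exon id is absent from the BED file are
#' an error.
#'
#' @param bed_path Path to a BED 6 file (the `name` column is the exon id).
#' @param group_path Path to the group table.
#' @return A list with `records` (data.frame: exon_id, contig, start, end,
#'   strand, group, expression_change; start/end 0-based half-open) and
#'   `rejects` (character vector of unmatched exon ids).
#' @export
read_exon_table <- function(bed_path, group_path) {
  gr <- rtracklayer::import(bed_path, format = "BED")
  if (length(gr) == 0L) stop("no records in BED file: ", bed_path)
  bed <- data.frame(
    exon_id = as.character(S4Vectors::mcols(gr)$name),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # back to 0-based
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (any(!bed$strand %in% c("+", "-")))
    stop("BED strand must be '+' or '-' for every exon")
  grp <- utils::read.table(group_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("exon_id", "group", "expression_change")
  if (!all(need %in% names(grp)))
    stop("group table must have columns: ", paste(need, collapse = ", "))
  grp$group <- tolower(trimws(grp$group))
  bad <- setdiff(unique(grp$group), GROUP_LEVELS)
  if (length(bad) > 0L)
    stop("unknown group labels: ", paste(bad, collapse = ", "))
  if (any(!is.finite(grp$expression_change)))
    stop("expression_change must be finite")
  missing_in_bed <- setdiff(grp$exon_id, bed$exon_id)
  if (length(missing_in_bed) > 0L)
    stop("exon ids in group table absent from BED: ",
         paste(missing_in_bed, collapse = ", "))
  rejects <- setdiff(bed$exon_id, grp$exon_id)
  rec <- merge(bed, grp, by = "exon_id", sort = FALSE)
  rec <- rec[match(setdiff(bed$exon_id, rejects), rec$exon_id), , drop = FALSE]
  rownames(rec) <- NULL
  list(records = rec, rejects = rejects)
}

#' Construct a 3'ss-anchored region object
#'
#' @param exon_id Identifier.
#' @param sequence Upper-case RNA text over A, C, G, U, N.
#' @param up_len,down_len Intron-side and exon-side window lengths (nt);
#'   their sum must equal `nchar(sequence)`.
#' @param truncated Flag set when the requested window ran off a contig end.
#' @param flank_up,flank_down Optional extra context sequence (RNA) lying
#'   immediately 5' / 3' of the window, used when folding with flanks.
#' @return An object of class `three_prime_region`.
#' @export
three_prime_region <- function(exon_id, sequence, up_len, down_len,
                               truncated = FALSE,
                               flank_up = "", flank_down = "") {
  sequence <- toupper(sequence)
  if (nchar(sequence) != up_len + down_len)
    stop("length(sequence) must equal up_len + down_len")
  if (grepl("[^ACGUN]", sequence))
    stop("sequence alphabet must be A, C, G, U, N")
  canonical <- up_len >= 2L &&
    substr(sequence, up_len - 1L, up_len) == "AG"
  structure(
    list(exon_id = exon_id, sequence = sequence,
         up_len = as.integer(up_len), down_len = as.integer(down_len),
         canonical = canonical, truncated = isTRUE(truncated),
         flank_up = flank_up, flank_down = flank_down),
    class = "three_prime_region"
  )
}

#' @export
print.three_prime_region <- function(x, ...) {
  cat(sprintf("three_prime_region %s: %d nt intron | %d nt exon%s%s\n",
              x$exon_id, x$up_len, x$down_len,
              if (x$canonical) ", canonical AG" else ", NON-CANONICAL",
              if (x$truncated) ", truncated" else ""))
  invisible(x)
}

#' Signed offsets of every position of a region
#'
#' Offsets run `-up_len .. -1` on the intron side and `+0 .. down_len - 1`
#' on the exon side; `-1` abuts `+0`.
#'
#' @param region A `three_prime_region`.
#' @return Integer vector, one offset per sequence position.
#' @export
region_offsets <- function(region) {
  seq_len(region$up_len + region$down_len) - region$up_len - 1L
}

#' Sequence index of a signed offset
#'
#' @param region A `three_prime_region`.
#' @param offset Signed offset (see [region_offsets()]).
#' @return 1-based index into `region$sequence`.
#' @export
region_index_of <- function(region, offset) {
  idx <- offset + region$up_len + 1L
  n <- region$up_len + region$down_len
  if (any(idx < 1L | idx > n)) stop("offset outside region")
  idx
}

#' Character at a signed offset
#' @inheritParams region_index_of
#' @return Single upper-case character.
#' @export
region_char_at <- function(region, offset) {
  substring(region$sequence, region_index_of(region, offset),
            region_index_of(region, offset))
}

rev_comp_rna <- function(s) {
  chartr("ACGUN", "UGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Extract a strand-corrected 3'ss-anchored window
#'
#' The window is anchored at the exon's 3' splice site (its 5' end in
#' transcript orientation) and reads 5'->3' on the transcribed strand;
#' minus-strand exons are reverse-complemented.  DNA `T`s are
#' transliterated to `U`.  Windows running off the contig are truncated and
#' flagged.
#'
#' @param genome Named character vector of contig sequences (from
#'   [read_fasta()]).
#' @param exon A list or one-row data.frame with fields `exon_id`, `contig`,
#'   `start`, `end` (0-based half-open) and `strand`.
#' @param up_len,down_len Window lengths on the intron and exon side (nt).
#' @param context Extra flank (nt) extracted on both sides and stored in the
#'   region's `flank_up` / `flank_down` fields for later folding.
#' @return A [three_prime_region()].
#' @export
extract_three_prime_region <- function(genome, exon, up_len = 100L,
                                       down_len = 50L, context = 0L) {
  exon <- as.list(exon)
  if (!exon$contig %in% names(genome))
    stop("contig not found in genome: ", exon$contig)
  ctg <- genome[[exon$contig]]
  clen <- nchar(ctg)
  anchor <- if (exon$strand == "+") exon$start else exon$end
  grab <- function(lo, hi) {                 # 0-based half-open, clipped
    lo2 <- max(0L, lo); hi2 <- min(clen, hi)
    if (hi2 <= lo2) "" else substr(ctg, lo2 + 1L, hi2)
  }
  if (exon$strand == "+") {
    up_eff <- min(up_len, anchor)
    down_eff <- min(down_len, clen - anchor)
    core <- grab(anchor - up_eff, anchor + down_eff)
    fu <- grab(anchor - up_eff - context, anchor - up_eff)
    fd <- grab(anchor + down_eff, anchor + down_eff + context)
  } else {
    up_eff <- min(up_len, clen - anchor)
    down_eff <- min(down_len, anchor)
    core <- rev_comp_rna(to_rna(grab(anchor - down_eff, anchor + up_eff)))
    fu <- rev_comp_rna(to_rna(grab(anchor + up_eff, anchor + up_eff + context)))
    fd <- rev_comp_rna(to_rna(grab(anchor - down_eff - context,
                                   anchor - down_eff)))
  }
  three_prime_region(
    exon_id = exon$exon_id, sequence = to_rna(core),
    up_len = up_eff, down_len = down_eff,
    truncated = (up_eff < up_len) || (down_eff < down_len),
    flank_up = to_rna(fu), flank_down = to_rna(fd)
  )
}

to_rna <- function(s) chartr("Tt", "Uu", toupper(s))

#' Write a set of regions to FASTA
#'
#' @param regions List of [three_prime_region()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
regions_to_fasta <- function(regions, path) {
  seqs <- vapply(regions, function(r) r$sequence, character(1))
  names(seqs) <- vapply(regions, function(r) r$exon_id, character(1))
  write_fasta(seqs, path)
}
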