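# Frequency-matrix (position weight matrix) models of splice-site and
# branch-point signals, scored as log2 odds against a background
# composition.  This is the "frequency matrix" flavour of intrinsic
# splice-site strength; no maximum-entropy model is provided.

#' Train a frequency-matrix site model
#'
#' Column probabilities are `(count + pseudocount) / (n + 4 * pseudocount)`.
#'
#' @param aligned_sites Character vector of equal-length sequences over
#'   A, C, G, U.
#' @param site_type One of `"3ss"`, `"5ss"`, `"bp"`.
#' @param pseudocount Non-negative smoothing constant added per base.
#' @param background Either `"uniform"` or `"empirical"` (overall base
#'   frequencies of the training set), or a named numeric vector over
#'   A, C, G, U summing to 1.
#' @param branch_a_pos For `site_type = "bp"`, the column holding the
#'   branch adenosine (default 6 of a 7-mer).
#' @return An object of class `site_model`.
#' @export
train_site_model <- function(aligned_sites, site_type = c("3ss", "5ss", "bp"),
                             pseudocount = 0.1, background = "uniform",
                             branch_a_pos = if (site_type == "bp") 6L else NA) {
  site_type <- match.arg(site_type)
  if (length(aligned_sites) < 1L) stop("need at least one training sequence")
  lens <- nchar(aligned_sites)
  if (length(unique(lens)) != 1L) stop("training sequences have ragged lengths")
  L <- lens[1]
  chars <- do.call(rbind, strsplit(toupper(aligned_sites), ""))
  if (any(!chars %in% RNA_BASES))
    stop("training sequences must be over A, C, G, U")
  n <- nrow(chars)
  counts <- vapply(seq_len(L), function(j) {
    tabulate(factor(chars[, j], levels = RNA_BASES), nbins = 4L)
  }, numeric(4))
  prob <- t((counts + pseudocount) / (n + 4 * pseudocount))
  colnames(prob) <- RNA_BASES
  if (is.character(background)) {
    bg <- switch(background,
      uniform = stats::setNames(rep(0.25, 4), RNA_BASES),
      empirical = {
        tot <- tabulate(factor(chars, levels = RNA_BASES), nbins = 4L)
        stats::setNames((tot + pseudocount) / sum(tot + pseudocount), RNA_BASES)
      },
      stop("background must be 'uniform', 'empirical' or a probability vector")
    )
  } else {
    bg <- background[RNA_BASES]
    if (abs(sum(bg) - 1) > 1e-9) stop("background must sum to 1")
  }
  stopifnot(all(abs(rowSums(prob) - 1) < 1e-9))
  structure(list(site_type = site_type, prob = prob, background = bg,
                 pseudocount = pseudocount, n_sites = n,
                 branch_a_pos = branch_a_pos),
            class = "site_model")
}

#' Score a sequence under a site model
#'
#' Sum over positions of `log2(column_prob / background_prob)`, in bits.
#' Sequences containing `N` get an `NA` score (flagged as undefined rather
#' than guessed).
#'
#' @param seq Character scalar whose length matches the model.
#' @param model A [train_site_model()] object.
#' @return Numeric score in bits (`NA` if the sequence contains `N`).
#' @export
score_site <- function(seq, model) {
  stopifnot(inherits(model, "site_model"))
  seq <- toupper(seq)
  L <- nrow(model$prob)
  if (nchar(seq) != L)
    stop("sequence length ", nchar(seq), " does not match model length ", L)
  ch <- strsplit(seq, "")[[1]]
  if (any(ch == "N")) return(NA_real_)
  if (any(!ch %in% RNA_BASES)) stop("sequence must be over A, C, G, U, N")
  idx <- match(ch, RNA_BASES)
  sum(log2(model$prob[cbind(seq_len(L), idx)] / model$background[idx]))
}

#' Serialize a site model to a plain-text matrix file
#' @param model A `site_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_site_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# site_type: ", model$site_type),
    paste0("# pseudocount: ", format(model$pseudocount, digits = 15)),
    paste0("# n_sites: ", model$n_sites),
    paste0("# branch_a_pos: ", model$branch_a_pos),
    paste0("# background: ",
           paste(format(model$background, digits = 15), collapse = "\t"))
  ), con)
  writeLines(paste(c("pos", RNA_BASES), collapse = "\t"), con)
  for (i in seq_len(nrow(model$prob)))
    writeLines(paste(c(i, format(model$prob[i, ], digits = 15)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a serialized site model
#' @param path Path written by [write_site_model()].
#' @return A `site_model`.
#' @export
read_site_model <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(paste0("^# ", key, ": "), "",
                           grep(paste0("^# ", key, ":"), hdr, value = TRUE))
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t")
  prob <- as.matrix(tab[, RNA_BASES])
  rownames(prob) <- NULL
  bp <- get("branch_a_pos")
  structure(list(
    site_type = get("site_type"),
    prob = prob,
    background = stats::setNames(
      as.numeric(strsplit(get("background"), "\t")[[1]]), RNA_BASES),
    pseudocount = as.numeric(get("pseudocount")),
    n_sites = as.integer(get("n_sites")),
    branch_a_pos = if (bp == "NA") NA else as.integer(bp)
  ), class = "site_model")
}

# Built-in training alignments.  These are synthetic consensus-derived site
# collections capturing the canonical human signals (yUnAy-like branch
# points; pyrimidine-rich 3'ss with cAG|g; 5'ss MAG|GURAGU-like), bundled so
# the package scores sites out of the box.  They are NOT derived from any
# genome-wide catalog; users with curated alignments should train their own
# models.

bp_training_sites <- function() {
  c("UACUAAC", "UGCUAAC", "UACUAAC", "CACUAAC", "UACUGAC", "UUCUAAC",
    "UACUAAU", "CGCUAAC", "UACUCAC", "UAUUAAC", "CACUAAU", "UGCUGAC",
    "UACUAAC", "UCCUAAC", "UACUAAG", "AACUAAC", "UACAAAC", "UGCUAAU")
}

#' Default branch-point model
#'
#' A log-odds weight-matrix scorer over a 7-mer window with the branch
#' adenosine fixed at position 6, trained from a bundled synthetic
#' consensus alignment.  This is a documented approximation of
#' SVM-based branch-point predictors: best-candidate selection downstream
#' (maximum score, 3'ss-proximal tie-break) is preserved while the scorer
#' itself is a transparent frequency matrix.
#'
#' @param pseudocount Smoothing constant.
#' @return A `site_model` with `site_type = "bp"`.
#' @export
default_bp_model <- function(pseudocount = 0.1) {
  train_site_model(bp_training_sites(), "bp", pseudocount = pseudocount)
}

#' Default 3'ss strength model (offsets -20..+2, 23-mer)
#'
#' Trained from a bundled synthetic alignment of canonical acceptor sites
#' (pyrimidine tract, cAG, exonic G).  Window follows standard acceptor
#' scoring practice: 20 intronic positions plus the first 3 exon-adjacent
#' columns, the AG at window positions 19-20.
#'
#' @param pseudocount Smoothing constant.
#' @return A `site_model` with `site_type = "3ss"`.
#' @export
default_3ss_model <- function(pseudocount = 0.1) {
  tract <- c(  # 18 columns: offsets -20..-3, last column the -3 position
    "UUUUUCUUUUCUUCUCUC",
    "CUUUUUUUUCUCCUUUCC",
    "UUCUCUUUUUUUUUCUCU",
    "UUUCCUUUUCUUUUUUUC",
    "CUCUCCUCUCUUCCCUCC",
    "UUUUUUCUCCUUUUCCUC",
    "UCUUCUUUUUCUCUUUUU",
    "UUCCUUUCUUUUUCCUCC",
    "UUUUGUUUUUCUUUUCUC",
    "CUUCCUCUUUUUUUCUUC",
    "UUUUCUUCUCUCUUUCUC",
    "UCUCUUUUUCCUUUUUUU",
    "UUUCUUUUUUUCUCCUUC",
    "CUUUUCUCCUUCUUUUCC",
    "UUUUUUUUCUUUCUUUCU",
    "UCCUUUCUUUUUCUUUUC")
  exon3 <- c("GUU", "GGC", "GAU", "AUG", "GGA", "GUC", "GCA", "GGU",
             "AAG", "GUG", "GGG", "AUC", "GCU", "GAC", "GUA", "CUG")
  sites <- paste0(tract, "AG", exon3)
  train_site_model(sites, "3ss", pseudocount = pseudocount)
}

#' Default 5'ss strength model (offsets -3..+5, 9-mer)
#'
#' Trained from a bundled synthetic alignment of canonical donor sites
#' (MAG | GURAGU-like).
#'
#' @param pseudocount Smoothing constant.
#' @return A `site_model` with `site_type = "5ss"`.
#' @export
default_5ss_model <- function(pseudocount = 0.1) {
  sites <- c(
    "CAGGUAAGU", "AAGGUAAGU", "CAGGUGAGU", "CAGGUAAGA", "AAGGUGAGU",
    "UAGGUAAGU", "CAGGUAUGU", "CAGGUAAGG", "CACGUAAGU", "AAGGUAAGC",
    "CAGGUAAUU", "GAGGUAAGU", "CAGGUCAGU", "AAGGUAGGU", "CUGGUAAGU",
    "CAGGUAAGU")
  train_site_model(sites, "5ss", pseudocount = pseudocount)
}
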