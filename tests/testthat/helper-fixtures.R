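# shared fixtures built in code

# region with a given upstream (intron) and downstream (exon) part
make_region <- function(up, down = "GAU", exon_id = "r1") {
  three_prime_region(exon_id, paste0(up, down), nchar(up), nchar(down))
}

# random RNA string
random_rna <- function(n, bases = c("A", "C", "G", "U")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# small cohort config for fast tests
small_cohort <- function(n = 15L, seed = 42L, ...) {
  cohort_config(n = c(up = n, down = n, control = n), seed = seed, ...)
}

# brute-force AGEZ: scan every upstream dinucleotide independently of the
# packaged scanner
brute_agez <- function(region) {
  ch <- strsplit(region$sequence, "")[[1]][seq_len(region$up_len)]
  offs <- seq_len(region$up_len) - region$up_len - 1L
  g_positions <- which(ch == "G" & c("X", ch[-length(ch)]) == "A")
  g_offs <- offs[g_positions]
  g_offs <- g_offs[g_offs <= -3L]
  if (length(g_offs) == 0L) region$up_len - 2L else -max(g_offs) - 3L
}
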