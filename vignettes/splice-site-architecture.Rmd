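---
title: "3' splice-site architecture, single-strandedness and APA classification"
author: "splicearch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3' splice-site architecture, single-strandedness and APA classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicearch)
```

## The problem

When the 3' splice-site recognition machinery is perturbed — for example by
depleting the small subunit of the U2 auxiliary factor (U2AF35), which
contacts the nearly invariant AG dinucleotide at the intron's 3' end —
some exons gain usage and others lose it. Which way a given exon goes is
not random: it tracks the *architecture* of its 3' splice site (3'ss).
This package computes the architecture features of 3'ss-anchored sequence
windows and the group-level statistics needed to compare cohorts of
upregulated, downregulated and control exons:

* **AGEZ** — the AG exclusion zone, the stretch upstream of the 3'ss AG
  containing no other AG dinucleotide. Exons activated under U2AF35
  depletion tend to carry longer AGEZs.
* **Branch point (BP)** — the intronic adenosine attacking the 5'ss in the
  first catalytic step, typically 17–38 nt upstream of the 3'ss, located
  here by a weight-matrix scorer.
* **PPT** — the polypyrimidine tract between the best BP and the 3'ss.
* **Intrinsic site strength** — a frequency-matrix log-odds score of the
  acceptor (or donor) signal.
* **PU / delta-PU** — per-position probabilities of being unpaired in the
  Boltzmann ensemble of RNA secondary structures, averaged per group, and
  the up-minus-down difference with positional Wilcoxon–Mann–Whitney
  tests.
* **Exon class and APA categories** — start/internal/terminal position
  within transcripts, and categorization of alternative polyadenylation
  (APA) events into tandem 3'UTR, intronic and alternative-3'ss APA with
  proximal/distal shift tallies.

A deterministic synthetic-cohort generator plants each of these effects
with known parameters, so the full pipeline is testable end to end without
any external data.

## Coordinate and alphabet conventions

All windows are anchored at the 3'ss and indexed by signed offsets:
`-1` is the last intron nucleotide (the G of the 3'ss AG), `-2` its A, and
`+0` the **first exon nucleotide** — there is no offset zero on the intron
side. Note that conventions which label the first exon base "+1"
correspond to this package's `+0`. Genomic inputs are BED-style 0-based
half-open intervals; minus-strand windows are reverse-complemented so that
offsets always read 5'→3' on the transcribed strand. The analysis
alphabet is RNA `{A, C, G, U, N}`: `N` is excluded from every composition
denominator and never pairs.

The default extraction window is 100 nt of intron and 50 nt of exon.
This covers the deepest offsets the positional analyses use (the
optimal BP zone at −17..−38 and the structure contrast down to −50) with
margin; it is a declared package default, not an inference of any
particular study's setting.

## AGEZ, branch points and PPT

`find_agez()` scans offsets −3, −4, … for the first upstream AG (A at
`o`, G at `o + 1`, with the G at or beyond −3) and reports the number of
nucleotides strictly between that G and the A of the 3'ss AG. Windows
without an upstream AG are *censored* at `up_len − 2`; whether a
particular study counted the zone inclusively of boundary nucleotides is
generally unstated, so this convention is declared, exact, and easy to
map onto others.

```{r agez}
r <- three_prime_region("demo", "UAGUUUUUUUUCAGGAU", 14L, 3L)
unlist(find_agez(r)[c("agez_length", "upstream_ag_offset", "censored")])
```

Branch points are scored by a log-odds weight matrix over a 7-mer with
the branch adenosine fixed at position 6 (a yUnAy-style consensus). The
reference predictors in this area are SVMs whose trained internals are
not redistributable; the weight matrix is a documented approximation that
preserves the downstream contract that matters — the PPT is anchored at
the **maximum-scoring** BP, with ties broken toward the 3'ss-proximal
candidate. Users with curated BP alignments can train a replacement via
`train_site_model()`.

The PPT for a branch point is the maximal-scoring contiguous window
between `bp + 1` and −3 under the declared score
`#pyrimidines − 2 × #purines`, with minimum length 5 nt and pyrimidine
fraction ≥ 0.6 required; ties prefer longer, then more 3'ss-proximal
windows. No published PPT formula accompanies the analyses this package
reimplements, so the constants are exposed as arguments and echoed in
every run manifest.

Intrinsic splice-site strength uses frequency-matrix log2-odds scores
(`score_site()`), the transparent member of the usual scorer pair
(maximum-entropy models are deliberately out of scope — one fully
specified scorer serves every pipeline contract, and the site-pair
preference statistic is scorer-agnostic). The bundled 3'ss (23-mer,
offsets −20..+2) and 5'ss (9-mer, −3..+5) models are trained from small
synthetic consensus alignments bundled in the package; they are
placeholders for user-trained matrices, not genome-derived catalogs.

## The energy model behind PU

Production folding engines implement the full nearest-neighbor
(Turner) energy model. Reimplementing it is out of scope here, and
wrapping an external engine would make the package's core claim —
that its inside–outside recursions are *exactly* verified — untestable.
Instead `energy_model()` defines a pair-additive, stacking-free model:

* allowed pairs GC/CG (−3.0 kcal/mol), AU/UA (−2.0), GU/UG (−1.0),
* kT = 0.616 kcal/mol, minimum hairpin loop 3 nt,
* structure energy = sum of pair energies; pseudoknot-free.

`partition_function()` runs McCaskill-style cubic-time inside–outside
recursions (in C++, with per-nucleotide scaling against overflow) and
returns the full base-pair probability matrix;
`enumerate_structures()` is an independent exhaustive oracle (≤ 22 nt)
against which the recursions agree to 1e-9 in the test suite. PU at a
position is `1 − Σ_j p[i, j]`; the probability that a whole substring is
unpaired is available as a restricted-ensemble ratio
(`pu_unpaired_stretch()`), but the positional pipeline uses length-1 PU,
which is the quantity that positional averaging defines unambiguously.

Two consequences of the simplification are worth knowing:

* The model has no loop penalties, so it *overfolds* random sequence;
  absolute PU values are lower than a Turner-model engine would give.
  Group **contrasts** (delta-PU), which the pipeline reports, are the
  meaningful output; absolute PU levels are not calibrated.
* Per-position PU is **not** monotone under a uniform weakening of all
  pair energies: weakening pairs globally can *increase* pairing at a
  position whose stronger competitors lose more weight (verified against
  the enumeration oracle). The monotone quantity is the ensemble-level
  expected number of paired positions, `Σ_i (1 − PU_i) = 2·E[#pairs]`,
  and that is the invariant the test suite asserts.

An adapter slot (`fold_fun` in the PU operations) lets an external
folding engine be swapped in for cross-checks without changing any
downstream contract.

Delta-PU compares per-region PU values of the up and down groups at each
offset with a two-sided Wilcoxon–Mann–Whitney test — exact when both
groups have ≤ 12 regions at the offset and no ties, otherwise the
tie-corrected normal approximation with continuity correction.
Significance stars use raw p < 0.05, mirroring the usual positional
starring convention; Benjamini–Hochberg q-values across offsets are
reported alongside for readers who prefer FDR control.

## APA categorization

Published APA categorizations are often produced by manual genome-browser
curation. `classify_apa_event()` encodes the three categories as an
explicit, ordered rule cascade over annotated transcript models and two
attributable APA point sites per gene:

1. both sites inside one annotated terminal exon → **tandem 3'UTR**;
2. proximal site inside an annotated intron *and in no annotated exon of
   any isoform*, with the distal site in or beyond a downstream terminal
   exon → **intronic APA**;
3. two isoforms whose terminal exons overlap but start at distinct 3'ss,
   one holding each site → **alternative-3'ss APA**.

The exon-exclusion clause in rule 2 is the package's formalization: an
alternative-3'ss proximal site always lies inside the *other* isoform's
intron, so without that clause rule 3 could never fire. The shift call
(proximal/distal) comes from the group labels of the differential exons
nearest each site; conflicting evidence (both or neither upregulated,
tied distances) flags the event as ambiguous — flagged events are
reported but excluded from all tallies. Exon–transcript matching is
exact (tolerance 0 nt): fixtures and synthetic annotations are generated
consistently, and fuzziness would hide bugs rather than absorb noise.

## The synthetic generator

`generate_cohort()` builds each upstream sequence outward from the fixed
3'ss AG: boundary AG at the sampled AGEZ distance, AG dinucleotides
rejected inside the zone at sampling time, BP motif planted at a sampled
offset (normal around −24, sd 3), pyrimidine tract of the configured
composition between BP and −3, positional adenosine modifiers (default:
×0.45 over −17..−38 for the up group), and per-group structure mode —
`unstructured` (pairing-poor composition over −25..−50) or
`hairpin_upstream` (an exact reverse-complement stem of 11 nt with a 4-nt
loop spanning −25..−50, guaranteeing a structure signal under the
simplified energy model). Expression changes are drawn with a configured
Pearson correlation to the *realized* AGEZ lengths (default r = 0.4 in
the up group only).

Defaults encode the study conditions the pipeline targets: AGEZ mean/sd
70/15 (up), 40/12 (down), 45/12 (control), 100 regions per group.
Sampled AGEZ lengths are clamped to `[28, up_len − 6]` so the BP motif
and boundary AG always fit; the per-region truth table records the
realized values, so planted = measured tests are exact rather than
statistical. A single root seed drives counter-derived per-region
substreams, making cohorts byte-reproducible independent of generation
order.

What the generator does **not** emulate: genome-scale base composition,
splice-site strength distributions, transcript structure realism, read
sampling, or any coupling between features beyond the planted ones.
Passing tests therefore demonstrate that the measurement pipeline
recovers known planted effects at realistic cohort sizes — they say
nothing about effect sizes in real transcriptomes.

## Statistics

All ordinary tests delegate to the standard R implementations behind a
uniform comparison record: Welch's t (variances not assumed equal),
Wilcoxon–Mann–Whitney as above, Pearson's chi-squared without continuity
correction, the upper-tail hypergeometric, and Pearson correlation with
the t-transform p. The exact two-tailed binomial uses the
point-probability method (sum of outcomes with point probability at most
that of the observed count) — with 51 of 138 promoted sites stronger,
this gives p = 0.0028, printed as 0.003 at one significant figure.
Zero-variance degenerate inputs return p = 1 with a zero statistic when
means agree, and correlations on constant vectors are flagged undefined
rather than guessed.

## Worked example

```{r pipeline}
cfg <- run_config(
  cohort = cohort_config(n = c(up = 25L, down = 25L, control = 25L),
                         seed = 7L),
  seed = 7L)
out <- file.path(tempdir(), "demo_run")
res <- run_architecture(cfg, out)
subset(res$comparisons, grepl("agez", contrast),
       select = c(contrast, statistic, p))
```

The planted 70-versus-40 AGEZ separation is recovered with overwhelming
significance, the planted correlation appears in the up group only, and
`features.tsv`, `comparisons.tsv` and `manifest.txt` in `out` hold the
full record. The test-suite scales (100/group for architecture recovery,
60/group for the structure contrast, windows of 55–100 nt upstream) keep
the whole suite under a minute of folding time while leaving the planted
effects unmistakable.

## Known limitations

* The BP scorer is a weight matrix, not the SVM used by reference BP
  predictors; scores are not comparable across scorers, only ranks
  within a window are used.
* Absolute PU values are not calibrated against nearest-neighbor models
  (see above); use delta-PU, not PU levels, for inference.
* The APA rule cascade requires exactly two attributable sites per gene
  and annotated transcript models; de novo APA site calling is out of
  scope.
* Positional composition and PU statistics treat regions as independent;
  overlapping windows from paralogous loci would violate that silently.
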