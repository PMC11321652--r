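---
title: "Quantifying base-editing outcomes and engineering screens with bescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying base-editing outcomes and engineering screens with bescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bescreen)
library(dplyr)
```

## The problem

Adenine base editors (ABEs) — an engineered TadA deaminase fused to a Cas9
nickase — install A·T→G·C substitutions without double-strand breaks. The
most active deaminases have a wide editing window: they deaminate not only
the intended adenine but bystander adenines several positions away, and they
act at off-target loci with partial sgRNA homology. For a therapeutic edit
the quantities of interest are therefore not a single "editing efficiency"
but a joint distribution: which *combinations* of positions are edited in
each sequenced molecule, what fraction of molecules carry exactly the
intended edit, and how on-target activity compares to off-target activity.

`bescreen` implements the computational side of a library-assisted editor
engineering campaign: enumerate a deaminase variant library, model the
sort-seq reporter screen that ranks the variants, quantify amplicon reads
into allele tables, and classify outcomes at disease-model loci. A synthetic
data module generates every input the pipeline needs, so all claims in this
vignette are backed by code that runs in the test suite.

## Coordinate model

All positions are protospacer coordinates on the protospacer strand:
positions 1–20 across the spacer, PAM at 21–23, and negative positions 5′ of
position 1 with no zero (−1 abuts +1). This matches how editing windows and
bystanders are reported in the field (+4…+9, −1). `protospacer_spec()`
anchors that coordinate system on an amplicon reference; reverse-strand
amplicons are reverse-complemented in exactly one place
(`protospacer_view()` / the aligner's strand mapping), so an A→G call means
the same thing regardless of sequencing orientation.

## From reads to allele tables

`align_and_call()` is deliberately an *ungapped* anchored matcher, not a
general aligner. Amplicon sequencing of a base-edited locus yields
fixed-layout reads; base editors produce almost no indels; and the audit
trail a quantifier must keep is about substitutions. Each read is anchored
at the offset (±5 nt) minimising Hamming distance to the reference.
Length-anomalous reads are counted (`n_discarded_indel`,
`n_discarded_short`) rather than resolved; reads with more out-of-window
mismatches than `mismatch_budget` (default 5) are counted as
`n_discarded_mismatch`. Conservation — passing plus discarded equals input —
is asserted in the tests. Reads are dereplicated before calling, so cost
scales with distinct sequences rather than depth.

Three tunables matter:

* `quant_window` (default −3…+12): where substitutions become edit calls.
  The default covers a −1 bystander (splice-donor loci) and a +12 bystander
  (synonymous HBB-type bystanders) with margin.
* `mismatch_budget` (default 5): tolerated sequencing-error mismatches
  outside the window; such mismatches are never called as edits.
* `pseudocount` (default 0.5, enrichment only): keeps variants absent from
  one pool finite; exposed in the config, as are all of these.

The **denominator of every frequency is total passing reads**, not edited
reads: an unedited molecule dilutes the editing percentage, which is how
"editing efficiency" is used throughout this literature. Positions whose
reference base is not the queried from-base are reported `NA` ("not
applicable"), never 0 — a C position has no A→G frequency.

`editing_window()` reports the maximal contiguous run of applicable
positions with frequency ≥ `threshold_fraction × max`, containing the
argmax, ties toward 5′. The threshold is relative to the maximum (the
field's convention for describing a window's extent); the monotonicity
property — raising the threshold never widens the window — is
property-tested over random frequency vectors.

## Outcome classification

`classify_outcomes()` partitions reads into four exhaustive categories:
*precise* (edited at the target position and nowhere else), *bystander
missense* (any combo containing a position whose consequence is missense or
nonsense), *wild type* (unedited), and *other edited* (everything else —
combos whose only extra edits are synonymous bystanders or fall outside the
locus's editable set, e.g. residual sequencing error). The fourth category
exists because a three-way precise/missense/wild-type chart is only
exhaustive at loci whose bystanders are all missense; at an HBB-like locus
with synonymous bystanders it is not. `fold_other = TRUE` recovers the
three-way view. Categories are decided by position sets; consequences come
from caller-supplied codon context (`target_spec()`), because the fixtures
are synthetic integrations whose reading frame is known by construction, and
no genome annotation is consulted.

`combo_distribution()` projects each read's combo onto a chosen position set
(single/dual/triple products), and `purity_ratio()` computes
focal/(focal+competing) between two such products — e.g. single editing at
+5 versus dual editing at +5 and +8. Both are exact combinatorial
re-aggregations of the allele table; tests verify them against brute-force
expansion oracles, and `per_position_frequencies()` must equal the
marginalisation of the combo distribution (a cross-module identity asserted
over random tables).

## The reporter and the screen

The screen couples editor activity to fluorescence through a defective EGFP:
a 27-nt insert between the start codon and the EGFP CDS carries an in-frame
TGA stop whose adenine sits at protospacer position +7; +7 A→G turns TGA
into TGG (Trp) and switches EGFP on. `egfp_state()` applies substitutions
and re-scans the insert in frame; it is checked against an independent
translate-and-scan oracle for all 81 single-base substitutions of the
insert. The bundled insert places the protospacer at offset 2 so that the
stop codon is in frame; of the 81 substitutions exactly 8 (those destroying
the TGA without creating a new stop) rescue fluorescence.

The screen statistic is a pseudocounted log2 relative-frequency ratio
between sorted and input pools. The underlying experiment specifies sorting
and sequencing but no particular score, so the minimal standard choice is
used and config-exposed; a `rank_by = "frequency"` mode ranks by sorted-pool
frequency alone, since either reading is defensible. Replicates are
aggregated by **union of per-replicate top-k** (`rank_aggregate()`): this is
the only rule consistent with triplicate top-10 lists yielding more than 10
hits (e.g. 22), and an intersection mode is available behind a flag.

## Synthetic data: what it does and does not emulate

`simulate_amplicon_reads()` draws a combo per read from a generating
distribution (the *joint* edit structure — co-occurrence, not independent
per-position coin flips), applies it to the reference, then applies i.i.d.
uniform substitution errors. Defaults are `error_rate = 0.001` and 20,000
reads per amplicon — a plausible error rate and depth for short-amplicon
Illumina sequencing, stated here as the package's choice of study
conditions. `simulate_screen_pools()` assigns cells to variants
multinomially, adds Gaussian reporter noise (sd 0.1) to each cell's
activity, and sorts the top `gate_fraction` (default 0.05, a top-5% gate)
into the sorted pool; both generators are byte-deterministic given their
seed.

The simulators deliberately omit PCR duplicates and amplification bias,
quality-score structure, indel-generating processes (beyond an optional
length anomaly to exercise the discard counters), lentiviral copy-number
variation, and any sequence-context dependence of editing. Passing tests
therefore show that the *quantification and ranking machinery* is correct
and calibrated under multinomial sampling — not that real libraries are free
of those artefacts. The round-trip property (generator → quantifier recovers
the generating distribution within multinomial error; χ² not rejected across
50 seeds at α = 0.001) is the package's core calibration claim, and the
planted-variant screen recovery (10 planted at activity 0.9 among 1000 at
0.05, 10⁶ cells, 5% gate, noise 0.1 — all 10 in every replicate's top 20) is
its core power claim. Problem sizes in the tests (20,000 reads, 10⁶ cells,
3 replicates, 50 seeds) are the package's chosen study conditions.

The locus fixtures are **synthetic stand-ins**: 83–100 nt amplicons that
honour the published positional logic of their namesakes — HFE C282Y (target
+5, missense bystanders at +1 ACG→GCG and +8 CAG→CGG), an HBB sickle-type
locus (target +7, synonymous bystanders +9/+12), a PCSK9 splice-donor locus
(target +6, bystander −1) — but are not genomic sequence. For the PCSK9
fixture the −1 bystander is intronic in reality and has no codon
consequence; the fixture assigns it a synthetic codon context whose edit is
missense so that the deleterious-bystander bookkeeping is exercised. The
bundled TadA pair is likewise synthetic: a fixed pseudorandom 167-residue
background identical between "modern" and "ancestral" sequences except at
the eight canonical divergence positions (109/111/119/122/147/149/166/167),
reproducing the six charge-swap parent residues (109S 111R 119N 122N 147D
149Y). Only the divergence layout, not the fold, matters to the enumeration
rules.

## Library rules and their edge cases

* Range scan: one variant per (position, amino acid) pair over residues
  106–157; parent-residue pairs collapse to a single identity variant, so
  52 positions × 20 amino acids = 1040 pairs yield 989 distinct variants.
  The identity variant is always included once — it is the normalisation
  anchor for enrichment.
* Site saturation at three positions is the full 20³ Cartesian product
  (8000 tuples, each a distinct variant; 7999 non-identity plus the
  identity).
* Charge swap: "same charge" is unambiguous only for charged residues, so
  the default classes are positive {K,R,H}, negative {D,E}, polar-uncharged
  {S,T,N,Q,C,Y}, nonpolar {the rest}, and the partition is configurable.
* Back mutation: for each single-substitution screen hit, the two nearest
  residues (scanning outward, ties toward the lower index, flank 10 —
  "adjacent" is otherwise underspecified) where modern differs from
  ancestral are reverted singly and jointly: three variants per two-neighbour
  hit, so three hits give nine, and with 22 screen hits the candidate pool
  is 31. Hits with fewer than two differing neighbours emit what exists,
  with a warning.
* Oligos: codons are chosen by a bundled human-usage preference ranking,
  falling back down the ranking when a choice would create the BsmBI site
  (CGTCTC, either strand) in context; a variant that cannot avoid the site
  becomes an explicit rejected record. Translating every emitted oligo must
  reproduce its variant's protein (round-trip test over the library).

The composition rules above report their own counts; no attempt is made to
reproduce any particular commercial library's total, which is not
recoverable from composition rules alone.

## Numerical and design choices

* Ties in enrichment ranking break by higher sorted count, then variant id,
  making ranks a deterministic permutation.
* `purity_ratio()` and the specificity ratio return `NA` ("not defined")
  when their denominators are zero, rather than 0 or 1.
* Off-target sites are summarised by the maximum per-position A→G frequency
  (one number per site, matching per-site bar plots); a `position` argument
  selects a fixed position instead. Negative-control background is
  subtracted by default (`net = max(freq − control, 0)`) and the summary
  records that choice in its output metadata; subtraction of a control from
  itself is idempotent (net 0).
* Sort-gate ties (e.g. zero reporter noise) resolve by stable ordering, so
  the gate is always exactly `round(gate_fraction × n_cells)` cells.
* All CLI outputs carry `#` metadata headers (tool, seed, config hash);
  identical config + seed reruns of every subcommand are byte-identical,
  which the test suite asserts by comparing raw bytes.

## Known limitations

Qualities are parsed but unused (quality-aware calling is config-surface
only); paired-end merging and gapped alignment are out of scope, so loci
with real indel byproducts need upstream processing; consequence annotation
requires caller-supplied codon context; and computational off-target site
nomination is not included — site lists are inputs, as in the experimental
practice the package models.
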