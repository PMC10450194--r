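---
title: "Sequence-based proxies of bacterial optimal growth temperature: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-based proxies of bacterial optimal growth temperature: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoproxy)
```

## The scientific problem

The optimal growth temperature (OGT) of a bacterium is an experimentally
expensive trait, unavailable for unculturable species. Ribosomal genes,
which are sequenced for essentially every organism, carry a usable record
of thermal adaptation. `thermoproxy` implements four sequence-derived OGT
proxies and the machinery to compare them on a common species set:

1. **C+ protein count.** Nine small ribosomal proteins (uS4, uS14, bS18,
   uL24, bL28, bL31, bL32, bL33, bL36) stabilise their fold at high
   temperature by chelating a metal: eight bind Zn²⁺ through a zinc-ribbon
   site and uS4 binds an iron–sulfur cluster. Each site is recognisable
   in sequence as two short elements holding four coordinating residues.
   Counting how many of the nine proteins of a species carry their site
   (its *C+ count*, 0–9) yields an integer proxy that rises with OGT.
2. **16S rRNA GC content**, whole-molecule or restricted to the helical
   (base-paired) segments of a reference structure, where GC pairs add
   thermal stability.
3. **16S rRNA U content**, which falls with OGT.
4. **YVIWREL content**: the summed fraction of Y, V, I, W, R, E and L
   residues in a designated protein set (written IVYWREL in part of the
   literature; the same 7-residue set, exposed once as `YVIWREL_SET`).

## The motif grammar

Each metal site is written in the field's pattern notation:
`(CXXC)-(CXXC)` for uL24, bL28, bL31, bL32 and uS14; `(CXXC)-(CXXH)` for
bS18 and bL36; `(CXXC)-(CXXXXC)` for uS4; and `(CXXC)-(CXX[C, D or E])`
for bL33, carried as three explicit variants (CCCC, CCCD, CCCE). The
grammar, implemented in `match_pattern()`, is:

* `X` is exactly one arbitrary residue; constrained positions admit only
  their listed residues.
* The two elements must occur **in order** and must **not overlap**; the
  spacer between them is any number of residues (configurable minimum,
  default 0). Non-overlap follows zinc-ribbon geometry, where the two
  element hairpins are distinct parts of the fold.
* The scan returns the leftmost feasible pair (smallest element-1 start,
  then smallest element-2 start). Classification depends only on match
  existence, but a deterministic position makes results reproducible.
* Ambiguity codes (X, B, Z, U, O) satisfy wildcards but never constrained
  positions: a reported `X` cannot be assumed to be a cysteine.

Each pattern carries exactly four constrained positions, so the scheme
defines 9 × 4 = 36 metal-coordinating residues
(`coordinating_residue_count()`), and the pair bL36 + bL32 alone defines
8. These analytic counts are asserted in the test suite and recomputed by
`scripts/acceptance.R`.

A species with several sequences of one protein is called `only_cplus`
(all match), `only_cminus` (none match) or `both`. For the C+ count,
`both` counts as C+: the metal-binding copy is the one expressed under
normal physiology, the metal-free copy is a zinc-starvation paralog. A
species with no sequence data for a protein is *excluded* from that
protein's denominators, not treated as C−: absence of data is not
evidence of absence of the site.

bL33 typing tests CCCC, then CCCD, then CCCE, first match wins: the
all-cysteine form is the canonical, experimentally characterised one, so
it takes priority when a sequence happens to match several variants.

## Consensus comparison

`find_temperature_associated_sites()` compares per-column profiles of
cold-adapted (OGT < 20 °C) and heat-adapted (OGT > 60 °C) rows of a
protein alignment. Two mutually exclusive categories are reported:

* **identity switch** — both classes conserved at ≥ the threshold
  (default 0.60) with different consensus residues (e.g. F in the cold
  class replaced by Y in the hot class);
* **conservation shift** — conserved in exactly one class (e.g. below
  40% in cold rows but 100% in hot rows), annotated gain-in-heat or
  loss-in-heat.

Design choices the inputs do not determine by themselves: class bounds
are strict inequalities (a species exactly at 20 °C or 60 °C belongs to
neither class); conservation is computed among non-gap rows only; columns
with more than 50% gaps in either class are skipped as unreliable and
reported; consensus ties break alphabetically and are logged; classes
smaller than `min_class_size` (default 5 rows) trigger a warning rather
than an error, because tiny classes make 100% conservation trivially easy.
The shift criterion is formalised as "≥ threshold in exactly one class";
this is an interpretation — the qualitative description it formalises
(poorly conserved in one class, highly conserved in the other) admits
variants, and the threshold is a parameter.

## Content proxies

GC and U content use the unambiguous-base denominator
(#A + #C + #G + #U): N and gaps are excluded from numerator and
denominator alike, and T is normalised to U on read. All values are
fractions in [0, 1]; per cent is formatting only. Helical GC maps helix
intervals (1-based, inclusive, in ungapped reference coordinates) onto
alignment columns through the reference row; columns where the reference
is gapped are never included, and a row entirely gapped at the mask is
skipped with a report rather than silently scored. YVIWREL content is a
single pooled ratio over all records of a species (equivalently: count
first, then divide), which makes it invariant to how residues are split
into records.

## Quality filters

* **Truncation**: records at least 25% shorter than the mean length of
  their protein are removed. The mean is computed once on the input set,
  not iteratively re-estimated after removals.
* **Decoding site**: 16S rows lacking the two decoding-site adenosines
  (positions 1492/1493 of the ungapped reference) are removed. The
  default requires a non-gap at both mapped columns; a strict flag
  additionally requires the base to be A. The weaker reading is the
  default because alignment gaps are the observable signature of a
  truncated molecule.
* **One record per species**: the lexicographically smallest record id is
  kept (C-locale radix order), which selects `rrnA`-style operon names
  deterministically.
* Plasmid-encoded genes cannot be recognised from sequence alone; their
  removal is delegated to a boolean column of the annotation table.

All user-facing coordinates are 1-based and inclusive, including
alignment columns (the R convention).

## Binning, regression, outliers

OGTs are assigned to nine upper-inclusive decade bins covering (0, 90]:
bin *i* is (10(*i*−1), 10*i*], labelled "1-10" … "81-90", so 40 °C falls
in "31-40". Nine bins are implemented although part of the literature
says "eight" while enumerating nine decade labels; the count is
configurable by simply ignoring empty bins, and empty bins are always
omitted from summaries.

`fit_linear_proxy()` regresses the proxy on OGT by ordinary least squares
(`stats::lm`), reports Pearson's *r*, and exposes t-based 95% confidence
bands for the mean response and 95% prediction bands for a new
observation. OLS is assumed; nothing in the compared quantities requires
a robust variant. Degenerate inputs are defined rather than left to
chance: a constant proxy gives slope 0 and *r* := 0 with a warning; zero
variance in OGT is an error. `estimate_ogt()` inverts the trend line and
reports the OGT range over which the 95% prediction band covers the
observed value (evaluated on a 4001-point grid spanning ±300 °C around
the point estimate; a side still covered at the grid edge is reported as
open, and a noiseless fit collapses the interval to the point).

Outlier analyses:

* `flag_cplus_outliers()` flags species whose C+ count deviates from
  their bin mean by ≥ δ (default 3). The bin mean includes the candidate
  (simplest reading; leave-one-out is a flag).
* `flag_extreme_at_temperature()` ranks species adapted to a target
  temperature (default 37 °C, matched ±0.5 °C because published OGT
  tables mix 37 and 37.0) by absolute deviation from the group mean and
  returns the top 10, ties broken by species id.

Before proxies are compared, `intersect_species()` reduces all tables to
their common species so every correlation is computed on an identical
set.

## The synthetic-data generator

`simulate_dataset()` generates the full input of the pipeline under one
master seed (stage *s* reseeds deterministically at `seed + s`, so any
stage can also be rerun standalone and two runs are identical). It
emulates: per-protein motif occupancy rising with OGT, rRNA GC rising and
U falling with OGT, YVIWREL rising with OGT, occasional C+/C− paralog
pairs, and planted outlier species. Defaults, chosen once as the study
conditions of the package:

| parameter | default | rationale |
|---|---|---|
| `n_species` | 500 | ~55 species per decade bin |
| `ogt_range` | (1, 90) °C | populates all nine bins |
| occupancy model | logistic in OGT | minimal monotone model for sigmoid-like empirical curves |
| `occupancy_midpoint` | 30–55 °C, protein-size order (bL36 lowest, uL24 highest) | smallest proteins keep their site down to the lowest temperatures |
| `occupancy_steepness` | 0.05 /°C | calibrated to the monotonicity contract, see below |
| `gc_intercept`, `gc_slope` | 0.50, +0.0015 /°C (sd 0.01) | 16S GC ~50–63% across the range |
| `u_intercept`, `u_slope` | 0.22, −0.0008 /°C (sd 0.008) | U falls with OGT |
| `yviwrel_intercept`, `yviwrel_slope` | 0.40, +0.0008 /°C (sd 0.005) | YVIWREL ~40–47% |
| `paralog_prob` | 0.05 | occasional two-copy species |
| `rrna_length` | 1500 nt | full-length 16S scale |

The steepness/midpoint pair deserves a note. The generator's contract
requires the per-bin only-C+ fraction of every protein to rise
detectably at these sample sizes (rank correlation ≥ 0.9 across bins).
With ~55 species per bin, a sampled bin fraction has a binomial standard
error of up to ~0.05; a steep logistic saturates several top bins within
one standard error of each other, and their sampled fractions then
permute at random, breaking the rank ordering. A 20-seed simulation over
a small steepness × midpoint-span grid showed 0.05 /°C with midpoints
30–55 °C keeps the minimum rank correlation over all nine proteins at
≥ 0.917 on every seed, while steeper settings fail intermittently; that
cell is the default.

Label purity is guaranteed by construction, not by chance: C+ backbones
are drawn from the 19 non-cysteine residues before the motif is embedded
(so no unintended motif, and no unintended bL33 variant, can arise), and
C− backbones are rejection-sampled from the full alphabet against *all*
patterns of the protein. Planted C+ sequences therefore always match and
planted C− sequences never do, which is why the classifier-vs-truth
closure test demands exactly zero errors.

`plant_outliers()` rebuilds designated species with a forced C+ count
(the first *k* proteins in midpoint order become C+, the rest C−, no
paralogs) or regenerates their 16S/proteome records with an offset
composition target, recording the ground truth.

What the generator does **not** emulate: phylogenetic correlation
(sequences are exchangeable given OGT; phyla are round-robin labels),
indels (each protein has a fixed length, so simulated record sets are
trivially aligned), codon-level structure, and any real secondary
structure (the packaged helix table is a regular synthetic grid, which is
adequate because the composition model is uniform along the molecule).
Consequently, passing tests validate the statistical machinery and the
classification logic, not the biological effect sizes: real alignments
have gaps, real occupancy curves need not be logistic, and real proxies
have phylogenetically structured residuals.

## Numerical and degenerate-input conventions

* Composition and occupancy means are clipped to [0.05, 0.95] before
  sampling; a GC/U combination summing above 1 is an error.
* An empty sequence is a no-match, not an error; an empty record set is
  an error for every aggregate (mean length, content, classification).
* Infinite occupancy steepness is a hard threshold at the midpoint
  (probability ½ exactly at it), used by tests to build noise-free
  datasets.
* Rejection sampling of pattern-free backbones aborts after a bounded
  number of attempts (default 1000) so a pathological configuration
  fails loudly.

## Problem sizes used by the tests

The suite exercises the scanner against a brute-force placement oracle on
10,000 random sequences, the generator/classifier closure and the
monotonicity, slope-recovery and outlier checks on the default 500-species
dataset, and prediction-interval calibration on 1,000 simulated fits of
50 points each; the whole suite runs in about a minute and a half.

## Known limitations

* The consensus shift criterion is one formalisation of a qualitative
  description; alternatives (explicit low/high cut pairs) would flag
  slightly different column sets.
* `estimate_ogt()` inverts a single fit; it does not combine proxies.
* The pipeline consumes alignments; it never computes them, so its
  consensus stage on real data is only as good as the upstream aligner.
* Decade bins hard-code the (0, 90] range; species outside it are
  rejected rather than binned into open-ended edge bins.
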