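---
title: "Methods: in silico polymorphic SSR markers and integrated SSR/SNP QTL-seq"
author: "ssrqtl authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in silico polymorphic SSR markers and integrated SSR/SNP QTL-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrqtl)
```

## Scope and model

`ssrqtl` implements two connected analyses used in marker-assisted rice
genetics, plus the synthetic-data machinery to exercise both with known
truth:

1. **In silico polymorphic SSR marker discovery.** Perfect microsatellites
   (simple sequence repeats, SSRs) are mined genome-wide from a reference
   assembly, anchored across a panel of accession genomes that share
   reference coordinates, and declared *in silico polymorphic* when the
   repeat tract length differs between at least two accessions while the
   flanking sequence is conserved. Markers are then annotated by gene
   context, reading-frame effect (for coding tracts) and population-level
   polymorphism category, and summarized with diversity statistics (PIC,
   Nei–Li distance, neighbor-joining trees).

2. **QTL-region bulked-segregant analysis (QTL-seq).** For a selfed
   biparental mapping population phenotyped for a quantitative trait,
   extreme homozygous bulks are selected, per-variant read counts give a
   SNP/SSR-index per bulk, and the difference profile
   $\Delta = \mathrm{index}_{\mathrm{high\ bulk}} -
   \mathrm{index}_{\mathrm{low\ bulk}}$ is scanned with sliding windows
   against Monte-Carlo confidence intervals simulated under the null
   hypothesis of no QTL.

## SSR mining rules

A tract qualifies when it is a *perfect* (uninterrupted) run of a
primitive 2–6 bp unit with at least **six repeats for dinucleotides** and
**five repeats for tri- to hexanucleotides** (`default_min_repeats()`).
Mononucleotide runs and compound/imperfect repeats are out of scope:
polymorphism is later defined on exact tract length, which is only
well-behaved for perfect tracts.

Numerical conventions worth stating explicitly:

* **Maximality.** A tract is reported only if its perfect run cannot be
  extended in either direction; the reported span covers the whole number
  of repeat units from the run start. Two adjacent tracts of different
  motifs may overlap by up to period−1 bases (the run of the second can
  begin on the last base of the first); both are reported, since each is
  maximal for its own motif.
* **Canonical motif.** The same tract can be written under any cyclic
  rotation of its unit on either strand. `canonical_motif()` returns the
  lexicographically smallest string among all rotations of the unit and
  of its reverse complement, so e.g. `"TG"`, `"GT"`, `"CA"` and `"AC"`
  all canonicalize to `"AC"`. Units that are themselves repetitions of a
  shorter unit (including homopolymer-like units) are rejected; during
  scanning this also resolves the same tract being visible at a multiple
  of its true period.
* **Ambiguity codes.** `N` (or any non-ACGT character) never matches and
  therefore terminates tracts; there is no IUPAC expansion.
* **Length classes.** Hypervariable **class I** tracts are ≥ 20 bp and
  potentially variable **class II** tracts are 12–19 bp. Published
  descriptions of the class II upper bound vary between 18, 19 and 20 bp;
  the 12–19/≥20 split is used here because it makes the two classes
  partition all emitted tracts with no overlap. `classify_length()` is
  total (shorter tracts map to `"below"`) even though the miner never
  emits them.
* **Coordinates.** All coordinates are 1-based inclusive, the native
  R/Bioconductor and GFF convention, in memory and on disk. BED export is
  converted to 0-based half-open at the boundary. The one deliberate
  exception is `interval_length()`, which reports `end − start`: that is
  the printed-span convention under which the flanking coordinates of a
  QTL interval reproduce its published length in bp.

## Cross-accession polymorphism scan

`anchor_and_compare()` emulates the transferability requirement of a PCR
marker: an accession contributes a tract length only when **both flanks
of length F match the reference exactly** at that locus. F defaults to
20 bp — a proxy for a conserved primer site; it is configurable, and
increasing it can only remove accessions from a marker (monotonicity is
guaranteed by re-locating the locus as the valid flank–tract–flank
structure nearest the expected position, so no tie re-resolution can add
an accession at larger F).

Because accession assemblies share reference coordinates only up to
indels, the upstream flank is searched within a bounded window
(`max_shift`, default 200 bp) around the expected position. The repeat is
then read out as whole units in the reference phase, and the downstream
flank must follow immediately. Consequences of this definition:

* an accession with a SNP in either flank is **absent** (NA), not zero;
* an accession whose tract is interrupted is absent (the structure test
  fails), matching the perfect-SSR restriction;
* a complete tract deletion with intact flanks is a measured length of 0.

A marker is polymorphic when ≥ 2 non-absent accessions disagree on tract
length (in bp, so cross-period comparisons are well-defined). Category
labels are assigned per accession pair: `within:<pop>` when the pair
shares a population, `between:<popA>:<popB>` (alphabetical, unordered)
otherwise; one marker can carry several labels.

## Annotation

Gene models are a plain segment table (gene, CDS, 5'/3' UTR, intron
rows); the **upstream regulatory region (URR)** is derived strand-aware
as the 2000 bp 5' of the transcription start (a common promoter-window
default for rice genes; configurable). Intervals spanning feature
boundaries receive the highest-priority overlapping context with
priority **CDS > UTR > intron > URR > intergenic** — published
single-category counts require some such rule, and coding impact
dominates. Overlap means ≥ 1 shared base.

Reading-frame effects of coding tract variants depend only on the
pairwise length differences mod 3: any difference not divisible by 3 is
a **frameshift**; otherwise the variant is an **in-frame indel**
(expansion/contraction of the encoded amino-acid run).

Cis-regulatory motif disruption is exact-string matching of literal
consensus sequences (default set: RAV1AAT `CAACA`, CARGCW8GAT
`CATAATTATG`) on both strands: a SNP *disrupts* every overlapping
occurrence present with the reference base and absent with the alternate
base; occurrences that exist only with the alternate base are reported
too, flagged `created`. Degenerate (IUPAC/PWM) motifs are out of scope;
the motif table is user-supplied.

## Diversity statistics

* **PIC** uses the Botstein three-term form
  $\mathrm{PIC} = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$, the
  convention of the standard marker-genotyping software; the simpler
  expected-heterozygosity form is available via `method = "het"`.
* **Nei–Li distance** treats each (marker, allele) as a band:
  $d = 1 - 2 n_{xy} / (n_x + n_y)$, with markers missing in either
  profile excluded from all three counts (pairwise deletion).
* **Neighbor joining** is the standard Saitou–Nei algorithm (via
  `ape::nj`), returned unrooted with branch lengths. Negative branch
  lengths — an artifact NJ can produce on non-additive input — are
  clamped to zero with the negative length transferred to the sister
  edge, preserving path lengths through the parent node.

## QTL-seq model

* **Index.** At a variant with distinct parental alleles, the index of a
  bulk is the fraction of usable reads carrying the **high-parent**
  allele. At SSR sites, reads are pre-classified by tract length;
  reads matching neither parental allele (stutter) are excluded from
  numerator and denominator. Zero usable depth gives an undefined (NA)
  index.
* **Delta sign.** $\Delta = \mathrm{index}_{HGWB} -
  \mathrm{index}_{LGWB}$, positive when the high-parent allele is
  enriched in the high bulk — the convention under which a QTL whose
  increasing allele comes from the high parent shows $\Delta$ near +1.
* **Filters.** A call passes at total depth ≥ 10 in *both* bulks, base
  quality ≥ 20 and distinct homozygous parental alleles; failures carry
  a reason code (`depth`, `quality`, `monomorphic`).
* **Bulk selection.** Individuals are ranked by entry mean; each bulk
  takes the k most extreme individuals *homozygous for the matching
  parental allele at every region marker*, skipping heterozygous or
  recombinant individuals; ties break by input order.
* **Segregation filter.** Markers entering map construction pass a
  Pearson χ² test of the two homozygous class counts against 1:1 at
  p ≥ 0.05; heterozygotes are excluded from the test (the expected ratio
  is stated for the parental classes; the handling is configurable
  upstream by what is passed in).
* **Windows.** 1 Mb windows advancing by 10 kb, anchored at position 0,
  half-open membership. Window means are unweighted; windows with fewer
  than 3 variants are undefined (NA) — *undefined, not zero* — and break
  significant runs during interval calling.
* **Null confidence intervals.** Under no QTL, each bulk samples k
  individuals from an F$_g$ selfing series — heterozygous with
  probability $h = (1/2)^{g-1}$ (so 1/8 at F4), each homozygote
  $(1-h)/2$ — giving a bulk allele frequency
  $p = (2\,n_{hom,high} + n_{het})/2k$; read counts are
  Binomial(depth, p). Empirical two-sided quantiles over R = 10,000
  replicates per depth give the 95%/99% bounds, interpolated
  piecewise-linearly across the depth grid and clamped beyond it.
* **Interval calling.** Windows whose mean Δ falls outside the bound at
  their mean depth are significant; maximal runs of spatially
  overlapping significant windows merge into one interval, trimmed to
  the outermost passing variants. With perfectly selected bulks Δ
  saturates at ±1 over a linkage plateau around a strong QTL, so the
  peak is reported as the **middle window of the tied maximum stretch**
  rather than its first — the plateau center is the natural point
  estimate when the statistic is flat at its ceiling.

## Synthetic data: what it emulates, and what it does not

`simulate_panel()` stands in for a multi-accession panel on shared
coordinates: a reference with planted perfect SSR loci (guard bases make
every planted tract maximal exactly as planned, so the truth table is
exact) and derived accessions with repeat-count mutations, background
SNPs and occasional flank mutations. Defaults: 11 accessions over four
population groups (4 indica, 2 aus, 2 japonica incl. the reference,
3 wild), 2 chromosomes × 40 loci, repeat-count mutation probability 0.4
per locus per accession, SNP rate 10⁻³/bp, flank mutation probability
0.05. Repeat-count steps are geometric (p = 0.5) in units with random
sign, so single-unit changes dominate, as observed for microsatellites.
Background SNPs are kept out of the tract ± flank windows so the truth
table stays exact; spontaneous background SSRs occur but are
monomorphic.

`simulate_f4_bulks()` emulates the mapping design: 190 F4 individuals
from a biparental cross (single-seed descent, one lineage per
individual), Haldane (Poisson, no-interference) crossovers on a 1.2
Morgan chromosome of 10 Mb, 400 variant sites, additive phenotype
$y = \mu + \sum a_i x_i + e$ with $x_i \in \{-1, 0, 1\}$ and
environmental variance set from the plot-level heritability target
(default 0.8, matching a strongly heritable trait such as grain weight);
bulks of k = 10 per tail; per-variant bulk depths Poisson(100) with
binomial allele counts at the true bulk frequency. When bulk selection
is infeasible the population regenerates under a shifted seed (≤ 5
attempts).

Deliberately **not** modeled: read-level errors and mapping artifacts,
segregation distortion, crossover interference, population structure
beyond the biparental cross, imperfect/compound repeats, and assembly
errors. Passing tests on this generator therefore demonstrate the
correctness of the algorithms under clean conditions — not robustness to
the full error structure of real resequencing data.

## Problem sizes and reproducibility

Every stochastic routine consumes a single seeded generator; fixed seeds
give bit-identical outputs, and simulation parameters are recorded in
the returned objects. The test suite exercises the miner against a
brute-force regex oracle on 200 random 10 kb sequences, panel-truth
recovery on the default 11-accession panel, null-CI calibration at
R = 10⁴ replicates, and planted-QTL recovery over 50 seeded F4 runs —
sizes chosen so the whole suite completes in a few minutes while keeping
Monte-Carlo standard errors well below the tested tolerances.

## Known limitations

* Marker discovery is reference-anchored: SSRs absent from the reference
  but present in another accession are invisible by design.
* Exact flank matching is stricter than real PCR (a primer tolerates
  some mismatches); F = 20 with exact matching is a conservative proxy.
* The null CI model conditions on fixed per-variant depth and ignores
  linkage between variants within a window; window-level significance is
  therefore conservative (window means aggregate correlated variants
  against per-variant bounds).
* `nei_li_distance()` assumes one allele call per marker per accession
  (homozygous material); heterozygous calls need pre-splitting into
  fragment presence/absence.
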