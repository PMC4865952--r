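---
title: "Autozygosity mapping and recessive variant prioritization with hbdscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autozygosity mapping and recessive variant prioritization with hbdscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbdscan)
library(dplyr)
```

## The problem

In a consanguineous family segregating a rare recessive disease, affected
individuals are expected to be *autozygous* at the disease locus: both of
their chromosomes descend from a single ancestral haplotype carried by a
shared ancestor, so the causal allele sits inside a long homozygous run.
This turns gene discovery into an interval problem. From exome sequencing
of a handful of affected individuals and unaffected relatives one can

1. filter the raw variant calls down to rare, protein-affecting candidates
   shared by all affected individuals under a recessive model,
2. map each sequenced individual's long homozygous stretches from the same
   exome data,
3. intersect the affected individuals' stretches into case-shared
   homozygosity-by-descent (HBD) regions and remove any interval that is
   also homozygous in an unaffected relative, and
4. keep the variants from step 1 that fall inside the surviving regions
   and segregate correctly (affecteds homozygous, carrier parents
   heterozygous).

hbdscan implements this pipeline end to end, plus a gene-drop simulator of
consanguineous pedigrees that provides ground truth — true autozygous
tracts and a planted causal variant — so that every stage can be validated
without access to patient data.

## Zygosity from read fractions

The mapping stages do not use genotype calls from a variant caller;
zygosity at each marker is re-derived from the raw allele-read fraction
`f = alt_reads / depth`:

| class | rule | depth gate |
|---|---|---|
| homozygous (`hom_ref`/`hom_alt`) | one allele holds $\ge$ 95% of reads | $\ge$ 5x |
| heterozygous (`het`) | $0.30 \le f \le 0.70$ | $\ge$ 10x |
| `ambiguous` | anything else (e.g. 70–95% alternate reads) | — |
| `unclassified` | site below the marker-selection gate | $\ge$ 20x to be a marker |

Two conventions needed fixing where the written rules overlap.  First, a
site with `f` below 5% satisfies both the homozygous-reference definition
and, read literally, the "below 30% is ambiguous" clause; classification
gives homozygous calls precedence over heterozygous, and heterozygous over
ambiguous.  Second, the 20x marker-selection gate subsumes the per-class
5x/10x gates; both are applied (the per-class gates matter only when the
selection gate is disabled via `apply_marker_depth_gate = FALSE`, which is
provided as an alternative reading).  `ambiguous` and `unclassified` sites
are removed from a sample's marker sequence before any windowing, so an
isolated noisy read does not break an otherwise clean homozygous run.

## Two detectors of homozygous stretches

**Windowed detection** (`homozygous_stretches()`): slide a window of 500
consecutive markers (step 1) along each chromosome; a window qualifies if
it contains at most 2 heterozygous markers and no adjacent-marker gap over
500 kb; overlapping and adjacent qualified windows are coalesced, and a
coalesced union is reported if it spans at least 1 Mb.  Window step,
per-chromosome scanning, and the boundary convention (a stretch runs from
its first to its last *marker*, not extended toward flanking markers) are
the package's choices where the procedure admits variants; step 1 is the
maximal-sensitivity reading of "all qualified windows".

**Run-based IBD detection** (`roh_runs()`): a maximal run of consecutive
homozygous markers with no intervening heterozygote, containing at least
50 SNPs and spanning at least 1 Mb.

The two detectors answer at different scales.  At exome-like marker
density (one marker per ~25 kb in the simulation), 500 markers span roughly
12.5 Mb, so the windowed detector only sees very long autozygous tracts —
but tolerates isolated heterozygous miscalls.  The run rule resolves
tracts down to ~1.25 Mb but is broken by a single heterozygote.  Because
the HBD source was genuinely open, `run_pipeline()` defaults to the
**union** of both detectors per sample (`use_window_stretches` and
`use_ibd_runs` toggle either alone).  An intersection default was
considered and rejected: it would inherit the window detector's ~12.5 Mb
floor and silently miss every shorter shared segment, which is exactly the
scale at which recessive loci are mapped in small families.

Correctness of the windowed detector is established against
`stretches_bruteforce()`, an independent oracle that enumerates every
window explicitly, marks covered markers, and takes maximal covered runs;
the test suite asserts equality on 200 randomized instances of up to 2,000
markers.

## Case-shared HBD and control exclusion

`case_shared_hbd()` takes the n-way interval intersection of the cases'
stretch sets (interval co-location only; allele-level agreement is
enforced later at prioritization), discarding fragments under 1 Mb.
`exclude_control_overlap()` then subtracts the union of the controls'
stretches and re-applies the 1 Mb floor.  Subtraction, rather than
discarding a region on any overlap, is the default because "no overlap
with controls" is satisfied by the trimmed remainder; the stricter
discard-entirely behaviour is available as `control_exclusion = "drop"`.
Interval arithmetic is delegated to IRanges throughout.

## The variant funnel

Variant-level filters, applied in order with counts recorded in the run
report:

* **QC** (`qc_filter()`): in every covered, genotyped individual,
  consensus quality $\ge$ 20, depth in [4, 500], annotated copy number
  $\le$ 2; then any SNP with another retained SNP at a different position
  closer than 5 bp is removed (both members of the pair — the criterion is
  a property of the pair, and keeping one would need an unstated
  tie-break). The 5 bp boundary is inclusive: SNPs exactly 5 bp apart are
  kept.  Indels are exempt from the adjacency rule.  QC gates are applied
  per sample over covered individuals because the alternative (pooled
  gating) is not well defined for multi-sample depth.
* **Consequence** (`consequence_filter()`): keep nonsynonymous,
  frameshift, and splice acceptor/donor variants; synonymous and
  non-coding variants are removed.  Annotations must be supplied; the
  package computes none.
* **Frequency** (`frequency_filter()`): remove variants with maximum
  annotated population frequency strictly above 0.5%; the boundary value
  0.005 is kept, and unannotated (novel) variants always pass.
* **Case/control sharing** (`case_control_filter()`): keep variants
  carried (het or hom-alt) by every case, homozygous-alternate in at
  least one case, and not homozygous-alternate in any control.  The
  default deliberately allows heterozygous carrier controls — the parents
  of an affected homozygote are obligate carriers — while
  `strict_absence = TRUE` gives the literal "absent in controls" reading,
  which would reject the very segregation pattern a recessive family
  shows.

`prioritize()` finally intersects the surviving variants with the
control-excluded HBD regions and keeps those passing
`check_ar_segregation()`: every case `hom_alt`, no control `hom_alt`,
every genotyped parent of a case heterozygous or unusable.  Candidates are
emitted unranked in position order; pathogenicity scoring and conservation
are out of scope, and a free-text `notes` column exists to carry such
externally computed annotations.

## The synthetic family

`simulate_family()` generates the data the pipeline is tested on:

* **Pedigree templates.** `first_cousin_single` produces offspring of one
  first-cousin couple (inbreeding coefficient $F = 1/16$);
  `first_cousin_double` mirrors a family with two first-cousin couples
  descending from one grandparental pair — four affected offspring (three
  under one couple, one under the other) and two genotyped unaffected
  parents as controls.
* **Gene drop.** Founder haplotypes carry unique labels; each meiosis
  draws a Poisson number of crossovers (uniform genetic map, 1 cM/Mb by
  default, no interference) at uniform positions.  Autozygous tracts are
  the intervals where an individual's two labels coincide — the ground
  truth.  The drop is *conditioned* on the causal transmission path: the
  phase of each meiosis on the path from the carrier founder to the cases
  is fixed so every designated case is autozygous at the causal position.
  Since transmission phase at a locus is an independent fair coin, fixing
  those coins is an exact draw from the conditional distribution; all
  crossover randomness is untouched.
* **Alleles and reads.** Marker positions are uniform per chromosome
  (2,000 per 50 Mb chromosome, 20 autosomes by default — exome-scale
  density); allele frequencies are uniform on [0.05, 0.5]; founder
  haplotypes draw alleles independently; the causal risk allele sits on
  exactly one founder haplotype and is annotated as a novel nonsynonymous
  variant, while every other site carries its own simulated frequency as
  its population-frequency annotation.  Read depth is Poisson (mean 80,
  matching deep exome coverage); alternate reads are binomial with
  success probability 0.01, 0.5, or 0.99 by genotype (1% base error).

What the simulation does *not* emulate: exome capture's clustered marker
spacing (positions are uniform; a clustered mode would shorten effective
windows), variable per-site quality, mapping artefacts, indels and
multi-allelic sites (fixtures cover the parsing paths instead),
phenocopies or reduced penetrance (affection status equals causal
genotype), and linkage disequilibrium between markers.  A pipeline that
passes the recovery tests is therefore validated for its interval logic
and noise tolerance, not for artefact robustness on real exomes.

## Calibration and recovery checks

The test suite and `scripts/acceptance.R` recompute, from scratch:

* **Oracle equivalence** of windowed detection versus brute force on 200
  random instances (up to 2,000 markers each).
* **Planted-signal recovery** over 50 simulated families at the default
  scale: the fraction of replicates whose candidate list contains the
  planted variant, the candidate-list length, and the reciprocal overlap
  between every true case-shared autozygous segment of at least 1.5 Mb
  and the detected case-shared HBD regions.  The residual failures are
  intrinsic to the fixed noise model: with 1% base error at ~80x, a truly
  homozygous site occasionally falls just below the 95% read-fraction
  rule and classifies ambiguous, and occasionally the true shared segment
  is shorter than the 1 Mb reporting floor.
* **Inbreeding calibration**: over 2,000 unconditioned gene drops, the
  mean autozygous genome fraction of first-cousin offspring is compared
  with the path-counting value $F = 1/16$ within three Monte-Carlo
  standard errors.
* **Threshold fixtures** with hand-derivable answers: a six-site QC table
  with exactly one survivor; 1,200 uniformly spaced homozygous markers
  giving 701 qualified windows coalescing to a single 1,199,001 bp
  stretch; 600 markers (599,001 bp, under the floor) giving none; run-rule
  boundary cases on either side of 50 SNPs and 1 Mb.

Problem sizes were chosen so the whole suite runs on a laptop-class
machine: the recovery study uses the default 20 x 50 Mb genome, the oracle
and calibration studies run at reduced sizes that still exercise every
code path.

## Known limitations

* Strictly homozygous-by-descent model: compound heterozygotes are never
  candidates.
* No genetic-map input: lengths are physical (bp), and the simulator's
  map is uniform.
* X-linked inheritance is out of scope; sex chromosomes are excluded from
  marker maps.
* Consequence and frequency annotations are inputs, not computed.
* Relatedness estimation (genome-wide IBD sharing proportions) is not
  implemented; only the run-based segment rule is.
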