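---
title: "Methods: detecting and analysing retrotransposon insertion polymorphisms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and analysing retrotransposon insertion polymorphisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripkit)
```

## The problem

A retrotransposon insertion polymorphism (RIP) is a presence/absence variant:
a SINE, LINE or ERV copy inserted at a genomic site in some haplotypes of a
population and absent from others. Young pig SINE subfamilies such as SINEA1
are still polymorphic across breeds, and insertions near or inside genes can
alter their expression — making RIPs both candidate causal variants and cheap,
gel-scorable markers for breeding. `ripkit` implements the complete desk-side
workflow around such a marker:

1. **discover** insertion/deletion differences of 50 bp and more between a
   *bait* locus (a gene plus ~5 kb upstream and ~3 kb downstream flank) and
   locus sequences extracted from other assembled genomes;
2. **annotate** the insertions against a repeat consensus library (family,
   strand, identity, coverage, target site duplication, gene feature);
3. **analyse** the resulting biallelic marker: genotype/allele frequencies,
   Hardy–Weinberg equilibrium and PIC per breed; genotype–phenotype ANOVA
   with Tukey HSD; `2^-ddCt` relative expression; and dual-luciferase
   relative promoter activity.

A seeded simulator (`sim_config()` and the `make_*` generators) fabricates
every input with planted ground truth, so the whole pipeline is testable
without downloading genomes.

## Discovery: anchor chaining instead of multiple alignment

The reference workflow for this kind of screen is a multiple alignment of the
bait against each assembly-derived locus, read off by eye for long gaps.
`ripkit` replaces this with a deterministic pairwise procedure per assembly:

* **Unique k-mer anchoring** (default `k = 31`): k-mers occurring exactly once
  in both sequences become candidate anchors. At desk scale (loci of tens of
  kb) almost every clean 31-mer is unique, and k-mers inside a planted element
  are absent from the bait, so insertions fall between anchors by
  construction.
* **Collinear chaining**: maximal co-diagonal anchor runs are chained by a
  dynamic programme maximising total anchored length; overlapping runs are
  trimmed along their diagonal. This resolves the anchor ambiguity a target
  site duplication (TSD) creates at an insertion junction.
* **Gap resolution**: each unanchored gap segment between chained runs is a
  candidate event. A gap whose net length difference `|query − bait|` reaches
  `min_sv_len` (default 50 bp, the conventional large-SV threshold) yields
  exactly one insertion or deletion. The event is placed by longest-common-
  prefix matching of the two gap sides, which preserves the net length
  *exactly* even when background SNPs sit near the junction — the property the
  recovery guarantees below rest on. We deliberately do not run a full
  banded alignment inside gaps: only the net difference and the extra bases
  are needed, and prefix placement provides both at a fraction of the cost.
* **Left normalisation**: breakpoints of repetitive junctions are ambiguous;
  all breakpoints are shifted to their leftmost equivalent position (the VCF
  convention), making calls comparable across genomes.
* **Clustering**: per-genome calls of the same type merge transitively when
  breakpoints agree within `cluster_pos_tol` (20 bp) and lengths within 10%
  relative; surviving clusters need support from at least `min_sources = 2`
  distinct breeds (the recurrence filter), the representative is the longest
  member, and sources accumulate as the union of breeds.

Assemblies that arrive reverse-complemented produce no forward collinear
chain; `discover_rips()` retries on the reverse complement.

## Annotation

`classify_insertion()` runs a Smith–Waterman local alignment (scores
2/−3, gap open −5, extend −1) of the inserted sequence against every library
consensus and its reverse complement; the best score wins. Identity is
matches over alignment columns; *insertion coverage* is the fraction of
inserted bases inside the aligned region — computed on the insertion, not the
consensus, so truncated copies of a long consensus still classify. Acceptance
requires identity ≥ 0.70 **and** coverage ≥ 0.80; these substitute for
RepeatMasker's score thresholds, which have no closed form, and both are
configurable. Below threshold the insertion is reported `unclassified` with
direction `"."` but its best identity/coverage are retained.

`detect_tsd()` looks for the duplicated target site flush at the insertion
junctions. A left-normalised insertion admits two equivalent placements of
the duplication (word at the start of the insert matching the bait just after
the breakpoint, or word at the end matching the bait just before it); both
are searched. Two numerical choices matter:

* **Exact duplications take precedence.** A naive "longest word with ≤ 1
  mismatch" rule is self-defeating: whenever an exact `l`-mer duplication
  exists, every `(l+1)`-mer containing it has at most one mismatch, so the
  rule systematically overshoots the true duplication. `ripkit` prefers the
  longest exact duplication and spends the mismatch budget only when no exact
  candidate of at least `tsd_min` exists, and the boundary columns must
  always match.
* **Reported element length excludes the TSD.** The duplication is target
  sequence, not element sequence; reported RIP lengths are therefore directly
  comparable to consensus lengths.

Report records are named `<gene>-<class>-RIP<serial>` (no serial when the
gene has a single RIP of that class), carry the gene feature of the
breakpoint (`Intron1`, `Exon3`, `upstream`, ... counted in transcription
order), and print the chromosome span in the conventional report dialect:
the 2-bp interval flanking the breakpoint when the insertion is absent from
the reference frame, the full inserted span otherwise. Machine-readable BED6
(0-based half-open) and minimal VCF 4.2 (`<INS>`/`<DEL>`) outputs keep
`bed_start = report_start − 1`.

## The simulator: what it emulates and what it does not

The generator's defaults are the packaged study fixture: a 15-kb bait locus
carrying a 22-exon gene; three SINE-like insertions of 286, 301 and 321 bp on
strands −/+/+ in introns 1, 2 and 21; a 12-bp TSD and 2% per-copy divergence
per insertion; six breed assemblies carrying overlapping subsets of the
insertions with a 1% background SNP rate and a 5×10⁻⁵ small-indel rate
(indel lengths capped at 49 bp so background never crosses the SV
threshold). Breed genotype tables, growth traits, Ct tables and luciferase
readings mirror the bundled population/trait structure. A single root seed
is split into named per-stage substreams, so any stage can be regenerated
independently and all generators are pure functions of `(config, seed)`.

Three identifiability choices deserve emphasis:

* **Background mutation applies to the shared backbone only.** Planted
  elements carry their own per-copy divergence process (substitution-only),
  and the TSD copies are left intact. This encodes the young-insertion
  assumption — a segregating SINE insertion is recent, so its TSD has had
  little time to diverge — and keeps planted lengths exact ground truth.
* **Junction disambiguation.** If the first (or last) element base happens to
  equal the flanking bait base, the planted coordinates are not the unique
  left-normalised representation of the variant and no annotator could
  recover "the" truth. The generator resamples such junction bases (at most
  two per copy), making the planted breakpoint, length and TSD unambiguous.
* **TSD default of 12 bp** sits in the typical SINE range; 2% divergence
  exercises, without stressing, the classifier.

The simulator does **not** model recombination, demography, nested or
truncated insertions, assembly errors beyond uniform SNP/indel noise, or
sequencing artefacts. Passing recovery tests therefore demonstrates the
pipeline's correctness on clean presence/absence structure at realistic
noise levels — not robustness to misassembled or highly repetitive loci.

## Population genetics

For genotype counts `(n++, n+-, n--)`: allele frequency
`p = (2 n++ + n+-) / 2N` at full precision (reports round to 2-decimal
percent); Hardy–Weinberg is the Pearson chi-square against
`(p², 2pq, q²)·N` with **df = 1 and no continuity correction** — the
convention of the classic population-genetics packages, and the one that
reproduces the published per-breed p-values this package is validated
against (an exact conditional test, `hwe_exact_test()`, is available but is
not the default). Monomorphic samples are flagged and skip the test rather
than erroring. PIC uses the m-allele form

\[
\mathrm{PIC} = 1 - \sum_i P_i^2 - \sum_{i<j} 2 P_i^2 P_j^2
\]

evaluated in closed form (`1 − s₂ − (s₂² − s₄)`); for two alleles it is
symmetric in `p ↔ 1−p`, maximal at `p = 0.5` with value 0.375, and the
report classifies PIC < 0.25 as low and 0.25–0.5 as moderate polymorphism.

## Association

`anova_tukey()` is a standard one-way ANOVA with Tukey HSD (Tukey–Kramer for
unbalanced groups) and compact letter displays at α = 0.05 (lowercase) and
α = 0.01 (uppercase), computed as maximal cliques of the
not-significantly-different graph — groups sharing no letter differ at that
level, and the letter partition is invariant under relabeling. Published
growth-trait tables in this field print "mean ± x" with x far too small to
be a standard deviation at the stated group sizes; `ripkit` interprets the ±
values as standard errors (SD = SEM·√n in the simulator, SEM in the
display), a deliberate design decision. The age-at-100-kg adjustment is a
pluggable hook whose packaged default,
`age + (100 − weight)·(age/weight)·c`, is an explicit linear stand-in (the
scheme-specific national formulae are not public); every report states which
adjustment was applied.

Under the packaged trait scenario (means 164.81/160.49/160.59 days, SEM-based
SDs, n = 63/297/90), the test suite measures the Monte-Carlo rate at which
the `+/+` group separates from both others at Tukey α = 0.05. That rate is
about 53% over 200 replicates (ANOVA significance alone ≈ 87%): with these
dispersions the second pairwise contrast (`+/+` vs `-/-`, t ≈ 2.6 against a
Tukey critical value ≈ 2.34) has power near 0.6, so consistent full
separation is not attainable, and the corresponding suite check documents
this as a known limitation rather than relaxing the threshold.

## Expression and reporter assays

`ddct()` follows the Livak convention: per-sample `dCt = Ct_target −
Ct_reference`, `ddCt` relative to the *calibrator group mean* (so the
calibrator's mean ddCt is exactly 0), fold change `2^−ddCt`. Group tests run
on the ddCt (log) scale, where normality is plausible, and are displayed as
folds; fold changes are invariant under plate-wide Ct offsets.
`luciferase_relative()` normalises per-well firefly/renilla ratios to the
control construct's mean ratio within each cell line and compares constructs
by two-sided t-tests on log ratios; results are invariant under joint
rescaling of both channels and under rescaling the firefly channel alone.

## Orchestration and problem sizes

`run_all()` executes simulate → discover → annotate → popgen → assoc → expr
from one JSON config, logs stage timings, and writes a manifest of input and
output checksums; a rerun with an unchanged config skips stages whose files
are unchanged. All thresholds of every module surface in the config, which
is the single source of truth for a run.

The packaged analyses run at desk scale by design: 15-kb loci, six
assemblies, populations of 18–450, 200-replicate association and
500-replicate expression Monte-Carlo checks. A full fixture pipeline takes a
few seconds on one core; the entire validation suite runs in well under a
minute. These sizes were chosen as the smallest at which every statistical
property under test is comfortably identifiable.

## Known limitations

* Discovery is pairwise + clustering; a true joint multiple alignment could
  resolve loci where different breeds carry different overlapping events.
* Best-hit-only classification: nested or fragmented repeats are not
  stitched.
* The repeat consensi shipped in the fixture are synthetic stand-ins named
  for their lengths; no claim is made that they match real pig SINEA1.
* Inversions, translocations and read-level SV calling are out of scope.
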