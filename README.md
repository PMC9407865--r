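# ripkit

Detection and population analysis of retrotransposon insertion polymorphisms
(RIPs).

A RIP is a presence/absence variant: a SINE, LINE or ERV copy inserted at a
genomic site in some haplotypes and absent from others. Young pig SINE
subfamilies (e.g. SINEA1) still segregate across breeds, and insertions in or
near genes such as *LEPROT* and *LEPR* can repress their expression and shift
growth traits — making RIPs both candidate causal variants and cheap,
gel-scorable markers for breeding. `ripkit` is the complete desk-side
workflow for such a marker, for geneticists working from assembled genome
sequences and routine phenotype/qPCR/reporter tables:

* **discover** — align a bait locus (gene ± flanks) against assembly-derived
  locus sequences by unique k-mer anchor chaining; every unanchored gap with
  a net length difference ≥ 50 bp becomes one insertion or deletion
  (left-normalised breakpoints); calls recur across genomes via clustering
  with a ≥ 2-breed support filter.
* **annotate** — Smith–Waterman classification against a repeat consensus
  library (family, strand, identity ≥ 0.70, insertion coverage ≥ 0.80),
  target-site-duplication detection, gene-feature labels, report/BED/VCF
  output.
* **popgen** — per-breed genotype and allele frequencies, Hardy–Weinberg
  chi-square (df = 1, no continuity correction), and polymorphic information
  content,
  `PIC = 1 − Σᵢ Pᵢ² − Σᵢ<ⱼ 2 Pᵢ² Pⱼ²`.
* **assoc** — one-way ANOVA with Tukey HSD and two-level compact letter
  displays (`a`/`A` conventions), plus an age-at-100-kg adjustment hook.
* **expr** — `2^−ΔΔCt` relative expression (Livak calibrator convention) and
  dual-luciferase relative promoter activity, tested on the log scale.
* **simulate** — a seeded generator that fabricates every input (loci,
  assemblies with planted insertions and TSDs, populations, traits, Ct and
  luciferase tables) with exact ground truth.

## Worked example

Simulate the packaged fixture (a 15-kb locus, three SINE insertions of
286/301/321 bp in introns 1, 2 and 21, six breed assemblies at 1% SNP
background), then discover and annotate:

```r
library(ripkit)

cfg <- sim_config()                         # packaged fixture defaults
loc <- make_locus(cfg)
asm <- make_assemblies(loc$bait, loc$model, loc$library, cfg)
svs <- discover_rips(loc$bait, asm$assemblies)
rips <- annotate_rips(svs, loc$library, loc$model, loc$bait)
rip_table(rips)[, 1:6]
#>                loci insertion_in length_bp direction       type       chromosome
#> 1 simgene-SINE-RIP1      Intron1       286         - SINEA1_286   bait:2519-2520
#> 2 simgene-SINE-RIP2      Intron2       301         + SINEA1_301   bait:3039-3040
#> 3 simgene-SINE-RIP3     Intron21       321         + SINEA1_321 bait:12919-12920
```

All three planted insertions come back with their exact element lengths
(the 12-bp TSD is detected and excluded), correct strands, families and
intron labels; `chromosome` shows the 2-bp breakpoint interval because the
insertions are absent from the bait frame.

Population genetics of the bundled genotype counts for the *LEPROT* SINE
RIP across seven breeds:

```r
pg <- popgen_table(rip_genotype_counts())
pg[pg$locus == "LEPROT-SINE-RIP", ]
#>            locus       breed   n geno % (+/+ +/- -/-) allele % (+ -)   HWE   PIC                  note
#>  LEPROT-SINE-RIP Large White 450    14.00 66.00 20.00    47.00 53.00 <0.01 0.374 moderate polymorphism
#>  LEPROT-SINE-RIP       Duroc  24    12.50 66.67 20.83    45.83 54.17  0.09 0.373 moderate polymorphism
#>  LEPROT-SINE-RIP    Landrace  24     0.00 37.50 62.50    18.75 81.25  0.26 0.258 moderate polymorphism
#>  LEPROT-SINE-RIP     Sujiang  24    29.17 37.50 33.33    47.92 52.08  0.22 0.375 moderate polymorphism
#>  LEPROT-SINE-RIP  Jiangquhai  24    62.50 20.83 16.67    72.92 27.08  0.02 0.317 moderate polymorphism
#>  LEPROT-SINE-RIP      Jinhua  24     75.00 0.00 25.00    75.00 25.00 <0.01 0.305 moderate polymorphism
#>  LEPROT-SINE-RIP   Rongchang  24     29.17 70.83 0.00    64.58 35.42 <0.01 0.353 moderate polymorphism
```

Each row gives genotype and insertion-allele frequencies in percent, the
Hardy–Weinberg p-value (`<0.01` marks disequilibrium at the 1% level — here
the Large White, Jinhua and Rongchang samples), and PIC: all seven breeds are
moderately polymorphic, so the marker is informative for selection.

Association and expression stages work the same way from plain tables:
`anova_tukey(phenotypes, "age_100kg")`, `ddct(ct_table, calibrator = "+/+")`,
`luciferase_relative(luc_table, control = "pGL3-basic")`. A whole run —
simulation through expression, with a checksum manifest and stage-skipping
reruns — is one call:

```r
run_all(list(seed = 1, expr = list(calibrator = "+/+", control = "pGL3-basic")),
        outdir = "run1")
```

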