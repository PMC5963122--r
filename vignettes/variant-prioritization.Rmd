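---
title: "Prioritizing exome variants under a dominant model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing exome variants under a dominant model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exocascade)
```

## The problem

Whole-exome sequencing of a single individual yields on the order of 20,000
single-nucleotide variants. In late-onset dominant disease, large multiplex
pedigrees are rarely available, so cosegregation cannot narrow that list;
instead, cohorts of unrelated patients are analysed one exome at a time and
the burden falls entirely on a filtering strategy. `exocascade` implements
such a strategy as a fixed cascade of conjunctive filters over a
multi-sample VCF, with per-stage accounting so that every elimination is
attributable.

The dominant hypothesis shapes the whole design: a single heterozygous hit
suffices, so only heterozygous calls are considered, and the first battle is
against *false-positive heterozygotes* — true homozygotes that the caller
reports as heterozygous, typically with grossly unbalanced allele depths.

## The reliable-heterozygote screen

For a heterozygous call with allele depths $AD_1, AD_2$ and total depth
$DP$, the screen computes the allele-balance statistic

$$ r = \frac{|AD_1 - AD_2|}{DP} $$

and accepts the call iff $DP \ge 50$ and $r < 0.3$ (strict). A genuine
heterozygote samples both alleles binomially with $p = 0.5$, so $r$
concentrates near 0 as depth grows; an artifact het behaves like a skewed
draw with small minor-allele fraction and pushes $r$ toward 1. Note that
$AD_1 + AD_2$ need not equal $DP$ — the reported total depth may include
unassigned reads — and the statistic deliberately uses the reported $DP$ as
its denominator.

The operating point is sharp at fixed depth. At $DP = 100$ a true het is
rejected iff $\mathrm{Bin}(100, 0.5)$ falls outside $[36, 64]$:

```{r oracle}
2 * pbinom(35, 100, 0.5)          # P(reject | true het, DP = 100)
pbinom(35, 100, 0.1)              # P(reject | artifact het, minor fraction 0.1)
```

so the screen keeps ~99.6% of true hets and rejects artifact hets
essentially always. `evaluate_screen()` measures both rates on simulated
cohorts against recorded ground truth; the test suite requires agreement
with these closed-form binomial tails within three Monte-Carlo standard
errors.

Two numerical points. Comparisons always use the full-precision ratio;
two-decimal values are display only. And the bundled calibration table of
six Sanger-validated sites (`inst/extdata/sanger_validated_sites.tsv`)
carries printed ratios that are not internally uniform: five agree with the
recomputed statistic to within one unit in the last printed digit (one of
them only under truncation rather than nearest rounding), while one row
prints 0.23 where the formula gives 0.19. `check_validated_sites()` flags
that row as inconsistent; the package implements the formula and does not
attempt to reconcile the printed value.

## The cascade

`run_cascade()` applies, in order:

1. **Primary selection** (per call): heterozygous, $GQ \ge 99$,
   $DP \ge 50$. Standard VCFs cap genotype quality at 99, so the quality
   gate is implemented as an inclusive bound; `gq_min = 100` recovers a
   strict reading, which selects nothing on capped data.
2. **Het reliability** (per call): the allele-balance screen above.
3. **Rarity and functional class** (per variant): class in
   {missense, nonsense} and MAF $\le$ 1% — inclusively — in every
   consulted database, with a missing frequency counting as rare (a novel
   variant passes). By default 1000 Genomes and ESP are consulted; ExAC
   and gnomAD are available via `maf_databases`.
4. **Predictor consensus** (per variant): at least 4 of the 10 categorical
   tools (SIFT, PROVEAN, PolyPhen-2 HVAR/HDIV, FATHMM, MutationAssessor,
   MutationTaster, LRT, MetaSVM, MetaLR) call the variant damaging.
   `unknown`, `tolerated` and missing verdicts contribute nothing — an
   unscored variant accrues no support, matching the strategy's
   strict-exclusion philosophy.
5. **Combined CADD/REVEL gate** (per variant): CADD Phred $> 20$ (strict;
   the top ~1% most deleterious substitutions) *and* REVEL $\ge 0.75$
   (inclusive; a high-specificity cutoff for rare missense variants).

A variant survives a per-call stage if at least one sample's call
survives. Because several of the ten predictors and both ensemble scores
are defined only for missense changes, nonsense variants can be unscored
through no fault of their own; the `missing_score_policy` option makes the
resolution explicit (`fail` by default, `pass_if_nonsense` for a
truncating-variant-tolerant gate) rather than baking in a guess.

Every stage is a pure conjunctive predicate, which gives three properties
the tests enforce: per-stage counts are non-increasing; the survivor set
equals the one-shot conjunction of all predicates regardless of staging
(checked against an independently written oracle on random cohorts); and
the cascade is idempotent on its own survivors. The per-patient
"two distinct surviving variants in one gene" check is reported as a
diagnostic attached to the report — under a single-hit dominant model it is
information, not a filter.

## Gene-set functional selection

The final step restricts survivors to genes of plausible relevance. A
proprietary literature-network query is not reproducible, so the package
takes explicit, versionable gene lists instead: one plain-text file of
symbols per keyword, matched exactly and case-insensitively (no alias
resolution — lists should use current symbols). `filter_by_gene_sets()`
selects survivors whose gene appears in the union of the lists and reports
per-keyword matches plus the intersection across all keywords — the genes
supported by every line of evidence. The two bundled lists
(`genes_pd.txt`, `genes_neuron.txt`) are small curated *examples* for
testing and demonstration, not an authoritative panel; real analyses
should supply their own lists.

`summarize_cohort()` then produces the cohort-level accounting: patients
carrying at least one candidate (as heterozygotes), patients with
candidates in two or more genes, and genes recurring with multiple
distinct variants. Percentages are stored at full precision and rounded
only for display.

## The synthetic cohort generator

No patient-level data ships with the package, so every stage is exercised
on simulated cohorts with recorded ground truth (`simulate_cohort()` in
memory, `generate_cohort()` on disk as VCF + annotation sidecar + truth
table). The generator emulates exactly the statistical structure the
cascade assumes:

- **Depths** are negative-binomial (`dp_mean = 40`, matching a typical 40x
  exome average; `dp_dispersion = 8`); `dp_dispersion = Inf` fixes every
  depth at the mean, which the screen-calibration experiments use. In
  simulated calls the reported DP equals $AD_1 + AD_2$; the
  AD-sum-different-from-DP contract is exercised by hand-written I/O
  fixtures instead.
- **True hets** draw $AD_1 \sim \mathrm{Bin}(DP, 0.5)$; **artifact hets**
  draw their minor depth from $\mathrm{Bin}(DP, 0.1)$ by default
  (`false_het_alt_fraction`). The artifact mechanism is modelled purely at
  the AD/DP level: the screen sees nothing else, so the underlying biology
  (mapping error, cross-sample contamination) is irrelevant to testing it.
- **Call states** are i.i.d. per variant x sample: genuine het with
  probability 0.2, artifact het 0.05, reference otherwise. GQ sits at the
  cap of 99 except for a 5% fraction of low-GQ decoys, so the primary
  filter has work to do.
- **MAFs** follow a rare-tailed spectrum: half the variants rare (scaled
  Beta with shape `maf_tail_shape = 0.3`), with a point mass of novel
  variants absent from every database, and per-database jitter and
  missingness around a shared base frequency.
- **Scores** are coupled through a shared latent pathogenicity: predictor
  votes, CADD and REVEL all load on one Gaussian factor with correlation
  `score_correlation = 0.7`, so consensus and the combined gate agree more
  often than chance, as real annotations do.
- **Planted candidates** (`n_planted`) are constructed to pass every
  default filter: a balanced-binomial het carrier at depth $\ge 60$ with
  GQ 99, all MAFs small or absent, 5–10 damaging votes, CADD in (22, 40),
  REVEL in (0.78, 0.99), and a gene drawn from the bundled example lists.
  The balanced AD draw is rejection-sampled into the acceptance region, so
  recovery of planted candidates is a construction guarantee the
  end-to-end tests can demand at 100%.

A single seeded RNG stream consumed in fixed variant-major order makes
cohorts reproducible; identical parameters give byte-identical files.

What the simulation does *not* model — linkage structure, per-gene
mutation-rate heterogeneity, batch effects, indel-specific error modes,
platform-dependent caller behaviour — bounds what passing tests show:
they certify the *logic* of the cascade (each predicate, their
composition, the I/O contracts, the screen's operating point under the
binomial error model), not the clinical yield of the thresholds on any
real cohort.

## Problem sizes and other choices

The test suite and the acceptance script run simulations sized to make
their statistical claims sharp but cheap: a 10,000-call fixed-depth cohort
for screen calibration, 100 cohorts of 1,000 variants for the
staged-versus-conjunction equivalence, 20 seeds of 300-variant cohorts for
end-to-end planted recovery, and 50–60 cohorts for round-trip identity.
These sizes were chosen once, as the smallest at which the Monte-Carlo
tolerances above are meaningful.

Other decisions made where the design was genuinely open:

- **Biallelic only.** The allele-balance statistic is defined for exactly
  two alleles; multiallelic records are skipped with a warning and a
  count. Split them upstream (e.g. `bcftools norm`) if they matter.
- **AD order is file order.** $AD_1$ is the first listed allele's depth,
  with no ref/alt re-sorting; the statistic is symmetric, so order cannot
  change a verdict (tested).
- **Sidecar precedence.** Annotations may arrive as INFO keys or as a
  TSV keyed by chrom/pos/ref/alt; on conflict the sidecar wins with a
  warning, on the view that a curated table is more deliberate than
  embedded INFO.
- **Indels** are accepted as arbitrary ref/alt strings; functional-class
  assignment is the annotator's job, not inferred from allele lengths.
- **Missing annotation guard.** The CLI refuses to run when more than a
  configurable fraction (default 50%) of variants carry no annotation at
  all, since every annotation gate would silently fail them.

## Limitations

The cascade is a conjunction of hard thresholds: it cannot rank
near-misses, and a variant failing one criterion by a hair is
indistinguishable from one failing all of them (the published risk
variants it excludes — all three failing the combined gate — illustrate
both the intended specificity and the bluntness). Thresholds are taken as
given, not estimated from data; recessive and compound-heterozygous
models, variant normalization, and score computation itself are all out
of scope. The gene-set step is only as good as the supplied lists.
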