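---
title: "Mapping a recessive locus by bulked segregant sequencing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive locus by bulked segregant sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamap)
```

## The experimental design being modelled

A wild-type line is crossed to a recessive mutant; the F1 is uniformly wild
type; the F2 segregates 1:2:1 by genotype at the causal locus and 3:1 by
phenotype. Two DNA pools are built from phenotypically scored F2 plants — a
wild-type pool (W) and a mutant pool (M) — and both pools are sequenced to
moderate depth. Because every mutant-pool plant is homozygous at the causal
locus, markers linked to it are skewed toward the mutant haplotype in the M
pool but only mildly enriched in the W pool, while unlinked markers behave
identically in both pools.

## The statistic

For a filtered bi-allelic SNP, let the *M-pool allele* be the allele that
the mutant pool predominantly carries. Each pool's **SNP-index** is the
fraction of its reads carrying that allele, and the **ΔSNP-index** is
`SNP-index(M) − SNP-index(W)`.

Under the recessive design, a marker at recombination fraction $r$ from the
causal locus has expected pooled frequencies (in the limit of large pools
and deep sequencing):

* M pool: every plant is homozygous mutant at the causal locus, so each of
  its gametes carries the marker's mutant allele with probability $1-r$;
  the expected frequency is $1-r$.
* W pool: non-mutant plants are 1/3 homozygous wild type and 2/3
  heterozygous; conditioning the two gametes accordingly gives expected
  frequency $(1+r)/3$.

Hence $E[\Delta] = (1-r) - (1+r)/3 = (2-4r)/3$: 2/3 at the causal marker,
0 at $r = 1/2$. This closed form is the package's main correctness oracle —
the simulator must reproduce it, and the acceptance script recomputes it at
$r \in \{0, 0.1, 0.25, 0.5\}$ with 500 plants per pool at 10,000× depth
(12 replicates; that size makes the Monte-Carlo standard error of each mean
a few thousandths while keeping the computation interactive).

### Orientation of the statistic

Real data do not label which allele is "the mutant's". The package orients
each site on the **majority allele of the M pool**, with ties broken toward
the alternate allele. Rationale: near the causal locus the M pool is almost
fixed for the causal-linked allele, so the majority allele is the correct
orientation exactly where the signal matters. The rule has a side effect —
`SNP-index(M) >= 0.5` always, so the *oriented* null distribution of Δ is
positively biased at noisy unlinked sites. The confidence band therefore
applies the identical rule (see below); band and statistic are exchangeable
and the miscalibration that a symmetric band would suffer is avoided.

The closed-form check above instead uses truth orientation
(`index_sites(..., orient = "alt")`, valid on simulated data where the
alternate allele *is* the mutant allele by construction), because the
$(2-4r)/3$ law concerns the true mutant-allele frequency; under majority
orientation the expectation at $r \approx 1/2$ is inflated by the
sign-flipping, which is a property of the estimator, not of the linkage law.

## The reliability filter

`filter_config()` defaults:

| parameter | default | meaning |
|---|---|---|
| `require_biallelic` | `TRUE` | more than one alternate allele → reject |
| `min_quality` | 20 (phred) | variant quality, and base quality when annotated, must exceed this |
| `quality_strict` | `TRUE` | comparison is `>` (set `FALSE` for `>=`) |
| `min_reads_exclusive`, `max_reads_exclusive` | 3, 120 | each pool's depth must lie strictly inside (3, 120) |

Choices worth stating:

* **Strict vs non-strict quality.** "Above 20" and "at least 20" both
  circulate as conventions; the default is strict, and `quality_strict`
  makes the other reachable rather than hiding the ambiguity.
* **Depth bound per pool.** "At any SNP site" is read symmetrically: both
  pools must satisfy the bound. This is the stricter reading; a site with
  one starved pool yields an unusable index anyway.
* **Failure reasons** are reported in a fixed order — multiallelic, then
  quality, then depth — first failure wins, and the tallies (including
  passes) always sum to the number of input sites. Records lacking
  per-sample allele depths are kept and flagged on input (never silently
  dropped) and fail with reason `"depth"`, since no in-bounds depth can be
  established for them.

## Sliding windows

Per-site indices are averaged over a 2500-kb window advanced in 20-kb steps
(the defaults of `bsa_scan()`). Windows are anchored at position 0 of each
chromosome, enumerated while their start lies inside the chromosome, and
truncated at the chromosome end; internally coordinates are 0-based
half-open, with the 1-based VCF position `p` mapped to `p - 1` (conversions
live in one place, the window/aggregation code). Means are unweighted over
the sites in a window; empty windows carry `NA` and are never significant.
Aggregation is implemented with cumulative sums over position-sorted sites
and is tested for exact equality against a brute-force site-by-window
recount.

## The null confidence band

The band construction simulates the experiment's own null: a marker
unlinked to the phenotype makes pool membership independent of genotype, so

1. each pool's allele frequency is the mean of `pool_size` genotype dosages
   drawn 1:2:1 from {0, 1, 2} — equivalently `Binomial(2n, 1/2) / 2n`;
2. read counts are `Binomial(depth, freq)` per pool;
3. Δ is computed with the majority orientation, exactly as the analysis
   does;
4. the band at level $L$ is the empirical $(1-L)/2$ and $1-(1-L)/2$
   quantiles (`stats::quantile` defaults), simulated per depth on a grid
   (default 10, 20, 40, 80×) and looked up at the grid depth nearest each
   window's mean depth.

Defaults: 2000 replicates per depth, levels 0.95 and 0.99, all parameters
and the seed stored in the returned object and stamped into output files.
The (pool = 1, read = 1) corner of this null is small enough to enumerate
exhaustively, which the test suite does; it also checks the 3:1 phenotype
ratio, the conditional W-pool frequency of 1/3, and that band width never
grows with depth.

A window is called significant when its mean Δ exceeds the upper band value
at its depth; runs of at least `min_consecutive = 3` significant windows
merge into a candidate region (the union of their spans). Three consecutive
windows suppress isolated noisy windows while costing only 40 kb of
resolution at the default step. Bands are applied per window although they
are simulated per site; window means of overlapping windows are strongly
correlated, so the procedure is deliberately conservative rather than an
exact window-level test — the end-to-end calibration is what the package
actually asserts (below).

## The simulator: what it emulates, and what not

`cross_model()` parameterizes the whole experiment; the defaults of
`study_cross_model()` are the study conditions the package is built around:
two 10-Mb chromosomes with markers every 20 kb, the causal locus at
chr1:5,000,000, an F2 of 300, pools of 50 + 50, Poisson(40) depth, and a
per-read error rate of 0.01 (a phred-20-scale base error, consistent with
the quality-20 filter threshold).

* **Meiosis**: gametes follow a Markov chain along ordered markers with
  Haldane recombination fractions $c = (1 - e^{-2d})/2$; physical distance
  converts to genetic distance at a uniform 3 cM/Mb. Haldane (no
  interference) is the minimal standard choice and is exactly consistent
  with the Markov-chain composition over subintervals. No map function was
  dictated by the design; 3 cM/Mb is a typical plant-genome density.
* **Pool construction** takes the first *k* individuals of each phenotype
  in simulation order — deterministic, so a model (with its seed) pins the
  entire dataset byte-for-byte.
* **Reads**: depth fixed or Poisson; each read reports the wrong allele
  with probability `error_rate` (symmetric flip). No indels, no mapping
  artifacts, no GC bias, no duplicate reads.
* **Output**: VCF v4.2 with samples `W` and `M`, genotypes `./.` (a pool
  has no single genotype), allele depths in `AD`, constant variant/base
  qualities; plus a truth table with each pool's true allele frequencies.

What passing tests on this generator do **not** show: robustness to
alignment and calling artifacts, to non-symmetric error, to segregation
distortion, to mis-phenotyped plants, or to polygenic traits. The
simulator's single global seed fans out to fixed per-stage streams
(gametes, W reads, M reads, null band), so each stage is independently
reproducible.

## Segregation statistics

`mendel_test()` is the Pearson goodness-of-fit χ² against arbitrary ratio
weights, `df = k - 1`, **without** continuity correction — the convention
under which a 300-plant 218:82 table tested against 3:1 gives 0.871 (the
Yates-corrected value would be 0.751; for segregation ratios the
uncorrected statistic is the standard report). Weights are invariant under
rescaling; non-integer observed counts and zero expected counts are
rejected. `cosegregation()` scores genotype calls (`hom_wt`, `het`,
`hom_mut`) against phenotypes under the recessive rule and reports the
concordance, the class counts and any discordant individuals.

## Calibration and recovery, as actually measured

The test suite and `scripts/acceptance.R` assert, at sizes chosen to keep
the Monte-Carlo error well below the effect being checked:

* closed-form linkage law within 4 standard errors (12 replicates of
  500-plant pools at 10,000×);
* causal-region recovery on the study design in ≥ 18 of 20 seeded runs,
  no region on the causal-free chromosome in ≥ 16 of 20, and the peak
  window containing the true locus in ≥ 16 of 20;
* site-level exceedance of the 95% band on unlinked data within
  [3%, 7%] over 6000 sites (bands from ≥ 5000 replicates);
* exact equality of window aggregation with the brute-force oracle, and
  agreement of the degenerate null with exhaustive enumeration within 4
  binomial standard deviations.

On the 10-Mb study genome at 3 cM/Mb the causal chromosome is linked end to
end (15 cM maximum distance), so recovered regions span most of the
chromosome; the peak window, not the region width, carries the positional
information at this scale. Larger genomes narrow the region naturally.

## Known limitations

* The nearest-depth band lookup is a step function; windows whose mean
  depth falls midway between grid points inherit the nearer band unmodified.
* Orientation by M-pool majority is undefined at zero M-pool depth (an
  error; such sites should be filtered) and intentionally biases the
  oriented null upward — always pair the statistic with a band built under
  the same rule.
* Only SNPs are handled; indels and structural variants must be genotyped
  separately (their co-segregation can still be tested with
  `cosegregation()`).
* One causal locus, recessive inheritance, F2 design. Backcross or RIL
  designs and dominant traits would need different pool expectations.
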