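---
title: "Methods: ROH detection, genomic inbreeding and island scans in autozyg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH detection, genomic inbreeding and island scans in autozyg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozyg)
```

`autozyg` implements the classical array-genotype autozygosity workflow:
quality control, population-structure checks, run-of-homozygosity (ROH)
detection, four genomic inbreeding coefficients, and ROH-island scans with
linkage-disequilibrium (LD) annotation. This vignette explains the models
and the choices behind them; every number quoted here is computed by the
package's test suite or acceptance script, not asserted from memory.

## The ROH model and its assumptions

An autozygous segment — both chromosome copies inherited from one recent
common ancestor — appears on a SNP array as a long run of homozygous calls.
The detector treats ROH as an outcome definition rather than emulating any
particular scanning implementation: a reported segment is a **maximal** run
of consecutive mapped SNPs of one sample on one chromosome such that

1. at most `max_het_in_roh` (default 1) heterozygous calls occur inside it;
2. at most `max_missing_in_roh` (default 1) missing calls occur inside it;
3. the spanned length (first to last SNP, 1-based inclusive) is at least
   `min_length_bp` (default 1 Mb);
4. it carries at least `min_snps` SNPs (below);
5. its mean marker density, span divided by SNP count, is at most
   `min_density_bp_per_snp` (default 100 kb per SNP);
6. no gap between neighbouring SNPs inside it reaches `max_gap_bp`
   (default 1 Mb).

Maximality refers to criteria 1, 2 and 6: extending the run one SNP at
either end would violate one of them. The one-heterozygote allowance exists
because a single genotyping error inside a genuinely long autozygous
segment would otherwise split or destroy it; the missing-call allowance
plays the same role for failed calls. The two allowances are independent: a
segment may contain one heterozygous and one missing call simultaneously.

The 1 Mb length floor reflects the strong background LD of livestock
genomes below ~100 kb: short homozygous haplotypes are ubiquitous and
uninformative about inbreeding, so only multi-megabase runs are treated as
autozygosity. Length classes (1–2, 2–4, 4–8, 8–16, >16 Mb, left-closed
right-open) support the usual inbreeding-age reading: long ROH come from
recent inbreeding, short ROH from ancient inbreeding, because recombination
whittles identity-by-descent segments down by roughly half a
recombination-unit per generation.

### The minimum SNP count

Criterion 4 controls chance runs. If `het` is the mean heterozygosity
across individuals, a window of `l` SNPs is fully homozygous by chance with
probability `(1 − het)^l`; requiring

`l = ceiling( ln(alpha / (n_a · n_s)) / ln(1 − het) )`

keeps the expected number of chance runs across `n_a` individuals and
`n_s` SNPs at or below `alpha` (default 0.5). The ceiling is deliberate:
rounding down would break the bound. `min_snp_count()` exposes the rule and
`detect_roh()` applies it per population, since cohort size and
heterozygosity differ between breeds.

Two caveats are worth stating plainly. First, the bound concerns *pure*
homozygous stretches; the one-het/one-missing allowance deliberately admits
more, inflating the chance-run rate by roughly `1 + l·het/(1 − het)`.
The acceptance suite therefore verifies the α-bound with the allowances set
to zero (its own regime on autozygosity-free panels: the observed rate is
well under α), while the allowance's purpose — robustness to injected
genotyping error — is verified separately. Second, on real data `het`
enters through an estimate; the package computes it as the population mean
of per-individual heterozygous-call fractions over QC-passing SNPs.

### Maximality, tie-breaks and degenerate inputs

With a one-het budget, two maximal candidate runs can overlap (each
spending the budget on a different heterozygote). The detector emits the
longer candidate, breaking ties leftmost, and discards overlapping
runners-up, so the segments of one sample never share a SNP — a documented,
deterministic rule rather than an implementation accident. Internally the
scan is vectorised: for every start index the furthest compatible end is
obtained from the sorted positions of violations, and maximal windows are
exactly the starts where that bound strictly increases. With a zero-het
budget a window starting on a heterozygote is empty and is dropped. The
test suite proves the scan equivalent to brute-force enumeration of all
contiguous windows on hundreds of random panels.

Because runs extend through background homozygosity until the first
disallowed call, a detected segment slightly overhangs the true autozygous
tract — on the order of a few marker spacings per side, plus one
heterozygote's worth when the budget is unspent. At 50 kb spacing this is
roughly 100–300 kb, which matters for 2 Mb tracts judged at strict
reciprocal-overlap thresholds; the tight-recovery property test therefore
runs on a 2 kb map where the overhang is negligible, and the
sensitivity/precision acceptance check uses the standard reciprocal-overlap
≥ 0.5 matching rule at array density.

## Inbreeding coefficients

For individual *i* with ROH lengths `L_ROH_j`:

* `F_ROH = Σ_j L_ROH_j / L_aut`, where `L_aut` is the autosome length
  covered by the map (2.5 Gb is the conventional cattle/buffalo value and
  the default; `map_span_bp()` derives a panel-specific alternative).

The three frequency-weighted estimators average per-SNP kernels over the
individual's non-missing genotypes, with `p` the reference-allele frequency
in the analysis cohort and `h = 2p(1 − p)`:

* `F_GRM`: `(x − 2p)²/h − 1` (diagonal of the genomic relationship matrix);
* `F_HOM`: `1 − x(2 − x)/h` (excess of homozygosity);
* `F_UNI`: `(x² − (1 + 2p)x + 2p²)/h` (correlation between uniting
  gametes).

The weight is `2p(1 − p)` throughout. At `p = 0.5` all three kernels give
+1 for either homozygote and −1 for a heterozygote, and each estimator is
invariant under relabelling the reference allele (`x → 2 − x`,
`p → 1 − p`); both facts are asserted in the tests. Frequencies are
computed within each population by default (per-breed tables are the usual
reporting unit); a pooled mode exists. SNPs monomorphic in the cohort
(`h = 0`) are excluded — ordinarily the MAF filter removes them first.
Missing genotypes shrink the per-sample denominator, mirroring standard
`--ibc`-style behaviour.

One algebraic identity is useful for sanity checks: when `p` is estimated
from exactly the cohort being scored, the *population means* of `F_GRM`,
`F_HOM` and `F_UNI` coincide (the per-sample values do not), so matching
mean columns across the three estimators indicate consistency, not a bug.
Unlike `F_ROH`, all three can be legitimately negative, and all three
depend on the frequency reference: feeding them frequencies from a drifted
cohort shifts their means while `F_ROH` is untouched — the classical
argument for preferring `F_ROH` when comparing populations. The test suite
demonstrates the shift's existence in simulation without asserting its
direction, which depends on the drift realised.

## Population structure and outlier removal

`ibs_similarity()` computes pairwise identity-by-state similarity (mean of
`(2 − |x_i − x_j|)/2` over jointly observed SNPs); principal components
come from the double-centred similarity matrix by the classical
multidimensional-scaling route (eigenvectors scaled by root-eigenvalues,
variance shares from positive eigenvalues, eigen-sign fixed by forcing each
component's largest-magnitude loading positive). The similarity form is the
default input; the distance view is available and equivalent up to
centring. Removing samples that plot outside their breed cluster is
traditionally done by eye; `flag_cluster_outliers()` formalises it —
flag a sample whose PC1–PC2 distance from its population centroid exceeds
`n_sd` (default 3) times the population's root-mean-square centroid
distance — so the step is deterministic and testable. The RMS includes the
candidate itself, which makes the rule slightly conservative in small
clusters.

## Quality control

Filters run in a fixed order: sample missingness (> 5% removed) →
unmapped/sex-chromosome markers → SNP missingness (> 5%) → minor allele
frequency (< 2%, strict) → Hardy–Weinberg chi-square (p < 1e-6). Marker
statistics are computed after sample removal, on the analysis cohort,
matching the conventional `--mind` before `--geno/--maf/--hwe` sequencing.
The HWE test is the plain 1-df chi-square; monomorphic SNPs get p = 1 by
convention and are caught by the MAF filter instead. QC is pooled across
populations by default with an opt-in per-population mode (a SNP must then
pass in every population). The operation is idempotent and the report
reconciles every removal count.

## ROH islands and LD

Within each population the per-SNP ROH incidence is the fraction of
scanned samples whose ROH cover the SNP. Islands are maximal runs of SNPs
with incidence **strictly greater than** the threshold (default 0.20 —
"more than 20% of individuals", so exactly 20% never qualifies), with
above-threshold runs on one chromosome merged across gaps of at most
`max_join_gap_bp` (default 500 kb) and islands carrying fewer than
`min_island_snps` (default 5) qualifying SNPs dropped. The grouping
defaults are conservative and configurable, since published island lists
rarely state their grouping rule. Each island is annotated with the ratio
of mean adjacent-SNP r² inside the island to the chromosome-wide mean;
r² is the squared Pearson correlation of unphased dosage vectors
(composite genotypic LD — phase is unavailable on arrays), pairs never span
chromosomes, and zero-variance pairs are skipped and counted. A ratio above
1 is the expected signature of a shared conserved haplotype.
`overlap_with_scores()` intersects islands with an external per-SNP
selection-score table (e.g. iHS computed elsewhere) as pure bookkeeping.

## The simulator: what it emulates and what it does not

`simulate_panel()` generates the conditions the analysis assumes: two (or
more) diverged populations (Balding–Nichols divergence, default Fst 0.05)
on an evenly spaced map; Hardy–Weinberg genotypes outside planted
structures; per-sample autozygous tracts (one haplotype drawn and
duplicated, so tract SNPs are homozygous before error) with Poisson counts
and exponential lengths; an optional island region where carriers are
homozygous for one fixed shared haplotype; symmetric state-flip genotyping
error (an allele-dropout mode exists because the two error kinds stress ROH
calling differently); missingness applied last. Identical seeds give
identical panels; per-sample substreams are derived from the global seed so
partial regeneration is stable.

Defaults are a scaled-down livestock array study chosen once: 50 + 25
samples, 5 chromosomes × 100 Mb with 2500 SNPs each (40 kb spacing, a ~90K
array over a 2.5 Gb autosome), MAF uniform on [0.05, 0.5] mirrored,
Poisson(5) tracts of exponential mean 4 Mb clamped to [1, 20] Mb (per-animal
ROH counts and a 4–6% autozygous fraction typical of river-buffalo-scale
breeds), an island at chr1:25–28 Mb carried by 35% of population A (array
studies report peak incidences near 30%), error 0.001 and missingness 0.004
(a 99.6% call rate). A `generations_to_ancestor` preset maps g generations
to mean tract length `100/(2g)` Mb via the morgan ≈ 100 Mb heuristic.

What the simulator does **not** model: recombination maps and
coalescent/pedigree ancestry (tracts are planted, not inherited), background
LD outside tracts and islands (markers are independent given frequencies),
allele-frequency-dependent array ascertainment, and cryptic relatedness.
Passing tests therefore demonstrate that the detector and estimators do
what their definitions promise under the stated model — recovery of planted
truth, false-positive control, estimator identities — not that real data
meet those assumptions; in particular, background LD in real genomes makes
short chance runs more common than the independence model predicts, which
is precisely why the 1 Mb floor and the SNP-count rule are in force.

## Problem sizes and tolerances

The suite sizes simulations for a single CPU: oracle-equivalence on 500
random ≤ 200-SNP panels; false-positive control on twenty 50 × 5000 null
panels judged against the 99.9% Poisson envelope of 20·α (fixed before
measurement); recovery on a 200 × 20,000 panel at 50 kb spacing (slope of
`F_ROH` on the true autozygous fraction within [0.9, 1.1], absolute mean
bias below 0.01, sensitivity and precision at least 0.95); `F_HOM`'s
Hardy–Weinberg mean within 3 standard errors of zero over 1000 samples;
island recovery demanding ≥ 90% span coverage and an LD ratio above 1.
Worked-example arithmetic (class percentages from published per-class
counts) is checked to one unit in the last printed decimal place, which
absorbs a one-ulp rounding discrepancy present in one published percentage.

## Reporting conventions and limitations

`run_pipeline()` writes full-precision TSV artifacts with provenance
headers (version, config hash, seed) and display tables rounded as
conventionally printed; the summary table's dispersion column is the sample
SD (population tables captioned "standard error" at these cohort sizes are
numerically SDs, so the neutral label avoids perpetuating the ambiguity).
The genome-coverage column is defined here as class summed length divided
by the population's sample count and by `L_aut`, times 100 — published
tables do not always document theirs, so cross-study comparison of that
column needs care. Known limitations: no model-based (HMM age-class)
homozygosity-by-descent classification — the genotype-counting definition
is the point of this package; no phased-haplotype statistics (iHS and kin
are external inputs); PED input infers allele roles from observed
frequencies, so allele labels (not dosage semantics) can swap at 50/50
ties; and medium-density arrays are known to overestimate long-ROH counts,
a property of the data rather than of the detector.
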