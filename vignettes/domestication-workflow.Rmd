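---
title: "Methods: contrasting wild populations with hatchery-selected strains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrasting wild populations with hatchery-selected strains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`domestiscan` implements a population-genomic workflow for detecting the
early genomic consequences of domestication in hatchery-bred shellfish
strains relative to their wild progenitor populations: quality filtering
and LD clumping of a dense SNP-array panel, per-population diversity and
relatedness, pairwise Weir–Cockerham FST, LD-based contemporary effective
size, LD-decay curves, runs of homozygosity and genomic inbreeding, two
complementary genome scans on the pooled wild-versus-selected contrast,
and Random-Forest distillation of the scan outliers into a minimal
diagnostic marker panel. A forward Wright–Fisher simulator of wild
populations and derived captive strains is a first-class component: it is
the substrate on which every statistical claim of the package is tested.

The workflow is organised as numbered drivers under `analysis/`
(`01_simulate.R` … `07_panel_report.R`), each a thin narrative script over
exported package functions; `run_pipeline()` chains the same stages
programmatically from one YAML-configurable object.

# The data model

`geno_dataset()` holds a samples × markers matrix of alternate-allele
dosages (0/1/2, `NA` for missing), a marker map (chromosome, 1-based bp
position), a sample-to-population map and a wild/selected class per
population. Internally coordinates are 0-based half-open; VCF positions
are converted on I/O and BED intervals are taken as standard 0-based
half-open. Ploidy is fixed at 2 and phase is ignored — array genotypes
are unphased, so all LD quantities are composite (dosage-based) measures.
Only the GT field of a VCF is consumed. Markers are sorted by chromosome
and position on construction; unsorted input is sorted with a message.

# The simulator and what it emulates

`simulate_wild()` builds a shared ancestral pool whose allele frequencies
start uniform on [0.05, 0.95] (array SNPs are ascertained to be common),
runs a burn-in of Wright–Fisher generations **at a historical bottleneck
size** (`ancestral_Ne`, default 100, for 100 generations) with Poisson
recombination and no interference, and then lets each wild population
drift independently at its contemporary size (`wild_Ne`, default 300).
The bottleneck phase is what creates realistic short-range LD: at large
Ne the drift–recombination equilibrium for linked pairs would take
hundreds of generations to approach, whereas a bottleneck equilibrates
quickly and subsequent growth preserves linked LD while background LD
between chromosomes re-equilibrates within a few generations.

Divergence among wild populations is calibrated analytically: for a
target mean pairwise FST `F`, each population drifts for
`t = ln(1 − F) / ln(1 − 1/(2 Ne))` generations after the split. With
`F = 0`, populations are disjoint draws from one panmictic pool and the
realized Weir–Cockerham estimate is ~0. The calibration is verified
empirically by the test suite (realized mean pairwise FST within
[0.02, 0.04] for a 0.03 target).

`derive_strain()` breeds a captive strain from a wild source: each
generation samples `n_female`/`n_male` broodstock from the previous
cohort (generation 1 from the wild pool), forms offspring by random
pairing of a random mother and father (Poisson family sizes; a Gamma
overdispersion knob emulates sweepstakes variance in reproductive
success), recombines, and applies viability selection — an oversized
candidate cohort is culled to the fixed cohort size with survival
probability proportional to `(1+s)` per copy of the favoured allele at
each selected locus. Founder-haplotype labels are propagated alongside
the alleles, so realized identity-by-descent tracts and realized
inbreeding are known exactly; a kinship recursion over the recorded
pedigree gives each individual's pedigree inbreeding coefficient, and
per-generation breeder counts give both the `4 Nf Nm / (Nf + Nm)`
expectation and a demographic (family-size variance) Nb. `admix_from`
lets a fraction of first-generation offspring take their father from
another, already-derived strain (a strain-by-strain cross); donor
ancestry is tracked per individual. Note that under viability selection
donor ancestry rises above the neutral `prop/2` expectation when the
donor strain is already near-fixed for the favoured alleles — an
adaptive-introgression effect the tests account for.

The default demonstration panel (`demo_config()`) has 10 chromosomes of
3 Mb with 300 markers each (≈10 kb spacing) and 0.25 Morgan per
chromosome, four wild populations of 32 samples, and four derived
strains spanning the realistic range of breeding histories: an old
25♀×25♂ line (12 generations), a small-broodstock 10♀×8♂ line (8
generations), a 4-generation admixture cross, and a single-generation
18♀×12♂ hatchery F1 cohort. The F1 cohort is **classed wild**: it
underwent no selective breeding, which is also how such cohorts are
conventionally grouped in field studies, and its LD-based estimate then
illustrates how a single hatchery generation leaves a breeder-count
signature inside a "wild" label. Eight loci, drawn among markers with
wild-mean allele frequency in [0.2, 0.6] (the regime in which a rapid
parallel response is possible at all), are under parallel viability
selection (`s = 0.5`) in all bred lines, emulating shared culture
pressure.

What the simulator does **not** emulate: array ascertainment bias and
genotype-calling error (dosages are error-free), mutation, rotational
crossbreeding of sublines beyond the single `admix_from` cross, sex
chromosomes, and selection on polygenic architectures. Passing tests
therefore demonstrate correctness of the estimators under a clean
drift–recombination–selection model, not robustness to array artefacts.

# Filtering and clumping

`apply_filters()` applies, in order: excluded-region removal (BED),
pooled minor-allele-frequency filter (MAF < 0.05 removed; exactly 0.05
kept), per-sample missingness (> 10% removed), per-population call rate
(< 0.95 in any population removed), and a per-population exact
Hardy–Weinberg test (two-sided Levene–Haldane exact p < 0.01 in ≥ 50% of
populations removed; all-missing loci are treated as passing). The
report telescopes and filtering is idempotent.

`ld_clump()` drops, for every within-10-kb pair with dosage-correlation
r² ≥ 0.2, the lower-MAF member (ties keep the left marker). Because each
pair's r² is a fixed quantity, the greedy positional pass is the unique
fixpoint of iterative pair elimination — the test suite checks it
against an O(n²) elimination oracle. An optional iterative PCA
loading-outlier removal (|robust z| > 6, ≤ 5 rounds) is off by default;
the threshold is not externally fixed, so the step is exposed but not
imposed.

# Diversity, relatedness, FST

Expected heterozygosity uses the unbiased `2pq·2n/(2n−1)` estimator;
allelic richness is rarefied to `g = 2 ×` the smallest per-locus
non-missing count over all populations (a single global depth keeps
values comparable; the depth is recorded in the output). Pairwise
relatedness is the Ritland estimator with **within-population** allele
frequencies (the natural choice when each population is analysed on its
own; it carries a small negative bias of order −1/n for unrelated pairs,
which is why the contract is property-based — clones → 1, unrelated → 0
— rather than numeric equality to any published table). Weir–Cockerham
(1984) variance components give per-locus a, b, c and the multilocus
ratio-of-sums θ; loci with fewer than two non-missing genotypes in a
group, or monomorphic across the compared groups, are excluded.

# LD-based Ne/Nb

`estimate_ne()` subsamples markers (default 5000; within-sample MAF
< 0.05 excluded), forms **between-chromosome pairs only** (physical
linkage excluded), and averages pairwise r². Internally the pairwise
measure is the Burrows composite disequilibrium with the n/(n−1) factor
over the product of allele-frequency variances — the estimator on which
the random-mating sampling corrections were calibrated; a Monte-Carlo
check under independence shows the plain Pearson r² of dosages has a
visibly smaller sampling expectation and would bias Ne upward by ~25%.
The drift residual subtracts `1/S + 3.19/S²` (harmonic-mean pair sample
size S ≥ 30) or `0.0018 + 0.907/S + 4.44/S²` (S < 30), and Ne inverts
the quadratic drift expectation
(`(1/3 + sqrt(1/9 − 2.76 r²'))/(2 r²')`, small-S variant with 0.308 and
2.08). A non-positive residual reports an infinite estimate with a
finite lower confidence bound. Confidence intervals use a delete-one
individual jackknife with a chi-square approximation on the effective
degrees of freedom `2 r̄²²/var_jack`; the jackknife runs on a capped
(800-marker) subset of the pair set to keep the resampling tractable —
the point estimate always uses the full subsample.

In a mixed-age wild sample the estimate is a per-generation Ne; on a
single hatchery cohort it estimates the effective number of breeders Nb
of the parents, which is why the demonstration panel's F1 cohort sits
near its `4·18·12/(18+12) = 28.8` parental expectation while true wild
populations are large or unbounded. Admixture LD biases the
single-sample method downward, so the wild-versus-strain contrast is
asserted for non-admixed strains.

# LD decay

`binned_ld()` takes all within-chromosome pairs up to 500 kb, in 100
equal-width bins, on a seeded subsample of 30 individuals per population.
`hill_weir_fit()` fits the drift–recombination equilibrium expectation

E(r²) = (10+C)/((2+C)(11+C)) · [1 + ((3+C)(12+12C+C²))/(n(2+C)(11+C))]

with `C = c·d` (c the fitted per-bp scaled recombination rate, d the bin
midpoint, n = 2 × individuals) by pair-count-weighted nonlinear least
squares, restarting from three fixed initial values (1e-3, 1e-4, 1e-5
per bp) before failing with diagnostics. The half-decay distance solves
`E(r²)(c·d) = E(r²)(0)/2` on the **fitted** curve — using the fitted
value at d→0 rather than the empirical maximum bin makes the statistic
robust to a noisy first bin. Bin means (not raw pairs) are fitted, with
pair counts as weights. The two-way ANOVA on half-decay distances is an
ordinary linear model `half_decay ~ class * chromosome` with sequential
(type-I) sums of squares; a constant response is reported as all-zero F.

# Runs of homozygosity

Window parameters follow the standardized array protocol:
`L = ceil( ln(α/(n_s·n_i)) / ln(1 − het̄) )` with α = 0.05 and the panel's
mean heterozygosity (rounding is upward — longer windows are the
conservative direction), and the per-SNP window-hit threshold
`t = (N_out + 1)/L` truncated to three decimals. Sliding windows of L
SNPs qualify with ≤ 1 heterozygote and ≤ 5 missing calls; a SNP is
in-ROH when ≥ t of its covering windows qualify; maximal runs are split
at inter-SNP gaps > 1 Mb; and the called segment is **the longest
sub-run of each piece that starts and ends with a homozygous call and
contains at most one heterozygote**. The last rule resolves a genuine
ambiguity: the window threshold marks a few flanking non-homozygous SNPs
(the outward smear that the N_out parameter of the protocol exists to
control), so a literal "≤ 1 heterozygote in the whole marked run" would
reject clean planted tracts bordered by heterozygous background.
Segments must further satisfy the L-SNP minimum, ≥ 200 kb length and
≥ 1 SNP / 50 kb density. The caller is verified against an
independently-coded brute-force scanner on dozens of random fixtures.

`froh()` divides the summed length of segments ≥ 1 Mb by L_TOTAL, the
summed segment length of a fully homozygous individual simulated on the
same map with the same parameters — so F_ROH ≤ 1 by construction. Before
ROH calling no MAF/HWE/LD filtering is applied (thinning is known to
harm ROH detection on arrays); per-population QC retains individuals
with > 90% call rate, removes near-duplicates (method-of-moments PI_HAT
> 0.95 on a marker subset) and markers under 95% call rate, and skips
populations at or below 15 individuals.

# Genome scans

Both scans pool all wild samples into one deme and all selected samples
into another, and both are parameterized on the clumped set while
testing every full-set locus.

The FST-based test computes per-locus uncorrected ratios (the
infinite-sample limit of the Weir–Cockerham components, `s²/(p̄q̄ + s²/r)`),
restricts to loci with pooled expected heterozygosity ≥ 0.1, trims 5%
from each tail of the clumped-set distribution and fits
`FST·df/FSTbar ~ χ²(df)` by maximum likelihood on the truncated sample
(Nelder–Mead on log-parameters; non-convergence is an error carrying the
trimmed sample size and mean). Right-tail p-values for all testable
full-set loci get Benjamini–Hochberg q-values; q < 0.05 flags an
outlier. BH is deliberately used instead of Storey's estimator — it is
conservative, which only lowers the outlier count.

The PC-based test computes principal components of the mean-imputed,
frequency-scaled clumped matrix; K defaults to the largest **log-scale**
eigenvalue gap among the first 10 components (the absolute gap nearly
always selects K = 1 on structured panels because the first eigenvalue
dominates, which hides class structure on later axes; the relative gap
is scale-free). Each full-set marker's scaled dosage vector is regressed
on the K orthonormal score vectors, giving K z-scores; the robust
Mahalanobis distance of the z-vectors (MASS::cov.rob), rescaled by the
genomic inflation factor (median distance over the χ²_K median), yields
χ²_K p-values and BH q-values.

The union of both outlier sets (deduplicated, stable marker order) feeds
the enrichment test and the Random-Forest panel; removing it from the
full set and re-clumping yields the "clumped-neutral" markers used for
the structure, diversity and Ne analyses. For the Random-Forest step,
`scan_candidates()` extends a union smaller than 20 markers with the
top-ranked remaining loci by combined q-value — backward purging needs a
candidate list of workable size on small panels, and the outlier calls
themselves are never altered by this.

On the 4-strain demonstration panel the drift background of small-Nb
strains is heavy-tailed enough that union recall of the eight planted
loci at q < 0.05 sits below one half — an honest property of a 4-versus-4
design, where parallelism averages over fewer lines than in a 9-versus-9
study. The package therefore asserts strong rank enrichment of planted
loci on the demonstration panel, and evaluates strict recall (≥ 0.5) and
per-scan FDR (≤ 0.10) on purpose-built parallel-sweep panels (completed
sweep in the selected pool, 2000 neutral loci, 60 + 60 samples, 10
seeds), where both hold with margin.

# Random-Forest panel distillation

`tune_forest()` reads the OOB error over the whole 1..1000 tree range
off one cumulative stratified forest (per-class bootstrap size = the
smallest class count) and picks the first size within one standard error
of the minimum, then scans the mtry grid
{⌊√p⌋, 2⌊√p⌋, ⌊0.1p⌋, ⌊0.2p⌋, ⌊p/3⌋, p} at that size the same way.
`backward_purge()` ranks candidates by permutation importance (mean
decrease in accuracy), screens nested top-importance fractions by OOB
error and keeps one fraction above the minimizer as the conservative
candidate list, then iteratively removes the lowest mean-importance
marker (3 replicate forests per step, deterministic sub-seeds) down to
two markers. The final panel is the **smallest panel within one standard
error of the minimum** recorded OOB error: with 3-replicate noise a
plain arg-min regularly absorbs chance-correlated noise markers, while
the 1-SE parsimony rule — the same allowance already used for tuning —
recovers planted informative panels reliably. Missing dosages are
mean-imputed within class (forests need complete columns). `dapc_confusion()`
validates the panel: principal components explaining ≥ 90% of panel
variance, a linear discriminant on the scores, leave-one-out predicted
classes, and the confusion matrix with overall accuracy; a singular
within-class covariance triggers a warning and a reduction in retained
components.

# Enrichment, ellipses, report

Term enrichment is a one-sided hypergeometric test per term (a marker
carries a term when any of its annotated genes does), BH-corrected, with
q < 0.1 flagged; the universe is the annotated full-SNP set. PCA ellipse
areas use the 95% two-degree-of-freedom chi-square radius
(A, B = sqrt(eigenvalue × 5.991), area πAB) on PC1/PC2 scores;
"standardized" area is the z-score across populations — any affine
standardization gives identical ANOVA F statistics, so nothing hinges on
that choice. The admixture index is Shannon–Wiener entropy of the
population-mean Q rows (a per-individual variant is exposed). The
ellipse ANOVA is a sequential-F linear model with admixture and
relatedness as predictors, with and without their interaction, matching
how such effects are reported separately. `report_tables()` assembles
the per-population summary with per-class group means and the pairwise
FST group summary; bundled reference tables
(`reference_diversity_ne()`, `reference_fst_groups()`) carry the
published per-site summaries of the eastern oyster wild/selected array
panel so the report arithmetic (group means, the wild Ne mean excluding
the single-generation F1 cohort, and the outlier-to-genome-wide FST
ratio) can be recomputed and checked end to end.

# Problem sizes and determinism

The test and acceptance workloads were sized to run comfortably on a
single core: the demonstration panel is 256 samples × 3000 markers
(built once per test session and reused), the Ne-recovery experiment
uses 20 replicates of a 600-marker/50-sample panel at true Ne = 100, the
F_ROH experiment uses one 20-chromosome, 10-Morgan genome with four
breeding programs spanning broodstock sizes 2×2 to 25×25, and the sweep
panels are 2000 markers × 120 samples × 10 seeds. Every stochastic step
takes a seed; stage sub-seeds derive deterministically from one global
seed via a stable string hash, so re-running any driver or
`run_pipeline()` with the same configuration reproduces outputs exactly.

# Known limitations

Ritland relatedness is reported with its small-sample negative bias
rather than bias-corrected; the single-sample Ne method is biased by
admixture LD (flagged, not corrected); the PC-scan's inflation-factor
rescaling assumes the bulk of loci are neutral; ROH calling inherits the
window protocol's boundary imprecision (segment ends are accurate to
about one window); and the simulator's clean genotypes mean the QC
cascade's error-oriented filters (call rate, HWE) are exercised mostly
by planted violations rather than by realistic error processes.
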