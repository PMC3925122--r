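---
title: "Methods: F2 QTL mapping and cross-species colocalization with crossqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: F2 QTL mapping and cross-species colocalization with crossqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossqtl)
```

crossqtl implements the statistical workflow used to dissect the genetic
architecture of crop domestication in an F2 cross between a cultivar and
its wild progenitor, together with a comparative step that asks whether
QTL for the same traits colocalize with those of an independently
domesticated relative, bridged through an intermediary genome. This
vignette explains the models, the tunable parameters and their defaults,
the numerical choices, and what the simulation-based tests do and do not
establish.

## The F2 model and its simulator

All genetics in the package assumes an F2 population derived by selfing
the F1 of a cross between two inbred parents, so linkage phase is known
and codominant markers segregate 1:2:1. A gamete is modelled as a Markov
chain along each linkage group: crossovers between adjacent positions
occur independently with probability given by the inverse map function,
with no crossover interference. The Haldane map function
($d = -50\,\ln(1-2r)$) is the default because it is the no-interference
model implied by the two-gamete simulator; Kosambi is available as a
configuration switch everywhere a map function enters. Throughout, the
`A` allele denotes the cultivar allele, and genotypes are counts of `A`.

`simulate_f2()` draws two independent gametes per individual and then
applies, in order:

* **viability selection** in configured distorted regions. Selection
  acts at the marker nearest the region midpoint: a gamete carrying the
  disfavored allele is rejected and redrawn with probability $s$;
  heterozygote excess is produced by rejecting homozygous zygotes with
  probability $s$ (both gametes redrawn). Each draw is tested exactly
  once, so the equilibrium allele frequency of the favored allele is
  $1/(2-s)$ at the selected locus, decaying toward 0.5 with map distance.
* **dominant re-coding**: a configured fraction of markers loses the
  distinction between the heterozygote and one (randomly chosen,
  recorded in the truth object) homozygote class, yielding the ambiguity
  codes `AX` ("AA or AB") and `BX` ("BB or AB").
* **missingness**, completely at random at the configured rate.

`safflower_cross_design()` encodes the default study conditions: 276 F2
individuals; 244 markers on 12 linkage groups totalling 858.2 cM (6-40
markers and 30.7-105.3 cM per group); 26 of 244 markers dominant-scored;
2% missing calls; and three distorted regions -- one favoring the wild
allele (LG K, $s = 0.3$), one favoring the cultivar allele more strongly
(LG L, $s = 0.4$), and one narrow heterozygote-excess region (LG E,
$s = 0.4$). The selection coefficients were chosen once so that the
distorted markers are detectable after Bonferroni correction over the
244-marker family while the genome still coalesces into 12 clean linkage
groups at the LOD-5 grouping threshold; much stronger selection induces
spurious two-point linkage between independently distorted regions,
because segregation distortion at both loci mimics association under a
likelihood that assumes Mendelian margins. Marker positions within a
group are uniform draws (ends fixed); real maps are more clustered than
this, which is why the marker-distribution diagnostic is exercised on
constructed clustered maps rather than on simulator output.

`simulate_trait()` adds per-QTL effects $a\,x + d\,z$ (with
$x \in \{-1, 0, 1\}$ counting cultivar alleles and $z$ the heterozygote
indicator), optional pairwise epistatic products of those codings, and
Gaussian noise. QTL genotypes at arbitrary map positions are sampled
per gamete, conditional on the flanking marker alleles of that same
gamete (and on previously sampled QTL to the left, so multiple QTL in
one interval remain phase-consistent). When a target PVE is requested,
the noise variance is solved from the realized genetic variance, so the
regression $R^2$ on the true QTL genotype converges to the target.

## Linkage-map construction

**Recombination fractions.** `estimate_rf()` maximises the F2 two-locus
likelihood by EM over the 16 ordered gamete pairs, which handles every
mix of codominant, dominant and missing calls in one framework (the
double heterozygote, and every ambiguity class, distributes its
recombination count over the compatible gamete configurations).
Convergence is $|\Delta r| < 10^{-8}$ or 200 iterations from a start of
$r = 0.25$; estimates are clamped to $[0, 0.5]$ and the LOD is
$\log_{10} L(\hat r)/L(0.5)$. Results are flagged low-confidence below
10 informative pairs or when the observed Fisher information at
$\hat r$ falls below 10 (as for dominant x dominant pairs in repulsion,
which carry almost no linkage information). `rf_matrix()` runs the same
EM vectorised across all marker pairs.

**Grouping** is the transitive closure of
$\{\text{LOD} \ge 5, r \le 0.4\}$ (both thresholds configurable),
computed by union-find; singletons are allowed.

**Ordering** is travelling-salesman-style seriation on the rf matrix:
seed with the marker pair of largest rf (the putative ends; ties break
lexicographically), insert each remaining marker -- most tightly linked
first -- at the slot minimising the adjacent-rf sum, then refine with
2-opt segment reversals interleaved with a sliding window-of-3
"ripple" until no move improves the objective. The 2-opt stage matters:
on long groups the noisy far-pair rf estimates can seed the greedy
insertion badly, and the resulting reversed blocks are invisible to a
width-3 window. The final order is canonicalised so the
lexicographically smaller terminal marker comes first, which makes map
length invariant under reversal by construction. Positions are
cumulative map-function distances of adjacent rf estimates.

**Diagnostics.** `segregation_distortion()` tests 1:2:1 (codominant,
df 2) or 3:1 (dominant, df 1) by Pearson chi-square, with an exact
multinomial fallback (flagged) when an expected count drops below 1;
direction is read from the signed deviations, with heterozygote excess
when both homozygote classes fall short. Tiers (0.05 / 0.01 / 0.001)
are assigned after Bonferroni correction over the mapped-marker family.
`marker_distribution_test()` bins markers into 10 cM bins (configurable)
per group and applies Fisher's index of dispersion against the Poisson
with the pooled markers-per-bin mean, upper tail. The upper tail is
deliberate: clustering inflates the dispersion index, while regularly
spaced markers deflate it, and a regular map should not be flagged as
non-random in the clustering sense. `summarize_map()` reports mean
spacing as total length over (markers minus groups), the convention
under which 244 markers in 12 groups spanning 858.2 cM give 3.7 cM.

## Composite interval mapping

At each test position (2 cM steps), the phenotype is regressed on the
expected additive and dominance codings of the putative QTL genotype
given the flanking marker calls (Haley-Knott style), plus background
cofactor markers. Conditional genotype probabilities come from the same
two-gamete transition model as the simulator and handle ambiguity codes
and missing flanks exactly, by summation over compatible gamete pairs.
The LOD is $\tfrac{n}{2}\log_{10}(\mathrm{RSS_0}/\mathrm{RSS_1})$
against the cofactor-only model, a regression-likelihood form that keeps
the 200-1000-fold permutation scans cheap; PVE at a position is
$1 - \mathrm{RSS_1}/\mathrm{RSS_0}$ in percent, i.e. variance explained
beyond the cofactors.

**Cofactors** (at most 5, as in the study design) are chosen by forward
selection and backward elimination on the joint 2-df additive+dominance
F-test per marker. Forward entry requires the candidate's p-value to
clear 0.05 after Bonferroni adjustment for the number of candidates;
backward elimination uses a nominal stay level of 0.10. The Bonferroni
entry rule is the package's own choice: with ~244 candidate markers, a
nominal 0.05 entry rule admits cofactors for pure-noise phenotypes
almost surely (the minimum of hundreds of null p-values), which both
distorts permutation-threshold calibration and contradicts the intended
behaviour of a background-marker screen. Cofactors within the 10 cM
window of the test position (same linkage group) are excluded from that
position's model.

**Thresholds** follow the permutation approach: the phenotype is
shuffled across individuals, the scan is repeated, and the genome-wide
maximum LOD is recorded; the threshold at level $\alpha$ is the
order statistic $X_{(\lfloor N(1-\alpha)\rfloor + 1)}$ of the $N$
permutation maxima — the classical "$\alpha N$-th largest maximum"
rule, under which an exchangeable scan exceeds the threshold with
probability $\lfloor N\alpha\rfloor/(N+1)$, i.e. the nominal level
without the small anti-conservative bias of interpolating quantile
estimators. With cofactors enabled, each
permutation repeats the full procedure including cofactor re-selection,
so the permuted scans are exchangeable with the original; with
`max_cofactors = 0` the permutations run through a batched
least-squares path (identical statistic, vectorised over permutations),
which makes large calibration experiments affordable. A permutation
threshold controls the genome-wide error rate *conditionally on the
trait's own phenotype*: the calibration test therefore scores each null
trait against its own permutation threshold. Applying one trait's
threshold to other, independent traits mixes the conditional maximum-LOD
distributions and inflates the marginal exceedance rate -- an effect
visible in the upper tail even for Gaussian traits.

**QTL calling**: local profile maxima above the $\alpha = 0.10$
threshold become candidate QTL; two maxima on one linkage group are
separate QTL only when the profile dips at least 2 LOD below the lower
peak between them. The 1-LOD support interval is the contiguous run of
positions within 1 LOD of the peak, clipped at the group ends. Records
carry the additive effect of the cultivar allele, the dominance effect,
their ratio, PVE, and the confidence tier.

**MIM refinement** jointly refits all called QTL and performs backward
elimination under $IC(k) = -2(\log L - k \log(n)/2)$ with natural logs
and $k$ = number of QTL effect parameters (two per QTL): a QTL is
retained only if removing it raises the IC. The search is restricted to
single drops from the scan-derived model; full position re-optimisation
is out of scope. Near-coincident QTL (< 1 cM on one group) are merged
with a warning before fitting.

**Classification.** Gene action is classified from $d/a$ with
left-closed/right-open cutoffs at
$-1.25, -0.75, -0.25, 0.25, 0.75, 1.25$ (underdominant through
overdominant); magnitude is `small` below 10% PVE, `large` above 25%,
`intermediate` in between (boundaries inclusive). Applying these strict
cutoffs to the packaged 61-row reference QTL table yields 45 small, 14
intermediate and 2 large QTL; the original report gives 13 intermediate
QTL for the same table, a one-record discrepancy that the package
reports as computed rather than reconciling. Effect direction is
`expected` when the sign of the cultivar-allele additive effect matches
the sign of the parental difference, and `NA` when the parents do not
differ significantly.

## Epistasis scan

Markers with byte-identical call vectors (including the missingness
pattern -- a single differing missing cell prevents merging) are first
collapsed into haplotypes. For every pair of codominant haplotypes the
two-locus model with per-locus additive $(-1, 0, 1)$ and dominance
$(-0.5, 1, -0.5)$ contrasts and their four products (aa, ad, da, dd) is
fitted; each product's t-test provides the component p-value, reported
`NA` when empty genotype cells alias the term. A pair is significant
when any component clears $\alpha / \binom{g}{2}$ with $g = 12$ linkage
groups, i.e. $0.05/66 \approx 7.6\times10^{-4}$. Pairs on one linkage
group closer than 20 cM are excluded (a package choice: such pairs are
dominated by linkage, and downstream counting collapses same-group-pair
findings anyway); `count_interactions()` counts each unordered
linkage-group pair once per trait. Estimates are defined up to the
declared contrast scaling.

## Trait-level statistics

The spine index is (spines per cm of leaf margin) x (longest spine),
averaged over the sampled leaves; floret color change is the difference
in the CIE L\*a\*b\* a\* coordinate between maturity and flowering
(positive = redder at maturity; only the magnitude matters downstream).
Parental comparisons screen both samples with Shapiro-Wilk at 0.05 and
use Welch's t-test when both pass, otherwise the two-sample Wilcoxon
rank-sum test -- the unpaired analogue of the signed-rank test, which
requires a pairing that independent parental samples do not have.
Spearman correlations use pairwise-complete observations with Holm
(sequential Bonferroni) flags over the full family of trait pairs.
Transgressive segregation flags individuals beyond a parent mean by
more than that parent's own SD on the relevant side (the per-parent
reading of "one standard deviation of the mapping parents"; a pooled-SD
reading is equally defensible but changes little). Genotype-ratio tests
are Pearson chi-square against the stated ratio with an exact
multinomial fallback below expected counts of 1.

## Cross-species colocalization

Homology between the two species' mapped loci is established through an
intermediary genome: per query locus, tabular BLAST hits with e-value
strictly below $10^{-6}$ are sorted (e-value, then bit score, then
subject id) and the top two retained; a locus pair is bridged when any
retained hits share a subject scaffold, one-to-many relations allowed.
Linkage-group pairs with at least three bridged loci become synteny
blocks, oriented by the sign of the Spearman correlation of the paired
positions. Intervals project through a block exactly at shared loci,
by linear interpolation between them, and beyond the outermost shared
locus by the block's overall length ratio (signed by orientation),
clipped to the target group. Same-trait QTL whose intervals overlap
within a block count as colocalized, once per focal-species QTL even
when several partner QTL overlap it.

The chance expectation uses the hypergeometric point probability
$\binom{l}{m}\binom{n-l}{s-m}/\binom{n}{s}$ with $n$ = genome size over
mean QTL interval width for the trait (rounded to the nearest integer),
$l$ and $s$ the larger and smaller QTL sample sizes, and $m$ the
colocalizing count; the upper-tail probability $P(X \ge m)$ is emitted
alongside, since colocalization tests of this family are usually
reported as tails -- both are computed, the point form is the default.
Per-trait probabilities combine by Fisher's method,
$X = -2\sum \ln p \sim \chi^2_{2k}$ (zero p-values are an error; the
caller floors them explicitly). Direction concordance simply compares
cultivar-allele effect signs across species.

`simulate_homology()` generates the whole comparative fixture --
hit tables with planted scaffolding, spurious hits straddling the
e-value threshold at a configurable rate, maps, and QTL tables with
known colocalization truth -- so the pipeline's precision and recall
are measurable against ground truth.

## Problem sizes and what the tests show

The test suite runs each component at a deliberately chosen scale:
full 244-marker/276-individual crosses for map recovery and threshold
calibration (400 null traits, each scored against its own
200-permutation threshold); 100 replicate traits for peak localisation;
n = 1000 for effect-estimate coverage; 20-block fixtures for
colocalization recovery. These sizes make the stochastic checks stable
without being exhaustive. Passing them shows the machinery is
internally consistent and calibrated under the simulator's assumptions
-- Markovian crossovers, Gaussian trait noise, missingness at random,
selection-driven distortion. Real data violate several of these
(interference, non-normal traits, informative missingness, genotyping
error, marker clustering), so simulation-based recovery rates should be
read as upper bounds on real-data performance, not guarantees.

## Known limitations

* Ordering is heuristic seriation, not multipoint maximum likelihood;
  very tight marker clusters can be locally permuted within their
  cluster without affecting group length much.
* CIM effect estimates at a peak are attenuated when a retained
  cofactor sits just outside the exclusion window on the same group;
  the MIM refit (no cofactors) is the estimate of record.
* The hypergeometric model treats QTL intervals as equal-width
  exchangeable units; traits with very heterogeneous interval widths
  stretch that approximation.
* EPISTACY-style sums-of-squares partitions are reproduced up to the
  declared contrast coding, not bit-for-bit.
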