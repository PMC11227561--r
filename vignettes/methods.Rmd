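---
title: "Methods: recurrent-mutation scans and fitness statistics for experimental evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recurrent-mutation scans and fitness statistics for experimental evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the statistical models implemented in
`adaptoscan`, the assumptions behind them, the choices made where the
design was genuinely open, and what the synthetic-data generator does
and does not emulate.

## The adaptive-unit scan

### Model

Consider one environment in which $R$ replicate populations evolved
from a common progenitor, and let sample $j$ carry $n_j$ substitutions
in a compartment (the coding genome, or the merged noncoding regions).
Under the neutral null, each substitution falls into unit $g$ (a gene,
or a merged noncoding unit) with probability proportional to the unit's
length — drift and hitchhiking scatter hits across the genome but do not
concentrate them in particular genes beyond their length share. The scan
asks, for each unit, whether its hit count pooled across the $R$
replicates exceeds what this length-proportional placement allows.

In Monte-Carlo mode (`scan_config(mode = "montecarlo")`) each of
`n_sim` repeats re-places every sample's $n_j$ substitutions and pools
them; the unit's empirical p-value is the fraction of repeats in which
its simulated count reaches the observed count. Because placements are
independent across substitutions and samples, the pooled count of a
unit with length fraction $p$ is exactly
$\mathrm{Binomial}(n, p)$ with $n = \sum_j n_j$, so the binomial upper
tail (`mode = "exact"`) is an analytic oracle for the same null: the
two modes must agree within Monte-Carlo error, and the test suite
verifies that they do. Simulating at unit-probability rather than
nucleotide resolution is distributionally identical for hit counts and
much faster.

P-values are Bonferroni-corrected with the number of units in the
compartment as the divisor (for the noncoding compartment, the number
of merged noncoding units — a symmetric extension of the per-gene
divisor used for the coding compartment), and a unit is flagged
putatively adaptive when its adjusted p-value is below `alpha = 0.05`.

### Numerical choices

* The empirical p-value is the plain fraction $r/\mathrm{n_{sim}}$, so
  $p = 0$ is attainable. With thousands of tests and $10^5$ repeats, an
  add-one pseudo-count would put a floor of
  $10^{-5} \times n_{\mathrm{tests}}$ under every adjusted p-value and
  make Bonferroni significance unattainable; the plain fraction is the
  construction that gives the test its power. The pseudo-count variant
  remains available (`pseudo_count = TRUE`) for conservative analyses.
* Identical substitutions appearing in several replicates each count as
  separate hits, matching the pooled-replicate null; a
  `collapse_duplicates` flag exists because shared substitutions can
  also reflect a shared clonal origin, and collapsing them is the
  conservative sensitivity analysis.
* Binomial tails are computed via `pbinom(..., lower.tail = FALSE)`,
  which is stable down to the smallest representable doubles.
* A single observed substitution can never survive Bonferroni
  correction (its raw p equals the unit's length fraction); the test by
  construction cannot detect adaptive units used only once.

## Neutral substitution-class expectations

Given a coding sequence set and a six-class strand-symmetric mutation
spectrum, the package enumerates, for every codon in the set, the nine
single-nucleotide changes, classifies each (synonymous, nonsynonymous,
nonsense) through the standard genetic code, and weights it by the rate
of its spectrum class. The implementation aggregates by codon type
(64 × 9 classifications against codon frequencies), which is
algebraically identical to per-site enumeration; the test suite checks
exact agreement with an independent per-site enumeration oracle.

Two spectrum presets are shipped: one estimated from
mutation-accumulation lines pooled over seven environments
(0.195, 0.110, 0.077, 0.286, 0.067, 0.265 for A:T→G:C, A:T→C:G,
A:T→T:A, C:G→A:T, C:G→G:C, C:G→T:A) and a rich-medium (YPD) estimate
(0.093, 0.221, 0.081, 0.314, 0.093, 0.198). Neither is hard-wired;
every function takes the spectrum as an argument. Expectations are
invariant to rescaling the spectrum.

Terminal stop codons are excluded from the enumeration: a change inside
a stop codon is neither synonymous, nonsynonymous, nor nonsense in the
usual sense, and including it would contaminate all three classes.
Stop-loss changes elsewhere are binned as nonsynonymous, as there is no
separate stop-loss class in the three-way scheme.

The neutral coding:noncoding substitution-count ratio is taken to equal
the coding:noncoding site-count ratio, i.e. per-site mutation rates are
assumed equal between compartments. The expected
frame-shifting:frame-conserving indel ratio cannot be derived from an
SNV spectrum; it is a plain configurable number (default 3), and any
serious use should supply an estimate from mutation-accumulation indel
data.

The chi-squared ratio test compares observed counts $(a, b)$ with
expected proportions $(r/(1{+}r),\, 1/(1{+}r))$ on 1 degree of freedom
and computes the p-value in log space, so statistics in the hundreds
report accurate p-values down to $10^{-300}$ instead of underflowing to
zero.

## Genome model and site accounting

Internal coordinates are 0-based half-open; GFF3 and VCF conversion
happens only at the I/O boundary. A base covered by any CDS is coding;
noncoding sites are everything else, so no base is counted twice even
under overlapping annotations. A substitution in the CDS overlap of two
genes contributes a hit to each gene for scan purposes but appears once
in category totals (classified in the first gene by coordinate and
flagged). Mitochondrial sequences are excluded by default, since the
noncoding-class accounting is defined on the nuclear genome.

Merged noncoding units are built in three steps: all UTRs and introns
of a gene collapse into one gene-associated unit; annotated elements
(ARS, ncRNA, LTR, retrotransposon, telomere, centromere) stay
individual units; remaining unannotated fragments lying between the
same two adjacent genes merge into one intergenic unit. Every interval
is intersected with the noncoding space first, so annotation sloppiness
cannot leak coding bases into noncoding units.

Validation is `strict` by default for synthetic genomes (frame, start
codon, stop codon, no internal stops); `lenient` downgrades frame
violations to warnings and skips the gene, for real annotations with
known oddities.

## Growth rates and relative fitness

The maximum growth rate of a culture is estimated from OD readings
taken every 10 min for 24 h: OD is mapped to cell density through a
monotone piecewise-linear calibration (identity by default, since
instrument calibrations are lab-specific), ln(density) is fitted by
least squares over every window of 7 measurements spaced 60 min apart,
and the rate is the mean of the 3rd–8th highest window slopes — the two
highest are discarded as potential artifacts. The windowed-slope rule
admits two readings of "slope": a least-squares fit over the 7 points
(the default) or the endpoint difference
$(\ln d_7 - \ln d_1)/360$, which equals the mean of the per-step
$\Delta\ln/60$ differences; both are available
(`slope_method`), and they coincide on exact exponentials. Ties among
sorted slopes are broken by earlier window start, making the estimator
deterministic. On noiseless exponentials the estimator is exact; on
logistic curves it recovers the exponential-phase rate to within a few
percent because the highest-slope windows sit in the exponential phase.

Relative fitness is $2^{R/\bar R_{\mathrm{ref}} - 1}$: equal rates give
1, a doubled rate gives 2. The environment summary reports the stress
level $F_i/F_{SC}$ (progenitor in environment $i$ vs the base medium;
lower = more stress) and the extent of adaptation $f_i/F_i$ (evolved
population vs progenitor in the same environment). $F_i/F_{SC}$
averages per-replicate ratios (the alternative — ratio of averaged
rates — differs only at second order; per-replicate ratios also give a
standard error directly).

Because the progenitor's measured rate enters $F_i/F_{SC}$ positively
and $f_i/F_i$ negatively, a shared measurement error induces a spurious
negative correlation between stress and adaptation across environments.
The `first_two_vs_third` split uses progenitor replicates 1–2 for
$F_i/F_{SC}$ and the held-out replicate 3 for the $f_i/F_i$
denominator, removing the shared term. The test suite demonstrates the
artifact and its removal on a no-adaptation simulation: with
multiplicative measurement noise of 5% (sdlog), the naive estimator's
null correlation is strongly negative (about −0.8 at 200 environments)
while the split estimator is centered on zero.

## Repeatability statistics

Dice's coefficient $2|X \cap Y|/(|X|+|Y|)$ compares the adaptive-gene
sets of two evolved lines; a line's set is the intersection of its own
hit genes with its environment's adaptive calls. The random expectation
under independent uniform draws from a $G$-gene universe is computed
exactly as $2 m_1 m_2 / (G (m_1+m_2))$ per pair (the expected
intersection of independently drawn sets is $m_1 m_2 / G$; the
denominator is fixed by the set sizes) — gene length does not enter
because the scan already equalizes each gene's chance of being called
adaptive. A Monte-Carlo mode draws the random sets explicitly;
both agree within sampling error. A downsampling wrapper re-identifies
adaptive sets on subsampled replicates via a caller-supplied function,
for comparing experiments with different replicate counts at equal
detection power. Pairs where both sets are empty have an undefined
coefficient and are excluded with a warning.

Per-gene overall contributions follow the 1/n rule: in an environment
with $n$ adaptive genes each contributes $1/n$, others 0, averaged over
all environments. Total contribution equals the fraction of
environments with at least one adaptive gene — an exact conservation
law asserted in the tests. The cumulative curve ranks genes by how many
environments identified them (ties broken by contribution, then
identifier, for determinism).

The cross-contamination diagnostic exploits the plate layout (one
environment per row): for every sample pair, the shared-substitution
fraction is the count of identical (chromosome, position, ref, alt)
records divided by the mean substitution count of the two samples.
Same-plate different-row pairs (X) are compared against between-plate
pairs (Y) with a two-tailed Wilcoxon rank-sum test; contamination
inflates X specifically. Same-row pairs are excluded because they share
an environment and parallel adaptation would masquerade as sharing.

## Environment-level statistics

Partial Spearman correlation is implemented as the partial Pearson
formula on average ranks,
$(\rho_{xy} - \rho_{xz}\rho_{yz}) / \sqrt{(1-\rho_{xz}^2)(1-\rho_{yz}^2)}$,
with a $t$ approximation on $n-3$ degrees of freedom. The two-tailed
binomial sign test doubles the smaller tail and caps at 1. The
benefit–stress trend for an engineered mutation excludes environments
where the mutation is significantly deleterious (one-sample two-tailed
t-test against 1 at $\alpha = 0.05$, chosen to match the convention
used for the per-environment effect tests) and reports a one-tailed
p-value for a negative correlation, the directional hypothesis that
benefits grow with stress. The home/foreign sign-concordance table
excludes effects exactly equal to 1 from both columns and uses a
one-tailed Fisher exact test. The early-gain extrapolation is plain
linearity: a fraction $f$ of the total gain accrued over generations
$[a, b]$ extrapolates to $f \cdot T/(b-a)$ over the first $T$
generations.

## The synthetic-data generator

The generator emulates the *structure* of a multi-environment
evolution-and-resequencing experiment at desk scale, not any particular
organism's biology:

* **Genome** — 200 single-exon ATG…stop genes of 60–250 codons on two
  chromosomes, placed with intergenic gaps sized so the coding:noncoding
  site ratio is 2.68, the value for a compact fungal genome; half the
  genes get annotated UTRs and a few gaps carry ARS/ncRNA features so
  the noncoding merging logic is exercised.
* **Stress levels** — drawn uniformly from 0.68–1.06, the observed band
  of progenitor relative fitness across diverse stressful media.
* **Substitution counts** — per sample Poisson with rate
  $u_i = \lambda_0 (1 + \kappa (1 - s_i))$, rising with stress
  ($\lambda_0 = 1$, $\kappa = 6$). These defaults keep the pooled
  per-gene background density in the regime where multi-hit genes are
  genuinely surprising — the operating regime of the scan when a genome
  has far more genes than an environment has substitutions. Matching a
  real experiment's absolute per-sample counts on a 200-gene toy would
  concentrate the background ~30-fold above that regime and change the
  scan's operating characteristics being tested.
* **Planted adaptation** — two adaptive genes per environment (the
  typical per-environment count in such experiments), each hit
  independently per replicate with probability $\pi = 0.5$; hit
  categories drawn as 40% nonsense, 40% frame-shifting, 20%
  nonsynonymous (loss-of-function-dominated, as adaptive substitutions
  in such experiments tend to be), realized by direct codon enumeration
  — an independent path from the classifier under test.
* **Fitness** — the benefit of adaptation is
  $b_i = b_0 + c\,(1 - s_i)$ with $b_0 = 0.05$, $c = 0.5$, so benefits
  rise with stress and a negative stress–adaptation correlation is
  built into the truth; growth curves are logistic (carrying capacity
  1.0, initial density 0.005, progenitor base-medium rate 0.007/min ≈ a
  99-min doubling time) sampled every 10 min for 24 h with 1%
  multiplicative lognormal noise.
* **Contamination** — optional donor→recipient copying of a fraction of
  records between same-plate, different-row samples, off by default.

Everything is a pure function of (config, seed), and a JSON truth
ledger records planted genes, every record's true category, true growth
rates and injected contamination, so each pipeline stage can be checked
against ground truth by re-parsing the emitted files.

What the generator does **not** emulate: linkage and clonal
interference (planted hits are independent across replicates; a
clonal-sharing pattern can be approximated with the contamination
machinery but is not modeled), mutation-spectrum bias in background
substitutions (placement is uniform, so spectrum-based expectations are
exercised on the real enumeration but not stressed by biased data),
aneuploidy and structural variation, multi-exon genes, and
context-dependent mutation rates. Passing tests therefore demonstrate
the statistical machinery's correctness and calibration under its own
null, not robustness to every artifact of real sequencing data.

## Problem sizes and runtime

The test suite and the acceptance script run the scan's oracle
comparison at $10^5$ Monte-Carlo repeats on 20-unit toys, the type-I
study on 1000 null environments (exact mode), parameter recovery on the
default 200-gene × 20-environment experiment at $10^5$ repeats, the
growth-rate recovery study on 200 noisy curves, and the replicate-split
study on 200 environments — sizes chosen so each study's sampling error
is small against the margins being asserted while the whole suite
completes in a couple of minutes.

## Known limitations

* The scan treats unit lengths as the only determinant of the neutral
  hit probability; regional mutation-rate variation would miscalibrate
  it equally in real data and in the randomization, so it cancels only
  if the study design pools many loci.
* Exact mode and Monte-Carlo mode share the independence assumption;
  neither models within-replicate linkage of substitutions.
* The indel neutral expectation is a user-supplied constant.
* `F_i/F_SC` standard errors from two replicates (under the split) are
  necessarily crude.
* The Dice random expectation conditions on observed set sizes; it is
  not a full null distribution, only its mean.
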