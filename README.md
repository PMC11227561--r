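# adaptoscan

Downstream analysis of microbial experimental-evolution studies, for
researchers who evolve replicate populations across many environments,
resequence the evolved clones, and ask which genes drove adaptation and
how repeatable that adaptation is.

## What it computes

**Putatively adaptive genes and noncoding regions.** After replicate
populations evolve in an environment, a gene hit by substitutions in
several replicates is a candidate target of selection — but long genes
collect more hits by chance. `adaptoscan` tests each gene (or merged
noncoding unit) against a length-proportional randomization null: each
sample's observed substitution count is re-placed across units with
probability proportional to unit length, samples are pooled, and the
empirical p-value of a unit with `k` observed hits is the fraction of
randomizations reaching `k` or more. Because placements are independent,
the pooled hit count of a unit covering a length fraction `p` of its
compartment is Binomial(`n`, `p`) for `n` pooled substitutions, so an
exact tail `P(X >= k)` is available as an analytic oracle
(`exact_unit_pvalue()`); both modes Bonferroni-correct over the number
of units and flag adjusted `p < 0.05`.

**Neutral substitution-class expectations.** From a six-class
strand-symmetric mutation spectrum (rates for A:T→G:C, A:T→C:G, A:T→T:A,
C:G→A:T, C:G→G:C, C:G→T:A) and a coding sequence set, the package
enumerates all three possible changes at every coding site, weights them
by class rate, and returns expected synonymous / nonsynonymous /
nonsense proportions; observed counts are tested against expected ratios
with a log-space chi-squared (`neutral_ratio_test()`), which stays
accurate for p-values as small as 1e-300. The neutral coding:noncoding
substitution ratio equals the coding:noncoding site ratio of the genome.

**Fitness from growth curves.** Maximum growth rate is the mean of the
3rd–8th highest slopes of ln(cell density) over 7-point windows spaced
60 min apart; relative fitness is `2^(R/R_ref − 1)`. Environment-level
summaries give the stress level `F_i/F_SC` (progenitor fitness in the
environment relative to the base medium) and the extent of adaptation
`f_i/F_i`, with an optional replicate split that keeps the measurement
error of the progenitor rate out of both quantities at once (otherwise
the shared error induces a spurious negative correlation between them).

**Repeatability.** Dice's coefficient `2|X∩Y|/(|X|+|Y|)` of
adaptive-gene sets within and between environments, with the exact
random expectation `2·m1·m2/(G·(m1+m2))` or its Monte-Carlo counterpart;
per-gene overall contributions (the 1/n rule, with cumulative curves);
plate-layout cross-contamination diagnostics; partial Spearman
correlations; sign tests; and a linear early-gain extrapolation.

**Synthetic data.** A generator emits complete datasets — toy genome
(FASTA + GFF3), per-sample VCFs with planted adaptive genes, a plate
manifest, logistic growth curves — together with a JSON truth ledger, so
the whole pipeline is testable without any external data.

## Worked example

```r
library(adaptoscan)

cfg <- sim_config()                      # 200 genes, 20 environments x 12 replicates
dir <- tempfile(); dir.create(dir)
fix <- end_to_end_fixture(cfg, seed = 1, out_dir = dir)

out <- run_scan_pipeline(fix$paths$fasta, fix$paths$gff3,
                         fix$paths$vcfs, fix$paths$manifest,
                         compartment = "coding",
                         config = scan_config(mode = "exact"))
out$model
#> genome_model: 2 chromosome(s), 123104 bp; 200 coding unit(s); 305 merged noncoding unit(s)
site_counts(out$model)
#> site counts: coding 89652 | noncoding 33452 | coding:noncoding ratio 2.68
head(out$scan[out$scan$adaptive, c("environment_id", "unit_id",
                                   "observed_hits", "p_raw", "p_adjusted")])
#> # A tibble: 6 × 5
#>   environment_id unit_id observed_hits    p_raw p_adjusted
#>   <chr>          <chr>           <int>    <dbl>      <dbl>
#> 1 env001         gene055             7 5.81e-11   1.16e- 8
#> 2 env001         gene115             7 5.08e-11   1.02e- 8
#> 3 env002         gene063             5 1.14e- 7   2.28e- 5
#> 4 env002         gene136             7 3.60e-10   7.20e- 8
#> 5 env003         gene033             7 9.07e-10   1.81e- 7
#> 6 env003         gene054             9 7.36e-13   1.47e-10
```

Each row is a unit called putatively adaptive in that environment:
`observed_hits` pools the 12 replicates, `p_raw` is the binomial tail of
that count under length-proportional placement, and `p_adjusted`
multiplies by the 200 genes tested. Checking calls against the
generator's truth ledger:

```r
sets <- adaptive_sets(out$scan)
planted <- setNames(fix$sim$environments$planted_genes,
                    fix$sim$environments$environment_id)
mean(mapply(function(e) mean(planted[[e]] %in% sets[[e]]), names(planted)))
#> [1] 0.95
```

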