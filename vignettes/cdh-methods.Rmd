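---
title: "The collapsed double heterozygosity test: model, power theory and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The collapsed double heterozygosity test: model, power theory and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdhtest)
```

## The problem and the model

Many genes harbor several loss-of-function (LOF) alleles, each at low
frequency (roughly 1--5%) and each largely recessive on its own.  An
individual carrying two *different* LOF alleles of the same gene, one per
homologous chromosome, is a compound heterozygote (CH) and is phenotypically
equivalent to a homozygote.  Because two distinct rare alleles combine in
many more ways than one allele pairs with itself, the CH genotype class is
systematically larger than either homozygote class: under independent
Hardy--Weinberg equilibrium with equal minor allele frequencies $q_1 = q_2$,

$$\frac{P(AaBb)}{P(AAbb)} = \frac{4 q_1 q_2 (1-q_1)(1-q_2)}{q_1^2 (1-q_2)^2} = 4 ,$$

which `ch_to_homozygote_ratio()` evaluates for any frequency pair.  Single-SNP
tests see only the homozygote signal; pooling the CH carriers with the
homozygotes quadruples the informative group and is the source of the power
gain this package is built around.

The **CDH test** (`cdh_test()`) cross-tabulates two SNPs by case/control
status into 3×3 count matrices $D$ (cases) and $U$ (controls), collapses the
risk genotypes into one column, and tests the resulting 2×2 table on 1 df.
Two collapse modes exist, and the distinction matters:

* **causal** — for directly observed causal variants: risk cells are all
  genotypes carrying a homozygote or CH configuration (dosage pairs 2/0,
  0/2, 1/1, 2/1, 1/2, 2/2).  The last three are near-empty at low
  frequencies because the causal alleles reside on different haplotypes.
* **tagging** — for markers in LD with unobserved causal alleles: the
  double-minor tag genotypes (2/1, 1/2, 2/2) join the *reference* group.
  The C--D tag haplotype carries no causal allele, so individuals
  homozygous for one tag and carrying the other cannot be CH carriers of
  the causal alleles; pooling them with the risk group would dilute it.
  Only the 2/0, 0/2 and 1/1 cells remain in the risk column.

In practice the tagging form can be used for causal variants too, since the
extra cells are negligible there; `power_table()` and the examples in the
test suite confirm the two modes agree within Monte Carlo noise for rare,
weakly linked pairs.

### Penetrance model

A binary phenotype has baseline prevalence $\alpha$ and the risk genotypes
have prevalence $\alpha\beta$, with $\beta$ the genotype relative risk (GRR)
and the constraint $\alpha\beta \le 1$.  The design is population-based: the
number of cases is random given $\alpha$, so the total sample size $n$ must
be large enough to contain a workable number of cases (10,000 samples yield
about 500 cases at $\alpha = 0.05$).

## Expected-count power theory

For two independent HWE SNPs the 3×3 genotype frequency matrix is
$R = h(q_1) h(q_2)^\top$ with $h(q) = ((1-q)^2,\, 2q(1-q),\, q^2)$.  With
penetrance matrix $F$ ($\alpha\beta$ on risk cells, $\alpha$ elsewhere), the
expected counts are $D = n\,(R \circ F)$ in cases and
$U = n\,(R \circ (1-F))$ in controls.  Collapsing the expected tables and
applying the Pearson formula to the *real-valued* expected 2×2 (no rounding
— the derivation is continuous) gives an expected chi-square, and its
upper-tail probability at 1 df is the "expected P" (`expected_cdh_p()`).
The single-SNP comparator marginalizes $D$ and $U$ over the partner SNP to a
2×3 table tested at 2 df (`expected_single_snp_p()`).  These expected P
values are noncentrality-style summaries, not finite-sample power integrals;
a Monte Carlo cross-check in the test suite verifies that the expected
$-\log_{10} P$ sits inside the central spread of simulated P values.

Two reference points from this theory:

```{r theory}
expected_cdh_p(0.045, 0.045, alpha = 0.05, beta = 4, n = 10000)
grr_threshold(q = 0.05, alpha = 0.05, n = 10000, target_p = 5e-8,
              test = "single")
```

At $q = 0.045$, GRR 4 and $n = 10{,}000$ the CDH test is expected to be
genome-wide significant ($P < 5\times10^{-8}$), while the single-SNP 2-df
test first reaches that threshold near GRR 5.6 even at $q = 0.05$.  The
bisection in `grr_threshold()` runs over GRR in $[1, \min(50, 1/\alpha)]$
(the penetrance bound caps the usable bracket) to a tolerance of $10^{-3}$.
Under models where the double heterozygote has *no* effect (two independent
recessive SNPs, or a single-SNP effect) the ordering reverses and single-SNP
analysis wins; the CDH test is a targeted instrument, not an omnibus one.

## Test-statistic conventions

* No Yates continuity correction anywhere: the theory and the simulations
  use the plain Pearson statistic.
* Missing data are handled pairwise complete-case per test, and every
  result carries the usable sample count.
* Genotypes are oriented to the minor allele; a frequency of exactly 0.5
  keeps the input orientation.
* Rows/columns with zero marginal are dropped before computing df; if
  fewer than two non-empty rows or columns remain the input is degenerate
  and an error is raised rather than a silent $p = 1$.  The one deliberate
  exception: a CDH collapse with an entirely empty risk column returns
  $p = 1$ flagged `"no-risk-genotypes"`, because a scan must be able to
  step over such pairs.
* `exact_threshold` (default 5) is the minimum-expected-cell rule: below
  it, the 2×2 chi-square is replaced by the two-sided Fisher exact test.
  The threshold is configurable; 0 disables the switch.  The Monte Carlo
  harness `power_table()` runs with the switch disabled, because the
  theory being checked there is the plain 1-df chi-square; the scan layer
  keeps the switch on, where small collapsed cells are routine.

## Simulation designs

### Causal pairs (`power_table()`)

Each replicate draws $q_1, q_2$ from the MAF sampler (default uniform on
$[0.01, 0.05]$), simulates independent Binomial(2, $q$) dosages for $n$
individuals (default 10,213), assigns the phenotype under the penetrance
model, and records the causal-mode CDH P value and the per-SNP
Cochran-Armitage trend P values against the thresholds 0.05, $5\times10^{-8}$
and $5\times10^{-11}$.  Replicates use seeds derived from one base seed, so
runs are reproducible.  The acceptance script uses 2,000 replicates per GRR;
the analytic grid shows the expected values change smoothly, so this
resolution (Monte Carlo SE about 0.5 percentage points near 5%) is adequate
to check calibration and gross power ordering.

What the uniform MAF sampler does *not* emulate: a genotyping chip's
within-band MAF density, inter-pair LD mixture (on a real 550K chip, about
56% of close rare pairs have $r^2 < 0.01$ but 18% have $r^2 > 0.9$), and
empirical departures from HWE.  Type-I error and the permissive-threshold
powers are insensitive to this, but tail powers at $5\times10^{-8}$ are
band-shape sensitive: uniform MAFs put more mass near the top of the 1--5%
band than a chip does, which inflates tail power by roughly ten percentage
points at GRR 5 relative to chip-based reports.  Passing these simulations
therefore validates calibration and ordering, not chip-exact power values.

### Tagging quartets (`simulate_linked_quartet()`)

Each causal/tag locus pair is generated from a two-locus haplotype model
with positive disequilibrium $D = \sqrt{r^2\, q_c(1-q_c)\, q_t(1-q_t)}$, so
the causal allele rides on tag haplotypes.  The attainable $r^2$ is capped
at $q_c(1-q_t)\,/\,((1-q_c)\,q_t)$ for $q_c < q_t$; requesting more is a
feasibility error reporting the maximum.  The two causal/tag pairs are
mutually independent.

### Regions (`simulate_region()`, `region_benchmark()`)

The regional generator emulates a 200-kb chip region with intra-region LD:

* 70 SNPs per region, 20 founder haplotypes with Dirichlet(1) population
  weights; every chromosome copies one founder with a per-site copy error
  of 0.002 (breaks perfect founder LD, adding a touch of recurrent
  mutation/genotyping noise).
* 60% of sites target the 1--5% band and are placed on a single random
  founder — their realized frequency is that founder's weight, and they
  are in LD with everything else that founder carries, including the
  occasional pair of rare variants sharing a founder (mimicking the
  minority of rare chip pairs in high LD).  Common sites accumulate
  founders until the target frequency is reached.
* Causal flags go to `portion_causal` (default 8%) of the *realized*
  MAF<0.05 sites, with a floor of two so the CH state exists.
* Exposure follows the recessive-set model: homozygous at any causal site,
  or heterozygous at two or more distinct causal sites.  The default is
  genotype-level (phase not checked), matching what a genotype-based test
  can see; `phase_aware = TRUE` restricts CH exposure to true trans
  carriers.

The CDH-vs-WSS benchmark masks the causal variants, runs the all-pairs CDH
scan (Bonferroni $m(m-1)/2$) and the WSS over the remaining MAF<0.05
variants, and scores power as the fraction of regions at or below
$5\times10^{-8}$.  300 regions of 10,000 individuals run in about a minute.
Because regional LD here is synthetic, the absolute powers are indicative
(they land in the right neighborhood of chip-based values, CDH several-fold
above WSS); the robust finding, reproduced in every seeded run, is the
ordering — pairwise collapsing retains power where the burden statistic is
diluted by the non-causal majority.

## WSS comparator

`wss_test()` implements the weighted sum statistic with the original
conventions: unaffected-group allele frequency with pseudocounts
$(m_U + 1)/(2 n_U + 2)$, weight $\sqrt{n\,q(1-q)}$, allelic (minor-allele
count) coding, midranks for ties, and a one-sided upper-tail normal P from
the rank sum standardized by $k$ phenotype permutations ($k = 1000$ by
default, sample SD with $k - 1$ denominator).  Genotypic/recessive coding
variants are not implemented; the comparison deliberately uses the
comparator's canonical form.

## Haplotype EM and the CH-vs-DH follow-up

`em_two_locus()` estimates the four two-locus haplotype frequencies by EM;
only the double-heterozygote class is ambiguous, split each E-step between
its cis (11/00) and trans (10/01) resolutions.  Convergence is declared
when the largest frequency change drops below $10^{-8}$ (cap 1000
iterations; non-convergence is an error reporting the last iterate).
Monomorphic inputs return the degenerate closed form with $r^2 = 0$ by
convention.  `ld_stats()` derives $r^2$ and $D'$; low $r^2$ between two
rare alleles is the empirical signature that they reside on different
haplotypes ($D'$ is uninformative for that purpose).

After a significant CDH result one can ask whether the signal really comes
from compound heterozygotes rather than cis double heterozygotes.
`ch_vs_dh_test()` contrasts case/control frequencies between trans and cis
carriers among the double heterozygotes.  A genuine limitation of the
two-SNP reduction: with genotypes alone, every double heterozygote has the
same cis/trans posterior, so a hard maximum-posterior assignment puts all
of them in one class and the contrast is undefined — the function then
errors with an explanation.  The practically useful path is the `phase`
argument, fed from phased data, simulation truth, or diplotypes inferred
with flanking markers; with phase supplied the test detects trans-specific
effects and stays null when cis and trans carry equal risk (both properties
are exercised in the test suite).

## Scanner bookkeeping

`sliding_window_scan()` pairs every SNP with the following `window_n` SNPs
(default 100, a safe window for 500--600K chips) on the same chromosome;
windows truncate at chromosome ends and never span chromosomes.  The
minimal P of each window is assigned to the window's first SNP and
Bonferroni-corrected by the number of tests *actually performed* in that
window, so the correction shrinks with truncated windows.  The exact total
over a chromosome of $N$ SNPs is

$$N\,w - \frac{w(w+1)}{2} \quad (N > w),$$

returned by `scan_test_count()` and verified by enumeration in the tests.
(The genome-scale shorthand $Nw - w(w-1)/2$ overcounts this by exactly $w$
per chromosome — harmless at $N \sim 5\times10^5$, and conservative if used
as a Bonferroni factor.)  Monomorphic SNPs are excluded from both the
tests and the correction factors, with a logged count.  The all-pairs
regional scan computes every pair's collapsed table from nine case and
nine control indicator cross-products, then re-tests exactly the pairs that
fail the expected-count rule; the per-pair loop and the vectorized path are
asserted equal in the tests.

## Known limitations

* Covariates, quantitative traits and imputed (non-integer) dosages are
  out of scope; the machinery is contingency-table based.
* The expected-P theory assumes independent HWE causal SNPs; for linked
  causal pairs only the simulation path applies.
* The founder-pool region model produces block-like LD, not
  coalescent-realistic LD; results on it demonstrate relative, not
  absolute, performance.
* CDH is strictly pairwise; regions with more than two LOF alleles are
  handled by iterating over pairs, which is the scan's job.
* The approach needs causal (or tagged) alleles at appreciable frequency
  (above roughly 1%); it is not a rare-variant burden method.
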