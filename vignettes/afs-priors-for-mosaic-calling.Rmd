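---
title: "AFS priors and the detection of low-level mosaic variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AFS priors and the detection of low-level mosaic variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicall)
```

## The problem

A postzygotic (somatic mosaic) point mutation is present in only a
fraction of an individual's cells, so at a heterozygous mosaic site the
variant allele may account for far less than the 50% of reads expected
for a constitutional heterozygote — 10% or less is common in the
megalencephaly syndromes (PIK3CA/PIK3R2/AKT3) that motivate this
package.  A Bayesian SNP caller combines per-genotype likelihoods with a
prior over the number of alternate alleles in the sample, the allele
frequency spectrum (AFS), and reports a site as variant when

$$P(\mathrm{ref}\mid D, F) \;=\;
  \frac{\phi_0 L(0)}{\sum_{k=0}^{M}\phi_k L(k)} \;<\; p ,$$

where $D$ is the pileup of reads, $F = (\phi_0,\dots,\phi_M)$ the AFS
over $k$ alternate alleles among $M$ chromosomes, $L(k)$ the likelihood
of the data given $k$, and $p$ the calling threshold (0.5 by default).
The default neutral Wright–Fisher spectrum,
$\phi_k = \theta/k$, $\phi_0 = 1-\theta H_M$ with $\theta = 0.001$,
puts prior odds of about 1000:1 on the non-variant state.  Moderate
heterozygous evidence — exactly the signature of a mosaic variant — is
swamped by that prior.  This package exists to quantify and exploit the
alternative: a flat (uniform) initial AFS, which removes the prior
penalty and maximizes sensitivity to low-level variants, with `cond2`
(the spectrum induced by the allele-frequency density $2(1-f)$) in
between.

The Phred-scaled quality reported for a call is
$\mathrm{QUAL} = -10\log_{10} P(\mathrm{ref}\mid D,F)$, i.e. the
confidence that the site is variant, including the prior.

## The likelihood model

Each read contributes through its effective error probability
$e = 10^{-\min(\mathrm{BQ},\,\mathrm{MQ},\,63)/10}$, clamped at 0.75.
Under homozygous genotypes a matching read contributes $1-e$ and any
mismatching read $e/3$; under the heterozygote a read carrying either
allele contributes exactly $1/2$ (either chromosome was sequenced with
equal probability) and a third allele $e/3$.  So a pileup of BQ30/MQ60
reads has $L(1) = 0.5^{\mathrm{depth}}$ exactly — a property the test
suite asserts to $10^{-12}$.

**Correlated errors.** Sequencing errors at a site are not independent:
the same local context that produced one spurious mismatch tends to
produce more.  Treating stacked mismatches as independent makes a pile
of four identical errors look like $(e/3)^4 \approx 10^{-14}$ —
essentially impossible — and the caller becomes overconfident.  In the
package's `correlated` mode (the default), the reads that *contradict*
each genotype hypothesis are sorted by descending quality and the
$i$-th such read (0-based) is down-weighted to effective quality
$q\,\eta^i$ before conversion to $e$.  Reads consistent with the
hypothesis keep their full quality, and $\eta = 1$ recovers the
independent model exactly.  This geometric decay is a deliberate
simplification of the per-quality-bin error-dependency recursion used
by classic pileup callers; it reproduces the qualitative behaviour
(diminishing evidence per additional mismatch) with a single tunable
parameter.

**Calibration of $\eta$.**  The decay rate is the one genuinely free
parameter of the package.  It was calibrated once against the
sensitivity sweep of the deterministic read simulator (below): with
$\eta = 0.89$ the mean minimum detectable mutant-allele percentage over
depths 4–100 is 12.8% for the flat prior and 17.1% for the default
full prior, and the same setting reproduces a Phred-scaled
likelihood-triple entry of $PL(0/0) = 12$ for a pileup of 32 reference
+ 4 alternate BQ30/MQ60 reads, the worked mosaic example the package's
tests pin down.  The value is frozen in `error_model()`'s default and
is not adjusted per dataset.  Note the direction of the effect: the
decay *inflates* the error probabilities of stacked mismatches, which
*raises* $L(0)$ for a mosaic pileup and therefore makes the caller more
conservative than independent errors would — the calibrated sweep means
sit above the independent-model ones (10.4% / 13.4%).

**BAQ.**  Base alignment quality matters only near indels; every input
this package simulates or fixtures is a gapless 100M alignment, so the
`baq_adjust()` hook is an identity by default and simply accepts
externally computed BAQ-capped qualities when they exist.

**Triallelic sites** keep the non-reference allele with the largest
base-quality sum; other alleles are treated as errors, matching
biallelic VCF output.

## Multi-sample calling

For $n$ samples the joint likelihood of $k$ alternate alleles among
$2n$ chromosomes is

$$P(D\mid k) = \binom{2n}{k}^{-1}
  \sum_{\substack{g_1+\dots+g_n=k}} \prod_i \binom{2}{g_i} L_i(g_i),$$

computed by sequential polynomial convolution over samples (never by
enumeration; the test suite checks the identity against brute force up
to $n = 4$).  Per-sample genotypes maximize
$L_i(g)\,w_g(\hat f)$ at the posterior mean allele frequency
$\hat f = E[k\mid D]/2n$ with Hardy–Weinberg weights $w$.  Joint
calling rescues a low-fraction variant *only* when some other sample
carries it at high fraction — with three simulated samples at
(36 reads, 4 alt), (36, 4), (27, 0) the site is not called, while
(36, 15), (36, 4), (27, 0) is called and the 11% sample is genotyped
heterozygous.

## EM refinement of the spectrum

`em_refine()` iterates
$\phi_k^{(t+1)} = \tfrac1S \sum_s P(k\mid D_s, \phi^{(t)})$ until
$\max_k|\Delta\phi_k| <$ `tol` (default $10^{-6}$, at most 100
iterations; non-convergence is a warning, not an error).  Each step is
an exact EM iteration for the mixture over $k$, so the observed-data
log-likelihood never decreases — a property test.  Because the
iteration can stop in a local optimum, the *initial* spectrum matters,
which is precisely why the flat initialization changes calls.  Per-site
calling uses the prior vector directly; refinement is an explicit,
optional step, which is the operative path when sites are evaluated
one at a time.

## The simulator and what it does (not) emulate

`simulate_site_reads()` builds the evaluation data: 100 bp paired-end
reads over a single site, all mapped perfectly (CIGAR `100M`, MAPQ 60),
uniform base quality Phred 30, the alternate mismatch exactly
mid-read (MD `50G49`; reference reads `MD:Z:100`), strands alternating
within each read class starting on "+" (an odd class leaves the extra
read on "+"), and proper-paired mates placed one insert size (300 bp)
away so they never cover the site.  Mutant fractions are realized as
integer alternate-read counts $0..\lfloor d/2\rfloor$ per depth $d$
— the spikes in the resulting power curves occur exactly where one more
alternate read becomes necessary.  The simulator is a pure function:
no seed, identical output always.

It deliberately omits sequencing-error injection, indels, GC and
coverage bias, and fragment-length variation.  Sensitivity numbers
derived from it are therefore *best-case* detection limits of the
caller configurations, not of a sequencing pipeline; passing the sweep
tests says nothing about alignment artifacts in real exomes, which is
what the hard-filter tiers are for.

## The sensitivity sweep

`sweep_sensitivity()` scans, for every depth 4..100 and each of seven
configurations (default, flat, cond2, $\theta$ = 0.01 and 0.1,
$p$ = 0.75 and 1.0), the smallest alternate-read count the caller
detects, and summarizes mean/min/max of the corresponding percentage.
The depth grid is every integer in 4..100 (97 points; the experiment's
range with unit step).  Configurations are compared with the two-sided
Wilcoxon signed-rank test on the paired per-depth minima (exact
distribution for ≤25 tie-free differences, otherwise the
continuity-corrected normal approximation; zero differences dropped,
ties mid-ranked).  Under the calibrated model the flat prior detects
at 1/4 reads (25%) at depth 4 where the default needs 2/4 (50%), is
never worse at any depth, and the paired comparison over 97 depths
yields $p < 10^{-10}$.  The whole seven-configuration sweep is
deterministic and runs in a few seconds.

```{r sweep, eval = FALSE}
sw <- sweep_sensitivity()          # 7 configs x depths 4:100
sw$summary[, c("config_id", "mean_pct", "min_pct", "max_pct")]
```

## Hard filtering

After calling, records pass through two tiers.  Tier 1 (moderate):
QUAL ≥ 10 (90% call accuracy), depth ≥ 4, ≥ 2 alternate reads,
strand-bias $p \ge 10^{-4}$ (two-sided Fisher exact on the DP4 table),
base-quality bias $p \ge 10^{-100}$ and tail-distance bias
$p \ge 10^{-4}$ (Welch t-tests between reference- and
alternate-supporting reads), HWE $p \ge 10^{-4}$ (1-df chi-square),
and exclusion of sites within or adjacent to (±1 bp) homopolymers ≥
5 bp or user-supplied BED repeat intervals.  Tier 2 (stringent): ≥ 3
alternate reads, ≥ 1 on each strand, all four bias p-values ≥ 0.01,
and exclusion of genes on a user-supplied flagged list (genes
notorious for spurious calls; an example ships in
`inst/extdata/flagged_genes_example.txt`).  The tiers are evaluated
independently.  "Tail distance" is the distance from the nearer read
end — the statistic is not standardized across tools, and this choice
is symmetric in read orientation.  Bias p-values of degenerate groups
(fewer than 2 reads, or zero variance with equal means) are defined
as 1; zero variance with *unequal* means is maximal bias, p = 0.

Cross-sample prioritization (`recurrent_genes()`) counts, per gene,
the distinct samples with at least one passing *novel* variant —
novelty is consumed as a precomputed flag, since database annotation
is out of scope.

## Numerical choices and degenerate inputs

* All posterior arithmetic is in log10 space with max-subtraction;
  posteriors are renormalized before output.
* PL values round half away from zero and floor at 0; genotype
  argmax ties break toward the reference.
* An empty pileup yields log-likelihoods (0,0,0), so the posterior is
  the prior itself and no variant is called under any proper prior.
* At threshold $p = 1$ every site is emitted, by contract, even when
  $P(\mathrm{ref}\mid D,F)$ rounds to exactly 1.0 in double precision
  (which happens at high depth with a single alternate read).
* GQ is $\min(99,\ \mathrm{round}(-10\log_{10}(1 - \max_k
  \text{posterior}_k)))$.  Genotype-quality conventions differ between
  callers and printed historical values are not exactly recoverable;
  GQ here is informative, not a compatibility surface.
* `full` priors require $\theta < 1/H_M$; larger values would make
  $\phi_0$ negative and are rejected.

## Known limitations

* SNVs only: no indel likelihoods, no haploid/sex-chromosome handling,
  no phasing.
* SAM support is text-only and limited to the CIGAR ops M/=/X/I/D/N/S/H;
  reads whose op at the queried site is not an alignment match are
  skipped with a warning.
* The correlated-error decay is a single-parameter approximation; its
  calibration transfers to real data only to the extent that real
  error stacks resemble the simulated ones.
* The VCF reader/writer handles exactly the fields this package emits
  (DP, DP4, PV4, GENE, NOVEL, GT:PL:GQ); it is not a general-purpose
  VCF parser.
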