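---
title: "Simulating case-control SNP data with high-order epistasis models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating case-control SNP data with high-order epistasis models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistasim)
```

## Why simulate

Methods that search genome-wide SNP data for epistatic interactions can only
be benchmarked on data where the interacting loci are known, which real
case-control cohorts never provide. `epistasim` produces such benchmarks in
two coupled steps: it constructs a *penetrance table* for a K-locus disease
model calibrated to a population target (prevalence or heritability), and it
generates genotype matrices whose allele-frequency spectrum — and, locally,
whose linkage disequilibrium (LD) — are inherited from a real or synthetic
sampling pool rather than invented.

## The disease model

A K-order epistasis model assigns a penetrance $P(D \mid g_i)$ to each of the
$3^K$ combination genotypes $g_i$. We support models *with marginal effects*
(eME models), whose cells are arithmetic expressions in two scalars: the
baseline penetrance $\alpha$ (risk of the all-common-homozygote reference)
and the relative penetrance $f$ (the factor through which minor alleles raise
risk). Three canonical families are built in, parameterised by the total
minor-allele dosage $s$ of a cell:

* additive: $\alpha\,(1 + f s)$
* multiplicative: $\alpha f^{s}$
* threshold: $\alpha$ if any locus is homozygous common, else $\alpha f$

Arbitrary models are read from a CSV of `genotype,expression` rows; cell
expressions are evaluated by a restricted interpreter (numbers, `x`, `y`,
`+ - * / ^`, parentheses) so that model files can never execute code.

Under Hardy-Weinberg equilibrium a locus with minor-allele frequency $m_k$
has genotype frequencies $\left((1-m_k)^2,\; 2m_k(1-m_k),\; m_k^2\right)$,
and under linkage equilibrium across the K model loci the combination
genotype frequency $P(g_i)$ is the product over loci. The two population
summaries are

$$P(D) = \sum_{i=1}^{3^K} P(D \mid g_i)\, P(g_i), \qquad
h^2 = \frac{\sum_i \left(P(D \mid g_i) - P(D)\right)^2 P(g_i)}
           {P(D)\,(1 - P(D))}.$$

### Solving for f

The user supplies $\alpha$, the locus MAFs and *one* target — $P(D)$ or
$h^2$ — and the package solves for $f$:

* **Prevalence.** $P(D)$ is non-decreasing in $f$ for any model whose cells
  are non-decreasing in `y` (all canonical families are). The root is
  bracketed by doubling an upper bound from 2 (capped at $2^{40}$) and
  refined by bisection to $10^{-12}$ relative on $f$ and $10^{-10}$ on the
  objective. Monotonicity is screened on a coarse grid first; a non-monotone
  user model yields the smallest root plus a warning.
* **Heritability.** $h^2$ is zero at the constant table and grows on the
  risk-increasing side, but it is *not* monotone through $f = 1$: for
  multiplicative-like models a protective root $f < 1$ with the same $h^2$
  usually exists. We adopt the risk-increasing convention: a multiplicative
  grid scan (factor 1.05 per step) starts at $f = 1$ and brackets the
  smallest root $\ge 1$, which is then bisected. This is what makes the
  forward–inverse round trip identity hold for simulated effect sizes
  $f > 1$; protective models can still be specified directly via a model
  file. (Note the additive family is constant at $f = 0$, not $f = 1$; its
  $h^2$ is nevertheless increasing on $f \ge 1$, so the same scan applies.)

Degenerate requests ($\alpha \in \{0,1\}$ for solving, targets at 0 or 1)
are rejected rather than producing constant or unreachable tables.

### Keeping penetrances in [0, 1]

Large $f$ can push cells above 1. The finalized table is then rescaled by
$S(p) = p / (1 + M)$ with $M$ the maximum cell — a monotone map into
$[0, 1)$ that preserves cell ordering. Published tables from tools of this
kind sometimes show a maximum cell of exactly 1, which $1 + M$ cannot
produce; because the correct denominator is ambiguous in the literature,
`normalize_mode = "max"` (divide by $M$) is available as an explicit switch,
with `"one_plus_max"` the default. Rescaling changes the achieved
$P(D)$ and $h^2$ relative to the requested target; rather than hiding the
drift, both achieved values are recomputed from the final table and written
into the output model file next to the request.

## Generating genotypes: fragment resampling

The sampling pool is the control subset of a labeled genotype matrix
(codes 1/2/3 for AA/Aa/aa), restricted to a random column subset of the
requested width. One simulated sample is built by cutting the columns into
contiguous fragments whose lengths are uniform on `[len_min, len_max]`
(defaults 10–30 SNPs) and copying each fragment wholesale from one
uniformly drawn donor row. Column-wise, every simulated genotype is an
unbiased draw from the pool column's empirical distribution — this is what
preserves the pool's MAF spectrum — while correlations between columns that
fall inside one fragment are inherited from the donor, preserving local LD
at the fragment scale.

Two points were genuinely open and decided here:

* **Breakpoints are redrawn per simulated sample** (better donor mixing and
  no artificial recombination cold-spots shared by all samples);
  `shared_plan = TRUE` restores the one-plan-for-all reading.
* **Donors are drawn with replacement** across fragments and samples, so a
  small pool can serve arbitrarily many simulated samples.

The K model loci are chosen from the pool by MAF matching: candidates lie
within a window of each target MAF that starts at 0.01 and widens by 0.01
until every target can claim a distinct column; ties are broken uniformly at
random. The *actual* pool MAFs of the selected columns — not the requested
targets — feed the genotype-frequency calculations, so the table is
calibrated to the data it will be embedded in.

## Labels

Each sample's label is a single Bernoulli draw with probability equal to the
penetrance at its combination genotype; the baseline $\alpha$ already
encodes the risk of unaffected configurations, so no separate background
rate exists. Balanced output rejection-samples candidates until the case and
control quotas are exactly met (capped at $1000 \times$ the requested total,
after which a quota error recommends changing parameters — this is what an
all-but-impossible group, e.g. cases under a near-zero table, produces).
Unbalanced output labels exactly `n_total` rows once and keeps the natural
proportions. Replicate r of a multi-dataset run is seeded with
`seed + r`, so any single replicate is reproducible without regenerating
its predecessors.

## The synthetic pool

Real sampling matrices (e.g. consortium case-control data) are
access-restricted, so the `fixtures` generator builds pools with known
structure: per-SNP true MAFs drawn uniformly from a range (default
0.05–0.5) or given explicitly, genotypes sampled from Hardy-Weinberg
proportions, and optional *block LD* — columns of a block share one true MAF
and copy a per-sample latent genotype with probability `block_cor`
(1 = identical columns, 0 = independence). Labels are assigned independently
of genotype, a null background. The block-copy construction was chosen over
a Markov chain because its implied correlation is exact and directly
assertable in tests.

What the generator does **not** emulate: realistic LD decay with distance,
recombination hotspots, population stratification, genotyping error and
missingness, and allele-frequency spectra skewed toward rare variants. A
green test on synthetic pools therefore establishes that the machinery
(MAF preservation, model embedding, label fidelity) is correct, not that
simulated data are indistinguishable from any particular cohort; with a real
sampling matrix the same machinery inherits that cohort's properties.

## Numerical choices

* Solver tolerances: $10^{-10}$ on the objective, $10^{-12}$ relative on
  $f$; bracket cap $2^{40}$; heritability scan factor 1.05.
* Heritability is declared undefined when $P(D) \le 0$ or
  $P(D) \ge 1 - 10^{-9}$; the guard is tolerant because a constant table of
  1s reaches prevalence 1 only up to float rounding.
* MAF folding: a column whose coded allele exceeds frequency 0.5 is folded
  to $1 - $MAF and flagged, instead of erroring — real data violate coding
  conventions routinely.
* Cell order is the base-3 enumeration with the first locus most
  significant; genotype labels pair letters per locus (`AaBb`), and model
  files may list rows in any order.

## Limitations

Only models with marginal effects are supported: the inverse problem is
solved along the one-parameter family $F(\alpha, f)$, which cannot express
pure (no-marginal-effect) epistasis tables; constructing those requires a
different calibration strategy altogether. Gene-environment interaction,
quantitative phenotypes, covariates and PLINK/VCF export are out of scope.
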