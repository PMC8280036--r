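---
title: "Methods: integrative candidate-gene prioritization for neurodevelopmental disorders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative candidate-gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndprio)
```

## The analysis

ndprio implements the analysis chain of a trio-based targeted-sequencing
study of neurodevelopmental disorders (NDDs): qualifying-variant selection,
gene-level Bayesian association, candidate cataloguing, and three
orthogonal lines of functional corroboration (brain co-expression,
protein-interaction networks, and gene-constraint scores). Each stage is an
ordinary R function over plain data frames, matrices and igraph objects, so
stages can be run, tested and replaced independently; `run_pipeline()`
chains them.

## Variant filtering

A variant qualifies when it is either protein-truncating (PTV: stop-gain,
stop-loss, frameshift, splicing) or deleterious missense (Dmis: ReVe score
strictly above 0.7), and every *observed* population allele frequency
(gnomAD, ExAC, in-house) is at most 0.1%. Two conventions deserve note:

* **Missing allele frequencies pass the filter.** Rare panel variants are
  typically absent from population databases; treating absence as failure
  would discard exactly the variants the design targets.
* **The ReVe bound is exclusive** (a score of exactly 0.7 is excluded),
  and missense variants with a missing score are excluded with a warning
  rather than guessed.

Inheritance is classified from trio genotypes: de novo requires both
parents genotyped homozygous-reference; a single carrier parent gives
phased transmission; both carrying gives unphased; any missing parental
genotype gives `unknown`. In the gene-count table the *case* arm pools
inherited and inheritance-unknown qualifying variants over all probands —
parent-less probands cannot contribute de novo calls, but their qualifying
variants still carry case-control information, which is how the cohort's
1102-proband case arm relates to its 935 trios.

Inherited X-linked hemizygous variants are detected separately: chrX calls
in male probands with a heterozygous mother and non-carrier father. De novo
hemizygous calls (both parents non-carriers) belong with the de novo
counts, not here. Chromosome names are normalized to the prefix-free form;
pseudoautosomal regions are not distinguished from the rest of chrX.

## The gene-level Bayesian model

Evidence for each gene and variant class $c \in \{\mathrm{PTV},
\mathrm{Dmis}\}$ is summarized by Bayes factors in the TADA (transmission
and de novo association) framework.

**De novo arm.** With $N$ trios and per-gene mutation rate $\mu_c$, the
null de novo count is $x \sim \mathrm{Pois}(\lambda_c)$ with $\lambda_c = 2
N \mu_c$; under the alternative the rate is multiplied by a relative risk
$\gamma \sim \mathrm{Gamma}(\bar\gamma \beta, \beta)$. Integrating
$\gamma$ gives the closed form

$$\mathrm{BF}_{dn} \;=\; e^{\lambda}\,
  \frac{\beta^{\alpha}\,\Gamma(x+\alpha)}
       {\Gamma(\alpha)\,(\lambda+\beta)^{x+\alpha}},
  \qquad \alpha = \bar\gamma\beta,$$

evaluated in log space with `lgamma()`. When $\mu = 0$ the BF is 1 for
$x = 0$; a positive count at a zero rate is impossible under the null and
raises an error rather than returning infinity silently.

**Case-control arm.** Counts follow $x_{ctrl} \sim \mathrm{Pois}(N_{ctrl}
q)$ and $x_{case} \sim \mathrm{Pois}(N_{case}\, q \gamma)$ with the
qualifying-variant frequency $q \sim \mathrm{Gamma}(\rho, \nu)$; under the
null $\gamma = 1$. $q$ integrates out analytically (Gamma–Poisson
conjugacy); the remaining one-dimensional integral over $\gamma$ is
evaluated by deterministic adaptive quadrature on $(0,\ \bar\gamma +
10\sqrt{\bar\gamma/\beta})$ at absolute tolerance $10^{-10}$, with the
integrand centred on its null value to avoid underflow and the truncated
prior mass renormalized (the truncation point sits ten prior standard
deviations above the mean, so the correction is numerically negligible).

**Combination and FDR.** A gene's total Bayes factor is the product over
classes and arms (absent arms contribute 1), accumulated in log space.
With prior risk-gene fraction $\pi$, the posterior probability of
association is $\pi B/(\pi B + 1 - \pi)$. Genes are ranked by decreasing
$B$ (ties broken by gene symbol — required for reproducible q-values), and
the Bayesian q-value at rank $k$ is the running mean of $1 -
\mathrm{pp}$ over the top $k$, made monotone non-decreasing down the
ranking by cumulative maximum (the raw running mean can dip). Candidates
are genes with $q$ below the FDR threshold, 0.1 by default with a 0.05
reporting stratum.

**Hyperparameters.** The study whose design this package follows does not
publish its hyperparameters, so the defaults are magnitudes conventional in
the TADA literature — $\bar\gamma_{dn} = 20$ (PTV) and $4.7$ (Dmis) with
$\beta_{dn} = 1$; $\bar\gamma_{cc} = 2.3$, $\beta_{cc} = 4$; $\rho = 0.1$,
$\nu = 200$ (prior mean qualifying frequency $5 \times 10^{-4}$ per
person); $\pi = 0.05$ — and every one is exposed through
`tada_hyperparams()`. Because of this, the package's acceptance surface for
the reported results is the *FDR stratum partition* of the printed
candidate table, not numerical equality of individual FDR values. The
published two-stage analysis (own cohort, then cohort plus public de novo
data) is simply two calls to `tada_prioritize()` on different count tables.

## Candidate catalogue

A candidate is *known* when any rule fires: named in one of the curated
large-scale sequencing studies, recorded as an NDD gene in OMIM, or SFARI
syndromic/category-1/category-2. The rules are a literal OR; no precedence
is defined between them. Manual literature support is a curated boolean
input (`pubmed_support`), not an automated query, and also disqualifies
novelty. The candidate set is the union of TADA candidates and X-linked
hemizygous genes; a gene qualifying under several sources is reported once
with all sources recorded and the FDR stratum listed first.

## Co-expression permutation test

Pearson correlations are computed between all gene pairs over postnatal
cortical samples (prenatal and non-cortical samples are removed first; at
least three samples are required). Pairs with $|r| > 0.7$ — two-sided, so
strong negative co-expression counts — are edges. Zero-variance genes have
undefined correlations and get no edges.

Three statistics compare the novel set to the known set: novel genes with
at least one edge to a known gene, known genes reached, and total
novel–known edges. The null redraws the novel set uniformly without
replacement from the graph genes not in the known set, recomputing all
three statistics on the *same* draws; each p-value is $(b+1)/(n+1)$ with
$b$ the count of null values at or above the observed one, so p is never
exactly zero. Which set to randomize is a genuine choice; randomizing the
novel set matches the question "are *these* genes unusually connected to
the established ones?". Genes absent from the expression matrix are
dropped from the sets before testing and reported. The default $10^6$
iterations matches the publication scale; tests and the demo pipeline use
$10^3$–$10^4$.

## Functional network

PPI records are thresholded at interaction confidence (miscore) $\ge 0.45$
(inclusive), duplicates collapsed keeping the maximum score. The evidence
graph is the union of co-expression and PPI edges among candidate genes,
each edge carrying provenance (`coexpr`, `ppi`, `both`). Known genes enter
the network only when connected to at least two novel genes in the
evidence graph; novel genes enter when they have at least one evidence
edge to another novel gene or an included known gene; nodes left without
any retained edge are dropped. One consequence: a novel hub whose known
neighbors all fail the two-connection rule vanishes with them — seed genes
are reported in the network only when they are actually interconnected.
Known–known edges among included nodes are kept by default (the published
network shows dense known–known clusters); `include_known_known = FALSE`
restricts to seed-incident edges. Over-representation of network genes in
annotation sets uses the one-sided hypergeometric upper tail with a
Haldane-corrected odds ratio.

## Constraint percentiles

pLI is ranked descending and RVIS ascending, so a *low* percentile always
means a more intolerant gene; percentiles are $100 \cdot \mathrm{rank}/n$
with average ranks for ties, over whatever gene universe is supplied — the
intended universe is a genome-wide constraint table, not the candidate set.
Set comparisons use the two-sided Mann–Whitney rank-sum test: exact by
enumeration of all $\binom{m+n}{m}$ group assignments when $m + n \le 12$
(the enumeration handles ties through the value-based U statistic, which
the classical exact distribution does not), and the normal approximation
with tie and continuity correction otherwise. The top-half count judges
genes on their available metrics, so a gene with only a pLI percentile is
counted on it alone — necessary because published constraint tables
genuinely lack RVIS for some genes (e.g. SHANK3 in the shipped table).

## Synthetic data

`simulate_cohort()` draws per-gene mutation rates log-normally (median
$5 \times 10^{-6}$ per chromosome per generation for PTV, twice that for
Dmis, log-sd 0.8 — the range typical of exome-wide per-gene rate tables),
plants risk status in 5% of genes, and generates de novo counts as
$\mathrm{Pois}(2 N \mu \gamma)$ with $\gamma = 20$ (PTV) / $4.7$ (Dmis) at
risk genes, and case/control counts from the Gamma–Poisson model with
case-control relative risk 2.3. Counts are expanded to annotated variant
rows (15% of inherited rows from parent-less probands with missing
parental genotypes), and non-qualifying noise rows (low-ReVe missense,
common variants) are appended so the filters have something to reject. The
defaults — 200 genes, 500 trios, 600 cases, 1500 controls — are the
package's desk-scale study conditions and match the planted fraction to
the analysis prior $\pi$, which is what makes the Bayesian FDR calibration
testable.

`simulate_expression()` builds co-expression modules from shared latent
factors: with loading $\lambda$ and noise sd $\sigma$, the expected
within-module absolute correlation is $\lambda^2/(\lambda^2 + \sigma^2)$
(0.9 at the defaults), printed in the truth map. `simulate_ppi()` connects
within-module pairs densely with Beta(8, 2) confidence scores (mass above
0.45) and background pairs sparsely with Beta(2, 8).
`simulate_constraint()` shifts risk genes toward intolerance (pLI toward
1, RVIS toward $-2$) by a configurable effect that vanishes at 0. Every
generator takes one seed and uses a single RNG stream whose state is
restored afterwards; identical seeds give byte-identical outputs.

What the generators deliberately do **not** emulate: linkage and sequence
context, genotype quality and read depth, batch structure in expression
data, literature-curation biases in interaction databases, and the true
genome-wide scale of the public resources. Passing tests therefore
demonstrate the statistical machinery — calibration, monotonicity,
reproducibility — under the stated model, not performance on real cohort
data.

## Problem sizes and numerical choices

The test and acceptance runs use desk-scale sizes chosen as the package's
own study conditions: 20 replicate cohorts of 200 genes and 500 trios for
FDR calibration (pooled discoveries compared to binomial 95% bounds of the
nominal 0.1); 200 permutation replicates of 2,000 iterations for p-value
uniformity (Kolmogorov–Smirnov at $\alpha = 0.01$, on a graph designed
with heterogeneous known-degrees so the connection statistic is
well-spread); 10,000 iterations for the planted-module alternative; and
quadrature oracle grids of a few hundred points. All probability
arithmetic is in log space; all rankings declare their tie-breaks (gene
symbol, ascending); all graph serializations sort vertices and edges so
identical inputs give byte-identical outputs.

## Limitations

Mutation rates are consumed, never estimated; X-linked genes use the same
$2N\mu$ de novo rate as autosomes (a male-hemizygosity correction would
need per-gene sex-specific rates the inputs do not carry);
compound-heterozygous and multi-allelic sites are treated as independent
rows; and the known-gene evidence lists are inputs — the package ships
only small fixtures, not the full curated catalogue.
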