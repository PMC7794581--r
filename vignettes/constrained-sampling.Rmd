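---
title: "Constrained resampling and the biological meaning of prognostic signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained resampling and the biological meaning of prognostic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigsurr)
```

## The question the package answers

A prognostic gene-expression signature is a set of genes whose joint
expression separates patients into groups with different survival. Because
such signatures predict outcome, their gene content is routinely read as a
window onto disease biology. That inference is only defensible if the
signature's prognostic performance is *specific* to its biological content
— if gene sets with entirely different annotations could not do the same
job. `sigsurr` implements a constrained resampling framework that makes
this specificity claim testable: it samples random gene sets from pools in
which the signature's genes, and progressively all genes sharing the
signature's ontology annotations, have been deleted, and measures how often
those sets predict survival as well as the signature does. A significant
random set is a *surrogate*: prognostically indistinguishable from the
signature while (in the strictest pools) sharing none of its biological
meaning.

## The scoring pipeline

Every candidate gene set — published signature or random draw — is scored
identically:

1. **Stratification.** The expression matrix is restricted to the set's
   genes; samples are observations and genes are features. A covariance PCA
   (features centred, not scaled, via `prcomp`) gives each sample a score
   on the first principal component, and samples are split at the median
   score into groups $-1$ (at or below) and $+1$ (above). A principal
   component's algebraic sign is arbitrary, so the split is defined up to a
   label swap; the downstream test is invariant under that swap. Samples
   tied exactly at the median go to group $-1$, which makes the split
   deterministic; for continuous expression such ties have measure zero.
2. **Survival comparison.** The two groups' Kaplan–Meier curves are
   compared with the two-sample Mantel–Haenszel (log-rank) chi-square on
   one degree of freedom, with the hypergeometric variance at tied event
   times and no weighting or stratification. P-values are taken from the
   chi-square upper tail at float precision and never truncated to zero.

Both steps go through the standard tools (`stats::prcomp`,
`survival::survfit`, `survival::survdiff`); the test suite cross-checks
them against independent brute-force oracles (explicit O/E/V tables,
hand product-limit computation).

## Meaning, levels, and the removal procedures

The *biological meaning* of a gene is the set of ontology terms annotated
to it; the meaning of a gene set is the union over its genes. Annotations
are used exactly as given — they are **not** propagated to ancestor terms.
The removal loop operates on the literal (term, level) pairs of the
signature's annotation; propagation would inflate the removal sets in a
way no part of the procedure calls for. This is the single most
consequential interpretation choice in the package and is therefore
surfaced here rather than buried in a default.

A term's *hierarchy level* is 1 plus the longest directed path from the
term to its namespace root (roots are level 1). Deeper terms are more
specific, and the longest-path convention guarantees that a child is
always strictly deeper than every parent; a shortest-path convention is
available via `compute_term_levels(..., convention = "shortest")`.

Three pool constructions are provided:

* **Procedure 1** (`grp1`): the pool is the universe minus the signature.
  Surrogates from this pool share no *gene* with the signature — the
  gene-centred (Mendelian) notion of distinctness.
* **Procedure 2 / 2\*** (`grp2`): starting from the procedure-1 pool
  (additionally minus a proliferation gene list for 2\*), the signature's
  biological-process terms are sorted by level and, looping from the
  signature's deepest level down to its shallowest, every gene annotated
  to a signature-derived term at the current level is deleted. Each level
  emits a pool with its removal bookkeeping (genes removed, cumulative
  sums, terms removed, pool size), and the loop stops at the shallowest
  level or as soon as the pool would fall below the signature's size.
  Only biological-process terms drive this removal — the procedure targets
  shared *processes* — but the namespace is a parameter.
* **Falsification test** (`falsification_test`): all the signature's terms
  (every namespace — the disjointness claim is about the full meaning set)
  are mapped back to their annotated genes and deleted in one shot,
  together with the signature's own unannotated genes, which its terms
  cannot reach but which would make a drawn set a non-surrogate. The two
  code paths (level loop vs one-shot) are deliberately kept separate so
  each stays auditable against its definition. `verify_disjoint` checks
  the guarantee on any pair of gene sets.

For each pool, `run_resampling` draws `repeats` sets (default 1000)
matched to the signature's size, scores each, applies a Bonferroni
correction with multiplicity equal to the number of repeats in the batch
(the correction is applied within a signature's repeat loop; correcting
across signatures or levels is a different experiment and is not done),
and reports the accuracy

$$\mathrm{Acc} = \frac{\mathrm{TP}}{\mathrm{TP} + \mathrm{FN}}
             = \frac{\#\{p < \alpha\}}{\mathrm{repeats}},$$

where significant sets are true positives and non-significant sets false
negatives; the declaration scheme admits no true negatives or false
positives. The default significance level is $\alpha = 0.001$. Degenerate
draws (constant submatrix, all PC1 scores tied) are counted as false
negatives with a logged reason — silently redrawing them would bias the
null. Reports also carry the batch median, the empirical 3rd-percentile
p-value (linear-interpolation quantile), and the signature's own p-value
on the same data.

When a signature references genes absent from the expression matrix, the
signature is intersected with the loaded universe and the *intersected*
size is used for sampling; the loss is logged. Matching the evaluable
signature keeps the comparison honest — random sets should not be larger
than the set actually scored.

### How many surrogates are there?

The number of candidate sets of size $k$ from a pool of $n$ genes is
$\binom{n}{k} \le (ne/k)^k = 10^x$ with $x = k\,\log_{10}(ne/k)$, rounded
half-away-from-zero to an integer (`surrogate_bound`). For $n = 10^4$,
$k = 10^2$ this gives $10^{243}$; even when meaning removal shrinks the
pool to $n \approx 10^3$ the bound is still $10^{143}$, and one percent of
either — the order of surrogates when a percent-range fraction of random
sets is significant — subtracts 2 from the exponent.

## The synthetic cohort generator

Real validation cohorts cannot ship with a package, and the framework's
properties do not depend on any particular cohort. `generate_dataset`
builds cohorts with the statistical structure the analysis assumes:

* a single latent factor $u_s \sim N(0,1)$ per sample (the dominant
  proliferation-like prognostic axis of breast-cancer transcriptomes);
* *prognostic* genes with expression $\beta u_s + \varepsilon$
  ($\beta = 1$, noise SD 1), a *weak* background tier with loading
  $\beta_w = 0.2$ on 30% of the remaining genes, and pure-noise genes;
* exponential event times with hazard
  $\lambda_0 \exp(\gamma u_s)$ ($\lambda_0 = 0.1$, $\gamma = 1$) under
  independent exponential censoring (rate 0.05), giving roughly
  two-thirds observed events; $\gamma = 0$
  (`generate_null_dataset`) severs the expression–survival link exactly;
* a layered biological-process DAG (depth 8, 60 terms per layer, each term
  wired to a parent in the layer above, so a term's level equals its
  layer) with a small block of deepest-layer "proliferation-like" terms
  that carry exactly the prognostic genes — these genes are the
  proliferation stand-in list `pg`;
* annotations of three terms per remaining gene, drawn away from the
  proliferation block (5% of genes stay unannotated), and signatures that
  mix prognostic and background genes (enrichment 0.5, size 100, 48
  signatures by default, 300 samples, 2000 genes).

The defaults are desk-scale reductions of the cohorts this kind of study
uses (hundreds of samples, $10^4$ genes, $10^2$-gene signatures). The
residual weak tier is deliberately set *below* the per-gene noise floor:
with it, pools stripped of all signature-related meaning remain weakly
prognostic, so the falsification pool still yields surrogates at a
percent-to-tens rate — the qualitative phenomenon the framework exists to
demonstrate — while staying clearly below the procedure-1 accuracy. The
DAG is scaled so that a signature's meaning covers about half the term
universe; in the real ontology the coverage is a few percent, so the
synthetic setting is, if anything, *harsher* on pool survival.

What the generator does **not** emulate: microarray/RNA-seq technical
noise, batch structure, molecular subtypes (a single shared factor is the
default outcome driver), realistic ontology topology (term sizes in real
annotation corpora are heavy-tailed), or gene–gene correlation beyond the
latent factor. Passing tests on synthetic cohorts therefore validate the
machinery and the qualitative surrogate phenomenon, not any statement
about a particular real signature.

## Numerical and design choices

* **Ties and determinism.** Median ties go to group $-1$; random draws are
  without replacement within a set and independent across repeats
  (repeat collisions are astronomically unlikely at realistic pool
  sizes); every pool draws from its own RNG stream derived from the master
  seed, so adding a signature never perturbs another's draws, and a rerun
  with the same seed is byte-identical.
* **Report orientation.** Level reports are emitted in iteration order,
  deepest level first — the order in which the removal actually happens.
* **Accuracy formula.** With TP + FN = repeats the accuracy reduces to
  TP/repeats; that form is implemented.
* **"Genes removed" semantics.** A level's removal count excludes genes
  already removed at deeper levels (or by the signature removal), so the
  cumulative column is an exact running sum and pool sizes telescope.
* **Percentile.** The "lower 3rd percentile" is the empirical 3rd
  percentile of the p-value distribution; for the question "is the bottom
  3% significant" this coincides with the lowest-3%-of-sets reading.
* **Degenerate inputs.** Loaders reject missing values, duplicate
  identifiers, negative times and non-binary event flags outright; gene
  identifiers are opaque case-sensitive strings (no alias resolution);
  a transposed expression file fails validation rather than being guessed
  at.
* **Stratification sample floor.** The median split is defined from two
  distinct samples upward; two samples yield one per group.

## Problem sizes used by the test suite

The packaged tests exercise the full grid — 48 signatures × 1000 repeats
× two correction regimes = 96,000 random sets — on a compact cohort
(300 genes × 60 samples, 5-gene signatures), chosen so a complete
protocol run remains a routine part of the suite. Calibration draws 1000
random sets spread over 100 *independent* null cohorts (400 genes × 150
samples, 50-gene sets): within a single cohort the sets share the
survival realization and their p-values are positively correlated, which
inflates the variance of the significant fraction roughly twentyfold over
binomial; only across-cohort draws follow the binomial error a
3-standard-deviation tolerance is stated in. Phenomenon recovery runs at
the generator's full default scale (2000 × 300, 100-gene signatures,
prognostic fraction 0.2). `scripts/acceptance.R` recomputes the same
quantities end to end from a supplied seed.

## Limitations

The verdict of `falsification_test` is a statement about identifiability
within the PC1/log-rank prognostic framework, not about the biology of
any gene set: "surrogates exist" means the framework cannot distinguish
the signature's biological content from unrelated content of equal
prognostic value. Equivalence is judged by significance at the stated
$\alpha$ after correction — no effect-size equivalence test is attempted,
because the procedure this package implements does not define one. And
with 1000 repeats the smallest resolvable surrogate probability is about
$10^{-3}$; a "no surrogate found" verdict at that resolution is an
absence of evidence below it, which the implementation flags with an
explicit warning.
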