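---
title: "Diagnostic modelling from SNP genotypes: methods and design notes"
author: "snpdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic modelling from SNP genotypes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpdx)
```

## The problem

A case/control SNP study observes, for each individual, a categorical
genotype (e.g. AA/AG/GG, possibly missing) at each of thousands to
millions of loci, plus a binary disease status. For complex diseases no
single locus is strongly predictive: the signal is dispersed over many
loci, each carrying a small amount of information. `snpdx` builds a
diagnostic classifier in three stages, each designed to survive that
regime, and then pairs two such classifiers so that one can remedy the
other's doubtful diagnoses.

Missing genotype calls are treated throughout as an *extra genotype
category* rather than being imputed or dropped. The missingness pattern of
a locus can itself carry information (assay chemistry interacting with the
local sequence, for instance), and keeping it as a first-class "chaos
state" lets the coding stage exploit it when it does — and discard it when
it does not. The reserved label is `missing_label()` and cannot collide
with real genotype strings.

## Stage 1 — optimal binary coding (`snp2bin`)

Let $T$ be the binary status and $X$ a genotype variable with categories
$\{x_1,\dots,x_\ell\}$ (missing included). Any nonempty, exclusive and
exhaustive bipartition $(\mathcal X_1, \mathcal X_0)$ of the categories
defines a binary variable $Y = \mathbf 1[X \in \mathcal X_1]$. `snp2bin`
scores every bipartition by the Pearson $\chi^2$ statistic of the induced
$2 \times 2$ table of $Y$ against $T$ and keeps the maximiser.

Two facts make this safe and useful:

* **Independence preservation.** If $T \perp X$ then
  $P(T{=}t, Y{=}y) = \sum_{x \in \mathcal X_y} P(T{=}t)P(X{=}x)
  = P(T{=}t)P(Y{=}y)$ for every bipartition, so no recoding can conjure an
  association out of a truly unrelated SNP. The test suite checks this
  empirically: codings selected on one null sample keep the nominal
  type-I level when evaluated on an independent replicate.
* **Power concentration.** A related SNP often has one or two genotypes
  that are nearly independent of the status; in the full multi-category
  table they inflate the degrees of freedom without adding signal. The
  best $2 \times 2$ collapse has a single degree of freedom and, in the
  planted-effect simulations, a p-value at or below the multi-category
  table's (checked as a median-over-replicates property).

Complementary bipartitions induce the same table up to row swap, so only
$2^{\ell-1}-1$ representatives are enumerated, in a canonical order (by
size of the "1" set, then lexicographically); ties in the score are broken
by that order, making the whole stage deterministic. Columns with a single
observed category admit no bipartition and are dropped by `preprocess()`.
The statistic is plain Pearson with no continuity correction — the same
statistic the reduction stage tests with, which keeps scoring and testing
consistent; for $2\times2$ tables maximising the statistic and minimising
the p-value coincide (df is always 1).

Codings are derived **once, on the full dataset**, before any
cross-validation. This mirrors a sequential pipeline in which encoding is
a preprocessing step, and it leaks label information into every later
accuracy estimate; see *Honest versus optimistic evaluation* below.

## Stage 2 — candidate reduction (`mmpc`, `itermmpc`)

In a Bayesian-network view the features worth giving a naive Bayes
classifier are the status variable's children; MMPC (max-min
parents-and-children) selects exactly the variables that no small
conditioning set can render conditionally independent of the status.

The forward phase repeatedly adds the candidate with the maximal
*min-association* — the minimum over conditioning subsets (size $\le$
`maxK`) of the current selected set of $1-p$ when the test rejects at
`threshold`, and 0 otherwise — stopping when the best remaining candidate
reaches 0. The backward phase removes any selected feature that some
subset of the others renders independent. Both phases use the same
stratified Pearson test: the data are split by the joint states of the
conditioners, each non-degenerate stratum contributes its $2\times2$
statistic and one degree of freedom, and degenerate strata contribute
nothing. A test whose sample size falls below five times the nominal
stratified df is deemed unreliable and reported as independence
($p = 1$), so sparse conditioning can only make the filter more
conservative.

Defaults `threshold = 0.1` and `maxK = 2` are deliberately permissive: the
reduction stage must not over-exclude, because the selection stage can
discard but never recover a candidate. Even so, conditioning erodes power
— a SNP with marginal $p \approx 10^{-3}$ can exceed the threshold under
some two-variable conditioning — so at desk-scale sample sizes the
surviving superset favours the stronger planted effects. The 0-order
versus 1-order association scans (`association_scan`) expose the flip
side: a SNP that merely shadows a truly associated one (a linkage proxy)
shows a *superficially* high marginal association that evaporates when
conditioned on its source.

MMPC's cost grows exponentially with the size of its output, so for large
feature sets `itermmpc` partitions the features into groups (default
`group_size = 1000`, a size at which per-group MMPC stays cheap), runs
MMPC per group, unions the survivors and iterates to a fixed point. Groups
are **re-randomised each iteration** (a fresh seeded shuffle): with fixed
groups, two mutually redundant features stranded in different groups could
both survive forever, whereas reshuffling eventually co-locates them. Once
the survivors fit in one group a final plain MMPC pass finishes, so the
one-group case reduces exactly to `mmpc`. A 50-iteration cap guards the
(never observed) possibility of a non-converging shuffle cycle.

## Stage 3 — greedy wrapper selection (`optnbc`, `suboptnbc`)

The classifier is a naive Bayes model over the selected binary features:
class priors are observed frequencies and each conditional probability is
Laplace-smoothed with pseudo-count `alpha = 1`,
$P(x{=}1 \mid c) = (n_{1c} + \alpha)/(n_c + 2\alpha)$. Smoothing keeps
every table entry strictly inside $(0,1)$, so the log-space posterior —
hundreds of factors — never degenerates; an unsmoothed model (`alpha = 0`)
is refused outright. The decision threshold is 0.5 with ties predicted
"case" (a posterior of exactly one half is read as a positive diagnosis).

Feature sets are scored by a cross-validated log-posterior: the stratified
10-fold split is frozen once per selection run, and the score is the sum
over held-out instances of the log posterior assigned to the instance's
true class (the log of the product of correct-diagnosis probabilities).
Freezing the folds makes greedy comparisons exact rather than noisy, and
makes the whole search reproducible from its seed; the fold split is the
only randomness in the selector.

The forward phase tentatively adds every remaining candidate and commits
the best scorer (`optnbc`) or the second best (`suboptnbc`), stopping as
soon as no addition strictly improves the score — so the committed score
sequence is strictly increasing by construction. The backward phase
tentatively deletes each feature, commits the deletion that yields the
highest resulting score provided the score does not decrease, and stops
otherwise. We read "does not decrease" as allowing equality so that ties
favour the smaller model; the deletion loop repeats until every deletion
would strictly hurt, and never empties the model below one feature. Ties
among tentative additions go to the earlier candidate in input order; a
tied first/second pair under `suboptnbc` yields the later-ordered one, so
the two variants genuinely diverge on exact duplicates.

The second-best variant is not a curiosity: it produces a deliberately
different feature set of comparable quality — a second expert whose
disagreements with the first are informative (see *Remedying*).

### Overfitting behaviour of the forward rule

"Stop when the score no longer increases", applied to a frozen fold
split, is a weak overfitting guard. With $k$ null candidates the best of
$k$ noisy CV deltas is positive with non-trivial probability, so on pure
noise (50 features, $n = 1000$) the selector typically admits seven to
eleven features before stopping — far fewer than the pool, but not the
two or three an oracle would keep. The test suite asserts the guard at
the level the rule actually provides (null models stay well under a third
of the pool). Users who need tighter control can cap the model with
`max_features` or evaluate with the nested protocol below, which prices
this optimism honestly.

## Remedying doubtful diagnoses

Given a main expert and an alternative expert, an instance whose main
posterior of "positive" lies in the open doubt band $(0.45, 0.55)$ is
routed to the alternative; everything else is `accepted` as-is. The band
endpoints are open by the package's reading — a posterior of exactly 0.45
is not doubtful — with `closed = TRUE` available since the convention is
genuinely ambiguous. With known true labels each routed outcome is
classified:

* `corrected` — the main prediction was wrong, the alternative's is right;
* `improved` — the main prediction was right and the alternative assigns a
  *strictly* higher probability to the correct class;
* `unresolved` — anything else (both wrong, or no strict improvement; an
  in-band instance whose alternative posterior is also in-band and no
  better lands here).

Two routing modes exist because evaluation needs more than production:
`band` mode (deployable without labels) touches only in-band instances and
therefore never alters a confident diagnosis; `audit` mode (labels known)
additionally examines every main-model error, whatever its posterior —
the setting in which a published error table can show main posteriors far
outside the band. The bundled `remedy_worked_examples()` table exercises
both: seventeen in-band doubt cases and seventeen audited errors, each
with its expected label, all reproduced by `remedy_conclusion()`.

## Honest versus optimistic evaluation

`loo_evaluate()` and `repeated_kfold()` refit the naive Bayes *parameters*
per fold but keep the binary codings and the selected feature set fixed —
the protocol a sequential pipeline naturally reports, and an optimistic
one, since codings and selection both saw every label. `nested_evaluate()`
re-runs the entire pipeline (coding, reduction, selection) inside each
training fold and diagnoses only genuinely unseen samples; genotype
categories unseen in a training fold fall into a coding's "0" set. On the
bundled polygenic fixture the gap is large and instructive: roughly 73%
non-nested leave-one-out accuracy against roughly 60% nested accuracy
(both computed by `scripts/acceptance.R`). Reported headline accuracies
from pipelines of this shape should be read with that gap in mind.

`repeated_kfold()` follows the mean-and-spread convention: each repeat
draws a fresh stratified partition, and metrics are reported per repeat
and as mean ± sd. When a class has fewer members than `k`, `k` is reduced
with a warning (a deterministic re-deal cannot fix an infeasible split).
The Matthews correlation coefficient is computed from the confusion
counts and equals the Pearson correlation of the binary
prediction/label vectors — an identity the tests assert to $10^{-12}$ —
with the convention that a zero denominator factor yields 0.

## The synthetic study generator

Controlled-access genotype data cannot ship with a package, so
`simulate_genotypes()` provides the test bed: genotypes drawn per SNP
under Hardy–Weinberg equilibrium at a minor-allele frequency uniform in
`maf_range` (default 0.05–0.5); disease status from a logistic liability
summing per-genotype weights over causal SNPs, centred so the baseline
prevalence is `plogis(intercept)`; linkage proxies as noisy copies of
source columns (re-drawn from the source's marginal with the stated flip
probability); and missing calls masked completely at random by default,
with an optional class-dependent multiplier for experiments where
missingness itself is informative. Case/control quotas are filled by
rejection sampling with a capped number of batches, so an infeasible
prevalence fails fast instead of spinning. Everything is reproducible
from the spec's seed, and the generator restores the caller's RNG state.

The canonical fixtures (`make_fixture()`) freeze four regimes: `null` (no
signal, for type-I-error suites), `planted_small` (five strong effects),
`duplicated_feature` (an exact-copy pair, for redundancy and
second-expert tests), and `planted_polygenic` — 2000 samples, 5000 SNPs,
50 causal SNPs at a per-allele log-odds of 0.45 (odds ratio ≈ 1.6) plus
25 proxies. That effect size is chosen as "weak but marginally
detectable" at $n = 2000$: a marginal scan flags most causal SNPs, yet
the conditional reduction at `threshold = 0.1`, `maxK = 2` retains only
the stronger part of the set — the many-small-effects predicament the
pipeline is designed for, reproduced at desk scale. A consequence worth
knowing: at this signal strength the selector admits every surviving
candidate, so the best- and second-best experts can coincide on this
fixture; their divergence is exercised where it is guaranteed, on the
duplicated-feature fixture.

What the generator does *not* emulate: realistic linkage-disequilibrium
block structure (proxies are pairwise copies), population stratification,
genotyping batch effects, and epistasis (the liability is additive).
Passing tests on these fixtures therefore demonstrate the algorithms'
statistical behaviour, not performance on any real cohort.

## Numerical and degenerate-input conventions

* $\chi^2$ of a table with any zero row or column margin is defined as 0
  (no evidence), never an error; negative counts are an error.
* Posteriors and CV scores are computed in log space with the usual
  max-subtraction; the posterior oracle tests agree to $10^{-12}$.
* Leave-one-out on $n = 2$ is defined (each fold trains on one sample);
  a prior-only model under LOO predicts each fold's training majority,
  which on balanced data is always the *other* class — accuracy 0, a
  useful reminder that LOO and the prior interact adversarially.
* Unknown candidate or feature ids, non-binary phenotypes, duplicate SNP
  ids, and instances missing a model feature all fail fast with explicit
  messages.

## Problem sizes used by the checks

The bundled checks run at deliberately modest sizes: oracle equivalence on
hundreds of small random columns; calibration loops of 1000 trials at
$n \in [300, 500]$; structure recovery over 20 seeds at $n = 2000$ with 55
features; exhaustive-subset comparisons over all $2^8$ feature subsets at
$n = 200$; and the full pipeline plus nested evaluation on the
2000 × 5000 polygenic fixture. These sizes make the whole suite and the
acceptance script reproducible in minutes on a single core while keeping
every statistical assertion at its stated tolerance.
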