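# snpdx

Diagnostic modelling of case/control status from SNP genotypes.

Genome-wide association studies are good at flagging risk loci and bad at
producing *diagnostic* models: for complex diseases no single SNP is
predictive, the signal is dispersed over many loci, and naive feature
selection drowns in redundant, superficially associated variants. `snpdx`
implements a pipeline built for exactly that regime, for statisticians
and bioinformaticians working with samples-by-SNPs categorical genotype
matrices (VCF, PLINK text, or a plain TSV dialect):

1. **Optimal binary coding** (`snp2bin`). Each SNP `X` with genotype
   categories `{x1, …, xℓ}` — missing calls kept as an explicit extra
   category, never imputed — is recoded as the binary variable
   `Y = 1[X ∈ X₁]` whose bipartition `(X₁, X₀)` maximises the Pearson χ²
   statistic of the induced 2×2 table against the status `T`. If
   `T ⊥ X` then `T ⊥ Y` for every bipartition, so recoding cannot
   fabricate associations; for truly associated SNPs it concentrates the
   signal into one degree of freedom.
2. **Candidate reduction** (`itermmpc`). MMPC (max-min
   parents-and-children) keeps the features that no conditioning subset
   (size ≤ `maxK = 2`) of already-selected features can render
   conditionally independent of `T` at level `threshold = 0.1`; a
   divide-and-conquer wrapper (partition, per-group MMPC, union, iterate
   to a fixed point) makes it tractable for large SNP panels and returns
   a small candidate superset.
3. **Greedy naive Bayes wrapper selection** (`optnbc` / `suboptnbc`).
   Starting from an empty naive Bayes classifier, each forward step adds
   the candidate with the best (or deliberately second-best)
   cross-validated log-posterior score — the sum over held-out instances
   of the log posterior of the true class, under a fold split frozen per
   run — until no addition strictly improves; a backward pass deletes
   features whose removal does not hurt. The two variants yield a main
   and an alternative "expert".
4. **Remedying** (`remedy_table`). Diagnoses whose main posterior of
   "positive" lies in the open doubt band (0.45, 0.55) are routed to the
   alternative expert; with known labels, outcomes are classified as
   *corrected* (wrong → right), *improved* (right, with strictly higher
   correct-class probability) or *unresolved*.

Evaluation (accuracy / sensitivity / specificity / MCC, leave-one-out,
repeated stratified 10-fold CV, and a fully nested honest protocol),
0-order/1-order association scans, and a synthetic case/control genotype
generator (Hardy–Weinberg genotypes, logistic liability over planted
causal SNPs, linkage proxies, missingness) are included. See the methods
vignette (`vignettes/snpdx-methods.Rmd`) for the statistical details and
design decisions.

## Worked example

```r
library(snpdx)

sim <- simulate_genotypes(simulation_spec(
  n_cases = 500, n_controls = 500, n_snps = 200,
  causal = causal_additive(1:5, beta = 0.8),
  ld_proxies = list(list(source = 1, copy = 6, flip_probability = 0.05)),
  missing_rate = 0.02, seed = 42))
sim$genotypes
#> Genotype matrix: 1000 samples x 200 SNPs
#>   phenotype: 500 cases / 500 controls
#>   missing-call rate: 0.020

fit <- snpdx_fit(sim$genotypes, group_size = 200, seed = 42)
summary(fit)
#> Dual naive Bayes diagnostic model
#>   binary features: 200 | candidate superset: 5
#>   main (opt):   5 features, CV score -642.8829
#>   alt (subopt): 5 features, CV score -642.8829
#> leave-one-out, main: accuracy 63.00%  sensitivity 67.80%  specificity 58.20%  MCC 0.2612
#> leave-one-out, alt:  accuracy 63.00%  sensitivity 67.80%  specificity 58.20%  MCC 0.2612
#>   expert feature overlap: 5 feature(s)
#> Remedy table (band mode): 253 instance(s) examined
#>   accepted  corrected   improved unresolved
#>        747          0          0        253
#>   accuracy: main 0.6300, alt 0.6300, combined 0.6300
```

Reading the output: the reduction kept a 5-feature candidate superset out
of 200 binary features (the five planted causal SNPs; the linkage proxy
of SNP 1 was recognised as redundant and excluded), both experts selected
all five, and leave-one-out accuracy is 63% — five odds-ratio-2.2 SNPs
simply do not carry more information than that, which is the point of the
many-weak-effects regime. With so few candidates the two experts
coincide, so in-band routing changes nothing here (253 doubtful instances
examined, none corrected or improved); the experts diverge when the
candidate pool outgrows what the forward phase admits, e.g. on panels
with duplicated or near-duplicated SNPs.

The conclusion classifier itself, on the package's bundled worked
examples (posterior pairs with known status):

```r
ex <- remedy_worked_examples()
band <- ex[ex$table == "doubt_band", ]
table(remedy_conclusion(band$main_posterior, band$remedy_posterior, band$true_status))
#> corrected  improved
#>         1        16
err <- ex[ex$table == "errors", ]
table(remedy_conclusion(err$main_posterior, err$remedy_posterior, err$true_status,
                        check_band = FALSE))
#> corrected
#>        17
```

A thin command-line interface over the same functions is installed at
`exec/snpdx` (`snpdx simulate | encode | scan | reduce | select | remedy |
evaluate`).

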