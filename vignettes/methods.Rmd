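---
title: "Classifying tumor cells with sctumor: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tumor cells with sctumor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sctumor` separates malignant from normal cells in annotated single-cell
RNA-seq data by combining gene-set signatures, rank-based scoring, a
logistic classifier, graph label propagation, and copy-number proofreading.
This vignette explains each model, its assumptions, every tunable parameter
that matters, and the design decisions taken where the procedure admitted
more than one reasonable reading.

## Input assumptions

All stages consume an `expression_dataset`: a cells × genes matrix of
library-size-normalized counts transformed as `log2(1 + x)`, plus per-cell
annotation columns, and (only for copy-number inference) a parallel matrix
of raw counts. Two assumptions are checked by `validate_normalization()`
and matter in practice:

* the matrix must not be z-scaled — scoring and differential expression
  rely on nonnegative, monotone-in-expression values;
* the full profiled gene complement must be present, not a preselected
  (e.g. highly-variable) subset — the recovery-curve score depends on the
  ranking depth being a fixed fraction of *all* genes, and the coverage
  guard depends on an honest denominator.

Gene identifiers are matched as whitespace-stripped, case-sensitive
symbols. No alias resolution is attempted: determinism across runs and
platforms is worth more here than a marginally larger intersection.

## Differential expression with overestimated variance

For genes tested for enrichment of class *u* (size $n_u$) over class *d*
(size $n_d$):

$$t = \frac{\bar{x}_u - \bar{x}_d}{\sqrt{s_u^2/n_u + s_d^2/n_u}}$$

Both variance terms share the $n_u$ denominator — the size of the group
under test, typically the small tumor population. Relative to Welch's
statistic this inflates the standard error whenever $n_u < n_d$, making the
gene ranking conservative in exactly the common situation of a 1:7
tumor:normal imbalance. Degrees of freedom follow Welch–Satterthwaite on
the inflated terms, with each term keeping its own group's $(n-1)$. The
"log2 fold change" is the difference of group means on the log2 layer; the
data are already log-transformed and nothing is exponentiated. P-values are
two-sided and Benjamini–Hochberg-adjusted within each comparison and
dataset.

Degenerate inputs are resolved explicitly: a gene with zero pooled variance
gets $t = 0, p = 1$ when the means agree and $t = \pm\infty, p = 0$ when
they differ; classes with fewer than two cells are an error.

## Signature consolidation

Per comparison, a gene's fold changes are averaged over exactly those
datasets where it passes `p_adj < 0.1`; datasets where it fails (or where
the gene is absent) contribute nothing, and genes failing everywhere are
dropped. The averaging denominator is therefore the number of *passing*
datasets — the alternative (fixed denominator over all datasets) silently
penalizes genes missing from one platform, which is a property of the
platform, not the gene. Genes are ranked by average fold change with ties
broken lexicographically by symbol (determinism), and the top `n_top = 300`
are kept. Across comparisons, the tumor-enriched signature is the
intersection (a marker must beat every contrasted class) and the
tumor-depleted signature the union (depletion against any class suffices).

## Recovery-curve scoring

Within each cell, genes are ranked by descending expression; ties are
broken lexicographically by symbol. The published scorer breaks ties
randomly; the deterministic rule is a documented divergence chosen for
testability, and it matters only for genuinely tied values. A signature's
score is the area under the step function counting its genes recovered
within the top $k$ ranks, $k = 1..K$ with
$K = \lceil \text{max\_rank\_fraction} \cdot G \rceil$, normalized by the
maximum area achievable given the number of signature genes present, so a
perfectly front-loaded signature scores exactly 1.

* `max_rank_fraction = 0.05` — the conventional top-5% ranking depth; the
  procedure's source does not print a value, so the conventional default is
  exposed rather than hidden.
* The 80% coverage guard refuses to score a dataset carrying less than 80%
  of a signature's genes; after the guard passes, absent genes are dropped
  from the recovery computation and the normalization shrinks accordingly.

Because only within-cell ranks enter, the score is invariant under any
strictly increasing transformation of a cell's expression — the property
that lets independently scored datasets be pooled without cross-dataset
normalization. The scorer targets single-cell matrices; bulk samples are
out of scope.

## The score classifier

A logistic regression of the binary label on `(tumor_score, normal_score)`
with a weak ridge penalty (`lambda = 1/(C·n)`, `C = 1`, intercept
unpenalized) for numerical stability on separable score spaces. Class order
is fixed as (Normal, Tumor) so the tumor probability is always column 2.
No hyperparameter search is performed anywhere in the package.

## Label propagation

The cell–cell graph restricts the expression matrix to the union of the two
signatures (so graph communities align with tumor/normal state rather than
generic cell type), reduces it by PCA (`n_pcs = 50`, capped at the
available dimensionality), finds `k = 30` exact Euclidean nearest
neighbors, and converts distances to connectivities with the fuzzy
simplicial-set construction: per-cell bandwidths are calibrated so each
cell's membership mass is $\log_2 k$, and the directed weights are
symmetrized by fuzzy union $P + P^T - P \circ P^T$, giving symmetric
weights in [0, 1] with zero diagonal.

Propagation iterates from $t = 0$:

1. threshold $N(t) = N_0 e^{-\lambda t}$, with $N_0$ the 90th percentile
   (`q0 = 0.9`, linear interpolation between order statistics) of the score
   difference $d_i = s^{tumor}_i - s^{normal}_i$, computed once at $t = 0$
   and decayed — not re-quantiled each round, matching the decay law as a
   formula in $t$;
2. cells with $|d_i| < N(t)$ have both probabilities masked to zero. The
   masking statistic is the score difference in absolute value: a one-sided
   mask would erase every confident-normal seed, leaving nothing to anchor
   the normal class. This is an interpretation of an ambiguous rule and is
   the package's choice;
3. probabilities are replaced by the connectivity-weighted average of the
   masked probabilities (a sparse matrix product), renormalized per cell;
   cells whose entire neighborhood is masked (zero rows) keep their
   previous probabilities and label rather than being forced to a class;
4. labels are the per-cell argmax (exact ties keep the previous label);
   the loop stops when fewer than `change_tol = 0.001` of labels change,
   or at `max_iter = 50` with a warning.

`lambda = 0.25` per iteration is the package default; the decay law is
fixed but its constant is not printed anywhere authoritative, so it is
exposed. Because $N(t)$ decays and $|d|$ is static, the seed set only ever
grows — masks loosen monotonically, which with the stopping rule gives
termination in practice (and `max_iter` guarantees it absolutely).

## Copy-number inference and proofreading

The CNV profile is the documented core of expression-based CNV inference,
without HMM state calling or tumor subclustering (those change no
downstream contract — the proofreading model consumes the continuous
profile): genes ordered by (chromosome, start); genes with mean raw count
below `cutoff = 0.1` dropped; retained counts log-normalized; per-gene
means of the reference cells (cells labeled normal — pipeline labels in
self-supervised mode, expert labels in harness mode) subtracted; values
clipped to ±3; a centered `window = 101`-gene moving average applied per
chromosome (never across a boundary, truncated at edges, with a warning
when a chromosome is shorter than the window); and each cell re-centered by
its median.

Proofreading trains a ridge logistic model of the pipeline's own labels on
the profile and predicts on the same cells. Two deliberate choices:

* **Penalty `0.1` (glmnet lambda).** The profile has more features than
  cells, so a near-unpenalized fit can memorize the very pseudo-label
  errors the step exists to repair — the assumption that plain logistic
  regression "does not overfit" here fails at $p > n$. A moderate ridge
  forces the model onto the population-level copy-number signal; the
  useful region is a broad plateau (roughly 0.01–0.5), with stronger
  penalties compressing probabilities below any useful flip confidence.
* **`flip_probability = 0.9`.** A label flips only when the CNV model
  assigns the opposite class more than 0.9 probability; "highly probable"
  is not quantified anywhere authoritative, so the threshold is explicit
  and configurable. Concordant labels are never touched, and the flip
  report lists every flipped cell with its probability.

`train_cnv_baseline()` reproduces the generalization experiment's
structure: random forests trained per cohort (plus one merged pair) and
evaluated on all cohorts show that CNV-only classifiers transfer only
between cohorts sharing copy-number architecture.

## The synthetic cohorts

`simulate_cohort()` emulates the statistical structure the method assumes:
negative-binomial counts (dispersion 0.5) with lognormal gene base means
shared across datasets, lognormal library sizes (sd 0.3), per-dataset
gene-wise batch offsets (sd 0.5 in log2 units), a 1:7 tumor:normal
imbalance (`tumor_fraction = 1/8`), 150 planted tumor-up and 150
tumor-depleted markers shifted by 1.5 log2 units in tumor cells, and one
300-gene 2× copy-number gain multiplying tumor-cell counts. The default
cohort is 4 datasets × 2000 cells × 6000 genes — sized so the full
pipeline, including the end-to-end and proofreading validations, runs in a
few minutes on one CPU; unit tests use smaller instances of the same
generator. Planted markers are sampled from the upper half of base
expression (a marker must be detectably expressed to be one) and never
overlap the CNV segment. The normalized layer is computed exactly as the
pipeline expects its inputs: `log2(1 + 1e4 · count / library size)`.

Two things the generator deliberately does *not* emulate: real cell-type
substructure within the normal compartment (normal cells are one
statistical population, so passing tests show robustness to imbalance and
batch, not to confusable cell states), and dropout beyond what the
negative-binomial marginal produces. A consequence worth knowing when
reading the tests: a planted 2× copy-number gain is *genuine* differential
signal — dosage drives expression — so genes under the gain legitimately
enter the tumor signature and are counted as true signal, not
contamination, by the signature-recovery checks.

Note also that at miniature scales (a few hundred cells, under ~1000
genes) the per-count increment of the log-normalized layer becomes large
and cross-dataset score calibration degrades; the cross-dataset accuracy
properties are therefore asserted at the default cohort scale, while small
fixtures exercise contracts and arithmetic.

## Limitations

* The signature machinery assumes at least one annotated dataset per
  training cohort with both classes present; single-class inputs are
  errors, not guesses.
* The propagation masking statistic and the decay constant are
  interpretations of an under-specified procedure (documented above);
  alternative readings (re-quantiled thresholds, probability-based
  masking) are not implemented.
* CNV proofreading assumes tumor cells carry copy-number alterations;
  tumors with flat genomes gain nothing from it, and the step is applied
  once, not iterated with re-propagation.
* The h5ad reader covers dense and CSR/CSC matrices and
  plain/categorical annotation columns — the subset of the format the
  pipeline touches — not the full AnnData schema.
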