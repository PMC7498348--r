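---
title: "Variance-adjusted Mahalanobis scoring: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-adjusted Mahalanobis scoring: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vamscore)
```

## The problem

Single-cell RNA-seq matrices are sparse (often 70--95% zeros) and noisy,
which makes gene-level statistics per cell unreliable. Single-sample gene
set scoring addresses this by aggregating expression to the pathway
level: a cells $\times$ genes matrix $X$ becomes a cells $\times$
pathways matrix of activity scores that can be visualised, clustered and
tested. The method implemented here produces scores in $[0,1]$ with a
calibrated null distribution, so each individual cell can also be
*tested* for elevated pathway activity -- something rank-walk (GSVA-type),
z-scoring and PCA-based scorers do not support.

## The score

For gene set $k$ with member columns $X_k$ ($g$ genes) and per-gene
technical variance estimates $\hat\sigma^2_{\mathrm{tech}}$, each cell's
squared variance-adjusted Mahalanobis distance from the **origin** is

$$
M[,k] \;=\; X_k^\top \left( I_g\,\hat\sigma^2_{g,\mathrm{tech}} \right)^{-1} X_k ,
\qquad\text{i.e.}\qquad
M_{c,k} = \sum_{j \in k} \frac{x_{c,j}^2}{\hat\sigma^2_j}.
$$

Two deliberate departures from the classical Mahalanobis distance
$(x-\bar x)^\top \hat\Sigma^{-1} (x-\bar x)$:

* **Diagonal technical variances instead of the full covariance.**
  Deviations along directions of high *technical* variance are
  discounted (large deviations are expected there), but deviations along
  directions of biological covariation are not -- under a null of purely
  technical noise those are exactly the deviations of interest.
* **Distance from the origin instead of the mean.** For nonnegative
  normalized expression, distance from the origin is unambiguous: 0
  means no expression of any set gene, and larger always means more
  coordinated expression. The mean-centered distance cannot distinguish
  a cell above the mean on every set gene from one below the mean on
  every gene -- in the two-gene example with mean $(1,1)$ and identity
  covariance, the cells $(0,0)$, $(2,0)$, $(0,2)$ and $(2,2)$ all sit at
  mean-centered distance 2, while their origin distances 0, 4, 4, 8
  separate them by combined expression.

`standard_mahalanobis()` implements the classical definition purely as a
comparison utility; it never enters the scoring path.

## The null and its calibration

Under multivariate normality the origin-based distance would follow a
non-central $\chi^2$ with $g$ degrees of freedom and non-centrality
$\sum_j \bar x_j^2/\hat\sigma^2_j$. On sparse data this approximation
fails: it matches the mean (that identity holds by construction of the
sample variance) but badly understates the spread once roughly half or
more of the entries are zero. The package therefore calibrates
empirically:

1. every gene column of $X$ is independently permuted
   (`permute_columns()`), which preserves each gene's marginal
   distribution exactly while destroying across-gene structure --
   precisely the null of uncorrelated technical noise;
2. distances $M_p$ are recomputed on the permuted matrix;
3. a gamma distribution is fitted by maximum likelihood to the *nonzero*
   values of each $M_p$ column;
4. scores are the gamma CDF of the observed distances, $S[,k] =
   F_{\gamma(\hat\alpha_k,\hat\beta_k)}(M[,k])$, and p-values are the
   gamma upper tail at $M[,k]$.

The CDF transform puts sets of different sizes on a common scale,
saturates for extreme cells (robustness to outliers) and yields exactly
0 for cells with no expression of any set gene. P-values are evaluated
through the survival function rather than as $1-S$ so that extreme cells
retain tiny but nonzero p-values (e.g. $e^{-50}$) instead of cancelling
to 0.

The gamma MLE profiles out the rate analytically and solves the shape
score equation $\log k - \psi(k) = \log \bar x - \overline{\log x}$ by
Newton iteration from the moment start $\bar x^2/s^2$ (gradient
tolerance $10^{-8}$, 200-iteration cap). Near-constant samples drive the
MLE shape to infinity; the fit is then capped at $10^6$ and flagged
rather than returning `NaN`. Columns with fewer than `min.nonzero.fit`
(default 50) nonzero permuted distances fall back to the nonzero
observed distances, and sets that still cannot be fitted are reported as
failed with `NA` score columns -- the run continues and the provenance of
every fit is recorded in the `fit_source` column of the result.

Fitting directly on $M$ (`fit.on.permuted = FALSE`) skips the
permutation for speed. Any genuine signal then inflates the fitting
sample, which can only make the test more conservative, so type I error
is not inflated; power is what is traded away.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `tech.var` | sample variances | per-gene technical variance (squared normalized-expression units); supply your own decomposition if the marginal variance is not all technical |
| `min.set.size` | 5 | smallest resolved set scored; smaller sets give unstable distances |
| `min.nonzero.fit` | 50 | fewest nonzero null distances accepted for a gamma MLE |
| `fit.on.permuted` | `TRUE` | permuted-null calibration vs the faster direct fit |
| `scale.factor` | 10,000 | log-normalization scale factor (the field's de-facto standard) |

Gene sets are resolved against the matrix by exact, case-sensitive
string match by default (`case.insensitive = TRUE` relaxes this);
unmatched symbols are dropped and counted, and genes with zero technical
variance are removed from every set before scoring since they carry no
information and would divide by zero.

## What the simulator emulates

`simulate_null_matrix()` draws each entry independently: zero with
probability `sparsity`, otherwise log-normal with `meanlog` solved so
the nonzero mean hits a target (default 0.642, the scale of
log-normalized peripheral-blood droplet data) at `sdlog = 0.5`.
`inject_signal()` re-draws a designated genes $\times$ cells block from
the same family with `meanlog` shifted to an inflated nonzero mean --
values are redrawn, not shifted, so the signal stays log-normal, and the
block's sparsity pattern is regenerated at the same rate.

The default sparsity is 0.7. It was fixed by reconciling the simulated
power curve against the published endpoints of the method (power
rising from about 0.11 at inflated mean 0.7 to about 0.99 at 1.7 over
50-gene/50-cell signals in 2000 $\times$ 500 matrices): sparsity 0.8
imposes an information ceiling incompatible with the high endpoint -- a
signal cell's nonzero signal-gene count is Binomial(50, 0.2), so about
2% of signal cells carry too few nonzero entries ever to reject --
while 0.7 reproduces both endpoints and remains realistic for droplet
data. This value was fixed once and is not tuned per experiment;
distribution-fit comparisons are still run at the sparsities 0.5 and
0.8 where the $\chi^2$ contrast is classically illustrated.

What the simulator does **not** emulate: library-size variation,
gene-specific dropout curves, correlated gene programs beyond the single
injected block, and discrete counts (values are continuous, as after
normalization). Passing the validation experiments therefore shows
correct behaviour under exchangeable technical noise, not robustness to
every artefact of real data; on real matrices the permutation null keeps
the calibration honest as long as the no-signal genes are approximately
exchangeable across cells.

## Validation experiments

* `type_one_error_experiment()`: 10 null datasets of 2000 $\times$ 500,
  one random 50-gene set each, 20,000 pooled cell-level tests; the
  rejection rate at $\alpha = 0.05$ should sit in the binomial noise
  band around 0.05.
* `power_experiment()`: the same design with a 50-gene block inflated in
  the first 50 cells; 500 signal-cell tests per inflated mean.
* `auc_experiment()`: classification of signal vs null cells by score
  rank (Mann-Whitney AUC with midranks), compared against the z-scoring
  comparator (standardized mean over set genes, `zscore_scores()`) and
  the PCA comparator (projection on the first PC of the set submatrix,
  sign fixed so the largest-magnitude loading is positive,
  `pca_scores()`).
* `cluster_enrichment()`: one-vs-rest Wilcoxon rank-sum per cluster and
  set on the cell-level scores (normal approximation with continuity
  and tie correction -- group sizes are in the thousands; exact
  enumeration appears only as a test oracle), ordered by p-value within
  cluster, with a Benjamini--Hochberg FDR over the whole table.
  `bh_fdr()` applies the same step-up adjustment to the full
  cells $\times$ sets p-value family (the default, matching how
  cell-level inference is reported) or per set.

Every experiment derives replicate seeds from one master seed
(`seed + replicate`), so results are reproducible end to end; the
experiment sizes above (the published study sizes) run in seconds to a
couple of minutes on a laptop, and the test suite uses reduced sizes
(300 $\times$ 120) for its structural checks.

## Numerical and degenerate-input choices

* Missing values in input matrices are rejected at load time, never
  imputed -- normalized scRNA-seq encodes absence as 0.
* Matrix Market indices are 1-based on disk per the standard; the
  orientation of an `.mtx` bundle is auto-detected from the sidecar
  lengths, with the genes $\times$ cells convention assumed for square
  matrices.
* Sample variances use the two-pass formula on dense input; the sparse
  path uses the sum-of-squares identity, which is safe for nonnegative
  sparse data (the mean is never close to the root-mean-square) and is
  clamped at zero against rounding.
* A cell with zero expression on every retained set gene has distance
  exactly 0, score exactly 0 and p-value exactly 1, by construction
  rather than by floating-point accident.
* Ties in a permuted column are treated as values, not labels; the
  distinction has no observable effect.
* One permuted matrix is used, not repeated permutation rounds: the
  gamma family smooths the single-pass null sample, and one pass keeps
  the cost at two distance computations per set.

## Known limitations

* The technical-variance default (sample variance) attributes *all*
  marginal variance to noise; with strong biological structure inside a
  set this is conservative. Supplying decomposition-based variances via
  `tech.var` is the intended remedy.
* Scores of different sets are calibrated marginally; the joint
  distribution across sets (overlapping genes, correlated pathways) is
  not modelled.
* The gamma fit needs enough nonzero null distances; very small or
  almost-empty sets fall back or fail explicitly rather than returning
  miscalibrated scores.
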