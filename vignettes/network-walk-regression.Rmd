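---
title: "Ranking disease-associated miRNAs with network walks and logistic regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking disease-associated miRNAs with network walks and logistic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mirwalkreg)
```

## The problem

Experimentally confirmed miRNA–disease associations are sparse: most
miRNA–disease pairs have simply never been tested. The working hypothesis of
similarity-based prediction is that functionally similar miRNAs tend to be
involved in phenotypically similar diseases, so the neighbourhood of a miRNA
in a similarity network carries information about which diseases it is likely
to be associated with. `mirwalkreg` turns that hypothesis into a ranking
procedure with four stages:

1. **Integrated miRNA similarity.** Curated functional similarity $FS$ where
   a pair has a value, Gaussian interaction-profile kernel similarity $GM$
   otherwise:
   $$SM(i,j) = \begin{cases} FS(i,j) & \text{pair } (i,j) \text{ has a curated value} \\ GM(i,j) & \text{otherwise.}\end{cases}$$
2. **Network propagation.** A random walk with restart from every miRNA on
   the $SM$-weighted network yields, for each miRNA, a stationary probability
   over all miRNAs — a global, smoothed notion of proximity.
3. **Ternary features per disease.** For a disease $d$ with binary label
   vector $y$ (the disease's column of the association matrix $A$), each
   miRNA's top-$K$ walk neighbours are split by label:
   $\phi_{i1}$ = stationary mass on neighbours with $y=1$,
   $\phi_{i0}$ = mass on neighbours with $y=0$, giving the feature vector
   $(1, \phi_{i1}, \phi_{i0})$.
4. **Binary logistic regression.** A weight vector $w$ is fitted by maximum
   likelihood on all miRNAs; unlabelled miRNAs are ranked by the posterior
   $P(y=1\mid x) = e^{w\cdot x} / (1 + e^{w\cdot x})$.

The interaction profile $IP(m_i)$ is the $i$-th row of $A$; the kernel is

$$GM(i,j) = \exp\!\left(-\gamma_m \lVert IP(m_i) - IP(m_j)\rVert^2\right),
\qquad
\gamma_m = \gamma'_m \Big/ \left(\tfrac{1}{n_m}\sum_i \lVert IP(m_i)\rVert^2\right),$$

i.e. the raw bandwidth $\gamma'_m$ is normalized by the average number of
known associations per miRNA, so the kernel's scale adapts to the density of
the catalogue.

## Parameters and defaults

| parameter | meaning | default | why |
|---|---|---|---|
| `gamma_prime` | raw kernel bandwidth (dimensionless) | 1 | the standard choice for interaction-profile kernels on association data |
| `restart` | per-step probability of returning to the seed distribution | 0.7 | no canonical value exists for this method; 0.7 is a common network-propagation default. Results should always be reported together with the value used. |
| `cutoff` | L1 convergence threshold of the walk | 1e-6 | the method's stated stopping rule |
| `top_k` | candidate-list size per seed | 50, or $\lceil 0.1\,n_m\rceil$ when $n_m < 51$ | about 10% of a several-hundred-miRNA catalogue; the small-$n$ rule keeps the same fraction on desk-scale networks |
| `ridge` | stabilizing penalty on the logistic fit | 1e-8 | guards against complete separation while leaving well-posed fits unchanged to ~8 decimal places; set 0 for the exact MLE |
| `tol` | gradient $\ell_\infty$ tolerance of the Newton fit | 1e-8 | 3-parameter concave problem; exact-Hessian Newton reaches this in a handful of steps |

The restart probability deserves emphasis: it controls how local the
diffusion stays (as $r \to 1$ the stationary vector collapses onto the
initial distribution; small $r$ diffuses globally), and the ranking is not
insensitive to it. It is exposed everywhere and echoed in printed summaries.

## Numerical choices

* **Transition matrix.** The fixed-point iteration
  $p(t+1) = (1-r)\,SM\,p(t) + r\,p(0)$ only preserves probability vectors if
  the matrix applied is stochastic, so $SM$ is column-normalized into $T$
  before iterating, which is the standard construction for restart walks on
  weighted graphs. The unit-diagonal policy of the integrated similarity
  guarantees positive column sums. Self-loops (the $SM$ diagonal) are kept.
* **Initial distribution.** The walk from seed $i$ starts at the normalized
  $i$-th row of $SM$, not at a point mass, spreading the restart mass over
  the seed's neighbourhood.
* **Convergence.** L1 change below `cutoff` (default $10^{-6}$); the
  iteration is a contraction with rate $1-r$, so iteration counts are
  bounded by roughly $\log(\text{cutoff})/\log(1-r)$, and every run is
  cross-checkable against the direct linear solve
  $p = r\,(I-(1-r)T)^{-1}p(0)$ (`stationary_solve()`).
* **Top-$K$ selection.** The seed is excluded from its own candidate list
  (the surrounding network, not the node itself, should carry its label),
  and ties at the $K$-th rank break by lexicographic identifier order so
  every result is deterministic.
* **Logistic fit.** Newton–Raphson with step-halving; the objective is
  concave, so the accepted log-likelihood trace is non-decreasing and
  convergence is declared on the score equations
  ($\lVert X^\top(y-\pi)\rVert_\infty <$ `tol`). The log-likelihood uses an
  overflow-safe softplus. With one label class the model is refused — a
  disease with no known miRNA cannot be scored by this method.
* **Identifier hygiene.** All identifiers are lower-cased and trimmed before
  matching, and every matrix shares one canonical lexicographic order;
  silent row misalignment between the association and similarity sources is
  the dominant failure mode this guards against. Functional-similarity
  coverage is tracked pairwise through an explicit defined-entry mask, with
  asymmetries up to $10^{-6}$ repaired by averaging and anything larger
  treated as a data error. miRNAs absent from the similarity file are kept
  with undefined rows and fall back to the kernel.

## Cross-validation protocol

`loocv_roc()` removes each known association $(i,j)$ in turn, sets miRNA
$i$'s label for disease $j$ to 0, refits the label-dependent half of the
pipeline (features and regression), and records where $i$ ranks among all
unlabelled miRNAs of disease $j$. Per-fold standings are pooled into one ROC
by sweeping a normalized rank threshold: fold $f$ contributes
$x_f = (\#\{\text{candidates above the test}\} + \tfrac12\,\#\text{ties})/\#\text{candidates}$,
and $TPR(t)$ is the fraction of folds with $x_f \le t$. The trapezoid area of
that staircase equals the tie-corrected Mann–Whitney statistic
$\frac{1}{F}\sum_f (1 - x_f)$ exactly, and the package computes both and
checks their agreement.

Two protocol decisions were genuinely open:

* **What is recomputed per fold.** Recomputing the kernel, the integrated
  similarity and all walks for each of thousands of folds is quadratically
  expensive, and the label-independent half of the pipeline depends on the
  held-out entry only through one coordinate of one interaction profile. By
  default the network and the stationary profiles are computed once from the
  full association matrix and held fixed; `strict = TRUE` rebuilds
  everything inside every fold and is practical at desk scale (it exists
  precisely so the two protocols can be compared on small data).
* **Pooling.** Folds have unequal candidate counts (diseases differ in how
  many miRNAs are unlabelled), so standings are normalized per fold before
  pooling rather than pooled as raw ranks.

### A leakage property worth knowing about

Under the default (fixed-profile) protocol the held-out association is still
present in the interaction profiles that define the kernel: miRNAs sharing a
disease are slightly more similar *because* they share it. The practical
consequence, measurable with the package, is that evaluating a network on
its own labels is optimistic even when there is no real structure — a
no-signal fixture self-evaluates around AUC 0.6–0.7 rather than 0.5. For
this reason the package's negative control is a proper permutation test:
`loocv_roc(net, label_matrix = permute_associations(...))` holds the network
(the design) fixed and permutes only each disease's label column (the
response), which restores AUC $\approx$ 0.5. Absolute AUC values from the
default protocol should be read as comparative, not calibrated; `strict`
mode removes the leak at the price of runtime.

## The synthetic generator

`simulate_fixture()` plants aligned communities: miRNAs and diseases are
partitioned into `n_blocks` groups, associations are Bernoulli with
probability `within_assoc` (default 0.6) inside a block and `cross_assoc`
(default 0.05) across, and functional similarity is the block mean
(`fs_within` 0.8 / `fs_cross` 0.2) plus Gaussian noise (sd 0.05), clipped to
$[0,1]$, with a fraction `fs_coverage` (default 0.7) of pairs defined. The
default size, 150 miRNAs × 30 diseases in 3 blocks, keeps a full LOOCV in
the low seconds while leaving ~50 members per block — large enough for the
top-$K$ rule to behave as it does at catalogue scale.

The generator realizes exactly the assumption the method exploits (aligned
similarity and association structure) and nothing else. It does **not**
emulate the heavy-tailed degree distribution of curated catalogues, the
block-free overlap structure of real disease families, or the biased
coverage of curated similarity resources (which is densest for well-studied
miRNAs). Passing the planted-signal tests therefore shows the machinery
recovers structure of the kind assumed; it is not a claim about performance
on any particular curated dataset.

Problem sizes used by the test suite were chosen to keep each property
readable and quick: 100 random networks of up to 20 nodes for the
walk-vs-solve equivalence, 30-miRNA matrices for kernel spectra, $N = 10^5$
for logistic parameter recovery, the 150×30 fixture for end-to-end signal
recovery, and a 60×12 version of the same fixture for unit-level pipeline
checks.

## A worked example

```{r example, eval = FALSE}
fx <- simulate_fixture(seed = 1)
net <- mda_network(fx$associations, fx$fs)
net

roc <- loocv_roc(net)
glance(roc)
autoplot(roc)

pred <- predict_disease(net, "disease-001")
head(pred)
```

## Limitations

* The restart probability has no canonical value for this method; rankings
  at different `restart` values are not directly comparable.
* Diseases with no known associated miRNA cannot be scored (the logistic
  model needs at least one positive and one negative label).
* The default LOOCV protocol carries the self-reinforcement described above;
  use the permutation null (and, where feasible, `strict = TRUE`) when an
  absolute error rate matters.
* Only miRNA-side similarity is used; disease-side similarity is outside
  this model.
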