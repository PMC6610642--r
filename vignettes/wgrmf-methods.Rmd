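---
title: "Graph-regularized matrix factorization for drug response: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-regularized matrix factorization for drug response: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgrmf)
```

## The model

The data are a drug × cell-line response matrix $R \in \mathbb{R}^{n
\times m}$ with a binary observation mask $W$, a drug–drug similarity
matrix $S_d$ and a cell-line–cell-line similarity matrix $S_c$. The
model assumes the responses are generated by a low-rank interaction of
latent drug vectors $a_i$ (rows of $A \in \mathbb{R}^{n \times k}$) and
latent cell-line vectors $b_j$ (rows of $B \in \mathbb{R}^{m \times
k}$), and that entities with similar measured features should have
similar latent vectors (local invariance). Both assumptions enter one
objective:

$$
\min_{A,B}\;
\|W \circ (R - AB^\top)\|_F^2
+ \lambda_l\,(\|A\|_F^2 + \|B\|_F^2)
+ \lambda_d\,\mathrm{Tr}(A^\top \tilde L_d A)
+ \lambda_c\,\mathrm{Tr}(B^\top \tilde L_c B).
$$

The first term fits observed entries only — unmeasured pairs contribute
nothing, which is what allows training on incomplete screens. The
Tikhonov term controls the scale of the factors and keeps every row
update well posed even for drugs or cell lines that lose all their
observations inside a cross-validation fold. The two trace terms are
graph regularizers: for a graph Laplacian $L$,
$\mathrm{Tr}(A^\top L A) = \tfrac12 \sum_{i,r} \hat S(i,r)\,\|a_i -
a_r\|^2$ for nonnegative weights, so they penalize latent distance
between similar entities.

### Similarities

Drug similarity is the Jaccard coefficient between binary substructure
fingerprints; cell-line similarity is the Pearson correlation between
expression profiles. Both are symmetrized numerically
($S \leftarrow (S + S^\top)/2$) because the Laplacian code downstream
assumes exact symmetry. Pearson similarity can be negative; a negative
"weight" in the graph penalty *rewards* latent distance, which inverts
the regularizer's meaning. The pipeline therefore clips negative
similarities to zero before graph construction by default
(`clip_negative = TRUE` in `wgrmf_params()`); the signed behavior is
available behind the flag, but the positive-semidefiniteness guarantees
below apply only to the nonnegative regime. Missing feature values are
rejected rather than imputed — there is no principled default
imputation for either fingerprints or expression.

### Sparsification

Raw similarity matrices are dense and noisy. Each is filtered through a
$p$-nearest-neighbor graph: $N(i,j) = 1$ if $i$ and $j$ are mutually
among each other's $p$ most similar entities, $1/2$ if only one side
holds, $0$ otherwise, and $\hat S = N \circ S$. Neighbor sets exclude
the entity itself (a self-loop would add diagonal mass that cancels in
$L = D - \hat S$ anyway, but exclusion matches the standard
construction), and ties in similarity are broken toward the smaller
index so results are reproducible. From $\hat S$ the package builds
$D(i,i) = \sum_r \hat S(i,r)$, $L = D - \hat S$ and the symmetric
normalized Laplacian $\tilde L = D^{-1/2} L D^{-1/2}$, with the
convention that zero-degree (isolated) nodes get a zero entry in
$D^{-1/2}$ and hence contribute nothing. For nonnegative $\hat S$, $L$
is positive semidefinite and the spectrum of $\tilde L$ lies in
$[0, 2]$ — both are asserted by tests.

## The solver

Setting the gradient of the objective with respect to one latent row to
zero gives, for drug $i$,

$$
a_i \Big[ \textstyle\sum_j W_{ij}\, b_j b_j^\top
  + \big(\lambda_l + \lambda_d \tilde L_d(i,i)\big) I_k \Big]
= \textstyle\sum_j W_{ij} R_{ij}\, b_j
  - \lambda_d \sum_{r \ne i} \tilde L_d(i,r)\, a_r ,
$$

and symmetrically for cell-line rows. `wgrmf_sweep()` solves these
$k \times k$ systems row by row (Gauss–Seidel: coupling terms use rows
already updated within the sweep), which makes each row update the
*exact* minimizer of the objective in that row — block coordinate
descent with guaranteed monotone descent. A close variant keeps the
diagonal Laplacian contribution $\lambda_d \tilde L_d(i,i)\,a_i$ on the
right-hand side at its pre-update value; that iteration has the same
fixed points but is not a descent method, and in experiments on small
random instances it oscillates or diverges once $\lambda_d$ is
comparable to $\lambda_l$. The descent form was chosen for that reason;
an objective-increase check (warning, not error) remains in the fit
loop as a safety net. The linear systems are solved, never inverted.

**Initialization.** Unobserved entries are filled with the mean of the
observed ones and the rank-$k$ truncated SVD $U \Sigma V^\top$ gives
$A = U\Sigma^{1/2}$, $B = V\Sigma^{1/2}$. This is deterministic and
close to the masked optimum whenever the mask is not extreme. A random
Gaussian initialization (scale $1/\sqrt k$, seeded) is selectable for
robustness checks.

**Convergence.** Sweeps stop when the relative objective change falls
below `tol` (default $10^{-5}$) or after `max_sweeps` (default 200).
The trajectory (including the initial value) is stored on the fit
object for inspection.

## Hyperparameters

| parameter | default | meaning / rationale |
|---|---|---|
| `k` | 2 | latent dimension; for real screens choose from {50, 100, min(n, m)} by grid search, for the bundled synthetic conditions the generating rank is 2 |
| `lambda_l` | $2^{-2}$ | ridge weight, from the grid $\{2^{-2},\dots,2^{1}\}$; must be $> 0$ for CV robustness |
| `lambda_d`, `lambda_c` | $2^{-2}$ | graph weights, grid $\{2^{-5},\dots,2^{1}\}$; selected on the synthetic conditions by the same grid-search-by-CV protocol the method prescribes for real data |
| `p_drug`, `p_cell` | 5 | neighbor count; screens with hundreds of entities use $p \approx 10$–$20$, and $p$ must stay below the entity count — 5 matches the neighbor-to-entity ratio of a small panel at the 25/40 scale of the bundled conditions |
| `tol`, `max_sweeps` | $10^{-5}$, 200 | stopping rule (no canonical value exists; these converge all bundled fixtures) |

`wgrmf_grid_search()` evaluates arbitrary Cartesian grids by inner
cross-validation on the training data only, so that selection inside an
outer CV never sees test entries. Ties favor larger `lambda_l`, then
smaller `k` — the stronger regularization.

## Evaluation protocol

Cross-validation is *entry-wise*: the observed entries are partitioned
into near-equal folds, each fold's entries are masked, the model is
refit on the rest and the held-out entries predicted. After a full
round every observed entry has exactly one held-out prediction, and
per-drug PCC and RMSE are computed from those pairs. PCCsr and RMSEsr
restrict each drug's pairs to the extreme quartiles of the *observed*
response ranking: with $n_d$ observations, the
$\lfloor n_d/4 \rfloor$ most sensitive and $\lfloor n_d/4 \rfloor$ most
resistant cell lines (middle remainder discarded, so both sets have
equal size; ties broken by input order). Response orientation is an
explicit flag: lower-is-sensitive for IC50-like data (default),
higher-is-sensitive for activity-area-like data. Drugs with fewer than
4 observations are excluded from the quartile metrics, and drugs whose
held-out predictions have zero variance are excluded from that repeat's
PCC average, both with counted notices. Summaries are means ± SD across
repeats of the drug-averaged metrics, with distinct partitions derived
deterministically from one master seed.

## Case-study utilities

`rank_unmeasured()` returns a drug's unobserved cell lines ordered
most-sensitive-first under the declared orientation — the candidate
list a screening follow-up would start from. `ranksum_test()` compares
two response groups (e.g. mutated vs wild-type cell lines) with a
two-sided Wilcoxon rank-sum test using midranks for ties; the null
distribution is enumerated exactly for combined $n \le 20$ and
approximated by a tie-corrected, continuity-corrected normal above
that. The threshold and the two-sided convention follow common
statistical practice; the exact and approximate branches agree to
within 0.01 absolute near the switch, which is tested.

## The synthetic generator

`simulate_drug_response()` draws standard-Gaussian factors, forms the
rank-$k$ truth $AB^\top$, adds Gaussian noise scaled to
`noise_sd * sd(truth)`, masks an exact count of uniformly chosen
entries, and derives both similarity matrices from the *true* factors
(cosine of factor rows mapped to $[0,1]$ via $(1+\cos)/2$, which is
bounded with unit diagonal). Deriving similarity from the truth makes
the local-invariance assumption hold by construction, so tests isolate
solver correctness from similarity quality. The default conditions —
25 drugs × 40 cell lines, rank 2, noise at 10% of the truth's spread,
20% masked — are the package's standard study conditions throughout the
tests and the acceptance script.

What the generator does **not** emulate: realistic IC50 distributions
(heavy tails, drug-specific scales), tissue or pathway block structure,
feature noise in fingerprints/expression (similarities are
truth-derived), and non-uniform missingness (real screens lose entries
in structured blocks). Passing tests therefore demonstrate correctness
of the algorithm and protocol under the model's own assumptions, not
expected accuracy on real screens, where similarity quality is the
binding constraint.

## Numerical choices and degenerate inputs

* Tie-breaks: neighbor selection and response rankings break ties by
  smallest index / input order — deterministic, tested.
* Zero-degree graph nodes: contribute nothing to $\tilde L$ (no
  division by zero).
* All-zero fingerprints and zero-variance expression profiles are
  rejected by name (Jaccard and Pearson are undefined for them).
* Rows/columns with no observations remain updatable whenever
  $\lambda_l > 0$ (their updates are driven by the graph and ridge
  terms alone); with $\lambda_l = 0$ the row system is singular and the
  error says so.
* The $k \times k$ systems use `solve()`, not explicit inverses.
* Model files and matrix CSVs are written at 17 significant digits so
  round trips are bit-exact.

## Problem sizes

The test suite and acceptance script run the standard 25 × 40
conditions (10-fold CV, 3 repeats), brute-force graph enumeration up to
$n = 12$, exact rank-sum enumeration up to pooled $n = 20$, and 20
gradient-oracle comparisons on instances up to 6 × 6 — sizes chosen so
the full protocol, including every refit inside repeated CV, completes
in seconds on one core while still exercising each code path at
non-trivial scale.

## Known limitations

* The alternating solver finds a stationary point, not a certified
  global optimum; the gradient-oracle test checks it is no worse than a
  quasi-Newton minimizer from the same start on small instances.
* Hyperparameter grids grow multiplicatively; full nested grid search
  at screen scale is expensive (it refits the model for every grid cell
  × fold).
* Cell-line similarity from expression alone ignores other genomic
  views (mutation, copy number); the interface accepts any precomputed
  similarity, but provides builders only for fingerprints and
  expression.
* The quartile (sensitive/resistant) metrics depend on the declared
  orientation; there is no attempt to infer it from the data.
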