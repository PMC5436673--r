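---
title: "Ordering directed networks with partial level information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordering directed networks with partial level information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierord)
```

`hierord` estimates hierarchy levels for the nodes of a directed graph
from its adjacency matrix and a small set of anchored levels. This
vignette is the package's account of the method: the model and its
assumptions, the parameters that matter, the synthetic benchmark, the
numerical choices, and what the package does *not* claim.

## The model

The input is a directed graph on $n$ nodes with nonnegative weight
matrix $\mathbf{W}$ ($W_{ij} > 0$ meaning information flows from node
$i$ to node $j$; cortical connectivity matrices are binary), plus an
anchor set: a few nodes whose hierarchy level is known and fixed, e.g.
the primary sensory area at level $0$. The output is a continuous level
$h(u_i) \in [0, K]$ and a discrete level in $\{0, \dots, K\}$ for every
node.

The method rests on one substantive assumption, a *locality* premise:
if information is processed in stepwise fashion, direct connections
between nodes far apart in the hierarchy are rare. Under that premise,
nodes that are connected or share many neighbours should sit close in
the hierarchy, and a connectivity-preserving embedding becomes an
indirect measurement of hierarchical proximity.

### Spectral embedding

The random walk on the graph has transition matrix
$\mathbf{P} = \mathbf{D}^{-1}\mathbf{W}$, with $\mathbf{D}$ the diagonal
out-degree matrix; rows with zero out-degree are replaced by the uniform
distribution, and an optional teleportation step
$\mathbf{P}' = \eta \mathbf{P} + (1 - \eta)\tfrac{1}{n}\mathbf{1}\mathbf{1}^\top$
guarantees irreducibility. Let $\boldsymbol\psi$ be the Perron vector
(the stationary distribution, i.e. the unique positive left eigenvector
at eigenvalue $\rho = 1$) and $\boldsymbol\Psi = \mathrm{diag}(\boldsymbol\psi)$.
The normalized directed Laplacian is

$$
\mathbf{L}_d = \mathbf{I} - \frac{\boldsymbol\Psi^{1/2}\mathbf{P}'\boldsymbol\Psi^{-1/2}
  + \boldsymbol\Psi^{-1/2}\mathbf{P}'^\top\boldsymbol\Psi^{1/2}}{2},
$$

a symmetric positive semidefinite operator with $\lambda_1 = 0$ and
eigenvector $\boldsymbol\psi^{1/2}$; for a symmetric graph walked
without teleportation it reduces to
$\mathbf{I} - \mathbf{D}^{-1/2}\mathbf{W}\mathbf{D}^{-1/2}$, and its
spectrum lies in $[0, 2]$. The matrix $\mathbf{Y}$ of the first $k$
eigenvectors, with each **row** rescaled to unit Euclidean norm, gives
the embedding $\mathbf{Z}$: node $u_i$'s representative vector
$f(u_i)$ is the $i$-th row, a point on the $k$-sphere. (The printed
form of the normalization, a diagonal scaling by
$\mathrm{diag}(\mathbf{Y}^\top\mathbf{Y})$, is a column operation and
cannot place row vectors on a sphere; the package implements the
row-wise normalization that the geometric statement requires.)

### From similarity to pseudo distance

Pairwise similarity uses a regularized Tanimoto form,

$$
s(u_i, u_j) = \frac{f_i^\top f_j}{\lVert f_i - f_j\rVert_2^2 + f_i^\top f_j + \epsilon},
\qquad \epsilon = 1/\delta,\ \delta = K/2,
$$

and the *pseudo hierarchical distance* is $\mu(u_i, u_j) = \delta - s(u_i, u_j)$:
an estimate of the absolute level difference $|h(u_i) - h(u_j)|$. For
unit-norm rows the similarity is confined to
$[-1/(3+\epsilon),\, 1/(1+\epsilon)]$ — a strict subset of
$[-\delta, \delta]$ — so $\mu$ always lies strictly inside $(0, K)$.
Two consequences are worth knowing. First, $\mu$ never reaches the
extremes $0$ or $K$: the pseudo distances compress the true range, and
the recovered hierarchy is driven by the *variation* of $\mu$ around
$\delta$, not its absolute scale. Second, because $\mu$ is bounded away
from $0$, even nodes with identical embeddings are assigned a nonzero
target separation; the least-squares stage, not $\mu$ itself, resolves
such conflicts.

### Anchored minimization and discretization

Levels minimize the sum of squared hierarchical-distance errors over
unordered pairs,

$$
\min_{\mathbf{h} \in [0,K]^n}\ \sum_{i<j}\left(\,|h(u_i) - h(u_j)| - \mu(u_i, u_j)\,\right)^2,
$$

with anchored coordinates removed from the optimization (hard equality,
not a penalty). Summing each pair once and excluding the diagonal
halves the symmetric double sum without moving the minimizer (diagonal
terms are constants). The continuous solution is then rounded half-up
and clipped to $\{0, \dots, K\}$. Without anchors the objective is
invariant under $h \mapsto K - h$; anchors both break that reflection
symmetry and pin the scale, which is exactly the role of the partial
level information.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `k` | embedding dimension | — | suggest from spectral gaps |
| `K` | maximum level; levels are `{0..K}` | — | sets $\delta = K/2$, $\epsilon = 2/K$ |
| `eta` | teleportation retention $\eta \in (0,1]$ | 1 if strongly connected, else 0.99 | $\eta < 1$ guarantees a positive Perron vector |
| `restarts` | random restarts of the minimization | 50 | nonconvex objective |
| `seed` | base seed; restart $r$ uses `seed + r` | 1 | full determinism |
| `tau` | smoothing width of $\lvert x\rvert \approx \sqrt{x^2 + \tau^2}$ | 1e-6 | final stage of the continuation |
| `keep_frac` | restarts within `(1+keep_frac)·best` are averaged | 0.05 | see below |
| `drop_first` | drop the first eigenvector from $\mathbf{Y}$ | `FALSE` | see below |

**Choosing `k` and `K`.** The spectral gaps
$\gamma_i = \lambda_{i+1} - \lambda_i$ of $\mathbf{L}_d$ (plotted by
`autoplot()` on the embedding) carry the evidence: leading gaps that
stand out against the bulk indicate well-separated coarse structure,
and a following run of similar-sized gaps indicates how many levels are
resolvable. `suggest_parameters()` codifies this — `k` is the index of
the last gap exceeding `c` times the median gap (default `c = 2`), the
level count is `k` plus the length of the following run of mutually
similar gaps, and `K` is the count minus one — but it is a heuristic:
it is reported together with the full gap vector and a justification,
and both values should be confirmed by eye on small noisy graphs, where
the profile can be flat and the fallback (`k = 4` with a warning) or an
eccentric suggestion is possible. The gaps are computed as magnitudes
($\lambda_{i+1} - \lambda_i \ge 0$ for the ascending spectrum), which is
the quantity the gap-profile inspection actually uses.

**First eigenvector.** The eigenmap is defined with
$\mathbf{Y} = [\mathbf{y}_1, \dots, \mathbf{y}_k]$, i.e. the first
eigenvector included, and that is the default. $\mathbf{y}_1$ is not
constant for a directed graph (it is $\boldsymbol\psi^{1/2}$), so it
carries stationary-mass information; the common alternative of dropping
it is exposed as `drop_first = TRUE`.

**Averaging rule.** Many distinct level assignments fit the pairwise
distances almost equally well — reference hierarchies themselves are
one of a huge family of equally consistent solutions — so the package
reports an average of local minima rather than the single best: the
coordinate-wise mean over restarts whose objective is within 5% of the
best, re-clipped with anchors re-imposed. Averaging over *all* restarts
would let badly converged runs corrupt the estimate; the 5% filter
makes the averaged set well-defined. The reported `objective` is the
objective re-evaluated at the averaged levels (typically above the best
single restart's — averaging trades objective value for stability),
and per-restart records are kept in the fit.

## Numerical choices

- **Dense symmetric eigendecomposition** of the full $\mathbf{L}_d$
  (base `eigen(symmetric = TRUE)`), eigenvalues ascending. Problem
  sizes in this domain are tens to a few hundreds of nodes; sparse or
  iterative solvers would buy nothing and cost determinism.
- **Sign convention.** Each eigenvector's first nonzero component is
  made positive, so repeated runs (and permuted-label runs) produce
  identical embeddings; without it, eigenvector signs are
  solver-arbitrary and downstream results are not reproducible.
- **Smoothing continuation.** The objective's absolute values create a
  lattice of spurious local minima at small smoothing. Each restart
  therefore anneals the smoothing width geometrically from $K/3$ down
  to `tau` ($1/3$ steps, warm-starting L-BFGS-B with the analytic
  gradient at each stage). On the planted benchmark below, single-stage
  minimization at `tau = 1e-6` stalls at objectives ~10% above what the
  continuation reaches, and the stalled solutions are materially less
  accurate; the continuation's final stage still uses `tau` itself, and
  reported objectives are always the unsmoothed ones.
- **Degenerate inputs.** Zero out-degree rows become uniform before
  teleportation; a reducible transition matrix (possible at
  $\eta = 1$) is reported with instructions to lower `eta`; an
  embedding row with norm below $10^{-12}$ (unnormalizable) is an
  error naming the offending node; rounding of `x.5` is always up, and
  the discrete range is clipped to $\{0, \dots, K\}$.
- **Tie-breaks and determinism.** All randomness flows from one integer
  seed (restart $r$ reseeds with `seed + r`); the generator, the fit
  and the pipeline are bitwise reproducible under a fixed
  configuration, and the RNG state of the calling session is restored
  afterwards.

## The planted-hierarchy benchmark

`simulate_hierarchy(n, K, p0, beta, seed)` generates graphs with a
known level structure embodying the locality premise: levels are
assigned round-robin over node indices (deterministic, so only edges
are random), and each ordered pair $(u, v)$ receives a directed edge
independently with probability $p_0 e^{-\beta\,|h(u) - h(v)|}$.
Exponential decay is the simplest monotone model of "distant
interactions are rare"; $p_0$ and $\beta$ sweep the difficulty.

The package's benchmark conditions — used by the test suite and
`scripts/acceptance.R` — are $n = 40$ nodes over levels $0..9$,
$p_0 = 0.6$, $\beta = 1.5$, the two true extreme nodes anchored at $0$
and $K$, $k = 4$, 50 restarts, ten replicate graphs. These sizes keep a
full run in tens of seconds while giving each level four nodes and an
average degree comparable to cortical connectivity matrices. Under
them, mean recovery PCC against the planted truth is well above the
0.7 the tests require, and a 5-node variant is checked exhaustively
against the anchored integer grid $\{0..9\}^3$.

What the generator does **not** emulate: reciprocity statistics of real
tract-tracing data (real feedforward/feedback pairs are often both
present), hub/degree heterogeneity, laminar feedforward/feedback
labels, and any anatomical geometry. Passing the planted benchmark
therefore shows that the pipeline recovers a hierarchy *when the
locality assumption holds and levels are evenly populated*; it does not
certify performance on real connectomes, where the assumption is only
approximate and some areas are far better connected than others.

## Evaluation conventions

`evaluate_levels()` aligns reference and computed tables **by node
label** (never by position), restricts to the common labels with a
message, and computes PCC, MAE and RMSE with population ($1/n$)
denominators, matching the standard printed formulas rather than the
$n-1$ sample convention. A constant vector makes the PCC undefined;
the report then carries an explicit `pcc_defined = FALSE` marker with
`pcc = NA` instead of a number. Note that both error metrics compare
*levels on the same scale*; when comparing a continuous fit to an
integer reference, MAE/RMSE on the discrete levels
(`use = "discrete"`) is usually the fairer reading, while PCC is
scale-free.

Connection counts are reported under both conventions (directed entries
and connected unordered pairs) wherever they appear —
`graph_counts()`, `anchor_fraction()` — because published totals for
cortical matrices do not always state which convention they use.

## Known limitations

- The minimization is local; multi-restart continuation finds good
  minima in practice (verified exhaustively on small instances) but
  carries no global guarantee.
- Pseudo distances live in a band strictly inside $(0, K)$; with very
  few anchors the continuous solution tends to compress toward the
  middle of the range, and levels near the anchored extremes are
  estimated more accurately than unanchored extremes.
- Anchors are trusted absolutely: a wrong anchor is not detectable from
  the fit and will distort the whole ordering.
- The dense eigendecomposition and $O(n^2)$ objective are intended for
  graphs up to a few hundred nodes; nothing in the package is tuned
  for larger systems.
- The spectral-gap heuristic for `(k, K)` is advisory; on small or
  noisy graphs its suggestion can be far from sensible and the gap
  profile should be inspected directly.
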