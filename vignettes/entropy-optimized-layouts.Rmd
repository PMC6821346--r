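---
title: "Entropy-optimized network layouts: model, optimizer and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-optimized network layouts: model, optimizer and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entopt)
```

## The representation model

A drawing of a network is useful to the extent that it preserves the
information in the network. `entopt` makes that statement operational by
treating both the network and its drawing as probability distributions over
node pairs and measuring the information lost in translation.

**Target distribution P.** For an undirected graph with non-negative weights
$w_{ij}$, the target places mass $p_{ij} = w_{ij} / \sum w$ on each unordered
node pair. Pairs without an edge carry $p_{ij} = 0$ but remain part of the
sample space. With `use_square = TRUE` the weight matrix is squared first,
$M = W^2$: entry $M_{ij}$ sums weighted two-step walks, i.e. shared
neighborhoods, so the target then encodes interaction-profile similarity
rather than direct adjacency. In protein interaction networks this sharpens
complexes: two proteins in the same complex share most partners even when
their direct edge is missing. The diagonal $M_{ii}$ (a node's weighted
degree of self-similarity) may be kept — becoming self-pairs $(i, i)$ — or
ignored (`ignore_square_diagonal = TRUE`, the default and the recommended
setting, since self-similarity carries no layout information).

**Representation distribution Q.** Every node $i$ is an isotropic 2-D
Gaussian with center $r_i$ (its position) and standard deviation $\sigma_i$
(its *width*). The affinity of a pair in the picture is the overlap
integral of the two Gaussians, which has the closed form

$$ o_{ij} \;=\; \frac{1}{2\pi(\sigma_i^2 + \sigma_j^2)}
   \exp\!\left(-\frac{\lVert r_i - r_j\rVert^2}
                     {2(\sigma_i^2 + \sigma_j^2)}\right), $$

and $q_{ij} = o_{ij} / \sum_{k<l} o_{kl}$, normalized over exactly the pair
set of P (self-pairs use the self-overlap $1/(4\pi\sigma_i^2)$ and enter
only in the kept-diagonal squared mode, this package's definition for that
switch). Widths are treated as standard deviations; the alternative
readings (variance, display diameter) differ only by reparameterization and
would not change the optimum.

**The loss.** The layout quality score is the Kullback–Leibler divergence

$$ D_{\mathrm{KL}}(P \,\|\, Q) = \sum_{p_{ij} > 0} p_{ij}
   \ln\frac{p_{ij}}{q_{ij}}, $$

normalized by the target entropy $H(P) = -\sum p \ln p$ to give the
dimensionless **normalized information loss**
$D = D_{\mathrm{KL}} / H(P)$, comparable across networks of different
sizes. $D = 0$ iff the picture reproduces the pair distribution exactly.
The normalization is this package's definition — a per-node conditional
normalization would change absolute values but cancels in the fold ratios
used for comparisons ([fold_improvement()]). When $H(P) = 0$ (a single
pair) the raw divergence is reported and flagged.

Because every overlap picks up the same factor $c^{-2}$ when positions and
widths are scaled jointly by $c$, and is unchanged by translations and
rotations, $D$ is invariant under similarity transforms: the score measures
the *shape* of a layout, not its units, origin or orientation. This also
means coordinates are unitless and no canvas convention is imposed.

## Gradients

Writing $Z = \sum o_{kl}$, the gradient of the loss with respect to any
layout parameter $\theta$ is

$$ \frac{\partial D_{\mathrm{KL}}}{\partial\theta}
   = \sum_{k<l} (q_{kl} - p_{kl})\,
     \frac{\partial \ln o_{kl}}{\partial\theta}, $$

the $q$-term arising from the normalization of Q. With
$s = \sigma_i^2 + \sigma_j^2$ and $d^2 = \lVert r_i - r_j\rVert^2$:
$\partial \ln o / \partial r_i = -(r_i - r_j)/s$ and
$\partial \ln o / \partial \sigma_i = 2\sigma_i\,(d^2/2s^2 - 1/s)$;
a self-pair contributes $-2/\sigma_i$. These are exact; the test suite
verifies every component against central finite differences at relative
error below $10^{-5}$ on random graphs in both squaring modes.

## The optimizer

Positions and widths play different geometric roles, so they are optimized
in alternating phases, by default `"PWPWP"`: position, width, position,
width, position. Each phase is full-batch projected gradient descent on
only its variables with an Armijo backtracking line search, so **every
accepted step strictly decreases the loss** and the loss trace is
non-increasing by construction. The trial step length is the
Barzilai–Borwein spectral estimate from the previous accepted step, which
in practice converges an order of magnitude faster than fixed-growth step
control while the backtracking safeguard preserves monotonicity. A phase
ends at `max_iter` accepted steps (default 500), after five consecutive
relative improvements below `rel_tol` (default $10^{-9}$; a window, because
single spectral steps can stall spuriously), or when no decreasing step
exists. Appending phases while the loss still decreases is always safe; on
the benchmark families shipped here the trace plateaus within the default
five phases.

Numerical choices that matter:

* **Width phase in log space.** Steps update $\ln\sigma_i$, so width
  changes are multiplicative and positivity is automatic. Raw-$\sigma$
  steps are catastrophically ill-scaled when a foreign layout's coordinate
  span dwarfs the initial width (the gradient components then differ by
  orders of magnitude and the line search stalls); the log
  reparameterization makes width-only scoring robust regardless of the
  source tool's units.
* **Width floor.** Widths are clamped at $10^{-6}$ of the current layout
  diameter (absolute floor $10^{-12}$), preventing degenerate
  delta-function nodes; the line search uses the projected decrement, so
  convergence at the floor is handled correctly.
* **Underflow.** Overlaps are computed in log space and floored at
  $10^{-300}$ before normalization; a layout whose *largest* overlap
  underflows aborts with a diagnostic rather than returning NaNs.
* **Initialization.** Random mode draws positions uniformly in the unit
  square under the configured seed, widths $\sigma_0 = 0.1$ (a tenth of
  the initial span — wide enough for informative gradients, narrow enough
  not to blur structure). Exactly coincident nodes are separated by a
  seeded $10^{-6}$ jitter, since a symmetric pair at zero distance has a
  vanishing position gradient and would lock. Runs are bit-reproducible
  given a seed; `restarts` reruns with derived seeds and keeps the best.
* **Pre-ordering.** A force-directed layout
  ([layout_force_directed()], Fruchterman–Reingold via igraph) is the
  recommended starting point: it shortens optimization and avoids the
  occasional mis-positioned node that a random start can leave behind.

The objective is non-convex; phases find local optima. On graphs whose
pair distribution is exactly representable (a triangle, disconnected
equal dyads) the optimizer reaches $D < 10^{-6}$ from most random seeds,
but on general graphs different seeds can land in different basins —
hence the pre-ordering recommendation and the `restarts` option.

Per-iteration cost is $\Theta(n^2)$: one overlap per node pair per loss or
gradient evaluation (the test suite asserts this by counting overlap
evaluations, not wall clock). The quadratic sums are exact — no Barnes–Hut
style approximation — which bounds practical sizes at a few thousand nodes.

## Scoring foreign layouts and comparing tools

Any fixed layout is scored by the **width-only protocol**
([score_layout()]): positions are frozen and only the node distributions
(widths, from $\sigma_0$ or the file's widths) are optimized. This gives
every tool's geometry its best achievable representation and makes scores
comparable without reconstructing the source tool's node sizes.
[compare_layouts()] applies the same protocol to every entrant — including
entropy-optimized layouts — and reports losses and fold improvements
versus the best.

A caution learned from the benchmarks below: on small networks with
well-separated modules, a converged force-directed layout is already
nearly optimal in *shape*, and the width-only protocol then recovers most
of its remaining loss, leaving modest fold differences (the acceptance
script in `scripts/` computes this ratio end to end). Large fold
improvements appear when the baseline geometry genuinely confounds modules
— the hairball regime of large dense interactomes — or when baseline widths
are not re-optimized. [module_separation()] (mean silhouette of positions
under module labels, with singleton and zero-denominator conventions set
to 0) is provided as an auxiliary geometric diagnostic; it is invariant
under similarity transforms, like $D$.

## Synthetic benchmarks

Real interactomes are not bundled; seeded generators stand in for them:

* [planted_partition()] — an equal-size stochastic block model
  ($k$ modules of $m$ nodes, within-module edge probability $p_{in}$,
  between-module $p_{out} < p_{in}$, unit or uniform weights). This
  emulates the one property the method targets — modular structure with
  ground-truth labels — at sizes (≤ 150 nodes here) where the exact
  $\Theta(n^2)$ sums run in seconds. The reference benchmark
  configurations used by the tests are 4×15 ($p_{in} = 0.4$,
  $p_{out} = 0.02$) for schedule behavior and 4×25 ($p_{in} = 0.3$,
  $p_{out} = 0.01$) for baseline comparisons.
* [ring_of_cliques()] — a deterministic worst-case-modularity toy:
  cliques joined in a ring by single bridges.

What these do **not** emulate: heavy-tailed degree distributions,
overlapping or nested complexes, degree-correlated module membership, and
the sheer size of real interactomes. Passing benchmarks here therefore
demonstrates correctness of the machinery and qualitative module
separation, not performance claims on organism-scale data.

## Known limitations

* Aesthetics (edge crossings, edge lengths) are not part of the objective;
  squared-adjacency layouts in particular can look unconventional while
  scoring well.
* The alternating scheme is a local optimizer; the schedule plateau is a
  stopping heuristic, not a global-optimality certificate.
* Only 2-D isotropic Gaussians are supported; 3-D layouts and anisotropic
  node distributions are out of scope.
* Directed and multi-graphs are not modelled; duplicate edges merge by
  weight summation, self-loops are dropped (the squared mode reintroduces
  diagonal mass explicitly and controllably).

## A worked example

```{r, eval = FALSE}
roc <- ring_of_cliques(4, 5)
fr  <- layout_force_directed(roc$graph, seed = 1)
fit <- entopt(roc$graph, init = fr, seed = 1, use_square = TRUE)
summary(fit)
module_separation(fit, roc$labels)
compare_layouts(roc$graph,
                list(entopt = fit, `force-directed` = fr,
                     random = layout_random(roc$graph, seed = 1)))
plot(fit, labels = roc$labels)
```

The same pipeline is available from the shell through the `entopt`
command (see `?entopt_cli`), which adds JSON loss reports and TSV
comparison tables for scripted use.
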