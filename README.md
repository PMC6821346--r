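# entopt — entropy-optimized network layouts

Network drawings of biological datasets — protein–protein interaction and
signalling networks above all — tend to collapse into "hairballs" in which
the functional modules (protein complexes) are invisible. `entopt` lays
networks out by information theory instead of aesthetics: it treats the
network and its drawing as two probability distributions over node pairs
and minimizes the information lost when the drawing stands in for the
network. The same quantity doubles as a quality score for *any* layout,
whatever tool produced it.

## The model

* **Target P.** Edge weights normalized to a distribution over node pairs,
  `p_ij = w_ij / Σw`. Optionally the adjacency matrix is squared first
  (`use_square = TRUE`), so that `p` reflects shared neighborhoods —
  interaction-profile similarity — which sharpens module structure; the
  diagonal of the square may be kept or ignored.
* **Representation Q.** Every node is an isotropic 2-D Gaussian with
  position `r_i` and width (standard deviation) `σ_i`. Pair affinities are
  the Gaussian overlap integrals
  `o_ij = exp(−|r_i − r_j|² / (2(σ_i² + σ_j²))) / (2π(σ_i² + σ_j²))`,
  normalized to a distribution `q` over the same pair set.
* **Score.** The Kullback–Leibler divergence
  `D_KL(P‖Q) = Σ_{p>0} p ln(p/q)`, divided by the target entropy `H(P)`,
  is the **normalized information loss `D`** — dimensionless, invariant
  under translation, rotation and uniform rescaling of the layout, and
  zero exactly when the drawing reproduces the pair distribution.

Positions and widths are optimized in alternating gradient-descent phases
(default schedule `PWPWP`) with exact analytic gradients and a
monotonicity-guaranteeing line search. Foreign layouts are scored by the
width-only protocol: positions frozen, only the node distributions
optimized.

## Worked example

Four 5-cliques joined in a ring, laid out from a force-directed
pre-ordering with the squared-adjacency target:

```r
library(entopt)
roc <- ring_of_cliques(4, 5)
fr  <- layout_force_directed(roc$graph, seed = 1)
fit <- entopt(roc$graph, init = fr, seed = 1, use_square = TRUE)
summary(fit)
#> Entropy-optimized network layout
#>   nodes: 20, edges: 44, target: squared adjacency
#>   schedule: PWPWP
#>   KL divergence: 0.137613 nats,  H(P): 4.15656 nats
#>   normalized information loss D: 0.0331074
#>   loss at phase ends:
#>     P1   iter  124   D = 0.0331667
#>     W2   iter   10   D = 0.0331222
#>     P3   iter   13   D = 0.0331109
#>     W4   iter    9   D = 0.0331081
#>     P5   iter   12   D = 0.0331074
#>   widths: [0.09852, 0.1024]
```

Only 3.3% of the target information is lost; the trace shows the loss
plateauing within the default five phases. The drawing separates the
planted modules cleanly — the mean silhouette of node positions under the
true clique labels is

```r
module_separation(fit, roc$labels)
#> [1] 0.735278
```

and scoring competing layouts of the same network by the width-only
protocol ranks them:

```r
compare_layouts(roc$graph, list(entopt = fit, fd = fr,
                                random = layout_random(roc$graph, seed = 1)))
#>   layout_name     kl target_entropy normalized_loss fold_vs_best
#> 1      entopt 0.0851           3.78          0.0225         1.00
#> 2          fd 0.0894           3.78          0.0236         1.05
#> 3      random 1.3282           3.78          0.3510        15.60
```

Here the entropy-optimized layout retains the most information (lowest
`D`); a random placement loses ~16× more. `plot(fit, labels = roc$labels)`
draws the result with nodes as circles of their fitted widths.

The same operations are available from the shell:

```sh
Rscript inst/exec/entopt generate --type ring --modules 4 --size 5 --out ring.tsv
Rscript inst/exec/entopt layout --input ring.tsv --square --seed 1 \
    --out layout.csv --report report.json
Rscript inst/exec/entopt evaluate --input ring.tsv --positions layout.csv
```

(after installation, the wrapper also lives at
`system.file("exec", "entopt", package = "entopt")`).

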