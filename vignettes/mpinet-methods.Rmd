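---
title: "Methods: network-based metabolite pathway identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based metabolite pathway identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpinet)
options(mpinet.log_level = "quiet")
```

## The problem

Metabolomic profiling reports only a small, non-random slice of the
metabolome. The metabolites that are detected — and subsequently flagged as
differential — are disproportionately the well-studied, well-connected ones
that sit in fundamental pathways (glutathione metabolism, the citrate
cycle, ...). A plain overrepresentation analysis (ORA) that treats every
metabolite as exchangeable therefore rediscovers fundamental pathways and
overlooks pathways built from *pathway-specific* metabolites: compounds
that participate in few pathways, have few functional partners able to
compensate for their dysregulation, and are rarely captured by the
instrument in the first place.

`mpinet` addresses both distortions at once. It scores every metabolite's
global connectivity in an edge-weighted functional network, models how
strongly detection/selection depends on that connectivity, and then runs a
*weighted* enrichment test in which pathways made of poorly-connected,
hard-to-detect metabolites compete on fair terms.

## The model, stage by stage

### Global connection strength and GN scores

The network is a simple undirected graph over metabolites; each edge
carries a confidence weight in (0, 1] (a combined association score
divided by 1000). The global connection strength between metabolites
$i$ and $j$ aggregates *all* walks between them, attenuated in length:

$$\mathrm{GCS}(i,j) \;=\; \sum_{L=1}^{l_{\max}} \beta^{\,L-1}\,
 \big(W^L\big)_{ij},$$

where $W$ is the weighted adjacency matrix, $\beta \in (0,1]$ is the
attenuation per additional step (default 0.5) and $l_{\max}$ caps the walk
length (default 6). This is a truncated, weighted walk-count — a member of
the strength-of-connection / communicability family — chosen because it
captures simultaneously the *number* and the *length* of the routes
connecting two metabolites, is computable by repeated matrix
multiplication, and is verifiable against an exact recursive walk
enumeration (`brute_force_gcs()`), which the test suite does on dozens of
random graphs to 1e-10. Walks, not simple paths, are counted: simple-path
enumeration is exponential and the walk-based variant is the standard one
in this family. The diagonal (self-connection) is excluded.

The GN (global nonequivalence) score of metabolite $i$ is the mean of
$\mathrm{GCS}(i,j)$ over the other $M-1$ network metabolites, zeros from
unreachable pairs included. A computational note: matrix powers densify a
sparse adjacency after very few multiplications, so a single dense code
path is used at every network size rather than a nominal sparse variant
with identical output.

### The detection-bias spline and CGNB scores

Detection and differential status are *not* independent of GN: the
better-connected a metabolite, the likelier it is to be in the profile.
Because the two factors interact, they are combined through a monotone
curve rather than an additive score. Let $y_j \in \{0,1\}$ flag the
interesting (e.g. differential) metabolites among the $M$ network
metabolites and $x_j$ be their GN scores. A cubic regression spline with
$k = 6$ knots at the equally-spaced quantiles of the GN distribution
(linear-interpolation quantiles) is fitted by penalized constrained least
squares:

$$\hat\beta \;=\; \arg\min_\beta\; \lVert Y - X\beta\rVert^2
  + \lambda\,\beta^{T} S\,\beta
  \quad\text{s.t. } \hat Y \text{ nondecreasing},$$

with $S$ the integrated squared second derivative (curvature) penalty of
the spline. The basis is mgcv's `"cr"` cubic regression spline
(values-at-knots parameterization with natural boundary conditions), which
spans constants — so degenerate all-0/all-1 label vectors are reproduced
exactly. Monotonicity is enforced as first-difference inequality
constraints of the fitted curve on a 200-point grid spanning the GN range;
at the smoothness levels reachable with six knots the cubic segments
cannot oscillate between adjacent grid points, so grid monotonicity is
curve monotonicity in practice (and every fit re-asserts it). The
quadratic program is solved with `mgcv::pcls()`, started from a strictly
increasing feasible point (knot values collinear in knot position, which
the natural-spline interpolant maps to a strictly increasing straight
line).

$\lambda$ is chosen by generalized cross-validation over a 40-point
logarithmic grid; the effective degrees of freedom use the unconstrained
penalized hat matrix, the usual approximation when inequality constraints
are present (a fixed $\lambda$ can be supplied instead). Least squares on
a binary response can leave $[0,1]$, so fitted values are clamped
post-fit; the combined global nonequivalence and bias score is then

$$C_j \;=\; 1 - \hat Y_j \in [0,1].$$

High $C_j$ marks a metabolite that is hard to detect *and* hard to
compensate — a pathway-specific metabolite that deserves extra weight.

### Weighted enrichment: Wallenius noncentral hypergeometric

For background size $N$, interesting count $n$, pathway annotated size
$m_1$ and observed overlap $g$, ORA uses the central hypergeometric tail.
`mpinet` instead gives pathway members an odds weight derived from the
pathway's relative mean detectability

$$W(P) = \frac{\mathrm{mean}_{j\in P}(1-C_j)}
 {\frac1K\sum_k \mathrm{mean}_{r\in P_k}(1-C_r)},
 \qquad w_1 = W^6,\; w_2 = 1,$$

so the mean of $W$ over the $K$ retained pathways is exactly 1 (asserted
to 1e-9 in the tests; per-pathway means and the across-pathway mean are
floored at 1e-6). Pathways rich in high-CGNB members get $W<1$, hence a
small $w_1$ and a *more surprising* observed overlap. The p-value is the
Wallenius noncentral hypergeometric upper tail

$$p = 1 - \sum_{x=0}^{g-1}\binom{m_1}{x}\binom{m_2}{n-x}
 \int_0^1 \big(1-t^{w_1/d_x}\big)^{x}\big(1-t^{w_2/d_x}\big)^{n-x}\,dt,$$

with $d_x = w_1(m_1-x) + w_2(m_2-(n-x))$ and $m_2 = N-m_1$. Numerically
the integral is evaluated after the substitution $t = u^{d_x}$, giving the
smooth Beta-like integrand $d_x\,u^{d_x-1}(1-u^{w_1})^x(1-u^{w_2})^{n-x}$;
the direct form concentrates essentially all of its mass within
$\approx[0, 10^{-9}]$ whenever $w/d_x$ is small and defeats adaptive
quadrature. Quadrature runs at relative tolerance 1e-10 in log space.
Degenerate cases are handled in closed form: $g=0$ gives $p=1$, and the
census draw $n=N$ gives $p=1$ (the overlap is then $m_1$ with certainty).
With $w_1 = w_2$ the test collapses to the central hypergeometric — the
suite verifies this exhaustively for all $(N \le 30, m_1, n, g)$ to 1e-6 —
and the p-value is monotone nondecreasing in $w_1$, which is exactly the
mechanism that promotes pathway-specific pathways. Correctness for
$w_1 \ne w_2$ is checked against an independent sequential-urn dynamic
program and Monte Carlo urn draws.

Benjamini–Hochberg adjustment is applied across all retained pathways of
the loaded collection; $K$ in the weight denominator is likewise the
retained-pathway count of that collection. Output rows are sorted by
p-value with ties broken by pathway id, so runs are byte-reproducible.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `beta` | 0.5 | walk attenuation per step (unitless); smaller = more local |
| `lmax` | 6 | maximum walk length counted |
| `knots` | 6 | spline knots at GN quantiles |
| `lambda` | `"gcv"` | spline smoothing; GCV-selected or fixed |
| `weight_exponent` | 6 | $w_1 = W^{\text{exponent}}$; 0 reduces to ORA |
| `min_pathway_size` | 3 | minimum background-annotated pathway size |
| `min_score` | 0 | combined-score cutoff when reading link files |
| `alpha` | 0.1 | raw-p threshold of the Wilcoxon differential screen |
| `fdr_cut` | 0.6 | adjusted-p cutoff of the drug-sensitivity screen |

The `min_pathway_size` default of 3 keeps the enrichment test defined for
small pathways while avoiding 1–2 member degeneracies; the network-bias
diagnostics (`pathway_gn_bias_test`) are typically run on pathways with
more than five members. The background defaults to all metabolites that
appear in at least one pathway of the collection *and* carry a CGNB score
(i.e. are in the network); an explicit background list can be supplied,
in which case members without a CGNB score contribute the background mean
of $1-C$ to their pathway's weight.

A diagnostic note on `pathway_gn_bias_test`: the rank-sum test compares a
pathway's member GN scores against the *complement* (all non-member
network metabolites) so the two samples are independent and null p-values
are exactly uniform; a pathway covering the whole network returns p = 1 by
the identical-distribution convention. Exact enumeration is used for at
most 10 tie-free members, the tie-corrected normal approximation
otherwise.

## What the synthetic generator emulates — and what it does not

`simulation_config()` + `simulate_*()` produce seeded fixtures with the
three structural features the method assumes:

* a connected, weighted metabolite network (preferential-attachment by
  default, giving the heavy-tailed degree distribution of real chemical
  association networks; Erdős–Rényi with enforced connectivity as a
  homogeneous alternative), with combined scores drawn uniformly from
  150–999;
* pathways drawn from GN-stratified pools: `specificity_mix` is the
  fraction of each pathway's members taken from the low-GN
  (pathway-specific) half of the network, the rest from the high-GN
  (common) half — default 0.5, sizes 8–15, 12 pathways, 300 nodes;
* an interesting-metabolite process whose selection probability is
  `clamp(0.1 + 0.6 * GN_norm, 0.01, 0.99)` — the documented detection
  bias, with an optional multiplier inside planted pathways.

One master seed drives three fixed substreams (network, pathways,
selection), so a config is fully reproducible while stages remain
independently re-runnable. The generator does **not** emulate abundance-
level noise, metabolite misidentification, correlated pathway membership
across databases, or the literature-driven component of detection bias;
passing the end-to-end benchmarks therefore demonstrates the statistical
mechanism (bias-corrected weighting helps exactly when pathway membership
correlates with connectivity), not field performance on any particular
platform. Problem sizes in the shipped benchmarks (networks of 60–300
nodes, 50-seed scenario sweeps, spline fits at $n$ = 5000) were chosen as
the smallest at which the asymptotic behaviour is already stable.

## Numerical choices and degenerate inputs

* duplicate link records keep the maximum combined score; self links are
  dropped and counted; weights are combined score / 1000;
* quantile knots that collide are collapsed (with `k` reduced); constant
  GN scores are rejected as a degenerate covariate;
* ties in GN receive identical fitted values by construction (the fit is
  a function of GN);
* `g = 0` pathways are reported with p = 1 rather than dropped;
* interesting metabolites outside the background are dropped from `n`
  with a logged count; pathways below `min_pathway_size` after background
  intersection are dropped with a logged count;
* all output orderings are deterministic (p-value, then pathway id).

## Known limitations

The exact strength-of-connection variant used to weight walks is one
documented choice within its family; `beta` and `lmax` are exposed rather
than asserted. GCV's unconstrained-trace approximation can oversmooth when
many monotonicity constraints are active at the optimum. The Wallenius
quadrature is exact to tolerance for the moderate weights produced by
$W^6$ on real CGNB distributions ($w_1$ roughly in $[10^{-3}, 10^{3}]$);
extreme weights outside that range were not a design target. Pathway
crosstalk uses the global off-diagonal GCS median as its edge threshold,
which is scale-free but collection-dependent.
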