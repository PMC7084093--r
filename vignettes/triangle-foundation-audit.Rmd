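---
title: "Auditing low-rank graph embeddings with the triangle foundation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing low-rank graph embeddings with the triangle foundation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trifound)
```

## The question the package answers

Complex networks are sparse (constant average degree) yet triangle-rich,
and crucially the triangles sit on *low-degree* vertices — the local
signature of community structure. A popular modelling step replaces the
graph by latent vectors $v_1,\dots,v_n \in \mathbb{R}^d$ with edge
probabilities driven by dot products, $d \ll n$. The tension: dot-product
models of low rank cannot generate graphs with many triangles among
low-degree vertices. This package turns that tension into a measurement.

The central statistic is the triangle foundation. For a degree bound $c$,
let $S_c$ be the vertices of degree at most $c$, degrees taken in the full
graph, and $T(c)$ the number of triangles induced by $S_c$. Then
$\Delta(c) = T(c)/n$ with $n$ the *total* vertex count — not $|S_c|$, so a
graph cannot look triangle-rich merely because $S_c$ is small. A graph has
a $(c,\Delta)$-triangle foundation when $\Delta(c) \ge \Delta$.

Two textual conventions had to be fixed. First, the defining phrase is
"degree at most $c$", while plot-style descriptions speak of removing
vertices of degree at least $x$; we standardize on the inclusive retain
rule (degree $\le c$) everywhere, so the curve's x axis is the inclusive
threshold. Second, membership in $S_c$ is a one-shot filter on full-graph
degrees; degrees are *not* recomputed recursively after removal. Both
choices follow the formal definition rather than the plotting shorthand.

## Computing the curve

`count_triangles()` uses the degree-ordered forward algorithm: rank
vertices by (degree, index), orient each edge toward the higher rank, and
intersect forward-neighbour lists — each triangle is found exactly once,
in $O(\sum_{(u,v)\in E} \min(\deg u, \deg v))$ for sparse graphs.
`degree_triangle_curve()` piggybacks on the same enumeration: every
triangle is tagged with the maximum full-graph degree over its corners,
and $T(c)$ is a cumulative tally over the distinct degree values present.
This makes the whole curve cost one triangle enumeration, and it provably
equals pointwise recomputation with `triangle_foundation()` — the suite
checks that identity, and checks both against exhaustive $O(n^3)$ triple
enumeration on random graphs up to $n = 60$.

Between observed degree values the curve is a step function;
`curve_at()` extends it by 0 below the smallest threshold and by the
total-triangle density above the largest. That extension is also how
replicate curves with different degree supports are merged onto a common
grid.

## The embedding and its sign signature

The spectral embedding takes the $d$ eigenpairs of the adjacency matrix
with largest $|\lambda|$ and sets $x_i = (\sqrt{|\lambda_r|}\,
\psi_r[i])_r$. Because adjacency matrices are indefinite, plain dot
products of real coordinates cannot represent the reconstruction
$A_d = \Psi_d \Lambda_d \Psi_d^\top$; we therefore carry a per-dimension
signature $\sigma_r = \mathrm{sign}(\lambda_r)$ and define the pair score
as $\sum_r \sigma_r x_{ir} x_{jr}$, which reproduces $A_d$ exactly. The
signed elementwise products $\sigma_r x_{ir} x_{jr}$ are also the LRHP
features, so spectral and file-loaded (all-positive-signature, e.g.
node2vec) embeddings flow through identical code.

Numerical choices: eigenpairs are ordered by decreasing $|\lambda|$ with
the positive eigenvalue preferred on magnitude ties; each eigenvector's
orientation is fixed by making its largest-magnitude entry positive.
Within exactly degenerate eigenspaces $A_d$ is basis-dependent, so tests
compare score matrices, never eigenvectors. At $d = n$ the eigenbasis is
complete and the score matrix equals $A$ to roughly $10^{-13}$; the suite
asserts $10^{-8}$.

External embeddings are ingested from the word2vec/node2vec text dialect
(header `n d`, then `id coord...`). File ids are matched to vertices
through the graph's original-id label map; we require that map explicitly
because nothing else pins down how file rows correspond to graph vertices
when ids are not contiguous.

## Edge models and calibration

All four models are symmetric with zero diagonal and values in $[0,1]$,
asserted property-style on random instances.

**TDP** needs no parameters: $p = \max(0,\min(s,1))$. A score of at least
1 forces the edge; a negative score forbids it.

**LRDP**, $p = L\,\sigma(k(s - x_0))$, is under-determined by its single
published constraint (match the expected edge count). Our resolution: fit
$(k, x_0)$ by logistic regression of edges against an equal-size uniform
sample of non-edges (seeded; the 1:1 ratio is configurable), constrain
$k \ge 0$ so probability is nondecreasing in the score, then calibrate
$L$. Since $\sum_{i<j} p = L \sum_{i<j} \sigma(\cdot)$ is linear in $L$,
the amplitude solution is exact in one step whenever it lands in
$(0,1]$; if matching would need $L > 1$ (the logistic fit, trained on a
balanced sample, almost always *over*-predicts the base rate, so this is
rare), $L$ is pinned at 1 and $x_0$ is shifted by monotone root finding
instead. Either way the calibration residual is at machine precision, far
inside the 1% default tolerance the fit enforces.

**LRHP** replaces the scalar score by the $d$ Hadamard features and is
ridge-regularized (`glmnet`, $\alpha = 0$, small fixed $\lambda$) because
separable planted instances make the unpenalized likelihood diverge; with
tied weights $w = k\mathbf{1}$, $b = -kx_0$ it reproduces LRDP exactly,
which the suite uses as an equivalence oracle. Amplitude calibration is
shared with LRDP.

**Softmax**: the printed form of this model's denominator omits the
exponential, but a softmax by definition exponentiates; we implement
$q(i\to j) = \deg(i)\,e^{s(i,j)} / \sum_{k\ne i} e^{s(i,k)}$ with per-row
max subtraction for overflow safety and the self-term excluded (no
self-loop mass). Rows of $q$ then sum to the true degrees *exactly*, which
is the model's calibration guarantee (asserted to $10^{-9}$). The directed
matrix is symmetrized by arithmetic mean and clamped to $[0,1]$
afterwards; clamping after averaging keeps the pre-clamp row-sum identity
clean, and the two orders differ only when some $q > 1$. An isolated
vertex yields an all-zero directed row rather than an error.

Probabilities are evaluated lazily in row blocks everywhere (fits,
expected degrees, sampling), so no contract requires materializing the
$n \times n$ matrix.

## Sampling and the replicate audit

`sample_graph()` performs one independent Bernoulli trial per unordered
pair, consuming uniforms row by row in a fixed order so the result depends
only on `(model, seed)`, not on the internal block size. Replicate $r$ of
`replicate_audit()` uses the counter-derived seed
$(\text{seed} + r \cdot 1000003) \bmod (2^{31}-1)$ — reproducible and
trivially parallelizable. The audit reports the pointwise *maximum*
$\Delta(c)$ over replicates on the merged threshold grid: a deliberately
generous aggregation, so that when the audit says density is missing, no
amount of sampling luck explains it away. Only min/mean/max edge counts
are kept per run; the sampler's second-moment property
$E[D_i^2] \le E[D_i] + E[D_i]^2$ (exact for independent pairs) is verified
empirically in the suite.

## Certificates

`rank_lemma_certificate()` evaluates
$(\sum_i M_{ii})^2 / \sum_{i,j} M_{ij}^2$, a lower bound on
$\mathrm{rank}(M)$ for any square matrix, alongside the numerical rank
(singular values above $\max(\dim) \cdot \varepsilon \cdot
\sigma_{\max}$, the standard cutoff, configurable). Equality holds on the
identity and all-ones matrices, which the tests pin.

`dot_sum_balance()` checks that negative pairwise dot mass never exceeds
positive mass over all ordered pairs including the diagonal — a direct
consequence of $\sum_{i,j} w_i\!\cdot\!w_j = \|\sum_i w_i\|^2 \ge 0$.

`packing_witness()` returns the *maximum* off-diagonal dot among $\ge 4d$
unit vectors in $\mathbb{R}^d$ (not merely some witness, so a hypothetical
violation would be maximally informative) and checks it against the
guaranteed $1/(4d)$.

`theorem1_rank_bound()` evaluates $\min(1, \alpha\Delta^4/c^9)\,
n/\lg^2 n$ under the hypotheses $c > 4$, $\Delta > 0$. The bound holds for
any sufficiently small constant $\alpha$; we fix it at the threshold value
$1/(128\cdot 3600\cdot 4^4)$ and expose it as an argument, so bound values
are reproducible. `equal_length_rank_bound()` evaluates the
equal-length-regime bound $\Delta^2/(c(\Delta^2+c^4))\cdot n$ together
with the minimum common vector length the triangle count forces: from
$\Delta n \le L^2 c^2 n$ it follows that $L \ge \sqrt{\Delta}/c$, and the
reported `L_min` is that derivation-consistent form.

## Synthetic fixtures: what they emulate and what they do not

`disjoint_cliques(m, k)` is the extremal triangle-rich sparse instance:
all triangles live on degree-$(k{-}1)$ vertices, and with $k = 3$ it
realizes $\Delta(2) = 1/3$ exactly — the canonical witness used across the
suite. `planted_triangle_graph()` overlays vertex-disjoint triangles on a
sparse $G(n,p)$ background; disjointness keeps the planted count an exact
lower bound and the degree impact at +2 per planted vertex.
`rdpg_vectors()` produces nonnegative coordinate families with all
pairwise dots in $[0,1]$ (clustered = stochastic-block-model regime,
spherical = unit-norm), so the truncated dot product equals the raw dot
and sampled block densities are predictable binomials.

These fixtures reproduce the *mechanism* — sparse, low-degree,
triangle-rich versus low-rank-sampled graphs — but not the heavy-tailed
degree distributions, degree–degree correlations, or the sheer scale of
real networks. Passing tests therefore demonstrate correctness of the
statistics, models, calibration, and the direction and rough magnitude of
the low-rank triangle loss; they do not certify the multi-order-of-
magnitude gaps seen on real million-edge networks, which require
downloading those networks and running the same audit via the CLI.

## Study sizes and defaults

The suite and the acceptance script run at sizes chosen to make every
stochastic check decisive at desk scale: 200 random graphs up to $n = 60$
against the exhaustive oracle; full-rank reconstruction up to $n = 100$;
500 random matrices for the rank lemma; $10^4$ unit-vector sets across
$d \in \{1,\dots,20\}$ for the packing bound; calibration fixtures at
$n = 200$; 500 sampling replicates for the second-moment check; and the
rank sweep $d \in \{10, 50, 150, 300\}$ with 20 replicates on the
100-triangle fixture ($n = 300$), where low-degree density is lost at
$d = 10$ and fully restored only at $d = n$. Audit defaults mirror the
headline experimental design (dimension 100, 100 replicates, density
ratios reported at $c \in \{5, 10, 25, 50\}$); the 1% calibration
tolerance, the 1:1 non-edge ratio, ridge $\lambda = 10^{-3}$, and all
seeds are exposed as arguments.

## Known limitations

* Dense eigendecomposition (`eigen()`) bounds practical graph size to a
  few thousand vertices; sparse iterative eigensolvers are a natural
  extension.
* Only undirected, unweighted simple graphs; no approximate triangle
  counting.
* LRDP/LRHP fits depend (mildly) on the non-edge sample; the seed is part
  of the model's serialized identity for exactly that reason.
* Distance-based (non-dot-product) latent space models fall outside the
  audited family and may well evade the rank bounds; the package does not
  model them.
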