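---
title: "Hub entropy diagnosis: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hub entropy diagnosis: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubdiag)
```

## The model

`hubdiag` rests on three ingredients.

**Scale-free vulnerability.** Protein–protein interaction networks are
dominated by hubs: vertices whose degree greatly exceeds the average.
Such networks tolerate random vertex failure but degrade quickly under
targeted removal of their most connected vertices. Therapeutically, an
up-regulated hub is an attractive target: inhibiting it should perturb the
malignant network strongly while drugs against non-differential proteins
mostly produce side effects.

**Network Shannon entropy.** Disorder of the connectivity distribution is
measured as $H = -\sum p \log p$. Two probability assignments are
implemented, and every result records which one was used:

* *vertex* variant: $p(v) = \deg(v) / \sum_u \deg(u)$ over vertices of
  positive degree. $H$ is maximal, $\log n_+$, exactly when the graph is
  regular.
* *degree-class* variant: $p(k) = n_k / n_+$ over observed degree classes
  $k \ge 1$, where $n_k$ is the number of vertices of degree $k$. $H = 0$
  for regular graphs; heterogeneous (scale-free) graphs score high.

Degree-0 vertices are excluded from both distributions — their probability
would otherwise be undefined — and an edgeless network has $H = 0$ by
convention. Both variants are exposed because published entropy values in
this area come on two irreconcilable scales (roughly 11.4 versus roughly
2.5 for comparable interactomes), consistent with different probability
assignments and/or bases having been used; the package refuses to combine
a survival calibration with an entropy computed under a different declared
variant unless explicitly overridden.

The two variants react to hub removal in opposite directions, which matters
for interpretation. Deleting hubs *homogenizes* the degree distribution, so
the vertex-variant entropy rises toward its regular-graph maximum, while
the degree-class entropy — a direct measure of degree heterogeneity — falls
once the hub layer is substantially depleted (the package's property tests
demonstrate this on preferential-attachment graphs with 200 vertices and 10
removals). The pipeline therefore defaults to the degree-class variant:
it is the quantity that targeted inhibition can push *down* toward a
survival threshold, and its magnitude (a few bits on interactome-scale
graphs) matches the scale of the built-in pan-cancer calibration line. On
large sparse graphs with only a handful of removals the degree-class
entropy can still move up before the hub layer is exhausted; the trajectory
is always reported so the direction is visible, and an unreachable
threshold is a first-class result, not an error.

**Entropy–survival calibration.** Across tumors, higher network entropy of
the up-regulated subnetwork accompanies lower 5-year overall survival. The
package models the relation linearly, $H = a + b \cdot \mathrm{OS}$, fitted
by *orthogonal* (total least squares) regression by default: both axes are
measured quantities, so minimizing perpendicular rather than vertical
residuals is the statistically appropriate choice. The closed-form
principal-axis solution of the $2 \times 2$ scatter matrix is used on raw,
unstandardized axes; on the built-in three-point breast-cell-line
calibration the orthogonal and ordinary fits agree to more than four
significant figures because the survival scatter dwarfs the entropy
scatter. Two published calibrations ship with the package; both are tagged
`entropy_variant = "unspecified"` because their sources do not state the
variant or base their entropies were computed under. The pan-cancer line
($y = -0.004x + 2.507$) is stored as given and never refit, since its
underlying points are not published.

Inverting the line converts a network's (post-inhibition) entropy into a
predicted 5-year OS; evaluating it at a survival goal gives an entropy
threshold, and walking the ranked hub list until the trajectory crosses
that threshold yields the recommended number of targets to inhibit.
Predictions above 100% are reported raw by default — they are read as
benefit beyond the 5-year horizon — with an optional cap.

## The differential-expression call

The caller deliberately avoids per-gene replicate tests (there is one tumor
and one control profile). Instead the *population* of per-gene RPKM
differences is modeled: differences are approximately symmetric around
zero, and after the odd signed-log transform
$s = \mathrm{sign}(d)\log_{10}(|d|+1)$ approximately normal. A normal is
fitted by moments (optionally median/MAD via `robust = TRUE`) and genes
outside the two-tailed quantile at level $\alpha$ are called. Note the
printed transform $\log_{10}(x_i + 1)$ cannot be applied to negative
differences as written; the odd extension is the unique continuation
preserving symmetry and monotonicity.

Tunable parameters:

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | two-tailed call level on the z-scale; `5e-4` selects the literal "0.05%" reading of the conventional cutoff phrase |
| `library_size` | sum of supplied counts | RPKM denominator $N$; pass the run's total mappable reads when counts cover only part of the transcriptome |
| `degree_scope` | `"sub"` | hub ranking by degree inside the up-regulated subnetwork (`"full"` ranks by whole-interactome degree) |
| `top_n` | 5 | number of candidate targets reported |
| `variant`, `log_base` | `degree_class`, 2 | entropy definition used throughout a run; echoed in every output file |

Ties in the hub ranking are broken by betweenness in the full network, then
lexicographic gene id; the ranking is a deterministic total order, so
repeated runs are byte-identical.

Degenerate inputs are handled explicitly: an exact self-comparison (every
difference zero) returns all-unchanged calls rather than an error, because
"nothing is differential" is the correct answer for identical profiles; any
other zero-variance difference distribution is refused as degenerate.
Fewer than three shared genes is an error; mismatched gene universes reduce
to the intersection with a warning.

## The synthetic-data generator

The generator exists so the full pipeline — file dialects included — can be
exercised and its statistical behavior asserted without any external
download. It emulates the *shape* of the real inputs, not their biology:

* **Interactome:** Barabási–Albert preferential attachment starting from a
  complete clique on $m+1$ vertices, each new vertex attaching $m$ edges
  with probability proportional to current degree. This reproduces the
  right-skewed, hub-dominated degree distribution of real interactomes.
  Default $n = 2000$, $m = 3$ gives mean degree ≈ 6, comparable to the
  sparsity of curated human interactome subsets, while keeping 100-replicate
  test loops cheap.
* **Expression:** control counts are log-normal around `base_mean = 500`
  reads (a mid-range RNA-seq expression level) with `noise_sd = 0.1`
  (sdlog; ≈ 10% multiplicative noise, i.e. a well-powered technical
  contrast); tumor counts use the same model with planted genes' means
  multiplied by `fold = 8`. Because non-planted genes share one mean model
  with independent noise, their tumor − control differences are symmetric
  around zero by construction — the property the differential caller
  assumes. CDS lengths are uniform on [300, 10000] bp.
* **Planting:** by default the planted up-regulated genes are the
  highest-degree vertices, so "hub" and "up-regulated" coincide and
  recovery of the planted set is the pipeline-level correctness check;
  `planted_random = TRUE` plants random-degree genes to emulate the absence
  of any degree–expression correlation (the negative control).

What the generator does **not** model: count overdispersion beyond
log-normal noise, length-dependent sequencing biases, correlated expression
within pathways, false edges or ascertainment bias in the interactome, and
any real gene identity. Passing tests therefore demonstrate the pipeline's
internal correctness and its statistical behavior under the stated
generative model — not performance on real tumor data.

A subtlety the planted-recovery tests respect: planting selects hubs by
*full-network* degree, while the default ranking scope is the up-regulated
*subnetwork*. The two scopes usually agree, but a genuine hub can land in
the subnetwork with few up-regulated neighbors and be out-ranked there by a
false-positive gene that happens to sit next to the other hubs. Mean top-5
precision/recall is asserted under the default sub-network scope; *exact*
recovery of the planted set is asserted under the matched full-network
scope.

## Numerical choices

* Entropy closed forms are asserted to $10^{-12}$; base conversion
  ($H_{10} = H_2 \log_{10} 2$) likewise.
* The TLS slope uses the stable closed form
  $b = \big(S_{yy} - S_{xx} + \sqrt{(S_{yy}-S_{xx})^2 + 4S_{xy}^2}\big) /
  (2S_{xy})$; when $S_{xy} = 0$ with $S_{xx} \ge S_{yy}$ the line is
  horizontal, and a vertical principal axis is refused as non-invertible.
* Refitting the three-point breast calibration reproduces the published
  intercept to nine significant figures and the slope to six (the seventh
  digit moves because the published entropy inputs are themselves rounded).
* Attack trajectories never mutate the input graph; random removal draws
  from an explicit seed, and no function touches the caller's global RNG
  state.
* Betweenness (Brandes, via igraph, unnormalized over unordered pairs with
  endpoints excluded) is verified in the test suite against an independent
  brute-force enumeration of all shortest paths on random connected graphs
  of up to 8 vertices.

Problem sizes in the test suite — 100-replicate loops at $n = 2000$ for
planted recovery, $n = 200$–300 for attack and correlation properties —
were chosen as the smallest scales at which the asserted statistics are
stable across seeds.

## Known limitations

* One tumor and one control profile; no replicate-based inference, no
  batch correction, no TPM/DESeq-style normalization alternatives.
* The survival calibrations are taken from their sources on entropy scales
  those sources leave unspecified; predictions on networks whose entropy
  lives on a different scale are extrapolations, and the package will
  happily report out-of-range survival values (or an unreachable
  threshold) rather than silently rescale.
* The graph is treated as undirected and unweighted; interaction
  confidence scores, orthology mapping and live database queries are out
  of scope by design (reproducible offline runs only).
* Entropy contributions of individual targets are not additive — removing
  a hub changes every remaining probability — which is why the cumulative
  trajectory, not the sum of individual drops, defines the net entropy.
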