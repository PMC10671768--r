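# hubdiag

Hub-based theranostic diagnosis from a protein–protein interaction network
and paired tumor/control RNA-seq profiles.

Cancer networks are approximately scale-free: a few highly connected
proteins (hubs) hold the signaling graph together, and removing them
degrades the network far faster than removing random proteins. `hubdiag`
operationalizes that observation as a target-prioritization pipeline for
computational biologists:

1. **Interactome in** — PSI-MITAB 2.5 or a plain 2-column edge list is
   parsed, cleaned (self-loops dropped, duplicate edges collapsed) and held
   as an undirected simple graph.
2. **Expression in** — per-gene read counts for one tumor and one control
   sample are normalized to RPKM,
   `RPKM = 10^9 · C / (N · L)`,
   with `C` the gene's read count, `N` total mapped reads and `L` the CDS
   length in bp.
3. **Differential call** — the per-gene difference
   `d = RPKM_tumor − RPKM_control` is transformed with the odd signed-log
   map `s = sign(d)·log10(|d|+1)`; a normal distribution is fitted to all
   `s` and genes beyond the two-tailed z cutoff at level α are labeled
   up- or down-regulated. This is a population-level cut on the whole
   difference distribution, not a per-gene replicate test.
4. **Hub ranking** — the induced subnetwork of up-regulated genes is built
   and its most connected members (degree, ties by betweenness
   `C_B(v) = Σ_{s≠v≠t} σ(s,t|v)/σ(s,t)`, then name) are ranked; the top
   *n* (conventionally 5) are the candidate targets.
5. **Entropy** — network Shannon entropy `H = −Σ p·log p` is computed in
   two variants over the connectivity distribution: per-vertex
   (`p(v) = deg(v)/Σdeg`) and per-degree-class (`p(k) = n_k/n₊`), in a
   configurable logarithm base. The entropy drop from removing the ranked
   hubs ("net entropy") quantifies the expected benefit of inhibiting them.
6. **Survival translation** — a linear calibration `H = a + b·(5-year OS %)`
   (orthogonal/total-least-squares fit, or taken from a published line)
   converts entropy into a predicted 5-year overall survival and into the
   number of ranked hubs whose removal brings entropy down to the
   100%-survival threshold.

A seeded synthetic-data module (preferential-attachment interactomes with
planted, fold-up-regulated hub genes) makes the whole pipeline testable
offline.

## Worked example

```r
library(hubdiag)

# synthetic study: 400-gene scale-free interactome, top-5 hubs planted
# 8-fold up-regulated in the tumor sample
ds  <- gen_dataset(n = 400, m = 2, seed = 1)
dir <- tempfile(); write_fixture(ds, dir)

res <- diagnose(interactome = file.path(dir, "interactome.tsv"),
                tumor       = file.path(dir, "tumor_counts.tsv"),
                control     = file.path(dir, "control_counts.tsv"),
                lengths     = file.path(dir, "lengths.tsv"),
                out_dir     = file.path(dir, "out"))
res
#> Hub-based diagnosis
#>   interactome: 400 vertices, 797 edges; entropy 2.399882 (degree_class, base 2)
#>   regulation calls: 11 up, 0 down, 389 unchanged
#>   top 5 hub target(s): g0001, g0007, g0004, g0006, g0020
#>   net entropy after inhibition: 2.619731 -> predicted 5-year OS -28.18%
#>   hubs needed for 100% OS: unreachable

ds$planted_up
#> [1] "g0004" "g0001" "g0007" "g0013" "g0006"
```

Reading the output: the differential caller flagged 11 genes up (the 5
planted hubs plus a few false positives at α = 0.05); four of the five
top-ranked subnetwork hubs are planted ones. The survival translation uses
the built-in `pancancer-2019` line (`H = −0.004·OS + 2.507`), whose entropy
scale belongs to the interactome it was calibrated on — on an arbitrary
synthetic graph the predicted OS and the "unreachable" threshold flag
demonstrate the mechanics (and the honest failure mode the package reports
when a calibration and a network live on different scales), not a clinical
estimate. Predictions above 100% or below 0% are reported as-is unless
capped.

The calibration itself reproduces the published breast-cell-line fit:

```r
fit <- fit_survline(read_calibration_points(
  system.file("extdata", "breast_cell_lines_calibration.tsv",
              package = "hubdiag")), method = "tls")
fit
#> Entropy ~ 5-year-OS calibration (tls)
#>   entropy = -0.000545267909573 * survival_pct + 11.4731986188
#>   fitted on 3 points
#>   entropy variant: unspecified
predict(fit, 11.4332400)   # triple-negative mean entropy
#> [1] 73.28254
```

A thin command-line front end wraps the same functions:

```sh
exec/hubdiag simulate --n 2000 --m 3 --planted 5 --fold 8 --seed 1 --out fix/
exec/hubdiag diagnose --interactome fix/interactome.tsv \
    --tumor fix/tumor_counts.tsv --control fix/control_counts.tsv \
    --lengths fix/lengths.tsv --calibration pancancer-2019 --out run/
exec/hubdiag calibrate --points calibration.tsv
```

Exit codes: 0 success, 2 "no targets found" (a valid biological outcome,
e.g. tumor ≡ control), 1 error.

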