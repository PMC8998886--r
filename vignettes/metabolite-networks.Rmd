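---
title: "Predicting metabolite abundances from transcriptomics with correlation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting metabolite abundances from transcriptomics with correlation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabnet)
```

## The problem

Paired metabolome/transcriptome datasets are rare and small; expression-only
datasets are plentiful. When both layers are co-measured across enough
samples, the correlation structure between metabolite abundances and
transcript levels is strong enough to act as a transferable predictor:
learn a metabolite–transcript network once, then score any expression
dataset for the relative abundance of each network metabolite. `metabnet`
implements that pipeline — network inference, prediction, and the
validation designs used to decide whether a network's predictions are
trustworthy — together with a simulator that provides ground truth for all
of it.

## The network model and its assumptions

The network is strictly bipartite-hubbed: metabolites are hubs, transcripts
are leaves, and an edge asserts a *direct* monotone co-variation between a
metabolite's abundance and a transcript's expression across samples.
"Direct" is operationalized, not mechanistic: the pipeline assumes

* linear (Pearson) association is an adequate screen — expression must
  therefore be pre-normalized (variance-stabilized or log-scale; raw counts
  are out of scope), and metabolite values on a scaled arbitrary-unit scale;
* indirect associations arise chiefly through *other metabolites*, so the
  Data Processing Inequality is applied to
  metabolite–metabolite–transcript triplets only. Indirectness through
  unmeasured factors or transcript–transcript chains is not modeled;
* sampling noise on edges can be quantified by resampling: the bootstrap
  likelihood ℓ = k/B is both a stability weight and the mechanism for
  recovering edges that full-data DPI removed for fragile reasons.

Inference proceeds in three stages (`candidate_edges`, `dpi_prune`,
`bootstrap_likelihood`, composed by `infer_network`):

1. **Gate.** Every metabolite×transcript and metabolite×metabolite pair is
   tested; pairs with two-sided `p <= p_threshold` (raw, default 0.001) and
   `min_pairs >= 10` complete observations are kept. P-values come from the
   exact t-tail formula `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df;
   `|r| = 1` maps to `p = 0`. The gate is deliberately *not* FDR-corrected:
   the bootstrap stage, not the gate, carries the burden of edge
   reliability, and the downstream enrichment statistic tolerates a few
   false edges with small weights. BH correction is applied where results
   are *reported* (prediction contrasts, evaluation tables).
2. **DPI.** For each triplet whose three correlations all passed the gate,
   the metabolite–transcript edge with the strictly lowest `|r|` is
   flagged. Strict inequality means exact ties keep all edges — a tolerance
   knob was considered and rejected because it adds a parameter the rest of
   the pipeline cannot calibrate. Flags are computed against the original
   candidate set in one pass (no cascading), which makes the operation
   order-independent and exactly matched by a brute-force triplet
   enumeration oracle in the tests. Note the rule's one subtlety: when the
   metabolite–metabolite correlation is itself the lowest of a triplet,
   nothing is removed, since only metabolite–transcript edges are network
   edges.
3. **Bootstrap.** `B` resamples of the sample set (with replacement, full
   size, one seeded stream). Candidate pairs — and only those — are
   re-tested in each resample; support requires passing the p-gate *and*
   surviving DPI re-evaluated within that bootstrap. Whether corto-style
   pipelines re-gate on the per-bootstrap p or the full-data p is a genuine
   open choice; per-bootstrap gating is implemented because it is the only
   variant under which "DPI-removed but bootstrap-supported" recovery is
   coherent. Recovery quorum is ≥ 1 supporting bootstrap. A full-data
   survivor with zero bootstrap support keeps likelihood 1/B rather than 0,
   so no stored edge silently vanishes from the enrichment weight; a pair
   that becomes constant within a resample simply counts as unsupported
   there.

## Prediction as rank-based enrichment

Applying a network to new expression data reduces each expression state to
a **signature** and aggregates each metabolite's neighborhood:

* *Sample mode:* per-gene z-scores against the dataset's own mean and sd
  (n − 1 divisor) — each sample is scored relative to the dataset mean, so
  predictions are relative, not absolute, abundances. Zero-variance genes
  are dropped.
* *Contrast mode:* Welch t-statistics between two groups over the gene
  intersection. Welch was chosen over the pooled-variance t because the
  two-group use case routinely has tiny, unbalanced groups with unequal
  variances; genes constant in both groups score 0 with a warning.

Signature scores are rank-transformed to normal quantiles
`q = qnorm(rank / (G + 1))` with average ranks for ties; the rank pool is
*all* signature genes, so targets are ranked against the transcriptome
background, not against each other. Each metabolite's score is

    NES = sum(w * q[targets]) / sqrt(sum(w^2)),   w = r * likelihood

The normalization makes NES exactly standard normal for a random signature
when targets are sampled without structure (the quantile grid has variance
slightly below 1 at finite G, which is visible as an NES sd of ~0.99 at
G = 500 in the calibration test); `p = 2 * pnorm(-abs(NES))`. Because the
enrichment-score formula behind this family of master-regulator methods is
a contract rather than a published equation, this closed form — signed
correlation × bootstrap likelihood as the weight, root-sum-square
normalization — *is* the package's documented contract, and the null
calibration and invariance properties (weight-scale invariance, signature
negation equivariance, target-order invariance) are tested directly.

`minsize` (default 10, boundary inclusive) counts a metabolite's network
targets that are *measured in the prediction dataset* (matched by
normalized exact name), not targets in the network; metabolites under the
gate are reported as skipped with the reason, never as NES 0.

## Validation designs

* **Split-half:** repeated random partitions, `floor(n/2)` training
  samples, network inferred per split, sample-mode prediction on the test
  half, per-metabolite Pearson r recorded (NA when skipped). Inner networks
  default to the same settings as full inference; the tests and the
  acceptance study run 50 splits with B = 10 inner bootstraps, which keeps
  a full study in the tens of seconds at n = 300 while the r distributions
  are already stable.
* **Cross-dataset:** predict dataset B from a network trained on dataset A;
  per-metabolite r, BH-FDR, and significance classes at α = 0.05, plus a
  one-tail Wilcoxon signed-rank test that the r distribution sits above 0.
  Classes are assigned on BH-adjusted p by default with a nominal-p class
  reported alongside, because figure-level conventions in this literature
  use the nominal rule while the blanket methods statement prescribes BH —
  both are exposed rather than silently picking one.
* **Shuffled-network null:** each edge's transcript endpoint is redrawn
  from the multiset of endpoints (probability proportional to degree, with
  replacement), preserving per-metabolite edge counts, r, ℓ, and DPI flags.
  Collisions on (metabolite, transcript) are redrawn up to 100 times and
  then dropped with a warning — the sampling law is the specified part; the
  collision policy is this package's choice and is logged when it fires.
  Predictions under shuffled networks should be uncorrelated with measured
  values; the acceptance study checks both that and the rank-sum dominance
  of real-network r over shuffled-network r.

## The simulator

`build_ground_truth` + `simulate_dataset` implement a linear-Gaussian
latent-factor model: latent activities `a ~ MVN(0, C)` with a coupling
correlation matrix `C`; metabolite value `a_m + N(0, sigma_m^2)`; each
planted target `s * beta * a_m + N(0, 1)`; background transcripts iid
N(0, 1). The closed form

    rho = s * beta / sqrt((1 + sigma_m^2) * (beta^2 + 1))

makes every planted edge's expected correlation analytic, which the tests
verify empirically at n = 5000. Coupling `C[m1, m2] > 0` induces indirect
metabolite–transcript correlations `C[m1, m2] * rho` — exactly the
structure DPI exists to remove.

Default study conditions (chosen once, as a desk-scale analog of the
real-use regimes: hundreds of co-measured samples, tens of metabolites,
top-pair correlations in the 0.3–0.8 band): 20 metabolites × 20 targets,
`beta ~ U(0.8, 1.2)` with `sigma_m = 0.5` (rho ≈ 0.56–0.69), 25% negative
signs, 100 background transcripts, independent latents in the base
scenario, coupling 0.9 in the DPI-specificity scenario, n = 300 training
and n = 57 held-out samples. What the simulator deliberately does **not**
emulate: heavy-tailed or nonlinear abundance relationships, batch effects,
platform-specific or missing-not-at-random metabolite dropout, and
name-harmonization noise across platforms. Passing tests therefore
demonstrate that the machinery recovers planted linear structure under
Gaussian noise at realistic scales — not that any particular real dataset
has such structure.

## Numerical and edge-case choices

* Pairwise-complete correlation handles missing values; no imputation is
  invented. Pairs with < 3 complete observations, or zero variance, return
  a not-computable marker and are skipped, never raised, during scans.
* Feature-name harmonization is exact after case/whitespace/underscore
  normalization; fuzzy matching is refused by design, so an empty overlap
  is a valid (and diagnosable) outcome.
* All randomness — bootstraps, splits, shuffles, simulation — flows through
  per-stage seeds drawn from one seeded stream; every stage is bit-identical
  under a fixed seed and restores the caller's RNG state.
* Network files are 6-column TSV with 17-significant-digit serialization
  plus a JSON metadata sidecar, so write → read is value-exact.
* The Wilcoxon summary uses the exact signed-rank distribution for n ≤ 25
  when absolute values are untied and the continuity-corrected normal
  approximation otherwise (ties force the approximation, as in base R).

## Limitations

DPI over metabolite-anchored triplets cannot remove indirectness of higher
order or through transcripts; partial-correlation or causal extensions are
out of scope. Predictions are relative scores (NES), not concentrations,
and contrast NES p-values inherit the usual caveats of an analytic null on
finitely many ranked genes. Cross-platform application stands or falls
with feature-name harmonization, which is intentionally conservative.
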