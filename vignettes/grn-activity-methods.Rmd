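---
title: "Methods: network assembly, conservation scoring and TF activity estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network assembly, conservation scoring and TF activity estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnest)
```

# Scope and model

`grnest` builds weighted, unsigned TF → target networks for organisms where
most regulation acts through promoter-proximal binding, and estimates TF
activities from differential-expression (DE) signatures against such a
network. This vignette documents the models, the tunable parameters with
their defaults and rationale, the numerical choices, what the synthetic
generators do and do not emulate, and the open design decisions we resolved.

# Promoter windows

A gene's promoter is a fixed window around its annotated gene-level TSS:
`upstream = 1000` bp and `downstream = 200` bp (defaults throughout). In
0-based half-open coordinates a plus-strand gene with TSS `t` owns
`[t - upstream, t + downstream)`; a minus-strand gene owns
`[t - downstream + 1, t + upstream + 1)`. The ±1 placement of the
downstream flank on the minus strand is a declared convention (annotation
conventions differ and nothing downstream depends on the choice); what does
matter, and is tested, is that every complete window has length
`upstream + downstream` and that minus-strand sequences are
reverse-complemented so position 0 is always the most upstream base.
Windows truncated by a chromosome edge are flagged incomplete and must be
excluded from cross-species sets, where a truncated window would bias the
best-match score downward.

Candidacy filters are inputs, not computations: a `detection_fraction`
(fraction of reference expression samples detecting the gene, threshold
2/3) selects robustly expressed targets, and any `operon_downstream*` flag
removes genes transcribed inside polycistronic units, which are not
controlled by their annotated proximal promoter. Keeping these as
annotation columns keeps the toolkit free of any expression-data download.
Overlapping promoters are deliberately not deduplicated: a ChIP peak in an
overlap region is evidence for every overlapping promoter.

# ChIP evidence and HOT regions

Peaks are assigned to all promoters they overlap by at least one base
(half-open arithmetic; an abutting peak does not overlap). Per TF, targets
are ordered by (1) the number of distinct experiments with a hit on that
promoter, (2) the maximum narrowPeak `signalValue`, (3) gene id — a total,
deterministic order. The full peak interval is used, not the summit,
because promoter-level overlap is the assignment unit.

High-occupancy-target (HOT) regions — loci bound promiscuously by large
numbers of TFs — confound target attribution. Regions are annotated with
the number of *distinct* TFs binding them in any experiment (repeat
experiments of one TF count once, so consistently assayed TFs do not
manufacture HOT calls), and any target whose promoter overlaps a region
with at least `hot_cutoff = 50` distinct TFs is excluded. The comparison is
`>=`; strictness at the boundary is a declared choice, pinned by tests.
HOT regions can be supplied externally or derived by merging all peak
intervals into maximal blocks — both paths fill the same table, which keeps
testing download-free. ChIP regulons default to *no* size cutoff (with HOT
exclusion on), the combination that benchmarks best for this evidence type.

# Motif evidence

Motifs are position frequency matrices; scanning scores are log2 likelihood
ratios against a 0-order background after mixing `pseudocount = 0.01` of
background mass into each cell. The match p-value — the probability that a
random L-mer drawn from the background scores at least as high — is
computed exactly by convolving the per-position score distributions after
discretizing scores to `precision = 1e-3`; tests require bit-level
agreement with exhaustive 4^L enumeration under the same discretization.
The scanning threshold defaults to `p_threshold = 1e-4`, the conventional
scanner default (the choice is not dictated by the method). Windows
containing ambiguous bases are never reported. Overlapping matches are all
retained — homotypic scoring is meant to count clustered sites — and ties
in best-match ordering break by lower p-value then gene id.

The homotypic score combines multiple matches in one promoter with
exponentially diminishing returns:

H = m₁ + m₂/5 + m₃/5² + …

with the base `diminishing = 5` selected by benchmarking. Regulons are
built per TF from the top `cutoff = 1000` promoters ordered by the best
single match (the default; homotypic ordering helps only at very small
cutoffs and is available as an option).

Motif-collection hygiene (`resolve_motif_map()`) enforces one motif per TF:
indirect motifs inferred from another focal TF's directly measured motif
are dropped, and a motif assigned to several TFs must be resolved by a
user-supplied preference — selection criteria such as similarity score and
expression are judgments we do not automate. De novo motif discovery itself
is out of scope; the conservation machinery accepts any per-TF motif,
including externally discovered ones.

# Cross-species conservation

Individual promoter motifs turn over quickly in evolution, but selectively
important TF-target interactions retain (or regain) the motif in
orthologous promoters. The scoring is alignment-free. For each TF, target
and congeneric species, the best significant match score in the one-to-one
orthologous promoter is recorded: `NA` when the orthologous promoter is
absent (or the TF itself has no orthologue in that species — conservation
is meaningless where the trans-factor is missing), `0` when present but
unmatched. Within each (TF, species), scores become rank-quantiles: best =
1/N, ties get mean ranks, no-match = exactly 1, with N the number of
matched promoters. The conservation score is the product of quantiles over
non-missing species; the focal species does not enter the product — it
contributes through the initial focal score cutoff instead, so the product
measures *additional* cross-species support.

Significance: within each species, quantiles are shuffled among the targets
non-missing in that species, preserving the per-species score distribution
and each target's species count; each target's observed product is compared
to its own null over `iterations = 10000` shuffles (tests and the
acceptance script use 2,000, which bounds the attainable p at ~5e-4 —
ample for an FDR threshold of 0.8). The estimator is add-one,
`p = (1 + #{null ≤ obs}) / (1 + B)`, so p is never 0; ties count, so a
uniquely best target can slightly exceed 1/(1+B) when a permutation
reassembles its own quantiles. Benjamini–Hochberg FDR is applied within
each TF's target list (a per-TF decision matches per-TF regulon
construction; global adjustment is available via `fdr_scope`).

The conservation-filtered motif regulon takes each TF's top
`initial_score_cutoff = 1000` focal targets, keeps those with
`fdr ≤ 0.8` — deliberately permissive, because the permutation FDRs are
conservative — and orders by FDR then score. For ChIP, conservation
*re-orders* targets (most conserved first, original priority as
tie-break) without changing membership; cutoffs are applied afterwards.

# Network assembly

Evidence regulons are combined unfiltered — a TF below the 15-target
threshold in every single source can still clear it by pooling — and the
minimum-regulon filter runs once, after combination. Weighted combination
assigns exactly 0.33 / 0.67 / 1.0 for support by 1 / 2 / 3 evidence types
(stored as printed, not as thirds, so files round-trip bit-for-bit; weights
are not renormalized for TFs absent from some evidence types). Duplicate
edges merge by unioning evidence labels and keeping the best rank — ranks
are source-local, integration only needs membership. Three recipes:

| recipe | ChIP component | motif component | size cap |
|---|---|---|---|
| `celest` | HOT-excluded, no cutoff | top-1000 best match | — |
| `orthcelest` | HOT-excluded, conservation-ordered, cut 1000 | conservation-filtered (FDR 0.8) | smaller regulons |
| `maxcelest` | no HOT exclusion, conservation-ordered, cut 500 | top-1000 best match | maximal TF coverage |

All recipes add the eY1H interactions, weight, and filter at
`min_targets = 15`.

# Activity estimation

Signatures are genes × experiments matrices of signed DE statistics. The
design matrix holds edge weights; genes targeted by no TF stay in the
regression, informing the intercept and residual variance. Estimators:

- `ulm`: per-TF OLS of y on [1, xₜ]; score = slope t, df = G − 2.
- `mlm` (default): one OLS of y on [1, X]; score = per-coefficient t,
  df = G − T − 1. Can disentangle TFs with overlapping regulons; requires
  G > T + 1 and full column rank (rank deficiency is reported naming
  duplicate regulons).
- `wsum`: raw weighted sum Σ w·y, plus a z-score against a null permuting y
  across genes (`permutations = 1000`, seed-controlled; the count is a
  pragmatic default, not a published value).
- `consensus`: per-experiment, per-method scores are standardized across
  TFs and averaged; p is two-sided standard normal on the consensus z.
  This simple definition is declared, the reference frameworks'
  internals being unspecified for our purposes.

t-statistics are invariant to shifting y by a constant and to rescaling all
weights — properties the tests assert. P-values floor at the smallest
positive double; geometric means are computed in log space. Meta-analysis
across the experiments of one condition z-scores each experiment's
activities across TFs, then reports each TF's mean z and geometric-mean p.

# Benchmarking

Gain (overexpression) signatures are negated so every perturbation is
loss-like. All (experiment, TF) activity scores are pooled into a single
ranked list — one AUROC/AUPRC per network-method pair — with classifier
value = −score (the perturbed TF should be most negative); |score| ranking
is available by flag. AUROC uses the tie-aware rank-sum formula; AUPRC is
step-wise average precision over the full pool with no negative
down-sampling, which keeps it deterministic (a down-sampled variant exists
behind a seeded flag). Experiments whose perturbed TF is missing from the
network are dropped and counted. Null performance evaluates 100
independently shuffled networks (target column permuted; per-TF regulon
sizes and weight multisets preserved; duplicate collisions re-drawn) and
reports mean ± SD per metric.

# Synthetic data: what it emulates, what it does not

The generators produce every input with recorded ground truth: consensus
motifs (0.85 consensus-base probability per column, length 8); focal and
congeneric genomes laid out as evenly spaced genes on one chromosome with
promoters drawn i.i.d. from the base composition (uniform default; an
AT-rich preset 0.32/0.18/0.18/0.32 stress-tests p-value calibration);
conserved targets carrying the consensus in the focal promoter and in each
species independently with probability 6/7 against 15% orthologue dropout
(the conserved-versus-absent contrast the conservation scoring is designed
to detect); decoy targets with focal-only implants; ChIP peaks with
lognormal signal, jittered repeat experiments and designated HOT
promoters; and perturbation signatures y = Xa + ε with one perturbed TF
per experiment (|a| = 3, σ = 1; defaults 2,000 genes, 50 TFs, regulons of
100, 50 experiments, 25% gain direction). Implant positions are uniform
within the window, avoiding the first and last L bases, to dodge edge
truncation.

Not emulated: realistic evolutionary sequence change (indels, phylogenetic
correlation between species — species are independent given the implant
pattern), transcript isoforms, operon structure, peak-calling noise, or
read-level data. Passing tests therefore demonstrate correctness of the
algorithms and calibration of the statistics under the stated generative
model, not performance on real genomes.

# Fixture scales and numerical choices

The test suite and `scripts/acceptance.R` use these problem sizes, chosen
as the smallest scales at which each property is cleanly measurable:
linear-model oracle checks on 100 (tests) / 50 (script) random instances
with G ≤ 200, T ≤ 10 at tolerance 1e-8; PWM p-value enumeration for motifs
of L ≤ 6; perturbation recovery at the full default scale (2,000 genes, 50
TFs, 50 experiments, 100 shuffles); conservation recovery on a 7-species
family of 150 genes, 4 TFs, 20 conserved + 20 decoy targets per TF with
2,000 permutation iterations; and null calibration on 500 unrelated
targets. Synthetic conservation analyses scan at `p_threshold = 1e-3`
rather than 1e-4: with 1.2 kb promoters a 1e-4 threshold leaves most
random promoters unmatched, collapsing the rank-quantiles onto the no-match
atom, whereas 1e-3 exercises the continuous part of the statistic that
real multi-kb scans encounter. Conservation p-values use 2,000 iterations
in tests (10,000 remains the analysis default).

Other numerics: PWM scores discretized at 1e-3 (error ≤ L/2 · 1e-3, far
below score differences of interest); deterministic tie-breaks everywhere
(documented per module); degenerate inputs — empty regulons, all-missing
conservation rows, zero-variance design columns — are dropped with
messages or raise informative errors rather than propagating NaN.

# Known limitations

Networks are unsigned; repressors surface as negative activities rather
than signed edges. The background model for scanning is 0-order. The
multivariate model assumes homoscedastic residuals across genes.
Conservation treats species as exchangeable and independent; a
phylogeny-aware null would be stricter. Benchmark AUPRC depends on pool
prevalence, so comparisons are meaningful only at matched benchmark
composition.
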