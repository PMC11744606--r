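---
title: "pHLA surface similarity and TCR cross-reactivity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pHLA surface similarity and TCR cross-reactivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phlacross)
```

## The model

T-cell receptors engage the composite surface of a peptide bound in the
HLA-I groove. The working hypothesis of this package is that similarity of
that surface — summarized either by per-residue charge/position/radius
features of the docked complex or by the electrostatic colouring of its
rendered image — predicts which epitope pairs a single TCR can
cross-recognize. The package therefore provides two distance layers and a
set of statistical procedures on top of them; it deliberately does not
perform docking, Poisson-Boltzmann electrostatics, rendering, or binding
prediction. Those stages are consumed as inputs (PQR structures, RGBA
renders, assay tables) or emulated by the synthetic generator.

### Structured features

Per-atom PQR records are averaged into one row per residue (unweighted
arithmetic means of charge, radius and coordinates — atoms are pseudo-atoms
of equal standing, so no mass weighting is applied). Three scopes filter the
residue table:

* `PHLA` — all rows (384 under the fixed 276 + 99 + 9 template topology);
* `EC_PHLA` — epitope plus HLA heavy-chain residues numbered <= 180 (the
  extracellular, TCR-facing portion; 189 rows), dropping
  beta-2-microglobulin. The rule is applied to the stored residue number
  as-is: the numbering is assumed 1-based and template-contiguous, and if a
  deposited structure had gaps the literal `<= 180` cut would still be
  used;
* `EPITOPE` — the nine peptide rows.

Feature vectors concatenate any subset of {charge, XYZ, radius} row by row.
Components are deliberately **not** standardized: charges are O(1) in
elementary-charge units while coordinates are tens of angstroms, so mixed
vectors are dominated by geometry. This mirrors the raw-concatenation
behaviour of the upstream analysis; the caveat is documented here rather
than silently "fixed", and charge-only vectors are available where a
charge-driven signal is expected. Anchor trimming removes epitope positions
2 and 9 (1-based; the HLA-binding anchors hidden from the TCR) after
aggregation — trimming before or after aggregation is equivalent for
per-residue means.

### Image composite and mask

Renders are decomposed into red/green/blue/alpha matrices in [0, 1]
(stored width x height; a 640 x 480 render gives four 640 x 480 matrices).
"Transparency" is read as the stored alpha channel (opaque = 1), so the
composite `red - blue + alpha` rewards opaque red (negative potential) and
penalizes opaque blue (positive potential), ranging over [-1, 2].

The informative-pixel mask keeps pixels whose composite standard deviation
across epitopes strictly exceeds the median of all per-pixel SDs (ties at
the median are dropped), intersected with a centered rectangle covering
`central_fraction` (default 0.5) of each axis — the contact zone facing the
TCR. The median is computed over all pixels first and intersected second;
with a continuous SD distribution and full central region the mask keeps
essentially half the pixels. Synthetic sequence variants can be excluded
from the SD pass so that near-duplicate images do not bias the variance
estimate.

### Distances

Image space uses the Canberra distance, `sum |a-b| / (|a|+|b|)` with 0/0
terms contributing zero — each pixel contributes at most 1, making the
distance robust to the many near-zero background pixels. Feature space uses
the Euclidean distance. Multi-perspective distances concatenate the masked
pixel vectors of the five views (top and +-10 degree tilts about x and y)
before a single Canberra computation, which equals the sum of per-view
distances.

### Statistics

* Cross-reactive CDR3 sets: records grouped by paired alpha/beta CDR3 key
  (single-chain grouping available); groups with >= 2 distinct epitopes
  qualify. Distinctness is exact string inequality.
* Target-vs-pool distance comparisons: two-sided Wilcoxon rank-sum with
  normal approximation and tie correction (sample sizes here make the
  approximation standard), medians, and Cohen's d (pooled SD; rank-based
  variant available).
* Activation associations: Spearman by default (two-sided, unadjusted);
  the feature-combination scan flags p < 0.05 per configuration without
  multiplicity adjustment, matching the exploratory reporting style it
  reproduces.
* Embedding regression: images are flattened (masked pixels), embedded with
  PCA (deterministic default) or UMAP via uwot (`n_neighbors = 30`,
  `min_dist = 0.3`, fixed seed — hyperparameters chosen once since the
  upstream choice is unreported), then the readout is regressed on the
  dimensions by OLS; the overall F-test p-value and per-dimension Pearson
  correlations are reported.
* Pool comparisons: Kruskal-Wallis across origin-pair classes; the
  closest-match rule labels a tumor epitope by whichever pool holds its
  nearest neighbour, with exact ties reported as `Tie` rather than silently
  assigned; the census percentage is printed at 2 significant figures and
  contingency percentages at 1 decimal, following the table style of the
  outputs they reproduce.
* Amino-acid classes default to Acid {D,E}, Basic {K,R,H}, Polar
  {S,T,N,Q,Y}, Neutral {G,P}, Hydrophobic {A,V,L,I,M,F,W,C} — an
  approximation of the five-class scheme, overridable via `class_map`.
* Atchley factors are embedded verbatim to 3 decimals (five factors per
  residue: polarity/accessibility, secondary structure, size, codon
  composition, charge).

## The synthetic generator

`synthetic_config()` fixes the study conditions: 989 self, 987 viral and
133 tumor epitopes (the modeled-cohort sizes), the 276 + 99 + 9 template
topology, 640 x 480 renders from five perspectives, and a non-positive
activation slope. Everything is a pure function of (config, seed).

What it emulates, and how:

* **Structures** — a fixed scaffold (HLA heavy chain and B2M) plus a
  peptide along the groove axis at ~3.3 A spacing. Each peptide residue
  carries its net charge at pH 7 (D/E -1, K/R +1, H +0.1, others 0) split
  over 2-4 pseudo-atoms with identity-dependent side-chain geometry. The
  scaffold is charge-neutral by design: every inter-structure difference —
  in feature space and on the rendered surface — is attributable to the
  peptide, which is the planted signal the pipeline stages are tested
  against. Real pHLA structures violate this (the HLA surface contributes
  charge texture and docking jitter), so passing tests demonstrate correct
  recovery of peptide-driven signal, not performance on crystallographic
  data.
* **Renders** — 2-D Gaussian splats of the extracellular residues, negative
  charge mapped to red, positive to blue, neutral to white, alpha = 1
  inside the molecular footprint, intensities clamped symmetrically (the
  +-10 kT analogue). This is not a solvent-excluded surface; it preserves
  exactly the properties the pipeline measures (localized, signed,
  position-attributable colour), and it emits the per-position pixel
  regions that the variant difference map needs.
* **TCR tables** — planted promiscuous CDR3s recognizing 12 and 10 epitopes
  that share residues at positions 3/6/7 but are otherwise random (most
  pairs <= 33% identical), smaller cross-reactive sets, background
  singletons, and decoys each failing exactly one study filter.
* **Assays** — `readout = max(0, intercept + slope * distance + noise)`;
  the default intercept keeps readouts positive over the observed distance
  range.
* **Pools** — unique anchor-compatible nonamers (P2 in {L, M}, P9 in
  {V, L, I}); the census overlap is planted exactly
  (`round(shared_fraction * n_self)` self sequences copied into the viral
  pool); multiplicities are geometric with the viral pool less redundant;
  tumor epitopes are conservative one-residue variants (same net charge,
  similar size, non-anchor position) of parents drawn 60/40 from the self
  and viral pools. The default `shared_fraction = 0.01` is a scaled overlap
  rate chosen once so the planted intersection is non-degenerate at the
  modeled-cohort size; the full-proteome census rate (< 0.2%) would round
  to zero sequences at n ~ 1000.

## Numerical choices and degenerate inputs

* Canberra 0/0 terms contribute 0; identical composites give an empty
  variability mask (strict inequality against a zero median).
* Chain-role assignment: explicit rules override a length heuristic (unique
  9-residue chain = epitope, longest = HLA, remainder = B2M); ambiguous or
  absent nonamer chains are errors, never guesses.
* Constant readouts or distances raise an explicit undefined-correlation
  error rather than returning 0.
* Extreme-pair ranking breaks distance ties by canonical pair id, making
  the output order-stable.
* PQR round trips are exact at 3 decimals (coordinates) and 4 decimals
  (charge, radius).
* Seeds: every stochastic routine takes or derives from a single integer
  seed and restores the caller's RNG state.

## Problem sizes

The test suite and the acceptance script run the full pipeline at reduced
but non-trivial sizes chosen as the package's own desk-scale defaults:
64 x 48 to 160 x 120 renders (640 x 480 where the shape itself is checked),
pools of 300-2000 sequences, 100-150 variants per assay, 100-1000
resampling repetitions. Statistical calibration uses 500-replicate nulls
and a 10 000-permutation oracle on small samples.

## Known limitations

* The generator's geometry is schematic; no claim of physical realism is
  made and absolute distance values are not comparable to those computed
  from crystallography-derived renders.
* Percentages and identity statistics assume the 20-letter amino-acid
  alphabet; non-standard residues are rejected, not translated.
* The census treats pools of one uniform peptide length per call; mixed
  lengths must be split by the caller.
* Database-version-dependent counts (total CDR3 pairs, proteome-wide binder
  counts) are outside the package's scope; only their arithmetic
  (percentages, contingencies) is reproduced.

## Worked pipeline

```{r pipeline, eval = FALSE}
cfg <- synthetic_config(seed = 1, image_size = c(160L, 120L))
st <- generate_phla_structure("ALWGPDPAA", cfg)
rows <- aggregate_residues(st)
nrow(apply_scope(rows, "EC_PHLA"))   # 189

img <- render_surface(st, "TOP", cfg)
fv <- build_feature_vector(rows, "EPITOPE", c("c", "XYZ"),
                           epitope_id = "ALWGPDPAA")
```

The numbered scripts under `analysis/` chain these calls into the full
study: simulate inputs, build features and distances, recover
cross-reactive CDR3s, associate activation readouts, and compare the
self/viral/tumor pools.
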