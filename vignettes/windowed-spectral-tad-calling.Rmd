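---
title: "Windowed spectral clustering for hierarchical TAD calling"
author: "EigenTAD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed spectral clustering for hierarchical TAD calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EigenTAD)
```

## The model

A chromosome-level Hi-C experiment yields a symmetric contact matrix $C$
binned at resolution $r$: entry $C_{ij}$ counts observed contacts between
genomic bins $i$ and $j$. Topologically associated domains (TADs) are
contiguous runs of bins with enriched internal contacts, visible as blocks
on the diagonal. EigenTAD treats $C$ as the adjacency matrix of a weighted
graph and segments the diagonal by spectral clustering, reading TAD
boundaries off gaps between consecutive rows of the leading eigenvectors.

Within each window the steps are:

1. **Laplacian.** Compute the symmetric normalized Laplacian
   $\bar L = D^{-1/2} C D^{-1/2}$ with $D = \mathrm{diag}(\mathbf{1}^T C)$.
   $\bar L$ is an affinity operator: its eigenvalues lie in $[-1, 1]$, the
   leading eigenvalue is exactly 1 when all marginals are positive, and the
   eigenvectors of the *largest* eigenvalues carry cluster structure.
2. **Unit-circle projection.** Take the $k$ leading eigenvectors (default
   $k = 2$) as the columns of $\bar V_{w \times k}$ and normalize each row
   to unit Euclidean norm. Each bin becomes a point on the unit circle;
   bins in the same domain project to nearly identical points.
3. **Gap vector.** $D_i$ is the Euclidean distance between the projected
   rows of bins $i$ and $i + 1$. Within a domain $D_i \approx 0$; at a
   domain boundary it spikes. The $l = \lfloor w / 5 \rfloor$ largest gaps
   are the candidate boundaries, so $l + 1$ bounds the number of TADs a
   window can hold.
4. **Model selection.** For each $m \in \{2, \dots, l + 1\}$ the window is
   cut at the $m - 1$ highest-ranked candidates and scored by the mean
   per-cluster silhouette under the contact distance
   $d_{ij} = 1 / (C_{ij} + 1)$ (the $+1$ bounds the distance at 1 for
   unobserved pairs). For cluster $i$, $a_i$ is its mean within-cluster
   distance, $b_i$ the mean distance to the nearest other cluster, and
   $s_i = (b_i - a_i) / \max(a_i, b_i)$. The $m$ maximizing
   $\bar s_m = \tfrac1m \sum_i s_i$ wins; ties go to fewer clusters.
   Clusters narrower than 5 bins are discarded from the output after
   selection.

### Sliding window

Spectral clustering of a full chromosome is both expensive and unstable,
so the eigenproblem is solved in windows of
$w = \text{window\_bp} / r$ bins along the diagonal — 2 Mb by default, the
usual upper bound on TAD size, giving $w = 200$ at 10 kb. After a window
is partitioned, everything except its last TAD is committed and the next
window starts at the first bin of that last TAD, which is re-called with
fuller context (it may have been truncated by the window edge). The window
size constraint implies a maximum usable resolution of
$\text{window\_bp} / (2 \cdot 5) = 200$ kb: any coarser and a window could
not hold two minimum-width TADs.

Two degenerate sweep situations need explicit rules the windowed scheme
does not otherwise determine:

* **No usable partition.** If a window yields fewer than two TADs, or the
  restart position would not advance, the window moves forward by
  $w - 5$ bins. This guarantees progress.
* **Single-TAD tail.** When the remaining chromosome tail is one domain,
  the final window holds a single uniform block, which silhouette cannot
  split (there is no $m = 1$ silhouette). If the *previous* window
  detected a TAD starting exactly at the final window's start, that TAD is
  committed extended to the end of the matrix: the boundary is supported
  by the previous window and the final window shows no evidence of
  further structure.

### Organized and gap regions

A window whose best mean silhouette falls below the organization
threshold (default 0.15) is declared unorganized and contributes no TADs.
This is a pragmatic stand-in for a dedicated gap/organization classifier:
it treats flat, structureless windows — uniform contact soup — the same
way as unmappable regions. Separately, bins with (near-)zero marginal
coverage can be masked with `find_gap_bins()`; masked bins are *deleted*
before clustering and coordinates mapped back afterwards, so a TAD may
legitimately span a small gap, but no TAD is ever reported inside one.
The coverage rule (marginal at or below `coverage_threshold` times the
median non-zero marginal, default threshold 0) is deliberately simple and
configurable.

## The hierarchy

Sub-TADs are found by recursive splitting. Each called TAD is treated as
a standalone matrix (no window), its gap vector $D$ is computed as above,
and $z$-scores of $\log D$ are formed; positions with $z > 2$ become
sub-boundaries. The log transform reflects the approximately lognormal
shape of eigenvector gap distributions in contact data. Every significant
sub-boundary ends a sub-TAD, the parent is partitioned completely, and
the procedure recurses into each child until the child is too small to
hold two 5-bin sub-TADs, no $z$ exceeds the threshold, or the depth cap
(default 3: primary, secondary, tertiary) is reached. The centering and
scaling population is always the gap vector of the TAD being split, never
pooled across TADs. The same rule can replace the silhouette pass for
primary TADs (`first_pass = "zscore"`).

Boundaries are the rightmost points of TADs. A boundary's *level* is the
number of TADs, across depths, sharing that right edge — a primary and
its final secondary ending together give a level-2 boundary.

### Numerical choices

* Gaps are floored at `gap_floor` ($10^{-10}$) before the log. Exact-zero
  and numerically-tied gaps all land on the floor and carry no signal; a
  structural gap sits orders of magnitude above it. If no gap clears the
  floor, or the log-gaps have zero spread, there is nothing to split.
* Identical consecutive rows of $\bar L$ are forced to gap 0. Without
  this, block-constant matrices (exactly tied rows) have degenerate
  eigenspaces in which the eigensolver's arbitrary basis choice can
  manufacture spurious gaps.
* Singleton clusters receive silhouette 0, the standard convention.
  A singleton otherwise has $a = 0$ and hence a perfect score, and model
  selection would shatter windows into single bins.
* Candidate ties (equal gaps) break to the left-most position; equal mean
  silhouettes break to fewer clusters. Both make the caller fully
  deterministic: identical input and configuration give identical output.

## Normalization

Three marginal-equalizing transforms are provided as pure matrix
operations, mainly so their effect on calling can be studied:
ICE (iterative bias correction, sqrt-damped so that even disconnected
matrices converge; output rescaled to the input total so the
$1/(C+1)$ distance keeps count-like scale), Knight–Ruiz (damped symmetric
fixed point for $\mathrm{diag}(x)\, C\, \mathrm{diag}(x)$ with unit row
sums), and square-root vanilla coverage
($C_{ij} / \sqrt{m_i m_j}$ — the same expression as $\bar L$, and
implemented identically). Gap bins are excluded from balancing and stay
zero; non-convergence is flagged, never thrown. Because $\bar L$ already
divides out coverage, the caller is largely insensitive to balancing: on
strong block fixtures, calls from raw and ICE-normalized matrices are
identical (this is asserted in the test suite).

## Evaluation utilities

* **Jaccard.** Boundary sets are snapped to the nearest bin edge and
  compared as sets; with a flank (default 50 kb) boundaries become
  intervals matched one-to-one greedily by distance, absorbing
  off-by-one-bin calls. The cross-resolution variant snaps both sets to
  the coarser grid first, so a 25 kb call and a 50 kb call of the same
  boundary agree. Two empty sets have similarity 1.
* **Perturbations.** Noise (add a constant, default 2, to a random
  fraction of cells), sparsity (zero a random fraction), and
  downsampling (multinomial resampling keeping a fraction of total
  contacts) all act on the upper triangle and mirror it, preserving
  symmetry; seeded runs are bit-reproducible and leave the caller's RNG
  stream untouched.
* **Enrichment.** The permutation test compares the mean number of
  annotation intervals overlapping 50 kb-flanked boundaries against the
  same statistic for boundaries placed uniformly on non-gap bins, with
  add-one p-values ($p \ge 1/(B+1)$, never 0). The null places
  boundaries independently — it does not preserve boundary spacing — and
  when the count statistic is very sparse (heavy ties between observed
  and null values) the add-one convention makes the p-values
  conservative rather than exactly uniform; both are deliberate,
  documented simplifications. Fisher's method
  ($X^2 = -2 \sum \log p_i \sim \chi^2_{2k}$) aggregates p-values across
  annotations.

## The synthetic generator

`simulate_matrix()` builds block-constant matrices with known ground
truth: bins sharing $d$ nested blocks have expected intensity
$I_d$, by default the geometric ladder
$I_d = \text{between} \cdot (\text{within}/\text{between})^d$, optionally
modulated by power-law distance decay and Poisson count noise. An
explicit `level_intensities` vector overrides the ladder; the nested test
fixture uses $(1, 8, 30, 60)$ — sub-TAD enrichment deliberately milder
than the primary contrast — because that is the regime in which each
hierarchy level is resolved at its own scale: with $k = 2$ eigenvectors,
a parent's split sees only the strongest sub-structure, and equally
self-similar nesting can surface grandchildren during the parent's split.
A shared-depth intensity model is the minimal generative family in which
nested structure is statistically detectable at all; a flat
within/between dichotomy would make every sub-block invisible.

What the generator emulates: block-enriched domains, nesting, shot noise,
sparsity and depth loss (via the perturbation module). What it does not:
distance-dependent contact decay within domains is optional and off by
default, and A/B compartment structure, loops, translocations, and
mappability artifacts are absent entirely. Passing the recovery tests
therefore demonstrates correctness of the algorithm on its own model
class, not calling accuracy on experimental Hi-C.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `window_bp` | 2,000,000 bp | maximum TAD size = window span |
| `min_tad_bins` | 5 bins | minimum TAD width; also sets $l = \lfloor w/5 \rfloor$ |
| `n_eigenvectors` | 2 | columns of the projection |
| `organization_threshold` | 0.15 | mean-silhouette floor for a window |
| `z_threshold` | 2 | sub-boundary cutoff on $z(\log D)$ |
| `max_levels` | 3 | hierarchy depth cap |
| `gap_floor` | 1e-10 | numerical floor for gaps before log |
| `coverage_threshold` | 0 | gap-bin marginal rule |

## Problem sizes in the test suite

The suite runs entirely on generated fixtures: exhaustive-search
equivalence on one hundred matrices of up to 60 bins (every subset of the
candidate cuts scored by an independent prefix-sum silhouette), exact
recovery on fifty noiseless fixtures of 3–8 blocks (widths 5–40 bins),
the three-level nested fixture above, degradation trends over nine
perturbation levels with twenty Poisson replicates each on a 120-bin
chromosome, and p-value calibration with 200 replicates of a 199-draw
permutation null. These sizes keep the full suite well under a minute of
compute per heavy test while leaving each check statistically
interpretable.

## Limitations

* The organization threshold conflates "uniform single domain" with
  "disorganized"; only the sweep's single-TAD-tail rule rescues the
  former, and only when a preceding window supports the boundary.
* Sub-TAD detection tests every gap at $z > 2$ with no multiplicity
  control; on noisy flat domains roughly 2% of gap positions can exceed
  the threshold by chance, so spurious depth-2 calls at low contrast are
  expected behaviour of the rule, not a defect of the implementation.
* The permutation null ignores boundary spacing and chromosome
  structure.
* Text-dialect I/O only; binary Hi-C containers are out of scope.

```{r example}
sim <- simulate_matrix(sim_spec(c(12, 18, 10), within_intensity = 10,
                                between_intensity = 2))
cfg <- window_config(resolution = 25000, window_bp = 40 * 25000)
call_tads(sim$cm, cfg)
```
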