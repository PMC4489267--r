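---
title: "Mining protein structures with the Binet–Cauchy fragment score"
author: "BCMine authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining protein structures with the Binet–Cauchy fragment score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BCMine)
options(bcmine.log.level = "warn")
```

## The model

BCMine compares two equal-length Cα fragments, held as *N* × 3 coordinate
matrices `X` and `Y` centered at the origin, by the Binet–Cauchy kernel
correlation

$$\mathrm{BC}(X, Y) \;=\; \frac{\det(X^\top Y)}
{\sqrt{\det(X^\top X)\,\det(Y^\top Y)}},$$

the cosine between the Grassmann representations of the two point sets.
The score is invariant to rotation and translation of either fragment,
symmetric, and bounded in $[-1, 1]$: 1 for identical shapes, values near
0 for unrelated conformations, and $-1$ for mirror images, because a
reflection multiplies $\det(X^\top Y)$ by $-1$. Chirality awareness is
what lets the same machinery search for mirror conformations such as
left-handed helices.

```{r score-laws}
h <- idealHelix(12)          # right-handed canonical helix
c(self = bcScore(h, h), mirror = bcScore(h, mirrorFragment(h)))
```

The BC score is intentionally *flexible*: it can equal 1 for fragments
that differ by a uniform or anisotropic scaling. The companion rigidity
score caps that flexibility with the maximum variation of
intra-distances,

$$R(X,Y) \;=\; \max\Big\{\max_i \big|\,\lVert X_i\rVert - \lVert
Y_i\rVert\,\big| ,\;\big|\,\lVert X_N - X_1\rVert - \lVert Y_N -
Y_1\rVert\,\big|\Big\},$$

in Å, using residue-to-centroid distances plus the terminal Cα–Cα
distance. It is zero for rigid copies *and* for mirror images (norms are
reflection-invariant), so the mirror search can reuse it unchanged.

```{r flexibility}
c(bc_scaled = bcScore(h, coords(h) * 2),
  rigidity_scaled = rigidityScore(h, coords(h) * 2))
```

A fragment whose centered Gram matrix is (near-)singular — collinear or
coplanar points — has no meaningful BC score. We declare a fragment
degenerate when $\det(X^\top X) < 10^{-6}\,(\mathrm{tr}(X^\top X)/3)^3$,
a relative, unit-safe criterion. Degenerate bank windows are skipped and
counted; a degenerate query is a hard error. Computed scores are clamped
to $[-1, 1]$, with a warning if the pre-clamp excursion exceeds
$10^{-6}$ (anything larger would indicate a bug, not rounding). To make
the score exactly symmetric at the bit level, the two centered matrices
are put in a canonical order before $\det(X^\top Y)$ is formed:
$\det(X^\top Y)$ and $\det(Y^\top X)$ are equal in exact arithmetic but
round differently.

## The four services

All services scan every window of the required length over every
*contiguous segment* of every bank structure, stride 1, reporting all
overlapping hits. Chains are segmented at residue-numbering jumps and
wherever the consecutive Cα–Cα distance leaves $[2.5, 4.5]$ Å — a gate
around the 3.8 Å virtual bond wide enough for cis-prolines and modest
distortion but not for unlabeled breaks. No window ever spans a segment
boundary.

**Fragment search** accepts a window iff $\mathrm{BC} \ge c$ and $R \le
r$, with published defaults $c = 0.95$ and $r = 1.0$ Å. Hits are ordered
by BC descending, then rigidity ascending, then hit identifier, then
window start — a deterministic total order, so repeated runs are
byte-identical. Each hit carries the Kabsch-superposition RMSD to the
query and an empirical P-value (below). Hits in the query's own structure
are kept and flagged `is_self` rather than removed, so users can exclude
them when counting.

**Mirror search** accepts $\mathrm{BC} \le -c$, orders ascending (most
anti-similar first), and reports the RMSD between the window and the
*mirrored* query — the quantity a modeler building the mirror actually
wants.

**Loop search** addresses gaps: given a structure with missing residues
and the complete sequence, gaps are detected by placing the observed
residues into the full sequence (numbering-anchored placement first,
leftmost exact-substring placement of each contiguous block as the
fallback; a conflict is an error naming the first mismatching position).
Each searchable gap of length $L$ is anchored by the four observed
residues on each side. Every bank window of length $4 + L + 4$ is scored
on its two flanks against the query's flanks, with both 8-point flank
sets centered *jointly* — one centroid per set — so the inter-flank
geometry that encodes the gap span constrains the match. Passing windows
are grafted into the template frame by Kabsch superposition of the 8
flank Cα, and a grafted candidate is discarded if any loop Cα comes
within 3 Å of a template Cα at least 3 sequence positions away along the
repaired chain (other chains always count; candidate-internal clashes are
not checked). The search is purely geometric: hit sequences are
unconstrained, and reported RMSD/P-values are flank-based.

**Specificity profiling** slides a window (default 9 residues) over a
whole query structure and, for each window, counts $N_\mathrm{hits}$, the
number of distinct bank proteins with at least one similar window — one
protein, one count, however many of its windows match. The specificity
score is

$$sp \;=\; 1 - \frac{N_\mathrm{hits}}{N_\mathrm{total}},$$

so $sp \to 1$ marks conformations rarely found in the bank. Banks can be
filtered by SCOP-style `class.fold.superfamily.family` prefixes on code
component boundaries (`g.37` matches `g.37.1`, not `g.370`), including
patterns like "class b minus fold b.47". The per-residue score is the
maximum $sp$ over the windows covering the residue: a residue is marked
specific if it belongs to at least one rare fragment. Degenerate windows
get `NA` rather than a fabricated value.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `bcCutoff` | 0.95 | – | minimum BC score (maximum $-$BC for mirror) |
| `rigidityCutoff` | 1.0 | Å | maximum intra-distance variation |
| `maxHits` | 1000 | hits | report truncation, best of the total order |
| `clashCutoff` | 3.0 | Å | grafted-loop/template Cα distance floor |
| `minSeqSep` | 3 | residues | separation at which the clash rule applies |
| `windowSize` | 9 | residues | specificity window |

The search cutoffs are the published service defaults; they are
independent of fragment size, which is what makes a single pair of
cutoffs usable across queries. Output tables print numeric fields with 4
decimals — the sources do not state a precision, so this is our choice.

## Empirical P-values

P-values come from an empirical null: `calibrateNull()` draws (with
replacement) pairs of same-length windows from *distinct* structures of
the bank, scores them, and `bcPValue()` converts a hit score into the
one-sided add-one tail

$$p \;=\; \frac{1 + \#\{s_\mathrm{null} \ge \mathrm{BC}\}}{n + 1},$$

with the lower tail used symmetrically for mirror hits. The null is
reproducible (seeded), recorded in the CSV header, and loop-search nulls
are calibrated on the same statistic the search uses (the 8 flank Cα of
windows of length $8 + L$).

```{r null}
bank <- syntheticBank(lapply(1:6, function(i)
  generatorSpec("random_walk", 40, seed = 300 + i)))$bank
nm <- calibrateNull(bank, 9, nSamples = 2000, seed = 1)
c(mean = mean(nm@scores), sd = sd(nm@scores))
```

One property deserves emphasis: **the empirical null is not independent
of fragment length**. On virtual-bond chain decoys the null narrows as
windows get longer (longer fragments are more anisotropic, concentrating
the Grassmann cosine), so a single null cannot serve all lengths. This is
why `calibrateNull()` takes the fragment length as an argument and every
search calibrates at its own length. An analytic significance law with
size-independent statistics exists for this kernel; swapping it in behind
`bcPValue()` would be straightforward, and the add-one empirical tail was
chosen here because it is assumption-free and exactly reproducible.

```{r null-length}
n8 <- calibrateNull(bank, 8, nSamples = 1000, seed = 3)
n20 <- calibrateNull(bank, 20, nSamples = 1000, seed = 4)
c(sd8 = sd(n8@scores), sd20 = sd(n20@scores))
```

## Structure input conventions

PDB files are read through `bio3d`, keeping the first `MODEL` only and
one Cα per residue: alternate locations resolve to the highest occupancy
(ties toward altloc `A`), residues without a Cα are skipped, and `HETATM`
residues are kept only when they are standard amino acids
(selenomethionine maps to `M`; other nonstandard residues become `X`).
Residue identity is the file's own `(chain, number, insertion code)` —
no renumbering — and hit reports use those labels. Bank manifests are
TSV files with columns `file_path`, `domain_id`, `sccs_code`, which
attach classification codes without bundling any classification database.
Unreadable bank files are logged and skipped; a bank with zero readable
structures is an error.

## The synthetic-structure generator

Every test runs against structures built by the `fixtures` generator, so
nothing is downloaded and every assertion has ground truth:

* `idealHelix()` — canonical α-helix (rise 1.5 Å/residue, radius 2.3 Å,
  100°/residue): consecutive Cα distances are the closed-form chord,
  ≈ 3.83 Å; its mirror is a left-handed helix.
* `idealStrand()` — near-straight zig-zag, 3.3 Å rise, 3.8 Å bonds.
* `randomWalkFragment()` — walks with exact 3.8 Å steps, pseudo-bond
  angles uniform in [80°, 150°] and uniform dihedrals: protein-like
  local geometry, unrelated global shapes. These are the decoys and the
  null-calibration material.
* `perturbFragment()` — seeded isotropic Gaussian coordinate noise.
* `syntheticBank()` — realizes a list of generator specs as single-chain
  PDB files (written, then re-read through the real parsing path), and
  can splice a given fragment as a rigid, randomly oriented copy at a
  known offset of one structure, returning that ground truth.

What the generator emulates: virtual-bond geometry, chain breaks,
classification codes, planted signals at exact or controlled noise
levels. What it does not emulate: real secondary-structure statistics,
side chains, crystallographic artifacts, sequence–structure correlation,
or the redundancy structure of real databases. Passing tests therefore
demonstrate the correctness of the scores, the window machinery, the
filters and the rankings — not retrieval performance on real banks, which
depends on the collection mined.

Fixture coordinates pass through PDB text with three decimals, so a
planted "identical" copy is identical only to ≈ 10⁻³ Å; planted-recovery
assertions use tolerances at that quantization scale (BC within 10⁻³ of
±1, rigidity and RMSD below 0.01 Å) rather than exact zeros.

## Numerical choices

* **Kabsch superposition** is computed from the SVD of the 3 × 3
  cross-covariance; when the raw optimum is improper, the singular
  direction with the smallest singular value is flipped, so the rotation
  always has determinant +1. RMSD between a chiral fragment and its
  mirror is therefore strictly positive, as it should be.
* **Mirror convention**: the z-axis is negated after centering. Any fixed
  reflection is equivalent up to rotation and the BC score is
  rotation-invariant, so one convention suffices.
* **Tie-breaks**: hit ordering is completed by hit identifier
  (C-locale radix sort) and window start, making all outputs
  deterministic down to the byte.
* **Degenerate inputs**: relative Gram-determinant floor of $10^{-6}$ as
  above; degenerate bank windows are skipped with a count, degenerate
  queries error, and specificity windows record `NA`.
* **Problem sizes**: the shipped tests use banks of a few hundred to two
  thousand windows and nulls of 10⁴ samples — sizes at which every
  service is also cross-checked against an independent naive
  implementation evaluated directly from the formulas.

## Limitations

All searches are ungapped: a single indel in an otherwise conserved
fragment hides it from the scan window, which is also why fragment hits
are stringent evidence of conformational identity. Scoring is Cα-only;
no sequence term enters any score. Loop candidates receive only the rough
3 Å clash pruning — no energy scoring or refinement — and should be
treated as a candidate pool, not models. P-values are empirical,
per-length, and uncorrected for multiple testing across windows.
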