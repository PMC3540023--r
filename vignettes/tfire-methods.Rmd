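---
title: "Structure-trained potentials for binding-site prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-trained potentials for binding-site prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfire)
```

## The problem

Position weight matrices (PWMs) are the standard representation of
transcription-factor binding specificity, but many factors have no
well-characterized PWM, and short degenerate motifs scanned against promoters
produce heavy false-positive loads. When a 3D structure of the factor bound
to DNA exists, the binding preference can instead be read off the structure:
replace each interface base pair in turn, score each variant with an energy
function, and turn the resulting energy profile into a motif. `tfire`
implements this strategy around a distance-dependent knowledge-based
potential that is *trained on the single template complex being analysed* —
the template-FIRE ("tFIRE") strategy — rather than on a large structure
database.

## The energy model

We assume rigid-body association: intra-protein and intra-DNA interactions
are unchanged by binding, so only cross protein-DNA atom pairs contribute.
The binding free energy of a complex is approximated as a sum over all
protein-DNA heavy-atom pairs within a cutoff:

$$\Delta G \;=\; \sum_{i,j,\,r < r_\mathrm{cut}} \bar u(i, j, r),$$

where $i$ and $j$ are *residue-specific atom types* (e.g. `GUA N2` and
`ADE N6` are distinct types) and $r$ the pair distance. Energies come from
comparing observed pair counts against a distance-scaled ideal-gas reference
state:

$$\bar u(i,j,r) \;=\; -\eta RT\,
  \ln\!\frac{\tilde N_\mathrm{obs}(i,j,r)}{N_\mathrm{ref}(i,j,r)},
\qquad
N_\mathrm{ref}(i,j,r) \;\propto\; r^{\alpha},$$

with $\tilde N_\mathrm{obs}$ the binned counts plus a pseudo-count, and the
reference normalized per type pair so that it carries the same total weight
as the observations (self-normalizing; no global prefactor survives).
Energies are identically zero at and beyond the cutoff.

Defaults (all settable through `potentialConfig()`):

| parameter | default | units | role |
|---|---|---|---|
| `rCut` | 10 | Å | interaction cutoff; matches the 10 Å interface rule used to define the effective binding site |
| `deltaR` | 0.25 (0.5 without smoothing) | Å | distance bin width |
| `alpha` | 1.61 | — | exponent of the distance-scaled reference (the published DFIRE value) |
| `etaRT` | 1 | arbitrary | overall energy scale; downstream conversions carry their own scale, so units are arbitrary |
| `pseudoCount` | 0.5 | counts/bin | low-count regularizer; guarantees finite energies |

### The four corrections

Four independently toggleable corrections refine the raw construction:

* **Volume fraction** (`useVolumeFraction`): protein and DNA atoms do not
  mix, so the ideal-gas reference overstates the available density. The
  reference is scaled by $2 v_\mathrm{p} v_\mathrm{d}$, the volume fractions
  being the heavy-atom count fractions of the two molecule classes over the
  training set.
* **Reweighting** (`useReweight`): plain pooling biases the statistics
  toward large structures. With reweighting, every training structure
  contributes *equal* total weight. We implement this on the raw count
  scale: each structure's pair weights are scaled by
  (mean total cross-pair count) / (its own total), and the accumulated
  histogram is averaged over structures. The alternative of normalizing
  every structure to total weight 1 has the same equal-contribution
  property, but it shrinks single-template counts to the order of
  $10^{-3}$ per bin, far below any fixed pseudo-count — the potential then
  degenerates to the reference and a template-trained model loses all
  sequence memory. Keeping the raw scale preserves equal contributions,
  makes training exactly invariant under duplicating a training structure,
  and leaves the pseudo-count meaningful.
* **Smoothing** (`useSmoothing`): with fine 0.25 Å bins, single-structure
  histograms are sparse; counts are convolved per type pair with the
  symmetric kernel $[1,2,4,2,1]/10$, edge-truncated and renormalized so the
  per-type total is conserved exactly.
* **Dipolar approximation** (`useDipolar`): polar-polar contacts (N/O vs
  N/O) are orientation dependent. Each pair's count weight is multiplied by
  $(1+\cos\theta_i)(1+\cos\theta_j)/4$, where $\theta_x$ is the angle
  between atom $x$'s dipole axis (mean direction from its bonded heavy
  neighbors, inferred at < 1.8 Å) and the interatomic vector; apolar atoms
  (C, S, P) always weight 1.

All four are on by default, which is the best-performing combination in the
benchmark this package's evaluation tables mirror.

### Why single-template training works

A potential trained on one complex observes each of its contacts exactly
once. After smoothing and pseudo-counting, a type pair seen at its native
distance is assigned a markedly lower energy than the fallback curve used
for unseen type pairs at the same distance. Because atom types are
residue-specific, this means the potential *memorizes which base contacts
which protein atom at which distance* — scanning with it is conceptually
similar to scanning with a consensus sequence derived from the structure,
but it degrades gracefully (near-isosteric substitutions such as purine for
purine score closer to native than drastic ones) and it needs no binding-site
collection at all, only the one complex. Two controls included here probe
exactly this: randomizing the template's own sequence before training (the
mutant control) removes the memorized signal and drops prediction accuracy
to chance, while rigid-body mis-positioning of the DNA does not remove it,
because training and evaluation see the same (displaced) geometry.

## From structure to motif

1. **Interface definition.** Watson-Crick pairs are detected from identity
   plus geometry (C1'-C1' within 10.4 ± 1.5 Å, central purine-N1 to
   pyrimidine-N3 distance < 3.5 Å). The *effective* binding site keeps the
   pairs with at least one atom within 10 Å of the protein; its length is
   $L_n$.
2. **Substitution.** Each interface pair is replaced by each of the four
   pair types (A-T, C-G, G-C, T-A, keyed by the first-strand base). The
   backbone and sugar atoms are left bit-identical; idealized base
   geometries are placed via the residue's base reference frame (origin at
   C1', x toward the glycosidic nitrogen, z along the base-plane normal
   with a fixed sign convention). Only the substituted pair's *base* atoms
   enter the energy: the backbone contribution is constant across the four
   variants and would cancel anyway, and excluding it makes entries
   comparable across positions.
3. **PEM.** The $4 \times L_n$ table of substitution energies.
4. **PWM.** Boltzmann conversion per position,
   $p_{ij} = e^{-\beta e_{ij}} / \sum_k e^{-\beta e_{kj}}$ with
   $\beta = 0.05$ per arbitrary energy unit (computed with max-subtraction).
   $\beta = 0$ gives the uniform matrix; the uniform ("even") PWM with 0.25
   everywhere also serves as the reference in motif-similarity comparisons.

## Scanning and evaluation

Promoters (500 bp upstream windows by convention) are threaded through the
PEM: a window of length $L_n$ at every offset, energy the sum of its
per-position entries, $500 - L_n + 1$ windows per promoter. Windows
containing ambiguous bases count toward the total but can never be
predicted. Per promoter, the 200 lowest-energy windows are kept; candidate
cutoffs are the kept windows' distinct energies; a window is predicted when
its energy is at or below the cutoff (so the maximizing candidate is
attainable); the returned cutoff maximizes sensitivity plus specificity,
ties broken toward the more stringent threshold.

Curated sites that overlap are merged to their union before scoring. A site
of length $L_d$ is recovered (TP) when a predicted window overlaps it by
*more than* 50% of $L_d$, or — because database sites can be much longer
than the structural site — by more than 50% of $L_n$ when $L_d > L_n$.
The "more than" is read strictly; the boundary case is configurable via
`scanConfig(overlapFraction = )`. Sites never hit are FN; predicted windows
hitting no site are FP; several windows on one site count one TP and no FP.
SE = TP/(TP+FN) and SP = TP/(TP+FP).

For ROC analysis the negative set must be explicit. We define it as the
kept candidate windows that do not overlap any annotated site under the
same rule — the only choice that makes a false-positive *rate* computable
from the scan output. The AUC is the trapezoidal area of the threshold
sweep, equal to the Mann-Whitney probability that a random positive window
scores below a random negative one (ties counted half). Summary tables
report per-factor rows plus unweighted means and sample (n-1) standard
deviations, rounded to two decimals; full precision is kept internally.

Coordinates are 0-based half-open internally and 1-based inclusive in
human-facing site files (`readSites(..., oneBased = TRUE)`), matching the
`chr1:1984-2007` style of curated databases. Scanning is forward-strand by
default; `scanConfig(scanReverse = TRUE)` adds the reverse complement.

## The synthetic test system

Nothing in the test suite or the acceptance script downloads anything; all
structural and sequence inputs are generated:

* `makeBDna()` builds an idealized B-form duplex: planar heavy-atom base
  geometries (regular-polygon rings with standard bond lengths), canonical
  Watson-Crick pairing (central N-N hydrogen bond 2.9 Å, parallel bond
  rails, C1'-C1' ≈ 11.2 Å), rise 3.38 Å and twist 36° per step, plus a
  schematic (deterministic, substitution-invariant) sugar/phosphate
  backbone. The generator and the substitution operator share one internal
  coordinate table, so self-substitution is exact by construction.
* `makeToyComplex()` adds single-atom pseudo-protein probes (GLY CA) in the
  major groove. At `specificityStrength = 1` each probe sits 3.5 Å outside
  the heavy atom unique to the native base at its position (N6/N4/O6/C7 for
  A/C/G/T), tying the contact geometry to the sequence; at 0 the anchoring
  is replaced by a seeded random offset. Note that removing the geometric
  anchoring does *not* push self-trained recovery to chance: the potential
  still memorizes the template's own atom types at whatever distances the
  probes ended up (see above). Chance-level behaviour requires breaking the
  type memory itself, which is what `mutateTemplateSequence()` does.
* `makePromoters()` plants motif instances (exact string or PWM draws) at
  seeded non-overlapping offsets in i.i.d. background of 38% GC (a
  yeast-like promoter composition), then rewrites any background window that
  matches the planted consensus exactly, so separability statements about
  the planted benchmark are constructive rather than probabilistic.
* `makeThreadingDecoys()` supplies uniform random sequences for the decoy
  discrimination test. Because the base-restricted energy is additive over
  positions, threading a decoy through the template equals summing PEM
  entries, which keeps the 500-decoy test fast.

What the synthetic system does *not* emulate: real protein geometry (probes
are point contacts), base-pair steps deviating from ideal B-form, water or
ion mediation, low-complexity promoter structure, and binding sites that
disagree with the template's motif. Passing tests therefore demonstrate the
pipeline's internal correctness and the tFIRE memorization mechanism, not
accuracy on crystallographic data.

## Problem sizes and numerical choices

The bundled benchmark suite runs a 12-bp template with 12 probes, 10
promoters of 500 bp with 15 planted sites, 500 threading decoys, 20 mutant
seeds and 4 perturbation groups; the whole suite and the acceptance script
each complete in well under a minute on one core. Other choices:

* Distance bins are half-open $[k\Delta r, (k+1)\Delta r)$; a pair exactly
  at the cutoff is excluded.
* Rigid perturbation draws one random axis and translation direction per
  seed and scales a single magnitude by bisection until the DNA RMSD
  (computed without re-superposition — perturbations are absolute) lands in
  the half-open group interval $(n-1, n]$; the boundary value belongs to
  group $n$. The effective binding site is re-derived afterwards, since
  displacement can move terminal pairs out of the 10 Å interface.
* Hydrogens are ignored throughout (heavy-atom potential); alternate
  locations other than blank/'A' and models beyond the first are dropped on
  reading; both `DA/DC/DG/DT` and bare `A/C/G/T` nucleotide naming dialects
  are accepted.
* PWM consensus ties break alphabetically and are flagged.
* The motif-similarity score is the mean per-position total-variation
  distance — 0 iff equal, symmetric, bounded by 1, a metric. It is isolated
  behind `psiTest()` so an alternative similarity could be swapped in.
* Zeroing non-minimal PEM entries (`zeroReference()`) preserves the
  per-position argmin whenever minima are negative (the binding regime it
  is meant for); with an all-positive column the zeroed entries become the
  minimum by construction.
* `summarizeTfResults()` averages the rounded per-row values, which is what
  reproduces published two-decimal summary rows exactly.

## Known limitations

* The potential's absolute energy scale is arbitrary; only comparisons
  within one trained potential are meaningful, and $\beta$ is calibrated to
  that scale.
* Multi-chain DNA beyond one duplex, modified bases, and protein mutation
  are out of scope; multi-protein (TF-TF) templates are supported simply by
  listing several protein chains.
* Compared PWMs must be pre-aligned and equal length; no offset search is
  performed.
* The mutant control's accuracy on planted promoters sits slightly above 1
  on average because optimizing the cutoff on the evaluation data itself
  inflates chance-level SE+SP a little; the effect shrinks as sites and
  promoters are added.
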