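---
title: "Models and methods behind sigcon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sigcon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigcon)
```

# The system being modelled

A signal-connector is a small trans-acting RNA with two kinds of modules:
an *antisense domain* — 20 nt, perfectly complementary to a window on the
5′-UTR or coding region of a chosen mRNA — and one or more *aptamer
domains*. Sensor aptamers bind a signal molecule (theophylline,
tetracycline) or protein (β-catenin, NF-κB, VEGF, OPN); the effector
aptamer binds eIF4G. Three topologies are supported:

* **repressor** — antisense + sensor copies. The ligand-aptamer complex
  parked on the mRNA obstructs scanning (5′-UTR targets) or elongating
  (CDS targets) ribosomes, so repression requires the ligand.
* **activator** — antisense + eIF4G-aptamer copies. Tethered eIF4G
  recruits initiation machinery and raises translation; used with an
  "uncapped" reporter in which the reporter ORF sits downstream of a
  primary ORF.
* **switch activator** — a sensor aptamer whose stem is complementary to
  the antisense, plus effector copies. Without ligand the antisense is
  sequestered by the stem; ligand binding stabilises the aptamer fold and
  frees the antisense.

The package covers the full desk workflow: window enumeration, chimera
assembly, structure-based selection, quantitative dose-response
modelling, gate and network composition. Wet-lab steps (transfection,
reporter chemistry, animal work) are out of scope by design.

# Folding model

`fold()` maximises a weighted count of non-crossing base pairs
(GC = 3, AU = 2, GU = 1; minimum hairpin loop 3 nt) by Nussinov-style
dynamic programming, with optional forced-unpaired constraints. This is a
deliberate trade: a transparent structural score instead of a
thermodynamic free-energy model. The reason is verifiability — the same
scoring scheme admits an exhaustive oracle, `enumerate_structures()`,
against which the optimiser is checked exactly on hundreds of random
sequences in the test suite. Structural selection criteria in this
package are therefore defined *relative to this model*, not to any
external folder; a pluggable backend can replace the engine without
touching callers, since all downstream code consumes only the pair list.

Determinism matters for reproducible selection, so ties are broken by a
fixed rule: the traceback prefers the branch pairing the smallest 5′
index, and among those the shortest span. `count_structures()` provides
an independent counting recurrence used to validate the enumeration
itself. Pseudoknots and base-pair probabilities are out of scope.

# Design selection

`score_design()` folds the assembled chimera and computes:

* **exposedness** — the fraction of antisense positions unpaired in the
  fold. For switch designs the ON state is scored: the ligand-occupied
  sensor is excluded from pairing (the DP cannot force pairs, so
  occupancy is represented by removing the sensor from the pairing
  competition) and its preservation is credited as 1.
* **preservation** — the fraction of each aptamer's reference pairs,
  shifted by the module offset, present in the chimera fold, averaged
  over copies. Comparing shifted pair sets is deterministic and avoids
  re-folding aptamers per call.
* **position prior** — `exp(-(start − 1)/λ)`. Repression and activation
  both weaken with target distance from the 5′ end; the exponential is
  the simplest strictly decreasing positive form. λ = 300 nt spreads
  meaningful contrast across a typical reporter transcript; it is a
  configurable shape parameter, not a measured constant.

Selection keeps designs with exposedness ≥ τₑ and preservation ≥ τₚ
(defaults 0.8 each — the qualitative "exposed and maintained" criterion
made concrete; both exposed as arguments) and ranks them by the product
of the three factors, ties broken by smaller window start, then id.

**Coordinates.** All intervals are 1-based and inclusive, the
Bioconductor convention. Note the annotation file format is unaffected by
this choice: a half-open 0-based end equals the 1-based index of the last
base, so `utr5_end`/`cds_end` columns read the same either way.

**Linkers.** Module linkers default to direct fusion. Under a
max-pairing score, any A- or C-spacer next to a hairpin can substitute
for a stem partner at equal score, creating degenerate optima whose
traceback scrambles the stems; removing the spacer removes the
degeneracy. The `linker` argument remains for users who want spacers and
accept the scoring consequences.

# The sequestration switch

`evaluate_switch()` compares two conformations that share a common
"rest" fold (computed once with the antisense and sensor excluded from
pairing):

* OFF = rest + antisense:stem duplex score;
* ON = rest + sensor reference score, plus `binding_bonus` when the
  ligand is present.

For a perfectly complementary switch the duplex and the reference stem
score identically, so the two states tie exactly without ligand — and a
tie rests OFF. Any positive binding bonus then flips the device ON, and
increasing the bonus can never flip it back. Binding bonuses are score
units standing in for unknown affinities: 5 for small-molecule aptamers,
7 for protein aptamers, large enough to decide the two-state comparison
yet small against a 20-bp duplex.

# Regulation model

Without the original quantitative model equations to reproduce, the
package declares the minimal saturating (Hill/Emax) forms and documents
them as such:

$$\theta(L) = \frac{L^h}{K^h + L^h},\qquad
E(L) = 1 - E_{max}\, v(c)\, \epsilon\, \theta(L),\qquad
F(\theta) = 1 + (F_{max} - 1)\, v(c)\, \epsilon\, \theta,$$

with efficacy ε the composite design score. The valency weight
`v(c) = (c/(c+κ)) / (2/(2+κ))`, capped at 1, makes the standard two-copy
device the reference (v(2) = 1) and encodes the observed ordering — one
copy much weaker, three copies barely stronger than two — for every
κ ∈ (0, 2]. Capping keeps outputs inside their calibrated bounds
(E ∈ (1−Emax, 1], F ∈ [1, Fmax]); the uncapped curve is available via
`normalize = FALSE` where strict monotonicity in copies is wanted.

Packaged calibrations: theophylline K = 300 µM, h = 1.3 (a sub-saturating
then saturating response over 0–1000 µM; logic-high 1000 µM);
tetracycline K = 20 µM (logic-high 100 µM); the two-copy eIF4G activator
Fmax = 15, from the saturating fold-activation of the reference device;
κ = 0.5. These are artifact calibrations consistent with the reported
qualitative behaviour, not published constants.

## Calibration

`calibrate()` fits the free parameters by multi-start least squares: a
3×3×3 grid of log-spaced starts refined by Levenberg-Marquardt, the best
converged fit winning with ties broken by grid order — deterministic,
with no stochastic search. Residuals are taken on the log scale by
default because reporter-assay noise is multiplicative; this choice
matters, as raw-scale residuals weight the high-expression points and
measurably degrade Hill-coefficient recovery. `dose_design()` supplies
the package's 20-point recovery panel: anchors at zero and deep
saturation plus duplicated log-spaced doses across K/4–4K, the region
that identifies `h`. The test suite checks recovery to within 1% on
noise-free data and 10% under 5% multiplicative noise.

# Gates and circuits

`build_gate()` selects devices by recipe: strong repressors for NOT,
NOR, XNOR; functionally weak repressors for NAND; strong ligand-gated
activators for OR, XOR; weak ones for AND. A device is classed by its
single-device effect at the logic-high concentration (defaults: fold ≥ 6
strong / ≤ 4 weak for activators, relative expression ≤ 0.5 / ≥ 0.7 for
repressors). Absolute bounds, rather than within-pool quantiles, are
used so that a pool of uniformly strong activators is *rejected* for an
AND gate — its defining property is that single inputs do not activate.

`simulate_gate()` combines devices multiplicatively (repressors on
relative expression, activators on fold terms) and raises the combined
effect of two or more co-bound same-arm devices to the synergy exponent
s = 2. The synergy law is a free parameter of the model: joint action is
reported as super-multiplicative without a quantitative law, and s = 2
is the smallest integer exponent that separates the AND gate's (1,1) row
from its single-input rows at the calibrated midpoint.

Complementary antisense pairs (≥ 16 of 20 antiparallel Watson-Crick
matches, all-or-none) annihilate each other — but only when both devices
are ligand-bound. This gating is forced by the XNOR construction: its
two repressors are complementary yet must each repress alone, so the
mutual duplex can only form between ligand-organised devices; the same
rule yields XOR's null output at (1,1), where both switch activators
have exposed antisense.

Digitisation thresholds at the midpoint of the gate's calibrated ON and
OFF reporter levels (computed from the selected devices at build time);
midpoint values count as ON.

# Networks and scenarios

`simulate_network()` integrates `d[X]/dt = production·(modifiers) −
decay·[X]` with fixed-step classical RK4 (deSolve backend, dt = 0.01,
t_end defaults 100), connector edges modulating *production* — the
translational layer — so a transcript-level readout stays untouched, as
in the pathway-rewiring experiments. Perturbations are timed `set`
(concentration) or `production` (rate, including knockdowns) events;
integration restarts at each event time, keeping the grid exact. The
packaged OPN–VEGF loops use production 1, decay 0.1 (unregulated steady
state 10 units) and edge parameters K = 30, h = 2, Emax = 0.8, Fmax = 3,
efficacy 0.9 — arbitrary units placing the steady state on the sensitive
part of the Hill curve so both loop directions are visible; halving dt
changes final states by far less than the 1e-6 convergence bound checked
in tests.

The rewiring scenario models a transcription factor that induces its
target ~2-fold at the mRNA level (the modest qPCR-scale induction seen
for transcription-factor stimulation) while a protein-sensing repressor
suppresses translation of the same target; the connector makes mRNA and
protein readouts move in opposite directions. The AND classifier is a
ribozyme-flanked repressor expressed from a cancer-selective promoter:
knockdown is non-zero only when promoter activity *and* ligand coincide.
The redirection scenario drives two switch activators and two repressors
from one oncogenic signal, moving tumour suppressors up and oncogenes
down simultaneously.

# Fixtures: what they emulate, and what they do not

`generate_fixture_transcript()` and `generate_toy_aptamer()` create
seeded random transcripts and perfect G/C hairpins (the generator
re-samples deterministically until the fold engine recovers the
reference hairpin, which is its contract). The demonstration pool
(`demo_device_pool()`) goes further: its 760-nt target carries implanted
low-complexity windows — poly-U sites near the 5′ end and deep in the
CDS, plus one complementary poly-A site — so that every designed device
*genuinely* achieves exposedness = preservation = 1 under the fold
model, strength classes arise purely from the 5′-distance prior, and a
complementary antisense pair exists for XOR/XNOR. This emulates the
*outcome* of the fold-and-select step on ideal targets. It does not
emulate real mRNA sequence complexity: on natural sequences many
candidate windows fail selection, off-target complementarity exists (no
transcriptome-wide search is attempted), and the max-pairing model
over-predicts pairing relative to thermodynamics. Passing gate tests on
these fixtures demonstrates the composition logic, not sequence-level
performance on natural transcripts.

Similarly, the packaged aptamer library contains *synthetic stand-in*
hairpins, one per ligand, engineered so the fold engine reproduces their
reference structures in every supported device context; the true device
sequences are not reproduced here, so the library preserves the
architecture, roles and binding-bonus classes rather than real aptamer
sequences.

# Numerical choices and degenerate inputs

* Fold scores are small integers; optimality comparisons use an absolute
  tolerance of 1e-9.
* `enumerate_structures()` refuses sequences longer than 25 nt.
* Empty aptamer libraries load with a warning; duplicate ids, unbalanced
  dot-brackets, out-of-range stems and non-ACGU characters are hard
  errors naming the offender.
* `calibrate()` requires ≥ 4 points and rejects constant responses as
  unidentifiable; parameter bounds keep K, h, Emax, Fmax in their valid
  ranges during fitting.
* Valencies outside {1, 2, 3} are errors everywhere — behaviour beyond
  three copies is unexplored territory the model refuses to extrapolate.
* A switch whose ON state beats OFF without ligand triggers a "leaky
  switch" warning at assembly time.

# Known limitations

The fold engine is a pairing-count model: it ignores stacking, loop
entropies and temperature, and its exposedness/preservation values are
not comparable to free-energy folders. The regulation model is
quasi-steady-state with no mRNA-level dynamics, no ribosome flux and no
resource competition between devices. Gate synergy and annihilation are
phenomenological (exponent and threshold exposed as parameters). Network
kinetics use arbitrary units and first-order decay. None of the in vivo
phenomena (tumour growth, apoptosis) are modelled.
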