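---
title: "Models and methods behind lnahelix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lnahelix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnahelix)
```

## The scientific problem

Triplex-forming oligonucleotides (TFOs) read double-stranded DNA
sequence-specifically by binding the polypurine strand in the major groove
through Hoogsteen (HG) hydrogen bonds: a parallel pyrimidine-motif TFO
pairs T with A and protonated C (C⁺) with G. Locked nucleic acid (LNA)
monomers — nucleotides whose 2′-O,4′-C methylene bridge fixes the furanose
in the north (C3′-endo) pucker — strongly stabilize such triplexes, and
their number and placement (3′ versus 5′ end, alternating versus blocked)
determine whether a triplex forms at all. The structural signatures of
these effects live in a handful of per-residue and per-step observables:
the sugar pseudorotation phase *P*, the glycosidic torsion χ, the
persistence of WC and HG hydrogen bonds over time, and the base-pair-step
helical parameters of the underlying duplex.

`lnahelix` implements this observable pipeline end to end: a sequence
model for LNA/DNA mixmer notation, a fiber-model builder for starting
structures, the conformational and pairing analyses, and a synthetic
trajectory generator that emulates the statistical structure of molecular
dynamics (MD) snapshot series so that every analysis can be validated
against known ground truth. Reproducing MD itself (force fields,
solvation, thermostats) is explicitly out of scope.

## Sequence model

Mixmer notation writes DNA in lowercase, LNA in uppercase, the base-free
TINA intercalator as a (bold) `P`, fluorophores as `Cy3`/`Cy5` tokens, and
segment boundaries (e.g. the TFO arm, linker and WC arm of a bisLNA clamp)
as `-`. `parse_mixmer()` accepts both typographic primes and apostrophes
and both `**P**` and bare `P` (a strict mode requires the bold form).
TINA monomers carry no base and are excluded from nucleotide counts; in
3D models they are skipped entirely, since no analysis here consumes an
explicit intercalator geometry.

Two complement rules coexist. The Watson–Crick complement is antiparallel
(A↔T, G↔C, sequence reversed). The parallel Hoogsteen complement is
position-wise — no reversal — mapping A→T and G→C with every C flagged
protonated; this is what `find_tfo_binding_site()` slides along the purine
strand to locate a TFO's target, requiring an exact match (the TFOs
modelled here are fully matched; mismatch-tolerant search is a non-goal).
Binding-site search errors on multiple matches rather than picking one.

One deliberately unimplemented quantity: the partial (10-nt)
WC-complementarity between a WC-invading 29-mer and the TFO binding site
is reported in the literature without a stated alignment rule, so the
package does not hard-code any.

## Fiber models

Structures are generated from fixed per-step helical parameters, the way
classical fiber models are: base-pair frame *k* is rotated by *k*·twist
about the global axis and translated by *k*·rise along it. Planar
idealized base geometries are expressed in the standard base reference
frame (origin near the pair center, x toward the major groove, y along
the long pair axis); the complementary base is flipped 180° about x, a
proper rotation, so both strands' sugars keep the same (D) chirality.
Defaults are the classical fiber values: B-DNA twist 36.0°, rise 3.38 Å,
C2′-endo sugars (*P* = 162°, τₘ = 38°); A-DNA twist 32.7°, rise 2.81 Å,
x-displacement −4.4 Å, C3′-endo sugars (*P* = 18°, τₘ = 40°). LNA
residues are always built north (*P* = 17°, τₘ = 48°); the 2′-O,4′-C
bridge atoms themselves are not placed because no analysis in this
package consumes them — only ring and base atoms matter downstream.

The default A-form spec has **zero inclination**: the base pairs are
displaced from the axis but stay perpendicular to it. This keeps an exact
identity between the builder's twist and the twist recovered by the step
analysis for *any* spec (with built-in inclination, the mid-frame twist
of a fiber is systematically below the generating rotation), and it is
precisely the geometry of the "LirA" conformation discussed below, which
the `hetero-duplex` preset uses as its starting structure. Users can set
a nonzero inclination; the twist identity then no longer holds exactly
and the step analysis reports the mid-frame value.

The Hoogsteen third strand is placed in the major groove, parallel to the
purine strand, from idealized T·A and C⁺·G triad templates fitted so that
both triad hydrogen bonds (N7–N3 and N6–O4 or O6–N4) measure 2.90 Å with
near-linear donor geometry. The published models behind this kind of
analysis were built with commercial/server tools whose exact triad
coordinates are unrecoverable; the contract here is therefore the
postcondition — every HG N7–N3 distance in a built model is below the
3.5 Å pairing cutoff — not any particular template's coordinates.
Phosphates are placed from a single calibrated position in the pair frame
chosen so a B fiber reproduces the textbook cross-strand P–P separations
(11.7 Å minor / 17.2 Å major); backbone torsional realism beyond that is
not guaranteed and not consumed.

## Sugar pucker: measurement and construction

The pseudorotation phase and amplitude come from the five endocyclic
torsions ν₀…ν₄ via tan *P* = ((ν₄+ν₁)−(ν₃+ν₀)) / (2ν₂(sin 36° + sin 72°)),
with the ν₂ < 0 branch shifting *P* by 180°, and τₘ = ν₂ / cos *P*.
Two numerical choices matter:

* At *P* = ±90°, cos *P* = 0 makes the amplitude formula 0/0; the package
  switches to the equivalent sine form τₘ = ((ν₄+ν₁)−(ν₃+ν₀)) /
  (2(sin 36° + sin 72°) sin *P*) whenever |cos *P*| < |sin *P*|. Same
  definition, conditioned everywhere.
* A ring is declared planar ("undefined pucker") only when all five
  torsions are below 10⁻⁶ degrees — ν₂ alone vanishes legitimately at
  *P* = ±90°, so testing ν₂ would reject valid geometries.

`set_sugar_pucker()` solves the inverse problem: rebuild the five ring
atoms so the *measured* (*P*, τₘ) equal a target. A closed five-ring with
fixed bond lengths cannot satisfy five prescribed torsions exactly, so
the constructor chains the atoms using ν₁ and ν₂ as inputs and fixed-point
iterates the input phase/amplitude until the measured values match the
target (to 10⁻⁹ degrees in the exported function; the trajectory
generator uses 10⁻⁵, far inside its 10⁻⁴ contract). The base is kept
fixed during a rebuild — preserving the glycosidic torsion exactly — and
remaining exocyclic atoms (the phosphate) follow the sugar-local frame
rigidly. LNA residues reject any south target (90° < *P* ≤ 270°) as
locked nucleotides. χ is reported in [0°, 360°) and *P* in (−90°, 270°]
so the literature bins — *syn* (30°, 90°), *anti* (170°, 320°) with low/mid/high
splits at 220° and 270°, north (−90°, 90°], south (90°, 270°] — form
true partitions; the unnamed anti region [220°, 270°] is labelled
`mid_anti` so that reported fractions are complete.

## Pairing and persistence

WC pairs are monitored through the purine N1 – pyrimidine N3 distance and
HG pairs through purine N7 – TFO N3; a heavy-atom distance below 3.5 Å
counts as a formed hydrogen bond. No hydrogens or angle criteria are used,
and no temporal smoothing is applied. A pair is "lost" when its unpaired
fraction over the final third of the trajectory exceeds 0.5 — a stated,
configurable criterion chosen to match how persistence plots are read
(blank endings), since lost-pair counts are conventionally reported
without one. Terminal fluctuations are reported, not suppressed; the
exclude-ends reporting option (default: two nucleotides per strand end,
matching the analysis convention for these systems) is the intended way
to ignore them.

## Step parameters and the conformation call

Base-pair frames come from least-squares (Kabsch) fits of the base ring
atoms to the idealized templates (fit RMSD > 0.5 Å errors as a deformed or
misnamed base); the strand-II frame is flipped about its x axis and
averaged with strand I via the half-rotation. Step parameters use the
mid-frame CEHS convention (twist about the mid z after symmetrizing the
roll/tilt hinge; shift/slide/rise as the origin displacement in mid-frame
axes). x-displacement and inclination come from the local helical
decomposition of each step: the screw axis of the frame-1→frame-2 motion,
the perpendicular offset of the pair origins from that axis along the
pair x, and the angle of the mid-frame y axis to the plane normal to the
axis. This differs from the curvilinear-axis convention of Curves+-style
analyses by a few tenths of an Å or degree on irregular structures, and
it computes x-displacement per *step* rather than per base pair; on ideal
fibers the two conventions agree. Terminal steps are flagged and excluded
from summaries by default.

The conformation call uses configurable thresholds bracketing the
reported mean tuples for these systems: **B** when x-displacement ≥
−1.5 Å and twist ≥ 34°; a candidate A family when x-displacement ≤
−3.0 Å, slide ≤ −1.0 Å and twist ≤ 32°, resolved to **A** when
inclination ≥ 12° or roll ≥ 8°, to **LirA** when inclination < 8° and
roll < 8°, and otherwise — including everything between the B and A
boxes — to **intermediate**. With these defaults the tuple
(−0.8 Å, 0 Å, 36°) classifies B and (−4.3 Å, −1.6 Å, 30°) classifies
LirA. Groove widths are minima of cross-strand P–P distances per level
minus a 5.8 Å phosphate-radius correction; they are reported
qualitatively (minor < major for B) rather than spline-refined.

## The synthetic trajectory generator

The generator is the package's source of ground-truthed test data. It
emulates the statistical structure of MD snapshot series — frames every
40 ps by default — without any kinetic realism:

* **Sugar repuckering** is a two-state Markov chain per residue whose
  stationary north fraction is the contract (DNA default 0.30, reflecting
  the south preference of DNA sugars; the exact fraction is free in the
  literature and configurable here; LNA is fixed at 1). In the north
  state *P* is drawn from Normal(17°, 5°) truncated to the north range;
  in the south state from Normal(162°, 8°) truncated south; each frame's
  ring is rebuilt at the drawn phase.
* **HG pair opening** is a two-state chain per pair with stationary open
  probability `p_open`; an open TFO nucleotide is displaced rigidly by
  3 Å along the groove-exit direction (2.9 Å closed → 5.9 Å open, cleanly
  straddling the 3.5 Å cutoff). `end_bias_profile()` raises `p_open` on
  the terminal DNA-only run of a TFO, emulating the observation that
  base-pair opening concentrates where LNA is absent, preferentially at
  the 3′ end.
* **Noise** is isotropic Gaussian (default σ = 0.15 Å) on every atom,
  with a consistency contract: noise draws that would contradict the
  realized states are rejected and redrawn — the two nitrogens of a
  monitored pair whose formed/open state would flip at the cutoff, and
  the five ring atoms of a residue whose measured north/south class would
  flip. The second redraw matters more than it may seem: 0.15 Å
  coordinate noise induces a ~27° standard deviation on the measured
  pseudorotation phase (torsions are noise-sensitive at 1.5 Å bond
  lengths), which would otherwise contradict the recorded state in about
  1% of residue-frames. With both redraws the emitted persistence matrix
  and the per-frame pucker classes equal the recorded ground truth
  exactly, which is what makes exact (rather than statistical) validation
  possible.
* Transition intensity defaults to 0.1 per frame (0.05 each way at
  p = 0.5), so consecutive frames are strongly correlated, as MD
  snapshots are. Statistical parameter-recovery tests in the package
  instead set the intensity to 1 — independent frames — because their
  tolerance is stated in binomial standard deviations, which is only the
  right error model for independent sampling; at the default correlation
  the true standard error is ~4.4× binomial. The correlated default is
  validated by the exact ground-truth-equality contract instead, which
  holds for every seed.

All randomness flows from the single integer seed; two runs with the same
spec are bit-identical, and the caller's RNG state is left untouched.

Presets bundle the studied systems at desk scale: `3prime-reduced` and
`5prime-reduced` (triplexes whose TFO lacks LNA in the 3′ or 5′ segment,
with opening probability 0.9 on the DNA-only run against a 0.02
baseline), `lna-tfo` (stable alternating-LNA triplex), `hetero-duplex`
(the LNA-substituted duplex started from the LirA-like spec: twist 30°,
x-displacement −4.3 Å, zero inclination), and `duplex-only`. Preset sizes
default to a few hundred frames; the recovery analyses in the test suite
use 15-residue single strands at 2000 frames and the full 53-residue
triplex at 2000 frames, sizes chosen so that binomial error bars are a
few percent while a full run stays in the minutes range on one CPU.

## What passing tests do and do not show

The generator reproduces the *statistical* structure the analyses assume
— locked LNA sugars, two-state repuckering, end-biased opening, additive
noise — not molecular mechanics. Recovery of generator parameters
therefore validates the analysis code (binning, distances, bookkeeping,
end exclusion), and the builder round trips validate the geometry engine;
neither says anything about force-field accuracy or about real DNA
beyond the geometric definitions themselves. Observables that emerge from
real MD ensembles (specific lost-pair counts, mean x-displacement of
relaxed triplexes) are deliberately not calibration targets.

## Known limitations

* Backbone torsions α–ζ and BI/BII substates are not computed; grooves
  are measured from phosphates placed by a calibrated template, so
  absolute groove numbers on non-fiber input are approximate.
* TINA and other intercalators have no 3D representation.
* The step-parameter scheme is the mid-frame/local-helical one; numbers
  on strongly bent structures differ from curvilinear-axis analyses.
* Hydrogen-bond detection is a single heavy-atom distance; bifurcated
  bonds and donor-angle criteria are out of scope.
* The PDB reader handles the v3.3 fixed-width subset this package writes
  (ATOM/MODEL/ENDMDL/END and its own REMARK); it is strict by design,
  erroring on truncated or malformed files rather than reading partially.
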