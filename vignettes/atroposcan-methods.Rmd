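---
title: "Screening and quantifying atropisomerism: methods and design choices"
author: "atroposcan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and quantifying atropisomerism: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atroposcan)
options(atroposcan.quiet = TRUE)
```

## The problem

Large, flexible drug molecules — PROTAC degraders, linear peptidomimetics and
other beyond-rule-of-5 chemotypes — carry many single bonds whose rotation can
be hindered enough to produce *atropisomers*: conformers that interconvert
slowly on experimental time scales. On the LaPlante scale, judged by the
racemization half-life at 37 °C (310.15 K), Class 1 axes (ΔG‡ < 20 kcal/mol,
t½ < 60 s) behave as achiral; Class 3 axes (> 30 kcal/mol, > 4.5 years) are
isolable compounds; the Class 2 window in between (minutes to months) is the
treacherous one — it can split NMR signal sets, impede crystallization and
make a single nominal structure behave as a slowly equilibrating mixture.
`atroposcan` implements the two desk-side routes for finding and quantifying
such axes: a fragment-based restrained torsion scan for *screening*, and
variable-temperature (VT) NMR coalescence analysis for *measurement*.

## Rotatable-bond detection

A bond qualifies as a rotatable axis when it is a single bond, not in a ring,
and both axis atoms are heavy atoms with at least two heavy neighbours
(nothing terminal rotates into a new heavy-atom conformation). Two deliberate
conventions refine this base rule:

* **Amide C–N bonds are included.** Standard "strict" rotor definitions
  exclude them, but the partial double-bond character of the peptide bond is
  precisely what creates high rotational barriers — amide axes are primary
  atropisomerism candidates in peptidomimetics, so the screen must see them.
* **The conjugation-locked bonds of ester and carbamate units are excluded**:
  both the carbonyl–oxygen single bond `(O=)C–O` and, in carbamates, the
  nitrogen–carbonyl bond `N–C(=O)O`, across which the π system is delocalised.
  The ester/carbamate *O–alkyl* bond remains rotatable.

With this convention the shipped tool-compound structures yield 20 axes for
ACBI1 and 17 for BI201335, and the toy expectations hold (ethane 0, butane 1,
biphenyl 1). The measured torsion quadruple (a, i, j, b) takes, on each side,
the heavy neighbour of highest atomic number, ties broken by lowest atom
index — deterministic and chemically sensible (heteroatoms define the frame).

```{r detect}
detect_rotatable_bonds(fixture_mol("butane"))
nrow(detect_rotatable_bonds(fixture_mol("acbi1")))
```

## Fragmentation

Scanning a torsion inside the full molecule is wasteful; the package carves a
fragment around each axis instead. The scheme is a transparent shell
expansion: keep both axis atoms and every heavy atom within `shells` bonds of
either (default 2), then complete — iterating to a fixed point — any ring
system, multiple-bond partner (carbonyls, imines) or charged group touched,
and cap cut heavy–heavy bonds with hydrogens. The published fragmenters this
emulates make finer electronic judgements; the shell scheme was chosen
because it is fully documented, deterministic and testable, and the shell
count is exposed rather than guessed (`shells` is a user parameter precisely
because no printed fragment structures exist to calibrate against).
Invariants enforced by construction and tests: the target torsion maps
injectively onto parent atoms, caps map to nothing, and molecules smaller
than the shell radius come back unchanged.

## 3D embedding

Fragments are embedded with the ETKDG distance-geometry generator followed by
an MMFF94 cleanup, driven through the system `python`'s RDKit. This embedder
is exactly reproducible for a fixed seed — a contract the test suite asserts
— which is why it was preferred over the OpenBabel generator (whose conformer
search draws system entropy and cannot be seeded through its available
interfaces; it remains a fallback when no RDKit-capable python is present,
with the loss of reproducibility documented). Geometric sanity is validated
on every embedding: no two atoms within 0.7 Å, bonded distances within
0.6–2.0 Å; failures retry with advanced seeds and then surface as per-fragment
error conditions that pipeline drivers log and skip.

## The restrained torsion scan

The target dihedral is driven over a uniform grid — 36 points at 10° by
default (`step_deg × n_points = 360` is enforced) — with each point starting
from the previous point's relaxed geometry (torsion-drive continuation,
disable with `continue_from_previous = FALSE`). At each angle the geometry is
relaxed under a harmonic dihedral restraint in two stages, with force
constants 10^5 then 10^6 kJ/mol. The printed force constants leave the unit
basis unstated; they are interpreted as kJ/mol·rad⁻², and the immaterial-ness
of that choice is made contractual: after stage 2 the dihedral must sit
within 0.5° of its target (asserted, else the point fails), and the residual
sub-degree offset is then snapped back onto the grid angle — the frozen-
dihedral limit of the very stiff stage-2 restraint — before the backend
energy is recorded. Profiles are reported as relative energies (minimum
exactly zero, enforced by exact subtraction). Up to two failed grid points
are interpolated linearly on the periodic grid; three or more mark the scan
failed. This failure policy is a package invention (the upstream procedure is
silent on scan failures) and is stated here so users can judge it.

### Energy backends

The engine is deliberately backend-agnostic behind a two-function contract
(`evaluate`, restrained `optimize`; optimization may never raise the
restrained energy):

* **Analytic cosine backends** (`cosine2`, `cosine3`, or any
  `backend_cosine(m, B, sign)`) depend on the target dihedral alone. They
  exist to validate the engine: a scan must reproduce the closed form at
  every grid point to 1e-6 kcal/mol — the engine adds no energy of its own —
  and the test suite holds it to that.
* **The steric backend** is a light molecular-mechanics surrogate authored in
  this package: harmonic springs on all 1-2 and 1-3 distances referenced to
  the embedded geometry (local bond lengths and angles held), plus a purely
  repulsive (σ/r)^12 term (σ = 0.9 × sum of van der Waals radii, ε = 0.1
  kcal/mol) between pairs three or more bonds apart, with analytic gradients
  for the Cartesian optimizer. It reproduces the *shape* physics of
  clash-driven profiles — ortho-substituted biphenyls show planar maxima and
  twisted minima — and is qualitative by design: it is not a literature force
  field and its barrier heights are not quantitative.
* **`stub-qm`** is an interface stub reserved for an external quantum-
  chemistry engine; evaluating it raises a configuration error. Reproducing
  published ML-potential or DFT profile energetics is explicitly out of
  scope: those require model weights and a QM engine, and nothing in this
  package's tests or acceptance quantities depends on them. What the analytic
  backends verify is the *workflow* around the energy model.

## Profile features and the screening rule

On the periodic profile, minima and maxima are located plateau-safely and
then filtered for *clarity* with a prominence rule (default 1 kcal/mol,
exposed — "clear" is not a defined term upstream, so the threshold is a
parameter, not a constant): the adjacent minimum–maximum pair of smallest
energy contrast is cancelled repeatedly while that contrast is below the
prominence. This is persistence cancellation on a circle, and the test suite
checks it against an independently implemented sublevel-set union-find
oracle on random profiles. Features follow by definition: ΔΔV_min is the
spread of the surviving minima; max(V_max) and min(V_max) are the highest and
lowest barrier heights. Barriers are measured above the *global* minimum by
default — consistent with profiles being re-referenced to their minimum —
with an `"adjacent"` option (barrier above the higher flanking minimum of
each saddle) because the upstream table does not state which reference it
used. A torsion is flagged **of interest** when max(V_max) > 13 kcal/mol and
at least 2 clear minima remain.

LaPlante classes from barriers use half-open bands, lower bound inclusive
(none < 10 ≤ Class 1 < 20 ≤ Class 2 < 30 ≤ Class 3); upstream prose and
figure captions disagree on boundary strictness, so one convention was fixed
and is stated here. Classification is monotone by construction.

## VT-NMR coalescence kinetics

For a rotamer signal pair resolved at slow exchange, the barrier follows from
the modified Eyring equation
ΔG‡ = R·T_coal·[22.96 + ln(T_coal/δν)] (J/mol), with
δν = |Δppm| × spectrometer MHz taken at the lowest measured temperature (the
slow-exchange convention; a user-supplied δν overrides it). When coalescence
is observed in range, T_coal is the bracketing temperature; otherwise the
peak separation in Hz is regressed linearly on temperature and extrapolated
to zero, with a delta-method standard error — a deliberately simple model,
matched by the synthetic-series generator below. When even extrapolation is
unwarranted, the report evaluates user-listed candidate temperatures, which
is how a barrier is honestly bracketed when the hardware cannot reach
coalescence: for the shipped ACBI1 pair (δν = 64.02 Hz) the candidates
393.15/423.15/453.15 K give 19.4/20.9/22.4 kcal/mol. Half-lives use the
standard Eyring rate k = (k_B·T/h)·exp(−ΔG‡/RT), t½ = ln 2/(s·k) with the
statistical factor s defaulting to 1 (set 2 to count racemization as
two-sided enantiomerization; the rate model is stated because the coalescence
formula alone does not fix it).

Two numerical conventions matter and are worth stating plainly:

* **Temperatures are Kelvin everywhere**, and the shipped experimental
  temperatures carry the +0.15 K offset of Celsius-set VT units (30 °C =
  303.15 K, 120 °C = 393.15 K). With integer-Kelvin nominal temperatures one
  of the six reference barriers lands a half-rounding-step low (19.348 →
  19.3 instead of 19.4); with the Celsius-derived values all six reproduce
  exactly at 0.1 kcal/mol rounding — which is the behaviour the acceptance
  checks assert.
* Barrier values are reported rounded to 0.1 kcal/mol in printed summaries
  and kept at full precision internally (the stored estimate must recompute
  from its own T_coal and δν to 1e-9).

## The synthetic VT-series generator

`synth_vt_series()` emulates the raw input of a coalescence analysis: a
signal pair whose Hz separation decays *linearly* to zero at the true
coalescence temperature, sampled on the experimental 10 K grid from
303.15 K, with optional Gaussian noise on the separation (seeded, restoring
the caller's RNG state). Defaults mirror the study conditions: 400.13 MHz
proton frequency, ten temperatures, separations of order 10²  Hz. Linear
decay is an idealisation — real separations curve as exchange broadening sets
in near coalescence — but it matches the estimator's assumption exactly,
which is what makes sharp parameter-recovery tests possible: noiseless series
must recover T_coal (and hence ΔG‡) exactly, and 2 Hz-noise series recover it
with sub-2 K mean error over 50 seeds. Passing those tests therefore
validates the estimator and the plumbing, not the physics of lineshapes near
coalescence; fitting real VT data close to coalescence is out of scope (a
Bloch–McConnell lineshape analysis would be the right tool there).

## Fixtures

BI201335 (faldaprevir) is transcribed from its published structure; the
2-acylamino-thiazole variant is the one consistent with the compound's
empirical formula C40H49BrN6O9S (the invariant the test suite checks) and
with the crystallographic observation of a doubly hydrogen-bonded
acid–amidothiazole motif. ACBI1, which never crystallized and has no printed
formula, is a curated transcription of the published SMARCA2/4 PROTAC:
phenol–pyridazine–piperazine warhead, short bis-amide glycol-diether linker,
VH032-class VHL ligand; residual transcription ambiguity (the exact linker
cap) was resolved in favour of the published detection count, as the fixture
documentation states. The four VT signal pairs carry the printed 303 K
chemical shifts. Problem sizes throughout the tests are desk-scale by
choice — toy rotors and fragments of a few dozen atoms — which keeps every
scan and embedding in the suite a sub-second to few-second affair.

## Known limitations

* The steric backend is qualitative; quantitative screening needs a real
  force field or ML potential behind the backend contract.
* One seed conformer per fragment: no conformer ensembles, no 2-D torsion
  surfaces, no wavefront propagation over coupled torsions.
* The coalescence extrapolation is linear and single-pair; no lineshape
  simulation, no ROESY cross-peak logic (rotamer-vs-diastereomer assignment
  stays with the spectroscopist).
* Detection conventions are calibrated for drug-like organic molecules;
  organometallics and exotic valences are outside the tested envelope.
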