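---
title: "Methods and design notes for the katpscreen pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for the katpscreen pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(katpscreen)
```

# Scope

katpscreen implements the computational stages of a pharmacochaperone
discovery campaign against the pancreatic K~ATP~ channel (four Kir6.2
subunits and four SUR1 sulfonylurea-receptor subunits): post-scoring
triage of a virtually screened compound library, quantification of Rb^+^
efflux dose-response assays with variable-slope Hill fits,
binding-pocket dynamics analysis of multi-run MD ensembles, and
spherical-probe pore-radius profiling of channel coordinates. The
upstream heavy machinery — the neural scoring of docked poses, cryoEM
reconstruction, and the MD engine itself — is out of scope; the package
starts from scores, plate readings, and coordinate ensembles.

Every analysis stage is paired with a synthetic-data generator that
plants a known truth, so the whole pipeline is testable end to end with
no downloads. The generators are first-class, tested code, not test
scaffolding: their defaults define the study conditions under which the
package's recovery claims are made.

# Screen triage

The funnel operates on binary ECFP4-like fingerprints (bit-index sets)
with a per-compound score from a pluggable source. Stages, in the order
`run_triage()` applies them:

1. **Novelty filter.** A compound is excluded iff its maximum Tanimoto
   similarity to any known binder of the target (or close homologs) is
   *strictly* greater than the cutoff (default 0.5). The boundary is
   deliberate: a compound at exactly 0.5 is retained.
2. **Rank and truncate.** Descending by score, ties broken ascending by
   compound id, keep the top *n* (default 30,000).
3. **Butina clustering** at similarity cutoff 0.35: neighbor lists at
   similarity ≥ cutoff; the unassigned compound with the most unassigned
   neighbors becomes the next centroid and sweeps its unassigned
   neighbors into a new cluster. Counts are recomputed each round, and
   ties on neighbor count break ascending by id. With the id tie-breaks
   the whole funnel is invariant to input order.
4. **Property filters.** Named predicates over a per-compound property
   list. The shipped defaults are Lipinski-style oral-availability rules
   (MW ≤ 500, logP ≤ 5, HBD ≤ 5, HBA ≤ 10) plus a toxicophore-count
   check. These are explicit stand-ins: industrial medicinal-chemistry
   rule sets are proprietary and are not reproduced here. A predicate
   touching a missing property is an error naming the property, never a
   silent pass.
5. **Candidate selection.** At most one compound per cluster — its
   best-scoring member — visiting clusters in decreasing order of their
   best member's score, until *n*~select~ (default 96) compounds are
   chosen. How to draw a fixed number of candidates from a clustered
   list is genuinely underdetermined; best-member-per-cluster in
   best-cluster order was chosen because it preserves both scaffold
   diversity (one per cluster) and score optimality within each
   scaffold, and it degenerates exactly to plain score ranking when all
   clusters are singletons (a property the tests exploit as a
   cross-check oracle).

Two conventions worth noting: the Tanimoto similarity of two *empty*
fingerprints is defined as 0 (with a warning) — featureless records
should neither be excluded as look-alikes nor merged into clusters — and
the funnel order (novelty → rank → cluster → filter → select) follows
the narrative order of a typical screening campaign but each stage is an
exported function, so other orders are a few lines of user code.

# Rb^+^ efflux dose-response

## Quantification

Fractional efflux of a well is Rb^+^ in the efflux solution over total
Rb^+^ (efflux + lysate), a number in [0, 1] by construction.
`preprocess_efflux()` then, per biological replicate (independent
transfection): averages technical duplicates, subtracts the mean
untransfected (background) fraction, clips negative results to 0 *with a
flag* (never silently), and normalizes to the mean background-subtracted
fraction of the reference condition. Reference wells therefore average
exactly 1 per replicate. Preprocessing refuses its own output: applying
background subtraction or normalization twice is silent data corruption,
so the result carries a class tag and a provenance attribute instead of
being a bare table.

## Hill fit

The inhibition model is the four-parameter logistic with variable slope,

$$y = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
      {1 + (x / \mathrm{IC}_{50})^{h}}, \qquad h > 0,$$

fit by Levenberg–Marquardt least squares (`minpack.lm`), multi-started
from five log-spaced IC~50~ seeds spanning the dosed range. The fit is
parameterized in log IC~50~, which makes dose-scale equivariance exact
(scaling all doses by *c* scales the fitted IC~50~ by *c*) and gives a
delta-method standard error on the natural scale. Vehicle (dose 0)
points cannot sit on a log-dose axis; they enter the residuals through
the zero-dose limit of the curve ($y = \mathrm{top}$) and so anchor the
upper asymptote without distorting the dose grid.

Numerical guards, chosen for noisy 5–8-point curves: top ∈ [0, 1.5],
bottom ∈ [0, 1.5] with bottom > top flagged as non-convergence, slope ∈
(0, 10], and an IC~50~ escaping [min dose/100, max dose×100] reported
but flagged. Flat response vectors are rejected up front as
non-convergent — there is no inhibition signal to fit.

Potency is reported as the mean IC~50~ with its SEM *across biological
replicates* (`ic50_with_sem()`), matching the convention of averaging
independent experiments; the covariance-based per-fit SE is attached to
each replicate fit as a secondary output, since published error bars are
sometimes one and sometimes the other.

Group comparisons (`compare_to_control()`) are a thin wrapper over
one-way ANOVA with Dunnett or Tukey post hoc adjustment via `multcomp`;
the all-constant degenerate case reports an undefined F and adjusted
p-values of 1 by convention rather than erroring.

## What the plate generator emulates

`gen_plate()` draws raw signal pairs, not fractions: the planted
noiseless fraction (background + Hill curve) splits a fixed total Rb^+^
into efflux and lysate signals, and each signal independently receives
mean-one multiplicative log-normal noise. Instrument readings are
positive, and noising the signals rather than the fractions gives the
derived fractions realistic heteroscedasticity. Defaults are the study
conditions used throughout the tests: vehicle plus eight log-spaced
doses over 1–200 µM, technical duplicates, three biological replicates,
5% signal CV, top fractional efflux 0.70 over a 0.10 untransfected
background (with top + background ≤ 1 enforced so fractions stay
physical), planted IC~50~ 9.23 µM with unit slope. The generator does
not emulate plate-position effects, pipetting covariance between
duplicate wells, or compound solubility artifacts, so recovery results
here say nothing about those failure modes in real assays.

# Binding-pocket dynamics

## Alignment

Each frame is rigidly superposed onto frame 0 of its own run over the
pocket Cα selection (the helices forming the binding site), using a
Kabsch SVD superposition with the reflection correction, so the
rotation is always proper. The same transform moves every atom, putting
ligand and peptide motion in the pocket frame of reference. Collinear or
coincident selections are rejected (the rotation about the degenerate
axis would be arbitrary). The test suite anchors the implementation to
an independent quaternion (Horn) superposition oracle.

## Fragment mobility

The ligand is divided into named fragments (a–e in the shipped scheme);
per fragment, the heavy-atom mass-weighted centre of mass is traced
through every frame (a geometric-centre option exists for sensitivity
checks). Mobility is summarized as the root-mean-square displacement of
the COM from its frame-0 position, per run, pooled across runs as the
root mean square of per-run values. For isotropic jitter of SD σ this
statistic has expectation √3·σ, which is what the planted-truth tests
assert; a single-frame run gives exactly 0.

## Contact analysis

A residue is in contact in a frame iff the minimum heavy-atom pair
distance between its atoms and any ligand atom is ≤ 3.5 Å. Hydrogens
are excluded by default: heavy-atom contact is the usual convention for
this cutoff, and synthetic or experimental hydrogen placement would
otherwise dominate the boundary. Both the hydrogen policy and the
cutoff are arguments. The inclusion rule for the retained-residue set is
whole-ligand contact for at least 30% of frames in at least 3 of 5 runs
(both comparisons inclusive, "at least"); per-fragment fractions are
reported but do not drive inclusion. For ensembles that are not
five-run, the quorum generalizes to ⌈3/5·n⌉. The reporting table is
filtered at a *strict* threshold (mean fraction > 0.40 across runs,
"over 40%") with per-fragment columns unfiltered for the retained rows;
pooling across runs (rather than picking a representative run) is the
default because it uses all the data and needs no selection rule.

Distances are computed by exact vectorized matrix algebra rather than a
cell-list neighbor search: at the ensemble sizes this package targets
(tens of atoms, hundreds of frames) the vectorized scan is faster in R
than an interpreted spatial index, and it is exact. Correctness is
anchored by a brute-force all-pairs oracle in the test suite, so the
search strategy remains an internal detail.

## What the trajectory generator emulates

`gen_trajectory()` builds pocket residues (three heavy atoms each) on a
14 Å ring around a five-fragment ligand. Contact occupancies are planted
through dedicated anchor atoms placed exactly 3.0 Å (contact) or 6.0 Å
(non-contact) from the residue's innermost atom in a random subset of
round(occupancy × n~frames~) frames, using the same distance definition
as the analyzer — so planted truths are exact, not approximate, and a
geometrically infeasible plan (e.g. two planted residues so close that
one residue's anchor is within the cutoff of the other) is detected by a
post-generation verification pass and rejected with a diagnostic.
Fragment jitter is drawn per frame as isotropic Gaussian displacement,
zero in frame 0 (so frame-0 is the reference pose) and truncated at 3σ;
the truncation guarantees jitter can never create accidental contacts,
at the cost of deflating the √3·σ mobility expectation by about 4%,
well inside the 15% tolerance the recovery tests use. Jitter draws
precede all drift draws in the RNG stream, so the same seed produces
identical internal motion with and without drift — that is what makes
the rigid-motion-invariance contract testable exactly. The default
sigmas (0.2–0.5 Å for fragments a–d, 2.0 Å for fragment e) mirror a
ligand that is anchored at one end and samples conformations at the
other. The generator makes no attempt at realistic protein geometry,
bonded structure, or force-field physics; it emulates exactly the
features the analyses measure (alignment selections, COM dispersion,
contact distances) and nothing else, so passing tests certify the
analysis code, not any biophysical realism.

# Pore profiling

`pore_profile()` is a HOLE-style spherical-probe profiler: at each plane
along the pore axis it finds the largest sphere centred in the plane
whose surface touches no atom's van der Waals sphere (default radii:
Bondi, overridable per element). Two numerical choices differ from
classic HOLE, both for reproducibility:

* **Deterministic search instead of simulated annealing.** Planes are
  traced in axial order; each plane's lateral search is a coarse
  0.25 Å grid within a bounded window around the previous plane's probe
  centre, refined by a local 0.1 Å grid and a Nelder–Mead polish.
  The windowed tracing is not just an optimization: an unconstrained
  lateral search escapes *outside* the wall wherever the channel
  narrows (the region beyond an hourglass waist is far from all atoms),
  so confinement to the connected lumen path is what makes the
  constriction measurable at all.
* **Capping and degeneracy flags.** Radii are capped at `max_probe`
  (flagged `capped`), a plane whose best sphere still overlaps an atom
  reports radius 0 (flagged `blocked`), and a plane with no atoms in
  reach is a capped sample, not an error.

On analytic fixtures the two-stage grid agrees with a dense brute-force
lateral grid to better than 0.05 Å, and the profile satisfies the exact
shift identity (shrinking all vdW radii by δ grows every radius by δ)
and rigid-rotation invariance when the axis is co-rotated. The axis is
supplied by the caller (default +z after pre-orientation); automatic
pore-axis detection and curved-axis tracing are out of scope.
`min_radius_near()` localizes a constriction near named landmark
residues — e.g. the helical-bundle-crossing gate of a closed Kir
channel, where a probe radius of ~0.75 Å (far below the ~1.3 Å of a
dehydrated K^+^ ion) means a sealed gate. The default constricted
fixture plants its waist at exactly that geometry (wall 2.25 Å, atom
radius 1.5 Å).

# Configuration and reproducibility

The umbrella `run_pipeline()` is driven by one YAML file with a strict
schema: unknown keys are fatal anywhere, so a mistyped threshold name
cannot silently revert a default. Units are fixed package-wide
(Angstrom, µM, 1-based PDB residue numbering in everything
user-facing). Every run writes a provenance manifest with the package
version, seed, config digest and per-output digests; identical config
and seed reproduce identical digests. All generators take explicit
seeds, use an isolated RNG stream (`withr::with_seed`), and record the
seed in their truth records.

# Problem sizes and verification

The shipped verification studies use: 500 simulated triplicate
dose-response experiments (IC~50~ drawn log-uniformly over 2–50 µM, 5%
noise) for IC~50~ recovery — observed median absolute relative error
about 2% with bias under 1%; 100 random five-run ensembles for
contact-oracle equivalence and exact planted-occupancy recovery; 100
random ≤ 12-compound libraries for Butina-vs-brute-force agreement;
analytic cylinder and constricted fixtures for the pore profiler; and
1,000 simulated global-null four-group experiments for the Dunnett
family-wise error rate. These sizes give Monte-Carlo error comfortably
below each tolerance while keeping the whole suite fast enough to run
on every change.

# Known limitations

* The triage property filters are labelled stand-ins, not a validated
  medicinal-chemistry rule set; fingerprint generation from structures
  is delegated to external chemistry toolkits and only precomputed
  bit-sets are handled natively.
* The Hill machinery models inhibition only (response decreasing in
  dose); stimulation/EC~50~ curves are out of scope.
* Contact analysis and mobility assume the alignment selection is
  itself quasi-rigid; a pocket that deforms substantially would make
  "mobility in the pocket frame" ill-defined, and no diagnostic for
  that is provided beyond the per-frame fit RMSDs.
* The pore profiler traces a straight axis; strongly curved or branched
  permeation pathways need a curved-axis method.
* Binary trajectory formats (DCD/XTC) are not parsed natively; convert
  to multi-frame XYZ, or read them with an external library and build a
  `trajectory_ensemble()` from the arrays.
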