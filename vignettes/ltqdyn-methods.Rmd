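---
title: "Methods: modelling and analysing LTQ/Cu active sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling and analysing LTQ/Cu active sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltqdyn)
```

## Scope and model

`ltqdyn` covers the desk-scale part of building a mature, LTQ-containing
model of a lysyl-oxidase-like amine oxidase from a precursor structure, and
of characterising the result: geometry editing (dihedral transplantation,
cofactor graph patches, metal swap, water placement), static metal-site
analysis (coordination sphere, Addison τ, Jahn–Teller axis, rotamers, ring
stacking, van der Waals contacts), and trajectory statistics (RMSD, RMSF,
B-factors, Cα PCA, displacement fields, τ and rotamer time series). Energy
minimisation and production molecular dynamics are deliberately out of
scope: those are jobs for a force-field engine. The package instead provides
the *geometric evaluators* (planarity impropers, target angles) that let a
user verify the constraints such an engine would impose, and synthetic
generators that stand in for production trajectories when testing the
analysis chain.

## Coordinates, units, conventions

Coordinates are ångström throughout; angles and torsions are degrees.
Torsions follow the standard sign convention used by the common structural
toolkits (trans = 180°; verified in the test suite against independent
implementations), reported in (−180°, 180°]. Trajectory statistics default
to nanometres (the unit in which RMSD/RMSF plots are usually read) with an
explicit ångström toggle; B-factors are always Å². Residues keep their
1-based author numbering; nothing is renumbered silently. Frames are
numbered from 1 in all reports; the default frame spacing is 40 ps, so a
251-frame series spans 10 ns.

## Structure I/O

PDB records are parsed with `bio3d`; CONECT records are additionally scanned
so that nonstandard connectivity (the Nζ–C2 crosslink, quinone ring bonds)
survives a round trip, and the writer emits CONECT for every recorded bond.
Alternate locations default to the highest-occupancy conformer because every
downstream geometry needs exactly one position per atom; `keep_altloc =
TRUE` retains all conformers. Hydrogens are read when present; all analyses
except the water-orientation restraint ignore them by default (selections
are explicit atom-index vectors, so the caller decides). The XYZ trajectory
dialect — atom count, comment line carrying `t= <ps>`, then `element x y z`
— was chosen so synthetic trajectories need no binary dependencies.

## Dihedral transplantation

`transplant_segment_dihedrals()` is a torsion-only rebuild: for each
backbone torsion in the segment it rotates the set of atoms distal to the
bond by the difference between current and target angle. Bond lengths and
bond angles are therefore preserved exactly (to rounding), which is the
property that makes the operation safe on an experimental structure. The
default anchor is the N-terminal side — the use case is re-shaping a short
internal strand while the domain fold stays put, so upstream atoms must not
move — and atoms beyond the segment ride rigidly with the last rebuilt
peptide frame. ω torsions are applied when the template provides them and
set to trans (180°) when it does not, so noisy or truncated templates cannot
introduce accidental cis peptides. A C–N distance above 2.5 Å inside the
segment is treated as a chain break and refused rather than rotated across.

Template side-chain χ values are applied through the same bond-rotation
machinery. χ extraction walks the lysine-type atom ladder
(N–Cα–Cβ–Cγ–Cδ–Cε–Nζ), which covers the chemistry this package exists for
(native and crosslinked lysines); other residue types yield as many χ as
their ladder prefix defines.

## Cofactor patches

A `cofactor_patch` is a declarative graph edit: atoms to delete, atoms to
add (absolute coordinates or an internal-coordinate rule — bond length,
angle, torsion against three reference atoms, placed by standard
natural-extension construction), bonds to add or delete, residue renames.
Two invariants are enforced and tested: applying a patch changes atom and
bond counts by exactly the patch sizes, and every patch is invertible
(`invert_patch()` reconstructs deleted atoms at their recorded coordinates
and undoes every bond edit). A deletion that would leave a dangling bond is
an error naming the bond — the patch must say what happens to it. The two
canonical patches bundled are the crosslink (delete the C2-bound oxygen of
the quinone–hydrazone, bond Nζ to C2 at a 1.40 Å aromatic C–N target
recorded in the patch metadata, rename to LTQ) and the hydrazone strip
(delete the 2-hydrazinopyridine-derived atoms, restore the C5 carbonyl
oxygen at 1.23 Å / 120°). Patches also round-trip through a one-edit-per-line
text format for use from the command line.

## Water placement and restraint evaluators

`place_coordination_waters()` completes a square pyramid from three basal
donors: the equatorial water goes into the basal least-squares plane along
the direction opposite the mean donor direction (the resolvable gap — if the
donors are symmetric there is no gap and the function refuses), the axial
water along the plane normal on the side with more clearance unless a
direction is given. Defaults are Cu–O_eq 2.00 Å and Cu–O_ax 2.40 Å: the
axial bond of a d⁹ ion is the elongated Jahn–Teller direction, typically
0.2–0.3 Å longer than the basal bonds. Optional hydrogens are built with
metal–O–H angles of exactly 120°, the orientation a charge-repulsion
restraint would enforce during refinement; the H–O–H angle of that
construction is 120° rather than the ideal 104.5°, which is irrelevant to
the restraint being checked and documented here for honesty.

The restraint evaluators score, not minimise: an improper-planarity
restraint reports |improper torsion − target| of four named atoms and an
angle restraint |angle − target|, each with a quadratic penalty
weight·deviation². Note the improper of four exactly coplanar atoms is 0 or
180° depending on the atom ordering (whether the a→b→c→d path is cis or
trans across the axis); the target must be chosen for the ordering used,
exactly as in force-field impropers.

## Addison τ and the coordination sphere

The first shell is every N/O/S atom within the cutoff of the metal. The
default cutoff of 2.6 Å is deliberate: it includes typical 2.0–2.2 Å M–N
bonds and an elongated ~2.5 Å axial oxygen, and excludes a second-shell
histidine at ≥ 3 Å that has detached from the metal. For a 5-coordinate
sphere, τ = (β − α)/60 with β ≥ α the two largest L–M–L angles; the apical
ligand is the one in neither angle. The labels (τ ≤ 0.3 square-pyramidal-
like, τ ≥ 0.7 trigonal-bipyramidal-like) are reporting conventions of this
package — the numeric τ is always given alongside. His donor atoms are
whichever of Nδ1/Nε2 is nearer the metal, since tautomer assignment is
rarely trustworthy. τ time series report frames whose coordination number
is not 5 as undefined with the observed count — they are excluded from the
mean/SD/max but never silently dropped — because transient coordination
changes are themselves a finding. Because a reported "± value" on a τ mean
can be read as SD or SEM, the series object carries mean, SD, SEM and max,
all labelled.

## Rotamer classification

Each χ maps to the nearest of p = +65°, t = 180°, m = −65° under circular
distance. This is the penultimate-library lettering with fixed canonical
values rather than per-position means: the fixed values are what the
letters are defined as in the figure captions this analysis serves, and the
recorded `max_deviation` (flagged "distorted" above 40°) carries the
information a per-position mean would. Run segmentation reports maximal
constant-code runs as (code, first_frame, last_frame); runs shorter than
`min_run` (default 5) frames merge into "mobile" stretches, capturing the
rapid flipping between stable rotamers seen mid-trajectory.

## Trajectory statistics

RMSF and PCA superpose all frames onto an iterated mean structure (two
rounds) on the analysis selection; the RMSD series superposes each frame
onto a reference frame (default the first). The fitting reference for
fluctuation statistics is a genuine choice — trajectories in the wild are
analysed against first frames, average structures, or crystal structures —
and the iterated mean is used here because it makes the RMSF definition
self-consistent and makes Σλ (PCA) equal Σ RMSF² exactly. To keep that
identity, the covariance is the population covariance (mean over frames,
not n−1). PCA is unweighted by default with a mass-weighting flag, since
plain Cα covariance PCA is the common reading of such analyses. B-factors
use the standard Debye–Waller form B = (8π²/3)·RMSF² with RMSF in Å (so
RMSF = 1 Å gives B ≈ 26.319 Å²); no rescaled variant is applied.

A statistical fact worth knowing when interpreting synthetic-data checks:
superposition absorbs 6 rigid degrees of freedom, so the fitted RMSF of N
iid-fluctuating atoms is biased low by a factor ≈ √(1 − 6/(3N)) — about 5%
at N = 20, under 1% at N = 100. The tests account for this explicitly
rather than widening tolerances.

## Synthetic generators and what they do (not) emulate

The harmonic trajectory generator draws independent Gaussian displacements
per frame, with per-residue amplitudes, optionally composed with a
cumulative rigid drift. It is a *statistical* surrogate: it reproduces the
distributional properties the estimators consume (per-atom fluctuation
amplitudes, rigid-motion nuisance components, a controllable collective
mode when one is added explicitly) but none of the physics — no inter-atom
correlations, no solvent, no thermostat, no barriers. Passing tests
therefore demonstrate that the estimators measure what they claim on data
of known ground truth; they say nothing about force fields. The interpolated
metal-site generator morphs one basal trans pair of a square pyramid out of
the plane so the realised τ equals the requested value exactly, giving a
parameter-recovery oracle across the full 0–1 range. The rotamer-switch
generator rebuilds one side chain per frame following a (code, run-length)
schedule with optional χ jitter. All generators take a mandatory seed and
are bitwise reproducible.

The toy active site is labelled synthetic in its title and construction: a
Cu at the origin, three imidazole-like N donors and an equatorial water
with basal trans angles built at 174° and 162° (τ = 0.200 by construction),
a quinone ring whose O4 sits at 2.5 Å on the elongated axis, a crosslinked
lysine-like arm, and a stacked phenyl ring. It is a fixture with documented
geometry, not a model of any deposited structure.

## Numerical choices and degenerate inputs

Superposition is Kabsch via SVD with a determinant guard: a reflection is
never returned, degenerate geometry (fewer than 3 points, rank-deficient
cross-covariance) is an error rather than a silent fallback. Dihedrals of
collinear quadruples, angles with zero-length arms, and trajectories whose
frames disagree with the topology atom count are errors naming the
offending residue or frame. Angles are compared circularly where wraparound
matters (χ near ±180°). Patch application validates every referenced atom
before editing.

## Problem sizes

The test and acceptance runs use 20-residue backbones (60 atoms), 100–1000
frame synthetic trajectories, an 11-point τ grid, and the exhaustive 81-code
rotamer set; amplitude-recovery runs use 1000 frames, where the recovery
error is comfortably inside 10%. These sizes were chosen so every
statistical check sits well clear of its tolerance while the whole suite
runs in well under a minute.

## Known limitations

* χ extraction and rebuilding cover lysine-type ladders; aromatic χ₂
  conventions and branched side chains are out of scope.
* `graft_sidechain_template()` rebuilds the bond graph of the edited residue
  from nothing — callers tracking bonds should re-derive or re-read them.
* The rotamer-switch generator rotates atoms distal to each χ bond by the
  name ladder; for a side chain crosslinked onward past Nζ, the atoms beyond
  Nζ stay put (the crosslink is treated as the fixed end).
* The real-structure measurement workflow (e.g. the lysine–tyrosine
  separation report of `residue_separation()`) is exercised on synthetic
  fixtures in the tests; applying it to a deposited entry requires the user
  to fetch that file.
* Restraint evaluators score geometry only; there is no minimiser and no
  force-field energy.
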