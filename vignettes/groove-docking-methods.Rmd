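---
title: "Grid-based flexible peptide docking into MHC grooves: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based flexible peptide docking into MHC grooves: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

grooveDock docks fully flexible peptide ligands into MHC class I and
class II binding grooves. The protocol has two preparatory stages —
receptor preparation and precomputation of grid potential maps over a
standardized docking box — followed by a single consolidated docking and
refinement stage: biased Monte Carlo sampling of the peptide's internal
coordinates with Metropolis acceptance at 300 K, then a restrained
refinement of the peptide–receptor interface. Docked poses are evaluated
by the C-alpha RMSD of the nonameric core against a reference pose and by
recovery of the binding register. This vignette describes the models, the
parameters that matter, and the design choices made where the design was
genuinely open.

## The peptide model

Peptides are represented in internal coordinates: ideal bond lengths and
angles, a torsion vector (phi/psi/omega plus side-chain chi angles per
residue) and a rigid-body placement. Cartesian coordinates are rebuilt
deterministically by natural-extension (NeRF) chain propagation, so a
conformation is fully specified by `(torsions, rotation, translation)` and
the torsion–Cartesian round trip is exact to numerical precision. Side
chains are built from per-residue heavy-atom templates with standard
branch geometry; rings are closed approximately (planar templates), and
proline's ring is held at fixed pucker with its chi angles non-rotatable.
Chemical analogues ("X" residues) are built and parameterized as their
nearest standard parent while keeping their original name in output.

The representation is united-atom: nonpolar hydrogens are implicit in
their heavy atoms, and polar hydrogens are not built explicitly — donor
capability lives on the heavy atom, with the donor's covalent antecedent
supplying the direction for the hydrogen-bond angular factor. One
consistent heavy-atom representation everywhere was preferred over mixing
explicit polar hydrogens (which the crystallographic inputs do not
contain) with implicit nonpolar ones.

A peptide extracted from a complex keeps the crystal coordinates verbatim
(`split_complex()` is a copy); its torsions are measured from those
coordinates so that randomization and docking operate in the
internal-coordinate model. "Extended" means antiparallel-beta backbone
values phi = −139°, psi = +135°, omega = 180°; randomization draws the
chi angles uniformly and the placement from the central half of the
docking box, all from one seed.

## The energy model

The force field is an internally consistent united-atom model shipped as
a versioned table (`inst/extdata/forcefield_v1.tsv`: per-class
Lennard-Jones radius and well depth, atomic solvation parameter,
apolarity). It does not attempt to reproduce any particular published
force field's numbers; all energies are in kcal/mol.

* **van der Waals** — pairwise 6-12 terms, pair minimum at the sum of the
  class radii, combined depths by geometric mean; smooth switch to zero
  over the last 1 Å of the 8 Å nonbonded cutoff; per-pair cap at +100
  kcal/mol so clashes stay finite. Within the ligand, 1-2/1-3/1-4
  neighbours are excluded.
* **Electrostatics** — Coulomb sum under the distance-dependent
  dielectric eps = 4r, i.e. pair energy k q1 q2 / (4 r²), with
  k = 332.06 kcal·Å/(mol·e²). Formal charges are screened (±0.7 e on
  ionized groups and free peptide termini) and a single pair contributes
  at most ±2.0 kcal/mol — standard damping for an implicit-solvent
  dielectric of this form, and required so that no single-pair reward can
  out-buy the capped steric wall of the grid.
* **Hydrogen bonds** — a heavy-atom donor–acceptor distance well with its
  minimum (−2 kcal/mol) at 2.90 Å, identically zero beyond the 3.65 Å
  cutoff with a smooth window over the last 0.15 Å, modulated by a
  donor-side angular factor (ideal antecedent–donor–acceptor angle 115°).
* **Hydrophobic contacts** — a favourable term between apolar atoms:
  full strength to 3.50 Å, linear ramp to zero at the 4.50 Å van der
  Waals contact distance.
* **Surface solvation** — atomic solvation parameters times
  solvent-accessible areas (Shrake–Rupley sampling, 960 golden-spiral
  points per atom, 1.4 Å probe).
* **Side-chain entropy** — a per-residue maximum (0 for Gly/Ala/Pro, up
  to 2.1 kcal/mol for Arg) scaled by the buried fraction of the side
  chain, 1 − SASA(complex)/SASA(free).
* **Torsion strain** — a 3-fold barrier (0.6 kcal/mol) on rotatable chi
  angles and a stiff single-well term keeping omega trans; used only in
  the refinement score, mirroring the two scoring equations below.

Two weighted totals are used. The docking-stage score is

E = E_vw + E_en + 2.16·E_el + 2.53·E_hb + 4.35·E_hp + 0.20·E_solv

and the refinement-stage score is the unweighted sum

E = E_vw + E_hb + E_tors + E_elec + E_solv + E_en.

During Monte Carlo sampling the solvation and entropy terms are estimated
from cheap burial counts (neighbours within 6 Å, saturating at 25) rather
than full surface integration; the exact surface-based versions are used
in refinement and in reported breakdowns. This is the usual
speed/accuracy split for sampling-time scoring and changes no test or
reported quantity that is defined through the exact terms.

## Grid potential maps

The docking box uses standardized class dimensions — 35.36 × 35.52 ×
35.79 Å (class I) and 58.32 × 56.36 × 48.87 Å (class II) — centered on
the centroid of the groove-domain C-alpha atoms, expanding (with a
warning) only if binding-site atoms would fall outside. Binding-site
atoms are selected by 5.00 Å spheres: five centers evenly spaced along
the first principal axis of the groove C-alpha cloud, spanning the
central 60% of the box length (count and layout are configurable; the
convention covers the cleft without reaching the receptor exterior).

Receptor interaction fields are precomputed on a 1.00 Å grid, one 3-D
array per channel: attractive and repulsive van der Waals (for a generic
carbon probe), electrostatic potential (per unit probe charge),
hydrogen-bond donor and acceptor wells, the hydrophobic contact field,
and a burial count. The repulsive wall saturates smoothly (onset 2.5,
asymptote 6 kcal/mol per pair) and the attractive core is clamped below
0.85 of the pair minimum distance: an uncapped 1/r¹² wall cannot be
interpolated meaningfully at 1 Å spacing, and the cap level is chosen
above every single-pair reward so that interpenetration is never
favourable. Ligand atoms read the channels by trilinear interpolation
(exact on nodes); atoms outside the box pay +10 kcal/mol each. The full
6-12 potential (cap +100) is used off-grid: inside the ligand and
throughout refinement. Maps depend only on the receptor; rebuilding them
is bit-reproducible.

## Biased Monte Carlo docking

A probe pseudo-atom is placed at the grid node with the lowest combined
steric field within the central third of the box (ties broken by node
index; the combined field is used because the bare attractive channel is
minimized inside receptor atoms). The ligand centroid is anchored there.

Because the randomized side chains of the extended start would make raw
orientation scores meaningless, orientations are screened on a
clean-side-chain copy: the peptide axis is aligned with the groove axis
in both directions over a fan of eight roll angles, each candidate gets a
brief deterministic relaxation, and the winning orientation per direction
is applied to the actual randomized ligand. Binding direction is
genuinely hard to call from starting scores, so a single run either
splits its step budget between the two directions (`direction =
"both"`) or commits its whole budget to one (`"axis+"`/`"axis-"`);
`dock_template()` alternates the committed direction across its
replicas so both directions receive fully converged runs, and the best
restrained objective decides. Re-docking (`redock()`) follows the
protocol's ligand-positioning rule for peptides taken from an existing
structure: the internal conformation is randomized and extended but the
rigid-body placement is inherited from the structure, so no
reorientation screen runs. Every start is polished over a fan of
vertical offsets before sampling — entry into a snug groove is
height-sensitive, and descent cannot recover a start pressed against
the floor or the roof. A mid-run and an end-of-run clean-slate repack
(template chi angles, then descent over a vertical fan) rescue poses
whose side-chain packing has jammed against the groove.

Each Monte Carlo step draws a move from the configured mix (0.5
side-chain pick perturbing 1–3 chi angles — about a third of these
resample the angles uniformly, which escapes locked rotamers that small
steps cannot leave — 0.3 backbone pivot, 0.2 rigid-body pseudo-Brownian
step; 30° / 1.0 Å / 10° maxima), locally minimizes the perturbed degrees
of freedom (Nelder–Mead, Brent in one dimension), and accepts by the
Metropolis criterion min(1, exp(−ΔG/RT)) at T = 300 K. Every 400 steps a
deterministic quench (coordinate descent over all degrees of freedom,
including a joint chi1/chi2 rotamer scan per residue) pulls the walk to
its basin floor; at RT ≈ 0.6 kcal/mol the sampler is close to a greedy
descent, and basin-hopping with periodic full minimization converges far
more reliably than bare Metropolis walking.

Three loose restraints implement the protocol's requirement that the
ligand stay close to its starting conformation and position: a harmonic
on C-alpha displacement from the current accepted pose (0.1
kcal/(mol·Å²)), a weak harmonic on backbone phi/psi about their extended
starting values (0.003 kcal/(mol·deg²)), and a centroid-to-probe anchor
(0.2 kcal/(mol·Å²)). Poses are ranked by the restrained objective the
search optimizes (score plus the stationary anchor and backbone
restraints); ranking by the bare score would occasionally report poses
from outside the restrained search region. Runs stop early after a
configurable number of steps without improvement (`patience`). The
re-docking driver defaults to 5,000 steps, patience 1,800 and four
independently seeded replicas, reporting the best
pose; `mc_params()` itself defaults to a single 20,000-step trajectory. All randomness flows
from one integer seed and trajectories are bit-reproducible.

## Interface refinement

Refinement minimizes the unweighted refinement score over the mobile set:
all ligand torsions and its rigid-body placement, plus the side-chain chi
rotations of receptor residues with atoms within 4.00 Å of the ligand.
Receptor backbone stays fixed — chi rotations of hand-placed or
crystallographic side chains are well defined from coordinates alone,
whereas backbone moves would require rebuilding receptor internal
coordinates for marginal gain at this scale. Optimization is a
deterministic cyclic coordinate descent (bounded line searches per
variable, two sweeps by default), so the refined score never exceeds the
input score and atoms outside the mobile set are returned bit-identical.
Harmonic C-alpha restraints (1.0 kcal/(mol·Å²) by default) keep the
ligand near its docked pose. The reported interface energy covers the
ligand plus receptor residues within the nonbonded cutoff of it;
fixed–fixed receptor pairs are constants and are excluded from the
reported value.

## Evaluation

`ca_rmsd()` computes the root-mean-square C-alpha deviation over the
nonameric core (the whole peptide when it has nine or fewer residues) in
the shared receptor frame without superposition — docking never moves the
receptor, so pose and reference already share a frame. A Kabsch
superposition on receptor C-alphas is available for cross-template
comparisons. A pose is correct when the core RMSD is at most 2.50 Å
(inclusive). `detect_register()` slides a 9-residue window along the
peptide and returns the window with the most heavy-atom contacts (≤ 4.50
Å) to the binding-site atoms, ties to the smallest start; this
contact-count operationalization is our choice, as is "highest
resolution = numerically smallest Å" in the non-redundancy filter (which
groups by peptide and allele, plus T-cell receptor type for TR/pMHC
entries).

## The synthetic mini-groove

`generate_mini_groove()` builds a small closed peptide-binding groove so
that every stage is testable without downloading structures: two
antiparallel poly-alanine helices (leucine-lined) flanking a three-strand
floor, glycine pocket cavities under the anchor positions (wide for
bulky anchors, narrow for small ones), glutamine clamps on inward-facing
wall positions aimed at the native peptide backbone, and — for 9-mers —
stacked helical plugs closing both groove ends (a glutamate coordinating
the ammonium N-terminus, an arginine salt-bridging the carboxylate) plus
short roof bridges over the small up-facing core positions. Each element
is the fixture analogue of a real groove feature: conserved polar
residues hydrogen-bonding the peptide backbone, the closed A/F end
pockets of class I clefts, and the ridges between specificity pockets.
Together they make the constructed pose the dominant basin of the energy
model, with reversed, rolled, slid and exterior poses all strongly
disfavoured — the property a re-docking benchmark needs. Longer peptides
(10–15 residues) keep an open groove so their flanks protrude, with
anchors at odd core positions so both core ends contact the floor and the
adjacent flanking residues point away; that makes the constructed
register unambiguous for contact counting.

The generator is byte-deterministic per specification. Receptor
coordinates get a small Gaussian jitter (0.05 Å default) so grids never
see perfectly regular geometry. After assembly the native pose is settled
by a restrained deterministic relaxation inside the model (rigid body,
chi, small backbone windows, C-alpha restraints to the construction) —
the recorded ground truth should be mechanically stable in the force
field, exactly as a crystal pose is for the force field that refined it.
Construction-time sanity rules prune any receptor side chain overlapping
the native peptide and any plug residue colliding with already-placed
chains, and generation fails loudly if the groove cannot hold the peptide.

What the fixture does not emulate: real MHC domain architecture (a
single folded alpha-1/alpha-2 platform rather than disconnected
secondary-structure pieces), bound waters, experimental coordinate error
beyond isotropic jitter, and the chemical diversity of real pocket
linings. Passing the re-docking bound here shows the pipeline recovers a
self-consistent native in a realistic-scale search space; it does not
certify accuracy against crystallographic pMHC complexes, which would
require the original engine's force field and structure set.

## Numerical choices and problem sizes

Grid spacing is fixed at 1.00 Å (the box standard); the spacing-halving
check in the test suite verifies that interpolation error shrinks at 0.5
Å. Pair terms are continuous at every cutoff (smoothstep switching).
Clashes are capped, never infinite. SASA uses 960 points per atom in
reported quantities and 240 or fewer inside iterative refinement loops.
Desk-scale problem sizes used throughout the tests: a ~470-atom receptor,
9–15-residue peptides, 6,000-step docking runs with three replicas, and
50-fixture register sweeps; these keep the full suite within routine
continuous-integration budgets while leaving every algorithmic path
exercised.

## Known limitations

* The force field is internally consistent but not transferable: absolute
  energies are not comparable to any published scale.
* Aromatic rings and proline are built from approximate planar/fixed
  templates; ring-closure bonds are treated as exclusions, not as
  geometric constraints during minimization.
* Receptor backbone flexibility is not sampled at any stage.
* Direction and register recovery lean on the restraints and on groove
  features (end pockets, clamps); featureless or open-ended receptors
  will show the translational and directional degeneracies the
  restraints are designed to suppress.
* The docking-stage solvation/entropy terms are burial-count surrogates;
  only refinement and reports use the exact surface-based forms.
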