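---
title: "Scoring ligand binding with multiple random conformations and MM-GBSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring ligand binding with multiple random conformations and MM-GBSA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Docking programs rank ligands with fast empirical scoring functions that
are good at enriching actives but poor at ordering them by binding
affinity.  Rigorous alchemical free-energy methods order them well but
are far too expensive for post-docking triage.  This package implements
a middle road: a binding-affinity *score* built from molecular-mechanics
energies in implicit solvent (MM-GBSA) and the Jarzynski exponential-work
identity,

$$ e^{-\Delta G / k_BT} \;=\; \left\langle e^{-W/k_BT} \right\rangle, $$

which relates an equilibrium free-energy difference to the average of
$e^{-W/k_BT}$ over repeated nonequilibrium realizations of the process
connecting the two states.  In the quasi-static limit of an infinitely
slow pull, the per-step work between adjacent states reduces to their
potential-energy difference $U_{i+1}-U_i$.  Instead of simulating the
pull, the method *samples* each intermediate state directly: for a
ladder of protein–ligand distances
$r \in \{0, 0.5, 1, 2, \dots, 10\}\,\mathring{A}$ (12 points), it
generates an ensemble of rigid-body ligand placements at each $r$ — six
random numbers per placement, three rotation angles
$(\theta_x,\theta_y,\theta_z)$ and a displacement
$(r_x,r_y,r_z)$ with $r_x^2+r_y^2+r_z^2=r^2$ — minimizes each
conformation in the GB/SA solvent model, and records the final-step
potential energy $U[j,i]$ for replicate $j$ at shell $i$.

Each adjacent-shell transition contributes a free-energy increment
obtained by exponential averaging of the quasi-static work samples, and
the total score is the sum of increments:

$$ \mathrm{score}_{r=i} = -k_BT\,
   \ln \frac{1}{N}\sum_j e^{-(U[j,i]-U[j,i+1])/k_BT},
   \qquad
   \mathrm{score} = \sum_i \mathrm{score}_{r=i}. $$

Transitions are taken in the binding direction (far shell to near
shell), so a stronger binder has a more negative score.  With the
defaults — 100 replicates, the 12-point ladder, 100 minimization steps
per conformation — a single score costs 1,200 energy minimizations and
one short bound-state trajectory, orders of magnitude less than a
steered simulation with comparable intent.

The package also provides the classical single-structure comparator
(S-MMGBSA), $G_{\mathrm{complex}}-G_{\mathrm{receptor}}-G_{\mathrm{ligand}}$
from independent minimizations, pose rescoring against a reference
complex with the 2.0 Å optimal-pose criterion, and the linear map
$\Delta G_{\mathrm{calc}} = \alpha\cdot\mathrm{score}+\beta$ with the
generalized slope $\alpha = 0.20$ for relative binding free energies
$\Delta\Delta G$ referenced to the weakest binder of a series.

## Work pairing: two readings of the exponential average

The shells are sampled independently, so the "work" between adjacent
shells is not defined by a trajectory.  Two constructions are offered:

* **replicate pairing** (default): shell conformations descend from the
  bound-state snapshots, one lineage per replicate, so
  $W_j = U[j,\mathrm{near}]-U[j,\mathrm{far}]$ is one work sample per
  lineage.  This is the faithful reading of "conformations generated
  based on the bound-state samples".
* **ensemble pairing**: no pairing at all; the increment is the
  log-ratio of the shells' Boltzmann sums,
  $-k_BT \ln (Z_\mathrm{near}/Z_\mathrm{far})$, i.e. a free-energy
  perturbation between shells under the uniform placement measure.

In the zero-variance limit both reduce to the same telescoping sum, and
on an exhaustively enumerated placement grid the ensemble form equals
the brute-force partition-ratio oracle to $10^{-6}$ kcal/mol (this is a
test).  Replicate pairing is more faithful but fragile when a far shell
contains hard clashes or poorly relaxed contacts: its exponential
average is dominated by the most negative work sample, so a single such
column can swing a ligand's total by tens of kcal/mol.  Ensemble
pairing suppresses high-energy states naturally and produces markedly
more stable totals across seeds.  Both are exposed via `pairing_mode`
in `mrc_score()`; replicate pairing is the default for a single score,
and the ligand-ranking summaries report the ensemble estimator
alongside it because ranking is exactly the setting where one outlier
column matters most.

A related sign question: summing transitions outward (unbinding) simply
negates the zero-variance score.  The binding direction is the default
because scores must become more negative for stronger binders to be
mapped onto experimental $\Delta G$ with a positive slope $\alpha$; a
`direction` argument exposes the other convention.

## The toy energy model

Real applications of the protocol use a full biomolecular force field;
the method itself only requires *some* energy model with a gradient.
The built-in engine is a complete but deliberately small MM-GBSA
functional form:

* harmonic bonds $k_b(b-b_0)^2$;
* Lennard-Jones 12-6 with Lorentz–Berthelot combining;
* Coulomb electrostatics $332.0636\,q_iq_j/(\varepsilon_{in} d)$
  (kcal·mol⁻¹·Å·e⁻²);
* the Still pairwise generalized-Born polar term with **fixed input Born
  radii** $a_i$,
  $E_{GB} = -\tfrac12\,332.0636\,(1/\varepsilon_{in}-1/\varepsilon_w)
  \sum_{i,j} q_iq_j/f_{ij}$,
  $f_{ij} = \sqrt{d^2 + a_ia_j e^{-d^2/4a_ia_j}}$ (the $i=j$ term is the
  Born self energy);
* a nonpolar term $\gamma\cdot\mathrm{SASA}$ with
  $\gamma = 0.005$ kcal·mol⁻¹·Å⁻² and a Shrake–Rupley
  solvent-accessible surface area (probe 1.4 Å).

Per-atom parameters (charge, $\sigma$, $\epsilon$, Born radius, mass)
are explicit inputs from a TSV sidecar table, because force-field
assignment and charge derivation are out of scope.  Born radii are not
re-derived from the geometry; the scoring layer only needs a consistent
potential.  The interior dielectric $\varepsilon_{in}$ plays the role of
the dielectric constant swept over $\{1, 2, 4\}$ in MM-GBSA practice;
$\varepsilon_w = 78.5$ is fixed.  Nonbonded interactions act between all
inter-molecular pairs and intra-molecular pairs $\ge 3$ bonds apart,
with no cutoff (the intended systems are small).

Two numerical choices deserve mention.  The lattice SASA is evaluated in
the configuration's principal-axes frame (axes of the coordinate
covariance, signs fixed by odd moments of the projections), which makes
the energy exactly invariant under global rigid motions rather than
invariant only up to the lattice discretization.  And because a
point-lattice area is piecewise constant in the coordinates, the SASA
term contributes energy but no gradient; at the finite-difference step
used to validate gradients ($10^{-5}$ Å) this is self-consistent.  Any
object with `energy(x)`, `gradient(x)` and `masses` satisfies the
engine contract, so an adapter around an external molecular-mechanics
package can replace the toy engine without touching the scoring layer.

## Minimizer and sampler

Minimization follows the conventional two-phase protocol: steepest
descent switching to Polak–Ribière conjugate gradient (after 100 steps
for template preparation, which runs to a gradient-RMS tolerance of
0.1 kcal·mol⁻¹·Å⁻¹; after 10 steps for shell conformations, which run a
fixed `n_min = 100` steps and sample the final energy).  The line
search starts from the step that moves the largest atomic displacement
0.01 Å.  Two refinements matter for the statistics:

* on failure the step is reduced by *quadratic interpolation* rather
  than plain halving — the accepted step then depends continuously on
  the energies, so the minimization paths of two conformations that
  differ only by a weak ligand interaction stay close, and their
  energies cancel properly in the work samples;
* on success the step may double, but only while each doubling still
  gains at least 0.5 kcal/mol.  Steep clash relaxation therefore escapes
  the displacement cap quickly, while gentle drift (e.g. slow surface
  adsorption of a distant ligand) does not run away from the
  conformation it is supposed to represent.

Steps are only accepted on an energy decrease, so the energy trace is
non-increasing by construction.

The bound state is sampled with BAOAB Langevin dynamics at 300 K,
collision frequency 2 ps⁻¹ (the conventional reading of that
thermostat parameter's unit) and a 1 fs time step, unconstrained — the
stiffest default bond has a ~43 fs period, so no SHAKE-style constraint
is needed.  Snapshots are saved at uniform intervals; 10 ps with a
0.1 ps cadence gives the default 100 bound-state conformations.  Shell-0
snapshots are minimized with the same `n_min` as every other shell; the
alternative (scoring raw thermal energies at shell 0 only) would mix
two energy baselines in one grid.

Randomness is controlled by a single top-level seed from which
per-(replicate, shell) substreams are derived, so grids are reproducible
and independent of generation order.  Placements that put any ligand
atom within 0.8 Å of the receptor are redrawn (up to 50 times) before
being handed to the minimizer.

Orientation sampling defaults to uniform over the rotation group
(random unit quaternion re-expressed as Euler angles); a literal
`euler-naive` mode drawing three independent uniform angles is provided
for comparison, since the three-angle description of the protocol is
not uniform over orientations and the method's statistics should not
hinge on that distinction.

## The synthetic fixtures and what they do (and do not) show

Reproducing published results on real targets requires protein
structures and a biomolecular force field, both out of scope.  The
package instead ships deterministic generators:

* `make_toy_complex()` — a bonded cage of LJ sites forming a concave
  pocket with a small rigid ligand seated in it, relaxed so the
  reference pose is a genuine local minimum.  The pair LJ well depth
  between pocket atoms and ligand atoms equals `pocket_depth` exactly,
  so at fixed geometry the receptor–ligand interaction energy is affine
  in that dial — the basis of the ranking experiments.  An optional apo
  variant dilates the cage radially, exercising the flexible-receptor
  protocol (holo receptor at $r=0$, apo elsewhere).
* `make_ligand_series()` — one complex per pocket depth on a shared
  geometry, with pseudo-experimental affinities affine in depth plus
  seeded noise.
* `make_pose_set()` — rigid rotation+translation perturbations hitting
  prescribed post-receptor-fit ligand RMSDs in closed form.
* `brute_force_score_oracle()` — exhaustive placement enumeration with
  naive exponential averages, the independent reference for the
  estimator.

Study conditions used by the statistical tests, chosen once:

* *Decay and schedule-consistency experiments* use a short-ranged probe
  (σ = 2 Å, 16-atom cage of radius 2 Å, single-atom ligand) so that the
  outer half of the default ladder is genuinely outside the interaction
  range, with the nonpolar term disabled (for a rigid neutral probe it
  adds only lattice noise).  The decay probe uses a weak pocket
  (0.5 kcal/mol); the schedule comparison a stable binder (2 kcal/mol),
  run at 30–40 replicates with both ladders sharing one seed (common
  random numbers).  The bound-state trajectory is shortened to 2 ps for
  these small systems — the probe decorrelates in well under that.
* *Ranking recovery* uses a 40-atom cage with σ = 2.3 Å and a two-atom
  ligand over pocket depths 1–5 kcal/mol at 50 replicates per shell.
* *Pose rescoring* uses a tight cage (radius 3.2 Å) whose pocket
  engages the ligand near the LJ optimum, and scores poses by
  single-point (rigid) S-MMGBSA evaluation: under deep relaxation the
  toy cage's global minimum can be surface adsorption on the cage
  exterior, which would silently break the fixture's premise that the
  reference pose is the energy minimum.

Passing these tests demonstrates that the estimator, the protocol
plumbing and the statistical behaviour (telescoping, Jensen bound,
decay beyond the interaction range, coarse/fine ladder agreement,
ranking and pose recovery) are implemented correctly.  It does *not*
demonstrate chemical accuracy on proteins: the toy systems have no
internal ligand flexibility, no rotamers, no water structure, weak
electrostatics, and interaction ranges tuned to desk scale.

## Known limitations

* With replicate pairing, the per-transition estimate is dominated by
  the most negative work sample; columns containing poorly relaxed
  clashes can inflate a score.  Ensemble pairing is the robust
  alternative and is one flag away.
* A fixed 100-step minimization leaves a path-dependent thermal residue
  in $U$; the quadratic line search keeps adjacent-shell lineages
  correlated, but per-transition estimates still carry a small negative
  bias that grows with the number of transitions in the ladder.
* Born radii are inputs, not recomputed; the GB term is therefore only
  as good as the radii supplied.
* The optimal-pose criterion uses heavy atoms matched by order for
  ligands and by (residue number, atom name) for receptors; symmetric
  ligands with permutable atoms are not canonicalized.
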