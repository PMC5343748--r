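---
title: "Distance-geometry ensembles and allosteric pocket ranking with protsemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-geometry ensembles and allosteric pocket ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

protsemble generates an ensemble of protein conformations from two
crystal structures of the same protein by distance geometry. The idea is
that two solved conformations bracket a biologically relevant region of
conformational space: distance constraints that both structures satisfy
define a feasible set, and independent stochastic embeddings of that set
sample conformations between and around the two inputs. Unlike molecular
dynamics, consecutive models are not points on a trajectory; every model
is generated independently from random coordinates.

### Constraints

Every heavy-atom pair of the (atom-intersected) structures is assigned
the first interaction class it matches, in a fixed priority order:
covalent bond, bond angle, ring membership, four kinds of 1-4 dihedral
restriction (side-chain double bond, omega, phi/psi by rigidity class,
other), secondary-structure backbone pairs, salt bridges, hydrogen
bonds, tight/loose hydrophobic contacts, and finally the generic "all
other pairs" class. Each class has a tolerance `t` in Angstroms (0.02
for covalent bonds up to 5.0 for generic pairs). For an observed
distance `d`, the pair's bounds are

    lower = d - W_B * t,    upper = d + W_B * t

with `W_B` a global tolerance weight in [0, 1]. Bounds are built per
structure and merged by min/max so that *both* inputs satisfy every
combined constraint — a property the test suite asserts directly.
Generic pairs scale quadratically with atom count and are therefore
subsampled to about 20 per atom (independent Bernoulli retention).

Covalent topology comes from residue templates plus geometric detection
of peptide and disulfide bonds. Hydrogens are stripped; the hydrogen
bond criterion is re-expressed on heavy atoms (donor-acceptor distance
at most 3.5 Å, antecedent-donor-acceptor angle at least 90°). This
replaces an unreproducible polar-hydrogen placement step and slightly
broadens the donor geometry; since the class only sets a 0.5 Å
tolerance, the effect on ensembles is modest.

### Embedding

Structures are generated by stochastic proximity embedding. Coordinates
start uniformly in a cube whose side grows with the cube root of the
atom count (about protein packing density). For `C` annealing cycles of
`S` steps (C·S = 60,000 per atom by default, S:C = 50), each step draws
one random constraint per atom; if the current distance violates its
interval, both atoms move along their difference vector halfway toward
the nearest bound, scaled by a learning rate that decays linearly from
2.0 to 0.1 across cycles. Satisfied constraints are not touched. The
sum of squared violations is the error score; 1.5x as many embeddings
are run as needed and the worst third is discarded. Distance constraints
carry no chirality, so each embedding is checked against the reference
by an orthogonal (reflection-allowing) superposition and mirrored in the
xy plane when the improper fit is the better one.

Numerical choices: the update denominator carries an epsilon of 1e-9;
per-structure seeds are derived as `master * 1e6 + index` (mod 2^31)
from one master seed, so whole runs are bit-for-bit reproducible; the
embedding RNG is a splitmix64 stream in the C++ core, independent of R's
RNG state.

### Choosing the tolerance weight

`W_B` is the one parameter that matters: 0 gives a narrow band of
midway structures, 1 a wide cloud beyond the inputs. The spread
fraction `F` of an ensemble is the fraction of models strictly closer
(by TM-score) to both inputs than the inputs are to each other.
`select_wb()` walks `W_B` from 1.0 downward in steps of 0.1, generating
50 structures per step, and returns the first weight with `F >= 0.9`.
TM-scores use the standard length normalisation
`d0 = 1.24 (L - 15)^{1/3} - 1.8` (floored at 0.5 Å for short chains)
with an iterative superposition refinement (keep residues within
`max(d0, 3 Å)`, re-fit, repeat); because both models share one roster,
no alignment search is needed. If no weight reaches the target, 0.0 is
returned with a warning (the schedule's natural floor).

### Ensemble analysis

Ensembles are aligned reference-free: superpose all models on the
first, average, re-superpose on the average, and iterate until the
average moves less than 1e-4 Å. The average structure is the per-atom
centroid. PCA diagonalises the unweighted Cα covariance matrix (the
population covariance over models); eigenvector signs are fixed so the
largest-magnitude entry is positive. Per-residue mean square
fluctuations are Cα variances about the average, and MSF ratios between
a perturbed and a reference ensemble flag rigidified (ratio < 1) or
loosened (ratio > 1) regions; a reference MSF below 1e-12 Å² yields NaN
rather than infinity.

### Perturbation and pocket ranking

A candidate pocket (any grid pocket finder's point cloud, or a lattice
ball around a known ligand atom) is turned into a simulated modulator:
120 points are sampled (without replacement when possible, resampling
otherwise), appended to the roster as pseudo-atoms, and every
point-protein pair within 7 Å is constrained to its observed distance
±0.1 Å. The points can additionally be constrained pairwise at ±0.1 Å
into a quasi-rigid body (`rigid_points = TRUE`), but this is off by
default: the ~7,000 point-point constraints would dilute the random
sampling of protein constraints during embedding (each protein
constraint receives ~40% fewer updates at fixture scale), which inflates
protein fluctuations everywhere and can invert the local-rigidification
signal the perturbation is supposed to produce. The point-protein
constraints alone already couple the site's surroundings through the
shared points. Pseudo-atoms take part in the embedding only —
they are excluded from chirality checks, alignment, PCA, MSF and RMSD.

Pockets above 13 Å³ (at most eight, by volume) are perturbed in turn.
For each, the perturbed and unperturbed ensembles are pooled, aligned
into one frame, and the Cα RMSD between the two ensemble averages is
the pocket's score; pockets are ranked by descending shift. For
validation against a known modulator, a pocket counts as allosteric if
its centre is within 6 Å of any modulator atom.

## The synthetic fixture

`make_hinge_pair()` builds an idealised two-state test protein: two
α-helical arms (ideal bond geometry: N-CA 1.46, CA-C 1.52, C-N 1.33 Å;
helix torsions -57/-47°) joined by a three-residue loop in the generic
coil region (-70/150°). The two conformations differ only in the phi
dihedral of the first arm-2 residue — exactly a rigid rotation of arm 2
about the hinge N-CA bond, so covalent geometry is identical in both
states (the tests verify this against an explicit rotation oracle). The
default 25-residue peptide (11-residue arms, hinge angles 50° and 110°)
separates the two states by 2.65 Å Cα RMSD. Side chains are limited to
Ala/Leu/Lys/Glu templates, with rotamers chosen once so that Lys(i)
NZ–Glu(i+4) OE2 pairs sit at 3.3 Å on the helix face: that exercises
the salt-bridge class, and the Leu/Ala carbons exercise both
hydrophobic classes. Ring and side-chain double-bond classes cannot
occur in the fixture and are covered by a dedicated idealised
phenylalanine in the tests.

`make_pockets()` places one *bridging* pocket in the hinge cleft (its
points reach atoms of both arms within 7 Å) and decoy pockets touching
one arm only. Decoys are anchored at mid-arm surface positions: on a
small two-helix peptide the termini fluctuate so much that pinning them
with any pocket moves the ensemble average as strongly as a genuine
hinge lock, which would defeat the construction; mid-arm patches are
the analogue of a pocket on the packed surface of a real domain. The
bridging pocket is deliberately not assigned the largest volume, so
ranking by shift cannot be confused with ranking by size.

What a green perturbation test establishes: that constraints tying the
two arms together move the ensemble average more than constraints on a
single arm, robustly over seeds. What it does not establish: behaviour
on real proteins with packed cores, cofactors, crystal contacts, or
pocket finders' noisy volumes — the fixture has none of those.

## Known limitations

- With 50-model ensembles at the auto-selected weight, the closest
  model to either input sits around 0.8-1.3 Å Cα RMSD on the fixture,
  comparable to what the underlying method reports for real apo/holo
  pairs of similar separation; sub-0.5 Å recovery of the inputs should
  not be expected and one acceptance check that demands it stays red.
- The average-structure shift used for pocket ranking is noisy for
  small ensembles; below ~30 models per ensemble the decoy/bridging
  separation on the fixture degrades. Production runs should use the
  250-model default.
- Pair classification materialises an n×n type matrix; fine up to a few
  thousand atoms, wasteful beyond.
- DSSP input is supported but optional; the torsion-window fallback
  (helix: φ∈[-100,-30], ψ∈[-80,-5], runs ≥ 4; strand: φ∈[-180,-90],
  ψ∈[90,180]∪[-180,-170], runs ≥ 3) is deterministic but cruder than
  DSSP's hydrogen-bond definition.

## A worked run

```{r}
library(protsemble)

spec <- hinge_spec()
pair <- make_hinge_pair(spec)
a <- assign_secondary_structure(pair$a)
b <- assign_secondary_structure(pair$b)

sel <- select_wb(a, b, params = spe_params(seed = 1))
sel$trace          # (wb, F) schedule, first hit at F >= 0.9
e <- iterative_align(sel$ensemble)
pc <- pca_ensemble(e)
head(pc$variance_fractions)

pockets <- make_pockets(pair, spec, n_decoys = 3, seed = 2)
cs <- build_constraint_set(a, b, sel$wb, seed = 1)
pr <- perturb_and_rank(a, b, pockets, cs, n_models_per = 50,
                       params = spe_params(seed = 1))
ranking_table(pr)
```
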