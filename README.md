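# protsemble

Protein conformational ensembles by distance-geometry embedding, and
allosteric pocket prediction by constraint perturbation.

## What it does, and for whom

Crystal structures are static; many questions — how a kinase swings
between active and inactive states, where an allosteric drug could
bind, how ligand binding rigidifies a remote site — need the
*ensemble* of conformations a protein can adopt. Molecular dynamics
reaches such transitions only with heavy machinery. `protsemble` takes
the distance-geometry route: given **two** conformations A and B of the
same protein, it converts them into one set of interatomic distance
bounds that both satisfy, and generates each ensemble member
independently by stochastic proximity embedding (SPE) from random
coordinates. It is aimed at structural bioinformaticians who have an
apo/holo or open/closed pair and want, in minutes on a laptop: an
ensemble spanning the two states, its principal motions, per-residue
flexibility, and a ranking of candidate pockets by predicted allosteric
effect.

## The model in brief

For every heavy-atom pair *ij* observed at distance *d<sub>ij</sub>*,
classified into one of 15 interaction types with tolerance
*t<sub>ij</sub>* (0.02 Å for covalent bonds … 5.0 Å for generic pairs):

&nbsp;&nbsp;&nbsp;&nbsp;*l<sub>ij</sub>* = *d<sub>ij</sub>* − *W<sub>B</sub>* *t<sub>ij</sub>*,&nbsp;&nbsp;
*u<sub>ij</sub>* = *d<sub>ij</sub>* + *W<sub>B</sub>* *t<sub>ij</sub>*

Bounds from the two structures are merged (min of lowers, max of
uppers), generic pairs are subsampled to ≈ 20 *N<sub>A</sub>*, and SPE
minimises interval violations under an annealed learning rate
(60,000 iterations per atom, S:C = 50). The weight *W<sub>B</sub>* ∈
[0, 1] controls ensemble spread and is selected automatically: walk
1.0 → 0.0 in steps of 0.1 and keep the first weight whose 50-structure
ensemble has spread fraction *F* ≥ 0.9, where *F* is the fraction of
models with TM(S, A) > TM(B, A) and TM(S, B) > TM(A, B). A pocket is
simulated as 120 pseudo-atoms whose contacts to protein atoms within
7 Å are constrained at ±0.1 Å; pockets (volume > 13 Å³, at most 8) are
ranked by the Cα RMSD between perturbed and unperturbed ensemble
averages.

## Worked example

The package ships a generator for a two-state 25-residue hinge peptide
(two ideal helical arms, 2.65 Å Cα RMSD between states):

```r
library(protsemble)

spec <- hinge_spec()                      # 11-residue arms, 50° vs 110° hinge
pair <- make_hinge_pair(spec)
a <- assign_secondary_structure(pair$a)   # torsion fallback; DSSP optional
b <- assign_secondary_structure(pair$b)

sel <- select_wb(a, b, params = spe_params(seed = 1))
sel$trace
#>     wb    f
#> 1  1.0 0.12
#> 2  0.9 0.16
#> 3  0.8 0.24
#> 4  0.7 0.44
#> 5  0.6 0.54
#> 6  0.5 0.70
#> 7  0.4 0.90
```

The spread fraction *F* rises as the tolerance weight shrinks (looser
ensembles overshoot the inputs and fail the strict TM inequalities);
the first weight reaching *F* ≥ 0.9 is chosen, here **W_B = 0.4**, with
the 50-model ensemble already in `sel$ensemble`. Pocket ranking against
one cleft-bridging pocket and three single-arm decoys:

```r
pockets <- make_pockets(pair, spec, n_decoys = 3, seed = 2)
attr(pockets, "bridging_id")
#> [1] 2
cs <- build_constraint_set(a, b, sel$wb, seed = derive_seed(1, 900))
pr <- perturb_and_rank(a, b, pockets, cs, n_models_per = 50,
                       params = spe_params(seed = 1))
ranking_table(pr)
#>   pocket_id volume n_constraints shift_rmsd rank
#> 2         2     90          3534  1.3175014    1
#> 3         3     60          3726  0.8352102    2
#> 4         4     40          4127  0.6867431    3
#> 1         1    150          4023  0.6146664    4
```

Pocket 2 — the one whose 120 pseudo-atoms touch both arms and
therefore lock the hinge — produces the largest shift of the ensemble
average (1.32 Å against ≈ 0.61–0.84 Å for the surface decoys) and
ranks first, despite not being the largest pocket. `shift_rmsd` is the
Cα RMSD between the unperturbed and perturbed ensemble averages in a
common frame; `n_constraints` counts the added modulator constraints.

Ensemble analysis on the generated ensemble:

```r
e <- iterative_align(sel$ensemble)
round(pca_ensemble(e)$variance_fractions[1:3], 2)
#> [1] 0.40 0.25 0.11                                 # dominant hinge mode
msf <- rmsf(e)                                      # per-residue Å²
```

A command-line wrapper with `fixtures`, `param`, `generate`,
`allostery` and `msf` subcommands is installed at
`inst/cli/protsemble`.

## Layout

- `R/structure_io.R` – PDB/DSSP reading, roster intersection, multi-model output
- `R/constraints.R`, `R/topology.R` – interaction classification and bounds
- `R/spe_engine.R`, `src/spe.cpp` – stochastic proximity embedding core
- `R/autoparam.R` – TM-score, spread fraction, tolerance-weight selection
- `R/ensemble_analysis.R` – alignment, averages, PCA, MSF
- `R/perturbation.R` – modulator constraints, pocket ranking
- `R/fixtures.R` – synthetic two-state hinge peptide, pockets, modulators
- `R/pipeline.R` – end-to-end runs with manifests
- `vignettes/ensemble-methods.Rmd` – the methods notes
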