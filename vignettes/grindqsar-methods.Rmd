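---
title: "Alignment-independent 3D-QSAR with grindqsar: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-independent 3D-QSAR with grindqsar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grindqsar)
```

## The problem

ATP-competitive kinase inhibitors of a common chemotype differ in where
their hydrogen-bonding and hydrophobic groups sit in space, and those
geometric relationships — not any particular superposition of the
molecules — carry the structure–activity signal. grindqsar builds
quantitative structure–activity (3D-QSAR) models from **GRid-INdependent
descriptors (GRIND)**: variables derived from molecular interaction fields
that depend only on *internal* distances between interaction hot spots, so
no alignment of the compound set is ever required. The pipeline is:

1. read 3D structures (V2000 SDF) with an activity table (pIC50 =
   −log10 IC50 [M]);
2. type atoms (H-bond donor/acceptor, hydrophobic) and assign
   Gasteiger-style partial charges;
3. evaluate interaction fields for four probes — DRY (hydrophobic), O
   (carbonyl oxygen, H-bond acceptor), N1 (amide nitrogen, H-bond donor)
   and TIP (molecular shape);
4. extract favourable field **nodes** and encode the **correlogram**: for
   every probe pair and every distance bin, the largest product of node
   energies at that separation (the MACC2 transform);
5. select variables by fractional factorial design (FFD), fit a NIPALS PLS
   model with the number of latent variables chosen by leave-one-out Q²;
6. validate internally (R², PRESS, Q², RMSEE) and externally (R²pred,
   RMSEP, the rm² metric family, k′), and delimit a leverage-based
   applicability domain (Williams plot);
7. report ranked, signed variables as pharmacophoric distance rules
   (e.g. "DRY-N1: 13.2–13.6 Å, favourable").

## The field model

Published GRIND implementations delegate the fields to proprietary
software and do not print their parameterisation, so grindqsar defines its
own documented energy model with the same probe semantics (constants in
`inst/extdata/probe_params.txt`):

* 12-6 Lennard-Jones term with per-element well depths/radii, combined by
  geometric mean (ε) and radius sum;
* electrostatics `332.0636 q_p q_a / (4 r²)` kcal/mol — a
  distance-dependent dielectric ε(r) = 4r;
* a directional Gaussian hydrogen-bond well (depth 4 kcal/mol, centre
  2.9 Å, width 0.4 Å) between a polar probe and complementary
  donor/acceptor atoms, weighted by `((1+cos θ)/2)²` against the donor H
  or acceptor lone-pair axis;
* the DRY probe carries no charge or H-bond term; its dispersion term is
  scaled up (×3) on hydrophobic carbons and damped (×0.5) on polar atoms;
* energies are clamped at +5 kcal/mol inside atoms; only negative
  (favourable) values can become nodes;
* TIP is an indicator shell, −1 on `[r_vdw, r_vdw + spacing)` outside the
  van der Waals surface — a concrete, testable reading of a "shape probe".

Absolute energies therefore do not reproduce any proprietary field
implementation; the package reproduces the *semantics* (where hydrophobic,
acceptor and donor hot spots appear) and the statistical behaviour of the
pipeline built on them.

## Node extraction and exact alignment independence

A grid (default spacing 0.5 Å, margin 5 Å) is the classical sampling
device, and `extract_nodes()` implements the classical recipe: negative
local minima of the sampled field, refined and then thinned by a greedy
rule that balances intensity against coverage — the first node is the
global minimum and each next node maximises
`w·|E|/|E_min| + (1−w)·d_nearest/d_max` (defaults `n_nodes = 100`,
`w = 0.5`; ties break to the lowest flat grid index).

Grid-snapped node positions, however, are **not** rotation-invariant: a
0.5 Å lattice quantises coordinates in the lab frame, and correlogram bins
are only 0.4 Å wide. Two design choices make the pipeline's descriptors
exactly alignment-independent:

* **Continuous stationary points, found from molecule-anchored seeds.**
  The pipeline (`molecule_nodes()`) discovers nodes by multistart local
  minimisation of the analytic probe energy, seeded from frame-free
  geometric constructions (outward continuations of interatomic axes,
  local plane normals, donor/acceptor axes at H-bond geometry). Each seed
  is polished by a Newton step sequence and kept only if the Hessian is
  positive definite. Because the seed cloud and the energy function both
  rotate rigidly with the molecule, the discovered minima — and therefore
  all node-pair distances and energies — are identical in any frame to
  machine precision.
* **Analytic TIP nodes.** Shape nodes are placed on the van der Waals
  surface along atom→centroid rays (`tip_nodes()`), surface-exposure
  filtered — again exactly rotation-equivariant, unlike a shell sampled on
  a grid.

The greedy selection normaliser `d_max` is the largest pairwise distance
among the candidates rather than the grid-box diagonal: a box diagonal
changes under rotation and would contaminate the selection, hence the
descriptors, with the lab frame.

The test suite verifies the end result: random rigid-body motions of input
molecules change no descriptor by more than 1e−6 relative (observed:
~1e−15).

## The correlogram (MACC2 vs CLACC)

For each of the 10 ordered probe-pair blocks (DRY-DRY, O-O, N1-N1,
TIP-TIP, DRY-O, DRY-N1, DRY-TIP, O-N1, O-TIP, N1-TIP) and each bin
`[k·bw, (k+1)·bw)` (default `bw = 0.4` Å up to 25 Å → 62 bins per block,
620 variables), the descriptor is the maximum product `E_i·E_j` over
admissible node pairs — per-molecule maximisation, i.e. the documented
MACC2 transform. The "consistently large" (CLACC) variant, which picks
pairs consistently across a dataset, is unpublished in detail; it is *not*
implemented, and no claim is made of matching any particular software's
variable indices. Variable numbering here is the deterministic scheme
`index = block_offset + bin`, and variables are always reported with their
(block, distance range) meaning, which is the comparable quantity.

On the bin width: interpretable variables in the field's literature span
0.4 Å ranges while the smoothing window is usually quoted as 0.8 Å; the
package defaults to `bin_width = 0.4` (so reported ranges match variable
labels) and exposes 0.8 as a configuration alternative. Hard binning is
used; whether reference implementations smooth distances with a kernel is
unknown.

## PLS, LOO and variable selection

`fit_pls()` is NIPALS PLS1 after column centring and (default) unit
-variance autoscaling ("pareto" and "none" are available; scaling is a
config, not a constant, because reference implementations are
configurable). With as many latent variables as the rank of centred X the
fit equals least squares, which the tests exploit as an oracle.

`loo_q2()` is a literal naive loop — each compound removed, the model
refit from scratch on the remaining n−1 (including re-centring and
re-scaling), the held-out activity predicted. No deflation shortcut is
allowed to change held-out predictions; the test suite asserts exact
equality with an independent loop. `Q² = 1 − PRESS/Σ(y−ȳ)²` uses the full
training-set mean, following the printed definition of the statistic.

`ffd_select()` implements GOLPE-style FFD selection: a fold-over two-level
design (+1 keep / −1 drop) over the informative variables plus 20%
dummies, each run scored by LOO `SDEP = sqrt(PRESS/n)`. A variable's
effect is mean SDEP over runs keeping it minus mean over runs dropping it;
variables whose effect exceeds `mean + 2·SD` of the dummy effects — i.e.
keeping them demonstrably worsens prediction — are removed. The number of
runs defaults to twice the design width (and must be at least V+1 to be
resolvable). Note a property verified in the tests: dummy effects estimate
pure design noise, so for a *large* design the retained fraction of
pure-noise variables approaches ~0.5, while informative variables are
essentially always retained; with small designs the dummy-noise floor is
higher and selection is more conservative.

`make_split()` stratifies the test draw over activity quintiles crossed
with structural clusters, forces the activity extremes into training (no
extrapolative test compound) and sends singleton clusters to training.
With 49 compounds and 15 test compounds this yields the canonical 34/15
partition (47 → 32/15).

## Validation and applicability domain

`internal_validation()`/`external_validation()` implement the printed
formulas literally, with two documented caveats:

* The printed rm² formula ("r²(1−r²−r0²)") is typographically broken; the
  standard Roy formulation `rm² = r²(1 − √(r² − r0²))` is implemented
  (and its axis-swapped partner r′m²), which is the form consistent with
  the criteria (mean rm², Δrm² < 0.2) used alongside it. A numerically
  negative radicand is clamped at zero with a message.
* RMSEE is defined from PRESS (`sqrt(PRESS/n)`) in the printed equations —
  an SDEP, strictly speaking — and is implemented as printed; the
  conventional fitted-residual error is reported separately as
  `rmse_fit` to avoid ambiguity.

`criteria_flags()` applies the criteria exactly as printed, all strict
except the k′ band: R² > 0.9, Q² > 0.5, R²pred > 0.6, RMSEP ≤ 2·RMSEE,
rm² > 0.5, r′m² > 0.5, mean rm² > 0.5, Δrm² < 0.2, (r²−r′0²)/r² < 0.1,
0.85 ≤ k′ ≤ 1.15. Because the axis orientation of the ratio criterion is
ambiguous in the sources, both `(r²−r′0²)/r²` and `(r²−r0²)/r²` are
computed and reported; the flag uses the primed orientation.

`applicability_domain()` computes leverages as the diagonal of the hat
projection on the centred, FFD-selected descriptor space plus 1/n (the
1/n intercept term can be dropped for the SPSS-style centred convention),
with `h* = 3(p+1)/n`. Standardized residuals are prediction residuals
divided by the training RMSEE (the source software's convention is not
published). A compound is outside the domain when leverage > h* or
|standardized residual| > 3. Rank-deficient descriptor covariances fall
back to a pseudoinverse with a message — with hundreds of retained GRIND
variables and a few dozen compounds this is the normal case, and h* > 1
then makes the leverage criterion inactive, exactly as it would in any
implementation that uses all retained variables; a smaller "key variable"
subset can be passed explicitly when a tighter domain is wanted.

## The synthetic data generator

No compound set is shipped with the package, so `generate_dataset()`
produces one with the statistical and geometric structure the analysis
assumes: by default 49 compounds in four clusters ("I"–"IV", mirroring a
typical four-chemotype inhibitor series), pIC50 spanning ≈ 3.9–8.8 with
noise σ = 0.2.

Each compound is a **pseudo-atom scaffold**, not a chemically valid
molecule: a heteroaromatic hinge fragment with one H-bond-accepting
nitrogen, an amide-like linker (C=O acceptor + N–H donor) and a
six-carbon hydrophobic ring whose distance from the hinge nitrogen is the
controlled geometric variable, plus 0–2 ring substituents and small
coordinate jitter. The field typing consumes only elements, bonds and
flags, so valid chemistry is unnecessary for pipeline testing; small real
molecules (pyridine, acetamide, benzene, formaldehyde, acetate) are built
in code for the structure-level tests instead.

Activity is **computed through the real encoder**: the generator runs the
full field/node/correlogram pipeline and sets
`y = 4.2 + Σ βk·x_k + N(0, σ)` where `x_k` are the values of the seeded
descriptor bins (default: one favourable DRY-N1 bin at 13.2–13.6 Å,
β = 0.33 — calibrated once so the activity span is ≈ 4.5–5 pIC50 units
within [3, 10]). "Signal" compounds (cluster-dependent probability,
highest in cluster IV) place the hinge→ring distance so their DRY-N1 node
pair lands in the seeded bin; the mapping from scaffold geometry to
node-pair distance was measured once from the refined node geometry
(constants `SIG_A`, `SIG_B`, `SIG_SUBST` in the source) and is verified by
an encoder audit test (≥ 95% of signal compounds populate exactly the
seeded bin).

What a green test on this generator does and does not establish: it shows
the pipeline recovers a known, geometrically encoded structure–activity
signal (Q² > 0.5, R² > 0.9, seeded variable in the top-5 favourable
coefficients in ≥ 90% of seeds) and that descriptors are
alignment-independent. It does not reproduce any published model's
statistics — those depend on an undeposited compound set and proprietary
descriptor values — and the generated activity distribution is more
bimodal (actives vs inactives) than a real series. With σ = 0.2 against
an activity span of ~4.5 units the attainable Q² here is high (~0.7–0.95),
comfortably above the 0.5 criterion.

## Numerical choices and degenerate inputs

* Charge iteration: 8 damped PEOE iterations; transfers are pairwise, so
  total charge equals the net formal charge to machine precision.
* Node refinement: gradient descent (adaptive step, cap 0.3 Å) followed by
  Newton polish; convergence at |∇E| < 1e−9; points whose Hessian is not
  positive definite (saddles, clamp plateaus) are discarded; basin
  duplicates merged within 0.25 Å keeping the deepest.
* Constant descriptor columns get scale 1 and drop out of the model;
  all-zero columns are removed before FFD.
* Ties: component selection takes the smallest A among Q² maximisers;
  greedy node selection breaks score ties to the lowest candidate index.
* Degenerate splits: singleton clusters go to training; one cluster
  reduces to pure activity stratification.
* All stochastic stages (split, FFD design, generator) require an explicit
  integer seed, which is recorded in the pipeline manifest together with
  an md5 hash of the full configuration.

## Known limitations

* Field energies are a documented in-package model, not a reimplementation
  of any proprietary force field; only probe semantics are comparable.
* CLACC-style dataset-consistent pair picking is not implemented (MACC2
  per-molecule maxima only).
* The synthetic world is a single-scaffold geometry with one seeded signal
  bin by default; it exercises the pipeline, not chemical diversity.
* Leverage-based AD with p ≥ n is rank-deficient by construction; the
  pseudoinverse keeps it defined but the h* cut-off is then inactive.
* pIC50 values are only rounded (2 d.p.) at the report layer, never
  internally.
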