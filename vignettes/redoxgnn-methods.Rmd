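---
title: "Predicting reduction potentials across solvents: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting reduction potentials across solvents: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The one-electron reduction potential E_red of a molecule — its energetic
tendency to accept an electron — governs its usefulness as an electrode
material, electrolyte additive, redox mediator, or anolyte. E_red depends
strongly on the solvent, yet most data-driven predictors are trained for a
single solvent. `redoxgnn` implements a predictor that conditions on two
cheap physical solvent descriptors, the static dielectric constant ε and
the refractive index n, so that a single model covers many solvents and can
extrapolate to solvents absent from training, plus the surrounding
machinery: thermodynamic-cycle arithmetic, data-curation filters,
leakage-guarded splitting with a leave-one-solvent-out (LOSO) protocol, a
synthetic ground-truth generator, and an evolutionary inverse-design loop.

## Thermodynamic conventions

E_red(solv) = −ΔG_red(solv)/F − E_REF, with F = 96485.3383 C mol⁻¹ and
E_REF the absolute potential of the reference electrode (−4.48 V for the
SHE under Fermi–Dirac statistics, so ΔG_red = 0 maps to +4.48 V vs SHE).
ΔG_red is assembled from a thermodynamic cycle — gas-phase reduction plus
the solvation free-energy difference of reduced and parent species — with
the gas-phase electron treated as a reactant under the electron convention,
G(e⁻) = −3.632 kJ mol⁻¹, hence subtracted: with every molecular term zero,
ΔG_red = +3632 J mol⁻¹, a sign convention covered by a dedicated test.
Electron affinities are free-energy differences converted to eV per
particle via F. Ferrocene and lithium reference couples have no universally
agreed absolute potential; their offsets are explicit configuration with
literature defaults (Fc⁰/Fc⁺ ≈ +0.40 V vs SHE in acetonitrile, Li/Li⁺ ≈
−3.04 V vs SHE), never silently assumed.

## Molecular graphs

SMILES are canonicalized and parsed through OpenBabel (ChemmineOB); the
package works on the implicit-hydrogen heavy-atom graph, because the
"number of heavy-atom neighbors" feature is only meaningful there.
Atom features: element index over a fixed vocabulary (default H, C, N, O,
F, S, Cl, Br, extensible; unknown elements are loud errors, not an "other"
bucket), heavy-neighbor count, ring membership (an edge is in a ring iff it
is not a bridge), aromaticity (from SYBYL atom types), atomic mass, van der
Waals radius and covalent radius min–max scaled over the vocabulary (Bondi
and Cordero values frozen in code), and total valence (bond orders with
aromatic = 1.5, plus implicit hydrogens). Bond features: type
(single/double/triple/aromatic), conjugation, ring membership. MOL2 does
not carry a conjugation flag, so the package uses the sp²/sp-adjacency
rule: a bond is conjugated iff it is aromatic or each endpoint carries a
multiple bond other than the bond itself (butadiene's central bond is
conjugated; formaldehyde's C=O is not). Multi-fragment SMILES (salts) are
rejected — the data model is single molecules.

## Architecture

Node and edge features are linearly projected into latent states
(defaults: node 128, edge 128). Six residual message-passing iterations
follow (weights shared across iterations): each directed edge computes a
message from (source state, target state, edge state) through a two-layer
MLP; messages are sum-aggregated per receiving node (sum is injective on
multisets) and added to the node state; the two directed messages of each
bond update its edge state residually. With all message weights zero the
states are unchanged — the residual identity is a test. The readout is a
Set Transformer pooling block: node and edge states are projected into a
common space and jointly attended by a single learned seed query with
multihead attention (default 4 heads over a 256-dimensional graph vector),
giving a permutation-invariant molecule representation; the alternative of
pooling nodes only was considered and rejected since edge states carry the
bond-type information the potential depends on.

Two output variants share this trunk. GNN-VS emits a fixed-order vector of
potentials for the five training solvents (acetonitrile, water,
tetrahydrofuran, DMSO, DMF) plus the EA. GNN-SD splits the last stage in
two: a molecule-only MLP head predicting the solvent-independent component
(the electron affinity, also trained as an auxiliary target) and a second
head receiving the graph vector concatenated with the two solvent
descriptors, predicting the solvent-dependent component; the final
potential is exactly their sum. Only GNN-SD can be queried in an unseen
solvent. Solvent descriptors are min–max rescaled (ε, n) over bounds frozen
from the default registry; an Onsager-style reaction-field transform
((ε−1)/(ε+2), (n²−1)/(n²+2)) is available behind a flag. Both transforms
are monotone in each argument and vanish at the vacuum point.

There is no autodiff dependency: forward and backward passes are written
directly in base R matrix operations, and the analytic gradients are
checked against central finite differences (relative error below 1e-5) in
the test suite. Weights initialize fan-in uniform under a recorded seed;
training is bit-reproducible for a fixed seed.

## Training and evaluation

The loss is the sum over output dimensions of the per-dimension MAE over
the batch, with missing targets masked (for GNN-SD the dimensions are the
potential and the auxiliary EA; for GNN-VS the five potentials and the
EA). AdamW defaults follow the published recipe: 60 epochs, batch size
32, learning rate 1e-4, weight decay 1e-5, no schedule, gradient clipping
off but exposed. The best-validation-epoch parameters are kept, not the
last. Splitting is by molecule at ratios 80/10/10: all records of one
molecule (every solvent and the EA) share one partition, eliminating
leakage through shared structure. The `"sd"` data loader expands each
molecule into one record per solvent; this expansion is explicit in the
code. Metrics are MAE and R² = 1 − SS_res/SS_tot, reported per solvent and
summarized both as the unweighted mean over solvents (the headline) and
pooled, since the two conventions genuinely differ. The LOSO protocol
removes every record of one solvent from training and validation, trains,
and evaluates only the withheld-solvent records of the test molecules; the
returned audit proves the training stream held zero withheld records.

## The synthetic ground truth

Tests and the desk-scale study run on synthetic data with a known
generating function: EA(g) is linear in size-normalized composition
features (element fractions, aromatic fraction, ring fraction, intercept),
and

E_red = EA(g) + w_s · q(g) · (1 − 1/ε) + w_n · (n² − 1)/(n² + 2) + noise,

with q(g) = (1 + n_hetero)/(1 + n_heavy), defaults w_s = 1.5 eV, w_n =
0.5 eV, Gaussian noise of 0.05 eV. Fractions rather than raw counts keep
the target intensive, like a physical potential: the attention readout
pools a convex combination of set elements, so an extensive (count-linear)
target would be unrepresentable by the architecture and the recovery study
would test the wrong thing. The Born-style ε-dependence makes zero-shot
solvent generalization genuinely learnable from the two descriptors — the
physical premise of the solvent-conditioned design. Molecules are grown as
random attachment trees (≤ 9 heavy atoms by default) with optional ring
closures and unsaturation under a typical-valence model; the generator
emulates table schema and smooth structure–property dependence, not the
ring-system statistics, radical fraction, or DFT error structure of real
curated data — passing the recovery study therefore shows the pipeline
learns what it should from clean data, not that it reaches any particular
accuracy on real chemistry.

The recovery study (in the acceptance tests) trains GNN-SD at desk scale —
200 molecules × 6 solvents (the five defaults plus a synthetic solvent at
ε = 25, n = 1.40 inside their envelope), 45 epochs, learning rate 3e-3,
latent sizes 32/32/64 — sizes chosen so the full study runs in minutes on
one CPU while leaving a wide margin to its thresholds: held-out-molecule
MAE below 0.10 eV (twice the noise) on the trained solvents and
unseen-solvent MAE below 0.20 eV. A representative run gives ≈ 0.05 eV
held-out and ≈ 0.06 eV unseen-solvent MAE (R² ≈ 0.98), the desk-scale
analogue of "only slightly reduced" zero-shot accuracy.

## Curation filters

Candidate records are filtered, in order, by: maximum relative bond-length
change upon reduction above 40% (bond list from the parent connectivity,
so reductive bond breaking registers as a large change — intended);
spin-squared deviation above 10% of the single-reference value S(S+1);
any imaginary (negative-wavenumber) frequency; and bulk electrostatic
contribution outside the closed keep-interval [−4.0, −0.1] eV (boundary
values kept). Removed records carry the first failing rule's tag; the
kept-set is order-independent because the rules are independent
predicates. The "max over bonds" and "any bond" readings of the 40% rule
are equivalent at the decision level; max is implemented because it also
yields a useful diagnostic. Missing fields for a requested filter produce
per-record error tags, never silent passes.

## Inverse design

The evolutionary loop is (μ+λ) elitist with mutation-only variation
(crossover out of scope): each generation mutates random parents with one
of five graph actions (add atom, remove atom, change bond order,
substitute atom type, move a terminal group — the implemented reading of
"move functional group"), keeps chemically valid offspring within the
constraints (≤ 15 heavy atoms; elements C, N, O, F, S, Cl, Br), gates them
on synthetic accessibility (reference fragment-contribution +
complexity-penalty scorer, batched one subprocess call per generation;
threshold 4.5 by default), scores them with the objective, and keeps the
best `population_size`. The objective wraps each ensemble member's
predicted potential in the windowed sigmoid f(x) = σ(k(x−lo)) − σ(k(x−hi))
and averages; a candidate is accepted only if **every** member predicts
inside [lo, hi] — the ensemble's implicit uncertainty treatment. Steepness
defaults to k = 50 V⁻¹ so even the narrowest application window (0.25 V)
still scores ≈ 1 at its midpoint while the edges sit at 0.5. Four named
application windows ship as presets (PEDOT and PPT redox matching vs
Fc⁰/Fc⁺, lithium-ion additives vs Li/Li⁺, flow-battery anolytes vs SHE);
converting them to the absolute scale uses the configurable electrode
offsets. Tests drive the loop with the synthetic-truth oracle as the
predictor, after confirming by direct enumeration that the target window
is attainable in the reachable space.

## Numerical choices and limitations

Attention softmax is computed with max-subtraction; zero-edge molecules
(single heavy atoms) take an identity message-passing path and pool nodes
only. Ties in candidate ranking resolve by list order under a fixed seed,
making runs reproducible. Known limitations: no uncertainty
quantification beyond the ensemble gate; no stereochemistry or 3D
features; the typical-valence model used by the molecule editor is
conservative (e.g. divalent sulfur only) so hypervalent chemistry is
neither generated nor mutated into; published-scale accuracy on the real
curated data set is reachable only through the optional external workflow
(download, long training) and is not asserted by the test suite.
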