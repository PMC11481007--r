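---
title: "Methods: a pharmacophore-driven virtual-screening funnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a pharmacophore-driven virtual-screening funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

pharmfunnel implements a staged ("funnel") virtual-screening workflow of
the kind used to hunt for G-protein-coupled receptor agonists — here
modeled on GPR40/FFAR1, whose agonist site is anchored by a carboxylate
interacting with Arg/Tyr side chains, flanked by a hydrophobic groove and
several aromatic contacts. Each stage discards candidates before a more
expensive evaluation: pharmacophore matching, then machine-learning
triage on potency data, then externally supplied docking scores, then a
fingerprint novelty filter, and finally MM-PBSA-style binding-energy
ranking against a control compound. Every stage is exercised end to end
on synthetic inputs with planted ground truth, so the package needs no
proprietary software and no external database.

## The pharmacophore model and matcher

A pharmacophore is an abstract 3D arrangement of typed chemical features
(aromatic ring, hydrophobic group, H-bond acceptor/donor, charged
center). The packaged five-feature agonist model has three aromatic
features (R1--R3), one hydrophobic (Hy1) and one acceptor (A1), with
pairwise distance constraints $d_{ij}$ taken from a fixed reference
arrangement. A molecule matches when at least `min_required` features
(default 4 of 5; A1 and Hy1 always required) map injectively onto
perceived feature points of the same kind such that every constrained
pair satisfies $|r_{ij} - d_{ij}| \le \tau\, d_{ij}$.

Key choices:

* **Tolerance** $\tau$ defaults to 0.125, the midpoint of the 10--15 %
  range conventional for structure-guided screens; it is per-pair
  overridable and must lie in (0, 0.5).
* **k-of-n semantics.** The acceptor and hydrophobic features are
  `required = TRUE` by default because the carboxylate anchor and the
  hydrophobic groove are the interactions structural work identifies as
  essential; one aromatic feature may be dropped. A config file can
  override both.
* **Scoring.** Matches are ranked by (weighted matched count, then
  lowest deviation), with the reported score
  $\sum_i w_i - \lambda\,\mathrm{RMS}\!\left(|r_{ij}-d_{ij}|/d_{ij}\right)$,
  $\lambda = 1$. Commercial alignment scores are unpublished; this form
  preserves their ordering intent (more features, tighter fit).
* **Search.** Backtracking over feature-to-point assignments with
  distance-feasibility pruning. The test suite proves it equivalent to
  exhaustive enumeration on hundreds of instances with up to 8 feature
  points, and checks rigid-motion invariance and monotonicity in
  $\tau$.
* **Tie-breaking** is lexicographic by molecule id everywhere, for
  bit-reproducible output. Exactly one conformer is reported per
  molecule.

Feature perception uses deliberately simple, documented rules (ring
centroids for 5/6-membered aromatic rings; every O and low-degree
uncharged N as acceptor; maximal all-carbon non-aromatic groups of at
least 3 atoms as hydrophobic centroids). These are cruder than a
commercial perception engine — the matcher, not the perception
chemistry, is the tested contribution, and the feature-cloud tier of the
synthetic library bypasses perception entirely to test the matcher with
exact geometric control.

## Screen validation statistics

Retrospective validation screens a database of $D$ molecules containing
$A$ known actives and reports $H_t$ hits of which $H_a$ are active.
From these counts the package derives the percentage yield
($100 H_a/H_t$), percentage ratio ($100 H_a/A$), enrichment factor
$EF = (H_a/H_t)/(A/D)$ and the Güner–Henry composite

$$GH = \frac{H_a\,(3A + H_t)}{4 H_t A}
  \left(1 - \frac{H_t - H_a}{D - A}\right),$$

which is 1 for a perfect screen. Values are carried at full precision;
printing rounds to two decimals. Published three-model validation tables
of this form anchor the unit tests; one published column (model 1's
yield and GH) is internally inconsistent with its own counts and is
flagged as irreproducible rather than matched.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of their seed — identical spec,
bit-identical output — and always emit ground-truth labels.

* `make_feature_library()` stands in for a natural-product screening
  library. Actives are exact 3D embeddings of the model's distance
  matrix (classical MDS) plus i.i.d. Gaussian noise (`geometric_noise_sd`,
  Å); decoys are rejection-sampled random clouds for which *every*
  injective assignment violates at least two constraints by more than
  twice the tolerance, and which fail k-of-n matching even at doubled
  tolerance. Each entry also carries a small templated scaffold SMILES
  (acid + biphenyl motifs for actives) so SDF/SMILES I/O and perception
  can be smoke-tested. Decoys are geometric, not property-matched
  (no DUD-E-style bias control): passing tests show matcher correctness,
  not screening power on real decoy sets.
* `make_activity_table()` emulates a potency table for a receptor
  target, with a planted structure–activity rule (carboxylic acid and at
  least two aromatic rings). Rule-positive compounds draw
  $\log_{10}$ EC50 (nM) around 2.0, negatives around 4.0, with
  log-normal noise (default sd 0.4 log units — potency data scatter
  multiplicatively), so the 1 µM threshold recovers the rule exactly at
  zero noise and flips labels rarely at the default.
* `make_trajectory()` produces ligand-in-pocket wobble: frames are a
  pose plus i.i.d. Gaussian displacement, optional linear drift, and
  optional planted low-rank collective modes. With wobble alone,
  $E[\mathrm{RMSD}^2] = 6\sigma^2$ between two frames, which the tests
  verify by Monte Carlo. Real MD has correlated, anisotropic dynamics,
  solvent and periodic boundaries; none of that is emulated.
* `make_toy_complex()` gives receptor/ligand spheres with per-atom
  $\sigma$, $\varepsilon$, $q$ so that Lennard-Jones and Coulomb sums
  have brute-force double-loop oracles.

## Machine-learning triage

Compounds with EC50 at or below 1 µM (inclusive) are labeled active.
Cleaning removes rows without a defined positive EC50 and keeps the
lowest EC50 among duplicate ids. Features are physicochemical
descriptors (H-bond counts, logP, molar refractivity, MW, TPSA, graph
counts), the 166 MACCS structural keys, and a radius-2 circular
(Morgan-type) fingerprint folded to 2048 bits; constant columns are
dropped and missing values median-imputed. 3D descriptors are not
computed: at funnel scale the 2D blocks already separate the planted
rule, and conformer-dependent descriptors would import embedding noise
into the classifier.

Seven classifier families are compared with fixed hyperparameters:
gradient-boosted trees, random forest, extremely randomized trees,
AdaBoost (SAMME over stumps), a single decision tree, bootstrap-
aggregated trees, and an RBF support-vector machine. A published survey
of ~29 model variants reduces to these families — family coverage, not
inventory, is what the pipeline exercises. The train/test split sweep
walks the training fraction from 0.80 to 0.70 in steps of 0.02 with
stratified shuffling (stratification guarantees both classes in every
desk-scale test set) and selects the (ratio, family) pair with the best
test accuracy; ties prefer the larger training set, then lexicographic
family name. Model selection is complemented by stratified 20-fold
cross-validation. Sanity is enforced by a permutation null: shuffled
labels must give AUC ≈ 0.5.

## Similarity and novelty

Tanimoto similarity $c/(a+b-c)$ over fingerprint bits, with 0/0 defined
as 0, computed for MACCS and Morgan schemes side by side; a compound is
"known-like" when its maximum similarity to any reference reaches 0.85
(inclusive) in either scheme — the conventional threshold above which
shared activity becomes likely — and "novel" otherwise.

## Trajectory analytics

Superposition uses the Kabsch SVD solution constrained to proper
rotations; degenerate (collinear) selections raise an error. RMSD series
fit each frame on a configurable selection before measuring (receptor
fit, ligand measurement reproduces the usual "ligand RMSD bound to
receptor" convention); RMSF is the per-atom fluctuation about the
time-mean after fitting. Hydrogen bonds use the GROMACS-compatible
geometric criterion: donor–acceptor distance ≤ 3.5 Å and H–D–A angle
≤ 30°, both configurable; because reporting conventions are ambiguous in
parts of the literature (donor–acceptor vs hydrogen–acceptor distances,
and occasional geometrically impossible printed angles), both distances
are reported. Contacts count cross-group pairs within 4 Å, where
non-covalent interactions live.

Covariance PCA diagonalizes the 3n × 3n covariance of superposed,
time-centered coordinates; the free-energy landscape Boltzmann-inverts
the 2D histogram of the two leading projections,
$G_i = -k_B T \ln(P_i / P_{\max})$ with
$k_B = 0.0019872\ \mathrm{kcal\,mol^{-1}K^{-1}}$, default 32 × 32 bins
at 300 K (no temperature is prescribed by the source workflow). The
most-populated bin sits at exactly $G = 0$; empty bins carry
$\max(G_{\text{sampled}}) + 1\,k_BT$ so the surface stays finite —
an unbounded $-\ln 0$ is undefined.

## Energy ledgers

MM-PBSA-style bookkeeping decomposes binding energy as
$\Delta G_{gas} = \Delta E_{vdW} + \Delta E_{el}$,
$\Delta G_{solv} = \Delta E_{GB} + \Delta E_{surf}$,
$\Delta G_{total} = \Delta G_{gas} + \Delta G_{solv}$ (kcal/mol).
`verify_ledger()` checks these identities at a tolerance of 0.015
kcal/mol, which absorbs two-decimal rounding of independently printed
components; rows assembled in-package satisfy them exactly. The polar
GB term is *ingested*, never computed — it comes from external
continuum-solvation tools — with the single-ion Born closed form
$-166\,q^2/R\,(1 - 1/\varepsilon_r)$ as the oracle for the ingestion
path. Entropy is excluded from totals (component tables in this
workflow do not carry $-T\Delta S$). Gas-phase toys use Lorentz–
Berthelot combination and the Coulomb constant 332.0637 kcal Å mol⁻¹ e⁻²;
SASA is Shrake–Rupley over Bondi radii with a deterministic
golden-spiral lattice (960 points, probe 1.4 Å), and the nonpolar term
is $\gamma\,\mathrm{SASA} + \beta$ with the community defaults
$\gamma = 0.0072$ kcal mol⁻¹ Å⁻², $\beta = 0$. Ranking against the
control keeps compounds whose total is strictly more negative.

One caution the verifier itself surfaces: in published component tables
of this shape, individual rows can be internally inconsistent
(a printed subtotal contradicting its own addends far beyond rounding);
`verify_ledger` flags such rows instead of averaging over them.

## Funnel orchestration

`run_funnel()` executes library → pharmacophore screen → ML triage →
docking cut → novelty filter → energetics ranking, skipping unconfigured
stages, writing per-stage CSV artifacts, and logging counts. Stage
counts are monotone non-increasing. Docking is external by design
(scores enter via CSV; commercial scores cannot be re-derived); the
control cut is non-strict by default (ties with the control survive,
matching how published cuts retain tied compounds) with a strict option.
Reported hit rates are always computed from the actual counts, never
copied from a source document. The command-line wrapper at
`inst/scripts/funnel.R` exposes each stage as a subcommand over these
same functions.

## Numerical and I/O choices

* Coordinates are Å throughout; SDF is V2000 only (V3000 rejected with a
  clear error); malformed SDF/SMILES records are skipped and counted,
  never raised.
* Conformers come from a seeded distance-geometry embedder: ideal bond
  lengths and 1–3 angle distances as equality bounds, aromatic rings as
  regular polygons (which enforces planarity), van-der-Waals lower
  bounds elsewhere, L-BFGS from seeded Gaussian starts. Up to 3
  conformers per ligand (mirroring typical per-ligand sampling depth in
  screening pipelines), deduplicated at 0.5 Å heavy-atom RMSD with
  reflections counted as duplicates, so rigid molecules collapse to one
  conformation. The embedder is deterministic by construction — a
  requirement the pipeline inherits everywhere (explicit seeds, no
  global RNG state, bit-identical reruns).
* Geometry quality is "screening grade": regular rings, ideal angles; it
  is not a substitute for force-field optimization, and no
  protonation/tautomer enumeration is attempted.
* Hydrogens are preserved when present; H-bond analysis requires them
  and errors instructively otherwise.

## Problem sizes

The bundled tests and demo configurations run at desk scale, chosen so
the full suite completes in a couple of minutes on one core: synthetic
libraries of 10²–10³ molecules (standing in for the ~2 × 10⁵-molecule
natural-product libraries such screens target), activity tables of
300–2000 rows, trajectories of 25–1000 frames over 8–500 atoms, and
200-instance oracle-equivalence sweeps for the matcher. All scale
linearly upward; nothing in the implementation is specific to these
sizes.

## Known limitations

Perception rules are heuristic; decoys are geometric rather than
property-matched; the ML stage does not attempt hyperparameter search;
GB polar terms and docking scores are ingested, not computed; MD
observables from microsecond-scale simulations (absolute RMSD levels,
hydrogen-bond census against a real receptor) are out of scope — the
trajectory module is validated on closed forms and planted synthetic
motion instead.
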