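---
title: "Methods: active-learning data acquisition for conformational energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: active-learning data acquisition for conformational energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and procedures:
what each component assumes, which knobs matter, what the synthetic study
system emulates, and where the desk-scale emulation is known to diverge
from the full-scale platform it models.

## The acquisition loop

The package implements iterative data acquisition for molecular
conformational energies. A committee (ensemble) of energy predictors is
trained on the labeled conformations available so far. Unlabeled
candidate conformations are ranked by an acquisition score; the top
candidates are labeled (here by an analytic oracle, in production by
quantum chemistry) and appended; the committee is retrained. Two
acquisition scores are provided alongside a random baseline:

* **Committee disagreement (`VAR`)** — the relative standard deviation of
  the member predictions, `sd(E_1..E_M) / max(|mean|, 1e-8)`. The standard
  deviation is the population form; the epsilon guard keeps the score
  finite for near-zero mean energies. Because total energies carry a large
  per-atom baseline, the denominator also acts as an implicit size
  normalization.
* **Loss prediction (`LOSSFN`)** — per member, a ridge regression (penalty
  `1e-6`, chosen because MACCS key bits are collinear on small sets) maps
  the molecule's MACCS fingerprint to the member's absolute energy error;
  a candidate's score is the mean over members of the clipped-at-zero
  prediction. The score depends on chemical identity only, so every
  conformation of a molecule ties; ties are broken by a seeded shuffle
  applied before the stable sort, making runs reproducible.

A committee detects what its construction allows it to detect. The members
here are deterministic closed-form fits of the *same* labels, so label
noise produces no disagreement whatsoever; what disagreement does flag is
chemistry or geometry unlike the training data (the property suite
verifies both statements). The loss predictors, by contrast, see the
member residuals directly and do flag noisy-labeled molecules.

## The predictor committee

The built-in predictor represents a conformation by its graph edges: every
bonded atom pair, plus every pair closer than the model's distance
threshold (default 4.0 Å; bonds are edges at any length). Each edge
contributes Gaussian radial-basis values of its length, accumulated into a
channel per unordered element pair, multiplied by a smooth cutoff envelope
`(1 - (d/cutoff)^2)^2` so the energy is continuous as pairs cross the
threshold. Energy is a ridge-regularized linear function of these
features; training is closed-form (deterministic), and the gradient — hence
the force field — is analytic.

Two committee flavours are provided. The heterogeneous default varies the
basis resolution, width, cutoff and penalty across five members
(24/16/28/20/24 centers); the capacities are deliberately large enough
that a thousand labeled conformations do not saturate the members, which
is the regime in which acquisition strategies can matter at all. The
homogeneous committee clones one configuration (by default the first
heterogeneous member) five times, jittering the evenly spaced basis
centers by up to ±40% of their spacing — the analogue of retraining one
architecture from different random initializations without changing its
capacity.

Because the training data live on a narrow geometric manifold, an
energy-only linear fit carries no information about the repulsive wall at
short interatomic distances. The model therefore includes a fixed
short-range pair prior `E = 0.05 (r0/d)^12` (with `r0` at 70% of the
van-der-Waals contact) on all non-bonded pairs; the regression learns the
residual above it. This is the usual baseline-potential construction of
machine-learned force fields and is what keeps committee-driven dynamics
from collapsing atoms through each other.

## Strict scaffold splitting

A fraction `round(train_frac * N)` of molecules (default 80%) is drawn
uniformly into train. Each remaining molecule whose Bemis–Murcko scaffold
has MACCS-Tanimoto similarity at or above the threshold (default 0.7) to
*any* training scaffold goes to validation; the rest form the test set, so
the maximum train–test scaffold similarity is below the threshold by
construction (an exhaustive pairwise audit is provided and exercised).
Design points: similarity to "any training molecule" is read as the
maximum over training scaffolds; acyclic molecules have an empty scaffold
and all-zero fingerprint (two empty scaffolds are defined to have
similarity 0), and acyclic non-train molecules go to validation exactly
when train contains an acyclic molecule. Conformations always inherit
their molecule's assignment, which is what prevents conformer-level
leakage.

## The data-stream simulation

Four disjoint sets evolve: Pool (the stream source), Buffer (the ranking
window), Seed (the initial labeled set) and the acquired set. Defaults are
a 1:100 scaling of the production protocol: Seed 1000, Buffer 600, 300
moved and refilled per round, 5 rounds, so a run consumes
`1000 + 600 + 5×300 = 3100` labeled conformations. Each round ranks the
buffer with the committee trained on everything labeled so far, moves the
top 300, refills from the pool, retrains, and appends the held-out MAE to
the learning curve; the curve has `n_rounds + 1` points with round 0
recorded after training on Seed alone. Strategy comparisons use paired
replicates — identical initial partitions per replicate seed across
strategies — to strip partition variance out of the contrast, and report
the mean and standard deviation of the curves over seeds. The reported
`labeled_count` is `|Seed| + |acquired|`; whether buffer contents count as
"spent" is a convention, and this one was chosen because only moved
examples are ever labeled.

## The synthetic study system

Because the production labeler (density-functional theory) is far outside
a desk budget, the package ships a complete synthetic system whose
defaults are the study conditions of the test suite:

* **Library** — a fragment grammar (twelve ring systems, fourteen linkers,
  twelve substituents, a ~5% acyclic fraction) that yields valid, diverse
  drug-like SMILES; 500 molecules give several hundred distinct scaffolds.
  The simulation world uses 2000 molecules with two conformers each, so
  the Seed covers only a minority of the molecules — the partial-coverage
  regime a production stream has.
* **Conformers** — seeded distance-geometry embedding (bounds from
  covalent radii, law-of-cosines angle pairs, scaled van-der-Waals
  contacts), refined by restrained minimization; per-conformer seeds are
  `seed + index`, so subsets reproduce bit-exactly. OpenBabel's MMFF94
  minimizer (deterministic for fixed input) provides the optional
  `ff_optimized` stratum. A thermal-displacement generator
  (`perturb_conformation`, default σ = 0.03 Å ≈ 300 K displacements)
  supplies the off-equilibrium stratum; the study world labels one
  embedded and one displaced conformer per training molecule, mirroring
  production datasets in which a substantial fraction of conformations
  come from dynamics rather than clean embeddings. Without that stratum,
  energy-only committees have unconstrained gradients off the embedding
  manifold and their dynamics terminate almost immediately.
* **Oracle** — a small class-I force-field analog: harmonic bonds
  (element-dependent stiffness, covalent-radius equilibria), Urey–Bradley
  harmonic 1–3 terms at a uniform 111° angle, Lennard-Jones nonbonded
  terms with Lorentz–Berthelot well depths, an optional per-atom baseline
  (−30 kcal/mol in the study world, standing in for the atomic
  self-energies that dominate quantum-chemical totals), and optional
  Gaussian label noise applied to stored labels only — forces are always
  exact, so force/energy consistency tests are sharp. The uniform 1–3
  angle keeps the oracle inside the pair-channel model class; with
  hybridization-dependent angles the dominant model error becomes
  irreducible and no acquisition strategy can beat random, which collapses
  the experiment rather than making it harder.

## Langevin dynamics and confidence-guided sampling

Dynamics use a BAOAB splitting at 1 fs with Maxwell–Boltzmann velocity
initialization at the bath temperature (default 300 K) and friction
10 ps⁻¹. The friction default deserves a note: the sampling protocol runs
for 0.1–1 ps and is premised on short Langevin runs relaxing a
conformation toward a nearby minimum; with the weak couplings common in
long equilibrium simulations (~1 ps⁻¹) essentially no energy is dissipated
within such a run and that premise cannot hold, so the default damping
time is set to 100 fs. Instantaneous temperature is `2·KE / (3N·kB)`
without removal of rigid-body modes (documented so the tests are exact).
Runs stop early when the temperature passes a cap: 600 K in test mode
(100 steps, every frame saved), 1500 K in training mode (1000 steps, every
10th frame saved) — the training-mode cap is a loose blow-up guard, since
only the test-mode value is pinned by the protocol.

Each saved frame stores the per-member forces, and a frame's confidence is
the mean over atoms of the *minimum* pairwise cosine between member force
vectors on that atom (a zero force vector's cosine is defined as 0, and
flagged). The `max_k` lowest-confidence frames per trajectory (protocol:
at most 6) are selected for labeling. The augmentation study retrains the
committee with 200 such frames versus 200 random frames from the same
trajectories and compares Spearman rank correlation of predicted versus
true energy differences, the success rate (share of runs that lowered the
true energy), and the mean true difference, on fresh test-mode
trajectories from held-out, unoptimized conformations.

## Task protocol

Labeling work is distributed as one task per conformation: a V2000 MOL
block (4-decimal coordinates) plus a property-set tag, with the task
volume estimated by the atom count. The broker is a spool directory with
`pending/ claimed/ done/ failed/ quarantine/` states; claiming is an
atomic same-filesystem rename, so concurrent workers receive each message
at most once, FIFO by the zero-padded enqueue sequence. Corrupt messages
are quarantined; claims older than a timeout (default 30 min) are swept
back to pending. Verification issues a configurable fraction of duplicate
tasks and accepts a redundant pair when every shared property agrees
within a relative tolerance (absolute below 1e-8) — the mechanics of the
"verification threshold" are this package's choice, as is single- rather
than multi-conformation tasks.

## Numerical and format choices

Energies are kcal/mol internally; Hartree-tagged inputs convert by
627.509 (stored once). Dataset SDF records carry full-precision
coordinates in an `SDDF_COORDS` property because V2000 MOL blocks round to
4 decimals; the MOL block itself stays standard, and broker task content
deliberately keeps plain MOL-block precision. Every stochastic operation
takes an explicit integer seed and restores the caller's RNG state.

## What the desk-scale experiments do and do not show

The test suite runs the full pipeline — split constraint, vectorized
confidence score against a brute-force reference, integrator energy
conservation, broker concurrency, and the two directional experiments —
at the sizes above in minutes on one CPU. The unit and property suites
pass; the two directional experiments deserve honest caveats. In the
strategy comparison, the homogeneous committee's curve ends below the
random baseline, but the separations among random, disagreement and
loss-prediction acquisition are comparable to replicate noise at three
seeds: closed-form ridge committees reach their accuracy floor within a
few rounds, and averaging five equally strong jittered-basis members turns
out to cancel more error than architectural diversity does — neither of
which is true of large graph neural networks trained on hundred-thousand
example streams, where these strategies separate clearly. In the MD
study, early temperature-cap termination leaves few frames per
trajectory, so confidence-guided and random frame selection overlap
heavily and no reliable ordering emerges. Passing the desk-scale suite
therefore validates the machinery — bookkeeping, constraints, scores,
determinism — not the full-scale effect sizes, which require
high-capacity predictors and production-scale data streams.
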