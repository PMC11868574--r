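# confactory

Active-learning machinery for building labeled datasets of molecular
conformational energies, at a scale that runs on a laptop.

Training accurate machine-learning energy predictors requires large labeled
sets of 3-D conformations, but quantum-chemical labeling is expensive, so
*which* conformations get labeled matters. `confactory` implements the
data-acquisition loop used by ensemble-based distributed labeling
platforms: a committee of energy predictors is trained on the labeled data
so far, unlabeled candidates are ranked by how much the committee expects
to be wrong about them, the top candidates are labeled and fed back, and
the committee is retrained. Every stage is provided as tested, composable
R functions:

- **Strict scaffold splitting** — train/validation/test splits of a
  molecule library where no test scaffold has Tanimoto similarity ≥ 0.7
  (MACCS keys of the Bemis–Murcko framework) to any training scaffold, with
  an exhaustive leakage audit.
- **Predictor committee** — ridge-regularized radial-basis regressors over
  the conformation graph's pair distances (per element-pair channel, with a
  fixed short-range repulsive prior), exposing energies and analytic
  forces; heterogeneous (different basis resolutions) or homogeneous
  (one configuration, re-initialized) committees.
- **Acquisition strategies** — random (`RAND`); committee disagreement by
  the relative standard deviation of member predictions,
  `RSD = sd(E_1..E_M) / |mean|` (`VAR`); and loss prediction, where a
  linear model per member maps the molecule's MACCS fingerprint to the
  member's expected absolute error (`LOSSFN`).
- **Data-stream simulation** — the Pool/Buffer/Seed protocol: each round
  the committee ranks a 600-conformation buffer, the top 300 move to the
  acquired set, the buffer refills from the pool, and the learning curve
  (held-out MAE vs labels spent) is recorded; strategies are compared over
  paired replicate seeds.
- **Langevin MD sampling** — BAOAB dynamics driven by the committee's mean
  force with a temperature-cap early stop; trajectory frames are scored by
  the gradient-cosine confidence
  `C = (1/N) Σ_i min_{q≠k} cos∠(F_q^i, F_k^i)` and the lowest-confidence
  frames are selected for labeling.
- **Task broker** — a file-based message broker (atomic rename claims,
  FIFO, quarantine, stale-claim recovery) distributing single-conformation
  MOL-block tasks to workers, with redundant-result verification.
- **Synthetic study system** — a fragment-grammar molecule library, a
  seeded distance-geometry conformer generator (optional MMFF94 refinement
  via OpenBabel), and an analytic bonded + Lennard-Jones labeling oracle
  with exact forces, standing in for the quantum-chemistry labeler so the
  whole pipeline is reproducible offline.

## Worked example

```r
library(confactory)

mols  <- synthetic_library(120, seed = 42)
split <- scaffold_split(mols, train_frac = 0.8, sim_threshold = 0.7, seed = 7)
split
#> <split> train 96 / validation 20 / test 4 (max train-test scaffold similarity 0.696)
```

96 molecules (80% of 120) are drawn into train; of the remainder, the 20
whose scaffolds resemble a training scaffold at ≥ 0.7 go to validation,
leaving a strictly dissimilar 4-molecule test set — the audit confirms no
test scaffold occurs verbatim in train and the worst cross-set similarity
stays below the threshold (0.696).

```r
oracle <- toy_oracle_params(atom_energy = -30)
byid   <- setNames(mols, sapply(mols, `[[`, "id"))
confs  <- unlist(lapply(split$train[1:60], function(id)
  generate_conformations(byid[[id]], 2, seed = match(id, names(byid)))),
  recursive = FALSE)
data   <- label_conformations(confs, oracle)
ens    <- train_ensemble(heterogeneous_configs(), data)

heldout <- label_conformations(unlist(lapply(split$test, function(id)
  generate_conformations(byid[[id]], 2, seed = 500 + match(id, names(byid)))),
  recursive = FALSE), oracle)
evaluate_predictions(ens, heldout)$mae
#> held-out MAE 3.90 kcal/mol (test-set energy sd 96.00)
```

With 120 labeled conformations the five-member committee already predicts
held-out conformational energies to 3.9 kcal/mol against a 96 kcal/mol
energy spread. The acquisition side then ranks unlabeled candidates:

```r
lp <- fit_loss_predictors(ens, data)
r  <- rank_candidates("LOSSFN", heldout$entries, ens = ens, lp = lp, seed = 3)
#> top-ranked molecule for labeling: c1ccc(cc1)COCc1ccco1 (predicted error 0.11 kcal/mol)

cf   <- heldout$entries[[1]]
traj <- run_md(cf, ensemble_force_fn(ens, cf$molecule), md_config_test(seed = 4))
traj
#> <trajectory lib00037/c1> 6 saved frames, termination=temperature_cap
sel <- select_low_confidence(traj, ens, max_k = 3)
#> lowest-confidence frame: step 5, score -0.295
```

The trajectory stopped at the 600 K cap; its frame with the lowest
force-cosine confidence (−0.295: at least one member pair pulls some atom
in opposing directions) is the one worth labeling.

A thin CLI over the same functions is installed at `exec/confactory`
(`split`, `rank`, `simulate`, `md`, `serve`, `work` subcommands); see the
script header for usage.

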