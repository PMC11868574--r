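# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(name, builder) {
  v <- get0(name, envir = .fixture_env)
  if (is.null(v)) {
    v <- builder()
    assign(name, v, envir = .fixture_env)
  }
  v
}

# A handful of small named molecules.
tiny_mols <- function() memo_fixture("tiny_mols", function() {
  parse_molecules(c("CCO ethanol", "Cc1ccccc1 toluene", "c1ccccc1 benzene",
                    "CC(=O)Nc1ccc(O)cc1 apap", "c1ccc2ccccc2c1 naphthalene",
                    "C1CCNCC1 piperidine"))
})

# Small labeled world: 60 molecules, oracle-labeled conformer sets, a
# held-out eval block. Used by predictor/sampler unit tests.
small_world <- function() memo_fixture("small_world", function() {
  mols <- synthetic_library(60, seed = 7)
  oracle <- toy_oracle_params(atom_energy = -30)
  confs <- unlist(lapply(seq_len(50), function(k)
    generate_conformations(mols[[k]], 4, seed = 100 + k)),
    recursive = FALSE)
  hconfs <- unlist(lapply(51:60, function(k)
    generate_conformations(mols[[k]], 3, seed = 500 + k)),
    recursive = FALSE)
  list(mols = mols, oracle = oracle,
       train = label_conformations(confs, oracle),
       heldout = label_conformations(hconfs, oracle))
})

# The full simulation world: a 2000-molecule synthetic library split by
# scaffold, with two conformers per molecule - one distance-geometry
# embedding and one thermal displacement of it (the off-equilibrium
# stratum) - labeled by the toy oracle with its atomic-baseline offset.
# Mirrors the desk-scale study conditions; built once per test run.
acceptance_world <- function() memo_fixture("acceptance_world", function() {
  mols <- synthetic_library(2000, seed = 101)
  split <- suppressWarnings(
    scaffold_split(mols, train_frac = 0.8, sim_threshold = 0.7,
                   seed = 202))
  byid <- stats::setNames(mols, vapply(mols, function(m) m$id, ""))
  oracle <- toy_oracle_params(atom_energy = -30)
  strata <- function(id, base_seed) {
    c1 <- generate_conformations(byid[[id]], 1,
                                 seed = base_seed + match(id, names(byid)))[[1]]
    list(c1, perturb_conformation(c1, sd = 0.03,
                                  seed = base_seed + 500000 +
                                    match(id, names(byid))))
  }
  train_confs <- unlist(lapply(split$train, strata, base_seed = 300),
                        recursive = FALSE)
  eval_ids <- c(split$validation, split$test)
  eval_ids <- eval_ids[seq(1, length(eval_ids),
                           by = max(1, ceiling(length(eval_ids) / 150)))]
  test_confs <- unlist(lapply(eval_ids, strata, base_seed = 900),
                       recursive = FALSE)
  list(mols = mols, split = split, oracle = oracle, byid = byid,
       train = label_conformations(train_confs, oracle),
       test = label_conformations(test_confs, oracle))
})

# Harmonic diatomics for oracle and integrator checks. The C-C pair has
# unit stiffness scaling (exact hand arithmetic); the heavier, softer
# Cl-Cl oscillator keeps a 1 fs step deep inside the stable regime.
cc_diatomic <- function(stretch = 0.05) {
  mol <- parse_molecules("[C][C] cc")[[1]]
  d0 <- 2 * 0.76
  conformation(mol, matrix(c(0, 0, 0, d0 + stretch, 0, 0), 2, 3,
                           byrow = TRUE), "c1")
}

cl2_diatomic <- function(stretch = 0.05) {
  mol <- parse_molecules("ClCl cl2")[[1]]
  d0 <- 2 * 1.02
  conformation(mol, matrix(c(0, 0, 0, d0 + stretch, 0, 0), 2, 3,
                           byrow = TRUE), "c1")
}
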