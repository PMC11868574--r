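# Domain types, chemistry utilities, synthetic library and toy oracle.

test_that("SMILES parsing assigns canonical SMILES and stable ids", {
  mols <- parse_molecules(c("CCO", "C1CCCCC1\nc1ccccc1"))
  expect_length(mols, 3)
  expect_equal(mols[[1]]$n_heavy, 3)
  expect_equal(mols[[1]]$id, "mol1")
  # cyclohexane and benzene canonicalize differently
  expect_false(mols[[2]]$smiles == mols[[3]]$smiles)
  # explicit hydrogens are materialized
  expect_equal(mols[[1]]$n_atoms, 9)
  # named records keep their names
  named <- parse_molecules("CCO ethanol")
  expect_equal(named[[1]]$id, "ethanol")
})

test_that("unparseable or empty input fails with record context", {
  expect_error(parse_molecules(c("CCO", "not_a_smiles")), "record 2")
  expect_error(parse_molecules("not_a_smiles"), "record 1")
  expect_error(parse_molecules("   \n  "), "empty")
})

test_that("Bemis-Murcko scaffolds keep rings and linkers, drop side chains", {
  mols <- tiny_mols()
  tol <- bemis_murcko(mols[[2]])     # toluene
  ben <- bemis_murcko(mols[[3]])     # benzene
  expect_equal(tol$smiles, ben$smiles)
  expect_equal(bemis_murcko(mols[[1]])$smiles, "")  # ethanol: acyclic
  # idempotence: re-scaffolding a scaffold is the identity
  for (m in mols) {
    s <- bemis_murcko(m)
    if (nzchar(s$smiles)) {
      again <- bemis_murcko(parse_molecules(s$smiles)[[1]])
      expect_equal(again$smiles, s$smiles)
    }
  }
})

test_that("scaffolds agree with an independent reference implementation", {
  skip_if(system2("python", c("-c", shQuote("import rdkit")),
                  stdout = FALSE, stderr = FALSE) != 0,
          "python rdkit unavailable")
  smis <- c("Cc1ccccc1", "CC(=O)Nc1ccc(O)cc1", "c1ccc(Cc2ccncc2)cc1",
            "O=C(Nc1ccccc1)c1ccsc1", "C1CCN(CC1)C(=O)c1ccccc1")
  mine <- vapply(parse_molecules(smis), function(m) bemis_murcko(m)$smiles, "")
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "from rdkit.Chem.Scaffolds import MurckoScaffold",
    "for s in sys.argv[1:]:",
    "    sc = MurckoScaffold.GetScaffoldForMol(Chem.MolFromSmiles(s))",
    "    print(Chem.MolToSmiles(sc))",
    sep = "\n")
  ref <- system2("python", c("-c", shQuote(script), shQuote(smis)),
                 stdout = TRUE)
  # compare through one canonicalizer (the package's)
  ref_can <- vapply(parse_molecules(ref), function(m) m$smiles, "")
  mine_can <- vapply(parse_molecules(mine), function(m) m$smiles, "")
  expect_equal(mine_can, ref_can)
})

test_that("MACCS fingerprints are identity-determined and informative", {
  a1 <- maccs("CCO")
  a2 <- maccs("CCO")
  b <- maccs("c1ccccc1")
  expect_identical(a1$bits, a2$bits)
  expect_false(identical(a1$bits, b$bits))
  mols <- synthetic_library(10, seed = 5)
  for (m in mols) expect_gt(sum(maccs(m)$bits), 0)
})

test_that("tanimoto similarity follows set arithmetic", {
  mk <- function(idx) {
    bits <- integer(166); bits[idx] <- 1L
    structure(list(bits = bits, length = 166L), class = "cf_fingerprint")
  }
  expect_equal(tanimoto(mk(c(1, 2, 3)), mk(c(2, 3, 4))), 0.5)
  expect_equal(tanimoto(mk(1:5), mk(1:5)), 1.0)
  expect_equal(tanimoto(mk(1:3), mk(7:9)), 0.0)
  expect_equal(tanimoto(mk(integer(0)), mk(integer(0))), 0.0)
  expect_error(tanimoto(mk(1), maccs("CCO")), "length")
  # symmetry and range on real fingerprints
  fps <- lapply(c("CCO", "c1ccncc1", "CC(=O)O"), maccs)
  for (i in 1:3) for (j in 1:3) {
    s <- tanimoto(fps[[i]], fps[[j]])
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s, tanimoto(fps[[j]], fps[[i]]))
  }
})

test_that("conformer generation is seeded, deterministic and chemically sane", {
  mol <- tiny_mols()[[4]]
  c1 <- generate_conformations(mol, 3, seed = 7)
  c2 <- generate_conformations(mol, 3, seed = 7)
  c3 <- generate_conformations(mol, 3, seed = 8)
  expect_identical(c1[[2]]$coords, c2[[2]]$coords)
  expect_false(identical(c1[[1]]$coords, c3[[1]]$coords))
  expect_equal(c1[[1]]$provenance, "generated")
  # different conformers of one call differ
  expect_false(identical(c1[[1]]$coords, c1[[2]]$coords))
})

test_that("MMFF94-optimized conformers have chemical bond lengths", {
  mols <- synthetic_library(10, seed = 21)
  for (m in mols) {
    cf <- generate_conformations(m, 1, seed = 3, optimize = TRUE)[[1]]
    expect_equal(cf$provenance, "ff_optimized")
    heavy <- m$atoms$symbol != "H"
    b <- m$bonds[heavy[m$bonds$i] & heavy[m$bonds$j], , drop = FALSE]
    if (nrow(b) == 0) next
    d <- sqrt(rowSums((cf$coords[b$i, , drop = FALSE] -
                         cf$coords[b$j, , drop = FALSE])^2))
    expect_true(all(d > 0.9 & d < 1.9))
  }
})

test_that("synthetic library is deterministic, parseable and scaffold-diverse", {
  lib1 <- synthetic_library(100, seed = 1)
  lib2 <- synthetic_library(100, seed = 1)
  expect_identical(vapply(lib1, function(m) m$smiles, ""),
                   vapply(lib2, function(m) m$smiles, ""))
  expect_length(lib1, 100)
  big <- synthetic_library(500, seed = 1)
  scafs <- vapply(big, function(m) bemis_murcko(m)$smiles, "")
  expect_gte(length(unique(scafs)), 50)
})

test_that("toy oracle matches hand-computed harmonic energies", {
  cc <- cc_diatomic(stretch = 0)
  p <- toy_oracle_params()
  out <- toy_oracle(cc, p)
  expect_equal(out$energy, 0, tolerance = 1e-12)
  expect_equal(max(abs(out$forces)), 0, tolerance = 1e-10)
  # stretch by 0.1 A with k = 300: E = 300 * 0.1^2 = 3 kcal/mol
  cc2 <- cc_diatomic(stretch = 0.1)
  expect_equal(toy_oracle(cc2, p)$energy, 3.0, tolerance = 1e-10)
})

test_that("toy oracle forces equal central finite differences", {
  w <- small_world()
  set.seed(99)
  picks <- sample(length(w$train$entries), 5)
  h <- 1e-5
  for (k in picks) {
    cf <- w$train$entries[[k]]
    out <- toy_oracle(cf, w$oracle)
    ffn <- toy_oracle_force_fn(cf$molecule, w$oracle)
    for (t in 1:4) {
      i <- sample(nrow(cf$coords), 1); c3 <- sample(3, 1)
      Xp <- cf$coords; Xp[i, c3] <- Xp[i, c3] + h
      Xm <- cf$coords; Xm[i, c3] <- Xm[i, c3] - h
      num <- -(ffn(Xp)$energy - ffn(Xm)$energy) / (2 * h)
      expect_equal(out$forces[i, c3], num,
                   tolerance = 1e-4 * max(1, abs(num)))
    }
  }
})

test_that("label noise shifts energies but never forces", {
  cf <- small_world()$train$entries[[1]]
  p0 <- toy_oracle_params(noise_sd = 0)
  p1 <- toy_oracle_params(noise_sd = 2, seed = 9)
  clean <- toy_oracle(cf, p0)
  noisy <- toy_oracle(cf, p1, noise = TRUE)
  noisy_again <- toy_oracle(cf, p1, noise = TRUE)
  expect_false(noisy$energy == clean$energy)
  expect_equal(noisy$energy, noisy_again$energy)   # deterministic noise
  expect_equal(noisy$forces, clean$forces)
  expect_error(toy_oracle(
    conformation(cf$molecule, cf$coords * 1e-3, "sq"), p0), "overlapping")
})

test_that("dataset SDF round-trip preserves ids, coordinates and energies", {
  w <- small_world()
  ds <- dataset_subset(w$train, 1:10)
  path <- withr::local_tempfile(fileext = ".sdf")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(length(back), 10)
  for (k in 1:10) {
    expect_equal(back$entries[[k]]$molecule$id, ds$entries[[k]]$molecule$id)
    expect_equal(back$entries[[k]]$conf_id, ds$entries[[k]]$conf_id)
    expect_lt(max(abs(back$entries[[k]]$coords - ds$entries[[k]]$coords)),
              1e-6)
    expect_equal(back$entries[[k]]$energy, ds$entries[[k]]$energy,
                 tolerance = 1e-9)
  }
  man <- withr::local_tempfile(fileext = ".csv")
  write_manifest(ds, man, path)
  df <- read.csv(man)
  expect_equal(nrow(df), 10)
  expect_equal(df$energy_kcal_mol, dataset_energies(ds), tolerance = 1e-6)
})

test_that("reading unlabeled or Hartree-labeled SDF behaves per contract", {
  w <- small_world()
  cf <- w$train$entries[[1]]
  path <- withr::local_tempfile(fileext = ".sdf")
  unl <- cf; unl$energy <- NULL
  write_dataset(list(unl), path, labeled = FALSE)
  expect_error(read_dataset(path), "SDDF_ENERGY")
  expect_silent(read_dataset(path, labeled = FALSE))
  # hartree-tagged energies convert by 627.509
  txt <- readLines(path)
  txt <- sub("^\\$\\$\\$\\$$",
             ">  <SDDF_ENERGY>\n0.5\n\n>  <SDDF_ENERGY_UNIT>\nhartree\n\n$$$$",
             txt)
  writeLines(txt, path)
  back <- read_dataset(path)
  expect_equal(back$entries[[1]]$energy, 0.5 * 627.509)
  expect_equal(back$entries[[1]]$energy_unit, "kcal/mol")
})
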