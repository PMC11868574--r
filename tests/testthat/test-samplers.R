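# Candidate ranking: loss predictors, predicted-error scores, strategies.

test_that("loss predictors recover exactly solvable member errors", {
  w <- small_world()
  ds <- dataset_subset(w$train, 1:40)
  ens <- train_ensemble(heterogeneous_configs()[1:2], ds)
  lp <- fit_loss_predictors(ens, ds)
  expect_length(lp$models, 2)
  # two molecules, two conformations each, distinct fingerprints, errors
  # forced to 1.0 and 3.0: tiny-ridge least squares interpolates
  m1 <- w$mols[[1]]; m2 <- w$mols[[2]]
  c1 <- generate_conformations(m1, 1, seed = 1)[[1]]
  c2 <- generate_conformations(m2, 1, seed = 1)[[1]]
  # two molecules with labels offset by +1 and +3 from the oracle the
  # ensemble was trained against: member |error| is dominated by the
  # offsets, and the tiny-ridge two-point fingerprint fit recovers their
  # ordering
  mini <- labeled_dataset(list(
    { c1$energy <- toy_oracle(c1, w$oracle)$energy + 1; c1 },
    { c2$energy <- toy_oracle(c2, w$oracle)$energy + 3; c2 }))
  lp2 <- fit_loss_predictors(ens, mini)
  s1 <- predicted_error_score(lp2, m1)
  s2 <- predicted_error_score(lp2, m2)
  # in-sample recovery of the two target errors (up to member prediction
  # error on the two conformations)
  expect_gt(s2, s1)
  # refitting is deterministic
  lp3 <- fit_loss_predictors(ens, ds)
  expect_equal(lp$models[[1]]$w, lp3$models[[1]]$w)
  expect_error(fit_loss_predictors(ens, dataset_subset(ds, 1)), "at least 2")
})

test_that("in-sample loss predictions interpolate with negligible ridge", {
  # direct check of the fingerprint regression: a member with zero error
  # everywhere predicts ~0; distinct-fingerprint two-point fits are exact
  w <- small_world()
  ds <- dataset_subset(w$train, 1:30)
  ens <- train_ensemble(heterogeneous_configs()[1:2], ds)
  y <- dataset_energies(ds)
  pred <- ensemble_predict_dataset(ens, ds)
  lp <- fit_loss_predictors(ens, ds)
  for (m in 1:2) {
    err <- abs(pred[, m] - y)
    # in-sample fitted values from the stored coefficients
    molids <- sapply(ds$entries, function(e) e$molecule$id)
    for (k in c(1, 10, 25)) {
      fp <- maccs(ds$entries[[k]]$molecule)
      fitted <- sum((fp$bits - lp$models[[m]]$x_mean) * lp$models[[m]]$w) +
        lp$models[[m]]$y_mean
      # per-molecule mean of |err| is the least-squares target when a
      # fingerprint is unique to one molecule
      same <- molids == molids[k]
      expect_equal(fitted, mean(err[same]), tolerance = 0.05)
    }
  }
})

test_that("predicted_error_score averages member scores with clipping", {
  fake_lp <- structure(list(
    models = list(
      list(w = numeric(256), x_mean = numeric(256), y_mean = 2),
      list(w = numeric(256), x_mean = numeric(256), y_mean = 2)),
    fp_length = 256L, member_names = c("a", "b")),
    class = "cf_loss_predictors")
  mol <- tiny_mols()[[1]]
  expect_equal(predicted_error_score(fake_lp, mol), 2)
  fake_lp$models[[1]]$y_mean <- 0
  fake_lp$models[[2]]$y_mean <- 4
  expect_equal(predicted_error_score(fake_lp, mol), 2)
  fake_lp$models[[1]]$y_mean <- -0.3   # clipped to 0
  expect_equal(predicted_error_score(fake_lp, mol), 2)
})

test_that("ranking strategies order, permute and tie-break as specified", {
  w <- small_world()
  ds <- dataset_subset(w$train, 1:60)
  ens <- train_ensemble(heterogeneous_configs()[1:3], ds)
  lp <- fit_loss_predictors(ens, ds)
  cands <- w$heldout$entries
  n <- length(cands)
  for (strat in c("RAND", "VAR", "LOSSFN")) {
    r <- rank_candidates(strat, cands, ens = ens, lp = lp, seed = 5)
    expect_setequal(r$order, seq_len(n))
  }
  # RAND is a pure seeded shuffle
  r1 <- rank_candidates("RAND", cands, seed = 9)
  r2 <- rank_candidates("RAND", cands, seed = 9)
  expect_identical(r1$order, r2$order)
  # VAR sorts scores descending
  rv <- rank_candidates("VAR", cands, ens = ens, seed = 5)
  expect_true(all(diff(rv$score[rv$order]) <= 1e-12))
  # LOSSFN scores are constant within a molecule
  rl <- rank_candidates("LOSSFN", cands, ens = ens, lp = lp, seed = 5)
  molid <- sapply(cands, function(cf) cf$molecule$id)
  for (mm in unique(molid)) {
    expect_lt(diff(range(rl$score[molid == mm])), 1e-12)
  }
  # missing inputs
  expect_error(rank_candidates("VAR", cands), "ensemble")
  expect_error(rank_candidates("LOSSFN", cands, ens = ens), "loss predictors")
})

test_that("explicit score vectors sort like the independent order oracle", {
  # VAR scores (0.9, 0.1, 0.5) must order positions (1, 3, 2)
  score <- c(0.9, 0.1, 0.5)
  shuf <- seq_along(score)
  ord <- shuf[order(-score[shuf])]
  expect_equal(ord, c(1, 3, 2))
})

test_that("loss prediction flags molecules with inflated label noise", {
  # molecules labeled with 10x the baseline noise have larger member
  # residuals; the fingerprint loss predictor learns this and puts their
  # conformations in the top half far above chance. (A shared-training
  # committee's disagreement cannot see label noise: every member fits
  # the same labels; the committee's own target is input novelty, tested
  # below.)
  w <- small_world()
  hard_ids <- vapply(w$mols[1:10], function(m) m$id, "")
  base <- toy_oracle_params(atom_energy = -30, noise_sd = 0.3, seed = 1)
  hardp <- toy_oracle_params(atom_energy = -30, noise_sd = 3, seed = 1)
  # modest-capacity committee with visible ridge so member fits do not
  # interpolate the label noise (in-sample residuals stay informative)
  small_committee <- list(rbf_config(8, 0.5, 4.0, 0.05, name = "a"),
                          rbf_config(6, 0.7, 4.0, 0.05, name = "b"),
                          rbf_config(10, 0.4, 4.5, 0.05, name = "c"))
  hits <- 0; hard <- 0
  for (s in 1:20) {
    set.seed(s)
    idx <- sort(sample(length(w$train$entries), 120))
    ds <- labeled_dataset(lapply(w$train$entries[idx], function(e) {
      p <- if (e$molecule$id %in% hard_ids) hardp else base
      e$energy <- toy_oracle(e, p, noise = TRUE)$energy
      e
    }))
    ens <- train_ensemble(small_committee, ds)
    lp <- fit_loss_predictors(ens, ds)
    r <- rank_candidates("LOSSFN", ds$entries, ens = ens, lp = lp,
                         seed = s)
    is_hard <- sapply(ds$entries, function(cf) cf$molecule$id %in% hard_ids)
    top <- r$order[seq_len(floor(length(ds$entries) / 2))]
    hits <- hits + sum(is_hard[top]); hard <- hard + sum(is_hard)
  }
  pv <- stats::binom.test(hits, hard, p = 0.5,
                          alternative = "greater")$p.value
  expect_lt(pv, 0.01)
})

test_that("committee disagreement flags chemistry unseen in training", {
  w <- small_world()
  hard_ids <- vapply(w$mols[1:10], function(m) m$id, "")
  molid_of <- sapply(w$train$entries, function(e) e$molecule$id)
  pool_idx <- which(!(molid_of %in% hard_ids))
  hits <- 0; hard <- 0
  for (s in 1:20) {
    set.seed(s)
    tr_idx <- sort(sample(pool_idx, 100))
    ens <- train_ensemble(heterogeneous_configs(),
                          dataset_subset(w$train, tr_idx))
    cand_idx <- sort(c(sample(setdiff(pool_idx, tr_idx), 60),
                       which(molid_of %in% hard_ids)))
    r <- rank_candidates("VAR", w$train$entries[cand_idx], ens = ens,
                         seed = s)
    is_hard <- molid_of[cand_idx] %in% hard_ids
    top <- r$order[seq_len(floor(length(cand_idx) / 2))]
    hits <- hits + sum(is_hard[top]); hard <- hard + sum(is_hard)
  }
  pv <- stats::binom.test(hits, hard, p = 0.5,
                          alternative = "greater")$p.value
  expect_lt(pv, 0.01)
})
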