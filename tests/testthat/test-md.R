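# Langevin MD, the gradient-cosine confidence score, frame selection and
# the minimization evaluation metrics.

test_that("confidence score matches hand trigonometry and edge conventions", {
  # identical forces: cosine 1 everywhere
  F <- matrix(rnorm(12), 4, 3)
  expect_equal(confidence_score(list(F, F)), 1)
  # exactly opposite forces: -1
  expect_equal(confidence_score(list(F, -F)), -1)
  # 3 members, 1 atom: (1,0,0), (0,1,0), (1,1,0)/sqrt(2) -> min cosine 0
  fs <- list(matrix(c(1, 0, 0), 1), matrix(c(0, 1, 0), 1),
             matrix(c(1, 1, 0) / sqrt(2), 1))
  expect_equal(confidence_score(fs), 0, tolerance = 1e-12)
  # zero force vector: cosine defined as 0
  expect_equal(confidence_score(list(matrix(0, 1, 3),
                                     matrix(c(1, 0, 0), 1))), 0)
  expect_error(confidence_score(list(F)), "at least 2")
})

test_that("confidence score equals a naive double-loop reference", {
  naive <- function(mf) {
    M <- length(mf); n <- nrow(mf[[1]])
    total <- 0
    for (i in seq_len(n)) {
      worst <- Inf
      for (q in 1:(M - 1)) for (k in (q + 1):M) {
        a <- mf[[q]][i, ]; b <- mf[[k]][i, ]
        na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
        cs <- if (na * nb > 1e-24) sum(a * b) / (na * nb) else 0
        worst <- min(worst, cs)
      }
      total <- total + worst
    }
    total / n
  }
  set.seed(12)
  for (t in 1:100) {
    M <- sample(2:5, 1); n <- sample(1:8, 1)
    mf <- replicate(M, matrix(rnorm(3 * n), n, 3), simplify = FALSE)
    expect_equal(confidence_score(mf), naive(mf), tolerance = 1e-12)
  }
})

test_that("confidence score is rotation- and member-scale-invariant", {
  set.seed(7)
  for (t in 1:10) {
    mf <- replicate(3, matrix(rnorm(15), 5, 3), simplify = FALSE)
    s0 <- confidence_score(mf)
    # common rotation (QR orthogonalization, det +1)
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    expect_equal(confidence_score(lapply(mf, function(F) F %*% Q)), s0,
                 tolerance = 1e-12)
    # positive rescaling of a single member
    mf2 <- mf; mf2[[2]] <- 17.3 * mf2[[2]]
    expect_equal(confidence_score(mf2), s0, tolerance = 1e-12)
  }
})

test_that("instantaneous temperature follows the kinetic-energy formula", {
  expect_equal(instantaneous_temperature(matrix(0, 4, 3), rep(12, 4)), 0)
  v <- matrix(rnorm(12), 4, 3)
  t1 <- instantaneous_temperature(v, rep(12, 4))
  expect_equal(instantaneous_temperature(2 * v, rep(12, 4)), 4 * t1)
  # single argon-mass atom with KE = (3/2) kB 300K -> 300 K
  m_ar <- 39.948
  ke <- 1.5 * cf_constants$kB * 300
  speed <- sqrt(2 * ke / (cf_constants$mvv_to_kcal * m_ar))
  v1 <- matrix(c(speed, 0, 0), 1, 3)
  expect_equal(instantaneous_temperature(v1, m_ar), 300, tolerance = 1e-10)
})

test_that("zero-friction zero-bath MD conserves harmonic diatomic energy", {
  cc <- cl2_diatomic(stretch = 0.05)
  ffn <- toy_oracle_force_fn(cc$molecule)
  cfg <- md_config(n_steps = 100, save_stride = 1, friction = 0,
                   temperature = 0, temp_cap = 1e9, seed = 1)
  traj <- run_md(cc, ffn, cfg)
  expect_equal(traj$termination, "completed")
  m <- cc$molecule$atoms$mass
  etot <- vapply(traj$frames, function(fr) {
    fr$energy + 0.5 * cf_constants$mvv_to_kcal *
      sum(m * rowSums(fr$velocities^2))
  }, 0)
  expect_lt(max(abs(etot - etot[1])), 0.01 * abs(etot[1]))
})

test_that("temperature cap halts a thermalized run at the first step", {
  cc <- cc_diatomic()
  ffn <- toy_oracle_force_fn(cc$molecule)
  cfg <- md_config(n_steps = 100, save_stride = 10, friction = 1,
                   temperature = 300, temp_cap = 0, seed = 2)
  traj <- run_md(cc, ffn, cfg)
  expect_equal(traj$termination, "temperature_cap")
  expect_equal(traj$frames[[length(traj$frames)]]$step, 1)
})

test_that("MD is deterministic per seed and saves frames on the stride", {
  w <- small_world()
  ens <- train_ensemble(heterogeneous_configs()[1:3],
                        dataset_subset(w$train, 1:60))
  cf <- w$heldout$entries[[1]]
  ffn <- ensemble_force_fn(ens, cf$molecule)
  cfg <- md_config(n_steps = 50, save_stride = 10, temp_cap = 1e9, seed = 5)
  t1 <- run_md(cf, ffn, cfg)
  t2 <- run_md(cf, ffn, cfg)
  expect_identical(t1$frames[[length(t1$frames)]]$coords,
                   t2$frames[[length(t2$frames)]]$coords)
  steps <- vapply(t1$frames, function(fr) fr$step, 0L)
  expect_true(all(steps %% 10 == 0 | steps == max(steps)))
  # xyz export round-trips frame count
  path <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory_xyz(t1, path)
  txt <- readLines(path)
  expect_equal(sum(grepl("^step=", txt)), length(t1$frames))
})

test_that("low-confidence selection returns ascending scores with tie order", {
  w <- small_world()
  ens <- train_ensemble(heterogeneous_configs()[1:3],
                        dataset_subset(w$train, 1:60))
  cf <- w$heldout$entries[[2]]
  ffn <- ensemble_force_fn(ens, cf$molecule)
  traj <- run_md(cf, ffn, md_config(n_steps = 30, save_stride = 10,
                                    temp_cap = 1e9, seed = 3))
  sel_all <- select_low_confidence(traj, ens, max_k = 100)
  expect_length(sel_all, length(traj$frames))   # fewer frames than max_k
  sc <- vapply(sel_all, function(s) attr(s, "confidence"), 0)
  expect_true(all(diff(sc) >= -1e-12))          # ascending
  sel2 <- select_low_confidence(traj, ens, max_k = 2)
  expect_length(sel2, 2)
  expect_equal(attr(sel2[[1]], "confidence"), sc[1])
  expect_equal(sel2[[1]]$provenance, "md")
})

test_that("minimization metrics match hand-counted examples", {
  w <- small_world()
  ens <- train_ensemble(heterogeneous_configs()[1:2],
                        dataset_subset(w$train, 1:60))
  # synthetic pairs with controlled true differences (-1, +1, +3):
  # feed an oracle function so reference energies are fully controlled
  cf <- w$heldout$entries[[1]]
  vals <- c(i1 = 0, f1 = -1, i2 = 0, f2 = 1, i3 = 0, f3 = 3)
  mk <- function(id) {
    x <- cf; x$conf_id <- id; x
  }
  pairs <- list(list(initial = mk("i1"), final = mk("f1")),
                list(initial = mk("i2"), final = mk("f2")),
                list(initial = mk("i3"), final = mk("f3")))
  efun <- function(conf) unname(vals[conf$conf_id])
  res <- suppressWarnings(evaluate_minimization(pairs, efun, ens))
  expect_equal(res$success_rate, 100 / 3, tolerance = 1e-6)
  expect_equal(res$mean_delta, 1, tolerance = 1e-6)
  expect_error(evaluate_minimization(pairs[1:2], toy_oracle_params(), ens),
               "at least 3")
})

test_that("monotone prediction-truth relations give Spearman 1", {
  w <- small_world()
  ens <- train_ensemble(heterogeneous_configs()[1:2],
                        dataset_subset(w$train, 1:60))
  # minimize on the ensemble surface: predicted differences track the
  # surface, and an oracle equal to the ensemble mean makes the relation
  # strictly monotone (identity)
  pairs <- lapply(w$heldout$entries[1:5], function(cf) {
    ffn <- ensemble_force_fn(ens, cf$molecule)
    list(initial = cf, final = minimize_conformation(cf, ffn, maxit = 40))
  })
  oracle_fn <- function(conf) ensemble_predict(ens, conf)$mean
  res <- evaluate_minimization(pairs, oracle_fn, ens)
  expect_equal(res$spearman, 1)
  expect_equal(res$success_rate, 100)  # minimization reduces its own energy
})
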