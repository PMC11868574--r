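# Pool/Buffer/Seed active-learning data-stream simulation.
#
# Four disjoint example sets evolve over selection rounds: Pool (the
# simulated stream), Buffer (the ranking window), Seed (the initial
# labeled set) and the actively acquired set (here called "acquired",
# mirroring the platform's continuously growing selection). Each round the
# committee trained on Seed + acquired ranks the Buffer, the top examples
# move to the acquired set, and the Buffer is refilled from the Pool.
# Per-member design matrices are precomputed once per simulation, so the
# closed-form retraining each round is cheap.

#' Simulation configuration
#'
#' Desk-scale defaults are a 1:100 scaling of the platform protocol
#' (Seed 100k / Buffer 60k / 30k moved per round): Seed 1000, Buffer 600,
#' 300 moved and refilled per round, 5 rounds. The refill size always
#' equals `per_round_moved`, replenishing exactly what was moved.
#'
#' @param seed_size,buffer_size,per_round_moved,n_rounds Protocol counts.
#' @param strategy `"RAND"`, `"VAR"` or `"LOSSFN"`.
#' @param ensemble_configs List of predictor configs (default the
#'   heterogeneous five-member committee).
#' @param test_data Held-out `cf_dataset` for the learning curve.
#' @return A `cf_sim_config`.
#' @export
sim_config <- function(seed_size = 1000, buffer_size = 600,
                       per_round_moved = 300, n_rounds = 5,
                       strategy = c("VAR", "RAND", "LOSSFN"),
                       ensemble_configs = heterogeneous_configs(),
                       test_data = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(per_round_moved <= buffer_size)
  structure(list(seed_size = seed_size, buffer_size = buffer_size,
                 per_round_moved = per_round_moved,
                 refill_size = per_round_moved, n_rounds = n_rounds,
                 strategy = strategy, ensemble_configs = ensemble_configs,
                 test_data = test_data),
            class = "cf_sim_config")
}

.config_key <- function(config) {
  paste(config$width, config$cutoff, config$ridge,
        paste(signif(config$centers, 8), collapse = ","))
}

# Design matrices are pure functions of (dataset, config); an optional
# environment cache lets paired strategy comparisons share them.
.cached_design <- function(ds, config, cache, tag) {
  if (is.null(cache)) return(.design_matrix(ds, config))
  key <- paste(tag, .config_key(config))
  X <- get0(key, envir = cache)
  if (is.null(X)) {
    X <- .design_matrix(ds, config)
    assign(key, X, envir = cache)
  }
  X
}

.sim_fit_from_X <- function(config, X, y) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  A <- crossprod(Xc) + diag(config$ridge, ncol(X))
  w <- solve(A, crossprod(Xc, y - ym))
  list(config = config, w = as.vector(w), x_mean = xm, y_mean = ym)
}

.sim_predict_X <- function(model, X) {
  as.vector(sweep(X, 2, model$x_mean) %*% model$w) + model$y_mean
}

# (Re)train all members on the current labeled rows and refresh the
# curve. Training and test targets are residuals above the repulsive
# prior, so errors are identical to full-energy errors.
.sim_retrain <- function(state, cfg) {
  idx <- c(state$seed_set, state$acquired)
  y <- state$y[idx]
  state$models <- lapply(seq_along(cfg$ensemble_configs), function(m) {
    .sim_fit_from_X(cfg$ensemble_configs[[m]],
                    state$Xdata[[m]][idx, , drop = FALSE], y)
  })
  pred_test <- rowMeans(sapply(seq_along(state$models), function(m) {
    .sim_predict_X(state$models[[m]], state$Xtest[[m]])
  }))
  mae <- mean(abs(pred_test - state$y_test))
  state$curve <- rbind(state$curve, data.frame(
    round = state$round, labeled_count = length(idx), test_mae = mae))
  state
}

#' Initialize a data-stream simulation
#'
#' Seed and Buffer are drawn uniformly without replacement; Pool is the
#' remainder; the acquired set starts empty. The initial committee is
#' trained on Seed and the round-0 test MAE recorded.
#'
#' @param data Labeled `cf_dataset` streaming source. Must hold at least
#'   `seed_size + buffer_size + n_rounds * per_round_moved` entries.
#' @param cfg A `cf_sim_config` (with `test_data` set).
#' @param seed Integer seed for the partition draw.
#' @param feature_cache Optional environment for sharing design matrices
#'   across runs on the same data.
#' @return A `cf_sim_state`.
#' @export
init_simulation <- function(data, cfg, seed = 1, feature_cache = NULL) {
  stopifnot(inherits(data, "cf_dataset"), inherits(cfg, "cf_sim_config"))
  need <- cfg$seed_size + cfg$buffer_size + cfg$n_rounds * cfg$per_round_moved
  if (length(data) < need) {
    stop(sprintf("insufficient data: %d entries, need >= %d",
                 length(data), need))
  }
  if (is.null(cfg$test_data)) stop("cfg$test_data is required")
  n <- length(data)
  picks <- .with_seed(seed, sample.int(n, cfg$seed_size + cfg$buffer_size))
  state <- structure(list(
    seed_set = sort(picks[seq_len(cfg$seed_size)]),
    buffer = sort(picks[(cfg$seed_size + 1):length(picks)]),
    pool = sort(setdiff(seq_len(n), picks)),
    acquired = integer(0),
    round = 0L,
    rng_seed = seed,
    data = data,
    y = dataset_energies(data) - .dataset_priors(data),
    prior = .dataset_priors(data),
    y_test = dataset_energies(cfg$test_data) -
      .dataset_priors(cfg$test_data),
    Xdata = lapply(cfg$ensemble_configs, function(c)
      .cached_design(data, c, feature_cache, "data")),
    Xtest = lapply(cfg$ensemble_configs, function(c)
      .cached_design(cfg$test_data, c, feature_cache, "test")),
    molids = vapply(data$entries, function(e) e$molecule$id, ""),
    smiles = vapply(data$entries, function(e) e$molecule$smiles, ""),
    curve = NULL), class = "cf_sim_state")
  .sim_retrain(state, cfg)
}

#' @export
print.cf_sim_state <- function(x, ...) {
  cat(sprintf(paste0("<simulation> round %d: pool %d, buffer %d, seed %d,",
                     " acquired %d\n"),
              x$round, length(x$pool), length(x$buffer),
              length(x$seed_set), length(x$acquired)))
  invisible(x)
}

# Rank current buffer rows under the configured strategy; returns buffer
# positions ordered best-first.
.sim_rank_buffer <- function(state, cfg, rank_seed) {
  nb <- length(state$buffer)
  if (cfg$strategy == "RAND") {
    return(.with_seed(rank_seed, sample.int(nb)))
  }
  if (cfg$strategy == "VAR") {
    P <- sapply(seq_along(state$models), function(m) {
      .sim_predict_X(state$models[[m]],
                     state$Xdata[[m]][state$buffer, , drop = FALSE])
    })
    P <- P + state$prior[state$buffer]  # full energies for the RSD scale
    score <- apply(P, 1, disagreement_rsd)
  } else {  # LOSSFN
    idx <- c(state$seed_set, state$acquired)
    y <- state$y[idx]
    molids <- state$molids[idx]
    um <- !duplicated(molids)
    fps <- .maccs_from_smiles(state$smiles[idx][um])
    FP <- do.call(rbind, lapply(fps, function(f) f$bits))
    rownames(FP) <- molids[um]
    Xf <- FP[molids, , drop = FALSE]
    xm <- colMeans(Xf); Xc <- sweep(Xf, 2, xm)
    A <- crossprod(Xc) + diag(1e-6, ncol(Xf))
    # per-member error regressions on MACCS keys
    buf_mol <- state$molids[state$buffer]
    ub <- !duplicated(buf_mol)
    bfps <- .maccs_from_smiles(state$smiles[state$buffer][ub])
    BFP <- do.call(rbind, lapply(bfps, function(f) f$bits))
    rownames(BFP) <- buf_mol[ub]
    Bc <- sweep(BFP[buf_mol, , drop = FALSE], 2, xm)
    scores_m <- sapply(seq_along(state$models), function(m) {
      err <- abs(.sim_predict_X(state$models[[m]],
                                state$Xdata[[m]][idx, , drop = FALSE]) - y)
      ym <- mean(err)
      w <- solve(A, crossprod(Xc, err - ym))
      pmax(as.vector(Bc %*% w) + ym, 0)
    })
    score <- rowMeans(scores_m)
  }
  shuf <- .with_seed(rank_seed, sample.int(nb))
  shuf[order(-score[shuf])]
}

#' Advance the simulation by one selection round
#'
#' Ranks the Buffer with the current committee, moves the top
#' `per_round_moved` examples into the acquired set, refills the Buffer
#' with random Pool examples (removed from the Pool), retrains the
#' committee on Seed + acquired, and appends the test MAE to the learning
#' curve. In the final-round mode (Pool smaller than the refill) the
#' Buffer simply shrinks.
#'
#' @param state A `cf_sim_state`.
#' @param cfg The `cf_sim_config` used at init.
#' @return The advanced `cf_sim_state`.
#' @export
run_round <- function(state, cfg) {
  stopifnot(inherits(state, "cf_sim_state"))
  state$round <- state$round + 1L
  rank_seed <- state$rng_seed * 1000L + state$round
  ord <- .sim_rank_buffer(state, cfg, rank_seed)
  take <- ord[seq_len(min(cfg$per_round_moved, length(ord)))]
  moved <- state$buffer[take]
  state$acquired <- c(state$acquired, moved)
  state$buffer <- state$buffer[-take]
  refill_n <- min(cfg$refill_size, length(state$pool))
  if (refill_n > 0) {
    add <- .with_seed(rank_seed + 500000L,
                      sample(state$pool, refill_n))
    state$buffer <- sort(c(state$buffer, add))
    state$pool <- setdiff(state$pool, add)
  }
  .sim_retrain(state, cfg)
}

#' Run a full simulation
#'
#' @param data Labeled streaming `cf_dataset`.
#' @param cfg A `cf_sim_config`.
#' @param seed Replicate seed (controls the initial partition and all
#'   ranking tie-breaks).
#' @param feature_cache Optional environment shared across runs.
#' @return Final `cf_sim_state`; `$curve` holds `n_rounds + 1` rows of
#'   round, labeled_count and test MAE (kcal/mol).
#' @export
run_simulation <- function(data, cfg, seed = 1, feature_cache = NULL) {
  state <- init_simulation(data, cfg, seed, feature_cache)
  for (r in seq_len(cfg$n_rounds)) state <- run_round(state, cfg)
  state
}

#' Compare selection strategies over paired replicates
#'
#' Runs each experimental arm (a strategy plus an ensemble configuration)
#' with identical initial partitions for every replicate seed (paired
#' design), and aggregates the learning curves.
#'
#' @param data Labeled streaming `cf_dataset`.
#' @param test_data Held-out `cf_dataset`.
#' @param arms Named list; each element is
#'   `list(strategy = "VAR", ensemble_configs = ...)` (configs default to
#'   the heterogeneous committee).
#' @param replicate_seeds Integer vector (>= 2 seeds).
#' @param ... Protocol-count overrides passed to [sim_config()].
#' @return List: `curves` (strategy, replicate_seed, round, labeled_count,
#'   test_mae) and `summary` (per strategy and round: mean and sd of the
#'   test MAE).
#' @export
compare_strategies <- function(data, test_data, arms, replicate_seeds,
                               ...) {
  stopifnot(length(arms) >= 2, length(replicate_seeds) >= 2)
  if (is.null(names(arms)) || any(!nzchar(names(arms)))) {
    stop("arms must be a named list")
  }
  curves <- list()
  cache <- new.env(parent = emptyenv())
  for (s in replicate_seeds) {
    for (a in names(arms)) {
      arm <- arms[[a]]
      cfg <- sim_config(strategy = arm$strategy,
                        ensemble_configs = arm$ensemble_configs %||%
                          heterogeneous_configs(),
                        test_data = test_data, ...)
      st <- run_simulation(data, cfg, seed = s, feature_cache = cache)
      cv <- st$curve
      cv$strategy <- a
      cv$replicate_seed <- s
      curves[[length(curves) + 1]] <- cv
    }
  }
  curves <- do.call(rbind, curves)
  agg <- stats::aggregate(test_mae ~ strategy + round, curves,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  summary <- data.frame(strategy = agg$strategy, round = agg$round,
                        mean_mae = agg$test_mae[, "mean"],
                        sd_mae = agg$test_mae[, "sd"])
  list(curves = curves[, c("strategy", "replicate_seed", "round",
                           "labeled_count", "test_mae")],
       summary = summary[order(summary$strategy, summary$round), ])
}
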