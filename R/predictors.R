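# Trainable energy predictors with analytic forces, the heterogeneous
# ensemble, and the relative-standard-deviation disagreement score.
#
# The built-in predictor is a ridge-regularized linear model over per-edge
# radial basis features: the conformation graph's edges (bonded pairs, plus
# any atom pair closer than the model's distance threshold) are expanded in
# Gaussian radial basis functions of the pair distance, in a channel per
# unordered element pair. Energy is the weighted sum over edges; the
# gradient (hence the force field) is analytic. Closed-form training keeps
# the active-learning harness fast and deterministic; ensemble diversity
# comes from differing basis widths, center counts, cutoffs and penalties.

.pd_vocab <- c("H", "C", "N", "O", "F", "S", "Cl", "X")

.pd_pair_index <- local({
  nv <- length(.pd_vocab)
  M <- matrix(0L, nv, nv, dimnames = list(.pd_vocab, .pd_vocab))
  k <- 0L
  for (a in seq_len(nv)) for (b in a:nv) {
    k <- k + 1L
    M[a, b] <- M[b, a] <- k
  }
  M
})
.pd_n_pairs <- max(.pd_pair_index)

# Per-molecule static pair table: every i<j atom pair with its element-pair
# channel, bonded flag, and the contact radius of the repulsive prior.
.mol_pairinfo <- function(mol) {
  n <- mol$n_atoms
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sym <- mol$atoms$symbol
  sym[!(sym %in% .pd_vocab)] <- "X"
  chan <- .pd_pair_index[cbind(match(sym[idx[, 1]], .pd_vocab),
                               match(sym[idx[, 2]], .pd_vocab))]
  bonded <- rep(FALSE, nrow(idx))
  key <- paste(idx[, 1], idx[, 2])
  bkey <- paste(pmin(mol$bonds$i, mol$bonds$j),
                pmax(mol$bonds$i, mol$bonds$j))
  bonded[key %in% bkey] <- TRUE
  rv <- .element_row(mol$atoms$symbol)$r_vdw
  list(i = idx[, 1], j = idx[, 2], chan = chan, bonded = bonded, n = n,
       r0 = 0.7 * (rv[idx[, 1]] + rv[idx[, 2]]))
}

# Fixed short-range repulsive prior on non-bonded pairs:
# E = A (r0/d)^12. The regressor fits the residual on top of it, so the
# predicted surface keeps a physical steric wall even far outside the
# training manifold (where the radial basis carries no information).
.repulsion_A <- 0.05

.prior_energy <- function(pairinfo, coords) {
  nb <- !pairinfo$bonded
  if (!any(nb)) return(0)
  dx <- coords[pairinfo$i[nb], , drop = FALSE] -
    coords[pairinfo$j[nb], , drop = FALSE]
  d <- pmax(sqrt(rowSums(dx^2)), 0.05)
  sum(.repulsion_A * (pairinfo$r0[nb] / d)^12)
}

.prior_forces <- function(pairinfo, coords) {
  F <- matrix(0, pairinfo$n, 3)
  nb <- !pairinfo$bonded
  if (!any(nb)) return(F)
  dx <- coords[pairinfo$i[nb], , drop = FALSE] -
    coords[pairinfo$j[nb], , drop = FALSE]
  d <- pmax(sqrt(rowSums(dx^2)), 0.05)
  # dE/dd = -12 A r0^12 / d^13 ; force = -dE/dx
  coefs <- -12 * .repulsion_A * (pairinfo$r0[nb] / d)^12 / d^2
  .accumulate_force(F, dx * coefs, pairinfo$i[nb], pairinfo$j[nb])
}

#' Featurize a conformation as a molecular graph
#'
#' Nodes carry the atomic number one-hot (over H, C, N, O, F, S, Cl, other)
#' and mass; edges connect atom pairs that share a bond or lie closer than
#' `distance_threshold` (bonded pairs are always edges, whatever their
#' length). The edge set is symmetric by construction; it is reported with
#' `i < j`.
#'
#' @param conf A `cf_conformation`.
#' @param distance_threshold Adjacency distance cutoff in Angstrom.
#' @return A `cf_molgraph`: `nodes` data frame and `edges` data frame
#'   (`i`, `j`, `bonded`, `dist`).
#' @export
featurize <- function(conf, distance_threshold = 4.0) {
  stopifnot(inherits(conf, "cf_conformation"))
  pi_ <- .mol_pairinfo(conf$molecule)
  d <- sqrt(rowSums((conf$coords[pi_$i, , drop = FALSE] -
                       conf$coords[pi_$j, , drop = FALSE])^2))
  keep <- pi_$bonded | d < distance_threshold
  sym <- conf$molecule$atoms$symbol
  sym[!(sym %in% .pd_vocab)] <- "X"
  onehot <- outer(sym, .pd_vocab, `==`) * 1L
  colnames(onehot) <- .pd_vocab
  nodes <- data.frame(symbol = conf$molecule$atoms$symbol,
                      number = conf$molecule$atoms$number,
                      mass = conf$molecule$atoms$mass)
  nodes <- cbind(nodes, onehot)
  structure(list(nodes = nodes,
                 edges = data.frame(i = pi_$i[keep], j = pi_$j[keep],
                                    bonded = pi_$bonded[keep],
                                    dist = d[keep])),
            class = "cf_molgraph")
}

#' Configuration of the built-in RBF pair regressor
#'
#' @param n_centers Number of radial basis centers.
#' @param width Gaussian basis width (A).
#' @param cutoff Adjacency distance threshold (A).
#' @param ridge Ridge penalty.
#' @param centers Optional explicit center positions; default evenly
#'   spaced on `[0.8, cutoff]`.
#' @param name Optional label.
#' @return A `cf_rbf_config`.
#' @export
rbf_config <- function(n_centers = 10, width = 0.5, cutoff = 4.0,
                       ridge = 1e-4, centers = NULL, name = NULL) {
  if (is.null(centers)) centers <- seq(0.8, cutoff, length.out = n_centers)
  structure(list(n_centers = length(centers), width = width,
                 cutoff = cutoff, ridge = ridge, centers = sort(centers),
                 name = name %||% sprintf("rbf%dw%.2fc%.1f", length(centers),
                                          width, cutoff)),
            class = "cf_rbf_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clone a predictor configuration with a fresh random initialization
#'
#' The homogeneous-ensemble analogue of re-initializing the same
#' architecture with a different seed: each evenly-spaced basis center is
#' jittered by a seeded uniform offset of up to +/- 40% of the center
#' spacing, preserving the basis resolution while decorrelating members.
#'
#' @param config A `cf_rbf_config`.
#' @param seed Integer seed.
#' @return A `cf_rbf_config`.
#' @export
clone_with_seed <- function(config, seed) {
  stopifnot(inherits(config, "cf_rbf_config"))
  base <- seq(0.8, config$cutoff, length.out = config$n_centers)
  spacing <- if (config$n_centers > 1) base[2] - base[1] else 0.5
  centers <- .with_seed(seed, {
    sort(base + stats::runif(config$n_centers, -0.4, 0.4) * spacing)
  })
  rbf_config(width = config$width, cutoff = config$cutoff,
             ridge = config$ridge, centers = centers,
             name = paste0(config$name, "-s", seed))
}

#' The default heterogeneous five-member ensemble configuration
#' @return List of five `cf_rbf_config` with differing basis resolutions,
#'   widths, cutoffs and penalties.
#' @export
heterogeneous_configs <- function() {
  list(rbf_config(24, 0.25, 4.0, 1e-5, name = "m1"),
       rbf_config(16, 0.40, 4.0, 1e-4, name = "m2"),
       rbf_config(28, 0.22, 5.0, 1e-5, name = "m3"),
       rbf_config(20, 0.30, 3.5, 3e-5, name = "m4"),
       rbf_config(24, 0.28, 4.5, 1e-5, name = "m5"))
}

#' Homogeneous ensemble configuration (one architecture, five seeds)
#'
#' Defaults to five random re-initializations of the first member of the
#' heterogeneous committee, mirroring an ensemble built from one selected
#' architecture.
#'
#' @param base A `cf_rbf_config` to clone.
#' @param seed Base seed; member k uses `seed + k`.
#' @param k Number of members.
#' @return List of `cf_rbf_config`.
#' @export
homogeneous_configs <- function(base = heterogeneous_configs()[[1]],
                                seed = 1, k = 5) {
  lapply(seq_len(k), function(m) clone_with_seed(base, seed + m))
}

# Basis expansion of edge distances, with a smooth cutoff envelope so the
# learned energy is continuous as edges cross the threshold.
.rbf_basis <- function(d, config, deriv = FALSE) {
  C <- matrix(config$centers, length(d), config$n_centers, byrow = TRUE)
  dd <- d - C
  phi <- exp(-dd^2 / (2 * config$width^2))
  u <- pmin(d / config$cutoff, 1)
  env <- (1 - u^2)^2
  B <- phi * env
  if (!deriv) return(B)
  denv <- -4 * u * (1 - u^2) / config$cutoff
  dB <- phi * (-dd / config$width^2) * env + phi * denv
  list(B = B, dB = dB)
}

# Design row(s): edge basis values accumulated into element-pair channels.
.design_row <- function(pairinfo, coords, config) {
  d <- sqrt(rowSums((coords[pairinfo$i, , drop = FALSE] -
                       coords[pairinfo$j, , drop = FALSE])^2))
  keep <- pairinfo$bonded | d < config$cutoff
  x <- numeric(.pd_n_pairs * config$n_centers)
  if (!any(keep)) return(x)
  B <- .rbf_basis(d[keep], config)
  S <- rowsum(B, pairinfo$chan[keep])
  ch <- as.integer(rownames(S))
  for (r in seq_along(ch)) {
    off <- (ch[r] - 1) * config$n_centers
    x[(off + 1):(off + config$n_centers)] <- S[r, ]
  }
  x
}

# Design matrix over a dataset, caching per-molecule pair tables.
.design_matrix <- function(ds, config) {
  cache <- new.env(parent = emptyenv())
  rows <- lapply(ds$entries, function(e) {
    key <- e$molecule$id
    pi_ <- get0(key, envir = cache)
    if (is.null(pi_)) {
      pi_ <- .mol_pairinfo(e$molecule)
      assign(key, pi_, envir = cache)
    }
    .design_row(pi_, e$coords, config)
  })
  do.call(rbind, rows)
}

# Repulsive-prior energies of every dataset entry.
.dataset_priors <- function(ds) {
  cache <- new.env(parent = emptyenv())
  vapply(ds$entries, function(e) {
    key <- e$molecule$id
    pi_ <- get0(key, envir = cache)
    if (is.null(pi_)) {
      pi_ <- .mol_pairinfo(e$molecule)
      assign(key, pi_, envir = cache)
    }
    .prior_energy(pi_, e$coords)
  }, 0)
}

#' Fit one RBF pair regressor
#'
#' Closed-form ridge regression of conformational energies on the edge
#' basis features. Deterministic for a fixed configuration.
#'
#' @param config A `cf_rbf_config`.
#' @param data A `cf_dataset` with at least 10 entries.
#' @return A fitted `cf_rbf_model`.
#' @export
fit_predictor <- function(config, data) {
  stopifnot(inherits(config, "cf_rbf_config"), inherits(data, "cf_dataset"))
  if (length(data) < 10) stop("need at least 10 labeled examples")
  y <- dataset_energies(data)
  if (stats::sd(y) < 1e-12) {
    warning("degenerate training data (all energies equal); constant model")
  }
  y <- y - .dataset_priors(data)  # learn the residual above the prior
  X <- .design_matrix(data, config)
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  A <- crossprod(Xc) + diag(config$ridge, ncol(X))
  w <- solve(A, crossprod(Xc, y - ym))
  structure(list(config = config, w = as.vector(w), x_mean = xm,
                 y_mean = ym,
                 W = matrix(as.vector(w), nrow = .pd_n_pairs,
                            ncol = config$n_centers, byrow = TRUE)),
            class = "cf_rbf_model")
}

#' Predicted energy of a conformation (kcal/mol)
#' @param model A fitted `cf_rbf_model`.
#' @param conf A `cf_conformation`.
#' @return Scalar energy.
#' @export
predict_energy <- function(model, conf) {
  pi_ <- .mol_pairinfo(conf$molecule)
  x <- .design_row(pi_, conf$coords, model$config)
  sum((x - model$x_mean) * model$w) + model$y_mean +
    .prior_energy(pi_, conf$coords)
}

#' Predicted forces (negative energy gradient), kcal/mol/A
#' @param model A fitted `cf_rbf_model`.
#' @param conf A `cf_conformation`.
#' @return N x 3 force matrix.
#' @export
predict_forces <- function(model, conf) {
  pi_ <- .mol_pairinfo(conf$molecule)
  .model_forces(model, pi_, conf$coords)
}

.model_forces <- function(model, pairinfo, coords) {
  cfg <- model$config
  dx <- coords[pairinfo$i, , drop = FALSE] - coords[pairinfo$j, , drop = FALSE]
  d <- sqrt(rowSums(dx^2))
  keep <- pairinfo$bonded | d < cfg$cutoff
  F <- matrix(0, pairinfo$n, 3)
  if (!any(keep)) return(F)
  bd <- .rbf_basis(d[keep], cfg, deriv = TRUE)
  s <- rowSums(bd$dB * model$W[pairinfo$chan[keep], , drop = FALSE])
  # dE/dxi = s_e * (xi - xj)/d ; force is the negative
  P <- dx[keep, , drop = FALSE] * (s / d[keep])
  .accumulate_force(F, P, pairinfo$i[keep], pairinfo$j[keep]) +
    .prior_forces(pairinfo, coords)
}

#' Train an ensemble of energy predictors
#'
#' Every member is fit independently on the same dataset snapshot;
#' prediction is the arithmetic mean of members.
#'
#' @param configs List of `cf_rbf_config` (>= 2 for a usable committee).
#' @param data A `cf_dataset`.
#' @param seed Unused by the closed-form fit, recorded for provenance.
#' @return A `cf_ensemble`.
#' @export
train_ensemble <- function(configs, data, seed = 1) {
  stopifnot(length(configs) >= 1)
  members <- lapply(configs, fit_predictor, data = data)
  names(members) <- vapply(configs, function(c) c$name, "")
  hetero <- length(unique(vapply(configs, function(c)
    paste(c$n_centers, c$width, c$cutoff, c$ridge), ""))) > 1
  structure(list(members = members, heterogeneous = hetero, seed = seed),
            class = "cf_ensemble")
}

#' @export
print.cf_ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d members (%s)\n", length(x$members),
              if (x$heterogeneous) "heterogeneous" else "homogeneous"))
  invisible(x)
}

#' Ensemble prediction for one conformation
#' @param ens A trained `cf_ensemble`.
#' @param conf A `cf_conformation`.
#' @return List with `mean` and the per-member energy vector `members`.
#' @export
ensemble_predict <- function(ens, conf) {
  stopifnot(inherits(ens, "cf_ensemble"))
  e <- vapply(ens$members, predict_energy, 0, conf = conf)
  list(mean = mean(e), members = unname(e))
}

#' Batched per-member predictions over a dataset
#' @param ens A `cf_ensemble`.
#' @param ds A `cf_dataset`.
#' @return Matrix, one row per entry, one column per member.
#' @export
ensemble_predict_dataset <- function(ens, ds) {
  prior <- .dataset_priors(ds)
  sapply(ens$members, function(m) {
    X <- .design_matrix(ds, m$config)
    as.vector(sweep(X, 2, m$x_mean) %*% m$w) + m$y_mean + prior
  })
}

#' Mean-energy force field of an ensemble
#'
#' Closure over a fixed molecule topology evaluating the ensemble mean
#' energy, its analytic forces, and the per-member force arrays (used by
#' the gradient-cosine confidence score).
#'
#' @param ens A `cf_ensemble`.
#' @param mol A `cf_molecule`.
#' @return Function `f(coords)` returning `list(energy, forces,
#'   member_forces, member_energies)`.
#' @export
ensemble_force_fn <- function(ens, mol) {
  pi_ <- .mol_pairinfo(mol)
  function(coords) {
    fs <- lapply(ens$members, .model_forces, pairinfo = pi_, coords = coords)
    prior <- .prior_energy(pi_, coords)
    es <- vapply(ens$members, function(m) {
      x <- .design_row(pi_, coords, m$config)
      sum((x - m$x_mean) * m$w) + m$y_mean + prior
    }, 0)
    list(energy = mean(es), forces = Reduce(`+`, fs) / length(fs),
         member_forces = fs, member_energies = unname(es))
  }
}

#' Relative standard deviation disagreement score
#'
#' Population standard deviation of the committee's energy predictions
#' divided by the magnitude of their mean (guarded below by
#' `eps = 1e-8` kcal/mol).
#'
#' @param per_member Numeric vector of at least 2 member predictions.
#' @param eps Denominator guard.
#' @return Non-negative score.
#' @export
disagreement_rsd <- function(per_member, eps = 1e-8) {
  if (length(per_member) < 2) stop("need at least 2 member predictions")
  m <- mean(per_member)
  s <- sqrt(mean((per_member - m)^2))
  s / max(abs(m), eps)
}

#' Evaluate a predictor or ensemble on labeled data
#'
#' @param object A `cf_rbf_model` or `cf_ensemble`.
#' @param data A non-empty `cf_dataset`.
#' @return List with `mae` and `rmse` (kcal/mol, per conformation).
#' @export
evaluate_predictions <- function(object, data) {
  stopifnot(inherits(data, "cf_dataset"), length(data) > 0)
  y <- dataset_energies(data)
  pred <- if (inherits(object, "cf_ensemble")) {
    rowMeans(ensemble_predict_dataset(object, data))
  } else {
    X <- .design_matrix(data, object$config)
    as.vector(sweep(X, 2, object$x_mean) %*% object$w) + object$y_mean +
      .dataset_priors(data)
  }
  err <- pred - y
  list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)))
}
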