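# Langevin molecular dynamics driven by predicted forces, the
# gradient-cosine confidence score, low-confidence frame selection, and
# the energy-minimization evaluation metrics.

#' Molecular dynamics configuration
#'
#' Langevin dynamics at `temperature` K with friction `friction` (1/ps),
#' integrated with a BAOAB splitting at `timestep` fs. Every
#' `save_stride`-th step is saved to the trajectory (plus the final step).
#' The run stops early when the instantaneous temperature exceeds
#' `temp_cap`, protecting against force-field blow-ups from randomly
#' initialized velocities.
#'
#' Two presets mirror the data-generation protocol: training mode
#' ([md_config_train()], 1000 steps, save every 10th) and test mode
#' ([md_config_test()], 100 steps, save every step).
#'
#' @param timestep Integration step, fs.
#' @param n_steps Maximum number of steps.
#' @param save_stride Save every k-th frame.
#' @param friction Langevin friction, 1/ps. The default damping time of
#'   100 fs lets runs of a few hundred steps actually relax toward nearby
#'   minima, matching the protocol's assumption that short Langevin runs
#'   are energy-minimizing.
#' @param temperature Bath temperature, K (also used for the
#'   Maxwell-Boltzmann velocity initialization).
#' @param temp_cap Early-stop temperature, K.
#' @param seed Seed for velocity initialization and the thermostat noise.
#' @return A `cf_md_config`.
#' @export
md_config <- function(timestep = 1, n_steps = 1000, save_stride = 10,
                      friction = 10, temperature = 300, temp_cap = 600,
                      seed = 1) {
  stopifnot(timestep > 0, n_steps >= 1, save_stride >= 1)
  structure(list(timestep = timestep, n_steps = n_steps,
                 save_stride = save_stride, friction = friction,
                 temperature = temperature, temp_cap = temp_cap,
                 seed = as.integer(seed)),
            class = "cf_md_config")
}

#' @rdname md_config
#' @param ... Overrides passed to [md_config()].
#' @export
md_config_train <- function(...) {
  # training mode explores: a loose 1500 K guard only stops blow-ups
  do.call(md_config, utils::modifyList(
    list(n_steps = 1000, save_stride = 10, temp_cap = 1500), list(...)))
}

#' @rdname md_config
#' @export
md_config_test <- function(...) {
  do.call(md_config, utils::modifyList(
    list(n_steps = 100, save_stride = 1, temp_cap = 600), list(...)))
}

#' Instantaneous temperature from velocities
#'
#' `T = 2 KE / (kB * N_dof)` with `N_dof = 3 N` (rigid-body modes are not
#' removed) and `KE = 0.5 * sum(m v^2)` converted to kcal/mol.
#'
#' @param velocities N x 3 matrix, Angstrom/fs.
#' @param masses Length-N vector, amu.
#' @return Temperature in K.
#' @export
instantaneous_temperature <- function(velocities, masses) {
  velocities <- as.matrix(velocities)
  stopifnot(nrow(velocities) == length(masses))
  ke <- 0.5 * cf_constants$mvv_to_kcal * sum(masses * rowSums(velocities^2))
  2 * ke / (cf_constants$kB * 3 * length(masses))
}

#' Ensemble confidence score from per-member forces
#'
#' For each atom, the cosine of the angle between every pair of members'
#' force vectors on that atom is computed and the minimum taken; the score
#' is the mean of these atomwise minima, in `[-1, 1]`. A zero force vector
#' has undefined direction; its cosine against anything is defined as 0
#' (maximally uninformative).
#'
#' @param member_forces List (length >= 2) of N x 3 force matrices, or a
#'   `cf_forceset`.
#' @return Scalar confidence score.
#' @export
confidence_score <- function(member_forces) {
  if (inherits(member_forces, "cf_forceset")) {
    member_forces <- member_forces$forces
  }
  M <- length(member_forces)
  if (M < 2) stop("confidence score needs at least 2 ensemble members")
  dims <- unique(lapply(member_forces, dim))
  if (length(dims) != 1) stop("member force arrays differ in shape")
  n <- dims[[1]][1]
  norms <- vapply(member_forces, function(F) sqrt(rowSums(F^2)),
                  numeric(n))
  norms <- matrix(norms, nrow = n)
  mins <- rep(Inf, n)
  for (q in 1:(M - 1)) for (k in (q + 1):M) {
    dot <- rowSums(member_forces[[q]] * member_forces[[k]])
    denom <- norms[, q] * norms[, k]
    cosv <- ifelse(denom > 1e-24, dot / pmax(denom, 1e-300), 0)
    mins <- pmin(mins, cosv)
  }
  mean(mins)
}

#' Run Langevin molecular dynamics
#'
#' Integrates the conformation under `force_fn` with a BAOAB splitting:
#' half kick, half drift, Ornstein-Uhlenbeck velocity refresh, half drift,
#' half kick. Velocities are initialized from the Maxwell-Boltzmann
#' distribution at the bath temperature. With zero friction and a 0 K
#' bath this reduces to velocity Verlet. The run is deterministic for a
#' fixed config seed, and stops early (termination reason
#' `"temperature_cap"`) as soon as the instantaneous temperature exceeds
#' the cap.
#'
#' @param conf Starting `cf_conformation`.
#' @param force_fn Function of an N x 3 coordinate matrix returning
#'   `list(energy, forces, ...)`; see [ensemble_force_fn()] and
#'   [toy_oracle_force_fn()]. Per-member forces, when present in the
#'   return value, are stored with each saved frame.
#' @param cfg A `cf_md_config`.
#' @return A `cf_trajectory`: saved `frames` (step, coords, velocities,
#'   temperature, energy, optional member forces), `termination`
#'   (`"completed"` or `"temperature_cap"`), and the originating ids.
#' @export
run_md <- function(conf, force_fn, cfg = md_config()) {
  stopifnot(inherits(conf, "cf_conformation"), inherits(cfg, "cf_md_config"))
  m <- conf$molecule$atoms$mass
  n <- length(m)
  dt <- cfg$timestep
  gamma <- cfg$friction / 1000  # 1/ps -> 1/fs
  Cu <- cf_constants$mvv_to_kcal
  sd_v <- sqrt(cf_constants$kB * cfg$temperature / (m * Cu))
  c1 <- exp(-gamma * dt)
  c2 <- sqrt(max(0, 1 - c1^2))
  frames <- list()
  termination <- "completed"
  .with_seed(cfg$seed, {
    X <- conf$coords
    V <- matrix(stats::rnorm(3 * n), n, 3) * sd_v
    ev <- force_fn(X)
    save_frame <- function(step) {
      frames[[length(frames) + 1]] <<- list(
        step = step, coords = X, velocities = V,
        temperature = instantaneous_temperature(V, m),
        energy = ev$energy, member_forces = ev$member_forces)
    }
    save_frame(0L)
    for (step in seq_len(cfg$n_steps)) {
      if (!all(is.finite(ev$forces))) {
        stop("non-finite force at step ", step)
      }
      V <- V + 0.5 * dt * ev$forces / (m * Cu)
      X <- X + 0.5 * dt * V
      if (gamma > 0 || cfg$temperature > 0) {
        V <- c1 * V + c2 * sd_v * matrix(stats::rnorm(3 * n), n, 3)
      }
      X <- X + 0.5 * dt * V
      ev <- force_fn(X)
      V <- V + 0.5 * dt * ev$forces / (m * Cu)
      temp <- instantaneous_temperature(V, m)
      if (temp > cfg$temp_cap) {
        termination <- "temperature_cap"
        save_frame(step)
        break
      }
      if (step %% cfg$save_stride == 0 || step == cfg$n_steps) {
        save_frame(step)
      }
    }
  })
  structure(list(frames = frames, termination = termination,
                 molecule = conf$molecule, conf_id = conf$conf_id,
                 cfg = cfg),
            class = "cf_trajectory")
}

#' @export
print.cf_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory %s/%s> %d saved frames, termination=%s\n",
              x$molecule$id, x$conf_id, length(x$frames), x$termination))
  invisible(x)
}

#' Export a trajectory as multi-frame XYZ
#'
#' One block per saved frame with the comment line
#' `step=<i> T=<K> E=<kcal/mol>`.
#'
#' @param traj A `cf_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  sym <- traj$molecule$atoms$symbol
  blocks <- vapply(traj$frames, function(fr) {
    paste0(length(sym), "\n",
           sprintf("step=%d T=%.2f E=%.6f", fr$step, fr$temperature,
                   fr$energy), "\n",
           paste(sprintf("%-2s %12.6f %12.6f %12.6f", sym,
                         fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]),
                 collapse = "\n"))
  }, "")
  writeLines(blocks, path)
  invisible(path)
}

#' Select the lowest-confidence frames of a trajectory
#'
#' Scores every saved frame with [confidence_score()] of the ensemble's
#' per-member forces (frames store them when the trajectory was run with
#' [ensemble_force_fn()]; otherwise they are recomputed) and returns up to
#' `max_k` conformations with the lowest scores, ascending, ties broken by
#' frame order. Provenance of the returned conformations is `"md"`.
#'
#' @param traj A `cf_trajectory`.
#' @param ens The `cf_ensemble` (used when frames lack member forces).
#' @param max_k Maximum number of frames to select.
#' @return List of `cf_conformation` with a `confidence` attribute each.
#' @export
select_low_confidence <- function(traj, ens = NULL, max_k = 6) {
  stopifnot(inherits(traj, "cf_trajectory"), length(traj$frames) > 0)
  ffn <- NULL
  scores <- vapply(traj$frames, function(fr) {
    mf <- fr$member_forces
    if (is.null(mf)) {
      if (is.null(ens)) stop("frames lack member forces; supply an ensemble")
      if (is.null(ffn)) ffn <<- ensemble_force_fn(ens, traj$molecule)
      mf <- ffn(fr$coords)$member_forces
    }
    confidence_score(mf)
  }, 0)
  ord <- order(scores)  # stable: ties keep frame order
  take <- ord[seq_len(min(max_k, length(ord)))]
  lapply(take, function(k) {
    fr <- traj$frames[[k]]
    cf <- conformation(traj$molecule, fr$coords,
                       conf_id = sprintf("%s_md%d", traj$conf_id, fr$step),
                       provenance = "md")
    attr(cf, "confidence") <- scores[k]
    cf
  })
}

#' Minimize a conformation on a predicted energy surface
#'
#' L-BFGS minimization of `force_fn`'s energy with its analytic gradient.
#'
#' @param conf Starting `cf_conformation`.
#' @param force_fn Energy/force closure (see [ensemble_force_fn()]).
#' @param maxit Iteration cap.
#' @return The relaxed `cf_conformation` (provenance `"md"`).
#' @export
minimize_conformation <- function(conf, force_fn, maxit = 200) {
  n <- nrow(conf$coords)
  opt <- stats::optim(as.vector(conf$coords),
                      fn = function(x) force_fn(matrix(x, n, 3))$energy,
                      gr = function(x)
                        -as.vector(force_fn(matrix(x, n, 3))$forces),
                      method = "L-BFGS-B",
                      control = list(maxit = maxit))
  conformation(conf$molecule, matrix(opt$par, n, 3),
               conf_id = paste0(conf$conf_id, "_min"), provenance = "md")
}

#' Compare MD-guided and random trajectory-frame augmentation
#'
#' The ensemble-guided data-acquisition experiment around molecular
#' dynamics: a base committee is trained on `data`; training-mode MD is run
#' from randomly chosen training conformations; from every trajectory, up
#' to `per_traj` frames are taken either with the lowest confidence scores
#' (MD-sampled arm) or uniformly at random (control arm, same
#' trajectories); each arm's frames are labeled by the oracle and appended
#' to the base data; the re-trained committees are then evaluated with
#' [evaluate_minimization()] on fresh test-mode trajectories from
#' `eval_confs`.
#'
#' @param data Base `cf_dataset`.
#' @param eval_confs List of held-out starting `cf_conformation`.
#' @param oracle `cf_oracle_params` used for labeling and reference
#'   energies.
#' @param configs Committee configuration list.
#' @param n_start Number of training trajectories.
#' @param per_traj Frames kept per trajectory (paper protocol: at most 6).
#' @param n_frames Cap on total appended frames per arm.
#' @param seed Integer seed.
#' @return List with `md` and `random` metric lists and the frame counts.
#' @export
md_sampling_study <- function(data, eval_confs, oracle,
                              configs = heterogeneous_configs(),
                              n_start = 34, per_traj = 6, n_frames = 200,
                              seed = 1) {
  base_ens <- train_ensemble(configs, data)
  starts <- .with_seed(seed, sample(data$entries, n_start))
  md_frames <- list()
  rnd_frames <- list()
  for (k in seq_along(starts)) {
    cf <- starts[[k]]
    ffn <- ensemble_force_fn(base_ens, cf$molecule)
    traj <- run_md(cf, ffn, md_config_train(seed = seed * 1000L + k))
    md_frames <- c(md_frames,
                   select_low_confidence(traj, base_ens, max_k = per_traj))
    nf <- length(traj$frames)
    ridx <- .with_seed(seed * 1000L + k + 7L, sample(nf, min(per_traj, nf)))
    rnd_frames <- c(rnd_frames, lapply(ridx, function(j) {
      fr <- traj$frames[[j]]
      conformation(traj$molecule, fr$coords,
                   sprintf("%s_rnd%d", cf$conf_id, fr$step), "md")
    }))
  }
  take <- function(fr) fr[seq_len(min(n_frames, length(fr)))]
  arm <- function(frames) {
    aug <- labeled_dataset(c(data$entries,
                             label_conformations(take(frames), oracle)$entries))
    ens <- train_ensemble(configs, aug)
    pairs <- lapply(seq_along(eval_confs), function(j) {
      cf <- eval_confs[[j]]
      ffn <- ensemble_force_fn(ens, cf$molecule)
      traj <- run_md(cf, ffn, md_config_test(seed = seed * 31L + j))
      last <- traj$frames[[length(traj$frames)]]
      list(initial = cf,
           final = conformation(cf$molecule, last$coords,
                                paste0(cf$conf_id, "_final"), "md"))
    })
    evaluate_minimization(pairs, oracle, ens)
  }
  list(md = arm(md_frames), random = arm(rnd_frames),
       n_md_frames = min(n_frames, length(md_frames)),
       n_random_frames = min(n_frames, length(rnd_frames)))
}

#' Energy-minimization evaluation metrics
#'
#' Given (initial, final) conformation pairs, computes the Spearman rank
#' correlation between the ensemble-predicted energy differences
#' `E_pred(final) - E_pred(initial)` and the reference differences, the
#' success rate (percent of pairs whose reference energy decreased), and
#' the mean reference difference (kcal/mol).
#'
#' @param pairs List of `list(initial = conf, final = conf)`.
#' @param oracle A `cf_oracle_params` (reference energies are noise-free)
#'   or a function mapping a conformation to its reference energy.
#' @param ens A trained `cf_ensemble`.
#' @return List with `spearman`, `success_rate` (percent) and
#'   `mean_delta`.
#' @export
evaluate_minimization <- function(pairs, oracle, ens) {
  if (length(pairs) < 3) stop("need at least 3 pairs for a rank correlation")
  efun <- if (inherits(oracle, "cf_oracle_params")) {
    function(cf) toy_oracle(cf, oracle)$energy
  } else oracle
  pred_d <- vapply(pairs, function(p) {
    ensemble_predict(ens, p$final)$mean - ensemble_predict(ens, p$initial)$mean
  }, 0)
  true_d <- vapply(pairs, function(p) efun(p$final) - efun(p$initial), 0)
  list(spearman = stats::cor(pred_d, true_d, method = "spearman"),
       success_rate = 100 * mean(true_d < 0),
       mean_delta = mean(true_d))
}
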