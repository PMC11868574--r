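# Candidate ranking strategies: random, ensemble-disagreement (relative
# standard deviation of committee predictions), and MACCS-fingerprint
# loss prediction.

#' Fit per-member loss predictors
#'
#' For each ensemble member, regresses the member's absolute energy error
#' on the molecule's MACCS fingerprint (least squares with intercept and a
#' small ridge penalty for the collinear key bits). The predictors depend
#' on chemical identity only, never on coordinates, so error estimates are
#' cheap across large candidate pools.
#'
#' @param ens A trained `cf_ensemble`.
#' @param data The `cf_dataset` the ensemble was trained on (>= 2 entries).
#' @param ridge Ridge penalty on the fingerprint regression.
#' @return A `cf_loss_predictors`.
#' @export
fit_loss_predictors <- function(ens, data, ridge = 1e-6) {
  stopifnot(inherits(ens, "cf_ensemble"), inherits(data, "cf_dataset"))
  if (length(data) < 2) stop("need at least 2 labeled examples")
  y <- dataset_energies(data)
  pred <- ensemble_predict_dataset(ens, data)
  molids <- vapply(data$entries, function(e) e$molecule$id, "")
  umols <- !duplicated(molids)
  smiles <- vapply(data$entries[umols], function(e) e$molecule$smiles, "")
  fps <- .maccs_from_smiles(smiles)
  FP <- do.call(rbind, lapply(fps, function(f) f$bits))
  rownames(FP) <- molids[umols]
  Xf <- FP[molids, , drop = FALSE]
  models <- lapply(seq_len(ncol(pred)), function(m) {
    err <- abs(pred[, m] - y)
    xm <- colMeans(Xf); ym <- mean(err)
    Xc <- sweep(Xf, 2, xm)
    A <- crossprod(Xc) + diag(ridge, ncol(Xf))
    w <- solve(A, crossprod(Xc, err - ym))
    list(w = as.vector(w), x_mean = xm, y_mean = ym)
  })
  structure(list(models = models, fp_length = ncol(FP),
                 member_names = names(ens$members)),
            class = "cf_loss_predictors")
}

#' @export
print.cf_loss_predictors <- function(x, ...) {
  cat(sprintf("<loss predictors> %d members, %d fingerprint bits\n",
              length(x$models), x$fp_length))
  invisible(x)
}

# raw per-member predicted errors for a fingerprint bit vector
.lp_member_scores <- function(lp, bits) {
  vapply(lp$models, function(m) {
    sum((bits - m$x_mean) * m$w) + m$y_mean
  }, 0)
}

#' Predicted-error acquisition score of a molecule
#'
#' Mean over ensemble members of the member's predicted absolute error,
#' each clipped below at zero. High scores flag molecules the committee is
#' expected to mispredict.
#'
#' @param lp A `cf_loss_predictors`.
#' @param mol A `cf_molecule` (or a `cf_fingerprint`).
#' @return Score in kcal/mol.
#' @export
predicted_error_score <- function(lp, mol) {
  stopifnot(inherits(lp, "cf_loss_predictors"))
  fp <- if (inherits(mol, "cf_fingerprint")) mol else maccs(mol)
  if (fp$length != lp$fp_length) stop("fingerprint length mismatch")
  mean(pmax(.lp_member_scores(lp, fp$bits), 0))
}

#' Rank candidate conformations for labeling
#'
#' Strategies: `"RAND"` is a seeded uniform shuffle; `"VAR"` sorts by the
#' committee's relative-standard-deviation disagreement, highest first;
#' `"LOSSFN"` sorts by the fingerprint loss predictor's score, highest
#' first. Ties (in particular, conformations of the same molecule under
#' LOSSFN, whose scores are identical by construction) are broken by a
#' seeded shuffle applied before the stable sort.
#'
#' @param strategy `"RAND"`, `"VAR"` or `"LOSSFN"`.
#' @param confs List of candidate `cf_conformation`.
#' @param ens Trained `cf_ensemble` (required for VAR and LOSSFN).
#' @param lp `cf_loss_predictors` (required for LOSSFN).
#' @param seed Integer tie-break / shuffle seed.
#' @return A `cf_ranked`: `order` (permutation of input positions),
#'   `score` per candidate (input order; NA for RAND), `strategy`.
#' @export
rank_candidates <- function(strategy, confs, ens = NULL, lp = NULL,
                            seed = 1) {
  strategy <- match.arg(strategy, c("RAND", "VAR", "LOSSFN"))
  n <- length(confs)
  stopifnot(n > 0)
  if (strategy == "RAND") {
    ord <- .with_seed(seed, sample.int(n))
    return(structure(list(order = ord, score = rep(NA_real_, n),
                          strategy = strategy, seed = seed),
                     class = "cf_ranked"))
  }
  if (is.null(ens)) stop(strategy, " ranking needs a trained ensemble")
  score <- if (strategy == "VAR") {
    ds_like <- labeled_dataset(lapply(confs, function(cf) {
      if (is.null(cf$energy)) cf$energy <- 0  # placeholder; only X is used
      cf
    }))
    P <- ensemble_predict_dataset(ens, ds_like)
    apply(P, 1, disagreement_rsd)
  } else {
    if (is.null(lp)) stop("LOSSFN ranking needs fitted loss predictors")
    molids <- vapply(confs, function(cf) cf$molecule$id, "")
    umol <- !duplicated(molids)
    smiles <- vapply(confs[umol], function(cf) cf$molecule$smiles, "")
    fps <- .maccs_from_smiles(smiles)
    s_mol <- vapply(fps, function(f)
      mean(pmax(.lp_member_scores(lp, f$bits), 0)), 0)
    names(s_mol) <- molids[umol]
    unname(s_mol[molids])
  }
  shuf <- .with_seed(seed, sample.int(n))
  ord <- shuf[order(-score[shuf])]   # stable sort after seeded shuffle
  structure(list(order = ord, score = score, strategy = strategy,
                 seed = seed),
            class = "cf_ranked")
}

#' @export
print.cf_ranked <- function(x, ...) {
  cat(sprintf("<ranking> %s over %d candidates\n", x$strategy,
              length(x$order)))
  invisible(x)
}
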