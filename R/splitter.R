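# Strict scaffold-and-similarity train/validation/test splitting.
#
# Train is a uniform random fraction of the molecules; of the remainder,
# anything whose Bemis-Murcko scaffold is Tanimoto-similar (>= threshold)
# to ANY training scaffold goes to validation, the rest to test. By
# construction every train-test scaffold pair is below the threshold.

# Scaffold SMILES and MACCS fingerprint matrix for a molecule list.
.scaffold_fps <- function(mols) {
  scaf <- vapply(mols, function(m) bemis_murcko(m)$smiles, "")
  uniq <- unique(scaf)
  fps <- .maccs_from_smiles(uniq)
  M <- do.call(rbind, lapply(fps, function(f) f$bits))
  list(scaffold = scaf, fp = M[match(scaf, uniq), , drop = FALSE])
}

#' Strict scaffold split of a molecule set
#'
#' Randomly assigns `round(train_frac * N)` molecules to the training set.
#' Each remaining molecule whose scaffold has Tanimoto similarity
#' `>= sim_threshold` (MACCS keys of the Bemis-Murcko scaffold) to any
#' training scaffold is sent to validation; the rest form the test set, so
#' the maximum train-test scaffold similarity is below the threshold by
#' construction. Acyclic molecules (empty scaffolds) outside train are sent
#' to validation whenever train also contains an acyclic molecule,
#' otherwise to test.
#'
#' @param mols List of `cf_molecule`.
#' @param train_frac Fraction of molecules in train, in (0, 1).
#' @param sim_threshold Scaffold-similarity threshold, in (0, 1].
#' @param seed Integer seed for the random train draw.
#' @return A `cf_split`: molecule-id vectors `train`, `validation`,
#'   `test`, plus a `report` (set sizes, unique scaffold counts, max
#'   train-test similarity) and the per-molecule scaffold table.
#' @export
scaffold_split <- function(mols, train_frac = 0.8, sim_threshold = 0.7,
                           seed = 1) {
  stopifnot(length(mols) >= 5)
  if (!(train_frac > 0 && train_frac < 1)) {
    stop("train_frac must be in (0, 1)")
  }
  stopifnot(sim_threshold > 0, sim_threshold <= 1)
  ids <- vapply(mols, function(m) m$id, "")
  if (anyDuplicated(ids)) stop("duplicate molecule ids")
  sf <- .scaffold_fps(mols)
  n <- length(mols)
  n_train <- round(train_frac * n)
  tr <- .with_seed(seed, sort(sample.int(n, n_train)))
  rest <- setdiff(seq_len(n), tr)
  sim <- .tanimoto_cross(sf$fp[rest, , drop = FALSE],
                         sf$fp[tr, , drop = FALSE])
  max_sim <- apply(sim, 1, max)
  acyclic <- !nzchar(sf$scaffold)
  train_has_acyclic <- any(acyclic[tr])
  to_val <- max_sim >= sim_threshold
  to_val[acyclic[rest]] <- train_has_acyclic
  va <- rest[to_val]
  te <- rest[!to_val]
  if (length(te) == 0) warning("empty test set at this threshold")
  split <- structure(list(
    train = ids[tr], validation = ids[va], test = ids[te],
    sim_threshold = sim_threshold,
    scaffolds = stats::setNames(sf$scaffold, ids),
    fp = sf$fp, ids = ids,
    report = list(
      n = n, n_train = length(tr), n_validation = length(va),
      n_test = length(te),
      scaffolds_train = length(unique(sf$scaffold[tr])),
      scaffolds_test = length(unique(sf$scaffold[te])),
      max_train_test_sim = if (length(te) > 0)
        max(.tanimoto_cross(sf$fp[te, , drop = FALSE],
                            sf$fp[tr, , drop = FALSE])) else 0
    )), class = "cf_split")
  split
}

#' @export
print.cf_split <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<split> train %d / validation %d / test %d",
                     " (max train-test scaffold similarity %.3f)\n"),
              r$n_train, r$n_validation, r$n_test, r$max_train_test_sim))
  invisible(x)
}

#' Audit a split for scaffold leakage
#'
#' Reports the fraction of test-set scaffolds present verbatim among the
#' training scaffolds, the maximum train-test scaffold Tanimoto similarity
#' (exhaustive pairwise scan), and whether the three sets are pairwise
#' disjoint and cover all molecules.
#'
#' @param split A `cf_split`.
#' @return List with `verbatim_overlap`, `max_train_test_sim`,
#'   `disjoint`, `complete`.
#' @export
leakage_audit <- function(split) {
  stopifnot(inherits(split, "cf_split"))
  tr <- match(split$train, split$ids)
  te <- match(split$test, split$ids)
  va <- match(split$validation, split$ids)
  disjoint <- anyDuplicated(c(split$train, split$validation,
                              split$test)) == 0
  complete <- setequal(c(split$train, split$validation, split$test),
                       split$ids)
  tr_scaf <- unique(split$scaffolds[tr])
  te_scaf <- unique(split$scaffolds[te])
  verbatim <- if (length(te_scaf) > 0) {
    mean(te_scaf %in% tr_scaf)
  } else 0
  max_sim <- if (length(te) > 0) {
    max(.tanimoto_cross(split$fp[te, , drop = FALSE],
                        split$fp[tr, , drop = FALSE]))
  } else 0
  list(verbatim_overlap = verbatim, max_train_test_sim = max_sim,
       disjoint = disjoint, complete = complete)
}
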