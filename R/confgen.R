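# Conformer generation: seeded distance-geometry embedding with optional
# MMFF94 refinement through OpenBabel.

# Evaluate an expression with a private, restored RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# All-pairs shortest path lengths on the bond graph (unweighted BFS).
.graph_dist <- function(n, bonds) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds$i[r]; j <- bonds$j[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[d[nxt] == Inf]
      if (length(nxt) == 0) break
      d[nxt] <- d[frontier[1]] + 1
      # BFS layer by layer: all frontier nodes share the same depth
      frontier <- nxt
    }
    D[s, ] <- d
  }
  D
}

.bond_length_factor <- c("1" = 1.00, "2" = 0.87, "3" = 0.78, "4" = 0.93)

# Distance restraints for one molecule: targets for 1-2 and 1-3 pairs,
# lower bounds (scaled vdW contact) for everything further apart.
.dg_restraints <- function(mol) {
  n <- mol$n_atoms
  el <- .element_row(mol$atoms$symbol)
  gd <- .graph_dist(n, mol$bonds)
  # per-bond target lengths
  bt <- matrix(NA_real_, n, n)
  for (r in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[r]; j <- mol$bonds$j[r]
    f <- .bond_length_factor[as.character(min(mol$bonds$order[r], 4))]
    if (is.na(f)) f <- 1
    bt[i, j] <- bt[j, i] <- f * (el$r_cov[i] + el$r_cov[j])
  }
  deg <- tabulate(c(mol$bonds$i, mol$bonds$j), nbins = n)
  angle <- ifelse(deg >= 4, 109.47, ifelse(deg == 3, 120, 180)) * pi / 180
  p1 <- integer(0); p2 <- integer(0); typ <- integer(0); val <- numeric(0)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    g <- gd[i, j]
    if (!is.finite(g)) next
    if (g == 1) {
      p1 <- c(p1, i); p2 <- c(p2, j); typ <- c(typ, 1L); val <- c(val, bt[i, j])
    } else if (g == 2) {
      # central atom: common bonded neighbor
      ni <- which(!is.na(bt[i, ])); nj <- which(!is.na(bt[j, ]))
      cen <- intersect(ni, nj)[1]
      a <- angle[cen]
      d13 <- sqrt(bt[i, cen]^2 + bt[j, cen]^2 -
                    2 * bt[i, cen] * bt[j, cen] * cos(a))
      p1 <- c(p1, i); p2 <- c(p2, j); typ <- c(typ, 2L); val <- c(val, d13)
    } else {
      lb <- 0.75 * (el$r_vdw[i] + el$r_vdw[j])
      p1 <- c(p1, i); p2 <- c(p2, j); typ <- c(typ, 3L); val <- c(val, lb)
    }
  }
  list(p1 = p1, p2 = p2, type = typ, value = val, gd = gd)
}

.dg_stress <- function(x, rs, n) {
  X <- matrix(x, n, 3)
  dx <- X[rs$p1, , drop = FALSE] - X[rs$p2, , drop = FALSE]
  d <- sqrt(rowSums(dx^2)) + 1e-12
  w <- c(10, 3, 1)[rs$type]
  viol <- ifelse(rs$type == 3L, pmin(d - rs$value, 0), d - rs$value)
  sum(w * viol^2)
}

.dg_grad <- function(x, rs, n) {
  X <- matrix(x, n, 3)
  dx <- X[rs$p1, , drop = FALSE] - X[rs$p2, , drop = FALSE]
  d <- sqrt(rowSums(dx^2)) + 1e-12
  w <- c(10, 3, 1)[rs$type]
  viol <- ifelse(rs$type == 3L, pmin(d - rs$value, 0), d - rs$value)
  coef <- 2 * w * viol / d
  G <- matrix(0, n, 3)
  P <- dx * coef
  A <- rowsum(P, rs$p1)
  G[as.integer(rownames(A)), ] <- G[as.integer(rownames(A)), ] + A
  B <- rowsum(P, rs$p2)
  G[as.integer(rownames(B)), ] <- G[as.integer(rownames(B)), ] - B
  as.vector(G)
}

# One seeded distance-geometry embedding: sample a distance matrix within
# bounds, metric-matrix (classical MDS) embed to 3-D, refine against the
# restraints with L-BFGS.
.dg_embed <- function(mol, rs, seed) {
  n <- mol$n_atoms
  .with_seed(seed, {
    D <- matrix(0, n, n)
    ub <- matrix(0, n, n)
    for (k in seq_along(rs$p1)) {
      i <- rs$p1[k]; j <- rs$p2[k]
      dij <- if (rs$type[k] == 3L) {
        hi <- min(1.6 * rs$value[k] + 0.6 * rs$gd[i, j], 12)
        stats::runif(1, rs$value[k], max(hi, rs$value[k] + 0.5))
      } else rs$value[k] * stats::runif(1, 0.98, 1.02)
      D[i, j] <- D[j, i] <- dij
    }
    J <- diag(n) - matrix(1 / n, n, n)
    B <- -0.5 * J %*% (D^2) %*% J
    ev <- eigen(B, symmetric = TRUE)
    lam <- pmax(ev$values[1:3], 1e-6)
    X0 <- ev$vectors[, 1:3, drop = FALSE] %*% diag(sqrt(lam), 3)
    X0 <- X0 + matrix(stats::rnorm(3 * n, sd = 0.05), n, 3)
    opt <- stats::optim(as.vector(X0), .dg_stress, .dg_grad, rs = rs, n = n,
                        method = "L-BFGS-B",
                        control = list(maxit = 150, factr = 1e7))
    matrix(opt$par, n, 3)
  })
}

# Sanity check for an embedding: every bonded pair within a loose
# chemical range.
.embed_ok <- function(mol, X) {
  i <- mol$bonds$i; j <- mol$bonds$j
  d <- sqrt(rowSums((X[i, , drop = FALSE] - X[j, , drop = FALSE])^2))
  all(d > 0.6 & d < 2.3)
}

#' Generate 3-D conformations of a molecule
#'
#' Produces `n` conformations by seeded distance-geometry embedding:
#' distances are sampled within topology-derived bounds (covalent radii for
#' bonds, law-of-cosines for angle pairs, scaled van der Waals contacts as
#' lower bounds elsewhere), embedded via the metric matrix, and refined by
#' restrained minimization. Per-conformer seeds are derived as
#' `seed + conformer index`, so any subset is reproducible. With
#' `optimize = TRUE` the conformers are additionally relaxed with the
#' MMFF94 force field (OpenBabel), and tagged `ff_optimized`.
#'
#' @param mol A `cf_molecule`.
#' @param n Number of conformations (>= 1).
#' @param seed Integer base seed.
#' @param optimize Relax with MMFF94 after embedding.
#' @return List of `cf_conformation` (may be shorter than `n`, with a
#'   warning, if some embeddings fail).
#' @export
generate_conformations <- function(mol, n, seed = 1, optimize = FALSE) {
  stopifnot(inherits(mol, "cf_molecule"), n >= 1)
  rs <- .dg_restraints(mol)
  confs <- vector("list", n)
  ok <- logical(n)
  for (k in seq_len(n)) {
    X <- NULL
    for (retry in 0:4) {
      Xt <- .dg_embed(mol, rs, seed + k + retry * 100003L)
      if (.embed_ok(mol, Xt)) { X <- Xt; break }
    }
    if (!is.null(X)) {
      ok[k] <- TRUE
      confs[[k]] <- conformation(mol, X, conf_id = paste0("c", k),
                                 provenance = "generated")
    }
  }
  confs <- confs[ok]
  if (length(confs) == 0) stop("all embeddings failed for molecule ", mol$id)
  if (length(confs) < n) {
    warning(sprintf("molecule %s: %d of %d embeddings failed",
                    mol$id, n - length(confs), n))
  }
  if (optimize) confs <- mmff94_optimize(confs)
  confs
}

#' Thermally displace a conformation
#'
#' Adds seeded isotropic Gaussian displacements to every coordinate,
#' emulating the off-equilibrium (thermal / dynamics-derived) stratum of a
#' conformational dataset. Provenance of the result is `"md"`.
#'
#' @param conf A `cf_conformation`.
#' @param sd Per-coordinate displacement standard deviation, Angstrom.
#' @param seed Integer seed.
#' @return A displaced `cf_conformation`.
#' @export
perturb_conformation <- function(conf, sd = 0.07, seed = 1) {
  stopifnot(inherits(conf, "cf_conformation"))
  X <- conf$coords + .with_seed(seed,
    matrix(stats::rnorm(length(conf$coords), sd = sd),
           nrow(conf$coords), 3))
  conformation(conf$molecule, X, conf_id = paste0(conf$conf_id, "p"),
               provenance = "md")
}

#' Relax conformations with the MMFF94 force field
#'
#' Runs OpenBabel's MMFF94 steepest-descent minimizer on each conformation
#' (deterministic for fixed input) and retags provenance `ff_optimized`.
#'
#' @param confs List of `cf_conformation`.
#' @param steps Maximum minimizer steps.
#' @return List of `cf_conformation` with relaxed coordinates.
#' @export
mmff94_optimize <- function(confs, steps = 500) {
  stopifnot(length(confs) > 0)
  blocks <- vapply(confs, function(cf) {
    .write_molblock(cf$molecule$atoms$symbol, cf$coords, cf$molecule$bonds)
  }, "")
  fin <- tempfile(fileext = ".sdf"); fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste0(blocks, "\n$$$$"), fin)
  status <- system2("obabel",
                    c(fin, "-osdf", "-O", fout, "--minimize", "--sd",
                      "--ff", "MMFF94", "--steps", as.integer(steps)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(fout)) stop("obabel MMFF94 minimization failed")
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(fout))
  if (length(sdfset) != length(confs)) {
    stop("MMFF94 minimization dropped conformations")
  }
  lapply(seq_along(confs), function(k) {
    ab <- ChemmineR::atomblock(sdfset[[k]])
    conformation(confs[[k]]$molecule, unname(ab[, 1:3]),
                 conf_id = confs[[k]]$conf_id, provenance = "ff_optimized")
  })
}
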