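# Toy labeling oracle: harmonic bonds plus Lennard-Jones nonbonded terms,
# with analytic forces. A desk-scale, pluggable stand-in for the quantum
# chemistry labeler: energies in kcal/mol, forces in kcal/mol/A.

#' Parameters of the toy labeling oracle
#'
#' The oracle is a small class-I force-field analog:
#' `E = sum_bonds k (d - d0)^2 + sum_13 k13 (d - d13)^2 +
#'  sum_nonbonded 4 eps_ij ((sigma/d)^12 - (sigma/d)^6)`.
#' `d0` is the covalent-radius equilibrium length of each bond (shortened
#' for higher bond orders); angle bending enters as Urey-Bradley harmonic
#' terms on 1-3 distances (equilibria from the law of cosines with
#' hybridization-typical angles); nonbonded pairs are atom pairs three or
#' more bonds apart, with `sigma` scaled from van der Waals radii and the
#' well depth `eps_ij` the Lorentz-Berthelot geometric mean of per-element
#' depths times `lj_epsilon`. Gaussian label noise (`noise_sd`, kcal/mol)
#' is applied to stored energy labels only, never to forces, so
#' force/energy consistency stays exact.
#'
#' An optional per-atom baseline (`atom_energy`, kcal/mol per atom, default
#' 0) mimics the atomic self-energy offset that dominates quantum-chemistry
#' total energies; it shifts energies without touching forces.
#'
#' @param k_bond Bond spring constant, kcal/mol/A^2.
#' @param k_angle Urey-Bradley 1-3 spring constant, kcal/mol/A^2.
#' @param lj_epsilon Global scale on the pairwise Lennard-Jones depths.
#' @param lj_sigma_scale `sigma = scale * (r_vdw_i + r_vdw_j)`.
#' @param atom_energy Baseline energy per atom, kcal/mol.
#' @param noise_sd Label noise standard deviation, kcal/mol.
#' @param seed Seed for the label-noise stream.
#' @return A `cf_oracle_params` list.
#' @export
toy_oracle_params <- function(k_bond = 300, k_angle = 35, lj_epsilon = 1,
                              lj_sigma_scale = 0.8, atom_energy = 0,
                              noise_sd = 0, seed = 1) {
  stopifnot(k_bond > 0, k_angle >= 0, lj_epsilon >= 0, noise_sd >= 0)
  structure(list(k_bond = k_bond, k_angle = k_angle,
                 lj_epsilon = lj_epsilon,
                 lj_sigma_scale = lj_sigma_scale,
                 atom_energy = atom_energy, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cf_oracle_params")
}

# Per-molecule oracle terms (bond list with equilibrium lengths, nonbonded
# pair list with sigma). Computed once per molecule and reused.
.oracle_terms <- function(mol, params) {
  el <- .element_row(mol$atoms$symbol)
  b <- mol$bonds
  f <- .bond_length_factor[as.character(pmin(b$order, 4))]
  f[is.na(f)] <- 1
  d0 <- f * (el$r_cov[b$i] + el$r_cov[b$j])
  kb <- sqrt(el$k_rel[b$i] * el$k_rel[b$j])
  gd <- .graph_dist(mol$n_atoms, b)
  # Urey-Bradley 1-3 terms: equilibrium distances by the law of cosines at
  # a uniform 111 degree valence angle, so the oracle stays a sum of
  # pair-distance functions per element pair (learnable in principle by a
  # pair-channel regressor).
  bt <- matrix(NA_real_, mol$n_atoms, mol$n_atoms)
  bt[cbind(b$i, b$j)] <- bt[cbind(b$j, b$i)] <- d0
  theta <- 111 * pi / 180
  a13 <- which(upper.tri(gd) & gd == 2, arr.ind = TRUE)
  d13 <- apply(a13, 1, function(p) {
    cen <- which(!is.na(bt[p[1], ]) & !is.na(bt[p[2], ]))[1]
    sqrt(bt[p[1], cen]^2 + bt[p[2], cen]^2 -
           2 * bt[p[1], cen] * bt[p[2], cen] * cos(theta))
  })
  nb <- which(upper.tri(gd) & gd >= 3, arr.ind = TRUE)
  sigma <- params$lj_sigma_scale * (el$r_vdw[nb[, 1]] + el$r_vdw[nb[, 2]])
  eps <- params$lj_epsilon * sqrt(el$lj_eps[nb[, 1]] * el$lj_eps[nb[, 2]])
  list(n = mol$n_atoms, bi = b$i, bj = b$j, d0 = d0, kb = kb,
       ai = a13[, 1], aj = a13[, 2], d13 = d13,
       nbi = nb[, 1], nbj = nb[, 2], sigma = sigma, eps = eps)
}

.pair_dist <- function(coords, i, j) {
  dx <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
  list(dx = dx, d = sqrt(rowSums(dx^2)))
}

.accumulate_force <- function(F, P, i, j) {
  A <- rowsum(P, i)
  ia <- as.integer(rownames(A))
  F[ia, ] <- F[ia, ] - A
  B <- rowsum(P, j)
  ib <- as.integer(rownames(B))
  F[ib, ] <- F[ib, ] + B
  F
}

# Core evaluation on raw coordinates.
.toy_eval <- function(tm, params, X) {
  F <- matrix(0, tm$n, 3)
  pb <- .pair_dist(X, tm$bi, tm$bj)
  kb <- params$k_bond * tm$kb
  e_bond <- sum(kb * (pb$d - tm$d0)^2)
  F <- .accumulate_force(F, pb$dx * (2 * kb * (pb$d - tm$d0) / pb$d),
                         tm$bi, tm$bj)
  e_ang <- 0
  if (params$k_angle > 0 && length(tm$ai) > 0) {
    pa <- .pair_dist(X, tm$ai, tm$aj)
    e_ang <- sum(params$k_angle * (pa$d - tm$d13)^2)
    F <- .accumulate_force(F, pa$dx *
                             (2 * params$k_angle * (pa$d - tm$d13) / pa$d),
                           tm$ai, tm$aj)
  }
  e_nb <- 0
  if (length(tm$nbi) > 0) {
    pn <- .pair_dist(X, tm$nbi, tm$nbj)
    if (any(pn$d < 0.1)) stop("overlapping atoms (distance < 0.1 A)")
    sr6 <- (tm$sigma / pn$d)^6
    e_nb <- sum(4 * tm$eps * (sr6^2 - sr6))
    cn <- 4 * tm$eps * (-12 * sr6^2 + 6 * sr6) / pn$d^2
    F <- .accumulate_force(F, pn$dx * cn, tm$nbi, tm$nbj)
  }
  list(energy = e_bond + e_ang + e_nb + params$atom_energy * tm$n,
       forces = F)
}

#' Toy oracle energy and forces for a conformation
#'
#' @param conf A `cf_conformation`.
#' @param params A `cf_oracle_params`.
#' @param noise Add the Gaussian label noise (deterministic per
#'   conformation id and `params$seed`) to the returned energy. Forces are
#'   always noise-free.
#' @return List with `energy` (kcal/mol) and `forces` (N x 3, kcal/mol/A).
#' @export
toy_oracle <- function(conf, params = toy_oracle_params(), noise = FALSE) {
  stopifnot(inherits(conf, "cf_conformation"),
            inherits(params, "cf_oracle_params"))
  tm <- .oracle_terms(conf$molecule, params)
  out <- .toy_eval(tm, params, conf$coords)
  if (noise && params$noise_sd > 0) {
    h <- sum(utf8ToInt(paste0(conf$molecule$id, "/", conf$conf_id))) +
      params$seed
    out$energy <- out$energy +
      .with_seed(h, stats::rnorm(1, sd = params$noise_sd))
  }
  out
}

#' Force function backed by the toy oracle
#'
#' Returns a closure suitable as the `force_fn` of [run_md()] or
#' [minimize_conformation()]: molecule topology terms are precomputed once,
#' then each call evaluates energy and analytic forces for a coordinate set.
#'
#' @param mol A `cf_molecule` (fixed topology for the trajectory).
#' @param params A `cf_oracle_params`.
#' @return Function `f(coords)` returning `list(energy, forces)`.
#' @export
toy_oracle_force_fn <- function(mol, params = toy_oracle_params()) {
  tm <- .oracle_terms(mol, params)
  function(coords) .toy_eval(tm, params, coords)
}

#' Label conformations with the toy oracle
#'
#' Computes the oracle energy for each conformation (with the params'
#' label noise, if any) and returns a labeled dataset.
#'
#' @param confs List of `cf_conformation`.
#' @param params A `cf_oracle_params`.
#' @return A `cf_dataset`.
#' @export
label_conformations <- function(confs, params = toy_oracle_params()) {
  labeled <- lapply(confs, function(cf) {
    cf$energy <- toy_oracle(cf, params, noise = TRUE)$energy
    cf$energy_unit <- "kcal/mol"
    cf
  })
  labeled_dataset(labeled)
}
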