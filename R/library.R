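# Synthetic drug-like molecule library assembled from a fixed fragment
# grammar (rings, linkers, substituents). Stands in for sampling a large
# compound database so the whole pipeline runs without downloads.

.lib_fragments <- list(
  # slotted ring (attachment point %s), digit-1 ring numbering
  ring_slot = c("c1ccc(%s)cc1", "c1ccnc(%s)c1", "c1cnc(%s)cn1",
                "c1csc(%s)c1", "c1coc(%s)c1", "c1cc(%s)[nH]c1",
                "c1csc(%s)n1", "C1CCC(%s)CC1", "C1CCN(%s)CC1",
                "O1CCN(%s)CC1", "C1CCC(%s)C1", "C1CN(%s)CCN1"),
  # same rings as terminal substituents, digit-2 numbering
  ring_sub = c("c2ccccc2", "c2ccncc2", "c2cncnc2", "c2ccsc2", "c2ccoc2",
               "c2cc[nH]c2", "c2cscn2", "C2CCCCC2", "C2CCNCC2",
               "N2CCOCC2", "C2CCCC2", "C2CNCCN2"),
  # slotted digit-2 rings for a substituent on the second ring
  ring_sub_slot = c("c2ccc(%s)cc2", "c2ccnc(%s)c2", "c2cnc(%s)cn2",
                    "c2csc(%s)c2", "c2coc(%s)c2", "c2cc(%s)[nH]c2",
                    "c2csc(%s)n2", "C2CCC(%s)CC2", "C2CCN(%s)CC2",
                    "O2CCN(%s)CC2", "C2CCC(%s)C2", "C2CN(%s)CCN2"),
  linker = c("", "C", "CC", "CCC", "O", "OC", "N", "NC", "C(=O)",
             "C(=O)N", "C(=O)O", "S", "C=C", "COC"),
  substituent = c("C", "CC", "O", "N", "F", "Cl", "OC", "C(F)(F)F",
                  "C#N", "C(C)C", "CO", "CC(=O)N"),
  acyclic = c("CCO", "CCN", "CCCC", "CC(C)O", "CCOC", "CC(=O)OC",
              "CCCl", "OCCO", "CC(C)C", "CC(=O)N")
)

.lib_one_smiles <- function(fr) {
  u <- stats::runif(1)
  if (u < 0.05) {
    sample(fr$acyclic, 1)
  } else if (u < 0.30) {
    sprintf(sample(fr$ring_slot, 1), sample(fr$substituent, 1))
  } else {
    ringB <- if (stats::runif(1) < 0.4) {
      sprintf(sample(fr$ring_sub_slot, 1), sample(fr$substituent, 1))
    } else sample(fr$ring_sub, 1)
    sprintf(sample(fr$ring_slot, 1), paste0(sample(fr$linker, 1), ringB))
  }
}

#' Generate a synthetic drug-like molecule library
#'
#' Assembles `n` distinct molecules from a fixed fragment grammar:
#' aromatic and aliphatic rings joined by short linkers (alkyl, ether,
#' amine, amide, ester, thioether, vinyl), decorated with common
#' substituents, plus a small acyclic fraction (about 5%) so that empty
#' Bemis-Murcko scaffolds occur. Deterministic for a fixed seed; the
#' SMILES are deduplicated, so the combinatorial grammar yields well over
#' `n / 10` distinct scaffolds at realistic sizes.
#'
#' @param n Number of molecules (>= 1).
#' @param seed Integer seed.
#' @return List of `cf_molecule`.
#' @export
synthetic_library <- function(n, seed = 1) {
  stopifnot(n >= 1)
  fr <- .lib_fragments
  smiles <- .with_seed(seed, {
    out <- character(0)
    tries <- 0
    while (length(out) < n && tries < 50 * n) {
      s <- .lib_one_smiles(fr)
      tries <- tries + 1
      if (!(s %in% out)) out <- c(out, s)
    }
    out
  })
  if (length(smiles) < n) stop("fragment grammar exhausted before n molecules")
  parse_molecules(paste(smiles, sprintf("lib%05d", seq_len(n))))
}
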