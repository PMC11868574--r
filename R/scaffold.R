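# Bemis-Murcko scaffolds: ring systems plus the linkers connecting them.

# Minimal V2000 MOL block writer (atoms with coordinates, bonds with orders).
# Used for scaffold canonicalization (zero coordinates), task content and
# dataset export. Coordinates are written at the standard 4 decimals.
.write_molblock <- function(symbols, coords, bonds, title = "") {
  n <- length(symbols)
  nb <- nrow(bonds)
  hdr <- c(title, " confactory", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                coords[, 1], coords[, 2], coords[, 3], symbols)
  bl <- if (nb > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", bonds$i, bonds$j, bonds$order)
  } else character(0)
  paste(c(hdr, at, bl, "M  END"), collapse = "\n")
}

# Atom indices (into the full atom table) retained by the Bemis-Murcko
# framework: iteratively prune terminal heavy atoms, then re-attach atoms
# multiply bonded to the retained core (e.g. amide oxygens on linkers).
.murcko_kept <- function(mol) {
  heavy <- which(mol$atoms$symbol != "H")
  if (length(heavy) == 0) return(integer(0))
  b <- mol$bonds
  hb <- b[b$i %in% heavy & b$j %in% heavy, , drop = FALSE]
  keep <- rep(TRUE, mol$n_atoms)
  keep[-heavy] <- FALSE
  repeat {
    deg <- integer(mol$n_atoms)
    act <- keep[hb$i] & keep[hb$j]
    if (any(act)) {
      t1 <- table(factor(hb$i[act], levels = seq_len(mol$n_atoms)))
      t2 <- table(factor(hb$j[act], levels = seq_len(mol$n_atoms)))
      deg <- as.integer(t1) + as.integer(t2)
    }
    term <- which(keep & deg <= 1)
    if (length(term) == 0) break
    keep[term] <- FALSE
  }
  core <- which(keep)
  if (length(core) == 0) return(integer(0))
  # re-attach double/triple-bonded substituents of the core
  extra <- with(hb, c(i[order >= 2 & j %in% core & !(i %in% core)],
                      j[order >= 2 & i %in% core & !(j %in% core)]))
  sort(unique(c(core, extra)))
}

#' Bemis-Murcko scaffold of a molecule
#'
#' Retains ring systems and the linker atoms connecting them, removing all
#' side chains (substituents double-bonded to a retained atom, such as
#' linker carbonyl oxygens, are kept). An acyclic molecule has an empty
#' scaffold.
#'
#' @param mol A `cf_molecule`.
#' @return A `cf_scaffold` with canonical SMILES (empty string if acyclic).
#' @export
bemis_murcko <- function(mol) {
  stopifnot(inherits(mol, "cf_molecule"))
  kept <- .murcko_kept(mol)
  if (length(kept) == 0) {
    return(structure(list(smiles = ""), class = "cf_scaffold"))
  }
  idx <- match(seq_len(mol$n_atoms), kept)  # old -> new position
  b <- mol$bonds
  bk <- b[b$i %in% kept & b$j %in% kept, , drop = FALSE]
  bk$i <- idx[bk$i]; bk$j <- idx[bk$j]
  mb <- .write_molblock(mol$atoms$symbol[kept],
                        matrix(0, length(kept), 3), bk)
  can <- .ob_convert("SDF", "CAN", paste0(mb, "\n$$$$\n"))
  can <- trimws(strsplit(can, "[\t\n]")[[1]][1])
  if (!nzchar(can)) stop("scaffold canonicalization failed for ", mol$id)
  structure(list(smiles = can), class = "cf_scaffold")
}

#' @export
print.cf_scaffold <- function(x, ...) {
  cat(sprintf("<scaffold> %s\n",
              if (nzchar(x$smiles)) x$smiles else "(acyclic: empty)"))
  invisible(x)
}
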