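# MACCS fingerprints (via OpenBabel) and Tanimoto similarity.

.fp_new <- function(bits) {
  structure(list(bits = as.integer(bits), length = length(bits)),
            class = "cf_fingerprint")
}

# Session cache: fingerprints are a pure function of the SMILES string.
.fp_cache <- new.env(parent = emptyenv())

# Batch MACCS computation from SMILES strings. Empty strings (acyclic
# scaffolds) yield all-zero fingerprints. Returns a list of cf_fingerprint.
.maccs_from_smiles <- function(smiles) {
  n <- length(smiles)
  out <- vector("list", n)
  fp_len <- 256L  # OpenBabel stores the 166 MACCS keys in a 256-bit vector
  for (k in seq_len(n)) {
    if (!nzchar(smiles[k])) {
      out[[k]] <- .fp_new(integer(fp_len))
    } else {
      out[k] <- list(get0(smiles[k], envir = .fp_cache))
    }
  }
  nonempty <- which(vapply(out, is.null, TRUE))
  if (length(nonempty) > 0) {
    text <- paste0(smiles[nonempty], " s", seq_along(nonempty), collapse = "\n")
    sdftext <- .ob_convert("SMI", "SDF", paste0(text, "\n"))
    tf <- tempfile(fileext = ".sdf")
    on.exit(unlink(tf), add = TRUE)
    writeLines(sdftext, tf)
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))
    if (length(sdfset) != length(nonempty)) {
      stop("fingerprint computation: SMILES conversion dropped records")
    }
    m <- methods::slot(ChemmineR::fingerprintOB(sdfset, "MACCS"), "fpma")
    for (r in seq_along(nonempty)) {
      fp <- .fp_new(m[r, ])
      out[[nonempty[r]]] <- fp
      assign(smiles[nonempty[r]], fp, envir = .fp_cache)
    }
  }
  out
}

#' MACCS key fingerprint of a molecule
#'
#' A deterministic function of chemical identity only (computed from the
#' canonical SMILES, never from coordinates). OpenBabel reports the 166
#' MACCS keys in a 256-bit padded vector; the padding bits are never set.
#'
#' @param mol A `cf_molecule`, a `cf_scaffold`, or a SMILES string.
#' @return A `cf_fingerprint`.
#' @export
maccs <- function(mol) {
  smi <- if (inherits(mol, "cf_molecule")) mol$smiles
         else if (inherits(mol, "cf_scaffold")) mol$smiles
         else as.character(mol)
  .maccs_from_smiles(smi)[[1]]
}

#' @export
print.cf_fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> %d bits, %d set\n", x$length, sum(x$bits)))
  invisible(x)
}

#' Tanimoto similarity between two fingerprints
#'
#' `|a AND b| / |a OR b|`. Two all-zero fingerprints (e.g. two acyclic
#' scaffolds) are defined to have similarity 0, avoiding a 0/0.
#'
#' @param a,b `cf_fingerprint` objects of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "cf_fingerprint"), inherits(b, "cf_fingerprint"))
  if (a$length != b$length) stop("fingerprint length mismatch")
  un <- sum(a$bits | b$bits)
  if (un == 0) return(0)
  sum(a$bits & b$bits) / un
}

# Fast pairwise Tanimoto between two fingerprint bit matrices
# (rows = fingerprints). Rows of all zeros yield 0 against everything.
.tanimoto_cross <- function(A, B) {
  inter <- A %*% t(B)
  pa <- rowSums(A); pb <- rowSums(B)
  un <- outer(pa, pb, `+`) - inter
  out <- ifelse(un > 0, inter / un, 0)
  out
}
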