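# Molecule and Conformation domain types, and parsing from SMILES / SDF.

#' @importFrom methods as is new
NULL

.strip_ob_noise <- function(x) x

# Convert between chemical text formats through OpenBabel, with options.
.ob_convert <- function(from, to, text, add_h = FALSE) {
  if (add_h) {
    opts <- data.frame(names = "h", args = "", stringsAsFactors = FALSE)
    suppressWarnings(ChemmineOB::convertFormat(from, to, source = text,
                                               options = opts))
  } else {
    suppressWarnings(ChemmineOB::convertFormat(from, to, source = text))
  }
}

.molecule_from_sdf <- function(sdf, id, smiles) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  symbols <- gsub("_.*$", "", rownames(ab))
  el <- .element_row(symbols)
  atoms <- data.frame(symbol = el$symbol, number = el$number, mass = el$mass,
                      stringsAsFactors = FALSE)
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1, dimnames = list(NULL, names(bb)))
  bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  structure(list(id = id, smiles = smiles, atoms = atoms, bonds = bonds,
                 n_atoms = nrow(atoms),
                 n_heavy = sum(atoms$symbol != "H")),
            class = "cf_molecule")
}

#' Parse molecules from SMILES text or an SDF file
#'
#' Accepts a character vector of SMILES records (one per element or one per
#' line, with an optional whitespace-separated name), or a path to a `.smi`
#' or `.sdf` file. Each record is canonicalized through OpenBabel and
#' expanded to an explicit-hydrogen atom/bond table.
#'
#' Molecule ids are taken from record names when present, otherwise
#' `mol<k>` by input order. Unparseable records abort with the offending
#' record number.
#'
#' @param source Character vector of SMILES, or a single path to a
#'   `.smi`/`.sdf` file.
#' @return List of `cf_molecule` objects.
#' @export
parse_molecules <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    if (grepl("\\.sdf$", source, ignore.case = TRUE)) {
      return(.parse_sdf_molecules(readChar(source, file.size(source))))
    }
    source <- readLines(source, warn = FALSE)
  }
  lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty molecule source")
  toks <- strsplit(lines, "[[:space:]]+")
  smi <- vapply(toks, `[[`, "", 1L)
  nm <- vapply(toks, function(t) if (length(t) > 1) t[[2]] else "", "")
  ids <- ifelse(nzchar(nm), nm, paste0("mol", seq_along(smi)))
  if (anyDuplicated(ids)) stop("duplicate molecule names in input")
  tags <- paste0("cfrec", seq_along(smi))
  text <- paste0(smi, " ", tags, collapse = "\n")
  can <- .ob_convert("SMI", "CAN", paste0(text, "\n"))
  can_lines <- strsplit(can, "\n", fixed = TRUE)[[1]]
  can_lines <- can_lines[nzchar(can_lines)]
  parts <- strsplit(can_lines, "\t", fixed = TRUE)
  got <- vapply(parts, function(p) p[length(p)], "")
  missing <- setdiff(tags, got)
  if (length(missing) > 0) {
    bad <- min(as.integer(sub("cfrec", "", missing)))
    stop(sprintf("unparseable SMILES at record %d: '%s'", bad, smi[bad]))
  }
  can_smiles <- vapply(parts, function(p) paste(p[-length(p)], collapse = "\t"), "")
  can_smiles <- can_smiles[match(tags, got)]
  sdftext <- .ob_convert("SMI", "SDF", paste0(text, "\n"), add_h = TRUE)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(sdftext, tf)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))
  if (length(sdfset) != length(smi)) {
    stop("internal: SDF expansion record count mismatch")
  }
  mols <- vector("list", length(smi))
  for (k in seq_along(smi)) {
    mols[[k]] <- .molecule_from_sdf(sdfset[[k]], ids[k], can_smiles[k])
  }
  mols
}

.parse_sdf_molecules <- function(sdftext) {
  can <- .ob_convert("SDF", "CAN", sdftext)
  can_lines <- strsplit(can, "\n", fixed = TRUE)[[1]]
  can_lines <- can_lines[nzchar(can_lines)]
  if (length(can_lines) == 0) stop("no parseable records in SDF source")
  parts <- strsplit(can_lines, "\t", fixed = TRUE)
  can_smiles <- vapply(parts, `[[`, "", 1L)
  names_in <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else "", "")
  withh <- .ob_convert("SDF", "SDF", sdftext, add_h = TRUE)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(withh, tf)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))
  if (length(sdfset) != length(can_smiles)) {
    stop("unparseable record in SDF source (record count mismatch)")
  }
  ids <- ifelse(nzchar(names_in), names_in,
                paste0("mol", seq_along(can_smiles)))
  mols <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    mols[[k]] <- .molecule_from_sdf(sdfset[[k]], ids[k], can_smiles[k])
  }
  mols
}

#' @export
print.cf_molecule <- function(x, ...) {
  cat(sprintf("<molecule %s> %s  (%d atoms, %d heavy)\n",
              x$id, x$smiles, x$n_atoms, x$n_heavy))
  invisible(x)
}

#' Construct a conformation
#'
#' Binds one 3-D coordinate set (Angstrom) to a molecule, with a provenance
#' tag mirroring the dataset strata (`generated`, `ff_optimized`, `md`) and
#' an optional energy label.
#'
#' @param molecule A `cf_molecule`.
#' @param coords Numeric matrix, one row per atom, columns x/y/z.
#' @param conf_id Opaque conformer id string.
#' @param provenance One of `"generated"`, `"ff_optimized"`, `"md"`.
#' @param energy Optional scalar energy.
#' @param energy_unit `"kcal/mol"` (default) or `"hartree"`.
#' @return A `cf_conformation`.
#' @export
conformation <- function(molecule, coords, conf_id,
                         provenance = c("generated", "ff_optimized", "md"),
                         energy = NULL, energy_unit = "kcal/mol") {
  stopifnot(inherits(molecule, "cf_molecule"))
  provenance <- match.arg(provenance)
  coords <- as.matrix(coords)
  if (nrow(coords) != molecule$n_atoms || ncol(coords) != 3) {
    stop(sprintf("coords must be %d x 3 for molecule %s",
                 molecule$n_atoms, molecule$id))
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (!is.null(energy)) {
    stopifnot(is.finite(energy))
    if (energy_unit == "hartree") {
      energy <- energy * cf_constants$hartree_to_kcal
      energy_unit <- "kcal/mol"
    }
  }
  structure(list(molecule = molecule, conf_id = as.character(conf_id),
                 coords = unname(coords), provenance = provenance,
                 energy = energy, energy_unit = energy_unit),
            class = "cf_conformation")
}

#' @export
print.cf_conformation <- function(x, ...) {
  cat(sprintf("<conformation %s/%s> %d atoms, provenance=%s, energy=%s\n",
              x$molecule$id, x$conf_id, nrow(x$coords), x$provenance,
              if (is.null(x$energy)) "unlabeled"
              else sprintf("%.4f %s", x$energy, x$energy_unit)))
  invisible(x)
}

# Pairwise distance matrix of a coordinate set.
.dist_matrix <- function(coords) as.matrix(stats::dist(coords))
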