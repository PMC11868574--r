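# LabeledDataset container and SDF / CSV-manifest I/O.

#' Build a labeled dataset from conformations
#'
#' Every entry must carry a finite energy in kcal/mol, and (molecule id,
#' conformer id) pairs must be unique.
#'
#' @param entries List of labeled `cf_conformation`.
#' @return A `cf_dataset` with a molecule-id index.
#' @export
labeled_dataset <- function(entries) {
  stopifnot(length(entries) > 0)
  keys <- vapply(entries, function(e) {
    stopifnot(inherits(e, "cf_conformation"))
    if (is.null(e$energy) || !is.finite(e$energy)) {
      stop("unlabeled entry: ", e$molecule$id, "/", e$conf_id)
    }
    if (!identical(e$energy_unit, "kcal/mol")) {
      stop("dataset entries must be in kcal/mol")
    }
    paste0(e$molecule$id, "/", e$conf_id)
  }, "")
  if (anyDuplicated(keys)) {
    stop("duplicate (molecule, conformer) pairs: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  molids <- vapply(entries, function(e) e$molecule$id, "")
  structure(list(entries = entries,
                 index = split(seq_along(entries), molids)),
            class = "cf_dataset")
}

#' @export
print.cf_dataset <- function(x, ...) {
  cat(sprintf("<dataset> %d labeled conformations of %d molecules\n",
              length(x$entries), length(x$index)))
  invisible(x)
}

#' @export
length.cf_dataset <- function(x) length(x$entries)

#' Energies of all dataset entries (kcal/mol)
#' @param ds A `cf_dataset`.
#' @return Numeric vector in entry order.
#' @export
dataset_energies <- function(ds) {
  vapply(ds$entries, function(e) e$energy, 0)
}

#' Subset a dataset by entry positions
#' @param ds A `cf_dataset`.
#' @param idx Integer entry positions.
#' @return A `cf_dataset`.
#' @export
dataset_subset <- function(ds, idx) labeled_dataset(ds$entries[idx])

.sdf_prop <- function(tag, value) sprintf(">  <%s>\n%s\n\n", tag, value)

# One SDF record for a conformation: standard V2000 MOL block (4-decimal
# coordinates) plus property fields; full-precision coordinates travel in
# SDDF_COORDS so read/write round-trips are exact beyond MOL precision.
.conf_sdf_record <- function(cf, require_energy = TRUE) {
  mol <- cf$molecule
  mb <- .write_molblock(mol$atoms$symbol, cf$coords, mol$bonds,
                        title = paste0(mol$id, "/", cf$conf_id))
  props <- c(
    .sdf_prop("SDDF_MOLID", mol$id),
    .sdf_prop("SDDF_CONFID", cf$conf_id),
    .sdf_prop("SDDF_SMILES", mol$smiles),
    .sdf_prop("SDDF_PROVENANCE", cf$provenance),
    .sdf_prop("SDDF_COORDS",    # one line: x y z;x y z;... per atom
              paste(apply(cf$coords, 1, function(r)
                sprintf("%.9f %.9f %.9f", r[1], r[2], r[3])),
                collapse = ";"))
  )
  if (!is.null(cf[["energy"]])) {
    props <- c(props,
               .sdf_prop("SDDF_ENERGY", sprintf("%.12g", cf[["energy"]])),
               .sdf_prop("SDDF_ENERGY_UNIT", "kcal/mol"))
  } else if (require_energy) {
    stop("entry ", mol$id, "/", cf$conf_id, " has no energy")
  }
  paste0(mb, "\n", paste(props, collapse = ""), "$$$$")
}

#' Write a labeled dataset to an SDF file
#'
#' Each record is a V2000 MOL block with `SDDF_*` property fields holding
#' ids, provenance, canonical SMILES, the energy (kcal/mol) and
#' full-precision coordinates.
#'
#' @param ds A `cf_dataset` (or list of conformations when
#'   `labeled = FALSE`).
#' @param path Output path.
#' @param labeled Require an energy on every record.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, labeled = TRUE) {
  entries <- if (inherits(ds, "cf_dataset")) ds$entries else ds
  recs <- vapply(entries, .conf_sdf_record, "", require_energy = labeled)
  writeLines(recs, path)
  invisible(path)
}

.datablock_value <- function(db, tag) {
  if (tag %in% names(db)) db[[tag]] else NA_character_
}

#' Read a labeled dataset from an SDF file
#'
#' Accepts files written by [write_dataset()] as well as third-party SDF
#' with an `SDDF_ENERGY` / `SDDF_ENERGY_UNIT` property pair
#' (`kcal/mol` or `hartree`; Hartree values are converted by the declared
#' constant 627.509). Records lacking the energy tag abort with their
#' record numbers unless `labeled = FALSE`.
#'
#' @param path SDF path.
#' @param labeled Require energies.
#' @return A `cf_dataset` (or plain list of conformations when
#'   `labeled = FALSE`).
#' @export
read_dataset <- function(path, labeled = TRUE) {
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  n <- length(sdfset)
  can_all <- NULL  # lazy canonical SMILES for records lacking SDDF_SMILES
  confs <- vector("list", n)
  missing_energy <- integer(0)
  for (k in seq_len(n)) {
    sdf <- sdfset[[k]]
    db <- ChemmineR::datablock(sdf)
    molid <- .datablock_value(db, "SDDF_MOLID")
    confid <- .datablock_value(db, "SDDF_CONFID")
    smiles <- .datablock_value(db, "SDDF_SMILES")
    if (is.na(molid)) molid <- paste0("mol", k)
    if (is.na(confid)) confid <- "c1"
    if (is.na(smiles)) {
      if (is.null(can_all)) {
        txt <- .ob_convert("SDF", "CAN",
                           readChar(path, file.size(path)))
        can_all <- vapply(strsplit(strsplit(txt, "\n")[[1]], "\t"),
                          `[[`, "", 1L)
      }
      smiles <- if (k <= length(can_all)) can_all[k] else ""
    }
    mol <- .molecule_from_sdf(sdf, molid, smiles)
    ab <- ChemmineR::atomblock(sdf)
    coords <- unname(ab[, 1:3, drop = FALSE])
    hp <- .datablock_value(db, "SDDF_COORDS")
    if (!is.na(hp)) {
      rows <- strsplit(strsplit(hp, ";", fixed = TRUE)[[1]],
                       "[[:space:]]+")
      coords <- do.call(rbind, lapply(rows, as.numeric))
    }
    prov <- .datablock_value(db, "SDDF_PROVENANCE")
    if (is.na(prov)) prov <- "generated"
    energy <- .datablock_value(db, "SDDF_ENERGY")
    unit <- .datablock_value(db, "SDDF_ENERGY_UNIT")
    if (is.na(unit)) unit <- "kcal/mol"
    if (is.na(energy)) {
      missing_energy <- c(missing_energy, k)
      confs[[k]] <- conformation(mol, coords, confid, prov)
    } else {
      unit <- ifelse(grepl("hartree", unit, ignore.case = TRUE),
                     "hartree", "kcal/mol")
      confs[[k]] <- conformation(mol, coords, confid, prov,
                                 energy = as.numeric(energy),
                                 energy_unit = unit)
    }
  }
  if (labeled) {
    if (length(missing_energy) > 0) {
      stop("records missing SDDF_ENERGY tag: ",
           paste(missing_energy, collapse = ", "))
    }
    labeled_dataset(confs)
  } else confs
}

#' Write a CSV manifest of a dataset
#'
#' Companion table with one row per conformation: molecule_id, conf_id,
#' provenance, energy_kcal_mol, sdf_path.
#'
#' @param ds A `cf_dataset`.
#' @param csv_path Output CSV path.
#' @param sdf_path The SDF file the rows refer to.
#' @return `csv_path`, invisibly.
#' @export
write_manifest <- function(ds, csv_path, sdf_path) {
  df <- data.frame(
    molecule_id = vapply(ds$entries, function(e) e$molecule$id, ""),
    conf_id = vapply(ds$entries, function(e) e$conf_id, ""),
    provenance = vapply(ds$entries, function(e) e$provenance, ""),
    energy_kcal_mol = dataset_energies(ds),
    sdf_path = sdf_path,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, csv_path, row.names = FALSE)
  invisible(csv_path)
}
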