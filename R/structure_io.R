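#' Read a predicted structure model from PDB or mmCIF
#'
#' Parses coordinates via bio3d, drops hydrogens, resolves alternate
#' locations to the highest-occupancy conformer, and carries the
#' B-factor column as per-residue pLDDT (the convention of structure
#' predictors). Residue numbering follows the file's author numbering.
#'
#' @param path Path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return An object of class `structure_model`: `atoms` (data frame with
#'   `chain`, `resno`, `resid`, `elety`, `x`, `y`, `z`, `b`), `residues`
#'   (one row per residue with `chain`, `resno`, `resid`, `plddt` and a
#'   global `index` over the concatenated chain order), and `chains`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "cif"
              else "pdb"
  }
  raw <- if (format == "pdb") {
    suppressWarnings(bio3d::read.pdb(path))
  } else {
    suppressWarnings(bio3d::read.cif(path))
  }
  at <- raw$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  # drop hydrogens
  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy)))
    elesy <- substr(gsub("^[0-9]", "", at$elety), 1, 1)
  at <- at[!(toupper(trimws(elesy)) %in% c("H", "D")), , drop = FALSE]
  # altloc: keep the highest-occupancy conformer per atom
  occ <- if (is.null(at$o)) rep(1, nrow(at)) else ifelse(is.na(at$o), 1, at$o)
  at <- at[order(at$chain, at$resno, at$elety, -occ), , drop = FALSE]
  at <- at[!duplicated(at[, c("chain", "resno", "elety")]), , drop = FALSE]
  if (anyNA(at$x) || anyNA(at$y) || anyNA(at$z) ||
      any(!is.finite(at$x + at$y + at$z)))
    stop("missing or non-finite coordinates in ", path)
  b <- if (is.null(at$b)) rep(NA_real_, nrow(at)) else at$b
  if (any(!is.na(b) & (b < 0 | b > 100)))
    stop("B-factor/pLDDT values outside [0, 100]")
  atoms <- data.frame(chain = as.character(at$chain), resno = at$resno,
                      resid = at$resid, elety = at$elety,
                      x = at$x, y = at$y, z = at$z, b = b,
                      stringsAsFactors = FALSE)
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)),
                       atoms$resno), , drop = FALSE]
  key <- !duplicated(paste(atoms$chain, atoms$resno))
  residues <- data.frame(chain = atoms$chain[key], resno = atoms$resno[key],
                         resid = atoms$resid[key], plddt = atoms$b[key],
                         stringsAsFactors = FALSE)
  for (ch in unique(residues$chain)) {
    r <- residues$resno[residues$chain == ch]
    if (is.unsorted(r, strictly = TRUE))
      stop("residue numbers not strictly increasing in chain ", ch)
  }
  residues$index <- seq_len(nrow(residues))
  structure(list(atoms = atoms, residues = residues,
                 chains = unique(residues$chain)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model> ", length(x$chains), " chain(s) [",
      paste(x$chains, collapse = ","), "], ", nrow(x$residues),
      " residues, ", nrow(x$atoms), " heavy atoms\n", sep = "")
  invisible(x)
}

#' Read a predicted aligned error (PAE) matrix
#'
#' Understands both common JSON dialects: the AlphaFold-DB form (key
#' `predicted_aligned_error`, possibly wrapped in a one-element array) and
#' the ColabFold form (key `pae`). The matrix is indexed over the
#' concatenated residue order of all chains of the accompanying
#' structure.
#'
#' @param path Path to the PAE JSON file.
#' @param structure The matching `structure_model`; used to validate the
#'   dimension and to attach the chain/residue index map.
#' @return A numeric matrix of class `pae_matrix` (entries in Angstrom)
#'   with attribute `residue_map` (the structure's residue table).
#' @export
read_pae <- function(path, structure = NULL) {
  js <- jsonlite::fromJSON(path)
  if (is.data.frame(js)) js <- as.list(js[1, , drop = FALSE])
  m <- NULL
  if (!is.null(js$pae)) m <- js$pae
  if (is.null(m) && !is.null(js$predicted_aligned_error))
    m <- js$predicted_aligned_error
  if (is.null(m) && is.list(js) && length(js) >= 1 &&
      !is.null(js[[1]]$predicted_aligned_error))
    m <- js[[1]]$predicted_aligned_error
  if (is.null(m)) stop("no PAE matrix found in ", path)
  if (is.list(m) && !is.matrix(m)) m <- do.call(rbind, m)
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop("PAE matrix is not square")
  if (any(m < 0)) stop("PAE entries must be non-negative")
  if (!is.null(structure)) {
    stopifnot(inherits(structure, "structure_model"))
    if (nrow(m) != nrow(structure$residues))
      stop("PAE dimension (", nrow(m), ") does not match residue count (",
           nrow(structure$residues), ")")
    attr(m, "residue_map") <- structure$residues
  }
  class(m) <- c("pae_matrix", class(m))
  m
}

# ---- writers (used by the synthetic generator) -----------------------------

#' Write a structure model as PDB or minimal mmCIF
#'
#' Emits the subset of either format that structure predictors populate:
#' ATOM records with chain, residue, coordinates, occupancy and a
#' B-factor column holding per-residue pLDDT.
#'
#' @param model A `structure_model` (or the list produced by the
#'   generator before reading back).
#' @param path Output path.
#' @param format `"pdb"` or `"cif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("pdb", "cif")) {
  format <- match.arg(format)
  at <- model$atoms
  elem <- substr(at$elety, 1, 1)
  if (format == "pdb") {
    lines <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)),
      ifelse(nchar(at$elety) < 4, paste0(" ", at$elety), at$elety),
      at$resid, at$chain, at$resno, at$x, at$y, at$z, 1, at$b, elem)
    writeLines(c(lines, "END"), path)
  } else {
    hdr <- c("data_synthetic", "#", "loop_",
             "_atom_site.group_PDB", "_atom_site.id",
             "_atom_site.type_symbol", "_atom_site.label_atom_id",
             "_atom_site.label_alt_id", "_atom_site.label_comp_id",
             "_atom_site.label_asym_id", "_atom_site.label_entity_id",
             "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
             "_atom_site.Cartn_x", "_atom_site.Cartn_y",
             "_atom_site.Cartn_z", "_atom_site.occupancy",
             "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
             "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
             "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
             "_atom_site.pdbx_PDB_model_num")
    rows <- sprintf(
      "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
      seq_len(nrow(at)), elem, at$elety, at$resid, at$chain, at$resno,
      at$x, at$y, at$z, 1, at$b, at$resno, at$resid, at$chain, at$elety)
    writeLines(c(hdr, rows, "#"), path)
  }
  invisible(path)
}

#' Write a PAE matrix in either predictor JSON dialect
#'
#' @param pae Square numeric matrix.
#' @param path Output path.
#' @param dialect `"colabfold"` (key `pae`, integer-valued entries per
#'   that tool's convention) or `"afdb"` (key `predicted_aligned_error`
#'   inside a one-element array, float entries).
#' @return `path`, invisibly.
#' @export
write_pae <- function(pae, path, dialect = c("colabfold", "afdb")) {
  dialect <- match.arg(dialect)
  m <- unclass(pae)
  attr(m, "residue_map") <- NULL
  if (dialect == "colabfold") {
    payload <- list(pae = round(m))
    jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  } else {
    payload <- list(list(predicted_aligned_error = m,
                         max_predicted_aligned_error = max(m)))
    jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}
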