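#' Structural ensemble container
#'
#' A `flex_ensemble` holds M models of the same A atoms: an atom identity
#' table plus an `M x A x 3` coordinate array in Angstrom.  It is the object
#' that superposition and per-atom variance act on.  Every model carries the
#' same atoms in the same order.
#'
#' @param atoms data.frame with columns `chain` (character), `resno`
#'   (integer, author numbering), `icode` (character, `""` when absent),
#'   `resname` (3-letter code) and `atom` (PDB v3 atom name).
#' @param xyz numeric array of dimension `c(M, A, 3)`, all values finite.
#' @param source_id free-text provenance label (e.g. a PDB ID).
#'
#' @return An object of class `flex_ensemble` with elements `atoms`, `xyz`
#'   and `source_id`.
#' @seealso [read_ensemble()], [superpose_to_mean()], [atom_variance()]
#' @export
flex_ensemble <- function(atoms, xyz, source_id = "ensemble") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("chain", "resno", "icode", "resname", "atom")
  if (!all(req %in% names(atoms)))
    stop("`atoms` must have columns ", paste(req, collapse = ", "))
  if (length(dim(xyz)) != 3L || dim(xyz)[3] != 3L)
    stop("`xyz` must be an M x A x 3 array")
  if (dim(xyz)[2] != nrow(atoms))
    stop("second dimension of `xyz` (", dim(xyz)[2],
         ") must equal nrow(atoms) (", nrow(atoms), ")")
  if (!all(is.finite(xyz))) stop("all coordinates must be finite")
  if (any(!nzchar(atoms$atom))) stop("atom names must be non-empty")
  key <- atom_key(atoms)
  if (anyDuplicated(key))
    stop("duplicate atom identities within a model: ",
         paste(utils::head(key[duplicated(key)], 3), collapse = ", "))
  structure(list(atoms = atoms, xyz = xyz, source_id = source_id),
            class = "flex_ensemble")
}

#' @export
print.flex_ensemble <- function(x, ...) {
  d <- dim(x$xyz)
  cat("<flex_ensemble> ", x$source_id, ": ", d[1], " models x ", d[2],
      " atoms\n", sep = "")
  res <- unique(residue_key(x$atoms))
  cat("  ", length(res), " residues, chains: ",
      paste(unique(x$atoms$chain), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.flex_ensemble <- function(x) dim(x$xyz)

# composite key identifying one atom (chain/resno/icode/atom)
atom_key <- function(atoms)
  paste(atoms$chain, atoms$resno, atoms$icode, atoms$atom, sep = "|")

# composite key identifying one residue
residue_key <- function(atoms)
  paste(atoms$chain, atoms$resno, atoms$icode, sep = "|")

#' Number of models in an ensemble
#' @param x a `flex_ensemble`
#' @return integer model count
#' @export
n_models <- function(x) {
  stopifnot(inherits(x, "flex_ensemble"))
  dim(x$xyz)[1]
}

#' Per-atom scalar table (coordinate variance or B-factor)
#'
#' The common input of the ranking stage: one non-negative scalar per atom,
#' either a coordinate variance from a superposed ensemble or a
#' crystallographic B-factor, both in Angstrom^2.  Using one container for
#' both makes the ensemble and crystal analyses share a single code path.
#'
#' @param atoms atom identity data.frame (see [flex_ensemble()]).
#' @param value numeric vector of non-negative finite scalars, one per atom.
#' @param kind `"coordinate_variance"` or `"bfactor"`.
#' @param source_id provenance label.
#' @return data.frame of class `flex_atomtable` with the atom identity
#'   columns plus `value`; attributes `kind`, `units` (`"A^2"`) and
#'   `source_id`.
#' @export
flex_atomtable <- function(atoms, value,
                           kind = c("coordinate_variance", "bfactor"),
                           source_id = "table") {
  kind <- match.arg(kind)
  if (length(value) != nrow(atoms))
    stop("one value per atom required")
  if (any(!is.finite(value)) || any(value < 0))
    stop("values must be finite and non-negative")
  out <- cbind(atoms[c("chain", "resno", "icode", "resname", "atom")],
               value = as.numeric(value))
  rownames(out) <- NULL
  structure(out, kind = kind, units = "A^2", source_id = source_id,
            class = c("flex_atomtable", "data.frame"))
}

#' @export
print.flex_atomtable <- function(x, ...) {
  cat("<flex_atomtable> ", attr(x, "source_id"), ": ", nrow(x), " atoms, kind=",
      attr(x, "kind"), " [", attr(x, "units"), "]\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}
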