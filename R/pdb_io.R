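# PDB reading/writing (fixed-column v3 records, MODEL/ENDMDL multi-model
# dialect).  Record-level control is needed here: atoms are intersected
# across models, alternate locations are resolved by occupancy, hydrogens
# other than the amide H are dropped, and HETATM is accepted for MSE only.

# parse ATOM/HETATM lines of one model into a data.frame
parse_pdb_block <- function(lines) {
  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | rec == "HETATM"
  lines <- lines[keep]
  if (!length(lines)) return(NULL)
  fw <- function(a, b) trimws(substr(lines, a, b))
  df <- data.frame(
    record  = trimws(rec[keep]),
    atom    = fw(13, 16),
    altloc  = fw(17, 17),
    resname = fw(18, 20),
    chain   = substr(lines, 22, 22),
    resno   = suppressWarnings(as.integer(fw(23, 26))),
    icode   = fw(27, 27),
    x       = suppressWarnings(as.numeric(fw(31, 38))),
    y       = suppressWarnings(as.numeric(fw(39, 46))),
    z       = suppressWarnings(as.numeric(fw(47, 54))),
    occ     = suppressWarnings(as.numeric(fw(55, 60))),
    b       = suppressWarnings(as.numeric(fw(61, 66))),
    element = fw(77, 78),
    stringsAsFactors = FALSE
  )
  if (any(is.na(df$resno)) || any(is.na(df$x) | is.na(df$y) | is.na(df$z)))
    stop("malformed ATOM/HETATM record: unparseable residue number or coordinates")
  df$occ[is.na(df$occ)] <- 1
  # HETATM: only selenomethionine is a residue we analyse
  df <- df[df$record == "ATOM" | df$resname == "MSE", , drop = FALSE]
  # hydrogens: keep the amide proton (name H) only
  hyd <- df$element == "H" | (!nzchar(df$element) & grepl("^[0-9]*H", df$atom))
  df <- df[!hyd | df$atom == "H", , drop = FALSE]
  df$record <- NULL
  df$element <- NULL
  resolve_altlocs(df)
}

# highest occupancy wins; ties -> first encountered in file order
resolve_altlocs <- function(df) {
  if (all(df$altloc == "")) { df$altloc <- NULL; return(df) }
  key <- paste(df$chain, df$resno, df$icode, df$atom, sep = "|")
  ord <- order(factor(key, levels = unique(key)), -df$occ,
               seq_len(nrow(df)))
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(paste(df$chain, df$resno, df$icode, df$atom,
                             sep = "|")), , drop = FALSE]
  # restore file order of the surviving records
  df <- df[order(as.integer(rownames(df))), , drop = FALSE]
  df$altloc <- NULL
  rownames(df) <- NULL
  df
}

# split PDB lines into per-model blocks; a file without MODEL records is
# one block
split_models <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (!length(starts)) return(list(lines))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  mapply(function(s, e) lines[s:e], starts, ends, SIMPLIFY = FALSE)
}

#' Read a multi-model PDB file into an ensemble
#'
#' Parses a multi-model PDB file (NMR ensemble or MD snapshot stack written
#' as MODEL/ENDMDL blocks) into a [flex_ensemble()].  Only atoms present in
#' every model are retained, in first-model order; atoms missing from any
#' model are dropped with a warning (variance across models requires
#' presence in all).  Alternate locations are resolved to the
#' highest-occupancy conformer (ties go to the first in file order).
#' Hydrogens are dropped except the amide proton `H`; `HETATM` records are
#' ignored except selenomethionine (`MSE`).
#'
#' @param path path to a PDB file with at least two `MODEL` records.
#' @param model_limit optional cap on the number of models read.
#' @return a [flex_ensemble()].
#' @examples
#' tmpl <- build_backbone_template(5, "alpha_helix")
#' ens <- simulate_additive_ensemble(tmpl, sigma = 0.1, n_models = 4, seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(ens, f)
#' read_ensemble(f)
#' @export
read_ensemble <- function(path, model_limit = NULL) {
  lines <- readLines(path, warn = FALSE)
  blocks <- split_models(lines)
  models <- Filter(Negate(is.null), lapply(blocks, parse_pdb_block))
  if (length(models) < 2L)
    stop("ensemble requires >= 2 models; file has ", length(models))
  if (!is.null(model_limit) && model_limit < length(models)) {
    if (model_limit < 2L) stop("model_limit must be >= 2")
    models <- models[seq_len(model_limit)]
  }
  keys <- lapply(models, function(m)
    paste(m$chain, m$resno, m$icode, m$atom, sep = "|"))
  for (i in seq_along(models)) {
    if (anyDuplicated(keys[[i]]))
      stop("model ", i, " contains colliding atom identities")
  }
  common <- Reduce(intersect, keys)
  dropped <- setdiff(keys[[1]], common)
  if (length(dropped))
    warning(length(dropped), " atom(s) absent from some model(s) dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  if (length(common) < 1L) stop("no atoms common to all models")
  atoms1 <- models[[1]][match(common, keys[[1]]), , drop = FALSE]
  M <- length(models); A <- length(common)
  xyz <- array(NA_real_, c(M, A, 3))
  for (i in seq_along(models)) {
    idx <- match(common, keys[[i]])
    xyz[i, , 1] <- models[[i]]$x[idx]
    xyz[i, , 2] <- models[[i]]$y[idx]
    xyz[i, , 3] <- models[[i]]$z[idx]
  }
  atoms <- atoms1[c("chain", "resno", "icode", "resname", "atom")]
  rownames(atoms) <- NULL
  flex_ensemble(atoms, xyz,
                source_id = sub("\\.pdb$", "", basename(path),
                                ignore.case = TRUE))
}

#' Extract crystallographic B-factors from a PDB file
#'
#' Reads the temperature-factor column (columns 61-66) of one model of a
#' PDB file into a [flex_atomtable()] of kind `"bfactor"`.  Altloc and
#' hydrogen handling are as in [read_ensemble()].
#'
#' @param path path to a PDB file with ATOM/HETATM records.
#' @param model_index which MODEL block to read (default 1; ignored for
#'   single-model files).
#' @param chain optional chain identifier; default keeps all chains.
#' @return a [flex_atomtable()] with one B-factor per retained atom.
#' @export
read_bfactors <- function(path, model_index = 1, chain = NULL) {
  lines <- readLines(path, warn = FALSE)
  blocks <- split_models(lines)
  if (model_index > length(blocks))
    stop("file has only ", length(blocks), " model(s)")
  df <- parse_pdb_block(blocks[[model_index]])
  if (is.null(df) || !nrow(df)) stop("no ATOM records in model ", model_index)
  if (any(is.na(df$b)))
    stop("missing or unparseable temperature-factor field")
  if (!is.null(chain)) df <- df[df$chain == chain, , drop = FALSE]
  flex_atomtable(df[c("chain", "resno", "icode", "resname", "atom")],
                 df$b, kind = "bfactor",
                 source_id = sub("\\.pdb$", "", basename(path),
                                 ignore.case = TRUE))
}

#' Restrict an ensemble or atom table to a named backbone atom set
#'
#' Keeps only the atoms of the requested set.  Residues possessing every
#' atom of the set form complete ranking blocks downstream; incomplete
#' residues (e.g. proline in the extended set, which has no amide H) are
#' flagged via the `"complete_residues"` attribute and excluded from
#' ranking by [rank_within_residue()].
#'
#' @param x a [flex_ensemble()] or [flex_atomtable()].
#' @param atom_set `"backbone4"` (N, CA, C, O), `"extended"`
#'   (N, CA, C, O, CB, H) or `"all_heavy"` (every non-hydrogen atom).
#' @return object of the same class restricted to the set, with attribute
#'   `"complete_residues"` (residue keys having the full set) and
#'   `"atom_types"` (the set's atom names, for `all_heavy` `NULL`).
#' @export
select_atoms <- function(x, atom_set = c("backbone4", "extended", "all_heavy")) {
  atom_set <- match.arg(atom_set)
  types <- switch(atom_set,
                  backbone4 = c("N", "CA", "C", "O"),
                  extended  = c("N", "CA", "C", "O", "CB", "H"),
                  all_heavy = NULL)
  atoms <- if (inherits(x, "flex_ensemble")) x$atoms else x
  keep <- if (is.null(types)) atoms$atom != "H" else atoms$atom %in% types
  sub_atoms <- atoms[keep, , drop = FALSE]
  complete <- if (is.null(types)) unique(residue_key(sub_atoms)) else {
    tab <- table(residue_key(sub_atoms), factor(sub_atoms$atom, levels = types))
    rownames(tab)[apply(tab == 1, 1, all)]
  }
  out <- if (inherits(x, "flex_ensemble")) {
    e <- flex_ensemble(sub_atoms, x$xyz[, keep, , drop = FALSE], x$source_id)
    e
  } else {
    flex_atomtable(sub_atoms, x$value[keep], kind = attr(x, "kind"),
                   source_id = attr(x, "source_id"))
  }
  attr(out, "complete_residues") <- complete
  attr(out, "atom_types") <- types
  out
}

#' Map selenomethionine to methionine
#'
#' Relabels `MSE` residues as `MET` and their `SE` atom as `SD`, so
#' crystallographic constructs phased with selenomethionine line up with
#' their NMR counterparts.  A no-op when no MSE is present.
#'
#' @param x a [flex_ensemble()] or [flex_atomtable()].
#' @param verbose message the number of residues mapped (default TRUE).
#' @return object of the same class with residues relabeled.
#' @export
map_modified_residues <- function(x, verbose = TRUE) {
  atoms <- if (inherits(x, "flex_ensemble")) x$atoms else x
  is_mse <- atoms$resname == "MSE"
  n_res <- length(unique(residue_key(atoms)[is_mse]))
  if (n_res > 0) {
    atoms$atom[is_mse & atoms$atom == "SE"] <- "SD"
    atoms$resname[is_mse] <- "MET"
    if (verbose) message("mapped ", n_res, " MSE residue(s) to MET")
  }
  if (inherits(x, "flex_ensemble")) {
    flex_ensemble(atoms, x$xyz, x$source_id)
  } else {
    flex_atomtable(atoms[c("chain", "resno", "icode", "resname", "atom")],
                   x$value, kind = attr(x, "kind"),
                   source_id = attr(x, "source_id"))
  }
}

#' Write an ensemble (or template) as a PDB file
#'
#' Writes fixed-column PDB v3 records; multi-model ensembles get
#' MODEL/ENDMDL blocks.  Coordinates are written at the format's 0.001 A
#' precision.
#'
#' @param x a [flex_ensemble()] or [flex_template()].
#' @param path output file path.
#' @param bfactors optional numeric vector (one per atom) written to the
#'   temperature-factor column; default 0.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path, bfactors = NULL) {
  if (inherits(x, "flex_template"))
    x <- flex_ensemble(x$atoms, array(x$xyz, c(1, nrow(x$atoms), 3)),
                       "template")
  stopifnot(inherits(x, "flex_ensemble"))
  a <- x$atoms
  M <- dim(x$xyz)[1]
  b <- if (is.null(bfactors)) rep(0, nrow(a)) else bfactors
  stopifnot(length(b) == nrow(a))
  elem <- ifelse(a$atom == "H", "H", substr(a$atom, 1, 1))
  name4 <- ifelse(nchar(a$atom) < 4, sprintf(" %-3s", a$atom), a$atom)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(M)) {
    if (M > 1) writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(sprintf(
      "ATOM  %5d %4s %-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)), name4, a$resname, a$chain, a$resno, a$icode,
      x$xyz[m, , 1], x$xyz[m, , 2], x$xyz[m, , 3], 1, b, elem), con)
    if (M > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
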