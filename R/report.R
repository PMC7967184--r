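# Orchestration: run the full analysis over a declared set of inputs and
# write deterministic TSV/JSON reports with provenance.

#' Run the full flexibility analysis over one or many structures
#'
#' For each declared input, runs the appropriate pipeline path —
#' ensembles are superposed and analysed via coordinate variances,
#' crystal structures via their B-factors — then aggregates average
#' ranks and significant pairwise comparisons across all inputs and
#' writes the report files.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{inputs}{data.frame with columns `path` and `kind`
#'       (`"nmr_ensemble"`, `"md_ensemble"` or `"crystal_bfactor"`).}
#'     \item{scheme}{superposition scheme (default `"lsq"`).}
#'     \item{atom_set}{`"backbone4"` (default) or `"extended"`.}
#'     \item{alpha}{nominal level (default 0.05).}
#'     \item{outdir}{output directory (created if needed).}
#'   }
#' @return invisibly, a list with `fits` (per-structure [flex_rank()]
#'   fits), `cohort` ([flex_cohort()] over the successful fits), `files`
#'   (paths written) and `failures` (named error messages).  Fails with
#'   an error only if every input fails.
#' @export
run_analysis <- function(config) {
  inputs <- config$inputs
  if (is.null(inputs) || !nrow(inputs)) stop("config$inputs is empty")
  stopifnot(all(c("path", "kind") %in% names(inputs)))
  scheme <- config$scheme %||% "lsq"
  atom_set <- config$atom_set %||% "backbone4"
  alpha <- config$alpha %||% 0.05
  outdir <- config$outdir %||% stop("config$outdir is required")
  atom_types <- switch(atom_set,
                       backbone4 = c("N", "CA", "C", "O"),
                       extended  = c("N", "CA", "C", "O", "CB", "H"),
                       stop("unknown atom_set: ", atom_set))
  fits <- list(); failures <- character()
  for (i in seq_len(nrow(inputs))) {
    path <- inputs$path[i]; kind <- inputs$kind[i]
    fit <- tryCatch({
      if (kind %in% c("nmr_ensemble", "md_ensemble")) {
        ens <- map_modified_residues(read_ensemble(path), verbose = FALSE)
        flex_rank(ens, atom_types = atom_types, superpose = scheme,
                  alpha = alpha)
      } else if (kind == "crystal_bfactor") {
        tab <- map_modified_residues(read_bfactors(path), verbose = FALSE)
        flex_rank(tab, atom_types = atom_types, alpha = alpha)
      } else stop("unknown input kind: ", kind)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      warning("input ", path, " failed: ", conditionMessage(fit))
      failures[path] <- conditionMessage(fit)
    } else fits[[fit$structure_id]] <- fit
  }
  if (!length(fits)) stop("all inputs failed")
  cohort <- if (length(fits) >= 1) flex_cohort(fits)
  files <- write_report(list(fits = fits, cohort = cohort,
                             config = config), outdir)
  invisible(list(fits = fits, cohort = cohort, files = files,
                 failures = failures))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

num6 <- function(x) {
  out <- sprintf("%.6g", x)
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], num6)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  path
}

#' Write deterministic analysis reports
#'
#' Emits, per structure: a per-atom value TSV, a per-residue rank TSV, a
#' per-residue F-score TSV (with category column) and a JSON Friedman
#' report; across structures: the average-rank table and the significant
#' directed-pair count table; plus a provenance JSON recording the
#' configuration and the post-hoc rule used.  Output is byte-deterministic
#' for identical results (sorted keys, `%.6g` floats).
#'
#' @param results list with `fits`, optional `cohort` and `config`
#'   (as assembled by [run_analysis()]).
#' @param outdir output directory, created if needed.
#' @return character vector of files written, invisibly.
#' @export
write_report <- function(results, outdir) {
  if (!dir.exists(outdir))
    if (!dir.create(outdir, recursive = TRUE))
      stop("cannot create output directory: ", outdir)
  files <- character()
  emit <- function(p) { files[[length(files) + 1]] <<- p; p }
  for (fit in results$fits) {
    id <- gsub("[^A-Za-z0-9._-]", "_", fit$structure_id)
    emit(write_tsv(as.data.frame(fit$values),
                   file.path(outdir, paste0(id, "_values.tsv"))))
    rk <- data.frame(residue = rownames(fit$ranks$ranks),
                     fit$ranks$ranks, check.names = FALSE)
    emit(write_tsv(rk, file.path(outdir, paste0(id, "_ranks.tsv"))))
    if (!is.null(fit$fscores))
      emit(write_tsv(fit$fscores,
                     file.path(outdir, paste0(id, "_fscores.tsv"))))
    fr <- fit$friedman
    rep_json <- list(structure_id = fr$structure_id, kind = fit$kind,
                     scheme = fit$scheme, statistic = fr$statistic,
                     dof = fr$dof, p_value = fr$p_value,
                     n_blocks = fr$n_blocks,
                     mean_ranks = as.list(fr$mean_ranks),
                     se = fr$se, threshold = fr$threshold,
                     degenerate = fr$degenerate,
                     comparisons = fr$comparisons)
    p <- file.path(outdir, paste0(id, "_friedman.json"))
    jsonlite::write_json(rep_json, p, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE)
    emit(p)
  }
  if (!is.null(results$cohort)) {
    co <- results$cohort
    ar <- data.frame(structure_id = rownames(co$average_ranks),
                     co$average_ranks, check.names = FALSE)
    emit(write_tsv(ar, file.path(outdir, "average_ranks.tsv")))
    emit(write_tsv(co$counts, file.path(outdir, "significance_counts.tsv")))
  }
  prov <- list(
    package = "flexrank",
    version = as.character(utils::packageVersion("flexrank")),
    config = results$config[setdiff(names(results$config), "inputs")],
    inputs = results$config$inputs,
    posthoc_rule = "mean ranks significantly different if |difference| > 3 * sqrt(k*(k+1)/(6*n))",
    variance = "trace of positional covariance, sample variance divisor M-1"
  )
  p <- file.path(outdir, "provenance.json")
  jsonlite::write_json(prov, p, auto_unbox = TRUE, pretty = TRUE)
  emit(p)
  invisible(unlist(files))
}

#' Write a molecular-viewer attribute file of F-score colors
#'
#' Emits a TSV of residue identifiers, F values and category colors that
#' can be loaded as a per-residue coloring attribute in molecular
#' viewers.
#'
#' @param fit a [flex_rank()] fit with F-scores.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fscore_colors <- function(fit, path) {
  stopifnot(inherits(fit, "flexrank"), !is.null(fit$fscores))
  write_tsv(fit$fscores[c("chain", "resno", "icode", "F", "category")], path)
  invisible(path)
}
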