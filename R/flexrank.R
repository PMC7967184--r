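#' Fit the rank-based backbone flexibility analysis to one structure
#'
#' The package's central fitting function.  Given a multi-model ensemble
#' it (1) superposes the models (least-squares to the mean,
#' variance-weighted, or restricted to a distance-variance core),
#' (2) computes per-atom coordinate variances, (3) ranks the backbone
#' atom types within each residue, (4) fits the tie-corrected Friedman
#' mean-rank test with 3-standard-error post-hoc pairwise comparisons and
#' (5) computes per-residue carbonyl-oxygen F-scores.  Given a
#' crystallographic B-factor table it runs the identical ranking
#' machinery (steps 3-5) on the B-factors, so ensemble and crystal
#' analyses share one code path.
#'
#' @param x a [flex_ensemble()] (NMR ensemble or MD snapshot stack) or a
#'   [flex_atomtable()] (e.g. from [read_bfactors()]).
#' @param atom_types atom types ranked within each residue; default the
#'   four backbone heavy atoms `c("N", "CA", "C", "O")`.
#' @param superpose superposition scheme for ensembles: `"lsq"`
#'   (least-squares to the mean over all heavy atoms), `"weighted"`
#'   (variance-weighted), `"core"` (least-squares over a
#'   distance-variance core), or `"none"` (input already superposed).
#' @param alpha nominal level recorded with the Friedman report.
#' @param core_cutoff distance-SD cutoff passed to [select_core_atoms()]
#'   when `superpose = "core"`.
#' @param ... further arguments passed to the superposition routine.
#' @return object of class `flexrank`: a list with `call`,
#'   `structure_id`, `kind` (`"coordinate_variance"` or `"bfactor"`),
#'   `scheme`, `superposition` (a `flex_superposition` or NULL),
#'   `values` (per-atom [flex_atomtable()]), `ranks` (`flex_ranktab`),
#'   `friedman` (`flex_friedman`), `fscores` (per-residue data.frame).
#' @seealso [flex_cohort()] for aggregating fits across structures.
#' @examples
#' tmpl <- build_backbone_template(30, "alpha_helix")
#' ens <- simulate_rocking_ensemble(tmpl, rock_sigma_deg = 10, seed = 42)
#' fit <- flex_rank(ens)
#' fit
#' coef(fit)
#' @export
flex_rank <- function(x, atom_types = c("N", "CA", "C", "O"),
                      superpose = c("lsq", "weighted", "core", "none"),
                      alpha = 0.05, core_cutoff = 0.5, ...) {
  superpose <- match.arg(superpose)
  cl <- match.call()
  sup <- NULL
  if (inherits(x, "flex_ensemble")) {
    heavy <- which(x$atoms$atom != "H")
    sup <- switch(superpose,
      none = NULL,
      lsq = superpose_to_mean(x, fit_atoms = heavy, ...),
      weighted = weighted_superpose(x, fit_atoms = heavy, ...),
      core = {
        core <- select_core_atoms(x, distance_sd_cutoff = core_cutoff)
        superpose_to_mean(x, fit_atoms = core, ...)
      })
    values <- atom_variance(if (is.null(sup)) x else sup$ensemble)
  } else if (inherits(x, "flex_atomtable")) {
    values <- x
  } else {
    stop("`x` must be a flex_ensemble or a flex_atomtable")
  }
  ranks <- rank_within_residue(values, atom_types = atom_types)
  fr <- friedman_test(ranks, alpha = alpha)
  fs <- if (all(c("N", "C", "O") %in% atom_types))
    fscore_table(values) else NULL
  structure(list(call = cl, structure_id = attr(values, "source_id"),
                 kind = attr(values, "kind"),
                 scheme = if (is.null(sup)) "none" else superpose,
                 superposition = sup, values = values, ranks = ranks,
                 friedman = fr, fscores = fs),
            class = "flexrank")
}

#' @export
print.flexrank <- function(x, ...) {
  cat("Backbone flexibility rank analysis\n")
  cat("  structure: ", x$structure_id, "  (", x$kind,
      if (x$scheme != "none") paste0(", superposition: ", x$scheme), ")\n",
      sep = "")
  cat("  residues ranked: ", x$friedman$n_blocks,
      if (x$ranks$n_excluded)
        paste0("  (", x$ranks$n_excluded, " incomplete excluded)"),
      "\n", sep = "")
  print(x$friedman)
  invisible(x)
}

#' @describeIn flex_rank mean rank of each atom type (1 = least variable).
#' @param object a `flexrank` fit.
#' @export
coef.flexrank <- function(object, ...) object$friedman$mean_ranks

#' @export
summary.flexrank <- function(object, ...) {
  fs <- object$fscores
  cat_counts <- if (!is.null(fs))
    table(factor(fs$category,
                 levels = c("red", "white", "blue", "green", "undefined")))
  structure(list(fit = object, category_counts = cat_counts),
            class = "summary.flexrank")
}

#' @export
print.summary.flexrank <- function(x, ...) {
  print(x$fit)
  cmp <- x$fit$friedman$comparisons
  cat("\nPairwise mean-rank comparisons (threshold ",
      sprintf("%.3f", x$fit$friedman$threshold), " = 3 SE):\n", sep = "")
  print(cmp, digits = 3)
  if (!is.null(x$category_counts)) {
    cat("\nPer-residue F-score categories:\n")
    print(x$category_counts)
  }
  invisible(x)
}

#' @export
plot.flexrank <- function(x, ...) {
  mr <- x$friedman$mean_ranks
  se <- x$friedman$se
  bp <- graphics::barplot(mr, ylim = c(0, max(mr + 3 * se) * 1.1),
                          ylab = "mean within-residue rank",
                          main = x$structure_id, ...)
  graphics::arrows(bp, mr - 3 * se, bp, mr + 3 * se, angle = 90, code = 3,
                   length = 0.05)
  graphics::abline(h = (length(mr) + 1) / 2, lty = 2)
  invisible(x)
}

#' Aggregate flexibility fits across structures
#'
#' Collects per-structure [flex_rank()] fits into the two cross-structure
#' summaries: the distribution of per-structure average ranks by atom
#' type, and the count of structures in which each directed atom-type
#' pair differs significantly by the 3-SE rule.
#'
#' @param fits a list of `flexrank` fits (or `flex_friedman` reports).
#' @return object of class `flexrank_cohort` with `average_ranks`,
#'   `rank_summary`, `counts` and `n_structures`.
#' @export
flex_cohort <- function(fits) {
  agg <- aggregate_average_ranks(fits)
  counts <- aggregate_significance_counts(fits)
  structure(list(average_ranks = agg$average_ranks,
                 rank_summary = agg$summary, counts = counts,
                 n_structures = nrow(agg$average_ranks)),
            class = "flexrank_cohort")
}

#' @export
print.flexrank_cohort <- function(x, ...) {
  cat("Flexibility rank analysis across ", x$n_structures,
      " structures\n\n", sep = "")
  cat("Average rank by atom type (min / median / max across structures):\n")
  print(round(x$rank_summary, 2))
  cat("\nStructures with significantly lower variability for X than Y:\n")
  nz <- x$counts[x$counts$count > 0, , drop = FALSE]
  if (nrow(nz)) {
    for (i in seq_len(nrow(nz)))
      cat(sprintf("  %-2s < %-2s : %d\n", nz$lower[i], nz$higher[i],
                  nz$count[i]))
  } else cat("  none\n")
  invisible(x)
}

#' @export
plot.flexrank_cohort <- function(x, ...) {
  cnt <- x$counts
  lab <- paste(cnt$lower, "<", cnt$higher)
  graphics::barplot(cnt$count, names.arg = lab, las = 2,
                    ylab = "number of structures",
                    ylim = c(0, max(cnt$count, x$n_structures)), ...)
  graphics::abline(h = x$n_structures, lty = 2)
  invisible(x)
}
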