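# Statistical core: per-atom coordinate variance, within-residue ranking,
# the tie-corrected Friedman mean-rank test with a 3-standard-error
# post-hoc comparison rule, and the per-residue carbonyl-oxygen F-score.

#' Per-atom coordinate variance of a superposed ensemble
#'
#' For each atom, the trace of its positional covariance across models:
#' the sample variance (divisor M-1) of x plus y plus z about the atom's
#' mean position, in Angstrom^2.  The ensemble must already be superposed;
#' variances of an unsuperposed ensemble mostly measure global rigid-body
#' motion.
#'
#' @param x a [flex_ensemble()] (typically `$ensemble` of a
#'   [superpose_to_mean()] result) or a `flex_superposition`.
#' @return a [flex_atomtable()] of kind `"coordinate_variance"`.
#' @export
atom_variance <- function(x) {
  if (inherits(x, "flex_superposition")) x <- x$ensemble
  stopifnot(inherits(x, "flex_ensemble"))
  if (dim(x$xyz)[1] < 2) stop("variance requires >= 2 models")
  flex_atomtable(x$atoms, per_atom_variance(x$xyz),
                 kind = "coordinate_variance", source_id = x$source_id)
}

#' Rank atom types within each residue
#'
#' Builds the blocks-by-treatments rank table for the Friedman test: one
#' row (block) per residue having every requested atom type, one column
#' (treatment) per atom type, entries the ascending within-residue ranks
#' of the per-atom values (1 = least variable).  Ties receive mid-ranks,
#' so each row sums to k(k+1)/2 exactly.  Residues missing any type are
#' excluded and counted.
#'
#' @param values a [flex_atomtable()] (coordinate variances or B-factors).
#' @param atom_types ordered atom-type labels; default the four backbone
#'   heavy atoms `c("N", "CA", "C", "O")`.
#' @return list of class `flex_ranktab`: `structure_id`, `atom_types`,
#'   `ranks` (n x k matrix, rownames = residue keys), `values` (n x k raw
#'   values), `residues` (data.frame chain/resno/icode/resname),
#'   `n_excluded`.
#' @export
rank_within_residue <- function(values, atom_types = c("N", "CA", "C", "O")) {
  stopifnot(inherits(values, "flex_atomtable"))
  k <- length(atom_types)
  df <- values[values$atom %in% atom_types, , drop = FALSE]
  rkey <- residue_key(df)
  tab <- table(factor(rkey, levels = unique(rkey)),
               factor(df$atom, levels = atom_types))
  complete <- rownames(tab)[apply(tab == 1, 1, all)]
  n_excluded <- length(unique(rkey)) - length(complete)
  if (length(complete) < 2)
    stop("fewer than 2 residues carry all atom types (",
         paste(atom_types, collapse = ","), "); cannot build rank blocks")
  df <- df[rkey %in% complete, , drop = FALSE]
  vals <- matrix(NA_real_, length(complete), k,
                 dimnames = list(complete, atom_types))
  idx <- cbind(match(residue_key(df), complete), match(df$atom, atom_types))
  vals[idx] <- df$value
  ranks <- t(apply(vals, 1, rank))   # ties.method = "average" -> mid-ranks
  dimnames(ranks) <- dimnames(vals)
  first <- df[!duplicated(residue_key(df)), c("chain", "resno", "icode", "resname")]
  rownames(first) <- NULL
  structure(list(structure_id = attr(values, "source_id"),
                 atom_types = atom_types, ranks = ranks, values = vals,
                 residues = first, n_excluded = n_excluded),
            class = "flex_ranktab")
}

#' Friedman mean-rank test with three-standard-error post-hoc comparisons
#'
#' The non-parametric repeated-measures analog of ANOVA, applied to the
#' within-residue rank table: blocks are residues, treatments are atom
#' types.  The statistic is
#' `S = 12/(n k (k+1)) * sum_j R_j^2 - 3 n (k+1)` divided by the tie
#' correction `1 - sum(t^3 - t) / (n k (k^2 - 1))` over all within-block
#' tie groups, referred to a chi-square distribution with k-1 degrees of
#' freedom.  All pairs of atom types are then compared: two mean ranks are
#' declared significantly different when they differ by more than three
#' standard errors, `SE = sqrt(k (k+1) / (6 n))`.
#'
#' @param tab a `flex_ranktab` from [rank_within_residue()].
#' @param alpha nominal level recorded with the report (the pairwise rule
#'   is the fixed 3-SE criterion and does not depend on it).
#' @return list of class `flex_friedman`: `statistic`, `dof`, `p_value`,
#'   `mean_ranks`, `n_blocks`, `se`, `threshold` (3 * se), `comparisons`
#'   (data.frame `type_a`, `type_b`, `mean_rank_difference`, `threshold`,
#'   `significant`), `degenerate`, `alpha`, `structure_id`.
#' @export
friedman_test <- function(tab, alpha = 0.05) {
  stopifnot(inherits(tab, "flex_ranktab"))
  r <- tab$ranks
  n <- nrow(r); k <- ncol(r)
  if (n < 2 || k < 2) stop("need n >= 2 blocks and k >= 2 treatments")
  Rj <- colSums(r)
  S <- 12 * sum(Rj^2) / (n * k * (k + 1)) - 3 * n * (k + 1)
  # tie correction from the multiplicities of equal ranks within blocks
  tie_sum <- sum(apply(r, 1, function(row) {
    t <- table(row); sum(t^3 - t)
  }))
  C <- 1 - tie_sum / (n * k * (k^2 - 1))
  degenerate <- C <= 0
  statistic <- if (degenerate) 0 else S / C
  p <- if (degenerate) 1 else stats::pchisq(statistic, k - 1, lower.tail = FALSE)
  mean_ranks <- Rj / n
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(k, 2)
  comparisons <- data.frame(
    type_a = tab$atom_types[pairs[1, ]],
    type_b = tab$atom_types[pairs[2, ]],
    mean_rank_difference = mean_ranks[pairs[1, ]] - mean_ranks[pairs[2, ]],
    threshold = 3 * se,
    stringsAsFactors = FALSE
  )
  comparisons$significant <- abs(comparisons$mean_rank_difference) > 3 * se
  rownames(comparisons) <- NULL
  structure(list(statistic = statistic, dof = k - 1, p_value = p,
                 mean_ranks = stats::setNames(mean_ranks, tab$atom_types),
                 n_blocks = n, se = se, threshold = 3 * se,
                 comparisons = comparisons, degenerate = degenerate,
                 alpha = alpha, structure_id = tab$structure_id),
            class = "flex_friedman")
}

#' @export
print.flex_friedman <- function(x, ...) {
  cat("Friedman mean-rank test (", x$structure_id, "): chi-squared = ",
      format(x$statistic, digits = 5), ", df = ", x$dof, ", p = ",
      format.pval(x$p_value, digits = 3), "\n", sep = "")
  if (x$degenerate) cat("  [degenerate: all blocks fully tied]\n")
  cat("  mean ranks over ", x$n_blocks, " residues: ",
      paste(names(x$mean_ranks), sprintf("%.2f", x$mean_ranks),
            sep = "=", collapse = "  "), "\n", sep = "")
  sig <- x$comparisons[x$comparisons$significant, , drop = FALSE]
  if (nrow(sig)) {
    lab <- ifelse(sig$mean_rank_difference < 0,
                  paste(sig$type_a, "<", sig$type_b),
                  paste(sig$type_b, "<", sig$type_a))
    cat("  significant at 3 SE (", sprintf("%.3f", x$threshold), "): ",
        paste(lab, collapse = ", "), "\n", sep = "")
  } else cat("  no pair differs by more than 3 SE\n")
  invisible(x)
}

#' Per-residue carbonyl-oxygen F-score
#'
#' `F = (u(O) - u(N))^2 / (u(C) - u(N))^2`, where `u` is the coordinate
#' variance, uncertainty or B-factor of the residue's carbonyl oxygen,
#' amide nitrogen and carbonyl carbon.  F measures how anomalously
#' variable the carbonyl oxygen is relative to the amide-nitrogen
#' baseline.  Categories: `green` whenever `u(O) < u(N)` (the oxygen is
#' better defined than the nitrogen, overriding F); otherwise `red` if
#' F > 10, `blue` if F < 0.1, `white` in between; `undefined` when both
#' numerator and denominator vanish.  A zero denominator with positive
#' numerator gives F = Inf.
#'
#' @param u_N,u_C,u_O non-negative finite scalars or equal-length vectors.
#' @return data.frame with columns `F` and `category`.
#' @examples
#' fscore(1, 2, 4)   # F = 9, white
#' fscore(2, 3, 1)   # green: u(O) < u(N)
#' @export
fscore <- function(u_N, u_C, u_O) {
  stopifnot(length(u_N) == length(u_C), length(u_N) == length(u_O))
  if (any(!is.finite(c(u_N, u_C, u_O))) || any(c(u_N, u_C, u_O) < 0))
    stop("inputs must be finite and non-negative")
  num <- (u_O - u_N)^2
  den <- (u_C - u_N)^2
  F <- ifelse(den == 0, ifelse(num > 0, Inf, NaN), num / den)
  category <- ifelse(u_O < u_N, "green",
              ifelse(den == 0 & num == 0, "undefined",
              ifelse(F > 10, "red",
              ifelse(F < 0.1, "blue", "white"))))
  data.frame(F = F, category = category, stringsAsFactors = FALSE)
}

#' Per-residue F-score table from an atom table
#'
#' Applies [fscore()] to every residue of a [flex_atomtable()] that has
#' its N, C and O atoms.
#'
#' @param values a [flex_atomtable()].
#' @return data.frame with residue identity columns, `u_N`, `u_C`, `u_O`,
#'   `F` and `category`.
#' @export
fscore_table <- function(values) {
  stopifnot(inherits(values, "flex_atomtable"))
  df <- values[values$atom %in% c("N", "C", "O"), , drop = FALSE]
  rkey <- residue_key(df)
  tab <- table(factor(rkey, levels = unique(rkey)),
               factor(df$atom, levels = c("N", "C", "O")))
  complete <- rownames(tab)[apply(tab == 1, 1, all)]
  df <- df[rkey %in% complete, , drop = FALSE]
  pick <- function(a) df$value[df$atom == a][match(complete,
                                   residue_key(df[df$atom == a, ]))]
  uN <- pick("N"); uC <- pick("C"); uO <- pick("O")
  first <- df[!duplicated(residue_key(df)), c("chain", "resno", "icode", "resname")]
  rownames(first) <- NULL
  cbind(first, u_N = uN, u_C = uC, u_O = uO, fscore(uN, uC, uO))
}

#' Aggregate per-structure average ranks across structures
#'
#' For a set of per-structure Friedman reports, collects the mean rank of
#' each atom type by structure and summarises their distribution, the
#' cross-structure view of how atom types rank.
#'
#' @param reports list of `flex_friedman` objects (or of [flex_rank()]
#'   fits, whose reports are extracted).
#' @return list with `average_ranks` (structures x atom types matrix) and
#'   `summary` (min/median/max of each atom type's average rank).
#' @export
aggregate_average_ranks <- function(reports) {
  reports <- as_friedman_list(reports)
  types <- names(reports[[1]]$mean_ranks)
  m <- do.call(rbind, lapply(reports, function(r) r$mean_ranks[types]))
  rownames(m) <- vapply(reports, `[[`, character(1), "structure_id")
  s <- apply(m, 2, function(v)
    c(min = min(v), median = stats::median(v), max = max(v)))
  list(average_ranks = m, summary = s)
}

#' Count significant directed pairwise comparisons across structures
#'
#' For every directed atom-type pair X < Y, counts the structures in which
#' the pair is significant by the 3-SE rule and the mean rank of X is
#' below the mean rank of Y — i.e. in how many structures the measure of
#' coordinate variability is significantly lower for X than for Y.
#'
#' @inheritParams aggregate_average_ranks
#' @return data.frame with columns `lower`, `higher`, `count`,
#'   `n_structures`.
#' @export
aggregate_significance_counts <- function(reports) {
  reports <- as_friedman_list(reports)
  types <- names(reports[[1]]$mean_ranks)
  pairs <- expand.grid(lower = types, higher = types,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$lower != pairs$higher, , drop = FALSE]
  pairs$count <- vapply(seq_len(nrow(pairs)), function(i) {
    X <- pairs$lower[i]; Y <- pairs$higher[i]
    sum(vapply(reports, function(r) {
      cmp <- r$comparisons
      j <- (cmp$type_a == X & cmp$type_b == Y) |
           (cmp$type_a == Y & cmp$type_b == X)
      any(cmp$significant[j]) && r$mean_ranks[X] < r$mean_ranks[Y]
    }, logical(1)))
  }, numeric(1))
  pairs$n_structures <- length(reports)
  rownames(pairs) <- NULL
  pairs
}

as_friedman_list <- function(reports) {
  if (inherits(reports, "flex_friedman") || inherits(reports, "flexrank"))
    reports <- list(reports)
  reports <- lapply(reports, function(r) {
    if (inherits(r, "flexrank")) r$friedman else r
  })
  if (!length(reports) || !all(vapply(reports, inherits, logical(1),
                                      "flex_friedman")))
    stop("expected one or more flex_friedman reports or flexrank fits")
  reports
}
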