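# Rigid-body superposition: Kabsch least squares, iterative fit to the
# evolving mean structure, a variance-weighted variant, and a
# distance-variance greedy core selector.

#' Optimal rigid-body fit of one coordinate set onto another
#'
#' Computes the proper rotation and translation minimising the (optionally
#' weighted) sum of squared deviations between paired points — the
#' SVD-based Kabsch solution.  Reflections are corrected by flipping the
#' sign of the smallest singular vector.
#'
#' @param mobile,target `A x 3` numeric matrices of paired coordinates
#'   (A >= 3, non-collinear).
#' @param weights optional length-A non-negative weights, not all zero.
#' @return list of class `flex_transform` with `rotation` (3x3 orthonormal,
#'   det +1) and `translation` (length 3); the fit maps
#'   `mobile %*% t(rotation) + translation` onto `target`.
#' @export
kabsch_fit <- function(mobile, target, weights = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  stopifnot(ncol(mobile) == 3, ncol(target) == 3,
            nrow(mobile) == nrow(target), nrow(mobile) >= 3)
  A <- nrow(mobile)
  w <- if (is.null(weights)) rep(1, A) else as.numeric(weights)
  if (length(w) != A || any(w < 0) || sum(w) == 0)
    stop("weights must be non-negative with positive sum")
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  ct <- colSums(target * w)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(target, 2, ct)
  H <- crossprod(P * w, Q)              # 3x3 weighted covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("degenerate geometry: points are (near-)collinear, rotation underdetermined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  structure(list(rotation = R, translation = as.numeric(ct - R %*% cm)),
            class = "flex_transform")
}

# apply a flex_transform to an A x 3 matrix
apply_transform <- function(xyz, tf)
  sweep(xyz %*% t(tf$rotation), 2, tf$translation, `+`)

rmsd_to <- function(xyz, ref) sqrt(mean(rowSums((xyz - ref)^2)))

#' Iteratively superpose ensemble models onto their mean structure
#'
#' Alternates fitting every model onto the current mean structure
#' (via [kabsch_fit()] over `fit_atoms`) with recomputing the mean, until
#' the mean moves by less than `tol` or `max_iter` is reached.  This is
#' the unweighted least-squares baseline scheme.
#'
#' @param ensemble a [flex_ensemble()] with at least two models.
#' @param fit_atoms indices (or logical mask) of atoms used for fitting;
#'   default all atoms.  At least 3 required.
#' @param tol convergence tolerance on the largest mean-coordinate change,
#'   in Angstrom.
#' @param max_iter iteration cap; non-convergence returns the current
#'   state with a warning and `converged = FALSE`.
#' @param weights optional per-fit-atom weights (used by the weighted
#'   scheme; not normally set directly).
#' @return list of class `flex_superposition`: `ensemble` (transformed),
#'   `transforms`, `fit_atoms`, `iterations`, `per_model_rmsd` (RMSD of
#'   each model's fit atoms to the mean), `converged`.
#' @export
superpose_to_mean <- function(ensemble, fit_atoms = NULL, tol = 1e-6,
                              max_iter = 100, weights = NULL) {
  stopifnot(inherits(ensemble, "flex_ensemble"))
  d <- dim(ensemble$xyz)
  M <- d[1]; A <- d[2]
  if (M < 2) stop("superposition requires >= 2 models")
  fit <- normalize_fit_atoms(fit_atoms, A)
  xyz <- ensemble$xyz
  mean_ref <- xyz[1, , ]
  transforms <- vector("list", M)
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    for (m in seq_len(M)) {
      tf <- kabsch_fit(xyz[m, fit, ], mean_ref[fit, ], weights = weights)
      xyz[m, , ] <- apply_transform(xyz[m, , ], tf)
      transforms[[m]] <- tf
    }
    new_mean <- colMeans(array(xyz, c(M, A * 3)))
    new_mean <- matrix(new_mean, A, 3)
    delta <- max(abs(new_mean - mean_ref))
    mean_ref <- new_mean
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("superposition did not converge in ", max_iter, " iterations")
  out <- ensemble
  out$xyz <- xyz
  per_model_rmsd <- vapply(seq_len(M), function(m)
    rmsd_to(xyz[m, fit, , drop = TRUE], mean_ref[fit, ]), numeric(1))
  structure(list(ensemble = out, transforms = transforms,
                 fit_atoms = fit, iterations = iterations,
                 per_model_rmsd = per_model_rmsd, converged = converged,
                 scheme = if (is.null(weights)) "lsq" else "weighted"),
            class = "flex_superposition")
}

normalize_fit_atoms <- function(fit_atoms, A) {
  fit <- if (is.null(fit_atoms)) seq_len(A)
         else if (is.logical(fit_atoms)) which(fit_atoms)
         else as.integer(fit_atoms)
  if (length(fit) < 3) stop("need at least 3 fit atoms")
  if (any(fit < 1 | fit > A)) stop("fit_atoms out of range")
  fit
}

#' Variance-weighted iterative superposition
#'
#' A simplified variance-weighted analog of maximum-likelihood ensemble
#' superposition: models are iteratively fit to the mean with per-atom
#' weights `1 / (v_i + eps)`, where `v_i` is the current per-atom
#' coordinate variance, so poorly converged atoms stop dominating the fit.
#' With equal variances it reduces to [superpose_to_mean()].
#'
#' @inheritParams superpose_to_mean
#' @param eps variance regulariser in Angstrom^2 preventing division by
#'   zero for perfectly converged atoms.
#' @return a `flex_superposition` (see [superpose_to_mean()]).
#' @export
weighted_superpose <- function(ensemble, fit_atoms = NULL, tol = 1e-6,
                               max_iter = 100, eps = 1e-6) {
  stopifnot(inherits(ensemble, "flex_ensemble"))
  d <- dim(ensemble$xyz)
  fit <- normalize_fit_atoms(fit_atoms, d[2])
  cur <- ensemble
  w <- rep(1, length(fit))
  prev_mean <- NULL
  res <- NULL
  for (outer in seq_len(max_iter)) {
    res <- superpose_to_mean(cur, fit_atoms = fit, tol = tol,
                             max_iter = max_iter, weights = w)
    cur <- res$ensemble
    v <- per_atom_variance(cur$xyz)
    w <- 1 / (v[fit] + eps)
    mean_now <- apply(cur$xyz, c(2, 3), mean)
    if (!is.null(prev_mean) && max(abs(mean_now - prev_mean)) < tol) break
    prev_mean <- mean_now
  }
  res$scheme <- "weighted"
  res
}

# trace of the per-atom positional covariance (sample variance, divisor M-1)
per_atom_variance <- function(xyz) {
  M <- dim(xyz)[1]
  v <- numeric(dim(xyz)[2])
  for (k in 1:3) {
    x <- xyz[, , k]
    mu <- colMeans(x)
    v <- v + (colSums(x^2) - M * mu^2) / (M - 1)
  }
  pmax(v, 0)
}

#' Select a superposition-independent core atom set
#'
#' Computes the `A x A` matrix of standard deviations of interatomic
#' distances across models (invariant under any per-model rigid
#' transform), then greedily grows a core: seed with the atom pair of
#' lowest distance SD, repeatedly add the atom whose maximum distance SD
#' to current core members is smallest, and stop when that value exceeds
#' `distance_sd_cutoff`.  A simplified analog of dendrogram-based core
#' identification methods.
#'
#' @param ensemble a [flex_ensemble()].
#' @param distance_sd_cutoff largest admissible distance SD (Angstrom) of
#'   a new core member to the existing core.
#' @param min_fraction smallest acceptable core size as a fraction of A;
#'   a smaller core raises an error suggesting a larger cutoff.
#' @return integer vector of core atom indices (sorted).
#' @export
select_core_atoms <- function(ensemble, distance_sd_cutoff = 0.5,
                              min_fraction = 0.2) {
  stopifnot(inherits(ensemble, "flex_ensemble"))
  xyz <- ensemble$xyz
  M <- dim(xyz)[1]; A <- dim(xyz)[2]
  if (M < 2) stop("core selection requires >= 2 models")
  s1 <- matrix(0, A, A); s2 <- matrix(0, A, A)
  for (m in seq_len(M)) {
    dm <- as.matrix(stats::dist(xyz[m, , ]))
    s1 <- s1 + dm
    s2 <- s2 + dm^2
  }
  dsd <- sqrt(pmax(s2 / (M - 1) - s1^2 / (M * (M - 1)), 0))
  diag(dsd) <- Inf
  seed <- which(dsd == min(dsd), arr.ind = TRUE)[1, ]
  core <- sort(unique(as.integer(seed)))
  diag(dsd) <- 0
  candidates <- setdiff(seq_len(A), core)
  # maximum distance SD of each candidate to current core members
  maxsd <- apply(dsd[candidates, core, drop = FALSE], 1, max)
  while (length(candidates)) {
    i <- which.min(maxsd)
    if (maxsd[i] > distance_sd_cutoff) break
    new <- candidates[i]
    core <- c(core, new)
    candidates <- candidates[-i]
    maxsd <- maxsd[-i]
    if (length(candidates))
      maxsd <- pmax(maxsd, dsd[candidates, new])
  }
  if (length(core) < min_fraction * A)
    stop("core too small (", length(core), " of ", A,
         " atoms); consider increasing distance_sd_cutoff")
  sort(core)
}

#' @export
print.flex_superposition <- function(x, ...) {
  cat("<flex_superposition> scheme=", x$scheme, ", ", x$iterations,
      " iteration(s), ", if (x$converged) "converged" else "NOT converged",
      "\n  per-model RMSD to mean (A): ",
      paste(sprintf("%.3f", utils::head(x$per_model_rmsd, 8)), collapse = " "),
      if (length(x$per_model_rmsd) > 8) " ..." else "", "\n", sep = "")
  invisible(x)
}
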