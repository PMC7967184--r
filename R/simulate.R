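# Synthetic data: an ideal-geometry backbone builder plus generators for
# additive-noise ensembles, peptide-plane rocking ensembles, and null
# B-factor tables.  Everything is seeded and reproducible, and simulated
# models receive random rigid transforms so the superposition stage is
# exercised by every end-to-end test.

# ideal internal coordinates (Engh-Huber-like); lengths in A, angles deg
.geom <- list(
  b_N_CA = 1.458, b_CA_C = 1.525, b_C_O = 1.231, b_C_N = 1.329,
  b_N_H = 1.010, b_CA_CB = 1.521,
  a_N_CA_C = 111.2, a_CA_C_N = 116.2, a_C_N_CA = 121.7,
  a_CA_C_O = 120.8, a_C_N_H = 119.15, a_C_CA_CB = 110.1,
  omega = 180
)

deg2rad <- function(x) x * pi / 180

vcross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

vunit <- function(v) v / sqrt(sum(v^2))

# natural-extension placement: new atom D bonded to c, with bond length,
# angle b-c-D and torsion a-b-c-D
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- deg2rad(angle_deg); tor <- deg2rad(torsion_deg)
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + cbind(bc, m, n) %*% d2
}

#' Build an ideal-geometry backbone template
#'
#' Constructs an N/CA/C/O backbone chain (optionally with CB and the amide
#' proton H) from ideal internal coordinates: N-CA 1.458 A, CA-C 1.525 A,
#' C-O 1.231 A, C-N 1.329 A, standard bond angles and a planar trans
#' peptide bond (omega = 180 deg).  Deterministic.
#'
#' @param n_residues chain length (>= 2).
#' @param conformation `"extended"` (beta-strand phi/psi -139/135) or
#'   `"alpha_helix"` (-57/-47).
#' @param h include the backbone amide proton H (residues 2..n).
#' @param cb include CB atoms.
#' @param chain chain identifier for the atom table.
#' @param residue_names recycled vector of 3-letter residue names.
#' @return list of class `flex_template`: `atoms` (identity table), `xyz`
#'   (`A x 3` matrix), `n_residues`, `geometry` (the internal-coordinate
#'   set used).
#' @export
build_backbone_template <- function(n_residues,
                                    conformation = c("extended", "alpha_helix"),
                                    h = TRUE, cb = FALSE, chain = "A",
                                    residue_names = "ALA") {
  conformation <- match.arg(conformation)
  if (n_residues < 2) stop("need at least 2 residues")
  pp <- switch(conformation,
               extended    = c(phi = -139, psi = 135),
               alpha_helix = c(phi = -57, psi = -47))
  g <- .geom
  n <- n_residues
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_N_CA, 0, 0)
  ang <- deg2rad(g$a_N_CA_C)
  C[1, ] <- CA[1, ] + g$b_CA_C * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    # next amide N via psi, defines this residue's peptide plane
    Nn <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_C_N, g$a_CA_C_N, pp["psi"])
    O[i, ] <- place_atom(Nn, CA[i, ], C[i, ], g$b_C_O, g$a_CA_C_O, 180)
    if (i < n) {
      N[i + 1, ] <- Nn
      CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ],
                                g$b_N_CA, g$a_C_N_CA, g$omega)
      C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ],
                               g$b_CA_C, g$a_N_CA_C, pp["phi"])
    }
  }
  resn <- rep_len(residue_names, n)
  rows <- list()
  for (i in seq_len(n)) {
    at <- c("N", "CA", "C", "O")
    xyz_i <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    if (h && i > 1) {
      Hx <- place_atom(O[i - 1, ], C[i - 1, ], N[i, ],
                       g$b_N_H, g$a_C_N_H, 180)
      at <- c(at, "H"); xyz_i <- rbind(xyz_i, as.numeric(Hx))
    }
    if (cb) {
      CBx <- place_atom(N[i, ], C[i, ], CA[i, ],
                        g$b_CA_CB, g$a_C_CA_CB, -122.6)
      at <- c(at, "CB"); xyz_i <- rbind(xyz_i, as.numeric(CBx))
    }
    rows[[i]] <- list(
      atoms = data.frame(chain = chain, resno = i, icode = "",
                         resname = resn[i], atom = at,
                         stringsAsFactors = FALSE),
      xyz = xyz_i)
  }
  atoms <- do.call(rbind, lapply(rows, `[[`, "atoms"))
  xyz <- do.call(rbind, lapply(rows, `[[`, "xyz"))
  rownames(atoms) <- rownames(xyz) <- NULL
  structure(list(atoms = atoms, xyz = xyz, n_residues = n,
                 conformation = conformation, geometry = g),
            class = "flex_template")
}

#' @export
print.flex_template <- function(x, ...) {
  cat("<flex_template> ", x$n_residues, " residues (", x$conformation,
      "), ", nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

# uniform random rotation (QR of a Gaussian matrix, det corrected) plus a
# translation drawn from U(-shift, shift)^3
random_rigid <- function(shift = 10) {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(rotation = R, translation = stats::runif(3, -shift, shift))
}

template_sigma <- function(template, sigma) {
  if (is.null(names(sigma))) {
    if (length(sigma) != 1) stop("unnamed `sigma` must be a single value")
    rep(sigma, nrow(template$atoms))
  } else {
    s <- sigma[template$atoms$atom]
    if (any(is.na(s)))
      stop("`sigma` lacks entries for atom type(s): ",
           paste(unique(template$atoms$atom[is.na(s)]), collapse = ", "))
    as.numeric(s)
  }
}

#' Simulate an ensemble with additive per-atom-type Gaussian noise
#'
#' Each model is the template plus independent Gaussian displacement with
#' per-axis standard deviation `sigma` (a single value, or a named vector
#' per atom type), after which the whole model receives a random rigid
#' transform — so variances are only recoverable after superposition.
#'
#' @param template a [build_backbone_template()] result.
#' @param sigma per-axis noise SD in Angstrom; scalar or named by atom
#'   type (`N`, `CA`, `C`, `O`, ...).
#' @param n_models number of models (>= 2); default 20, a typical NMR
#'   ensemble size.
#' @param seed integer RNG seed; required for reproducibility.
#' @param rigid apply a random rigid transform to each model (default
#'   TRUE).
#' @param source_id provenance label.
#' @return a [flex_ensemble()].
#' @export
simulate_additive_ensemble <- function(template, sigma = 0.1, n_models = 20,
                                       seed, rigid = TRUE,
                                       source_id = "additive_sim") {
  stopifnot(inherits(template, "flex_template"), n_models >= 2)
  s <- template_sigma(template, sigma)
  A <- nrow(template$atoms)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  xyz <- array(NA_real_, c(n_models, A, 3))
  for (m in seq_len(n_models)) {
    mdl <- template$xyz + matrix(stats::rnorm(A * 3, sd = rep(s, 3)), A, 3)
    if (rigid) {
      tf <- random_rigid()
      mdl <- sweep(mdl %*% t(tf$rotation), 2, tf$translation, `+`)
    }
    xyz[m, , ] <- mdl
  }
  flex_ensemble(template$atoms, xyz, source_id)
}

# Rodrigues rotation of points (rows of xyz) about axis through `origin`
# with unit direction `dir`, by angle theta (radians)
rotate_about_axis <- function(xyz, origin, dir, theta) {
  p <- sweep(xyz, 2, origin)
  ct <- cos(theta); st <- sin(theta)
  dot <- as.numeric(p %*% dir)
  crossp <- cbind(dir[2] * p[, 3] - dir[3] * p[, 2],
                  dir[3] * p[, 1] - dir[1] * p[, 3],
                  dir[1] * p[, 2] - dir[2] * p[, 1])
  rot <- p * ct + crossp * st + outer(dot * (1 - ct), dir)
  sweep(rot, 2, origin, `+`)
}

#' Simulate peptide-plane rocking motion
#'
#' Emulates the motional model in which planar peptide units rock about an
#' axis near the N-C' bond: for each peptide plane i, the atoms CA(i),
#' C(i), O(i), N(i+1) (and H(i+1) when present) are rotated by a random
#' angle `theta ~ Normal(0, rock_sigma_deg)` about an axis through N(i+1)
#' directed along the N-C' bond but tilted by `tilt_deg` toward CA(i).
#' This geometry places the carbonyl oxygen furthest from the axis and
#' the C-alpha second furthest, so in the small-angle limit
#' `var(O) > var(CA) > var(C') > var(N)`, with the per-atom variance
#' proportional to (distance from axis)^2 * Var(theta).  Optional
#' isotropic jitter is added to every atom, and each model receives a
#' random rigid transform.
#'
#' @inheritParams simulate_additive_ensemble
#' @param rock_sigma_deg SD of the rocking angle in degrees.
#' @param tilt_deg tilt of the rocking axis from the N->C' direction
#'   toward CA, in degrees.
#' @param jitter per-axis SD of additional isotropic Gaussian noise in
#'   Angstrom (default 0.05, a small coordinate-precision floor).
#' @return a [flex_ensemble()].
#' @export
simulate_rocking_ensemble <- function(template, rock_sigma_deg = 10,
                                      tilt_deg = 15, jitter = 0.05,
                                      n_models = 20, seed, rigid = TRUE,
                                      source_id = "rocking_sim") {
  stopifnot(inherits(template, "flex_template"), n_models >= 2)
  atoms <- template$atoms
  n <- template$n_residues
  A <- nrow(atoms)
  # per-plane atom indices and axis geometry, from the template
  idx_of <- function(res, name) which(atoms$resno == res & atoms$atom == name)
  planes <- lapply(seq_len(n - 1), function(i) {
    iN <- idx_of(i + 1, "N")
    iC <- idx_of(i, "C")
    iCA <- idx_of(i, "CA")
    members <- c(iCA, iC, idx_of(i, "O"), iN, idx_of(i + 1, "H"))
    origin <- template$xyz[iN, ]
    u <- vunit(template$xyz[iC, ] - origin)          # N -> C' direction
    v <- vunit(template$xyz[iCA, ] - origin)         # N -> CA direction
    perp <- v - sum(v * u) * u
    tilt <- deg2rad(tilt_deg)
    dir <- vunit(u * cos(tilt) + vunit(perp) * sin(tilt))
    list(members = members, origin = origin, dir = dir)
  })
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  xyz <- array(NA_real_, c(n_models, A, 3))
  sig_rad <- deg2rad(rock_sigma_deg)
  for (m in seq_len(n_models)) {
    mdl <- template$xyz
    for (pl in planes) {
      theta <- stats::rnorm(1, sd = sig_rad)
      mdl[pl$members, ] <- rotate_about_axis(mdl[pl$members, , drop = FALSE],
                                             pl$origin, pl$dir, theta)
    }
    if (jitter > 0)
      mdl <- mdl + matrix(stats::rnorm(A * 3, sd = jitter), A, 3)
    if (rigid) {
      tf <- random_rigid()
      mdl <- sweep(mdl %*% t(tf$rotation), 2, tf$translation, `+`)
    }
    xyz[m, , ] <- mdl
  }
  flex_ensemble(atoms, xyz, source_id)
}

#' Simulate a null B-factor table (no atom-type effect)
#'
#' Draws one B-factor per template atom i.i.d. from
#' `Normal(mean_b, sd_b)` truncated at zero and quantised to 0.01, the
#' precision of the PDB temperature-factor column (which makes ties
#' likely, exercising the mid-rank path).  Under this null every atom
#' type is exchangeable.
#'
#' @param template a [build_backbone_template()] result.
#' @param mean_b,sd_b mean and SD of the B-factor distribution (A^2).
#' @param seed integer RNG seed.
#' @param source_id provenance label.
#' @return a [flex_atomtable()] of kind `"bfactor"`.
#' @export
simulate_null_bfactors <- function(template, mean_b = 20, sd_b = 5, seed,
                                   source_id = "null_bfactor_sim") {
  stopifnot(inherits(template, "flex_template"), sd_b >= 0)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  b <- pmax(stats::rnorm(nrow(template$atoms), mean_b, sd_b), 0)
  b <- round(b, 2)
  flex_atomtable(template$atoms, b, kind = "bfactor", source_id = source_id)
}

# seed handling: set a local seed, restoring the caller's RNG state
set_local_seed <- function(seed) {
  if (missing(seed) || is.null(seed)) stop("a `seed` is required")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
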