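# In-code fixtures: hand-built PDB records, small rank tables, and
# brute-force oracles used across the test files.

# one fixed-column ATOM record (PDB v3 layout)
pdb_atom_line <- function(serial, name, resname, chain, resno, xyz,
                          occ = 1, b = 0, altloc = " ", icode = " ",
                          element = substr(name, 1, 1)) {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, altloc, resname, chain, resno, icode,
          xyz[1], xyz[2], xyz[3], occ, b, element)
}

# write a multi-model PDB from a list of per-model data.frames with
# columns name, resname, chain, resno, x, y, z (+ optional occ, b, altloc)
write_fixture_pdb <- function(models, path = tempfile(fileext = ".pdb")) {
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1
  for (m in seq_along(models)) {
    df <- models[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    for (i in seq_len(nrow(df))) {
      writeLines(pdb_atom_line(
        i, df$name[i], df$resname[i], df$chain[i], df$resno[i],
        c(df$x[i], df$y[i], df$z[i]),
        occ = if ("occ" %in% names(df)) df$occ[i] else 1,
        b = if ("b" %in% names(df)) df$b[i] else 0,
        altloc = if ("altloc" %in% names(df)) df$altloc[i] else " "), con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  path
}

# a minimal 5-atom single-residue model data.frame at given offset
toy_model <- function(shift = 0, resno = 1) {
  data.frame(name = c("N", "CA", "C", "O", "CB"),
             resname = "ALA", chain = "A", resno = resno,
             x = c(0, 1.4, 2, 1.5, 2.0) + shift,
             y = c(0, 0, 1.2, 2.3, -1.0),
             z = c(0, 0, 0, 0, 1.0),
             stringsAsFactors = FALSE)
}

# wrap a plain rank matrix as a flex_ranktab
ranktab_from_matrix <- function(m, atom_types = c("N", "CA", "C", "O")[seq_len(ncol(m))],
                                id = "toy") {
  structure(list(structure_id = id, atom_types = atom_types,
                 ranks = m, values = m, residues = NULL, n_excluded = 0L),
            class = "flex_ranktab")
}

# all permutations of 1..k
all_perms <- function(k) {
  if (k == 1) return(list(1))
  out <- list()
  for (p in all_perms(k - 1))
    for (pos in seq_len(k))
      out[[length(out) + 1]] <- append(p + (p >= k) * 0, k, after = pos - 1)
  out
}

# untied Friedman statistic of a rank matrix (direct formula evaluation,
# independent of the package implementation)
friedman_stat_direct <- function(r) {
  n <- nrow(r); k <- ncol(r)
  12 / (n * k * (k + 1)) * sum(colSums(r)^2) - 3 * n * (k + 1)
}

# exact permutation p-value by enumerating all (k!)^n within-block rank
# assignments (tie-free tables)
friedman_perm_pvalue <- function(r) {
  n <- nrow(r); k <- ncol(r)
  perms <- all_perms(k)
  obs <- friedman_stat_direct(r)
  grid <- expand.grid(rep(list(seq_along(perms)), n))
  stats <- apply(grid, 1, function(ix) {
    friedman_stat_direct(do.call(rbind, perms[ix]))
  })
  mean(stats >= obs - 1e-9)
}

# rotation matrix from z-y-z Euler angles
euler_zyz <- function(a, b, g) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
  Rz(a) %*% matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3) %*% Rz(g)
}

# brute-force minimal RMSD over rotations: grid over Euler angles plus
# Nelder-Mead refinement; translation handled by centering
brute_force_rmsd <- function(mobile, target, grid_step = 20) {
  P <- scale(mobile, scale = FALSE)
  Q <- scale(target, scale = FALSE)
  obj <- function(ang) {
    R <- euler_zyz(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  step <- grid_step * pi / 180
  best <- NULL; bestv <- Inf
  for (a in seq(0, 2 * pi - step / 2, by = step))
    for (b in seq(0, pi, by = step))
      for (g in seq(0, 2 * pi - step / 2, by = step)) {
        v <- obj(c(a, b, g))
        if (v < bestv) { bestv <- v; best <- c(a, b, g) }
      }
  for (i in 1:3) {
    o <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
    best <- o$par
  }
  o$value
}

# RMSD between a model's fit atoms and the ensemble mean after a fit
superposed_rmsd <- function(sup) sup$per_model_rmsd

expect_ranks_sum <- function(tab) {
  k <- length(tab$atom_types)
  expect_true(all(abs(rowSums(tab$ranks) - k * (k + 1) / 2) < 1e-12))
}
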