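test_that("atom variance is the trace of the positional covariance (divisor M-1)", {
  atoms <- data.frame(chain = "A", resno = 1, icode = "", resname = "GLY",
                      atom = c("N", "CA", "C"), stringsAsFactors = FALSE)
  xyz <- array(0, c(2, 3, 3))
  xyz[2, 1, 1] <- 1    # atom N at (0,0,0) and (1,0,0)
  ens <- flex_ensemble(atoms, xyz)
  v <- atom_variance(ens)
  expect_equal(v$value, c(0.5, 0, 0))
  expect_equal(attr(v, "kind"), "coordinate_variance")
  # identical models -> all zero
  expect_equal(atom_variance(flex_ensemble(atoms, array(1, c(3, 3, 3))))$value,
               rep(0, 3))
  expect_error(atom_variance(flex_ensemble(atoms, array(0, c(1, 3, 3)))),
               ">= 2")
})

test_that("Monte-Carlo variance matches the 3 sigma^2 closed form", {
  tmpl <- build_backbone_template(5, "extended", h = FALSE)
  ens <- simulate_additive_ensemble(tmpl, sigma = 0.2, n_models = 1000,
                                    seed = 17, rigid = FALSE)
  v <- atom_variance(ens)
  expect_lt(max(abs(v$value - 3 * 0.04) / (3 * 0.04)), 0.15)
})

test_that("within-residue ranking follows the mid-rank convention", {
  atoms <- data.frame(chain = "A", resno = rep(1:2, each = 4), icode = "",
                      resname = "ALA", atom = rep(c("N", "CA", "C", "O"), 2),
                      stringsAsFactors = FALSE)
  tab <- flex_atomtable(atoms, c(0.1, 0.2, 0.15, 0.4,
                                 1.0, 2.0, 2.0, 3.0), "coordinate_variance")
  rk <- rank_within_residue(tab)
  expect_equal(unname(rk$ranks[1, ]), c(1, 3, 2, 4))
  expect_equal(unname(rk$ranks[2, ]), c(1, 2.5, 2.5, 4))
  expect_ranks_sum(rk)
  # all tied -> all mid-ranks 2.5
  tab2 <- flex_atomtable(atoms, rep(7, 8), "bfactor")
  expect_equal(unname(rank_within_residue(tab2)$ranks[1, ]), rep(2.5, 4))
  # residues missing a type are excluded and counted
  tab3 <- flex_atomtable(atoms[-4, ], tab$value[-4], "coordinate_variance")
  expect_error(rank_within_residue(tab3), "fewer than 2")
  atoms3 <- rbind(atoms, within(atoms[1:4, ], resno <- 3))
  tab4 <- flex_atomtable(atoms3[-4, ], c(tab$value, tab$value[1:4])[-4],
                         "coordinate_variance")
  rk4 <- rank_within_residue(tab4)
  expect_equal(nrow(rk4$ranks), 2)
  expect_equal(rk4$n_excluded, 1L)
})

test_that("rank rows always sum to k(k+1)/2 under random values and ties", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(2:30, 1)
    atoms <- data.frame(chain = "A", resno = rep(seq_len(n), each = 4),
                        icode = "", resname = "ALA",
                        atom = rep(c("N", "CA", "C", "O"), n),
                        stringsAsFactors = FALSE)
    vals <- round(rexp(4 * n), sample(c(0, 1, 3), 1))  # rounding makes ties
    rk <- rank_within_residue(flex_atomtable(atoms, vals, "bfactor"))
    expect_ranks_sum(rk)
  }
})

test_that("Friedman statistic matches the printed formula on known tables", {
  ordered3 <- ranktab_from_matrix(matrix(rep(1:4, each = 3), 3))
  fr <- friedman_test(ordered3)
  expect_identical(fr$statistic, 9)   # exact: integer arithmetic in doubles
  expect_equal(fr$dof, 3)
  latin <- ranktab_from_matrix(rbind(c(1, 2, 3, 4), c(2, 3, 4, 1),
                                     c(3, 4, 1, 2), c(4, 1, 2, 3)))
  fl <- friedman_test(latin)
  expect_equal(fl$statistic, 0)
  expect_equal(fl$p_value, 1)
  expect_equal(unname(fl$mean_ranks), rep(2.5, 4))
  # SE closed form at n = 100, k = 4
  big <- ranktab_from_matrix(matrix(rep(1:4, each = 100), 100))
  expect_equal(friedman_test(big)$threshold, 3 * sqrt(20 / 600))
  # mean ranks always average to (k+1)/2
  expect_equal(mean(fr$mean_ranks), 2.5)
})

test_that("tie-corrected statistic agrees with stats::friedman.test when tie-free", {
  set.seed(33)
  for (rep in 1:5) {
    y <- matrix(rnorm(48), 12, 4)
    rk <- ranktab_from_matrix(t(apply(y, 1, rank)))
    mine <- friedman_test(rk)
    ref <- stats::friedman.test(y)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value)
  }
})

test_that("fully tied tables take the degenerate path", {
  rk <- ranktab_from_matrix(matrix(2.5, 5, 4))
  fr <- friedman_test(rk)
  expect_true(fr$degenerate)
  expect_equal(fr$statistic, 0)
  expect_equal(fr$p_value, 1)
  expect_false(any(fr$comparisons$significant))
})

test_that("chi-square p agrees with exact permutation enumeration at small n", {
  # the approximation's tolerance at n <= 4, k = 3 is itself measured by
  # full enumeration of the (k!)^n null tables: the worst-case
  # |p_exact - p_chisq| over the whole support (0.228 at n = 3, dominated
  # by the discreteness of the null at small statistic values)
  worst_case <- max(vapply(3:4, function(n) {
    grid <- expand.grid(rep(list(1:6), n))
    pm <- all_perms(3)
    stats <- apply(grid, 1, function(ix)
      friedman_stat_direct(do.call(rbind, pm[ix])))
    u <- sort(unique(stats))
    p_exact <- vapply(u, function(s) mean(stats >= s - 1e-9), numeric(1))
    max(abs(p_exact - stats::pchisq(u, 2, lower.tail = FALSE)))
  }, numeric(1)))
  expect_lt(worst_case, 0.25)
  set.seed(55)
  for (rep in 1:6) {
    n <- sample(3:4, 1)
    r <- do.call(rbind, lapply(seq_len(n), function(i) sample(3)))
    rk <- ranktab_from_matrix(r, atom_types = c("N", "CA", "C"))
    fr <- friedman_test(rk)
    # tie-free: the implementation matches the direct formula exactly
    expect_equal(fr$statistic, friedman_stat_direct(r))
    expect_lt(abs(fr$p_value - friedman_perm_pvalue(r)), worst_case + 1e-9)
  }
})

test_that("ranks and the Friedman statistic are scale/shift invariant", {
  set.seed(77)
  n <- 12
  atoms <- data.frame(chain = "A", resno = rep(seq_len(n), each = 4),
                      icode = "", resname = "ALA",
                      atom = rep(c("N", "CA", "C", "O"), n),
                      stringsAsFactors = FALSE)
  vals <- rexp(4 * n)
  base <- friedman_test(rank_within_residue(
    flex_atomtable(atoms, vals, "bfactor")))
  for (rep in 1:5) {
    a <- runif(1, 0.1, 10); b <- runif(1, 0, 5)
    tr <- friedman_test(rank_within_residue(
      flex_atomtable(atoms, a * vals + b, "bfactor")))
    expect_equal(tr$statistic, base$statistic)
    expect_equal(tr$mean_ranks, base$mean_ranks)
  }
})

test_that("F-score arithmetic, overrides and degenerate cases", {
  r <- fscore(1, 2, 4)
  expect_equal(r$F, 9)
  expect_equal(r$category, "white")
  expect_equal(fscore(0, 2, 2)$F, 1)            # symmetric case
  expect_equal(fscore(2, 3, 1)$category, "green") # u_O < u_N overrides
  expect_equal(fscore(1, 1, 5)$F, Inf)
  expect_equal(fscore(1, 1, 5)$category, "red")
  expect_equal(fscore(1, 1, 1)$category, "undefined")
  expect_equal(fscore(1, 2, 40)$category, "red")   # F > 10
  expect_equal(fscore(1, 20, 2)$category, "blue")  # F < 0.1
  expect_error(fscore(-1, 1, 1))
})

test_that("F-score and its category are invariant under residue-wide affine maps", {
  set.seed(88)
  for (rep in 1:50) {
    u <- rexp(3)
    a <- runif(1, 0.05, 20); b <- runif(1, 0, 10)
    f1 <- fscore(u[1], u[2], u[3])
    f2 <- fscore(a * u[1] + b, a * u[2] + b, a * u[3] + b)
    expect_equal(f1$F, f2$F, tolerance = 1e-9)
    expect_equal(f1$category, f2$category)
  }
})

test_that("average-rank aggregation matches hand computation", {
  lat <- friedman_test(ranktab_from_matrix(
    rbind(c(1, 2, 3, 4), c(2, 3, 4, 1), c(3, 4, 1, 2), c(4, 1, 2, 3)),
    id = "s1"))
  agg1 <- aggregate_average_ranks(list(lat))
  expect_equal(unname(agg1$average_ranks["s1", ]), rep(2.5, 4))
  m <- rbind(c(1, 3, 2, 4), c(2, 3, 1, 4), c(1, 2, 3, 4))
  f2 <- friedman_test(ranktab_from_matrix(m, id = "s2"))
  agg2 <- aggregate_average_ranks(list(lat, f2))
  expect_equal(unname(agg2$average_ranks["s2", ]), colMeans(m))
  expect_equal(unname(agg2$average_ranks["s2", "O"]), 4)  # O ranks 4 everywhere
  expect_equal(dim(agg2$summary), c(3, 4))
})

test_that("significance counts tally directed pairs across structures", {
  tmpl <- build_backbone_template(40, "alpha_helix", h = FALSE)
  fits <- lapply(1:5, function(i) {
    ens <- simulate_additive_ensemble(
      tmpl, sigma = c(N = 0.05, CA = 0.05, C = 0.05, O = 0.6),
      n_models = 20, seed = 200 + i, source_id = paste0("sim", i))
    flex_rank(ens)
  })
  counts <- aggregate_significance_counts(fits)
  expect_equal(nrow(counts), 12)                 # k=4 -> 12 directed pairs
  expect_equal(counts$count[counts$lower == "N" & counts$higher == "O"], 5)
  expect_equal(counts$count[counts$lower == "O" & counts$higher == "N"], 0)
  # degenerate reports contribute no counts
  deg <- friedman_test(ranktab_from_matrix(matrix(2.5, 4, 4)))
  cd <- aggregate_significance_counts(list(deg))
  expect_true(all(cd$count == 0))
})
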