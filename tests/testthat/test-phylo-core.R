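# phylo_core: substitution model, transition kernels, pruning, EM fitting

test_that("rev_model satisfies detailed balance and unit expected rate", {
  set.seed(42)
  for (i in 1:5) {
    m <- rev_model(runif(6, 0.2, 5), runif(4, 0.1, 1))
    Q <- m$Q; pi <- m$pi
    expect_equal(unname(rowSums(Q)), rep(0, 4), tolerance = 1e-12)
    expect_equal(unname(pi * Q), unname(t(pi * Q)),
                 tolerance = 1e-12) # pi_i Q_ij = pi_j Q_ji
    expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
  }
  expect_error(rev_model(c(-1, 1, 1, 1, 1, 1), rep(0.25, 4)), ">= 0")
  expect_error(rev_model(rep(1, 6), c(0, 0.3, 0.3, 0.4)), "> 0")
})

test_that("transition_matrix: identity at t=0, ergodic limit, stochastic", {
  m <- fix_model()
  expect_equal(transition_matrix(m, 0), diag(4), ignore_attr = TRUE)
  P <- transition_matrix(m, 0.37, rho = 1.4)
  expect_true(all(P >= 0))
  expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
  Pbig <- transition_matrix(m, 500)
  for (i in 1:4) expect_equal(unname(Pbig[i, ]), m$pi, tolerance = 1e-9)
  expect_error(transition_matrix(m, -1), ">= 0")
  expect_error(transition_matrix(m, NaN), "finite")
})

test_that("eigendecomposition matches scaling-and-squaring series to 1e-10", {
  set.seed(7)
  for (i in 1:5) {
    m <- rev_model(runif(6, 0.2, 5), runif(4, 0.1, 1))
    t <- 0.1
    # independent oracle: truncated Taylor series with scaling and squaring
    A <- m$Q * t / 64
    S <- diag(4); term <- diag(4)
    for (k in 1:20) {
      term <- term %*% A / k
      S <- S + term
    }
    for (k in 1:6) S <- S %*% S
    expect_equal(unname(transition_matrix(m, t)), unname(S),
                 tolerance = 1e-10)
  }
})

test_that("model serialization round-trips", {
  m <- rev_model(c(0.9, 3.7, 1.1, 0.8, 4.2, 1), c(0.28, 0.21, 0.22, 0.29))
  f <- withr::local_tempfile()
  write_model(m, f, tree_scale = 1.37)
  back <- read_model(f)
  expect_equal(back$model$pi, m$pi, tolerance = 1e-9)
  expect_equal(back$model$Q, m$Q, tolerance = 1e-8)
  expect_equal(back$tree_scale, 1.37)
})

test_that("column_loglik trivial cases: single tip and all-missing", {
  phy <- phylogeny("(A:0.1);")
  m <- fix_model()
  expect_equal(column_loglik(aln1("A", "A"), phy, m), log(m$pi[1]),
               ignore_attr = TRUE)
  phy4 <- tree4()
  # all symbols missing -> probability one
  expect_equal(column_loglik(aln1(rep("N", 4), c("A", "B", "C", "D")),
                             phy4, m), 0)
  expect_equal(column_loglik(aln1(c("-", "N", "-", "N"), c("A", "B", "C", "D")),
                             phy4, m), 0)
})

test_that("pruning equals brute-force enumeration on small trees", {
  m <- fix_model()
  trees <- list(tree4(), tree5_rerooted()[[1]])
  set.seed(99)
  for (phy in trees) {
    sp <- phy$tree$tip.label
    for (rep in 1:25) {
      syms <- sample(c("A", "C", "G", "T", "N", "-"), length(sp),
                     replace = TRUE, prob = c(rep(0.22, 4), 0.06, 0.06))
      if (all(syms %in% c("N", "-"))) syms[1] <- "A"
      a <- aln1(syms, sp)
      expect_equal(column_loglik(a, phy, m),
                   brute_force_loglik(a, phy, m), tolerance = 1e-12)
    }
    # and with a clade scaling on a subtree
    phy_cl <- phylogeny(phy$tree, clades = list(ab = c("A", "B")))
    for (rep in 1:10) {
      syms <- sample(c("A", "C", "G", "T"), length(sp), replace = TRUE)
      a <- aln1(syms, sp)
      expect_equal(column_loglik(a, phy_cl, m, rho = 0.3, clade = "ab"),
                   brute_force_loglik(a, phy_cl, m, rho = 0.3, clade = "ab"),
                   tolerance = 1e-12)
    }
  }
})

test_that("likelihood is invariant to re-rooting (reversibility)", {
  m <- fix_model()
  set.seed(5)
  pairs <- list(tree4_rerooted(), tree5_rerooted())
  for (pr in pairs) {
    sp <- pr[[1]]$tree$tip.label
    for (rep in 1:20) {
      syms <- sample(c("A", "C", "G", "T", "N"), length(sp), replace = TRUE,
                     prob = c(rep(0.23, 4), 0.08))
      a <- aln1(syms, sp)
      expect_equal(column_loglik(a, pr[[1]], m), column_loglik(a, pr[[2]], m),
                   tolerance = 1e-10)
    }
  }
})

test_that("compiled and pure-R pruning agree on deep-tree alignments", {
  phy <- demo_phy_cache()
  m <- fix_model()
  sim <- simulate_alignment(simulation_config(phy = phy, length = 100,
                                              missing_rate = 0.2, seed = 8))
  codes <- constraintdepth:::code_columns(sim$alignment)
  pm <- constraintdepth:::edge_pmats(m, phy$tree,
                                     rep(1, nrow(phy$tree$edge)))
  a <- constraintdepth:::prune_loglik(codes, phy, m, pm)
  b <- constraintdepth:::prune_loglik_r(codes, phy, m, pm)
  expect_equal(a$per_column, b$per_column, tolerance = 1e-12)
})

test_that("fit_neutral_model recovers parameters from simulated columns", {
  # 8-tip tree, 10,000 columns under a known REV model
  old <- options(warn = 1)
  on.exit(options(old))
  set.seed(314)
  tr <- ape::rcoal(8, tip.label = paste0("t", 1:8))
  tr$edge.length <- tr$edge.length * 2 / sum(tr$edge.length) * 8
  phy <- phylogeny(tr)
  truth <- rev_model(c(1.5, 4, 0.8, 1.2, 3.5, 1), c(0.35, 0.18, 0.17, 0.30))
  sim <- simulate_alignment(simulation_config(
    phy = phy, model = truth, length = 10000, missing_rate = 0, seed = 271))
  fit <- fit_neutral_model(sim$alignment, phy)
  expect_true(fit$converged)
  expect_true(all(abs(fit$model$pi - truth$pi) < 0.02))
  s_hat <- fit$model$s / fit$model$s[6]
  s_true <- truth$s / truth$s[6]
  expect_true(all(abs(s_hat / s_true - 1) < 0.15))
  expect_equal(fit$tree_scale, 1, tolerance = 0.1)
  # EM monotonicity: trace never decreases by more than numerical slack
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
})

test_that("fit_neutral_model handles degenerate and small inputs", {
  phy <- demo_phy_cache()
  # all columns identical across species: branch scaling driven to floor
  m <- matrix("A", 48, 60, dimnames = list(phy$tree$tip.label, NULL))
  aln <- alignment_columns(m, seq_len(60) - 1L)
  fit <- fit_neutral_model(aln, phy, min_columns = 10)
  expect_lt(fit$tree_scale, 1e-3)
  expect_error(fit_neutral_model(aln, phy, min_columns = 1000),
               "informative columns")
})

test_that("refitting improves the likelihood over the init model", {
  set.seed(21)
  tr <- ape::rcoal(6, tip.label = paste0("t", 1:6))
  tr$edge.length <- tr$edge.length * 3 / sum(tr$edge.length)
  phy <- phylogeny(tr)
  truth <- rev_model(c(1, 6, 1, 1, 6, 1), c(0.4, 0.1, 0.1, 0.4))
  sim <- simulate_alignment(simulation_config(
    phy = phy, model = truth, length = 3000, missing_rate = 0, seed = 4))
  init <- rev_model(rep(1, 6), rep(0.25, 4))
  ll_init <- column_loglik(sim$alignment, phy, init)
  fit <- fit_neutral_model(sim$alignment, phy, init = init)
  expect_gt(fit$loglik, ll_init)
})

test_that("regional fits: fallback flag and rate-multiplier ordering", {
  phy <- demo_phy_cache()
  # two windows simulated at rate multipliers 1.0 and 2.0
  tr2 <- phy$tree; tr2$edge.length <- tr2$edge.length * 2
  phy2 <- phylogeny(tr2, phy$clades)
  s1 <- simulate_alignment(simulation_config(phy = phy, length = 1500,
                                             missing_rate = 0, seed = 31))
  s2 <- simulate_alignment(simulation_config(phy = phy2, length = 1500,
                                             missing_rate = 0, seed = 32))
  sym <- cbind(s1$alignment$symbols, s2$alignment$symbols)
  aln <- alignment_columns(sym, seq_len(3000) - 1L)
  neutral <- data.frame(start = 0L, end = 3000L)
  fits <- fit_regional_models(aln, phy, neutral, window_size = 1500L,
                              sample_size = 800L, min_columns = 100L,
                              seed = 9)
  expect_length(fits, 2L)
  expect_false(fits[[1]]$fallback)
  expect_gt(fits[[2]]$fit$tree_scale, 1.5 * fits[[1]]$fit$tree_scale)
  # a window that is all missing beyond tolerance falls back
  sym_na <- aln$symbols
  sym_na[2:48, 1:1500] <- "N"
  aln_na <- alignment_columns(sym_na, aln$coords)
  fits_na <- fit_regional_models(aln_na, phy, neutral, window_size = 1500L,
                                 sample_size = 400L, min_columns = 100L,
                                 seed = 9)
  expect_true(fits_na[[1]]$fallback)
})
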