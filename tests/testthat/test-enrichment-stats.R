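# enrichment_stats: PIP enrichment, motif OR meta-analysis, reporter-assay
# correlation, mismatch regression

test_that("dedupe_max_pip keeps each variant's highest PIP", {
  v <- data.frame(variant_id = c("a", "a", "b"), PIP = c(0.2, 0.9, 0.4),
                  trait = c("t1", "t2", "t1"))
  d <- dedupe_max_pip(v)
  expect_equal(nrow(d), 2L)
  expect_equal(d$PIP[d$variant_id == "a"], 0.9)
  expect_equal(d$trait[d$variant_id == "a"], "t2")
})

test_that("pip_enrichment arithmetic and edge cases", {
  # a=10/A=100 vs b=20/B=2000 -> (0.10)/(0.01) = 10
  v <- data.frame(
    variant_id = paste0("v", 1:2100),
    PIP = c(rep(0.9, 100), rep(0.001, 2000)),
    in_annotation = c(rep(c(TRUE, FALSE), c(10, 90)),
                      rep(c(TRUE, FALSE), c(20, 1980))))
  r <- pip_enrichment(v)
  expect_equal(r$a, 10); expect_equal(r$A, 100)
  expect_equal(r$b, 20); expect_equal(r$B, 2000)
  expect_equal(r$enrichment, 10)
  expect_true(r$ci[1] <= r$odds_ratio && r$odds_ratio <= r$ci[2])
  # annotation covering everything -> enrichment 1
  v$in_annotation <- TRUE
  expect_equal(pip_enrichment(v)$enrichment, 1)
  # mid-PIP variants are excluded from both tails
  v2 <- rbind(v, data.frame(variant_id = "mid", PIP = 0.3,
                            in_annotation = TRUE))
  r2 <- pip_enrichment(v2)
  expect_equal(r2$A, 100); expect_equal(r2$B, 2000)
  # empty tails error; zero cells are flagged
  expect_error(pip_enrichment(data.frame(variant_id = "x", PIP = 0.3,
                                         in_annotation = TRUE)), "empty PIP tail")
  v3 <- v; v3$in_annotation <- rep(c(FALSE, TRUE), c(100, 2000))
  expect_true("zero-cell" %in% pip_enrichment(v3)$flags)
})

test_that("pip_enrichment matches an independent hypergeometric route", {
  set.seed(9)
  for (i in 1:100) {
    A <- sample(20:200, 1); B <- sample(200:2000, 1)
    a <- rbinom(1, A, runif(1, 0.05, 0.5)); b <- rbinom(1, B, runif(1, 0.05, 0.5))
    a <- max(a, 1); b <- max(b, 1)
    v <- data.frame(
      variant_id = paste0("v", seq_len(A + B)),
      PIP = c(rep(1, A), rep(0, B)),
      in_annotation = c(rep(c(TRUE, FALSE), c(a, A - a)),
                        rep(c(TRUE, FALSE), c(b, B - b))))
    r <- pip_enrichment(v)
    # oracle: hypergeometric two-sided p via dhyper enumeration
    m <- a + b; n_ <- (A - a) + (B - b); k <- A
    dens <- dhyper(0:min(m, k), m, n_, k)
    p_or <- sum(dens[dens <= dhyper(a, m, n_, k) * (1 + 1e-7)])
    expect_equal(r$p_value, p_or, tolerance = 1e-6)
  }
})

test_that("generative recovery: planted 5x causal enrichment", {
  ests <- vapply(1:50, function(i) {
    tab <- simulate_pip_table(n_variants = 20000, causal_enrichment = 5,
                              seed = 100 + i)
    pip_enrichment(dedupe_max_pip(tab))$enrichment
  }, numeric(1))
  expect_true(mean(ests) > 3.5 && mean(ests) < 6.5)
  expect_gt(mean(ests >= 3.5 & ests <= 6.5), 0.8)
})

test_that("Woolf log OR and the meta-analysis identity", {
  w <- constraintdepth:::woolf_log_or(20, 80, 10, 90)
  expect_equal(w$log_or, log(2.25))
  expect_equal(w$var, 1 / 20 + 1 / 80 + 1 / 10 + 1 / 90)
  # zero cells get the Haldane correction rather than infinities
  w0 <- constraintdepth:::woolf_log_or(0, 80, 10, 90)
  expect_true(is.finite(w0$log_or))
  # identical tables in every bin: pooled OR = common OR, var / n_bins
  fp <- do.call(rbind, lapply(1:10, function(b) {
    len <- b # one distinct length per decile
    data.frame(
      footprint_id = sprintf("b%d_%d", b, 1:200), length = len,
      motif = rep(c("m1", "m2"), c(100, 100)),
      primate_constrained = rep(c(TRUE, FALSE, TRUE, FALSE),
                                c(20, 80, 10, 90)),
      mammal_constrained = rep(c(TRUE, FALSE, TRUE, FALSE),
                               c(10, 90, 20, 80)))
  }))
  res <- motif_or_meta(fp, n_bins = 10)
  r1 <- res[res$motif == "m1", ]
  # per-bin table for m1: a=20,b=10,c=10,d=20 -> OR 4
  expect_equal(r1$log_or, log(4), tolerance = 1e-9)
  wb <- constraintdepth:::woolf_log_or(20, 10, 10, 20)
  expect_equal(r1$se^2, wb$var / 10, tolerance = 1e-9)
  expect_equal(r1$n_bins_used, 10L)
})

test_that("pooled estimate is invariant to bin granularity on homogeneous data", {
  set.seed(33)
  fp <- simulate_footprints(n = 3000, motif_effects = c(motif1 = 1),
                            seed = 7)
  r10 <- motif_or_meta(fp, n_bins = 10)
  r1 <- motif_or_meta(fp, n_bins = 1)
  # no length confounder: binned and unbinned pooled ORs agree closely
  m <- merge(r10, r1, by = "motif")
  expect_lt(max(abs(m$log_or.x - m$log_or.y)), 0.25)
})

test_that("binned meta-analysis removes a planted length confounder", {
  pooled <- matrix(NA_real_, 50, 2) # columns: unbinned, binned
  for (i in 1:50) {
    fp <- simulate_footprints(n = 4000, length_confounder = 1.2,
                              seed = 400 + i)
    r1 <- motif_or_meta(fp, n_bins = 1)
    r10 <- motif_or_meta(fp, n_bins = 10)
    # short-preferring motif: most biased by the confounder
    pooled[i, 1] <- r1$log_or[r1$motif == "motif1"]
    pooled[i, 2] <- r10$log_or[r10$motif == "motif1"]
  }
  se_unb <- sd(pooled[, 1]) / sqrt(50)
  se_bin <- sd(pooled[, 2]) / sqrt(50)
  # unbinned OR is biased away from 1; binned pooled OR is centred at 0
  expect_gt(abs(mean(pooled[, 1])), 4 * se_unb)
  expect_lt(abs(mean(pooled[, 2])), 2 * se_bin)
})

test_that("null footprints give pooled ORs centred at 1", {
  los <- vapply(1:30, function(i) {
    fp <- simulate_footprints(n = 3000, seed = 600 + i)
    mean(motif_or_meta(fp, n_bins = 10)$log_or)
  }, numeric(1))
  expect_lt(abs(mean(los)), 2 * sd(los) / sqrt(30))
})

test_that("reporter-assay correlation: truncation, degeneracy, recovery", {
  # all-negative scores truncate to zero variance -> untestable
  eff <- data.frame(element_id = "e1", position = 1:3,
                    mean_effect = c(0.5, 0.2, 0.1), phylop = c(-2, -1, 0))
  r <- mpra_constraint_correlation(eff)
  expect_true(r$untestable)
  # effects exactly proportional to truncated scores -> r = 1
  eff2 <- data.frame(element_id = "e2", position = 1:5,
                     mean_effect = c(0, 0, 1, 2, 3) * 0.1,
                     phylop = c(-1, 0, 1, 2, 3))
  r2 <- mpra_constraint_correlation(eff2)
  expect_equal(r2$r, 1, tolerance = 1e-12)
  # mixture recovery: 148 elements, 40% with planted correlation
  set.seed(77)
  frac_sig <- vapply(1:10, function(rep) {
    rows <- lapply(1:148, function(i) {
      n <- 40
      sc <- pmax(stats::rnorm(n, 1, 1.2), -1)
      eff <- if (i <= 59) {
        0.6 * pmax(sc, 0) + stats::rnorm(n, 0, sqrt(1 - 0.6^2) * sd(pmax(sc, 0)))
      } else {
        stats::rnorm(n)
      }
      data.frame(element_id = paste0("el", i), position = 1:n,
                 mean_effect = eff, phylop = sc)
    })
    res <- mpra_constraint_correlation(do.call(rbind, rows))
    mean(res$significant)
  }, numeric(1))
  expect_true(mean(frac_sig) > 0.25 && mean(frac_sig) < 0.45)
})

test_that("truncation helps when effects are monotone in constraint", {
  set.seed(15)
  n <- 200
  sc <- stats::rnorm(n, 0.5, 1.5)
  eff <- pmax(sc, 0) * 0.8 + abs(stats::rnorm(n, 0, 0.1))
  r_trunc <- cor(eff, pmax(sc, 0))
  r_raw <- cor(eff, sc)
  expect_gte(r_trunc, r_raw)
})

test_that("mismatch regression recovers the residual error rate", {
  # zero-noise linear data: exact intercept, R^2 = 1
  pairs0 <- data.frame(heterozygosity = seq(1e-4, 5e-3, length.out = 10))
  pairs0$mismatch <- 4e-4 + 0.9 * pairs0$heterozygosity
  f0 <- suppressWarnings(mismatch_regression(pairs0)) # exact fit warns in summary.lm
  expect_equal(f0$intercept, 4e-4, tolerance = 1e-12)
  expect_equal(f0$r_squared, 1, tolerance = 1e-9)
  expect_equal(f0$residual_rate, f0$intercept)
  # noisy synthetic pairs at the reported magnitude
  set.seed(44)
  ok <- vapply(1:20, function(i) {
    h <- runif(25, 5e-4, 5e-3)
    m <- 4e-4 + 0.9 * h + stats::rnorm(25, 0, 2e-5)
    fit <- mismatch_regression(data.frame(heterozygosity = h, mismatch = m))
    fit$intercept > 3e-4 && fit$intercept < 5e-4
  }, logical(1))
  expect_gte(mean(ok), 0.9)
  expect_error(mismatch_regression(data.frame(heterozygosity = rep(1e-3, 5),
                                              mismatch = rep(1e-3, 5))),
               "constant")
  expect_error(mismatch_regression(pairs0[1:2, ]), "at least 3")
})
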