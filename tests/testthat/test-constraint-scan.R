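# constraint_scan: LRT scoring, scale-factor MLE, phylo-HMM segmentation

neutral_m <- default_neutral_model()

test_that("null boundary: rho = 1 gives LRT 0, p 1, score 0", {
  r <- constraintdepth:::make_constraint_result("x", "primates",
                                                -10, -10, 1)
  expect_equal(r$lrt, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$score, 0)
  # sign convention follows rho
  rc <- constraintdepth:::make_constraint_result("x", "p", -10, -8, 0.3)
  ra <- constraintdepth:::make_constraint_result("x", "p", -10, -8, 3)
  expect_gt(rc$score, 0)
  expect_lt(ra$score, 0)
  expect_equal(rc$score, -ra$score)
})

test_that("score > 1.3 if and only if p < 0.05 (constraint side)", {
  for (p in c(0.049, 0.05, 0.051, 0.01, 0.5)) {
    score <- -log10(p)
    expect_equal(score > -log10(0.05), p < 0.05)
  }
  expect_equal(-log10(0.05), 1.30103, tolerance = 1e-5)
})

test_that("uninformative and flagged columns are handled", {
  phy <- demo_phy_cache()
  sim <- simulate_alignment(simulation_config(phy = phy, length = 50,
                                              missing_rate = 0, seed = 5))
  aln <- sim$alignment
  # blank out the primate clade at one column
  prim <- clade_tips(phy, "primates")
  aln$symbols[prim, 11] <- "N"
  r <- phylop_site(aln, phy, neutral_m, clade = "primates", position = 10)
  expect_equal(r$p_value, 1)
  expect_equal(r$score, 0)
  expect_true("uninformative" %in% r$flags)
  # low-coverage flag when < 3 clade species are informative
  aln$symbols[prim[-(1:2)], 21] <- "N"
  r2 <- phylop_site(aln, phy, neutral_m, clade = "primates", position = 20)
  expect_true("low-coverage" %in% r2$flags)
})

test_that("single-column constraint and acceleration are detected directionally", {
  # dense primate-scale tree, single column, rho = 0.05 vs rho = 5
  phy <- primate_tree()
  n_rep <- 200
  pos_ok <- 0; neg_ok <- 0
  for (i in seq_len(n_rep)) {
    sim_c <- simulate_alignment(simulation_config(
      phy = phy, length = 1, missing_rate = 0, seed = 9000 + i,
      elements = data.frame(start = 0, end = 1, rho = 0.05,
                            clade = "primates")))
    sim_a <- simulate_alignment(simulation_config(
      phy = phy, length = 1, missing_rate = 0, seed = 19000 + i,
      elements = data.frame(start = 0, end = 1, rho = 5,
                            clade = "primates")))
    rc <- phylop_site(sim_c$alignment, phy, neutral_m, clade = "primates",
                      position = 0)
    ra <- phylop_site(sim_a$alignment, phy, neutral_m, clade = "primates",
                      position = 0)
    pos_ok <- pos_ok + (rc$score > 0)
    neg_ok <- neg_ok + (ra$score < 0)
  }
  expect_gte(pos_ok / n_rep, 0.95)
  expect_gte(neg_ok / n_rep, 0.95)
})

test_that("1-bp element scoring reduces to the site test", {
  phy <- demo_phy_cache()
  sim <- simulate_alignment(simulation_config(phy = phy, length = 30,
                                              missing_rate = 0.1, seed = 12))
  rs <- phylop_site(sim$alignment, phy, neutral_m, clade = "primates",
                    position = 7)
  re <- phylop_element(sim$alignment, phy, neutral_m, clade = "primates",
                       element = list(start = 7, end = 8, element_id = "e"))
  expect_equal(re$lrt, rs$lrt, tolerance = 1e-8)
  expect_equal(re$p_value, rs$p_value, tolerance = 1e-8)
  expect_equal(re$rho, rs$rho, tolerance = 1e-3)
})

test_that("element p-values are uniform under the null and power grows with width", {
  phy <- demo_phy_cache()
  scen <- planted_scenario(n_planted = 0, n_null = 500, gap = 0,
                           neutral_train = 0, missing_rate = 0.1, seed = 77)
  sim <- simulate_alignment(scen$config)
  sc <- phylop_elements(sim$alignment, phy, neutral_m, clade = "primates",
                        elements = scen$elements)
  ks <- stats::ks.test(sc$p_value, "punif")
  expect_gt(ks$p.value, 0.01)
  # type-I error at nominal 5% within binomial tolerance
  rate <- mean(sc$p_value < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 500) + 1e-9)
})

test_that("element-wide rho sharing gains power over single sites", {
  phy <- demo_phy_cache()
  n_rep <- 100
  p_el <- numeric(n_rep)
  p_site <- matrix(NA_real_, n_rep, 40)
  for (i in seq_len(n_rep)) {
    sim <- simulate_alignment(simulation_config(
      phy = phy, length = 40, missing_rate = 0.1, seed = 3000 + i,
      elements = data.frame(start = 0, end = 40, rho = 0.3,
                            clade = "primates")))
    ctx <- constraintdepth:::scoring_context(sim$alignment, phy, neutral_m,
                                             "primates", 1)
    p_el[i] <- constraintdepth:::score_element_ctx(ctx, 1:40, "el")$p_value
    p_site[i, ] <- vapply(1:40, function(j) {
      constraintdepth:::score_element_ctx(ctx, j, "s")$p_value
    }, numeric(1))
  }
  site_medians <- apply(p_site, 2, stats::median)
  expect_lt(stats::median(p_el), min(site_medians))
})

test_that("estimate_scale recovers a planted rho = 0.3", {
  phy <- primate_tree()
  hits <- 0
  n_rep <- 20
  for (i in seq_len(n_rep)) {
    sim <- simulate_alignment(simulation_config(
      phy = phy, length = 40, missing_rate = 0, seed = 500 + i,
      elements = data.frame(start = 0, end = 40, rho = 0.3,
                            clade = "primates")))
    est <- estimate_scale(sim$alignment, phy, neutral_m, clade = "primates")
    hits <- hits + (est$rho >= 0.2 && est$rho <= 0.4)
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("estimate_scale: degenerate input pegs rho at the lower bound", {
  phy <- demo_phy_cache()
  m <- matrix("C", 48, 30, dimnames = list(phy$tree$tip.label, NULL))
  aln <- alignment_columns(m, seq_len(30) - 1L)
  est <- estimate_scale(aln, phy, neutral_m, clade = "primates")
  expect_lt(est$rho, 1e-3)
})

test_that("golden-section agrees with a fine grid search", {
  phy <- tree4()
  phy <- phylogeny(phy$tree, clades = list(ab = c("A", "B")))
  aln <- aln_from_rows(c(A = "ACGTA", B = "ACGTA", C = "AGGTC", D = "ATGAA"))
  est <- estimate_scale(aln, phy, neutral_m, clade = "ab")
  ctx <- constraintdepth:::scoring_context(aln, phy, neutral_m, "ab", 1)
  grid <- seq(1e-4, 20, by = 1e-3)
  lls <- vapply(grid, function(r) {
    constraintdepth:::context_loglik(ctx, 1:5, r)
  }, numeric(1))
  expect_lt(abs(est$rho - grid[which.max(lls)]), 2e-3)
})

test_that("score antisymmetry between reciprocal rate scalings", {
  phy <- demo_phy_cache()
  score_at <- function(rho, seeds) {
    mean(vapply(seeds, function(s) {
      sim <- simulate_alignment(simulation_config(
        phy = phy, length = 20, missing_rate = 0, seed = s,
        elements = data.frame(start = 0, end = 20, rho = rho,
                              clade = "primates")))
      phylop_element(sim$alignment, phy, neutral_m, clade = "primates",
                     element = list(start = 0, end = 20,
                                    element_id = "e"))$score
    }, numeric(1)))
  }
  m_c <- score_at(0.25, 101:115)
  m_a <- score_at(4, 201:215)
  expect_gt(m_c, 0)
  expect_lt(m_a, 0)
})

test_that("hmm_params derives the transition rates from L and gamma", {
  p <- hmm_params()
  expect_equal(p$mu, 1 / 45)
  expect_equal(p$nu, 0.3 * (1 / 45) / 0.7)
  expect_equal(p$mu, 0.022222, tolerance = 1e-4)
  expect_equal(p$nu, 0.009524, tolerance = 1e-4)
  # stationary conserved fraction equals gamma analytically
  expect_equal(p$nu / (p$nu + p$mu), 0.3, tolerance = 1e-12)
  expect_error(hmm_params(target_coverage = 1.2), "target_coverage")
})

test_that("conserved sojourn length under the prior matches L", {
  set.seed(1234)
  p <- hmm_params()
  states <- simulate_state_chain(p, 1e5)
  soj <- conserved_sojourns(states)
  expect_lt(abs(soj$mean_length - 45), 3 * soj$se)
  expect_lt(abs(mean(states) - 0.3), 3 * sqrt(0.3 * 0.7 / 1e5) * 20)
})

test_that("phastCons: forward/backward agree; identical columns give one segment", {
  phy <- demo_phy_cache()
  m <- matrix("G", 48, 200, dimnames = list(phy$tree$tip.label, NULL))
  aln <- alignment_columns(m, seq_len(200) - 1L)
  seg <- phastcons_segment(aln, phy, neutral_m)
  expect_equal(seg$loglik_forward, seg$loglik_backward, tolerance = 1e-8)
  expect_equal(nrow(seg$segments), 1L)
  expect_equal(seg$segments$start, 0L)
  expect_equal(seg$segments$end, 200L)
  expect_error(phastcons_segment(
    alignment_columns(m[, 0, drop = FALSE], integer(0)), phy, neutral_m),
    "empty")
})

test_that("phastCons recovers a planted 60-bp element inside 1 kb", {
  # at full species density; the sparser demo tree yields occasional short
  # spurious segments under the 0.3-coverage prior (see methods vignette)
  phy <- primate_tree()
  n_rep <- 100
  ok <- 0
  for (i in seq_len(n_rep)) {
    sim <- simulate_alignment(simulation_config(
      phy = phy, length = 1000, missing_rate = 0.1, seed = 7000 + i,
      elements = data.frame(start = 470, end = 530, rho = 0.2,
                            clade = "primates")))
    seg <- phastcons_segment(sim$alignment, phy, neutral_m)$segments
    mid_in <- nrow(seg) == 1 &&
      (seg$start + seg$end) / 2 >= 470 && (seg$start + seg$end) / 2 < 530
    ok <- ok + mid_in
  }
  expect_gte(ok / n_rep, 0.95)
})

test_that("posterior decoding is exposed and coverage gaps split runs", {
  phy <- demo_phy_cache()
  m <- matrix("G", 48, 60, dimnames = list(phy$tree$tip.label, NULL))
  coords <- c(0:29, 100:129) # two contiguous stretches
  aln <- alignment_columns(m, coords)
  seg <- phastcons_segment(aln, phy, neutral_m, decode = "posterior")
  expect_equal(nrow(seg$segments), 2L)
  expect_equal(seg$segments$start, c(0L, 100L))
  expect_true(all(seg$segments$mean_posterior > 0.5))
})
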