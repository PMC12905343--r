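test_that("expected pair-site probability matches hand algebra and limits", {
  # zero branch length: no time to change, probability 0
  q <- c(1, 0, 0, 0)
  P0 <- diag(4)
  expect_equal(expected_pair_site_prob(q, q, P0, P0), 0)

  # 2-state closed form: P(t) known, q concentrated on state 1
  exch <- matrix(c(0, 1, 1, 0), 2)
  m2 <- aa_model(exch, c(0.5, 0.5), states = c("0", "1"))
  alpha <- -m2$Q[1, 1]
  t1 <- 0.4; t2 <- 0.8
  P1 <- transition_matrix(m2, t1); P2 <- transition_matrix(m2, t2)
  q1 <- c(1, 0); q2 <- c(1, 0)
  # both must change 0 -> 1: p = P1[1,2] * P2[1,2]
  expect_equal(expected_pair_site_prob(q1, q2, P1, P2),
               P1[1, 2] * P2[1, 2], tolerance = 1e-12)
  # soft ancestors: full double sum, written out by hand
  qa <- c(0.7, 0.3); qb <- c(0.2, 0.8)
  hand <- 0
  for (d in 1:2) for (a in 1:2) for (b in 1:2)
    if (a != d && b != d)
      hand <- hand + qa[a] * qb[b] * P1[a, d] * P2[b, d]
  expect_equal(expected_pair_site_prob(qa, qb, P1, P2), hand,
               tolerance = 1e-12)

  expect_error(expected_pair_site_prob(NULL, qb, P1, P2), "posterior")
})

test_that("expected pair-site probability matches Monte-Carlo endpoints", {
  set.seed(4242)
  for (i in 1:3) {
    m <- toy_model(4, seed = 600 + i)
    ta <- runif(1, 0.1, 0.8); tb <- runif(1, 0.1, 0.8)
    Pa <- transition_matrix(m, ta); Pb <- transition_matrix(m, tb)
    qa <- as.vector(rmultinom(1, 40, rep(0.25, 4))) + 0.5
    qa <- qa / sum(qa)
    qb <- rev(qa)
    p <- expected_pair_site_prob(qa, qb, Pa, Pb)
    n <- 1e5
    a <- sample.int(4, n, TRUE, qa); b <- sample.int(4, n, TRUE, qb)
    da <- vapply(a, function(x) sample.int(4, 1, prob = Pa[x, ]), integer(1))
    db <- vapply(b, function(x) sample.int(4, 1, prob = Pb[x, ]), integer(1))
    phat <- mean(da == db & da != a & db != b)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(phat - p), 3 * se + 1e-12)
  }
})

test_that("the gene-level Poisson test has its closed forms", {
  expect_equal(gene_poisson_test(0, 2.5), 1)
  expect_equal(gene_poisson_test(5, 1), 1 - sum(exp(-1) / factorial(0:4)),
               tolerance = 1e-10)
  expect_equal(gene_poisson_test(1, 1), 1 - exp(-1), tolerance = 1e-12)
  expect_error(gene_poisson_test(3, 0), "lambda")
  expect_error(gene_poisson_test(-1, 1), "non-negative")
})

test_that("BH adjustment matches a textbook implementation exactly", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 0)), "0, 1")
  set.seed(11)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), bh_textbook(p))
  }
})

test_that("omegaC decomposes into observed/expected count ratios", {
  d <- default_design()
  cm <- build_codon_model(2, 1, codon_frequencies(NULL, "uniform"))
  sim <- simulate_codon_msa(d$tree, cm, 150,
                            list(fraction = 0.06,
                                 clades = list(d$focal_a, d$focal_b)),
                            seed = 77)
  fit <- fit_codon_model(sim$alignment, d$tree)
  labs <- c(d$tree$tip.label, d$tree$node.label)
  stems <- c(labs[d$focal_a$mrca], labs[d$focal_b$mrca])
  oc <- omega_c(sim$alignment, d$tree, stems, fit)
  expect_equal(oc$dNC, (oc$OCN + 0.5) / (oc$ECN + 0.5), tolerance = 1e-12)
  expect_equal(oc$dSC, (oc$OCS + 0.5) / (oc$ECS + 0.5), tolerance = 1e-12)
  expect_equal(oc$omega_c, oc$dNC / oc$dSC, tolerance = 1e-12)
  expect_true(is.finite(oc$omega_c))
  expect_gt(oc$OCN, 0)              # forced convergence is visible
  expect_gt(oc$omega_c, 1)

  # scale consistency: duplicating every column doubles all four counts
  dup <- paas_alignment(unclass(sim$alignment)[, rep(1:150, 2)], "codon")
  oc2 <- omega_c(dup, d$tree, stems, fit)
  expect_equal(oc2$OCN, 2 * oc$OCN)
  expect_equal(oc2$OCS, 2 * oc$OCS)
  expect_equal(oc2$ECN, 2 * oc$ECN, tolerance = 1e-8)
  expect_equal(oc2$ECS, 2 * oc$ECS, tolerance = 1e-8)
})

test_that("the rank-sum comparison has exact small-sample behaviour", {
  expect_equal(rates_vs_controls(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rates_vs_controls(c(10, 11, 12), c(1, 2, 3)), 0.1)  # 2/20
  expect_error(rates_vs_controls(numeric(0), 1:3), "non-empty")
  set.seed(5)
  hits <- mean(replicate(20, {
    rates_vs_controls(rnorm(100) + 2, rnorm(100)) < 0.01
  }))
  expect_gte(hits, 0.95)
})
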