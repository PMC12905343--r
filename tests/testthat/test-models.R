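test_that("the JTT model satisfies the reversible-model invariants", {
  m <- jtt_model()
  expect_equal(sum(m$freqs), 1, tolerance = 1e-12)
  expect_lt(max(abs(rowSums(m$Q))), 1e-12)
  expect_equal(-sum(m$freqs * diag(m$Q)), 1, tolerance = 1e-12)
  # detailed balance pi_i Q_ij = pi_j Q_ji
  flux <- m$freqs * m$Q
  expect_lt(max(abs(flux - t(flux))), 1e-12)
})

test_that("transition matrices behave like exp(Qt)", {
  m <- jtt_model()
  expect_equal(transition_matrix(m, 0), diag(20), ignore_attr = TRUE)
  expect_error(transition_matrix(m, -1), ">= 0")

  # 2-state symmetric toy: P_00(t) = (1 + exp(-2 alpha t)) / 2
  exch <- matrix(c(0, 1, 1, 0), 2)
  m2 <- aa_model(exch, c(0.5, 0.5), states = c("0", "1"))
  alpha <- -m2$Q[1, 1]
  for (t in c(0.1, 0.7, 2)) {
    P <- transition_matrix(m2, t)
    expect_equal(P[1, 1], (1 + exp(-2 * alpha * t)) / 2, tolerance = 1e-12)
  }

  # stationarity: long branches forget the starting state
  P <- transition_matrix(m, 500)
  expect_lt(max(abs(sweep(P, 2, m$freqs))), 1e-6)

  # semigroup and row-stochasticity across models and times
  for (mod in list(m, toy_model(4, 2), build_codon_model(2, 0.5))) {
    for (t in c(0.01, 0.1, 1, 10)) {
      P <- transition_matrix(mod, t)
      expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
      expect_true(all(P >= 0 & P <= 1 + 1e-12))
    }
    Pst <- transition_matrix(mod, 0.3)
    expect_lt(max(abs(Pst %*% Pst - transition_matrix(mod, 0.6))), 1e-8)
    # detailed balance of the finite-time kernel
    F1 <- mod$freqs * transition_matrix(mod, 0.5)
    expect_lt(max(abs(F1 - t(F1))), 1e-9)
  }
})

test_that("site-specific frequency families renormalise per site", {
  m <- jtt_model()
  fam <- with_site_frequencies(m, matrix(m$freqs, 20, 3))
  s1 <- site_model(fam, 1)
  expect_equal(s1$Q, m$Q, tolerance = 1e-12)

  conc <- rep(0.01 / 19, 20); conc[5] <- 0.99
  fam2 <- with_site_frequencies(m, cbind(conc))
  s2 <- site_model(fam2, 1)
  expect_equal(-sum(s2$freqs * diag(s2$Q)), 1, tolerance = 1e-12)

  # 2-state toy with equal frequencies: off-diagonal rates are equal
  exch <- matrix(c(0, 3, 3, 0), 2)
  m2 <- aa_model(exch, c(0.3, 0.7), states = c("0", "1"))
  fam3 <- with_site_frequencies(m2, cbind(c(0.5, 0.5)))
  s3 <- site_model(fam3, 1)
  expect_equal(s3$Q[1, 2], s3$Q[2, 1], tolerance = 1e-12)

  expect_error(with_site_frequencies(m, cbind(c(rep(0.05, 19), 0))),
               "pseudocount")
})

test_that("site frequencies are counted with pseudocounts, excluding gaps", {
  m <- matrix(c("A", "A", "A", "A",
                "A", "C", "-", "G"), nrow = 4,
              dimnames = list(paste0("t", 1:4), NULL))
  aln <- paas_alignment(m, "amino20")
  f0 <- estimate_site_frequencies(aln, pseudocount = 0)
  expect_equal(unname(f0["A", 1]), 1)
  f1 <- estimate_site_frequencies(aln, pseudocount = 0.1)
  expect_equal(unname(f1["A", 1]), 4.1 / (4 + 20 * 0.1))
  # gap excluded from the counts: denominator 3 + 20 * pc
  expect_equal(unname(f1["A", 2]), 1.1 / (3 + 20 * 0.1))
  expect_equal(unname(f1["G", 2]), 1.1 / (3 + 20 * 0.1))

  allgap <- paas_alignment(matrix("-", 4, 1,
                                  dimnames = list(paste0("t", 1:4), NULL)),
                           "amino20")
  expect_warning(fg <- estimate_site_frequencies(allgap), "all-gap")
  expect_equal(unname(fg[, 1]), unname((paraconv:::.JTT_FREQS + 0.1) /
                                         sum(paraconv:::.JTT_FREQS + 0.1)))
})

test_that("the codon model restricts rates to single-nucleotide changes", {
  cm <- build_codon_model(kappa = 3, omega_codon = 0.4)
  states <- cm$states
  expect_lt(max(abs(rowSums(cm$Q))), 1e-12)
  expect_equal(sum(cm$freqs), 1, tolerance = 1e-12)

  idx <- function(c1) which(states == c1)
  # multi-nucleotide change has exactly zero rate
  expect_identical(cm$Q[idx("AAA"), idx("ACG")], 0)
  # AAA->AAG (K->K, synonymous transition) vs AAA->AAC (K->N, nonsyn
  # transversion): rate ratio kappa / omega, read off the code table
  r1 <- cm$Q[idx("AAA"), idx("AAG")] / cm$freqs[idx("AAG")]
  r2 <- cm$Q[idx("AAA"), idx("AAC")] / cm$freqs[idx("AAC")]
  expect_equal(r1 / r2, 3 / 0.4, tolerance = 1e-12)

  # omega = kappa = 1 with uniform frequencies: all allowed rates equal
  cm1 <- build_codon_model(1, 1)
  off <- cm1$Q[row(cm1$Q) != col(cm1$Q)]
  expect_equal(length(unique(round(off[off > 0], 14))), 1)

  # with omega = 1 the stationary nonsyn/syn flux equals the code's
  # opportunity ratio (pure counting of single-nt changes)
  meta <- paraconv:::codon_meta()
  nonsyn <- meta$single & meta$nonsyn
  syn <- meta$single & !meta$nonsyn
  fluxN <- sum((cm1$freqs * cm1$Q)[nonsyn])
  fluxS <- sum((cm1$freqs * cm1$Q)[syn])
  expect_equal(fluxN / fluxS, sum(nonsyn) / sum(syn), tolerance = 1e-10)

  expect_error(build_codon_model(-1, 1), "> 0")
})

test_that("codon frequencies come from F3x4 position-specific counts", {
  tr <- default_design()$tree
  cm <- build_codon_model(2, 0.5)
  sim <- simulate_codon_msa(tr, cm, 80, NULL, seed = 11)
  f <- codon_frequencies(sim$alignment, "F3x4")
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_true(all(f > 0))
  expect_length(f, 61)
  u <- codon_frequencies(NULL, "uniform")
  expect_equal(unname(u), rep(1 / 61, 61))
})

test_that("kappa and omega are recovered by the bounded ML fit", {
  tr <- default_design()$tree
  truth <- build_codon_model(4, 0.2, codon_frequencies(NULL, "uniform"))
  sim <- simulate_codon_msa(tr, truth, 400, NULL, seed = 21)
  fit <- fit_codon_model(sim$alignment, tr)
  expect_gt(fit$kappa, 2.5)
  expect_lt(fit$kappa, 6.5)
  expect_gt(fit$omega_codon, 0.1)
  expect_lt(fit$omega_codon, 0.35)
})
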