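test_that("closed-form likelihoods hold on one- and two-leaf trees", {
  m <- toy_model(4, seed = 7)
  # single leaf at distance t from the root: stationarity gives log pi_a
  tr1 <- read_tree("(A:0.4);")
  aln1 <- paas_alignment(matrix("C", 1, 1, dimnames = list("A", NULL)),
                         "nucleotide4")
  m4 <- toy_model(4, seed = 7, states = c("A", "C", "G", "T"))
  expect_equal(site_log_likelihood(tr1, aln1, m4),
               unname(log(m4$freqs[m4$states == "C"])),
               tolerance = 1e-10, ignore_attr = TRUE)

  # two leaves: direct summation over the root state
  tr2 <- read_tree("(A:0.3,B:0.6);")
  aln2 <- paas_alignment(matrix(c("A", "G"), 2, 1,
                                dimnames = list(c("A", "B"), NULL)),
                         "nucleotide4")
  P1 <- transition_matrix(m4, 0.3)
  P2 <- transition_matrix(m4, 0.6)
  direct <- log(sum(m4$freqs * P1[, 1] * P2[, 3]))
  expect_equal(site_log_likelihood(tr2, aln2, m4), direct,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("pruning and marginal posteriors match exhaustive enumeration", {
  for (seed in 1:6) {
    n <- sample(4:5, 1)
    tr <- random_tree(n, seed = 100 + seed)
    m <- toy_model(4, seed = 200 + seed)
    aln <- random_toy_alignment(tr, m, 3, seed = 300 + seed)
    post <- marginal_posteriors(tr, aln, m)
    for (s in 1:3) {
      bf <- brute_force_site(tr, aln, m, s)
      expect_equal(post$loglik[s], bf$loglik, tolerance = 1e-9)
      expect_equal(unname(post$post[, s, ]), unname(bf$post),
                   tolerance = 1e-9)
    }
  }
})

test_that("posteriors approach limiting distributions", {
  # star-ish tree with very long branches: root posterior approaches pi
  tr <- read_tree("((A:60,B:60):60,(C:60,D:60):60);")
  m <- toy_model(4, seed = 3, states = c("A", "C", "G", "T"))
  aln <- paas_alignment(matrix(c("A", "C", "G", "T"), 4, 1,
                               dimnames = list(LETTERS[c(1:3, 4)], NULL)),
                        "nucleotide4")
  rownames(aln) <- c("A", "B", "C", "D")
  post <- marginal_posteriors(tr, aln, m)
  expect_lt(max(abs(post$post[, 1, 1] - m$freqs)), 1e-4)  # root node

  # near-zero branch lengths on a clade of identical states: mass -> 1
  tr0 <- read_tree("((A:0.0001,B:0.0001):0.3,(C:0.3,D:0.3):0.2);")
  aln0 <- paas_alignment(matrix(c("G", "G", "A", "C"), 4, 1,
                                dimnames = list(c("A", "B", "C", "D"), NULL)),
                         "nucleotide4")
  post0 <- marginal_posteriors(tr0, aln0, m)
  mrca <- ape::getMRCA(tr0, c("A", "B"))
  expect_gt(post0$post[3, 1, mrca - 4], 0.999)
})

test_that("posteriors sum to one and are invariant to re-rooting", {
  tr <- read_tree("(((A:0.2,B:0.3):0.15,(C:0.25,D:0.1):0.2):0.1,(E:0.3,F:0.2):0.12);")
  m <- jtt_model()
  aln <- simulate_msa(tr, m, 15, seed = 9)$alignment
  p1 <- marginal_posteriors(tr, aln, m)
  expect_lt(max(abs(apply(p1$post, c(2, 3), sum) - 1)), 1e-10)

  suppressMessages(
    tr2 <- prepare_tree(ape::root(ape::unroot(tr), outgroup = "A",
                                  resolve.root = TRUE)))
  p2 <- marginal_posteriors(tr2, aln, m)
  for (pairset in list(c("C", "D"), c("E", "F"))) {
    n1 <- ape::getMRCA(tr, pairset) - ape::Ntip(tr)
    n2 <- ape::getMRCA(tr2, pairset) - ape::Ntip(tr2)
    expect_lt(max(abs(p1$post[, , n1] - p2$post[, , n2])), 1e-8)
  }
})

test_that("MAP reconstruction breaks ties canonically and applies the floor", {
  # fabricate a posterior object with known probabilities
  post <- structure(list(
    post = array(c(0.7, 0.3, 0.5, 0.5), c(2, 2, 1)),
    loglik = c(-1, -1), node_labels = "N1", n_tips = 2,
    states = c("A", "B")), class = "ancestral_posterior")
  mp <- map_reconstruction(post)
  expect_equal(unname(mp$state[1, ]), c("A", "A"))  # tie -> lowest index
  expect_equal(unname(mp$confidence[1, ]), c(0.7, 0.5))
  expect_false(mp$ambiguous[1, 1])
  expect_true(mp$ambiguous[1, 2])

  mp2 <- map_reconstruction(post, conf_floor = 0.8)
  expect_true(all(mp2$low_confidence[1, ]))
})

test_that("substitution events are extracted per branch, skipping gaps", {
  tr <- read_tree("((s1:0.1,s2:0.1):0.1,(s3:0.1,s4:0.1):0.1);")
  m <- jtt_model()
  base <- matrix("H", 4, 200, dimnames = list(paste0("s", 1:4), NULL))
  base[1, 150] <- "R"   # one derived change on a terminal branch
  base[2, 150] <- "H"
  base[3, 7] <- "-"     # gap emits nothing
  aln <- paas_alignment(base, "amino20")
  post <- marginal_posteriors(tr, aln, m)
  map <- map_reconstruction(post)
  ev <- extract_events(tr, map, aln)
  hit <- ev[ev$site == 150 & ev$branch == "s1", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$anc, "H")
  expect_equal(hit$der, "R")
  expect_false(any(ev$site == 7 & ev$branch == "s3"))
  expect_true(all(ev$anc != ev$der))
  expect_true(all(ev$anc_pp > 0 & ev$anc_pp <= 1))

  # no variation anywhere -> no events
  flat <- paas_alignment(matrix("K", 4, 5,
                                dimnames = list(paste0("s", 1:4), NULL)),
                         "amino20")
  post2 <- marginal_posteriors(tr, flat, m)
  ev2 <- extract_events(tr, map_reconstruction(post2), flat)
  expect_equal(nrow(ev2), 0)
})

test_that("MAP ancestral states beat a frequency-only guess on simulated data", {
  d <- default_design()
  m <- jtt_model()
  sim <- simulate_msa(d$tree, m, 400, seed = 77)
  post <- marginal_posteriors(d$tree, sim$alignment, m)
  map <- map_reconstruction(post)
  tp <- paraconv:::tree_post(d$tree)
  root_truth <- m$states[sim$node_states[tp$root, ]]
  acc <- mean(map$state[tp$root - tp$n_tips, ] == root_truth)
  expect_gt(acc, max(m$freqs))  # > best frequency-only guesser
})
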