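test_that("the default study design matches the two-clade layout", {
  d <- make_default_tree()
  expect_equal(ape::Ntip(d$tree), 22)
  expect_equal(length(d$focal_a$node_ids), 5)
  expect_equal(length(d$focal_b$node_ids), 5)
  expect_length(d$control_sets, 7)
  # control sets are disjoint, monophyletic, non-focal
  all_members <- unlist(d$control_sets)
  expect_equal(anyDuplicated(all_members), 0)
  expect_length(intersect(all_members,
                          c(d$focal_a$members, d$focal_b$members)), 0)
  for (cs in d$control_sets)
    expect_s3_class(clade_spec(d$tree, cs), "clade_spec")
  expect_true(all(d$tree$edge.length >= 0.02 & d$tree$edge.length <= 0.30))

  d2 <- make_default_tree(scale = 2)
  expect_equal(sort(d2$tree$edge.length), sort(2 * d$tree$edge.length))
})

test_that("null simulation is seeded, stationary, and degenerate at t = 0", {
  d <- default_design()
  m <- jtt_model()
  s1 <- simulate_msa(d$tree, m, 40, seed = 42)
  s2 <- simulate_msa(d$tree, m, 40, seed = 42)
  expect_identical(unclass(s1$alignment), unclass(s2$alignment))
  expect_true(all(s1$truth$label == "background"))

  # zero branch lengths: every column constant, equal to the root draw
  tz <- d$tree
  tz$edge.length[] <- 0
  suppressMessages(tz <- prepare_tree(tz))
  sz <- simulate_msa(tz, m, 25, seed = 1)
  expect_true(all(apply(unclass(sz$alignment), 2,
                        function(x) length(unique(x)) == 1)))

  # law of large numbers: empirical frequencies near pi
  big <- simulate_msa(d$tree, m, 50000, seed = 7)
  emp <- table(factor(unclass(big$alignment), levels = m$states))
  emp <- as.vector(emp) / sum(emp)
  expect_lt(sum(abs(emp - m$freqs)), 0.02)
})

test_that("convergent shifts are injected at labelled sites in both clades", {
  d <- default_design()
  sim <- inject_convergent_shifts(d$tree, list(d$focal_a, d$focal_b),
                                  n_sites = 200, shift_fraction = 0.05,
                                  concentration = 0.9, seed = 13)
  expect_equal(sum(sim$truth$label == "shifted"), floor(0.05 * 200))
  expect_true(all(!is.na(sim$truth$target[sim$truth$label == "shifted"])))

  # degenerate limit: concentration 1 pins every foreground leaf to the target
  sim1 <- inject_convergent_shifts(d$tree, list(d$focal_a, d$focal_b),
                                   n_sites = 200, shift_fraction = 0.1,
                                   concentration = 1, seed = 14)
  sh <- which(sim1$truth$label == "shifted")
  fg <- c(d$focal_a$members, d$focal_b$members)
  hits <- sapply(sh, function(s)
    all(unclass(sim1$alignment)[fg, s] == sim1$truth$target[s]))
  expect_true(all(hits))

  # fraction 0 is bit-identical to the null generator under the same seed
  pis <- constrained_site_frequencies(100, 0.97, seed = 16)
  fam <- with_site_frequencies(jtt_model(), pis)
  a0 <- inject_convergent_shifts(d$tree, list(d$focal_a, d$focal_b),
                                 model = fam, n_sites = 100,
                                 shift_fraction = 0, seed = 15)
  a1 <- simulate_msa(d$tree, fam, 100, seed = 15)
  expect_identical(unclass(a0$alignment), unclass(a1$alignment))

  equus <- c("Equus_caballus", "Equus_asinus")
  expect_error(inject_convergent_shifts(
    d$tree, list(equus, setdiff(d$tree$tip.label, equus)),
    n_sites = 10, seed = 1), "whole tree")
})

test_that("shifted-site backgrounds remain distributed like null sites", {
  # calibration property: site log-likelihoods of background sites in a
  # shifted dataset are indistinguishable from a pure-null simulation
  d <- default_design()
  pis <- constrained_site_frequencies(400, 0.97, seed = 61)
  fam <- with_site_frequencies(jtt_model(), pis)
  shifted <- inject_convergent_shifts(d$tree, list(d$focal_a, d$focal_b),
                                      model = fam, n_sites = 400,
                                      shift_fraction = 0.05,
                                      concentration = 0.9, seed = 60)
  pure <- simulate_msa(d$tree, fam, 400, seed = 62)
  bg <- shifted$truth$site[shifted$truth$label == "background"]
  ll_bg <- site_log_likelihood(d$tree, shifted$alignment, fam)[bg]
  ll_null <- site_log_likelihood(d$tree, pure$alignment, fam)[bg]
  expect_gt(suppressWarnings(ks.test(ll_bg, ll_null)$p.value), 0.01)
})

test_that("codon simulation forces convergent amino acids at labelled sites", {
  d <- default_design()
  cm <- build_codon_model(2, 0.5)
  cfg <- list(fraction = 0.05, clades = list(d$focal_a, d$focal_b))
  sim <- simulate_codon_msa(d$tree, cm, 200, cfg, seed = 19)
  expect_equal(sum(sim$truth$label == "forced"), floor(0.05 * 200))
  sim_b <- simulate_codon_msa(d$tree, cm, 200, cfg, seed = 19)
  expect_identical(unclass(sim$alignment), unclass(sim_b$alignment))

  # at forced sites both clade MRCAs carry codons for the target residue
  forced <- which(sim$truth$label == "forced")
  mrcas <- c(d$focal_a$mrca, d$focal_b$mrca)
  for (s in forced) {
    codons <- cm$states[sim$node_states[mrcas, s]]
    expect_equal(unname(translate_codons(codons)),
                 rep(sim$truth$target[s], 2))
  }
  expect_error(simulate_codon_msa(d$tree, cm, 10,
                                  list(fraction = 1, clades = cfg$clades),
                                  seed = 1), "fraction")
})
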