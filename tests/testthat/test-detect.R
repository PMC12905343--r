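test_that("branch-pair enumeration is the product of foreground node sets", {
  d <- default_design()
  pairs <- enumerate_pairs(d$focal_a, d$focal_b)
  expect_equal(nrow(pairs), 25)          # (2*3-1) x (2*3-1)
  expect_equal(anyDuplicated(paste(pairs$node_a, pairs$node_b)), 0)

  two <- clade_spec(d$tree, c("Vicugna_pacos", "Lama_glama"))
  expect_equal(nrow(enumerate_pairs(two, d$focal_b)), 15)  # 3 x 5
  expect_error(enumerate_pairs(d$focal_a, d$focal_a), "overlap")

  # |pairs| = (2|A|-1)(2|B|-1) for clade sizes 2..3 on the default tree
  three <- clade_spec(d$tree, c("Bubalus_bubalis", "Bos_taurus", "Bos_mutus"))
  expect_equal(nrow(enumerate_pairs(two, three)), 3 * 5)
  expect_equal(nrow(enumerate_pairs(three, d$focal_a)), 5 * 5)
})

test_that("pair classification matches the exhaustive truth table", {
  ab <- c("A", "C", "G", "T")
  grid <- expand.grid(anc_a = ab, der_a = ab, anc_b = ab, der_b = ab,
                      stringsAsFactors = FALSE)
  got <- with(grid, paraconv:::classify_states(anc_a, der_a, anc_b, der_b))
  # independent truth table straight from the definitions
  want <- apply(grid, 1, function(r) {
    if (r["anc_a"] == r["der_a"] || r["anc_b"] == r["der_b"]) return("none")
    if (r["der_a"] != r["der_b"]) return("none")
    if (r["anc_a"] == r["anc_b"]) "parallel" else "convergent"
  })
  expect_identical(got, unname(want))
  expect_equal(sum(got == "parallel"), 4 * 3)        # anc x der, anc != der
  expect_equal(sum(got == "convergent"), 4 * 3 * 2)  # der, anc_a != anc_b != der

  e1 <- list(site = 5, anc = "L", der = "R")
  e2 <- list(site = 5, anc = "L", der = "R")
  expect_equal(classify_pair_site(e1, e2), "parallel")
  expect_equal(classify_pair_site(list(site = 5, anc = "H", der = "R"),
                                  list(site = 5, anc = "Q", der = "R")),
               "convergent")
  expect_equal(classify_pair_site(list(site = 5, anc = "H", der = "R"),
                                  list(site = 5, anc = "H", der = "K")),
               "none")
  expect_error(classify_pair_site(e1, list(site = 6, anc = "L", der = "R")),
               "different sites")
})

test_that("CCS classification implements the three admissible patterns", {
  bg <- rep("H", 16)
  expect_equal(ccs_classify(bg, c("H", "H"), c("R", "R")), "S2S")
  expect_equal(ccs_classify(bg, c("H", "Q"), c("R", "R")), "D2S")
  expect_equal(ccs_classify(bg, c("H", "H"), c("R", "K")), "S2D")
  expect_equal(ccs_classify(bg, c("H", "Q"), c("R", "K")), "none")

  # variable background fails the conservation screen
  bg5 <- rep(c("A", "C", "D", "E", "F"), c(4, 4, 4, 2, 2))
  expect_equal(ccs_classify(bg5, c("H", "H"), c("R", "R")), "none")
  # two states but weak majority
  expect_equal(ccs_classify(rep(c("H", "Q"), 8), c("H", "H"), c("R", "R")),
               "none")
  # two states with a >= 0.8 majority passes
  expect_equal(ccs_classify(rep(c("H", "Q"), c(14, 2)), c("H", "H"),
                            c("R", "R")), "S2S")
  # mostly-gap background is unclassifiable
  expect_equal(ccs_classify(c(rep("-", 12), rep("H", 4)), c("H", "H"),
                            c("R", "R")), "none")
})

test_that("swapped-outgroup control scenarios validate and count correctly", {
  d <- default_design()
  ctl <- swap_control(d$tree, d$focal_a, d$focal_b, d$scenarios)
  expect_length(ctl, 7)
  for (sc in ctl) {
    expect_s3_class(sc$a, "clade_spec")
    expect_length(intersect(sc$a$members, sc$b$members), 0)
  }
  expect_error(
    swap_control(d$tree, d$focal_a, d$focal_b,
                 list(list(a = d$focal_a$members, b = "focalB"))),
    "overlaps")
  expect_warning(empty <- swap_control(d$tree, d$focal_a, d$focal_b, list()),
                 "empty")
  expect_length(empty, 0)
})

test_that("per-gene scans find planted convergent substitutions", {
  d <- default_design()
  sim <- inject_convergent_shifts(d$tree, list(d$focal_a, d$focal_b),
                                  n_sites = 300, shift_fraction = 0.05,
                                  concentration = 0.9, seed = 31)
  scan <- scan_gene(d$tree, sim$alignment, d$focal_a, d$focal_b)
  true <- sim$truth$site[sim$truth$label == "shifted"]
  expect_gt(length(intersect(unique(scan$calls$site), true)),
            0.5 * length(true))
  expect_true(all(scan$calls$category %in% c("parallel", "convergent")))
  expect_true(all(scan$calls$der_a == scan$calls$der_b))
  expect_gte(scan$n_obs, nrow(scan$calls) * 0)
  expect_equal(sum(scan$per_pair$n_obs), scan$n_obs)
  expect_equal(sum(scan$per_pair$lambda), scan$lambda, tolerance = 1e-9)
})

test_that("collation deduplicates sites per gene but keeps pair counts", {
  calls <- data.frame(
    site = c(3, 3, 3, 9), node_a = c("x", "y", "z", "x"),
    node_b = c("u", "u", "u", "u"),
    category = "parallel", ccs_pass = TRUE,
    stringsAsFactors = FALSE)
  out <- collate_paas(list(geneB = calls[0, ], geneA = calls))
  expect_equal(out$gene_sites$gene, c("geneA", "geneB"))  # sorted
  expect_equal(out$gene_sites$n_sites, c(2, 0))
  expect_equal(sum(out$pair_counts$n_calls), 4)
  expect_lte(out$gene_sites$n_sites[1], sum(out$pair_counts$n_calls))
})
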