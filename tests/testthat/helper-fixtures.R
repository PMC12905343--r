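# Shared fixtures and independent oracles. Everything is generated in code;
# no binary data ships with the package.

# Memoised default study design (tree + clades + controls).
default_design <- local({
  d <- NULL
  function() {
    if (is.null(d)) d <<- make_default_tree()
    d
  }
})

# A small reversible toy model over an arbitrary alphabet.
toy_model <- function(k = 4, seed = 1,
                      states = c("A", "C", "G", "T")[seq_len(k)]) {
  set.seed(seed)
  exch <- matrix(0, k, k)
  exch[lower.tri(exch)] <- runif(k * (k - 1) / 2, 0.5, 2)
  exch <- exch + t(exch)
  freqs <- as.vector(stats::rgamma(k, 2)) + 0.05
  aa_model(exch, freqs / sum(freqs), states)
}

# Random rooted binary tree with branch lengths, prepared for the package.
random_tree <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves, rooted = TRUE,
                   br = function(n) runif(n, 0.05, 0.5))
  prepare_tree(tr)
}

# A tiny alignment over a model's states, one row per tree leaf.
random_toy_alignment <- function(tree, model, n_sites, seed) {
  simulate_msa(tree, model, n_sites, seed)$alignment
}

# Exhaustive-enumeration oracle: site likelihood and marginal posteriors by
# summing over all internal-node state assignments. Independent of the
# pruning engine (uses only transition_matrix and the edge table).
brute_force_site <- function(tree, aln, model, site) {
  tp <- paraconv:::tree_post(tree)
  k <- length(model$states)
  n_int <- tp$n_nodes - tp$n_tips
  P <- lapply(seq_len(nrow(tp$edge)), function(e)
    transition_matrix(model, tp$edge_length[e]))
  obs <- match(unclass(aln)[tree$tip.label, site], model$states)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n_int))
  tot <- 0
  post <- matrix(0, k, n_int)
  for (r in seq_len(nrow(grid))) {
    assign_int <- as.integer(grid[r, ])
    ns <- c(obs, assign_int)
    pr <- model$freqs[ns[tp$root]]
    for (e in seq_len(nrow(tp$edge))) {
      a <- ns[tp$edge[e, 1]]; b <- ns[tp$edge[e, 2]]
      if (is.na(b)) next                 # missing tip: sums out to 1
      pr <- pr * (if (is.na(a)) NA else P[[e]][a, b])
    }
    tot <- tot + pr
    for (j in seq_len(n_int))
      post[assign_int[j], j] <- post[assign_int[j], j] + pr
  }
  list(loglik = log(tot), post = post / tot)
}

# Textbook step-up BH, written independently of stats::p.adjust.
bh_textbook <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Run the detection + profile-shift cascade on one simulated gene and
# return the detected site set (the pipeline's focal code path).
cascade_detected_sites <- function(aln, design = default_design(),
                                   pp_threshold = 0.99) {
  scan <- run_pipeline(list(g = aln), design$tree, design$focal_a,
                       design$focal_b)
  calls <- scan$scenarios$focal$calls
  unique(calls$site[calls$ccs_pass & calls$pp > pp_threshold])
}
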