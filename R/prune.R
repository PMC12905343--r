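# Internal bridges between phylo trees, alignments and the C++ pruning
# engines. All heavy lifting (per-site scaling, up-down passes, per-site
# rate matrices) happens in src/pruning.cpp.

# Per-edge P-matrix cube for a global model on a postorder edge table.
edge_P_cube <- function(tp, model) {
  k <- length(model$states)
  P <- array(0, c(k, k, nrow(tp$edge)))
  for (e in seq_len(nrow(tp$edge)))
    P[, , e] <- transition_matrix(model, tp$edge_length[e])
  P
}

# Pruning log-likelihoods (and optionally posteriors) for a global model.
prune_model <- function(tp, states, model, posterior = FALSE) {
  P <- edge_P_cube(tp, model)
  prune_edge_P(tp$edge, P, states, model$freqs, tp$n_tips, posterior)
}

prune_model_loglik <- function(tp, states, model) {
  prune_model(tp, states, model, posterior = FALSE)$loglik
}

# Dispatch on model type; want_edges are postorder edge rows whose per-site
# P matrices should be returned (fsite models need them site by site).
prune_dispatch <- function(tp, states, model, posterior = FALSE,
                           want_edges = integer(0), keep_P = TRUE,
                           map_w = FALSE) {
  if (inherits(model, "aa_model_fsite")) {
    if (ncol(model$pis) != ncol(states))
      stop("fsite family covers ", ncol(model$pis), " sites, alignment has ",
           ncol(states))
    prune_fsite(tp$edge, tp$edge_length, states, model$exch, model$pis,
                tp$n_tips, posterior, as.integer(want_edges), keep_P, map_w)
  } else if (inherits(model, "aa_model")) {
    out <- prune_model(tp, states, model, posterior)
    if (length(want_edges)) {
      P <- edge_P_cube(tp, model)
      out$edge_P <- lapply(want_edges, function(e)
        array(P[, , e], c(dim(P)[1], dim(P)[2], ncol(states))))
    }
    out
  } else stop("unsupported model class: ", paste(class(model), collapse = "/"))
}

check_alphabet_model <- function(aln, model) {
  astates <- alphabet_states(attr(aln, "alphabet"))
  if (!identical(astates, model$states))
    stop("alignment alphabet (", attr(aln, "alphabet"),
         ") does not match the model's state space")
}
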