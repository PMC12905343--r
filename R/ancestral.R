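#' Per-site log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning in scaled arithmetic with per-node rescaling, safe for
#' 20- and 61-state alphabets on deep trees.
#'
#' @param tree prepared `phylo` (see [read_tree()]).
#' @param aln matching `paas_aln`.
#' @param model an `aa_model`, `codon_model`, or `aa_model_fsite` family.
#' @return numeric vector of per-site log-likelihoods.
#' @export
site_log_likelihood <- function(tree, aln, model) {
  tree <- match_tree_alignment(tree, aln)
  check_alphabet_model(aln, model)
  tp <- tree_post(tree)
  states <- aln_state_matrix(aln, tree$tip.label)
  ll <- prune_dispatch(tp, states, model)$loglik
  if (any(!is.finite(ll)))
    stop("non-finite log-likelihood at site ", which(!is.finite(ll))[1])
  ll
}

#' Marginal ancestral-state posteriors
#'
#' Standard up-down (inside-outside) marginal reconstruction: at every
#' internal node the posterior over states is proportional to the partial
#' likelihood of the data below the node times the outside contribution from
#' the rest of the tree. This is the in-package equivalent of codeml's
#' marginal ancestral reconstruction.
#'
#' @inheritParams site_log_likelihood
#' @param want_edges optional postorder edge rows for which per-site
#'   transition matrices are returned (used by the expected-convergence
#'   computation).
#' @param keep_P return the full per-site transition matrices for
#'   `want_edges` (`edge_P`); set `FALSE` to keep only the summaries the
#'   expected-convergence computation needs.
#' @param map_w condition the exported per-edge change probabilities on the
#'   parent's MAP state rather than integrating over its posterior (used by
#'   the pipeline so observed and expected convergence counts share the
#'   same conditioning).
#' @return an `ancestral_posterior`: `post` (states x sites x internal
#'   nodes), `loglik`, `node_labels` (internal, in node-id order), `states`,
#'   and `tp` (the postorder edge table).
#' @export
marginal_posteriors <- function(tree, aln, model, want_edges = integer(0),
                                keep_P = TRUE, map_w = FALSE) {
  tree <- match_tree_alignment(tree, aln)
  check_alphabet_model(aln, model)
  tp <- tree_post(tree)
  states <- aln_state_matrix(aln, tree$tip.label)
  out <- prune_dispatch(tp, states, model, posterior = TRUE,
                        want_edges = want_edges, keep_P = keep_P,
                        map_w = map_w)
  if (any(!is.finite(out$loglik)))
    stop("non-finite log-likelihood at site ", which(!is.finite(out$loglik))[1])
  int_ids <- tp$n_tips + seq_len(tp$n_nodes - tp$n_tips)
  structure(list(post = out$posterior, loglik = out$loglik,
                 node_labels = tp$labels[int_ids], n_tips = tp$n_tips,
                 states = model$states, tp = tp, tree = tree,
                 edge_P = out$edge_P, edge_W = out$edge_W,
                 want_edges = want_edges),
            class = "ancestral_posterior")
}

#' @export
print.ancestral_posterior <- function(x, ...) {
  cat("<ancestral_posterior> ", dim(x$post)[3], " internal nodes x ",
      dim(x$post)[2], " sites, ", length(x$states), " states\n", sep = "")
  cat("  total log-likelihood: ", sum(x$loglik), "\n", sep = "")
  invisible(x)
}

#' Maximum-a-posteriori ancestral states
#'
#' Takes the argmax state per internal node and site. Exact ties are broken
#' towards the lowest index in canonical alphabet order and flagged
#' ambiguous. States whose posterior mass falls below `conf_floor` are
#' flagged low-confidence; [extract_events()] skips them when a floor is set.
#'
#' @param posterior an `ancestral_posterior`.
#' @param conf_floor confidence floor in `[0, 1]`; 0 (default) disables
#'   filtering, i.e. MAP states are used as-is.
#' @return `map_states`: character matrix `state` (internal nodes x sites),
#'   numeric `confidence`, logical `ambiguous` and `low_confidence`.
#' @export
map_reconstruction <- function(posterior, conf_floor = 0) {
  stopifnot(inherits(posterior, "ancestral_posterior"))
  p <- posterior$post
  k <- dim(p)[1]; S <- dim(p)[2]; n_int <- dim(p)[3]
  st <- matrix("", n_int, S, dimnames = list(posterior$node_labels, NULL))
  conf <- matrix(0, n_int, S, dimnames = dimnames(st))
  amb <- matrix(FALSE, n_int, S)
  for (i in seq_len(n_int)) {
    m <- p[, , i]
    idx <- max.col(t(m), ties.method = "first")
    conf[i, ] <- m[cbind(idx, seq_len(S))]
    st[i, ] <- posterior$states[idx]
    amb[i, ] <- colSums(abs(m - rep(conf[i, ], each = k)) < 1e-12) > 1
  }
  structure(list(state = st, confidence = conf, ambiguous = amb,
                 low_confidence = conf < conf_floor,
                 conf_floor = conf_floor, states = posterior$states),
            class = "map_states")
}

# Full node-state matrix: observed leaves on top of MAP internal states.
# Rows ordered by node id (1..n_tips tips, then internal).
node_state_matrix <- function(tree, aln, map) {
  obs <- unclass(aln)[tree$tip.label, , drop = FALSE]
  miss <- is_missing_cell(obs, attr(aln, "alphabet"))
  obs[miss] <- NA_character_
  rbind(obs, map$state)
}

#' Extract per-branch substitution events
#'
#' For every branch (parent to child) and site where the parent MAP state
#' differs from the child state (observed at leaves, MAP at internal nodes),
#' one event is emitted. Gapped or ambiguous child states, and ancestors
#' below the confidence floor, emit nothing.
#'
#' @param tree prepared `phylo`.
#' @param map a `map_states` from [map_reconstruction()].
#' @param aln the `paas_aln` supplying observed leaf states.
#' @return data frame: `branch` (child node label), `child_id`, `site`
#'   (1-based), `anc`, `der`, `anc_pp`, `der_pp`.
#' @export
extract_events <- function(tree, map, aln) {
  tp <- tree_post(tree)
  ns <- node_state_matrix(tree, aln, map)
  S <- ncol(ns)
  keep_anc <- !(map$low_confidence)
  rows <- vector("list", nrow(tp$edge))
  for (e in seq_len(nrow(tp$edge))) {
    par <- tp$edge[e, 1]; ch <- tp$edge[e, 2]
    ip <- par - tp$n_tips
    anc <- map$state[ip, ]
    der <- ns[ch, ]
    ok <- !is.na(der) & anc != der & keep_anc[ip, ]
    if (ch > tp$n_tips) ok <- ok & keep_anc[ch - tp$n_tips, ]
    if (!any(ok)) next
    s <- which(ok)
    rows[[e]] <- data.frame(
      branch = tp$labels[ch], child_id = ch, site = s,
      anc = anc[s], der = der[s],
      anc_pp = map$confidence[ip, s],
      der_pp = if (ch > tp$n_tips) map$confidence[ch - tp$n_tips, s] else 1.0,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(branch = character(), child_id = integer(),
                      site = integer(), anc = character(), der = character(),
                      anc_pp = numeric(), der_pp = numeric())
  rownames(out) <- NULL
  out
}
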