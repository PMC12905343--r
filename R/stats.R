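#' Expected probability of a convergence event for one branch pair at a site
#'
#' The probability that the two branches independently end in the same
#' derived state, different from each branch's own ancestral state:
#' \deqn{\sum_d \sum_{a \ne d} \sum_{b \ne d} q_A(a)\, q_B(b)\,
#'       P_A(a \to d)\, P_B(b \to d)}
#' where \eqn{q_A, q_B} are the marginal ancestral posteriors at the two
#' parent nodes and \eqn{P_A, P_B} the branch transition matrices under the
#' detection model. Summing these probabilities over sites and branch pairs
#' gives the Poisson expectation \eqn{\lambda} of [gene_poisson_test()].
#'
#' @param q_a,q_b ancestral posterior vectors at the parents of the two
#'   branches.
#' @param P_a,P_b transition matrices across the two branches.
#' @return scalar probability.
#' @export
expected_pair_site_prob <- function(q_a, q_b, P_a, P_b) {
  if (is.null(q_a) || is.null(q_b)) stop("missing ancestral posterior")
  stopifnot(length(q_a) == nrow(P_a), length(q_b) == nrow(P_b))
  w_a <- as.vector(q_a %*% P_a) - q_a * diag(P_a)
  w_b <- as.vector(q_b %*% P_b) - q_b * diag(P_b)
  sum(w_a * w_b)
}

# Per-pair and total expectations for a gene, reusing the per-site P
# matrices exported by the pruning engine. fg_edges/fg_nodes are parallel
# vectors over the foreground nodes of both clades.
expected_convergence <- function(post, pairs, fg_edges, fg_nodes) {
  k <- length(post$states)
  S <- length(post$loglik)
  tp <- post$tp
  # W[[node]]: k x S matrix of "changed into d" probabilities on the branch
  W <- vector("list", length(fg_nodes))
  names(W) <- as.character(fg_nodes)
  for (i in seq_along(fg_nodes)) {
    e <- fg_edges[i]
    if (!is.null(post$edge_W)) {                   # precomputed by the engine
      W[[i]] <- post$edge_W[[match(e, post$want_edges)]]
      next
    }
    par <- tp$edge[e, 1]
    q <- post$post[, , par - post$n_tips, drop = FALSE]
    dim(q) <- c(k, S)                              # k x S
    P <- post$edge_P[[match(e, post$want_edges)]][, , 1]  # global model
    astar <- max.col(t(q), ties.method = "first")
    w <- t(P[astar, , drop = FALSE])               # row astar of P, per site
    w[cbind(astar, seq_len(S))] <- 0               # require a change
    W[[i]] <- w
  }
  per_site_pair <- matrix(0, S, nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    wa <- W[[as.character(pairs$id_a[p])]]
    wb <- W[[as.character(pairs$id_b[p])]]
    per_site_pair[, p] <- colSums(wa * wb)
  }
  list(per_site_pair = per_site_pair,
       per_pair = colSums(per_site_pair),
       total = sum(per_site_pair))
}

#' One-sided Poisson test for excess convergence
#'
#' Upper-tail probability \eqn{P(X \ge n_{obs})} for
#' \eqn{X \sim \mathrm{Poisson}(\lambda)}; screens genes whose observed
#' parallel+convergent event count exceeds the model expectation.
#'
#' @param n_obs observed convergence event count (integer, >= 0).
#' @param lambda expected count, > 0.
#' @return p-value in (0, 1]; `n_obs = 0` gives exactly 1.
#' @export
gene_poisson_test <- function(n_obs, lambda) {
  if (!length(n_obs)) return(numeric(0))
  if (any(lambda <= 0)) stop("lambda must be > 0")
  if (any(n_obs < 0) || any(n_obs != round(n_obs)))
    stop("n_obs must be a non-negative integer")
  ifelse(n_obs == 0, 1, ppois(n_obs - 1, lambda, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up adjustment with monotonicity enforcement (as in
#' `p.adjust`), with input validation; genes are screened at `q < 0.1` by
#' default downstream.
#'
#' @param p_values p-values in (0, 1].
#' @return q-values of the same length.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Codon-level convergence rate ratio omegaC for a branch pair
#'
#' Counts codon sites where both branches substitute towards the same
#' outcome and compares the counts with their model expectations.
#' Nonsynonymous convergence (OCN): the derived codons encode the same amino
#' acid, which differs from both branches' ancestral amino acids.
#' Synonymous convergence (OCS): both branches reach the same derived codon
#' with the amino acid preserved. The corresponding expectations ECN/ECS sum
#' the analogous joint probabilities from the ancestral codon posteriors and
#' the codon transition matrices, and
#' \deqn{\omega_C = \frac{OCN/ECN}{OCS/ESC}.}
#' A half-count continuity correction (`correction`, default 0.5) is added
#' to all four quantities so the ratio stays finite at gene-sized counts;
#' expectations are additionally floored at `1e-8`.
#'
#' @param aln codon `paas_aln`.
#' @param tree prepared `phylo`.
#' @param branch_pair length-2 vector of child-node labels naming the two
#'   branches (typically the stem branches of the two clades).
#' @param model fitted `codon_model` (see [fit_codon_model()]).
#' @param correction continuity correction added to observed and expected
#'   counts.
#' @return an `omega_c` list: `OCN`, `ECN`, `OCS`, `ECS`, `dNC`, `dSC`,
#'   `omega_c`, plus the per-branch substitution counts.
#' @export
omega_c <- function(aln, tree, branch_pair, model, correction = 0.5) {
  stopifnot(inherits(model, "codon_model"), length(branch_pair) == 2)
  tree <- match_tree_alignment(tree, aln)
  check_alphabet_model(aln, model)
  tp <- tree_post(tree)
  ids <- node_id(tree, branch_pair)
  edges <- vapply(ids, function(n) edge_into(tp, n), integer(1))
  post <- marginal_posteriors(tree, aln, model, want_edges = edges)
  map <- map_reconstruction(post)
  ns <- node_state_matrix(tree, aln, map)
  aa_of <- setNames(translate_codons(model$states), model$states)

  anc <- lapply(seq_along(ids), function(i) {
    par <- tp$edge[edges[i], 1]
    map$state[par - tp$n_tips, ]
  })
  der <- lapply(ids, function(id) ns[id, ])

  sub1 <- !is.na(der[[1]]) & anc[[1]] != der[[1]]
  sub2 <- !is.na(der[[2]]) & anc[[2]] != der[[2]]
  both <- sub1 & sub2
  aa_anc1 <- aa_of[anc[[1]]]; aa_der1 <- aa_of[der[[1]]]
  aa_anc2 <- aa_of[anc[[2]]]; aa_der2 <- aa_of[der[[2]]]
  OCN <- sum(both & aa_der1 == aa_der2 &
               aa_der1 != aa_anc1 & aa_der2 != aa_anc2, na.rm = TRUE)
  OCS <- sum(both & der[[1]] == der[[2]] &
               aa_der1 == aa_anc1 & aa_der2 == aa_anc2, na.rm = TRUE)

  exp_counts <- expected_codon_convergence(post, edges, aa_of)
  ECN <- max(exp_counts$ECN, 1e-8)
  ECS <- max(exp_counts$ECS, 1e-8)
  dNC <- (OCN + correction) / (ECN + correction)
  dSC <- (OCS + correction) / (ECS + correction)
  structure(list(branch_pair = branch_pair, OCN = OCN, ECN = ECN,
                 OCS = OCS, ECS = ECS, dNC = dNC, dSC = dSC,
                 omega_c = dNC / dSC, correction = correction,
                 n_sub = c(sum(sub1), sum(sub2)), n_sites = ncol(ns)),
            class = "omega_c")
}

#' @export
print.omega_c <- function(x, ...) {
  cat("<omega_c> branches ", paste(x$branch_pair, collapse = " x "), "\n",
      "  OCN=", x$OCN, " ECN=", format(x$ECN, digits = 4),
      "  OCS=", x$OCS, " ECS=", format(x$ECS, digits = 4), "\n",
      "  dNC=", format(x$dNC, digits = 4), " dSC=", format(x$dSC, digits = 4),
      "  omegaC=", format(x$omega_c, digits = 4), "\n", sep = "")
  invisible(x)
}

# ECN/ECS: expected counts of joint nonsynonymous / synonymous convergent
# substitutions for two branches, from ancestral posteriors q and the codon
# P matrices (global model: P shared across sites).
expected_codon_convergence <- function(post, edges, aa_of) {
  k <- length(post$states)
  tp <- post$tp
  aa <- unname(aa_of[post$states])
  aa_classes <- split(seq_len(k), aa)
  syn_mat <- outer(aa, aa, "==")
  qs <- Ps <- vector("list", 2)
  for (i in 1:2) {
    par <- tp$edge[edges[i], 1]
    qs[[i]] <- post$post[, , par - post$n_tips]               # k x S
    Ps[[i]] <- post$edge_P[[match(edges[i], post$want_edges)]][, , 1]
  }
  V <- lapply(1:2, function(i) t(qs[[i]]) %*% Ps[[i]])        # S x k: end in d
  ECN <- 0
  for (cls in aa_classes) {
    # P(end inside the class having started outside it), per branch and site
    term <- lapply(1:2, function(i) {
      inside <- t(qs[[i]][cls, , drop = FALSE]) %*%
        Ps[[i]][cls, cls, drop = FALSE]
      rowSums(V[[i]][, cls, drop = FALSE]) - rowSums(inside)
    })
    ECN <- ECN + sum(term[[1]] * term[[2]])
  }
  U <- lapply(1:2, function(i) {
    Psyn <- Ps[[i]] * syn_mat
    diag(Psyn) <- 0                                  # require a codon change
    t(qs[[i]]) %*% Psyn                              # S x k
  })
  ECS <- sum(U[[1]] * U[[2]])
  list(ECN = ECN, ECS = ECS)
}

#' Compare focal and control convergence rates
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test; exact for small
#' tie-free samples, normal approximation with tie correction otherwise.
#'
#' @param focal_values,control_values non-empty numeric samples (e.g.
#'   omegaC values of focal versus control branch pairs).
#' @return two-sided p-value.
#' @export
rates_vs_controls <- function(focal_values, control_values) {
  if (!length(focal_values) || !length(control_values))
    stop("both samples must be non-empty")
  suppressWarnings(
    wilcox.test(focal_values, control_values, alternative = "two.sided",
                exact = NULL)$p.value)
}
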