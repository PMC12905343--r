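#' Amino-acid preference profile libraries
#'
#' A profile library is a set of frequency vectors over the 20 amino acids
#' used by the profile-shift (PCOC-like) score. The built-in library holds
#' one concentrated profile per amino acid (mass `concentration` on the
#' target residue, remainder uniform) plus the flat JTT profile, so a
#' preference shift towards any residue can be represented.
#'
#' @param concentration equilibrium mass on the preferred residue of each
#'   concentrated profile (default 0.9).
#' @return a `profile_library`: matrix (20 x K) of profiles, with
#'   `provenance` attribute.
#' @export
builtin_profiles <- function(concentration = 0.9) {
  stopifnot(concentration > 0, concentration < 1)
  k <- length(AA_STATES)
  conc <- matrix((1 - concentration) / (k - 1), k, k,
                 dimnames = list(AA_STATES, paste0("C_", AA_STATES)))
  diag(conc) <- concentration
  lib <- cbind(conc, flat = .JTT_FREQS)
  structure(lib, provenance = "built-in", class = c("profile_library", "matrix", "array"))
}

#' @rdname builtin_profiles
#' @param aln amino-acid alignment(s) whose per-site frequency vectors are
#'   clustered.
#' @param K number of profiles (>= 2).
#' @param seed RNG seed making the k-means clustering deterministic.
#' @param pseudocount pseudocount for the site-frequency vectors.
#' @return `estimate_profiles()`: a `profile_library` of K centroids
#'   (renormalised), provenance `"estimated"`.
#' @export
estimate_profiles <- function(aln, K = 10, seed = 1729, pseudocount = 0.1) {
  if (K < 2) stop("K must be >= 2 (a one-profile library cannot express a shift)")
  f <- estimate_site_frequencies(aln, pseudocount)
  X <- t(unclass(f))
  if (nrow(unique(X)) < K)
    stop("fewer distinct site-frequency vectors (", nrow(unique(X)),
         ") than K = ", K, "; use a smaller K")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  km <- kmeans(X, centers = K, nstart = 5, iter.max = 50)
  lib <- t(km$centers)
  lib[lib < 1e-6] <- 1e-6
  lib <- sweep(lib, 2, colSums(lib), "/")
  rownames(lib) <- AA_STATES
  colnames(lib) <- paste0("P", seq_len(K))
  structure(lib, provenance = "estimated", seed = seed,
            class = c("profile_library", "matrix", "array"))
}

#' Profile-shift posterior probability per site
#'
#' A simplified profile-change-with-one-change score. The null model evolves
#' the whole tree under a single preference profile (best of the library);
#' the alternative uses one profile on background branches and a different
#' one on the foreground branches, with the child state at each foreground
#' stem branch drawn directly from the foreground profile's equilibrium (the
#' "one change" component). Both models maximise over the library, and
#' \deqn{PP = L_1 / (L_0 + L_1)} with equal prior mass on the two models.
#' High PP indicates a convergent shift in amino-acid preference, which
#' captures convergence towards biochemically similar residues as well as
#' identical ones.
#'
#' @param tree prepared `phylo`.
#' @param aln amino-acid `paas_aln`.
#' @param foreground the foreground specification: a list of one or more
#'   node labels (or ids); each node's stem branch plus all branches of its
#'   descendant subtree become foreground. For a branch-pair comparison this
#'   is the pair's two nodes; for a clade-level scan, the two clade MRCAs.
#' @param library a `profile_library`.
#' @param exch exchangeability source model (default [jtt_model()]).
#' @param sites site indices to score (default all).
#' @return data frame: `site`, `pp`, `logL0`, `logL1`, `profile_bg`,
#'   `profile_fg`.
#' @export
site_pp <- function(tree, aln, foreground, library = builtin_profiles(),
                    exch = jtt_model(), sites = NULL) {
  tree <- match_tree_alignment(tree, aln)
  if (!length(foreground)) stop("foreground node set is empty")
  tp <- tree_post(tree)
  ids <- if (is.character(foreground)) node_id(tree, foreground)
         else as.integer(foreground)
  fg_nodes <- unique(unlist(lapply(ids, function(n)
    c(n, if (n > tp$n_tips) phangorn::Descendants(tree, n, type = "all")))))
  if (length(fg_nodes) >= tp$n_nodes - 1)
    stop("foreground covers the whole tree; no background branches remain")
  stem_edges <- vapply(ids, function(n) edge_into(tp, n), integer(1))
  fg_edges <- setdiff(vapply(fg_nodes, function(n) edge_into(tp, n), integer(1)),
                      stem_edges)

  states <- aln_state_matrix(aln, tree$tip.label)
  if (is.null(sites)) sites <- seq_len(ncol(states))
  allgap <- colSums(states[, sites, drop = FALSE] >= 0) == 0
  if (any(allgap)) {
    warning("skipping ", sum(allgap), " all-gap site(s) in profile scoring")
    sites <- sites[!allgap]
  }
  states <- states[, sites, drop = FALSE]
  K <- ncol(library)
  nE <- nrow(tp$edge)
  k <- nrow(library)

  # per-profile models and per-edge P cubes
  models <- lapply(seq_len(K), function(j) aa_model(exch$exch, library[, j]))
  cubes <- lapply(models, function(m) edge_P_cube(tp, m))

  L0 <- matrix(-Inf, length(sites), K)
  for (j in seq_len(K))
    L0[, j] <- prune_edge_P(tp$edge, cubes[[j]], states,
                            models[[j]]$freqs, tp$n_tips, FALSE)$loglik
  best0 <- max.col(L0, ties.method = "first")
  logL0 <- L0[cbind(seq_along(sites), best0)]

  logL1 <- rep(-Inf, length(sites))
  best1 <- matrix(1L, length(sites), 2)
  for (ja in seq_len(K)) for (jc in seq_len(K)) {
    if (ja == jc) next
    P <- cubes[[ja]]
    P[, , fg_edges] <- cubes[[jc]][, , fg_edges]
    Pstem <- matrix(rep(library[, jc], each = k), k, k)  # rows = fg equilibrium
    for (e in stem_edges) P[, , e] <- Pstem
    ll <- prune_edge_P(tp$edge, P, states, models[[ja]]$freqs, tp$n_tips,
                       FALSE)$loglik
    upd <- ll > logL1
    logL1[upd] <- ll[upd]
    best1[upd, 1] <- ja
    best1[upd, 2] <- jc
  }
  pp <- 1 / (1 + exp(logL0 - logL1))
  data.frame(site = sites, pp = pp, logL0 = logL0, logL1 = logL1,
             profile_bg = colnames(library)[best1[, 1]],
             profile_fg = colnames(library)[best1[, 2]],
             null_profile = colnames(library)[best0],
             stringsAsFactors = FALSE)
}

#' Threshold profile-shift posteriors
#'
#' @param pp_table output of [site_pp()] (or a numeric vector of PPs).
#' @param threshold strict lower bound; a site is called only when
#'   `pp > threshold` (default 0.99, so `pp = 0.99` exactly is not called).
#' @return vector of passing site indices (or positions for a bare vector).
#' @export
call_sites <- function(pp_table, threshold = 0.99) {
  if (is.data.frame(pp_table)) {
    pp_table$site[pp_table$pp > threshold]
  } else {
    which(pp_table > threshold)
  }
}
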