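#' Enumerate cross-clade branch-pair comparisons
#'
#' The Cartesian product of the two clades' foreground node sets, in
#' deterministic (postorder x postorder) order. Two 3-leaf clades (3 terminal
#' + 2 ancestral nodes each) yield 25 comparisons.
#'
#' @param clade_a,clade_b disjoint [clade_spec()] objects.
#' @return data frame with `node_a`, `node_b` (labels) and `id_a`, `id_b`.
#' @export
enumerate_pairs <- function(clade_a, clade_b) {
  stopifnot(inherits(clade_a, "clade_spec"), inherits(clade_b, "clade_spec"))
  if (length(intersect(clade_a$node_ids, clade_b$node_ids)))
    stop("clades overlap; branch pairs must come from disjoint clades")
  g <- expand.grid(ia = seq_along(clade_a$node_ids),
                   ib = seq_along(clade_b$node_ids))
  g <- g[order(g$ia, g$ib), ]
  data.frame(node_a = clade_a$node_labels[g$ia],
             node_b = clade_b$node_labels[g$ib],
             id_a = clade_a$node_ids[g$ia],
             id_b = clade_b$node_ids[g$ib],
             stringsAsFactors = FALSE, row.names = NULL)
}

# Vectorised category assignment from ancestral/derived state 4-tuples.
classify_states <- function(anc_a, der_a, anc_b, der_b) {
  out <- rep("none", length(anc_a))
  changed <- !is.na(anc_a) & !is.na(der_a) & !is.na(anc_b) & !is.na(der_b) &
    anc_a != der_a & anc_b != der_b
  same_der <- changed & der_a == der_b
  out[same_der & anc_a == anc_b] <- "parallel"
  out[same_der & anc_a != anc_b] <- "convergent"
  out
}

#' Classify a cross-clade substitution pair
#'
#' Parallel: identical substitutions derived from the same ancestral amino
#' acid on both branches. Convergent: the same derived amino acid reached
#' from different ancestral amino acids. Anything else (including different
#' derived states) is `"none"`.
#'
#' @param event_a,event_b single substitution events (rows of
#'   [extract_events()] output, or lists with `site`, `anc`, `der`) from
#'   branches of different clades.
#' @return `"parallel"`, `"convergent"` or `"none"`.
#' @export
classify_pair_site <- function(event_a, event_b) {
  if (event_a$site != event_b$site)
    stop("events are at different sites (", event_a$site, " vs ",
         event_b$site, ")")
  classify_states(event_a$anc, event_a$der, event_b$anc, event_b$der)
}

#' Conservation-pattern (CCS) classification of a convergent site
#'
#' A site passes the conservation screen only when its background (all
#' non-foreground taxa) is moderately conserved: at most
#' `max_background_states` distinct residues with a majority residue at
#' frequency at least `min_background_majority` (gaps excluded; columns with
#' more than `max_background_gap` missing background taxa are not
#' classifiable). Passing sites are assigned a foreground pattern class:
#' `S2S` (one shared ancestral and one shared derived state), `D2S`
#' (different ancestral states to one specific derived state), or `S2D` (one
#' specific ancestral state to different derived states).
#'
#' @param background_states character vector of residues observed in the
#'   background taxa at the site (may include gaps).
#' @param anc_states,der_states ancestral and derived states of all
#'   foreground substitution events at the site (both clades pooled).
#' @param max_background_states maximum distinct background residues
#'   (default 2).
#' @param min_background_majority minimum frequency of the majority
#'   background residue (default 0.8).
#' @param max_background_gap maximum tolerated fraction of missing
#'   background taxa (default 0.5).
#' @return `"S2S"`, `"D2S"`, `"S2D"`, or `"none"`.
#' @export
ccs_classify <- function(background_states, anc_states, der_states,
                         max_background_states = 2,
                         min_background_majority = 0.8,
                         max_background_gap = 0.5) {
  if (!length(anc_states) || !length(der_states)) return("none")
  if (!ccs_background_ok(background_states, max_background_states,
                         min_background_majority, max_background_gap))
    return("none")
  n_anc <- length(unique(anc_states))
  n_der <- length(unique(der_states))
  if (n_anc == 1 && n_der == 1) return("S2S")
  if (n_anc >= 2 && n_der == 1) return("D2S")
  if (n_anc == 1 && n_der >= 2) return("S2D")
  "none"
}

# The background-conservation screen on its own.
ccs_background_ok <- function(background_states, max_background_states = 2,
                              min_background_majority = 0.8,
                              max_background_gap = 0.5) {
  miss <- background_states %in% MISSING_AA | is.na(background_states)
  bg <- background_states[!miss]
  if (!length(bg) || mean(miss) > max_background_gap) return(FALSE)
  tab <- table(bg)
  length(tab) <= max_background_states &&
    max(tab) / sum(tab) >= min_background_majority
}

#' Build swapped-outgroup control scenarios
#'
#' Each scenario replaces one or both focal clades with a control lineage;
#' the identical downstream pipeline is then run on the scenario. A scenario
#' is given either as a list with elements `a` and `b` (each a character
#' vector of leaves, or the keyword `"focalA"`/`"focalB"` to keep a focal
#' clade) or as an unnamed list of two leaf vectors.
#'
#' @param tree prepared `phylo`.
#' @param focal_a,focal_b the focal [clade_spec()]s.
#' @param control_lineages list of scenarios (see details).
#' @return list of scenarios, each a list with clade_specs `a`, `b` and a
#'   `name`.
#' @export
swap_control <- function(tree, focal_a, focal_b, control_lineages) {
  if (!length(control_lineages)) {
    warning("empty control lineage list; no control scenarios built")
    return(list())
  }
  build_side <- function(x, keyword_name, i, side) {
    if (is.character(x) && length(x) == 1 && x %in% c("focalA", "focalB"))
      return(if (x == "focalA") focal_a else focal_b)
    members <- as.character(unlist(x))
    for (f in list(focal_a, focal_b)) {
      ov <- intersect(members, f$members)
      if (length(ov))
        stop("control scenario ", i, " (", side, ") overlaps focal clade '",
             f$name, "': ", paste(ov, collapse = ", "))
    }
    clade_spec(tree, members, paste0("control", i, side))
  }
  out <- vector("list", length(control_lineages))
  for (i in seq_along(control_lineages)) {
    sc <- control_lineages[[i]]
    if (is.null(names(sc))) names(sc) <- c("a", "b")[seq_along(sc)]
    a <- build_side(sc$a, "focalA", i, "a")
    b <- build_side(sc$b, "focalB", i, "b")
    if (identical(sort(a$members), sort(focal_a$members)) &&
        identical(sort(b$members), sort(focal_b$members)))
      stop("control scenario ", i, " equals the focal configuration")
    if (length(intersect(a$members, b$members)))
      stop("control scenario ", i, ": the two clades overlap")
    out[[i]] <- list(a = a, b = b, name = paste0("control", i))
  }
  out
}

#' Scan one gene for parallel/convergent substitutions
#'
#' Runs the per-gene detection core: ancestral reconstruction under the
#' requested model (default: JTT with per-site frequencies estimated from
#' this gene), substitution-event extraction, branch-pair enumeration,
#' parallel/convergent classification, the CCS conservation screen, and the
#' observed/expected convergence counts feeding the gene-level Poisson test.
#'
#' @param tree prepared `phylo`.
#' @param aln amino-acid `paas_aln`.
#' @param clade_a,clade_b focal [clade_spec()]s (on the tree matched to this
#'   gene's taxa).
#' @param model substitution model; `NULL` builds JTT-fsite from the gene.
#' @param conf_floor MAP confidence floor for event extraction (default 0).
#' @param ccs list of CCS knobs: `max_background_states`,
#'   `min_background_majority`, `max_background_gap`, and `pattern`
#'   (`"pair"`, default: the substitution pattern is read off each branch
#'   pair; `"pooled"`: [ccs_classify()] over all foreground events at the
#'   site).
#' @param pseudocount pseudocount for site-frequency estimation.
#' @return a `gene_scan`: `calls` (one row per site x pair with a
#'   parallel/convergent call), `events`, `pairs`, `n_obs`, `lambda`,
#'   `per_pair` (observed and expected per comparison), and the
#'   `ancestral_posterior`.
#' @export
scan_gene <- function(tree, aln, clade_a, clade_b, model = NULL,
                      conf_floor = 0,
                      ccs = list(max_background_states = 2,
                                 min_background_majority = 0.8,
                                 max_background_gap = 0.5,
                                 pattern = "pair"),
                      pseudocount = 0.1) {
  tree <- match_tree_alignment(tree, aln)
  if (is.null(model))
    model <- with_site_frequencies(jtt_model(),
                                   estimate_site_frequencies(aln, pseudocount))
  tp <- tree_post(tree)
  fg_nodes <- c(clade_a$node_ids, clade_b$node_ids)
  fg_edges <- vapply(fg_nodes, function(n) edge_into(tp, n), integer(1))
  post <- marginal_posteriors(tree, aln, model, want_edges = fg_edges,
                              keep_P = !inherits(model, "aa_model_fsite"),
                              map_w = TRUE)
  map <- map_reconstruction(post, conf_floor = conf_floor)
  events <- extract_events(tree, map, aln)
  pairs <- enumerate_pairs(clade_a, clade_b)
  ns <- node_state_matrix(tree, aln, map)
  S <- ncol(ns)
  n_tips <- tp$n_tips
  parent_of <- function(id) tp$edge[edge_into(tp, id), 1]

  anc_der <- function(id) {
    par <- parent_of(id)
    list(anc = map$state[par - n_tips, ], der = ns[id, ])
  }
  cache <- lapply(setNames(fg_nodes, fg_nodes), anc_der)

  calls <- vector("list", nrow(pairs))
  n_obs_pair <- integer(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    A <- cache[[as.character(pairs$id_a[p])]]
    B <- cache[[as.character(pairs$id_b[p])]]
    cat_p <- classify_states(A$anc, A$der, B$anc, B$der)
    hit <- which(cat_p != "none")
    n_obs_pair[p] <- length(hit)
    if (length(hit))
      calls[[p]] <- data.frame(
        site = hit, node_a = pairs$node_a[p], node_b = pairs$node_b[p],
        anc_a = A$anc[hit], der_a = A$der[hit],
        anc_b = B$anc[hit], der_b = B$der[hit],
        category = cat_p[hit], stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)
  if (is.null(calls))
    calls <- data.frame(site = integer(), node_a = character(),
                        node_b = character(), anc_a = character(),
                        der_a = character(), anc_b = character(),
                        der_b = character(), category = character())

  # CCS classification per called site (background = non-foreground leaves)
  bg_taxa <- setdiff(tree$tip.label, c(clade_a$members, clade_b$members))
  fg_children <- fg_nodes
  pattern <- if (is.null(ccs$pattern)) "pair" else ccs$pattern
  calls$ccs_class <- character(nrow(calls))
  if (nrow(calls)) {
    calls$ccs_class <- "none"
    for (s in unique(calls$site)) {
      at_s <- calls$site == s
      if (pattern == "pooled") {
        # pattern from all foreground events at the site (both clades)
        ev <- events[events$site == s & events$child_id %in% fg_children, ]
        cls <- ccs_classify(unclass(aln)[bg_taxa, s], ev$anc, ev$der,
                            ccs$max_background_states,
                            ccs$min_background_majority,
                            ccs$max_background_gap)
        calls$ccs_class[at_s] <- cls
      } else {
        # background conservation assessed at the site; the substitution
        # pattern is read off each branch pair: one shared derived state
        # from one shared (S2S) or two distinct (D2S) ancestral states
        ok <- ccs_background_ok(unclass(aln)[bg_taxa, s],
                                ccs$max_background_states,
                                ccs$min_background_majority,
                                ccs$max_background_gap)
        calls$ccs_class[at_s] <- if (!ok) "none" else
          ifelse(calls$anc_a[at_s] == calls$anc_b[at_s], "S2S", "D2S")
      }
    }
  }
  calls$ccs_pass <- calls$ccs_class != "none"

  lam <- expected_convergence(post, pairs, fg_edges, fg_nodes)
  per_pair <- data.frame(pairs, n_obs = n_obs_pair, lambda = lam$per_pair,
                         stringsAsFactors = FALSE)
  structure(list(calls = calls, events = events, pairs = pairs,
                 n_obs = sum(n_obs_pair), lambda = lam$total,
                 per_pair = per_pair, per_site_pair = lam$per_site_pair,
                 posterior = post, map = map, tree = tree,
                 clade_a = clade_a, clade_b = clade_b, model = model),
            class = "gene_scan")
}

#' @export
print.gene_scan <- function(x, ...) {
  cat("<gene_scan> ", length(x$posterior$loglik), " sites, ",
      nrow(x$pairs), " branch pairs\n", sep = "")
  cat("  ", x$n_obs, " observed convergence events (expected ",
      format(x$lambda, digits = 4), ")\n", sep = "")
  cat("  ", nrow(x$calls), " site x pair calls, ",
      sum(x$calls$ccs_pass), " past the CCS screen\n", sep = "")
  invisible(x)
}

#' Collate per-pair calls into gene-level site lists and pair counts
#'
#' A site is counted once per gene even when called in several branch pairs;
#' per-pair counts are kept for comparison-level reporting.
#'
#' @param gene_calls named list (by gene id) of `calls` data frames from
#'   [scan_gene()], or of `gene_scan` objects.
#' @param filtered if `TRUE` (default) only calls passing the CCS screen
#'   (and the profile-shift threshold, when a `pp` column is present) are
#'   counted.
#' @return list with `gene_sites` (gene, n_sites, sites) and `pair_counts`
#'   (node_a, node_b, n_calls summed over genes), both sorted.
#' @export
collate_paas <- function(gene_calls, filtered = TRUE) {
  if (!length(gene_calls))
    return(list(gene_sites = data.frame(gene = character(), n_sites = integer(),
                                        sites = character()),
                pair_counts = data.frame(node_a = character(),
                                         node_b = character(),
                                         n_calls = integer())))
  calls <- lapply(gene_calls, function(x) if (inherits(x, "gene_scan")) x$calls else x)
  keep <- lapply(calls, function(cl) {
    if (!nrow(cl)) return(cl)
    ok <- rep(TRUE, nrow(cl))
    if (filtered) {
      ok <- cl$ccs_pass
      if (!is.null(cl$pp_pass)) ok <- ok & cl$pp_pass
    }
    cl[ok, , drop = FALSE]
  })
  gene_sites <- data.frame(
    gene = names(keep),
    n_sites = vapply(keep, function(cl) length(unique(cl$site)), integer(1)),
    sites = vapply(keep, function(cl)
      paste(sort(unique(cl$site)), collapse = ","), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  gene_sites <- gene_sites[order(gene_sites$gene), ]
  all_calls <- do.call(rbind, keep)
  pair_counts <- if (!is.null(all_calls) && nrow(all_calls)) {
    agg <- aggregate(list(n_calls = all_calls$site),
                     by = list(node_a = all_calls$node_a,
                               node_b = all_calls$node_b), FUN = length)
    agg[order(agg$node_a, agg$node_b), ]
  } else data.frame(node_a = character(), node_b = character(),
                    n_calls = integer())
  rownames(pair_counts) <- NULL
  list(gene_sites = gene_sites, pair_counts = pair_counts)
}
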