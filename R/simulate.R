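# Synthetic-data generators with known ground truth. Every generator is a
# pure function of (parameters, seed): rerunning with the echoed parameters
# reproduces data and truth bit-for-bit.

# Fixed 22-taxon ungulate-style topology: two disjoint 3-leaf desert-adapted
# focal clades (camels; hippotragine antelopes) in distant subtrees, and
# seven non-focal monophyletic lineages usable as swapped-outgroup controls.
# Branch lengths are fixed constants in [0.02, 0.30] (expected
# substitutions/site), chosen so ancestral reconstruction is informative but
# not trivial.
.DEFAULT_NEWICK <- paste0(
  "((Equus_caballus:0.05,Equus_asinus:0.05):0.22,",
  "(((Camelus_bactrianus:0.12,(Camelus_ferus:0.12,Camelus_dromedarius:0.12)",
  ":0.09):0.12,(Vicugna_pacos:0.05,Lama_glama:0.05):0.09):0.08,",
  "((Sus_scrofa:0.06,Phacochoerus_africanus:0.06):0.10,",
  "(Hippopotamus_amphibius:0.14,((Cervus_elaphus:0.05,Rangifer_tarandus:0.05)",
  ":0.06,((Bubalus_bubalis:0.05,(Bos_taurus:0.03,Bos_mutus:0.03):0.03):0.05,",
  "((Ovis_aries:0.04,Capra_hircus:0.04):0.04,",
  "((Kobus_ellipsiprymnus:0.04,Kobus_leche:0.04):0.04,",
  "(Addax_nasomaculatus:0.12,(Oryx_dammah:0.12,Oryx_gazella:0.12):0.09):0.12)",
  ":0.03):0.03):0.04):0.03):0.04):0.05):0.22);")

#' Default study design: tree, focal clades and control lineages
#'
#' A fixed rooted 22-leaf tree mimicking a two-desert-clade ungulate design:
#' a 3-species camel clade and a 3-species hippotragine antelope clade as
#' focal foregrounds (each contributing 3 terminal + 2 ancestral nodes, so
#' 25 branch-pair comparisons), plus seven disjoint non-focal monophyletic
#' lineages used to build swapped-outgroup control scenarios (scenario i
#' replaces one focal clade - alternating A and B - with control lineage i).
#'
#' @param scale multiplies all branch lengths (default 1).
#' @param n_controls number of control scenarios (up to 7, default 7).
#' @return list: `tree` (prepared `phylo`), `focal_a`, `focal_b`
#'   ([clade_spec()]s), `control_sets` (named list of leaf sets), and
#'   `scenarios` (control scenario specs for [swap_control()]).
#' @export
make_default_tree <- function(scale = 1, n_controls = 7) {
  stopifnot(scale > 0, n_controls >= 0, n_controls <= 7)
  tree <- ape::read.tree(text = .DEFAULT_NEWICK)
  tree$edge.length <- tree$edge.length * scale
  tree <- prepare_tree(tree)
  focal_a <- clade_spec(tree, c("Camelus_bactrianus", "Camelus_ferus",
                                "Camelus_dromedarius"), "Camelus")
  focal_b <- clade_spec(tree, c("Addax_nasomaculatus", "Oryx_dammah",
                                "Oryx_gazella"), "Hippotraginae")
  control_sets <- list(
    Laminae   = c("Vicugna_pacos", "Lama_glama"),
    Suidae    = c("Sus_scrofa", "Phacochoerus_africanus"),
    Cervidae  = c("Cervus_elaphus", "Rangifer_tarandus"),
    Bovina    = c("Bubalus_bubalis", "Bos_taurus", "Bos_mutus"),
    Caprinae  = c("Ovis_aries", "Capra_hircus"),
    Reduncinae = c("Kobus_ellipsiprymnus", "Kobus_leche"),
    Equus     = c("Equus_caballus", "Equus_asinus"))
  control_sets <- control_sets[seq_len(n_controls)]
  scenarios <- lapply(seq_along(control_sets), function(i) {
    if (i %% 2 == 1) list(a = control_sets[[i]], b = "focalB")
    else list(a = "focalA", b = control_sets[[i]])
  })
  names(scenarios) <- names(control_sets)
  list(tree = tree, focal_a = focal_a, focal_b = focal_b,
       control_sets = control_sets, scenarios = scenarios)
}

# eigen machinery for simulating under (exch, pi) site models
sim_site_eig <- function(exch, pi) {
  m <- aa_model(exch, pi, states = as.character(seq_along(pi)))
  m$eig
}

sim_P <- function(eig, t) {
  E <- eig$vectors * rep(exp(eig$values * t), each = length(eig$sqp))
  P <- E %*% t(eig$vectors) * ((1 / eig$sqp) %o% eig$sqp)
  P[P < 0] <- 0
  P / rowSums(P)
}

# vectorised: children states for all sites on one edge
sample_children <- function(P, parent_states) {
  k <- nrow(P)
  out <- integer(length(parent_states))
  for (a in unique(parent_states)) {
    idx <- which(parent_states == a)
    out[idx] <- sample.int(k, length(idx), replace = TRUE, prob = P[a, ])
  }
  out
}

# node x site integer state matrix simulated under a global model
sim_states_global <- function(tp, model, S) {
  k <- length(model$freqs)
  ns <- matrix(0L, tp$n_nodes, S)
  ns[tp$root, ] <- sample.int(k, S, replace = TRUE, prob = model$freqs)
  Ps <- lapply(seq_len(nrow(tp$edge)), function(e)
    transition_matrix(model, tp$edge_length[e]))
  for (e in rev(seq_len(nrow(tp$edge)))) {      # preorder
    par <- tp$edge[e, 1]; ch <- tp$edge[e, 2]
    ns[ch, ] <- sample_children(Ps[[e]], ns[par, ])
  }
  ns
}

states_to_aln <- function(tp, node_states, states, alphabet) {
  m <- matrix(states[node_states[seq_len(tp$n_tips), , drop = FALSE]],
              tp$n_tips, ncol(node_states))
  rownames(m) <- tp$labels[seq_len(tp$n_tips)]
  paas_alignment(m, alphabet)
}

#' Simulate an alignment on a tree (null model, known truth)
#'
#' Root states are drawn from the model's equilibrium (per-site equilibria
#' for an `aa_model_fsite` family) and evolved down every branch via
#' P(t) = exp(Qt).
#'
#' @param tree prepared `phylo`.
#' @param model `aa_model`, `codon_model`, or `aa_model_fsite` family (the
#'   family must cover `n_sites` sites).
#' @param n_sites number of sites (alignment columns) to simulate.
#' @param seed RNG seed; same seed, same output.
#' @return list with `alignment` (a `paas_aln`), `truth` (per-site labels,
#'   all `"background"`), and `node_states` (all-node integer states, rows
#'   in node-id order).
#' @export
simulate_msa <- function(tree, model, n_sites, seed) {
  stopifnot(n_sites >= 1)
  tp <- tree_post(tree)
  set.seed(seed)
  if (inherits(model, "aa_model_fsite")) {
    if (ncol(model$pis) != n_sites)
      stop("fsite family covers ", ncol(model$pis), " sites, need ", n_sites)
    ns <- matrix(0L, tp$n_nodes, n_sites)
    for (s in seq_len(n_sites)) {
      eig <- sim_site_eig(model$exch, model$pis[, s])
      Ps <- lapply(tp$edge_length, function(t) sim_P(eig, t))
      ns[tp$root, s] <- sample.int(length(model$states), 1,
                                   prob = model$pis[, s])
      for (e in rev(seq_len(nrow(tp$edge))))
        ns[tp$edge[e, 2], s] <- sample.int(
          length(model$states), 1, prob = Ps[[e]][ns[tp$edge[e, 1], s], ])
    }
    alphabet <- "amino20"
  } else {
    ns <- sim_states_global(tp, model, n_sites)
    alphabet <- if (inherits(model, "codon_model")) "codon" else
      if (length(model$states) == 20) "amino20" else "nucleotide4"
  }
  truth <- data.frame(site = seq_len(n_sites), label = "background",
                      target = NA_character_, stringsAsFactors = FALSE)
  attr(truth, "params") <- list(n_sites = n_sites, seed = seed,
                                generator = "simulate_msa")
  aln <- if (length(model$states) %in% c(4, 20, 61))
    states_to_aln(tp, ns, model$states, alphabet) else NULL
  list(alignment = aln, truth = truth, node_states = ns)
}

#' Per-site constrained background frequencies
#'
#' Draws, for each site, a preference profile concentrated on one random
#' residue (mass `concentration`, remainder uniform). This emulates the
#' site-specific purifying constraint of real protein alignments, under
#' which most columns are moderately conserved - the regime the CCS screen
#' assumes.
#'
#' @param n_sites number of sites.
#' @param concentration equilibrium mass on the preferred residue.
#' @param seed RNG seed.
#' @return 20 x n_sites frequency matrix (attribute `preferred` gives each
#'   site's preferred residue).
#' @export
constrained_site_frequencies <- function(n_sites, concentration = 0.9, seed) {
  set.seed(seed)
  k <- length(AA_STATES)
  pref <- sample.int(k, n_sites, replace = TRUE)
  f <- matrix((1 - concentration) / (k - 1), k, n_sites)
  f[cbind(pref, seq_len(n_sites))] <- concentration
  rownames(f) <- AA_STATES
  attr(f, "preferred") <- AA_STATES[pref]
  f
}

#' Simulate convergent amino-acid preference shifts in two focal clades
#'
#' Background sites evolve under the background model everywhere. A fraction
#' of sites is "shifted": outside the foreground subtrees they evolve under
#' the background model, but on all foreground branches of both clades they
#' evolve under a shifted profile (same exchangeabilities, equilibrium mass
#' `concentration` on a random target residue), and the child state of each
#' foreground stem branch is resampled from the shifted profile - the
#' convergent-shift scenario the profile-shift score is designed to detect.
#'
#' @param tree prepared `phylo`.
#' @param foregrounds list of two [clade_spec()]s (or leaf-member vectors).
#' @param model background model: an `aa_model`, an `aa_model_fsite` family
#'   covering `n_sites`, or `NULL` (default) for per-site constrained
#'   frequencies from [constrained_site_frequencies()].
#' @param n_sites number of sites.
#' @param shift_fraction fraction of sites shifted, in `[0, 1)`; the truth
#'   lists exactly `floor(shift_fraction * n_sites)` shifted sites.
#' @param concentration equilibrium mass on the target residue, in (0, 1].
#' @param seed RNG seed.
#' @param bg_concentration strength of the per-site background constraint
#'   used when `model = NULL` (default 0.97, emulating the strongly
#'   conserved columns the CCS screen targets).
#' @param one_clade_only if `TRUE`, apply the shift to the first clade only
#'   (a non-convergent control mode for detector false-positive testing).
#' @return list: `alignment`, `truth` (site, label, target residue),
#'   `node_states`.
#' @export
inject_convergent_shifts <- function(tree, foregrounds, model = NULL, n_sites,
                                     shift_fraction = 0.05,
                                     concentration = 0.9, seed,
                                     bg_concentration = 0.97,
                                     one_clade_only = FALSE) {
  stopifnot(shift_fraction >= 0, shift_fraction < 1,
            concentration > 0, concentration <= 1)
  tp <- tree_post(tree)
  clades <- lapply(seq_along(foregrounds), function(i) {
    f <- foregrounds[[i]]
    if (inherits(f, "clade_spec")) f
    else clade_spec(tree, f, paste0("foreground", i))
  })
  fg_nodes <- unique(unlist(lapply(clades, `[[`, "node_ids")))
  if (length(fg_nodes) >= tp$n_nodes - 1)
    stop("foreground covers the whole tree")
  if (one_clade_only) clades <- clades[1]
  stem_nodes <- vapply(clades, `[[`, integer(1), "mrca")
  shift_nodes <- unique(unlist(lapply(clades, `[[`, "node_ids")))
  stem_edges <- vapply(stem_nodes, function(n) edge_into(tp, n), integer(1))
  shift_edges <- vapply(shift_nodes, function(n) edge_into(tp, n), integer(1))

  exch <- jtt_model()$exch
  if (is.null(model)) {
    pis <- constrained_site_frequencies(n_sites, concentration = bg_concentration,
                                        seed = seed + 1L)
    model <- with_site_frequencies(jtt_model(), pis)
  }
  n_shift <- floor(shift_fraction * n_sites)
  if (n_shift == 0) {
    out <- simulate_msa(tree, model, n_sites, seed)
    attr(out$truth, "params") <- list(n_sites = n_sites, seed = seed,
                                      shift_fraction = shift_fraction,
                                      concentration = concentration,
                                      generator = "inject_convergent_shifts")
    return(out)
  }

  set.seed(seed)
  shifted <- sort(sample.int(n_sites, n_shift))
  k <- length(AA_STATES)
  # a preference shift moves preference to a residue the site does not
  # already prefer: the target is drawn from the 19 non-preferred residues
  pref <- if (inherits(model, "aa_model_fsite"))
    apply(model$pis[, shifted, drop = FALSE], 2, which.max)
  else rep(which.max(model$freqs), n_shift)
  targets <- vapply(pref, function(p) {
    ch <- setdiff(seq_len(k), p)
    ch[sample.int(k - 1L, 1)]
  }, integer(1))
  per_site_pi <- function(s) {
    if (inherits(model, "aa_model_fsite")) model$pis[, s] else model$freqs
  }
  shift_pi <- function(target) {
    p <- rep((1 - concentration) / (k - 1), k)
    p[target] <- concentration
    if (concentration == 1) { p <- rep(1e-9, k); p[target] <- 1 }
    p / sum(p)
  }

  ns <- matrix(0L, tp$n_nodes, n_sites)
  is_shift_edge <- seq_len(nrow(tp$edge)) %in% shift_edges
  is_stem_edge <- seq_len(nrow(tp$edge)) %in% stem_edges
  for (s in seq_len(n_sites)) {
    pi_bg <- per_site_pi(s)
    eig_bg <- sim_site_eig(exch, pi_bg)
    sh <- match(s, shifted)
    if (!is.na(sh)) {
      pi_fg <- shift_pi(targets[sh])
      eig_fg <- sim_site_eig(exch, pmax(pi_fg, 1e-9) / sum(pmax(pi_fg, 1e-9)))
    }
    ns[tp$root, s] <- sample.int(k, 1, prob = pi_bg)
    for (e in rev(seq_len(nrow(tp$edge)))) {
      par <- tp$edge[e, 1]; ch <- tp$edge[e, 2]
      if (!is.na(sh) && is_stem_edge[e]) {
        ns[ch, s] <- sample.int(k, 1, prob = pi_fg)
      } else {
        eig <- if (!is.na(sh) && is_shift_edge[e]) eig_fg else eig_bg
        P <- sim_P(eig, tp$edge_length[e])
        ns[ch, s] <- sample.int(k, 1, prob = P[ns[par, s], ])
      }
    }
  }
  truth <- data.frame(site = seq_len(n_sites), label = "background",
                      target = NA_character_, stringsAsFactors = FALSE)
  truth$label[shifted] <- "shifted"
  truth$target[shifted] <- AA_STATES[targets]
  attr(truth, "params") <- list(n_sites = n_sites, seed = seed,
                                shift_fraction = shift_fraction,
                                concentration = concentration,
                                generator = "inject_convergent_shifts")
  list(alignment = states_to_aln(tp, ns, AA_STATES, "amino20"),
       truth = truth, node_states = ns)
}

#' Simulate a codon alignment, optionally with forced convergent changes
#'
#' Codon columns evolve under the codon model. With a `convergent_config`, a
#' fraction of sites is forced: on both focal stem branches the child codon
#' is overwritten with a codon encoding a common amino acid different from
#' the ancestral amino acid on both sides, and evolution continues below.
#'
#' @param tree prepared `phylo`.
#' @param codon_model a `codon_model`.
#' @param n_sites number of codon sites.
#' @param convergent_config `NULL` for a pure null, or a list with
#'   `fraction` (in `[0, 1)`) and `clades` (list of two [clade_spec()]s or
#'   member vectors naming the focal clades whose stems are forced).
#' @param seed RNG seed.
#' @return list: `alignment` (codon `paas_aln`), `truth`, `node_states`.
#' @export
simulate_codon_msa <- function(tree, codon_model, n_sites,
                               convergent_config = NULL, seed) {
  stopifnot(inherits(codon_model, "codon_model"))
  if (!is.null(convergent_config) && convergent_config$fraction >= 1)
    stop("forced-convergence fraction must be < 1")
  tp <- tree_post(tree)
  set.seed(seed)
  ns <- sim_states_global(tp, codon_model, n_sites)
  truth <- data.frame(site = seq_len(n_sites), label = "background",
                      target = NA_character_, stringsAsFactors = FALSE)

  if (!is.null(convergent_config) && convergent_config$fraction > 0) {
    clades <- lapply(seq_along(convergent_config$clades), function(i) {
      f <- convergent_config$clades[[i]]
      if (inherits(f, "clade_spec")) f else
        clade_spec(tree, f, paste0("forced", i))
    })
    stems <- vapply(clades, `[[`, integer(1), "mrca")
    stem_par <- vapply(stems, function(n) tp$edge[edge_into(tp, n), 1],
                       integer(1))
    n_forced <- floor(convergent_config$fraction * n_sites)
    forced <- sort(sample.int(n_sites, n_forced))
    aa <- names(codon_states())
    aa_letters <- unique(aa)
    codons_of <- split(seq_along(aa), aa)
    for (s in forced) {
      anc_aa <- aa[ns[stem_par, s]]
      choices <- setdiff(aa_letters, anc_aa)
      target <- choices[sample.int(length(choices), 1)]
      truth$label[s] <- "forced"
      truth$target[s] <- target
      for (ci in seq_along(stems)) {
        cod <- codons_of[[target]]
        ns[stems[ci], s] <- cod[sample.int(length(cod), 1)]
      }
    }
    # re-evolve below the stems at forced sites
    for (ci in seq_along(stems)) {
      desc_edges <- vapply(setdiff(clades[[ci]]$node_ids, stems[ci]),
                           function(n) edge_into(tp, n), integer(1))
      desc_edges <- desc_edges[order(-desc_edges)]   # preorder within clade
      for (e in desc_edges) {
        P <- transition_matrix(codon_model, tp$edge_length[e])
        ns[tp$edge[e, 2], forced] <-
          sample_children(P, ns[tp$edge[e, 1], forced])
      }
    }
  }
  attr(truth, "params") <- list(n_sites = n_sites, seed = seed,
                                config = convergent_config,
                                generator = "simulate_codon_msa")
  list(alignment = states_to_aln(tp, ns, codon_model$states, "codon"),
       truth = truth, node_states = ns)
}
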