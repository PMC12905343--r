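#' Run the full convergence-detection pipeline
#'
#' Per gene and scenario: ancestral reconstruction, substitution events,
#' branch-pair enumeration, parallel/convergent classification, CCS
#' conservation screen, profile-shift posterior scoring of candidate calls,
#' gene-level Poisson test of observed versus expected convergence with
#' pooled Benjamini-Hochberg correction, and (when codon alignments are
#' supplied) the omegaC screen with a focal-versus-control rank-sum
#' comparison. Control scenarios run through the identical code path as the
#' focal scenario.
#'
#' @param genes named list of amino-acid `paas_aln` objects.
#' @param tree prepared `phylo` covering all taxa.
#' @param focal_a,focal_b focal clades ([clade_spec()] or leaf vectors).
#' @param controls control scenarios: output of [swap_control()] or the raw
#'   scenario list accepted by it (default none).
#' @param codon_genes optional named list of codon `paas_aln` objects for
#'   the omegaC screen.
#' @param thresholds list of screen thresholds: `pp` (profile-shift PP,
#'   default 0.99, strict), `fdr` (BH q cut, default 0.1), `omega_c`
#'   (default 1), and the CCS knobs `ccs_max_background_states` (2),
#'   `ccs_min_background_majority` (0.8), `ccs_max_background_gap` (0.5).
#' @param profile_library profile library for the PP score (default
#'   [builtin_profiles()]).
#' @param conf_floor MAP-confidence floor for event extraction (default 0).
#' @param out_dir if non-`NULL`, per-stage TSVs are written there
#'   (deterministic content: identical inputs give byte-identical files).
#' @param verbose print per-scenario progress to stderr.
#' @return a `paas_scan` object; see [report_summary()].
#' @export
run_pipeline <- function(genes, tree, focal_a, focal_b, controls = list(),
                         codon_genes = NULL, thresholds = list(),
                         profile_library = builtin_profiles(),
                         conf_floor = 0, out_dir = NULL, verbose = FALSE) {
  thr <- utils::modifyList(list(
    pp = 0.99, fdr = 0.1, omega_c = 1,
    ccs_max_background_states = 2, ccs_min_background_majority = 0.8,
    ccs_max_background_gap = 0.5, ccs_pattern = "pair"), thresholds)
  known_thr <- c("pp", "fdr", "omega_c", "ccs_max_background_states",
                 "ccs_min_background_majority", "ccs_max_background_gap",
                 "ccs_pattern")
  if (length(setdiff(names(thresholds), known_thr)))
    stop("unknown threshold key(s): ",
         paste(setdiff(names(thresholds), known_thr), collapse = ", "))
  if (length(genes) && (is.null(names(genes)) || any(!nzchar(names(genes)))))
    stop("genes must be a named list of alignments")
  if (!inherits(focal_a, "clade_spec")) focal_a <- clade_spec(tree, focal_a, "focalA")
  if (!inherits(focal_b, "clade_spec")) focal_b <- clade_spec(tree, focal_b, "focalB")
  if (length(controls) && !all(vapply(controls, function(x)
      is.list(x) && inherits(x$a, "clade_spec"), logical(1))))
    controls <- swap_control(tree, focal_a, focal_b, controls)

  ccs <- list(max_background_states = thr$ccs_max_background_states,
              min_background_majority = thr$ccs_min_background_majority,
              max_background_gap = thr$ccs_max_background_gap,
              pattern = thr$ccs_pattern)
  scen_specs <- c(list(list(a = focal_a, b = focal_b, name = "focal")), controls)
  scenarios <- lapply(scen_specs, function(sc) {
    if (verbose) message("scenario ", sc$name, ": ", length(genes), " genes")
    run_scenario(genes, tree, sc$a, sc$b, sc$name, thr, profile_library,
                 conf_floor, ccs)
  })
  names(scenarios) <- vapply(scen_specs, `[[`, character(1), "name")

  omega <- omega_rank_p <- NULL
  if (!is.null(codon_genes)) {
    om <- lapply(seq_along(scen_specs), function(i) {
      sc <- scen_specs[[i]]
      stems <- c(node_labels(tree)[sc$a$mrca], node_labels(tree)[sc$b$mrca])
      do.call(rbind, lapply(names(codon_genes), function(g) {
        m <- fit_codon_model(codon_genes[[g]], tree)
        oc <- omega_c(codon_genes[[g]], tree, stems, m)
        data.frame(scenario = sc$name, gene = g, kappa = m$kappa,
                   omega = m$omega_codon, OCN = oc$OCN, ECN = oc$ECN,
                   OCS = oc$OCS, ECS = oc$ECS, dNC = oc$dNC, dSC = oc$dSC,
                   omega_c = oc$omega_c, stringsAsFactors = FALSE)
      }))
    })
    omega <- do.call(rbind, om)
    omega$pass <- omega$omega_c > thr$omega_c
    foc <- omega$omega_c[omega$scenario == "focal"]
    ctl <- omega$omega_c[omega$scenario != "focal"]
    if (length(foc) && length(ctl))
      omega_rank_p <- rates_vs_controls(foc, ctl)
  }

  scan <- structure(list(scenarios = scenarios, omega = omega,
                         omega_ranksum_p = omega_rank_p, thresholds = thr,
                         n_genes = length(genes),
                         profile_provenance = attr(profile_library, "provenance")),
                    class = "paas_scan")
  if (!is.null(out_dir)) write_scan(scan, out_dir)
  scan
}

# One scenario (focal or control) over all genes - the shared code path.
run_scenario <- function(genes, tree, clade_a, clade_b, name, thr,
                         library, conf_floor, ccs) {
  per_gene <- vector("list", length(genes))
  all_calls <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- names(genes)[gi]
    scan <- scan_gene(tree, genes[[gi]], clade_a, clade_b,
                      conf_floor = conf_floor, ccs = ccs)
    calls <- scan$calls
    calls$pp <- numeric(nrow(calls)) * NA_real_
    if (nrow(calls)) {
      # profile-shift PP per branch pair, scored on that pair's candidate sites
      key <- paste(calls$node_a, calls$node_b)
      for (kp in unique(key)) {
        idx <- which(key == kp)
        fg <- c(calls$node_a[idx[1]], calls$node_b[idx[1]])
        pp <- site_pp(scan$tree, genes[[gi]], fg, library,
                      sites = unique(calls$site[idx]))
        calls$pp[idx] <- pp$pp[match(calls$site[idx], pp$site)]
      }
    }
    calls$pp_pass <- !is.na(calls$pp) & calls$pp > thr$pp
    all_calls[[gi]] <- if (nrow(calls))
      cbind(gene = g, calls, stringsAsFactors = FALSE) else NULL
    per_gene[[gi]] <- data.frame(
      gene = g, n_sites = ncol(genes[[gi]]), n_obs = scan$n_obs,
      lambda = scan$lambda, stringsAsFactors = FALSE)
  }
  genes_df <- do.call(rbind, per_gene)
  if (is.null(genes_df))
    genes_df <- data.frame(gene = character(), n_sites = integer(),
                           n_obs = integer(), lambda = numeric())
  genes_df$p <- gene_poisson_test(genes_df$n_obs, genes_df$lambda)
  genes_df$q <- bh_fdr(genes_df$p)
  genes_df$significant <- genes_df$q < thr$fdr
  calls_df <- do.call(rbind, all_calls)
  if (is.null(calls_df))
    calls_df <- data.frame(gene = character(), site = integer(),
                           node_a = character(), node_b = character(),
                           anc_a = character(), der_a = character(),
                           anc_b = character(), der_b = character(),
                           category = character(), ccs_class = character(),
                           ccs_pass = logical(), pp = numeric(),
                           pp_pass = logical())
  coll <- collate_paas(split(calls_df, calls_df$gene), filtered = TRUE)
  list(name = name, clade_a = clade_a, clade_b = clade_b,
       genes = genes_df, calls = calls_df, collation = coll)
}

#' Summarise a pipeline run
#'
#' @param scan a `paas_scan` from [run_pipeline()].
#' @return list of data frames: `filter_cascade` (per scenario: site x pair
#'   calls surviving each successive screen, and gene counts),
#'   `per_comparison` (per-pair call counts, focal scenario), `per_gene`
#'   (focal gene table), and `omega` when the codon screen ran.
#' @export
report_summary <- function(scan) {
  stopifnot(inherits(scan, "paas_scan"))
  cascade <- do.call(rbind, lapply(scan$scenarios, function(sc) {
    cl <- sc$calls
    data.frame(
      scenario = sc$name,
      n_genes = nrow(sc$genes),
      calls_raw = nrow(cl),
      calls_ccs = sum(cl$ccs_pass),
      calls_ccs_pp = sum(cl$ccs_pass & cl$pp_pass),
      sites = sum(sc$collation$gene_sites$n_sites),
      genes_with_sites = sum(sc$collation$gene_sites$n_sites > 0),
      genes_significant = sum(sc$genes$significant),
      stringsAsFactors = FALSE)
  }))
  rownames(cascade) <- NULL
  # all branch pairs of the focal comparison, zero-filled where no call
  foc <- scan$scenarios[[1]]
  grid <- enumerate_pairs(foc$clade_a, foc$clade_b)[, c("node_a", "node_b")]
  pc <- foc$collation$pair_counts
  grid$n_calls <- pc$n_calls[match(paste(grid$node_a, grid$node_b),
                                   paste(pc$node_a, pc$node_b))]
  grid$n_calls[is.na(grid$n_calls)] <- 0L
  out <- list(filter_cascade = cascade,
              per_comparison = grid,
              per_gene = foc$genes)
  if (!is.null(scan$omega)) {
    out$omega <- scan$omega
    out$omega_ranksum_p <- scan$omega_ranksum_p
  }
  out
}

#' @export
print.paas_scan <- function(x, ...) {
  cat("<paas_scan> ", x$n_genes, " genes, ", length(x$scenarios),
      " scenario(s) [", paste(names(x$scenarios), collapse = ", "), "]\n",
      sep = "")
  s <- report_summary(x)
  print(s$filter_cascade, row.names = FALSE)
  if (!is.null(x$omega)) {
    cat("omegaC > ", x$thresholds$omega_c, ": ",
        sum(x$omega$pass[x$omega$scenario == "focal"]), "/",
        sum(x$omega$scenario == "focal"), " focal genes", sep = "")
    if (!is.null(x$omega_ranksum_p))
      cat("; focal vs control rank-sum p = ",
          format(x$omega_ranksum_p, digits = 3), sep = "")
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.paas_scan <- function(object, ...) report_summary(object)

# Deterministic TSV writers; provenance header lines start with '#'.
write_scan <- function(scan, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(
    paste0("# thresholds: pp>", scan$thresholds$pp, " fdr<",
           scan$thresholds$fdr, " omega_c>", scan$thresholds$omega_c),
    paste0("# ccs: max_background_states=",
           scan$thresholds$ccs_max_background_states,
           " min_background_majority=",
           scan$thresholds$ccs_min_background_majority,
           " max_background_gap=", scan$thresholds$ccs_max_background_gap,
           " pattern=", scan$thresholds$ccs_pattern),
    paste0("# profile_library: ", scan$profile_provenance))
  wtsv <- function(df, file) {
    con <- file(file.path(out_dir, file), "w")
    writeLines(prov, con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  calls <- do.call(rbind, lapply(scan$scenarios, function(sc)
    if (nrow(sc$calls)) cbind(scenario = sc$name, sc$calls) else NULL))
  if (!is.null(calls)) wtsv(calls, "calls.tsv")
  genes <- do.call(rbind, lapply(scan$scenarios, function(sc)
    cbind(scenario = sc$name, sc$genes)))
  wtsv(genes, "genes.tsv")
  s <- report_summary(scan)
  wtsv(s$filter_cascade, "summary.tsv")
  if (nrow(s$per_comparison)) wtsv(s$per_comparison, "pairs.tsv")
  if (!is.null(scan$omega)) wtsv(scan$omega, "omegac.tsv")
  invisible(out_dir)
}

#' Read and validate a pipeline run configuration (YAML or JSON)
#'
#' Recognised keys: `alignments` (directory or vector of FASTA/PHYLIP
#' files), `tree`, `focal_a`, `focal_b`, `controls`, `codon_alignments`,
#' `thresholds`, `seed`, `out_dir`. Unknown keys are rejected.
#'
#' @param path config file.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("alignments", "tree", "focal_a", "focal_b", "controls",
             "codon_alignments", "thresholds", "seed", "out_dir")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (need in c("alignments", "tree", "focal_a", "focal_b"))
    if (is.null(cfg[[need]])) stop("config is missing required key: ", need)
  cfg
}
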