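#' Empirical amino-acid substitution models
#'
#' `jtt_model()` returns the built-in Jones-Taylor-Thornton model;
#' `aa_model()` builds a reversible model from an arbitrary symmetric
#' exchangeability matrix and equilibrium frequencies. Rate matrices are
#' normalised to one expected substitution per unit branch length
#' (\eqn{-\sum_i \pi_i Q_{ii} = 1}).
#'
#' @param exch symmetric non-negative exchangeability matrix, zero diagonal.
#' @param freqs equilibrium frequencies, strictly positive, summing to 1.
#' @param states state labels (row/column order of `exch`).
#' @return an `aa_model`: states, `exch`, `freqs`, normalised `Q`, and the
#'   symmetric eigendecomposition used for matrix exponentials.
#' @export
aa_model <- function(exch, freqs, states = AA_STATES) {
  k <- length(states)
  stopifnot(nrow(exch) == k, ncol(exch) == k, length(freqs) == k)
  if (any(freqs <= 0)) stop("equilibrium frequencies must be strictly positive")
  freqs <- freqs / sum(freqs)
  if (max(abs(exch - t(exch))) > 1e-9) stop("exchangeability matrix must be symmetric")
  Q <- exch * rep(freqs, each = k)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  if (mu <= 0) stop("degenerate rate matrix (zero total rate)")
  Q <- Q / mu
  sqp <- sqrt(freqs)
  A <- Q * (sqp %o% (1 / sqp))
  A <- (A + t(A)) / 2
  es <- eigen(A, symmetric = TRUE)
  structure(list(states = states, exch = exch, freqs = freqs, Q = Q,
                 eig = list(values = es$values, vectors = es$vectors, sqp = sqp)),
            class = "aa_model")
}

#' @rdname aa_model
#' @export
jtt_model <- function() {
  exch <- matrix(0, 20, 20, dimnames = list(AA_STATES, AA_STATES))
  exch[lower.tri(exch)] <- .JTT_RATES
  exch <- exch + t(exch)
  m <- aa_model(exch, .JTT_FREQS, AA_STATES)
  m$name <- "JTT"
  m
}

#' @export
print.aa_model <- function(x, ...) {
  cat("<", class(x)[1], "> ", if (!is.null(x$name)) x$name else "custom",
      ", ", length(x$states), " states\n", sep = "")
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed from the symmetric eigendecomposition of the
#' \eqn{\pi}-symmetrised rate matrix (exact for reversible models). Tiny
#' negative entries from round-off are clipped to zero.
#'
#' @param model an `aa_model`/`codon_model`, or a plain rate matrix `Q`
#'   (rows summing to zero).
#' @param t branch length, `t >= 0`.
#' @return stochastic matrix with rows summing to 1.
#' @export
transition_matrix <- function(model, t) {
  if (length(t) != 1 || is.na(t) || t < 0) stop("branch length t must be >= 0")
  if (inherits(model, "aa_model")) {
    e <- model$eig
    E <- e$vectors * rep(exp(e$values * t), each = length(e$sqp))
    P <- E %*% t(e$vectors)
    P <- P * ((1 / e$sqp) %o% e$sqp)
  } else {
    if (!is.matrix(model)) stop("model must be an aa_model or a rate matrix")
    if (max(abs(rowSums(model))) > 1e-8) stop("rate matrix rows must sum to 0")
    ev <- eigen(model)
    P <- Re(ev$vectors %*% diag(exp(ev$values * t), nrow(model)) %*% solve(ev$vectors))
  }
  if (min(P) < -1e-8) stop("transition matrix has large negative entries")
  P[P < 0] <- 0
  dimnames(P) <- if (inherits(model, "aa_model"))
    list(model$states, model$states) else dimnames(model)
  P
}

#' Per-site ("fsite") model family
#'
#' Combines a model's exchangeabilities with site-specific equilibrium
#' frequencies: at each site \eqn{Q_s} is rebuilt from the shared
#' exchangeabilities with \eqn{\pi} replaced by \eqn{\pi_s} and renormalised,
#' so every site evolves at one expected substitution per unit branch length.
#'
#' @param model an `aa_model` supplying exchangeabilities.
#' @param site_freqs matrix (states x sites) of strictly positive per-site
#'   frequencies, e.g. from [estimate_site_frequencies()].
#' @return an `aa_model_fsite` family.
#' @export
with_site_frequencies <- function(model, site_freqs) {
  stopifnot(inherits(model, "aa_model"))
  site_freqs <- as.matrix(site_freqs)
  if (nrow(site_freqs) != length(model$states))
    stop("site_freqs must have one row per model state")
  if (any(site_freqs <= 0))
    stop("zero site frequency; apply a pseudocount before building the family")
  site_freqs <- sweep(site_freqs, 2, colSums(site_freqs), "/")
  structure(list(states = model$states, exch = model$exch, pis = site_freqs,
                 base = model),
            class = "aa_model_fsite")
}

#' @rdname with_site_frequencies
#' @param family an `aa_model_fsite`.
#' @param site site index (1-based).
#' @return `site_model()`: the single-site `aa_model`.
#' @export
site_model <- function(family, site) {
  stopifnot(inherits(family, "aa_model_fsite"))
  aa_model(family$exch, family$pis[, site], family$states)
}

#' @export
print.aa_model_fsite <- function(x, ...) {
  cat("<aa_model_fsite> ", length(x$states), " states x ", ncol(x$pis),
      " sites\n", sep = "")
  invisible(x)
}

#' Empirical per-site amino-acid frequencies
#'
#' Column-wise observed frequencies with an additive pseudocount; gaps and
#' ambiguity codes are excluded from the counts. All-gap columns fall back to
#' the global JTT frequencies with a warning.
#'
#' @param aln amino-acid `paas_aln` (or a list of them, pooled column-wise
#'   in order).
#' @param pseudocount additive count per state (default 0.1).
#' @return matrix 20 x sites of frequencies; attribute `pseudocount`.
#' @export
estimate_site_frequencies <- function(aln, pseudocount = 0.1) {
  if (inherits(aln, "paas_aln")) aln <- list(aln)
  mats <- lapply(aln, function(a) {
    stopifnot(attr(a, "alphabet") == "amino20")
    aln_state_matrix(a)
  })
  m <- do.call(cbind, mats)
  S <- ncol(m)
  k <- length(AA_STATES)
  counts <- matrix(0, k, S)
  for (j in seq_len(k))
    counts[j, ] <- colSums(m == (j - 1L))
  allgap <- colSums(counts) == 0
  if (any(allgap)) {
    warning(sum(allgap), " all-gap column(s); using global JTT frequencies there")
    counts[, allgap] <- .JTT_FREQS
  }
  f <- counts + pseudocount
  f <- sweep(f, 2, colSums(f), "/")
  rownames(f) <- AA_STATES
  attr(f, "pseudocount") <- pseudocount
  f
}

# ---- codon model (MG94 x HKY type) ----------------------------------------

# metadata for single-nucleotide codon changes, built once
codon_meta <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    codons <- unname(codon_states())
    aa <- names(codon_states())
    k <- length(codons)
    cm <- do.call(rbind, strsplit(codons, ""))
    ts_pairs <- c("AG", "GA", "CT", "TC")
    diffpos <- matrix(0L, k, k)
    is_ts <- matrix(FALSE, k, k)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      d <- which(cm[i, ] != cm[j, ])
      if (length(d) == 1L) {
        diffpos[i, j] <- d
        is_ts[i, j] <- paste0(cm[i, d], cm[j, d]) %in% ts_pairs
      }
    }
    cache <<- list(codons = codons, aa = aa, single = diffpos > 0,
                   is_ts = is_ts, nonsyn = outer(aa, aa, "!="))
    cache
  }
})

#' Codon substitution model (MG94 x HKY style)
#'
#' Instantaneous rates are restricted to single-nucleotide codon changes,
#' with rate proportional to the target codon frequency times
#' \eqn{\kappa} for transitions and \eqn{\omega} for nonsynonymous changes;
#' the matrix is normalised to one expected substitution per unit branch
#' length. The model is reversible with respect to the codon frequencies.
#'
#' @param kappa transition/transversion rate ratio, > 0.
#' @param omega_codon nonsynonymous/synonymous rate ratio, > 0.
#' @param codon_freqs frequencies over the 61 sense codons (e.g.
#'   [codon_frequencies()]); uniform by default.
#' @return a `codon_model` (subclass of `aa_model` over 61 codon states).
#' @export
build_codon_model <- function(kappa, omega_codon,
                              codon_freqs = rep(1 / 61, 61)) {
  if (kappa <= 0 || omega_codon <= 0) stop("kappa and omega_codon must be > 0")
  meta <- codon_meta()
  if (length(codon_freqs) != 61) stop("codon_freqs must have 61 entries")
  if (abs(sum(codon_freqs) - 1) > 1e-6) stop("codon_freqs must sum to 1")
  exch <- matrix(0, 61, 61)
  exch[meta$single] <- 1
  exch[meta$single & meta$is_ts] <- kappa
  exch[meta$single & meta$nonsyn] <- exch[meta$single & meta$nonsyn] * omega_codon
  m <- aa_model(exch, codon_freqs, meta$codons)
  m$kappa <- kappa
  m$omega_codon <- omega_codon
  m$name <- "MG94xHKY"
  class(m) <- c("codon_model", class(m))
  m
}

#' Codon equilibrium frequencies from a codon alignment
#'
#' @param aln codon `paas_aln`.
#' @param method `"F3x4"` (position-specific nucleotide frequencies,
#'   default), `"F1x4"`, or `"uniform"`. Stop codons are excluded and the
#'   result renormalised; a nucleotide pseudocount of 0.1 keeps all sense
#'   codons strictly positive.
#' @return length-61 frequency vector named by codon.
#' @export
codon_frequencies <- function(aln, method = c("F3x4", "F1x4", "uniform")) {
  method <- match.arg(method)
  meta <- codon_meta()
  if (method == "uniform")
    return(setNames(rep(1 / 61, 61), meta$codons))
  stopifnot(attr(aln, "alphabet") == "codon")
  cells <- unclass(aln)[!is_missing_cell(unclass(aln), "codon")]
  chars <- do.call(rbind, strsplit(cells, ""))
  ntc <- sapply(1:3, function(p) {
    tab <- table(factor(chars[, p], levels = NT_STATES))
    as.numeric(tab) + 0.1
  })
  ntf <- sweep(ntc, 2, colSums(ntc), "/")
  if (method == "F1x4") ntf <- matrix(rowMeans(ntf), 4, 3)
  rownames(ntf) <- NT_STATES
  cm <- do.call(rbind, strsplit(meta$codons, ""))
  f <- ntf[cm[, 1], 1] * ntf[cm[, 2], 2] * ntf[cm[, 3], 3]
  setNames(f / sum(f), meta$codons)
}

#' Fit kappa and omega of the codon model by maximum likelihood
#'
#' Bounded two-parameter optimisation of the pruning likelihood over
#' \eqn{\kappa \in [0.1, 20]} and \eqn{\omega \in [0.01, 10]}; codon
#' frequencies are held at their empirical estimate.
#'
#' @param aln codon `paas_aln`.
#' @param tree prepared `phylo` matching the alignment.
#' @param freq_method passed to [codon_frequencies()].
#' @param init optional `c(kappa, omega)` start values.
#' @return fitted `codon_model` with elements `loglik` and `convergence`.
#' @export
fit_codon_model <- function(aln, tree, freq_method = "F3x4",
                            init = c(2, 0.5)) {
  tree <- match_tree_alignment(tree, aln)
  freqs <- codon_frequencies(aln, freq_method)
  tp <- tree_post(tree)
  states <- aln_state_matrix(aln, tree$tip.label)
  nll <- function(par) {
    m <- build_codon_model(par[1], par[2], freqs)
    -sum(prune_model_loglik(tp, states, m))
  }
  fit <- optim(init, nll, method = "L-BFGS-B",
               lower = c(0.1, 0.01), upper = c(20, 10),
               control = list(factr = 1e10, maxit = 50))
  m <- build_codon_model(fit$par[1], fit$par[2], freqs)
  m$loglik <- -fit$value
  m$convergence <- fit$convergence
  m
}
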