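---
title: "Detecting parallel and convergent amino-acid substitutions with paraconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting parallel and convergent amino-acid substitutions with paraconv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paraconv)
```

# The problem

Independent adaptation of distant lineages to the same environment can leave
a molecular fingerprint: the same amino-acid replacement fixed independently
on both sides of the tree. The difficulty is that identical substitutions
also happen by chance, at a rate governed by the substitution process, the
branch lengths, and the per-site amino-acid preferences. `paraconv`
implements a detection cascade that (i) finds candidate parallel/convergent
substitutions between two focal clades, (ii) filters them by the
conservation pattern of the background taxa and by a profile-shift posterior
score, and (iii) tests, per gene and per branch pair, whether the amount of
convergence exceeds what the substitution model predicts.

Throughout, a *focal clade* is a monophyletic group of phenotypically
convergent species; its *foreground nodes* are its leaves plus the internal
nodes of the induced subtree (a 3-leaf clade contributes 3 terminal and 2
ancestral nodes, so two such clades give 25 branch-pair comparisons). All
remaining taxa are *background*.

# Models

## Amino-acid model

The single built-in empirical model is JTT, embedded as program data
(`jtt_model()`). Rate matrices are assembled as
$Q_{ij} = s_{ij}\pi_j$ from the symmetric exchangeabilities $s_{ij}$ and
equilibrium frequencies $\pi$, normalised so that
$-\sum_i \pi_i Q_{ii} = 1$ (branch lengths are expected substitutions per
site). The model is reversible, so $P(t) = e^{Qt}$ is computed through the
symmetric eigendecomposition of $D^{1/2} Q D^{-1/2}$, $D=\mathrm{diag}(\pi)$
— numerically stable for 20 and 61 states, and fast because $P(t)v$ can be
applied as two matrix–vector products without forming $P(t)$.

The *fsite* variant (`with_site_frequencies()`) replaces $\pi$ by per-site
frequencies $\pi_s$ estimated from the alignment column with an additive
pseudocount (default 0.1 per residue; the pseudocount prevents derived
states unseen in a column from having probability zero, which would nullify
the expected-convergence computation). Each $Q_s$ is renormalised, so every
site evolves at unit expected rate. Frequencies are estimated per site
within each gene; gaps and ambiguity codes are excluded from the counts, and
all-gap columns fall back to the global JTT frequencies with a warning.

Gaps (`-`) and ambiguity codes (`X`) are missing data everywhere: they
contribute a flat partial likelihood in the pruning and never generate
substitution events. This is the standard pruning convention; columns that
are mostly missing are additionally excluded from the conservation screen.

## Ancestral reconstruction

`marginal_posteriors()` runs the standard up–down (inside–outside) marginal
reconstruction: at each internal node the posterior over states is
proportional to the inside partial likelihood times the outside
contribution. Marginal — not joint — reconstruction is used, matching the
common use of codeml's marginal output; MAP states are the per-node argmax,
with exact ties broken towards the lower index in the canonical alphabet
order and flagged ambiguous (determinism). An optional confidence floor
(default 0, i.e. off) can exclude low-confidence ancestors from event
extraction. Partial likelihoods are rescaled per node to avoid underflow.

## Codon model

The ωC screen uses an MG94×HKY-type codon model over the 61 sense codons:
instantaneous rates are restricted to single-nucleotide codon changes, with
target-codon frequency times $\kappa$ for transitions and $\omega$ for
nonsynonymous changes. Codon frequencies default to F3×4 estimated from the
alignment; $\kappa \in [0.1, 20]$ and $\omega \in [0.01, 10]$ are estimated
by bounded L-BFGS-B maximisation of the pruning likelihood
(`fit_codon_model()`).

# The detection cascade

## Classification

For a branch pair (one foreground branch per clade) and site, both branches
must carry a substitution event; a call is *parallel* when ancestral and
derived states agree across the pair, *convergent* when the derived states
agree but the ancestral states differ. One-sided patterns are never called.

## CCS conservation screen

A site is retained only when its background column is moderately conserved:
at most `max_background_states = 2` distinct residues with a majority
frequency of at least `min_background_majority = 0.8` (both exposed in the
configuration and echoed into output provenance; the quantification of
"moderately conserved" is this package's choice). Columns with more than
50% missing background taxa are unclassifiable — conservation is undefined
on mostly-missing columns.

The admissible foreground substitution patterns are D2S (different
ancestral states to one specific derived state), S2S, and S2D. The
site-level classifier `ccs_classify()` pools all foreground events at the
site. In the pipeline, however, the pattern is by default read off each
branch pair (`ccs_pattern = "pair"`; the pair's shared derived state from
one shared or two distinct ancestral states). The reason is practical:
pooling all foreground events mixes in back-substitution noise from deep
foreground subtrees, which pushes genuinely convergent sites into the
inadmissible "≥2 ancestral and ≥2 derived states" corner and silently
deletes them. The pooled behaviour is available via
`ccs_pattern = "pooled"`.

## Profile-shift posterior

`site_pp()` scores each candidate site with a simplified
profile-change-with-one-change model. The null likelihood $L_0$ maximises,
over a profile library, the pruning likelihood with a single amino-acid
preference profile on all branches; the alternative $L_1$ maximises over
ordered profile pairs (ancestral ≠ convergent), with the convergent profile
on the foreground subtrees and the child state of each foreground stem
branch drawn directly from the convergent profile's equilibrium — the
simplest construction with "at least one change" on the shift branch. With
equal priors, $PP = L_1/(L_0 + L_1)$, and sites pass at $PP > 0.99$
(strict). This is a deliberate simplification of the PCOC model class
(maximisation instead of integration, equal priors, one shift event);
exact parity with PCOC is a non-goal.

The default library (`builtin_profiles()`) holds 21 profiles: one
concentrated profile per residue (mass 0.9, remainder uniform) plus the
flat JTT profile. A small *estimated* library (seeded k-means over per-site
frequency vectors, `estimate_profiles()`, default K = 10, seed 1729) is also
provided, but it is not the default: a 10-cluster summary of one gene's
columns cannot represent preference shifts towards arbitrary residues, and
using it as the default would make the screen's sensitivity depend on which
targets happen to be clustered. One concentrated profile per residue is the
minimal library that can represent any single-target shift. The exhaustive
search over the K×(K−1) ordered profile pairs avoids local optima.

Per branch-pair comparison, the foreground is the pair's two branches plus
their descendant subtrees (the clade-root pair therefore covers the full
clades); widening every comparison to the full clades is a configuration
choice.

## Gene-level excess-convergence test

Per gene, the observed count $n$ sums parallel+convergent calls over sites
and all branch pairs, and the expectation
$$\lambda = \sum_{\text{sites}} \sum_{\text{pairs}} \sum_{d}
  P_A(a^\ast \to d)\, P_B(b^\ast \to d), \qquad d \neq a^\ast,\ d \neq b^\ast$$
uses the same per-site (fsite) transition matrices as the reconstruction.
Overlapping pairs share internal branches; the double-counting is accepted
identically on both sides of the test, keeping it internally consistent.
`gene_poisson_test()` returns the one-sided upper tail
$P(X \ge n)$, $X \sim \text{Poisson}(\lambda)$, and genes are screened at
BH FDR < 0.1, pooled across genes within a run.

A calibration subtlety: the observed count conditions on the MAP ancestral
states $a^\ast, b^\ast$, so the expectation must condition on the same
states. The generic helper `expected_pair_site_prob()` accepts any ancestral
distribution $q$ (and reduces to the formula above when $q$ is the MAP point
mass); the pipeline deliberately uses the MAP point mass, because averaging
over the full posterior produces an expectation for a *different* (soft)
counting rule and systematically overshoots MAP-based observed counts,
making the test conservative and the null calibration drift out of its
nominal range.

## ωC

For a branch pair, OCN counts codon sites where both branches substitute
and the derived codons encode the same amino acid, different from both
ancestral amino acids; OCS counts sites where both branches reach the same
derived codon synonymously. ECN and ECS are the corresponding model
expectations from the ancestral codon posteriors and the codon transition
matrices, and $\omega_C = (OCN/ECN)/(OCS/ECS)$. Only the same-derived-state
(spe2spe-style) convergence category is implemented; the wider catalog of
derived-state categories is out of scope.

At the scale of a single gene and two stem branches, the raw counts are
tiny — OCS in particular is usually zero — so the raw ratio is 0/0 or
infinite for most genes. A half-count continuity correction (0.5 added to
all four counts, exposed as `correction`) keeps ωC finite and centred near
1 under the null while leaving strong signals clearly above 1; expectations
are additionally floored at 1e-8 and the floor is flagged when applied.
Focal-versus-control comparisons use the two-sided Wilcoxon rank-sum test
(exact for small tie-free samples).

## Controls

Control scenarios swap one focal clade (alternating A and B in the default
design) for a non-focal monophyletic lineage and re-run the identical code
path; the seven control lineages are explicit configuration, not a guessed
selection rule.

# The synthetic-data generators

The generators exist so the cascade can be validated against known truth.

* `make_default_tree()` is a fixed, rooted 22-leaf ungulate-style topology:
  a 3-species camel clade and a 3-species hippotragine antelope clade in
  distant subtrees, plus seven disjoint monophyletic control lineages.
  Branch lengths are fixed constants in [0.02, 0.30]: focal terminal
  branches 0.12 and focal internal branches 0.08–0.12, long enough that a
  lineage which misses the stem-level shift can still reach the target
  residue within the clade, while ancestral reconstruction stays informative
  but not trivial; background branches 0.02–0.22.
* `simulate_msa()` draws root states from the model equilibrium and evolves
  them down each branch via $P(t)$ — the null generator.
* `inject_convergent_shifts()` labels a fraction of sites (default 0.05) as
  shifted: outside the foreground they evolve under the background model;
  on all foreground branches of *both* clades they evolve under a shifted
  profile (same exchangeabilities, mass `concentration`, default 0.9, on a
  target residue), and the child state of each foreground stem branch is
  resampled from the shifted profile. Two generator semantics are fixed by
  design: the target residue is drawn from the 19 residues *other than* the
  site's preferred residue (a preference shift towards the already-preferred
  residue is no shift), and the default background model is per-site
  constrained frequencies (`constrained_site_frequencies()`, concentration
  0.97 on a random residue per site), emulating the purifying constraint
  that makes real protein columns conserved — the regime the CCS screen
  presumes. A `one_clade_only` mode shifts a single clade, for
  false-positive testing of the detector.
* `simulate_codon_msa()` simulates codon columns; a forced-convergence
  configuration overwrites both focal stem children with codons encoding a
  common amino acid different from both ancestral amino acids, then lets
  evolution continue below.

Every generator is a pure function of (parameters, seed).

What these simulations do **not** emulate: alignment error, incomplete
lineage sorting, introgression, rate variation beyond the per-site
frequency profiles, indel processes (gaps appear only if injected), and
selection on codon usage. Passing the validation therefore demonstrates the
cascade's statistical behaviour under its own model class, not robustness
to real-data artefacts.

# Validation design and problem sizes

The test suite validates each operation against independent oracles
(exhaustive enumeration over internal states on small trees; closed forms
on 1–2 leaf trees and 2-state chains; Monte-Carlo endpoint simulation for
the expected-convergence probability; a textbook BH implementation; the
published behaviour of `wilcox.test` on exact small samples), and the
acceptance layer re-runs the full cascade at these sizes: 2,000 null genes
of 300 sites for the Poisson calibration; 20 replicates of 1,000 sites with
5% injected shifts for sensitivity and empirical FDR; 50 null plus 50
forced-convergence codon genes of 200 codons for ωC, with
focal-versus-control rank-sum comparisons in blocks of 8 genes. These sizes
give stable estimates of the reported fractions on a single CPU in a few
minutes and are the package's documented validation design.

# Numerical choices

* Per-node rescaling of partial likelihoods (underflow on deep 20/61-state
  problems).
* Matrix exponentials through the symmetric eigendecomposition of the
  π-symmetrised rate matrix; tiny negative entries from round-off are
  clipped to zero.
* MAP ties broken canonically (lowest alphabet index) and flagged.
* Expectation floors (1e-8) in ωC; half-count continuity correction as
  described above.
* Internal nodes without labels are auto-named `N1, N2, ...` by postorder
  rank, so reports are reproducible across runs. Site indices are 1-based
  in all human-facing outputs.

# Known limitations

* Only JTT is built in; other empirical matrices (WAG, LG) are non-goals.
* No gamma rate heterogeneity; per-site frequencies are the only source of
  among-site variation.
* The profile-shift score is PCOC-like, not PCOC: maximisation over a small
  profile library with equal priors, a single shift event per site, and no
  published C-series profile sets.
* ωC implements one convergence category (same derived amino acid on both
  branches) for a single branch pair at a time.
* Genes with missing taxa are analysed on the pruned induced tree with a
  warning; how the original study handled such genes is not documented, so
  this permissive policy is a package choice.
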