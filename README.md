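# paraconv

Detection of parallel and convergent amino-acid substitutions between
independently adapted clades on a phylogeny.

When two distantly related lineages adapt to the same environment — the
motivating case is desert ungulates: camels on one side of the artiodactyl
tree, hippotragine antelopes on the other — their proteins sometimes fix the
*same* amino-acid changes independently. Separating such adaptive molecular
convergence from the background of chance identical substitutions requires a
cascade of complementary screens, and `paraconv` implements that cascade as
a single tested R package:

1. **Ancestral reconstruction.** Marginal ancestral-state posteriors by
   Felsenstein pruning (up–down algorithm) under the JTT amino-acid model,
   optionally with site-specific equilibrium frequencies ("JTT-fsite"),
   implemented in C++ for 20- and 61-state alphabets.
2. **Branch-pair comparisons.** For two 3-leaf focal clades, all
   5 × 5 = 25 pairs of foreground branches (3 terminals + 2 ancestral nodes
   per clade) are compared. A site is *parallel* when both branches derive
   the same residue from the same ancestral residue, and *convergent* when
   the same derived residue arises from different ancestral residues.
3. **CCS conservation screen.** Calls are kept only at moderately conserved
   background columns (≤ 2 distinct background residues, majority ≥ 0.8),
   with the admissible foreground patterns D2S / S2S / S2D.
4. **Profile-shift posterior (PCOC-like).** Each candidate site is scored
   with PP = L₁/(L₀+L₁), where L₀ is the best single amino-acid preference
   profile over the whole tree and L₁ the best background/foreground profile
   pair with at least one change on the foreground stem branches; sites pass
   at PP > 0.99.
5. **Excess-convergence test (Conv_cal-style).** Per gene, the observed
   number of convergence events n is compared with its model expectation
   λ = Σ_sites Σ_pairs Σ_d P_A(a→d) P_B(b→d) (a ≠ d, b ≠ d) via a one-sided
   Poisson test, with Benjamini–Hochberg correction across genes
   (screen at FDR < 0.1).
6. **Codon-level convergence rate (ωC).** For a branch pair,
   ωC = dNC/dSC = (OCN/ECN)/(OCS/ECS) compares observed-to-expected
   convergent nonsynonymous and synonymous substitution counts under an
   MG94×HKY codon model with ML estimates of κ and ω; candidates are kept at
   ωC > 1 and focal pairs are compared against swapped-outgroup controls
   with a Wilcoxon rank-sum test.
7. **Controls.** Every control scenario (a focal clade swapped for a
   non-adapted lineage) runs through the identical code path.

Because the real inputs of such a study are dozens of whole genomes, the
package ships a synthetic-data module (`make_default_tree`, `simulate_msa`,
`inject_convergent_shifts`, `simulate_codon_msa`) that generates alignments
on a fixed 22-taxon ungulate-style tree with known ground truth, so every
stage of the cascade is validated end to end without any download.

## Worked example

Simulate one gene on the default 22-taxon tree with convergent preference
shifts injected at 5% of 300 sites in both desert clades, then run the full
cascade with two swapped-outgroup control scenarios:

```r
library(paraconv)
design <- make_default_tree()

sim <- inject_convergent_shifts(design$tree,
                                list(design$focal_a, design$focal_b),
                                n_sites = 300, shift_fraction = 0.05,
                                concentration = 0.9, seed = 42)
genes <- list(simulated_gene = sim$alignment)

scan <- run_pipeline(genes, design$tree, design$focal_a, design$focal_b,
                     controls = design$scenarios[1:2])
print(scan)
```

```
<paas_scan> 1 genes, 3 scenario(s) [focal, control1, control2]
 scenario n_genes calls_raw calls_ccs calls_ccs_pp sites genes_with_sites
    focal       1        14        13           13    13                1
 control1       1         0         0            0     0                0
 control2       1         0         0            0     0                0
 genes_significant
                 1
                 0
                 0
```

The focal scenario yields 14 raw site × pair calls, of which 13 survive the
CCS conservation screen and the PP > 0.99 profile-shift screen, covering 13
distinct sites; both control scenarios are clean. The detected sites match
the injected truth closely:

```r
detected <- with(scan$scenarios$focal$calls,
                 sort(unique(site[ccs_pass & pp > 0.99])))
detected
#> [1]  20  24  74  89 110 122 128 146 153 228 283 291 300
sim$truth$site[sim$truth$label == "shifted"]
#> [1]  20  24  49  74  89 110 122 128 146 153 165 228 283 291 300

scan$scenarios$focal$genes[, c("gene", "n_obs", "lambda", "p", "q", "significant")]
#>             gene n_obs   lambda           p           q significant
#> 1 simulated_gene    14 4.174458 0.000118315 0.000118315        TRUE
```

13 of the 15 injected sites are recovered with no false positives, and the
gene shows a clear excess of convergence events (14 observed versus an
expectation of 4.2, one-sided Poisson p = 1.2e-4, significant at FDR < 0.1).

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/scripts/paraconv.R simulate --seed 7 --out sim/
Rscript inst/scripts/paraconv.R all --config run.yaml --out results/
```

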