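# pleiocfdr

Pleiotropy-informed conditional false discovery rate (cFDR) analysis of
GWAS summary statistics, in R.

## What problem this solves

Polygenic traits such as bone mineral density (BMD) hide most of their
true association signal below genome-wide significance. When a second
trait (blood lipids, blood pressure, diabetes, anthropometry, ...)
shares genetic architecture with the primary one, each SNP's p-value in
the secondary GWAS carries information about its status in the primary
one. `pleiocfdr` turns that into power: it re-ranks primary-trait SNPs
by their FDR *conditional* on the secondary association, needing only
per-trait summary statistics (rsid + p-value, optionally direction,
MAF and a genic/intergenic flag), an LD r² table, a gene table, and —
optionally — an expression matrix for downstream validation.

## The statistic

For a SNP with primary p-value *p₁* and conditioning p-value *p₂*,

    FDR(p₁ | p₂) = π₀(p₂) · p₁ / F(p₁ | p₂),

the posterior probability that the SNP is null for the primary trait
given both p-values are at or below the observed ones. The package
estimates this conservatively with π₀(p₂) = 1 and the empirical
conditional CDF for *F*, evaluates it on a 2-D grid of
(−log₁₀ p₁ × −log₁₀ p₂) nodes, and assigns per-SNP values by bilinear
interpolation on the −log₁₀ scale. SNPs with minimum cFDR < 0.01 across
conditioning traits are declared, clumped into independent loci at
LD r² > 0.2 (lead = minimal-cFDR SNP, greedy pruning), annotated with
their closest genes, classified novel vs replication against a known
locus list, and optionally validated by age- and BMI-adjusted Pearson
correlation of gene expression with the phenotype. Genomic control
(λ_GC from intergenic SNPs, median-χ² formulation) is applied per trait
before anything else; stratified conditional Q-Q curves visualize the
cross-trait enrichment the method exploits.

A seeded synthetic-data generator (`simulate_panel()`,
`simulate_expression()`, `simulate_genes()`) produces inputs with known
truth labels — a null / trait-specific / pleiotropic z-score mixture
with optional block LD and planted inflation — so every stage is
testable end to end without any external download.

## Worked example

```r
library(pleiocfdr)

# two synthetic GWAS with 2% pleiotropic SNPs and block LD
sim <- simulate_panel(sim_config(
  n_snps = 50000, pi_null = 0.94, pi_1 = 0.02, pi_2 = 0.02, pi_pleio = 0.02,
  ld_block_size = 5, within_block_r = 0.7, seed = 42))

panel  <- intersect_traits(sim$sumstats$trait1,
                           list(lipids = sim$sumstats$trait2),
                           primary_name = "bmd")
lookup <- build_lookup(panel, "lipids")
res    <- cfdr_summarize(panel, list(lipids = lookup), threshold = 0.01)

sum(res$significant)          # SNPs declared at conditional FDR < 0.01
sum(res$uncond_fdr < 0.01)    # what the unconditional FDR alone declares

sig <- data.frame(rsid = res$rsid, cfdr = res$min_cfdr, p = res$p_primary,
                  chrom = res$chrom, pos = res$pos)[res$significant, ]
leads <- greedy_lead_selection(sig, sim$ld, r2_cut = 0.2)
loci  <- assign_blocks(leads, sig, sim$ld)
nrow(loci)                    # independent loci
```

printed output:

```
SNPs declared at cFDR < 0.01:    584
SNPs at unconditional FDR < 0.01: 445
independent loci: 571
  locus_id      lead chrom     pos n_members     min_cfdr
1        1 rs0001212     1  285000         1 5.635101e-06
2        2 rs0005391     1 1230000         1 1.557895e-06
3        3 rs0005611     1 1280000         1 3.566412e-04
```

Conditioning on the pleiotropic trait declares 584 SNPs where the
unconditional FDR finds 445 — the power gain the method exists for —
and greedy LD pruning collapses them to 571 independent loci. Against
the generator's truth labels, 2.9% of the declared SNPs in this run are
false (see the vignette for why the realized error rate sits above the
nominal 1-per-100 reading of the threshold).

The same analysis runs end to end from files via `run_pipeline()`
(YAML-able configuration; per-stage TSVs, a locus summary table, a JSON
run manifest, and optional Q-Q / Manhattan / lookup-heatmap figures).
`vignettes/conditional-fdr-methods.Rmd` documents the model,
estimators, defaults and limitations.

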