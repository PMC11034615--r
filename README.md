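# dyneqtl

Condition-dependent eQTL mapping and GWAS integration for diversity panels.

## The problem

A panel of accessions is genotyped once and expression-profiled under two
conditions (e.g. normal vs salt stress). `dyneqtl` implements the full
discovery chain for finding condition-responsive regulatory candidates in
such a design:

1. **Population-level response classification** — per accession,
   `log2FC = log2((stress + c)/(normal + c))`; a gene is salt-inducible /
   salt-repressed / responsive-variable when more than 10% of the panel
   responds past `|log2FC| >= 2`, with prevalence classes A (10–50%),
   B (50–90%), C (90–100%).
2. **Mixed-model association scans** — EMMAX-style: the model
   `y = Wα + xβ + u + ε`, `u ~ N(0, σg²K)` is eigen-rotated once per
   kinship, REML estimates `δ = σe²/σg²` under the null, and every variant
   is a weighted regression; leave-one-chromosome-out kinship by default.
3. **eQTL catalogue** — greedy lead-SNP clumping (200 kb window or dosage
   r² ≥ 0.2), cis/trans by an inclusive 200 kb interval rule, 1-to-1
   matching of peaks across conditions into static / dynamic categories,
   per-gene roll-up into static eGenes, neGenes (normal-only) and reGenes
   (stress-only), exclusion of genes with > 15 peaks, Poisson-tail
   trans-hotspot screening.
4. **GWAS loci, colocalization, triangulation** — trait peaks ± 200 kb
   define candidate windows; per-variant approximate Bayes factors
   (`ABF = sqrt(1−r)·exp(z²r/2)`, `r = W/(W+se²)`) are combined over the
   five standard hypotheses into posteriors PP0–PP4; candidates are ranked
   by evidence flags (DEG, reGene, colocalization PP4 ≥ 0.7,
   non-synonymous variant).

A synthetic-data generator (`simulate_dataset()`) plants known cis/trans
effects in all three condition categories, response genes in all prevalence
classes, and a trait QTL sharing its causal variant with a stress-only
cis-eQTL of a salt-inducible gene — so the whole chain is validated by
parameter recovery, not by eyeballing.

## Worked example

```r
library(dyneqtl)

spec <- simulation_spec(rng_seed = 1)          # 202 accessions, 2,000 SNPs, 150 genes
ds   <- simulate_dataset(spec)
cfg  <- analysis_config(eqtl_p_threshold = 0.05 / spec$n_snps)
res  <- run_pipeline(ds, cfg)
res
#> dyneqtl pipeline result
#>   expressed genes: 145 normal / 145 stress (140 common)
#>   DEGs: 46 of 150 profiled genes
#>   eQTL peaks: 67 (threshold 2.5e-05); eGenes: 45
#>   GWAS loci: 1; colocalized genes: 4; candidates ranked: 4

head(res$candidates[, c("gene_id", "rank_score", "in_DEG", "in_reGene",
                        "coloc_pass", "has_nonsyn_variant", "coloc_pp4")], 4)
#>     gene_id rank_score in_DEG in_reGene coloc_pass has_nonsyn_variant  coloc_pp4
#> 1 gene_0114          4   TRUE      TRUE       TRUE               TRUE 0.99951760
#> 2 gene_0113          1   TRUE     FALSE      FALSE              FALSE 0.09452516
#> 3 gene_0116          0  FALSE     FALSE      FALSE              FALSE 0.06645980
#> 4 gene_0115          0  FALSE     FALSE      FALSE              FALSE 0.06263743

ds$truth$coloc_gene
#> [1] "gene_0114"
```

The top-ranked candidate carries all four evidence flags and a
shared-causal-variant posterior of 0.9995 — and it is exactly the gene the
generator planted: a stress-only cis-eQTL, salt-inducible (class C), whose
causal variant also drives the survival-rate trait. The runner-up is its
genomic neighbour, picked up as a DEG but failing the regulatory flags.

Real data enter through the same containers: `read_vcf()` (biallelic SNPs,
MAF/missingness filters), `read_tables()` (expression TSVs with replicate
averaging, BED6/GFF3 annotation, phenotype TSV), `align_panel()` to put all
inputs on one canonical accession panel, then `run_pipeline()`.

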