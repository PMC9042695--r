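# tricontrast

Three-contrast differential expression and perturbation classification
for interferon-treated macrophage RNA-seq.

## The problem

IFN-λ3 and IFN-λ4 share a receptor yet drive distinct macrophage
phenotypes. Comparing each interferon only against the untreated
condition (NT) misses genes the two cytokines push *weakly in opposite
directions*: insignificant in both NT comparisons, but clearly
significant when the λ4- and λ3-treated conditions are compared
directly. `tricontrast` analyses, per cell type (M1/M2), the contrast
triplet

- **A**: IFN-λ3 vs NT
- **B**: IFN-λ4 vs NT
- **C**: IFN-λ4 vs IFN-λ3

and combines them into per-gene verdicts. Differential testing uses TMM
normalization and a negative-binomial exact conditional test with a
common dispersion φ (variance μ + φμ²); a DEG has |fold change| > 1.5
and raw p < 0.05, with signed fold changes displayed as ratio or
negative reciprocal. Each interferon's effect is tiered —
**strong** (significant, |FC| ≥ 4), **moderate** (significant),
**weak** (insignificant but |FC| ≥ 1.1 or separating in contrast C),
**null** — and a decision table turns tiers into verdicts: strong and
moderate effects always perturb, null never does, and a weak effect
perturbs only when the other interferon is moderate in the same
direction or weak in the opposite direction (a weak effect shadowed by
a strong one, or opposed by a moderate one, is unperturbed). Genes
perturbed by both interferons in opposite directions are
**reciprocally regulated**. The package also provides three-set Venn
accounting, hypergeometric over-representation analysis of gene lists
against GMT collections, PCA/scatter/top-table reporting, a
negative-binomial simulator with planted archetypes, and a
deterministic fixture builder for the classification algebra. See the
methods vignette (`vignettes/tricontrast-methods.Rmd`) for the full
model.

## Worked example

The packaged worked example rebuilds the gene-level classification of a
published M1/M2 comparison of the two interferons from its printed
region counts:

```r
library(tricontrast)
fx <- build_fixture(worked_example_regions())
summary <- summarize_classes(classify_genes(fx))
print(summary)
```

```
== M1 (1873 genes, 1873 significant in >= 1 contrast)
  Venn regions: A_only=681 B_only=126 C_only=521 AB=0 AC=433 BC=103 ABC=9 none=0
  Categories:   reciprocal=530 same_direction=559 l4_unique=103 l3_unique=681 unperturbed_both=0 other=0
  unperturbed by lambda4: 681; unperturbed by lambda3: 103
  lambda4-significant-only: 229 (same direction: 126)
== M2 (2538 genes, 2538 significant in >= 1 contrast)
  Venn regions: A_only=1707 B_only=10 C_only=230 AB=0 AC=587 BC=3 ABC=1 none=0
  Categories:   reciprocal=231 same_direction=597 l4_unique=3 l3_unique=1707 unperturbed_both=0 other=0
  unperturbed by lambda4: 1707; unperturbed by lambda3: 3
  lambda4-significant-only: 13 (same direction: 10)
== Totals: reciprocal=761 lambda4-unique=242 (same-direction 136 + opposite 106)
```

Reading the totals: 761 genes are reciprocally regulated (530 in M1 —
521 unique to contrast C, split 290 down-λ3/up-λ4 and 231 up-λ3/down-λ4,
plus 9 significant in both NT comparisons — and 231 in M2); 242 genes
are significant for IFN-λ4 but not IFN-λ3 (136 moved in the same
direction by both interferons, 106 strong λ4 effects with a weak
opposite λ3 effect); and 1707 M2 genes are unperturbed by IFN-λ4,
reflecting its much higher signaling threshold in M2 macrophages.

A full simulated study runs end to end the same way:

```r
cfg <- pipeline_config(sim = sim_config(n_genes = 2000, seed = 1))
bundle <- run_pipeline(cfg, out_dir = "results")
print(bundle$summary)
```

or from the shell via `Rscript inst/scripts/run-pipeline.R --simulate
--seed 1 --out results/`.

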