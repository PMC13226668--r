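# isletpipe

An end-to-end analysis pipeline for droplet scRNA-seq cohorts of human
pancreatic islets spanning non-diabetic (ND), pre-diabetic (PD; HbA1c
5.7–6.4%) and type 2 diabetic (T2D) donors. The package is aimed at
computational biologists who want the full chain — from raw gene×droplet UMI
matrices to prioritized candidate effector genes — as plain, testable R
functions rather than a stack of external tools, together with a seeded
synthetic-cohort generator carrying complete ground truth so every stage can
be validated offline.

## What it implements

- **Ambient-RNA ("soup") decontamination.** The background profile is
  estimated from empty droplets (total UMIs < 10) as
  `b_g = Σ_e n_ge / Σ_e Σ_g n_ge`; per-cell contamination fractions `ρ_c`
  come from a cluster-level unexpressed-gene estimator, and corrected counts
  are `ñ_gc = n_gc − N_c·ρ_c·b_g`. Per-gene removal metrics (`M_g`, `A_g`,
  mean contamination rank `r_g`) summarize the correction across libraries.
- **Genotype demultiplexing of pooled libraries.** Droplets are assigned to
  donors (or donor pairs) by maximizing the read likelihood
  `L(m1, m2, α) = Π_v Σ_{g1,g2} [Π_i ((1−α)P(b_i|g1) + αP(b_i|g2))]
  P_{m1v}(g1) P_{m2v}(g2)` with base-call error `ε`; cross-donor doublets
  are removed.
- **Layered QC.** Per-droplet metrics (nUMI, nFEA, pMT); the preliminary
  filter (nFEA ≤ 500, nUMI ≤ 1000, pMT ≥ 50%); simulated-doublet scoring
  (pN = 0.25, pK = 0.09, nExp = 0.1, nPC = 10, threshold 0.25) with a
  two-scorer consensus; an adaptive per-library feature cutoff (1400,
  relaxed to 1000 for exocrine-enriched clusters); ANOVA + Tukey HSD
  comparisons of per-donor pMT quantiles; and per-cell-type pMT exclusion
  (β at ≥ 40%, others at ≥ 20%).
- **Clustering and annotation.** Library-size log-normalization (scale
  factor 10,000), top-2000 variable genes, PCA, iterative covariate
  alignment (sex, chemistry, ancestry), shared-nearest-neighbour Jaccard
  graphs with seeded Louvain modularity clustering, marker-panel annotation
  (INS/GCG/SST/PPY/…), and one-vs-rest marker tests (logistic-regression or
  negative-binomial LRT).
- **Cluster doublet enrichment.** Per-cluster doublet ratios, odds ratio,
  two-sided Fisher exact test with BH FDR (enriched: OR > 2, FDR ≤ 1%), and
  multi-hormone co-expression corroboration before cluster removal.
- **Pseudobulk NB-GLM differential expression.** Donor×cell-type count
  aggregation, per-gene negative-binomial log-linear models with library
  offsets, profile-likelihood dispersions shrunk toward the common value,
  likelihood-ratio contrasts (T2D vs ND at |log2FC| ≥ 0.585, FDR ≤ 5%),
  and cell-type signature presets.
- **Signed co-expression modules.** Soft-threshold scan for scale-free fit,
  signed adjacency `((1+cor)/2)^t` (default t = 12), topological overlap
  matrix, average-linkage module detection with eigengene merging
  (mergedCutHeight 0.25), and module–trait Spearman correlations.
- **Candidate-gene prioritization.** LD-proxy expansion (r² ≥ 0.80),
  islet eQTL filtering (P < 0.05, direction `++++`/`----` across four
  cohorts), risk-allele-oriented concordance classification against the
  T2D-vs-ND fold change, and integration of islet proteomics and mouse
  knockout glucose-tolerance evidence into a ranked candidate table.
- **Cohort statistics.** Glycemic-state attribute cosine similarity,
  composition ANOVA/Tukey and Games–Howell tests, and composition–HbA1c
  Spearman correlations.

## Worked example

```r
library(isletpipe)

cfg <- sim_config(seed = 42, cells_per_donor = 200, n_genes = 1000,
                  n_empty_droplets = 60000)
sc  <- simulate_cohort(cfg)

# soup profile of one library from its empty droplets
soup <- estimate_soup_profile(sc$raw$LIB01)
soup
#> <soup_profile> 59935 empty droplets (< 10 UMIs); top genes: GCG, INS, SST, ...

# cluster, estimate contamination, demultiplex
filt <- sc$filtered$LIB01
nm   <- lognormalize(filt)
emb  <- embed_pca(nm[select_hvg(nm, 800), ], n_pcs = 20)
cl   <- snn_cluster(emb, k = 20, resolution = 1, seed = 1)
est  <- estimate_contamination(filt, soup, cl$labels)
est$cluster_rho
#> # A tibble: 4 x 2
#>   cluster    rho
#> 1       0 0.0693
#> 2       1 0.0583
#> 3       2 0.0814 ...

dm <- demux_library(filt, subset(sc$pileups, library_id == "LIB01"),
                    sc$genotypes,
                    subset(sc$library_donors, library_id == "LIB01")$donor_id)
table(dm$best_type)
#> doublet singlet
#>      23     326
```

The estimated per-cluster contamination fractions sit near the generative
mean (ρ ~ Beta, mean 0.08, modulated by cell type), the soup ranking is
headed by the hormone genes that dominate islet ambient RNA, and every
singlet call above matches the ground-truth donor (accuracy 1.00 on this
library). `run_pipeline(pipeline_config())` chains all stages on the default
six-donor cohort and returns each stage's result plus a cell-accounting
report in which every removed droplet carries a machine-readable reason.

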