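# topobeta

Matched population diversity of interacting symbiotic gene pools, with a
"topological beta-diversity" statistic (ΔG) for comparing the *unlabeled*
tree structure of two populations.

## The problem

In rhizobium–legume symbiosis the partners talk through the Nod factor: a
rhizobial acyltransferase gene (*nodA*) shapes the signal, a plant LysM
receptor-kinase gene (*NFR5*) reads it.  If host populations mold their
symbiont populations, then across host species (i) the nucleotide diversity
of the plant receptor pool and of the nodule symbiont pool should rank the
same way, and (ii) the *structure* of the nodule pool should resemble the
plant pool more than the surrounding soil pool does.  `topobeta` implements
the complete analysis for pooled amplicon data — plant / nodule / soil pools
per host species — plus a synthetic-data generator so the whole pipeline is
testable without any sequencing data.

## What it computes

* **Diversity**: π (mean pairwise p-distance per site), bootstrap
  distributions (70 sequences × 2000 trials by default), rarefaction, and a
  Spearman rank concordance of plant vs nodule π across species
  (ρ > 0.8 ⇒ monotonic relationship).
* **Selection**: within-pool pN, pS, pN/pS by Nei–Gojobori (1986) counting,
  Tajima's D, one-sided Welch contrasts of nodule over soil on bootstrap
  replicates (α = 0.01), and a synonymous/nonsynonymous site-linkage check.
* **Gene trees**: greedy 95%-identity OTU picking, neighbor-joining trees
  with outgroup rooting, and biovar-clade filtering of improper sequences.
* **Topological beta-diversity (ΔG)**: haplotypes → frequency-weighted
  agglomerative clusters (m clusters with weights f and mean differences σ)
  → median normalization → metric MDS into K = 3 dimensions → Gaussian
  mixture `G(x) = Σ f_i N(x | x_i, σ_i² I)`.  For two pools,

  ΔG = ∫ (G₁/√E₁₁ − G₂/√E₂₂)² dx = 2(1 − E₁₂/√(E₁₁E₂₂)) ∈ [0, 2],

  minimized over rotation, translation and mirror reflection (Procrustes
  superimposition); `E_ij = ∫ G_i G_j dx` has a closed form.  Nodule and
  soil pools are embedded **jointly** and split only for the comparison;
  bootstrap ΔG sets are compared by a one-sided Mann–Whitney U test.
* **Tanglegrams**: plant vs rhizobial cluster NJ trees face to face, leaves
  connected by mutual 5-nearest-neighborhood in the aligned embedding.

## Worked example

```r
library(topobeta)

cfg <- simulation_config(plant_pool_size = 100, rhizobial_pool_size = 400,
                         n_clades = 4, n_haps_per_clade = 6,
                         between_clade_divergence = 10,
                         within_clade_divergence = 2,
                         clade_frequencies = c(0.4, 0.3, 0.2, 0.1),
                         sfs_skew = 0.5, seed = 42)
sys <- simulate_system(cfg)
sys
#> <synthetic_system> plant n=100, nodule n=400, soil n=400 (210 bp, matched)

pi_diversity(sys$plant_pool)
#> <diversity_estimate> plant: pi = 0.04880 (n = 100)
pi_diversity(sys$nodule_pool)
#> <diversity_estimate> nodule: pi = 0.06244 (n = 400)

pn_ps(sys$nodule_pool)
#> <selection_stats> pN=0.0250 pS=0.1850 pN/pS=0.1352 (n=400)
tajimas_d(sys$nodule_pool)
#> [1] 1.9404

tr <- bootstrap_delta_g(sys$plant_pool, sys$nodule_pool, sys$soil_pool,
                        m = 4, K = 3, n_boot = 100, seed = 1)
tr
#> <topology_test_result> DeltaG nodule=0.2503 soil=0.6214
#>   (medians 0.2556 / 0.6203); U=0 p=1.28e-34 alpha=0.01
```

Reading the output: the generated system is "matched" — the nodule pool
mirrors the plant pool's clade structure while the soil pool's clade profile
is permuted and lacks one host-amplified clade.  The aligned ΔG of the
nodule comparison (0.25) is well below the soil comparison (0.62); every one
of the 100 bootstrap ΔG values for nodule sits below every soil value
(U = 0), so the one-sided Mann–Whitney test rejects decisively: the nodule
pool's topology is significantly closer to the plant pool's.  Tajima's D of
+1.94 reflects the balanced four-clade structure of this (unfiltered)
example pool; after biovar-style filtering, skewed within-clade worlds give
the negative D values typical of real amplicon pools.

The full pipeline (ingest → biovar filter → diversity → selection →
topology → tanglegram, one JSON report) runs from a manifest:

```r
fx <- write_fixture_set(sys, "fixtures")
report <- run_full("fixtures/manifest.tsv", out_dir = "out", seed = 1,
                   outgroup_path = "fixtures/outgroup.fasta")
```

or from the shell:

```sh
Rscript inst/cli/topobeta-pipeline.R simulate --out fixtures --seed 1
Rscript inst/cli/topobeta-pipeline.R run-all --manifest fixtures/manifest.tsv \
        --outgroup fixtures/outgroup.fasta --out out --seed 1
```

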