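---
title: "Matched diversity of symbiotic gene pools: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched diversity of symbiotic gene pools: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topobeta)
```

## The scientific question

In rhizobium-legume symbiosis, the first molecular handshake runs through the
Nod factor: a rhizobial acyltransferase gene (*nodA*-like) shapes the signal
molecule, and a plant LysM receptor-kinase gene (*NFR5*-like) reads it.  If
host populations shape their symbiont populations, the *population-level*
diversity of these two interacting gene pools should be matched: more diverse
host receptor pools should carry more diverse nodule symbiont pools, and the
*structure* (tree topology) of the nodule pool should resemble the host pool
more than the surrounding soil pool does.

`topobeta` implements the full analysis for pooled amplicon data: each unit
is a "pool" — an aligned, gap-free set of equal-length sequences from one
origin (plant clones, nodule reads, soil reads) for one host species.

Three lines of evidence are computed:

1. **Diversity concordance.** Nucleotide diversity pi per pool, bootstrap
   distributions (70 sequences with replacement, 2000 trials by default),
   random one-to-one pairing of plant and nodule bootstrap values per
   species, and Spearman's rank correlation over the pooled pairs.  rho
   above 0.8 is read, by convention, as a monotonic relationship.
2. **Selection contrasts.** Within-pool pN, pS, pN/pS (Nei-Gojobori 1986
   counting) and Tajima's D, with one-sided Welch t tests between nodule
   and soil pools on bootstrap replicate values, at alpha = 0.01.
3. **Topological beta-diversity (Delta-G).** The novel statistic: each
   pool's haplotype set is reduced to m clusters by frequency-weighted
   agglomeration, normalized, embedded in K-dimensional space by metric MDS,
   and turned into a Gaussian mixture; Delta-G is the L2 distance between
   two mixtures after Procrustes superimposition (rotation, translation,
   reflection).  Bootstrap Delta-G sets for the plant-nodule and plant-soil
   comparisons are compared by a one-sided Mann-Whitney U test.

## The Delta-G pipeline in detail

**Clustering.** Starting from singleton clusters, the pair at the smallest
distance is merged; the merged cluster's distance to any third cluster is the
frequency-weighted average `(D[i,k] f_i + D[j,k] f_j) / (f_i + f_j)`, its
frequency is `f_i + f_j`, and its "mean difference" sigma is the merge
distance.  Ties are broken by the smallest index pair, making the procedure
fully deterministic.

**Normalization.** Distances and sigmas are divided by the median
off-diagonal reduced distance, so pools of different absolute divergence
become comparable.  Singleton clusters (sigma = 0) receive
`min over clusters with sigma != 0 of sigma_i * f_i`.  The operator scope of
that substitution rule is ambiguous in prose; the alternative reading
(`min(sigma) * f_i` with the cluster's own frequency) is available via
`zero_sigma_rule = "min_sigma_times_own_f"`.  If *every* sigma is zero (a
monomorphic-cluster corner case), sigmas are set to a fixed 0.1 of the median
and the result is flagged degenerate.

**Embedding.** Metric MDS minimizes raw stress by SMACOF majorization,
initialized from classical Torgerson scaling.  Majorization never increases
stress, so the result is at least as good as the classical start; the
embedding is centered and deterministic (the seed only jitters a degenerate
all-coincident start).

**The mixture and Delta-G.** Each cluster becomes an isotropic Gaussian
component with weight f and standard deviation sigma (sigma is interpreted
as an SD, not a variance).  For two mixtures with cross-integrals
`E_ij = int G_i G_j dx` (closed form via Gaussian product integrals),

\[
\Delta G \;=\; \int \Bigl(\tfrac{G_1}{\sqrt{E_{11}}} -
\tfrac{G_2}{\sqrt{E_{22}}}\Bigr)^2 dx
\;=\; 2\Bigl(1 - \tfrac{E_{12}}{\sqrt{E_{11}E_{22}}}\Bigr) \in [0, 2].
\]

This is an L2 distance between *unit-L2-normalized* mixtures.  The design
space here was genuinely open (the originating method defers to an external
formula that is not reprinted); we first implemented the plain normalized L2
`(E11 + E22 - 2 E12)/sqrt(E11 E22)` and found it degenerates in practice:
whenever the two pools' sigma profiles differ, the energy ratio term
`sqrt(E11/E22) + sqrt(E22/E11)` dominates and Delta-G stops measuring
geometry at all (it is then hypersensitive to the sharpest component's
sigma).  The unit-normalized form coincides with the plain form whenever the
energies are equal, is bounded in [0, 2], is zero iff the mixtures are equal,
and approaches 2 as they separate — and it preserves discriminative power on
synthetic systems.  The choice is isolated in `delta_g()`.

**Procrustes superimposition.** Components are unlabeled, so the search is
over rigid transforms, not correspondences.  Candidate rotations come from
aligning the frequency-weighted component covariances' principal axes under
all `2^K` sign combinations (covering mirror reflections), plus random
orthogonal starts and optional warm starts; the best candidates are refined
by Nelder-Mead over rotation parameters (exponential map of a skew-symmetric
matrix) and translation.  A restarted second refinement escapes shallow
Nelder-Mead stalls.  With 20 random starts this recovers a planted random
rotation + translation + reflection to Delta-G <= 1e-6 in >= 95% of trials.

**Joint embed/split protocol.** Nodule and soil sequences are pooled before
clustering and MDS and separated only for the Procrustes comparisons, so
shared haplotypes are represented identically in both comparisons.
Per-origin mixtures reuse the joint coordinates and sigmas with weights
equal to the origin's share of each cluster; clusters an origin never
touches are omitted from its mixture.

**Bootstrap and inference.** The joint clustering and embedding are held
fixed; each replicate resamples sequences with replacement within each
rhizobial origin, recomputes that origin's cluster weights through the fixed
membership map, and re-runs the alignment.  One subtlety discovered during
null calibration: if each arm's bootstrap alignments are warm-started only
from that arm's own full-data transform, an arm that happened to land in a
better optimization basin keeps a systematic advantage, and the
Mann-Whitney test anti-conservatively rejects even for *identical* nodule
and soil pools.  Both full-data transforms are therefore supplied as warm
starts to every replicate alignment, making the candidate sets symmetric;
with identical pools the rejection rate at alpha = 0.01 is then nominal.

The one-sided Mann-Whitney U test uses the exact Wilcoxon distribution when
there are no ties and the smaller sample has at most 8 values, otherwise a
tie-corrected normal approximation with continuity correction.

## Tanglegrams

Two neighbor-joining trees (plant clusters vs rhizobial clusters, built from
the between-cluster distance matrices) are drawn face to face; leaves are
connected when their embedded points are mutual k-nearest neighbors (k = 5
by default) in the Procrustes-aligned frame, neighborhoods taken within the
opposite set only.  On matched synthetic systems the plant-nodule tanglegram
carries at least as many edges as the plant-soil one in the large majority
of replicates.

## Supporting machinery and conventions

* **pi** is the raw mean pairwise p-distance (no multiple-hit correction):
  the source analyses use plain "numbers of differences" throughout, and at
  these divergences (< 15%) the correction would be a near-constant factor.
* **Tajima's D** uses the standard 1989 constants with pi as the
  unnormalized mean pairwise difference count.
* **Nei-Gojobori counting**: each codon position contributes fractional
  synonymous weight (#synonymous single-base changes)/3; multi-difference
  codons are averaged over all mutational pathways, excluding pathways
  through stop codons unless all are blocked; mutations to stop codons count
  as nonsynonymous.
* **OTU picking** is deterministic abundance-ordered greedy centroid
  clustering at 95% identity (the core UCLUST heuristic, reimplemented so no
  external binary is needed); identity is `1 - hamming/length`.
* **Neighbor joining** clamps negative branch lengths to zero (the common
  MEGA convention) and roots at the midpoint of the outgroup's pendant
  edge.  The two biovar clades are delimited by descending from the root
  past the outgroup to the first node whose children both contain OTU
  leaves — one reasonable formalization of a split that the source describes
  only visually.
* **Welch contrasts** run on bootstrap replicate values of the statistic
  (the replicate unit was not stated in the source; resampling sequences
  with replacement mirrors the pi bootstrap).
* **Seed fan-out**: the pipeline derives each stage's seed from the global
  seed and the stage name by a documented integer hash, so stages are
  independently reproducible and two runs with one seed are identical.

## What the synthetic generator emulates — and what it does not

`simulate_system()` emits one plant/nodule/soil triplet: ~100 plant clones
and (by default) 3500 rhizobial reads of 210 bp, collapsing to a few dozen
haplotypes organized in clades, with an outgroup at twice the between-clade
divergence.  Key dials:

* **Clade structure**: `n_clades` founders at `between_clade_divergence`
  expected substitutions from the ancestor; haplotypes arise on a star
  genealogy (`within_clade_divergence` expected private substitutions), with
  haplotype 1 being the founder itself.
* **SFS skew**: within-clade weights are flat Dirichlet plus `sfs_skew`
  extra mass on the founder.  Because the star genealogy makes each variant
  private to one derived haplotype, founder mass directly controls the
  rare-allele excess; `sfs_skew = 0` is neutral-like and larger values drive
  Tajima's D down.  (An earlier design that skewed the Dirichlet
  concentration itself moved D the *wrong* way: uneven weights create
  intermediate-frequency variants, which raise D.)
* **Topology matching**: under a star genealogy the haplotype distance
  matrix is governed by per-haplotype mutation counts, so
  `topology_match = "matched"` shares one set of counts (but not positions)
  between the plant and rhizobial sides, making the two cluster geometries
  congruent; the nodule pool then mirrors the plant pool's clade and
  haplotype weights.  The soil pool gets a permuted, Dirichlet-perturbed
  clade profile and, with `nodule_private_clade = TRUE`, entirely lacks the
  plant's second-most-frequent clade — emulating a host-amplified clade that
  sits below the soil detection limit.  Choosing a *prominent* clade for
  this role follows the source's own causal story (host-selected genotypes
  are amplified in nodules); dropping the rarest clade instead produces a
  much weaker, noisier signal.
* **Codon structure**: mutations are placed by rejection against the codon
  table with probability `nonsyn_fraction` of being nonsynonymous, and no
  sequence ever contains an in-frame stop.

Two deliberate simplifications: there is no sequencing-error or chimera
model, and the within-clade genealogy is a star rather than a full
coalescent (a neutral Kingman coalescent mode exists separately, used only
to calibrate Tajima's D).  A green test on these fixtures therefore
establishes the statistical machinery and the direction of the designed
effects — not robustness to real amplicon noise.

The power and null properties of the topology test are exercised in a
"post-biovar-filter" world: `n_clades = 4` sub-clades at moderate divergence
(10 between, 2 within) analysed at `m = 4`, so clusters resolve clades and
the mixture blobs overlap enough for Delta-G to be informative.  With deep
two-clade structure (the OTU/biovar world), cluster blobs are so widely
separated relative to their sigmas that Delta-G saturates near its maximum
and carries little signal; this matches the source's workflow, which applies
the topology analysis only after improper-biovar sequences are removed.
Test runs scale pool sizes down (400 rhizobial reads) purely for runtime;
the prescribed statistical settings (subsample 70, n_boot = 100,
alpha = 0.01, rho threshold 0.8) are used as stated, with the prescribed
2000 bootstrap trials scaled to 200 where the build contract says so.

## Known limitations

* Delta-G is a pseudo-metric on aligned mixtures; it is not a tree metric
  and has no analytic null distribution — inference is purely by bootstrap
  contrast, which tests the *difference between comparisons*, not absolute
  congruence.
* With distributionally identical (rather than literally identical) nodule
  and soil pools, a bootstrap-vs-bootstrap Mann-Whitney comparison is
  intrinsically anti-conservative, as any two-sample test on bootstrap
  replicates is; the null calibration here uses identical pools, which is
  the well-defined null of the procedure.
* The Procrustes search is a heuristic global optimization; with very many
  clusters (m >> 10) or near-symmetric configurations it can return local
  optima.  All alignments report a `converged` flag and accept extra
  random starts.
* `pN/pS` is reported but, as the linkage check (`site_linkage_check()`)
  will typically confirm on short amplicons, pN and pS are not independent,
  so pN is the primary contrast statistic.
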