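# matdiv

Population-genetic analysis of a mating-type (MAT A) linked sequence
marker in dikaryotic fungi, with a forward simulator of the underlying
balancing selection. The package is aimed at researchers studying
mating-type systems in basidiomycetes (and analogous multiallelic
self-incompatibility systems), where negative frequency-dependent
selection — rare MAT alleles find compatible mates more often — maintains
allelic richness through founder bottlenecks and, via linkage, elevates
diversity at neighbouring neutral sequence such as the *mip* region next
to MAT A.

## What it computes

Given per-locus alignments, per-isolate clone reads and a sample sheet
(or their simulated equivalents), the pipeline runs:

- **Clone-based allele calling** — single-linkage clustering of the
  cloned amplicons at 2% divergence, then per-cluster consensus with the
  PCR-artifact rules: variants carried by exactly one clone
  (autapomorphic) are discarded when m ≥ 3, disagreements between exactly
  two copies become two-fold IUPAC codes, single copies are accepted
  verbatim.
- **Haplotype phasing** of IUPAC-coded genotype sequences, minimising the
  number of distinct alleles: 0/1-het sequences are forced and act as
  templates; multi-het sequences are matched to templates or resolved by
  minimum mutational steps, with fixed tie-breaks.
- **Diversity and neutrality statistics** per locus and group, under
  complete deletion: segregating sites S, mutation counts η and η_s, mean
  pairwise differences k, nucleotide diversity π = k/L, per-locus
  Watterson estimator θ_W = S / a₁(n) with a₁(n) = Σ_{i=1}^{n−1} 1/i,
  Tajima's D = (k − S/a₁) / √(e₁S + e₂S(S−1)), and Fu & Li's outgroup-free
  D\* and F\* with the Simonsen-corrected constants.
- **Multilocus two-taxon HKA test**: per locus, E[S_a] = θ_i a₁(n_a),
  E[S_b] = fθ_i a₁(n_b), E[d] = θ_i(T + (1+f)/2); the X² goodness-of-fit
  statistic is minimised numerically and its null distribution is built
  by coalescent simulation with refitting in every replicate.
- **Within-dikaryon divergence test**: mean pairwise similarity of the
  two alleles co-occurring in an isolate versus allele pairs across
  isolates, by Welch's unequal-variance t test plus a seeded permutation
  test.
- **Forward Wright–Fisher simulation** of a haploid population where
  every offspring requires two MAT-incompatible parents (mechanical
  rare-allele advantage), with a linked marker, unlinked neutral loci,
  founder bottlenecks, dikaryon sampling, IUPAC genotypes and PCR-error
  clone reads — generating every input above with a truth record.

## Worked example

Simulate a bottlenecked founder population and run the full pipeline on
the emitted files:

```r
library(matdiv)
cfg <- sim_config(N = 120, generations = 150, L_marker = 300, L_neutral = 300,
                  n_neutral_loci = 2, K_init = 6,
                  bottleneck = list(time = 100, size = 12, duration = 20),
                  sample_n_dikaryons = 30, epsilon = 0, missing_allele_prob = 0.3,
                  seed = 42)
res <- run_pipeline(run_config(out_dir = tempfile(), sim = cfg,
                               n_perm = 999, seed = 42))
format_summary_table(res$summary)
```

```
    Locus Group    Ecol  #  S       k     pi ThetaW TajimaD FuLiDstar FuLiFstar
   marker   all       B 52 28 13.8198 0.0461 6.1963  4.0447    1.8148    2.9321
 neutral1   all unknown 60  1  0.0333 0.0001 0.2144 -1.0839   -1.8935   -1.7004
 neutral2   all unknown 60  2  0.0989 0.0003 0.4289 -1.3153   -0.9429   -1.0924
```

The bottleneck flattened the neutral loci (π ≈ 10⁻⁴, one or two
segregating sites among 60 haplotypes) while the MAT-linked marker kept
π = 0.046 across 28 segregating sites — the linkage-to-MAT signature. Its
positive Tajima's D reflects the few deeply diverged allele lineages kept
at intermediate frequency by the compatibility constraint. The dikaryon
test on the same run:

```r
res$dikaryon
#> within = 0.910, across = 0.955, t = -35.68 (df 1323.9),
#> Welch p = 6.7e-196, permutation p = 0.001
```

Alleles co-occurring in an individual are less similar than random allele
pairs (negative t): with only a few MAT alleles left after the
bottleneck, compatible pairings are forced across divergent allele
lineages.

And the headline worked value: `watterson_theta(116, 182)$theta_w`
returns `34.17` (per-locus θ_W from 182 segregating sites in 116 marker
haplotypes).

## The analysis workflow

`analysis/01_simulate.R` … `06_dikaryon_test.R` run the study end to end
on two simulated sister populations (a bottlenecked indoor founder
population and a diverse outdoor source population sharing founder
lineages): simulate and emit inputs, call alleles from clone reads, phase
the neutral genotypes, tabulate per-locus/per-group statistics, run the
HKA test of the marker against the neutral loci (with a neutral-only
control), and run the within-dikaryon divergence test per population.
Each script prints what it found and writes its tables under
`results/analysis/`. Run them in order from the repository root:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

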