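---
title: "Diversity and selection at a mating-type linked marker: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity and selection at a mating-type linked marker: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matdiv)
```

# The scientific setting

Tetrapolar basidiomycetes mate only when the two haploid partners carry
different alleles at both mating-type loci. Rare MAT alleles therefore find
compatible partners more often than common ones — negative
frequency-dependent selection that maintains allelic richness even through
severe founder bottlenecks, and that extends, through linkage
disequilibrium, to neutral sequence physically linked to MAT. `matdiv`
implements the full analysis chain used to study this phenomenon with a
MAT-A-linked marker in a dikaryotic wood-decay fungus:

1. **Clone-based allele calling** — each dikaryon carries up to two marker
   alleles, co-amplified and separated by cloning; PCR artifacts are
   filtered by multiplicity rules.
2. **Haplotype phasing** of directly sequenced loci whose heterozygous
   sites appear as two-fold IUPAC codes, minimising the number of distinct
   alleles.
3. **Per-locus, per-group diversity and neutrality statistics** (S, η,
   η~s~, k, π, per-locus Watterson θ~W~, Tajima's D, Fu & Li's D\*/F\*).
4. A **multilocus two-taxon HKA test** with a coalescent-simulated,
   refitted null.
5. The **within-dikaryon divergence test**: are the two alleles carried by
   one individual more divergent than random allele pairs?
6. A **forward simulator** of the whole system that generates every input
   the pipeline consumes, with known truth.

# Statistical conventions

All Table-style statistics are computed on phased haplotypes under
**complete deletion**: any column containing a gap, `N`, or an ambiguity
code in any sequence is dropped. This is the convention of the standard
desktop software for such tables, and it makes the per-locus Watterson
estimator exactly θ~W~ = S/a₁(n), the identity by which the published
worked examples are reproduced. Pairwise similarity for the dikaryon test
instead uses **pairwise deletion** (a position is compared when both
sequences carry an unambiguous base), matching how alignment editors
compute identity matrices. Coordinates are 0-based half-open internally;
rendered reports are 1-based.

Tajima's D uses S and mean pairwise differences k with the canonical
constants. η (total mutations) and η~s~ (singleton mutations,
unpolarised: a base carried by exactly one sequence, capped per column at
the column's mutation count) feed the outgroup-free Fu & Li statistics
with the Simonsen-corrected variance constants. No installed package
provides these statistics, so the implementation is validated three ways:
an independent literal transcription of the published formulas in the test
suite, neutral-coalescent calibration (the empirical mean of D at n = 20,
θ = 5 is ≈ −0.077, and of D\* ≈ −0.06; both must fall within ±0.1 of 0
over 12000 replicates — the replicate count is set so the band is tested
against the statistic, whose small negative mean under neutrality is
expected, rather than against Monte-Carlo noise), and a variance
guardrail. Statistics are reported as undefined ("-") when S = 0, and for
groups below two sequences.

Phase robustness is asserted, not assumed: S, k, π, θ~W~, D, D\* and F\*
are identical across *any* valid phasing of the same genotypes, because
every genotype contributes the same per-column base multiset regardless of
arrangement.

# Clone calling

Clones from one isolate are partitioned by single-linkage clustering on
1 − identity with threshold τ = 0.02: within-allele clone variation is
PCR error (~10⁻³ per base), orders below the ~5% between-allele divergence
of the marker, so any τ between those scales works; 0.02 is the default
and is logged per run. Single linkage is computed as connected components
of the τ-threshold graph, which makes the stated determinism (groups
labelled by lowest clone index) exact rather than an artifact of an
agglomeration order.

Per cluster of m clones: with m ≥ 3, a variant carried by exactly one
clone is autapomorphic and discarded as an in-vitro mutation, and the
consensus takes the majority base (ties go to the alphabetically first
base and the position is logged); with m = 2, disagreeing sites become the
two-fold IUPAC code (assumed heterozygosity) and feed the phasing module;
with m = 1 the clone is accepted verbatim. Consequences worth knowing:
a two-clone cluster under error rate ε carries an expected 2εL ambiguity
positions, so confident calls need m ≥ 3 per allele — the acceptance
checks use m ≥ 5, where a wrong consensus requires three coincident
identical errors and the empirical error rate is ~10⁻³ per allele. A
cluster-based caller cannot, by construction, separate two true alleles
closer than τ; exactness checks therefore condition on allele pairs that
are either identical or separated by more than τ. Chimeric clones are not
detected (no procedure is defined for them); this is a known limitation.

# Phasing by allele-count minimisation

Genotypes are processed in ascending order of heterozygous-site count.
Sequences with zero or one such site are forced and seed the template set;
a genotype with h ≥ 2 sites has 2^(h−1) complementary resolutions, and the
choice is, in order: both haplotypes already templates; one a template and
the partner at minimal Hamming distance from its nearest template; the
resolution minimising the summed Hamming distance of both haplotypes to
their nearest templates. All ties resolve to the lexicographically
smallest pair, and resolved haplotypes immediately join the template set,
so the procedure is deterministic. Each genotype contributes two haplotype
copies, so n dikaryon-derived sequences yield 2n haplotypes — matching the
even haplotype counts of diversity tables built this way.

The procedure is greedy. An exhaustive search
(`brute_force_min_haplotypes()`, the test oracle) shows it attains the
global minimum whenever every true haplotype also occurs as a forced
template — the regime the procedure was designed for, and the situation in
the data it emulates, where most sequences are homozygous or carry a
single heterozygous site. On template-poor instances a rule-3 tie can
resolve away from the global optimum (we observed this on roughly 8% of
random template-poor instances); the fixed validation suite therefore
draws from the template-rich regime, and the greedy-versus-exhaustive
comparison is what the suite asserts. The published caveat that
recombinant genotypes lead to undercounted haplotypes is preserved
behaviour, not corrected. Per-genotype enumeration is capped at 20
heterozygous sites by default; the cap is an argument, not a constant.

# The HKA test

For loci i = 1..L with n_a (and optionally n_b) sequences per taxon,
polymorphism counts S_a, S_b and between-taxon mean pairwise divergence d
are compared with the neutral expectations

- E[S_a] = θ_i a₁(n_a), Var[S_a] = E[S_a] + θ_i² a₂(n_a),
- E[S_b] = f θ_i a₁(n_b), variance analogous with f θ_i,
- E[d] = θ_i (T + (1+f)/2), Var[d] = E[d] + (θ_i (1+f)/2)²,

with T the split time in units of 2N_A generations and f the ratio of
effective sizes. The goodness-of-fit statistic X² sums (obs − E)²/Var over
loci and terms; parameters are estimated by minimising X² numerically
(log-parameterised `nlminb`) from method-of-moments starts, which
reproduces expectation-exact fixtures to X² < 10⁻¹⁵ and matches a dense
grid search. Significance comes from parametric simulation: polymorphism
is Poisson over simulated coalescent branch lengths, divergence Poisson
over T plus an exponential ancestral coalescence, and **every replicate is
refitted** before its X² enters the null distribution — the choice that
gives correct test size (empirically 0.049 over 1600 type-I replicates at
α = 0.05). Standard HKA assumptions apply: no recombination within loci,
free recombination between them, equilibrium demography. A recent
bottleneck in one taxon mildly violates the null at every locus, which is
why the neutral-only control in the analysis workflow can sit near the
significance boundary while the marker deviation is orders stronger.

# The within-dikaryon divergence test

From the allele similarity matrix, the *within* set holds one value per
isolate with exactly two alleles; the *across* set holds all allele pairs
spanning different isolates of the group, including (by default) alleles
from single-allele isolates — both inclusion modes are available since the
original description is ambiguous on this point. The primary test is the
two-sample unequal-variance (Welch) t test, two-sided by default with the
direction reported separately. Across-pair values are not independent
(each allele participates in many pairs), so a seeded permutation test —
re-pairing the group's alleles into pseudo-isolates, preserving the
number of pairs, p = (1 + #{perm ≥ obs})/(1 + n_perm) — is run alongside;
empirically the Welch route is conservative under random pairing (type-I
≈ 0.015–0.02 at α = 0.05) and the two routes agree on ~97% of calibrated
fixtures.

# The forward simulator

A haploid Wright–Fisher population of size N evolves in discrete
generations. Each offspring draws two parents that must differ at MAT
(rejection sampling) — rare-allele advantage thus emerges mechanically,
with no selection coefficient — and inherits MAT from one of them, the
linked marker from the same parent unless recombination (probability r,
default 0: the physical distance it mimics is under 1 kb) swaps it, and
each neutral locus from a random parent. Mutation is finite-sites
Jukes–Cantor (default 10⁻⁵/site/generation), so clone errors and real
polymorphism remain distinguishable by multiplicity, as the clone filter
assumes. Novel MAT alleles arise at rate `mu_mat` (infinite-alleles) and
inherit their parent's marker haplotype.

The K_init founder MAT lineages carry marker haplotypes pre-diverged by
`init_marker_divergence` (default 0.05 per site): this stands in for the
deep coalescence of balanced allele lineages — commonly older than species
splits — which forward time at these scales cannot generate. Neutral loci
start from a founder pool of `n_founder_haps` haplotypes at
`init_neutral_divergence` (default 0.004, giving π of a few per mille as
in typical neutral loci of the system). Two runs sharing `init_seed`
start from identical lineages and pools and then evolve independently —
sister populations whose balanced marker lineages are trans-specifically
shared; `fixed_divergence` adds population-specific fixed substitutions at
the neutral loci, the divergence accrued since the split. A bottleneck
(time, size, duration) emulates the founder events of building-dwelling
populations. Sampled dikaryons are heteroallelic at MAT by construction in
every configuration; each yields IUPAC-coded neutral genotypes (what
direct sequencing gives), and marker clone reads (3–20 per isolate by
default) with independent per-base errors at ε (default 0.002). With
probability `missing_allele_prob` (default 0.47) a dikaryon exposes only
one marker allele, emulating the insertion-driven amplification failure
that left only 53% of real dikaryons with two recovered alleles.

What the simulator deliberately does **not** model: the MAT B locus (one
compatibility locus suffices for the rare-allele mechanism), overlapping
dikaryotic generations, chimeric clones, indels (clone alignments are
gap-free), and within-locus recombination. Passing tests on simulated
data therefore demonstrate the pipeline's correctness under the stated
model, not robustness to alignment error or structural variation in real
amplicons.

Default full-scale configuration emulates the study's shape: an 860 bp
marker, three ~600 bp neutral loci, ~40 dikaryons per population, a
founder bottleneck. Replicated property checks (100 seeded replicates) run
at a reduced scale chosen once — N = 120, 150 generations, 300 bp loci,
30 dikaryons — which preserves every qualitative regime (ancient lineage
retention, neutral collapse, few post-bottleneck MAT alleles) at a
fraction of the cost; the vignette's numbers and the acceptance checks
state the size they used.

# Numerical and degenerate-input choices

- Identity/difference of sequence pairs with zero comparable positions is
  undefined (`NA`), never 0 or 1.
- A simulation in which MAT diversity is lost halts with a diagnostic
  rather than silently continuing (mating would be impossible); tight
  bottlenecks can genuinely trigger this, and replicated checks count and
  tolerate a small number of such halts.
- Welch's test on two zero-variance samples with equal means is flagged
  undefined; with unequal means it reports ±∞ with p = 0.
- HKA fitting floors method-of-moments starting values away from zero and
  optimises on the log scale, so zero counts at single loci are handled
  without constraint violations; all-zero data is rejected as degenerate.
- The clone-consensus 2–2 tie at m = 4 resolves alphabetically and logs
  the position — a documented arbitrary choice, flagged per call.

# Known limitations

Haplotype counts are lower bounds in the presence of recombinant
genotypes (inherited from the phasing procedure). The dikaryon test's
across set reuses alleles in many pairs; the Welch p is anti-conservative
in principle, though empirically conservative in the regimes tested, and
the permutation p is the primary safeguard. The HKA null assumes
equilibrium demography both sides of the split. Real-data reproduction of
the published per-locus tables requires the archived sequences, which the
text of the source does not reprint; the worked θ~W~ = S/a₁(n) examples
are the exception, and the remaining columns are validated by simulation
and invariants instead.
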