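---
title: "Methods: colony racial ancestry from pooled SNPs and mtDNA haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colony racial ancestry from pooled SNPs and mtDNA haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apiadmix)
```

## The problem

Africanized honey bees are hybrids of the African lineage (*A*, derived from
*Apis mellifera scutellata*) with European-derived subspecies of the Western
European (*M*) and Eastern European (*C*) lineages. A colony's ancestry has
two distinct components: the maternal line, read from the maternally
inherited COI--COII intergenic region of the mitochondrial genome, and the
nuclear genome, which mixes the queen's ancestry with that of the many
drones she mated with. The two can disagree — a European-mothered colony
whose queen mated with Africanized drones carries European mtDNA over a
largely African nuclear background — and quantifying that disagreement per
region and management type is the scientific point of this package.

`apiadmix` implements the full chain: per-colony nuclear admixture
estimation by maximum likelihood from pooled-worker SNP allele counts,
maternal lineage classification and haplotype-network construction from
mtDNA sequences, and the confidence-interval machinery that compares the
two marker systems at their respective effective sample sizes.

## Nuclear admixture model

Each colony is genotyped as a pool of 20 workers, i.e. `n = 40` allele
copies per locus. For a panel of `L` ancestry-informative biallelic SNPs
with known reference-allele frequencies `pA_j, pM_j, pC_j` in the three
source lineages, a colony with admixture proportions `(A, M, C)` on the
2-simplex has expected pooled frequency

    p_j = A * pA_j + M * pM_j + C * pC_j.

The observed copy number `r_j` of the reference allele among the 40 sampled
alleles is modelled as `Binomial(40, p_j)`, independently across loci, so
the log-likelihood is the sum of binomial log-probabilities over the
colony's non-missing SNPs. The estimate is the simplex point minimizing the
negative log-likelihood.

Assumptions worth stating explicitly:

* **Independence of the 40 alleles.** Workers share a queen and fall into
  patrilines (subfamilies by drone father), so pooled alleles are not truly
  independent draws. The estimator keeps the binomial form regardless — that
  is the model the study design uses — and the simulator's *family* mode
  exists precisely to quantify the extra variance this ignores (see below).
* **Independence across loci.** No linkage modelling; the likelihood is a
  product over SNPs.
* **Deterministic mixture frequency.** `p_j` is a deterministic function of
  `(A, M, C)`; no colony-level random effect on frequencies is modelled.
  A hierarchical reading (random `p` per colony) would need a different
  integral and is deliberately not implemented.

### Optimization

The simplex constraint is handled by a softmax reparameterization: two free
logits (the third pinned to 0 for identifiability) map to `(A, M, C)`, and
the objective is minimized unconstrained with `stats::nlm`. Because weakly
informative panels can produce flat or multimodal surfaces, every fit uses
multi-start: the three simplex corners (at logit magnitude 4, i.e. about
0.96 ancestry, so gradients remain useful), the barycenter, and four seeded
random starts. Defaults: gradient tolerance `1e-8`, 500 iterations per
start.

Two numerical guards matter:

* **Frequency clamping.** Mixture frequencies are clamped to
  `[1e-6, 1 - 1e-6]` before entering the likelihood. Without this, a panel
  frequency of exactly 0 or 1 combined with a disagreeing observed count
  gives a negative-infinite log-likelihood and a dead optimizer.
* **Flat-likelihood detection.** When every lineage has the same frequency
  at every SNP the likelihood is constant on the simplex and `(A, M, C)` is
  unidentifiable. A fit is flagged when both the spread of the multi-start
  optima and the spread of the likelihood across the three simplex corners
  fall below `1e-6`. Flagged estimates should not be interpreted.

An exhaustive **grid oracle** (`grid_oracle()`) evaluates the likelihood on
the full 0.01-step simplex lattice (5151 points) with ties broken toward
lexicographically smallest `(A, M)`. It exists to verify the smooth
optimizer — the estimate must never be worse than the best lattice point —
and is used that way in the test suite and acceptance checks, not as the
production estimator.

### Counts versus frequencies

The likelihood consumes integer counts. Files that carry pooled
*frequencies* (as variant callers emit) are converted once at load time by
rounding `p * n_alleles` half away from zero; the conversion never happens
inside the optimizer, keeping the binomial exact. Panel SNPs absent from a
colony are dropped from that colony's likelihood product rather than
imputed.

## The synthetic-colony generator

No field data ship with the package; the generator provides datasets with
known truth for every estimator. Its defaults *are* the study conditions:

| parameter | default | why |
|---|---|---|
| `n_snps` | 94 | size of the ancestry-informative panel used in the field |
| `n_workers` | 20 | workers pooled per colony (40 allele copies) |
| `n_drones` | 12 | conservative estimate of queen mating frequency |
| `true_admixture` | (0.59, 0.24, 0.17) | national mean nuclear ancestry |
| `maternal_lineage_probs` | (0.59, 0.02, 0.39) | observed mito lineage frequencies over A/M/C |
| `n_colonies`, `n_apiaries` | 48, 8 | desk-scale stand-in for 509 colonies / 64 apiaries; 6 colonies per apiary sits inside the field range of 3--12 |
| `prop_managed` | 0.713 | managed share of sampled colonies (363/509) |
| `seq_length` | 600 | typical COI--COII amplicon scale |

Two panel modes: *diagnostic* (each SNP nearly fixed in one lineage,
frequency `1 - eps` with `eps = 0.01`; maximally informative, and `eps` is
kept off zero so likelihoods stay finite) and *beta* (iid Beta(0.5, 0.5)
frequencies per lineage, a spread of informativeness closer to a real
panel).

Two sampling modes:

* **idealized** — pooled counts drawn `Binomial(40, p_j)`; exactly the
  estimator's model, so recovery failures indicate estimator bugs, not
  model mismatch.
* **family** — the queen's two alleles and each drone's single allele are
  drawn per locus from lineage origins sampled by the truth vector; each
  worker gets one queen allele (independent meiosis per locus) and the
  allele of a father assigned uniformly at random among the `d` drones
  (multinomial patrilines — queens use sperm randomly; patriline skew is
  not modelled). Pooled counts sum the workers. With few drones this
  inflates between-colony variance well beyond binomial, which is the
  honest analogue of the field's pooled design. By construction the pooled
  frequency equals the mean of the workers' individual genotypic
  frequencies exactly, so the pooled-vs-individual concordance is 1 here —
  the package documents this as a structural identity, not a reproduction
  of the empirical correlation reported for the lab protocol.

Maternal lineage is drawn independently of the nuclear truth vector by
default. That decoupling is intentional: the central comparison of the
analysis is between mitochondrial and nuclear ancestry, so the simulator
must be able to produce concordant and discordant scenarios at will.

mtDNA sequences are simulated over `{A, C, G, T}` without indels: one
ancestor per lineage (A, M, C, O, Y), each mutated at its own disjoint
block of `between_lineage_substitutions` sites from a shared root (pairwise
ancestor distance therefore at least twice that), and each colony sequence
is its maternal ancestor with at most `within_lineage_mutations` extra
substitutions. The precondition `between > 2 * within` guarantees
nearest-reference classification recovers the simulated lineage exactly.
Real COI--COII data have length variation (P/Q element copy number) that
this generator does not emulate; indel handling is exercised through the
aligner's unit-cost model on hand-written fixtures in the tests instead.
Passing tests on simulated data therefore demonstrate correctness of the
estimators under their assumed model, not robustness to every artefact of
field sequences.

All randomness flows from the single `seed` in the configuration; public
simulation functions save and restore the caller's RNG state.

## mtDNA haplotyping

Sequences are normalized (uppercase, gaps stripped, alphabet checked), and
all distances are unit-cost global-alignment edit distances in which `N`
matches any base at zero cost — an ambiguous base call should not mint a
new haplotype. On N-free sequences the distance is a metric; the wildcard
breaks the triangle inequality in general, which is why the metric
property tests use N-free draws.

* **Classification** assigns the lineage of the nearest reference; ties
  across lineages return `unknown` with an ambiguity flag. This
  deterministic nearest-reference rule replaces the phylogenetic placement
  a tree-building tool would give; the two agree whenever lineages are well
  separated, and it is fully testable.
* **Deduplication** groups exact matches after normalization; haplotype ids
  are ordered by count (descending) then first appearance. Published
  haplotype nomenclature (A1e, C2j, ...) is not assigned — that requires a
  curated catalogue; ids here are generated.
* **The network** connects haplotypes at most `max_steps` mutational steps
  apart (default 10) and keeps a minimum-total-distance spanning forest
  (Kruskal), plus any non-forest edge that could replace a forest edge at
  equal weight, flagged as an alternate. The statistical-parsimony
  connection limit of TCS-style methods is replaced by this user-set step
  limit; the probability-of-parsimony formula is intentionally out of
  scope.
* **Mitochondrial Africanization** of an apiary is the percentage of its
  classified colonies carrying an A-lineage haplotype; `unknown` colonies
  shrink the denominator rather than counting as non-African, and an
  apiary with no classifiable colony reports a missing value.

## Comparing mitochondrial and nuclear ancestry

For a group of `n` colonies, the mitochondrial proportion of a lineage is a
true binomial proportion over `n` classified colonies. The nuclear side
uses the group mean of the per-colony admixture proportions with an
effective allele count of `(2 + 12) * n`: two queen alleles plus twelve
drone alleles per colony. Both get Wald intervals
`p ± z * sqrt(p (1 - p) / n_eff)` with `z = 1.96`, truncated to `[0, 1]`,
degenerate (zero-width) at `p` of exactly 0 or 1. Non-overlapping intervals
give a verdict for the side with the higher point estimate; overlapping
intervals are reported as not distinguishable.

Applying a binomial-proportion interval to a mean of continuous admixture
fractions is not orthodox statistics — the admixture mean is not a count —
but it is exactly the comparison the analysis pipeline is defined to
perform, so the package reproduces it faithfully and documents the choice
here rather than silently substituting, say, a t-interval. Lineages O and Y
can appear in mitochondrial summaries but have no nuclear counterpart (the
SNP panel spans A/M/C only); their rows carry missing nuclear columns and
no verdict. Regression-style analyses of ancestry on latitude or altitude
are out of scope; the exported tables carry the covariates so any model can
be fitted downstream.

## Problem sizes and runtime

The shipped tests and acceptance checks run at the study's marker scale
(L = 94, 40 alleles) with replicate counts chosen to keep the whole suite
in the low minutes on one core: 100 random instances for exact-likelihood
agreement, 50 colonies for grid-oracle dominance, 200 replicates for
vertex/interior recovery, 200 colonies for haplotype-lineage recovery, 500
triples for metric axioms. Consistency checks use L in {10, 94, 500}.

## Known limitations

* Point estimates only: no standard errors on `(A, M, C)` beyond the
  flat-likelihood flag, and exactly three source lineages.
* The Wald interval misbehaves near 0/1 at small `n`; degenerate intervals
  at observed 0% or 100% are reported as zero-width rather than widened by
  a continuity correction, matching the defined comparison rule.
* The simulator covers one sampling instant — no swarming, selection, or
  spatial dynamics — and its sequences carry no indels or length variants.
* Real pooled sequencing adds read-depth noise on top of the 40-allele
  binomial; the generator emits exact counts and leaves any
  frequency-to-count rounding to the loader.
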