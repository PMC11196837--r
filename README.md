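# apiadmix

Racial ancestry of honey-bee (*Apis mellifera*) colonies from two marker
systems: nuclear admixture estimated by maximum likelihood from
pooled-worker SNP allele counts, and maternal ancestry classified from
COI–COII intergenic mtDNA sequences. Built for studies of Africanization —
the spread of African-lineage (*A*) ancestry through managed and feral
colonies that also carry Western European (*M*) and Eastern European (*C*)
ancestry — where the interesting signal is often the *disagreement* between
a colony's maternal line and its nuclear genome.

## The model

Each colony is genotyped as a pool of 20 workers (40 allele copies per
locus) at L ancestry-informative biallelic SNPs with known reference-allele
frequencies `pA_j, pM_j, pC_j` in the three source lineages. A colony with
admixture proportions (A, M, C) on the simplex has expected pooled
frequency

```
p_j = A·pA_j + M·pM_j + C·pC_j
```

and the observed copy number r_j among the 40 alleles is modelled
`r_j ~ Binomial(40, p_j)` independently across loci. `estimate_admixture()`
minimizes the negative log-likelihood over the simplex (softmax
reparameterization, multi-start `nlm`), with an exhaustive simplex-grid
oracle available for verification. On the mitochondrial side,
`classify_lineage()` assigns each colony the lineage of its nearest
reference sequence by unit-cost edit distance, `dedupe_haplotypes()` and
`build_network()` give the haplotype inventory and a minimum-spanning
parsimony-style network, and `mito_africanization()` reports the percentage
of African haplotypes per apiary. `summarize_groups()` compares
mitochondrial and nuclear ancestry per lineage through 95% Wald intervals —
n colonies effective for mtDNA, (2 + 12)·n effective alleles for nuclear
(two queen alleles plus twelve drone matings per colony) — with
non-overlapping intervals read as a real difference.

A colony simulator (`simulate_dataset()`) generates panels, pooled
observations (either the estimator's exact binomial model or an explicit
queen + 12-drones + patrilines family model) and lineage-structured mtDNA
sequences with known truth for every estimator.

## Worked example

```r
library(apiadmix)

cfg <- simulation_config(seed = 11, n_colonies = 12, n_apiaries = 3)
sim <- simulate_dataset(cfg)

estimate_batch(sim$colonies[1:4], sim$panel)
#>   colony_id         A         M         C      nll converged flat_flag error
#> 1    col001 0.6168368 0.2200657 0.1630975 206.5551      TRUE     FALSE  <NA>
#> 2    col002 0.5878683 0.2395888 0.1725429 221.2831      TRUE     FALSE  <NA>
#> 3    col003 0.5838449 0.2570828 0.1590722 226.5162      TRUE     FALSE  <NA>
#> 4    col004 0.5846536 0.2535981 0.1617483 222.4911      TRUE     FALSE  <NA>
```

The simulated truth here is (A, M, C) = (0.59, 0.24, 0.17) — the estimates
recover it to about ±0.03 per colony from 94 SNPs. The mtDNA side, and the
comparison of the two marker systems:

```r
refs <- read_reference_fasta(  # lineage|name headers
  simulate_dataset(cfg, dir = tempdir())$paths$references)
mito <- classify_colonies(sim$sequences$colonies, refs)
table(mito$lineage, sim$truth$maternal_lineage)
#>     A C
#>   A 5 0
#>   C 0 7        # 100% recovery of the simulated maternal lineages
```

The numbered scripts under `analysis/` run the same workflow at full scale
(48 colonies, 8 apiaries, seed 20240624) and write their tables under
`results/`: `01_simulate_dataset.R` (data + truth), `02_estimate_admixture.R`
(per-colony estimates, grid-oracle spot check), `03_mtdna_haplotypes.R`
(lineage calls, haplotype network, per-apiary Africanization),
`04_ancestry_comparison.R` (region × management verdicts). `run_pipeline()`
does the whole chain from one YAML config.

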