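# synflux

Estimating the ratio of genome rearrangement to gene flux from gene
order in closely related prokaryote genomes.

## The problem

Gene order is poorly conserved in bacteria and archaea, even between
close relatives. Two processes erode it: genome rearrangement (single
gene translocations, at short range) and gene flux (gene gain, mostly
via horizontal transfer, and gene loss). `synflux` quantifies their
relative contributions for a clade of closely related genomes whose
genes are labelled by clade-specific ortholog clusters (COGs), the
setting of ATGC-like genome collections. It is aimed at comparative
genomicists who have per-genome gene-order tables with ortholog labels
and want a per-clade rearrangement-to-flux ratio with a robustness
assessment.

## The method

For each genome pair *A, B* in a clade:

* **Gene content distance** (flux clock):
  `d(A,B) = -ln( N_AB / sqrt(N_A * N_B) )`, the log-corrected fraction
  of shared COGs — order-blind, paralogy-blind.
* **Syntenic block lengths** (rearrangement clock): both genomes are
  reduced to their shared single-copy COG complement and split into
  maximal runs of genes consecutive in both genomes, regardless of
  orientation, with circular wrap-around; length-1 blocks count. On the
  reduced complement, clean gains and losses are invisible, so block
  structure responds to rearrangement only.
* **Jump model**: with `h = exp(-lambda)`, the expected fraction of
  blocks of length *k* after `lambda` translocations per gene is

      f(1)    = (1 + 4 h^2 (1-h)) / (1 + 4 h^2 / (1+h))
      f(k>=2) = 4 h^2 (1-h) h^(2(k-1)) / (1 + 4 h^2 / (1+h))

  a singleton spike plus a geometric tail with ratio `exp(-2 lambda)`.
* **Ratio fit**: assuming a clade-constant ratio `q` with
  `lambda = q * d(A,B)` per pair, `q*` minimizes the summed
  1-Wasserstein distance between observed and predicted block-length
  distributions over all usable pairs (log-grid scan plus
  golden-section refinement). 100 bootstrap resamples of the pair list
  flag `q*` robust when the 6th and 95th ranked replicates differ by at
  most a factor of 2. `1/q` is then the number of gain-loss pairs per
  translocation and `1/(1+q)` the fraction of synteny decay driven by
  flux.

A synthetic clade generator (star tree, balanced gains/losses,
single-gene jumps, optional segmental-inversion confounder) provides
ground truth for every stage.

## Worked example

```r
library(synflux)

clade <- make_clade(n_genes = 3000, n_genomes = 6, q_true = 0.1,
                    d_range = c(0.02, 0.1), seed = 42)
pairs <- compare_all_pairs(clade$dataset)
head(pairs_table(pairs)[, c("genome_a", "genome_b", "gcd", "n_blocks", "mean_sbl")], 3)
#>     genome_a   genome_b        gcd n_blocks mean_sbl
#> 1 SYN001_g01 SYN001_g02 0.09467705       73 37.38356
#> 2 SYN001_g01 SYN001_g03 0.06756532       54 51.92593
#> 3 SYN001_g01 SYN001_g04 0.08992471       66 41.54545

fit <- fit_q(pairs)
fit
#> <q_fit> q* = 0.097753 (interior), W = 100.6 over 15 pairs

bootstrap_q(pairs, B = 100, seed = 7)
#> <q_bootstrap> B = 100, middle 90% in [0.09463, 0.1009] -> robust

flux_accounting(fit$q_star)
#> <flux_accounting> q = 0.09775: 10.23 gain-loss pairs per translocation, 91.1% of synteny disruption from flux
```

The clade was generated at a true ratio of 0.1; the fit recovers
0.098 with a tight bootstrap band. The flux accounting says that at
this ratio about ten gain-loss pairs occur per translocation, i.e.
roughly 91% of the observed synteny decay is attributable to gene flux
rather than rearrangement.

Real data enter through `read_gene_order_table()` (TSV with columns
`genome_id`, `replicon_id`, `topology`, `position`, `strand`,
`cog_id`), and `run_pipeline()` drives
read → clique reduction → size filter → pair comparison → fit →
bootstrap for a directory of clade tables, writing per-pair and
per-clade TSVs. A thin command-line wrapper ships in
`inst/scripts/synflux-pipeline.R`. See the vignette
(`vignettes/rearrangement-to-flux.Rmd`) for the model's assumptions,
numerical choices and limitations.

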