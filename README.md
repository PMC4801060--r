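# lsvtools

Detection and Bayesian quantification of **local splicing variations
(LSVs)** from RNA-seq junction reads.

Most splicing tools quantify a fixed catalogue of binary event types.
Real transcriptomes also produce *complex* variations — one exon
splicing to three alternative acceptors, skipping mixed with splice-site
choice, junctions competing with intron retention. `lsvtools` works at
the level of the splice graph instead: an LSV is any split where two or
more junctions leave (single-source) or enter (single-target) one
reference exon. The package is for people analysing bulk or single-cell
RNA-seq who need per-junction inclusion estimates with honest
uncertainty, differential-splicing calls between conditions, and a way
to benchmark those calls.

## What it computes

For each junction *j* of an LSV *e*, the **percent selected index**
Ψ<sub>e,j</sub> (the fraction of transcripts through the LSV using that
junction, ∑<sub>j</sub> Ψ<sub>e,j</sub> = 1), and between two conditions
the difference ΔΨ = Ψ<sub>t</sub> − Ψ<sub>t′</sub>. Both are estimated
as full posterior distributions discretized on a grid (V = 40 bins,
2.5 percentage-point resolution):

* junction read evidence is counted **per read-start position**; a
  per-experiment zero-truncated negative-binomial dispersion is fitted,
  implausible single-position **read stacks** (NB upper tail
  p ≤ 10⁻⁷) are removed, and read rates μ<sub>j</sub> are estimated by
  bootstrapping positions (μ = W · mean of resampled counts, M = 100
  samples);
* each bootstrap sample updates the conjugate prior
  Beta(η/J, η(J−1)/J) (η = 1: the Jeffreys prior for binary LSVs);
  the M discretized posteriors are averaged;
* ΔΨ uses the joint prior P₀(Ψ<sub>t</sub>)P₀(Ψ<sub>t′</sub>)P₀(ΔΨ)
  with a three-component Beta mixture on ΔΨ — a spike at 0, small
  perturbations, a uniform slab — which regularizes low-coverage
  comparisons toward 0;
* LSVs are called **changing** when P(|ΔΨ| > 0.2) > 0.95.

Around the core: splice-graph construction from GFF3 + BAM (or a plain
TSV of per-position junction counts) with de novo junctions, de novo
exons (500 bp cap, open-ended regions beyond), and windowed-coverage
intron-retention detection; LSV classification/type strings and
redundancy removal; reproducibility-ratio (RR) curves, complex-LSV
binomial enrichment, LSV-controlled permutation Fisher tests; a static
HTML report with splice graphs and posterior violins; and a seeded
synthetic-data generator with known ground truth.

## A worked example

Simulate 30 genes (80% cassette exons, 20% complex splits), three
replicates per condition, and run the full pipeline:

```r
library(lsvtools)
library(dplyr)

sim   <- simulate_genes(30, structure = c(cassette = 0.8, multiway = 0.2),
                        seed = 7)
cts_a <- simulate_counts(sim$truth, condition = "a", n_replicates = 3,
                         experiment_prefix = "a", seed = 7)
cts_b <- simulate_counts(sim$truth, condition = "b", n_replicates = 3,
                         experiment_prefix = "b", seed = 8)

graphs <- lapply(split(tibble::as_tibble(sim$genes), sim$genes$gene_id),
                 build_splice_graph, counts = cts_a)
lsvs   <- detect_lsvs(graphs, cts_a)    # 60 LSVs: an SS/ST pair per gene

dpsi  <- quantify_dpsi(lsvs, cts_a, cts_b, seed = 7)
head(tidy(dpsi), 4)
#>   lsv_id                junction_id    junction_idx psi_t psi_tp     dpsi p_change
#> 1 gene00001:s:1000-1150 chrS:1150-1950            1 0.182  0.154  0.0147  0.00000309
#> 2 gene00001:s:1000-1150 chrS:1150-2900            2 0.268  0.263  0.00251 0.0000123
#> 3 gene00001:s:1000-1150 chrS:1150-3850            3 0.299  0.277  0.0107  0.0000413
#> 4 gene00001:s:1000-1150 chrS:1150-4800            4 0.251  0.306 -0.0289  0.000406
```

`psi_t`/`psi_tp` are posterior mean inclusions per condition, `dpsi` the
posterior mean change, `p_change` = P(|ΔΨ| > 0.2) — gene 1 is a 4-way
complex LSV with no real change, and the spike prior keeps every
`p_change` near zero. Select confident calls, drop exon-overlapping
duplicates (a changing cassette exon yields two LSVs), and score against
the simulation truth:

```r
calls <- select_differential(dpsi, lsvs) |> overlap_filter()
head(as_tibble(calls), 2)
#>   lsv_id                   e_dpsi p_change selected chrom complex
#> 1 gene00009:s:65000-65150  0.318     0.974 TRUE     chrS  FALSE
#> 2 gene00012:t:89950-90100  0.231     0.607 FALSE    chrS  FALSE

truth_compare(dpsi, lsvs, sim$truth, calls = calls)$summary
#>       n    mae      bias   rmse    tp    fp    fn    tn
#> 1   152 0.0209 0.0000558 0.0309     1     0     1    28
```

At this desk scale the mean absolute ΔΨ error is ~0.02; one of the two
truly differential genes is called with zero false positives (the other
sits below the conservative 0.95 confidence bar).

`autoplot()` works on PSI/dPSI fits (posterior mass over the grid) and
RR curves; `write_report()` renders splice graphs and violin glyphs to a
single static HTML page. A thin CLI over the same functions lives in
`inst/cli/lsvtools` (subcommands `build`, `psi`, `deltapsi`, `report`,
`rr`, `simulate`) with a YAML run configuration.

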