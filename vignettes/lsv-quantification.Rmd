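---
title: "Local splicing variations: model, priors and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local splicing variations: model, priors and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsvtools)
library(dplyr)
```

## The problem

Alternative splicing is usually catalogued as a handful of binary event
types — cassette exons, alternative 5'/3' splice sites, retained introns.
Real transcriptomes are messier: a single exon often splices to three or
more alternative acceptors, mixes exon skipping with splice-site choice,
or combines junctions with intron retention. `lsvtools` works with
*local splicing variations* (LSVs): a split in a gene's splice graph
where two or more edges leave a single reference exon (a single-source
LSV) or enter it (a single-target LSV). Binary events are the special
case of two edges; anything more is a *complex* LSV. The unit of
quantification is the junction: its percent selected index
$\Psi_{e,j}$ is the fraction of transcripts through LSV $e$ that use
junction $j$, with $\sum_j \Psi_{e,j} = 1$, and differential inclusion
between conditions is $\Delta\Psi = \Psi_t - \Psi_{t'}$.

The package covers the full path from a GFF3 annotation plus
junction-spanning read evidence to discretized posterior distributions
over $\Psi$ and $\Delta\Psi$, together with the evaluation machinery
(reproducibility-ratio curves, enrichment tests) and a synthetic-data
generator with known ground truth.

## Splice-graph construction

Each gene's annotated transcripts define exons and junctions; BAM split
reads (or the plain per-position count table) contribute *de novo*
junctions. A de novo junction enters the graph only if it is *reliable*:
at least 2 reads at 2 distinct read-start positions (configurable, per
experiment by default — a pooled mode exists for sparse replicates).
Junction evidence is positional on purpose: a read is attributed to the
offset where it *starts* in the junction window, not to every position it
overlaps, which makes the counts (nearly) independent and supports the
stack test and bootstrap below.

De novo splice sites landing inside an intron extend the proximal exon
(a novel donor extends the upstream exon out to it; a novel acceptor
extends the downstream exon back to it), and an acceptor followed by a
donor inside the same intron delimits a putative de novo exon. Closed de
novo exonic regions are capped at 500 bp — roughly the 95th percentile of
known exon lengths — beyond which the region is kept *open-ended*: it is
drawn in reports, but its edges are excluded from LSV enumeration because
the missing boundary cannot define a splice-site ordinal.

Retained introns are detected from per-base coverage: the intron between
two exons gains a retention edge only if **every** 50 bp window tiled
across it (last window truncated; short introns are one window) averages
at least `min_intronic_cov` in at least one experiment. We read
"consecutive windows" in the strictest sense — all windows must pass —
because a single coverage gap is good evidence that apparent intronic
signal is something else (an unannotated exon, a mapping artifact). The
default threshold is 1.5; a relaxed evaluation mode (e.g. 0.5) is the
same code with a different threshold, and the trade-off is monotone:
lowering the threshold can only add retention edges.

## LSV enumeration and redundancy

Every exon with $\ge 2$ outgoing (incoming) edges in transcript
orientation yields one source (target) LSV. Junctions within an LSV are
ordered by reference splice-site coordinate then partner coordinate, in
transcript orientation, so the canonical type string (direction tag plus
per-junction reference/partner splice-site ordinals, `i` for a retention
edge) is identical for mirror-image genes on opposite strands.

Two LSVs of one gene can carry the same evidence: an LSV whose edge set
is a strict subset of another's is dropped, and of two LSVs with
identical edge sets exactly one is kept (the single-source one — an
arbitrary but deterministic tie-break). The SS/ST pair of a cassette
exon survives this filter by design: the two LSVs rest on different
junction reads and their agreement is itself informative.

Downstream filters follow the same two-tier logic: an LSV *exists* if
all its junctions are reliable and at least one has 2 reads at 2
positions; it is *quantifiable* if at least one junction has 10 reads at
3 positions, counted **after** stack removal so that a single
pathological pile-up cannot make an LSV quantifiable.

## The read-rate model

Per-position counts are overdispersed. Three stages deal with this:

1. **Global dispersion.** Non-zero position counts are modelled as
   zero-truncated negative binomial with a junction-specific mean and
   one dispersion $r$ per experiment, fitted by maximum likelihood on up
   to 10,000 randomly chosen quantifiable junctions (the subsample is
   the seeded part). The per-junction mean is plugged in as the observed
   non-zero-position mean rather than profiled — at quantifiable
   coverage the zero-truncation correction to the mean is negligible,
   and the plug-in keeps the fit a one-dimensional optimization. The fit
   is clamped to $[10^{-2}, 10^{6}]$; Poisson-like data hits the upper
   clamp, degenerate all-equal counts return the floor with a warning.

2. **Stack removal.** A *read stack* is a position whose count is
   implausible under NB$(r,\ \bar x_{\text{others}})$, where
   $\bar x_{\text{others}}$ averages the junction's other non-zero
   positions. Positions with upper-tail $p \le 10^{-7}$ (deliberately
   conservative) are flagged and removed everywhere downstream. A
   junction with a single non-zero position is untestable and retained.

3. **Positional bootstrap.** Even after 1–2 the data show junction-level
   variability, so the read rate is estimated by resampling: with $W_j$
   relevant positions (non-zero, non-stack), each bootstrap sample draws
   $W_j$ positions with replacement and sets
   $\mu_j = W_j \cdot \overline{c}$. Repeating $M = 100$ times (an
   engineering default; exposed) gives an empirical distribution over
   read rates per junction. "Relevant" defaults to observed non-zero
   positions; counting all mappable positions instead is a configurable
   alternative reading.

Optionally, counts are first rescaled by a smooth loess factor of
junction GC content, normalized to mean 1. This is a deliberately simple
monotone-trend correction and is off unless GC fractions are supplied;
it runs before stack flagging so the stack null sees corrected rates.

## Posteriors on a grid

For an LSV with $J$ junctions the marginal prior is
$\Psi_{e,j} \sim \mathrm{Beta}(\eta/J,\ \eta(J-1)/J)$ with $\eta = 1$:
for $J = 2$ this is the Jeffreys prior, which favours strong inclusion
or exclusion, matching how junction usage behaves in practice. Each
bootstrap index $m$ contributes a conjugate posterior with successes
$\mu_j^{(m)}$ and failures $\sum_{k \ne j}\mu_k^{(m)}$; the $M$
discretized posteriors are averaged. The reported point estimate
$E[\Psi]$ averages the closed-form Beta means, so the junction means of
an LSV sum to exactly 1.

$\Psi$ lives on $V = 40$ bins of width $1/V$ (2.5 percentage points —
about the precision an RT-PCR validation can resolve), $\Delta\Psi$ on
the $2V-1$ differences of bin indices. For $\Delta\Psi$ the joint prior
is $P_0(\Psi_t)P_0(\Psi_{t'})P_0(\Delta\Psi)$ with the regularizer

$$P_0(\Delta\Psi)\ =\ \sum_{k=1}^{3} w_k\,
  \mathrm{Beta}\!\left(\tfrac{\Delta\Psi+1}{2}\,\middle|\,
  \alpha_k, \beta_k\right),$$

a spike at 0 (Beta(1500, 1500), $w=0.2$), small perturbations
(Beta(75, 75), $w=0.3$) and a uniform slab ($\alpha=\beta=1$, $w=0.5$).
The component shapes and weights are declared engineering choices — the
three roles (spike, perturbation, slab) are the model; the numbers make
the prior visibly trimodal in width and are all configurable. The spike
is what keeps low-coverage LSVs from producing spuriously large
$|E[\Delta\Psi]|$: on fixed data the mixture can only shrink the
estimate relative to the uniform slab (a property the test suite
asserts), and with replicates the data overwhelm it quickly because the
conjugate updates simply add the sampled read rates across replicates
(the chain rule for the conjugate prior).

## Numerical choices

Marginal $\Psi$ masses are exact Beta CDF differences — no quadrature
error. The joint $(\Psi_t, \Psi_{t'})$ grid needs more care: the spike
component's standard deviation (about 0.018 on the $\Delta\Psi$ scale)
is *smaller than a grid cell* (0.025), so evaluating its density at cell
centers misclassifies a large share of near-diagonal mass. Two measures
keep the discretization honest:

* the mixture factor of each cell is its **exact average** over the
  cell, computed from the second antiderivative of the Beta mixture CDF
  (within a cell the difference $x - y$ is triangularly distributed);
* the joint is evaluated on an internally refined grid
  ($5V$ per axis) and aggregated onto the reported $V$-bin cells, which
  suppresses the residual covariance between the two Beta factors and
  the mixture weight within a cell.

With both, the total-variation distance between the $V = 40$ posterior
and a fine-grid (4000-bin) numeric integration of the same joint is
about $10^{-4}$ on binary and 3-junction test cases, an order of
magnitude inside the $10^{-3}$ tolerance the test suite enforces.
Degenerate inputs are defined, not special-cased: an LSV with no reads
returns the discretized prior flagged low-confidence; a zero-count
junction is shaped by its prior pseudo-counts alone; swapping the two
conditions exactly mirrors the $\Delta\Psi$ posterior.

Reproducibility is a contract: every random step (dispersion subsample,
bootstrap, simulator) derives a private stream by hashing the junction
or gene identity together with the run seed, so results are independent
of row order and identical across reruns.

## Selection and evaluation statistics

An LSV is called *changing* when $P(|\Delta\Psi| > 0.2) > 0.95$ for some
junction (both thresholds configurable; relaxed settings only ever grow
the selected set). Ranked lists are compared with the reproducibility
ratio: with $N$ the first run's selected-set size,
$RR(n) = n^*/n$ where $n^*$ counts how many of the first $n$ LSVs also
sit in the other run's best $N$ — a statistic deliberately invariant to
rank shuffling inside the top $N$. Because a differentially included
cassette exon contributes two LSVs, ranked lists are first filtered so
that no retained LSV shares an overlapping exon with a higher-ranked one
(greedy in rank order); this is conservative for complex genes, where a
single retained LSV may stand for several real variations.

Complex-LSV enrichment among changing LSVs uses an exact binomial tail
against the detected-set proportion with a Bonferroni factor for the
number of datasets. Feature enrichment on junction tables uses per-feature
Fisher exact tests with a permutation correction that shuffles labels
between LSVs *of the same junction count* (whole label vectors swap, so
group sizes and within-LSV correlation survive every permutation); the
corrected p-value follows the family-wise min-p convention by default,
with a per-feature empirical mode available. Junction dominance uses a
strict $E[\Psi] > 0.6$.

## The synthetic-data generator

The generator emulates exactly what the quantifier assumes: genes with
cassette exons, alternative 5'/3' sites, 3–6-way complex splits and
retainable introns; per-junction totals marginally
$\mathrm{NB}(\text{coverage}\cdot\phi_j,\ r)$; reads spread multinomially
over $W = 40$ start positions (a typical read length minus two
overhangs), near-uniform by default with an optional exponential tilt;
optional single-position stacks at a stated rate; optional monotone GC
bias. The NB overdispersion enters through a shared per-gene
Gamma$(r, r)$ expression factor with Poisson junction counts given the
factor — marginally NB as stated, while splicing *ratios* within a gene
remain clean multinomial choices, which is how reads actually sample
isoforms; a fully independent per-junction NB mode exists for contrast.

Defaults, chosen once as desk-scale stand-ins for a typical bulk
RNA-seq experiment and not revisited: dispersion $r = 30$, coverage 50
per fully included junction, 20% of genes differential at
$|\Delta\Psi| = 0.3$, no stacks, no GC bias. The simulation sizes used
by the checks — 500 LSVs for $\Psi$ recovery and null calibration, 200
LSVs at 3-vs-3 replicates for $\Delta\Psi$ recovery, 1000 junctions for
the dispersion fit — are the package's chosen desk-scale study
conditions.

What the generator does **not** emulate: mappability holes and soft-clip
artifacts, fragment-level positional autocorrelation, annotation errors,
unannotated transcription start/end effects, and expression-correlated
GC structure. Passing recovery tests on these simulations therefore
demonstrates that the inference machinery is correct under its own
model, not that real libraries satisfy that model.

## A short tour

```{r tour, eval = FALSE}
sim <- simulate_genes(50, structure = c(cassette = 0.8, multiway = 0.2),
                      seed = 7)
cts_a <- simulate_counts(sim$truth, condition = "a", n_replicates = 3,
                         experiment_prefix = "a", seed = 7)
cts_b <- simulate_counts(sim$truth, condition = "b", n_replicates = 3,
                         experiment_prefix = "b", seed = 8)

graphs <- lapply(split(tibble::as_tibble(sim$genes), sim$genes$gene_id),
                 build_splice_graph, counts = cts_a)
lsvs <- detect_lsvs(graphs, cts_a)

dpsi <- quantify_dpsi(lsvs, cts_a, cts_b, seed = 7)
calls <- select_differential(dpsi, lsvs) |> overlap_filter()
truth_compare(dpsi, lsvs, sim$truth, calls = calls)$summary
```

## Known limitations

* The $\Delta\Psi$ regularizer trades recovery sharpness for null
  calibration. Its influence fades quickly across
  $|\Delta\Psi| \approx 0.15$–$0.35$, so the posterior-mean map is
  locally expansive there: moderate true changes are estimated with
  somewhat more spread (and a small bias toward 0) than a
  flat-prior analysis of the same counts, the price of near-zero false
  discovery on null data. Analyses that need unshrunk point estimates
  can pass `uniform_dpsi_prior()`.
* $\Psi$ is marginal per junction; the package never reconstructs
  full-isoform abundances, and correlations between junctions of one
  LSV are only those induced by the shared total.
* Intron-retention edges are quantified from boundary-region positional
  counts supplied in the counts schema; no EM over ambiguous
  intron-exon reads is attempted.
* The GC correction removes a smooth marginal trend only.
* The ZTNB dispersion is global per experiment; junction-level
  variability is handled by the bootstrap, not by a hierarchical model.
* Open-ended de novo regions are reported but never quantified.
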