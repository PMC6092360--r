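---
title: "Models and methods behind raretaxa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind raretaxa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raretaxa)
```

`raretaxa` analyses rarefied OTU count tables with a focus on contrasting
abundant and rare subcommunities. This vignette explains the models the
package implements, the tunable parameters and their defaults, the design
choices made where the methodology left room, and what the synthetic-data
generators do and do not emulate.

## Data model

The community container is a wide tibble: an `otu_id` column followed by one
integer column per sample (OTUs as rows, the amplicon convention). Readers
accept the transposed layout via a flag or auto-detect it against metadata
sample IDs. Structural invariants — unique IDs, non-negative integer counts,
at least one OTU and two samples, positive sample totals — are enforced by
`validate_otu_table()` at every entry point.

Rarefaction (`rarefy_counts()`) subsamples each sample without replacement
(multivariate hypergeometric) to a common depth. Each sample draws from a
private RNG stream derived from the master seed and a hash of the sample
identifier, so the subsample obtained for a sample is reproducible and
independent of the column order in the input file. Whole-dataset singletons
can be removed beforehand (`remove_singletons()`), and OTUs left with zero
reads after rarefaction are dropped explicitly and counted in the pipeline
manifest, so the post-rarefaction OTU total is always well defined.

## Abundance classification

Classification works on per-sample relative abundances, not pooled ones,
because "abundant in all samples" and "rare in some samples" are per-sample
statements. With thresholds `abundant_cut` (default 1%) and `rare_cut`
(default 0.01%), the per-OTU minimum and maximum across samples decide the
category; abundant comparisons are inclusive (≥) and rare ones strict (<),
following the conventional wording of the six-category scheme. The moderate
category therefore owns the half-open band [0.01%, 1%) for both minimum and
maximum, and an OTU sitting exactly at 1% in some samples with minimum above
0.01% is conditionally abundant. The six rules partition the (min, max)
plane, which the test suite verifies against a brute-force re-statement over
a boundary grid.

Venn (shared-OTU) summaries use presence = count > 0 on the rarefied table,
with no extra abundance floor; ternary exports renormalise the three period
means per OTU, flagging OTUs absent everywhere.

## Alpha diversity and sampling coverage

Shannon–Wiener diversity uses natural logarithms (nats), the dominant
convention in ecology; Simpson is reported in its Gini–Simpson form 1 − Σp².
Pielou's evenness H/ln(S) is undefined for one-species samples and reported
as 1 with a flag. Chao1 is the classic estimator S + F₁²/(2F₂) with the
standard degenerate-case fallbacks; ACE uses the usual 10-individual
rare/abundant split (and equals observed richness when the rare class is
empty). The Preston analysis bins pooled abundances into doubling octaves
with the half-split of boundary counts, fits a Gaussian truncated at the veil
line, and extrapolates total richness as the area under the untruncated
curve. The extrapolation is reliable when most of the curve is visible
(coverage around 85–95%, the regime the package's tests exercise); with deep
veiling it degrades, which is inherent to the method rather than to the
implementation. The two-way ANOVA uses type-II sums of squares, which
coincide with type-I/III on the balanced period × depth designs the package
targets and degrade gracefully when a sample drops out.

## Beta diversity and temporal turnover

Bray–Curtis dissimilarity is partitioned per sample pair into the
balanced-variation component min(B,C)/(A+min(B,C)) and the abundance-gradient
remainder, where A is the shared abundance and B, C the sample-specific
surpluses; the two components add to the total exactly (checked to 1e-12 on
10,000 random pairs). The components are reported under these standard
algebraic names; interpreting them as "turnover" versus "richness
difference" is left to the user, since the literature's parenthetical labels
are not used consistently.

Time-lag regression fits ordinary least squares of pairwise dissimilarity on
the absolute difference in sampling-event index (1…6 by default, calendar
units optional), using all unordered pairs; a `sqrt_lag` option provides the
classic square-root variant. The slope's t test treats pairs as independent,
which they are not (pairs share samples): under a completely static
community the test is mildly anticonservative (empirically ~8–10% rejection
at α = 5% instead of the nominal rate in the package's null simulations).
The positive-slope power under genuine succession is unaffected. NMDS is
export-oriented plumbing around `vegan::metaMDS` with a fixed seed.

Levins' niche breadth B = 1/ΣP² row-normalises each OTU's reads over
samples; the abundance–occupancy relationship reports both the Spearman
correlation and an OLS fit of occupancy on log10 mean relative abundance.

## Permutation tests

All permutation P-values use the add-one estimator
(1 + #{perm ≥ obs})/(1 + n), which never returns zero, and count ties as
exceedances. ANOSIM midranks all pairwise distances and permutes group
labels; for small n an exact mode enumerates all label permutations, and the
test suite checks the exact tail against an independent enumeration. IndVal
uses group-size-equalised specificity (group means of relative abundance,
not pooled sums), fidelity as the fraction of the group's samples occupied,
and the √(A·B) statistic, with the 0.7 threshold applied on that square-root
scale; permutation P uses the best-group statistic under each permuted
labelling, and only single-period ("strict") indicators are considered.
Mantel tests correlate upper triangles (Spearman by default) and permute one
matrix's rows and columns simultaneously. Environmental distances are
absolute differences of log(x+1)-transformed values (natural log; a log10
option exists), with pH used untransformed and ordered factors coded
ordinally. Each variable gets its own distance matrix, mirroring
one-row-per-variable Mantel tables.

## Neutral community model

The Sloan model predicts a taxon's occurrence frequency from its
metacommunity mean relative abundance p as 1 − F(d; Nm·p, Nm·(1−p)), where F
is the Beta CDF, Nm the product of metacommunity size and immigration rate,
and d the detection limit. Defaults: p includes zero counts in the mean (it
estimates the metacommunity mean), d = 1/N with N the rarefied depth
(configurable), and Nm is fitted by bounded least squares over log(Nm) in
[0, log 10⁷] from three deterministic starts. R² = 1 − SSE/SStot is not
clamped: negative values flag a worse-than-mean fit and are diagnostic. A
95% Wilson binomial envelope around the fitted curve classifies OTUs as
above, within, or below the neutral expectation.

One bias is worth knowing about: the model's threshold detection
approximation (detected iff the underlying relative abundance exceeds d)
differs from the exact sampling process (detected iff at least one read is
drawn), so on data generated by Dirichlet-multinomial sampling the fitted Nm
runs ≈ 15% above the generating value. This is a property of the standard
fitting procedure itself — fitting the threshold model to the exact
closed-form detection curve reproduces the same offset — and is documented
rather than corrected, since the conventional estimator is what practitioners
compare against. The model can be fitted either on subcommunity-only tables
or on all-community abundances restricted post hoc; the package computes
whatever table it is given, and the pipeline fits the full table by default.

## Co-occurrence networks

The prevalence prefilter keeps OTUs present in strictly more than 6 samples
with strictly more than 20 total reads. All pairwise Spearman correlations
(midrank ties) are screened at |r| > 0.8 and P < 0.01 via the t
approximation t = r√((n−2)/(1−r²)); no multiple-testing correction is
applied, matching the conventional raw-P screen (at n = 18 the |r| threshold
is the binding constraint anyway — the P rule removes nothing extra).
Correlation signs are kept as edge attributes, but all topology is computed
on the unsigned simple graph; isolated OTUs are dropped from the reported
network and counted. Modules come from seeded Louvain at resolution 1,
relabelled by size with a "major" flag above 40 nodes. Average path length
is taken over the largest connected component, since the screened graph need
not be connected. The scale-free diagnostic is the R² of an OLS fit of
log frequency on log degree over the positive-count degree histogram — a
regression-style summary, not a maximum-likelihood exponent fit. Null
comparison uses G(n, m) Erdős–Rényi graphs with exactly the observed node
and edge counts (1,000 by default), reporting mean, sd, z and the empirical
percentile of each observed metric. Zi–Pi roles use the customary
thresholds z ≥ 2.5 and P ≥ 0.62; keystones are nodes with raw degree > 100
and raw betweenness < 5000 (raw counts, as the magnitude of the conventional
threshold implies). Those absolute thresholds are meaningful at
survey scale (hundreds of nodes, ten-thousand-edge networks); on small
simulated networks the keystone list is legitimately empty, which is why the
package's tests verify the rule on a purpose-built dense graph with a
planted high-degree member instead.

## Synthetic communities

Three generators provide ground truth, all deterministic under a seed:

- `simulate_neutral_table()` draws metacommunity abundances from a
  log-normal SAD (default sdlog 2.5, chosen so that at the default scale
  ≈ 2% of OTUs classify abundant and ≈ 90–97% rare, the long-tailed mix
  typical of eukaryotic plankton surveys) and assembles each sample as a
  Dirichlet(Nm·p)-multinomial draw — the Sloan diffusion-limit kernel. An
  exact Hubbell forward simulation is out of scope.
- `simulate_succession()` perturbs log abundances by a Gaussian random walk
  (sd = `turnover_rate`, default 1) between periods and raises planted
  indicators to `indicator_effect` × the mean OTU abundance (default 10)
  within their period only. The default design is 18 samples = 3 periods ×
  3 depths × 2 dates at 10,000 reads — a desk-scale stand-in for deep
  sequencing runs.
- `simulate_modular_counts()` gives each planted module a latent factor per
  sample; member log abundances load on it so the latent carries `rho`
  (default 0.9) of their variance, and environmental variables are noisy
  copies of the latents, producing block-wise OTU–OTU and OTU–environment
  correlation.

What the generators do **not** emulate: sequencing error and chimeras,
compositional coupling beyond the multinomial constraint, taxon-specific
selection, phylogenetic structure, and calendar-scale autocorrelation within
periods. Tests passing on these communities therefore validate the
statistical machinery and its detectability claims, not the biology of any
particular real dataset.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately modest sizes —
2,000-OTU communities at 10,000 reads, 200-replicate power studies,
500-replicate size calibrations with 199 permutations, 1,000-graph null
ensembles — chosen as the smallest scales at which the studied effects are
stable. Optimisations are bounded and deterministic; permutation streams are
seeded separately from data-generation streams (coupling them induces subtle
dependence between the observed statistic and its reference distribution).
Degenerate inputs — empty subcommunities, constant profiles, isolated nodes,
all-zero OTUs — are flagged or skipped with logged counts rather than
silently dropped.
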