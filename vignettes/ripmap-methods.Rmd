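---
title: "Mock-IP-controlled RIP-seq enrichment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mock-IP-controlled RIP-seq enrichment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripmap)
```

# The problem

RIP-seq (RNA immunoprecipitation followed by sequencing) asks which
transcripts a protein of interest is bound to in vivo. Read counts from the
IP library alone confound binding with mRNA abundance: an unbound but highly
expressed message yields more IP reads than a tightly bound, rare one. The
analysis implemented here therefore measures binding as *enrichment of the
IP over a mock IP* — an identical immunoprecipitation from an untagged
strain, which captures the background of sticky, abundant RNA without any
specific signal — and asks whether the IP/mock count ratio for each
transcript is larger than library-size differences alone can explain.

`ripmap` provides that statistic, the replicate-consensus target call built
on it, positional refinements (per-region enrichment and composite metagene
profiles), downstream comparative statistics, and a synthetic data generator
with known ground truth so that the whole chain can be validated end to end.

# The enrichment model

## Exact two-sample Poisson test

Counts for one feature are modelled as Poisson: $y_{ip} \sim
\mathrm{Pois}(\lambda_{ip} n_{ip})$ and $y_{mock} \sim
\mathrm{Pois}(\lambda_{mock} n_{mock})$, where $n$ are the library sizes
(reads assigned to any non-rRNA transcript). Under the null
$\lambda_{ip} = \lambda_{mock}$, conditioning on the total $t = y_{ip} +
y_{mock}$ gives

$$ y_{ip} \mid t \;\sim\; \mathrm{Binomial}\!\left(t,\;
   \frac{n_{ip}}{n_{ip} + n_{mock}}\right), $$

which removes the unknown rate entirely. `exact_poisson_test()` computes the
two-sided p-value by the minimum-likelihood rule: the sum of the
probabilities of all outcomes no more likely than the observed one. This is
the common convention for exact two-sided tests and is symmetric in the two
samples; a doubled-smaller-tail variant is available via `method =
"doubled"`. A total of zero carries no information and returns p = 1.
Numerically, outcome probabilities within a relative $10^{-7}$ of the
observed one are treated as tied, which guards against floating-point
asymmetry among genuinely tied outcomes; true ties are always included,
which can make the p-value slightly more conservative than a sorted-cumsum
implementation that splits ties by position.

## Log2 enrichment with a prior count

$$ \log_2 E = \log_2 \frac{(y_{ip} + c)/n_{ip}}{(y_{mock} + c)/n_{mock}},
   \qquad c = 1 \text{ by default}. $$

The prior count keeps the ratio finite when the mock library — typically
shallow and low-complexity — has zero reads for a gene. The prior is added
to the *raw* counts before library-size division. A consequence worth
knowing: the statistic is exactly invariant under scaling both library
sizes (counts fixed), but duplicating every read *and* both libraries
shifts low-count values unless the prior is scaled along with the data
(`prior = 2` for doubled data restores exact invariance). We accept this in
exchange for a simple, bit-stable definition.

## Replicate pairs and the consensus call

With three biological replicates per arm, the replicates are processed two
at a time in all three combinations (1v2, 2v3, 1v3). Within each pair the
two IP replicates are pooled (counts and library sizes summed) and likewise
the two mock replicates; each feature then receives an exact test, a log2
enrichment and a Benjamini–Hochberg adjustment across features. Pooling
maximises the counts entering each exact test while keeping three
quasi-independent assessments. The phrase "two replicates at a time" could
also mean unpooled single-replicate contrasts; that reading is available as
`pairing = "crossed"` (IP replicate i against mock replicate j).

The combined enrichment per feature is the mean of per-pair log2 values over
the pairs with FDR < 1%; if no pair passes, all pairs are averaged and the
feature is flagged (`all_pairs_averaged`). This keeps a defined value for
every feature — needed by the percentile analyses downstream — while the
FDR gate still governs target calling. A feature is a **target** when at
least 2 of the 3 pairs show > 1 log2 enrichment at FDR < 1%
(`call_targets()`, thresholds exposed). Features with zero counts
everywhere are reported with log2 = 0 and p = 1 rather than the
prior-driven library-ratio artifact.

## Regional enrichment

The same machinery runs on per-region counts: 5'UTR/CDS/3'UTR, length-thirds
(floor partition in transcript orientation, remainder to the 3'-most third),
and introns. Regional analyses keep only genes longer than 400 nt, and
region tallies count genes above fourfold combined enrichment (twofold for
introns).

# Read counting

A read belongs to the feature whose interval contains the read's *midpoint*
on the matching strand. The upstream tools the procedure is modelled on
(interval-overlap counters) do not state an overlap rule; midpoint
containment is our documented choice because it guarantees single
assignment, making partition conservation exact: thirds (and
utr5/cds/utr3 where they tile the transcript) sum to the whole-gene count,
read for read. A midpoint inside two same-strand transcripts goes to the
one with the nearer TTS (transcript termination site) — deterministic, and
biased toward the 3' end where the proteins of interest act. Note this
tie-break is orientation-dependent by construction, so exact strand-flip
symmetry of counts holds on non-overlapping transcripts. Library size is
the number of reads assigned to any non-rRNA transcript in the
whole-transcript scheme, computed once and reused by region schemes, so
that rRNA filtering and normalization are consistent across analyses.

# Composite profiles

`anchor_profile()` places each matching-strand read's 5' end at its
transcript-oriented offset from the TSS or TTS of every qualifying gene
(> 400 nt) and sums over genes; on the minus strand the TSS is the high
genomic coordinate and offsets increase toward lower coordinates. 5'-end
counting (rather than per-base coverage) makes mass conservation exact; a
coverage mode was deliberately left out for this reason.
`normalize_bin_smooth()` scales to read density per 100 million mapped
reads per contributing gene, sums into 15-bp bins, and smooths with a 6-bin
sliding window. The smoother is *mass-preserving*: each bin spreads its
value uniformly over its (edge-shrunk) window, so the vector sum is
conserved exactly — a plain shrinking-window moving average does not have
this property. Because a "6 bp" window over 15-bp bins is ambiguous, the
literal single-nucleotide reading is available as
`smooth_unit = "positions"`; the default treats it as 6 bins.

# Comparative statistics

* `percent_rank()` uses the spreadsheet PERCENTRANK convention:
  (#values strictly below)/(n−1), ties sharing a rank.
* `top_fraction()` selects percent rank ≥ 1−fraction with boundary ties
  included; with heavy ties where no gene reaches the threshold, the genes
  tying the maximum are returned (so an all-tied input returns everything).
* `bin_by_percentile()` partitions genes into five percent-rank groups;
  `compare_bins()` tests each group's response values against a reference
  (all genes, or the bottom group) with a two-sided Wilcoxon rank-sum test —
  normal approximation with continuity correction, exact for tie-free
  groups of ≤ 25.
* `correlation_panel()` correlates enrichment against each external table
  over the pairwise-complete gene intersection and BH-adjusts within the
  panel (the correction family is per panel; the source procedure does not
  state its family), reporting only FDR < 1% entries.
* `overlap_chi2()` is the 1-df Pearson chi-square on the 2×2 membership
  table, without Yates correction by default (the correction is a flag);
  degenerate margins return chi2 = 0, p = 1, flagged rather than erroring.
  The universe is the gene set present in both tables being compared.
* `percent_ip()` implements the qPCR recovery formula
  $2^{Ct_{input} - Ct_{IP}}$, warning when the apparent recovery exceeds
  100%.
* `compute_rpkm()` adds 0.5 to each count before RPKM so later logs are
  finite, then averages per-replicate RPKM across input replicates.

# The synthetic world

`generate_transcriptome()`, `generate_ground_truth()` and
`simulate_reads()` produce data with the statistical structure the analysis
assumes, not sequence-level realism. Defaults, chosen once:

| parameter | default | rationale |
|---|---|---|
| transcript length | lognormal, median ≈ 1200 nt, sd(log) 0.35, floor 300 | typical yeast mRNA span |
| UTR fractions | 8% (5') / 15% (3') | short yeast UTRs, 3' longer than 5' |
| abundance | lognormal, sd(log) = 1 | 2–3 decades of expression |
| rRNA | 2% of genes, abundance ×20 | emulates dominant rRNA reads that the filter must remove |
| bound fraction | 15% of non-rRNA genes | thousands of targets at genome scale |
| enrichment factor | 8× exactly (sd(log) = 0) | a strong, unambiguous spike for recovery benchmarks |
| abundance coupling | −2 (log-odds per SD of log abundance) | reproduces a moderate negative enrichment–abundance correlation (r ≈ −0.4) |
| 3' bias | 80% of bound-gene IP reads start in the 3'-terminal 200 nt | deadenylase-machinery positional signature |
| mock | same abundance weights + 5% flat contaminant floor | untagged-strain IP: background, not signal; no quantitative background model is published, these are stated choices |
| read length | uniform 30–50 nt | short post-trimming reads |

Each (role, replicate) pair draws from its own RNG stream derived from the
master seed, so adding replicates never perturbs existing ones. Reads
always lie within their transcript; when the 3' window exceeds a bound
transcript, the whole transcript is used and the event is counted in an
attribute.

What the generator does **not** emulate: intergenic/antisense background,
multi-mapping, fragment-length effects (positional bias is injected
directly through the 3' window instead), PCR duplicates, or overlapping
gene models. A green recovery test therefore establishes that the
statistics recover the structure they are designed for — not that the
pipeline is robust to every artifact of real libraries.

The detection benchmark (2,000 genes, 300 bound at 8×, three 200,000-read
replicates per arm) is run with the abundance coupling switched off so that
it measures the exact test's detection performance at a fixed effect size;
the anti-correlation recovery is exercised separately with coupling −2.
With equal IP and mock library sizes the composition effect is visible:
unbound genes sit near $\log_2(1/Z) < 0$ where $Z = \sum_g a_g f_g$, and
bound genes near $\log_2(8/Z)$ — the target threshold of +1 log2 separates
them cleanly at these settings.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open (BED convention) everywhere; boundary
  midpoints belong to the interval whose half-open span contains them.
* Genes shorter than 3 nt are excluded from thirds; empty intron sets yield
  empty (not failing) tables.
* p-values are capped into (0, 1]; BH is `stats::p.adjust(method = "BH")`
  behind the module surface, verified against the literal step-up
  definition in the test suite.
* Exact-test ties: see above; the relative tie tolerance is $10^{-7}$.
* All-equal value vectors: `top_fraction()` returns all genes;
  `bin_by_percentile()` collapses into bin 1 with a message.
* Wilcoxon p-values for a group tested against itself are near 1, not
  exactly 1 (rank-sum discreteness).
* `run_pipeline()` is deterministic for a fixed config: rerunning writes
  byte-identical tables (md5 checksums recorded in the JSON manifest).

# Limitations

The Poisson model ignores biological overdispersion by design (the
procedure it implements assumes Poisson); with three replicates a
negative-binomial dispersion estimate would be unstable, and the
replicate-pair consensus is the robustness mechanism instead. The
enrichment of very low-abundance transcripts is power-limited, not
bias-limited: they fail the FDR gate rather than acquiring spurious
enrichment. Composite profiles average over genes and can be dominated by
few high-count transcripts; the regional tallies are the per-gene
complement, and both are reported.
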