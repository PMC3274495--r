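---
title: "Composite chromatin profiling of tiling-array data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite chromatin profiling of tiling-array data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genome-wide maps of histone modifications in budding yeast are commonly
measured on high-density oligonucleotide tiling arrays: an
immunoprecipitated (IP) channel against a control channel, at probes spaced
roughly every 5 bp, in biological replicates. For a modification such as H2B
monoubiquitylation (H2BK123ub1), the control channel is total H2B, so the
log2(IP/control) ratio measures the modification level independently of
local histone density. The scientific questions this package serves are
positional: is the mark enriched over coding regions relative to intergenic
and silent chromatin; does its level track transcription rate and
coding-region length; and how is it distributed across the exon1–intron–
exon2 architecture of intron-containing genes, relative to nucleosome
occupancy?

`chdipmeta` implements the full analysis path from per-probe intensities to
these composite summaries, plus a synthetic-data generator that emulates the
study design with *planted* structure, so every stage can be validated
against a known ground truth.

## Normalization model

For probe $i$ and replicate $r$, with IP intensity $IP_{ir}$ and control
intensity $C_{ir}$ (both positive), the per-probe signal is

$$ s_i \;=\; \frac{1}{R}\sum_{r=1}^{R}\,\mathrm{qn}_r\!\left[\log_2\frac{IP_{ir}}{C_{ir}}\right], $$

where $\mathrm{qn}$ denotes quantile normalization across the $R$ replicate
log-ratio columns and $R = 2$ is the canonical two-replicate design (the
implementation accepts any $R \ge 2$; the half-sum formula is the $R = 2$
special case of the mean).

Two deliberate choices:

* **Order of operations.** Log ratios are formed first and quantile
  normalization is applied to the log-ratio columns (the default,
  `normalization_mode = "log_ratio"`). The alternative reading — normalize
  raw intensities, then form ratios — is exposed as
  `normalization_mode = "intensity"`; it quantile-normalizes the IP
  channels across replicates and the control channels across replicates
  *separately*, never jointly, since joint normalization would flatten the
  IP-vs-control contrast that is the measurement itself. In the noise-free
  limit both modes coincide.
* **Ties.** Quantile normalization maps each column's sorted values onto
  the vector of row means of the column-sorted matrix. Tied values within a
  column receive the mean of the reference values over their tied ranks,
  which makes the operation invariant to row permutation. This differs
  slightly from `limma::normalizeQuantiles(ties = TRUE)`, which
  interpolates the reference at the average tied rank; on tie-free data the
  two are identical, and the test suite uses limma as an independent
  cross-check there. Exact idempotence holds on tie-free data; with ties
  across columns of unequal tie structure a second application can shift
  values marginally, which is a property of quantile normalization itself,
  not of this implementation.

Probes present in only a subset of replicate arrays are dropped with a
logged count, never imputed.

## The averaged gene

Each gene contributes a fixed-length vector: its 5' intergenic flank scaled
to 20 bins, its ORF to 40 bins, and its 3' intergenic flank to 20 bins, so
the ORF occupies bins 21–60 of an 80-bin axis. A bp at transcription-
oriented offset $o$ in a region of length $L$ with $B$ bins falls in bin
$\lfloor oB/L \rfloor + 1$; bin lengths therefore differ by at most one bp
and every probe lands in exactly one bin. For minus-strand genes offsets
are counted from the genomic right end, so bin 1 is always 5'-most in
transcription orientation.

Averaging is two-level: probes are averaged per bin *within* each gene,
then the per-gene bin means are averaged *across* genes with equal gene
weight — a long gene with many probes counts exactly as much as a short
one. Bins in which a gene has no probes are missing for that gene and are
excluded (never treated as zero); the composite records how many genes
contributed to each bin. Profiles are smoothed with a 5-bin moving window
(missing bins excluded from each window mean), leaving the outermost two
bins on each side unsmoothed.

Design points that the upstream description of such analyses leaves open,
decided here:

* **Intergenic extent.** Flanks run to the neighbouring gene but are
  truncated to the `intergenic_cap` (default 1000 bp) nearest the gene.
  Uncapped flanks would let megabase-scale gaps dominate the flank bins
  and make them incomparable across genes. The cap is configurable.
* **Overlapping genes.** The flank on an overlapped side is empty — the
  gene simply contributes no data to those bins — rather than a negative
  interval.
* **Telomere class.** The region summary's telomere class is the terminal
  window (default 20 kb) at *both* ends of every chromosome; "the last
  20 kb" of a chromosome is read as each terminal 20 kb. A probe may
  belong to several region classes (a telomeric ORF counts in both).
* **Class boundaries.** Rate classes default to boundaries (2, 4, 8, 16)
  mRNA/h, giving five classes whose top class is strictly `> 16`, the one
  boundary that is externally fixed; a gene at exactly 16 falls below.
  Genes without a detectable rate are excluded from rate classification.
  Length classes default to octile ranks (ties share a class, so equal-
  length genes are never split across a boundary); both are configurable.

## Exon1–intron–exon2 profiles

Intron-containing genes are profiled on a 10/30/40-bin axis: the 5' exon
(exon1), the intron, and the 3' exon (exon2), each segment binned
independently and strand-aware, then concatenated. Multi-intron genes are
decomposed into one exon–intron–exon unit per intron; units are averaged
within the gene first so multi-intron genes are not over-weighted. Yeast 5'
exons can be as small as 1 bp; when a segment is shorter than its bin
count, probes still map by the floor rule and unoccupied bins propagate as
missing values. Smoothing is applied per segment, with the first two and
last two bins of each of the three segments exempt, and bin means are
plotted at bin midpoints (bin 3 sits at x = 2.5).

Nucleosome occupancy (percent of DNA bound in a nucleosome, 0–100) is
profiled with the identical machinery applied to per-bp values, and
additionally summarised per segment class as the length-weighted mean

$$ \widehat{occ} \;=\; \frac{\sum_g \ell_g\,\overline{occ}_g}{\sum_g \ell_g}, $$

so longer introns (or exons) contribute proportionally more. This weighting
is additive under any sub-division of a segment, which the tests assert.

## The synthetic study design

The generator's defaults are the package's study conditions and are chosen
once, on yeast scale:

| parameter | default | rationale |
|---|---|---|
| probe spacing | 5 bp | high-density tiling-array resolution |
| replicates | 2 | paired IP/control arrays per replicate |
| ORF length | log-normal, median 1.4 kb (min 400 bp) | yeast ORF scale |
| intergenic gaps | log-normal, median 400 bp (min 200 bp) | yeast gene density |
| transcription rate | log-normal, median 4 mRNA/h, sdlog 1 | ~8% of detectable genes exceed 16 mRNA/h, matching the published census of the top transcription class |
| detectable-rate fraction | 0.8 | roughly 4800 of ~6000 yeast genes have measured rates |
| intron-containing fraction | 0.05 | ~280 of ~6000 yeast genes; one 5'-proximal intron each, small exon1 (10–60 bp), intron median 300 bp |
| intergenic baseline | −0.5 log2 | depletion outside coding regions |
| rate slope | 0.2 log2 per log2(1+rate) | planted rate effect |
| length slope | 0.1 log2 per kb | planted length effect |
| intron depletion | 0.5 log2 | planted exon-vs-intron contrast |
| boundary bump | height 0.5, sd 20 bp | planted peak at each 3' intron–exon boundary |
| occupancy | exon 80%, intron 40%, intergenic 60%, ramp 5 bp, noise sd 8 | intron-depleted nucleosome landscape |
| channel noise | sd 0.2 (log2) per channel | multiplicative replicate noise; E[log2(IP/C)] equals the planted signal |

Noise enters multiplicatively and independently per channel:
$IP_{ir} = c_0\,2^{t_i + \varepsilon}$, $C_{ir} = c_0\,2^{\varepsilon'}$
with $\varepsilon, \varepsilon' \sim N(0, \sigma^2)$, so the *expected*
log ratio equals the planted enrichment $t_i$ and the per-replicate log-
ratio variance is $2\sigma^2$. Each simulation stage (annotation, probes,
occupancy) draws from its own sub-seed derived from the master seed, so
regenerating one stage never perturbs another.

What the generator does *not* emulate — and hence what passing tests do not
show about real arrays: hybridization chemistry and probe-sequence (GC)
bias, dye effects, spatial artefacts, copy-number structure, mismatch
probes, and probe-level inference of the upstream extraction step. The
generator plants a piecewise-constant enrichment per gene; real profiles
have within-gene trends. Recovery results therefore validate the
*analysis machinery*, not the array platform.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout; GFF3 (1-based inclusive)
  is converted on read. BED12 blocks become exons; both writers round-trip
  exactly.
* Bin assignment uses exact integer-valued arithmetic
  ($\lfloor oB/L\rfloor$); the test suite proves equivalence with a
  boundary-counting oracle for every interval length up to 1000 and every
  bin count up to 80.
* Empty bins, empty flanks, and gene classes left without genes are
  missing values or omissions with warnings — never silent zeros.
* The occupancy ramp (a moving-average transition at annotation
  boundaries) keeps positions more than 5 bp from any boundary at their
  exact expected value, which the noise-free tests rely on; segment means
  near boundaries are biased toward the neighbouring context by design,
  visible as roughly 2 points on very small 5' exons.
* The smoothing window must be odd; an even window is a configuration
  error reported by `validate_config()` alongside all other violations.

## Problem sizes

The bundled analysis scripts run 600 genes on two chromosomes
(~1.2 Mb, ~240 k probes per replicate); the validation suite uses 200-gene
genomes for recovery checks and 10–60-gene fixtures for exactness checks.
These sizes give per-class composites with 25+ genes per stratum, which is
where the planted monotone orderings become deterministic under the default
noise, and they are the package's reference conditions for the reproducible
summary written by `scripts/acceptance.R`.

## Known limitations

* Genes are ORFs: no UTRs, no isoforms, no overlapping-transcript
  disambiguation; overlapping gene bodies only affect flank derivation.
* The RP-vs-other split is an explicit id list; the package has no gene-
  name ontology and does not infer gene families.
* Statistical testing of profile differences (confidence bands, per-bin
  tests) is out of scope; the composites are descriptive summaries.
* The pipeline consumes extracted per-probe intensities; probe-level
  signal extraction from raw arrays is upstream of this package.
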