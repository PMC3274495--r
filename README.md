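# chdipmeta

Composite chromatin profiling for two-channel tiling-array data, built
around the budding-yeast H2B-monoubiquitylation (H2BK123ub1) ChDIP-chip
design: a sequential-immunoprecipitation assay whose log2(IP/control) probe
ratios measure a histone mark's level relative to total histone, genome-wide
at ~5 bp resolution.

The package is for analysts who have per-probe replicate intensities plus a
gene annotation and want the standard positional summaries of such maps:

* **Probe normalization** — per-replicate log2(IP/control), quantile
  normalization across replicates, replicate averaging:
  ½[log2(IP₁/C₁) + log2(IP₂/C₂)].
* **Averaged gene** — every gene scaled to 20 bins of 5′ intergenic flank,
  40 bins of ORF and 20 bins of 3′ intergenic flank (strand-aware; probes
  averaged per bin within genes, then across genes with equal gene weight;
  5-bin moving-window smoothing), optionally stratified into five
  transcription-rate classes (top class strictly > 16 mRNA/h) or eight
  coding-length classes.
* **Region summary** — mean signal over ORF, intergenic, telomeric
  (terminal 20 kb of each chromosome end) and user-defined silent regions
  (rDNA, HM).
* **Exon1–intron–exon2 composites** — intron-containing genes on a
  10/30/40-bin axis aligned at the intron, smoothed per segment with the
  two outermost bins of each segment exempt; group-vs-rest splits (e.g.
  ribosomal-protein genes).
* **Nucleosome occupancy** — the same composite machinery on per-bp
  occupancy tracks (0–100 %), plus length-weighted segment means
  Σ ℓ_g·occ̄_g / Σ ℓ_g.
* **Synthetic study generator** — annotations, two-replicate probe
  intensities and occupancy tracks with *planted* enrichment structure
  (intergenic baseline, rate- and length-dependent ORF enrichment, intron
  depletion, 3′ intron–exon boundary bump, intron-depleted occupancy), so
  every stage is validated against ground truth.

Inputs are standard formats: BED12 or GFF3 annotation, chrom.sizes,
probe TSV, bedGraph tracks, two-column rate TSV.

## Worked example

The `analysis/` scripts run the whole study on a simulated genome
(600 genes, two chromosomes, ~240 k probes per replicate):

```sh
Rscript analysis/01_simulate.R     # synthetic bundle -> scratch/sim/
Rscript analysis/02_normalize.R    # normalized signal track
Rscript analysis/03_metagene.R     # averaged gene + stratified + regions
Rscript analysis/04_intron_exon.R  # exon-intron + occupancy
```

Output of the last two steps (tables under `results/`):

```
composite ORF mean 0.035 vs intergenic -0.5
ORF means across rate classes: -0.118 < 0.029 < 0.197 < 0.358 < 0.565
monotone in rate: TRUE
exon mean 0.107 | intron interior mean -0.398 | contrast 0.504 log2
composite peak at bin 41 (intron/exon2 boundary sits between bins 40 and 41)
length-weighted occupancy: exon1 77.448 | intron 40.285 | exon2 79.949 %
```

Reading: coding regions are enriched over the −0.5 log2 intergenic
baseline; ORF enrichment increases strictly across the five transcription-
rate classes; introns run ~0.5 log2 below their flanking exons (recovering
the planted 0.5 contrast) with the composite peaking at the 3′ intron–exon
boundary; and nucleosome occupancy is halved in introns (40 %) relative to
exons (80 %).

The same pipeline runs end-to-end from a single config:

```r
library(chdipmeta)
cfg <- pipeline_config(
  annotation = "scratch/sim/genes.bed",
  chrom_sizes = "scratch/sim/genome.chrom.sizes",
  probes = "scratch/sim/probes.tsv",
  rates = "scratch/sim/rates.tsv",
  occupancy = "scratch/sim/occupancy.bedgraph",
  out_dir = "scratch/run")
run_pipeline(cfg)   # TSVs + bedGraph + manifest.json + log
```

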