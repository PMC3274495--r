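#' Simulation parameters for the synthetic tiling-array study
#'
#' The defaults emulate the design of a budding-yeast ChDIP-chip experiment:
#' probes every 5 bp across the genome, two biological replicates with
#' multiplicative (log-normal) noise, ORF enrichment that grows with
#' transcription rate and coding-region length, a planted intron depletion
#' with a Gaussian bump at every 3' intron-exon boundary, and
#' nucleosome occupancy that is high in exons and depleted in introns.
#' Gene lengths, transcription rates, and intergenic gaps follow log-normal
#' distributions with yeast-scale medians (ORF ~1.4 kb, rate ~4 mRNA/h with
#' roughly 8% of detectable genes above 16 mRNA/h, gaps ~400 bp). Most
#' intron-containing genes carry a single 5'-proximal intron flanked by a
#' small first exon.
#'
#' @param n_chroms number of chromosomes.
#' @param n_genes total number of genes, split evenly across chromosomes.
#' @param gene_length_meanlog,gene_length_sdlog log-normal parameters of ORF
#'   length (bp).
#' @param min_gene_length lower clamp on ORF length (bp).
#' @param gap_meanlog,gap_sdlog,min_gap log-normal parameters and lower clamp
#'   of intergenic gaps (bp).
#' @param fraction_intron_containing probability that a gene carries one
#'   intron.
#' @param exon1_min,exon1_max uniform range of the (small) 5' exon length (bp).
#' @param intron_meanlog,intron_sdlog,min_intron log-normal parameters and
#'   lower clamp of intron length (bp).
#' @param min_exon2 minimum 3' exon length retained after intron placement (bp).
#' @param rate_meanlog,rate_sdlog log-normal parameters of transcription rate
#'   (mRNA copies per hour).
#' @param rate_detected_fraction fraction of genes whose rate is observable;
#'   the rest get `NA` (transcription not detectable).
#' @param probe_spacing distance between probe centres (bp).
#' @param intergenic_baseline planted log2 enrichment outside genes.
#' @param enrichment_slope_rate planted log2 enrichment per unit
#'   log2(1 + rate) inside ORFs.
#' @param enrichment_slope_length planted log2 enrichment per kb of ORF
#'   length.
#' @param intron_exon_delta planted log2 depletion of intron probes relative
#'   to exons of the same gene.
#' @param boundary_bump_height,boundary_bump_width height (log2 units) and
#'   Gaussian sd (bp) of the planted peak centred on each 3' intron-exon
#'   boundary.
#' @param noise_sd sd (log2 scale) of the per-channel multiplicative noise;
#'   each replicate's IP and control channels draw independent noise, so the
#'   expected log2(IP/control) equals the planted enrichment.
#' @param control_level mean control-channel intensity (arbitrary
#'   fluorescence units).
#' @param occupancy_exon_mean,occupancy_intron_mean,occupancy_intergenic_mean
#'   expected nucleosome occupancy (percent) by annotation context.
#' @param occupancy_ramp half-width (bp) of the smoothed transition at
#'   occupancy boundaries.
#' @param occupancy_noise_sd sd (percentage points) of additive occupancy
#'   noise; values are clipped to `[0, 100]`.
#' @param chrom_length optional fixed chromosome length (bp); genes that do
#'   not fit raise an error. `NULL` (default) sizes each chromosome to its
#'   content.
#' @param seed integer seed; all stages derive their own substream from it.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_chroms = 2L,
                       n_genes = 200L,
                       gene_length_meanlog = log(1400),
                       gene_length_sdlog = 0.45,
                       min_gene_length = 400L,
                       gap_meanlog = log(400),
                       gap_sdlog = 0.5,
                       min_gap = 200L,
                       fraction_intron_containing = 0.05,
                       exon1_min = 10L,
                       exon1_max = 60L,
                       intron_meanlog = log(300),
                       intron_sdlog = 0.4,
                       min_intron = 60L,
                       min_exon2 = 100L,
                       rate_meanlog = log(4),
                       rate_sdlog = 1.0,
                       rate_detected_fraction = 0.8,
                       probe_spacing = 5L,
                       intergenic_baseline = -0.5,
                       enrichment_slope_rate = 0.2,
                       enrichment_slope_length = 0.1,
                       intron_exon_delta = 0.5,
                       boundary_bump_height = 0.5,
                       boundary_bump_width = 20,
                       noise_sd = 0.2,
                       control_level = 1000,
                       occupancy_exon_mean = 80,
                       occupancy_intron_mean = 40,
                       occupancy_intergenic_mean = 60,
                       occupancy_ramp = 5L,
                       occupancy_noise_sd = 8,
                       chrom_length = NULL,
                       seed = 1L) {
  p <- as.list(environment())
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(
    p$n_chroms >= 1, p$n_genes >= 1,
    p$probe_spacing >= 1,
    p$fraction_intron_containing >= 0, p$fraction_intron_containing <= 1,
    p$rate_detected_fraction >= 0, p$rate_detected_fraction <= 1,
    p$occupancy_exon_mean >= 0, p$occupancy_exon_mean <= 100,
    p$occupancy_intron_mean >= 0, p$occupancy_intron_mean <= 100,
    p$occupancy_intergenic_mean >= 0, p$occupancy_intergenic_mean <= 100,
    p$noise_sd >= 0, p$occupancy_noise_sd >= 0,
    p$min_gene_length >= p$exon1_max + p$min_intron + p$min_exon2
  )
  invisible(p)
}

# Stage substreams: annotation, probes and occupancy each reset the RNG from
# a seed derived from the master seed, so regenerating one stage (or adding
# downstream stages) never perturbs the draws of another.
stage_seed <- function(seed, stage) {
  offsets <- c(genome = 1L, probes = 2L, occupancy = 3L)
  (as.integer(seed) + 10007L * offsets[[stage]]) %% .Machine$integer.max
}

#' Simulate a genome annotation
#'
#' Places non-overlapping genes separated by log-normal intergenic gaps on
#' `n_chroms` chromosomes, assigns strands, transcription rates, and gives a
#' fraction of genes a single 5'-proximal intron (small first exon, larger
#' final exon), the typical architecture of yeast intron-containing genes.
#' Deterministic under a fixed seed.
#'
#' @param params a [sim_params()] object.
#' @return list with elements `layout` (a [genome_layout()]), `genes`
#'   (a [gene_table()] with the `rate` column filled) and `rates`
#'   (data.frame `gene_id`, `rate` restricted to detectable genes).
#' @export
simulate_genome <- function(params) {
  validate_sim_params(params)
  set.seed(stage_seed(params$seed, "genome"))
  n <- params$n_genes
  per_chrom <- rep(n %/% params$n_chroms, params$n_chroms)
  extra <- n %% params$n_chroms
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L

  lens <- pmax(params$min_gene_length,
               round(stats::rlnorm(n, params$gene_length_meanlog,
                                   params$gene_length_sdlog)))
  gaps <- pmax(params$min_gap,
               round(stats::rlnorm(n + params$n_chroms, params$gap_meanlog,
                                   params$gap_sdlog)))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  rates <- stats::rlnorm(n, params$rate_meanlog, params$rate_sdlog)
  detected <- stats::runif(n) < params$rate_detected_fraction
  has_intron <- stats::runif(n) < params$fraction_intron_containing
  exon1_len <- round(stats::runif(n, params$exon1_min, params$exon1_max))
  intron_len <- pmax(params$min_intron,
                     round(stats::rlnorm(n, params$intron_meanlog,
                                         params$intron_sdlog)))
  # introns must leave room for the 3' exon
  intron_len <- pmin(intron_len, lens - exon1_len - params$min_exon2)

  gene_id <- sprintf("gene%04d", seq_len(n))
  chrom <- character(n)
  start <- integer(n)
  chrom_sizes <- integer(params$n_chroms)
  names(chrom_sizes) <- sprintf("chr%02d", seq_len(params$n_chroms))
  g <- 1L
  gi <- 1L
  for (ci in seq_len(params$n_chroms)) {
    pos <- 0L
    for (k in seq_len(per_chrom[ci])) {
      pos <- pos + gaps[gi]
      gi <- gi + 1L
      chrom[g] <- names(chrom_sizes)[ci]
      start[g] <- pos
      pos <- pos + lens[g]
      g <- g + 1L
    }
    pos <- pos + gaps[gi]
    gi <- gi + 1L
    chrom_sizes[ci] <- pos
    if (!is.null(params$chrom_length)) {
      if (pos > params$chrom_length) {
        stop("genes do not fit on a chromosome of length ",
             params$chrom_length, "; reduce n_genes or gene sizes")
      }
      chrom_sizes[ci] <- as.integer(params$chrom_length)
    }
  }

  exons <- vector("list", n)
  for (i in seq_len(n)) {
    s <- start[i]; e <- start[i] + lens[i]
    if (!has_intron[i]) {
      exons[[i]] <- cbind(start = s, end = e)
    } else if (strands[i] == "+") {
      # 5'-proximal intron: small exon1 on the left
      i_s <- s + exon1_len[i]
      i_e <- i_s + intron_len[i]
      exons[[i]] <- cbind(start = c(s, i_e), end = c(i_s, e))
    } else {
      # transcription right-to-left: exon1 is the rightmost block
      i_e <- e - exon1_len[i]
      i_s <- i_e - intron_len[i]
      exons[[i]] <- cbind(start = c(s, i_e), end = c(i_s, e))
    }
  }

  rate_col <- ifelse(detected, rates, NA_real_)
  genes <- gene_table(gene_id, chrom, start, start + lens, strands,
                      exons = exons, rate = rate_col)
  layout <- genome_layout(chrom_sizes)
  list(
    layout = layout,
    genes = genes,
    rates = data.frame(gene_id = gene_id[detected],
                       rate = rates[detected],
                       stringsAsFactors = FALSE)
  )
}

#' Planted log2 enrichment at arbitrary positions
#'
#' The ground-truth signal model: `intergenic_baseline` outside genes; inside
#' an ORF, `baseline + slope_rate * log2(1 + rate) + slope_length * (length
#' in kb)`, lowered by `intron_exon_delta` inside introns, plus a Gaussian
#' bump of the configured height and width centred on every 3' intron-exon
#' boundary. Genes without a detectable rate contribute no rate term.
#'
#' @param chrom,pos parallel vectors of positions (0-based bp).
#' @param genes a [gene_table()].
#' @param params a [sim_params()].
#' @return numeric vector of planted log2 enrichments.
#' @export
true_signal <- function(chrom, pos, genes, params) {
  val <- rep(params$intergenic_baseline, length(pos))
  for (i in seq_len(nrow(genes))) {
    sel <- chrom == genes$chrom[i] & pos >= genes$start[i] & pos < genes$end[i]
    if (!any(sel)) next
    rate <- genes$rate[i]
    orf <- params$intergenic_baseline +
      params$enrichment_slope_rate * log2(1 + if (is.na(rate)) 0 else rate) +
      params$enrichment_slope_length * (genes$end[i] - genes$start[i]) / 1000
    v <- rep(orf, sum(sel))
    intr <- gene_introns(genes, i)
    if (nrow(intr) > 0) {
      p <- pos[sel]
      for (j in seq_len(nrow(intr))) {
        v[p >= intr[j, 1] & p < intr[j, 2]] <-
          v[p >= intr[j, 1] & p < intr[j, 2]] - params$intron_exon_delta
        # 3' intron-exon boundary in transcription orientation
        b <- if (genes$strand[i] == "+") intr[j, 2] else intr[j, 1]
        v <- v + params$boundary_bump_height *
          exp(-0.5 * ((p + 0.5 - b) / params$boundary_bump_width)^2)
      }
    }
    val[sel] <- v
  }
  val
}

#' Simulate two-replicate probe intensities
#'
#' Lays probes every `probe_spacing` bp along each chromosome and draws, for
#' each replicate, IP and control intensities around `control_level` with
#' independent multiplicative log-normal noise such that the expected
#' log2(IP/control) of every probe equals its planted enrichment
#' ([true_signal()]).
#'
#' @param layout a [genome_layout()].
#' @param genes a [gene_table()].
#' @param params a [sim_params()].
#' @param n_replicates number of replicate array pairs (default 2).
#' @return probe table data.frame (`chrom`, `pos`, `ip_1`, `c_1`, ...).
#' @export
simulate_probe_arrays <- function(layout, genes, params, n_replicates = 2L) {
  validate_sim_params(params)
  set.seed(stage_seed(params$seed, "probes"))
  chrom <- character(0)
  pos <- integer(0)
  for (cn in names(layout$chrom_sizes)) {
    p <- seq.int(0L, layout$chrom_sizes[[cn]] - 1L, by = params$probe_spacing)
    chrom <- c(chrom, rep(cn, length(p)))
    pos <- c(pos, p)
  }
  truth <- true_signal(chrom, pos, genes, params)
  out <- data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  for (r in seq_len(n_replicates)) {
    eps_ip <- stats::rnorm(length(pos), 0, params$noise_sd)
    eps_c <- stats::rnorm(length(pos), 0, params$noise_sd)
    out[[paste0("ip_", r)]] <- params$control_level * 2^(truth + eps_ip)
    out[[paste0("c_", r)]] <- params$control_level * 2^eps_c
  }
  out
}

#' Simulate a per-bp nucleosome-occupancy track
#'
#' Expected occupancy is `occupancy_exon_mean` in exons,
#' `occupancy_intron_mean` in introns and `occupancy_intergenic_mean`
#' elsewhere, smoothed at every boundary by a moving average of half-width
#' `occupancy_ramp` bp; additive Gaussian noise (sd `occupancy_noise_sd`) is
#' applied per bp and values are clipped to `[0, 100]`. Positions further
#' than `occupancy_ramp` bp from any boundary keep their exact expected
#' value when noise is off.
#'
#' @inheritParams simulate_probe_arrays
#' @return per-bp data.frame (`chrom`, `pos`, `value`).
#' @export
simulate_occupancy_track <- function(layout, genes, params) {
  validate_sim_params(params)
  set.seed(stage_seed(params$seed, "occupancy"))
  out <- vector("list", length(layout$chrom_sizes))
  for (ci in seq_along(layout$chrom_sizes)) {
    cn <- names(layout$chrom_sizes)[ci]
    size <- layout$chrom_sizes[[ci]]
    base <- rep(params$occupancy_intergenic_mean, size)
    for (i in which(genes$chrom == cn)) {
      base[(genes$start[i] + 1):genes$end[i]] <- params$occupancy_exon_mean
      intr <- gene_introns(genes, i)
      for (j in seq_len(nrow(intr))) {
        base[(intr[j, 1] + 1):intr[j, 2]] <- params$occupancy_intron_mean
      }
    }
    if (params$occupancy_ramp > 0) {
      w <- 2L * as.integer(params$occupancy_ramp) + 1L
      sm <- stats::filter(base, rep(1, w), sides = 2) / w
      smoothed <- as.numeric(sm)
      smoothed[is.na(smoothed)] <- base[is.na(smoothed)]  # chromosome ends
      base <- smoothed
    }
    if (params$occupancy_noise_sd > 0) {
      base <- base + stats::rnorm(size, 0, params$occupancy_noise_sd)
    }
    out[[ci]] <- data.frame(chrom = cn, pos = seq_len(size) - 1L,
                            value = pmin(100, pmax(0, base)),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write a full synthetic study bundle to disk
#'
#' Emits the same formats the readers consume: BED12 annotation,
#' chrom.sizes, transcription-rate TSV, probe TSV and occupancy bedGraph.
#'
#' @param params a [sim_params()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_simulation_bundle <- function(params, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(params)
  probes <- simulate_probe_arrays(sim$layout, sim$genes, params)
  occ <- simulate_occupancy_track(sim$layout, sim$genes, params)
  paths <- c(
    annotation = file.path(dir, "genes.bed"),
    chrom_sizes = file.path(dir, "genome.chrom.sizes"),
    rates = file.path(dir, "rates.tsv"),
    probes = file.path(dir, "probes.tsv"),
    occupancy = file.path(dir, "occupancy.bedgraph")
  )
  write_gene_annotation(sim$genes, paths[["annotation"]], "bed12")
  write_chrom_sizes(sim$layout$chrom_sizes, paths[["chrom_sizes"]])
  write_rate_table(sim$rates, paths[["rates"]])
  write_probe_table(probes, paths[["probes"]])
  write_occupancy_bedgraph(occ, paths[["occupancy"]])
  invisible(paths)
}
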