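make_two_gene_setup <- function() {
  layout <- genome_layout(c(chrI = 3000L))
  genes <- gene_table(c("gA", "gB"), "chrI", c(500L, 2000L), c(900L, 2400L),
                      c("+", "+"))
  list(layout = layout, genes = genes,
       intergenic = derive_intergenic_regions(genes, layout))
}

test_that("cross-gene averaging weights genes equally", {
  s <- make_two_gene_setup()
  # gene A probes all 1.0 (many), gene B probes all 3.0 (few)
  track <- rbind(make_track(seq(500, 899, by = 5), 1.0),
                 make_track(seq(2000, 2399, by = 10), 3.0))
  prof <- composite_average_gene(track, s$genes, s$intergenic)
  seg <- rep(prof$segments$segment, prof$segments$n_bins)
  expect_equal(unique(prof$values[seg == "ORF"]), 2.0)
  expect_equal(unique(prof$n_genes[seg == "ORF"]), 2L)
  # single gene: composite equals that gene's own bin means
  one <- s$genes[1, ]
  class(one) <- class(s$genes)
  p1 <- composite_average_gene(track, one, s$intergenic)
  expect_equal(p1$values[seg == "ORF"],
               bin_region(track, "chrI", 500, 900, "+", 40))
  expect_error(composite_average_gene(track, s$genes[0, ], s$intergenic),
               "no genes")
})

test_that("duplicating probes changes nothing; adding a gene copy does", {
  s <- make_two_gene_setup()
  track <- rbind(make_track(seq(500, 899, by = 5), 1.0),
                 make_track(seq(2000, 2399, by = 5), 3.0))
  base <- composite_average_gene(track, s$genes, s$intergenic)
  # extra probes carrying the same value inside gene A leave bin means and
  # hence the composite unchanged
  extra <- make_track(seq(500, 899, by = 5) + 2L, 1.0)
  dup2 <- rbind(track, extra)
  pd <- composite_average_gene(dup2, s$genes, s$intergenic)
  seg <- rep(base$segments$segment, base$segments$n_bins)
  expect_equal(pd$values[seg == "ORF"], base$values[seg == "ORF"])
  # a third gene identical to gene A pulls the composite toward 1.0
  genes3 <- gene_table(c("gA", "gB", "gA2"), "chrI",
                       c(500L, 2000L, 1200L), c(900L, 2400L, 1600L),
                       c("+", "+", "+"))
  track3 <- rbind(track, make_track(seq(1200, 1599, by = 5), 1.0))
  ig3 <- derive_intergenic_regions(genes3, genome_layout(c(chrI = 3000L)))
  p3 <- composite_average_gene(track3, genes3, ig3)
  expect_equal(unique(round(p3$values[seg == "ORF"], 10)), 5 / 3)
})

test_that("noise-free planted profile is recovered exactly in every bin", {
  p <- sim_params(n_genes = 20, fraction_intron_containing = 0,
                  noise_sd = 0, rate_detected_fraction = 1, seed = 31)
  sim <- simulate_genome(p)
  probes <- simulate_probe_arrays(sim$layout, sim$genes, p)
  track <- normalize_probe_table(probes)
  ig <- derive_intergenic_regions(sim$genes, sim$layout)
  prof <- composite_average_gene(track, sim$genes, ig)
  seg <- rep(prof$segments$segment, prof$segments$n_bins)
  # every gene's ORF carries a flat planted enrichment; the composite ORF
  # bins must all equal the mean of those per-gene constants exactly
  planted <- p$intergenic_baseline +
    p$enrichment_slope_rate * log2(1 + sim$genes$rate) +
    p$enrichment_slope_length * (sim$genes$end - sim$genes$start) / 1000
  expect_equal(unname(prof$values[seg == "ORF"]),
               rep(mean(planted), 40), tolerance = 1e-9)
  expect_equal(unname(prof$values[seg != "ORF"]),
               rep(p$intergenic_baseline, 40), tolerance = 1e-9)
})

test_that("region summary classifies probes and flags empty classes", {
  layout <- genome_layout(
    c(chrI = 1000L), telomere_width = 100L,
    special_regions = list(
      rDNA = data.frame(chrom = "chrI", start = 450L, end = 470L),
      HM = data.frame(chrom = "chrI", start = 980L, end = 1000L)
    )
  )
  genes <- gene_table("g1", "chrI", 200L, 400L, "+")
  uniform <- make_track(seq(0, 999, by = 10), 1.0)
  rs <- region_summary(uniform, genes, layout)
  expect_equal(rs$mean, rep(1.0, nrow(rs)))
  expect_setequal(rs$region,
                  c("genome", "ORF", "intergenic", "telomere", "rDNA", "HM"))

  orfy <- uniform
  orfy$value <- ifelse(orfy$pos >= 200 & orfy$pos < 400, 2.0, 0.0)
  rs2 <- region_summary(orfy, genes, layout)
  expect_equal(rs2$mean[rs2$region == "ORF"], 2.0)
  expect_equal(rs2$mean[rs2$region == "intergenic"], 0.0)

  empty_layout <- genome_layout(
    c(chrI = 1000L), telomere_width = 100L,
    special_regions = list(rDNA = data.frame(chrom = "chrI", start = 451L,
                                             end = 455L))
  )
  expect_warning(rs3 <- region_summary(uniform, genes, empty_layout),
                 "rDNA")
  expect_true(is.na(rs3$mean[rs3$region == "rDNA"]))
})

test_that("intergenic baseline is recovered from a synthetic genome", {
  p <- sim_params(n_genes = 60, noise_sd = 0.2, seed = 17)
  sim <- simulate_genome(p)
  probes <- simulate_probe_arrays(sim$layout, sim$genes, p)
  track <- normalize_probe_table(probes)
  rs <- region_summary(track, sim$genes, sim$layout)
  expect_lt(abs(rs$mean[rs$region == "intergenic"] - p$intergenic_baseline),
            0.05)
})

test_that("stratified profiles separate planted class enrichments", {
  # two rate classes with disjoint planted ORF enrichments, noise off
  p <- sim_params(n_genes = 16, fraction_intron_containing = 0,
                  noise_sd = 0, enrichment_slope_rate = 0,
                  enrichment_slope_length = 0, rate_detected_fraction = 1,
                  seed = 19)
  sim <- simulate_genome(p)
  probes <- simulate_probe_arrays(sim$layout, sim$genes, p)
  track <- normalize_probe_table(probes)
  # plant disjoint enrichments by hand: first half 0.5, second half 1.5
  in_gene_half <- function(track, genes, rows, value) {
    for (i in rows) {
      sel <- track$chrom == genes$chrom[i] & track$pos >= genes$start[i] &
        track$pos < genes$end[i]
      track$value[sel] <- value
    }
    track
  }
  track <- in_gene_half(track, sim$genes, 1:8, 0.5)
  track <- in_gene_half(track, sim$genes, 9:16, 1.5)
  classes <- stats::setNames(
    factor(rep(c("lo", "hi"), each = 8), levels = c("lo", "hi")),
    sim$genes$gene_id)
  ig <- derive_intergenic_regions(sim$genes, sim$layout)
  profs <- stratified_profiles(track, sim$genes, classes, ig)
  expect_equal(segment_mean(profs$lo), 0.5, tolerance = 1e-9)
  expect_equal(segment_mean(profs$hi), 1.5, tolerance = 1e-9)
  # all genes in one class reduces to the plain composite
  all_one <- stats::setNames(factor(rep("all", 16)), sim$genes$gene_id)
  p_all <- stratified_profiles(track, sim$genes, all_one, ig)$all
  expect_equal(p_all$values,
               composite_average_gene(track, sim$genes, ig)$values)
  # a rate filter restricts the gene set before stratification
  lows <- suppressWarnings(
    stratified_profiles(track, sim$genes, classes, ig,
                        rate_filter = function(r) !is.na(r) & r < 2))
  kept <- sim$genes$gene_id[!is.na(sim$genes$rate) & sim$genes$rate < 2]
  expect_equal(sum(vapply(lows, function(pp) max(pp$n_genes), numeric(1))),
               length(kept))
})

test_that("mirroring the genome leaves the composite unchanged", {
  p <- sim_params(n_genes = 30, fraction_intron_containing = 0.4,
                  noise_sd = 0.2, seed = 23)
  sim <- simulate_genome(p)
  probes <- simulate_probe_arrays(sim$layout, sim$genes, p)
  track <- normalize_probe_table(probes)
  ig <- derive_intergenic_regions(sim$genes, sim$layout)
  prof <- composite_average_gene(track, sim$genes, ig)

  m_genes <- mirror_genes(sim$genes, sim$layout)
  m_track <- mirror_track(track, sim$layout)
  m_ig <- derive_intergenic_regions(m_genes, sim$layout)
  m_prof <- composite_average_gene(m_track, m_genes, m_ig)
  expect_identical(prof$n_genes, m_prof$n_genes)
  expect_equal(prof$values, m_prof$values, tolerance = 1e-12)
})
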