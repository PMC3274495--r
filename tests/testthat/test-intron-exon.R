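test_that("exon-intron units enumerate flanking exons in both orientations", {
  g <- gene_table("g3x", "chrI", 0L, 500L, "+",
                  exons = list(cbind(c(0L, 110L, 310L), c(10L, 210L, 500L))))
  u <- exon_intron_units(g)
  expect_equal(nrow(u), 2L)
  expect_equal(u$unit_index, 1:2)
  expect_equal(unlist(u[1, c("e1_start", "e1_end", "i_start", "i_end",
                             "e2_start", "e2_end")], use.names = FALSE),
               c(0L, 10L, 10L, 110L, 110L, 210L))
  expect_equal(unlist(u[2, c("e1_start", "e1_end", "i_start", "i_end",
                             "e2_start", "e2_end")], use.names = FALSE),
               c(110L, 210L, 210L, 310L, 310L, 500L))

  gm <- g
  gm$strand <- "-"
  class(gm) <- class(g)
  um <- exon_intron_units(gm)
  # unit 1's exon1 is the genomically rightmost exon
  expect_equal(unlist(um[1, c("e1_start", "e1_end")], use.names = FALSE),
               c(310L, 500L))
  expect_equal(unlist(um[1, c("i_start", "i_end")], use.names = FALSE),
               c(210L, 310L))
  expect_equal(unlist(um[1, c("e2_start", "e2_end")], use.names = FALSE),
               c(110L, 210L))

  intronless <- gene_table("flat", "chrI", 600L, 900L, "+")
  expect_equal(nrow(exon_intron_units(intronless)), 0L)
})

test_that("multi-intron fixture units match hand enumeration", {
  genes <- gene_table(
    c("a", "b"), c("chrI", "chrII"), c(100L, 50L), c(1000L, 700L),
    c("+", "-"),
    exons = list(cbind(c(100L, 300L, 600L), c(200L, 500L, 1000L)),
                 cbind(c(50L, 400L), c(300L, 700L)))
  )
  u <- exon_intron_units(genes)
  expect_equal(u$gene_id, c("a", "a", "b"))
  # gene b is minus-strand single intron: exon1 = [400,700), intron [300,400)
  expect_equal(unlist(u[3, c("e1_start", "i_start", "i_end", "e2_end")],
                      use.names = FALSE),
               c(400L, 300L, 400L, 300L))
})

test_that("noise-free exon and intron levels are recovered exactly", {
  # one shared planted ORF level across genes (constant rate, no length
  # term), so every bin equals it no matter which genes cover the bin
  p <- sim_params(n_genes = 10, fraction_intron_containing = 1,
                  noise_sd = 0, boundary_bump_height = 0,
                  rate_sdlog = 0, enrichment_slope_length = 0,
                  rate_detected_fraction = 1, seed = 41)
  sim <- simulate_genome(p)
  probes <- simulate_probe_arrays(sim$layout, sim$genes, p)
  track <- normalize_probe_table(probes)
  prof <- composite_exon_intron(track, sim$genes)
  seg <- rep(prof$segments$segment, prof$segments$n_bins)
  e <- p$intergenic_baseline +
    p$enrichment_slope_rate * log2(1 + exp(p$rate_meanlog))
  exon_bins <- prof$values[seg != "intron"]
  intron_bins <- prof$values[seg == "intron"]
  expect_gt(sum(!is.na(exon_bins)), 40)
  expect_equal(unname(exon_bins[!is.na(exon_bins)]),
               rep(e, sum(!is.na(exon_bins))), tolerance = 1e-9)
  expect_gt(sum(!is.na(intron_bins)), 25)
  expect_equal(unname(intron_bins[!is.na(intron_bins)]),
               rep(e - p$intron_exon_delta, sum(!is.na(intron_bins))),
               tolerance = 1e-9)
})

test_that("uniform signal yields a flat profile that smoothing preserves", {
  genes <- gene_table("u1", "chrI", 0L, 600L, "+",
                      exons = list(cbind(c(0L, 150L), c(50L, 600L))))
  track <- make_flat_track(600, 2.0)
  prof <- composite_exon_intron(track, genes)
  expect_equal(prof$values, rep(2.0, 80))
  sm <- smooth_profile(prof, per_segment = TRUE)
  expect_equal(sm$values, rep(2.0, 80))
})

test_that("the planted 3' boundary bump lands at the intron/exon2 junction", {
  p <- sim_params(n_genes = 40, fraction_intron_containing = 1,
                  noise_sd = 0, boundary_bump_height = 0.8,
                  boundary_bump_width = 15, rate_sdlog = 0,
                  enrichment_slope_length = 0, rate_detected_fraction = 1,
                  seed = 43)
  sim <- simulate_genome(p)
  probes <- simulate_probe_arrays(sim$layout, sim$genes, p)
  track <- normalize_probe_table(probes)
  prof <- composite_exon_intron(track, sim$genes)
  # remove the per-gene flat level by subtracting exon2's far end
  peak_bin <- which.max(prof$values)
  # layout 10/30/40: intron is bins 11-40, exon2 starts at bin 41
  expect_true(peak_bin %in% 39:42)
})

test_that("minus-strand genes profile identically to their mirror image", {
  p <- sim_params(n_genes = 16, fraction_intron_containing = 1,
                  noise_sd = 0.3, seed = 47)
  sim <- simulate_genome(p)
  probes <- simulate_probe_arrays(sim$layout, sim$genes, p)
  track <- normalize_probe_table(probes)
  prof <- composite_exon_intron(track, sim$genes)
  m_prof <- composite_exon_intron(mirror_track(track, sim$layout),
                                  mirror_genes(sim$genes, sim$layout))
  expect_equal(prof$values, m_prof$values, tolerance = 1e-12)
  expect_identical(prof$n_genes, m_prof$n_genes)
})

test_that("weighted occupancy is a length-weighted mean with additivity", {
  # two introns, lengths 100 and 300, occupancies 50 and 100 -> 87.5
  genes <- gene_table(
    c("w1", "w2"), "chrI", c(0L, 1000L), c(500L, 1800L), c("+", "+"),
    exons = list(cbind(c(0L, 150L), c(50L, 500L)),
                 cbind(c(1000L, 1400L), c(1100L, 1800L)))
  )
  occ <- make_flat_track(2000, 0)
  occ$value[occ$pos >= 50 & occ$pos < 150] <- 50    # intron 1 (100 bp)
  occ$value[occ$pos >= 1100 & occ$pos < 1400] <- 100  # intron 2 (300 bp)
  units <- exon_intron_units(genes)
  expect_equal(weighted_occupancy(occ, units, "intron"), 87.5)
  # equal lengths reduce to the simple mean
  occ2 <- occ
  occ2$value[occ2$pos >= 1100 & occ2$pos < 1400] <- 70
  genes_eq <- gene_table(
    c("w1", "w2"), "chrI", c(0L, 1000L), c(500L, 1800L), c("+", "+"),
    exons = list(cbind(c(0L, 150L), c(50L, 500L)),
                 cbind(c(1000L, 1200L), c(1100L, 1800L)))
  )
  units_eq <- exon_intron_units(genes_eq)
  expect_equal(weighted_occupancy(occ2, units_eq, "intron"), 60)
  # single unit: its own mean
  expect_equal(weighted_occupancy(occ, units[1, ], "intron"), 50)
  # additivity: splitting a segment into sub-intervals changes nothing
  w_all <- weighted_occupancy(occ, units, "intron")
  sub <- units[c(1, 2, 2), ]
  sub$i_end[2] <- 1250L
  sub$i_start[3] <- 1250L
  expect_equal(weighted_occupancy(occ, sub, "intron"), w_all)
  bad <- units
  bad$i_end <- bad$i_start
  expect_error(weighted_occupancy(occ, bad, "intron"), "zero total")
})

test_that("occupancy composite recovers planted exon/intron levels", {
  p <- sim_params(n_genes = 12, fraction_intron_containing = 1,
                  occupancy_noise_sd = 0, occupancy_ramp = 0, seed = 51)
  sim <- simulate_genome(p)
  occ <- simulate_occupancy_track(sim$layout, sim$genes, p)
  prof <- composite_occupancy(occ, sim$genes)
  seg <- rep(prof$segments$segment, prof$segments$n_bins)
  exon_bins <- prof$values[seg != "intron"]
  expect_equal(unname(exon_bins[!is.na(exon_bins)]),
               rep(p$occupancy_exon_mean, sum(!is.na(exon_bins))))
  expect_equal(unname(prof$values[seg == "intron"]),
               rep(p$occupancy_intron_mean, 30))
  # with noise, intron bins stay clearly below exon bins
  p2 <- sim_params(n_genes = 200, fraction_intron_containing = 1, seed = 53)
  sim2 <- simulate_genome(p2)
  occ2 <- simulate_occupancy_track(sim2$layout, sim2$genes, p2)
  prof2 <- composite_occupancy(occ2, sim2$genes)
  seg2 <- rep(prof2$segments$segment, prof2$segments$n_bins)
  expect_lt(max(prof2$values[seg2 == "intron"][3:28]),
            min(prof2$values[seg2 == "exon2"][3:38]))
})

test_that("group split partitions intron-containing genes", {
  p <- sim_params(n_genes = 10, fraction_intron_containing = 1, seed = 57)
  sim <- simulate_genome(p)
  ids <- sim$genes$gene_id
  sp <- gene_group_split(sim$genes, ids[1:4])
  expect_equal(nrow(sp$group), 4L)
  expect_equal(nrow(sp$complement), 6L)
  # empty list: everything is complement
  sp0 <- gene_group_split(sim$genes, character(0))
  expect_equal(nrow(sp0$group), 0L)
  expect_equal(nrow(sp0$complement), 10L)
  # duplicates are deduplicated, unknown ids warn and are skipped
  expect_warning(spd <- gene_group_split(sim$genes,
                                         c(ids[1], ids[1], "nope")),
                 "absent")
  expect_equal(nrow(spd$group), 1L)

  # recombining group and complement composites with gene counts restores
  # the all-genes composite
  probes <- simulate_probe_arrays(sim$layout, sim$genes, p)
  track <- normalize_probe_table(probes)
  all_prof <- composite_exon_intron(track, sim$genes)
  pg <- composite_exon_intron(track, sp$group)
  pc <- composite_exon_intron(track, sp$complement)
  wsum <- function(p) ifelse(p$n_genes > 0, p$values * p$n_genes, 0)
  recombined <- (wsum(pg) + wsum(pc)) / (pg$n_genes + pc$n_genes)
  recombined[is.nan(recombined)] <- NA_real_
  expect_equal(recombined, all_prof$values, tolerance = 1e-12)
})
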