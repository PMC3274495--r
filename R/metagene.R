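#' Averaged-gene composite profile
#'
#' The "averaged gene": every gene's 5' intergenic flank, ORF and 3'
#' intergenic flank are scaled to a fixed bin layout (default 20/40/20, i.e.
#' the ORF occupies bins 21-60), probes are averaged per bin within each
#' gene, and the per-gene bin means are then averaged across genes with
#' equal gene weight (a gene's length or probe count does not change its
#' contribution). Intergenic flanks are taken from `intergenic` (see
#' [derive_intergenic_regions()]) and truncated to the `intergenic_cap` bp
#' nearest the gene so that rare huge gaps do not dominate the flank bins.
#' All binning is strand-aware: bin 1 is the 5'-most flank bin in
#' transcription orientation.
#'
#' @param track signal track (`chrom`, `pos`, `value`).
#' @param genes a [gene_table()].
#' @param intergenic per-gene flank table from [derive_intergenic_regions()].
#' @param layout named integer vector of bin counts, in order
#'   `c(upstream, orf, downstream)`.
#' @param intergenic_cap maximum flank extent in bp (default 1000).
#' @return a [composite_profile()] (unsmoothed).
#' @export
composite_average_gene <- function(track, genes, intergenic,
                                   layout = c(upstream = 20L, orf = 40L,
                                              downstream = 20L),
                                   intergenic_cap = 1000L) {
  if (nrow(genes) == 0) stop("no genes to profile")
  stopifnot(length(layout) == 3, all(layout >= 1))
  mat <- t(vapply(seq_len(nrow(genes)), function(i) {
    gene_segment_bins(track, genes, intergenic, i, layout, intergenic_cap)
  }, numeric(sum(layout))))
  segments <- data.frame(
    segment = c("5'_intergenic", "ORF", "3'_intergenic"),
    n_bins = as.integer(layout),
    stringsAsFactors = FALSE
  )
  aggregate_gene_matrix(mat, segments)
}

# 80-bin (by default) vector for one gene: capped 5' flank, ORF, capped 3'
# flank, in transcription orientation.
gene_segment_bins <- function(track, genes, intergenic, i, layout,
                              intergenic_cap) {
  j <- match(genes$gene_id[i], intergenic$gene_id)
  if (is.na(j)) stop("no intergenic entry for gene ", genes$gene_id[i])
  up <- cap_flank(intergenic$up_start[j], intergenic$up_end[j],
                  genes$strand[i], side = "up", cap = intergenic_cap)
  down <- cap_flank(intergenic$down_start[j], intergenic$down_end[j],
                    genes$strand[i], side = "down", cap = intergenic_cap)
  segs <- list(
    list(chrom = genes$chrom[i], start = up[1], end = up[2],
         n_bins = layout[[1]]),
    list(chrom = genes$chrom[i], start = genes$start[i], end = genes$end[i],
         n_bins = layout[[2]]),
    list(chrom = genes$chrom[i], start = down[1], end = down[2],
         n_bins = layout[[3]])
  )
  bin_segments(track, segs, genes$strand[i])
}

# Truncate a flank interval to the `cap` bp adjacent to the gene. For a
# plus-strand gene the 5' flank ends at the gene start (keep its right part)
# and the 3' flank begins at the gene end (keep its left part); minus strand
# mirrors this.
cap_flank <- function(start, end, strand, side, cap) {
  if (end <= start) return(c(start, start))
  near_gene_right <- (strand == "+" && side == "up") ||
    (strand == "-" && side == "down")
  if (near_gene_right) {
    c(max(start, end - cap), end)
  } else {
    c(start, min(end, start + cap))
  }
}

#' Mean signal over genomic region classes
#'
#' Summarises a signal track over the region classes used for genome-wide
#' comparisons: the whole genome, ORFs, intergenic space, telomeres (the
#' terminal `telomere_width` window at both ends of every chromosome) and
#' any special silent-chromatin regions carried by the layout (conventional
#' names `rDNA`, `HM`). A probe may contribute to several classes (a
#' telomeric ORF probe counts in both `ORF` and `telomere`).
#'
#' @param track signal track.
#' @param genes a [gene_table()].
#' @param layout a [genome_layout()].
#' @return data.frame with columns `region`, `mean`, `n_probes`; classes
#'   with no probes get `NA` with a warning.
#' @export
region_summary <- function(track, genes, layout) {
  in_orf <- rep(FALSE, nrow(track))
  for (i in seq_len(nrow(genes))) {
    in_orf <- in_orf | (track$chrom == genes$chrom[i] &
                          track$pos >= genes$start[i] &
                          track$pos < genes$end[i])
  }
  in_telomere <- rep(FALSE, nrow(track))
  for (cn in names(layout$chrom_sizes)) {
    size <- layout$chrom_sizes[[cn]]
    w <- min(layout$telomere_width, size)
    in_telomere <- in_telomere |
      (track$chrom == cn & (track$pos < w | track$pos >= size - w))
  }
  classes <- list(
    genome = rep(TRUE, nrow(track)),
    ORF = in_orf,
    intergenic = !in_orf,
    telomere = in_telomere
  )
  for (nm in names(layout$special_regions)) {
    reg <- layout$special_regions[[nm]]
    sel <- rep(FALSE, nrow(track))
    for (k in seq_len(nrow(reg))) {
      sel <- sel | (track$chrom == reg$chrom[k] &
                      track$pos >= reg$start[k] & track$pos < reg$end[k])
    }
    classes[[nm]] <- sel
  }
  means <- vapply(classes, function(sel) {
    if (!any(sel)) return(NA_real_)
    mean(track$value[sel])
  }, numeric(1))
  empty <- names(classes)[vapply(classes, function(s) !any(s), logical(1))]
  if (length(empty)) {
    warning("region class(es) without probes: ", paste(empty, collapse = ", "))
  }
  data.frame(
    region = names(classes),
    mean = unname(means),
    n_probes = vapply(classes, sum, numeric(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Class-stratified composite profiles
#'
#' Computes one averaged-gene profile per gene class (e.g. the five
#' transcription-rate classes or eight coding-length classes). An optional
#' `rate_filter` predicate restricts the gene set before stratification,
#' reproducing designs such as "genes below 16 mRNA/hour, split by length".
#'
#' @param track signal track.
#' @param genes a [gene_table()].
#' @param classes named vector/factor `gene_id` -> class label (see
#'   [classify_by_rate()], [classify_by_length()]).
#' @param intergenic flank table from [derive_intergenic_regions()].
#' @param rate_filter optional predicate on the numeric rate (e.g.
#'   `function(r) !is.na(r) & r < 16`) applied before profiling.
#' @param ... passed to [composite_average_gene()] (`layout`,
#'   `intergenic_cap`).
#' @return named list of [composite_profile()], one per class (ascending
#'   class levels); classes left without genes are omitted with a warning.
#' @export
stratified_profiles <- function(track, genes, classes, intergenic,
                                rate_filter = NULL, ...) {
  if (length(classes) == 0) stop("empty class map")
  if (!is.null(rate_filter)) {
    keep_ids <- genes$gene_id[rate_filter(genes$rate)]
    classes <- classes[names(classes) %in% keep_ids]
  }
  lev <- if (is.factor(classes)) levels(classes) else sort(unique(classes))
  out <- list()
  for (cl in lev) {
    ids <- names(classes)[!is.na(classes) & classes == cl]
    sub <- genes[genes$gene_id %in% ids, , drop = FALSE]
    if (nrow(sub) == 0) {
      warning("class '", cl, "' has no genes; omitted")
      next
    }
    class(sub) <- class(genes)
    out[[cl]] <- composite_average_gene(track, sub, intergenic, ...)
  }
  out
}

#' Mean ORF signal of a composite profile
#'
#' Convenience accessor: the mean of the bins belonging to the `ORF`
#' segment (ignoring missing bins).
#'
#' @param profile a [composite_profile()].
#' @param segment segment name (default `"ORF"`).
#' @return scalar mean.
#' @export
segment_mean <- function(profile, segment = "ORF") {
  seg <- rep(profile$segments$segment, profile$segments$n_bins)
  mean(profile$values[seg == segment], na.rm = TRUE)
}
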