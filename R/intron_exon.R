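#' Enumerate exon1-intron-exon2 units of intron-containing genes
#'
#' Unit k of a gene pairs its k-th intron (in transcription orientation)
#' with the flanking exons: exon1 is the 5' exon, exon2 the 3' exon. A
#' single-intron gene yields exactly one unit; intronless genes contribute
#' none. For minus-strand genes exon1 is the genomically rightmost of the
#' pair.
#'
#' @param genes a [gene_table()].
#' @return data.frame with one row per unit: `gene_id`, `unit_index`,
#'   `chrom`, `strand` and genomic (0-based half-open) interval columns
#'   `e1_start`, `e1_end`, `i_start`, `i_end`, `e2_start`, `e2_end`, where
#'   e1/i/e2 are in transcription orientation.
#' @export
exon_intron_units <- function(genes) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    k <- nrow(ex) - 1L
    if (k < 1) next
    # genomic-order units; transcription order on minus strand is reversed
    ord <- if (genes$strand[i] == "+") seq_len(k) else rev(seq_len(k))
    for (u in seq_len(k)) {
      g <- ord[u]  # genomic index of this unit's intron
      if (genes$strand[i] == "+") {
        e1 <- ex[g, ]; e2 <- ex[g + 1L, ]
      } else {
        e1 <- ex[g + 1L, ]; e2 <- ex[g, ]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = genes$gene_id[i], unit_index = u,
        chrom = genes$chrom[i], strand = genes$strand[i],
        e1_start = e1[[1]], e1_end = e1[[2]],
        i_start = ex[g, 2][[1]], i_end = ex[g + 1L, 1][[1]],
        e2_start = e2[[1]], e2_end = e2[[2]],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(0), unit_index = integer(0),
                      chrom = character(0), strand = character(0),
                      e1_start = integer(0), e1_end = integer(0),
                      i_start = integer(0), i_end = integer(0),
                      e2_start = integer(0), e2_end = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Exon1-intron-exon2 composite profile
#'
#' Each unit's three segments are binned independently (default layout
#' exon1: 10, intron: 30, exon2: 40 bins, i.e. bins 1-10, 11-40, 41-80),
#' strand-aware, and concatenated. Units of multi-intron genes are averaged
#' within the gene first, then genes are averaged with equal weight, so
#' multi-intron genes are not over-weighted. Tiny 5' exons shorter than the
#' bin count are handled by the floor rule with the unoccupied bins left
#' missing. Smoothing is not applied here; use
#' `smooth_profile(p, per_segment = TRUE)`, which leaves the first two and
#' last two bins of each of the three segments unsmoothed.
#'
#' @param track signal track (`chrom`, `pos`, `value`); a per-bp occupancy
#'   track works identically (see [composite_occupancy()]).
#' @param genes a [gene_table()]; only intron-containing genes contribute.
#' @param layout named bin counts `c(exon1, intron, exon2)`.
#' @return a [composite_profile()] (unsmoothed).
#' @export
composite_exon_intron <- function(track, genes,
                                  layout = c(exon1 = 10L, intron = 30L,
                                             exon2 = 40L)) {
  stopifnot(length(layout) == 3, all(layout >= 1))
  units <- exon_intron_units(genes)
  if (nrow(units) == 0) stop("no intron-containing genes")
  n_bins <- sum(layout)
  ids <- unique(units$gene_id)
  mat <- matrix(NA_real_, nrow = length(ids), ncol = n_bins)
  for (gi in seq_along(ids)) {
    uu <- units[units$gene_id == ids[gi], , drop = FALSE]
    umat <- t(vapply(seq_len(nrow(uu)), function(k) {
      segs <- list(
        list(chrom = uu$chrom[k], start = uu$e1_start[k], end = uu$e1_end[k],
             n_bins = layout[[1]]),
        list(chrom = uu$chrom[k], start = uu$i_start[k], end = uu$i_end[k],
             n_bins = layout[[2]]),
        list(chrom = uu$chrom[k], start = uu$e2_start[k], end = uu$e2_end[k],
             n_bins = layout[[3]])
      )
      bin_segments(track, segs, uu$strand[k])
    }, numeric(n_bins)))
    gene_means <- colMeans(umat, na.rm = TRUE)
    gene_means[is.nan(gene_means)] <- NA_real_
    mat[gi, ] <- gene_means
  }
  segments <- data.frame(
    segment = c("exon1", "intron", "exon2"),
    n_bins = as.integer(layout),
    stringsAsFactors = FALSE
  )
  aggregate_gene_matrix(mat, segments)
}

#' Exon1-intron-exon2 composite of nucleosome occupancy
#'
#' Identical binning and averaging machinery to [composite_exon_intron()],
#' applied to a per-bp occupancy track (every bp carries a value, so bin
#' means are means over bp rather than over probes).
#'
#' @param occupancy per-bp occupancy data.frame (`chrom`, `pos`, `value`).
#' @param genes a [gene_table()].
#' @param layout named bin counts `c(exon1, intron, exon2)`.
#' @return a [composite_profile()].
#' @export
composite_occupancy <- function(occupancy, genes,
                                layout = c(exon1 = 10L, intron = 30L,
                                           exon2 = 40L)) {
  composite_exon_intron(occupancy, genes, layout)
}

#' Length-weighted mean occupancy of a segment class
#'
#' Averages per-unit mean occupancy over all units, weighting each unit's
#' segment by its length in bp, so longer segments contribute
#' proportionally more:
#' \deqn{\sum_g len_g \cdot \bar{occ}_g \; / \; \sum_g len_g.}
#'
#' @param occupancy per-bp occupancy data.frame.
#' @param units unit table from [exon_intron_units()].
#' @param segment `"exon1"`, `"intron"` or `"exon2"`.
#' @return scalar percent (0-100).
#' @export
weighted_occupancy <- function(occupancy, units,
                               segment = c("intron", "exon1", "exon2")) {
  segment <- match.arg(segment)
  cols <- switch(segment,
                 exon1 = c("e1_start", "e1_end"),
                 intron = c("i_start", "i_end"),
                 exon2 = c("e2_start", "e2_end"))
  total_len <- 0
  total_sum <- 0
  for (k in seq_len(nrow(units))) {
    s <- units[[cols[1]]][k]
    e <- units[[cols[2]]][k]
    len <- e - s
    if (len <= 0) next
    sel <- occupancy$chrom == units$chrom[k] &
      occupancy$pos >= s & occupancy$pos < e
    if (!any(sel)) next
    total_len <- total_len + len
    total_sum <- total_sum + len * mean(occupancy$value[sel])
  }
  if (total_len == 0) stop("zero total ", segment, " length")
  total_sum / total_len
}

#' Split intron-containing genes into a named group and its complement
#'
#' Partition used e.g. to separate ribosomal-protein (RP) genes, which carry
#' most yeast splicing activity, from the remaining intron-containing genes.
#' Membership is an explicit id list, not inferred. Listed ids absent from
#' the annotation are skipped with a warning; duplicates are ignored.
#'
#' @param genes a [gene_table()].
#' @param group_ids character vector of gene ids (or a file path readable by
#'   [read_group_list()]).
#' @return list with [gene_table()] elements `group` and `complement`,
#'   together covering exactly the intron-containing genes.
#' @export
gene_group_split <- function(genes, group_ids) {
  if (is.character(group_ids) && length(group_ids) == 1 &&
      file.exists(group_ids)) {
    group_ids <- read_group_list(group_ids)
  }
  group_ids <- unique(group_ids)
  unknown <- setdiff(group_ids, genes$gene_id)
  if (length(unknown)) {
    warning(length(unknown), " listed id(s) absent from annotation; skipped")
    group_ids <- setdiff(group_ids, unknown)
  }
  ic <- genes[n_introns(genes) >= 1, , drop = FALSE]
  class(ic) <- class(genes)
  grp <- ic[ic$gene_id %in% group_ids, , drop = FALSE]
  cmp <- ic[!ic$gene_id %in% group_ids, , drop = FALSE]
  class(grp) <- class(genes)
  class(cmp) <- class(genes)
  list(group = grp, complement = cmp)
}
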