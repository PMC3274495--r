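#' Construct a gene table
#'
#' The central annotation container: one row per gene, with the coding region
#' (ORF) as the gene body and exon structure as a list column. All coordinates
#' are 0-based, half-open `[start, end)`; GFF3 input is converted on read.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom chromosome name per gene.
#' @param start,end integer ORF bounds, 0-based half-open.
#' @param strand `"+"` or `"-"` per gene.
#' @param exons list of two-column matrices (`start`, `end`), one per gene, in
#'   genomic order and contained in `[start, end)`. `NULL` means every gene is
#'   a single exon spanning its ORF.
#' @param rate numeric transcription rate (mRNA copies per hour), `NA` when
#'   the gene's transcription is not detectable.
#' @return A `data.frame` of class `gene_table` with columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `rate` and list column `exons`.
#' @export
gene_table <- function(gene_id, chrom, start, end, strand,
                       exons = NULL, rate = NA_real_) {
  n <- length(gene_id)
  if (is.null(exons)) {
    exons <- Map(function(s, e) cbind(start = s, end = e), start, end)
  }
  genes <- data.frame(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    rate = rep_len(as.numeric(rate), n),
    stringsAsFactors = FALSE
  )
  genes$exons <- lapply(exons, function(m) {
    m <- matrix(as.integer(m), ncol = 2, dimnames = list(NULL, c("start", "end")))
    m[order(m[, 1]), , drop = FALSE]
  })
  class(genes) <- c("gene_table", "data.frame")
  validate_genes(genes)
  genes
}

#' Validate a gene table
#'
#' Checks the structural invariants: unique ids, strand in `{+,-}`,
#' `end > start`, exons sorted, non-overlapping, contained in the gene body,
#' and every intron at least 1 bp long.
#'
#' @param genes a [gene_table()].
#' @return `genes`, invisibly; errors name the offending `gene_id`.
#' @export
validate_genes <- function(genes) {
  stopifnot(is.data.frame(genes))
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicated gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1])
  }
  bad <- !genes$strand %in% c("+", "-")
  if (any(bad)) {
    stop("invalid strand for gene ", genes$gene_id[bad][1])
  }
  bad <- genes$end <= genes$start
  if (any(bad)) {
    stop("end must exceed start for gene ", genes$gene_id[bad][1])
  }
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    id <- genes$gene_id[i]
    if (nrow(ex) == 0) stop("gene ", id, " has no exons")
    if (any(ex[, 2] <= ex[, 1])) stop("empty exon in gene ", id)
    if (ex[1, 1] < genes$start[i] || ex[nrow(ex), 2] > genes$end[i]) {
      stop("exon outside gene bounds for gene ", id)
    }
    if (nrow(ex) > 1) {
      gaps <- ex[-1, 1] - ex[-nrow(ex), 2]
      if (any(gaps < 1)) {
        stop("overlapping or abutting exons (intron length < 1) in gene ", id)
      }
    }
  }
  invisible(genes)
}

#' Intron intervals of one gene
#'
#' @param genes a [gene_table()].
#' @param i row index.
#' @return Two-column matrix of intron intervals (0-based half-open) in
#'   genomic order; zero rows for an intronless gene.
#' @export
gene_introns <- function(genes, i) {
  ex <- genes$exons[[i]]
  if (nrow(ex) < 2) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = ex[-nrow(ex), 2], end = ex[-1, 1])
}

#' Number of introns per gene
#' @param genes a [gene_table()].
#' @return integer vector.
#' @export
n_introns <- function(genes) {
  vapply(genes$exons, nrow, integer(1)) - 1L
}

#' Construct a genome layout
#'
#' Chromosome sizes plus the named special regions used by
#' [region_summary()] (silent chromatin classes). The telomere class is not a
#' stored interval set: it is defined as the terminal `telomere_width` bp at
#' both ends of every chromosome.
#'
#' @param chrom_sizes named integer vector, chromosome -> length in bp.
#' @param telomere_width width in bp of the terminal windows forming the
#'   telomere class (default 20000, i.e. the last 20 kb of each chromosome).
#' @param special_regions named list of data.frames with columns
#'   `chrom`, `start`, `end` (0-based half-open); conventional names are
#'   `"rDNA"` and `"HM"`.
#' @return list of class `genome_layout`.
#' @export
genome_layout <- function(chrom_sizes, telomere_width = 20000L,
                          special_regions = list()) {
  stopifnot(!is.null(names(chrom_sizes)), all(chrom_sizes > 0))
  for (nm in names(special_regions)) {
    reg <- special_regions[[nm]]
    stopifnot(all(c("chrom", "start", "end") %in% names(reg)))
    sz <- chrom_sizes[reg$chrom]
    if (any(is.na(sz)) || any(reg$start < 0) || any(reg$end > sz)) {
      stop("special region '", nm, "' outside chromosome bounds")
    }
  }
  structure(
    list(
      chrom_sizes = stats::setNames(as.integer(chrom_sizes), names(chrom_sizes)),
      telomere_width = as.integer(telomere_width),
      special_regions = special_regions
    ),
    class = "genome_layout"
  )
}

#' Derive 5' and 3' intergenic regions for every gene
#'
#' Each gene's 5' intergenic interval runs from the end of the nearest
#' upstream neighbour (or the chromosome start) to the gene's
#' transcription-oriented start; symmetrically for the 3' side. Orientation
#' follows the strand, so the 5' interval of a minus-strand gene lies to its
#' genomic right. When neighbouring genes overlap, the interval on the
#' overlapped side is empty (never negative) and a warning is raised.
#'
#' @param genes a [gene_table()].
#' @param layout a [genome_layout()] supplying chromosome bounds.
#' @return data.frame keyed by `gene_id` with 0-based half-open columns
#'   `up_start`, `up_end` (5' flank) and `down_start`, `down_end` (3' flank);
#'   an empty flank has `start == end`.
#' @export
derive_intergenic_regions <- function(genes, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  missing_chrom <- setdiff(unique(genes$chrom), names(layout$chrom_sizes))
  if (length(missing_chrom)) {
    stop("chromosome not in layout: ", missing_chrom[1])
  }
  out <- data.frame(
    gene_id = genes$gene_id,
    up_start = NA_integer_, up_end = NA_integer_,
    down_start = NA_integer_, down_end = NA_integer_,
    stringsAsFactors = FALSE
  )
  n_overlap <- 0L
  for (chr in unique(genes$chrom)) {
    idx <- which(genes$chrom == chr)
    idx <- idx[order(genes$start[idx], genes$end[idx])]
    size <- layout$chrom_sizes[[chr]]
    ends <- genes$end[idx]
    # bound on the left: running max of previous ends handles nested overlaps
    left_bound <- c(0L, cummax(ends)[-length(idx)])
    right_bound <- c(genes$start[idx][-1], size)
    for (k in seq_along(idx)) {
      i <- idx[k]
      ls <- min(left_bound[k], genes$start[i])
      le <- genes$start[i]
      if (left_bound[k] > genes$start[i]) {
        ls <- le  # overlapped on the left
        n_overlap <- n_overlap + 1L
      }
      rs <- genes$end[i]
      re <- max(right_bound[k], genes$end[i])
      if (right_bound[k] < genes$end[i]) {
        re <- rs  # overlapped on the right
        n_overlap <- n_overlap + 1L
      }
      if (genes$strand[i] == "+") {
        out[i, c("up_start", "up_end", "down_start", "down_end")] <-
          c(ls, le, rs, re)
      } else {
        out[i, c("up_start", "up_end", "down_start", "down_end")] <-
          c(rs, re, ls, le)
      }
    }
  }
  if (n_overlap > 0) {
    warning(n_overlap, " gene flank(s) emptied by overlapping neighbours")
  }
  out
}

#' Classify genes by transcription rate
#'
#' Genes without a detectable rate (`NA`) are excluded, mirroring analyses
#' restricted to genes with assigned transcription rates. Class intervals are
#' half-open `(lo, hi]`; the top class is strictly `rate > max(boundaries)`,
#' so a gene at exactly the highest boundary falls in the class below.
#'
#' @param genes a [gene_table()] with a `rate` column.
#' @param boundaries ascending rate thresholds (mRNA/hour); the default
#'   `c(2, 4, 8, 16)` yields five classes with top class "> 16".
#' @return named factor, `gene_id` -> class label, ascending levels.
#' @export
classify_by_rate <- function(genes, boundaries = c(2, 4, 8, 16)) {
  if (length(boundaries) == 0) stop("boundaries must be non-empty")
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop("boundaries must be strictly ascending")
  }
  keep <- !is.na(genes$rate)
  rate <- genes$rate[keep]
  labels <- c(
    paste0("<=", boundaries[1]),
    if (length(boundaries) > 1) {
      paste0("(", boundaries[-length(boundaries)], ",", boundaries[-1], "]")
    },
    paste0(">", boundaries[length(boundaries)])
  )
  cls <- cut(rate, breaks = c(-Inf, boundaries, Inf), labels = labels,
             right = TRUE)
  stats::setNames(cls, genes$gene_id[keep])
}

#' Classify genes by coding-region length
#'
#' Default mode partitions by empirical length quantiles into `n_classes`
#' classes of near-equal size (sizes differ by at most one when lengths are
#' distinct). Ties share a class, so identically sized genes can never be
#' split across a boundary; a fully degenerate input (all lengths equal)
#' collapses to one class with a warning. Explicit `boundaries` switch to
#' fixed half-open `(lo, hi]` intervals instead.
#'
#' @param genes a [gene_table()].
#' @param n_classes number of length classes (default 8).
#' @param boundaries optional fixed length cut points overriding quantile mode.
#' @return named factor, `gene_id` -> class label `L1` (shortest) upward.
#' @export
classify_by_length <- function(genes, n_classes = 8, boundaries = NULL) {
  len <- genes$end - genes$start
  if (!is.null(boundaries)) {
    labels <- paste0("L", seq_len(length(boundaries) + 1))
    cls <- cut(len, breaks = c(-Inf, boundaries, Inf), labels = labels,
               right = TRUE)
    return(stats::setNames(cls, genes$gene_id))
  }
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (nrow(genes) < n_classes) {
    stop("fewer genes (", nrow(genes), ") than classes (", n_classes, ")")
  }
  r <- rank(len, ties.method = "min")
  k <- ceiling(r * n_classes / nrow(genes))
  cls <- factor(paste0("L", k), levels = paste0("L", seq_len(n_classes)))
  if (length(unique(k)) < n_classes) {
    warning("tied lengths collapsed some classes; ",
            length(unique(k)), " of ", n_classes, " classes populated")
  }
  stats::setNames(cls, genes$gene_id)
}
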