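#' Bin a genomic interval and average probe values per bin
#'
#' The interval `[start, end)` is split into `n_bins` contiguous
#' sub-intervals whose bp lengths differ by at most one: the bp at
#' transcription-oriented offset `o` (0-based) in a region of length `L`
#' falls in bin `floor(o * n_bins / L) + 1`. Every probe inside the interval
#' lands in exactly one bin; for minus-strand regions offsets are counted
#' from the right end, so bin 1 is always 5'-most in transcription
#' orientation. Bins containing no probes are `NA` (missing, never zero).
#'
#' @param track signal track data.frame (`chrom`, `pos`, `value`); per-bp
#'   tracks (e.g. occupancy) work identically.
#' @param chrom chromosome of the interval.
#' @param start,end 0-based half-open interval bounds.
#' @param strand `"+"` or `"-"`.
#' @param n_bins number of bins; by default must not exceed the interval
#'   length.
#' @param allow_sparse allow `n_bins > length`: bp still map by the floor
#'   rule and bins that receive no bp stay missing. Used for the tiny 5'
#'   exons of exon-intron layouts.
#' @return numeric vector of per-bin means, length `n_bins`.
#' @export
bin_region <- function(track, chrom, start, end, strand = "+", n_bins,
                       allow_sparse = FALSE) {
  len <- end - start
  if (n_bins < 1) stop("n_bins must be >= 1")
  if (len < 1) stop("interval must have length >= 1")
  if (n_bins > len && !allow_sparse) {
    stop("n_bins (", n_bins, ") exceeds interval length (", len, ")")
  }
  sel <- track$chrom == chrom & track$pos >= start & track$pos < end
  out <- rep(NA_real_, n_bins)
  if (!any(sel)) return(out)
  pos <- track$pos[sel]
  offset <- if (strand == "+") pos - start else (end - 1L) - pos
  bin <- floor(as.numeric(offset) * n_bins / len) + 1L
  sums <- rowsum(track$value[sel], bin)
  counts <- rowsum(rep(1, length(bin)), bin)
  out[as.integer(rownames(sums))] <- sums / counts
  out
}

# Per-gene binned vector across a named segment layout. segs is a list of
# lists with fields chrom, start, end, n_bins; all share the gene's strand.
# For minus-strand genes the segment order is already transcription-oriented
# by the caller. Empty segments (start == end) give all-NA bins.
bin_segments <- function(track, segs, strand) {
  unlist(lapply(segs, function(s) {
    if (s$end <= s$start) {
      return(rep(NA_real_, s$n_bins))
    }
    bin_region(track, s$chrom, s$start, s$end, strand, s$n_bins,
               allow_sparse = TRUE)
  }), use.names = FALSE)
}

#' Moving-window smoothing of binned values
#'
#' Interior element `i` becomes the mean of the `window` adjacent elements
#' centred on it; missing bins are excluded from each window mean. Under the
#' default `edge_policy = "keep"`, the first and last `window %/% 2`
#' elements are left unsmoothed; `"shrink"` smooths them with a truncated
#' window instead.
#'
#' @param values numeric vector (may contain `NA`).
#' @param window odd window size (default 5).
#' @param edge_policy `"keep"` or `"shrink"`.
#' @return smoothed vector, same length as the input.
#' @export
smooth_moving_window <- function(values, window = 5,
                                 edge_policy = c("keep", "shrink")) {
  edge_policy <- match.arg(edge_policy)
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  n <- length(values)
  if (window > n) {
    warning("window (", window, ") exceeds length (", n, "); not smoothed")
    return(values)
  }
  half <- window %/% 2
  out <- values
  idx <- if (edge_policy == "keep") {
    seq_len(n)[seq_len(n) > half & seq_len(n) <= n - half]
  } else {
    seq_len(n)
  }
  for (i in idx) {
    w <- values[max(1, i - half):min(n, i + half)]
    m <- mean(w, na.rm = TRUE)
    out[i] <- if (is.nan(m)) NA_real_ else m
  }
  out
}

#' Composite profile container
#'
#' A binned cross-gene average: one mean per bin plus the per-bin count of
#' genes that contributed data, annotated with the segment layout
#' (e.g. 5' intergenic: 20 / ORF: 40 / 3' intergenic: 20 bins).
#'
#' @param values per-bin mean signal (`NA` where no gene had data).
#' @param n_genes per-bin count of contributing genes.
#' @param segments data.frame with columns `segment`, `n_bins`.
#' @param smoothed logical: have the values been moving-window smoothed?
#' @return object of class `composite_profile`.
#' @export
composite_profile <- function(values, n_genes, segments, smoothed = FALSE) {
  stopifnot(length(values) == sum(segments$n_bins),
            length(n_genes) == length(values),
            all(n_genes >= 0))
  structure(
    list(values = values, n_genes = n_genes, segments = segments,
         smoothed = smoothed),
    class = "composite_profile"
  )
}

#' @export
print.composite_profile <- function(x, ...) {
  cat("composite_profile:",
      paste(sprintf("%s(%d)", x$segments$segment, x$segments$n_bins),
            collapse = " | "),
      if (x$smoothed) "[smoothed]" else "[raw]", "\n")
  cat("  bins:", length(x$values),
      " genes (max/bin):", max(x$n_genes), "\n")
  invisible(x)
}

#' Convert a composite profile to a data.frame
#'
#' Bin means are assigned to the middle point of each bin (bin 3 sits at
#' x = 2.5) for plotting.
#'
#' @param x a [composite_profile()].
#' @param ... unused.
#' @return data.frame with `bin`, `midpoint`, `segment`, `value`, `n_genes`.
#' @method as.data.frame composite_profile
#' @export
as.data.frame.composite_profile <- function(x, ...) {
  data.frame(
    bin = seq_along(x$values),
    midpoint = seq_along(x$values) - 0.5,
    segment = rep(x$segments$segment, x$segments$n_bins),
    value = x$values,
    n_genes = x$n_genes,
    stringsAsFactors = FALSE
  )
}

#' Smooth a composite profile
#'
#' Applies [smooth_moving_window()] either across the whole bin axis
#' (`per_segment = FALSE`, the whole-gene convention: the window runs across
#' segment boundaries and only the outermost bins stay unsmoothed) or within
#' each segment independently (`per_segment = TRUE`, the exon-intron
#' convention: the first two and last two bins of every segment stay
#' unsmoothed under the default window of 5).
#'
#' @param profile a [composite_profile()].
#' @param window odd smoothing window (default 5).
#' @param per_segment smooth each segment separately?
#' @param edge_policy passed to [smooth_moving_window()].
#' @return a new [composite_profile()] with `smoothed = TRUE`.
#' @export
smooth_profile <- function(profile, window = 5, per_segment = FALSE,
                           edge_policy = "keep") {
  if (per_segment) {
    ends <- cumsum(profile$segments$n_bins)
    starts <- ends - profile$segments$n_bins + 1L
    vals <- profile$values
    for (k in seq_along(starts)) {
      vals[starts[k]:ends[k]] <-
        smooth_moving_window(profile$values[starts[k]:ends[k]],
                             window, edge_policy)
    }
  } else {
    vals <- smooth_moving_window(profile$values, window, edge_policy)
  }
  composite_profile(vals, profile$n_genes, profile$segments, smoothed = TRUE)
}

# Cross-gene average of a per-gene bin matrix (genes x bins): per-gene means
# are combined with equal gene weight regardless of length or probe count.
aggregate_gene_matrix <- function(mat, segments) {
  values <- colMeans(mat, na.rm = TRUE)
  values[is.nan(values)] <- NA_real_
  n_genes <- colSums(!is.na(mat))
  composite_profile(values, n_genes, segments)
}
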