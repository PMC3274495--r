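#' Per-probe, per-replicate log2(IP/control) ratios
#'
#' @param probes probe table with paired `ip_r` / `c_r` columns
#'   (see [read_probe_table()]).
#' @return numeric matrix, probes x replicates, entry (i, r) =
#'   `log2(ip_ir / c_ir)`.
#' @export
probe_log_ratios <- function(probes) {
  validate_probe_table(probes)
  ip_cols <- grep("^ip_", names(probes), value = TRUE)
  c_cols <- sub("^ip_", "c_", ip_cols)
  m <- log2(as.matrix(probes[, ip_cols, drop = FALSE]) /
              as.matrix(probes[, c_cols, drop = FALSE]))
  colnames(m) <- sub("^ip_", "rep_", ip_cols)
  m
}

#' Quantile normalization across replicate columns
#'
#' Makes the value distribution of every column identical (each column's
#' sorted values become the vector of row means of the column-sorted matrix)
#' while preserving within-column rank order. Tied values within a column
#' receive the mean of the reference values over their tied ranks, which
#' makes the operation invariant to row permutation. On tie-free data the
#' result coincides with [limma::normalizeQuantiles()]; the tie convention
#' differs (limma interpolates the reference at the average tied rank).
#'
#' @param m numeric matrix (probes x replicates), no missing values.
#' @return normalized matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("quantile_normalize: missing values not allowed")
  if (ncol(m) < 2) {
    warning("single column: quantile normalization is a no-op")
    return(m)
  }
  ref <- rowMeans(apply(m, 2, sort))
  cs <- c(0, cumsum(ref))
  out <- apply(m, 2, function(col) {
    lo <- rank(col, ties.method = "min")
    hi <- rank(col, ties.method = "max")
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Average normalized replicate log ratios into a signal track
#'
#' The two-replicate averaged log ratio
#' \deqn{\frac{1}{2}\left[\log_2(IP_{i1}/C_{i1}) + \log_2(IP_{i2}/C_{i2})\right]}
#' generalized to the arithmetic mean over R >= 2 replicates of the
#' already-normalized log-ratio columns.
#'
#' @param m numeric matrix, probes x replicates, of normalized log ratios.
#' @param probes the probe table the rows of `m` came from (supplies
#'   `chrom` and `pos`).
#' @return signal track data.frame (`chrom`, `pos`, `value`).
#' @export
average_replicates <- function(m, probes) {
  stopifnot(nrow(m) == nrow(probes))
  data.frame(chrom = probes$chrom, pos = probes$pos,
             value = rowMeans(m), stringsAsFactors = FALSE)
}

#' Full probe-normalization pipeline
#'
#' Default order of operations: per-replicate log2(IP/control) first, then
#' quantile normalization of the log-ratio columns across replicates, then
#' the replicate mean. `mode = "intensity"` instead quantile-normalizes the
#' log2 IP intensities across replicates and the log2 control intensities
#' across replicates (each channel type separately, so the enrichment
#' contrast between channels is preserved) before forming ratios; both
#' orders are exposed because descriptions of such pipelines are often
#' ambiguous about whether ratios or intensities were normalized.
#'
#' @param probes probe table.
#' @param mode `"log_ratio"` (default) or `"intensity"`.
#' @return signal track data.frame (`chrom`, `pos`, `value`).
#' @export
normalize_probe_table <- function(probes, mode = c("log_ratio", "intensity")) {
  mode <- match.arg(mode)
  if (mode == "log_ratio") {
    m <- quantile_normalize(probe_log_ratios(probes))
  } else {
    validate_probe_table(probes)
    ip_cols <- grep("^ip_", names(probes), value = TRUE)
    c_cols <- sub("^ip_", "c_", ip_cols)
    qn_ip <- quantile_normalize(log2(as.matrix(probes[, ip_cols])))
    qn_c <- quantile_normalize(log2(as.matrix(probes[, c_cols])))
    m <- qn_ip - qn_c
    colnames(m) <- sub("^ip_", "rep_", ip_cols)
  }
  average_replicates(m, probes)
}

#' Express an enrichment ratio relative to a reference region
#'
#' Pairwise-ratio helper for qPCR-style validation data: divides a target
#' IP/Input ratio by the IP/Input ratio of a reference locus (e.g. a
#' non-transcribed control region), or expresses one mark relative to
#' another (e.g. a modification level relative to total histone).
#'
#' @param target numeric vector of target IP/Input ratios.
#' @param reference scalar (or equal-length vector) reference IP/Input ratio.
#' @return `target / reference`.
#' @export
normalize_to_reference <- function(target, reference) {
  if (any(reference <= 0)) stop("reference ratio must be positive")
  target / reference
}
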