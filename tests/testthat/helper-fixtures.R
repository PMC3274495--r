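# Shared fixture builders: everything is generated in code at test time.

# A track with one probe per given position.
make_track <- function(pos, value, chrom = "chrI") {
  data.frame(chrom = chrom, pos = as.integer(pos), value = value,
             stringsAsFactors = FALSE)
}

# A uniform per-bp track over [0, size).
make_flat_track <- function(size, value, chrom = "chrI") {
  make_track(seq_len(size) - 1L, rep(value, size), chrom)
}

# Probe table with given per-replicate (ip, c) intensity pairs.
make_probe_table <- function(pos, ip1, c1, ip2, c2, chrom = "chrI") {
  data.frame(chrom = chrom, pos = as.integer(pos),
             ip_1 = ip1, c_1 = c1, ip_2 = ip2, c_2 = c2,
             stringsAsFactors = FALSE)
}

# Independent quantile-normalization oracle: explicit rank / row-mean
# construction, with column ties receiving the mean reference value over
# their tied ranks.
qn_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(col) {
    lo <- rank(col, ties.method = "min")
    hi <- rank(col, ties.method = "max")
    mapply(function(a, b) mean(ref[a:b]), lo, hi)
  })
}

# Independent bin-assignment oracle: bins are the real-boundary intervals
# [j*L/B, (j+1)*L/B); bp o belongs to bin j+1 iff j*L <= o*B < (j+1)*L,
# found by counting boundary crossings in integer arithmetic.
bin_oracle_assign <- function(offsets, len, n_bins) {
  if (n_bins == 1) return(rep(1L, length(offsets)))
  boundaries <- seq_len(n_bins - 1) * as.numeric(len)
  findInterval(as.numeric(offsets) * n_bins, boundaries) + 1L
}

# Per-bp brute-force binned means for probes in [start, end).
bin_oracle_means <- function(track, chrom, start, end, strand, n_bins) {
  sel <- track$chrom == chrom & track$pos >= start & track$pos < end
  out <- rep(NA_real_, n_bins)
  if (!any(sel)) return(out)
  pos <- track$pos[sel]
  offset <- if (strand == "+") pos - start else (end - 1L) - pos
  bins <- bin_oracle_assign(offset, end - start, n_bins)
  for (b in unique(bins)) out[b] <- mean(track$value[sel][bins == b])
  out
}

# Mirror a genome: reverse all coordinates, flip strands, mirror probes.
mirror_genes <- function(genes, layout) {
  sizes <- layout$chrom_sizes
  m <- genes
  for (i in seq_len(nrow(m))) {
    L <- sizes[[m$chrom[i]]]
    s <- m$start[i]; e <- m$end[i]
    m$start[i] <- L - e
    m$end[i] <- L - s
    ex <- m$exons[[i]]
    m$exons[[i]] <- cbind(start = rev(L - ex[, 2]), end = rev(L - ex[, 1]))
    m$strand[i] <- if (m$strand[i] == "+") "-" else "+"
  }
  class(m) <- class(genes)
  m
}

mirror_track <- function(track, layout) {
  sizes <- layout$chrom_sizes
  out <- track
  out$pos <- sizes[track$chrom] - 1L - track$pos
  out[order(out$chrom, out$pos), , drop = FALSE]
}
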