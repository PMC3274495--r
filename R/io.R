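#' Read gene annotations from GFF3 or BED12
#'
#' Both dialects are parsed with rtracklayer and converted to the internal
#' 0-based half-open convention (GFF3 is 1-based inclusive on disk; BED is
#' already 0-based). BED12 block fields become exons. In GFF3 mode, records
#' of type `gene` define gene bodies and `exon` records are attached through
#' their `Parent` attribute; a gene without exon children is treated as a
#' single-exon gene.
#'
#' @param path annotation file.
#' @param format `"bed12"`, `"gff3"`, or `"auto"` (by file extension).
#' @param rates optional named numeric vector or two-column TSV path
#'   (`gene_id`, `rate`) used to populate the `rate` column.
#' @return a [gene_table()].
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed12", "gff3"),
                                 rates = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) {
      "gff3"
    } else {
      "bed12"
    }
  }
  check_annotation_lines(path, format)
  genes <- if (format == "bed12") read_bed12_genes(path) else read_gff3_genes(path)
  if (!is.null(rates)) {
    if (is.character(rates) && length(rates) == 1) {
      rt <- read_rate_table(rates)
      rates <- stats::setNames(rt$rate, rt$gene_id)
    }
    genes$rate <- unname(rates[genes$gene_id])
  }
  genes
}

# Cheap structural pre-scan so malformed records fail with a line number
# before being handed to rtracklayer.
check_annotation_lines <- function(path, format) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1]])
    ok <- if (format == "gff3") nf == 9 else nf >= 6
    if (!ok) {
      stop("malformed ", format, " record at line ", i, " of ", path)
    }
  }
  invisible(TRUE)
}

read_bed12_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$blocks)) {
    ex <- Map(function(s, e) cbind(start = s, end = e),
              GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
  } else {
    gstart <- GenomicRanges::start(gr) - 1L
    ex <- lapply(seq_along(gr), function(i) {
      b <- gr$blocks[[i]]  # block ranges are relative, 1-based
      cbind(start = gstart[i] + IRanges::start(b) - 1L,
            end = gstart[i] + IRanges::end(b))
    })
  }
  gene_table(
    gene_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    exons = ex
  )
}

read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  is_gene <- gr$type == "gene"
  gg <- gr[is_gene]
  ids <- as.character(gg$ID)
  exrec <- gr[gr$type == "exon"]
  parent <- as.character(S4Vectors::unstrsplit(exrec$Parent, ","))
  ex <- lapply(seq_along(gg), function(i) {
    sel <- parent == ids[i]
    if (!any(sel)) {
      return(cbind(start = GenomicRanges::start(gg)[i] - 1L,
                   end = GenomicRanges::end(gg)[i]))
    }
    cbind(start = GenomicRanges::start(exrec)[sel] - 1L,
          end = GenomicRanges::end(exrec)[sel])
  })
  gene_table(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gg)),
    start = GenomicRanges::start(gg) - 1L,
    end = GenomicRanges::end(gg),
    strand = as.character(GenomicRanges::strand(gg)),
    exons = ex
  )
}

#' Write gene annotations
#'
#' Inverse of [read_gene_annotation()]; round-trips exactly in both formats.
#'
#' @param genes a [gene_table()].
#' @param path output file.
#' @param format `"bed12"` or `"gff3"`.
#' @export
write_gene_annotation <- function(genes, path, format = c("bed12", "gff3")) {
  format <- match.arg(format)
  if (format == "bed12") {
    lines <- vapply(seq_len(nrow(genes)), function(i) {
      ex <- genes$exons[[i]]
      paste(genes$chrom[i], genes$start[i], genes$end[i], genes$gene_id[i],
            0, genes$strand[i], genes$start[i], genes$end[i], 0, nrow(ex),
            paste0(paste(ex[, 2] - ex[, 1], collapse = ","), ","),
            paste0(paste(ex[, 1] - genes$start[i], collapse = ","), ","),
            sep = "\t")
    }, character(1))
    writeLines(lines, path)
  } else {
    lines <- c("##gff-version 3")
    for (i in seq_len(nrow(genes))) {
      id <- genes$gene_id[i]
      lines <- c(lines, paste(
        genes$chrom[i], "chdipmeta", "gene", genes$start[i] + 1L, genes$end[i],
        ".", genes$strand[i], ".", paste0("ID=", id), sep = "\t"))
      ex <- genes$exons[[i]]
      for (j in seq_len(nrow(ex))) {
        lines <- c(lines, paste(
          genes$chrom[i], "chdipmeta", "exon", ex[j, 1] + 1L, ex[j, 2],
          ".", genes$strand[i], ".",
          paste0("ID=", id, ".e", j, ";Parent=", id), sep = "\t"))
      }
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read / write chromosome sizes (two-column TSV: chrom, size)
#' @param path file path.
#' @return named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "size"),
                         colClasses = c("character", "integer"))
  stats::setNames(d$size, d$chrom)
}

#' @rdname read_chrom_sizes
#' @param chrom_sizes named integer vector.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  utils::write.table(
    data.frame(chrom = names(chrom_sizes), size = unname(chrom_sizes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a transcription-rate table (TSV: gene_id, rate)
#' @param path file path.
#' @return data.frame with columns `gene_id`, `rate`.
#' @export
read_rate_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "numeric"))
}

#' @rdname read_rate_table
#' @param rates data.frame with columns `gene_id`, `rate`.
#' @export
write_rate_table <- function(rates, path) {
  utils::write.table(rates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-probe intensity table
#'
#' TSV with header `chrom pos ip_1 c_1 ip_2 c_2 ...` (one `ip_r`/`c_r` pair
#' per replicate). Probes with a missing value in any channel (probes present
#' on only some replicate arrays) are dropped with a message, not imputed.
#'
#' @param path file path.
#' @return data.frame sorted by (chrom, pos); positions unique per chromosome.
#' @export
read_probe_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  validate_probe_table(d, allow_na = TRUE)
  n_na <- sum(!stats::complete.cases(d))
  if (n_na > 0) {
    message("dropping ", n_na, " probe(s) missing in at least one replicate")
    d <- d[stats::complete.cases(d), , drop = FALSE]
  }
  d <- d[order(d$chrom, d$pos), , drop = FALSE]
  rownames(d) <- NULL
  validate_probe_table(d)
  d
}

validate_probe_table <- function(d, allow_na = FALSE) {
  stopifnot(all(c("chrom", "pos") %in% names(d)))
  ip_cols <- grep("^ip_", names(d), value = TRUE)
  c_cols <- sub("^ip_", "c_", ip_cols)
  if (length(ip_cols) == 0 || !all(c_cols %in% names(d))) {
    stop("probe table needs paired ip_r / c_r columns")
  }
  vals <- as.matrix(d[, c(ip_cols, c_cols)])
  if (!allow_na && anyNA(vals)) stop("missing intensities")
  bad <- which(vals <= 0)
  if (length(bad)) {
    row <- (bad[1] - 1) %% nrow(d) + 1
    stop("non-positive intensity at probe ", d$chrom[row], ":", d$pos[row])
  }
  dup <- duplicated(d[, c("chrom", "pos")])
  if (any(dup)) {
    stop("duplicate probe position ", d$chrom[dup][1], ":", d$pos[dup][1])
  }
  invisible(d)
}

#' @rdname read_probe_table
#' @param probes probe table.
#' @export
write_probe_table <- function(probes, path) {
  utils::write.table(probes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a signal track as bedGraph
#'
#' A signal track is a data.frame `(chrom, pos, value)` carrying one
#' normalized, replicate-averaged log2(IP/control) value per probe position.
#' On disk each probe is a 1 bp bedGraph interval `[pos, pos + 1)`.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `pos`, `value`.
#' @export
read_signal_bedgraph <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "value"),
                         colClasses = c("character", "integer", "integer",
                                        "numeric"))
  data.frame(chrom = d$chrom, pos = d$start, value = d$value,
             stringsAsFactors = FALSE)
}

#' @rdname read_signal_bedgraph
#' @param track signal track data.frame.
#' @export
write_signal_bedgraph <- function(track, path) {
  utils::write.table(
    data.frame(track$chrom, track$pos, track$pos + 1L, track$value),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a per-bp nucleosome-occupancy track as bedGraph
#'
#' Occupancy is the percentage of DNA bound to a nucleosome (0-100). Interval
#' records are expanded to one value per bp on read; on write, runs of equal
#' consecutive values are merged back into intervals.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `pos`, `value`, one row per bp.
#' @export
read_occupancy_bedgraph <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "value"),
                         colClasses = c("character", "integer", "integer",
                                        "numeric"))
  if (any(d$value < 0 | d$value > 100)) {
    stop("occupancy values must lie in [0, 100]")
  }
  w <- d$end - d$start
  out <- data.frame(
    chrom = rep(d$chrom, w),
    pos = unlist(Map(function(s, e) seq.int(s, e - 1L), d$start, d$end),
                 use.names = FALSE),
    value = rep(d$value, w),
    stringsAsFactors = FALSE
  )
  out
}

#' @rdname read_occupancy_bedgraph
#' @param occupancy per-bp occupancy data.frame.
#' @export
write_occupancy_bedgraph <- function(occupancy, path) {
  runs <- rle(paste(occupancy$chrom, occupancy$value,
                    occupancy$pos - seq_len(nrow(occupancy))))
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  utils::write.table(
    data.frame(occupancy$chrom[idx_start], occupancy$pos[idx_start],
               occupancy$pos[idx_end] + 1L, occupancy$value[idx_start]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-group list (one gene_id per line)
#' @param path file path.
#' @return character vector of unique ids (order preserved).
#' @export
read_group_list <- function(path) {
  ids <- readLines(path)
  ids <- ids[nzchar(trimws(ids))]
  unique(trimws(ids))
}
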