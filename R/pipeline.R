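#' Default pipeline configuration
#'
#' A pipeline configuration is a plain named list; [pipeline_config()] fills
#' unset keys with defaults. Paths (all optional except `probes`,
#' `annotation`, `chrom_sizes`, `out_dir`): `rates` (transcription-rate TSV),
#' `occupancy` (per-bp bedGraph), `groups` (gene-id list, e.g. RP genes).
#' Options cover the normalization mode, bin layouts, class boundaries, the
#' smoothing window and edge policy, the intergenic cap, the telomere window
#' and the seed recorded in the run manifest.
#'
#' @param ... key = value overrides of the defaults.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    annotation = NULL,
    chrom_sizes = NULL,
    probes = NULL,
    rates = NULL,
    occupancy = NULL,
    groups = NULL,
    out_dir = NULL,
    normalization_mode = "log_ratio",
    layout_metagene = c(20L, 40L, 20L),
    layout_exon_intron = c(10L, 30L, 40L),
    rate_boundaries = c(2, 4, 8, 16),
    n_length_classes = 8L,
    smoothing_window = 5L,
    edge_policy = "keep",
    intergenic_cap = 1000L,
    telomere_width = 20000L,
    seed = 1L
  )
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' Validate a pipeline configuration
#'
#' Collects all violations rather than stopping at the first.
#'
#' @param config a [pipeline_config()] (or plain list).
#' @return character vector of issues; empty means valid.
#' @export
validate_config <- function(config) {
  issues <- character(0)
  need <- function(cond, msg) {
    if (!isTRUE(cond)) issues <<- c(issues, msg)
    invisible(NULL)
  }
  for (key in c("annotation", "chrom_sizes", "probes")) {
    need(!is.null(config[[key]]), paste0("missing required path: ", key))
    if (!is.null(config[[key]])) {
      need(file.exists(config[[key]]),
           paste0(key, " file not found: ", config[[key]]))
    }
  }
  for (key in c("rates", "occupancy", "groups")) {
    if (!is.null(config[[key]])) {
      need(file.exists(config[[key]]),
           paste0(key, " file not found: ", config[[key]]))
    }
  }
  need(!is.null(config$out_dir), "missing out_dir")
  need(config$normalization_mode %in% c("log_ratio", "intensity"),
       "normalization_mode must be 'log_ratio' or 'intensity'")
  need(length(config$layout_metagene) == 3 && all(config$layout_metagene >= 1),
       "layout_metagene must be three positive bin counts")
  need(length(config$layout_exon_intron) == 3 &&
         all(config$layout_exon_intron >= 1),
       "layout_exon_intron must be three positive bin counts")
  need(length(config$rate_boundaries) >= 1 &&
         !is.unsorted(config$rate_boundaries, strictly = TRUE),
       "rate_boundaries must be ascending and non-empty")
  need(config$n_length_classes >= 2, "n_length_classes must be >= 2")
  need(config$smoothing_window >= 1 && config$smoothing_window %% 2 == 1,
       "smoothing_window must be odd and >= 1")
  need(config$edge_policy %in% c("keep", "shrink"),
       "edge_policy must be 'keep' or 'shrink'")
  need(config$intergenic_cap >= 1, "intergenic_cap must be positive")
  need(config$telomere_width >= 1, "telomere_width must be positive")
  issues
}

#' Run the full profiling pipeline
#'
#' Executes normalize -> averaged-gene composite (all genes + stratified by
#' rate and by length) -> region summary -> exon-intron composites (all
#' intron-containing genes, plus group/complement when a group list is
#' given) -> occupancy composites and length-weighted occupancy summary
#' (when an occupancy track is given). Writes every table as TSV with the
#' governing parameters in a comment header, the normalized track as
#' bedGraph, a machine-readable JSON manifest and a log file. Identical
#' config plus inputs produce byte-identical outputs.
#'
#' @param config a [pipeline_config()], plain list, or path to a YAML file.
#' @return (invisibly) list with the computed objects and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  issues <- validate_config(config)
  if (length(issues)) {
    stop("invalid config:\n  ", paste(issues, collapse = "\n  "))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " INFO ", ...)
    writeLines(line, log_con)
    message(...)
  }
  manifest <- list(
    package = "chdipmeta",
    version = as.character(utils::packageVersion("chdipmeta")),
    seed = config$seed,
    inputs = Filter(Negate(is.null),
                    config[c("annotation", "chrom_sizes", "probes", "rates",
                             "occupancy", "groups")]),
    parameters = config[c("normalization_mode", "layout_metagene",
                          "layout_exon_intron", "rate_boundaries",
                          "n_length_classes", "smoothing_window",
                          "edge_policy", "intergenic_cap", "telomere_width")],
    outputs = character(0),
    status = "running"
  )
  write_manifest <- function() {
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  stage <- function(name, expr) {
    logmsg("stage ", name, " started")
    tryCatch(expr, error = function(e) {
      manifest$status <<- paste0("failed at stage ", name)
      write_manifest()
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  emit <- function(obj, name, extra_header = character(0)) {
    path <- file.path(config$out_dir, name)
    header <- c(
      paste0("# chdipmeta ", manifest$version),
      paste0("# seed=", config$seed),
      paste0("# normalization_mode=", config$normalization_mode),
      paste0("# smoothing_window=", config$smoothing_window,
             " edge_policy=", config$edge_policy),
      paste0("# intergenic_cap=", config$intergenic_cap,
             " telomere_width=", config$telomere_width),
      extra_header
    )
    writeLines(header, path)
    suppressWarnings(
      utils::write.table(obj, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, append = TRUE)
    )
    manifest$outputs <<- c(manifest$outputs, name)
    logmsg("wrote ", name)
  }
  profile_table <- function(profile, per_segment = FALSE) {
    d <- as.data.frame(profile)
    sm <- smooth_profile(profile, config$smoothing_window,
                         per_segment = per_segment,
                         edge_policy = config$edge_policy)
    d$smoothed <- sm$values
    d
  }

  # --- load inputs -----------------------------------------------------
  inputs <- stage("load", {
    chrom_sizes <- read_chrom_sizes(config$chrom_sizes)
    genes <- read_gene_annotation(config$annotation, rates = config$rates)
    layout <- genome_layout(chrom_sizes,
                            telomere_width = config$telomere_width)
    probes <- read_probe_table(config$probes)
    list(genes = genes, layout = layout, probes = probes)
  })
  genes <- inputs$genes
  layout <- inputs$layout

  # --- normalize -------------------------------------------------------
  track <- stage("normalize", {
    normalize_probe_table(inputs$probes, mode = config$normalization_mode)
  })
  stage("normalize", {
    write_signal_bedgraph(track, file.path(config$out_dir, "signal.bedgraph"))
    manifest$outputs <- c(manifest$outputs, "signal.bedgraph")
    logmsg("normalized ", nrow(track), " probes")
  })

  # --- metagene --------------------------------------------------------
  results <- list(track = track)
  stage("metagene", {
    intergenic <- derive_intergenic_regions(genes, layout)
    all_prof <- composite_average_gene(
      track, genes, intergenic,
      layout = stats::setNames(config$layout_metagene,
                               c("upstream", "orf", "downstream")),
      intergenic_cap = config$intergenic_cap)
    emit(profile_table(all_prof), "composite_all_genes.tsv",
         paste0("# n_genes=", nrow(genes)))
    results$composite_all <- all_prof
    results$intergenic <- intergenic

    if (!is.null(config$rates)) {
      rate_classes <- classify_by_rate(genes, config$rate_boundaries)
      by_rate <- stratified_profiles(track, genes, rate_classes, intergenic,
                                     intergenic_cap = config$intergenic_cap)
      emit(stratified_table(by_rate, profile_table),
           "composite_by_rate.tsv",
           paste0("# rate_boundaries=",
                  paste(config$rate_boundaries, collapse = ",")))
      results$by_rate <- by_rate
    }
    length_classes <- classify_by_length(genes, config$n_length_classes)
    by_length <- stratified_profiles(track, genes, length_classes, intergenic,
                                     intergenic_cap = config$intergenic_cap)
    emit(stratified_table(by_length, profile_table),
         "composite_by_length.tsv",
         paste0("# n_length_classes=", config$n_length_classes))
    results$by_length <- by_length
  })

  # --- region summary --------------------------------------------------
  stage("region_summary", {
    rs <- suppressWarnings(region_summary(track, genes, layout))
    emit(rs, "region_summary.tsv")
    results$region_summary <- rs
  })

  # --- exon-intron -----------------------------------------------------
  stage("exon_intron", if (sum(n_introns(genes) >= 1) == 0) {
    logmsg("no intron-containing genes; exon-intron stage skipped")
  } else {
    ei_layout <- stats::setNames(config$layout_exon_intron,
                                 c("exon1", "intron", "exon2"))
    ei <- composite_exon_intron(track, genes, layout = ei_layout)
    emit(profile_table(ei, per_segment = TRUE), "exon_intron_all.tsv")
    results$exon_intron_all <- ei
    if (!is.null(config$groups)) {
      split <- gene_group_split(genes, config$groups)
      for (nm in c("group", "complement")) {
        if (nrow(split[[nm]]) == 0) next
        p <- composite_exon_intron(track, split[[nm]], layout = ei_layout)
        emit(profile_table(p, per_segment = TRUE),
             paste0("exon_intron_", nm, ".tsv"),
             paste0("# n_genes=", nrow(split[[nm]])))
        results[[paste0("exon_intron_", nm)]] <- p
      }
    }
    if (!is.null(config$occupancy)) {
      occ <- read_occupancy_bedgraph(config$occupancy)
      occ_prof <- composite_occupancy(occ, genes, layout = ei_layout)
      emit(profile_table(occ_prof, per_segment = TRUE),
           "occupancy_composite.tsv")
      units <- exon_intron_units(genes)
      wo <- data.frame(
        segment = c("exon1", "intron", "exon2"),
        weighted_occupancy = c(
          weighted_occupancy(occ, units, "exon1"),
          weighted_occupancy(occ, units, "intron"),
          weighted_occupancy(occ, units, "exon2")
        ),
        n_genes = length(unique(units$gene_id)),
        stringsAsFactors = FALSE
      )
      emit(wo, "weighted_occupancy.tsv")
      results$occupancy_composite <- occ_prof
      results$weighted_occupancy <- wo
    }
  })

  manifest$status <- "complete"
  write_manifest()
  logmsg("pipeline complete")
  results$manifest <- manifest
  invisible(results)
}

# Long-format table for a named list of composite profiles.
stratified_table <- function(profiles, profile_table_fn) {
  do.call(rbind, lapply(names(profiles), function(cl) {
    d <- profile_table_fn(profiles[[cl]])
    cbind(class = cl, d, stringsAsFactors = FALSE)
  }))
}
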