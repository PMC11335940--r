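#' Pipeline configuration
#'
#' Bundles the simulation settings with the analysis parameters. The
#' analysis defaults are the standard ones for this design: 15-SNP windows
#' advanced by 2 SNPs, SNP MAF filter at 5%, haplotype-allele MAF filter at
#' 0.01, and the genome-wide significance threshold `5e-8`.
#'
#' @param sim A [sim_config()].
#' @param window_size,step Window geometry (defaults 15 and 2).
#' @param snp_maf SNP MAF threshold (default 0.05).
#' @param hap_maf Haplotype-allele MAF threshold (default 0.01).
#' @param alpha Genome-wide significance threshold (default `5e-8`).
#' @param out_dir Output directory for [run_pipeline()] artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), window_size = 15L,
                            step = 2L, snp_maf = 0.05, hap_maf = 0.01,
                            alpha = 5e-8, out_dir = "hapanchor_out") {
  stopifnot(inherits(sim, "sim_config"),
            window_size >= 2L, step >= 1L,
            snp_maf >= 0, snp_maf <= 0.5, hap_maf >= 0, hap_maf <= 0.5,
            alpha > 0, alpha <= 1)
  structure(list(sim = sim, window_size = as.integer(window_size),
                 step = as.integer(step), snp_maf = snp_maf,
                 hap_maf = hap_maf, alpha = alpha, out_dir = out_dir),
            class = "pipeline_config")
}

#' Write a pipeline configuration to a YAML file
#'
#' The flat key/value serialization round-trips losslessly through
#' [read_pipeline_config()].
#'
#' @param config A [pipeline_config()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(config, path) {
  flat <- c(unclass(config$sim)[setdiff(names(config$sim),
                                        c("window_size", "step"))],
            unclass(config)[setdiff(names(config), "sim")])
  yaml::write_yaml(flat, path, precision = 15L)
  invisible(path)
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path File written by [write_pipeline_config()].
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  flat <- yaml::read_yaml(path)
  sim_names <- setdiff(names(formals(sim_config)), c("window_size", "step"))
  sim_args <- flat[intersect(names(flat), sim_names)]
  sim_args$window_size <- flat$window_size
  sim_args$step <- flat$step
  if (is.null(sim_args$causal_window_index) ||
      length(sim_args$causal_window_index) == 0L)
    sim_args$causal_window_index <- NA_integer_
  sim <- do.call(sim_config, sim_args)
  pipeline_config(sim = sim, window_size = flat$window_size,
                  step = flat$step, snp_maf = flat$snp_maf,
                  hap_maf = flat$hap_maf, alpha = flat$alpha,
                  out_dir = flat$out_dir)
}

#' Run the full pipeline: simulate, window, associate, meta-analyze, report
#'
#' Chains the five stages under one configuration and one seed, writing all
#' stage artifacts under `config$out_dir`: haps/sample files and a phased
#' VCF per population, marker and scan TSVs, the anchored meta TSV, and the
#' region outputs (summary TSV, BED, forest TSV). A `manifest.json` records
#' the configuration, its hash, the seed, and per-stage record counts;
#' rerunning an identical configuration yields a byte-identical manifest.
#'
#' @param config A [pipeline_config()].
#' @param panels Optional pre-built list of [phased_panel()]s; when given,
#'   the simulation stage is skipped and these panels are analyzed.
#' @param write_files Write stage artifacts to disk (default `TRUE`); when
#'   `FALSE` only the in-memory results and counts are produced.
#' @return Invisibly, a list: `panels`, `scans`, `meta` (all anchor
#'   candidates), `meta_resolved` (after [resolve_overlaps()]), `regions`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, panels = NULL, write_files = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (write_files) {
    parent <- dirname(config$out_dir)
    if (!dir.exists(parent))
      stop("parent of out_dir does not exist: ", parent)
    dir.create(config$out_dir, showWarnings = FALSE)
  }

  if (is.null(panels)) panels <- simulate_panels(config$sim)
  names(panels) <- vapply(panels, function(p) p$label, character(1))

  scans <- list()
  hms <- list()
  for (p in panels) {
    pf <- filter_snp_maf(p, config$snp_maf)
    hm <- call_markers(pf, hap_maf = config$hap_maf,
                       window_size = config$window_size, step = config$step)
    hms[[p$label]] <- hm
    scans[[p$label]] <- run_population_scan(pf, hm)
  }

  vmap <- unique(do.call(rbind, lapply(panels, function(p)
    p$variants[, c("id", "pos")])))
  am <- anchored_meta(scans, vmap)
  am_res <- resolve_overlaps(am)
  regions <- filter_regions(am, alpha = config$alpha,
                            k_required = length(panels))

  manifest <- list(
    config = yaml::as.yaml(c(unclass(config$sim),
                             unclass(config)[setdiff(names(config),
                                                     c("sim", "out_dir"))]),
                           precision = 15L),
    seed = config$sim$seed,
    counts = list(
      populations = length(panels),
      variants = vapply(panels, function(p) nrow(p$variants), integer(1)),
      markers = vapply(hms, function(h) nrow(h$markers), integer(1)),
      scanned = vapply(scans, nrow, integer(1)),
      skipped = vapply(scans, function(s) sum(s$status != "ok"), integer(1)),
      anchor_candidates = if (is.null(am$anchors)) 0L else nrow(am$anchors),
      anchors_resolved = if (is.null(am_res$anchors)) 0L else
        nrow(am_res$anchors),
      regions = nrow(regions)))
  manifest$config_hash <- config_hash(config)

  if (write_files) {
    for (p in panels) {
      write_haps_sample(p, file.path(config$out_dir, tolower(p$label)))
      write_phased_vcf(p, file.path(config$out_dir,
                                    paste0(tolower(p$label), ".vcf")))
    }
    for (lab in names(scans)) {
      write_scan_tsv(scans[[lab]],
                     file.path(config$out_dir, paste0("scan_", tolower(lab), ".tsv")))
      export_ped(hms[[lab]], panels[[lab]],
                 file.path(config$out_dir, paste0("markers_", tolower(lab))))
    }
    if (!is.null(am_res$anchors))
      utils::write.table(am_res$anchors,
                         file.path(config$out_dir, "anchored_meta.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    write_region_outputs(regions, am, config$out_dir)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(panels = panels, scans = scans, meta = am,
                 meta_resolved = am_res, regions = regions,
                 manifest = manifest))
}

# Stable md5 of the serialized configuration (out_dir excluded: the hash
# captures the scientific settings, not where artifacts land).
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(c(unclass(config$sim),
                             unclass(config)[setdiff(names(config),
                                                     c("sim", "out_dir"))]),
                           precision = 15L),
             tmp)
  unname(tools::md5sum(tmp))
}
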