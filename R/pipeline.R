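# Orchestration: simulate -> genoprob -> (normalize) -> scan -> classify ->
# (compare) -> (enrich) as one configurable, reproducible run.

default_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    stages = list(simulate = TRUE, genoprob = TRUE, normalize = FALSE,
                  scan = TRUE, classify = TRUE, compare = FALSE,
                  enrich = FALSE),
    simulate = list(
      n_individuals = 123L,
      chr_lengths_cM = rep(100, 5),
      marker_spacing_cM = 10,
      mb_per_cM = 2,
      cross_fraction = 0.5, sex_fraction = 0.5, missing_rate = 0,
      genes = list(n_null = 300L, n_cis = 100L, cis_effect = 1.5,
                   n_trans = 0L, trans_effect = 1.5, hotspot = NULL,
                   sd = 1, b_s = 0.5, b_c = 0.25)
    ),
    normalize = list(bg_mean = 100, bg_sd = 10, signal_scale = 60,
                     score_threshold = 0.5, sample_fraction = 0.5,
                     snp_probes = character(0), attenuation = 1),
    genoprob = list(step_cM = 2.5, error_rate = 0.002),
    scan = list(mode = "additive", n_perm = 1000L, fdr = 0.05,
                dominance = TRUE),
    classify = list(window_strict_Mb = 5, window_Mb = 10, bin_cM = 5,
                    hotspot_alpha = 0.001),
    compare = list(other_table = NULL, mode = "tissue", window = 15),
    enrich = list(gmt = NULL, fdr = 0.05)
  )
}

# recursively overlay user values onto the defaults, rejecting unknown keys
merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    if (!(nm %in% names(base))) {
      stopf("unknown configuration key '%s%s'", path, nm)
    }
    if (is.list(base[[nm]]) && is.list(user[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]],
                                 paste0(path, nm, "."))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  if (!is_count(cfg$seed + 1)) stopf("seed must be an integer")
  st <- cfg$stages
  for (nm in names(st)) {
    if (!is.logical(st[[nm]]) || length(st[[nm]]) != 1L) {
      stopf("stage toggle '%s' must be TRUE or FALSE", nm)
    }
  }
  if (any(unlist(st[c("genoprob", "scan")])) && !st$simulate) {
    stopf("genoprob/scan stages need the simulate stage (no external genotype input is configured)")
  }
  if (st$classify && !st$scan) stopf("classify needs the scan stage")
  sim <- cfg$simulate
  if (!is_count(sim$n_individuals)) stopf("n_individuals must be a positive integer")
  if (cfg$scan$n_perm < 10) stopf("scan n_perm must be at least 10")
  if (!(cfg$scan$mode %in% c("additive", "sex_int", "cross_int"))) {
    stopf("scan mode must be additive, sex_int or cross_int")
  }
  invisible(cfg)
}

# build the gene-effect table for the configured scenario
config_genes <- function(gcfg, map, seed) {
  pieces <- list()
  if (gcfg$n_null > 0) {
    pieces$null <- genes_null(gcfg$n_null, map, seed = substream_seed(seed, 11L),
                              sd = gcfg$sd, b_s = gcfg$b_s, b_c = gcfg$b_c)
  }
  if (gcfg$n_cis > 0) {
    pieces$cis <- genes_cis(gcfg$n_cis, map, effect = gcfg$cis_effect * gcfg$sd,
                            seed = substream_seed(seed, 12L),
                            sd = gcfg$sd, b_s = gcfg$b_s, b_c = gcfg$b_c)
  }
  if (gcfg$n_trans > 0) {
    pieces$trans <- genes_trans(gcfg$n_trans, map,
                                effect = gcfg$trans_effect * gcfg$sd,
                                seed = substream_seed(seed, 13L),
                                sd = gcfg$sd, b_s = gcfg$b_s, b_c = gcfg$b_c)
  }
  if (!is.null(gcfg$hotspot)) {
    hs <- gcfg$hotspot
    pieces$hotspot <- hotspot_targets(
      hs$n_targets, map, chr = as.character(hs$chr), cM = hs$cM,
      effect_mean = hs$effect_mean, effect_sd = hs$effect_sd,
      seed = substream_seed(seed, 14L),
      sd = gcfg$sd, b_s = gcfg$b_s, b_c = gcfg$b_c)
  }
  do.call(rbind, unname(pieces))
}

#' Run the full eQTL mapping pipeline
#'
#' Executes the enabled stages in order — simulate, genoprob, normalize,
#' scan, classify, compare, enrich — from a single configuration document,
#' and returns (optionally writes) a machine-readable report.  The run is
#' a pure function of the configuration: re-running with the same config
#' produces identical outputs.
#'
#' @param config A configuration list, or the path to a YAML file.  Any
#'   subset of the default configuration (see the package vignette) may be
#'   given; unknown keys are an error before any computation starts.
#' @return A list of class `"eqtl_report"` with the executed stage list,
#'   per-stage summaries (eQTL counts by class, hotspots, conservation,
#'   enrichment), the full result tables, and a provenance block (seed,
#'   configuration, package version).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(merge_config(default_config(), config))
  seed <- as.integer(cfg$seed)
  cfg_prov <- cfg
  cfg_prov$out_dir <- NULL  # keep reports path-independent
  report <- list(stages = character(0), summary = list(), tables = list(),
                 provenance = list(
                   seed = seed, config = cfg_prov,
                   package = "eqtlcross",
                   version = as.character(utils::packageVersion("eqtlcross"))))

  map <- NULL; cross <- NULL; sim <- NULL; gp <- NULL
  scan <- NULL; records <- NULL; expr <- NULL

  if (cfg$stages$simulate) {
    sm <- cfg$simulate
    map <- sim_map(sm$chr_lengths_cM, sm$marker_spacing_cM, sm$mb_per_cM)
    genes <- config_genes(sm$genes, map, seed)
    arch <- sim_architecture(sm$n_individuals, genes,
                             cross_fraction = sm$cross_fraction,
                             sex_fraction = sm$sex_fraction,
                             missing_rate = sm$missing_rate,
                             seed = substream_seed(seed, 1L))
    cross <- sim_f2_cross(map, arch)
    sim <- sim_expression(cross, map, arch)
    expr <- sim$expr
    report$stages <- c(report$stages, "simulate")
    report$summary$simulate <- list(
      n_individuals = nrow(cross$geno), n_markers = ncol(cross$geno),
      n_genes = nrow(expr), n_true_eqtl = sum(!sim$truth$is_null))
    report$tables$truth <- sim$truth
    report$tables$annot <- sim$annot
  }

  if (cfg$stages$normalize && !is.null(expr)) {
    nc <- cfg$normalize
    if (nc$attenuation < 1 && length(nc$snp_probes)) {
      expr <- inject_probe_artifacts(expr, cross, map, sim$annot,
                                     nc$snp_probes, nc$attenuation)
    }
    rawres <- sim_raw_intensities(expr, nc$bg_mean, nc$bg_sd, nc$signal_scale,
                                  seed = substream_seed(seed, 2L))
    expr <- preprocess_intensities(rawres$raw, rawres$detection,
                                   exclude = nc$snp_probes,
                                   score_threshold = nc$score_threshold,
                                   sample_fraction = nc$sample_fraction)
    report$stages <- c(report$stages, "normalize")
    report$summary$normalize <- list(n_probes_kept = nrow(expr))
  }

  if (cfg$stages$genoprob) {
    gp <- calc_genoprob(cross, step_cM = cfg$genoprob$step_cM,
                        error_rate = cfg$genoprob$error_rate)
    report$stages <- c(report$stages, "genoprob")
    report$summary$genoprob <- list(n_grid_loci = nrow(gp$grid),
                                    step_cM = cfg$genoprob$step_cM)
  }

  if (cfg$stages$scan) {
    covar <- cross_covariates(cross)
    scan <- scan_transcripts(expr, gp, covar, mode = cfg$scan$mode,
                             n_perm = cfg$scan$n_perm,
                             seed = substream_seed(seed, 3L),
                             dominance = cfg$scan$dominance)
    records <- declare_eqtls(scan, fdr = cfg$scan$fdr)
    report$stages <- c(report$stages, "scan")
    report$summary$scan <- list(
      n_transcripts = nrow(scan$table),
      n_declared = length(unique(records$gene)),
      n_records = nrow(records))
    report$tables$scan <- scan$table
    report$tables$eqtls <- records
  }

  if (cfg$stages$classify && !is.null(records)) {
    cc <- cfg$classify
    records <- classify_eqtls(records, sim$annot, cc$window_strict_Mb,
                              cc$window_Mb)
    hot <- detect_hotspots(records, map, bin_cM = cc$bin_cM,
                           alpha = cc$hotspot_alpha)
    poly <- polygenic_genes(records)
    dirs <- direction_summary(records)
    report$stages <- c(report$stages, "classify")
    report$summary$classify <- list(
      class_counts = as.list(table(records$class)),
      n_hotspots = nrow(hot), polygenic_genes = poly,
      frac_gk_down = dirs$frac_gk_down)
    report$tables$eqtls <- records
    report$tables$hotspots <- hot
  }

  if (cfg$stages$compare && !is.null(records)) {
    other <- cfg$compare$other_table
    if (is.character(other)) other <- read_tsv_file(other)
    pairs <- if (cfg$compare$mode == "tissue") {
      conserved_crosstissue(records, other, window_cM = cfg$compare$window)
    } else {
      conserved_crossmodel(records, other, window_Mb = cfg$compare$window)
    }
    report$stages <- c(report$stages, "compare")
    report$summary$compare <- list(n_conserved = nrow(pairs))
    report$tables$conserved <- pairs
  }

  if (cfg$stages$enrich && !is.null(records)) {
    sets <- cfg$enrich$gmt
    if (is.character(sets)) sets <- read_gmt(sets)
    background <- unique(rownames(expr))
    query <- intersect(unique(records$gene), background)
    enr <- hypergeom_enrich(query, sets, background)
    report$stages <- c(report$stages, "enrich")
    report$summary$enrich <- list(
      n_sets_tested = nrow(enr),
      n_significant = sum(enr$q < cfg$enrich$fdr))
    report$tables$enrichment <- enr
  }

  class(report) <- "eqtl_report"
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' Write a pipeline report bundle
#'
#' Writes `report.json` (stage list, summaries, provenance; stable field
#' ordering) plus one TSV per result table into `out_dir`.
#'
#' @param report An `"eqtl_report"` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(schema = "eqtlcross-report/1",
               stages = report$stages,
               summary = report$summary,
               provenance = report$provenance)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  for (nm in names(report$tables)) {
    write_tsv_file(report$tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  invisible(out_dir)
}

#' @export
print.eqtl_report <- function(x, ...) {
  cat("eQTL pipeline report\n")
  cat("  stages run:", if (length(x$stages)) paste(x$stages, collapse = ", ")
      else "(none)", "\n")
  if (!is.null(x$summary$scan)) {
    cat(sprintf("  declared eQTL genes: %d (%d records)\n",
                x$summary$scan$n_declared, x$summary$scan$n_records))
  }
  if (!is.null(x$summary$classify)) {
    cc <- x$summary$classify$class_counts
    cat("  classes:", paste(sprintf("%s=%s", names(cc), unlist(cc)),
                            collapse = ", "), "\n")
    cat(sprintf("  hotspots: %d\n", x$summary$classify$n_hotspots))
  }
  invisible(x)
}
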