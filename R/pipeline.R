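#' Run the whole pipeline end to end on a simulated experiment
#'
#' Composes every stage in analysis order — simulate and sequence the
#' fermentation, optionally downsample to a fixed depth, quantify MSPs per
#' catalogue, merge, normalize, assign niches, and build the invasion
#' report — writing every stage output plus a run manifest into `out_dir`.
#' All randomness flows from the config's root seed, so two runs with the
#' same config produce byte-identical data files (the manifest, which
#' records wall times, is the one file that legitimately differs).
#'
#' @param config An [sim_config()], a plain list of `sim_config()`
#'   arguments, or the path of a YAML file of them. The extra keys
#'   `downsample_depth` (rarefaction depth; omit to skip) and
#'   `min_marker_fraction` are read from the same list/file.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with `manifest` (also written as
#'   `manifest.json`), the `report` ([invasion_report()]) and the `paths`
#'   of all written files. Configuration errors abort before any stage
#'   runs.
#' @export
run_e2e <- function(config = sim_config(), out_dir) {
  opts <- list(downsample_depth = NULL, min_marker_fraction = 0.10)
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  if (!inherits(config, "oralgut_sim_config")) {
    stopifnot(is.list(config))
    for (k in names(opts)) {
      if (!is.null(config[[k]])) {
        opts[[k]] <- config[[k]]
        config[[k]] <- NULL
      }
    }
    config <- do.call(sim_config, config)
  }
  validate_sim_config(config) # validation-first: fail before any compute
  if (!is.null(opts$downsample_depth) &&
        opts$downsample_depth > config$sequencing_depth) {
    abort_config("`downsample_depth` exceeds the sequencing depth.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  paths <- list()
  timings <- list()
  warnings <- character(0)
  emit <- function(name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    paths[[name]] <<- p
    p
  }
  timed <- function(stage, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      force(code),
      warning = function(w) {
        warnings <<- c(warnings, paste0(stage, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  write_manifest <- function(status, error = NULL) {
    digests <- lapply(paths, function(p) unname(tools::md5sum(p)))
    manifest <- list(
      tool = "oralgut",
      version = as.character(utils::packageVersion("oralgut")),
      seed = config$seed,
      config = unclass(config),
      options = opts,
      outputs = digests,
      stage_seconds = timings,
      warnings = warnings,
      status = status
    )
    if (!is.null(error)) manifest$error <- error
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
    manifest
  }

  result <- tryCatch({
    exp <- timed("simulate", simulate_experiment(config))
    emit("config.yaml", function(p) {
      yaml::write_yaml(c(unclass(config), opts), p)
    })
    emit("catalogue.tsv", function(p) write_catalogue(exp$catalogue, p))
    emit("overlaps.tsv", function(p) readr::write_tsv(exp$catalogue$overlaps, p))
    emit("sample_meta.tsv", function(p) readr::write_tsv(exp$meta, p))
    emit("gene_counts.tsv", function(p) write_gene_table(exp$genes, p))
    emit("ground_truth.json", function(p) {
      jsonlite::write_json(
        list(
          niche = exp$truth$niche,
          planted_invaders = exp$truth$planted_invaders,
          planted_oral = exp$truth$planted_oral,
          stool = as.list(exp$truth$stool),
          saliva = as.list(exp$truth$saliva),
          enriched = lapply(exp$truth$enriched, as.list),
          trajectory = exp$truth$trajectory
        ),
        p, auto_unbox = TRUE, digits = NA
      )
    })

    genes <- exp$genes
    if (!is.null(opts$downsample_depth)) {
      genes <- timed("downsample", downsample_genes(
        genes, opts$downsample_depth,
        seed = stream_seed(config$seed, "downsample")
      ))
    }
    quant <- timed("quantify", quantify_msp(
      genes, exp$catalogue, min_marker_fraction = opts$min_marker_fraction
    ))
    emit("msp_gut.tsv", function(p) write_msp_table(quant$gut, p))
    emit("msp_oral.tsv", function(p) write_msp_table(quant$oral, p))
    merged <- timed("merge", merge_msp_tables(
      quant$gut, quant$oral, exp$catalogue$overlaps
    ))
    emit("msp_merged.tsv", function(p) write_msp_table(merged, p))
    merged_norm <- timed("normalize", normalize_msp(merged))
    emit("msp_merged_norm.tsv", function(p) write_msp_table(merged_norm, p))
    emit("richness.tsv", function(p) readr::write_tsv(msp_richness(merged), p))
    emit("mapping_rates.tsv", function(p) {
      readr::write_tsv(mapping_rate(genes, exp$catalogue), p)
    })

    report <- timed("invasion", invasion_report(
      merged_norm, exp$meta,
      first_injection_day = min(c(config$injection_days, Inf))
    ))
    emit("niches.tsv", function(p) readr::write_tsv(report$niches, p))
    emit("niche_series.tsv", function(p) readr::write_tsv(report$series, p))
    emit("invader_matrix.tsv", function(p) {
      wide <- report$invader_matrix
      if (nrow(wide) > 0) {
        wide <- tidyr::pivot_wider(
          wide[, c("donor", "msp_id", "pre_existing", "sample_id", "abundance")],
          names_from = "sample_id", values_from = "abundance", values_fill = 0
        )
      }
      readr::write_tsv(wide, p)
    })
    emit("invader_summary.tsv", function(p) {
      readr::write_tsv(report$invader_summary, p)
    })
    emit("bray_curtis.tsv", function(p) {
      readr::write_tsv(bray_curtis_matrix(merged_norm), p)
    })
    emit("correlations.tsv", function(p) {
      readr::write_tsv(report$correlations, p)
    })

    manifest <- write_manifest(status = 0)
    list(manifest = manifest, report = report, paths = paths,
         merged = merged_norm, experiment = exp)
  }, error = function(e) {
    write_manifest(status = 1, error = conditionMessage(e))
    abort_runtime(paste0("Pipeline failed: ", conditionMessage(e)),
                  parent = e)
  })
  invisible(result)
}
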