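#' Write run results to disk
#'
#' For each scenario result: the probe time series as CSV (full double
#' precision), the per-cycle metrics as JSON and a metadata JSON naming the
#' configuration hash, package version, seed and transient handling. When
#' several scenarios including the healthy-walking baseline are written
#' together, a comparison report (Markdown and CSV) is added.
#'
#' @param results a [run_scenario()] result or a named list of them.
#' @param out_dir output directory (created if missing).
#' @param seed integer recorded in the metadata.
#' @return character vector of the written paths, invisibly.
#' @export
write_results <- function(results, out_dir, seed = 1L) {
  if (inherits(results, "scenario_result")) {
    results <- stats::setNames(list(results), results$scenario)
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(errorCondition(paste0("cannot create directory: ", out_dir),
                                 class = c("venapump_io_error", "venapump_error")))
  }
  paths <- character(0)
  for (nm in names(results)) {
    r <- results[[nm]]
    cfg_file <- tempfile(fileext = ".yaml")
    write_config(r$config, cfg_file)
    digest <- unname(tools::md5sum(cfg_file))
    unlink(cfg_file)

    p_csv <- file.path(out_dir, paste0(nm, "_series.csv"))
    ser <- r$run$series
    ser[] <- lapply(ser, function(col) {
      if (is.numeric(col)) signif(col, 12) else col
    })
    utils::write.csv(format(ser, digits = 12, scientific = FALSE,
                            trim = TRUE),
                     p_csv, row.names = FALSE, quote = FALSE)

    metrics <- list(
      scenario = nm,
      knee = list(net_volume_ml = r$knee$net_volume_ml,
                  antegrade_volume_ml = r$knee$antegrade_volume_ml,
                  retrograde_volume_ml = r$knee$retrograde_volume_ml,
                  cycles_averaged = r$knee$cycles_averaged),
      ankle = list(net_volume_ml = r$ankle$net_volume_ml,
                   antegrade_volume_ml = r$ankle$antegrade_volume_ml,
                   retrograde_volume_ml = r$ankle$retrograde_volume_ml,
                   cycles_averaged = r$ankle$cycles_averaged),
      ejection_fraction_pct = r$ejection_fraction_pct)
    p_json <- file.path(out_dir, paste0(nm, "_metrics.json"))
    jsonlite::write_json(metrics, p_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)

    meta <- list(scenario = nm, config_md5 = digest,
                 package_version = as.character(utils::packageVersion("venapump")),
                 seed = seed, dt_s = r$run$dt_s, dx_cm = r$run$disc$dx_cm,
                 scheme = r$run$scheme,
                 cycles_total = r$run$n_cycles,
                 cycles_discarded = r$knee$cycles_discarded)
    p_meta <- file.path(out_dir, paste0(nm, "_meta.json"))
    jsonlite::write_json(meta, p_meta, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, p_csv, p_json, p_meta)
  }

  if (length(results) > 1 && "walking_healthy" %in% names(results)) {
    cmp <- compare_scenarios(results)
    p_cmp_csv <- file.path(out_dir, "comparison.csv")
    utils::write.csv(cmp$table, p_cmp_csv, row.names = FALSE)
    p_cmp_md <- file.path(out_dir, "comparison.md")
    lines <- c("# Scenario comparison (knee probe, heart-ward positive)", "",
               "| scenario | net (mL/cycle) | retrograde (mL/cycle) | reduction vs healthy |",
               "|---|---|---|---|")
    for (i in seq_len(nrow(cmp$table))) {
      lines <- c(lines, sprintf("| %s | %.4g | %.4g | %d%% |",
                                cmp$table$scenario[i],
                                cmp$table$net_volume_ml[i],
                                cmp$table$retrograde_volume_ml[i],
                                round(cmp$table$reduction_vs_healthy_pct[i])))
    }
    if (is.finite(cmp$pump_gain)) {
      lines <- c(lines, "",
                 sprintf("Calf-pump gain over orthostatism: %.2f x", cmp$pump_gain))
    }
    writeLines(lines, p_cmp_md)
    paths <- c(paths, p_cmp_csv, p_cmp_md)
  }
  invisible(paths)
}
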