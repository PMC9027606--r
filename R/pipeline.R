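# Orchestration: samples + standards + config -> capacity tables, warning
# tables, rasters, manifest and report.

stage_stop <- function(stage, e) {
  stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
}

pipeline_log <- function(level, ...) {
  message(sprintf("%s %-5s %s", format(Sys.time(), "%H:%M:%S"), level,
                  paste0(...)))
}

#' Run the full capacity / warning / mapping pipeline
#'
#' Executes every stage in order — read standards and samples, compute the
#' per-unit capacity table, score and classify each unit, optionally
#' rasterize residual capacities by IDW — and writes `capacity.csv`,
#' `warning.csv`, `capacity_units.json` (column units), one `.asc` raster
#' per requested element, `manifest.json` and a human-readable
#' `report.md` into `out_dir`. Any stage failure aborts with a
#' stage-tagged message and removes partial outputs. Two runs on the same
#' inputs produce byte-identical tables.
#'
#' Config fields used beyond [model_config()]: `standards` (path or
#' `"builtin"`), `samples` (path to a sample CSV; required), `out_dir`,
#' `aggregation` (`"city"` or `"sample"`), `elements` (optional subset),
#' `rasters` (elements whose residual capacity is mapped; needs `grid`),
#' `norm_bounds` (optional path to a manifest JSON whose normalization
#' bounds are reused).
#'
#' @param config A `soilcap_config` (see [load_config()]) or the path to
#'   a YAML config file.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return The output directory path, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "soilcap_config"))
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("[config] no output directory given",
                             call. = FALSE)

  staging <- tempfile("soilcap-run-")
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)

  # -- inputs ---------------------------------------------------------
  pipeline_log("INFO", "stage standards: loading")
  standards <- tryCatch(
    load_standards(config$standards %||% "builtin"),
    error = function(e) stage_stop("standards", e))

  pipeline_log("INFO", "stage samples: loading")
  if (is.null(config$samples)) {
    stop("[samples] config field 'samples' is required", call. = FALSE)
  }
  samples <- tryCatch(load_samples(config$samples, standards),
                      error = function(e) stage_stop("samples", e))
  elements <- config$elements %||%
    setdiff(names(samples), c("sample_id", "x", "y", "unit"))
  samples <- samples[c("sample_id", "x", "y", "unit", elements)]

  # -- capacity -------------------------------------------------------
  aggregation <- config$aggregation %||% "city"
  pipeline_log("INFO", "stage capacity: ", aggregation, " aggregation, ",
               length(elements), " elements")
  cap <- tryCatch(
    capacity_table(samples, standards, config, aggregation = aggregation),
    error = function(e) stage_stop("capacity", e))
  write.csv_det(cap, file.path(staging, "capacity.csv"))
  qn_cols <- grep("^Qn_", names(cap), value = TRUE)
  units_doc <- c(list(Qs = "kg/hm^2", Qi = "kg/hm^2", Cio = "mg/kg"),
                 stats::setNames(as.list(rep("kg/(hm^2 a)",
                                             length(qn_cols))), qn_cols))
  jsonlite::write_json(units_doc, file.path(staging, "capacity_units.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  # -- warning --------------------------------------------------------
  pipeline_log("INFO", "stage warning: scoring units")
  bounds <- NULL
  if (!is.null(config$norm_bounds)) {
    prev <- tryCatch(jsonlite::read_json(config$norm_bounds,
                                         simplifyVector = TRUE),
                     error = function(e) stage_stop("warning", e))
    bounds <- lapply(prev$norm_bounds, as.numeric)
  }
  unit_cap <- if (aggregation == "city") cap else
    tryCatch(capacity_table(samples, standards, config, "city"),
             error = function(e) stage_stop("warning", e))
  warn <- tryCatch(warn_units(unit_cap, elements = elements,
                              bounds = bounds),
                   error = function(e) stage_stop("warning", e))
  write.csv_det(warn, file.path(staging, "warning.csv"))

  # -- rasters --------------------------------------------------------
  raster_files <- character(0)
  if (length(config$rasters %||% character(0)) > 0) {
    if (is.null(config$grid)) {
      stop("[map] rasters requested but no grid configured", call. = FALSE)
    }
    per_sample <- tryCatch(
      capacity_table(samples, standards, config, "sample"),
      error = function(e) stage_stop("map", e))
    for (el in config$rasters) {
      pipeline_log("INFO", "stage map: rasterizing residual ", el)
      sub <- per_sample[per_sample$element == el, ]
      pts <- merge(sub, samples[c("sample_id", "x", "y")], by = "sample_id")
      g <- tryCatch(
        rasterize_idw(pts, "Qi", config$grid,
                      power = config$idw_power, k = config$idw_neighbors),
        error = function(e) stage_stop("map", e))
      f <- paste0("residual_", el, ".asc")
      write_esri_ascii(g, file.path(staging, f))
      raster_files <- c(raster_files, f)
    }
  }

  # -- manifest and report -------------------------------------------
  pipeline_log("INFO", "stage report: writing manifest and summary")
  manifest <- list(
    package = "soilcap",
    version = as.character(utils::packageVersion("soilcap")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config[c("M", "K", "baseline_year", "horizons", "idw_power",
                      "idw_neighbors", "grid")],
    aggregation = aggregation,
    elements = elements,
    inputs = list(
      standards = config$standards %||% "builtin",
      samples = config$samples,
      digests = as.list(tools::md5sum(config$samples))
    ),
    norm_bounds = attr(warn, "norm_bounds"),
    outputs = c("capacity.csv", "warning.csv", "capacity_units.json",
                raster_files)
  )
  # digits = I(17): normalization bounds must survive the JSON round trip
  # bit-exactly so that reruns reusing them are byte-identical
  jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = I(17))
  writeLines(render_report(unit_cap, warn, config),
             file.path(staging, "report.md"))

  # -- commit ---------------------------------------------------------
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (f in list.files(staging)) {
    file.copy(file.path(staging, f), file.path(out_dir, f),
              overwrite = TRUE)
  }
  pipeline_log("INFO", "pipeline complete: ", out_dir)
  invisible(out_dir)
}

# deterministic CSV writer: fixed field order, no row names, full precision
write.csv_det <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

render_report <- function(cap, warn, config) {
  qn_cols <- grep("^Qn_", names(cap), value = TRUE)
  lines <- c(
    "# Soil heavy-metal environmental capacity report",
    "",
    sprintf("Baseline year %d; horizons %s years; M = %g kg/hm^2; K = %s.",
            config$baseline_year,
            paste(config$horizons, collapse = ", "),
            config$M, paste(config$K, collapse = ", ")),
    "",
    "## Per-unit comprehensive warning",
    "",
    "| Unit | Pave | Pmin | P | Grade | Capacity | Health risk |",
    "|---|---|---|---|---|---|---|",
    sprintf("| %s | %.3f | %.3f | %.3f | %s | %s | %s |",
            warn$unit, warn$Pave, warn$Pmin, warn$P, warn$grade,
            warn$capacity_label, warn$risk_label),
    "",
    "## Lowest residual capacity per unit",
    ""
  )
  for (u in unique(cap$unit)) {
    sub <- cap[cap$unit == u, ]
    worst <- sub[which.min(sub$Qi), ]
    horiz <- paste(sprintf("%s = %.2f", qn_cols,
                           as.numeric(worst[1, qn_cols])), collapse = ", ")
    lines <- c(lines, sprintf(
      "- %s: worst element %s (Qi = %.2f kg/hm^2; annual %s kg/(hm^2 a))",
      u, worst$element, worst$Qi, horiz))
  }
  lines
}

`%||%` <- function(a, b) if (is.null(a)) b else a
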