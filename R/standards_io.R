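# Data model and readers for element standards, soil samples, grade tables
# and run configuration.

#' Heavy-metal element codes handled by the package
#'
#' The eight elements for which regional background values and agricultural
#' risk screening values are tabulated: arsenic, lead, zinc, chromium,
#' mercury, copper, nickel and cadmium.
#'
#' @return Character vector of element codes.
#' @export
soilcap_elements <- function() {
  c("As", "Pb", "Zn", "Cr", "Hg", "Cu", "Ni", "Cd")
}

#' Load an element standards table
#'
#' A standards table holds, per element, the regional soil background
#' concentration (`background`, mg/kg) and the risk reference value
#' (`reference`, mg/kg) above which pollution risk to agricultural produce
#' is presumed. The built-in table carries the Pearl River Basin regional
#' background values (DB44/T 1415-2014) and the pH < 6.5 agricultural risk
#' screening values (GB 15618).
#'
#' @param path Path to a CSV with columns `element,background,reference`,
#'   or `"builtin"` for the shipped Pearl River Basin table.
#' @return A data.frame with columns `element`, `background`, `reference`.
#' @examples
#' std <- load_standards("builtin")
#' std[std$element == "Cd", ]
#' @export
load_standards <- function(path = "builtin") {
  if (identical(path, "builtin")) {
    path <- system.file("extdata", "standards.csv", package = "soilcap",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) {
    stop("standards file not found: ", path, call. = FALSE)
  }
  std <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_standards(std)
  std
}

validate_standards <- function(std) {
  required <- c("element", "background", "reference")
  missing <- setdiff(required, names(std))
  if (length(missing) > 0) {
    stop("standards table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dup <- unique(std$element[duplicated(std$element)])
  if (length(dup) > 0) {
    stop("duplicate element(s) in standards table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(std$background) || !is.numeric(std$reference)) {
    stop("background and reference columns must be numeric", call. = FALSE)
  }
  if (any(!is.finite(std$background)) || any(!is.finite(std$reference))) {
    stop("standards table contains non-finite values", call. = FALSE)
  }
  if (any(std$background < 0)) {
    stop("background values must be >= 0", call. = FALSE)
  }
  if (any(std$reference <= 0)) {
    stop("reference values must be > 0", call. = FALSE)
  }
  invisible(std)
}

#' Load a soil-sample table
#'
#' A sample table has one row per georeferenced composite sample: an id,
#' planar `x`/`y` coordinates in meters, the administrative `unit` (city)
#' the sample belongs to, and one measured concentration column (mg/kg)
#' per element. Element columns must be a subset of the standards table's
#' elements; negative or missing concentrations are rejected.
#'
#' @param path Path to a CSV with columns `sample_id,x,y,unit` plus element
#'   columns.
#' @param standards A standards table (see [load_standards()]) used to
#'   validate the element columns.
#' @return A data.frame with the same columns, validated.
#' @export
load_samples <- function(path, standards = load_standards("builtin")) {
  if (!file.exists(path)) {
    stop("samples file not found: ", path, call. = FALSE)
  }
  smp <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_samples(smp, standards)
}

validate_samples <- function(smp, standards) {
  required <- c("sample_id", "x", "y", "unit")
  missing <- setdiff(required, names(smp))
  if (length(missing) > 0) {
    stop("samples table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  elems <- setdiff(names(smp), required)
  unknown <- setdiff(elems, standards$element)
  if (length(unknown) > 0) {
    stop("unknown element column(s) not in standards: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(elems) == 0) {
    stop("samples table has no element columns", call. = FALSE)
  }
  if (!is.numeric(smp$x) || !is.numeric(smp$y) ||
      any(!is.finite(smp$x)) || any(!is.finite(smp$y))) {
    stop("sample coordinates must be finite numbers", call. = FALSE)
  }
  for (el in elems) {
    col <- smp[[el]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      stop("non-numeric concentration in column ", el, ", row ", bad,
           call. = FALSE)
    }
    if (anyNA(col)) {
      stop("missing concentration in column ", el, ", row ",
           which(is.na(col))[1], call. = FALSE)
    }
    if (any(col < 0)) {
      stop("negative concentration in column ", el, ", row ",
           which(col < 0)[1], call. = FALSE)
    }
  }
  smp
}

#' Five-grade capacity / health-risk classification table
#'
#' Grades the comprehensive index P on \[0, 1): grade I (overload capacity,
#' extreme risk) for P below 0.2 up to grade V (high capacity, no risk) for
#' P of 0.8 and above. Bins are lower-inclusive, upper-exclusive; P = 1 is
#' closed into grade V.
#'
#' @return A data.frame with columns `grade` (Roman numeral), `lower`,
#'   `upper`, `capacity_label`, `risk_label`.
#' @export
builtin_grade_table <- function() {
  data.frame(
    grade = c("I", "II", "III", "IV", "V"),
    lower = c(0, 0.2, 0.4, 0.6, 0.8),
    upper = c(0.2, 0.4, 0.6, 0.8, 1),
    capacity_label = c("Overload capacity", "Alert capacity", "Low capacity",
                       "Medium capacity", "High capacity"),
    risk_label = c("Extreme risk", "Severe risk", "Moderate risk",
                   "Mild risk", "No risk"),
    stringsAsFactors = FALSE
  )
}

validate_grade_table <- function(bins) {
  stopifnot(is.data.frame(bins),
            all(c("grade", "lower", "upper",
                  "capacity_label", "risk_label") %in% names(bins)))
  o <- order(bins$lower)
  bins <- bins[o, , drop = FALSE]
  if (bins$lower[1] != 0 || bins$upper[nrow(bins)] != 1) {
    stop("grade bins must span [0, 1)", call. = FALSE)
  }
  if (nrow(bins) > 1 &&
      any(abs(bins$upper[-nrow(bins)] - bins$lower[-1]) > 1e-12)) {
    stop("grade bins must partition [0, 1) without gaps or overlaps",
         call. = FALSE)
  }
  bins
}

#' Build a model configuration
#'
#' Bundles the physical and numerical parameters of a capacity run:
#' plough-layer soil mass `M` (kg/hm^2, default 2.25e6 for the 0-20 cm
#' layer), annual residual rate `K` (fraction of an element's soil content
#' retained from one year to the next, default 0.9), the baseline year and
#' prediction horizons (years after baseline), IDW interpolation settings
#' and an optional grid specification.
#'
#' @param M Plough-layer mass per hectare, kg/hm^2.
#' @param K Residual rate in (0, 1); scalar, or a named vector by element.
#' @param baseline_year Integer year the status concentrations refer to.
#' @param horizons Integer vector of prediction horizons, in years.
#' @param idw_power Positive IDW distance-decay exponent.
#' @param idw_neighbors Number of nearest samples used per prediction, or
#'   `"all"`.
#' @param grid Optional list with `origin_x`, `origin_y`, `cell_size`,
#'   `n_rows`, `n_cols` describing the interpolation raster.
#' @param seed Integer seed for any stochastic step.
#' @return A list of class `soilcap_config`.
#' @export
model_config <- function(M = 2.25e6, K = 0.9, baseline_year = 2014,
                         horizons = c(14, 24), idw_power = 2,
                         idw_neighbors = 12, grid = NULL, seed = 1L) {
  if (!is.numeric(M) || length(M) != 1 || !is.finite(M) || M <= 0) {
    stop("M must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(K) || any(!is.finite(K)) || any(K <= 0) || any(K >= 1)) {
    stop("K must lie strictly between 0 and 1", call. = FALSE)
  }
  horizons <- as.integer(horizons)
  if (length(horizons) == 0 || any(horizons < 1)) {
    stop("every horizon must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(idw_power) || idw_power <= 0) {
    stop("idw_power must be > 0", call. = FALSE)
  }
  if (!identical(idw_neighbors, "all")) {
    idw_neighbors <- as.integer(idw_neighbors)
    if (is.na(idw_neighbors) || idw_neighbors < 1) {
      stop("idw_neighbors must be a positive integer or \"all\"",
           call. = FALSE)
    }
  }
  if (!is.null(grid)) grid <- validate_grid_spec(grid)
  structure(
    list(M = M, K = K, baseline_year = as.integer(baseline_year),
         horizons = horizons, idw_power = idw_power,
         idw_neighbors = idw_neighbors, grid = grid, seed = as.integer(seed)),
    class = "soilcap_config"
  )
}

validate_grid_spec <- function(grid) {
  required <- c("origin_x", "origin_y", "cell_size", "n_rows", "n_cols")
  missing <- setdiff(required, names(grid))
  if (length(missing) > 0) {
    stop("grid spec is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (grid$cell_size <= 0) stop("grid cell_size must be > 0", call. = FALSE)
  grid$n_rows <- as.integer(grid$n_rows)
  grid$n_cols <- as.integer(grid$n_cols)
  if (grid$n_rows < 1 || grid$n_cols < 1) {
    stop("grid dimensions must be positive", call. = FALSE)
  }
  grid[required]
}

#' Read a run configuration from YAML
#'
#' Reads a YAML file mirroring the fields of [model_config()], plus optional
#' pipeline fields `standards`, `samples`, `out_dir`, `aggregation`,
#' `elements` and `rasters` used by [run_pipeline()]. Absent fields take
#' the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A list of class `soilcap_config`, with any pipeline fields
#'   attached.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  known <- c("M", "K", "baseline_year", "horizons", "idw_power",
             "idw_neighbors", "grid", "seed")
  args <- raw[intersect(names(raw), known)]
  cfg <- do.call(model_config, args)
  extra <- setdiff(names(raw), known)
  for (nm in extra) cfg[[nm]] <- raw[[nm]]
  cfg
}
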