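# Fixture construction from the shipped city capacity tables, and a
# seeded generator of synthetic nine-city sampling campaigns with known
# ground truth.

fixture_path <- function(name) {
  system.file("extdata", name, package = "soilcap", mustWork = TRUE)
}

#' Shipped city-level capacity tables
#'
#' `city_static_table()` returns the published per-city static capacities
#' and `city_residual_table()` the per-city residual capacities (kg/hm^2)
#' for the nine Pearl River Basin cities; the residual table also carries
#' two Yangtze River Basin comparison rows which `pearl_river_only = TRUE`
#' (the default) drops. `city_pi_table()` returns the published per-city
#' comprehensive index values and labels.
#'
#' @param pearl_river_only Drop comparison rows from other basins.
#' @return A data.frame, one row per city.
#' @export
city_static_table <- function() {
  utils::read.csv(fixture_path("city_static.csv"), stringsAsFactors = FALSE)
}

#' @rdname city_static_table
#' @export
city_residual_table <- function(pearl_river_only = TRUE) {
  tab <- utils::read.csv(fixture_path("city_residual.csv"),
                         stringsAsFactors = FALSE)
  if (pearl_river_only) {
    tab <- tab[tab$area == "Pearl River Basin", ]
    tab$area <- NULL
    rownames(tab) <- NULL
  }
  tab
}

#' @rdname city_static_table
#' @export
city_pi_table <- function(pearl_river_only = TRUE) {
  tab <- utils::read.csv(fixture_path("city_pi.csv"),
                         stringsAsFactors = FALSE)
  if (pearl_river_only) {
    tab <- tab[tab$area == "Pearl River Basin", ]
    tab$area <- NULL
    rownames(tab) <- NULL
  }
  tab
}

# Approximate city extents: centers placed at each city's position within
# the basin's lon/lat window, rescaled to planar kilometers (1 deg lon at
# ~22.5 N ~ 102.8 km, 1 deg lat ~ 111 km), with a +/- 20 km box. These are
# synthetic rectangles for exercising spatial interpolation, not real
# administrative boundaries.
city_bboxes <- function(half_width = 20000) {
  centers <- data.frame(
    city = c("Dongguan", "Foshan", "Guangzhou", "Huizhou", "Jiangmen",
             "Shenzhen", "Zhaoqing", "Zhongshan", "Zhuhai"),
    lon = c(113.75, 113.12, 113.26, 114.42, 113.08,
            114.06, 112.47, 113.39, 113.58),
    lat = c(23.02, 23.02, 23.13, 23.11, 22.58,
            22.55, 23.05, 22.52, 22.27),
    stringsAsFactors = FALSE
  )
  x <- (centers$lon - 112) * 102800
  y <- (centers$lat - 21) * 111000
  data.frame(
    city = centers$city,
    xmin = x - half_width, xmax = x + half_width,
    ymin = y - half_width, ymax = y + half_width,
    stringsAsFactors = FALSE
  )
}

#' Back-derive per-city concentration fixtures from capacity tables
#'
#' Inverts the static- and residual-capacity formulas cell by cell:
#' per (city, element), `background = Cic - Qs / (M * 1e-6)` and
#' `status_mean = Cic - Qi / (M * 1e-6)`. Forward recomputation of the
#' capacities from the result reproduces every input cell exactly (up to
#' the tables' two-decimal rounding), which the function asserts.
#'
#' @param standards A standards table supplying the reference values.
#' @param static_table Per-city static capacities (default the shipped
#'   table).
#' @param residual_table Per-city residual capacities (default the shipped
#'   Pearl River rows).
#' @param M Plough-layer mass, kg/hm^2.
#' @return A list of class `city_fixtures` with data.frames `background`
#'   and `status_mean` (mg/kg, one row per city, one column per element),
#'   the `bbox` table, and the element/city vectors.
#' @export
build_city_fixtures <- function(standards = load_standards("builtin"),
                                static_table = city_static_table(),
                                residual_table = city_residual_table(),
                                M = 2.25e6) {
  elems <- intersect(soilcap_elements(), names(static_table))
  cities <- static_table$city
  if (!setequal(cities, residual_table$city)) {
    stop("static and residual tables cover different cities", call. = FALSE)
  }
  residual_table <- residual_table[match(cities, residual_table$city), ]

  background <- data.frame(city = cities, stringsAsFactors = FALSE)
  status_mean <- data.frame(city = cities, stringsAsFactors = FALSE)
  for (el in elems) {
    cic <- standards$reference[standards$element == el]
    if (length(cic) != 1) {
      stop("no reference value for element ", el, call. = FALSE)
    }
    qs <- static_table[[el]]
    qi <- residual_table[[el]]
    if (anyNA(qs) || anyNA(qi)) {
      stop("missing capacity cell for element ", el, call. = FALSE)
    }
    background[[el]] <- invert_static(qs, cic, M)
    status_mean[[el]] <- invert_residual(qi, cic, M)
    # forward consistency: re-derived concentrations must reproduce the
    # printed capacities to better than their two-decimal rounding
    stopifnot(
      all(abs(static_capacity(cic, background[[el]], M) - qs) < 0.005),
      all(abs(residual_capacity(cic, status_mean[[el]], M) - qi) < 0.005)
    )
  }
  if (any(as.matrix(status_mean[elems]) < 0)) {
    stop("back-derived status concentration is negative", call. = FALSE)
  }
  structure(
    list(background = background, status_mean = status_mean,
         bbox = city_bboxes(), cities = cities, elements = elems),
    class = "city_fixtures"
  )
}

#' Per-unit standards table from city fixtures
#'
#' Expands fixtures into the long per-unit standards layout accepted by
#' [capacity_table()]: one row per (city, element) with the city-specific
#' background and the basin-wide reference value.
#'
#' @param fixtures A `city_fixtures` object.
#' @param standards The basin-wide standards table.
#' @return A data.frame with columns `unit`, `element`, `background`,
#'   `reference`.
#' @export
fixture_standards <- function(fixtures,
                              standards = load_standards("builtin")) {
  stopifnot(inherits(fixtures, "city_fixtures"))
  grid <- expand.grid(unit = fixtures$cities, element = fixtures$elements,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$background <- mapply(
    function(u, el) fixtures$background[fixtures$background$city == u, el],
    grid$unit, grid$element)
  grid$reference <- standards$reference[match(grid$element,
                                              standards$element)]
  grid
}

#' Generate a synthetic sampling campaign
#'
#' Draws `n_per_city` composite samples per city. Concentrations are
#' lognormal with the city's fixture status mean and a common coefficient
#' of variation `cv` (`cv = 0` returns the means exactly); coordinates are
#' uniform in the city's bounding box. Fully determined by `seed`.
#'
#' @param fixtures A `city_fixtures` object.
#' @param n_per_city Samples per city (default 50).
#' @param cv Coefficient of variation of the multiplicative sampling noise
#'   (default 0.3).
#' @param seed Integer seed.
#' @return A sample table (columns `sample_id`, `x`, `y`, `unit`, one per
#'   element) in the layout of [load_samples()].
#' @export
generate_campaign <- function(fixtures, n_per_city = 50, cv = 0.3,
                              seed = 1L) {
  stopifnot(inherits(fixtures, "city_fixtures"))
  if (n_per_city < 1) stop("n_per_city must be >= 1", call. = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + cv^2))
  rows <- lapply(fixtures$cities, function(city) {
    bb <- fixtures$bbox[fixtures$bbox$city == city, ]
    out <- data.frame(
      sample_id = sprintf("%s-%03d", city, seq_len(n_per_city)),
      x = stats::runif(n_per_city, bb$xmin, bb$xmax),
      y = stats::runif(n_per_city, bb$ymin, bb$ymax),
      unit = city,
      stringsAsFactors = FALSE
    )
    means <- fixtures$status_mean[fixtures$status_mean$city == city, ]
    for (el in fixtures$elements) {
      m <- means[[el]]
      if (cv == 0 || m == 0) {
        out[[el]] <- rep(m, n_per_city)
      } else {
        # lognormal with E[X] = m, CV[X] = cv
        out[[el]] <- stats::rlnorm(n_per_city,
                                   meanlog = log(m) - sdlog^2 / 2,
                                   sdlog = sdlog)
      }
    }
    out
  })
  do.call(rbind, rows)
}

#' Noiseless pipeline ground truth for the fixture cities
#'
#' Runs the capacity and warning stages on a cv = 0 campaign (one sample
#' per city at the exact fixture status means) with city-specific
#' backgrounds. The result is the exact expected output of any pipeline
#' run on noiseless fixture data and serves as a regression baseline.
#'
#' @param fixtures A `city_fixtures` object.
#' @param config A [model_config()].
#' @return List with elements `capacity` (per-city capacity table) and
#'   `warning` (per-city warning table).
#' @export
end_to_end_truth <- function(fixtures, config = model_config()) {
  stopifnot(inherits(fixtures, "city_fixtures"))
  samples <- generate_campaign(fixtures, n_per_city = 1, cv = 0,
                               seed = config$seed)
  std <- fixture_standards(fixtures)
  cap <- capacity_table(samples, std, config, aggregation = "city")
  warn <- warn_units(cap)
  list(capacity = cap, warning = warn)
}
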