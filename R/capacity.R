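# Material-balance environmental-capacity model: static, residual and
# dynamic capacities per element, their algebraic inverses, and per-unit
# aggregation.

MG_PER_KG <- 1e-6  # converts mg/kg * kg/hm^2 to kg/hm^2

check_finite <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals))) {
    stop("non-finite input to capacity formula", call. = FALSE)
  }
  invisible(TRUE)
}

#' Static environmental capacity
#'
#' The load a unit of soil can hold between its natural background
#' concentration and the risk reference value:
#' `Qs = M * (Cic - Cib) * 1e-6` (kg/hm^2). Negative when the background
#' already exceeds the reference value.
#'
#' @param Cic Risk reference value, mg/kg.
#' @param Cib Soil background value, mg/kg.
#' @param M Plough-layer mass, kg/hm^2 (default 2.25e6).
#' @return Static capacity Qs in kg/hm^2. Vectorized over inputs.
#' @examples
#' static_capacity(40, 25)  # 33.75 kg/hm^2 for As
#' @export
static_capacity <- function(Cic, Cib, M = 2.25e6) {
  check_finite(Cic, Cib, M)
  if (any(M <= 0)) stop("M must be > 0", call. = FALSE)
  M * (Cic - Cib) * MG_PER_KG
}

#' Residual (remaining) environmental capacity
#'
#' The load still admissible given the measured status concentration:
#' `Qi = M * (Cic - Cio) * 1e-6` (kg/hm^2). Negative values signal
#' overload (status above the reference value).
#'
#' @param Cic Risk reference value, mg/kg.
#' @param Cio Measured status concentration, mg/kg.
#' @param M Plough-layer mass, kg/hm^2.
#' @return Residual capacity Qi in kg/hm^2. Vectorized over inputs.
#' @export
residual_capacity <- function(Cic, Cio, M = 2.25e6) {
  check_finite(Cic, Cio, M)
  if (any(M <= 0)) stop("M must be > 0", call. = FALSE)
  if (any(Cio < 0)) stop("Cio must be >= 0", call. = FALSE)
  M * (Cic - Cio) * MG_PER_KG
}

#' Invert the static-capacity formula for the background value
#'
#' Solves `Qs = M * (Cic - Cib) * 1e-6` for `Cib`. Used to back-derive
#' background concentrations from published per-city capacity tables.
#'
#' @param Qs Static capacity, kg/hm^2.
#' @param Cic Risk reference value, mg/kg.
#' @param M Plough-layer mass, kg/hm^2.
#' @return Background concentration Cib, mg/kg.
#' @export
invert_static <- function(Qs, Cic, M = 2.25e6) {
  check_finite(Qs, Cic, M)
  if (any(M <= 0)) stop("M must be > 0", call. = FALSE)
  Cic - Qs / (M * MG_PER_KG)
}

#' Invert the residual-capacity formula for the status concentration
#'
#' Solves `Qi = M * (Cic - Cio) * 1e-6` for `Cio`.
#'
#' @inheritParams invert_static
#' @param Qi Residual capacity, kg/hm^2.
#' @return Status concentration Cio, mg/kg.
#' @export
invert_residual <- function(Qi, Cic, M = 2.25e6) {
  check_finite(Qi, Cic, M)
  if (any(M <= 0)) stop("M must be > 0", call. = FALSE)
  Cic - Qi / (M * MG_PER_KG)
}

#' Average annual dynamic environmental capacity
#'
#' Under a first-order retention model where a fraction `K` of the soil
#' content persists from one year to the next, the constant annual input
#' that drives the soil from its current state to the reference value over
#' an `n`-year horizon is
#' `Qn = M * (Cic - Cib - Cio * K^n) * (1 - K) / (K * (1 - K^n)) * 1e-6`
#' in kg/(hm^2 a).
#'
#' @param Cic Risk reference value, mg/kg.
#' @param Cib Soil background value, mg/kg.
#' @param Cio Measured status concentration, mg/kg.
#' @param K Residual rate, strictly between 0 and 1.
#' @param n Horizon in years, integer >= 1.
#' @param M Plough-layer mass, kg/hm^2.
#' @return Average annual dynamic capacity Qn in kg/(hm^2 a). Vectorized.
#' @examples
#' dynamic_capacity(40, 25, 30, K = 0.9, n = 14)
#' @export
dynamic_capacity <- function(Cic, Cib, Cio, K = 0.9, n, M = 2.25e6) {
  check_finite(Cic, Cib, Cio, K, M)
  if (any(K <= 0) || any(K >= 1)) {
    stop("K must lie strictly between 0 and 1", call. = FALSE)
  }
  if (any(n < 1) || any(n != round(n))) {
    stop("n must be an integer >= 1", call. = FALSE)
  }
  if (any(M <= 0)) stop("M must be > 0", call. = FALSE)
  Kn <- K^n
  M * (Cic - Cib - Cio * Kn) * (1 - K) / (K * (1 - Kn)) * MG_PER_KG
}

#' Year-by-year accumulation trajectory under the retention model
#'
#' Independent recursion behind the dynamic-capacity closed form: each
#' year the retained fraction `K` acts on the previous content plus that
#' year's input, `C_{t+1} = K * (C_t + input_t)`. Useful as a brute-force
#' cross-check of [dynamic_capacity()].
#'
#' @param Cio Starting concentration, mg/kg.
#' @param K Residual rate in (0, 1\].
#' @param annual_input Input concentration added each year, mg/kg; a scalar
#'   (constant input) or a length-`n` vector.
#' @param n Number of years.
#' @return Numeric vector of length `n + 1`: contents at years `0..n`.
#' @export
accumulation_trajectory <- function(Cio, K, annual_input, n) {
  check_finite(Cio, K, annual_input)
  n <- as.integer(n)
  stopifnot(n >= 0, K > 0, K <= 1)
  inputs <- rep_len(annual_input, max(n, 1L))
  out <- numeric(n + 1L)
  out[1L] <- Cio
  for (t in seq_len(n)) {
    out[t + 1L] <- K * (out[t] + inputs[t])
  }
  out
}

#' Per-unit capacity table
#'
#' Computes static, residual and dynamic capacities for every evaluation
#' unit and element. With `aggregation = "city"` the status concentration
#' of a unit is the arithmetic mean of its samples' concentrations and one
#' record per (unit, element) is returned; with `aggregation = "sample"`
#' one record per (sample, element) is returned.
#'
#' @param samples A validated sample table (see [load_samples()]).
#' @param standards A standards table; if it carries a `unit` column,
#'   backgrounds/references are looked up per unit, otherwise the single
#'   table applies to all units.
#' @param config A [model_config()]; supplies `M`, `K` and the horizons.
#' @param aggregation `"city"` (per administrative unit) or `"sample"`.
#' @return A data.frame with columns `unit`, (`sample_id`,) `element`,
#'   `Cio`, `Qs`, `Qi` and one `Qn_<n>` column per configured horizon.
#'   Units kg/hm^2 for Qs/Qi and kg/(hm^2 a) for Qn.
#' @export
capacity_table <- function(samples, standards, config = model_config(),
                           aggregation = c("city", "sample")) {
  aggregation <- match.arg(aggregation)
  meta <- c("sample_id", "x", "y", "unit")
  elems <- setdiff(names(samples), meta)
  per_unit <- "unit" %in% names(standards)

  units <- unique(samples$unit)
  empty <- units[!units %in% samples$unit]
  if (length(empty) > 0) {
    stop("unit with no samples: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }

  std_for <- function(unit, el) {
    if (per_unit) {
      row <- standards[standards$unit == unit & standards$element == el, ]
      if (nrow(row) == 0) {
        row <- standards[is.na(standards$unit) & standards$element == el, ]
      }
    } else {
      row <- standards[standards$element == el, ]
    }
    if (nrow(row) != 1) {
      stop("no standards row for element ", el, " in unit ", unit,
           call. = FALSE)
    }
    row
  }

  if (aggregation == "city") {
    grid <- expand.grid(unit = units, element = elems,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cio <- mapply(function(u, el) mean(samples[samples$unit == u, el]),
                  grid$unit, grid$element)
    ids <- NULL
  } else {
    grid <- expand.grid(sample_id = samples$sample_id, element = elems,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    idx <- match(grid$sample_id, samples$sample_id)
    grid$unit <- samples$unit[idx]
    cio <- mapply(function(i, el) samples[i, el], idx, grid$element)
  }

  std_rows <- mapply(function(u, el) std_for(u, el),
                     grid$unit, grid$element, SIMPLIFY = FALSE)
  cib <- vapply(std_rows, function(r) r$background, numeric(1))
  cic <- vapply(std_rows, function(r) r$reference, numeric(1))
  K <- config$K
  k_of <- function(el) if (length(K) > 1) unname(K[el]) else K
  kvec <- vapply(grid$element, k_of, numeric(1))

  out <- data.frame(
    unit = grid$unit,
    element = grid$element,
    Cio = cio,
    Qs = static_capacity(cic, cib, config$M),
    Qi = residual_capacity(cic, cio, config$M),
    stringsAsFactors = FALSE
  )
  if (aggregation == "sample") {
    out <- cbind(sample_id = grid$sample_id, out)
  }
  for (n in config$horizons) {
    out[[paste0("Qn_", n)]] <-
      dynamic_capacity(cic, cib, cio, kvec, n, config$M)
  }
  ord <- order(match(out$unit, units), match(out$element, elems))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
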