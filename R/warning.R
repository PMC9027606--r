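# Range normalization, improved Nemerow comprehensive index, and the
# five-grade capacity / health-risk classification.

#' Min-max (range) normalization
#'
#' Linearly rescales capacities to \[0, 1\] over a normalization
#' population: `x -> (x - min) / (max - min)`. By default the bounds are
#' the minimum and maximum of `x` itself (the set of evaluation units in
#' the current run); externally supplied bounds make results comparable
#' across runs, with values outside the bounds clamped to \[0, 1\].
#'
#' @param x Numeric vector of capacities (may be negative: overload).
#' @param bounds Optional numeric `c(min, max)` to normalize against.
#' @return Numeric vector in \[0, 1\], same names as `x`.
#' @export
range_normalize <- function(x, bounds = NULL) {
  if (any(!is.finite(x))) stop("non-finite capacity value", call. = FALSE)
  if (is.null(bounds)) bounds <- range(x)
  lo <- bounds[1]; hi <- bounds[2]
  if (hi - lo <= 0) {
    stop("degenerate range: max equals min, normalization undefined",
         call. = FALSE)
  }
  pmin(pmax((x - lo) / (hi - lo), 0), 1)
}

#' Improved Nemerow comprehensive index
#'
#' Composite of the mean and the minimum of a unit's normalized
#' capacities, `P = sqrt((Pave^2 + Pmin^2) / 2)`. Replacing the classical
#' maximum term with the minimum makes the worst (lowest-capacity)
#' element dominate the score, so overload in a single element drags the
#' whole unit down.
#'
#' @param Pave Mean of the normalized capacities, in \[0, 1\].
#' @param Pmin Minimum of the normalized capacities, in \[0, 1\].
#' @return The comprehensive index P, with `Pmin <= P <= Pave`. Vectorized.
#' @export
nemerow_index <- function(Pave, Pmin) {
  if (any(!is.finite(Pave)) || any(!is.finite(Pmin))) {
    stop("non-finite index input", call. = FALSE)
  }
  if (any(Pmin > Pave + 1e-12)) {
    stop("Pmin must not exceed Pave (arguments are (Pave, Pmin))",
         call. = FALSE)
  }
  if (any(Pmin < 0) || any(Pave > 1)) {
    stop("normalized indices must lie in [0, 1]", call. = FALSE)
  }
  sqrt((Pave^2 + Pmin^2) / 2)
}

#' Classify a comprehensive index into a capacity grade
#'
#' Assigns P to one of the five grades. Bins are lower-inclusive and
#' upper-exclusive; P is clamped to \[0, 1\] first and P = 1 falls in
#' grade V.
#'
#' @param P Comprehensive index (vectorized).
#' @param bins A grade table, default [builtin_grade_table()].
#' @return A data.frame with columns `grade`, `capacity_label`,
#'   `risk_label`, one row per element of `P`.
#' @examples
#' classify(c(0.64, 0.44))
#' @export
classify <- function(P, bins = builtin_grade_table()) {
  bins <- validate_grade_table(bins)
  P <- pmin(pmax(P, 0), 1)
  idx <- findInterval(P, c(bins$lower, 1), rightmost.closed = TRUE)
  data.frame(
    grade = bins$grade[idx],
    capacity_label = bins$capacity_label[idx],
    risk_label = bins$risk_label[idx],
    stringsAsFactors = FALSE
  )
}

#' Per-unit capacity warning table
#'
#' The full warning stage: per element, residual capacities are
#' range-normalized across all evaluation units (the normalization
#' population is the current run unless `bounds` supplies per-element
#' min/max pairs); per unit, the mean (`Pave`) and minimum (`Pmin`) of the
#' normalized values feed [nemerow_index()] and the result is classified.
#' The per-element normalized scores are retained as the single-factor
#' warning layer.
#'
#' @param capacity A capacity table from [capacity_table()] (columns
#'   `unit`, `element`, `Qi`).
#' @param bins A grade table.
#' @param elements Optional subset of elements to score; default all
#'   elements present.
#' @param bounds Optional named list `element -> c(min, max)` of external
#'   normalization bounds.
#' @return A data.frame with one row per unit: `<element>_norm` columns,
#'   `Pave`, `Pmin`, `P`, `grade`, `capacity_label`, `risk_label`. The
#'   normalization bounds actually used are attached as attribute
#'   `"norm_bounds"`.
#' @export
warn_units <- function(capacity, bins = builtin_grade_table(),
                       elements = NULL, bounds = NULL) {
  stopifnot(all(c("unit", "element", "Qi") %in% names(capacity)))
  if (is.null(elements)) elements <- unique(capacity$element)
  units <- unique(capacity$unit)

  norm <- matrix(NA_real_, nrow = length(units), ncol = length(elements),
                 dimnames = list(units, elements))
  used_bounds <- list()
  for (el in elements) {
    rows <- capacity[capacity$element == el, ]
    if (!all(units %in% rows$unit)) {
      stop("missing residual capacity for element ", el, call. = FALSE)
    }
    qi <- rows$Qi[match(units, rows$unit)]
    b <- if (!is.null(bounds)) bounds[[el]] else NULL
    if (is.null(b)) b <- range(qi)
    norm[, el] <- range_normalize(qi, bounds = b)
    used_bounds[[el]] <- b
  }

  Pave <- rowMeans(norm)
  Pmin <- apply(norm, 1, min)
  P <- nemerow_index(Pave, Pmin)
  cls <- classify(P, bins)

  out <- data.frame(unit = units, stringsAsFactors = FALSE)
  for (el in elements) out[[paste0(el, "_norm")]] <- norm[, el]
  out$Pave <- Pave
  out$Pmin <- Pmin
  out$P <- P
  out <- cbind(out, cls)
  rownames(out) <- NULL
  attr(out, "norm_bounds") <- used_bounds
  out
}
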