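# Range normalization, Nemerow index, classification, warning table.

test_that("range normalization maps endpoints and clamps", {
  expect_equal(range_normalize(c(0, 5, 10)), c(0, 0.5, 1))
  x <- c(a = 3, b = 9, c = 6)
  nx <- range_normalize(x)
  expect_equal(unname(nx[c("a", "b")]), c(0, 1))
  # external bounds: values outside clamp to [0, 1]
  expect_equal(range_normalize(c(-5, 2, 20), bounds = c(0, 10)),
               c(0, 0.2, 1))
  expect_error(range_normalize(c(4, 4, 4)), "degenerate range")
})

test_that("Nemerow index matches the closed form and sits between Pmin and Pave", {
  expect_equal(nemerow_index(0.68, 0.44), sqrt((0.68^2 + 0.44^2) / 2))
  expect_equal(nemerow_index(0.68, 0.44), 0.5727, tolerance = 0.0005)
  expect_equal(nemerow_index(1, 1), 1)
  for (p in c(0, 0.3, 0.77)) expect_equal(nemerow_index(p, p), p)
  expect_error(nemerow_index(0.4, 0.6), "Pmin")
  set.seed(11)
  for (i in 1:50) {
    v <- sort(runif(2))
    P <- nemerow_index(v[2], v[1])
    expect_true(v[1] <= P && P <= v[2])
  }
})

test_that("classification follows the five-grade bins, lower-inclusive", {
  got <- classify(c(0.64, 0.44, 0.2, 0, 1, 0.8))
  expect_equal(got$grade, c("IV", "III", "II", "I", "V", "V"))
  expect_equal(got$capacity_label[1], "Medium capacity")
  expect_equal(got$risk_label[1], "Mild risk")
  expect_equal(got$capacity_label[2], "Low capacity")
  expect_equal(got$risk_label[2], "Moderate risk")
  # out-of-range values are clamped before classification
  expect_equal(classify(c(-0.3, 1.7))$grade, c("I", "V"))
  # every bin edge belongs to the upper bin
  bins <- builtin_grade_table()
  expect_equal(classify(bins$lower)$grade, bins$grade)
})

test_that("classification of the published city index values follows the bins", {
  pi_tab <- city_pi_table()
  got <- classify(pi_tab$Pi)
  medium <- pi_tab$Pi[got$capacity_label == "Medium capacity"]
  expect_setequal(medium, c(0.60, 0.63, 0.67, 0.70, 0.71, 0.74, 0.76))
  expect_equal(got$capacity_label[pi_tab$Pi == 0.44], "Low capacity")
  expect_equal(got$risk_label[pi_tab$Pi == 0.44], "Moderate risk")
  # 0.87 falls in the high-capacity bin by the bin table
  expect_equal(got$grade[pi_tab$Pi == 0.87], "V")
})

test_that("warn_units composes normalize, index and classify per unit", {
  cap <- data.frame(
    unit = rep(c("u1", "u2"), each = 1),
    element = "As",
    Qi = c(0, 10))
  w <- warn_units(cap)
  expect_equal(w$P[match(c("u1", "u2"), w$unit)], c(0, 1))
  expect_equal(w$grade[match(c("u1", "u2"), w$unit)], c("I", "V"))

  # degenerate population
  cap2 <- cap; cap2$Qi <- c(5, 5)
  expect_error(warn_units(cap2), "degenerate range")
})

test_that("warning invariants hold on randomized multi-element populations", {
  set.seed(99)
  for (rep in 1:10) {
    n_units <- sample(3:8, 1); n_el <- sample(2:6, 1)
    cap <- expand.grid(unit = paste0("u", 1:n_units),
                       element = paste0("e", 1:n_el),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cap$Qi <- rnorm(nrow(cap), 50, 40)
    w <- warn_units(cap)
    norm_cols <- paste0(paste0("e", 1:n_el), "_norm")
    nm <- as.matrix(w[norm_cols])
    expect_equal(w$Pave, unname(rowMeans(nm)))
    expect_equal(w$Pmin, unname(apply(nm, 1, min)))
    expect_true(all(w$Pmin <= w$P + 1e-12 & w$P <= w$Pave + 1e-12))
    expect_true(all(nm >= 0 & nm <= 1))
    # permutation invariance of unit order
    perm <- cap[sample(nrow(cap)), ]
    w2 <- warn_units(perm)
    w2 <- w2[match(w$unit, w2$unit), ]
    expect_equal(w2$P, w$P, ignore_attr = TRUE)
    expect_equal(w2$grade, w$grade, ignore_attr = TRUE)
  }
})

test_that("improving one element under fixed bounds never decreases P", {
  cap <- expand.grid(unit = c("a", "b", "c"), element = c("e1", "e2"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cap$Qi <- c(10, 40, 70, 5, 20, 60)
  bounds <- list(e1 = c(0, 100), e2 = c(0, 100))
  base <- warn_units(cap, bounds = bounds)
  for (delta in c(5, 15, 40)) {
    up <- cap
    up$Qi[up$unit == "b" & up$element == "e2"] <-
      up$Qi[up$unit == "b" & up$element == "e2"] + delta
    w <- warn_units(up, bounds = bounds)
    expect_true(w$P[w$unit == "b"] >= base$P[base$unit == "b"] - 1e-12)
  }
})
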