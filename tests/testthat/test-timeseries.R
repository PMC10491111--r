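test_that("F/F_pre normalization subtracts background and scales by the pre-window mean", {
  expect_equal(normalizeTrace(c(3, 3, 5), background = 1, preWindow = 1:2),
               c(1, 1, 2))
  expect_equal(normalizeTrace(rep(8, 5), background = 3, preWindow = 1:2),
               rep(1, 5))

  # noiseless generator trace: value at t = 693 s is exp(-k t) ~ 0.5
  k <- 0.001
  t <- seq(-66, 990, by = 33)
  raw <- 100 + 500 * ifelse(t >= 0, exp(-k * t), 1)
  norm <- normalizeTrace(raw, background = 100, preWindow = which(t < 0))
  expect_equal(norm[t == 693], exp(-0.693), tolerance = 1e-12)
  expect_equal(exp(-0.693), 0.5, tolerance = 1e-3)

  # idempotence: normalizing a normalized trace (background 0) is identity
  expect_equal(normalizeTrace(norm, 0, which(t < 0)), norm)

  expect_error(normalizeTrace(c(1, 2), background = 5, preWindow = 1), "positive")
  expect_error(normalizeTrace(c(1, 2), preWindow = integer(0)), "non-empty")
  expect_error(normalizeTrace(c(1, 2), preWindow = 3), "range")
})

test_that("AUC is the baseline-subtracted trapezoid with interpolated bounds", {
  t <- seq(0, 10)
  expect_equal(areaUnderCurve(rep(1, 11), t, 0, 10), 0)
  expect_equal(areaUnderCurve(1 - t / 10, t, 0, 10), -5)

  # closed form for exponential decay sampled every 30 s
  k <- 0.001; T <- 900
  ts <- seq(0, T, by = 30)
  auc <- areaUnderCurve(exp(-k * ts), ts, 0, T)
  closed <- (1 - exp(-k * T)) / k - T
  expect_equal(auc, closed, tolerance = 0.005)

  # partial-interval interpolation: integral of -t/10 over [0.5, 9.5]
  expect_equal(areaUnderCurve(1 - t / 10, t, 0.5, 9.5),
               -(9.5^2 - 0.5^2) / 20, tolerance = 1e-12)

  # linearity over a shared grid
  f <- sin(t / 3) + 1; g <- cos(t / 4) + 1
  a <- 2; b <- -0.5
  lhs <- areaUnderCurve(a * f + b * g - (a + b - 1), t, 0, 10)
  rhs <- a * areaUnderCurve(f, t, 0, 10) + b * areaUnderCurve(g, t, 0, 10)
  expect_equal(lhs, rhs, tolerance = 1e-9)

  expect_error(areaUnderCurve(f, t, 5, 5), "tStart")
  expect_error(areaUnderCurve(f, t, -1, 5), "span")
})

test_that("superplot aggregation weights experiments, not cells", {
  agg <- superplotAggregate(c(1, 1, 3), c("A", "A", "B"))
  expect_equal(agg$grandMean, 2.0)  # not the pooled 5/3
  expect_equal(unname(agg$experimentMeans), c(1, 3))
  expect_equal(agg$nExperiments, 2L); expect_equal(agg$nCells, 3L)

  same <- superplotAggregate(rep(4, 9), rep(c("A", "B", "C"), 3))
  expect_equal(same$grandMean, 4); expect_equal(same$sem, 0)

  single <- superplotAggregate(c(1, 2), c("A", "A"))
  expect_true(is.na(single$sem))

  # duplicating every cell within one experiment changes nothing
  v <- c(1, 2, 3, 7); e <- c("A", "A", "B", "B")
  dup <- superplotAggregate(c(v, v[e == "A"]), c(e, e[e == "A"]))
  ref <- superplotAggregate(v, e)
  expect_equal(dup$grandMean, ref$grandMean)
  expect_equal(dup$sem, ref$sem)
})

test_that("trace tables are tidy, round-trip through CSV, and demand one grid", {
  mkTrace <- function(id, exp, times = c(-30, 0, 30))
    cellTrace(id, exp, times, c(10, 10, 12), background = 0, preWindow = 1L)
  tab <- traceMatrix(list(mkTrace("c1", "A"), mkTrace("c2", "B")))
  expect_equal(nrow(tab), 6)
  expect_named(tab, c("cell", "experiment", "time_s", "normalized"))

  empty <- traceMatrix(list())
  expect_equal(nrow(empty), 0)

  f <- tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  back <- read.csv(f)
  expect_equal(back$normalized, tab$normalized)
  expect_equal(back$time_s, tab$time_s)

  expect_error(traceMatrix(list(mkTrace("c1", "A"),
                                mkTrace("c3", "A", times = c(-30, 0, 60)))),
               "inconsistent")
})

test_that("time-resolved aggregation averages experiment means per timepoint", {
  traces <- generateDecaySeries(decaySeriesSpec(nCells = 3, nExperiments = 2,
                                                noiseSdFraction = 0, seed = 3))
  gm <- aggregateTraces(traceMatrix(traces))
  expect_equal(nrow(gm), length(traces[[1]]@timesS))
  expect_true(all(gm$n_experiments == 2))
  # noiseless: grand mean equals the exact normalized expectation
  post <- gm$time_s >= 0
  expect_equal(gm$grand_mean[post], exp(-0.001 * gm$time_s[post]),
               tolerance = 1e-9)
})
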