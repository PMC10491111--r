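#' F/F_pre normalization of an intensity trace
#'
#' Subtracts the background and divides by the mean background-subtracted
#' intensity over the pre-stimulation window, so the normalized trace
#' averages to 1 before treatment.
#'
#' @param raw numeric vector of raw mean intensities.
#' @param background scalar background (default 0).
#' @param preWindow integer indices of the pre-stimulation frames.
#' @return numeric vector, `(raw - background) / mean(raw[preWindow] -
#'   background)`.
#' @examples
#' normalizeTrace(c(3, 3, 5), background = 1, preWindow = 1:2)
#' @export
normalizeTrace <- function(raw, background = 0, preWindow) {
  if (length(preWindow) < 1L) stop("preWindow must be non-empty")
  if (any(preWindow < 1L) || any(preWindow > length(raw)))
    stop("preWindow indices out of range")
  denom <- mean(raw[preWindow] - background)
  if (!is.finite(denom) || denom <= 0)
    stop("pre-stimulation mean (after background subtraction) must be positive")
  (raw - background) / denom
}

#' Baseline-subtracted area under a normalized trace
#'
#' Trapezoidal integral of `normalized - baseline` over `[tStart, tEnd]`.
#' Partial first and last intervals are handled by linear interpolation of
#' the trace at the integration bounds.  With `baseline = 1` (the
#' pre-stimulation level of an F/F_pre trace) an unchanged trace has AUC 0,
#' accumulation is positive and loss negative; units are the time-axis
#' units.
#'
#' @param normalized numeric vector.
#' @param times numeric vector of times, strictly increasing.
#' @param tStart,tEnd integration bounds, within the trace span.
#' @param baseline subtracted level (default 1).
#' @return numeric scalar.
#' @examples
#' t <- seq(0, 10, by = 1)
#' areaUnderCurve(rep(1, 11), t, 0, 10)          # 0
#' areaUnderCurve(1 - t / 10, t, 0, 10)          # -5 (triangle)
#' @export
areaUnderCurve <- function(normalized, times, tStart = 0, tEnd = max(times),
                           baseline = 1) {
  if (length(normalized) != length(times))
    stop("normalized and times must have equal length")
  if (tStart >= tEnd) stop("tStart must be < tEnd")
  if (tStart < min(times) || tEnd > max(times))
    stop("integration bounds must lie within the trace time span")
  inner <- times > tStart & times < tEnd
  xs <- c(tStart, times[inner], tEnd)
  ys <- stats::approx(times, normalized, xout = xs)$y
  trapz(xs, ys - baseline)
}

#' Hierarchical (superplot) aggregation of per-cell values
#'
#' Cells are summarized within their experiment first; the grand mean is
#' the unweighted mean of experiment means and the s.e.m. is computed
#' across experiments (denominator `nExperiments - 1`), never across
#' pooled cells.  This respects the hierarchical structure of imaging
#' experiments, where cells within an experiment are not independent
#' replicates.
#'
#' @param values numeric vector of per-cell values (e.g. AUCs).
#' @param experiments factor/character vector of experiment identifiers,
#'   same length as `values`.
#' @return list with `experimentMeans` (named numeric), `grandMean`,
#'   `sem` (`NA` for a single experiment), `nExperiments`, `nCells`.
#' @examples
#' superplotAggregate(c(1, 1, 3), c("A", "A", "B"))$grandMean  # 2, not 5/3
#' @export
superplotAggregate <- function(values, experiments) {
  if (length(values) < 1L) stop("need at least one cell value")
  if (length(values) != length(experiments))
    stop("values and experiments must have equal length")
  expMeans <- tapply(values, as.character(experiments), mean)
  expMeans <- expMeans[order(names(expMeans))]
  nExp <- length(expMeans)
  list(
    experimentMeans = c(expMeans),
    grandMean = mean(expMeans),
    sem = if (nExp > 1L) stats::sd(expMeans) / sqrt(nExp) else NA_real_,
    nExperiments = nExp,
    nCells = length(values)
  )
}

#' Tidy long-format table of normalized traces
#'
#' @param traces list of [CellTrace-class] sharing one time grid.
#' @return data.frame with columns `cell`, `experiment`, `time_s`,
#'   `normalized` (one row per cell per frame); empty input gives an empty
#'   table.
#' @export
traceMatrix <- function(traces) {
  if (length(traces) == 0L)
    return(data.frame(cell = character(), experiment = character(),
                      time_s = numeric(), normalized = numeric()))
  ref <- traces[[1]]@timesS
  for (tr in traces) {
    if (length(tr@timesS) != length(ref) || any(tr@timesS != ref))
      stop(sprintf("inconsistent time grids: cell '%s' does not match the first trace",
                   tr@cellId))
  }
  do.call(rbind, lapply(traces, function(tr) {
    data.frame(cell = tr@cellId, experiment = tr@experimentId,
               time_s = tr@timesS, normalized = tr@normalized)
  }))
}

#' Time-resolved grand mean across experiments
#'
#' At every timepoint, cells are averaged within experiment, then
#' experiment means are averaged into the grand mean with an s.e.m. across
#' experiments.
#'
#' @param traceTable long-format table from [traceMatrix()].
#' @return data.frame with `time_s`, `grand_mean`, `sem`, `n_experiments`.
#' @export
aggregateTraces <- function(traceTable) {
  if (nrow(traceTable) == 0L)
    return(data.frame(time_s = numeric(), grand_mean = numeric(),
                      sem = numeric(), n_experiments = integer()))
  byTime <- split(traceTable, traceTable$time_s)
  out <- do.call(rbind, lapply(byTime, function(df) {
    agg <- superplotAggregate(df$normalized, df$experiment)
    data.frame(time_s = df$time_s[1], grand_mean = agg$grandMean,
               sem = agg$sem, n_experiments = agg$nExperiments)
  }))
  out <- out[order(out$time_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}
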