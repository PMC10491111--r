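#' Total lipid transfer flux of a transporter population
#'
#' Copies per cell times per-molecule transfer rate: e.g. 36,000 copies at
#' 0.5 transfer cycles per second give 18,000 molecules per second.
#'
#' @param copies transporter copies per cell (>= 0).
#' @param turnoverPerS transfer cycles per second per molecule (>= 0).
#' @return flux in molecules per second.
#' @examples
#' transferFlux(36000, 0.5)
#' @export
transferFlux <- function(copies, turnoverPerS) {
  if (copies < 0 || turnoverPerS < 0)
    stop("copies and turnoverPerS must be non-negative")
  copies * turnoverPerS
}

#' First-order fractional rate constant
#'
#' Under first-order kinetics a constant molecular flux out of a pool of
#' `pool` molecules corresponds to the fractional rate constant
#' `k = flux / pool` (1/s).
#'
#' @param flux molecules per second (>= 0).
#' @param pool pool size, molecules (> 0).
#' @return k in 1/s.
#' @examples
#' rateConstant(18000, 1e7)
#' @export
rateConstant <- function(flux, pool) {
  if (pool <= 0) stop("pool must be positive")
  if (flux < 0) stop("flux must be non-negative")
  flux / pool
}

#' Half-life of a first-order process
#'
#' @param k rate constant, 1/s (> 0).
#' @return half-life `ln(2) / k` in seconds.
#' @examples
#' halfLife(0.00036)       # ~1925 s, i.e. ~32 min
#' halfLife(0.00036) / 60
#' @export
halfLife <- function(k) {
  if (k <= 0) stop("k must be positive")
  log(2) / k
}

#' First-order turnover calculator
#'
#' Chains [transferFlux()], [rateConstant()] and [halfLife()] into one
#' model object: copies x turnover -> flux; flux / pool -> k; ln(2)/k ->
#' half-life.  A user-supplied `k` overrides the chained value (recorded as
#' `kSource = "supplied"`); the chained flux is still reported, and the two
#' routes are never merged silently.
#'
#' @param copies transporter copies per cell.
#' @param turnoverPerS transfer cycles per second per molecule.
#' @param pool lipid pool size, molecules per cell.
#' @param k optional rate-constant override, 1/s.
#' @return a [TurnoverModel-class].
#' @examples
#' turnoverModel(36000, 0.5, 1e7)              # k derived: 0.0018 1/s
#' turnoverModel(36000, 0.5, 1e7, k = 0.00036) # supplied k: t1/2 = 1925 s
#' @export
turnoverModel <- function(copies, turnoverPerS, pool, k = NULL) {
  flux <- transferFlux(copies, turnoverPerS)
  if (is.null(k)) {
    k <- rateConstant(flux, pool)
    src <- "derived"
  } else {
    if (k < 0) stop("supplied k must be non-negative")
    src <- "supplied"
  }
  tHalf <- if (k > 0) log(2) / k else Inf
  new("TurnoverModel", copies = as.numeric(copies),
      turnoverPerS = as.numeric(turnoverPerS), pool = as.numeric(pool),
      flux = flux, k = as.numeric(k), tHalfS = tHalf, kSource = src)
}

#' Fit a mono-exponential decay to a normalized trace
#'
#' Fits `f(t) = plateau + (f0 - plateau) exp(-k t)` to post-treatment
#' values by nonlinear least squares (Levenberg-Marquardt), initialized by
#' regressing `log(f - plateauGuess)` on `t` with
#' `plateauGuess = 0.9 * min(f)` (or the fixed plateau).  `fixPlateau` pins
#' the plateau (e.g. at 0 for complete decay).  An all-equal trace returns
#' `k = 0` exactly with the plateau at that value.
#'
#' @param times numeric vector of post-treatment times (>= 0), seconds.
#' @param values normalized intensities, same length (>= 4 points).
#' @param fixPlateau optional fixed plateau value.
#' @param maxIter iteration bound (default 200).
#' @param tol relative convergence tolerance (default 1e-10).
#' @return a [DecayFit-class].
#' @examples
#' t <- seq(0, 870, by = 30)
#' fitMonoexponential(t, exp(-0.001 * t), fixPlateau = 0)
#' @export
fitMonoexponential <- function(times, values, fixPlateau = NULL,
                               maxIter = 200L, tol = 1e-10) {
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) < 4L) stop("need at least 4 post-treatment points")
  if (any(times < 0)) stop("times must be >= 0 (post-treatment)")
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("times and values must be finite")
  fixed <- !is.null(fixPlateau)

  if (diff(range(values)) == 0) {
    pl <- if (fixed) fixPlateau else values[1]
    return(new("DecayFit", f0 = values[1], plateau = as.numeric(pl),
               kFit = 0, residualRms = 0, nPoints = length(values),
               plateauFixed = fixed))
  }

  plateauGuess <- if (fixed) fixPlateau else min(values) * 0.9
  pos <- values > plateauGuess & is.finite(log(pmax(values - plateauGuess, 0)))
  if (sum(pos) >= 2L) {
    lf <- stats::lm(log(values[pos] - plateauGuess) ~ times[pos])
    k0 <- max(-unname(stats::coef(lf)[2]), 1e-8)
    f00 <- exp(unname(stats::coef(lf)[1])) + plateauGuess
  } else {
    k0 <- 1e-4
    f00 <- values[1]
  }

  df <- data.frame(t = times, y = values)
  ctrl <- minpack.lm::nls.lm.control(maxiter = as.integer(maxIter),
                                     ftol = tol, ptol = tol)
  fit <- tryCatch({
    if (fixed) {
      minpack.lm::nlsLM(y ~ fixPlateau + (f0 - fixPlateau) * exp(-k * t),
                        data = df, start = list(f0 = f00, k = k0),
                        lower = c(f0 = -Inf, k = 0), control = ctrl)
    } else {
      minpack.lm::nlsLM(y ~ plateau + (f0 - plateau) * exp(-k * t),
                        data = df,
                        start = list(f0 = f00, plateau = plateauGuess, k = k0),
                        lower = c(f0 = -Inf, plateau = -Inf, k = 0),
                        control = ctrl)
    }
  }, error = function(e) {
    stop(sprintf("mono-exponential fit failed (start f0=%.4g, k=%.4g): %s",
                 f00, k0, conditionMessage(e)))
  })
  co <- stats::coef(fit)
  new("DecayFit",
      f0 = unname(co["f0"]),
      plateau = if (fixed) as.numeric(fixPlateau) else unname(co["plateau"]),
      kFit = unname(co["k"]),
      residualRms = sqrt(mean(stats::residuals(fit)^2)),
      nPoints = length(values),
      plateauFixed = fixed)
}

#' Evaluate a decay fit on a time grid
#'
#' @param fit a [DecayFit-class].
#' @param times numeric vector of times, seconds.
#' @return numeric vector `plateau + (f0 - plateau) exp(-k times)`.
#' @export
predictDecay <- function(fit, times) {
  stopifnot(is(fit, "DecayFit"))
  fit@plateau + (fit@f0 - fit@plateau) * exp(-fit@kFit * times)
}
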