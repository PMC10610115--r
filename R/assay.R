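#' @include AllClasses.R
NULL

#' Construct four-parameter logistic parameters
#' @param bottom,top Lower/upper response asymptotes.
#' @param logIC50 log10 of the IC50 (in the concentration unit used,
#'   log10 nM by package convention).
#' @param hillSlope Hill slope (finite, nonzero).
#' @return A \linkS4class{FourPLParams}.
#' @export
fourPLParams <- function(bottom, top, logIC50, hillSlope = 1) {
  methods::new("FourPLParams", bottom = bottom, top = top,
               logIC50 = logIC50, hillSlope = hillSlope)
}

#' Evaluate the four-parameter logistic dose-response model
#'
#' response = bottom + (top - bottom) / (1 + 10^((logIC50 - x) * hillSlope))
#' with x = log10(concentration). At x = logIC50 the response is exactly
#' the midpoint (top + bottom) / 2; the exponent is clamped to +/-300 so
#' the function is total (asymptotes are returned exactly for extreme x).
#'
#' @param x log10 concentration (vectorized).
#' @param p A \linkS4class{FourPLParams}.
#' @return Numeric vector of responses.
#' @examples
#' p <- fourPLParams(0, 100, 2, 1)
#' fourPLResponse(2, p)  # 50
#' @export
fourPLResponse <- function(x, p) {
  stopifnot(is(p, "FourPLParams"))
  expo <- pmin(300, pmax(-300, (p@logIC50 - x) * p@hillSlope))
  p@bottom + (p@top - p@bottom) / (1 + 10^expo)
}

#' Construct a dose-response curve
#' @param concNM Concentrations in nM.
#' @param response Responses (percent inhibition).
#' @param replicate Optional replicate labels.
#' @return A \linkS4class{DoseResponseCurve} (x stored as log10 nM).
#' @export
doseResponseCurve <- function(concNM, response, replicate = NULL) {
  if (is.null(replicate)) replicate <- rep(1L, length(concNM))
  methods::new("DoseResponseCurve", x = log10(concNM), y = response,
               replicate = as.integer(replicate))
}

#' Fit the four-parameter logistic model by least squares
#'
#' Replicates are averaged per dose before fitting (switchable).
#' Self-starting defaults: bottom = min(y), top = max(y), logIC50 = x at
#' the half-range crossing, hillSlope = 1. Fitting uses
#' Levenberg-Marquardt least squares; `fixBottom`/`fixTop` constrain the
#' asymptotes when supplied.
#'
#' @param curve A \linkS4class{DoseResponseCurve}.
#' @param init Optional \linkS4class{FourPLParams} starting values.
#' @param averageReplicates Average replicate responses per dose first
#'   (default TRUE).
#' @param fixBottom,fixTop Optional fixed asymptote values.
#' @return List with `params` (\linkS4class{FourPLParams}), `sse`,
#'   `converged`, and `fitted` values.
#' @export
fitFourPL <- function(curve, init = NULL, averageReplicates = TRUE,
                      fixBottom = NULL, fixTop = NULL) {
  stopifnot(is(curve, "DoseResponseCurve"))
  x <- curve@x; y <- curve@y
  if (averageReplicates) {
    agg <- stats::aggregate(y, by = list(x = x), FUN = mean)
    x <- agg$x; y <- agg[[2]]
  }
  if (length(unique(x)) < 4)
    stop("need at least 4 distinct doses to fit a 4PL curve")
  if (stats::sd(y) < .Machine$double.eps^0.25 * max(1, abs(mean(y))))
    stop("degenerate (flat) response data")
  if (is.null(init)) {
    bottom0 <- if (is.null(fixBottom)) min(y) else fixBottom
    top0 <- if (is.null(fixTop)) max(y) else fixTop
    half <- (min(y) + max(y)) / 2
    logIC500 <- x[which.min(abs(y - half))]
    init <- fourPLParams(bottom0, top0, logIC500, 1)
  }
  dat <- data.frame(x = x, y = y)
  fitted4pl <- function(x, bottom, top, logIC50, hill) {
    expo <- pmin(300, pmax(-300, (logIC50 - x) * hill))
    bottom + (top - bottom) / (1 + 10^expo)
  }
  start <- list(logIC50 = init@logIC50, hill = init@hillSlope)
  if (is.null(fixBottom)) start$bottom <- init@bottom
  if (is.null(fixTop)) start$top <- init@top
  form <- if (!is.null(fixBottom) && !is.null(fixTop)) {
    stats::as.formula(sprintf(
      "y ~ fitted4pl(x, %.10g, %.10g, logIC50, hill)", fixBottom, fixTop))
  } else if (!is.null(fixBottom)) {
    stats::as.formula(sprintf(
      "y ~ fitted4pl(x, %.10g, top, logIC50, hill)", fixBottom))
  } else if (!is.null(fixTop)) {
    stats::as.formula(sprintf(
      "y ~ fitted4pl(x, bottom, %.10g, logIC50, hill)", fixTop))
  } else {
    y ~ fitted4pl(x, bottom, top, logIC50, hill)
  }
  environment(form) <- environment()
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("4PL fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  params <- fourPLParams(
    bottom = if (is.null(fixBottom)) cf[["bottom"]] else fixBottom,
    top = if (is.null(fixTop)) cf[["top"]] else fixTop,
    logIC50 = cf[["logIC50"]], hillSlope = cf[["hill"]])
  fittedY <- fourPLResponse(x, params)
  list(params = params, sse = sum((y - fittedY)^2),
       converged = fit$convInfo$isConv %||% TRUE, fitted = fittedY)
}

#' IC50 (concentration units) from fitted parameters
#' @param p A \linkS4class{FourPLParams} on the log10 nM scale.
#' @return IC50 in nM.
#' @examples
#' ic50FromFit(fourPLParams(0, 100, 2, 1))  # 100 nM
#' @export
ic50FromFit <- function(p) {
  stopifnot(is(p, "FourPLParams"))
  structure(10^p@logIC50, unit = "nM")
}

#' Percent inhibition relative to controls
#'
#' 100 * (negCtrl - signal) / (negCtrl - posCtrl): 0% at the negative
#' (uninhibited) control, 100% at the positive (fully inhibited) control.
#'
#' @param signal Observed signal(s).
#' @param negCtrl Negative (no-inhibition) control signal.
#' @param posCtrl Positive (full-inhibition) control signal.
#' @return Percent inhibition (vectorized over `signal`).
#' @export
percentInhibition <- function(signal, negCtrl, posCtrl) {
  if (negCtrl == posCtrl) stop("controls must differ")
  100 * (negCtrl - signal) / (negCtrl - posCtrl)
}
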