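#' Four-parameter logistic dose-response fit
#'
#' Fits the rising four-parameter logistic (Hill) curve
#' \deqn{r(d) = bottom + \frac{top - bottom}{1 + (IC_{50}/d)^{hill}}}
#' to percent-inhibition responses by least squares in log10-dose space
#' (Levenberg-Marquardt via \pkg{minpack.lm}). With `hill = 1`,
#' `bottom = 0`, `top = 100` this is the Emax curve with half-maximal
#' inhibition at `d = IC50`.
#'
#' Initialization: `bottom` and `top` at the smallest and largest per-dose
#' mean response, `IC50` at the dose whose mean response is nearest the
#' half-maximum, `hill = 1`. Box bounds keep `IC50` within
#' `[min(dose)/10, max(dose)*10]`, `hill` within `[0.1, 10]` and the
#' asymptotes within 50 percentage points of the observed per-dose mean
#' range (responses are control-normalized percent inhibition, so wider
#' asymptotes are not meaningful and destabilize shallow fits). If the
#' optimizer fails, the IC50 is instead taken from monotone linear
#' interpolation of the per-dose mean response across log-dose at the 50%
#' crossing (`method = "interpolation"`). If the per-dose mean responses
#' span less than `flat_range` percentage points the curve is flagged flat
#' and no IC50 is reported.
#'
#' @param dose concentrations in uM; at least 3 distinct positive values.
#' @param response percent inhibition, one value per replicate well,
#'   parallel to `dose`.
#' @param hill optional fixed Hill slope; when given, only bottom, top and
#'   IC50 are estimated.
#' @param flat_range minimum span of per-dose mean responses (percentage
#'   points) below which the curve is declared flat; default 10.
#' @return An object of class `"pl4"`: a list with elements `ic50`, `hill`,
#'   `top`, `bottom`, `converged`, `method` (`"model_fit"`,
#'   `"interpolation"` or `"flat"`), `flat`, `data` (the input points),
#'   `mean_response` (per-dose means) and `residuals`.
#' @examples
#' d <- rep(c(0.1, 0.3, 1, 3, 10), each = 2)
#' r <- 100 * d / (d + 2)
#' fit <- fit_4pl(d, r)
#' coef(fit)
#' @seealso [predict.pl4()], [assess_predominance()]
#' @export
fit_4pl <- function(dose, response, hill = NULL, flat_range = 10) {
  dose <- as.numeric(dose)
  response <- as.numeric(response)
  stopifnot(length(dose) == length(response))
  ok <- is.finite(dose) & is.finite(response)
  dose <- dose[ok]
  response <- response[ok]
  if (any(dose <= 0)) stop("doses must be positive", call. = FALSE)
  dgrid <- sort(unique(dose))
  if (length(dgrid) < 3L) {
    stop("insufficient doses: need >= 3 distinct dose levels", call. = FALSE)
  }
  mr <- vapply(dgrid, function(d) mean(response[dose == d]), numeric(1))
  mean_response <- data.frame(dose = dgrid, response = mr)

  obj <- list(ic50 = NA_real_, hill = if (is.null(hill)) NA_real_ else hill,
              top = max(mr), bottom = min(mr), converged = FALSE,
              method = "flat", flat = FALSE,
              data = data.frame(dose = dose, response = response),
              mean_response = mean_response, residuals = NULL)
  class(obj) <- "pl4"

  if (diff(range(mr)) < flat_range) {
    obj$flat <- TRUE
    return(obj)
  }

  lo_d <- log10(min(dgrid) / 10)
  hi_d <- log10(max(dgrid) * 10)
  half <- (max(mr) + min(mr)) / 2
  ld <- log10(dose)
  # parameter vector: bottom, top, log10(ic50) [, hill]
  resid_fn <- function(p) {
    h <- if (is.null(hill)) p[4] else hill
    response - (p[1] + (p[2] - p[1]) / (1 + 10^(h * (p[3] - ld))))
  }
  # percent inhibition is control-normalized, so the asymptotes are kept
  # within 50 points of the observed response range; unbounded asymptotes
  # let the optimizer trade top -> infinity against ic50 -> infinity on
  # shallow noisy curves
  start <- c(min(mr), max(mr), log10(dgrid[which.min(abs(mr - half))]))
  lower <- c(min(mr) - 50, min(mr), lo_d)
  upper <- c(max(mr), max(mr) + 50, hi_d)
  if (is.null(hill)) {
    start <- c(start, 1)
    lower <- c(lower, 0.1)
    upper <- c(upper, 10)
  }
  fit <- try(minpack.lm::nls.lm(
    par = start, fn = resid_fn, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12)), silent = TRUE)

  # info codes 1-3 are proper convergence; 0 and >3 mean the iteration
  # stalled or ran out -- keep the estimate but mark it unconverged
  if (!inherits(fit, "try-error") && fit$info %in% 1:3) {
    p <- fit$par
    obj$bottom <- p[1]
    obj$top <- p[2]
    obj$ic50 <- 10^p[3]
    obj$hill <- if (is.null(hill)) p[4] else hill
    obj$converged <- TRUE
    obj$method <- "model_fit"
    obj$residuals <- resid_fn(p)
    if (obj$top < obj$bottom) {  # keep top as the high-dose asymptote label
      tmp <- obj$top; obj$top <- obj$bottom; obj$bottom <- tmp
    }
    return(obj)
  }
  # optimizer failure: 50% crossing by linear interpolation across log-dose
  ic <- interp_ic50(dgrid, mr)
  obj$ic50 <- ic
  obj$method <- if (is.na(ic)) "flat" else "interpolation"
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' IC50 by linear interpolation of the mean response across log-dose
#'
#' Finds the first dose interval in which the per-dose mean response
#' crosses `level` (default 50%) and interpolates the crossing linearly in
#' log10 dose. Returns `NA` when the curve never crosses.
#'
#' @param dose distinct doses in uM, ascending.
#' @param mean_response mean percent inhibition per dose.
#' @param level crossing level in percent; default 50.
#' @return Interpolated crossing dose in uM, or `NA`.
#' @export
interp_ic50 <- function(dose, mean_response, level = 50) {
  o <- order(dose)
  dose <- dose[o]
  y <- mean_response[o]
  for (i in seq_len(length(dose) - 1L)) {
    y0 <- y[i]; y1 <- y[i + 1L]
    if ((y0 - level) * (y1 - level) <= 0 && y0 != y1) {
      f <- (level - y0) / (y1 - y0)
      return(10^(log10(dose[i]) + f * (log10(dose[i + 1L]) - log10(dose[i]))))
    }
    if (y0 == level) return(dose[i])
  }
  NA_real_
}

#' @export
print.pl4 <- function(x, ...) {
  cat("Four-parameter logistic dose-response fit\n")
  cat(sprintf("  method: %s%s\n", x$method,
              if (x$flat) " (flat curve, no IC50)" else ""))
  if (!is.na(x$ic50)) {
    cat(sprintf("  IC50: %.4g uM   hill: %.3g\n", x$ic50, x$hill))
    cat(sprintf("  bottom: %.3g%%   top: %.3g%%\n", x$bottom, x$top))
  }
  cat(sprintf("  converged: %s   n points: %d, %d dose levels\n",
              x$converged, nrow(x$data), nrow(x$mean_response)))
  invisible(x)
}

#' @export
coef.pl4 <- function(object, ...) {
  c(bottom = object$bottom, top = object$top, ic50 = object$ic50,
    hill = object$hill)
}

#' Predicted percent inhibition from a 4PL fit
#'
#' @param object a `"pl4"` fit.
#' @param newdata optional data.frame with a `dose` column (uM); defaults
#'   to the doses used in the fit.
#' @param ... unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.pl4 <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$dose else newdata$dose
  if (is.na(object$ic50) || object$method != "model_fit") {
    stats::approx(log10(object$mean_response$dose),
                  object$mean_response$response, xout = log10(d),
                  rule = 2)$y
  } else {
    object$bottom + (object$top - object$bottom) /
      (1 + (object$ic50 / d)^object$hill)
  }
}

#' @export
residuals.pl4 <- function(object, ...) {
  object$data$response - predict(object)
}

#' @export
summary.pl4 <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object, rmse = sqrt(mean(res^2)),
                 n = nrow(object$data)), class = "summary.pl4")
}

#' @export
print.summary.pl4 <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual RMSE: %.3g%% over %d points\n", x$rmse, x$n))
  invisible(x)
}

#' @export
plot.pl4 <- function(x, ...) {
  plot(x$data$dose, x$data$response, log = "x",
       xlab = "dose (uM)", ylab = "percent inhibition", ...)
  dd <- 10^seq(log10(min(x$data$dose)), log10(max(x$data$dose)),
               length.out = 100)
  graphics::lines(dd, predict(x, data.frame(dose = dd)))
  invisible(x)
}

#' Per-dose IL-1beta predominance over IL-6
#'
#' At each dose of the confirmation grid, the mean IL-1beta and IL-6
#' percent inhibitions are compared; the dose is called predominant when
#' IL-1beta inhibition exceeds IL-6 inhibition by at least `margin`
#' percentage points AND IL-1beta inhibition itself reaches `floor`.
#' Replicates are averaged per dose before the comparison.
#'
#' @param dose doses in uM (one per response row; both analytes must share
#'   the same dose grid).
#' @param il1b,il6 percent-inhibition responses per replicate for the two
#'   analytes, each parallel to its own `dose` vector.
#' @param dose_il6 dose vector for the IL-6 responses; defaults to `dose`.
#' @param margin required (IL-1beta - IL-6) difference in percentage
#'   points; default 30.
#' @param floor required minimum IL-1beta inhibition in percent; default 30.
#' @return A data.frame with one row per dose: `dose`, `il1b_inhibition`,
#'   `il6_inhibition`, `predominant`; the number of predominant doses is
#'   attached as attribute `n_predominant`.
#' @export
assess_predominance <- function(dose, il1b, il6, dose_il6 = dose,
                                margin = 30, floor = 30) {
  g1 <- sort(unique(dose))
  g6 <- sort(unique(dose_il6))
  if (length(g1) != length(g6) || any(g1 != g6)) {
    stop("dose grids for IL-1B and IL-6 do not align", call. = FALSE)
  }
  m1 <- vapply(g1, function(d) mean(il1b[dose == d]), numeric(1))
  m6 <- vapply(g1, function(d) mean(il6[dose_il6 == d]), numeric(1))
  pred <- (m1 - m6) >= margin & m1 >= floor
  out <- data.frame(dose = g1, il1b_inhibition = m1, il6_inhibition = m6,
                    predominant = pred)
  attr(out, "n_predominant") <- sum(pred)
  out
}
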