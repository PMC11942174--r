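#' Four-parameter variable-slope Hill inhibition curve
#'
#' \deqn{y = bottom + \frac{top - bottom}{1 + (x / IC_{50})^{h}}}
#'
#' with Hill slope \eqn{h > 0} parameterizing inhibition (response
#' decreasing in dose).  At dose 0 the curve equals `top`; at
#' `dose == ic50` it equals the midpoint `(top + bottom) / 2`.
#'
#' @param dose dose vector (µM; 0 allowed).
#' @param top,bottom upper/lower asymptotes (fractions).
#' @param ic50 half-maximal inhibitory concentration (µM, > 0).
#' @param slope Hill coefficient (> 0).
#' @return response vector.
#' @export
hill_curve <- function(dose, top, bottom, ic50, slope) {
  stopifnot(ic50 > 0, slope > 0)
  y <- bottom + (top - bottom) / (1 + (dose / ic50)^slope)
  y[dose == 0] <- top
  y
}

.hill_pred <- function(x, top, bottom, lic50, slope) {
  y <- bottom + (top - bottom) / (1 + exp(slope * (log(pmax(x, 1e-300)) - lic50)))
  y[x == 0] <- top
  y
}

#' Fit a variable-slope Hill inhibition curve
#'
#' Least-squares fit of the four-parameter logistic
#' ("log(inhibitor) vs response -- variable slope") model via
#' Levenberg-Marquardt, multi-started from log-spaced IC50 seeds spanning
#' the dosed range.  The fit is performed in log(IC50), so dose-scale
#' equivariance is exact: multiplying all doses by `c` multiplies the
#' fitted IC50 by `c`.  Vehicle (dose 0) points cannot enter a log-dose
#' axis; they contribute to the fit only through the zero-dose limit of
#' the curve (`y = top`), anchoring the upper asymptote.
#'
#' Bounds: `top` in \[0, 1.5\], `bottom` in \[0, 1.5\] (a fit with
#' `bottom > top` is flagged non-converged), `slope` in (0, 10\], and
#' log(IC50) within \[min dose / 100, max dose x 100\]; an IC50 escaping
#' that window is reported but flagged non-converged.  These guards avoid
#' spurious minima on noisy 5--8 point curves.
#'
#' @param doses dose vector (µM); at least 4 distinct nonzero doses.
#' @param responses normalized fractional responses, same length.
#' @param weights optional nonnegative fit weights.
#' @param n_starts number of log-spaced IC50 starting values.
#' @return object of class `hill_fit`: list with elements `top`, `bottom`,
#'   `ic50`, `slope`, `se_ic50`, `se_slope`, `n_points`, `converged`,
#'   `residual_sse`.
#' @export
fit_hill <- function(doses, responses, weights = NULL, n_starts = 5L) {
  stopifnot(length(doses) == length(responses))
  ok <- is.finite(doses) & is.finite(responses)
  doses <- doses[ok]; responses <- responses[ok]
  if (!is.null(weights)) weights <- weights[ok]
  nz <- doses[doses > 0]
  if (length(unique(nz)) < 4)
    stop("need at least 4 distinct nonzero doses")

  failed <- function() {
    structure(list(top = NA_real_, bottom = NA_real_, ic50 = NA_real_,
                   slope = NA_real_, se_ic50 = NA_real_, se_slope = NA_real_,
                   n_points = length(doses), converged = FALSE,
                   residual_sse = NA_real_),
              class = "hill_fit")
  }
  # flat / degenerate response: no inhibition signal to fit
  if (diff(range(responses)) < 1e-8) return(failed())

  lo <- c(top = 0, bottom = 0, lic50 = log(min(nz) / 100), slope = 1e-3)
  hi <- c(top = 1.5, bottom = 1.5, lic50 = log(max(nz) * 100), slope = 10)
  starts_l <- seq(log(min(nz)), log(max(nz)), length.out = n_starts)
  top0 <- min(max(responses), 1.5)
  bot0 <- max(min(responses), 0)
  df <- data.frame(x = doses, y = responses)
  w <- if (is.null(weights)) rep(1, nrow(df)) else weights

  best <- NULL
  for (l0 in starts_l) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ .hill_pred(x, top, bottom, lic50, slope),
        data = df, weights = w,
        start = list(top = top0, bottom = bot0, lic50 = l0, slope = 1),
        lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2 * w)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) return(failed())

  cf <- stats::coef(best$fit)
  vc <- tryCatch(stats::vcov(best$fit), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, 4) else sqrt(pmax(diag(vc), 0))
  names(se) <- names(cf)
  ic50 <- exp(cf[["lic50"]])
  converged <- is.finite(ic50) &&
    ic50 >= min(nz) / 100 && ic50 <= max(nz) * 100 &&
    cf[["bottom"]] <= cf[["top"]]
  structure(list(top = cf[["top"]], bottom = cf[["bottom"]],
                 ic50 = ic50, slope = cf[["slope"]],
                 se_ic50 = ic50 * se[["lic50"]],   # delta method from log scale
                 se_slope = se[["slope"]],
                 n_points = length(doses), converged = converged,
                 residual_sse = best$sse),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "Hill fit (variable slope): IC50 = %.3g uM (SE %.2g), slope = %.3g\n",
    x$ic50, x$se_ic50, x$slope))
  cat(sprintf("  top = %.3g, bottom = %.3g, SSE = %.3g, converged: %s\n",
              x$top, x$bottom, x$residual_sse, x$converged))
  invisible(x)
}

#' IC50 with SEM across biological replicates
#'
#' Fits each biological replicate separately and reports the mean IC50 and
#' its standard error of the mean across replicates (the convention used
#' when reporting dose-response potency over independent transfections).
#' The per-fit covariance-based SE is available from each attached fit as
#' a secondary output.
#'
#' @param table a [preprocess_efflux()] table (or any data.frame with
#'   `dose_uM`, `fraction`, `biological_rep`).
#' @return list: `mean_ic50`, `sem_ic50`, `n_replicates`, `fits`.
#' @export
ic50_with_sem <- function(table) {
  reps <- unique(table$biological_rep)
  if (length(reps) < 2)
    stop("need at least 2 biological replicates")
  fits <- lapply(reps, function(br) {
    d <- table[table$biological_rep == br, ]
    fit_hill(d$dose_uM, d$fraction)
  })
  names(fits) <- as.character(reps)
  conv <- vapply(fits, function(f) f$converged, logical(1))
  if (any(!conv))
    warning("excluding non-convergent replicate(s): ",
            paste(names(fits)[!conv], collapse = ", "))
  if (sum(conv) < 2)
    stop("fewer than 2 convergent replicate fits")
  ic50s <- vapply(fits[conv], function(f) f$ic50, numeric(1))
  list(mean_ic50 = mean(ic50s),
       sem_ic50 = stats::sd(ic50s) / sqrt(length(ic50s)),
       n_replicates = length(ic50s),
       fits = fits)
}
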