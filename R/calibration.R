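#' Regional chlorophyll calibration coefficients
#'
#' The three parameters of the regionalized chlorophyll-from-IOPs model
#' `Chl = A * (a_pig + B * (a_det + a_cdom))^C`: a scale `A` (mg m-3), the
#' weight `B` of the non-pigment absorptions relative to pigment absorption,
#' and an exponent `C`. The canonical regional values are
#' `A = 21, B = 0.77, C = 1.04`.
#'
#' @param A scale, mg m-3 (> 0)
#' @param B detritus + CDOM weight (>= 0)
#' @param C exponent (> 0)
#' @return object of class `calibration_coefficients`
#' @export
calibration_coefficients <- function(A = 21, B = 0.77, C = 1.04) {
  stopifnot(is.numeric(A), A > 0, is.numeric(B), B >= 0, is.numeric(C), C > 0)
  structure(list(A = as.numeric(A), B = as.numeric(B), C = as.numeric(C)),
            class = "calibration_coefficients")
}

#' Chlorophyll from inherent optical properties
#'
#' Evaluates `Chl = A * (a_pig + B * (a_det + a_cdom))^C` elementwise
#' (scalars, vectors or rasters). All absorptions are in 1/m, the result in
#' mg m-3. Zero absorptions give 0; `NA`s propagate. Negative absorptions
#' are an error -- real retrievals can produce them, but such pixels must be
#' flagged invalid upstream, never fed to the model.
#'
#' @param a_pig pigment absorption, 1/m
#' @param a_det detritus absorption, 1/m
#' @param a_cdom CDOM absorption, 1/m
#' @param coeffs a [calibration_coefficients()]
#' @return chlorophyll-a, mg m-3, same shape as the inputs
#' @export
chl_from_iops <- function(a_pig, a_det = 0, a_cdom = 0,
                          coeffs = calibration_coefficients()) {
  if (any(a_pig < 0, na.rm = TRUE) || any(a_det < 0, na.rm = TRUE) ||
      any(a_cdom < 0, na.rm = TRUE))
    stop("negative absorption: flag such pixels invalid upstream")
  coeffs$A * (a_pig + coeffs$B * (a_det + a_cdom))^coeffs$C
}

#' Invert the chlorophyll model to consistent IOPs
#'
#' Produces an absorption triple that the forward model maps back exactly
#' onto the given chlorophyll: the inner term is `(chl / A)^(1/C)`, of which
#' a fraction `f_pig` is assigned to pigment absorption and the remainder is
#' split between detritus and CDOM (fraction `f_det` of it to detritus)
#' after dividing by `B`. Any `f_pig` in (0, 1) satisfies the identity; the
#' synthetic generator varies it per pixel so that all three coefficients
#' stay identifiable from simulated match-ups.
#'
#' @param chl chlorophyll-a, mg m-3 (>= 0, vectorized)
#' @param coeffs a [calibration_coefficients()]
#' @param f_pig pigment share of the inner term, in (0, 1); recycled
#' @param f_det detritus share of the non-pigment part, in `[0, 1]`; recycled
#' @return list with components `a_pig`, `a_det`, `a_cdom` (1/m)
#' @export
iops_from_chl <- function(chl, coeffs = calibration_coefficients(),
                          f_pig = 0.7, f_det = 0.5) {
  if (any(chl < 0, na.rm = TRUE)) stop("chlorophyll must be >= 0")
  if (any(f_pig <= 0 | f_pig >= 1)) stop("f_pig must be in (0, 1)")
  inner <- (chl / coeffs$A)^(1 / coeffs$C)
  a_pig <- f_pig * inner
  rest <- (1 - f_pig) * inner / coeffs$B
  list(a_pig = a_pig, a_det = f_det * rest, a_cdom = (1 - f_det) * rest)
}

#' Goodness of fit on the linear concentration scale
#'
#' `r_squared` is the squared Pearson correlation of predicted vs observed;
#' `rmse` the root-mean-square difference, both in mg m-3 terms. Zero
#' variance in either vector makes the correlation undefined: `r_squared`
#' is then `NA` with a warning.
#'
#' @param predicted,observed equal-length numeric vectors (n >= 2)
#' @return list with `r_squared`, `rmse`, `n`
#' @export
evaluate_fit <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 2L)
  rmse <- sqrt(mean((predicted - observed)^2))
  r2 <- if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    warning("zero variance: r_squared undefined")
    NA_real_
  } else stats::cor(predicted, observed)^2
  list(r_squared = r2, rmse = rmse, n = length(observed))
}

#' Refit the regional calibration against match-ups
#'
#' Nonlinear least squares of `log(chl_insitu)` on
#' `log(A) + C * log(a_pig + B * (a_det + a_cdom))`, with all parameters
#' bounded positive by optimizing on the log-parameter scale (L-BFGS-B,
#' tight tolerances, deterministic given `init`). Residuals are taken on
#' the log scale because lake chlorophyll spans orders of magnitude across
#' the trophic gradient; diagnostics (`r_squared`, `rmse`) are reported on
#' the linear mg m-3 scale.
#'
#' @param matchups a data frame with columns `a_pig`, `a_det`, `a_cdom`
#'   (macropixel-mean absorptions, 1/m) and `chl_insitu` (mg m-3), e.g. the
#'   passing rows of [build_matchups()]
#' @param init starting [calibration_coefficients()]
#' @param fix_AC if `TRUE`, freeze `A` and `C` at their `init` values and
#'   refit only the non-pigment weight `B`
#' @return object of class `calibration_fit`: `coefficients`, `r_squared`,
#'   `rmse` (linear scale), `n`, `convergence` label
#' @export
fit_regional_coefficients <- function(matchups,
                                      init = calibration_coefficients(),
                                      fix_AC = FALSE) {
  need <- c("a_pig", "a_det", "a_cdom", "chl_insitu")
  if (!all(need %in% names(matchups)))
    stop("matchups must have columns: ", paste(need, collapse = ", "))
  d <- matchups[stats::complete.cases(matchups[need]), need, drop = FALSE]
  if (nrow(d) < 5L) stop("at least 5 passing match-ups required, got ", nrow(d))
  if (any(d$chl_insitu <= 0)) stop("in-situ chlorophyll must be > 0")
  s <- d$a_det + d$a_cdom
  ly <- log(d$chl_insitu)

  obj <- function(p) {
    A <- exp(p[1L]); B <- exp(p[2L]); C <- exp(p[3L])
    inner <- d$a_pig + B * s
    if (any(inner <= 0)) return(1e12)
    sum((ly - (log(A) + C * log(inner)))^2)
  }
  p0 <- log(c(init$A, init$B, init$C))
  # Nelder-Mead to near the optimum, then a guarded L-BFGS-B polish for
  # the last digits (the polish occasionally aborts its line search on
  # noisy data; the simplex solution is then already converged)
  run <- function(par0, fn) {
    nm <- stats::optim(par0, fn, method = "Nelder-Mead",
                       control = list(reltol = 1e-14, maxit = 5000L))
    pol <- tryCatch(
      stats::optim(nm$par, fn, method = "L-BFGS-B",
                   lower = rep(log(1e-8), length(par0)),
                   upper = rep(log(1e8), length(par0)),
                   control = list(factr = 1e3, pgtol = 1e-12, maxit = 500L)),
      error = function(e) NULL)
    if (!is.null(pol) && pol$convergence == 0L && pol$value <= nm$value) pol
    else nm
  }
  if (fix_AC) {
    # 1-D refit of B alone: golden-section over log B
    fit1 <- stats::optimize(function(pb) obj(c(p0[1L], pb, p0[3L])),
                            interval = log(c(1e-8, 1e8)), tol = 1e-12)
    par <- c(p0[1L], fit1$minimum, p0[3L]); conv <- 0L
  } else {
    fit1 <- run(p0, obj)
    par <- fit1$par; conv <- fit1$convergence
  }
  if (conv != 0L)
    stop("calibration fit did not converge (optim code ", conv, "): ",
         fit1$message)
  co <- calibration_coefficients(exp(par[1L]), exp(par[2L]), exp(par[3L]))
  gof <- evaluate_fit(chl_from_iops(d$a_pig, d$a_det, d$a_cdom, co),
                      d$chl_insitu)
  structure(list(coefficients = co, r_squared = gof$r_squared,
                 rmse = gof$rmse, n = nrow(d),
                 convergence = "converged",
                 objective = "log-scale least squares",
                 fixed_AC = fix_AC),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("Regional Chl calibration: Chl = %.4g (a_pig + %.4g (a_det + a_cdom))^%.4g\n",
              co$A, co$B, co$C))
  cat(sprintf("  n = %d match-ups, r^2 = %.3f, RMSE = %.3g mg m-3 (%s)\n",
              x$n, x$r_squared, x$rmse, x$convergence))
  invisible(x)
}
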