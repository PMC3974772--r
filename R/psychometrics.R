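# Weibull psychometric function and nonlinear least-squares threshold
# fitting.

#' Weibull psychometric parameters
#'
#' The four parameters of the Weibull psychometric function:
#' `A` the maximum performance, `b` the steepness, `a` the threshold
#' concentration, and `g` the false-alarm/floor rate (the chance level of
#' the paradigm: 0.5 for Go/No-Go success rates, 0 for
#' habituation/dis-habituation responses). `g` is held fixed during
#' fitting.
#'
#' @param A Maximum performance (response units); must satisfy `A >= g`.
#' @param b Steepness (dimensionless, > 0).
#' @param a Threshold concentration (s.v. fraction, > 0).
#' @param g Floor rate (response units).
#' @return Object of class `psychometric_params`.
#' @export
psychometric_params <- function(A, b, a, g = 0) {
  for (v in list(A = A, b = b, a = a, g = g)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_olf("psychometric parameters must be finite scalars")
    }
  }
  if (b <= 0) stop_olf("steepness b must be > 0", class = "olf_domain_error")
  if (a <= 0) stop_olf("threshold a must be > 0", class = "olf_domain_error")
  if (A < g) stop_olf("A must be >= g", class = "olf_domain_error")
  structure(list(A = A, b = b, a = a, g = g),
            class = "psychometric_params")
}

#' Evaluate the Weibull psychometric function
#'
#' `psi(x) = g + (A - g) * (1 - exp(-(x / a)^b))`: a monotone
#' non-decreasing curve from the floor `g` at `x = 0` to the ceiling `A` as
#' `x` grows, passing `g + (A - g)(1 - 1/e)` (about 63% of the rise) at the
#' threshold `x = a`.
#'
#' @param x Stimulus intensities (concentration, s.v. fraction; `x >= 0`).
#' @param params A `psychometric_params`, or `A`, `b`, `a`, `g` given
#'   separately.
#' @param A,b,a,g Parameter values used when `params` is missing.
#' @return Response values, same length as `x`.
#' @examples
#' p <- psychometric_params(A = 1, b = 1.5, a = 1e-5, g = 0)
#' weibull_psychometric(c(0, 1e-5, 1e-3), p)
#' @export
weibull_psychometric <- function(x, params = NULL, A, b, a, g = 0) {
  if (!is.null(params)) {
    stopifnot(inherits(params, "psychometric_params"))
    A <- params$A; b <- params$b; a <- params$a; g <- params$g
  } else {
    params <- psychometric_params(A, b, a, g)  # validates
  }
  if (any(x < 0)) stop_olf("x must be >= 0", class = "olf_domain_error")
  g + (A - g) * (1 - exp(-(x / a)^b))
}

#' Fit the Weibull psychometric function
#'
#' Nonlinear least squares on (`A`, `b`, `a`) with the floor `g` held fixed
#' at the paradigm's chance level. The fit is run on the linear
#' concentration scale; positivity of `b` and `a` (and `A > g`) is enforced
#' by an unconstrained log reparameterization, and a small deterministic
#' multi-start around the data-driven initial guess guards against local
#' minima. Degenerate inputs (responses flat at or below the floor, so the
#' threshold is unidentifiable) return a fit flagged `converged = FALSE`
#' rather than a silent fallback.
#'
#' @param x Concentrations (> 0, strictly ascending).
#' @param y Responses (success rate or mean response change), same length.
#' @param g_fixed Fixed floor: 0.5 for Go/No-Go SR, 0 for
#'   habituation/dis-habituation responses.
#' @param n_starts Number of deterministic multi-start initializations
#'   (default 3).
#' @return Object of class `psychometric_fit`: list with `params`
#'   (`psychometric_params`), `rss`, `n`, `converged`, `g_fixed`, and
#'   `message`.
#' @examples
#' p <- psychometric_params(A = 0.95, b = 1.5, a = 1e-5, g = 0.5)
#' x <- 10^seq(-7, -3, length.out = 7)
#' fit <- fit_psychometric(x, weibull_psychometric(x, p), g_fixed = 0.5)
#' fit$params$a
#' @export
fit_psychometric <- function(x, y, g_fixed, n_starts = 3L) {
  if (length(x) != length(y)) stop_olf("x and y lengths differ")
  if (length(x) < 3L) stop_olf("need at least 3 points to fit")
  if (any(x <= 0)) stop_olf("concentrations must be > 0")
  if (any(diff(x) <= 0)) stop_olf("concentrations must be strictly ascending")
  if (!is.numeric(g_fixed) || length(g_fixed) != 1L) {
    stop_olf("g_fixed must be a scalar (0.5 for Go/No-Go, 0 for habituation)")
  }

  y_span <- diff(range(y))
  if (y_span <= .Machine$double.eps^0.5 * max(1, abs(max(y))) ||
      max(y) <= g_fixed) {
    return(new_psychometric_fit(
      params = list(A = max(y), b = NA_real_, a = NA_real_, g = g_fixed),
      rss = sum((y - mean(y))^2), n = length(x), converged = FALSE,
      g_fixed = g_fixed,
      message = "responses flat or at floor; threshold unidentifiable"
    ))
  }

  # theta = (log(A - g), log b, log a)
  obj <- function(theta) {
    A <- g_fixed + exp(theta[1])
    b <- exp(theta[2])
    a <- exp(theta[3])
    r <- y - (g_fixed + (A - g_fixed) * (1 - exp(-(x / a)^b)))
    sum(r * r)
  }

  A0 <- max(y)
  half <- g_fixed + 0.5 * (A0 - g_fixed)
  a0 <- interpolate_half_rise(x, y, half)
  # base init plus deterministic jitters: (b0*2, a0/5) and (b0/2, a0*5)
  starts <- list(
    c(log(A0 - g_fixed), 0, log(a0)),
    c(log(A0 - g_fixed), log(2), log(a0 / 5)),
    c(log(A0 - g_fixed), -log(2), log(a0 * 5))
  )[seq_len(max(1L, min(3L, n_starts)))]

  best <- NULL
  for (s in starts) {
    res <- tryCatch({
      r1 <- stats::optim(s, obj, method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-14))
      r2 <- stats::optim(r1$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 5000, reltol = 1e-12))
      # sharpen the optimum; keep the simplex convergence verdict
      r3 <- stats::optim(r2$par, obj, method = "BFGS",
                         control = list(maxit = 200, reltol = 1e-15))
      if (r3$value <= r2$value) r2$par <- r3$par
      r2$value <- min(r2$value, r3$value)
      r2
    }, error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) {
    return(new_psychometric_fit(
      params = list(A = A0, b = NA_real_, a = NA_real_, g = g_fixed),
      rss = NA_real_, n = length(x), converged = FALSE, g_fixed = g_fixed,
      message = "all optimizer starts failed"
    ))
  }
  A_hat <- g_fixed + exp(best$par[1])
  b_hat <- exp(best$par[2])
  a_hat <- exp(best$par[3])
  # a outside any plausible extrapolation of the sampled range means the
  # optimizer ran off to a flat region of the objective
  identifiable <- a_hat > min(x) * 1e-4 && a_hat < max(x) * 1e4 &&
    is.finite(best$value)
  new_psychometric_fit(
    params = list(A = A_hat, b = b_hat, a = a_hat, g = g_fixed),
    rss = best$value, n = length(x),
    converged = best$convergence == 0 && identifiable,
    g_fixed = g_fixed,
    message = if (best$convergence == 0 && identifiable) "converged"
              else "optimizer did not converge or threshold outside data range"
  )
}

new_psychometric_fit <- function(params, rss, n, converged, g_fixed,
                                 message) {
  structure(
    list(params = params, rss = rss, n = n, converged = converged,
         g_fixed = g_fixed, message = message),
    class = "psychometric_fit"
  )
}

# x at which y first crosses `level`, linearly interpolated on log10(x);
# falls back to the geometric mean of the x range.
interpolate_half_rise <- function(x, y, level) {
  above <- which(y >= level)
  if (length(above) == 0L || above[1] == 1L) {
    return(sqrt(min(x) * max(x)))
  }
  i <- above[1]
  lx <- log10(x)
  frac <- (level - y[i - 1]) / (y[i] - y[i - 1])
  if (!is.finite(frac)) frac <- 0.5
  10^(lx[i - 1] + frac * (lx[i] - lx[i - 1]))
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("<psychometric_fit>\n")
  cat(sprintf("  A = %.6g, b = %.6g, a (threshold) = %.6g, g = %.6g (fixed)\n",
              x$params$A, x$params$b, x$params$a, x$params$g))
  cat(sprintf("  rss = %.6g on %d points; converged: %s\n",
              x$rss, x$n, x$converged))
  invisible(x)
}

#' Predicted response from a fitted psychometric curve
#' @param object A `psychometric_fit` with `converged = TRUE`.
#' @param x Concentrations at which to evaluate.
#' @param ... Unused.
#' @return Predicted responses.
#' @export
predict.psychometric_fit <- function(object, x, ...) {
  p <- object$params
  if (!object$converged) {
    stop_olf("cannot predict from a non-converged fit")
  }
  p$g + (p$A - p$g) * (1 - exp(-(x / p$a)^p$b))
}

#' Write a psychometric fit report as JSON
#' @param fit A `psychometric_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "psychometric_fit"))
  jsonlite::write_json(
    list(params = fit$params, rss = fit$rss, n = fit$n,
         converged = fit$converged, g_fixed = fit$g_fixed,
         message = fit$message),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}
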