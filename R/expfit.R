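#' Logarithmic timescale grid
#'
#' A fixed grid of `n` timescales equidistantly spaced in log between
#' `tau_min` and `tau_max` (ps). The grid is the spectral "basis" of the
#' multi-exponential fit: its fineness, not an explicit regularizer, controls
#' the resolution of the recovered weight distribution.
#'
#' Two presets match common use: `"NH"` (n = 100, 1 ps to 100 ns) for
#' peptide backbone N-H bonds, and `"CH"` (n = 500, 1 fs to 1 us) for
#' detergent C-H bonds with substantial sub-ps dynamics.
#'
#' @param n grid size (>= 2), or a preset name `"NH"` / `"CH"`.
#' @param tau_min,tau_max grid end points in ps (0 < tau_min < tau_max).
#' @return An object of class `timescale_grid` with fields `n`, `tau_min`,
#'   `tau_max`, `taus`.
#' @export
timescale_grid <- function(n, tau_min = NULL, tau_max = NULL) {
  if (is.character(n)) {
    preset <- match.arg(n, c("NH", "CH"))
    return(switch(preset,
      NH = timescale_grid(100L, 1, 1e5),       # 1 ps .. 100 ns
      CH = timescale_grid(500L, 1e-3, 1e6)))   # 1 fs .. 1 us
  }
  n <- as.integer(n)
  if (n < 2L) stop("'n' must be >= 2")
  if (is.null(tau_min) || is.null(tau_max)) stop("'tau_min' and 'tau_max' required")
  if (tau_min <= 0 || tau_max <= tau_min) stop("need 0 < tau_min < tau_max")
  taus <- exp(seq(log(tau_min), log(tau_max), length.out = n))
  taus[1L] <- tau_min; taus[n] <- tau_max
  structure(list(n = n, tau_min = tau_min, tau_max = tau_max, taus = taus),
            class = "timescale_grid")
}

#' @export
print.timescale_grid <- function(x, ...) {
  cat(sprintf("<timescale_grid> n = %d, %g ps .. %g ps (ratio %.6g)\n",
              x$n, x$tau_min, x$tau_max, x$taus[2L] / x$taus[1L]))
  invisible(x)
}

.same_grid <- function(a, b)
  a$n == b$n && all(abs(a$taus - b$taus) <= 1e-9 * b$taus)

#' Construct a multi-exponential fit object directly
#'
#' Builds an `expfit` from known weights, e.g. an analytic mono- or
#' bi-exponential model, without fitting. Mostly useful for closed-form
#' relaxation calculations and testing.
#'
#' @param weights non-negative weights, one per grid timescale.
#' @param grid a [timescale_grid()].
#' @param site_label site label.
#' @return An object of class `expfit`.
#' @export
expfit <- function(weights, grid, site_label = "site") {
  stopifnot(inherits(grid, "timescale_grid"))
  weights <- as.numeric(weights)
  if (length(weights) != grid$n) stop("one weight per grid timescale required")
  if (any(weights < 0)) stop("weights must be non-negative")
  structure(list(grid = grid, weights = weights, residual = 0,
                 flags = logical(grid$n), site_label = site_label,
                 lags = NULL, values = NULL),
            class = "expfit")
}

#' Fit a non-negative sum of exponentials to a correlation function
#'
#' Solves min || C(t_k) - sum_i alpha_i exp(-t_k / tau_i) ||_2 over
#' alpha_i >= 0 on a fixed logarithmic timescale grid, by non-negative least
#' squares (Lawson-Hanson, via [pracma::lsqnonneg()]). All lag points enter
#' with equal weight. The fitted weight vector is the spectral
#' representation of the site's rotational dynamics: the weight at tau_i is
#' the relevance of that timescale for the rotational relaxation of the
#' bond.
#'
#' Individual weights at near-degenerate neighbouring grid points can trade
#' off between solvers; the reconstructed curve and spectral density are the
#' well-determined quantities.
#'
#' @param cf a [correlation_function()] with at least 10 lags.
#' @param grid a [timescale_grid()]; default the `"NH"` preset.
#' @param subsample optional integer: keep roughly this many log-spaced lag
#'   points instead of all of them (a speed knob for very finely saved
#'   trajectories; `NULL`, the default, fits every lag point).
#' @return An object of class `expfit` with fields `grid`, `weights`,
#'   `residual` (RMS misfit), `flags` (timescales zeroed by
#'   [filter_artificial_slow()]), `site_label`, and the input `lags` /
#'   `values`.
#' @seealso [spectral_density()], [effective_correlation_time()],
#'   [filter_artificial_slow()], [predict.expfit()]
#' @export
fit_exponentials <- function(cf, grid = timescale_grid("NH"), subsample = NULL) {
  stopifnot(inherits(cf, "correlation_function"), inherits(grid, "timescale_grid"))
  t <- cf$lags; y <- cf$values
  if (length(t) < 10L) stop("need at least 10 lag points to fit")
  if (any(!is.finite(y))) stop("non-finite correlation values")
  if (all(y == 0)) stop("all-zero correlation function")
  if (!is.null(subsample) && subsample < length(t)) {
    keep <- unique(c(1L, round(exp(seq(log(2), log(length(t)), length.out = subsample - 1L)))))
    t <- t[keep]; y <- y[keep]
  }
  A <- exp(-outer(t, grid$taus, "/"))
  sol <- pracma::lsqnonneg(A, y)
  w <- pmax(sol$x, 0)
  res <- sqrt(mean((y - drop(A %*% w))^2))
  structure(list(grid = grid, weights = w, residual = res,
                 flags = logical(grid$n), site_label = cf$site_label,
                 lags = cf$lags, values = cf$values),
            class = "expfit")
}

#' @export
print.expfit <- function(x, ...) {
  nz <- sum(x$weights > 0)
  cat(sprintf("<expfit> '%s': %d/%d non-zero weights on %g ps .. %g ps grid\n",
              x$site_label, nz, x$grid$n, x$grid$tau_min, x$grid$tau_max))
  cat(sprintf("  total weight %.4f, RMS misfit %.3g, tau_eff = %.4g ps\n",
              sum(x$weights), x$residual, effective_correlation_time(x)))
  if (any(x$flags))
    cat(sprintf("  %d slow timescale(s) zeroed as artificial\n", sum(x$flags)))
  invisible(x)
}

#' @export
summary.expfit <- function(object, ...) {
  w <- object$weights
  nz <- which(w > 0)
  out <- list(site_label = object$site_label,
              table = data.frame(tau_ps = object$grid$taus[nz], weight = w[nz]),
              total_weight = sum(w), residual = object$residual,
              tau_eff_ps = effective_correlation_time(object),
              n_flagged = sum(object$flags))
  class(out) <- "summary.expfit"
  out
}

#' @export
print.summary.expfit <- function(x, ...) {
  cat(sprintf("Multi-exponential spectral fit for '%s'\n", x$site_label))
  cat(sprintf("  total weight: %.4f   RMS misfit: %.3g   tau_eff: %.4g ps\n",
              x$total_weight, x$residual, x$tau_eff_ps))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.expfit <- function(object, ...) {
  stats::setNames(object$weights, sprintf("tau=%.4gps", object$grid$taus))
}

#' Evaluate the fitted correlation model
#'
#' @param object an `expfit`.
#' @param times lag times (ps) at which to evaluate the exponential sum;
#'   defaults to the lags the model was fitted on.
#' @param ... unused.
#' @return Numeric vector of C_fit(t).
#' @export
predict.expfit <- function(object, times = object$lags, ...) {
  if (is.null(times)) stop("no stored lags; supply 'times'")
  drop(exp(-outer(as.numeric(times), object$grid$taus, "/")) %*% object$weights)
}

#' @export
fitted.expfit <- function(object, ...) predict(object)

#' @export
residuals.expfit <- function(object, ...) {
  if (is.null(object$values)) stop("no stored data to compute residuals from")
  object$values - predict(object)
}

#' @export
plot.expfit <- function(x, log_time = TRUE, ...) {
  if (is.null(x$lags)) stop("no stored data to plot")
  pos <- x$lags > 0
  graphics::plot(x$lags[pos], x$values[pos], log = if (log_time) "x" else "",
                 xlab = "lag (ps)", ylab = "C(t)", pch = 16, cex = 0.4,
                 main = x$site_label, ...)
  graphics::lines(x$lags[pos], predict(x)[pos], col = 2, lwd = 2)
  invisible(x)
}

#' Zero artificially slow spectral weight
#'
#' Small but non-zero weight on the slowest grid timescale typically arises
#' from a correlation function that has not fully equilibrated to its zero
#' plateau, not from a real motion. If the weight on the slowest timescale
#' is below `weight_threshold` (default 1%), it is zeroed and flagged;
#' otherwise the fit is returned unchanged with a warning that a genuinely
#' large slow component is present.
#'
#' @param fit an `expfit`.
#' @param weight_threshold weight below which the slowest timescale is
#'   considered artificial (default 0.01).
#' @param k number of slowest grid points the filter may touch (default 1).
#' @return The (possibly modified) `expfit`.
#' @export
filter_artificial_slow <- function(fit, weight_threshold = 0.01, k = 1L) {
  stopifnot(inherits(fit, "expfit"))
  if (weight_threshold < 0 || weight_threshold > 1)
    stop("'weight_threshold' must be in [0, 1]")
  n <- fit$grid$n
  idx <- seq.int(n - as.integer(k) + 1L, n)
  for (i in rev(idx)) {
    w <- fit$weights[i]
    if (w == 0) next
    if (w < weight_threshold) {
      fit$weights[i] <- 0
      fit$flags[i] <- TRUE
    } else {
      warning(sprintf("weight %.3g on slow timescale %.4g ps exceeds the threshold %g; not removed (likely a real slow motion or a too-short trajectory)",
                      w, fit$grid$taus[i], weight_threshold))
      break
    }
  }
  fit
}

#' Spectral density of a fitted correlation model
#'
#' Analytic cosine transform of the exponential sum:
#' J(omega) = 2 sum_i alpha_i tau_i / (1 + omega^2 tau_i^2), in ps (with the
#' C(0) = 1 normalization of the correlation function; the Redfield layer
#' applies its own 1/5 normalization).
#'
#' @param fit an `expfit`.
#' @param omega angular frequency (rad/ps), scalar or vector, >= 0.
#' @return J(omega), same length as `omega`.
#' @export
spectral_density <- function(fit, omega) {
  stopifnot(inherits(fit, "expfit"))
  omega <- as.numeric(omega)
  if (any(omega < 0)) stop("'omega' must be >= 0")
  taus <- fit$grid$taus; w <- fit$weights
  vapply(omega, function(o) 2 * sum(w * taus / (1 + o^2 * taus^2)), numeric(1))
}

#' Effective correlation time
#'
#' Time integral of the fitted correlation function,
#' tau_eff = sum_i alpha_i tau_i = J(0)/2, in ps.
#'
#' @param fit an `expfit`.
#' @return tau_eff in ps.
#' @export
effective_correlation_time <- function(fit) {
  stopifnot(inherits(fit, "expfit"))
  sum(fit$weights * fit$grid$taus)
}
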