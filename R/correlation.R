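#' Rotational correlation function container
#'
#' Holds the P2 (second-order Legendre) rotational autocorrelation of one
#' site (or one group-averaged set of equivalent sites): lag times starting
#' at 0 with the trajectory's frame spacing, and dimensionless correlation
#' values in \[-0.5, 1\].
#'
#' @param lags lag times in ps, starting at 0, uniformly spaced.
#' @param values correlation values.
#' @param site_label site (or group) label.
#' @param n_frames_used number of frames the estimate used.
#' @param max_lag_fraction fraction of the total length used as maximum lag.
#' @param value_tol tolerance on the \[-0.5, 1\] range check (default 1e-6;
#'   noisy synthetic curves may need a larger band).
#' @return An object of class `correlation_function`.
#' @export
correlation_function <- function(lags, values, site_label = "site",
                                 n_frames_used = NA_integer_,
                                 max_lag_fraction = NA_real_,
                                 value_tol = 1e-6) {
  lags <- as.numeric(lags); values <- as.numeric(values)
  if (length(lags) != length(values)) stop("'lags' and 'values' lengths differ")
  if (length(lags) < 1L) stop("empty correlation function")
  if (abs(lags[1L]) > 1e-12) stop("lags must start at 0")
  if (length(lags) > 2L) {
    d <- diff(lags)
    if (any(abs(d - d[1L]) > 1e-9 * max(d[1L], 1)))
      stop("lags must be uniformly spaced")
  }
  if (any(!is.finite(values))) stop("non-finite correlation values")
  if (any(values > 1 + value_tol) || any(values < -0.5 - value_tol))
    stop("correlation values outside [-0.5, 1]")
  structure(list(lags = lags, values = values, site_label = site_label,
                 n_frames_used = n_frames_used,
                 max_lag_fraction = max_lag_fraction),
            class = "correlation_function")
}

#' @export
print.correlation_function <- function(x, ...) {
  cat(sprintf("<correlation_function> '%s': %d lags, 0..%g ps, C(0) = %.4f\n",
              x$site_label, length(x$lags), max(x$lags), x$values[1L]))
  invisible(x)
}

#' P2 rotational autocorrelation functions
#'
#' Computes, for each site of a bond-vector trajectory, the autocorrelation
#' of the second Legendre polynomial of the angle swept by the bond vector,
#' C(t) = < 3/2 cos^2(theta) - 1/2 >, averaging over all available time
#' origins for each lag. P2 of the inter-frame dot products is evaluated
#' through the identity P2(u.v) = (3 (u.v)^2 - 1)/2, which allows an exact
#' FFT formulation over the six component-product series.
#'
#' Lags run from 0 up to `max_lag_fraction` times the total trajectory
#' length. The default fraction is 1/100 for single sites and 1/20 when
#' `groups` averages several equivalent sites (e.g. the same carbon in every
#' detergent molecule of a micelle), where the extra molecule averaging
#' supports longer lags.
#'
#' @param vt a [vector_trajectory()] with at least 2 frames.
#' @param max_lag_fraction fraction (0, 1] of the total length to use as the
#'   maximum lag; `NULL` selects the defaults above.
#' @param groups optional named list of character vectors of site labels;
#'   the per-site correlation functions of each group are averaged into one
#'   function named after the group.
#' @param method `"fft"` (default, exact up to round-off) or `"direct"`.
#' @return A named list of [correlation_function()] objects.
#' @export
p2_autocorrelation <- function(vt, max_lag_fraction = NULL, groups = NULL,
                               method = c("fft", "direct")) {
  stopifnot(inherits(vt, "vector_trajectory"))
  method <- match.arg(method)
  if (vt$n_frames < 2L) stop("need at least 2 frames")
  if (is.null(max_lag_fraction))
    max_lag_fraction <- if (is.null(groups)) 1 / 100 else 1 / 20
  if (max_lag_fraction <= 0 || max_lag_fraction > 1)
    stop("'max_lag_fraction' must be in (0, 1]")

  L <- floor(max_lag_fraction * (vt$n_frames - 1L))
  if (L < 1L) L <- 1L
  if (L + 1L < 10L)
    warning(sprintf("only %d lags available at max_lag_fraction = %g; statistics will be poor",
                    L + 1L, max_lag_fraction))
  lags <- vt$dt * (0:L)

  per_site <- lapply(vt$vectors, function(v) {
    if (method == "fft") .p2_fft(v, L) else .p2_direct(v, L)
  })

  coarse <- vapply(per_site, function(cv) length(cv) > 1L && cv[2L] < 0.95, logical(1))
  if (any(coarse))
    warning(sprintf("C(dt) < 0.95 for site(s) %s: the trajectory saving frequency may be too coarse to resolve the fastest motions",
                    paste(sQuote(names(per_site)[coarse]), collapse = ", ")))

  mk <- function(vals, lab) correlation_function(
    lags, vals, site_label = lab, n_frames_used = vt$n_frames,
    max_lag_fraction = max_lag_fraction, value_tol = 1e-6)

  if (is.null(groups)) {
    out <- Map(mk, per_site, names(per_site))
  } else {
    if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
    out <- lapply(seq_along(groups), function(g) {
      members <- groups[[g]]
      if (length(members) == 0L) stop(sprintf("group '%s' is empty", names(groups)[g]))
      missing <- setdiff(members, names(per_site))
      if (length(missing))
        stop(sprintf("group '%s' names unknown site(s): %s", names(groups)[g],
                     paste(sQuote(missing), collapse = ", ")))
      mk(Reduce(`+`, per_site[members]) / length(members), names(groups)[g])
    })
    names(out) <- names(groups)
  }
  out
}

# Exact all-origin P2 autocorrelation via FFT of the six component products.
.p2_fft <- function(v, L) {
  n <- nrow(v)
  m <- stats::nextn(n + L + 1L)
  acc <- numeric(L + 1L)
  idx <- list(c(1L, 1L), c(2L, 2L), c(3L, 3L), c(1L, 2L), c(1L, 3L), c(2L, 3L))
  for (p in idx) {
    s <- v[, p[1L]] * v[, p[2L]]
    w <- if (p[1L] == p[2L]) 1 else 2
    f <- stats::fft(c(s, numeric(m - n)))
    a <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / m
    acc <- acc + w * a[seq_len(L + 1L)]
  }
  counts <- n - 0:L
  1.5 * acc / counts - 0.5
}

# Straightforward O(n * L) evaluation; used as a cross-check and for tiny inputs.
.p2_direct <- function(v, L) {
  n <- nrow(v)
  vapply(0:L, function(l) {
    if (l == 0L) return(1.5 * mean(rowSums(v * v)^2) - 0.5)
    d <- rowSums(v[1:(n - l), , drop = FALSE] * v[(1 + l):n, , drop = FALSE])
    1.5 * mean(d^2) - 0.5
  }, numeric(1))
}

#' Average correlation functions
#'
#' Arithmetic mean of several correlation functions on identical lag grids,
#' e.g. replicate simulations of the same site or equivalent sites across
#' molecules.
#'
#' @param cfs list of [correlation_function()] objects with identical lags.
#' @param label label for the averaged function.
#' @return A [correlation_function()].
#' @export
average_correlation <- function(cfs, label = "average") {
  stopifnot(length(cfs) >= 1L)
  lags <- cfs[[1L]]$lags
  for (cf in cfs) {
    stopifnot(inherits(cf, "correlation_function"))
    if (length(cf$lags) != length(lags) || any(abs(cf$lags - lags) > 1e-9 * pmax(lags, 1)))
      stop("correlation functions have different lag grids")
  }
  vals <- Reduce(`+`, lapply(cfs, `[[`, "values")) / length(cfs)
  correlation_function(lags, vals, site_label = label,
                       n_frames_used = cfs[[1L]]$n_frames_used,
                       max_lag_fraction = cfs[[1L]]$max_lag_fraction)
}
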