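#' Simulate an isotropically diffusing bond vector
#'
#' Brownian rotational diffusion of a unit vector: each step applies a small
#' random rotation in the tangent plane with total angular variance
#' 4 D_r dt (two rotational degrees of freedom). The exact P2
#' autocorrelation of this process is exp(-6 D_r t), which makes the
#' trajectory a ground-truth oracle for the whole correlation -> fit ->
#' relaxation chain. The small-angle scheme is accurate for 6 D_r dt << 1;
#' a warning is emitted above 0.01.
#'
#' All randomness comes from R's RNG: call `set.seed()` (or pass `seed`) for
#' bit-reproducible trajectories.
#'
#' @param D_r rotational diffusion coefficient in ns^-1 (tau_c = 1/(6 D_r)).
#' @param dt time step in ps.
#' @param n_steps number of frames.
#' @param seed optional integer seed.
#' @param n_sites number of independent vectors to simulate.
#' @param labels site labels.
#' @return A [vector_trajectory()].
#' @export
simulate_isotropic_rotor <- function(D_r, dt = 1, n_steps, seed = NULL,
                                     n_sites = 1L,
                                     labels = paste0("rotor", seq_len(n_sites))) {
  if (D_r <= 0 || dt <= 0 || n_steps < 2L) stop("invalid rotor specification")
  D_ps <- D_r * 1e-3
  if (6 * D_ps * dt > 0.01)
    warning(sprintf("6 D_r dt = %.3g > 0.01: time step too coarse for accurate rotational diffusion", 6 * D_ps * dt))
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(2 * D_ps * dt)
  vecs <- lapply(seq_len(n_sites), function(i)
    .cpp_isotropic_rotor(as.integer(n_steps), sigma, .random_unit_vector()))
  names(vecs) <- labels
  vector_trajectory(dt * (seq_len(n_steps) - 1L), vecs, labels,
                    normalize = TRUE)
}

#' Simulate overall tumbling plus fast local wobble
#'
#' Superimposes wobble-in-a-cone internal motion on an isotropically
#' diffusing director. The cone semi-angle is chosen so that the cone order
#' parameter S = cos(theta0)(1 + cos(theta0))/2 satisfies S^2 = `S2`, and
#' the internal diffusion coefficient is set from the closed-form effective
#' correlation time of diffusion in a cone so that the internal decay
#' time is `tau_int`. The target correlation function is approximately
#' C(t) = \[S^2 + (1 - S^2) exp(-t/tau_int)\] exp(-6 D_r t).
#'
#' @inheritParams simulate_isotropic_rotor
#' @param S2 squared generalized order parameter in (0, 1]; `S2 = 1`
#'   degenerates to [simulate_isotropic_rotor()].
#' @param tau_int internal (wobble) correlation time in ps.
#' @return A [vector_trajectory()].
#' @export
simulate_two_mode <- function(D_r, dt = 1, n_steps, S2, tau_int,
                              seed = NULL, n_sites = 1L,
                              labels = paste0("two_mode", seq_len(n_sites))) {
  if (D_r <= 0 || dt <= 0 || n_steps < 2L) stop("invalid rotor specification")
  if (S2 <= 0 || S2 > 1) stop("'S2' must be in (0, 1]")
  if (tau_int <= 0) stop("'tau_int' must be positive")
  if (!is.null(seed)) set.seed(seed)
  D_ps <- D_r * 1e-3
  if (6 * D_ps * dt > 0.01)
    warning(sprintf("6 D_r dt = %.3g > 0.01: time step too coarse", 6 * D_ps * dt))
  sim_one <- function() {
    if (S2 == 1)
      return(.cpp_isotropic_rotor(as.integer(n_steps), sqrt(2 * D_ps * dt),
                                  .random_unit_vector()))
    theta0 <- cone_semiangle(S2)
    D_w <- .cone_diffusion_coefficient(S2, tau_int)
    sig_w <- sqrt(2 * D_w * dt)
    if (sig_w > 0.4 * theta0)
      warning("time step too coarse for the requested internal timescale; reduce dt")
    .cpp_two_mode_rotor(as.integer(n_steps), sqrt(2 * D_ps * dt),
                        sig_w, cos(theta0), .random_unit_vector())
  }
  vecs <- stats::setNames(lapply(seq_len(n_sites), function(i) sim_one()), labels)
  vector_trajectory(dt * (seq_len(n_steps) - 1L), vecs, labels,
                    normalize = TRUE)
}

#' Cone semi-angle for a given order parameter
#'
#' Inverts the wobble-in-a-cone relation S = cos(theta0)(1 + cos(theta0))/2
#' for the cone semi-angle.
#'
#' @param S2 squared order parameter in (0, 1].
#' @return Cone semi-angle theta0 in radians.
#' @export
cone_semiangle <- function(S2) {
  if (S2 <= 0 || S2 > 1) stop("'S2' must be in (0, 1]")
  S <- sqrt(S2)
  x0 <- (-1 + sqrt(1 + 8 * S)) / 2
  acos(min(1, x0))
}

# Wobbling diffusion coefficient (ps^-1) giving an effective internal
# correlation time tau_int (ps) for diffusion inside a cone of semi-angle
# theta0 = cone_semiangle(S2), using the closed-form effective time
# D_w tau (1 - S^2) = f(cos theta0) of the cone model.
.cone_diffusion_coefficient <- function(S2, tau_int) {
  x0 <- cos(cone_semiangle(S2))
  f <- x0^2 * (1 + x0)^2 / (2 * (x0 - 1)) * (log((1 + x0) / 2) + (1 - x0) / 2) +
    (1 - x0) * (6 + 8 * x0 - x0^2 - 12 * x0^3 - 7 * x0^4) / 24
  f / (tau_int * (1 - S2))
}

.random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

#' Analytic multi-exponential correlation function
#'
#' Evaluates C(t) = sum_i alpha_i exp(-t/tau_i) exactly on a given time
#' grid, optionally with additive Gaussian noise - a noise-free (or
#' noise-controlled) stand-in for a simulated correlation function.
#'
#' @param weights non-negative weights with sum <= 1.
#' @param taus timescales in ps (> 0), same length as `weights`.
#' @param times lag times in ps, starting at 0, uniformly spaced.
#' @param noise_sd standard deviation of additive Gaussian noise (default 0).
#' @param seed optional seed for the noise.
#' @param label site label.
#' @return A [correlation_function()].
#' @export
analytic_correlation <- function(weights, taus, times, noise_sd = 0,
                                 seed = NULL, label = "analytic") {
  weights <- as.numeric(weights); taus <- as.numeric(taus)
  if (length(weights) != length(taus)) stop("'weights' and 'taus' lengths differ")
  if (any(weights < 0) || sum(weights) > 1 + 1e-9)
    stop("weights must be non-negative with sum <= 1")
  if (any(taus <= 0)) stop("'taus' must be positive")
  vals <- drop(exp(-outer(as.numeric(times), taus, "/")) %*% weights)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    vals <- vals + stats::rnorm(length(vals), sd = noise_sd)
  }
  correlation_function(times, vals, site_label = label,
                       value_tol = 1e-6 + 6 * noise_sd)
}
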