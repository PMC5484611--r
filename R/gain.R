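#' Gaussian-input gain function of a binary threshold neuron
#'
#' Expected activation probability of a threshold unit whose summed input is
#' Gaussian with mean `mu` and standard deviation `sigma`:
#' `phi = erfc((theta - mu) / (sqrt(2) sigma)) / 2 = Phi((mu - theta) / sigma)`,
#' with `Phi` the standard normal CDF. Smooth and strictly increasing in `mu`.
#'
#' @param mu Mean input (input units). Vectorized.
#' @param sigma Input standard deviation (input units), strictly positive.
#' @param theta Activation threshold (input units).
#' @return Activation probability in `[0, 1]`.
#' @seealso [susceptibility()], [dsusceptibility_dmu()]
#' @examples
#' gain_phi(0, 1, 0)            # 0.5 at threshold
#' gain_phi(10, 1, 0)           # saturates at 1
#' @export
gain_phi <- function(mu, sigma, theta) {
  check_sigma(sigma)
  pnorm((mu - theta) / sigma)
}

#' Susceptibility: slope of the gain function
#'
#' `S = d phi / d mu = exp(-(mu - theta)^2 / (2 sigma^2)) / (sqrt(2 pi) sigma)`,
#' the linear gain of a population to a slow change of its mean input.
#' Always positive, maximal at `mu = theta` where it equals
#' `1 / (sqrt(2 pi) sigma)`.
#'
#' @inheritParams gain_phi
#' @return Susceptibility in 1/(input units).
#' @export
susceptibility <- function(mu, sigma, theta) {
  check_sigma(sigma)
  dnorm((mu - theta) / sigma) / sigma
}

#' Curvature of the gain function
#'
#' `dS/dmu = ((theta - mu) / sigma^2) * S(mu, sigma, theta)`, the second
#' derivative of the gain. Its sign equals `sign(theta - mu)`; it vanishes at
#' the susceptibility peak `mu = theta`. This curvature is what converts a
#' modulation of the mean input into a modulation of the *transmission* of
#' covariances (the susceptibility terms of the covariance response).
#'
#' @inheritParams gain_phi
#' @return Curvature in 1/(input units)^2.
#' @export
dsusceptibility_dmu <- function(mu, sigma, theta) {
  check_sigma(sigma)
  (theta - mu) / sigma^2 * susceptibility(mu, sigma, theta)
}

check_sigma <- function(sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    abort("`sigma` must be strictly positive.", class = "oscibin_invalid_parameter")
  }
  invisible(sigma)
}

# Fast internal input-moment computation on plain vectors/matrices.
# mu_a   = sum_b K_ab J_ab m_b + h
# sig2_net,a = [(K*J) c (K*J)^T]_aa + sum_b K_ab J_ab^2 a_b   (full Eq-19 part)
# sig2_shot,a = sum_b K_ab J_ab^2 a_b                          (binomial part)
# sig2_a = sig2_net,a + sigma_noise,a^2
compute_input_moments <- function(m, cmat, spec, external_input = 0) {
  KJ <- spec$K * spec$J
  a <- m * (1 - m)
  mu <- as.vector(KJ %*% m) + external_input
  sig2_shot <- as.vector((spec$K * spec$J^2) %*% a)
  sig2_cov <- rowSums((KJ %*% cmat) * KJ)
  sig2_net <- sig2_shot + sig2_cov
  sigma <- sqrt(pmax(sig2_net, 0) + spec$sigma_noise^2)
  list(
    mu = setNames(mu, spec$labels),
    sigma = setNames(sigma, spec$labels),
    sigma_network = setNames(sqrt(pmax(sig2_net, 0)), spec$labels),
    sigma_shot = setNames(sqrt(sig2_shot), spec$labels)
  )
}

#' Mean and width of the summed synaptic input per population
#'
#' Computes the Gaussian input moments implied by a moment state: the mean
#' input `mu`, and the decomposition of the input variance into the
#' network-generated part and the private-noise part,
#' `sigma^2 = sigma_network^2 + sigma_noise^2`. The network part itself
#' contains the shot-noise (binomial) contribution of conditionally
#' independent senders, `sigma_shot^2 = sum_b K_ab J_ab^2 m_b (1 - m_b)`
#' (also reported separately), plus the contribution of pairwise covariances
#' among the senders, `[(K * J) c (K * J)^T]_aa`.
#'
#' @param state A [moment_state()] (or a [stationary_state][solve_stationary]
#'   object, whose moments are then used).
#' @param spec A [network_spec()].
#' @param external_input Constant external offset added to every `mu`
#'   (input units); the instantaneous value of the drive, for example.
#' @return A tibble with one row per population: `population`, `mu`, `sigma`,
#'   `sigma_network`, `sigma_shot`, `sigma_noise`.
#' @examples
#' spec <- preset_network("single_inhibitory")
#' st <- moment_state(m = 0.3, spec = spec)
#' input_moments(st, spec)   # sigma_shot = sqrt(105) ~ 10.25
#' @export
input_moments <- function(state, spec, external_input = 0) {
  if (inherits(state, "stationary_state")) {
    state <- moment_state(state$m, state$c, spec)
  }
  if (!inherits(state, "moment_state")) abort("`state` must be a moment_state.")
  if (length(state$m) != n_pop(spec)) abort("state/spec dimension mismatch.")
  im <- compute_input_moments(state$m, state$c, spec, external_input)
  tibble(
    population = spec$labels,
    mu = unname(im$mu),
    sigma = unname(im$sigma),
    sigma_network = unname(im$sigma_network),
    sigma_shot = unname(im$sigma_shot),
    sigma_noise = unname(spec$sigma_noise)
  )
}

#' Calibrate thresholds to target mean activities
#'
#' Sets the activation thresholds of all dynamic populations such that the
#' stationary mean activities equal `target_m`. Uses the stationarity
#' condition `phi(mu, sigma) = m`, inverted as
#' `theta = mu + sqrt(2) sigma erfc^{-1}(2 m) = mu + sigma qnorm(1 - m)`,
#' and iterates jointly with the exact stationary covariance solution (the
#' input width `sigma` depends on the covariances, which depend on the
#' thresholds) until self-consistency.
#'
#' @param spec A [network_spec()] (thresholds may be unset).
#' @param target_m Named vector of target means in `(0, 1)` for the dynamic
#'   populations; defaults to `spec$target_m`.
#' @param tol Convergence tolerance on the threshold/covariance updates.
#' @param max_iter Maximum number of iterations.
#' @return The spec with `theta` filled in and `target_m` recorded;
#'   attributes `iterations` and `residual` report the final fixed-point
#'   residual `max |phi(m) - m|`.
#' @examples
#' spec <- preset_network("biological_EI")  # presets ship pre-calibrated
#' solve_stationary(spec)$m
#' @export
calibrate_thresholds <- function(spec, target_m = spec$target_m,
                                 tol = 1e-13, max_iter = 10000) {
  if (is.null(target_m)) abort("no `target_m` given and none stored in the spec.")
  dyn <- spec$dynamic
  target_m <- expand_named(target_m, spec$labels[dyn], "target_m")
  if (any(target_m <= 0 | target_m >= 1)) abort("`target_m` must lie in (0, 1).")

  m <- ifelse(dyn, NA_real_, spec$m_clamped)
  m[spec$labels[dyn]] <- target_m
  names(m) <- spec$labels
  cmat <- matrix(0, n_pop(spec), n_pop(spec))
  theta <- setNames(rep(0, n_pop(spec)), spec$labels)
  z <- qnorm(1 - target_m)  # = sqrt(2) * erfcinv(2 * target_m)

  converged <- FALSE
  for (it in seq_len(max_iter)) {
    im <- compute_input_moments(m, cmat, spec)
    theta_new <- theta
    theta_new[dyn] <- im$mu[dyn] + z * im$sigma[dyn]
    S <- rep(0, n_pop(spec))
    S[dyn] <- susceptibility(im$mu[dyn], im$sigma[dyn], theta_new[dyn])
    W <- S * (spec$K * spec$J)
    c_new <- solve_stationary_covariance(W, m * (1 - m), spec$N)
    delta <- max(max(abs(theta_new - theta)[dyn]), max(abs(c_new - cmat)))
    theta <- 0.5 * theta + 0.5 * theta_new
    cmat <- 0.5 * cmat + 0.5 * c_new
    if (delta < tol) { converged <- TRUE; break }
  }
  im <- compute_input_moments(m, cmat, spec)
  resid <- max(abs(gain_phi(im$mu[dyn], im$sigma[dyn], theta[dyn]) - target_m))
  if (!converged || resid > 1e-10) {
    abort(sprintf("threshold calibration did not converge (residual %.3g after %d iterations).",
                  resid, it),
          class = "oscibin_convergence_error")
  }
  spec$theta[dyn] <- theta[dyn]
  spec$target_m <- target_m
  attr(spec, "calibration") <- list(iterations = it, residual = resid)
  spec
}
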