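# state packing: dynamic means first, then the upper triangle (incl. diagonal)
# of the population covariance matrix. Symmetry is structural, not integrated.
pack_state <- function(m_dyn, cmat) {
  c(m_dyn, cmat[upper.tri(cmat, diag = TRUE)])
}

unpack_state <- function(x, spec) {
  P <- n_pop(spec)
  dyn <- spec$dynamic
  m <- ifelse(dyn, NA_real_, spec$m_clamped)
  m[dyn] <- x[seq_len(sum(dyn))]
  names(m) <- spec$labels
  cmat <- matrix(0, P, P)
  cmat[upper.tri(cmat, diag = TRUE)] <- x[-seq_len(sum(dyn))]
  cmat <- cmat + t(cmat) - diag(diag(cmat), nrow = P)
  list(m = m, c = cmat)
}

moment_rhs <- function(t, x, pars) {
  spec <- pars$spec
  dyn <- spec$dynamic
  st <- unpack_state(x, spec)
  h_t <- pars$h_ext * sin(pars$omega * t)
  im <- compute_input_moments(st$m, st$c, spec, external_input = h_t)
  sigma <- if (is.null(pars$sigma_frozen)) im$sigma else pars$sigma_frozen
  P <- n_pop(spec)
  S <- rep(0, P)
  S[dyn] <- susceptibility(im$mu[dyn], sigma[dyn], spec$theta[dyn])
  a <- st$m * (1 - st$m)
  Mterm <- S * (pars$T_mat %*% (st$c + diag(a / spec$N, nrow = P)))
  dc <- (-2 * st$c + Mterm + t(Mterm)) / spec$tau
  dm_dyn <- (-st$m[dyn] + gain_phi(im$mu[dyn], sigma[dyn], spec$theta[dyn])) / spec$tau
  list(pack_state(dm_dyn, dc))
}

#' Integrate the full time-dependent mean-field moment equations
#'
#' Numerically integrates the coupled population equations
#' `tau dm/dt = -m + phi(mu(m, h sin(omega t)), sigma(m, c))` and
#' `tau dc/dt = -2c + S (K * J)(c + diag(a / N)) + transpose`, with
#' `a(t) = m(t)(1 - m(t))`, using a stiff-capable adaptive integrator
#' (`deSolve::lsoda`). No linearization is involved; this is the reference
#' the closed-form linear response is validated against.
#'
#' By default (`sigma_dynamics = "full"`) the input width `sigma(t)` follows
#' the instantaneous moments, including the covariance contribution. With
#' `sigma_dynamics = "frozen"` the width is pinned at its stationary value
#' (the approximation the analytic layer makes), which isolates the
#' mechanisms the linear-response decomposition describes.
#'
#' @param spec A [network_spec()] with thresholds set.
#' @param drive A [drive_spec()].
#' @param periods Number of drive periods to cover *after* the transient
#'   window (used when `drive$f > 0`). The transient is
#'   `max(20 tau, 2 periods)`, rounded up to whole periods.
#' @param t_end Total duration in ms; overrides `periods` (required when
#'   `drive$f == 0`).
#' @param init Optional [moment_state()] initial condition; defaults to the
#'   stationary state.
#' @param sigma_dynamics `"full"` (default) or `"frozen"`.
#' @param samples_per_period Output grid resolution (ignored if `f = 0`).
#' @param rtol,atol Integrator tolerances.
#' @return A `moment_trajectory`: a tibble with columns `time` (ms),
#'   `m_<pop>` and `c_<pop><pop>`, carrying the spec, drive, the analysis
#'   start time and integration settings as attributes.
#' @examples
#' spec <- preset_network("biological_EI")
#' traj <- integrate_moments(spec, drive_spec(1, 80), periods = 6)
#' extract_harmonics(traj)
#' @export
integrate_moments <- function(spec, drive, periods = 8, t_end = NULL,
                              init = NULL, sigma_dynamics = c("full", "frozen"),
                              samples_per_period = 64,
                              rtol = 1e-8, atol = 1e-10) {
  sigma_dynamics <- match.arg(sigma_dynamics)
  stopifnot(inherits(spec, "network_spec"), inherits(drive, "drive_spec"))
  dyn <- spec$dynamic

  st0 <- NULL
  if (is.null(init) || sigma_dynamics == "frozen") st0 <- solve_stationary(spec)
  if (is.null(init)) init <- moment_state(st0$m, st0$c, spec)
  if (!inherits(init, "moment_state")) abort("`init` must be a moment_state.")

  if (drive$f > 0) {
    period <- 1000 / drive$f
    trans_periods <- ceiling(max(20 * spec$tau, 2 * period) / period)
    t_start <- trans_periods * period
    t_total <- t_start + periods * period
    dt <- period / samples_per_period
    times <- seq(0, t_total, by = dt)
  } else {
    if (is.null(t_end)) abort("`t_end` is required when the drive frequency is 0.")
    t_start <- 0
    times <- seq(0, t_end, length.out = 401)
  }

  pars <- list(
    spec = spec, h_ext = drive$h_ext, omega = drive$omega,
    T_mat = spec$K * spec$J,
    sigma_frozen = if (sigma_dynamics == "frozen") st0$sigma else NULL
  )
  x0 <- pack_state(init$m[dyn], init$c)
  sol <- deSolve::lsoda(y = x0, times = times, func = moment_rhs, parms = pars,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    abort(sprintf("moment ODE integration failed at t = %.3f ms.", max(sol[, 1])),
          class = "oscibin_integration_error")
  }
  nm <- sum(dyn)
  mvals <- sol[, 1 + seq_len(nm), drop = FALSE]
  if (any(mvals < -1e-6 | mvals > 1 + 1e-6)) {
    abort("mean activities left [0, 1]: the moment closure broke down.",
          class = "oscibin_model_violation")
  }

  P <- n_pop(spec)
  labs <- spec$labels
  out <- tibble(time = sol[, 1])
  for (k in seq_len(P)) {
    out[[paste0("m_", labs[k])]] <-
      if (dyn[k]) pmin(1, pmax(0, sol[, 1 + which(which(dyn) == k)])) else
        rep(spec$m_clamped[k], nrow(sol))
  }
  iu <- which(upper.tri(matrix(0, P, P), diag = TRUE), arr.ind = TRUE)
  iu <- iu[order(iu[, 2], iu[, 1]), , drop = FALSE]  # column-major = packing order
  for (k in seq_len(nrow(iu))) {
    out[[paste0("c_", labs[iu[k, 1]], labs[iu[k, 2]])]] <- sol[, 1 + nm + k]
  }
  structure(
    out,
    class = c("moment_trajectory", class(out)),
    spec = spec, drive = drive, analysis_start = t_start,
    sigma_dynamics = sigma_dynamics, rtol = rtol, atol = atol
  )
}

#' Extract Fourier harmonics from a cyclostationary trajectory
#'
#' Projects every trajectory component onto the drive harmonics over an
#' integer number of periods, after discarding the transient. The
#' convention is `x(t) = X0 + sum_k Im(Xk exp(i k omega t))`, estimated as
#' `X0 = <x>` and `Xk = 2i <x exp(-i k omega t)>`; a pure input-following
#' signal `beta sin(omega t)` yields `X1 = beta` with phase 0, and
#' `beta cos(omega t)` yields `X1 = i beta` (phase `+pi/2`).
#'
#' @param traj A `moment_trajectory` from [integrate_moments()], or any
#'   tibble with a uniform `time` column (ms) and numeric component columns
#'   (then `drive` and `analysis_start` must be supplied).
#' @param max_order Highest harmonic to extract (default 2).
#' @param drive,analysis_start Override/supply the drive and the start of
#'   the analysis window (defaults come from the trajectory attributes).
#' @return A `harmonic_set` tibble: `kind` (`"mean"`/`"covariance"`),
#'   `component`, `order`, `re`, `im`, `amplitude`, `phase`.
#' @export
extract_harmonics <- function(traj, max_order = 2, drive = NULL,
                              analysis_start = NULL) {
  drive <- drive %||% attr(traj, "drive")
  analysis_start <- analysis_start %||% attr(traj, "analysis_start") %||% 0
  if (is.null(drive) || drive$f <= 0) {
    abort("harmonic extraction needs a drive with f > 0.")
  }
  period <- 1000 / drive$f
  tt <- traj$time
  keep <- tt >= analysis_start - 1e-9
  if (!any(keep)) abort("no samples after the transient.", class = "oscibin_insufficient_data")
  tt <- tt[keep]
  dt <- diff(tt)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
    abort("harmonic extraction requires a uniform time grid.")
  }
  spp <- period / dt[1]
  if (abs(spp - round(spp)) > 1e-6) {
    abort("the time grid must subdivide the drive period evenly.")
  }
  spp <- round(spp)
  n_full <- floor(length(tt) / spp)
  if (n_full < 5) {
    abort("need at least 5 full drive periods after the transient.",
          class = "oscibin_insufficient_data")
  }
  idx <- seq_len(n_full * spp)
  tt <- tt[idx]
  omega <- drive$omega

  cols <- setdiff(names(traj), "time")
  res <- purrr::map(cols, function(cn) {
    x <- traj[[cn]][keep][idx]
    coefs <- purrr::map(seq_len(max_order), function(k) {
      2i * mean(x * exp(-1i * k * omega * tt))
    })
    tibble(
      kind = if (startsWith(cn, "m_")) "mean" else "covariance",
      component = sub("^[mc]_", "", cn),
      order = 0:max_order,
      value = c(complex(real = mean(x)), unlist(coefs))
    )
  })
  out <- bind_rows(res)
  out <- mutate(out,
                re = Re(.data$value), im = Im(.data$value),
                amplitude = Mod(.data$value), phase = Arg(.data$value),
                value = NULL)
  class(out) <- c("harmonic_set", class(out))
  out
}
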