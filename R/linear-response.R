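#' First-harmonic linear response of the mean activities
#'
#' Closed-form complex amplitude of the modulation of the population mean
#' activities under a weak sinusoidal drive, to first order in `h_ext`.
#' With the convention `delta m(t) = Im(M1 exp(i omega t))` (so a drive
#' `h_ext sin(omega t)` that is followed 1:1 gives a real, positive `M1`),
#'
#' `M1 = U diag(1 / (i tau omega + 1 - lambda)) U^-1 S h_ext`,
#'
#' where `(U, lambda)` is the eigensystem of the effective connectivity
#' `W = diag(S) (K * J)`. Every eigenmode responds as a first-order low-pass
#' filter: the phase lags the drive and the amplitude decays like `1/omega`
#' at high frequency. Eigenvalue pairs with nonzero imaginary part produce a
#' resonance near `tau omega = |Im(lambda)|`.
#'
#' @param st A [stationary_state][solve_stationary] (stable, diagonalizable).
#' @param f Drive frequency in Hz (scalar).
#' @param h_ext Drive amplitude in input units.
#' @return Named complex vector `M1`, one entry per population (zero for
#'   clamped populations).
#' @examples
#' st <- solve_stationary(preset_network("biological_EI"))
#' Mod(mean_response(st, f = 80)) / st$spec$tau * 1000  # rate modulation, Hz
#' @export
mean_response <- function(st, f, h_ext = 1) {
  stopifnot(inherits(st, "stationary_state"), length(f) == 1, f >= 0)
  omega <- 2 * pi * f / 1000
  L <- 1 / (1i * st$spec$tau * omega + 1 - st$lambda)
  M1 <- as.vector(st$U %*% (L * (st$Uinv %*% st$S))) * h_ext
  setNames(M1, st$spec$labels)
}

#' First-harmonic linear response of the covariances, with mechanistic
#' decomposition
#'
#' Solves the linearized covariance equation for the complex first-harmonic
#' amplitude `C1` of the pairwise covariance modulation,
#' `delta c(t) = Im(C1 exp(i omega t))`, in the eigenbasis of the effective
#' connectivity: for each (symmetrized) inhomogeneity `A`,
#' `C1 = U [ (U^-1 (A + A^T) U^-T)_ab / (i tau omega + 2 - lambda_a - lambda_b) ] U^T`.
#'
#' The inhomogeneity splits additively into the three mechanisms by which a
#' global drive reaches the covariances:
#'
#' * **direct drive** (`C1_Sh`): the drive itself modulates the
#'   susceptibility; `A_Sh = h_ext V c_total`, once low-pass filtered.
#' * **recurrent drive** (`C1_Sm`): the oscillating mean activities feed
#'   back through the network and modulate the susceptibility;
#'   `A_Sm = diag(T M1) V c_total`, filtered twice (it contains `M1`).
#' * **modulated autocovariances** (`C1_a`): the single-unit variances
#'   `a(t) = m(t)(1 - m(t))` follow the mean and drive the pairwise
#'   covariances; `A_a = W diag((1 - 2 m) / N * M1)`, filtered twice.
#'
#' Here `T = K * J`, `V = diag(dS/dmu) T` and `c_total = c + diag(a / N)`.
#' The decomposition is exact: `C1 = C1_Sh + C1_Sm + C1_a` by construction.
#' In balanced networks the direct and recurrent drive have opposite sign at
#' low frequency and partially cancel.
#'
#' @inheritParams mean_response
#' @return An object of class `linear_response` with fields `f`, `omega`,
#'   `h_ext`, `M1`, `C1`, `C1_Sh`, `C1_Sm`, `C1_a` (complex symmetric
#'   matrices), and the auxiliary matrices `T_mat`, `V`.
#' @examples
#' st <- solve_stationary(preset_network("single_inhibitory"))
#' lr <- covariance_response(st, f = 10)
#' tidy(lr)
#' @export
covariance_response <- function(st, f, h_ext = 1) {
  stopifnot(inherits(st, "stationary_state"), length(f) == 1, f >= 0)
  spec <- st$spec
  omega <- 2 * pi * f / 1000
  P <- n_pop(spec)
  dyn <- spec$dynamic

  M1 <- mean_response(st, f, h_ext)
  T_mat <- spec$K * spec$J
  dSdmu <- rep(0, P)
  dSdmu[dyn] <- dsusceptibility_dmu(st$mu[dyn], st$sigma[dyn], spec$theta[dyn])
  V <- dSdmu * T_mat
  Vc <- V %*% st$c_total

  A_Sh <- h_ext * Vc
  A_Sm <- as.vector(T_mat %*% M1) * Vc
  A_a <- st$W %*% diag(((1 - 2 * st$m) / spec$N) * M1, nrow = P)

  den <- 1i * spec$tau * omega + 2 - outer(st$lambda, st$lambda, `+`)
  solve_term <- function(A) {
    As <- A + t(A)
    Ct <- (st$Uinv %*% As %*% t(st$Uinv)) / den
    C1 <- st$U %*% Ct %*% t(st$U)
    asym <- max(abs(C1 - t(C1)))
    if (asym > 1e-10) {
      warn(sprintf("covariance response asymmetry %.2e before symmetrization.", asym))
    }
    C1 <- (C1 + t(C1)) / 2
    dimnames(C1) <- dimnames(spec$J)
    C1
  }
  C1_Sh <- solve_term(A_Sh)
  C1_Sm <- solve_term(A_Sm)
  C1_a <- solve_term(A_a)

  structure(
    list(
      f = f, omega = omega, h_ext = h_ext,
      labels = spec$labels, tau = spec$tau,
      M1 = M1,
      C1 = C1_Sh + C1_Sm + C1_a,
      C1_Sh = C1_Sh, C1_Sm = C1_Sm, C1_a = C1_a,
      T_mat = T_mat, V = V
    ),
    class = "linear_response"
  )
}

#' @export
print.linear_response <- function(x, ...) {
  cat(sprintf("<linear_response> f = %g Hz, h_ext = %g\n", x$f, x$h_ext))
  print(tidy(x), n = 20)
  invisible(x)
}

#' @describeIn covariance_response Long tibble of complex amplitudes: one
#'   row per component (each mean `m_a`, each covariance `c_ab`) and term
#'   (`total`, and for covariances also `Sh`, `Sm`, `a`), with `amplitude`,
#'   `phase`, `re`, `im`.
#' @param x A `linear_response`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.linear_response <- function(x, ...) {
  labs <- x$labels
  P <- length(labs)
  iu <- which(upper.tri(matrix(0, P, P), diag = TRUE), arr.ind = TRUE)
  cov_rows <- function(M, term) {
    tibble(
      kind = "covariance",
      component = paste0(labs[iu[, 1]], labs[iu[, 2]]),
      term = term,
      value = M[iu]
    )
  }
  out <- bind_rows(
    tibble(kind = "mean", component = labs, term = "total", value = unname(x$M1)),
    cov_rows(x$C1, "total"),
    cov_rows(x$C1_Sh, "Sh"),
    cov_rows(x$C1_Sm, "Sm"),
    cov_rows(x$C1_a, "a")
  )
  out$f_hz <- x$f
  mutate(out,
         amplitude = Mod(.data$value),
         phase = Arg(.data$value),
         re = Re(.data$value),
         im = Im(.data$value),
         value = NULL)
}

#' Resonance frequencies implied by complex eigenvalues
#'
#' Each complex-conjugate eigenvalue pair of the effective connectivity `W`
#' produces a damped resonance of the mean activities at
#' `f_res = |Im(lambda)| / (2 pi tau)`; the covariance modes additionally
#' mix kernels at the doubled frequency `2 f_res`. Networks whose `W` has
#' only real eigenvalues have no resonance (empty result). The observed
#' maximum of the mean response is generally *near* (not exactly at) `f_res`
#' because the populations mix several eigenmodes.
#'
#' @param st A [stationary_state][solve_stationary].
#' @return A tibble with one row per conjugate pair: `lambda` (the member
#'   with positive imaginary part), `f_res_hz` and `f_res_cov_hz = 2 f_res_hz`.
#' @export
resonance_frequency <- function(st) {
  stopifnot(inherits(st, "stationary_state"))
  lam <- st$lambda[Im(st$lambda) > 1e-12]
  f_res <- abs(Im(lam)) / (2 * pi * st$spec$tau) * 1000
  tibble(lambda = lam, f_res_hz = f_res, f_res_cov_hz = 2 * f_res)
}

#' Amplitude and phase of a complex harmonic coefficient
#'
#' Converts complex first-harmonic coefficients (under the sine convention
#' `x(t) = Im(X exp(i omega t))`, so phase 0 means in phase with the drive
#' `h_ext sin(omega t)` and negative phase means lag) into amplitude and
#' principal-value phase in `(-pi, pi]`. No unwrapping is attempted.
#'
#' @param X Complex vector of harmonic coefficients.
#' @return A tibble with columns `amplitude` (`>= 0`) and `phase`.
#' @examples
#' amp_phase(c(1, -2i))   # in phase; quarter-cycle lag
#' @export
amp_phase <- function(X) {
  tibble(amplitude = Mod(X), phase = Arg(X))
}
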