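#' Eigendecomposition of the effective connectivity
#'
#' Decomposes `W = U diag(lambda) U^-1`. Eigenpairs are ordered by
#' descending real part with complex-conjugate pairs adjacent. The
#' linear-response formulas require `W` to be diagonalizable; a
#' badly conditioned eigenvector matrix triggers an error.
#'
#' @param W Square (effective connectivity) matrix.
#' @return A list with `U` (eigenvectors), `lambda` (eigenvalues, possibly
#'   complex) and `Uinv`.
#' @export
eigensystem <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) abort("`W` must be square.")
  ev <- eigen(W)
  ord <- order(-Re(ev$values), -Im(ev$values))
  U <- ev$vectors[, ord, drop = FALSE]
  lambda <- as.complex(ev$values[ord])
  if (eig_cond(U) > 1e12) {
    U <- repair_degenerate_eigenvectors(W, U, lambda)
  }
  if (eig_cond(U) > 1e12) {
    abort("effective connectivity is (numerically) defective: eigenvector matrix condition number > 1e12.",
          class = "oscibin_defective_matrix")
  }
  list(U = U, lambda = lambda, Uinv = solve(U))
}

eig_cond <- function(U) {
  sv <- svd(U, nu = 0, nv = 0)$d
  if (min(sv) == 0) Inf else max(sv) / min(sv)
}

# LAPACK can return (numerically) parallel eigenvectors for a repeated
# eigenvalue even when its geometric multiplicity is full (e.g. the double
# zero mode of a network with identical E and I rows plus a clamped source).
# For each group of coinciding real eigenvalues, rebuild the eigenspace as
# the null space of W - lambda I from an SVD; if the geometric multiplicity
# is genuinely deficient, the caller's condition check still fails.
repair_degenerate_eigenvectors <- function(W, U, lambda) {
  n <- length(lambda)
  tol <- 1e-8 * (1 + max(abs(lambda)))
  grp <- integer(n)
  g <- 0L
  for (i in seq_len(n)) {
    if (i > 1 && abs(lambda[i] - lambda[i - 1]) <= tol) {
      grp[i] <- grp[i - 1]
    } else {
      g <- g + 1L
      grp[i] <- g
    }
  }
  for (gg in unique(grp)) {
    idx <- which(grp == gg)
    if (length(idx) < 2 || any(abs(Im(lambda[idx])) > tol)) next
    A <- W - Re(mean(lambda[idx])) * diag(n)
    sv <- svd(A)
    small <- sv$d <= max(sv$d) * 1e-10
    if (sum(small) >= length(idx)) {
      U[, idx] <- sv$v[, order(sv$d)[seq_along(idx)], drop = FALSE]
    }
  }
  U
}

# Exact solution of the stationary covariance relation
#   2 c = W (c + diag(a / N)) + transpose
# in the eigenbasis of W: componentwise division by 2 - (lambda_a + lambda_b).
solve_stationary_covariance <- function(W, a, N) {
  es <- eigensystem(W)
  D <- W %*% diag(a / N, nrow = length(a))
  Dt <- es$Uinv %*% (D + t(D)) %*% t(es$Uinv)
  den <- 2 - outer(es$lambda, es$lambda, `+`)
  cc <- es$U %*% (Dt / den) %*% t(es$U)
  cc <- Re(cc)
  (cc + t(cc)) / 2
}

#' Self-consistent stationary state of the mean-field equations
#'
#' Solves the coupled fixed-point equations for the undriven network:
#' `m = phi(mu(m), sigma(m, c))` componentwise, and the stationary
#' covariance relation `2 c = W (c + diag(a / N)) + transpose`, where
#' `W = diag(S) (K * J)` is the susceptibility-weighted (effective)
#' connectivity. The mean equation is solved by Newton iteration
#' (Jacobian `I - W`, with backtracking line search); the covariance equation is solved exactly in the
#' eigenbasis of `W` at each outer iteration, with damping 0.5, until joint
#' convergence.
#'
#' @param spec A [network_spec()] with thresholds set (see
#'   [calibrate_thresholds()]).
#' @param init_m Optional initial mean vector for the dynamic populations;
#'   defaults to `spec$target_m` if present, else 0.5.
#' @param tol Convergence tolerance on the joint update (default 1e-12).
#' @param max_iter Maximum number of outer iterations.
#' @return An object of class `stationary_state`: population vectors `m`,
#'   `a`, `mu`, `sigma`, `sigma_network`, `sigma_shot`, `S`, `theta`, the
#'   covariance matrix `c`, `c_total = c + diag(a / N)`, the effective
#'   connectivity `W` with its eigensystem (`U`, `lambda`, `Uinv`),
#'   `max_re_lambda` and the logical `stable` (`max Re(lambda) < 1`). An
#'   instability is reported as a warning, not an error.
#' @examples
#' st <- solve_stationary(preset_network("single_inhibitory"))
#' tidy(st)
#' glance(st)
#' @export
solve_stationary <- function(spec, init_m = NULL, tol = 1e-12, max_iter = 10000) {
  dyn <- spec$dynamic
  if (any(is.na(spec$theta[dyn]))) {
    if (!is.null(spec$target_m)) {
      spec <- calibrate_thresholds(spec)
    } else {
      abort("spec has unset thresholds and no target_m to calibrate them from.")
    }
  }
  P <- n_pop(spec)
  m <- ifelse(dyn, NA_real_, spec$m_clamped)
  names(m) <- spec$labels
  if (!is.null(init_m)) {
    m[dyn] <- expand_named(init_m, spec$labels[dyn], "init_m")
  } else if (!is.null(spec$target_m)) {
    m[dyn] <- spec$target_m[spec$labels[dyn]]
  } else {
    m[dyn] <- 0.5
  }
  cmat <- matrix(0, P, P)

  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # Newton step on r(m) = m - phi(mu(m), sigma(m, c)) for dynamic populations
    im <- compute_input_moments(m, cmat, spec)
    phi_v <- gain_phi(im$mu[dyn], im$sigma[dyn], spec$theta[dyn])
    S <- rep(0, P)
    S[dyn] <- susceptibility(im$mu[dyn], im$sigma[dyn], spec$theta[dyn])
    W <- S * (spec$K * spec$J)
    r <- m[dyn] - phi_v
    Jac <- diag(sum(dyn)) - W[dyn, dyn, drop = FALSE]
    step <- solve(Jac, r)
    # backtracking line search keeps the Newton update from cycling between
    # the saturated branches of the gain when started far from the fixed point
    m_new <- m
    alpha <- 1
    for (ls in 1:12) {
      trial <- pmin(1 - 1e-12, pmax(1e-12, m[dyn] - alpha * step))
      m_try <- m
      m_try[dyn] <- trial
      im_try <- compute_input_moments(m_try, cmat, spec)
      r_try <- m_try[dyn] - gain_phi(im_try$mu[dyn], im_try$sigma[dyn], spec$theta[dyn])
      if (max(abs(r_try)) <= (1 - 1e-4 * alpha) * max(abs(r))) break
      alpha <- alpha / 2
    }
    m_new[dyn] <- trial
    # exact covariance solve at the updated mean, damped
    im2 <- compute_input_moments(m_new, cmat, spec)
    S2 <- rep(0, P)
    S2[dyn] <- susceptibility(im2$mu[dyn], im2$sigma[dyn], spec$theta[dyn])
    W2 <- S2 * (spec$K * spec$J)
    c_new <- solve_stationary_covariance(W2, m_new * (1 - m_new), spec$N)
    delta <- max(max(abs(m_new - m)), max(abs(c_new - cmat)))
    m <- m_new
    cmat <- cmat + 0.5 * (c_new - cmat)
    if (delta < tol) { converged <- TRUE; break }
  }

  im <- compute_input_moments(m, cmat, spec)
  phi_res <- max(abs(gain_phi(im$mu[dyn], im$sigma[dyn], spec$theta[dyn]) - m[dyn]))
  if (!converged || phi_res > 1e-10) {
    abort(sprintf("stationary solver did not converge (residual %.3g after %d iterations).",
                  phi_res, it),
          class = "oscibin_convergence_error")
  }
  S <- rep(0, P)
  S[dyn] <- susceptibility(im$mu[dyn], im$sigma[dyn], spec$theta[dyn])
  names(S) <- spec$labels
  W <- S * (spec$K * spec$J)
  es <- eigensystem(W)
  max_re <- max(Re(es$lambda))
  if (max_re >= 1) {
    warn(sprintf("stationary state is unstable: max Re(lambda) = %.4f >= 1.", max_re))
  }
  a <- m * (1 - m)
  dimnames(cmat) <- dimnames(spec$J)
  structure(
    list(
      spec = spec, m = m, a = a, c = cmat,
      c_total = cmat + diag(a / spec$N, nrow = P),
      mu = im$mu, sigma = im$sigma,
      sigma_network = im$sigma_network, sigma_shot = im$sigma_shot,
      S = S, theta = spec$theta, W = W,
      U = es$U, lambda = es$lambda, Uinv = es$Uinv,
      max_re_lambda = max_re, stable = max_re < 1,
      iterations = it, residual = phi_res
    ),
    class = "stationary_state"
  )
}

#' @export
print.stationary_state <- function(x, ...) {
  cat(sprintf("<stationary_state> '%s' (%s, max Re(lambda) = %.4f)\n",
              x$spec$name, if (x$stable) "stable" else "UNSTABLE", x$max_re_lambda))
  print(tidy(x), n = Inf)
  cat("eigenvalues of W:", paste(format(x$lambda, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn solve_stationary One row per population: mean activity `m`,
#'   rate `nu_hz = 1000 m / tau`, variance `a`, input moments, susceptibility
#'   and threshold.
#' @param x A `stationary_state`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.stationary_state <- function(x, ...) {
  tibble(
    population = x$spec$labels,
    kind = ifelse(x$spec$dynamic, "dynamic", "clamped"),
    m = unname(x$m),
    nu_hz = unname(1000 * x$m / x$spec$tau),
    a = unname(x$a),
    mu = unname(x$mu),
    sigma = unname(x$sigma),
    sigma_network = unname(x$sigma_network),
    sigma_shot = unname(x$sigma_shot),
    S = unname(x$S),
    theta = unname(x$theta)
  )
}

#' @describeIn solve_stationary One-row summary: stability, spectral numbers
#'   and the resonance frequency (if any).
#' @exportS3Method generics::glance
glance.stationary_state <- function(x, ...) {
  res <- resonance_frequency(x)
  tibble(
    n_pop = n_pop(x$spec),
    max_re_lambda = x$max_re_lambda,
    stable = x$stable,
    f_res_hz = if (nrow(res)) res$f_res_hz[1] else NA_real_,
    iterations = x$iterations,
    residual = x$residual
  )
}
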