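# Shared fixtures: all inputs are generated in code at test time.

# A random inhibition-dominated network with sensible scales; resampled (up
# to `tries` times) until calibration + stationary solve succeed.
random_stable_spec <- function(seed, n_pop_max = 3, tries = 20) {
  set.seed(seed)
  for (k in seq_len(tries)) {
    P <- sample.int(n_pop_max, 1)
    labels <- LETTERS[seq_len(P)]
    N <- sample(200:2000, P, replace = TRUE)
    sign_col <- sample(c(1, -1), P, replace = TRUE)
    if (all(sign_col > 0)) sign_col[P] <- -1  # need inhibition for stability
    J <- matrix(runif(P * P, 0.1, 0.8), P, P) %*% diag(sign_col, P)
    J[, sign_col < 0] <- J[, sign_col < 0, drop = FALSE] * 2
    p <- matrix(runif(P * P, 0.05, 0.3), P, P)
    target <- runif(P, 0.05, 0.45)
    spec <- try(network_spec(
      labels = labels, N = N, tau = runif(1, 2, 12),
      p = p, J = J, sigma_noise = runif(1, 5, 15),
      target_m = setNames(target, labels)
    ), silent = TRUE)
    if (inherits(spec, "try-error")) next
    out <- try(suppressWarnings({
      spec2 <- calibrate_thresholds(spec)
      st <- solve_stationary(spec2)
      list(spec = spec2, st = st)
    }), silent = TRUE)
    if (!inherits(out, "try-error") && out$st$stable) return(out)
  }
  stop("could not generate a stable random network")
}

# quarter-scale single-inhibitory network (sizes and noise scaled with sqrt(K))
single_i_scaled <- function(N = 1250) {
  sigma_sys <- sqrt(1 * 0.1 * N * 0.3 * 0.7)
  calibrate_thresholds(network_spec(
    labels = "I", N = c(I = N), tau = 10,
    p = matrix(0.1), J = matrix(-1),
    sigma_noise = sigma_sys, target_m = c(I = 0.3),
    name = sprintf("single_inhibitory_N%d", N)
  ))
}

# quarter-scale biological preset: N / 4, everything else as shipped
biological_scaled <- function(frac = 0.25) {
  full <- preset_network("biological_EI", calibrate = FALSE)
  calibrate_thresholds(network_spec(
    labels = full$labels,
    N = round(full$N * frac),
    tau = full$tau, p = full$p, J = full$J,
    sigma_noise = full$sigma_noise,
    clamped = "X", m_clamped = c(X = 0.1),
    target_m = full$target_m,
    name = "biological_EI_scaled"
  ))
}

# independent-neuron network: no synapses, thresholds set for a given mean
independent_spec <- function(m = 0.2, N = 400, sigma_noise = 5, tau = 10) {
  network_spec(
    labels = "A", N = c(A = N), tau = tau,
    p = matrix(0), J = matrix(0),
    sigma_noise = sigma_noise,
    theta = c(A = sigma_noise * qnorm(1 - m)),
    name = "independent"
  )
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
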