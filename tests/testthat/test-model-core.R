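test_that("gain function: threshold point, calibration identity, saturation", {
  expect_equal(gain_phi(3.7, 2.2, 3.7), 0.5)
  expect_equal(gain_phi(-1, 0.5, -1), 0.5)
  # inverse identity used by threshold calibration: theta - mu = sigma * qnorm(1 - m)
  m <- 0.045
  sigma <- 4.3
  expect_equal(gain_phi(0, sigma, sigma * qnorm(1 - m)), m, tolerance = 1e-12)
  expect_lt(abs(gain_phi(10 * 3, 3, 0) - 1), 1e-12)
  expect_error(gain_phi(0, 0, 0), class = "oscibin_invalid_parameter")
  expect_error(susceptibility(0, -1, 0), class = "oscibin_invalid_parameter")
})

test_that("gain function is monotone in mu for random parameter draws", {
  set.seed(42)
  for (k in 1:1000) {
    sigma <- runif(1, 0.01, 50)
    theta <- runif(1, -30, 30)
    mu <- sort(runif(5, -60, 60))
    expect_true(all(diff(gain_phi(mu, sigma, theta)) >= 0))
  }
})

test_that("susceptibility and its derivative match finite differences of the gain", {
  set.seed(7)
  for (k in 1:50) {
    sigma <- runif(1, 0.5, 20)
    theta <- runif(1, -10, 10)
    mu <- theta + runif(1, -3, 3) * sigma  # away from deep saturation
    hstep <- 1e-5 * sigma
    S_fd <- (gain_phi(mu + hstep, sigma, theta) - gain_phi(mu - hstep, sigma, theta)) / (2 * hstep)
    S <- susceptibility(mu, sigma, theta)
    expect_lt(abs(S - S_fd) / S, 1e-6)
    dS_fd <- (susceptibility(mu + hstep, sigma, theta) -
                susceptibility(mu - hstep, sigma, theta)) / (2 * hstep)
    dS <- dsusceptibility_dmu(mu, sigma, theta)
    if (abs(dS) > 1e-12) expect_lt(abs(dS - dS_fd) / max(abs(dS), 1e-12), 1e-6)
  }
  # peak value and zero-curvature point at mu = theta
  expect_equal(susceptibility(2, 3, 2), 1 / (sqrt(2 * pi) * 3))
  expect_equal(dsusceptibility_dmu(2, 3, 2), 0)
  # sign(dS/dmu) = sign(theta - mu); value at theta - mu = sigma
  expect_gt(dsusceptibility_dmu(1, 2, 5), 0)
  expect_lt(dsusceptibility_dmu(8, 2, 5), 0)
  expect_equal(dsusceptibility_dmu(3, 2, 5), susceptibility(3, 2, 5) / 2)
})

test_that("susceptibility integrates to one over the input axis", {
  val <- integrate(function(mu) susceptibility(mu, 4.2, 1.3), -Inf, Inf)$value
  expect_equal(val, 1, tolerance = 1e-8)
})

test_that("input moments: empty network, worked example, linearity in c", {
  spec0 <- independent_spec(m = 0.3, sigma_noise = 7)
  im <- input_moments(moment_state(0.3, spec = spec0), spec0, external_input = 1.5)
  expect_equal(im$mu, 1.5)
  expect_equal(im$sigma, 7)
  expect_equal(im$sigma_network, 0)

  # single inhibitory population at m = 0.3: network SD = sqrt(J^2 p N m (1-m))
  spec <- preset_network("single_inhibitory", calibrate = FALSE)
  im1 <- input_moments(moment_state(0.3, spec = spec), spec)
  expect_equal(im1$sigma_shot, sqrt(105), tolerance = 1e-12)
  expect_equal(im1$sigma_network, sqrt(105), tolerance = 1e-12)  # c = 0 here

  # doubling c doubles the covariance contribution to sigma_network^2 exactly
  cmat <- matrix(-2e-5, 1, 1)
  net2 <- function(cm) {
    input_moments(moment_state(0.3, cm, spec), spec)$sigma_network^2 - im1$sigma_shot^2
  }
  expect_equal(net2(2 * cmat), 2 * net2(cmat), tolerance = 1e-12)

  expect_error(input_moments(moment_state(c(0.3, 0.4), spec = spec0), spec))
})

test_that("threshold calibration reproduces target means to 1e-8 (round trip)", {
  for (seed in 1:20) {
    fx <- random_stable_spec(seed)
    dyn <- fx$spec$dynamic
    expect_lt(max(abs(fx$st$m[dyn] - fx$spec$target_m[fx$spec$labels[dyn]])), 1e-8)
  }
})

test_that("calibration with symmetric target 0.5 puts the threshold at the mean input", {
  spec <- network_spec(
    labels = "A", N = c(A = 1000), tau = 5,
    p = matrix(0.1), J = matrix(-0.4), sigma_noise = 8, target_m = c(A = 0.5)
  )
  spec <- calibrate_thresholds(spec)
  st <- solve_stationary(spec)
  expect_equal(unname(spec$theta["A"]), unname(st$mu["A"]), tolerance = 1e-9)
})

test_that("spec validation enforces the model invariants", {
  expect_error(network_spec("A", 100, -1, matrix(0.1), matrix(1), 1), "tau")
  expect_error(network_spec("A", 100, 1, matrix(1.5), matrix(1), 1), "\\[0, 1\\]")
  expect_error(
    network_spec(c("A", "B"), c(100, 100), 1,
                 matrix(0.1, 2, 2), matrix(c(1, -1, 1, 1), 2, 2), 1),
    "mixes signs"
  )
  expect_error(
    network_spec(c("A", "X"), c(100, 100), 1,
                 matrix(0.1, 2, 2), matrix(0.1, 2, 2), 1,
                 clamped = "X", m_clamped = c(X = 1.2)),
    "m_clamped"
  )
  # clamped rows of K are forced to zero
  spec <- network_spec(c("A", "X"), c(100, 100), 1,
                       matrix(0.1, 2, 2), matrix(0.1, 2, 2), 1,
                       clamped = "X", m_clamped = c(X = 0.3))
  expect_true(all(spec$K["X", ] == 0))
  # moment_state forces clamped-clamped covariance to zero
  ms <- moment_state(c(A = 0.2, X = 0.3), matrix(1e-4, 2, 2), spec)
  expect_identical(ms$c["X", "X"], 0)
  expect_equal(ms$a, c(A = 0.16, X = 0.21))
})
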