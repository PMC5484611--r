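test_that("mean response: quasi-static limit and high-frequency asymptote", {
  st <- solve_stationary(single_i_scaled(2500))
  lam <- Re(st$lambda[1])
  M0 <- mean_response(st, 0, h_ext = 2)
  expect_equal(unname(M0["I"]), complex(real = 2 * st$S["I"] / (1 - lam)),
               tolerance = 1e-10)
  expect_gt(Re(M0[["I"]]), 0)
  expect_equal(Im(M0[["I"]]), 0, tolerance = 1e-12)

  # |M1| * tau * omega -> h S as omega -> infinity (check at tau omega = 1e3)
  f_hi <- 1000 / (2 * pi * st$spec$tau) * 1000
  Mhi <- mean_response(st, f_hi, h_ext = 1)
  expect_rel_equal(Mod(Mhi["I"]) * st$spec$tau * 2 * pi * f_hi / 1000,
                   unname(st$S["I"]), 0.01)
})

test_that("amp_phase follows the sine convention; corner-frequency phase is -pi/4", {
  ap <- amp_phase(c(1 + 0i, -2i))
  expect_equal(ap$amplitude, c(1, 2))
  expect_equal(ap$phase, c(0, -pi / 2))

  st <- solve_stationary(single_i_scaled(2500))
  lam <- Re(st$lambda[1])
  f_corner <- (1 - lam) / (2 * pi * st$spec$tau) * 1000
  M <- mean_response(st, f_corner)
  expect_equal(unname(Arg(M["I"])), -pi / 4, tolerance = 1e-9)
  # phases lag the drive across a sweep (real-eigenvalue network)
  for (f in c(1, 10, 100, 1000)) {
    ph <- Arg(mean_response(st, f)["I"])
    expect_true(ph <= 0 && ph > -pi)
  }
})

test_that("covariance response vanishes without drive and decomposes exactly", {
  for (preset in c("single_inhibitory", "biological_EI")) {
    st <- solve_stationary(preset_network(preset))
    lr0 <- covariance_response(st, 40, h_ext = 0)
    expect_equal(max(abs(lr0$C1)), 0)
    expect_equal(max(abs(lr0$C1_Sh)), 0)
    expect_equal(max(abs(lr0$C1_Sm)), 0)
    expect_equal(max(abs(lr0$C1_a)), 0)
    for (f in c(1, 15.7, 200, 900)) {
      lr <- covariance_response(st, f, h_ext = 1)
      expect_identical(lr$C1, lr$C1_Sh + lr$C1_Sm + lr$C1_a)
      expect_lt(max(abs(lr$C1 - t(lr$C1))), 1e-14)
    }
  }
})

test_that("clamped-clamped covariance response is zero", {
  st <- solve_stationary(preset_network("homogeneous_EI"))
  lr <- covariance_response(st, 25, h_ext = 1)
  expect_lt(abs(lr$C1["X", "X"]), 1e-16)
  expect_equal(unname(lr$M1["X"]), 0 + 0i)
})

test_that("single inhibitory population: susceptibility terms cancel at low
           frequency and the a-term masks their peak", {
  st <- solve_stationary(preset_network("single_inhibitory"))
  lr1 <- covariance_response(st, 1, h_ext = 1)
  s_h <- lr1$C1_Sh[1, 1]; s_m <- lr1$C1_Sm[1, 1]
  # opposite phase, partial cancellation
  expect_gt(abs(Arg(s_h) - Arg(s_m)), pi / 2)
  expect_lt(Mod(s_h + s_m), min(Mod(s_h), Mod(s_m)))

  f_grid <- exp(seq(log(1), log(1000), length.out = 40))
  amps <- t(vapply(f_grid, function(f) {
    lr <- covariance_response(st, f, h_ext = 1)
    c(total = Mod(lr$C1[1, 1]), s = Mod(lr$C1_Sh[1, 1] + lr$C1_Sm[1, 1]),
      a = Mod(lr$C1_a[1, 1]))
  }, numeric(3)))
  # the a-term dominates the summed susceptibility terms throughout the
  # low-pass regime (tau * omega <= 10) ...
  low <- 2 * pi * f_grid / 1000 * st$spec$tau <= 10
  expect_true(all(amps[low, "a"] > amps[low, "s"]))
  # ... so the intermediate S-term peak is masked: the total covariance
  # response has no interior maximum
  expect_equal(which.max(amps[, "total"]), 1L)
  expect_true(all(diff(amps[, "total"]) < 0))
})

test_that("quasi-static covariance response solves the static linearized equation", {
  st <- solve_stationary(preset_network("biological_EI"))
  f_tiny <- 1e-6 / (2 * pi) * 1000  # omega = 1e-6 rad/ms
  lr <- covariance_response(st, f_tiny, h_ext = 1)
  # independent route: direct dense linear solve of
  # 2 dc - W dc - dc W^T = A + A^T  via Kronecker vectorization
  P <- length(st$lambda)
  M1 <- mean_response(st, f_tiny, 1)
  Vc <- lr$V %*% st$c_total
  A <- (1 + as.vector(lr$T_mat %*% M1)) * Vc +
    st$W %*% diag(((1 - 2 * st$m) / st$spec$N) * M1, nrow = P)
  lhs <- 2 * diag(P * P) - kronecker(diag(P), st$W) - kronecker(st$W, diag(P))
  dc <- matrix(solve(lhs, as.vector(A + t(A))), P)
  expect_lt(max(abs(dc - lr$C1)), 1e-8)
})

test_that("time-dependent covariance response scales like the mean response over N", {
  ratio <- vapply(c(2500, 5000), function(N) {
    st <- solve_stationary(single_i_scaled(N))
    lr <- covariance_response(st, 10, h_ext = 1)
    N * Mod(lr$C1[1, 1]) / Mod(lr$M1["I"])
  }, numeric(1))
  expect_lt(abs(diff(ratio)) / mean(ratio), 0.3)
})

test_that("resonances: none for real spectra, one conjugate pair for the
           inhomogeneous E-I network, response peak near f_res", {
  st_h <- solve_stationary(preset_network("homogeneous_EI"))
  expect_equal(nrow(resonance_frequency(st_h)), 0)

  st_b <- solve_stationary(preset_network("biological_EI"))
  res <- resonance_frequency(st_b)
  expect_equal(nrow(res), 1)
  expect_equal(res$f_res_cov_hz, 2 * res$f_res_hz)
  expect_equal(res$f_res_hz, abs(Im(st_b$lambda[2])) / (2 * pi * 2.5) * 1000)

  f_grid <- exp(seq(log(1), log(1000), length.out = 120))
  aE <- vapply(f_grid, function(f) Mod(mean_response(st_b, f)["E"]), numeric(1))
  f_peak <- f_grid[which.max(aE)]
  expect_gt(f_peak / res$f_res_hz, 0.5)
  expect_lt(f_peak / res$f_res_hz, 2)
})

test_that("closed-form response matches the frozen-width ODE across frequencies", {
  spec <- preset_network("biological_EI")
  st <- solve_stationary(spec)
  for (f in c(10, 80, 320)) {
    traj <- integrate_moments(spec, drive_spec(0.1, f), periods = 6,
                              sigma_dynamics = "frozen")
    h <- extract_harmonics(traj)
    h1 <- h[h$order == 1, ]
    M1 <- mean_response(st, f, 0.1)
    C1 <- covariance_response(st, f, 0.1)$C1
    for (comp in c("E", "I")) {
      got <- h1$amplitude[h1$kind == "mean" & h1$component == comp]
      expect_rel_equal(got, Mod(M1[comp]), 0.02)
    }
    for (comp in list(c("E", "E"), c("E", "I"), c("I", "I"))) {
      got <- h1$amplitude[h1$kind == "covariance" &
                            h1$component == paste0(comp[1], comp[2])]
      expect_rel_equal(got, Mod(C1[comp[1], comp[2]]), 0.05)
    }
  }
})
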