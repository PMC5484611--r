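test_that("network construction: exact in-degrees, no self loops or duplicates,
           deterministic given the seed", {
  spec <- single_i_scaled(1250)   # K = 125
  net <- build_network(spec, seed = 5)
  ind <- oscibin:::in_degrees(net)
  expect_true(all(ind[, "I"] == 125))
  # no self-connections, no duplicate edges from one sender to one receiver
  edges <- paste(net$edge_sender, net$out_to + 1L)
  expect_false(any(net$edge_sender == net$out_to + 1L))
  expect_false(anyDuplicated(edges) > 0)

  net2 <- build_network(spec, seed = 5)
  expect_identical(net$out_to, net2$out_to)
  net3 <- build_network(spec, seed = 6)
  expect_false(identical(net$out_to, net3$out_to))

  # empty adjacency for K = 0; over-full K errors
  net0 <- build_network(independent_spec(), seed = 1)
  expect_length(net0$out_to, 0)
  expect_error(
    build_network(network_spec("A", 10, 1, matrix(1), matrix(-1), 1,
                               theta = c(A = 0)), seed = 1),
    "exceeds"
  )

  # mean out-degree equals sum_a N_a K_ab / N_b
  spec2 <- biological_scaled(0.25)
  netb <- build_network(spec2, seed = 3)
  outdeg <- diff(netb$out_ptr)
  is_E <- netb$pop_of == 1
  expect_equal(mean(outdeg[is_E]),
               sum(spec2$N * spec2$K[, "E"]) / spec2$N["E"],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("update process: Poisson event count, exponential per-neuron
           intervals, deterministic event streams", {
  spec <- independent_spec(m = 0.2, N = 200, sigma_noise = 5)
  net <- build_network(spec, seed = 1)
  run <- simulate_glauber(net, drive_spec(0, 0), duration = 600, seed = 42,
                          record = "events", transient = 0)
  ev <- run$events
  expect_true(all(diff(ev$time) > 0))
  lambda <- 600 * 200 / spec$tau
  expect_lt(abs(nrow(ev) - lambda), 5 * sqrt(lambda))

  # inter-update intervals of single neurons are Exp(tau)
  iv <- unlist(tapply(ev$time, ev$neuron, diff), use.names = FALSE)
  ks <- suppressWarnings(stats::ks.test(iv, "pexp", rate = 1 / spec$tau))
  expect_gt(ks$p.value, 0.01)

  run2 <- simulate_glauber(net, drive_spec(0, 0), duration = 600, seed = 42,
                           record = "events", transient = 0)
  expect_identical(run$events, run2$events)
  expect_identical(run$final_state, run2$final_state)
})

test_that("independent neurons relax to the gain-function activity", {
  spec <- independent_spec(m = 0.2, N = 400, sigma_noise = 5)
  net <- build_network(spec, seed = 2)
  run <- simulate_glauber(net, drive_spec(0, 0), duration = 1500, seed = 7)
  ma <- mean_activity(run)
  expect_lt(abs(ma$m_hat - 0.2), 3 * ma$se)
})

test_that("single inhibitory network reproduces the mean-field activity and
           near-Gaussian inputs", {
  spec <- preset_network("single_inhibitory")
  st <- solve_stationary(spec)
  net <- build_network(spec, seed = 11)
  run <- simulate_glauber(net, drive_spec(0, 0), duration = 450, seed = 12,
                          record_inputs = TRUE, transient = 100)
  ma <- mean_activity(run)
  expect_lt(abs(ma$m_hat - st$m["I"]), 4 * ma$se)

  # with sigma_noise = sigma_network, the per-update input distribution is
  # Gaussian with the mean-field moments (smoothing of the binomial input)
  inputs <- run$inputs[round(0.3 * length(run$inputs)):length(run$inputs)]
  inputs <- inputs[seq_len(min(1e5, length(inputs)))]
  ks <- suppressWarnings(
    stats::ks.test(inputs, "pnorm", mean = st$mu["I"], sd = st$sigma["I"])
  )
  expect_gt(ks$p.value, 0.01)
})

test_that("fixed-step update scheme agrees with the event-driven one", {
  spec <- single_i_scaled(1250)
  st <- solve_stationary(spec)
  net <- build_network(spec, seed = 21)
  run <- simulate_glauber(net, drive_spec(0, 0), duration = 800, seed = 22,
                          scheme = "fixed")
  ma <- mean_activity(run)
  expect_lt(abs(ma$m_hat - st$m["I"]), 4 * ma$se)
})

test_that("cyclostationary estimator: independent neurons give zero
           covariance and the Bernoulli variance identity", {
  spec <- independent_spec(m = 0.25, N = 300, sigma_noise = 5)
  net <- build_network(spec, seed = 3)
  drive <- drive_spec(0, 40)  # phase folding with zero amplitude
  runs <- lapply(1:10, function(r) {
    simulate_glauber(net, drive, duration = 600, seed = 30 + r, n_bins = 10,
                     tracked_per_pop = 300)
  })
  expect_error(cyclostationary_stats(runs[1]), "at least 2")
  est <- cyclostationary_stats(runs, pairs = 5000)
  stats <- tidy(est)
  cc <- stats[stats$kind == "c", ]
  expect_gte(mean(abs(cc$estimate) < 3 * cc$se), 0.95)
  mm <- stats[stats$kind == "m", ]
  aa <- stats[stats$kind == "a", ]
  expect_true(all(abs(aa$estimate - mm$estimate * (1 - mm$estimate)) <
                    3 * pmax(aa$se, 1e-4)))
})

test_that("driven E-I network: phase-resolved covariance modulation matches
           the linear-response prediction", {
  spec <- preset_network("biological_EI")
  st <- solve_stationary(spec)
  net <- build_network(spec, seed = 101)
  drive <- drive_spec(1, 80)
  runs <- lapply(1:12, function(r) {
    simulate_glauber(net, drive, duration = 800, seed = 200 + r, n_bins = 20,
                     tracked_per_pop = c(E = 400, I = 230, X = 2))
  })
  est <- cyclostationary_stats(runs, pairs = 20000)
  stats <- tidy(est)
  harm <- function(kind, comp) {
    sub <- stats[stats$kind == kind & stats$component == comp, ]
    sub <- sub[order(sub$bin), ]
    X1 <- 2i * mean(sub$estimate * exp(-1i * sub$phase))
    se <- 2 * sqrt(sum(sub$se^2)) / nrow(sub)
    list(X1 = X1, se = se)
  }
  hm <- harm("m", "E")
  expect_lt(abs(Mod(hm$X1) - Mod(mean_response(st, 80)["E"])), 3 * hm$se)
  lr <- covariance_response(st, 80, 1)
  for (comp in c("EE", "II")) {
    hc <- harm("c", comp)
    th <- Mod(lr$C1[substr(comp, 1, 1), substr(comp, 2, 2)])
    expect_lt(abs(Mod(hc$X1) - th), 3 * hc$se)
  }
  # time-averaged covariances carry the stationary structure
  c0_EE <- mean(stats$estimate[stats$kind == "c" & stats$component == "EE"])
  expect_gt(c0_EE, 0)
})

test_that("population ellipse geometry: diagonal, tilted and nested cases", {
  pe <- population_ellipse(diag(c(4e-4, 1e-4)))
  expect_equal(sort(pe$half_lengths), c(0.01, 0.02))
  expect_equal(abs(pe$axes), diag(2), tolerance = 1e-12)

  # positive cross-covariance tilts the principal axes
  cp <- matrix(c(4e-4, 1.5e-4, 1.5e-4, 2e-4), 2)
  pe2 <- population_ellipse(cp, center = c(0.27, 0.045))
  expect_gt(min(abs(pe2$axes)), 0.1)

  # PSD pairwise covariances: the full ellipse encloses the variances-only one
  d <- diag(c(3e-4, 1.2e-4))
  chat <- 2e-4 * outer(c(0.8, 0.5), c(0.8, 0.5))
  full <- d + chat
  phi <- seq(0, 2 * pi, length.out = 73)
  ed <- eigen(d)
  boundary <- ed$vectors %*% (t(cbind(cos(phi), sin(phi))) * sqrt(ed$values))
  q <- colSums(boundary * solve(full, boundary))
  expect_true(all(q <= 1 + 1e-12))

  expect_error(population_ellipse(matrix(c(1e-4, 0, 0, 0), 2)),
               class = "oscibin_degenerate_ellipse")
})
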