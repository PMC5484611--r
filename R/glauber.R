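#' Draw a fixed in-degree random network realization
#'
#' Realizes the population-level connectivity of a [network_spec()] as an
#' explicit neuron-level graph: every neuron in population `a` receives
#' exactly `K[a, b]` inputs from population `b`, drawn uniformly without
#' replacement among the allowed senders (self-connections excluded). The
#' construction is deterministic given `seed`.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for the wiring.
#' @return An object of class `binary_network`: neuron population labels,
#'   the sender-major (CSR) out-edge lists with per-edge weights, and
#'   bookkeeping used by [simulate_glauber()].
#' @examples
#' net <- build_network(preset_network("single_inhibitory"), seed = 1)
#' net
#' @export
build_network <- function(spec, seed) {
  stopifnot(inherits(spec, "network_spec"))
  P <- n_pop(spec)
  N <- as.integer(spec$N)
  n <- sum(N)
  pop_end <- cumsum(N)
  pop_start <- c(0L, head(pop_end, -1L))  # 0-based offsets
  pop_of <- rep.int(seq_len(P), N)

  for (a in seq_len(P)) {
    for (b in seq_len(P)) {
      need <- spec$K[a, b] + as.integer(a == b)
      if (spec$K[a, b] > 0 && need > N[b]) {
        abort(sprintf("K[%s,%s] = %d exceeds the available senders.",
                      spec$labels[a], spec$labels[b], spec$K[a, b]))
      }
    }
  }

  set.seed(seed)
  senders <- vector("list", P * P)
  receivers <- vector("list", P * P)
  weights <- numeric(P * P)
  blk <- 0L
  for (a in seq_len(P)) {
    for (b in seq_len(P)) {
      Kab <- spec$K[a, b]
      if (Kab == 0) next
      blk <- blk + 1L
      Nb <- N[b]
      recv_ids <- pop_start[a] + seq_len(N[a])  # 1-based global ids
      if (a == b) {
        # sample among Nb - 1 senders, then skip the receiver's own slot
        sl <- lapply(seq_len(N[a]), function(li) {
          x <- sample.int(Nb - 1L, Kab)
          x + (x >= li)
        })
      } else {
        sl <- lapply(seq_len(N[a]), function(li) sample.int(Nb, Kab))
      }
      senders[[blk]] <- pop_start[b] + unlist(sl, use.names = FALSE)
      receivers[[blk]] <- rep(recv_ids, each = Kab)
      weights[blk] <- spec$J[a, b]
      names(weights)[blk] <- ""
    }
  }
  blocks <- seq_len(blk)
  snd <- as.integer(unlist(senders[blocks], use.names = FALSE))
  rcv <- as.integer(unlist(receivers[blocks], use.names = FALSE))
  wts <- if (blk > 0) {
    rep.int(weights[blocks], vapply(senders[blocks], length, integer(1)))
  } else {
    numeric(0)
  }

  # sender-major CSR
  ord <- order(snd)
  snd <- snd[ord]; rcv <- rcv[ord]; wts <- wts[ord]
  out_deg <- tabulate(snd, nbins = n)
  out_ptr <- c(0L, cumsum(out_deg))

  structure(
    list(
      spec = spec, seed = seed,
      n = n, pop_of = pop_of, pop_start = pop_start,
      out_ptr = as.integer(out_ptr),
      out_to = as.integer(rcv - 1L),
      out_w = wts,
      edge_sender = snd  # kept for structural checks; sender-major order
    ),
    class = "binary_network"
  )
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> '%s': %d neurons, %d edges (seed %d)\n",
              x$spec$name, x$n, length(x$out_to), x$seed))
  invisible(x)
}

# in-degree of each neuron from each sending population (for tests)
in_degrees <- function(net) {
  P <- n_pop(net$spec)
  rcv <- net$out_to + 1L
  snd_pop <- net$pop_of[net$edge_sender]
  out <- matrix(0L, net$n, P, dimnames = list(NULL, net$spec$labels))
  for (b in seq_len(P)) {
    out[, b] <- tabulate(rcv[snd_pop == b], nbins = net$n)
  }
  out
}

#' Simulate Glauber dynamics of a binary network
#'
#' Exact event-driven stochastic simulation: update events arrive as a
#' Poisson process of rate `N / tau`; at each event a uniformly chosen
#' neuron is re-drawn, becoming active iff its recurrent input plus the
#' common drive `h_ext sin(omega t)` plus fresh Gaussian noise reaches its
#' threshold (clamped neurons become active with their fixed probability).
#' Identical seeds give identical event streams.
#'
#' Besides an optional full event log, the simulator records snapshots of
#' the network state once per drive phase bin and cycle (after the
#' transient): the per-population active counts for all neurons and the
#' individual states of a tracked subsample, which is what the
#' cyclostationary estimator consumes.
#'
#' @param net A [build_network()] realization.
#' @param drive A [drive_spec()].
#' @param duration Total simulated time in ms.
#' @param seed Integer seed for the dynamics (and the random initial state).
#' @param record `"stats"` (snapshots only) or `"events"` (additionally the
#'   full update log; memory scales with `duration * N / tau`).
#' @param n_bins Number of phase bins per drive cycle (ignored if `f = 0`,
#'   where a single bin is sampled every `snapshot_dt`).
#' @param transient Discarded initial window in ms; default
#'   `max(20 tau, 2 periods)`.
#' @param snapshot_dt Snapshot spacing for undriven runs (default `5 tau`).
#' @param tracked_per_pop Number of neurons per population whose individual
#'   states are snapshotted (the first ones of each population; neurons are
#'   exchangeable by construction). Scalar or named per-population vector.
#'   Default 400.
#' @param record_inputs Also return the summed input of every (dynamic)
#'   update decision — the empirical input distribution.
#' @param scheme `"event"` (exponential waiting times) or `"fixed"`
#'   (deterministic step `dt = tau / N`, for cross-checking).
#' @param init Optional initial 0/1 state vector; default draws each neuron
#'   independently at its population's target (or clamped) mean.
#' @return A `glauber_run` object; see [cyclostationary_stats()].
#' @export
simulate_glauber <- function(net, drive, duration, seed,
                             record = c("stats", "events"),
                             n_bins = 20, transient = NULL,
                             snapshot_dt = NULL, tracked_per_pop = 400,
                             record_inputs = FALSE,
                             scheme = c("event", "fixed"), init = NULL) {
  stopifnot(inherits(net, "binary_network"), inherits(drive, "drive_spec"),
            duration > 0)
  record <- match.arg(record)
  scheme <- match.arg(scheme)
  spec <- net$spec
  P <- n_pop(spec)
  tau <- spec$tau

  period <- if (drive$f > 0) 1000 / drive$f else Inf
  transient <- transient %||% max(20 * tau, if (is.finite(period)) 2 * period else 0)

  # snapshot schedule: one per phase bin per cycle, at bin centers
  if (drive$f > 0) {
    first_cycle <- ceiling(transient / period)
    cycles <- seq(first_cycle, floor(duration / period + 1e-9) - 1L)
    if (length(cycles) < 1) abort("duration leaves no full cycle after the transient.")
    grid <- expand.grid(bin = seq_len(n_bins), cycle = cycles)
    snap_time <- (grid$cycle + (grid$bin - 0.5) / n_bins) * period
    snap_bin <- grid$bin
    snap_cycle <- grid$cycle
  } else {
    n_bins <- 1L
    snapshot_dt <- snapshot_dt %||% (5 * tau)
    snap_time <- seq(transient + snapshot_dt / 2, duration, by = snapshot_dt)
    snap_bin <- rep(1L, length(snap_time))
    snap_cycle <- seq_along(snap_time)
  }

  # per-neuron parameters
  th <- spec$theta[net$pop_of]
  th[is.na(th)] <- 0
  cl <- !spec$dynamic[net$pop_of]
  mcl <- spec$m_clamped[net$pop_of]
  mcl[is.na(mcl)] <- 0
  sn <- spec$sigma_noise[net$pop_of]

  tpp <- if (length(tracked_per_pop) == 1 && is.null(names(tracked_per_pop))) {
    setNames(rep(tracked_per_pop, P), spec$labels)
  } else {
    expand_named(tracked_per_pop, spec$labels, "tracked_per_pop")
  }
  tracked <- unlist(lapply(seq_len(P), function(a) {
    net$pop_start[a] + seq_len(min(tpp[a], spec$N[a]))
  }), use.names = FALSE)

  set.seed(seed)
  if (is.null(init)) {
    m0 <- ifelse(spec$dynamic, spec$target_m[spec$labels] %||% 0.5, spec$m_clamped)
    m0[is.na(m0)] <- 0.5
    init <- as.integer(runif(net$n) < m0[net$pop_of])
  }
  res <- glauber_run_cpp(
    n = net$n, pop = net$pop_of - 1L, n_pop = P,
    out_ptr = net$out_ptr, out_to = net$out_to, out_w = net$out_w,
    theta = unname(th), clamped = unname(cl), m_clamp = unname(mcl),
    sigma_noise = unname(sn), tau = tau,
    h_ext = drive$h_ext, omega = drive$omega, duration = duration,
    init = init, snap_times = snap_time, tracked = as.integer(tracked - 1L),
    record_events = record == "events", record_inputs = record_inputs,
    active_from = transient, fixed_step = scheme == "fixed"
  )

  events <- NULL
  if (record == "events") {
    events <- tibble(time = res$event_time, neuron = res$event_neuron,
                     state = res$event_state)
  }
  structure(
    list(
      labels = spec$labels, N = spec$N, dynamic = spec$dynamic,
      tau = tau, drive = drive, duration = duration, transient = transient,
      n_bins = n_bins, seed = seed,
      snapshots = res$snapshots, popcounts = res$popcounts,
      snap_time = snap_time, snap_bin = snap_bin, snap_cycle = snap_cycle,
      tracked = tracked, tracked_pop = net$pop_of[tracked],
      active_time = res$active_time, n_events = res$n_events,
      final_state = res$final_state,
      events = events, inputs = res$inputs
    ),
    class = "glauber_run"
  )
}

#' @export
print.glauber_run <- function(x, ...) {
  cat(sprintf("<glauber_run> %d neurons, %.0f ms, %g events, %d snapshot(s) x %d bin(s)\n",
              sum(x$N), x$duration, x$n_events, length(x$snap_time), x$n_bins))
  invisible(x)
}

#' Time-averaged activity of a run
#'
#' Per-population mean activity over the post-transient window, from the
#' exact per-neuron active-time integral.
#'
#' @param run A `glauber_run`.
#' @return A tibble with `population`, `m_hat` and the across-neuron
#'   standard error of the (population) mean.
#' @export
mean_activity <- function(run) {
  frac <- run$active_time / (run$duration - run$transient)
  pop <- rep.int(seq_along(run$labels), run$N)
  tibble(
    population = run$labels,
    m_hat = as.vector(tapply(frac, pop, mean)),
    se = as.vector(tapply(frac, pop, function(x) sd(x) / sqrt(length(x))))
  )
}

#' Cyclostationary ensemble statistics from repeated simulations
#'
#' Estimates the phase-resolved population statistics from an ensemble of
#' independent simulation runs: the mean activities `m(phi)`, the
#' single-unit variances `a(phi)`, the population-averaged pairwise
#' covariances `c(phi)` over a fixed random subsample of ordered neuron
#' pairs, and the population-activity covariance
#' `c_pop(phi) = diag(a / N) + c`.
#'
#' The ensemble at a given phase consists of one state snapshot per (trial,
#' cycle): snapshots of the same phase in different cycles are separated by
#' at least one drive period (much longer than the update time constant) and
#' are treated as independent realizations of the cyclostationary ensemble;
#' pairwise covariances are computed across these realizations (divisor
#' R - 1). Standard errors are computed across trials, so residual
#' within-trial dependence is reflected in the reported SEs.
#'
#' @param runs List of at least two `glauber_run` objects with identical
#'   network/drive settings but different seeds.
#' @param pairs Number of ordered pairs per population block (capped at the
#'   number available among tracked neurons). Default 2000.
#' @param pair_seed Seed for the fixed pair subsample.
#' @return A `cyclostat_estimate`: tibble `stats` with one row per phase
#'   bin, kind (`m`, `a`, `c`) and component, columns `estimate` and `se`;
#'   plus the `c_pop` array (`P x P x n_bins`) and bin metadata.
#' @export
cyclostationary_stats <- function(runs, pairs = 2000, pair_seed = 1) {
  if (!is.list(runs) || length(runs) < 2 ||
      !all(vapply(runs, inherits, logical(1), "glauber_run"))) {
    abort("need a list of at least 2 glauber_run objects (ensemble statistics).")
  }
  r0 <- runs[[1]]
  P <- length(r0$labels)
  n_bins <- r0$n_bins
  R <- length(runs)
  for (r in runs[-1]) {
    if (!identical(r$labels, r0$labels) || r$n_bins != n_bins ||
        length(r$snap_time) != length(r0$snap_time)) {
      abort("all runs must share network, drive and snapshot layout.")
    }
  }

  tracked_pop <- r0$tracked_pop
  pool <- split(seq_along(r0$tracked), tracked_pop)  # row indices by population

  # fixed ordered-pair subsample per block
  set.seed(pair_seed)
  pair_idx <- list()
  for (a in seq_len(P)) {
    for (b in a:P) {
      ia <- pool[[as.character(a)]] %||% integer(0)
      ib <- pool[[as.character(b)]] %||% integer(0)
      n_av <- length(ia) * length(ib) - if (a == b) length(ia) else 0
      if (n_av <= 0) next
      npair <- min(pairs, n_av)
      ii <- ia[sample.int(length(ia), 2 * npair + 100, replace = TRUE)]
      jj <- ib[sample.int(length(ib), 2 * npair + 100, replace = TRUE)]
      keep <- ii != jj
      if (sum(keep) < npair) {
        grid <- expand.grid(i = ia, j = ib)
        grid <- grid[grid$i != grid$j, ]
        sel <- sample.int(nrow(grid), npair)
        pair_idx[[paste0(a, ".", b)]] <- list(i = grid$i[sel], j = grid$j[sel])
      } else {
        pair_idx[[paste0(a, ".", b)]] <- list(i = ii[keep][seq_len(npair)],
                                              j = jj[keep][seq_len(npair)])
      }
    }
  }

  labs <- r0$labels
  stats <- list()
  c_pop <- array(NA_real_, c(P, P, n_bins), dimnames = list(labs, labs, NULL))
  c_hat_arr <- array(NA_real_, c(P, P, n_bins), dimnames = list(labs, labs, NULL))

  for (b in seq_len(n_bins)) {
    cols <- which(r0$snap_bin == b)
    ncyc <- length(cols)
    X <- do.call(cbind, lapply(runs, function(r) r$snapshots[, cols, drop = FALSE]))
    trial_of <- rep(seq_len(R), each = ncyc)
    Rreal <- ncol(X)

    # population means from full population counts
    pc <- matrix(vapply(runs, function(r) {
      rowMeans(r$popcounts[, cols, drop = FALSE] / as.vector(r0$N))
    }, numeric(P)), nrow = P)  # P x R
    m_hat <- rowMeans(pc)
    m_se <- apply(pc, 1, sd) / sqrt(R)

    # single-unit variances from tracked neurons
    p_i <- rowMeans(X)
    v_i <- p_i * (1 - p_i) * Rreal / (Rreal - 1)
    a_hat <- as.vector(tapply(v_i, tracked_pop, mean))
    a_se <- as.vector(tapply(v_i, tracked_pop, function(x) sd(x) / sqrt(length(x))))

    Xc <- X - p_i
    for (a in seq_len(P)) {
      for (bb in a:P) {
        key <- paste0(a, ".", bb)
        pr <- pair_idx[[key]]
        if (is.null(pr)) {
          c_hat_arr[a, bb, b] <- c_hat_arr[bb, a, b] <- 0
          next
        }
        s_r <- colMeans(Xc[pr$i, , drop = FALSE] * Xc[pr$j, , drop = FALSE])
        per_trial <- tapply(s_r, trial_of, mean)
        c_ab <- mean(per_trial) * Rreal / (Rreal - 1)
        c_se <- sd(per_trial) / sqrt(R)
        c_hat_arr[a, bb, b] <- c_hat_arr[bb, a, b] <- c_ab
        stats[[length(stats) + 1L]] <- tibble(
          bin = b, kind = "c", component = paste0(labs[a], labs[bb]),
          estimate = c_ab, se = c_se
        )
      }
    }
    stats[[length(stats) + 1L]] <- tibble(
      bin = b, kind = "m", component = labs, estimate = m_hat, se = m_se
    )
    stats[[length(stats) + 1L]] <- tibble(
      bin = b, kind = "a", component = labs, estimate = a_hat, se = a_se
    )
    c_pop[, , b] <- diag(a_hat / as.vector(r0$N), nrow = P) + c_hat_arr[, , b]
  }

  stats <- bind_rows(stats)
  stats$phase <- (stats$bin - 0.5) / n_bins * 2 * pi
  structure(
    list(
      stats = arrange(stats, .data$kind, .data$component, .data$bin),
      c_pop = c_pop, c_hat = c_hat_arr,
      labels = labs, N = r0$N, dynamic = r0$dynamic,
      n_bins = n_bins, n_trials = R,
      n_realizations = length(r0$snap_time) %/% n_bins * R,
      drive = r0$drive,
      n_pairs = vapply(pair_idx, function(p) length(p$i), integer(1))
    ),
    class = "cyclostat_estimate"
  )
}

#' @export
print.cyclostat_estimate <- function(x, ...) {
  cat(sprintf("<cyclostat_estimate> %d trials x %d realizations/bin, %d phase bin(s)\n",
              x$n_trials, x$n_realizations %/% x$n_trials, x$n_bins))
  print(head(x$stats, 12))
  invisible(x)
}

#' @describeIn cyclostationary_stats Phase-binned estimates as a tibble.
#' @param x A `cyclostat_estimate`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cyclostat_estimate <- function(x, ...) x$stats

#' One-standard-deviation ellipse of the population activity
#'
#' The population-averaged activity vector fluctuates around its
#' (phase-dependent) mean with covariance `c_pop = diag(a / N) + c`. The set
#' of states one standard deviation away, `dm^T c_pop^{-1} dm = 1`,
#' restricted to the dynamic populations, is an ellipse centered at the mean
#' activity with principal axes along the eigenvectors of `c_pop` and
#' half-lengths equal to the square roots of its eigenvalues. Nonzero
#' cross-covariance tilts the axes; positive covariances make the full
#' ellipse enclose the variances-only ellipse.
#'
#' @param est A `cyclostat_estimate`, or directly a covariance matrix
#'   (`c_pop` on the dynamic sub-block).
#' @param bin Phase bin to use (when `est` is a `cyclostat_estimate`).
#' @param center Optional center (defaults to the estimated means, or zero
#'   for a bare matrix).
#' @return A list of class `population_ellipse`: `center`, `axes`
#'   (eigenvector columns), `half_lengths`, `c_pop`.
#' @export
population_ellipse <- function(est, bin = 1, center = NULL) {
  if (inherits(est, "cyclostat_estimate")) {
    dyn <- est$dynamic
    cp <- est$c_pop[dyn, dyn, bin]
    if (is.null(center)) {
      ms <- filter(est$stats, .data$kind == "m", .data$bin == !!bin)
      center <- setNames(ms$estimate, ms$component)[est$labels[dyn]]
    }
  } else if (is.matrix(est)) {
    cp <- est
    center <- center %||% rep(0, nrow(cp))
  } else {
    abort("`est` must be a cyclostat_estimate or a covariance matrix.")
  }
  ev <- eigen(cp, symmetric = TRUE)
  if (any(ev$values <= 0)) {
    abort("population covariance is singular or not positive definite: degenerate ellipse.",
          class = "oscibin_degenerate_ellipse")
  }
  structure(
    list(center = center, axes = ev$vectors,
         half_lengths = sqrt(ev$values), c_pop = cp),
    class = "population_ellipse"
  )
}

#' @export
print.population_ellipse <- function(x, ...) {
  cat("<population_ellipse> center:", format(x$center, digits = 4),
      " half-lengths:", format(x$half_lengths, digits = 4), "\n")
  invisible(x)
}
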