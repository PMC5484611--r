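#' Frequency sweep across the analytic, ODE and simulation layers
#'
#' Runs the requested analysis layers over a grid of drive frequencies and
#' collects the first-harmonic amplitudes and phases of the mean activities
#' and covariances in one tidy table: the machine-readable analogue of the
#' package's response spectra. Layers:
#'
#' * `"analytic"`: closed-form linear response ([mean_response()],
#'   [covariance_response()]), including the three-term decomposition.
#' * `"ode"`: numerical integration of the full moment equations
#'   ([integrate_moments()]) and harmonic extraction.
#' * `"simulate"`: Glauber-dynamics ensembles ([simulate_glauber()],
#'   [cyclostationary_stats()]) with harmonics of the phase-binned
#'   estimates.
#'
#' A failure in one layer at one frequency is recorded (`ok = FALSE`,
#' message in `note`) and the sweep continues.
#'
#' @param spec A [network_spec()].
#' @param h_ext Drive amplitude.
#' @param f_grid Frequency grid in Hz; default 60 log-spaced points in
#'   1--1000 Hz.
#' @param modes Subset of `c("analytic", "ode", "simulate")`.
#' @param periods ODE analysis periods per frequency.
#' @param sigma_dynamics Passed to [integrate_moments()] for the ODE layer;
#'   `"frozen"` reproduces the approximation of the analytic layer.
#' @param sim Options for the simulation layer: a list with elements
#'   `trials`, `duration`, `n_bins`, `tracked_per_pop`, `pairs`.
#' @param seed Base seed for the simulation layer.
#' @return An `oscibin_sweep` tibble: one row per frequency, layer, kind
#'   (`mean`/`covariance`), component and term (`total`, `Sh`, `Sm`, `a`),
#'   with `amplitude`, `phase`, `ok`, `note`. Attributes record the spec
#'   hash, seed and tolerances.
#' @examples
#' st_sweep <- run_frequency_sweep(preset_network("single_inhibitory"),
#'                                 h_ext = 0.5, f_grid = c(1, 10, 100))
#' @export
run_frequency_sweep <- function(spec, h_ext,
                                f_grid = exp(seq(log(1), log(1000), length.out = 60)),
                                modes = "analytic",
                                periods = 8,
                                sigma_dynamics = c("full", "frozen"),
                                sim = list(),
                                seed = 1) {
  stopifnot(inherits(spec, "network_spec"))
  if (length(f_grid) == 0) abort("`f_grid` must not be empty.")
  modes <- match.arg(modes, c("analytic", "ode", "simulate"), several.ok = TRUE)
  sigma_dynamics <- match.arg(sigma_dynamics)
  st <- solve_stationary(spec)
  sim_opts <- modifyList(list(trials = 10, duration = NULL, n_bins = 20,
                              tracked_per_pop = 400, pairs = 2000), sim)

  net <- NULL
  if ("simulate" %in% modes) net <- build_network(spec, seed = seed)

  rows <- purrr::map(seq_along(f_grid), function(k) {
    f <- f_grid[k]
    out <- list()
    if ("analytic" %in% modes) {
      out$analytic <- tryCatch({
        lr <- covariance_response(st, f, h_ext)
        mutate(tidy(lr), layer = "analytic", ok = TRUE, note = "")
      }, error = function(e) sweep_failure("analytic", f, e))
    }
    if ("ode" %in% modes) {
      out$ode <- tryCatch({
        traj <- integrate_moments(spec, drive_spec(h_ext, f), periods = periods,
                                  sigma_dynamics = sigma_dynamics)
        h <- extract_harmonics(traj, max_order = 2)
        h <- filter(h, .data$order == 1)
        tibble(kind = h$kind, component = h$component, term = "total",
               f_hz = f, amplitude = h$amplitude, phase = h$phase,
               re = h$re, im = h$im, layer = "ode", ok = TRUE, note = "")
      }, error = function(e) sweep_failure("ode", f, e))
    }
    if ("simulate" %in% modes) {
      out$simulate <- tryCatch({
        dur <- sim_opts$duration %||%
          (max(20 * spec$tau, 2000 / f) + 20 * 1000 / f)
        runs <- lapply(seq_len(sim_opts$trials), function(r) {
          simulate_glauber(net, drive_spec(h_ext, f), duration = dur,
                           seed = seed + 1000 * k + r,
                           n_bins = sim_opts$n_bins,
                           tracked_per_pop = sim_opts$tracked_per_pop)
        })
        est <- cyclostationary_stats(runs, pairs = sim_opts$pairs)
        harmonics_of_cyclostat(est)
      }, error = function(e) sweep_failure("simulate", f, e))
    }
    bind_rows(out)
  })
  out <- bind_rows(rows)
  structure(
    out,
    class = c("oscibin_sweep", class(out)),
    spec_name = spec$name, spec_hash = rlang::hash(spec),
    h_ext = h_ext, seed = seed, stationary = st
  )
}

sweep_failure <- function(layer, f, e) {
  tibble(kind = NA_character_, component = NA_character_, term = "total",
         f_hz = f, amplitude = NA_real_, phase = NA_real_,
         re = NA_real_, im = NA_real_,
         layer = layer, ok = FALSE, note = conditionMessage(e))
}

# first harmonic of the phase-binned estimates of a cyclostat_estimate
harmonics_of_cyclostat <- function(est) {
  f <- est$drive$f
  stats <- est$stats
  comps <- unique(stats[, c("kind", "component")])
  rows <- purrr::map(seq_len(nrow(comps)), function(i) {
    sub <- filter(stats, .data$kind == comps$kind[i],
                  .data$component == comps$component[i])
    sub <- arrange(sub, .data$bin)
    X1 <- 2i * mean(sub$estimate * exp(-1i * sub$phase))
    se <- 2 * sqrt(sum(sub$se^2)) / nrow(sub)
    tibble(
      kind = c(m = "mean", a = "variance", c = "covariance")[[comps$kind[i]]],
      component = comps$component[i], term = "total", f_hz = f,
      amplitude = Mod(X1), phase = Arg(X1), re = Re(X1), im = Im(X1),
      layer = "simulate", ok = TRUE, note = sprintf("se=%.3g", se)
    )
  })
  bind_rows(rows)
}

#' Plot a frequency sweep
#'
#' Log-log amplitude spectra of the first-harmonic responses, faceted by
#' component, with the covariance decomposition terms color-coded and the
#' layers distinguished by linetype/points.
#'
#' @param object An `oscibin_sweep` from [run_frequency_sweep()].
#' @param kind `"mean"`, `"covariance"` or both (default).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.oscibin_sweep <- function(object, kind = c("mean", "covariance"), ...) {
  df <- filter(as_tibble(object), .data$ok, .data$kind %in% !!kind,
               .data$amplitude > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f_hz, y = .data$amplitude,
                                   colour = .data$term,
                                   linetype = .data$layer)) +
    ggplot2::geom_line(data = ~ filter(.x, .data$layer == "analytic")) +
    ggplot2::geom_point(data = ~ filter(.x, .data$layer != "analytic"),
                        size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~ kind + component, scales = "free_y") +
    ggplot2::labs(x = "drive frequency (Hz)", y = "first-harmonic amplitude",
                  colour = "term", linetype = "layer") +
    ggplot2::theme_minimal()
}

#' Plot a moment trajectory
#'
#' Mean activities (and optionally covariances) against time.
#'
#' @param object A `moment_trajectory` from [integrate_moments()].
#' @param what `"m"`, `"c"` or both.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.moment_trajectory <- function(object, what = c("m", "c"), ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -"time",
                            names_to = c("kind", "component"), names_sep = "_")
  df <- filter(df, .data$kind %in% !!what)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ kind, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot phase-resolved cyclostationary estimates
#'
#' Estimates with ±2 SE ribbons against drive phase, faceted by statistic.
#'
#' @param object A `cyclostat_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cyclostat_estimate <- function(object, ...) {
  df <- object$stats
  ggplot2::ggplot(df, ggplot2::aes(.data$phase, .data$estimate,
                                   colour = .data$component,
                                   fill = .data$component)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$estimate - 2 * .data$se,
                                      ymax = .data$estimate + 2 * .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ kind, scales = "free_y", ncol = 1,
                        labeller = ggplot2::as_labeller(
                          c(m = "mean activity", a = "variance", c = "covariance"))) +
    ggplot2::labs(x = "drive phase (rad)", y = NULL) +
    ggplot2::theme_minimal()
}
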