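#' Define a population-level binary network model
#'
#' A network specification collects everything the mean-field layer, the
#' linear-response layer and the stochastic simulator need to know about a
#' recurrent random network of binary neurons: the populations, their sizes,
#' the fixed in-degree connectivity, synaptic weights, activation thresholds,
#' private noise and the update time constant.
#'
#' Populations are either *dynamic* (binary neurons updated through Glauber
#' dynamics, with a threshold `theta`) or *clamped* (source populations such
#' as an external pool whose mean activity is pinned at `m_clamped`; they
#' receive no input and have no threshold, but their Bernoulli variance
#' still feeds fluctuations into the network).
#'
#' The in-degree from population `b` into a neuron of population `a` is the
#' deterministic `K[a, b] = round(p[a, b] * N[b])`; every neuron in `a`
#' receives exactly that many connections, drawn uniformly without
#' replacement (and without self-connections).
#'
#' @param labels Character vector of population labels, e.g. `c("E", "I")`.
#'   Order fixes the index convention for all matrices.
#' @param N Named (or ordered) integer vector of population sizes.
#' @param tau Update time constant in milliseconds.
#' @param p Connection-probability matrix, rows = receiving population,
#'   columns = sending population, entries in `[0, 1]`.
#' @param J Synaptic-weight matrix (input units), same orientation as `p`.
#'   Each *column* (sending population) must carry a single sign.
#' @param sigma_noise Per-update Gaussian noise SD (input units) for dynamic
#'   populations; scalar or named vector.
#' @param theta Activation thresholds (input units) for dynamic populations;
#'   leave `NULL` (or `NA`) and use [calibrate_thresholds()] to set them from
#'   target mean activities.
#' @param clamped Character vector naming the clamped populations (possibly
#'   empty).
#' @param m_clamped Named vector of fixed mean activities in `(0, 1)` for the
#'   clamped populations.
#' @param target_m Optional named vector of target mean activities for the
#'   dynamic populations, used by [calibrate_thresholds()] and as the
#'   initialization of [solve_stationary()].
#' @param name Optional short name carried in printouts and file headers.
#' @param notes Optional free-text metadata (e.g. provenance of parameters).
#'
#' @return An object of class `network_spec`.
#' @seealso [preset_network()], [calibrate_thresholds()], [solve_stationary()]
#' @examples
#' spec <- network_spec(
#'   labels = "I", N = 5000, tau = 10, p = matrix(0.1), J = matrix(-1),
#'   sigma_noise = 10.2, target_m = 0.3
#' )
#' spec
#' @export
network_spec <- function(labels, N, tau, p, J, sigma_noise = 0,
                         theta = NULL, clamped = character(0),
                         m_clamped = NULL, target_m = NULL,
                         name = NULL, notes = NULL) {
  labels <- as.character(labels)
  P <- length(labels)
  if (P == 0 || anyDuplicated(labels)) {
    abort("`labels` must be a non-empty set of unique population names.")
  }
  N <- expand_named(N, labels, "N")
  p <- as_pop_matrix(p, labels, "p")
  J <- as_pop_matrix(J, labels, "J")
  sigma_noise <- expand_named(sigma_noise, labels, "sigma_noise")
  dynamic <- !(labels %in% clamped)
  names(dynamic) <- labels
  if (!all(clamped %in% labels)) abort("`clamped` must name existing populations.")

  theta_full <- setNames(rep(NA_real_, P), labels)
  if (!is.null(theta)) {
    theta <- expand_named(theta, labels[dynamic], "theta")
    theta_full[names(theta)] <- theta
  }
  m_cl <- setNames(rep(NA_real_, P), labels)
  if (any(!dynamic)) {
    if (is.null(m_clamped)) abort("clamped populations need `m_clamped`.")
    m_clamped <- expand_named(m_clamped, labels[!dynamic], "m_clamped")
    m_cl[names(m_clamped)] <- m_clamped
  }
  tgt <- NULL
  if (!is.null(target_m)) tgt <- expand_named(target_m, labels[dynamic], "target_m")

  # clamped populations receive nothing
  p[!dynamic, ] <- 0
  K <- round(p %*% diag(N, nrow = P))
  dimnames(K) <- dimnames(p)
  storage.mode(K) <- "double"

  spec <- structure(
    list(
      labels = labels, dynamic = dynamic, N = N, tau = tau,
      p = p, J = J, K = K, theta = theta_full,
      sigma_noise = sigma_noise, m_clamped = m_cl, target_m = tgt,
      name = name %||% "network", notes = notes
    ),
    class = "network_spec"
  )
  validate_network_spec(spec)
  spec
}

expand_named <- function(x, labels, what) {
  if (length(x) == 1 && is.null(names(x))) x <- rep(x, length(labels))
  if (is.null(names(x))) {
    if (length(x) != length(labels)) {
      abort(sprintf("`%s` must have length %d or be named.", what, length(labels)))
    }
    names(x) <- labels
  }
  if (!all(labels %in% names(x))) {
    abort(sprintf("`%s` is missing entries for: %s", what,
                  paste(setdiff(labels, names(x)), collapse = ", ")))
  }
  x <- x[labels]
  if (anyNA(x)) abort(sprintf("`%s` contains missing values.", what))
  x
}

as_pop_matrix <- function(x, labels, what) {
  P <- length(labels)
  x <- as.matrix(x)
  if (!all(dim(x) == c(P, P))) {
    abort(sprintf("`%s` must be a %d x %d matrix (receiver rows, sender columns).",
                  what, P, P))
  }
  dimnames(x) <- list(labels, labels)
  x
}

validate_network_spec <- function(spec) {
  with(spec, {
    if (!is.numeric(tau) || length(tau) != 1 || tau <= 0) abort("`tau` must be > 0.")
    if (any(N < 1)) abort("all population sizes must be >= 1.")
    if (any(sigma_noise < 0)) abort("`sigma_noise` must be >= 0.")
    if (any(p < 0 | p > 1)) abort("`p` entries must lie in [0, 1].")
    bad_k <- K > matrix(N, nrow = length(N), ncol = length(N), byrow = TRUE)
    if (any(bad_k)) abort("in-degrees K must not exceed the sending population size.")
    for (b in seq_along(labels)) {
      col <- J[, b][K[, b] > 0]
      if (length(col) && any(col > 0) && any(col < 0)) {
        abort(sprintf("column '%s' of `J` mixes signs; a sending population is either excitatory or inhibitory.",
                      labels[b]))
      }
    }
    if (any(!dynamic)) {
      mc <- m_clamped[!dynamic]
      if (any(mc <= 0 | mc >= 1)) abort("`m_clamped` must lie strictly in (0, 1).")
      if (any(K[!dynamic, , drop = FALSE] != 0)) {
        abort("clamped populations must have zero in-degree.")
      }
    }
  })
  invisible(spec)
}

n_pop <- function(spec) length(spec$labels)

#' @export
print.network_spec <- function(x, ...) {
  P <- n_pop(x)
  cat(sprintf("<network_spec> '%s': %d population%s, tau = %g ms\n",
              x$name, P, if (P > 1) "s" else "", x$tau))
  df <- data.frame(
    population = x$labels,
    kind = ifelse(x$dynamic, "dynamic", "clamped"),
    N = as.integer(x$N),
    theta = round(x$theta, 4),
    sigma_noise = x$sigma_noise,
    m_clamped = x$m_clamped,
    row.names = NULL
  )
  print(df)
  cat("in-degrees K (receiver x sender):\n")
  print(x$K)
  cat("weights J:\n")
  print(x$J)
  invisible(x)
}

#' Specify the sinusoidal drive
#'
#' All neurons receive a common input `h_ext * sin(2 pi f t)` on top of their
#' recurrent and noise input. Frequencies are user-facing in Hz; internally
#' the angular frequency is carried in rad/ms (`omega = 2 pi f / 1000`).
#'
#' @param h_ext Drive amplitude in input units (`>= 0`).
#' @param f Drive frequency in Hz (`>= 0`; `f = 0` means no modulation).
#' @return An object of class `drive_spec` with fields `h_ext`, `f` and
#'   `omega` (rad/ms).
#' @examples
#' drive_spec(1, 80)
#' @export
drive_spec <- function(h_ext, f) {
  if (!is.numeric(h_ext) || length(h_ext) != 1 || h_ext < 0) abort("`h_ext` must be >= 0.")
  if (!is.numeric(f) || length(f) != 1 || f < 0) abort("`f` must be >= 0.")
  structure(list(h_ext = h_ext, f = f, omega = 2 * pi * f / 1000),
            class = "drive_spec")
}

#' @export
print.drive_spec <- function(x, ...) {
  cat(sprintf("<drive_spec> h_ext = %g, f = %g Hz (omega = %g rad/ms)\n",
              x$h_ext, x$f, x$omega))
  invisible(x)
}

#' Bundle population means and covariances at one time point
#'
#' @param m Vector of population mean activities in `[0, 1]` (ordered as
#'   `spec$labels`).
#' @param c Symmetric matrix of population-averaged pairwise covariances;
#'   defaults to all zeros. Entries between pairs of clamped populations are
#'   forced to zero.
#' @param spec A [network_spec()].
#' @return An object of class `moment_state` with fields `m`, `c` and the
#'   derived Bernoulli variances `a = m * (1 - m)`.
#' @export
moment_state <- function(m, c = NULL, spec) {
  P <- n_pop(spec)
  m <- expand_named(m, spec$labels, "m")
  if (any(m < 0 | m > 1)) abort("mean activities must lie in [0, 1].")
  if (is.null(c)) c <- matrix(0, P, P)
  c <- as_pop_matrix(c, spec$labels, "c")
  if (max(abs(c - t(c))) > 1e-10) abort("`c` must be symmetric.")
  c <- (c + t(c)) / 2
  cl <- !spec$dynamic
  c[cl, cl] <- 0
  structure(list(m = m, c = c, a = m * (1 - m)), class = "moment_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
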