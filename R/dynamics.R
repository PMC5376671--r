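#' The logistic regulation function
#'
#' \eqn{F(u) = 1 / (1 + e^{-\sigma u})}: strictly increasing in `u`, range
#' (0, 1), `F(0) = 0.5`. Because the production term of every species is a
#' value of `F`, the unit box is forward-invariant for the dynamics.
#'
#' @param u Regulatory input (any numeric array).
#' @param sigma Steepness, strictly positive.
#' @return Values of `F(u)`, same shape as `u`.
#' @export
sigmoid <- function(u, sigma) {
  assert_scalar_number(sigma, "sigma", positive = TRUE)
  1 / (1 + exp(-sigma * u))
}

#' Summed regulatory input of one species
#'
#' Computes \eqn{u_i = b_i + \sum_j \omega_{j\to i} X_j +
#' \omega_{RA\to i} RA + \omega_{FGF\to i} FGF} for a single cell.
#'
#' @param spec A [network_spec()].
#' @param state Named numeric vector of species values \eqn{X_j}.
#' @param morphogens Named numeric vector with elements `RA` and `FGF`
#'   (non-negative levels); missing morphogens are taken as 0.
#' @param target Species identifier.
#' @return The scalar input \eqn{u_i}.
#' @export
regulatory_input <- function(spec, state, morphogens = c(RA = 0, FGF = 0),
                             target) {
  stopifnot(inherits(spec, "network_spec"))
  if (!target %in% spec$species) {
    stop("unknown species `", target, "`", call. = FALSE)
  }
  m <- c(RA = 0, FGF = 0)
  m[names(morphogens)] <- morphogens
  if (any(m < 0)) stop("morphogen levels must be non-negative", call. = FALSE)
  x <- state[spec$species]
  if (any(is.na(x))) stop("`state` must cover every species", call. = FALSE)
  w <- spec$omega[target, ]
  unname(spec$basal[[target]] +
    sum(w[spec$species] * x) + w[["RA"]] * m[["RA"]] + w[["FGF"]] * m[["FGF"]])
}

#' Time derivatives of all species in one cell
#'
#' \eqn{dX_i/dt = \gamma_i\,(F(u_i) - X_i)}; zero exactly when
#' \eqn{X_i = F(u_i)}. Species listed in `spec$clamp_zero` have derivative 0.
#'
#' @inheritParams regulatory_input
#' @return Named numeric vector of rates, one per species.
#' @export
derivatives <- function(spec, state, morphogens = c(RA = 0, FGF = 0)) {
  stopifnot(inherits(spec, "network_spec"))
  eng <- build_engine(spec, n_cells = 1L)
  S <- matrix(state[spec$species], nrow = 1L)
  m <- c(RA = 0, FGF = 0)
  m[names(morphogens)] <- morphogens
  M <- matrix(m, nrow = 1L)
  setNames(drop(engine_deriv(eng, S, engine_const(eng, M))), spec$species)
}

# ---- internal vectorised engine -------------------------------------------
#
# All simulation paths funnel through this fixed-step RK4 integrator acting
# on an (n_cells x n_species) state matrix. Morphogen inputs are
# piecewise-constant in time (one matrix per noise interval), so the
# constant part of the regulatory input, basal + M %*% t(omega_morph),
# is folded once per interval.

build_engine <- function(spec, n_cells) {
  n <- length(spec$species)
  structure(list(
    species = spec$species,
    t_osp = t(spec$omega[, spec$species, drop = FALSE]),
    t_om = t(spec$omega[, c("RA", "FGF"), drop = FALSE]),
    basal_mat = matrix(spec$basal, n_cells, n, byrow = TRUE),
    gamma_mat = matrix(spec$gamma, n_cells, n, byrow = TRUE),
    sigma = spec$sigma,
    clamp = spec$species %in% spec$clamp_zero,
    n_cells = n_cells
  ), class = "hoxmir_engine")
}

# Constant part of u for a fixed morphogen matrix M (n_cells x 2).
engine_const <- function(eng, M) {
  eng$basal_mat + M %*% eng$t_om
}

engine_deriv <- function(eng, S, C) {
  U <- S %*% eng$t_osp + C
  D <- eng$gamma_mat * (1 / (1 + exp(-eng$sigma * U)) - S)
  if (any(eng$clamp)) D[, eng$clamp] <- 0
  D
}

rk4_step <- function(eng, S, C, dt) {
  k1 <- engine_deriv(eng, S, C)
  k2 <- engine_deriv(eng, S + dt / 2 * k1, C)
  k3 <- engine_deriv(eng, S + dt / 2 * k2, C)
  k4 <- engine_deriv(eng, S + dt * k3, C)
  S + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# Integrate over [0, t_span] with morphogen matrices given per noise
# interval. `m_list` is a list of (n_cells x 2) matrices, `interval` their
# common duration. Returns list(times, states = array[cell, species, time]).
engine_integrate <- function(eng, S0, m_list, interval, t_span, dt,
                             store_every = dt) {
  if (!is_multiple(interval, dt)) {
    stop("noise interval must be a multiple of the integration step `dt`",
      call. = FALSE
    )
  }
  if (!is_multiple(store_every, dt)) {
    stop("`store_every` must be a multiple of `dt`", call. = FALSE)
  }
  n_steps <- round(t_span / dt)
  steps_per_interval <- round(interval / dt)
  store_stride <- round(store_every / dt)
  store_idx <- seq(0L, n_steps, by = store_stride)
  times <- store_idx * dt

  if (any(eng$clamp)) S0[, eng$clamp] <- 0
  n_sp <- length(eng$species)
  states <- array(NA_real_,
    dim = c(eng$n_cells, n_sp, length(times)),
    dimnames = list(NULL, eng$species, NULL)
  )
  states[, , 1L] <- S0

  S <- S0
  slot <- 1L
  for (step in seq_len(n_steps)) {
    iv <- min((step - 1L) %/% steps_per_interval + 1L, length(m_list))
    if ((step - 1L) %% steps_per_interval == 0L || step == 1L) {
      C <- engine_const(eng, m_list[[iv]])
    }
    S <- rk4_step(eng, S, C, dt)
    if (step %% store_stride == 0L) {
      slot <- slot + 1L
      if (any(!is.finite(S))) {
        bad <- which(!is.finite(S), arr.ind = TRUE)
        stop(sprintf(
          "non-finite trajectory at t = %.4g (species `%s`)",
          step * dt, eng$species[bad[1L, 2L]]
        ), call. = FALSE)
      }
      states[, , slot] <- S
    }
  }
  list(times = times, states = states)
}

# ---- user-facing integration ----------------------------------------------

#' Integrate the network ODEs for one or more cells
#'
#' Fixed-step fourth-order Runge-Kutta integration of the
#' sigmoidal-relaxation system, supporting many cells in parallel (same
#' network, per-cell morphogen input). Morphogens may be a constant level,
#' or a [sample_noise_trace()] object giving piecewise-constant noisy
#' levels; noise interval boundaries always coincide with step boundaries.
#'
#' @param spec A [network_spec()].
#' @param initial Initial state: named numeric vector (one cell, recycled
#'   across cells) or an `n_cells` x `n_species` matrix.
#' @param morphogens Either a named vector `c(RA=, FGF=)` of constant
#'   levels applied to every cell, or a `morphogen_trace` from
#'   [sample_noise_trace()] (which also fixes `n_cells`).
#' @param t_span Length of simulated time, days.
#' @param dt Integration step, days (default 0.01).
#' @param store_every Interval between stored time points, days; must be a
#'   multiple of `dt`.
#' @param n_cells Number of cells when `morphogens` is a constant vector.
#' @return A tibble in long format with columns `cell`, `species`, `time`,
#'   `value`. The dense array is attached as attribute `"states"`
#'   (`cell` x `species` x `time`) with `"times"`.
#' @export
#' @examples
#' spec <- hox_consensus_network()
#' traj <- integrate_network(spec,
#'   initial = rep(0, 5), morphogens = c(RA = 1, FGF = 0),
#'   t_span = 2, store_every = 0.1
#' )
#' head(traj)
integrate_network <- function(spec, initial, morphogens, t_span,
                              dt = 0.01, store_every = dt, n_cells = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  assert_scalar_number(dt, "dt", positive = TRUE)
  assert_scalar_number(t_span, "t_span", positive = TRUE)
  if (t_span < dt) stop("`t_span` must be at least `dt`", call. = FALSE)

  if (inherits(morphogens, "morphogen_trace")) {
    if (t_span > morphogens$duration + 1e-9) {
      stop("morphogen trace does not cover `t_span`", call. = FALSE)
    }
    n_cells <- morphogens$n_cells
    m_list <- trace_matrices(morphogens)
    interval <- morphogens$interval
  } else {
    m <- c(RA = 0, FGF = 0)
    m[names(morphogens)] <- morphogens
    n_cells <- n_cells %||% if (is.matrix(initial)) nrow(initial) else 1L
    m_list <- list(matrix(m, n_cells, 2L, byrow = TRUE,
      dimnames = list(NULL, c("RA", "FGF"))
    ))
    interval <- t_span
  }

  S0 <- init_state_matrix(spec, initial, n_cells)
  eng <- build_engine(spec, n_cells)
  res <- engine_integrate(eng, S0, m_list, interval, t_span, dt, store_every)

  out <- tidy_states(res$states, res$times, spec$species)
  attr(out, "states") <- res$states
  attr(out, "times") <- res$times
  out
}

init_state_matrix <- function(spec, initial, n_cells) {
  n <- length(spec$species)
  if (is.matrix(initial)) {
    stopifnot(ncol(initial) == n, nrow(initial) == n_cells)
    S0 <- initial
  } else {
    x <- if (!is.null(names(initial))) initial[spec$species] else initial
    stopifnot(length(x) == n, !any(is.na(x)))
    S0 <- matrix(x, n_cells, n, byrow = TRUE)
  }
  colnames(S0) <- spec$species
  S0
}

tidy_states <- function(states, times, species) {
  n_cells <- dim(states)[1L]
  cell_col <- rep(seq_len(n_cells), times = length(species) * length(times))
  species_col <- rep(rep(species, each = n_cells), times = length(times))
  time_col <- rep(times, each = n_cells * length(species))
  tibble::tibble(
    cell = cell_col, species = species_col, time = time_col,
    value = as.vector(states)
  )
}

#' Relax a network to steady state under constant morphogens
#'
#' Integrates until every per-species rate is below `tol` (in absolute
#' value), mirroring the pre-morphogen equilibration phase of the
#' developmental protocol.
#'
#' @inheritParams integrate_network
#' @param morphogens Named vector of constant levels (default: none).
#' @param tol Convergence tolerance on `max |dX/dt|` (1/day).
#' @param t_max Maximum integration time before giving up, days.
#' @param dt Integration step used during relaxation; by default chosen
#'   from the network's stiffness bound
#'   (\eqn{\max_i \gamma_i (1 + \sigma \max_j |\omega_{j\to i}| / 4)}) so
#'   the explicit scheme stays stable for strongly coupled networks.
#' @return Named numeric vector: the steady state (single cell).
#' @export
relax_to_steady_state <- function(spec, initial = NULL,
                                  morphogens = c(RA = 0, FGF = 0),
                                  tol = 1e-6, t_max = 100, dt = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  assert_scalar_number(tol, "tol", positive = TRUE)
  if (is.null(dt)) {
    # largest local rate: gamma_i * (1 + sigma/4 * max_j |omega_{j->i}|)
    lam <- max(spec$gamma * (1 + spec$sigma / 4 *
      apply(abs(spec$omega), 1L, max)))
    dt <- min(0.02, 1 / lam)
  }
  n <- length(spec$species)
  initial <- initial %||% setNames(rep(0, n), spec$species)
  S <- init_state_matrix(spec, initial, 1L)
  eng <- build_engine(spec, 1L)
  m <- c(RA = 0, FGF = 0)
  m[names(morphogens)] <- morphogens
  C <- engine_const(eng, matrix(m, 1L, 2L))
  if (any(eng$clamp)) S[, eng$clamp] <- 0

  chunk_steps <- max(1L, round(1 / dt)) # check residual every ~1 day
  t <- 0
  repeat {
    D <- engine_deriv(eng, S, C)
    if (max(abs(D)) < tol) {
      return(setNames(drop(S), spec$species))
    }
    if (t >= t_max) {
      stop(sprintf(
        "steady state not reached by t_max = %g (max residual %.3g)",
        t_max, max(abs(D))
      ), call. = FALSE)
    }
    for (i in seq_len(chunk_steps)) S <- rk4_step(eng, S, C, dt)
    if (any(!is.finite(S))) {
      stop("non-finite state during relaxation", call. = FALSE)
    }
    t <- t + chunk_steps * dt
  }
}
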