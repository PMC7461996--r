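#' Reservoir hyper-parameters
#'
#' Bundles every constant of the leaky-integrate rate network:
#' \deqn{\tau \, dx/dt = -\alpha_l x + W_{res}\, r + W_{in}^T u + \xi,
#'       \qquad r = \tanh(x),}
#' integrated with Heun's predictor--corrector method at step `dt`.
#' A trial has two phases: a sensory phase of `sensory_ms` during which
#' the input drives the network, and a motor phase of `motor_ms` during
#' which the input is detached and the readout draws its trajectory.
#'
#' Defaults follow the usual desk references for this architecture:
#' \itemize{
#'   \item `tau = 40` ms, `leak = 0.8`, `dt = 1` ms;
#'   \item `spectral_radius = 1.5`, placing the autonomous reservoir in
#'     the rich, near-chaotic regime whose transients carry the echo;
#'   \item `sensory_ms = motor_ms = 300` ms, `n_in = 39` input channels
#'     (a cochleagram-like band count), `n_out = 2` (x, y coordinates
#'     per drawn pattern).
#' }
#'
#' @param n_res number of reservoir neurons.
#' @param n_in number of input channels.
#' @param n_out readout channels per output pattern (2 for x/y drawing).
#' @param tau uniform membrane time constant, ms.
#' @param leak leak coefficient \eqn{\alpha_l}, in (0, 1].
#' @param dt integration step, ms.
#' @param spectral_radius target spectral radius for the recurrent
#'   weight matrix after rescaling.
#' @param sensory_ms,motor_ms phase durations, ms; positive multiples of
#'   `dt`.
#' @param seed default RNG seed for weight initialization.
#' @return An object of class `reservoir_params` (a validated list).
#' @export
reservoir_params <- function(n_res = 400L, n_in = 39L, n_out = 2L,
                             tau = 40, leak = 0.8, dt = 1,
                             spectral_radius = 1.5,
                             sensory_ms = 300, motor_ms = 300,
                             seed = 1L) {
  p <- list(
    n_res = check_count(n_res, "n_res"),
    n_in = check_count(n_in, "n_in"),
    n_out = check_count(n_out, "n_out"),
    tau = check_positive(tau, "tau"),
    leak = check_positive(leak, "leak"),
    dt = check_positive(dt, "dt"),
    spectral_radius = check_positive(spectral_radius, "spectral_radius"),
    sensory_ms = check_positive(sensory_ms, "sensory_ms"),
    motor_ms = check_positive(motor_ms, "motor_ms"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (p$leak > 1) stop_config("leak must lie in (0, 1]")
  for (ph in c("sensory_ms", "motor_ms")) {
    k <- p[[ph]] / p$dt
    if (abs(k - round(k)) > 1e-9)
      stop_config(ph, " (", p[[ph]], ") must be a multiple of dt (", p$dt, ")")
  }
  structure(p, class = "reservoir_params")
}

#' @rdname reservoir_params
#' @param params a `reservoir_params` object.
#' @export
sensory_steps <- function(params) as.integer(round(params$sensory_ms / params$dt))

#' @rdname reservoir_params
#' @export
motor_steps <- function(params) as.integer(round(params$motor_ms / params$dt))

#' @rdname reservoir_params
#' @export
total_steps <- function(params) sensory_steps(params) + motor_steps(params)

#' @export
print.reservoir_params <- function(x, ...) {
  cat("<reservoir_params> n_res=", x$n_res, " n_in=", x$n_in,
      " n_out=", x$n_out, "\n  tau=", x$tau, "ms leak=", x$leak,
      " dt=", x$dt, "ms spectral_radius=", x$spectral_radius,
      "\n  sensory=", x$sensory_ms, "ms motor=", x$motor_ms,
      "ms seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Rescale a square matrix to a target spectral radius
#'
#' Multiplies `W` by `target / max(Mod(eigenvalues))`.  Idempotent up to
#' floating precision: rescaling an already-rescaled matrix is a no-op.
#'
#' @param W square numeric matrix with nonzero spectral radius.
#' @param target desired spectral radius (> 0).
#' @return The rescaled matrix.
#' @export
scale_spectral_radius <- function(W, target) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop_config("W must be a square matrix")
  target <- check_positive(target, "target")
  sr <- max(Mod(eigen(W, only.values = TRUE)$values))
  if (sr == 0) stop_config("matrix has zero spectral radius; cannot rescale")
  W * (target / sr)
}

#' Initialize network weights
#'
#' Input and recurrent weights are drawn i.i.d. standard normal; the
#' recurrent matrix is then rescaled so its spectral radius equals
#' `params$spectral_radius` exactly (to floating precision).  The
#' network is fully connected (no sparsity mask) because every
#' connection is subsequently trained.  Readout weights start at zero.
#'
#' @param params a [reservoir_params()].
#' @param rng_seed integer seed; identical seeds give bit-identical
#'   weights.  Defaults to `params$seed`.
#' @return An object of class `weight_set` with elements
#'   \describe{
#'     \item{W_in}{`n_in x n_res` input weights (input `u` enters the
#'       state equation as `t(W_in) %*% u`).}
#'     \item{W_res}{`n_res x n_res` recurrent weights.}
#'     \item{W_out}{named list of `n_res x n_out` readout matrices, one
#'       per output pattern, initialized to a single all-zero entry.}
#'   }
#' @export
init_weights <- function(params, rng_seed = params$seed) {
  stopifnot(inherits(params, "reservoir_params"))
  rng_seed <- check_count(rng_seed, "rng_seed", min = 0L)
  with_seed(rng_seed, {
    W_in <- matrix(stats::rnorm(params$n_in * params$n_res),
                   params$n_in, params$n_res)
    W_res <- matrix(stats::rnorm(params$n_res^2),
                    params$n_res, params$n_res)
    W_res <- scale_spectral_radius(W_res, params$spectral_radius)
    structure(list(W_in = W_in, W_res = W_res,
                   W_out = list(output = matrix(0, params$n_res,
                                                params$n_out))),
              class = "weight_set")
  })
}

#' @export
print.weight_set <- function(x, ...) {
  cat("<weight_set> W_in ", nrow(x$W_in), "x", ncol(x$W_in),
      ", W_res ", nrow(x$W_res), "x", ncol(x$W_res),
      ", ", length(x$W_out), " readout block(s)\n", sep = "")
  invisible(x)
}

#' Network state
#'
#' @param x length-`n_res` membrane state vector.
#' @return A list with `x` and the firing rates `r = tanh(x)`.
#' @export
network_state <- function(x) {
  if (!is.numeric(x)) stop_config("state x must be numeric")
  list(x = as.numeric(x), r = tanh(as.numeric(x)))
}

# One Heun step of the leaky-integrator ODE.  `Wu` is the (constant over
# the step) input drive t(W_in) %*% u plus any noise term; noise enters
# the drift and is held fixed across predictor and corrector.
heun_step_x <- function(x, Wu, W_res, leak, tau, dt) {
  d1 <- (W_res %*% tanh(x) + (Wu - leak * x)) / tau
  xp <- x + dt * d1
  d2 <- (W_res %*% tanh(xp) + (Wu - leak * xp)) / tau
  x + (dt / 2) * (d1 + d2)
}

#' Advance the reservoir by one integration step
#'
#' Performs a single Heun (predictor--corrector) step of the state
#' equation with the input held constant over the step (zero-order
#' hold), then recomputes the rates.  Gaussian noise of standard
#' deviation `noise_amp` is added to the drift, drawn once per step and
#' shared between predictor and corrector; `noise_amp = 0` is fully
#' deterministic.
#'
#' @param state a [network_state()] (list with `x`, `r`).
#' @param u_t input vector of length `params$n_in`.
#' @param weights a [init_weights()] weight set.
#' @param params a [reservoir_params()].
#' @param noise_amp standard deviation of the additive state noise.
#' @return The new `network_state`.
#' @export
reservoir_step <- function(state, u_t, weights, params, noise_amp = 0) {
  if (length(u_t) != params$n_in)
    stop_config("input vector has length ", length(u_t),
                " but params$n_in = ", params$n_in)
  if (length(state$x) != params$n_res)
    stop_config("state has length ", length(state$x),
                " but params$n_res = ", params$n_res)
  Wu <- drop(crossprod(weights$W_in, u_t))
  if (noise_amp > 0) Wu <- Wu + stats::rnorm(params$n_res, 0, noise_amp)
  x_new <- drop(heun_step_x(state$x, Wu, weights$W_res,
                            params$leak, params$tau, params$dt))
  network_state(x_new)
}

#' Simulate the reservoir over a full input signal
#'
#' Integrates the network over every column of `input`, holding the
#' input at zero from the phase boundary on (the motor phase is driven
#' only by the echo of the sensory input).  With `x0 = 0` and
#' `noise_amp = 0` the result is deterministic; with noise, `seed`
#' makes it reproducible.
#'
#' @param input a [temporal_signal()] whose `dt` equals `params$dt`.
#' @param weights,params network weights and parameters.
#' @param x0 initial state vector (default all zeros).
#' @param noise_amp per-step Gaussian state-noise SD (default 0).
#' @param seed optional seed applied when `noise_amp > 0`.
#' @return A `temporal_signal` holding the `n_res x timesteps` rate
#'   trajectory `r(t)`, with the input's `dt` and phase boundary.
#' @export
simulate_reservoir <- function(input, weights, params, x0 = NULL,
                               noise_amp = 0, seed = NULL) {
  stopifnot(inherits(input, "temporal_signal"))
  if (!isTRUE(all.equal(input$dt, params$dt)))
    stop_config("input dt (", input$dt, ") does not match params dt (",
                params$dt, ")")
  if (nrow(input$values) != params$n_in)
    stop_config("input has ", nrow(input$values),
                " channels but params$n_in = ", params$n_in)
  run <- function() {
    U <- input$values
    pb <- input$phase_boundary
    if (!is.null(pb) && pb < ncol(U)) U[, (pb + 1L):ncol(U)] <- 0
    T_n <- ncol(U)
    x <- if (is.null(x0)) numeric(params$n_res) else as.numeric(x0)
    if (length(x) != params$n_res)
      stop_config("x0 must have length n_res = ", params$n_res)
    R <- matrix(0, params$n_res, T_n)
    WinT <- t(weights$W_in)
    for (t in seq_len(T_n)) {
      Wu <- drop(WinT %*% U[, t])
      if (noise_amp > 0)
        Wu <- Wu + stats::rnorm(params$n_res, 0, noise_amp)
      x <- drop(heun_step_x(x, Wu, weights$W_res,
                            params$leak, params$tau, params$dt))
      R[, t] <- tanh(x)
    }
    temporal_signal(R, dt = params$dt, phase_boundary = input$phase_boundary)
  }
  if (!is.null(seed) && noise_amp > 0) with_seed(seed, run()) else run()
}

#' Linear readout of a rate trajectory
#'
#' Applies `y(t) = t(W_out) %*% r(t)` at every step; the readout is
#' purely linear with no output nonlinearity and no feedback into the
#' reservoir.
#'
#' @param rates a rate trajectory ([temporal_signal()] or `n_res x T`
#'   matrix).
#' @param W_out `n_res x n_out` readout matrix.
#' @return A `temporal_signal` of the `n_out x T` output (when `rates`
#'   is a `temporal_signal`), else a plain matrix.
#' @export
readout <- function(rates, W_out) {
  R <- signal_values(rates)
  if (!is.matrix(W_out) || nrow(W_out) != nrow(R))
    stop_config("W_out must have one row per reservoir neuron (",
                nrow(R), ")")
  Y <- crossprod(W_out, R)
  if (inherits(rates, "temporal_signal"))
    temporal_signal(Y, dt = rates$dt, phase_boundary = rates$phase_boundary)
  else Y
}

#' Eigenvalue spectrum of a weight matrix
#'
#' Returns all complex eigenvalues, used to compare the recurrent
#' matrix before and after training (training compresses the spectrum,
#' a signature of increased stability).
#'
#' @param W square numeric matrix.
#' @return Complex vector of length `nrow(W)`.
#' @export
eigen_spectrum <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop_config("eigen_spectrum needs a square matrix")
  eigen(W, only.values = TRUE)$values
}
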