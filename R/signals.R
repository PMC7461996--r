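#' Multi-channel temporal signal
#'
#' The basic container for channel-by-time data: inputs to the reservoir
#' (e.g. cochleagram-like band amplitudes), reservoir firing-rate
#' trajectories, and readout outputs.  Rows are channels, columns are
#' time steps.  An optional `phase_boundary` marks the first step of the
#' motor phase (the step count of the sensory phase): during the motor
#' phase the input to the reservoir is detached (held at zero) and the
#' readout draws its trajectory.
#'
#' @param values numeric matrix, channels x timesteps.
#' @param dt time step in ms per column.
#' @param phase_boundary integer index of the first motor-phase step
#'   (equivalently, the number of sensory-phase steps), in
#'   `[0, timesteps]`, or `NULL` for a pure sensory signal.
#' @return An object of class `temporal_signal`: a list with elements
#'   `values`, `dt`, `phase_boundary`.
#' @export
#' @examples
#' s <- temporal_signal(matrix(rnorm(20), 2, 10), dt = 1)
#' n_channels(s); n_steps(s)
temporal_signal <- function(values, dt, phase_boundary = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_config("values must be a numeric matrix (channels x timesteps)")
  if (ncol(values) < 1L)
    stop_config("a temporal signal needs at least one time step")
  dt <- check_positive(dt, "dt")
  if (!is.null(phase_boundary)) {
    phase_boundary <- check_count(phase_boundary, "phase_boundary", min = 0L)
    if (phase_boundary > ncol(values))
      stop_config("phase_boundary (", phase_boundary,
                  ") exceeds the number of time steps (", ncol(values), ")")
  }
  structure(list(values = values, dt = dt, phase_boundary = phase_boundary),
            class = "temporal_signal")
}

#' @rdname temporal_signal
#' @param x a `temporal_signal`.
#' @export
n_channels <- function(x) nrow(x$values)

#' @rdname temporal_signal
#' @export
n_steps <- function(x) ncol(x$values)

#' @export
print.temporal_signal <- function(x, ...) {
  cat("<temporal_signal> ", n_channels(x), " channel(s) x ", n_steps(x),
      " step(s), dt = ", x$dt, " ms", sep = "")
  if (!is.null(x$phase_boundary))
    cat(", motor phase from step ", x$phase_boundary + 1L, sep = "")
  cat("\n")
  invisible(x)
}

# Accept either a temporal_signal or a bare matrix where convenient.
signal_values <- function(x) {
  if (inherits(x, "temporal_signal")) x$values
  else if (is.matrix(x)) x
  else stop_config("expected a temporal_signal or a numeric matrix")
}

#' Write / read a temporal signal as delimited text
#'
#' One row per channel, tab-separated, preceded by a header line
#' `# dt=<dt> phase_boundary=<k or NA>`.  Values are printed with 17
#' significant digits so a write/read round trip is bit exact.
#'
#' @param x a [temporal_signal()].
#' @param path file path.
#' @return `write_temporal_signal` returns `path` invisibly;
#'   `read_temporal_signal` returns a `temporal_signal`.
#' @export
write_temporal_signal <- function(x, path) {
  stopifnot(inherits(x, "temporal_signal"))
  pb <- if (is.null(x$phase_boundary)) "NA" else as.character(x$phase_boundary)
  header <- sprintf("# dt=%.17g phase_boundary=%s", x$dt, pb)
  rows <- apply(x$values, 1L, function(v)
    paste(sprintf("%.17g", v), collapse = "\t"))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_temporal_signal
#' @export
read_temporal_signal <- function(path) {
  if (!file.exists(path)) stop_data("no such signal file: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[[1L]], "# dt="))
    stop_data("not a temporal-signal file: ", path)
  m <- regmatches(lines[[1L]],
                  regexec("^# dt=([^ ]+) phase_boundary=([^ ]+)$", lines[[1L]]))[[1L]]
  if (length(m) != 3L) stop_data("malformed signal header in ", path)
  dt <- as.numeric(m[[2L]])
  pb <- if (m[[3L]] == "NA") NULL else as.integer(m[[3L]])
  vals <- do.call(rbind, lapply(lines[-1L], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1L]])))
  temporal_signal(vals, dt = dt, phase_boundary = pb)
}

#' Down-sample a signal along the time axis by block averaging
#'
#' Replaces each run of `factor` consecutive time steps by their mean and
#' multiplies `dt` accordingly, mirroring the x4 temporal down-sampling
#' applied to band-amplitude inputs before they reach the reservoir.  A
#' trailing incomplete block is dropped; a phase boundary is divided by
#' `factor` and floored.
#'
#' @param signal a [temporal_signal()].
#' @param factor integer block length (>= 1); `1` is the identity.
#' @return A `temporal_signal` with `floor(timesteps / factor)` columns.
#' @export
#' @examples
#' s <- temporal_signal(matrix(1:8, 1), dt = 1)
#' downsample_time(s, 4)$values  # block means 2.5, 6.5
downsample_time <- function(signal, factor = 4L) {
  stopifnot(inherits(signal, "temporal_signal"))
  factor <- check_count(factor, "factor")
  T_in <- n_steps(signal)
  if (factor > T_in)
    stop_config("downsampling factor (", factor,
                ") exceeds the number of time steps (", T_in, ")")
  if (factor == 1L) return(signal)
  n_blocks <- T_in %/% factor
  idx <- seq_len(n_blocks * factor)
  v <- signal$values[, idx, drop = FALSE]
  dim(v) <- c(nrow(v), factor, n_blocks)
  out <- apply(v, c(1L, 3L), mean)
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(signal$values))
  pb <- if (is.null(signal$phase_boundary)) NULL
        else signal$phase_boundary %/% factor
  temporal_signal(out, dt = signal$dt * factor, phase_boundary = pb)
}

#' Append a zero-input motor phase to a sensory signal
#'
#' Training and evaluation drive the reservoir with the input during the
#' sensory phase, then detach it: the motor phase sees all-zero input
#' while the echo of the stimulus unfolds.  This helper pads a
#' sensory-only signal with `motor_ms / dt` zero columns and records the
#' phase boundary.
#'
#' @param signal a sensory-phase [temporal_signal()]; its length must
#'   equal `params$sensory_ms / params$dt`.
#' @param params a [reservoir_params()].
#' @return A full-horizon `temporal_signal` with `phase_boundary` set.
#' @export
pad_motor_phase <- function(signal, params) {
  stopifnot(inherits(signal, "temporal_signal"))
  if (!isTRUE(all.equal(signal$dt, params$dt)))
    stop_config("signal dt (", signal$dt, ") does not match params dt (",
                params$dt, ")")
  n_s <- sensory_steps(params)
  if (n_steps(signal) != n_s)
    stop_config("sensory signal has ", n_steps(signal),
                " steps but params imply ", n_s)
  zeros <- matrix(0, n_channels(signal), motor_steps(params))
  temporal_signal(cbind(signal$values, zeros), dt = signal$dt,
                  phase_boundary = n_s)
}

#' Align a signal to a fixed number of time steps
#'
#' Variable-duration instances are mapped onto the fixed sensory-phase
#' grid either by linear time-rescaling (each channel linearly
#' interpolated onto `n_steps` equally spaced points spanning the
#' original duration) or by zero-padding / truncation at the end.
#'
#' @param signal a [temporal_signal()].
#' @param n_steps target number of time steps.
#' @param method `"rescale"` (default) or `"pad"`.
#' @return A `temporal_signal` with exactly `n_steps` columns.
#' @export
align_signal_length <- function(signal, n_steps,
                                method = c("rescale", "pad")) {
  stopifnot(inherits(signal, "temporal_signal"))
  n_steps <- check_count(n_steps, "n_steps")
  method <- match.arg(method)
  T_in <- ncol(signal$values)
  if (T_in == n_steps) return(signal)
  v <- if (method == "rescale") {
    if (T_in == 1L) {
      matrix(signal$values[, 1L], nrow(signal$values), n_steps)
    } else {
      xt <- seq(1, T_in, length.out = n_steps)
      t(apply(signal$values, 1L, function(ch)
        stats::approx(seq_len(T_in), ch, xout = xt)$y))
    }
  } else {
    if (T_in > n_steps) signal$values[, seq_len(n_steps), drop = FALSE]
    else cbind(signal$values,
               matrix(0, nrow(signal$values), n_steps - T_in))
  }
  temporal_signal(v, dt = signal$dt, phase_boundary = signal$phase_boundary)
}
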