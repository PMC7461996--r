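#' Specification of a synthetic class-structured dataset
#'
#' The generator emulates the statistical shape of cochleagram-like
#' speech inputs: each word class has a smooth band-limited base pattern
#' across `n_channels` channels, and instances vary around the base by
#' a per-instance amplitude gain, a smooth monotone time warp, and
#' additive white noise.  Classes can be factored as word classes x 2
#' attribute groups (mirroring a word x speaker-gender design): the
#' second group's base is a spectrally tilted variant of the first's,
#' so cross-group classes are deliberately similar and discrimination
#' training has subtle differences to exaggerate.
#'
#' Default jitter magnitudes (10% amplitude SD, 5% warp SD, 2% additive
#' noise relative to the unit-RMS bases) are typical of the trial-to-
#' trial variability seen in band-amplitude representations of repeated
#' utterances.
#'
#' @param n_classes number of word classes.
#' @param attribute_groups 1 (no factoring) or 2 (word x attribute).
#' @param n_channels input channels (default 39, a cochleagram band
#'   count).
#' @param duration_steps sensory-phase length in time steps.
#' @param instances_per_class instances per (word, attribute) class.
#' @param base_overlap correlation between word-class bases: each base
#'   is `base_overlap` parts a shared pattern and
#'   `sqrt(1 - base_overlap^2)` parts class-specific (0 = independent
#'   classes; values near 1 make all word classes mutually
#'   confusable).
#' @param attribute_tilt slope of the linear spectral tilt that
#'   derives the second attribute group's base from the first's
#'   (bottom channel scaled by `1 - tilt`, top by `1 + tilt`).  Small
#'   tilts make cross-group classes hard to tell apart.
#' @param amplitude_sd SD of the per-instance multiplicative gain
#'   jitter (gain = 1 + N(0, amplitude_sd)).
#' @param warp_sd SD of the smooth endpoint-fixed time warp (fraction
#'   of the duration).
#' @param noise_sd SD of the additive white noise.
#' @param dt time step of the generated signals, ms.
#' @param seed RNG seed; the whole dataset is a deterministic function
#'   of the spec.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_classes = 4L, attribute_groups = 1L,
                       n_channels = 39L, duration_steps = 300L,
                       instances_per_class = 10L, base_overlap = 0,
                       attribute_tilt = 0.25,
                       amplitude_sd = 0.1, warp_sd = 0.05,
                       noise_sd = 0.02, dt = 1, seed = 1L) {
  spec <- list(
    n_classes = check_count(n_classes, "n_classes"),
    attribute_groups = check_count(attribute_groups, "attribute_groups"),
    base_overlap = as.numeric(base_overlap),
    attribute_tilt = check_positive(attribute_tilt, "attribute_tilt"),
    n_channels = check_count(n_channels, "n_channels"),
    duration_steps = check_count(duration_steps, "duration_steps"),
    instances_per_class = check_count(instances_per_class,
                                      "instances_per_class"),
    amplitude_sd = as.numeric(amplitude_sd),
    warp_sd = as.numeric(warp_sd),
    noise_sd = as.numeric(noise_sd),
    dt = check_positive(dt, "dt"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (spec$attribute_groups > 2L)
    stop_config("attribute_groups must be 1 or 2")
  if (!is.finite(spec$base_overlap) || spec$base_overlap < 0 ||
      spec$base_overlap >= 1)
    stop_config("base_overlap must lie in [0, 1)")
  for (f in c("amplitude_sd", "warp_sd", "noise_sd"))
    if (!is.finite(spec[[f]]) || spec[[f]] < 0)
      stop_config(f, " must be a non-negative number")
  structure(spec, class = "synth_spec")
}

# Smooth band-limited base pattern: per channel, a sum of K = 3
# random-phase sinusoids with 0.5--3 cycles over the duration, so the
# pattern is slow relative to the integration step.  Normalized to
# unit RMS over the whole pattern.
make_base_pattern <- function(n_channels, duration_steps) {
  tt <- seq(0, 1, length.out = duration_steps)
  base <- matrix(0, n_channels, duration_steps)
  for (c in seq_len(n_channels)) {
    v <- numeric(duration_steps)
    for (k in 1:3) {
      f <- stats::runif(1, 0.5, 3)
      a <- stats::rnorm(1)
      phi <- stats::runif(1, 0, 2 * pi)
      v <- v + a * sin(2 * pi * f * tt + phi)
    }
    base[c, ] <- v
  }
  base / sqrt(mean(base^2))
}

# Per-channel linear spectral tilt distinguishing attribute group 2
# from group 1 (e.g. the systematic spectral shift between speaker
# groups); channel 1 is attenuated, the top channel amplified.
apply_spectral_tilt <- function(base, tilt = 0.25) {
  n_ch <- nrow(base)
  pos <- if (n_ch == 1L) 0 else 2 * (seq_len(n_ch) - 1) / (n_ch - 1) - 1
  base * (1 + tilt * pos)
}

# Smooth monotone endpoint-fixed time warp; z controls the magnitude.
# warp(t) = t + s * sin(pi t) with |s| small enough for monotonicity.
warp_times <- function(n, warp_sd) {
  tt <- seq(0, 1, length.out = n)
  s <- warp_sd * max(min(stats::rnorm(1), 2), -2)
  s <- max(min(s, 0.3), -0.3)  # keeps 1 + s*pi*cos(pi t) > 0
  tt + s * sin(pi * tt)
}

#' Generate a labeled synthetic dataset
#'
#' Draws one base pattern per word class (and a tilted variant per
#' attribute group), then produces `instances_per_class` jittered
#' instances per combined class: `(1 + gain) * base(warp(t)) + noise`.
#' With all jitter SDs zero every instance equals its class base
#' exactly.  The dataset is a deterministic function of `spec$seed`.
#'
#' @param spec a [synth_spec()].
#' @return A list of class `synth_dataset` with elements
#'   \describe{
#'     \item{instances}{list; each has `id`, `class` (combined label
#'       `"w<i>.a<g>"`), `labels` (named vector with `word`, `attr`),
#'       and `signal` (a sensory-phase [temporal_signal()]).}
#'     \item{bases}{named list of the ground-truth channels x steps base
#'       matrix per combined class.}
#'     \item{spec}{the generating spec.}
#'   }
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    shared <- if (spec$base_overlap > 0)
      make_base_pattern(spec$n_channels, spec$duration_steps)
    word_bases <- lapply(seq_len(spec$n_classes), function(i) {
      own <- make_base_pattern(spec$n_channels, spec$duration_steps)
      if (spec$base_overlap > 0)
        spec$base_overlap * shared +
          sqrt(1 - spec$base_overlap^2) * own
      else own
    })
    bases <- list()
    for (w in seq_len(spec$n_classes)) {
      for (g in seq_len(spec$attribute_groups)) {
        b <- word_bases[[w]]
        if (g == 2L) b <- apply_spectral_tilt(b, spec$attribute_tilt)
        bases[[sprintf("w%d.a%d", w, g)]] <- b
      }
    }
    instances <- list()
    idx <- 0L
    tt <- seq(0, 1, length.out = spec$duration_steps)
    for (w in seq_len(spec$n_classes)) {
      for (g in seq_len(spec$attribute_groups)) {
        cls <- sprintf("w%d.a%d", w, g)
        base <- bases[[cls]]
        for (k in seq_len(spec$instances_per_class)) {
          idx <- idx + 1L
          gain <- 1 + stats::rnorm(1, 0, spec$amplitude_sd)
          wt <- if (spec$warp_sd > 0) warp_times(spec$duration_steps,
                                                 spec$warp_sd) else tt
          v <- t(apply(base, 1L, function(ch)
            stats::approx(tt, ch, xout = wt, rule = 2)$y))
          v <- gain * v
          if (spec$noise_sd > 0)
            v <- v + matrix(stats::rnorm(length(v), 0, spec$noise_sd),
                            nrow(v), ncol(v))
          instances[[idx]] <- list(
            id = sprintf("inst%04d", idx),
            class = cls,
            labels = c(word = sprintf("w%d", w), attr = sprintf("a%d", g)),
            signal = temporal_signal(v, dt = spec$dt))
        }
      }
    }
    structure(list(instances = instances, bases = bases, spec = spec),
              class = "synth_dataset")
  })
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("<synth_dataset> ", length(x$instances), " instance(s), ",
      length(x$bases), " class(es), ", x$spec$n_channels,
      " channel(s) x ", x$spec$duration_steps, " step(s)\n", sep = "")
  invisible(x)
}

#' 2-D motor trajectory
#'
#' An ordered list of (x, y) coordinates, by convention inside the unit
#' square, equally spaced in arc length after resampling.
#'
#' @param coords numeric matrix with two columns (x, y).
#' @return Object of class `trajectory2d` (the coordinate matrix with
#'   columns named `x`, `y`).
#' @export
trajectory2d <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L || nrow(coords) < 1L || !is.numeric(coords))
    stop_config("coords must be an n x 2 numeric matrix")
  colnames(coords) <- c("x", "y")
  structure(coords, class = c("trajectory2d", "matrix", "array"))
}

#' @export
print.trajectory2d <- function(x, ...) {
  cat("<trajectory2d> ", nrow(x), " point(s)\n", sep = "")
  invisible(unclass(x))
}

#' @export
plot.trajectory2d <- function(x, ..., type = "l", asp = 1) {
  graphics::plot(x[, 1L], x[, 2L], type = type, asp = asp,
                 xlab = "x", ylab = "y", ...)
  invisible(x)
}

# Resample a polyline to n points equally spaced in arc length.  For a
# closed curve (first point == last, or closed = TRUE) the n points
# cover the full loop without duplicating the start.
resample_arclength <- function(coords, n_points, closed = FALSE) {
  d <- sqrt(rowSums(diff(coords)^2))
  s <- c(0, cumsum(d))
  total <- s[[length(s)]]
  if (total == 0) stop_config("degenerate zero-length path")
  keep <- c(TRUE, d > 0)  # drop duplicated vertices for interpolation
  s_u <- s[keep]; c_u <- coords[keep, , drop = FALSE]
  targets <- if (closed) seq(0, total, length.out = n_points + 1L)[seq_len(n_points)]
             else seq(0, total, length.out = n_points)
  cbind(stats::approx(s_u, c_u[, 1L], xout = targets)$y,
        stats::approx(s_u, c_u[, 2L], xout = targets)$y)
}

#' Build a single-stroke target trajectory
#'
#' Either a built-in single-stroke shape (drawable without lifting the
#' pen) or a user polyline, resampled to `n_points` points equally
#' spaced in arc length.  Built-ins live in the unit square.
#'
#' @param shape `"circle"`, `"eight"`, `"lpath"`, `"zigzag"`, or an
#'   `n x 2` coordinate matrix (polyline).
#' @param n_points number of resampled points (e.g. the number of
#'   motor-phase steps).
#' @return A [trajectory2d()] with `n_points` rows.
#' @export
#' @examples
#' tr <- make_target_trajectory("circle", 100)
#' range(sqrt((tr[, 1] - 0.5)^2 + (tr[, 2] - 0.5)^2))  # constant radius
make_target_trajectory <- function(shape, n_points) {
  n_points <- check_count(n_points, "n_points")
  dense <- 2048L
  closed <- FALSE
  if (is.character(shape)) {
    th <- seq(0, 2 * pi, length.out = dense)
    coords <- switch(shape,
      circle = {
        closed <- TRUE
        cbind(0.5 + 0.35 * cos(th), 0.5 + 0.35 * sin(th))
      },
      eight = {
        closed <- TRUE
        cbind(0.5 + 0.35 * sin(th), 0.5 + 0.35 * sin(th) * cos(th))
      },
      lpath = {
        resample_arclength(rbind(c(0.3, 0.9), c(0.3, 0.1), c(0.8, 0.1)),
                           dense)
      },
      zigzag = {
        resample_arclength(rbind(c(0.1, 0.9), c(0.37, 0.1),
                                 c(0.63, 0.9), c(0.9, 0.1)), dense)
      },
      stop_config("unknown shape '", shape, "'")
    )
  } else {
    coords <- as.matrix(shape)
    if (ncol(coords) != 2L || nrow(coords) < 2L)
      stop_config("a polyline shape needs an n x 2 matrix with n >= 2")
    closed <- isTRUE(all.equal(coords[1L, ], coords[nrow(coords), ],
                               check.attributes = FALSE))
  }
  trajectory2d(resample_arclength(coords, n_points, closed = closed))
}

#' Default assignment of target shapes to class labels
#'
#' Cycles the built-in single-stroke shapes over the given labels; used
#' by the command-line pipeline to give every word class (and attribute
#' group) a drawable target.
#'
#' @param labels character vector of class labels.
#' @param n_points points per trajectory.
#' @param shapes shape names to cycle through.
#' @return Named list of [trajectory2d()], one per label.
#' @export
default_targets <- function(labels, n_points,
                            shapes = c("circle", "eight", "lpath",
                                       "zigzag")) {
  stats::setNames(lapply(seq_along(labels), function(i)
    make_target_trajectory(shapes[[(i - 1L) %% length(shapes) + 1L]],
                           n_points)), labels)
}
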