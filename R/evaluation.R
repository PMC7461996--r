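#' Mean squared trajectory error
#'
#' The motor-output error: for each example, the sum over output points
#' of the squared coordinate differences between actual and target
#' trajectories, averaged over examples:
#' \deqn{d = \frac{1}{N_{ex}} \sum_i \sum_j (x^t_{ij} - x^a_{ij})^2 +
#'       (y^t_{ij} - y^a_{ij})^2.}
#' Coordinates are in raw squared units; by convention targets live in
#' the unit square so errors are comparable across fixtures.
#'
#' @param actual,target lists of [trajectory2d()] (or single
#'   trajectories) with matching point counts.
#' @return Object of class `error_report`: list with `d`,
#'   `per_example`, `n_ex`, `n_points`.
#' @export
trajectory_error <- function(actual, target) {
  if (inherits(actual, "trajectory2d")) actual <- list(actual)
  if (inherits(target, "trajectory2d")) target <- list(target)
  if (length(actual) != length(target))
    stop_config("actual and target must have the same number of examples")
  if (length(actual) == 0L) stop_config("no examples to score")
  per <- vapply(seq_along(actual), function(i) {
    a <- unclass(actual[[i]]); tg <- unclass(target[[i]])
    if (nrow(a) != nrow(tg))
      stop_config("example ", i, ": point counts differ (", nrow(a),
                  " vs ", nrow(tg), ")")
    sum((a - tg)^2)
  }, numeric(1))
  structure(list(d = mean(per), per_example = per,
                 n_ex = length(per), n_points = nrow(actual[[1L]])),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> d = %.6g over %d example(s) x %d point(s)\n",
              x$d, x$n_ex, x$n_points))
  invisible(x)
}

# Integer line rasterization (Bresenham) between two pixel coordinates.
bresenham_points <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx + dy
  pts <- matrix(0L, dx - dy + 1L, 2L)
  n <- 0L
  repeat {
    n <- n + 1L
    pts[n, ] <- c(x0, y0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2L * err
    if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
    if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
  }
  pts[seq_len(n), , drop = FALSE]
}

#' Rasterize a trajectory to a binary image
#'
#' Affinely maps the trajectory into a `grid x grid` pixel box with a
#' fixed margin — one uniform scale for both axes (so the drawing's
#' aspect ratio and any overall size are normalized away), centered in
#' the box — then connects consecutive points with Bresenham lines.
#' Row 1 is the top of the image; y increases upward in trajectory
#' space.
#'
#' @param traj a [trajectory2d()].
#' @param grid image side length in pixels (default 28).
#' @param margin pixel margin kept free on each side (default 2).
#' @return `grid x grid` integer matrix of 0/1 pixel values.
#' @export
rasterize <- function(traj, grid = 28L, margin = 2L) {
  grid <- check_count(grid, "grid")
  margin <- check_count(margin, "margin", min = 0L)
  coords <- unclass(trajectory2d(traj))
  avail <- grid - 1L - 2L * margin
  if (avail < 1L) stop_config("margin too large for the grid")
  rx <- range(coords[, 1L]); ry <- range(coords[, 2L])
  span <- max(diff(rx), diff(ry))
  img <- matrix(0L, grid, grid)
  if (span == 0) {  # degenerate single point
    img[(grid + 1L) %/% 2L, (grid + 1L) %/% 2L] <- 1L
    return(img)
  }
  sc <- avail / span
  offx <- margin + (avail - diff(rx) * sc) / 2
  offy <- margin + (avail - diff(ry) * sc) / 2
  px <- as.integer(round(offx + (coords[, 1L] - rx[[1L]]) * sc)) + 1L
  py <- as.integer(round(offy + (coords[, 2L] - ry[[1L]]) * sc)) + 1L
  row <- grid + 1L - py  # y up -> row index down
  for (i in seq_len(nrow(coords) - 1L)) {
    pts <- bresenham_points(px[[i]], row[[i]], px[[i + 1L]], row[[i + 1L]])
    img[cbind(pts[, 2L], pts[, 1L])] <- 1L
  }
  if (nrow(coords) == 1L) img[row[[1L]], px[[1L]]] <- 1L
  img
}

#' Write a binary image as a portable graymap
#'
#' @param img integer 0/1 matrix from [rasterize()].
#' @param path output file path (plain-text P2 PGM).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path) {
  stopifnot(is.matrix(img))
  lines <- c("P2", paste(ncol(img), nrow(img)), "1",
             apply(img, 1L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Nearest-template classification of a drawn trajectory
#'
#' Labels an output trajectory with the target it is closest to in
#' mean-squared trajectory distance.  This is a lightweight
#' recognizability score: a drawing counts as legible when it is
#' nearer its own class target than any other.  Ties break toward the
#' first label in the target list and are flagged.
#'
#' @param output a [trajectory2d()].
#' @param targets named list of [trajectory2d()] with the same point
#'   count.
#' @return List with `label`, `margin` (runner-up distance minus best),
#'   `distances` (named), and `tie` (logical).
#' @export
nearest_template_classify <- function(output, targets) {
  if (length(targets) == 0L) stop_config("empty target set")
  d <- vapply(targets, function(tg)
    trajectory_error(output, tg)$d, numeric(1))
  best <- which.min(d)  # first minimum wins ties
  margin <- if (length(d) > 1L) sort(d)[[2L]] - d[[best]] else Inf
  list(label = names(targets)[[best]], margin = margin,
       distances = d, tie = sum(d == d[[best]]) > 1L)
}

#' Generate the motor output of a trained network for one input
#'
#' Simulates the (sensory + detached motor phase) response to a sensory
#' signal and reads out the motor-phase trajectory of every trained
#' readout.
#'
#' @param model an [train_full()] result (or a list with `weights`,
#'   `params`).
#' @param signal a sensory-phase [temporal_signal()].
#' @return Named list of [trajectory2d()], one per readout block.
#' @export
generate_motor_output <- function(model, signal) {
  weights <- model$weights; params <- model$params
  rates <- simulate_reservoir(pad_motor_phase(signal, params), weights,
                              params)
  n_s <- sensory_steps(params)
  motor <- rates$values[, (n_s + 1L):ncol(rates$values), drop = FALSE]
  lapply(weights$W_out, function(W) trajectory2d(t(crossprod(W, motor))))
}

#' Score a model's drawings against targets
#'
#' Generates the motor output for every instance and reports, per
#' readout, the mean squared trajectory error and the nearest-template
#' classification accuracy.
#'
#' @param model a trained [train_full()] model.
#' @param dataset instances to evaluate.
#' @param targets per-readout named target lists (as in
#'   [readout_train()]).
#' @return List with `errors` (named list of [trajectory_error()]
#'   reports), `accuracy` (named numeric, fraction correctly
#'   classified), and `predictions` (per instance, per readout labels).
#' @export
evaluate_trajectories <- function(model, dataset, targets) {
  instances <- dataset_instances(dataset)
  if (length(instances) == 0L) stop_data("empty evaluation set")
  outputs <- lapply(instances, function(inst)
    generate_motor_output(model, inst$signal))
  errors <- list(); accuracy <- numeric(0); predictions <- list()
  for (rd in names(targets)) {
    actual <- lapply(outputs, `[[`, rd)
    truth <- vapply(instances, instance_label, character(1), rd = rd)
    tgt <- lapply(truth, function(l) targets[[rd]][[l]])
    errors[[rd]] <- trajectory_error(actual, tgt)
    pred <- vapply(actual, function(a)
      nearest_template_classify(a, targets[[rd]])$label, character(1))
    accuracy[[rd]] <- mean(pred == truth)
    predictions[[rd]] <- pred
  }
  list(errors = errors, accuracy = accuracy, predictions = predictions)
}

#' Sweep the separation scaling factor
#'
#' Retrains the full pipeline at each value of `gamma` (shared seed and
#' identical data), recording the final attractor separation SP, the
#' discriminant ratio DR of the instance dynamics after training, and
#' the mean squared trajectory error `d`, averaged over readouts, on the
#' evaluation set.  The DR maximum predicts the error-optimal amount
#' of separation without readout-level evaluation.
#'
#' @param dataset training instances.
#' @param targets per-readout named target lists.
#' @param params,base_config shared parameters; `base_config$gamma` is
#'   overridden per sweep point.
#' @param gammas numeric vector of scaling factors (>= 2 values).
#' @param eval_dataset instances scored for `d` (defaults to
#'   `dataset`).
#' @return Object of class `sweep_result`: data frame with columns
#'   `gamma`, `sp`, `dr`, `d`, and attributes `argmin_d` /
#'   `argmax_dr` (indices into the grid).
#' @export
gamma_sweep <- function(dataset, targets, params, base_config, gammas,
                        eval_dataset = dataset) {
  if (length(gammas) < 2L)
    stop_config("a sweep needs at least 2 gamma values")
  rows <- lapply(gammas, function(g) {
    cfg <- base_config
    cfg$gamma <- as.numeric(g)
    model <- train_full(dataset, targets, params, cfg)
    ev <- evaluate_trajectories(model, eval_dataset, targets)
    data.frame(gamma = g,
               sp = model$sp_history[[length(model$sp_history)]],
               dr = model_instance_dr(model, eval_dataset),
               d = mean(vapply(ev$errors, `[[`, numeric(1), "d")))
  })
  res <- do.call(rbind, rows)
  class(res) <- c("sweep_result", "data.frame")
  attr(res, "argmin_d") <- which.min(res$d)
  attr(res, "argmax_dr") <- which.max(res$dr)
  res
}

# Discriminant ratio of the vectorized motor-phase dynamics of a set of
# instances under a trained model.
model_instance_dr <- function(model, dataset) {
  instances <- dataset_instances(dataset)
  params <- model$params
  n_s <- sensory_steps(params)
  vecs <- lapply(instances, function(inst) {
    R <- simulate_reservoir(pad_motor_phase(inst$signal, params),
                            model$weights, params)$values
    vectorize_rates(R[, (n_s + 1L):ncol(R), drop = FALSE])
  })
  labels <- vapply(instances, function(i) i$class, character(1))
  scatter_summary(labeled_dynamics(vecs, labels))$DR
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> over", nrow(x), "gamma value(s)\n")
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("argmin-d gamma = %g, argmax-DR gamma = %g\n",
              x$gamma[[attr(x, "argmin_d")]],
              x$gamma[[attr(x, "argmax_dr")]]))
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(1L, 2L))
  on.exit(graphics::par(op))
  graphics::plot(x$gamma, x$d, type = "b", log = "x",
                 xlab = expression(gamma), ylab = "trajectory error d", ...)
  graphics::plot(x$gamma, x$dr, type = "b", log = "x",
                 xlab = expression(gamma), ylab = "discriminant ratio", ...)
  invisible(x)
}
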