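#' Training configuration
#'
#' All tunables of the three-step algorithm:
#' \enumerate{
#'   \item separation-based input-weight training, which pushes the
#'     per-class attractors apart by amplifying the input features that
#'     distinguish classes;
#'   \item approximation-based ("innate") recurrent-weight training via
#'     recursive least squares (FORCE), which pulls every instance's
#'     dynamics onto its class attractor;
#'   \item linear readout training against the target motor
#'     trajectories.
#' }
#'
#' @param gamma separation scaling factor; larger values exaggerate
#'   inter-class differences more aggressively.  Moderate values help;
#'   extreme values create oscillatory, hard-to-approximate attractors.
#' @param alpha_sep inverse learning rate for step 1 (the `P` matrix of
#'   the input-weight update starts at `I / alpha_sep`); default 500.
#' @param alpha_approx inverse learning rate for step 2; default 100.
#' @param alpha_readout inverse learning rate for step 3; default 100
#'   (the readout uses the same recursive rule as step 2).
#' @param epochs_sep,epochs_innate,epochs_readout iteration counts for
#'   the three steps.
#' @param delta_steps simulation steps between consecutive weight
#'   updates (>= 1; 1 updates at every integration step).
#' @param inv_error_clip ceiling on each component of the element-wise
#'   inverse error `1/e` used by step 1; keeps the update finite when
#'   an error component vanishes.
#' @param noise_amp Gaussian state-noise SD during training simulations
#'   (0 = deterministic).
#' @param skip_separation if `TRUE`, step 1 is skipped (attractors stay
#'   at the untrained innate dynamics); used for ablation comparisons.
#' @param train_window `"full"` trains step 2 over sensory + motor
#'   phases; `"motor"` restricts updates to the motor phase.
#' @param seed RNG seed for any training-time randomness.
#' @return Object of class `training_config`.
#' @export
training_config <- function(gamma = 1, alpha_sep = 500, alpha_approx = 100,
                            alpha_readout = 100,
                            epochs_sep = 10L, epochs_innate = 20L,
                            epochs_readout = 10L,
                            delta_steps = 1L, inv_error_clip = 1e3,
                            noise_amp = 0, skip_separation = FALSE,
                            train_window = c("full", "motor"),
                            seed = 1L) {
  cfg <- list(
    gamma = as.numeric(gamma),
    alpha_sep = check_positive(alpha_sep, "alpha_sep"),
    alpha_approx = check_positive(alpha_approx, "alpha_approx"),
    alpha_readout = check_positive(alpha_readout, "alpha_readout"),
    epochs_sep = check_count(epochs_sep, "epochs_sep", min = 0L),
    epochs_innate = check_count(epochs_innate, "epochs_innate", min = 0L),
    epochs_readout = check_count(epochs_readout, "epochs_readout", min = 0L),
    delta_steps = check_count(delta_steps, "delta_steps"),
    inv_error_clip = check_positive(inv_error_clip, "inv_error_clip"),
    noise_amp = as.numeric(noise_amp),
    skip_separation = isTRUE(skip_separation),
    train_window = match.arg(train_window),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (!is.finite(cfg$gamma) || cfg$gamma < 0)
    stop_config("gamma must be a non-negative number")
  if (cfg$noise_amp < 0) stop_config("noise_amp must be >= 0")
  structure(cfg, class = "training_config")
}

#' Initial state of a recursive-least-squares learner
#'
#' @param n dimension of the regression vector.
#' @param alpha regularizer; `P` starts at `I / alpha` (1/alpha is the
#'   learning rate).
#' @param delta_steps steps between updates.
#' @return List of class `rls_state` with `P`, `alpha`, `delta_steps`.
#' @export
rls_state <- function(n, alpha, delta_steps = 1L) {
  n <- check_count(n, "n")
  alpha <- check_positive(alpha, "alpha")
  structure(list(P = diag(n) / alpha, alpha = alpha,
                 delta_steps = check_count(delta_steps, "delta_steps")),
            class = "rls_state")
}

#' Sherman--Morrison update of the inverse-correlation matrix
#'
#' `P <- P - (P v)(v' P) / (1 + v' P v)`.  Starting from `I / alpha`,
#' repeated updates with vectors `v_k` keep `P` equal (exactly, up to
#' floating error) to `(alpha I + sum v_k v_k')^{-1}`.  Symmetry is
#' preserved.
#'
#' @param P square symmetric matrix.
#' @param v regression vector of conforming length.
#' @return The updated matrix.
#' @export
rls_p_update <- function(P, v) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stop_config("P must be a square matrix")
  v <- as.numeric(v)
  if (length(v) != nrow(P))
    stop_config("v must have length ", nrow(P))
  Pv <- drop(P %*% v)
  k <- 1 + sum(v * Pv)
  P - tcrossprod(Pv) / k
}

#' Per-class mean input templates
#'
#' The template of each class is the element-wise mean of its aligned
#' instances; templates seed the innate attractor of the class.
#'
#' @param dataset a [generate_dataset()] result or bare list of
#'   instances (each with `$class` and `$signal`).
#' @param n_steps optional common length; when instances differ in
#'   duration they are first aligned with [align_signal_length()]
#'   (linear time-rescaling).  When `NULL`, instances must already
#'   share one length.
#' @return Object of class `class_templates`: named list of
#'   channels x steps matrices plus attributes `dt` and `classes`.
#' @export
compute_class_templates <- function(dataset, n_steps = NULL) {
  instances <- dataset_instances(dataset)
  if (length(instances) == 0L) stop_data("dataset has no instances")
  labels <- vapply(instances, function(i) i$class, character(1))
  lens <- vapply(instances, function(i) ncol(i$signal$values), integer(1))
  if (is.null(n_steps)) {
    if (length(unique(lens)) != 1L)
      stop_config("instances differ in length (", min(lens), "..",
                  max(lens), "); pass n_steps to align them")
    n_steps <- lens[[1L]]
  }
  dt <- instances[[1L]]$signal$dt
  classes <- sort(unique(labels))
  templates <- list()
  for (cls in classes) {
    members <- instances[labels == cls]
    if (length(members) == 0L) stop_data("class '", cls, "' is empty")
    mats <- lapply(members, function(i)
      align_signal_length(i$signal, n_steps)$values)
    templates[[cls]] <- Reduce(`+`, mats) / length(mats)
  }
  structure(templates, class = "class_templates", dt = dt,
            classes = classes)
}

dataset_instances <- function(dataset) {
  if (inherits(dataset, "synth_dataset")) dataset$instances
  else if (is.list(dataset)) dataset
  else stop_config("dataset must be a synth_dataset or a list of instances")
}

#' Capture the innate attractor of every class
#'
#' Applies each class template (sensory phase, then a detached motor
#' phase) to the reservoir from a zero initial state with zero noise
#' and stores the full rate trajectory.  These innate dynamics are the
#' per-class training targets ("class attractors"): deterministic,
#' regenerable functions of the templates and weights.
#'
#' @param templates a [compute_class_templates()] result.
#' @param weights,params network weights and parameters.
#' @return Object of class `attractor_set`: named list of `n_res x T`
#'   rate matrices (sensory + motor horizon).
#' @export
capture_attractors <- function(templates, weights, params) {
  stopifnot(inherits(templates, "class_templates"))
  out <- lapply(templates, function(tm) {
    inp <- pad_motor_phase(temporal_signal(tm, dt = attr(templates, "dt")),
                           params)
    simulate_reservoir(inp, weights, params, noise_amp = 0)$values
  })
  structure(out, class = "attractor_set",
            phase_boundary = sensory_steps(params))
}

# Vectorized motor-phase dynamics of an attractor set, as
# labeled_dynamics with equal priors (one attractor per class).
attractor_dynamics <- function(attractors, window = c("motor", "full")) {
  window <- match.arg(window)
  pb <- attr(attractors, "phase_boundary")
  vecs <- lapply(attractors, function(a) {
    m <- if (window == "motor" && !is.null(pb) && pb < ncol(a))
      a[, (pb + 1L):ncol(a), drop = FALSE] else a
    vectorize_rates(m)
  })
  labeled_dynamics(vecs, names(attractors))
}

#' Separation of an attractor set
#'
#' Trace of the between-class scatter of the vectorized attractor
#' dynamics (motor phase by default, where the attractors live), with
#' equal class priors.
#'
#' @param attractors an [capture_attractors()] result.
#' @param window `"motor"` (default) or `"full"`.
#' @return Scalar separation property (trace of S_b).
#' @export
attractor_separation <- function(attractors, window = c("motor", "full")) {
  scatter_summary(attractor_dynamics(attractors, window))$S_b_trace
}

# Clipped element-wise inverse: |1/e| capped at clip; components with
# |e| < 1/clip (including exact zeros) contribute +/- clip, zeros
# resolving to +clip.
inv_error_clipped <- function(e, clip) {
  s <- ifelse(e >= 0, 1, -1)
  ifelse(abs(e) < 1 / clip, s * clip, 1 / e)
}

#' Step 1: separation-based input-weight training
#'
#' For each epoch the class attractors are captured once (frozen within
#' the epoch).  Then for every ordered class pair (i, j), i != j, the
#' template of class i is run through the reservoir online; every
#' `delta_steps` sensory-phase steps the inverse-correlation matrix of
#' the input vector is updated (Sherman--Morrison) and the input
#' weights move along
#' `W_in <- W_in + gamma * (P u)(1 / e_ij)'`,
#' where `e_ij(t)` is the difference between the current rates and the
#' frozen attractor of class j and `1/e` is the clipped element-wise
#' inverse.  Small differences produce large inverse components, so the
#' update amplifies precisely the subtle input features that barely
#' distinguish the classes, driving the attractors apart.
#'
#' @param weights a [init_weights()] weight set.
#' @param templates a [compute_class_templates()] result (>= 2 classes).
#' @param params a [reservoir_params()].
#' @param config a [training_config()].
#' @return List with `weights` (trained) and `sp_history` (separation
#'   property of the re-captured attractors at epoch 0 .. epochs_sep).
#' @export
separation_train <- function(weights, templates, params, config) {
  stopifnot(inherits(templates, "class_templates"),
            inherits(config, "training_config"))
  classes <- attr(templates, "classes")
  if (length(classes) < 2L)
    stop_config("separation training needs at least 2 classes")
  n_s <- sensory_steps(params)
  attractors <- capture_attractors(templates, weights, params)
  sp_history <- attractor_separation(attractors)
  if (config$gamma == 0 || config$epochs_sep == 0L)
    return(list(weights = weights,
                sp_history = rep(sp_history, config$epochs_sep + 1L)))
  W_in <- weights$W_in
  P <- diag(params$n_in) / config$alpha_sep
  inputs <- lapply(templates, function(tm)
    pad_motor_phase(temporal_signal(tm, dt = attr(templates, "dt")),
                    params))
  for (epoch in seq_len(config$epochs_sep)) {
    for (i in classes) {
      U <- inputs[[i]]$values
      for (j in classes) {
        if (j == i) next
        A_j <- attractors[[j]]
        x <- numeric(params$n_res)
        WinT <- t(W_in)
        for (t in seq_len(n_s)) {
          u_t <- U[, t]
          Wu <- drop(WinT %*% u_t)
          if (config$noise_amp > 0)
            Wu <- Wu + stats::rnorm(params$n_res, 0, config$noise_amp)
          x <- drop(heun_step_x(x, Wu, weights$W_res, params$leak,
                                params$tau, params$dt))
          if (t %% config$delta_steps == 0L) {
            P <- rls_p_update(P, u_t)
            e <- tanh(x) - A_j[, t]
            inv_e <- inv_error_clipped(e, config$inv_error_clip)
            dW <- config$gamma * tcrossprod(drop(P %*% u_t), inv_e)
            if (!all(is.finite(dW)))
              stop("separation_train: non-finite weight update at epoch ",
                   epoch, ", pair (", i, ",", j, "), step ", t)
            W_in <- W_in + dW
            WinT <- t(W_in)
          }
        }
      }
    }
    weights$W_in <- W_in
    attractors <- capture_attractors(templates, weights, params)
    sp_history <- c(sp_history, attractor_separation(attractors))
  }
  list(weights = weights, sp_history = sp_history)
}

#' Step 2: approximation-based ("innate") recurrent-weight training
#'
#' FORCE training of the recurrent matrix: each instance is simulated
#' online and, every `delta_steps` steps inside the training window,
#' the shared inverse-correlation matrix of the rates is updated and
#' the recurrent weights move along `W_res <- W_res - e (P r)'`, where
#' `e(t)` is the difference between the current rates and the
#' instance's class attractor.  Weight changes take effect immediately
#' within the ongoing simulation, keeping the error controlled
#' throughout (first-order reduced and controlled error).
#'
#' @param weights a weight set (typically after [separation_train()]).
#' @param attractors the class attractors to converge to.
#' @param dataset labeled instances (each with `$class`, `$signal`).
#' @param params,config network parameters and training configuration.
#' @return List with `weights` and `dist_history`: mean
#'   [pairwise_separation()] between instance dynamics and their class
#'   attractor before training (epoch 0) and after each epoch.
#' @export
innate_train <- function(weights, attractors, dataset, params, config) {
  stopifnot(inherits(attractors, "attractor_set"),
            inherits(config, "training_config"))
  instances <- dataset_instances(dataset)
  labels <- vapply(instances, function(i) i$class, character(1))
  missing <- setdiff(unique(labels), names(attractors))
  if (length(missing) > 0L)
    stop_data("no attractor for class(es): ", paste(missing, collapse = ", "))
  inputs <- lapply(instances, function(i) pad_motor_phase(i$signal, params))
  T_n <- total_steps(params)
  n_s <- sensory_steps(params)
  t_start <- if (config$train_window == "motor") n_s + 1L else 1L
  mean_dist <- function(W_res) {
    w <- weights; w$W_res <- W_res
    mean(vapply(seq_along(instances), function(k) {
      rates <- simulate_reservoir(inputs[[k]], w, params)$values
      pairwise_separation(rates, attractors[[labels[[k]]]])
    }, numeric(1)))
  }
  W_res <- weights$W_res
  dist_history <- mean_dist(W_res)
  P <- diag(params$n_res) / config$alpha_approx
  for (epoch in seq_len(config$epochs_innate)) {
    for (k in seq_along(instances)) {
      U <- inputs[[k]]$values
      A <- attractors[[labels[[k]]]]
      x <- numeric(params$n_res)
      WinT <- t(weights$W_in)
      for (t in seq_len(T_n)) {
        Wu <- if (t <= n_s) drop(WinT %*% U[, t]) else numeric(params$n_res)
        if (config$noise_amp > 0)
          Wu <- Wu + stats::rnorm(params$n_res, 0, config$noise_amp)
        x <- drop(heun_step_x(x, Wu, W_res, params$leak,
                              params$tau, params$dt))
        if (t >= t_start && (t - t_start) %% config$delta_steps == 0L) {
          r <- tanh(x)
          Pr <- drop(P %*% r)
          k_sc <- 1 + sum(r * Pr)
          P <- P - tcrossprod(Pr) / k_sc
          e <- r - A[, t]
          W_res <- W_res - tcrossprod(e, Pr / k_sc)
        }
      }
    }
    dist_history <- c(dist_history, mean_dist(W_res))
  }
  weights$W_res <- W_res
  list(weights = weights, dist_history = dist_history)
}

#' Step 3: readout training for motor pattern generation
#'
#' Trains one independent linear readout per output pattern (for
#' example, the drawn word shape and the drawn attribute mark) with the
#' same recursive-least-squares rule, against the target (x, y)
#' coordinates during the motor phase.  The readouts share the
#' reservoir rates but update independently; swapping their target
#' sets exactly swaps the trained outputs.
#'
#' @param weights a weight set with trained `W_in` / `W_res`.
#' @param dataset labeled instances; each instance's `$labels` names
#'   which target it draws for each readout.
#' @param targets named list: for each readout name, a named list of
#'   [trajectory2d()] targets keyed by that readout's label values.
#'   Every target must have exactly `motor_steps(params)` points.
#' @param params,config network parameters and training configuration.
#' @return The weight set with `W_out` holding one trained
#'   `n_res x 2` matrix per readout.
#' @export
readout_train <- function(weights, dataset, targets, params, config) {
  stopifnot(inherits(config, "training_config"))
  instances <- dataset_instances(dataset)
  n_m <- motor_steps(params)
  for (rd in names(targets))
    for (lbl in names(targets[[rd]]))
      if (nrow(targets[[rd]][[lbl]]) != n_m)
        stop_config("target '", lbl, "' of readout '", rd, "' has ",
                    nrow(targets[[rd]][[lbl]]), " points but the motor ",
                    "phase has ", n_m, " steps")
  rd_names <- names(targets)
  W_out <- lapply(rd_names, function(.) matrix(0, params$n_res, 2L))
  P_out <- lapply(rd_names, function(.) diag(params$n_res) / config$alpha_readout)
  names(W_out) <- names(P_out) <- rd_names
  n_s <- sensory_steps(params)
  # Rates do not depend on W_out (no output feedback), so simulate once.
  rates <- lapply(instances, function(inst)
    simulate_reservoir(pad_motor_phase(inst$signal, params), weights,
                       params)$values)
  for (epoch in seq_len(config$epochs_readout)) {
    for (k in seq_along(instances)) {
      inst <- instances[[k]]
      R <- rates[[k]]
      for (rd in rd_names) {
        lbl <- instance_label(inst, rd)
        tgt <- targets[[rd]][[lbl]]
        if (is.null(tgt))
          stop_data("no target '", lbl, "' for readout '", rd, "'")
        W <- W_out[[rd]]; P <- P_out[[rd]]
        for (t in seq_len(n_m)) {
          if ((t - 1L) %% config$delta_steps != 0L) next
          r <- R[, n_s + t]
          Pr <- drop(P %*% r)
          k_sc <- 1 + sum(r * Pr)
          P <- P - tcrossprod(Pr) / k_sc
          e <- drop(crossprod(W, r)) - tgt[t, ]
          W <- W - tcrossprod(Pr / k_sc, e)
        }
        W_out[[rd]] <- W; P_out[[rd]] <- P
      }
    }
  }
  weights$W_out <- W_out
  weights
}

# Which target label instance `inst` draws for readout `rd`: its named
# label when present, else its class (single-readout datasets).
instance_label <- function(inst, rd) {
  if (!is.null(inst$labels) && rd %in% names(inst$labels))
    unname(inst$labels[[rd]])
  else inst$class
}

#' Full three-step training
#'
#' Runs separation training (unless `config$skip_separation`), innate
#' FORCE training toward the (re-captured) class attractors, and
#' readout training, then evaluates the mean squared trajectory error
#' on the training set.  All randomness is seeded, so identical inputs
#' and configuration reproduce the result bit for bit.
#'
#' @param dataset labeled instances (>= 2 classes).
#' @param targets per-readout named target lists; see [readout_train()].
#' @param params a [reservoir_params()].
#' @param config a [training_config()].
#' @return Object of class `esn_model`: list with `weights`,
#'   `templates`, `attractors` (final), `sp_history`, `dist_history`,
#'   `errors` (per-readout [trajectory_error()] reports on the training
#'   set), `error` (their mean `d`), `eig_before`, `eig_after`
#'   (recurrent-weight spectra), `params`, `config`.
#' @export
train_full <- function(dataset, targets, params, config) {
  instances <- dataset_instances(dataset)
  if (length(unique(vapply(instances, function(i) i$class,
                           character(1)))) < 2L)
    stop_config("training needs at least 2 classes")
  templates <- compute_class_templates(instances,
                                       n_steps = sensory_steps(params))
  weights <- init_weights(params, rng_seed = params$seed)
  eig_before <- eigen_spectrum(weights$W_res)
  if (config$skip_separation) {
    a0 <- capture_attractors(templates, weights, params)
    sp_history <- rep(attractor_separation(a0), config$epochs_sep + 1L)
  } else {
    sep <- with_seed(config$seed,
                     separation_train(weights, templates, params, config))
    weights <- sep$weights
    sp_history <- sep$sp_history
  }
  attractors <- capture_attractors(templates, weights, params)
  inn <- with_seed(config$seed + 1L,
                   innate_train(weights, attractors, instances, params,
                                config))
  weights <- inn$weights
  weights <- readout_train(weights, instances, targets, params, config)
  eig_after <- eigen_spectrum(weights$W_res)
  model <- structure(
    list(weights = weights, templates = templates, attractors = attractors,
         sp_history = sp_history, dist_history = inn$dist_history,
         params = params, config = config,
         eig_before = eig_before, eig_after = eig_after),
    class = "esn_model")
  model$errors <- evaluate_trajectories(model, instances, targets)$errors
  model$error <- mean(vapply(model$errors, function(e) e$d, numeric(1)))
  model
}

#' @export
print.esn_model <- function(x, ...) {
  cat("<esn_model> ", x$params$n_res, " neurons, ",
      length(x$attractors), " class attractor(s)\n", sep = "")
  cat(sprintf("  separation  : %.4g -> %.4g over %d epoch(s)\n",
              x$sp_history[[1L]], x$sp_history[[length(x$sp_history)]],
              length(x$sp_history) - 1L))
  cat(sprintf("  approximation: mean distance %.4g -> %.4g over %d epoch(s)\n",
              x$dist_history[[1L]], x$dist_history[[length(x$dist_history)]],
              length(x$dist_history) - 1L))
  if (!is.null(x$error))
    cat(sprintf("  training trajectory error d = %.4g\n", x$error))
  invisible(x)
}
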