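test_that("rls_p_update is the Sherman-Morrison rank-one update", {
  P <- diag(5) / 100
  expect_identical(rls_p_update(P, numeric(5)), P)

  # symmetry is preserved under repeated unit-basis updates
  Q <- diag(5) / 3
  for (i in 1:50) Q <- rls_p_update(Q, diag(5)[, (i %% 5) + 1])
  expect_lt(max(abs(Q - t(Q))), 1e-10)

  # oracle: P after presenting {v_k} equals (alpha I + sum v v')^{-1}
  set.seed(51)
  alpha <- 2
  P <- diag(5) / alpha
  V <- matrix(rnorm(5 * 40), 5, 40)
  for (k in 1:40) P <- rls_p_update(P, V[, k])
  expect_equal(P, solve(tcrossprod(V) + alpha * diag(5)),
               tolerance = 1e-10)

  expect_error(rls_p_update(P, numeric(4)), class = "esndisc_config_error")
})

test_that("class templates are element-wise means of aligned instances", {
  b1 <- matrix(rnorm(3 * 10), 3, 10)
  ds <- manual_dataset(list(a = b1))
  tpl <- compute_class_templates(ds)
  expect_equal(tpl$a, b1)

  ds2 <- list(
    list(class = "a", signal = temporal_signal(b1, 1)),
    list(class = "a", signal = temporal_signal(-b1, 1)))
  expect_equal(compute_class_templates(ds2)$a, matrix(0, 3, 10))

  set.seed(52)
  mats <- replicate(3, matrix(rnorm(30), 3, 10), simplify = FALSE)
  ds3 <- lapply(mats, function(m)
    list(class = "a", signal = temporal_signal(m, 1)))
  expect_equal(compute_class_templates(ds3)$a,
               (mats[[1]] + mats[[2]] + mats[[3]]) / 3,
               tolerance = 1e-12)

  # unequal lengths need an explicit alignment target
  ds4 <- list(list(class = "a", signal = temporal_signal(b1, 1)),
              list(class = "a",
                   signal = temporal_signal(b1[, 1:5], 1)))
  expect_error(compute_class_templates(ds4),
               class = "esndisc_config_error")
  expect_silent(compute_class_templates(ds4, n_steps = 10L))
})

test_that("capture_attractors equals external simulation and is innate", {
  p <- tiny_params()
  w <- init_weights(p)
  zero_tpl <- structure(list(z = matrix(0, p$n_in, sensory_steps(p))),
                        class = "class_templates", dt = 1,
                        classes = "z")
  att0 <- capture_attractors(zero_tpl, w, p)
  expect_true(all(att0$z == 0))

  spec <- easy_spec(n_channels = p$n_in, duration_steps = sensory_steps(p))
  ds <- generate_dataset(spec)
  tpl <- compute_class_templates(ds$instances)
  a1 <- capture_attractors(tpl, w, p)
  a2 <- capture_attractors(tpl, w, p)
  expect_identical(a1, a2)

  manual <- simulate_reservoir(
    pad_motor_phase(temporal_signal(tpl[[1]], 1), p), w, p)
  expect_identical(a1[[1]], manual$values)
})

test_that("separation training with gamma = 0 is the identity", {
  p <- tiny_params()
  spec <- easy_spec(n_classes = 2L, n_channels = p$n_in,
                    duration_steps = sensory_steps(p))
  ds <- generate_dataset(spec)
  tpl <- compute_class_templates(ds$instances)
  w <- init_weights(p)
  res <- separation_train(w, tpl, p, std_config(gamma = 0, epochs_sep = 3L))
  expect_identical(res$weights$W_in, w$W_in)
  expect_length(res$sp_history, 4L)
  expect_true(all(res$sp_history == res$sp_history[1]))

  one_class <- compute_class_templates(ds$instances[
    sapply(ds$instances, `[[`, "class") == "w1.a1"])
  expect_error(separation_train(w, one_class, p, std_config()),
               class = "esndisc_config_error")
})

test_that("the clipped inverse error never overflows", {
  clip <- 1e3
  e <- c(1e-15, -1e-15, 0, 0.5, -0.25, 2)
  inv <- esndisc:::inv_error_clipped(e, clip)
  expect_true(all(is.finite(inv)))
  expect_equal(inv[1:3], c(clip, -clip, clip))
  expect_equal(inv[4:6], c(2, -4, 0.5))
  expect_true(all(abs(inv) <= clip))
})

test_that("innate training leaves a converged system untouched", {
  p <- tiny_params(n_res = 40L)
  spec <- easy_spec(n_classes = 2L, n_channels = p$n_in,
                    duration_steps = sensory_steps(p),
                    amplitude_sd = 0, warp_sd = 0, noise_sd = 0,
                    instances_per_class = 1L)
  ds <- generate_dataset(spec)
  tpl <- compute_class_templates(ds$instances)
  w <- init_weights(p)
  att <- capture_attractors(tpl, w, p)
  # the dataset IS the templates: error is identically zero
  res <- innate_train(w, att, ds$instances, p,
                      std_config(epochs_innate = 2L))
  expect_lt(max(abs(res$weights$W_res - w$W_res)), 1e-10)
  expect_lt(res$dist_history[length(res$dist_history)], 1e-10)

  bad <- list(list(class = "nope", signal = ds$instances[[1]]$signal))
  expect_error(innate_train(w, att, bad, p, std_config()),
               class = "esndisc_data_error")
})

test_that("delta_steps variants both reduce the attractor distance", {
  p <- std_params(n_res = 60L)
  spec <- easy_spec(n_classes = 2L, instances_per_class = 3L)
  ds <- generate_dataset(spec)
  tpl <- compute_class_templates(ds$instances)
  w <- init_weights(p)
  att <- capture_attractors(tpl, w, p)
  h1 <- innate_train(w, att, ds$instances, p,
                     std_config(epochs_innate = 5L,
                                delta_steps = 1L))$dist_history
  h2 <- innate_train(w, att, ds$instances, p,
                     std_config(epochs_innate = 5L,
                                delta_steps = 2L))$dist_history
  expect_lt(h1[length(h1)], h1[1])
  expect_lt(h2[length(h2)], h2[1])
  expect_false(identical(h1, h2))
})

test_that("readout training recovers a planted linear readout", {
  p <- std_params(n_res = 60L)
  spec <- easy_spec(n_classes = 2L, instances_per_class = 2L,
                    amplitude_sd = 0, warp_sd = 0, noise_sd = 0)
  ds <- generate_dataset(spec)
  w <- init_weights(p)
  set.seed(53)
  W0 <- matrix(rnorm(p$n_res * 2, sd = 0.2), p$n_res, 2)
  n_s <- sensory_steps(p)
  # realizable targets: exactly what W0 would read out per class
  targets <- list(word = list())
  for (inst in ds$instances) {
    R <- simulate_reservoir(pad_motor_phase(inst$signal, p), w, p)$values
    tr <- trajectory2d(t(crossprod(W0, R[, (n_s + 1):ncol(R)])))
    targets$word[[inst$labels[["word"]]]] <- tr
  }
  cfg <- std_config(epochs_readout = 10L, alpha_readout = 1)
  wt <- readout_train(w, ds$instances, targets, p, cfg)
  mse <- mean(sapply(ds$instances, function(inst) {
    R <- simulate_reservoir(pad_motor_phase(inst$signal, p), w, p)$values
    Y <- crossprod(wt$W_out$word, R[, (n_s + 1):ncol(R)])
    Y0 <- crossprod(W0, R[, (n_s + 1):ncol(R)])
    mean((Y - Y0)^2)
  }))
  expect_lt(mse, 1e-4)

  # zero targets drive the readout to zero output
  zt <- list(word = lapply(targets$word, function(t)
    trajectory2d(matrix(0, nrow(t), 2))))
  wz <- readout_train(w, ds$instances, zt, p, cfg)
  Rz <- simulate_reservoir(pad_motor_phase(ds$instances[[1]]$signal, p),
                           w, p)$values
  Yz <- crossprod(wz$W_out$word, Rz[, (n_s + 1):ncol(Rz)])
  expect_lt(mean(Yz^2), 1e-4)

  # swapping the two readouts' target sets swaps the trained outputs
  # (targets keyed by combined class label, the fallback for readout
  # names that are not label fields)
  by_class <- stats::setNames(targets$word[c("w1", "w2")],
                              c("w1.a1", "w2.a1"))
  zero_by_class <- lapply(by_class, function(t)
    trajectory2d(matrix(0, nrow(t), 2)))
  two <- list(A = by_class, B = zero_by_class)
  wA <- readout_train(w, ds$instances, two, p, cfg)
  swapped <- list(A = zero_by_class, B = by_class)
  wB <- readout_train(w, ds$instances, swapped, p, cfg)
  expect_identical(wA$W_out$A, wB$W_out$B)
  expect_identical(wA$W_out$B, wB$W_out$A)

  short <- list(word = list(w1 = trajectory2d(matrix(0, 5, 2)),
                            w2 = trajectory2d(matrix(0, 5, 2))))
  expect_error(readout_train(w, ds$instances, short, p, cfg),
               class = "esndisc_config_error")
})

test_that("full training is deterministic and records its diagnostics", {
  p <- std_params(n_res = 60L)
  spec <- easy_spec(n_classes = 2L, instances_per_class = 2L)
  ds <- generate_dataset(spec)
  targets <- word_targets(spec, p)
  cfg <- std_config(epochs_sep = 2L, epochs_innate = 3L,
                    epochs_readout = 3L)
  m1 <- train_full(ds, targets, p, cfg)
  m2 <- train_full(ds, targets, p, cfg)
  expect_identical(m1$sp_history, m2$sp_history)
  expect_identical(m1$dist_history, m2$dist_history)
  expect_identical(m1$error, m2$error)
  expect_identical(m1$weights$W_res, m2$weights$W_res)
  expect_length(m1$sp_history, cfg$epochs_sep + 1L)
  expect_length(m1$dist_history, cfg$epochs_innate + 1L)
  expect_length(m1$eig_before, p$n_res)
  expect_length(m1$eig_after, p$n_res)
  expect_gte(m1$error, 0)
})
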