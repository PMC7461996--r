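# Shared fixture builders.  The "standard" fixture is the desk-scale
# study condition used throughout: 100 neurons, 8 input channels,
# 80 ms sensory + 80 ms motor at dt = 1 ms, tau = 10 ms.

tiny_params <- function(...) {
  args <- utils::modifyList(
    list(n_res = 20L, n_in = 3L, tau = 10, dt = 1,
         sensory_ms = 30, motor_ms = 30, seed = 7L),
    list(...))
  do.call(reservoir_params, args)
}

std_params <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_res = 100L, n_in = 8L, tau = 10, dt = 1,
         sensory_ms = 80, motor_ms = 80, seed = seed),
    list(...))
  do.call(reservoir_params, args)
}

# Easy fixture: four well-separated word classes, mild jitter.
easy_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_classes = 4L, attribute_groups = 1L, n_channels = 8L,
         duration_steps = 80L, instances_per_class = 4L,
         amplitude_sd = 0.05, warp_sd = 0.02, noise_sd = 0.01,
         seed = seed),
    list(...))
  do.call(synth_spec, args)
}

# Hard fixture: one word class split into two attribute groups by a
# weak spectral tilt, under heavy jitter -- the only class distinction
# is the subtle one separation training exists to exaggerate.  The
# last two instances per class are held out; the trajectory error is
# compared on the held-out instances, as for a test set.
hard_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_classes = 1L, attribute_groups = 2L, n_channels = 8L,
         duration_steps = 80L, instances_per_class = 8L,
         attribute_tilt = 0.06, amplitude_sd = 0.1, warp_sd = 0.08,
         noise_sd = 0.1, seed = seed),
    list(...))
  do.call(synth_spec, args)
}

# Confusable-pair fixture for separation-factor sweeps: one word class
# in two weakly tilted attribute groups, so the only class distinction
# is the one separation training must find.
pair_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_classes = 1L, attribute_groups = 2L, n_channels = 8L,
         duration_steps = 80L, instances_per_class = 6L,
         attribute_tilt = 0.12, amplitude_sd = 0.1, warp_sd = 0.08,
         noise_sd = 0.05, seed = seed),
    list(...))
  do.call(synth_spec, args)
}

std_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(gamma = 0.3, epochs_sep = 10L, epochs_innate = 20L,
         epochs_readout = 10L, seed = seed),
    list(...))
  do.call(training_config, args)
}

word_targets <- function(spec, params) {
  tg <- list()
  if (spec$n_classes >= 2L)
    tg$word <- default_targets(sprintf("w%d", seq_len(spec$n_classes)),
                               motor_steps(params))
  if (spec$attribute_groups == 2L)
    tg$attr <- default_targets(c("a1", "a2"), motor_steps(params),
                               shapes = c("lpath", "zigzag"))
  tg
}

# Minimal hand-built dataset: one instance per class from given base
# matrices (no jitter), dt = 1.
manual_dataset <- function(bases) {
  lapply(names(bases), function(cls)
    list(id = cls, class = cls, labels = c(word = cls),
         signal = temporal_signal(bases[[cls]], dt = 1)))
}
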