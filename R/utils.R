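`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a configuration error
#'
#' Used for invalid parameters, mismatched dimensions declared up front,
#' and malformed config files.  Carries class `esndisc_config_error` so
#' callers (and the command-line wrapper, which maps it to exit code 2)
#' can distinguish it from data errors.
#'
#' @param ... message parts passed to [sprintf()]-free paste.
#' @keywords internal
#' @noRd
stop_config <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("esndisc_config_error", "error")))
}

#' Signal a data error (missing files, empty classes, bad manifests).
#' Mapped to exit code 3 by the command-line wrapper.
#' @keywords internal
#' @noRd
stop_data <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("esndisc_data_error", "error")))
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library calls never disturb a user's random stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Stable hash of an R object (md5 of its canonical deparse).  Used to stamp
# run artifacts with the configuration that produced them.
config_hash <- function(x) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(deparse(x, control = c("exact", "niceNames")), tf)
  unname(tools::md5sum(tf))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != round(x)) {
    stop_config(name, " must be a single integer >= ", min, " (got ",
                deparse(substitute(x)), " = ", paste(x, collapse = ","), ")")
  }
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_config(name, " must be a single positive number")
  as.numeric(x)
}
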