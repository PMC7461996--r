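#' Labeled collection of vectorized dynamics
#'
#' Holds one flattened dynamics vector per item together with its class
#' label and (optionally non-empirical) class priors.  This is the input
#' to the scatter-trace separation metrics and the PCA diagnostic: each
#' reservoir trajectory is first concatenated into a single long vector
#' (see [vectorize_rates()]).
#'
#' @param vectors numeric matrix with one row per item (items x D), or a
#'   list of equal-length numeric vectors.
#' @param labels character/factor vector of class labels, one per item.
#' @param priors optional named numeric vector of class probabilities
#'   P(class); defaults to the empirical class frequencies.  Must sum
#'   to 1 within 1e-12.
#' @return An object of class `labeled_dynamics` with elements
#'   `vectors` (matrix), `labels` (character), `priors` (named numeric),
#'   `L` (number of classes).
#' @export
labeled_dynamics <- function(vectors, labels, priors = NULL) {
  if (is.list(vectors)) {
    lens <- lengths(vectors)
    if (length(unique(lens)) != 1L)
      stop_config("all dynamics vectors must share one length")
    vectors <- do.call(rbind, lapply(vectors, as.numeric))
  }
  if (!is.matrix(vectors) || !is.numeric(vectors))
    stop_config("vectors must be a numeric matrix or list of vectors")
  labels <- as.character(labels)
  if (length(labels) != nrow(vectors))
    stop_config("need one label per row of vectors")
  classes <- sort(unique(labels))
  if (is.null(priors)) {
    priors <- table(labels)[classes] / length(labels)
    priors <- stats::setNames(as.numeric(priors), classes)
  } else {
    if (is.null(names(priors)) || !setequal(names(priors), classes))
      stop_config("priors must be named with exactly the observed classes")
    priors <- priors[classes]
    if (abs(sum(priors) - 1) > 1e-12)
      stop_config("priors must sum to 1 (got ", sum(priors), ")")
  }
  structure(list(vectors = vectors, labels = labels,
                 priors = priors, L = length(classes)),
            class = "labeled_dynamics")
}

#' @export
print.labeled_dynamics <- function(x, ...) {
  cat("<labeled_dynamics> ", nrow(x$vectors), " item(s), ",
      x$L, " class(es), D = ", ncol(x$vectors), "\n", sep = "")
  invisible(x)
}

#' Pairwise separation of two trajectories
#'
#' The mean over time samples of the Euclidean distance between two
#' state (or rate) trajectories: a scalar measure of how far apart the
#' reservoir responses to two inputs stay.
#'
#' @param traj_u,traj_v `n x N` matrices or [temporal_signal()]s of
#'   equal shape (one column per sample point).
#' @return Non-negative scalar.
#' @export
pairwise_separation <- function(traj_u, traj_v) {
  A <- signal_values(traj_u); B <- signal_values(traj_v)
  if (!all(dim(A) == dim(B)))
    stop_config("trajectories must have equal shape (",
                paste(dim(A), collapse = "x"), " vs ",
                paste(dim(B), collapse = "x"), ")")
  mean(sqrt(colSums((A - B)^2)))
}

#' Linear-separation rank of a state matrix
#'
#' Numerical rank of the matrix whose columns are reservoir states
#' sampled at one time point under m different inputs: the number of
#' singular values exceeding `tol` times the largest.  Rank m means a
#' linear readout can realize any target assignment at that instant.
#'
#' @param states `N x m` numeric matrix of sampled states.
#' @param tol relative tolerance; default
#'   `max(dim(states)) * .Machine$double.eps`.
#' @return Integer rank in `[0, min(N, m)]`.
#' @export
linear_separation_rank <- function(states, tol = NULL) {
  if (!is.matrix(states) || length(states) == 0L)
    stop_config("states must be a nonempty matrix")
  sv <- svd(states, nu = 0L, nv = 0L)$d
  if (is.null(tol)) tol <- max(dim(states)) * .Machine$double.eps
  if (sv[[1L]] == 0) return(0L)
  sum(sv > tol * sv[[1L]])
}

#' Between/within-class scatter traces and discriminant ratio
#'
#' Separation property `SP = trace(S_b)` where
#' `S_b = sum_i P(w_i) (mu_i - mu_g)(mu_i - mu_g)^T`, plus the
#' within-class counterpart `trace(S_w) = sum_i P(w_i) trace(Cov_i)`
#' with `Cov_i` the unbiased per-class sample covariance, and their
#' ratio, the discriminant ratio `DR`.  Traces are accumulated directly
#' from class means and per-dimension variances, so the full D x D
#' scatter matrices are never materialized.
#'
#' Classes with a single member contribute zero within-class scatter;
#' division by a vanishing `trace(S_w)` is guarded by `eps`.
#'
#' @param data a [labeled_dynamics()].
#' @param eps floor for the within-class trace in the ratio.
#' @return An object of class `scatter_summary` with elements
#'   `S_b_trace`, `S_w_trace`, `DR`.
#' @export
scatter_summary <- function(data, eps = 1e-12) {
  stopifnot(inherits(data, "labeled_dynamics"))
  if (data$L < 2L)
    warning("scatter_summary: a single class gives zero between-class scatter")
  classes <- names(data$priors)
  D <- ncol(data$vectors)
  mus <- matrix(0, length(classes), D)
  s_w <- 0
  for (k in seq_along(classes)) {
    Xi <- data$vectors[data$labels == classes[[k]], , drop = FALSE]
    mus[k, ] <- colMeans(Xi)
    if (nrow(Xi) > 1L) {
      centered <- sweep(Xi, 2L, mus[k, ])
      s_w <- s_w + data$priors[[k]] * sum(centered^2) / (nrow(Xi) - 1L)
    }
  }
  mu_g <- drop(crossprod(mus, data$priors))
  s_b <- sum(data$priors * rowSums(sweep(mus, 2L, mu_g)^2))
  structure(list(S_b_trace = s_b, S_w_trace = s_w,
                 DR = s_b / max(s_w, eps)),
            class = "scatter_summary")
}

#' @export
print.scatter_summary <- function(x, ...) {
  cat(sprintf("<scatter_summary> tr(S_b) = %.6g  tr(S_w) = %.6g  DR = %.6g\n",
              x$S_b_trace, x$S_w_trace, x$DR))
  invisible(x)
}

#' Kernel-quality metric D
#'
#' Combines a separation rank `R_S` (states from distinct inputs) and a
#' generalization rank `R_G` (states from jittered versions of the same
#' inputs) into `D = (R_S - R_G) / R_S`.
#'
#' @param R_S separation rank (>= 1).
#' @param R_G generalization rank (>= 0).
#' @return Scalar in `(-Inf, 1]`; 0 when both ranks agree.
#' @export
kernel_quality_D <- function(R_S, R_G) {
  R_S <- check_count(R_S, "R_S", min = 0L)
  R_G <- check_count(R_G, "R_G", min = 0L)
  if (R_S == 0L)
    stop_config("kernel-quality D is undefined for R_S = 0")
  (R_S - R_G) / R_S
}

#' Flatten a rate trajectory into a single vector
#'
#' Neuron-major concatenation: the full time series of neuron 1, then
#' neuron 2, and so on; length `n_res * T`.  The inverse reshape is
#' `matrix(v, nrow = n_res, byrow = TRUE)`.
#'
#' @param rates `n_res x T` matrix or [temporal_signal()].
#' @return Numeric vector of length `n_res * T`.
#' @export
vectorize_rates <- function(rates) {
  R <- signal_values(rates)
  if (length(R) == 0L) stop_config("cannot vectorize an empty trajectory")
  as.vector(t(R))
}

#' Project labeled dynamics onto the first two principal components
#'
#' Centers the item vectors and projects them onto the top-2 principal
#' axes of their covariance; used to visualize how well classes are
#' separated and approximated.  Deterministic up to the sign of each
#' axis.
#'
#' @param data a [labeled_dynamics()] with at least 2 items.
#' @param n_components number of components (2).
#' @return Matrix of item scores (items x `n_components`), with the
#'   labels attached as attribute `labels`.
#' @export
pca_project <- function(data, n_components = 2L) {
  stopifnot(inherits(data, "labeled_dynamics"))
  n_components <- check_count(n_components, "n_components")
  if (nrow(data$vectors) < n_components)
    stop_config("need at least ", n_components, " items for ",
                n_components, " components")
  pc <- stats::prcomp(data$vectors, center = TRUE, scale. = FALSE,
                      rank. = n_components)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  attr(scores, "labels") <- data$labels
  attr(scores, "sdev") <- pc$sdev
  scores
}
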