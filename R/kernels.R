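#' Base kernel specification
#'
#' One of the three base kernel families used by the multi-kernel
#' classifier. "Gaussian" and "RBF" name the same family and are implemented
#' once.
#'
#' @param kind `"linear"`, `"polynomial"` or `"rbf"`.
#' @param degree polynomial degree (polynomial only, default 3).
#' @param coef0 polynomial offset (polynomial only, default 1).
#' @param bandwidth RBF bandwidth sigma (rbf only); `NULL` requests the
#'   median-pairwise-distance heuristic, resolved at fit time.
#' @return an object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("linear", "polynomial", "rbf"),
                        degree = 3L, coef0 = 1, bandwidth = NULL) {
  kind <- match.arg(kind)
  if (kind == "polynomial") {
    if (degree < 1 || degree != as.integer(degree)) stop_config("degree must be a positive integer")
  }
  if (kind == "rbf" && !is.null(bandwidth) && bandwidth <= 0) {
    stop_config("bandwidth must be positive")
  }
  structure(list(kind = kind,
                 degree = if (kind == "polynomial") as.integer(degree),
                 coef0 = if (kind == "polynomial") coef0,
                 bandwidth = if (kind == "rbf") bandwidth),
            class = "kernel_spec")
}

#' Evaluate a base kernel between two sample blocks
#'
#' linear: \eqn{x^\top x'}; polynomial: \eqn{(x^\top x' + c_0)^d};
#' rbf: \eqn{\exp(-\|x - x'\|^2 / (2\sigma^2))}.
#'
#' @param spec a [kernel_spec()].
#' @param A,B numeric matrices with the same number of columns.
#' @return `nrow(A)` by `nrow(B)` kernel matrix.
#' @export
base_kernel <- function(spec, A, B = A) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) {
    stop_input("kernel blocks disagree in feature dimension (%d vs %d)", ncol(A), ncol(B))
  }
  G <- tcrossprod(A, B)
  switch(spec$kind,
    linear = G,
    polynomial = (G + spec$coef0)^spec$degree,
    rbf = {
      if (is.null(spec$bandwidth)) {
        stop_config("rbf bandwidth unresolved; call resolve_bandwidth() or set it explicitly")
      }
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * G
      d2[d2 < 0] <- 0
      exp(-d2 / (2 * spec$bandwidth^2))
    })
}

# Median pairwise Euclidean distance on a bounded seeded subsample; the
# standard RBF bandwidth heuristic.
median_heuristic <- function(X, max_n = 200L, seed = 1L) {
  n <- nrow(X)
  if (n > max_n) {
    rs <- local_rng(seed)
    X <- X[sort(rs$sample_int(n, max_n)), , drop = FALSE]
  }
  d <- stats::dist(X)
  m <- stats::median(as.numeric(d))
  if (!is.finite(m) || m <= 0) 1 else m
}

# Fill in any NULL rbf bandwidths from the data.
resolve_bandwidths <- function(ck, X, seed = 1L) {
  ck$specs <- lapply(ck$specs, function(sp) {
    if (sp$kind == "rbf" && is.null(sp$bandwidth)) {
      sp$bandwidth <- median_heuristic(X, seed = seed)
    }
    sp
  })
  ck
}

#' Composite (multi-)kernel
#'
#' Convex combination of base kernels: \eqn{K = \sum_m \beta_m k_m} with
#' \eqn{\beta_m \ge 0}, \eqn{\sum_m \beta_m = 1}. A convex combination of
#' positive semidefinite kernels is positive semidefinite.
#'
#' @param specs list of [kernel_spec()] objects.
#' @param beta simplex weight vector, same length as `specs`; default
#'   uniform.
#' @return an object of class `composite_kernel`.
#' @export
composite_kernel <- function(specs, beta = NULL) {
  if (!length(specs)) stop_config("composite kernel needs at least one base kernel")
  if (inherits(specs, "kernel_spec")) specs <- list(specs)
  if (is.null(beta)) beta <- rep(1 / length(specs), length(specs))
  if (length(beta) != length(specs)) stop_config("beta length must match number of kernels")
  if (any(beta < 0) || abs(sum(beta) - 1) > 1e-9) {
    stop_config("beta must be nonnegative and sum to 1 (within 1e-9)")
  }
  structure(list(specs = specs, beta = as.numeric(beta)), class = "composite_kernel")
}

#' Default base-kernel set
#'
#' Linear, polynomial (degree 3, offset 1) and RBF with the median-distance
#' bandwidth heuristic, uniformly weighted.
#'
#' @return a [composite_kernel()].
#' @export
default_kernels <- function() {
  composite_kernel(list(kernel_spec("linear"),
                        kernel_spec("polynomial", degree = 3L, coef0 = 1),
                        kernel_spec("rbf")))
}

#' Composite kernel matrix between two sample blocks
#'
#' @param ck a [composite_kernel()].
#' @param A,B numeric matrices with the same number of columns.
#' @return weighted sum of the base kernel matrices.
#' @export
composite_kernel_matrix <- function(ck, A, B = A) {
  mats <- lapply(ck$specs, base_kernel, A = A, B = B)
  out <- matrix(0, nrow(as.matrix(A)), nrow(as.matrix(B)))
  for (m in seq_along(mats)) out <- out + ck$beta[m] * mats[[m]]
  out
}

#' Centered-kernel-alignment weight update
#'
#' Scores each base kernel by its centered alignment with the ideal target
#' matrix \eqn{yy^\top} on a bounded subsample, clips negative alignments to
#' zero and renormalizes onto the simplex; if every alignment is zero the
#' weights fall back to uniform. Multiclass labels are reduced one-vs-rest
#' against the first class. The alignment depends only on the data and
#' labels, so within a training run the update is stationary after its first
#' application.
#'
#' @param ck a [composite_kernel()] (bandwidths resolved).
#' @param X numeric matrix of samples.
#' @param y labels (2 classes; multiclass reduced one-vs-rest).
#' @param max_n alignment subsample bound (default 500).
#' @return new simplex weight vector, same length as `ck$specs`.
#' @export
update_kernel_weights <- function(ck, X, y, max_n = 500L) {
  y <- as.factor(y)
  yy <- ifelse(y == levels(y)[1], -1, 1)
  if (nlevels(y) > 2L) yy <- ifelse(y == levels(y)[1], 1, -1)
  n <- nrow(X)
  if (n > max_n) {
    keep <- seq_len(max_n)  # bounded deterministic subsample
    X <- X[keep, , drop = FALSE]
    yy <- yy[keep]
  }
  n <- nrow(X)
  Tmat <- tcrossprod(yy)
  H <- diag(n) - matrix(1 / n, n, n)
  Tc <- H %*% Tmat %*% H
  tnorm <- sqrt(sum(Tc^2))
  align <- vapply(ck$specs, function(sp) {
    K <- base_kernel(sp, X)
    Kc <- H %*% K %*% H
    knorm <- sqrt(sum(Kc^2))
    if (knorm <= 0 || tnorm <= 0) return(0)
    sum(Kc * Tc) / (knorm * tnorm)
  }, numeric(1))
  align[align < 0] <- 0
  if (sum(align) <= 0) {
    rep(1 / length(align), length(align))
  } else {
    align / sum(align)
  }
}
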