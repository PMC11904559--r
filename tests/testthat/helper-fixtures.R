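# Shared fixtures and the independent centralized QP oracle.

tiny_dataset <- function(X, y) {
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  skr_dataset(X, y, preprocessed = TRUE)
}

write_tmp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# Canonical row order used inside dmkcf_fit (label, then feature columns);
# lets tests line raw labels up with the model's internal basis.
canonical_order <- function(ds) {
  X <- ds$X
  do.call(order, c(list(as.integer(ds$y)),
                   lapply(seq_len(ncol(X)), function(j) X[, j])))
}

# Independent centralized solve of the hinge + ridge problem on a kernel
# basis (bias unregularized), via kernlab's interior-point QP on the dual:
#   max sum(lambda) - 1/2 lambda' (yy' * K K') lambda,  y'lambda = 0,
#   0 <= lambda <= C.
# Returns basis coefficients, bias, and the primal objective.
centralized_oracle <- function(K, yv, C) {
  n <- nrow(K)
  H <- (yv %o% yv) * (K %*% K)
  sol <- kernlab::ipop(c = rep(-1, n), H = H + diag(1e-8, n),
                       A = matrix(yv, 1), b = 0,
                       l = rep(0, n), u = rep(C, n), r = 0)
  lam <- kernlab::primal(sol)
  aL <- as.numeric(crossprod(K, lam * yv))
  f_nob <- as.numeric(K %*% aL)
  sv <- which(lam > 1e-5 & lam < C - 1e-5)
  b <- if (length(sv)) mean(yv[sv] - f_nob[sv]) else 0
  list(aL = aL, b = b,
       objective = 0.5 * sum(aL^2) + C * sum(pmax(0, 1 - yv * (f_nob + b))))
}

hinge_ridge_objective <- function(K, yv, C, aL, b) {
  0.5 * sum(aL^2) + C * sum(pmax(0, 1 - yv * (as.numeric(K %*% aL) + b)))
}

linear_kernel <- function() composite_kernel(list(kernel_spec("linear")))

linear_rbf_kernel <- function(bw = 2) {
  composite_kernel(list(kernel_spec("linear"), kernel_spec("rbf", bandwidth = bw)))
}
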