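#' Configuration for the distributed multi-kernel classifier
#'
#' @param P number of simulated compute nodes (default 1).
#' @param C positive SVM regularization parameter (default 1).
#' @param rho positive consensus penalty parameter (default 1).
#' @param epsilon convergence tolerance on both the global-variable change
#'   and the consensus residual (default 1e-4).
#' @param max_iter maximum outer iterations (default 100).
#' @param n_landmarks size of the shared landmark basis; default
#'   `min(100, N)`, resolved at fit time.
#' @param landmark_seed integer seed fixing landmark choice and partitioning
#'   (default 1).
#' @param partition_mode `"stratified"` (class proportions preserved per
#'   node within one sample) or `"random"`.
#' @return an object of class `dmkcf_config`.
#' @export
dmkcf_config <- function(P = 1L, C = 1, rho = 1, epsilon = 1e-4,
                         max_iter = 100L, n_landmarks = NULL,
                         landmark_seed = 1L,
                         partition_mode = c("stratified", "random")) {
  partition_mode <- match.arg(partition_mode)
  if (P < 1) stop_config("P must be >= 1")
  if (C <= 0) stop_config("C must be positive")
  if (rho <= 0) stop_config("rho must be positive")
  if (epsilon <= 0) stop_config("epsilon must be positive")
  if (max_iter < 1) stop_config("max_iter must be >= 1")
  if (!is.null(n_landmarks) && n_landmarks < 1) stop_config("n_landmarks must be >= 1")
  structure(list(P = as.integer(P), C = C, rho = rho, epsilon = epsilon,
                 max_iter = as.integer(max_iter),
                 n_landmarks = if (!is.null(n_landmarks)) as.integer(n_landmarks),
                 landmark_seed = as.integer(landmark_seed),
                 partition_mode = partition_mode),
            class = "dmkcf_config")
}

#' Partition sample indices across nodes
#'
#' Produces a disjoint cover of `1..N` in `P` blocks. Stratified mode deals
#' each class's (seeded, shuffled) indices round-robin with a global cursor,
#' so class proportions per node are preserved within one sample and block
#' sizes differ by at most one. Deterministic given `cfg$landmark_seed`.
#'
#' @param y label vector of length N.
#' @param cfg a [dmkcf_config()].
#' @return list of `P` integer index vectors.
#' @export
partition_nodes <- function(y, cfg) {
  n <- length(y)
  P <- cfg$P
  if (P > n) stop_config("P = %d exceeds sample count N = %d", P, n)
  rs <- local_rng(sub_seed(cfg$landmark_seed, "partition"))
  if (P == 1L) return(list(seq_len(n)))
  blocks <- vector("list", P)
  if (cfg$partition_mode == "stratified") {
    y <- as.factor(y)
    cursor <- 0L
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[rs$sample_int(length(idx))]
      for (i in seq_along(idx)) {
        node <- (cursor %% P) + 1L
        blocks[[node]] <- c(blocks[[node]], idx[i])
        cursor <- cursor + 1L
      }
    }
  } else {
    perm <- rs$sample_int(n)
    sizes <- rep(n %/% P, P)
    extra <- n %% P
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    at <- 1L
    for (j in seq_len(P)) {
      blocks[[j]] <- perm[at:(at + sizes[j] - 1L)]
      at <- at + sizes[j]
    }
  }
  lapply(blocks, sort)
}

#' Local composite-kernel block against the shared landmarks
#'
#' Each node's kernel computation is the composite kernel between its own
#' samples and the common landmark set, giving a `|D_j|` by `L` block. All
#' node coefficient vectors live on this shared basis, which makes them
#' dimension-compatible for consensus averaging.
#'
#' @param ck a [composite_kernel()] with resolved bandwidths.
#' @param ds an [skr_dataset()].
#' @param node_indices integer sample indices of the node.
#' @param landmarks landmark sample matrix (L by M).
#' @return `length(node_indices)` by `nrow(landmarks)` matrix.
#' @export
local_kernel_matrix <- function(ck, ds, node_indices, landmarks) {
  if (!length(node_indices)) stop_input("node has no samples")
  X <- dataset_matrix(ds)
  composite_kernel_matrix(ck, X[node_indices, , drop = FALSE], landmarks)
}

# Dual coordinate descent for the node subproblem
#   min_a 1/2 ||a_{1:L}||^2 + C sum_i max(0, 1 - y_i phi_i' a) + rho ||v - a||^2
# where phi_i = (K_i, 1) appends the bias coordinate and v is the proximal
# center. The quadratic part is 1/2 a' D a - 2 rho v' a with
# D = diag(1 + 2 rho, ..., 1 + 2 rho, 2 rho): the ridge excludes the bias,
# the proximal term covers every coordinate. The dual in the box [0, C]^n is
# solved by cyclic exact coordinate maximization, which for this strongly
# convex problem converges linearly; sweeps stop when the largest projected
# gradient falls below `tol`.
solve_node_qp <- function(Phi, yv, C, rho, v, tol = 1e-9, max_sweeps = 5000L,
                          lambda = NULL) {
  n <- nrow(Phi)
  L1 <- ncol(Phi)              # L + 1, bias last
  d <- c(rep(1 + 2 * rho, L1 - 1L), 2 * rho)
  if (rho <= 0) stop_numeric("node solver requires rho > 0")
  if (is.null(lambda)) lambda <- numeric(n)   # warm-startable across calls
  a <- (2 * rho * v + as.numeric(crossprod(Phi, lambda * yv))) / d
  Dinv_Phi <- sweep(Phi, 2, d, "/")          # rows phi_i / d
  h <- rowSums(Phi * Dinv_Phi)               # phi_i' D^-1 phi_i
  for (sweep_i in seq_len(max_sweeps)) {
    max_viol <- 0
    for (i in seq_len(n)) {
      g <- 1 - yv[i] * sum(Phi[i, ] * a)     # dual gradient coordinate
      # projected-gradient violation at the box
      pg <- if (lambda[i] <= 0) max(g, 0) else if (lambda[i] >= C) max(-g, 0) else abs(g)
      if (pg > max_viol) max_viol <- pg
      if (pg > 0 && h[i] > 0) {
        li <- min(max(lambda[i] + g / h[i], 0), C)
        if (li != lambda[i]) {
          a <- a + (li - lambda[i]) * yv[i] * Dinv_Phi[i, ]
          lambda[i] <- li
        }
      }
    }
    if (max_viol < tol) break
  }
  list(a = a, lambda = lambda, kkt_violation = max_viol, sweeps = sweep_i)
}

# Node objective of the subproblem above, used for diagnostics and tests.
node_objective <- function(a, Phi, yv, C, rho, v) {
  L1 <- length(a)
  margins <- 1 - yv * as.numeric(Phi %*% a)
  0.5 * sum(a[-L1]^2) + C * sum(pmax(0, margins)) + rho * sum((v - a)^2)
}

#' Solve one node's regularized subproblem
#'
#' Minimizes the local objective — ridge on the landmark coefficients
#' (bias excluded), C-weighted hinge losses over the node's samples, and
#' the proximal consensus penalty \eqn{\rho\|z - \alpha_j\|^2} — exactly,
#' via dual coordinate descent on the equivalent box-constrained QP.
#'
#' @param K_block node-by-landmark composite kernel block.
#' @param yv node labels in \{-1, +1\}.
#' @param z proximal center (consensus variable, possibly dual-shifted),
#'   length L + 1 with the bias last.
#' @param cfg a [dmkcf_config()] supplying `C` and `rho`.
#' @param tol inner KKT tolerance (default 1e-9).
#' @return the minimizing coefficient vector alpha_j (length L + 1).
#' @export
local_admm_update <- function(K_block, yv, z, cfg, tol = 1e-9, warm = NULL) {
  if (!all(yv %in% c(-1, 1))) stop_input("node labels must be in {-1, +1}")
  Phi <- cbind(K_block, 1)
  if (length(z) != ncol(Phi)) stop_input("z length %d does not match basis size %d",
                                         length(z), ncol(Phi))
  if (cfg$C == 0) {
    if (cfg$rho == 0) return(numeric(ncol(Phi)))  # pure ridge: minimum at 0
    d <- c(rep(1 + 2 * cfg$rho, ncol(Phi) - 1L), 2 * cfg$rho)
    return((2 * cfg$rho * z) / d)
  }
  sol <- solve_node_qp(Phi, yv, cfg$C, cfg$rho, z, tol = tol, lambda = warm)
  if (sol$kkt_violation > 1e-5) {
    stop_numeric("node solver did not reach tolerance: KKT violation %.3g after %d sweeps",
                 sol$kkt_violation, sol$sweeps)
  }
  sol$a
}

#' Average node coefficients into the consensus variable
#'
#' @param alphas list of equal-length coefficient vectors.
#' @return their elementwise mean.
#' @export
consensus_update <- function(alphas) {
  if (!length(alphas)) stop_input("no node coefficients to average")
  lens <- vapply(alphas, length, integer(1))
  if (length(unique(lens)) != 1L) stop_input("node coefficient lengths differ")
  Reduce(`+`, alphas) / length(alphas)
}

#' Fit the distributed multi-kernel classifier
#'
#' Trains a binary kernel classifier \eqn{f(x) = \sum_l z_l K(x, x_l) + b}
#' on a shared landmark basis by consensus ADMM across `cfg$P` simulated
#' nodes. Each outer iteration performs (a) a local update at every node —
#' ridge + hinge + proximal penalty toward the consensus variable shifted by
#' the node's scaled dual variable — (b) consensus averaging, (c) a
#' centered-kernel-alignment update of the kernel weights, and (d) a
#' convergence check requiring both the consensus-variable change and the
#' worst node residual \eqn{\max_j \|\alpha_j - z\|} to fall below
#' `cfg$epsilon`. The scaled dual variables drive the node coefficients into
#' exact consensus, so at convergence the recorded residual is below
#' tolerance by construction.
#'
#' Rows are internally sorted into a canonical order (label, then feature
#' values) before landmark selection and partitioning, making the fitted
#' model invariant to the ordering of training samples.
#'
#' @param ds a preprocessed [skr_dataset()] with 2 classes.
#' @param ck a [composite_kernel()]; default [default_kernels()].
#' @param cfg a [dmkcf_config()].
#' @return an object of class `dmkcf_model`.
#' @export
dmkcf_fit <- function(ds, ck = default_kernels(), cfg = dmkcf_config()) {
  X <- dataset_matrix(ds)
  y <- droplevels(ds$y)
  if (nlevels(y) != 2L) stop_input("dmkcf_fit requires exactly 2 classes (got %d)", nlevels(y))
  n <- nrow(X)
  # canonical row order: label first, then lexicographic feature values
  ord <- do.call(order, c(list(as.integer(y)), lapply(seq_len(ncol(X)), function(j) X[, j])))
  X <- X[ord, , drop = FALSE]
  y <- y[ord]
  yv <- ifelse(y == levels(y)[2], 1, -1)

  n_land <- if (is.null(cfg$n_landmarks)) min(100L, n) else min(cfg$n_landmarks, n)
  rs <- local_rng(sub_seed(cfg$landmark_seed, "landmarks"))
  land_idx <- sort(rs$sample_int(n, n_land))
  landmarks <- X[land_idx, , drop = FALSE]

  ck <- resolve_bandwidths(ck, X, seed = sub_seed(cfg$landmark_seed, "bandwidth"))
  parts <- partition_nodes(y, cfg)
  P <- length(parts)

  # per-node base-kernel blocks, computed once; composite blocks are cheap
  # beta-recombinations
  base_blocks <- lapply(parts, function(idx) {
    lapply(ck$specs, base_kernel, A = X[idx, , drop = FALSE], B = landmarks)
  })
  recombine <- function(node, beta) {
    out <- matrix(0, length(parts[[node]]), n_land)
    for (m in seq_along(beta)) out <- out + beta[m] * base_blocks[[node]][[m]]
    out
  }

  L1 <- n_land + 1L
  z <- numeric(L1)
  alphas <- replicate(P, numeric(L1), simplify = FALSE)
  duals <- replicate(P, numeric(L1), simplify = FALSE)
  beta <- ck$beta
  history <- list()
  converged <- FALSE

  full_Phi <- function(beta) {
    do.call(rbind, lapply(seq_len(P), function(j) cbind(recombine(j, beta), 1)))
  }
  yv_all <- unlist(lapply(parts, function(idx) yv[idx]))

  # residual-balancing adaptive penalty (standard ADMM practice): the
  # configured rho is the starting value; warm-started node solvers keep the
  # per-iteration cost low once the active sets stabilize.
  rho <- cfg$rho
  relax <- if (P > 1L) 1.6 else 1  # over-relax the consensus path only
  warms <- replicate(P, NULL, simplify = FALSE)
  align_beta <- NULL           # alignment depends only on (X, y); memoized
  for (t in seq_len(cfg$max_iter)) {
    blocks <- lapply(seq_len(P), function(j) recombine(j, beta))
    sols <- lapply(seq_len(P), function(j) {
      solve_node_qp(cbind(blocks[[j]], 1), yv[parts[[j]]], cfg$C, rho,
                    z - duals[[j]], lambda = warms[[j]])
    })
    alphas <- lapply(sols, `[[`, "a")
    warms <- lapply(sols, `[[`, "lambda")
    relaxed <- lapply(alphas, function(a) relax * a + (1 - relax) * z)
    z_new <- consensus_update(lapply(seq_len(P), function(j) relaxed[[j]] + duals[[j]]))
    duals <- lapply(seq_len(P), function(j) duals[[j]] + relaxed[[j]] - z_new)
    if (is.null(align_beta)) {
      align_beta <- update_kernel_weights(composite_kernel(ck$specs, beta), X, y)
    }
    beta_new <- align_beta

    dz <- sqrt(sum((z_new - z)^2))
    res <- max(vapply(alphas, function(a) sqrt(sum((a - z_new)^2)), numeric(1)))
    Phi <- full_Phi(beta_new)
    obj <- 0.5 * sum(z_new[-L1]^2) +
      cfg$C * sum(pmax(0, 1 - yv_all * as.numeric(Phi %*% z_new)))
    history[[t]] <- list(iter = t, dz = dz, consensus_residual = res,
                         objective = obj, beta = beta_new, rho = rho)
    z <- z_new
    beta <- beta_new
    if (dz < cfg$epsilon && res <= cfg$epsilon) {
      converged <- TRUE
      break
    }
    if (P > 1L) {
      r_norm <- sqrt(sum(vapply(alphas, function(a) sum((a - z)^2), numeric(1))))
      s_norm <- rho * sqrt(P) * dz
      if (r_norm > 10 * s_norm) {
        rho <- rho * 2; duals <- lapply(duals, `/`, 2)
      } else if (s_norm > 10 * r_norm) {
        rho <- rho / 2; duals <- lapply(duals, `*`, 2)
      }
    }
  }
  if (!converged) {
    warning(sprintf("dmkcf_fit did not converge in %d iterations (dz = %.3g, residual = %.3g)",
                    cfg$max_iter, history[[length(history)]]$dz,
                    history[[length(history)]]$consensus_residual))
  }
  structure(list(
    landmarks = landmarks, z = z, per_node_alpha = alphas, duals = duals,
    train_X = X, train_yv = yv, partitions = parts,
    kernel = composite_kernel(ck$specs, beta), config = cfg,
    levels = levels(y), n_features = ncol(X), feature_names = colnames(X),
    history = history, converged = converged,
    n_iter = length(history)), class = "dmkcf_model")
}

#' @export
print.dmkcf_model <- function(x, ...) {
  cat(sprintf("<dmkcf_model> %d landmarks, %d nodes, %d kernels, %s after %d iterations\n",
              nrow(x$landmarks), length(x$per_node_alpha), length(x$kernel$specs),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat("  beta:", paste(sprintf("%.3f", x$kernel$beta), collapse = ", "), "\n")
  invisible(x)
}

#' Decision scores of a fitted model
#'
#' \eqn{f(x) = \sum_l z_l K(x, x_l) + b} over the landmark basis.
#'
#' @param model a [dmkcf_fit()] result.
#' @param X_new numeric matrix of new samples.
#' @return numeric vector of real-valued scores.
#' @export
decision_function <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != model$n_features) {
    stop_input("X_new has %d features; model expects %d", ncol(X_new), model$n_features)
  }
  L <- nrow(model$landmarks)
  K <- composite_kernel_matrix(model$kernel, X_new, model$landmarks)
  as.numeric(K %*% model$z[seq_len(L)] + model$z[L + 1L])
}

#' Predict class labels
#'
#' Labels are the sign of the decision score; a score of exactly zero maps
#' to the positive (second) class.
#'
#' @param object a `dmkcf_model`.
#' @param newdata numeric matrix or `skr_dataset`.
#' @param ... unused.
#' @return factor of predicted labels with the training levels.
#' @export
predict.dmkcf_model <- function(object, newdata, ...) {
  if (inherits(newdata, "skr_dataset")) newdata <- dataset_matrix(newdata)
  s <- decision_function(object, newdata)
  factor(ifelse(s >= 0, object$levels[2], object$levels[1]), levels = object$levels)
}

#' Serialize a fitted model to versioned JSON
#'
#' @param model a `dmkcf_model`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_model <- function(model, path) {
  doc <- list(
    format = "dmkcf_model", version = 1L,
    kernel = list(specs = lapply(model$kernel$specs, unclass), beta = model$kernel$beta),
    landmarks = model$landmarks,
    z = model$z,
    per_node_alpha = model$per_node_alpha,
    config = unclass(model$config),
    levels = model$levels,
    n_features = model$n_features,
    feature_names = model$feature_names,
    converged = model$converged,
    n_iter = model$n_iter,
    history = lapply(model$history, function(h) h[c("iter", "dz", "consensus_residual", "objective", "beta")])
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a serialized model
#'
#' @param path path to a JSON document written by [write_model()].
#' @return a `dmkcf_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop_config("model file does not exist: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$format) || doc$format != "dmkcf_model") {
    stop_input("%s is not a dmkcf model document", path)
  }
  specs <- lapply(doc$kernel$specs, function(sp) {
    switch(sp$kind,
      linear = kernel_spec("linear"),
      polynomial = kernel_spec("polynomial", degree = sp$degree, coef0 = sp$coef0),
      rbf = kernel_spec("rbf", bandwidth = sp$bandwidth),
      stop_input("unknown kernel kind '%s' in %s", sp$kind, path))
  })
  cfgl <- doc$config
  nl <- cfgl$n_landmarks
  if (length(nl) != 1L || !is.finite(suppressWarnings(as.numeric(nl)))) nl <- NULL
  cfg <- dmkcf_config(P = cfgl$P, C = cfgl$C, rho = cfgl$rho, epsilon = cfgl$epsilon,
                      max_iter = cfgl$max_iter, n_landmarks = nl,
                      landmark_seed = cfgl$landmark_seed,
                      partition_mode = cfgl$partition_mode)
  landmarks <- do.call(rbind, lapply(doc$landmarks, function(r) as.numeric(unlist(r))))
  structure(list(
    landmarks = landmarks, z = as.numeric(unlist(doc$z)),
    per_node_alpha = lapply(doc$per_node_alpha, function(a) as.numeric(unlist(a))),
    kernel = composite_kernel(specs, as.numeric(unlist(doc$kernel$beta))),
    config = cfg, levels = as.character(unlist(doc$levels)),
    n_features = doc$n_features,
    feature_names = as.character(unlist(doc$feature_names)),
    converged = isTRUE(doc$converged),
    n_iter = doc$n_iter, history = NULL), class = "dmkcf_model")
}
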