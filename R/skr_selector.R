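#' Per-feature variance contribution
#'
#' Variance quantifies the spread of a feature's values around its mean and
#' is the first ingredient of the relevance score. The population
#' (divide-by-N) convention is used throughout:
#' \deqn{V_i = \frac{1}{N}\sum_{j=1}^N (x_{ij} - \mu_i)^2.}
#'
#' @param ds a preprocessed [skr_dataset()] (numeric matrix).
#' @return numeric vector of length M, named by feature.
#' @export
variance_contribution <- function(ds) {
  X <- dataset_matrix(ds)
  if (nrow(X) < 1L || ncol(X) < 1L) stop_input("empty feature matrix")
  v <- apply(X, 2, function(x) mean((x - mean(x))^2))
  stats::setNames(v, colnames(X))
}

#' Kruskal-type rank separability metric
#'
#' For each feature the sample values are ranked 1..N (ties share the
#' average of their rank range) and the metric is the class-size-weighted
#' spread of mean ranks:
#' \deqn{R_i = \sum_{c=1}^{k} \frac{n_c}{N} (\bar r_c - \bar r)^2,}
#' with \eqn{\bar r_c} the mean rank within class c and \eqn{\bar r} the
#' overall mean rank. With no ties this is a rescaling of the Kruskal-Wallis
#' H statistic, \eqn{R = H (N+1)/12}, so the induced feature ordering is the
#' Kruskal-Wallis ordering; working on ranks makes the score robust to
#' outliers and monotone transformations.
#'
#' @param ds a preprocessed [skr_dataset()] with at least 2 classes, each
#'   with at least one sample.
#' @return numeric vector of length M, named by feature.
#' @export
rank_metric <- function(ds) {
  X <- dataset_matrix(ds)
  y <- ds$y
  if (nlevels(droplevels(y)) < 2L) stop_input("rank metric needs at least 2 classes")
  y <- droplevels(y)
  n <- nrow(X)
  nc <- table(y)
  r <- apply(X, 2, function(x) {
    rk <- rank(x, ties.method = "average")
    rbar <- mean(rk)
    rbar_c <- tapply(rk, y, mean)
    sum((as.numeric(nc) / n) * (rbar_c - rbar)^2)
  })
  stats::setNames(r, colnames(X))
}

#' Ranking weights for the relevance score
#'
#' @param alpha nonnegative weight on the variance contribution.
#' @param beta nonnegative weight on the rank metric.
#' @return an object of class `ranking_weights`.
#' @export
ranking_weights <- function(alpha = 0.5, beta = 0.5) {
  if (!is.numeric(alpha) || !is.numeric(beta) || alpha < 0 || beta < 0 ||
      alpha + beta <= 0) {
    stop_config("ranking weights must be nonnegative with alpha + beta > 0")
  }
  structure(list(alpha = alpha, beta = beta), class = "ranking_weights")
}

#' Combine variance and rank metric into relevance scores
#'
#' The relevance score of feature i is the weighted combination
#' \eqn{S_i = \alpha V_i + \beta R_i}. Because variance and the rank metric
#' live on incomparable scales, both are min-max rescaled to \[0, 1\] across
#' features before combining (the default); constant vectors rescale to
#' all-zeros. Set `normalize = FALSE` for the literal un-rescaled sum.
#'
#' @param V variance vector, length M.
#' @param R rank-metric vector, length M.
#' @param w a [ranking_weights()].
#' @param normalize rescale V and R to \[0,1\] before combining (default TRUE).
#' @return an object of class `feature_ranking` with fields `V`, `R`, `S`,
#'   `normalized`, `weights`.
#' @export
relevance_scores <- function(V, R, w = ranking_weights(), normalize = TRUE) {
  if (length(V) != length(R)) stop_input("V and R must have the same length")
  if (any(V < 0) || any(R < 0)) stop_input("V and R must be nonnegative")
  Vh <- if (normalize) rescale01(V) else V
  Rh <- if (normalize) rescale01(R) else R
  S <- w$alpha * Vh + w$beta * Rh
  nms <- names(V)
  structure(list(V = V, R = R, S = stats::setNames(S, nms),
                 normalized = isTRUE(normalize), weights = w),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> %d features (alpha=%g, beta=%g, %s)\n",
              length(x$S), x$weights$alpha, x$weights$beta,
              if (x$normalized) "min-max normalized" else "literal"))
  ord <- order(x$S, decreasing = TRUE)
  top <- utils::head(ord, 5)
  cat("  top:", paste(sprintf("%s=%.3f", names(x$S)[top], x$S[top]), collapse = ", "), "\n")
  invisible(x)
}

#' Write per-feature scores as CSV
#'
#' @param ranking a [relevance_scores()] result.
#' @param path output CSV path.
#' @param selected optional integer vector of selected feature indices.
#' @return invisibly, `path`.
#' @export
write_ranking <- function(ranking, path, selected = NULL) {
  df <- data.frame(feature = names(ranking$S), V = as.numeric(ranking$V),
                   R = as.numeric(ranking$R), S = as.numeric(ranking$S),
                   selected = if (is.null(selected)) NA else
                     seq_along(ranking$S) %in% selected)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Linear soft-margin SVM primal weights on a binary problem.
# Returns the primal weight vector w (length = ncol(X)).
linear_svm_weights <- function(X, y, C) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop_input("SVM subset contains a single class")
  fit <- tryCatch(
    e1071::svm(X, y, kernel = "linear", cost = C, scale = FALSE),
    error = function(e) stop_numeric("linear SVM solver failed: %s", conditionMessage(e))
  )
  w <- crossprod(fit$coefs, fit$SV)
  as.numeric(w)
}

#' SVM-derived per-feature importance weights
#'
#' Fits the linear soft-margin SVM
#' \deqn{\min_{w,b} \tfrac12 \|w\|^2 + C \sum_j \max(0, 1 - y_j(w^\top x_j + b))}
#' on the given columns and returns the importance of feature i as
#' \eqn{|w_i|}, the magnitude of the corresponding primal weight component —
#' the standard SVM-RFE elimination criterion. Multiclass problems are
#' handled one-vs-rest with per-feature importance the maximum over the
#' binary problems.
#'
#' @param ds a preprocessed [skr_dataset()] (features standardized).
#' @param C positive regularization parameter, default 1.
#' @return nonnegative numeric vector of length M, named by feature.
#' @export
svm_feature_weights <- function(ds, C = 1) {
  X <- dataset_matrix(ds)
  y <- droplevels(ds$y)
  if (nlevels(y) < 2L) stop_input("SVM feature weighting needs at least 2 classes")
  if (C <= 0) stop_config("C must be positive")
  if (nlevels(y) == 2L) {
    w <- abs(linear_svm_weights(X, y, C))
  } else {
    per_class <- vapply(levels(y), function(cl) {
      yy <- factor(ifelse(y == cl, "pos", "rest"), levels = c("rest", "pos"))
      abs(linear_svm_weights(X, yy, C))
    }, numeric(ncol(X)))
    w <- apply(per_class, 1, max)
  }
  stats::setNames(w, colnames(X))
}

#' Recursive-elimination configuration
#'
#' @param gamma features removed per iteration; default
#'   `max(1, floor(0.1 * M))`, resolved at run time.
#' @param t_max maximum number of elimination iterations (default 50).
#' @param T_min minimum retained feature count; default
#'   `max(2, ceiling(0.05 * M))`, resolved at run time.
#' @param svm_C SVM regularization parameter for both the weight fits and
#'   the cross-validated accuracy term (default 1).
#' @param cv_folds stratified folds for the accuracy term (default 3).
#' @param lambdas nonnegative triple (lambda1, lambda2, lambda3) weighting
#'   relevance, accuracy and efficiency in the joint objective (default 1,1,1).
#' @param objective_form `"normalized"` (all three terms in \[0,1\]) or
#'   `"literal"` (raw sums, 1/T efficiency proxy).
#' @param seed integer seed fixing fold assignment (default 1).
#' @return an object of class `rfe_config`.
#' @export
rfe_config <- function(gamma = NULL, t_max = 50L, T_min = NULL, svm_C = 1,
                       cv_folds = 3L, lambdas = c(1, 1, 1),
                       objective_form = c("normalized", "literal"), seed = 1L) {
  objective_form <- match.arg(objective_form)
  if (!is.null(gamma) && (gamma < 1 || gamma != as.integer(gamma)))
    stop_config("gamma must be a positive integer")
  if (t_max < 0) stop_config("t_max must be nonnegative")
  if (!is.null(T_min) && T_min < 1) stop_config("T_min must be >= 1")
  if (svm_C <= 0) stop_config("svm_C must be positive")
  if (cv_folds < 2) stop_config("cv_folds must be >= 2")
  if (length(lambdas) != 3 || any(lambdas < 0)) stop_config("lambdas must be 3 nonnegative reals")
  structure(list(gamma = gamma, t_max = as.integer(t_max), T_min = T_min,
                 svm_C = svm_C, cv_folds = as.integer(cv_folds),
                 lambdas = as.numeric(lambdas), objective_form = objective_form,
                 seed = as.integer(seed)),
            class = "rfe_config")
}

# Resolve data-dependent defaults against the feature count M.
resolve_rfe_config <- function(cfg, M) {
  if (is.null(cfg$gamma)) cfg$gamma <- max(1L, as.integer(floor(0.1 * M)))
  if (is.null(cfg$T_min)) cfg$T_min <- max(2L, as.integer(ceiling(0.05 * M)))
  cfg$gamma <- as.integer(cfg$gamma)
  cfg$T_min <- as.integer(cfg$T_min)
  if (cfg$T_min > M) stop_config("T_min = %d exceeds feature count M = %d", cfg$T_min, M)
  cfg
}

#' Combine objective terms into the joint selection objective
#'
#' \deqn{L = \lambda_1 \cdot \mathrm{relevance} + \lambda_2 \cdot
#'   \mathrm{accuracy} + \lambda_3 \cdot \mathrm{efficiency}.}
#' The terms are produced by the elimination loop: in the default
#' `"normalized"` form relevance is the mean relevance score over retained
#' features, accuracy the cross-validated accuracy, and efficiency
#' `1 - T/T_total`, all in \[0,1\]; in the `"literal"` form relevance is the
#' raw sum of scores and efficiency `1/T` (retained-feature count standing
#' in for compute time, so the objective is reproducible across machines).
#'
#' @param terms numeric triple `(relevance, accuracy, efficiency)`.
#' @param lambdas nonnegative triple.
#' @param form `"normalized"` or `"literal"` (recorded; the terms themselves
#'   are computed upstream under the same form).
#' @return the scalar objective value L.
#' @export
objective_value <- function(terms, lambdas = c(1, 1, 1),
                            form = c("normalized", "literal")) {
  form <- match.arg(form)
  terms <- as.numeric(terms)
  if (length(terms) != 3) stop_input("terms must be (relevance, accuracy, efficiency)")
  if (terms[2] < 0 || terms[2] > 1) stop_input("accuracy term must lie in [0, 1]")
  sum(as.numeric(lambdas) * terms)
}

# Objective terms for a retained set. S: full relevance vector; retained:
# integer indices; acc: CV accuracy; T_total: original feature count.
objective_terms <- function(S, retained, acc, T_total, form) {
  T_cur <- length(retained)
  if (T_cur == 0L) stop_input("retained set is empty")
  if (form == "normalized") {
    c(relevance = mean(S[retained]), accuracy = acc,
      efficiency = 1 - T_cur / T_total)
  } else {
    c(relevance = sum(S[retained]), accuracy = acc, efficiency = 1 / T_cur)
  }
}

# Stratified-CV accuracy of a linear SVM on the retained columns.
cv_accuracy <- function(X, y, retained, C, folds, seed) {
  y <- droplevels(as.factor(y))
  fold_id <- stratified_folds(y, folds, seed)
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    te <- !tr
    if (!any(te)) next
    ytr <- droplevels(y[tr])
    if (nlevels(ytr) < 2L) {
      # degenerate fold: predict the majority class
      pred <- rep(names(which.max(table(ytr))), sum(te))
    } else {
      fit <- e1071::svm(X[tr, retained, drop = FALSE], ytr, kernel = "linear",
                        cost = C, scale = FALSE)
      pred <- as.character(stats::predict(fit, X[te, retained, drop = FALSE]))
    }
    correct <- correct + sum(pred == as.character(y[te]))
  }
  correct / length(y)
}

#' Recursive feature elimination driven by SVM weights
#'
#' Starting from all M features, each iteration fits a linear SVM on the
#' retained columns, removes the `gamma` features with smallest importance
#' \eqn{|w_i|} (ties broken by lower relevance score, then lower column
#' index), and records the joint objective. The retained count follows the
#' schedule \eqn{T_t = T - \gamma t}; the loop halts when `t_max` iterations
#' have run or removing another batch would drop below `T_min`. Iteration 0
#' (the full feature set) is always recorded, so an empty schedule selects
#' all features.
#'
#' @param ds a preprocessed [skr_dataset()].
#' @param ranking a [relevance_scores()] result for `ds`.
#' @param cfg an [rfe_config()].
#' @return an object of class `selection_trace`: `iterations` (list of
#'   records with `t`, `retained`, `weights`, `terms`, `L`) and `best_index`
#'   (first L-maximizing iteration).
#' @export
rfe_run <- function(ds, ranking, cfg = rfe_config()) {
  X <- dataset_matrix(ds)
  y <- ds$y
  M <- ncol(X)
  cfg <- resolve_rfe_config(cfg, M)
  S <- ranking$S
  if (length(S) != M) stop_input("ranking length %d does not match M = %d", length(S), M)
  retained <- seq_len(M)
  iterations <- list()
  t <- 0L
  repeat {
    sub <- skr_dataset(X[, retained, drop = FALSE], y, preprocessed = TRUE)
    W <- svm_feature_weights(sub, C = cfg$svm_C)
    acc <- cv_accuracy(X, y, retained, cfg$svm_C, cfg$cv_folds, cfg$seed)
    terms <- objective_terms(S, retained, acc, M, cfg$objective_form)
    L <- objective_value(terms, cfg$lambdas, cfg$objective_form)
    iterations[[length(iterations) + 1L]] <- list(
      t = t, retained = retained, weights = W, terms = terms, L = L)
    if (t >= cfg$t_max) break
    if (length(retained) - cfg$gamma < cfg$T_min) break
    # eliminate: smallest W first, then smallest S, then lowest column index
    ord <- order(W, S[retained], retained)
    drop_local <- ord[seq_len(cfg$gamma)]
    retained <- retained[-drop_local]
    t <- t + 1L
  }
  Ls <- vapply(iterations, `[[`, numeric(1), "L")
  structure(list(iterations = iterations, best_index = which.max(Ls)),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  ns <- vapply(x$iterations, function(it) length(it$retained), integer(1))
  Ls <- vapply(x$iterations, `[[`, numeric(1), "L")
  cat(sprintf("<selection_trace> %d iterations, retained %d -> %d features\n",
              length(ns), ns[1], ns[length(ns)]))
  cat(sprintf("  best: iteration %d (t=%d), %d features, L = %.4f\n",
              x$best_index, x$iterations[[x$best_index]]$t,
              ns[x$best_index], Ls[x$best_index]))
  invisible(x)
}

#' Write a selection trace as JSON
#'
#' One record per iteration with retained indices and objective terms.
#'
#' @param trace a [rfe_run()] result.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  recs <- lapply(trace$iterations, function(it) {
    list(t = it$t, retained = it$retained, n_retained = length(it$retained),
         terms = as.list(it$terms), L = it$L)
  })
  jsonlite::write_json(list(iterations = recs, best_index = trace$best_index),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full feature selector
#'
#' End-to-end selector: variance contribution and rank metric are combined
#' into relevance scores, recursive elimination prunes the feature pool, and
#' the retained set of the first L-maximizing iteration is returned.
#' Deterministic given `cfg$seed`.
#'
#' @param ds a preprocessed [skr_dataset()].
#' @param w a [ranking_weights()].
#' @param cfg an [rfe_config()].
#' @param normalize passed to [relevance_scores()].
#' @return an object of class `skr_selection` with fields `selected`
#'   (integer feature indices), `trace` (a `selection_trace`) and `ranking`
#'   (a `feature_ranking`).
#' @export
skr_select <- function(ds, w = ranking_weights(), cfg = rfe_config(),
                       normalize = TRUE) {
  if (!isTRUE(ds$preprocessed)) {
    # tolerated for already-numeric input, but scoring assumes comparable scales
    dataset_matrix(ds)
  }
  V <- variance_contribution(ds)
  R <- rank_metric(ds)
  ranking <- relevance_scores(V, R, w, normalize = normalize)
  trace <- rfe_run(ds, ranking, cfg)
  selected <- trace$iterations[[trace$best_index]]$retained
  structure(list(selected = selected, trace = trace, ranking = ranking),
            class = "skr_selection")
}

#' @export
print.skr_selection <- function(x, ...) {
  cat(sprintf("<skr_selection> %d of %d features selected\n",
              length(x$selected), length(x$ranking$S)))
  cat("  features:", paste(utils::head(names(x$ranking$S)[x$selected], 10),
                           collapse = ", "),
      if (length(x$selected) > 10) "..." else "", "\n")
  invisible(x)
}
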