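#' Synthetic dataset generator specification
#'
#' Describes a seeded synthetic tabular dataset emulating one of four
#' clinical data archetypes: `numeric` (low-dimensional numeric predictors,
#' diabetes-style), `categorical_mixed` (numeric plus coded categorical
#' columns, cardiology-style), `signal` (nonlinearly mixed
#' frequency/amplitude-like vocal features), and `highdim` (p >> n omics
#' panels with correlated redundant blocks).
#'
#' Informative features are class-conditional Gaussians with unit
#' within-class standard deviation and a between-class mean gap of `effect`,
#' so the effect size has a closed-form meaning; noise features are
#' label-independent standard normals; redundant features are an informative
#' parent plus `N(0, noise_sd)` noise, which at the default `noise_sd = 0.5`
#' yields parent correlation \eqn{1/\sqrt{1.25} \approx 0.89 \ge 0.8} by
#' construction.
#'
#' @param archetype one of `"numeric"`, `"categorical_mixed"`, `"signal"`,
#'   `"highdim"`.
#' @param n sample count.
#' @param p feature count (for `highdim`, `p >= 5 n` is enforced).
#' @param p_informative number of informative features (<= p).
#' @param effect standardized class-mean separation (> 0, default 1.5).
#' @param imbalance minority-class fraction in (0, 0.5], default 0.5.
#' @param redundant_blocks correlated copies per informative feature
#'   (default 0).
#' @param noise_sd noise level of redundant copies (default 0.5).
#' @param n_categorical columns converted to 3-level codes by quantile
#'   binning (`categorical_mixed` only, default 0).
#' @param seed integer seed; generation is bitwise reproducible.
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(archetype = c("numeric", "categorical_mixed",
                                         "signal", "highdim"),
                           n = 200L, p = 10L, p_informative = 5L,
                           effect = 1.5, imbalance = 0.5,
                           redundant_blocks = 0L, noise_sd = 0.5,
                           n_categorical = 0L, seed = 1L) {
  archetype <- match.arg(archetype)
  if (p_informative > p) stop_config("p_informative = %d exceeds p = %d", p_informative, p)
  if (p_informative * (1 + redundant_blocks) > p) {
    stop_config("p too small for %d informative features with %d redundant copies each",
                p_informative, redundant_blocks)
  }
  if (effect <= 0) stop_config("effect must be positive")
  if (imbalance <= 0 || imbalance > 0.5) stop_config("imbalance must lie in (0, 0.5]")
  if (noise_sd <= 0) stop_config("noise_sd must be positive")
  if (archetype == "highdim" && p < 5 * n) {
    stop_config("highdim archetype requires p >= 5 n (got p = %d, n = %d)", p, n)
  }
  if (archetype != "categorical_mixed" && n_categorical > 0) {
    stop_config("n_categorical applies to the categorical_mixed archetype only")
  }
  if (n_categorical > p) stop_config("n_categorical exceeds p")
  structure(list(archetype = archetype, n = as.integer(n), p = as.integer(p),
                 p_informative = as.integer(p_informative), effect = effect,
                 imbalance = imbalance, redundant_blocks = as.integer(redundant_blocks),
                 noise_sd = noise_sd, n_categorical = as.integer(n_categorical),
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a synthetic labelled dataset
#'
#' Draws a dataset from a [generator_spec()]: binary labels (`case` the
#' minority class at the configured imbalance, exact up to integer
#' rounding), informative/redundant/noise feature blocks, archetype
#' post-processing (quantile-coded categorical columns for
#' `categorical_mixed`; a bounded sinusoid-plus-amplitude mixture
#' `x + 0.75 sin(2 x)` applied to every column for `signal`, breaking
#' linearity while preserving rank structure), and a ground-truth
#' `informative_mask` flagging the informative columns.
#'
#' @param spec a [generator_spec()].
#' @return an [skr_dataset()] with `informative_mask` set and the spec
#'   recorded in field `generator`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  n <- spec$n; p <- spec$p; p_inf <- spec$p_informative
  n_case <- as.integer(round(n * spec$imbalance))
  y <- factor(c(rep("case", n_case), rep("control", n - n_case)),
              levels = c("control", "case"))
  y <- y[sample.int(n)]
  delta <- spec$effect  # within-class sd is 1, so the gap IS the effect size
  X <- matrix(stats::rnorm(n * p), n, p)
  mu <- ifelse(y == "case", delta / 2, -delta / 2)
  for (j in seq_len(p_inf)) X[, j] <- X[, j] + mu
  n_red <- p_inf * spec$redundant_blocks
  if (n_red > 0) {
    for (b in seq_len(spec$redundant_blocks)) {
      for (j in seq_len(p_inf)) {
        col <- p_inf + (b - 1L) * p_inf + j
        X[, col] <- X[, j] + stats::rnorm(n, sd = spec$noise_sd)
      }
    }
  }
  kinds <- rep(switch(spec$archetype, numeric = "numeric",
                      categorical_mixed = "numeric", signal = "signal",
                      highdim = "omics"), p)
  nm <- paste0("f", seq_len(p))
  mask <- c(rep(TRUE, p_inf), rep(FALSE, p - p_inf))
  if (spec$archetype == "signal") {
    X <- X + 0.75 * sin(2 * X)
  }
  if (spec$archetype == "categorical_mixed" && spec$n_categorical > 0) {
    cat_cols <- seq.int(p - spec$n_categorical + 1L, p)
    df <- as.data.frame(X)
    names(df) <- nm
    for (j in cat_cols) {
      q <- stats::quantile(X[, j], probs = c(1 / 3, 2 / 3))
      df[[j]] <- cut(X[, j], breaks = c(-Inf, q, Inf), labels = c("low", "mid", "high"))
      df[[j]] <- as.character(df[[j]])
      kinds[j] <- "categorical"
    }
    meta <- data.frame(name = nm, kind = kinds, original = nm, stringsAsFactors = FALSE)
    ds <- skr_dataset(df, y, feature_meta = meta, informative_mask = mask)
    ds$generator <- spec
    return(ds)
  }
  colnames(X) <- nm
  meta <- data.frame(name = nm, kind = kinds, original = nm, stringsAsFactors = FALSE)
  ds <- skr_dataset(X, y, feature_meta = meta, informative_mask = mask)
  ds$generator <- spec
  ds
}

#' Canonical four-archetype fixture suite
#'
#' Four seeded datasets whose shapes mirror familiar public clinical
#' benchmarks: a 768 x 8 numeric table, a 300 x 13 mixed table with 5
#' categorical columns, a 195 x 22 signal-feature table, and a 100 x 2000
#' high-dimensional table (p/n = 20) with 20 informative features and
#' class imbalance 0.3. The shapes are used purely as familiar scales; no
#' distributional fidelity to any real dataset is claimed.
#'
#' @return named list of four [skr_dataset()] objects
#'   (`numeric`, `mixed`, `signal`, `highdim`).
#' @export
fixture_suite <- function() {
  list(
    numeric = generate_dataset(generator_spec("numeric", n = 768L, p = 8L,
                                              p_informative = 4L, seed = 101L)),
    mixed = generate_dataset(generator_spec("categorical_mixed", n = 300L, p = 13L,
                                            p_informative = 4L, n_categorical = 5L,
                                            seed = 102L)),
    signal = generate_dataset(generator_spec("signal", n = 195L, p = 22L,
                                             p_informative = 6L, seed = 103L)),
    highdim = generate_dataset(generator_spec("highdim", n = 100L, p = 2000L,
                                              p_informative = 20L, imbalance = 0.3,
                                              seed = 104L))
  )
}

#' Two well-separated Gaussian blobs
#'
#' A separable two-dimensional binary fixture used in tests and examples of
#' the distributed classifier; by construction a margin exists between the
#' classes at the default separation.
#'
#' @param n sample count (default 200).
#' @param separation distance between class means (default 4).
#' @param seed integer seed (default 3).
#' @return an [skr_dataset()] (already numeric, marked preprocessed).
#' @export
blob_dataset <- function(n = 200L, separation = 4, seed = 3L) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  n1 <- n %/% 2L
  X <- rbind(
    cbind(stats::rnorm(n1, -separation / 2), stats::rnorm(n1, 0)),
    cbind(stats::rnorm(n - n1, separation / 2), stats::rnorm(n - n1, 0)))
  colnames(X) <- c("f1", "f2")
  y <- factor(c(rep("neg", n1), rep("pos", n - n1)), levels = c("neg", "pos"))
  perm <- sample.int(n)
  skr_dataset(X[perm, ], y[perm], preprocessed = TRUE)
}
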