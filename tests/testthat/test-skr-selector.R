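test_that("variance contribution follows the population convention", {
  expect_equal(unname(variance_contribution(
    tiny_dataset(cbind(c(1, 2, 3)), c("a", "a", "b")))), 2 / 3)
  expect_equal(unname(variance_contribution(
    tiny_dataset(cbind(c(5, 5, 5)), c("a", "a", "b")))), 0)
  expect_equal(unname(variance_contribution(
    tiny_dataset(cbind(c(0, 4)), c("a", "b")))), 4)
})

test_that("rank metric matches hand-computed class rank separation", {
  expect_equal(unname(rank_metric(
    tiny_dataset(cbind(c(1, 2, 3, 4)), c("A", "A", "B", "B")))), 1.0)
  expect_equal(unname(rank_metric(
    tiny_dataset(cbind(c(7, 7, 7, 7)), c("A", "A", "B", "B")))), 0)
  expect_equal(unname(rank_metric(
    tiny_dataset(cbind(c(1, 2, 3, 10, 11, 12)), rep(c("A", "B"), each = 3)))), 2.25)
  expect_error(rank_metric(tiny_dataset(cbind(1:4), rep("A", 4))),
               class = "skr_input_error")
})

test_that("rank metric is a rescaled Kruskal-Wallis H and orders features identically", {
  set.seed(1234)
  for (rep in 1:50) {
    n <- sample(8:30, 1)
    k <- sample(2:3, 1)
    y <- factor(sample(rep_len(letters[1:k], n)))
    X <- matrix(rnorm(n * 4), n, 4)  # continuous draws: ties have probability 0
    ds <- tiny_dataset(X, y)
    R <- rank_metric(ds)
    H <- apply(X, 2, function(x) unname(kruskal.test(x, y)$statistic))
    expect_equal(unname(R), H * (n + 1) / 12, tolerance = 1e-9)
    # identical ordering (statistics equal up to the 1e-9 tolerance tie)
    expect_equal(rank(round(unname(R), 9), ties.method = "average"),
                 rank(round(H * (n + 1) / 12, 9), ties.method = "average"))
    # with no ties the overall mean rank is (n+1)/2 exactly
    expect_equal(mean(rank(X[, 1])), (n + 1) / 2)
  }
})

test_that("relevance scores combine normalized metrics linearly and monotonically", {
  fr <- relevance_scores(c(1, 0.5, 0), c(0, 1, 0.5),
                         ranking_weights(0.7, 0.3), normalize = FALSE)
  expect_equal(unname(fr$S), c(0.7, 0.65, 0.15))
  # boundary: both metrics at 1 with alpha = beta = 0.5
  both <- relevance_scores(c(0, 1), c(0, 1), ranking_weights(0.5, 0.5))
  expect_equal(unname(both$S[2]), 1)
  only_v <- relevance_scores(c(3, 1, 2), c(5, 5, 5), ranking_weights(1, 0))
  expect_equal(unname(only_v$S), rescale01(c(3, 1, 2)))
  # monotone in V with R fixed
  base <- relevance_scores(c(1, 2, 3), c(2, 2, 2), normalize = FALSE)
  bumped <- relevance_scores(c(1, 2.5, 3), c(2, 2, 2), normalize = FALSE)
  expect_gte(bumped$S[2], base$S[2])
  expect_error(relevance_scores(c(1, 2), c(1, 2, 3)), class = "skr_input_error")
})

test_that("SVM feature weights isolate the informative dimension", {
  X <- rbind(c(1, 0), c(-1, 0), c(1, 0.1), c(-1, -0.1))
  ds <- tiny_dataset(X, c("pos", "neg", "pos", "neg"))
  w <- svm_feature_weights(ds, C = 1000)
  expect_equal(unname(w[1]), 1, tolerance = 1e-3)
  expect_lt(w[2], 0.05)
  expect_error(svm_feature_weights(tiny_dataset(X, rep("pos", 4))),
               class = "skr_input_error")
})

test_that("a pure-noise feature gets smaller SVM weight than the informative one", {
  set.seed(7)
  n <- 40
  y <- rep(c("a", "b"), each = n / 2)
  X <- cbind(sig = ifelse(y == "a", -2, 2) + rnorm(n, sd = 0.3), noise = rnorm(n))
  w <- svm_feature_weights(tiny_dataset(X, y), C = 1)
  expect_gt(w["sig"], w["noise"])
})

test_that("elimination schedule follows T_t = T - gamma t and halts at T_min", {
  set.seed(11)
  y <- rep(c("a", "b"), each = 15)
  X <- matrix(rnorm(30 * 10), 30, 10)
  X[, 1] <- X[, 1] + ifelse(y == "a", -1, 1)
  ds <- tiny_dataset(X, y)
  rk <- relevance_scores(variance_contribution(ds), rank_metric(ds))
  tr <- rfe_run(ds, rk, rfe_config(gamma = 3, T_min = 5, t_max = 50, seed = 1))
  expect_equal(vapply(tr$iterations, function(it) length(it$retained), integer(1)),
               c(10L, 7L))  # next step would hit 4 < T_min
  tr2 <- rfe_run(ds, rk, rfe_config(gamma = 2, T_min = 2, t_max = 3, seed = 1))
  expect_equal(vapply(tr2$iterations, function(it) length(it$retained), integer(1)),
               c(10L, 8L, 6L, 4L))  # t_max bound
  # retained sets are nested, strictly decreasing, and conserve the pool
  rets <- lapply(tr2$iterations, `[[`, "retained")
  for (i in seq_len(length(rets) - 1)) {
    expect_true(all(rets[[i + 1]] %in% rets[[i]]))
    expect_lt(length(rets[[i + 1]]), length(rets[[i]]))
  }
  removed <- setdiff(rets[[1]], rets[[length(rets)]])
  expect_setequal(c(removed, rets[[length(rets)]]), seq_len(10))
})

test_that("objective value is the lambda-weighted sum of its terms", {
  expect_equal(objective_value(c(0.8, 0.9, 0.5), c(1, 1, 1)), 2.2)
  expect_equal(objective_value(c(0.8, 0.9, 0.5), c(0, 1, 0)), 0.9)
  expect_equal(objective_value(c(1, 1, 1), c(0.3, 0.5, 0.2)), 1.0)
  expect_error(objective_value(c(0.5, 1.7, 0.2)), class = "skr_input_error")
})

test_that("selection with an empty schedule keeps all features and is deterministic", {
  ds <- preprocess(generate_dataset(generator_spec("numeric", n = 60, p = 6,
                                                   p_informative = 2, seed = 4)))
  sel_all <- skr_select(ds, cfg = rfe_config(t_max = 0, seed = 1))
  expect_equal(sel_all$selected, 1:6)
  s1 <- skr_select(ds, cfg = rfe_config(seed = 5))
  s2 <- skr_select(ds, cfg = rfe_config(seed = 5))
  expect_identical(s1$selected, s2$selected)
  expect_error(rfe_run(ds, s1$ranking, rfe_config(T_min = 99)),
               class = "skr_config_error")
})

test_that("selector recovers informative features on the numeric archetype", {
  ds <- preprocess(generate_dataset(generator_spec("numeric", n = 300, p = 50,
                                                   p_informative = 5, seed = 1)))
  sel <- skr_select(ds, cfg = rfe_config(seed = 1))
  hits <- sum(sel$selected %in% which(ds$informative_mask))
  expect_gte(hits, 4)
})

test_that("selector attains a small retained fraction on high-dimensional data", {
  ds <- preprocess(generate_dataset(generator_spec("highdim", n = 100, p = 500,
                                                   p_informative = 10, seed = 7)))
  sel <- skr_select(ds, cfg = rfe_config(seed = 7))
  frr <- feature_reduction_ratio(length(sel$selected), 500)
  expect_lte(frr, 0.2)
})

test_that("ranking and trace writers produce machine-readable files", {
  ds <- preprocess(generate_dataset(generator_spec("numeric", n = 40, p = 5,
                                                   p_informative = 2, seed = 2)))
  sel <- skr_select(ds, cfg = rfe_config(seed = 2))
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_ranking(sel$ranking, csv, selected = sel$selected)
  write_trace(sel$trace, js)
  scores <- read.csv(csv)
  expect_equal(nrow(scores), 5L)
  expect_equal(sum(scores$selected), length(sel$selected))
  doc <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(doc$best_index, sel$trace$best_index)
})
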