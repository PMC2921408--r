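# a linearly separable two-class feature fixture
separable_fixture <- function(n_pos = 40, n_neg = 60, d = 5, seed = 19) {
  withr::with_seed(seed, {
    X <- rbind(
      matrix(rnorm(n_pos * d, mean = 3), ncol = d),
      matrix(rnorm(n_neg * d, mean = -3), ncol = d)
    )
    y <- c(rep(1L, n_pos), rep(0L, n_neg))
    dasa <- ifelse(y == 1, 1 + rexp(n_pos + n_neg, 1 / 30), 0)[seq_along(y)]
    list(X = X, y = y, dasa = ifelse(y == 1, 2 + seq_along(y), 0))
  })
}

test_that("the ensemble has one member per subset pair", {
  fx <- separable_fixture()
  part <- partition_by_dasa(fx$dasa, fx$y, M = 2, N = 5, seed = 1)
  model <- train_ensemble(fx$X, fx$y, part, seed = 1)
  expect_identical(model$K, 10L)
  pairs <- t(vapply(model$members, function(m) c(m$i, m$j), numeric(2)))
  expect_identical(nrow(unique(pairs)), 10L)

  part1 <- partition_by_dasa(fx$dasa, fx$y, M = 1, N = 1, seed = 1)
  model1 <- train_ensemble(fx$X, fx$y, part1, seed = 1)
  expect_identical(model1$K, 1L)
})

test_that("every member separates a linearly separable fixture", {
  fx <- separable_fixture()
  part <- partition_by_dasa(fx$dasa, fx$y, M = 2, N = 2, seed = 1)
  model <- train_ensemble(fx$X, fx$y, part, seed = 1)
  votes <- predict_votes(model, fx$X)
  for (k in seq_len(model$K)) {
    m <- model$members[[k]]
    idx <- c(part$pos_subsets[[m$i]], part$neg_subsets[[m$j]])
    # training accuracy 1 on its own pair
    expect_identical(votes[idx, k], fx$y[idx])
  }
})

test_that("vote prediction is deterministic and handles empty input", {
  fx <- separable_fixture()
  part <- partition_by_dasa(fx$dasa, fx$y, M = 2, N = 2, seed = 1)
  model <- train_ensemble(fx$X, fx$y, part, seed = 1)
  v1 <- predict_votes(model, fx$X)
  v2 <- predict_votes(model, fx$X)
  expect_identical(v1, v2)
  v0 <- predict_votes(model, fx$X[0, , drop = FALSE])
  expect_identical(dim(v0), c(0L, model$K))
  expect_error(predict_votes(model, fx$X[, 1:2]), "dimension")
})

test_that("a member's votes depend only on its own training pair", {
  fx <- separable_fixture(seed = 23)
  part <- partition_by_dasa(fx$dasa, fx$y, M = 2, N = 3, seed = 1)
  model_a <- train_ensemble(fx$X, fx$y, part, seed = 1)
  # permute the contents of the other subsets, leaving pair (1, 1) untouched
  part_b <- part
  part_b$pos_subsets[[2]] <- rev(part$pos_subsets[[2]])
  swap <- part$neg_subsets[[2]][1]
  part_b$neg_subsets[[2]][1] <- part$neg_subsets[[3]][1]
  part_b$neg_subsets[[3]][1] <- swap
  model_b <- train_ensemble(fx$X, fx$y, part_b, seed = 1)
  k11 <- which(vapply(model_a$members, function(m) m$i == 1 && m$j == 1, logical(1)))
  expect_identical(
    predict_votes(model_a, fx$X)[, k11],
    predict_votes(model_b, fx$X)[, k11]
  )
})

test_that("combine_votes applies the at-least-TH rule", {
  expect_identical(combine_votes(matrix(1, 1, 10), 10), 1L)
  row5 <- matrix(c(rep(1, 5), rep(0, 5)), 1, 10)
  expect_identical(combine_votes(row5, 5), 1L)
  expect_identical(combine_votes(row5, 6), 0L)
  expect_error(combine_votes(row5, 0), "TH")
  expect_error(combine_votes(row5, 11), "TH")
})

test_that("combine_votes matches exhaustive enumeration for K = 10", {
  rows <- as.matrix(expand.grid(rep(list(0:1), 10)))
  colnames(rows) <- NULL
  for (TH in 1:10) {
    got <- combine_votes(rows, TH)
    want <- as.integer(apply(rows, 1, function(r) sum(r) >= TH))
    expect_identical(got, want)
  }
})

test_that("positive sets are nested and rates monotone across the sweep", {
  set.seed(37)
  for (rep_i in 1:5) {
    votes <- matrix(rbinom(200 * 10, 1, runif(1, 0.2, 0.8)), 200, 10)
    labels <- rbinom(200, 1, 0.3)
    prev <- rep(1L, 200)
    for (TH in 1:10) {
      cur <- combine_votes(votes, TH)
      expect_true(all(cur <= prev))
      prev <- cur
    }
    sw <- threshold_sweep(votes, labels)
    expect_true(all(diff(sw$sen) <= 1e-12))
    expect_true(all(diff(sw$spec) >= -1e-12))
    # TH = 1 calls the most positives
    npos <- vapply(1:10, function(th) sum(combine_votes(votes, th)), numeric(1))
    expect_identical(which.max(npos), 1L)
  }
})

test_that("the sweep is self-consistent with its stored vote matrix", {
  fx <- separable_fixture()
  part <- partition_by_dasa(fx$dasa, fx$y, M = 2, N = 2, seed = 1)
  model <- train_ensemble(fx$X, fx$y, part, seed = 1)
  votes <- predict_votes(model, fx$X)
  sw <- threshold_sweep(votes, fx$y)
  for (th in sw$TH) {
    cm <- confusion(combine_votes(votes, th), fx$y)
    m <- metrics(cm)
    expect_equal(sw$mcc[sw$TH == th], m$mcc, tolerance = 1e-12)
    expect_equal(sw$f1[sw$TH == th], m$f1, tolerance = 1e-12)
  }
  expect_true(sw$best_mcc[which.max(sw$mcc)])
  expect_true(sw$best_f1[which.max(sw$f1)])
})

test_that("decision values are stored only on request", {
  fx <- separable_fixture()
  part <- partition_by_dasa(fx$dasa, fx$y, M = 1, N = 2, seed = 1)
  m0 <- train_ensemble(fx$X, fx$y, part, seed = 1)
  expect_null(attr(predict_votes(m0, fx$X), "decision_values"))
  m1 <- train_ensemble(fx$X, fx$y, part,
                       config = svm_config(store_decision_values = TRUE), seed = 1)
  dv <- attr(predict_votes(m1, fx$X), "decision_values")
  expect_identical(dim(dv), dim(predict_votes(m1, fx$X)))
})
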