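two_blob_data <- function(n_per = 30, d = 3, sep = 8, seed = 17) {
  withr::with_seed(seed, {
    rbind(
      matrix(rnorm(n_per * d), ncol = d),
      matrix(rnorm(n_per * d, mean = sep), ncol = d)
    )
  })
}

test_that("SOM training is seeded, bounded, and steps = 0 returns the init", {
  X <- two_blob_data()
  g1 <- train_som(X, N = 2, steps = 20, seed = 4)
  g2 <- train_som(X, N = 2, steps = 20, seed = 4)
  expect_identical(g1$weights, g2$weights)
  # weights stay within the data bounding box
  for (j in seq_len(ncol(X))) {
    expect_true(all(g1$weights[, j] >= min(X[, j]) - 1e-9))
    expect_true(all(g1$weights[, j] <= max(X[, j]) + 1e-9))
  }
  g0 <- train_som(X, N = 2, steps = 0, seed = 4)
  # untrained weights are sampled data points
  expect_true(all(apply(g0$weights, 1, function(w) {
    any(apply(X, 1, function(x) isTRUE(all.equal(x, w))))
  })))
  expect_error(train_som(X[1:3, ], N = 2), "N\\^2")
})

test_that("well-separated blobs occupy disjoint neuron sets", {
  X <- two_blob_data()
  g <- train_som(X, N = 2, steps = 20, seed = 4)
  asg <- assign_clusters(g, X)
  blob <- rep(1:2, each = 30)
  neurons1 <- unique(asg$hard[blob == 1])
  neurons2 <- unique(asg$hard[blob == 2])
  expect_length(intersect(neurons1, neurons2), 0)
})

test_that("cluster assignment is nearest-weight with row-stochastic memberships", {
  X <- two_blob_data()
  g <- train_som(X, N = 2, steps = 10, seed = 4)
  asg <- assign_clusters(g, X)
  expect_equal(unname(rowSums(asg$U)), rep(1, nrow(X)), tolerance = 1e-12)
  expect_identical(asg$hard, max.col(asg$U, ties.method = "first"))
  # a sample equal to a weight vector maps to a zero-distance neuron
  asg_w <- assign_clusters(g, g$weights)
  # near-duplicate neurons may tie; the mapped neuron must coincide with
  # the sample up to numerical noise
  expect_equal(g$weights[asg_w$hard, ], g$weights, tolerance = 1e-6)
  expect_error(assign_clusters(g, X[, 1:2]), "dimension")
})

test_that("a hand-built two-neuron grid orders soft memberships by distance", {
  g <- structure(
    list(N = 1L, R = 2L, weights = matrix(c(0, 1), 2, 1),
         grid = cbind(x = c(1, 2), y = c(0, 0)), steps = 0L, seed = 1L),
    class = "som_grid"
  )
  asg <- assign_clusters(g, matrix(0.25, 1, 1))
  expect_identical(asg$hard, 1L)
  expect_gt(asg$U[1, 1], asg$U[1, 2])
})

test_that("the entropy index matches its bounds and the hand example", {
  mk <- function(U, hard) {
    structure(list(U = U, hard = hard,
                   counts = tabulate(hard, ncol(U)), tau = 1),
              class = "cluster_assignment")
  }
  crisp <- mk(diag(3), 1:3)
  expect_equal(entropy_index(crisp)$E, 0)
  unif <- mk(matrix(1 / 4, 5, 4), rep(1L, 5))
  expect_equal(entropy_index(unif)$E, log(4), tolerance = 1e-12)
  hand <- mk(rbind(c(0.5, 0.5), c(1, 0)), c(1L, 1L))
  expect_equal(entropy_index(hand)$E, log(2) / 2, tolerance = 1e-12)
  expect_equal(entropy_index(hand, base = 2)$E, 0.5, tolerance = 1e-12)
  # permutation invariance over neuron relabeling
  set.seed(5)
  U <- matrix(rexp(40), 10, 4)
  U <- U / rowSums(U)
  hard <- max.col(U)
  perm <- sample(4)
  expect_equal(entropy_index(mk(U, hard))$E,
               entropy_index(mk(U[, perm], order(perm)[hard]))$E,
               tolerance = 1e-12)
})

test_that("sharpening memberships never increases the entropy index", {
  set.seed(6)
  U <- matrix(rexp(60), 15, 4)
  U <- U / rowSums(U)
  hard <- max.col(U)
  mk <- function(U) structure(list(U = U, hard = max.col(U),
                                   counts = tabulate(max.col(U), ncol(U)), tau = 1),
                              class = "cluster_assignment")
  e_prev <- entropy_index(mk(U))$E
  for (t in c(0.25, 0.5, 0.75, 1)) {
    onehot <- matrix(0, nrow(U), ncol(U))
    onehot[cbind(seq_len(nrow(U)), hard)] <- 1
    Us <- (1 - t) * U + t * onehot
    e_now <- entropy_index(mk(Us))$E
    expect_lte(e_now, e_prev + 1e-12)
    e_prev <- e_now
  }
})

test_that("cluster selection prunes small and high-entropy neurons", {
  X <- two_blob_data()
  g <- train_som(X, N = 2, steps = 20, seed = 4)
  asg <- assign_clusters(g, X)

  # identity filter keeps everything
  sel_id <- select_clusters(g, asg, min_count = 0, entropy_rule = Inf)
  expect_setequal(sel_id$retained, seq_len(g$R))
  expect_length(sel_id$removed_small, 0)
  expect_length(sel_id$removed_entropy, 0)
  expect_true(all(filter_by_clusters(sel_id, asg)))

  # retained/removed sets partition the neurons; counts are consistent
  sel <- select_clusters(g, asg, min_count = 2, entropy_rule = "median")
  expect_setequal(
    c(sel$retained, sel$removed_small, sel$removed_entropy), seq_len(g$R)
  )
  keep <- filter_by_clusters(sel, asg)
  expect_equal(sum(keep), sum(asg$counts[sel$retained]))

  expect_error(select_clusters(g, asg, min_count = nrow(X) + 1), "relax")
})

test_that("a lone sample's neuron is removed as small and an injected noise cloud by entropy", {
  X <- two_blob_data(n_per = 40, d = 2, sep = 10, seed = 23)
  # an overlapping noise cloud spanning both blobs
  noise <- withr::with_seed(29, matrix(runif(40, -2, 12), ncol = 2))
  Xn <- rbind(X, noise)
  g <- train_som(Xn, N = 2, steps = 20, seed = 8)
  asg <- assign_clusters(g, Xn)
  ent <- entropy_index(asg)
  sel <- select_clusters(g, asg, min_count = 0, entropy_rule = "median")
  noisiest <- which.max(ent$per_neuron)
  expect_true(noisiest %in% sel$removed_entropy)

  # a neuron holding a single sample falls to min_count = 2
  lone <- which(asg$counts == min(asg$counts))
  sel2 <- select_clusters(g, asg, min_count = min(asg$counts) + 1,
                          entropy_rule = Inf)
  expect_true(all(lone %in% sel2$removed_small))

  rep <- cluster_report(sel)
  expect_identical(nrow(rep), g$R)
  expect_setequal(unique(rep$status),
                  intersect(c("retained", "removed_small", "removed_entropy"),
                            rep$status))
})
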