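# Modified self-organizing map stage: an N x N hexagonal Kohonen map is
# trained on the feature vectors, then low-population neurons and neurons
# with large cluster entropy are pruned; only samples in retained clusters
# flow on to the classifiers.

hex_grid_coords <- function(N) {
  row <- rep(seq_len(N), each = N)
  col <- rep(seq_len(N), times = N)
  cbind(
    x = col + 0.5 * ((row - 1) %% 2),
    y = (row - 1) * sqrt(3) / 2
  )
}

#' Train a hexagonal self-organizing map
#'
#' Online Kohonen training on an `N x N` hexagonal grid: per epoch every
#' sample (in seeded random order) pulls its best-matching unit and, with a
#' Gaussian neighborhood over grid distance, that unit's neighbours, toward
#' itself. Learning rate and neighborhood radius both decay linearly over the
#' epochs. Weights are initialized by seeded sampling of training points, so
#' `steps = 0` returns the initialization and all training is deterministic
#' under the seed.
#'
#' @param features Numeric matrix, one row per sample.
#' @param N Grid side length; the map has `N^2` neurons.
#' @param steps Number of training epochs (default 20).
#' @param seed Integer seed.
#' @param alpha Length-2 numeric: initial and final learning rate.
#' @param radius Length-2 numeric or `NULL`: initial and final neighborhood
#'   radius (grid units). Default spans from half the grid diagonal to 0.5.
#' @return An object of class `som_grid` with the `N^2 x L` weight matrix.
#' @export
train_som <- function(features, N, steps = 20, seed = 1,
                      alpha = c(0.5, 0.01), radius = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != floor(N)) {
    abort("`N` must be a positive integer grid side.")
  }
  R <- as.integer(N) * as.integer(N)
  if (n < R) {
    abort(sprintf("Map has %d neurons but only %d samples; need n >= N^2.", R, n))
  }
  if (steps < 0 || steps != floor(steps)) abort("`steps` must be a non-negative integer.")
  grid <- hex_grid_coords(N)
  grid_d2 <- as.matrix(stats::dist(grid))^2
  if (is.null(radius)) radius <- c(max(sqrt(grid_d2)) / 2, 0.5)

  W <- withr::with_seed(derive_seed(seed, 41L), {
    W <- features[sample(n, R), , drop = FALSE]
    for (t in seq_len(steps)) {
      frac <- if (steps == 1L) 0 else (t - 1) / (steps - 1)
      a_t <- alpha[1] + (alpha[2] - alpha[1]) * frac
      r_t <- radius[1] + (radius[2] - radius[1]) * frac
      for (i in sample(n)) {
        x <- features[i, ]
        d2 <- rowSums(sweep(W, 2, x)^2)
        bmu <- which.min(d2)
        h <- exp(-grid_d2[, bmu] / (2 * r_t^2))
        # move each neuron toward x, scaled by learning rate and neighborhood
        W <- W + (a_t * h) * (rep(x, each = R) - W)
      }
    }
    W
  })
  dimnames(W) <- NULL
  structure(
    list(
      N = as.integer(N), R = R, weights = W, grid = grid,
      steps = as.integer(steps), seed = as.integer(seed),
      alpha = alpha, radius = radius
    ),
    class = "som_grid"
  )
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf(
    "<som_grid> %d x %d hexagonal map, %d features, trained %d steps\n",
    x$N, x$N, ncol(x$weights), x$steps
  ))
  invisible(x)
}

squared_distances <- function(X, W) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(W))) - 2 * X %*% t(W) +
    outer(rep(1, nrow(X)), rowSums(W^2))
  d2[d2 < 0] <- 0
  d2
}

#' Assign samples to map clusters
#'
#' Hard assignment is to the nearest (Euclidean) weight vector. Soft
#' memberships are Gaussian in the squared distance,
#' `U[n, r] proportional to exp(-d2(n, r) / (2 tau^2))`, normalized so each
#' sample's memberships sum to 1, with bandwidth `tau` set to the median
#' nearest-neighbour distance among the weight vectors (crisp one-hot
#' memberships if that distance degenerates to 0).
#'
#' @param grid A [train_som()] result.
#' @param features Numeric matrix with the grid's feature dimension.
#' @return An object of class `cluster_assignment`: `U` (`n x R` row-stochastic
#'   membership matrix), `hard` (best-matching neuron per sample), `counts`
#'   (samples per neuron), and `tau`.
#' @export
assign_clusters <- function(grid, features) {
  stopifnot(inherits(grid, "som_grid"))
  features <- as.matrix(features)
  if (nrow(features) == 0L) abort("No samples to assign.")
  if (ncol(features) != ncol(grid$weights)) {
    abort(sprintf(
      "Feature dimension %d does not match the map's %d.",
      ncol(features), ncol(grid$weights)
    ))
  }
  d2 <- squared_distances(features, grid$weights)
  hard <- max.col(-d2, ties.method = "first")
  dw <- as.matrix(stats::dist(grid$weights))
  diag(dw) <- Inf
  tau <- median(apply(dw, 1, min))
  if (!is.finite(tau) || tau <= .Machine$double.eps) {
    U <- matrix(0, nrow(d2), ncol(d2))
    U[cbind(seq_len(nrow(d2)), hard)] <- 1
  } else {
    logu <- -d2 / (2 * tau^2)
    logu <- logu - apply(logu, 1, max)
    U <- exp(logu)
    U <- U / rowSums(U)
  }
  structure(
    list(
      U = U, hard = hard,
      counts = tabulate(hard, nbins = grid$R), tau = tau
    ),
    class = "cluster_assignment"
  )
}

#' Cluster-entropy validation index
#'
#' The entropy of the soft memberships, averaged over samples:
#' `E = -(1/n) * sum_n sum_r U[n, r] * log(U[n, r])` with `0 log 0 = 0`.
#' `E` is 0 for crisp assignments (perfectly distinct clusters) and `log(R)`
#' for uniform memberships (no clustering structure). The per-neuron values
#' average each neuron's hard-assigned samples' entropies (NA for empty
#' neurons).
#'
#' @param assignment An [assign_clusters()] result.
#' @param base Logarithm base (default `exp(1)`, natural log).
#' @return List with overall index `E` and numeric `per_neuron`.
#' @export
entropy_index <- function(assignment, base = exp(1)) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  U <- assignment$U
  if (nrow(U) == 0L) abort("Empty assignment.")
  H <- -rowSums(ifelse(U > 0, U * log(U, base = base), 0))
  R <- ncol(U)
  per_neuron <- vapply(seq_len(R), function(r) {
    idx <- assignment$hard == r
    if (!any(idx)) NA_real_ else mean(H[idx])
  }, numeric(1))
  list(E = mean(H), per_neuron = per_neuron)
}

#' Prune map clusters by population and entropy
#'
#' Applies the two modifications of the SOM stage: neurons holding fewer than
#' `min_count` samples are removed as unimportant, and among the remainder the
#' neurons with relatively large cluster entropy are removed as insufficiently
#' distinct. With `min_count = 0` and `entropy_rule = Inf` the filter is the
#' identity.
#'
#' @param grid A [train_som()] result.
#' @param assignment Matching [assign_clusters()] result.
#' @param min_count Minimum samples a neuron must hold; default
#'   `max(2, ceiling(0.01 * n / R))`.
#' @param entropy_rule `"median"` (remove neurons whose per-neuron entropy
#'   exceeds the median over surviving neurons) or a numeric cutoff
#'   (`Inf` disables entropy pruning).
#' @param base Logarithm base for the entropy.
#' @return An object of class `cluster_selection` with `retained`,
#'   `removed_small`, `removed_entropy` neuron index sets, `index_values`
#'   (per-neuron entropies), and the overall index `E`.
#' @export
select_clusters <- function(grid, assignment, min_count = NULL,
                            entropy_rule = "median", base = exp(1)) {
  stopifnot(inherits(grid, "som_grid"), inherits(assignment, "cluster_assignment"))
  R <- grid$R
  counts <- assignment$counts
  n <- sum(counts)
  if (is.null(min_count)) min_count <- max(2, ceiling(0.01 * n / R))
  ent <- entropy_index(assignment, base = base)
  removed_small <- which(counts < min_count)
  remaining <- setdiff(seq_len(R), removed_small)
  if (identical(entropy_rule, "median")) {
    vals <- ent$per_neuron[remaining]
    cutoff <- if (all(is.na(vals))) Inf else median(vals, na.rm = TRUE)
  } else if (is.numeric(entropy_rule) && length(entropy_rule) == 1L) {
    cutoff <- entropy_rule
  } else {
    abort("`entropy_rule` must be \"median\" or a single numeric cutoff.")
  }
  ev <- ent$per_neuron[remaining]
  removed_entropy <- remaining[!is.na(ev) & ev > cutoff]
  retained <- setdiff(remaining, removed_entropy)
  if (length(retained) == 0L || sum(counts[retained]) == 0L) {
    abort(sprintf(
      paste0(
        "Cluster selection removed every sample ",
        "(min_count = %s, entropy cutoff = %s); relax the rules."
      ),
      format(min_count), format(cutoff)
    ))
  }
  structure(
    list(
      retained = retained, removed_small = removed_small,
      removed_entropy = removed_entropy,
      index_values = ent$per_neuron, E = ent$E,
      min_count = min_count, cutoff = cutoff, counts = counts
    ),
    class = "cluster_selection"
  )
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat(sprintf(
    "<cluster_selection> %d retained, %d removed (small), %d removed (entropy); E = %.4f\n",
    length(x$retained), length(x$removed_small), length(x$removed_entropy), x$E
  ))
  invisible(x)
}

#' Which samples survive a cluster selection?
#'
#' @param selection A [select_clusters()] result.
#' @param assignment The [assign_clusters()] result for the samples to gate
#'   (training or test samples assigned on the same grid).
#' @return Logical vector: `TRUE` for samples in retained clusters.
#' @export
filter_by_clusters <- function(selection, assignment) {
  stopifnot(inherits(selection, "cluster_selection"),
            inherits(assignment, "cluster_assignment"))
  assignment$hard %in% selection$retained
}

#' Tidy per-neuron cluster report
#'
#' @param selection A [select_clusters()] result.
#' @return Tibble `neuron, count, entropy, status`.
#' @export
cluster_report <- function(selection) {
  stopifnot(inherits(selection, "cluster_selection"))
  R <- length(selection$index_values)
  status <- rep("retained", R)
  status[selection$removed_small] <- "removed_small"
  status[selection$removed_entropy] <- "removed_entropy"
  tibble::tibble(
    neuron = seq_len(R),
    count = selection$counts,
    entropy = selection$index_values,
    status = status
  )
}
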