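#' SVM member configuration
#'
#' Hyperparameters shared by every ensemble member. The defaults are a radial
#' basis kernel with `cost = 1` and `gamma = 1 / L` (set at training time when
#' `gamma` is `NULL`), with per-member feature standardization fitted on that
#' member's own training subset.
#'
#' @param kernel Kernel name passed to [e1071::svm()] (default `"radial"`).
#' @param cost Soft-margin cost `C` (default 1).
#' @param gamma RBF width, or `NULL` for `1 / feature dimension`.
#' @param store_decision_values Keep raw decision values alongside the binary
#'   votes, for diagnostics only (default `FALSE`).
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(kernel = "radial", cost = 1, gamma = NULL,
                       store_decision_values = FALSE) {
  if (!is.null(gamma)) assert_scalar_number(gamma, "gamma")
  assert_scalar_number(cost, "cost")
  structure(
    list(
      kernel = kernel, cost = cost, gamma = gamma,
      store_decision_values = isTRUE(store_decision_values)
    ),
    class = "svm_config"
  )
}

fit_scaler <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(center = mu, scale = sdv)
}

apply_scaler <- function(scaler, x) {
  scale(x, center = scaler$center, scale = scaler$scale)
}

#' Train a balanced SVM ensemble
#'
#' Fits one binary SVM per (positive-subset, negative-subset) pair of the
#' partition: member `(i, j)` sees only positive subset `i` and negative
#' subset `j`, so the `M x N` members train on non-overlapping, roughly
#' balanced data despite the global class imbalance. Features are
#' standardized per member on that member's training rows.
#'
#' @param features Numeric matrix, one row per sample.
#' @param labels Binary 0/1 vector, one per sample.
#' @param partition A [partition_by_dasa()] or [partition_random()] result
#'   indexing rows of `features`.
#' @param config An [svm_config()].
#' @param seed Integer seed (SVM fitting itself is deterministic; the seed is
#'   recorded and used for any stochastic kernel extensions).
#' @return An object of class `svm_ensemble_model` with `K = M x N` members.
#' @export
train_ensemble <- function(features, labels, partition,
                           config = svm_config(), seed = 1) {
  stopifnot(inherits(partition, "training_partition"), inherits(config, "svm_config"))
  features <- as.matrix(features)
  if (nrow(features) != length(labels)) {
    abort("`features` and `labels` must agree in length.")
  }
  gamma <- config$gamma %||% (1 / ncol(features))
  members <- list()
  k <- 0L
  for (i in seq_len(partition$M)) {
    for (j in seq_len(partition$N)) {
      idx <- c(partition$pos_subsets[[i]], partition$neg_subsets[[j]])
      y <- labels[idx]
      if (!any(y == 1L) || !any(y == 0L)) {
        abort(sprintf("Member (%d, %d) has an empty class.", i, j))
      }
      x <- features[idx, , drop = FALSE]
      scaler <- fit_scaler(x)
      fit <- withr::with_seed(derive_seed(seed, 50L, i, j), {
        e1071::svm(
          x = apply_scaler(scaler, x),
          y = factor(y, levels = c(0L, 1L)),
          kernel = config$kernel, cost = config$cost, gamma = gamma,
          scale = FALSE
        )
      })
      k <- k + 1L
      members[[k]] <- list(i = i, j = j, scaler = scaler, fit = fit)
    }
  }
  structure(
    list(
      members = members, K = k,
      M = partition$M, N = partition$N,
      feature_dim = ncol(features),
      strategy = partition$strategy,
      config = config, gamma = gamma, seed = as.integer(seed)
    ),
    class = "svm_ensemble_model"
  )
}

#' @export
print.svm_ensemble_model <- function(x, ...) {
  cat(sprintf(
    "<svm_ensemble_model> %d members (%d pos x %d neg subsets, %s), %d features, %s kernel\n",
    x$K, x$M, x$N, x$strategy, x$feature_dim, x$config$kernel
  ))
  invisible(x)
}

#' Per-member binary votes
#'
#' Runs every ensemble member on the feature rows and collects its hard 0/1
#' output. Inference is deterministic given the trained model.
#'
#' @param model A [train_ensemble()] result.
#' @param features Numeric matrix with the model's feature dimension.
#' @return Integer `n x K` matrix of votes; if
#'   `config$store_decision_values` was set, the numeric decision values are
#'   attached as attribute `"decision_values"`.
#' @export
predict_votes <- function(model, features) {
  stopifnot(inherits(model, "svm_ensemble_model"))
  features <- as.matrix(features)
  if (ncol(features) != model$feature_dim) {
    abort(sprintf(
      "Feature dimension %d does not match the model's %d.",
      ncol(features), model$feature_dim
    ))
  }
  n <- nrow(features)
  votes <- matrix(0L, nrow = n, ncol = model$K)
  dec <- if (model$config$store_decision_values) votes * 0 else NULL
  if (n > 0L) {
    for (k in seq_len(model$K)) {
      m <- model$members[[k]]
      xs <- apply_scaler(m$scaler, features)
      pred <- stats::predict(
        m$fit, xs,
        decision.values = model$config$store_decision_values
      )
      votes[, k] <- as.integer(as.character(pred))
      if (!is.null(dec)) dec[, k] <- as.numeric(attr(pred, "decision.values"))
    }
  }
  if (!is.null(dec)) attr(votes, "decision_values") <- dec
  votes
}

#' Combine member votes at a threshold
#'
#' A residue is called an interface residue when at least `TH` of the `K`
#' member outputs are positive.
#'
#' @param votes Integer/binary `n x K` vote matrix.
#' @param TH Integer threshold in `1..K`.
#' @return Integer 0/1 vector of length `n`.
#' @export
combine_votes <- function(votes, TH) {
  votes <- as.matrix(votes)
  if (!all(votes %in% c(0L, 1L))) abort("`votes` must be a binary matrix.")
  K <- ncol(votes)
  if (!is.numeric(TH) || length(TH) != 1L || TH < 1 || TH > K || TH != floor(TH)) {
    abort(sprintf("`TH` must be an integer in 1..%d.", K))
  }
  as.integer(rowSums(votes) >= TH)
}

#' Metrics across all vote thresholds
#'
#' Evaluates the combined prediction at every threshold `TH` in `1..K`
#' against the true labels and marks the rows attaining the largest MCC and
#' the largest F-measure.
#'
#' @param votes Binary `n x K` vote matrix.
#' @param labels Binary truth vector of length `n`.
#' @return Tibble with one row per `TH`: confusion counts, the six measures,
#'   and logical columns `best_mcc`, `best_f1`.
#' @export
threshold_sweep <- function(votes, labels) {
  votes <- as.matrix(votes)
  if (nrow(votes) != length(labels)) {
    abort("`votes` and `labels` must agree in length.")
  }
  K <- ncol(votes)
  rows <- lapply(seq_len(K), function(th) {
    cm <- confusion(combine_votes(votes, th), labels)
    dplyr::bind_cols(
      tibble::tibble(TH = th, TP = cm$tp, FP = cm$fp, TN = cm$tn, FN = cm$fn),
      metrics(cm)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$best_mcc <- out$mcc == max(out$mcc)
  out$best_f1 <- out$f1 == max(out$f1)
  out
}
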