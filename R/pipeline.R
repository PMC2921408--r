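#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end pipeline with the method's
#' defaults: window length 19, integrative encoding, a 2 x 5 ensemble (ten
#' SVMs) on delta-ASA-ordered subsets, no SOM gate, 20 SOM training steps
#' when a map is used, a full threshold sweep, and 5-fold chain-level
#' cross-validation.
#'
#' @param L Odd sliding-window length (default 19).
#' @param mode Encoding mode: `"integrative"`, `"profile_only"`, or
#'   `"hydropathy_only"`.
#' @param M,N Positive/negative subset counts (defaults 2 and 5).
#' @param strategy Partitioning strategy, `"dasa_ordered"` or `"random"`.
#' @param som SOM gate: `"none"` or an integer grid side (3, 5, 7, ...).
#' @param som_steps SOM training epochs (default 20).
#' @param min_count SOM population pruning threshold, or `NULL` for the
#'   default `max(2, ceiling(0.01 * n / R))`.
#' @param entropy_rule SOM entropy pruning rule: `"median"` or a numeric
#'   cutoff (`Inf` disables).
#' @param svm An [svm_config()].
#' @param k Cross-validation folds (default 5).
#' @param profile_scale `"fraction"` or `"percent"` profile units.
#' @param sigma_divisor Window variance divisor, `"unbiased"` or `"n"`.
#' @param seed Integer master seed; all stage seeds derive from it.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(L = 19, mode = "integrative", M = 2, N = 5,
                       strategy = c("dasa_ordered", "random"),
                       som = "none", som_steps = 20,
                       min_count = NULL, entropy_rule = "median",
                       svm = svm_config(), k = 5,
                       profile_scale = c("fraction", "percent"),
                       sigma_divisor = c("unbiased", "n"),
                       seed = 1) {
  L <- assert_odd_window(L)
  mode <- check_mode(mode)
  strategy <- match.arg(strategy)
  profile_scale <- match.arg(profile_scale)
  sigma_divisor <- match.arg(sigma_divisor)
  if (!identical(som, "none")) {
    if (!is.numeric(som) || length(som) != 1L || som < 1 || som != floor(som)) {
      abort("`som` must be \"none\" or a positive integer grid side.")
    }
    som <- as.integer(som)
  }
  if (M < 1 || N < 1) abort("`M` and `N` must be >= 1.")
  if (k < 2) abort("`k` must be >= 2.")
  stopifnot(inherits(svm, "svm_config"))
  structure(
    list(
      L = L, mode = mode, M = as.integer(M), N = as.integer(N),
      strategy = strategy, som = som, som_steps = as.integer(som_steps),
      min_count = min_count, entropy_rule = entropy_rule,
      svm = svm, k = as.integer(k),
      profile_scale = profile_scale, sigma_divisor = sigma_divisor,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> L=%d mode=%s M=%d N=%d strategy=%s som=%s k=%d seed=%d\n",
    x$L, x$mode, x$M, x$N, x$strategy, as.character(x$som), x$k, x$seed
  ))
  invisible(x)
}

config_manifest <- function(config) {
  cfg <- unclass(config)
  cfg$svm <- unclass(cfg$svm)
  cfg$min_count <- cfg$min_count %||% "auto"
  cfg$entropy_rule <- as.character(cfg$entropy_rule)
  cfg$som <- as.character(cfg$som)
  cfg
}

#' Run chain-level cross-validation of the full pipeline
#'
#' For each fold: encode all chains with the configured window and mode,
#' train on the out-of-fold chains (optionally gating samples through the
#' SOM cluster filter), partition the training residues into balanced
#' subsets, fit the SVM ensemble, and collect member votes on the held-out
#' chains. Votes pooled over folds give the headline threshold sweep;
#' per-fold sweeps and slot-wise individual-member metrics are also
#' returned. Everything is deterministic under the config seed and is
#' recorded in a run manifest.
#'
#' @param chains Named list of [chain_profile()] objects.
#' @param labels Tibble `chain_id, position, aa, delta_asa, label` covering
#'   exactly the residues of `chains`.
#' @param config A [run_config()].
#' @return An object of class `cv_report`: `pooled` (threshold sweep on
#'   pooled votes), `member` (per-member pooled metrics), `folds` (per-fold
#'   sweeps), `votes`, `meta`, `truth`, `cluster_reports`, and `manifest`.
#' @export
run_cross_validation <- function(chains, labels, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(names(chains)) || anyDuplicated(names(chains))) {
    abort("`chains` must be a uniquely named list of chain_profile objects.")
  }
  if (!setequal(names(chains), unique(labels$chain_id))) {
    abort("Chain ids in `chains` and `labels` do not match.")
  }
  coeffs <- gaussian_coefficients(config$L, divisor = config$sigma_divisor)
  features <- encode_chains(
    chains, coeffs,
    mode = config$mode, profile_scale = config$profile_scale
  )
  merged <- dplyr::inner_join(
    features, labels[, c("chain_id", "position", "delta_asa", "label")],
    by = c("chain_id", "position")
  )
  if (nrow(merged) != nrow(features)) {
    abort("`labels` must cover every residue of every chain.")
  }
  X <- feature_matrix(merged)
  folds <- make_cv_folds(names(chains), k = config$k,
                         seed = derive_seed(config$seed, 101L))
  fold_of <- stats::setNames(folds$fold, folds$chain_id)

  pooled_votes <- NULL
  pooled_truth <- integer(0)
  pooled_meta <- list()
  fold_sweeps <- vector("list", config$k)
  cluster_reports <- vector("list", config$k)

  for (f in seq_len(config$k)) {
    in_test <- fold_of[merged$chain_id] == f
    tr_idx <- which(!in_test)
    te_idx <- which(in_test)
    Xtr <- X[tr_idx, , drop = FALSE]
    ytr <- merged$label[tr_idx]
    dtr <- merged$delta_asa[tr_idx]
    Xte <- X[te_idx, , drop = FALSE]
    yte <- merged$label[te_idx]
    keep_te <- rep(TRUE, length(te_idx))

    if (!identical(config$som, "none")) {
      grid <- train_som(Xtr, N = config$som, steps = config$som_steps,
                        seed = derive_seed(config$seed, 200L, f))
      asg_tr <- assign_clusters(grid, Xtr)
      sel <- select_clusters(grid, asg_tr, min_count = config$min_count,
                             entropy_rule = config$entropy_rule)
      cluster_reports[[f]] <- cluster_report(sel)
      keep_tr <- filter_by_clusters(sel, asg_tr)
      asg_te <- assign_clusters(grid, Xte)
      keep_te <- filter_by_clusters(sel, asg_te)
      Xtr <- Xtr[keep_tr, , drop = FALSE]
      ytr <- ytr[keep_tr]
      dtr <- dtr[keep_tr]
      Xte <- Xte[keep_te, , drop = FALSE]
      yte <- yte[keep_te]
      te_idx <- te_idx[keep_te]
      if (!any(ytr == 1L) || !any(ytr == 0L)) {
        abort(sprintf("Fold %d: SOM filtering removed an entire class.", f))
      }
    }

    part_seed <- derive_seed(config$seed, 300L, f)
    partition <- if (config$strategy == "dasa_ordered") {
      partition_by_dasa(dtr, ytr, M = config$M, N = config$N, seed = part_seed)
    } else {
      partition_random(dtr, ytr, M = config$M, N = config$N, seed = part_seed)
    }
    model <- train_ensemble(Xtr, ytr, partition, config = config$svm,
                            seed = derive_seed(config$seed, 400L, f))
    votes <- predict_votes(model, Xte)
    fold_sweeps[[f]] <- if (length(yte) > 0L && length(unique(yte)) > 0L) {
      threshold_sweep(votes, yte)
    } else {
      NULL
    }
    pooled_votes <- rbind(pooled_votes, votes)
    pooled_truth <- c(pooled_truth, yte)
    pooled_meta[[f]] <- merged[te_idx, c("chain_id", "position", "aa")]
  }

  meta <- dplyr::bind_rows(pooled_meta)
  pooled <- threshold_sweep(pooled_votes, pooled_truth)
  K <- ncol(pooled_votes)
  member <- dplyr::bind_rows(lapply(seq_len(K), function(kk) {
    dplyr::bind_cols(
      tibble::tibble(
        member = kk,
        pos_subset = ((kk - 1L) %/% config$N) + 1L,
        neg_subset = ((kk - 1L) %% config$N) + 1L
      ),
      metrics(confusion(pooled_votes[, kk], pooled_truth))
    )
  }))
  manifest <- list(
    package = "ippred",
    version = as.character(utils::packageVersion("ippred")),
    config = config_manifest(config),
    seed = config$seed,
    n_chains = length(chains),
    n_residues = nrow(merged),
    n_scored = length(pooled_truth),
    input_hash = rlang::hash(list(
      lapply(chains, unclass),
      labels[, c("chain_id", "position", "delta_asa", "label")]
    )),
    fold_sizes = as.integer(table(folds$fold))
  )
  structure(
    list(
      pooled = pooled, member = member, folds = fold_sweeps,
      votes = pooled_votes, meta = meta, truth = pooled_truth,
      cluster_reports = cluster_reports, cv_split = folds,
      manifest = manifest
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  best <- x$pooled[which.max(x$pooled$mcc), ]
  bestf <- x$pooled[which.max(x$pooled$f1), ]
  cat(sprintf(
    paste0(
      "<cv_report> %d chains, %d residues scored, %d-member ensemble\n",
      "  best MCC %.4f at TH=%d (Sen %.2f%%, Spec %.2f%%, Acc %.2f%%, Prec %.2f%%, F1 %.2f%%)\n",
      "  best F1  %.2f%% at TH=%d (MCC %.4f)\n"
    ),
    x$manifest$n_chains, x$manifest$n_scored, ncol(x$votes),
    best$mcc, best$TH, 100 * best$sen, 100 * best$spec, 100 * best$acc,
    100 * best$prec, 100 * best$f1,
    100 * bestf$f1, bestf$TH, bestf$mcc
  ))
  invisible(x)
}

#' Align threshold sweeps of several runs
#'
#' Binds the pooled sweeps of named cross-validation reports into one table
#' sharing the threshold grid, with each model's best-MCC and best-F1 rows
#' marked.
#'
#' @param ... Named `cv_report` objects (or one named list of them).
#' @return Tibble with a leading `model` column.
#' @export
compare_models <- function(...) {
  reports <- list(...)
  if (length(reports) == 1L && !inherits(reports[[1L]], "cv_report")) {
    reports <- reports[[1L]]
  }
  if (is.null(names(reports)) || any(!nzchar(names(reports)))) {
    abort("Reports must be named.")
  }
  ths <- lapply(reports, function(r) r$pooled$TH)
  if (length(unique(lapply(ths, identical, ths[[1L]]))) != 1L ||
      !all(vapply(ths, identical, logical(1), ths[[1L]]))) {
    abort("Reports do not share a threshold grid.")
  }
  dplyr::bind_rows(lapply(names(reports), function(nm) {
    dplyr::bind_cols(tibble::tibble(model = nm), reports[[nm]]$pooled)
  }))
}
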