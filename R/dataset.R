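#' Interface label from an accessible-surface-area change
#'
#' A residue is an interface residue when its accessible surface area shrinks
#' by strictly more than 1 square Angstrom upon complex formation
#' (unbound minus bound).
#'
#' @param delta_asa Numeric vector of non-negative ASA changes (A^2).
#' @return Integer vector of 0/1 labels.
#' @export
#' @examples
#' label_interface(c(0, 1, 1.2))  # 0 0 1
label_interface <- function(delta_asa) {
  if (!is.numeric(delta_asa) || any(!is.finite(delta_asa))) {
    abort("`delta_asa` must be finite and numeric.")
  }
  if (any(delta_asa < 0)) abort("`delta_asa` must be non-negative.")
  as.integer(delta_asa > 1.0)
}

validate_partition <- function(part, n_pos, n_neg) {
  pos_all <- sort(unlist(part$pos_subsets))
  neg_all <- sort(unlist(part$neg_subsets))
  if (anyDuplicated(pos_all) || anyDuplicated(neg_all)) {
    abort("Partition subsets overlap.")
  }
  sizes_ok <- function(ss) diff(range(lengths(ss))) <= 1L
  if (!sizes_ok(part$pos_subsets) || !sizes_ok(part$neg_subsets)) {
    abort("Partition subset sizes differ by more than 1.")
  }
  if (length(pos_all) != n_pos || length(neg_all) != n_neg) {
    abort("Partition does not exhaust its class.")
  }
  invisible(part)
}

new_partition <- function(pos_subsets, neg_subsets, strategy, seed, n_pos, n_neg) {
  part <- structure(
    list(
      pos_subsets = pos_subsets, neg_subsets = neg_subsets,
      strategy = strategy, seed = as.integer(seed),
      M = length(pos_subsets), N = length(neg_subsets)
    ),
    class = "training_partition"
  )
  validate_partition(part, n_pos, n_neg)
}

#' @export
print.training_partition <- function(x, ...) {
  cat(sprintf(
    "<training_partition> strategy = %s, %d positive x %d negative subsets (sizes %s | %s)\n",
    x$strategy, x$M, x$N,
    paste(lengths(x$pos_subsets), collapse = ","),
    paste(lengths(x$neg_subsets), collapse = ",")
  ))
  invisible(x)
}

check_partition_input <- function(delta_asa, label, M, N) {
  if (length(delta_asa) != length(label)) {
    abort("`delta_asa` and `label` must have equal length.")
  }
  if (!all(label %in% c(0L, 1L))) abort("`label` must be binary 0/1.")
  if (M < 1 || N < 1) abort("Subset counts `M` and `N` must be >= 1.")
  if (!any(label == 1L)) abort("No positive (interface) samples to partition.")
  if (!any(label == 0L)) abort("No negative (non-interface) samples to partition.")
}

#' Partition training samples by ordered delta-ASA
#'
#' Splits the two classes into balanced, non-overlapping subsets in the order
#' of the ASA change. Positives are sorted by increasing delta-ASA and cut
#' into `M` contiguous near-equal blocks, so every delta-ASA in block `m` is
#' at most every delta-ASA in block `m + 1`. Negatives with delta-ASA exactly
#' 0 are shuffled (seeded), the few negatives with delta-ASA in `(0, 1]` are
#' appended in increasing order, and the resulting list is cut into `N`
#' near-equal blocks. Each of the `M x N` subset pairs later trains one
#' balanced ensemble member.
#'
#' @param delta_asa Numeric vector of ASA changes, one per sample.
#' @param label Binary 0/1 vector of the same length.
#' @param M Number of positive subsets (default 2).
#' @param N Number of negative subsets (default 5).
#' @param seed Integer seed for the shuffle of zero-delta-ASA negatives.
#' @return A `training_partition`: lists `pos_subsets` and `neg_subsets` of
#'   sample indices into the input vectors.
#' @export
partition_by_dasa <- function(delta_asa, label, M = 2, N = 5, seed = 1) {
  check_partition_input(delta_asa, label, M, N)
  pos <- which(label == 1L)
  pos <- pos[order(delta_asa[pos])]
  neg_zero <- which(label == 0L & delta_asa == 0)
  neg_rest <- which(label == 0L & delta_asa > 0)
  neg_zero <- withr::with_seed(derive_seed(seed, 11L), sample(neg_zero))
  neg_rest <- neg_rest[order(delta_asa[neg_rest])]
  neg <- c(neg_zero, neg_rest)
  new_partition(
    split_near_equal(pos, M), split_near_equal(neg, N),
    strategy = "dasa_ordered", seed = seed,
    n_pos = length(pos), n_neg = length(neg)
  )
}

#' Partition training samples at random
#'
#' Baseline partitioning: both classes are shuffled with the seed and cut
#' into near-equal non-overlapping blocks, ignoring delta-ASA order.
#'
#' @inheritParams partition_by_dasa
#' @return A `training_partition`.
#' @export
partition_random <- function(delta_asa, label, M = 2, N = 5, seed = 1) {
  check_partition_input(delta_asa, label, M, N)
  pos <- withr::with_seed(derive_seed(seed, 21L), sample(which(label == 1L)))
  neg <- withr::with_seed(derive_seed(seed, 22L), sample(which(label == 0L)))
  new_partition(
    split_near_equal(pos, M), split_near_equal(neg, N),
    strategy = "random", seed = seed,
    n_pos = length(pos), n_neg = length(neg)
  )
}

#' Chain-level cross-validation folds
#'
#' Assigns whole protein chains (never individual residues) to `k` folds of
#' near-equal size, deterministically under the seed.
#'
#' @param chain_ids Character vector of unique chain identifiers.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Tibble with columns `chain_id` and `fold` (1..k).
#' @export
make_cv_folds <- function(chain_ids, k = 5, seed = 1) {
  chain_ids <- as.character(chain_ids)
  if (anyDuplicated(chain_ids)) abort("`chain_ids` must be unique.")
  if (k < 2) abort("`k` must be at least 2.")
  if (length(chain_ids) < k) {
    abort(sprintf("Need at least %d chains for %d folds.", k, k))
  }
  shuffled <- withr::with_seed(derive_seed(seed, 31L), sample(chain_ids))
  blocks <- split_near_equal(shuffled, k)
  tibble::tibble(
    chain_id = unlist(blocks),
    fold = rep(seq_len(k), lengths(blocks))
  ) |>
    dplyr::arrange(match(.data$chain_id, chain_ids))
}
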