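#' Canonical amino-acid ordering
#'
#' All 20-value per-residue vectors in this package (sequence profiles, the
#' hydropathy scale) share one fixed ordering of the standard amino acids.
#' Profile tables on disk use these letters as column names, in this order.
#'
#' @return Character vector of the 20 standard one-letter codes.
#' @export
#' @examples
#' aa_order()
aa_order <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Derive a reproducible sub-seed
#'
#' Folds an arbitrary sequence of small integers into a single 32-bit seed so
#' that every randomized stage of a pipeline draws from its own deterministic
#' stream. Same inputs always give the same seed.
#'
#' @param seed Base integer seed.
#' @param ... Further integer tags (stage id, fold index, ...).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  s <- 0
  for (p in parts) s <- (s * 69069 + p + 1) %% 2147483647
  as.integer(s)
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

assert_odd_window <- function(L) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) ||
      L < 1 || L != floor(L) || (L %% 2) == 0) {
    abort("Window length `L` must be a positive odd integer.")
  }
  invisible(as.integer(L))
}

# near-equal split of a vector of indices into k contiguous blocks;
# earlier blocks take the remainder
split_near_equal <- function(idx, k) {
  n <- length(idx)
  base <- n %/% k
  extra <- n %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) {
    if (sizes[i] == 0L) integer(0) else idx[starts[i]:ends[i]]
  })
}
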