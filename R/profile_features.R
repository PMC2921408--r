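#' Construct a chain profile
#'
#' Bundles one protein chain's identifier, sequence, and per-residue sequence
#' profile (alignment-derived amino-acid frequencies, one 20-value row per
#' residue in the canonical ordering [aa_order()]).
#'
#' @param chain_id Chain identifier string.
#' @param sequence One-letter amino-acid string.
#' @param profile Numeric matrix, `nchar(sequence)` rows by 20 columns, all
#'   entries finite and non-negative. Columns may be named by amino acid; if
#'   so they are reordered canonically.
#' @return An object of class `chain_profile`.
#' @export
chain_profile <- function(chain_id, sequence, profile) {
  if (!is.character(chain_id) || length(chain_id) != 1L || !nzchar(chain_id)) {
    abort("`chain_id` must be a non-empty string.")
  }
  if (!is.character(sequence) || length(sequence) != 1L) {
    abort("`sequence` must be a single string.")
  }
  profile <- as.matrix(profile)
  n <- nchar(sequence)
  if (nrow(profile) != n) {
    abort(sprintf(
      "Profile has %d rows but the sequence has %d residues.",
      nrow(profile), n
    ))
  }
  if (ncol(profile) != 20L) {
    abort("A sequence profile must have 20 columns (one per amino acid).")
  }
  if (!all(is.finite(profile)) || any(profile < 0)) {
    abort("Profile entries must be finite and non-negative.")
  }
  if (!is.null(colnames(profile))) {
    if (!setequal(colnames(profile), aa_order())) {
      abort("Profile column names must be the 20 standard amino acids.")
    }
    profile <- profile[, aa_order(), drop = FALSE]
  } else {
    colnames(profile) <- aa_order()
  }
  structure(
    list(chain_id = chain_id, sequence = sequence, profile = profile),
    class = "chain_profile"
  )
}

#' @export
print.chain_profile <- function(x, ...) {
  cat(sprintf(
    "<chain_profile> %s: %d residues\n  %s%s\n",
    x$chain_id, nchar(x$sequence),
    substr(x$sequence, 1, 60),
    if (nchar(x$sequence) > 60) "..." else ""
  ))
  invisible(x)
}

#' @export
length.chain_profile <- function(x) nchar(x$sequence)

#' Gaussian influence coefficients for a sliding window
#'
#' Residues in a window of odd length `L` influence the central target residue
#' following a normal density centred on the window midpoint
#' `mu = (L + 1) / 2`. The position variance is computed from the window
#' positions themselves: `sigma2 = sum((i - mu)^2) / (L - 1)` by default
#' (unbiased divisor), or with divisor `L`. The coefficients are the normal
#' density evaluated at positions `1..L`; no renormalization to sum 1 is
#' applied.
#'
#' @param L Odd positive window length (residues).
#' @param divisor `"unbiased"` (divide by `L - 1`, the default) or `"n"`
#'   (divide by `L`).
#' @return An object of class `window_coefficients` with fields `L`, `mu`,
#'   `sigma2`, and `p` (length-`L` coefficient vector).
#' @export
#' @examples
#' gaussian_coefficients(19)$mu  # 10
gaussian_coefficients <- function(L, divisor = c("unbiased", "n")) {
  L <- assert_odd_window(L)
  divisor <- match.arg(divisor)
  mu <- (L + 1) / 2
  pos <- seq_len(L)
  ss <- sum((pos - mu)^2)
  sigma2 <- if (L == 1L) 0 else ss / if (divisor == "unbiased") L - 1 else L
  # L = 1 degenerates to a point window: a single unit coefficient
  p <- if (sigma2 == 0) rep(1, L) else dnorm(pos, mean = mu, sd = sqrt(sigma2))
  structure(
    list(L = L, mu = mu, sigma2 = sigma2, p = p, divisor = divisor),
    class = "window_coefficients"
  )
}

#' @export
print.window_coefficients <- function(x, ...) {
  cat(sprintf(
    "<window_coefficients> L = %d, mu = %g, sigma2 = %g (divisor %s)\n",
    x$L, x$mu, x$sigma2, x$divisor
  ))
  invisible(x)
}

#' Integrative standard deviation of a residue
#'
#' The core per-residue statistic: the unbiased sample standard deviation of
#' the elementwise product of a residue's 20-value sequence profile with the
#' hydropathy scale. It measures the spread of the residue's evolutionary
#' frequencies once each amino-acid axis is weighted by its hydrophobicity —
#' the residue's "evolutionary context with respect to hydrophobicity".
#'
#' @param sp Numeric 20-vector of profile frequencies (canonical ordering).
#' @param kd Numeric 20-vector of hydropathy values (same ordering).
#' @return A single non-negative number.
#' @export
#' @examples
#' sp <- c(1, rep(0, 19))
#' integrative_sd(sp, kyte_doolittle())  # 1.8 * sqrt(0.05)
integrative_sd <- function(sp, kd) {
  if (!is.numeric(sp) || length(sp) != 20L || !all(is.finite(sp))) {
    abort("`sp` must be a numeric vector of 20 finite values.")
  }
  if (!is.numeric(kd) || length(kd) != 20L || !all(is.finite(kd))) {
    abort("`kd` must be a numeric vector of 20 finite values.")
  }
  sd(as.numeric(sp) * as.numeric(kd))
}

# per-residue scalar under each encoding mode (length-n vector for a chain)
residue_scalars <- function(chain, kd, mode, profile_scale) {
  sp <- chain$profile
  if (profile_scale == "percent") sp <- sp / 100
  kdv <- unname(kd[aa_order()])
  switch(mode,
    integrative = apply(sweep(sp, 2, kdv, `*`), 1, sd),
    profile_only = apply(sp, 1, sd),
    hydropathy_only = hydropathy_values(chain$sequence, kd),
    abort(sprintf("Unknown encoding mode '%s'.", mode))
  )
}

check_mode <- function(mode) {
  modes <- c("integrative", "profile_only", "hydropathy_only")
  if (!is.character(mode) || length(mode) != 1L || !(mode %in% modes)) {
    abort(sprintf(
      "`mode` must be one of %s.", paste(sprintf("'%s'", modes), collapse = ", ")
    ))
  }
  mode
}

#' Encode one residue as a windowed feature vector
#'
#' Builds the `1 x L` feature vector for a residue: slot `j` holds the
#' integrative standard deviation of the residue at window position `j` (the
#' centre slot `mu` is the target residue itself) multiplied by the Gaussian
#' influence coefficient `p[j]`. Window slots falling outside the chain
#' contribute 0.
#'
#' @param chain A [chain_profile()].
#' @param position 1-based residue index within the chain.
#' @param coeffs A [gaussian_coefficients()] object.
#' @param kd Hydropathy scale; default [kyte_doolittle()].
#' @param mode Encoding mode: `"integrative"` (default), `"profile_only"`
#'   (standard deviation of the sequence profile alone), or
#'   `"hydropathy_only"` (the residue's own hydropathy value).
#' @param profile_scale `"fraction"` if profile entries are frequencies in
#'   `[0, 1]` (default), `"percent"` if they are HSSP-style percentages to be
#'   divided by 100 first.
#' @return List with `chain_id`, `position`, and numeric `v` of length `L`.
#' @export
encode_residue <- function(chain, position, coeffs,
                           kd = kyte_doolittle(),
                           mode = "integrative",
                           profile_scale = c("fraction", "percent")) {
  stopifnot(inherits(chain, "chain_profile"), inherits(coeffs, "window_coefficients"))
  profile_scale <- match.arg(profile_scale)
  mode <- check_mode(mode)
  kd <- check_hydropathy_scale(kd)
  n <- length(chain)
  if (!is.numeric(position) || length(position) != 1L ||
      position < 1 || position > n || position != floor(position)) {
    abort(sprintf("`position` must be an integer in 1..%d.", n))
  }
  s <- residue_scalars(chain, kd, mode, profile_scale)
  v <- window_features(s, coeffs)[position, ]
  list(chain_id = chain$chain_id, position = as.integer(position), v = v)
}

# n x L matrix of windowed features from a per-residue scalar vector,
# zero-padded at the termini
window_features <- function(s, coeffs) {
  n <- length(s)
  L <- coeffs$L
  mu <- coeffs$mu
  spad <- c(rep(0, mu - 1), s, rep(0, L - mu))
  V <- matrix(0, nrow = n, ncol = L)
  for (j in seq_len(L)) {
    V[, j] <- spad[seq_len(n) + j - 1L] * coeffs$p[j]
  }
  V
}

#' Encode every residue of a chain
#'
#' Applies [encode_residue()] to all positions of a chain and returns a tidy
#' feature table, one row per residue with columns `v_1 .. v_L`.
#'
#' @inheritParams encode_residue
#' @return A tibble with columns `chain_id`, `position`, `aa`, `v_1..v_L`.
#' @export
encode_chain <- function(chain, coeffs,
                         kd = kyte_doolittle(),
                         mode = "integrative",
                         profile_scale = c("fraction", "percent")) {
  stopifnot(inherits(chain, "chain_profile"), inherits(coeffs, "window_coefficients"))
  profile_scale <- match.arg(profile_scale)
  mode <- check_mode(mode)
  kd <- check_hydropathy_scale(kd)
  s <- residue_scalars(chain, kd, mode, profile_scale)
  V <- window_features(s, coeffs)
  colnames(V) <- paste0("v_", seq_len(coeffs$L))
  dplyr::bind_cols(
    tibble::tibble(
      chain_id = chain$chain_id,
      position = seq_len(length(chain)),
      aa = strsplit(chain$sequence, "")[[1L]]
    ),
    tibble::as_tibble(V)
  )
}

#' Encode a list of chains
#'
#' @param chains List of [chain_profile()] objects.
#' @inheritParams encode_residue
#' @return Row-bound tibble of [encode_chain()] results.
#' @export
encode_chains <- function(chains, coeffs,
                          kd = kyte_doolittle(),
                          mode = "integrative",
                          profile_scale = c("fraction", "percent")) {
  profile_scale <- match.arg(profile_scale)
  dplyr::bind_rows(lapply(
    chains, encode_chain,
    coeffs = coeffs, kd = kd, mode = mode, profile_scale = profile_scale
  ))
}

# extract the numeric feature matrix from an encoded tibble
feature_matrix <- function(features) {
  vcols <- grep("^v_\\d+$", names(features), value = TRUE)
  vcols <- vcols[order(as.integer(sub("^v_", "", vcols)))]
  as.matrix(features[, vcols, drop = FALSE])
}
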