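# Shared fixtures and a memoising cache so the benchmark cross-validation
# runs are computed once per test session and reused across test files.

.run_cache <- new.env(parent = emptyenv())

# Benchmark conditions used by the qualitative pipeline checks:
# 40 chains of 100-200 residues at the 0.2756 interface fraction.
benchmark_fixture <- function(seed, signal_strength = 1) {
  key <- sprintf("fix_%d_%g", seed, signal_strength)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- generate_fixture(fixture_config(
      seed = seed, signal_strength = signal_strength
    ))
  }
  .run_cache[[key]]
}

benchmark_cv <- function(seed, mode = "integrative", signal_strength = 1) {
  key <- sprintf("cv_%d_%s_%g", seed, mode, signal_strength)
  if (is.null(.run_cache[[key]])) {
    fix <- benchmark_fixture(seed, signal_strength)
    .run_cache[[key]] <- run_cross_validation(
      fix$chains, fix$labels, run_config(mode = mode, seed = seed)
    )
  }
  .run_cache[[key]]
}

# Small fixed fixture for SOM and determinism round-trips.
small_fixture <- function(seed = 5) {
  key <- sprintf("small_%d", seed)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- generate_fixture(fixture_config(
      n_chains = 10, chain_length_range = c(60, 90), seed = seed
    ))
  }
  .run_cache[[key]]
}

benchmark_small_run <- function(config) {
  key <- sprintf("smallrun_%s", rlang::hash(unclass(config)))
  if (is.null(.run_cache[[key]])) {
    fix <- small_fixture()
    .run_cache[[key]] <- run_cross_validation(fix$chains, fix$labels, config)
  }
  .run_cache[[key]]
}

# A tiny chain with seeded random profile rows.
random_chain <- function(n = 8, seed = 42, chain_id = "rand") {
  withr::with_seed(seed, {
    sp <- matrix(stats::runif(n * 20), nrow = n, ncol = 20)
    seq_chr <- paste(sample(aa_order(), n, replace = TRUE), collapse = "")
    chain_profile(chain_id, seq_chr, sp)
  })
}

# Independent two-pass standard-deviation oracle (never calls the package).
oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# Independent six-measure oracle from textbook formulas.
oracle_metrics <- function(tp, fp, tn, fn) {
  div <- function(a, b) if (b > 0) a / b else 0
  sen <- div(tp, tp + fn)
  prec <- div(tp, tp + fp)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    sen = sen,
    spec = div(tn, tn + fp),
    acc = (tp + tn) / (tp + fp + tn + fn),
    prec = prec,
    f1 = if (sen + prec > 0 && (tp + fn) > 0 && (tp + fp) > 0) {
      2 * sen * prec / (sen + prec)
    } else {
      0
    },
    mcc = if (den > 0) (tp * tn - fp * fn) / den else 0
  )
}
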