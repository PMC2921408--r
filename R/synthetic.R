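# Seeded synthetic fixture generator. It emulates the three pipeline inputs
# (chain sequences, per-residue 20-value profiles, per-residue delta-ASA with
# labels) with a plantable class signal, so every stage of the package is
# testable without any external database.

#' Synthetic fixture configuration
#'
#' Defaults describe the benchmark conditions used throughout the package's
#' tests: 40 chains of 100-200 residues, an interface fraction of 0.2756
#' (the positive rate of large-scale hetero-complex datasets), and a unit
#' class-signal strength.
#'
#' @param n_chains Number of chains (default 40).
#' @param chain_length_range Integer min/max chain length; minimum 30
#'   (shorter chains are conventionally excluded from interface datasets).
#' @param interface_fraction Target positive rate in `(0, 1)`
#'   (default 0.2756).
#' @param signal_strength Non-negative real scaling the class separation of
#'   the profile distributions; 0 plants no signal (default 1).
#' @param dasa_max Scale of positive delta-ASA values in A^2; positive
#'   delta-ASA is drawn as `1 + Exponential(mean = dasa_max / 3)`
#'   (default 100).
#' @param identity_coupling Weight in `[0, 1]` mixing the residue's own
#'   profile into its sequence-letter distribution; small values keep the
#'   planted signal in the profile rather than in the bare sequence
#'   (default 0.25).
#' @param patch_mean Mean length of contiguous interface patches (default 6).
#' @param seed Integer seed; the whole fixture is deterministic under it.
#' @return A validated list of class `fixture_config`.
#' @export
fixture_config <- function(n_chains = 40,
                           chain_length_range = c(100, 200),
                           interface_fraction = 0.2756,
                           signal_strength = 1,
                           dasa_max = 100,
                           identity_coupling = 0.25,
                           patch_mean = 6,
                           seed = 1) {
  if (n_chains < 1 || n_chains != floor(n_chains)) {
    abort("`n_chains` must be a positive integer.")
  }
  if (length(chain_length_range) != 2L || any(chain_length_range < 30) ||
      chain_length_range[1] > chain_length_range[2]) {
    abort("`chain_length_range` must be an increasing pair with minimum >= 30.")
  }
  if (interface_fraction <= 0 || interface_fraction >= 1) {
    abort("`interface_fraction` must lie in (0, 1).")
  }
  if (signal_strength < 0) abort("`signal_strength` must be non-negative.")
  if (dasa_max <= 1) abort("`dasa_max` must exceed 1 A^2.")
  if (identity_coupling < 0 || identity_coupling > 1) {
    abort("`identity_coupling` must lie in [0, 1].")
  }
  if (round(interface_fraction * chain_length_range[1]) < 1) {
    abort("Infeasible config: no chain would contain an interface residue.")
  }
  structure(
    list(
      n_chains = as.integer(n_chains),
      chain_length_range = as.integer(chain_length_range),
      interface_fraction = interface_fraction,
      signal_strength = signal_strength,
      dasa_max = dasa_max,
      identity_coupling = identity_coupling,
      patch_mean = patch_mean,
      seed = as.integer(seed)
    ),
    class = "fixture_config"
  )
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g <- rep(1, length(alpha))
  g / sum(g)
}

# Dirichlet concentrations for the two classes. Interface residues tilt
# toward the hydrophilic amino acids R, Y, W, H with per-residue weight
# inversely proportional to |KD|, which flattens the profile-hydropathy
# products and lowers the integrative standard deviation; non-interface
# residues tilt uniformly toward the hydrophobic A, G, V, whose spread-out
# products raise it. The class signal therefore lives in the
# profile-hydropathy interaction, not in the profile shape or the bare
# sequence. Tilts scale with signal_strength; strength 0 makes the
# class-conditional distributions identical.
class_alphas <- function(signal_strength) {
  base <- rep(1, 20)
  names(base) <- aa_order()
  kd <- kyte_doolittle()
  hydrophilic <- c("R", "Y", "W", "H")
  w <- 1 / abs(kd[hydrophilic])
  w <- w / sum(w) * 24
  a_pos <- base
  a_pos[hydrophilic] <- a_pos[hydrophilic] + w * signal_strength
  a_neg <- base
  a_neg[c("A", "G", "V")] <- a_neg[c("A", "G", "V")] + 8 * signal_strength
  list(pos = a_pos, neg = a_neg)
}

place_patches <- function(len, target, patch_mean) {
  lab <- integer(len)
  added <- integer(0)
  while (sum(lab) < target) {
    start <- sample.int(len, 1L)
    plen <- 1L + stats::rgeom(1L, prob = 1 / patch_mean)
    idx <- start:min(len, start + plen - 1L)
    new <- idx[lab[idx] == 0L]
    lab[new] <- 1L
    added <- c(added, new)
  }
  excess <- sum(lab) - target
  if (excess > 0L) lab[added[(length(added) - excess + 1L):length(added)]] <- 0L
  lab
}

#' Generate a synthetic interface-prediction fixture
#'
#' Produces chains whose interface residues occur in contiguous patches.
#' Each residue's 20-value profile is drawn from a class-conditional
#' Dirichlet (interface residues tilted toward R, Y, W, H; non-interface
#' toward A, G, V; tilt proportional to `signal_strength`), its sequence
#' letter from a mixture of that profile and a uniform background, and its
#' delta-ASA from `1 + Exponential(mean = dasa_max / 3)` for interface
#' residues versus mostly exact zeros (with a small mass in `(0, 1]`) for
#' non-interface residues. Labels always satisfy the delta-ASA rule. The
#' whole fixture is deterministic under the config seed.
#'
#' @param config A [fixture_config()].
#' @return An object of class `ippred_fixture`: named list `chains` of
#'   [chain_profile()] objects, tibble `labels`
#'   (`chain_id, position, aa, delta_asa, label`), and the `config`.
#' @export
generate_fixture <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  alphas <- class_alphas(config$signal_strength)
  aa <- aa_order()
  withr::with_seed(derive_seed(config$seed, 61L), {
    chains <- list()
    labels <- vector("list", config$n_chains)
    for (ci in seq_len(config$n_chains)) {
      id <- sprintf("syn%03d", ci)
      len <- sample(seq(config$chain_length_range[1], config$chain_length_range[2]), 1L)
      target <- round(config$interface_fraction * len)
      if (target < 1L) abort("Infeasible config: chain with no interface residue.")
      lab <- place_patches(len, target, config$patch_mean)
      sp <- t(vapply(
        lab,
        function(l) rdirichlet1(if (l == 1L) alphas$pos else alphas$neg),
        numeric(20)
      ))
      colnames(sp) <- aa
      lam <- config$identity_coupling
      seq_letters <- vapply(seq_len(len), function(i) {
        pr <- lam * sp[i, ] + (1 - lam) / 20
        sample(aa, 1L, prob = pr)
      }, character(1))
      dasa <- numeric(len)
      npos <- sum(lab == 1L)
      nneg <- len - npos
      dasa[lab == 1L] <- 1 + rexp(npos, rate = 3 / config$dasa_max)
      small <- runif(nneg) < 0.1
      dneg <- numeric(nneg)
      dneg[small] <- runif(sum(small), 0, 1)
      dasa[lab == 0L] <- dneg
      stopifnot(all(label_interface(dasa) == lab))
      chains[[id]] <- chain_profile(id, paste(seq_letters, collapse = ""), sp)
      labels[[ci]] <- tibble::tibble(
        chain_id = id, position = seq_len(len), aa = seq_letters,
        delta_asa = dasa, label = lab
      )
    }
    structure(
      list(chains = chains, labels = dplyr::bind_rows(labels), config = config),
      class = "ippred_fixture"
    )
  })
}

#' @export
print.ippred_fixture <- function(x, ...) {
  cat(sprintf(
    "<ippred_fixture> %d chains, %d residues, positive rate %.4f (signal %.2f, seed %d)\n",
    length(x$chains), nrow(x$labels), mean(x$labels$label),
    x$config$signal_strength, x$config$seed
  ))
  invisible(x)
}

#' Write a fixture to disk
#'
#' Writes `chains.fasta`, `profiles.tsv`, `dasa.tsv`, and a `manifest.yaml`
#' recording the config and seed.
#'
#' @param fixture An [generate_fixture()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "ippred_fixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seqs <- vapply(fixture$chains, function(ch) ch$sequence, character(1))
  write_chain_fasta(seqs, file.path(dir, "chains.fasta"))
  prof <- dplyr::bind_rows(lapply(fixture$chains, function(ch) {
    dplyr::bind_cols(
      tibble::tibble(
        chain_id = ch$chain_id,
        position = seq_len(length(ch)),
        aa = strsplit(ch$sequence, "")[[1L]]
      ),
      tibble::as_tibble(ch$profile)
    )
  }))
  write_profile_table(prof, file.path(dir, "profiles.tsv"))
  write_dasa_table(fixture$labels, file.path(dir, "dasa.tsv"))
  yaml::write_yaml(
    c(unclass(fixture$config), list(generator = "ippred synthetic fixture")),
    file.path(dir, "manifest.yaml")
  )
  invisible(dir)
}

#' Read a fixture back from disk
#'
#' @param dir Directory written by [write_fixture()].
#' @return An `ippred_fixture` (config restored from the manifest).
#' @export
read_fixture <- function(dir) {
  seqs <- read_chain_fasta(file.path(dir, "chains.fasta"))
  prof <- read_profile_table(file.path(dir, "profiles.tsv"))
  labels <- read_dasa_table(file.path(dir, "dasa.tsv"))
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  cfg <- fixture_config(
    n_chains = man$n_chains,
    chain_length_range = unlist(man$chain_length_range),
    interface_fraction = man$interface_fraction,
    signal_strength = man$signal_strength,
    dasa_max = man$dasa_max,
    identity_coupling = man$identity_coupling,
    patch_mean = man$patch_mean,
    seed = man$seed
  )
  structure(
    list(chains = profiles_to_chains(prof, seqs), labels = labels, config = cfg),
    class = "ippred_fixture"
  )
}

#' A tiny hand-specified worked-example chain
#'
#' A fixed five-residue chain with hand-written profile rows, together with
#' its precomputed integrative standard deviations and its window-length-3
#' feature matrix. The expected numbers were produced once by the package's
#' brute-force oracle (two-pass variance, slot-by-slot windowing) and frozen
#' here; tests recompute them through the public API.
#'
#' @return List with `chain` (a [chain_profile()]), `expected_sd`
#'   (numeric 5-vector), and `expected_features_L3` (5 x 3 matrix).
#' @export
worked_example_chain <- function() {
  sp <- matrix(0, nrow = 5, ncol = 20, dimnames = list(NULL, aa_order()))
  sp[1, "A"] <- 1
  sp[2, c("R", "K")] <- c(0.6, 0.4)
  sp[3, ] <- 0.05
  sp[4, c("G", "V", "Y")] <- c(0.2, 0.5, 0.3)
  sp[5, c("W", "H")] <- c(0.7, 0.3)
  chain <- chain_profile("worked_example", "ARSVW", sp)
  list(
    chain = chain,
    expected_sd = c(
      0.40249223594996214, 0.68118395382405206, 0.14934858553063032,
      0.48317235673803760, 0.25048321721277683
    ),
    expected_features_L3 = matrix(
      c(
        0.00000000000000000, 0.16057117045374941, 0.16482657483762059,
        0.09739133794614234, 0.27175307991143155, 0.03613798544675587,
        0.16482657483762059, 0.05958146528631808, 0.11691356522752495,
        0.03613798544675587, 0.19275788182400727, 0.06060960554886157,
        0.11691356522752495, 0.09992834587715259, 0.00000000000000000
      ),
      nrow = 5, ncol = 3, byrow = TRUE
    )
  )
}
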