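test_that("gaussian window coefficients have the stated centre and variance", {
  expect_equal(gaussian_coefficients(19)$mu, 10)
  w5 <- gaussian_coefficients(5)
  expect_equal(w5$sigma2, 2.5)
  expect_equal(w5$p[3], 1 / sqrt(2 * pi * 2.5), tolerance = 1e-12)
  # alternative divisor L
  expect_equal(gaussian_coefficients(5, divisor = "n")$sigma2, 2)
  expect_error(gaussian_coefficients(4), "odd")
  expect_error(gaussian_coefficients(-3), "odd")
})

test_that("coefficients are positive, symmetric, unimodal for all odd L up to 41", {
  for (L in seq(1, 41, by = 2)) {
    p <- gaussian_coefficients(L)$p
    expect_true(all(p > 0))
    expect_equal(p, rev(p), tolerance = 1e-12)
    expect_equal(which.max(p), (L + 1) / 2)
    if (L >= 3) {
      centre <- (L + 1) / 2
      expect_true(all(diff(p[centre:L]) < 0))
    }
  }
})

test_that("integrative_sd matches its definition and basic identities", {
  kd <- kyte_doolittle()
  expect_equal(integrative_sd(rep(0.05, 20), rep(2, 20)), 0)
  sp <- c(1, rep(0, 19))
  kd1 <- unname(kd["A"])
  expect_equal(integrative_sd(sp, kd), kd1 * sqrt(0.05), tolerance = 1e-12)
  # positive homogeneity
  set.seed(7)
  sp2 <- runif(20)
  expect_equal(
    integrative_sd(3.5 * sp2, kd), 3.5 * integrative_sd(sp2, kd),
    tolerance = 1e-12
  )
  expect_error(integrative_sd(runif(19), kd), "20")
  expect_error(integrative_sd(c(NA, runif(19)), kd), "finite")
})

test_that("integrative_sd agrees with the two-pass oracle on 1000 seeded pairs", {
  set.seed(11)
  got <- numeric(1000)
  want <- numeric(1000)
  for (i in 1:1000) {
    sp <- runif(20, 0, 2)
    kd <- runif(20, -5, 5)
    got[i] <- integrative_sd(sp, kd)
    want[i] <- oracle_sd(sp * kd)
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("integrative_sd is invariant under a shared amino-acid permutation", {
  set.seed(13)
  sp <- runif(20)
  kd <- runif(20, -5, 5)
  base <- integrative_sd(sp, kd)
  permuted <- vapply(1:20, function(i) {
    perm <- sample(20)
    integrative_sd(sp[perm], kd[perm])
  }, numeric(1))
  expect_equal(permuted, rep(base, 20), tolerance = 1e-12)
})

test_that("encode_residue zero-pads termini and scales by the coefficients", {
  w19 <- gaussian_coefficients(19)
  single <- chain_profile("one", "A", matrix(runif(20), 1, 20))
  v <- encode_residue(single, 1, w19)$v
  expect_length(v, 19)
  expect_true(v[10] != 0)
  expect_true(all(v[-10] == 0))

  # constant-profile chain: interior window is SD * p
  sp_row <- withr::with_seed(3, runif(20))
  const <- chain_profile("const", strrep("K", 9), matrix(sp_row, 9, 20, byrow = TRUE))
  w3 <- gaussian_coefficients(3)
  sdval <- integrative_sd(sp_row, kyte_doolittle())
  v_mid <- encode_residue(const, 5, w3)$v
  expect_equal(v_mid, sdval * w3$p, tolerance = 1e-12)

  expect_error(encode_residue(const, 0, w3), "position")
  expect_error(encode_residue(const, 10, w3), "position")
})

test_that("encode_residue matches a slot-by-slot oracle on a 3-residue chain", {
  set.seed(21)
  sp <- matrix(runif(60), 3, 20)
  ch <- chain_profile("tri", "ARN", sp)
  w3 <- gaussian_coefficients(3)
  kd <- kyte_doolittle()
  sds <- vapply(1:3, function(i) oracle_sd(sp[i, ] * unname(kd)), numeric(1))
  for (pos in 1:3) {
    v <- encode_residue(ch, pos, w3)$v
    for (j in 1:3) {
      src <- pos - 2 + j
      want <- if (src >= 1 && src <= 3) sds[src] * w3$p[j] else 0
      expect_equal(v[j], want, tolerance = 1e-12)
    }
  }
})

test_that("interior encodings are translation invariant", {
  ch1 <- random_chain(8, seed = 42)
  set.seed(99)
  pad_front <- matrix(runif(40), 2, 20)
  pad_back <- matrix(runif(20), 1, 20)
  ch2 <- chain_profile(
    "shifted",
    paste0("GG", ch1$sequence, "G"),
    rbind(pad_front, ch1$profile, pad_back)
  )
  w3 <- gaussian_coefficients(3)
  for (pos in 2:7) {
    expect_equal(
      encode_residue(ch1, pos, w3)$v,
      encode_residue(ch2, pos + 2, w3)$v,
      tolerance = 1e-12
    )
  }
})

test_that("encode_chain modes behave as documented", {
  ch <- random_chain(8, seed = 42)
  w3 <- gaussian_coefficients(3)
  enc <- encode_chain(ch, w3)
  # integrative mode equals per-position encode_residue
  for (pos in c(1, 4, 8)) {
    expect_equal(unlist(enc[pos, paste0("v_", 1:3)], use.names = FALSE),
                 encode_residue(ch, pos, w3)$v)
  }
  # hydropathy_only depends only on the sequence, not the profile
  ch_other <- chain_profile(ch$chain_id, ch$sequence,
                            matrix(runif(160), 8, 20))
  expect_equal(
    encode_chain(ch, w3, mode = "hydropathy_only"),
    encode_chain(ch_other, w3, mode = "hydropathy_only")
  )
  # the three modes give three distinct matrices on a fixture chain
  m1 <- as.matrix(encode_chain(ch, w3)[, 4:6])
  m2 <- as.matrix(encode_chain(ch, w3, mode = "profile_only")[, 4:6])
  m3 <- as.matrix(encode_chain(ch, w3, mode = "hydropathy_only")[, 4:6])
  expect_false(isTRUE(all.equal(m1, m2)))
  expect_false(isTRUE(all.equal(m1, m3)))
  expect_false(isTRUE(all.equal(m2, m3)))
  expect_error(encode_chain(ch, w3, mode = "nonsense"), "mode")
})

test_that("percent-scale profiles are rescaled before the statistic", {
  ch_frac <- random_chain(5, seed = 8)
  ch_pct <- chain_profile(ch_frac$chain_id, ch_frac$sequence, ch_frac$profile * 100)
  w3 <- gaussian_coefficients(3)
  expect_equal(
    encode_chain(ch_pct, w3, profile_scale = "percent"),
    encode_chain(ch_frac, w3),
    tolerance = 1e-12
  )
})

test_that("non-standard residues get hydropathy 0 with a warning", {
  expect_warning(v <- hydropathy_values("AXR"), "Non-standard")
  expect_equal(v, c(1.8, 0, -4.5))
})

test_that("the worked example chain matches oracle recomputation", {
  we <- worked_example_chain()
  expect_identical(we$chain, worked_example_chain()$chain)
  kd <- unname(kyte_doolittle())
  sds <- apply(we$chain$profile, 1, function(r) oracle_sd(r * kd))
  expect_equal(unname(sds), we$expected_sd, tolerance = 1e-12)
  enc <- encode_chain(we$chain, gaussian_coefficients(3))
  expect_equal(unname(as.matrix(enc[, paste0("v_", 1:3)])),
               unname(we$expected_features_L3), tolerance = 1e-8)
})
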