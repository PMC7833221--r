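# The Psi / Delta / Gamma criteria: exact toy-system values, verdicts,
# bound chains, k-behaviour, redundancy penalty, surrogates.

test_that("variant 1 shows pure causal decoupling at every tested (n, gamma)", {
  for (n in c(2, 4)) for (g in c(0.6, 0.99)) {
    rep <- emergence(exact_joint(parity_system(1, n, g), feature = "parity"),
                     feature = "v_t")
    expect_equal(rep$psi, 1 - binary_entropy(g), tolerance = 1e-12)
    expect_equal(rep$delta, 0, tolerance = 1e-10)
    expect_equal(rep$gamma, 0, tolerance = 1e-10)
    expect_true(rep$verdicts$emergent)
    expect_false(rep$verdicts$downward)
    expect_true(rep$verdicts$decoupled)
  }
})

test_that("variant 2 shows pure downward causation", {
  rep <- emergence(exact_joint(parity_system(2, 3), feature = "parity"),
                   feature = "v_t")
  expect_equal(rep$delta, 1, tolerance = 1e-10)
  expect_equal(rep$gamma, 1, tolerance = 1e-10)
  expect_true(rep$verdicts$downward)
  expect_false(rep$verdicts$decoupled)
})

test_that("variant 3 carries decoupling and downward causation at once", {
  rep <- emergence(exact_joint(parity_system(3, 3, 0.9), feature = "parity"),
                   feature = "v_t")
  expect_gt(rep$psi, 0)
  expect_gt(rep$delta, 0)
  expect_true(rep$verdicts$emergent)
  expect_true(rep$verdicts$downward)
})

test_that("an independent noise feature scores exactly zero on the exact path", {
  # feature_noise = 1/2 makes v a fair coin independent of everything
  p <- exact_joint(parity_system(1, 3, 0.9), feature = "parity",
                   feature_noise = 0.5)
  expect_equal(emergence_psi(p, "v_t"), 0, tolerance = 1e-10)
  expect_equal(emergence_gamma(p, "v_t"), 0, tolerance = 1e-10)
})

test_that("copy dynamics with a single-part feature never flag downward causation", {
  # X' = X with two independent bits; V = X^1
  S <- 4
  states <- emergence:::state_space(2)
  p4 <- array(0, c(2, 2, 2, 2, 2, 2))
  for (s in 1:S) {
    b <- states[s, ]
    p4[b[1] + 1, b[2] + 1, b[1] + 1, b[2] + 1, b[1] + 1, b[1] + 1] <- 0.25
  }
  p <- prob_table(p4, vars = c("x1_t", "x2_t", "x1_tp", "x2_tp", "v_t", "v_tp"))
  expect_lte(emergence_delta(p, "v_t"), 1e-10)
  # and Psi = 0 here: the part's bit is fully counted in the sum
  expect_lte(emergence_psi(p, "v_t"), 1e-10)
})

test_that("criteria respect the Psi <= Un <= Syn chain on random kernels", {
  # The middle term is the unique information the feature carries about its
  # own future beyond any single part; the unique information about the
  # whole future state is separately capped by the synergy.
  set.seed(51)
  for (i in 1:15) {
    p <- random_kernel_table(2, feature = TRUE)
    tgt <- paste0("x", 1:2, "_tp")
    psi <- emergence_psi(p, "v_t")
    un_feat <- un_mmi(p, "v_t", parts_t(2), "v_tp", k = 1)
    un_sys <- un_mmi(p, "v_t", parts_t(2), tgt, k = 1)
    syn <- syn_k(p, parts_t(2), tgt, k = 1)
    expect_lte(psi, un_feat + 1e-9)
    expect_lte(un_feat, syn + 1e-9)
    expect_lte(un_sys, syn + 1e-9)
  }
})

test_that("Psi is non-increasing in the order k", {
  for (variant in c(1, 3)) {
    p <- exact_joint(parity_system(variant, 3, 0.9), feature = "parity")
    psis <- vapply(1:3, function(k) emergence_psi(p, "v_t", k = k), numeric(1))
    expect_true(all(diff(psis) <= 1e-10))
  }
})

test_that("duplicating a part never increases Psi (redundancy penalty)", {
  set.seed(52)
  for (i in 1:10) {
    p <- random_kernel_table(2, feature = TRUE)
    psi <- emergence_psi(p, "v_t")
    # duplicate part 1 by counting it twice in the parts list
    psi_dup <- emergence_psi(p, "v_t",
                             parts_t = list("x1_t", "x2_t", "x1_t"),
                             parts_tp = parts_tp(2))
    expect_lte(psi_dup, psi + 1e-10)
  }
})

test_that("sampled criteria approach the exact values on toy systems", {
  sys <- parity_system(1, 3, 0.99)
  exact <- emergence(exact_joint(sys, feature = "parity"), "v_t")
  sm <- sample_trajectories(sys, trials = 2e4, steps = 1, seed = 9)
  v <- array(0L, dim = c(2e4, 2, 1))
  v[, 1, 1] <- apply(sm$values[, 1, ], 1, parity)
  v[, 2, 1] <- apply(sm$values[, 2, ], 1, parity)
  feat <- sample_matrix(v, "discrete", card = 2L, vars = "v")
  for (est in c("plug_in", "jackknife")) {
    rep <- emergence(sm, feat, estimator = est, n_surrogates = 0)
    expect_equal(rep$psi, exact$psi, tolerance = 0.03)
    expect_equal(rep$gamma, exact$gamma, tolerance = 0.03)
  }
})

test_that("surrogate machinery is deterministic and centred at chance", {
  sys <- parity_system(1, 3, 0.99)
  sm <- sample_trajectories(sys, trials = 4000, steps = 1, seed = 12)
  v <- array(0L, dim = c(4000, 2, 1))
  v[, 1, 1] <- apply(sm$values[, 1, ], 1, parity)
  v[, 2, 1] <- apply(sm$values[, 2, ], 1, parity)
  feat <- sample_matrix(v, "discrete", card = 2L, vars = "v")
  s1 <- surrogate_test(sm, feat, "psi", n_surrogates = 30, seed = 5)
  s2 <- surrogate_test(sm, feat, "psi", n_surrogates = 30, seed = 5)
  expect_identical(s1$values, s2$values)
  expect_lt(abs(s1$mean), 0.01)              # shuffling destroys temporal MI
  expect_gt(s1$observed, max(s1$values))     # observed clearly exceeds null
  expect_equal(s1$p_value, 1 / 31)
  expect_error(surrogate_test(sm, feat, "psi", n_surrogates = 5, seed = 1),
               "at least 19")
  # a full report carries the verdicts and provenance
  rep <- emergence(sm, feat, estimator = "plug_in", n_surrogates = 30, seed = 5)
  expect_true(rep$verdicts$emergent)
  expect_true(rep$verdicts$decoupled)
  expect_identical(rep$provenance$seed, 5)
  expect_equal(rep$psi, emergence_psi(sm, feat, estimator = "plug_in"))
})

test_that("misaligned or mixed-kind features are rejected", {
  sm <- sample_matrix(matrix(sample(0:1, 60, TRUE), 30, 2), kind = "discrete")
  bad <- sample_matrix(matrix(0L, 10, 1), kind = "discrete")
  expect_error(emergence(sm, bad, n_surrogates = 0), "not aligned")
  contf <- sample_matrix(matrix(rnorm(30), 30, 1), kind = "continuous")
  expect_error(emergence(sm, contf, n_surrogates = 0), "discretise")
})
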