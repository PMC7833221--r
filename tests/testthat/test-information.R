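# Entropy, mutual information and the three estimators (plug-in,
# Dirichlet-smoothed, Gaussian).

test_that("entropy matches closed forms and respects bounds", {
  u <- prob_table(c(0.5, 0.5), vars = "x", card = 2)
  expect_equal(entropy(u, "x"), 1.0)
  d <- prob_table(c(1, 0), vars = "x", card = 2)
  expect_equal(entropy(d, "x"), 0.0)
  bern <- prob_table(c(0.25, 0.75), vars = "x", card = 2)
  expect_equal(entropy(bern, "x"), -0.75 * log2(0.75) - 0.25 * log2(0.25),
               tolerance = 1e-12)
  expect_equal(round(entropy(bern, "x"), 4), 0.8113)
  expect_error(entropy(bern, "nope"), "unknown variable label")
  # 0 <= H <= log2(prod card) on random tables
  set.seed(41)
  for (i in 1:10) {
    p <- random_table(c("a", "b"), c(3L, 4L))
    h <- entropy(p)
    expect_gte(h, 0)
    expect_lte(h, log2(12))
  }
})

test_that("mutual information: independence, copying, symmetry, overlap", {
  ind <- prob_table(outer(c(0.3, 0.7), c(0.6, 0.4)), vars = c("a", "b"))
  expect_equal(mutual_information(ind, "a", "b"), 0, tolerance = 1e-12)
  cp <- prob_table(c(0.5, 0, 0, 0.5), vars = c("a", "b"), card = c(2, 2))
  expect_equal(mutual_information(cp, "a", "b"), 1.0)
  set.seed(42)
  p <- random_table(c("a", "b", "c"))
  expect_equal(mutual_information(p, c("a", "b"), "c"),
               mutual_information(p, "c", c("a", "b")))
  expect_error(mutual_information(p, c("a", "b"), c("b", "c")), "disjoint")
})

test_that("parity self-prediction MI matches 1 - Hb(gamma) on the toy kernel", {
  for (g in c(0.7, 0.9)) {
    p <- exact_joint(parity_system(1, n = 3, gamma = g), feature = "parity")
    expect_equal(mutual_information(p, "v_t", "v_tp"), 1 - binary_entropy(g),
                 tolerance = 1e-12)
  }
})

test_that("conditional MI detects (conditional) independence", {
  # chain a -> c -> b built by explicit factorisation: I(a;b|c) = 0
  m <- array(0, c(2, 2, 2))
  pc_a <- matrix(c(0.8, 0.3, 0.2, 0.7), 2)   # p(c|a)
  pb_c <- matrix(c(0.6, 0.1, 0.4, 0.9), 2)   # p(b|c)
  for (a in 1:2) for (c2 in 1:2) for (b in 1:2)
    m[a, b, c2] <- 0.5 * pc_a[a, c2] * pb_c[c2, b]
  chain <- prob_table(m, vars = c("a", "b", "c"))
  expect_equal(conditional_mutual_information(chain, "a", "b", "c"), 0,
               tolerance = 1e-12)
  # a = b, both independent of c: I(a;b|c) = H(a) = 1
  m2 <- array(0, c(2, 2, 2))
  m2[1, 1, ] <- 0.25; m2[2, 2, ] <- 0.25
  dup <- prob_table(m2, vars = c("a", "b", "c"))
  expect_equal(conditional_mutual_information(dup, "a", "b", "c"), 1.0)
  expect_error(conditional_mutual_information(dup, "a", "b", "a"), "disjoint")
})

test_that("chain rule I(A;B,C) = I(A;B) + I(A;C|B) holds on random tables", {
  set.seed(7)
  for (i in 1:20) {
    p <- random_table(c("a", "b", "c"), c(2L, 3L, 2L))
    expect_equal(mutual_information(p, "a", c("b", "c")),
                 mutual_information(p, "a", "b") +
                   conditional_mutual_information(p, "a", "c", "b"),
                 tolerance = 1e-10)
  }
})

test_that("plug-in tables reproduce empirical frequencies", {
  sm <- sample_matrix(matrix(c(0, 0, 1, 1), ncol = 1), kind = "discrete")
  pt <- plug_in_table(sm)
  expect_equal(as.vector(pt$p), c(0.5, 0.5))
  one <- sample_matrix(matrix(1L, 1, 1), kind = "discrete", card = 3)
  expect_equal(entropy(plug_in_table(one)), 0)
  cont <- sample_matrix(matrix(rnorm(10), ncol = 1), kind = "continuous")
  expect_error(plug_in_table(cont), "discrete")
})

test_that("plug-in tables converge in total variation to the source law", {
  truth <- c(0.1, 0.2, 0.3, 0.4)
  set.seed(99)
  x <- sample(0:3, 1e5, replace = TRUE, prob = truth)
  sm <- sample_matrix(matrix(x, ncol = 1), kind = "discrete", card = 4)
  pt <- plug_in_table(sm)
  expect_lt(0.5 * sum(abs(as.vector(pt$p) - truth)), 0.01)
})

test_that("Dirichlet-smoothed MI behaves across prior strengths", {
  set.seed(123)
  n <- 1e4
  a <- sample(0:1, n, replace = TRUE)
  b <- sample(0:1, n, replace = TRUE)
  sm <- sample_matrix(cbind(a = a, b = b), kind = "discrete")
  # vanishing prior recovers the plug-in estimate
  expect_equal(bayesian_mi(sm, "a", "b", prior_strength = 1e-12),
               plug_in_mi(sm, "a", "b"), tolerance = 1e-6)
  # independent variables: estimate near zero
  expect_lt(bayesian_mi(sm, "a", "b", prior_strength = 1), 0.01)
  # perfectly copied pair at N = 1e3: close to 1 bit
  cp <- sample_matrix(cbind(a = a[1:1000], b = a[1:1000]), kind = "discrete")
  expect_equal(bayesian_mi(cp, "a", "b", prior_strength = 1), 1.0,
               tolerance = 0.05)
  expect_error(bayesian_mi(sm, "a", "b", prior_strength = -1), "non-negative")
})

test_that("Gaussian MI matches the bivariate closed form", {
  set.seed(11)
  n <- 1e5
  x <- rnorm(n)
  y0 <- rnorm(n)
  y <- as.vector(residuals(lm(y0 ~ x)))        # exact zero sample correlation
  sm0 <- sample_matrix(cbind(x = x, y = y), kind = "continuous")
  expect_equal(gaussian_mi(sm0, "x", "y"), 0, tolerance = 1e-12)
  rho <- 0.9
  y2 <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  sm <- sample_matrix(cbind(x = x, y = y2), kind = "continuous")
  expect_equal(gaussian_mi(sm, "x", "y"), -0.5 * log2(1 - rho^2),
               tolerance = 0.02)
  dup <- sample_matrix(cbind(x = x, y = y2, z = y2), kind = "continuous")
  expect_error(gaussian_mi(dup, "x", c("y", "z")), "groupB.*singular")
})

test_that("data processing: a feature never out-predicts the full state", {
  for (variant in c(1, 3)) {
    p <- exact_joint(parity_system(variant, n = 3, gamma = 0.8),
                     feature = "parity")
    xt <- paste0("x", 1:3, "_t"); xtp <- paste0("x", 1:3, "_tp")
    expect_lte(mutual_information(p, "v_t", "v_tp"),
               mutual_information(p, xt, xtp) + 1e-12)
  }
})

test_that("plug-in and smoothed estimators converge to the exact MI", {
  sys <- parity_system(1, n = 3, gamma = 0.9)
  exact <- exact_joint(sys)
  xt <- paste0("x", 1:3, "_t"); xtp <- paste0("x", 1:3, "_tp")
  true_mi <- mutual_information(exact, xt, xtp)
  sm <- sample_trajectories(sys, trials = 1e5, steps = 1, seed = 5)
  pr <- lagged_pairs_public(sm)
  joint <- sample_matrix(cbind(pr$past, pr$future), kind = "discrete",
                         card = 2L, vars = c(xt, xtp))
  expect_lt(abs(plug_in_mi(joint, xt, xtp) - true_mi), 0.02)
  expect_lt(abs(bayesian_mi(joint, xt, xtp, prior_strength = 1) - true_mi),
            0.02)
})
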