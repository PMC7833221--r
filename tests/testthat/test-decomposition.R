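# PID / PhiID under the MMI redundancy: lattice structure, canonical atoms,
# conservation, additivity, and the synergy/unique bounds.

test_that("antichain lattice has the known sizes and bottom element", {
  lat1 <- antichain_lattice(1)
  expect_length(lat1$antichains, 1)
  lat2 <- antichain_lattice(2)
  expect_length(lat2$antichains, 4)
  expect_identical(lat2$labels[1], "{1}{2}")      # bottom: full redundancy
  expect_identical(lat2$labels[4], "{12}")        # top: full synergy
  lat3 <- antichain_lattice(3)
  expect_length(lat3$antichains, 18)
  expect_error(antichain_lattice(4), "n <= 3")
  # strict order is antisymmetric and the bottom is below everything
  expect_true(all(lat2$below[1, 2:4]))
  expect_false(any(lat2$below & t(lat2$below)))
})

test_that("PID atoms land on the canonical corners", {
  # XOR target: pure synergy
  m <- array(0, c(2, 2, 2))
  for (a in 0:1) for (b in 0:1) m[a + 1, b + 1, (a != b) + 1] <- 0.25
  xor_t <- prob_table(m, vars = c("a", "b", "y"))
  at <- pid_mmi(xor_t, list("a", "b"), "y")
  expect_equal(at$atom[at$antichain == "{12}"], 1, tolerance = 1e-12)
  expect_equal(sum(abs(at$atom[at$antichain != "{12}"])), 0, tolerance = 1e-12)
  # duplicated source: pure redundancy
  m2 <- array(0, c(2, 2, 2)); m2[1, 1, 1] <- 0.5; m2[2, 2, 2] <- 0.5
  dup <- prob_table(m2, vars = c("a", "b", "y"))
  at2 <- pid_mmi(dup, list("a", "b"), "y")
  expect_equal(at2$atom[at2$antichain == "{1}{2}"], 1, tolerance = 1e-12)
  # independent target: every atom zero
  m3 <- array(1 / 8, c(2, 2, 2))
  at3 <- pid_mmi(prob_table(m3, vars = c("a", "b", "y")), list("a", "b"), "y")
  expect_equal(sum(abs(at3$atom)), 0, tolerance = 1e-12)
})

test_that("atoms sum to the total MI (conservation) for n = 2 and 3", {
  set.seed(31)
  for (i in 1:15) {
    p3 <- random_table(c("a", "b", "y"), c(2L, 2L, 3L))
    at <- pid_mmi(p3, list("a", "b"), "y")
    expect_equal(sum(at$atom), attr(at, "total"), tolerance = 1e-9)
    p4 <- random_table(c("a", "b", "c", "y"))
    at3 <- pid_mmi(p4, list("a", "b", "c"), "y")
    expect_equal(sum(at3$atom), attr(at3, "total"), tolerance = 1e-9)
  }
})

test_that("syn_k closed form equals the lattice Moebius sum", {
  set.seed(32)
  for (i in 1:10) {
    p <- random_table(c("a", "b", "c", "y"))
    src <- list("a", "b", "c")
    at <- pid_mmi(p, src, "y")
    lat <- antichain_lattice(3)
    for (k in 1:2)
      expect_equal(syn_k(p, src, "y", k),
                   emergence:::syn_k_lattice(at, lat, k), tolerance = 1e-9)
  }
  expect_error(syn_k(random_table(c("a", "b", "y")), list("a", "b"), "y", 2),
               "1 <= k < n")
})

test_that("unique information detects parity emergence and bounds features", {
  g <- 0.9
  for (n in 2:3) {
    p <- exact_joint(parity_system(1, n = n, gamma = g), feature = "parity")
    tgt <- paste0("x", seq_len(n), "_tp")
    un <- un_mmi(p, "v_t", parts_t(n), tgt, k = 1)
    expect_equal(un, 1 - binary_entropy(g), tolerance = 1e-12)
    expect_gt(un, 0)  # causal emergence detected
    # and it is capped by the synergy of the system (emergence capacity)
    expect_lte(un, syn_k(p, parts_t(n), tgt, 1) + 1e-9)
  }
})

test_that("single-part features are never emergent (order 1)", {
  set.seed(33)
  for (i in 1:10) {
    p <- random_kernel_table(2)
    # feature = g(x1_t): here the identity and the negation
    for (flip in c(FALSE, TRUE)) {
      S <- dim(p$p)
      arr <- array(0, c(S, 2))
      idx <- which(array(TRUE, S), arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        v <- if (flip) 1L - (idx[r, 1] - 1L) else idx[r, 1] - 1L
        arr[cbind(rbind(idx[r, ]), v + 1L)] <- p$p[rbind(idx[r, ])]
      }
      pv <- prob_table(arr, vars = c(p$vars, "v_t"))
      expect_lte(un_mmi(pv, "v_t", parts_t(2), paste0("x", 1:2, "_tp"), 1),
                 1e-12)
    }
  }
  # constant features carry nothing
  p <- random_kernel_table(2)
  arr <- array(0, c(dim(p$p), 2))
  arr[, , , , 1] <- p$p
  pc <- prob_table(arr, vars = c(p$vars, "v_t"))
  expect_lte(un_mmi(pc, "v_t", parts_t(2), paste0("x", 1:2, "_tp"), 1), 0)
})

test_that("PhiID atoms land on the canonical corners", {
  # synergistic cause with a unique effect: x1' = x1 xor x2, x2' a coin
  p4 <- array(0, c(2, 2, 2, 2))
  for (a in 0:1) for (b in 0:1) for (c2 in 0:1)
    p4[a + 1, b + 1, (a != b) + 1, c2 + 1] <- 1 / 8
  pt <- prob_table(p4, vars = c("x1_t", "x2_t", "x1_tp", "x2_tp"))
  at <- phiid_mmi(pt, list("x1_t", "x2_t"), list("x1_tp", "x2_tp"))
  expect_equal(at$atom[at$past == "{12}" & at$future == "{1}"], 1,
               tolerance = 1e-9)
  expect_equal(sum(abs(at$atom)), 1, tolerance = 1e-9)
  # all four variables copies of each other: double redundancy only
  p4b <- array(0, c(2, 2, 2, 2)); p4b[1, 1, 1, 1] <- 0.5; p4b[2, 2, 2, 2] <- 0.5
  ptb <- prob_table(p4b, vars = c("x1_t", "x2_t", "x1_tp", "x2_tp"))
  atb <- phiid_mmi(ptb, list("x1_t", "x2_t"), list("x1_tp", "x2_tp"))
  expect_equal(atb$atom[atb$past == "{1}{2}" & atb$future == "{1}{2}"], 1,
               tolerance = 1e-9)
  # independent past and future: all atoms vanish
  ptc <- prob_table(array(1 / 16, c(2, 2, 2, 2)),
                    vars = c("x1_t", "x2_t", "x1_tp", "x2_tp"))
  atc <- phiid_mmi(ptc, list("x1_t", "x2_t"), list("x1_tp", "x2_tp"))
  expect_equal(sum(abs(atc$atom)), 0, tolerance = 1e-9)
  expect_error(phiid_mmi(ptc, list("x1_t"), list("x1_tp")), "exactly 2")
})

test_that("downward causation and decoupling indices split the synergy", {
  # variant 2 restricted to n = 2: pure downward causation
  p2 <- exact_joint(parity_system(2, n = 2))
  a2 <- phiid_mmi(p2, parts_t(2), parts_tp(2))
  expect_equal(d_k(a2, 1), 1, tolerance = 1e-9)
  expect_equal(g_k(a2, 1), 0, tolerance = 1e-9)
  # variant 1, gamma = 0.99: pure causal decoupling
  p1 <- exact_joint(parity_system(1, n = 2, gamma = 0.99))
  a1 <- phiid_mmi(p1, parts_t(2), parts_tp(2))
  expect_equal(g_k(a1, 1), 1 - binary_entropy(0.99), tolerance = 1e-9)
  expect_equal(d_k(a1, 1), 0, tolerance = 1e-9)
  expect_error(d_k(a1, 2), "smaller than")
})

test_that("PhiID conservation and Syn = D + G hold on random kernels", {
  set.seed(34)
  for (i in 1:30) {
    p <- random_kernel_table(2)
    at <- suppressWarnings(phiid_mmi(p, parts_t(2), parts_tp(2)))
    expect_equal(sum(at$atom), attr(at, "total"), tolerance = 1e-9)
    syn <- syn_k(p, parts_t(2), paste0("x", 1:2, "_tp"), 1)
    expect_equal(d_k(at, 1) + g_k(at, 1), syn, tolerance = 1e-9)
  }
})
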