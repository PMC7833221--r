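# Fixture builders used across the suite: random probability tables and
# random two-time kernels with an attached deterministic feature.

binary_entropy <- function(g) -g * log2(g) - (1 - g) * log2(1 - g)

# random joint table over the named binary variables (Dirichlet-ish masses)
random_table <- function(vars, card = rep(2L, length(vars))) {
  m <- stats::rgamma(prod(card), shape = 1)
  prob_table(m / sum(m), vars = vars, card = card)
}

# Random Markov kernel over n binary parts, uniform initial state, as a
# joint table over (x1_t..xn_t, x1_tp..xn_tp); optionally extended with a
# deterministic binary feature v = f(state) evaluated at both times.
random_kernel_table <- function(n, feature = FALSE) {
  S <- 2^n
  K <- matrix(stats::rgamma(S * S, shape = 1), S, S)
  K <- K / rowSums(K)
  joint <- K / S
  vt <- paste0("x", seq_len(n), "_t")
  vtp <- paste0("x", seq_len(n), "_tp")
  if (!feature)
    return(prob_table(as.vector(joint), vars = c(vt, vtp), card = rep(2L, 2 * n)))
  f <- sample(0:1, S, replace = TRUE)           # deterministic feature map
  p4 <- array(0, dim = c(S, S, 2, 2))
  for (x in 1:S) for (xp in 1:S)
    p4[x, xp, f[x] + 1, f[xp] + 1] <- joint[x, xp]
  prob_table(as.vector(p4), vars = c(vt, vtp, "v_t", "v_tp"),
             card = rep(2L, 2 * n + 2))
}

parts_t <- function(n) as.list(paste0("x", seq_len(n), "_t"))
parts_tp <- function(n) as.list(paste0("x", seq_len(n), "_tp"))

lagged_pairs_public <- function(sm, tau = 1) emergence:::lagged_pairs(sm, tau)
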