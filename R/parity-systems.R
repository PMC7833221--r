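#' Parity bit for a binary state
#'
#' Returns 1 when the number of ones in `bits` is even, 0 otherwise.  Note
#' the convention: the even-count indicator (so the all-zero state has
#' parity 1), not the XOR of the bits.
#'
#' @param bits vector of 0/1 values.
#' @return 0 or 1.
#' @export
parity <- function(bits) {
  if (!length(bits)) stop("`bits` must be non-empty")
  as.integer(sum(bits) %% 2 == 0)
}

# All 2^n states as an (2^n) x n 0/1 matrix; variable 1 is the least
# significant bit, so state s (0-based) sits in row s + 1.
state_space <- function(n) {
  s <- 0:(2^n - 1)
  m <- sapply(seq_len(n), function(j) bitwAnd(bitwShiftR(s, j - 1L), 1L))
  matrix(m, ncol = n)
}

#' Parity-preserving Markov toy systems
#'
#' Constructs one of three minimal n-bit Markov systems built around the
#' parity of the state, each started from the uniform distribution:
#' \describe{
#'   \item{variant 1}{the next state is a uniform draw from the strings with
#'     the same parity as the current state with probability `gamma`, and
#'     from the opposite-parity strings with probability `1 - gamma`
#'     (collective self-prediction with no part-to-part structure).}
#'   \item{variant 2}{bit 1 of the next state equals the parity of the
#'     current state; all other bits are fair coins (a whole-to-part
#'     effect).}
#'   \item{variant 3}{both mechanisms at once: bit 1 of the next state is
#'     forced to the current parity, and the parity itself is preserved with
#'     probability `gamma`.}
#' }
#'
#' @param variant 1, 2 or 3.
#' @param n number of binary parts (>= 2).
#' @param gamma parity-preservation probability in (0, 1); ignored for
#'   variant 2.
#' @return an object of class `parity_system` holding the row-stochastic
#'   2^n x 2^n transition kernel and the state space.
#' @export
parity_system <- function(variant = 1, n = 3, gamma = 0.99) {
  if (!variant %in% 1:3) stop("`variant` must be 1, 2 or 3")
  if (n < 2) stop("`n` must be at least 2")
  if (variant != 2 && (gamma <= 0 || gamma >= 1))
    stop("`gamma` must lie strictly between 0 and 1")
  states <- state_space(n)
  par <- apply(states, 1, parity)
  same <- outer(par, par, "==")            # parity(x') == parity(x), rows x
  K <- switch(as.character(variant),
    "1" = {
      k <- matrix(0, 2^n, 2^n)
      k[same]  <- gamma / 2^(n - 1)
      k[!same] <- (1 - gamma) / 2^(n - 1)
      k
    },
    "2" = {
      # row x: mass 2^{-(n-1)} on states x' with x'_1 == parity(x)
      ok <- outer(par, states[, 1], "==")
      ifelse(ok, 2^-(n - 1), 0)
    },
    "3" = {
      ok <- outer(par, states[, 1], "==")  # x'_1 == parity(x)
      k <- matrix(0, 2^n, 2^n)
      k[ok & same]  <- gamma / 2^(n - 2)
      k[ok & !same] <- (1 - gamma) / 2^(n - 2)
      k
    })
  stopifnot(max(abs(rowSums(K) - 1)) < 1e-12)
  structure(list(variant = variant, n = n,
                 gamma = if (variant == 2) NA_real_ else gamma,
                 kernel = K, states = states, parity = par,
                 initial = rep(2^-n, 2^n)),
            class = "parity_system")
}

#' @export
print.parity_system <- function(x, ...) {
  cat(sprintf("<parity_system> variant %d, n = %d%s\n", x$variant, x$n,
              if (is.na(x$gamma)) "" else sprintf(", gamma = %g", x$gamma)))
  invisible(x)
}

#' Transition kernel of a parity system
#'
#' @param system a [parity_system].
#' @return the 2^n x 2^n row-stochastic matrix, rows indexed by the current
#'   state (variable 1 = least significant bit).
#' @export
transition_matrix <- function(system) {
  stopifnot(inherits(system, "parity_system"))
  system$kernel
}

#' Exact one-step joint distribution of a parity system
#'
#' Builds the joint probability table over (X_t, X_{t+1}) --- and optionally
#' the parity feature at both times --- from the uniform initial state and
#' the transition kernel: p(x, x') = 2^{-n} K(x, x').
#'
#' @param system a [parity_system] with n <= 12.
#' @param feature "none" or "parity"; with "parity" the table gains
#'   variables `v_t`, `v_tp` holding the (possibly noisy) parity at each
#'   time.
#' @param feature_noise probability that the feature value is flipped,
#'   independently at each time (observational noise; default 0).
#' @return a [prob_table] with variables `x1_t..xn_t`, `x1_tp..xn_tp` and,
#'   if requested, `v_t`, `v_tp`.
#' @export
exact_joint <- function(system, feature = c("none", "parity"),
                        feature_noise = 0) {
  stopifnot(inherits(system, "parity_system"))
  feature <- match.arg(feature)
  n <- system$n
  if (n > 12)
    stop("n too large for exact enumeration (4^n entries); use sample_trajectories()")
  S <- 2^n
  joint <- system$initial * system$kernel   # p(x, x'), rows x, cols x'
  vt  <- paste0("x", seq_len(n), "_t")
  vtp <- paste0("x", seq_len(n), "_tp")
  if (feature == "none") {
    return(prob_table(as.vector(joint), vars = c(vt, vtp), card = rep(2L, 2 * n)))
  }
  # expand with the feature channel applied independently at t and t'
  par <- system$parity
  pv <- function(v, x) ifelse(v == par[x], 1 - feature_noise, feature_noise)
  p4 <- array(0, dim = c(S, S, 2, 2))
  for (a in 0:1) for (b in 0:1)
    p4[, , a + 1, b + 1] <- joint *
      outer(pv(a, seq_len(S)), pv(b, seq_len(S)))
  prob_table(as.vector(p4), vars = c(vt, vtp, "v_t", "v_tp"),
             card = c(rep(2L, 2 * n), 2L, 2L))
}

#' Sample trajectories from a parity system
#'
#' Iterates the one-step kernel from independent uniform initial states.
#'
#' @param system a [parity_system].
#' @param trials number of independent trajectories.
#' @param steps number of transitions per trajectory (time length is
#'   `steps + 1`).
#' @param seed integer RNG seed (required; sampling is reproducible).
#' @return a discrete [sample_matrix] of dimension
#'   `trials x (steps + 1) x n` with variables `x1..xn`.
#' @export
sample_trajectories <- function(system, trials, steps = 1, seed) {
  stopifnot(inherits(system, "parity_system"))
  if (missing(seed)) stop("`seed` is required")
  if (trials < 1) stop("`trials` must be >= 1")
  n <- system$n
  S <- 2^n
  out <- array(0L, dim = c(trials, steps + 1, n))
  withr_seed(seed, {
    state <- sample.int(S, trials, replace = TRUE)     # 1-based state index
    out[, 1, ] <- system$states[state, , drop = FALSE]
    cumK <- t(apply(system$kernel, 1, cumsum))
    for (s in seq_len(steps)) {
      u <- stats::runif(trials)
      state <- vapply(seq_len(trials), function(i)
        findInterval(u[i], cumK[state[i], ], left.open = TRUE) + 1L,
        integer(1))
      out[, s + 1, ] <- system$states[state, , drop = FALSE]
    }
  })
  sample_matrix(out, kind = "discrete", card = rep(2L, n),
                vars = paste0("x", seq_len(n)))
}

# evaluate `expr` under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  force(seed)   # before snapshotting the RNG state below
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Supervenience deviation of a feature
#'
#' A feature V_t is supervenient on X_t when V_t and X_{t'} are
#' conditionally independent given X_t.  This returns the deviation
#' I(V_t; X_{t'} | X_t) in bits; values below ~1e-10 on exact tables
#' indicate supervenience.
#'
#' @param p a [prob_table] containing the feature and both system times.
#' @param feature label of V_t.
#' @param system_t labels of X_t.
#' @param system_tp labels of X_{t'}.
#' @export
supervenience_check <- function(p, feature, system_t, system_tp) {
  conditional_mutual_information(p, feature, system_tp, system_t)
}
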