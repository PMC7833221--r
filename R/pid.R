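# Partial information decomposition (PID) and integrated information
# decomposition (PhiID) on the Williams-Beer redundancy lattice, under the
# minimum-mutual-information (MMI) redundancy.  The redundancy function is
# pluggable: every decomposition routine takes `redundancy` as an argument
# so other PIDs can be swapped in; MMI is the shipped default.

# ---- antichain lattice ---------------------------------------------------

# non-empty subsets of 1..n, as sorted integer vectors
all_subsets <- function(n) {
  out <- list()
  for (m in 1:(2^n - 1))
    out[[m]] <- which(bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) != 0L)
  out
}

subset_contains <- function(a, b) all(b %in% a)   # b subseteq a

#' Antichain lattice of source collections
#'
#' Enumerates all antichains of non-empty subsets of `1..n` (collections of
#' subsets none of which contains another), the index set of PID atoms.
#' The partial order used for Moebius inversion is
#' alpha <= beta iff every member of beta contains some member of alpha.
#'
#' @param n number of sources (n <= 3; the lattice grows
#'   super-exponentially).
#' @return list with `antichains` (list of lists of integer vectors, sorted
#'   bottom-up), `labels` (canonical strings such as `"{1}{2}"`), and
#'   `below` (logical matrix of the strict order, `below[i, j]` iff
#'   antichain i < antichain j).
#' @export
antichain_lattice <- function(n) {
  if (n > 3) stop("antichain lattice is only enumerated for n <= 3 sources")
  if (n < 1) stop("n must be >= 1")
  subs <- all_subsets(n)
  ns <- length(subs)
  acs <- list()
  for (m in 1:(2^ns - 1)) {
    idx <- which(bitwAnd(m, bitwShiftL(1L, 0:(ns - 1))) != 0L)
    col <- subs[idx]
    ok <- TRUE
    if (length(col) > 1) {
      for (i in seq_along(col)) for (j in seq_along(col)) {
        if (i != j && subset_contains(col[[i]], col[[j]])) { ok <- FALSE; break }
      }
    }
    if (ok) acs[[length(acs) + 1]] <- col
  }
  leq <- function(a, b) {           # a <= b in the redundancy lattice
    all(vapply(b, function(bb)
      any(vapply(a, function(aa) subset_contains(bb, aa), logical(1))),
      logical(1)))
  }
  K <- length(acs)
  below_eq <- matrix(FALSE, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    below_eq[i, j] <- leq(acs[[i]], acs[[j]])
  # sort bottom-up (topological by number of antichains below)
  ord <- order(colSums(below_eq))
  acs <- acs[ord]
  below_eq <- below_eq[ord, ord, drop = FALSE]
  labels <- vapply(acs, antichain_label, character(1))
  dimnames(below_eq) <- list(labels, labels)
  list(antichains = acs, labels = labels,
       below = below_eq & !diag(K))
}

antichain_label <- function(col) {
  parts <- vapply(col, function(a) paste0("{", paste(a, collapse = ""), "}"),
                  character(1))
  paste(parts[order(vapply(col, length, integer(1)),
                    vapply(col, function(a) paste(a, collapse = ","),
                           character(1)))], collapse = "")
}

# ---- redundancy functions ------------------------------------------------

#' Minimum-mutual-information redundancy
#'
#' The cumulative redundancy of an antichain `{a1..aL}` about target Y is
#' `min_i I(X^{ai}; Y)`.  This is the package's default redundancy function
#' for both PID and PhiID.
#'
#' @param p a [prob_table].
#' @param collection list of integer vectors indexing into `sources`.
#' @param sources list of character vectors: the variable labels of each
#'   source part.
#' @param target character vector of target variable labels.
#' @export
redundancy_mmi <- function(p, collection, sources, target) {
  min(vapply(collection, function(a)
    mutual_information(p, unlist(sources[a]), target), numeric(1)))
}

# ---- PID -----------------------------------------------------------------

#' Exact partial information decomposition (MMI redundancy)
#'
#' Decomposes I(X; Y) into atoms indexed by antichains of source
#' collections, by Moebius inversion of the cumulative redundancy over the
#' Williams-Beer lattice.
#'
#' @param p a discrete [prob_table].
#' @param sources list of character vectors (or a character vector, one
#'   source per label): the source parts X^1..X^n, n <= 3.
#' @param target character vector: target labels Y.
#' @param redundancy cumulative redundancy function with the signature of
#'   [redundancy_mmi()].
#' @return an `atom_table`: data.frame with columns `antichain` and `atom`
#'   (bits), with attributes `total` (I(X;Y)) and `n`.
#' @export
pid_mmi <- function(p, sources, target, redundancy = redundancy_mmi) {
  stopifnot(inherits(p, "prob_table"))
  if (is.character(sources)) sources <- as.list(sources)
  n <- length(sources)
  lat <- antichain_lattice(n)
  K <- length(lat$antichains)
  cum <- vapply(seq_len(K), function(i)
    redundancy(p, lat$antichains[[i]], sources, target), numeric(1))
  atoms <- numeric(K)
  for (i in seq_len(K))
    atoms[i] <- cum[i] - sum(atoms[lat$below[, i]])
  total <- mutual_information(p, unlist(sources), target)
  out <- data.frame(antichain = lat$labels, atom = atoms,
                    stringsAsFactors = FALSE)
  attr(out, "total") <- total
  attr(out, "n") <- n
  class(out) <- c("atom_table", "data.frame")
  out
}

#' @export
print.atom_table <- function(x, ...) {
  cat(sprintf("PID atom table (n = %d sources, total I = %.6f bits)\n",
              attr(x, "n"), attr(x, "total")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' k-th order synergy (MMI redundancy)
#'
#' Information that the whole source set carries about the target beyond
#' every group of k parts: the sum of PID atoms whose members all have more
#' than k sources.  Under MMI redundancy this equals the closed form
#' `I(X;Y) - max_{|a| = k} I(X^a; Y)`, which is what is computed (and what
#' scales to large n); the lattice route is available through [pid_mmi()].
#'
#' @inheritParams pid_mmi
#' @param k order, 1 <= k < n.
#' @export
syn_k <- function(p, sources, target, k = 1) {
  if (is.character(sources)) sources <- as.list(sources)
  n <- length(sources)
  if (k < 1 || k >= n) stop("`k` must satisfy 1 <= k < n")
  total <- mutual_information(p, unlist(sources), target)
  total - max_group_mi(p, sources, target, k)
}

max_group_mi <- function(p, sources, target, k) {
  combs <- utils::combn(length(sources), k, simplify = FALSE)
  max(vapply(combs, function(a)
    mutual_information(p, unlist(sources[a]), target), numeric(1)))
}

# sum of atoms over S(k) = antichains whose smallest member has > k sources
syn_k_lattice <- function(atom_table, lattice, k) {
  in_sk <- vapply(lattice$antichains, function(col)
    min(vapply(col, length, integer(1))) > k, logical(1))
  sum(atom_table$atom[in_sk])
}

#' Unique information of a feature beyond size-k parts (MMI redundancy)
#'
#' The MMI instantiation of the unique information a supervenient feature
#' V_t carries about the future system state beyond every group of k parts:
#' `I(V_t; X_t') - max_{|a| = k} I(X_t^a; X_t')`.  A positive value is the
#' defining signature of causal emergence of order k.
#'
#' @param p a [prob_table] containing the feature and both system times.
#' @param feature label(s) of V_t.
#' @param sources list of label groups: the parts of X_t.
#' @param target labels of X_t' (the prediction target).
#' @param k order, 1 <= k < number of parts.
#' @export
un_mmi <- function(p, feature, sources, target, k = 1) {
  if (is.character(sources)) sources <- as.list(sources)
  check_labels(p, feature, "feature")
  n <- length(sources)
  if (k < 1 || k >= n) stop("`k` must satisfy 1 <= k < n")
  mutual_information(p, feature, target) - max_group_mi(p, sources, target, k)
}

# ---- PhiID ---------------------------------------------------------------

#' Exact integrated information decomposition for two parts (MMI)
#'
#' Decomposes I(X_t; X_t') for a bipartite system into 16 atoms indexed by
#' pairs of antichains (one for the past sources, one for the future
#' targets).  The double redundancy of a pair of collections is
#' `min_{a, b} I(X_t^a; X_t'^b)`; atoms follow by Moebius inversion over
#' the product order.  Atoms are reported as-is: MMI Moebius inversion can
#' yield negative atoms, which are flagged (`attr(x, "negative_atoms")`)
#' rather than clipped, so the conservation identity is preserved exactly.
#'
#' @param p a discrete [prob_table].
#' @param parts_t list of two character vectors: the parts of X_t.
#' @param parts_tp list of two character vectors: the parts of X_t'.
#' @param redundancy cumulative redundancy function used for the underlying
#'   single-target decomposition (default [redundancy_mmi()]).
#' @return a `phiid_atom_table`: data.frame with columns `past`, `future`
#'   and `atom` (bits); attribute `total` is I(X_t; X_t').
#' @export
phiid_mmi <- function(p, parts_t, parts_tp, redundancy = redundancy_mmi) {
  stopifnot(inherits(p, "prob_table"))
  if (length(parts_t) != 2 || length(parts_tp) != 2)
    stop("PhiID is implemented for exactly 2 parts at each time")
  lat <- antichain_lattice(2)
  K <- length(lat$antichains)
  # cumulative double redundancy on the product lattice
  cum <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    pairs <- expand.grid(a = seq_along(lat$antichains[[i]]),
                         b = seq_along(lat$antichains[[j]]))
    cum[i, j] <- min(vapply(seq_len(nrow(pairs)), function(r) {
      a <- lat$antichains[[i]][[pairs$a[r]]]
      b <- lat$antichains[[j]][[pairs$b[r]]]
      mutual_information(p, unlist(parts_t[a]), unlist(parts_tp[b]))
    }, numeric(1)))
  }
  below_eq <- lat$below | diag(K)
  atoms <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    s <- sum(atoms[below_eq[, i], below_eq[, j]]) - atoms[i, j]
    atoms[i, j] <- cum[i, j] - s
  }
  total <- mutual_information(p, unlist(parts_t), unlist(parts_tp))
  out <- data.frame(past = rep(lat$labels, times = K),
                    future = rep(lat$labels, each = K),
                    atom = as.vector(atoms), stringsAsFactors = FALSE)
  attr(out, "total") <- total
  attr(out, "negative_atoms") <- any(atoms < -1e-9)
  if (any(atoms < -1e-9))
    warning("PhiID produced negative atoms (reported as-is; a known ",
            "feature of MMI Moebius inversion)")
  class(out) <- c("phiid_atom_table", "data.frame")
  out
}

#' @export
print.phiid_atom_table <- function(x, ...) {
  cat(sprintf("PhiID atom table (total I = %.6f bits)%s\n", attr(x, "total"),
              if (isTRUE(attr(x, "negative_atoms"))) " [has negative atoms]" else ""))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

phiid_sk_labels <- function(k = 1) {
  lat <- antichain_lattice(2)
  in_sk <- vapply(lat$antichains, function(col)
    min(vapply(col, length, integer(1))) > k, logical(1))
  list(sk = lat$labels[in_sk], rest = lat$labels[!in_sk])
}

#' Downward-causation index D^(k) from a PhiID atom table
#'
#' Sum of atoms whose past collection is synergistic (all members larger
#' than k) while the future collection is not: collective causes with
#' effects on small groups of parts.
#'
#' @param atoms a `phiid_atom_table` from [phiid_mmi()].
#' @param k order (k = 1 for the two-part decomposition).
#' @export
d_k <- function(atoms, k = 1) {
  stopifnot(inherits(atoms, "phiid_atom_table"))
  if (k >= 2) stop("`k` must be smaller than the number of parts (2)")
  lab <- phiid_sk_labels(k)
  sum(atoms$atom[atoms$past %in% lab$sk & atoms$future %in% lab$rest])
}

#' Causal-decoupling index G^(k) from a PhiID atom table
#'
#' Sum of atoms with synergistic collections on both sides: collective
#' causes whose effects are themselves collective.
#'
#' @inheritParams d_k
#' @export
g_k <- function(atoms, k = 1) {
  stopifnot(inherits(atoms, "phiid_atom_table"))
  if (k >= 2) stop("`k` must be smaller than the number of parts (2)")
  lab <- phiid_sk_labels(k)
  sum(atoms$atom[atoms$past %in% lab$sk & atoms$future %in% lab$sk])
}
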