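#' Joint probability table over labelled discrete variables
#'
#' `prob_table()` builds an explicit joint probability mass function over a
#' tuple of labelled discrete variables.  It is the basic container for all
#' exact information-theoretic computations in the package: entropies,
#' mutual informations, partial and integrated information decompositions.
#'
#' Outcome codes for each variable run from 0 to `cardinality - 1`.  Masses
#' are stored as a dense array with one dimension per variable, in the order
#' given by `vars`.
#'
#' @param masses numeric array (or vector) of non-negative masses summing to
#'   one.  If a vector, `card` must be supplied and the layout is
#'   column-major with the first variable varying fastest.
#' @param vars character vector of variable names, one per dimension.
#' @param card integer vector of cardinalities (only needed when `masses` is
#'   not already a dim-ed array).
#' @return an object of class `prob_table`.
#' @examples
#' # a pair of perfectly correlated fair bits
#' p <- prob_table(c(0.5, 0, 0, 0.5), vars = c("a", "b"), card = c(2, 2))
#' entropy(p, "a")
#' mutual_information(p, "a", "b")
#' @export
prob_table <- function(masses, vars, card = NULL) {
  if (is.null(dim(masses))) {
    if (is.null(card)) stop("`card` is required when `masses` has no dim")
    if (length(masses) != prod(card))
      stop("length of `masses` does not match prod(card)")
    dim(masses) <- card
  }
  card <- dim(masses)
  if (length(vars) != length(card))
    stop("`vars` must name every dimension of `masses`")
  if (anyDuplicated(vars)) stop("variable names must be unique")
  if (any(masses < -1e-12))
    stop("probability masses must be non-negative")
  masses[masses < 0] <- 0
  s <- sum(masses)
  if (abs(s - 1) > 1e-8)
    stop(sprintf("masses must sum to 1 (got %.12f)", s))
  dimnames(masses) <- stats::setNames(lapply(card, function(k) as.character(0:(k - 1))), vars)
  structure(list(p = masses, vars = vars, card = as.integer(card)),
            class = "prob_table")
}

#' @export
print.prob_table <- function(x, ...) {
  cat("<prob_table> ", length(x$vars), " variables: ",
      paste0(x$vars, "[", x$card, "]", collapse = " "), "\n", sep = "")
  invisible(x)
}

check_labels <- function(p, labels, arg = "subset") {
  bad <- setdiff(labels, p$vars)
  if (length(bad))
    stop(sprintf("unknown variable label(s) in %s: %s", arg,
                 paste(bad, collapse = ", ")))
}

#' Marginalise a probability table
#'
#' @param p a [prob_table].
#' @param keep character vector of variable labels to keep.
#' @return a [prob_table] over `keep` (in table order).
#' @export
marginalise <- function(p, keep) {
  stopifnot(inherits(p, "prob_table"))
  if (!length(keep)) stop("`keep` must be non-empty")
  check_labels(p, keep, "keep")
  idx <- which(p$vars %in% keep)
  if (length(idx) == length(p$vars)) return(p)
  m <- apply(p$p, idx, sum)
  if (is.null(dim(m))) dim(m) <- p$card[idx]
  prob_table(m, vars = p$vars[idx])
}

#' Shannon entropy of a subset of variables, in bits
#'
#' Computes \eqn{H = -\sum p \log_2 p} over the marginal distribution of
#' `subset`, with the convention \eqn{0 \log 0 = 0}.
#'
#' @inheritParams marginalise
#' @param subset variable labels (default: all variables).
#' @return entropy in bits.
#' @export
entropy <- function(p, subset = p$vars) {
  stopifnot(inherits(p, "prob_table"))
  if (!length(subset)) stop("`subset` must be non-empty")
  check_labels(p, subset)
  m <- marginalise(p, subset)$p
  m <- m[m > 0]
  -sum(m * log2(m))
}

#' Mutual information between two groups of variables, in bits
#'
#' \eqn{I(A;B) = H(A) + H(B) - H(A,B)}.
#'
#' @inheritParams marginalise
#' @param groupA,groupB disjoint character vectors of variable labels.
#' @return mutual information in bits.
#' @export
mutual_information <- function(p, groupA, groupB) {
  stopifnot(inherits(p, "prob_table"))
  check_labels(p, groupA, "groupA")
  check_labels(p, groupB, "groupB")
  if (length(intersect(groupA, groupB)))
    stop("groupA and groupB must be disjoint")
  entropy(p, groupA) + entropy(p, groupB) - entropy(p, c(groupA, groupB))
}

#' Conditional mutual information I(A;B|C), in bits
#'
#' \eqn{I(A;B\mid C) = H(A,C) + H(B,C) - H(A,B,C) - H(C)}.  Equals zero iff
#' A and B are conditionally independent given C.
#'
#' @inheritParams mutual_information
#' @param groupC conditioning variable labels, disjoint from both groups.
#' @export
conditional_mutual_information <- function(p, groupA, groupB, groupC) {
  stopifnot(inherits(p, "prob_table"))
  check_labels(p, groupA, "groupA")
  check_labels(p, groupB, "groupB")
  check_labels(p, groupC, "groupC")
  if (length(intersect(groupA, groupB)) || length(intersect(groupA, groupC)) ||
      length(intersect(groupB, groupC)))
    stop("groupA, groupB and groupC must be pairwise disjoint")
  entropy(p, c(groupA, groupC)) + entropy(p, c(groupB, groupC)) -
    entropy(p, c(groupA, groupB, groupC)) - entropy(p, groupC)
}
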