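# Adjusted mutual information and adjusted Rand index, implemented from
# the contingency table. AMI uses the hypergeometric model of randomness
# for the expected MI and arithmetic-mean normalization.

contingency <- function(u, v) {
  if (length(u) != length(v)) stop("label vectors differ in length")
  tab <- table(factor(u), factor(v))
  tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
}

entropy_nat <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# Expected mutual information under random permutations of one labelling
# with fixed marginals (hypergeometric model).
expected_mi <- function(a, b, n) {
  s <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1L, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      term <- nij / n * log(n * nij / (ai * bj))
      s <- s + sum(term * stats::dhyper(nij, bj, n - bj, ai))
    }
  }
  s
}

#' Adjusted mutual information between two labellings
#'
#' Chance-corrected mutual information with arithmetic-mean
#' normalization: `(MI - E[MI]) / (mean(H(u), H(v)) - E[MI])` with the
#' expectation under the hypergeometric model of randomness. Equals 1
#' iff the two partitions are identical up to relabelling (including
#' the degenerate case where both are a single cluster); a zero
#' normalizer on non-identical partitions returns 0.
#'
#' @param u,v label vectors of equal length (>= 2).
#' @return A scalar `<= 1`.
#' @export
ami <- function(u, v) {
  if (length(u) != length(v)) stop("label vectors differ in length")
  if (length(u) < 2) stop("need at least 2 observations")
  tab <- contingency(u, v)
  n <- sum(tab)
  a <- rowSums(tab); b <- colSums(tab)
  hu <- entropy_nat(a); hv <- entropy_nat(b)
  if (hu == 0 && hv == 0) return(1)  # both single-cluster: identical
  # identical partitions (up to relabelling) are 1 by convention, which
  # also covers the all-singleton case where the normalizer vanishes
  if (all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)) return(1)
  nz <- tab > 0
  mi <- sum((tab[nz] / n) *
              log(n * tab[nz] / (outer(a, b)[nz])))
  emi <- expected_mi(as.integer(a), as.integer(b), as.integer(n))
  denom <- (hu + hv) / 2 - emi
  if (abs(denom) < 1e-14) return(0)
  (mi - emi) / denom
}

# TRUE when two labellings induce the same partition (one nonzero cell
# per row and per column of the contingency table).
same_partition <- function(u, v) {
  tab <- contingency(u, v)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

#' Adjusted Rand index between two labellings
#'
#' @param u,v label vectors of equal length.
#' @return A scalar `<= 1`, 1 iff identical partitions.
#' @export
adjusted_rand <- function(u, v) {
  tab <- contingency(u, v)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expct <- sum_a * sum_b / choose(n, 2)
  mx <- (sum_a + sum_b) / 2
  if (mx == expct) return(1)  # both partitions trivial
  (sum_ij - expct) / (mx - expct)
}
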