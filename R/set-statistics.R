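#' Upper-tail hypergeometric probability, computed in log space
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing at least
#' k members of a K-sized class when n items are drawn without replacement
#' from a universe of N. Each term is evaluated as a log-gamma binomial
#' triple and the tail is summed from its far (smallest) end, so extreme
#' enrichment p-values remain accurate down to the double-precision floor.
#'
#' @param k observed overlap count, `0 <= k <= min(K, n)` (vectorized).
#' @param K size of the target class in the universe.
#' @param n number of draws.
#' @param N universe size, `K <= N` and `n <= N`.
#' @return probability (or vector of probabilities) in \[0, 1\].
#' @examples
#' hypergeom_tail_upper(2, 4, 5, 10)   # 31/42
#' hypergeom_tail_upper(44, 181, 170, 20000) < 1e-10
#' @export
hypergeom_tail_upper <- function(k, K, n, N) {
  for (nm in c("k", "K", "n", "N")) {
    v <- get(nm)
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != floor(v)))
      stop("`", nm, "` must be (a) nonnegative integer(s)")
  }
  if (length(K) != 1 || length(n) != 1 || length(N) != 1)
    stop("`K`, `n` and `N` must be scalars")
  if (K > N || n > N)
    stop("need K <= N and n <= N")
  upper <- min(K, n)
  lower <- max(0, K + n - N)
  if (any(k > upper))
    stop("`k` exceeds min(K, n) = ", upper)
  lden <- lchoose(N, n)
  vapply(k, function(ki) {
    if (ki <= lower) return(1)
    i <- upper:ki                       # smallest terms first
    lterm <- lchoose(K, i) + lchoose(N - K, n - i) - lden
    min(sum(exp(lterm)), 1)
  }, numeric(1))
}

#' Construct an overlap/enrichment result
#'
#' @param k observed overlap; `K` size of set A; `n` size of set B; `N`
#'   universe size.
#' @return An `OverlapResult` with the counts, the expected overlap `K*n/N`,
#'   the fold enrichment `k/expected` (`NA` when the expectation is 0), and
#'   the upper-tail hypergeometric probability `p_upper = P(X >= k)`.
#' @keywords internal
overlap_result <- function(k, K, n, N) {
  expected <- K * n / N
  structure(list(
    k = k, K = K, n = n, N = N,
    expected = expected,
    fold_enrichment = if (expected > 0) k / expected else NA_real_,
    p_upper = hypergeom_tail_upper(k, K, n, N)
  ), class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf(
    "Overlap: k=%d of K=%d vs n=%d in universe N=%d\n  expected %.3f, fold enrichment %.2f, upper-tail p = %.3g\n",
    x$k, x$K, x$n, x$N, x$expected, x$fold_enrichment, x$p_upper))
  invisible(x)
}

#' @export
as.data.frame.OverlapResult <- function(x, ...) {
  data.frame(k = x$k, K = x$K, n = x$n, N = x$N, expected = x$expected,
             fold_enrichment = x$fold_enrichment, p_upper = x$p_upper)
}

resolve_universe <- function(a, b, universe) {
  if (inherits(universe, "GeneSet")) {
    bad_a <- setdiff(a$members, universe$members)
    bad_b <- setdiff(b$members, universe$members)
    if (length(bad_a) || length(bad_b))
      stop("set member(s) outside the universe: ",
           paste(unique(c(bad_a, bad_b)), collapse = ", "))
    length(universe$members)
  } else if (is.numeric(universe) && length(universe) == 1) {
    N <- as.integer(universe)
    if (N < length(union(a$members, b$members)))
      stop("numeric universe smaller than the union of the two sets")
    N
  } else {
    stop("`universe` must be a GeneSet or a single universe size")
  }
}

#' Hypergeometric overlap test between two gene sets
#'
#' Tests whether the observed intersection of two sets drawn from a common
#' measured universe is larger than chance (one-sided, enrichment only).
#'
#' @param a,b `GeneSet` objects.
#' @param universe a `GeneSet` containing both (typically all measured
#'   genes), or a single number giving the universe size.
#' @return An `OverlapResult` (see [overlap_result()]).
#' @export
overlap_test <- function(a, b, universe) {
  stopifnot(inherits(a, "GeneSet"), inherits(b, "GeneSet"))
  N <- resolve_universe(a, b, universe)
  overlap_result(length(intersect(a$members, b$members)),
                 length(a$members), length(b$members), N)
}

#' Enrichment of a query set for known targets
#'
#' Same statistic as [overlap_test()] with the conventional roles: is the
#' query (e.g. the preactivated genes) enriched for a reference target list
#' (e.g. direct Nrf2 targets)?
#'
#' @param query non-empty `GeneSet` under test.
#' @param targets reference `GeneSet`.
#' @inheritParams overlap_test
#' @return An `OverlapResult`.
#' @export
enrichment_test <- function(query, targets, universe) {
  stopifnot(inherits(query, "GeneSet"))
  if (!length(query$members)) stop("`query` gene set is empty")
  overlap_test(query, targets, universe)
}

#' Benjamini-Hochberg adjustment helper
#'
#' Convenience wrapper around [stats::p.adjust()]. The overlap tests report
#' raw hypergeometric p-values by default; apply this only when running many
#' tests at once.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values (FDR).
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
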