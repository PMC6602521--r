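#' Minimum-hypergeometric test on a ranked 0/1 series
#'
#' Given a binary membership indicator in ranking order (index 1 = top
#' gene), `mhgStatistic()` computes the mHG statistic: over every prefix
#' length `n`, the hypergeometric upper tail `P[X >= b_n]` for `X ~
#' Hypergeom(N, B, n)` (with `b_n` the number of ones among the top
#' `n`), minimized over `n`. `mhgPvalue()` converts the statistic into
#' an exact p-value: the probability, under uniform random placement of
#' the `B` ones among `N` positions, that the minimum tail is at most
#' the observed statistic. The p-value is computed by a dynamic program
#' over the prefix lattice run in probability space (conditional path
#' probabilities), which is exact up to floating point and safe from
#' overflow at any `N`, `B`. `mhgTest()` runs both.
#'
#' @param indicator Integer/logical vector of 0s and 1s in ranking
#'   order.
#' @param stat An mHG statistic as returned by `mhgStatistic()`.
#' @param N,B Universe size and number of ones.
#' @return `mhgStatistic()`: list with `mhg_stat`, `n_opt` (smallest
#'   prefix attaining the minimum), `b_at_cutoff`, `N`, `B`.
#'   `mhgPvalue()`: the exact p-value in `(0, 1]`. `mhgTest()`: the
#'   `mhgStatistic()` list with `pvalue` added.
#' @examples
#' mhgTest(c(1, 1, 0, 0))  # stat = 1/6 at n = 2, exact p = 1/6
#' @export
mhgStatistic <- function(indicator) {
    .mhg_scan(as.integer(indicator))
}

#' @rdname mhgStatistic
#' @export
mhgPvalue <- function(stat, N, B) {
    p <- .mhg_pvalue(stat, as.integer(N), as.integer(B))
    # the attaining arrangement has positive probability; guard underflow
    max(p, .Machine$double.xmin)
}

#' @rdname mhgStatistic
#' @export
mhgTest <- function(indicator) {
    s <- mhgStatistic(indicator)
    s$pvalue <- mhgPvalue(s$mhg_stat, s$N, s$B)
    s
}
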