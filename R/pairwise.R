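#' @name pairwise-association
#' @title Pairwise co-mutation screening
#'
#' @description
#' Anchor-versus-gene association screening on a binary mutation matrix:
#' a 2x2 contingency table per candidate, a two-sided Fisher exact test,
#' Benjamini-Hochberg adjustment across the candidate family of each
#' anchor, and significance at an adjusted p-value at or below alpha.
#' A one-sample chi-squared test compares an observed prevalence to a
#' published reference proportion.
NULL

#' 2x2 contingency table for an anchor/gene pair
#'
#' Counts: `a` anchor+ gene+, `b` anchor+ gene-, `c` anchor- gene+,
#' `d` anchor- gene-.
#'
#' @param mm A [MutationMatrix-class].
#' @param anchor,gene distinct column genes.
#' @return named integer vector `c(a =, b =, c =, d =)`.
#' @export
contingency <- function(mm, anchor, gene) {
  genes <- panelGenes(mm)
  if (!anchor %in% genes) stop("unknown gene: ", anchor)
  if (!gene %in% genes) stop("unknown gene: ", gene)
  if (anchor == gene) stop("anchor and gene must differ")
  x <- mutationCalls(mm)[, anchor]; y <- mutationCalls(mm)[, gene]
  c(a = sum(x == 1L & y == 1L), b = sum(x == 1L & y == 0L),
    c = sum(x == 0L & y == 1L), d = sum(x == 0L & y == 0L))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Minimum-likelihood convention: with both margins fixed, the p-value is
#' the sum of hypergeometric point probabilities of every table whose
#' point probability does not exceed that of the observed table (within a
#' 1e-7 relative tolerance for ties). Degenerate margins give p = 1.
#'
#' @param a,b,c,d non-negative integer cell counts (`a` may also be the
#'   full table as returned by [contingency()], with `b`, `c`, `d`
#'   missing).
#' @return the two-sided p-value in `[0, 1]`.
#' @examples
#' fisherExactTwoSided(5, 1, 1, 5)
#' @export
fisherExactTwoSided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.null(b)) { d <- a[["d"]]; c <- a[["c"]]; b <- a[["b"]]; a <- a[["a"]] }
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d >= 1)
  m1 <- a + b          # anchor-positive margin
  k <- a + c           # gene-positive margin
  n <- a + b + c + d
  if (m1 == 0 || k == 0 || m1 == n || k == n) return(1)
  lo <- max(0L, k - (n - m1)); hi <- min(m1, k)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m1, n - m1, k)
  pObs <- stats::dhyper(a, m1, n - m1, k)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted p-values, capped at 1, returned in input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Screen candidates for association with an anchor gene
#'
#' One Fisher test per candidate against the anchor; adjustment is
#' performed across exactly this candidate family. The odds ratio is the
#' sample cross-product ratio, reported as `Inf` when `b * c = 0` and
#' `a * d > 0` (a 0.5 Haldane correction is never applied to the test
#' itself).
#'
#' @param mm A [MutationMatrix-class].
#' @param anchor anchor gene (not among `candidates`).
#' @param candidates character vector of candidate genes.
#' @param alpha significance level on the adjusted p-value (default 0.05,
#'   significant when `p_adj <= alpha`).
#' @return data frame with one row per candidate: `anchor`, `gene`, `a`,
#'   `b`, `c`, `d`, `odds_ratio`, `p_raw`, `p_adj`, `significant`.
#' @export
screenAssociations <- function(mm, anchor, candidates, alpha = 0.05) {
  stopifnot(!(anchor %in% candidates))
  if (length(candidates) == 0L)
    return(data.frame(anchor = character(0), gene = character(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), odds_ratio = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      significant = logical(0)))
  tabs <- t(vapply(candidates, function(g) contingency(mm, anchor, g),
                   integer(4)))
  orat <- apply(tabs, 1, function(t) {
    if (t[2] * t[3] == 0) { if (t[1] * t[4] == 0) NaN else Inf }
    else t[1] * t[4] / (t[2] * t[3])
  })
  praw <- apply(tabs, 1, function(t) fisherExactTwoSided(t[1], t[2], t[3], t[4]))
  padj <- bhAdjust(praw)
  data.frame(anchor = anchor, gene = candidates,
             a = tabs[, 1], b = tabs[, 2], c = tabs[, 3], d = tabs[, 4],
             odds_ratio = orat, p_raw = praw, p_adj = padj,
             significant = padj <= alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-sample chi-squared prevalence comparison
#'
#' Compares an observed mutation prevalence to a published reference
#' proportion: two-cell goodness-of-fit statistic
#' sum((obs - exp)^2 / exp) on 1 degree of freedom.
#'
#' @param observedCount number of mutation-positive patients.
#' @param n cohort size.
#' @param referenceProportion reference prevalence, strictly in (0, 1).
#' @return named numeric `c(statistic =, p =)`.
#' @examples
#' prevalenceChiSquared(46, 1000, 0.03)
#' @export
prevalenceChiSquared <- function(observedCount, n, referenceProportion) {
  stopifnot(observedCount >= 0, observedCount <= n)
  if (referenceProportion <= 0 || referenceProportion >= 1)
    stop("referenceProportion must be strictly inside (0, 1)")
  expd <- c(n * referenceProportion, n * (1 - referenceProportion))
  obs <- c(observedCount, n - observedCount)
  stat <- sum((obs - expd)^2 / expd)
  c(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Write an association result table
#'
#' @param res data frame from [screenAssociations()].
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
writeAssociations <- function(res, path, sep = "\t") {
  utils::write.table(res, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
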