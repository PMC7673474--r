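#' @include AllClasses.R
NULL

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (average ranks for ties), two-sided p
#' from the t approximation on n - 2 degrees of freedom. Constant input
#' yields an NA statistic (excluded downstream from correction families
#' rather than coerced to p = 1).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with elements \code{rho} and \code{p} (both NA for
#'   degenerate input).
#' @export
spearmanRho <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(rank(x), rank(y))
  list(rho = rho, p = .spearmanP(rho, n))
}

.spearmanP <- function(rho, n) {
  r <- pmin(1 - 1e-15, pmax(-1 + 1e-15, rho))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

# Column-wise Spearman of a matrix against one covariate; returns rho and
# p vectors with NA for constant columns. The workhorse behind the edge,
# node and feature families.
.spearmanCols <- function(X, y) {
  n <- length(y)
  ry <- rank(y)
  constant <- apply(X, 2, function(col) all(col == col[1]))
  RX <- apply(X, 2, rank)
  rho <- suppressWarnings(as.numeric(stats::cor(RX, ry)))
  rho[constant] <- NA_real_
  p <- ifelse(is.na(rho), NA_real_, .spearmanP(rho, n))
  list(rho = rho, p = p)
}

#' Mann-Whitney U test
#'
#' U is reported for the first group. The two-sided p-value is exact (full
#' enumeration of group assignments, tie-safe) when both groups have at
#' most 8 observations, and otherwise uses the normal approximation with
#' tie and continuity corrections.
#'
#' @param a,b numeric vectors (non-empty).
#' @return list with elements \code{U} and \code{p}.
#' @export
mannWhitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= 8 && n2 <= 8) {
    p <- .mwExactP(c(a, b), n1, U)
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 1))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, p = p)
}

# Exact two-sided p by enumerating all C(n, n1) assignments of the pooled
# sample to the first group; two-sided via equal tail distance from the
# null mean n1*n2/2.
.mwExactP <- function(pool, n1, Uobs) {
  n <- length(pool)
  r <- rank(pool)
  combos <- utils::combn(n, n1)
  Us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  mean(abs(Us - mu) >= abs(Uobs - mu) - 1e-9)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level \code{q}: reject all ordered p-values up to
#' the largest i with \eqn{p_{(i)} \le i q / m}. Adjusted p-values are the
#' usual monotone BH values (via \code{p.adjust}).
#'
#' @param pValues p-values in (0, 1] (NAs not allowed; filter the family
#'   first).
#' @param q FDR level.
#' @return list with logical \code{reject} and numeric \code{adjusted}.
#' @export
bhFdr <- function(pValues, q = 0.05) {
  .checkP(pValues)
  adj <- stats::p.adjust(pValues, method = "BH")
  list(reject = adj <= q, adjusted = adj)
}

.checkP <- function(p) {
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1] with no missing values")
}

#' Storey positive-FDR q-values
#'
#' Estimates the null proportion \eqn{\pi_0 = \#\{p > \lambda\} /
#' ((1 - \lambda) m)} at a fixed \eqn{\lambda}, clips it to (0, 1], and
#' returns \eqn{q_{(i)} = \min_{j \ge i} \pi_0 m p_{(j)} / j} capped at 1.
#' With \eqn{\pi_0 = 1} this reduces to BH-adjusted p-values; smaller
#' estimated \eqn{\pi_0} gives uniformly smaller q.
#'
#' @param pValues p-values in (0, 1].
#' @param lambda tuning point in (0, 1).
#' @return numeric q-values, monotone in p.
#' @export
storeyPfdr <- function(pValues, lambda = 0.5) {
  .checkP(pValues)
  if (lambda <= 0 || lambda >= 1) stop("lambda must lie in (0, 1)")
  m <- length(pValues)
  pi0 <- sum(pValues > lambda) / ((1 - lambda) * m)
  pi0 <- min(1, max(pi0, 1 / m))
  ord <- order(pValues)
  ranked <- pi0 * m * pValues[ord] / seq_len(m)
  qv <- rev(cummin(rev(pmin(ranked, 1))))
  out <- numeric(m)
  out[ord] <- qv
  out
}

# Apply the configured correction to a p-value family with possible NAs
# (missing units are excluded from the family).
.correctFamily <- function(p, method = c("pfdr", "bh"), q = 0.05,
                           lambda = 0.5) {
  method <- match.arg(method)
  qv <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) {
    qv[ok] <- if (method == "pfdr") storeyPfdr(p[ok], lambda = lambda)
    else bhFdr(p[ok], q = q)$adjusted
  }
  list(q = qv, significant = !is.na(qv) & qv <= q, familySize = sum(ok))
}
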