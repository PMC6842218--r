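# Exact tests used throughout the pipeline.
#
# All two-sided p-values follow the method of small p-values: the p-value is
# the sum of the probabilities of every outcome whose null probability does
# not exceed that of the observed outcome (with the customary 1 + 1e-7
# relative tolerance guarding floating-point ties). This is the same
# two-sidedness rule used by stats::binom.test and stats::fisher.test, which
# serve as independent checks in the test suite.

.REL_TOL <- 1 + 1e-07

#' Two-sided exact binomial p-values
#'
#' Vectorised exact binomial test of `x` successes in `n` trials against
#' success probability `prob`. Used for the allelic-imbalance test (null:
#' the two parental alleles are equally expressed in the hybrid) and the
#' parental-difference test (null: the two parents express the gene
#' equally), and as the Poisson limit of the negative-binomial exact test.
#'
#' @param x number of successes (vector).
#' @param n number of trials (vector, recycled against `x`).
#' @param prob null success probability.
#' @return vector of two-sided p-values; `n == 0` gives 1.
#' @examples
#' binom_test_p(15, 20)   # ~0.0414
#' binom_test_p(10, 20)   # 1
#' @export
binom_test_p <- function(x, n, prob = 0.5) {
  k <- max(length(x), length(n))
  x <- rep_len(as.numeric(x), k)
  n <- rep_len(as.numeric(n), k)
  if (any(x < 0 | n < 0 | x > n)) stop("need 0 <= x <= n")
  vapply(seq_len(k), function(i) {
    ni <- n[i]
    if (ni == 0) return(1)
    d <- stats::dbinom(0:ni, ni, prob)
    pobs <- d[x[i] + 1]
    min(1, sum(d[d <= pobs * .REL_TOL]))
  }, numeric(1))
}

#' Two-sided Fisher exact p-values for 2x2 tables
#'
#' Vectorised Fisher exact test on tables `[[a, b], [c, d]]` by full
#' hypergeometric enumeration. In the pipeline the table rows are the
#' parental counts (P1, P2) and the hybrid allelic counts (F1A1, F1A2), so
#' the null is that the parental ratio equals the hybrid allelic ratio —
#' i.e. no trans-regulatory divergence.
#'
#' @param a,b,c,d cell counts (vectors, recycled).
#' @return vector of two-sided p-values; any zero margin gives 1.
#' @examples
#' fisher_test_p(5, 0, 0, 5)     # 2/252
#' fisher_test_p(10, 10, 10, 10) # 1
#' @export
fisher_test_p <- function(a, b, c, d) {
  k <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), k); b <- rep_len(as.numeric(b), k)
  c <- rep_len(as.numeric(c), k); d <- rep_len(as.numeric(d), k)
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be nonnegative")
  vapply(seq_len(k), function(i) {
    r1 <- a[i] + b[i]; r2 <- c[i] + d[i]
    c1 <- a[i] + c[i]; c2 <- b[i] + d[i]
    if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
    kk <- max(0, r1 - c2):min(r1, c1)
    dk <- stats::dhyper(kk, c1, c2, r1)
    pobs <- stats::dhyper(a[i], c1, c2, r1)
    min(1, sum(dk[dk <= pobs * .REL_TOL]))
  }, numeric(1))
}

# Conditional negative-binomial exact test of equal group means given the
# pooled total. With per-replicate counts NB(mu, phi) (var = mu + phi mu^2),
# the group sum over n replicates is NB with size n/phi, and conditional on
# the pooled total the group-A sum follows a negative hypergeometric law
# that does not depend on mu. phi = 0 degenerates to the binomial split
# (Poisson limit).
#' @noRd
nb_cond_exact_p <- function(sa, s, n_a, n_b, dispersion) {
  if (s == 0) return(1)
  if (dispersion <= 0) return(binom_test_p(sa, s, prob = n_a / (n_a + n_b)))
  ra <- n_a / dispersion
  rb <- n_b / dispersion
  kk <- 0:s
  lp <- lgamma(kk + ra) - lgamma(kk + 1) + lgamma(s - kk + rb) - lgamma(s - kk + 1)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  pobs <- p[sa + 1]
  min(1, sum(p[p <= pobs * .REL_TOL]))
}

#' Conditional negative-binomial exact test for two replicate groups
#'
#' In-repo differential-expression engine: an exact two-sided test of equal
#' means between two groups of replicated counts under a negative-binomial
#' law with common dispersion, conditioning on the pooled total. Counts are
#' expected on a common (effective-library-size-equalised) scale, rounded
#' to integers. The fold change is `log2((mean A + 0.5) / (mean B + 0.5))`.
#'
#' @param a,b integer count vectors (replicates of groups A and B), or
#'   matrices (genes x replicates) for the vectorised form.
#' @param dispersion negative-binomial dispersion (variance = mu + phi mu^2);
#'   0 gives the Poisson-limit binomial test.
#' @return a data frame with columns `log2fc` and `pvalue` (one row per
#'   gene; a single row for vector input).
#' @examples
#' nb_exact_test(c(100, 100, 100), c(100, 100, 100), dispersion = 0.1)
#' nb_exact_test(c(5, 5, 5), c(2, 2, 1), dispersion = 0)
#' @export
nb_exact_test <- function(a, b, dispersion) {
  if (is.null(dim(a))) a <- matrix(as.numeric(a), nrow = 1)
  if (is.null(dim(b))) b <- matrix(as.numeric(b), nrow = 1)
  if (nrow(a) != nrow(b)) stop("groups must cover the same genes")
  if (ncol(a) < 2 || ncol(b) < 2) stop("need >= 2 replicates per group")
  if (length(dispersion) != 1 || dispersion < 0) {
    stop("dispersion must be a single nonnegative number")
  }
  sa <- rowSums(a)
  sb <- rowSums(b)
  log2fc <- log2((rowMeans(a) + 0.5) / (rowMeans(b) + 0.5))
  log2fc[sa + sb == 0] <- 0
  p <- vapply(seq_len(nrow(a)), function(i) {
    nb_cond_exact_p(sa[i], sa[i] + sb[i], ncol(a), ncol(b), dispersion)
  }, numeric(1))
  data.frame(log2fc = log2fc, pvalue = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, applied separately to each test family
#' (parental, allelic, trans) by the callers.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted values.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
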